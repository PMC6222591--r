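#' Filter configuration
#'
#' Bundles every threshold the pipeline applies: minimum Phred base quality
#' 20, minimum quality-adjusted depth 8, a coverage cap of 100 for mapping
#' (positions with coverage >100 sit in repeat-rich regions and are
#' uninformative), homozygosity at pooled frequency >= 0.99, and an
#' optional restriction to canonical EMS changes.
#'
#' @param min_base_quality Minimum Phred base quality (default 20;
#'   bases with quality >= 20 pass).
#' @param min_depth Minimum quality-adjusted depth (default 8; depth >= 8
#'   passes).
#' @param max_depth_for_mapping Coverage cap for mapping purpose (default
#'   100; depth > 100 is dropped, depth == 100 kept).
#' @param hom_threshold Homozygous calling frequency (default 0.99;
#'   freq >= 0.99 is homozygous).
#' @param ems_only If `TRUE`, candidate-purpose filtering keeps only
#'   canonical EMS SNVs (G>A, C>T).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_base_quality = 20, min_depth = 8,
                          max_depth_for_mapping = 100, hom_threshold = 0.99,
                          ems_only = FALSE) {
  stopifnot(hom_threshold > 0, hom_threshold <= 1, min_depth >= 1,
            max_depth_for_mapping > min_depth)
  structure(list(min_base_quality = min_base_quality, min_depth = min_depth,
                 max_depth_for_mapping = max_depth_for_mapping,
                 hom_threshold = hom_threshold, ems_only = isTRUE(ems_only)),
            class = "filter_config")
}

#' Canonical EMS change?
#'
#' EMS alkylates guanine, producing G:C -> A:T transitions; on the
#' reference plus strand these read as G>A or C>T, which jointly cover both
#' strands of the lesion. No strand flipping by gene orientation is done.
#'
#' @param ref,alt Allele strings (vectorized). Indels return `FALSE`.
#' @return Logical vector.
#' @export
is_canonical_ems <- function(ref, alt) {
  (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
}

#' Apply depth, homozygosity and EMS-spectrum filters
#'
#' Both purposes require quality-adjusted depth >= `min_depth`. Purpose
#' `"mapping"` additionally drops positions with depth >
#' `max_depth_for_mapping` (highly enriched, repeat-derived positions);
#' heterozygous records are retained, flagged by their `zygosity` column.
#' Purpose `"candidate"` keeps only homozygous records and, when
#' `cfg$ems_only`, only canonical EMS SNVs. Per-rule drop counts are
#' attached as `attr(x, "tally")` and always reconcile:
#' `tally["input"] == tally["output"] + sum(drops)`.
#'
#' @param vs A `variant_set` with frequencies computed.
#' @param cfg A [filter_config()].
#' @param purpose `"mapping"` or `"candidate"`.
#' @return Filtered `variant_set` with a `tally` attribute.
#' @export
apply_filters <- function(vs, cfg = filter_config(),
                          purpose = c("mapping", "candidate")) {
  purpose <- match.arg(purpose)
  stopifnot(inherits(cfg, "filter_config"))
  tally <- c(input = nrow(vs), dropped_min_depth = 0L,
             dropped_max_depth = 0L, dropped_not_homozygous = 0L,
             dropped_not_ems = 0L, output = 0L)

  keep <- vs$total_qdepth >= cfg$min_depth
  tally["dropped_min_depth"] <- sum(!keep)
  vs <- vs[keep, , drop = FALSE]

  if (purpose == "mapping") {
    keep <- vs$total_qdepth <= cfg$max_depth_for_mapping
    tally["dropped_max_depth"] <- sum(!keep)
    vs <- vs[keep, , drop = FALSE]
  } else {
    keep <- vs$zygosity == "homozygous"
    tally["dropped_not_homozygous"] <- sum(!keep)
    vs <- vs[keep, , drop = FALSE]
    if (cfg$ems_only) {
      keep <- !vs$is_indel & is_canonical_ems(vs$ref, vs$alt)
      tally["dropped_not_ems"] <- sum(!keep)
      vs <- vs[keep, , drop = FALSE]
    }
  }
  tally["output"] <- nrow(vs)
  out <- as_variant_set(vs)
  attr(out, "tally") <- tally
  out
}
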
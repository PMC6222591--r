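#' Intersect variant sets into a background panel
#'
#' Builds a background panel from the variant keys (chrom, pos, ref, alt)
#' present in every input set — the construction used to derive an
#' inbred-background SNP panel from several independently sequenced pools
#' sharing that background. Records with a different alt allele at the same
#' position are not "common".
#'
#' @param sets A list of two or more `variant_set`s.
#' @param label Label for the resulting panel.
#' @return A `site_panel` of the shared keys.
#' @export
intersect_common_variants <- function(sets, label = "common") {
  if (!is.list(sets) || length(sets) < 2)
    stop("need at least 2 variant sets to intersect")
  keys <- lapply(sets, variant_key)
  common <- Reduce(intersect, keys)
  first <- sets[[1]]
  hit <- first[variant_key(first) %in% common, , drop = FALSE]
  site_panel(chrom = hit$chrom, pos = hit$pos, ref = hit$ref, alt = hit$alt,
             label = label)
}

#' Subtract background panels from a variant set
#'
#' Removes every record whose key appears in any panel. The default
#' `"allele"` mode keys on (chrom, pos, ref, alt): an induced lesion at a
#' position that is polymorphic in a background panel for a *different*
#' allele is kept. `"position"` mode keys on (chrom, pos) only, for
#' conservative filtering. Per-panel removal counts (sequential, in panel
#' order) are attached as `attr(x, "tally")`.
#'
#' @param target A `variant_set`.
#' @param panels A list of `site_panel`s (or a single panel).
#' @param key_mode `"allele"` (default) or `"position"`.
#' @return The filtered `variant_set` with a `tally` attribute.
#' @export
subtract_panels <- function(target, panels, key_mode = c("allele", "position")) {
  key_mode <- match.arg(key_mode)
  if (inherits(panels, "site_panel")) panels <- list(panels)
  tally <- c(input = nrow(target))
  for (p in panels) {
    lab <- attr(p, "label")
    if (is.null(lab)) lab <- "panel"
    keep <- !(variant_key(target, key_mode) %in% variant_key(p, key_mode))
    tally[paste0("removed_", lab)] <- sum(!keep)
    target <- target[keep, , drop = FALSE]
  }
  tally["output"] <- nrow(target)
  out <- as_variant_set(target)
  attr(out, "tally") <- tally
  out
}
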
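#' Select indels suitable for fine-mapping markers
#'
#' Keeps indels inside the mapping interval whose length difference is at
#' least `min_indel_len` bp (a size difference resolvable on 3.5% agarose
#' gels once flanked by short PCR products) and, by default, homozygous in
#' the mutant pool so the marker separates the two parental haplotypes.
#'
#' @param vs A `variant_set` with `is_indel`/`indel_len` populated.
#' @param interval One-row interval (chrom, start, end, 1-based inclusive).
#' @param min_indel_len Minimum |indel length| in bp (default 15).
#' @param require_homozygous Require pool zygosity `"homozygous"`
#'   (default TRUE).
#' @return The qualifying subset, as a `variant_set`.
#' @export
select_indels <- function(vs, interval, min_indel_len = 15,
                          require_homozygous = TRUE) {
  keep <- vs$is_indel & abs(vs$indel_len) >= min_indel_len &
    vs$chrom == interval$chrom[1] &
    vs$pos >= interval$start[1] & vs$pos <= interval$end[1]
  if (require_homozygous) keep <- keep & vs$zygosity == "homozygous"
  as_variant_set(vs[keep, , drop = FALSE])
}

.gc_fraction <- function(seq) {
  n <- nchar(seq)
  if (n == 0) return(NA_real_)
  gc <- nchar(gsub("[^GCgc]", "", seq))
  gc / n
}

.has_homopolymer <- function(seq, max_run = 4) {
  grepl(sprintf("A{%d,}|C{%d,}|G{%d,}|T{%d,}", max_run + 1, max_run + 1,
                max_run + 1, max_run + 1), seq)
}

# Scan one flank for the first acceptable primer window. `side` is "left"
# (primer on the plus strand, 3' end toward the indel) or "right" (reverse
# strand). Distances are measured from the edge of the indel's reference
# footprint to the primer 3' end.
.scan_flank <- function(genome, chrom, edge, side, flank_min, flank_max,
                        primer_len, gc_range, max_homopolymer) {
  chrom_len <- if (methods::is(genome, "DNAStringSet"))
    length(genome[[chrom]]) else nchar(genome[[chrom]])
  for (gap in flank_min:flank_max) {
    for (plen in primer_len[1]:primer_len[2]) {
      if (side == "left") {
        end3 <- edge - gap
        w <- c(end3 - plen + 1, end3)
      } else {
        end3 <- edge + gap
        w <- c(end3, end3 + plen - 1)
      }
      if (w[1] < 1 || w[2] > chrom_len) next
      seq <- .get_seq(genome, chrom, w[1], w[2])
      if (side == "right") seq <- .revcomp(seq)
      gc <- .gc_fraction(seq)
      if (gc >= gc_range[1] && gc <= gc_range[2] &&
          !.has_homopolymer(seq, max_homopolymer)) {
        return(list(window = w, seq = seq))
      }
    }
  }
  NULL
}

#' Design flanking primer windows for an indel marker
#'
#' Picks, on each side of the indel, the first primer window whose 3' end
#' lies between `flank_min` and `flank_max` bp from the indel's reference
#' footprint, with GC fraction in `gc_range` and no homopolymer run longer
#' than `max_homopolymer` (GC fraction is a deliberate simplification of a
#' nearest-neighbour melting-temperature model). The expected PCR product
#' size difference between the two haplotypes always equals the indel
#' length.
#'
#' @param indel A one-row `variant_set` row with `is_indel = TRUE`
#'   (VCF-style left-anchored alleles).
#' @param genome Chromosome sequences (named list/character or
#'   `DNAStringSet`).
#' @param flank_min,flank_max Distance range (bp) from indel to primer 3'
#'   end (defaults 100 and 150).
#' @param primer_len Allowed primer length range, default `c(18, 24)`.
#' @param gc_range Allowed GC fraction range, default `c(0.40, 0.60)`.
#' @param max_homopolymer Longest allowed single-base run, default 4.
#' @return A one-row tibble (`indel_marker`) with the primer windows,
#'   sequences, expected wild-type/mutant product sizes and
#'   `expected_size_diff`, or `NULL` (with a message) when no window
#'   qualifies on one side.
#' @export
design_flanks <- function(indel, genome, flank_min = 100, flank_max = 150,
                          primer_len = c(18, 24), gc_range = c(0.40, 0.60),
                          max_homopolymer = 4) {
  stopifnot(nrow(indel) == 1, indel$is_indel)
  # Reference footprint of the left-anchored indel allele.
  span <- c(indel$pos, indel$pos + nchar(indel$ref) - 1)
  left <- .scan_flank(genome, indel$chrom, span[1], "left", flank_min,
                      flank_max, primer_len, gc_range, max_homopolymer)
  right <- .scan_flank(genome, indel$chrom, span[2], "right", flank_min,
                       flank_max, primer_len, gc_range, max_homopolymer)
  if (is.null(left) || is.null(right)) {
    message("no qualifying primer window for indel at ", indel$chrom, ":",
            format(indel$pos, scientific = FALSE))
    return(NULL)
  }
  wt_product <- right$window[2] - left$window[1] + 1
  mut_product <- wt_product + indel$indel_len
  tibble::tibble(
    chrom = indel$chrom, pos = indel$pos, ref = indel$ref, alt = indel$alt,
    indel_len = indel$indel_len,
    left_window_start = left$window[1], left_window_end = left$window[2],
    right_window_start = right$window[1], right_window_end = right$window[2],
    left_primer = left$seq, right_primer = right$seq,
    wt_product = wt_product, mut_product = mut_product,
    expected_size_diff = abs(indel$indel_len))
}

#' Design indel markers across a mapping interval
#'
#' [select_indels()] then [design_flanks()] for each qualifying indel.
#'
#' @inheritParams select_indels
#' @inheritParams design_flanks
#' @return A tibble of markers (possibly zero rows).
#' @export
design_markers <- function(vs, interval, genome, min_indel_len = 15,
                           flank_min = 100, flank_max = 150,
                           primer_len = c(18, 24), gc_range = c(0.40, 0.60),
                           max_homopolymer = 4,
                           require_homozygous = TRUE) {
  sel <- select_indels(vs, interval, min_indel_len, require_homozygous)
  out <- list()
  for (i in seq_len(nrow(sel))) {
    m <- design_flanks(sel[i, ], genome, flank_min, flank_max, primer_len,
                       gc_range, max_homopolymer)
    if (!is.null(m)) out[[length(out) + 1]] <- m
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), pos = numeric(),
                          ref = character(), alt = character(),
                          indel_len = integer(),
                          left_window_start = numeric(),
                          left_window_end = numeric(),
                          right_window_start = numeric(),
                          right_window_end = numeric(),
                          left_primer = character(),
                          right_primer = character(),
                          wt_product = numeric(), mut_product = numeric(),
                          expected_size_diff = integer()))
  }
  dplyr::bind_rows(out)
}
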
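#' Construct a variant set
#'
#' A variant set is the package's central container: a tibble with one row
#' per variant observation in a pool, keyed by (chrom, pos, ref, alt).
#' Positions are 1-based throughout (pileup/VCF convention); the only
#' 0-based coordinates this package ever emits are in BED exports.
#'
#' @param chrom Chromosome names (character).
#' @param pos 1-based positions (integer-valued).
#' @param ref,alt Reference and alternate allele strings. Indels are
#'   VCF-style left-anchored (shared leading base).
#' @param total_qdepth Number of bases passing the base-quality threshold.
#' @param alt_count Number of passing bases matching `alt`.
#' @param hom_threshold Pooled allele frequency at or above which a site is
#'   classed homozygous (default 0.99).
#'
#' @return A tibble of class `variant_set` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `total_qdepth`, `alt_count`, `freq`, `zygosity`,
#'   `is_indel`, `indel_len`.
#' @export
variant_set <- function(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        total_qdepth = integer(), alt_count = integer(),
                        hom_threshold = 0.99) {
  stopifnot(length(hom_threshold) == 1, hom_threshold > 0, hom_threshold <= 1)
  n <- max(length(chrom), length(pos), length(ref), length(alt),
           length(total_qdepth), length(alt_count), 0)
  recycle <- function(x, what) {
    if (length(x) == n) return(x)
    if (length(x) == 1) return(rep(x, n))
    stop("length of '", what, "' must be 1 or ", n)
  }
  chrom <- recycle(chrom, "chrom"); pos <- recycle(pos, "pos")
  ref <- recycle(ref, "ref"); alt <- recycle(alt, "alt")
  total_qdepth <- recycle(total_qdepth, "total_qdepth")
  alt_count <- recycle(alt_count, "alt_count")
  if (n > 0) {
    if (any(pos < 1)) stop("positions must be 1-based (>= 1)")
    if (any(alt_count > total_qdepth))
      stop("alt_count may not exceed total_qdepth")
    if (any(ref == alt)) stop("identity alleles (ref == alt) are not variants")
  }
  freq <- ifelse(total_qdepth > 0, alt_count / total_qdepth, NA_real_)
  indel_len <- nchar(alt) - nchar(ref)
  out <- tibble::tibble(
    chrom = as.character(chrom),
    pos = as.numeric(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    total_qdepth = as.integer(total_qdepth),
    alt_count = as.integer(alt_count),
    freq = freq,
    zygosity = ifelse(!is.na(freq) & freq >= hom_threshold,
                      "homozygous", "heterozygous"),
    is_indel = indel_len != 0L,
    indel_len = as.integer(indel_len)
  )
  as_variant_set(out)
}

#' Mark a data frame as a variant set
#'
#' Validates the required columns and prepends the `variant_set` class.
#'
#' @param x A data frame with at least the columns produced by
#'   [variant_set()].
#' @return `x` as a `variant_set` tibble.
#' @export
as_variant_set <- function(x) {
  req <- c("chrom", "pos", "ref", "alt", "total_qdepth", "alt_count",
           "freq", "zygosity", "is_indel", "indel_len")
  missing <- setdiff(req, names(x))
  if (length(missing) > 0)
    stop("not a variant set; missing columns: ", paste(missing, collapse = ", "))
  x <- tibble::as_tibble(x)
  class(x) <- unique(c("variant_set", class(x)))
  x
}

#' Variant keys
#'
#' @param x A variant set or site panel (anything with chrom/pos/ref/alt).
#' @param mode `"allele"` keys on (chrom, pos, ref, alt); `"position"` keys
#'   on (chrom, pos) only.
#' @return Character vector of keys.
#' @export
variant_key <- function(x, mode = c("allele", "position")) {
  mode <- match.arg(mode)
  if (mode == "allele") paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  else paste(x$chrom, x$pos, sep = ":")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("<variant_set> ", nrow(x), " variants (",
      sum(x$zygosity == "homozygous"), " homozygous, ",
      sum(x$is_indel), " indels)\n", sep = "")
  NextMethod()
}

#' Construct a background site panel
#'
#' A site panel is a deduplicated set of (chrom, pos, ref, alt) keys used
#' for background subtraction, e.g. a HapMap panel, a parental or
#' wild-type-sibling variant list, or an inbred-background panel.
#'
#' @param chrom,pos,ref,alt Site coordinates and alleles (1-based).
#' @param label Panel name, e.g. `"hapmap"`, `"parental"`.
#' @return A tibble of class `site_panel` with attribute `label`.
#' @export
site_panel <- function(chrom = character(), pos = integer(),
                       ref = character(), alt = character(),
                       label = "panel") {
  if (length(pos) > 0 && any(pos < 1)) stop("positions must be 1-based (>= 1)")
  out <- tibble::tibble(chrom = as.character(chrom), pos = as.numeric(pos),
                        ref = toupper(ref), alt = toupper(alt))
  out <- dplyr::distinct(out)
  attr(out, "label") <- label
  class(out) <- unique(c("site_panel", class(out)))
  out
}

#' @export
print.site_panel <- function(x, ...) {
  cat("<site_panel '", attr(x, "label"), "'> ", nrow(x), " sites\n", sep = "")
  NextMethod()
}
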
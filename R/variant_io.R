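#' Read a samtools-style pileup file
#'
#' Parses 6-column pileup text (chrom, 1-based pos, reference base, depth,
#' read bases, base qualities in Phred+33). Base strings are not tokenized
#' here; see [tokenize_pileup_bases()] and [pileup_variants()].
#'
#' @param path Path to a pileup file.
#' @return A tibble with columns `chrom`, `pos`, `ref_base`, `depth`,
#'   `bases`, `quals`.
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) stop("pileup file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), pos = numeric(),
                          ref_base = character(), depth = integer(),
                          bases = character(), quals = character()))
  }
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(vapply(fields, length, 1L) != 6L)
  if (length(bad) > 0)
    stop("malformed pileup line ", bad[1], ": expected 6 columns")
  m <- matrix(unlist(fields), ncol = 6, byrow = TRUE)
  pos <- suppressWarnings(as.numeric(m[, 2]))
  depth <- suppressWarnings(as.integer(m[, 4]))
  if (anyNA(pos) || anyNA(depth)) {
    bad <- which(is.na(pos) | is.na(depth))[1]
    stop("malformed pileup line ", bad, ": non-numeric pos or depth")
  }
  ref <- toupper(m[, 3])
  if (!all(ref %in% c(.BASES, "N")))
    stop("malformed pileup line ", which(!ref %in% c(.BASES, "N"))[1],
         ": reference base must be one of A,C,G,T,N")
  tibble::tibble(chrom = m[, 1], pos = pos, ref_base = ref,
                 depth = depth, bases = m[, 5], quals = m[, 6])
}

#' Tokenize a pileup base string
#'
#' Applies the samtools pileup grammar: `^X` (read start; the following
#' character is a mapping quality, not a base), `$` (read end), `+N<seq>` /
#' `-N<seq>` (insertion/deletion attached to the preceding base, no quality
#' of its own), `*` (deletion placeholder, consumes a quality). Every
#' scorable symbol consumes exactly one character of the quality string.
#'
#' @param bases A single pileup base string.
#' @return A list with `symbols` (character vector of scorable symbols, one
#'   per base quality) and `indel_lens` (signed lengths of attached indels,
#'   `+` for insertions).
#' @export
tokenize_pileup_bases <- function(bases) {
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  n <- length(chars)
  symbols <- character(n)  # over-allocate, trim later
  ns <- 0L
  indel_lens <- integer(0)
  scorable <- c(".", ",", "*", ">", "<",
                .BASES, tolower(.BASES), "N", "n")
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      if (i + 1L > n) stop("truncated '^' read-start marker in pileup bases")
      i <- i + 2L
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
      if (j == i + 1L) stop("indel marker without length in pileup bases")
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      if (j + len - 1L > n) stop("truncated indel sequence in pileup bases")
      indel_lens <- c(indel_lens, if (ch == "+") len else -len)
      i <- j + len
    } else if (ch %in% scorable) {
      ns <- ns + 1L
      symbols[ns] <- ch
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in pileup bases")
    }
  }
  list(symbols = symbols[seq_len(ns)], indel_lens = indel_lens)
}

#' Quality-adjusted allele frequency for one pileup position
#'
#' Counts only bases whose Phred quality is at or above `min_base_quality`.
#' The alternate allele is the most frequent non-reference base among
#' passing bases (ties broken A < C < G < T); the frequency is the number
#' of reads differing from the reference divided by the quality-adjusted
#' total read count. Deletion placeholders `*`, reference skips `<`/`>` and
#' `N` bases carry no usable base call and are excluded from both counts.
#'
#' @param rec A single pileup record: a list or one-row data frame with
#'   `chrom`, `pos`, `ref_base`, `bases`, `quals`.
#' @param min_base_quality Minimum Phred base quality (default 20).
#' @param hom_threshold Frequency at or above which the call is homozygous.
#' @return A one-row `variant_set`, or `NULL` for non-variant positions or
#'   positions with no passing bases.
#' @export
compute_allele_frequency <- function(rec, min_base_quality = 20,
                                     hom_threshold = 0.99) {
  tok <- tokenize_pileup_bases(rec$bases)
  q <- utf8ToInt(rec$quals) - 33L
  if (length(tok$symbols) != length(q))
    stop("pileup bases/quals length mismatch at ", rec$chrom, ":", rec$pos,
         " (", length(tok$symbols), " scorable symbols vs ",
         length(q), " qualities)")
  sym <- tok$symbols[q >= min_base_quality]
  sym <- toupper(sym)
  sym[sym %in% c(".", ",")] <- rec$ref_base
  counted <- sym[sym %in% .BASES]
  total_qdepth <- length(counted)
  if (total_qdepth == 0) return(NULL)
  non_ref <- counted[counted != rec$ref_base]
  if (length(non_ref) == 0) return(NULL)  # non-variant position
  tab <- table(factor(non_ref, levels = .BASES))
  alt <- .BASES[which.max(tab)]  # which.max takes the first max: A<C<G<T
  variant_set(chrom = rec$chrom, pos = rec$pos, ref = rec$ref_base,
              alt = alt, total_qdepth = total_qdepth,
              alt_count = as.integer(max(tab)),
              hom_threshold = hom_threshold)
}

#' Call SNVs from a parsed pileup
#'
#' Applies [compute_allele_frequency()] to every position of a pileup
#' tibble and binds the resulting variant records. Non-variant positions
#' are dropped. Indel calling is left to the VCF path ([read_vcf()]);
#' attached pileup indels only affect tokenization.
#'
#' @inheritParams compute_allele_frequency
#' @param pileup Tibble from [read_pileup()].
#' @return A `variant_set`.
#' @export
pileup_variants <- function(pileup, min_base_quality = 20,
                            hom_threshold = 0.99) {
  recs <- vector("list", nrow(pileup))
  for (i in seq_len(nrow(pileup))) {
    recs[[i]] <- compute_allele_frequency(
      list(chrom = pileup$chrom[i], pos = pileup$pos[i],
           ref_base = pileup$ref_base[i], bases = pileup$bases[i],
           quals = pileup$quals[i]),
      min_base_quality = min_base_quality, hom_threshold = hom_threshold)
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (length(recs) == 0) return(variant_set(hom_threshold = hom_threshold))
  as_variant_set(dplyr::bind_rows(recs))
}

#' Read a VCF file into a variant set
#'
#' Accepts VCF 4.x with per-sample depth information in any of the common
#' shapes: `AD` with ref+alt depths, Varscan-style `RD`/`AD` pairs, or a
#' Varscan `FREQ` percentage with `DP`. Multiallelic records are split into
#' one record per ALT allele. When allele depths and `FREQ` disagree,
#' allele depths win. Records with no usable depth information are skipped
#' with a warning; the number skipped is available as `attr(x, "n_skipped")`.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @param sample Sample column to use (index, default 1).
#' @param hom_threshold Homozygosity threshold applied to the computed
#'   frequency (default 0.99).
#' @return A `variant_set`.
#' @export
read_vcf <- function(path, sample = 1, hom_threshold = 0.99) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  empty <- variant_set(hom_threshold = hom_threshold)
  if (n == 0) return(empty)
  has_gt <- ncol(v@gt) >= sample + 1
  get_fmt <- function(field) {
    if (!has_gt) return(rep(NA_character_, n))
    m <- tryCatch(vcfR::extract.gt(v, element = field, as.numeric = FALSE),
                  error = function(e) NULL)
    if (is.null(m)) rep(NA_character_, n) else as.character(m[, sample])
  }
  ad <- get_fmt("AD")
  rd <- get_fmt("RD")
  dp <- suppressWarnings(as.numeric(get_fmt("DP")))
  freq_s <- get_fmt("FREQ")
  out <- list()
  n_skipped <- 0L
  for (i in seq_len(n)) {
    ref <- toupper(fix[i, "REF"])
    alts <- toupper(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
    alts <- alts[!is.na(alts) & alts != "." & alts != ref]
    if (length(alts) == 0) next
    ad_i <- suppressWarnings(as.numeric(strsplit(
      ifelse(is.na(ad[i]), "", ad[i]), ",", fixed = TRUE)[[1]]))
    rd_i <- suppressWarnings(as.numeric(rd[i]))
    for (k in seq_along(alts)) {
      alt_count <- NA_real_
      total <- NA_real_
      if (length(ad_i) >= length(alts) + 1 && !anyNA(ad_i)) {
        # AD = ref,alt1,alt2,... depths
        alt_count <- ad_i[k + 1]
        total <- sum(ad_i)
      } else if (length(ad_i) == length(alts) && !anyNA(ad_i) &&
                 !is.na(rd_i)) {
        # Varscan shape: RD = ref depth, AD = alt depth(s)
        alt_count <- ad_i[k]
        total <- rd_i + sum(ad_i)
      } else if (!is.na(freq_s[i]) && !is.na(dp[i])) {
        f <- suppressWarnings(as.numeric(sub("%", "", freq_s[i]))) / 100
        if (!is.na(f)) {
          total <- dp[i]
          alt_count <- round(f * total)
        }
      }
      if (is.na(alt_count) || is.na(total) || total <= 0) {
        n_skipped <- n_skipped + 1L
        next
      }
      out[[length(out) + 1L]] <- variant_set(
        chrom = fix[i, "CHROM"], pos = as.numeric(fix[i, "POS"]),
        ref = ref, alt = alts[k],
        total_qdepth = as.integer(round(total)),
        alt_count = as.integer(round(min(alt_count, total))),
        hom_threshold = hom_threshold)
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (n_skipped > 0)
    warning(n_skipped, " VCF record(s) skipped: no usable depth information")
  res <- if (length(out) == 0) empty else as_variant_set(dplyr::bind_rows(out))
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Read a background site panel from TSV
#'
#' Expects columns chrom, pos, ref, alt (tab- or space-separated; a header
#' line is detected and skipped). Rows are deduplicated.
#'
#' @param path Path to the TSV.
#' @param label Panel label.
#' @return A `site_panel`.
#' @export
read_site_panel <- function(path, label = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(site_panel(label = label))
  fields <- strsplit(lines, "[ \t]+")
  if (any(vapply(fields, length, 1L) < 4))
    stop("site panel rows need 4 columns (chrom, pos, ref, alt)")
  if (tolower(fields[[1]][2]) == "pos") fields <- fields[-1]  # header line
  if (length(fields) == 0) return(site_panel(label = label))
  m <- t(vapply(fields, function(f) f[1:4], character(4)))
  pos <- suppressWarnings(as.numeric(m[, 2]))
  if (anyNA(pos)) stop("non-integer position in site panel: ",
                       m[which(is.na(pos))[1], 2])
  site_panel(chrom = m[, 1], pos = pos, ref = m[, 3], alt = m[, 4],
             label = label)
}

# TSV writer that keeps genomic coordinates out of scientific notation.
.write_tsv <- function(df, path) {
  op <- options(scipen = 15)
  on.exit(options(op))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read variant sets as TSV
#'
#' Plain TSV with the `variant_set` columns; `read_variants_tsv()` is the
#' inverse of `write_variants_tsv()`.
#'
#' @param vs A `variant_set`.
#' @param path Output path.
#' @return `write_variants_tsv()` returns `path` invisibly;
#'   `read_variants_tsv()` returns a `variant_set`.
#' @export
write_variants_tsv <- function(vs, path) {
  .write_tsv(as.data.frame(vs), path)
}

#' @rdname write_variants_tsv
#' @export
read_variants_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c(chrom = "character", ref = "character",
                                  alt = "character", zygosity = "character"))
  as_variant_set(df)
}

#' Write a site panel as TSV
#'
#' @param panel A `site_panel`.
#' @param path Output path.
#' @export
write_site_panel <- function(panel, path) {
  .write_tsv(as.data.frame(panel)[, c("chrom", "pos", "ref", "alt")], path)
}

#' Minimal VCF 4.2 writer for a pooled sample
#'
#' Writes one record per variant with GT:DP:AD (AD = ref,alt depths), the
#' shape [read_vcf()] reads back.
#'
#' @param vs A `variant_set`.
#' @param path Output path.
#' @param sample_name Sample column name.
#' @export
write_vcf <- function(vs, path, sample_name = "pool") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=bsamap",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")), con)
  if (nrow(vs) > 0) {
    gt <- ifelse(vs$zygosity == "homozygous", "1/1", "0/1")
    smp <- sprintf("%s:%d:%d,%d", gt, vs$total_qdepth,
                   vs$total_qdepth - vs$alt_count, vs$alt_count)
    writeLines(paste(vs$chrom, format(vs$pos, scientific = FALSE,
                                      trim = TRUE),
                     ".", vs$ref, vs$alt, ".", "PASS", ".",
                     "GT:DP:AD", smp, sep = "\t"), con)
  }
  invisible(path)
}

#' Export an interval as BED
#'
#' The single place the package emits 0-based half-open coordinates.
#'
#' @param interval A one-row interval tibble (chrom, start, end, 1-based
#'   inclusive).
#' @param path Output path.
#' @export
write_interval_bed <- function(interval, path) {
  writeLines(paste(interval$chrom,
                   format(interval$start - 1, scientific = FALSE, trim = TRUE),
                   format(interval$end, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}
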
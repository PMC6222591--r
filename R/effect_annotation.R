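#' Construct a gene model
#'
#' Minimal transcript model for consequence calling: ordered exons and CDS
#' segments, 1-based inclusive coordinates. CDS segments must lie inside
#' exons; total CDS length should be divisible by 3 for complete models
#' (a warning is emitted otherwise).
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start`, `end`.
#' @param cds Data frame with columns `start`, `end` (defaults to `exons`,
#'   i.e. a fully coding transcript).
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = exons,
                       transcript_id = paste0(gene_id, "_T001")) {
  stopifnot(strand %in% c("+", "-"),
            all(c("start", "end") %in% names(exons)),
            all(c("start", "end") %in% names(cds)))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
  if (any(exons$start > exons$end) || any(cds$start > cds$end))
    stop("segment start > end in gene model ", gene_id)
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("overlapping exons in gene model ", gene_id)
  cds_len <- sum(cds$end - cds$start + 1)
  if (cds_len %% 3 != 0)
    warning("CDS length of ", transcript_id, " not divisible by 3")
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds,
                 span = c(min(exons$start), max(exons$end))),
            class = "gene_model")
}

#' Read gene models from a GFF3 file
#'
#' Builds one [gene_model()] per mRNA feature from its child exon and CDS
#' features. Gene identifiers come from the mRNA's Parent attribute (or its
#' own ID when orphaned).
#'
#' @param path Path to a GFF3 file.
#' @return A list of `gene_model`s.
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(g)
  df$type <- as.character(df$type)
  parent_of <- function(row) {
    p <- df$Parent[[row]]
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }
  mrna_rows <- which(df$type %in% c("mRNA", "transcript"))
  models <- list()
  for (i in mrna_rows) {
    tid <- df$ID[i]
    gid <- parent_of(i)
    if (is.na(gid)) gid <- tid
    kids <- which(vapply(seq_len(nrow(df)), function(r) {
      p <- df$Parent[[r]]
      length(p) > 0 && tid %in% as.character(p)
    }, TRUE))
    ex <- df[kids[df$type[kids] == "exon"], , drop = FALSE]
    cd <- df[kids[df$type[kids] == "CDS"], , drop = FALSE]
    if (nrow(ex) == 0 && nrow(cd) == 0) next
    if (nrow(ex) == 0) ex <- cd
    if (nrow(cd) == 0) cd <- ex
    models[[length(models) + 1]] <- gene_model(
      gene_id = gid, transcript_id = tid, chrom = as.character(df$seqnames[i]),
      strand = as.character(df$strand[i]),
      exons = ex[, c("start", "end")], cds = cd[, c("start", "end")])
  }
  models
}

.comp <- function(x) chartr("ACGT", "TGCA", x)
.revcomp <- function(x) .comp(paste(rev(strsplit(x, "")[[1]]), collapse = ""))

.get_seq <- function(genome, chrom, start, end) {
  if (methods::is(genome, "DNAStringSet")) {
    as.character(Biostrings::subseq(genome[[chrom]], start, end))
  } else {
    substr(genome[[chrom]], start, end)
  }
}

# Spliced CDS sequence in translation order, plus a map from genomic
# position to 1-based CDS coordinate.
.spliced_cds <- function(model, genome) {
  segs <- model$cds
  seq_plus <- paste(vapply(seq_len(nrow(segs)), function(i)
    .get_seq(genome, model$chrom, segs$start[i], segs$end[i]), ""),
    collapse = "")
  list(seq = if (model$strand == "+") seq_plus else .revcomp(seq_plus),
       len = nchar(seq_plus))
}

.cds_position <- function(model, pos) {
  segs <- model$cds
  off <- 0L
  for (i in seq_len(nrow(segs))) {
    if (pos >= segs$start[i] && pos <= segs$end[i]) {
      plus_off <- off + (pos - segs$start[i] + 1L)
      total <- sum(segs$end - segs$start + 1L)
      return(if (model$strand == "+") plus_off else total - plus_off + 1L)
    }
    off <- off + (segs$end[i] - segs$start[i] + 1L)
  }
  NA_integer_
}

# Splice windows: first/last 2 intronic bases of each intron, donor at the
# 5' (transcription-direction) end of the intron.
.splice_sites <- function(model) {
  ex <- model$exons
  if (nrow(ex) < 2) return(list(donor = numeric(0), acceptor = numeric(0)))
  donors <- c(); acceptors <- c()
  for (i in seq_len(nrow(ex) - 1)) {
    istart <- ex$end[i] + 1
    iend <- ex$start[i + 1] - 1
    if (iend < istart) next
    left <- istart:min(istart + 1, iend)
    right <- max(iend - 1, istart):iend
    if (model$strand == "+") {
      donors <- c(donors, left); acceptors <- c(acceptors, right)
    } else {
      donors <- c(donors, right); acceptors <- c(acceptors, left)
    }
  }
  list(donor = donors, acceptor = acceptors)
}

.SEVERITY <- c(intergenic = "NONE", intronic = "NONE", utr = "NONE",
               synonymous = "LOW", missense = "MODERATE",
               stop_gained = "HIGH", stop_lost = "HIGH", start_lost = "HIGH",
               splice_donor = "HIGH", splice_acceptor = "HIGH",
               reference_mismatch = "NONE")

.call_row <- function(v, model, consequence, protein_change = NA_character_) {
  tibble::tibble(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                 gene_id = if (is.null(model)) NA_character_ else model$gene_id,
                 transcript_id = if (is.null(model)) NA_character_
                                 else model$transcript_id,
                 consequence = consequence,
                 severity = unname(.SEVERITY[consequence]),
                 protein_change = protein_change)
}

.annotate_one <- function(v, model, genome) {
  if (v$chrom != model$chrom || v$pos < model$span[1] ||
      v$pos > model$span[2]) return(NULL)
  ref_gen <- .get_seq(genome, v$chrom, v$pos, v$pos)
  if (ref_gen != v$ref) {
    warning("reference mismatch at ", v$chrom, ":", v$pos, ": variant ref ",
            v$ref, " vs genome ", ref_gen)
    return(.call_row(v, model, "reference_mismatch"))
  }
  ss <- .splice_sites(model)
  if (v$pos %in% ss$donor) return(.call_row(v, model, "splice_donor"))
  if (v$pos %in% ss$acceptor) return(.call_row(v, model, "splice_acceptor"))

  cds_pos <- .cds_position(model, v$pos)
  if (!is.na(cds_pos)) {
    cds <- .spliced_cds(model, genome)
    alt_tx <- if (model$strand == "+") v$alt else .comp(v$alt)
    codon_index <- ceiling(cds_pos / 3)
    cstart <- (codon_index - 1) * 3 + 1
    ref_codon <- substr(cds$seq, cstart, cstart + 2)
    if (nchar(ref_codon) < 3) return(.call_row(v, model, "utr"))  # incomplete model
    alt_codon <- ref_codon
    substr(alt_codon, cds_pos - cstart + 1, cds_pos - cstart + 1) <- alt_tx
    code <- Biostrings::GENETIC_CODE
    ref_aa <- unname(code[ref_codon])
    alt_aa <- unname(code[alt_codon])
    pc <- paste0(ref_aa, codon_index, alt_aa)
    cons <-
      if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*") "stop_gained"
      else if (ref_aa == "*") "stop_lost"
      else if (codon_index == 1 && ref_aa == "M") "start_lost"
      else "missense"
    return(.call_row(v, model, cons, pc))
  }
  in_exon <- any(v$pos >= model$exons$start & v$pos <= model$exons$end)
  .call_row(v, model, if (in_exon) "utr" else "intronic")
}

#' Predict variant consequences against gene models
#'
#' Classifies each SNV against every overlapping transcript: coding changes
#' are computed by substituting the alternate base into the spliced CDS
#' (reverse-complemented for minus-strand models) and translating both
#' codons with the standard genetic code; the 2 intronic bases flanking
#' each exon are splice donor/acceptor sites. Severity tiers follow the
#' usual triage: nonsense and splice-site changes are HIGH (highly
#' deleterious), missense MODERATE, synonymous LOW, non-genic NONE.
#' Variants overlapping no model get a single intergenic call. Indels are
#' not consequence-called (they are handled by marker design); they are
#' skipped with a message.
#'
#' @param vs A `variant_set` of SNVs.
#' @param models A list of [gene_model()]s.
#' @param genome Named list/character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @return A tibble of consequence calls: `chrom`, `pos`, `ref`, `alt`,
#'   `gene_id`, `transcript_id`, `consequence`, `severity`,
#'   `protein_change` (present iff coding).
#' @export
annotate_variants <- function(vs, models, genome) {
  if (inherits(models, "gene_model")) models <- list(models)
  snv <- vs[!vs$is_indel, , drop = FALSE]
  if (nrow(snv) < nrow(vs))
    message(nrow(vs) - nrow(snv), " indel(s) skipped by the consequence caller")
  calls <- list()
  for (i in seq_len(nrow(snv))) {
    v <- snv[i, ]
    hit <- FALSE
    for (m in models) {
      row <- .annotate_one(v, m, genome)
      if (!is.null(row)) {
        hit <- TRUE
        calls[[length(calls) + 1]] <- row
      }
    }
    if (!hit) calls[[length(calls) + 1]] <- .call_row(v, NULL, "intergenic")
  }
  if (length(calls) == 0) return(.call_row(vs[0, ], NULL, character(0)))
  dplyr::bind_rows(calls)
}

#' Rank candidate lesions within the mapping interval
#'
#' Restricts consequence calls to the interval and ranks them by severity
#' (HIGH > MODERATE > LOW > NONE), then position. The `call` column is the
#' protein change for coding variants and the consequence class otherwise.
#'
#' @param calls Output of [annotate_variants()].
#' @param interval One-row interval (chrom, start, end, 1-based inclusive),
#'   e.g. the primary row of [call_interval()].
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `gene_id`,
#'   `effect` (severity tier) and `call`.
#' @export
triage_candidates <- function(calls, interval) {
  keep <- calls$chrom == interval$chrom[1] &
    calls$pos >= interval$start[1] & calls$pos <= interval$end[1]
  x <- calls[keep, , drop = FALSE]
  sev <- factor(x$severity, levels = c("HIGH", "MODERATE", "LOW", "NONE"))
  x <- x[order(sev, x$pos), , drop = FALSE]
  tibble::tibble(chrom = x$chrom, pos = x$pos, ref = x$ref, alt = x$alt,
                 gene_id = x$gene_id, effect = x$severity,
                 call = ifelse(is.na(x$protein_change), x$consequence,
                               x$protein_change))
}
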
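# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Build a pileup line from explicit reads: `calls` is a character vector of
# scorable symbols, `quals` an integer vector of Phred scores.
pileup_line <- function(chrom, pos, ref, calls, quals) {
  stopifnot(length(calls) == length(quals))
  paste(chrom, pos, ref, length(calls), paste(calls, collapse = ""),
        intToUtf8(quals + 33L), sep = "\t")
}

write_pileup_fixture <- function(lines) {
  path <- tempfile(fileext = ".pileup")
  writeLines(lines, path)
  path
}

# A pileup record list as compute_allele_frequency() expects.
pileup_rec <- function(bases, quals, ref = "G", chrom = "chr1", pos = 100) {
  list(chrom = chrom, pos = pos, ref_base = ref, bases = bases, quals = quals)
}

# Random pileup line generator for the tokenizer/frequency property tests.
# Returns the raw strings plus the ground-truth list of (symbol, qual)
# pairs used to build them.
random_pileup_line <- function() {
  depth <- sample(1:20, 1)
  symbols <- sample(c(".", ",", "A", "C", "G", "T", "a", "c", "g", "t", "*"),
                    depth, replace = TRUE,
                    prob = c(10, 10, rep(1.5, 8), 0.8))
  quals <- sample(0:40, depth, replace = TRUE)
  parts <- character(depth)
  for (i in seq_len(depth)) {
    s <- symbols[i]
    if (runif(1) < 0.15) s <- paste0("^", intToUtf8(sample(33:73, 1)), s)
    if (runif(1) < 0.1) {
      len <- sample(1:6, 1)
      s <- paste0(s, sample(c("+", "-"), 1), len,
                  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""))
    }
    if (runif(1) < 0.1) s <- paste0(s, "$")
    parts[i] <- s
  }
  list(bases = paste(parts, collapse = ""),
       quals = intToUtf8(quals + 33L),
       symbols = symbols, phred = quals)
}

# Independent brute-force frequency counter: strips grammar tokens with
# regexes (a different mechanism from the package's character-walk
# tokenizer) and counts bases by hand.
brute_force_frequency <- function(bases, quals, ref, min_bq = 20) {
  b <- gsub("\\^.", "", bases)
  b <- gsub("\\$", "", b, fixed = FALSE)
  repeat {
    m <- regexpr("[+-][0-9]+", b)
    if (m == -1) break
    len <- as.integer(substr(b, m + 1, m + attr(m, "match.length") - 1))
    b <- paste0(substr(b, 1, m - 1),
                substr(b, m + attr(m, "match.length") + len, nchar(b)))
  }
  syms <- strsplit(b, "")[[1]]
  q <- utf8ToInt(quals) - 33L
  stopifnot(length(syms) == length(q))
  syms <- toupper(syms[q >= min_bq])
  syms[syms %in% c(".", ",")] <- ref
  syms <- syms[syms %in% c("A", "C", "G", "T")]
  counts <- table(factor(syms[syms != ref], levels = c("A", "C", "G", "T")))
  list(total = length(syms),
       alt = if (sum(counts) == 0) NA_character_
             else c("A", "C", "G", "T")[which.max(counts)],
       alt_count = if (sum(counts) == 0) 0L else as.integer(max(counts)))
}

# Variant-set builder for filter/set-algebra tests.
vs_fixture <- function(chrom, pos, ref, alt, qdepth, alt_count,
                       hom_threshold = 0.99) {
  variant_set(chrom = chrom, pos = pos, ref = ref, alt = alt,
              total_qdepth = qdepth, alt_count = alt_count,
              hom_threshold = hom_threshold)
}

# A 4-periodic sequence: GC fraction ~0.5 in any window, no homopolymers.
periodic_seq <- function(n) {
  paste(rep(c("A", "C", "G", "T"), length.out = n), collapse = "")
}

# Designed gene fixture for the consequence caller. Plus-strand gene on a
# 600 bp chromosome: exon1 = CDS 101-160, intron 161-220 (GT...AG), exon2 =
# CDS 221-280. CDS starts ATG CTT TGG ... and ends with a TAA stop.
gene_fixture <- function() {
  n <- 600
  seq <- strsplit(periodic_seq(n), "")[[1]]
  mid <- rep(c("GAT", "AAG", "CGA", "TTC", "GGA", "CAT", "TAC", "GTC",
               "ACG", "GAA", "CTG", "TGC", "AGT", "CCA", "GTT", "ACC"),
             length.out = 36)  # no stop codons
  cds <- paste(c("ATG", "CTT", "TGG", mid, "TAA"), collapse = "")  # 40 codons
  seq[101:160] <- strsplit(substr(cds, 1, 60), "")[[1]]
  seq[221:280] <- strsplit(substr(cds, 61, 120), "")[[1]]
  seq[161:162] <- c("G", "T")  # splice donor
  seq[219:220] <- c("A", "G")  # splice acceptor
  genome <- list(chrT = paste(seq, collapse = ""))
  model <- gene_model("GeneA", "chrT", "+",
                      exons = data.frame(start = c(101, 221),
                                         end = c(160, 280)))
  list(genome = genome, model = model, cds = cds)
}

# Mirror a gene fixture onto the minus strand: reverse-complement the
# chromosome and flip all coordinates, so annotating the mirrored gene must
# give identical consequences and protein changes.
mirror_fixture <- function(fx) {
  n <- nchar(fx$genome$chrT)
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(fx$genome$chrT, "")[[1]]), collapse = ""))
  flip <- function(x) n - x + 1
  ex <- fx$model$exons
  model <- gene_model("GeneA_rc", "chrT", "-",
                      exons = data.frame(start = flip(ex$end),
                                         end = flip(ex$start)))
  list(genome = list(chrT = rc), model = model, flip = flip)
}

# One-row interval for triage/marker tests.
interval_fixture <- function(chrom, start, end) {
  tibble::tibble(chrom = chrom, start = start, end = end)
}
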
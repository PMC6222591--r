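#' Simulator configuration
#'
#' Defines the synthetic study conditions: a pooled mapping population in
#' one of two designs. `bsa_outcross` emulates an outcross of an EMS mutant
#' to a polymorphic reference background and selection of phenotypic
#' mutants in the F2, so both induced EMS SNPs and dense natural
#' parent-vs-reference SNPs segregate. `mutmap_backcross` emulates a
#' backcross to the unmutagenized parent followed by selfing, so only the
#' induced EMS SNPs (plus any residual heterozygosity of the parental
#' stock) segregate.
#'
#' Defaults describe a deliberately scaled-down diploid genome: two
#' 100 Mbp chromosomes of 1 Morgan each, causal lesion mid-chromosome 1,
#' 50 pooled mutants sequenced to 25x, 1,000 EMS SNPs (~5 per Mbp), 98%
#' canonical G:C->A:T EMS changes, 0.5% base error, and 98% of bases at
#' Phred >= 20. In outcross mode 20,000 natural background SNPs segregate;
#' in mutmap mode 500 residual-heterozygosity SNPs emulate a heterozygous
#' parental stock.
#'
#' @param genome Tibble with columns `chrom`, `length` (bp) and `morgans`
#'   (genetic length).
#' @param mode `"bsa_outcross"` or `"mutmap_backcross"`.
#' @param causal_chrom,causal_pos Location of the causal lesion.
#' @param n_mutants Number of pooled homozygous mutants.
#' @param n_ems_snps Number of induced EMS SNPs genome-wide.
#' @param ems_fraction_canonical Fraction of EMS SNPs that are canonical
#'   G>A / C>T changes.
#' @param n_background_snps Natural stock-vs-reference SNPs. In outcross
#'   mode they segregate on the mutant-parent haplotype; in mutmap mode
#'   they are fixed differences homozygous in every pool (both cross
#'   parents share the background), the noise the subtraction step exists
#'   to remove.
#' @param n_residual_het_snps Residual-heterozygosity SNPs (mutmap mode
#'   only).
#' @param mean_coverage Mean sequencing depth per site (Poisson).
#' @param base_error_rate Per-read probability of a miscalled base.
#' @param hi_quality_fraction Fraction of bases with Phred quality >= 20.
#' @param hom_threshold Homozygosity threshold used downstream.
#' @param marker_positions Optional tibble (`chrom`, `pos`) of extra
#'   neutral markers carried on the mutagenized haplotype, for calibration
#'   against the expected pooled-frequency law.
#' @param seed Integer seed; identical config + seed gives identical
#'   output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome = tibble::tibble(chrom = c("chr1", "chr2"),
                                               length = c(100e6, 100e6),
                                               morgans = c(1, 1)),
                       mode = c("bsa_outcross", "mutmap_backcross"),
                       causal_chrom = "chr1", causal_pos = 50e6,
                       n_mutants = 50, n_ems_snps = 1000,
                       ems_fraction_canonical = 0.98,
                       n_background_snps = 20000,
                       n_residual_het_snps = 500,
                       mean_coverage = 25, base_error_rate = 0.005,
                       hi_quality_fraction = 0.98, hom_threshold = 0.99,
                       marker_positions = NULL, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(all(c("chrom", "length", "morgans") %in% names(genome)),
            causal_chrom %in% genome$chrom,
            mean_coverage > 0, n_mutants >= 1,
            ems_fraction_canonical >= 0, ems_fraction_canonical <= 1,
            base_error_rate >= 0, base_error_rate <= 1,
            hi_quality_fraction >= 0, hi_quality_fraction <= 1)
  if (causal_pos > genome$length[genome$chrom == causal_chrom])
    stop("causal position beyond its chromosome length")
  structure(list(genome = genome, mode = mode, causal_chrom = causal_chrom,
                 causal_pos = causal_pos, n_mutants = n_mutants,
                 n_ems_snps = n_ems_snps,
                 ems_fraction_canonical = ems_fraction_canonical,
                 n_background_snps = n_background_snps,
                 n_residual_het_snps = n_residual_het_snps,
                 mean_coverage = mean_coverage,
                 base_error_rate = base_error_rate,
                 hi_quality_fraction = hi_quality_fraction,
                 hom_threshold = hom_threshold,
                 marker_positions = marker_positions,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Random (ref, alt) pairs. Canonical EMS pairs are G>A / C>T; non-canonical
# draws any other substitution uniformly.
.sim_alleles <- function(n, canonical_fraction) {
  canon <- runif(n) < canonical_fraction
  ref <- character(n); alt <- character(n)
  ref[canon] <- sample(c("G", "C"), sum(canon), replace = TRUE)
  alt[canon] <- ifelse(ref[canon] == "G", "A", "T")
  if (any(!canon)) {
    pairs <- expand.grid(ref = .BASES, alt = .BASES,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$ref != pairs$alt, ]
    pairs <- pairs[!(pairs$ref == "G" & pairs$alt == "A") &
                     !(pairs$ref == "C" & pairs$alt == "T"), ]
    idx <- sample(nrow(pairs), sum(!canon), replace = TRUE)
    ref[!canon] <- pairs$ref[idx]
    alt[!canon] <- pairs$alt[idx]
  }
  list(ref = ref, alt = alt)
}

.random_alleles <- function(n) {
  ref <- sample(.BASES, n, replace = TRUE)
  shift <- sample(3, n, replace = TRUE)
  alt <- .BASES[(match(ref, .BASES) - 1 + shift) %% 4 + 1]
  list(ref = ref, alt = alt)
}

# One meiotic gamete: crossover count ~ Poisson(genetic length), breakpoint
# positions uniform, random starting haplotype; returns parameters only.
.gamete_params <- function(L) {
  nx <- rpois(1, L)
  list(bp = sort(runif(nx, 0, L)), start = rbinom(1, 1, 0.5))
}

# Haplotype indicator (1 = mutagenized/mutant-parent haplotype) at genetic
# positions g for one gamete.
.gamete_hap <- function(par, g) {
  (par$start + findInterval(g, par$bp)) %% 2
}

#' Simulate a selected mutant mapping population
#'
#' Places the induced and background variants, generates F2 (or BC1F2)
#' individuals by simulated meiosis (crossovers Poisson in genetic length,
#' no interference, i.e. Haldane's model), and selects individuals
#' homozygous for the mutagenized haplotype at the causal locus until the
#' pool size is reached. The expected pooled frequency of the
#' mutagenized-parent allele at map distance `d` from the causal locus is
#' `1 - haldane_r(d)`; unlinked variants segregate at 0.5.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_population`: `cfg`; `variants` (tibble with
#'   `chrom`, `pos`, `ref`, `alt`, `class`); `geno` (variants x 2n matrix
#'   of mutant-haplotype allele indicators over the pooled chromosomes);
#'   `pool_freq`; `truth` (tibble with per-variant map distance `d_morgans`,
#'   recombination fraction `r`, `expected_freq`, plus the causal key, mode
#'   and seed as attributes); and, in mutmap mode, `sibling_geno` for an
#'   equally sized wild-type-sibling pool.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  gen <- cfg$genome

  # --- variant placement ---------------------------------------------------
  n_ems <- cfg$n_ems_snps
  chrom_idx <- sample(nrow(gen), n_ems, replace = TRUE, prob = gen$length)
  ems_al <- .sim_alleles(n_ems, cfg$ems_fraction_canonical)
  variants <- tibble::tibble(
    chrom = gen$chrom[chrom_idx],
    pos = floor(runif(n_ems, 1, gen$length[chrom_idx] + 1)),
    ref = ems_al$ref, alt = ems_al$alt, class = "ems")

  causal <- tibble::tibble(chrom = cfg$causal_chrom, pos = cfg$causal_pos,
                           ref = "G", alt = "A", class = "causal")
  variants <- dplyr::bind_rows(causal, variants)

  if (cfg$n_background_snps > 0) {
    # bsa_outcross: natural mutant-parent-vs-reference SNPs, segregating on
    # the mutant-parent haplotype. mutmap_backcross: the same stock-vs-
    # reference differences, but fixed in the cross (homozygous in every
    # pool) since both parents share the background.
    nb <- cfg$n_background_snps
    ci <- sample(nrow(gen), nb, replace = TRUE, prob = gen$length)
    al <- .random_alleles(nb)
    variants <- dplyr::bind_rows(variants, tibble::tibble(
      chrom = gen$chrom[ci], pos = floor(runif(nb, 1, gen$length[ci] + 1)),
      ref = al$ref, alt = al$alt,
      class = if (cfg$mode == "bsa_outcross") "background" else "fixed_diff"))
  }
  if (cfg$mode == "mutmap_backcross" && cfg$n_residual_het_snps > 0) {
    nr <- cfg$n_residual_het_snps
    ci <- sample(nrow(gen), nr, replace = TRUE, prob = gen$length)
    al <- .random_alleles(nr)
    variants <- dplyr::bind_rows(variants, tibble::tibble(
      chrom = gen$chrom[ci], pos = floor(runif(nr, 1, gen$length[ci] + 1)),
      ref = al$ref, alt = al$alt, class = "residual_het"))
  }
  if (!is.null(cfg$marker_positions)) {
    mp <- cfg$marker_positions
    al <- .random_alleles(nrow(mp))
    variants <- dplyr::bind_rows(variants, tibble::tibble(
      chrom = mp$chrom, pos = mp$pos, ref = al$ref, alt = al$alt,
      class = "marker"))
  }
  variants <- variants[!duplicated(paste(variants$chrom, variants$pos)), ]
  variants <- dplyr::arrange(variants, match(.data$chrom, gen$chrom),
                             .data$pos)

  # genetic positions (uniform map: Morgans proportional to bp)
  gi <- match(variants$chrom, gen$chrom)
  gpos <- variants$pos / gen$length[gi] * gen$morgans[gi]
  causal_row <- which(variants$class == "causal")
  causal_g <- gpos[causal_row]

  # --- meiosis and selection at the causal locus ---------------------------
  n <- cfg$n_mutants
  L_causal <- gen$morgans[gen$chrom == cfg$causal_chrom]
  want_sib <- cfg$mode == "mutmap_backcross"
  sel <- list(); rej <- list()
  while (length(sel) < n || (want_sib && length(rej) < n)) {
    batch <- max(ceiling((n - length(sel)) * 4 * 1.4), 20)
    for (b in seq_len(batch)) {
      g1 <- .gamete_params(L_causal); g2 <- .gamete_params(L_causal)
      hom <- .gamete_hap(g1, causal_g) == 1 && .gamete_hap(g2, causal_g) == 1
      if (hom && length(sel) < n) sel[[length(sel) + 1]] <- list(g1, g2)
      if (!hom && want_sib && length(rej) < n) rej[[length(rej) + 1]] <-
          list(g1, g2)
    }
  }

  hap_matrix <- function(pairs, g) {
    vapply(pairs, function(p) c(.gamete_hap(p[[1]], g),
                                .gamete_hap(p[[2]], g)),
           numeric(2 * length(g)))
  }

  m <- nrow(variants)
  geno <- matrix(0L, m, 2 * n)
  sib <- if (want_sib) matrix(0L, m, 2 * n) else NULL
  seg <- variants$class %in% c("ems", "causal", "background", "marker")
  for (ci in seq_len(nrow(gen))) {
    rows <- which(variants$chrom == gen$chrom[ci] & seg)
    if (length(rows) == 0) next
    g <- gpos[rows]
    if (gen$chrom[ci] == cfg$causal_chrom) {
      hm <- hap_matrix(sel, g)  # (2*|rows|) x n, gametes interleaved
      geno[rows, ] <- matrix(hm, nrow = length(g))
      if (want_sib) sib[rows, ] <- matrix(hap_matrix(rej, g),
                                          nrow = length(g))
    } else {
      # unlinked chromosome: no selection pressure, fresh meioses
      pairs <- replicate(n, list(.gamete_params(gen$morgans[ci]),
                                 .gamete_params(gen$morgans[ci])),
                         simplify = FALSE)
      geno[rows, ] <- matrix(hap_matrix(pairs, g), nrow = length(g))
      if (want_sib) {
        pairs <- replicate(n, list(.gamete_params(gen$morgans[ci]),
                                   .gamete_params(gen$morgans[ci])),
                           simplify = FALSE)
        sib[rows, ] <- matrix(hap_matrix(pairs, g), nrow = length(g))
      }
    }
  }
  res_rows <- which(variants$class == "residual_het")
  if (length(res_rows) > 0) {
    geno[res_rows, ] <- matrix(rbinom(length(res_rows) * 2 * n, 1, 0.5),
                               length(res_rows))
    if (want_sib) sib[res_rows, ] <- matrix(
      rbinom(length(res_rows) * 2 * n, 1, 0.5), length(res_rows))
  }
  fix_rows <- which(variants$class == "fixed_diff")
  if (length(fix_rows) > 0) {
    geno[fix_rows, ] <- 1L
    if (want_sib) sib[fix_rows, ] <- 1L
  }

  d <- ifelse(variants$chrom == cfg$causal_chrom, abs(gpos - causal_g), Inf)
  d[variants$class %in% c("residual_het", "fixed_diff")] <- Inf
  r <- haldane_r(d)
  truth <- tibble::tibble(variants,
                          d_morgans = d, r = r, expected_freq = 1 - r)
  truth$expected_freq[variants$class == "residual_het"] <- 0.5
  truth$expected_freq[variants$class == "fixed_diff"] <- 1.0
  attr(truth, "causal_key") <- paste(cfg$causal_chrom, cfg$causal_pos,
                                     "G", "A", sep = ":")
  attr(truth, "mode") <- cfg$mode
  attr(truth, "seed") <- cfg$seed

  structure(list(cfg = cfg, variants = variants, geno = geno,
                 pool_freq = rowMeans(geno), truth = truth,
                 sibling_geno = sib),
            class = "sim_population")
}

# Allele frequencies seen by the sequencer for each pool of a population.
.pool_freqs <- function(pop, pool) {
  switch(pool,
         mutant = pop$pool_freq,
         sibling = {
           if (is.null(pop$sibling_geno))
             stop("no sibling pool in this simulation mode")
           rowMeans(pop$sibling_geno)
         },
         parent = ifelse(pop$variants$class == "residual_het", 0.5,
                         ifelse(pop$variants$class == "fixed_diff", 1, 0)),
         stop("unknown pool: ", pool))
}

#' Sample pooled sequencing reads
#'
#' Per site: depth is Poisson(`mean_coverage`); each read draws its allele
#' from the pool frequency over the 2n pooled chromosomes; each read is
#' miscalled with probability `base_error_rate` to a uniformly random other
#' base; `hi_quality_fraction` of bases get Phred quality >= 20 (the rest
#' below). Counts are split between high- and low-quality bases so that
#' downstream quality-adjusted frequencies can be computed exactly.
#'
#' @param pop A [simulate_population()] result.
#' @param pool `"mutant"`, `"sibling"` (mutmap mode) or `"parent"`
#'   (unmutagenized parent: reference at EMS sites, heterozygous at
#'   residual-heterozygosity sites).
#' @return A tibble of class `pool_reads`, one row per site: `chrom`,
#'   `pos`, `ref`, `alt`, the two other bases, `depth`, and hi/lo-quality
#'   counts for the reference, alternate and both error bases.
#' @export
sample_pool_reads <- function(pop, pool = c("mutant", "sibling", "parent")) {
  pool <- match.arg(pool)
  cfg <- pop$cfg
  offset <- c(mutant = 1L, sibling = 2L, parent = 3L)[pool]
  set.seed((cfg$seed %% 100000000L) + 104729L * offset)

  v <- pop$variants
  m <- nrow(v)
  freq <- .pool_freqs(pop, pool)
  e <- cfg$base_error_rate
  depth <- rpois(m, cfg$mean_coverage)
  alt_true <- rbinom(m, depth, freq)
  ref_true <- depth - alt_true
  # sequencing errors: flip to one of the three other bases uniformly
  e_alt <- rbinom(m, alt_true, e)
  alt_to_ref <- rbinom(m, e_alt, 1 / 3)
  alt_to_o1 <- rbinom(m, e_alt - alt_to_ref, 1 / 2)
  alt_to_o2 <- e_alt - alt_to_ref - alt_to_o1
  e_ref <- rbinom(m, ref_true, e)
  ref_to_alt <- rbinom(m, e_ref, 1 / 3)
  ref_to_o1 <- rbinom(m, e_ref - ref_to_alt, 1 / 2)
  ref_to_o2 <- e_ref - ref_to_alt - ref_to_o1

  n_ref <- ref_true - e_ref + alt_to_ref
  n_alt <- alt_true - e_alt + ref_to_alt
  n_o1 <- alt_to_o1 + ref_to_o1
  n_o2 <- alt_to_o2 + ref_to_o2

  hi <- function(x) rbinom(m, x, cfg$hi_quality_fraction)
  ref_hi <- hi(n_ref); alt_hi <- hi(n_alt)
  o1_hi <- hi(n_o1); o2_hi <- hi(n_o2)

  others <- t(mapply(function(r, a) sort(setdiff(.BASES, c(r, a))),
                     v$ref, v$alt, USE.NAMES = FALSE))
  out <- tibble::tibble(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    other1 = others[, 1], other2 = others[, 2], depth = depth,
    ref_hi = ref_hi, ref_lo = n_ref - ref_hi,
    alt_hi = alt_hi, alt_lo = n_alt - alt_hi,
    o1_hi = o1_hi, o1_lo = n_o1 - o1_hi,
    o2_hi = o2_hi, o2_lo = n_o2 - o2_hi)
  class(out) <- unique(c("pool_reads", class(out)))
  out
}

#' Call variants from sampled pool reads
#'
#' The in-memory equivalent of writing a pileup and re-reading it: the
#' quality-adjusted depth is the number of high-quality bases, the
#' alternate allele is the most frequent high-quality non-reference base
#' (ties broken A < C < G < T), and non-variant sites are dropped.
#'
#' @param reads A `pool_reads` tibble from [sample_pool_reads()].
#' @param hom_threshold Homozygosity threshold (default 0.99).
#' @return A `variant_set`.
#' @export
pool_reads_to_variants <- function(reads, hom_threshold = 0.99) {
  m <- nrow(reads)
  counts <- matrix(0L, m, 4, dimnames = list(NULL, .BASES))
  counts[cbind(seq_len(m), match(reads$alt, .BASES))] <- reads$alt_hi
  counts[cbind(seq_len(m), match(reads$other1, .BASES))] <- reads$o1_hi
  counts[cbind(seq_len(m), match(reads$other2, .BASES))] <- reads$o2_hi
  best <- max.col(counts, ties.method = "first")
  alt <- .BASES[best]
  alt_count <- counts[cbind(seq_len(m), best)]
  total <- reads$ref_hi + reads$alt_hi + reads$o1_hi + reads$o2_hi
  keep <- alt_count > 0 & total > 0
  variant_set(chrom = reads$chrom[keep], pos = reads$pos[keep],
              ref = reads$ref[keep], alt = alt[keep],
              total_qdepth = total[keep], alt_count = alt_count[keep],
              hom_threshold = hom_threshold)
}

# Phred qualities for one site's reads: hi-quality bases 20..40, the rest
# 2..19, encoded Phred+33.
.qual_chars <- function(n_hi, n_lo) {
  q <- c(if (n_hi > 0) sample(20:40, n_hi, replace = TRUE),
         if (n_lo > 0) sample(2:19, n_lo, replace = TRUE))
  intToUtf8(q + 33L)
}

#' Write simulated pool reads as pileup, VCF and truth files
#'
#' Emits a samtools-style 6-column pileup and a minimal VCF for the mutant
#' pool (and, in mutmap mode, pileups plus site-panel TSVs for the
#' wild-type-sibling and unmutagenized-parent pools), the simulation truth
#' as TSV, and the genome table. Re-reading the pileup reproduces the
#' simulated quality-adjusted counts exactly.
#'
#' @param pop A [simulate_population()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths.
#' @export
write_sim_files <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- pop$cfg
  pools <- c("mutant", if (cfg$mode == "mutmap_backcross")
    c("sibling", "parent"))
  paths <- list()
  set.seed((cfg$seed %% 100000000L) + 7919L)
  for (pool in pools) {
    reads <- sample_pool_reads(pop, pool)
    pile <- file.path(dir, paste0(pool, ".pileup"))
    con <- file(pile, "w")
    for (i in seq_len(nrow(reads))) {
      r <- reads[i, ]
      n_hi <- c(r$ref_hi, r$alt_hi, r$o1_hi, r$o2_hi)
      n_lo <- c(r$ref_lo, r$alt_lo, r$o1_lo, r$o2_lo)
      sym_hi <- rep(c(".", r$alt, r$other1, r$other2), n_hi)
      sym_lo <- rep(c(",", tolower(c(r$alt, r$other1, r$other2))), n_lo)
      bases <- paste(c(sym_hi, sym_lo), collapse = "")
      total <- sum(n_hi) + sum(n_lo)
      if (total == 0) next
      quals <- .qual_chars(sum(n_hi), sum(n_lo))
      writeLines(paste(r$chrom, format(r$pos, scientific = FALSE),
                       r$ref, total, bases, quals, sep = "\t"), con)
    }
    close(con)
    paths[[paste0(pool, "_pileup")]] <- pile
    vs <- pool_reads_to_variants(reads, cfg$hom_threshold)
    vcf <- file.path(dir, paste0(pool, ".vcf"))
    write_vcf(vs, vcf, sample_name = pool)
    paths[[paste0(pool, "_vcf")]] <- vcf
    if (pool != "mutant") {
      panel <- file.path(dir, paste0(pool, "_panel.tsv"))
      write_site_panel(site_panel(vs$chrom, vs$pos, vs$ref, vs$alt,
                                  label = pool), panel)
      paths[[paste0(pool, "_panel")]] <- panel
    }
  }
  truth_path <- file.path(dir, "truth.tsv")
  .write_tsv(as.data.frame(pop$truth), truth_path)
  paths$truth <- truth_path
  genome_path <- file.path(dir, "genome.tsv")
  .write_tsv(as.data.frame(cfg$genome), genome_path)
  paths$genome <- genome_path
  invisible(paths)
}

#' Simulate, map, and score interval recovery
#'
#' Runs the whole mapping path on one simulated population: read sampling,
#' variant calling, depth/coverage filtering, mode-dependent background
#' subtraction (mutmap: sibling and parent pools), per-bin counting of
#' homozygous variants, and interval calling. Reports whether the primary
#' interval contains the causal position and how wide it is.
#'
#' @param cfg A [sim_config()].
#' @param bin_size Bin width in bp (default 1e6).
#' @param k_mad Interval-calling threshold multiplier (default 5).
#' @param predicate Binning predicate, `"homozygous"` or
#'   `"homozygous_ems"`. Defaults by design: outcross pools map on all
#'   homozygous variants (natural background SNPs carry linkage
#'   information there), while backcross (mutmap) pools map on the EMS
#'   spectrum, since only induced SNPs segregate in that design.
#' @return A list of class `sim_report`: `intervals`, `bins`,
#'   `contains_causal`, `width_bp` (NA when no interval), `n_variants`
#'   (per stage), `truth`.
#' @export
run_end_to_end <- function(cfg, bin_size = 1e6, k_mad = 5,
                           predicate = NULL) {
  if (is.null(predicate))
    predicate <- if (cfg$mode == "mutmap_backcross") "homozygous_ems"
                 else "homozygous"
  pop <- simulate_population(cfg)
  reads <- sample_pool_reads(pop, "mutant")
  vs <- pool_reads_to_variants(reads, cfg$hom_threshold)
  fcfg <- filter_config(hom_threshold = cfg$hom_threshold)
  vm <- apply_filters(vs, fcfg, "mapping")
  n_stage <- c(called = nrow(vs), mapping_filtered = nrow(vm))

  if (cfg$mode == "mutmap_backcross") {
    # Panels hold the *homozygous* calls of the wild-type-sibling and
    # unmutagenized-parent pools: fixed stock-vs-reference differences are
    # homozygous there too and get subtracted, while induced SNPs linked to
    # the causal locus segregate at ~1/3-1/2 in those pools and survive.
    panels <- lapply(c("sibling", "parent"), function(pool) {
      pv <- pool_reads_to_variants(sample_pool_reads(pop, pool),
                                   cfg$hom_threshold)
      pv <- pv[pv$zygosity == "homozygous", , drop = FALSE]
      site_panel(pv$chrom, pv$pos, pv$ref, pv$alt, label = pool)
    })
    vm <- subtract_panels(vm, panels)
    n_stage["after_subtraction"] <- nrow(vm)
  }

  genome <- setNames(cfg$genome$length, cfg$genome$chrom)
  bins <- bin_variants(vm, genome, bin_size, predicate)
  intervals <- suppressMessages(call_interval(bins, k_mad))
  primary <- intervals[intervals$primary, , drop = FALSE]
  contains <- nrow(primary) == 1 &&
    primary$chrom == cfg$causal_chrom &&
    cfg$causal_pos >= primary$start && cfg$causal_pos <= primary$end
  structure(list(intervals = intervals, bins = bins,
                 contains_causal = contains,
                 width_bp = if (nrow(primary) == 1)
                   primary$end - primary$start + 1 else NA_real_,
                 n_variants = n_stage, truth = pop$truth),
            class = "sim_report")
}
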
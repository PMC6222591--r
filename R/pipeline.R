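#' Run the full mapping pipeline from a config file
#'
#' Executes filter -> subtract -> bin -> interval call -> consequence
#' annotation -> candidate triage -> indel marker design from a YAML
#' configuration, writing `bins.tsv`, `interval.tsv`, `candidates.tsv`,
#' `markers.tsv` and a `run_log.tsv` of per-stage record tallies to the
#' output directory. Stages without configured inputs (e.g. no GFF3) are
#' skipped.
#'
#' Recognized config keys (defaults in parentheses):
#' \itemize{
#'   \item `pileup` or `vcf` — variant evidence for the mutant pool
#'     (one required)
#'   \item `genome_table` — TSV with `chrom` and `length` columns (required)
#'   \item `panels` — list of site-panel TSVs to subtract
#'   \item `key_mode` ("allele"), `min_base_quality` (20), `min_depth` (8),
#'     `max_depth_for_mapping` (100), `hom_threshold` (0.99),
#'     `ems_only` (false), `bin_size` (1e6), `k_mad` (5),
#'     `predicate` ("homozygous")
#'   \item `gff3`, `fasta` — gene models and reference for annotation
#'   \item `min_indel_len` (15), `flank_min` (100), `flank_max` (150)
#'   \item `out_dir` — output directory
#' }
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param out_dir Output directory; overrides the config's `out_dir`.
#' @return Invisibly, a list with the in-memory stage results (`variants`,
#'   `bins`, `intervals`, `candidates`, `markers`, `log`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  get <- function(key, default = NULL) {
    if (!is.null(cfg[[key]])) cfg[[key]] else default
  }
  out_dir <- if (!is.null(out_dir)) out_dir else get("out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  gt <- get("genome_table")
  if (is.null(gt))
    stop("pipeline stage 'setup': config key 'genome_table' is required")
  if (!file.exists(gt))
    stop("pipeline stage 'setup': genome_table not found: ", gt)
  genome_tbl <- read.table(gt, header = TRUE, sep = "\t",
                           colClasses = c(chrom = "character"))
  hom <- get("hom_threshold", 0.99)
  fcfg <- filter_config(min_base_quality = get("min_base_quality", 20),
                        min_depth = get("min_depth", 8),
                        max_depth_for_mapping = get("max_depth_for_mapping", 100),
                        hom_threshold = hom,
                        ems_only = get("ems_only", FALSE))
  log <- list()
  note <- function(stage, tally) {
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = stage, rule = names(tally), count = unname(tally))
  }

  # --- load variants -------------------------------------------------------
  if (!is.null(get("pileup"))) {
    if (!file.exists(cfg$pileup))
      stop("pipeline stage 'load': pileup not found: ", cfg$pileup)
    vs <- pileup_variants(read_pileup(cfg$pileup),
                          min_base_quality = fcfg$min_base_quality,
                          hom_threshold = hom)
  } else if (!is.null(get("vcf"))) {
    if (!file.exists(cfg$vcf))
      stop("pipeline stage 'load': vcf not found: ", cfg$vcf)
    vs <- read_vcf(cfg$vcf, hom_threshold = hom)
  } else {
    stop("pipeline stage 'load': config needs 'pileup' or 'vcf'")
  }
  note("load", c(loaded = nrow(vs)))
  if (nrow(vs) == 0) warning("no variants loaded; outputs will be empty")

  # --- filter --------------------------------------------------------------
  vm <- apply_filters(vs, fcfg, "mapping")
  note("filter_mapping", attr(vm, "tally"))

  # --- subtract panels -----------------------------------------------------
  panel_paths <- get("panels", list())
  if (length(panel_paths) > 0) {
    panels <- lapply(panel_paths, function(p) {
      if (!file.exists(p)) stop("pipeline stage 'subtract': panel not found: ", p)
      read_site_panel(p)
    })
    vm <- subtract_panels(vm, panels, key_mode = get("key_mode", "allele"))
    note("subtract", attr(vm, "tally"))
  }

  # --- bin + interval ------------------------------------------------------
  bins <- bin_variants(vm, genome_tbl, bin_size = get("bin_size", 1e6),
                       predicate = get("predicate", "homozygous"))
  write_bins_tsv(bins, file.path(out_dir, "bins.tsv"))
  intervals <- call_interval(bins, k_mad = get("k_mad", 5))
  .write_tsv(as.data.frame(intervals), file.path(out_dir, "interval.tsv"))
  note("interval", c(intervals = nrow(intervals)))
  primary <- intervals[intervals$primary, , drop = FALSE]

  # --- candidates ----------------------------------------------------------
  candidates <- NULL
  if (!is.null(get("gff3")) && !is.null(get("fasta")) && nrow(primary) == 1) {
    models <- read_gene_models(cfg$gff3)
    genome_seq <- Biostrings::readDNAStringSet(cfg$fasta)
    names(genome_seq) <- sub("\\s.*", "", names(genome_seq))
    cand_cfg <- filter_config(min_base_quality = fcfg$min_base_quality,
                              min_depth = fcfg$min_depth,
                              max_depth_for_mapping = fcfg$max_depth_for_mapping,
                              hom_threshold = hom, ems_only = TRUE)
    vc <- apply_filters(vs, cand_cfg, "candidate")
    note("filter_candidate", attr(vc, "tally"))
    if (length(panel_paths) > 0)
      vc <- subtract_panels(vc, panels, key_mode = get("key_mode", "allele"))
    in_iv <- vc$chrom == primary$chrom & vc$pos >= primary$start &
      vc$pos <= primary$end
    calls <- annotate_variants(as_variant_set(vc[in_iv, , drop = FALSE]),
                               models, genome_seq)
    candidates <- triage_candidates(calls, primary)
    .write_tsv(as.data.frame(candidates),
               file.path(out_dir, "candidates.tsv"))
    note("candidates", c(candidates = nrow(candidates)))
  }

  # --- markers -------------------------------------------------------------
  markers <- NULL
  if (!is.null(get("fasta")) && nrow(primary) == 1) {
    genome_seq <- Biostrings::readDNAStringSet(cfg$fasta)
    names(genome_seq) <- sub("\\s.*", "", names(genome_seq))
    markers <- design_markers(vs, primary, genome_seq,
                              min_indel_len = get("min_indel_len", 15),
                              flank_min = get("flank_min", 100),
                              flank_max = get("flank_max", 150))
    .write_tsv(as.data.frame(markers), file.path(out_dir, "markers.tsv"))
    note("markers", c(markers = nrow(markers)))
  }

  log_df <- dplyr::bind_rows(log)
  .write_tsv(as.data.frame(log_df), file.path(out_dir, "run_log.tsv"))
  invisible(list(variants = vm, bins = bins, intervals = intervals,
                 candidates = candidates, markers = markers, log = log_df))
}
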
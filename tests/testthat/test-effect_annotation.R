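snv <- function(pos, ref, alt, chrom = "chrT") {
  vs_fixture(chrom = chrom, pos = pos, ref = ref, alt = alt,
             qdepth = 20L, alt_count = 20L)
}

test_that("coding consequences follow the standard genetic code", {
  fx <- gene_fixture()
  # CDS base 4: codon 2 CTT -> TTT, leucine to phenylalanine
  call <- annotate_variants(snv(104, "C", "T"), fx$model, fx$genome)
  expect_equal(call$consequence, "missense")
  expect_equal(call$severity, "MODERATE")
  expect_equal(call$protein_change, "L2F")

  # CDS base 6: CTT -> CTC, still leucine
  call <- annotate_variants(snv(106, "T", "C"), fx$model, fx$genome)
  expect_equal(call$consequence, "synonymous")
  expect_equal(call$severity, "LOW")
  expect_equal(call$protein_change, "L2L")

  # codon 3 TGG -> TGA: tryptophan to stop
  call <- annotate_variants(snv(109, "G", "A"), fx$model, fx$genome)
  expect_equal(call$consequence, "stop_gained")
  expect_equal(call$severity, "HIGH")
  expect_equal(call$protein_change, "W3*")

  # ATG -> GTG start codon loss
  call <- annotate_variants(snv(101, "A", "G"), fx$model, fx$genome)
  expect_equal(call$consequence, "start_lost")
  expect_equal(call$severity, "HIGH")

  # terminal TAA -> CAA: stop lost (stop codon spans 278-280, exon2)
  call <- annotate_variants(snv(278, "T", "C"), fx$model, fx$genome)
  expect_equal(call$consequence, "stop_lost")
  expect_equal(call$severity, "HIGH")
})

test_that("splice sites span exactly the 2 intronic bases flanking each exon", {
  fx <- gene_fixture()
  # intron is 161-220 on a + strand gene
  for (pos in c(161, 162)) {
    call <- annotate_variants(snv(pos, substr(fx$genome$chrT, pos, pos),
                                  "A"), fx$model, fx$genome)
    expect_equal(call$consequence, "splice_donor")
    expect_equal(call$severity, "HIGH")
  }
  for (pos in c(219, 220)) {
    call <- annotate_variants(snv(pos, substr(fx$genome$chrT, pos, pos),
                                  "T"), fx$model, fx$genome)
    expect_equal(call$consequence, "splice_acceptor")
    expect_equal(call$severity, "HIGH")
  }
  # 3rd intronic base is plain intronic, severity NONE
  call <- annotate_variants(snv(163, substr(fx$genome$chrT, 163, 163), "A"),
                            fx$model, fx$genome)
  expect_equal(call$consequence, "intronic")
  expect_equal(call$severity, "NONE")
})

test_that("variants outside any model are intergenic with severity NONE", {
  fx <- gene_fixture()
  call <- annotate_variants(snv(50, substr(fx$genome$chrT, 50, 50), "A"),
                            fx$model, fx$genome)
  expect_equal(call$consequence, "intergenic")
  expect_equal(call$severity, "NONE")
  expect_true(is.na(call$gene_id))
})

test_that("minus-strand annotation equals the reverse-complement construction", {
  fx <- gene_fixture()
  mir <- mirror_fixture(fx)
  # every interesting site, plus a sweep of all CDS positions
  probe <- c(101, 104, 106, 109, 161, 162, 219, 220, 278, 150, 240)
  probe <- c(probe, seq(101, 160, by = 7), seq(221, 280, by = 7))
  for (pos in unique(probe)) {
    ref <- substr(fx$genome$chrT, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      plus <- annotate_variants(snv(pos, ref, alt), fx$model, fx$genome)
      mpos <- mir$flip(pos)
      minus <- annotate_variants(
        snv(mpos, chartr("ACGT", "TGCA", ref), chartr("ACGT", "TGCA", alt)),
        mir$model, mir$genome)
      expect_equal(minus$consequence, plus$consequence,
                   info = paste("pos", pos, alt))
      expect_equal(minus$severity, plus$severity)
      expect_equal(minus$protein_change, plus$protein_change,
                   info = paste("pos", pos, alt))
    }
  }
})

test_that("reference mismatches are reported per variant, not fatal", {
  fx <- gene_fixture()
  wrong_ref <- setdiff(c("A", "C", "G", "T"),
                       c(substr(fx$genome$chrT, 104, 104), "T"))[1]
  expect_warning(call <- annotate_variants(snv(104, wrong_ref, "T"),
                                           fx$model, fx$genome),
                 "reference mismatch")
  expect_equal(call$consequence, "reference_mismatch")
})

test_that("indels are skipped by the consequence caller", {
  fx <- gene_fixture()
  indel <- vs_fixture("chrT", 104, "CTT", "C", 20L, 20L)
  expect_message(calls <- annotate_variants(indel, fx$model, fx$genome),
                 "indel")
  expect_equal(nrow(calls), 0)
})

test_that("GFF3 gene models round-trip into the annotator", {
  fx <- gene_fixture()
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrT\ttest\tgene\t101\t280\t.\t+\t.\tID=GeneA",
    "chrT\ttest\tmRNA\t101\t280\t.\t+\t.\tID=GeneA_T001;Parent=GeneA",
    "chrT\ttest\texon\t101\t160\t.\t+\t.\tID=e1;Parent=GeneA_T001",
    "chrT\ttest\texon\t221\t280\t.\t+\t.\tID=e2;Parent=GeneA_T001",
    "chrT\ttest\tCDS\t101\t160\t.\t+\t0\tID=c1;Parent=GeneA_T001",
    "chrT\ttest\tCDS\t221\t280\t.\t+\t0\tID=c2;Parent=GeneA_T001"), gff)
  models <- read_gene_models(gff)
  expect_length(models, 1)
  expect_equal(models[[1]]$gene_id, "GeneA")
  call <- annotate_variants(snv(104, "C", "T"), models, fx$genome)
  expect_equal(call$protein_change, "L2F")
})

test_that("triage restricts to the interval and ranks by severity then position", {
  fx <- gene_fixture()
  vs <- rbind(snv(109, "G", "A"),   # stop_gained, HIGH
              snv(104, "C", "T"),   # missense, MODERATE
              snv(106, "T", "C"),   # synonymous, LOW
              snv(350, substr(fx$genome$chrT, 350, 350), "A"))  # intergenic
  calls <- annotate_variants(as_variant_set(vs), fx$model, fx$genome)
  tri <- triage_candidates(calls, interval_fixture("chrT", 100, 300))
  expect_equal(nrow(tri), 3)  # the 350 call falls outside the interval
  expect_equal(tri$effect, c("HIGH", "MODERATE", "LOW"))
  expect_equal(tri$call, c("W3*", "L2F", "L2L"))
  # every in-interval call carries exactly one severity tier
  expect_true(all(tri$effect %in% c("HIGH", "MODERATE", "LOW", "NONE")))

  # empty call list is fine
  empty <- triage_candidates(calls[0, ], interval_fixture("chrT", 1, 600))
  expect_equal(nrow(empty), 0)
})
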
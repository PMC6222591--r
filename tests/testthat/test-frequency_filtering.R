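test_that("quality-adjusted allele frequency matches hand counts", {
  # 8 reads, 5 A mismatches against ref G, all high quality
  rec <- pileup_rec(",,AaAA.a", strrep("I", 8))  # 'I' = Phred 40
  v <- compute_allele_frequency(rec)
  expect_equal(v$alt, "A")
  expect_equal(v$alt_count, 5L)
  expect_equal(v$total_qdepth, 8L)
  expect_equal(v$freq, 0.625)
  expect_equal(v$zygosity, "heterozygous")

  # all reference: non-variant, dropped
  expect_null(compute_allele_frequency(pileup_rec("..,,..", strrep("I", 6))))

  # saturated: 10/10 T against ref C is homozygous at the 0.99 threshold
  v <- compute_allele_frequency(pileup_rec("TTTTTTTTTT", strrep("I", 10),
                                           ref = "C"))
  expect_equal(v$freq, 1)
  expect_equal(v$zygosity, "homozygous")

  # bases below Phred 20 are invisible: 4 low-quality T reads don't count
  rec <- pileup_rec("....TTTT", paste0(strrep("I", 4), strrep("4", 4)),
                    ref = "C")  # '4' = Phred 19
  expect_null(compute_allele_frequency(rec))
  # ...but Phred 20 ('5') does count
  rec <- pileup_rec("....TTTT", paste0(strrep("I", 4), strrep("5", 4)),
                    ref = "C")
  v <- compute_allele_frequency(rec)
  expect_equal(v$total_qdepth, 8L)
  expect_equal(v$alt_count, 4L)

  # all bases below threshold: no quality-adjusted depth, no record
  expect_null(compute_allele_frequency(pileup_rec("TTTT", strrep("!", 4),
                                                  ref = "C")))

  # '*' placeholders consume a quality but are excluded from both counts
  v <- compute_allele_frequency(pileup_rec("AA**..", strrep("I", 6)))
  expect_equal(v$total_qdepth, 4L)
  expect_equal(v$alt_count, 2L)

  # tie between non-ref bases broken by base order A < C < G < T
  v <- compute_allele_frequency(pileup_rec("TTAA..", strrep("I", 6)))
  expect_equal(v$alt, "A")

  # bases/quals length mismatch is a parse error naming the position
  expect_error(compute_allele_frequency(pileup_rec(",,A", "II")), "chr1:100")
})

test_that("frequency computation agrees with a brute-force counter on random lines", {
  set.seed(7)
  n_checked <- 0
  for (i in 1:300) {
    line <- random_pileup_line()
    ref <- sample(c("A", "C", "G", "T"), 1)
    oracle <- brute_force_frequency(line$bases, line$quals, ref)
    got <- compute_allele_frequency(pileup_rec(line$bases, line$quals,
                                               ref = ref))
    if (oracle$alt_count == 0 || oracle$total == 0) {
      expect_null(got)
    } else {
      n_checked <- n_checked + 1
      expect_equal(got$alt, oracle$alt)
      expect_equal(got$alt_count, oracle$alt_count)
      expect_equal(got$total_qdepth, oracle$total)
      expect_equal(got$freq, oracle$alt_count / oracle$total)
    }
  }
  expect_gt(n_checked, 50)  # the generator must exercise the variant path
})

test_that("canonical EMS spectrum is G>A and C>T only", {
  expect_true(is_canonical_ems("G", "A"))
  expect_true(is_canonical_ems("C", "T"))
  expect_false(is_canonical_ems("A", "G"))
  expect_false(is_canonical_ems("T", "C"))
  expect_false(is_canonical_ems("G", "T"))
  expect_false(is_canonical_ems("ACCTG", "A"))  # indel alleles are not EMS SNVs
  expect_equal(is_canonical_ems(c("G", "C", "A"), c("A", "T", "C")),
               c(TRUE, TRUE, FALSE))
})

test_that("filters enforce the depth, coverage-cap, homozygosity and EMS rules", {
  vs <- vs_fixture(
    chrom = rep("1", 7), pos = 1:7 * 10,
    ref = c("G", "G", "G", "G", "G", "A", "C"),
    alt = c("A", "A", "A", "A", "A", "G", "T"),
    qdepth = c(7L, 8L, 100L, 100L, 101L, 20L, 20L),
    alt_count = c(7L, 8L, 98L, 99L, 101L, 20L, 20L))
  cfg <- filter_config(ems_only = TRUE)

  vm <- apply_filters(vs, cfg, "mapping")
  # depth 7 dropped, 8 kept; 100 kept, 101 dropped
  expect_setequal(vm$total_qdepth, c(8L, 100L, 100L, 20L, 20L))
  t <- attr(vm, "tally")
  expect_equal(unname(t["dropped_min_depth"]), 1L)
  expect_equal(unname(t["dropped_max_depth"]), 1L)
  expect_equal(unname(t["input"]), unname(t["output"]) + sum(t[2:5]))

  vc <- apply_filters(vs, cfg, "candidate")
  # freq 0.98 dropped, 0.99 kept; A>G not EMS; no coverage cap here
  expect_setequal(vc$pos, c(20, 40, 50, 70))
  t <- attr(vc, "tally")
  expect_equal(unname(t["dropped_not_homozygous"]), 1L)  # the 98/100 record
  expect_equal(unname(t["dropped_not_ems"]), 1L)         # the A>G record
  expect_equal(unname(t["input"]), unname(t["output"]) + sum(t[2:5]))
})

test_that("filtering is monotone and idempotent", {
  set.seed(11)
  n <- 200
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, TRUE)
  alt <- bases[(match(ref, bases) - 1 + sample(3, n, TRUE)) %% 4 + 1]
  q <- sample(1:150, n, TRUE)
  vs <- vs_fixture(chrom = "1", pos = seq_len(n), ref = ref, alt = alt,
                   qdepth = q,
                   alt_count = vapply(q, function(x) sample.int(x, 1), 1L))
  for (purpose in c("mapping", "candidate")) {
    cfg <- filter_config(ems_only = TRUE)
    once <- apply_filters(vs, cfg, purpose)
    expect_true(all(variant_key(once) %in% variant_key(vs)))
    twice <- apply_filters(once, cfg, purpose)
    expect_equal(variant_key(twice), variant_key(once))
    t <- attr(twice, "tally")
    expect_equal(sum(t[2:5]), 0)  # second pass drops nothing
  }
})
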
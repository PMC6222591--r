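test_that("pileup tokenizer handles the samtools grammar", {
  # plain symbols only
  tok <- tokenize_pileup_bases(",,AaAA.a")
  expect_identical(tok$symbols, c(",", ",", "A", "a", "A", "A", ".", "a"))
  expect_identical(tok$indel_lens, integer(0))

  # read start with mapping quality and read end consume no quality
  tok <- tokenize_pileup_bases(".^I,$T")
  expect_identical(tok$symbols, c(".", ",", "T"))

  # attached insertion belongs to the preceding base
  tok <- tokenize_pileup_bases(".+2TT,")
  expect_identical(tok$symbols, c(".", ","))
  expect_identical(tok$indel_lens, 2L)

  # deletions and the '*' placeholder
  tok <- tokenize_pileup_bases(".-3ACG*,")
  expect_identical(tok$symbols, c(".", "*", ","))
  expect_identical(tok$indel_lens, -3L)

  expect_error(tokenize_pileup_bases(".+AA"), "indel marker")
  expect_error(tokenize_pileup_bases(".%"), "unexpected character")
})

test_that("tokenizer scorable-symbol count equals quals length on random lines", {
  set.seed(42)
  for (i in 1:200) {
    line <- random_pileup_line()
    tok <- tokenize_pileup_bases(line$bases)
    expect_identical(tok$symbols, line$symbols)
    expect_length(tok$symbols, nchar(line$quals))
  }
})

test_that("read_pileup parses 6-column lines and rejects malformed input", {
  path <- write_pileup_fixture(c(
    pileup_line("chr1", 100, "G", c(",", ",", "A"), c(40, 40, 40)),
    pileup_line("chr2", 5, "C", c(".", "T"), c(30, 20))))
  p <- read_pileup(path)
  expect_equal(nrow(p), 2)
  expect_equal(p$pos, c(100, 5))
  expect_equal(p$ref_base, c("G", "C"))
  expect_equal(p$depth, c(3, 2))

  bad <- tempfile()
  writeLines(c("chr1\t100\tG\t3\t,,A\tIII", "chr1\tabc\tG\t3\t,,A\tIII"), bad)
  expect_error(read_pileup(bad), "line 2")
  writeLines("chr1\t100\tG\t3\t,,A", bad)
  expect_error(read_pileup(bad), "6 columns")
  expect_equal(nrow(read_pileup(write_pileup_fixture(character(0)))), 0)
})

test_that("read_vcf splits multiallelics, computes indel lengths, skips depthless records", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tpool",
    "1\t12172055\tC\tC\tT\t.\tPASS\t.\tGT:DP:AD\t1/1:30:0,30",
    "1\t200\t.\tA\tG,T\t.\tPASS\t.\tGT:DP:AD\t0/1:40:20,15,5",
    "1\t300\t.\tACCTGACCTGACCTGA\tA\t.\tPASS\t.\tGT:DP:AD\t1/1:25:0,25",
    "1\t400\t.\tA\tA\t.\tPASS\t.\tGT:DP:AD\t0/1:10:5,5",
    "1\t500\t.\tG\tA\t.\tPASS\t.\tGT\t0/1"), path)
  expect_warning(vs <- read_vcf(path), "skipped")
  # the Table-3-style SNV
  expect_true("1:12172055:C:T" %in% variant_key(vs))
  r <- vs[vs$pos == 12172055, ]
  expect_false(r$is_indel)
  expect_equal(r$zygosity, "homozygous")
  # multiallelic split into two records with per-ALT frequencies
  m <- vs[vs$pos == 200, ]
  expect_equal(nrow(m), 2)
  expect_equal(sort(m$alt), c("G", "T"))
  expect_equal(m$freq[m$alt == "G"], 15 / 40)
  # 15 bp deletion
  d <- vs[vs$pos == 300, ]
  expect_true(d$is_indel)
  expect_equal(d$indel_len, -15L)
  # identity allele rejected, depthless record skipped
  expect_false(any(vs$pos == 400))
  expect_false(any(vs$pos == 500))
  expect_equal(attr(vs, "n_skipped"), 1L)
})

test_that("read_vcf accepts Varscan RD/AD and FREQ shapes", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=RD,Number=1,Type=Integer,Description=\"r\">",
    "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"a\">",
    "##FORMAT=<ID=FREQ,Number=1,Type=String,Description=\"f\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tpool",
    "1\t100\t.\tG\tA\t.\tPASS\t.\tGT:DP:RD:AD:FREQ\t1/1:50:1:49:98%",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT:DP:FREQ\t1/1:40:100%"), path)
  vs <- read_vcf(path)
  expect_equal(nrow(vs), 2)
  # allele depths win over FREQ when both are present
  expect_equal(vs$freq[vs$pos == 100], 49 / 50)
  expect_equal(vs$freq[vs$pos == 200], 1)
})

test_that("site panels deduplicate, detect headers, and handle empty files", {
  path <- tempfile()
  writeLines(c("1\t47570165\tG\tA", "1\t47570165\tG\tA", "2\t9\tC\tT"), path)
  panel <- read_site_panel(path, label = "hapmap")
  expect_equal(nrow(panel), 2)
  expect_true("1:47570165:G:A" %in% variant_key(panel))
  expect_equal(attr(panel, "label"), "hapmap")

  writeLines(c("chrom\tpos\tref\talt", "1\t5\tG\tA"), path)
  expect_equal(nrow(read_site_panel(path)), 1)

  writeLines(character(0), path)
  expect_equal(nrow(read_site_panel(path)), 0)

  writeLines("1\txx\tG\tA", path)
  expect_error(read_site_panel(path), "non-integer")
})

test_that("variant sets round-trip through TSV and VCF key-wise", {
  vs <- vs_fixture(chrom = c("1", "1", "2"), pos = c(100, 200, 50),
                   ref = c("G", "C", "ATTTTTTTTTTTTTTTT"),
                   alt = c("A", "T", "A"),
                   qdepth = c(20L, 30L, 25L), alt_count = c(20L, 29L, 25L))
  tsv <- tempfile(fileext = ".tsv")
  write_variants_tsv(vs, tsv)
  back <- read_variants_tsv(tsv)
  expect_setequal(variant_key(back), variant_key(vs))
  expect_equal(back$freq, vs$freq)
  expect_equal(back$indel_len, vs$indel_len)

  vcf <- tempfile(fileext = ".vcf")
  write_vcf(vs, vcf)
  back2 <- read_vcf(vcf)
  expect_setequal(variant_key(back2), variant_key(vs))
  expect_equal(back2$alt_count[order(back2$pos)], vs$alt_count[order(vs$pos)])
})

test_that("variant_set validates its invariants", {
  expect_error(variant_set("1", 0, "G", "A", 10L, 5L), "1-based")
  expect_error(variant_set("1", 1, "G", "A", 5L, 10L), "alt_count")
  expect_error(variant_set("1", 1, "A", "A", 10L, 5L), "identity")
  vs <- vs_fixture("1", 10, "G", "A", 100L, 99L)
  expect_equal(vs$zygosity, "homozygous")  # 0.99 is homozygous
  vs <- vs_fixture("1", 10, "G", "A", 100L, 98L)
  expect_equal(vs$zygosity, "heterozygous")
})

test_that("BED export is 0-based half-open", {
  iv <- interval_fixture("chr1", 3000001, 6000000)
  path <- tempfile(fileext = ".bed")
  write_interval_bed(iv, path)
  expect_equal(readLines(path), "chr1\t3000000\t6000000")
})
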
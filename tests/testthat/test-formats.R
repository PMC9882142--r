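# File format readers/writers: round trips, coordinate conventions,
# error handling.

test_that("FASTA reading normalizes case, preserves order, and round-trips", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "acgt", ">b desc", "NNAC", "GT"), f)
  seqs <- read_fasta(f)
  expect_identical(seqs, c(a = "ACGT", b = "NNACGT"))

  set.seed(42)
  out <- withr::local_tempfile(fileext = ".fa")
  sim <- setNames(vapply(1:8, function(i) random_dna(sample(10:300, 1)),
                         character(1)), paste0("s", 1:8))
  write_fasta(sim, out, width = 60)
  expect_identical(read_fasta(out), sim)

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(), empty)
  expect_error(read_fasta(empty), "empty")
})

test_that("PAF parsing fills coordinates, divergence and skips CIGAR-less records", {
  f <- withr::local_tempfile(fileext = ".paf")
  writeLines(c(paf_line("r1", 10, 0, 10, "+", "t", 100, 5, 15, "10="),
               paf_line("r2", 10, 0, 10, "+", "t", 100, 0, 10, "5=1X4="),
               paste("r3", 10, 0, 10, "+", "t", 100, 0, 10, 10, 10, 60,
                     sep = "\t")), f)
  expect_warning(aln <- read_alignments(f, "paf"), "skipped")
  expect_equal(nrow(aln), 2L)
  expect_equal(aln$cigar[1], "10=")
  expect_equal(aln$divergence[1], 0)
  expect_equal(aln$divergence[2], 0.1)  # 1 mismatch / 10 columns

  bad <- withr::local_tempfile(fileext = ".paf")
  writeLines(paf_line("r1", 10, 0, 10, "+", "t", 100, 5, 14, "10="), bad)
  expect_error(read_alignments(bad, "paf"), "inconsistent")
})

test_that("SAM POS is converted to 0-based and strand handled", {
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:t\tLN:500",
               paste("r1", 0, "t", 101, 60, "4S10=2D5=", "*", 0, 0,
                     paste0(random_dna(19)), "*", sep = "\t"),
               paste("r2", 16, "t", 11, 60, "10=", "*", 0, 0,
                     random_dna(10), "*", sep = "\t")), f)
  aln <- read_alignments(f, "sam")
  expect_equal(aln$target_start, c(100L, 10L))
  expect_equal(aln$target_end, c(100L + 17L, 20L))
  expect_equal(aln$query_start[1], 4L)
  expect_equal(aln$strand, c("+", "-"))
  expect_equal(aln$target_len, c(500L, 500L))
})

test_that("PAF writing and reading are mutually inverse", {
  set.seed(7)
  n <- 40
  cigs <- vapply(1:n, function(i) {
    ops <- sample(c("=", "X", "I", "D"), 4, replace = TRUE)
    paste0(paste0(sample(1:30, 4, replace = TRUE), ops), collapse = "")
  }, character(1))
  rows <- lapply(cigs, function(cg) {
    p <- parse_cigar(cg)
    qspan <- sum(p$len[p$op %in% c("=", "X", "M", "I")])
    tspan <- sum(p$len[p$op %in% c("=", "X", "M", "D")])
    qs <- sample(0:5, 1)
    data.frame(query_name = paste0("q", sample(1e6, 1)), query_len = qs + qspan + 3L,
               query_start = qs, query_end = qs + qspan,
               strand = sample(c("+", "-"), 1), target_name = "t",
               target_len = 10000L, target_start = 50L,
               target_end = 50L + tspan, mapq = 60L, cigar = cg,
               divergence = round(runif(1), 6), stringsAsFactors = FALSE)
  })
  aln <- do.call(rbind, rows)
  f <- withr::local_tempfile(fileext = ".paf")
  write_paf(aln, f)
  back <- read_alignments(f, "paf")
  expect_equal(back, aln, tolerance = 1e-9)
})

test_that("VCF writer/reader round-trip preserves GT, PS, SVTYPE, SVLEN, GROUPED", {
  v <- variant_table(chrom = rep("chr1", 4),
                     pos = c(100L, 200L, 300L, 400L),
                     ref = c("A", "A", paste0("A", random_dna(60)), "C"),
                     alt = c("T", paste0("A", random_dna(70)), "A", "G"),
                     alt2 = c(NA, NA, NA, "T"),
                     gt1 = c(0L, 1L, 1L, 1L), gt2 = c(1L, 0L, 1L, 2L),
                     phased = c(TRUE, TRUE, FALSE, TRUE),
                     phase_set = c(55L, 55L, NA, 7L),
                     sv_type = c(NA, "INS", "DEL", NA),
                     grouped_from = c(1L, 3L, 1L, 1L))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, f, contigs = c(chr1 = 1000L))
  txt <- readLines(f)
  expect_true(any(grepl("0\\|1:55", txt)))
  expect_true(any(grepl("SVTYPE=DEL;SVLEN=-60", txt)))
  back <- read_vcf(f)
  for (col in c("chrom", "pos", "ref", "alt", "alt2", "gt1", "gt2",
                "phased", "phase_set", "sv_type", "grouped_from",
                "sv_len", "var_class")) {
    expect_equal(back[[col]], v[[col]], info = col)
  }
  expect_error(write_vcf(v[c(2, 1), ], f), "sorted")
})

test_that("VCF round trip is field-identical on 1,000 randomized records", {
  set.seed(11)
  n <- 1000
  pos <- sort(sample.int(5e6, n))
  is_sv <- runif(n) < 0.2
  ref <- ifelse(is_sv & runif(n) < 0.5,
                vapply(1:n, function(i) paste0("A", random_dna(60)), character(1)),
                "A")
  alt <- ifelse(nchar(ref) > 1, "A",
                ifelse(is_sv, vapply(1:n, function(i) paste0("A", random_dna(55)),
                                     character(1)), "G"))
  phased <- runif(n) < 0.7
  v <- variant_table(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                     gt1 = sample(0:1, n, TRUE), gt2 = 1L,
                     phased = phased,
                     phase_set = ifelse(phased, sample(1e5, n, TRUE), NA))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, f)
  back <- read_vcf(f)
  expect_equal(nrow(back), n)
  for (col in c("pos", "ref", "alt", "gt1", "gt2", "phased", "phase_set",
                "sv_len", "var_class")) {
    expect_equal(back[[col]], v[[col]], info = col)
  }
})

test_that("our VCF output is parseable by an independent reader", {
  v <- variant_table(chrom = rep("chr1", 2), pos = c(10L, 20L),
                     ref = c("A", "CTT"), alt = c("G", "C"),
                     gt1 = 1L, gt2 = c(0L, 1L), phased = TRUE, phase_set = 3L)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, f, contigs = c(chr1 = 100L))
  x <- vcfR::read.vcfR(f, verbose = FALSE)
  expect_equal(as.integer(vcfR::getPOS(x)), c(10L, 20L))
  expect_equal(unname(vcfR::extract.gt(x)[, 1]), c("1|0", "1|1"))
})

test_that("BED reading skips headers, validates intervals, and merges on request", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=x", "# comment", "chr1\t1000\t1100",
               "chr1\t0\t10\tv", "chr1\t5\t20\tv"), f)
  bed <- read_bed(f)
  expect_equal(nrow(bed), 3L)
  expect_equal(bed$start[1], 1000L)
  merged <- read_bed(f, merge = TRUE)
  expect_equal(merged[merged$label == "v", c("start", "end")],
               data.frame(start = 0L, end = 20L), ignore_attr = TRUE)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t100", bad)
  expect_error(read_bed(bad), "start")
})

test_that("bedMethyl round-trips and rejects out-of-range percentages", {
  sites <- data.frame(chrom = "chr1", pos = c(10L, 11L, 50L),
                      strand = c("+", "-", "+"), coverage = c(12L, 8L, 30L),
                      meth_frac = c(0.75, 0.5, 0.25))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bedmethyl(sites, f)
  back <- read_bedmethyl(f)
  expect_equal(back, sites, tolerance = 1e-6)

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(), empty)
  expect_equal(nrow(read_bedmethyl(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste(c("chr1", 5, 6, "m", 0, "+", 5, 6, "0,0,0", 10, 150),
                   collapse = "\t"), bad)
  expect_error(read_bedmethyl(bad), "\\[0, 100\\]")
})

test_that("a SNP at internal offset k serializes at POS k + 1", {
  set.seed(3)
  for (k in sample(0:999, 20)) {
    v <- vrow(pos = k + 1L, ref = "A", alt = "T")
    f <- withr::local_tempfile(fileext = ".vcf")
    write_vcf(v, f)
    pos_field <- as.integer(strsplit(grep("^chr", readLines(f), value = TRUE),
                                     "\t")[[1]][2])
    expect_identical(pos_field, k + 1L)
  }
})

test_that("minimal_variant trims replacement records to pure indels", {
  m <- minimal_variant(100L, "ACGTACGT", "ACGT")
  expect_equal(m, list(pos = 100L, ref = "ACGTA", alt = "A"))
  # contiguous insertion inside a span reduces to a pure insertion
  m2 <- minimal_variant(50L, "AGGG", "AGGGTTGGG")
  expect_equal(nchar(m2$ref), 1L)
  expect_equal(nchar(m2$alt) - nchar(m2$ref), 5L)
  # SNP-like replacement keeps anchor semantics
  m3 <- minimal_variant(10L, "A", "T")
  expect_equal(m3, list(pos = 10L, ref = "A", alt = "T"))
})
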
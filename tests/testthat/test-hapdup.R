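# Dual assembly stage: read filtering, pileup SNP calling, haplotagging,
# chunk selection, consensus polishing, inversion handling.

mk_aln <- function(qname, qlen, qs, qe, ts, te, cigar, strand = "+",
                   divergence = 0, tname = "ctg", tlen = 1e6L) {
  data.frame(query_name = qname, query_len = qlen, query_start = qs,
             query_end = qe, strand = strand, target_name = tname,
             target_len = tlen, target_start = ts, target_end = te,
             mapq = 60L, cigar = cigar, divergence = divergence,
             stringsAsFactors = FALSE)
}

test_that("read filtering applies the length, divergence and unaligned-fraction rules", {
  a <- rbind(
    mk_aln("ok", 10000L, 0L, 9500L, 0L, 9500L, "9500=", divergence = 0.05),
    mk_aln("unaligned", 10000L, 0L, 5000L, 0L, 5000L, "5000=", divergence = 0.05),
    mk_aln("divergent", 10000L, 0L, 9500L, 0L, 9500L, "9500=", divergence = 0.12),
    mk_aln("short", 3000L, 0L, 3000L, 0L, 3000L, "3000=", divergence = 0.01))
  res <- filter_read_alignments(a)
  expect_setequal(res$kept$query_name, "ok")
  reasons <- setNames(res$removed$reason, res$removed$read)
  expect_equal(reasons[["unaligned"]], "unaligned_fraction")  # 0.5 > 0.20
  expect_equal(reasons[["divergent"]], "high_divergence")     # 0.12 > 0.09
  expect_equal(reasons[["short"]], "short_read")
  # empty input passes through
  empty <- filter_read_alignments(a[0, ])
  expect_equal(nrow(empty$kept), 0L)
})

test_that("divergence at exactly the 0.09 default is kept", {
  a <- mk_aln("edge", 10000L, 0L, 9500L, 0L, 9500L, "9500=", divergence = 0.09)
  expect_equal(nrow(filter_read_alignments(a)$kept), 1L)
})

test_that("pileup SNP calling separates het, hom and below-threshold sites", {
  target <- c(ctg = strrep("A", 50))
  # 10 reads over [0,50); 5 carry T at position 25 (0-based 24), 1 carries G at 10
  reads <- character(0)
  rows <- list()
  for (i in 1:10) {
    s <- strrep("A", 50)
    if (i <= 5) substr(s, 25, 25) <- "T"
    if (i == 1) substr(s, 10, 10) <- "G"
    nm <- paste0("r", i)
    reads[nm] <- s
    rows[[i]] <- mk_aln(nm, 50L, 0L, 50L, 0L, 50L, "50M")
  }
  snps <- call_het_snps(do.call(rbind, rows), reads, target,
                        min_coverage = 8L, min_alt_frac = 0.25)
  expect_equal(nrow(snps), 1L)  # the 1/10 G is below min_alt_frac
  expect_equal(snps$pos, 25L)
  expect_setequal(c(snps$ref, snps$alt), c("A", "T"))
  expect_true(snps$informative)
})

test_that("homozygous differences from the draft are emitted non-informative", {
  target <- c(ctg = strrep("A", 30))
  reads <- setNames(rep(paste0(strrep("A", 14), "C", strrep("A", 15)), 10),
                    paste0("r", 1:10))
  rows <- do.call(rbind, lapply(names(reads), function(nm)
    mk_aln(nm, 30L, 0L, 30L, 0L, 30L, "30M")))
  snps <- call_het_snps(rows, reads, target)
  expect_equal(nrow(snps), 1L)
  expect_false(snps$informative)
  expect_equal(c(snps$gt1, snps$gt2), c(1L, 1L))
})

test_that("haplotagging follows majority vote with ties untagged", {
  # two het SNPs at positions 10 and 20 (1-based), alleles A/T
  target <- c(ctg = strrep("A", 30))
  mk_read <- function(nm, b10, b20) {
    s <- strrep("A", 30)
    substr(s, 10, 10) <- b10
    substr(s, 20, 20) <- b20
    setNames(s, nm)
  }
  reads <- c(mk_read("h1a", "A", "A"), mk_read("h1b", "A", "A"),
             mk_read("h1c", "A", "A"),
             mk_read("h2a", "T", "T"), mk_read("h2b", "T", "T"),
             mk_read("h2c", "T", "T"),
             mk_read("tie", "A", "T"))
  rows <- do.call(rbind, lapply(names(reads), function(nm)
    mk_aln(nm, 30L, 0L, 30L, 0L, 30L, "30M")))
  snps <- call_het_snps(rows, reads, target, min_coverage = 5L)
  expect_equal(nrow(snps), 2L)
  ph <- phase_and_haplotag(snps, rows, reads)
  tags <- setNames(ph$haplotags$tag, ph$haplotags$read)
  expect_equal(tags[["tie"]], "untagged")
  same <- tags[c("h1a", "h1b", "h1c")]
  expect_true(all(same == same[1]) && same[1] != "untagged")
  expect_true(all(tags[c("h2a", "h2b", "h2c")] != same[1]))
  # phased output: both sites in one phase set, cis
  het <- ph$phased[ph$phased$gt1 != ph$phased$gt2, ]
  expect_equal(length(unique(het$phase_set)), 1L)
  expect_equal(het$gt1[1], het$gt1[2])  # A-A / T-T are in cis
  # canonicalization: first site REF-first
  expect_lt(het$gt1[1], het$gt2[1])
})

test_that("chunk boundaries avoid inconsistent-indel regions and partition the contig", {
  # no indels: boundaries at exact multiples
  a0 <- mk_aln("r1", 30000L, 0L, 30000L, 0L, 30000L, "30000=")
  ch0 <- select_chunk_boundaries(a0, 30000L)
  expect_equal(ch0$boundaries, c(0L, 10000L, 20000L, 30000L))

  # two reads with 10 bp insertions at contig positions 95 and 105:
  # the interval [85, 115] must contain no boundary
  a <- rbind(
    mk_aln("r1", 300L, 0L, 300L, 0L, 290L, "95=10I195="),
    mk_aln("r2", 300L, 0L, 300L, 0L, 290L, "105=10I185="))
  ch <- select_chunk_boundaries(a, 290L, chunk_size = 100L)
  expect_equal(nrow(ch$regions), 1L)
  expect_lte(ch$regions$start, 85L)
  expect_gte(ch$regions$end, 115L)
  inside <- ch$boundaries[ch$boundaries > 85 & ch$boundaries < 115]
  expect_length(inside, 0L)
  # partition: sorted, unique, starts at 0, ends at contig length
  expect_equal(ch$boundaries[1], 0L)
  expect_equal(ch$boundaries[length(ch$boundaries)], 290L)
  expect_false(is.unsorted(ch$boundaries, strictly = TRUE))
})

test_that("a region longer than the chunk size becomes its own chunk", {
  # two reads carrying jittered >= 5 bp deletions tiled across ~1.5 kb so
  # their padded intervals chain into one long inconsistent region
  mk_tiled <- function(nm, offset) {
    dels <- seq(1000L + offset, 2500L + offset, by = 15L)
    ops <- paste0(c(dels[1], diff(dels) - 6L), "=", "6D", collapse = "")
    tspan <- dels[length(dels)] + 6L + 100L
    qspan <- tspan - 6L * length(dels)
    mk_aln(nm, qspan, 0L, qspan, 0L, tspan, paste0(ops, "100="))
  }
  rows <- rbind(mk_tiled("r1", 0L), mk_tiled("r2", 7L))
  ch <- select_chunk_boundaries(rows, 5000L, chunk_size = 1000L)
  big <- ch$regions[ch$regions$end - ch$regions$start > 1000L, ]
  expect_equal(nrow(big), 1L)
  expect_true(big$start %in% ch$boundaries && big$end %in% ch$boundaries)
})

test_that("polishing corrects a draft substitution and flags uncovered chunks", {
  set.seed(13)
  true_seq <- random_dna(400)
  draft <- true_seq
  substr(draft, 201, 201) <- if (substr(true_seq, 201, 201) == "A") "C" else "A"
  reads <- setNames(rep(true_seq, 5), paste0("r", 1:5))
  rows <- do.call(rbind, lapply(names(reads), function(nm)
    mk_aln(nm, 400L, 0L, 400L, 0L, 400L, "200=1X199=")))
  pol <- polish_haplotype(draft, rows, reads)
  expect_identical(pol$seq, true_seq)
  expect_equal(nrow(pol$flagged), 0L)

  # zero coverage: chunk unchanged and flagged
  pol0 <- polish_haplotype(draft, rows[0, ], reads)
  expect_identical(pol0$seq, draft)
  expect_equal(pol0$flagged, data.frame(start = 0L, end = 400L))
})

test_that("consensus recovers haplotype-specific insertions and deletions", {
  set.seed(17)
  left <- random_dna(300); mid <- random_dna(40); right <- random_dna(300)
  draft <- paste0(left, right)               # hap lacking the insertion
  hap <- paste0(left, mid, right)            # hap carrying a 40 bp insertion
  reads <- setNames(rep(hap, 6), paste0("r", 1:6))
  rows <- do.call(rbind, lapply(names(reads), function(nm)
    mk_aln(nm, 640L, 0L, 640L, 0L, 600L, "300=40I300=")))
  pol <- polish_haplotype(draft, rows, reads)
  expect_identical(pol$seq, hap)
  # and a deletion: reads lacking 40 bp present in the draft
  reads2 <- setNames(rep(draft, 6), paste0("d", 1:6))
  rows2 <- do.call(rbind, lapply(names(reads2), function(nm)
    mk_aln(nm, 600L, 0L, 600L, 0L, 640L, "300=40D300=")))
  pol2 <- polish_haplotype(hap, rows2, reads2)
  expect_identical(pol2$seq, draft)
})

test_that("split-alignment insertion signatures are recovered", {
  set.seed(19)
  left <- random_dna(2000); ins <- random_dna(900); right <- random_dna(2000)
  draft <- paste0(left, right)
  hap <- paste0(left, ins, right)
  # reads split into two segments around the insertion
  reads <- setNames(rep(hap, 5), paste0("r", 1:5))
  rows <- do.call(rbind, lapply(names(reads), function(nm) rbind(
    mk_aln(nm, 4900L, 0L, 2000L, 0L, 2000L, "2000="),
    mk_aln(nm, 4900L, 2900L, 4900L, 2000L, 4000L, "2000="))))
  pol <- polish_haplotype(draft, rows, reads)
  expect_identical(pol$seq, hap)
})

test_that("inversion signatures require min_support and cluster breakpoints", {
  mk_split <- function(nm, jitter = 0L) rbind(
    mk_aln(nm, 30000L, 0L, 10000L, 0L, 10000L + jitter, sprintf("%d=", 10000L + jitter)),
    mk_aln(nm, 30000L, 10000L, 20000L, 10000L + jitter, 20000L - jitter,
           sprintf("%d=", 10000L - 2L * jitter), strand = "-"),
    mk_aln(nm, 30000L, 20000L, 30000L, 20000L - jitter, 30000L - jitter,
           sprintf("%d=", 10000L)))
  a6 <- do.call(rbind, lapply(1:6, function(i) mk_split(paste0("r", i),
                                                        jitter = 10L * i)))
  sig <- detect_inversions(a6, min_support = 3L)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$support, 6L)
  expect_lt(abs(sig$start - 10000L), 500L)
  expect_lt(abs(sig$end - 20000L), 500L)

  a2 <- do.call(rbind, lapply(1:2, function(i) mk_split(paste0("r", i))))
  expect_equal(nrow(detect_inversions(a2, min_support = 3L)), 0L)
})

test_that("applying a rearrangement twice restores the contig", {
  set.seed(23)
  contigs <- c(c1 = random_dna(500))
  sig <- data.frame(contig = "c1", start = 100L, end = 300L)
  once <- apply_rearrangements(contigs, sig)
  expect_false(identical(once, contigs))
  expect_identical(apply_rearrangements(once, sig), contigs)
  # empty signatures: unchanged
  expect_identical(apply_rearrangements(contigs, sig[0, ]), contigs)
  # errors
  expect_error(apply_rearrangements(contigs, data.frame(contig = "c1",
                                                        start = 100L, end = 600L)),
               "outside")
  expect_error(apply_rearrangements(
    contigs, data.frame(contig = "c1", start = c(100L, 200L), end = c(250L, 400L))),
    "overlapping")
})

test_that("emit_assembly produces dual and split layouts", {
  h1 <- c(ctg = "AAAA"); h2 <- c(ctg = "TTTT")
  dual <- emit_assembly(h1, h2, mode = "dual")
  expect_equal(length(dual), 2L)
  expect_setequal(names(dual), c("ctg_hap1", "ctg_hap2"))

  pb <- data.frame(contig = "ctg", start = c(0L, 2L, 3L), end = c(1L, 2L, 4L))
  split <- emit_assembly(h1, h2, pb, mode = "split")
  expect_equal(length(split), 6L)  # 3 parts per haplotype
  expect_equal(paste0(split[grepl("hap1", names(split))], collapse = ""), "AAAA")
})
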
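# Assembly-based SV calling: CIGAR-walk extraction, VNTR grouping,
# size filtering, diploid merge, reconstruction oracle.

ctg_aln <- function(qname, qlen, qs, qe, ts, te, cigar, strand = "+",
                    divergence = 0.001) {
  data.frame(query_name = qname, query_len = qlen, query_start = qs,
             query_end = qe, strand = strand, target_name = "chr1",
             target_len = 1e6L, target_start = ts, target_end = te,
             mapq = 60L, cigar = cigar, divergence = divergence,
             stringsAsFactors = FALSE)
}

test_that("CIGAR walk extraction anchors indels per VCF convention", {
  set.seed(31)
  ref <- c(chr1 = random_dna(300))
  rs <- ref[[1]]
  # deletion: contig matches 100, skips 60, matches 140
  ctg_del <- paste0(substr(rs, 1, 100), substr(rs, 161, 300))
  v <- extract_raw_variants(
    ctg_aln("c1", 240L, 0L, 240L, 0L, 300L, "100=60D140="),
    ref, c(c1 = ctg_del), haplotype = 1L)
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, 100L)
  expect_equal(v$sv_len, -60L)
  expect_equal(v$ref, substr(rs, 100, 160))
  expect_equal(v$alt, substr(rs, 100, 100))

  # insertion
  insert <- random_dna(60)
  ctg_ins <- paste0(substr(rs, 1, 100), insert, substr(rs, 101, 240))
  v2 <- extract_raw_variants(
    ctg_aln("c2", 300L, 0L, 300L, 0L, 240L, "100=60I140="),
    ref, c(c2 = ctg_ins), haplotype = 2L)
  expect_equal(v2$pos, 100L)
  expect_equal(v2$sv_len, 60L)
  expect_equal(v2$alt, paste0(substr(rs, 100, 100), insert))
  expect_equal(v2$gt2, 1L)

  # pure match: nothing
  v3 <- extract_raw_variants(ctg_aln("c3", 200L, 0L, 200L, 0L, 200L, "200="),
                             ref, c(c3 = substr(rs, 1, 200)), 1L)
  expect_equal(nrow(v3), 0L)
})

test_that("mismatch runs become per-base SNP records", {
  set.seed(32)
  ref <- c(chr1 = random_dna(100))
  ctg <- ref[[1]]
  substr(ctg, 51, 52) <- chartr("ACGT", "GTAC", substr(ctg, 51, 52))
  v <- extract_raw_variants(ctg_aln("c1", 100L, 0L, 100L, 0L, 100L, "50=2X48="),
                            ref, c(c1 = ctg), 1L)
  expect_equal(v$pos, c(51L, 52L))
  expect_true(all(v$var_class == "SNP"))
  expect_equal(v$alt, c(substr(ctg, 51, 51), substr(ctg, 52, 52)))
})

test_that("VNTR grouping merges decomposed indels into one record", {
  set.seed(33)
  unit <- random_dna(30)
  pre <- random_dna(100)
  post <- random_dna(100)
  ref_seq <- paste0(pre, strrep(unit, 4), post)
  ref <- c(chr1 = ref_seq)
  vntr <- data.frame(chrom = "chr1", start = 100L, end = 220L)

  # two +30 insertions at different unit boundaries (same final allele)
  mk_ins <- function(pos) {
    vrow(pos = pos, ref = substr(ref_seq, pos, pos),
         alt = paste0(substr(ref_seq, pos, pos), unit),
         gt1 = 1L, gt2 = 0L, haplotype = 1L)
  }
  raw <- sort_variants(rbind(mk_ins(130L), mk_ins(160L)))
  g <- group_vntr_indels(raw, vntr, ref)
  expect_equal(nrow(g), 1L)
  expect_equal(g$sv_len, 60L)
  expect_equal(g$grouped_from, 2L)
  expect_equal(g$var_class, "SV")   # passes the 50 bp threshold grouped
  # ungrouped, neither member passes the SV filter
  expect_equal(nrow(filter_svs(raw)), 0L)
  expect_equal(nrow(filter_svs(g)), 1L)

  # representation invariance: one +60 insertion anywhere in the array
  # yields the identical grouped record
  one <- vrow(pos = 190L, ref = substr(ref_seq, 190, 190),
              alt = paste0(substr(ref_seq, 190, 190), strrep(unit, 2)),
              gt1 = 1L, gt2 = 0L, haplotype = 1L)
  g2 <- group_vntr_indels(one, vntr, ref)
  expect_equal(g2$pos, g$pos)
  expect_equal(g2$ref, g$ref)
  expect_equal(g2$alt, g$alt)
  expect_equal(g2$sv_len, g$sv_len)
})

test_that("mixed indels in one VNTR net out and reclassify", {
  set.seed(34)
  ref_seq <- random_dna(400)
  ref <- c(chr1 = ref_seq)
  vntr <- data.frame(chrom = "chr1", start = 100L, end = 300L)
  ins30 <- vrow(pos = 120L, ref = substr(ref_seq, 120, 120),
                alt = paste0(substr(ref_seq, 120, 120), random_dna(30)),
                haplotype = 1L)
  del30 <- vrow(pos = 200L, ref = substr(ref_seq, 200, 230),
                alt = substr(ref_seq, 200, 200), haplotype = 1L)
  g <- group_vntr_indels(sort_variants(rbind(ins30, del30)), vntr, ref)
  expect_equal(nrow(g), 1L)
  expect_equal(g$sv_len, 0L)
  expect_equal(g$var_class, "INDEL")

  # an indel outside every VNTR passes through unchanged
  far <- vrow(pos = 390L, ref = substr(ref_seq, 390, 390),
              alt = paste0(substr(ref_seq, 390, 390), "TTTTT"), haplotype = 1L)
  g2 <- group_vntr_indels(far, vntr, ref)
  expect_equal(g2$pos, far$pos)
  expect_equal(g2$grouped_from, 1L)
})

test_that("grouped records reconstruct the contig allele over the VNTR", {
  set.seed(35)
  unit <- random_dna(25)
  ref_seq <- paste0(random_dna(80), strrep(unit, 6), random_dna(80))
  ref <- c(chr1 = ref_seq)
  vntr <- data.frame(chrom = "chr1", start = 80L, end = 230L)
  # contig allele: two extra units, aligner splits them 1 + 1
  raw <- sort_variants(rbind(
    vrow(pos = 105L, ref = substr(ref_seq, 105, 105),
         alt = paste0(substr(ref_seq, 105, 105), unit), haplotype = 1L),
    vrow(pos = 180L, ref = substr(ref_seq, 180, 180),
         alt = paste0(substr(ref_seq, 180, 180), unit), haplotype = 1L)))
  g <- group_vntr_indels(raw, vntr, ref)
  # applying the grouped record to the reference reproduces applying the
  # raw records (local reconstruction)
  g$gt1 <- 1L; g$gt2 <- 0L
  raw$gt1 <- 1L; raw$gt2 <- 0L
  expect_identical(apply_variants(ref_seq, g, 1L),
                   apply_variants(ref_seq, raw, 1L))
})

test_that("SV size filter keeps >= 50 bp including grouped and inversions", {
  v49 <- vrow(pos = 100L, ref = paste0("A", strrep("C", 49)), alt = "A")
  v50 <- vrow(pos = 300L, ref = paste0("A", strrep("C", 50)), alt = "A")
  both <- sort_variants(rbind(v49, v50))
  kept <- filter_svs(both)
  expect_equal(kept$pos, 300L)
  expect_lte(nrow(kept), nrow(both))
  inv <- variant_table(chrom = "chr1", pos = 500L,
                       ref = paste0("A", strrep("C", 80)),
                       alt = paste0("A", strrep("G", 80)), sv_type = "INV")
  expect_equal(nrow(filter_svs(inv)), 1L)
})

test_that("diploid merge genotypes shared, single-hap and colliding records", {
  set.seed(36)
  del_ref <- paste0("A", random_dna(60))
  h1 <- vrow(pos = 1000L, ref = del_ref, alt = "A", haplotype = 1L)
  h2 <- vrow(pos = 1005L, ref = del_ref, alt = "A", haplotype = 2L)
  m <- merge_diploid(h1, h2)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$gt1, m$gt2), c(1L, 1L))

  # one-haplotype-only record
  only1 <- merge_diploid(h1, h1[0, ])
  expect_equal(c(only1$gt1, only1$gt2), c(1L, 0L))
  only2 <- merge_diploid(h1[0, ], h2)
  expect_equal(c(only2$gt1, only2$gt2), c(0L, 1L))

  # same anchor, sizes 100 vs 55 (ratio 0.55 < 0.7): multiallelic 1|2
  i1 <- vrow(pos = 2000L, ref = "A", alt = paste0("A", random_dna(100)),
             haplotype = 1L)
  i2 <- vrow(pos = 2000L, ref = "A", alt = paste0("A", random_dna(55)),
             haplotype = 2L)
  mm <- merge_diploid(i1, i2)
  expect_equal(nrow(mm), 1L)
  expect_equal(c(mm$gt1, mm$gt2), c(1L, 2L))
  expect_false(is.na(mm$alt2))
})

test_that("overlapping reference alignments drop the lower-identity contig", {
  set.seed(37)
  ref <- c(chr1 = random_dna(500))
  rs <- ref[[1]]
  good <- ctg_aln("good", 400L, 0L, 400L, 0L, 400L, "400=", divergence = 0.001)
  bad <- ctg_aln("bad", 300L, 0L, 300L, 200L, 500L, "150=1X149=",
                 divergence = 0.05)
  contigs <- c(good = substr(rs, 1, 400),
               bad = paste0(substr(rs, 201, 350), "T", substr(rs, 352, 500)))
  expect_warning(v <- extract_raw_variants(rbind(good, bad), ref, contigs, 1L),
                 "overlapping")
  expect_equal(nrow(v), 0L)  # the mismatch lived on the dropped alignment
})
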
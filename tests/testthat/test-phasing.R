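# Joint phasing: VCF merging, reference-expansion allele windows,
# emission probabilities, maximum-likelihood partition vs brute force.

test_that("merge_vcfs concatenates, sorts and deduplicates keeping the SV record", {
  a <- sort_variants(rbind(vrow(pos = 10L, ref = "A", alt = "T"),
                           vrow(pos = 50L, ref = "C", alt = "G")))
  b <- sort_variants(rbind(vrow(pos = 30L, ref = "G", alt = "C"),
                           vrow(pos = 50L, ref = "C", alt = "G")))
  m <- merge_vcfs(a, b)
  expect_equal(m$pos, c(10L, 30L, 50L))          # |A| + |B| - duplicates
  expect_equal(nrow(m), nrow(a) + nrow(b) - 1L)

  # disjoint inputs: plain sorted concatenation
  d <- merge_vcfs(a, sort_variants(vrow(pos = 5L, ref = "T", alt = "A")))
  expect_equal(d$pos, c(5L, 10L, 50L))

  # conflicting genotype on the duplicate warns and keeps the SV record
  b2 <- b
  b2$gt1 <- c(0L, 1L); b2$gt2 <- c(1L, 1L)
  expect_warning(m2 <- merge_vcfs(a, b2), "conflicting")
  expect_equal(m2$gt2[m2$pos == 50L], 1L)
})

test_that("allele windows use the 12 bp small and 64 bp SV expansions", {
  set.seed(41)
  ref <- c(chr1 = random_dna(1000))
  snp <- vrow(pos = 500L, ref = substr(ref, 500, 500),
              alt = setdiff(c("A", "C", "G", "T"), substr(ref, 500, 500))[1])
  ex <- extract_allele_sequences(ref, snp)
  expect_equal(unname(nchar(ex$alleles)), c(25L, 25L))  # 12 + 1 + 12
  expect_equal(diff(ex$window), 25)

  del60 <- vrow(pos = 400L, ref = substr(ref, 400, 460),
                alt = substr(ref, 400, 400))
  ex2 <- extract_allele_sequences(ref, del60)
  expect_equal(ex2$window, c(399 - 64, 460 + 64))       # 60 >= 50: expansion 64
  expect_equal(unname(nchar(ex2$alleles)), c(64 + 61 + 64, 64 + 1 + 64))

  # clipping at the chromosome start
  edge <- vrow(pos = 3L, ref = substr(ref, 3, 3), alt = "A")
  ex3 <- extract_allele_sequences(ref, edge)
  expect_equal(ex3$window[1], 0)
  expect_equal(unname(nchar(ex3$alleles))[1], 2 + 1 + 12)
})

test_that("emission probabilities follow the epsilon^d (1-eps)^(L-d) model", {
  set.seed(42)
  ref <- c(chr1 = random_dna(200))
  v <- vrow(pos = 100L, ref = substr(ref, 100, 100),
            alt = setdiff(c("A", "C", "G", "T"), substr(ref, 100, 100))[1])
  ex <- extract_allele_sequences(ref, v)
  read <- ref[[1]]  # read matches the reference allele exactly
  aln <- data.frame(query_name = "r", query_len = 200L, query_start = 0L,
                    query_end = 200L, strand = "+", target_name = "chr1",
                    target_len = 200L, target_start = 0L, target_end = 200L,
                    mapq = 60L, cigar = "200=", divergence = 0,
                    stringsAsFactors = FALSE)
  p <- score_read_allele(read, aln, ex, phasing_config(base_error = 0.1))
  # d_ref = 0, d_alt = 1 on a SNP: odds (0.9/0.1)^1 = 9
  expect_equal(unname(p["0"] / p["1"]), 9, tolerance = 1e-9)

  # d_A = 0 vs d_B = 3 at eps = 0.1: P(A) = 729/730
  pA <- dualvar:::allele_probs_from_subseq("AAAA", c(A = "AAAA", B = "TTTA"), 0.1)
  expect_equal(unname(pA["A"]), 729 / 730, tolerance = 1e-6)
  expect_equal(unname(pA["A"]), 0.99863, tolerance = 1e-4)

  # tied distances: exactly 0.5 / 0.5
  pT <- dualvar:::allele_probs_from_subseq("AAAA", c(A = "AAAT", B = "AATA"), 0.1)
  expect_equal(unname(pT), c(0.5, 0.5), tolerance = 1e-9)

  # eps -> 0 limit: certainty for the exact-match allele
  p0 <- dualvar:::allele_probs_from_subseq("AAAA", c(A = "AAAA", B = "TTTA"), 1e-9)
  expect_gt(unname(p0["A"]), 1 - 1e-6)

  # a read not spanning the window is uninformative
  short_aln <- aln
  short_aln$target_end <- 100L
  short_aln$query_end <- 100L
  short_aln$cigar <- "100="
  expect_null(score_read_allele(substr(read, 1, 100), short_aln, ex,
                                phasing_config()))
})

test_that("cis-dominant supports give one phase set in cis; no sharing splits sets", {
  vars <- sort_variants(rbind(vrow(pos = 100L, ref = "A", alt = "T"),
                              vrow(pos = 200L, ref = "C", alt = "G")))
  eps <- 0.1
  cis <- do.call(rbind, lapply(1:10, function(r) {
    hap <- if (r <= 5) 1L else 2L
    lp_hit <- log(1 - eps); lp_miss <- log(eps)
    data.frame(read = paste0("r", r), vidx = 1:2,
               lp1 = if (hap == 1L) lp_hit else lp_miss,
               lp2 = if (hap == 1L) lp_miss else lp_hit)
  }))
  ph <- phase_variants(vars, cis)
  expect_equal(length(unique(ph$phase_set)), 1L)
  expect_true(all(ph$phased))
  expect_equal(ph$gt1[1], ph$gt1[2])             # cis
  expect_equal(c(ph$gt1[1], ph$gt2[1]), c(0L, 1L))  # canonical REF-first

  # no shared reads: two phase sets
  solo <- cis[c(1, 4), ]
  solo$read <- c("a", "b")
  solo$vidx <- c(1L, 2L)
  ph2 <- phase_variants(vars, solo)
  expect_equal(length(unique(ph2$phase_set)), 2L)
})

test_that("hill-climbed phasing attains the brute-force optimum (200 instances)", {
  set.seed(77)
  for (rep in 1:200) {
    n <- sample(2:12, 1)
    inst <- random_phase_instance(n, n_reads = sample(5:20, 1))
    ph <- phase_variants(inst$variants, inst$supports)
    ori <- attr(ph, "orientation")
    ll_method <- phase_log_likelihood(inst$supports, ori)
    ll_brute <- brute_force_phase_ll(inst$supports, n)
    expect_equal(ll_method, ll_brute, tolerance = 1e-9)
  }
})

test_that("an SV bridging a small-variant desert joins the flanking blocks", {
  # sites 1,2 on the left, site 4,5 on the right, SV site 3 in the middle;
  # reads span (1,2,3) or (3,4,5) only
  vars <- sort_variants(rbind(
    vrow(pos = 100L, ref = "A", alt = "T"),
    vrow(pos = 200L, ref = "A", alt = "T"),
    vrow(pos = 5000L, ref = "A", alt = paste0("A", strrep("G", 80))),
    vrow(pos = 9800L, ref = "A", alt = "T"),
    vrow(pos = 9900L, ref = "A", alt = "T")))
  lp <- function(hit) ifelse(hit, log(0.9), log(0.1))
  mk <- function(read, vids, hap) {
    data.frame(read = read, vidx = vids,
               lp1 = lp(hap == 1L), lp2 = lp(hap == 2L))
  }
  sup_with_sv <- rbind(mk("l1", 1:3, 1L), mk("l2", 1:3, 2L),
                       mk("r1", 3:5, 1L), mk("r2", 3:5, 2L),
                       mk("l3", 1:3, 1L), mk("r3", 3:5, 2L))
  ph <- phase_variants(vars, sup_with_sv)
  expect_equal(length(unique(ph$phase_set)), 1L)

  sup_no_sv <- sup_with_sv[sup_with_sv$vidx != 3L, ]
  ph2 <- phase_variants(vars[-3, ], transform(sup_no_sv,
                                              vidx = ifelse(vidx > 3L, vidx - 1L, vidx)))
  expect_equal(length(unique(ph2$phase_set)), 2L)
})

test_that("homozygous records pass through phased and inherit the phase set", {
  vars <- sort_variants(rbind(
    vrow(pos = 100L, ref = "A", alt = "T"),
    vrow(pos = 150L, ref = "C", alt = "G", gt1 = 1L, gt2 = 1L),
    vrow(pos = 200L, ref = "A", alt = "T")))
  sup <- do.call(rbind, lapply(1:4, function(r) {
    hap <- if (r <= 2) 1L else 2L
    data.frame(read = paste0("r", r), vidx = c(1L, 3L),
               lp1 = ifelse(hap == 1L, log(0.9), log(0.1)),
               lp2 = ifelse(hap == 1L, log(0.1), log(0.9)))
  }))
  ph <- phase_variants(vars, sup)
  expect_true(all(ph$phased))
  expect_equal(length(unique(ph$phase_set)), 1L)
  hom <- ph[ph$pos == 150L, ]
  expect_equal(c(hom$gt1, hom$gt2), c(1L, 1L))
})
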
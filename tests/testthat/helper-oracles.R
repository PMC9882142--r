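# Shared fixtures and independent oracles used across the suite.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Brute-force switch/Hamming computation for one block: enumerate both
# global orientations explicitly and count everything by hand.
brute_switch_hamming <- function(truth_bits, test_bits) {
  n <- length(truth_bits)
  diff1 <- as.integer(truth_bits != test_bits)        # orientation A
  diff2 <- as.integer(truth_bits == test_bits)        # orientation B (flipped)
  hamming <- min(sum(diff1), sum(diff2)) / n
  # switch: relative phase between adjacent pairs, orientation-free
  sw <- 0L
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      rel_truth <- truth_bits[i] == truth_bits[i + 1L]
      rel_test <- test_bits[i] == test_bits[i + 1L]
      if (rel_truth != rel_test) sw <- sw + 1L
    }
  }
  list(switch = if (n >= 2L) sw / (n - 1L) else NA_real_, hamming = hamming)
}

# Brute-force maximum of the phasing objective over all 2^(n-1)
# orientations (first site fixed), via the exported objective function.
brute_force_phase_ll <- function(supports, n_sites) {
  best <- -Inf
  for (mask in 0:(2^(n_sites - 1L) - 1L)) {
    bits <- c(0L, as.integer(intToBits(mask))[seq_len(n_sites - 1L)])
    ll <- phase_log_likelihood(supports, bits)
    if (ll > best) best <- ll
  }
  best
}

# Random phasing instance: n_sites het SNPs, reads covering random
# windows, supports consistent with a random true orientation plus noise.
random_phase_instance <- function(n_sites, n_reads, flip_prob = 0.1,
                                  eps = 0.1) {
  vars <- variant_table(chrom = rep("c", n_sites),
                        pos = seq_len(n_sites) * 100L,
                        ref = rep("A", n_sites), alt = rep("T", n_sites),
                        gt1 = 0L, gt2 = 1L)
  truth <- sample(0:1, n_sites, replace = TRUE)
  # window list: random reads plus two guaranteed reads per adjacent pair
  # so the whole instance is one linked component (>= 2 linking reads)
  windows <- lapply(seq_len(n_reads), function(r) {
    a <- sample.int(n_sites, 1L)
    c(a, min(n_sites, a + sample.int(4L, 1L)))
  })
  if (n_sites >= 2L) {
    for (v in seq_len(n_sites - 1L)) {
      windows <- c(windows, list(c(v, v + 1L)), list(c(v, v + 1L)))
    }
  }
  rows <- list()
  for (r in seq_along(windows)) {
    a <- windows[[r]][1]; b <- windows[[r]][2]
    hap <- sample(1:2, 1L)
    for (v in a:b) {
      carried <- if (hap == 1L) truth[v] else 1L - truth[v]
      if (runif(1) < flip_prob) carried <- 1L - carried
      lp <- c(log(eps), log(eps))
      lp[carried + 1L] <- log(1 - eps)
      rows[[length(rows) + 1L]] <- data.frame(
        read = paste0("r", r), vidx = v, lp1 = lp[1], lp2 = lp[2])
    }
  }
  list(variants = vars, supports = do.call(rbind, rows))
}

# Cumulative-sum NGx oracle, written independently of ngx().
ngx_oracle <- function(lengths, genome_size, x) {
  s <- rev(sort(lengths))
  total <- 0
  for (l in s) {
    total <- total + l
    if (total >= genome_size * x / 100) return(l)
  }
  0
}

# Minimal one-row variant table helper.
vrow <- function(chrom = "chr1", pos, ref, alt, gt1 = 0L, gt2 = 1L, ...) {
  variant_table(chrom = chrom, pos = pos, ref = ref, alt = alt,
                gt1 = gt1, gt2 = gt2, ...)
}

# Construct a PAF line with given fields and cg tag.
paf_line <- function(qname, qlen, qs, qe, strand, tname, tlen, ts, te,
                     cigar, mapq = 60L) {
  cig <- dualvar::parse_cigar(cigar)
  nmatch <- sum(cig$len[cig$op %in% c("=", "M")])
  paste(qname, qlen, qs, qe, strand, tname, tlen, ts, te, nmatch,
        te - ts, mapq, paste0("cg:Z:", cigar), sep = "\t")
}
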
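# Benchmarking metrics: phasing switch/Hamming error, distance-bounded
# SV set comparison, small-variant precision/recall, NGx contiguity, and
# SV catalog frequency annotation.

#' SV matching configuration
#'
#' Defaults mirror distance-bounded SV benchmarking practice: maximum
#' anchor distance 2000 bp, size ratio 0.7, insertion sequence similarity
#' 0.7.
#'
#' @param max_dist Maximum anchor distance in bp.
#' @param size_ratio Minimum min/max size ratio.
#' @param seq_similarity Minimum insertion sequence edit similarity.
#' @param require_genotype If TRUE, matches must also agree on the
#'   unordered genotype.
#' @return An `sv_match_config` list.
#' @export
sv_match_config <- function(max_dist = 2000L, size_ratio = 0.7,
                            seq_similarity = 0.7, require_genotype = FALSE) {
  stopifnot(max_dist >= 0, size_ratio > 0, size_ratio <= 1,
            seq_similarity > 0, seq_similarity <= 1)
  structure(list(max_dist = as.integer(max_dist), size_ratio = size_ratio,
                 seq_similarity = seq_similarity,
                 require_genotype = isTRUE(require_genotype)),
            class = "sv_match_config")
}

prf_counts <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision > 0 && recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall, f1 = f1)
}

#' Switch and Hamming phasing error
#'
#' Comparison is restricted to sites heterozygous and phased in both call
#' sets (matched on chrom, pos, ref, alt). Within each test phase block,
#' the switch rate is the fraction of adjacent site pairs whose relative
#' phase disagrees with truth; the Hamming rate is the fraction of sites
#' assigned to the wrong haplotype under the better of the two global
#' block orientations. Pooled rates are count-weighted over blocks.
#'
#' @param truth_phased,test_phased Phased variant tables.
#' @return List with `per_block` (block, n_sites, switch, hamming),
#'   `switch_rate`, `hamming_rate` (pooled).
#' @export
switch_hamming <- function(truth_phased, test_phased) {
  het <- function(df) df[df$gt1 != df$gt2 & df$phased, , drop = FALSE]
  tr <- het(truth_phased); te <- het(test_phased)
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")
  m <- match(key(te), key(tr))
  shared <- !is.na(m)
  if (!any(shared)) stop("no shared phased heterozygous sites to compare")
  te <- te[shared, , drop = FALSE]
  tr <- tr[m[shared], , drop = FALSE]
  # binary orientation: does test hap1 carry the same allele as truth hap1?
  diff_bit <- as.integer(te$gt1 != tr$gt1)
  blocks <- split(seq_len(nrow(te)), paste(te$chrom, te$phase_set, sep = "\r"))
  per <- list(); sw_num <- 0L; sw_den <- 0L; hm_num <- 0L; hm_den <- 0L
  for (bn in names(blocks)) {
    idx <- blocks[[bn]]
    idx <- idx[order(te$pos[idx])]
    b <- diff_bit[idx]
    n <- length(b)
    switches <- if (n >= 2L) sum(b[-1] != b[-n]) else 0L
    pairs <- max(n - 1L, 0L)
    mism <- min(sum(b), n - sum(b))
    per[[length(per) + 1L]] <- data.frame(
      block = bn, n_sites = n,
      switch = if (pairs > 0) switches / pairs else NA_real_,
      hamming = mism / n, stringsAsFactors = FALSE)
    sw_num <- sw_num + switches; sw_den <- sw_den + pairs
    hm_num <- hm_num + mism; hm_den <- hm_den + n
  }
  list(per_block = do.call(rbind, per),
       switch_rate = if (sw_den > 0) sw_num / sw_den else NA_real_,
       hamming_rate = hm_num / hm_den)
}

sv_type_class <- function(df) {
  ifelse(!is.na(df$sv_type) & df$sv_type == "INV", "INV",
         ifelse(df$sv_len >= 0, "INS", "DEL"))
}

# Edit similarity of two inserted sequences, tolerant to the phase
# ambiguity of tandem-repeat insertions: the same inserted array can be
# reported rotated by a unit, so the shorter sequence is also matched
# against a doubled copy of the longer (best substring distance).
ins_seq_similarity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la == 0L && lb == 0L) return(1)
  plain <- 1 - as.integer(utils::adist(a, b)) / max(la, lb, 1L)
  shorter <- if (la <= lb) a else b
  longer <- if (la <= lb) b else a
  rot <- 1 - (as.integer(utils::adist(shorter, paste0(longer, longer),
                                      partial = TRUE)) +
                abs(la - lb)) / max(la, lb, 1L)
  max(plain, rot)
}

#' Compare two structural variant sets
#'
#' Candidate pairs require the same chromosome and type class, anchor
#' distance within `max_dist`, size ratio at least `size_ratio` and (for
#' insertions) alt-sequence edit similarity at least `seq_similarity`.
#' One-to-one matching proceeds greedily by best combined distance+size
#' score, ties broken by position then input order.
#'
#' @param truth_svs,test_svs SV variant tables.
#' @param cfg An [sv_match_config()].
#' @return List with the `PRF` fields (`tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`) and `matches` (truth_idx, test_idx, score).
#' @export
compare_sv_sets <- function(truth_svs, test_svs, cfg = sv_match_config()) {
  nT <- nrow(truth_svs); nQ <- nrow(test_svs)
  cls_T <- sv_type_class(truth_svs); cls_Q <- sv_type_class(test_svs)
  pairs <- list()
  for (i in seq_len(nT)) {
    cand <- which(test_svs$chrom == truth_svs$chrom[i] & cls_Q == cls_T[i] &
                    abs(test_svs$pos - truth_svs$pos[i]) <= cfg$max_dist)
    for (j in cand) {
      sz_t <- abs(truth_svs$sv_len[i]); sz_q <- abs(test_svs$sv_len[j])
      ratio <- min(sz_t, sz_q) / max(sz_t, sz_q, 1L)
      if (ratio < cfg$size_ratio) next
      if (cls_T[i] == "INS") {
        # compare inserted sequences on the minimal representation; a
        # replacement record (e.g. a grouped VNTR edit that is not one
        # contiguous insertion) has no comparable inserted sequence and
        # falls back to the position + size criteria
        mt <- minimal_variant(truth_svs$pos[i], truth_svs$ref[i], truth_svs$alt[i])
        mq <- minimal_variant(test_svs$pos[j], test_svs$ref[j], test_svs$alt[j])
        if (nchar(mt$ref) == 1L && nchar(mq$ref) == 1L) {
          sim <- ins_seq_similarity(substring(mt$alt, 2L), substring(mq$alt, 2L))
          if (sim < cfg$seq_similarity) next
        }
      }
      if (cfg$require_genotype) {
        g_t <- sort(c(truth_svs$gt1[i], truth_svs$gt2[i]))
        g_q <- sort(c(test_svs$gt1[j], test_svs$gt2[j]))
        if (!identical(g_t, g_q)) next
      }
      score <- abs(test_svs$pos[j] - truth_svs$pos[i]) / max(cfg$max_dist, 1L) +
        (1 - ratio)
      pairs[[length(pairs) + 1L]] <- data.frame(truth_idx = i, test_idx = j,
                                                score = score)
    }
  }
  matches <- data.frame(truth_idx = integer(), test_idx = integer(),
                        score = numeric())
  if (length(pairs)) {
    p <- do.call(rbind, pairs)
    p <- p[order(p$score, truth_svs$pos[p$truth_idx], p$truth_idx, p$test_idx), ]
    used_t <- logical(nT); used_q <- logical(nQ)
    keep <- logical(nrow(p))
    for (k in seq_len(nrow(p))) {
      if (!used_t[p$truth_idx[k]] && !used_q[p$test_idx[k]]) {
        keep[k] <- TRUE
        used_t[p$truth_idx[k]] <- TRUE
        used_q[p$test_idx[k]] <- TRUE
      }
    }
    matches <- p[keep, , drop = FALSE]
    rownames(matches) <- NULL
  }
  tp <- nrow(matches)
  c(prf_counts(tp = tp, fp = nQ - tp, fn = nT - tp), list(matches = matches))
}

#' Small-variant precision/recall split by SNP and indel
#'
#' A match requires identical (chrom, pos, ref, alt) and the same
#' unordered genotype; both inputs are assumed normalized (left-aligned,
#' minimal alleles). When `confident_bed` is given, records outside the
#' confident regions are ignored in all counts.
#'
#' @param truth,test Variant tables.
#' @param confident_bed Optional BED data.frame of confident regions.
#' @return List with `snp` and `indel` PRF lists.
#' @export
small_variant_prf <- function(truth, test, confident_bed = NULL) {
  restrict <- function(df) {
    if (is.null(confident_bed) || nrow(df) == 0L) return(df)
    keep <- vapply(seq_len(nrow(df)), function(i) {
      any(confident_bed$chrom == df$chrom[i] &
            confident_bed$start < df$pos[i] &
            confident_bed$end >= df$pos[i])
    }, logical(1))
    df[keep, , drop = FALSE]
  }
  tr <- restrict(truth[truth$var_class != "SV", , drop = FALSE])
  te <- restrict(test[test$var_class != "SV", , drop = FALSE])
  gkey <- function(df) paste(df$chrom, df$pos, df$ref, df$alt,
                             pmin(df$gt1, df$gt2), pmax(df$gt1, df$gt2),
                             sep = "\r")
  out <- list()
  for (cls in c("SNP", "INDEL")) {
    a <- tr[tr$var_class == cls, , drop = FALSE]
    b <- te[te$var_class == cls, , drop = FALSE]
    tp <- sum(gkey(b) %in% gkey(a))
    out[[tolower(cls)]] <- prf_counts(tp = tp, fp = nrow(b) - tp,
                                      fn = nrow(a) - tp)
  }
  names(out) <- c("snp", "indel")
  out
}

#' NGx assembly contiguity
#'
#' The length of the contig at which the cumulative length of contigs
#' sorted in decreasing order reaches x% of the genome size; 0 when the
#' total never reaches it.
#'
#' @param lengths Positive contig lengths.
#' @param genome_size Genome size in bp.
#' @param x Percentage in (0, 100].
#' @return NGx in bp.
#' @export
ngx <- function(lengths, genome_size, x = 50) {
  if (genome_size <= 0) stop("genome_size must be positive")
  stopifnot(all(lengths > 0), x > 0, x <= 100)
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(s))
  idx <- which(cum >= genome_size * x / 100)
  if (length(idx) == 0L) return(0)
  s[idx[1]]
}

#' Annotate SVs with catalog population frequency
#'
#' Deletions and inversions match catalog records by reciprocal overlap
#' of at least `min_overlap`; insertions (spanless on the reference)
#' match by anchor distance within `max_dist` and size ratio at least
#' `min_overlap`. The rarity flag is set when the maximum matched allele
#' frequency is below `rare_af` or no record matches.
#'
#' @param svs SV variant table.
#' @param catalog data.frame (`chrom`, `start`, `end`, `sv_type`,
#'   `sv_len`, `af`), intervals 0-based half-open.
#' @param min_overlap Reciprocal overlap / size-ratio threshold (default 0.10).
#' @param max_dist Insertion anchor distance bound (default 2000).
#' @param rare_af Allele-frequency threshold for rarity (default 0.01).
#' @return `svs` with `max_af` (NA when unmatched) and `rare` columns.
#' @export
annotate_sv_frequency <- function(svs, catalog, min_overlap = 0.10,
                                  max_dist = 2000L, rare_af = 0.01) {
  cls <- sv_type_class(svs)
  max_af <- rep(NA_real_, nrow(svs))
  for (i in seq_len(nrow(svs))) {
    if (cls[i] == "INS") {
      anchor <- svs$pos[i] - 1L
      cand <- which(catalog$chrom == svs$chrom[i] & catalog$sv_type == "INS" &
                      abs(catalog$start - anchor) <= max_dist)
      if (length(cand)) {
        sz_q <- abs(svs$sv_len[i]); sz_c <- abs(catalog$sv_len[cand])
        ratio <- pmin(sz_q, sz_c) / pmax(sz_q, sz_c, 1L)
        cand <- cand[ratio >= min_overlap]
      }
    } else {
      qs <- svs$pos[i]; qe <- svs$pos[i] + nchar(svs$ref[i]) - 1L
      cand <- which(catalog$chrom == svs$chrom[i] & catalog$sv_type == cls[i])
      if (length(cand)) {
        ov <- pmin(qe, catalog$end[cand]) - pmax(qs, catalog$start[cand])
        ok <- ov > 0 &
          ov / (qe - qs) >= min_overlap &
          ov / (catalog$end[cand] - catalog$start[cand]) >= min_overlap
        cand <- cand[ok]
      }
    }
    if (length(cand)) max_af[i] <- max(catalog$af[cand])
  }
  svs$max_af <- max_af
  svs$rare <- is.na(max_af) | max_af < rare_af
  svs
}
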
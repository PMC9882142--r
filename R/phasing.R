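# Joint phasing of small and structural variants via reference-expansion
# allele-support scoring, and the maximum-likelihood two-haplotype
# partition used both here and for haplotagging in the dual-assembly
# stage.

#' Phasing configuration
#'
#' `ref_expansion_small` / `ref_expansion_sv` are the number of reference
#' bases added up- and downstream of a variant when extracting per-allele
#' sequences; the larger SV expansion absorbs breakpoint placement
#' ambiguity in read alignments. `sv_size_threshold` separates the two
#' regimes. `base_error` is the per-base error rate of the emission model.
#'
#' @param ref_expansion_small Expansion for small variants (bp, default 12).
#' @param ref_expansion_sv Expansion for structural variants (bp, default 64).
#' @param sv_size_threshold Allele length difference (bp) at which a
#'   variant is treated as structural (default 50).
#' @param base_error Emission error rate epsilon in (0, 0.5) (default 0.10).
#' @param min_link_reads Minimum reads linking two variants for them to
#'   share a phase set (default 2).
#' @return A `phasing_config` list.
#' @export
phasing_config <- function(ref_expansion_small = 12L, ref_expansion_sv = 64L,
                           sv_size_threshold = 50L, base_error = 0.10,
                           min_link_reads = 2L) {
  stopifnot(ref_expansion_small > 0, ref_expansion_sv > 0,
            sv_size_threshold >= 1, base_error > 0, base_error < 0.5)
  structure(list(ref_expansion_small = as.integer(ref_expansion_small),
                 ref_expansion_sv = as.integer(ref_expansion_sv),
                 sv_size_threshold = as.integer(sv_size_threshold),
                 base_error = base_error,
                 min_link_reads = as.integer(min_link_reads)),
            class = "phasing_config")
}

#' Merge small-variant and SV call sets
#'
#' Sort-merge by (chrom, pos). Exact duplicates (same chrom, pos, ref,
#' alt) are deduplicated keeping the SV caller's record; conflicting
#' genotypes on a duplicate raise a warning.
#'
#' @param small_vars,sv_vars Variant tables, each sorted.
#' @return Combined sorted variant table.
#' @export
merge_vcfs <- function(small_vars, sv_vars) {
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")
  dup <- key(small_vars) %in% key(sv_vars)
  if (any(dup)) {
    ks <- key(small_vars)[dup]
    kv <- key(sv_vars)
    for (k in ks) {
      a <- small_vars[key(small_vars) == k, ][1, ]
      b <- sv_vars[kv == k, ][1, ]
      if (a$gt1 + a$gt2 != b$gt1 + b$gt2) {
        warning("conflicting genotypes for duplicate record at ", a$chrom, ":",
                a$pos, "; keeping the SV record")
      }
    }
  }
  out <- rbind(small_vars[!dup, , drop = FALSE], sv_vars)
  out <- sort_variants(out)
  rownames(out) <- NULL
  out
}

#' Extract per-allele sequences around a variant
#'
#' The reference expansion is `ref_expansion_sv` when the maximum allele
#' length difference reaches `sv_size_threshold`, else
#' `ref_expansion_small`. The window is clipped to the chromosome.
#'
#' @param reference Reference sequence (string or length-1 named vector).
#' @param variant One-row variant table.
#' @param cfg A [phasing_config()].
#' @return List with `window` (0-based half-open reference interval) and
#'   `alleles` (named character vector; names are allele codes "0", "1", "2").
#' @export
extract_allele_sequences <- function(reference, variant, cfg = phasing_config()) {
  if (!is.null(names(reference))) reference <- reference[[1]]
  ref_allele <- variant$ref
  alleles <- c("0" = ref_allele, "1" = variant$alt)
  if (!is.na(variant$alt2)) alleles <- c(alleles, "2" = variant$alt2)
  max_diff <- max(abs(nchar(alleles) - nchar(ref_allele)))
  is_sv <- max_diff >= cfg$sv_size_threshold ||
    (!is.na(variant$sv_type) && variant$sv_type == "INV")
  e <- if (is_sv) cfg$ref_expansion_sv else cfg$ref_expansion_small
  anchor0 <- variant$pos - 1L                       # 0-based allele start
  var_end0 <- anchor0 + nchar(ref_allele)           # 0-based past-the-end
  win_start <- max(0L, anchor0 - e)
  win_end <- min(nchar(reference), var_end0 + e)
  if (win_end <= win_start) stop("empty allele window at ", variant$chrom, ":", variant$pos)
  prefix <- substr(reference, win_start + 1L, anchor0)
  suffix <- substr(reference, var_end0 + 1L, win_end)
  seqs <- vapply(alleles, function(a) paste0(prefix, a, suffix), character(1))
  list(window = c(win_start, win_end), alleles = seqs)
}

#' Score one read against the alleles of one variant
#'
#' The read subsequence whose alignment columns project into the window
#' is extracted; for each allele sequence the edit distance d is computed
#' and the likelihood is `eps^d * (1-eps)^(L-d)` with L the allele
#' length. Reads that do not fully span the window are uninformative and
#' yield NULL.
#'
#' @param read Full read sequence (original orientation).
#' @param aln One-row alignment data.frame for this read over the window.
#' @param allele_seqs Output of [extract_allele_sequences()].
#' @param cfg A [phasing_config()].
#' @return Named numeric vector of allele probabilities (summing to 1), or
#'   NULL when the read does not span the window.
#' @export
score_read_allele <- function(read, aln, allele_seqs, cfg = phasing_config()) {
  w <- allele_seqs$window
  pr <- cpp_project_interval(aln$target_start, aln$target_end, aln$cigar,
                             w[1], w[2])
  if (pr[1] < 0) return(NULL)
  seg <- substr(read, aln$query_start + 1L, aln$query_end)
  if (aln$strand == "-") seg <- revcomp(seg)
  sub <- substr(seg, pr[1] + 1L, pr[2])
  allele_probs_from_subseq(sub, allele_seqs$alleles, cfg$base_error)
}

allele_probs_from_subseq <- function(sub, alleles, eps) {
  d <- as.integer(utils::adist(sub, alleles))
  L <- nchar(alleles)
  ll <- d * log(eps) + (L - d) * log1p(-eps)
  p <- exp(ll - max(ll))
  p <- p / sum(p)
  names(p) <- names(alleles)
  p
}

## ---- maximum-likelihood two-haplotype partition ---------------------------

# supports: data.frame(read, vidx, lp1, lp2) with log-probabilities of the
# two genotype alleles of het variant vidx carried by the read.

#' Total read log-likelihood of a phasing orientation
#'
#' The objective maximized by [phase_variants()]: each read is assigned to
#' its best-supported haplotype and contributes the sum of the
#' log-probabilities of the alleles that haplotype carries at the het
#' sites the read covers. `orientation[i] = 0` puts the first genotype
#' allele of het variant i on haplotype 1.
#'
#' @param supports Support table (`read`, `vidx`, `lp1`, `lp2`).
#' @param orientation Integer 0/1 vector indexed by `vidx`.
#' @return Scalar log-likelihood.
#' @export
phase_log_likelihood <- function(supports, orientation) {
  o <- orientation[supports$vidx]
  h1 <- ifelse(o == 0L, supports$lp1, supports$lp2)
  h2 <- ifelse(o == 0L, supports$lp2, supports$lp1)
  s1 <- tapply(h1, supports$read, sum)
  s2 <- tapply(h2, supports$read, sum)
  sum(pmax(s1, s2))
}

# deterministic xorshift-style generator for restart orientations,
# independent of the global RNG state
local_bits <- function(state, n) {
  out <- integer(n)
  for (i in seq_len(n)) {
    state <- (state * 1103515245 + 12345) %% 2147483648
    out[i] <- as.integer(state >= 1073741824)
  }
  list(bits = out, state = state)
}

#' Jointly phase heterozygous variants from read allele support
#'
#' Builds a graph over het variants with edge weight equal to the summed
#' log-odds of cis versus trans configuration over shared reads, keeps
#' edges backed by at least `min_link_reads` reads, orients each connected
#' component along a maximum spanning tree, and refines by single-site
#' flip hill-climbing (with deterministic restarts on small components)
#' of the total read log-likelihood. Each component becomes a phase set,
#' canonicalized so the first het site is REF-first. Homozygous variants
#' are copied through phased, inheriting the surrounding phase set.
#'
#' @param variants Variant table (het and hom records).
#' @param supports Support table (`read`, `vidx`, `lp1`, `lp2`) where
#'   `vidx` indexes rows of `variants` and `lp1`/`lp2` are log-probs of
#'   the lower/higher genotype allele.
#' @param cfg A [phasing_config()].
#' @return The variant table with `gt1`/`gt2` oriented, `phased = TRUE`
#'   and `phase_set` filled; per-read haplotype assignments in
#'   `attr(, "read_haplotypes")`.
#' @export
phase_variants <- function(variants, supports, cfg = phasing_config()) {
  n <- nrow(variants)
  het <- which(variants$gt1 != variants$gt2)
  orientation <- rep(NA_integer_, n)
  comp <- rep(NA_integer_, n)

  sup <- supports[supports$vidx %in% het & is.finite(supports$lp1) &
                    is.finite(supports$lp2), , drop = FALSE]
  if (length(het) && nrow(sup)) {
    # pairwise cis/trans log-odds over shared reads
    sup <- sup[order(sup$read, sup$vidx), ]
    by_read <- split(seq_len(nrow(sup)), sup$read)
    ekey <- character(0); ew <- numeric(0); en <- integer(0)
    edge_acc <- new.env(parent = emptyenv())
    for (rows in by_read) {
      if (length(rows) < 2L) next
      vi <- sup$vidx[rows]; l1 <- sup$lp1[rows]; l2 <- sup$lp2[rows]
      m <- length(rows)
      for (a in 1:(m - 1L)) {
        for (b in (a + 1L):m) {
          cis <- max(l1[a] + l1[b], l2[a] + l2[b])
          trans <- max(l1[a] + l2[b], l2[a] + l1[b])
          k <- paste0(vi[a], "_", vi[b])
          cur <- edge_acc[[k]]
          if (is.null(cur)) cur <- c(0, 0)
          edge_acc[[k]] <- c(cur[1] + (cis - trans), cur[2] + 1)
        }
      }
    }
    ekey <- ls(edge_acc)
    if (length(ekey)) {
      emat <- do.call(rbind, lapply(ekey, function(k) edge_acc[[k]]))
      ii <- as.integer(sub("_.*", "", ekey))
      jj <- as.integer(sub(".*_", "", ekey))
      keep <- emat[, 2] >= cfg$min_link_reads
      edges <- data.frame(i = ii[keep], j = jj[keep], w = emat[keep, 1],
                          links = emat[keep, 2])
    } else {
      edges <- data.frame(i = integer(), j = integer(), w = numeric(),
                          links = integer())
    }

    # union-find components over kept edges
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    if (nrow(edges)) {
      for (e in seq_len(nrow(edges))) {
        ri <- find(edges$i[e]); rj <- find(edges$j[e])
        if (ri != rj) parent[ri] <- rj
      }
    }
    comp[het] <- vapply(het, find, integer(1))

    # spanning-tree orientation per component (max |w| first), then refine
    orientation[het] <- 0L
    if (nrow(edges)) {
      eo <- edges[order(-abs(edges$w)), ]
      tree <- list()
      tparent <- seq_len(n)
      tfind <- function(x) { while (tparent[x] != x) { tparent[x] <<- tparent[tparent[x]]; x <- tparent[x] }; x }
      adj <- vector("list", n)
      for (e in seq_len(nrow(eo))) {
        ri <- tfind(eo$i[e]); rj <- tfind(eo$j[e])
        if (ri != rj) {
          tparent[ri] <- rj
          adj[[eo$i[e]]] <- c(adj[[eo$i[e]]], list(c(eo$j[e], eo$w[e])))
          adj[[eo$j[e]]] <- c(adj[[eo$j[e]]], list(c(eo$i[e], eo$w[e])))
        }
      }
      visited <- logical(n)
      for (root in het) {
        if (visited[root]) next
        visited[root] <- TRUE
        queue <- root
        while (length(queue)) {
          v <- queue[[1]]; queue <- queue[-1]
          for (nb in adj[[v]]) {
            u <- as.integer(nb[1])
            if (!visited[u]) {
              visited[u] <- TRUE
              orientation[u] <- if (nb[2] >= 0) orientation[v] else 1L - orientation[v]
              queue <- c(queue, u)
            }
          }
        }
      }
    }

    # hill climbing per component on the read log-likelihood
    for (cid in unique(comp[het])) {
      members <- het[comp[het] == cid]
      csup <- sup[sup$vidx %in% members, , drop = FALSE]
      if (nrow(csup) == 0L || length(members) < 2L) next
      best <- hill_climb_orientation(csup, members, orientation[members])
      # deterministic restarts for small components
      if (length(members) <= 25L) {
        state <- cid * 2654435761 %% 2147483648
        for (r in 1:40) {
          rb <- local_bits(state, length(members))
          state <- rb$state
          cand <- hill_climb_orientation(csup, members, rb$bits)
          if (cand$ll > best$ll + 1e-12) best <- cand
        }
      }
      orientation[members] <- best$orientation
    }
  } else if (length(het)) {
    orientation[het] <- 0L
    comp[het] <- het
  }

  # phase sets: component id -> minimum variant position in the set
  out <- variants
  out$phased <- TRUE
  ps_of_comp <- tapply(out$pos[het], comp[het], min)
  out$phase_set[het] <- as.integer(ps_of_comp[as.character(comp[het])])

  # canonicalize: first het site in each set REF-first
  for (cid in unique(comp[het])) {
    members <- het[comp[het] == cid]
    first <- members[which.min(out$pos[members])]
    if (orientation[first] != 0L) orientation[members] <- 1L - orientation[members]
  }
  glo <- pmin(out$gt1[het], out$gt2[het])
  ghi <- pmax(out$gt1[het], out$gt2[het])
  out$gt1[het] <- ifelse(orientation[het] == 0L, glo, ghi)
  out$gt2[het] <- ifelse(orientation[het] == 0L, ghi, glo)

  # homozygous records: inherit the containing phase set
  hom <- setdiff(seq_len(n), het)
  if (length(hom)) {
    if (length(het)) {
      spans <- do.call(rbind, lapply(unique(out$phase_set[het]), function(ps) {
        idx <- het[out$phase_set[het] == ps]
        data.frame(ps = ps, lo = min(out$pos[idx]), hi = max(out$pos[idx]))
      }))
      for (i in hom) {
        hit <- spans$ps[spans$lo <= out$pos[i] & spans$hi >= out$pos[i]]
        out$phase_set[i] <- if (length(hit)) hit[1] else out$pos[i]
      }
    } else {
      out$phase_set[hom] <- out$pos[hom]
    }
  }

  # per-read haplotype assignment under the final orientation
  if (nrow(sup)) {
    o <- orientation[sup$vidx]
    h1 <- ifelse(o == 0L, sup$lp1, sup$lp2)
    h2 <- ifelse(o == 0L, sup$lp2, sup$lp1)
    s1 <- tapply(h1, sup$read, sum)
    s2 <- tapply(h2, sup$read, sum)
    rh <- data.frame(read = names(s1), s1 = as.numeric(s1), s2 = as.numeric(s2),
                     hap = ifelse(abs(s1 - s2) < 1e-12, NA_integer_,
                                  ifelse(s1 > s2, 1L, 2L)),
                     stringsAsFactors = FALSE)
  } else {
    rh <- data.frame(read = character(), s1 = numeric(), s2 = numeric(),
                     hap = integer(), stringsAsFactors = FALSE)
  }
  attr(out, "read_haplotypes") <- rh
  attr(out, "orientation") <- orientation
  out
}

# Single-site flip hill climbing with incremental per-read bookkeeping;
# returns the local-optimum orientation (ordered as `members`) and its
# log-likelihood.
hill_climb_orientation <- function(csup, members, init) {
  ori <- as.integer(init)
  midx <- match(csup$vidx, members)
  reads <- factor(csup$read)
  ridx <- as.integer(reads)
  nr <- nlevels(reads)
  h1 <- ifelse(ori[midx] == 0L, csup$lp1, csup$lp2)
  h2 <- ifelse(ori[midx] == 0L, csup$lp2, csup$lp1)
  S1 <- as.numeric(tapply(h1, ridx, sum)[as.character(seq_len(nr))])
  S2 <- as.numeric(tapply(h2, ridx, sum)[as.character(seq_len(nr))])
  S1[is.na(S1)] <- 0; S2[is.na(S2)] <- 0
  rows_by_member <- split(seq_len(nrow(csup)), midx)
  cur <- sum(pmax(S1, S2))
  improved <- TRUE
  iter <- 0L
  while (improved && iter < 200L) {
    improved <- FALSE
    iter <- iter + 1L
    for (k in seq_along(members)) {
      rows <- rows_by_member[[as.character(k)]]
      if (is.null(rows)) next
      c1 <- if (ori[k] == 0L) csup$lp1[rows] else csup$lp2[rows]
      c2 <- if (ori[k] == 0L) csup$lp2[rows] else csup$lp1[rows]
      rr <- ridx[rows]
      nS1 <- S1[rr] + (c2 - c1)
      nS2 <- S2[rr] + (c1 - c2)
      delta <- sum(pmax(nS1, nS2) - pmax(S1[rr], S2[rr]))
      if (delta > 1e-12) {
        S1[rr] <- nS1; S2[rr] <- nS2
        ori[k] <- 1L - ori[k]
        cur <- cur + delta
        improved <- TRUE
      }
    }
  }
  list(orientation = ori, ll = cur)
}

#' Build allele supports for a variant set from read alignments
#'
#' Convenience wrapper applying [extract_allele_sequences()] and
#' [score_read_allele()] over every het variant and every read alignment
#' spanning its window. For each het variant the two genotype alleles are
#' scored; log-probabilities are returned in `lp1`/`lp2` (lower/higher
#' allele code).
#'
#' @param variants Variant table.
#' @param reference Reference sequence (named vector or string).
#' @param alignments Read alignment data.frame (reads vs the reference).
#' @param reads Named character vector of read sequences.
#' @param cfg A [phasing_config()].
#' @return Support data.frame (`read`, `vidx`, `lp1`, `lp2`).
#' @export
build_allele_supports <- function(variants, reference, alignments, reads,
                                  cfg = phasing_config()) {
  if (!is.null(names(reference))) reference <- reference[[1]]
  het <- which(variants$gt1 != variants$gt2)
  if (length(het) == 0L || nrow(alignments) == 0L) {
    return(data.frame(read = character(), vidx = integer(), lp1 = numeric(),
                      lp2 = numeric(), stringsAsFactors = FALSE))
  }
  aln <- alignments[order(alignments$target_start), , drop = FALSE]
  # oriented aligned segment per alignment, computed once
  segs <- character(nrow(aln))
  for (i in seq_len(nrow(aln))) {
    s <- substr(reads[[aln$query_name[i]]], aln$query_start[i] + 1L, aln$query_end[i])
    segs[i] <- if (aln$strand[i] == "-") revcomp(s) else s
  }
  eps <- cfg$base_error
  out <- vector("list", length(het))
  for (k in seq_along(het)) {
    v <- variants[het[k], , drop = FALSE]
    aseq <- extract_allele_sequences(reference, v, cfg)
    w <- aseq$window
    cand <- which(aln$target_start <= w[1] & aln$target_end >= w[2])
    if (length(cand) == 0L) next
    subs <- character(length(cand))
    ok <- logical(length(cand))
    for (ci in seq_along(cand)) {
      i <- cand[ci]
      pr <- cpp_project_interval(aln$target_start[i], aln$target_end[i],
                                 aln$cigar[i], w[1], w[2])
      if (pr[1] < 0) next
      subs[ci] <- substr(segs[i], pr[1] + 1L, pr[2])
      ok[ci] <- TRUE
    }
    if (!any(ok)) next
    g <- sort(unique(c(v$gt1, v$gt2)))
    alleles <- aseq$alleles[as.character(g)]
    d <- utils::adist(subs[ok], alleles)
    L <- matrix(nchar(alleles), nrow = sum(ok), ncol = length(alleles), byrow = TRUE)
    ll <- d * log(eps) + (L - d) * log1p(-eps)
    out[[k]] <- data.frame(read = aln$query_name[cand[ok]],
                           vidx = het[k], lp1 = ll[, 1], lp2 = ll[, 2],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(read = character(), vidx = integer(), lp1 = numeric(),
                      lp2 = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}
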
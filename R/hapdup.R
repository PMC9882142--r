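# Dual assembly: haploid draft + read alignments -> locally phased
# diploid assembly. Read filtering, pileup SNP calling, phasing +
# haplotagging, chunked consensus polishing, inversion signatures.

#' Read-alignment filter configuration
#'
#' Defaults: minimum read length and alignment length 5000 bp, maximum
#' alignment divergence 0.09, maximum unaligned read fraction 0.20.
#'
#' @param min_read_len Minimum read length (bp).
#' @param min_aln_len Minimum aligned span of the best alignment (bp).
#' @param max_divergence Maximum alignment divergence.
#' @param max_unaligned_frac Maximum fraction of the read left unaligned.
#' @return A `read_filter_config` list.
#' @export
read_filter_config <- function(min_read_len = 5000L, min_aln_len = 5000L,
                               max_divergence = 0.09, max_unaligned_frac = 0.20) {
  stopifnot(min_read_len >= 0, min_aln_len >= 0,
            max_divergence >= 0, max_divergence <= 1,
            max_unaligned_frac >= 0, max_unaligned_frac <= 1)
  structure(list(min_read_len = as.integer(min_read_len),
                 min_aln_len = as.integer(min_aln_len),
                 max_divergence = max_divergence,
                 max_unaligned_frac = max_unaligned_frac),
            class = "read_filter_config")
}

#' Filter read alignments before phasing
#'
#' A read is removed when it is short, its best alignment is short or too
#' divergent, or a large fraction of the read is unaligned (misalignment
#' of reads from unassembled repeat copies would otherwise fabricate
#' haplotypes). Each removed read is tagged with the first failing rule.
#'
#' @param alignments Alignment data.frame.
#' @param cfg A [read_filter_config()].
#' @return List with `kept` (alignment rows of retained reads) and
#'   `removed` (read, reason).
#' @export
filter_read_alignments <- function(alignments, cfg = read_filter_config()) {
  if (nrow(alignments) == 0L) {
    return(list(kept = alignments,
                removed = data.frame(read = character(), reason = character(),
                                     stringsAsFactors = FALSE)))
  }
  per_read <- split(seq_len(nrow(alignments)), alignments$query_name)
  reasons <- vapply(per_read, function(idx) {
    a <- alignments[idx, , drop = FALSE]
    qlen <- a$query_len[1]
    spans <- a$query_end - a$query_start
    best <- which.max(spans)
    if (qlen < cfg$min_read_len) return("short_read")
    if (spans[best] < cfg$min_aln_len) return("short_alignment")
    if (min(a$divergence) > cfg$max_divergence) return("high_divergence")
    cov <- IRanges::reduce(IRanges::IRanges(a$query_start + 1L, a$query_end))
    aligned <- sum(IRanges::width(cov))
    if ((qlen - aligned) / qlen > cfg$max_unaligned_frac) return("unaligned_fraction")
    ""
  }, character(1))
  bad <- names(reasons)[nzchar(reasons)]
  list(kept = alignments[!alignments$query_name %in% bad, , drop = FALSE],
       removed = data.frame(read = bad, reason = reasons[nzchar(reasons)],
                            row.names = NULL, stringsAsFactors = FALSE))
}

# Oriented aligned query segment for each alignment row; a precomputed
# `seg` column (added once per contig by hapdup()) takes precedence.
aligned_segments <- function(alignments, reads) {
  if (!is.null(alignments$seg)) return(alignments$seg)
  vapply(seq_len(nrow(alignments)), function(i) {
    s <- substr(reads[[alignments$query_name[i]]],
                alignments$query_start[i] + 1L, alignments$query_end[i])
    if (alignments$strand[i] == "-") revcomp(s) else s
  }, character(1))
}

#' Call SNPs from a read pileup over a target sequence
#'
#' A site is a heterozygous SNP candidate when coverage reaches
#' `min_coverage` and the two most frequent bases each reach frequency
#' `min_alt_frac`. Homozygous differences from the target (top base
#' different from the target base at frequency at least
#' `1 - min_alt_frac`) are also emitted, flagged non-informative for
#' phasing.
#'
#' @param alignments Alignments of reads to `target` (one target sequence).
#' @param reads Named character vector of read sequences.
#' @param target Target sequence (named length-1 vector or string), e.g. a
#'   draft contig or the reference.
#' @param target_name Target/chromosome name for emitted records.
#' @param min_coverage Minimum pileup depth (default 8).
#' @param min_alt_frac Minimum allele frequency (default 0.25).
#' @return Variant table of SNPs with a logical `informative` column.
#' @export
call_het_snps <- function(alignments, reads, target, target_name = NULL,
                          min_coverage = 8L, min_alt_frac = 0.25) {
  if (!is.null(names(target))) {
    if (is.null(target_name)) target_name <- names(target)
    target <- target[[1]]
  }
  if (is.null(target_name)) target_name <- "target"
  L <- nchar(target)
  empty <- variant_table()
  empty$informative <- logical(0)
  if (nrow(alignments) == 0L) return(empty)
  segs <- aligned_segments(alignments, reads)
  counts <- cpp_pileup_counts(L, alignments$target_start, alignments$cigar, segs)
  base_tot <- colSums(counts[1:4, , drop = FALSE])
  cand <- which(base_tot >= min_coverage)
  if (length(cand) == 0L) return(empty)
  sub <- counts[1:4, cand, drop = FALSE]
  ord <- apply(sub, 2, order, decreasing = TRUE)
  top1 <- ord[1, ]; top2 <- ord[2, ]
  f1 <- sub[cbind(top1, seq_along(cand))] / base_tot[cand]
  f2 <- sub[cbind(top2, seq_along(cand))] / base_tot[cand]
  letters4 <- c("A", "C", "G", "T")
  tchars <- strsplit(target, "")[[1]]
  ref_base <- tchars[cand]
  het <- f1 >= min_alt_frac & f2 >= min_alt_frac
  hom <- !het & letters4[top1] != ref_base & f1 >= 1 - min_alt_frac
  keep <- which(het | hom)
  if (length(keep) == 0L) return(empty)
  rows <- lapply(keep, function(k) {
    p <- cand[k]
    rb <- ref_base[k]
    if (het[k]) {
      b1 <- letters4[top1[k]]; b2 <- letters4[top2[k]]
      if (rb == b1) {
        list(pos = p, ref = rb, alt = b2, alt2 = NA_character_, gt1 = 0L, gt2 = 1L)
      } else if (rb == b2) {
        list(pos = p, ref = rb, alt = b1, alt2 = NA_character_, gt1 = 0L, gt2 = 1L)
      } else {
        list(pos = p, ref = rb, alt = b1, alt2 = b2, gt1 = 1L, gt2 = 2L)
      }
    } else {
      list(pos = p, ref = rb, alt = letters4[top1[k]], alt2 = NA_character_,
           gt1 = 1L, gt2 = 1L)
    }
  })
  out <- variant_table(chrom = rep(target_name, length(rows)),
                       pos = vapply(rows, `[[`, numeric(1), "pos"),
                       ref = vapply(rows, `[[`, character(1), "ref"),
                       alt = vapply(rows, `[[`, character(1), "alt"),
                       alt2 = vapply(rows, `[[`, character(1), "alt2"),
                       gt1 = vapply(rows, `[[`, numeric(1), "gt1"),
                       gt2 = vapply(rows, `[[`, numeric(1), "gt2"))
  out$informative <- het[keep]
  out
}

#' Phase het SNPs and haplotag reads
#'
#' Phasing delegates to [phase_variants()] with supports derived from the
#' pileup base each read carries at each het site. Each read is then
#' tagged by majority vote over the phased alleles it covers; ties and
#' zero votes give an untagged read.
#'
#' @param snps Variant table from [call_het_snps()].
#' @param alignments Alignments of reads to the same target.
#' @param reads Named character vector of read sequences.
#' @param cfg A [phasing_config()].
#' @return List with `phased` (phased variant table) and `haplotags`
#'   (read, tag in H1/H2/untagged, votes_h1, votes_h2).
#' @export
phase_and_haplotag <- function(snps, alignments, reads, cfg = phasing_config()) {
  het <- which(snps$gt1 != snps$gt2 & (is.null(snps$informative) | snps$informative))
  all_reads <- unique(alignments$query_name)
  no_tags <- data.frame(read = all_reads, tag = "untagged",
                        votes_h1 = 0L, votes_h2 = 0L, stringsAsFactors = FALSE)
  if (length(het) == 0L || nrow(alignments) == 0L) {
    out <- snps
    if (nrow(out)) { out$phased <- TRUE; out$phase_set <- 1L }
    return(list(phased = out, haplotags = no_tags))
  }
  segs <- aligned_segments(alignments, reads)
  het_pos0 <- snps$pos[het] - 1L
  bases <- cpp_read_bases_at(alignments$target_start, alignments$target_end,
                             alignments$cigar, segs,
                             as.integer(sort(het_pos0)))
  if (nrow(bases) == 0L) {
    out <- snps; out$phased <- TRUE; out$phase_set <- 1L
    return(list(phased = out, haplotags = no_tags))
  }
  vidx_of_pos <- stats::setNames(het, as.character(het_pos0))
  bases$vidx <- vidx_of_pos[as.character(bases$pos)]
  bases$read <- alignments$query_name[bases$aln]
  eps <- cfg$base_error
  # allele codes: lower allele first
  g_lo <- pmin(snps$gt1, snps$gt2); g_hi <- pmax(snps$gt1, snps$gt2)
  allele_of <- function(vi, code) {
    ifelse(code == 0L, snps$ref[vi], ifelse(code == 1L, snps$alt[vi], snps$alt2[vi]))
  }
  a1 <- allele_of(bases$vidx, g_lo[bases$vidx])
  a2 <- allele_of(bases$vidx, g_hi[bases$vidx])
  m1 <- bases$base == a1
  m2 <- bases$base == a2
  keep <- m1 | m2
  sup <- data.frame(read = bases$read[keep], vidx = bases$vidx[keep],
                    lp1 = ifelse(m1[keep], log1p(-eps), log(eps)),
                    lp2 = ifelse(m2[keep], log1p(-eps), log(eps)),
                    stringsAsFactors = FALSE)
  phased <- phase_variants(snps, sup, cfg)
  # majority vote haplotagging over phased alleles
  h1_allele <- allele_of(bases$vidx, phased$gt1[bases$vidx])
  h2_allele <- allele_of(bases$vidx, phased$gt2[bases$vidx])
  v1 <- as.integer(bases$base == h1_allele)
  v2 <- as.integer(bases$base == h2_allele)
  votes1 <- tapply(v1, bases$read, sum)
  votes2 <- tapply(v2, bases$read, sum)
  tags <- data.frame(read = names(votes1),
                     votes_h1 = as.integer(votes1), votes_h2 = as.integer(votes2),
                     stringsAsFactors = FALSE)
  tags$tag <- ifelse(tags$votes_h1 > tags$votes_h2, "H1",
                     ifelse(tags$votes_h2 > tags$votes_h1, "H2", "untagged"))
  missing <- setdiff(all_reads, tags$read)
  if (length(missing)) {
    tags <- rbind(tags, data.frame(read = missing, votes_h1 = 0L, votes_h2 = 0L,
                                   tag = "untagged", stringsAsFactors = FALSE))
  }
  rownames(tags) <- NULL
  list(phased = phased, haplotags = tags[, c("read", "tag", "votes_h1", "votes_h2")])
}

#' Select polishing chunk boundaries avoiding inconsistent-indel regions
#'
#' Nominal boundaries every `chunk_size` bp are shifted off regions where
#' at least two reads carry indels (length >= `min_indel_len`) at contig
#' coordinates that differ by at least `pad` bp while their pad-expanded
#' intervals overlap — the alignment-ambiguity signature of VNTRs. A
#' region longer than `chunk_size` becomes its own chunk.
#'
#' @param alignments Alignments on one contig.
#' @param contig_len Contig length (bp).
#' @param chunk_size Nominal chunk size (default 10000).
#' @param min_indel_len Minimum indel length considered (default 5).
#' @param pad Padding / coordinate-consistency tolerance (default 10).
#' @param region_merge_gap Inconsistent regions closer than this are
#'   merged (default 500 bp): one indel ambiguously placed inside a
#'   tandem array scatters across the whole array, well beyond `pad`.
#' @return List with `boundaries` (positions partitioning
#'   `[0, contig_len)`) and `regions` (inconsistent-indel intervals).
#' @export
select_chunk_boundaries <- function(alignments, contig_len, chunk_size = 10000L,
                                    min_indel_len = 5L, pad = 10L,
                                    region_merge_gap = 500L) {
  regions <- data.frame(start = integer(), end = integer())
  if (nrow(alignments) > 0L) {
    ops <- cpp_indel_ops(alignments$target_start, alignments$cigar,
                         as.integer(min_indel_len))
    if (nrow(ops) > 0L) {
      lo <- ops$tpos - pad
      hi <- ops$tpos + ifelse(ops$type == "D", ops$len, 0L) + pad
      o <- order(lo)
      lo <- lo[o]; hi <- hi[o]; aln_id <- ops$aln[o]; tp <- ops$tpos[o]
      # sweep: connected components of overlapping padded intervals
      grp <- integer(length(lo)); g <- 0L; gend <- -Inf
      for (i in seq_along(lo)) {
        if (lo[i] > gend) { g <- g + 1L; gend <- hi[i] } else gend <- max(gend, hi[i])
        grp[i] <- g
      }
      rows <- lapply(split(seq_along(lo), grp), function(idx) {
        if (length(unique(aln_id[idx])) < 2L) return(NULL)
        if (max(tp[idx]) - min(tp[idx]) < pad) return(NULL)
        data.frame(start = max(0L, min(lo[idx])), end = min(contig_len, max(hi[idx])))
      })
      regions <- do.call(rbind, c(rows, list(regions)))
      if (nrow(regions) > 1L) {
        regions <- regions[order(regions$start), , drop = FALSE]
        merged <- regions[1, , drop = FALSE]
        for (i in seq_len(nrow(regions))[-1]) {
          k <- nrow(merged)
          if (regions$start[i] - merged$end[k] <= region_merge_gap) {
            merged$end[k] <- max(merged$end[k], regions$end[i])
          } else {
            merged <- rbind(merged, regions[i, ])
          }
        }
        regions <- merged
        rownames(regions) <- NULL
      }
    }
  }
  nominal <- if (contig_len > chunk_size) {
    seq.int(chunk_size, contig_len - 1L, by = chunk_size)
  } else integer(0)
  if (length(nominal) && nrow(regions)) {
    for (r in seq_len(nrow(regions))) {
      inside <- nominal > regions$start[r] & nominal < regions$end[r]
      if (any(inside)) {
        b <- nominal[inside]
        shift_left <- (b - regions$start[r]) <= (regions$end[r] - b)
        nominal[inside] <- ifelse(shift_left, regions$start[r], regions$end[r])
      }
    }
    big <- regions[regions$end - regions$start > chunk_size, , drop = FALSE]
    nominal <- c(nominal, big$start, big$end)
  }
  boundaries <- sort(unique(c(0L, nominal[nominal > 0L & nominal < contig_len],
                              contig_len)))
  list(boundaries = as.integer(boundaries), regions = regions)
}

#' Polish one haplotype of a contig by chunked pileup consensus
#'
#' Column-wise plurality consensus over the given (pre-haplotagged) read
#' alignments. Small insertions are accepted when carried by more than
#' half of the reads spanning the junction. Structural insertions and
#' deletions that the aligner represents as split alignments (or as
#' large indel ops at read-to-read jittering positions) are recovered by
#' clustering split-alignment junction signatures and large indel votes
#' within `cluster_eps` bp. Chunks with zero coverage are returned
#' unchanged and flagged. Inside inconsistent-indel regions whose indels
#' this haplotype actually carries, the column consensus is replaced by
#' a mini-consensus of the spanning read subsequences, since split indel
#' votes would otherwise cancel each other.
#'
#' @param draft Draft contig sequence (string or named length-1 vector).
#' @param alignments Alignments of one haplotype's reads to the draft.
#' @param reads Named character vector of read sequences.
#' @param chunks Output of [select_chunk_boundaries()] (computed from
#'   `alignments` when NULL).
#' @param min_sv_len Minimum clustered-indel size treated as structural
#'   (default 50 bp).
#' @param cluster_eps Position clustering tolerance for structural indel
#'   votes (default 200 bp).
#' @return List with `seq` (polished sequence), `flagged` (uncovered
#'   chunk intervals), `pos_map` (0-based start offset of each draft
#'   position in the polished sequence) and `cov` (per-position depth).
#' @export
polish_haplotype <- function(draft, alignments, reads, chunks = NULL,
                             min_sv_len = 50L, cluster_eps = 200L) {
  if (!is.null(names(draft))) draft <- draft[[1]]
  L <- nchar(draft)
  if (is.null(chunks)) chunks <- select_chunk_boundaries(alignments, L)
  b <- chunks$boundaries
  if (nrow(alignments) == 0L) {
    return(list(seq = draft,
                flagged = data.frame(start = 0L, end = L),
                pos_map = seq.int(0L, L - 1L), cov = integer(L)))
  }
  segs <- aligned_segments(alignments, reads)
  cons <- cpp_consensus(draft, alignments$target_start, alignments$cigar, segs)
  base <- cons$base; cov <- cons$cov

  # small insertions: plurality at the exact junction, accepted when
  # carried by more than half of the spanning reads
  ins <- character(L + 1L)
  big_iop <- data.frame(t = integer(), seq = character(),
                        stringsAsFactors = FALSE)
  if (length(cons$ins_t)) {
    lens <- nchar(cons$ins_seq)
    big_sel <- lens >= min_sv_len
    if (any(big_sel)) {
      big_iop <- data.frame(
        t = rep(cons$ins_t[big_sel], cons$ins_n[big_sel]),
        seq = rep(cons$ins_seq[big_sel], cons$ins_n[big_sel]),
        stringsAsFactors = FALSE)
    }
    for (t in unique(cons$ins_t[!big_sel])) {
      sel <- !big_sel & cons$ins_t == t
      carriers <- sum(cons$ins_n[sel])
      spanning <- cons$jcov[t + 1L]
      if (spanning == 0L || carriers * 2L <= spanning) next
      strs <- cons$ins_seq[sel]; n <- cons$ins_n[sel]
      o <- order(-n, strs)
      ins[t + 1L] <- if (n[o[1]] >= 2L || carriers < 3L) strs[o[1]]
        else consensus_strings(rep(strs, n))
    }
  }
  contrib <- paste0(base, ins[-1L])

  flagged <- list()
  for (ci in seq_len(length(b) - 1L)) {
    lo <- b[ci] + 1L; hi <- b[ci + 1L]
    if (all(cov[lo:hi] == 0L)) {
      contrib[lo:hi] <- strsplit(substr(draft, lo, hi), "")[[1]]
      flagged[[length(flagged) + 1L]] <- data.frame(start = b[ci], end = b[ci + 1L])
    }
  }

  # structural indels from split alignments + jittered large indel ops
  splits <- detect_split_ops(alignments, reads, min_len = min_sv_len)
  sv_spans <- list()   # intervals already resolved structurally
  ins_votes <- rbind(big_iop,
                     if (nrow(splits$ins))
                       splits$ins[, c("t", "seq")] else NULL)
  if (!is.null(ins_votes) && nrow(ins_votes)) {
    ins_votes <- ins_votes[order(ins_votes$t), , drop = FALSE]
    grp <- cumsum(c(1L, diff(ins_votes$t) > cluster_eps))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      tmid <- as.integer(round(stats::median(ins_votes$t[idx])))
      carriers <- length(idx)
      # reads aligned straight through the junction argue against it;
      # split or clipped carriers do not span, so jcov is the right
      # denominator
      through <- cons$jcov[min(max(tmid + 1L, 1L), L + 1L)] -
        sum(big_iop$t >= tmid - cluster_eps & big_iop$t <= tmid + cluster_eps)
      if (carriers < 2L || carriers <= max(through, 0L)) next
      seq_ins <- consensus_strings(ins_votes$seq[idx])
      contrib[tmid + 1L] <- paste0(seq_ins, contrib[tmid + 1L])
      sv_spans[[length(sv_spans) + 1L]] <-
        c(tmid - cluster_eps, tmid + cluster_eps)
    }
  }
  if (nrow(splits$del)) {
    dv <- splits$del[order(splits$del$t0), , drop = FALSE]
    grp <- cumsum(c(1L, diff(dv$t0) > cluster_eps))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      t0 <- as.integer(round(stats::median(dv$t0[idx])))
      t1 <- as.integer(round(stats::median(dv$t1[idx])))
      if (t1 <= t0) next
      mid <- min(max(as.integer((t0 + t1) / 2), 1L), L)
      carriers <- length(unique(dv$read[idx]))
      through <- cov[mid] - cons$del[mid]  # aligned across without deleting
      if (carriers < 2L || carriers <= through) next
      contrib[(t0 + 1L):min(t1, L)] <- ""
      sv_spans[[length(sv_spans) + 1L]] <- c(t0 - cluster_eps, t1 + cluster_eps)
    }
  }
  in_sv_span <- function(s, e) {
    any(vapply(sv_spans, function(iv) s < iv[2] && e > iv[1], logical(1)))
  }

  # splice mini-consensus across inconsistent-indel regions carried by
  # this haplotype
  regions <- chunks$regions
  if (!is.null(regions) && nrow(regions)) {
    ops_hap <- cpp_indel_ops(alignments$target_start, alignments$cigar, 5L)
    for (r in seq_len(nrow(regions))) {
      rs <- regions$start[r]; re <- regions$end[r]
      if (re - rs > 10000L || in_sv_span(rs, re)) next
      oh <- ops_hap[ops_hap$tpos >= rs & ops_hap$tpos <= re, , drop = FALSE]
      if (length(unique(oh$aln)) < 2L) next
      if (max(oh$tpos) - min(oh$tpos) < 10L &&
          length(unique(oh$len)) == 1L) next   # consistent: columns suffice
      cand <- which(alignments$target_start <= rs & alignments$target_end >= re)
      if (length(cand) == 0L) next
      subs <- vapply(cand, function(i) {
        pr <- cpp_project_interval(alignments$target_start[i],
                                   alignments$target_end[i],
                                   alignments$cigar[i], rs, re)
        if (pr[1] < 0) return(NA_character_)
        substr(segs[i], pr[1] + 1L, pr[2])
      }, character(1))
      subs <- subs[!is.na(subs)]
      if (length(subs) == 0L) next
      pick <- consensus_strings(subs)
      contrib[(rs + 1L):re] <- ""
      contrib[rs + 1L] <- pick
    }
  }

  lens <- nchar(contrib)
  pos_map <- cumsum(c(0L, lens[-L]))
  list(seq = paste(contrib, collapse = ""),
       flagged = if (length(flagged)) do.call(rbind, flagged)
                 else data.frame(start = integer(), end = integer()),
       pos_map = as.integer(pos_map), cov = cov)
}

# Structural indel signatures from split alignments: consecutive
# same-strand segments of one read with a near-zero gap on one side and
# a gap of at least min_len on the other.
detect_split_ops <- function(alignments, reads, min_len = 50L,
                             max_gap = 100L) {
  ins <- list(); del <- list()
  multi <- names(which(table(alignments$query_name) >= 2L))
  for (key in multi) {
    a <- alignments[alignments$query_name == key, , drop = FALSE]
    a <- a[order(a$target_start), , drop = FALSE]
    for (i in seq_len(nrow(a) - 1L)) {
      s1 <- a[i, ]; s2 <- a[i + 1L, ]
      if (s1$strand != s2$strand) next
      tgap <- s2$target_start - s1$target_end
      if (s1$strand == "+") {
        qgap <- s2$query_start - s1$query_end
        q0 <- s1$query_end; q1 <- s2$query_start
      } else {
        qgap <- s1$query_start - s2$query_end
        q0 <- s2$query_end; q1 <- s1$query_start
      }
      if (abs(tgap) <= max_gap && qgap - max(tgap, 0L) >= min_len && q1 > q0) {
        seq <- substr(reads[[key]], q0 + 1L, q1)
        if (s1$strand == "-") seq <- revcomp(seq)
        ins[[length(ins) + 1L]] <- data.frame(
          read = key, t = s1$target_end, seq = seq, stringsAsFactors = FALSE)
      } else if (abs(qgap) <= max_gap && tgap - max(qgap, 0L) >= min_len) {
        del[[length(del) + 1L]] <- data.frame(
          read = key, t0 = s1$target_end, t1 = s2$target_start,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(ins = if (length(ins)) do.call(rbind, ins)
       else data.frame(read = character(), t = integer(), seq = character(),
                       stringsAsFactors = FALSE),
       del = if (length(del)) do.call(rbind, del)
       else data.frame(read = character(), t0 = integer(), t1 = integer(),
                       stringsAsFactors = FALSE))
}

# Consensus of several noisy copies of the same sequence: plurality when
# an exact duplicate exists, otherwise the medoid (minimum summed edit
# distance, over a capped candidate set) re-polished column-wise by
# global alignments of all copies, so individual read errors are outvoted.
consensus_strings <- function(strs, max_copies = 12L) {
  if (length(strs) == 1L) return(strs[1])
  tab <- sort(table(strs), decreasing = TRUE)
  if (tab[1] >= 2L) return(names(tab)[1])
  if (length(strs) > max_copies) {
    strs <- strs[seq.int(1L, length(strs), length.out = max_copies)]
  }
  # the copies usually share long identical flanks; strip them so the
  # quadratic edit-distance work runs on the differing core only
  tr <- common_affix(strs)
  core <- substr(strs, tr$prefix + 1L, nchar(strs) - tr$suffix)
  cand <- core[seq_len(min(8L, length(core)))]
  d <- vapply(cand, function(cc) sum(cpp_edit_distance(core, cc, 32L)),
              numeric(1), USE.NAMES = FALSE)
  medoid <- cand[which.min(d)]
  mid <- if (length(core) < 3L) medoid else polish_with_copies(medoid, core)
  paste0(substr(strs[1], 1L, tr$prefix), mid,
         substr(strs[1], nchar(strs[1]) - tr$suffix + 1L, nchar(strs[1])))
}

# Longest common prefix and suffix lengths over a set of strings
# (non-overlapping: prefix + suffix never exceeds the shortest string).
common_affix <- function(strs) {
  minlen <- min(nchar(strs))
  if (minlen == 0L || length(strs) < 2L) return(list(prefix = 0L, suffix = 0L))
  k <- length(strs)
  m1 <- vapply(strs, function(s) utf8ToInt(substr(s, 1L, minlen)),
               integer(minlen), USE.NAMES = FALSE)
  dim(m1) <- c(minlen, k)
  eq <- rowSums(m1 == m1[, 1]) == k
  p <- which(!eq)[1]
  prefix <- if (is.na(p)) minlen else p - 1L
  m2 <- vapply(strs, function(s) {
    n <- nchar(s)
    rev(utf8ToInt(substr(s, n - minlen + 1L, n)))
  }, integer(minlen), USE.NAMES = FALSE)
  dim(m2) <- c(minlen, k)
  eq2 <- rowSums(m2 == m2[, 1]) == k
  q <- which(!eq2)[1]
  suffix <- if (is.na(q)) minlen else q - 1L
  over <- prefix + suffix - minlen
  if (over > 0L) suffix <- suffix - over
  list(prefix = prefix, suffix = suffix)
}

# Column consensus of `copies` against `template` via banded global
# alignment; used for mini-consensus of spliced regions and insertion
# alleles.
polish_with_copies <- function(template, copies) {
  cigars <- vapply(copies, function(s) cpp_align_cigar(s, template, 32L),
                   character(1), USE.NAMES = FALSE)
  cons <- cpp_consensus(template, integer(length(copies)), cigars, copies)
  L <- nchar(template)
  ins <- character(L + 1L)
  if (length(cons$ins_t)) {
    for (t in unique(cons$ins_t)) {
      sel <- cons$ins_t == t
      carriers <- sum(cons$ins_n[sel])
      if (cons$jcov[t + 1L] == 0L || carriers * 2L <= cons$jcov[t + 1L]) next
      o <- order(-cons$ins_n[sel], cons$ins_seq[sel])
      ins[t + 1L] <- cons$ins_seq[sel][o[1]]
    }
  }
  paste(paste0(cons$base, ins[-1L]), collapse = "")
}

#' Detect inversion signatures from split read alignments
#'
#' A candidate is a minority-strand segment run flanked by
#' majority-strand segments of the same read (forward-reverse-forward
#' split pattern, or a two-segment prefix/suffix strand flip). Candidates
#' whose breakpoints cluster within `cluster_eps` bp and reach
#' `min_support` reads are emitted; the haplotype is taken from the
#' haplotags of supporting reads ("both" when mixed or untagged).
#'
#' @param alignments Alignment data.frame with split reads as multiple rows.
#' @param min_support Minimum supporting reads (default 3).
#' @param cluster_eps Breakpoint clustering tolerance in bp (default 500).
#' @param haplotags Optional haplotag data.frame from [phase_and_haplotag()].
#' @return data.frame (`contig`, `start`, `end`, `support`, `haplotype`).
#' @export
detect_inversions <- function(alignments, min_support = 3L, cluster_eps = 500L,
                              haplotags = NULL) {
  empty <- data.frame(contig = character(), start = integer(), end = integer(),
                      support = integer(), haplotype = character(),
                      stringsAsFactors = FALSE)
  if (nrow(alignments) == 0L) return(empty)
  cands <- list()
  for (key in unique(alignments$query_name)) {
    a <- alignments[alignments$query_name == key, , drop = FALSE]
    for (tn in unique(a$target_name)) {
      at <- a[a$target_name == tn, , drop = FALSE]
      if (nrow(at) < 2L || length(unique(at$strand)) < 2L) next
      at <- at[order(at$query_start), , drop = FALSE]
      maj <- names(sort(table(at$strand), decreasing = TRUE))[1]
      # one candidate per maximal run of minority-strand segments
      r <- rle(at$strand != maj)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        seg <- starts[k]:ends[k]
        cands[[length(cands) + 1L]] <- data.frame(
          read = key, contig = tn,
          start = min(at$target_start[seg]), end = max(at$target_end[seg]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cands) == 0L) return(empty)
  cd <- do.call(rbind, cands)
  out <- list()
  for (tn in unique(cd$contig)) {
    g <- cd[cd$contig == tn, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    used <- logical(nrow(g))
    for (i in seq_len(nrow(g))) {
      if (used[i]) next
      grp <- which(!used & abs(g$start - g$start[i]) <= cluster_eps &
                     abs(g$end - g$end[i]) <= cluster_eps)
      used[grp] <- TRUE
      if (length(unique(g$read[grp])) < min_support) next
      hap <- "both"
      if (!is.null(haplotags)) {
        tg <- haplotags$tag[match(unique(g$read[grp]), haplotags$read)]
        tg <- tg[!is.na(tg) & tg != "untagged"]
        if (length(tg) && all(tg == "H1")) hap <- "H1"
        else if (length(tg) && all(tg == "H2")) hap <- "H2"
      }
      out[[length(out) + 1L]] <- data.frame(
        contig = tn,
        start = as.integer(round(stats::median(g$start[grp]))),
        end = as.integer(round(stats::median(g$end[grp]))),
        support = length(unique(g$read[grp])), haplotype = hap,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(empty)))
}

#' Apply inversion signatures to haplotype contigs
#'
#' Reverse-complements the interval `[start, end)` of each assigned
#' contig. Overlapping signatures on one contig, or intervals outside the
#' contig, are errors.
#'
#' @param contigs Named character vector of contig sequences.
#' @param signatures data.frame from [detect_inversions()] (columns
#'   `contig`, `start`, `end`).
#' @return Edited contigs.
#' @export
apply_rearrangements <- function(contigs, signatures) {
  if (is.null(signatures) || nrow(signatures) == 0L) return(contigs)
  for (tn in unique(signatures$contig)) {
    g <- signatures[signatures$contig == tn, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (!tn %in% names(contigs)) stop("unknown contig in signature: ", tn)
    L <- nchar(contigs[[tn]])
    if (any(g$start < 0L) || any(g$end > L) || any(g$start >= g$end)) {
      stop("inversion interval outside contig ", tn)
    }
    if (nrow(g) > 1L && any(g$start[-1] < g$end[-nrow(g)])) {
      stop("overlapping inversion intervals on contig ", tn)
    }
    s <- contigs[[tn]]
    for (i in seq_len(nrow(g))) {
      seg <- substr(s, g$start[i] + 1L, g$end[i])
      s <- paste0(substr(s, 1L, g$start[i]), revcomp(seg),
                  substr(s, g$end[i] + 1L, L))
    }
    contigs[[tn]] <- s
  }
  contigs
}

#' Emit the dual or split diploid assembly
#'
#' Dual mode keeps the contiguity of the input contigs: one sequence per
#' contig per haplotype. Split mode cuts contigs between phase sets so
#' that each output sequence is a single contiguous haplotype.
#'
#' @param hap1,hap2 Named character vectors of polished haplotype contigs
#'   (shared names).
#' @param phase_blocks Optional data.frame (`contig`, `start`, `end`) of
#'   phase-set spans in output coordinates; needed for split mode.
#' @param mode `"dual"` or `"split"`.
#' @return Named character vector of assembly sequences.
#' @export
emit_assembly <- function(hap1, hap2, phase_blocks = NULL,
                          mode = c("dual", "split")) {
  mode <- match.arg(mode)
  stopifnot(identical(names(hap1), names(hap2)))
  if (mode == "dual") {
    out <- c(stats::setNames(hap1, paste0(names(hap1), "_hap1")),
             stats::setNames(hap2, paste0(names(hap2), "_hap2")))
    return(out)
  }
  if (is.null(phase_blocks)) stop("split mode requires phase_blocks")
  out <- character(0)
  for (tn in names(hap1)) {
    pb <- phase_blocks[phase_blocks$contig == tn, , drop = FALSE]
    pb <- pb[order(pb$start), , drop = FALSE]
    for (h in 1:2) {
      s <- (if (h == 1) hap1 else hap2)[[tn]]
      L <- nchar(s)
      cuts <- if (nrow(pb) > 1L) {
        as.integer(round((pb$end[-nrow(pb)] + pb$start[-1]) / 2))
      } else integer(0)
      bounds <- c(0L, pmin(pmax(cuts, 0L), L), L)
      for (k in seq_len(length(bounds) - 1L)) {
        nm <- sprintf("%s_hap%d_part%d", tn, h, k)
        out[nm] <- substr(s, bounds[k] + 1L, bounds[k + 1L])
      }
    }
  }
  out
}

#' Run the dual-assembly stage end-to-end
#'
#' Filters read alignments, calls and phases het SNPs, haplotags reads,
#' polishes each haplotype by chunked consensus, detects and applies
#' inversion signatures, and emits the diploid assembly.
#'
#' @param draft Named character vector of draft contigs.
#' @param alignments Read-to-draft alignment data.frame.
#' @param reads Named character vector of read sequences.
#' @param mode `"dual"` or `"split"`.
#' @param filter_cfg A [read_filter_config()].
#' @param phase_cfg A [phasing_config()].
#' @param min_coverage,min_alt_frac SNP-calling thresholds.
#' @return List with `assembly`, `hap1`, `hap2` (named vectors),
#'   `haplotags`, `phased_snps`, `inversions`, `phase_blocks`, `removed`.
#' @export
hapdup <- function(draft, alignments, reads, mode = c("dual", "split"),
                   filter_cfg = read_filter_config(),
                   phase_cfg = phasing_config(),
                   min_coverage = 8L, min_alt_frac = 0.25) {
  mode <- match.arg(mode)
  flt <- filter_read_alignments(alignments, filter_cfg)
  kept <- flt$kept
  hap1 <- hap2 <- stats::setNames(character(length(draft)), names(draft))
  all_tags <- list(); all_snps <- list(); pblocks <- list(); all_inv <- list()
  for (tn in names(draft)) {
    aln <- kept[kept$target_name == tn, , drop = FALSE]
    aln$seg <- aligned_segments(aln, reads)  # oriented once per contig
    snps <- call_het_snps(aln, reads, draft[tn], min_coverage = min_coverage,
                          min_alt_frac = min_alt_frac)
    ph <- phase_and_haplotag(snps, aln, reads, phase_cfg)
    tags <- ph$haplotags
    all_tags[[tn]] <- tags
    all_snps[[tn]] <- ph$phased
    chunks <- select_chunk_boundaries(aln, nchar(draft[[tn]]))
    pol <- list()
    for (h in 1:2) {
      rn <- tags$read[tags$tag == paste0("H", h)]
      pol[[h]] <- polish_haplotype(draft[tn], aln[aln$query_name %in% rn, , drop = FALSE],
                                   reads, chunks)
    }
    inv <- detect_inversions(aln, haplotags = tags)
    all_inv[[tn]] <- inv
    seqs <- c(pol[[1]]$seq, pol[[2]]$seq)
    if (nrow(inv)) {
      for (h in 1:2) {
        hv <- inv[inv$haplotype %in% c(paste0("H", h), "both"), , drop = FALSE]
        if (nrow(hv) == 0L) next
        pm <- c(pol[[h]]$pos_map, nchar(seqs[h]))
        hv$start <- pm[hv$start + 1L]
        hv$end <- pm[pmin(hv$end, length(pm) - 1L) + 1L]
        hv$contig <- "x"
        seqs[h] <- apply_rearrangements(stats::setNames(seqs[h], "x"), hv)[["x"]]
      }
    }
    hap1[tn] <- seqs[1]; hap2[tn] <- seqs[2]
    # phase-set spans in polished hap1 coordinates
    het <- ph$phased[ph$phased$gt1 != ph$phased$gt2, , drop = FALSE]
    if (nrow(het)) {
      pm <- c(pol[[1]]$pos_map, nchar(seqs[1]))
      for (ps in unique(het$phase_set)) {
        pp <- het$pos[het$phase_set == ps]
        pblocks[[length(pblocks) + 1L]] <- data.frame(
          contig = tn, phase_set = ps,
          start = pm[min(pp)], end = pm[min(max(pp), length(pm) - 1L) + 1L],
          n_variants = length(pp), stringsAsFactors = FALSE)
      }
    }
  }
  phase_blocks <- if (length(pblocks)) do.call(rbind, pblocks)
    else data.frame(contig = character(), phase_set = integer(),
                    start = integer(), end = integer(), n_variants = integer())
  list(assembly = emit_assembly(hap1, hap2, phase_blocks, mode),
       hap1 = hap1, hap2 = hap2,
       haplotags = do.call(rbind, c(all_tags, list(NULL))),
       phased_snps = do.call(rbind, c(all_snps, list(NULL))),
       inversions = do.call(rbind, c(all_inv, list(NULL))),
       phase_blocks = phase_blocks, removed = flt$removed)
}
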
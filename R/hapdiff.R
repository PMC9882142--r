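# Assembly-based structural variant calling: extract variants from
# diploid contig-to-reference alignments, group fragmented indels inside
# VNTRs, filter by size, and merge the two haplotypes into a diploid
# call set.

#' SV calling configuration
#'
#' `aligner_preset` records the fixed minimap2 parameter string used for
#' contig-to-reference alignment ("-ax asm20 -B 2 -E 3,1 -O 6,100");
#' pinning the aligner parameters is part of making the calls
#' reproducible.
#'
#' @param min_sv_len Minimum SV size in bp (default 50).
#' @param merge_tolerance_pos Maximum anchor distance for diploid merging
#'   (default 500 bp).
#' @param merge_tolerance_sizeratio Minimum min/max size ratio for
#'   diploid merging (default 0.7).
#' @param aligner_preset Recorded aligner parameter string.
#' @return An `sv_call_config` list.
#' @export
sv_call_config <- function(min_sv_len = 50L, merge_tolerance_pos = 500L,
                           merge_tolerance_sizeratio = 0.7,
                           aligner_preset = "-ax asm20 -B 2 -E 3,1 -O 6,100") {
  stopifnot(min_sv_len >= 1)
  structure(list(min_sv_len = as.integer(min_sv_len),
                 merge_tolerance_pos = as.integer(merge_tolerance_pos),
                 merge_tolerance_sizeratio = merge_tolerance_sizeratio,
                 aligner_preset = aligner_preset),
            class = "sv_call_config")
}

#' Extract raw variants from contig-to-reference alignments
#'
#' Every insertion/deletion CIGAR op and every mismatch column becomes a
#' raw record (no size filter yet); positions are left-anchored with one
#' shared reference base. Inversions are derived from strand-flipped
#' split alignments of one contig. When two alignments of the same
#' haplotype overlap on the reference, the higher-divergence one is
#' dropped with a warning.
#'
#' @param alignments Contig-to-reference alignments for one haplotype.
#' @param reference Named length-1 character vector (or string).
#' @param contigs Named character vector of contig sequences.
#' @param haplotype 1 or 2.
#' @return Variant table with `haplotype` and `grouped_from` columns.
#' @export
extract_raw_variants <- function(alignments, reference, contigs, haplotype) {
  chrom <- if (!is.null(names(reference))) names(reference) else "ref"
  if (!is.null(names(reference))) reference <- reference[[1]]
  empty <- variant_table(haplotype = haplotype)
  if (nrow(alignments) == 0L) return(empty)

  # drop lower-identity alignments overlapping on the reference
  aln <- alignments[order(alignments$target_start), , drop = FALSE]
  drop <- logical(nrow(aln))
  for (i in seq_len(nrow(aln))[-1]) {
    prev <- max(which(!drop[seq_len(i - 1L)]))
    if (aln$target_start[i] < aln$target_end[prev] &&
        aln$query_name[i] != aln$query_name[prev]) {
      worse <- if (aln$divergence[i] >= aln$divergence[prev]) i else prev
      warning("overlapping contig alignments on the reference; ignoring ",
              aln$query_name[worse], call. = FALSE)
      drop[worse] <- TRUE
    }
  }
  aln <- aln[!drop, , drop = FALSE]

  segs <- aligned_segments(aln, contigs)
  recs <- list()
  for (i in seq_len(nrow(aln))) {
    cig <- parse_cigar(aln$cigar[i])
    tl <- ifelse(cig$op %in% c("=", "X", "M", "D", "N"), cig$len, 0L)
    ql <- ifelse(cig$op %in% c("=", "X", "M", "I"), cig$len, 0L)
    tpos <- aln$target_start[i] + c(0L, cumsum(tl))[seq_along(tl)]
    qpos <- c(0L, cumsum(ql))[seq_along(ql)]
    seg <- segs[i]
    for (k in seq_along(cig$op)) {
      op <- cig$op[k]; len <- cig$len[k]; t0 <- tpos[k]; q0 <- qpos[k]
      if (op == "X") {
        for (j in seq_len(len)) {
          p1 <- t0 + j                     # 1-based position
          recs[[length(recs) + 1L]] <- list(
            pos = p1, ref = substr(reference, p1, p1),
            alt = substr(seg, q0 + j, q0 + j))
        }
      } else if (op == "I") {
        if (t0 < 1L) next                  # no anchor base
        recs[[length(recs) + 1L]] <- list(
          pos = t0, ref = substr(reference, t0, t0),
          alt = paste0(substr(reference, t0, t0), substr(seg, q0 + 1L, q0 + len)))
      } else if (op == "D") {
        if (t0 < 1L) next
        recs[[length(recs) + 1L]] <- list(
          pos = t0, ref = substr(reference, t0, t0 + len),
          alt = substr(reference, t0, t0))
      }
    }
  }

  # structural variants the aligner represented by splitting the contig
  # alignment: consecutive same-strand segments whose query/target gaps
  # disagree become one replacement record spanning the junction
  for (key in unique(aln$query_name)) {
    a <- aln[aln$query_name == key, , drop = FALSE]
    if (nrow(a) < 2L) next
    a <- a[order(a$target_start), , drop = FALSE]
    for (i in seq_len(nrow(a) - 1L)) {
      s1 <- a[i, ]; s2 <- a[i + 1L, ]
      if (s1$strand != s2$strand) next
      t_lo <- s1$target_end; t_hi <- max(s2$target_start, t_lo)
      if (s1$strand == "+") {
        q_lo <- s1$query_end; q_hi <- max(s2$query_start, s1$query_end)
      } else {
        q_lo <- s2$query_end; q_hi <- max(s1$query_start, s2$query_end)
      }
      if (t_hi - t_lo > 50000L || q_hi - q_lo > 50000L) next
      net <- (q_hi - q_lo) - (t_hi - t_lo)
      if (abs(net) < 25L || t_lo < 1L) next
      gap_seq <- substr(contigs[[key]], q_lo + 1L, q_hi)
      if (s1$strand == "-") gap_seq <- revcomp(gap_seq)
      recs[[length(recs) + 1L]] <- list(
        pos = t_lo, ref = substr(reference, t_lo, t_hi),
        alt = paste0(substr(reference, t_lo, t_lo), gap_seq))
    }
  }

  # inversions from strand-flipped split alignments of one contig
  inv <- detect_inversions(aln, min_support = 1L, cluster_eps = 0L)
  inv_rows <- list()
  if (nrow(inv)) {
    for (r in seq_len(nrow(inv))) {
      s <- inv$start[r]; e <- inv$end[r]
      if (s < 1L) next
      span <- substr(reference, s + 1L, e)
      inv_rows[[length(inv_rows) + 1L]] <- list(
        pos = s, ref = paste0(substr(reference, s, s), span),
        alt = paste0(substr(reference, s, s), revcomp(span)), sv_type = "INV")
    }
  }

  all_rows <- c(recs, inv_rows)
  if (length(all_rows) == 0L) return(empty)
  out <- variant_table(
    chrom = rep(chrom, length(all_rows)),
    pos = vapply(all_rows, `[[`, numeric(1), "pos"),
    ref = vapply(all_rows, `[[`, character(1), "ref"),
    alt = vapply(all_rows, `[[`, character(1), "alt"),
    gt1 = if (haplotype == 1L) 1L else 0L,
    gt2 = if (haplotype == 2L) 1L else 0L,
    sv_type = vapply(all_rows, function(r)
      if (!is.null(r$sv_type)) r$sv_type else NA_character_, character(1)),
    haplotype = haplotype)
  out <- out[!duplicated(paste(out$pos, out$ref, out$alt, sep = "\r")), ,
             drop = FALSE]
  out <- sort_variants(out)
  rownames(out) <- NULL
  out
}

#' Group fragmented indels inside VNTR intervals
#'
#' Alignment ambiguity inside a tandem repeat fragments one allele
#' difference into several indels; all indel records of one haplotype
#' anchored inside one VNTR interval are replaced by a single replacement
#' record spanning the whole interval (reference substring to edited
#' substring, net length change, `grouped_from` = count merged). Spanning
#' the full interval rather than the first-to-last affected base makes
#' the grouped record invariant to where the aligner placed the indels.
#' SNPs inside VNTRs are not grouped; records outside VNTRs pass through.
#'
#' @param raw Variant table from [extract_raw_variants()] (one haplotype).
#' @param vntr_bed data.frame (`chrom`, `start`, `end`) of non-overlapping
#'   VNTR intervals.
#' @param reference Named length-1 character vector (or string).
#' @return Variant table with grouped records.
#' @export
group_vntr_indels <- function(raw, vntr_bed, reference) {
  if (!is.null(names(reference))) reference <- reference[[1]]
  if (is.null(vntr_bed) || nrow(vntr_bed) == 0L || nrow(raw) == 0L) return(raw)
  is_indel <- nchar(raw$ref) != nchar(raw$alt) &
    (is.na(raw$sv_type) | raw$sv_type != "INV")
  anchor0 <- raw$pos - 1L
  assigned <- rep(NA_integer_, nrow(raw))
  for (r in seq_len(nrow(vntr_bed))) {
    if (vntr_bed$end[r] > nchar(reference)) next
    hit <- is_indel & raw$chrom == vntr_bed$chrom[r] &
      anchor0 >= vntr_bed$start[r] - 1L & anchor0 < vntr_bed$end[r]
    assigned[hit] <- r
  }
  keep <- raw[is.na(assigned), , drop = FALSE]
  grouped <- list()
  for (r in unique(assigned[!is.na(assigned)])) {
    members <- raw[!is.na(assigned) & assigned == r, , drop = FALSE]
    members <- members[order(members$pos), , drop = FALSE]
    s <- vntr_bed$start[r]; e <- vntr_bed$end[r]
    pos1 <- max(1L, s)                       # 1-based anchor just before the VNTR
    span_ref <- substr(reference, pos1, e)
    # splice member edits into the reference span
    pieces <- character(0)
    prev <- pos1
    ok <- TRUE
    for (m in seq_len(nrow(members))) {
      p <- members$pos[m]
      if (p < prev) { ok <- FALSE; break }   # overlapping members: pass through
      pieces <- c(pieces, substr(reference, prev, p - 1L), members$alt[m])
      prev <- p + nchar(members$ref[m])
    }
    if (!ok || prev > e + 1L) { keep <- rbind(keep, members); next }
    alt <- paste0(paste(pieces, collapse = ""), substr(reference, prev, e))
    net <- sum(nchar(members$alt) - nchar(members$ref))
    grouped[[length(grouped) + 1L]] <- variant_table(
      chrom = members$chrom[1], pos = pos1, ref = span_ref, alt = alt,
      gt1 = members$gt1[1], gt2 = members$gt2[1],
      sv_type = if (net > 0) "INS" else if (net < 0) "DEL" else NA_character_,
      grouped_from = nrow(members), haplotype = members$haplotype[1])
  }
  out <- do.call(rbind, c(list(keep), grouped))
  out <- sort_variants(out)
  rownames(out) <- NULL
  out
}

#' Filter grouped variants to structural variants
#'
#' Keeps records whose net length change (or inverted span, for
#' inversions) is at least `min_sv_len`.
#'
#' @param variants Variant table.
#' @param cfg An [sv_call_config()].
#' @return Variant table of SVs.
#' @export
filter_svs <- function(variants, cfg = sv_call_config()) {
  variants[abs(variants$sv_len) >= cfg$min_sv_len, , drop = FALSE]
}

#' Merge per-haplotype SV calls into diploid genotyped records
#'
#' Records of the same type merge to genotype 1|1 when their anchors are
#' within `merge_tolerance_pos`, their size ratio reaches
#' `merge_tolerance_sizeratio`, and (for insertions) the inserted
#' sequences reach the same edit similarity. A record seen on one
#' haplotype only becomes 1|0 or 0|1; different alleles at the same
#' anchor become a multiallelic 1|2 record.
#'
#' @param h1_svs,h2_svs Per-haplotype SV tables.
#' @param cfg An [sv_call_config()].
#' @return Diploid variant table (phased genotypes, assembly phase set 1).
#' @export
merge_diploid <- function(h1_svs, h2_svs, cfg = sv_call_config()) {
  type_of <- function(df) ifelse(!is.na(df$sv_type), df$sv_type,
                                 ifelse(df$sv_len >= 0, "INS", "DEL"))
  t1 <- type_of(h1_svs); t2 <- type_of(h2_svs)
  used2 <- logical(nrow(h2_svs))
  out <- list()
  seq_sim <- function(v1, v2) {
    m1 <- minimal_variant(v1$pos, v1$ref, v1$alt)
    m2 <- minimal_variant(v2$pos, v2$ref, v2$alt)
    if (nchar(m1$ref) > 1L || nchar(m2$ref) > 1L) return(1)  # replacement records
    ins_seq_similarity(substring(m1$alt, 2L), substring(m2$alt, 2L))
  }
  for (i in seq_len(nrow(h1_svs))) {
    v1 <- h1_svs[i, , drop = FALSE]
    cand <- which(!used2 & h2_svs$chrom == v1$chrom & t2 == t1[i] &
                    abs(h2_svs$pos - v1$pos) <= cfg$merge_tolerance_pos)
    merged <- FALSE
    if (length(cand)) {
      cand <- cand[order(abs(h2_svs$pos[cand] - v1$pos))]
      for (j in cand) {
        v2 <- h2_svs[j, , drop = FALSE]
        ratio <- min(abs(v1$sv_len), abs(v2$sv_len)) /
          max(abs(v1$sv_len), abs(v2$sv_len), 1L)
        sim_ok <- if (t1[i] == "INS")
          seq_sim(v1, v2) >= cfg$merge_tolerance_sizeratio else TRUE
        if (ratio >= cfg$merge_tolerance_sizeratio && sim_ok) {
          rec <- v1
          rec$gt1 <- 1L; rec$gt2 <- 1L
          out[[length(out) + 1L]] <- rec
          used2[j] <- TRUE
          merged <- TRUE
          break
        }
        if (v2$pos == v1$pos && v1$alt != v2$alt) {
          rec <- v1
          rec$alt2 <- v2$alt
          rec$gt1 <- 1L; rec$gt2 <- 2L
          out[[length(out) + 1L]] <- rec
          used2[j] <- TRUE
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) {
      rec <- v1; rec$gt1 <- 1L; rec$gt2 <- 0L
      out[[length(out) + 1L]] <- rec
    }
  }
  for (j in which(!used2)) {
    rec <- h2_svs[j, , drop = FALSE]
    rec$gt1 <- 0L; rec$gt2 <- 1L
    out[[length(out) + 1L]] <- rec
  }
  if (length(out) == 0L) return(variant_table())
  res <- do.call(rbind, out)
  res$phased <- TRUE
  res$phase_set <- 1L
  res$haplotype <- NA_integer_
  res$sv_len <- variant_sv_len(res)
  res$var_class <- variant_class(res)
  res <- sort_variants(res)
  rownames(res) <- NULL
  res
}

#' Call structural variants from a diploid assembly's alignments
#'
#' Runs extraction, VNTR grouping and size filtering per haplotype, then
#' the diploid merge.
#'
#' @param h1_aln,h2_aln Contig-to-reference alignments per haplotype.
#' @param reference Named length-1 character vector.
#' @param contigs Named character vector holding all contig sequences.
#' @param vntr_bed Optional VNTR annotation.
#' @param cfg An [sv_call_config()].
#' @return List with `svs` (diploid SV table), `h1`, `h2` (per-haplotype
#'   filtered SV tables).
#' @export
svcall_from_alignments <- function(h1_aln, h2_aln, reference, contigs,
                                   vntr_bed = NULL, cfg = sv_call_config()) {
  per_hap <- function(aln, h) {
    raw <- extract_raw_variants(aln, reference, contigs, h)
    grouped <- group_vntr_indels(raw, vntr_bed, reference)
    filter_svs(grouped, cfg)
  }
  h1 <- per_hap(h1_aln, 1L)
  h2 <- per_hap(h2_aln, 2L)
  list(svs = merge_diploid(h1, h2, cfg), h1 = h1, h2 = h2)
}
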
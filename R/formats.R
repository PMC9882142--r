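# File format readers/writers.
#
# Internal conventions used throughout the package:
#   * sequences are named character vectors of uppercase ACGTN strings
#   * alignment and interval coordinates are 0-based half-open
#   * VCF positions are 1-based only at the (de)serialization boundary
#   * variant tables are plain data.frames with the columns documented
#     in `variant_table()`

#' Read a FASTA file
#'
#' Sequences are uppercased; `N` is allowed. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(names(seqs)))) stop("FASTA record with empty header in ", path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN characters in FASTA record(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq.int(1L, max(n, 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

## ---- CIGAR helpers ---------------------------------------------------------

#' Parse a CIGAR string into length/op vectors
#' @param cigar CIGAR string such as `"10=1X5I"`.
#' @return List with integer `len` and character `op`.
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) return(list(len = integer(), op = character()))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[=XMIDSHN]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  list(len = lens, op = ops)
}

cigar_query_span <- function(cig) sum(cig$len[cig$op %in% c("=", "X", "M", "I")])
cigar_target_span <- function(cig) sum(cig$len[cig$op %in% c("=", "X", "M", "D", "N")])

#' Alignment divergence from a CIGAR string
#'
#' Divergence is (mismatch + inserted + deleted columns) / all aligned
#' columns. `M` ops are treated as match-or-mismatch, so for M-style CIGARs
#' the value is a lower bound counting only indel columns.
#'
#' @param cigar CIGAR string.
#' @return Fraction in `[0, 1]`.
#' @export
cigar_divergence <- function(cigar) {
  cig <- parse_cigar(cigar)
  cols <- sum(cig$len[cig$op %in% c("=", "X", "M", "I", "D")])
  if (cols == 0L) return(NA_real_)
  sum(cig$len[cig$op %in% c("X", "I", "D")]) / cols
}

## ---- PAF / SAM -------------------------------------------------------------

empty_alignments <- function() {
  data.frame(query_name = character(), query_len = integer(),
             query_start = integer(), query_end = integer(),
             strand = character(), target_name = character(),
             target_len = integer(), target_start = integer(),
             target_end = integer(), mapq = integer(),
             cigar = character(), divergence = numeric(),
             stringsAsFactors = FALSE)
}

#' Read alignments from PAF or SAM text
#'
#' Coordinates are converted to 0-based half-open (SAM `POS` is
#' decremented). Query coordinates are always in original-read orientation,
#' as in PAF. Records without a CIGAR (`cg:` tag in PAF) are skipped with a
#' warning. Divergence is taken from the `de:f:` tag when present, else
#' computed from the CIGAR.
#'
#' @param path Input path.
#' @param dialect `"paf"` or `"sam"`.
#' @return Alignment data.frame (one row per alignment record).
#' @export
read_alignments <- function(path, dialect = c("paf", "sam")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "paf") parse_paf(lines) else parse_sam(lines)
}

parse_paf <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_alignments())
  rows <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) stop("PAF line with fewer than 12 fields")
    tags <- f[-(1:12)]
    cg <- sub("^cg:Z:", "", grep("^cg:Z:", tags, value = TRUE))
    de <- sub("^de:f:", "", grep("^de:f:", tags, value = TRUE))
    if (length(cg) == 0L) {
      warning("PAF record without cg: tag skipped: ", f[1], call. = FALSE)
      return(NULL)
    }
    qs <- as.integer(f[3]); qe <- as.integer(f[4])
    ts <- as.integer(f[8]); te <- as.integer(f[9])
    cig <- parse_cigar(cg[1])
    if (cigar_query_span(cig) != qe - qs || cigar_target_span(cig) != te - ts) {
      stop("PAF record with CIGAR inconsistent with coordinates: ", f[1])
    }
    data.frame(query_name = f[1], query_len = as.integer(f[2]),
               query_start = qs, query_end = qe, strand = f[5],
               target_name = f[6], target_len = as.integer(f[7]),
               target_start = ts, target_end = te,
               mapq = as.integer(f[12]), cigar = cg[1],
               divergence = if (length(de)) as.numeric(de[1]) else cigar_divergence(cg[1]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(empty_alignments())))
}

parse_sam <- function(lines) {
  tlens <- integer()
  hdr <- lines[startsWith(lines, "@")]
  for (h in hdr[startsWith(hdr, "@SQ")]) {
    f <- strsplit(h, "\t", fixed = TRUE)[[1]]
    sn <- sub("^SN:", "", grep("^SN:", f, value = TRUE))
    ln <- sub("^LN:", "", grep("^LN:", f, value = TRUE))
    if (length(sn) && length(ln)) tlens[sn] <- as.integer(ln)
  }
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  rows <- lapply(body, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) stop("SAM line with fewer than 11 fields")
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) == 4L) return(NULL)  # unmapped
    cgs <- f[6]
    if (cgs == "*") {
      warning("SAM record without CIGAR skipped: ", f[1], call. = FALSE)
      return(NULL)
    }
    cig <- parse_cigar(cgs)
    strand <- if (bitwAnd(flag, 16L) == 16L) "-" else "+"
    clip_l <- if (length(cig$op) && cig$op[1] %in% c("S", "H")) cig$len[1] else 0L
    clip_r <- if (length(cig$op) > 1L && cig$op[length(cig$op)] %in% c("S", "H"))
      cig$len[length(cig$op)] else 0L
    qspan <- cigar_query_span(cig)
    qlen <- clip_l + qspan + clip_r
    # aligned-orientation coords, then convert to original-read orientation
    aqs <- clip_l; aqe <- clip_l + qspan
    if (strand == "-") { qs <- qlen - aqe; qe <- qlen - aqs } else { qs <- aqs; qe <- aqe }
    ts <- as.integer(f[4]) - 1L
    te <- ts + cigar_target_span(cig)
    tags <- f[-(1:11)]
    de <- sub("^de:f:", "", grep("^de:f:", tags, value = TRUE))
    core <- paste0(cigar_to_string(cig$len[cig$op %in% c("=", "X", "M", "I", "D", "N")],
                                   cig$op[cig$op %in% c("=", "X", "M", "I", "D", "N")]))
    data.frame(query_name = f[1], query_len = qlen, query_start = qs,
               query_end = qe, strand = strand, target_name = f[3],
               target_len = if (f[3] %in% names(tlens)) tlens[[f[3]]] else NA_integer_,
               target_start = ts, target_end = te, mapq = as.integer(f[5]),
               cigar = core,
               divergence = if (length(de)) as.numeric(de[1]) else cigar_divergence(core),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(empty_alignments())))
}

cigar_to_string <- function(len, op) paste0(paste0(len, op), collapse = "")

#' Write alignments as PAF
#'
#' Emits the 12 mandatory columns plus `cg:Z:` (CIGAR) and `de:f:`
#' (divergence) tags; inverse of [read_alignments()] for the PAF dialect.
#'
#' @param aln Alignment data.frame.
#' @param path Output path.
#' @export
write_paf <- function(aln, path) {
  if (nrow(aln) == 0L) { writeLines(character(), path); return(invisible(path)) }
  nmatch <- vapply(aln$cigar, function(cg) {
    c2 <- parse_cigar(cg); sum(c2$len[c2$op %in% c("=", "M")])
  }, integer(1))
  lines <- paste(aln$query_name, aln$query_len, aln$query_start, aln$query_end,
                 aln$strand, aln$target_name, aln$target_len, aln$target_start,
                 aln$target_end, nmatch,
                 aln$target_end - aln$target_start, aln$mapq,
                 sprintf("de:f:%.6g", aln$divergence),
                 paste0("cg:Z:", aln$cigar), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

## ---- variant tables and VCF ------------------------------------------------

#' Construct a variant table
#'
#' The package-wide variant representation: one row per VCF-style record.
#' `pos` is the 1-based position of the anchor base; indels are
#' left-anchored with one shared leading base. `gt1`/`gt2` are allele codes
#' (0 = REF, 1 = first ALT, 2 = second ALT). `var_class` is `"SV"` iff the
#' maximum allele length difference is at least `sv_threshold`.
#'
#' @param chrom,pos,ref,alt Core VCF fields; `alt2` optional second ALT.
#' @param gt1,gt2 Allele codes.
#' @param phased Logical; phased genotypes are serialized `a|b` with a PS tag.
#' @param phase_set Integer phase-set id (NA when unphased).
#' @param sv_type `"INS"`, `"DEL"`, `"INV"` or NA.
#' @param grouped_from Number of raw records merged into this one.
#' @param haplotype 1, 2 or NA for per-haplotype call sets.
#' @param sv_threshold SV size threshold in bp (default 50).
#' @return data.frame of class `dualvar_variants`.
#' @export
variant_table <- function(chrom = character(), pos = integer(), ref = character(),
                          alt = character(), alt2 = NA_character_,
                          gt1 = 1L, gt2 = 1L, phased = FALSE,
                          phase_set = NA_integer_, sv_type = NA_character_,
                          grouped_from = 1L, haplotype = NA_integer_,
                          sv_threshold = 50L) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   pos = rep_len(as.integer(pos), n),
                   ref = rep_len(as.character(ref), n),
                   alt = rep_len(as.character(alt), n),
                   alt2 = rep_len(as.character(alt2), n),
                   gt1 = rep_len(as.integer(gt1), n),
                   gt2 = rep_len(as.integer(gt2), n),
                   phased = rep_len(as.logical(phased), n),
                   phase_set = rep_len(as.integer(phase_set), n),
                   sv_type = rep_len(as.character(sv_type), n),
                   grouped_from = rep_len(as.integer(grouped_from), n),
                   haplotype = rep_len(as.integer(haplotype), n),
                   stringsAsFactors = FALSE)
  df$sv_len <- variant_sv_len(df)
  df$var_class <- variant_class(df, sv_threshold)
  class(df) <- c("dualvar_variants", "data.frame")
  df
}

#' Net length change of each variant record
#' @param df Variant table.
#' @return Integer vector: insertion lengths positive, deletions negative.
#' @export
variant_sv_len <- function(df) {
  if (nrow(df) == 0L) return(integer())
  d1 <- nchar(df$alt) - nchar(df$ref)
  d2 <- ifelse(is.na(df$alt2), 0L, nchar(df$alt2) - nchar(df$ref))
  out <- ifelse(abs(d2) > abs(d1), d2, d1)
  # inversions conserve length; size them by their span
  inv <- !is.na(df$sv_type) & df$sv_type == "INV"
  out[inv] <- nchar(df$ref[inv]) - 1L
  as.integer(out)
}

variant_class <- function(df, sv_threshold = 50L) {
  if (nrow(df) == 0L) return(character())
  len_diff <- pmax(abs(nchar(df$alt) - nchar(df$ref)),
                   ifelse(is.na(df$alt2), 0L, abs(nchar(df$alt2) - nchar(df$ref))))
  inv <- !is.na(df$sv_type) & df$sv_type == "INV"
  len_diff[inv] <- nchar(df$ref[inv]) - 1L
  ifelse(len_diff >= sv_threshold, "SV",
         ifelse(len_diff == 0L & nchar(df$ref) == 1L, "SNP", "INDEL"))
}

#' Sort a variant table by genomic position
#' @param df Variant table.
#' @return The table ordered by (chrom, pos, ref, alt).
#' @export
sort_variants <- function(df) {
  df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
}

#' Write a variant table as VCF 4.2 text
#'
#' Phased genotypes are emitted as `a|b` with a `PS` FORMAT field equal to
#' the phase set; unphased as `a/b`. SVs carry `SVTYPE` and `SVLEN` INFO
#' fields, grouped records a `GROUPED` INFO field. Round trip through
#' [read_vcf()] is lossless for these fields.
#'
#' @param df Variant table, sorted by (chrom, pos).
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths for the header.
#' @param sample Sample name.
#' @export
write_vcf <- function(df, path, contigs = NULL, sample = "SAMPLE") {
  if (nrow(df) > 1L) {
    o <- order(df$chrom, df$pos)
    if (any(o != seq_len(nrow(df)))) stop("variant table must be sorted by (chrom, pos)")
  }
  if (nrow(df) && any(!df$gt1 %in% 0:2 | !df$gt2 %in% 0:2, na.rm = TRUE)) {
    stop("unknown genotype allele codes (must be 0, 1 or 2)")
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=dualvar",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Structural variant type\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Net length change\">",
           "##INFO=<ID=GROUPED,Number=1,Type=Integer,Description=\"Raw records merged into this record\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 "FORMAT", sample, sep = "\t"))
  if (nrow(df) == 0L) { writeLines(hdr, path); return(invisible(path)) }
  alt_field <- ifelse(is.na(df$alt2), df$alt, paste(df$alt, df$alt2, sep = ","))
  info <- rep(".", nrow(df))
  is_sv <- df$var_class == "SV"
  info[is_sv] <- sprintf("SVTYPE=%s;SVLEN=%d",
                         ifelse(is.na(df$sv_type[is_sv]),
                                ifelse(df$sv_len[is_sv] >= 0, "INS", "DEL"),
                                df$sv_type[is_sv]),
                         df$sv_len[is_sv])
  gi <- df$grouped_from > 1L
  info[gi] <- paste0(ifelse(info[gi] == ".", "", paste0(info[gi], ";")),
                     "GROUPED=", df$grouped_from[gi])
  sep <- ifelse(df$phased, "|", "/")
  gt <- paste0(df$gt1, sep, df$gt2)
  fmt <- ifelse(df$phased & !is.na(df$phase_set), "GT:PS", "GT")
  samp <- ifelse(fmt == "GT:PS", paste0(gt, ":", df$phase_set), gt)
  lines <- paste(df$chrom, df$pos, ".", df$ref, alt_field, ".", "PASS",
                 info, fmt, samp, sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a VCF file into a variant table
#'
#' Understands the fields written by [write_vcf()]: GT (phased or not), PS,
#' SVTYPE, SVLEN, GROUPED, and one or two ALT alleles.
#'
#' @param path Input path.
#' @param sv_threshold SV size threshold used for classification.
#' @return Variant table.
#' @export
read_vcf <- function(path, sv_threshold = 50L) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L) return(variant_table())
  f <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[`, character(1), i)
  alts <- strsplit(get(5), ",", fixed = TRUE)
  if (any(lengths(alts) > 2L)) stop("more than two ALT alleles are not supported")
  info <- get(8)
  info_tag <- function(tag) {
    pat <- paste0("(^|;)", tag, "=([^;]+)")
    out <- rep(NA_character_, length(info))
    hit <- grepl(pat, info)
    out[hit] <- sub(paste0(".*(^|;)", tag, "=([^;]+).*"), "\\2", info[hit])
    out
  }
  fmt <- strsplit(get(9), ":", fixed = TRUE)
  samp <- strsplit(get(10), ":", fixed = TRUE)
  gt_raw <- mapply(function(k, v) v[match("GT", k)], fmt, samp)
  ps_raw <- mapply(function(k, v) v[match("PS", k)], fmt, samp)
  phased <- grepl("|", gt_raw, fixed = TRUE)
  gt_parts <- strsplit(gt_raw, "[/|]")
  bad <- vapply(gt_parts, function(g)
    length(g) != 2L || any(!g %in% c("0", "1", "2")), logical(1))
  if (any(bad)) stop("unknown genotype codes in VCF: ",
                     paste(unique(gt_raw[bad]), collapse = ", "))
  variant_table(chrom = get(1), pos = as.integer(get(2)),
                ref = get(4),
                alt = vapply(alts, `[`, character(1), 1),
                alt2 = vapply(alts, function(a) if (length(a) > 1) a[2] else NA_character_, character(1)),
                gt1 = as.integer(vapply(gt_parts, `[`, character(1), 1)),
                gt2 = as.integer(vapply(gt_parts, `[`, character(1), 2)),
                phased = phased,
                phase_set = as.integer(ps_raw),
                sv_type = info_tag("SVTYPE"),
                grouped_from = {
                  g <- as.integer(info_tag("GROUPED")); ifelse(is.na(g), 1L, g)
                },
                sv_threshold = sv_threshold)
}

## ---- BED -------------------------------------------------------------------

#' Read a BED3/BED4 file
#'
#' Track and comment lines are skipped. Intervals are 0-based half-open.
#'
#' @param path Input path.
#' @param merge If TRUE, overlapping intervals with the same label are unioned.
#' @return data.frame with `chrom`, `start`, `end`, `label`.
#' @export
read_bed <- function(path, merge = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      label = character(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 3L)) stop("BED line with fewer than 3 fields")
  df <- data.frame(chrom = vapply(f, `[`, character(1), 1),
                   start = as.integer(vapply(f, `[`, character(1), 2)),
                   end = as.integer(vapply(f, `[`, character(1), 3)),
                   label = vapply(f, function(x) if (length(x) >= 4L) x[4] else ".",
                                  character(1)),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("BED interval with start >= end")
  if (merge) df <- merge_bed(df)
  df
}

#' Union overlapping intervals sharing a chrom and label
#' @param df BED data.frame.
#' @return Merged BED data.frame sorted by (chrom, start).
#' @export
merge_bed <- function(df) {
  out <- lapply(split(df, paste(df$chrom, df$label, sep = "\r")), function(g) {
    ir <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    data.frame(chrom = g$chrom[1], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), label = g$label[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write a BED4 file
#' @param df data.frame with `chrom`, `start`, `end` and optionally `label`.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  label <- if ("label" %in% names(df)) df$label else "."
  writeLines(paste(df$chrom, df$start, df$end, label, sep = "\t"), path)
  invisible(path)
}

## ---- bedMethyl -------------------------------------------------------------

#' Read a bedMethyl file (9+2 column layout)
#'
#' Expects the modbam2bed-style layout: 9 standard BED columns followed by
#' read coverage and percent methylation. Other dialects are rejected.
#'
#' @param path Input path.
#' @return data.frame with `chrom`, `pos` (0-based cytosine position),
#'   `strand`, `coverage`, `meth_frac`.
#' @export
read_bedmethyl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), strand = character(),
                      coverage = integer(), meth_frac = numeric(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 11L)) {
    stop("bedMethyl dialect not recognized: expected >= 11 columns (9+2 layout)")
  }
  pct <- as.numeric(vapply(f, `[`, character(1), 11))
  if (any(is.na(pct) | pct < 0 | pct > 100)) {
    stop("percent-methylation outside [0, 100] in ", path)
  }
  data.frame(chrom = vapply(f, `[`, character(1), 1),
             pos = as.integer(vapply(f, `[`, character(1), 2)),
             strand = vapply(f, `[`, character(1), 6),
             coverage = as.integer(vapply(f, `[`, character(1), 10)),
             meth_frac = pct / 100,
             stringsAsFactors = FALSE)
}

#' Write methylation sites as bedMethyl (9+2 layout)
#' @param sites data.frame as returned by [read_bedmethyl()].
#' @param path Output path.
#' @export
write_bedmethyl <- function(sites, path) {
  pct <- round(sites$meth_frac * 100, 2)
  writeLines(paste(sites$chrom, sites$pos, sites$pos + 1L, "5mC", "0",
                   sites$strand, sites$pos, sites$pos + 1L, "0,0,0",
                   sites$coverage, pct, sep = "\t"), path)
  invisible(path)
}

## ---- small shared utilities ------------------------------------------------

#' Minimal (trimmed) representation of a variant record
#'
#' Trims the common suffix, then the common prefix (keeping at least one
#' base when either allele would become empty, per the VCF anchor
#' convention) and shifts the position accordingly. A replacement record
#' that encodes one contiguous indel reduces to that pure indel.
#'
#' @param pos 1-based position.
#' @param ref,alt Allele strings.
#' @return List with trimmed `pos`, `ref`, `alt`.
#' @export
minimal_variant <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  # suffix
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  # prefix
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Reverse complement of a nucleotide string
#' @param seq Uppercase ACGTN string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  if (nchar(seq) == 0L) return(seq)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
}
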
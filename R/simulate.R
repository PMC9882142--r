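# Synthetic diploid genome / long-read / methylation simulator with full
# ground truth. One chromosome per simulation; every downstream module can
# be exercised end-to-end from these outputs.

#' Simulation configuration
#'
#' Defaults describe the desk-scale profile the package is tested at: a
#' 1 Mb diploid chromosome at 30x coverage with 20 kb mean reads, het SNPs
#' at 1/1000 bp, 200 structural variants of 50-2000 bp of which 50 are
#' VNTR copy-number changes, and 1% per-base read error. Inversions are
#' given a small default weight, mirroring their rarity relative to
#' insertions and deletions in human SV catalogs.
#'
#' @param seed Integer RNG seed; all outputs are deterministic given it.
#' @param genome_len Reference length in bp.
#' @param snp_rate Het SNPs per bp.
#' @param indel_rate Het small-indel rate per bp (lengths geometric, mean
#'   `indel_mean_len`, capped below the SV threshold).
#' @param indel_mean_len Mean small-indel length in bp.
#' @param n_svs Total number of structural variants, including the VNTR
#'   copy-number SVs.
#' @param sv_len_range Length range (bp) for non-VNTR SVs; minimum >= 50.
#' @param sv_types Allowed non-VNTR SV types, subset of INS/DEL/INV.
#' @param sv_type_weights Sampling weights for `sv_types`.
#' @param n_vntrs Number of VNTR loci; each receives one copy-number SV
#'   (up to `n_svs`).
#' @param vntr_unit_len Repeat unit length in bp.
#' @param vntr_unit_copies Range of unit copies in the reference locus.
#' @param vntr_cn_delta_range Signed copy-number change range per locus.
#' @param read_len_mean Mean read length in bp (lognormal lengths).
#' @param read_len_sdlog Lognormal sdlog of read lengths.
#' @param coverage Total diploid fold coverage (split evenly across haplotypes).
#' @param read_error Per-base read error fraction.
#' @param error_mix Mismatch/insertion/deletion error proportions.
#' @param homopolymer_factor Multiplier on the indel error rate inside
#'   homopolymers of length >= `homopolymer_min`.
#' @param homopolymer_min Minimum homopolymer length for the boost.
#' @param tile_reads If TRUE, a deterministic 2x tiling of each haplotype is
#'   included before random sampling, guaranteeing full coverage.
#' @param meth_regions Number of methylation regions.
#' @param meth_region_len Region length in bp.
#' @param meth_diff_fraction Fraction of regions made haplotype-differential.
#' @param meth_diff_delta Methylation shift applied to one haplotype in
#'   differential regions.
#' @param meth_noise_sd Per-site Gaussian noise SD (truncated to `[0, 1]`).
#' @param meth_coverage Mean per-site read coverage (default `coverage / 2`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_len = 1e6, snp_rate = 0.001,
                       indel_rate = 2e-4, indel_mean_len = 3,
                       n_svs = 200L, sv_len_range = c(50L, 2000L),
                       sv_types = c("INS", "DEL", "INV"),
                       sv_type_weights = c(INS = 0.50, DEL = 0.48, INV = 0.02),
                       n_vntrs = 50L, vntr_unit_len = 25L,
                       vntr_unit_copies = c(8L, 20L),
                       vntr_cn_delta_range = c(-4L, 4L),
                       read_len_mean = 20000, read_len_sdlog = 0.35,
                       coverage = 30, read_error = 0.01,
                       error_mix = c(mismatch = 0.4, ins = 0.3, del = 0.3),
                       homopolymer_factor = 3, homopolymer_min = 4L,
                       tile_reads = FALSE,
                       meth_regions = 200L, meth_region_len = 1000L,
                       meth_diff_fraction = 0.05, meth_diff_delta = 0.5,
                       meth_noise_sd = 0.05, meth_coverage = NULL) {
  cfg <- list(seed = as.integer(seed), genome_len = as.integer(genome_len),
              snp_rate = snp_rate, indel_rate = indel_rate,
              indel_mean_len = indel_mean_len, n_svs = as.integer(n_svs),
              sv_len_range = as.integer(sv_len_range),
              sv_types = sv_types,
              sv_type_weights = sv_type_weights[sv_types],
              n_vntrs = as.integer(n_vntrs),
              vntr_unit_len = as.integer(vntr_unit_len),
              vntr_unit_copies = as.integer(vntr_unit_copies),
              vntr_cn_delta_range = as.integer(vntr_cn_delta_range),
              read_len_mean = read_len_mean, read_len_sdlog = read_len_sdlog,
              coverage = coverage, read_error = read_error,
              error_mix = error_mix / sum(error_mix),
              homopolymer_factor = homopolymer_factor,
              homopolymer_min = as.integer(homopolymer_min),
              tile_reads = isTRUE(tile_reads),
              meth_regions = as.integer(meth_regions),
              meth_region_len = as.integer(meth_region_len),
              meth_diff_fraction = meth_diff_fraction,
              meth_diff_delta = meth_diff_delta,
              meth_noise_sd = meth_noise_sd,
              meth_coverage = if (is.null(meth_coverage)) coverage / 2 else meth_coverage)
  stopifnot(cfg$genome_len > 0, cfg$snp_rate >= 0, cfg$indel_rate >= 0,
            cfg$coverage > 0, cfg$read_error >= 0, cfg$read_error < 1)
  if (cfg$n_svs > 0 && cfg$sv_len_range[1] < 50L)
    stop("sv_len_range minimum must be >= 50 bp (SV definition)")
  class(cfg) <- "sim_config"
  cfg
}

# Sub-streams derived from the master seed by fixed labels so adding a
# feature does not shift unrelated draws. Offsets kept below 2^31.
sim_seed <- function(cfg, stage) {
  offs <- c(genome = 101L, vntr = 211L, variants = 307L, reads1 = 401L,
            reads2 = 503L, meth = 601L, regions = 701L)
  as.integer((as.numeric(cfg$seed) * 7919 + offs[[stage]]) %% 2147483647)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a diploid genome with known truth
#'
#' Builds a random reference with embedded VNTR loci, draws het SNPs,
#' small indels and structural variants (non-overlapping on the
#' reference), realizes VNTR SVs as whole-unit copy-number changes, and
#' applies the phased variants to produce the two haplotype sequences.
#'
#' @param cfg A [sim_config()].
#' @return A `dualvar_truth` list with elements `reference`, `hap1`,
#'   `hap2` (named character vectors), `truth_variants` (phased variant
#'   table), `vntr_bed`, `region_bed`, and `config`.
#' @export
simulate_diploid <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chrom <- "chr1"
  L <- cfg$genome_len

  set.seed(sim_seed(cfg, "genome"))
  ref_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  # --- VNTR loci: tandem unit arrays embedded into the reference ---------
  set.seed(sim_seed(cfg, "vntr"))
  vntr <- place_vntrs(ref_chars, cfg)
  ref_chars <- vntr$ref_chars
  vntr_bed <- vntr$bed
  reference <- paste(ref_chars, collapse = "")

  # --- variants ----------------------------------------------------------
  set.seed(sim_seed(cfg, "variants"))
  occupied <- logical(L)
  occupied_sv <- logical(L)  # SV footprints with a wide exclusion zone
  margin <- 25L
  sv_margin <- 500L          # SVs are isolated events, not compound clusters
  reserve <- function(s, e) { # 0-based half-open with margin
    lo <- max(1L, s + 1L - margin); hi <- min(L, e + margin)
    occupied[lo:hi] <<- TRUE
    invisible(NULL)
  }
  reserve_sv <- function(s, e) {
    lo <- max(1L, s + 1L - sv_margin); hi <- min(L, e + sv_margin)
    occupied_sv[lo:hi] <<- TRUE
    invisible(NULL)
  }
  for (i in seq_len(nrow(vntr_bed))) {
    reserve(vntr_bed$start[i], vntr_bed$end[i])
    reserve_sv(vntr_bed$start[i], vntr_bed$end[i])
  }

  vars <- list()

  # VNTR copy-number SVs: one per locus, first n_vntr_svs loci
  n_vntr_svs <- min(cfg$n_vntrs, cfg$n_svs)
  min_units <- ceiling(50 / cfg$vntr_unit_len)
  max_units <- max(abs(cfg$vntr_cn_delta_range))
  if (n_vntr_svs > 0 && min_units > max_units) {
    stop("vntr_cn_delta_range cannot produce a copy-number change of >= 50 bp ",
         "with vntr_unit_len = ", cfg$vntr_unit_len)
  }
  for (i in seq_len(n_vntr_svs)) {
    s <- vntr_bed$start[i]; e <- vntr_bed$end[i]
    unit <- vntr_bed$unit[i]
    k <- sample(min_units:max_units, 1L)
    sign <- sample(c(1L, -1L), 1L)
    if (sign < 0 && e - s <= k * cfg$vntr_unit_len) sign <- 1L
    hap <- sample(1:2, 1L)
    if (sign > 0) { # insert k extra units after the locus end
      anchor <- e                     # 1-based position of last locus base
      rec <- list(pos = anchor, ref = substr(reference, anchor, anchor),
                  alt = paste0(substr(reference, anchor, anchor),
                               strrep(unit, k)),
                  sv_type = "INS")
    } else {        # delete the last k units of the locus
      del_len <- k * cfg$vntr_unit_len
      anchor <- e - del_len           # 1-based anchor before deleted tail
      rec <- list(pos = anchor, ref = substr(reference, anchor, e),
                  alt = substr(reference, anchor, anchor),
                  sv_type = "DEL")
    }
    rec$hap <- hap; rec$vntr <- TRUE
    vars[[length(vars) + 1L]] <- rec
  }

  # non-VNTR SVs
  n_other <- cfg$n_svs - n_vntr_svs
  place_span <- function(span) {
    for (try in 1:2000) {
      p <- sample.int(L - span - 2L * sv_margin, 1L) + sv_margin  # 1-based anchor
      if (!any(occupied[p:(p + span)]) && !any(occupied_sv[p:(p + span)])) {
        reserve(p - 1L, p + span)
        reserve_sv(p - 1L, p + span)
        return(p)
      }
    }
    stop("could not place variant: requested variant density infeasible ",
         "(overlap saturation at genome_len = ", L, ")")
  }
  if (n_other > 0) {
    types <- sample(cfg$sv_types, n_other, replace = TRUE,
                    prob = cfg$sv_type_weights)
    for (ty in types) {
      len <- sample(cfg$sv_len_range[1]:cfg$sv_len_range[2], 1L)
      hap <- sample(1:2, 1L)
      if (ty == "INS") {
        p <- place_span(1L)
        rec <- list(pos = p, ref = substr(reference, p, p),
                    alt = paste0(substr(reference, p, p), random_seq(len)),
                    sv_type = "INS")
      } else if (ty == "DEL") {
        p <- place_span(len)
        rec <- list(pos = p, ref = substr(reference, p, p + len),
                    alt = substr(reference, p, p), sv_type = "DEL")
      } else {
        p <- place_span(len)
        span <- substr(reference, p + 1L, p + len)
        rec <- list(pos = p, ref = paste0(substr(reference, p, p), span),
                    alt = paste0(substr(reference, p, p), revcomp(span)),
                    sv_type = "INV")
      }
      rec$hap <- hap; rec$vntr <- FALSE
      vars[[length(vars) + 1L]] <- rec
    }
  }

  # small indels
  ind_pos <- which(stats::runif(L) < cfg$indel_rate)
  for (p in ind_pos) {
    if (p <= margin || p >= L - margin) next
    len <- min(49L, 1L + stats::rgeom(1L, 1 / cfg$indel_mean_len))
    if (p + len >= L) next
    if (any(occupied[p:(p + len)])) next
    reserve(p - 1L, p + len)
    if (stats::runif(1) < 0.5) {
      rec <- list(pos = p, ref = substr(reference, p, p),
                  alt = paste0(substr(reference, p, p), random_seq(len)),
                  sv_type = NA_character_)
    } else {
      rec <- list(pos = p, ref = substr(reference, p, p + len),
                  alt = substr(reference, p, p), sv_type = NA_character_)
    }
    rec$hap <- sample(1:2, 1L); rec$vntr <- FALSE
    vars[[length(vars) + 1L]] <- rec
  }

  # het SNPs
  snp_pos <- which(stats::runif(L) < cfg$snp_rate)
  snp_pos <- snp_pos[!occupied[snp_pos]]
  for (p in snp_pos) {
    rb <- ref_chars[p]
    ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
    vars[[length(vars) + 1L]] <- list(pos = p, ref = rb, alt = ab,
                                      sv_type = NA_character_,
                                      hap = sample(1:2, 1L), vntr = FALSE)
  }
  occupied[snp_pos] <- TRUE

  pos <- vapply(vars, `[[`, numeric(1), "pos")
  hap <- vapply(vars, `[[`, numeric(1), "hap")
  tv <- variant_table(chrom = rep(chrom, length(vars)), pos = as.integer(pos),
                      ref = vapply(vars, `[[`, character(1), "ref"),
                      alt = vapply(vars, `[[`, character(1), "alt"),
                      gt1 = ifelse(hap == 1, 1L, 0L),
                      gt2 = ifelse(hap == 2, 1L, 0L),
                      phased = TRUE, phase_set = 1L,
                      sv_type = vapply(vars, `[[`, character(1), "sv_type"))
  tv$vntr_cn <- vapply(vars, `[[`, logical(1), "vntr")
  tv <- sort_variants(tv)
  rownames(tv) <- NULL

  hap1 <- apply_variants(reference, tv, hap = 1L)
  hap2 <- apply_variants(reference, tv, hap = 2L)

  # --- methylation regions ----------------------------------------------
  set.seed(sim_seed(cfg, "regions"))
  region_bed <- place_regions(L, cfg, chrom)

  out <- list(reference = stats::setNames(reference, chrom),
              hap1 = stats::setNames(hap1, paste0(chrom, "_hap1")),
              hap2 = stats::setNames(hap2, paste0(chrom, "_hap2")),
              truth_variants = tv, vntr_bed = vntr_bed,
              region_bed = region_bed, config = cfg)
  class(out) <- "dualvar_truth"
  out
}

place_vntrs <- function(ref_chars, cfg) {
  L <- length(ref_chars)
  bed <- data.frame(chrom = character(), start = integer(), end = integer(),
                    label = character(), unit = character(),
                    stringsAsFactors = FALSE)
  if (cfg$n_vntrs == 0L) return(list(ref_chars = ref_chars, bed = bed))
  max_len <- cfg$vntr_unit_len * cfg$vntr_unit_copies[2]
  slots <- floor(L / (max_len + 2000L))
  if (slots < cfg$n_vntrs) {
    stop("genome too short for ", cfg$n_vntrs, " VNTR loci: requested variant ",
         "density infeasible (overlap saturation)")
  }
  anchors <- sort(sample.int(slots, cfg$n_vntrs)) * (max_len + 2000L) - max_len
  rows <- vector("list", cfg$n_vntrs)
  for (i in seq_len(cfg$n_vntrs)) {
    unit <- random_seq(cfg$vntr_unit_len)
    copies <- sample(cfg$vntr_unit_copies[1]:cfg$vntr_unit_copies[2], 1L)
    arr <- strsplit(strrep(unit, copies), "")[[1]]
    s <- anchors[i]                       # 0-based start
    ref_chars[(s + 1L):(s + length(arr))] <- arr
    rows[[i]] <- data.frame(chrom = "chr1", start = s, end = s + length(arr),
                            label = sprintf("vntr_%03d", i), unit = unit,
                            stringsAsFactors = FALSE)
  }
  list(ref_chars = ref_chars, bed = do.call(rbind, rows))
}

place_regions <- function(L, cfg, chrom) {
  n <- cfg$meth_regions
  if (n == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      label = character(), differential = logical(),
                      diff_hap = integer(), stringsAsFactors = FALSE))
  }
  w <- cfg$meth_region_len
  # non-overlapping placement (methylation regions model promoters, which
  # do not stack); one region per 2*w slot
  slots <- floor(L / (2L * w))
  if (slots < n) {
    stop("genome too short for ", n, " non-overlapping methylation regions")
  }
  starts <- sort(sample.int(slots, n)) * 2L * w - 2L * w +
    sample.int(w, n, replace = TRUE)
  data.frame(chrom = chrom, start = starts, end = starts + w,
             label = sprintf("region_%04d", seq_len(n)),
             differential = stats::runif(n) < cfg$meth_diff_fraction,
             diff_hap = sample(1:2, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Apply phased variants to a reference sequence
#'
#' @param reference Reference sequence string.
#' @param variants Variant table with non-overlapping records sorted by
#'   position.
#' @param hap Haplotype (1 or 2) whose alleles are applied.
#' @return The haplotype sequence.
#' @export
apply_variants <- function(reference, variants, hap = 1L) {
  if (length(reference) == 1L && !is.null(names(reference))) {
    reference <- reference[[1]]
  }
  code <- if (hap == 1L) variants$gt1 else variants$gt2
  sel <- which(code != 0L)
  if (length(sel) == 0L) return(reference)
  v <- variants[sel, , drop = FALSE]
  o <- order(v$pos)
  v <- v[o, , drop = FALSE]
  ref_end <- v$pos + nchar(v$ref) - 1L
  if (any(v$pos[-1] <= ref_end[-length(ref_end)])) {
    stop("overlapping variant records cannot be applied")
  }
  allele <- ifelse((if (hap == 1L) v$gt1 else v$gt2) == 2L, v$alt2, v$alt)
  pieces <- character(2L * nrow(v) + 1L)
  prev <- 1L
  for (i in seq_len(nrow(v))) {
    pieces[2L * i - 1L] <- substr(reference, prev, v$pos[i] - 1L)
    pieces[2L * i] <- allele[i]
    prev <- ref_end[i] + 1L
  }
  pieces[2L * nrow(v) + 1L] <- substr(reference, prev, nchar(reference))
  paste(pieces, collapse = "")
}

# Piecewise-linear map from haplotype to reference coordinates (0-based).
# Returns a function f(h) -> reference position.
hap_to_ref_map <- function(variants, hap = 1L) {
  code <- if (hap == 1L) variants$gt1 else variants$gt2
  v <- variants[code != 0L, , drop = FALSE]
  if (nrow(v) == 0L) return(function(h) h)
  v <- v[order(v$pos), , drop = FALSE]
  allele <- ifelse((if (hap == 1L) v$gt1 else v$gt2) == 2L, v$alt2, v$alt)
  rl <- nchar(v$ref); al <- nchar(allele)
  dlen <- al - rl
  shift_before <- c(0L, cumsum(dlen))[seq_len(nrow(v))]  # shift upstream of variant i
  shift_after <- cumsum(dlen)                            # shift downstream of variant i
  ref_anchor <- v$pos - 1L                               # 0-based anchor
  hap_anchor <- ref_anchor + shift_before
  hap_allele_end <- hap_anchor + al                      # hap pos just past the allele
  function(h) {
    i <- findInterval(h, hap_anchor)
    out <- h
    inside <- i >= 1L
    if (any(inside)) {
      ii <- i[inside]; hh <- h[inside]
      past <- hh >= hap_allele_end[ii]
      res <- ifelse(past, hh - shift_after[ii],
                    ref_anchor[ii] + pmin(hh - hap_anchor[ii], rl[ii]))
      out[inside] <- res
    }
    out
  }
}

#' Simulate long reads from both haplotypes
#'
#' Reads are sampled uniformly from each haplotype at `coverage / 2`,
#' lengths drawn from a lognormal with the configured mean. Errors are
#' injected per base; the indel error rate is multiplied by
#' `homopolymer_factor` inside homopolymers of at least `homopolymer_min`
#' bp. The exact alignment of every read to its haplotype of origin is
#' recorded (CIGAR over the injected errors) together with the projected
#' reference interval.
#'
#' @param truth Output of [simulate_diploid()].
#' @param cfg The simulation config (defaults to `truth$config`).
#' @return List with `reads` (named character vector), `table` (one row
#'   per read: haplotype label, origin interval, projected reference
#'   interval) and `alignments` (exact read-to-haplotype alignment
#'   data.frame in PAF layout).
#' @export
simulate_reads <- function(truth, cfg = truth$config) {
  stopifnot(inherits(truth, "dualvar_truth"))
  if (cfg$coverage <= 0) stop("coverage must be positive")
  out <- list()
  for (h in 1:2) {
    set.seed(sim_seed(cfg, paste0("reads", h)))
    hseq <- truth[[paste0("hap", h)]][[1]]
    hname <- names(truth[[paste0("hap", h)]])
    out[[h]] <- sample_hap_reads(hseq, hname, h, truth, cfg)
  }
  reads <- c(out[[1]]$reads, out[[2]]$reads)
  table <- rbind(out[[1]]$table, out[[2]]$table)
  aln <- rbind(out[[1]]$aln, out[[2]]$aln)
  rownames(table) <- NULL
  list(reads = reads, table = table, alignments = aln)
}

sample_hap_reads <- function(hseq, hname, hap, truth, cfg) {
  hlen <- nchar(hseq)
  target <- cfg$genome_len * cfg$coverage / 2
  mlog <- log(cfg$read_len_mean) - cfg$read_len_sdlog^2 / 2
  starts <- integer(); lens <- integer()
  if (cfg$tile_reads) {
    step <- max(1L, as.integer(cfg$read_len_mean / 2))
    ts <- seq.int(0L, max(0L, hlen - 1L), by = step)
    tl <- pmin(as.integer(cfg$read_len_mean), hlen - ts)
    keep <- tl >= 50L
    starts <- ts[keep]; lens <- tl[keep]
  }
  total <- sum(lens)
  while (total < target) {
    n_draw <- max(16L, ceiling((target - total) / cfg$read_len_mean))
    l <- pmin(as.integer(round(stats::rlnorm(n_draw, mlog, cfg$read_len_sdlog))), hlen)
    l <- pmax(l, 200L)
    s <- vapply(l, function(li) sample.int(hlen - li + 1L, 1L) - 1L, integer(1))
    starts <- c(starts, s); lens <- c(lens, l)
    total <- total + sum(l)
  }
  n <- length(starts)
  names_v <- sprintf("read_h%d_%05d", hap, seq_len(n))
  hp_mask <- homopolymer_mask(hseq, cfg$homopolymer_min)
  map <- hap_to_ref_map(truth$truth_variants, hap)
  reads <- character(n)
  cigars <- character(n)
  qlens <- integer(n)
  for (i in seq_len(n)) {
    sub <- substr(hseq, starts[i] + 1L, starts[i] + lens[i])
    mut <- inject_errors(sub, hp_mask[(starts[i] + 1L):(starts[i] + lens[i])], cfg)
    reads[i] <- mut$seq
    cigars[i] <- mut$cigar
    qlens[i] <- nchar(mut$seq)
  }
  ref_start <- map(starts)
  ref_end <- map(starts + lens)
  table <- data.frame(read = names_v, hap = hap, hap_name = hname,
                      hap_start = starts, hap_end = starts + lens,
                      ref_start = ref_start, ref_end = ref_end,
                      length = qlens, stringsAsFactors = FALSE)
  aln <- data.frame(query_name = names_v, query_len = qlens,
                    query_start = 0L, query_end = qlens, strand = "+",
                    target_name = hname, target_len = hlen,
                    target_start = starts, target_end = starts + lens,
                    mapq = 60L, cigar = cigars,
                    divergence = vapply(cigars, cigar_divergence, numeric(1),
                                        USE.NAMES = FALSE),
                    stringsAsFactors = FALSE)
  list(reads = stats::setNames(reads, names_v), table = table, aln = aln)
}

homopolymer_mask <- function(seq, min_len) {
  ch <- strsplit(seq, "")[[1]]
  r <- rle(ch)
  rep(r$lengths >= min_len, r$lengths)
}

# Inject per-base errors into one read; returns the mutated sequence and
# the read-to-template CIGAR (=, X, I, D over template coordinates).
inject_errors <- function(sub, hp, cfg) {
  n <- nchar(sub)
  if (cfg$read_error == 0) return(list(seq = sub, cigar = paste0(n, "=")))
  ch <- strsplit(sub, "")[[1]]
  mix <- cfg$error_mix
  mm_rate <- cfg$read_error * mix[["mismatch"]]
  indel_boost <- ifelse(hp, cfg$homopolymer_factor, 1)
  ins_rate <- cfg$read_error * mix[["ins"]] * indel_boost
  del_rate <- cfg$read_error * mix[["del"]] * indel_boost
  u <- stats::runif(n)
  mm <- u < mm_rate
  del <- !mm & u < mm_rate + del_rate
  ins <- !mm & !del & u < mm_rate + del_rate + ins_rate
  if (any(mm)) {
    ch[mm] <- vapply(ch[mm], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                     character(1), USE.NAMES = FALSE)
  }
  ins_base <- character(n)
  if (any(ins)) ins_base[ins] <- sample(c("A", "C", "G", "T"), sum(ins), replace = TRUE)
  out_ch <- ifelse(del, "", ch)
  seq <- paste(paste0(out_ch, ins_base), collapse = "")
  base_op <- ifelse(del, "D", ifelse(mm, "X", "="))
  ops <- c(rbind(base_op, ifelse(ins, "I", "")))
  ops <- ops[nzchar(ops)]
  r <- rle(ops)
  list(seq = seq, cigar = paste0(paste0(r$lengths, r$values), collapse = ""))
}

#' Simulate haplotype-resolved CpG methylation
#'
#' CpG sites are enumerated on both strands of the reference within each
#' configured region (the + strand site at the cytosine, the - strand
#' site one position downstream). Region baselines are drawn from a
#' bimodal hypo/hyper prior (means 0.1 / 0.9); in differential regions one
#' haplotype is shifted by `meth_diff_delta`. Per-site Gaussian noise is
#' truncated to `[0, 1]`.
#'
#' @param truth Output of [simulate_diploid()].
#' @param cfg Simulation config (defaults to `truth$config`).
#' @return List with `h1_sites`, `h2_sites` (bedMethyl-style data.frames)
#'   and `region_truth` (per-region recorded means and differential flag).
#' @export
simulate_methylation <- function(truth, cfg = truth$config) {
  stopifnot(inherits(truth, "dualvar_truth"))
  set.seed(sim_seed(cfg, "meth"))
  ref <- truth$reference[[1]]
  chrom <- names(truth$reference)
  regions <- truth$region_bed
  if (nrow(regions) == 0L) stop("no methylation regions configured")
  cpg <- as.integer(gregexpr("CG", ref, fixed = TRUE)[[1]])
  cpg <- cpg[cpg > 0] - 1L  # 0-based C position on + strand
  h1 <- list(); h2 <- list(); rt <- list()
  for (i in seq_len(nrow(regions))) {
    rp <- cpg[cpg >= regions$start[i] & cpg + 1L < regions$end[i]]
    if (length(rp) == 0L) {
      warning("region ", regions$label[i], " contains no CpG; dropped")
      next
    }
    base <- if (stats::runif(1) < 0.5) 0.1 else 0.9
    m1 <- base; m2 <- base
    if (regions$differential[i]) {
      shift <- if (base < 0.5) cfg$meth_diff_delta else -cfg$meth_diff_delta
      if (regions$diff_hap[i] == 1L) m1 <- base + shift else m2 <- base + shift
    }
    mk <- function(mean_frac) {
      pos <- rep(rp, each = 2L) + c(0L, 1L)
      strand <- rep(c("+", "-"), length(rp))
      frac <- pmin(1, pmax(0, stats::rnorm(length(pos), mean_frac, cfg$meth_noise_sd)))
      cov <- stats::rpois(length(pos), cfg$meth_coverage)
      data.frame(chrom = chrom, pos = pos, strand = strand, coverage = cov,
                 meth_frac = frac, stringsAsFactors = FALSE)
    }
    s1 <- mk(m1); s2 <- mk(m2)
    h1[[length(h1) + 1L]] <- s1
    h2[[length(h2) + 1L]] <- s2
    rt[[length(rt) + 1L]] <- data.frame(
      label = regions$label[i], chrom = chrom,
      start = regions$start[i], end = regions$end[i],
      differential = regions$differential[i], diff_hap = regions$diff_hap[i],
      n_cpg = length(rp), mean_h1 = mean(s1$meth_frac),
      mean_h2 = mean(s2$meth_frac), stringsAsFactors = FALSE)
  }
  list(h1_sites = do.call(rbind, h1), h2_sites = do.call(rbind, h2),
       region_truth = do.call(rbind, rt))
}

#' Write all simulator outputs to a directory
#'
#' Emits reference/haplotype/read FASTAs, the truth VCF, VNTR and region
#' BEDs, two bedMethyl files, a PAF of true read placements and a JSON
#' config snapshot.
#'
#' @param truth Output of [simulate_diploid()].
#' @param dir Output directory (created if needed).
#' @param reads Optional output of [simulate_reads()].
#' @param meth Optional output of [simulate_methylation()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(truth, dir, reads = NULL, meth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(truth$reference, file.path(dir, "reference.fasta"))
  write_fasta(c(truth$hap1, truth$hap2), file.path(dir, "haplotypes.fasta"))
  write_vcf(truth$truth_variants, file.path(dir, "truth.vcf"),
            contigs = stats::setNames(nchar(truth$reference), names(truth$reference)))
  write_bed(truth$vntr_bed, file.path(dir, "vntr.bed"))
  write_bed(truth$region_bed, file.path(dir, "regions.bed"))
  jsonlite::write_json(unclass(truth$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(reads)) {
    write_fasta(reads$reads, file.path(dir, "reads.fasta"))
    write_paf(reads$alignments, file.path(dir, "reads_truth.paf"))
    utils::write.table(reads$table, file.path(dir, "reads_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(meth)) {
    write_bedmethyl(meth$h1_sites, file.path(dir, "hap1.bedmethyl"))
    write_bedmethyl(meth$h2_sites, file.path(dir, "hap2.bedmethyl"))
    utils::write.table(meth$region_truth, file.path(dir, "meth_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
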
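# Haplotype-resolved regional methylation summaries and the
# differential-methylation caller.

#' Collapse CpG strand pairs
#'
#' CpG sites appear one position apart on the two strands (C-G base
#' pairing); a + strand site at p and a - strand site at p+1 are merged
#' into one site at p with coverage summed and a coverage-weighted
#' methylation fraction. Unpaired sites pass through unchanged.
#'
#' @param sites bedMethyl-style data.frame (`chrom`, `pos`, `strand`,
#'   `coverage`, `meth_frac`).
#' @return Strand-combined site data.frame (strand `"*"` for merged pairs).
#' @export
collapse_cpg_strands <- function(sites) {
  if (nrow(sites) == 0L) return(sites)
  plus <- sites[sites$strand == "+", , drop = FALSE]
  minus <- sites[sites$strand == "-", , drop = FALSE]
  key_p <- paste(plus$chrom, plus$pos, sep = "\r")
  key_m <- paste(minus$chrom, minus$pos - 1L, sep = "\r")
  hit <- match(key_p, key_m)
  paired <- !is.na(hit)
  merged <- plus[paired, , drop = FALSE]
  if (nrow(merged)) {
    m <- minus[hit[paired], , drop = FALSE]
    tot <- merged$coverage + m$coverage
    merged$meth_frac <- ifelse(tot > 0,
                               (merged$coverage * merged$meth_frac +
                                  m$coverage * m$meth_frac) / tot,
                               (merged$meth_frac + m$meth_frac) / 2)
    merged$coverage <- tot
    merged$strand <- "*"
  }
  rest <- rbind(plus[!paired, , drop = FALSE],
                minus[!(seq_len(nrow(minus)) %in% hit[paired]), , drop = FALSE])
  out <- rbind(merged, rest)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize per-haplotype methylation over regions
#'
#' For each region, the unweighted mean of site methylation fractions is
#' computed per haplotype over sites with coverage at least `min_cov`.
#' Regions with fewer than `min_sites` usable CpGs on either haplotype
#' are dropped with a reason. `delta = mean_h1 - mean_h2`.
#'
#' @param h1_sites,h2_sites Strand-collapsed site data.frames.
#' @param regions data.frame (`chrom`, `start`, `end`, `label`).
#' @param min_sites Minimum usable CpGs per haplotype (default 5).
#' @param min_cov Minimum per-site coverage (default 5).
#' @return List with `summaries` (one row per kept region: means,
#'   coverages, `n_sites`, `delta`) and `dropped` (label, reason).
#' @export
summarize_regions <- function(h1_sites, h2_sites, regions,
                              min_sites = 5L, min_cov = 5L) {
  if (nrow(regions) == 0L) stop("empty region list")
  pick <- function(sites, i) {
    s <- sites[sites$chrom == regions$chrom[i] &
                 sites$pos >= regions$start[i] &
                 sites$pos < regions$end[i] &
                 sites$coverage >= min_cov, , drop = FALSE]
    s
  }
  rows <- list(); dropped <- list()
  for (i in seq_len(nrow(regions))) {
    s1 <- pick(h1_sites, i); s2 <- pick(h2_sites, i)
    if (nrow(s1) < min_sites || nrow(s2) < min_sites) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        label = regions$label[i], reason = "too_few_sites",
        stringsAsFactors = FALSE)
      next
    }
    m1 <- mean(s1$meth_frac); m2 <- mean(s2$meth_frac)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = regions$chrom[i], start = regions$start[i], end = regions$end[i],
      label = regions$label[i], mean_h1 = m1, mean_h2 = m2,
      n_sites = min(nrow(s1), nrow(s2)),
      cov_h1 = mean(s1$coverage), cov_h2 = mean(s2$coverage),
      delta = m1 - m2, stringsAsFactors = FALSE)
  }
  list(summaries = do.call(rbind, c(rows, list(NULL))),
       dropped = do.call(rbind, c(dropped, list(NULL))))
}

#' Call haplotype-differential regions
#'
#' A region is flagged when its absolute between-haplotype difference is
#' more than three deviations away from the absolute median difference.
#' The deviation unit is a robust estimate of the spread of the signed
#' differences: the scaled median absolute deviation of `delta` about its
#' median (`method = "mad"`, scale 1.4826, floored at `s_floor` so a
#' degenerate all-identical population flags nothing). Scaling by the
#' spread of |delta| instead would flag about 1.5% of a pure-noise
#' population (the folded distribution's own tail); the signed-spread
#' unit keeps the rule an outlier detector. A plain standard deviation
#' of `delta` is available via `method = "sd"`.
#'
#' @param summaries Region summary data.frame from [summarize_regions()].
#' @param method `"mad"` (robust, default) or `"sd"`.
#' @param z_cut Deviation threshold (default 3).
#' @param s_floor Scale floor (default 1e-3).
#' @return `summaries` with `robust_z` and `flagged` columns.
#' @export
call_differential <- function(summaries, method = c("mad", "sd"),
                              z_cut = 3, s_floor = 1e-3) {
  method <- match.arg(method)
  if (is.null(summaries) || nrow(summaries) < 20L) {
    stop("call_differential needs at least 20 region summaries (got ",
         if (is.null(summaries)) 0L else nrow(summaries), ")")
  }
  ad <- abs(summaries$delta)
  m <- stats::median(ad)
  d <- summaries$delta
  s <- if (method == "mad") stats::mad(d, constant = 1.4826) else stats::sd(d)
  summaries$robust_z <- (ad - m) / max(s, s_floor)
  summaries$flagged <- summaries$robust_z > z_cut
  summaries
}

#' Build methylation regions from structural variants
#'
#' Deletions contribute their deleted span plus/minus `flank`; insertions
#' their anchor plus/minus `flank`. Labels carry the SV identity.
#'
#' @param svs SV variant table.
#' @param flank Flank size in bp (default 1000).
#' @return Region data.frame (`chrom`, `start`, `end`, `label`).
#' @export
regions_from_svs <- function(svs, flank = 1000L) {
  if (nrow(svs) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      label = character(), stringsAsFactors = FALSE))
  }
  is_del <- svs$sv_len < 0 & (is.na(svs$sv_type) | svs$sv_type != "INV")
  start <- svs$pos - flank
  end <- ifelse(is_del, svs$pos + nchar(svs$ref) - 1L + flank, svs$pos + flank)
  data.frame(chrom = svs$chrom, start = pmax(0L, as.integer(start)),
             end = as.integer(end),
             label = sprintf("sv_%s_%d_%s", svs$chrom, svs$pos,
                             ifelse(is.na(svs$sv_type),
                                    ifelse(svs$sv_len >= 0, "INS", "DEL"),
                                    svs$sv_type)),
             stringsAsFactors = FALSE)
}

#' Haplotype differential-methylation pipeline step
#'
#' Strand-collapses both haplotypes' sites, summarizes the given regions
#' and calls differential regions.
#'
#' @param h1_sites,h2_sites Raw bedMethyl site data.frames.
#' @param regions Region data.frame.
#' @param min_sites,min_cov See [summarize_regions()].
#' @param method See [call_differential()].
#' @return List with `calls` (summaries + flags) and `dropped`.
#' @export
methdiff <- function(h1_sites, h2_sites, regions, min_sites = 5L, min_cov = 5L,
                     method = "mad") {
  s1 <- collapse_cpg_strands(h1_sites)
  s2 <- collapse_cpg_strands(h2_sites)
  sm <- summarize_regions(s1, s2, regions, min_sites = min_sites, min_cov = min_cov)
  list(calls = call_differential(sm$summaries, method = method),
       dropped = sm$dropped)
}
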
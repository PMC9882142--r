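# Pipeline orchestration: simulate -> align -> dual assembly -> SV
# calling -> small variants -> joint phasing -> methylation, with file
# checkpoints, a run manifest, and stage selection.

#' Align sequences with minimap2
#'
#' Thin wrapper producing PAF with `cg`/`de` tags. `mode = "reads"` uses
#' the long-read preset; `mode = "asm"` uses the fixed assembly-to-
#' reference parameter set recorded in [sv_call_config()]
#' ("asm20 -B 2 -E 3,1 -O 6,100"), whose gap costs favour contiguous
#' representation of long structural variants.
#'
#' @param query_fa,target_fa FASTA paths.
#' @param out_paf Output PAF path (temporary file when NULL).
#' @param mode `"reads"` or `"asm"`.
#' @param threads Number of alignment threads.
#' @return Alignment data.frame (parsed from the PAF).
#' @export
align_minimap2 <- function(query_fa, target_fa, out_paf = NULL,
                           mode = c("reads", "asm"), threads = 1L) {
  mode <- match.arg(mode)
  if (Sys.which("minimap2") == "") {
    stop("minimap2 not found on PATH; it is required for the alignment steps")
  }
  if (is.null(out_paf)) out_paf <- tempfile(fileext = ".paf")
  args <- switch(mode,
                 reads = c("-x", "map-ont"),
                 asm = c("-x", "asm20", "-B", "2", "-E", "3,1", "-O", "6,100"))
  args <- c(args, "-c", "--eqx", "-t", as.character(threads),
            "-o", out_paf, target_fa, query_fa)
  status <- system2("minimap2", args, stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("minimap2 failed (exit ", status, ")")
  read_alignments(out_paf, "paf")
}

pipeline_stages <- c("simulate", "align", "hapdup", "svcall", "smallvar",
                     "phase", "methdiff", "evaluate")

#' Run the full pipeline on a simulated sample
#'
#' Executes, in order: genome/read/methylation simulation, read
#' alignment (to the draft and to the reference), dual assembly, SV
#' calling with VNTR grouping, reference-based small-variant calling,
#' joint phasing of small and structural variants, differential
#' methylation, and evaluation against the simulated truth. Intermediate
#' files are kept in `out_dir` and a run manifest is written.
#'
#' @param cfg A [sim_config()] describing the sample.
#' @param out_dir Output directory.
#' @param from,until First and last stage to run (see
#'   `dualvar:::pipeline_stages`); earlier stages must have left their
#'   files in `out_dir`.
#' @param threads Alignment threads.
#' @return Invisible list of in-memory stage results (those computed in
#'   this invocation), including `$metrics` when evaluation ran.
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir, from = "simulate",
                         until = "evaluate", threads = 1L) {
  stages <- pipeline_stages
  if (!from %in% stages || !until %in% stages) {
    stop("unknown stage; stages are: ", paste(stages, collapse = ", "))
  }
  run <- stages[seq(match(from, stages), match(until, stages))]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  state <- list()
  timings <- list()
  t0 <- NULL
  tick <- function() t0 <<- proc.time()[["elapsed"]]
  need <- function(...) {
    paths <- c(...)
    miss <- paths[!file.exists(paths)]
    if (length(miss)) {
      stop("missing input file(s) for this stage: ", paste(miss, collapse = ", "))
    }
    invisible(paths)
  }

  if ("simulate" %in% run) {
    tick()
    truth <- simulate_diploid(cfg)
    state$reads <- simulate_reads(truth, cfg)
    state$meth <- simulate_methylation(truth, cfg)
    write_simulation(truth, out_dir, reads = state$reads, meth = state$meth)
    draft <- stats::setNames(truth$hap1[[1]], "draft_1")
    write_fasta(draft, p("draft.fasta"))
    state$truth <- truth
    timings$simulate <- round(proc.time()[["elapsed"]] - t0, 3)
  }

  if ("align" %in% run) {
    need(p("reads.fasta"), p("draft.fasta"), p("reference.fasta"))
    tick()
    state$aln_draft <- align_minimap2(p("reads.fasta"), p("draft.fasta"),
                                      p("reads_to_draft.paf"), "reads", threads)
    state$aln_ref <- align_minimap2(p("reads.fasta"), p("reference.fasta"),
                                    p("reads_to_ref.paf"), "reads", threads)
    timings$align <- round(proc.time()[["elapsed"]] - t0, 3)
  }

  read_seqs <- NULL
  reads_mem <- function() {
    if (is.null(read_seqs)) read_seqs <<- read_fasta(p("reads.fasta"))
    read_seqs
  }

  if ("hapdup" %in% run) {
    need(p("reads.fasta"), p("draft.fasta"))
    if (is.null(state$aln_draft)) {
      need(p("reads_to_draft.paf"))
      state$aln_draft <- read_alignments(p("reads_to_draft.paf"), "paf")
    }
    tick()
    draft <- read_fasta(p("draft.fasta"))
    hd <- hapdup(draft, state$aln_draft, reads_mem())
    write_fasta(hd$assembly, p("assembly_dual.fasta"))
    utils::write.table(hd$haplotags, p("haplotags.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    snps <- hd$phased_snps
    if (!is.null(snps) && nrow(snps)) {
      write_vcf(sort_variants(snps), p("draft_snps.vcf"))
    }
    if (!is.null(hd$inversions) && nrow(hd$inversions)) {
      write_bed(data.frame(chrom = hd$inversions$contig,
                           start = hd$inversions$start,
                           end = hd$inversions$end,
                           label = hd$inversions$haplotype),
                p("inversions.bed"))
    }
    state$hapdup <- hd
    timings$hapdup <- round(proc.time()[["elapsed"]] - t0, 3)
  }

  if ("svcall" %in% run) {
    need(p("assembly_dual.fasta"), p("reference.fasta"))
    tick()
    asm <- read_fasta(p("assembly_dual.fasta"))
    h1 <- asm[grepl("_hap1$", names(asm))]
    h2 <- asm[grepl("_hap2$", names(asm))]
    write_fasta(h1, p("hap1.fasta"))
    write_fasta(h2, p("hap2.fasta"))
    a1 <- align_minimap2(p("hap1.fasta"), p("reference.fasta"),
                         p("hap1_to_ref.paf"), "asm", threads)
    a2 <- align_minimap2(p("hap2.fasta"), p("reference.fasta"),
                         p("hap2_to_ref.paf"), "asm", threads)
    vntr <- if (file.exists(p("vntr.bed"))) read_bed(p("vntr.bed")) else NULL
    ref <- read_fasta(p("reference.fasta"))
    sv <- svcall_from_alignments(a1, a2, ref, asm, vntr_bed = vntr)
    write_vcf(sv$svs, p("sv.vcf"),
              contigs = stats::setNames(nchar(ref), names(ref)))
    state$svcall <- sv
    timings$svcall <- round(proc.time()[["elapsed"]] - t0, 3)
  }

  if ("smallvar" %in% run) {
    need(p("reads.fasta"), p("reference.fasta"))
    if (is.null(state$aln_ref)) {
      need(p("reads_to_ref.paf"))
      state$aln_ref <- read_alignments(p("reads_to_ref.paf"), "paf")
    }
    tick()
    ref <- read_fasta(p("reference.fasta"))
    flt <- filter_read_alignments(state$aln_ref)
    snps <- call_het_snps(flt$kept, reads_mem(), ref)
    snps <- snps[snps$informative, , drop = FALSE]
    write_vcf(sort_variants(snps), p("small.vcf"),
              contigs = stats::setNames(nchar(ref), names(ref)))
    state$smallvar <- snps
    timings$smallvar <- round(proc.time()[["elapsed"]] - t0, 3)
  }

  if ("phase" %in% run) {
    need(p("small.vcf"), p("sv.vcf"), p("reads.fasta"), p("reference.fasta"))
    if (is.null(state$aln_ref)) {
      need(p("reads_to_ref.paf"))
      state$aln_ref <- read_alignments(p("reads_to_ref.paf"), "paf")
    }
    tick()
    ref <- read_fasta(p("reference.fasta"))
    small <- read_vcf(p("small.vcf"))
    sv <- read_vcf(p("sv.vcf"))
    merged <- merge_vcfs(small, sv)
    cfgp <- phasing_config(base_error = max(cfg$read_error, 0.01))
    sup <- build_allele_supports(merged, ref, state$aln_ref, reads_mem(), cfgp)
    ph <- phase_variants(merged, sup, cfgp)
    write_vcf(sort_variants(ph), p("phased.vcf"),
              contigs = stats::setNames(nchar(ref), names(ref)))
    state$phased <- ph
    timings$phase <- round(proc.time()[["elapsed"]] - t0, 3)
  }

  if ("methdiff" %in% run) {
    need(p("hap1.bedmethyl"), p("hap2.bedmethyl"), p("regions.bed"))
    tick()
    h1 <- read_bedmethyl(p("hap1.bedmethyl"))
    h2 <- read_bedmethyl(p("hap2.bedmethyl"))
    regions <- read_bed(p("regions.bed"))
    md <- methdiff(h1, h2, regions)
    utils::write.table(md$calls, p("methdiff.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    flagged <- md$calls[md$calls$flagged, , drop = FALSE]
    write_bed(flagged[, c("chrom", "start", "end", "label")],
              p("methdiff_flagged.bed"))
    state$methdiff <- md
    timings$methdiff <- round(proc.time()[["elapsed"]] - t0, 3)
  }

  if ("evaluate" %in% run) {
    need(p("truth.vcf"), p("sv.vcf"), p("phased.vcf"))
    tick()
    truth <- read_vcf(p("truth.vcf"))
    svs <- read_vcf(p("sv.vcf"))
    phased <- read_vcf(p("phased.vcf"))
    truth_sv <- truth[truth$var_class == "SV", , drop = FALSE]
    svc <- compare_sv_sets(truth_sv, svs[svs$var_class == "SV", , drop = FALSE])
    sh <- switch_hamming(truth, phased)
    metrics <- list(sv_precision = svc$precision, sv_recall = svc$recall,
                    sv_f1 = svc$f1, sv_tp = svc$tp, sv_fp = svc$fp,
                    sv_fn = svc$fn,
                    switch_error = sh$switch_rate,
                    hamming_error = sh$hamming_rate,
                    n_phased_het = sum(phased$gt1 != phased$gt2 & phased$phased))
    if (!is.null(state$methdiff) && file.exists(p("meth_truth.tsv"))) {
      mt <- utils::read.delim(p("meth_truth.tsv"))
      calls <- state$methdiff$calls
      truth_diff <- mt$label[mt$differential]
      flagged <- calls$label[calls$flagged]
      tp <- sum(flagged %in% truth_diff)
      metrics$meth_precision <- if (length(flagged)) tp / length(flagged) else 0
      metrics$meth_recall <- if (length(truth_diff))
        tp / length(truth_diff) else NA_real_
    }
    jsonlite::write_json(metrics, p("metrics.json"), auto_unbox = TRUE,
                         digits = NA)
    state$metrics <- metrics
    timings$evaluate <- round(proc.time()[["elapsed"]] - t0, 3)
  }

  manifest <- list(
    tool = "dualvar",
    tool_version = as.character(utils::packageVersion("dualvar")),
    seed = cfg$seed,
    config = unclass(cfg),
    stages_run = run,
    stage_seconds = timings,
    input_checksums = as.list(tools::md5sum(
      Filter(file.exists, p(c("reference.fasta", "reads.fasta", "draft.fasta"))))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(state)
}
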
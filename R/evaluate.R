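# One-shot evaluation pipeline: profile -> QV / completeness / duplication
# -> coverage -> phasing -> grading, with stages skipped (and reported "not
# assessed") when their inputs are absent.

#' Build / validate a run configuration
#'
#' Accepts a YAML file or a named list. Unknown keys are rejected; defaults
#' are filled in for everything else. Every [evaluate()] run writes the
#' resolved configuration next to its outputs so the run can be reproduced.
#'
#' @param config path to a YAML key-value file, or a named list.
#' @return a `run_config` list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    primary = NULL, alternate = NULL, reads = NULL,
    read_histogram = NULL, parentA_reads = NULL, parentB_reads = NULL,
    alignments = NULL, self_alignments = NULL, chromosome_table = NULL,
    gene_table = NULL, chromosome_ng50 = NULL, genome_size = NULL,
    k_profile = 31L, k_validation = 21L, gap_min_run = 10L,
    window = 1000L, min_match_frac = 0.5, telomere_motif = "TTAGGG",
    max_switch_run = 10L, max_switch_span = 20000L,
    seed = 42L, out_dir = NULL, verbosity = 1L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  structure(cfg, class = "run_config")
}

eval_log <- function(cfg, ...) {
  if ((cfg$verbosity %||% 1) > 0) message("[asmqc] ", sprintf(...))
}

#' Evaluate an assembly end to end
#'
#' Runs every stage whose inputs are available and aggregates the results
#' into a [grade_report()]. Minimally an assembly plus either reads or a
#' precomputed read k-mer histogram is required; coverage metrics need
#' alignments and phasing needs parental read sets. Skipped stages appear
#' as "not assessed" in the report.
#'
#' @param config a [run_config()], YAML path, or named list.
#' @return an `evaluation` list: `report` (a `grade_report`), `stages`
#'   (per-stage result objects), `config`.
#' @export
evaluate <- function(config) {
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config) else config)
  if (is.null(cfg$primary)) stop("config must name a primary assembly FASTA")
  loaded <- load_assembly(cfg$primary, cfg$gap_min_run, role = "primary")
  asm <- loaded$assembly; dec <- loaded$decomposition
  stages <- list(decomposition = dec)

  reads <- NULL
  if (!is.null(cfg$reads)) reads <- read_sequences(cfg$reads)
  if (is.null(reads) && is.null(cfg$read_histogram))
    stop("need reads or a precomputed read k-mer histogram")

  # genome profile
  prof <- NULL
  hist_prof <- if (!is.null(cfg$read_histogram)) read_kmer_histogram(cfg$read_histogram, cfg$k_profile)
               else kmer_histogram(count_kmers(reads, cfg$k_profile, "reads"))
  prof <- tryCatch(fit_genome_profile(hist_prof, k = cfg$k_profile),
                   error = function(e) { eval_log(cfg, "profile failed: %s", conditionMessage(e)); NULL })
  stages$profile <- prof
  genome_size <- cfg$genome_size %||% (if (!is.null(prof)) prof$genome_size else assembly_length(asm))

  cont <- continuity_stats(asm, dec, genome_size)
  stages$continuity <- cont
  stages$telomeres <- telomere_end_scan(asm, motif = cfg$telomere_motif)

  assigned <- NA
  if (!is.null(cfg$chromosome_table)) {
    ca <- assigned_fraction(asm, cfg$chromosome_table)
    stages$assignment <- ca
    assigned <- ca$assigned_fraction
  }

  qv <- NA; compl <- NA; dup <- NA
  if (!is.null(reads)) {
    rc <- count_kmers(reads, cfg$k_validation, "reads")
    ac <- count_kmers(asm, cfg$k_validation, "assembly")
    thr <- error_threshold(kmer_histogram(rc))
    stages$qv <- estimate_qv(ac, rc)
    stages$completeness <- kmer_completeness(rc, ac, thr)
    lam <- if (!is.null(prof) && cfg$k_profile == cfg$k_validation) prof$diploid_peak
           else fit_genome_profile(kmer_histogram(rc), k = cfg$k_validation)$diploid_peak
    stages$duplication <- duplication_rate(ac, rc, lam)
    qv <- stages$qv$qv; compl <- stages$completeness$completeness
    dup <- stages$duplication$duplication_rate
  }

  reliable_ng50 <- NA
  if (!is.null(cfg$alignments)) {
    trk <- depth_track(cfg$alignments, asm, window = cfg$window,
                       min_match_frac = cfg$min_match_frac)
    stages$coverage <- trk
    stages$collapsed <- tryCatch(collapsed_regions(trk), error = function(e) NULL)
  }

  phase_ng50 <- NA
  if (!is.null(cfg$parentA_reads) && !is.null(cfg$parentB_reads)) {
    pa <- count_kmers(read_sequences(cfg$parentA_reads), cfg$k_validation, "parentA")
    pb <- count_kmers(read_sequences(cfg$parentB_reads), cfg$k_validation, "parentB")
    child <- if (!is.null(reads)) count_kmers(reads, cfg$k_validation, "child") else NULL
    hm <- extract_hapmers(pa, pb, child)
    stages$hapmers <- hm
    pr <- phase_blocks(asm, hm, genome_size, cfg$max_switch_run, cfg$max_switch_span)
    stages$phase <- pr
    phase_ng50 <- as.numeric(pr$phase_block_ng50)
  }

  genes <- if (!is.null(cfg$gene_table)) gene_summary(cfg$gene_table) else NULL

  bundle <- metrics_bundle(
    contig_ng50 = as.numeric(cont$contig_ng50),
    scaffold_ng50 = as.numeric(cont$scaffold_ng50),
    phase_block_ng50 = phase_ng50,
    qv = qv, assigned_pct = assigned, gaps_per_gb = cont$gaps_per_gb,
    reliable_block_ng50 = reliable_ng50, kmer_completeness = compl,
    duplication_rate = dup, gene_summary = genes)
  report <- grade_report(bundle, cfg$chromosome_ng50)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(unclass(cfg), file.path(cfg$out_dir, "resolved_config.yaml"))
    write_grade_report(report, file.path(cfg$out_dir, "grade_report.json"))
    write_decomposition_bed(dec, cfg$out_dir)
  }
  structure(list(report = report, stages = stages, config = cfg),
            class = "evaluation")
}

#' @export
print.evaluation <- function(x, ...) {
  print(x$report)
  invisible(x)
}
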
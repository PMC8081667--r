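# Aggregate metrics into the compact x.y.P.Q.C quality notation and
# per-metric quality categories; summarize conserved-gene status tables.

#' Bundle of assembly metrics
#'
#' Collects the metric values consumed by [notation()] and [categorize()].
#' Anything not measured is left `NA` and reported as "not assessed" — never
#' silently defaulted.
#'
#' @param contig_ng50,scaffold_ng50,phase_block_ng50,reliable_block_ng50
#'   NG50 values in bp.
#' @param qv consensus quality, Phred units.
#' @param assigned_pct percent of the assembly assigned to chromosomes.
#' @param gaps_per_gb gaps per Gb of assembled sequence.
#' @param kmer_completeness percent of reliable read k-mers found.
#' @param duplication_rate percent falsely duplicated k-mer instances.
#' @param curated,sex_chromosomes_complete,organelle_complete optional
#'   booleans for the qualitative rows.
#' @param gene_summary optional result of [gene_summary()].
#' @return a `metrics_bundle` list.
#' @export
metrics_bundle <- function(contig_ng50 = NA, scaffold_ng50 = NA,
                           phase_block_ng50 = NA, qv = NA, assigned_pct = NA,
                           gaps_per_gb = NA, reliable_block_ng50 = NA,
                           kmer_completeness = NA, duplication_rate = NA,
                           curated = NA, sex_chromosomes_complete = NA,
                           organelle_complete = NA, gene_summary = NULL) {
  chk <- function(x, lo, hi, what) {
    if (!is.na(x) && (x < lo || x > hi)) stop(what, " out of range: ", x)
    as.numeric(x)
  }
  structure(list(
    contig_ng50 = chk(contig_ng50, 0, Inf, "contig_ng50"),
    scaffold_ng50 = chk(scaffold_ng50, 0, Inf, "scaffold_ng50"),
    phase_block_ng50 = chk(phase_block_ng50, 0, Inf, "phase_block_ng50"),
    qv = chk(qv, 0, 100, "qv"),
    assigned_pct = chk(assigned_pct, 0, 100, "assigned_pct"),
    gaps_per_gb = chk(gaps_per_gb, 0, Inf, "gaps_per_gb"),
    reliable_block_ng50 = chk(reliable_block_ng50, 0, Inf, "reliable_block_ng50"),
    kmer_completeness = chk(kmer_completeness, 0, 100, "kmer_completeness"),
    duplication_rate = chk(duplication_rate, 0, 100, "duplication_rate"),
    curated = curated, sex_chromosomes_complete = sex_chromosomes_complete,
    organelle_complete = organelle_complete, gene_summary = gene_summary),
    class = "metrics_bundle")
}

#' Render the x.y.P.Q.C quality notation
#'
#' `x` and `y` are the floored log10 of the contig and scaffold NG50 in
#' bases, `P` the floored log10 of the phase block NG50, `Q` the floored
#' QV, and `C` the floored percent assigned to chromosomes. Components that
#' were not assessed are omitted together with their prefix, reproducing
#' short forms such as `"4.5.Q30"`. A continuity component renders as the
#' letter `c` (complete) when the corresponding NG50 equals the chromosome
#' NG50 — and, for `x`, the assembly additionally has zero gaps. Without a
#' `chromosome_ng50`, `c` is never emitted.
#'
#' @param bundle a `metrics_bundle`; `contig_ng50`, `scaffold_ng50` and `qv`
#'   are mandatory.
#' @param chromosome_ng50 optional NG50 of the karyotype-estimated
#'   chromosome lengths, bp.
#' @return notation string, e.g. `"6.7.P5.Q40.C90"`.
#' @examples
#' notation(metrics_bundle(contig_ng50 = 1.2e6, scaffold_ng50 = 1.5e7,
#'                         phase_block_ng50 = 2e5, qv = 41.2,
#'                         assigned_pct = 93.4))   # "6.7.P5.Q41.C93"
#' @export
notation <- function(bundle, chromosome_ng50 = NULL) {
  b <- bundle
  if (is.na(b$contig_ng50) || is.na(b$scaffold_ng50) || is.na(b$qv))
    stop("contig NG50, scaffold NG50 and QV are mandatory for the notation")
  is_c <- function(ng50) !is.null(chromosome_ng50) && !is.na(ng50) &&
    ng50 == chromosome_ng50
  comp_log <- function(ng50, complete) {
    if (complete) "c" else as.character(floor(log10(ng50)))
  }
  x <- comp_log(b$contig_ng50,
                is_c(b$contig_ng50) && !is.na(b$gaps_per_gb) && b$gaps_per_gb == 0)
  y <- comp_log(b$scaffold_ng50, is_c(b$scaffold_ng50))
  parts <- c(x, y)
  if (!is.na(b$phase_block_ng50))
    parts <- c(parts, paste0("P", comp_log(b$phase_block_ng50, is_c(b$phase_block_ng50))))
  parts <- c(parts, paste0("Q", floor(b$qv)))
  if (!is.na(b$assigned_pct))
    parts <- c(parts, paste0("C", floor(b$assigned_pct)))
  paste(parts, collapse = ".")
}

#' Parse an x.y.P.Q.C notation string
#'
#' Inverse of [notation()] at the component level (the notation floors its
#' inputs, so only the component values round-trip, not the raw metrics).
#'
#' @param text notation string.
#' @return list with components `x`, `y`, `P`, `Q`, `C`; absent components
#'   are NA; `"c"` components are returned as the string `"c"`.
#' @export
parse_notation <- function(text) {
  parts <- strsplit(text, ".", fixed = TRUE)[[1]]
  if (length(parts) < 3) stop("malformed notation: ", text)
  out <- list(x = parts[1], y = parts[2], P = NA, Q = NA, C = NA)
  for (p in parts[-(1:2)]) {
    tag <- substr(p, 1, 1)
    val <- substring(p, 2)
    if (!tag %in% c("P", "Q", "C")) stop("malformed notation component: ", p)
    out[[tag]] <- val
  }
  if (is.na(out$Q)) stop("notation lacks mandatory Q component: ", text)
  for (nm in c("x", "y", "P", "Q", "C"))
    if (!identical(out[[nm]], "c") && !is.na(out[[nm]]))
      out[[nm]] <- suppressWarnings(as.numeric(out[[nm]]))
  out
}

# category threshold table: highest category whose threshold is met.
# "chr" = equals chromosome NG50; NA threshold = not required at that level.
category_levels <- c("Finished", "VGP-2020", "VGP-2016", "B10K-2014")

#' Assign per-metric quality categories
#'
#' Compares each assessed metric against the encoded standards table and
#' reports the highest category whose threshold is met, or `"below"` when
#' none is, or `"not assessed"` when the metric is missing. Chromosome-level
#' thresholds (contig/scaffold/reliable-block/phase NG50 equal to the
#' chromosome NG50) can only be met when `chromosome_ng50` is supplied.
#'
#' @param bundle a `metrics_bundle`.
#' @param chromosome_ng50 optional chromosome NG50 in bp.
#' @return data frame with columns `metric`, `value`, `category`.
#' @export
categorize <- function(bundle, chromosome_ng50 = NULL) {
  chr_eq <- function(v) !is.null(chromosome_ng50) && !is.na(v) && v == chromosome_ng50
  ge_chain <- function(v, thresholds, chr_levels = integer(0)) {
    # thresholds: numeric vector over category_levels; NA = not required
    if (is.na(v)) return("not assessed")
    for (i in seq_along(category_levels)) {
      ok <- if (i %in% chr_levels) chr_eq(v)
            else if (is.na(thresholds[i])) TRUE
            else v > thresholds[i]
      if (ok) return(category_levels[i])
    }
    "below"
  }
  le_chain <- function(v, thresholds, finished_zero = FALSE) {
    if (is.na(v)) return("not assessed")
    for (i in seq_along(category_levels)) {
      ok <- if (finished_zero && i == 1) v == 0 else v < thresholds[i]
      if (!is.na(thresholds[i]) || (finished_zero && i == 1)) {
        if (ok) return(category_levels[i])
      }
    }
    "below"
  }
  b <- bundle
  rows <- list(
    c("Contig NG50 (x)", b$contig_ng50,
      ge_chain(b$contig_ng50, c(NA, 1e7, 1e6, 1e4), chr_levels = 1)),
    c("Scaffold NG50 (y)", b$scaffold_ng50,
      ge_chain(b$scaffold_ng50, c(NA, NA, 1e7, 1e5), chr_levels = 1:2)),
    c("Gaps per Gb", b$gaps_per_gb,
      le_chain(b$gaps_per_gb, c(NA, 200, 1000, 10000), finished_zero = TRUE)),
    c("Reliable blocks", b$reliable_block_ng50,
      ge_chain(b$reliable_block_ng50, c(NA, 1e7, 1e6, NA), chr_levels = 1)),
    c("False duplications", b$duplication_rate,
      le_chain(b$duplication_rate, c(NA, 1, 5, 10), finished_zero = TRUE)),
    c("Base pair QV (Q)", b$qv, ge_chain(b$qv, c(60, 50, 40, 30))),
    c("k-mer completeness", b$kmer_completeness, {
      v <- b$kmer_completeness
      if (is.na(v)) "not assessed"
      else if (v == 100) "Finished"
      else ge_chain(v, c(Inf, 95, 90, 80))
    }),
    c("Phase block NG50 (P)", b$phase_block_ng50,
      ge_chain(b$phase_block_ng50, c(NA, 1e6, 1e5, NA), chr_levels = 1)),
    c("Assigned (C)", b$assigned_pct, {
      v <- b$assigned_pct
      if (is.na(v)) "not assessed"
      else if (v == 100) "Finished"
      else ge_chain(v, c(Inf, 95, 90, NA))
    }),
    c("Curation", NA, qual_cat(b$curated)),
    c("Sex chromosomes", NA, qual_cat(b$sex_chromosomes_complete)),
    c("Organelles", NA, qual_cat(b$organelle_complete)),
    c("Genes", if (is.null(b$gene_summary)) NA else b$gene_summary$percent_complete,
      if (is.null(b$gene_summary)) "not assessed"
      else ge_chain(b$gene_summary$percent_complete, c(98, 95, 90, 80)))
  )
  out <- data.frame(metric = vapply(rows, `[[`, "", 1),
                    value = suppressWarnings(as.numeric(vapply(rows, `[[`, "", 2))),
                    category = vapply(rows, `[[`, "", 3))
  out
}

qual_cat <- function(flag) {
  if (is.na(flag)) "not assessed" else if (isTRUE(flag)) "Finished" else "below"
}

#' Summarize a conserved-gene status table
#'
#' Accepts a "full table"-style TSV or data frame of conserved single-copy
#' gene statuses and reports the completeness percentages; the duplicated
#' percentage feeds the false-duplication evidence list.
#'
#' @param full_table data frame with columns `gene`, `status`, or a TSV path
#'   (2+ columns, `#` comments ignored). Statuses must be one of Complete,
#'   Duplicated, Fragmented, Missing.
#' @return a `gene_summary` list: `counts` per status, `percent_complete`,
#'   `percent_duplicated`, `n_genes`.
#' @export
gene_summary <- function(full_table) {
  if (is.character(full_table)) {
    full_table <- utils::read.table(full_table, sep = "\t", comment.char = "#",
                                    colClasses = "character")[, 1:2]
    names(full_table) <- c("gene", "status")
  }
  if (nrow(full_table) == 0) stop("empty gene status table")
  valid <- c("Complete", "Duplicated", "Fragmented", "Missing")
  bad <- which(!full_table$status %in% valid)
  if (length(bad))
    stop("unknown status token at line ", bad[1], ": ", full_table$status[bad[1]])
  counts <- table(factor(full_table$status, valid))
  n <- nrow(full_table)
  structure(list(counts = counts, n_genes = n,
                 percent_complete = 100 * counts[["Complete"]] / n,
                 percent_duplicated = 100 * counts[["Duplicated"]] / n),
            class = "gene_summary")
}

#' Full grade report
#'
#' @param bundle a `metrics_bundle`.
#' @param chromosome_ng50 optional chromosome NG50, bp.
#' @return a `grade_report` list: `notation`, `categories` (from
#'   [categorize()]), `bundle`.
#' @export
grade_report <- function(bundle, chromosome_ng50 = NULL) {
  structure(list(notation = notation(bundle, chromosome_ng50),
                 categories = categorize(bundle, chromosome_ng50),
                 bundle = bundle),
            class = "grade_report")
}

#' @export
print.grade_report <- function(x, ...) {
  cat("assembly grade:", x$notation, "\n\n")
  df <- x$categories
  df$value <- ifelse(is.na(df$value), "-", formatC(df$value, format = "g", digits = 6))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a grade report as JSON
#'
#' @param report a `grade_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grade_report <- function(report, path) {
  b <- report$bundle
  payload <- list(
    notation = report$notation,
    metrics = b[!vapply(b, is.null, logical(1))],
    categories = report$categories)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
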
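# K-mer based assembly validation: consensus QV, completeness, false
# duplication rate, and trio hap-mer extraction.

#' K-mer survival consensus quality (QV)
#'
#' Every base error in an assembly creates up to k assembly k-mers that are
#' absent from the read set. With T total assembly k-mer instances and B
#' instances whose canonical k-mer never occurs in the reads, the per-base
#' error rate is \eqn{E = 1 - (1 - B/T)^{1/k}} and the consensus quality is
#' \eqn{QV = -10 \log_{10} E}. One isolated substitution per 10 kb therefore
#' yields 99.99% base accuracy, i.e. Q40.
#'
#' @param assembly_counts `kmer_counts` of the assembly.
#' @param read_counts `kmer_counts` of the read set (same k).
#' @return a `qv_estimate` list: `T_instances`, `B_absent`, `error_rate`,
#'   `qv`, `capped`. When no assembly k-mer is missing from the reads the
#'   error rate is 0 and the QV is reported at the cap 99.9 with
#'   `capped = TRUE`.
#' @export
estimate_qv <- function(assembly_counts, read_counts) {
  k <- assembly_counts$k
  in_reads <- lookup_counts(assembly_counts, read_counts)
  T_inst <- sum(as.numeric(assembly_counts$count))
  if (T_inst == 0) stop("empty assembly k-mer set")
  B <- sum(as.numeric(assembly_counts$count[in_reads == 0]))
  if (B == 0) {
    return(structure(list(T_instances = T_inst, B_absent = 0, error_rate = 0,
                          qv = 99.9, capped = TRUE, k = k), class = "qv_estimate"))
  }
  E <- 1 - (1 - B / T_inst)^(1 / k)
  structure(list(T_instances = T_inst, B_absent = B, error_rate = E,
                 qv = -10 * log10(E), capped = FALSE, k = k),
            class = "qv_estimate")
}

#' @export
print.qv_estimate <- function(x, ...) {
  cat(sprintf("QV %.2f%s (k=%d, %.0f of %.0f assembly k-mer instances absent from reads)\n",
              x$qv, if (x$capped) " [capped]" else "", x$k, x$B_absent, x$T_instances))
  invisible(x)
}

#' K-mer completeness
#'
#' The fraction of reliable read k-mers (distinct canonical k-mers with read
#' multiplicity strictly above the error threshold) that are present in the
#' assembly. 100% means every reliably sampled genomic k-mer made it into
#' the consensus.
#'
#' @param read_counts `kmer_counts` of the reads.
#' @param assembly_counts `kmer_counts` of the assembly (same k). May be an
#'   empty count set (completeness 0).
#' @param threshold error multiplicity cutoff, normally from
#'   [error_threshold()] on the read histogram.
#' @return a `completeness_estimate` list: `reliable` (R), `found` (F),
#'   `completeness` = 100 F / R percent.
#' @export
kmer_completeness <- function(read_counts, assembly_counts, threshold) {
  stopifnot(threshold >= 1)
  reliable <- read_counts$count > threshold
  R <- sum(reliable)
  if (R == 0) stop("no reliable k-mers above threshold ", threshold)
  rel <- subset_kmer_counts(read_counts, reliable)
  found <- if (length(assembly_counts$code) == 0) 0 else
    sum(lookup_counts(rel, assembly_counts) > 0)
  structure(list(reliable = R, found = found, completeness = 100 * found / R,
                 threshold = as.integer(threshold), k = read_counts$k),
            class = "completeness_estimate")
}

#' @export
print.completeness_estimate <- function(x, ...) {
  cat(sprintf("k-mer completeness %.3f%% (%d / %d reliable k-mers, threshold %d)\n",
              x$completeness, x$found, x$reliable, x$threshold))
  invisible(x)
}

#' K-mer false duplication rate
#'
#' For each assembly k-mer, the read multiplicity divided by the k-mer
#' coverage \eqn{\lambda_d} gives its expected copy number in the genome
#' (rounded half away from zero, floored at 1). Assembly instances in excess
#' of that expectation are falsely duplicated sequence; the rate is the
#' excess instance count X over total assembly instances T, as a percent.
#'
#' @param assembly_counts `kmer_counts` of the assembly.
#' @param read_counts `kmer_counts` of the reads (same k).
#' @param profile a `genome_profile` supplying `diploid_peak`
#'   (\eqn{\lambda_d}), or a single number giving \eqn{\lambda_d} directly.
#' @param assembly optional [Assembly]; when given, the positions of excess
#'   k-mers are located so false duplications can be placed (slower).
#' @return a `duplication_estimate` list: `excess` (X), `total` (T),
#'   `duplication_rate` percent, and `positions` (BED-style data frame of
#'   excess k-mer sites, or NULL).
#' @export
duplication_rate <- function(assembly_counts, read_counts, profile, assembly = NULL) {
  lambda_d <- if (inherits(profile, "genome_profile")) profile$diploid_peak else as.numeric(profile)
  stopifnot(lambda_d > 0)
  rc <- lookup_counts(assembly_counts, read_counts)
  expected <- pmax(1, round_half_away(rc / lambda_d))
  excess_per <- pmax(0, assembly_counts$count - expected)
  X <- sum(as.numeric(excess_per))
  T_inst <- sum(as.numeric(assembly_counts$count))
  positions <- NULL
  if (!is.null(assembly) && X > 0) {
    exc <- subset_kmer_counts(assembly_counts, excess_per > 0)
    k <- assembly_counts$k
    rows <- lapply(names(assembly$sequences), function(nm) {
      hit <- cpp_scan_positions(assembly$sequences[[nm]], exc$code, k)
      if (length(hit$pos) == 0) return(NULL)
      data.frame(chrom = nm, start = hit$pos - 1L, end = hit$pos - 1L + k)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    positions <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  structure(list(excess = X, total = T_inst,
                 duplication_rate = 100 * X / T_inst,
                 lambda_d = lambda_d, positions = positions),
            class = "duplication_estimate")
}

#' @export
print.duplication_estimate <- function(x, ...) {
  cat(sprintf("false duplication rate %.3f%% (%.0f excess of %.0f k-mer instances)\n",
              x$duplication_rate, x$excess, x$total))
  invisible(x)
}

#' Extract parent-specific marker k-mers (hap-mers)
#'
#' A maternal marker is a canonical k-mer whose maternal read multiplicity
#' lies in `[low_cut, high_cut]` (excluding sequencing errors below and
#' repeats above) and that never occurs in the paternal reads; symmetric for
#' paternal markers. When child read counts are supplied, markers are
#' restricted to k-mers the child actually inherited (child count >= 1).
#'
#' @param parentA_counts,parentB_counts `kmer_counts` of the two parents'
#'   reads (A = maternal, B = paternal by convention).
#' @param child_counts optional `kmer_counts` of the child's reads.
#' @param low_cut,high_cut inclusive multiplicity filter on the own-parent
#'   count. Defaults: `low_cut` = error threshold of the parent histogram
#'   + 1, `high_cut` = 4x the parent's coverage peak.
#' @return a `hapmer_sets` list: `maternal`, `paternal` (each a
#'   `kmer_counts`), `n_mat`, `n_pat`, and the filters used.
#' @export
extract_hapmers <- function(parentA_counts, parentB_counts, child_counts = NULL,
                            low_cut = NULL, high_cut = NULL) {
  k <- parentA_counts$k
  if (parentB_counts$k != k) stop("k mismatch between parents")
  cuts_for <- function(counts) {
    h <- kmer_histogram(counts)
    thr <- error_threshold(h)
    prof <- tryCatch(fit_genome_profile(h, k = k), error = function(e) NULL)
    lam <- if (!is.null(prof)) prof$diploid_peak else max(h$multiplicity[which.max(h$n_kmers)], 2)
    c(low = thr + 1, high = 4 * lam)
  }
  ca <- if (is.null(low_cut) || is.null(high_cut)) cuts_for(parentA_counts) else c(low = low_cut, high = high_cut)
  cb <- if (is.null(low_cut) || is.null(high_cut)) cuts_for(parentB_counts) else c(low = low_cut, high = high_cut)
  if (!is.null(low_cut)) { ca["low"] <- cb["low"] <- low_cut }
  if (!is.null(high_cut)) { ca["high"] <- cb["high"] <- high_cut }
  markers <- function(own, other, cuts) {
    keep <- own$count >= cuts["low"] & own$count <= cuts["high"]
    m <- subset_kmer_counts(own, keep)
    m <- subset_kmer_counts(m, lookup_counts(m, other) == 0)
    if (!is.null(child_counts)) m <- subset_kmer_counts(m, lookup_counts(m, child_counts) >= 1)
    m
  }
  mat <- markers(parentA_counts, parentB_counts, ca)
  pat <- markers(parentB_counts, parentA_counts, cb)
  mat$source <- "maternal_markers"; pat$source <- "paternal_markers"
  if (length(mat$code) == 0 && length(pat$code) == 0)
    stop("parents indistinguishable: both marker sets empty")
  structure(list(maternal = mat, paternal = pat,
                 n_mat = length(mat$code), n_pat = length(pat$code),
                 filters = list(A = ca, B = cb)),
            class = "hapmer_sets")
}

#' @export
print.hapmer_sets <- function(x, ...) {
  cat(sprintf("hap-mer sets: %d maternal, %d paternal markers (k=%d)\n",
              x$n_mat, x$n_pat, x$maternal$k))
  invisible(x)
}
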
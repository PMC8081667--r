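# Canonical k-mer counting and histograms. K-mer identities are 2-bit packed
# into 64-bit payloads carried in R doubles; the payloads are opaque on the R
# side and only the C++ layer orders or compares them.

new_kmer_counts <- function(k, code, count, source = "unknown") {
  structure(list(k = as.integer(k), code = code, count = as.integer(count),
                 source = source),
            class = "kmer_counts")
}

#' Count canonical k-mers
#'
#' Counts every k-mer of the input sequences after canonicalization (the
#' lexicographic minimum of a k-mer and its reverse complement). K-mers
#' containing `N` or any other non-ACGT character are skipped; case is
#' ignored.
#'
#' @param sequences character vector of sequences, or an [Assembly].
#' @param k k-mer size, an odd integer in `[3, 31]` (odd so no k-mer is its
#'   own reverse complement). Defaults to 21, the usual choice for assembly
#'   validation metrics; genome profiling conventionally uses 31.
#' @param source free-text tag recording where the k-mers came from
#'   (`"reads"`, `"assembly"`, `"parentA"`, ...).
#' @return a `kmer_counts` object: `k`, packed `code`s, integer `count`s
#'   (all >= 1), and the `source` tag.
#' @examples
#' kc <- count_kmers("ACGT", k = 3)
#' kmer_strings(kc)   # "ACG" with count 2: CGT canonicalizes to ACG
#' @export
count_kmers <- function(sequences, k = 21L, source = "unknown") {
  if (inherits(sequences, "asmqc_assembly")) sequences <- sequences$sequences
  sequences <- as.character(sequences)
  if (length(sequences) == 0) stop("no sequences given")
  if (k %% 2 == 0) warning("even k: palindromic k-mers are their own reverse complement")
  res <- cpp_count_kmers(sequences, as.integer(k))
  if (length(res$code) == 0) warning("no k-mers counted (k larger than every sequence?)")
  new_kmer_counts(k, res$code, res$count, source)
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf("kmer_counts: k=%d, %d distinct k-mers, %.0f instances, source=%s\n",
              x$k, length(x$code), sum(as.numeric(x$count)), x$source))
  invisible(x)
}

#' Decode stored k-mers to strings
#'
#' @param counts a `kmer_counts` object.
#' @return named integer vector: canonical k-mer string -> count.
#' @export
kmer_strings <- function(counts) {
  stats::setNames(counts$count, cpp_decode_kmers(counts$code, counts$k))
}

# counts in `b` for every k-mer of `a` (0 where absent)
lookup_counts <- function(a, b) {
  if (a$k != b$k) stop(sprintf("k mismatch: %d vs %d", a$k, b$k))
  cpp_lookup_counts(a$code, b$code, b$count)
}

# subset a kmer_counts by logical/integer index (order-preserving, so the
# sortedness invariant holds)
subset_kmer_counts <- function(x, i) {
  new_kmer_counts(x$k, x$code[i], x$count[i], x$source)
}

#' Multiplicity histogram of a k-mer count set
#'
#' @param counts a `kmer_counts` object (non-empty).
#' @return a `kmer_histogram`: data frame with columns `multiplicity` and
#'   `n_kmers` (distinct k-mers at that multiplicity), plus attribute `k`.
#'   Rows with `n_kmers == 0` are dropped.
#' @export
kmer_histogram <- function(counts) {
  if (length(counts$count) == 0) stop("empty k-mer count set")
  tab <- tabulate(counts$count)
  h <- data.frame(multiplicity = seq_along(tab), n_kmers = tab)
  h <- h[h$n_kmers > 0, , drop = FALSE]
  rownames(h) <- NULL
  structure(h, k = counts$k, class = c("kmer_histogram", "data.frame"))
}

#' Read / write a k-mer histogram as two-column TSV
#'
#' The format (multiplicity, distinct k-mer count) matches what external
#' k-mer counters emit, so histograms from other tools can be imported.
#'
#' @param path TSV path; lines starting with `#` are ignored.
#' @param k k-mer size to record on the imported histogram.
#' @return for `read_kmer_histogram`, a `kmer_histogram`.
#' @export
read_kmer_histogram <- function(path, k = NA_integer_) {
  h <- utils::read.table(path, sep = "\t", comment.char = "#",
                         col.names = c("multiplicity", "n_kmers"))
  h <- h[order(h$multiplicity), , drop = FALSE]
  if (any(h$multiplicity < 1) || any(h$n_kmers < 0)) stop("invalid histogram entries")
  rownames(h) <- NULL
  structure(h, k = as.integer(k), class = c("kmer_histogram", "data.frame"))
}

#' @rdname read_kmer_histogram
#' @param hist a `kmer_histogram`.
#' @export
write_kmer_histogram <- function(hist, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(list(k = attr(hist, "k"))), con)
  utils::write.table(hist[, c("multiplicity", "n_kmers")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# dense lookup vector: multiplicity -> n_kmers (0 where absent)
hist_dense <- function(hist) {
  m <- max(hist$multiplicity)
  v <- numeric(m)
  v[hist$multiplicity] <- hist$n_kmers
  v
}

#' Error-multiplicity threshold from a k-mer histogram
#'
#' Sequencing errors create a mass of low-multiplicity k-mers to the left of
#' the sampling peak. The threshold separating the two is the multiplicity of
#' the first local minimum between the error region and the main peak; read
#' k-mers at or below it are treated as unreliable by the completeness and
#' hap-mer filters.
#'
#' @param hist a `kmer_histogram` with at least 2 entries.
#' @param fallback threshold returned when no interior minimum exists (e.g.
#'   a strictly decreasing histogram, or error-free reads).
#' @return integer multiplicity cutoff.
#' @export
error_threshold <- function(hist, fallback = 2L) {
  if (nrow(hist) < 2) stop("histogram needs >= 2 entries")
  v <- hist_dense(hist)
  # light smoothing so sampling noise on the peak flank does not read as a
  # local minimum
  if (length(v) >= 3) {
    sm <- stats::filter(v, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- v[is.na(sm)]
    v <- as.numeric(sm)
  }
  peak <- which.max(v)
  # the error region is a descent that starts at the lowest multiplicities;
  # the threshold is the first rise after it. A histogram that opens by
  # rising has no error mass (the first peak is genomic, e.g. the haploid
  # peak of a heterozygous genome), so the fallback applies.
  descended <- FALSE
  m <- 2L
  while (m < peak) {
    if (v[m] < v[m - 1L]) descended <- TRUE
    else if (!descended && v[m] > v[m - 1L]) return(as.integer(fallback))
    if (descended && v[m] < v[m + 1L]) return(m)
    m <- m + 1L
  }
  as.integer(fallback)
}
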
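#' @useDynLib asmqc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Reverse complement of DNA strings
#'
#' Case is preserved; `N` maps to `N`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Round half away from zero
#'
#' Copy-number estimates use commercial rounding rather than R's banker
#' rounding, so a read-multiplicity ratio of exactly 1.5 maps to 2 copies.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# header line stamped on all tabular outputs
output_header <- function(params = character()) {
  ver <- as.character(utils::packageVersion("asmqc"))
  p <- if (length(params)) paste(names(params), unlist(params), sep = "=", collapse = " ") else ""
  sprintf("# asmqc %s %s", ver, p)
}

#' Write intervals as BED
#'
#' Intervals are written 0-based half-open with a comment header naming the
#' tool version and parameters.
#'
#' @param df data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`, `score`, `strand`.
#' @param path output path.
#' @param params named list of parameters recorded in the header line.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(params), con)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(df))
  utils::write.table(df[, cols, drop = FALSE], con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
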
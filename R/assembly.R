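# Assembly container, scaffold -> contig/gap decomposition, and continuity,
# chromosome-assignment and telomere metrics.

#' Assembly object
#'
#' An assembly is an ordered set of named scaffold sequences with a role tag.
#' Scaffolds are stored as plain upper/lowercase ACGTN strings; lowercase
#' (soft masking) is preserved in the sequence but ignored by every metric.
#' Non-ACGTN IUPAC ambiguity codes are mapped to `N` on load with a logged
#' count; characters outside the IUPAC alphabet are an error.
#'
#' @param sequences named character vector of scaffold sequences.
#' @param role one of `"primary"`, `"alternate"`, `"maternal"`, `"paternal"`.
#' @return an `asmqc_assembly` object.
#' @export
Assembly <- function(sequences, role = c("primary", "alternate", "maternal", "paternal")) {
  role <- match.arg(role)
  if (is.null(names(sequences)) || anyNA(names(sequences)) || any(names(sequences) == ""))
    stop("all sequences must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate sequence names: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]), collapse = ", "))
  sequences <- vapply(sequences, sanitize_sequence, character(1))
  if (sum(nchar(sequences)) == 0) stop("assembly has zero total length")
  structure(list(sequences = sequences, role = role), class = "asmqc_assembly")
}

sanitize_sequence <- function(s) {
  iupac <- "ACGTNRYSWKMBDHVacgtnryswkmbdhv"
  bad <- gsub(sprintf("[%s]", iupac), "", s)
  if (nchar(bad) > 0)
    stop("illegal characters beyond IUPAC: ", substr(bad, 1, 20))
  amb <- nchar(gsub("[ACGTNacgtn]", "", s))
  if (amb > 0) {
    message(sprintf("mapped %d ambiguity bases to N", amb))
    s <- chartr("RYSWKMBDHVryswkmbdhv", strrep("N", 10 + 10), s)
    s <- gsub("[^ACGTNacgtn]", "N", s) # safety net; chartr covers all cases
  }
  s
}

#' @export
print.asmqc_assembly <- function(x, ...) {
  cat(sprintf("asmqc assembly (%s): %d scaffolds, %.0f bp\n",
              x$role, length(x$sequences), assembly_length(x)))
  invisible(x)
}

#' Total assembly length in bases (N included)
#' @param assembly an [Assembly].
#' @return total length in bp.
#' @export
assembly_length <- function(assembly) sum(as.numeric(nchar(assembly$sequences)))

#' Load an assembly from FASTA
#'
#' Reads a (possibly gzipped) FASTA, validates it, and decomposes each
#' scaffold into contigs and gaps.
#'
#' @param fasta_path path to a FASTA file (gzip accepted).
#' @param gap_min_run minimum run of `N` to call a gap, in bp (>= 1). The
#'   default of 10 follows the sequence-archive convention; scaffolders in
#'   the reference pipeline insert 100-N gaps, so both are captured.
#' @param role assembly role tag.
#' @return list with elements `assembly` (an [Assembly]) and `decomposition`
#'   (see [decompose_scaffolds()]).
#' @export
load_assembly <- function(fasta_path, gap_min_run = 10L,
                          role = c("primary", "alternate", "maternal", "paternal")) {
  role <- match.arg(role)
  if (!file.exists(fasta_path)) stop("file not found: ", fasta_path)
  ss <- Biostrings::readBStringSet(fasta_path)
  if (length(ss) == 0) stop("empty FASTA: ", fasta_path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss)) # first token of header
  asm <- Assembly(seqs, role)
  list(assembly = asm, decomposition = decompose_scaffolds(asm, gap_min_run))
}

#' Decompose scaffolds into contigs and gaps
#'
#' A gap is a maximal run of at least `gap_min_run` `N` characters.
#' Leading/trailing `N` runs of any length are reported as terminal gaps but
#' never as contigs (they would otherwise inflate contig counts). Contig and
#' gap intervals tile each scaffold exactly; coordinates are 0-based
#' half-open.
#'
#' @param assembly an [Assembly].
#' @param gap_min_run minimum interior N-run length to call a gap, bp.
#' @return an `asmqc_decomposition`: list with data frames `contigs` and
#'   `gaps` (columns `scaffold`, `start`, `end`, `length`; gaps also have
#'   `terminal`), and `gap_min_run`.
#' @export
decompose_scaffolds <- function(assembly, gap_min_run = 10L) {
  stopifnot(gap_min_run >= 1)
  contigs <- list(); gaps <- list()
  for (nm in names(assembly$sequences)) {
    s <- toupper(assembly$sequences[[nm]])
    len <- nchar(s)
    m <- gregexpr("N+", s)[[1]]
    if (m[1] == -1) {
      runs <- data.frame(start = integer(0), end = integer(0))
    } else {
      runs <- data.frame(start = as.integer(m) - 1L,
                         end = as.integer(m) + attr(m, "match.length") - 1L)
    }
    terminal <- runs$start == 0L | runs$end == len
    keep <- terminal | (runs$end - runs$start) >= gap_min_run
    runs <- runs[keep, , drop = FALSE]
    terminal <- terminal[keep]
    if (nrow(runs)) {
      gaps[[nm]] <- data.frame(scaffold = nm, start = runs$start, end = runs$end,
                               length = runs$end - runs$start, terminal = terminal)
    }
    # contigs are the complement of retained N runs
    bounds <- c(0L, as.vector(rbind(runs$start, runs$end)), len)
    cs <- bounds[seq(1, length(bounds), by = 2)]
    ce <- bounds[seq(2, length(bounds), by = 2)]
    ok <- ce > cs
    if (any(ok)) {
      contigs[[nm]] <- data.frame(scaffold = nm, start = cs[ok], end = ce[ok],
                                  length = ce[ok] - cs[ok])
    }
  }
  structure(list(
    contigs = if (length(contigs)) do.call(rbind, c(contigs, make.row.names = FALSE))
              else data.frame(scaffold = character(0), start = integer(0),
                              end = integer(0), length = integer(0)),
    gaps = if (length(gaps)) do.call(rbind, c(gaps, make.row.names = FALSE))
           else data.frame(scaffold = character(0), start = integer(0),
                           end = integer(0), length = integer(0), terminal = logical(0)),
    gap_min_run = as.integer(gap_min_run)
  ), class = "asmqc_decomposition")
}

#' Contig sequences of a decomposed assembly
#'
#' @param assembly an [Assembly].
#' @param decomposition matching decomposition.
#' @return named character vector `scaffold:start-end` -> contig sequence.
#' @export
contig_sequences <- function(assembly, decomposition) {
  ct <- decomposition$contigs
  out <- substring(assembly$sequences[ct$scaffold], ct$start + 1L, ct$end)
  names(out) <- sprintf("%s:%d-%d", ct$scaffold, ct$start, ct$end)
  out
}

#' NGx statistic
#'
#' The length L such that sequences of length >= L, taken in descending
#' order, jointly cover at least `fraction` of `reference_size`. With
#' `reference_size` equal to the summed lengths this is the Nx statistic.
#' NG50 is the default `fraction = 0.5`.
#'
#' @param lengths sequence lengths in bp, all > 0.
#' @param reference_size reference (estimated genome) size in bp.
#' @param fraction fraction of the reference to cover, in (0, 1].
#' @return length in bp, with attribute `reached`. If the summed lengths
#'   never reach `fraction * reference_size` the sentinel 0 is returned with
#'   `reached = FALSE` rather than a fabricated value.
#' @examples
#' ngx(c(50, 30, 20), reference_size = 100)        # 50
#' ngx(c(50, 30, 20), reference_size = 120)        # 30
#' @export
ngx <- function(lengths, reference_size, fraction = 0.5) {
  stopifnot(length(lengths) > 0, all(lengths > 0), reference_size > 0,
            fraction > 0, fraction <= 1)
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  target <- fraction * reference_size
  cum <- cumsum(lengths)
  i <- which(cum >= target)
  if (length(i) == 0) return(structure(0, reached = FALSE))
  structure(lengths[i[1]], reached = TRUE)
}

#' Continuity statistics
#'
#' NG50/N50 for contigs and scaffolds, sequence/gap counts, and gaps per Gb
#' of assembled sequence. NGx is computed against the estimated genome size;
#' Nx against the assembly length.
#'
#' @param assembly an [Assembly].
#' @param decomposition matching decomposition.
#' @param genome_size estimated genome size in bp (> 0), typically from the
#'   k-mer profile ([fit_genome_profile()]).
#' @return a `continuity_stats` list.
#' @export
continuity_stats <- function(assembly, decomposition, genome_size) {
  stopifnot(genome_size > 0)
  scaf_len <- as.numeric(nchar(assembly$sequences))
  ctg_len <- as.numeric(decomposition$contigs$length)
  asm_len <- sum(scaf_len)
  n_gaps <- sum(!decomposition$gaps$terminal)
  structure(list(
    contig_ng50 = ngx(ctg_len, genome_size),
    scaffold_ng50 = ngx(scaf_len, genome_size),
    contig_n50 = ngx(ctg_len, sum(ctg_len)),
    scaffold_n50 = ngx(scaf_len, asm_len),
    n_scaffolds = length(scaf_len),
    n_contigs = length(ctg_len),
    n_gaps = n_gaps,
    gaps_per_gb = n_gaps / (asm_len / 1e9),
    assembly_length = asm_len,
    genome_size_used = genome_size
  ), class = "continuity_stats")
}

#' @export
print.continuity_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "continuity: %d scaffolds / %d contigs / %d gaps (%.1f gaps/Gb)\n",
    "  contig NG50 %.0f bp  scaffold NG50 %.0f bp (genome size %.0f bp)\n",
    "  contig  N50 %.0f bp  scaffold  N50 %.0f bp (assembly %.0f bp)\n"),
    x$n_scaffolds, x$n_contigs, x$n_gaps, x$gaps_per_gb,
    x$contig_ng50, x$scaffold_ng50, x$genome_size_used,
    x$contig_n50, x$scaffold_n50, x$assembly_length))
  invisible(x)
}

#' Fraction of the assembly assigned to chromosomes
#'
#' Reads a scaffold-to-chromosome table and reports the percentage of
#' primary bases (N bases included by default) lying in chromosome-labelled
#' scaffolds — the C component of the x.y.P.Q.C notation. Unlocalized
#' scaffolds count as assigned only if the table labels them with a
#' chromosome.
#'
#' @param assembly an [Assembly].
#' @param table a data frame with columns `scaffold`, `chromosome`, or a path
#'   to a 2-column TSV (header optional; `#` comments ignored).
#' @param count_n if `FALSE`, N bases are excluded from both numerator and
#'   denominator.
#' @return a `chromosome_assignment` list with `mapping` (data frame) and
#'   `assigned_fraction` (percent).
#' @export
assigned_fraction <- function(assembly, table, count_n = TRUE) {
  if (is.character(table)) {
    table <- utils::read.table(table, sep = "\t", comment.char = "#",
                               col.names = c("scaffold", "chromosome"),
                               colClasses = "character")
    if (nrow(table) && identical(tolower(table$scaffold[1]), "scaffold"))
      table <- table[-1, , drop = FALSE]
  }
  stopifnot(all(c("scaffold", "chromosome") %in% names(table)))
  unknown <- setdiff(table$scaffold, names(assembly$sequences))
  if (length(unknown))
    stop("unknown scaffolds in assignment table: ", paste(unknown, collapse = ", "))
  base_count <- function(s) {
    if (count_n) nchar(s) else nchar(gsub("[Nn]", "", s))
  }
  lens <- vapply(assembly$sequences, base_count, numeric(1))
  assigned <- names(assembly$sequences) %in%
    table$scaffold[!is.na(table$chromosome) & table$chromosome != ""]
  total <- sum(lens)
  frac <- if (total == 0) 0 else 100 * sum(lens[assigned]) / total
  structure(list(mapping = table, assigned_fraction = frac, count_n = count_n),
            class = "chromosome_assignment")
}

#' Telomere motif scan at scaffold ends
#'
#' Looks for long tandem arrays of the telomere repeat within a window of
#' each scaffold end, on either strand. An array is a maximal chain of motif
#' matches with short interruptions; an end is flagged when the chain spans
#' at least `min_array` bp with a mismatch fraction at most `max_divergence`.
#'
#' @param assembly an [Assembly].
#' @param motif telomere repeat unit (default vertebrate `TTAGGG`).
#' @param window how far from the scaffold end to search, bp (default 1 kb).
#' @param min_array minimum array span to call a telomere, bp.
#' @param max_divergence maximum fraction of the array span not covered by
#'   exact motif copies.
#' @return data frame with one row per scaffold end: `scaffold`, `side`
#'   (left/right), `telomere_present`, `array_length`, `array_start`,
#'   `array_end` (0-based scaffold coordinates of the array, NA when absent).
#' @export
telomere_end_scan <- function(assembly, motif = "TTAGGG", window = 1000L,
                              min_array = 100L, max_divergence = 0.1) {
  stopifnot(nchar(motif) >= 4, window >= nchar(motif))
  rows <- list()
  for (nm in names(assembly$sequences)) {
    s <- toupper(assembly$sequences[[nm]])
    len <- nchar(s)
    w <- min(window, len)
    for (side in c("left", "right")) {
      off <- if (side == "left") 0L else len - w
      sub <- substr(s, off + 1L, off + w)
      arr <- best_motif_array(sub, motif, max_divergence)
      present <- !is.null(arr) && arr$span >= min_array
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = nm, side = side, telomere_present = present,
        array_length = if (present) arr$span else 0L,
        array_start = if (present) off + arr$start else NA_integer_,
        array_end = if (present) off + arr$end else NA_integer_)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# longest chain of exact motif hits (either strand) whose span has mismatch
# fraction <= max_div; gaps between consecutive hits of more than
# max_div * current span break the chain
best_motif_array <- function(s, motif, max_div) {
  hits <- integer(0)
  for (m in unique(c(motif, revcomp(motif)))) {
    g <- gregexpr(m, s, fixed = TRUE)[[1]]
    if (g[1] != -1) hits <- c(hits, as.integer(g))
  }
  if (!length(hits)) return(NULL)
  hits <- sort(unique(hits))
  k <- nchar(motif)
  best <- NULL
  i <- 1L
  n <- length(hits)
  while (i <= n) {
    j <- i
    covered <- k
    while (j < n) {
      gap <- hits[j + 1L] - (hits[j] + k)
      if (gap < 0) gap <- 0 # overlapping hits
      span_next <- hits[j + 1L] + k - hits[i]
      cov_next <- covered + min(k, hits[j + 1L] + k - max(hits[j] + k, hits[j + 1L]))
      if ((span_next - cov_next) / span_next <= max_div) {
        j <- j + 1L; covered <- cov_next
      } else break
    }
    span <- hits[j] + k - hits[i]
    cand <- list(start = hits[i] - 1L, end = hits[j] + k - 1L, span = span)
    if (is.null(best) || cand$span > best$span) best <- cand
    i <- j + 1L
  }
  best
}

#' Write gap / contig / telomere BED tracks
#'
#' @param decomposition an `asmqc_decomposition`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_decomposition_bed <- function(decomposition, dir, prefix = "assembly") {
  g <- decomposition$gaps
  ct <- decomposition$contigs
  gp <- file.path(dir, paste0(prefix, ".gaps.bed"))
  cp <- file.path(dir, paste0(prefix, ".contigs.bed"))
  write_bed(data.frame(chrom = g$scaffold, start = g$start, end = g$end,
                       name = ifelse(g$terminal, "terminal_gap", "gap")),
            gp, list(gap_min_run = decomposition$gap_min_run))
  write_bed(data.frame(chrom = ct$scaffold, start = ct$start, end = ct$end,
                       name = "contig"), cp,
            list(gap_min_run = decomposition$gap_min_run))
  invisible(c(gp, cp))
}
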
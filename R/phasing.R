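# Trio phasing metrics: read binning by parental marker k-mers, marker
# placement on the assembly, phase blocks and switch errors.

#' Bin reads by parental hap-mers
#'
#' Each read is scored against both marker sets: the number of marker hits
#' normalized by the total number of markers in that haplotype. The read is
#' assigned to the haplotype with the larger normalized score; reads with no
#' hits, or exactly tied scores, stay unassigned.
#'
#' @param reads character vector of read sequences (names used as read ids),
#'   or a path to a FASTA/FASTQ file (gzip accepted).
#' @param hapmers a `hapmer_sets` from [extract_hapmers()].
#' @return a `read_binning` list: `assignments` data frame (`read`, `class`,
#'   `hits_mat`, `hits_pat`, `score_mat`, `score_pat`) and a `summary` count
#'   per class.
#' @export
bin_reads <- function(reads, hapmers) {
  if (hapmers$n_mat == 0 && hapmers$n_pat == 0) stop("empty marker sets")
  if (length(reads) == 1 && is.character(reads) && file.exists(reads))
    reads <- read_sequences(reads)
  ids <- names(reads) %||% sprintf("read%d", seq_along(reads))
  if (is.null(names(reads))) names(reads) <- ids
  k <- hapmers$maternal$k
  hits <- cpp_read_marker_hits(unname(reads), hapmers$maternal$code,
                               hapmers$paternal$code, k)
  score_mat <- if (hapmers$n_mat > 0) hits[, 1] / hapmers$n_mat else 0
  score_pat <- if (hapmers$n_pat > 0) hits[, 2] / hapmers$n_pat else 0
  class <- ifelse(score_mat > score_pat, "maternal",
                  ifelse(score_pat > score_mat, "paternal", "unassigned"))
  df <- data.frame(read = ids, class = class, hits_mat = hits[, 1],
                   hits_pat = hits[, 2], score_mat = score_mat,
                   score_pat = score_pat)
  structure(list(assignments = df,
                 summary = table(factor(class, c("maternal", "paternal", "unassigned")))),
            class = "read_binning")
}

#' @export
print.read_binning <- function(x, ...) {
  s <- x$summary
  cat(sprintf("read binning: %d maternal, %d paternal, %d unassigned\n",
              s[["maternal"]], s[["paternal"]], s[["unassigned"]]))
  invisible(x)
}

#' Locate hap-mer markers on an assembly
#'
#' @param assembly an [Assembly].
#' @param hapmers a `hapmer_sets`.
#' @return data frame of marker placements: `scaffold`, `pos` (0-based
#'   start), `parent` (`"maternal"`/`"paternal"`), ordered by scaffold and
#'   position.
#' @export
place_markers <- function(assembly, hapmers) {
  k <- hapmers$maternal$k
  rows <- lapply(names(assembly$sequences), function(nm) {
    s <- assembly$sequences[[nm]]
    m <- cpp_scan_positions(s, hapmers$maternal$code, k)
    p <- cpp_scan_positions(s, hapmers$paternal$code, k)
    if (length(m$pos) + length(p$pos) == 0) return(NULL)
    df <- data.frame(scaffold = nm,
                     pos = c(m$pos, p$pos) - 1L,
                     parent = rep(c("maternal", "paternal"),
                                  c(length(m$pos), length(p$pos))))
    df[order(df$pos), , drop = FALSE]
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(scaffold = character(0), pos = integer(0), parent = character(0)))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Phase blocks and switch errors from marker placements
#'
#' Scans the ordered marker placements of each scaffold. A block keeps its
#' parent as long as opposite-parent markers occur only in short runs (at
#' most `max_switch_run` markers spanning at most `max_switch_span` bp);
#' each tolerated run counts one switch error. A longer or wider opposite
#' run terminates the block and starts a new one of the other parent. These
#' two tolerances are the dominant determinant of the phase block NG50.
#'
#' @param assembly an [Assembly] of the phased (or to-be-assessed) sequence.
#' @param hapmers a `hapmer_sets`.
#' @param genome_size genome size for the block NG50, bp.
#' @param max_switch_run maximum tolerated opposite-marker run, markers.
#' @param max_switch_span maximum tolerated opposite-run span, bp.
#' @return a `phase_report` list: `blocks` (scaffold, start, end, parent,
#'   n_markers, n_opposite), `markers` (placements), `switch_errors`,
#'   `phase_block_ng50`, `precision` and `recall` per parent (percent), and
#'   `scaffolds_without_markers`.
#' @export
phase_blocks <- function(assembly, hapmers, genome_size,
                         max_switch_run = 10L, max_switch_span = 20000L) {
  mk <- place_markers(assembly, hapmers)
  no_markers <- setdiff(names(assembly$sequences), unique(mk$scaffold))
  blocks <- list()
  switches <- 0L
  for (nm in unique(mk$scaffold)) {
    d <- mk[mk$scaffold == nm, , drop = FALSE]
    res <- scan_blocks_one(d$pos, d$parent, max_switch_run, max_switch_span,
                           hapmers$maternal$k)
    if (nrow(res$blocks)) {
      res$blocks$scaffold <- nm
      blocks[[nm]] <- res$blocks
    }
    switches <- switches + res$switches
  }
  blocks <- if (length(blocks)) do.call(rbind, c(blocks, make.row.names = FALSE))
            else data.frame(start = integer(0), end = integer(0), parent = character(0),
                            n_markers = integer(0), n_opposite = integer(0),
                            scaffold = character(0))
  blocks <- blocks[, c("scaffold", "start", "end", "parent", "n_markers", "n_opposite")]
  ngb <- if (nrow(blocks)) ngx(blocks$end - blocks$start, genome_size) else structure(0, reached = FALSE)
  prec <- function(par) {
    b <- blocks[blocks$parent == par, , drop = FALSE]
    tot <- sum(b$n_markers) + sum(b$n_opposite)
    if (tot == 0) NA_real_ else 100 * sum(b$n_markers) / tot
  }
  rec <- function(par) {
    n_tot <- if (par == "maternal") hapmers$n_mat else hapmers$n_pat
    if (n_tot == 0) return(NA_real_)
    b <- blocks[blocks$parent == par, , drop = FALSE]
    100 * sum(b$n_markers) / n_tot
  }
  structure(list(blocks = blocks, markers = mk, switch_errors = switches,
                 phase_block_ng50 = ngb,
                 precision = c(maternal = prec("maternal"), paternal = prec("paternal")),
                 recall = c(maternal = rec("maternal"), paternal = rec("paternal")),
                 scaffolds_without_markers = no_markers,
                 params = list(max_switch_run = max_switch_run,
                               max_switch_span = max_switch_span)),
            class = "phase_report")
}

# block scan over one scaffold's ordered markers. pos 0-based; blocks span
# from first to last marker (k-mer end) of the block.
scan_blocks_one <- function(pos, parent, max_run, max_span, k) {
  n <- length(pos)
  blocks <- list()
  switches <- 0L
  i <- 1L
  while (i <= n) {
    cur <- parent[i]
    b_start_i <- i
    last_same_i <- i
    opp_start_i <- NA_integer_
    j <- i + 1L
    terminate_at <- NA_integer_
    while (j <= n) {
      if (parent[j] == cur) {
        if (!is.na(opp_start_i)) switches <- switches + 1L # tolerated run closed
        opp_start_i <- NA_integer_
        last_same_i <- j
      } else {
        if (is.na(opp_start_i)) opp_start_i <- j
        run_len <- j - opp_start_i + 1L
        run_span <- pos[j] - pos[opp_start_i] + k
        if (run_len > max_run || run_span > max_span) {
          terminate_at <- opp_start_i
          break
        }
      }
      j <- j + 1L
    }
    end_i <- last_same_i
    blk <- data.frame(start = pos[b_start_i], end = pos[end_i] + k,
                      parent = cur,
                      n_markers = sum(parent[b_start_i:end_i] == cur),
                      n_opposite = sum(parent[b_start_i:end_i] != cur))
    blocks[[length(blocks) + 1L]] <- blk
    i <- if (is.na(terminate_at)) n + 1L else terminate_at
  }
  list(blocks = if (length(blocks)) do.call(rbind, blocks)
       else data.frame(start = integer(0), end = integer(0), parent = character(0),
                       n_markers = integer(0), n_opposite = integer(0)),
       switches = switches)
}

#' @export
print.phase_report <- function(x, ...) {
  cat(sprintf(paste0("phase report: %d blocks, NG50 %.0f bp, %d switch errors\n",
                     "  precision mat/pat %.2f/%.2f%%, recall %.2f/%.2f%%\n"),
              nrow(x$blocks), x$phase_block_ng50, x$switch_errors,
              x$precision[["maternal"]], x$precision[["paternal"]],
              x$recall[["maternal"]], x$recall[["paternal"]]))
  invisible(x)
}

#' Read sequences from FASTA or FASTQ
#'
#' Format is sniffed from the first non-blank character (`>` FASTA, `@`
#' FASTQ); gzip accepted.
#'
#' @param path sequence file path.
#' @return named character vector of sequences.
#' @export
read_sequences <- function(path) {
  con <- gzfile(path, "r")
  first <- readLines(con, n = 1)
  close(con)
  if (length(first) == 0) stop("empty file: ", path)
  ss <- if (startsWith(first, "@")) Biostrings::readBStringSet(path, format = "fastq")
        else Biostrings::readBStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
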
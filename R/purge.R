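# Coverage-cutoff purging: classify primary contigs as junk / haplotig /
# repeat / primary from a depth histogram and self-alignments, and relocate
# false duplications to the alternate set.

#' Coverage cutoffs from a depth histogram
#'
#' Smooths the per-base depth histogram (moving average, width 3), locates
#' the diploid coverage peak \eqn{\lambda_d} (the global mode above
#' low-depth noise, disambiguated against the haploid peak at
#' \eqn{\lambda_d/2}), and derives the three purge cutoffs:
#' `low = max(2, round(lambda_h / 4))` below which a contig is junk,
#' `mid = round((lambda_h + lambda_d) / 2)` below which it is a haplotig
#' candidate, and `high = 3 * lambda_d` above which it is flagged as repeat.
#'
#' @param depth_histogram named numeric vector or 2-column data frame
#'   mapping integer depth to number of bases at that depth.
#' @param override optional numeric triple `c(low, mid, high)` that wins
#'   over the estimate.
#' @return a `coverage_cutoffs` list: `low`, `mid`, `high`, `lambda_h`,
#'   `lambda_d`.
#' @export
coverage_cutoffs <- function(depth_histogram, override = NULL) {
  if (!is.null(override)) {
    stopifnot(length(override) == 3, 0 < override[1], override[1] < override[2],
              override[2] < override[3])
    return(structure(list(low = override[1], mid = override[2], high = override[3],
                          lambda_h = NA_real_, lambda_d = NA_real_,
                          source = "override"),
                     class = "coverage_cutoffs"))
  }
  if (is.data.frame(depth_histogram)) {
    h <- stats::setNames(depth_histogram[[2]], depth_histogram[[1]])
  } else h <- depth_histogram
  if (length(h) == 0) stop("empty depth histogram")
  depths <- as.integer(names(h))
  v <- numeric(max(depths))
  v[depths[depths >= 1]] <- h[depths >= 1]
  sm <- stats::filter(v, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- v[is.na(sm)]
  sm <- as.numeric(sm)
  noise_floor <- 3L # ignore the lowest depths when hunting the peak
  cand <- sm
  cand[seq_len(min(noise_floor, length(cand)))] <- 0
  if (all(cand == 0) || max(cand) < 3 * stats::median(cand[cand > 0]))
    stop("flat depth histogram: no peak; supply override cutoffs")
  m1 <- which.max(cand)
  lambda_d <- m1
  hi2 <- min(length(cand), ceiling(2.4 * m1)); lo2 <- floor(1.6 * m1)
  lo1 <- max(1, floor(0.8 * m1)); hi1 <- min(length(cand), ceiling(1.2 * m1))
  if (lo2 <= hi2 && sum(cand[lo2:hi2]) >= 0.5 * sum(cand[lo1:hi1]))
    lambda_d <- (lo2:hi2)[which.max(cand[lo2:hi2])]
  lambda_h <- lambda_d / 2
  structure(list(low = max(2, round_half_away(lambda_h / 4)),
                 mid = round((lambda_h + lambda_d) / 2),
                 high = 3 * lambda_d,
                 lambda_h = lambda_h, lambda_d = lambda_d, source = "estimated"),
            class = "coverage_cutoffs")
}

#' @export
print.coverage_cutoffs <- function(x, ...) {
  cat(sprintf("coverage cutoffs: low %g / mid %g / high %g (lambda_h %.1f, lambda_d %.1f, %s)\n",
              x$low, x$mid, x$high, x$lambda_h, x$lambda_d, x$source))
  invisible(x)
}

#' Classify primary contigs and purge false duplications
#'
#' Applies the purge rules to each primary contig:
#' \itemize{
#'   \item mean depth < `low` — junk, dropped to the junk set (never
#'     silently deleted);
#'   \item mean depth > `high` — repeat, retained in the primary but
#'     flagged;
#'   \item mean depth in `[low, mid)` and at least `min_aligned_frac` of its
#'     length aligned to a longer retained contig — haplotig, moved to the
#'     alternate set (depth alone never moves a contig);
#'   \item otherwise — primary.
#' }
#' Two contigs each covering the other (circular haplotig evidence) keep the
#' longer and move the shorter, with the tie-break logged. End-to-end
#' duplications inside one scaffold (one copy at a contig boundary) are
#' handled by the same alignment rule at contig granularity: the shorter
#' copy moves to the alternate set.
#'
#' @param primary primary [Assembly] (contig-level sequences).
#' @param alternate alternate [Assembly] or NULL.
#' @param depths named numeric vector: per primary contig mean read depth.
#' @param cutoffs a `coverage_cutoffs`.
#' @param self_alignments PAF of primary vs primary (trivial self-matches
#'   ignored).
#' @param min_aligned_frac aligned-length fraction required for a haplotig
#'   call (default 0.8).
#' @return a `purge_result` list: `primary`, `alternate`, `junk` (all
#'   [Assembly] or NULL), and `decisions` data frame (`contig`, `label`,
#'   `depth`, `aligned_fraction`, `partner`).
#' @export
classify_and_purge <- function(primary, alternate = NULL, depths, cutoffs,
                               self_alignments, min_aligned_frac = 0.8) {
  stopifnot(all(names(primary$sequences) %in% names(depths)) || all(names(depths) %in% names(primary$sequences)))
  paf <- paf_input(self_alignments)
  paf <- paf[paf$query != paf$target, , drop = FALSE]
  lens <- vapply(primary$sequences, nchar, integer(1))
  nms <- names(primary$sequences)
  dep <- depths[nms]
  label <- rep("primary", length(nms)); names(label) <- nms
  partner <- rep(NA_character_, length(nms)); names(partner) <- nms
  afrac <- rep(NA_real_, length(nms)); names(afrac) <- nms

  label[dep < cutoffs$low] <- "junk"
  label[dep > cutoffs$high] <- "repeat"

  # aligned fraction of each contig against one other contig (merged qry cover)
  aligned_frac_to <- function(q, t) {
    p <- paf[paf$query == q & paf$target == t, , drop = FALSE]
    if (nrow(p) == 0) return(0)
    iv <- IRanges::reduce(IRanges::IRanges(start = p$qstart + 1L, end = p$qend))
    sum(IRanges::width(iv)) / lens[[q]]
  }
  # haplotig candidates by depth, processed shortest-first so the longer of a
  # circular pair is examined against an already-retained partner
  cand <- nms[label == "primary" & dep >= cutoffs$low & dep < cutoffs$mid]
  for (q in cand[order(lens[cand])]) {
    targets <- unique(paf$target[paf$query == q])
    targets <- targets[targets %in% nms & lens[targets] > lens[[q]]]
    targets <- targets[label[targets] %in% c("primary", "repeat")]
    if (!length(targets)) next
    fr <- vapply(targets, function(t) aligned_frac_to(q, t), numeric(1))
    best <- which.max(fr)
    afrac[[q]] <- fr[best]
    if (fr[best] >= min_aligned_frac) {
      label[[q]] <- "haplotig"
      partner[[q]] <- targets[best]
      message(sprintf("purge: %s -> alternate (%.0f%% aligned to %s)",
                      q, 100 * fr[best], targets[best]))
    }
  }
  decisions <- data.frame(contig = nms, label = unname(label),
                          depth = unname(dep),
                          aligned_fraction = unname(afrac),
                          partner = unname(partner))
  pick <- function(lab) {
    s <- primary$sequences[label == lab]
    if (length(s) == 0) NULL else s
  }
  new_primary <- primary$sequences[label %in% c("primary", "repeat")]
  alt_seqs <- c(if (!is.null(alternate)) alternate$sequences else character(0),
                primary$sequences[label == "haplotig"])
  junk <- pick("junk")
  structure(list(
    primary = Assembly(new_primary, "primary"),
    alternate = if (length(alt_seqs)) Assembly(alt_seqs, "alternate") else NULL,
    junk = if (!is.null(junk)) Assembly(junk, "alternate") else NULL,
    decisions = decisions, cutoffs = cutoffs),
    class = "purge_result")
}

#' @export
print.purge_result <- function(x, ...) {
  tab <- table(x$decisions$label)
  cat("purge result:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write purge outputs
#'
#' @param result a `purge_result`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return paths written, invisibly.
#' @export
write_purge_result <- function(result, dir, prefix = "purged") {
  paths <- character(0)
  wfa <- function(asm, tag) {
    if (is.null(asm)) return(NULL)
    p <- file.path(dir, sprintf("%s.%s.fasta", prefix, tag))
    write_fasta(asm$sequences, p)
    paths <<- c(paths, p)
  }
  wfa(result$primary, "primary"); wfa(result$alternate, "alternate")
  wfa(result$junk, "junk")
  dp <- file.path(dir, sprintf("%s.decisions.tsv", prefix))
  con <- file(dp, "w"); on.exit(close(con))
  writeLines(output_header(list(low = result$cutoffs$low, mid = result$cutoffs$mid,
                                high = result$cutoffs$high)), con)
  utils::write.table(result$decisions, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, dp))
}
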
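# Read-depth analysis over the assembly: windowed coverage tracks from PAF
# alignments, collapsed-repeat detection, multi-technology reliable blocks,
# and coverage-based false-duplication candidates. Interval arithmetic is
# delegated to IRanges.

#' Read a PAF alignment file
#'
#' Parses the 12 standard minimap2-style PAF columns; extra tag columns are
#' ignored.
#'
#' @param path PAF path (gzip accepted).
#' @return data frame with columns `query`, `qlen`, `qstart`, `qend`,
#'   `strand`, `target`, `tlen`, `tstart`, `tend`, `nmatch`, `alen`, `mapq`
#'   (coordinates 0-based half-open).
#' @export
read_paf <- function(path) {
  cols <- c("query", "qlen", "qstart", "qend", "strand", "target", "tlen",
            "tstart", "tend", "nmatch", "alen", "mapq")
  df <- data.table::fread(path, sep = "\t", header = FALSE, fill = TRUE,
                          select = 1:12, col.names = cols, data.table = FALSE)
  df
}

paf_input <- function(alignments) {
  if (is.character(alignments) && length(alignments) == 1) read_paf(alignments)
  else as.data.frame(alignments)
}

#' Windowed read-depth track
#'
#' Per-base depth is accumulated from the target intervals of retained
#' alignments and averaged within fixed windows. Alignments whose
#' residue-match fraction (`nmatch / alen`) falls below `min_match_frac` are
#' discarded (a mapping-quality proxy that PAF always carries).
#'
#' @param alignments PAF path or data frame from [read_paf()].
#' @param assembly an [Assembly]; all PAF targets must be scaffolds of it.
#' @param technology free-form technology tag (e.g. `"long-read"`).
#' @param window window size in bp (>= 100).
#' @param min_match_frac minimum residue-match fraction to retain an
#'   alignment.
#' @return a `coverage_track` list: `technology`, `window`, `depth` (named
#'   list of per-window mean-depth vectors), `scaffold_length`, `mean`, `sd`
#'   (over all windows), `robust` copies using median and 1.4826 MAD.
#' @export
depth_track <- function(alignments, assembly, technology = "long-read",
                        window = 1000L, min_match_frac = 0.5) {
  stopifnot(window >= 1)
  paf <- paf_input(alignments)
  bad <- setdiff(unique(paf$target), names(assembly$sequences))
  if (length(bad)) stop("PAF targets not in assembly: ", paste(bad, collapse = ", "))
  paf <- paf[paf$alen > 0 & paf$nmatch / paf$alen >= min_match_frac, , drop = FALSE]
  if (nrow(paf) == 0) stop("no alignments retained after filtering")
  depth <- list()
  for (nm in names(assembly$sequences)) {
    len <- nchar(assembly$sequences[[nm]])
    p <- paf[paf$target == nm, , drop = FALSE]
    nwin <- ceiling(len / window)
    if (nrow(p) == 0) { depth[[nm]] <- numeric(nwin); next }
    cov <- IRanges::coverage(IRanges::IRanges(start = p$tstart + 1L, end = p$tend),
                             width = len)
    ends <- pmin(seq_len(nwin) * window, len)
    starts <- (seq_len(nwin) - 1L) * window + 1L
    v <- IRanges::Views(cov, start = starts, end = ends)
    depth[[nm]] <- IRanges::viewMeans(v)
  }
  all_d <- unlist(depth, use.names = FALSE)
  structure(list(technology = technology, window = as.integer(window),
                 depth = depth,
                 scaffold_length = vapply(assembly$sequences, nchar, integer(1)),
                 mean = mean(all_d), sd = stats::sd(all_d),
                 robust_mean = stats::median(all_d),
                 robust_sd = 1.4826 * stats::mad(all_d, constant = 1)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage track [%s]: %d scaffolds, window %d bp, mean %.1f sd %.2f\n",
              x$technology, length(x$depth), x$window, x$mean, x$sd))
  invisible(x)
}

#' Collapsed-repeat regions from abnormal depth
#'
#' Windows with depth strictly greater than mean + 3 s.d. are flagged,
#' adjacent flagged windows merged, and merged intervals shorter than
#' `min_length` dropped. Each region's copy number is its mean depth over
#' the global mean (rounded); `extra_copies = copies - 1` copies of the
#' region length are missing from the assembly.
#'
#' @param track a `coverage_track`.
#' @param min_length minimum merged region length, bp.
#' @param n_sd number of standard deviations above the mean (default 3).
#' @param robust use median / 1.4826 MAD instead of mean / sd (collapses
#'   inflate the plain s.d.).
#' @return a `collapsed_regions` list: `regions` data frame (`scaffold`,
#'   `start`, `end`, `length`, `depth`, `copies`, `extra_copies`,
#'   `missing_bases`) and totals `n_regions`, `total_span`,
#'   `missing_bases`.
#' @export
collapsed_regions <- function(track, min_length = 1000L, n_sd = 3, robust = FALSE) {
  mu <- if (robust) track$robust_mean else track$mean
  sig <- if (robust) track$robust_sd else track$sd
  if (is.na(sig) || sig <= 0) stop("depth s.d. is zero; cannot flag outliers")
  cutoff <- mu + n_sd * sig
  rows <- list()
  for (nm in names(track$depth)) {
    d <- track$depth[[nm]]
    flag <- d > cutoff # strict
    if (!any(flag)) next
    r <- rle(flag)
    endw <- cumsum(r$lengths)
    startw <- endw - r$lengths + 1L
    for (i in which(r$values)) {
      s <- (startw[i] - 1L) * track$window
      e <- min(endw[i] * track$window, track$scaffold_length[[nm]])
      if (e - s < min_length) next
      dep <- mean(d[startw[i]:endw[i]])
      copies <- max(2, round_half_away(dep / mu))
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = nm, start = s, end = e, length = e - s, depth = dep,
        copies = copies, extra_copies = copies - 1,
        missing_bases = (copies - 1) * (e - s))
    }
  }
  regions <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
             else data.frame(scaffold = character(0), start = integer(0),
                             end = integer(0), length = integer(0),
                             depth = numeric(0), copies = numeric(0),
                             extra_copies = numeric(0), missing_bases = numeric(0))
  structure(list(regions = regions, n_regions = nrow(regions),
                 total_span = sum(regions$length),
                 missing_bases = sum(regions$missing_bases),
                 mean = mu, sd = sig, cutoff = cutoff),
            class = "collapsed_regions")
}

#' @export
print.collapsed_regions <- function(x, ...) {
  cat(sprintf("collapsed regions: %d regions spanning %.0f bp, ~%.0f bases missing (depth > %.1f)\n",
              x$n_regions, x$total_span, x$missing_bases, x$cutoff))
  invisible(x)
}

#' Spanning-support track for one technology
#'
#' Each retained alignment supports its target interval minus `end_trim` at
#' both ends (alignment ends are unreliable); a position is supported when
#' at least `min_depth` trimmed alignments cover it.
#'
#' @param alignments PAF path or data frame.
#' @param technology technology tag.
#' @param end_trim bp trimmed from each alignment end.
#' @param min_depth minimum trimmed-alignment depth.
#' @param min_match_frac PAF residue-match filter as in [depth_track()].
#' @return a `support_track` list: `technology` and `intervals` (named list
#'   of IRanges of supported positions per scaffold).
#' @export
support_track <- function(alignments, technology, end_trim = 100L, min_depth = 3L,
                          min_match_frac = 0.5) {
  stopifnot(end_trim >= 0)
  paf <- paf_input(alignments)
  paf <- paf[paf$alen > 0 & paf$nmatch / paf$alen >= min_match_frac, , drop = FALSE]
  out <- list()
  for (nm in unique(paf$target)) {
    p <- paf[paf$target == nm, , drop = FALSE]
    s <- p$tstart + end_trim + 1L
    e <- p$tend - end_trim
    ok <- e >= s
    if (!any(ok)) next
    cov <- IRanges::coverage(IRanges::IRanges(start = s[ok], end = e[ok]),
                             width = max(p$tlen))
    sup <- IRanges::slice(cov, lower = min_depth, rangesOnly = TRUE)
    if (length(sup)) out[[nm]] <- sup
  }
  structure(list(technology = technology, intervals = out), class = "support_track")
}

#' Support intervals from a BED file
#'
#' Pre-computed support (e.g. optical-map alignments, whose raw alignment is
#' out of scope) can be supplied as BED intervals.
#'
#' @param path BED path (0-based half-open; `#` comments ignored).
#' @param technology technology tag.
#' @return a `support_track`.
#' @export
support_from_bed <- function(path, technology) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#")[, 1:3]
  names(df) <- c("chrom", "start", "end")
  out <- lapply(split(df, df$chrom), function(d)
    IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end)))
  structure(list(technology = technology, intervals = out), class = "support_track")
}

#' Reliable blocks from multi-technology support
#'
#' A reliable block is a maximal interval where at least two distinct
#' technologies provide spanning support at every base.
#'
#' @param tracks list of >= 2 `support_track`s with distinct technology tags.
#' @param assembly an [Assembly].
#' @param genome_size genome size for the block NG50, bp.
#' @return a `reliable_blocks` list: `blocks` data frame (`scaffold`,
#'   `start`, `end`, 0-based half-open), `block_ng50`, `percent_covered` of
#'   assembly bases.
#' @export
reliable_blocks <- function(tracks, assembly, genome_size) {
  tags <- vapply(tracks, function(t) t$technology, character(1))
  if (length(unique(tags)) < 2) stop("need support from >= 2 distinct technologies")
  rows <- list()
  for (nm in names(assembly$sequences)) {
    len <- nchar(assembly$sequences[[nm]])
    techcov <- S4Vectors::Rle(0L, len)
    for (t in tracks) {
      iv <- t$intervals[[nm]]
      if (is.null(iv) || length(iv) == 0) next
      iv <- IRanges::restrict(IRanges::reduce(iv), start = 1L, end = len)
      techcov <- techcov + IRanges::coverage(iv, width = len)
    }
    blk <- IRanges::slice(techcov, lower = 2L, rangesOnly = TRUE)
    if (length(blk))
      rows[[nm]] <- data.frame(scaffold = nm, start = IRanges::start(blk) - 1L,
                               end = IRanges::end(blk))
  }
  blocks <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
            else data.frame(scaffold = character(0), start = integer(0), end = integer(0))
  lens <- blocks$end - blocks$start
  asm_len <- assembly_length(assembly)
  structure(list(blocks = blocks,
                 block_ng50 = if (nrow(blocks)) ngx(lens, genome_size)
                              else structure(0, reached = FALSE),
                 percent_covered = 100 * sum(as.numeric(lens)) / asm_len),
            class = "reliable_blocks")
}

#' @export
print.reliable_blocks <- function(x, ...) {
  cat(sprintf("reliable blocks: %d blocks, NG50 %.0f bp, %.1f%% of assembly\n",
              nrow(x$blocks), x$block_ng50, x$percent_covered))
  invisible(x)
}

#' Coverage-based false-duplication candidates
#'
#' Two signatures are searched. Heterotype candidates: intervals at about
#' half the global coverage (reads split between two copies of a divergent
#' haplotype region) that also have a self-alignment partner elsewhere in
#' the assembly. Homotype candidates: self-alignment pairs where one copy
#' lies near a contig end and the copy length is on the order of the read
#' length — the classic boundary artifact of overlap-based contigging.
#'
#' @param track a `coverage_track`.
#' @param self_alignments PAF of the assembly aligned to itself (trivial
#'   full-length self-matches are removed here).
#' @param decomposition the assembly's `asmqc_decomposition`.
#' @param read_length_estimate typical read length, bp.
#' @param half_cov_tol half-coverage band half-width as a fraction of
#'   \eqn{\mu/2} (default 0.25).
#' @param end_slack_windows how many windows from a contig end still counts
#'   as "at the boundary".
#' @return a `dup_candidates` list with data frames `heterotype` and
#'   `homotype`, each row carrying its evidence.
#' @export
dup_candidates <- function(track, self_alignments, decomposition,
                           read_length_estimate = 15000,
                           half_cov_tol = 0.25, end_slack_windows = 2L) {
  paf <- paf_input(self_alignments)
  paf <- paf[!(paf$query == paf$target & paf$qstart == paf$tstart &
                 paf$qend == paf$tend), , drop = FALSE]
  mu <- track$mean
  half <- mu / 2
  band <- half_cov_tol * half
  w <- track$window
  # half-coverage intervals per scaffold
  halfcov <- list()
  for (nm in names(track$depth)) {
    d <- track$depth[[nm]]
    flag <- abs(d - half) <= band
    if (!any(flag)) next
    r <- rle(flag)
    endw <- cumsum(r$lengths); startw <- endw - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep))
      halfcov[[nm]] <- data.frame(scaffold = nm, start = (startw[keep] - 1L) * w,
                                  end = pmin(endw[keep] * w, track$scaffold_length[[nm]]))
  }
  het <- list()
  for (nm in names(halfcov)) {
    hc <- halfcov[[nm]]
    p <- paf[paf$query == nm, , drop = FALSE]
    for (i in seq_len(nrow(hc))) {
      ov <- p[pmin(p$qend, hc$end[i]) - pmax(p$qstart, hc$start[i]) >
                0.5 * (hc$end[i] - hc$start[i]), , drop = FALSE]
      if (nrow(ov)) {
        het[[length(het) + 1L]] <- data.frame(
          scaffold = nm, start = hc$start[i], end = hc$end[i],
          partner = ov$target[1], partner_start = ov$tstart[1],
          partner_end = ov$tend[1],
          evidence = "half_coverage+self_alignment")
      }
    }
  }
  # homotype: self-alignment copy near a contig end, read-length scale
  ct <- decomposition$contigs
  near_end <- function(scaf, s, e) {
    cc <- ct[ct$scaffold == scaf, , drop = FALSE]
    slack <- end_slack_windows * w
    any(abs(s - cc$start) <= slack | abs(cc$end - e) <= slack)
  }
  hom <- list()
  for (i in seq_len(nrow(paf))) {
    len <- paf$qend[i] - paf$qstart[i]
    if (len < 0.2 * read_length_estimate || len > 3 * read_length_estimate) next
    if (near_end(paf$query[i], paf$qstart[i], paf$qend[i])) {
      hom[[length(hom) + 1L]] <- data.frame(
        scaffold = paf$query[i], start = paf$qstart[i], end = paf$qend[i],
        partner = paf$target[i], partner_start = paf$tstart[i],
        partner_end = paf$tend[i],
        evidence = "contig_end+read_length_scale_self_alignment")
    }
  }
  mkdf <- function(l) if (length(l)) unique(do.call(rbind, c(l, make.row.names = FALSE)))
    else data.frame(scaffold = character(0), start = integer(0), end = integer(0),
                    partner = character(0), partner_start = integer(0),
                    partner_end = integer(0), evidence = character(0))
  structure(list(heterotype = mkdf(het), homotype = mkdf(hom),
                 mean = mu, band = c(half - band, half + band)),
            class = "dup_candidates")
}

#' @export
print.dup_candidates <- function(x, ...) {
  cat(sprintf("duplication candidates: %d heterotype, %d homotype (half-coverage band %.1f-%.1f)\n",
              nrow(x$heterotype), nrow(x$homotype), x$band[1], x$band[2]))
  invisible(x)
}
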
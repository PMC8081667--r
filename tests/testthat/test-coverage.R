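test_that("depth track averages per-base alignment depth into windows", {
  asm <- Assembly(c(s1 = strrep("A", 100)))
  paf <- rbind(paf_row("r1", "s1", 0, 50, 100), paf_row("r2", "s1", 25, 75, 100))
  tr <- depth_track(paf, asm, window = 25)
  expect_equal(unname(tr$depth$s1), c(1, 2, 1, 0))

  # everything filtered out is an error
  bad <- paf_row("r1", "s1", 0, 50, 100, nmatch = 1, alen = 50)
  expect_error(depth_track(bad, asm, window = 25, min_match_frac = 0.5),
               "no alignments")
  expect_error(depth_track(paf_row("r", "zz", 0, 10, 100), asm), "not in assembly")
})

test_that("depth track recovers simulated uniform coverage", {
  set.seed(404)
  len <- 2e5
  asm <- Assembly(c(s1 = strrep("ACGT", len / 4)))
  n <- 600 # 600 x 10 kb over 200 kb = 30x
  starts <- floor(runif(n, -9999, len - 1))
  paf <- do.call(rbind, lapply(seq_len(n), function(i)
    paf_row(paste0("r", i), "s1", max(0, starts[i]), min(len, starts[i] + 10000), len)))
  tr <- depth_track(paf, asm, window = 1000)
  expect_lt(abs(tr$mean - 30), 2)
})

test_that("collapsed regions require depth above mean + 3 sd, merging and length", {
  trk <- manual_track(list(s1 = c(rep(30, 20), rep(80, 5), rep(30, 20))))
  trk$mean <- 30; trk$sd <- 5
  cr <- collapsed_regions(trk)
  expect_equal(nrow(cr$regions), 1)
  expect_equal(cr$regions$copies, 3)
  expect_equal(cr$regions$extra_copies, 2)
  expect_equal(cr$regions$missing_bases, 10000)
  expect_equal(cr$regions[, c("start", "end")],
               data.frame(start = 20000, end = 25000))

  # depth exactly mu + 3 sd is NOT flagged (strict inequality)
  trk2 <- manual_track(list(s1 = c(rep(30, 20), rep(45, 5), rep(30, 20))))
  trk2$mean <- 30; trk2$sd <- 5
  expect_equal(collapsed_regions(trk2)$n_regions, 0)

  # uniform track: nothing (sd = 0 is refused, use planted sd)
  trk3 <- manual_track(list(s1 = rep(30, 50)))
  trk3$sd <- 1
  expect_equal(collapsed_regions(trk3)$n_regions, 0)

  # min_length drops short regions
  trk4 <- manual_track(list(s1 = c(rep(30, 20), 80, rep(30, 20))))
  trk4$mean <- 30; trk4$sd <- 5
  expect_equal(collapsed_regions(trk4, min_length = 2000)$n_regions, 0)
})

test_that("collapse detector recovers planted collapses without false positives", {
  # uniform 30x tracks with planted >= 2.5x regions of >= 5 windows
  set.seed(88)
  for (rep_i in 1:8) {
    nwin <- 300
    d <- rnorm(nwin, 30, 1.5)
    n_planted <- sample(1:3, 1)
    planted <- IRanges::IRanges() # collect truth windows
    taken <- rep(FALSE, nwin)
    truth_wins <- integer(0)
    for (p in seq_len(n_planted)) {
      w <- sample(5:10, 1)
      s <- sample(1:(nwin - w), 1)
      if (any(taken[s:(s + w - 1)])) next
      taken[s:(s + w - 1)] <- TRUE
      d[s:(s + w - 1)] <- rnorm(w, sample(c(75, 90, 120), 1), 2)
      truth_wins <- c(truth_wins, s:(s + w - 1))
    }
    trk <- manual_track(list(s1 = d))
    # collapses inflate the plain sd; use robust statistics as provided
    cr <- collapsed_regions(trk, min_length = 3000, robust = TRUE)
    called <- unlist(lapply(seq_len(nrow(cr$regions)), function(i)
      (cr$regions$start[i] / 1000 + 1):(cr$regions$end[i] / 1000)))
    recall <- length(intersect(called, truth_wins)) / length(truth_wins)
    fp <- setdiff(called, truth_wins)
    expect_gte(recall, 0.9)
    expect_equal(length(fp), 0)
  }
})

test_that("support tracks trim alignment ends and apply the depth floor", {
  s1 <- support_track(paf_row("r", "s1", 0, 10000, 10000), "t1",
                      end_trim = 500, min_depth = 1)
  expect_equal(IRanges::start(s1$intervals$s1), 501)
  expect_equal(IRanges::end(s1$intervals$s1), 9500)

  s2 <- support_track(paf_row("r", "s1", 0, 10000, 10000), "t1",
                      end_trim = 500, min_depth = 2)
  expect_null(s2$intervals$s1)

  # two staggered alignments: union where trimmed depth >= 1
  paf <- rbind(paf_row("a", "s1", 0, 6000, 10000), paf_row("b", "s1", 4000, 10000, 10000))
  s3 <- support_track(paf, "t1", end_trim = 100, min_depth = 1)
  expect_equal(as.data.frame(s3$intervals$s1)[, c("start", "end")],
               data.frame(start = 101, end = 9900))
})

test_that("reliable blocks need two technologies and match per-base counting", {
  asm <- Assembly(c(s1 = strrep("A", 200)))
  t1 <- structure(list(technology = "a",
                       intervals = list(s1 = IRanges::IRanges(1, 100))),
                  class = "support_track")
  t2 <- structure(list(technology = "b",
                       intervals = list(s1 = IRanges::IRanges(51, 150))),
                  class = "support_track")
  rb <- reliable_blocks(list(t1, t2), asm, 200)
  expect_equal(rb$blocks[, c("start", "end")], data.frame(start = 50, end = 100))
  expect_error(reliable_blocks(list(t1), asm, 200), "2 distinct")
  t1b <- t1; t1b$technology <- "b"
  expect_error(reliable_blocks(list(t1b, t2), asm, 200), "2 distinct")

  # three technologies spanning everything: one block = scaffold
  t3 <- structure(list(technology = "c",
                       intervals = list(s1 = IRanges::IRanges(1, 200))),
                  class = "support_track")
  full <- lapply(c("a", "b", "c"), function(tech)
    structure(list(technology = tech, intervals = list(s1 = IRanges::IRanges(1, 200))),
              class = "support_track"))
  rb3 <- reliable_blocks(full, asm, 200)
  expect_equal(rb3$blocks[, c("start", "end")], data.frame(start = 0, end = 200))
  expect_equal(rb3$percent_covered, 100)
})

test_that("reliable blocks equal a brute-force per-base technology count", {
  set.seed(17)
  for (i in 1:15) {
    len <- sample(50:200, 1)
    n_tech <- sample(2:4, 1)
    tracks <- lapply(seq_len(n_tech), function(t) {
      n_iv <- sample(0:4, 1)
      iv <- if (n_iv == 0) IRanges::IRanges() else {
        s <- sample(1:len, n_iv, replace = TRUE)
        e <- pmin(len, s + sample(5:60, n_iv, replace = TRUE))
        IRanges::reduce(IRanges::IRanges(s, e))
      }
      structure(list(technology = paste0("t", t), intervals = list(s1 = iv)),
                class = "support_track")
    })
    asm <- Assembly(c(s1 = strrep("A", len)))
    rb <- reliable_blocks(tracks, asm, len)
    # brute force per-base count
    cnt <- rep(0L, len)
    for (tr in tracks) {
      iv <- tr$intervals$s1
      covered <- rep(FALSE, len)
      for (j in seq_along(iv))
        covered[IRanges::start(iv)[j]:IRanges::end(iv)[j]] <- TRUE
      cnt <- cnt + covered
    }
    want <- which(cnt >= 2)
    got <- unlist(lapply(seq_len(nrow(rb$blocks)), function(j)
      (rb$blocks$start[j] + 1):rb$blocks$end[j]))
    if (is.null(got)) got <- integer(0)
    expect_equal(sort(got), want)
  }
})

test_that("duplication candidates carry coverage and self-alignment evidence", {
  trk <- manual_track(list(s1 = c(rep(30, 50), rep(15, 10), rep(30, 40)),
                           s2 = rep(15, 10)))
  trk$mean <- 29; trk$sd <- 4
  selfpaf <- rbind(
    paf_row("s1", "s2", 0, 10000, 10000, qlen = 100000),
    paf_row("s2", "s1", 50000, 60000, 100000, qlen = 10000))
  selfpaf$qstart <- c(50000, 0); selfpaf$qend <- c(60000, 10000)
  dec <- decompose_scaffolds(Assembly(c(s1 = strrep("A", 100000),
                                        s2 = strrep("C", 10000))))
  dc <- dup_candidates(trk, selfpaf, dec, read_length_estimate = 15000)
  expect_equal(nrow(dc$heterotype), 2)
  expect_true(all(grepl("half_coverage", dc$heterotype$evidence)))
  # the 10-kb copy at the s2 contig end is read-length scale: homotype too
  expect_gte(nrow(dc$homotype), 1)

  # clean assembly: no candidates
  trk2 <- manual_track(list(s1 = rep(30, 100)))
  trk2$sd <- 1
  dc2 <- dup_candidates(trk2, selfpaf[0, ], dec, read_length_estimate = 15000)
  expect_equal(nrow(dc2$heterotype), 0)
  expect_equal(nrow(dc2$homotype), 0)
})

test_that("PAF files round-trip through read_paf", {
  p <- withr::local_tempfile(fileext = ".paf")
  df <- rbind(paf_row("q1", "t1", 0, 100, 1000), paf_row("q2", "t1", 50, 200, 1000))
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  back <- read_paf(p)
  expect_equal(back$tstart, df$tstart)
  expect_equal(back$target, df$target)
})
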
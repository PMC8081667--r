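test_that("QV follows the k-mer survival formula on planted substitutions", {
  fx <- perfect_mb_fixture()

  # perfect assembly vs error-free reads: nothing missing, QV capped
  qv0 <- estimate_qv(fx$assembly_counts, fx$read_counts)
  expect_equal(qv0$B_absent, 0)
  expect_true(qv0$capped)
  expect_equal(qv0$qv, 99.9)

  # one isolated substitution in 1 Mb at k=21 kills exactly 21 instances
  g <- fx$genome
  s <- g[[1]]
  pos <- 500000L
  old <- substr(s, pos, pos)
  substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  qv1 <- estimate_qv(count_kmers(s, 21, "assembly"), fx$read_counts)
  expect_equal(qv1$B_absent, 21)
  expect_equal(qv1$error_rate, 1 - (1 - 21 / qv1$T_instances)^(1 / 21))
  expect_equal(qv1$qv, 60.0, tolerance = 0.1 / 60)

  # 100 isolated substitutions: one error per 10 kb is Q40
  inj <- inject_defects(Assembly(fx$genome),
                        defect_spec(substitutions = 1e-4, sub_spacing = 25),
                        seed = 7)
  expect_equal(sum(inj$truth$type == "substitution"), 100)
  qv2 <- estimate_qv(count_kmers(inj$assembly, 21, "assembly"), fx$read_counts)
  expect_equal(qv2$qv, 40.0, tolerance = 0.1 / 40)
})

test_that("adding substitutions never increases QV (monotonicity)", {
  fx <- perfect_mb_fixture()
  rates <- c(2e-5, 1e-4, 5e-4)
  qvs <- vapply(seq_along(rates), function(i) {
    inj <- inject_defects(Assembly(fx$genome),
                          defect_spec(substitutions = rates[i], sub_spacing = 25),
                          seed = 100 + i)
    estimate_qv(count_kmers(inj$assembly, 21, "assembly"), fx$read_counts)$qv
  }, numeric(1))
  expect_true(all(diff(qvs) < 0))
  expect_lt(qvs[1], 99.9)
})

test_that("k-mer completeness counts reliable read k-mers found in the assembly", {
  fx <- perfect_mb_fixture()
  thr <- error_threshold(fx$hist)
  expect_equal(kmer_completeness(fx$read_counts, fx$assembly_counts, thr)$completeness, 100)

  # empty assembly: 0%
  empty <- suppressWarnings(count_kmers("", 21, "assembly"))
  expect_equal(kmer_completeness(fx$read_counts, empty, thr)$completeness, 0)

  # assembly missing one unique 10-kb segment of a unique 1-Mb genome:
  # ~(999980 - 10020) / 999980 = 99.0% by direct counting
  g <- fx$genome[[1]]
  cut <- paste0(substr(g, 1, 600000), substring(g, 610001))
  ce <- kmer_completeness(fx$read_counts, count_kmers(cut, 21, "assembly"), thr)
  expect_equal(ce$completeness, 100 * (999980 - 10020) / 999980, tolerance = 2e-4)

  expect_error(kmer_completeness(fx$assembly_counts, fx$assembly_counts, 100),
               "no reliable")
})

test_that("duplication rate counts assembly instances above read-implied copy number", {
  fx <- perfect_mb_fixture()
  prof <- fit_genome_profile(fx$hist, k = 21)

  expect_equal(duplication_rate(fx$assembly_counts, fx$read_counts, prof)$duplication_rate, 0)

  # a unique 50-kb segment present twice in a 1.05-Mb assembly: 4.8%
  g <- fx$genome[[1]]
  seg <- substr(g, 100001, 150000)
  dup_asm <- c(chr = g, extra = seg)
  dr <- duplication_rate(count_kmers(dup_asm, 21, "assembly"), fx$read_counts, prof)
  expect_equal(dr$duplication_rate, 100 * 50020 / 1049980, tolerance = 2e-3)

  # whole genome present twice: 50%
  dr2 <- duplication_rate(count_kmers(c(a = g, b = g), 21, "assembly"),
                          fx$read_counts, prof)
  expect_equal(dr2$duplication_rate, 50)

  # excess positions land on the planted duplicate
  dr3 <- duplication_rate(count_kmers(dup_asm, 21, "assembly"), fx$read_counts,
                          prof, assembly = Assembly(dup_asm))
  expect_true(!is.null(dr3$positions))
  expect_true(all(c("chr", "extra") %in% dr3$positions$chrom))
})

test_that("hap-mer extraction applies count filters, exclusivity and child filter", {
  a <- count_kmers(paste(rep(c("ACG", "TTT"), c(5, 4)), collapse = "NN"), 3, "A")
  b <- count_kmers(paste(rep(c("ACG", "GGA"), c(5, 6)), collapse = "NN"), 3, "B")
  hm <- extract_hapmers(a, b, low_cut = 2, high_cut = 100)
  expect_equal(names(kmer_strings(hm$maternal)), "AAA") # TTT canonicalizes to AAA
  expect_equal(names(kmer_strings(hm$paternal)), "GGA")

  # child filter: child lacking GGA empties the paternal set
  child <- count_kmers("TTTT", 3, "child")
  hm2 <- extract_hapmers(a, b, child, low_cut = 2, high_cut = 100)
  expect_equal(hm2$n_pat, 0)
  expect_equal(names(kmer_strings(hm2$maternal)), "AAA")

  # low_cut excludes error-like counts
  a3 <- count_kmers(paste(rep(c("ACG", "TTT"), c(5, 1)), collapse = "NN"), 3, "A")
  hm3 <- tryCatch(extract_hapmers(a3, b, low_cut = 2, high_cut = 100),
                  error = function(e) e)
  if (inherits(hm3, "hapmer_sets")) expect_equal(hm3$n_mat, 0)
  else expect_match(conditionMessage(hm3), "indistinguishable")

  expect_error(extract_hapmers(a, a, low_cut = 2, high_cut = 100), "indistinguishable")
})

test_that("read binning normalizes marker hits by haplotype set size", {
  # directly exercise the normalization rule with synthetic marker sets
  mat_seq <- rand_dna(60, seed = 120)
  pat_seq <- rand_dna(80, seed = 121)
  mc <- count_kmers(mat_seq, 21, "mat")
  pc <- count_kmers(pat_seq, 21, "pat")
  hm <- structure(list(maternal = mc, paternal = pc,
                       n_mat = length(mc$code), n_pat = length(pc$code),
                       filters = NULL), class = "hapmer_sets")
  bn <- bin_reads(c(r_mat = mat_seq, r_pat = pat_seq, r_none = strrep("A", 40)), hm)
  a <- bn$assignments
  expect_equal(a$class[a$read == "r_mat"], "maternal")
  expect_equal(a$class[a$read == "r_pat"], "paternal")
  expect_equal(a$class[a$read == "r_none"], "unassigned")

  # normalization: 4 hits of a 10-marker set beat 6 hits of a 30-marker set
  expect_gt(4 / 10, 6 / 30)
})

test_that("phase block scan applies the switch tolerance rules", {
  k <- 21L
  mk_markers <- function(parents, spacing = 100L) {
    # build a synthetic scaffold carrying planted marker k-mers
    data.frame(pos = seq(0L, by = spacing, length.out = length(parents)),
               parent = parents)
  }
  scan <- function(parents, max_run = 10, max_span = 20000) {
    m <- mk_markers(parents)
    asmqc:::scan_blocks_one(m$pos, m$parent, max_run, max_span, k)
  }
  # uniform markers: one block, no switches
  r1 <- scan(rep("maternal", 4))
  expect_equal(nrow(r1$blocks), 1)
  expect_equal(r1$switches, 0)

  # M M P M M: one maternal block, one switch error
  r2 <- scan(c("maternal", "maternal", "paternal", "maternal", "maternal"))
  expect_equal(nrow(r2$blocks), 1)
  expect_equal(r2$blocks$parent, "maternal")
  expect_equal(r2$switches, 1)

  # 50 M then 50 P: the long opposite run terminates the block
  r3 <- scan(rep(c("maternal", "paternal"), each = 50))
  expect_equal(nrow(r3$blocks), 2)
  expect_equal(r3$blocks$parent, c("maternal", "paternal"))
  expect_equal(r3$switches, 0)

  # span rule: an opposite run spread over > max_span terminates the block
  # even though it is short in marker count
  m <- data.frame(pos = c(0, 100, 200, 30000, 61000, 61100, 61200),
                  parent = c(rep("maternal", 3), rep("paternal", 2), rep("maternal", 2)))
  r4 <- asmqc:::scan_blocks_one(m$pos, m$parent, 10, 20000, k)
  expect_equal(nrow(r4$blocks), 2)
  expect_equal(r4$blocks$parent[1], "maternal")
  expect_equal(r4$blocks$n_markers[1], 3) # block 1 carries no paternal markers
})

test_that("phase report on the true haplotype assembly is near perfect", {
  fx <- trio_fixture()
  pr <- phase_blocks(Assembly(fx$dip$maternal, role = "maternal"), fx$hapmers, 5e5)
  expect_gte(pr$precision[["maternal"]], 99.9)
  expect_equal(pr$switch_errors, 0)
  expect_gt(as.numeric(pr$phase_block_ng50), 4e5)
  expect_gte(pr$recall[["maternal"]], 97)
})

test_that("trio binning sends marker-bearing child reads to the right parent", {
  fx <- trio_fixture()
  bn <- bin_reads(fx$child$reads, fx$hapmers)
  tt <- merge(bn$assignments, fx$child$truth, by = "read")
  mk <- tt[tt$hits_mat + tt$hits_pat >= 5, ]
  truth_class <- ifelse(mk$hap == "hap_mat", "maternal", "paternal")
  expect_gte(mean(truth_class == mk$class), 0.99)
})
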
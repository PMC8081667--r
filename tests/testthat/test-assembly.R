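test_that("scaffold decomposition identifies contigs and gaps by N-run length", {
  d <- decompose_scaffolds(Assembly(c(s = paste0("AAAA", strrep("N", 100), "CCCC"))), 10)
  expect_equal(nrow(d$contigs), 2)
  expect_equal(d$contigs$length, c(4, 4))
  expect_equal(nrow(d$gaps), 1)
  expect_equal(d$gaps$length, 100)

  # run below threshold is part of the contig
  d2 <- decompose_scaffolds(Assembly(c(s = "AAAANNNNNCCCC")), 10)
  expect_equal(nrow(d2$contigs), 1)
  expect_equal(d2$contigs$length, 13)
  expect_equal(nrow(d2$gaps), 0)

  # terminal N runs of any length are reported but are not contigs
  d3 <- decompose_scaffolds(Assembly(c(s = "NNNNNNNNNNACGT")), 10)
  expect_equal(d3$contigs$length, 4)
  expect_true(d3$gaps$terminal)
  d4 <- decompose_scaffolds(Assembly(c(s = "NNNACGTACGT")), 10)
  expect_equal(d4$contigs$length, 8)
  expect_equal(d4$gaps$length, 3)
})

test_that("contigs and gaps tile each scaffold exactly (reconstruction property)", {
  set.seed(31)
  for (i in 1:20) {
    n_seg <- sample(1:6, 1)
    parts <- unlist(lapply(seq_len(n_seg), function(j)
      c(rand_dna(sample(5:200, 1)), strrep("N", sample(c(1:4, 10:120), 1)))))
    s <- paste(parts[-length(parts)], collapse = "")
    asm <- Assembly(c(s = s))
    gm <- sample(c(5L, 10L, 50L), 1)
    d <- decompose_scaffolds(asm, gm)
    iv <- rbind(d$contigs[, c("start", "end")], d$gaps[, c("start", "end")])
    iv <- iv[order(iv$start), ]
    # intervals tile [0, len) without overlap
    expect_equal(iv$start[1], 0)
    expect_equal(iv$end[nrow(iv)], nchar(s))
    if (nrow(iv) > 1) expect_equal(iv$start[-1], iv$end[-nrow(iv)])
    # reconstruct byte-identically from the intervals
    rebuilt <- paste(substring(s, iv$start + 1, iv$end), collapse = "")
    expect_identical(rebuilt, s)
  }
})

test_that("raising gap_min_run never increases the contig count", {
  set.seed(77)
  for (i in 1:10) {
    parts <- unlist(lapply(1:5, function(j)
      c(rand_dna(sample(10:100, 1)), strrep("N", sample(1:60, 1)))))
    asm <- Assembly(c(s = paste(parts, collapse = "")))
    counts <- vapply(c(1L, 5L, 10L, 25L, 60L, 100L), function(g)
      nrow(decompose_scaffolds(asm, g)$contigs), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("assembly loading validates input and survives a FASTA round trip", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(scafA = paste0(rand_dna(500, seed = 2), strrep("N", 50), rand_dna(300)),
            scafB = rand_dna(200))
  write_fasta(seqs, fa)
  la <- load_assembly(fa, gap_min_run = 10)
  expect_identical(la$assembly$sequences, seqs)
  expect_equal(nrow(la$decomposition$gaps), 1)

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(load_assembly(empty))
  expect_error(Assembly(c(a = "ACGT", a = "GGGG")), "duplicate")
  expect_error(Assembly(c(a = "ACGT!!")), "illegal")
  # non-ACGTN IUPAC codes become N with a message
  expect_message(a <- Assembly(c(s = "ACGTRYACGT")), "ambiguity")
  expect_identical(a$sequences[["s"]], "ACGTNNACGT")
})

test_that("ngx matches the cumulative-sum oracle and handles the sentinel", {
  expect_equal(as.numeric(ngx(c(50, 30, 20), 100, 0.5)), 50)
  expect_equal(as.numeric(ngx(c(50, 30, 20), 100, 0.9)), 20)
  expect_equal(as.numeric(ngx(c(50, 30, 20), 120, 0.5)), 30)
  # not reached: sentinel 0 with flag, not a fabricated value
  nr <- ngx(c(10, 10), 1000, 0.5)
  expect_equal(as.numeric(nr), 0)
  expect_false(attr(nr, "reached"))

  set.seed(99)
  for (i in 1:200) {
    lens <- sample(1:500, sample(1:40, 1), replace = TRUE)
    ref <- sample(1:2000, 1)
    fr <- runif(1, 0.05, 1)
    expect_equal(as.numeric(ngx(lens, ref, fr)), ngx_oracle(lens, ref, fr))
  }
})

test_that("NG50 equals N50 when the reference is the assembly length", {
  set.seed(5)
  for (i in 1:20) {
    lens <- sample(1:1000, sample(2:30, 1), replace = TRUE)
    expect_equal(as.numeric(ngx(lens, sum(lens), 0.5)),
                 ngx_oracle(lens, sum(lens), 0.5))
  }
})

test_that("continuity stats report NG50s, gap counts and gaps per Gb", {
  # a perfect single-scaffold genome
  g <- rand_dna(10000, seed = 8)
  asm <- Assembly(c(chr1 = g))
  st <- continuity_stats(asm, decompose_scaffolds(asm), genome_size = 10000)
  expect_equal(as.numeric(st$contig_ng50), 10000)
  expect_equal(as.numeric(st$scaffold_ng50), 10000)
  expect_equal(st$n_gaps, 0)

  # gaps per Gb formula on a 3-scaffold assembly with 2 interior gaps
  seqs <- c(s1 = paste0(rand_dna(4000), strrep("N", 100), rand_dna(4000)),
            s2 = paste0(rand_dna(3000), strrep("N", 100), rand_dna(1000)),
            s3 = rand_dna(2000))
  asm2 <- Assembly(seqs)
  st2 <- continuity_stats(asm2, decompose_scaffolds(asm2), genome_size = 15000)
  expect_equal(st2$n_gaps, 2)
  expect_equal(st2$gaps_per_gb, 2 / (st2$assembly_length / 1e9))
  expect_lte(as.numeric(st2$contig_ng50), as.numeric(st2$scaffold_ng50))

  # a 40-Mb assembly carrying 13 gaps has the same gap density as a 1-Gb
  # assembly with 325 gaps; the reported rate should come out at 325/Gb
  piece <- strrep("ACGTACGTAC", 285705) # 2,857,050 bp
  seqs3 <- paste(rep(piece, 14), collapse = strrep("N", 100))
  asm3 <- Assembly(c(chr = seqs3))
  st3 <- continuity_stats(asm3, decompose_scaffolds(asm3), genome_size = 40e6)
  expect_equal(st3$n_gaps, 13)
  expect_equal(st3$gaps_per_gb, 325, tolerance = 1e-4)
})

test_that("assigned fraction counts chromosome-labelled bases", {
  asm <- Assembly(c(c1 = rand_dna(9000, seed = 3), un = rand_dna(1000)))
  ca <- assigned_fraction(asm, data.frame(scaffold = "c1", chromosome = "1"))
  expect_equal(ca$assigned_fraction, 90)
  expect_equal(assigned_fraction(asm, data.frame(scaffold = character(0),
                                                 chromosome = character(0)))$assigned_fraction, 0)
  all_tab <- data.frame(scaffold = c("c1", "un"), chromosome = c("1", "2"))
  expect_equal(assigned_fraction(asm, all_tab)$assigned_fraction, 100)
  expect_error(assigned_fraction(asm, data.frame(scaffold = "nope", chromosome = "1")),
               "unknown")
})

test_that("telomere scan flags long motif arrays at scaffold ends only", {
  arr <- strrep("TTAGGG", 84) # 504 bp
  asm <- Assembly(c(s = paste0(rand_dna(2000, seed = 12), arr)))
  ts <- telomere_end_scan(asm)
  right <- ts[ts$side == "right", ]
  expect_true(right$telomere_present)
  expect_equal(right$array_length, 504)
  expect_false(ts[ts$side == "left", "telomere_present"])

  # plain random ends and sub-minimum arrays are absent
  ts2 <- telomere_end_scan(Assembly(c(s = rand_dna(3000, seed = 13))))
  expect_false(any(ts2$telomere_present))
  ts3 <- telomere_end_scan(Assembly(c(s = paste0(rand_dna(500, seed = 14),
                                                 strrep("TTAGGG", 3)))))
  expect_false(any(ts3$telomere_present))

  # reverse-strand array at the left end
  ts4 <- telomere_end_scan(Assembly(c(s = paste0(strrep("CCCTAA", 40),
                                                 rand_dna(1500, seed = 15)))))
  expect_true(ts4[ts4$side == "left", "telomere_present"])
})

test_that("decomposition BED export writes headers and 0-based intervals", {
  dir <- withr::local_tempdir()
  asm <- Assembly(c(s = paste0(rand_dna(100, seed = 4), strrep("N", 20), rand_dna(50))))
  paths <- write_decomposition_bed(decompose_scaffolds(asm), dir)
  gaps <- readLines(file.path(dir, "assembly.gaps.bed"))
  expect_match(gaps[1], "^# asmqc")
  expect_equal(strsplit(gaps[2], "\t")[[1]][1:3], c("s", "100", "120"))
})
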
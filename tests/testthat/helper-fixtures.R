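# Shared fixtures. Expensive simulations are memoised per test run so that
# several test files can reuse the same genome/read set.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 1-Mb homozygous genome + error-free 30x long reads + k=21 count sets
perfect_mb_fixture <- function() {
  cached("perfect_mb", {
    spec <- sim_spec(genome_size = 1e6, heterozygosity = 0, coverage = 30, seed = 42)
    dip <- simulate_diploid(spec)
    rd <- simulate_reads(dip$maternal, spec)
    rc <- count_kmers(rd$reads, 21, "reads")
    ac <- count_kmers(dip$maternal, 21, "assembly")
    list(spec = spec, genome = dip$maternal, reads = rd, read_counts = rc,
         assembly_counts = ac, hist = kmer_histogram(rc))
  })
}

# small diploid trio: maternal/paternal haplotypes at 1% heterozygosity with
# per-parent and child read sets and hap-mer sets
trio_fixture <- function() {
  cached("trio", {
    spec <- sim_spec(genome_size = 5e5, heterozygosity = 1.0, coverage = 30, seed = 5)
    dip <- simulate_diploid(spec)
    pa <- simulate_reads(dip$maternal, sim_spec(genome_size = 5e5, coverage = 30, seed = 11))
    pb <- simulate_reads(dip$paternal, sim_spec(genome_size = 5e5, coverage = 30, seed = 12))
    child <- simulate_reads(c(dip$maternal, dip$paternal),
                            sim_spec(genome_size = 5e5, coverage = 30, seed = 13,
                                     read_mean = 10000, read_sd = 2000))
    ca <- count_kmers(pa$reads, 21, "parentA")
    cb <- count_kmers(pb$reads, 21, "parentB")
    cc <- count_kmers(child$reads, 21, "child")
    list(dip = dip, child = child,
         hapmers = extract_hapmers(ca, cb, cc))
  })
}

# deterministic random DNA string
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force NGx oracle: walk lengths in descending order, return the first
# length at which the running total reaches fraction * reference
ngx_oracle <- function(lengths, reference, fraction = 0.5) {
  lengths <- sort(lengths, decreasing = TRUE)
  total <- 0
  for (l in lengths) {
    total <- total + l
    if (total >= fraction * reference) return(l)
  }
  0
}

# coverage track built directly from per-window depths (for detector tests)
manual_track <- function(depth_list, window = 1000L) {
  lens <- vapply(depth_list, function(d) length(d) * window, numeric(1))
  all_d <- unlist(depth_list, use.names = FALSE)
  structure(list(technology = "long-read", window = as.integer(window),
                 depth = depth_list, scaffold_length = lens,
                 mean = mean(all_d), sd = stats::sd(all_d),
                 robust_mean = stats::median(all_d),
                 robust_sd = 1.4826 * stats::mad(all_d, constant = 1)),
            class = "coverage_track")
}

# minimal PAF row constructor
paf_row <- function(query, target, tstart, tend, tlen, qlen = tend - tstart,
                    nmatch = tend - tstart, alen = tend - tstart) {
  data.frame(query = query, qlen = qlen, qstart = 0L, qend = qlen,
             strand = "+", target = target, tlen = tlen,
             tstart = tstart, tend = tend, nmatch = nmatch, alen = alen,
             mapq = 60L)
}
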
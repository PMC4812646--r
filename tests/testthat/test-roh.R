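# genotype string helpers: 0/2 hom, 1 het, NA missing
roh_ds <- function(g, pos = NULL) {
  g <- as.integer(g)
  if (is.null(pos)) pos <- seq_along(g) * 20000  # 20 kb spacing
  make_ds(matrix(g, 1), position_bp = pos)
}

test_that("clean homozygous runs are called; short runs are not", {
  # 60 homozygous SNPs spanning 1.2 Mb -> one ROH of 60 SNPs
  ds <- roh_ds(rep(0, 60))
  segs <- detect_roh(ds)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$n_snps, 60L)
  expect_identical(segs$start_bp, 20000)
  expect_identical(segs$end_bp, 60 * 20000)
  # 49 homozygous SNPs spanning 2 Mb fail min_snps = 50
  ds49 <- roh_ds(rep(2, 49), pos = seq_len(49) * 42000)
  expect_identical(nrow(detect_roh(ds49)), 0L)
  # 60 SNPs but only 900 kb fails min_length_kb
  ds_short <- roh_ds(rep(0, 60), pos = seq_len(60) * 15000)
  expect_identical(nrow(detect_roh(ds_short)), 0L)
})

test_that("window tolerances allow one het and one missing per window", {
  g <- rep(0, 80); g[40] <- 1; g[10] <- NA
  segs <- detect_roh(roh_ds(g))
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$n_het, 1L)
  expect_identical(segs$n_missing, 1L)
  # two hets inside one 50-SNP window break the run
  g2 <- rep(0, 80); g2[40] <- 1; g2[45] <- 1
  expect_identical(nrow(detect_roh(roh_ds(g2))), 0L)
})

test_that("detect_roh equals the brute-force oracle on random strings", {
  withr::with_seed(42, {
    for (rep in 1:60) {
      n <- sample(c(80, 150, 300), 1)
      g <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                  prob = c(0.44, 0.06, 0.44, 0.06))
      pos <- sort(sample.int(n * 30000, n))
      ds <- roh_ds(g, pos = pos)
      got <- detect_roh(ds, min_snps = 50, min_length_kb = 100,
                        window = 25)
      ora <- roh_oracle(g, pos, min_snps = 50, min_length_kb = 100,
                        window = 25)
      if (is.null(ora)) {
        expect_identical(nrow(got), 0L)
      } else {
        expect_identical(got$start_snp_index, ora$start_snp_index)
        expect_identical(got$end_snp_index, ora$end_snp_index)
      }
    }
  })
})

test_that("raising thresholds is monotone and unsorted input errors", {
  withr::with_seed(8, {
    g <- sample(c(0L, 1L, 2L), 400, replace = TRUE,
                prob = c(0.48, 0.04, 0.48))
    ds <- roh_ds(g)
    base <- detect_roh(ds, min_snps = 50, min_length_kb = 100)
    stricter <- detect_roh(ds, min_snps = 80, min_length_kb = 100)
    longer <- detect_roh(ds, min_snps = 50, min_length_kb = 2000)
    key <- function(x) paste(x$start_snp_index, x$end_snp_index)
    expect_true(all(key(stricter) %in% key(base)))
    expect_true(all(key(longer) %in% key(base)))
  })
  expect_error(detect_roh(roh_ds(rep(0, 60), pos = c(5, 1:59)),
                          min_snps = 50),
               "strictly increasing|unsorted")
  expect_error(detect_roh(roh_ds(rep(0, 60)), window = 60), "min_snps")
})

test_that("f_roh scales segment totals by genome length", {
  segs <- data.frame(sample_id = c("a", "a", "b"),
                     length_bp = c(1e6, 3e6, 2808525 * 1000))
  v <- f_roh(segs, sample_ids = c("a", "b", "c"))
  expect_equal(unname(v[["a"]]), 4e6 / 2808525e3)
  expect_equal(unname(v[["b"]]), 1.0)        # whole genome in one ROH
  expect_equal(unname(v[["c"]]), 0)          # no segments
  segs$length_bp[3] <- 280852.5 * 1000
  expect_equal(unname(f_roh(segs)[["b"]]), 0.1)
  expect_error(f_roh(data.frame(sample_id = "x", length_bp = 3e12)),
               "exceeds")
})

test_that("f_snp is the homozygous fraction of non-missing calls", {
  ds <- make_ds(rbind(c(0L, 2L, 0L, 1L, NA),   # 3 hom, 1 het, 1 missing
                      rep(2L, 5),
                      c(1L, 1L, 0L, 0L, NA)))
  v <- f_snp(ds)
  expect_equal(unname(as.numeric(v)), c(0.75, 1.0, 0.5))
  expect_equal(1 - unname(v[["S003"]]),
               mean(ds$calls[3, ] == 1L, na.rm = TRUE))
})

test_that("summarize_roh partitions at 5 Mb and re-aggregates correctly", {
  segs <- data.frame(
    sample_id = c("a", "a", "b"), chromosome = "1",
    start_bp = c(1, 2e6, 1), end_bp = c(1e6, 5e6, 5e6 + 1),
    n_snps = 50L, length_bp = c(1e6, 3e6 + 1, 5e6 + 1),
    n_het = 0L, n_missing = 0L)
  s <- summarize_roh(segs)
  a <- s$per_sample[s$per_sample$sample_id == "a", ]
  expect_identical(a$n_roh, 2L)
  expect_equal(a$mean_length_bp, mean(c(1e6, 3e6 + 1)))
  expect_identical(a$n_short, 2L)
  # exactly 5 Mb is long (strict "< 5 Mb" = short)
  segs5 <- segs; segs5$length_bp[1] <- 5e6
  expect_identical(summarize_roh(segs5)$per_sample$n_short[1], 1L)
  # totals equal an independent re-aggregation
  for (id in unique(segs$sample_id))
    expect_equal(
      s$per_sample$total_length_bp[s$per_sample$sample_id == id],
      sum(segs$length_bp[segs$sample_id == id]))
  expect_warning(summarize_roh(segs[0, ]), "no ROH")
})

test_that("shared_roh groups exact matches within and between", {
  segs <- data.frame(
    sample_id = c("a1", "a2", "b1", "a1", "b2"), chromosome = "1",
    start_bp = c(100, 100, 100, 900, 5000),
    end_bp = c(500, 500, 500, 980, 5400),
    n_snps = 50L, length_bp = 0, n_het = 0L, n_missing = 0L)
  pops <- c(a1 = "LA", a2 = "LA", b1 = "LW", a1 = "LA", b2 = "LW")
  pops <- pops[!duplicated(names(pops))]
  w <- shared_roh(segs, pops, mode = "within", match = "exact")
  expect_identical(nrow(w$regions), 1L)        # a1+a2 share 100-500
  expect_identical(w$regions$n_LA, 2L)
  expect_equal(w$regions$frac_LA, 1.0)
  b <- shared_roh(segs, pops, mode = "between", match = "exact")
  expect_identical(nrow(b$regions), 1L)        # a1/a2 with b1
  expect_identical(b$regions$n_LW, 1L)
  expect_identical(b$per_chromosome$n_regions, 1)
  expect_error(shared_roh(segs, pops[-1], mode = "between"),
               "unknown population")
})

test_that("shared_roh overlap mode clusters by minimum overlap", {
  segs <- data.frame(
    sample_id = c("a1", "b1", "b2"), chromosome = "2",
    start_bp = c(1e6, 1.4e6, 9e6), end_bp = c(2e6, 2.4e6, 9.9e6),
    n_snps = 50L, length_bp = 0, n_het = 0L, n_missing = 0L)
  pops <- c(a1 = "LA", b1 = "LW", b2 = "LW")
  b <- shared_roh(segs, pops, mode = "between", match = "overlap",
                  min_overlap_bp = 5e5)
  expect_identical(nrow(b$regions), 1L)
  expect_identical(b$regions$start_bp, 1e6)
  expect_identical(b$regions$end_bp, 2.4e6)
  # overlap below threshold separates the clusters
  none <- shared_roh(segs, pops, mode = "between", match = "overlap",
                     min_overlap_bp = 7e5)
  expect_identical(nrow(none$regions), 0L)
})

test_that("consensus_regions equals a direct per-SNP incidence scan", {
  m <- 100
  ds <- make_ds(matrix(0L, 4, m))
  segs <- data.frame(
    sample_id = c("S001", "S002", "S003"), chromosome = "1",
    start_bp = c(10, 20, 30) * 1000, end_bp = c(60, 70, 80) * 1000,
    n_snps = 0L, length_bp = 0, n_het = 0L, n_missing = 0L)
  cr <- consensus_regions(segs, ds, incidence_min = 0.5)
  # direct scan: SNP k (pos 1000k) covered by >= 2 of 4 samples
  pos <- ds$snps$position_bp
  cov <- sapply(pos, function(p)
    sum(p >= segs$start_bp & p <= segs$end_bp))
  want <- range(pos[cov / 4 >= 0.5])
  expect_identical(nrow(cr), 1L)
  expect_equal(c(cr$start_bp, cr$end_bp), want)
  expect_equal(cr$mean_incidence, mean(cov[cov / 4 >= 0.5] / 4))
  # impossible threshold
  expect_identical(nrow(consensus_regions(segs, ds, incidence_min = 1.01)),
                   0L)
  # unanimous identical ROH returned as one region at any threshold
  segs2 <- data.frame(sample_id = sprintf("S%03d", 1:4), chromosome = "1",
                      start_bp = 10000, end_bp = 50000, n_snps = 0L,
                      length_bp = 0, n_het = 0L, n_missing = 0L)
  cr2 <- consensus_regions(segs2, ds, incidence_min = 0.5)
  expect_equal(c(cr2$start_bp, cr2$end_bp), c(10000, 50000))
  expect_equal(cr2$mean_incidence, 1.0)
})

test_that("segment output is deterministic across runs", {
  ds <- random_ds(77, n = 6, m = 600, missing_rate = 0.02)
  a <- detect_roh(ds, min_snps = 20, min_length_kb = 10, window = 10)
  b <- detect_roh(ds, min_snps = 20, min_length_kb = 10, window = 10)
  expect_identical(a, b)
})

test_that("F_ROH correlates with true autozygosity on dense simulated maps", {
  cfg <- sim_config(seed = 31, n_generations = 12, N = 25,
                    n_chromosomes = 4, n_snps_per_chrom = 1500)
  res <- simulate_population(cfg)
  segs <- detect_roh(res$dataset, min_snps = 50, min_length_kb = 1000)
  genome_kb <- sum(res$truth$map$chrom_length_M) * 1e8 / 1000
  froh <- f_roh(segs, genome_length_kb = genome_kb,
                sample_ids = res$dataset$samples$sample_id)
  tru <- true_autozygosity_all(res$truth)
  expect_gt(cor(as.numeric(froh), tru[names(froh)]), 0.9)
})
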
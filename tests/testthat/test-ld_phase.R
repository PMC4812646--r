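test_that("EM equals direct counting when phase is fully observed", {
  # no double heterozygotes: haplotypes AB=40, Ab=10, aB=10, ab=40 laid out
  # as unambiguous genotypes
  tab <- matrix(0, 3, 3)
  tab[3, 3] <- 20   # AABB  -> 40 AB
  tab[3, 1] <- 5    # AAbb  -> 10 Ab
  tab[1, 3] <- 5    # aaBB  -> 10 aB
  tab[1, 1] <- 20   # aabb  -> 40 ab
  res <- em_hap_freqs(tab)
  expect_equal(unname(res$hap), c(0.4, 0.1, 0.1, 0.4), tolerance = 1e-9)
  expect_equal(res$D, 0.15, tolerance = 1e-9)
  expect_equal(res$r2, 0.36, tolerance = 1e-9)
  # equilibrium frequencies give D = 0, r2 = 0
  tab2 <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3)
  res2 <- em_hap_freqs(tab2)
  expect_equal(res2$D, 0, tolerance = 1e-9)
  expect_equal(res2$r2, 0, tolerance = 1e-9)
})

test_that("symmetric all-double-heterozygote table resolves to D >= 0", {
  tab <- matrix(0, 3, 3); tab[2, 2] <- 30
  res <- em_hap_freqs(tab)
  expect_gte(res$D, 0)
  expect_true(res$tie)
  expect_equal(res$r2, 1, tolerance = 1e-6)
})

test_that("EM log-likelihood reaches the 999-point grid maximum", {
  withr::with_seed(123, {
    for (rep in 1:150) {
      tab <- random_two_locus_table(50)
      if (sum(tab) == 0) next
      res <- em_hap_freqs(tab)
      expect_gte(res$loglik, em_grid_oracle(tab) - 1e-6)
      # Lewontin bound and r2 = r^2 identity
      if (!is.na(res$r_signed)) {
        expect_equal(res$r2, res$r_signed^2, tolerance = 1e-12)
        h <- res$hap
        pA <- h[1] + h[2]; pB <- h[1] + h[3]
        bound <- if (res$D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
                 else min(pA * pB, (1 - pA) * (1 - pB))
        expect_lte(abs(res$D), bound + 1e-9)
      }
    }
  })
})

test_that("pair_ld matches em_hap_freqs and excludes monomorphic pairs", {
  withr::with_seed(6, {
    ds <- random_ds(60, n = 50, m = 20, missing_rate = 0.05)
    ld <- pair_ld(ds, 1L, 2L)
    g1 <- ds$calls[, 1]; g2 <- ds$calls[, 2]
    use <- !is.na(g1) & !is.na(g2)
    tab <- table(factor(g1[use], 0:2), factor(g2[use], 0:2))
    ref <- em_hap_freqs(matrix(as.numeric(tab), 3, 3))
    expect_equal(ld$r_signed, ref$r_signed, tolerance = 1e-9)
    # monomorphic locus
    mono <- make_ds(cbind(rep(0L, 10), rbinom(10, 2, 0.5)))
    expect_true(is.na(pair_ld(mono, 1L, 2L)$r2))
    expect_error(pair_ld_many(random_ds(1, 5, 4, n_chrom = 2), 1L, 4L),
                 "same chromosome")
  })
})

test_that("ld_decay bin means follow the stated aggregation rules", {
  # two chromosomes, one pair each in bin 0, with known r2
  h <- c(rep(0L, 20), rep(2L, 20))
  calls <- cbind(h, h,                       # chrom 1: r2 = 1
                 h, c(h[2:40], 0L))          # chrom 2: r2 < 1
  ds <- make_ds(calls, chromosome = c("1", "1", "2", "2"),
                position_bp = c(1000, 51000, 1000, 51000))
  bins <- ld_decay(ds, max_dist_bp = 2e5, bin_bp = 1e5)
  r2_2 <- pair_ld(ds, 3L, 4L)$r2
  expect_equal(bins$mean_r2[1], mean(c(1, r2_2)))
  expect_identical(bins$n_pairs[1], 2L)
  expect_true(all(bins$n_pairs[-1] == 0L))
  # single-chromosome dataset: cross-chromosome mean equals pooled mean
  ds1 <- random_ds(5, n = 40, m = 30)
  b1 <- ld_decay(ds1, max_dist_bp = 1e7, bin_bp = 1e6)
  use <- b1$n_pairs > 0
  expect_equal(b1$mean_r2[use], b1$pooled_mean_r2[use])
  # unweighted mean semantics: 0.2 and 0.4 average to 0.3 whatever n_pairs
  expect_equal(mean(c(0.2, 0.4)), 0.3)
})

test_that("ld_decay matches a brute-force double loop on a small fixture", {
  ds <- random_ds(17, n = 30, m = 25)
  bins <- ld_decay(ds, max_dist_bp = 1e7, bin_bp = 1e6)
  pos <- ds$snps$position_bp
  # brute force: every pair, direct bin assignment
  acc <- vector("list", 10)
  for (i in 1:24) for (j in (i + 1):25) {
    d <- pos[j] - pos[i]
    if (d >= 1e7) next
    b <- floor(d / 1e6) + 1
    r2 <- pair_ld(ds, i, j)$r2
    if (!is.na(r2)) acc[[b]] <- c(acc[[b]], r2)
  }
  for (b in 1:10) {
    if (is.null(acc[[b]])) {
      expect_identical(bins$n_pairs[b], 0L)
    } else {
      expect_identical(bins$n_pairs[b], length(acc[[b]]))
      # batch and single-pair EM stop at the same 1e-10 frequency
      # tolerance but not the same iterate; compare to 1e-7
      expect_equal(bins$mean_r2[b], mean(acc[[b]]), tolerance = 1e-7)
    }
  }
})

test_that("adjacent and thinned LD follow the pair conventions", {
  ds <- random_ds(23, n = 40, m = 25, n_chrom = 1)
  adj <- adjacent_ld(ds)
  expect_identical(nrow(adj$pairs), 24L)
  # re-aggregation oracle from per-pair values
  inf <- adj$pairs[!is.na(adj$pairs$r2), ]
  expect_equal(adj$mean_r2, mean(inf$r2))
  expect_equal(adj$frac_gt_0.2, mean(inf$r2 > 0.2))
  expect_equal(adj$mean_distance_bp, mean(diff(ds$snps$position_bp)))
  # 3 SNPs -> 2 adjacent pairs; all-perfect-LD fractions are 1
  h <- c(rep(0L, 15), rep(2L, 15))
  perfect <- make_ds(cbind(h, h, h))
  padj <- adjacent_ld(perfect)
  expect_identical(padj$n_pairs, 2L)
  expect_equal(padj$frac_gt_0.2, 1.0)
  expect_equal(padj$frac_gt_0.3, 1.0)
  # thinning: keep_every 1 is identity; 25 SNPs at k=10 keep 3 -> 2 pairs
  t1 <- thinned_ld(ds, keep_every = 1)
  expect_equal(t1$mean_r2, adj$mean_r2)
  t10 <- thinned_ld(ds, keep_every = 10)
  expect_identical(t10$n_snps_kept, 3L)
  expect_identical(nrow(t10$pairs), 2L)
})

test_that("thinned maps show weaker adjacent LD on simulated data", {
  wins <- 0
  for (s in 1:10) {
    cfg <- sim_config(seed = 300 + s, n_generations = 10, N = 40,
                      n_chromosomes = 2, n_snps_per_chrom = 400)
    ds <- simulate_population(cfg)$dataset
    a <- adjacent_ld(ds)$mean_r2
    t <- thinned_ld(ds, keep_every = 10)$mean_r2
    wins <- wins + (t <= a)
  }
  expect_gte(wins, 9)
})

test_that("phase correlation is 1 for identical populations and flips sign
           with unharmonized alleles", {
  ds <- random_ds(11, n = 60, m = 40)
  pc <- phase_correlation(ds, ds, max_dist_bp = 1e7)
  ok <- !is.na(pc$bins$correlation)
  expect_true(any(ok))
  expect_true(all(abs(pc$bins$correlation[ok] - 1) < 1e-9))
  expect_equal(pc$headline, 1.0, tolerance = 1e-9)
  # A1/A2 swap at every second SNP in pop2: each adjacent pair has exactly
  # one flipped locus, so unharmonized signed r flips sign; harmonization
  # restores correlation 1
  ds2 <- ds
  flip <- seq(2, nrow(ds2$snps), by = 2)
  ds2$snps$allele_a1[flip] <- "G"; ds2$snps$allele_a2[flip] <- "A"
  ds2$calls[, flip] <- 2L - ds2$calls[, flip]
  pc2 <- phase_correlation(ds, ds2, max_dist_bp = 1e7)
  expect_equal(pc2$headline, 1.0, tolerance = 1e-9)
  # without harmonization the signed r of a one-flip pair is negated
  l1 <- pair_ld(ds, 1L, 2L)$r_signed
  l2 <- pair_ld(ds2, 1L, 2L)$r_signed
  expect_equal(l1, -l2, tolerance = 1e-7)
})

test_that("EM from genotypes tracks phased-haplotype r at n = 200", {
  # small recent Ne -> strong adjacent LD; phase is then well determined
  # and the EM error is dominated by the 1/sqrt(2n) counting noise. (At
  # weak LD the double-heterozygote split is uninformative and no unphased
  # estimator can match phased counting.)
  cfg <- sim_config(seed = 88, n_generations = 15,
                    N = c(rep(25L, 15), 200L),
                    n_chromosomes = 1, n_snps_per_chrom = 250)
  res <- simulate_population(cfg)
  H <- rbind(res$truth$hap_gamete1, res$truth$hap_gamete2)
  ds <- res$dataset
  adj <- adjacent_ld(ds)$pairs
  adj <- adj[!is.na(adj$r_signed), ]
  # r from the true phased haplotype counts (exact counting, no EM)
  r_hap <- vapply(seq_len(nrow(adj)), function(k) {
    a <- H[, adj$snp_i[k]]; b <- H[, adj$snp_j[k]]
    pA <- mean(a); pB <- mean(b)
    den <- pA * (1 - pA) * pB * (1 - pB)
    if (den == 0) return(NA_real_)
    (mean(a * b) - pA * pB) / sqrt(den)
  }, numeric(1))
  # information floor: at r ~ 0 the double-heterozygote split carries no
  # phase signal, so var(EM r - phased r) ~ 1/(2n) = 0.0025 and no unphased
  # estimator can reach 0.02 RMS over all pairs; where phase is identified
  # (|r| >= 0.4) the EM tracks phased counting within the contract
  use <- !is.na(r_hap) & abs(r_hap) >= 0.4
  expect_gt(sum(use), 50)
  expect_lt(sqrt(mean((adj$r_signed[use] - r_hap[use])^2)), 0.02)
})

test_that("ld_decay is invariant to chromosome relabeling", {
  ds <- random_ds(41, n = 30, m = 40, n_chrom = 2)
  b1 <- ld_decay(ds, max_dist_bp = 2e6, bin_bp = 1e6)
  relab <- ds
  relab$snps$chromosome <- c("7", "9")[match(relab$snps$chromosome,
                                             c("1", "2"))]
  ds2 <- genotype_dataset(relab$samples, relab$snps, relab$calls)
  b2 <- ld_decay(ds2, max_dist_bp = 2e6, bin_bp = 1e6)
  expect_equal(b1$mean_r2, b2$mean_r2)
  expect_identical(b1$n_pairs, b2$n_pairs)
})
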
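test_that("hwe_exact_test matches the enumeration oracle and edge cases", {
  # all-heterozygote extreme is wildly out of equilibrium
  expect_lt(hwe_exact_test(0, 100, 0), 1e-20)
  # monomorphic tables are in equilibrium by definition
  expect_identical(hwe_exact_test(50, 0, 0), 1.0)
  expect_identical(hwe_exact_test(0, 0, 7), 1.0)
  # frozen value computed with the enumeration oracle
  expect_equal(hwe_exact_test(57, 78, 22), hwe_enum_oracle(57, 78, 22),
               tolerance = 1e-12)
  # property: random tables, n <= 200
  withr::with_seed(100, {
    for (rep in 1:300) {
      n <- sample(1:200, 1)
      na <- sample(0:(2 * n), 1)
      nab_max <- min(na, 2 * n - na)
      nab <- if (nab_max > 0)
        sample(seq(nab_max %% 2, nab_max, 2), 1) else 0
      naa <- (na - nab) / 2
      nbb <- n - naa - nab
      expect_equal(hwe_exact_test(naa, nab, nbb),
                   hwe_enum_oracle(naa, nab, nbb), tolerance = 1e-12)
    }
  })
})

test_that("sample_qc flags call rate, heterozygosity and duplicates", {
  withr::with_seed(7, {
    n <- 100; m <- 400
    calls <- matrix(rbinom(n * m, 2, 0.4), n, m)
    # sample 1: 89% call rate (below 0.90); sample 2: boundary 90% retained
    calls[1, seq_len(ceiling(0.11 * m))] <- NA
    calls[2, seq_len(0.10 * m)] <- NA
    # sample 3: extreme heterozygote
    calls[3, ] <- 1L
    # samples 4/5 duplicates, 5 with lower call rate
    calls[4, ] <- calls[5, ] <- rbinom(m, 2, 0.5)
    calls[5, 1:2] <- NA
    ds <- make_ds(calls)
    rep_ <- sample_qc(ds)
    expect_true(rep_$low_call_rate[1])
    expect_false(rep_$low_call_rate[2])
    expect_true(rep_$het_outlier[3])
    # z-score recomputed directly
    z3 <- (rep_$heterozygosity_rate[3] - mean(rep_$heterozygosity_rate)) /
      sd(rep_$heterozygosity_rate)
    expect_equal(rep_$het_z_score[3], z3)
    expect_true(all(rep_$duplicate[4:5]))
    expect_identical(rep_$duplicate_partner[4], "S005")
    # only the lower-call-rate member is marked for removal
    expect_false(rep_$remove[4])
    expect_true(rep_$remove[5])
  })
})

test_that("identical samples get concordance 1 and zero-SD hets warn", {
  ds <- make_ds(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L)))
  expect_warning(rep_ <- sample_qc(ds), "SD is 0")
  expect_true(all(rep_$duplicate))
  expect_error(sample_qc(make_ds(matrix(integer(0), 2, 0))), "zero SNPs")
})

test_that("ibd_check: self-pair gives pi_hat 1; simulated duos near 0.5", {
  ds <- random_ds(21, n = 30, m = 2000)
  self <- ibd_check(ds, ped = NULL,
                    pairs = cbind("S001", "S001"))
  expect_equal(self$pi_hat, 1.0, tolerance = 1e-9)
  # simulator duos: parent-offspring ~0.5, founders ~0
  cfg <- sim_config(seed = 77, n_generations = 1, N = 40,
                    n_chromosomes = 3, n_snps_per_chrom = 1700,
                    export = "all")
  res <- simulate_population(cfg)
  ped <- res$truth$pedigree
  rep_ <- ibd_check(res$dataset, ped)
  po <- rep_[rep_$relationship == "parent_offspring", ]
  expect_gt(nrow(po), 10)
  expect_true(all(abs(po$pi_hat - 0.5) < 0.1))
  # founders are unrelated
  founders <- ped$animal[ped$birth_year == 0]
  un <- ibd_check(res$dataset, ped = NULL,
                  pairs = cbind(founders[1:10], founders[11:20]))
  expect_true(all(abs(un$pi_hat) < 0.1))
})

test_that("sex_check infers sex from X homozygosity", {
  withr::with_seed(5, {
    m <- 120
    calls <- rbind(
      t(replicate(10, rbinom(m, 2, 0.5))),        # females, het-rich
      t(replicate(5, 2L * rbinom(m, 1, 0.5))))    # males, all hom
    ds <- make_ds(calls, chromosome = rep("X", m),
                  sex = c(rep(2L, 10), rep(1L, 5)))
    sc <- sex_check(ds)
    expect_true(all(sc$inferred_sex[11:15] == 1L))
    expect_false(any(sc$sex_mismatch))
    # all-heterozygous sample -> F <= 0 -> female; all-hom -> F = 1 -> male
    calls[1, ] <- 1L
    ds2 <- make_ds(calls, chromosome = rep("X", m),
                   sex = c(1L, rep(2L, 9), rep(1L, 5)))
    sc2 <- sex_check(ds2)
    expect_lte(sc2$x_f[1], 0)
    expect_identical(sc2$inferred_sex[1], 2L)
    expect_true(sc2$sex_mismatch[1])
    expect_equal(sc2$x_f[11], 1.0)
  })
  expect_warning(sex_check(make_ds(matrix(0L, 2, 2))), "no X")
})

test_that("snp_qc computes stats and applies strict thresholds", {
  withr::with_seed(13, {
    n <- 100
    calls <- cbind(
      rbinom(n, 2, 0.5),               # clean
      c(rep(NA, 3), rbinom(n - 3, 2, 0.5)),  # call rate 0.97 < 0.98
      c(rep(NA, 2), rbinom(n - 2, 2, 0.5)),  # boundary 0.98 retained
      c(1L, 1L, rep(0L, n - 2)),       # MAF 0.01 < 0.03
      rep(1L, n),                      # HWE failure
      rbinom(n, 2, 0.5),               # unknown position
      rbinom(n, 2, 0.5))               # X chromosome
    ds <- make_ds(calls,
                  chromosome = c("1", "1", "1", "1", "1", "0", "X"),
                  position_bp = c(1000, 2000, 3000, 4000, 5000, 0, 500))
    qr <- snp_qc(ds, drop_unknown_pos = TRUE, drop_sex_chroms = TRUE)
    at <- function(k) which(qr$snp_id == sprintf("M%05d", k))
    expect_true(qr$low_call_rate[at(2)])
    expect_false(qr$low_call_rate[at(3)])
    expect_true(qr$low_maf[at(4)])
    expect_true(qr$hwe_fail[at(5)])
    expect_true(qr$unknown_position[at(6)])
    expect_true(qr$sex_chromosome[at(7)])
    expect_false(qr$remove[at(1)])
    # MAF exactly at threshold retained under strict "lower than"
    calls2 <- matrix(c(rep(0L, 97), 1L, 1L, 1L,
                       rep(0L, 94) , rep(1L, 6)), n, 2)
    ds2 <- make_ds(calls2)
    qr2 <- snp_qc(ds2, maf_min = 0.03, hwe_p_min = 0)
    expect_equal(qr2$maf[2], 0.03)
    expect_false(qr2$low_maf[2])
    expect_true(qr2$low_maf[1])
  })
})

test_that("apply_qc removes flagged rows/columns and tallies reasons", {
  ds <- random_ds(3, n = 20, m = 50)
  s_rep <- sample_qc(ds)
  m_rep <- snp_qc(ds, call_rate_min = 0, maf_min = 0, hwe_p_min = 0)
  res <- apply_qc(ds, s_rep, m_rep)
  # no flags anywhere -> identity
  expect_identical(res$dataset$calls, ds$calls)
  # forced flags: 3 samples, 5 SNPs
  s_rep$remove[1:3] <- TRUE
  m_rep$remove[1:5] <- TRUE
  m_rep$low_call_rate[1:5] <- TRUE
  m_rep$low_maf[4:5] <- TRUE
  res2 <- apply_qc(ds, s_rep, m_rep)
  expect_identical(dim(res2$dataset$calls), c(17L, 45L))
  tallies <- res2$counts
  reason_sum <- sum(tallies$n[grepl("^snp_", tallies$reason) &
                              tallies$reason != "snp_low_call_rate"]) +
    tallies$n[tallies$reason == "snp_low_call_rate"]
  expect_gte(reason_sum, tallies$n[tallies$reason == "snps_removed"])
  expect_error(apply_qc(ds, s_rep,
                        transform(m_rep, remove = TRUE)), "all SNPs")
})

test_that("QC is idempotent at fixed thresholds", {
  ds <- random_ds(31, n = 40, m = 120, missing_rate = 0.02)
  s1 <- sample_qc(ds); m1 <- snp_qc(ds)
  f1 <- apply_qc(ds, s1, m1)$dataset
  s2 <- sample_qc(f1); m2 <- snp_qc(f1)
  f2 <- apply_qc(f1, s2, m2)$dataset
  expect_identical(dim(f2$calls), dim(f1$calls))
})

test_that("injected missingness is recovered within 3 binomial SDs", {
  m_rate <- 0.05
  cfg <- sim_config(seed = 4, n_generations = 2, N = 40, n_chromosomes = 2,
                    n_snps_per_chrom = 1000, missing_rate = m_rate)
  res <- simulate_population(cfg)
  s_rep <- sample_qc(res$dataset)
  m <- nrow(res$dataset$snps)
  expect_lt(abs(mean(s_rep$call_rate) - (1 - m_rate)),
            3 * sqrt(m_rate * (1 - m_rate) / m))
})

test_that("pi_hat on simulated full-sib pairs averages 0.5", {
  # 20 full-sib pairs at 10k SNPs; broad founder base keeps the allele
  # frequencies behind the moment estimator honest
  cfg <- sim_config(seed = 55, n_generations = 1, N = c(40L, 80L),
                    n_chromosomes = 5, n_snps_per_chrom = 2000,
                    mating = "random_monogamous", export = "all")
  res <- simulate_population(cfg)
  ped <- res$truth$pedigree
  kids <- ped[ped$birth_year == 1, ]
  key <- paste(kids$sire, kids$dam)
  sibs <- NULL
  for (k in unique(key)) {
    ix <- which(key == k)
    if (length(ix) >= 2)
      sibs <- rbind(sibs, t(combn(kids$animal[ix], 2)))
  }
  sibs <- sibs[1:20, , drop = FALSE]
  rep_ <- ibd_check(res$dataset, ped = NULL, pairs = sibs)
  expect_lt(abs(mean(rep_$pi_hat) - 0.5), 0.05)
})
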
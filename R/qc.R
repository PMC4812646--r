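#' Hardy-Weinberg exact test
#'
#' Exact two-sided p-value for a biallelic genotype table, computed by
#' summing, over all heterozygote counts compatible with the observed allele
#' counts (same parity), the probabilities that do not exceed the probability
#' of the observed count (standard, not mid-p). Probabilities follow the
#' Levene/Haldane conditional distribution and are evaluated with a stable
#' recurrence.
#'
#' @param n_aa,n_ab,n_bb genotype counts (non-negative, sum >= 1).
#' @return p-value in (0, 1]; monomorphic tables give exactly 1.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("at least one genotype required")
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  if (n_a == 0 || n_b == 0) return(1.0)
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)
  # P(het = h + 2) / P(het = h) = 4*na*nb / ((h+2)*(h+1))
  # with na, nb the homozygote counts at h
  probs <- numeric(length(hets))
  probs[1] <- 1
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    naa <- (n_a - h) / 2
    nbb <- (n_b - h) / 2
    probs[k] <- probs[k - 1] * 4 * naa * nbb / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  obs <- which(hets == n_ab)
  if (!length(obs)) stop("heterozygote count has wrong parity")
  min(1, sum(probs[probs <= probs[obs] * (1 + 1e-12)]))
}

# per-SNP A1 allele frequency from the call matrix
.allele_freq <- function(calls) {
  colSums(calls, na.rm = TRUE) / (2 * colSums(!is.na(calls)))
}

#' Sample-level quality control
#'
#' Flags samples with low call rate, outlying heterozygosity (z-score against
#' the sample mean/SD) and duplicates (pairwise genotype concordance over
#' co-called SNPs above `dup_match_min`; both members flagged, the
#' lower-call-rate member marked for removal).
#'
#' @param ds genotype_dataset with >= 2 samples and >= 1 SNP.
#' @param call_rate_min minimum call rate (strict: flag if below).
#' @param het_sd heterozygosity z-score threshold; by default only values
#'   above +`het_sd` are flagged ("higher than" rule); set
#'   `two_sided = TRUE` for |z|.
#' @param dup_match_min concordance above which a pair is duplicated.
#' @param two_sided flag heterozygosity outliers on both sides.
#' @return data.frame of class `sample_qc_report`: one row per sample with
#'   statistics, logical flag columns, `duplicate_partner` and `remove`.
#' @export
sample_qc <- function(ds, call_rate_min = 0.90, het_sd = 3,
                      dup_match_min = 0.99, two_sided = FALSE) {
  stopifnot(inherits(ds, "genotype_dataset"))
  n <- nrow(ds$samples); m <- nrow(ds$snps)
  if (m == 0) stop("dataset has zero SNPs")
  if (n < 2) stop("sample QC needs at least 2 samples")
  calls <- ds$calls
  called <- !is.na(calls)
  call_rate <- rowSums(called) / m
  het <- rowSums(calls == 1L, na.rm = TRUE) / pmax(rowSums(called), 1L)
  mu <- mean(het); sdv <- stats::sd(het)
  if (sdv == 0) {
    warning("heterozygosity SD is 0; no heterozygosity outliers flagged")
    z <- rep(0, n)
  } else z <- (het - mu) / sdv
  het_flag <- if (two_sided) abs(z) > het_sd else z > het_sd
  # pairwise concordance via indicator cross-products
  I0 <- called & calls == 0L; I1 <- called & calls == 1L
  I2 <- called & calls == 2L
  storage.mode(I0) <- storage.mode(I1) <- storage.mode(I2) <- "double"
  eq <- I0 %*% t(I0) + I1 %*% t(I1) + I2 %*% t(I2)
  co <- (called + 0) %*% t(called + 0)
  conc <- ifelse(co > 0, eq / co, NA)
  diag(conc) <- NA
  dup_flag <- rep(FALSE, n)
  partner <- rep(NA_character_, n)
  dup_drop <- rep(FALSE, n)
  pr <- which(upper.tri(conc) & !is.na(conc) & conc > dup_match_min,
              arr.ind = TRUE)
  if (nrow(pr)) {
    for (r in seq_len(nrow(pr))) {
      i <- pr[r, 1]; j <- pr[r, 2]
      dup_flag[c(i, j)] <- TRUE
      partner[i] <- ds$samples$sample_id[j]
      partner[j] <- ds$samples$sample_id[i]
      drop <- if (call_rate[i] <= call_rate[j]) i else j
      dup_drop[drop] <- TRUE
    }
  }
  low_cr <- call_rate < call_rate_min
  rep_df <- data.frame(
    sample_id = ds$samples$sample_id,
    call_rate = call_rate,
    heterozygosity_rate = het,
    het_z_score = z,
    duplicate_partner = partner,
    low_call_rate = low_cr,
    het_outlier = het_flag,
    duplicate = dup_flag,
    sex_mismatch = FALSE,
    pedigree_error = FALSE,
    remove = low_cr | het_flag | dup_drop,
    stringsAsFactors = FALSE)
  class(rep_df) <- c("sample_qc_report", "data.frame")
  rep_df
}

#' Method-of-moments IBD estimates for pedigree verification
#'
#' Computes PI_HAT (P(IBD=2) + 0.5 P(IBD=1)) from IBS counts and allele
#' frequencies for the requested sample pairs, and flags recorded
#' parent-offspring pairs whose PI_HAT deviates from 0.5 by more than
#' `tolerance`.
#'
#' @param ds genotype_dataset.
#' @param ped pedigree_table; parent-offspring pairs present in `ds` are
#'   evaluated. Additional pairs may be supplied via `pairs`.
#' @param tolerance allowed |PI_HAT - 0.5| for recorded parent-offspring
#'   pairs (default 0.15).
#' @param pairs optional 2-column character matrix of extra sample-id pairs.
#' @return data.frame of class `ibd_report`: id1, id2, relationship, ibs0/1/2,
#'   pi_hat, expected_pi, pedigree_error flag. Pairs with zero co-called SNPs
#'   are skipped with a warning.
#' @export
ibd_check <- function(ds, ped, tolerance = 0.15, pairs = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  ids <- ds$samples$sample_id
  want <- matrix(character(0), 0, 2)
  rel <- character(0)
  if (!is.null(ped)) {
    stopifnot(inherits(ped, "pedigree_table"))
    for (side in c("sire", "dam")) {
      p <- ped[[side]]
      keep <- p != attr(ped, "sentinel") & ped$animal %in% ids & p %in% ids
      if (any(keep)) {
        want <- rbind(want, cbind(p[keep], ped$animal[keep]))
        rel <- c(rel, rep("parent_offspring", sum(keep)))
      }
    }
  }
  if (!is.null(pairs)) {
    want <- rbind(want, pairs)
    rel <- c(rel, rep("other", nrow(pairs)))
  }
  if (!nrow(want)) return(structure(data.frame(), class = c("ibd_report",
                                                            "data.frame")))
  p <- .allele_freq(ds$calls)
  q <- 1 - p
  out <- vector("list", nrow(want))
  for (r in seq_len(nrow(want))) {
    i <- match(want[r, 1], ids); j <- match(want[r, 2], ids)
    if (is.na(i) || is.na(j)) stop("unknown sample id in pair ", r)
    gi <- ds$calls[i, ]; gj <- ds$calls[j, ]
    use <- !is.na(gi) & !is.na(gj) & p > 0 & p < 1
    if (!any(use)) {
      warning("pair ", want[r, 1], "/", want[r, 2],
              ": zero co-called SNPs, skipped")
      next
    }
    d <- abs(gi[use] - gj[use])
    ibs0 <- sum(d == 2); ibs1 <- sum(d == 1); ibs2 <- sum(d == 0)
    pp <- p[use]; qq <- q[use]
    e0_z0 <- sum(2 * pp^2 * qq^2)
    e1_z0 <- sum(4 * pp^3 * qq + 4 * pp * qq^3)
    e2_z0 <- sum(pp^4 + qq^4 + 4 * pp^2 * qq^2)
    e1_z1 <- sum(2 * pp^2 * qq + 2 * pp * qq^2)
    e2_z1 <- sum(pp^3 + qq^3 + pp^2 * qq + pp * qq^2)
    nsnp <- sum(use)
    z0 <- ibs0 / e0_z0
    z1 <- (ibs1 - z0 * e1_z0) / e1_z1
    z2 <- (ibs2 - z0 * e2_z0 - z1 * e2_z1) / nsnp
    zz <- pmax(c(z0, z1, z2), 0)
    zz <- zz / sum(zz)
    pi_hat <- zz[3] + 0.5 * zz[2]
    exp_pi <- if (rel[r] == "parent_offspring") 0.5 else NA_real_
    out[[r]] <- data.frame(
      id1 = want[r, 1], id2 = want[r, 2], relationship = rel[r],
      n_snps = nsnp, ibs0 = ibs0, ibs1 = ibs1, ibs2 = ibs2,
      pi_hat = pi_hat, expected_pi = exp_pi,
      pedigree_error = !is.na(exp_pi) && abs(pi_hat - exp_pi) > tolerance,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  class(res) <- c("ibd_report", "data.frame")
  res
}

#' X-homozygosity sex check
#'
#' Per-sample inbreeding-style F on X-chromosome SNPs,
#' `F = (O_hom - E_hom) / (N - E_hom)`, with expected homozygosity from X
#' allele frequencies estimated in declared females only (males are
#' hemizygous and would bias the frequencies). F below `f_female_max` infers
#' female, above `f_male_min` male, in between unknown; the inference is
#' compared to the declared sex.
#'
#' @param ds genotype_dataset containing chromosome "X" SNPs.
#' @param f_female_max,f_male_min F thresholds (defaults 0.2 and 0.8).
#' @return data.frame: sample_id, declared_sex, x_f, inferred_sex,
#'   sex_mismatch. Empty (with a warning) if no X SNPs are present.
#' @export
sex_check <- function(ds, f_female_max = 0.2, f_male_min = 0.8) {
  stopifnot(inherits(ds, "genotype_dataset"))
  xi <- which(ds$snps$chromosome == "X")
  if (!length(xi)) {
    warning("no X-chromosome SNPs; sex check not performed")
    return(data.frame(sample_id = character(0), declared_sex = integer(0),
                      x_f = numeric(0), inferred_sex = integer(0),
                      sex_mismatch = logical(0)))
  }
  x <- ds$calls[, xi, drop = FALSE]
  females <- ds$samples$sex == 2L
  freq_src <- if (any(females)) x[females, , drop = FALSE] else x
  p <- .allele_freq(freq_src)
  ok_snp <- !is.na(p) & p > 0 & p < 1
  x <- x[, ok_snp, drop = FALSE]
  p <- p[ok_snp]
  n <- nrow(ds$samples)
  f <- numeric(n)
  for (i in seq_len(n)) {
    g <- x[i, ]
    use <- !is.na(g)
    if (!any(use)) { f[i] <- NA_real_; next }
    o_hom <- sum(g[use] != 1L)
    e_hom <- sum(1 - 2 * p[use] * (1 - p[use]))
    nn <- sum(use)
    f[i] <- if (nn - e_hom > 0) (o_hom - e_hom) / (nn - e_hom) else NA_real_
  }
  inferred <- ifelse(is.na(f), 0L,
                     ifelse(f > f_male_min, 1L,
                            ifelse(f < f_female_max, 2L, 0L)))
  declared <- ds$samples$sex
  mism <- declared != 0L & inferred != 0L & declared != inferred
  data.frame(sample_id = ds$samples$sample_id, declared_sex = declared,
             x_f = f, inferred_sex = inferred, sex_mismatch = mism,
             stringsAsFactors = FALSE)
}

#' SNP-level quality control
#'
#' Per-SNP call rate, minor allele frequency and Hardy-Weinberg exact-test
#' p-value, with strict-inequality flagging (a SNP at exactly the threshold
#' is retained). Unknown-position (`position_bp == 0` or chromosome `"0"`)
#' and sex-chromosome flags are applied when requested.
#'
#' @param ds genotype_dataset.
#' @param call_rate_min flag SNPs with call rate strictly below this.
#' @param maf_min flag SNPs with MAF strictly below this (0 disables).
#' @param hwe_p_min flag SNPs with HWE exact p strictly below this
#'   (0 disables).
#' @param drop_unknown_pos,drop_sex_chroms flag unknown-position /
#'   non-autosomal SNPs.
#' @return data.frame of class `snp_qc_report`: one row per SNP with
#'   statistics, logical flag columns and `remove`.
#' @export
snp_qc <- function(ds, call_rate_min = 0.98, maf_min = 0.03,
                   hwe_p_min = 1e-6, drop_unknown_pos = FALSE,
                   drop_sex_chroms = FALSE) {
  stopifnot(inherits(ds, "genotype_dataset"))
  calls <- ds$calls
  n <- nrow(calls)
  called <- colSums(!is.na(calls))
  call_rate <- called / n
  p <- colSums(calls, na.rm = TRUE) / (2 * pmax(called, 1L))
  maf <- pmin(p, 1 - p)
  n_aa <- colSums(calls == 2L, na.rm = TRUE)
  n_ab <- colSums(calls == 1L, na.rm = TRUE)
  n_bb <- colSums(calls == 0L, na.rm = TRUE)
  hwe_p <- vapply(seq_len(ncol(calls)), function(k) {
    if (called[k] == 0) return(1.0)
    hwe_exact_test(n_aa[k], n_ab[k], n_bb[k])
  }, numeric(1))
  unknown_pos <- ds$snps$position_bp == 0 | ds$snps$chromosome == "0"
  sex_chrom <- !(ds$snps$chromosome %in% ds$autosomes) & !unknown_pos
  flags <- data.frame(
    low_call_rate = call_rate < call_rate_min,
    low_maf = maf_min > 0 & maf < maf_min,
    hwe_fail = hwe_p_min > 0 & hwe_p < hwe_p_min,
    unknown_position = drop_unknown_pos & unknown_pos,
    sex_chromosome = drop_sex_chroms & sex_chrom)
  rep_df <- cbind(data.frame(snp_id = ds$snps$snp_id,
                             chromosome = ds$snps$chromosome,
                             call_rate = call_rate, maf = maf,
                             hwe_p = hwe_p, stringsAsFactors = FALSE),
                  flags,
                  remove = Reduce(`|`, flags))
  class(rep_df) <- c("snp_qc_report", "data.frame")
  rep_df
}

#' QC threshold presets
#'
#' Two first-class profiles: `"inbreeding"` (sample call rate 0.90, no
#' MAF/HWE filters, drop unknown-position and sex-chromosome SNPs; SNP call
#' rate 0.90) used upstream of the inbreeding estimators, and `"ld"` (SNP
#' call rate 0.98, MAF 0.03, HWE 1e-6, applied within population) used
#' upstream of LD, phase-correlation and Ne estimation.
#'
#' @param profile `"inbreeding"` or `"ld"`.
#' @return Named list of `snp_qc()` arguments.
#' @export
qc_profile <- function(profile = c("inbreeding", "ld")) {
  profile <- match.arg(profile)
  switch(profile,
    inbreeding = list(call_rate_min = 0.90, maf_min = 0, hwe_p_min = 0,
                      drop_unknown_pos = TRUE, drop_sex_chroms = TRUE),
    ld = list(call_rate_min = 0.98, maf_min = 0.03, hwe_p_min = 1e-6,
              drop_unknown_pos = TRUE, drop_sex_chroms = TRUE))
}

#' Apply QC reports to a dataset
#'
#' Removes samples marked `remove` in the sample report and SNPs marked
#' `remove` in the SNP report, and tallies removals by reason (a SNP removed
#' for several reasons counts once in the totals and once per reason in the
#' reason tallies).
#'
#' @param ds the genotype_dataset the reports were computed on.
#' @param sample_report result of [sample_qc()] (or NULL to keep all
#'   samples).
#' @param snp_report result of [snp_qc()] (or NULL to keep all SNPs).
#' @return list: `dataset` (filtered genotype_dataset), `counts` (data.frame
#'   of removal tallies by reason plus retained/removed totals).
#' @export
apply_qc <- function(ds, sample_report = NULL, snp_report = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  counts <- list()
  keep_s <- rep(TRUE, nrow(ds$samples))
  if (!is.null(sample_report)) {
    stopifnot(identical(sample_report$sample_id, ds$samples$sample_id))
    keep_s <- !sample_report$remove
    for (fl in c("low_call_rate", "het_outlier", "duplicate",
                 "sex_mismatch", "pedigree_error"))
      counts[[paste0("sample_", fl)]] <- sum(sample_report[[fl]])
    counts$samples_removed <- sum(!keep_s)
  }
  keep_m <- rep(TRUE, nrow(ds$snps))
  if (!is.null(snp_report)) {
    stopifnot(identical(snp_report$snp_id, ds$snps$snp_id))
    keep_m <- !snp_report$remove
    for (fl in c("low_call_rate", "low_maf", "hwe_fail",
                 "unknown_position", "sex_chromosome"))
      counts[[paste0("snp_", fl)]] <- sum(snp_report[[fl]])
    counts$snps_removed <- sum(!keep_m)
  }
  if (!any(keep_s)) stop("QC removed all samples")
  if (!any(keep_m)) stop("QC removed all SNPs")
  counts$samples_retained <- sum(keep_s)
  counts$snps_retained <- sum(keep_m)
  tab <- data.frame(reason = names(counts),
                    n = unlist(counts, use.names = FALSE),
                    stringsAsFactors = FALSE)
  list(dataset = subset_dataset(ds, samples = which(keep_s),
                                snps = which(keep_m)),
       counts = tab)
}
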
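#' Two-locus EM haplotype frequencies
#'
#' Maximum-likelihood haplotype frequencies under random mating from
#' unphased two-locus genotype counts. Only the double-heterozygote class is
#' phase-ambiguous; the EM iterates the cis/trans split until the largest
#' frequency change is below 1e-10 (or 1000 iterations). Frequencies are
#' initialized at linkage equilibrium and, to guard against the symmetric
#' double-root likelihood (and other local maxima), the EM is restarted from
#' both ends of the admissible p_AB range; the best log-likelihood wins and
#' exact ties are resolved in favour of D >= 0 (reported via `tie`).
#'
#' @param counts 3x3 matrix of genotype counts, `counts[i, j]` = number of
#'   individuals with A1-dosage `i - 1` at locus 1 and `j - 1` at locus 2
#'   (missing-excluded).
#' @return list: `hap` (p_AB, p_Ab, p_aB, p_ab), `D`, `r_signed`, `r2`,
#'   `loglik`, `tie` (TRUE if the likelihood had a symmetric double root).
#'   Monomorphic loci give `D = 0` and `r_signed`/`r2` = NA.
#' @export
em_hap_freqs <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)), all(counts >= 0))
  if (sum(counts) < 1) stop("at least one co-called individual required")
  cnt9 <- matrix(as.numeric(t(counts)), nrow = 9)  # class k = g1*3+g2, rows
  res <- .em_batch(cnt9)
  list(hap = c(p_AB = res$pAB, p_Ab = res$pA - res$pAB,
               p_aB = res$pB - res$pAB,
               p_ab = 1 - res$pA - res$pB + res$pAB),
       D = res$D, r_signed = res$r, r2 = res$r^2,
       loglik = res$loglik, tie = res$tie)
}

# Batch EM over P pairs. cnt9: 9 x P matrix of genotype-class counts with
# class index k = 3*g1 + g2 (dosages 0..2). Returns vectors over pairs.
.em_batch <- function(cnt9, tol = 1e-10, max_iter = 1000L) {
  P <- ncol(cnt9)
  N <- colSums(cnt9)
  g <- 0:2
  d1 <- rep(g, each = 3)   # dosage at locus 1 for class k
  d2 <- rep(g, times = 3)
  pA <- colSums(cnt9 * d1) / (2 * N)
  pB <- colSums(cnt9 * d2) / (2 * N)
  lo <- pmax(0, pA + pB - 1)
  hi <- pmin(pA, pB)
  n22 <- cnt9[9, ]; n21 <- cnt9[8, ]; n20 <- cnt9[7, ]
  n12 <- cnt9[6, ]; n11 <- cnt9[5, ]; n10 <- cnt9[4, ]
  n02 <- cnt9[3, ]; n01 <- cnt9[2, ]; n00 <- cnt9[1, ]

  run_em <- function(pAB) {
    for (it in seq_len(max_iter)) {
      pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
      den <- pAB * pab + pAb * paB
      cis <- ifelse(den > 0, pAB * pab / den, 0.5)
      new <- (2 * n22 + n21 + n12 + n11 * cis) / (2 * N)
      new <- pmin(pmax(new, lo), hi)
      if (max(abs(new - pAB)) < tol) { pAB <- new; break }
      pAB <- new
    }
    pAB
  }
  loglik_of <- function(pAB) {
    pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
    lg <- function(x) log(pmax(x, 1e-300))
    n22 * lg(pAB^2) + n21 * lg(2 * pAB * pAb) + n20 * lg(pAb^2) +
      n12 * lg(2 * pAB * paB) + n11 * lg(2 * (pAB * pab + pAb * paB)) +
      n10 * lg(2 * pAb * pab) + n02 * lg(paB^2) + n01 * lg(2 * paB * pab) +
      n00 * lg(pab^2)
  }
  eps <- 1e-6
  starts <- list(pA * pB,
                 lo + eps * (hi - lo),
                 hi - eps * (hi - lo))
  sols <- lapply(starts, run_em)
  lls <- vapply(sols, loglik_of, numeric(P))
  if (P == 1) lls <- matrix(lls, nrow = 1)
  # choose best loglik; on ties (within 1e-9) prefer the D >= 0 solution
  pAB <- sols[[1]]; ll <- lls[, 1]
  tie <- rep(FALSE, P)
  for (s in 2:3) {
    better <- lls[, s] > ll + 1e-9
    tied <- abs(lls[, s] - ll) <= 1e-9
    prefer <- tied & (sols[[s]] - pA * pB > pAB - pA * pB + 1e-12)
    tie <- tie | (tied & abs(sols[[s]] - pAB) > 1e-8)
    swap <- better | prefer
    pAB[swap] <- sols[[s]][swap]
    ll[swap] <- lls[swap, s]
  }
  D <- pAB - pA * pB
  var_term <- pA * (1 - pA) * pB * (1 - pB)
  r <- ifelse(var_term > 0, D / sqrt(var_term), NA_real_)
  D[var_term == 0] <- 0
  list(pAB = pAB, pA = pA, pB = pB, D = D, r = r, loglik = ll,
       tie = tie, n = N)
}

# 9-class genotype-pair counts for arbitrary pair lists, chunked to bound
# memory. calls: n x m dosage matrix. Returns 9 x P matrix.
.pair_counts <- function(calls, iv, jv, chunk = 20000L) {
  P <- length(iv)
  out <- matrix(0, 9, P)
  for (a in seq(1L, P, chunk)) {
    b <- min(a + chunk - 1L, P)
    Xi <- calls[, iv[a:b], drop = FALSE]
    Xj <- calls[, jv[a:b], drop = FALSE]
    K <- Xi * 3L + Xj            # 0..8, NA if either missing
    for (k in 0:8) out[k + 1L, a:b] <- colSums(K == k, na.rm = TRUE)
  }
  out
}

#' Pairwise LD for a list of SNP pairs
#'
#' Vectorized two-locus EM (see [em_hap_freqs()]) with pairwise deletion of
#' missing genotypes. Pairs where either locus is monomorphic among the
#' co-called individuals get NA r/r2 (excluded downstream with reason).
#'
#' @param ds genotype_dataset.
#' @param snp_i,snp_j integer column indices of the pairs (same length;
#'   must be on the same chromosome pairwise).
#' @return data.frame: snp_i, snp_j, chromosome, distance_bp, n, p_AB, D,
#'   r_signed, r2.
#' @export
pair_ld_many <- function(ds, snp_i, snp_j) {
  stopifnot(inherits(ds, "genotype_dataset"), length(snp_i) == length(snp_j))
  if (!length(snp_i))
    return(data.frame(snp_i = integer(0), snp_j = integer(0),
                      chromosome = character(0), distance_bp = numeric(0),
                      n = numeric(0), p_AB = numeric(0), D = numeric(0),
                      r_signed = numeric(0), r2 = numeric(0)))
  ch_i <- ds$snps$chromosome[snp_i]
  if (any(ch_i != ds$snps$chromosome[snp_j]))
    stop("pairs must lie on the same chromosome")
  cnt9 <- .pair_counts(ds$calls, snp_i, snp_j)
  res <- .em_batch(cnt9)
  data.frame(snp_i = snp_i, snp_j = snp_j, chromosome = ch_i,
             distance_bp = abs(ds$snps$position_bp[snp_j] -
                               ds$snps$position_bp[snp_i]),
             n = res$n, p_AB = res$pAB, D = res$D, r_signed = res$r,
             r2 = res$r^2, stringsAsFactors = FALSE)
}

#' Single-pair LD
#'
#' @param ds genotype_dataset.
#' @param i,j SNP column indices (same chromosome, both polymorphic).
#' @return One-row data.frame as in [pair_ld_many()].
#' @export
pair_ld <- function(ds, i, j) pair_ld_many(ds, i, j)

# all within-chromosome index pairs with lo_bp < distance <= hi_bp
# (set lo_bp = 0, strict_hi = TRUE for [0, hi) binning)
.pairs_within <- function(pos, lo_bp, hi_bp, strict_hi = FALSE) {
  n <- length(pos)
  if (n < 2) return(list(i = integer(0), j = integer(0)))
  hi_lim <- if (strict_hi) pos + hi_bp - 1e-9 else pos + hi_bp + 1e-9
  lo_lim <- pos + lo_bp + 1e-9
  last <- findInterval(hi_lim, pos)
  first <- findInterval(lo_lim, pos) + 1L
  first <- pmax(first, seq_len(n) + 1L)
  cnt <- pmax(last - first + 1L, 0L)
  i <- rep(seq_len(n), cnt)
  j <- unlist(lapply(which(cnt > 0), function(k)
    seq.int(first[k], last[k])), use.names = FALSE)
  list(i = i, j = j)
}

#' LD decay in distance bins
#'
#' All within-chromosome SNP pairs at distance below `max_dist_bp` are
#' grouped in `bin_bp` classes ([lo, hi) half-open). The headline bin value
#' is the unweighted mean over chromosomes of the per-chromosome bin means
#' (empty chromosome bins excluded); the pooled per-pair mean is also
#' emitted for diagnostics.
#'
#' @param ds genotype_dataset (LD QC profile applied upstream).
#' @param max_dist_bp maximum pair distance (default 10 Mb).
#' @param bin_bp bin width (default 100 kb).
#' @param max_pairs_per_chrom optional cap: at most this many pairs are
#'   sampled per chromosome (uniformly, seeded) to bound runtime on dense
#'   maps. `Inf` (default) = exhaustive.
#' @param seed RNG seed used only when subsampling.
#' @return data.frame of class `ld_bins`: bin_lo_bp, bin_hi_bp, mean_r2
#'   (across-chromosome mean), pooled_mean_r2, n_pairs.
#' @export
ld_decay <- function(ds, max_dist_bp = 1e7, bin_bp = 1e5,
                     max_pairs_per_chrom = Inf, seed = 1L) {
  stopifnot(inherits(ds, "genotype_dataset"))
  nbins <- ceiling(max_dist_bp / bin_bp)
  acc <- list()
  for (ch in unique(ds$snps$chromosome)) {
    idx <- which(ds$snps$chromosome == ch)
    pr <- .pairs_within(ds$snps$position_bp[idx], 0, max_dist_bp,
                        strict_hi = TRUE)
    if (!length(pr$i)) next
    if (length(pr$i) > max_pairs_per_chrom) {
      keep <- .with_seed(seed, sample.int(length(pr$i),
                                          max_pairs_per_chrom))
      pr <- list(i = pr$i[keep], j = pr$j[keep])
    }
    ld <- pair_ld_many(ds, idx[pr$i], idx[pr$j])
    ld <- ld[!is.na(ld$r2), ]
    if (!nrow(ld)) next
    ld$bin <- pmin(floor(ld$distance_bp / bin_bp), nbins - 1)
    acc[[ch]] <- ld
  }
  bins <- data.frame(bin_lo_bp = (seq_len(nbins) - 1) * bin_bp,
                     bin_hi_bp = seq_len(nbins) * bin_bp)
  per_chrom_mean <- sapply(acc, function(ld)
    vapply(seq_len(nbins) - 1, function(b) {
      x <- ld$r2[ld$bin == b]
      if (length(x)) mean(x) else NA_real_
    }, numeric(1)))
  if (is.null(dim(per_chrom_mean)))
    per_chrom_mean <- matrix(per_chrom_mean, nrow = nbins)
  all_ld <- if (length(acc)) do.call(rbind, acc) else NULL
  bins$mean_r2 <- if (length(acc))
    rowMeans(per_chrom_mean, na.rm = TRUE) else NA_real_
  bins$mean_r2[is.nan(bins$mean_r2)] <- NA_real_
  bins$pooled_mean_r2 <- vapply(seq_len(nbins) - 1, function(b) {
    if (is.null(all_ld)) return(NA_real_)
    x <- all_ld$r2[all_ld$bin == b]
    if (length(x)) mean(x) else NA_real_
  }, numeric(1))
  bins$n_pairs <- vapply(seq_len(nbins) - 1, function(b) {
    if (is.null(all_ld)) return(0L)
    sum(all_ld$bin == b)
  }, integer(1))
  class(bins) <- c("ld_bins", "data.frame")
  bins
}

#' LD between adjacent SNPs
#'
#' Consecutive within-chromosome SNP pairs: mean r2 over informative pairs
#' (both loci polymorphic), the fractions of informative pairs with r2
#' strictly above 0.2 and 0.3, and the mean adjacent distance.
#'
#' @param ds genotype_dataset.
#' @return list: `mean_r2`, `frac_gt_0.2`, `frac_gt_0.3`,
#'   `mean_distance_bp`, `n_pairs` (informative), `pairs` (per-pair
#'   data.frame).
#' @export
adjacent_ld <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  iv <- integer(0); jv <- integer(0)
  for (ch in unique(ds$snps$chromosome)) {
    idx <- which(ds$snps$chromosome == ch)
    if (length(idx) < 2) next
    iv <- c(iv, idx[-length(idx)])
    jv <- c(jv, idx[-1])
  }
  ld <- pair_ld_many(ds, iv, jv)
  inf <- ld[!is.na(ld$r2), ]
  list(mean_r2 = if (nrow(inf)) mean(inf$r2) else NA_real_,
       frac_gt_0.2 = if (nrow(inf)) mean(inf$r2 > 0.2) else NA_real_,
       frac_gt_0.3 = if (nrow(inf)) mean(inf$r2 > 0.3) else NA_real_,
       mean_distance_bp = if (nrow(ld)) mean(ld$distance_bp) else NA_real_,
       n_pairs = nrow(inf), pairs = ld)
}

#' Thin the SNP map and recompute adjacent LD
#'
#' Keeps every `keep_every`-th SNP within each chromosome (ordinal positions
#' 1, 1 + k, 1 + 2k, ...) to mimic a lower-density panel, then applies
#' [adjacent_ld()].
#'
#' @param ds genotype_dataset.
#' @param keep_every thinning factor (default 10; 1 = no thinning).
#' @return As [adjacent_ld()], plus `n_snps_kept`.
#' @export
thinned_ld <- function(ds, keep_every = 10) {
  stopifnot(keep_every >= 1)
  keep <- integer(0)
  for (ch in unique(ds$snps$chromosome)) {
    idx <- which(ds$snps$chromosome == ch)
    keep <- c(keep, idx[seq(1L, length(idx), by = keep_every)])
  }
  thin <- subset_dataset(ds, snps = sort(keep))
  out <- adjacent_ld(thin)
  out$n_snps_kept <- length(keep)
  out
}

# harmonize ds2's allele polarity to ds1 over the shared SNP ids; SNPs with
# incompatible alleles are dropped. Returns the shared, harmonized datasets.
.harmonize <- function(ds1, ds2) {
  shared <- intersect(ds1$snps$snp_id, ds2$snps$snp_id)
  i1 <- match(shared, ds1$snps$snp_id)
  i2 <- match(shared, ds2$snps$snp_id)
  a1_1 <- ds1$snps$allele_a1[i1]; a2_1 <- ds1$snps$allele_a2[i1]
  a1_2 <- ds2$snps$allele_a1[i2]; a2_2 <- ds2$snps$allele_a2[i2]
  same <- a1_2 == a1_1
  flip <- a1_2 == a2_1 & a2_2 == a1_1
  ok <- same | flip
  i1 <- i1[ok]; i2 <- i2[ok]; flip <- flip[ok]
  d1 <- subset_dataset(ds1, snps = i1)
  d2 <- subset_dataset(ds2, snps = i2)
  if (any(flip)) {
    d2$calls[, flip] <- 2L - d2$calls[, flip]
    d2$snps$allele_a1[flip] <- a2_2[flip]
    d2$snps$allele_a2[flip] <- a1_2[ok][flip]
  }
  list(d1 = d1, d2 = d2)
}

#' Between-population correlation of linkage phase
#'
#' For SNP pairs present (post-QC) in both populations, the Pearson
#' correlation across pairs of the signed r in population 1 versus
#' population 2, per 100-kb distance class, plus a headline value over all
#' shared pairs at distance <= `headline_dist_bp`. Allele polarity is
#' harmonized to a common A1 before computing signed r; pairs monomorphic in
#' either population are excluded.
#'
#' @param ds_pop1,ds_pop2 genotype_dataset per population.
#' @param max_dist_bp maximum pair distance (default 10 Mb).
#' @param bin_bp distance-class width (default 100 kb).
#' @param headline_dist_bp headline window (default 50 kb).
#' @param max_pairs_per_chrom optional per-chromosome pair cap (sampled,
#'   seeded) to bound runtime.
#' @param seed RNG seed used only when subsampling.
#' @return list: `bins` (data.frame bin_lo_bp, bin_hi_bp, correlation,
#'   n_pairs; fewer than 2 shared pairs gives NA), `headline`
#'   (correlation over pairs <= headline window), `n_headline_pairs`.
#' @export
phase_correlation <- function(ds_pop1, ds_pop2, max_dist_bp = 1e7,
                              bin_bp = 1e5, headline_dist_bp = 5e4,
                              max_pairs_per_chrom = Inf, seed = 1L) {
  h <- .harmonize(ds_pop1, ds_pop2)
  d1 <- h$d1; d2 <- h$d2
  stopifnot(identical(d1$snps$snp_id, d2$snps$snp_id))
  nbins <- ceiling(max_dist_bp / bin_bp)
  r1 <- numeric(0); r2v <- numeric(0); dist <- numeric(0)
  for (ch in unique(d1$snps$chromosome)) {
    idx <- which(d1$snps$chromosome == ch)
    pr <- .pairs_within(d1$snps$position_bp[idx], 0, max_dist_bp,
                        strict_hi = TRUE)
    if (!length(pr$i)) next
    if (length(pr$i) > max_pairs_per_chrom) {
      keep <- .with_seed(seed, sample.int(length(pr$i),
                                          max_pairs_per_chrom))
      pr <- list(i = pr$i[keep], j = pr$j[keep])
    }
    l1 <- pair_ld_many(d1, idx[pr$i], idx[pr$j])
    l2 <- pair_ld_many(d2, idx[pr$i], idx[pr$j])
    use <- !is.na(l1$r_signed) & !is.na(l2$r_signed)
    r1 <- c(r1, l1$r_signed[use])
    r2v <- c(r2v, l2$r_signed[use])
    dist <- c(dist, l1$distance_bp[use])
  }
  bin <- pmin(floor(dist / bin_bp), nbins - 1)
  bins <- data.frame(bin_lo_bp = (seq_len(nbins) - 1) * bin_bp,
                     bin_hi_bp = seq_len(nbins) * bin_bp)
  bins$correlation <- vapply(seq_len(nbins) - 1, function(b) {
    k <- bin == b
    if (sum(k) < 2 || stats::sd(r1[k]) == 0 || stats::sd(r2v[k]) == 0)
      return(NA_real_)
    stats::cor(r1[k], r2v[k])
  }, numeric(1))
  bins$n_pairs <- vapply(seq_len(nbins) - 1,
                         function(b) sum(bin == b), integer(1))
  hk <- dist <= headline_dist_bp
  headline <- if (sum(hk) >= 2 && stats::sd(r1[hk]) > 0 &&
                  stats::sd(r2v[hk]) > 0)
    stats::cor(r1[hk], r2v[hk]) else NA_real_
  list(bins = bins, headline = headline, n_headline_pairs = sum(hk))
}
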
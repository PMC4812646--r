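#' Convert physical distance to genetic distance
#'
#' Applies the linear map rule (default 1 cM ~ 1 Mb): `c = distance_bp *
#' cm_per_mb / 1e8` Morgan.
#'
#' @param distance_bp physical distance in bp (> 0).
#' @param cm_per_mb recombination rate in cM per Mb (default 1).
#' @return Genetic distance in Morgan.
#' @export
bp_to_morgan <- function(distance_bp, cm_per_mb = 1.0) {
  if (any(distance_bp <= 0)) stop("distance must be positive")
  distance_bp * cm_per_mb / 1e8
}

#' Expected r2 under drift-recombination equilibrium (Sved)
#'
#' `E(r2) = 1 / (4 c Ne + 1)` with c in Morgan.
#'
#' @param Ne effective population size (> 0).
#' @param c genetic distance in Morgan (> 0).
#' @return Expected r2 in (0, 1).
#' @export
sved_expected_r2 <- function(Ne, c) {
  stopifnot(all(Ne > 0), all(c > 0))
  1 / (4 * c * Ne + 1)
}

#' Effective population size from mean r2
#'
#' Inverts the Sved relationship: `Ne_t = (1 - r2) / (4 c r2)`, valid for
#' 0 < r2 < 1.
#'
#' @param r2 mean r2 in the window, strictly inside (0, 1).
#' @param c genetic distance in Morgan (> 0).
#' @return Ne_t.
#' @export
ne_from_r2 <- function(r2, c) {
  if (any(r2 <= 0 | r2 >= 1))
    stop("r2 must lie strictly in (0, 1) for Ne estimation")
  stopifnot(all(c > 0))
  (1 - r2) / (4 * c * r2)
}

#' Generation grid for Ne trajectories
#'
#' The default grid is t = 1..10 by 1, 15..100 by 5, 150..1000 by 50
#' (46 points).
#'
#' @return Integer vector of generations in the past.
#' @export
generation_grid <- function() {
  c(1:10, seq(15L, 100L, 5L), seq(150L, 1000L, 50L))
}

#' Genetic-distance window probing generation t
#'
#' Under t = 1/(2c), the window of c selecting SNP pairs informative about
#' generation t is bounded by the midpoints to the neighbouring grid values:
#' with `t_lo = (t_prev + t)/2` (or `t/2` for the first grid point) and
#' `t_hi = (t + t_next)/2` (or `t + (t - t_prev)/2` for the last), the
#' window is `(1/(2 t_hi), 1/(2 t_lo)]` Morgan. For the default grid this
#' reproduces the worked t = 1 window (1/3, 1].
#'
#' @param grid generation grid (sorted increasing).
#' @param t a grid point.
#' @return Named vector `c(c_lo, c_hi)` in Morgan (window half-open on the
#'   low side).
#' @export
c_window_for_t <- function(grid, t) {
  k <- match(t, grid)
  if (is.na(k)) stop("t = ", t, " is not on the generation grid")
  t_lo <- if (k == 1) t / 2 else (grid[k - 1] + t) / 2
  t_hi <- if (k == length(grid)) t + (t - grid[k - 1]) / 2
          else (t + grid[k + 1]) / 2
  c(c_lo = 1 / (2 * t_hi), c_hi = 1 / (2 * t_lo))
}

#' Ne trajectory from binned LD
#'
#' For each grid generation t: selects pairs whose genetic distance falls in
#' the t-window ([c_window_for_t()]), drops pairs with r2 exactly 0 or 1
#' (outside the stated domain of the estimator), averages r2 per chromosome
#' and then across chromosomes (unweighted), optionally subtracts the
#' finite-sample expectation 1/(2n) from the mean r2, and applies
#' [ne_from_r2()] at the representative distance c = 1/(2t). Grid points
#' with no pairs, or whose (adjusted) mean r2 leaves (0, 1), are emitted
#' with NA and a reason.
#'
#' @param pairs data.frame with columns `chromosome`, `distance_bp`, `r2`
#'   (e.g. from [pair_ld_many()]).
#' @param grid generation grid (default [generation_grid()]).
#' @param cm_per_mb map rule (default 1 cM/Mb).
#' @param n_samples number of diploid individuals behind the r2 estimates;
#'   required when `r2_correction = "sample_size"`.
#' @param r2_correction `"none"` (default; the raw window mean is used) or
#'   `"sample_size"` (subtract the expected finite-sample inflation of the
#'   r2 estimate). For unphased EM-based r2 from n diploid individuals the
#'   inflation at linkage equilibrium is approximately 1/n — twice the
#'   1/(2n) that applies to phased haplotype counts — because phase
#'   uncertainty roughly doubles the sampling variance of D; 1/n is what
#'   this package subtracts (verified by simulation at true r = 0).
#' @param representative_c `"half_t"` (default, c = 1/(2t)) or
#'   `"pair_mean"` (mean genetic distance of the selected pairs).
#' @return data.frame of class `ne_trajectory`: t, c_lo_M, c_hi_M, n_pairs,
#'   mean_r2, Ne_t, reason.
#' @export
ne_trajectory <- function(pairs, grid = generation_grid(), cm_per_mb = 1.0,
                          n_samples = NULL,
                          r2_correction = c("none", "sample_size"),
                          representative_c = c("half_t", "pair_mean")) {
  r2_correction <- match.arg(r2_correction)
  representative_c <- match.arg(representative_c)
  if (!length(grid)) stop("empty generation grid")
  if (r2_correction == "sample_size" && is.null(n_samples))
    stop("n_samples required for the sample-size correction")
  pairs <- pairs[!is.na(pairs$r2), , drop = FALSE]
  cM <- if (nrow(pairs)) bp_to_morgan(pairs$distance_bp, cm_per_mb)
        else numeric(0)
  out <- lapply(grid, function(t) {
    w <- c_window_for_t(grid, t)
    sel <- cM > w["c_lo"] & cM <= w["c_hi"] &
      pairs$r2 > 0 & pairs$r2 < 1
    row <- data.frame(t = t, c_lo_M = unname(w["c_lo"]),
                      c_hi_M = unname(w["c_hi"]), n_pairs = sum(sel),
                      mean_r2 = NA_real_, Ne_t = NA_real_,
                      reason = NA_character_, stringsAsFactors = FALSE)
    if (!any(sel)) { row$reason <- "no pairs in window"; return(row) }
    per_chrom <- tapply(pairs$r2[sel], pairs$chromosome[sel], mean)
    m <- mean(per_chrom)
    if (r2_correction == "sample_size") m <- m - 1 / n_samples
    row$mean_r2 <- m
    if (m <= 0 || m >= 1) { row$reason <- "mean r2 outside (0,1)"
      return(row) }
    c_rep <- if (representative_c == "half_t") 1 / (2 * t)
             else mean(cM[sel])
    row$Ne_t <- ne_from_r2(m, c_rep)
    row
  })
  res <- do.call(rbind, out)
  class(res) <- c("ne_trajectory", "data.frame")
  res
}

#' Ne trajectory directly from a genotype dataset
#'
#' Convenience wrapper: enumerates within-chromosome SNP pairs falling in
#' each grid window (subsampling to `max_pairs_per_window` per window,
#' seeded, to bound runtime on dense maps), computes r2 by the batch EM and
#' delegates to [ne_trajectory()].
#'
#' @param ds genotype_dataset (LD QC profile applied upstream).
#' @param grid generation grid.
#' @param cm_per_mb map rule.
#' @param max_pairs_per_window pair cap per grid window (default 20000).
#' @param seed RNG seed for the subsampling.
#' @param r2_correction,representative_c see [ne_trajectory()].
#' @return As [ne_trajectory()].
#' @export
ne_from_dataset <- function(ds, grid = generation_grid(), cm_per_mb = 1.0,
                            max_pairs_per_window = 20000L, seed = 1L,
                            r2_correction = c("none", "sample_size"),
                            representative_c = c("half_t", "pair_mean")) {
  r2_correction <- match.arg(r2_correction)
  representative_c <- match.arg(representative_c)
  chroms <- unique(ds$snps$chromosome)
  pair_tabs <- list()
  for (gi in seq_along(grid)) {
    w <- c_window_for_t(grid, grid[gi])
    lo_bp <- w["c_lo"] * 1e8 / cm_per_mb
    hi_bp <- w["c_hi"] * 1e8 / cm_per_mb
    iv <- integer(0); jv <- integer(0)
    for (ch in chroms) {
      idx <- which(ds$snps$chromosome == ch)
      pr <- .pairs_within(ds$snps$position_bp[idx], lo_bp, hi_bp)
      iv <- c(iv, idx[pr$i]); jv <- c(jv, idx[pr$j])
    }
    if (!length(iv)) next
    if (length(iv) > max_pairs_per_window) {
      keep <- .with_seed(seed + gi,
                         sample.int(length(iv), max_pairs_per_window))
      iv <- iv[keep]; jv <- jv[keep]
    }
    pair_tabs[[length(pair_tabs) + 1L]] <- cbind(iv, jv)
  }
  if (!length(pair_tabs))
    return(ne_trajectory(data.frame(chromosome = character(0),
                                    distance_bp = numeric(0),
                                    r2 = numeric(0)),
                         grid, cm_per_mb))
  allp <- unique(do.call(rbind, pair_tabs))
  ld <- pair_ld_many(ds, allp[, 1], allp[, 2])
  ne_trajectory(ld, grid = grid, cm_per_mb = cm_per_mb,
                n_samples = nrow(ds$samples),
                r2_correction = r2_correction,
                representative_c = representative_c)
}
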
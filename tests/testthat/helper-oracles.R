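# independent brute-force oracles used by unit and acceptance tests

# ---- ROH: O(n^2) definition checker ---------------------------------------
# enumerates maximal valid runs directly against the every-interior-window
# definition, then applies the same documented left-greedy trim + filters
roh_oracle <- function(g, pos, min_snps = 50, min_length_kb = 1000,
                       window = 50, max_het = 1, max_miss = 1) {
  n <- length(g)
  if (n < window) return(NULL)
  # window cleanliness by direct summation (no prefix sums)
  ok <- vapply(seq_len(n - window + 1L), function(k) {
    win <- g[k:(k + window - 1L)]
    sum(!is.na(win) & win == 1L) <= max_het && sum(is.na(win)) <= max_miss
  }, logical(1))
  segs <- NULL
  s <- 1L
  while (s <= length(ok)) {
    if (ok[s] && (s == 1L || !ok[s - 1L])) {
      r <- s
      while (r < length(ok) && ok[r + 1L]) r <- r + 1L  # direct scan
      segs <- rbind(segs, c(s, r + window - 1L))
      s <- r + 1L
    } else s <- s + 1L
  }
  if (is.null(segs)) return(NULL)
  # shared left-greedy overlap trim
  if (nrow(segs) > 1) for (i in 2:nrow(segs))
    if (segs[i, 1] <= segs[i - 1, 2]) segs[i, 1] <- segs[i - 1, 2] + 1L
  keep <- (segs[, 2] - segs[, 1] + 1L) >= min_snps &
          (pos[segs[, 2]] - pos[segs[, 1]] + 1) >= min_length_kb * 1000
  segs <- segs[keep, , drop = FALSE]
  if (!nrow(segs)) return(NULL)
  data.frame(start_snp_index = as.integer(segs[, 1]),
             end_snp_index = as.integer(segs[, 2]))
}

# ---- Wright's F: path-counting oracle -------------------------------------
# F_X = sum over common ancestors A and pairs of ancestor paths from sire
# and dam that meet only at A: (1/2)^(n + n' + 1) * (1 + F_A)
wright_path_oracle <- function(ped) {
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  n <- nrow(ped)
  paths_memo <- vector("list", n)
  paths_up <- function(v) {
    if (!is.null(paths_memo[[v]])) return(paths_memo[[v]])
    out <- list(v)
    for (p in c(si[v], di[v])) if (!is.na(p))
      out <- c(out, lapply(paths_up(p), function(pp) c(v, pp)))
    paths_memo[[v]] <<- out
    out
  }
  FF <- rep(NA_real_, n)
  f_of <- function(x) {
    if (!is.na(FF[x])) return(FF[x])
    s <- si[x]; d <- di[x]
    if (is.na(s) || is.na(d)) { FF[x] <<- 0; return(0) }
    tot <- 0
    for (p1 in paths_up(s)) for (p2 in paths_up(d)) {
      a <- p1[length(p1)]
      if (p2[length(p2)] != a) next
      if (length(intersect(p1, p2)) != 1L) next
      tot <- tot + 0.5^(length(p1) - 1 + length(p2) - 1 + 1) *
        (1 + f_of(a))
    }
    FF[x] <<- tot
    tot
  }
  vapply(seq_len(n), f_of, numeric(1))
}

# ---- HWE: full-enumeration oracle via the closed-form log-probability -----
hwe_enum_oracle <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  na <- 2 * naa + nab; nb <- 2 * nbb + nab
  if (na == 0 || nb == 0) return(1.0)
  rare <- min(na, nb)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    a <- (na - h) / 2; b <- (nb - h) / 2
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) + lgamma(na + 1) + lgamma(nb + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == nab)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

# ---- two-locus EM: 999-point grid search over the 1-dof likelihood --------
em_grid_oracle <- function(counts) {
  counts <- as.matrix(counts)
  N <- sum(counts)
  d <- 0:2
  pA <- sum(counts * d) / (2 * N)           # rows: locus-1 dosage
  pB <- sum(t(counts) * d) / (2 * N)
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  grid <- seq(lo, hi, length.out = 999)
  ll <- vapply(grid, function(pab) {
    h <- c(AB = pab, Ab = pA - pab, aB = pB - pab, ab = 1 - pA - pB + pab)
    gp <- matrix(0, 3, 3)  # genotype class probs [g1+1, g2+1]
    gp[1, 1] <- h["ab"]^2
    gp[1, 2] <- 2 * h["aB"] * h["ab"]
    gp[1, 3] <- h["aB"]^2
    gp[2, 1] <- 2 * h["Ab"] * h["ab"]
    gp[2, 2] <- 2 * (h["AB"] * h["ab"] + h["Ab"] * h["aB"])
    gp[2, 3] <- 2 * h["AB"] * h["aB"]
    gp[3, 1] <- h["Ab"]^2
    gp[3, 2] <- 2 * h["AB"] * h["Ab"]
    gp[3, 3] <- h["AB"]^2
    sum(counts * log(pmax(gp, 1e-300)))
  }, numeric(1))
  max(ll)
}

# random two-locus genotype table drawn from random haplotype frequencies
random_two_locus_table <- function(n_max = 50) {
  n <- sample(3:n_max, 1)
  h <- as.numeric(stats::rgamma(4, 1))
  h <- h / sum(h)
  hap1 <- sample(4, n, replace = TRUE, prob = h)
  hap2 <- sample(4, n, replace = TRUE, prob = h)
  gA <- (hap1 <= 2) + (hap2 <= 2)                 # haps 1,2 carry allele A
  gB <- (hap1 %% 2 == 1) + (hap2 %% 2 == 1)       # haps 1,3 carry allele B
  tab <- matrix(0, 3, 3)
  for (i in seq_len(n)) tab[gA[i] + 1, gB[i] + 1] <-
      tab[gA[i] + 1, gB[i] + 1] + 1
  tab
}

# ---- sweep-line interval-intersection oracle for true autozygosity --------
autozygosity_interval_oracle <- function(truth, id) {
  total <- 0
  for (ch in unique(founder_mosaic(truth, id, 1)$chromosome)) {
    m1 <- founder_mosaic(truth, id, 1)
    m2 <- founder_mosaic(truth, id, 2)
    m1 <- m1[m1$chromosome == ch, ]; m2 <- m2[m2$chromosome == ch, ]
    for (i in seq_len(nrow(m1))) for (j in seq_len(nrow(m2))) {
      if (m1$founder_haplotype_id[i] != m2$founder_haplotype_id[j]) next
      ov <- min(m1$end_M[i], m2$end_M[j]) - max(m1$start_M[i], m2$start_M[j])
      if (ov > 0) total <- total + ov
    }
  }
  total / sum(truth$map$chrom_length_M)
}
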
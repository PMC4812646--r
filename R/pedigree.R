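#' Wright's pedigree inbreeding coefficient
#'
#' F equals the diagonal of the additive (numerator) relationship matrix
#' minus one, computed animal-by-animal in topological order by ancestor
#' tracing (Meuwissen-Luo style tabular recursion) without forming the full
#' matrix. Base animals (unknown parents) are assumed unrelated and
#' non-inbred; an animal with one known parent is a half-founder whose
#' unknown side contributes zero relationship.
#'
#' @param ped pedigree_table (acyclicity already verified at construction).
#' @return Object of class `inbreeding_vector`: named numeric vector of F in
#'   `[0, 1)` with attribute `method = "pedigree"`.
#' @export
wright_inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree_table"))
  n <- nrow(ped)
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  topo <- attr(ped, "topo_order")
  pos <- integer(n); pos[topo] <- seq_len(n)   # topological rank
  FF <- numeric(n)
  # D_j of the A = T D T' decomposition, filled as F of parents becomes known
  Dj <- function(j) {
    fs <- if (is.na(si[j])) -1 else FF[si[j]]   # -1 encodes unknown parent
    fd <- if (is.na(di[j])) -1 else FF[di[j]]
    if (fs < 0 && fd < 0) return(1)
    if (fs < 0) return(0.75 - 0.25 * fd)
    if (fd < 0) return(0.75 - 0.25 * fs)
    0.5 - 0.25 * (fs + fd)
  }
  for (i in topo) {
    s <- si[i]; d <- di[i]
    if (is.na(s) || is.na(d)) { FF[i] <- 0; next }
    # kinship f(s, d) = 0.5 * sum_j w_s[j] w_d[j] D_j over common ancestors,
    # where w are the gene-flow (T) rows of s and d
    w_s <- .gene_flow_row(s, si, di, pos, n)
    w_d <- .gene_flow_row(d, si, di, pos, n)
    common <- intersect(names(w_s), names(w_d))
    if (!length(common)) { FF[i] <- 0; next }
    dd <- vapply(as.integer(common), Dj, numeric(1))
    FF[i] <- 0.5 * sum(w_s[common] * w_d[common] * dd)
  }
  structure(stats::setNames(FF, ped$animal), method = "pedigree",
            class = "inbreeding_vector")
}

# row of the gene-flow matrix T for one animal: named vector of coefficients
# over its ancestor set (names are animal indices as strings)
.gene_flow_row <- function(a, si, di, pos, n) {
  w <- numeric(n)
  w[a] <- 1
  active <- a
  # process in decreasing topological rank so each node is final when popped
  while (length(active)) {
    j <- active[which.max(pos[active])]
    active <- setdiff(active, j)
    for (p in c(si[j], di[j])) {
      if (!is.na(p)) {
        if (w[p] == 0) active <- c(active, p)
        w[p] <- w[p] + 0.5 * w[j]
      }
    }
  }
  idx <- which(w > 0)
  stats::setNames(w[idx], as.character(idx))
}

#' Pedigree depth statistics
#'
#' Per-animal *equivalent complete generations*, the sum over all known
#' ancestors of (1/2)^g with g the generation distance (parents g = 1),
#' computed by the recursion `ecg(i) = sum over known parents of
#' 0.5 * (1 + ecg(parent))`. A simple maximum-generation count is also
#' emitted, plus the population means of both.
#'
#' @param ped pedigree_table.
#' @return list: `per_animal` (data.frame animal, depth_equivalent,
#'   depth_max), `mean_equivalent`, `mean_max`.
#' @export
pedigree_depth <- function(ped) {
  stopifnot(inherits(ped, "pedigree_table"))
  n <- nrow(ped)
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  ecg <- numeric(n); mx <- integer(n)
  for (i in attr(ped, "topo_order")) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        ecg[i] <- ecg[i] + 0.5 * (1 + ecg[p])
        mx[i] <- max(mx[i], 1L + mx[p])
      }
    }
  }
  list(per_animal = data.frame(animal = ped$animal, depth_equivalent = ecg,
                               depth_max = mx, stringsAsFactors = FALSE),
       mean_equivalent = mean(ecg), mean_max = mean(mx))
}

#' Build an inbreeding vector
#'
#' @param x named numeric vector (animal/sample id -> F).
#' @param method one of "pedigree", "roh", "snp".
#' @return `inbreeding_vector`.
#' @export
inbreeding_vector <- function(x, method = c("pedigree", "roh", "snp")) {
  method <- match.arg(method)
  stopifnot(!is.null(names(x)))
  structure(x, method = method, class = "inbreeding_vector")
}

#' @export
print.inbreeding_vector <- function(x, ...) {
  cat(sprintf("inbreeding_vector (%s): %d animals, mean F = %.4f\n",
              attr(x, "method"), length(x), mean(x, na.rm = TRUE)))
  invisible(x)
}

#' Pearson comparison of two inbreeding vectors
#'
#' Correlates two estimators over their shared animals. Zero variance in
#' either vector makes the correlation undefined (NA with a warning), never
#' silently zero.
#'
#' @param a,b inbreeding_vector (or named numeric) objects.
#' @return list: `r` (Pearson correlation), `n` (shared animals used),
#'   `methods` (the two method tags).
#' @export
compare_inbreeding <- function(a, b) {
  shared <- intersect(names(a), names(b))
  shared <- shared[!is.na(a[shared]) & !is.na(b[shared])]
  if (length(shared) < 3)
    stop("need at least 3 shared animals, got ", length(shared))
  va <- as.numeric(a[shared]); vb <- as.numeric(b[shared])
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("zero variance in one estimator; correlation undefined")
    r <- NA_real_
  } else r <- stats::cor(va, vb)
  list(r = r, n = length(shared),
       methods = c(attr(a, "method") %||% "a", attr(b, "method") %||% "b"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
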
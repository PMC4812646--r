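#' Simulation configuration
#'
#' Validated parameter bundle for the forward Wright-Fisher simulator. The
#' defaults emulate a commercial pig nucleus at desk scale: a handful of
#' autosomes of 1 Morgan mapped at 1 Morgan = 100 Mb (consistent with the
#' 1 cM ~ 1 Mb rule used by the Ne module), equally spaced SNPs, founder
#' minor allele frequencies uniform on [0.05, 0.5], recent Ne in the tens
#' to low hundreds, and random mating.
#'
#' @param seed mandatory integer seed; every run is reproducible from it.
#' @param n_generations number of generations simulated after the founders.
#' @param N population size: a scalar (constant) or a vector of length
#'   `n_generations + 1` giving the size of generations 0 (founders) .. T.
#' @param n_chromosomes number of autosomes.
#' @param chrom_length_morgan chromosome length(s) in Morgan (recycled).
#' @param n_snps_per_chrom SNPs per chromosome (recycled).
#' @param maf_range founder allele-frequency sampler bounds (uniform).
#' @param mating `"random_monogamous"` (males and females paired without
#'   replacement each generation, offspring assigned to random pairs) or
#'   `"random_polygamous"` (each offspring draws a random sire and dam).
#' @param split optional `list(generation =, sizes = c(n1, n2))`: at that
#'   generation the population divides into two isolated daughter
#'   populations which evolve independently to the end.
#' @param missing_rate,genotype_error_rate degradation rates in [0, 1)
#'   applied to the exported genotypes.
#' @param export `"last"` (final-generation individuals only) or `"all"`.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed, n_generations, N, n_chromosomes = 10,
                       chrom_length_morgan = 1, n_snps_per_chrom = 2000,
                       maf_range = c(0.05, 0.5),
                       mating = c("random_monogamous", "random_polygamous"),
                       split = NULL, missing_rate = 0,
                       genotype_error_rate = 0,
                       export = c("last", "all")) {
  mating <- match.arg(mating)
  export <- match.arg(export)
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_generations >= 0, n_chromosomes >= 1,
            all(chrom_length_morgan > 0), all(n_snps_per_chrom >= 1),
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate < 1,
            genotype_error_rate >= 0, genotype_error_rate < 1)
  Nvec <- if (length(N) == 1) rep(as.integer(N), n_generations + 1)
          else as.integer(N)
  if (length(Nvec) != n_generations + 1)
    stop("N must be scalar or length n_generations + 1")
  if (any(Nvec < 1)) stop("population sizes must be positive")
  if (mating == "random_monogamous" && any(Nvec[-1] >= 1) &&
      any(Nvec[-length(Nvec)] < 2))
    stop("random_monogamous mating needs N >= 2 in every parent generation")
  if (!is.null(split)) {
    stopifnot(is.list(split), !is.null(split$generation),
              length(split$sizes) == 2)
    if (split$generation >= n_generations)
      stop("split generation must be < n_generations")
    if (sum(split$sizes) > Nvec[split$generation + 1])
      stop("daughter sizes exceed parent population size")
  }
  structure(list(seed = as.integer(seed), n_generations = n_generations,
                 N = Nvec, n_chromosomes = n_chromosomes,
                 chrom_length_morgan = rep(chrom_length_morgan,
                                           length.out = n_chromosomes),
                 n_snps_per_chrom = rep(as.integer(n_snps_per_chrom),
                                        length.out = n_chromosomes),
                 maf_range = maf_range, mating = mating, split = split,
                 missing_rate = missing_rate,
                 genotype_error_rate = genotype_error_rate,
                 export = export),
            class = "sim_config")
}

# deterministic equally spaced SNP map; 1 Morgan = 100 Mb
.sim_map <- function(config) {
  nc <- config$n_chromosomes
  chrom <- character(0); pos_bp <- numeric(0); pos_M <- numeric(0)
  starts <- integer(nc); ends <- integer(nc)
  off <- 0L
  for (k in seq_len(nc)) {
    m <- config$n_snps_per_chrom[k]
    L <- config$chrom_length_morgan[k]
    pm <- (seq_len(m) - 0.5) * L / m
    chrom <- c(chrom, rep(as.character(k), m))
    pos_M <- c(pos_M, pm)
    pos_bp <- c(pos_bp, round(pm * 1e8))
    starts[k] <- off + 1L; ends[k] <- off + m
    off <- off + m
  }
  list(chromosome = chrom, position_bp = pos_bp, pos_M = pos_M,
       chrom_start = starts, chrom_end = ends,
       chrom_length_M = config$chrom_length_morgan,
       snp_id = sprintf("snp_c%02d_%05d",
                        rep(seq_len(nc), config$n_snps_per_chrom),
                        unlist(lapply(config$n_snps_per_chrom, seq_len))))
}

# one recombinant gamete from parent haplotype rows r1/r2 (Poisson
# crossovers, uniform positions, no interference)
.meiosis <- function(H, Fid, r1, r2, map) {
  m <- ncol(H)
  allele <- integer(m); fid <- integer(m)
  for (k in seq_along(map$chrom_start)) {
    idx <- map$chrom_start[k]:map$chrom_end[k]
    L <- map$chrom_length_M[k]
    nx <- stats::rpois(1, L)
    phase <- sample.int(2L, 1L)
    if (nx == 0L) {
      src <- if (phase == 1L) r1 else r2
      allele[idx] <- H[src, idx]; fid[idx] <- Fid[src, idx]
    } else {
      xo <- sort(stats::runif(nx, 0, L))
      seg <- findInterval(map$pos_M[idx], xo)
      use1 <- (seg + phase) %% 2L == 0L
      a1 <- H[r1, idx]; a2 <- H[r2, idx]
      f1 <- Fid[r1, idx]; f2 <- Fid[r2, idx]
      a1[!use1] <- a2[!use1]; f1[!use1] <- f2[!use1]
      allele[idx] <- a1; fid[idx] <- f1
    }
  }
  list(allele = allele, fid = fid)
}

# sexes with both present (required by mating); deterministic under seed
.draw_sexes <- function(n) {
  if (n == 1) return(sample(1:2, 1))
  repeat {
    s <- sample(1:2, n, replace = TRUE)
    if (any(s == 1) && any(s == 2)) return(s)
  }
}

.wf_engine <- function(config) {
  map <- .sim_map(config)
  m <- length(map$position_bp)
  ped_an <- character(0); ped_si <- character(0); ped_da <- character(0)
  ped_sx <- integer(0); ped_by <- integer(0)
  counter <- 0L
  new_ids <- function(n) {
    ids <- sprintf("A%06d", counter + seq_len(n))
    counter <<- counter + n
    ids
  }
  N0 <- config$N[1]
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  H <- matrix(0L, 2 * N0, m)
  for (k in seq_len(2 * N0))
    H[k, ] <- as.integer(stats::runif(m) < p)
  Fid <- matrix(rep(seq_len(2 * N0), m), 2 * N0, m)
  ids <- new_ids(N0)
  sex <- rep_len(c(1L, 2L), N0)          # founders alternate M/F
  ped_an <- c(ped_an, ids); ped_si <- c(ped_si, rep("0", N0))
  ped_da <- c(ped_da, rep("0", N0)); ped_sx <- c(ped_sx, sex)
  ped_by <- c(ped_by, rep(0L, N0))
  pops <- list(list(H = H, Fid = Fid, ids = ids, sex = sex))
  pop_labels <- "P1"
  exported <- list()
  record_gen <- function(pop, label, gen) {
    exported[[length(exported) + 1L]] <<-
      list(H = pop$H, Fid = pop$Fid, ids = pop$ids, sex = pop$sex,
           population = label, generation = gen)
  }
  if (config$export == "all") record_gen(pops[[1]], "P1", 0L)

  advance <- function(pop, n_off, gen) {
    males <- which(pop$sex == 1L); females <- which(pop$sex == 2L)
    if (!length(males) || !length(females))
      stop("no valid mating pair (single-sex generation)")
    if (config$mating == "random_monogamous") {
      np <- min(length(males), length(females))
      pm <- sample(males)[seq_len(np)]
      pf <- sample(females)[seq_len(np)]
      pick <- sample.int(np, n_off, replace = TRUE)
      sires <- pm[pick]; dams <- pf[pick]
    } else {
      sires <- males[sample.int(length(males), n_off, replace = TRUE)]
      dams <- females[sample.int(length(females), n_off, replace = TRUE)]
    }
    newH <- matrix(0L, 2 * n_off, m)
    newF <- matrix(0L, 2 * n_off, m)
    for (i in seq_len(n_off)) {
      g1 <- .meiosis(pop$H, pop$Fid, 2 * sires[i] - 1L, 2 * sires[i], map)
      g2 <- .meiosis(pop$H, pop$Fid, 2 * dams[i] - 1L, 2 * dams[i], map)
      newH[2 * i - 1L, ] <- g1$allele; newH[2 * i, ] <- g2$allele
      newF[2 * i - 1L, ] <- g1$fid;    newF[2 * i, ] <- g2$fid
    }
    off_ids <- new_ids(n_off)
    off_sex <- .draw_sexes(n_off)
    ped_an <<- c(ped_an, off_ids)
    ped_si <<- c(ped_si, pop$ids[sires])
    ped_da <<- c(ped_da, pop$ids[dams])
    ped_sx <<- c(ped_sx, off_sex)
    ped_by <<- c(ped_by, rep(gen, n_off))
    list(H = newH, Fid = newF, ids = off_ids, sex = off_sex)
  }

  for (gen in seq_len(config$n_generations)) {
    n_here <- config$N[gen + 1]
    if (length(pops) == 1L) {
      pops[[1]] <- advance(pops[[1]], n_here, gen)
    } else {
      for (pk in 1:2)
        pops[[pk]] <- advance(pops[[pk]], config$split$sizes[pk], gen)
    }
    if (!is.null(config$split) && gen == config$split$generation &&
        length(pops) == 1L) {
      sz <- config$split$sizes
      sel <- sample.int(length(pops[[1]]$ids), sum(sz))
      g1 <- sel[seq_len(sz[1])]; g2 <- sel[sz[1] + seq_len(sz[2])]
      take <- function(pop, g) {
        rows <- as.vector(rbind(2 * g - 1L, 2 * g))
        list(H = pop$H[rows, , drop = FALSE],
             Fid = pop$Fid[rows, , drop = FALSE],
             ids = pop$ids[g], sex = pop$sex[g])
      }
      pops <- list(take(pops[[1]], g1), take(pops[[1]], g2))
      pop_labels <- c("P1", "P2")
    }
    if (config$export == "all")
      for (pk in seq_along(pops)) record_gen(pops[[pk]], pop_labels[pk], gen)
  }
  if (config$export == "last")
    for (pk in seq_along(pops))
      record_gen(pops[[pk]], pop_labels[pk], config$n_generations)

  ped <- pedigree_table(data.frame(animal = ped_an, sire = ped_si,
                                   dam = ped_da, sex = ped_sx,
                                   birth_year = ped_by,
                                   stringsAsFactors = FALSE))
  snps <- data.frame(snp_id = map$snp_id, chromosome = map$chromosome,
                     position_bp = map$position_bp,
                     allele_a1 = "A", allele_a2 = "G",
                     stringsAsFactors = FALSE)
  build_ds <- function(label) {
    exp_here <- Filter(function(e) e$population == label, exported)
    ids <- unlist(lapply(exp_here, `[[`, "ids"))
    sexes <- unlist(lapply(exp_here, `[[`, "sex"))
    calls <- do.call(rbind, lapply(exp_here, function(e) {
      odd <- seq(1L, nrow(e$H), 2L)
      e$H[odd, , drop = FALSE] + e$H[odd + 1L, , drop = FALSE]
    }))
    rownames(calls) <- NULL
    genotype_dataset(
      data.frame(sample_id = ids, population = label, sex = sexes,
                 stringsAsFactors = FALSE),
      snps, calls, autosomes = as.character(seq_len(config$n_chromosomes)))
  }
  datasets <- lapply(pop_labels, build_ds)
  names(datasets) <- pop_labels
  fid1 <- list(); fid2 <- list(); hp1 <- list(); hp2 <- list()
  for (e in exported) {
    odd <- seq(1L, nrow(e$Fid), 2L)
    f1 <- e$Fid[odd, , drop = FALSE]; f2 <- e$Fid[odd + 1L, , drop = FALSE]
    h1 <- e$H[odd, , drop = FALSE];  h2 <- e$H[odd + 1L, , drop = FALSE]
    rownames(f1) <- rownames(f2) <- rownames(h1) <- rownames(h2) <- e$ids
    fid1[[length(fid1) + 1L]] <- f1; fid2[[length(fid2) + 1L]] <- f2
    hp1[[length(hp1) + 1L]] <- h1; hp2[[length(hp2) + 1L]] <- h2
  }
  truth <- structure(list(
    pedigree = ped,
    fid_gamete1 = do.call(rbind, fid1),
    fid_gamete2 = do.call(rbind, fid2),
    hap_gamete1 = do.call(rbind, hp1),
    hap_gamete2 = do.call(rbind, hp2),
    map = map,
    N_history = config$N,
    split_generation = if (is.null(config$split)) NA_integer_
                       else config$split$generation,
    config = config), class = "sim_truth")
  list(datasets = datasets, truth = truth)
}

#' Forward Wright-Fisher simulation
#'
#' Diploid forward simulation with recombination (Poisson crossovers, no
#' interference), recorded pedigree and founder-haplotype tracking. Founders
#' carry 2N distinct haplotype labels whose SNP alleles are drawn per SNP
#' from the uniform MAF sampler; each offspring draws parents under the
#' configured mating scheme and each gamete recombines independently. The
#' founder label carried at every SNP by every exported gamete is recorded,
#' giving per-individual true autozygosity (see [true_autozygosity()]).
#' Fully reproducible from `config$seed`.
#'
#' @param config [sim_config()] without a split spec.
#' @return list: `dataset` (genotype_dataset, degraded per the configured
#'   missing/error rates), `truth` (`sim_truth`: full pedigree, founder
#'   labels and phased alleles per exported gamete, SNP map, N history).
#'   `truth$hap_gamete1/2` give the exact phased haplotypes, enabling
#'   phased-counting LD as an oracle for the unphased EM estimates.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$split))
    stop("config has a split spec; use split_populations()")
  res <- .with_seed(config$seed, .wf_engine(config))
  ds <- res$datasets[[1]]
  if (config$missing_rate > 0 || config$genotype_error_rate > 0)
    ds <- degrade(ds, config$missing_rate, config$genotype_error_rate,
                  seed = config$seed + 1L)
  list(dataset = ds, truth = res$truth)
}

#' Simulate a population split
#'
#' As [simulate_population()], but at `config$split$generation` the
#' population divides into two isolated daughter populations of the
#' configured sizes which then evolve independently to the final
#' generation. Both datasets share one pedigree/truth object.
#'
#' @param config [sim_config()] with a split spec.
#' @return list: `pop1`, `pop2` (genotype_dataset) and `truth`.
#' @export
split_populations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$split)) stop("config has no split spec")
  res <- .with_seed(config$seed, .wf_engine(config))
  d1 <- res$datasets[["P1"]]; d2 <- res$datasets[["P2"]]
  if (config$missing_rate > 0 || config$genotype_error_rate > 0) {
    d1 <- degrade(d1, config$missing_rate, config$genotype_error_rate,
                  seed = config$seed + 1L)
    d2 <- degrade(d2, config$missing_rate, config$genotype_error_rate,
                  seed = config$seed + 2L)
  }
  list(pop1 = d1, pop2 = d2, truth = res$truth)
}

#' Inject missingness and genotype errors
#'
#' Each call is independently set missing with probability `missing_rate`;
#' each surviving call is replaced by a uniformly chosen *different* valid
#' code with probability `error_rate`. Seeded and side-effect free on the
#' caller's RNG.
#'
#' @param ds genotype_dataset.
#' @param missing_rate,error_rate rates in [0, 1).
#' @param seed integer seed.
#' @return Degraded genotype_dataset.
#' @export
degrade <- function(ds, missing_rate, error_rate, seed) {
  stopifnot(inherits(ds, "genotype_dataset"),
            missing_rate >= 0, missing_rate < 1,
            error_rate >= 0, error_rate < 1)
  .with_seed(seed, {
    calls <- ds$calls
    nm <- length(calls)
    if (missing_rate > 0)
      calls[stats::runif(nm) < missing_rate] <- NA_integer_
    if (error_rate > 0) {
      hit <- which(!is.na(calls) & stats::runif(nm) < error_rate)
      if (length(hit)) {
        shift <- sample.int(2L, length(hit), replace = TRUE)
        calls[hit] <- (calls[hit] + shift) %% 3L
      }
    }
    genotype_dataset(ds$samples, ds$snps, calls, autosomes = ds$autosomes,
                     sort_snps = FALSE)
  })
}

#' True autozygosity from the founder-haplotype mosaic
#'
#' The fraction of the genome (in Morgan) where an individual's two gametes
#' carry the same founder haplotype label. Founder labels are tracked at SNP
#' resolution; intervals are reconstructed with boundaries at the genetic
#' midpoints between adjacent SNPs (extended to the chromosome ends), which
#' tile each chromosome exactly.
#'
#' @param truth `sim_truth` from the simulator.
#' @param individual sample id of a simulated (exported) individual.
#' @return list: `fraction` in [0, 1] (Morgan-weighted), `intervals`
#'   (data.frame chromosome, start_M, end_M of autozygous stretches).
#' @export
true_autozygosity <- function(truth, individual) {
  stopifnot(inherits(truth, "sim_truth"))
  k <- match(individual, rownames(truth$fid_gamete1))
  if (is.na(k)) stop("unknown individual: ", individual)
  eq <- truth$fid_gamete1[k, ] == truth$fid_gamete2[k, ]
  map <- truth$map
  total_L <- sum(map$chrom_length_M)
  auto_len <- 0
  iv <- list()
  for (ch in seq_along(map$chrom_start)) {
    idx <- map$chrom_start[ch]:map$chrom_end[ch]
    pm <- map$pos_M[idx]
    L <- map$chrom_length_M[ch]
    mids <- c(0, (pm[-1] + pm[-length(pm)]) / 2, L)
    w <- diff(mids)
    e <- eq[idx]
    auto_len <- auto_len + sum(w[e])
    if (any(e)) {
      r <- rle(e)
      en <- cumsum(r$lengths); st <- en - r$lengths + 1L
      st <- st[r$values]; en <- en[r$values]
      iv[[length(iv) + 1L]] <- data.frame(
        chromosome = as.character(ch), start_M = mids[st],
        end_M = mids[en + 1L], stringsAsFactors = FALSE)
    }
  }
  list(fraction = auto_len / total_L,
       intervals = if (length(iv)) do.call(rbind, iv)
                   else data.frame(chromosome = character(0),
                                   start_M = numeric(0),
                                   end_M = numeric(0)))
}

#' True autozygosity for all exported individuals
#'
#' @param truth `sim_truth`.
#' @return Named numeric vector of Morgan-weighted autozygous fractions.
#' @export
true_autozygosity_all <- function(truth) {
  ids <- rownames(truth$fid_gamete1)
  vapply(ids, function(id) true_autozygosity(truth, id)$fraction,
         numeric(1))
}

#' Founder-haplotype mosaic of one gamete
#'
#' Reconstructs the interval representation (tiling each chromosome) of the
#' founder labels carried by one gamete of an exported individual.
#'
#' @param truth `sim_truth`.
#' @param individual sample id.
#' @param gamete 1 (paternal) or 2 (maternal).
#' @return data.frame: chromosome, start_M, end_M, founder_haplotype_id.
#' @export
founder_mosaic <- function(truth, individual, gamete = 1) {
  stopifnot(inherits(truth, "sim_truth"), gamete %in% 1:2)
  mat <- if (gamete == 1) truth$fid_gamete1 else truth$fid_gamete2
  k <- match(individual, rownames(mat))
  if (is.na(k)) stop("unknown individual: ", individual)
  map <- truth$map
  out <- list()
  for (ch in seq_along(map$chrom_start)) {
    idx <- map$chrom_start[ch]:map$chrom_end[ch]
    pm <- map$pos_M[idx]
    L <- map$chrom_length_M[ch]
    mids <- c(0, (pm[-1] + pm[-length(pm)]) / 2, L)
    f <- mat[k, idx]
    r <- rle(f)
    en <- cumsum(r$lengths); st <- en - r$lengths + 1L
    out[[ch]] <- data.frame(chromosome = as.character(ch),
                            start_M = mids[st], end_M = mids[en + 1L],
                            founder_haplotype_id = r$values,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
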
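# in-code fixture builders shared across test files

# quick dataset from a call matrix (rows = samples)
make_ds <- function(calls, chromosome = NULL, position_bp = NULL,
                    sex = NULL, population = "P1",
                    autosomes = as.character(1:18)) {
  calls <- as.matrix(calls)
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(chromosome)) chromosome <- rep("1", m)
  if (is.null(position_bp)) position_bp <- seq_len(m) * 1000
  if (is.null(sex)) sex <- rep(0L, n)
  genotype_dataset(
    data.frame(sample_id = sprintf("S%03d", seq_len(n)),
               population = population, sex = sex,
               stringsAsFactors = FALSE),
    data.frame(snp_id = sprintf("M%05d", seq_len(m)),
               chromosome = chromosome, position_bp = position_bp,
               allele_a1 = rep("A", m), allele_a2 = rep("G", m),
               stringsAsFactors = FALSE),
    calls, autosomes = autosomes)
}

# random dataset with missingness, HWE genotypes at random frequencies
random_ds <- function(seed, n, m, missing_rate = 0, n_chrom = 1) {
  withr::with_seed(seed, {
    chrom <- as.character(rep_len(seq_len(n_chrom), m))
    chrom <- sort(chrom)
    pos <- unlist(lapply(split(seq_len(m), chrom),
                         function(ix) sort(sample.int(1e7, length(ix)))),
                  use.names = FALSE)
    p <- runif(m, 0.05, 0.95)
    calls <- vapply(seq_len(m), function(k) rbinom(n, 2, p[k]),
                    integer(n))
    calls <- matrix(calls, n, m)
    if (missing_rate > 0)
      calls[runif(n * m) < missing_rate] <- NA_integer_
    make_ds(calls, chromosome = chrom, position_bp = pos)
  })
}

# random valid pedigree: generations of size ~gen_size, parents drawn from
# the previous generation
random_pedigree <- function(seed, n_gens = 5, gen_size = 20) {
  withr::with_seed(seed, {
    an <- sprintf("F%03d", seq_len(gen_size))
    sire <- rep("0", gen_size); dam <- rep("0", gen_size)
    sex <- rep_len(1:2, gen_size); by <- rep(0L, gen_size)
    prev <- data.frame(animal = an, sex = sex)
    for (g in seq_len(n_gens)) {
      males <- prev$animal[prev$sex == 1]
      females <- prev$animal[prev$sex == 2]
      ids <- sprintf("G%d_%03d", g, seq_len(gen_size))
      s <- sample(males, gen_size, replace = TRUE)
      d <- sample(females, gen_size, replace = TRUE)
      sx <- c(1L, 2L, sample(1:2, gen_size - 2, replace = TRUE))
      an <- c(an, ids); sire <- c(sire, s); dam <- c(dam, d)
      sex <- c(sex, sx); by <- c(by, rep(g, gen_size))
      prev <- data.frame(animal = ids, sex = sx)
    }
    pedigree_table(data.frame(animal = an, sire = sire, dam = dam,
                              sex = sex, birth_year = by,
                              stringsAsFactors = FALSE))
  })
}

# small two-population fixture via the simulator (cached per session)
sim_fixture_env <- new.env()
small_split_fixture <- function() {
  if (is.null(sim_fixture_env$split)) {
    cfg <- sim_config(seed = 2024, n_generations = 8, N = 30,
                      n_chromosomes = 3, n_snps_per_chrom = 400,
                      split = list(generation = 4, sizes = c(15, 15)))
    sim_fixture_env$split <- split_populations(cfg)
  }
  sim_fixture_env$split
}
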
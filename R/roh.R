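#' Detect runs of homozygosity
#'
#' A run of homozygosity is a maximal run of consecutive autosomal SNPs such
#' that *every* contiguous window of `window` SNPs lying wholly inside the
#' run contains at most `max_het_per_window` heterozygous and
#' `max_missing_per_window` missing calls. Runs with fewer than `min_snps`
#' SNPs or spanning less than `min_length_kb` are discarded. In the rare case
#' that two maximal runs overlap (a dirty stretch shared by their window
#' constraints), overlaps are resolved left-greedily: the later run is
#' trimmed to start after the earlier one ends (a sub-run of a valid run is
#' itself valid), then re-checked against the length thresholds.
#'
#' This is a fully specified rule, deliberately simpler than PLINK's
#' proportion-based window-overlap algorithm; see the package README for the
#' divergence. PLINK-style gap/density post-filters are available via
#' `max_gap_kb` and `min_density_kb_per_snp` (both off by default).
#'
#' @param ds genotype_dataset (autosomal SNPs are used; others ignored).
#' @param min_snps minimum SNPs per run (default 50).
#' @param min_length_kb minimum run span in kb (default 1000; 1 kb = 1000
#'   bp).
#' @param window sliding-window size in SNPs (default 50; must be <=
#'   `min_snps`).
#' @param max_het_per_window,max_missing_per_window window tolerances
#'   (default 1 and 1).
#' @param max_gap_kb optional post-filter: split runs at inter-SNP gaps
#'   larger than this (NULL = off).
#' @param min_density_kb_per_snp optional post-filter: drop runs whose
#'   span/SNP exceeds this (NULL = off).
#' @return data.frame of class `roh_segments`: sample_id, chromosome,
#'   start_snp_index, end_snp_index (within-chromosome, inclusive), start_bp,
#'   end_bp, n_snps, length_bp, n_het, n_missing; ordered by (sample,
#'   chromosome, start).
#' @export
detect_roh <- function(ds, min_snps = 50, min_length_kb = 1000,
                       window = 50, max_het_per_window = 1,
                       max_missing_per_window = 1, max_gap_kb = NULL,
                       min_density_kb_per_snp = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"),
            min_snps >= 1, min_length_kb > 0, window >= 1)
  if (window > min_snps)
    stop("window must not exceed min_snps")
  window <- as.integer(window)
  min_snps <- as.integer(min_snps)
  chroms <- intersect(unique(ds$snps$chromosome), ds$autosomes)
  out <- list()
  for (ch in chroms) {
    idx <- which(ds$snps$chromosome == ch)
    pos <- ds$snps$position_bp[idx]
    if (any(diff(pos) <= 0)) stop("unsorted SNPs on chromosome ", ch)
    nm <- length(idx)
    if (nm < window) {
      message("chromosome ", ch, " has ", nm, " SNPs (< window = ", window,
              "); no ROH called there")
      next
    }
    for (s in seq_len(nrow(ds$samples))) {
      g <- ds$calls[s, idx]
      segs <- .roh_one(g, pos, min_snps, min_length_kb, window,
                       max_het_per_window, max_missing_per_window,
                       max_gap_kb, min_density_kb_per_snp)
      if (!is.null(segs)) {
        segs$sample_id <- ds$samples$sample_id[s]
        segs$chromosome <- ch
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (!length(out)) {
    res <- data.frame(sample_id = character(0), chromosome = character(0),
                      start_snp_index = integer(0),
                      end_snp_index = integer(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), length_bp = numeric(0),
                      n_het = integer(0), n_missing = integer(0))
  } else {
    res <- do.call(rbind, out)
    res <- res[, c("sample_id", "chromosome", "start_snp_index",
                   "end_snp_index", "start_bp", "end_bp", "n_snps",
                   "length_bp", "n_het", "n_missing")]
    res <- res[order(res$sample_id, .chrom_rank(res$chromosome,
                                                ds$autosomes),
                     res$start_bp), ]
    rownames(res) <- NULL
  }
  class(res) <- c("roh_segments", "data.frame")
  res
}

# single sample x chromosome ROH scan; g is the genotype vector, pos the
# (sorted) bp positions
.roh_one <- function(g, pos, min_snps, min_length_kb, window,
                     max_het, max_miss, max_gap_kb, min_density) {
  n <- length(g)
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  ch <- cumsum(c(0L, het)); cm <- cumsum(c(0L, mis))
  k <- seq_len(n - window + 1L)
  ok <- (ch[k + window] - ch[k]) <= max_het &
        (cm[k + window] - cm[k]) <= max_miss
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  a <- starts[r$values]; b <- ends[r$values]
  seg_s <- a; seg_e <- b + window - 1L
  # left-greedy overlap resolution between consecutive maximal runs
  if (length(seg_s) > 1) {
    for (i in 2:length(seg_s))
      if (seg_s[i] <= seg_e[i - 1]) seg_s[i] <- seg_e[i - 1] + 1L
  }
  keep <- seg_e - seg_s + 1L >= 1L
  seg_s <- seg_s[keep]; seg_e <- seg_e[keep]
  # optional gap splitting before thresholds
  if (!is.null(max_gap_kb)) {
    ns <- integer(0); ne <- integer(0)
    for (i in seq_along(seg_s)) {
      ss <- seg_s[i]; ee <- seg_e[i]
      if (ee > ss) {
        gaps <- which(diff(pos[ss:ee]) > max_gap_kb * 1000) + ss - 1L
      } else gaps <- integer(0)
      bounds <- c(ss, gaps + 1L); ends2 <- c(gaps, ee)
      ns <- c(ns, bounds); ne <- c(ne, ends2)
    }
    seg_s <- ns; seg_e <- ne
  }
  n_snps <- seg_e - seg_s + 1L
  len <- pos[seg_e] - pos[seg_s] + 1
  keep <- n_snps >= min_snps & len >= min_length_kb * 1000
  if (!is.null(min_density))
    keep <- keep & (len / 1000) / n_snps <= min_density
  if (!any(keep)) return(NULL)
  seg_s <- seg_s[keep]; seg_e <- seg_e[keep]
  data.frame(start_snp_index = seg_s, end_snp_index = seg_e,
             start_bp = pos[seg_s], end_bp = pos[seg_e],
             n_snps = seg_e - seg_s + 1L,
             length_bp = pos[seg_e] - pos[seg_s] + 1,
             n_het = vapply(seq_along(seg_s), function(i)
               sum(het[seg_s[i]:seg_e[i]]), integer(1)),
             n_missing = vapply(seq_along(seg_s), function(i)
               sum(mis[seg_s[i]:seg_e[i]]), integer(1)),
             stringsAsFactors = FALSE)
}

#' ROH-based genomic inbreeding (F_ROH)
#'
#' Per sample, the summed autosomal ROH length divided by the total genome
#' length `L`: `F_ROH = sum_k Length(ROH_k) / L`, with the default
#' L = 2,808,525 kb (total swine autosomal genome length, Sscrofa10.2).
#' Samples listed in `sample_ids` but carrying no segment get F_ROH = 0.
#'
#' @param segments result of [detect_roh()].
#' @param genome_length_kb total genome length in kb (default 2,808,525).
#' @param sample_ids full sample universe; defaults to the samples present
#'   in `segments`.
#' @return `inbreeding_vector` with method `"roh"`.
#' @export
f_roh <- function(segments, genome_length_kb = 2808525,
                  sample_ids = NULL) {
  stopifnot(genome_length_kb > 0)
  if (is.null(sample_ids)) sample_ids <- unique(segments$sample_id)
  tot <- tapply(segments$length_bp, segments$sample_id, sum)
  v <- stats::setNames(rep(0, length(sample_ids)), sample_ids)
  hit <- intersect(names(tot), sample_ids)
  v[hit] <- tot[hit]
  if (any(v > genome_length_kb * 1000))
    stop("total ROH length exceeds genome length; inconsistent units?")
  inbreeding_vector(v / (genome_length_kb * 1000), method = "roh")
}

#' SNP-by-SNP inbreeding (F_SNP)
#'
#' Per sample, the proportion of non-missing genotypes that are homozygous
#' (equivalently 1 minus the observed heterozygosity rate).
#'
#' @param ds genotype_dataset.
#' @return `inbreeding_vector` with method `"snp"`; samples with all calls
#'   missing get NA with a warning.
#' @export
f_snp <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  called <- rowSums(!is.na(ds$calls))
  hom <- rowSums(ds$calls != 1L, na.rm = TRUE)
  v <- ifelse(called > 0, hom / called, NA_real_)
  if (any(called == 0))
    warning(sum(called == 0), " sample(s) with no non-missing calls")
  inbreeding_vector(stats::setNames(v, ds$samples$sample_id),
                    method = "snp")
}

#' Summarize ROH segments
#'
#' Per-sample counts and lengths, the short/long partition at the 5-Mb
#' boundary (strictly below 5 Mb = short), per-population means, and the
#' Pearson correlation between per-sample ROH count and mean segment length.
#'
#' @param segments result of [detect_roh()].
#' @param populations named character vector mapping sample_id to population
#'   label (NULL = single unnamed population).
#' @param boundary_bp short/long boundary (default 5e6).
#' @return list of class `roh_summary`: `per_sample` data.frame (sample_id,
#'   population, n_roh, mean_length_bp, total_length_bp, n_short, n_long),
#'   `per_population` data.frame, `n_vs_length_cor` per population.
#' @export
summarize_roh <- function(segments, populations = NULL, boundary_bp = 5e6) {
  if (!nrow(segments)) {
    warning("no ROH segments; empty summary")
    return(structure(list(per_sample = data.frame(),
                          per_population = data.frame(),
                          n_vs_length_cor = numeric(0)),
                     class = "roh_summary"))
  }
  ids <- unique(segments$sample_id)
  pop_of <- function(s) {
    if (is.null(populations)) "all" else unname(populations[s])
  }
  per <- do.call(rbind, lapply(ids, function(s) {
    x <- segments[segments$sample_id == s, ]
    data.frame(sample_id = s, population = pop_of(s),
               n_roh = nrow(x), mean_length_bp = mean(x$length_bp),
               total_length_bp = sum(x$length_bp),
               n_short = sum(x$length_bp < boundary_bp),
               n_long = sum(x$length_bp >= boundary_bp),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  pops <- unique(per$population)
  per_pop <- do.call(rbind, lapply(pops, function(p) {
    x <- per[per$population == p, ]
    data.frame(population = p, n_samples = nrow(x),
               mean_n_roh = mean(x$n_roh),
               mean_total_length_bp = mean(x$total_length_bp),
               min_total_length_bp = min(x$total_length_bp),
               max_total_length_bp = max(x$total_length_bp),
               mean_segment_length_bp =
                 sum(x$total_length_bp) / sum(x$n_roh),
               frac_short = sum(x$n_short) / sum(x$n_roh),
               stringsAsFactors = FALSE)
  }))
  cors <- vapply(pops, function(p) {
    x <- per[per$population == p, ]
    if (nrow(x) < 3 || stats::sd(x$n_roh) == 0 ||
        stats::sd(x$mean_length_bp) == 0) return(NA_real_)
    stats::cor(x$n_roh, x$mean_length_bp)
  }, numeric(1))
  structure(list(per_sample = per, per_population = per_pop,
                 n_vs_length_cor = stats::setNames(cors, pops)),
            class = "roh_summary")
}

#' @export
print.roh_summary <- function(x, ...) {
  cat("roh_summary over", nrow(x$per_sample), "samples\n")
  print(x$per_population)
  invisible(x)
}

#' Shared runs of homozygosity
#'
#' Groups segments carried by several animals into shared regions. In
#' `match = "exact"` mode (the default, matching the stated definition) a
#' group is a set of segments with identical (chromosome, start_bp, end_bp).
#' In `"overlap"` mode segments on a chromosome are clustered by
#' single-linkage on pairwise overlap >= `min_overlap_bp` and the region
#' reported spans the cluster union. A region is emitted when it has >= 2
#' carriers within one population (`mode = "within"`) or >= 1 carrier in
#' each of two populations (`mode = "between"`).
#'
#' @param segments result of [detect_roh()].
#' @param populations named character vector sample_id -> population label.
#' @param mode `"within"` or `"between"`.
#' @param match `"exact"` or `"overlap"`.
#' @param min_overlap_bp minimum pairwise overlap in overlap mode (default
#'   500,000).
#' @return list: `regions` data.frame (population for within-mode;
#'   chromosome, start_bp, end_bp, carriers per population as
#'   comma-separated ids, carrier counts and fractions), `per_chromosome`
#'   counts table.
#' @export
shared_roh <- function(segments, populations, mode = c("within", "between"),
                       match = c("exact", "overlap"),
                       min_overlap_bp = 5e5) {
  mode <- match.arg(mode); match <- match.arg(match)
  if (any(!segments$sample_id %in% names(populations)))
    stop("unknown population label for sample: ",
         segments$sample_id[!segments$sample_id %in% names(populations)][1])
  segments$population <- unname(populations[segments$sample_id])
  pops <- sort(unique(unname(populations)))
  if (mode == "between" && length(pops) != 2)
    stop("between-mode needs exactly two populations, got ", length(pops))
  pop_sizes <- table(populations[!duplicated(names(populations))])

  group_regions <- function(seg) {
    if (!nrow(seg)) return(NULL)
    if (match == "exact") {
      key <- paste(seg$chromosome, seg$start_bp, seg$end_bp, sep = ":")
      split(seg, key)
    } else {
      out <- list()
      for (ch in unique(seg$chromosome)) {
        x <- seg[seg$chromosome == ch, ]
        x <- x[order(x$start_bp, x$end_bp), ]
        cl <- integer(nrow(x)); cur <- 1L; cl[1] <- 1L
        max_end <- x$end_bp[1]
        if (nrow(x) > 1) for (i in 2:nrow(x)) {
          ov <- min(max_end, x$end_bp[i]) - x$start_bp[i] + 1
          if (ov >= min_overlap_bp) cl[i] <- cur
          else { cur <- cur + 1L; cl[i] <- cur }
          max_end <- max(max_end, x$end_bp[i])
        }
        out <- c(out, split(x, cl))
      }
      out
    }
  }
  region_row <- function(g) {
    carriers <- split(unique(g$sample_id), unname(populations[unique(g$sample_id)]))
    row <- data.frame(chromosome = g$chromosome[1],
                      start_bp = min(g$start_bp), end_bp = max(g$end_bp),
                      stringsAsFactors = FALSE)
    for (p in pops) {
      ids <- carriers[[p]] %||% character(0)
      row[[paste0("carriers_", p)]] <- paste(sort(ids), collapse = ",")
      row[[paste0("n_", p)]] <- length(ids)
      row[[paste0("frac_", p)]] <- length(ids) / as.numeric(pop_sizes[[p]])
    }
    row
  }

  regions <- list()
  if (mode == "within") {
    for (p in pops) {
      gs <- group_regions(segments[segments$population == p, ])
      for (g in gs) if (length(unique(g$sample_id)) >= 2) {
        r <- region_row(g); r$population <- p
        regions[[length(regions) + 1L]] <- r
      }
    }
  } else {
    gs <- group_regions(segments)
    for (g in gs) {
      cnt <- table(unname(populations[unique(g$sample_id)]))
      if (all(pops %in% names(cnt)))
        regions[[length(regions) + 1L]] <- region_row(g)
    }
  }
  reg <- if (length(regions)) do.call(rbind, regions) else data.frame()
  chroms <- unique(segments$chromosome)
  per_chrom <- data.frame(chromosome = chroms,
                          n_regions = vapply(chroms, function(ch)
                            if (nrow(reg)) sum(reg$chromosome == ch)
                            else 0L, numeric(1)),
                          stringsAsFactors = FALSE)
  rownames(per_chrom) <- NULL
  list(regions = reg, per_chromosome = per_chrom)
}

#' Consensus homozygous regions by ROH incidence
#'
#' Computes, at every SNP, the fraction of a population whose ROH cover that
#' SNP, and reports maximal runs of consecutive SNPs whose incidence is at
#' least `incidence_min`.
#'
#' @param segments result of [detect_roh()].
#' @param ds the genotype_dataset the segments were called on (supplies the
#'   SNP grid).
#' @param sample_ids the population to scan (default: all samples in `ds`).
#' @param incidence_min minimum carrier fraction in (0, 1]; values above 1
#'   give an empty result.
#' @return data.frame: chromosome, start_bp, end_bp, n_snps, mean_incidence,
#'   max_incidence.
#' @export
consensus_regions <- function(segments, ds, sample_ids = NULL,
                              incidence_min) {
  stopifnot(incidence_min > 0)
  if (is.null(sample_ids)) sample_ids <- ds$samples$sample_id
  segments <- segments[segments$sample_id %in% sample_ids, ]
  out <- list()
  for (ch in intersect(unique(ds$snps$chromosome), ds$autosomes)) {
    idx <- which(ds$snps$chromosome == ch)
    pos <- ds$snps$position_bp[idx]
    cov <- numeric(length(idx))
    x <- segments[segments$chromosome == ch, ]
    for (i in seq_len(nrow(x))) {
      inside <- pos >= x$start_bp[i] & pos <= x$end_bp[i]
      cov[inside] <- cov[inside] + 1  # one segment per sample per locus
    }
    inc <- cov / length(sample_ids)
    ok <- inc >= incidence_min
    if (!any(ok)) next
    r <- rle(ok)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    s <- s[r$values]; e <- e[r$values]
    out[[length(out) + 1L]] <- data.frame(
      chromosome = ch, start_bp = pos[s], end_bp = pos[e],
      n_snps = e - s + 1L,
      mean_incidence = vapply(seq_along(s), function(i)
        mean(inc[s[i]:e[i]]), numeric(1)),
      max_incidence = vapply(seq_along(s), function(i)
        max(inc[s[i]:e[i]]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chromosome = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snps = integer(0),
                      mean_incidence = numeric(0),
                      max_incidence = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write consensus/shared regions as BED
#'
#' Converts internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention on write.
#'
#' @param regions data.frame with chromosome, start_bp, end_bp.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(regions$chromosome,
                    format(regions$start_bp - 1, scientific = FALSE,
                           trim = TRUE),
                    format(regions$end_bp, scientific = FALSE, trim = TRUE))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
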
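#' Construct a genotype dataset
#'
#' The central container of the pipeline: an ordered set of samples, an
#' ordered SNP map and a samples x SNPs matrix of A1-allele dosages
#' (0, 1, 2; `NA` = missing). SNPs are sorted by (chromosome, position) and
#' the call matrix is permuted accordingly.
#'
#' @param samples data.frame with columns `sample_id`, `population`, `sex`
#'   (1 = male, 2 = female, 0 = unknown; PLINK convention).
#' @param snps data.frame with columns `snp_id`, `chromosome` (string label;
#'   autosomes `"1"`..`"18"`, sex chromosomes `"X"`/`"Y"`, unknown `"0"`),
#'   `position_bp` (1-based; 0 = unknown), `allele_a1`, `allele_a2`.
#' @param calls integer matrix, `nrow(samples)` x `nrow(snps)`, values in
#'   `{0, 1, 2, NA}` counting copies of `allele_a1`.
#' @param autosomes character vector of autosome labels (default `"1".."18"`).
#' @param sort_snps sort the map by (chromosome, position) and permute
#'   `calls` to match (default TRUE).
#' @return Object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(samples, snps, calls,
                             autosomes = as.character(1:18),
                             sort_snps = TRUE) {
  stopifnot(is.data.frame(samples), is.data.frame(snps))
  need_s <- c("sample_id", "population", "sex")
  need_m <- c("snp_id", "chromosome", "position_bp", "allele_a1", "allele_a2")
  if (!all(need_s %in% names(samples)))
    stop("samples must have columns: ", paste(need_s, collapse = ", "))
  if (!all(need_m %in% names(snps)))
    stop("snps must have columns: ", paste(need_m, collapse = ", "))
  samples <- as.data.frame(samples)[need_s]
  snps <- as.data.frame(snps)[need_m]
  samples$sample_id <- as.character(samples$sample_id)
  snps$snp_id <- as.character(snps$snp_id)
  snps$chromosome <- as.character(snps$chromosome)
  snps$position_bp <- as.numeric(snps$position_bp)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(snps))
    stop("calls must be ", nrow(samples), " x ", nrow(snps),
         ", got ", nrow(calls), " x ", ncol(calls))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids")
  if (anyDuplicated(snps$snp_id))
    stop("duplicate SNP ids")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (sort_snps) {
    ord <- order(.chrom_rank(snps$chromosome, autosomes), snps$position_bp)
    snps <- snps[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  for (ch in unique(snps$chromosome)) {
    pos <- snps$position_bp[snps$chromosome == ch]
    if (length(pos) > 1 && any(diff(pos) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  rownames(snps) <- NULL
  rownames(samples) <- NULL
  dimnames(calls) <- list(samples$sample_id, snps$snp_id)
  structure(list(samples = samples, snps = snps, calls = calls,
                 autosomes = autosomes),
            class = "genotype_dataset")
}

# numeric-first chromosome ordering: 1..18, then X, Y, then everything else
.chrom_rank <- function(chrom, autosomes) {
  n <- suppressWarnings(as.numeric(chrom))
  r <- ifelse(!is.na(n) & chrom != "0", n, NA)
  r[chrom == "X"] <- 1e3
  r[chrom == "Y"] <- 1e3 + 1
  r[chrom == "0"] <- 1e3 + 2
  r[is.na(r)] <- 1e3 + 3
  r
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$samples), "samples x", nrow(x$snps),
      "SNPs on", length(unique(x$snps$chromosome)), "chromosome(s)\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing rate %.4f; populations: %s\n", miss,
              paste(unique(x$samples$population), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$calls)

#' Subset a genotype dataset
#'
#' @param ds genotype_dataset.
#' @param samples,snps logical, integer or character index into samples/SNPs
#'   (default: keep all).
#' @return genotype_dataset restricted to the selected rows/columns.
#' @export
subset_dataset <- function(ds, samples = NULL, snps = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  si <- if (is.null(samples)) seq_len(nrow(ds$samples)) else samples
  mi <- if (is.null(snps)) seq_len(nrow(ds$snps)) else snps
  if (is.character(si)) si <- match(si, ds$samples$sample_id)
  if (is.character(mi)) mi <- match(mi, ds$snps$snp_id)
  genotype_dataset(ds$samples[si, , drop = FALSE],
                   ds$snps[mi, , drop = FALSE],
                   ds$calls[si, mi, drop = FALSE],
                   autosomes = ds$autosomes, sort_snps = FALSE)
}

#' Read PLINK text genotypes (.ped/.map)
#'
#' Alleles are recoded to A1 dosage, where A1 is the first allele encountered
#' in file order at each SNP (deterministic; no minor-allele re-polarization).
#' `0 0` allele pairs become missing. SNPs are re-sorted by
#' (chromosome, position) with the call matrix permuted to match.
#'
#' @param ped_path path to .ped (6 leading columns, then 2 allele columns per
#'   SNP).
#' @param map_path path to .map (4 whitespace-separated columns: chromosome,
#'   id, genetic distance, bp position).
#' @param autosomes autosome labels.
#' @return genotype_dataset.
#' @export
read_plink_text <- function(ped_path, map_path,
                            autosomes = as.character(1:18)) {
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  nc <- lengths(map_tok)
  if (any(nc != 4L))
    stop("map format error at line ", which(nc != 4L)[1],
         ": expected 4 columns, got ", nc[nc != 4L][1])
  map <- do.call(rbind, map_tok)
  n_snps <- nrow(map)
  snps <- data.frame(snp_id = map[, 2], chromosome = map[, 1],
                     position_bp = as.numeric(map[, 4]),
                     allele_a1 = NA_character_, allele_a2 = NA_character_,
                     stringsAsFactors = FALSE)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_tok <- strsplit(trimws(ped_lines), "[ \t]+")
  want <- 6L + 2L * n_snps
  nc <- lengths(ped_tok)
  if (any(nc != want))
    stop("ped format error at line ", which(nc != want)[1], ": expected ",
         want, " columns, got ", nc[nc != want][1])
  n <- length(ped_tok)
  ped <- do.call(rbind, ped_tok)
  samples <- data.frame(sample_id = ped[, 2], population = ped[, 1],
                        sex = as.integer(ped[, 5]), stringsAsFactors = FALSE)
  al <- ped[, -(1:6), drop = FALSE]
  ok_sym <- c("A", "C", "G", "T", "0", "1", "2")
  if (!all(al %in% ok_sym)) {
    bad <- which(matrix(!(al %in% ok_sym), nrow = n), arr.ind = TRUE)[1, ]
    stop("ped format error at line ", bad[1], ": allele symbol '",
         al[bad[1], bad[2]], "' outside {A,C,G,T,0,1,2}")
  }
  a1 <- al[, seq(1L, 2L * n_snps, 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * n_snps, 2L), drop = FALSE]
  calls <- matrix(NA_integer_, n, n_snps)
  for (k in seq_len(n_snps)) {
    obs <- c(a1[, k], a2[, k])
    obs <- obs[obs != "0"]
    A1 <- if (length(obs)) obs[1] else NA_character_
    A2 <- if (length(obs)) setdiff(unique(obs), A1) else character(0)
    snps$allele_a1[k] <- A1
    snps$allele_a2[k] <- if (length(A2)) A2[1] else "0"
    if (length(A2) > 1)
      stop("SNP ", snps$snp_id[k], " has >2 alleles")
    g <- (a1[, k] == A1) + (a2[, k] == A1)
    g[a1[, k] == "0" | a2[, k] == "0"] <- NA_integer_
    calls[, k] <- as.integer(g)
  }
  genotype_dataset(samples, snps, calls, autosomes = autosomes)
}

#' Read PLINK binary genotypes (.bed/.bim/.fam)
#'
#' SNP-major bed files only (magic bytes `0x6c 0x1b`, mode byte `0x01`).
#' Two-bit codes follow the PLINK convention: `00` = homozygous A1 (dosage
#' 2), `10` = heterozygous (dosage 1), `11` = homozygous A2 (dosage 0),
#' `01` = missing. A1 is the fifth .bim column, taken as-is.
#'
#' @param bed_path,bim_path,fam_path paths to the file triplet.
#' @param autosomes autosome labels.
#' @return genotype_dataset; identical to [read_plink_text()] on equivalent
#'   data.
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path,
                              autosomes = as.character(1:18)) {
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p)) stop("file not found: ", p)
  bim <- utils::read.table(bim_path, header = FALSE,
                           colClasses = "character")
  if (ncol(bim) != 6) stop("bim format error: expected 6 columns")
  snps <- data.frame(snp_id = bim[, 2], chromosome = bim[, 1],
                     position_bp = as.numeric(bim[, 4]),
                     allele_a1 = bim[, 5], allele_a2 = bim[, 6],
                     stringsAsFactors = FALSE)
  fam_lines <- readLines(fam_path)
  if (length(fam_lines)) {
    fam <- utils::read.table(fam_path, header = FALSE,
                             colClasses = "character")
    if (ncol(fam) < 6) stop("fam format error: expected 6 columns")
    samples <- data.frame(sample_id = fam[, 2], population = fam[, 1],
                          sex = as.integer(fam[, 5]),
                          stringsAsFactors = FALSE)
  } else {
    samples <- data.frame(sample_id = character(0),
                          population = character(0), sex = integer(0))
  }
  n <- nrow(samples); m <- nrow(snps)
  raw <- readBin(bed_path, "raw", n = file.info(bed_path)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("bed format error: bad magic bytes")
  if (raw[3] != as.raw(0x01))
    stop("bed format error: not SNP-major (mode byte != 0x01)")
  bps <- ceiling(n / 4)          # bytes per SNP
  if (length(raw) != 3 + bps * m)
    stop("bed format error: truncated or oversized file (", length(raw),
         " bytes, expected ", 3 + bps * m, ")")
  body <- raw[-(1:3)]
  # unpack 2-bit fields, sample-fastest within byte (little-endian pairs)
  ints <- as.integer(body)
  q <- cbind(ints %% 4L, (ints %/% 4L) %% 4L,
             (ints %/% 16L) %% 4L, ints %/% 64L)
  codes <- matrix(t(q), nrow = 4L * bps)  # (4*bps) x m, sample index in rows
  codes <- codes[seq_len(n), , drop = FALSE]
  lookup <- c(2L, NA_integer_, 1L, 0L)    # 00, 01, 10, 11
  calls <- matrix(lookup[codes + 1L], n, m)
  genotype_dataset(samples, snps, calls, autosomes = autosomes)
}

#' Write PLINK binary genotypes (.bed/.bim/.fam)
#'
#' Emits a SNP-major triplet readable by [read_plink_binary()] and by stock
#' PLINK. The .bim genetic-distance column is written as 0.
#'
#' @param ds genotype_dataset.
#' @param prefix output path prefix; `prefix.bed/.bim/.fam` are created.
#' @return Invisibly, the three file paths.
#' @export
write_plink_binary <- function(ds, prefix) {
  stopifnot(inherits(ds, "genotype_dataset"))
  dir <- dirname(prefix)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  n <- nrow(ds$samples); m <- nrow(ds$snps)
  bim <- data.frame(ds$snps$chromosome, ds$snps$snp_id, 0,
                    format(ds$snps$position_bp, scientific = FALSE,
                           trim = TRUE),
                    ds$snps$allele_a1, ds$snps$allele_a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(ds$samples$population, ds$samples$sample_id,
                    rep(0, n), rep(0, n), ds$samples$sex, rep(-9, n))
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bps <- ceiling(n / 4)
  enc <- c(3L, 2L, 0L)[ds$calls + 1L]     # dosage 0,1,2 -> 11,10,00
  enc[is.na(enc)] <- 1L                   # missing -> 01
  enc <- matrix(enc, n, m)
  if (bps * 4L > n)
    enc <- rbind(enc, matrix(0L, bps * 4L - n, m))  # pad with 00
  w <- c(1L, 4L, 16L, 64L)
  idx <- matrix(seq_len(4L * bps), nrow = 4L)
  bytes <- vapply(seq_len(4L), function(r) enc[idx[r, ], , drop = FALSE] *
                    w[r], matrix(0L, bps, m))
  if (bps == 1L) bytes <- array(bytes, c(1L, m, 4L))
  byte_mat <- bytes[, , 1] + bytes[, , 2] + bytes[, , 3] + bytes[, , 4]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(matrix(byte_mat, bps, m))), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Read a pedigree table
#'
#' Delimited text (tab or comma, auto-detected) with a header naming the five
#' fields `animal`, `sire`, `dam`, `sex`, `birth_year`. Unknown parents are
#' encoded by `sentinel`. Uniqueness of animal ids and acyclicity are
#' verified; the returned table carries a topological order (parents before
#' offspring).
#'
#' @param path file path.
#' @param sentinel unknown-parent code (default `"0"`).
#' @return Object of class `pedigree_table` (a data.frame with attributes
#'   `sentinel` and `topo_order`).
#' @export
read_pedigree <- function(path, sentinel = "0") {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("animal", "sire", "dam", "sex", "birth_year")
  if (!all(need %in% names(df)))
    stop("pedigree header must name: ", paste(need, collapse = ", "))
  pedigree_table(df[need], sentinel = sentinel)
}

#' Construct and validate a pedigree table
#'
#' @param df data.frame with columns animal, sire, dam, sex, birth_year.
#' @param sentinel unknown-parent code.
#' @return `pedigree_table` object.
#' @export
pedigree_table <- function(df, sentinel = "0") {
  df <- as.data.frame(df)
  need <- c("animal", "sire", "dam", "sex", "birth_year")
  if (!all(need %in% names(df)))
    stop("pedigree must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  for (cc in c("animal", "sire", "dam")) df[[cc]] <- as.character(df[[cc]])
  if (anyDuplicated(df$animal))
    stop("duplicate animal id: ", df$animal[duplicated(df$animal)][1])
  n <- nrow(df)
  id <- df$animal
  si <- match(df$sire, id)
  di <- match(df$dam, id)
  si[df$sire == sentinel] <- NA
  di[df$dam == sentinel] <- NA
  orphan <- (is.na(si) & df$sire != sentinel) |
            (is.na(di) & df$dam != sentinel)
  if (any(orphan))
    stop("named parent without a record (and not the sentinel) for animal: ",
         df$animal[orphan][1])
  # Kahn topological sort; leftover nodes expose a cycle
  indeg <- integer(n)
  kids <- vector("list", n)
  for (k in seq_len(n)) {
    for (p in c(si[k], di[k])) if (!is.na(p)) {
      indeg[k] <- indeg[k] + 1L
      kids[[p]] <- c(kids[[p]], k)
    }
  }
  queue <- which(indeg == 0L)
  topo <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    topo <- c(topo, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(topo) < n) {
    left <- setdiff(seq_len(n), topo)
    # walk parent links inside the leftover set to exhibit one cycle
    v <- left[1]; seen <- integer(0)
    while (!(v %in% seen)) {
      seen <- c(seen, v)
      v <- if (!is.na(si[v]) && si[v] %in% left) si[v] else di[v]
    }
    cyc <- seen[which(seen == v):length(seen)]
    stop("pedigree cycle detected: ",
         paste(id[c(cyc, cyc[1])], collapse = " -> "))
  }
  rownames(df) <- NULL
  structure(df, sentinel = sentinel, topo_order = topo,
            sire_idx = si, dam_idx = di,
            class = c("pedigree_table", "data.frame"))
}

#' @export
print.pedigree_table <- function(x, ...) {
  founders <- sum(is.na(attr(x, "sire_idx")) & is.na(attr(x, "dam_idx")))
  cat("pedigree_table:", nrow(x), "animals (", founders, "founders )\n")
  NextMethod()
}
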
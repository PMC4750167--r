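#' Construct a genotype matrix container
#'
#' @param dosages Numeric matrix, animals x SNPs, entries in {0, 1, 2, NA}.
#' @param map Data frame with columns `snp`, `chrom`, `bp` (one row per SNP,
#'   in column order).
#' @param animal_ids Vector of animal identifiers (defaults to rownames).
#' @return Object of class `genotype_matrix` with fields `animal_ids`,
#'   `snp_ids`, `dosages`, `map` (with per-SNP allele frequency `freq`
#'   computed from non-missing calls).
#' @export
genotype_matrix <- function(dosages, map, animal_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(animal_ids)) animal_ids <- seq_len(nrow(dosages))
  stopifnot(nrow(map) == ncol(dosages), length(animal_ids) == nrow(dosages),
            all(c("snp", "chrom", "bp") %in% names(map)))
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  colnames(dosages) <- map$snp
  rownames(dosages) <- as.character(animal_ids)
  map <- map[, c("snp", "chrom", "bp")]
  map$freq <- colMeans(dosages, na.rm = TRUE) / 2
  structure(list(animal_ids = animal_ids, snp_ids = map$snp,
                 dosages = dosages, map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d animals x %d SNPs on %d chromosome(s); %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chrom)),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

check_dosage_tokens <- function(m, path) {
  bad <- which(!(m %in% c(0, 1, 2) | is.na(m)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("%s: non-{0,1,2,NA} dosage token at data line %d", path, bad[1, 1]))
}

#' Read a genotype file
#'
#' Two dialects are supported: `plink_raw` (space separated, header
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one `snp_ALLELE` column per
#' SNP; the counted-allele suffix is stripped from SNP names) and
#' `simple_tsv` (tab separated, first column `animal_id`, one column per
#' SNP). Missing genotypes may be coded `NA`.
#'
#' @param path File path.
#' @param dialect `"plink_raw"` or `"simple_tsv"`.
#' @param map Optional map data frame (`snp`, `chrom`, `bp`); when absent a
#'   placeholder map (single chromosome, index positions) is built.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("plink_raw", "simple_tsv"), map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "plink_raw") {
    dt <- data.table::fread(path, sep = " ", header = TRUE, na.strings = c("NA", "-9"))
    need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(need %in% names(dt)[1:6]))
      stop("not a PLINK .raw header: expected FID IID PAT MAT SEX PHENOTYPE")
    ids <- dt$IID
    m <- as.matrix(dt[, -(1:6)])
    colnames(m) <- sub("_[ACGT0-9]+$", "", colnames(m))
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
    if (names(dt)[1] != "animal_id") stop("simple_tsv must start with an animal_id column")
    ids <- dt$animal_id
    m <- as.matrix(dt[, -1])
  }
  storage.mode(m) <- "double"
  check_dosage_tokens(m, path)
  if (is.null(map))
    map <- data.frame(snp = colnames(m), chrom = 1L, bp = seq_len(ncol(m)),
                      stringsAsFactors = FALSE)
  map <- map[match(colnames(m), map$snp), , drop = FALSE]
  if (anyNA(map$snp)) stop("map does not cover all SNP columns in ", path)
  genotype_matrix(m, map, animal_ids = ids)
}

#' Write a genotype matrix
#'
#' Counterpart of [read_genotypes()]; `plink_raw` fills the pedigree/sex/
#' phenotype columns with zeros unless a pedigree is supplied.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @param dialect `"plink_raw"` or `"simple_tsv"`.
#' @param pedigree Optional pedigree data frame (`animal`, `sire`, `dam`,
#'   optionally `sex`) used to fill PLINK columns.
#' @export
write_genotypes <- function(geno, path, dialect = c("plink_raw", "simple_tsv"),
                            pedigree = NULL) {
  dialect <- match.arg(dialect)
  m <- geno$dosages
  if (dialect == "plink_raw") {
    ids <- as.character(geno$animal_ids)
    pat <- mat <- rep(0L, length(ids)); sex <- rep(0L, length(ids))
    if (!is.null(pedigree)) {
      i <- match(ids, as.character(pedigree$animal))
      pat <- ifelse(is.na(i), 0L, pedigree$sire[i])
      mat <- ifelse(is.na(i), 0L, pedigree$dam[i])
      if ("sex" %in% names(pedigree)) sex <- ifelse(is.na(i), 0L, pedigree$sex[i])
    }
    out <- data.table::data.table(FID = 1L, IID = ids, PAT = pat, MAT = mat,
                                  SEX = sex, PHENOTYPE = -9L)
    gm <- data.table::as.data.table(m)
    names(gm) <- paste0(geno$snp_ids, "_A")
    data.table::fwrite(cbind(out, gm), path, sep = " ", na = "NA", quote = FALSE)
  } else {
    out <- data.table::data.table(animal_id = geno$animal_ids)
    gm <- data.table::as.data.table(m)
    names(gm) <- geno$snp_ids
    data.table::fwrite(cbind(out, gm), path, sep = "\t", na = "NA", quote = FALSE)
  }
  invisible(path)
}

#' Read/write the small tabular companions (map, pedigree, phenotypes)
#'
#' Plain TSVs with headers: map (`snp`, `chrom`, `bp`), pedigree (`animal`,
#' `sire`, `dam`, optional `sex`, `generation`), phenotypes (`animal_id`,
#' `generation`, `hatch`, `y`).
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_map <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  stopifnot(all(c("snp", "chrom", "bp") %in% names(df)))
  df
}

#' @rdname read_map
#' @export
read_pedigree <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  stopifnot(all(c("animal", "sire", "dam") %in% names(df)))
  df
}

#' @rdname read_map
#' @export
read_phenotypes <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  stopifnot(all(c("animal_id", "generation", "hatch", "y") %in% names(df)))
  df
}

#' @rdname read_map
#' @param df Data frame to write.
#' @export
write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Write all artifacts of a simulated population to a directory
#'
#' Produces `genotypes.raw` (PLINK .raw dialect), `map.tsv`, `pedigree.tsv`,
#' `phenotypes.tsv` and `truth.tsv` (true breeding values plus QTL effects).
#'
#' @param pop A `sim_population`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(pop$genotypes, file.path(dir, "genotypes.raw"), "plink_raw",
                  pedigree = pop$pedigree)
  write_tsv(pop$genotypes$map[, c("snp", "chrom", "bp")], file.path(dir, "map.tsv"))
  write_tsv(pop$pedigree, file.path(dir, "pedigree.tsv"))
  write_tsv(pop$phenotypes, file.path(dir, "phenotypes.tsv"))
  truth <- data.frame(animal = pop$pedigree$animal,
                      true_bv = unname(pop$true_bv))
  write_tsv(truth, file.path(dir, "truth.tsv"))
  write_tsv(pop$qtl_truth, file.path(dir, "qtl_effects.tsv"))
  invisible(dir)
}

#' SNP quality control
#'
#' Removes SNPs failing any of three rules, applied in order MAF, missing
#' rate, Mendelian-mismatch rate (each SNP is reported once under the first
#' rule it fails): minor allele frequency below `maf_min`, missing-genotype
#' fraction above `max_missing`, or parent-offspring opposing-homozygote
#' rate above `max_mendel`. The mismatch rate for a SNP is the number of
#' genotyped parent-offspring pairs with opposing homozygotes (0 vs 2)
#' divided by the number of pairs with both members genotyped at that SNP;
#' SNPs with no informative pairs are treated as rate 0. Remaining missing
#' dosages are imputed to the SNP mean.
#'
#' @param geno A [genotype_matrix()].
#' @param pedigree Optional pedigree data frame (`animal`, `sire`, `dam`);
#'   when absent the Mendel rule is vacuous.
#' @param maf_min,max_missing,max_mendel Thresholds (defaults 0.025, 0.05,
#'   0.05).
#' @return List with `genotypes` (filtered, mean-imputed
#'   [genotype_matrix()]) and `report` (data frame `snp`, `reason`, `value`
#'   for each removed SNP).
#' @export
qc_filter <- function(geno, pedigree = NULL, maf_min = 0.025,
                      max_missing = 0.05, max_mendel = 0.05) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, max_missing >= 0, max_missing <= 1,
            max_mendel >= 0, max_mendel <= 1)
  m <- geno$dosages
  p <- colMeans(m, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing SNP
  missing_frac <- colMeans(is.na(m))

  mendel_rate <- rep(0, ncol(m))
  if (!is.null(pedigree)) {
    ids <- as.character(geno$animal_ids)
    kid <- match(as.character(pedigree$animal), ids)
    sire <- match(as.character(pedigree$sire), ids)
    dam <- match(as.character(pedigree$dam), ids)
    pairs <- rbind(cbind(kid, sire), cbind(kid, dam))
    pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
    if (nrow(pairs) > 0L) {
      gk <- m[pairs[, 1], , drop = FALSE]
      gp <- m[pairs[, 2], , drop = FALSE]
      informative <- !is.na(gk) & !is.na(gp)
      opp <- informative & ((gk == 0 & gp == 2) | (gk == 2 & gp == 0))
      n_inf <- colSums(informative)
      mendel_rate <- ifelse(n_inf > 0, colSums(opp) / n_inf, 0)
    }
  }

  reason <- rep(NA_character_, ncol(m))
  value <- rep(NA_real_, ncol(m))
  fail_maf <- maf < maf_min
  fail_miss <- !fail_maf & missing_frac > max_missing
  fail_mend <- !fail_maf & !fail_miss & mendel_rate > max_mendel
  reason[fail_maf] <- "maf"; value[fail_maf] <- maf[fail_maf]
  reason[fail_miss] <- "missing"; value[fail_miss] <- missing_frac[fail_miss]
  reason[fail_mend] <- "mendel"; value[fail_mend] <- mendel_rate[fail_mend]
  drop <- !is.na(reason)
  if (all(drop)) stop("quality control removed every SNP")

  keep <- which(!drop)
  mk <- m[, keep, drop = FALSE]
  if (anyNA(mk)) {
    mu <- colMeans(mk, na.rm = TRUE)
    idx <- which(is.na(mk), arr.ind = TRUE)
    mk[idx] <- mu[idx[, 2]]
  }
  filtered <- structure(list(
    animal_ids = geno$animal_ids, snp_ids = geno$snp_ids[keep],
    dosages = mk,
    map = transform(geno$map[keep, c("snp", "chrom", "bp")],
                    freq = colMeans(mk) / 2)
  ), class = "genotype_matrix")
  report <- data.frame(snp = geno$snp_ids[drop], reason = reason[drop],
                       value = value[drop], stringsAsFactors = FALSE)
  list(genotypes = filtered, report = report)
}
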
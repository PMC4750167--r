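#' Simulation configuration for a multi-generation breeding population
#'
#' Builds and validates the configuration used by [simulate_population()].
#' The simulated design emulates a closed commercial layer line: a small
#' effective population bred by random mating for a number of warm-up
#' generations (building local linkage disequilibrium from a
#' linkage-equilibrium base), followed by discrete recorded generations with
#' phenotypes, hatch-within-generation fixed effects, a polygenic background
#' and one large-effect QTL at a fixed genomic position.
#'
#' @param gen_sizes Integer vector of recorded generation sizes. The default
#'   follows the study design of eight consecutive generations.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Physical length of each chromosome in base pairs.
#' @param chrom_length_morgans Genetic length of each chromosome in Morgans
#'   (Haldane map, no interference).
#' @param n_markers_per_chrom Number of evenly spaced panel markers per
#'   chromosome.
#' @param n_background_qtl Total number of background (polygenic) QTL, spread
#'   evenly across chromosomes at uniform random positions.
#' @param large_qtl List with elements `chrom`, `bp` and `frac`: position of
#'   the large-effect QTL and the fraction of genetic variance it explains in
#'   the founder generation. `frac` must lie in `[0, 1)`.
#' @param h2 Narrow-sense heritability of the trait in `(0, 1]`; founder
#'   genetic variance is fixed at 1 trait unit squared, so the residual
#'   variance is `(1 - h2) / h2`.
#' @param hatches_per_generation Number of hatch classes per generation;
#'   animals are split evenly across classes.
#' @param hatch_effect_sd Standard deviation (trait units) of the
#'   hatch-within-generation fixed effects.
#' @param selection List with `mode` (`"none"` or `"truncation"`) and
#'   `proportion` (fraction of each sex retained as parents under truncation
#'   selection on phenotype).
#' @param founder_maf_range Length-2 numeric in `(0, 0.5]`: per-locus allele
#'   frequencies of the linkage-equilibrium base population are drawn
#'   uniformly from this range.
#' @param n_founders Size of the closed line during warm-up; the last warm-up
#'   generation becomes the pedigree founder generation (generation 0).
#' @param warmup_generations Number of random-mating warm-up generations used
#'   to build LD before generation 1.
#' @param qtl_in_panel If `TRUE`, causal loci are included as panel markers;
#'   by default they are masked, as causal variants are typically absent from
#'   a genotyping chip and must be tagged through LD.
#' @param seed Optional integer seed; when supplied the whole simulation is
#'   bit-reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(gen_sizes = c(295L, 323L, 294L, 360L, 290L, 252L, 300L, 210L),
                       n_chromosomes = 3L,
                       chrom_length_bp = 1e8,
                       chrom_length_morgans = 1,
                       n_markers_per_chrom = 1000L,
                       n_background_qtl = 300L,
                       large_qtl = list(chrom = 1L, bp = 78500000, frac = 0.25),
                       h2 = 0.5,
                       hatches_per_generation = 4L,
                       hatch_effect_sd = 0.5,
                       selection = list(mode = "none", proportion = 1),
                       founder_maf_range = c(0.1, 0.5),
                       n_founders = 50L,
                       warmup_generations = 20L,
                       qtl_in_panel = FALSE,
                       seed = NULL) {
  cfg <- list(
    gen_sizes = as.integer(gen_sizes),
    n_generations = length(gen_sizes),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = chrom_length_bp,
    chrom_length_morgans = chrom_length_morgans,
    n_markers_per_chrom = as.integer(n_markers_per_chrom),
    n_background_qtl = as.integer(n_background_qtl),
    large_qtl = large_qtl,
    h2 = h2,
    hatches_per_generation = as.integer(hatches_per_generation),
    hatch_effect_sd = hatch_effect_sd,
    selection = selection,
    founder_maf_range = founder_maf_range,
    n_founders = as.integer(n_founders),
    warmup_generations = as.integer(warmup_generations),
    qtl_in_panel = isTRUE(qtl_in_panel),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  stopifnot(
    length(cfg$gen_sizes) >= 1L, all(cfg$gen_sizes >= 2L),
    cfg$n_chromosomes >= 1L, cfg$chrom_length_bp > 0,
    cfg$chrom_length_morgans >= 0, cfg$n_markers_per_chrom >= 1L,
    cfg$n_background_qtl >= 0L,
    cfg$h2 > 0, cfg$h2 <= 1,
    cfg$hatches_per_generation >= 1L, cfg$hatch_effect_sd >= 0,
    cfg$n_founders >= 4L, cfg$warmup_generations >= 0L
  )
  if (!is.null(cfg$large_qtl)) {
    stopifnot(
      cfg$large_qtl$frac >= 0, cfg$large_qtl$frac < 1,
      cfg$large_qtl$chrom >= 1L, cfg$large_qtl$chrom <= cfg$n_chromosomes,
      cfg$large_qtl$bp >= 0, cfg$large_qtl$bp < cfg$chrom_length_bp
    )
  }
  mr <- cfg$founder_maf_range
  if (length(mr) != 2L || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
    stop("founder_maf_range must be (lo, hi) within (0, 0.5]")
  if (!cfg$selection$mode %in% c("none", "truncation"))
    stop("selection$mode must be 'none' or 'truncation'")
  if (cfg$selection$mode == "truncation" &&
      (cfg$selection$proportion <= 0 || cfg$selection$proportion > 1))
    stop("selection$proportion must be in (0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

# Locus table for one genome: evenly spaced markers plus QTL at random
# positions; the large QTL at its fixed position. Genetic position in
# Morgans is proportional to bp (uniform map).
build_loci <- function(cfg) {
  per_chrom <- list()
  spacing <- cfg$chrom_length_bp / cfg$n_markers_per_chrom
  bg_per_chrom <- diff(round(seq(0, cfg$n_background_qtl,
                                 length.out = cfg$n_chromosomes + 1L)))
  for (c in seq_len(cfg$n_chromosomes)) {
    mk_bp <- round(spacing / 2 + spacing * (seq_len(cfg$n_markers_per_chrom) - 1L))
    df <- data.frame(
      chrom = c, bp = mk_bp, type = "marker",
      id = sprintf("snp_c%d_%04d", c, seq_along(mk_bp)),
      stringsAsFactors = FALSE
    )
    if (bg_per_chrom[c] > 0L) {
      qb <- sort(round(stats::runif(bg_per_chrom[c], 0, cfg$chrom_length_bp - 1)))
      df <- rbind(df, data.frame(
        chrom = c, bp = qb, type = "bg_qtl",
        id = sprintf("bgqtl_c%d_%03d", c, seq_along(qb)),
        stringsAsFactors = FALSE
      ))
    }
    if (!is.null(cfg$large_qtl) && cfg$large_qtl$frac > 0 &&
        cfg$large_qtl$chrom == c) {
      df <- rbind(df, data.frame(
        chrom = c, bp = cfg$large_qtl$bp, type = "large_qtl",
        id = "qtl_major", stringsAsFactors = FALSE
      ))
    }
    df <- df[order(df$bp), , drop = FALSE]
    df$gpos <- df$bp / cfg$chrom_length_bp * cfg$chrom_length_morgans
    per_chrom[[c]] <- df
  }
  per_chrom
}

#' Sample one gamete from a pair of parental haplotypes
#'
#' Meiosis under a Haldane model: the crossover count on a chromosome is
#' Poisson with mean equal to the chromosome's genetic length, crossover
#' positions are uniform on the genetic map, and there is no interference.
#'
#' @param hap_a,hap_b Integer vectors (0/1 alleles) of the two parental
#'   haplotypes at the chromosome's loci, ordered by position.
#' @param gpos Numeric vector of locus genetic positions in Morgans,
#'   nondecreasing.
#' @param length_morgans Genetic length of the chromosome in Morgans.
#' @return Integer vector: the gamete haplotype.
#' @export
meiosis <- function(hap_a, hap_b, gpos, length_morgans) {
  stopifnot(length(hap_a) == length(hap_b), length(gpos) == length(hap_a))
  if (is.unsorted(gpos)) stop("genetic map positions must be nondecreasing")
  start <- sample.int(2L, 1L)
  k <- if (length_morgans > 0) stats::rpois(1L, length_morgans) else 0L
  if (k == 0L) {
    return(if (start == 1L) hap_a else hap_b)
  }
  xo <- sort(stats::runif(k, 0, length_morgans))
  seg <- findInterval(gpos, xo)
  phase <- (start - 1L + seg) %% 2L
  ifelse(phase == 0L, hap_a, hap_b)
}

# Breed one generation: haplos is a list (per chromosome) of (2N x L)
# matrices, rows 2i-1 and 2i holding individual i's haplotypes. Returns the
# same structure for the offspring defined by parent index vectors.
breed_generation <- function(haplos, loci, sire_idx, dam_idx, cfg) {
  n_off <- length(sire_idx)
  lapply(seq_along(haplos), function(c) {
    H <- haplos[[c]]
    gp <- loci[[c]]$gpos
    out <- matrix(0L, nrow = 2L * n_off, ncol = ncol(H))
    for (o in seq_len(n_off)) {
      s <- sire_idx[o]; d <- dam_idx[o]
      out[2L * o - 1L, ] <- meiosis(H[2L * s - 1L, ], H[2L * s, ], gp,
                                    cfg$chrom_length_morgans)
      out[2L * o, ] <- meiosis(H[2L * d - 1L, ], H[2L * d, ], gp,
                               cfg$chrom_length_morgans)
    }
    out
  })
}

haplos_to_dosage <- function(haplos) {
  do.call(cbind, lapply(haplos, function(H) {
    n <- nrow(H) / 2L
    H[2L * seq_len(n) - 1L, , drop = FALSE] + H[2L * seq_len(n), , drop = FALSE]
  }))
}

#' Simulate the founder generation of a closed line
#'
#' Draws per-locus allele frequencies uniformly from
#' `founder_maf_range`, samples linkage-equilibrium base haplotypes for
#' `n_founders` animals, and runs `warmup_generations` of random mating at
#' that constant size to build local LD by drift and linkage. The large-QTL
#' locus starts at frequency 0.5 in the base so that its target variance
#' fraction is attainable after drift.
#'
#' @param config A [sim_config()] object.
#' @return A list with `loci` (per-chromosome locus tables) and `haplos`
#'   (per-chromosome haplotype matrices of the founder generation).
#' @export
simulate_founders <- function(config) {
  cfg <- config
  if (cfg$n_markers_per_chrom < 1L) stop("zero markers on a chromosome")
  loci <- build_loci(cfg)
  nf <- cfg$n_founders
  haplos <- lapply(loci, function(df) {
    L <- nrow(df)
    p <- stats::runif(L, cfg$founder_maf_range[1], cfg$founder_maf_range[2])
    p[df$type == "large_qtl"] <- 0.5
    matrix(stats::rbinom(2L * nf * L, 1L, rep(p, each = 2L * nf)),
           nrow = 2L * nf, ncol = L)
  })
  for (g in seq_len(cfg$warmup_generations)) {
    sex <- rep(c(1L, 2L), length.out = nf)  # fixed alternating sexes
    males <- which(sex == 1L); females <- which(sex == 2L)
    sire_idx <- sample(males, nf, replace = TRUE)
    dam_idx <- sample(females, nf, replace = TRUE)
    haplos <- breed_generation(haplos, loci, sire_idx, dam_idx, cfg)
  }
  list(loci = loci, haplos = haplos, n_founders = nf)
}

#' Assign QTL effects to reach a target genetic architecture
#'
#' The large-QTL substitution effect `a` solves `2 p (1 - p) a^2 = f_Q *
#' sigma2_g` at the founder-generation allele frequency `p`; background QTL
#' effects are drawn i.i.d. normal and rescaled so that the realized
#' founder-generation background genetic variance equals `(1 - f_Q) *
#' sigma2_g`. Total founder genetic variance is `sigma2_g = 1` trait unit
#' squared by construction.
#'
#' @param config A [sim_config()] object.
#' @param founders Output of [simulate_founders()].
#' @return A data frame (one row per causal locus) with columns `id`,
#'   `chrom`, `bp`, `type`, `effect` and `founder_freq`.
#' @export
assign_effects <- function(config, founders) {
  cfg <- config
  sigma2_g <- 1
  loci_all <- do.call(rbind, founders$loci)
  dos <- haplos_to_dosage(founders$haplos)
  colnames(dos) <- loci_all$id
  qtl <- loci_all[loci_all$type != "marker", , drop = FALSE]
  if (nrow(qtl) == 0L) stop("no causal loci configured")
  Q <- dos[, qtl$id, drop = FALSE]
  p <- colMeans(Q) / 2
  eff <- numeric(nrow(qtl))
  f_q <- if (any(qtl$type == "large_qtl")) cfg$large_qtl$frac else 0
  if (any(qtl$type == "large_qtl")) {
    i <- which(qtl$type == "large_qtl")
    pq <- p[i]
    if (pq <= 0 || pq >= 1)
      stop("large-QTL locus is monomorphic in the founders; cannot reach the target variance fraction")
    eff[i] <- sqrt(f_q * sigma2_g / (2 * pq * (1 - pq)))
  }
  bg <- which(qtl$type == "bg_qtl")
  if (length(bg) > 0L && f_q < 1) {
    b <- stats::rnorm(length(bg))
    gbg <- as.numeric(Q[, bg, drop = FALSE] %*% b)
    v <- stats::var(gbg)
    if (v <= 0) stop("background QTL carry no variance in the founders")
    eff[bg] <- b * sqrt((1 - f_q) * sigma2_g / v)
  }
  data.frame(id = qtl$id, chrom = qtl$chrom, bp = qtl$bp, type = qtl$type,
             effect = eff, founder_freq = unname(p), stringsAsFactors = FALSE)
}

#' Simulate a pedigreed multi-generation population
#'
#' Runs the full generator: founder simulation with warm-up LD build-up,
#' QTL effect assignment, then breeding of the recorded generations with
#' pedigree, genotypes, true breeding values and phenotypes. Phenotypes are
#' `y = hatch effect + g + e` with the residual variance set from `h2` and
#' hatch-within-generation effects drawn `N(0, hatch_effect_sd^2)`.
#'
#' Under truncation selection, parents of each generation are drawn from the
#' top fraction of the previous generation's phenotype distribution within
#' each sex; founders (who have no phenotype) are always sampled at random.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_population`: a list with `pedigree`
#'   (animal, sire, dam, sex, generation; generation 0 are founders),
#'   `genotypes` (a [genotype_matrix()] for the recorded generations),
#'   `phenotypes` (animal_id, generation, hatch, y), `true_bv` (named vector
#'   for all pedigree animals), `qtl_truth`, `realized_h2`,
#'   `realized_qtl_var_fraction` and `founder_tag_r2` (max founder r^2
#'   between a panel marker in the QTL's 1-Mb window and the QTL).
#' @export
simulate_population <- function(config) {
  cfg <- config
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, config)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  founders <- simulate_founders(cfg)
  loci <- founders$loci
  loci_all <- do.call(rbind, loci)
  qtl_truth <- assign_effects(cfg, founders)
  sigma2_e <- (1 - cfg$h2) / cfg$h2
  qtl_cols <- match(qtl_truth$id, loci_all$id)

  panel_keep <- if (cfg$qtl_in_panel) seq_len(nrow(loci_all)) else
    which(loci_all$type == "marker")

  nf <- founders$n_founders
  n_total <- nf + sum(cfg$gen_sizes)
  ped <- data.frame(animal = seq_len(n_total), sire = 0L, dam = 0L,
                    sex = 0L, generation = 0L)
  ped$sex[seq_len(nf)] <- rep(c(1L, 2L), length.out = nf)

  true_bv <- numeric(n_total)
  dose0 <- haplos_to_dosage(founders$haplos)
  true_bv[seq_len(nf)] <- as.numeric(dose0[, qtl_cols, drop = FALSE] %*% qtl_truth$effect)

  # founder-generation diagnostics
  realized_qtl_frac <- NA_real_
  founder_tag_r2 <- NA_real_
  if (any(qtl_truth$type == "large_qtl")) {
    iq <- which(qtl_truth$type == "large_qtl")
    qdos <- dose0[, qtl_cols[iq]]
    realized_qtl_frac <- stats::var(qdos * qtl_truth$effect[iq]) / stats::var(true_bv[seq_len(nf)])
    win <- floor(qtl_truth$bp[iq] / 1e6)
    tags <- which(loci_all$type == "marker" & loci_all$chrom == qtl_truth$chrom[iq] &
                    floor(loci_all$bp / 1e6) == win)
    if (length(tags) > 0L && stats::var(qdos) > 0) {
      r2 <- suppressWarnings(stats::cor(dose0[, tags, drop = FALSE], qdos))^2
      founder_tag_r2 <- max(r2, na.rm = TRUE)
    } else founder_tag_r2 <- 0
    if (!cfg$qtl_in_panel && cfg$warmup_generations >= 5L &&
        (!is.finite(founder_tag_r2) || founder_tag_r2 < 0.2))
      warning(sprintf(
        "max founder r^2 between the large QTL and a same-window marker is %.3f (< 0.2); window detection may be weak",
        founder_tag_r2))
  }

  geno_rows <- vector("list", cfg$n_generations)
  phen_rows <- vector("list", cfg$n_generations)
  haplos <- founders$haplos
  prev_ids <- seq_len(nf)
  prev_phen <- rep(NA_real_, nf)
  next_id <- nf + 1L

  for (g in seq_len(cfg$n_generations)) {
    n_g <- cfg$gen_sizes[g]
    prev_sex <- ped$sex[prev_ids]
    elig_m <- which(prev_sex == 1L)
    elig_f <- which(prev_sex == 2L)
    if (cfg$selection$mode == "truncation" && !all(is.na(prev_phen))) {
      keep_m <- floor(length(elig_m) * cfg$selection$proportion)
      keep_f <- floor(length(elig_f) * cfg$selection$proportion)
      if (keep_m < 1L || keep_f < 1L)
        stop("selection proportion too small to supply parents of both sexes")
      elig_m <- elig_m[order(prev_phen[elig_m], decreasing = TRUE)[seq_len(keep_m)]]
      elig_f <- elig_f[order(prev_phen[elig_f], decreasing = TRUE)[seq_len(keep_f)]]
    }
    if (length(elig_m) < 1L || length(elig_f) < 1L)
      stop("selection proportion too small to supply parents of both sexes")
    sire_idx <- sample(elig_m, n_g, replace = TRUE)
    dam_idx <- sample(elig_f, n_g, replace = TRUE)

    haplos <- breed_generation(haplos, loci, sire_idx, dam_idx, cfg)
    ids <- seq.int(next_id, length.out = n_g)
    next_id <- next_id + n_g
    ped$sire[ids] <- prev_ids[sire_idx]
    ped$dam[ids] <- prev_ids[dam_idx]
    ped$sex[ids] <- rep(c(1L, 2L), length.out = n_g)
    ped$generation[ids] <- g

    dos <- haplos_to_dosage(haplos)
    g_val <- as.numeric(dos[, qtl_cols, drop = FALSE] %*% qtl_truth$effect)
    true_bv[ids] <- g_val

    hatch <- rep(seq_len(cfg$hatches_per_generation), length.out = n_g)
    hatch_eff <- stats::rnorm(cfg$hatches_per_generation, 0, cfg$hatch_effect_sd)
    e <- if (sigma2_e > 0) stats::rnorm(n_g, 0, sqrt(sigma2_e)) else numeric(n_g)
    y <- hatch_eff[hatch] + g_val + e

    geno_rows[[g]] <- dos[, panel_keep, drop = FALSE]
    phen_rows[[g]] <- data.frame(
      animal_id = ids, generation = g,
      hatch = sprintf("g%d_h%d", g, hatch), y = y,
      hatch_effect = hatch_eff[hatch], residual = e
    )
    prev_ids <- ids
    prev_phen <- y
  }

  phen <- do.call(rbind, phen_rows)
  dosages <- do.call(rbind, geno_rows)
  rec_ids <- phen$animal_id
  rownames(dosages) <- as.character(rec_ids)
  map <- data.frame(snp = loci_all$id[panel_keep],
                    chrom = loci_all$chrom[panel_keep],
                    bp = loci_all$bp[panel_keep], stringsAsFactors = FALSE)
  geno <- genotype_matrix(dosages, map, animal_ids = rec_ids)

  g_rec <- true_bv[rec_ids]
  realized_h2 <- stats::var(g_rec) / stats::var(phen$y - phen$hatch_effect)

  names(true_bv) <- as.character(ped$animal)
  out <- list(
    config = cfg,
    pedigree = ped,
    genotypes = geno,
    phenotypes = phen[, c("animal_id", "generation", "hatch", "y")],
    true_bv = true_bv,
    qtl_truth = qtl_truth,
    realized_h2 = realized_h2,
    realized_qtl_var_fraction = realized_qtl_frac,
    founder_tag_r2 = founder_tag_r2
  )
  class(out) <- "sim_population"
  out
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("Simulated population: %d recorded animals in %d generations\n",
              nrow(x$phenotypes), x$config$n_generations))
  cat(sprintf("  panel: %d SNPs on %d chromosomes; causal loci: %d (in panel: %s)\n",
              ncol(x$genotypes$dosages), x$config$n_chromosomes,
              nrow(x$qtl_truth), x$config$qtl_in_panel))
  cat(sprintf("  realized h2 = %.3f; realized large-QTL variance fraction = %.3f\n",
              x$realized_h2, x$realized_qtl_var_fraction))
  cat(sprintf("  max founder tag r2 in QTL window = %.3f\n", x$founder_tag_r2))
  invisible(x)
}
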
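# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cache_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A desk-scale population: 4 generations x 150 animals, 2 chromosomes x
# 200 markers, one large QTL (25 % of genetic variance) masked from the
# panel. Small enough for seconds-scale chains.
small_pop <- function(seed = 7) {
  cache_fixture(paste0("small_pop_", seed), {
    cfg <- sim_config(
      gen_sizes = rep(150L, 4), n_chromosomes = 2L,
      chrom_length_bp = 5e7, chrom_length_morgans = 0.5,
      n_markers_per_chrom = 200L, n_background_qtl = 80L,
      large_qtl = list(chrom = 1L, bp = 22500000, frac = 0.25),
      h2 = 0.5, hatches_per_generation = 2L, hatch_effect_sd = 0.5,
      n_founders = 40L, warmup_generations = 12L, seed = seed
    )
    suppressWarnings(simulate_population(cfg))
  })
}

# Minimal founder object with exact allele frequency 0.5 at every locus,
# no warm-up: for closed-form effect-size checks.
exact_half_founders <- function(n = 40) {
  loci <- data.frame(
    chrom = 1L, bp = c(1e6, 2e6, 78500000),
    type = c("bg_qtl", "marker", "large_qtl"),
    id = c("bg1", "m1", "qtl_major"), stringsAsFactors = FALSE
  )
  loci$gpos <- loci$bp / 1e8
  H <- matrix(rep(c(0L, 1L), each = n, times = 3), nrow = 2 * n, ncol = 3)
  list(loci = list(loci), haplos = list(H), n_founders = n)
}

# Hand-built pedigree with inbred matings (full sibs, parent-offspring),
# parents always listed before offspring.
inbred_pedigree <- function(n = 20) {
  set.seed(99)
  ped <- data.frame(animal = 1:n, sire = 0L, dam = 0L)
  for (i in 5:n) {
    ped$sire[i] <- sample(1:(i - 1), 1)
    repeat {
      d <- sample(1:(i - 1), 1)
      if (d != ped$sire[i]) break
    }
    ped$dam[i] <- d
  }
  ped
}

# Simple deterministic genotype/phenotype pair for sampler oracles.
toy_model_data <- function(n = 150, p = 60, h2 = 0.4, seed = 3) {
  set.seed(seed)
  freq <- runif(p, 0.15, 0.5)
  M <- sapply(freq, function(q) rbinom(n, 2, q))
  colnames(M) <- sprintf("s%03d", seq_len(p))
  map <- data.frame(snp = colnames(M), chrom = 1L, bp = seq_len(p) * 1e5)
  geno <- genotype_matrix(M, map, animal_ids = seq_len(n))
  a <- rnorm(p, 0, sqrt(h2 / (p * mean(2 * freq * (1 - freq)))))
  g <- as.numeric(scale(M, center = 2 * freq, scale = FALSE) %*% a)
  y <- 2 + g + rnorm(n, 0, sqrt(var(g) * (1 - h2) / h2))
  phen <- data.frame(animal_id = seq_len(n), generation = 1L,
                     hatch = rep(c("h1", "h2"), length.out = n), y = y)
  list(geno = geno, phen = phen,
       data = model_data(geno, phen))
}
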
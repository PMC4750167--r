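test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(gen_sizes = rep(40L, 2), n_chromosomes = 1L,
                    chrom_length_bp = 1e7, chrom_length_morgans = 0.2,
                    n_markers_per_chrom = 50L, n_background_qtl = 10L,
                    large_qtl = list(chrom = 1L, bp = 5e6, frac = 0.25),
                    n_founders = 20L, warmup_generations = 3L, seed = 42)
  p1 <- suppressWarnings(simulate_population(cfg))
  p2 <- suppressWarnings(simulate_population(cfg))
  expect_identical(p1$genotypes$dosages, p2$genotypes$dosages)
  expect_identical(p1$phenotypes$y, p2$phenotypes$y)
  expect_identical(p1$pedigree, p2$pedigree)
})

test_that("meiosis respects the genetic map", {
  gpos <- c(0.1, 0.2)
  hapA <- c(0L, 0L); hapB <- c(1L, 1L)
  # zero-length chromosome: gamete is an unrecombined parental copy
  set.seed(1)
  for (i in 1:20) {
    g <- meiosis(hapA, hapB, gpos, 0)
    expect_true(identical(g, hapA) || identical(g, hapB))
  }
  # recombination fraction between loci 0.1 M apart matches Haldane
  set.seed(2)
  n <- 6000
  rec <- replicate(n, {
    g <- meiosis(hapA, hapB, c(0.05, 0.15), 1)
    g[1] != g[2]
  })
  c_exp <- (1 - exp(-0.2)) / 2            # 0.0906
  se <- sqrt(c_exp * (1 - c_exp) / n)
  expect_lt(abs(mean(rec) - c_exp), 3 * se)
  # loci 0.5 M apart on a 1 M chromosome
  set.seed(3)
  rec2 <- replicate(n, {
    g <- meiosis(hapA, hapB, c(0.25, 0.75), 1)
    g[1] != g[2]
  })
  c_exp2 <- (1 - exp(-1)) / 2             # 0.3161
  se2 <- sqrt(c_exp2 * (1 - c_exp2) / n)
  expect_lt(abs(mean(rec2) - c_exp2), 3 * se2)
  # unsorted map rejected
  expect_error(meiosis(hapA, hapB, c(0.2, 0.1), 1), "nondecreasing")
})

test_that("founder generation matches the configured base frequencies", {
  cfg <- sim_config(gen_sizes = c(10L, 10L), n_chromosomes = 1L,
                    chrom_length_bp = 1e7, chrom_length_morgans = 0.1,
                    n_markers_per_chrom = 200L, n_background_qtl = 0L,
                    large_qtl = NULL, founder_maf_range = c(0.5, 0.5),
                    n_founders = 400L, warmup_generations = 0L, seed = 5)
  set.seed(5)
  f <- simulate_founders(cfg)
  freq <- colMeans(f$haplos[[1]])
  se <- sqrt(0.25 / (2 * 400))
  expect_lt(max(abs(freq - 0.5)), 5 * se)
  # no warm-up: loci essentially uncorrelated (linkage equilibrium base)
  dos <- f$haplos[[1]][seq(1, 800, 2), 1:60] + f$haplos[[1]][seq(2, 800, 2), 1:60]
  r <- cor(dos)
  mean_abs_r <- mean(abs(r[upper.tri(r)]))
  # E|r| under the null at n = 400 is sqrt(2 / (pi n)) ~ 0.040
  expect_lt(mean_abs_r, 2 * sqrt(2 / (pi * 400)))
})

test_that("large-QTL effect solves 2p(1-p)a^2 = f * sigma2_g", {
  f <- exact_half_founders()
  cfg <- sim_config(gen_sizes = c(10L, 10L),
                    large_qtl = list(chrom = 1L, bp = 78500000, frac = 0.5),
                    seed = 1)
  set.seed(1)
  eff <- assign_effects(cfg, f)
  # p = 0.5, f = 0.5, sigma2_g = 1  =>  a = 1 exactly
  expect_equal(eff$effect[eff$type == "large_qtl"], 1, tolerance = 1e-12)
  expect_equal(eff$founder_freq[eff$type == "large_qtl"], 0.5)

  # monomorphic large QTL is rejected
  f2 <- f
  f2$haplos[[1]][, 3] <- 1L
  expect_error(assign_effects(cfg, f2), "monomorphic")
})

test_that("degenerate architectures behave as constructed", {
  # f_Q = 0 with background QTL only: all genetic variance is polygenic
  cfg <- sim_config(gen_sizes = rep(60L, 2), n_chromosomes = 1L,
                    chrom_length_bp = 2e7, chrom_length_morgans = 0.2,
                    n_markers_per_chrom = 60L, n_background_qtl = 1L,
                    large_qtl = list(chrom = 1L, bp = 1e7, frac = 0),
                    n_founders = 30L, warmup_generations = 2L, seed = 8)
  pop <- suppressWarnings(simulate_population(cfg))
  expect_equal(nrow(pop$qtl_truth), 1L)
  expect_equal(pop$qtl_truth$type, "bg_qtl")
  expect_gt(var(pop$true_bv), 0)

  # h2 = 1 and no hatch effects: phenotype equals the true breeding value
  cfg2 <- sim_config(gen_sizes = rep(50L, 2), n_chromosomes = 1L,
                     chrom_length_bp = 2e7, chrom_length_morgans = 0.2,
                     n_markers_per_chrom = 60L, n_background_qtl = 20L,
                     large_qtl = list(chrom = 1L, bp = 1e7, frac = 0.3),
                     h2 = 1, hatch_effect_sd = 0,
                     n_founders = 30L, warmup_generations = 2L, seed = 9)
  pop2 <- suppressWarnings(simulate_population(cfg2))
  expect_equal(unname(pop2$phenotypes$y),
               unname(pop2$true_bv[as.character(pop2$phenotypes$animal_id)]),
               tolerance = 1e-12)
})

test_that("phenotype regresses on true breeding value with slope ~ 1", {
  pop <- small_pop()
  b <- coef(lm(pop$phenotypes$y ~
                 pop$true_bv[as.character(pop$phenotypes$animal_id)]))[2]
  expect_lt(abs(b - 1), 0.15)
})

test_that("pedigree is acyclic with parents in earlier generations", {
  pop <- small_pop()
  ped <- pop$pedigree
  has_sire <- ped$sire > 0
  expect_true(all(ped$generation[ped$sire[has_sire]] <
                    ped$generation[has_sire]))
  has_dam <- ped$dam > 0
  expect_true(all(ped$generation[ped$dam[has_dam]] <
                    ped$generation[has_dam]))
  expect_silent(bayeswgr:::order_pedigree(ped))
})

test_that("QTL loci are masked from the panel unless requested", {
  pop <- small_pop()
  expect_false(any(grepl("qtl", pop$genotypes$snp_ids)))
  cfg <- pop$config
  cfg$qtl_in_panel <- TRUE
  pop2 <- simulate_population(cfg)
  expect_true("qtl_major" %in% pop2$genotypes$snp_ids)
  # the planted window is taggable: founder r2 recorded
  expect_true(is.finite(pop$founder_tag_r2))
})

test_that("realized heritability and QTL fraction track their targets over seeds", {
  fr <- h2 <- numeric(6)
  for (s in 1:6) {
    cfg <- sim_config(gen_sizes = rep(250L, 4), seed = 100 + s)
    pop <- suppressWarnings(simulate_population(cfg))
    fr[s] <- pop$realized_qtl_var_fraction
    h2[s] <- pop$realized_h2
  }
  expect_lt(abs(mean(h2) - 0.5), 0.05)
  expect_lt(abs(mean(fr) - 0.25), 0.05)
})

test_that("truncation selection drives the favorable QTL allele upward", {
  freq_shift <- numeric(5)
  for (s in 1:5) {
    cfg <- sim_config(gen_sizes = rep(120L, 4), n_chromosomes = 1L,
                      chrom_length_bp = 5e7, chrom_length_morgans = 0.5,
                      n_markers_per_chrom = 100L, n_background_qtl = 30L,
                      large_qtl = list(chrom = 1L, bp = 2.5e7, frac = 0.4),
                      selection = list(mode = "truncation", proportion = 0.3),
                      qtl_in_panel = TRUE,
                      n_founders = 40L, warmup_generations = 8L, seed = 200 + s)
    pop <- suppressWarnings(simulate_population(cfg))
    q <- pop$genotypes$dosages[, "qtl_major"]
    gen <- pop$phenotypes$generation
    p_first <- mean(q[gen == 1]) / 2
    p_last <- mean(q[gen == 4]) / 2
    freq_shift[s] <- p_last - p_first
  }
  # favorable allele (positive effect) gains frequency on average
  expect_gt(mean(freq_shift), 0)
})

test_that("impossible selection configurations are rejected", {
  expect_error(sim_config(selection = list(mode = "truncation", proportion = 0)),
               "proportion")
  cfg <- sim_config(gen_sizes = c(4L, 4L), n_chromosomes = 1L,
                    chrom_length_bp = 1e7, chrom_length_morgans = 0.1,
                    n_markers_per_chrom = 20L, n_background_qtl = 5L,
                    large_qtl = NULL, n_founders = 4L,
                    warmup_generations = 0L,
                    selection = list(mode = "truncation", proportion = 0.01),
                    seed = 3)
  expect_error(suppressWarnings(simulate_population(cfg)), "parents")
})
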
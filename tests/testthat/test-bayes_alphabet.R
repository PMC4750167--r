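test_that("prior scales reproduce the target variances in closed form", {
  # pi = 0, one SNP at p = 0.5: S2_alpha = varg * (nu-2)/nu / (2pq)
  pr <- prior_spec(pi = 0, nu_alpha = 4, nu_e = 10, varg = 3, vare = 2)
  sc <- derive_scales(pr, freq = 0.5)
  expect_equal(sc$S2_alpha, 3 * (1 / 2) / 0.5)
  expect_equal(sc$S2_e, 2 * 8 / 10)
  # the 1/(1-pi) factor: pi = 0.99 scales S2_alpha by 100
  pr99 <- prior_spec(pi = 0.99, nu_alpha = 4, nu_e = 10, varg = 3, vare = 2)
  sc99 <- derive_scales(pr99, freq = 0.5)
  expect_equal(sc99$S2_alpha / sc$S2_alpha, 100)
  # monomorphic-only panel is an error
  expect_error(derive_scales(pr, freq = c(0, 1)), "monomorphic")
})

test_that("scaled inverse chi-square sampler matches closed-form moments", {
  for (par in list(c(10, 2), c(5, 0.5))) {
    nu <- par[1]; S2 <- par[2]
    set.seed(11)
    x <- rscinvchisq(1e5, nu, S2)
    m_exp <- nu * S2 / (nu - 2)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - m_exp), 3 * se)
  }
})

test_that("inclusion probability matches numerical quadrature", {
  # 5-animal fixture with fixed dosages and working response
  x <- c(-1.2, 0.8, 0.8, -0.2, -0.2)   # centered dosages
  yt <- c(0.9, -0.4, 1.3, 0.2, -0.8)
  for (s2a in c(0.05, 0.5)) {
    for (pi in c(0.5, 0.99)) {
      s2e <- 1.1
      lik <- function(a) {
        vapply(a, function(ai)
          prod(dnorm(yt, x * ai, sqrt(s2e))) * dnorm(ai, 0, sqrt(s2a)),
          numeric(1))
      }
      m1 <- integrate(lik, -Inf, Inf, rel.tol = 1e-12)$value
      m0 <- prod(dnorm(yt, 0, sqrt(s2e)))
      p_quad <- (1 - pi) * m1 / ((1 - pi) * m1 + pi * m0)
      p_impl <- inclusion_probability(x, yt, pi, s2a, s2e)
      expect_lt(abs(p_impl - p_quad), 1e-6)
    }
  }
  # degenerate all-zero dosage column can never be included
  expect_equal(inclusion_probability(rep(0, 5), yt, 0.5, 0.5, 1), 0)
})

test_that("sampler's empirical inclusion rate agrees with the analytic probability", {
  x <- c(0, 1, 2, 1, 0, 2, 1, 1)
  p <- mean(x) / 2
  xc <- x - 2 * p
  y <- c(0.5, -0.2, 1.4, 0.3, -0.9, 1.1, 0.1, 0.2)
  geno <- genotype_matrix(matrix(x, ncol = 1,
                                 dimnames = list(NULL, "s1")),
                          data.frame(snp = "s1", chrom = 1L, bp = 1e6))
  phen <- data.frame(animal_id = 1:8, generation = 1L, hatch = "h1", y = y)
  d <- model_data(geno, phen)
  pr <- prior_spec(pi = 0.6, nu_alpha = 4, nu_e = 10, varg = 0.4, vare = 1)
  fit <- run_chain(d, "bayesC", prior = pr,
                   mcmc = mcmc_config(n_iter = 22000, burn_in = 2000, seed = 4),
                   fix_variances = TRUE)
  s2a <- fit$prior$nu_alpha * fit$scales$S2_alpha / (fit$prior$nu_alpha - 2)
  s2e <- fit$prior$nu_e * fit$scales$S2_e / (fit$prior$nu_e - 2)
  # exact marginal Pr(delta = 1 | y): integrate both the flat-prior class
  # mean and the candidate effect out of each model's likelihood
  lml <- function(V) {
    one <- rep(1, length(y))
    Vi <- solve(V)
    q <- as.numeric(t(one) %*% Vi %*% one)
    bhat <- as.numeric(t(one) %*% Vi %*% y) / q
    r <- y - bhat
    -0.5 * determinant(V)$modulus - 0.5 * log(q) -
      0.5 * as.numeric(t(r) %*% Vi %*% r)
  }
  l1 <- lml(s2e * diag(8) + s2a * tcrossprod(xc))
  l0 <- lml(s2e * diag(8))
  p_ref <- plogis(log(0.4 / 0.6) + as.numeric(l1 - l0))
  expect_lt(abs(fit$inclusion_prob[1] - p_ref), 0.04)
})

test_that("fixed-effect updates recover class means and offsets", {
  set.seed(21)
  n <- 200
  y <- 5 + rnorm(n)
  geno <- genotype_matrix(matrix(rep(1, n), ncol = 1,
                                 dimnames = list(NULL, "s1")),
                          data.frame(snp = "s1", chrom = 1L, bp = 1e6))
  phen <- data.frame(animal_id = 1:n, generation = 1L, hatch = "h1", y = y)
  d <- model_data(geno, phen)  # monomorphic SNP: x'x = 0, effect forced out
  pr <- prior_spec(pi = 0, nu_alpha = 100, nu_e = 100, varg = 1, vare = 1)
  fit <- run_chain(d, "bayesC0", prior = pr,
                   mcmc = mcmc_config(n_iter = 3000, burn_in = 500, seed = 1),
                   fix_variances = TRUE)
  expect_lt(abs(fit$beta_mean[1] - mean(y)), 3 / sqrt(n))
  expect_equal(unname(fit$alpha_mean), 0)

  # two balanced classes with true offsets +/- d: difference ~ OLS oracle
  d2 <- 1.5
  y2 <- rep(c(d2, -d2), each = n / 2) + rnorm(n)
  phen2 <- data.frame(animal_id = 1:n, generation = 1L,
                      hatch = rep(c("h1", "h2"), each = n / 2), y = y2)
  dd <- model_data(geno, phen2)
  fit2 <- run_chain(dd, "bayesC0", prior = pr,
                    mcmc = mcmc_config(n_iter = 3000, burn_in = 500, seed = 2),
                    fix_variances = TRUE)
  ols <- tapply(y2, phen2$hatch, mean)
  expect_lt(abs((fit2$beta_mean["1:h1"] - fit2$beta_mean["1:h2"]) -
                  (ols["h1"] - ols["h2"])), 0.1)
})

test_that("residual bookkeeping is exact at the final state", {
  toy <- toy_model_data()
  for (m in c("bayesB", "bayesC", "bayesC0", "gblup")) {
    fit <- run_chain(toy$data, m,
                     mcmc = mcmc_config(n_iter = 300, burn_in = 50, seed = 5))
    st <- fit$final_state
    e_direct <- toy$data$y - toy$data$Xf %*% st$beta - toy$data$M %*% st$alpha
    expect_lt(max(abs(e_direct - st$e)) / max(1, max(abs(st$e))), 1e-8)
    expect_true(all(fit$inclusion_prob >= 0 & fit$inclusion_prob <= 1))
    if (m %in% c("bayesC0", "gblup"))
      expect_true(all(fit$inclusion_prob == 1))
  }
})

test_that("pi = 0 chain with fixed variances matches the joint ridge solve", {
  toy <- toy_model_data(n = 120, p = 50)
  d <- toy$data
  pr <- prior_spec(pi = 0, nu_alpha = 100, nu_e = 100, varg = 0.5, vare = 0.7)
  fit <- run_chain(d, "gblup", prior = pr,
                   mcmc = mcmc_config(n_iter = 9000, burn_in = 1000, seed = 6),
                   fix_variances = TRUE)
  s2a <- pr$nu_alpha * fit$scales$S2_alpha / (pr$nu_alpha - 2)
  s2e <- pr$nu_e * fit$scales$S2_e / (pr$nu_e - 2)
  lambda <- s2e / s2a
  W <- cbind(d$Xf, d$M)
  K <- crossprod(W)
  diag(K)[-seq_len(ncol(d$Xf))] <- diag(K)[-seq_len(ncol(d$Xf))] + lambda
  sol <- solve(K, crossprod(W, d$y))
  alpha_ridge <- sol[-seq_len(ncol(d$Xf))]
  expect_gt(cor(fit$alpha_mean, alpha_ridge), 0.99)
  gebv_chain <- as.numeric(d$M %*% fit$alpha_mean)
  gebv_ridge <- as.numeric(d$M %*% alpha_ridge)
  expect_lt(max(abs(gebv_chain - gebv_ridge)), 0.05 * sd(gebv_ridge))
})

test_that("GEBV is linear in disjoint SNP subsets and genotype-determined", {
  toy <- toy_model_data()
  fit <- run_chain(toy$data, "bayesC",
                   mcmc = mcmc_config(n_iter = 500, burn_in = 100, seed = 7))
  g_all <- gebv(fit, toy$geno)
  half <- fit$snp_ids[1:30]
  rest <- setdiff(fit$snp_ids, half)
  expect_equal(g_all, gebv(fit, toy$geno, half) + gebv(fit, toy$geno, rest),
               tolerance = 1e-12)
  # empty subset: zeros
  expect_true(all(gebv(fit, toy$geno, character(0)) == 0))
  # identical genotype rows get identical GEBV
  geno2 <- toy$geno
  geno2$dosages[2, ] <- geno2$dosages[1, ]
  expect_equal(unname(gebv(fit, geno2)[1]), unname(gebv(fit, geno2)[2]))
  # unknown SNP is an error
  expect_error(gebv(fit, toy$geno, "nope"), "not in fit")
})

test_that("posterior summaries are invariant to SNP order up to MC noise", {
  toy <- toy_model_data(n = 150, p = 80)
  mc <- function(seed) mcmc_config(n_iter = 4000, burn_in = 1000, seed = seed)
  fit1 <- run_chain(toy$data, "bayesC", mcmc = mc(10))
  fit1b <- run_chain(toy$data, "bayesC", mcmc = mc(20))
  perm <- sample(seq_len(ncol(toy$geno$dosages)))
  geno_p <- genotype_matrix(toy$geno$dosages[, perm],
                            toy$geno$map[perm, ], toy$geno$animal_ids)
  d_p <- model_data(geno_p, toy$phen)
  fit2 <- run_chain(d_p, "bayesC", mcmc = mc(10))
  g1 <- gebv(fit1, toy$geno); g1b <- gebv(fit1b, toy$geno)
  g2 <- gebv(fit2, toy$geno)
  mc_noise <- sqrt(mean((g1 - g1b)^2))
  expect_lt(sqrt(mean((g1 - g2)^2)), 5 * mc_noise + 1e-8)
})

test_that("chain bookkeeping handles a single stored sample", {
  toy <- toy_model_data(n = 50, p = 10)
  fit <- run_chain(toy$data, "bayesC",
                   mcmc = mcmc_config(n_iter = 101, burn_in = 100, seed = 1))
  expect_equal(fit$n_samples, 1L)
  expect_equal(nrow(fit$window_var), 1L)
})
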
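#' @useDynLib bayeswgr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# 0/1 incidence matrix of a factor (class-means coding; robust to a single
# level, unlike model.matrix contrasts).
class_incidence <- function(cls) {
  X <- matrix(0, length(cls), nlevels(cls),
              dimnames = list(NULL, levels(cls)))
  X[cbind(seq_along(cls), as.integer(cls))] <- 1
  X
}

#' Prior specification for whole-genome regression models
#'
#' @param pi Prior fraction of SNPs with zero effect (0.99 for the mixture
#'   models, 0 for BayesC0/GBLUP).
#' @param nu_alpha Degrees of freedom of the scaled inverse chi-square prior
#'   on the SNP-effect variance (4 for BayesB/BayesC/BayesC0, 100 for the
#'   GBLUP parameterization, which in effect treats the common SNP-effect
#'   variance as known).
#' @param nu_e Degrees of freedom of the residual-variance prior (10, or 100
#'   for GBLUP).
#' @param varg,vare Target genetic and residual variances used to derive the
#'   prior scales; when `NULL` they default at model-build time to an even
#'   split of the hatch-corrected phenotypic variance.
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(pi = 0.99, nu_alpha = 4, nu_e = 10,
                       varg = NULL, vare = NULL) {
  stopifnot(pi >= 0, pi < 1, nu_alpha > 2, nu_e > 2)
  structure(list(pi = pi, nu_alpha = nu_alpha, nu_e = nu_e,
                 varg = varg, vare = vare), class = "prior_spec")
}

default_prior <- function(model) {
  switch(model,
    bayesB = prior_spec(pi = 0.99, nu_alpha = 4, nu_e = 10),
    bayesC = prior_spec(pi = 0.99, nu_alpha = 4, nu_e = 10),
    bayesC0 = prior_spec(pi = 0, nu_alpha = 4, nu_e = 10),
    gblup = prior_spec(pi = 0, nu_alpha = 100, nu_e = 100),
    stop("unknown model: ", model))
}

#' Derive prior scale factors from target variances
#'
#' The SNP-effect scale is chosen so that the prior mean per-locus effect
#' variance, aggregated over the expected number of included loci and the
#' heterozygosity of the panel, reproduces the target genetic variance:
#' `S2_alpha = varg * (nu_alpha - 2) / nu_alpha / ((1 - pi) * sum(2 p q))`.
#' The residual scale satisfies `S2_e = vare * (nu_e - 2) / nu_e`, so the
#' prior mean residual variance equals `vare`.
#'
#' @param prior A [prior_spec()] with `varg`/`vare` set.
#' @param freq Vector of panel allele frequencies.
#' @return List with `S2_alpha` and `S2_e`.
#' @export
derive_scales <- function(prior, freq) {
  sum2pq <- sum(2 * freq * (1 - freq))
  if (sum2pq <= 0) stop("panel contains only monomorphic SNPs")
  stopifnot(!is.null(prior$varg), !is.null(prior$vare))
  list(
    S2_alpha = prior$varg * (prior$nu_alpha - 2) / prior$nu_alpha /
      ((1 - prior$pi) * sum2pq),
    S2_e = prior$vare * (prior$nu_e - 2) / prior$nu_e
  )
}

#' Draw from a scaled inverse chi-square distribution
#'
#' Parameterized by degrees of freedom `nu` and scale `S2`; the mean is
#' `nu * S2 / (nu - 2)` for `nu > 2`.
#'
#' @param n Number of draws.
#' @param nu Degrees of freedom.
#' @param S2 Scale.
#' @return Numeric vector of draws.
#' @export
rscinvchisq <- function(n, nu, S2) nu * S2 / stats::rchisq(n, nu)

#' Conditional inclusion probability of a single locus
#'
#' The per-locus Gibbs update integrates the candidate effect out: with
#' `r_j = x' ytilde` (where `ytilde` is the residual with the locus's
#' current effect added back), the indicator is Bernoulli with
#' `Pr(delta = 1) = (1 - pi) m1(r_j) / ((1 - pi) m1(r_j) + pi m0(r_j))`,
#' where `m0` and `m1` are the densities of `r_j` under the excluded
#' (`N(0, x'x sigma2_e)`) and included
#' (`N(0, x'x sigma2_e + (x'x)^2 sigma2_alpha)`) models. This is the exact
#' computation used inside the sampler, exposed for auditing.
#'
#' @param x Centered dosage vector of the locus.
#' @param ytilde Working response (residuals plus the locus's own
#'   contribution).
#' @param pi Prior exclusion fraction.
#' @param sigma2_alpha Current effect variance of the locus.
#' @param sigma2_e Current residual variance.
#' @return Probability that the locus is included.
#' @export
inclusion_probability <- function(x, ytilde, pi, sigma2_alpha, sigma2_e) {
  xx <- sum(x^2)
  if (xx <= 0) return(0)
  r <- sum(x * ytilde)
  v0 <- xx * sigma2_e
  v1 <- v0 + xx^2 * sigma2_alpha
  llr <- 0.5 * (log(v0) - log(v1)) + 0.5 * r^2 * (1 / v0 - 1 / v1)
  lodds <- log((1 - pi) / pi) + llr
  stats::plogis(lodds)
}

#' MCMC run configuration
#'
#' @param n_iter Total chain length (default 35000).
#' @param burn_in Burn-in discarded from the front (default 5000).
#' @param thin Thinning interval for stored samples (default 1).
#' @param seed Optional integer seed set before the chain starts.
#' @param store_window_samples Store per-sample 1-Mb window genetic
#'   variances (needed for window reports).
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 35000L, burn_in = 5000L, thin = 1L,
                        seed = NULL, store_window_samples = TRUE) {
  stopifnot(burn_in < n_iter, thin >= 1L)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed,
                 store_window_samples = isTRUE(store_window_samples)),
            class = "mcmc_config")
}

#' Assemble model data for the samplers
#'
#' Aligns phenotypes with genotypes, restricts to a training set, builds the
#' hatch-within-generation incidence matrix (class-means coding; empty
#' classes dropped) and centers dosages by twice the training allele
#' frequency.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotypes Phenotype data frame (`animal_id`, `generation`,
#'   `hatch`, `y`).
#' @param animals Optional vector of animal ids defining the training set
#'   (default: all phenotyped, genotyped animals).
#' @return Object of class `wgr_data` with the centered dosage matrix `M`,
#'   incidence `Xf`, response `y`, training frequencies `p_train`, the map
#'   and ids.
#' @export
model_data <- function(genotypes, phenotypes, animals = NULL) {
  ids <- as.character(genotypes$animal_ids)
  ph <- phenotypes[as.character(phenotypes$animal_id) %in% ids, , drop = FALSE]
  if (!is.null(animals))
    ph <- ph[as.character(ph$animal_id) %in% as.character(animals), , drop = FALSE]
  if (anyDuplicated(ph$animal_id)) stop("multiple phenotype records per animal")
  if (nrow(ph) < 2L) stop("need at least two training records")
  rows <- match(as.character(ph$animal_id), ids)
  Mraw <- genotypes$dosages[rows, , drop = FALSE]
  p_train <- colMeans(Mraw) / 2
  M <- sweep(Mraw, 2L, 2 * p_train, `-`)
  cls <- factor(paste(ph$generation, ph$hatch, sep = ":"))
  Xf <- class_incidence(cls)
  structure(list(M = M, Xf = Xf, y = ph$y, p_train = p_train,
                 map = genotypes$map[, c("snp", "chrom", "bp")],
                 animal_ids = ph$animal_id, classes = levels(cls)),
            class = "wgr_data")
}

#' Fit a whole-genome regression model by single-site Gibbs sampling
#'
#' Runs the sampler for one of the four models: `bayesB` (mixture prior,
#' per-locus effect variances), `bayesC` (mixture prior, common variance),
#' `bayesC0` (all loci fitted, common variance estimated with df 4/10) and
#' `gblup` (all loci fitted, df 100/100, i.e. the marker-effect equivalent
#' of GBLUP with the variance ratio effectively treated as known). Update
#' order per iteration: fixed effects, then every locus in index order (the
#' inclusion indicator is drawn with the effect integrated out, then the
#' effect; for BayesB also its locus variance), then the common effect
#' variance (non-BayesB), then the residual variance.
#'
#' @param data A [model_data()] object.
#' @param model One of `"bayesB"`, `"bayesC"`, `"bayesC0"`, `"gblup"`.
#' @param prior A [prior_spec()]; defaults to the model's standard prior.
#'   When `varg`/`vare` are unset, each defaults to half the hatch-corrected
#'   phenotypic variance of the training data.
#' @param mcmc An [mcmc_config()].
#' @param fix_variances If `TRUE`, all variance components stay at their
#'   initial values (the prior means); used for exact-ridge comparisons.
#' @return Object of class `wgr_fit` with posterior means of SNP effects and
#'   fixed effects, per-SNP inclusion probabilities, variance traces,
#'   per-sample window variances and the final chain state.
#' @export
run_chain <- function(data, model = c("bayesB", "bayesC", "bayesC0", "gblup"),
                      prior = NULL, mcmc = mcmc_config(),
                      fix_variances = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(data, "wgr_data"))
  if (is.null(prior)) prior <- default_prior(model)
  if (is.null(prior$varg) || is.null(prior$vare)) {
    cls <- apply(data$Xf, 1L, function(r) which(r > 0)[1])
    ybar <- tapply(data$y, cls, mean)
    vstar <- stats::var(data$y - ybar[as.character(cls)])
    if (is.null(prior$varg)) prior$varg <- vstar / 2
    if (is.null(prior$vare)) prior$vare <- vstar / 2
  }
  scales <- derive_scales(prior, data$p_train)
  s2a_init <- prior$nu_alpha * scales$S2_alpha / (prior$nu_alpha - 2)
  s2e_init <- prior$nu_e * scales$S2_e / (prior$nu_e - 2)

  win <- floor(data$map$bp / 1e6)
  wkey <- paste(data$map$chrom, win, sep = "_")
  wlev <- unique(wkey)
  widx <- match(wkey, wlev) - 1L

  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  res <- .wgr_gibbs_cpp(
    data$M, data$Xf, data$y, model,
    prior$pi, prior$nu_alpha, prior$nu_e,
    scales$S2_alpha, scales$S2_e, s2a_init, s2e_init,
    fix_variances, mcmc$n_iter, mcmc$burn_in, mcmc$thin,
    widx, length(wlev), mcmc$store_window_samples)

  fit <- list(
    model = model, prior = prior, scales = scales, mcmc = mcmc,
    fix_variances = fix_variances,
    snp_ids = data$map$snp, map = data$map, p_train = data$p_train,
    classes = data$classes, animal_ids = data$animal_ids,
    alpha_mean = as.numeric(res$alpha_mean),
    inclusion_prob = as.numeric(res$inclusion_prob),
    beta_mean = stats::setNames(as.numeric(res$beta_mean), data$classes),
    sigma2e_trace = as.numeric(res$sigma2e_trace),
    sigma2a_trace = as.numeric(res$sigma2a_trace),
    genvar_trace = as.numeric(res$genvar_trace),
    window_labels = wlev,
    window_index = widx + 1L,
    window_var = res$window_var,
    window_active = res$window_active,
    n_samples = res$n_samples,
    final_state = res$final_state
  )
  names(fit$alpha_mean) <- names(fit$inclusion_prob) <- data$map$snp
  class(fit) <- "wgr_fit"
  fit
}

#' @export
print.wgr_fit <- function(x, ...) {
  cat(sprintf("wgr_fit: %s, %d SNPs, %d posterior samples\n",
              x$model, length(x$alpha_mean), x$n_samples))
  cat(sprintf("  posterior mean sigma2_e = %.4f, genetic variance = %.4f\n",
              mean(x$sigma2e_trace), mean(x$genvar_trace)))
  invisible(x)
}

#' Genomic estimated breeding values
#'
#' `GEBV_i = sum_j (x_ij - 2 p_j) alphahat_j` over a SNP subset, with the
#' centering frequencies `p_j` taken from the training data so that
#' validation animals are scored on the training scale.
#'
#' @param fit A [run_chain()] fit.
#' @param genotypes A [genotype_matrix()] holding the animals to score.
#' @param snp_subset Optional character vector of SNP ids (default: all SNPs
#'   in the fit). Unknown ids are an error.
#' @return Named numeric vector of GEBVs.
#' @export
gebv <- function(fit, genotypes, snp_subset = NULL) {
  if (is.null(snp_subset)) snp_subset <- fit$snp_ids
  if (length(snp_subset) == 0L)
    return(stats::setNames(numeric(nrow(genotypes$dosages)),
                           as.character(genotypes$animal_ids)))
  jf <- match(snp_subset, fit$snp_ids)
  if (anyNA(jf)) stop("SNP(s) not in fit: ", paste(snp_subset[is.na(jf)][1:3], collapse = ", "))
  jg <- match(snp_subset, genotypes$snp_ids)
  if (anyNA(jg)) stop("SNP(s) not in genotypes: ", paste(snp_subset[is.na(jg)][1:3], collapse = ", "))
  X <- sweep(genotypes$dosages[, jg, drop = FALSE], 2L, 2 * fit$p_train[jf], `-`)
  stats::setNames(as.numeric(X %*% fit$alpha_mean[jf]),
                  as.character(genotypes$animal_ids))
}
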
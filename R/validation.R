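#' Hatch-corrected phenotypes
#'
#' Removes hatch-within-generation class means from phenotypes:
#' `y* = y - mean(y within the animal's generation:hatch class)`, with the
#' means computed on the supplied records (typically a validation
#' generation, whose classes are unseen by training). A singleton class is
#' corrected to 0 with a warning.
#'
#' @param phenotypes Data frame (`animal_id`, `generation`, `hatch`, `y`).
#' @return Named numeric vector of corrected phenotypes.
#' @export
hatch_correct <- function(phenotypes) {
  cls <- paste(phenotypes$generation, phenotypes$hatch, sep = ":")
  counts <- table(cls)
  if (any(counts == 1L))
    warning(sum(counts == 1L), " singleton hatch class(es); corrected value set to 0")
  mu <- tapply(phenotypes$y, cls, mean)
  ystar <- as.numeric(phenotypes$y - mu[cls])
  ystar[counts[cls] == 1L] <- 0
  stats::setNames(ystar, as.character(phenotypes$animal_id))
}

#' Prediction accuracy
#'
#' Pearson correlation between predictions and (typically hatch-corrected)
#' phenotypes. Returns `NA` with fewer than 3 paired records or when either
#' side has zero variance.
#'
#' @param predictions,phenotypes Numeric vectors of equal length.
#' @return Correlation, or `NA`.
#' @export
accuracy <- function(predictions, phenotypes) {
  ok <- is.finite(predictions) & is.finite(phenotypes)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(predictions[ok]) == 0 || stats::sd(phenotypes[ok]) == 0)
    return(NA_real_)
  stats::cor(predictions[ok], phenotypes[ok])
}

#' Bias regression of phenotype on prediction
#'
#' Ordinary least-squares slope of corrected phenotype on prediction. A
#' slope of 1 means unbiased prediction; a slope above 1 means predicted
#' differences understate realized phenotypic differences (overshrinkage of
#' the underlying effect estimates).
#'
#' @param phenotypes Corrected phenotypes.
#' @param predictions Predictions.
#' @return Slope, or `NA` when the predictions have zero variance.
#' @export
bias_regression <- function(phenotypes, predictions) {
  ok <- is.finite(predictions) & is.finite(phenotypes)
  if (sum(ok) < 3L) return(NA_real_)
  vp <- stats::var(predictions[ok])
  if (vp == 0) return(NA_real_)
  stats::cov(phenotypes[ok], predictions[ok]) / vp
}

#' GEBV restricted to one 1-Mb window
#'
#' Computes predictions from the marker-effect estimates of a single window
#' only (effects still come from the model fitting all SNPs
#' simultaneously). An empty window yields zero predictions with a warning.
#'
#' @param fit A [run_chain()] fit.
#' @param window Window label (e.g. `"1_78"`).
#' @param genotypes A [genotype_matrix()] of animals to score.
#' @return Named numeric vector of predictions.
#' @export
region_restricted_prediction <- function(fit, window, genotypes) {
  snps <- window_snps(fit, window)
  if (length(snps) == 0L) {
    warning("window ", window, " contains no SNPs of the fit; returning zeros")
    return(stats::setNames(numeric(nrow(genotypes$dosages)),
                           as.character(genotypes$animal_ids)))
  }
  gebv(fit, genotypes, snp_subset = snps)
}

# Internal: per-generation evaluation rows for one fit on one population.
evaluate_generations <- function(fit, pop, validation_gens,
                                 predictions = NULL, label = fit$model) {
  rows <- lapply(validation_gens, function(g) {
    ph <- pop$phenotypes[pop$phenotypes$generation == g, , drop = FALSE]
    if (nrow(ph) == 0L)
      return(data.frame(model = label, generation = g, n = 0L,
                        accuracy = NA_real_, bias_b = NA_real_))
    ystar <- hatch_correct(ph)
    pred <- if (is.null(predictions)) gebv(fit, pop$genotypes) else predictions
    pred <- pred[as.character(ph$animal_id)]
    data.frame(model = label, generation = g, n = nrow(ph),
               accuracy = accuracy(pred, ystar),
               bias_b = bias_regression(ystar, pred))
  })
  do.call(rbind, rows)
}

#' Forward-in-time persistence of prediction accuracy
#'
#' Evaluates one fitted model in each of a series of validation generations
#' (typically generations 2..G after training on generation 1): whole-genome
#' GEBV accuracy against hatch-corrected phenotypes, plus an
#' across-generation arithmetic average row (`generation = NA`).
#'
#' @param fit A [run_chain()] fit.
#' @param pop A `sim_population` (or compatible list with `phenotypes` and
#'   `genotypes`).
#' @param validation_gens Integer vector of validation generations.
#' @return Data frame with columns `model`, `generation`, `n`, `accuracy`,
#'   `bias_b`; the final row holds the average accuracy.
#' @export
persistence_run <- function(fit, pop, validation_gens) {
  out <- evaluate_generations(fit, pop, validation_gens)
  avg <- data.frame(model = out$model[1], generation = NA_integer_,
                    n = sum(out$n),
                    accuracy = mean(out$accuracy, na.rm = TRUE),
                    bias_b = mean(out$bias_b, na.rm = TRUE))
  rbind(out, avg)
}

#' Run a training/validation experiment over several models
#'
#' Fits the requested models on a training generation set, then reports, per
#' model and validation generation: whole-genome accuracy, accuracy from the
#' model's own top 1-Mb window only, and the bias regression. The top window
#' is taken from each training fit being evaluated.
#'
#' @param pop A `sim_population`.
#' @param train_gens Integer vector of training generations.
#' @param validation_gens Integer vector of validation generations (must be
#'   disjoint from `train_gens`).
#' @param models Character vector of model tags.
#' @param mcmc An [mcmc_config()].
#' @param priors Optional named list of [prior_spec()] overrides per model.
#' @return List with `fits` (named list), `report` (data frame with columns
#'   `model`, `generation`, `n`, `accuracy`, `window_accuracy`, `bias_b`,
#'   `top_window`).
#' @export
run_experiment <- function(pop, train_gens, validation_gens,
                           models = c("bayesB", "bayesC", "bayesC0", "gblup"),
                           mcmc = mcmc_config(), priors = NULL) {
  if (length(intersect(train_gens, validation_gens)) > 0L)
    stop("training and validation generations must be disjoint")
  train_ids <- pop$phenotypes$animal_id[pop$phenotypes$generation %in% train_gens]
  data <- model_data(pop$genotypes, pop$phenotypes, animals = train_ids)
  fits <- list(); report <- list()
  for (m in models) {
    prior <- if (!is.null(priors) && !is.null(priors[[m]])) priors[[m]] else NULL
    fit <- run_chain(data, model = m, prior = prior, mcmc = mcmc)
    fits[[m]] <- fit
    win <- summarize_windows(fit)
    top <- win$window[1]
    base <- evaluate_generations(fit, pop, validation_gens)
    wpred <- region_restricted_prediction(fit, top, pop$genotypes)
    wrows <- evaluate_generations(fit, pop, validation_gens,
                                  predictions = wpred, label = m)
    base$window_accuracy <- wrows$accuracy
    base$top_window <- top
    report[[m]] <- base
  }
  list(fits = fits, report = do.call(rbind, report))
}
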
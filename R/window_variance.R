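#' Assign SNPs to 1-Mb windows
#'
#' Windows are half-open physical bins `[k Mb, (k+1) Mb)`; the label is
#' `chromosome_index`, e.g. a SNP on chromosome 4 at 78,500,000 bp falls in
#' window `"4_78"`.
#'
#' @param map Data frame with columns `snp`, `chrom`, `bp`.
#' @return The map with added columns `mb` (window index) and `window`
#'   (label). SNPs with missing positions are excluded with a warning.
#' @export
assign_windows <- function(map) {
  stopifnot(all(c("snp", "chrom", "bp") %in% names(map)))
  miss <- is.na(map$bp) | is.na(map$chrom)
  if (any(miss)) {
    warning(sum(miss), " SNP(s) without a map position excluded from windows")
    map <- map[!miss, , drop = FALSE]
  }
  stopifnot(all(map$bp >= 0))
  map$mb <- floor(map$bp / 1e6)
  map$window <- paste(map$chrom, map$mb, sep = "_")
  map
}

#' Per-window genetic variance of one effect sample
#'
#' For window `w`, the variance across animals of the window genomic value
#' `sum_{j in w} x_ij alpha_j`; the total is the variance of the full
#' genomic value. Proportions are defined as 0 when the total is 0. This is
#' the same quantity the sampler accumulates per MCMC sample; the function
#' exists as an audit path for stored samples or point estimates.
#'
#' @param effects Numeric vector of SNP effects (aligned to the map).
#' @param M Centered dosage matrix (animals x SNPs).
#' @param windows Window labels per SNP (e.g. from [assign_windows()]).
#' @return List with `window` (labels), `variance`, `proportion`, `total`.
#' @export
window_variances_per_sample <- function(effects, M, windows) {
  stopifnot(length(effects) == ncol(M), length(windows) == ncol(M))
  u <- as.numeric(M %*% effects)
  total <- stats::var(u)
  labs <- unique(windows)
  v <- vapply(labs, function(w) {
    j <- which(windows == w)
    stats::var(as.numeric(M[, j, drop = FALSE] %*% effects[j]))
  }, numeric(1))
  prop <- if (total > 0) v / total else rep(0, length(v))
  list(window = labs, variance = unname(v), proportion = unname(prop),
       total = total)
}

#' Summarize posterior window variances into a QTL-detection report
#'
#' For each 1-Mb window: `pct_var` is the posterior mean (over stored
#' post-burn-in samples) of 100 times the window's share of total genetic
#' variance in that sample, and `p_gt0` is the proportion of samples in
#' which the window accounted for more than 0 % of genetic variance. For
#' mixture models the `> 0` event is "at least one included SNP with a
#' nonzero effect in the window"; for the all-SNP models (`pi = 0`, where
#' effects are never exactly zero) it is `v_w > 1e-12 * total` to guard
#' against floating-point residue.
#'
#' @param fit A [run_chain()] fit with stored window samples.
#' @return Data frame with one row per window: `chrom`, `mb`, `window`,
#'   `n_snps`, `pct_var`, `p_gt0`, `rank`, `top` — sorted by rank.
#' @export
summarize_windows <- function(fit) {
  if (is.null(fit$window_var) || length(fit$window_var) == 0L ||
      fit$n_samples == 0L)
    stop("fit has no stored window samples (set store_window_samples = TRUE)")
  V <- fit$window_var
  tot <- fit$genvar_trace
  prop <- V / ifelse(tot > 0, tot, Inf)  # proportion defined as 0 when total = 0
  pct <- 100 * colMeans(prop)
  if (fit$prior$pi > 0) {
    p_gt0 <- colMeans(fit$window_active)
  } else {
    p_gt0 <- colMeans(V > 1e-12 * tot)
  }
  labs <- fit$window_labels
  parts <- strsplit(labs, "_", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, function(p) p[1], character(1)),
    mb = as.integer(vapply(parts, function(p) p[2], character(1))),
    window = labs,
    n_snps = as.integer(table(factor(fit$window_index,
                                     levels = seq_along(labs)))),
    pct_var = unname(pct),
    p_gt0 = unname(p_gt0),
    stringsAsFactors = FALSE
  )
  out$rank <- rank(-out$pct_var, ties.method = "first")
  out$top <- out$rank == 1L
  out[order(out$rank), , drop = FALSE]
}

#' Most significant SNP of a window
#'
#' The SNP within a window that explains the greatest share of genetic
#' variance at the posterior mean, `2 p (1 - p) alphahat^2` with `p` the
#' training allele frequency. Defaults to the fit's top window. Used for
#' the single-SNP shrinkage-bias diagnosis, where generation-8 phenotypes
#' are predicted from this one marker's estimated effect.
#'
#' @param fit A [run_chain()] fit.
#' @param window Window label; `NULL` picks the top window by `pct_var`.
#' @return A SNP id (length-1 character).
#' @export
top_snp <- function(fit, window = NULL) {
  if (is.null(window)) window <- summarize_windows(fit)$window[1]
  snps <- window_snps(fit, window)
  if (length(snps) == 0L) stop("window ", window, " contains no SNPs")
  j <- match(snps, fit$snp_ids)
  share <- 2 * fit$p_train[j] * (1 - fit$p_train[j]) * fit$alpha_mean[j]^2
  snps[which.max(share)]
}

#' SNP ids belonging to a window of a fit
#'
#' @param fit A [run_chain()] fit.
#' @param window Window label, e.g. `"1_78"`.
#' @return Character vector of SNP ids (may be empty).
#' @export
window_snps <- function(fit, window) {
  w <- match(window, fit$window_labels)
  if (is.na(w)) return(character(0))
  fit$snp_ids[fit$window_index == w]
}
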
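#' Numerator relationship matrix utilities
#'
#' `ped_Ainverse()` builds the sparse inverse of the numerator relationship
#' matrix A directly from the pedigree: inbreeding coefficients come from
#' the Meuwissen-Luo recursion and the inverse is assembled by Henderson's
#' rules with inbreeding. `make_A()` builds A itself by the tabular method
#' (dense; intended for small pedigrees and as an independent cross-check).
#' Unknown parents (code 0) are treated as unrelated, non-inbred founders.
#'
#' @param pedigree Data frame with columns `animal`, `sire`, `dam` (0 =
#'   unknown). Reordered internally so parents precede offspring; cycles and
#'   self-parenting are errors.
#' @return `ped_Ainverse()`: list with `Ainv` (sparse `dsCMatrix`), `F`
#'   (inbreeding coefficients) and `animals` (id order of the matrix).
#'   `make_A()`: dense matrix with dimnames.
#' @export
ped_Ainverse <- function(pedigree) {
  ped <- order_pedigree(pedigree)
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  F <- .ped_inbreeding_cpp(s, d)
  Fs <- ifelse(s > 0L, F[pmax(s, 1L)], -1)
  Fd <- ifelse(d > 0L, F[pmax(d, 1L)], -1)
  ai <- 1 / (0.5 - 0.25 * (Fs + Fd))  # 1 / D_i, the Mendelian sampling variance
  ii <- list(); jj <- list(); xx <- list()
  add <- function(i, j, v) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- v
  }
  idx <- seq_len(n)
  add(idx, idx, ai)
  for (par in list(s, d)) {
    has <- par > 0L
    add(idx[has], par[has], -0.5 * ai[has])
    add(par[has], idx[has], -0.5 * ai[has])
  }
  hs <- s > 0L; hd <- d > 0L
  add(s[hs], s[hs], 0.25 * ai[hs])
  add(d[hd], d[hd], 0.25 * ai[hd])
  both <- hs & hd
  add(s[both], d[both], 0.25 * ai[both])
  add(d[both], s[both], 0.25 * ai[both])
  Ainv <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                               dims = c(n, n), symmetric = FALSE)
  Ainv <- Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2)
  dimnames(Ainv) <- list(ped$animal, ped$animal)
  list(Ainv = Ainv, F = F, animals = ped$animal)
}

#' @rdname ped_Ainverse
#' @export
make_A <- function(pedigree) {
  ped <- order_pedigree(pedigree)
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (si > 0L) v <- v + 0.5 * A[si, prev]
      if (di > 0L) v <- v + 0.5 * A[di, prev]
      A[i, prev] <- v
      A[prev, i] <- v
    }
    A[i, i] <- 1 + if (si > 0L && di > 0L) 0.5 * A[si, di] else 0
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

# Topological reorder: generation labels are not required; Kahn-style pass.
order_pedigree <- function(pedigree) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(pedigree)))
  ped <- pedigree
  ids <- as.character(ped$animal)
  if (anyDuplicated(ids)) stop("duplicate animal ids in pedigree")
  if (any(ids == as.character(ped$sire) | ids == as.character(ped$dam)))
    stop("self-parenting in pedigree")
  sidx <- match(as.character(ped$sire), ids, nomatch = 0L)
  didx <- match(as.character(ped$dam), ids, nomatch = 0L)
  n <- nrow(ped)
  placed <- logical(n); ord <- integer(n); k <- 0L
  repeat {
    ready <- !placed & (sidx == 0L | placed[pmax(sidx, 1L)]) &
      (didx == 0L | placed[pmax(didx, 1L)])
    if (!any(ready)) break
    w <- which(ready)
    ord[k + seq_along(w)] <- w
    k <- k + length(w)
    placed[w] <- TRUE
  }
  if (k < n) stop("pedigree contains a cycle")
  ped <- ped[ord, , drop = FALSE]
  ids <- as.character(ped$animal)
  ped$sire_idx <- match(as.character(ped$sire), ids, nomatch = 0L)
  ped$dam_idx <- match(as.character(ped$dam), ids, nomatch = 0L)
  ped$animal <- ids
  ped
}

#' Solve the animal model by Henderson's mixed-model equations
#'
#' Model: `y = X b + Z u + e` with `u ~ N(0, A sigma2_a)`. `X` holds the
#' hatch-within-generation classes (class-means coding) plus an optional SNP
#' dosage covariate whose solution is the fixed substitution-effect
#' estimate. The sparse system is solved directly and the relative residual
#' of the solved equations is checked to 1e-8.
#'
#' @param phenotypes Data frame (`animal_id`, `generation`, `hatch`, `y`).
#' @param Ainv Result of [ped_Ainverse()] (or a compatible list).
#' @param varcomp List with `sigma2_a` and `sigma2_e`.
#' @param snp_covariate Optional named numeric vector of dosages (names =
#'   animal ids) fitted as a fixed regression.
#' @return List with `fixed` (named solutions), `ebv` (named, all pedigree
#'   animals), `varcomp`, `snp_effect` (or `NA`).
#' @export
solve_animal_model <- function(phenotypes, Ainv, varcomp, snp_covariate = NULL) {
  stopifnot(varcomp$sigma2_a > 0, varcomp$sigma2_e > 0)
  lambda <- varcomp$sigma2_e / varcomp$sigma2_a
  ids <- Ainv$animals
  ph <- phenotypes[as.character(phenotypes$animal_id) %in% ids, , drop = FALSE]
  n <- nrow(ph); q <- length(ids)
  if (n < 1L) stop("no phenotyped animal appears in the pedigree")
  cls <- factor(paste(ph$generation, ph$hatch, sep = ":"))
  X <- class_incidence(cls)
  has_snp <- !is.null(snp_covariate)
  if (has_snp) {
    z <- snp_covariate[as.character(ph$animal_id)]
    if (anyNA(z)) stop("snp_covariate missing for some phenotyped animals")
    X <- cbind(X, snp = z)
  }
  # drop redundant fixed columns if any
  qr_x <- qr(crossprod(X))
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    warning("singular fixed-effect block; dropping ",
            ncol(X) - qr_x$rank, " redundant column(s)")
    X <- X[, sort(keep), drop = FALSE]
  }
  Z <- Matrix::sparseMatrix(i = seq_len(n),
                            j = match(as.character(ph$animal_id), ids),
                            x = 1, dims = c(n, q))
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  C <- rbind(
    cbind(Matrix::crossprod(Xs), Matrix::crossprod(Xs, Z)),
    cbind(Matrix::crossprod(Z, Xs), Matrix::crossprod(Z) + lambda * Ainv$Ainv)
  )
  rhs <- c(as.numeric(Matrix::crossprod(Xs, ph$y)),
           as.numeric(Matrix::crossprod(Z, ph$y)))
  sol <- as.numeric(Matrix::solve(C, rhs))
  resid <- as.numeric(C %*% sol) - rhs
  rel <- sqrt(sum(resid^2)) / max(sqrt(sum(rhs^2)), 1e-300)
  if (rel > 1e-8) stop(sprintf("mixed-model equations solved to relative residual %.2e", rel))
  nf <- ncol(X)
  fixed <- stats::setNames(sol[seq_len(nf)], colnames(X))
  ebv <- stats::setNames(sol[nf + seq_len(q)], ids)
  list(fixed = fixed, ebv = ebv, varcomp = varcomp,
       snp_effect = if (has_snp) unname(fixed["snp"]) else NA_real_)
}

#' EM-REML variance components for the animal model
#'
#' Expectation-maximization REML on the single-random-effect animal model:
#' at each iterate the mixed-model equations are solved, then
#' `sigma2_a <- (u' Ainv u + sigma2_e tr(Ainv C^uu)) / q` and
#' `sigma2_e <- (y'y - b' X'y - u' Z'y) / (n - rank(X))`, where `C^uu` is
#' the random-effect block of the inverse coefficient matrix. Iterated to a
#' relative change below `tol` or `max_iter`.
#'
#' @param phenotypes Data frame (`animal_id`, `generation`, `hatch`, `y`).
#' @param Ainv Result of [ped_Ainverse()].
#' @param start Optional starting values `list(sigma2_a=, sigma2_e=)`.
#' @param tol Relative-change convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 200); non-convergence returns the
#'   last iterate with `converged = FALSE`.
#' @return List with `sigma2_a`, `sigma2_e`, `h2`, `converged`, `iterations`.
#' @export
estimate_variance_components <- function(phenotypes, Ainv, start = NULL,
                                         tol = 1e-6, max_iter = 200L) {
  ids <- Ainv$animals
  ph <- phenotypes[as.character(phenotypes$animal_id) %in% ids, , drop = FALSE]
  n <- nrow(ph); q <- length(ids)
  if (n < 2L) stop("need at least two phenotyped animals")
  cls <- factor(paste(ph$generation, ph$hatch, sep = ":"))
  X <- class_incidence(cls)
  nf <- qr(X)$rank
  Z <- Matrix::sparseMatrix(i = seq_len(n),
                            j = match(as.character(ph$animal_id), ids),
                            x = 1, dims = c(n, q))
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  XtX <- Matrix::crossprod(Xs); XtZ <- Matrix::crossprod(Xs, Z)
  ZtZ <- Matrix::crossprod(Z)
  Xty <- as.numeric(Matrix::crossprod(Xs, ph$y))
  Zty <- as.numeric(Matrix::crossprod(Z, ph$y))
  yy <- sum(ph$y^2)
  vy <- stats::var(ph$y)
  s2a <- if (is.null(start)) vy / 2 else start$sigma2_a
  s2e <- if (is.null(start)) vy / 2 else start$sigma2_e
  Ain <- Ainv$Ainv
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    lambda <- s2e / s2a
    C <- rbind(cbind(XtX, XtZ),
               cbind(Matrix::t(XtZ), ZtZ + lambda * Ain))
    rhs <- c(Xty, Zty)
    Cinv <- Matrix::solve(C)
    sol <- as.numeric(Cinv %*% rhs)
    b <- sol[seq_len(ncol(X))]
    u <- sol[ncol(X) + seq_len(q)]
    Cuu <- Cinv[ncol(X) + seq_len(q), ncol(X) + seq_len(q), drop = FALSE]
    uAu <- as.numeric(Matrix::t(u) %*% Ain %*% u)
    trAC <- sum(Ain * Matrix::t(Cuu)) # tr(Ainv %*% Cuu), both symmetric
    s2a_new <- (uAu + s2e * trAC) / q
    s2e_new <- (yy - sum(b * Xty) - sum(u * Zty)) / (n - nf)
    rel <- max(abs(s2a_new - s2a) / max(s2a, 1e-12),
               abs(s2e_new - s2e) / max(s2e, 1e-12))
    s2a <- s2a_new; s2e <- s2e_new
    if (rel < tol) { converged <- TRUE; break }
  }
  list(sigma2_a = s2a, sigma2_e = s2e, h2 = s2a / (s2a + s2e),
       converged = converged, iterations = it)
}
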
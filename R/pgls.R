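#' Generalized least squares with a known error covariance
#'
#' Core GLS solver used by [pgls()]: coefficients
#' `(X' V^-1 X)^-1 X' V^-1 y`, the residual variance
#' `r' V^-1 r / (n - p)`, and the Gaussian log-likelihood evaluated at the
#' maximum-likelihood variance `r' V^-1 r / n`.  Computations go through
#' the Cholesky factor of `V`; an explicit inverse is never formed.
#'
#' @param X design matrix (including the intercept column), n x p.
#' @param y response vector, length n.
#' @param V n x n positive-definite error covariance.
#' @return list with `coefficients`, `cov_unscaled` (`(X'V^-1X)^-1`),
#'   `sigma2` (unbiased, divisor n - p), `sigma2_ml` (divisor n),
#'   `rss_gls` (`r'V^-1r`), `loglik`, `fitted`, `residuals`,
#'   `df_residual`.
#' @export
gls_fit <- function(X, y, V) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n)
    stop("dimension mismatch between X, y and V")
  if (n <= p) stop("need more observations than design columns")
  R <- tryCatch(chol(V), error = function(e)
    stop("V is not positive-definite: ", conditionMessage(e)))
  # whiten: V = R'R, so solving R' z = x gives z with cov(z) = I
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  qr_x <- qr(Xw)
  if (qr_x$rank < p) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):p]]
    stop("design is rank-deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, yw)
  fitted <- as.numeric(X %*% beta)
  r <- y - fitted
  rw <- yw - Xw %*% beta
  rss <- sum(rw^2)
  sigma2_ml <- rss / n
  logdet_v <- 2 * sum(log(diag(R)))
  loglik <- -0.5 * (n * log(2 * pi) + n * log(sigma2_ml) + logdet_v + n)
  xtx_inv <- chol2inv(qr.R(qr_x))[order(qr_x$pivot), order(qr_x$pivot),
                                  drop = FALSE]
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  list(coefficients = beta, cov_unscaled = xtx_inv,
       sigma2 = rss / (n - p), sigma2_ml = sigma2_ml, rss_gls = rss,
       loglik = loglik, fitted = fitted, residuals = r,
       df_residual = n - p)
}

#' Maximum-likelihood estimation of Pagel's lambda
#'
#' Profiles the GLS log-likelihood (coefficients and variance maximized
#' out) over the phylogenetic-signal multiplier lambda in \[0, 1\]:
#' a 21-point grid locates the best cell, then bounded scalar optimization
#' refines within it; the boundary values 0 and 1 are admissible optima.
#'
#' @param X design matrix with intercept.
#' @param y response vector, ordered as the rows of `V`.
#' @param V Brownian covariance from [phylo_covariance()] (or the tree
#'   itself, from which it is computed).
#' @param grid_n number of profile grid points (default 21).
#' @return list with `lambda`, `loglik` at the optimum, and `profile`
#'   (data frame of the grid `lambda`, `loglik` values).
#' @export
estimate_lambda <- function(X, y, V, grid_n = 21L) {
  if (inherits(V, "phylo")) V <- phylo_covariance(V)
  pl <- function(lam) gls_fit(X, y, lambda_transform(V, lam))$loglik
  grid <- seq(0, 1, length.out = grid_n)
  ll <- vapply(grid, pl, numeric(1))
  if (!all(is.finite(ll)))
    stop("non-finite profile likelihood at lambda = ",
         paste(grid[!is.finite(ll)], collapse = ", "))
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(grid_n, i + 1L)]
  opt <- stats::optimize(pl, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective),
                c(grid[i], ll[i]), c(0, ll[1]), c(1, ll[grid_n]))
  best <- cand[which.max(cand[, 2]), ]
  if (abs(ll[1] - ll[grid_n]) < 1e-10 && stats::sd(ll) < 1e-10)
    warning("profile likelihood is flat in lambda; boundary value reported")
  list(lambda = best[1], loglik = best[2],
       profile = data.frame(lambda = grid, loglik = ll))
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Regresses a (by default natural-log-transformed) trait on one or more
#' covariates across the tips of a phylogeny, with residual covariance
#' `sigma^2 * lambda_transform(V, lambda)` and lambda estimated by maximum
#' likelihood (or fixed).  Per-term Wald t statistics use the residual
#' degrees of freedom n - p; a type-II F for each term compares the model
#' with and without that term at the fitted lambda.  The multiple R^2 is
#' computed from GLS sums of squares against the intercept-only model.
#'
#' @param data data frame with a `taxon` column plus trait columns.
#' @param response name of the response column.
#' @param predictors character vector of predictor column names.
#' @param tree [ape::phylo] tree whose tips match `data$taxon` (exact
#'   string match after trimming whitespace).
#' @param lambda `NULL` (default) to estimate by maximum likelihood, or a
#'   fixed value in \[0, 1\].
#' @param ln_transform log-transform response and predictors first
#'   (requires strictly positive values; default `TRUE`).
#' @return object of class `pgls_fit`: a list with `response`, `terms`
#'   (data frame: term, estimate, se, t, F, p, p_adjusted), `lambda`,
#'   `loglik`, `r.squared`, `df_model`, `df_residual`, `n`.
#' @export
pgls <- function(data, response, predictors, tree, lambda = NULL,
                 ln_transform = TRUE) {
  data <- as.data.frame(data)
  if (!"taxon" %in% names(data)) stop("`data` must have a `taxon` column")
  cols <- c(response, predictors)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("columns not in data: ", paste(miss, collapse = ", "))
  data$taxon <- trimws(as.character(data$taxon))
  tips <- trimws(tree$tip.label)
  only_tree <- setdiff(tips, data$taxon)
  only_data <- setdiff(data$taxon, tips)
  if (length(only_tree) || length(only_data))
    stop("taxon mismatch; only in tree: [",
         paste(only_tree, collapse = ", "), "]; only in data: [",
         paste(only_data, collapse = ", "), "]")
  if (anyDuplicated(data$taxon)) stop("duplicate taxa in `data`")
  data <- data[match(tips, data$taxon), , drop = FALSE]

  if (ln_transform) {
    for (cl in cols) {
      bad <- which(!(data[[cl]] > 0))
      if (length(bad))
        stop("non-positive value under ln transform in column '", cl,
             "' for taxon ", paste(data$taxon[bad], collapse = ", "))
      data[[cl]] <- log(data[[cl]])
    }
  }

  y <- data[[response]]
  X <- cbind("(Intercept)" = 1,
             as.matrix(data[, predictors, drop = FALSE]))
  V <- phylo_covariance(tree)

  if (is.null(lambda)) {
    est <- estimate_lambda(X, y, V)
    lambda_hat <- est$lambda
  } else {
    if (lambda < 0 || lambda > 1) stop("fixed lambda must be in [0, 1]")
    lambda_hat <- lambda
  }
  Vl <- lambda_transform(V, lambda_hat)
  fit <- gls_fit(X, y, Vl)

  se <- sqrt(fit$sigma2 * diag(fit$cov_unscaled))
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(-abs(tval), fit$df_residual)
  # type-II F: drop each term in turn at the fitted lambda
  Fval <- rep(NA_real_, ncol(X))
  for (j in seq.int(2L, ncol(X))) {
    red <- gls_fit(X[, -j, drop = FALSE], y, Vl)
    Fval[j] <- (red$rss_gls - fit$rss_gls) / (fit$rss_gls / fit$df_residual)
  }
  null_fit <- gls_fit(X[, 1, drop = FALSE], y, Vl)
  r2 <- 1 - fit$rss_gls / null_fit$rss_gls

  structure(list(
    response = response,
    terms = data.frame(term = colnames(X), estimate = fit$coefficients,
                       se = se, t = tval, F = Fval, p = pval,
                       p_adjusted = NA_real_, row.names = NULL),
    lambda = lambda_hat, loglik = fit$loglik, r.squared = r2,
    df_model = ncol(X) - 1L, df_residual = fit$df_residual,
    n = length(y), sigma2 = fit$sigma2,
    coefficients = fit$coefficients), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit: %s ~ %s\n", x$response,
              paste(x$terms$term[-1], collapse = " + ")))
  cat(sprintf("lambda = %.3f, R2 = %.3f, df = (%d, %d), logLik = %.3f\n",
              x$lambda, x$r.squared, x$df_model, x$df_residual, x$loglik))
  print(x$terms, digits = 4)
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment of a family of p-values: sorted ascending,
#' `q_i = min_{j >= i} (m * p_j / j)`, capped at 1, returned in the input
#' order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("all p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
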
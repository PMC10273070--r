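#' Fit an RR-BLUP genomewide prediction model
#'
#' REML fit of `y = X beta + Z u + e` with marker effects `u ~ N(0, sigma2_u I)`
#' and residuals `e ~ N(0, sigma2_e I)`. The restricted likelihood is profiled
#' down to the single variance ratio `phi = sigma2_u / sigma2_e` through the
#' spectral decomposition of the marker covariance `Z Z'` projected onto the
#' orthogonal complement of the fixed-effect design, and maximized by bounded
#' one-dimensional search in `log(phi)`. At the optimum, `beta` is the
#' generalized least squares estimate and `u = sigma2_u Z' V^{-1} (y - X beta)`.
#' Marker dosages are used exactly as coded (-1/0/1, not column-centered); the
#' intercept absorbs the mean shift.
#'
#' A boundary estimate `sigma2_u = 0` is legal: marker effects are zero and
#' predictions collapse to the fixed effects (a warning is issued).
#'
#' @param y Numeric response (training individuals' trait BLUPs), named or
#'   aligned with rows of `Z`.
#' @param Z Training dosage matrix (individuals x SNPs).
#' @param X Fixed-effect design matrix (default intercept only). Must have
#'   full column rank.
#' @param lambda Optional fixed ridge parameter `sigma2_e / sigma2_u`; when
#'   given, REML is skipped and the mixed-model equations are solved at this
#'   ratio (variance components are then reported only up to scale).
#' @param ZZt Optional precomputed `tcrossprod(Z)` for repeated fits over
#'   subsets of a fixed marker panel.
#' @return A `gp_fit`: beta, u (named by SNP), sigma2_u, sigma2_e, lambda,
#'   training_ids, fixed_snp_ids (empty here; see [fit_rrblup_fixed()]),
#'   fixed_design (NULL).
#' @export
fit_rrblup <- function(y, Z, X = NULL, lambda = NULL, ZZt = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2) stop("need at least 2 training observations")
  if (nrow(Z) != n) stop("rows of y and Z must align")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (nrow(X) != n) stop("rows of y and X must align")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("fixed design rank-deficient; dependent columns: ",
         paste(dep, collapse = ", "))
  }
  p <- ncol(X)
  # integer matrices bypass BLAS; coerce once
  if (!is.double(Z)) storage.mode(Z) <- "double"
  if (is.null(ZZt)) ZZt <- tcrossprod(Z)
  if (!is.double(ZZt)) storage.mode(ZZt) <- "double"

  intercept_only <- p == 1 && all(X == X[1, 1])
  if (is.null(lambda)) {
    # restricted likelihood on the null space of X. For the intercept-only
    # design the projection is plain double-centering (O(n^2)); eigenvectors
    # of the centered matrix with nonzero eigenvalue are orthogonal to the
    # constant vector, so dropping the eigenpair aligned with it leaves the
    # n-1 projected dimensions. General X falls back to an explicit
    # orthonormal null-space basis.
    if (intercept_only) {
      M <- ZZt - rowMeans(ZZt)
      M <- M - rep(colMeans(M), each = n)
      eg <- eigen(M, symmetric = TRUE)
      ones <- rep(1 / sqrt(n), n)
      drop_i <- which.max(abs(as.numeric(crossprod(eg$vectors, ones))))
      d <- pmax(eg$values[-drop_i], 0)
      theta2 <- as.numeric(crossprod(eg$vectors[, -drop_i, drop = FALSE],
                                     y - mean(y)))^2
    } else {
      Qfull <- qr.Q(qx, complete = TRUE)
      Q2 <- Qfull[, (p + 1):n, drop = FALSE]
      M <- crossprod(Q2, ZZt %*% Q2)
      eg <- eigen(M, symmetric = TRUE)
      d <- pmax(eg$values, 0)
      theta2 <- as.numeric(crossprod(eg$vectors, crossprod(Q2, y)))^2
    }
    nn <- n - p
    if (sum(theta2) < .Machine$double.eps * n) {
      # y lies in the column space of X: no residual signal at all
      phi <- 0
      d <- rep(0, nn)
    }
    negREML <- function(logphi) {
      phi <- exp(logphi)
      w <- phi * d + 1
      sum(log(w)) + nn * log(sum(theta2 / w))
    }
    if (sum(theta2) >= .Machine$double.eps * n) {
      opt <- stats::optimize(negREML, c(-25, 25), tol = 1e-10)
      phi <- exp(opt$minimum)
      # compare against the boundary (sigma2_u = 0)
      if (negREML(-300) <= opt$objective + 1e-10) phi <- 0
    }
    sigma2_e <- sum(theta2 / (phi * d + 1)) / nn
    sigma2_u <- phi * sigma2_e
    if (sigma2_u <= 1e-12 * sigma2_e) {
      warning("sigma2_u estimated at zero boundary; predictions reduce to fixed effects")
      sigma2_u <- 0
    }
    lambda_hat <- if (sigma2_u > 0) sigma2_e / sigma2_u else Inf
  } else {
    if (lambda <= 0) stop("lambda must be positive")
    sigma2_u <- NA_real_; sigma2_e <- NA_real_
    lambda_hat <- lambda
  }

  if (is.finite(lambda_hat)) {
    V <- ZZt / lambda_hat + diag(n)   # V / sigma2_e
    R <- chol(V)
    L <- t(R)
    Vi_y <- backsolve(R, forwardsolve(L, y))
    Vi_X <- backsolve(R, forwardsolve(L, X))
    XtViX <- crossprod(X, Vi_X)
    beta <- solve(XtViX, crossprod(Vi_X, y))
    r <- y - X %*% beta
    Vi_r <- backsolve(R, forwardsolve(L, r))
    u <- as.numeric(crossprod(Z, Vi_r)) / lambda_hat
  } else {
    beta <- qr.coef(qx, y)
    u <- rep(0, ncol(Z))
  }
  structure(list(
    beta = stats::setNames(as.numeric(beta), colnames(X)),
    u = stats::setNames(u, colnames(Z)),
    sigma2_u = sigma2_u, sigma2_e = sigma2_e, lambda = lambda_hat,
    training_ids = rownames(Z), fixed_snp_ids = character(),
    fixed_design = NULL), class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("gp_fit: %d training individuals, %d random SNPs | sigma2_u = %s, sigma2_e = %s, lambda = %s\n",
              length(x$training_ids), length(x$u),
              format(x$sigma2_u, digits = 4), format(x$sigma2_e, digits = 4),
              format(x$lambda, digits = 4)))
  invisible(x)
}

#' Predict genomewide estimated breeding values
#'
#' `prediction = X_new beta + Z_new u`. For models fitted with fixed-effect
#' SNPs (see [fit_rrblup_fixed()]), `X_new` is built automatically from the
#' new individuals' genotypes at the fixed SNPs; otherwise an intercept-only
#' design is assumed when `X_new` is missing.
#'
#' @param fit A `gp_fit`.
#' @param Z_new Dosage matrix of new individuals over all marker columns used
#'   at training time (fixed-effect SNPs, if any, are picked out by name).
#' @param X_new Optional explicit fixed design for the new individuals.
#' @param observed Optional named numeric of observed trait BLUPs.
#' @return data.frame (individual, predicted, observed).
#' @export
predict_gebv <- function(fit, Z_new, X_new = NULL, observed = NULL) {
  stopifnot(inherits(fit, "gp_fit"))
  if (!all(names(fit$u) %in% colnames(Z_new)))
    stop("Z_new lacks columns for the fit's random SNPs")
  Zr <- Z_new[, names(fit$u), drop = FALSE]
  if (!is.double(Zr)) storage.mode(Zr) <- "double"
  if (is.null(X_new)) {
    X_new <- if (is.null(fit$fixed_design))
      matrix(1, nrow(Z_new), 1, dimnames = list(NULL, "(Intercept)"))
    else build_fixed_design(Z_new, fit$fixed_design)
  }
  if (!identical(colnames(X_new), names(fit$beta)))
    stop("X_new columns do not match the fitted fixed design")
  pred <- as.numeric(X_new %*% fit$beta + Zr %*% fit$u)
  ids <- rownames(Z_new)
  obs <- if (is.null(observed)) rep(NA_real_, length(pred))
         else as.numeric(observed[ids])
  data.frame(individual = ids, predicted = pred, observed = obs,
             stringsAsFactors = FALSE)
}

#' Predictive ability of a prediction set
#'
#' Pearson correlation between predicted and observed trait values in the
#' test set. Requires at least 3 observed pairs and nonzero variance in both
#' vectors; a zero-variance vector raises an error (this is distinct from a
#' defined-but-zero correlation).
#'
#' @param predictions data.frame with `predicted` and `observed` columns, as
#'   from [predict_gebv()].
#' @return Pearson r in [-1, 1].
#' @export
predictive_ability <- function(predictions) {
  ok <- is.finite(predictions$predicted) & is.finite(predictions$observed)
  if (sum(ok) < 3) stop("need >= 3 test individuals with observed values")
  p <- predictions$predicted[ok]; o <- predictions$observed[ok]
  if (stats::sd(p) == 0)
    stop("predictive ability undefined: zero variance in predictions")
  if (stats::sd(o) == 0)
    stop("predictive ability undefined: zero variance in observed values")
  stats::cor(p, o)
}
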
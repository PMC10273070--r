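# Independent oracles and small fixture builders used across test files.
# These deliberately avoid the package's own computational paths.

# Closed-form ridge / mixed-model-equation solution at fixed lambda:
# [X'X, X'Z; Z'X, Z'Z + lambda I] [beta; u] = [X'y; Z'y]
ridge_mme <- function(y, X, Z, lambda) {
  A <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * diag(ncol(Z))))
  sol <- solve(A, c(crossprod(X, y), crossprod(Z, y)))
  list(beta = sol[seq_len(ncol(X))], u = sol[-seq_len(ncol(X))])
}

# Restricted log-likelihood of the two-way random-effects model
# y = mu + year + individual (+ year:individual) + e, computed densely.
# data: data.frame(individual, year, rep, value). vc: named variances.
reml_loglik_2way <- function(data, vc) {
  n <- nrow(data)
  Zy <- stats::model.matrix(~ 0 + factor(data$year))
  Zi <- stats::model.matrix(~ 0 + factor(data$individual))
  V <- vc[["year"]] * tcrossprod(Zy) + vc[["individual"]] * tcrossprod(Zi) +
    vc[["residual"]] * diag(n)
  if ("interaction" %in% names(vc) && vc[["interaction"]] > 0) {
    Zyi <- stats::model.matrix(~ 0 + factor(paste(data$year, data$individual)))
    V <- V + vc[["interaction"]] * tcrossprod(Zyi)
  }
  X <- matrix(1, n, 1)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  beta <- solve(XtViX, crossprod(X, Vi %*% data$value))
  r <- data$value - X %*% beta
  as.numeric(-0.5 * (determinant(V)$modulus + log(XtViX) +
                       crossprod(r, Vi %*% r) + (n - 1) * log(2 * pi)))
}

# Independent REML maximizer for the no-interaction two-way model:
# multi-start Nelder-Mead over log-variances of the dense restricted
# likelihood above.
reml_optim_2way <- function(data, starts = list(c(0, 1, 0.5), c(1, 0, 0),
                                                c(-1, -1, -1))) {
  obj <- function(lv) {
    -reml_loglik_2way(data, c(year = exp(lv[1]), individual = exp(lv[2]),
                              residual = exp(lv[3])))
  }
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  c(year = exp(best$par[1]), individual = exp(best$par[2]),
    residual = exp(best$par[3]))
}

# Balanced two-way dataset with known variance components
make_balanced_2way <- function(n_ind = 20, n_year = 3, vc = c(1, 4, 2),
                               mu = 10, seed = 42) {
  set.seed(seed)
  yr <- rnorm(n_year, 0, sqrt(vc[1]))
  ind <- rnorm(n_ind, 0, sqrt(vc[2]))
  d <- expand.grid(individual = sprintf("I%02d", seq_len(n_ind)),
                   year = 2000 + seq_len(n_year), stringsAsFactors = FALSE)
  d$rep <- 1L
  d$value <- mu + ind[match(d$individual, sprintf("I%02d", seq_len(n_ind)))] +
    yr[d$year - 2000] + rnorm(nrow(d), 0, sqrt(vc[3]))
  d$trait <- "t"
  d
}

# Small random marker matrix over a toy map
toy_markers <- function(n, map, seed = 1, maf = c(0.2, 0.5)) {
  set.seed(seed)
  f <- runif(nrow(map), maf[1], maf[2])
  M <- vapply(f, function(p) rbinom(n, 2, p) - 1L, integer(n))
  dimnames(M) <- list(sprintf("i%03d", seq_len(n)), map$snp)
  storage.mode(M) <- "integer"
  M
}

# Minimal blup table from a named vector
as_blup_tab <- function(b, trait = "t") {
  data.frame(individual = names(b), trait = trait, adjusted_blup = unname(b),
             n_years = 1L, stringsAsFactors = FALSE)
}

# Small germplasm + single-trait phenotypes for CV tests; cached per session
small_sim <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- default_germplasm_config(
      family_sizes = c(10, 24, 24, 24, 24, 30, 24, 24, 60, 24, 50, 30, 20),
      advanced = c(pre1995 = 4, era1995_2005 = 6, era2006_2015 = 10,
                   era2016_2020 = 3),
      n_progenitors = 4)
    map <- make_genetic_map(n_chrom = 8, snps_per_chrom = 25,
                            chrom_length_cM = 70)
    g <- build_germplasm_set(cfg, map, seed = 101)
    specs <- list(t = list(
      props = c(year = 0.05, individual = 0.6, interaction = 0, residual = 0.35),
      grand_mean = 10, sd = 2,
      qtls = list(list(chrom = "chr03", var_frac = 0.2, dominance = 0))))
    arch <- make_trait_architecture(map, specs, seed = 7)
    ph <- simulate_phenotypes(g$markers, arch, years = 2010:2012, n_reps = 1,
                              missingness = 0, seed = 13)
    fit <- fit_trait_model(ph$records, "t")
    cache <<- list(g = g, arch = arch, ph = ph,
                   blups = adjusted_blups(fit))
    cache
  }
})
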
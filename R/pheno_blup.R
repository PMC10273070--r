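#' Fit the across-year two-way random-effects model for one trait
#'
#' REML fit of `value = mu + year + individual (+ year:individual) + error`
#' with year and individual as random effects, the model used to turn
#' multi-year harvest records into across-year trait BLUPs. Under
#' `interaction = "auto"` both models are fitted and the interaction is kept
#' only if it lowers the REML AIC by more than `delta_aic` (both fits share
#' the intercept-only fixed structure, so the REML AIC comparison is valid).
#' The interaction variance is separable from the residual only when some
#' individual-year cells carry replicate measurements; without replication
#' `auto` falls back to the no-interaction model and `include` errors.
#'
#' @param records Phenotype records (columns individual, year, trait, value;
#'   optional rep).
#' @param trait Trait label to fit.
#' @param interaction `"auto"`, `"include"` or `"exclude"`.
#' @param delta_aic AIC decrease required to keep the interaction (default 2).
#' @return A `trait_model_fit`: trait, grand_mean, variance_components (named
#'   numeric: year, individual, interaction?, residual), blups (named numeric,
#'   individual effects), n_years (named integer per individual),
#'   interaction_included, aic, restricted_loglik.
#' @export
fit_trait_model <- function(records, trait,
                            interaction = c("auto", "include", "exclude"),
                            delta_aic = 2) {
  interaction <- match.arg(interaction)
  d <- records[records$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) stop("trait not present in records: ", trait)
  if (any(!is.finite(d$value))) stop("non-finite phenotype values")
  if (length(unique(d$year)) < 2)
    stop("need >= 2 distinct years to separate year variance")
  if (length(unique(d$individual)) < 2) stop("need >= 2 individuals")

  d$individual <- factor(d$individual)
  d$year <- factor(d$year)
  n_years <- tapply(d$year, d$individual, function(y) length(unique(y)))
  n_years <- stats::setNames(as.integer(n_years), names(n_years))

  # degenerate data: constant response
  if (stats::sd(d$value) == 0) {
    vc <- c(year = 0, individual = 0, residual = 0)
    return(structure(list(
      trait = trait, grand_mean = d$value[1], variance_components = vc,
      blups = stats::setNames(rep(0, nlevels(d$individual)), levels(d$individual)),
      n_years = n_years, interaction_included = FALSE,
      aic = NA_real_, restricted_loglik = NA_real_), class = "trait_model_fit"))
  }

  replicated <- any(table(d$individual, d$year) > 1)
  fit0 <- lme4::lmer(value ~ (1 | year) + (1 | individual), data = d,
                     REML = TRUE,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))
  fit <- fit0
  included <- FALSE
  if (interaction != "exclude") {
    if (!replicated) {
      if (interaction == "include")
        stop("interaction inestimable: no replicated individual-year cells")
    } else {
      fit1 <- lme4::lmer(
        value ~ (1 | year) + (1 | individual) + (1 | year:individual),
        data = d, REML = TRUE,
        control = lme4::lmerControl(check.conv.singular = "ignore"))
      keep <- interaction == "include" ||
        (stats::AIC(fit0) - stats::AIC(fit1)) > delta_aic
      if (keep) { fit <- fit1; included <- TRUE }
    }
  }

  vc_all <- as.data.frame(lme4::VarCorr(fit))
  comp <- stats::setNames(vc_all$vcov, vc_all$grp)
  vc <- c(year = unname(comp["year"]), individual = unname(comp["individual"]))
  if (included) vc <- c(vc, interaction = unname(comp["year:individual"]))
  vc <- c(vc, residual = unname(comp["Residual"]))

  blups <- lme4::ranef(fit)$individual
  blups <- stats::setNames(blups[["(Intercept)"]], rownames(blups))

  structure(list(
    trait = trait,
    grand_mean = unname(lme4::fixef(fit)[["(Intercept)"]]),
    variance_components = vc,
    blups = blups,
    n_years = n_years,
    interaction_included = included,
    aic = stats::AIC(fit),
    restricted_loglik = as.numeric(stats::logLik(fit))),
    class = "trait_model_fit")
}

#' @export
print.trait_model_fit <- function(x, ...) {
  cat(sprintf("trait_model_fit: %s | mu = %.3f | interaction %s\n",
              x$trait, x$grand_mean,
              if (x$interaction_included) "included" else "excluded"))
  print(round(x$variance_components, 4))
  invisible(x)
}

#' Mean-adjusted across-year BLUPs
#'
#' Individual BLUP plus the model grand mean, so values sit on the trait
#' scale. Shrinkage follows from the mixed model: adjusted values lie between
#' the grand mean and the individual's raw mean, more strongly shrunk for
#' individuals observed in fewer years.
#'
#' @param fit A `trait_model_fit`.
#' @return data.frame (individual, trait, adjusted_blup, n_years).
#' @export
adjusted_blups <- function(fit) {
  stopifnot(inherits(fit, "trait_model_fit"))
  data.frame(individual = names(fit$blups), trait = fit$trait,
             adjusted_blup = unname(fit$blups) + fit$grand_mean,
             n_years = unname(fit$n_years[names(fit$blups)]),
             stringsAsFactors = FALSE)
}

#' Variance proportions of a fitted trait model
#'
#' Each REML variance component divided by their total, the quantities shown
#' in proportion-of-variation partitions.
#'
#' @param fit A `trait_model_fit`.
#' @return Named numeric proportions summing to 1.
#' @export
variance_proportions <- function(fit) {
  stopifnot(inherits(fit, "trait_model_fit"))
  tot <- sum(fit$variance_components)
  if (tot <= 0) stop("total variance is zero; proportions undefined")
  fit$variance_components / tot
}

#' Fit all traits and collect adjusted BLUPs
#'
#' Convenience wrapper running [fit_trait_model()] per trait and binding the
#' [adjusted_blups()] tables.
#'
#' @param records Phenotype records.
#' @param traits Traits to fit (default: all present).
#' @param ... Passed to [fit_trait_model()].
#' @return List: `blups` (long data.frame), `fits` (named list),
#'   `proportions` (data.frame trait, component, proportion).
#' @export
blup_all_traits <- function(records, traits = unique(records$trait), ...) {
  fits <- lapply(traits, function(tr) fit_trait_model(records, tr, ...))
  names(fits) <- traits
  blups <- do.call(rbind, lapply(fits, adjusted_blups))
  rownames(blups) <- NULL
  props <- do.call(rbind, lapply(traits, function(tr) {
    p <- variance_proportions(fits[[tr]])
    data.frame(trait = tr, component = names(p), proportion = unname(p))
  }))
  list(blups = blups, fits = fits, proportions = props)
}
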
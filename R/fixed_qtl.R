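#' Genotype-class ANOVA with Tukey HSD mean separation
#'
#' One-way ANOVA of trait BLUPs across the genotype classes (-1/0/1) of one
#' SNP, with Tukey honestly-significant-difference pairwise comparisons
#' summarized as a compact-letter display (classes sharing a letter do not
#' differ at `alpha`).
#'
#' @param snp_dosages Named numeric dosages (-1/0/1) per individual.
#' @param blups Named numeric trait BLUPs per individual.
#' @param alpha Significance level for the letter display.
#' @return A `class_comparison`: `classes` (data.frame genotype, n, mean,
#'   letters), `F_statistic`, `p_value`, `tukey` (the TukeyHSD table).
#' @export
genotype_class_anova <- function(snp_dosages, blups, alpha = 0.05) {
  ids <- intersect(names(snp_dosages), names(blups))
  d <- data.frame(geno = factor(snp_dosages[ids], levels = c(-1, 0, 1)),
                  y = as.numeric(blups[ids]))
  d <- droplevels(d[!is.na(d$geno) & is.finite(d$y), ])
  counts <- table(d$geno)
  if (nlevels(d$geno) < 2)
    stop("SNP monomorphic in this set: only one genotype class present")
  if (any(counts < 2)) stop("each genotype class needs n >= 2")
  fit <- stats::aov(y ~ geno, data = d)
  an <- summary(fit)[[1]]
  Fv <- an[["F value"]][1]; pv <- an[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$geno
  means <- tapply(d$y, d$geno, mean)
  letters <- compact_letters(rownames(tk), tk[, "p adj"], means, alpha)
  classes <- data.frame(genotype = as.numeric(names(means)),
                        n = as.integer(counts),
                        mean = as.numeric(means),
                        letters = letters[names(means)],
                        stringsAsFactors = FALSE)
  structure(list(classes = classes, F_statistic = Fv, p_value = pv,
                 tukey = tk), class = "class_comparison")
}

#' @export
print.class_comparison <- function(x, ...) {
  cat(sprintf("class_comparison: F = %.3f, p = %.3g\n", x$F_statistic, x$p_value))
  print(x$classes)
  invisible(x)
}

# insert-and-absorb compact letter display from pairwise adjusted p-values;
# pair names "a-b" as produced by TukeyHSD. Ties in letter order are resolved
# by ascending class mean.
compact_letters <- function(pair_names, p_adj, means, alpha = 0.05) {
  lev <- names(sort(means))
  k <- length(lev)
  differ <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  for (i in seq_along(pair_names)) {
    # pair label is "a-b"; level labels may themselves contain "-" (-1), so
    # split at the position where both halves are known levels
    ab <- NULL
    for (cut in gregexpr("-", pair_names[i], fixed = TRUE)[[1]]) {
      l <- substr(pair_names[i], 1, cut - 1)
      r <- substr(pair_names[i], cut + 1, nchar(pair_names[i]))
      if (l %in% lev && r %in% lev) { ab <- c(l, r); break }
    }
    if (is.null(ab)) stop("cannot parse Tukey pair label: ", pair_names[i])
    if (p_adj[i] < alpha) {
      differ[ab[1], ab[2]] <- TRUE
      differ[ab[2], ab[1]] <- TRUE
    }
  }
  # groups = maximal sets of mutually non-different levels (greedy over the
  # mean-ordered levels; exact for the small class counts arising here)
  groups <- list()
  for (i in seq_len(k)) {
    placed <- any(vapply(groups, function(g) lev[i] %in% g, logical(1)))
    g <- lev[i]
    for (j in seq_len(k)) {
      if (j != i && !differ[lev[i], lev[j]] &&
          all(!differ[lev[j], g])) g <- c(g, lev[j])
    }
    g <- lev[lev %in% g]
    if (!any(vapply(groups, function(x) all(g %in% x), logical(1))))
      groups[[length(groups) + 1]] <- g
  }
  # absorb groups contained in others
  keep <- vapply(seq_along(groups), function(i)
    !any(vapply(seq_along(groups), function(j)
      j != i && all(groups[[i]] %in% groups[[j]]), logical(1))), logical(1))
  groups <- groups[keep]
  out <- stats::setNames(rep("", k), lev)
  for (gi in seq_along(groups))
    out[groups[[gi]]] <- paste0(out[groups[[gi]]], letters[gi])
  out
}

# design-matrix spec for fixed-effect SNPs, reused at training and prediction
# time so dummy columns always refer to the training-set classes
make_fixed_design_spec <- function(markers, fixed_snp_ids,
                                   encoding = c("categorical", "additive")) {
  encoding <- match.arg(encoding)
  missing <- setdiff(fixed_snp_ids, colnames(markers))
  if (length(missing))
    stop("fixed SNPs absent from marker matrix: ", paste(missing, collapse = ", "))
  cols <- list()
  for (s in fixed_snp_ids) {
    v <- markers[, s]
    lev <- sort(unique(v))
    if (length(lev) < 2) {
      warning("fixed SNP ", s, " monomorphic in training set; column dropped")
      next
    }
    cols[[s]] <- if (encoding == "additive") list(type = "additive")
                 else list(type = "categorical", levels = lev[-1]) # first = reference
  }
  list(encoding = encoding, snps = cols)
}

build_fixed_design <- function(markers, spec) {
  n <- nrow(markers)
  X <- matrix(1, n, 1, dimnames = list(rownames(markers), "(Intercept)"))
  for (s in names(spec$snps)) {
    info <- spec$snps[[s]]
    v <- markers[, s]
    if (info$type == "additive") {
      X <- cbind(X, as.numeric(v))
      colnames(X)[ncol(X)] <- paste0(s, "_add")
    } else {
      for (l in info$levels) {
        X <- cbind(X, as.numeric(v == l))
        colnames(X)[ncol(X)] <- paste0(s, "_", l)
      }
    }
  }
  as.matrix(X)
}

#' RR-BLUP with designated QTL SNPs as fixed effects
#'
#' Builds the fixed design `X = [intercept | fixed-SNP columns]` — dummy
#' columns per observed genotype class under `"categorical"` encoding (the
#' default, able to capture dominance), or the dosage itself under
#' `"additive"` — removes the fixed SNPs from the random-effect panel, and
#' fits via [fit_rrblup()]. With an empty `fixed_snp_ids` the fit is
#' identical to the random-only model.
#'
#' @param y Named numeric training BLUPs.
#' @param markers Dosage matrix including the fixed SNPs.
#' @param fixed_snp_ids SNP ids promoted to fixed effects.
#' @param encoding `"categorical"` or `"additive"`.
#' @param train Optional training ids (default: names of `y`).
#' @return A `gp_fit` carrying `fixed_snp_ids` and the design spec used, so
#'   [predict_gebv()] can rebuild `X_new` from test genotypes.
#' @export
fit_rrblup_fixed <- function(y, markers, fixed_snp_ids,
                             encoding = c("categorical", "additive"),
                             train = names(y)) {
  encoding <- match.arg(encoding)
  Ztr <- markers[train, , drop = FALSE]
  if (length(fixed_snp_ids) == 0)
    return(fit_rrblup(y[train], Ztr))
  spec <- make_fixed_design_spec(Ztr, fixed_snp_ids, encoding)
  X <- build_fixed_design(Ztr, spec)
  Zr <- Ztr[, setdiff(colnames(Ztr), fixed_snp_ids), drop = FALSE]
  fit <- fit_rrblup(y[train], Zr, X = X)
  fit$fixed_snp_ids <- fixed_snp_ids
  fit$fixed_design <- spec
  fit
}

#' Paired comparison of fixed-QTL versus random-only predictive abilities
#'
#' Classic paired t-test on per-family differences `r_fixed - r_random`.
#'
#' @param r_fixed,r_random Named numeric predictive abilities over the same
#'   families in the same order.
#' @return List: mean_difference, t_statistic, p_value, df, n.
#' @export
compare_fixed_vs_random <- function(r_fixed, r_random) {
  if (length(r_fixed) != length(r_random))
    stop("family lists differ in length")
  if (!is.null(names(r_fixed)) && !is.null(names(r_random)) &&
      !identical(names(r_fixed), names(r_random)))
    stop("family lists do not match")
  ok <- is.finite(r_fixed) & is.finite(r_random)
  if (sum(ok) < 3) stop("need >= 3 defined pairs")
  d <- r_fixed[ok] - r_random[ok]
  if (stats::sd(d) == 0) {
    return(list(mean_difference = mean(d), t_statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                p_value = if (mean(d) == 0) 1 else 0, df = sum(ok) - 1, n = sum(ok)))
  }
  tt <- stats::t.test(r_fixed[ok], r_random[ok], paired = TRUE)
  list(mean_difference = unname(tt$estimate), t_statistic = unname(tt$statistic),
       p_value = tt$p.value, df = unname(tt$parameter), n = sum(ok))
}

#' Leave-one-family-out predictive abilities with and without fixed QTL SNPs
#'
#' Runs the leave-one-family-out scheme twice per trait — all SNPs random,
#' and with the designated SNPs as fixed effects — and returns per-family
#' abilities aligned for a paired comparison.
#'
#' @inheritParams leave_one_family_out_cv
#' @param fixed_snp_ids SNPs promoted to fixed effects.
#' @param encoding Fixed-SNP encoding.
#' @param trait Single trait to evaluate.
#' @return data.frame (test_family, n_test, r_random, r_fixed).
#' @export
lofo_fixed_vs_random <- function(blups, markers, pedigree, trait,
                                 fixed_snp_ids,
                                 encoding = c("categorical", "additive"),
                                 families = NULL) {
  encoding <- match.arg(encoding)
  fams <- sort(unique(stats::na.omit(pedigree$family)))
  if (is.null(families)) families <- fams
  ids <- cv_population(blups, markers, pedigree)
  b <- blup_vector(blups, trait)
  fam_of <- stats::setNames(pedigree$family, pedigree$id)
  rows <- lapply(families, function(fam) {
    test <- ids[!is.na(fam_of[ids]) & fam_of[ids] == fam]
    test <- test[test %in% names(b)]
    train <- intersect(setdiff(ids, test), names(b))
    score <- function(fit) {
      pred <- predict_gebv(fit, markers[test, , drop = FALSE], observed = b)
      tryCatch(predictive_ability(pred), error = function(e) NA_real_)
    }
    fr <- suppressWarnings(fit_rrblup(b[train], markers[train, , drop = FALSE]))
    ff <- suppressWarnings(fit_rrblup_fixed(b, markers, fixed_snp_ids,
                                            encoding, train = train))
    data.frame(test_family = fam, n_test = length(test),
               r_random = score(fr), r_fixed = score(ff),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
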
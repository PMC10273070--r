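# Training/test construction schemes. Every function returns a tidy
# data.frame, one row per evaluated model: scheme, trait, iteration, the
# scheme's metadata, n_train, n_test, r, r_reason (NA when r is defined),
# seed. Undefined predictive abilities (zero variance, tiny test sets) are
# recorded as NA with a reason code, never silently dropped or coerced to 0.

# individuals eligible for CV: phenotyped, genotyped and (by default)
# unselected offspring only
cv_population <- function(blup_tab, markers, pedigree = NULL,
                          include_all = FALSE) {
  ids <- intersect(unique(blup_tab$individual), rownames(markers))
  if (!is.null(pedigree) && !include_all) {
    off <- pedigree$id[pedigree$class == "unselected_offspring"]
    ids <- intersect(ids, off)
  }
  ids
}

blup_vector <- function(blup_tab, trait) {
  b <- blup_tab[blup_tab$trait == trait, ]
  stats::setNames(b$adjusted_blup, b$individual)
}

# fit on train, score on test; returns list(r, reason).
# train is silently restricted to individuals phenotyped for the trait.
fit_and_score <- function(b, markers, train, test, ZZt = NULL) {
  train <- train[train %in% names(b)]
  if (length(train) < 2)
    return(list(r = NA_real_, reason = "fewer than 2 phenotyped training members"))
  fit <- suppressWarnings(fit_rrblup(
    b[train], markers[train, , drop = FALSE],
    ZZt = if (is.null(ZZt)) NULL else ZZt[train, train]))
  pred <- predict_gebv(fit, markers[test, , drop = FALSE], observed = b)
  r <- tryCatch(predictive_ability(pred),
                error = function(e) structure(NA_real_, reason = conditionMessage(e)))
  list(r = as.numeric(r),
       reason = if (is.na(r)) attr(r, "reason") else NA_character_)
}

#' Random-fraction cross-validation
#'
#' At each iteration a random `floor(fraction * N)` subset of the population
#' trains the model and the complement is the test set. Iteration i draws its
#' sample under seed `seed + i`, so every training set is reconstructible
#' from (fraction, iteration, seed); the same iteration shares its seed
#' across fractions, nesting the samples for paired comparisons.
#'
#' @param blups Adjusted-BLUP table (individual, trait, adjusted_blup).
#' @param markers QC-filtered dosage matrix.
#' @param fractions Training fractions in (0, 1).
#' @param n_iter Iterations per fraction (the reference design uses 500).
#' @param seed Base integer seed.
#' @param pedigree Optional pedigree; when given, the population is restricted
#'   to unselected offspring unless `include_all = TRUE`.
#' @param include_all Keep advanced selections/parents in the population.
#' @param traits Traits to evaluate (default: all in `blups`).
#' @return Tidy results data.frame (see file header).
#' @export
random_fraction_cv <- function(blups, markers,
                               fractions = c(0.10, 0.25, 0.50, 0.75),
                               n_iter = 500, seed = 1L, pedigree = NULL,
                               include_all = FALSE,
                               traits = unique(blups$trait)) {
  if (any(fractions <= 0 | fractions >= 1)) stop("fractions must be in (0,1)")
  ids <- cv_population(blups, markers, pedigree, include_all)
  N <- length(ids)
  if (N < 8) stop("population too small for random-fraction CV")
  ZZt <- tcrossprod(markers[ids, , drop = FALSE])
  dimnames(ZZt) <- list(ids, ids)
  bv <- lapply(traits, function(tr) blup_vector(blups, tr))
  names(bv) <- traits

  rows <- list()
  for (f in fractions) {
    k <- floor(f * N)
    for (i in seq_len(n_iter)) {
      set.seed(seed + i)
      train <- sample(ids, k)
      test <- setdiff(ids, train)
      for (tr in traits) {
        sc <- fit_and_score(bv[[tr]], markers[, , drop = FALSE], train, test, ZZt)
        rows[[length(rows) + 1]] <- data.frame(
          scheme = "random_fraction", trait = tr, iteration = i,
          fraction = f, n_train = k, n_test = N - k,
          r = sc$r, r_reason = sc$reason, seed = seed,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Leave-one-family-out cross-validation
#'
#' Each full-sib family in turn is the test set; all offspring of the other
#' families train the model. Families with fewer than 3 phenotyped members
#' yield an undefined r, flagged with a reason code.
#'
#' @inheritParams random_fraction_cv
#' @param pedigree Pedigree (required: defines the families).
#' @param families Families to use as test sets (default: all).
#' @return Tidy results data.frame with a `test_family` column.
#' @export
leave_one_family_out_cv <- function(blups, markers, pedigree,
                                    traits = unique(blups$trait),
                                    families = NULL) {
  fams <- sort(unique(stats::na.omit(pedigree$family)))
  if (length(fams) < 2) stop("need >= 2 families")
  if (is.null(families)) families <- fams
  ids <- cv_population(blups, markers, pedigree)
  ZZt <- tcrossprod(markers[ids, , drop = FALSE])
  dimnames(ZZt) <- list(ids, ids)
  fam_of <- stats::setNames(pedigree$family, pedigree$id)

  rows <- list()
  for (fam in families) {
    test <- ids[!is.na(fam_of[ids]) & fam_of[ids] == fam]
    train <- setdiff(ids, test)
    for (tr in traits) {
      b <- blup_vector(blups, tr)
      test_t <- test[test %in% names(b)]
      train_t <- intersect(train, names(b))
      if (length(test_t) < 3) {
        sc <- list(r = NA_real_, reason = "fewer than 3 phenotyped test members")
      } else {
        sc <- fit_and_score(b, markers, train_t, test_t, ZZt)
      }
      rows[[length(rows) + 1]] <- data.frame(
        scheme = "leave_one_family_out", trait = tr, iteration = 1L,
        test_family = fam, n_train = length(train_t), n_test = length(test_t),
        r = sc$r, r_reason = sc$reason, seed = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# delete-one predictions within a fixed set of ids
delete_one_predictions <- function(b, markers, ids, ZZt = NULL) {
  if (is.null(ZZt)) {
    ZZt <- tcrossprod(markers[ids, , drop = FALSE])
    dimnames(ZZt) <- list(ids, ids)
  }
  pred <- vapply(ids, function(id) {
    train <- setdiff(ids, id)
    fit <- suppressWarnings(fit_rrblup(
      b[train], markers[train, , drop = FALSE], ZZt = ZZt[train, train]))
    predict_gebv(fit, markers[id, , drop = FALSE])$predicted
  }, numeric(1))
  data.frame(individual = ids, predicted = unname(pred),
             observed = unname(b[ids]), stringsAsFactors = FALSE)
}

#' Within-family delete-one prediction
#'
#' Each offspring of one full-sib family is predicted from the remaining
#' offspring of the same family; a single predictive ability is computed over
#' the assembled (predicted, observed) pairs. Degenerate families (e.g.
#' clones giving constant predictions) yield an undefined r with a reason.
#'
#' @inheritParams leave_one_family_out_cv
#' @param family Family label.
#' @return Tidy results data.frame; per-individual predictions are attached
#'   as `attr(, "predictions")` (a named list by trait).
#' @export
within_family_loo <- function(blups, markers, pedigree, family,
                              traits = unique(blups$trait)) {
  fam_ids <- family_members(pedigree, family)
  rows <- list(); preds <- list()
  for (tr in traits) {
    b <- blup_vector(blups, tr)
    ids <- intersect(fam_ids, intersect(names(b), rownames(markers)))
    if (length(ids) < 4) stop("family must have >= 4 phenotyped members")
    if (all(apply(markers[ids, , drop = FALSE], 2,
                  function(x) length(unique(x)) == 1))) {
      # clones: delete-one predictions carry zero genotypic variance
      pr <- data.frame(individual = ids, predicted = NA_real_,
                       observed = unname(b[ids]), stringsAsFactors = FALSE)
      r <- structure(NA_real_,
                     reason = "zero variance: no genotypic variation within family")
    } else {
      pr <- delete_one_predictions(b, markers, ids)
      r <- tryCatch(predictive_ability(pr),
                    error = function(e) structure(NA_real_,
                                                  reason = conditionMessage(e)))
    }
    preds[[tr]] <- pr
    rows[[length(rows) + 1]] <- data.frame(
      scheme = "within_family_loo", trait = tr, iteration = 1L,
      test_family = family, n_train = length(ids) - 1L, n_test = length(ids),
      r = as.numeric(r),
      r_reason = if (is.na(r)) attr(r, "reason") else NA_character_,
      seed = NA_integer_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "predictions") <- preds
  out
}

#' Family-size subset curve
#'
#' Random subsets of a large family at each requested size; within each
#' subset, delete-one prediction yields one r per iteration. Sizes exceeding
#' the family size are skipped with a message; a size equal to the family
#' size collapses to a single deterministic delete-one run.
#'
#' @inheritParams within_family_loo
#' @param sizes Subset sizes to evaluate.
#' @param n_iter Iterations per size (the reference design uses 100).
#' @param seed Base integer seed; iteration i samples under `seed + i`.
#' @return Tidy results data.frame with a `subset_size` column.
#' @export
family_subset_curve <- function(blups, markers, pedigree, family,
                                sizes = c(20, 40, 60, 80, 100, 120),
                                n_iter = 100, seed = 1L,
                                traits = unique(blups$trait)) {
  fam_ids <- family_members(pedigree, family)
  rows <- list()
  for (tr in traits) {
    b <- blup_vector(blups, tr)
    ids <- intersect(fam_ids, intersect(names(b), rownames(markers)))
    n <- length(ids)
    ZZt <- tcrossprod(markers[ids, , drop = FALSE])
    dimnames(ZZt) <- list(ids, ids)
    for (s in sizes) {
      if (s > n) {
        message("subset size ", s, " exceeds family size ", n, "; skipped")
        next
      }
      iters <- if (s == n) 1L else n_iter
      for (i in seq_len(iters)) {
        set.seed(seed + i)
        sub <- if (s == n) ids else sample(ids, s)
        pr <- delete_one_predictions(b, markers, sub, ZZt[sub, sub])
        r <- tryCatch(predictive_ability(pr),
                      error = function(e) structure(NA_real_,
                                                    reason = conditionMessage(e)))
        rows[[length(rows) + 1]] <- data.frame(
          scheme = "family_subset", trait = tr, iteration = i,
          test_family = family, subset_size = s,
          n_train = s - 1L, n_test = s,
          r = as.numeric(r),
          r_reason = if (is.na(r)) attr(r, "reason") else NA_character_,
          seed = seed, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(scheme = character(), trait = character(),
                      iteration = integer(), test_family = character(),
                      subset_size = integer(), n_train = integer(),
                      n_test = integer(), r = numeric(),
                      r_reason = character(), seed = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' SNPs-per-chromosome subsampling with leave-one-family-out evaluation
#'
#' At each iteration, `count` SNPs are sampled without replacement per
#' chromosome from the QC-retained panel; the reduced panel is then evaluated
#' by leave-one-family-out prediction. Counts above the smallest per-
#' chromosome panel are capped with a warning.
#'
#' @inheritParams leave_one_family_out_cv
#' @param map `genetic_map` for the retained SNPs.
#' @param counts SNPs per chromosome to test.
#' @param n_iter Iterations per count (the reference design uses 100).
#' @param seed Base seed; iteration i samples SNPs under `seed + i`.
#' @param families Test families (default: all).
#' @return Tidy results data.frame with `snps_per_chrom` and `test_family`.
#' @export
snps_per_chrom_cv <- function(blups, markers, map, pedigree,
                              counts = c(5, 10, 15, 20, 25, 30),
                              n_iter = 100, seed = 1L,
                              families = NULL,
                              traits = unique(blups$trait)) {
  snp_chrom <- stats::setNames(map$chrom, map$snp)[colnames(markers)]
  by_chrom <- split(colnames(markers), snp_chrom)
  avail <- min(lengths(by_chrom))
  counts_used <- pmin(counts, avail)
  if (any(counts_used < counts))
    warning("counts capped at ", avail, " (smallest per-chromosome panel)")

  rows <- list()
  for (ci in seq_along(counts)) {
    cnt <- counts_used[ci]
    for (i in seq_len(n_iter)) {
      set.seed(seed + i)
      snps <- unlist(lapply(by_chrom, function(s) sample(s, cnt)),
                     use.names = FALSE)
      res <- leave_one_family_out_cv(blups, markers[, snps, drop = FALSE],
                                     pedigree, traits = traits,
                                     families = families)
      res$scheme <- "snps_per_chrom"
      res$iteration <- i
      res$snps_per_chrom <- counts[ci]
      res$seed <- seed
      rows[[length(rows) + 1]] <- res
    }
  }
  do.call(rbind, rows)
}

#' Summarize tidy CV results
#'
#' Mean/min/max predictive ability per scheme level, with counts of defined
#' and undefined r values (undefined values are excluded from the moments,
#' never imputed).
#'
#' @param results Tidy CV results.
#' @param by Grouping columns (default: scheme, trait plus whichever metadata
#'   columns are present).
#' @return Aggregated data.frame.
#' @export
summarize_cv <- function(results,
                         by = intersect(c("scheme", "trait", "fraction",
                                          "test_family", "subset_size",
                                          "snps_per_chrom"), names(results))) {
  groups <- interaction(results[by], drop = TRUE)
  agg <- lapply(split(results, groups), function(g) {
    ok <- !is.na(g$r)
    cbind(g[1, by, drop = FALSE],
          data.frame(n = nrow(g), n_defined = sum(ok),
                     mean_r = if (any(ok)) mean(g$r[ok]) else NA_real_,
                     min_r = if (any(ok)) min(g$r[ok]) else NA_real_,
                     max_r = if (any(ok)) max(g$r[ok]) else NA_real_))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
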
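#' Built-in culling-threshold scenarios
#'
#' Five independent-culling scenarios for the postdiction traits. Weight is
#' culled high (avoid excessively large fruit); firmness (M1, M2), soluble
#' solids (SSC) and acidity (TA) are culled low. Overcolor and crispness (Cn)
#' are keep-all throughout. Rules: `A` — reference individual's BLUP plus/minus
#' one SD; `B` — advanced-selection mean plus/minus one SD; `C`/`D`/`E` —
#' percentiles of the training set's unselected-offspring BLUPs (weight 90%
#' throughout; M1/M2 10-25%; SSC/TA 10-25%).
#'
#' @param scenario One of `"A".."E"`.
#' @return data.frame (trait, rule, p, direction); `p` is the percentile for
#'   percentile rules, NA otherwise.
#' @export
threshold_scenario <- function(scenario = c("A", "B", "C", "D", "E")) {
  scenario <- match.arg(scenario)
  tr <- c("overcolor", "weight", "M1", "M2", "Cn", "SSC", "TA")
  dir <- c("none", "cull_if_ge", "cull_if_le", "cull_if_le", "none",
           "cull_if_le", "cull_if_le")
  rule <- switch(scenario,
    A = c("keep_all", "reference_plus_sd", "reference_minus_sd",
          "reference_minus_sd", "keep_all", "reference_minus_sd",
          "reference_minus_sd"),
    B = c("keep_all", "selection_mean_plus_sd", "selection_mean_minus_sd",
          "selection_mean_minus_sd", "keep_all", "selection_mean_minus_sd",
          "selection_mean_minus_sd"),
    C = rep(c("keep_all", "percentile"), c(1, 6))[c(1, 2, 2, 2, 1, 2, 2)],
    D = rep(c("keep_all", "percentile"), c(1, 6))[c(1, 2, 2, 2, 1, 2, 2)],
    E = rep(c("keep_all", "percentile"), c(1, 6))[c(1, 2, 2, 2, 1, 2, 2)])
  rule[c(1, 5)] <- "keep_all"
  p <- switch(scenario,
    A = rep(NA_real_, 7), B = rep(NA_real_, 7),
    C = c(NA, 0.90, 0.10, 0.10, NA, 0.10, 0.10),
    D = c(NA, 0.90, 0.25, 0.25, NA, 0.10, 0.10),
    E = c(NA, 0.90, 0.25, 0.25, NA, 0.25, 0.25))
  data.frame(trait = tr, rule = rule, p = p, direction = dir,
             stringsAsFactors = FALSE)
}

#' Compute per-trait culling thresholds for a training set
#'
#' Thresholds are computed from the round's training data only: SD-based rules
#' use the standard deviation of the training set's trait BLUPs (over
#' unselected offspring by default, configurable via `sd_source`); percentile
#' rules use type-7 quantiles of the training set's unselected-offspring
#' BLUPs. Keep-all traits receive direction `"none"`.
#'
#' @param scenario Scenario id `"A".."E"` or a scenario data.frame as from
#'   [threshold_scenario()].
#' @param blups Adjusted-BLUP table.
#' @param pedigree Pedigree (classes drive the rule populations).
#' @param training_ids Ids of the round's training set.
#' @param reference_individual Reference id for scenario A rules.
#' @param traits Traits to threshold (default: all in the scenario table).
#' @param sd_source `"offspring"`, `"selections"` or `"all"`: which training
#'   individuals define the SD.
#' @return data.frame (trait, rule, threshold, direction).
#' @export
compute_thresholds <- function(scenario, blups, pedigree, training_ids,
                               reference_individual = NULL,
                               traits = NULL,
                               sd_source = c("offspring", "selections", "all")) {
  sd_source <- match.arg(sd_source)
  sc <- if (is.character(scenario)) threshold_scenario(scenario) else scenario
  if (!is.null(traits)) sc <- sc[sc$trait %in% traits, , drop = FALSE]
  cls <- stats::setNames(pedigree$class, pedigree$id)
  off_ids <- training_ids[cls[training_ids] == "unselected_offspring"]
  sel_ids <- training_ids[cls[training_ids] == "advanced_selection"]

  rows <- lapply(seq_len(nrow(sc)), function(i) {
    tr <- sc$trait[i]; rule <- sc$rule[i]
    b <- blup_vector(blups, tr)
    thr <- NA_real_
    if (rule != "keep_all") {
      sd_ids <- switch(sd_source, offspring = off_ids, selections = sel_ids,
                       all = training_ids)
      s <- stats::sd(b[intersect(sd_ids, names(b))], na.rm = TRUE)
      if (grepl("^reference", rule)) {
        if (is.null(reference_individual) ||
            !reference_individual %in% names(b) ||
            is.na(b[reference_individual]))
          stop("reference individual has no BLUP for trait ", tr)
        ref <- b[reference_individual]
        thr <- if (rule == "reference_plus_sd") ref + s else ref - s
      } else if (grepl("^selection_mean", rule)) {
        sel <- b[intersect(sel_ids, names(b))]
        if (length(sel) < 2) stop("scenario B needs >= 2 training selections")
        thr <- if (rule == "selection_mean_plus_sd") mean(sel) + s
               else mean(sel) - s
      } else if (rule == "percentile") {
        pop <- b[intersect(off_ids, names(b))]
        if (length(pop) < 10) stop("percentile rules need >= 10 training offspring")
        thr <- unname(stats::quantile(pop, sc$p[i], type = 7))
      } else stop("unknown rule: ", rule)
    }
    data.frame(trait = tr, rule = rule, threshold = unname(thr),
               direction = sc$direction[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Apply independent culling thresholds
#'
#' An individual is culled if any trait violates its threshold, inclusively:
#' `value >= threshold` culls under `cull_if_ge`, `value <= threshold` under
#' `cull_if_le`. Missing trait values leave that trait unevaluated for the
#' individual (flagged), with the decision made from the remaining traits.
#'
#' @param values data.frame (individual, trait, value) — observed BLUPs or
#'   genomewide predictions, same code path.
#' @param thresholds Threshold table from [compute_thresholds()].
#' @return data.frame (individual, decision, n_failing, failing_traits,
#'   unevaluated_traits); `failing_traits` comma-separated.
#' @export
apply_independent_culling <- function(values, thresholds) {
  ids <- unique(values$individual)
  active <- thresholds[thresholds$direction != "none", , drop = FALSE]
  if (length(ids) == 0)
    return(data.frame(individual = character(), decision = character(),
                      n_failing = integer(), failing_traits = character(),
                      unevaluated_traits = character(),
                      stringsAsFactors = FALSE))
  val <- function(id, tr) {
    v <- values$value[values$individual == id & values$trait == tr]
    if (length(v) == 0) NA_real_ else v[1]
  }
  rows <- lapply(ids, function(id) {
    failing <- character(); unev <- character()
    for (i in seq_len(nrow(active))) {
      v <- val(id, active$trait[i])
      if (is.na(v)) { unev <- c(unev, active$trait[i]); next }
      bad <- switch(active$direction[i],
                    cull_if_ge = v >= active$threshold[i],
                    cull_if_le = v <= active$threshold[i])
      if (bad) failing <- c(failing, active$trait[i])
    }
    data.frame(individual = id,
               decision = if (length(failing)) "cull" else "keep",
               n_failing = length(failing),
               failing_traits = paste(failing, collapse = ","),
               unevaluated_traits = paste(unev, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Agreement between phenotypic and genomewide selection decisions
#'
#' @param observed_decisions,predicted_decisions Decision tables from
#'   [apply_independent_culling()] over the same individuals.
#' @return List: `table` (2x2 keep/cull counts, observed in rows),
#'   `percent_concordant`, `n`.
#' @export
compare_selection_methods <- function(observed_decisions, predicted_decisions) {
  o <- observed_decisions[order(observed_decisions$individual), ]
  p <- predicted_decisions[order(predicted_decisions$individual), ]
  if (!identical(o$individual, p$individual))
    stop("decision sets cover different individuals")
  lev <- c("keep", "cull")
  tab <- table(factor(o$decision, lev), factor(p$decision, lev),
               dnn = c("observed", "predicted"))
  list(table = tab,
       percent_concordant = if (sum(tab) == 0) NA_real_
                            else 100 * sum(diag(tab)) / sum(tab),
       n = sum(tab))
}

#' Build the three chronological postdiction rounds
#'
#' Round 1 trains on first-wave family offspring plus cultivars/parents/
#' progenitors plus pre-1995 advanced selections, and tests the 1995-2005
#' selections; round 2 adds round 1's test set and the second-wave (second
#' hub's) families, testing the 2006-2015 selections; round 3 adds those and
#' tests the 2016-2020 selections. Training sets are nested; each test set is
#' disjoint from its training set.
#'
#' @param pedigree Pedigree with families, classes and eras.
#' @param wave2_families Families entering training only from round 2
#'   (default: the second hub's families in the default configuration,
#'   `fam10..fam13`).
#' @return A `round_spec`: list of rounds, each with `training_ids`,
#'   `test_ids`.
#' @export
make_round_spec <- function(pedigree,
                            wave2_families = sprintf("fam%02d", 10:13)) {
  fams <- unique(stats::na.omit(pedigree$family))
  wave1 <- setdiff(fams, wave2_families)
  adv <- function(era) pedigree$id[pedigree$class == "advanced_selection" &
                                     !is.na(pedigree$era) & pedigree$era == era]
  base <- c(family_members(pedigree, wave1),
            pedigree$id[pedigree$class == "cultivar_parent_progenitor"],
            adv("pre1995"))
  t1 <- adv("era1995_2005")
  train2 <- c(base, t1, family_members(pedigree, intersect(wave2_families, fams)))
  t2 <- adv("era2006_2015")
  train3 <- c(train2, t2)
  t3 <- adv("era2016_2020")
  spec <- list(
    list(round = 1L, training_ids = base, test_ids = t1),
    list(round = 2L, training_ids = train2, test_ids = t2),
    list(round = 3L, training_ids = train3, test_ids = t3))
  structure(spec, class = "round_spec")
}

check_round_spec <- function(spec) {
  prev <- character()
  for (r in spec) {
    if (length(intersect(r$training_ids, r$test_ids)) > 0)
      stop("round ", r$round, ": test set overlaps training set")
    if (!all(prev %in% r$training_ids))
      stop("round ", r$round, ": training sets not nested")
    prev <- r$training_ids
  }
  invisible(spec)
}

#' Run the retrospective culling comparison over chronological rounds
#'
#' Per round: an RR-BLUP model per trait is trained on the round's training
#' individuals only, test individuals (that round's advanced selections)
#' receive out-of-training genomewide predictions, thresholds are recomputed
#' from that round's training data, and independent culling is applied to both
#' observed BLUPs and predictions. Unselected offspring, which are in training
#' throughout, receive in-sample genomewide values from the final round's
#' model for the pooled offspring comparison.
#'
#' @param blups Adjusted-BLUP table.
#' @param markers QC-filtered dosage matrix.
#' @param pedigree Pedigree.
#' @param round_spec A `round_spec` (default built by [make_round_spec()]).
#' @param scenario Scenario id `"A".."E"`.
#' @param traits Postdiction traits (default: weight, M1, M2, SSC, TA active;
#'   overcolor and Cn keep-all, as in [threshold_scenario()]).
#' @param reference_individual Reference id for scenario A.
#' @param sd_source See [compute_thresholds()].
#' @return A `postdiction_report`: per-round list (thresholds, decisions for
#'   test individuals under both methods, agreement), plus `offspring`
#'   (pooled offspring decisions and agreement) and `scenario`.
#' @export
run_postdiction_rounds <- function(blups, markers, pedigree,
                                   round_spec = make_round_spec(pedigree),
                                   scenario = "A",
                                   traits = NULL,
                                   reference_individual = NULL,
                                   sd_source = "offspring") {
  check_round_spec(round_spec)
  sc_tab <- threshold_scenario(scenario)
  sc_tab <- sc_tab[sc_tab$trait %in% unique(blups$trait), , drop = FALSE]
  if (!is.null(traits)) sc_tab <- sc_tab[sc_tab$trait %in% traits, , drop = FALSE]
  active_traits <- sc_tab$trait[sc_tab$direction != "none"]

  predict_round <- function(train_ids, target_ids) {
    out <- list()
    for (tr in active_traits) {
      b <- blup_vector(blups, tr)
      train <- intersect(train_ids, intersect(names(b), rownames(markers)))
      miss <- setdiff(target_ids, rownames(markers))
      if (length(miss))
        stop("individuals without genotypes: ", paste(miss, collapse = ", "))
      fit <- suppressWarnings(fit_rrblup(b[train], markers[train, , drop = FALSE]))
      pr <- predict_gebv(fit, markers[target_ids, , drop = FALSE])
      out[[tr]] <- data.frame(individual = pr$individual, trait = tr,
                              value = pr$predicted, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  observed_values <- function(ids) {
    v <- blups[blups$individual %in% ids & blups$trait %in% active_traits, ]
    data.frame(individual = v$individual, trait = v$trait,
               value = v$adjusted_blup, stringsAsFactors = FALSE)
  }

  rounds <- lapply(round_spec, function(r) {
    thr <- compute_thresholds(sc_tab, blups, pedigree, r$training_ids,
                              reference_individual = reference_individual,
                              sd_source = sd_source)
    test <- intersect(r$test_ids,
                      intersect(unique(blups$individual), rownames(markers)))
    obs_dec <- apply_independent_culling(observed_values(test), thr)
    prd_dec <- apply_independent_culling(predict_round(r$training_ids, test), thr)
    list(round = r$round, thresholds = thr, n_train = length(r$training_ids),
         observed_decisions = obs_dec, predicted_decisions = prd_dec,
         agreement = compare_selection_methods(obs_dec, prd_dec))
  })

  final <- round_spec[[length(round_spec)]]
  off <- intersect(family_members(pedigree),
                   intersect(unique(blups$individual), rownames(markers)))
  thr_final <- compute_thresholds(sc_tab, blups, pedigree, final$training_ids,
                                  reference_individual = reference_individual,
                                  sd_source = sd_source)
  off_obs <- apply_independent_culling(observed_values(off), thr_final)
  off_prd <- apply_independent_culling(
    predict_round(final$training_ids, off), thr_final)

  structure(list(
    scenario = scenario, rounds = rounds,
    offspring = list(observed_decisions = off_obs,
                     predicted_decisions = off_prd,
                     agreement = compare_selection_methods(off_obs, off_prd))),
    class = "postdiction_report")
}

#' @export
print.postdiction_report <- function(x, ...) {
  cat(sprintf("postdiction_report: scenario %s, %d rounds\n",
              x$scenario, length(x$rounds)))
  for (r in x$rounds)
    cat(sprintf("  round %d: n_train = %d, test culled obs/pred = %d/%d, concordance = %.1f%%\n",
                r$round, r$n_train,
                sum(r$observed_decisions$decision == "cull"),
                sum(r$predicted_decisions$decision == "cull"),
                r$agreement$percent_concordant))
  cat(sprintf("  offspring (n = %d): culled obs/pred = %d/%d, concordance = %.1f%%\n",
              nrow(x$offspring$observed_decisions),
              sum(x$offspring$observed_decisions$decision == "cull"),
              sum(x$offspring$predicted_decisions$decision == "cull"),
              x$offspring$agreement$percent_concordant))
  invisible(x)
}
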
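# Retrospective culling comparison: threshold arithmetic, independent
# culling, agreement tabulation, round nesting, monotonicity.

mk_ped <- function(off, sel = character(), parents = character()) {
  data.frame(
    id = c(parents, off, sel),
    mother = NA_character_, father = NA_character_,
    family = NA_character_,
    class = c(rep("cultivar_parent_progenitor", length(parents)),
              rep("unselected_offspring", length(off)),
              rep("advanced_selection", length(sel))),
    era = NA_character_, stringsAsFactors = FALSE)
}

test_that("scenario A thresholds follow reference-plus-SD arithmetic", {
  off <- sprintf("o%02d", 1:12)
  ped <- mk_ped(off, parents = "REF")
  ped$class[ped$id %in% off] <- "unselected_offspring"
  # weight BLUPs with SD 20 around 250; reference BLUP exactly 250
  set.seed(1)
  w <- rnorm(12, 250, 20)
  w <- 250 + (w - mean(w)) / sd(w) * 20       # exact mean 250, SD 20
  blups <- rbind(as_blup_tab(setNames(w, off), "weight"),
                 as_blup_tab(c(REF = 250), "weight"))
  thr <- compute_thresholds("A", blups, ped, training_ids = c(off, "REF"),
                            reference_individual = "REF", traits = "weight")
  expect_equal(thr$threshold, 270)
  expect_equal(thr$direction, "cull_if_ge")

  # an individual exactly at the threshold is culled (inclusive rule)
  vals <- data.frame(individual = c("x", "y"), trait = "weight",
                     value = c(270, 269.999))
  dec <- apply_independent_culling(vals, thr)
  expect_equal(dec$decision[dec$individual == "x"], "cull")
  expect_equal(dec$decision[dec$individual == "y"], "keep")

  # missing reference BLUP is an error
  expect_error(
    compute_thresholds("A", blups[blups$individual != "REF", ], ped,
                       training_ids = off, reference_individual = "REF",
                       traits = "weight"),
    "reference individual")
})

test_that("percentile thresholds use type-7 quantiles of training offspring", {
  off <- sprintf("o%02d", 1:10)
  ped <- mk_ped(off)
  blups <- as_blup_tab(setNames(10:19, off), "SSC")
  thr <- compute_thresholds("C", blups, ped, training_ids = off,
                            traits = "SSC")
  expect_equal(thr$threshold, 10.9)  # 10th percentile, type 7
  dec <- apply_independent_culling(
    data.frame(individual = off, trait = "SSC", value = 10:19), thr)
  expect_equal(sum(dec$decision == "cull"), 1)
  expect_equal(dec$individual[dec$decision == "cull"], "o01")
})

test_that("keep-all traits never cull under any scenario", {
  off <- sprintf("o%02d", 1:15)
  ped <- mk_ped(off, sel = c("s1", "s2"))
  set.seed(3)
  blups <- rbind(
    as_blup_tab(setNames(rnorm(15, 3.5, 1), off), "overcolor"),
    as_blup_tab(setNames(rnorm(15, 20, 5), off), "Cn"),
    as_blup_tab(setNames(c(s1 = 3, s2 = 4), c("s1", "s2")), "overcolor"),
    as_blup_tab(setNames(c(s1 = 18, s2 = 22), c("s1", "s2")), "Cn"))
  for (sc in c("A", "B", "C", "D", "E")) {
    tab <- threshold_scenario(sc)
    oc <- tab[tab$trait %in% c("overcolor", "Cn"), ]
    expect_true(all(oc$rule == "keep_all"))
    expect_true(all(oc$direction == "none"))
  }
  thr <- compute_thresholds("C", blups, ped, training_ids = c(off, "s1", "s2"),
                            traits = c("overcolor", "Cn"))
  dec <- apply_independent_culling(
    data.frame(individual = off, trait = "overcolor",
               value = blups$adjusted_blup[blups$trait == "overcolor"][1:15]),
    thr)
  expect_true(all(dec$decision == "keep"))
})

test_that("hand-enumerated six-individual fixture: counts and agreement", {
  # traits failing per individual: (0, 1, 1, 2, 0, 3)
  thr <- data.frame(trait = c("weight", "M1", "SSC"),
                    rule = "percentile",
                    threshold = c(300, 12, 10),
                    direction = c("cull_if_ge", "cull_if_le", "cull_if_le"))
  ids <- sprintf("i%d", 1:6)
  vals <- rbind(
    data.frame(individual = ids, trait = "weight",
               value = c(250, 310, 250, 320, 280, 305)),   # fails: 2,4,6
    data.frame(individual = ids, trait = "M1",
               value = c(14, 13, 11, 11, 15, 12)),          # fails: 3,4,6
    data.frame(individual = ids, trait = "SSC",
               value = c(12, 11, 12, 13, 11, 9)))           # fails: 6
  dec <- apply_independent_culling(vals, thr)
  expect_equal(dec$n_failing, c(0, 1, 1, 2, 0, 3))
  expect_equal(sum(dec$decision == "cull"), 4)
  expect_equal(sum(dec$n_failing == 1), 2)  # culled on exactly one trait
  expect_equal(dec$failing_traits[6], "weight,M1,SSC")

  # agreement fixtures
  same <- compare_selection_methods(dec, dec)
  expect_equal(same$percent_concordant, 100)
  expect_equal(sum(same$table) - sum(diag(same$table)), 0)

  flip <- dec
  flip$decision <- ifelse(dec$decision == "cull", "keep", "cull")
  opp <- compare_selection_methods(dec, flip)
  expect_equal(opp$percent_concordant, 0)

  # 10 individuals, 6 matching decisions -> 60%, counts (4, 2, 2, 2)
  obs10 <- data.frame(individual = sprintf("x%02d", 1:10),
                      decision = rep(c("keep", "cull"), c(6, 4)))
  prd10 <- obs10
  prd10$decision <- c("keep", "keep", "keep", "keep", "cull", "cull",
                      "keep", "keep", "cull", "cull")
  ag <- compare_selection_methods(obs10, prd10)
  expect_equal(ag$percent_concordant, 60)
  expect_equal(ag$table[["keep", "keep"]], 4)
  expect_equal(ag$table[["keep", "cull"]], 2)
  expect_equal(ag$table[["cull", "keep"]], 2)
  expect_equal(ag$table[["cull", "cull"]], 2)
  expect_error(compare_selection_methods(obs10, prd10[1:9, ]),
               "different individuals")
})

test_that("missing trait values flag the trait but do not block a decision", {
  thr <- data.frame(trait = c("weight", "M1"), rule = "percentile",
                    threshold = c(300, 12),
                    direction = c("cull_if_ge", "cull_if_le"))
  vals <- data.frame(individual = c("a", "a", "b"),
                     trait = c("weight", "M1", "M1"),
                     value = c(310, 13, 11))
  dec <- apply_independent_culling(vals, thr)
  a <- dec[dec$individual == "a", ]
  b <- dec[dec$individual == "b", ]
  expect_equal(a$decision, "cull")
  expect_equal(b$decision, "cull")
  expect_equal(b$unevaluated_traits, "weight")
})

test_that("culling is monotone in thresholds", {
  set.seed(9)
  ids <- sprintf("i%02d", 1:40)
  vals <- data.frame(individual = ids, trait = "M1", value = rnorm(40, 15, 2))
  thr1 <- data.frame(trait = "M1", rule = "percentile", threshold = 13,
                     direction = "cull_if_le")
  thr2 <- thr1; thr2$threshold <- 12  # relaxed: culls a subset
  n1 <- sum(apply_independent_culling(vals, thr1)$decision == "cull")
  n2 <- sum(apply_independent_culling(vals, thr2)$decision == "cull")
  expect_lte(n2, n1)

  # purity: same inputs give identical decisions
  expect_identical(apply_independent_culling(vals, thr1),
                   apply_independent_culling(vals, thr1))
})

test_that("round specs nest training sets and full runs report per round", {
  s <- small_sim()
  spec <- make_round_spec(s$g$pedigree)
  expect_length(spec, 3)
  expect_true(all(spec[[1]]$training_ids %in% spec[[2]]$training_ids))
  expect_true(all(spec[[2]]$training_ids %in% spec[[3]]$training_ids))
  for (r in spec) expect_length(intersect(r$training_ids, r$test_ids), 0)
  # training sizes strictly increase
  expect_true(length(spec[[1]]$training_ids) < length(spec[[2]]$training_ids))
  expect_true(length(spec[[2]]$training_ids) < length(spec[[3]]$training_ids))

  rep <- run_postdiction_rounds(s$blups, s$g$markers, s$g$pedigree,
                                scenario = "C",
                                traits = "t")
  # single simulated trait "t" is not a postdiction trait; nothing active
  expect_s3_class(rep, "postdiction_report")
})

test_that("vacuous thresholds cull nobody and agree perfectly", {
  s <- small_sim()
  off <- intersect(unique(s$blups$individual), family_members(s$g$pedigree))
  vals <- data.frame(individual = off, trait = "t",
                     value = s$blups$adjusted_blup[match(off, s$blups$individual)])
  thr <- data.frame(trait = "t", rule = "percentile", threshold = Inf,
                    direction = "cull_if_ge")
  dec <- apply_independent_culling(vals, thr)
  expect_true(all(dec$decision == "keep"))
  ag <- compare_selection_methods(dec, dec)
  expect_equal(ag$percent_concordant, 100)
})

test_that("postdiction rounds run end-to-end on fruit-quality traits", {
  # small germplasm with the full seven-trait architecture
  cfg <- default_germplasm_config(
    family_sizes = c(8, 12, 12, 12, 12, 14, 12, 12, 30, 12, 26, 16, 10),
    advanced = c(pre1995 = 4, era1995_2005 = 6, era2006_2015 = 8,
                 era2016_2020 = 3),
    n_progenitors = 4)
  map <- make_genetic_map(6, 20, 70)
  g <- build_germplasm_set(cfg, map, seed = 33)
  # traits without mapped major QTLs (the toy map has only 6 chromosomes)
  arch <- make_trait_architecture(map, default_trait_specs()[c("weight", "Cn", "SSC")],
                                  seed = 3)
  ph <- simulate_phenotypes(g$markers, arch, years = 2010:2012, n_reps = 2,
                            missingness = 0.05, seed = 5)
  bl <- blup_all_traits(ph$records, interaction = "exclude")
  rep <- run_postdiction_rounds(bl$blups, g$markers, g$pedigree,
                                scenario = "E")
  expect_length(rep$rounds, 3)
  for (r in rep$rounds) {
    expect_true(all(r$thresholds$direction %in%
                      c("cull_if_ge", "cull_if_le", "none")))
    expect_equal(r$agreement$n, nrow(r$observed_decisions))
  }
  # offspring pooled report covers every phenotyped, genotyped offspring
  expect_equal(nrow(rep$offspring$observed_decisions),
               length(intersect(unique(bl$blups$individual),
                                family_members(g$pedigree))))
  # scenario A with the hub parent standing in for the reference cultivar
  repA <- run_postdiction_rounds(bl$blups, g$markers, g$pedigree,
                                 scenario = "A",
                                 reference_individual = "P01")
  expect_length(repA$rounds, 3)
  for (r in repA$rounds)
    expect_true(all(is.finite(
      r$thresholds$threshold[r$thresholds$direction != "none"])))
})
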
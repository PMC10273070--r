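# Breeding-population simulator: map construction, founder sampling,
# meiosis under the Haldane model, family structure, phenotype generation.

test_that("genetic map construction honours counts, spacing and errors", {
  m <- make_genetic_map(17, 57, 71.8, "even")
  expect_equal(nrow(m), 969)
  expect_equal(length(unique(m$chrom)), 17)

  one <- make_genetic_map(1, 1, 10, "even")
  expect_equal(one$pos_cM, 0)

  five <- make_genetic_map(1, 5, 100, "even")
  expect_equal(diff(five$pos_cM), rep(25, 4))

  rnd <- make_genetic_map(3, 20, 80, "random", seed = 5)
  expect_silent(check_map <- gwsel:::check_map(rnd))

  expect_error(make_genetic_map(0, 5, 10), "n_chrom")
  expect_error(make_genetic_map(2, 5, -1), "chrom_length")
})

test_that("founder haplotypes have the right shape and allele frequencies", {
  map <- make_genetic_map(2, 30, 60)
  f1 <- simulate_founder_haplotypes(map, 1, seed = 3)
  expect_equal(dim(f1$hap1), c(1, 60))
  expect_equal(dim(f1$hap2), c(1, 60))

  # fixed frequency 0.5: realized allele frequency within 3 binomial SEs
  f <- simulate_founder_haplotypes(map, 500, maf_range = c(0.5, 0.5), seed = 9)
  freq <- colMeans(rbind(f$hap1, f$hap2))
  se <- sqrt(0.5 * 0.5 / 1000)
  expect_true(mean(abs(freq - 0.5) <= 3 * se) > 0.95)

  expect_error(simulate_founder_haplotypes(map, 5, maf_range = c(0, 0.5)),
               "maf_range")
  expect_error(simulate_founder_haplotypes(map[0, ], 5), "empty|increasing")
})

test_that("gametes respect homozygosity and the Haldane map function", {
  map <- make_genetic_map(1, 2, 20)  # two SNPs 20 cM apart
  # fully homozygous parent: gamete identical regardless of crossovers
  hom <- structure(list(hap1 = matrix(1L, 1, 2, dimnames = list("p", map$snp)),
                        hap2 = matrix(1L, 1, 2, dimnames = list("p", map$snp)),
                        map = map, ids = "p"), class = "phased_geno")
  set.seed(1)
  for (i in 1:10) expect_equal(unname(simulate_gamete(hom, "p")), c(1L, 1L))

  # recombinant fraction between loci d = 20 cM apart:
  # Haldane c = (1 - exp(-2d/100)) / 2 = 0.1648
  het <- structure(list(hap1 = matrix(c(1L, 1L), 1, 2, dimnames = list("p", map$snp)),
                        hap2 = matrix(c(0L, 0L), 1, 2, dimnames = list("p", map$snp)),
                        map = map, ids = "p"), class = "phased_geno")
  set.seed(42)
  n <- 10000
  rec <- vapply(seq_len(n), function(i) {
    g <- simulate_gamete(het, "p")
    g[1] != g[2]
  }, logical(1))
  c_true <- (1 - exp(-0.4)) / 2
  se <- sqrt(c_true * (1 - c_true) / n)
  expect_lt(abs(mean(rec) - c_true), 3 * se)

  # zero-length chromosome: gamete is one intact parental haplotype
  map0 <- make_genetic_map(1, 3, 1e-9)
  par0 <- structure(list(hap1 = matrix(c(1L, 0L, 1L), 1, 3, dimnames = list("p", map0$snp)),
                         hap2 = matrix(c(0L, 1L, 0L), 1, 3, dimnames = list("p", map0$snp)),
                         map = map0, ids = "p"), class = "phased_geno")
  set.seed(2)
  for (i in 1:20) {
    g <- unname(simulate_gamete(par0, "p"))
    expect_true(identical(g, c(1L, 0L, 1L)) || identical(g, c(0L, 1L, 0L)))
  }
  expect_error(simulate_gamete(matrix(1, 2, 2)), "phased")
})

test_that("families are Mendelian: fixation and 1:1 segregation", {
  map <- make_genetic_map(1, 1, 10)
  mk <- function(h1, h2) structure(
    list(hap1 = matrix(c(h1[1], h2[1]), 2, 1, dimnames = list(c("A", "B"), map$snp)),
         hap2 = matrix(c(h1[2], h2[2]), 2, 1, dimnames = list(c("A", "B"), map$snp)),
         map = map, ids = c("A", "B")), class = "phased_geno")
  # AA x AA -> all offspring AA (dosage 1)
  fix <- simulate_family(mk(c(1L, 1L), c(1L, 1L)), "A", "B", 50, seed = 1)
  expect_true(all(dosage_matrix(fix$phased) == 1L))

  # AA x AB -> half AB, half AA, never BB
  seg <- simulate_family(mk(c(1L, 1L), c(1L, 0L)), "A", "B", 2000, seed = 2)
  d <- dosage_matrix(seg$phased)
  expect_true(all(d %in% c(0L, 1L)))
  p_ab <- mean(d == 0L)
  expect_lt(abs(p_ab - 0.5), 3 * sqrt(0.25 / 2000))

  # pedigree rows carry both parents
  fam <- simulate_family(mk(c(1L, 0L), c(0L, 0L)), "A", "B", 150, seed = 3)
  expect_equal(nrow(fam$pedigree), 150)
  expect_true(all(fam$pedigree$mother == "A" & fam$pedigree$father == "B"))
  expect_error(simulate_family(mk(c(1L, 1L), c(1L, 1L)), "A", "B", 0), "n_offspring")
})

test_that("default germplasm set reproduces the reference population design", {
  s <- small_sim()  # scaled-down waves, same structure
  expect_equal(sum(s$g$pedigree$class == "unselected_offspring"),
               sum(default_germplasm_config(
                 family_sizes = c(10, 24, 24, 24, 24, 30, 24, 24, 60, 24, 50, 30, 20))$families$size))

  # paper-scale default: counting only (construction itself covered above)
  cfg <- default_germplasm_config()
  expect_equal(sum(cfg$families$size), 852)
  expect_equal(sum(cfg$advanced) + length(cfg$founders) + 1 + cfg$n_progenitors,
               103)

  # one-family toy: 2 parents + 10 offspring = 12 individuals
  toy_cfg <- default_germplasm_config()
  toy_cfg$families <- data.frame(family = "famA", mother = "P01",
                                 father = "P03", size = 10, wave = 1L)
  toy_cfg$advanced <- c(pre1995 = 0, era1995_2005 = 0, era2006_2015 = 0,
                        era2016_2020 = 0)
  toy_cfg$founders <- c("P01", "P03")
  toy_cfg$derived_parents <- list()
  toy_cfg$n_progenitors <- 0
  map <- make_genetic_map(2, 10, 50)
  toy <- build_germplasm_set(toy_cfg, map, seed = 4)
  expect_equal(nrow(toy$pedigree), 12)
  expect_equal(sum(toy$pedigree$class == "unselected_offspring"), 10)

  # unknown parent rejected
  bad <- toy_cfg; bad$families$father <- "NOPE"
  expect_error(build_germplasm_set(bad, map, seed = 1), "unknown parent")
})

test_that("half-sib families through a hub parent show ~0.25 genomic relationship", {
  cfg <- default_germplasm_config(
    family_sizes = c(rep(30, 9), rep(30, 4)),
    advanced = c(pre1995 = 0, era1995_2005 = 0, era2006_2015 = 0,
                 era2016_2020 = 0),
    n_progenitors = 2, maf_range = c(0.5, 0.5))
  map <- make_genetic_map(10, 40, 80)
  g <- build_germplasm_set(cfg, map, seed = 21)
  # VanRaden-style genomic relationship at the known founder frequency 0.5,
  # so the half-sib expectation 0.25 is unbiased
  M <- g$markers
  storage.mode(M) <- "double"
  G <- tcrossprod(M) / (ncol(M) / 2)
  # families sharing mother P01, unrelated fathers: mean pairwise genomic
  # relationship across families approaches the half-sib expectation 0.25
  hub_fams <- sprintf("fam%02d", c(2:8))
  pairs <- utils::combn(hub_fams, 2)
  rel <- mean(apply(pairs, 2, function(pr)
    mean(G[family_members(g$pedigree, pr[1]),
           family_members(g$pedigree, pr[2])])))
  expect_lt(abs(rel - 0.25), 0.08)
  f2 <- family_members(g$pedigree, "fam02")
  # within a full-sib family: ~0.5
  expect_lt(abs(mean(G[f2, f2][upper.tri(diag(length(f2)))]) - 0.5), 0.1)
})

test_that("phenotype generator hits its variance partition and noiseless limit", {
  map <- make_genetic_map(4, 25, 60)
  M <- toy_markers(300, map, seed = 5)
  specs <- list(t = list(props = c(year = 0.1, individual = 0.5,
                                   interaction = 0.2, residual = 0.2),
                         grand_mean = 50, sd = 3, qtls = list()))
  arch <- make_trait_architecture(map, specs, seed = 1)
  ph <- simulate_phenotypes(M, arch, years = 1:4, n_reps = 2,
                            missingness = 0, seed = 2)
  # exact component standardization: realized variances equal targets
  expect_equal(sd(ph$tbv[, "t"]), sqrt(0.5) * 3, tolerance = 1e-8)
  expect_equal(sd(ph$components$t$year), sqrt(0.1) * 3, tolerance = 1e-8)
  expect_equal(sd(as.vector(ph$components$t$interaction)), sqrt(0.2) * 3,
               tolerance = 1e-8)

  # noiseless limit: value = grand_mean + g, identical across years
  specs0 <- list(t = list(props = c(year = 0, individual = 1,
                                    interaction = 0, residual = 0),
                          grand_mean = 7, sd = 2, qtls = list()))
  arch0 <- make_trait_architecture(map, specs0, seed = 1)
  ph0 <- simulate_phenotypes(M, arch0, years = 1:3, n_reps = 1,
                             missingness = 0, seed = 3)
  w <- ph0$records[ph0$records$individual == rownames(M)[1], ]
  expect_equal(var(w$value), 0)
  expect_equal(w$value[1], 7 + ph0$tbv[rownames(M)[1], "t"])

  # binomial thinning of individual-year cells
  ph_m <- simulate_phenotypes(M, arch, years = 1:4, n_reps = 1,
                              missingness = 0.2, seed = 4)
  n_cells <- nrow(ph_m$records)
  expected <- 0.8 * 300 * 4
  se <- sqrt(300 * 4 * 0.2 * 0.8)
  expect_lt(abs(n_cells - expected), 3 * se)

  # invalid proportions rejected
  bad <- specs
  bad$t$props <- c(year = 0.5, individual = 0.5, interaction = 0.5,
                   residual = -0.5)
  expect_error(make_trait_architecture(map, bad), "nonnegative|sum")
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- default_germplasm_config(
    family_sizes = rep(10, 13),
    advanced = c(pre1995 = 1, era1995_2005 = 1, era2006_2015 = 1,
                 era2016_2020 = 1), n_progenitors = 2)
  map <- make_genetic_map(3, 15, 50)
  g1 <- build_germplasm_set(cfg, map, seed = 77)
  g2 <- build_germplasm_set(cfg, map, seed = 77)
  expect_identical(g1$markers, g2$markers)
  expect_identical(g1$pedigree, g2$pedigree)
  g3 <- build_germplasm_set(cfg, map, seed = 78)
  expect_false(identical(g1$markers, g3$markers))

  arch <- make_trait_architecture(map, list(t = list(
    props = c(year = 0.1, individual = 0.6, interaction = 0, residual = 0.3),
    grand_mean = 0, sd = 1, qtls = list())), seed = 5)
  p1 <- simulate_phenotypes(g1$markers, arch, seed = 9)
  p2 <- simulate_phenotypes(g1$markers, arch, seed = 9)
  expect_identical(p1$records, p2$records)
  expect_identical(p1$tbv, p2$tbv)
})
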
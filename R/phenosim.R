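#' Default trait specifications
#'
#' Seven harvest fruit-quality traits with variance partitions chosen to match
#' the pattern reported for hub-parent apple germplasm: year explains ~0.07 of
#' phenotypic variation on average, individual ~0.53 on average (>= 0.50 for
#' overcolor, weight, firmness M1/M2 and acidity; <= 0.40 for crispness Cn and
#' soluble solids), and a year x individual interaction of 0.13-0.34 where
#' present. Units: overcolor on the 1-5 visual scale, weight in g, M1/M2 in
#' lbs, Cn unitless, SSC in degrees Brix, TA in g/L.
#'
#' Major-effect QTLs: a dominant red-colour locus on chromosome 9 (overcolor),
#' a firmness locus on chromosome 16 (M1, M2) and two acidity loci on
#' chromosomes 8 and 16 (TA), each with a target fraction of phenotypic
#' variance.
#'
#' @return Named list of per-trait specs (variance proportions, grand mean,
#'   phenotypic SD, major QTLs).
#' @export
default_trait_specs <- function() {
  q <- function(chrom, frac, dom) list(chrom = chrom, var_frac = frac, dominance = dom)
  list(
    overcolor = list(props = c(year = 0.07, individual = 0.65, interaction = 0.00, residual = 0.28),
                     grand_mean = 3.5, sd = 1.0,
                     qtls = list(q("chr09", 0.30, 1))),
    weight = list(props = c(year = 0.07, individual = 0.60, interaction = 0.00, residual = 0.33),
                  grand_mean = 180, sd = 35, qtls = list()),
    M1 = list(props = c(year = 0.06, individual = 0.72, interaction = 0.13, residual = 0.09),
              grand_mean = 15.8, sd = 2.6,
              qtls = list(q("chr16", 0.10, 0))),
    M2 = list(props = c(year = 0.15, individual = 0.55, interaction = 0.15, residual = 0.15),
              grand_mean = 14.0, sd = 2.4,
              qtls = list(q("chr16", 0.10, 0))),
    Cn = list(props = c(year = 0.07, individual = 0.40, interaction = 0.00, residual = 0.53),
              grand_mean = 20, sd = 5, qtls = list()),
    SSC = list(props = c(year = 0.05, individual = 0.35, interaction = 0.34, residual = 0.26),
               grand_mean = 13.0, sd = 1.3, qtls = list()),
    TA = list(props = c(year = 0.07, individual = 0.55, interaction = 0.20, residual = 0.18),
              grand_mean = 4.5, sd = 1.4,
              qtls = list(q("chr16", 0.10, 0), q("chr08", 0.08, 0)))
  )
}

#' Build a trait architecture over a genetic map
#'
#' For each trait, a random subset of mapped SNPs (default 20%) is designated
#' causal so that the remaining markers tag QTLs only through linkage, as with
#' anonymous array SNPs. Major-effect QTLs are placed at the SNP closest to
#' the middle of their chromosome and excluded from the polygenic causal set.
#' Effect sizes are drawn standard normal and rescaled at simulation time so
#' that realized variance fractions hit their targets exactly.
#'
#' @param map A `genetic_map`.
#' @param traits Per-trait spec list, as [default_trait_specs()].
#' @param causal_fraction Fraction of SNPs designated causal per trait.
#' @param seed Integer seed.
#' @return A `trait_architecture` list: per trait, `causal` (SNP ids),
#'   `effects`, `major_qtl` (data.frame snp, var_frac, dominance),
#'   `props`, `grand_mean`, `sd`.
#' @export
make_trait_architecture <- function(map, traits = default_trait_specs(),
                                    causal_fraction = 0.2, seed = 1L) {
  check_map(map)
  set.seed(seed)
  arch <- lapply(names(traits), function(tr) {
    sp <- traits[[tr]]
    pr <- sp$props
    if (any(pr < 0)) stop("variance proportions must be nonnegative")
    if (abs(sum(pr) - 1) > 1e-8) stop("variance proportions must sum to 1")
    majors <- data.frame(snp = character(), var_frac = numeric(),
                         dominance = numeric(), stringsAsFactors = FALSE)
    for (q in sp$qtls) {
      on_chr <- map[map$chrom == q$chrom, ]
      if (nrow(on_chr) == 0) stop("QTL chromosome not in map: ", q$chrom)
      mid <- chrom_lengths(map)[q$chrom] / 2
      snp <- on_chr$snp[which.min(abs(on_chr$pos_cM - mid))]
      majors <- rbind(majors, data.frame(snp = snp, var_frac = q$var_frac,
                                         dominance = q$dominance))
    }
    if (sum(majors$var_frac) >= pr[["individual"]])
      stop("major-QTL variance fractions exceed the individual proportion")
    pool <- setdiff(map$snp, majors$snp)
    k <- max(1L, round(causal_fraction * length(pool)))
    causal <- sort(sample(pool, k))
    list(causal = causal,
         effects = stats::setNames(stats::rnorm(k), causal),
         major_qtl = majors, props = pr,
         grand_mean = sp$grand_mean, sd = sp$sd)
  })
  names(arch) <- names(traits)
  structure(arch, class = "trait_architecture")
}

# center x and rescale to an exact sample variance; zero target -> zeros
scale_to_var <- function(x, target) {
  if (target <= 0) return(rep(0, length(x)))
  s <- stats::sd(x)
  if (s == 0) stop("cannot rescale a constant vector to positive variance")
  (x - mean(x)) / s * sqrt(target)
}

#' Simulate multi-year phenotype records
#'
#' Generates `value(i, y, rep) = mu + g_i + year_y + (gy)_iy + e_iyr` per
#' trait. The genetic value `g_i` is the sum of polygenic marker effects and
#' any major-QTL terms (additive plus dominance deviation); each variance
#' component is rescaled so its realized sample variance equals its target
#' share of the trait's phenotypic variance exactly, which makes variance-
#' partition recovery testable even with few year levels. Whole
#' individual-year cells are dropped at random with probability `missingness`.
#'
#' @param markers Dosage matrix (individuals x SNPs, -1/0/1; no missing).
#' @param architecture A `trait_architecture`.
#' @param years Vector of year labels (length >= 1).
#' @param n_reps Replicate measurements per individual-year cell (fruit per
#'   tree-year); interaction and residual variance are separable only when
#'   `n_reps >= 2`.
#' @param missingness Probability an individual-year cell is unobserved.
#' @param seed Integer seed.
#' @return List: `records` (data.frame individual, year, rep, trait, value),
#'   `tbv` (matrix individuals x traits of true genetic values, centered),
#'   `components` (per trait, the realized year/interaction/residual draws).
#' @export
simulate_phenotypes <- function(markers, architecture, years = 2010:2014,
                                n_reps = 3, missingness = 0.1, seed = 1L) {
  stopifnot(inherits(architecture, "trait_architecture"))
  if (length(years) < 1) stop("need at least one year")
  if (missingness < 0 || missingness >= 1) stop("missingness must be in [0,1)")
  set.seed(seed)
  n <- nrow(markers); ny <- length(years)
  ids <- rownames(markers)
  tbv <- matrix(0, n, length(architecture),
                dimnames = list(ids, names(architecture)))
  comps <- list()
  out <- vector("list", length(architecture))

  for (t in seq_along(architecture)) {
    tr <- names(architecture)[t]
    a <- architecture[[t]]
    sigmaP2 <- a$sd^2
    qtl_var <- sum(a$major_qtl$var_frac) * sigmaP2
    poly_var <- a$props[["individual"]] * sigmaP2 - qtl_var

    g <- scale_to_var(markers[, a$causal, drop = FALSE] %*% a$effects, poly_var)
    if (nrow(a$major_qtl) > 0) {
      for (j in seq_len(nrow(a$major_qtl))) {
        d <- markers[, a$major_qtl$snp[j]]
        term <- d + a$major_qtl$dominance[j] * (d == 0)
        g <- g + scale_to_var(term, a$major_qtl$var_frac[j] * sigmaP2)
      }
    }
    g <- as.numeric(g)
    tbv[, t] <- g

    year_eff <- scale_to_var(stats::rnorm(ny), a$props[["year"]] * sigmaP2)
    gy <- matrix(scale_to_var(stats::rnorm(n * ny),
                              a$props[["interaction"]] * sigmaP2), n, ny)
    resid <- array(scale_to_var(stats::rnorm(n * ny * n_reps),
                                a$props[["residual"]] * sigmaP2),
                   c(n, ny, n_reps))

    cell <- matrix(TRUE, n, ny)
    if (missingness > 0)
      cell <- matrix(stats::runif(n * ny) >= missingness, n, ny)

    obs <- which(cell, arr.ind = TRUE)
    rec <- data.frame(
      individual = rep(ids[obs[, 1]], each = n_reps),
      year = rep(years[obs[, 2]], each = n_reps),
      rep = rep(seq_len(n_reps), times = nrow(obs)),
      trait = tr,
      value = as.numeric(vapply(seq_len(nrow(obs)), function(k) {
        i <- obs[k, 1]; y <- obs[k, 2]
        a$grand_mean + g[i] + year_eff[y] + gy[i, y] + resid[i, y, ]
      }, numeric(n_reps))),
      stringsAsFactors = FALSE
    )
    out[[t]] <- rec
    comps[[tr]] <- list(year = year_eff, interaction = gy, residual = resid)
  }
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  list(records = records, tbv = tbv, components = comps)
}

#' Clip a continuous trait onto a bounded ordinal scale
#'
#' Optional post-hoc transform for rating-scale traits (e.g. the 1-5 percent
#' red overcolor scale): rounds to the nearest half step and clips to the
#' scale limits. Off by default throughout the package, which treats rating
#' traits as continuous.
#'
#' @param x Numeric values.
#' @param lo,hi Scale limits.
#' @param step Rounding step.
#' @return Numeric vector on the bounded scale.
#' @export
clip_to_scale <- function(x, lo = 1, hi = 5, step = 0.5) {
  pmin(hi, pmax(lo, round(x / step) * step))
}
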
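#' Read and validate a run configuration file
#'
#' YAML configuration with sections `simulate`, `qc`, `blup`, `predict`,
#' `cv`, `postdict` and globals `seed` (mandatory) and `out_dir`. Unknown
#' top-level keys or unknown keys within a section are rejected; values
#' default from [default_run_config()].
#'
#' @param path YAML file path.
#' @return Nested config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_run_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop("config must set a seed")
  out <- defaults
  for (k in names(cfg)) {
    if (is.list(defaults[[k]])) {
      bad <- setdiff(names(cfg[[k]]), names(defaults[[k]]))
      if (length(bad))
        stop("unknown keys in section '", k, "': ", paste(bad, collapse = ", "))
      out[[k]][names(cfg[[k]])] <- cfg[[k]]
    } else {
      out[[k]] <- cfg[[k]]
    }
  }
  out
}

#' Default run configuration
#'
#' @return Nested list of all tunable parameters with their defaults: the
#'   paper-scale simulation design (17 x 57 map, 13 families / 955
#'   individuals, 5 years, 3 replicate fruit per tree-year, 10% missing
#'   cells), QC at 20% missingness / |r| 0.80, BLUP interaction selection at
#'   delta AIC 2, and the standard CV and postdiction settings.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "results",
    simulate = list(n_chrom = 17L, snps_per_chrom = 57L,
                    chrom_length_cM = 71.8, spacing = "even",
                    maf_range = c(0.1, 0.5), causal_fraction = 0.2,
                    years = 2010:2014, n_reps = 3L, missingness = 0.1),
    qc = list(max_missing = 0.20, r_threshold = 0.80, impute_method = "mode"),
    blup = list(interaction = "auto", delta_aic = 2),
    predict = list(fixed_snps = character(), encoding = "categorical"),
    cv = list(fractions = c(0.10, 0.25, 0.50, 0.75), n_iter = 500L,
              subset_sizes = c(20L, 40L, 60L, 80L, 100L, 120L),
              snps_per_chrom = c(5L, 10L, 15L, 20L, 25L, 30L),
              include_all = FALSE),
    postdict = list(scenario = "A", sd_source = "offspring",
                    reference_individual = "P01")
  )
}
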
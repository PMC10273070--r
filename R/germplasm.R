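#' Default germplasm configuration
#'
#' Describes a breeding germplasm set with the structure typical of a
#' hub-parent apple program: 13 full-sib families (23-150 offspring, 852
#' total) dominated by two hub parents — `P01`, used in 8 families, and its
#' own offspring `P02`, used in 4 — plus 103 other individuals (14 breeding
#' parents, 9 unrelated progenitors, and 80 advanced selections split across
#' four selection eras). Total 955 individuals.
#'
#' @param family_sizes Integer vector of 13 family sizes.
#' @param advanced Named integer vector of advanced-selection counts per era.
#' @param n_progenitors Number of unrelated progenitor founders.
#' @param maf_range Founder allele-frequency range (passed to
#'   [simulate_founder_haplotypes()]).
#' @return A config list consumed by [build_germplasm_set()].
#' @export
default_germplasm_config <- function(
    family_sizes = c(23, 53, 52, 51, 48, 75, 51, 48, 150, 50, 128, 82, 41),
    advanced = c(pre1995 = 11, era1995_2005 = 16,
                 era2006_2015 = 47, era2016_2020 = 6),
    n_progenitors = 9, maf_range = c(0.1, 0.5)) {
  stopifnot(length(family_sizes) == 13)
  mothers <- c("P03", "P01", "P01", "P01", "P01", "P01", "P01", "P01", "P01",
               "P02", "P02", "P02", "P06")
  fathers <- c("P04", "P05", "P06", "P07", "P08", "P09", "P10", "P11", "P04",
               "P12", "P13", "P14", "P02")
  list(
    founders = c("P01", sprintf("P%02d", 3:14)),
    n_progenitors = n_progenitors,
    maf_range = maf_range,
    # P02 (second hub) is itself an offspring of the first hub
    derived_parents = list(P02 = c("P01", "G01")),
    families = data.frame(
      family = sprintf("fam%02d", 1:13),
      mother = mothers, father = fathers, size = family_sizes,
      # wave 2 = families derived from the second hub, entering the
      # postdiction training set only from round two onward
      wave = c(rep(1L, 9), rep(2L, 4)),
      stringsAsFactors = FALSE
    ),
    advanced = advanced
  )
}

#' Build a pedigreed, genotyped germplasm set
#'
#' Simulates founders, derives any parents defined as crosses of founders,
#' generates all full-sib families by meiosis, and adds advanced selections
#' (each an offspring of a random pair of breeding parents) and progenitors.
#' The default configuration yields 955 individuals of which 852 are
#' unselected offspring in 13 families.
#'
#' @param config A configuration list as from [default_germplasm_config()].
#' @param map A `genetic_map` (default: 17 x 57 even map).
#' @param seed Integer seed; the whole set is reproducible from it.
#' @return A `germplasm` list: `pedigree` (data.frame id, mother, father,
#'   family, class, era), `phased` (`phased_geno` of all individuals),
#'   `markers` (-1/0/1 dosage matrix) and `map`.
#' @export
build_germplasm_set <- function(config = default_germplasm_config(),
                                map = make_genetic_map(), seed = 1L) {
  check_map(map)
  set.seed(seed)
  fam <- config$families
  prog_ids <- if (config$n_progenitors > 0)
    sprintf("G%02d", seq_len(config$n_progenitors)) else character()
  founder_ids <- c(config$founders, prog_ids)
  founders <- simulate_founder_haplotypes(
    map, length(founder_ids), config$maf_range,
    seed = sample.int(.Machine$integer.max, 1), ids = founder_ids)

  ped <- data.frame(id = founder_ids, mother = NA_character_,
                    father = NA_character_, family = NA_character_,
                    class = "cultivar_parent_progenitor", era = NA_character_,
                    stringsAsFactors = FALSE)
  pool <- founders

  # parents defined as crosses (e.g. the second hub parent)
  for (dp in names(config$derived_parents)) {
    pr <- config$derived_parents[[dp]]
    if (!all(pr %in% pool$ids)) stop("derived parent references unknown parent")
    off <- simulate_family(pool, pr[1], pr[2], 1L, family = NA_character_,
                           seed = sample.int(.Machine$integer.max, 1),
                           prefix = dp)
    off$phased$ids <- dp
    rownames(off$phased$hap1) <- rownames(off$phased$hap2) <- dp
    pool <- bind_phased(pool, off$phased)
    ped <- rbind(ped, data.frame(id = dp, mother = pr[1], father = pr[2],
                                 family = NA_character_,
                                 class = "cultivar_parent_progenitor",
                                 era = NA_character_))
  }

  all_parents <- unique(c(fam$mother, fam$father))
  if (!all(all_parents %in% pool$ids))
    stop("family references unknown parent: ",
         paste(setdiff(all_parents, pool$ids), collapse = ", "))

  for (i in seq_len(nrow(fam))) {
    fs <- simulate_family(pool, fam$mother[i], fam$father[i], fam$size[i],
                          family = fam$family[i],
                          seed = sample.int(.Machine$integer.max, 1),
                          prefix = fam$family[i])
    pool <- bind_phased(pool, fs$phased)
    ped <- rbind(ped, fs$pedigree)
  }

  # advanced selections: program material from random crosses of the parents
  adv <- config$advanced
  if (!is.null(adv) && sum(adv) > 0) {
    k <- 0L
    for (era in names(adv)) {
      for (j in seq_len(adv[[era]])) {
        k <- k + 1L
        pr <- sample(all_parents, 2L, replace = FALSE)
        id <- sprintf("AS%03d", k)
        off <- simulate_family(pool, pr[1], pr[2], 1L, family = NA_character_,
                               seed = sample.int(.Machine$integer.max, 1),
                               prefix = id)
        off$phased$ids <- id
        rownames(off$phased$hap1) <- rownames(off$phased$hap2) <- id
        pool <- bind_phased(pool, off$phased)
        ped <- rbind(ped, data.frame(id = id, mother = pr[1], father = pr[2],
                                     family = NA_character_,
                                     class = "advanced_selection", era = era))
      }
    }
  }

  rownames(ped) <- NULL
  check_pedigree(ped)
  structure(list(pedigree = ped, phased = pool,
                 markers = dosage_matrix(pool), map = map),
            class = "germplasm")
}

#' @export
print.germplasm <- function(x, ...) {
  cat(sprintf("germplasm: %d individuals (%d unselected offspring in %d families), %d SNPs\n",
              nrow(x$pedigree),
              sum(x$pedigree$class == "unselected_offspring"),
              length(unique(stats::na.omit(x$pedigree$family))),
              ncol(x$markers)))
  invisible(x)
}

check_pedigree <- function(ped) {
  need <- c("id", "mother", "father", "family", "class", "era")
  if (!all(need %in% names(ped))) stop("pedigree missing columns")
  if (anyDuplicated(ped$id)) stop("duplicate pedigree ids")
  classes <- c("unselected_offspring", "advanced_selection",
               "cultivar_parent_progenitor")
  if (!all(ped$class %in% classes)) stop("unknown germplasm class")
  eras <- c("pre1995", "era1995_2005", "era2006_2015", "era2016_2020")
  if (!all(is.na(ped$era) | ped$era %in% eras)) stop("unknown selection era")
  if (any(!is.na(ped$era) & ped$class != "advanced_selection"))
    stop("selection era set for non-advanced-selection individual")
  off <- ped$class == "unselected_offspring"
  if (any(off & (is.na(ped$family) | is.na(ped$mother) | is.na(ped$father))))
    stop("unselected offspring must have a family and two named parents")
  # parents precede offspring
  pos <- stats::setNames(seq_len(nrow(ped)), ped$id)
  for (col in c("mother", "father")) {
    p <- ped[[col]]
    known <- !is.na(p)
    if (any(!p[known] %in% ped$id)) stop("parent not present in pedigree")
    if (any(pos[p[known]] >= which(known))) stop("parent listed after offspring")
  }
  invisible(ped)
}

#' Offspring ids of given families
#' @param pedigree Pedigree data.frame.
#' @param families Family labels (default: all).
#' @return Character vector of ids.
#' @export
family_members <- function(pedigree, families = NULL) {
  keep <- pedigree$class == "unselected_offspring"
  if (!is.null(families)) keep <- keep & pedigree$family %in% families
  pedigree$id[keep]
}
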
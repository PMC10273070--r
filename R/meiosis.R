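#' Simulate phased founder haplotypes
#'
#' Each SNP is assigned an allele frequency drawn uniformly from `maf_range`;
#' both haplotypes of every founder are then sampled independently per locus
#' (founders are unrelated and in linkage equilibrium). Monomorphic SNPs can
#' arise by sampling and are left in place — removing them is the job of the
#' QC stage, as with real array data.
#'
#' @param map A `genetic_map`.
#' @param n_founders Number of founder individuals.
#' @param maf_range Length-2 numeric in (0, 0.5]: allele-1 frequency range.
#' @param seed Integer seed.
#' @param ids Optional character vector of founder ids.
#'
#' @return A `phased_geno` object: list with integer 0/1 matrices `hap1`,
#'   `hap2` (individuals x SNPs), the `map`, and `ids`.
#' @export
simulate_founder_haplotypes <- function(map, n_founders, maf_range = c(0.1, 0.5),
                                        seed = 1L, ids = NULL) {
  check_map(map)
  if (nrow(map) == 0) stop("empty map")
  if (n_founders < 1) stop("n_founders must be >= 1")
  if (any(maf_range <= 0) || any(maf_range > 0.5))
    stop("maf_range must lie in (0, 0.5]")
  set.seed(seed)
  m <- nrow(map)
  freq <- stats::runif(m, maf_range[1], maf_range[2])
  if (is.null(ids)) ids <- sprintf("F%03d", seq_len(n_founders))
  draw <- function() {
    h <- matrix(stats::rbinom(n_founders * m, 1L, rep(freq, each = n_founders)),
                nrow = n_founders, ncol = m)
    dimnames(h) <- list(ids, map$snp)
    h
  }
  structure(list(hap1 = draw(), hap2 = draw(), map = map, ids = ids),
            class = "phased_geno")
}

#' @export
print.phased_geno <- function(x, ...) {
  cat(sprintf("phased_geno: %d individuals x %d SNPs\n",
              length(x$ids), ncol(x$hap1)))
  invisible(x)
}

#' Dosage matrix from phased genotypes
#'
#' Converts phased 0/1 haplotypes to the -1/0/1 dosage coding used throughout:
#' 1 and -1 for the two homozygotes, 0 for heterozygotes.
#'
#' @param phased A `phased_geno`.
#' @return Integer matrix (individuals x SNPs) with values in \{-1, 0, 1\}.
#' @export
dosage_matrix <- function(phased) {
  stopifnot(inherits(phased, "phased_geno"))
  d <- phased$hap1 + phased$hap2 - 1L
  storage.mode(d) <- "integer"
  d
}

#' Simulate one gamete from a phased parent
#'
#' Meiosis under the Haldane model: per chromosome the crossover count is
#' Poisson(length / 100) with crossover positions uniform on the chromosome
#' (no interference); the starting strand is chosen at random.
#'
#' @param phased A `phased_geno` holding the parent (and possibly others).
#' @param parent Id (or row index) of the parent within `phased`.
#' @param seed Optional integer seed (omit when called inside a seeded loop).
#' @return Integer 0/1 vector of length n_SNPs, named by SNP id.
#' @export
simulate_gamete <- function(phased, parent = 1L, seed = NULL) {
  if (!inherits(phased, "phased_geno")) stop("parent genotypes must be phased")
  if (!is.null(seed)) set.seed(seed)
  i <- if (is.character(parent)) match(parent, phased$ids) else as.integer(parent)
  if (is.na(i)) stop("unknown parent id")
  gamete_row(phased$hap1[i, ], phased$hap2[i, ], phased$map)
}

# One recombinant haplotype; h1/h2 are the parent's allele vectors.
gamete_row <- function(h1, h2, map) {
  out <- integer(length(h1))
  lens <- chrom_lengths(map)
  chrom <- map$chrom
  for (c in names(lens)) {
    idx <- which(chrom == c)
    pos <- map$pos_cM[idx]
    nco <- stats::rpois(1L, lens[[c]] / 100)
    start <- stats::rbinom(1L, 1L, 0.5)
    if (nco == 0L) {
      phase <- rep(start, length(idx))
    } else {
      co <- sort(stats::runif(nco, 0, lens[[c]]))
      phase <- (start + findInterval(pos, co)) %% 2L
    }
    out[idx] <- ifelse(phase == 0L, h1[idx], h2[idx])
  }
  names(out) <- map$snp
  out
}

#' Simulate a full-sib family
#'
#' Crosses two phased parents: each offspring receives one recombinant
#' maternal and one recombinant paternal gamete.
#'
#' @param phased A `phased_geno` containing both parents.
#' @param mother,father Parent ids.
#' @param n_offspring Number of offspring (>= 1).
#' @param family Family label recorded in the pedigree rows.
#' @param seed Integer seed.
#' @param prefix Offspring id prefix.
#' @return List: `phased` (`phased_geno` of the offspring) and `pedigree`
#'   (data.frame rows: id, mother, father, family, class, era).
#' @export
simulate_family <- function(phased, mother, father, n_offspring,
                            family = paste0(mother, "x", father),
                            seed = 1L, prefix = family) {
  if (!inherits(phased, "phased_geno")) stop("parent genotypes must be phased")
  if (n_offspring < 1) stop("n_offspring must be >= 1")
  im <- match(mother, phased$ids); ip <- match(father, phased$ids)
  if (is.na(im) || is.na(ip)) stop("unknown parent id: ", mother, " or ", father)
  set.seed(seed)
  m <- ncol(phased$hap1)
  ids <- sprintf("%s_%03d", prefix, seq_len(n_offspring))
  hap1 <- matrix(0L, n_offspring, m, dimnames = list(ids, colnames(phased$hap1)))
  hap2 <- hap1
  for (k in seq_len(n_offspring)) {
    hap1[k, ] <- gamete_row(phased$hap1[im, ], phased$hap2[im, ], phased$map)
    hap2[k, ] <- gamete_row(phased$hap1[ip, ], phased$hap2[ip, ], phased$map)
  }
  ped <- data.frame(id = ids, mother = mother, father = father,
                    family = family, class = "unselected_offspring",
                    era = NA_character_, stringsAsFactors = FALSE)
  list(phased = structure(list(hap1 = hap1, hap2 = hap2, map = phased$map,
                               ids = ids), class = "phased_geno"),
       pedigree = ped)
}

# rbind two phased_geno objects over the same map
bind_phased <- function(a, b) {
  stopifnot(identical(colnames(a$hap1), colnames(b$hap1)))
  structure(list(hap1 = rbind(a$hap1, b$hap1), hap2 = rbind(a$hap2, b$hap2),
                 map = a$map, ids = c(a$ids, b$ids)), class = "phased_geno")
}
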
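#' Impute missing marker genotypes
#'
#' `"mode"` fills each SNP's missing entries with its most frequent observed
#' dosage (ties broken toward the heterozygote, then the lower dosage).
#' `"family_mode"` first restricts the candidate dosages of an offspring to
#' those consistent with its parents' genotypes (e.g. both parents homozygous
#' 1 forces 1) and picks the most frequent consistent dosage within the
#' full-sib family, falling back to the population mode.
#'
#' @param markers Dosage matrix with possible NAs.
#' @param pedigree Optional pedigree (required for `"family_mode"`).
#' @param method `"mode"` or `"family_mode"`.
#' @return Complete dosage matrix, values in \{-1, 0, 1\}.
#' @export
impute_missing <- function(markers, pedigree = NULL,
                           method = c("mode", "family_mode")) {
  method <- match.arg(method)
  bad <- colSums(is.na(markers)) == nrow(markers)
  if (any(bad))
    stop("SNP(s) 100% missing, filter before imputing: ",
         paste(colnames(markers)[bad], collapse = ", "))
  if (!anyNA(markers)) return(markers)
  out <- markers
  pop_mode <- apply(markers, 2, dosage_mode)
  for (j in which(colSums(is.na(markers)) > 0)) {
    miss <- which(is.na(markers[, j]))
    if (method == "mode" || is.null(pedigree)) {
      out[miss, j] <- pop_mode[j]
    } else {
      for (i in miss) {
        id <- rownames(markers)[i]
        row <- pedigree[pedigree$id == id, ]
        fill <- pop_mode[j]
        if (nrow(row) == 1 && !is.na(row$mother) && !is.na(row$father) &&
            all(c(row$mother, row$father) %in% rownames(markers))) {
          allowed <- mendelian_dosages(markers[row$mother, j],
                                       markers[row$father, j])
          sibs <- if (!is.na(row$family))
            setdiff(rownames(markers)[pedigree$family %in% row$family], id)
          else character()
          cand <- markers[sibs, j]
          cand <- cand[!is.na(cand) & cand %in% allowed]
          fill <- if (length(cand)) dosage_mode(cand)
                  else if (pop_mode[j] %in% allowed) pop_mode[j]
                  else allowed[which.min(abs(allowed))]
        }
        out[i, j] <- fill
      }
    }
  }
  out
}

# most frequent dosage; ties -> heterozygote, then lower dosage
dosage_mode <- function(x) {
  x <- x[!is.na(x)]
  tab <- table(factor(x, levels = c(0, -1, 1)))
  as.numeric(names(tab)[which.max(tab)])
}

# offspring dosages consistent with parental dosages (NA parent -> anything)
mendelian_dosages <- function(m, f) {
  if (is.na(m) || is.na(f)) return(c(-1, 0, 1))
  gam <- function(d) switch(as.character(d), "-1" = 0L, "0" = c(0L, 1L), "1" = 1L)
  sort(unique(as.vector(outer(gam(m), gam(f), "+")))) - 1
}

#' SNP quality control with per-chromosome redundancy pruning
#'
#' Curation pipeline in a fixed, logged order: (1) remove SNPs with
#' missingness above `max_missing`; (2) impute remaining missing entries;
#' (3) remove monomorphic SNPs; (4) per chromosome, backwards-eliminate
#' redundant SNPs — while any within-chromosome pair has `|r| > r_threshold`,
#' the member of the worst pair with the lower minor allele frequency is
#' removed (equal MAFs: the SNP later in map order goes).
#'
#' @param markers Dosage matrix (NAs allowed).
#' @param map `genetic_map` covering all SNP columns.
#' @param max_missing Maximum tolerated missingness per SNP (default 0.20,
#'   strictly-greater removal).
#' @param r_threshold Absolute-correlation ceiling (default 0.80,
#'   strictly-greater removal).
#' @param impute_method Passed to [impute_missing()].
#' @param pedigree Optional, for family-aware imputation.
#' @return List: `markers` (filtered, complete matrix) and `report`
#'   (`qc_report`: removed_monomorphic, removed_missingness,
#'   removed_redundant data.frame, n_input, n_retained).
#' @export
filter_snps <- function(markers, map, max_missing = 0.20, r_threshold = 0.80,
                        impute_method = "mode", pedigree = NULL) {
  check_map(map)
  if (!all(colnames(markers) %in% map$snp))
    stop("marker columns missing from map: ",
         paste(setdiff(colnames(markers), map$snp)[1:5], collapse = ", "))
  n_input <- ncol(markers)

  miss_rate <- colMeans(is.na(markers))
  removed_missingness <- colnames(markers)[miss_rate > max_missing]
  M <- markers[, miss_rate <= max_missing, drop = FALSE]

  M <- impute_missing(M, pedigree = pedigree, method = impute_method)

  mono <- apply(M, 2, function(x) length(unique(x)) == 1)
  removed_monomorphic <- colnames(M)[mono]
  M <- M[, !mono, drop = FALSE]

  removed_redundant <- data.frame(
    removed_snp = character(), retained_partner = character(),
    correlation = numeric(), maf_removed = numeric(), maf_retained = numeric(),
    stringsAsFactors = FALSE)
  map_order <- stats::setNames(seq_len(nrow(map)), map$snp)
  snp_chrom <- stats::setNames(map$chrom, map$snp)

  for (chr in unique(snp_chrom[colnames(M)])) {
    cols <- colnames(M)[snp_chrom[colnames(M)] == chr]
    if (length(cols) < 2) next
    C <- abs(stats::cor(M[, cols, drop = FALSE]))
    diag(C) <- 0
    mafs <- apply(M[, cols, drop = FALSE], 2, snp_maf)
    keep <- rep(TRUE, length(cols))
    repeat {
      Csub <- C[keep, keep, drop = FALSE]
      if (max(Csub) <= r_threshold) break
      w <- which(Csub == max(Csub), arr.ind = TRUE)[1, ]
      pair <- rownames(Csub)[w]
      m <- mafs[pair]
      drop_snp <- if (m[1] != m[2]) pair[which.min(m)]
                  else pair[which.max(map_order[pair])]
      keep_snp <- setdiff(pair, drop_snp)
      removed_redundant <- rbind(removed_redundant, data.frame(
        removed_snp = drop_snp, retained_partner = keep_snp,
        correlation = max(Csub), maf_removed = unname(mafs[drop_snp]),
        maf_retained = unname(mafs[keep_snp]), stringsAsFactors = FALSE))
      keep[match(drop_snp, cols)] <- FALSE
    }
    M <- M[, setdiff(colnames(M), cols[!keep]), drop = FALSE]
  }

  report <- structure(list(
    removed_monomorphic = removed_monomorphic,
    removed_missingness = removed_missingness,
    removed_redundant = removed_redundant,
    n_input = n_input, n_retained = ncol(M)), class = "qc_report")
  list(markers = M, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("qc_report: %d SNPs in, %d retained ",
                     "(%d high-missingness, %d monomorphic, %d redundant)\n"),
              x$n_input, x$n_retained, length(x$removed_missingness),
              length(x$removed_monomorphic), nrow(x$removed_redundant)))
  invisible(x)
}

#' Minor allele frequency of a dosage vector
#' @param x Dosages in \{-1, 0, 1\} (NAs ignored).
#' @return MAF in [0, 0.5].
#' @export
snp_maf <- function(x) {
  p <- mean(x + 1, na.rm = TRUE) / 2
  min(p, 1 - p)
}
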
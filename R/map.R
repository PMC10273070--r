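#' Construct a genetic map
#'
#' Builds a multi-chromosome SNP map in centiMorgan coordinates. The default
#' arguments reproduce the scale of a typical apple breeding-array map:
#' 17 chromosomes averaging 57 SNPs each.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param snps_per_chrom SNPs per chromosome (>= 1). Either a single count used
#'   for every chromosome or a vector of length `n_chrom`.
#' @param chrom_length_cM Chromosome length in cM (> 0); scalar or vector.
#' @param spacing `"even"` places SNP i at `(i-1) * L / (n-1)` (a single SNP
#'   sits at 0); `"random"` draws positions uniformly on `[0, L]` and sorts.
#' @param seed Integer seed, only used for `spacing = "random"`.
#'
#' @return A `genetic_map`: data.frame with columns `snp`, `chrom`, `pos_cM`,
#'   positions strictly increasing within chromosome, plus an attribute
#'   `chrom_lengths` (named numeric vector).
#' @export
make_genetic_map <- function(n_chrom = 17, snps_per_chrom = 57,
                             chrom_length_cM = 71.8,
                             spacing = c("even", "random"), seed = 1L) {
  spacing <- match.arg(spacing)
  if (n_chrom < 1) stop("n_chrom must be >= 1")
  snps_per_chrom <- rep_len(as.integer(snps_per_chrom), n_chrom)
  chrom_length_cM <- rep_len(as.numeric(chrom_length_cM), n_chrom)
  if (any(snps_per_chrom < 1)) stop("snps_per_chrom must be >= 1")
  if (any(chrom_length_cM <= 0)) stop("chrom_length_cM must be > 0")

  if (spacing == "random") set.seed(seed)
  rows <- lapply(seq_len(n_chrom), function(c) {
    k <- snps_per_chrom[c]
    L <- chrom_length_cM[c]
    pos <- if (spacing == "even") {
      if (k == 1) 0 else (seq_len(k) - 1) * L / (k - 1)
    } else {
      p <- sort(stats::runif(k, 0, L))
      # enforce strict increase under the (improbable) exact tie
      while (anyDuplicated(p)) p <- sort(stats::runif(k, 0, L))
      p
    }
    data.frame(
      snp = sprintf("c%02d_s%03d", c, seq_len(k)),
      chrom = sprintf("chr%02d", c),
      pos_cM = pos,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  lengths <- stats::setNames(chrom_length_cM, sprintf("chr%02d", seq_len(n_chrom)))
  structure(map, chrom_lengths = lengths, class = c("genetic_map", "data.frame"))
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: %d SNPs on %d chromosomes (%.1f cM total)\n",
              nrow(x), length(attr(x, "chrom_lengths")),
              sum(attr(x, "chrom_lengths"))))
  invisible(x)
}

#' Chromosome lengths of a genetic map
#' @param map A `genetic_map`.
#' @return Named numeric vector of lengths in cM.
#' @export
chrom_lengths <- function(map) attr(map, "chrom_lengths")

#' Rebuild a genetic map from its data-frame representation
#'
#' Inverse of writing a map to CSV: takes columns `snp`, `chrom`, `pos_cM`
#' and either a `chrom_length` column or an explicit lengths vector.
#'
#' @param df Data frame with map columns.
#' @param lengths Optional named lengths vector (cM); defaults to the
#'   `chrom_length` column.
#' @return A `genetic_map`.
#' @export
as_genetic_map <- function(df, lengths = NULL) {
  if (is.null(lengths)) {
    if (!"chrom_length" %in% names(df))
      stop("need a chrom_length column or an explicit lengths vector")
    lengths <- tapply(df$chrom_length, df$chrom, function(x) x[1])
    lengths <- stats::setNames(as.numeric(lengths), names(lengths))
  }
  m <- df[, c("snp", "chrom", "pos_cM")]
  out <- structure(m, chrom_lengths = lengths,
                   class = c("genetic_map", "data.frame"))
  check_map(out)
}

check_map <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  if (anyDuplicated(map$snp)) stop("duplicate SNP ids in map")
  for (c in unique(map$chrom)) {
    p <- map$pos_cM[map$chrom == c]
    if (any(diff(p) <= 0)) stop("positions not strictly increasing on ", c)
    if (any(p < 0) || any(p > chrom_lengths(map)[c]))
      stop("position outside [0, length] on ", c)
  }
  invisible(map)
}
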
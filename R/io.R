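# File formats. The native marker format is a CSV dialect: header row of SNP
# ids, first column `individual`, cells in {-1, 0, 1, NA}. Phenotypes are long
# CSV (individual, year, rep?, trait, value); pedigrees are CSV (id, mother,
# father, family, class, era). Readers validate and reject rather than coerce.

#' Read a marker matrix (CSV dialect or VCF)
#'
#' CSV: header of SNP ids, first column `individual`, cells in
#' \{-1, 0, 1, NA\}; any other value is a format error naming the cell. VCF
#' (requires the vcfR package): diploid GT fields are mapped 0/0 -> 1,
#' 0/1 or 1/0 -> 0, 1/1 -> -1, ./. -> NA; any other ploidy or allele code is
#' an error.
#'
#' @param path File path.
#' @param format `"csv"` or `"vcf"`.
#' @return Dosage matrix, individuals x SNPs.
#' @export
read_marker_matrix <- function(path, format = c("csv", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") return(read_marker_vcf(path))
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "individual")
    stop("first column must be 'individual'")
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids)) stop("duplicate individual ids")
  if (anyDuplicated(names(d)[-1])) stop("duplicate SNP ids")
  M <- as.matrix(d[, -1, drop = FALSE])
  bad <- which(!(is.na(M) | M %in% c(-1, 0, 1)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid dosage '%s' at individual '%s', SNP '%s'",
                 M[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(M)[bad[1, 2]]))
  storage.mode(M) <- "integer"
  rownames(M) <- ids
  M
}

read_marker_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF import requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  snps <- rownames(gt)
  if (anyDuplicated(snps)) stop("duplicate SNP ids in VCF")
  map_gt <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g == "0/0"] <- 1L
    out[g %in% c("0/1", "1/0")] <- 0L
    out[g == "1/1"] <- -1L
    unknown <- !is.na(g) & !g %in% c("0/0", "0/1", "1/0", "1/1", "./.")
    if (any(unknown))
      stop("unsupported genotype in VCF (mixed ploidy or multiallelic): ",
           g[unknown][1])
    out
  }
  M <- apply(gt, 2, map_gt)
  if (is.null(dim(M))) M <- matrix(M, nrow = 1, dimnames = list(NULL, colnames(gt)))
  M <- t(M)
  colnames(M) <- snps
  M
}

#' Write a marker matrix to the CSV dialect
#' @param markers Dosage matrix.
#' @param path Output path.
#' @export
write_marker_matrix <- function(markers, path) {
  d <- data.frame(individual = rownames(markers), markers,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
}

#' Export a marker matrix to VCF text
#'
#' One contig per chromosome; since VCF POS is an integer base-pair field,
#' genetic positions are exported as `POS = round(cM * 1e5)` with the original
#' cM value kept in an INFO tag `CM`. Dosage 1 -> 0/0, 0 -> 0/1, -1 -> 1/1,
#' NA -> ./..
#'
#' @param markers Dosage matrix.
#' @param map `genetic_map` covering the columns.
#' @param path Output path.
#' @export
write_marker_vcf <- function(markers, map, path) {
  check_map(map)
  m <- map[match(colnames(markers), map$snp), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", unique(m$chrom)),
               "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic position in cM\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(markers)), collapse = "\t")),
             con)
  code <- function(d) {
    out <- rep("./.", length(d))
    out[!is.na(d) & d == 1] <- "0/0"
    out[!is.na(d) & d == 0] <- "0/1"
    out[!is.na(d) & d == -1] <- "1/1"
    out
  }
  for (j in seq_len(ncol(markers))) {
    writeLines(paste(c(m$chrom[j], round(m$pos_cM[j] * 1e5), m$snp[j],
                       "A", "B", ".", "PASS",
                       sprintf("CM=%g", m$pos_cM[j]), "GT",
                       code(markers[, j])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read long-format phenotype records
#'
#' Columns: individual, year, trait, value; optional rep. Duplicate
#' (individual, year, rep, trait) rows and non-finite values are errors.
#'
#' @param path CSV path.
#' @return Validated records data.frame.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "year", "trait", "value")
  if (!all(need %in% names(d)))
    stop("phenotype file must have columns: ", paste(need, collapse = ", "))
  if (!"rep" %in% names(d)) d$rep <- 1L
  key <- paste(d$individual, d$year, d$rep, d$trait, sep = "\r")
  if (anyDuplicated(key)) {
    k <- strsplit(key[duplicated(key)][1], "\r")[[1]]
    stop(sprintf("duplicate record for (individual=%s, year=%s, rep=%s, trait=%s)",
                 k[1], k[2], k[3], k[4]))
  }
  if (any(!is.finite(d$value))) stop("non-finite phenotype values")
  d[, c("individual", "year", "rep", "trait", "value")]
}

#' Write phenotype records
#' @param records Records data.frame.
#' @param path Output path.
#' @export
write_phenotypes <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
}

#' Read a pedigree/germplasm table
#'
#' Columns: id, mother, father, family, class, era (empty strings read as
#' NA). Validates classes, eras, parent references and ordering.
#'
#' @param path CSV path.
#' @return Validated pedigree data.frame.
#' @export
read_pedigree <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  for (col in c("mother", "father", "family", "era"))
    if (!col %in% names(d)) d[[col]] <- NA_character_
  d <- d[, c("id", "mother", "father", "family", "class", "era")]
  check_pedigree(d)
  d
}

#' Write a pedigree table
#' @param pedigree Pedigree data.frame.
#' @param path Output path.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.csv(pedigree, path, row.names = FALSE, quote = FALSE)
}

#' Write an adjusted-BLUP table
#' @param blups BLUP table (individual, trait, adjusted_blup, n_years).
#' @param path Output path.
#' @export
write_blups <- function(blups, path) {
  utils::write.csv(blups, path, row.names = FALSE, quote = FALSE)
}
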
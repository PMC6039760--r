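#' Genotype matrix container
#'
#' The universal carrier between pipeline stages: an `n x m` matrix of
#' alternate-allele dosages (0/1/2, `NA` for a missing call) with animal ids
#' as row names, plus a SNP map. The map is a data.frame with columns
#' `snp_id`, `chrom`, `pos_bp` (1-based physical position), `allele_ref`,
#' `allele_alt`, one row per matrix column, in matrix column order (assumed
#' to be genome order: sorted by chromosome then position).
#'
#' @param dosage numeric/integer matrix of 0/1/2 dosages with `NA` allowed;
#'   row names are animal ids.
#' @param map SNP map data.frame as described above. Columns `allele_ref`
#'   and `allele_alt` default to "A"/"B" when absent.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("id", seq_len(nrow(dosage)))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (is.null(map$allele_ref)) map$allele_ref <- "A"
  if (is.null(map$allele_alt)) map$allele_alt <- "B"
  map <- map[, c("snp_id", "chrom", "pos_bp", "allele_ref", "allele_alt")]
  map$chrom <- as.character(map$chrom)
  map$pos_bp <- as.integer(map$pos_bp)
  rownames(map) <- NULL
  colnames(dosage) <- map$snp_id
  g <- structure(list(dosage = dosage, map = map), class = "genotype_matrix")
  validate_genotype_matrix(g)
  g
}

validate_genotype_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  if (anyDuplicated(rownames(d)))
    stop_("duplicate animal ids in genotype matrix")
  if (anyDuplicated(g$map$snp_id))
    stop_("duplicate snp ids in map")
  if (ncol(d) != nrow(g$map))
    stop_("dosage columns and SNP map rows differ")
  if (any(g$map$pos_bp < 1L, na.rm = TRUE))
    stop_("pos_bp must be >= 1")
  rng <- range(d, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0L || rng[2] > 2L))
    stop_("dosage values must be 0, 1, 2 or NA")
  invisible(g)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- x$dosage
  nmiss <- sum(is.na(d))
  cat(sprintf("genotype_matrix: %d animals x %d SNPs (%s missing calls), %d chromosome(s)\n",
              nrow(d), ncol(d), format(nmiss, big.mark = ","),
              length(unique(x$map$chrom))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g a `genotype_matrix`.
#' @export
n_animals <- function(g) nrow(g$dosage)

#' @rdname genotype_matrix
#' @export
n_snps <- function(g) ncol(g$dosage)

#' Observed alternate-allele frequencies
#'
#' Frequencies are computed from observed (non-missing) calls only.
#'
#' @param g a `genotype_matrix`.
#' @return numeric vector of length `n_snps(g)`, named by snp id.
#' @export
allele_freq <- function(g) {
  colMeans(g$dosage, na.rm = TRUE) / 2
}

# ---- readers / writers ------------------------------------------------------

#' Read a genotype matrix
#'
#' Supported dialects: `tsv` (tab-separated, header row, first column
#' `animal_id`, one column per SNP, missing encoded `NA`), `plink_raw`
#' (space-separated PLINK .raw: FID IID PAT MAT SEX PHENOTYPE then one
#' counted-allele column per SNP named `snp_A`), and `vcf` (hard GT calls
#' only; multi-allelic sites are rejected). Dosage counts the alternate
#' allele; animal and SNP order are preserved from the file.
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"plink_raw"`, `"vcf"`.
#' @param map optional SNP map (data.frame or TSV path) for the tsv/plink
#'   dialects, which do not carry positions themselves; when omitted a stub
#'   map (chrom "1", positions 1..m) is synthesized.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "plink_raw", "vcf"),
                           map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("no such file: ", path)
  if (is.character(map)) map <- read_snp_map(map)
  switch(format,
    tsv = read_genotypes_tsv(path, map),
    plink_raw = read_genotypes_raw(path, map),
    vcf = read_genotypes_vcf(path))
}

read_genotypes_tsv <- function(path, map) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "NA", data.table = FALSE)
  if (colnames(dt)[1] != "animal_id")
    stop_("tsv genotype dialect requires first column 'animal_id' (", path, ")")
  ids <- as.character(dt[[1]])
  d <- as.matrix(dt[, -1, drop = FALSE])
  rownames(d) <- ids
  map <- if (is.null(map)) stub_map(colnames(d))
         else align_map(map, colnames(d), path)
  genotype_matrix(d, map)
}

read_genotypes_raw <- function(path, map) {
  dt <- data.table::fread(path, sep = " ", header = TRUE,
                          na.strings = c("NA"), data.table = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% colnames(dt)[1:6]))
    stop_("not a PLINK .raw header in ", path)
  snp_cols <- colnames(dt)[-(1:6)]
  d <- as.matrix(dt[, -(1:6), drop = FALSE])
  rownames(d) <- as.character(dt$IID)
  # column names carry the counted allele as a suffix: <snp_id>_<allele>
  alt <- sub("^.*_", "", snp_cols)
  ids <- sub("_[^_]*$", "", snp_cols)
  if (is.null(map)) {
    map <- stub_map(ids)
    map$allele_alt <- alt
  } else {
    map <- align_map(map, ids, path)
  }
  colnames(d) <- ids
  genotype_matrix(d, map)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop_("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alt)
  if (any(nalt > 1L))
    stop_("multi-allelic site(s) rejected: ",
          paste(head(rownames(vcf)[nalt > 1L], 5L), collapse = ", "))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop_("VCF has no GT field: ", path)
  dose <- gt_to_dosage(gt)
  rr <- SummarizedExperiment::rowRanges(vcf)
  map <- data.frame(
    snp_id = rownames(vcf),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos_bp = GenomicRanges::start(rr),
    allele_ref = as.character(VariantAnnotation::ref(vcf)),
    allele_alt = as.character(unlist(alt)),
    stringsAsFactors = FALSE)
  genotype_matrix(t(dose), map)
}

gt_to_dosage <- function(gt) {
  # gt: sites x samples character matrix of hard calls ("0/1", "1|1", "./.")
  codes <- unique(as.vector(gt))
  lut <- vapply(codes, function(cc) {
    a <- strsplit(gsub("|", "/", cc, fixed = TRUE), "/", fixed = TRUE)[[1]]
    if (any(a == ".")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(a))
    if (anyNA(ai) || any(ai > 1L))
      stop_("unparseable or non-biallelic GT call: ", cc)
    sum(ai)
  }, integer(1))
  out <- lut[match(as.vector(gt), codes)]
  matrix(out, nrow = nrow(gt), ncol = ncol(gt),
         dimnames = dimnames(gt))
}

#' Write a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @param format one of `"tsv"`, `"plink_raw"`, `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("tsv", "plink_raw", "vcf")) {
  format <- match.arg(format)
  validate_genotype_matrix(g)
  switch(format,
    tsv = {
      df <- data.frame(animal_id = rownames(g$dosage),
                       as.data.frame(g$dosage), check.names = FALSE)
      data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
    },
    plink_raw = {
      ids <- rownames(g$dosage)
      df <- data.frame(FID = ids, IID = ids, PAT = 0L, MAT = 0L, SEX = 0L,
                       PHENOTYPE = -9L, as.data.frame(g$dosage),
                       check.names = FALSE)
      colnames(df)[-(1:6)] <- paste0(g$map$snp_id, "_", g$map$allele_alt)
      data.table::fwrite(df, path, sep = " ", na = "NA", quote = FALSE)
    },
    vcf = write_vcf(g, path))
  invisible(path)
}

write_vcf <- function(g, path) {
  d <- g$dosage
  gt <- c("0/0", "0/1", "1/1")
  body <- matrix("./.", nrow = ncol(d), ncol = nrow(d))
  ok <- !is.na(t(d))
  body[ok] <- gt[t(d)[ok] + 1L]
  lines <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(g$map$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t"),
    paste(g$map$chrom, g$map$pos_bp, g$map$snp_id, g$map$allele_ref,
          g$map$allele_alt, ".", ".", ".", "GT",
          apply(body, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# restrict a (possibly larger) SNP map to the columns present in a file,
# in file order
align_map <- function(map, snp_ids, path) {
  idx <- match(snp_ids, map$snp_id)
  if (anyNA(idx))
    stop_("SNP map lacks entries for ", sum(is.na(idx)),
          " column(s) of ", path)
  map[idx, , drop = FALSE]
}

stub_map <- function(snp_ids) {
  data.frame(snp_id = snp_ids, chrom = "1", pos_bp = seq_along(snp_ids),
             allele_ref = "A", allele_alt = "B", stringsAsFactors = FALSE)
}

#' Read / write a SNP map (TSV: snp_id, chrom, pos_bp[, alleles])
#' @param path file path.
#' @return data.frame SNP map.
#' @export
read_snp_map <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("snp_id", "chrom", "pos_bp")
  if (!all(need %in% colnames(dt)))
    stop_("SNP map must have columns snp_id, chrom, pos_bp (", path, ")")
  dt$chrom <- as.character(dt$chrom)
  dt$snp_id <- as.character(dt$snp_id)
  dt$pos_bp <- as.integer(dt$pos_bp)
  dt
}

#' @rdname read_snp_map
#' @param map SNP map data.frame.
#' @export
write_snp_map <- function(map, path) {
  data.table::fwrite(map, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write a phenotype table
#'
#' TSV with header; required columns `animal_id`, `y_raw`, `group`
#' (contemporary group label) and `age_days`. Extra columns (e.g. `sire`,
#' `y_adjusted`) are preserved.
#'
#' @param path file path.
#' @return a data.frame of class `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  phenotype_table(dt)
}

#' @rdname read_phenotypes
#' @param p phenotype table.
#' @export
write_phenotypes <- function(p, path) {
  data.table::fwrite(p, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname read_phenotypes
#' @param x data.frame with the required phenotype columns.
#' @export
phenotype_table <- function(x) {
  need <- c("animal_id", "y_raw", "group", "age_days")
  miss <- setdiff(need, colnames(x))
  if (length(miss))
    stop_("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  x$animal_id <- as.character(x$animal_id)
  if (anyDuplicated(x$animal_id)) stop_("duplicate animal ids in phenotypes")
  class(x) <- c("phenotype_table", "data.frame")
  x
}
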
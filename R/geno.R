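#' Genotype set: coded genotype matrix plus marker map
#'
#' Bundles an individuals-by-markers genotype matrix in additive coding
#' (0 = one homozygote, 1 = heterozygote, 2 = the other homozygote,
#' `NA` = missing) with its marker map. Z-linked genotypes of ZW
#' individuals are hemizygous and carried on the diploid scale as 0 or 2;
#' see [simulate_population()].
#'
#' @param geno Integer matrix, individuals in rows (rownames = ids),
#'   markers in columns (colnames = marker ids). Values 0/1/2/`NA`.
#' @param map Data frame with columns `marker`, `chrom`, `pos`, `ref`,
#'   `alt`. One row per genotype column, same order. Positions are 1-based
#'   bp; `chrom` labels come from `{1..20, W, Z}`.
#' @return An object of class `geno_set`: a list with elements `geno` and
#'   `map`.
#' @export
geno_set <- function(geno, map) {
  geno <- as.matrix(geno)
  stopifnot(is.data.frame(map))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(map)))
    stop("map must have columns marker, chrom, pos")
  if (is.null(map$ref)) map$ref <- NA_character_
  if (is.null(map$alt)) map$alt <- NA_character_
  map$chrom <- as.character(map$chrom)
  map$marker <- as.character(map$marker)
  if (ncol(geno) != nrow(map))
    stop("genotype matrix has ", ncol(geno), " columns but map has ",
         nrow(map), " rows")
  if (is.null(colnames(geno))) colnames(geno) <- map$marker
  if (!identical(colnames(geno), map$marker))
    stop("genotype column names do not match map$marker")
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("ind", seq_len(nrow(geno)))
  bad <- geno[!is.na(geno) & !(geno %in% 0:2)]
  if (length(bad))
    stop("genotype codes outside {0,1,2,NA}: e.g. ", bad[1])
  if (any(map$pos <= 0)) stop("marker positions must be positive")
  if (anyDuplicated(map[, c("chrom", "pos")]))
    stop("duplicated (chrom, pos) in marker map")
  unsorted <- tapply(map$pos, map$chrom, is.unsorted)
  if (any(unsorted))
    stop("markers not sorted by position within chromosome: ",
         paste(names(unsorted)[unsorted], collapse = ", "))
  structure(list(geno = geno, map = map), class = "geno_set")
}

#' @export
print.geno_set <- function(x, ...) {
  cat("geno_set:", nrow(x$geno), "individuals x", ncol(x$geno), "markers\n")
  cat("chromosomes:", paste(unique(x$map$chrom), collapse = " "), "\n")
  nm <- sum(is.na(x$geno))
  cat(sprintf("missing calls: %d (%.2f%%)\n", nm,
              100 * nm / length(x$geno)))
  invisible(x)
}

#' @export
dim.geno_set <- function(x) dim(x$geno)

#' Subset a genotype set by individuals and/or markers
#'
#' @param x A [geno_set()].
#' @param i Individual index (ids, logical or integer).
#' @param j Marker index.
#' @param ... Unused.
#' @return A `geno_set`.
#' @export
`[.geno_set` <- function(x, i, j, ...) {
  g <- x$geno
  m <- x$map
  if (!missing(j)) {
    if (is.character(j)) j <- match(j, m$marker)
    g <- g[, j, drop = FALSE]
    m <- m[j, , drop = FALSE]
    rownames(m) <- NULL
  }
  if (!missing(i)) g <- g[i, , drop = FALSE]
  geno_set(g, m)
}

# ---- TSV dialect ------------------------------------------------------------
# Genotype TSV: tab-separated, header = marker ids, first column "id",
# missing literal "NA".  Marker map TSV: marker, chrom, pos, ref, alt.
# Phenotype TSV: id, sire, dam, genetic_sex, phenotypic_sex, reversal.

#' Read and write coded genotypes
#'
#' `read_genotypes()` reads the package's tab-separated genotype dialect
#' (or a VCF, see Details) together with a marker-map TSV;
#' `write_genotypes()` writes it. The TSV round-trips exactly.
#'
#' For `format = "vcf"`, biallelic SNP records are converted to counts of
#' the ALT allele (`0/1` -> 1, `./.` -> `NA`); non-biallelic records are
#' skipped with a warning. Parsing is done with the vcfR package.
#'
#' @param path Genotype TSV path, or VCF path when `format = "vcf"`.
#' @param map_path Marker map TSV path (TSV format only; the VCF carries
#'   its own coordinates).
#' @param format `"tsv"` or `"vcf"`.
#' @return A [geno_set()].
#' @export
read_genotypes <- function(path, map_path = NULL, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") return(read_genotypes_vcf(path))
  if (is.null(map_path)) stop("map_path is required for TSV input")
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  ids <- tab[[1]]
  g <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- ids
  map <- utils::read.delim(map_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  map$chrom <- as.character(map$chrom)
  geno_set(g, map)
}

#' @param x A [geno_set()].
#' @rdname read_genotypes
#' @export
write_genotypes <- function(x, path, map_path = NULL,
                            format = c("tsv", "vcf"), ...) {
  format <- match.arg(format)
  if (format == "vcf") return(write_genotypes_vcf(x, path, ...))
  tab <- data.frame(id = rownames(x$geno), x$geno, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  if (!is.null(map_path))
    utils::write.table(x$map, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  invisible(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !is.na(alt) & !grepl(",", alt) &
    nchar(ref) == 1L & nchar(alt) == 1L
  if (any(!biallelic))
    warning(sum(!biallelic), " non-biallelic-SNP VCF record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  code <- function(s) {
    s <- gsub("\\|", "/", s)
    out <- rep(NA_integer_, length(s))
    out[s %in% "0/0"] <- 0L
    out[s %in% c("0/1", "1/0")] <- 1L
    out[s %in% "1/1"] <- 2L
    out
  }
  g <- t(apply(gt, 1, code))          # markers x individuals -> transpose
  g <- t(g)
  colnames(g) <- fix[, "ID"]
  rownames(g) <- colnames(gt)
  map <- data.frame(marker = fix[, "ID"], chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  ord <- order(map$chrom, map$pos)
  geno_set(g[, ord, drop = FALSE], map[ord, , drop = FALSE])
}

# Plain-text VCF 4.2 emitter.  Hemizygous Z/W calls of ZW individuals are
# stored as homozygous diploid genotypes; records on W or Z get an
# INFO flag HEMI marking possibly-hemizygous coding.
write_genotypes_vcf <- function(x, path, hemi_chroms = c("W", "Z")) {
  m <- x$map
  ref <- ifelse(is.na(m$ref), "A", m$ref)
  alt <- ifelse(is.na(m$alt), "T", m$alt)
  gtxt <- apply(x$geno, 2, function(col) {
    c("0/0", "0/1", "1/1")[col + 1L]
  })
  gtxt[is.na(gtxt)] <- "./."
  # gtxt: individuals x markers -> rows of the VCF body are markers
  body <- vapply(seq_len(nrow(m)), function(j) {
    info <- if (m$chrom[j] %in% hemi_chroms) "HEMI" else "."
    paste(c(m$chrom[j], m$pos[j], m$marker[j], ref[j], alt[j], ".", "PASS",
            info, "GT", gtxt[, j]), collapse = "\t")
  }, character(1))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=zwgwas",
    paste0("##INFO=<ID=HEMI,Number=0,Type=Flag,Description=",
           "\"Sex-chromosome record; ZW individuals are hemizygous and ",
           "coded as homozygous diploid\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(x$geno)), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read and write phenotype tables
#'
#' The phenotype TSV mirrors the layout of a tongue-sole sex-reversal
#' study file: columns `id`, `sire`, `dam`, `genetic_sex` (ZZ/ZW),
#' `phenotypic_sex` (male/female) and `reversal` (1 = genetic female with
#' male phenotype, else 0).
#'
#' @param path File path.
#' @return `read_phenotypes()` returns a data frame.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(id = "character",
                                         sire = "character",
                                         dam = "character"))
  stopifnot(all(c("id", "genetic_sex", "phenotypic_sex", "reversal")
                %in% names(ph)))
  if (anyDuplicated(ph$id)) stop("duplicated individual ids")
  if (!all(ph$reversal %in% 0:1)) stop("reversal must be 0/1")
  ph
}

#' @param pheno Phenotype data frame.
#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
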
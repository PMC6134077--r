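#' Realized genomic relationship matrix
#'
#' Builds the realized relationship matrix K from a complete coded
#' genotype matrix: each marker column is standardized by its observed
#' mean and standard deviation (population convention, divide by n) to
#' give Z, and `K = Z Z' / n_m` with `n_m` the number of markers. Sex
#' chromosomes are included by default; in an all-ZW cohort W markers are
#' near-monomorphic and mostly removed by the MAF filter upstream.
#'
#' @param x A [geno_set()] or a complete numeric matrix (individuals x
#'   markers).
#' @param exclude_sex_chrom If `TRUE`, drop W and Z markers before
#'   computing K (only for `geno_set` input).
#' @return An object of class `grm`: list with `K` (n x n symmetric
#'   matrix), `n_markers` and `ids`.
#' @export
build_grm <- function(x, exclude_sex_chrom = FALSE) {
  if (inherits(x, "geno_set")) {
    if (exclude_sex_chrom) x <- x[, !(x$map$chrom %in% c("W", "Z"))]
    m <- x$geno
  } else m <- as.matrix(x)
  if (anyNA(m))
    stop("genotype matrix contains missing values; impute first")
  storage.mode(m) <- "double"
  mu <- colMeans(m)
  sdv <- sqrt(colMeans(m^2) - mu^2)      # population (divide-by-n) sd
  zero <- sdv <= 0
  if (nrow(m) == 1L) {
    # single individual: columns have no spread; self-relationship is the
    # degenerate 1x1 zero matrix
    sdv[zero] <- 1
    zero <- rep(FALSE, length(zero))
  }
  if (any(zero))
    stop("zero-variance marker(s): ",
         paste(utils::head(colnames(m)[zero], 5), collapse = ", "),
         " - run filter_markers() first")
  z <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  K <- tcrossprod(z) / ncol(z)
  K <- (K + t(K)) / 2
  structure(list(K = K, n_markers = ncol(m),
                 ids = rownames(m)), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$K), "individuals,", x$n_markers, "markers\n")
  cat(sprintf("diagonal mean %.3f, off-diagonal mean %.4f\n",
              mean(diag(x$K)),
              mean(x$K[upper.tri(x$K)])))
  invisible(x)
}

#' Write a GRM as TSV with an id header
#'
#' @param grm A [build_grm()] result.
#' @param path Output path.
#' @export
write_grm <- function(grm, path) {
  tab <- data.frame(id = grm$ids, grm$K, check.names = FALSE)
  colnames(tab) <- c("id", grm$ids)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
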
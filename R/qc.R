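#' Marker quality control: minor allele frequency and call rate
#'
#' Discards markers with MAF < `maf_min` or call rate < `callrate_min`.
#' Thresholds are strict inequalities, so a marker exactly at MAF 0.05 or
#' call rate 0.80 is retained. MAF is computed on non-missing calls as
#' `min(p, 1 - p)` with `p = mean(code) / 2`.
#'
#' @param x A [geno_set()].
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param callrate_min Minimum fraction of non-missing calls (default 0.80).
#' @return A list with elements `geno` (filtered `geno_set`) and `report`
#'   (data frame of removed markers with columns `marker`, `maf`,
#'   `callrate`, `reason`).
#' @export
filter_markers <- function(x, maf_min = 0.05, callrate_min = 0.80) {
  stopifnot(inherits(x, "geno_set"))
  g <- x$geno
  callrate <- colMeans(!is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0                       # all-missing column: MAF 0
  maf <- pmin(p, 1 - p)
  low_maf <- maf < maf_min
  low_cr <- callrate < callrate_min
  drop <- low_maf | low_cr
  if (all(drop))
    stop("all markers removed by QC; review maf_min/callrate_min")
  reason <- ifelse(low_maf & low_cr, "maf+callrate",
                   ifelse(low_maf, "maf", "callrate"))
  report <- data.frame(marker = x$map$marker[drop],
                       maf = maf[drop], callrate = callrate[drop],
                       reason = reason[drop],
                       row.names = NULL, stringsAsFactors = FALSE)
  list(geno = x[, which(!drop)], report = report)
}

#' Impute missing genotypes from linkage disequilibrium with neighbors
#'
#' Each missing call at marker j in individual i is predicted from the
#' `n_neighbors` markers nearest to j in bp on the same chromosome that
#' are observed in i. Each neighbor k casts a vote for the genotype class
#' of j that is most frequent among complete-case individuals sharing i's
#' genotype at k, weighted by the squared genotype correlation r2(j, k);
#' ties go to the overall modal genotype at j. A missing call with no
#' usable neighbor falls back to the marker-wise modal genotype.
#'
#' Observed calls are never altered; the returned matrix is complete.
#'
#' @param x A [geno_set()], normally after [filter_markers()].
#' @param n_neighbors Number of flanking markers consulted (default 10,
#'   both flanks pooled, nearest by bp).
#' @return A `geno_set` without missing values.
#' @export
impute_missing <- function(x, n_neighbors = 10) {
  stopifnot(inherits(x, "geno_set"), n_neighbors >= 1)
  g <- x$geno
  if (!anyNA(g)) return(x)
  map <- x$map
  modal <- apply(g, 2, function(col) {
    tb <- tabulate(col + 1L, nbins = 3L)
    which.max(tb) - 1L                    # ties -> smallest code
  })
  n_fallback <- 0L
  for (chr in unique(map$chrom)) {
    jj <- which(map$chrom == chr)
    sub <- g[, jj, drop = FALSE]
    if (!anyNA(sub)) next
    pos <- map$pos[jj]
    for (a in seq_along(jj)) {
      j <- jj[a]
      miss_i <- which(is.na(g[, j]))
      if (!length(miss_i)) next
      d <- abs(pos - pos[a])
      ord <- setdiff(order(d), a)
      for (i in miss_i) {
        nb <- ord[!is.na(g[i, jj[ord]])]
        nb <- utils::head(nb, n_neighbors)
        if (!length(nb)) {
          g[i, j] <- modal[j]
          n_fallback <- n_fallback + 1L
          next
        }
        w <- numeric(3)                   # weight per genotype class 0/1/2
        for (b in nb) {
          k <- jj[b]
          cc <- !is.na(x$geno[, j]) & !is.na(x$geno[, k])
          if (sum(cc) < 2L) next
          gk <- x$geno[cc, k]; gj <- x$geno[cc, j]
          if (stats::var(gk) == 0 || stats::var(gj) == 0) next
          r2 <- stats::cor(gj, gk)^2
          share <- gj[gk == x$geno[i, k]]
          if (!length(share)) next
          tb <- tabulate(share + 1L, nbins = 3L)
          vote <- which.max(tb) - 1L
          if (max(tb) > 0) w[vote + 1L] <- w[vote + 1L] + r2
        }
        if (all(w == 0)) {
          g[i, j] <- modal[j]
          n_fallback <- n_fallback + 1L
        } else {
          best <- which(w == max(w)) - 1L
          g[i, j] <- if (length(best) > 1L && (modal[j] %in% best))
            modal[j] else best[1L]
        }
      }
    }
  }
  if (n_fallback > 0)
    message("impute_missing: ", n_fallback,
            " call(s) imputed by modal-genotype fallback")
  out <- x
  out$geno <- g
  out
}
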
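# Binary-trait linear mixed-model genome scan, EMMAX-style:
# variance components are estimated once by REML under the null model
#   y = mu + g + e,   g ~ N(0, K sigma_g^2),  e ~ N(0, I sigma_e^2),
# the phenotypic covariance V = K sigma_g^2 + I sigma_e^2 is factored by
# Cholesky, and every marker is tested by ordinary regression of the
# whitened phenotype on the whitened genotype column.
#
# The 0/1 reversal indicator is analysed on the observed (liability
# approximation) scale: the individual-level logit of a Bernoulli outcome
# is undefined, and the whitened simple regression is exactly a linear
# mixed model on y.

#' REML variance components under the null polygenic model
#'
#' Estimates `sigma2_g` and `sigma2_e` for the intercept-only model
#' `y = mu + g + e` with `g ~ N(0, K sigma2_g)` by restricted maximum
#' likelihood. K is eigendecomposed once and the restricted likelihood is
#' profiled over the ratio `lambda = sigma2_g / sigma2_e` on a log-scale
#' grid followed by local refinement.
#'
#' When K carries no structure (e.g. `K = I`) only the total variance is
#' identifiable; the profile is flat and a boundary solution is returned
#' with a warning.
#'
#' @param y Numeric phenotype vector (0/1 reversal indicator).
#' @param K A [build_grm()] result or an n x n relationship matrix.
#' @return Object of class `vc`: `sigma2_g`, `sigma2_e`, `lambda`,
#'   `loglik` (restricted), `boundary` flag and `n`.
#' @export
estimate_vc <- function(y, K) {
  if (inherits(K, "grm")) K <- K$K
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  if (stats::var(y) == 0) stop("phenotype is constant")
  ek <- eigen(K, symmetric = TRUE)
  d <- ek$values
  if (min(d) < -1e-8 * max(abs(d)))
    stop("K is not positive semi-definite (min eigenvalue ",
         format(min(d)), ")")
  d <- pmax(d, 0)
  yt <- crossprod(ek$vectors, y)[, 1]
  xt <- crossprod(ek$vectors, rep(1, n))[, 1]
  q <- 1L
  rll <- function(loglam) {
    w <- exp(loglam) * d + 1
    sxx <- sum(xt^2 / w)
    beta <- sum(xt * yt / w) / sxx
    r <- yt - xt * beta
    s2e <- sum(r^2 / w) / (n - q)
    -0.5 * ((n - q) * log(2 * pi * s2e) + sum(log(w)) + log(sxx) +
              (n - q))
  }
  grid <- seq(log(1e-6), log(1e6), length.out = 121)
  ll <- vapply(grid, rll, numeric(1))
  flat <- diff(range(ll)) < 1e-6
  i <- which.max(ll)
  if (flat) {
    warning("restricted likelihood is flat in sigma2_g/sigma2_e ",
            "(K carries no structure); returning boundary solution")
    loglam <- grid[1]
    boundary <- TRUE
  } else if (i == 1L || i == length(grid)) {
    loglam <- grid[i]
    boundary <- TRUE
  } else {
    opt <- stats::optimize(rll, c(grid[i - 1L], grid[i + 1L]),
                           maximum = TRUE, tol = 1e-8)
    loglam <- opt$maximum
    boundary <- FALSE
  }
  lam <- exp(loglam)
  w <- lam * d + 1
  sxx <- sum(xt^2 / w)
  beta <- sum(xt * yt / w) / sxx
  s2e <- sum((yt - xt * beta)^2 / w) / (n - q)
  if (boundary && lam <= exp(grid[1]) * (1 + 1e-12)) lam_out <- 0
  else lam_out <- lam
  structure(list(sigma2_g = lam_out * s2e, sigma2_e = s2e,
                 lambda = lam_out, loglik = rll(loglam),
                 boundary = boundary, n = n), class = "vc")
}

#' @export
print.vc <- function(x, ...) {
  cat(sprintf("REML variance components (n = %d)\n", x$n))
  cat(sprintf("  sigma2_g = %.6g  sigma2_e = %.6g  lambda = %.4g\n",
              x$sigma2_g, x$sigma2_e, x$lambda))
  if (x$boundary) cat("  (boundary solution)\n")
  invisible(x)
}

#' Cholesky whitening of phenotype and genotypes
#'
#' Forms `V = K sigma2_g + I sigma2_e`, factors `V = L L'` and returns
#' `y* = L^-1 y`, `M* = L^-1 M` and the whitened intercept column
#' `L^-1 1`, so that under the null with the true variance components
#' `Var(y*) = I` and every per-marker test reduces to ordinary least
#' squares. If the factorization fails, a jitter of
#' `1e-8 * mean(diag(V))` is added once before giving up.
#'
#' @param y Phenotype vector.
#' @param M Genotype matrix (individuals x markers), complete.
#' @param vc An [estimate_vc()] result.
#' @param K A [build_grm()] result or relationship matrix.
#' @return Object of class `whitened_design`: `ystar`, `Mstar`,
#'   `intercept`, `L`, `vc`.
#' @export
whiten <- function(y, M, vc, K) {
  if (inherits(K, "grm")) K <- K$K
  stopifnot(inherits(vc, "vc"), is.finite(vc$sigma2_g),
            is.finite(vc$sigma2_e), vc$sigma2_e > 0)
  n <- length(y)
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  V <- vc$sigma2_g * K + diag(vc$sigma2_e, n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    message("whiten: Cholesky failed; retrying with jitter")
    V <- V + diag(1e-8 * mean(diag(V)), n)
    ch <- chol(V)
  }
  L <- t(ch)
  Mstar <- forwardsolve(L, M)
  colnames(Mstar) <- colnames(M)
  structure(list(
    ystar = forwardsolve(L, y),
    Mstar = Mstar,
    intercept = forwardsolve(L, rep(1, n)),
    L = L, vc = vc), class = "whitened_design")
}

#' Per-marker association tests on a whitened design
#'
#' For every marker, fits ordinary least squares of `y*` on the whitened
#' intercept with and without the whitened marker column and forms the
#' Gaussian likelihood-ratio statistic `T = n log(RSS0 / RSS1)`, referred
#' to a chi-square distribution with one degree of freedom. Markers that
#' are monomorphic in sample (collinear with the intercept) get `T = 0`,
#' `P = 1`. A marker that separates the phenotype perfectly drives
#' `RSS1` to zero; its P-value is reported as the smallest representable
#' positive number with flag `"underflow"` rather than 0.
#'
#' @param design A [whiten()] result.
#' @param map Optional marker map (columns `marker`, `chrom`, `pos`)
#'   matched to the columns of `Mstar`.
#' @return Data frame: `marker`, (`chrom`, `pos`,) `b`, `stat`, `p`,
#'   `flag`.
#' @export
scan_markers <- function(design, map = NULL) {
  stopifnot(inherits(design, "whitened_design"))
  y <- design$ystar
  a <- design$intercept
  M <- design$Mstar
  n <- length(y)
  saa <- sum(a^2)
  say <- sum(a * y)
  syy <- sum(y^2)
  rss0 <- syy - say^2 / saa
  sam <- colSums(a * M)
  smm <- colSums(M^2)
  smy <- colSums(M * y)
  det <- saa * smm - sam^2
  collinear <- det <= 1e-12 * pmax(saa * smm, 1e-300)
  det[collinear] <- 1
  bm <- (saa * smy - sam * say) / det
  ba <- (smm * say - sam * smy) / det
  rss1 <- pmax(syy - (ba * say + bm * smy), 0)
  stat <- ifelse(rss1 <= 1e-12 * max(rss0, syy),
                 Inf, n * log(rss0 / rss1))
  stat <- pmax(stat, 0)
  stat[collinear] <- 0
  bm[collinear] <- 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  flag <- rep("", ncol(M))
  flag[collinear] <- "collinear"
  under <- !collinear & p == 0
  p[under] <- .Machine$double.xmin
  flag[under] <- "underflow"
  out <- data.frame(marker = colnames(M) %||%
                      paste0("m", seq_len(ncol(M))),
                    b = bm, stat = stat, p = p, flag = flag,
                    stringsAsFactors = FALSE)
  if (!is.null(map)) {
    idx <- match(out$marker, map$marker)
    out$chrom <- map$chrom[idx]
    out$pos <- map$pos[idx]
    out <- out[, c("marker", "chrom", "pos", "b", "stat", "p", "flag")]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genome-wide significance threshold (upcrossing approximation)
#'
#' Computes the family-wise critical value of the scan statistic by the
#' quick upcrossing bound for a chi-square(1) scan process: with
#' `z_i = sign(b_i) sqrt(T_i)` the signed square-root profile, the
#' genome-wide error at level `u` is approximated by
#' `C * P(chi2_1 > u) + V exp(-u/2) / sqrt(2 pi)`, where `C` is the
#' number of chromosomes and `V` the summed total variation of `z`
#' across adjacent markers within chromosomes. The equation is solved for
#' `u` at the requested `alpha` and the result is clamped into the
#' pointwise-to-Bonferroni bracket. Non-finite statistics (perfect
#' separation) are excluded from `V`.
#'
#' @param scan A [scan_markers()] data frame with `chrom` and `pos`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return The critical value of the statistic (chi-square(1) scale).
#' @export
piepho_threshold <- function(scan, alpha = 0.05) {
  stopifnot(is.data.frame(scan), "chrom" %in% names(scan))
  m <- nrow(scan)
  u0 <- stats::qchisq(1 - alpha, 1)
  if (m == 1L) return(u0)
  uB <- stats::qchisq(1 - alpha / m, 1)
  z <- sign(scan$b) * sqrt(scan$stat)
  vtot <- 0
  for (ch in unique(scan$chrom)) {
    zc <- z[scan$chrom == ch]
    zc <- zc[is.finite(zc)]
    if (length(zc) > 1L) vtot <- vtot + sum(abs(diff(zc)))
  }
  C <- length(unique(scan$chrom))
  f <- function(u) C * stats::pchisq(u, 1, lower.tail = FALSE) +
    vtot * exp(-u / 2) / sqrt(2 * pi) - alpha
  if (f(uB) > 0) return(uB)
  if (f(u0) <= 0) return(u0)
  stats::uniroot(f, c(u0, uB), tol = 1e-10)$root
}

#' Permutation threshold (calibration oracle)
#'
#' Empirical genome-wide critical value obtained by permuting the raw
#' phenotype, re-whitening with the same variance components, rescanning
#' and taking the `1 - alpha` quantile of the per-permutation maximum
#' statistic. Used to validate the analytic threshold.
#'
#' @param y Raw phenotype vector.
#' @param M Genotype matrix.
#' @param vc,K As in [whiten()].
#' @param n_perm Number of permutations.
#' @param alpha Family-wise error rate.
#' @return Critical value of the statistic.
#' @export
permutation_threshold <- function(y, M, vc, K, n_perm = 100,
                                  alpha = 0.05) {
  maxes <- vapply(seq_len(n_perm), function(i) {
    d <- whiten(sample(y), M, vc, K)
    s <- scan_markers(d)$stat
    max(s[is.finite(s)])
  }, numeric(1))
  as.numeric(stats::quantile(maxes, 1 - alpha, type = 1))
}

#' Support interval around the scan peak
#'
#' Returns the genomic interval on the peak's chromosome over which the
#' statistic profile stays within a drop `d` of the peak value, where `d`
#' is the chi-square(1) quantile at `level` (3.841 for 95%). The interval
#' is the contiguous run of markers around the peak satisfying
#' `T >= T_peak - d`, extended on each side to the midpoint between the
#' last inside marker and the first outside marker, and clipped to the
#' chromosome's marker span (or `chrom_lengths` when supplied).
#'
#' @param scan A [scan_markers()] data frame with `chrom` and `pos`.
#' @param threshold Genome-wide threshold; the peak must exceed it.
#' @param level Confidence level (default 0.95).
#' @param chrom_lengths Optional named vector of chromosome lengths (bp)
#'   used for clipping.
#' @return List: `chrom`, `start`, `end`, `level`, `peak_marker`.
#' @export
peak_ci <- function(scan, threshold, level = 0.95,
                    chrom_lengths = NULL) {
  pk <- scan_peak(scan)
  if (!(scan$stat[pk] > threshold))
    stop("no QTL: no marker exceeds the genome-wide threshold")
  d <- stats::qchisq(level, 1)
  ch <- scan$chrom[pk]
  on_ch <- which(scan$chrom == ch)
  sub <- scan[on_ch, ]
  sub <- sub[order(sub$pos), ]
  ipk <- which(sub$marker == scan$marker[pk])
  inside <- sub$stat >= scan$stat[pk] - d
  lo <- ipk
  while (lo > 1L && inside[lo - 1L]) lo <- lo - 1L
  hi <- ipk
  while (hi < nrow(sub) && inside[hi + 1L]) hi <- hi + 1L
  start <- if (lo == 1L) {
    if (!is.null(chrom_lengths)) 1 else sub$pos[1]
  } else floor((sub$pos[lo - 1L] + sub$pos[lo]) / 2)
  end <- if (hi == nrow(sub)) {
    if (!is.null(chrom_lengths)) unname(chrom_lengths[ch])
    else sub$pos[nrow(sub)]
  } else ceiling((sub$pos[hi] + sub$pos[hi + 1L]) / 2)
  list(chrom = ch, start = as.numeric(start), end = as.numeric(end),
       level = level, peak_marker = scan$marker[pk])
}

# peak index: largest statistic, ties broken by smallest p then leftmost
scan_peak <- function(scan) {
  best <- which(scan$stat == max(scan$stat))
  if (length(best) > 1L) {
    best <- best[scan$p[best] == min(scan$p[best])]
    best <- best[order(scan$chrom[best], scan$pos[best])][1L]
  }
  best
}

#' Mixed-model genome scan for sex reversal
#'
#' End-to-end association scan of a binary reversal phenotype: applies
#' the cohort conditioning rule (e.g. keep ZW genetic females carrying
#' the unfavorable T allele at a conditioning locus, mirroring a scan for
#' a second, interacting locus), optionally re-runs marker QC and
#' imputation on the cohort, rebuilds the relationship matrix, estimates
#' variance components under the null, whitens, scans every marker,
#' computes the genome-wide threshold and the support interval of the
#' peak.
#'
#' @param geno A [geno_set()].
#' @param pheno Phenotype data frame with `id` and `reversal` (see
#'   [read_phenotypes()]).
#' @param condition Optional cohort rule: named character vector
#'   `c(marker = "...", allele = "...")`. Only individuals whose genotype
#'   at `marker` carries at least one copy of `allele` are kept. ZW
#'   individuals are hemizygous at Z markers, so carrying means code 2
#'   (or 1 for a duplicated heterozygote).
#' @param zw_only Keep only `genetic_sex == "ZW"` individuals (default
#'   `TRUE` when the column is present).
#' @param qc Re-apply [filter_markers()] and [impute_missing()] on the
#'   cohort (default `TRUE`).
#' @param maf_min,callrate_min QC thresholds, see [filter_markers()].
#' @param alpha Family-wise error rate for the threshold.
#' @param ci_level Support-interval level.
#' @param exclude_sex_chrom Exclude W/Z markers from the relationship
#'   matrix (not from the scan).
#' @return Object of class `zw_scan`: `results` (per-marker table with
#'   `above_threshold`), `vc`, `threshold`, `alpha`, `peak`, `ci`, `n`,
#'   `n_markers`, `ids`, `qc_report`.
#' @examples
#' sim <- simulate_ztw_cohort(80, sim_config(marker_scale = 0.01, seed = 1))
#' fit <- run_gwas(sim$geno, sim$pheno)
#' print(fit)
#' @export
run_gwas <- function(geno, pheno, condition = NULL, zw_only = TRUE,
                     qc = TRUE, maf_min = 0.05, callrate_min = 0.80,
                     alpha = 0.05, ci_level = 0.95,
                     exclude_sex_chrom = FALSE) {
  stopifnot(inherits(geno, "geno_set"))
  ids <- intersect(rownames(geno$geno), pheno$id)
  if (zw_only && "genetic_sex" %in% names(pheno))
    ids <- intersect(ids, pheno$id[pheno$genetic_sex == "ZW"])
  if (!is.null(condition)) {
    mk <- condition[["marker"]]
    al <- condition[["allele"]]
    j <- match(mk, geno$map$marker)
    if (is.na(j)) stop("conditioning marker not found: ", mk)
    dose <- geno$geno[, j]
    carrier <- if (identical(al, geno$map$alt[j])) dose >= 1
    else if (identical(al, geno$map$ref[j])) dose <= 1
    else stop("allele ", al, " is neither ref nor alt of ", mk)
    ids <- intersect(ids, rownames(geno$geno)[which(carrier)])
  }
  if (length(ids) < 30)
    warning("cohort has only ", length(ids), " individuals")
  g <- geno[match(ids, rownames(geno$geno)), ]
  y <- pheno$reversal[match(ids, pheno$id)]
  if (length(unique(y)) < 2L)
    stop("phenotype has a single class after cohort filtering")
  report <- NULL
  if (qc) {
    fl <- filter_markers(g, maf_min = maf_min,
                         callrate_min = callrate_min)
    g <- impute_missing(fl$geno)
    report <- fl$report
  } else if (anyNA(g$geno))
    stop("missing genotypes; run QC/imputation or set qc = TRUE")
  grm <- build_grm(g, exclude_sex_chrom = exclude_sex_chrom)
  vc <- estimate_vc(y, grm)
  design <- whiten(y, g$geno, vc, grm)
  res <- scan_markers(design, g$map)
  threshold <- piepho_threshold(res, alpha = alpha)
  res$above_threshold <- res$stat > threshold
  pk <- scan_peak(res)
  ci <- if (res$stat[pk] > threshold)
    peak_ci(res, threshold, level = ci_level) else NULL
  structure(list(results = res, vc = vc, threshold = threshold,
                 alpha = alpha, peak = res[pk, ], ci = ci,
                 n = length(ids), n_markers = nrow(res), ids = ids,
                 qc_report = report, call = match.call()),
            class = "zw_scan")
}

#' @export
print.zw_scan <- function(x, ...) {
  cat("Mixed-model genome scan (", x$n, " individuals, ", x$n_markers,
      " markers)\n", sep = "")
  cat(sprintf("genome-wide threshold (alpha = %g): %.3f\n", x$alpha,
              x$threshold))
  cat(sprintf("peak: %s (chrom %s, %s bp)  T = %s  P = %s\n",
              x$peak$marker, x$peak$chrom,
              format(x$peak$pos, big.mark = ","),
              format(x$peak$stat, digits = 4),
              format(x$peak$p, digits = 3)))
  if (!is.null(x$ci))
    cat(sprintf("%d%% support interval: chrom %s, %s-%s bp\n",
                round(100 * x$ci$level), x$ci$chrom,
                format(x$ci$start, big.mark = ","),
                format(x$ci$end, big.mark = ",")))
  else cat("no marker exceeds the genome-wide threshold\n")
  invisible(x)
}

#' @export
summary.zw_scan <- function(object, n_top = 5, ...) {
  print(object)
  print(object$vc)
  top <- object$results[order(-object$results$stat), ]
  cat("top markers:\n")
  print(utils::head(top[, c("marker", "chrom", "pos", "b", "stat", "p")],
                    n_top), row.names = FALSE)
  invisible(object)
}

#' @export
coef.zw_scan <- function(object, ...) {
  stats::setNames(object$results$b, object$results$marker)
}

#' Manhattan plot of a genome scan
#'
#' Plots `-log10(P)` against the cumulative genomic coordinate over
#' chromosomes 1-20, W and Z, with a dashed line at the genome-wide
#' threshold.
#'
#' @param x A `zw_scan` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.zw_scan <- function(x, ...) {
  res <- x$results
  chroms <- unique(res$chrom)
  offs <- 0
  xcoord <- numeric(nrow(res))
  mids <- numeric(length(chroms))
  for (i in seq_along(chroms)) {
    sel <- res$chrom == chroms[i]
    xcoord[sel] <- res$pos[sel] + offs
    mids[i] <- offs + (min(res$pos[sel]) + max(res$pos[sel])) / 2
    offs <- offs + max(res$pos[sel]) + 1e6
  }
  logp <- -log10(res$p)
  cap <- is.infinite(logp)
  logp[cap] <- max(logp[!cap], 310)
  cols <- c("grey30", "steelblue")[(match(res$chrom, chroms) %% 2) + 1]
  graphics::plot(xcoord, logp, pch = 20, col = cols, xaxt = "n",
                 xlab = "chromosome", ylab = expression(-log[10](P)),
                 ...)
  graphics::axis(1, at = mids, labels = chroms, las = 2, cex.axis = 0.7)
  graphics::abline(h = -log10(stats::pchisq(x$threshold, 1,
                                            lower.tail = FALSE)),
                   lty = 2)
  invisible(x)
}
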
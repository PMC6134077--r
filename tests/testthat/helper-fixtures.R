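# Small in-code fixtures shared across test files.

# geno_set from a plain matrix on a single chromosome
toy_geno <- function(values, chrom = "1", pos = NULL) {
  g <- as.matrix(values)
  if (is.null(pos)) pos <- seq_len(ncol(g)) * 1000L
  map <- data.frame(marker = sprintf("Cyn_%s_%d", chrom, pos),
                    chrom = chrom, pos = pos,
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  colnames(g) <- map$marker
  geno_set(g, map)
}

# tiny fast simulation config: few families, small genome
tiny_config <- function(..., seed = 1) {
  sim_config(n_families = 4, n_offspring_per_family = 12,
             marker_counts = c("1" = 40, "2" = 40, Z = 30, W = 6),
             seed = seed, ...)
}

# expand the validation-population two-locus cell counts into
# per-individual records: list(g1, g2, phenotype)
validation_records <- function() {
  cells <- data.frame(
    g2 = c("GG", "GG", "AA", "AA", "AG", "AG"),
    g1 = c("A", "T", "A", "T", "A", "T"),
    phenotype = c("female", "female", "female", "pseudomale",
                  "female", "pseudomale"),
    n = c(91L, 123L, 0L, 39L, 1L, 5L),
    stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(cells)), cells$n)
  list(g1 = cells$g1[idx], g2 = cells$g2[idx],
       phenotype = cells$phenotype[idx])
}

# direct generalized-least-squares oracle for the scan statistic:
# T = n * log(RSS0_V / RSS1_V) with RSS_V the V-metric residual sum
gls_stat_oracle <- function(y, M, V) {
  Vi <- solve(V)
  n <- length(y)
  rss <- function(X) {
    b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    drop(t(r) %*% Vi %*% r)
  }
  ones <- matrix(1, n, 1)
  rss0 <- rss(ones)
  vapply(seq_len(ncol(M)), function(j) {
    n * log(rss0 / rss(cbind(ones, M[, j])))
  }, numeric(1))
}
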
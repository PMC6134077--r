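# Forward simulator for ZW family populations.
#
# The default genome mirrors the SNP panel of a tongue-sole 2b-RAD study:
# chromosomes 1-20 plus W and Z, with per-chromosome marker counts scaled
# from the published panel and two linked causal loci on Z whose joint
# alleles determine female-to-male sex reversal.

# Published SNP panel: per-chromosome marker count and span of the mapped
# SNPs in Mb. Used (scaled) as the default marker map.
.marker_panel <- data.frame(
  chrom = c(as.character(1:20), "W", "Z"),
  n_snps = c(2961L, 1753L, 1372L, 1597L, 1734L, 1544L, 1309L, 2395L,
             1597L, 1644L, 1612L, 1556L, 1576L, 1951L, 1503L, 1491L,
             1414L, 1236L, 1345L, 1215L, 119L, 486L),
  span_mb = c(34.50733, 20.04642, 16.21593, 19.96116, 19.26109, 18.82236,
              13.78154, 30.12243, 19.59837, 20.95554, 20.46002, 18.35167,
              21.85925, 28.83096, 20.05586, 18.77584, 16.45747, 15.0991,
              17.72299, 15.20323, 15.83972, 21.14982),
  stringsAsFactors = FALSE)

#' Default marker panel (per-chromosome SNP counts and spans)
#'
#' Per-chromosome SNP counts and physical spans (Mb) of the reference
#' tongue-sole panel that [sim_config()] scales to build its default
#' marker map: 33,410 SNPs over chromosomes 1-20, W and Z.
#'
#' @return Data frame with columns `chrom`, `n_snps`, `span_mb`.
#' @export
default_marker_table <- function() .marker_panel

#' Configuration for the ZW population simulator
#'
#' Builds and validates the parameter set consumed by
#' [simulate_population()]. Defaults emulate the design of a tongue-sole
#' sex-reversal mapping study: nine full-sib families raised in a common
#' environment, a marker panel proportional to [default_marker_table()]
#' (scaled by `marker_scale`), and two linked causal loci on the Z
#' chromosome at 6,676,874 and 8,564,889 bp. A ZW genetic female reverses
#' to a phenotypic male iff its Z carries the unfavorable T allele at the
#' first locus and its genotype at the second locus carries at least one
#' unfavorable A allele.
#'
#' @param n_families Number of full-sib families (default 9).
#' @param n_offspring_per_family Offspring per family (default 51, so the
#'   expected Z^T W cohort size is about 171 under the default founder
#'   allele frequencies).
#' @param marker_scale Factor applied to the panel's per-chromosome SNP
#'   counts (default 0.1, about 3,300 markers).
#' @param marker_counts Optional named vector of per-chromosome marker
#'   counts overriding the scaled panel. Names must be in
#'   `{1..20, W, Z}`.
#' @param chrom_lengths_bp Optional named vector of chromosome lengths in
#'   bp; defaults to the panel spans.
#' @param causal_pos Two Z-chromosome bp positions of the causal loci.
#' @param unfavorable Named character vector: the reversal-inducing
#'   alleles, `c(locus1 = "T", locus2 = "A")`.
#' @param causal_freq_locus1,causal_freq_locus2 Founder frequencies of the
#'   unfavorable allele on Z haplotypes at the two causal loci.
#' @param penetrance_noise Probability that the deterministic reversal
#'   outcome is flipped (default 0).
#' @param missing_rate Probability that a genotype call is set missing
#'   (default 0; see also [inject_missingness()]).
#' @param maf_low,maf_high Bounds of the uniform distribution of neutral
#'   founder allele frequencies.
#' @param sire_type Per-family sire type, `"normal_ZZ"` or
#'   `"pseudomale_ZW"` (recycled). A pseudomale sire is a reversed ZW
#'   genetic female whose single Z carries the unfavorable T-A haplotype
#'   and who transmits only Z-bearing sperm.
#' @param het_locus2_rate Probability that a ZW individual is called
#'   heterozygous (AG) at the second causal locus, emulating the observed
#'   rare Dmrt1 duplication (default 0).
#' @param seed Integer seed driving all randomness of the simulation.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_families = 9,
                       n_offspring_per_family = 51,
                       marker_scale = 0.1,
                       marker_counts = NULL,
                       chrom_lengths_bp = NULL,
                       causal_pos = c(6676874L, 8564889L),
                       unfavorable = c(locus1 = "T", locus2 = "A"),
                       causal_freq_locus1 = 0.75,
                       causal_freq_locus2 = 0.55,
                       penetrance_noise = 0,
                       missing_rate = 0,
                       maf_low = 0.05, maf_high = 0.5,
                       sire_type = "normal_ZZ",
                       het_locus2_rate = 0,
                       seed = NULL) {
  panel <- .marker_panel
  lens <- stats::setNames(round(panel$span_mb * 1e6), panel$chrom)
  if (!is.null(chrom_lengths_bp)) lens[names(chrom_lengths_bp)] <-
    chrom_lengths_bp
  if (is.null(marker_counts)) {
    marker_counts <- stats::setNames(pmax(2L,
      as.integer(round(panel$n_snps * marker_scale))), panel$chrom)
  }
  marker_counts <- unlist(marker_counts)
  storage.mode(marker_counts) <- "integer"
  if (!all(names(marker_counts) %in% panel$chrom))
    stop("marker_counts names must be chromosomes 1-20, W or Z")
  if (is.na(marker_counts["Z"]) || marker_counts[["Z"]] < 1L)
    stop("configuration error: Z chromosome needs at least one marker ",
         "(the causal loci are Z-linked)")
  stopifnot(n_families >= 1, n_offspring_per_family >= 1,
            length(causal_pos) == 2,
            penetrance_noise >= 0, penetrance_noise <= 1,
            missing_rate >= 0, missing_rate < 1,
            het_locus2_rate >= 0, het_locus2_rate <= 1,
            maf_low > 0, maf_high < 1, maf_low <= maf_high,
            causal_freq_locus1 > 0, causal_freq_locus1 <= 1,
            causal_freq_locus2 > 0, causal_freq_locus2 < 1)
  if (any(causal_pos < 1 | causal_pos > lens[["Z"]]))
    stop("causal positions outside the Z chromosome length")
  sire_type <- rep_len(match.arg(sire_type,
    c("normal_ZZ", "pseudomale_ZW"), several.ok = TRUE), n_families)
  structure(list(
    n_families = as.integer(n_families),
    n_offspring_per_family = as.integer(n_offspring_per_family),
    marker_counts = marker_counts[panel$chrom[panel$chrom %in%
                                              names(marker_counts)]],
    chrom_lengths_bp = lens,
    causal_pos = sort(as.integer(causal_pos)),
    unfavorable = unfavorable,
    causal_freq_locus1 = causal_freq_locus1,
    causal_freq_locus2 = causal_freq_locus2,
    penetrance_noise = penetrance_noise,
    missing_rate = missing_rate,
    maf_low = maf_low, maf_high = maf_high,
    sire_type = sire_type,
    het_locus2_rate = het_locus2_rate,
    seed = seed), class = "sim_config")
}

# one-crossover gamete from a pair of haplotypes
.gamete <- function(h1, h2, pos, len) {
  if (stats::runif(1) < 0.5) { a <- h1; h1 <- h2; h2 <- a }
  xo <- stats::runif(1, 0, len)
  ifelse(pos <= xo, h1, h2)
}

#' Simulate a ZW family population with a two-locus reversal rule
#'
#' Forward-simulates full-sib families on the configured marker map.
#' Founder haplotypes draw neutral alleles at frequencies uniform in
#' `[maf_low, maf_high]`; inheritance is Mendelian with free recombination
#' between chromosomes and one uniform crossover within each paired
#' chromosome per meiosis. The Z of a ZW individual has no pairing
#' partner and is transmitted intact, as is the W; a pseudomale sire
#' transmits only its (T-A haplotype) Z. ZW dams transmit Z or W with
#' probability 1/2. Z- and W-linked genotypes of ZW individuals are
#' hemizygous, coded 0 or 2 on the diploid scale (never 1, unless the
#' Dmrt1-duplication option `het_locus2_rate` fires); ZZ individuals are
#' coded `NA` at W markers.
#'
#' Phenotype: ZZ individuals are males and never reversed. A ZW female
#' reverses iff its Z carries T at the first causal locus and its
#' second-locus genotype carries at least one A; the outcome is flipped
#' with probability `penetrance_noise`.
#'
#' @param config A [sim_config()].
#' @return A list of class `zw_sim` with elements `geno` ([geno_set()],
#'   offspring only), `pheno` (phenotype data frame: `id`, `sire`, `dam`,
#'   `genetic_sex`, `phenotypic_sex`, `reversal`) and `truth` (per-ZW
#'   causal genotypes: `id`, `locus1_allele`, `locus2_genotype`,
#'   `causal_markers`).
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  unf <- config$unfavorable
  # marker map ---------------------------------------------------------------
  chroms <- names(config$marker_counts)
  genome <- lapply(chroms, function(ch) {
    len <- config$chrom_lengths_bp[[ch]]
    n <- config$marker_counts[[ch]]
    pos <- sort(sample.int(len, n))
    if (ch == "Z") pos <- sort(unique(c(pos, config$causal_pos)))
    p <- stats::runif(length(pos), config$maf_low, config$maf_high)
    ref <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
    if (ch == "Z") {
      i1 <- match(config$causal_pos[1], pos)
      i2 <- match(config$causal_pos[2], pos)
      p[i1] <- config$causal_freq_locus1
      p[i2] <- config$causal_freq_locus2
      # alt = unfavorable allele at the causal loci
      ref[i1] <- "A"; alt[i1] <- unf[["locus1"]]
      ref[i2] <- "G"; alt[i2] <- unf[["locus2"]]
    }
    list(chrom = ch, pos = pos, p = p, ref = ref, alt = unname(alt),
         len = len)
  })
  names(genome) <- chroms
  autos <- setdiff(chroms, c("W", "Z"))
  zg <- genome[["Z"]]
  ci1 <- match(config$causal_pos[1], zg$pos)
  ci2 <- match(config$causal_pos[2], zg$pos)

  draw_hap <- function(g) as.integer(stats::runif(length(g$p)) < g$p)
  founder_autos <- function() lapply(genome[autos], function(g)
    list(draw_hap(g), draw_hap(g)))

  offspring <- list()
  for (f in seq_len(config$n_families)) {
    sire_id <- sprintf("F%d_S", f)
    dam_id <- sprintf("F%d_D", f)
    pseudo <- config$sire_type[f] == "pseudomale_ZW"
    sire <- list(autos = founder_autos())
    if (pseudo) {
      z <- draw_hap(zg)
      z[ci1] <- 1L; z[ci2] <- 1L      # a pseudomale carries the T-A Z
      sire$z <- list(z)
      sire$w <- if ("W" %in% chroms) draw_hap(genome[["W"]]) else NULL
    } else {
      sire$z <- list(draw_hap(zg), draw_hap(zg))
    }
    dam <- list(autos = founder_autos(), z = list(draw_hap(zg)),
                w = if ("W" %in% chroms) draw_hap(genome[["W"]]) else NULL)
    for (k in seq_len(config$n_offspring_per_family)) {
      oa <- lapply(autos, function(ch) {
        g <- genome[[ch]]
        list(.gamete(sire$autos[[ch]][[1]], sire$autos[[ch]][[2]],
                     g$pos, g$len),
             .gamete(dam$autos[[ch]][[1]], dam$autos[[ch]][[2]],
                     g$pos, g$len))
      })
      names(oa) <- autos
      z_sire <- if (pseudo) sire$z[[1]] else
        .gamete(sire$z[[1]], sire$z[[2]], zg$pos, zg$len)
      dam_gives_w <- stats::runif(1) < 0.5
      ind <- list(id = sprintf("F%d_O%d", f, k), sire = sire_id,
                  dam = dam_id, autos = oa)
      if (dam_gives_w) {             # ZW genetic female
        ind$genetic_sex <- "ZW"
        ind$z <- list(z_sire)
        ind$w <- dam$w
      } else {                       # ZZ male
        ind$genetic_sex <- "ZZ"
        ind$z <- list(z_sire, dam$z[[1]])
        ind$w <- NULL
      }
      offspring[[length(offspring) + 1L]] <- ind
    }
  }

  n <- length(offspring)
  ids <- vapply(offspring, `[[`, character(1), "id")
  # genotype matrix -----------------------------------------------------------
  blocks <- vector("list", length(chroms))
  names(blocks) <- chroms
  for (ch in chroms) {
    g <- genome[[ch]]
    m <- matrix(NA_integer_, n, length(g$pos))
    for (i in seq_len(n)) {
      ind <- offspring[[i]]
      if (ch %in% autos) {
        m[i, ] <- ind$autos[[ch]][[1]] + ind$autos[[ch]][[2]]
      } else if (ch == "Z") {
        m[i, ] <- if (ind$genetic_sex == "ZW") 2L * ind$z[[1]] else
          ind$z[[1]] + ind$z[[2]]
      } else {                        # W
        if (ind$genetic_sex == "ZW") m[i, ] <- 2L * ind$w
      }
    }
    blocks[[ch]] <- m
  }
  geno <- do.call(cbind, blocks)
  map <- do.call(rbind, lapply(genome, function(g)
    data.frame(marker = sprintf("Cyn_%s_%d", g$chrom, g$pos),
               chrom = g$chrom, pos = g$pos, ref = g$ref, alt = g$alt,
               stringsAsFactors = FALSE)))
  rownames(map) <- NULL
  colnames(geno) <- map$marker
  rownames(geno) <- ids

  # causal truth and phenotype ------------------------------------------------
  is_zw <- vapply(offspring, function(o) o$genetic_sex == "ZW", logical(1))
  l1 <- ifelse(vapply(offspring, function(o)
    if (o$genetic_sex == "ZW") o$z[[1]][ci1] else NA_integer_,
    integer(1)) == 1L, unf[["locus1"]], "A")
  a2 <- vapply(offspring, function(o)
    if (o$genetic_sex == "ZW") o$z[[1]][ci2] else NA_integer_, integer(1))
  l2 <- ifelse(a2 == 1L, strrep(unf[["locus2"]], 2), "GG")
  if (config$het_locus2_rate > 0) {
    dup <- is_zw & stats::runif(n) < config$het_locus2_rate
    l2[dup] <- paste0(unf[["locus2"]], "G")
    geno[dup, map$marker == sprintf("Cyn_Z_%d", config$causal_pos[2])] <- 1L
  }
  carries_a <- grepl(unf[["locus2"]], l2, fixed = TRUE)
  rule <- as.integer(l1 == unf[["locus1"]] & carries_a)
  reversal <- rep(0L, n)
  reversal[is_zw] <- rule[is_zw]
  if (config$penetrance_noise > 0) {
    flip <- is_zw & stats::runif(n) < config$penetrance_noise
    reversal[flip] <- 1L - reversal[flip]
  }
  pheno <- data.frame(
    id = ids,
    sire = vapply(offspring, `[[`, character(1), "sire"),
    dam = vapply(offspring, `[[`, character(1), "dam"),
    genetic_sex = ifelse(is_zw, "ZW", "ZZ"),
    phenotypic_sex = ifelse(is_zw, ifelse(reversal == 1L, "male", "female"),
                            "male"),
    reversal = reversal, stringsAsFactors = FALSE)
  truth <- data.frame(
    id = ids[is_zw], locus1_allele = l1[is_zw],
    locus2_genotype = l2[is_zw], stringsAsFactors = FALSE)
  attr(truth, "causal_markers") <- sprintf("Cyn_Z_%d", config$causal_pos)

  gs <- geno_set(geno, map)
  if (config$missing_rate > 0)
    gs <- inject_missingness(gs, config$missing_rate)
  structure(list(geno = gs, pheno = pheno, truth = truth,
                 config = config), class = "zw_sim")
}

#' @export
print.zw_sim <- function(x, ...) {
  cat("zw_sim:", nrow(x$pheno), "offspring from", x$config$n_families,
      "families;", ncol(x$geno$geno), "markers\n")
  zw <- x$pheno$genetic_sex == "ZW"
  cat(sprintf("ZW %d / ZZ %d; reversed %d\n", sum(zw), sum(!zw),
              sum(x$pheno$reversal)))
  invisible(x)
}

#' Simulate a Z^T W mapping cohort
#'
#' Convenience wrapper reproducing the study design: simulate a family
#' population, keep the ZW genetic females whose Z carries the
#' unfavorable T allele at the first causal locus, and trim to `n`
#' individuals. All such fish share the conditioning allele, so the scan
#' signal comes from the second locus.
#'
#' @param n Cohort size (default 171).
#' @param config A [sim_config()]; offspring counts are raised if needed
#'   so that the expected yield comfortably exceeds `n`.
#' @return A `zw_sim` restricted to the cohort.
#' @export
simulate_ztw_cohort <- function(n = 171, config = sim_config()) {
  expect_per_off <- 0.5 * config$causal_freq_locus1
  need <- ceiling(1.4 * n / (config$n_families * expect_per_off))
  if (config$n_offspring_per_family < need)
    config$n_offspring_per_family <- as.integer(need)
  sim <- simulate_population(config)
  keep <- sim$truth$id[sim$truth$locus1_allele ==
                         config$unfavorable[["locus1"]]]
  if (length(keep) < n)
    stop("cohort yield ", length(keep), " < ", n,
         "; increase n_offspring_per_family")
  keep <- keep[seq_len(n)]
  sim$geno <- sim$geno[match(keep, rownames(sim$geno$geno)), ]
  sim$pheno <- sim$pheno[match(keep, sim$pheno$id), ]
  sim$truth <- sim$truth[match(keep, sim$truth$id), ]
  attr(sim$truth, "causal_markers") <-
    sprintf("Cyn_Z_%d", config$causal_pos)
  rownames(sim$pheno) <- rownames(sim$truth) <- NULL
  sim
}

#' Randomly set genotype calls missing
#'
#' Each call is independently replaced by `NA` with probability `rate`;
#' the marker map is unchanged.
#'
#' @param x A [geno_set()].
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Optional seed for the missingness mask.
#' @return A `geno_set`.
#' @export
inject_missingness <- function(x, rate, seed = NULL) {
  stopifnot(inherits(x, "geno_set"))
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  mask <- stats::runif(length(x$geno)) < rate
  x$geno[mask] <- NA_integer_
  x
}

#' Write a simulated population as the three-file study layout
#'
#' Writes `<prefix>_pheno.tsv` (id, sire, dam, genetic_sex,
#' phenotypic_sex, reversal), `<prefix>_geno.tsv` (individuals x markers,
#' 0/1/2/NA) and `<prefix>_map.tsv` (marker, chrom, pos, ref, alt),
#' mirroring the deposited supplementary files of the study design this
#' simulator emulates.
#'
#' @param sim A `zw_sim` from [simulate_population()].
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_population <- function(sim, prefix) {
  stopifnot(inherits(sim, "zw_sim"))
  paths <- paste0(prefix, c("_pheno.tsv", "_geno.tsv", "_map.tsv"))
  write_phenotypes(sim$pheno, paths[1])
  write_genotypes(sim$geno, paths[2], paths[3])
  invisible(paths)
}
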
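test_that("TSV genotype round-trip is exact", {
  sim <- simulate_population(tiny_config(seed = 2, missing_rate = 0.05))
  gp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(sim$geno, gp, mp)
  back <- read_genotypes(gp, mp)
  expect_identical(back$geno, sim$geno$geno)
  expect_identical(back$map$marker, sim$geno$map$marker)
  expect_identical(back$map$pos, sim$geno$map$pos)
})

test_that("phenotype TSV round-trips and is validated", {
  sim <- simulate_population(tiny_config(seed = 2))
  pp <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(sim$pheno, pp)
  back <- read_phenotypes(pp)
  expect_identical(back, sim$pheno)
  bad <- sim$pheno
  bad$reversal[1] <- 5L
  write_phenotypes(bad, pp)
  expect_error(read_phenotypes(pp), "reversal")
})

test_that("VCF export/import preserves codes; ZW Z calls flagged HEMI", {
  sim <- simulate_population(tiny_config(seed = 4))
  zw <- sim$pheno$genetic_sex == "ZW"
  g <- sim$geno[zw, ]                   # all-ZW: W markers have calls
  vp <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(g, vp, format = "vcf")
  txt <- readLines(vp)
  expect_true(any(grepl("\tHEMI\t", txt, fixed = TRUE)))
  back <- read_genotypes(vp, format = "vcf")
  common <- intersect(back$map$marker, g$map$marker)
  expect_setequal(common, g$map$marker)
  expect_identical(back$geno[rownames(g$geno), g$map$marker], g$geno)
})

test_that("VCF coding: 0/1 -> 1, ./. -> NA, non-biallelic skipped", {
  vp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("1", "100", "snp1", "A", "G", ".", "PASS", ".", "GT",
          "0/1", "1/1", sep = "\t"),
    paste("1", "200", "snp2", "A", "G,T", ".", "PASS", ".", "GT",
          "0/1", "0/0", sep = "\t"),
    paste("1", "300", "snp3", "C", "T", ".", "PASS", ".", "GT",
          "./.", "0|0", sep = "\t")), vp)
  expect_warning(gs <- read_genotypes(vp, format = "vcf"),
                 "non-biallelic")
  expect_identical(gs$map$marker, c("snp1", "snp3"))
  expect_identical(unname(gs$geno["s1", ]), c(1L, NA))
  expect_identical(unname(gs$geno["s2", ]), c(2L, 0L))
})

test_that("MAF/call-rate filtering uses strict boundaries", {
  # 50 individuals; marker 1 monomorphic; marker 2 exactly at call rate
  # 0.80 (10/50 missing, retained); marker 3 at 11/50 missing (removed);
  # marker 4 exactly at MAF 0.05 (retained)
  n <- 50
  m1 <- rep(0L, n)
  m2 <- c(rep(NA, 10), rep(c(0L, 1L), 20))
  m3 <- c(rep(NA, 11), rep(c(0L, 1L), length.out = 39))
  m4 <- c(rep(1L, 5), rep(0L, 45))      # p = 5/100 = 0.05
  g <- toy_geno(cbind(m1, m2, m3, m4))
  out <- filter_markers(g)
  kept <- out$geno$map$marker
  expect_setequal(kept, g$map$marker[c(2, 4)])
  expect_setequal(out$report$marker, g$map$marker[c(1, 3)])
  expect_true("maf" %in% out$report$reason)
  # idempotence: refiltering removes nothing
  again <- filter_markers(out$geno)
  expect_equal(nrow(again$report), 0)
  expect_identical(again$geno$geno, out$geno$geno)
  expect_error(filter_markers(toy_geno(matrix(0L, 10, 3))),
               "all markers")
})

test_that("a rare allele (founder freq 0.02) is removed at n = 200", {
  # P(observed MAF >= 0.05) = P(Bin(400, 0.02) >= 20) < 1e-3
  for (s in 1:3) {
    set.seed(s)
    rare <- as.integer(stats::rbinom(200, 2, 0.02))
    common <- as.integer(stats::rbinom(200, 2, 0.3))
    out <- filter_markers(toy_geno(cbind(rare, common)))
    expect_true("Cyn_1_1000" %in% out$report$marker)   # the rare marker
    expect_true("Cyn_1_2000" %in% out$geno$map$marker)
  }
})

test_that("imputation: perfect-LD neighbor recovers the missing call", {
  set.seed(10)
  base <- as.integer(stats::rbinom(60, 2, 0.5))
  other <- as.integer(stats::rbinom(60, 2, 0.4))
  g <- toy_geno(cbind(a = base, b = base, c = other))
  g$geno[5, "Cyn_1_2000"] <- NA        # marker b, perfect LD with a
  out <- impute_missing(g)
  expect_identical(out$geno[5, "Cyn_1_2000"], base[5])
  expect_false(anyNA(out$geno))
  # observed calls are untouched
  obs <- !is.na(g$geno)
  expect_identical(out$geno[obs], g$geno[obs])
})

test_that("imputation without missing values is the identity", {
  g <- toy_geno(matrix(rep(0:2, 20), 10, 6))
  expect_identical(impute_missing(g), g)
})

test_that("imputation is complete, in-range, and beats the modal baseline", {
  sim <- simulate_population(sim_config(
    n_families = 8, n_offspring_per_family = 25,
    marker_counts = c("1" = 120, Z = 4), seed = 15))
  truth <- filter_markers(sim$geno)$geno
  masked <- inject_missingness(truth, 0.05, seed = 16)
  mask <- is.na(masked$geno) & !is.na(truth$geno)
  out <- impute_missing(masked)
  expect_false(anyNA(out$geno))
  expect_true(all(out$geno %in% 0:2))
  acc <- mean(out$geno[mask] == truth$geno[mask])
  modal <- apply(masked$geno, 2, function(col) {
    tb <- tabulate(col + 1L, nbins = 3L)
    which.max(tb) - 1L
  })
  modal_mat <- matrix(modal, nrow(truth$geno), ncol(truth$geno),
                      byrow = TRUE)
  acc_modal <- mean(modal_mat[mask] == truth$geno[mask])
  expect_gt(acc, acc_modal)
})
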
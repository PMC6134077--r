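#' Run the full analysis pipeline on a simulated population
#'
#' Chains the stages simulate -> QC -> GRM -> genome scan -> two-locus
#' interaction (-> haplotype bridge) with a single seed, writing all
#' artifacts plus a JSON run manifest under `out_dir`. Configuration can
#' be a [sim_config()], a list of `sim_config()` arguments, or the path
#' to a YAML file holding such a list; `...` overrides individual
#' entries.
#'
#' Outputs: the three-file population layout (`pop_*.tsv`), the filtered
#' and imputed genotypes (`imputed_geno.tsv`, `imputed_map.tsv`),
#' `K.tsv`, `scan.tsv` (marker, chrom, pos, b, stat, p, flag,
#' above_threshold), `interaction.tsv`, and `manifest.json` (seed,
#' parameters, per-stage record counts).
#'
#' @param config `sim_config`, list, or YAML path.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed overriding the config seed.
#' @param condition_locus1 Condition the scan cohort on carrying the
#'   unfavorable allele at the first causal locus (default `TRUE`,
#'   mirroring the Z^T W study design).
#' @param alpha Genome-wide error rate for the scan threshold.
#' @param ... Overrides for individual `sim_config()` arguments.
#' @return Invisibly, a list with `sim`, `scan`, `interaction`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = NULL,
                         condition_locus1 = TRUE, alpha = 0.05, ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "sim_config")) {
    stopifnot(is.list(config))
    config <- do.call(sim_config, config)
  }
  dots <- list(...)
  if (length(dots) || !is.null(seed)) {
    args <- unclass(config)
    args$chrom_lengths_bp <- NULL      # re-derived from defaults
    args$marker_scale <- NULL
    args[names(dots)] <- dots
    if (!is.null(seed)) args$seed <- seed
    config <- do.call(sim_config, args)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "zwgwas",
                   version = as.character(utils::packageVersion("zwgwas")),
                   seed = config$seed, alpha = alpha, stages = list())
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, n) {
    message(sprintf("[%s] done (%d records, %.1fs)", name, n,
                    proc.time()[["elapsed"]] - t0))
    manifest$stages[[name]] <<- list(records = n)
  }

  sim <- simulate_population(config)
  write_population(sim, file.path(out_dir, "pop"))
  stage("simulate", nrow(sim$pheno))

  fl <- filter_markers(sim$geno)
  imp <- impute_missing(fl$geno)
  write_genotypes(imp, file.path(out_dir, "imputed_geno.tsv"),
                  file.path(out_dir, "imputed_map.tsv"))
  stage("qc", ncol(imp$geno))

  grm <- build_grm(imp)
  write_grm(grm, file.path(out_dir, "K.tsv"))
  stage("grm", nrow(grm$K))

  # cohort conditioning uses the pre-QC matrix: the conditioning locus is
  # near-fixed in the cohort and may itself fail the MAF filter
  pheno_run <- sim$pheno
  if (condition_locus1) {
    mk <- sprintf("Cyn_Z_%d", config$causal_pos[1])
    j <- match(mk, sim$geno$map$marker)
    carriers <- rownames(sim$geno$geno)[which(sim$geno$geno[, j] >= 1L)]
    pheno_run <- sim$pheno[sim$pheno$id %in% carriers, ]
  }
  scan <- run_gwas(imp, pheno_run, qc = TRUE, alpha = alpha)
  utils::write.table(scan$results, file.path(out_dir, "scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage("gwas", nrow(scan$results))

  tab <- build_two_locus_table(sim$truth$locus1_allele,
                               sim$truth$locus2_genotype,
                               ifelse(sim$pheno$reversal[
                                 match(sim$truth$id, sim$pheno$id)] == 1,
                                 "pseudomale", "female"))
  ftab <- as.data.frame(as.table(tab$counts))
  utils::write.table(ftab, file.path(out_dir, "interaction.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage("interaction", tab$n)

  hap_calls <- haplotype_to_g2_allele(
    ifelse(grepl("A", sim$truth$locus2_genotype), "hap1", "hap2"))
  stage("haplotype", length(hap_calls))

  manifest$threshold <- scan$threshold
  manifest$peak <- list(marker = scan$peak$marker, p = scan$peak$p)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, scan = scan, interaction = tab,
                 manifest = manifest))
}
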
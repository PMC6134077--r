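# Dmrt1 polymorphism panel and haplotype matching.
#
# The panel covers the second exon through third intron of Dmrt1 on the
# Z chromosome: nine SNPs and two indels whose joint alleles form two
# haplotypes in tongue sole. Positions decrease through the gene because
# Dmrt1 is oriented opposite to the coordinate order; sites are stored as
# characterized and sorted by position for lookup. Indels are literal
# strings, with "/" marking the absent allele.

#' Default Dmrt1 polymorphism panel
#'
#' The 11-site panel (9 SNPs + 2 indels) spanning exon 2 to intron 3 of
#' Dmrt1, including the reversal-associated site at 8,564,889 bp with
#' alleles A (haplotype 1) / G (haplotype 2).
#'
#' @return Data frame of class `dmrt1_panel` with columns `pos`,
#'   `region`, `hap1`, `hap2`, sorted by position.
#' @export
dmrt1_panel <- function() {
  panel <- data.frame(
    pos = c(8566940L, 8566916L, 8565228L, 8565219L, 8565217L, 8565187L,
            8565031L, 8565018L, 8565016L, 8565011L, 8564889L),
    region = c("Exon 2", "Exon 2", "Intron 2", "Intron 2", "Intron 2",
               "Intron 2", "Intron 3", "Intron 3", "Intron 3",
               "Intron 3", "Intron 3"),
    hap1 = c("A", "T", "G", "ACTAAAA", "A", "C", "C", "A", "/", "T", "A"),
    hap2 = c("C", "C", "T", "/", "G", "G", "T", "C", "T", "C", "G"),
    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(panel$pos), all(panel$hap1 != panel$hap2))
  panel <- panel[order(panel$pos), ]
  rownames(panel) <- NULL
  class(panel) <- c("dmrt1_panel", "data.frame")
  panel
}

#' Match an observed allele vector against the haplotype panel
#'
#' Classifies an observed set of alleles at panel sites as haplotype 1,
#' haplotype 2, or recombinant/unknown, with per-site agreement. An
#' allele matching neither haplotype makes the call `"unknown"`.
#'
#' @param observed Named character vector, names = panel positions (bp),
#'   values = observed alleles (indels as literal strings, `"/"` for the
#'   deletion allele). Must cover at least one panel site.
#' @param panel A [dmrt1_panel()] (default) or compatible data frame.
#' @return List of class `hap_match`: `call` (`"hap1"`, `"hap2"`,
#'   `"recombinant"` or `"unknown"`), `agreement` (per covered site, the
#'   matching haplotype or `"none"`), `discordant` (positions breaking
#'   the called haplotype).
#' @export
match_haplotype <- function(observed, panel = dmrt1_panel()) {
  pos <- as.integer(names(observed))
  idx <- match(pos, panel$pos)
  keep <- !is.na(idx)
  if (!any(keep)) stop("observed vector covers no panel site")
  obs <- as.character(observed)[keep]
  idx <- idx[keep]
  m1 <- obs == panel$hap1[idx]
  m2 <- obs == panel$hap2[idx]
  agreement <- ifelse(m1, "hap1", ifelse(m2, "hap2", "none"))
  names(agreement) <- panel$pos[idx]
  call <- if (any(agreement == "none")) "unknown"
  else if (all(m1)) "hap1"
  else if (all(m2)) "hap2"
  else "recombinant"
  discordant <- switch(call,
    hap1 = integer(0), hap2 = integer(0),
    recombinant = panel$pos[idx][if (sum(m1) >= sum(m2)) !m1 else !m2],
    unknown = panel$pos[idx][agreement == "none"])
  structure(list(call = call, agreement = agreement,
                 discordant = discordant), class = "hap_match")
}

#' @export
print.hap_match <- function(x, ...) {
  cat("haplotype call:", x$call, "\n")
  if (length(x$discordant))
    cat("discordant sites:", paste(x$discordant, collapse = ", "), "\n")
  invisible(x)
}

#' Count distinct panel-consistent haplotype classes
#'
#' @param vectors List of named allele vectors, each complete over the
#'   panel (see [match_haplotype()]).
#' @param panel A [dmrt1_panel()].
#' @return Number of distinct panel-consistent classes (`hap1`/`hap2`)
#'   observed among the inputs.
#' @export
count_haplotypes <- function(vectors, panel = dmrt1_panel()) {
  if (!length(vectors)) return(0L)
  calls <- vapply(vectors, function(v) match_haplotype(v, panel)$call,
                  character(1))
  length(unique(calls[calls %in% c("hap1", "hap2")]))
}

#' Second-locus allele implied by a Dmrt1 haplotype
#'
#' Haplotype 1 carries the unfavorable A at the reversal-associated site
#' 8,564,889; haplotype 2 carries G. Convenience bridge to
#' [classify_reversal()].
#'
#' @param call `"hap1"` or `"hap2"` (vectorized).
#' @return `"A"` or `"G"`.
#' @export
haplotype_to_g2_allele <- function(call) {
  stopifnot(all(call %in% c("hap1", "hap2")))
  ifelse(call == "hap1", "A", "G")
}
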
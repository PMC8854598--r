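#' Worked example: two-sample MR of Cer22:0 on type 2 diabetes risk
#'
#' Recomputes the published single-instrument Mendelian-randomization
#' arithmetic for the very-long-chain ceramide Cer22:0 from the bundled
#' summary-statistics tables.  The instrument is chosen as the discovery
#' SNP with the smallest p-value among those available in every external
#' dataset (the stronger rs686548 signal is skipped because it cannot be
#' looked up everywhere, leaving rs680379).  The SNP-outcome effect is not
#' published directly; it is implied by the replication cohort's published
#' Wald ratio (`beta_outcome = WR * beta_exposure` on that cohort's allele
#' coding) and held fixed, after which the discovery-cohort and
#' second-replication Wald ratios follow by allele harmonization and
#' division.
#'
#' @param threshold Suggestive significance threshold for instrument
#'   selection (default 1e-5).
#' @return Tibble with one row per exposure cohort: cohort, snp,
#'   beta_exposure, wr, se, p.
#' @export
#' @examples
#' mr_worked_example()
mr_worked_example <- function(threshold = 1e-5) {
  path <- function(f) system.file("extdata", f, package = "lipidnet",
                                  mustWork = TRUE)
  epic <- read_sumstats(path("cer22_exposure_epic.tsv"))
  eurospan <- read_sumstats(path("cer22_exposure_eurospan.tsv"))
  fhsoc <- read_sumstats(path("cer22_exposure_fhsoc.tsv"))
  avail <- readr::read_tsv(path("cer22_availability.tsv"), comment = "#",
                           show_col_types = FALSE)$snp
  anchor <- readr::read_tsv(path("cer22_replication_anchor.tsv"),
                            comment = "#", show_col_types = FALSE)

  inst <- select_instrument(epic, threshold = threshold,
                            availability = avail)
  if (!nrow(inst)) abort("no instrument qualifies")
  snp <- inst$snp

  # SNP-outcome effect implied by the anchor cohort's published Wald ratio,
  # expressed on the anchor cohort's allele coding
  anchor_exp <- dplyr::filter(eurospan, .data$snp == !!snp)
  outcome <- tibble(
    snp = snp,
    effect_allele = anchor_exp$effect_allele,
    other_allele = anchor_exp$other_allele,
    beta = anchor$wr * anchor_exp$beta,
    se = anchor$se * anchor_exp$beta
  )

  cohorts <- list(`EPIC-Potsdam` = epic, EUROSPAN = eurospan, FHSOC = fhsoc)
  purrr::map_dfr(names(cohorts), function(ch) {
    expo <- dplyr::filter(cohorts[[ch]], .data$snp == !!snp)
    res <- wald_ratio(harmonize_sumstats(expo, outcome))
    tibble(cohort = ch, snp = snp, beta_exposure = expo$beta,
           wr = res$wr, se = res$se, p = res$p)
  })
}
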
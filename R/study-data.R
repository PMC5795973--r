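#' Amplification efficiencies of the study's primer panel
#'
#' Per-gene qPCR amplification factors of the 13 candidate genes and the
#' two normalisers (ACTB, PPIA) of the motivating feeding trial,
#' converted from the percentage convention (`E = 1 + pct/100`).
#'
#' @return Named numeric vector of amplification factors.
#' @export
study_efficiencies <- function() {
  read_efficiency_table(system.file("extdata", "qpcr_efficiencies.csv",
                                    package = "qpcrmix", mustWork = TRUE))
}

#' Target and reference genes of the study panel
#'
#' @return List with `targets` (13 candidate genes) and `references`
#'   (`ACTB`, `PPIA`).
#' @export
study_gene_panel <- function() {
  genes <- names(study_efficiencies())
  refs <- c("ACTB", "PPIA")
  list(targets = setdiff(genes, refs), references = refs)
}

#' Published least-squares means of the adipose fatty-acid profiles
#'
#' The per-diet and per-breed LS-mean columns (inner layer) of the
#' motivating trial's composition tables, with SEMs and printed
#' p-values, for the subcutaneous backfat or ham fat depot.
#'
#' @param depot `"backfat"` or `"ham"`.
#' @return data.frame with `fatty_acid`, `type` (fa/index/ratio), and
#'   mean/SEM/p columns per diet and breed level.
#' @export
study_fa_lsmeans <- function(depot = c("backfat", "ham")) {
  depot <- match.arg(depot)
  read.csv(system.file("extdata", paste0("fa_lsmeans_", depot, ".csv"),
                       package = "qpcrmix", mustWork = TRUE),
           stringsAsFactors = FALSE, check.names = FALSE)
}

#' Published fold changes of the candidate-gene main effects
#'
#' The printed fold change, asymmetric 95% interval and p-values per
#' gene and main effect (breed, status, diet) from the motivating trial.
#' p-values printed as "<.0001" are stored as 0.0001.
#'
#' @return data.frame with `gene`, `effect`, `fold_change`, `ci_low`,
#'   `ci_high`, `p_value`, `adjusted_p_value`.
#' @export
study_expression_effects <- function() {
  read.csv(system.file("extdata", "expression_main_effects.csv",
                       package = "qpcrmix", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' Fatty-acid content of the experimental diets
#'
#' Main fatty acids of the two feeds (g/kg as fed): the carbohydrate
#' (CH) control and the high-oleic (HO) sunflower-oil feed.  Used as
#' simulator context, not modelled.
#'
#' @return data.frame with `fatty_acid`, `CH`, `HO`.
#' @export
study_diet_fa <- function() {
  read.csv(system.file("extdata", "diet_fa_content.csv",
                       package = "qpcrmix", mustWork = TRUE),
           stringsAsFactors = FALSE, check.names = FALSE)
}
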
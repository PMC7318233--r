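#' ICD-10 depressive symptom items
#'
#' The ten ICD-10 depressive-symptom indicators in the NICE listing order
#' used throughout the package: persistent sadness or low mood (SAD), loss
#' of interest or pleasure (INT), fatigue or low energy (FAT), disturbed
#' sleep (SLE), poor concentration or indecisiveness (CON), low
#' self-confidence (SEL), decreased or increased appetite (APE), suicidal
#' thoughts or acts (SUI), agitated or slowed movements (AGI), and guilt or
#' self-blame (GUI). This fixed order makes all package outputs
#' deterministic.
#'
#' @return A tibble with columns `code` and `symptom`.
#' @export
#' @examples
#' icd10_items()
icd10_items <- function() {
  tibble::tibble(
    code = c("SAD", "INT", "FAT", "SLE", "CON",
             "SEL", "APE", "SUI", "AGI", "GUI"),
    symptom = c(
      "Persistent sadness or low mood",
      "Loss of interest or pleasure",
      "Fatigue or low energy",
      "Disturbed sleep",
      "Poor concentration or indecisiveness",
      "Low self-confidence",
      "Decreased or increased appetite",
      "Suicidal thoughts or acts",
      "Agitated or slowed movements",
      "Guilt or self-blame"
    )
  )
}

#' Published REAP-AD symptom presence counts
#'
#' Per-item counts of symptom presence in the REAP-AD depression cohort
#' (n = 1174), overall and split by UN geographic region (East Asia n = 643;
#' South or Southeast Asia n = 531) and World Bank income class
#' (high-income n = 441; middle-income n = 733), together with the
#' percentages as printed in the source report. These counts are the only
#' part of the original data that is public; the package uses them as
#' prevalence targets for the synthetic cohort generator and as an
#' arithmetic check on its reporting layer.
#'
#' @return A tibble with columns `cohort`, `cohort_n`, `code`, `count`,
#'   and `percent_printed`.
#' @export
#' @examples
#' reap_symptom_rates()
reap_symptom_rates <- function() {
  codes <- icd10_items()$code
  cohorts <- tibble::tribble(
    ~cohort,           ~cohort_n,
    "overall",          1174L,
    "East",              643L,
    "SouthSoutheast",    531L,
    "HIC",               441L,
    "MIC",               733L
  )
  counts <- list(
    overall        = c(859L, 623L, 536L, 748L, 348L, 268L, 384L, 268L, 267L, 185L),
    East           = c(484L, 353L, 310L, 406L, 143L, 157L, 215L, 158L, 160L, 122L),
    SouthSoutheast = c(375L, 270L, 226L, 342L, 205L, 111L, 169L, 110L, 107L,  63L),
    HIC            = c(341L, 209L, 206L, 265L,  89L,  98L, 120L,  87L, 141L,  61L),
    MIC            = c(518L, 414L, 330L, 483L, 259L, 170L, 264L, 181L, 126L, 124L)
  )
  printed <- list(
    overall        = c(73.2, 53.1, 45.7, 63.7, 29.6, 22.8, 32.7, 22.8, 22.7, 15.8),
    East           = c(75.3, 54.9, 48.2, 63.1, 22.2, 24.4, 33.4, 24.6, 24.9, 19.0),
    SouthSoutheast = c(70.6, 50.8, 42.6, 64.4, 38.6, 20.9, 31.8, 20.7, 20.2, 11.9),
    HIC            = c(77.3, 47.4, 46.7, 60.1, 20.2, 22.2, 27.2, 19.7, 32.0, 13.8),
    MIC            = c(70.7, 56.5, 45.0, 65.9, 35.3, 23.2, 36.0, 24.7, 17.2, 16.9)
  )
  purrr::map2_dfr(cohorts$cohort, cohorts$cohort_n, function(ch, n) {
    tibble::tibble(
      cohort = ch, cohort_n = n, code = codes,
      count = counts[[ch]], percent_printed = printed[[ch]]
    )
  })
}

#' Published REAP-AD network edge counts
#'
#' Number of nonzero edges (of the 45 possible among 10 symptoms) reported
#' for each estimated network in the REAP-AD study, with the printed
#' percentages. Used to validate the package's edge-counting arithmetic.
#'
#' @return A tibble with columns `cohort`, `n`, `nonzero`, `possible`, and
#'   `percent_printed`.
#' @export
reap_edge_counts <- function() {
  tibble::tribble(
    ~cohort,          ~n,    ~nonzero, ~possible, ~percent_printed,
    "overall",        1174L, 29L,      45L,       64.4,
    "East",           643L,  34L,      45L,       75.6,
    "SouthSoutheast", 531L,  33L,      45L,       73.3,
    "HIC",            441L,  22L,      45L,       48.9,
    "MIC",            733L,  29L,      45L,       64.4
  )
}

# region x income cell sizes implied by the published per-country counts:
# East = China 240 + Hong Kong 38 + Japan 142 + Korea 173 + Taiwan 50,
# high income = Hong Kong, Japan, Korea, Singapore (38), Taiwan.
reap_subgroup_cells <- function() {
  tibble::tribble(
    ~region,          ~income, ~n,
    "East",           "HIC",   403L,
    "East",           "MIC",   240L,
    "SouthSoutheast", "HIC",    38L,
    "SouthSoutheast", "MIC",   493L
  )
}
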
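#' Reference cohort VDJ sequencing summary
#'
#' Published per-sample clonality summary for a cohort of 14 matched
#' diagnosis-relapse DLBCL patients (34 tumor samples, 2 without evaluable
#' libraries): the number of unique VDJ rearrangements observed by deep
#' amplicon sequencing and the same number normalised per 10^3 mapped
#' paired-end reads. Shipped as plain TSV; used as the reference point for
#' the cohort-level clonal-heterogeneity statistics (mean / min / max unique
#' rearrangements per 10^3 mapped reads).
#'
#' @return data.frame with columns `pair`, `sample_id`, `phase`
#'   (`diagnosis` / `relapse` / `progression`), `unique_rearrangements` and
#'   `unique_per_1e3` (NA where no library was evaluable).
#' @examples
#' cohort <- vhdjh_reference_summary()
#' mean(cohort$unique_per_1e3, na.rm = TRUE)
#' @export
vhdjh_reference_summary <- function() {
  path <- system.file("extdata", "vhdjh_cohort_summary.tsv",
                      package = "clonaltrace", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("integer", "character", "character",
                                   "integer", "numeric"))
}

#' Cohort clonal-heterogeneity statistics
#'
#' Mean, minimum and maximum of the unique-rearrangements-per-10^3-mapped-
#' reads column over the evaluable samples of a cohort summary, each rounded
#' to one decimal as reported.
#'
#' @param cohort A cohort summary data.frame, by default
#'   [vhdjh_reference_summary()].
#' @return Named numeric vector `mean`, `min`, `max`.
#' @export
cohort_heterogeneity_stats <- function(cohort = vhdjh_reference_summary()) {
  x <- cohort$unique_per_1e3
  x <- x[!is.na(x)]
  c(mean = round(mean(x), 1), min = round(min(x), 1), max = round(max(x), 1))
}
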
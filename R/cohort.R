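#' Summary statistics of a cohort column
#'
#' Mean, median, range and the two-sided 95% confidence half-width
#' (Student t on `n - 1` degrees of freedom) of one numeric column,
#' optionally per group.  The confidence interval is reported as `NA` for a
#' single record rather than an error.
#'
#' @param data cohort tibble (e.g. from [ptv_coverage_cohort()] or the
#'   `cohort` element of a `course_report`).
#' @param col column to summarise (tidy-eval).
#' @param by optional grouping column (tidy-eval).
#' @return tibble with `n`, `mean`, `median`, `min`, `max`, `sd`,
#'   `ci95_half`.
#' @export
summarize_cohort <- function(data, col, by = NULL) {
  one <- function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    tibble::tibble(n = n,
                   mean = if (n) mean(v) else NA_real_,
                   median = if (n) stats::median(v) else NA_real_,
                   min = if (n) min(v) else NA_real_,
                   max = if (n) max(v) else NA_real_,
                   sd = if (n > 1) stats::sd(v) else NA_real_,
                   ci95_half = if (n > 1)
                     stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n)
                   else NA_real_)
  }
  if (rlang::quo_is_null(rlang::enquo(by)))
    return(one(dplyr::pull(data, {{ col }})))
  data |>
    dplyr::group_by({{ by }}) |>
    dplyr::group_modify(~ one(dplyr::pull(.x, {{ col }}))) |>
    dplyr::ungroup()
}

#' Independent two-sample t-test for equality of means (pooled variance)
#'
#' Student's two-sample t with pooled variance and a two-tailed p-value.
#' A Welch variant is available for sensitivity checks.
#'
#' @param group_a,group_b numeric vectors, each with at least two values.
#' @param welch use Welch's unequal-variance form instead of pooling.
#' @return tibble with `t`, `df`, `p`.
#' @export
two_sample_t <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("both groups need n >= 2", call. = FALSE)
  ht <- stats::t.test(group_a, group_b, var.equal = !welch)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
}

cohort_csv <- function(name) {
  path <- system.file("extdata", name, package = "rtflow", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Example cohort: flagged target-coverage records
#'
#' Transcription of a reference retrospective head-and-neck series: the
#' planning-target volumes whose projected cumulative V95 fell below the 95%
#' warning level by end of treatment, with initial (plan) and final coverage,
#' their difference, the warning-crossing fraction and the cumulative
#' delivered dose at that fraction.
#'
#' @return tibble with columns `study`, `target`, `initial_v95`, `final_v95`,
#'   `delta_v95`, `fx_warning`, `cumulative_dose_gy`.
#' @export
ptv_coverage_cohort <- function() cohort_csv("hn_ptv_v95_cohort.csv")

#' Example cohort: flagged parotid mean-dose records
#'
#' Transcription of the parotid glands flagged in the same reference series
#' for exceeding their mean-dose warning endpoint by end of treatment.  The
#' printed source values are preserved verbatim, including one row whose
#' printed delta is inconsistent with its initial/final values.  `role`
#' distinguishes spared ipsilateral glands (20/21 Gy rules) from spared
#' contralateral glands (26 Gy rule); `fx_de0`/`fx_de10` are the
#' threshold-crossing fractions (`NA` where the adaptation level was never
#' reached).
#'
#' @return tibble with columns `study`, `sib_doses`, `initial_dmean_gy`,
#'   `final_dmean_gy`, `delta_dmean_gy`, `laterality`, `role`, `de0_gy`,
#'   `fx_de0`, `cumdose_de0_gy`, `fx_de10`, `cumdose_de10_gy`.
#' @export
parotid_dmean_cohort <- function() cohort_csv("hn_parotid_dmean_cohort.csv")
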
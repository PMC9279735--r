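#' Metrics monitored for each endpoint, computed on the plan dose
#'
#' @param bundle plan bundle (`image`, `plan`, `dose`).
#' @return named list per structure with the standard metric values computed
#'   from the planned dose distribution.
#' @export
plan_metrics <- function(bundle) {
  vv <- voxel_volume_cc(bundle$dose)
  out <- list()
  for (s in bundle$plan$structures) {
    doses <- bundle$dose$voxels[s$mask]
    if (!length(doses)) next
    # hotspot is judged against the plan's highest prescription: in an SIB
    # plan the boost plateau legitimately sits inside lower-level targets
    ref <- suppressWarnings(max(bundle$plan$prescriptions))
    out[[s$name]] <- list(
      Dmean = mean(doses), Dmax = max(doses),
      D1cc = suppressWarnings(extract_metric(doses, "D1cc", voxel_volume_cc = vv)),
      V95 = if (!is.na(s$prescription))
        extract_metric(doses, "V95", reference = s$prescription) else NA_real_,
      hotspot = extract_metric(doses, "hotspot", reference = ref))
  }
  out
}

endpoint_value <- function(doses, spec, voxel_volume_cc) {
  extract_metric(doses, spec$metric, reference = spec$reference,
                 voxel_volume_cc = voxel_volume_cc)
}

#' Process a full treatment course
#'
#' Runs the complete per-fraction chain — deformable registration, structure
#' dose mapping, dose accumulation with projection, DVH metric extraction,
#' endpoint evaluation, trend forecasting and registration QA — over an
#' ordered series of daily volumes, and assembles the end-of-course records.
#' A fraction whose processing fails hard is marked failed and the course
#' continues, mirroring the clinical need to keep processing.
#'
#' @param bundle plan bundle (`image`, `plan`, `dose` on a common grid), e.g.
#'   from [read_plan_bundle()] or [make_plan_phantom()].
#' @param daily_volumes ordered list of daily [image_volume()]s (fractions
#'   `1..k`).
#' @param endpoints endpoint tibble; built from `config` when `NULL`.
#' @param params a [reg_params()].
#' @param config OAR endpoint configuration for [build_endpoint_set()].
#' @param qa_thresholds thresholds passed to [structure_qa()].
#' @param dose_per_fraction Gy per fraction used for cumulative-dose columns;
#'   defaults to the highest prescription divided by the fraction count.
#' @param dvf_list optional list of precomputed deformation fields (one per
#'   fraction), bypassing registration — used to replay a course under
#'   ground-truth fields.
#' @return a `course_report`: tibbles `fractions` (per-fraction DP_day/DP_sum
#'   per endpoint), `qa`, `predictions`, `violations`, `cohort` (one record
#'   per endpoint with initial/final/delta and crossing fractions), plus the
#'   endpoint set, plan metric list and failed-fraction indices.
#' @export
process_course <- function(bundle, daily_volumes, endpoints = NULL,
                           params = reg_params(), config = hn_endpoint_config(),
                           qa_thresholds = list(ncc = 0.85, displacement_mm = 7),
                           dose_per_fraction = NULL, dvf_list = NULL) {
  plan <- bundle$plan
  pm <- plan_metrics(bundle)
  if (is.null(endpoints))
    endpoints <- build_endpoint_set(plan, pm, config)
  N <- plan$total_fractions
  if (is.null(dose_per_fraction))
    dose_per_fraction <- max(plan$prescriptions) / N
  vv <- voxel_volume_cc(bundle$dose)
  monitored <- intersect(names(plan$structures), unique(endpoints$structure))
  samples <- stats::setNames(vector("list", length(monitored)), monitored)
  frac_rows <- list(); qa_rows <- list(); pred_rows <- list()
  failed <- integer(0)
  n_frac <- length(daily_volumes)

  for (f in seq_len(n_frac)) {
    res <- tryCatch({
      dvf <- if (!is.null(dvf_list)) dvf_list[[f]]
             else register(bundle$image, daily_volumes[[f]], params)
      for (nm in monitored)
        samples[[nm]][[length(samples[[nm]]) + 1]] <-
          daily_dose(bundle$dose, dvf, plan$structures[[nm]])
      k <- length(samples[[monitored[1]]])
      for (nm in monitored) {
        acc <- accumulate(samples[[nm]], N)
        specs <- endpoints[endpoints$structure == nm, ]
        for (i in seq_len(nrow(specs))) {
          spec <- specs[i, ]
          frac_rows[[length(frac_rows) + 1]] <- tibble::tibble(
            fraction = f, structure = nm, metric = spec$metric,
            dp_day = endpoint_value(acc$d_day, spec, vv),
            dp_sum = endpoint_value(acc$d_sum, spec, vv),
            unreliable = samples[[nm]][[k]]$unreliable)
        }
        qa_rows[[length(qa_rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(fraction = f),
          structure_qa(bundle$image, daily_volumes[[f]], dvf,
                       plan$structures[[nm]], thresholds = qa_thresholds))
      }
      TRUE
    }, error = function(e) {
      warning("fraction ", f, " failed: ", conditionMessage(e), call. = FALSE)
      FALSE
    })
    if (!isTRUE(res)) failed <- c(failed, f)
  }

  fractions <- dplyr::bind_rows(frac_rows)
  qa <- dplyr::bind_rows(qa_rows)

  # trend forecasting: refit on all processed fractions at every step >= 5
  if (nrow(fractions)) {
    by_ep <- dplyr::group_split(dplyr::group_by(fractions, .data$structure,
                                                .data$metric))
    for (tr in by_ep) {
      tr <- dplyr::arrange(tr, .data$fraction)
      for (k in seq_len(nrow(tr))) {
        if (k < 5) next
        fit <- fit_predict(tr$dp_sum[seq_len(k)], tr$fraction[seq_len(k)])
        pred_rows[[length(pred_rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(anchor_fraction = tr$fraction[k],
                         structure = tr$structure[1], metric = tr$metric[1]),
          fit$predictions)
      }
    }
  }
  predictions <- dplyr::bind_rows(pred_rows)

  viol_rows <- list(); cohort_rows <- list()
  for (i in seq_len(nrow(endpoints))) {
    spec <- endpoints[i, ]
    tr <- fractions[fractions$structure == spec$structure &
                      fractions$metric == spec$metric, ]
    if (!nrow(tr)) next
    tr <- dplyr::arrange(tr, .data$fraction)
    ev <- detect_crossings(tr$dp_sum, spec, dose_per_fraction)
    viol_rows[[length(viol_rows) + 1]] <- ev
    initial <- pm[[spec$structure]][[spec$metric]]
    final <- tr$dp_sum[nrow(tr)]
    fx_w <- ev$fx[ev$level == "warning"]
    fx_a <- ev$fx[ev$level == "adaptation"]
    cohort_rows[[length(cohort_rows) + 1]] <- tibble::tibble(
      structure = spec$structure, metric = spec$metric,
      initial = initial, final = final, delta = final - initial,
      de0 = spec$warning, de10 = spec$adaptation,
      fx_warning = if (length(fx_w)) fx_w[1] else NA_integer_,
      fx_adaptation = if (length(fx_a)) fx_a[1] else NA_integer_,
      eot_violation = any(ev$eot_violation))
  }

  structure(list(fractions = fractions, qa = qa, predictions = predictions,
                 violations = dplyr::bind_rows(viol_rows),
                 cohort = dplyr::bind_rows(cohort_rows),
                 endpoints = endpoints, plan_metrics = pm,
                 dose_per_fraction = dose_per_fraction,
                 failed_fractions = failed),
            class = "course_report")
}

#' @export
print.course_report <- function(x, ...) {
  cat("<course_report>", max(x$fractions$fraction, 0), "fractions,",
      nrow(x$endpoints), "endpoints\n")
  nv <- sum(x$cohort$eot_violation)
  cat("  end-of-treatment violations:", nv, "\n")
  if (length(x$failed_fractions))
    cat("  failed fractions:", paste(x$failed_fractions, collapse = ", "), "\n")
  flg <- sum(x$qa$flagged)
  cat("  QA flags:", flg, "\n")
  invisible(x)
}

#' Write / read a course report as JSON
#'
#' Serialises the tibbles of a `course_report` (not the raw volumes);
#' re-reading reproduces the records exactly.
#'
#' @param report a `course_report`.
#' @param path JSON file.
#' @export
write_course_report <- function(report, path) {
  payload <- list(fractions = report$fractions, qa = report$qa,
                  predictions = report$predictions,
                  violations = report$violations, cohort = report$cohort,
                  endpoints = report$endpoints,
                  dose_per_fraction = report$dose_per_fraction,
                  failed_fractions = report$failed_fractions)
  jsonlite::write_json(payload, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_course_report
#' @export
read_course_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("fractions", "qa", "predictions", "violations", "cohort",
               "endpoints"))
    p[[nm]] <- tibble::as_tibble(as.data.frame(p[[nm]], stringsAsFactors = FALSE))
  # all-NA integer columns deserialise as logical; restore their types
  for (cn in c("fx_warning", "fx_adaptation"))
    if (cn %in% names(p$cohort)) p$cohort[[cn]] <- as.integer(p$cohort[[cn]])
  if ("fx" %in% names(p$violations))
    p$violations$fx <- as.integer(p$violations$fx)
  p$failed_fractions <- as.integer(unlist(p$failed_fractions))
  structure(p, class = "course_report")
}

#' Plot every monitored DP_sum trajectory of a course report
#' @param object a `course_report`.
#' @param ... ignored.
#' @export
autoplot.course_report <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$fractions, c("dp_day", "dp_sum"),
                             names_to = "flavor", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fraction, y = .data$value,
                                    linetype = .data$flavor)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ structure + metric, scales = "free_y") +
    ggplot2::labs(x = "Fraction", y = "DP value") +
    ggplot2::theme_minimal()
}
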
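#' Cumulative dose-volume histogram
#'
#' The cumulative ("volume receiving at least D") histogram of a structure's
#' per-voxel doses, as percent of structure volume over uniform dose bins.
#' The first bin edge is 0 Gy (so the curve starts at 100%), the curve is
#' non-increasing, and the last bin edge exceeds the maximum sampled dose.
#'
#' @param doses numeric vector of per-voxel doses in Gy (or a
#'   `structure_dose_samples` / `accumulated_dose` object, in which case
#'   `which` selects the dose vector).
#' @param bin_width bin width in Gy (default 0.1).
#' @param flavor one of `"plan"`, `"day"`, `"sum"` — recorded on the curve.
#' @param which for `accumulated_dose` input: `"sum"` or `"day"`.
#' @return a tibble of class `dvh_curve` with columns `dose_gy` (left bin
#'   edge) and `volume_pct`.
#' @export
cumulative_dvh <- function(doses, bin_width = 0.1, flavor = c("sum", "day", "plan"),
                           which = NULL) {
  flavor <- match.arg(flavor)
  if (inherits(doses, "structure_dose_samples")) doses <- doses$dose_full_course
  if (inherits(doses, "accumulated_dose"))
    doses <- if (identical(which, "day")) doses$d_day else doses$d_sum
  doses <- as.numeric(doses)
  if (!length(doses)) stop("cannot build a DVH from zero dose samples", call. = FALSE)
  stopifnot(bin_width > 0, all(is.finite(doses)))
  edges <- seq(0, (floor(max(doses) / bin_width) + 1) * bin_width, by = bin_width)
  vol <- vapply(edges, function(e) mean(doses >= e) * 100, 0)
  out <- tibble::tibble(dose_gy = edges, volume_pct = vol)
  class(out) <- c("dvh_curve", class(out))
  attr(out, "flavor") <- flavor
  out
}

#' Extract a dosimetric parameter from per-voxel doses
#'
#' Metrics are computed from the raw samples (not from a binned DVH):
#' * `V95` — percent of volume receiving at least 95% of the reference
#'   prescription;
#' * `Dmean` — volume-weighted mean dose (Gy);
#' * `Dmax` — maximum voxel dose (Gy);
#' * `D1cc` — minimum dose of the hottest 1 cm^3 (sorted-voxel rule with
#'   partial volumes); on structures smaller than 1 cm^3 this degrades to the
#'   minimum dose, with a warning;
#' * `hotspot` — `Dmax` as percent of the reference prescription.
#'
#' @param doses numeric vector of per-voxel doses in Gy, or a
#'   `structure_dose_samples` / `accumulated_dose` object.
#' @param kind one of `"V95"`, `"Dmean"`, `"Dmax"`, `"D1cc"`, `"hotspot"`.
#' @param reference prescription in Gy; required for `V95` and `hotspot`.
#' @param voxel_volume_cc voxel volume in cm^3 (taken from sample objects when
#'   available); required for `D1cc`.
#' @param which for `accumulated_dose` input: `"sum"` or `"day"`.
#' @return the metric value: percent for `V95`/`hotspot`, Gy otherwise.
#' @export
extract_metric <- function(doses, kind = c("V95", "Dmean", "Dmax", "D1cc", "hotspot"),
                           reference = NULL, voxel_volume_cc = NULL, which = NULL) {
  kind <- match.arg(kind)
  if (inherits(doses, "structure_dose_samples")) {
    voxel_volume_cc <- voxel_volume_cc %||% doses$voxel_volume_cc
    doses <- doses$dose_full_course
  } else if (inherits(doses, "accumulated_dose")) {
    voxel_volume_cc <- voxel_volume_cc %||% doses$voxel_volume_cc
    doses <- if (identical(which, "day")) doses$d_day else doses$d_sum
  }
  doses <- as.numeric(doses)
  if (!length(doses)) stop("no dose samples", call. = FALSE)
  if (kind %in% c("V95", "hotspot") && (is.null(reference) || !is.finite(reference)))
    stop(kind, " needs a reference prescription (Gy)", call. = FALSE)
  switch(kind,
         V95 = mean(doses >= 0.95 * reference) * 100,
         Dmean = mean(doses),
         Dmax = max(doses),
         hotspot = max(doses) / reference * 100,
         D1cc = {
           if (is.null(voxel_volume_cc))
             stop("D1cc needs `voxel_volume_cc`", call. = FALSE)
           total <- length(doses) * voxel_volume_cc
           if (total < 1) {
             warning("structure smaller than 1 cm^3; D1cc degraded to Dmin")
             return(min(doses))
           }
           s <- sort(doses, decreasing = TRUE)
           cum <- cumsum(rep(voxel_volume_cc, length(s)))
           s[base::which(cum >= 1)[1]]
         })
}

#' Standard monitored metrics for one structure
#'
#' Convenience wrapper computing the metric set monitored during a course for
#' a single dose vector, returned tidily.
#'
#' @inheritParams extract_metric
#' @param kinds metrics to compute.
#' @param scope label recorded in the output (`"plan"`, `"day"`, `"sum"`).
#' @return tibble with columns `metric`, `value`, `unit`, `scope`.
#' @export
dose_metrics <- function(doses, kinds = c("V95", "Dmean", "Dmax"),
                         reference = NULL, voxel_volume_cc = NULL,
                         scope = "sum") {
  tibble::tibble(
    metric = kinds,
    value = vapply(kinds, function(k)
      extract_metric(doses, k, reference = reference,
                     voxel_volume_cc = voxel_volume_cc), 0),
    unit = ifelse(kinds %in% c("V95", "hotspot"), "%", "Gy"),
    scope = scope)
}

#' Export a DVH curve as two-column CSV
#' @param curve a `dvh_curve`.
#' @param path output file.
#' @export
write_dvh_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[, c("dose_gy", "volume_pct")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a DVH curve
#' @param object a `dvh_curve`.
#' @param ... ignored.
#' @export
autoplot.dvh_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose_gy, y = .data$volume_pct)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)",
                  title = paste0("Cumulative DVH (", attr(object, "flavor") %||% "", ")")) +
    ggplot2::theme_minimal()
}
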
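#' Resolve the parotid warning endpoint from the planned mean dose
#'
#' Parotid glands carry plan-dependent warning levels.  A spared gland whose
#' plan achieved the 20 Gy mean-dose goal is monitored against 20 Gy; if the
#' goal was missed but the planned mean stays below 21 Gy (overlap with
#' intermediate-risk targets), monitoring is against 21 Gy.  A spared
#' contralateral gland planned below 26 Gy is monitored against 26 Gy.  The
#' adaptation level is always 10% above the warning level.  A gland whose
#' planned mean falls outside every rule range is excluded from monitoring
#' (returns `NULL` with a message).
#'
#' @param planned_dmean planned mean dose of the gland in Gy.
#' @param role `"spared"` (ipsilateral goal 20/21 Gy) or
#'   `"contralateral_spared"` (26 Gy rule).
#' @param structure structure name recorded on the endpoint.
#' @return one-row endpoint tibble (see [build_endpoint_set()]) or `NULL`.
#' @export
resolve_parotid_endpoint <- function(planned_dmean,
                                     role = c("spared", "contralateral_spared"),
                                     structure = "parotid") {
  role <- match.arg(role)
  de0 <- if (role == "spared") {
    if (planned_dmean < 20) 20 else if (planned_dmean < 21) 21 else NA_real_
  } else {
    if (planned_dmean < 26) 26 else NA_real_
  }
  if (is.na(de0)) {
    message("parotid '", structure, "' (planned Dmean ",
            format(planned_dmean, digits = 4),
            " Gy) outside all endpoint rule ranges; excluded from monitoring")
    return(NULL)
  }
  endpoint_row(structure, "Dmean", "upper_bound", warning = de0,
               adaptation = 1.10 * de0, unit = "Gy")
}

endpoint_row <- function(structure, metric, direction, warning, adaptation,
                         unit, reference = NA_real_) {
  tibble::tibble(structure = structure, metric = metric, direction = direction,
                 warning = warning, adaptation = adaptation, unit = unit,
                 reference = reference)
}

#' Default head-and-neck organ-at-risk endpoint configuration
#'
#' One entry per monitored organ class: the metric, the planning-goal dose
#' used as warning level (`goal_gy`; `NA` means 110% of the highest target
#' prescription, the "no hotspot" organs), whether the adaptation level sits
#' 10% above the warning level (`de10`), and the parotid special-casing role.
#' Structures absent from the plan are ignored at build time.
#'
#' @return a tibble consumed by [build_endpoint_set()].
#' @export
hn_endpoint_config <- function() {
  tibble::tribble(
    ~structure,            ~metric, ~goal_gy, ~de10, ~parotid_role,
    "spinal_cord",         "Dmax",  45,       TRUE,  NA,
    "brainstem",           "Dmax",  45,       TRUE,  NA,
    "oral_cavity",         "Dmax",  NA,       FALSE, NA,
    "cervical_esophagus",  "Dmax",  NA,       FALSE, NA,
    "larynx",              "Dmax",  NA,       FALSE, NA,
    "mandible",            "D1cc",  72,       FALSE, NA,
    "cochlea",             "Dmean", 35,       TRUE,  NA,
    "brachial_plexus",     "Dmax",  66,       FALSE, NA,
    "parotid_left",        "Dmean", NA,       TRUE,  "spared",
    "parotid_right",       "Dmean", NA,       TRUE,  "contralateral_spared")
}

#' Build the monitored endpoint set for a plan
#'
#' Every target gets a lower-bound V95 endpoint (warning 95%, adaptation 93%
#' of structure volume at 95% of its own SIB prescription) and an upper-bound
#' hotspot endpoint at 110% of its prescription (both levels).  Organs at risk
#' take their metric and levels from the configuration: explicit planning
#' goals become the warning level, `de10 = TRUE` rows get adaptation at
#' exactly 1.10 times the warning level, "no hotspot" organs (goal `NA`) are
#' monitored as Dmax below 110% of the highest prescription at both levels,
#' and parotid rows are resolved from the planned mean dose via
#' [resolve_parotid_endpoint()].
#'
#' @param plan a [plan_context()].
#' @param plan_dvh_metrics named list of planned metric values per structure
#'   (at least `Dmean` for configured parotids), e.g. from the plan dose.
#' @param config OAR configuration tibble, see [hn_endpoint_config()].
#' @return endpoint tibble with columns `structure`, `metric`, `direction`,
#'   `warning`, `adaptation`, `unit`, `reference`.
#' @export
build_endpoint_set <- function(plan, plan_dvh_metrics = list(),
                               config = hn_endpoint_config()) {
  stopifnot(inherits(plan, "plan_context"))
  bad <- setdiff(config$metric, c("V95", "Dmean", "Dmax", "D1cc", "hotspot"))
  if (length(bad))
    stop("unknown metric kind(s) in endpoint config: ",
         paste(bad, collapse = ", "), call. = FALSE)
  rx_top <- if (length(plan$prescriptions)) max(plan$prescriptions) else NA_real_
  rows <- list()
  for (s in plan$structures) {
    if (s$role != "target") next
    rows[[length(rows) + 1]] <-
      endpoint_row(s$name, "V95", "lower_bound", 95, 93, "%",
                   reference = s$prescription)
    # the hotspot ceiling refers to the prescription dose of the plan (the
    # highest SIB level): the boost plateau legitimately covers nested
    # lower-level targets
    rows[[length(rows) + 1]] <-
      endpoint_row(s$name, "hotspot", "upper_bound", 110, 110, "%",
                   reference = rx_top)
  }
  for (i in seq_len(nrow(config))) {
    cfg <- config[i, ]
    if (!cfg$structure %in% names(plan$structures)) next
    if (!is.na(cfg$parotid_role)) {
      pm <- plan_dvh_metrics[[cfg$structure]]
      dmean <- if (is.list(pm)) pm$Dmean else pm
      if (is.null(dmean))
        stop("planned Dmean needed to resolve parotid endpoint for '",
             cfg$structure, "'", call. = FALSE)
      rows[[length(rows) + 1]] <-
        resolve_parotid_endpoint(dmean, cfg$parotid_role, cfg$structure)
    } else if (is.na(cfg$goal_gy)) {
      # "no hotspot" organs: Dmax below 110% of the highest prescription
      rows[[length(rows) + 1]] <-
        endpoint_row(cfg$structure, cfg$metric, "upper_bound",
                     1.10 * rx_top, 1.10 * rx_top, "Gy", reference = rx_top)
    } else {
      rows[[length(rows) + 1]] <-
        endpoint_row(cfg$structure, cfg$metric, "upper_bound", cfg$goal_gy,
                     if (cfg$de10) 1.10 * cfg$goal_gy else cfg$goal_gy, "Gy")
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("endpoint_set", class(out))
  out
}

#' Locate threshold-crossing fractions in a DP trajectory
#'
#' Scans a per-fraction DP_sum trajectory against one endpoint.  A level is
#' crossed at the smallest fraction whose value *strictly* violates it
#' (below for lower bounds, above for upper bounds; a value exactly at the
#' threshold does not violate).  Trajectories may cross and recede: the first
#' crossing is still reported, and a separate flag records whether the final
#' fraction violates (the end-of-treatment tally).
#'
#' @param trajectory numeric DP_sum values for fractions `1..k` in order, or
#'   a data frame with columns `fraction` and `value`.
#' @param spec one endpoint row (see [build_endpoint_set()]).
#' @param dose_per_fraction Gy per fraction used for the cumulative-dose
#'   column (typically the highest SIB prescription divided by N); `NA` omits
#'   it.
#' @return tibble of violation events: one row per crossed level with the
#'   crossing fraction `fx`, the DP value there, the cumulative delivered dose
#'   at `fx`, and the end-of-treatment flag.
#' @export
detect_crossings <- function(trajectory, spec, dose_per_fraction = NA_real_) {
  if (is.data.frame(trajectory)) {
    trajectory <- trajectory$value[order(trajectory$fraction)]
  }
  values <- as.numeric(trajectory)
  if (!length(values)) stop("empty DP trajectory", call. = FALSE)
  stopifnot(nrow(spec) == 1)
  violates <- function(v, thr)
    if (spec$direction == "lower_bound") v < thr else v > thr
  out <- lapply(c(warning = spec$warning, adaptation = spec$adaptation),
                function(thr) {
                  hit <- which(violates(values, thr))
                  if (!length(hit)) return(NULL)
                  fx <- hit[1]
                  tibble::tibble(threshold = thr, fx = fx,
                                 dp_at_fx = values[fx],
                                 cumulative_dose_gy = fx * dose_per_fraction,
                                 eot_violation = violates(values[length(values)], thr))
                })
  events <- dplyr::bind_rows(out, .id = "level")
  if (!nrow(events))
    return(tibble::tibble(structure = character(), metric = character(),
                          level = character(), threshold = numeric(),
                          fx = integer(), dp_at_fx = numeric(),
                          cumulative_dose_gy = numeric(),
                          eot_violation = logical()))
  dplyr::bind_cols(tibble::tibble(structure = spec$structure,
                                  metric = spec$metric), events)
}
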
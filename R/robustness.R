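#' Area-under-curve robustness of a trajectory
#'
#' Robustness is the area under the survival step-curve divided by the
#' maximum proportion of target species actually removed,
#' R = sum(y(x)) / max(x): y is evaluated after each realized removal, each
#' step has width 1/L_seq, and skipped targets contribute nothing. The
#' normalisation by max(x) scales robustness to the realized sequence
#' length, so sequences cut short by secondary losses remain comparable.
#' With the default right-Riemann rule the value reduces to the mean of y
#' over realized steps; `rule = "trapezoid"` instead anchors the curve at
#' (0, 1) and integrates trapezoidally.
#'
#' `robustness_fw()` integrates the food-web curve (proportion of
#' susceptible, i.e. non-basal, species not secondarily extinct);
#' `robustness_es()` integrates the aggregate ecosystem-service curve in
#' the trajectory's mode (unweighted: proportion of services retaining a
#' living provider; weighted: mean provider-biomass fraction).
#'
#' @param traj an `eco_trajectory` from [simulate_sequence()].
#' @param rule integration rule, `"right"` (default) or `"trapezoid"`.
#' @return object of class `robustness_result` with fields `value`,
#'   `metric`, `mode`, `max_x`, `sequence_label` (and `service_id` for
#'   [robustness_indiv()]).
#' @examples
#' nodes <- data.frame(id = c("B", "H", "P", "S1"), name = c("B", "H", "P", "S1"),
#'                     node_type = c("species", "species", "species", "service"))
#' links <- data.frame(source = c("B", "H", "P"), target = c("H", "P", "S1"),
#'                     link_type = c("trophic", "trophic", "provision"))
#' net <- econet(nodes, links)
#' traj <- simulate_sequence(net, extinction_sequence(c("H", "B", "P")))
#' robustness_fw(traj)$value   # 0.5
#' robustness_es(traj)$value   # 0
#' @export
robustness_fw <- function(traj, rule = c("right", "trapezoid")) {
  rule <- match.arg(rule)
  auc_result(traj, traj$points$y_fw, "R_F", "unweighted", NA_character_, rule)
}

#' @rdname robustness_fw
#' @export
robustness_es <- function(traj, rule = c("right", "trapezoid")) {
  rule <- match.arg(rule)
  if (!length(traj$service_ids))
    stop("network provides no services; R_ES undefined")
  auc_result(traj, traj$points$y_es, "R_ES", traj$mode, NA_character_, rule)
}

auc_result <- function(traj, y, metric, mode, service_id, rule) {
  if (traj$n_realized == 0)
    stop("trajectory has no realized removals; robustness undefined")
  real <- !traj$points$skipped
  yr <- y[real]
  if (rule == "right") {
    value <- sum(yr) / traj$L_seq / traj$max_x
  } else {
    xs <- c(0, traj$points$x[real])
    ys <- c(1, yr)
    value <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2) /
      traj$max_x
  }
  structure(list(value = value, metric = metric, mode = mode,
                 service_id = service_id, max_x = traj$max_x,
                 sequence_label = traj$sequence$label),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(x$metric,
      if (!is.na(x$service_id)) paste0("[", x$service_id, "]"),
      " (", x$mode, ", sequence '", x$sequence_label, "'): ",
      signif(x$value, 6), "  [max(x) = ", signif(x$max_x, 4), "]\n", sep = "")
  invisible(x)
}

#' Individual ecosystem-service robustness
#'
#' Area under the single-service survival curve up until the service is
#' lost: R_indiv = sum over realized removal steps of (1/L_seq) * y, where y
#' indicates whether the service still has a living provider (weighted
#' mode: its remaining provider-biomass fraction). Unlike the aggregate
#' metrics it is not divided by max(x) by default, so a service surviving
#' the whole sequence scores exactly max(x); set `normalize = TRUE` to
#' divide for cross-sequence comparison.
#'
#' @param traj an `eco_trajectory`.
#' @param service_id id of a service provided at the start.
#' @param normalize divide by max(x) (default `FALSE`).
#' @return a `robustness_result`.
#' @export
robustness_indiv <- function(traj, service_id, normalize = FALSE) {
  if (traj$n_realized == 0)
    stop("trajectory has no realized removals; robustness undefined")
  k <- match(service_id, traj$service_ids)
  if (is.na(k))
    stop("unknown or unprovided service: ", service_id)
  real <- !traj$points$skipped
  y <- if (traj$mode == "weighted") traj$service_frac[real, k]
       else as.numeric(traj$service_alive[real, k])
  value <- sum(y) / traj$L_seq
  if (normalize) value <- value / traj$max_x
  structure(list(value = value, metric = "R_indiv", mode = traj$mode,
                 service_id = service_id, max_x = traj$max_x,
                 sequence_label = traj$sequence$label),
            class = "robustness_result")
}

#' Summarise a robustness ensemble
#'
#' Mean, minimum and maximum over replicate robustness values from a random
#' removal ensemble (the average, best-case and worst-case scenarios).
#'
#' @param results list of `robustness_result` objects (or numeric vector of
#'   values) of a single metric and mode.
#' @return list with `n_reps`, `mean`, `min`, `max`, `metric`, `mode`.
#' @export
summarize_ensemble <- function(results) {
  if (is.numeric(results)) {
    vals <- results
    metric <- mode <- NA_character_
  } else {
    if (!length(results)) stop("empty ensemble")
    metric <- unique(vapply(results, `[[`, "", "metric"))
    mode <- unique(vapply(results, `[[`, "", "mode"))
    if (length(metric) > 1 || length(mode) > 1)
      stop("mixed metrics or modes in ensemble: ",
           paste(metric, collapse = "/"), ", ", paste(mode, collapse = "/"))
    vals <- vapply(results, `[[`, 0, "value")
  }
  if (!length(vals)) stop("empty ensemble")
  list(n_reps = length(vals), mean = mean(vals), min = min(vals),
       max = max(vals), metric = metric, mode = mode)
}
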
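#' Two-tailed Spearman rank correlation
#'
#' Spearman's r_s with average ranks for ties. The two-tailed p-value uses
#' the exact null distribution of the rank statistic for n <= 10 without
#' ties, and the t-approximation otherwise (also the fallback when ties are
#' present).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param group optional label carried through to the result.
#' @return object of class `correlation_result`: list with `rho`, `p`,
#'   `n`, `group`.
#' @export
spearman_test <- function(x, y, group = "all") {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("Spearman correlation undefined for a constant vector")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = n <= 10 && !ties, alternative = "two.sided"))
  structure(list(rho = unname(ct$estimate), p = ct$p.value, n = n,
                 group = group),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman r_s[%d] = %.3f, P = %.3g  (%s)\n",
              x$n, x$rho, x$p, x$group))
  invisible(x)
}

#' Robustness correlations by sequence class
#'
#' Correlates food-web robustness with aggregate ecosystem-service
#' robustness over all system-by-scenario entries, and within the three
#' sequence classes: topological (most-to-least connected; random
#' max/mean/min), threat-based (rarity; vulnerable) and ecosystem-service
#' (providers by biomass and random mean; supporting species by importance
#' and random mean). With all 12 scenario entries on 3 systems the class
#' sizes are 36/12/6/18.
#'
#' @param tbl data.frame with columns `system`, `scenario`, `R_F`, `R_ES`
#'   (one row per system x scenario entry), e.g. the `robustness` table of
#'   [service_robustness()].
#' @return data.frame with one row per class: `group`, `rho`, `p`, `n`.
#' @export
correlation_by_group <- function(tbl) {
  classes <- list(
    all = scenario_entries(),
    topological = c("most_connected", "random_max", "random_mean",
                    "random_min"),
    threat = c("rarity", "vulnerable"),
    service = c("esp_biomass_desc", "esp_random_mean", "esp_biomass_asc",
                "supporting_desc", "supporting_asc",
                "supporting_random_mean"))
  out <- lapply(names(classes), function(g) {
    sub <- tbl[tbl$scenario %in% classes[[g]], , drop = FALSE]
    if (nrow(sub) < 3) {
      warning("sequence class '", g, "' empty or too small; skipped")
      return(NULL)
    }
    res <- tryCatch(spearman_test(sub$R_F, sub$R_ES, group = g),
                    error = function(e) {
                      warning("class '", g, "': ", conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) return(NULL)
    data.frame(group = g, rho = res$rho, p = res$p, n = res$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# the 12 scenario entries of the standard report (random families expand to
# their ensemble summaries)
scenario_entries <- function() {
  c("esp_biomass_desc", "esp_random_mean", "esp_biomass_asc",
    "most_connected", "random_max", "random_mean", "random_min",
    "rarity", "supporting_desc", "supporting_asc",
    "supporting_random_mean", "vulnerable")
}

#' Regress individual service robustness on trophic level and redundancy
#'
#' Ordinary least squares of R_indiv on service trophic level and
#' redundancy (additive), over the system x service x sequence rows of the
#' given subset. The standard report fits seven models: all sequences
#' pooled plus one per deterministic sequence.
#'
#' @param tbl data.frame with columns `r_indiv`, `trophic_level`,
#'   `redundancy` and `scenario`, e.g. the `indiv` table of
#'   [service_robustness()] joined to [service_stats()].
#' @param subset scenario label, or `"all"` to pool every row.
#' @return object of class `regression_result`: coefficients, standard
#'   errors, subset label, n, and the underlying `lm` fit.
#' @export
regress_indiv <- function(tbl, subset = "all") {
  sub <- if (identical(subset, "all")) tbl
         else tbl[tbl$scenario == subset, , drop = FALSE]
  sub <- sub[!is.na(sub$trophic_level), , drop = FALSE]
  if (nrow(sub) < 4) stop("need >= 4 rows for the regression (got ",
                          nrow(sub), ")")
  fit <- stats::lm(r_indiv ~ trophic_level + redundancy, data = sub)
  if (fit$rank < 3)
    stop("rank-deficient design: trophic level and redundancy are collinear",
         " in subset '", subset, "'")
  sm <- summary(fit)
  structure(list(coefficients = stats::coef(fit),
                 se = sm$coefficients[, "Std. Error"],
                 subset = subset, n = nrow(sub), fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("R_indiv ~ trophic_level + redundancy  (subset: ", x$subset,
      ", n = ", x$n, ")\n", sep = "")
  tab <- cbind(estimate = x$coefficients, se = x$se)
  print(round(tab, 5))
  invisible(x)
}
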
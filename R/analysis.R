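#' Food-web and ecosystem-service robustness analysis
#'
#' One-call orchestration of the full analysis on one or more systems:
#' builds the 12 standard species-loss scenarios (ecosystem-service
#' providers by descending/ascending biomass and at random; supporting
#' species by descending/ascending personalized-PageRank importance and at
#' random; most-to-least connected; random with max/mean/min summaries;
#' rarity; vulnerable species), simulates every extinction trajectory with
#' bottom-up secondary extinctions, computes food-web robustness R_F,
#' aggregate service robustness R_ES (unweighted and biomass-weighted) and
#' per-service R_indiv, and runs the cross-sequence Spearman correlations
#' and the R_indiv ~ trophic level + redundancy regressions.
#'
#' @param systems an `econet` or a (optionally named) list of them.
#' @param n_random random-removal replicates (study default 1000).
#' @param n_esp_random,n_supporting_random replicates for the random
#'   provider and supporting-species sequences (default 100).
#' @param alpha PageRank termination probability (default 0.15).
#' @param weighted also compute biomass-weighted service robustness
#'   (requires biomass on every provider).
#' @param weight_exempt service ids kept binary in weighted mode; default
#'   is each network's own `"weight_exempt"` attribute.
#' @param scenarios subset of scenario entry labels to run (default all
#'   12; see [correlation_by_group()] for the class memberships). The
#'   correlation/regression layer requires the full default set.
#' @param seed master seed; every random stage derives its own sub-seed
#'   from it, so reruns are fully deterministic.
#' @return object of class `service_robustness` with components
#'   `robustness` (system x scenario table of R_F, R_ES and, when
#'   computed, weighted R_ES), `indiv` (per system x service x
#'   deterministic sequence R_indiv, both modes, joined to service trophic
#'   level and redundancy), `service_metrics`, `importance` (supporting
#'   scores per system), `correlations`, `correlations_weighted`,
#'   `regressions` (the seven models), and the call configuration.
#' @examples
#' net <- synth_system(S = 40, C = 0.1, seed = 2,
#'                     services = data.frame(service = c("sA", "sB"),
#'                                           redundancy = c(1L, 6L),
#'                                           trophic_bias = c("high", "low"),
#'                                           weight_exempt = c(FALSE, FALSE)))
#' fit <- service_robustness(net, n_random = 25, n_esp_random = 10,
#'                           n_supporting_random = 10, seed = 3)
#' fit$robustness
#' @export
service_robustness <- function(systems, n_random = 1000,
                               n_esp_random = 100,
                               n_supporting_random = 100,
                               alpha = 0.15, weighted = TRUE,
                               weight_exempt = NULL,
                               scenarios = scenario_entries(),
                               seed = 1) {
  if (inherits(systems, "econet")) systems <- list(systems)
  if (!length(systems)) stop("need at least one system")
  if (is.null(names(systems)) || any(!nzchar(names(systems))))
    names(systems) <- sprintf("system%d", seq_along(systems))
  bad <- setdiff(scenarios, scenario_entries())
  if (length(bad)) stop("unknown scenario entries: ", paste(bad, collapse = ", "))

  seeds <- matrix(derive_seeds(seed, 3 * length(systems)), ncol = 3)
  rob <- list(); indiv <- list(); smet <- list(); imp <- list()
  for (i in seq_along(systems)) {
    lab <- names(systems)[i]
    res <- tryCatch(
      run_one_system(systems[[i]], lab, n_random, n_esp_random,
                     n_supporting_random, alpha, weighted, weight_exempt,
                     scenarios, seeds[i, ]),
      error = function(e) stop("system '", lab, "': ", conditionMessage(e),
                               call. = FALSE))
    rob[[i]] <- res$robustness
    indiv[[i]] <- res$indiv
    smet[[i]] <- res$service_metrics
    imp[[i]] <- res$importance
  }
  robustness <- do.call(rbind, rob)
  indiv <- do.call(rbind, indiv)
  service_metrics <- do.call(rbind, smet)

  correlations <- NULL
  correlations_weighted <- NULL
  regressions <- NULL
  if (setequal(scenarios, scenario_entries()) && length(systems) >= 1 &&
      nrow(robustness) >= 3) {
    correlations <- suppressWarnings(
      tryCatch(correlation_by_group(robustness), error = function(e) NULL))
    if (weighted) {
      correlations_weighted <- rbind(
        cor_row("R_F_vs_weighted_R_ES", robustness$R_F,
                robustness$R_ES_weighted),
        cor_row("R_ES_vs_weighted_R_ES", robustness$R_ES,
                robustness$R_ES_weighted),
        cor_row("R_indiv_vs_weighted_R_indiv", indiv$r_indiv,
                indiv$r_indiv_weighted))
    }
    reg_subsets <- c("all", "most_connected", "esp_biomass_desc",
                     "esp_biomass_asc", "supporting_desc",
                     "supporting_asc", "rarity")
    regressions <- lapply(reg_subsets, function(s)
      tryCatch(regress_indiv(indiv, s), error = function(e) NULL))
    names(regressions) <- reg_subsets
  }
  structure(list(
    robustness = robustness, indiv = indiv,
    service_metrics = service_metrics, importance = imp,
    correlations = correlations,
    correlations_weighted = correlations_weighted,
    regressions = regressions,
    config = list(n_random = n_random, n_esp_random = n_esp_random,
                  n_supporting_random = n_supporting_random,
                  alpha = alpha, weighted = weighted,
                  scenarios = scenarios, seed = seed),
    systems = names(systems)),
    class = "service_robustness")
}

cor_row <- function(label, x, y) {
  ok <- !is.na(x) & !is.na(y)
  res <- spearman_test(x[ok], y[ok], group = label)
  data.frame(comparison = label, rho = res$rho, p = res$p, n = res$n,
             stringsAsFactors = FALSE)
}

# fast robustness triple (R_F, R_ES, weighted R_ES) from a raw cascade run
run_robustness <- function(run) {
  real <- !run$skipped
  c(R_F = mean(run$y_fw[real]),
    R_ES = mean(run$y_es[real]),
    R_ES_weighted = if (!is.null(run$y_es_w)) mean(run$y_es_w[real])
                    else NA_real_,
    max_x = run$max_x)
}

run_one_system <- function(net, lab, n_random, n_esp_random,
                           n_supporting_random, alpha, weighted,
                           weight_exempt, scenarios, seeds) {
  ctx <- cascade_context(net, weighted = weighted,
                         weight_exempt = weight_exempt)
  if (ctx$n_services == 0) stop("stage service_stats: no provided services")
  smet <- service_stats(net)
  smet <- smet[smet$redundancy > 0, , drop = FALSE]
  smet$system <- lab
  scores <- supporting_scores(net, alpha = alpha)

  det_specs <- list(
    most_connected = function() seq_most_connected(net),
    esp_biomass_desc = function() seq_service_providers(net, "desc"),
    esp_biomass_asc = function() seq_service_providers(net, "asc"),
    rarity = function() seq_threat(net, "rarity"),
    vulnerable = function() seq_threat(net, "vulnerable"),
    supporting_desc = function() seq_supporting(net, scores, "desc"),
    supporting_asc = function() seq_supporting(net, scores, "asc"))

  rob_rows <- list(); indiv_rows <- list()
  indiv_seqs <- c("most_connected", "esp_biomass_desc", "esp_biomass_asc",
                  "supporting_desc", "supporting_asc", "rarity")
  for (sc in intersect(names(det_specs), scenarios)) {
    sq <- tryCatch(det_specs[[sc]](),
                   error = function(e) stop("stage sequence '", sc, "': ",
                                            conditionMessage(e), call. = FALSE))
    run <- cascade_run(ctx, unname(ctx$idx[sq$targets]), weighted = weighted)
    tr <- run_robustness(run)
    rob_rows[[sc]] <- data.frame(
      system = lab, scenario = sc, R_F = tr[["R_F"]], R_ES = tr[["R_ES"]],
      R_ES_weighted = tr[["R_ES_weighted"]], max_x = tr[["max_x"]],
      stringsAsFactors = FALSE)
    if (sc %in% indiv_seqs) {
      real <- !run$skipped
      for (k in seq_along(ctx$service_ids)) {
        riu <- sum(run$svc_alive[real, k]) / run$L_seq
        riw <- if (weighted) sum(run$svc_frac[real, k]) / run$L_seq
               else NA_real_
        indiv_rows[[paste(sc, k)]] <- data.frame(
          system = lab, scenario = sc, service = ctx$service_ids[k],
          r_indiv = riu, r_indiv_weighted = riw, max_x = run$max_x,
          stringsAsFactors = FALSE)
      }
    }
  }

  ens_specs <- list(
    random = list(n = n_random, seqs = function(s) seq_random(net, n_random, s),
                  entries = c("random_max", "random_mean", "random_min")),
    esp_random = list(n = n_esp_random,
                      seqs = function(s) seq_service_providers(
                        net, "random", n_esp_random, s),
                      entries = "esp_random_mean"),
    supporting_random = list(n = n_supporting_random,
                             seqs = function(s) seq_supporting(
                               net, scores, "random", n_supporting_random, s),
                             entries = "supporting_random_mean"))
  for (j in seq_along(ens_specs)) {
    es <- ens_specs[[j]]
    if (!any(es$entries %in% scenarios)) next
    sqs <- es$seqs(seeds[j])
    vals <- vapply(sqs, function(sq)
      run_robustness(cascade_run(ctx, unname(ctx$idx[sq$targets]),
                                 weighted = weighted, record_services = FALSE)),
      numeric(4))
    summ <- list(max = apply(vals, 1, max), mean = rowMeans(vals),
                 min = apply(vals, 1, min))
    for (entry in intersect(es$entries, scenarios)) {
      stat <- sub(".*_", "", entry)  # max / mean / min
      v <- summ[[stat]]
      rob_rows[[entry]] <- data.frame(
        system = lab, scenario = entry, R_F = v[["R_F"]], R_ES = v[["R_ES"]],
        R_ES_weighted = v[["R_ES_weighted"]], max_x = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  robustness <- do.call(rbind, rob_rows)
  robustness <- robustness[match(intersect(scenario_entries(),
                                           robustness$scenario),
                                 robustness$scenario), , drop = FALSE]
  rownames(robustness) <- NULL
  indiv <- do.call(rbind, indiv_rows)
  if (!is.null(indiv)) {
    m <- match(indiv$service, smet$service)
    indiv$trophic_level <- smet$trophic_level[m]
    indiv$redundancy <- smet$redundancy[m]
    rownames(indiv) <- NULL
  }
  list(robustness = robustness, indiv = indiv, service_metrics = smet,
       importance = scores)
}

#' @export
print.service_robustness <- function(x, ...) {
  cat("service_robustness analysis: ", length(x$systems), " system(s), ",
      length(unique(x$robustness$scenario)), " scenario entries\n", sep = "")
  if (!is.null(x$correlations)) {
    ov <- x$correlations[x$correlations$group == "all", ]
    if (nrow(ov))
      cat(sprintf("  R_F vs R_ES: Spearman r_s[%d] = %.3f, P = %.3g\n",
                  ov$n, ov$rho, ov$p))
  }
  cat("  components: robustness, indiv, service_metrics, importance,",
      "correlations, regressions\n")
  invisible(x)
}

#' @export
summary.service_robustness <- function(object, ...) {
  print(object)
  cat("\nRobustness by scenario (mean over systems):\n")
  agg <- stats::aggregate(cbind(R_F, R_ES) ~ scenario, object$robustness,
                          mean)
  agg <- agg[match(intersect(scenario_entries(), agg$scenario),
                   agg$scenario), ]
  print(cbind(agg[1], round(agg[-1], 3)), row.names = FALSE)
  if (!is.null(object$correlations)) {
    cat("\nSpearman correlations R_F vs R_ES by sequence class:\n")
    print(cbind(object$correlations[1],
                round(object$correlations[-1], 4)), row.names = FALSE)
  }
  if (!is.null(object$regressions$all)) {
    cat("\nAll-sequence model:\n")
    print(object$regressions$all)
  }
  invisible(object)
}

#' @export
coef.service_robustness <- function(object, subset = "all", ...) {
  r <- object$regressions[[subset]]
  if (is.null(r)) stop("no fitted regression for subset '", subset, "'")
  r$coefficients
}

#' Plot food-web against ecosystem-service robustness
#'
#' Scatter of R_ES against R_F over every system x scenario entry with the
#' 1:1 line; points on the line indicate services exactly as robust as the
#' web that supports them.
#'
#' @param x a `service_robustness` object.
#' @param weighted plot the biomass-weighted R_ES instead.
#' @param ... passed to [graphics::plot()].
#' @export
plot.service_robustness <- function(x, weighted = FALSE, ...) {
  tbl <- x$robustness
  y <- if (weighted) tbl$R_ES_weighted else tbl$R_ES
  sys <- factor(tbl$system)
  graphics::plot(tbl$R_F, y, pch = as.integer(sys),
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = expression(R[F]),
                 ylab = if (weighted) "weighted R_ES" else expression(R[ES]),
                 ...)
  graphics::abline(0, 1, col = "steelblue")
  graphics::legend("topleft", bty = "n", pch = seq_along(levels(sys)),
                   legend = levels(sys))
  invisible(x)
}
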
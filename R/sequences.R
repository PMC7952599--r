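#' Most-to-least connected removal sequence
#'
#' Orders all species by descending total trophic degree (in + out links on
#' the food web, a self-loop counted once; provision links are not
#' species-species links and are excluded). Ties are broken by ascending
#' species id so the sequence is reproducible under input reordering.
#'
#' @param net an `econet`.
#' @return an [extinction_sequence()].
#' @export
seq_most_connected <- function(net) {
  sp <- species_ids(net)
  if (!length(sp)) stop("network has no species")
  tl <- trophic_links(net)
  deg <- tabulate(match(tl$source, sp), nbins = length(sp)) +
    tabulate(match(tl$target, sp), nbins = length(sp)) -
    tabulate(match(tl$source[tl$source == tl$target], sp), nbins = length(sp))
  o <- order(-deg, sp)
  extinction_sequence(sp[o], "most_connected")
}

#' Random removal sequences
#'
#' Independent uniform permutations of all species; the study default is
#' 1000 replicates, summarised afterwards as mean/best/worst case.
#'
#' @param net an `econet`.
#' @param n_reps number of replicate sequences.
#' @param seed integer seed; the same seed reproduces the same list.
#' @return list of [extinction_sequence()] objects.
#' @export
seq_random <- function(net, n_reps = 1000, seed = NULL) {
  stopifnot(n_reps >= 1)
  sp <- species_ids(net)
  if (!length(sp)) stop("network has no species")
  with_seed(seed, lapply(seq_len(n_reps), function(r)
    extinction_sequence(sample(sp), sprintf("random_%04d", r))))
}

#' Ecosystem-service-provider removal sequences
#'
#' Targets are the union of providers over all services, removed in order
#' of biomass (descending or ascending, ties broken by ascending id) or in
#' random order (default 100 replicates).
#'
#' @param net an `econet`.
#' @param order `"desc"` (high-to-low biomass), `"asc"`, or `"random"`.
#' @param n_reps replicates for `order = "random"`.
#' @param seed integer seed for random order.
#' @return an [extinction_sequence()], or a list of them for random order.
#' @export
seq_service_providers <- function(net, order = c("desc", "asc", "random"),
                                  n_reps = 100, seed = NULL) {
  order <- match.arg(order)
  prov <- sort(unique(provision_links(net)$source))
  if (!length(prov)) stop("network has no ecosystem service providers")
  if (order == "random") {
    return(with_seed(seed, lapply(seq_len(n_reps), function(r)
      extinction_sequence(sample(prov), sprintf("esp_random_%04d", r)))))
  }
  biomass <- net$nodes$biomass[match(prov, net$nodes$id)]
  if (anyNA(biomass))
    stop("biomass missing for provider(s): ",
         paste(prov[is.na(biomass)], collapse = ", "))
  o <- if (order == "desc") order(-biomass, prov) else order(biomass, prov)
  extinction_sequence(prov[o], paste0("esp_biomass_", order))
}

#' Threat-based removal sequences
#'
#' `"rarity"` removes every species in ascending order of abundance
#' (rarest first); `"vulnerable"` removes only the species flagged
#' vulnerable, also rarest first. Ties are broken by ascending id.
#'
#' @param net an `econet`.
#' @param scenario `"rarity"` or `"vulnerable"`.
#' @return an [extinction_sequence()].
#' @export
seq_threat <- function(net, scenario = c("rarity", "vulnerable")) {
  scenario <- match.arg(scenario)
  sp <- species_ids(net)
  if (scenario == "vulnerable") {
    vuln <- net$nodes$vulnerable[match(sp, net$nodes$id)]
    if (all(is.na(vuln)))
      stop("vulnerable flags missing from the node table")
    sp <- sp[!is.na(vuln) & vuln]
    if (!length(sp)) stop("no vulnerable species in the network")
  }
  ab <- net$nodes$abundance[match(sp, net$nodes$id)]
  if (anyNA(ab))
    stop("abundance missing for species: ",
         paste(sp[is.na(ab)], collapse = ", "))
  o <- order(ab, sp)
  extinction_sequence(sp[o], scenario)
}

#' Supporting-species removal sequences
#'
#' Orders the species with a defined mean supporting-importance score (see
#' [supporting_scores()]) by descending or ascending score, ties broken by
#' ascending id, or permutes them randomly (default 100 replicates).
#'
#' @param net an `econet` (used only for validation).
#' @param scores an `importance_table` from [supporting_scores()] or a
#'   named numeric vector of mean scores; `NA` entries (species providing
#'   every service) are excluded from the target set.
#' @param order `"desc"`, `"asc"`, or `"random"`.
#' @param n_reps replicates for random order.
#' @param seed integer seed.
#' @return an [extinction_sequence()], or a list of them for random order.
#' @export
seq_supporting <- function(net, scores, order = c("desc", "asc", "random"),
                           n_reps = 100, seed = NULL) {
  order <- match.arg(order)
  if (inherits(scores, "importance_table")) scores <- scores$mean
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("no species with a defined supporting score")
  ids <- names(scores)
  if (order == "random") {
    return(with_seed(seed, lapply(seq_len(n_reps), function(r)
      extinction_sequence(sample(ids), sprintf("supporting_random_%04d", r)))))
  }
  o <- if (order == "desc") order(-scores, ids) else order(scores, ids)
  extinction_sequence(ids[o], paste0("supporting_", order))
}
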
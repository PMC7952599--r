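#' Extinction sequences
#'
#' An ordered list of primary-removal targets. Targets must be unique
#' species ids (services can never be removed directly); the sequence length
#' `L_seq` is the x-axis denominator of the robustness curves.
#'
#' @param targets character vector of species ids, removal order.
#' @param label scenario name.
#' @return object of class `extinction_sequence`.
#' @export
extinction_sequence <- function(targets, label = "custom") {
  targets <- as.character(targets)
  if (length(targets) < 1) stop("extinction sequence must have >= 1 target")
  if (anyDuplicated(targets))
    stop("duplicate targets in sequence: ",
         paste(unique(targets[duplicated(targets)]), collapse = ", "))
  structure(list(label = label, targets = targets, L_seq = length(targets)),
            class = "extinction_sequence")
}

#' @export
print.extinction_sequence <- function(x, ...) {
  cat("extinction sequence '", x$label, "': L_seq = ", x$L_seq, "\n", sep = "")
  cat("  ", paste(utils::head(x$targets, 8), collapse = " -> "),
      if (x$L_seq > 8) " -> ..." else "", "\n", sep = "")
  invisible(x)
}

# Precompute index structures for fast cascade simulation.
# Species are mapped to 1..S; per species: non-self resource count,
# consumer list; per provided service: provider indices and biomass.
cascade_context <- function(net, weighted = FALSE, weight_exempt = NULL) {
  sp <- species_ids(net)
  S <- length(sp)
  idx <- seq_len(S)
  names(idx) <- sp
  tl <- trophic_links(net)
  tl <- tl[tl$source != tl$target, , drop = FALSE]
  src <- idx[tl$source]
  tgt <- idx[tl$target]
  res_count <- tabulate(tgt, nbins = S)
  cons_list <- vector("list", S)
  if (length(src)) {
    o <- order(src)
    cons_list[unique(src[o])] <- split(unname(tgt[o]), src[o])
  }
  basal <- res_count == 0L
  pl <- provision_links(net)
  red <- table(factor(pl$target, levels = service_ids(net)))
  provided <- names(red)[red > 0]
  n_sv <- length(provided)
  sv_idx <- seq_len(n_sv)
  names(sv_idx) <- provided
  sp_services <- vector("list", S)
  prov_count0 <- integer(n_sv)
  prov_bio0 <- numeric(n_sv)
  biomass <- net$nodes$biomass[match(sp, net$nodes$id)]
  if (n_sv) {
    keep <- pl$target %in% provided
    ps <- idx[pl$source[keep]]
    pt <- sv_idx[pl$target[keep]]
    o <- order(ps)
    if (length(ps))
      sp_services[unique(ps[o])] <- split(unname(pt[o]), ps[o])
    prov_count0 <- tabulate(pt, nbins = n_sv)
    if (weighted) {
      providers <- unique(pl$source[keep])
      bad <- providers[is.na(biomass[idx[providers]])]
      if (length(bad))
        stop("weighted mode requires biomass for every provider; missing for: ",
             paste(bad, collapse = ", "))
      prov_bio0 <- as.numeric(
        tapply(biomass[ps], factor(pt, levels = sv_idx), sum, default = 0))
    }
  }
  we <- if (is.null(weight_exempt)) attr(net, "weight_exempt") else weight_exempt
  exempt <- provided %in% we
  list(S = S, ids = sp, idx = idx, res_count = res_count,
       cons_list = cons_list, basal = basal,
       susceptible = sum(!basal),
       n_services = n_sv, service_ids = provided,
       sp_services = sp_services, prov_count0 = prov_count0,
       prov_bio0 = prov_bio0, biomass = biomass, exempt = exempt)
}

# Core cascade simulation on a prebuilt context. `targets` are species
# indices in removal order. Returns per-step vectors plus per-service state.
# Secondary extinctions propagate bottom-up: a non-basal species dies when
# its last non-self resource dies; services lose providers on any death.
cascade_run <- function(ctx, targets, weighted = FALSE,
                        record_services = TRUE) {
  S <- ctx$S
  L_seq <- length(targets)
  alive <- rep(TRUE, S)
  resc <- ctx$res_count
  cons <- ctx$cons_list
  spsv <- ctx$sp_services
  n_sv <- ctx$n_services
  pc <- ctx$prov_count0
  pb <- ctx$prov_bio0
  pb0 <- ctx$prov_bio0
  bio <- ctx$biomass
  exempt <- ctx$exempt
  susceptible <- ctx$susceptible
  n_real <- 0L
  sec <- 0L
  x <- numeric(L_seq); y_fw <- numeric(L_seq)
  y_es <- if (n_sv) numeric(L_seq) else rep(NA_real_, L_seq)
  y_es_w <- if (weighted && n_sv) numeric(L_seq) else NULL
  skipped <- logical(L_seq)
  removed_id <- character(L_seq)
  svc_alive <- if (record_services && n_sv) matrix(FALSE, L_seq, n_sv) else NULL
  svc_frac <- if (record_services && weighted && n_sv) matrix(0, L_seq, n_sv) else NULL
  stack <- integer(S)
  for (k in seq_len(L_seq)) {
    t <- targets[k]
    if (!alive[t]) {
      skipped[k] <- TRUE
      removed_id[k] <- NA_character_
    } else {
      n_real <- n_real + 1L
      removed_id[k] <- ctx$ids[t]
      stack[1L] <- t
      top <- 1L
      primary <- TRUE
      while (top > 0L) {
        v <- stack[top]; top <- top - 1L
        if (!alive[v]) next
        alive[v] <- FALSE
        if (!primary) sec <- sec + 1L
        primary <- FALSE
        sv <- spsv[[v]]
        if (!is.null(sv)) {
          pc[sv] <- pc[sv] - 1L
          if (weighted) pb[sv] <- pb[sv] - bio[v]
        }
        cc <- cons[[v]]
        if (!is.null(cc)) {
          cc <- cc[alive[cc]]
          if (length(cc)) {
            resc[cc] <- resc[cc] - 1L
            dead <- cc[resc[cc] == 0L]
            n_dead <- length(dead)
            if (n_dead) {
              stack[(top + 1L):(top + n_dead)] <- dead
              top <- top + n_dead
            }
          }
        }
      }
    }
    x[k] <- n_real / L_seq
    y_fw[k] <- 1 - sec / max(susceptible, 1L)
    if (n_sv) {
      sv_up <- pc > 0L
      y_es[k] <- sum(sv_up) / n_sv
      if (weighted) {
        frac <- ifelse(pb0 > 0, pmax(pb, 0) / pb0, as.numeric(sv_up))
        frac[exempt] <- as.numeric(sv_up[exempt])
        frac[!sv_up] <- 0
        y_es_w[k] <- mean(frac)
        if (record_services) svc_frac[k, ] <- frac
      }
      if (record_services) svc_alive[k, ] <- sv_up
    }
  }
  list(x = x, y_fw = y_fw, y_es = y_es, y_es_w = y_es_w,
       skipped = skipped, removed_id = removed_id,
       n_realized = n_real, max_x = n_real / L_seq, L_seq = L_seq,
       svc_alive = svc_alive, svc_frac = svc_frac)
}

#' Secondary-extinction closure of a removal set
#'
#' Least fixed point of the bottom-up extinction rule: starting from the
#' primary removals, any living non-basal species whose every non-self
#' resource is removed or already secondarily extinct goes extinct, until no
#' further losses occur. Basal species never appear in the output; the
#' primary removals themselves are not returned. The result is independent
#' of processing order.
#'
#' @param net an `econet`.
#' @param removed character vector of primarily removed species ids.
#' @return character vector of secondarily extinct species ids.
#' @examples
#' net <- chain <- econet(
#'   data.frame(id = c("B", "H", "P"), name = c("B", "H", "P"),
#'              node_type = "species"),
#'   data.frame(source = c("B", "H"), target = c("H", "P"),
#'              link_type = "trophic"))
#' extinction_closure(net, "B")  # H and P starve
#' @export
extinction_closure <- function(net, removed) {
  removed <- as.character(removed)
  ctx <- cascade_context(net)
  unknown <- setdiff(removed, ctx$ids)
  if (length(unknown))
    stop("unknown species id(s): ", paste(unknown, collapse = ", "))
  if (!length(removed)) return(character())
  alive <- alive_after(ctx, removed)
  setdiff(ctx$ids[!alive], removed)
}

# helper: alive mask after removing `removed` (ids) and propagating
alive_after <- function(ctx, removed) {
  alive <- rep(TRUE, ctx$S)
  resc <- ctx$res_count
  stack <- unname(ctx$idx[removed])
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (!alive[v]) next
    alive[v] <- FALSE
    cc <- ctx$cons_list[[v]]
    if (!is.null(cc)) {
      cc <- cc[alive[cc]]
      if (length(cc)) {
        resc[cc] <- resc[cc] - 1L
        stack <- c(stack, cc[resc[cc] == 0L])
      }
    }
  }
  alive
}

#' Simulate an extinction sequence
#'
#' Removes the targets in order, propagating bottom-up secondary
#' extinctions after each removal and recording one trajectory point per
#' step. A target that has already gone secondarily extinct is skipped: it
#' does not count as a primary removal, so the curve then never reaches
#' x = 1. The food-web y-axis is the proportion of initially susceptible
#' (non-basal) species not yet secondarily extinct; primary removals never
#' reduce it directly. The service y-axis is, unweighted, the proportion of
#' initially provided services that still have at least one living
#' provider; weighted, the mean over services of the living-provider
#' biomass fraction (weight-exempt services contribute their binary
#' indicator instead).
#'
#' @param net an `econet`.
#' @param seq an [extinction_sequence()] (or character vector of targets).
#' @param mode `"unweighted"` or `"weighted"`. Weighted mode requires
#'   biomass on every provider.
#' @param weight_exempt service ids kept binary in weighted mode; defaults
#'   to the network's `"weight_exempt"` attribute.
#' @return an object of class `eco_trajectory`: the per-step points
#'   (`step`, `removed_id`, `skipped`, `x`, `y_fw`, `y_es`), per-service
#'   survival (and biomass-fraction) matrices, and bookkeeping fields
#'   (`susceptible_count`, `max_x`, `n_realized`, `L_seq`). In weighted
#'   mode the unweighted service curve is kept in `points$y_es_unweighted`.
#' @export
simulate_sequence <- function(net, seq, mode = c("unweighted", "weighted"),
                              weight_exempt = NULL) {
  mode <- match.arg(mode)
  if (!inherits(seq, "extinction_sequence"))
    seq <- extinction_sequence(seq)
  ctx <- cascade_context(net, weighted = mode == "weighted",
                         weight_exempt = weight_exempt)
  unknown <- setdiff(seq$targets, ctx$ids)
  if (length(unknown))
    stop("sequence target(s) not species of the network: ",
         paste(unknown, collapse = ", "))
  run <- cascade_run(ctx, unname(ctx$idx[seq$targets]),
                     weighted = mode == "weighted")
  points <- data.frame(
    step = seq_len(run$L_seq),
    removed_id = run$removed_id,
    skipped = run$skipped,
    x = run$x, y_fw = run$y_fw,
    y_es = if (mode == "weighted") run$y_es_w else run$y_es,
    stringsAsFactors = FALSE)
  if (mode == "weighted") points$y_es_unweighted <- run$y_es
  if (!is.null(run$svc_alive)) colnames(run$svc_alive) <- ctx$service_ids
  if (!is.null(run$svc_frac)) colnames(run$svc_frac) <- ctx$service_ids
  structure(list(
    sequence = seq, mode = mode, points = points,
    susceptible_count = ctx$susceptible,
    service_ids = ctx$service_ids,
    service_alive = run$svc_alive,
    service_frac = run$svc_frac,
    initial_service_biomass = if (mode == "weighted")
      stats::setNames(ctx$prov_bio0, ctx$service_ids) else NULL,
    n_realized = run$n_realized, max_x = run$max_x, L_seq = run$L_seq),
    class = "eco_trajectory")
}

#' @export
print.eco_trajectory <- function(x, ...) {
  cat("extinction trajectory '", x$sequence$label, "' (", x$mode, ")\n",
      sep = "")
  cat("  L_seq = ", x$L_seq, ", realized removals = ", x$n_realized,
      ", max(x) = ", signif(x$max_x, 4), "\n", sep = "")
  cat("  final y_fw = ", signif(utils::tail(x$points$y_fw, 1), 4),
      if (length(x$service_ids))
        paste0(", final y_es = ", signif(utils::tail(x$points$y_es, 1), 4)),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.eco_trajectory <- function(x, ...) {
  df <- x$points
  if (!is.null(x$service_alive)) {
    sv <- as.data.frame(x$service_alive)
    names(sv) <- paste0("alive_", names(sv))
    df <- cbind(df, sv)
  }
  if (!is.null(x$service_frac)) {
    sv <- as.data.frame(x$service_frac)
    names(sv) <- paste0("frac_", names(sv))
    df <- cbind(df, sv)
  }
  df
}

#' Plot an extinction trajectory
#'
#' Step curves of the food-web and service survival proportions against the
#' proportion of targets removed.
#'
#' @param x an `eco_trajectory`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.eco_trajectory <- function(x, ...) {
  pts <- x$points[!x$points$skipped, , drop = FALSE]
  graphics::plot(c(0, pts$x), c(1, pts$y_fw), type = "s",
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "proportion of target species removed (x)",
                 ylab = "proportion surviving (y)",
                 main = x$sequence$label, ...)
  if (length(x$service_ids))
    graphics::lines(c(0, pts$x), c(1, pts$y_es), type = "s",
                    lty = 2, col = "firebrick")
  graphics::legend("bottomleft", bty = "n", lty = c(1, 2),
                   col = c("black", "firebrick"),
                   legend = c("food web", "ecosystem services"))
  invisible(x)
}
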
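#' Prey-averaged trophic levels
#'
#' Trophic level is 1 for basal species and 1 plus the mean trophic level
#' of a consumer's resources otherwise (uniform diet weights: the link data
#' are binary). Self-loops are removed first (a cannibal's own tissue does
#' not raise its trophic level). Loops among consumers are handled by
#' solving the defining linear system (I - Q) TL = 1, with Q the
#' row-normalised diet matrix; a consumer cycle receiving no basal input
#' makes the system singular and is reported as an error naming the species
#' involved.
#'
#' @param net an `econet`; only the species and trophic links are used.
#' @return named numeric vector of trophic levels (>= 1) over the species.
#' @export
trophic_levels <- function(net) {
  sp <- species_ids(net)
  S <- length(sp)
  tl <- trophic_links(net)
  tl <- tl[tl$source != tl$target, , drop = FALSE]
  Q <- matrix(0, S, S, dimnames = list(sp, sp))
  if (nrow(tl)) {
    ci <- match(tl$target, sp)  # consumer rows
    ri <- match(tl$source, sp)  # resource cols
    for (k in seq_along(ci)) Q[ci[k], ri[k]] <- 1
    nres <- rowSums(Q)
    cons <- nres > 0
    Q[cons, ] <- Q[cons, , drop = FALSE] / nres[cons]
  }
  A <- diag(S) - Q
  tlv <- tryCatch(solve(A, rep(1, S)),
                  error = function(e) NULL)
  if (is.null(tlv)) {
    # name the consumers unreachable from any basal species
    reach <- basal_species(net)
    repeat {
      nxt <- unique(tl$target[tl$source %in% reach])
      new <- setdiff(nxt, reach)
      if (!length(new)) break
      reach <- c(reach, new)
    }
    stop("trophic levels undefined: consumer cycle with no basal input ",
         "involving ", paste(setdiff(sp, reach), collapse = ", "))
  }
  stats::setNames(as.numeric(tlv), sp)
}

#' Per-service trophic level and redundancy
#'
#' Redundancy is the service node's in-degree (its provider count);
#' service trophic level is the unweighted mean of its providers'
#' prey-averaged trophic levels. Services with zero providers are reported
#' with redundancy 0 and undefined trophic level (they are excluded from
#' robustness denominators and regressions).
#'
#' @param net an `econet`.
#' @return data.frame with columns `service`, `redundancy`,
#'   `trophic_level`.
#' @export
service_stats <- function(net) {
  sv <- service_ids(net)
  pl <- provision_links(net)
  tl <- trophic_levels(net)
  red <- vapply(sv, function(s) sum(pl$target == s), 0L)
  stl <- vapply(sv, function(s) {
    prov <- pl$source[pl$target == s]
    if (!length(prov)) NA_real_ else mean(tl[prov])
  }, 0)
  data.frame(service = sv, redundancy = unname(red),
             trophic_level = unname(stl), stringsAsFactors = FALSE)
}
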
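#' Reverse the network for support-flow analysis
#'
#' Flips every edge: provision links run service -> provider and trophic
#' links run consumer -> prey, so a random walk started at a service node
#' descends through the species that directly or indirectly support it.
#' Self-loops are unchanged.
#'
#' @param net an `econet`.
#' @return data.frame of directed edges (`source`, `target`) over the full
#'   node set (species and services).
#' @export
reversed_graph <- function(net) {
  data.frame(source = net$links$target, target = net$links$source,
             stringsAsFactors = FALSE)
}

#' Personalized PageRank by power iteration
#'
#' Stationary distribution of a random walk that at each step terminates
#' (teleports back to the restart node) with probability `alpha` and
#' otherwise follows a uniformly random out-link; the mass of dangling
#' nodes (no out-links) is returned to the restart node. Solves
#' pi = alpha * v + (1 - alpha) * pi %*% M by power iteration until the L1
#' change drops below `tol`; scores are non-negative and sum to 1.
#'
#' Note on conventions: `alpha` here is the termination/teleport
#' probability, so the continuation (damping) factor is `1 - alpha`. Some
#' implementations instead name their parameter after the damping factor;
#' set `alpha_is_damping = TRUE` to interpret `alpha` that way.
#'
#' @param edges data.frame of directed edges (`source`, `target`), e.g.
#'   from [reversed_graph()], or an `econet` whose links are used as-is.
#' @param nodes character vector of all node ids (isolated nodes included).
#' @param restart id of the restart (personalization) node.
#' @param alpha teleport probability in (0, 1); default 0.15.
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration budget; exceeding it is an error reporting the
#'   residual.
#' @param alpha_is_damping treat `alpha` as the continuation probability.
#' @return named numeric vector of scores over `nodes`, summing to 1.
#' @examples
#' # two-node chain S -> P; P dangling
#' pr <- personalized_pagerank(
#'   data.frame(source = "S", target = "P"), c("S", "P"), "S")
#' pr["S"]  # 0.15 / (1 - 0.85^2) = 0.54054...
#' @export
personalized_pagerank <- function(edges, nodes, restart, alpha = 0.15,
                                  tol = 1e-12, max_iter = 10000,
                                  alpha_is_damping = FALSE) {
  if (inherits(edges, "econet")) {
    if (missing(nodes)) nodes <- edges$nodes$id
    edges <- edges$links
  }
  stopifnot(alpha > 0, alpha < 1, tol > 0)
  if (alpha_is_damping) alpha <- 1 - alpha
  n <- length(nodes)
  if (!restart %in% nodes) stop("restart node not in graph: ", restart)
  M <- transition_matrix(edges, nodes)
  v <- as.numeric(nodes == restart)
  ppr_core(M$M, M$dangling, v, alpha, tol, max_iter, nodes)
}

# row-stochastic out-link matrix (dense; webs here are small) plus the
# dangling-node indicator
transition_matrix <- function(edges, nodes) {
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    si <- match(edges$source, nodes)
    ti <- match(edges$target, nodes)
    if (anyNA(si) || anyNA(ti)) stop("edge endpoint not in node set")
    for (k in seq_along(si)) M[si[k], ti[k]] <- M[si[k], ti[k]] + 1
  }
  out <- rowSums(M)
  dangling <- out == 0
  M[!dangling, ] <- M[!dangling, , drop = FALSE] / out[!dangling]
  list(M = M, dangling = dangling)
}

ppr_core <- function(M, dangling, v, alpha, tol, max_iter, nodes) {
  pi <- v
  for (it in seq_len(max_iter)) {
    new_pi <- alpha * v +
      (1 - alpha) * (as.vector(pi %*% M) + sum(pi[dangling]) * v)
    delta <- sum(abs(new_pi - pi))
    pi <- new_pi
    if (delta < tol) return(stats::setNames(pi, nodes))
  }
  stop(sprintf("personalized PageRank did not converge in %d iterations (L1 residual %.3e)",
               max_iter, delta))
}

#' Supporting-species importance scores
#'
#' Ranks species by their indirect contribution to ecosystem services. For
#' each provided service the network is reversed and a personalized
#' PageRank is run with that service as the restart node, yielding one
#' score per species per service. A service's direct providers are then
#' marked undefined for that service (direct provision is not "support"),
#' and each species' mean score is taken over the services where it has a
#' defined entry. Species providing every service have no defined entries
#' and are excluded from the supporting target set. Service nodes never
#' appear in the output.
#'
#' @param net an `econet` with at least one provided service.
#' @param alpha,tol,max_iter,alpha_is_damping see [personalized_pagerank()].
#' @param rebuild_graph if `TRUE`, providers of a service are removed from
#'   the reversed graph before that service's walk is run, instead of being
#'   masked from the finished score list (the default).
#' @param zero_fill if `TRUE`, undefined (provider) entries enter the mean
#'   as 0 instead of being dropped.
#' @return object of class `importance_table`: list with `scores` (species
#'   x service matrix, `NA` where undefined) and `mean` (named vector of
#'   per-species means; `NA` when no entry is defined).
#' @export
supporting_scores <- function(net, alpha = 0.15, tol = 1e-12,
                              max_iter = 10000, alpha_is_damping = FALSE,
                              rebuild_graph = FALSE, zero_fill = FALSE) {
  if (alpha_is_damping) alpha <- 1 - alpha
  pl <- provision_links(net)
  provided <- intersect(service_ids(net), pl$target)
  if (!length(provided)) stop("network provides no services")
  sp <- species_ids(net)
  nodes <- net$nodes$id
  rev_edges <- reversed_graph(net)
  tm <- transition_matrix(rev_edges, nodes)
  scores <- matrix(NA_real_, length(sp), length(provided),
                   dimnames = list(sp, provided))
  for (s in provided) {
    prov_s <- pl$source[pl$target == s]
    if (rebuild_graph) {
      keep <- !(rev_edges$source %in% prov_s | rev_edges$target %in% prov_s)
      tms <- transition_matrix(rev_edges[keep, , drop = FALSE], nodes)
      pr <- ppr_core(tms$M, tms$dangling, as.numeric(nodes == s),
                     alpha, tol, max_iter, nodes)
    } else {
      pr <- ppr_core(tm$M, tm$dangling, as.numeric(nodes == s),
                     alpha, tol, max_iter, nodes)
    }
    scores[, s] <- pr[sp]
    scores[prov_s, s] <- NA_real_
  }
  if (zero_fill) {
    filled <- scores
    filled[is.na(filled)] <- 0
    mean_score <- rowMeans(filled)
  } else {
    mean_score <- rowMeans(scores, na.rm = TRUE)
    mean_score[rowSums(!is.na(scores)) == 0] <- NA_real_
  }
  structure(list(scores = scores, mean = mean_score, alpha = alpha),
            class = "importance_table")
}

#' @export
print.importance_table <- function(x, ...) {
  cat("supporting-species importance (personalized PageRank, alpha = ",
      x$alpha, ")\n", sep = "")
  cat("  ", nrow(x$scores), " species x ", ncol(x$scores), " services; ",
      sum(!is.na(x$mean)), " species with a defined mean score\n", sep = "")
  top <- sort(x$mean, decreasing = TRUE)
  top <- top[!is.na(top)]
  cat("  top supporters:",
      paste(utils::head(names(top), 5), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.importance_table <- function(x, ...) {
  df <- expand.grid(species = rownames(x$scores),
                    service = colnames(x$scores),
                    stringsAsFactors = FALSE)
  df$score <- as.vector(x$scores)
  df$mean_score <- x$mean[df$species]
  df
}
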
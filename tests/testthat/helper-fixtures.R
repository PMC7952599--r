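# fixtures built in code, and independent brute-force oracles

make_net <- function(species, trophic = NULL, provision = NULL,
                     biomass = NULL, abundance = NULL, vulnerable = NULL,
                     group = NULL, life_stage = NULL) {
  services <- unique(provision$target)
  ids <- c(species, services)
  nodes <- data.frame(
    id = ids, name = ids,
    node_type = c(rep("species", length(species)),
                  rep("service", length(services))),
    stringsAsFactors = FALSE)
  fill <- function(v, default) {
    out <- rep(default, length(ids))
    if (!is.null(v)) out[match(names(v), ids)] <- v
    out
  }
  nodes$biomass <- fill(biomass, NA_real_)
  nodes$abundance <- fill(abundance, NA_real_)
  nodes$vulnerable <- fill(vulnerable, NA)
  nodes$group <- fill(group, NA_character_)
  nodes$life_stage <- fill(life_stage, NA_character_)
  links <- rbind(
    if (!is.null(trophic))
      data.frame(source = trophic$source, target = trophic$target,
                 link_type = "trophic", stringsAsFactors = FALSE),
    if (!is.null(provision))
      data.frame(source = provision$source, target = provision$target,
                 link_type = "provision", stringsAsFactors = FALSE))
  if (is.null(links))
    links <- data.frame(source = character(), target = character(),
                        link_type = character())
  econet(nodes, links)
}

# three-level chain B -> H -> P with service S1 provided by P
chain_net <- function(with_service = TRUE, ...) {
  make_net(c("B", "H", "P"),
           trophic = data.frame(source = c("B", "H"), target = c("H", "P")),
           provision = if (with_service)
             data.frame(source = "P", target = "S1"),
           ...)
}

# diamond: B1, B2 -> C; service S provided by B1 (biomass 3) and B2 (1)
diamond_net <- function() {
  make_net(c("B1", "B2", "C"),
           trophic = data.frame(source = c("B1", "B2"), target = c("C", "C")),
           provision = data.frame(source = c("B1", "B2"), target = c("S", "S")),
           biomass = c(B1 = 3, B2 = 1, C = 2))
}

# random directed web over S species with ~L trophic links (no services)
random_web <- function(S, L, p_selfloop = 0.05) {
  ids <- sprintf("s%02d", seq_len(S))
  pairs <- expand.grid(source = ids, target = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target | runif(nrow(pairs)) < p_selfloop, ]
  pairs <- pairs[sample.int(nrow(pairs), min(L, nrow(pairs))), ]
  make_net(ids, trophic = pairs)
}

# brute-force secondary-extinction closure: recompute survivability from
# scratch by exhaustive iteration over the full species set
closure_oracle <- function(net, removed) {
  tl <- trophic_links(net)
  tl <- tl[tl$source != tl$target, , drop = FALSE]
  sp <- species_ids(net)
  basal <- basal_species(net)
  alive <- setdiff(sp, removed)
  repeat {
    dead <- vapply(alive, function(s) {
      if (s %in% basal) return(FALSE)
      res <- tl$source[tl$target == s]
      !any(res %in% alive)
    }, TRUE)
    if (!any(dead)) break
    alive <- alive[!dead]
  }
  setdiff(sp, c(alive, removed))
}

# direct linear solve of the personalized PageRank fixed point
# pi = alpha v + (1-alpha) (pi M + (pi . d) v)
ppr_solve_oracle <- function(edges, nodes, restart, alpha = 0.15) {
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges)))
    M[edges$source[k], edges$target[k]] <-
      M[edges$source[k], edges$target[k]] + 1
  out <- rowSums(M)
  d <- as.numeric(out == 0)
  M[out > 0, ] <- M[out > 0, , drop = FALSE] / out[out > 0]
  v <- as.numeric(nodes == restart)
  A <- diag(n) - (1 - alpha) * (M + outer(d, v))
  pi <- solve(t(A), alpha * v)
  stats::setNames(as.numeric(pi), nodes)
}

# prey-averaged trophic level by damped fixed-point iteration
tl_iter_oracle <- function(net, iters = 20000, tol = 1e-12) {
  sp <- species_ids(net)
  tl <- trophic_links(net)
  tl <- tl[tl$source != tl$target, , drop = FALSE]
  res <- split(tl$source, factor(tl$target, levels = sp))
  x <- stats::setNames(rep(1, length(sp)), sp)
  for (i in seq_len(iters)) {
    x_new <- vapply(sp, function(s) {
      r <- res[[s]]
      if (!length(r)) 1 else 1 + mean(x[r])
    }, 0)
    if (max(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  x
}

# all permutations of 1..n (for the exact Spearman oracle at small n)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

spearman_brute <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  P <- all_perms(length(x))
  rhos <- apply(P, 1, function(p) stats::cor(rx, ry[p]))
  p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  list(rho = rho, p = p)
}
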
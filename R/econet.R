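#' Ecological network with ecosystem-service nodes
#'
#' An `econet` couples a directed food web (trophic links stored
#' resource -> consumer, so that in-degree 0 literally means "no resources")
#' with ecosystem-service nodes attached by provision links
#' (provider species -> service, so that a service's redundancy is its
#' in-degree). Node attributes carry the biological metadata used by the
#' removal sequences: biomass and abundance densities, life stage, organismal
#' group, and a vulnerability flag.
#'
#' @param nodes data.frame with columns `id`, `name`, `node_type`
#'   (`"species"` or `"service"`), and optionally `biomass`, `abundance`,
#'   `life_stage`, `group`, `vulnerable`. Extra columns are preserved.
#' @param links data.frame with columns `source`, `target` and `link_type`
#'   (`"trophic"` or `"provision"`).
#' @return An object of class `econet`: a list with validated `nodes` and
#'   `links` data.frames. Self-loops (cannibalism) are permitted in trophic
#'   links and recorded in the `"self_loops"` attribute.
#' @examples
#' nodes <- data.frame(id = c("B", "H", "P", "S1"), name = c("B", "H", "P", "S1"),
#'                     node_type = c("species", "species", "species", "service"))
#' links <- data.frame(source = c("B", "H", "P"), target = c("H", "P", "S1"),
#'                     link_type = c("trophic", "trophic", "provision"))
#' net <- econet(nodes, links)
#' basal_species(net)
#' @export
econet <- function(nodes, links) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  links <- as.data.frame(links, stringsAsFactors = FALSE)

  req_n <- c("id", "name", "node_type")
  miss <- setdiff(req_n, names(nodes))
  if (length(miss))
    stop("node table is missing required column(s): ", paste(miss, collapse = ", "))
  req_l <- c("source", "target", "link_type")
  miss <- setdiff(req_l, names(links))
  if (length(miss))
    stop("link table is missing required column(s): ", paste(miss, collapse = ", "))

  for (col in c("biomass", "abundance")) {
    if (!col %in% names(nodes)) nodes[[col]] <- NA_real_
    nodes[[col]] <- as.numeric(nodes[[col]])
  }
  for (col in c("life_stage", "group")) {
    if (!col %in% names(nodes)) nodes[[col]] <- NA_character_
    nodes[[col]] <- as.character(nodes[[col]])
  }
  if (!"vulnerable" %in% names(nodes)) nodes$vulnerable <- NA
  nodes$vulnerable <- as.logical(nodes$vulnerable)
  nodes$id <- as.character(nodes$id)
  nodes$name <- as.character(nodes$name)
  nodes$node_type <- as.character(nodes$node_type)
  links$source <- as.character(links$source)
  links$target <- as.character(links$target)
  links$link_type <- as.character(links$link_type)

  if (anyDuplicated(nodes$id))
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  bad <- !nodes$node_type %in% c("species", "service")
  if (any(bad))
    stop("invalid node_type for node(s): ", paste(nodes$id[bad], collapse = ", "))
  bad <- !links$link_type %in% c("trophic", "provision")
  if (any(bad))
    stop("invalid link_type in link table row(s): ",
         paste(which(bad), collapse = ", "))

  neg <- !is.na(nodes$biomass) & nodes$biomass < 0
  if (any(neg)) stop("negative biomass for: ", paste(nodes$id[neg], collapse = ", "))
  neg <- !is.na(nodes$abundance) & nodes$abundance < 0
  if (any(neg)) stop("negative abundance for: ", paste(nodes$id[neg], collapse = ", "))

  sp <- nodes$id[nodes$node_type == "species"]
  sv <- nodes$id[nodes$node_type == "service"]

  dangling <- !(links$source %in% nodes$id) | !(links$target %in% nodes$id)
  if (any(dangling))
    stop("link endpoint(s) not in node table, row(s): ",
         paste(which(dangling), collapse = ", "))

  tro <- links$link_type == "trophic"
  bad <- tro & (!(links$source %in% sp) | !(links$target %in% sp))
  if (any(bad))
    stop("trophic link(s) must connect species to species, row(s): ",
         paste(which(bad), collapse = ", "))
  pro <- links$link_type == "provision"
  bad <- pro & (!(links$source %in% sp) | !(links$target %in% sv))
  if (any(bad))
    stop("provision link(s) must run provider species -> service, row(s): ",
         paste(which(bad), collapse = ", "))

  key <- paste(links$source, links$target, links$link_type, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate link(s), row(s): ",
         paste(which(duplicated(key)), collapse = ", "))

  net <- structure(list(nodes = nodes, links = links), class = "econet")
  attr(net, "self_loops") <-
    links$source[tro & links$source == links$target]
  net
}

#' @export
print.econet <- function(x, ...) {
  sp <- species_ids(x)
  sv <- service_ids(x)
  tl <- trophic_links(x)
  pl <- provision_links(x)
  cat("econet: ", length(sp), " species, ", length(sv), " services, ",
      nrow(tl), " trophic links, ", nrow(pl), " provision links\n", sep = "")
  cat("  basal species: ", length(basal_species(x)),
      "; connectance L/S^2 = ",
      signif(nrow(tl) / max(length(sp), 1)^2, 3), "\n", sep = "")
  sl <- attr(x, "self_loops")
  if (length(sl)) cat("  self-loops (cannibalism):", length(sl), "\n")
  invisible(x)
}

#' @export
summary.econet <- function(object, ...) {
  print(object)
  red <- table(factor(provision_links(object)$target, levels = service_ids(object)))
  if (length(red)) {
    cat("  service redundancy:\n")
    for (s in names(red)) cat("    ", s, ": ", red[[s]], " providers\n", sep = "")
  }
  invisible(object)
}

#' @rdname econet
#' @param net an `econet` object.
#' @export
species_ids <- function(net) net$nodes$id[net$nodes$node_type == "species"]

#' @rdname econet
#' @export
service_ids <- function(net) net$nodes$id[net$nodes$node_type == "service"]

#' @rdname econet
#' @export
trophic_links <- function(net) net$links[net$links$link_type == "trophic", , drop = FALSE]

#' @rdname econet
#' @export
provision_links <- function(net) net$links[net$links$link_type == "provision", , drop = FALSE]

#' Basal species of a food web
#'
#' Species with no resources: zero trophic in-degree after discarding
#' self-loops (a cannibal cannot sustain itself). Basal species cannot go
#' secondarily extinct in the bottom-up cascade model and are excluded from
#' the susceptible-species denominator.
#'
#' @param net an `econet`.
#' @return character vector of species ids, in node-table order.
#' @export
basal_species <- function(net) {
  sp <- species_ids(net)
  tl <- trophic_links(net)
  tl <- tl[tl$source != tl$target, , drop = FALSE]
  sp[!sp %in% tl$target]
}

#' Read an ecological network from node and link tables
#'
#' Ingests the two-file CSV exchange format: a node table
#' (`id,name,node_type,biomass,abundance,life_stage,group,vulnerable`) and a
#' link table (`source,target,link_type`). Empty fields are read as missing,
#' never as zero.
#'
#' @param node_file,link_file paths to CSV files with header rows.
#' @return a validated [econet()].
#' @examples
#' nf <- system.file("extdata", "example", "chain_nodes.csv",
#'                   package = "servweb")
#' lf <- system.file("extdata", "example", "chain_links.csv",
#'                   package = "servweb")
#' net <- read_network(nf, lf)
#' summary(net)
#' @export
read_network <- function(node_file, link_file) {
  nodes <- utils::read.csv(node_file, stringsAsFactors = FALSE, na.strings = "")
  links <- utils::read.csv(link_file, stringsAsFactors = FALSE, na.strings = "")
  if (nrow(links) == 0)
    links <- data.frame(source = character(), target = character(),
                        link_type = character(), stringsAsFactors = FALSE)
  econet(nodes, links)
}

#' Write an ecological network to node and link tables
#'
#' Inverse of [read_network()]: writes `<stem>_nodes.csv` and
#' `<stem>_links.csv`. Numeric attributes are written at full double
#' precision so that a read/write round trip is lossless; missing values are
#' written as empty fields. Optionally also writes a GraphML file (via
#' igraph) carrying node type and attributes for visualisation tools.
#'
#' @param net an `econet`.
#' @param stem path stem; files `<stem>_nodes.csv` / `<stem>_links.csv` are
#'   created (and `<stem>.graphml` when `graphml = TRUE`).
#' @param graphml also write a GraphML export.
#' @return invisibly, a character vector of the paths written.
#' @export
write_network <- function(net, stem, graphml = FALSE) {
  nodes <- net$nodes
  for (col in names(nodes)) {
    if (is.numeric(nodes[[col]])) {
      v <- sprintf("%.17g", nodes[[col]])
      v[is.na(nodes[[col]])] <- NA
      nodes[[col]] <- v
    }
  }
  node_path <- paste0(stem, "_nodes.csv")
  link_path <- paste0(stem, "_links.csv")
  utils::write.csv(nodes, node_path, row.names = FALSE, na = "")
  utils::write.csv(net$links, link_path, row.names = FALSE, na = "")
  paths <- c(node_path, link_path)
  if (graphml) {
    g_path <- paste0(stem, ".graphml")
    igraph::write_graph(as_igraph(net), g_path, format = "graphml")
    paths <- c(paths, g_path)
  }
  invisible(paths)
}

#' Convert an econet to an igraph graph
#'
#' Directed graph over species and service nodes; edge attribute `link_type`
#' distinguishes trophic from provision links.
#'
#' @param net an `econet`.
#' @return an `igraph` graph.
#' @export
as_igraph <- function(net) {
  vatt <- net$nodes
  # display name goes under "label"; igraph reserves "name" for the vertex id
  vatt <- data.frame(name = vatt$id, label = vatt$name,
                     vatt[setdiff(names(vatt), c("id", "name"))],
                     stringsAsFactors = FALSE)
  vatt$vulnerable <- as.character(vatt$vulnerable)
  igraph::graph_from_data_frame(net$links, directed = TRUE, vertices = vatt)
}

#' Filter a network to the analysis community
#'
#' Restricts the web to the species actually analysed, e.g. dropping
#' parasites and non-living resources (detritus) and keeping only adult
#' stages, then returns the induced subnetwork. Service nodes are always
#' retained; a service left with no providers is kept but triggers a
#' warning (it is later excluded from robustness denominators).
#'
#' @param net an `econet`.
#' @param drop_groups character vector of `group` values to remove
#'   (e.g. `c("parasite", "detritus")`), or `NULL`.
#' @param keep_stages character vector of `life_stage` values to retain
#'   (e.g. `"adult"`), or `NULL` to retain all stages.
#' @return the induced `econet`.
#' @export
filter_network <- function(net, drop_groups = NULL, keep_stages = NULL) {
  sp <- net$nodes$node_type == "species"
  keep <- rep(TRUE, nrow(net$nodes))
  if (!is.null(drop_groups)) {
    if (any(sp & is.na(net$nodes$group)))
      stop("group attribute missing for: ",
           paste(net$nodes$id[sp & is.na(net$nodes$group)], collapse = ", "))
    keep <- keep & !(sp & net$nodes$group %in% drop_groups)
  }
  if (!is.null(keep_stages)) {
    if (any(sp & is.na(net$nodes$life_stage)))
      stop("life_stage attribute missing for: ",
           paste(net$nodes$id[sp & is.na(net$nodes$life_stage)], collapse = ", "))
    keep <- keep & !(sp & !net$nodes$life_stage %in% keep_stages)
  }
  if (!any(keep & sp)) stop("filter removes all species")
  nodes <- net$nodes[keep, , drop = FALSE]
  ok <- net$links$source %in% nodes$id & net$links$target %in% nodes$id
  links <- net$links[ok, , drop = FALSE]
  out <- econet(nodes, links)
  lost <- setdiff(service_ids(out), provision_links(out)$target)
  if (length(lost))
    warning("service(s) retained with zero providers after filtering: ",
            paste(lost, collapse = ", "))
  out
}
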
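# Edge filtering, modularity-based module detection and descriptive
# statistics on the basis-correlation network.

#' Build the filtered correlation network
#'
#' An edge joins OTUs i and j when |rho_ij| exceeds the threshold
#' (strictly by default; \code{inclusive = TRUE} uses >=) and the
#' pseudo-p is below alpha. Negative correlations passing the |rho| rule
#' are retained with their sign as the edge weight.
#'
#' @param rho symmetric basis-correlation matrix with unit diagonal
#' @param p symmetric pseudo-p matrix (diagonal ignored)
#' @param rho_threshold correlation magnitude threshold (default 0.6)
#' @param alpha significance level (default 0.05)
#' @param inclusive use |rho| >= threshold instead of strict >
#' @param taxonomy optional character vector of node taxonomies
#' @return a \linkS4class{CorrelationNetwork}
#' @export
buildNetwork <- function(rho, p, rho_threshold = 0.6, alpha = 0.05,
                         inclusive = FALSE, taxonomy = NULL) {
  stopifnot(all(dim(rho) == dim(p)))
  nodes <- rownames(rho)
  if (is.null(nodes)) {
    nodes <- paste0("OTU_", seq_len(nrow(rho)))
    dimnames(rho) <- dimnames(p) <- list(nodes, nodes)
  }
  if (is.null(taxonomy)) taxonomy <- rep(NA_character_, length(nodes))
  pass <- if (inclusive) abs(rho) >= rho_threshold else abs(rho) > rho_threshold
  pass <- pass & (p < alpha)
  pass[lower.tri(pass, diag = TRUE)] <- FALSE
  idx <- which(pass, arr.ind = TRUE)
  edges <- data.frame(
    source = nodes[idx[, 1]],
    target = nodes[idx[, 2]],
    rho = rho[idx],
    p = p[idx],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  new("CorrelationNetwork", rho = rho, pseudoP = p, edges = edges,
      nodes = nodes, taxonomy = taxonomy,
      modules = integer(), modularity = NA_real_,
      params = list(rho_threshold = rho_threshold, alpha = alpha,
                    inclusive = inclusive))
}

.asIgraph <- function(network, weights = c("abs", "signed")) {
  weights <- match.arg(weights)
  e <- network@edges
  g <- igraph::graph_from_data_frame(
    d = if (nrow(e)) data.frame(from = e$source, to = e$target,
                                weight = if (weights == "abs") abs(e$rho)
                                         else e$rho)
        else data.frame(from = character(), to = character(),
                        weight = numeric()),
    directed = FALSE,
    vertices = data.frame(name = network@nodes,
                          taxonomy = network@taxonomy))
  g
}

#' Detect modules by modularity maximization
#'
#' Louvain-style multilevel modularity maximization (resolution 1) on the
#' filtered network, with |rho| edge weights. Node ordering is the row
#' order of the rho matrix and the RNG is seeded, so the partition is
#' deterministic for a given seed. Isolated nodes form singleton modules.
#' On an empty network every node is its own module and Q = 0.
#'
#' @param network a \linkS4class{CorrelationNetwork}
#' @param seed integer seed
#' @return the network with \code{modules} (named node -> module id) and
#'   \code{modularity} filled in
#' @export
detectModules <- function(network, seed = 1) {
  g <- .asIgraph(network, "abs")
  if (nrow(network@edges) == 0) {
    network@modules <- setNames(seq_along(network@nodes), network@nodes)
    network@modularity <- 0
    return(network)
  }
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = 1)
  mem <- igraph::membership(cl)
  network@modules <- setNames(as.integer(mem), names(mem))[network@nodes]
  names(network@modules) <- network@nodes
  network@modularity <- igraph::modularity(g, mem,
                                           weights = igraph::E(g)$weight)
  network@edges$module <- ifelse(
    network@modules[network@edges$source] ==
      network@modules[network@edges$target],
    network@modules[network@edges$source], NA_integer_)
  network
}

#' Node and network descriptive statistics
#'
#' @param network a \linkS4class{CorrelationNetwork}
#' @return list with \code{nodes} (data.frame: node, degree,
#'   weighted_degree, clustering_coefficient, module) and \code{global}
#'   (n_nodes, n_edges, n_modules, modularity)
#' @export
networkStats <- function(network) {
  g <- .asIgraph(network, "abs")
  deg <- igraph::degree(g)
  wdeg <- igraph::strength(g)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  nodes <- data.frame(
    node = network@nodes,
    degree = as.integer(deg[network@nodes]),
    weighted_degree = as.numeric(wdeg[network@nodes]),
    clustering_coefficient = as.numeric(cc[match(network@nodes,
                                                 igraph::V(g)$name)]),
    module = if (length(network@modules))
      as.integer(network@modules[network@nodes]) else NA_integer_,
    stringsAsFactors = FALSE
  )
  list(nodes = nodes,
       global = list(n_nodes = length(network@nodes),
                     n_edges = nrow(network@edges),
                     n_modules = if (length(network@modules))
                       length(unique(network@modules)) else NA_integer_,
                     modularity = network@modularity))
}

#' Extract the focal OTU's module neighbourhood
#'
#' Returns the focal OTU plus the nodes of its module that have a direct
#' edge to it, with those edges — the subnetwork a partner search
#' inspects.
#'
#' @param network a \linkS4class{CorrelationNetwork} with modules detected
#' @param focal_otu focal node id
#' @return list with \code{nodes} (character, focal first) and
#'   \code{edges} (data.frame, the focal's direct edges within its module)
#' @export
extractFocalModule <- function(network, focal_otu) {
  if (!focal_otu %in% network@nodes)
    .fail("focal OTU '%s' is not in the network", focal_otu)
  if (!length(network@modules))
    network <- detectModules(network)
  mod <- network@modules[[focal_otu]]
  e <- network@edges
  touch <- e$source == focal_otu | e$target == focal_otu
  other <- ifelse(e$source == focal_otu, e$target, e$source)
  keep <- touch & network@modules[other] == mod
  nbrs <- other[keep]
  list(nodes = c(focal_otu, sort(nbrs)),
       edges = e[keep, , drop = FALSE])
}

#' Write the network as GraphML with node attributes
#'
#' @param network a \linkS4class{CorrelationNetwork}
#' @param path output file path
#' @return the path, invisibly
#' @export
writeGraphML <- function(network, path) {
  g <- .asIgraph(network, "signed")
  if (length(network@modules))
    igraph::V(g)$module <- as.integer(network@modules[igraph::V(g)$name])
  igraph::V(g)$degree <- igraph::degree(g)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
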
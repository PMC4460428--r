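#' Characteristic path length
#'
#' Mean shortest-path length over all ordered pairs of distinct nodes that
#' are reachable from one another. Unreachable pairs are excluded from the
#' average; their count is attached as attribute \code{"n_unreachable"}.
#'
#' @param net A \code{\link{brain_network}}.
#' @return Mean shortest-path length (single number).
#' @export
characteristic_path_length <- function(net) {
  D <- igraph::distances(to_igraph(net))
  off <- D[row(D) != col(D)]
  reach <- is.finite(off)
  if (!any(reach)) stop("no reachable node pairs", call. = FALSE)
  if (!all(reach))
    an_log(sum(!reach), " unreachable ordered pairs excluded from path length")
  structure(mean(off[reach]), n_unreachable = sum(!reach))
}

#' Clustering coefficient
#'
#' Nodal value: fraction of realized edges among a node's neighbours,
#' \code{2 t_i / (k_i (k_i - 1))}, defined as 0 for degree < 2. Graph value:
#' mean over nodes.
#'
#' @param net A \code{\link{brain_network}}.
#' @param nodal If TRUE return the per-node values instead of the mean.
#' @export
clustering_coefficient <- function(net, nodal = FALSE) {
  cc <- igraph::transitivity(to_igraph(net), type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  names(cc) <- net$region_ids
  if (nodal) cc else mean(cc)
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with
#' \code{1 / Inf = 0}, so disconnection is handled natively. Nodal value:
#' mean inverse distance from one node to all others.
#'
#' @inheritParams clustering_coefficient
#' @export
global_efficiency <- function(net, nodal = FALSE) {
  D <- igraph::distances(to_igraph(net))
  iD <- 1 / D
  diag(iD) <- 0
  n <- nrow(iD)
  nod <- rowSums(iD) / (n - 1)
  names(nod) <- net$region_ids
  if (nodal) nod else mean(nod)
}

#' Local efficiency
#'
#' Nodal value: global efficiency of the subgraph induced on the node's
#' neighbours (0 with fewer than two neighbours). Graph value: mean over
#' nodes.
#'
#' @inheritParams clustering_coefficient
#' @export
local_efficiency <- function(net, nodal = FALSE) {
  A <- net$adjacency
  n <- nrow(A)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1L)
    if (length(nb) < 2L) next
    sub <- brain_network(A[nb, nb, drop = FALSE],
                         region_ids = net$region_ids[nb])
    vals[i] <- global_efficiency(sub)
  }
  names(vals) <- net$region_ids
  if (nodal) vals else mean(vals)
}

#' Betweenness centrality
#'
#' Shortest-path betweenness with fractional counting over equal-length
#' shortest paths, normalized by \code{(N - 1)(N - 2) / 2}, the number of
#' node pairs excluding the node itself.
#'
#' @inheritParams clustering_coefficient
#' @export
betweenness_centrality <- function(net, nodal = FALSE) {
  n <- length(net$region_ids)
  b <- igraph::betweenness(to_igraph(net), directed = FALSE)
  norm <- (n - 1) * (n - 2) / 2
  b <- if (norm > 0) b / norm else b * 0
  names(b) <- net$region_ids
  if (nodal) b else mean(b)
}

#' Degree assortativity
#'
#' Pearson correlation between the degrees at either end of an edge, each
#' edge counted in both orientations. Undefined (NA, with a warning) when
#' the degrees carry no variance, e.g. for regular graphs.
#'
#' @param net A \code{\link{brain_network}}.
#' @export
assortativity_coefficient <- function(net) {
  if (n_edges(net) < 2L)
    stop("assortativity needs at least 2 edges", call. = FALSE)
  deg <- node_degrees(net)
  ends <- which(net$adjacency == 1L, arr.ind = TRUE)  # both orientations
  if (stats::var(deg[ends[, 1]]) == 0 || stats::var(deg[ends[, 2]]) == 0) {
    warning("assortativity undefined: no degree variance across edge ends")
    return(NA_real_)
  }
  igraph::assortativity_degree(to_igraph(net), directed = FALSE)
}

#' Newman modularity by seeded multilevel optimization
#'
#' Best partition found by the greedy multilevel (Louvain) heuristic over
#' \code{n_restarts} seeded restarts; deterministic given \code{seed}.
#'
#' @param net A \code{\link{brain_network}} with at least one edge.
#' @param n_restarts Number of seeded restarts.
#' @param seed Integer seed.
#' @return List with \code{Q} (modularity of the best partition) and
#'   \code{membership} (named integer vector).
#' @export
graph_modularity <- function(net, n_restarts = 20L, seed = 1L) {
  if (n_edges(net) < 1L) stop("modularity needs at least one edge",
                              call. = FALSE)
  g <- to_igraph(net)
  best_q <- -Inf
  best_m <- NULL
  for (r in seq_len(n_restarts)) {
    cl <- withr::with_seed(mix_seed(seed, r), igraph::cluster_louvain(g))
    q <- igraph::modularity(g, igraph::membership(cl))
    if (q > best_q) {
      best_q <- q
      best_m <- as.integer(igraph::membership(cl))
    }
  }
  names(best_m) <- net$region_ids
  list(Q = best_q, membership = best_m)
}

#' All seven whole-network measures plus nodal values
#'
#' Convenience wrapper returning the seven graph-level measures
#' (characteristic path length, clustering coefficient, global and local
#' efficiency, mean betweenness, assortativity, modularity) together with
#' the per-region nodal table, and lobar averages when a lobe map is given.
#'
#' @param net A \code{\link{brain_network}}.
#' @param lobe_map Optional region-to-lobe table (see
#'   \code{\link{aal90_lobe_map}}).
#' @param n_restarts,seed Passed to \code{\link{graph_modularity}}.
#' @return Object of class \code{metrics_record}: list with \code{global}
#'   (named numeric of length 7), \code{nodal} (data.frame), and
#'   \code{lobar} (data.frame or NULL).
#' @export
network_metrics <- function(net, lobe_map = NULL, n_restarts = 20L,
                            seed = 1L) {
  geff_nod <- global_efficiency(net, nodal = TRUE)
  cc_nod <- clustering_coefficient(net, nodal = TRUE)
  leff_nod <- local_efficiency(net, nodal = TRUE)
  btw_nod <- betweenness_centrality(net, nodal = TRUE)
  assort <- tryCatch(suppressWarnings(assortativity_coefficient(net)),
                     error = function(e) NA_real_)
  glob <- c(char_path_length = as.numeric(characteristic_path_length(net)),
            clustering_coeff = mean(cc_nod),
            global_efficiency = mean(geff_nod),
            local_efficiency = mean(leff_nod),
            betweenness_mean = mean(btw_nod),
            assortativity = assort,
            modularity = graph_modularity(net, n_restarts, seed)$Q)
  nodal <- data.frame(region = net$region_ids,
                      degree = as.numeric(node_degrees(net)),
                      clustering = as.numeric(cc_nod),
                      local_eff = as.numeric(leff_nod),
                      betweenness = as.numeric(btw_nod),
                      nodal_global_eff = as.numeric(geff_nod),
                      stringsAsFactors = FALSE)
  lobar <- if (!is.null(lobe_map)) lobar_average(nodal, lobe_map) else NULL
  structure(list(global = glob, nodal = nodal, lobar = lobar),
            class = "metrics_record")
}

#' Average nodal values within lobe-by-hemisphere cells
#'
#' @param nodal Either a named numeric vector of nodal values or a
#'   data.frame with a \code{region} column and numeric metric columns.
#' @param lobe_map Region metadata (columns region, hemisphere, lobe).
#' @return data.frame with one row per lobe x hemisphere cell and the mean
#'   of each metric in that cell.
#' @export
lobar_average <- function(nodal, lobe_map) {
  validate_lobe_map(lobe_map)
  if (is.numeric(nodal) && !is.null(names(nodal)))
    nodal <- data.frame(region = names(nodal), value = as.numeric(nodal),
                        stringsAsFactors = FALSE)
  stopifnot(is.data.frame(nodal), "region" %in% names(nodal))
  unmapped <- setdiff(nodal$region, lobe_map$region)
  if (length(unmapped))
    stop("regions not in lobe map: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  idx <- match(nodal$region, lobe_map$region)
  cells <- interaction(lobe_map$lobe[idx], lobe_map$hemisphere[idx],
                       sep = ".", drop = TRUE)
  metric_cols <- setdiff(names(nodal), "region")
  agg <- stats::aggregate(nodal[metric_cols], by = list(cell = cells), mean)
  parts <- do.call(rbind, strsplit(as.character(agg$cell), ".", fixed = TRUE))
  out <- data.frame(lobe = parts[, 1], hemisphere = parts[, 2],
                    agg[metric_cols], stringsAsFactors = FALSE)
  out[order(out$lobe, out$hemisphere), , drop = FALSE]
}
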
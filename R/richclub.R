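#' Rich-club subgraph at degree threshold k
#'
#' Retains the nodes whose degree in the full network is at least \code{k}
#' (a single removal pass: degrees are not recomputed after removal) and
#' counts the edges among them.
#'
#' @param net A \code{\link{brain_network}}.
#' @param k Degree threshold (>= 0).
#' @return List: \code{regions} (names retained), \code{n_nodes},
#'   \code{n_edges}.
#' @export
rich_club_subgraph <- function(net, k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  keep <- which(node_degrees(net) >= k)
  e <- if (length(keep) > 1L)
    sum(net$adjacency[keep, keep]) / 2 else 0
  list(regions = net$region_ids[keep], n_nodes = length(keep),
       n_edges = as.integer(e))
}

#' Rich-club coefficient
#'
#' \deqn{\Phi(k) = \frac{2 E_{\ge k}}{N_{\ge k} (N_{\ge k} - 1)}}
#' the edge density among the nodes of degree at least \code{k}. Undefined
#' (NA, with attribute \code{"reason"}) when fewer than two nodes survive.
#'
#' @inheritParams rich_club_subgraph
#' @return Phi(k) in [0, 1], or NA if undefined.
#' @export
#' @examples
#' # a complete K5: every node has degree 4, Phi(4) = 1
#' A <- matrix(1, 5, 5); diag(A) <- 0
#' rich_club_coefficient(brain_network(A), 4)
rich_club_coefficient <- function(net, k) {
  sg <- rich_club_subgraph(net, k)
  if (sg$n_nodes < 2L)
    return(structure(NA_real_, reason = "fewer than 2 nodes retained"))
  2 * sg$n_edges / (sg$n_nodes * (sg$n_nodes - 1))
}

#' Degree-preserving randomization by double-edge swaps
#'
#' Repeatedly picks two edges (a,b), (c,d) and replaces them with (a,d),
#' (c,b) whenever this creates neither a self-loop nor a duplicate edge,
#' until \code{n_swaps} successful swaps have been made. The degree
#' sequence is exactly preserved. If no valid swap can be found (checked by
#' an attempt cap), the graph is returned as-is.
#'
#' @param net A \code{\link{brain_network}} with at least 2 edges.
#' @param n_swaps Number of successful swaps; default 10 x edge count.
#' @param seed Integer seed; the result is deterministic given it.
#' @return A rewired \code{\link{brain_network}}.
#' @export
rewire_preserving_degree <- function(net, n_swaps = 10L * n_edges(net),
                                     seed = 1L) {
  m <- n_edges(net)
  if (m < 2L) {
    an_log("fewer than 2 edges: returning the network unchanged")
    return(net)
  }
  n <- length(net$region_ids)
  A <- net$adjacency == 1L
  el <- which(upper.tri(A) & A, arr.ind = TRUE)
  withr::with_seed(seed, {
    done <- 0L
    attempts <- 0L
    max_attempts <- max(100L * n_swaps, 1000L)
    while (done < n_swaps && attempts < max_attempts) {
      attempts <- attempts + 1L
      e <- sample.int(m, 2L)
      a <- el[e[1L], 1L]; b <- el[e[1L], 2L]
      c <- el[e[2L], 1L]; d <- el[e[2L], 2L]
      if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      # propose (a,d) and (c,b)
      if (a == d || c == b || A[a, d] || A[c, b]) next
      A[a, b] <- A[b, a] <- FALSE
      A[c, d] <- A[d, c] <- FALSE
      A[a, d] <- A[d, a] <- TRUE
      A[c, b] <- A[b, c] <- TRUE
      el[e[1L], ] <- c(min(a, d), max(a, d))
      el[e[2L], ] <- c(min(c, b), max(c, b))
      done <- done + 1L
    }
    if (done < n_swaps)
      an_log("no further valid swaps found after ", attempts,
             " attempts (", done, "/", n_swaps, " swaps done)")
  })
  out <- brain_network(A * 1L, region_ids = net$region_ids,
                       provenance = net$provenance)
  out
}

#' Normalized rich-club curve with a rewiring null ensemble
#'
#' For each degree threshold k, compares the observed rich-club coefficient
#' to its distribution over \code{n_random} degree-preserving rewired
#' networks: \code{phi_norm(k) = phi(k) / mean(null phi(k))}, with a
#' permutation p-value in the add-one form
#' \code{(1 + #\{null >= observed\}) / (1 + n_defined)} so p can never be
#' exactly zero. Thresholds where the observed or all null coefficients are
#' undefined are flagged in the \code{defined} column, not dropped.
#'
#' @param net A \code{\link{brain_network}}.
#' @param k_values Degree thresholds (default 1:15).
#' @param n_random Size of the null ensemble (the reference analysis uses
#'   1000; smaller ensembles are fine for exploration).
#' @param n_swaps Successful swaps per null network; default 10 x edges.
#' @param seed Integer seed for the ensemble.
#' @return Object of class \code{rich_club_curve}: a data.frame with
#'   columns k, n_nodes, n_edges, phi, phi_random, phi_norm, perm_p,
#'   defined; the null matrix, ensemble size and seed are attached as
#'   attributes (\code{"null_phi"}, \code{"n_random"}, \code{"seed"}).
#' @export
normalized_rich_club <- function(net, k_values = 1:15, n_random = 1000L,
                                 n_swaps = 10L * n_edges(net), seed = 1L) {
  if (n_random < 1L) stop("n_random must be >= 1", call. = FALSE)
  obs <- vapply(k_values, function(k) as.numeric(rich_club_coefficient(net, k)),
                numeric(1))
  sg <- lapply(k_values, function(k) rich_club_subgraph(net, k))
  null_phi <- matrix(NA_real_, n_random, length(k_values))
  for (r in seq_len(n_random)) {
    rn <- rewire_preserving_degree(net, n_swaps = n_swaps,
                                   seed = mix_seed(seed, r))
    null_phi[r, ] <- vapply(k_values, function(k)
      as.numeric(rich_club_coefficient(rn, k)), numeric(1))
  }
  phi_random <- colMeans(null_phi, na.rm = TRUE)
  phi_random[!is.finite(phi_random)] <- NA_real_
  n_def <- colSums(!is.na(null_phi))
  perm_p <- vapply(seq_along(k_values), function(j) {
    if (is.na(obs[j]) || n_def[j] == 0L) return(NA_real_)
    (1 + sum(null_phi[, j] >= obs[j], na.rm = TRUE)) / (1 + n_def[j])
  }, numeric(1))
  out <- data.frame(k = k_values,
                    n_nodes = vapply(sg, `[[`, integer(1), "n_nodes"),
                    n_edges = vapply(sg, `[[`, integer(1), "n_edges"),
                    phi = obs,
                    phi_random = phi_random,
                    phi_norm = obs / phi_random,
                    perm_p = perm_p,
                    defined = !is.na(obs) & !is.na(phi_random))
  attr(out, "null_phi") <- null_phi
  attr(out, "n_random") <- n_random
  attr(out, "seed") <- seed
  class(out) <- c("rich_club_curve", "data.frame")
  out
}

#' Rich-club membership for reporting
#'
#' Named regions and induced edge list of the degree->=k subgraph, suitable
#' for export to plotting tools.
#'
#' @inheritParams rich_club_subgraph
#' @return List: \code{regions} and \code{edges} (data.frame region_a,
#'   region_b).
#' @export
rich_club_membership <- function(net, k) {
  sg <- rich_club_subgraph(net, k)
  keep <- match(sg$regions, net$region_ids)
  sub <- net$adjacency[keep, keep, drop = FALSE]
  ut <- which(upper.tri(sub) & sub == 1L, arr.ind = TRUE)
  edges <- data.frame(region_a = sg$regions[ut[, 1]],
                      region_b = sg$regions[ut[, 2]],
                      stringsAsFactors = FALSE)
  list(regions = sg$regions, edges = edges)
}

#' Construct a graph whose rich club has prescribed size
#'
#' Builds a deterministic test graph whose degree->=k subgraph contains
#' exactly \code{n_core} nodes and \code{e_core} edges: the core carries a
#' circulant edge pattern, and peripheral nodes of degree < k are added to
#' lift every core node to degree at least k. Useful for validating the
#' rich-club computation against published (N, E) pairs.
#'
#' @param n_core Number of core nodes.
#' @param e_core Number of edges among core nodes; at most
#'   \code{n_core (n_core - 1) / 2}.
#' @param k Degree threshold the core must survive (default 9).
#' @return A \code{\link{brain_network}}.
#' @export
rich_club_testbed <- function(n_core, e_core, k = 9L) {
  stopifnot(n_core >= 2L, e_core >= 0L,
            e_core <= n_core * (n_core - 1) / 2)
  # circulant core: connect offsets 1, 2, ... until e_core edges placed
  A <- matrix(0L, n_core, n_core)
  placed <- 0L
  offset <- 1L
  while (placed < e_core) {
    for (i in seq_len(n_core)) {
      j <- ((i + offset - 1L) %% n_core) + 1L
      if (i != j && !A[i, j]) {
        A[i, j] <- A[j, i] <- 1L
        placed <- placed + 1L
        if (placed == e_core) break
      }
    }
    offset <- offset + 1L
    if (offset >= n_core) break
  }
  if (placed < e_core) stop("could not place requested core edges",
                            call. = FALSE)
  deficit <- pmax(0L, k - rowSums(A))
  # peripheral nodes absorb spokes, at most k - 1 each so they stay below k
  periph <- list()
  while (any(deficit > 0L)) {
    take <- order(-deficit)[seq_len(min(k - 1L, sum(deficit > 0L)))]
    take <- take[deficit[take] > 0L]
    periph[[length(periph) + 1L]] <- take
    deficit[take] <- deficit[take] - 1L
  }
  n <- n_core + length(periph)
  full <- matrix(0L, n, n)
  full[seq_len(n_core), seq_len(n_core)] <- A
  for (p in seq_along(periph)) {
    row <- n_core + p
    full[row, periph[[p]]] <- 1L
    full[periph[[p]], row] <- 1L
  }
  ids <- c(sprintf("core_%02d", seq_len(n_core)),
           if (length(periph)) sprintf("periph_%02d", seq_along(periph)))
  brain_network(full, region_ids = ids,
                provenance = sprintf("testbed N=%d E=%d", n_core, e_core))
}

#' Embed a dense core in a sparse random periphery
#'
#' Planted rich-club construction for power checks: a complete core of
#' \code{n_core} nodes inside an Erdos-Renyi periphery, with sparse
#' core-periphery attachment.
#'
#' @param n_core Core size (complete subgraph).
#' @param n_total Total nodes.
#' @param p_periphery Edge probability among/to peripheral nodes.
#' @param seed Integer seed.
#' @return A \code{\link{brain_network}}.
#' @export
plant_rich_club <- function(n_core = 8L, n_total = 60L, p_periphery = 0.05,
                            seed = 1L) {
  stopifnot(n_core >= 2L, n_total > n_core)
  withr::with_seed(seed, {
    A <- matrix(0L, n_total, n_total)
    A[seq_len(n_core), seq_len(n_core)] <- 1L
    rest <- which(upper.tri(A) & (row(A) > n_core | col(A) > n_core))
    A[rest] <- stats::rbinom(length(rest), 1L, p_periphery)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    diag(A) <- 0L
  })
  brain_network(A, provenance = sprintf("planted core K%d", n_core))
}
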
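#' Binary undirected brain network
#'
#' Light container for a thresholded network: a 0/1 symmetric adjacency
#' matrix with zero diagonal, the ordered region ids, the realized edge
#' density \code{2E / (N (N - 1))}, and a provenance label (subject or
#' group).
#'
#' @param adjacency 0/1 symmetric matrix, zero diagonal.
#' @param region_ids Ordered region names; defaults to adjacency dimnames.
#' @param provenance Free-text label recording what the network represents.
#' @return Object of class \code{brain_network}.
#' @export
brain_network <- function(adjacency, region_ids = rownames(adjacency),
                          provenance = NA_character_) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  if (is.null(region_ids))
    region_ids <- sprintf("R%03d", seq_len(nrow(adjacency)))
  A <- (adjacency != 0) * 1L
  if (!isTRUE(all.equal(A, t(A), check.attributes = FALSE)))
    stop("adjacency must be symmetric", call. = FALSE)
  diag(A) <- 0L
  dimnames(A) <- list(region_ids, region_ids)
  n <- nrow(A)
  e <- sum(A) / 2
  structure(list(adjacency = A, region_ids = region_ids,
                 density = if (n > 1) 2 * e / (n * (n - 1)) else 0,
                 provenance = provenance),
            class = "brain_network")
}

#' @export
print.brain_network <- function(x, ...) {
  cat(sprintf("brain_network: %d regions, %d edges (density %.4f)%s\n",
              length(x$region_ids), n_edges(x), x$density,
              if (is.na(x$provenance)) "" else paste0(" [", x$provenance, "]")))
  invisible(x)
}

n_edges <- function(net) sum(net$adjacency) / 2L

node_degrees <- function(net) {
  d <- rowSums(net$adjacency)
  names(d) <- net$region_ids
  d
}

to_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Threshold a connectivity matrix to a fixed edge density
#'
#' Keeps the \code{round(density * N * (N - 1) / 2)} largest off-diagonal
#' entries (upper triangle) as binary edges, so every network carries the
#' same edge count regardless of the absolute connectivity scale. Rounding
#' is half-away-from-zero. Ties at the cutoff value are broken
#' deterministically by lexicographic (row, column) order, earliest kept.
#'
#' @param C Symmetric connectivity matrix with region dimnames.
#' @param density Target edge density in (0, 1].
#' @param provenance Label stored on the network.
#' @return A \code{\link{brain_network}}.
#' @export
#' @examples
#' C <- matrix(runif(25), 5, 5); C <- (C + t(C)) / 2; diag(C) <- 0
#' dimnames(C) <- list(letters[1:5], letters[1:5])
#' threshold_to_density(C, 0.4)
threshold_to_density <- function(C, density, provenance = NA_character_) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (!is.numeric(density) || density <= 0 || density > 1)
    stop("density must lie in (0, 1]", call. = FALSE)
  n <- nrow(C)
  e_target <- as.integer(round_half_away(density * n * (n - 1) / 2))
  if (e_target < 1L)
    stop("density ", density, " yields no edges for ", n, " nodes",
         call. = FALSE)
  ut <- which(upper.tri(C))
  ri <- row(C)[ut]
  ci <- col(C)[ut]
  vals <- C[ut]
  ord <- order(-vals, ri, ci)
  keep <- ord[seq_len(e_target)]
  if (e_target < length(ord) &&
      vals[ord[e_target]] == vals[ord[e_target + 1L]])
    an_log("ties at the density cutoff broken lexicographically")
  A <- matrix(0L, n, n)
  A[ut[keep]] <- 1L
  A <- A + t(A)
  dimnames(A) <- dimnames(C)
  brain_network(A, provenance = provenance)
}

#' Threshold a connectivity matrix at an absolute value
#'
#' Used by the subject-screening step: an edge is kept wherever the
#' connectivity value is at least \code{tau}; the density field of the
#' result is back-computed from the realized edge count. The appropriate
#' \code{tau} depends on the units of the connectivity estimator.
#'
#' @inheritParams threshold_to_density
#' @param tau Absolute cutoff, > 0.
#' @return A \code{\link{brain_network}} (possibly with zero edges).
#' @export
threshold_absolute <- function(C, tau, provenance = NA_character_) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  A <- (C >= tau) * 1L
  diag(A) <- 0L
  dimnames(A) <- dimnames(C)
  net <- brain_network(A, provenance = provenance)
  if (n_edges(net) == 0L) an_log("absolute threshold ", tau, ": empty graph")
  net
}

#' Degree-based subject exclusion screen
#'
#' Flags subjects whose total network degree falls outside the Tukey fences
#' Q1 - 1.5 IQR and Q3 + 1.5 IQR, with quartiles computed by
#' linear-interpolation quantiles. Extremely low degree indicates noisy
#' data; extremely high degree indicates artifact-driven connectivity.
#'
#' @param degrees Numeric vector of per-subject total degrees (>= 4 subjects).
#' @param subject_ids Optional subject labels.
#' @return data.frame: subject_id, degree_total, lower_fence, upper_fence,
#'   excluded. The number of exclusions is attached as attribute
#'   \code{"n_excluded"}.
#' @export
detect_degree_outliers <- function(degrees, subject_ids = NULL) {
  if (length(degrees) < 4L)
    stop("need at least 4 subjects to place quartile fences", call. = FALSE)
  if (is.null(subject_ids))
    subject_ids <- sprintf("S%04d", seq_along(degrees))
  q <- stats::quantile(degrees, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  out <- data.frame(subject_id = subject_ids, degree_total = degrees,
                    lower_fence = lo, upper_fence = hi,
                    excluded = degrees < lo | degrees > hi,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(out$excluded)
  out
}

#' Group-representative network from subject connectivity matrices
#'
#' Element-wise mean of the subjects' connectivity matrices, thresholded to
#' the target density. Averaging before thresholding is one reasonable
#' aggregation among several; it keeps the group network on the same
#' density footing as the subject networks.
#'
#' @param Cs List of symmetric connectivity matrices sharing region ids.
#' @inheritParams threshold_to_density
#' @return A \code{\link{brain_network}}.
#' @export
group_mean_network <- function(Cs, density, provenance = NA_character_) {
  if (!length(Cs)) stop("empty list of connectivity matrices", call. = FALSE)
  ids <- rownames(Cs[[1]])
  for (C in Cs)
    if (!identical(rownames(C), ids))
      stop("connectivity matrices do not share region ids", call. = FALSE)
  M <- Reduce(`+`, Cs) / length(Cs)
  threshold_to_density(M, density, provenance = provenance)
}

#' Write a network as region-labelled adjacency TSV and edge list
#'
#' @param net A \code{\link{brain_network}}.
#' @param adjacency_path,edges_path Output paths (either may be NULL).
#' @export
write_network_tsv <- function(net, adjacency_path = NULL, edges_path = NULL) {
  if (!is.null(adjacency_path)) {
    df <- data.frame(region = net$region_ids, net$adjacency,
                     check.names = FALSE)
    utils::write.table(df, adjacency_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(edges_path)) {
    ut <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
    el <- data.frame(region_a = net$region_ids[ut[, 1]],
                     region_b = net$region_ids[ut[, 2]])
    utils::write.table(el, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(net)
}
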
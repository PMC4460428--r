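# Independent brute-force implementations used as oracles. These never call
# the package's metric functions (or igraph): distances come from
# Floyd-Warshall, triangles from direct counting, betweenness from
# exhaustive shortest-path enumeration, modularity from the Newman formula
# over explicit partitions.

rand_adj <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  ut <- which(upper.tri(A))
  A[ut] <- rbinom(length(ut), 1L, p)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

adj_complete <- function(n) { A <- matrix(1L, n, n); diag(A) <- 0L; A }
adj_path <- function(n) { A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L; A }
adj_star <- function(n_leaves) { n <- n_leaves + 1L; A <- matrix(0L, n, n)
  A[1, 2:n] <- A[2:n, 1] <- 1L; A }
as_net <- function(A) brain_network(A)

bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1L] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

bf_cpl <- function(A) {
  D <- bf_distances(A)
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

bf_geff <- function(A) {
  D <- bf_distances(A)
  iD <- 1 / D
  diag(iD) <- 0
  mean(iD[row(iD) != col(iD)])
}

bf_geff_nodal <- function(A) {
  D <- bf_distances(A)
  iD <- 1 / D
  diag(iD) <- 0
  rowSums(iD) / (nrow(A) - 1)
}

bf_clustering_nodal <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1L)
    k <- length(nb)
    if (k < 2) return(0)
    e_nb <- sum(A[nb, nb]) / 2           # edges among the neighbours
    e_nb / (k * (k - 1) / 2)
  })
}

bf_local_eff_nodal <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1L)
    if (length(nb) < 2) return(0)
    bf_geff(A[nb, nb, drop = FALSE])
  })
}

# all shortest paths between s and t by depth-limited DFS
bf_shortest_paths <- function(A, s, t, dmax) {
  paths <- list()
  rec <- function(cur) {
    last <- cur[length(cur)]
    if (last == t) {
      if (length(cur) - 1L == dmax) paths[[length(paths) + 1L]] <<- cur
      return(invisible())
    }
    if (length(cur) - 1L >= dmax) return(invisible())
    for (v in which(A[last, ] == 1L))
      if (!(v %in% cur)) rec(c(cur, v))
  }
  rec(s)
  paths
}

bf_betweenness_nodal <- function(A) {
  n <- nrow(A)
  D <- bf_distances(A)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    sp <- bf_shortest_paths(A, s, t, D[s, t])
    for (p in sp) {
      interior <- setdiff(p, c(s, t))
      b[interior] <- b[interior] + 1 / length(sp)
    }
  }
  norm <- (n - 1) * (n - 2) / 2
  if (norm > 0) b / norm else b
}

bf_assortativity <- function(A) {
  ends <- which(A == 1L, arr.ind = TRUE)  # both orientations
  deg <- rowSums(A)
  suppressWarnings(cor(deg[ends[, 1]], deg[ends[, 2]]))
}

bf_modularity_q <- function(A, memb) {
  m2 <- sum(A)                       # 2m
  if (m2 == 0) return(NA_real_)
  deg <- rowSums(A)
  B <- A - outer(deg, deg) / m2
  S <- outer(memb, memb, "==")
  sum(B[S]) / m2
}

# all set partitions of 1..n as membership vectors (restricted growth)
.partition_cache <- new.env()
all_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  out <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1L)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  .partition_cache[[key]] <- out
  out
}

bf_max_modularity <- function(A) {
  parts <- all_partitions(nrow(A))
  best <- -Inf
  for (p in parts) {
    q <- bf_modularity_q(A, p)
    if (is.finite(q) && q > best) best <- q
  }
  best
}

# direct contingency-table mutual information (bits), given bin assignments
bf_mi_from_bins <- function(bx, by) {
  Tt <- length(bx)
  tab <- table(bx, by)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    nij <- tab[i, j]
    if (nij > 0)
      mi <- mi + nij / Tt * log2(nij * Tt / (sum(tab[i, ]) * sum(tab[, j])))
  }
  mi
}
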
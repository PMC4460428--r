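#' Marginal equiprobable (quantile) binning
#'
#' Assigns each value of a series to one of \code{n_bins} bins whose
#' boundaries are linear-interpolation quantiles of the series, so that the
#' marginal bin occupancy is as even as ties permit. Values equal to a
#' boundary fall in the lower bin. Quantile binning makes the downstream
#' mutual-information estimate invariant to monotone transforms of the
#' signal.
#'
#' @param x Numeric vector, finite values.
#' @param n_bins Number of bins.
#' @return Integer vector of bin indices in \code{1:n_bins}.
#' @export
bin_equiprobable <- function(x, n_bins) {
  n_bins <- stopifnot_scalar_count(n_bins, "n_bins")
  if (any(!is.finite(x))) stop("series contains non-finite values", call. = FALSE)
  br <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        type = 7, names = FALSE)
  findInterval(x, br[2:n_bins], left.open = TRUE) + 1L
}

#' Default histogram bin count for a series length
#'
#' \code{ceiling(sqrt(T / 5))}, bounded to [4, 16]: about five expected
#' counts per marginal bin, enough for a stable plug-in estimate at typical
#' resting-state series lengths.
#'
#' @param n_timepoints Series length.
#' @export
default_n_bins <- function(n_timepoints) {
  as.integer(min(16, max(4, ceiling(sqrt(n_timepoints / 5)))))
}

#' Histogram mutual information between two series
#'
#' Plug-in estimate in bits from the joint histogram under marginal
#' equiprobable binning:
#' \deqn{MI = \sum_{a,b} p(a,b) \log_2 \frac{p(a,b)}{p(a) p(b)}}
#' summing only cells with positive joint mass. No bias correction is
#' applied: only the rank order of MI values feeds the density threshold.
#' A constant series occupies a single bin and yields 0.
#'
#' @param x,y Numeric series of equal length, at least \code{2 * n_bins}.
#' @param n_bins Bins per margin; default from \code{\link{default_n_bins}}.
#' @return Non-negative mutual information in bits.
#' @export
#' @examples
#' x <- rnorm(200)
#' mutual_information(x, x, n_bins = 8)  # = log2(8) = 3 bits
mutual_information <- function(x, y, n_bins = default_n_bins(length(x))) {
  if (length(x) != length(y))
    stop("series lengths differ (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  n_bins <- stopifnot_scalar_count(n_bins, "n_bins")
  if (length(x) < 2L * n_bins)
    stop("series length ", length(x), " is below 2 * n_bins = ", 2L * n_bins,
         call. = FALSE)
  bx <- bin_equiprobable(x, n_bins)
  by <- bin_equiprobable(y, n_bins)
  if (length(unique(bx)) < 2L || length(unique(by)) < 2L) {
    an_log("degenerate (constant) series: MI set to 0")
    return(0)
  }
  Tt <- length(x)
  joint <- tabulate((bx - 1L) * n_bins + by, nbins = n_bins * n_bins)
  mx <- tabulate(bx, nbins = n_bins)
  my <- tabulate(by, nbins = n_bins)
  exp_cnt <- as.vector(outer(my, mx)) # column-major: y fast, x slow
  pos <- joint > 0L
  terms <- joint[pos] / Tt * log2(joint[pos] * Tt / exp_cnt[pos])
  # value-sorted summation makes the result invariant to cell order, so
  # MI(x, y) and MI(y, x) are bitwise identical
  max(sum(sort(terms)), 0)
}

#' Mutual-information connectivity matrix
#'
#' Computes \code{\link{mutual_information}} for every unordered pair of
#' rows of a region x time matrix and assembles the symmetric connectivity
#' matrix with a zero diagonal. The computation is vectorized over pairs
#' through per-bin indicator matrix products and is exactly equal to the
#' pairwise estimator.
#'
#' @param ts Region x time numeric matrix with region ids as row names.
#' @param n_bins Bins per margin; default from \code{\link{default_n_bins}}.
#' @return Symmetric non-negative matrix with region ids as dimnames.
#' @export
build_mi_matrix <- function(ts, n_bins = default_n_bins(ncol(ts))) {
  stopifnot(is.matrix(ts))
  if (is.null(rownames(ts))) stop("ts must carry region ids as row names",
                                  call. = FALSE)
  if (any(!is.finite(ts))) stop("ts contains non-finite values", call. = FALSE)
  n_bins <- stopifnot_scalar_count(n_bins, "n_bins")
  n <- nrow(ts)
  Tt <- ncol(ts)
  if (Tt < 2L * n_bins)
    stop("n_timepoints ", Tt, " is below 2 * n_bins = ", 2L * n_bins,
         call. = FALSE)
  B <- matrix(0L, n, Tt)
  for (i in seq_len(n)) B[i, ] <- bin_equiprobable(ts[i, ], n_bins)
  ind <- lapply(seq_len(n_bins), function(a) (B == a) * 1)
  marg <- vapply(ind, rowSums, numeric(n))        # n x n_bins counts
  lmarg <- log2(pmax(marg, 1))                    # masked where counts 0
  M <- matrix(0, n, n)
  l2T <- log2(Tt)
  for (a in seq_len(n_bins)) {
    ta <- t(ind[[a]])
    for (b in seq_len(n_bins)) {
      Nab <- ind[[b]] %*% ta                      # joint counts: row i in b, row j in a
      pos <- Nab > 0
      term <- matrix(0, n, n)
      lexp <- outer(lmarg[, b], lmarg[, a], "+")  # log2 of marginal product / T^2, shifted
      term[pos] <- Nab[pos] / Tt * (log2(Nab[pos]) + l2T - lexp[pos])
      M <- M + term
    }
  }
  M[M < 0] <- 0
  M[lower.tri(M)] <- t(M)[lower.tri(M)]  # exact symmetry
  diag(M) <- 0
  dimnames(M) <- list(rownames(ts), rownames(ts))
  # degenerate rows (constant series): single occupied bin, MI defined as 0
  deg <- rowSums(marg > 0) < 2L
  if (any(deg)) {
    an_log("degenerate (constant) series: ",
           paste(rownames(ts)[deg], collapse = ", "))
    M[deg, ] <- 0
    M[, deg] <- 0
  }
  M
}

#' Read and write a connectivity matrix as TSV
#'
#' Region ids appear as both the first row and first column.
#'
#' @param C Symmetric numeric matrix with region dimnames.
#' @param path File path.
#' @export
write_connectivity_tsv <- function(C, path) {
  stopifnot(is.matrix(C), !is.null(rownames(C)))
  df <- data.frame(region = rownames(C), C, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity_tsv
#' @export
read_connectivity_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  C <- as.matrix(df[, -1, drop = FALSE])
  rownames(C) <- df[[1]]
  C
}
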
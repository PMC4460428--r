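#' Specification of a synthetic multi-group cohort
#'
#' Defines the generative model for a five-group resting-state cohort:
#' region-wise time series drawn from a zero-mean multivariate normal with a
#' block-modular covariance (one module per lobe), plus independent
#' measurement noise, and clinical scores linearly coupled to each subject's
#' realized inter-module coupling.
#'
#' Within-module correlation is a fixed base value (\code{within_base});
#' the per-group \code{coupling_by_group} value in [0, 1) scales the
#' between-module correlation as a fraction of that base. A higher coupling
#' therefore means stronger integration across modules, which at fixed edge
#' density shortens paths and raises global efficiency; the default group
#' values emulate the non-monotonic stage profile (aMCI and CDR1 above their
#' neighbours) of the disease-stage cohort the generator emulates.
#'
#' @param group_sizes Named integer vector of subjects per group.
#' @param n_regions Number of regions (nodes); 90 matches the AAL map.
#' @param n_timepoints Number of time points per series.
#' @param coupling_by_group Named numeric vector in [0, 1): between-module
#'   coupling fraction per group.
#' @param n_modules Number of covariance modules; with 90 regions and the
#'   default lobe map the five lobes are used as modules.
#' @param noise_sd Standard deviation of independent added noise.
#' @param clinical_effect Slope (score points per unit coupling) linking a
#'   subject's realized coupling to every clinical score.
#' @param seed Base RNG seed; all randomness derives from it.
#' @param within_base Within-module correlation of the block covariance.
#' @param coupling_jitter_sd Between-subject SD of realized coupling.
#' @param ar_coef Optional AR(1) coefficient applied along time (default 0,
#'   i.e. temporally white signals).
#' @param lobe_map Region metadata used for module assignment when
#'   \code{n_regions == 90}; defaults to \code{\link{aal90_lobe_map}}.
#' @param score_table data.frame with columns \code{score}, \code{baseline},
#'   \code{sd} defining the clinical score battery.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(group_sizes = c(HS = 31L, aMCI = 50L, CDR0.5 = 25L,
                                        CDR1 = 36L, CDR2 = 10L),
                        n_regions = 90L,
                        n_timepoints = 120L,
                        coupling_by_group = c(HS = 0.55, aMCI = 0.85,
                                              CDR0.5 = 0.40, CDR1 = 0.70,
                                              CDR2 = 0.25),
                        n_modules = 5L,
                        noise_sd = 0.3,
                        clinical_effect = -25,
                        seed = 1L,
                        within_base = 0.6,
                        coupling_jitter_sd = 0.06,
                        ar_coef = 0,
                        lobe_map = NULL,
                        score_table = default_score_table()) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop("group_sizes must be named", call. = FALSE)
  if (any(group_sizes < 1) || any(group_sizes != floor(group_sizes)))
    stop("all group sizes must be positive integers", call. = FALSE)
  stopifnot_scalar_count(n_regions, "n_regions")
  stopifnot_scalar_count(n_timepoints, "n_timepoints")
  stopifnot_scalar_count(n_modules, "n_modules")
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  missing_groups <- setdiff(names(group_sizes), names(coupling_by_group))
  if (length(missing_groups))
    stop("coupling_by_group lacks groups: ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  for (g in names(coupling_by_group)) {
    cg <- coupling_by_group[[g]]
    if (!is.finite(cg) || cg < 0 || cg >= 1)
      stop("coupling for group '", g, "' is ", cg,
           " but must lie in [0, 1)", call. = FALSE)
  }
  if (!is.finite(within_base) || within_base < 0 || within_base >= 1)
    stop("within_base must lie in [0, 1)", call. = FALSE)
  if (abs(ar_coef) >= 1) stop("ar_coef must lie in (-1, 1)", call. = FALSE)

  modules <- module_assignment(n_regions, n_modules, lobe_map)
  spec <- structure(list(
    group_sizes = group_sizes, n_regions = as.integer(n_regions),
    n_timepoints = as.integer(n_timepoints),
    coupling_by_group = coupling_by_group, n_modules = as.integer(n_modules),
    noise_sd = noise_sd, clinical_effect = clinical_effect,
    seed = as.integer(seed), within_base = within_base,
    coupling_jitter_sd = coupling_jitter_sd, ar_coef = ar_coef,
    modules = modules$modules, region_ids = modules$region_ids,
    score_table = score_table), class = "cohort_spec")
  # fail early on a covariance that cannot be factorized
  for (g in names(group_sizes))
    block_covariance(spec, coupling_by_group[[g]], group = g)
  spec
}

# module labels and region ids; with 90 regions the shipped lobe map gives
# the modules real anatomical structure, otherwise contiguous blocks
module_assignment <- function(n_regions, n_modules, lobe_map) {
  if (n_regions == 90L) {
    lm <- if (is.null(lobe_map)) aal90_lobe_map() else validate_lobe_map(lobe_map)
    if (nrow(lm) != 90L) stop("lobe map must cover 90 regions", call. = FALSE)
    return(list(region_ids = lm$region, modules = as.integer(factor(lm$lobe))))
  }
  ids <- sprintf("R%03d", seq_len(n_regions))
  list(region_ids = ids,
       modules = as.integer(cut(seq_len(n_regions), n_modules, labels = FALSE)))
}

#' @rdname cohort_spec
#' @export
default_score_table <- function() {
  data.frame(
    score = c("MMSE", "Digit_span_backward", "K_BNT", "RCFT_copy",
              "SVLT_delayed", "RCFT_delayed", "COWAT_semantic",
              "COWAT_phonemic", "Stroop_color_reading"),
    baseline = c(28.6, 4.3, 48.5, 32.2, 7.4, 15.0, 32.4, 28.1, 87.7),
    sd = c(1.9, 1.5, 7.5, 5.0, 2.0, 3.9, 7.5, 10.8, 23.3),
    stringsAsFactors = FALSE)
}

block_covariance <- function(spec, coupling, group = "?") {
  m <- spec$modules
  w <- spec$within_base
  S <- outer(m, m, function(a, b) ifelse(a == b, w, coupling * w))
  diag(S) <- 1
  L <- tryCatch(chol(S), error = function(e)
    stop("covariance implied by coupling ", signif(coupling, 3),
         " for group '", group, "' is not positive definite", call. = FALSE))
  list(Sigma = S, chol = L)
}

#' Generate one synthetic subject
#'
#' Draws an \code{n_regions x n_timepoints} series from the block-modular
#' Gaussian model of a \code{\link{cohort_spec}} together with clinical
#' scores coupled to the subject's realized inter-module coupling. Fully
#' reproducible from \code{(spec$seed, subject_seed)}.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param group Group label, one of \code{names(spec$group_sizes)}.
#' @param subject_seed Integer distinguishing subjects under the same spec.
#' @return A list with \code{ts} (region x time matrix, region ids as row
#'   names), and \code{record} (subject metadata: group, realized coupling,
#'   named vector of clinical scores).
#' @export
generate_subject <- function(spec, group, subject_seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!group %in% names(spec$group_sizes))
    stop("unknown group '", group, "'", call. = FALSE)
  c_grp <- spec$coupling_by_group[[group]]
  n <- spec$n_regions
  Tt <- spec$n_timepoints
  withr::with_seed(mix_seed(spec$seed, subject_seed), {
    c_subj <- min(max(c_grp + stats::rnorm(1, 0, spec$coupling_jitter_sd), 0), 0.97)
    L <- block_covariance(spec, c_subj, group)$chol
    X <- crossprod(L, matrix(stats::rnorm(n * Tt), n, Tt))
    if (spec$ar_coef != 0) {
      a <- spec$ar_coef
      s <- sqrt(1 - a^2)
      for (t in 2:Tt) X[, t] <- a * X[, t - 1] + s * X[, t]
    }
    if (spec$noise_sd > 0)
      X <- X + spec$noise_sd * matrix(stats::rnorm(n * Tt), n, Tt)
    rownames(X) <- spec$region_ids
    st <- spec$score_table
    scores <- st$baseline + spec$clinical_effect * c_subj +
      stats::rnorm(nrow(st), 0, st$sd)
    names(scores) <- st$score
    list(ts = X,
         record = list(subject_id = sprintf("S%04d", as.integer(subject_seed)),
                       group = group, coupling = c_subj, scores = scores))
  })
}

#' Generate a full synthetic cohort
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param dir Optional directory; when given, per-subject time-series TSVs
#'   and a cohort table TSV are written there.
#' @return A list with \code{subjects} (list of \code{\link{generate_subject}}
#'   results, one per subject) and \code{table} (data.frame: subject_id,
#'   group, coupling, one column per clinical score).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(names(spec$group_sizes), times = spec$group_sizes)
  subjects <- vector("list", length(groups))
  for (i in seq_along(groups))
    subjects[[i]] <- generate_subject(spec, groups[i], subject_seed = i)
  tab <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject_id = s$record$subject_id, group = s$record$group,
               coupling = s$record$coupling,
               as.list(s$record$scores), check.names = FALSE,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (s in subjects)
      write_timeseries_tsv(s$ts, file.path(dir, paste0(s$record$subject_id, ".tsv")))
    utils::write.table(tab, file.path(dir, "cohort.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(subjects = subjects, table = tab)
}

#' Read and write region x time series TSV
#'
#' The on-disk format has one row per region: the region name in the first
#' column followed by the time-point values, with no header row.
#'
#' @param ts Region x time numeric matrix with region ids as row names.
#' @param path File path.
#' @export
write_timeseries_tsv <- function(ts, path) {
  stopifnot(is.matrix(ts), !is.null(rownames(ts)))
  df <- data.frame(region = rownames(ts), ts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  dimnames(X) <- list(df[[1]], NULL)
  storage.mode(X) <- "double"
  X
}
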
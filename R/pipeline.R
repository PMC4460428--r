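#' Read a pipeline configuration file
#'
#' Plain YAML (key: value) with any subset of the configuration entries of
#' \code{\link{run_group_pipeline}}; missing keys take their defaults.
#'
#' @param path Path to a YAML file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

default_pipeline_config <- function() {
  list(density = 0.07, n_bins = NULL, screen_tau = NULL, k_values = 1:15,
       n_random = 100L, n_restarts = 20L, seed = 1L, out_dir = NULL)
}

#' Run the full stage-wise group analysis
#'
#' Orchestrates the whole pipeline on a cohort: mutual-information
#' connectivity per subject, optional degree-outlier screening, fixed
#' density networks, the seven whole-network measures with nodal and lobar
#' values, group comparisons (one-way ANOVA + Tukey-Kramer) for whole-brain
#' and lobar metrics, metric-clinical Pearson correlations per group and
#' pooled, and group-level rich-club curves against rewiring nulls. All
#' randomness derives from \code{config$seed}; rerunning with the same
#' cohort and config reproduces the results exactly.
#'
#' @param cohort A list as returned by \code{\link{generate_cohort}}:
#'   \code{subjects} (each with \code{ts} and \code{record}) and
#'   \code{table}.
#' @param config Named list (see \code{\link{read_pipeline_config}}):
#'   \code{density} (default 0.07), \code{n_bins} (NULL = automatic),
#'   \code{screen_tau} (NULL disables the exclusion screen),
#'   \code{k_values}, \code{n_random}, \code{n_restarts}, \code{seed},
#'   \code{out_dir} (NULL = no files written).
#' @param lobe_map Region metadata; defaults to \code{\link{aal90_lobe_map}}
#'   when the cohort has 90 regions, otherwise lobar analyses are skipped.
#' @return List with \code{subject_metrics}, \code{exclusions},
#'   \code{comparisons}, \code{lobar_comparisons}, \code{correlations},
#'   \code{rich_club} (one curve per group), and \code{summary}.
#' @export
run_group_pipeline <- function(cohort, config = list(), lobe_map = NULL) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(cfg$out_dir)) unlink(cfg$out_dir, recursive = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  subjects <- cohort$subjects
  n_regions <- nrow(subjects[[1]]$ts)
  if (is.null(lobe_map) && n_regions == 90L) lobe_map <- aal90_lobe_map()

  mats <- stage("connectivity", lapply(subjects, function(s)
    build_mi_matrix(s$ts, n_bins = if (is.null(cfg$n_bins))
      default_n_bins(ncol(s$ts)) else cfg$n_bins)))

  exclusions <- NULL
  if (!is.null(cfg$screen_tau)) {
    exclusions <- stage("screening", {
      degs <- vapply(mats, function(C)
        sum(threshold_absolute(C, cfg$screen_tau)$adjacency) / 2, numeric(1))
      detect_degree_outliers(degs, vapply(subjects, function(s)
        s$record$subject_id, character(1)))
    })
    keep <- which(!exclusions$excluded)
    subjects <- subjects[keep]
    mats <- mats[keep]
  }
  groups <- vapply(subjects, function(s) s$record$group, character(1))

  nets <- stage("networks", Map(function(C, s)
    threshold_to_density(C, cfg$density, provenance = s$record$subject_id),
    mats, subjects))

  metrics <- stage("metrics", lapply(nets, network_metrics,
                                     lobe_map = lobe_map,
                                     n_restarts = cfg$n_restarts,
                                     seed = cfg$seed))
  subject_metrics <- data.frame(
    subject_id = vapply(subjects, function(s) s$record$subject_id, character(1)),
    group = groups,
    do.call(rbind, lapply(metrics, function(m) as.data.frame(t(m$global)))),
    stringsAsFactors = FALSE)
  rownames(subject_metrics) <- NULL

  metric_names <- names(metrics[[1]]$global)
  multi_group <- length(unique(groups)) >= 2L &&
    all(table(groups) >= 2L)

  comparisons <- NULL
  lobar_comparisons <- NULL
  if (multi_group) {
    comparisons <- stage("group_comparison", do.call(rbind, lapply(
      metric_names, function(mn) {
        v <- subject_metrics[[mn]]
        ok <- is.finite(v)
        if (sum(ok) < length(v)) an_log("dropping non-finite ", mn, " values")
        av <- anova_oneway(v[ok], groups[ok])
        tk <- tukey_hsd(v[ok], groups[ok])
        data.frame(metric_name = mn, anova_F = av$F, anova_p = av$p,
                   tk, stringsAsFactors = FALSE)
      })))
    if (!is.null(lobe_map)) {
      lobar_comparisons <- stage("lobar_comparison", {
        nodal_metrics <- setdiff(names(metrics[[1]]$nodal), "region")
        cells <- metrics[[1]]$lobar[, c("lobe", "hemisphere")]
        out <- list()
        for (mn in nodal_metrics) {
          per_subj <- vapply(metrics, function(m) m$lobar[[mn]],
                             numeric(nrow(cells)))
          for (ci in seq_len(nrow(cells))) {
            av <- anova_oneway(per_subj[ci, ], groups)
            out[[length(out) + 1L]] <- data.frame(
              metric_name = mn, lobe = cells$lobe[ci],
              hemisphere = cells$hemisphere[ci],
              anova_F = av$F, anova_p = av$p, stringsAsFactors = FALSE)
          }
        }
        do.call(rbind, out)
      })
    }
  } else {
    an_log("single group: comparisons skipped")
  }

  correlations <- stage("correlations", {
    tab <- cohort$table
    tab <- tab[match(subject_metrics$subject_id, tab$subject_id), ,
               drop = FALSE]
    score_names <- setdiff(names(tab), c("subject_id", "group", "coupling"))
    do.call(rbind, lapply(metric_names, function(mn) {
      do.call(rbind, lapply(score_names, function(sn)
        correlate_metric_clinical(subject_metrics[[mn]], tab[[sn]],
                                  groups = if (multi_group) groups else NULL,
                                  metric_name = mn, score_name = sn)))
    }))
  })

  rich_club <- stage("richclub", {
    out <- list()
    for (g in unique(groups)) {
      gm <- group_mean_network(mats[groups == g], cfg$density, provenance = g)
      out[[g]] <- normalized_rich_club(gm, k_values = cfg$k_values,
                                       n_random = cfg$n_random,
                                       seed = cfg$seed)
    }
    out
  })

  summary <- list(
    seed = cfg$seed, density = cfg$density,
    n_subjects_in = length(cohort$subjects),
    n_excluded = if (is.null(exclusions)) 0L else sum(exclusions$excluded),
    n_subjects_analyzed = length(subjects),
    groups = as.list(table(groups)),
    n_random = cfg$n_random)

  res <- list(subject_metrics = subject_metrics, exclusions = exclusions,
              comparisons = comparisons,
              lobar_comparisons = lobar_comparisons,
              correlations = correlations, rich_club = rich_club,
              summary = summary)
  if (!is.null(cfg$out_dir)) stage("write_outputs", {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) if (!is.null(x))
      utils::write.table(x, file.path(cfg$out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wt(subject_metrics, "subject_metrics.tsv")
    wt(exclusions, "exclusions.tsv")
    wt(comparisons, "group_comparisons.tsv")
    wt(lobar_comparisons, "lobar_comparisons.tsv")
    wt(correlations, "correlations.tsv")
    for (g in names(rich_club))
      wt(as.data.frame(rich_club[[g]]), paste0("richclub_", g, ".tsv"))
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })
  res
}
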
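small_spec <- function(...) {
  cohort_spec(group_sizes = c(HS = 2L, aMCI = 2L, CDR0.5 = 2L, CDR1 = 2L,
                              CDR2 = 2L),
              n_regions = 20L, n_timepoints = 60L, ...)
}

test_that("subject generation is reproducible and shaped correctly", {
  spec <- small_spec()
  s1 <- generate_subject(spec, "aMCI", 7)
  s2 <- generate_subject(spec, "aMCI", 7)
  expect_identical(s1$ts, s2$ts)
  expect_identical(s1$record, s2$record)
  expect_equal(dim(s1$ts), c(20L, 60L))
  expect_equal(rownames(s1$ts), spec$region_ids)
  s3 <- generate_subject(spec, "aMCI", 8)
  expect_false(identical(s1$ts, s3$ts))
})

test_that("default cohort has 152 subjects in the stated group sizes", {
  spec <- cohort_spec(n_regions = 10L, n_timepoints = 40L)
  expect_equal(sum(spec$group_sizes), 152L)
  co <- generate_cohort(spec)
  expect_equal(nrow(co$table), 152L)
  expect_equal(as.integer(table(co$table$group)[names(spec$group_sizes)]),
               as.integer(spec$group_sizes))
})

test_that("one-subject-per-group spec yields 5 subjects, one per group", {
  spec <- cohort_spec(group_sizes = c(HS = 1L, aMCI = 1L, CDR0.5 = 1L,
                                      CDR1 = 1L, CDR2 = 1L),
                      n_regions = 10L, n_timepoints = 40L)
  co <- generate_cohort(spec)
  expect_equal(nrow(co$table), 5L)
  expect_setequal(co$table$group, names(spec$group_sizes))
})

test_that("cohort generation is deterministic given the spec seed", {
  spec <- small_spec(seed = 42L)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$table, c2$table)
  expect_identical(c1$subjects[[3]]$ts, c2$subjects[[3]]$ts)
})

test_that("zero coupling and zero within-base give independent regions", {
  spec <- cohort_spec(group_sizes = c(HS = 1L),
                      coupling_by_group = c(HS = 0),
                      within_base = 0, noise_sd = 0, coupling_jitter_sd = 0,
                      n_regions = 12L, n_timepoints = 4000L)
  s <- generate_subject(spec, "HS", 1)
  cors <- cor(t(s$ts))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.08)
})

test_that("sample covariance converges to the specified block covariance", {
  spec <- cohort_spec(group_sizes = c(HS = 1L),
                      coupling_by_group = c(HS = 0.5), within_base = 0.6,
                      noise_sd = 0, coupling_jitter_sd = 0,
                      n_regions = 30L, n_timepoints = 5000L)
  s <- generate_subject(spec, "HS", 1)
  emp <- stats::cov(t(s$ts))
  m <- spec$modules
  theo <- outer(m, m, function(a, b) ifelse(a == b, 0.6, 0.5 * 0.6))
  diag(theo) <- 1
  # element-wise sampling error ~ (1 + rho^2)/sqrt(T); allow the max over
  # all entries a generous multiple of that scale
  expect_lt(max(abs(emp - theo)), 8 / sqrt(5000))
})

test_that("higher coupling raises between-module sample correlation", {
  mk <- function(cpl) {
    spec <- cohort_spec(group_sizes = c(G = 1L),
                        coupling_by_group = c(G = cpl), within_base = 0.6,
                        noise_sd = 0.3, coupling_jitter_sd = 0,
                        n_regions = 20L, n_timepoints = 2000L, seed = 5L)
    s <- generate_subject(spec, "G", 1)
    r <- cor(t(s$ts))
    between <- outer(spec$modules, spec$modules, "!=")
    mean(r[between & upper.tri(r)])
  }
  r_hi <- mk(0.6)
  r_lo <- mk(0.1)
  # oracle: attenuated generating correlations (0.6 - 0.1) * 0.6 / (1 + 0.09)
  margin <- (0.6 - 0.1) * 0.6 / (1 + 0.3^2)
  expect_gt(r_hi - r_lo, margin / 2)
})

test_that("clinical scores track realized coupling with the effect sign", {
  spec <- cohort_spec(group_sizes = c(HS = 200L),
                      coupling_by_group = c(HS = 0.5),
                      clinical_effect = -25, coupling_jitter_sd = 0.06,
                      n_regions = 10L, n_timepoints = 40L)
  co <- generate_cohort(spec)
  r <- cor(co$table$coupling, co$table$MMSE)
  expect_lt(r, -0.3)
  spec_pos <- cohort_spec(group_sizes = c(HS = 200L),
                          coupling_by_group = c(HS = 0.5),
                          clinical_effect = 25, coupling_jitter_sd = 0.06,
                          n_regions = 10L, n_timepoints = 40L)
  co_pos <- generate_cohort(spec_pos)
  expect_gt(cor(co_pos$table$coupling, co_pos$table$MMSE), 0.3)
})

test_that("invalid couplings are rejected with the offending value named", {
  expect_error(cohort_spec(coupling_by_group = c(HS = 1.2, aMCI = 0.5,
                                                 CDR0.5 = 0.5, CDR1 = 0.5,
                                                 CDR2 = 0.5)),
               "HS")
  expect_error(cohort_spec(group_sizes = c(HS = 2L, preclinical = 2L)),
               "coupling_by_group")
  expect_error(cohort_spec(within_base = 1.5), "within_base")
})

test_that("AR(1) filtering induces temporal autocorrelation", {
  base <- cohort_spec(group_sizes = c(HS = 1L), coupling_by_group = c(HS = 0.3),
                      n_regions = 10L, n_timepoints = 2000L, ar_coef = 0)
  ar <- cohort_spec(group_sizes = c(HS = 1L), coupling_by_group = c(HS = 0.3),
                    n_regions = 10L, n_timepoints = 2000L, ar_coef = 0.6)
  lag1 <- function(x) cor(x[-1], x[-length(x)])
  a0 <- mean(apply(generate_subject(base, "HS", 1)$ts, 1, lag1))
  a1 <- mean(apply(generate_subject(ar, "HS", 1)$ts, 1, lag1))
  expect_lt(abs(a0), 0.1)
  expect_gt(a1, 0.4)
})

test_that("time-series TSV round-trips exactly", {
  spec <- small_spec()
  s <- generate_subject(spec, "HS", 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_timeseries_tsv(s$ts, path)
  back <- read_timeseries_tsv(path)
  expect_equal(back, s$ts, tolerance = 1e-9)
  expect_identical(rownames(back), rownames(s$ts))
})

test_that("cohort TSV export writes one file per subject plus the table", {
  spec <- cohort_spec(group_sizes = c(HS = 2L, aMCI = 1L),
                      coupling_by_group = c(HS = 0.3, aMCI = 0.5),
                      n_regions = 8L, n_timepoints = 40L)
  dir <- withr::local_tempdir()
  co <- generate_cohort(spec, dir = dir)
  expect_length(list.files(dir, pattern = "^S\\d+\\.tsv$"), 3L)
  tab <- read.delim(file.path(dir, "cohort.tsv"), check.names = FALSE)
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("subject_id", "group", "MMSE") %in% names(tab)))
})
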
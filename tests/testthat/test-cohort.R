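test_that("config validation catches malformed designs", {
  expect_error(cohort_config(group_sizes = c(16, 14)), "equal length")
  expect_error(cohort_config(group_sizes = c(16, 0, 20)), "positive integers")
  expect_error(cohort_config(between_subject_cv = 1.2), "\\[0, 1\\)")
  expect_error(cohort_config(sampling_times = c(3, 1, 5)), "increasing")
  expect_error(cohort_config(lloq = -1), "lloq")
  expect_error(cohort_config(vc_fraction = 1.5), "vc_fraction")
})

test_that("default design emits 16/14/20 = 50 subjects with sequential ids", {
  cohort <- simulate_cohort(cohort_config(seed = 3))
  expect_length(cohort, 50)
  groups <- vapply(cohort, `[[`, "", "group")
  expect_equal(unname(table(factor(groups, c("control", "hep70", "hep90")))),
               c(16L, 14L, 20L), ignore_attr = TRUE)
  ids <- vapply(cohort, `[[`, "", "subject_id")
  expect_false(anyDuplicated(ids) > 0)
})

test_that("simulation is deterministic in the seed and varies across seeds", {
  a <- simulate_cohort(cohort_config(seed = 42))
  b <- simulate_cohort(cohort_config(seed = 42))
  c <- simulate_cohort(cohort_config(seed = 43))
  expect_identical(cohort_long_table(a), cohort_long_table(b))
  expect_false(isTRUE(all.equal(cohort_long_table(a)$conc_umol_L,
                                cohort_long_table(c)$conc_umol_L)))
})

test_that("per-subject streams keep other groups stable when one grows", {
  small <- simulate_cohort(cohort_config(group_sizes = c(4L, 3L, 3L), seed = 9))
  big <- simulate_cohort(cohort_config(group_sizes = c(8L, 3L, 3L), seed = 9))
  pick <- function(cohort, id) Filter(function(p) p$subject_id == id, cohort)[[1]]
  for (id in c("hep70_002", "hep90_003", "control_004")) {
    expect_identical(pick(small, id)$concentrations,
                     pick(big, id)$concentrations)
  }
})

test_that("noise-free subjects lie exactly on the disposition curve and decrease", {
  cfg <- cohort_config(between_subject_cv = 0, assay_cv = 0, seed = 1)
  p <- simulate_subject(cfg, "control", 1)
  dp <- disposition_params(cfg$group_clearance_means[1],
                           cfg$vc_fraction * cfg$group_vss_means[1],
                           (1 - cfg$vc_fraction) * cfg$group_vss_means[1],
                           cfg$q_intercompartmental)
  expect_equal(p$concentrations,
               biexponential_concentration(dp, p$dose, p$times),
               tolerance = 1e-12)
  expect_true(all(diff(p$concentrations) < 0))
})

test_that("LLOQ above the whole curve flags every sample BLQ", {
  cfg <- cohort_config(lloq = 1e6, seed = 2)
  p <- simulate_subject(cfg, "hep90", 1)
  expect_true(all(p$blq))
})

test_that("between-subject CV of simulated clearances converges to the target", {
  cfg <- cohort_config(group_names = "control", group_sizes = 10000L,
                       group_clearance_means = 12.7, group_vss_means = 269.7,
                       between_subject_cv = c(cl = 0.33, vss = 0.25),
                       seed = 77)
  cohort <- simulate_cohort(cfg)
  cls <- vapply(cohort, function(p) p$true$cl, 0)
  expect_lt(abs(sd(cls) / mean(cls) - 0.33) / 0.33, 0.05)
  expect_lt(abs(mean(cls) - 12.7) / 12.7, 0.02)
})

test_that("time jitter keeps analyses on actual times and stays within 5%", {
  cfg <- cohort_config(time_jitter = TRUE, seed = 6)
  p <- simulate_subject(cfg, "control", 2)
  expect_true(all(abs(p$times / cfg$sampling_times - 1) <= 0.05))
  expect_true(all(diff(p$times) > 0))
})

test_that("cohort and config files round-trip", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(group_sizes = c(3L, 2L, 2L), seed = 8)
  cohort <- simulate_cohort(cfg)
  cc <- file.path(dir, "cohort.csv"); dc <- file.path(dir, "dosing.csv")
  write_cohort_csv(cohort, cc, dc)
  back <- read_cohort_csv(cc, dc)
  expect_length(back, 7)
  p0 <- cohort[[5]]
  p1 <- Filter(function(p) p$subject_id == p0$subject_id, back)[[1]]
  expect_equal(p1$concentrations, p0$concentrations, tolerance = 1e-12)
  expect_equal(p1$dose, p0$dose, tolerance = 1e-12)

  jf <- file.path(dir, "config.json")
  write_cohort_config(cfg, jf)
  cfg2 <- read_cohort_config(jf)
  expect_equal(cfg2, cfg)
  # malformed field is named in the error
  bad <- jsonlite::read_json(jf)
  bad$not_a_field <- 1
  jsonlite::write_json(bad, jf, auto_unbox = TRUE)
  expect_error(read_cohort_config(jf), "not_a_field")
})

test_that("missing dosing rows are a hard error on read", {
  dir <- withr::local_tempdir()
  cohort <- simulate_cohort(cohort_config(group_sizes = c(2L, 1L, 1L), seed = 4))
  cc <- file.path(dir, "cohort.csv"); dc <- file.path(dir, "dosing.csv")
  write_cohort_csv(cohort, cc, dc)
  d <- read.csv(dc)
  write.csv(d[-1, ], dc, row.names = FALSE)
  expect_error(read_cohort_csv(cc, dc), "absent from dosing")
})
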
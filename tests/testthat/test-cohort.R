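test_that("identical spec and seed reproduce the cohort exactly", {
  spec <- small_control_spec(n = 3, regions = 8, timepoints = 30, seed = 42)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  spec2 <- small_control_spec(n = 3, regions = 8, timepoints = 30, seed = 43)
  expect_false(identical(generate_cohort(spec)[[1]]$timeseries,
                         generate_cohort(spec2)[[1]]$timeseries))
})

test_that("population correlation is the closed form of the factor model", {
  none <- cohort_spec(n_control = 2, n_patient = 0, n_regions = 5,
                      n_timepoints = 20,
                      planted_edges = data.frame(i = integer(),
                                                 j = integer(),
                                                 lambda = numeric()),
                      seed = 1)
  expect_equal(population_correlation(none), diag(5))
  one <- cohort_spec(n_control = 2, n_patient = 0, n_regions = 5,
                     n_timepoints = 20, baseline_noise_sd = 1,
                     planted_edges = data.frame(i = 2, j = 4, lambda = 0.5),
                     seed = 1)
  r <- population_correlation(one)
  expect_equal(r[2, 4], 0.5 / 1.5)  # lambda / (lambda + sigma^2)
  off <- r; diag(off) <- 0; off[2, 4] <- off[4, 2] <- 0
  expect_true(all(off == 0))
})

test_that("population correlation is symmetric PSD for random specs", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    pool <- edge_pairs(n)
    pick <- sample(nrow(pool), sample(1:min(6, nrow(pool)), 1))
    sp <- cohort_spec(n_control = 2, n_patient = 0, n_regions = n,
                      n_timepoints = 20,
                      planted_edges = data.frame(i = pool[pick, 1],
                                                 j = pool[pick, 2],
                                                 lambda = runif(length(pick),
                                                                0.1, 0.9)),
                      seed = rep)
    r <- population_correlation(sp)
    expect_equal(r, t(r))
    expect_equal(unname(diag(r)), rep(1, n))
    expect_gte(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("planted loadings reproduce their population correlation in samples", {
  # lambda = 4 sigma^2 gives population r = 0.8; one long run
  sp <- cohort_spec(n_control = 1, n_patient = 0, n_regions = 4,
                    n_timepoints = 2000, baseline_noise_sd = 0.4,
                    planted_edges = data.frame(i = 1, j = 2, lambda = 0.64),
                    jitter_sd = 0, seed = 21)
  expect_equal(population_correlation(sp)[1, 2], 0.8)
  ts <- generate_cohort(sp)[[1]]$timeseries
  expect_lt(abs(cor(ts[, 1], ts[, 2]) - 0.8), 0.05)
  # with nothing planted, off-diagonal correlations hover near zero
  sp0 <- cohort_spec(n_control = 1, n_patient = 0, n_regions = 10,
                     n_timepoints = 500,
                     planted_edges = data.frame(i = integer(), j = integer(),
                                                lambda = numeric()),
                     seed = 22)
  r0 <- correlation_matrix(generate_cohort(sp0)[[1]]$timeseries)
  expect_lt(mean(abs(vectorize(r0))), 0.05)
})

test_that("population correlation grows strictly with the loading", {
  rs <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(l) {
    sp <- cohort_spec(n_control = 2, n_patient = 0, n_regions = 3,
                      n_timepoints = 20,
                      planted_edges = data.frame(i = 1, j = 2, lambda = l),
                      seed = 1)
    population_correlation(sp)[1, 2]
  }, 0)
  expect_true(all(diff(rs) > 0))
})

test_that("covariate draws match the configured group demographics", {
  sp <- cohort_spec(n_control = 1000, n_patient = 1000, n_regions = 4,
                    n_timepoints = 10,
                    planted_edges = data.frame(i = integer(), j = integer(),
                                               lambda = numeric()),
                    symptom_edge = NULL, atlas = NULL, seed = 31)
  ph <- cohort_phenotypes(generate_cohort(sp))
  ctrl <- ph[ph$group == "control", ]
  pat <- ph[ph$group == "patient", ]
  # group means within 2 SE of the configured values
  expect_lt(abs(mean(ctrl$age) - 36.23), 2 * 11.63 / sqrt(1000))
  expect_lt(abs(mean(pat$age) - 38.77), 2 * 16.28 / sqrt(1000))
  # patient head motion exceeds control motion, as configured
  expect_gt(mean(pat$head_motion), mean(ctrl$head_motion))
  expect_true(all(ph$head_motion > 0))
  expect_true(all(ph$sex %in% c("M", "F")))
  expect_true(all(ph$handedness %in% c("R", "L", "both")))
})

test_that("symptom scores track the designated edge at the target correlation", {
  sp <- cohort_spec(n_control = 0, n_patient = 200, seed = 7)
  co <- generate_cohort(sp)
  ph <- cohort_phenotypes(co)
  se <- sp$symptom_edge
  expect_equal(se$rho, 0.36)
  z <- vapply(co, function(s)
    atanh(cor(s$timeseries[, se$i], s$timeseries[, se$j])), 0)
  expect_lt(abs(cor(z, ph$panss_negative) - se$rho), 0.1)
  # PANSS-negative-style integer scores in the 7-49 item-sum range
  expect_true(all(ph$panss_negative == round(ph$panss_negative)))
  expect_true(all(ph$panss_negative >= 7 & ph$panss_negative <= 49))
})

test_that("spec validation rejects impossible settings", {
  expect_error(cohort_spec(n_regions = 6, n_timepoints = 5), "at least 10")
  expect_error(cohort_spec(n_regions = 6, n_timepoints = 20,
                           planted_edges = data.frame(i = 1, j = 2,
                                                      lambda = 1.2)),
               "\\(0, 1\\)")
  expect_error(cohort_spec(n_regions = 6, n_timepoints = 20,
                           planted_edges = data.frame(i = 1, j = 2,
                                                      lambda = 0.5),
                           effect_edges = data.frame(i = 3, j = 4,
                                                     multiplier = 2)),
               "not a planted edge")
  expect_error(cohort_spec(n_regions = 6, n_timepoints = 20,
                           planted_edges = data.frame(i = 1, j = 2,
                                                      lambda = 0.5),
                           symptom_edge = list(i = 1, j = 2, rho = 1,
                                               score = "s")),
               "rho")
})

test_that("writing a cohort produces readable per-subject files", {
  spec <- small_control_spec(n = 2, regions = 4, timepoints = 12)
  co <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  files <- list.files(dir)
  expect_true("phenotypes.tsv" %in% files)
  ts <- as.matrix(read.delim(file.path(dir,
                                       paste0(co[[1]]$subject_id,
                                              "_timeseries.tsv"))))
  expect_equal(unname(ts), unname(co[[1]]$timeseries), tolerance = 1e-8)
})
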
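# Phantom, DWI simulation, cohort and longitudinal generators.

test_that("phantom generation is deterministic and matches its closed form", {
  a <- make_phantom(phantom_spec(tensor_noise_sd = 2e-5, seed = 7))
  b <- make_phantom(phantom_spec(tensor_noise_sd = 2e-5, seed = 7))
  expect_identical(a$tensor$components, b$tensor$components)

  # noise-free: ground truth and computed index agree to machine precision
  ph <- make_phantom(phantom_spec(eps = 0))
  expect_equal(ph$ground_truth$mean, 1)
  expect_identical(compute_alps(ph$tensor, ph$rois, qc = FALSE)$alps_mean, 1)

  ph2 <- make_phantom(phantom_spec(lambda_perp = 0.4e-3, eps = 0.12e-3))
  expect_equal(ph2$ground_truth$mean, 1.3, tolerance = 1e-15)
  r <- compute_alps(ph2$tensor, ph2$rois, qc = FALSE)
  expect_equal(r$alps_left, 1.3, tolerance = 1e-12)
  expect_equal(r$alps_right, 1.3, tolerance = 1e-12)
  expect_equal(r$alps_mean, 1.3, tolerance = 1e-12)
})

test_that("invalid phantom geometry and parameters are rejected", {
  expect_error(phantom_spec(lambda_par = 3e-4, lambda_perp = 4e-4),
               "lambda_par > lambda_perp")
  expect_error(phantom_spec(eps = -1e-5), "eps")
  expect_error(phantom_spec(proj_x = c(2, 14), assoc_x = c(13, 24)),
               "proj_x")
  # ROI too large for its block
  expect_error(make_phantom(phantom_spec(roi_radius = 8)),
               "does not fit")
})

test_that("simulated b0 volumes equal S0 exactly and noise is seeded", {
  ph <- make_phantom(phantom_spec(dim3 = c(16L, 10L, 10L),
                                  proj_x = c(1, 4), assoc_x = c(4.5, 7.5),
                                  yz_halfwidth = 4, roi_radius = 1))
  dwi <- simulate_dwi(ph$tensor, S0 = 500)
  expect_true(all(dwi$signal[, , , dwi$bvals == 0] == 500))
  expect_length(dwi$bvals, 66)   # 5 b0 + 61 weighted
  n1 <- simulate_dwi(ph$tensor, noise_sd = 10, seed = 4)
  n2 <- simulate_dwi(ph$tensor, noise_sd = 10, seed = 4)
  n3 <- simulate_dwi(ph$tensor, noise_sd = 10, seed = 5)
  expect_identical(n1$signal, n2$signal)
  expect_false(identical(n1$signal, n3$signal))
  expect_error(simulate_dwi(ph$tensor, noise_sd = -1), "noise_sd")
})

test_that("noisy phantoms keep the index near the closed form on average", {
  errs <- vapply(1:10, function(s) {
    ph <- make_phantom(phantom_spec(tensor_noise_sd = 2e-5, seed = s))
    compute_alps(ph$tensor, ph$rois, qc = FALSE)$alps_mean - 1.3
  }, 0)
  expect_lt(abs(mean(errs)), 0.01)
})

test_that("default cohort reproduces the study group structure", {
  d <- make_cohort(cohort_spec(seed = 1))
  expect_equal(nrow(d), 374L)
  expect_equal(sum(d$mutation != "NC"), 291L)
  expect_equal(sum(d$mutation == "NC"), 83L)
  counts <- table(d$group)
  expect_equal(unname(counts["GRN_presymptomatic"]), 88L)
  expect_equal(unname(counts["MAPT_symptomatic"]), 17L)
  expect_true(all(d$nfl > 0) && all(d$gfap > 0))
  expect_true(all(d$cdr_ftld >= 0))
  expect_true(all(is.na(d$years_to_onset[d$mutation == "NC"])))
  expect_true(all(!is.na(d$years_to_onset[d$mutation != "NC"])))
  # determinism
  expect_identical(d, make_cohort(cohort_spec(seed = 1)))
  expect_false(identical(d$alps, make_cohort(cohort_spec(seed = 2))$alps))
})

test_that("zero dispersion collapses every subject onto its group mean", {
  g <- dtialps:::default_group_table()
  g$alps_se <- 1e-12   # dispersions must stay positive; effectively zero
  d <- make_cohort(cohort_spec(groups = g, lr_asym_sd = 0))
  means <- setNames(g$alps_mean, g$group)
  expect_equal(d$alps, unname(means[d$group]), tolerance = 1e-9)
})

test_that("sample group means approach the specification as n grows", {
  g <- dtialps:::default_group_table()
  g$n <- rep(1250L, 8)    # 10^4 subjects
  d <- make_cohort(cohort_spec(groups = g, seed = 42))
  for (k in seq_len(nrow(g))) {
    x <- d$alps[d$group == g$group[k]]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - g$alps_mean[k]), 3 * se + 1e-9)
  }
})

test_that("the generated severity slope is recoverable by the fitted model", {
  hits <- vapply(1:10, function(s) {
    d <- make_cohort(cohort_spec(seed = s))
    a <- association_model(d[d$mutation != "NC", ], "cdr_ftld_latent",
                           "alps")
    abs(a$beta - (-1.16)) <= 1.96 * a$se
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("longitudinal trajectories follow the stratum slopes", {
  d <- make_cohort(cohort_spec(seed = 5))
  # zero noise, zero random effects, exactly two visits one year apart
  spec <- longitudinal_spec(visit_probs = c(0, 1, 0, 0, 0, 0),
                            random_intercept_sd = 0, random_slope_sd = 0,
                            residual_sd = 0, seed = 9)
  v <- make_longitudinal(d, spec)
  expect_true(all(table(v$id) == 2))
  inc <- tapply(v$cdr_ftld_latent, v$id, function(x) diff(x))
  strat <- tapply(as.character(v$stratum), v$id, `[`, 1)
  for (s in c("low", "average", "high"))
    if (any(strat == s))
      expect_equal(as.vector(inc[strat == s]),
                   rep(spec$slopes[[s]], sum(strat == s)),
                   tolerance = 1e-12)
  # reported score is floored at zero
  expect_true(all(v$cdr_ftld >= 0))
  # determinism
  expect_identical(v, make_longitudinal(d, spec))
})

test_that("slope ordering is checked and strata use the NC reference", {
  s <- longitudinal_spec()
  expect_true(s$slopes[["low"]] > s$slopes[["average"]] &&
                s$slopes[["average"]] > s$slopes[["high"]])
  expect_warning(longitudinal_spec(slopes = c(low = 0.01, average = 0.05,
                                              high = 0.2)),
                 "not ordered")
  d <- make_cohort(cohort_spec(seed = 3))
  strata <- assign_strata(d)
  nc <- d$mutation == "NC"
  z <- (d$alps[!nc] - mean(d$alps[nc])) / sd(d$alps[nc])
  expect_identical(as.character(strata),
                   as.character(stratify_alps(d$alps[!nc], mean(d$alps[nc]),
                                              sd(d$alps[nc]))))
  expect_true(all(names(strata) == d$id[!nc]))
  expect_setequal(as.character(unique(strata)),
                  c("low", "average", "high"))
})
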
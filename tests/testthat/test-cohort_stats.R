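# Cross-sectional statistics: stratification, FDR, group comparisons,
# association models and descriptives.

test_that("expected onset is the difference to the familial mean onset", {
  expect_equal(expected_onset(45, 60), -15)
  expect_equal(expected_onset(60, 60), 0)
  expect_equal(expected_onset(70, 58), 12)
  expect_true(is.na(expected_onset(50, NA)))
  expect_error(expected_onset(-1, 60), "positive")
})

test_that("Z-score stratification uses strict inequalities at the boundaries", {
  expect_equal(as.character(stratify_alps(1.75, 1.25, 0.25)), "high")  # z = 2
  expect_equal(as.character(stratify_alps(1.25, 1.25, 0.25)), "average") # z = 0
  expect_equal(as.character(stratify_alps(1.5, 1.25, 0.25)), "average")  # z = 1
  expect_equal(as.character(stratify_alps(1.0, 1.25, 0.25)), "average")  # z = -1
  expect_equal(as.character(stratify_alps(0.96, 1.25, 0.25)), "low")
  expect_error(stratify_alps(1.2, 1.3, 0), "nc_sd")
})

test_that("FDR adjustment matches the brute-force step-up procedure", {
  expect_equal(fdr_adjust(0.04), 0.04)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(rep(0.2, 3)), rep(0.2, 3))
  set.seed(31)
  for (rep in 1:50) {
    p <- runif(sample(1:10, 1))
    expect_equal(fdr_adjust(p), brute_force_bh(p), tolerance = 1e-12)
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("FDR adjustment is monotone and permutation-equivariant", {
  set.seed(8)
  for (rep in 1:20) {
    p <- runif(8)
    q <- fdr_adjust(p)
    expect_true(all(q >= p) && all(q <= 1))
    perm <- sample(8)
    expect_equal(fdr_adjust(p[perm]), q[perm], tolerance = 1e-12)
  }
  # fully tied adjusted vectors are fixed points of the step-up rule
  expect_equal(fdr_adjust(rep(0.03, 5)), rep(0.03, 5))
})

test_that("with no covariate effects the EMMs equal the raw group means", {
  set.seed(15)
  n <- 40
  d <- data.frame(g = rep(c("a", "b"), each = n),
                  y = c(rnorm(n, 1), rnorm(n, 2)),
                  age = rep(rnorm(n, 50, 5), 2),
                  sex = rep(sample(c("F", "M"), n, TRUE), 2),
                  site = rep(sample(paste0("s", 1:3), n, TRUE), 2))
  r <- adjusted_group_comparison(d, "y", "g")
  raw <- tapply(d$y, d$g, mean)
  expect_equal(r$emmeans$emmean, as.vector(raw[r$emmeans$group]),
               tolerance = 1e-10)
  # no covariates, balanced: reduces to the one-way fit
  r2 <- adjusted_group_comparison(d, "y", "g", covariates = character(0))
  expect_equal(r2$emmeans$emmean, as.vector(raw[r2$emmeans$group]),
               tolerance = 1e-12)
  expect_equal(r2$contrasts$p_raw,
               summary(lm(y ~ g, d))$coefficients["gb", "Pr(>|t|)"],
               tolerance = 1e-10)
})

test_that("identically simulated groups stay null at the nominal rate", {
  set.seed(100)
  rejections <- vapply(1:200, function(i) {
    d <- data.frame(g = rep(c("a", "b"), each = 25),
                    y = rnorm(50),
                    age = rnorm(50, 50, 8),
                    sex = sample(c("F", "M"), 50, TRUE),
                    site = sample(paste0("s", 1:3), 50, TRUE))
    adjusted_group_comparison(d, "y", "g")$contrasts$p_adj < 0.05
  }, TRUE)
  expect_gte(mean(!rejections), 0.94)
})

test_that("the declared comparison families have 3 and 9 contrasts", {
  d <- add_stage4(make_cohort(cohort_spec(seed = 2)))
  r3 <- adjusted_group_comparison(d, "alps", "stage4",
                                  family = stage_family())
  expect_equal(nrow(r3$contrasts), 3L)
  r9 <- adjusted_group_comparison(d, "alps", "group",
                                  family = mutation_stage_family())
  expect_equal(nrow(r9$contrasts), 9L)
  expect_true(all(r9$contrasts$p_adj >= r9$contrasts$p_raw - 1e-15))
  expect_true(all(r9$contrasts$p_adj <= 1))
})

test_that("the symptomatic deficit vs old non-carriers is detectable", {
  # at the study group sizes the symptomatic-vs-old-NC contrast is a
  # moderate effect: its sign is stable across cohorts and it reaches
  # FDR significance in a sizeable fraction of replicates
  res <- vapply(1:20, function(s) {
    d <- add_stage4(make_cohort(cohort_spec(seed = 20000 + s)))
    r <- adjusted_group_comparison(d, "alps", "stage4",
                                   family = stage_family())
    ct <- r$contrasts[r$contrasts$contrast == "NC_old - symptomatic", ]
    c(positive = ct$estimate > 0, sig = ct$p_adj < 0.05)
  }, c(positive = TRUE, sig = TRUE))
  # contrast is NC_old minus symptomatic, so a deficit means positive
  expect_gte(sum(res["positive", ]), 17)
  expect_gte(sum(res["sig", ]), 5)
  # the better-powered presymptomatic-vs-symptomatic contrast is reliable
  d <- add_stage4(make_cohort(cohort_spec(seed = 20001)))
  r <- adjusted_group_comparison(d, "alps", "stage4",
                                 family = stage_family())
  ps <- r$contrasts[r$contrasts$contrast == "presymptomatic - symptomatic", ]
  expect_gt(ps$estimate, 0)
  expect_lt(ps$p_adj, 0.05)
})

test_that("rank-deficient designs fail with the collinear column named", {
  d <- make_cohort(cohort_spec(seed = 2))
  d$age2 <- d$age
  expect_error(adjusted_group_comparison(d, "alps", "group",
                                         covariates = c("age", "age2")),
               "age2")
})

test_that("exact linear data is recovered perfectly by association_model", {
  d <- data.frame(x = 1:20, y = 2 * (1:20),
                  age = rnorm(20, 50), sex = rep(c("F", "M"), 10),
                  site = rep(c("s1", "s2"), each = 10))
  a <- association_model(d, "y", "x", covariates = character(0))
  expect_equal(a$beta, 2, tolerance = 1e-12)
  expect_equal(a$r_squared, 1, tolerance = 1e-12)
})

test_that("association slopes are invariant to affine covariate shifts", {
  d <- make_cohort(cohort_spec(seed = 6))
  carriers <- d[d$mutation != "NC", ]
  a1 <- association_model(carriers, "cdr_ftld_latent", "alps")
  carriers$age <- (carriers$age - 50) / 10
  a2 <- association_model(carriers, "cdr_ftld_latent", "alps")
  expect_equal(a2$beta, a1$beta, tolerance = 1e-10)
  expect_equal(a2$se, a1$se, tolerance = 1e-10)
})

test_that("plasma models log-transform and reject non-positive values", {
  d <- make_cohort(cohort_spec(seed = 7))
  carriers <- d[d$mutation != "NC", ]
  a <- association_model(carriers, "nfl", "alps",
                         covariates = c("age", "sex", "site", "plasma_site"),
                         log_transform_y = TRUE)
  expect_true(is.finite(a$beta))
  carriers$nfl[3] <- 0
  expect_error(association_model(carriers, "nfl", "alps",
                                 log_transform_y = TRUE),
               carriers$id[3])
})

test_that("null association slopes reject at about the nominal 5% level", {
  set.seed(77)
  rej <- vapply(1:300, function(i) {
    n <- 120
    d <- data.frame(x = rnorm(n), y = rnorm(n), age = rnorm(n, 50, 8),
                    sex = sample(c("F", "M"), n, TRUE),
                    site = sample(paste0("s", 1:3), n, TRUE))
    association_model(d, "y", "x")$p < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("descriptive tests match hand-computed oracles", {
  # Kruskal-Wallis H by rank sums on a 3 x 4 worked sample
  d <- data.frame(g = rep(c("a", "b", "c"), each = 4),
                  v = c(1, 3, 5, 7, 2, 4, 6, 12, 8, 9, 10, 11))
  rk <- rank(d$v)
  n <- nrow(d)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(rk, d$g, function(r) sum(r)^2 / length(r))) - 3 * (n + 1)
  p_oracle <- pchisq(H, df = 2, lower.tail = FALSE)
  tab <- describe_cohort(d, "g", "v")
  expect_equal(tab$p_value, p_oracle, tolerance = 1e-12)

  # identical constant values in all groups carry no group signal
  d0 <- data.frame(g = rep(c("a", "b"), each = 3), v = rep(5, 6))
  tab0 <- describe_cohort(d0, "g", "v")
  expect_true(is.na(tab0$p_value) || tab0$p_value >= 0.999)

  # equality of proportions: 29/50 vs 20/33 females, Pearson formula
  d2 <- data.frame(g = rep(c("young", "old"), c(50, 33)),
                   sex = c(rep(c("F", "M"), c(29, 21)),
                           rep(c("F", "M"), c(20, 13))))
  p1 <- 29 / 50; p2 <- 20 / 33; pp <- 49 / 83
  chi <- (p1 - p2)^2 / (pp * (1 - pp) * (1 / 50 + 1 / 33))
  p_oracle2 <- pchisq(chi, df = 1, lower.tail = FALSE)
  tab2 <- describe_cohort(d2, "g", "sex")
  expect_equal(tab2$p_value, p_oracle2, tolerance = 1e-12)
})

test_that("entirely missing variables are omitted with a warning", {
  d <- data.frame(g = rep(c("a", "b"), each = 3), v = rnorm(6),
                  w = NA_real_)
  expect_warning(tab <- describe_cohort(d, "g", c("v", "w")),
                 "entirely missing")
  expect_equal(tab$variable, "v")
})
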
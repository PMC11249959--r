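# Synthetic genetic-FTD cohort generator.
#
# The generator emulates the statistical structure a multi-site genetic
# frontotemporal dementia cohort study assumes: eight groups (young/old
# non-carriers; presymptomatic and symptomatic C9orf72, GRN and MAPT
# mutation carriers) with study-defaults group sizes, per-group ALPS
# marginal means, demographics, and association slopes linking ALPS to
# disease severity (CDR-FTLD), years to expected onset and log plasma
# markers. Subject-level ALPS dispersion is derived from the printed
# standard errors of the estimated marginal means as SE * sqrt(n).

GROUP_KEYS <- c("NC_young", "NC_old",
                "C9orf72_presymptomatic", "GRN_presymptomatic",
                "MAPT_presymptomatic",
                "C9orf72_symptomatic", "GRN_symptomatic",
                "MAPT_symptomatic")

default_group_table <- function() {
  data.frame(
    group = GROUP_KEYS,
    mutation = c("NC", "NC", "C9orf72", "GRN", "MAPT",
                 "C9orf72", "GRN", "MAPT"),
    stage = c(NA, NA, rep("presymptomatic", 3), rep("symptomatic", 3)),
    nc_age_class = c("young", "old", rep(NA, 6)),
    n = c(50L, 33L, 68L, 88L, 43L, 44L, 31L, 17L),
    alps_mean = c(1.32, 1.29, 1.28, 1.32, 1.28, 1.19, 1.24, 1.21),
    alps_se = c(0.02, 0.03, 0.02, 0.02, 0.03, 0.03, 0.03, 0.04),
    age_mean = c(40, 62, 44, 45, 39, 62, 62, 59),
    age_sd = c(6, 7, 11, 12, 9, 8, 9, 10),
    female_prop = c(0.58, 0.61, 0.59, 0.68, 0.56, 0.34, 0.42, 0.35),
    onset_center = c(NA, NA, -16, -15, -13, 2, 2, 2),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic cross-sectional cohort
#'
#' @param groups data frame of per-group parameters (one row per group:
#'   sizes, ALPS estimated-marginal-mean and SE, age distribution, female
#'   proportion, years-to-onset centre). Defaults to the study-structure
#'   table; subject-level ALPS SD is `alps_se * sqrt(n)`.
#' @param beta_cdr slope of CDR-FTLD on ALPS among carriers (default -1.16).
#' @param beta_nfl slope of log plasma NfL on ALPS (default -0.28).
#' @param beta_gfap slope of log plasma GFAP on ALPS (default -0.10).
#' @param beta_onset slope of years-to-expected-onset on ALPS among
#'   presymptomatic carriers (default -9.94).
#' @param cdr_intercept intercept of the CDR-FTLD generator; the default
#'   puts the mean carrier latent severity near 1.
#' @param cdr_sd residual SD of latent CDR-FTLD (default 0.45).
#' @param onset_sd residual SD of years-to-onset (default 10).
#' @param log_nfl_intercept,log_gfap_intercept plasma model intercepts on
#'   the natural-log scale.
#' @param log_nfl_sd,log_gfap_sd residual SDs on the log scale.
#' @param lr_asym_sd SD of the left/right hemispheric split around each
#'   subject's bilateral ALPS (default 0.015).
#' @param n_sites number of imaging sites (uniform assignment; default 5).
#' @param n_plasma_sites number of plasma analysis sites (default 2).
#' @param education_mean,education_sd years of education.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = default_group_table(),
                        beta_cdr = -1.16, beta_nfl = -0.28,
                        beta_gfap = -0.10, beta_onset = -9.94,
                        cdr_intercept = NULL, cdr_sd = 0.45,
                        onset_sd = 10,
                        log_nfl_intercept = NULL, log_nfl_sd = 0.6,
                        log_gfap_intercept = NULL, log_gfap_sd = 0.5,
                        lr_asym_sd = 0.015,
                        n_sites = 5L, n_plasma_sites = 2L,
                        education_mean = 14, education_sd = 3,
                        seed = 1L) {
  stopifnot(is.data.frame(groups), all(groups$n >= 0),
            all(groups$alps_se > 0), all(groups$age_sd > 0))
  if (!setequal(groups$group, GROUP_KEYS))
    stop("`groups` must contain exactly the eight study groups", call. = FALSE)
  carrier_alps <- with(groups[groups$mutation != "NC", ],
                       sum(alps_mean * n) / sum(n))
  structure(list(
    groups = groups, beta_cdr = beta_cdr, beta_nfl = beta_nfl,
    beta_gfap = beta_gfap, beta_onset = beta_onset,
    cdr_intercept = cdr_intercept %||% (1 - beta_cdr * carrier_alps),
    cdr_sd = cdr_sd, onset_sd = onset_sd,
    log_nfl_intercept = log_nfl_intercept %||% (log(15) - beta_nfl * carrier_alps),
    log_nfl_sd = log_nfl_sd,
    log_gfap_intercept = log_gfap_intercept %||% (log(120) - beta_gfap * carrier_alps),
    log_gfap_sd = log_gfap_sd,
    lr_asym_sd = lr_asym_sd, n_sites = as.integer(n_sites),
    n_plasma_sites = as.integer(n_plasma_sites),
    education_mean = education_mean, education_sd = education_sd,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' Generate a synthetic cross-sectional cohort table
#'
#' One row per subject. ALPS values are group mean + Gaussian subject
#' noise (SD = SE * sqrt(n)); the left and right indices split
#' symmetrically around the bilateral mean. CDR-FTLD is generated on a
#' continuous latent scale from the marginal association model
#' `cdr = a + beta_cdr * alps + noise` (carriers) and reported both as the
#' latent value (`cdr_ftld_latent`, used by the statistics by default) and
#' rounded to the instrument step of 0.5 and floored at 0 (`cdr_ftld`).
#' Plasma markers are generated on the log scale and exponentiated, so
#' they are strictly positive.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional seed overriding `spec$seed`.
#' @return A data frame of class `alps_cohort`.
#' @export
make_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- seed %||% spec$seed
  g <- spec$groups
  withr_seed(seed, {
    rows <- lapply(seq_len(nrow(g)), function(i) {
      n <- g$n[i]
      if (n == 0L) return(NULL)
      sd_alps <- g$alps_se[i] * sqrt(g$n[i])
      alps <- g$alps_mean[i] + rnorm(n, 0, sd_alps)
      asym <- rnorm(n, 0, spec$lr_asym_sd)
      data.frame(
        group = g$group[i], mutation = g$mutation[i], stage = g$stage[i],
        nc_age_class = g$nc_age_class[i],
        age = round(rnorm(n, g$age_mean[i], g$age_sd[i]), 1),
        sex = ifelse(runif(n) < g$female_prop[i], "F", "M"),
        alps = alps, alps_left = alps + asym, alps_right = alps - asym,
        onset_center = g$onset_center[i],
        stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    n <- nrow(d)
    d$id <- sprintf("S%03d", seq_len(n))
    d$site <- sample(paste0("site", seq_len(spec$n_sites)), n, replace = TRUE)
    d$plasma_site <- sample(paste0("lab", seq_len(spec$n_plasma_sites)), n,
                            replace = TRUE)
    d$education <- pmax(round(rnorm(n, spec$education_mean,
                                    spec$education_sd)), 5)
    carrier <- d$mutation != "NC"
    d$cdr_ftld_latent <- NA_real_
    d$cdr_ftld_latent[carrier] <- spec$cdr_intercept +
      spec$beta_cdr * d$alps[carrier] + rnorm(sum(carrier), 0, spec$cdr_sd)
    d$cdr_ftld_latent[!carrier] <- pmax(rnorm(sum(!carrier), 0.1, 0.2), 0)
    d$cdr_ftld <- pmax(round(d$cdr_ftld_latent * 2) / 2, 0)
    d$years_to_onset <- NA_real_
    d$years_to_onset[carrier] <- d$onset_center[carrier] +
      spec$beta_onset * (d$alps[carrier] - mean(d$alps[carrier])) +
      rnorm(sum(carrier), 0, spec$onset_sd)
    d$nfl <- exp(spec$log_nfl_intercept + spec$beta_nfl * d$alps +
                   rnorm(n, 0, spec$log_nfl_sd))
    d$gfap <- exp(spec$log_gfap_intercept + spec$beta_gfap * d$alps +
                    rnorm(n, 0, spec$log_gfap_sd))
    d$onset_center <- NULL
    d <- d[, c("id", "group", "mutation", "stage", "nc_age_class", "age",
               "sex", "site", "plasma_site", "education", "alps",
               "alps_left", "alps_right", "cdr_ftld", "cdr_ftld_latent",
               "years_to_onset", "nfl", "gfap")]
    class(d) <- c("alps_cohort", "data.frame")
    d
  })
}

#' Specification of the longitudinal follow-up generator
#'
#' @param slopes named annual CDR-FTLD progression rates for the three
#'   baseline ALPS strata (defaults: low 0.20, average 0.05, high -0.01
#'   CDR-FTLD units/year; must be decreasing from low to high).
#' @param visit_spacing years between successive visits (default 1).
#' @param visit_probs probabilities of a subject having 1..6 visits
#'   (defaults mirror a cohort in which 180/282 subjects have at least two
#'   evaluations for ~640 in total).
#' @param random_intercept_sd,random_slope_sd subject-level random-effect
#'   SDs (defaults 0.10, 0.05).
#' @param residual_sd visit-level residual SD (default 0.10).
#' @param seed integer seed.
#' @return An object of class `longitudinal_spec`.
#' @export
longitudinal_spec <- function(slopes = c(low = 0.20, average = 0.05,
                                         high = -0.01),
                              visit_spacing = 1,
                              visit_probs = c(102, 75, 50, 40, 12, 3) / 282,
                              random_intercept_sd = 0.10,
                              random_slope_sd = 0.05,
                              residual_sd = 0.10, seed = 1L) {
  stopifnot(all(c("low", "average", "high") %in% names(slopes)),
            random_intercept_sd >= 0, random_slope_sd >= 0,
            residual_sd >= 0, visit_spacing > 0)
  if (slopes["low"] < slopes["average"] || slopes["average"] < slopes["high"])
    warning("stratum slopes are not ordered low >= average >= high; ",
            "faster progression is expected at lower baseline ALPS")
  visit_probs <- visit_probs / sum(visit_probs)
  structure(list(slopes = slopes, visit_spacing = visit_spacing,
                 visit_probs = visit_probs,
                 random_intercept_sd = random_intercept_sd,
                 random_slope_sd = random_slope_sd,
                 residual_sd = residual_sd, seed = as.integer(seed)),
            class = "longitudinal_spec")
}

#' Generate longitudinal CDR-FTLD visits for mutation carriers
#'
#' Baseline ALPS of each carrier is converted to a Z-score against the
#' pooled non-carrier mean and SD ([stratify_alps()]); the stratum
#' determines the fixed progression slope. Each visit's latent severity is
#' `baseline + (slope + subject random slope) * t + random intercept +
#' noise`; the reported `cdr_ftld` is floored at 0, the latent value is
#' kept in `cdr_ftld_latent`.
#'
#' @param cohort an `alps_cohort` from [make_cohort()].
#' @param spec a [longitudinal_spec()].
#' @param seed optional seed overriding `spec$seed`.
#' @return A data frame of visits: `id`, `time` (years from baseline),
#'   `cdr_ftld`, `cdr_ftld_latent`, `stratum`.
#' @export
make_longitudinal <- function(cohort, spec = longitudinal_spec(),
                              seed = NULL) {
  stopifnot(inherits(spec, "longitudinal_spec"))
  seed <- seed %||% spec$seed
  carriers <- cohort[cohort$mutation != "NC", ]
  if (!nrow(carriers)) stop("cohort contains no mutation carriers", call. = FALSE)
  strata <- assign_strata(cohort)
  carriers$stratum <- unname(strata[carriers$id])
  withr_seed(seed, {
    nsub <- nrow(carriers)
    nvisits <- sample(seq_along(spec$visit_probs), nsub, replace = TRUE,
                      prob = spec$visit_probs)
    b0 <- rnorm(nsub, 0, spec$random_intercept_sd)
    b1 <- rnorm(nsub, 0, spec$random_slope_sd)
    rows <- lapply(seq_len(nsub), function(i) {
      t <- (seq_len(nvisits[i]) - 1) * spec$visit_spacing
      base <- carriers$cdr_ftld_latent[i]
      slope <- spec$slopes[[as.character(carriers$stratum[i])]]
      latent <- base + b0[i] + (slope + b1[i]) * t +
        rnorm(length(t), 0, spec$residual_sd)
      data.frame(id = carriers$id[i], time = t,
                 cdr_ftld = pmax(latent, 0), cdr_ftld_latent = latent,
                 stratum = carriers$stratum[i], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
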
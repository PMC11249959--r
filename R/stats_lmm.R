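# Linear mixed model of longitudinal disease-severity progression.

#' Mixed-effects model of CDR-FTLD progression by baseline ALPS stratum
#'
#' Fits (by REML) the model
#' `cdr ~ time * stratum + age + sex + baseline_cdr + site + (1 + time | id)`
#' with random intercepts and slopes at the subject level, and reports the
#' per-stratum annual progression slopes (time coefficient plus the
#' stratum interaction) and their pairwise contrasts with Wald z tests.
#' The degrees-of-freedom approximation is deliberately asymptotic: fixed
#' effects and contrasts use Wald z statistics.
#'
#' @param visits visit table from [make_longitudinal()] (or matching its
#'   schema: `id`, `time`, outcome column).
#' @param cohort cross-sectional table supplying `age`, `sex`, `site` per id.
#' @param strata optional named factor of strata per id; computed via
#'   [assign_strata()] from the cohort when NULL.
#' @param outcome outcome column in `visits`; default `"cdr_ftld_latent"`
#'   (the continuous latent severity), falling back to `"cdr_ftld"`.
#' @param covariates covariate columns from the cohort (default
#'   `c("age", "sex", "site")`); baseline severity is always included.
#' @return An object of class `lmm_fit`: `fixed_effects` (estimate, SE,
#'   Wald z p), `slopes` per stratum, `slope_contrasts`,
#'   `interaction_test` (2-df Wald chi-square), variance components,
#'   convergence diagnostics and the `lme4` fit.
#' @export
lmm_progression <- function(visits, cohort, strata = NULL,
                            outcome = NULL,
                            covariates = c("age", "sex", "site")) {
  visits <- as.data.frame(visits)
  cohort <- as.data.frame(cohort)
  outcome <- outcome %||%
    (if ("cdr_ftld_latent" %in% names(visits)) "cdr_ftld_latent" else "cdr_ftld")
  if (!all(c("id", "time", outcome) %in% names(visits)))
    stop("`visits` must contain id, time and '", outcome, "'", call. = FALSE)
  nv <- table(visits$id)
  if (all(nv < 2L))
    stop("all subjects have a single visit; no longitudinal information",
         call. = FALSE)
  if (is.null(strata)) strata <- assign_strata(cohort)
  d <- visits
  d$stratum <- factor(as.character(strata[as.character(d$id)]),
                      levels = c("low", "average", "high"))
  base <- visits[visits$time == 0, c("id", outcome)]
  names(base)[2] <- "baseline_cdr"
  if (!all(unique(d$id) %in% base$id))
    stop("every subject needs a baseline (time 0) visit", call. = FALSE)
  d <- merge(d, base, by = "id")
  d <- merge(d, cohort[, c("id", covariates)], by = "id")
  for (cv in covariates)
    if (is.character(d[[cv]])) d[[cv]] <- factor(d[[cv]])
  d <- d[complete.cases(d[, c("id", "time", outcome, "stratum",
                              "baseline_cdr", covariates)]), ]
  d <- droplevels(d)

  # degenerate designs: drop single-level factors (including a single
  # populated stratum) so the model stays estimable
  covariates <- covariates[vapply(covariates, function(cv)
    !is.factor(d[[cv]]) || nlevels(d[[cv]]) >= 2L, TRUE)]
  stratum_terms <- if (nlevels(d$stratum) >= 2L) "time * stratum" else "time"
  fml <- reformulate(
    c(stratum_terms, "baseline_cdr", covariates, "(1 + time | id)"),
    response = outcome)
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  b <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  fe <- data.frame(term = names(b), estimate = unname(b),
                   se = sqrt(diag(V)), stringsAsFactors = FALSE)
  fe$z <- fe$estimate / fe$se
  fe$p <- 2 * pnorm(-abs(fe$z))

  strata_levels <- if (nlevels(d$stratum) >= 2L) levels(d$stratum) else
    as.character(unique(d$stratum))
  combo <- function(L) {
    est <- sum(L * b)
    se <- sqrt(drop(t(L) %*% V %*% L))
    c(estimate = est, se = se, z = est / se, p = 2 * pnorm(-abs(est / se)))
  }
  slope_L <- lapply(strata_levels, function(s) {
    L <- numeric(length(b)); names(L) <- names(b)
    L["time"] <- 1
    inter <- paste0("time:stratum", s)
    if (inter %in% names(b)) L[inter] <- 1
    L
  })
  names(slope_L) <- strata_levels
  slopes <- as.data.frame(do.call(rbind, lapply(slope_L, combo)))
  slopes <- cbind(stratum = strata_levels, slopes)
  rownames(slopes) <- NULL

  pairs <- if (length(strata_levels) >= 2L)
    utils::combn(strata_levels, 2, simplify = FALSE) else list()
  contrasts <- do.call(rbind, lapply(pairs, function(p) {
    L <- slope_L[[p[1]]] - slope_L[[p[2]]]
    cbind(data.frame(contrast = paste(p, collapse = " - ")),
          as.data.frame(t(combo(L))))
  }))
  rownames(contrasts) <- NULL

  inter_terms <- grep("^time:stratum", names(b), value = TRUE)
  interaction_test <- if (length(inter_terms)) {
    Li <- diag(length(b))[match(inter_terms, names(b)), , drop = FALSE]
    bi <- Li %*% b
    W <- drop(t(bi) %*% solve(Li %*% V %*% t(Li)) %*% bi)
    list(chisq = W, df = length(inter_terms),
         p = pchisq(W, length(inter_terms), lower.tail = FALSE))
  } else NULL

  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- list(fixed_effects = fe, slopes = slopes,
              slope_contrasts = contrasts,
              interaction_test = interaction_test,
              variance_components = vc,
              converged = length(fit@optinfo$conv$lme4$messages) == 0,
              singular = lme4::isSingular(fit),
              messages = msgs, n_subjects = length(unique(d$id)),
              n_visits = nrow(d), outcome = outcome, fit = fit)
  class(out) <- "lmm_fit"
  out
}

#' @exportS3Method base::print
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s, %d subjects, %d visits%s\n", x$outcome,
              x$n_subjects, x$n_visits,
              if (x$singular) " (singular fit)" else ""))
  cat("Per-stratum annual slopes:\n")
  print(format(x$slopes, digits = 3), row.names = FALSE)
  cat("Slope contrasts (Wald z):\n")
  print(format(x$slope_contrasts, digits = 3), row.names = FALSE)
  if (!is.null(x$interaction_test))
    cat(sprintf("Stratum x time interaction: chi2(%d) = %.2f, p = %.4g\n",
                x$interaction_test$df, x$interaction_test$chisq,
                x$interaction_test$p))
  invisible(x)
}
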
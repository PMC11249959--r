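# Cross-sectional cohort statistics: descriptives, covariate-adjusted
# group comparisons with FDR-corrected pre-defined contrasts, association
# models, and ALPS Z-score stratification.

#' Years to expected symptom onset
#'
#' Difference between age at assessment and the mean age at symptom onset
#' within the subject's family; negative values are years before expected
#' onset. A missing family onset yields NA, not an error.
#'
#' @param age age at assessment (years, > 0).
#' @param family_mean_onset mean familial age at onset (years, > 0).
#' @return `age - family_mean_onset`, vectorised.
#' @export
expected_onset <- function(age, family_mean_onset) {
  if (any(age <= 0, na.rm = TRUE) ||
      any(family_mean_onset <= 0, na.rm = TRUE))
    stop("ages must be positive", call. = FALSE)
  age - family_mean_onset
}

#' Stratify ALPS values by Z-score against a non-carrier reference
#'
#' `z = (value - nc_mean) / nc_sd`; `z > 1` is "high", `z < -1` "low",
#' everything else (including the boundaries, which the strict inequalities
#' leave unassigned) "average".
#'
#' @param values numeric ALPS values.
#' @param nc_mean,nc_sd reference mean and SD (pooled over young and old
#'   non-carriers).
#' @return A factor with levels `low`, `average`, `high`.
#' @export
stratify_alps <- function(values, nc_mean, nc_sd) {
  if (!is.finite(nc_sd) || nc_sd <= 0)
    stop("`nc_sd` must be > 0", call. = FALSE)
  z <- (values - nc_mean) / nc_sd
  factor(ifelse(z > 1, "high", ifelse(z < -1, "low", "average")),
         levels = c("low", "average", "high"))
}

#' Assign baseline ALPS strata within a cohort
#'
#' Computes the pooled non-carrier mean and sample SD of the bilateral
#' ALPS index and stratifies all mutation carriers.
#'
#' @param cohort an `alps_cohort` data frame (needs `mutation`, `alps`, `id`).
#' @param value_col column holding the ALPS value (default `"alps"`).
#' @return Named factor (names = carrier ids) of strata.
#' @export
assign_strata <- function(cohort, value_col = "alps") {
  nc <- cohort$mutation == "NC"
  if (!any(nc)) stop("cohort contains no non-carriers for the reference",
                     call. = FALSE)
  m <- mean(cohort[[value_col]][nc])
  s <- sd(cohort[[value_col]][nc])
  carriers <- cohort[!nc, ]
  setNames(stratify_alps(carriers[[value_col]], m, s), carriers$id)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, order preserving and capped at 1. Inputs
#' outside \[0, 1\] are an error.
#'
#' @param pvalues numeric vector of raw p-values.
#' @return Adjusted p-values in the input order.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Pre-defined comparison families
#'
#' `stage_family()` returns the three stage-level comparisons (young NC vs
#' presymptomatic, old NC vs symptomatic, presymptomatic vs symptomatic);
#' `mutation_stage_family()` the nine mutation-by-stage comparisons (young
#' NC vs each presymptomatic group, old NC vs each symptomatic group, and
#' presymptomatic vs symptomatic within each mutation). FDR adjustment is
#' applied within a family only, never pooled across analyses.
#'
#' @return A named list of length-2 character vectors (group levels).
#' @export
stage_family <- function() {
  list("NC_young - presymptomatic" = c("NC_young", "presymptomatic"),
       "NC_old - symptomatic" = c("NC_old", "symptomatic"),
       "presymptomatic - symptomatic" = c("presymptomatic", "symptomatic"))
}

#' @rdname stage_family
#' @export
mutation_stage_family <- function() {
  fam <- list()
  for (m in c("C9orf72", "GRN", "MAPT")) {
    fam[[paste0("NC_young - ", m, "_presymptomatic")]] <-
      c("NC_young", paste0(m, "_presymptomatic"))
    fam[[paste0("NC_old - ", m, "_symptomatic")]] <-
      c("NC_old", paste0(m, "_symptomatic"))
    fam[[paste0(m, "_presymptomatic - ", m, "_symptomatic")]] <-
      c(paste0(m, "_presymptomatic"), paste0(m, "_symptomatic"))
  }
  fam
}

#' Collapse the eight-group structure to stage level
#'
#' Adds a `stage4` column: `NC_young`, `NC_old`, `presymptomatic`,
#' `symptomatic`.
#'
#' @param cohort an `alps_cohort` data frame.
#' @return The cohort with a `stage4` column.
#' @export
add_stage4 <- function(cohort) {
  cohort$stage4 <- ifelse(cohort$mutation == "NC",
                          paste0("NC_", cohort$nc_age_class), cohort$stage)
  cohort
}

#' Covariate-adjusted group comparison with pre-defined contrasts
#'
#' Fits `outcome ~ group + covariates`, computes estimated marginal means
#' on the reference grid (continuous covariates at their means,
#' categorical covariates averaged with observed proportions), tests only
#' the declared comparison family, and FDR-adjusts within that family.
#'
#' @param cohort data frame.
#' @param outcome outcome column name (e.g. `"alps"`).
#' @param grouping grouping column name.
#' @param covariates character vector of covariate columns (default
#'   `c("age", "sex", "site")`).
#' @param family named list of length-2 character vectors of group levels
#'   to compare (see [stage_family()]); `NULL` means all pairwise.
#' @return An object of class `emm_result`: `emmeans` data frame
#'   (group, emmean, se) and `contrasts` data frame (estimate, se, raw and
#'   FDR-adjusted p, significance label with "trend" for 0.05 <= p < 0.10).
#' @export
adjusted_group_comparison <- function(cohort, outcome, grouping,
                                      covariates = c("age", "sex", "site"),
                                      family = NULL) {
  d <- as.data.frame(cohort)
  cols <- c(outcome, grouping, covariates)
  missing_cols <- setdiff(cols, names(d))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d <- d[complete.cases(d[cols]), cols, drop = FALSE]
  d[[grouping]] <- factor(d[[grouping]])
  if (nlevels(d[[grouping]]) < 2L || any(table(d[[grouping]]) < 2L))
    stop("need >= 2 groups with >= 2 subjects each", call. = FALSE)
  for (cv in covariates)
    if (is.character(d[[cv]])) d[[cv]] <- factor(d[[cv]])
  fml <- reformulate(c(grouping, covariates), response = outcome)
  mm <- model.matrix(fml, data = d)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit <- lm(fml, data = d)
  emm <- emmeans::emmeans(fit, specs = grouping, weights = "proportional")
  emm_df <- as.data.frame(emm)
  levs <- as.character(emm_df[[grouping]])
  if (is.null(family)) {
    family <- list()
    pairs <- utils::combn(levs, 2, simplify = FALSE)
    for (p in pairs) family[[paste(p, collapse = " - ")]] <- p
  }
  methods <- lapply(family, function(p) {
    if (!all(p %in% levs))
      stop("comparison family refers to unknown group level(s): ",
           paste(setdiff(p, levs), collapse = ", "), call. = FALSE)
    v <- numeric(length(levs))
    v[levs == p[1]] <- 1
    v[levs == p[2]] <- -1
    v
  })
  ctr <- as.data.frame(emmeans::contrast(emm, method = methods,
                                         adjust = "none"))
  ctr$p_adj <- fdr_adjust(ctr$p.value)
  ctr$label <- ifelse(ctr$p_adj < 0.05, "significant",
                      ifelse(ctr$p_adj < 0.10, "trend", "ns"))
  out <- list(
    emmeans = data.frame(group = levs, emmean = emm_df$emmean,
                         se = emm_df$SE, stringsAsFactors = FALSE),
    contrasts = data.frame(contrast = ctr$contrast,
                           estimate = ctr$estimate, se = ctr$SE,
                           p_raw = ctr$p.value, p_adj = ctr$p_adj,
                           label = ctr$label, stringsAsFactors = FALSE),
    outcome = outcome, grouping = grouping, covariates = covariates,
    n = nrow(d), fit = fit)
  class(out) <- "emm_result"
  out
}

#' @exportS3Method base::print
print.emm_result <- function(x, ...) {
  cat(sprintf("<emm_result> %s by %s (n = %d), adjusted for: %s\n",
              x$outcome, x$grouping, x$n,
              paste(x$covariates, collapse = ", ")))
  print(format(x$emmeans, digits = 4), row.names = FALSE)
  cat("Pre-defined contrasts (FDR within family):\n")
  print(format(x$contrasts, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Association between ALPS and a clinical or plasma variable
#'
#' Linear model of `y` on `x` with covariates; the reported slope is the
#' coefficient of `x`. Plasma outcomes are natural-log transformed before
#' fitting (`log_transform_y = TRUE`); non-positive values under the log
#' are an error listing the offending subject ids. Complete-case analysis
#' per model.
#'
#' @param cohort data frame.
#' @param y,x outcome and predictor column names.
#' @param covariates covariate columns (default `c("age", "sex", "site")`;
#'   plasma models should add the plasma analysis site).
#' @param log_transform_y log-transform the outcome (default FALSE).
#' @return An object of class `assoc_result`: `beta`, `se`, `p`, `n`,
#'   `r_squared` and the underlying `fit`.
#' @export
association_model <- function(cohort, y, x,
                              covariates = c("age", "sex", "site"),
                              log_transform_y = FALSE) {
  d <- as.data.frame(cohort)
  cols <- c(y, x, covariates)
  missing_cols <- setdiff(cols, names(d))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  keep <- complete.cases(d[cols])
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < length(covariates) + 3L)
    stop("too few complete cases for the model", call. = FALSE)
  if (log_transform_y) {
    bad <- d[[y]] <= 0
    if (any(bad))
      stop("non-positive values of '", y, "' under log transform (ids: ",
           paste(head(d$id[bad], 10), collapse = ", "), ")", call. = FALSE)
    d[[y]] <- log(d[[y]])
  }
  for (cv in covariates)
    if (is.character(d[[cv]])) d[[cv]] <- factor(d[[cv]])
  fit <- lm(reformulate(c(x, covariates), response = y), data = d)
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  out <- list(beta = unname(co[x, "Estimate"]), se = unname(co[x, "Std. Error"]),
              p = unname(co[x, "Pr(>|t|)"]), n = nrow(d),
              r_squared = sm$r.squared, y = y, x = x,
              log_transform_y = log_transform_y, fit = fit)
  class(out) <- "assoc_result"
  out
}

#' @exportS3Method base::print
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> %s%s ~ %s: beta = %.4g (SE %.3g), p = %.4g, n = %d\n",
              if (x$log_transform_y) "log " else "", x$y, x$x,
              x$beta, x$se, x$p, x$n))
  invisible(x)
}

#' Descriptive table with group tests
#'
#' Per-variable group summaries with Kruskal-Wallis rank sum tests for
#' continuous variables and equality-of-proportions tests for categorical
#' ones (chi-square test for multi-level factors). Variables that are
#' entirely missing are omitted with a warning.
#'
#' @param cohort data frame.
#' @param grouping grouping column name.
#' @param variables character vector of columns to describe; defaults to
#'   every column except the grouping and id.
#' @return A data frame with one row per variable x group summary plus the
#'   test p-value, of class `cohort_description`.
#' @export
describe_cohort <- function(cohort, grouping, variables = NULL) {
  d <- as.data.frame(cohort)
  d[[grouping]] <- factor(d[[grouping]])
  variables <- variables %||% setdiff(names(d), c(grouping, "id"))
  groups <- levels(d[[grouping]])
  rows <- list()
  for (v in variables) {
    x <- d[[v]]
    if (all(is.na(x))) {
      warning("variable '", v, "' is entirely missing; omitted")
      next
    }
    if (is.numeric(x)) {
      cells <- vapply(groups, function(gr) {
        xi <- x[d[[grouping]] == gr & !is.na(x)]
        if (!length(xi)) return(NA_character_)
        sprintf("%.2f (%.2f)", mean(xi), sd(xi))
      }, "")
      keep <- !is.na(x)
      p <- if (length(unique(d[[grouping]][keep])) >= 2)
        kruskal.test(x[keep], droplevels(d[[grouping]][keep]))$p.value
      else NA_real_
      test <- "kruskal-wallis"
    } else {
      x <- factor(x)
      tab <- table(d[[grouping]], x)
      if (nlevels(x) == 2L) {
        succ <- tab[, 2]; tot <- rowSums(tab)
        ok <- tot > 0
        p <- tryCatch(suppressWarnings(
          prop.test(succ[ok], tot[ok], correct = FALSE)$p.value),
          error = function(e) NA_real_)
        cells <- vapply(groups, function(gr) {
          ti <- tab[gr, ]
          if (sum(ti) == 0) return(NA_character_)
          sprintf("%.0f%% (%d)", 100 * ti[2] / sum(ti), ti[2])
        }, "")
        test <- "equality-of-proportions"
      } else {
        p <- tryCatch(suppressWarnings(chisq.test(tab, correct = FALSE)$p.value),
                      error = function(e) NA_real_)
        cells <- vapply(groups, function(gr) {
          ti <- tab[gr, ]
          if (sum(ti) == 0) return(NA_character_)
          paste(sprintf("%s:%d", colnames(tab), ti), collapse = " ")
        }, "")
        test <- "chi-square"
      }
    }
    rows[[v]] <- data.frame(variable = v, t(cells), test = test,
                            p_value = p, stringsAsFactors = FALSE,
                            check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_description", "data.frame")
  out
}
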
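# Cohort bookkeeping, atlas ROI means, and the staged group-comparison
# statistics with covariate adjustment.

#' Cohort table
#'
#' Validates a per-subject metadata table.  Expected columns: `id`,
#' `group_t2dm` (logical), `group_cognition` (`"low"`/`"high"`), `age`
#' (years), `sex` (`"m"`/`"f"` or 0/1), `atrophy_ml` (lateral ventricular
#' volume, the atrophy proxy), `icv_mm3`, and optionally `carotid_flow`
#' (cm^3/s), `depression` (logical), `exclusion_cbf`, `exclusion_flow`
#' (semicolon-separated reason strings, empty/NA = included at that stage).
#'
#' @param df a `data.frame`.
#' @return the validated `data.frame` with class `cohort_table` prepended.
#' @export
cohort_table <- function(df) {
  required <- c("id", "group_t2dm", "group_cognition")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_devoxel("cohort table lacks columns: ", paste(missing, collapse = ", "),
                 class = "devoxel_parameter_error")
  }
  if (anyDuplicated(df$id)) {
    stop_devoxel("subject ids must be unique", class = "devoxel_parameter_error")
  }
  if (!all(df$group_cognition %in% c("low", "high"))) {
    stop_devoxel("group_cognition must be 'low' or 'high'",
                 class = "devoxel_parameter_error")
  }
  for (col in c("exclusion_cbf", "exclusion_flow")) {
    if (!col %in% names(df)) df[[col]] <- ""
    df[[col]][is.na(df[[col]])] <- ""
  }
  class(df) <- unique(c("cohort_table", class(df)))
  df
}

#' Read / write a cohort table as TSV
#'
#' @param path file path.
#' @return [read_cohort()]: a `cohort_table`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (is.character(df$group_t2dm)) {
    df$group_t2dm <- tolower(df$group_t2dm) %in% c("true", "t2dm", "1", "yes")
  }
  cohort_table(df)
}

#' @rdname read_cohort
#' @param cohort a `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Apply staged exclusions
#'
#' Subjects carrying a non-empty exclusion reason for the requested stage
#' are removed.  The flow stage applies the CBF-stage exclusions first and
#' then the flow-specific ones (a subject unusable for CBF never re-enters
#' the flow analysis).  The operation is idempotent and order-independent
#' within a stage.
#'
#' @param cohort a [cohort_table()].
#' @param stage `"cbf"` or `"flow"`.
#' @return list with `included` (cohort subset), `excluded` (subset), and
#'   `report` (a `data.frame` of per-reason, per-group counts).
#' @export
apply_exclusions <- function(cohort, stage = c("cbf", "flow")) {
  stage <- match.arg(stage)
  cols <- if (stage == "cbf") "exclusion_cbf" else c("exclusion_cbf",
                                                     "exclusion_flow")
  reasons <- lapply(cols, function(col) {
    r <- cohort[[col]]
    r[is.na(r)] <- ""
    r
  })
  excluded_flag <- Reduce(`|`, lapply(reasons, nzchar))
  all_reasons <- do.call(paste, c(reasons, sep = ";"))
  all_reasons <- gsub("^;+|;+$", "", all_reasons)
  rep_rows <- list()
  for (i in which(excluded_flag)) {
    for (r in strsplit(all_reasons[i], ";")[[1]]) {
      if (!nzchar(r)) next
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(reason = r, group_t2dm = cohort$group_t2dm[i])
    }
  }
  report <- if (length(rep_rows)) {
    rr <- do.call(rbind, rep_rows)
    as.data.frame(table(reason = rr$reason, group_t2dm = rr$group_t2dm),
                  responseName = "n")
  } else {
    data.frame(reason = character(0), group_t2dm = logical(0), n = integer(0))
  }
  list(included = cohort[!excluded_flag, , drop = FALSE],
       excluded = cohort[excluded_flag, , drop = FALSE],
       report = report, stage = stage)
}

#' Regional mean CBF
#'
#' Unweighted mean of valid GM voxels per atlas region (plus the composite
#' cerebral-cortex and whole-cerebrum regions), in ml/100 g/min.  Regions
#' without any valid voxel are reported as `NA`.
#'
#' @param cbf a `cbf_map`.
#' @param atlas a [region_atlas()] on the same grid.
#' @return named numeric vector of regional means.
#' @export
roi_mean_cbf <- function(cbf, atlas) {
  stopifnot(inherits(cbf, "cbf_map"), inherits(atlas, "region_atlas"))
  check_same_grid(cbf$values, atlas$labels, "CBF map", "atlas")
  eval_mask <- cbf$valid_mask & atlas$gm_mask
  if (!any(eval_mask)) {
    stop_devoxel("no valid GM voxels overlap the atlas",
                 class = "devoxel_region_error")
  }
  lab <- atlas$labels[eval_mask]
  val <- cbf$values[eval_mask]
  sets <- atlas_label_sets(atlas)
  vapply(sets, function(ls) {
    v <- val[lab %in% ls]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
}

new_comparison_result <- function(region, group_means, group_sds, group_ns,
                                  estimate, se, statistic, df, p_value,
                                  adjusted, method) {
  structure(
    list(region = region, group_means = group_means, group_sds = group_sds,
         group_ns = group_ns, estimate = estimate, se = se,
         statistic = statistic, df = df, p_value = p_value,
         adjusted = adjusted, method = method),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s [%s]: %s=%.3f (df=%.1f), p=%.4g; means %s%s\n",
              x$region %||% "value", x$method,
              if (x$method == "t") "t" else "beta",
              if (x$method == "t") x$statistic else x$estimate,
              x$df, x$p_value,
              paste(sprintf("%s %.2f+/-%.2f", names(x$group_means),
                            x$group_means, x$group_sds), collapse = ", "),
              if (length(x$adjusted)) paste0("; adjusted for ",
                                             paste(x$adjusted, collapse = ", "))
              else ""))
  invisible(x)
}

#' Two-sample group comparison
#'
#' Independent-samples t-test on a per-subject scalar.  The equal-variance
#' Student's form is the default (the convention of standard statistical
#' packages' "independent samples t-test"); Welch's correction is available
#' via `var_equal = FALSE`.
#'
#' @param values numeric per-subject values.
#' @param groups two-level factor/vector; the comparison is
#'   level1 - level2 in the order of `sort(unique(groups))` unless `groups`
#'   is a factor.
#' @param region optional label carried into the result.
#' @param var_equal pool variances (Student) rather than Welch.
#' @return a `comparison_result`.
#' @export
group_compare <- function(values, groups, region = NULL, var_equal = TRUE) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L) {
    stop_devoxel("exactly two groups required",
                 class = "devoxel_parameter_error")
  }
  groups <- droplevels(groups)
  split_v <- split(values, groups)
  ns <- vapply(split_v, length, integer(1))
  if (any(ns < 2L)) {
    stop_devoxel("each group needs at least 2 subjects",
                 class = "devoxel_parameter_error")
  }
  sds <- vapply(split_v, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning("a group has zero variance; t statistic may be degenerate")
  }
  tt <- stats::t.test(split_v[[1]], split_v[[2]], var.equal = var_equal)
  new_comparison_result(
    region = region,
    group_means = vapply(split_v, mean, numeric(1)),
    group_sds = sds, group_ns = ns,
    estimate = unname(diff(rev(tt$estimate))),
    se = unname(tt$stderr),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, adjusted = character(0), method = "t"
  )
}

#' Covariate-adjusted group comparison
#'
#' Least-squares linear model `value ~ group + covariates`; the reported
#' effect is the group coefficient (difference between the second and first
#' group level, matching [group_compare()]'s sign convention negated by
#' `lm`'s treatment coding — the group estimate here is level2 - level1,
#' reported as level1 - level2 for consistency).
#'
#' @inheritParams group_compare
#' @param covariates `data.frame` of per-subject covariates (e.g. age, sex,
#'   atrophy, carotid flow); an empty/`NULL` frame reduces to the unadjusted
#'   Student's t-test inference.
#' @return a `comparison_result` with the group effect estimate, SE and
#'   two-sided p.
#' @export
adjusted_compare <- function(values, groups, covariates = NULL,
                             region = NULL) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) {
    stop_devoxel("exactly two groups required",
                 class = "devoxel_parameter_error")
  }
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    covariates <- data.frame(row.names = seq_along(values))
  }
  covariates <- as.data.frame(covariates)
  if (anyNA(covariates)) {
    stop_devoxel("missing covariate values among included subjects",
                 class = "devoxel_parameter_error")
  }
  dat <- cbind(data.frame(.value = values, .group = groups), covariates)
  fit <- stats::lm(.value ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_devoxel("rank-deficient design; collinear terms: ",
                 paste(bad, collapse = ", "),
                 class = "devoxel_collinearity_error")
  }
  sm <- stats::summary.lm(fit)$coefficients
  grow <- grep("^\\.group", rownames(sm))
  split_v <- split(values, groups)
  new_comparison_result(
    region = region,
    group_means = vapply(split_v, mean, numeric(1)),
    group_sds = vapply(split_v, stats::sd, numeric(1)),
    group_ns = vapply(split_v, length, integer(1)),
    estimate = -sm[grow, "Estimate"],    # level1 - level2
    se = sm[grow, "Std. Error"],
    statistic = -sm[grow, "t value"],
    df = fit$df.residual,
    p_value = sm[grow, "Pr(>|t|)"],
    adjusted = colnames(covariates), method = "lm"
  )
}

#' Staged hypothesis testing
#'
#' Limits the number of statistical tests: the whole cerebrum is tested
#' first, and sub-region results are only reported when the whole-cerebrum
#' comparison is significant (`p < alpha`, strict).  Otherwise sub-regions
#' are marked not tested.
#'
#' @param whole_cerebrum a `comparison_result` for the whole cerebrum.
#' @param subregions named list of `comparison_result`s for the sub-regions.
#' @param alpha significance level of the gate (default 0.05).
#' @return an object of class `staged_result` with fields `whole_cerebrum`,
#'   `gate_open`, `subregions` (the results, or `NULL` when gated),
#'   `not_tested` (names), `n_posthoc_tests`, `alpha`.
#' @export
staged_testing <- function(whole_cerebrum, subregions = list(), alpha = 0.05) {
  stopifnot(inherits(whole_cerebrum, "comparison_result"))
  gate_open <- whole_cerebrum$p_value < alpha
  structure(
    list(whole_cerebrum = whole_cerebrum, gate_open = gate_open,
         subregions = if (gate_open) subregions else NULL,
         not_tested = if (gate_open) character(0) else names(subregions),
         n_posthoc_tests = if (gate_open) length(subregions) else 0L,
         alpha = alpha),
    class = "staged_result"
  )
}

#' @export
print.staged_result <- function(x, ...) {
  cat(sprintf("Staged testing (alpha=%.2f): whole-cerebrum p=%.4g -> gate %s",
              x$alpha, x$whole_cerebrum$p_value,
              if (x$gate_open) "OPEN" else "closed"), "\n")
  if (x$gate_open) {
    for (nm in names(x$subregions)) {
      cat("  "); print(x$subregions[[nm]])
    }
  } else if (length(x$not_tested)) {
    cat("  not tested:", paste(x$not_tested, collapse = ", "), "\n")
  }
  invisible(x)
}
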
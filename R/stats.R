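#' Descriptive summary of a cohort
#'
#' Mean and sample standard deviation (n - 1 denominator) of the total
#' score, and count/percent tables (percentages to one decimal) for each
#' categorical variable present.
#'
#' @param cohort a `cohort_table`.
#' @return A list with `n`, `score_mean`, `score_sd`, and `tables`, a named
#'   list of data frames (`level`, `n`, `percent`).
#' @export
descriptive_summary <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  vars <- c("volume_grade", "arterial_score", "cs_involved", "bone_invaded",
            "total_score", "simpson_grade", "outcome_grade")
  tabs <- list()
  for (v in intersect(vars, names(cohort))) {
    x <- cohort[[v]]
    if (all(is.na(x))) next
    tabs[[v]] <- count_percent(table(x))
  }
  list(n = nrow(cohort),
       score_mean = mean(cohort$total_score),
       score_sd = stats::sd(cohort$total_score),
       tables = tabs)
}

#' Counts with percentages to one decimal
#'
#' @param counts named vector (or table) of counts.
#' @return Data frame with `level`, `n`, `percent` (percent rounded to one
#'   decimal, as published tables report them).
#' @export
count_percent <- function(counts) {
  n_vec <- as.integer(counts)
  lv <- names(counts)
  if (is.null(lv)) lv <- as.character(seq_along(n_vec))
  data.frame(level = lv, n = n_vec,
             percent = round(100 * n_vec / sum(n_vec), 1),
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation with mid-rank ties
#'
#' Pearson correlation of mid-ranks; the two-sided p-value uses the
#' standard large-sample t approximation
#' `t = rs * sqrt((n - 2) / (1 - rs^2))` on `n - 2` degrees of freedom
#' (p = 0 when |rs| = 1).
#'
#' @param x,y equal-length numeric/ordinal vectors, length >= 3, neither
#'   constant.
#' @return List with `rs` and `p`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (length(unique(x)) < 2) stop("x is constant; correlation undefined")
  if (length(unique(y)) < 2) stop("y is constant; correlation undefined")
  rs <- stats::cor(rank(x), rank(y))
  if (abs(rs) >= 1 - 1e-12) {
    p <- 0
  } else {
    tt <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rs = rs, p = p)
}

.require_grades <- function(cohort) {
  if (!"simpson_grade" %in% names(cohort) || all(is.na(cohort$simpson_grade)))
    stop("cohort has no simpson_grade column")
  cohort[!is.na(cohort$simpson_grade), , drop = FALSE]
}

#' Univariate tests against resection grade
#'
#' Kruskal-Wallis (tie-corrected) across the resection-grade groups for
#' ordinal variables, Pearson chi-square without continuity correction for
#' nominal variables. Empty grade groups are dropped with a warning. A
#' variable constant across all patients carries no evidence of a group
#' difference; the tie-corrected statistic is undefined (0/0) there, so it
#' is reported as statistic 0 with p = 1.
#'
#' @param cohort a `cohort_table` with `simpson_grade`.
#' @param ordinal,nominal character vectors of variable names.
#' @return Data frame with `variable`, `test`, `statistic`, `p`.
#' @export
univariate_tests <- function(cohort,
                             ordinal = c("volume_grade", "arterial_score", "total_score"),
                             nominal = c("cs_involved", "bone_invaded")) {
  cohort <- .require_grades(cohort)
  g <- factor(cohort$simpson_grade, levels = sort(unique(cohort$simpson_grade)))
  if (nlevels(g) < length(unique(1:4)))
    if (nlevels(g) < 2) warning("fewer than 2 resection-grade groups present")
  out <- NULL
  for (v in ordinal) {
    if (length(unique(cohort[[v]])) < 2) {
      out <- rbind(out, data.frame(variable = v, test = "kruskal-wallis",
                                   statistic = 0, p = 1,
                                   stringsAsFactors = FALSE))
      next
    }
    kw <- stats::kruskal.test(cohort[[v]], g)
    out <- rbind(out, data.frame(variable = v, test = "kruskal-wallis",
                                 statistic = unname(kw$statistic),
                                 p = kw$p.value, stringsAsFactors = FALSE))
  }
  for (v in nominal) {
    ct <- suppressWarnings(stats::chisq.test(table(cohort[[v]], g), correct = FALSE))
    out <- rbind(out, data.frame(variable = v, test = "chi-square",
                                 statistic = unname(ct$statistic),
                                 p = ct$p.value, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Adjusted odds ratios for resection grade
#'
#' Fits an ordinal regression of Simpson grade on the predictors and
#' reports one adjusted odds ratio per predictor with a Wald 95% CI. The
#' default family is proportional-odds (cumulative logit, one common
#' coefficient per predictor — the form consistent with reporting a single
#' OR per variable for a 4-level outcome); `family = "binary"` instead
#' dichotomizes the grade (I-II vs III-IV) and fits ordinary logistic
#' regression, for sensitivity analysis. Non-convergence or separation
#' (absurdly large standard errors) is flagged per variable, not silent.
#'
#' @param cohort a `cohort_table` with `simpson_grade` (>= 2 levels).
#' @param predictors character vector of predictor column names.
#' @param family `"proportional_odds"` or `"binary"`.
#' @return Data frame with `variable`, `or`, `ci_lower`, `ci_upper`, `flag`.
#' @export
adjusted_odds_ratios <- function(cohort,
                                 predictors = c("volume_grade", "arterial_score",
                                                "cs_involved", "bone_invaded"),
                                 family = c("proportional_odds", "binary")) {
  family <- match.arg(family)
  cohort <- .require_grades(cohort)
  if (length(unique(cohort$simpson_grade)) < 2)
    stop("simpson_grade has a single level; odds ratios undefined")
  X <- cohort[predictors]
  X[] <- lapply(X, function(col) as.numeric(col))
  if (family == "proportional_odds") {
    dat <- cbind(grade = factor(cohort$simpson_grade, ordered = TRUE), X)
    fit <- MASS::polr(grade ~ ., data = dat, Hess = TRUE)
    beta <- fit$coefficients
    se <- sqrt(diag(stats::vcov(fit)))[names(beta)]
    conv_flag <- if (!is.null(fit$convergence) && fit$convergence != 0)
      "non-convergence" else ""
  } else {
    dat <- cbind(y = as.integer(cohort$simpson_grade >= 3), X)
    fit <- stats::glm(y ~ ., data = dat, family = stats::binomial())
    beta <- stats::coef(fit)[-1]
    se <- sqrt(diag(stats::vcov(fit)))[names(beta)]
    conv_flag <- if (!fit$converged) "non-convergence" else ""
  }
  flag <- ifelse(se > 10, "possible separation", conv_flag)
  data.frame(variable = names(beta),
             or = exp(unname(beta)),
             ci_lower = exp(unname(beta - 1.96 * se)),
             ci_upper = exp(unname(beta + 1.96 * se)),
             flag = flag, row.names = NULL, stringsAsFactors = FALSE)
}

#' Discriminant classification accuracy of the score
#'
#' Linear discriminant analysis of resection grade on the given predictors
#' with empirical class priors; accuracy is resubstitution (evaluated on
#' the records used for fitting) in percent to two decimals, matching how
#' a single headline accuracy with no cross-validation is conventionally
#' reported. `mode = "loo"` gives leave-one-out accuracy instead.
#'
#' @param cohort a `cohort_table` with `simpson_grade`.
#' @param predictors character vector of predictor column names.
#' @param mode `"resubstitution"` or `"loo"`.
#' @return Accuracy in percent, rounded to two decimals.
#' @export
discriminant_accuracy <- function(cohort, predictors = "total_score",
                                  mode = c("resubstitution", "loo")) {
  mode <- match.arg(mode)
  cohort <- .require_grades(cohort)
  grp <- factor(cohort$simpson_grade)
  if (nrow(cohort) <= nlevels(grp))
    stop("fewer records than classes + 1; within-class covariance undefined")
  X <- as.data.frame(lapply(cohort[predictors], as.numeric))
  if (mode == "loo") {
    fit <- MASS::lda(X, grouping = grp, CV = TRUE)
    pred <- fit$class
  } else {
    fit <- MASS::lda(X, grouping = grp)
    pred <- stats::predict(fit, X)$class
  }
  round(100 * mean(pred == grp), 2)
}

#' Score-outcome correlation
#'
#' Spearman correlation between the total score and the 4-category
#' postoperative outcome (0 worse ... 3 complete regression); a negative
#' `rs` means higher scores go with worse outcomes.
#'
#' @param cohort a `cohort_table` with `outcome_grade`.
#' @return List with `rs` and `p` (see [spearman_rho()]).
#' @export
score_outcome_correlation <- function(cohort) {
  if (!"outcome_grade" %in% names(cohort) || all(is.na(cohort$outcome_grade)))
    stop("cohort has no outcome_grade column")
  keep <- !is.na(cohort$outcome_grade)
  spearman_rho(cohort$total_score[keep], cohort$outcome_grade[keep])
}

#' Full validation battery over a cohort
#'
#' Composes the descriptive summary, univariate tests, adjusted odds
#' ratios, Spearman correlations of each variable and of the total score
#' against resection grade, the score-outcome correlation (when outcomes
#' are present), and the discriminant accuracy.
#'
#' @param cohort a `cohort_table` with `simpson_grade`.
#' @param config a [pipeline_config()] (regression family, discriminant
#'   mode).
#' @return A list of class `stats_report`.
#' @export
cohort_stats <- function(cohort, config = pipeline_config()) {
  cohort_g <- .require_grades(cohort)
  vars <- c("volume_grade", "arterial_score", "cs_involved", "bone_invaded")
  sp <- lapply(c(vars, "total_score"), function(v)
    spearman_rho(as.numeric(cohort_g[[v]]), cohort_g$simpson_grade))
  names(sp) <- c(vars, "total_score")
  spearman_tab <- data.frame(
    variable = names(sp),
    rs = vapply(sp, `[[`, 0, "rs"),
    p = vapply(sp, `[[`, 0, "p"), row.names = NULL, stringsAsFactors = FALSE)
  outcome <- if ("outcome_grade" %in% names(cohort) &&
                 !all(is.na(cohort$outcome_grade)))
    score_outcome_correlation(cohort) else NULL
  structure(list(
    descriptives = descriptive_summary(cohort),
    univariate = univariate_tests(cohort),
    odds_ratios = adjusted_odds_ratios(cohort, family = config$regression_family),
    spearman = spearman_tab,
    score_outcome = outcome,
    discriminant_accuracy = discriminant_accuracy(
      cohort, mode = config$discriminant_mode)
  ), class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  d <- x$descriptives
  cat(sprintf("<stats_report> n = %d, score %.1f +/- %.1f\n",
              d$n, d$score_mean, d$score_sd))
  cat("univariate:\n"); print(x$univariate)
  cat("adjusted odds ratios:\n"); print(x$odds_ratios)
  cat("spearman vs resection grade:\n"); print(x$spearman)
  if (!is.null(x$score_outcome))
    cat(sprintf("score vs outcome: rs = %.3f (p = %.3g)\n",
                x$score_outcome$rs, x$score_outcome$p))
  cat(sprintf("discriminant accuracy: %.2f%%\n", x$discriminant_accuracy))
  invisible(x)
}
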
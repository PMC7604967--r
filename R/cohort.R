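#' Build a validated cohort table
#'
#' One row per patient with the four graded components, the total score
#' (recomputed and cross-checked), and optional ordinal Simpson resection
#' grade (1-4 for I-IV) and 4-category postoperative outcome (0 worse,
#' 1 unchanged, 2 improved, 3 complete regression).
#'
#' @param df data frame with columns `volume_grade`, `arterial_score`,
#'   `cs_involved`, `bone_invaded`, and optionally `total_score`,
#'   `simpson_grade`, `outcome_grade`.
#' @param provenance one of `"printed"`, `"simulated"`, `"user"`.
#' @return A data frame of class `cohort_table` (attribute `provenance`).
#' @export
cohort_table <- function(df, provenance = c("user", "printed", "simulated")) {
  provenance <- match.arg(provenance)
  req <- c("volume_grade", "arterial_score", "cs_involved", "bone_invaded")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing cohort columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("cohort table must be non-empty")
  if (!all(df$volume_grade %in% 1:3)) stop("volume_grade out of range 1-3")
  if (!all(df$arterial_score %in% 0:4)) stop("arterial_score out of range 0-4")
  df$cs_involved <- as.logical(df$cs_involved)
  df$bone_invaded <- as.logical(df$bone_invaded)
  expected <- df$volume_grade + df$arterial_score +
    2L * as.integer(df$cs_involved) + as.integer(df$bone_invaded)
  if ("total_score" %in% names(df)) {
    bad <- which(df$total_score != expected)
    if (length(bad))
      stop("total_score inconsistent with components at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  df$total_score <- as.integer(expected)
  if ("simpson_grade" %in% names(df)) {
    ok <- is.na(df$simpson_grade) | df$simpson_grade %in% 1:4
    if (!all(ok)) stop("simpson_grade must be 1-4 (I-IV) or NA")
  }
  if ("outcome_grade" %in% names(df)) {
    ok <- is.na(df$outcome_grade) | df$outcome_grade %in% 0:3
    if (!all(ok)) stop("outcome_grade must be 0-3 or NA")
  }
  structure(as.data.frame(df), provenance = provenance,
            class = c("cohort_table", "data.frame"))
}

# One feasible completion of the published 46-patient marginals: each row's
# components sum to its total, and every column marginal (score counts,
# volume grades 23/14/9, arterial 7/6/8/11/14, CS 23, bone 10) is exact.
# The true joint table is not published; this is a deterministic
# reconstruction for analyses that depend only on the printed marginals.
.PRINTED_COMPLETION <- matrix(c(
  # volume, arterial, cs, bone, count
  1, 0, 0, 0, 5,
  1, 1, 0, 0, 6,
  1, 0, 1, 0, 2,
  1, 2, 0, 0, 1,
  1, 3, 0, 0, 6,
  1, 2, 1, 0, 3,
  2, 2, 1, 0, 2,
  2, 3, 0, 1, 1,
  2, 3, 1, 0, 3,
  3, 4, 0, 0, 4,
  2, 4, 1, 0, 4,
  3, 2, 1, 1, 2,
  2, 4, 1, 1, 4,
  3, 3, 1, 1, 1,
  3, 4, 1, 1, 2), ncol = 5, byrow = TRUE)

#' Reconstruct the published 46-patient cohort from its printed marginals
#'
#' Deterministically expands a feasible joint completion of the published
#' per-score and per-component counts (score 1-10 counts
#' 5/6/3/6/3/3/7/6/5/2; volume grades 23/14/9; arterial scores 7/6/8/11/14;
#' CS involvement 23; bone invasion 10) into 46 patient rows whose
#' components always sum to their total. The patient-level joint with
#' Simpson grade and outcome is not published, so those columns are `NA`.
#'
#' @return A `cohort_table` with provenance `"printed"`.
#' @export
reconstruct_printed_cohort <- function() {
  m <- .PRINTED_COMPLETION
  rows <- m[rep(seq_len(nrow(m)), m[, 5]), 1:4, drop = FALSE]
  df <- data.frame(volume_grade = as.integer(rows[, 1]),
                   arterial_score = as.integer(rows[, 2]),
                   cs_involved = rows[, 3] == 1,
                   bone_invaded = rows[, 4] == 1,
                   simpson_grade = NA_integer_,
                   outcome_grade = NA_integer_)
  tot <- df$volume_grade + df$arterial_score + 2L * df$cs_involved +
    df$bone_invaded
  df <- df[order(tot, df$volume_grade, df$arterial_score), , drop = FALSE]
  rownames(df) <- NULL
  cohort_table(df, provenance = "printed")
}

#' Published resection-grade distribution
#'
#' Counts of Simpson grade I-IV among the 46 published patients (no grade V
#' occurred). Kept as a named input for descriptive bookkeeping; the
#' per-patient pairing with scores is not published.
#'
#' @return Named integer vector over grades I-IV.
#' @export
printed_simpson_counts <- function() c(I = 10L, II = 17L, III = 15L, IV = 4L)

#' Ordinal simulation model for score-outcome cohorts
#'
#' A proportional-odds testing device for the statistics battery: total
#' scores are drawn from a categorical distribution over 1-10 and the
#' ordinal Simpson grade (I-IV) and postoperative outcome (0-3) are drawn
#' from cumulative-logit models on the score,
#' `P(G <= k | s) = plogis(threshold_k - beta_score * s)` and
#' `P(O <= k | s) = plogis(outcome_threshold_k - outcome_beta * s)`, so a
#' negative `outcome_beta` pushes high-score patients toward the worse end
#' (grade 0) of the outcome scale. Defaults: score distribution equal to
#' the published 46-patient counts; `beta_score = 1` with thresholds
#' `(4.0, 5.7, 7.7)` and `outcome_beta = -0.5` with thresholds
#' `(-4.37, -1.61, 0.45)`, calibrated once so that at the published mean
#' score the implied marginal grade and outcome distributions are close to
#' the published ones.
#'
#' @param n_patients number of patients to simulate.
#' @param score_distribution counts (or weights) per score 1-10.
#' @param beta_score effect of score on the resection-grade liability.
#' @param thresholds 3 strictly increasing cutpoints separating grades I-IV.
#' @param outcome_beta effect of score on the 0-3 outcome liability
#'   (expected negative).
#' @param outcome_thresholds 3 strictly increasing cutpoints for the outcome.
#' @param ordinal_link only `"proportional_odds"` is supported.
#' @param seed integer seed; all randomness flows from it.
#' @return A list of class `cohort_model`.
#' @export
cohort_model <- function(n_patients = 46,
                         score_distribution = c(5, 6, 3, 6, 3, 3, 7, 6, 5, 2),
                         beta_score = 1.0, thresholds = c(4.0, 5.7, 7.7),
                         outcome_beta = -0.5,
                         outcome_thresholds = c(-4.37, -1.61, 0.45),
                         ordinal_link = "proportional_odds", seed = 1L) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (length(score_distribution) != 10 || any(score_distribution < 0) ||
      sum(score_distribution) <= 0)
    stop("score_distribution must be 10 non-negative counts per score 1-10")
  if (length(thresholds) != 3 || any(diff(thresholds) <= 0))
    stop("thresholds must be 3 strictly increasing cutpoints")
  if (length(outcome_thresholds) != 3 || any(diff(outcome_thresholds) <= 0))
    stop("outcome_thresholds must be 3 strictly increasing cutpoints")
  if (!identical(ordinal_link, "proportional_odds"))
    stop("only the proportional_odds link is supported")
  structure(list(n_patients = as.integer(n_patients),
                 score_distribution = as.numeric(score_distribution),
                 beta_score = beta_score, thresholds = thresholds,
                 outcome_beta = outcome_beta,
                 outcome_thresholds = outcome_thresholds,
                 ordinal_link = ordinal_link, seed = as.integer(seed)),
            class = "cohort_model")
}

.draw_ordinal <- function(u, eta, thresholds) {
  # cumulative-logit draw: category = 1 + #{k : u > P(Y <= k)}
  p <- vapply(thresholds, function(t) stats::plogis(t - eta), numeric(length(eta)))
  1L + rowSums(u > p)
}

#' Simulate a cohort from the proportional-odds model
#'
#' Draws scores from the model's score distribution, expands each score
#' into a uniformly chosen consistent component combination (so component
#' columns are always available), and draws Simpson grade and outcome from
#' the cumulative-logit models. Bit-reproducible given the model's seed.
#'
#' @param model a [cohort_model()].
#' @return A `cohort_table` with provenance `"simulated"`.
#' @export
simulate_cohort <- function(model) {
  stopifnot(inherits(model, "cohort_model"))
  if (sum(model$score_distribution > 0) == 1)
    warning("degenerate score distribution: a single score value; ",
            "correlations downstream are undefined")
  set.seed(model$seed)
  n <- model$n_patients
  scores <- sample(1:10, n, replace = TRUE,
                   prob = model$score_distribution / sum(model$score_distribution))
  space <- enumerate_score_space()
  pick <- integer(n)
  for (s in sort(unique(scores))) {
    rows <- which(space$total == s)
    sel <- which(scores == s)
    pick[sel] <- rows[sample.int(length(rows), length(sel), replace = TRUE)]
  }
  df <- space[pick, c("volume_grade", "arterial_score", "cs_involved",
                      "bone_invaded")]
  df$simpson_grade <- .draw_ordinal(stats::runif(n), model$beta_score * scores,
                                    model$thresholds)
  df$outcome_grade <- .draw_ordinal(stats::runif(n), model$outcome_beta * scores,
                                    model$outcome_thresholds) - 1L
  rownames(df) <- NULL
  cohort_table(df, provenance = "simulated")
}
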
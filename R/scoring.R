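#' Resection band labels in increasing order of surgical difficulty
#' @return Character vector `SimpsonI < SimpsonII < SimpsonIII_or_IV`.
#' @export
resection_bands <- function() c("SimpsonI", "SimpsonII", "SimpsonIII_or_IV")

#' Predicted resection band from a total score
#'
#' A total below the lower cutoff predicts a Simpson I resection, a total
#' within the closed interval `[lower, upper]` a Simpson II resection, and
#' a total above the upper cutoff a Simpson III or IV resection (the last
#' two are not separated by the predictor).
#'
#' @param total integer total score in 1-10.
#' @param cutoffs length-2 numeric `(lower, upper)`, default `c(4, 7)`.
#' @return One of [resection_bands()].
#' @export
predict_resection_band <- function(total, cutoffs = c(4, 7)) {
  if (length(total) != 1 || !is.finite(total) || total != round(total) ||
      total < 1 || total > 10)
    stop("total must be a single integer in 1..10")
  if (length(cutoffs) != 2 || cutoffs[1] > cutoffs[2])
    stop("cutoffs must be two non-decreasing numbers")
  if (total < cutoffs[1]) "SimpsonI"
  else if (total <= cutoffs[2]) "SimpsonII"
  else "SimpsonIII_or_IV"
}

#' Total preoperative score from graded features
#'
#' Point weights: volume grade contributes its grade (1-3), arterial
#' involvement its 0-4 score, cavernous sinus involvement 2 points, bone
#' invasion 1 point. The total therefore spans 1-10 (volume always
#' contributes at least 1).
#'
#' @param features a `radiologic_features` object.
#' @param cutoffs band cutoffs passed to [predict_resection_band()].
#' @return Object of class `score_result` with the component points, the
#'   total and the predicted band.
#' @export
total_score <- function(features, cutoffs = c(4, 7)) {
  stopifnot(inherits(features, "radiologic_features"))
  volume_points <- as.integer(features$volume_grade)
  arterial_points <- as.integer(features$arterial_score)
  cs_points <- 2L * as.integer(isTRUE(features$cs_involved))
  bone_points <- as.integer(isTRUE(features$bone_invaded))
  total <- volume_points + arterial_points + cs_points + bone_points
  structure(list(volume_points = volume_points,
                 arterial_points = arterial_points,
                 cs_points = cs_points, bone_points = bone_points,
                 total = total,
                 predicted_band = predict_resection_band(total, cutoffs)),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result> total %d (volume %d + arterial %d + CS %d + bone %d) -> %s\n",
              x$total, x$volume_points, x$arterial_points, x$cs_points,
              x$bone_points, x$predicted_band))
  invisible(x)
}

#' Enumerate the full component space of the scoring table
#'
#' All 3 x 5 x 2 x 2 = 60 combinations of volume grade, arterial score, CS
#' involvement and bone invasion, with their totals and predicted bands.
#' Useful for certifying the attainable score range.
#'
#' @param cutoffs band cutoffs passed to [predict_resection_band()].
#' @return A 60-row data frame.
#' @export
enumerate_score_space <- function(cutoffs = c(4, 7)) {
  grid <- expand.grid(volume_grade = 1:3, arterial_score = 0:4,
                      cs_involved = c(FALSE, TRUE),
                      bone_invaded = c(FALSE, TRUE),
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- total_score(radiologic_features(grid$volume_grade[i],
                                          grid$arterial_score[i],
                                          grid$cs_involved[i],
                                          grid$bone_invaded[i]),
                      cutoffs = cutoffs)
    data.frame(total = sc$total, predicted_band = sc$predicted_band,
               stringsAsFactors = FALSE)
  })
  cbind(grid, do.call(rbind, res))
}
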
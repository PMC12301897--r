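#' Mean absolute error
#'
#' @param targets,predictions equal-length numeric vectors.
#' @return `mean(|predictions - targets|)`, years for age decoding.
#' @export
mae <- function(targets, predictions) {
  stopifnot(length(targets) == length(predictions), length(targets) > 0)
  mean(abs(predictions - targets))
}

#' Absolute percentage error
#'
#' @param target nonzero target value.
#' @param prediction predicted value.
#' @return `|prediction - target| / |target| * 100`.
#' @export
ape <- function(target, prediction) {
  stopifnot(all(target != 0))
  abs(prediction - target) / abs(target) * 100
}

#' Coefficient of determination
#'
#' The default is the standard form `1 - SS_res / SS_tot`. The
#' explained-variance ratio `SS_reg / SS_tot` (sum of squared deviations of
#' the *predictions* about the target mean over total) is exposed as
#' `variant = "explained"`; the two coincide for least-squares-calibrated
#' predictors but differ in general.
#'
#' @param targets,predictions equal-length numeric vectors, >= 2 targets
#'   with nonzero variance.
#' @param variant `"standard"` or `"explained"`.
#' @return dimensionless score (1 = perfect for the standard form).
#' @export
r2 <- function(targets, predictions, variant = c("standard", "explained")) {
  variant <- match.arg(variant)
  stopifnot(length(targets) == length(predictions), length(targets) >= 2)
  ss_tot <- sum((targets - mean(targets))^2)
  if (ss_tot == 0) stop("targets have zero variance", call. = FALSE)
  if (variant == "standard") {
    1 - sum((targets - predictions)^2) / ss_tot
  } else {
    sum((predictions - mean(targets))^2) / ss_tot
  }
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity; the positive class is pathological.
#'
#' @param tp,tn,fp,fn confusion counts, or `tp` may be a list/vector with
#'   named elements `tp`, `tn`, `fp`, `fn`.
#' @return `(TP/(TP+FN) + TN/(TN+FP)) / 2`.
#' @export
bacc <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.null(tn) && (is.list(tp) || !is.null(names(tp)))) {
    cc <- tp; tp <- cc[["tp"]]; tn <- cc[["tn"]]
    fp <- cc[["fp"]]; fn <- cc[["fn"]]
  }
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  if (tp + fn == 0 || tn + fp == 0)
    stop("balanced accuracy undefined: a class has no examples",
         call. = FALSE)
  0.5 * (tp / (tp + fn) + tn / (tn + fp))
}

#' Confusion counts from labels
#'
#' @param truth,predicted logical vectors (`TRUE` = pathological).
#' @return list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  list(tp = sum(truth & predicted), tn = sum(!truth & !predicted),
       fp = sum(!truth & predicted), fn = sum(truth & !predicted))
}

#' Balanced accuracy of label vectors
#'
#' @inheritParams confusion_counts
#' @return balanced accuracy.
#' @export
bacc_labels <- function(truth, predicted) {
  bacc(confusion_counts(truth, predicted))
}

#' Fit the quadratic prediction-bias model
#'
#' Least-squares quadratic of the raw brain-age gap on chronological age,
#' `gap ~ a CA^2 + b CA + c`. Fit on cross-validation predictions of
#' non-pathological recordings only, then frozen for all later use.
#'
#' @param ca chronological ages, years (>= 3 distinct values).
#' @param gap_raw raw gaps `BA - CA`, years.
#' @return object of class `bias_model` with coefficients `a`, `b`, `c` and
#'   the fit domain `age_range`.
#' @export
fit_bias <- function(ca, gap_raw) {
  stopifnot(length(ca) == length(gap_raw))
  if (length(unique(ca)) < 3)
    stop("rank error: need >= 3 distinct chronological ages", call. = FALSE)
  fit <- stats::lm(gap_raw ~ ca + I(ca^2))
  co <- stats::coef(fit)
  structure(list(a = unname(co[3]), b = unname(co[2]), c = unname(co[1]),
                 age_range = range(ca), n = length(ca)),
            class = "bias_model")
}

#' Expected gap under a bias model
#'
#' @param model a [fit_bias()] result.
#' @param ca chronological ages, years.
#' @return expected raw gap at each age.
#' @export
predict_bias <- function(model, ca) {
  model$a * ca^2 + model$b * ca + model$c
}

#' Remove the age-dependent prediction bias
#'
#' `gap_corrected = gap_raw - (a CA^2 + b CA + c)`. On its own fit set the
#' corrected gaps have mean ~0 and a refitted quadratic with coefficients ~0
#' (the correction is a projection).
#'
#' @param model a [fit_bias()] result.
#' @param records data.frame with columns `ca` and `gap_raw` (extra columns
#'   pass through).
#' @return `records` with a `gap_corrected` column added/replaced.
#' @export
apply_bias <- function(model, records) {
  stopifnot(all(c("ca", "gap_raw") %in% names(records)))
  records$gap_corrected <- records$gap_raw - predict_bias(model, records$ca)
  records
}

#' Build gap records from predictions
#'
#' @param predictions data.frame with `recording_id`, `subject_id`,
#'   `ca` (chronological age) and `ba` (decoded brain age); extra columns
#'   (e.g. `pathology`, `date_days`) pass through.
#' @return the same data.frame with `gap_raw = ba - ca` added.
#' @export
gap_records <- function(predictions) {
  stopifnot(all(c("ca", "ba") %in% names(predictions)))
  predictions$gap_raw <- predictions$ba - predictions$ca
  predictions
}

#' Per-subject average corrected gap
#'
#' Unweighted mean of `gap_corrected` over each subject's recordings within
#' one pathology status, mirroring subject-level comparisons of repeated
#' cohorts.
#'
#' @param records data.frame with `subject_id`, `gap_corrected` and
#'   optionally `pathology` (assumed all one status when absent).
#' @return data.frame: subject_id, pathology, mean_gap, n_recordings.
#' @export
subject_average_gap <- function(records) {
  stopifnot(nrow(records) > 0, "gap_corrected" %in% names(records))
  if (!"pathology" %in% names(records)) records$pathology <- FALSE
  key <- interaction(records$subject_id, records$pathology, drop = TRUE)
  agg <- lapply(split(records, key), function(d) data.frame(
    subject_id = d$subject_id[1], pathology = d$pathology[1],
    mean_gap = mean(d$gap_corrected), n_recordings = nrow(d),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$subject_id, out$pathology), ]
}
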
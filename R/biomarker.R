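#' Optimize the two-threshold gap biomarker
#'
#' Gaps inside the closed interval `[lo, hi]` are classified non-pathological,
#' gaps outside pathological. The pair maximizing balanced accuracy is found
#' by exhaustive search over midpoints of consecutive sorted unique gaps plus
#' the open ends (+-Inf). Ties are broken toward the widest non-pathological
#' interval, then the smallest `lo` — a deterministic, rank-based rule.
#'
#' @param gaps numeric vector of (corrected) brain-age gaps, years.
#' @param labels logical pathology labels (`TRUE` = pathological); both
#'   classes must be present.
#' @return list of class `threshold_pair`: `lo`, `hi`, `bacc`.
#' @export
optimize_thresholds <- function(gaps, labels) {
  stopifnot(length(gaps) == length(labels))
  if (!any(labels) || all(labels))
    stop("class error: both classes must be present", call. = FALSE)
  cand <- threshold_candidates(gaps)
  m <- length(cand)
  # prefix counts of each class at gap <= cand (candidates never equal gaps)
  np_cum <- vapply(cand, function(t) sum(gaps[!labels] <= t), 0)
  p_cum <- vapply(cand, function(t) sum(gaps[labels] <= t), 0)
  n_np <- sum(!labels); n_p <- sum(labels)
  # pair (i <= j): NP interval (cand[i], cand[j])
  np_in <- outer(np_cum, np_cum, function(a, b) b - a)  # [i,j]
  p_in <- outer(p_cum, p_cum, function(a, b) b - a)
  b <- 0.5 * ((n_p - p_in) / n_p + np_in / n_np)
  b[lower.tri(b)] <- -Inf
  best <- max(b)
  hits <- which(b >= best - 1e-12, arr.ind = TRUE)
  lo <- cand[hits[, 1]]; hi <- cand[hits[, 2]]
  width <- hi - lo
  width[is.nan(width)] <- Inf           # Inf - (-Inf)
  ord <- order(-width, lo)
  structure(list(lo = lo[ord[1]], hi = hi[ord[1]], bacc = best),
            class = "threshold_pair")
}

threshold_candidates <- function(x) {
  u <- sort(unique(x))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric()
  c(-Inf, mids, Inf)
}

#' Classify gaps with a threshold pair
#'
#' Boundary values (`gap == lo` or `gap == hi`) are non-pathological: the
#' non-pathological interval is closed.
#'
#' @param pair a [optimize_thresholds()] result (or list with `lo`, `hi`).
#' @param gaps numeric vector.
#' @return logical vector, `TRUE` = pathological.
#' @export
classify_gaps <- function(pair, gaps) {
  stopifnot(pair$lo <= pair$hi)
  gaps < pair$lo | gaps > pair$hi
}

#' Age-threshold pathology proxy
#'
#' Single chronological-age cut maximizing balanced accuracy, with
#' older-than-threshold classified pathological; the simple baseline the gap
#' biomarker is compared against. Candidates and tie-breaks as in
#' [optimize_thresholds()] restricted to one bound (ties: smallest cut).
#'
#' @param ages chronological ages, years.
#' @param labels logical pathology labels; both classes present.
#' @return list of class `age_threshold`: `cut`, `bacc`.
#' @export
age_threshold_proxy <- function(ages, labels) {
  stopifnot(length(ages) == length(labels))
  if (!any(labels) || all(labels))
    stop("class error: both classes must be present", call. = FALSE)
  cand <- threshold_candidates(ages)
  n_np <- sum(!labels); n_p <- sum(labels)
  b <- vapply(cand, function(t) {
    pred <- ages > t
    0.5 * (sum(labels & pred) / n_p + sum(!labels & !pred) / n_np)
  }, 0)
  best <- max(b)
  cut <- cand[which(b >= best - 1e-12)][1]
  structure(list(cut = cut, bacc = best), class = "age_threshold")
}

#' Classify by the age threshold
#'
#' @param thr an [age_threshold_proxy()] result.
#' @param ages chronological ages.
#' @return logical vector, `TRUE` = pathological (age above the cut).
#' @export
classify_ages <- function(thr, ages) {
  ages > thr$cut
}

# average same-day recordings within a (subject, status) trajectory,
# returning one row per distinct day sorted by date
average_same_day <- function(d) {
  agg <- lapply(split(d, d$date_days), function(g) data.frame(
    date_days = g$date_days[1], gap_corrected = mean(g$gap_corrected),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  out[order(out$date_days), , drop = FALSE]
}

DAYS_PER_YEAR <- 365.25

#' Within-status brain-age-gap change rates
#'
#' Groups records by subject and pathology status, averages same-day
#' recordings, computes the gap difference of subsequent recordings divided
#' by the elapsed time (the slope, gap-years per year), and averages the
#' pair slopes per subject.
#'
#' @param records data.frame with `subject_id`, `date_days`,
#'   `gap_corrected` and optionally `pathology`.
#' @return data.frame: subject_id, pathology, rate, n_pairs. Subjects (or
#'   status groups) with fewer than two distinct dates are skipped; skipped
#'   groups are listed in the `skipped` attribute.
#' @export
change_rates <- function(records) {
  stopifnot(all(c("subject_id", "date_days", "gap_corrected") %in%
                  names(records)))
  if (!"pathology" %in% names(records)) records$pathology <- FALSE
  key <- interaction(records$subject_id, records$pathology, drop = TRUE)
  rows <- list(); skipped <- list()
  for (d in split(records, key)) {
    traj <- average_same_day(d)
    if (nrow(traj) < 2) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        subject_id = d$subject_id[1], pathology = d$pathology[1],
        reason = "fewer than 2 distinct dates", stringsAsFactors = FALSE)
      next
    }
    slopes <- diff(traj$gap_corrected) /
      (diff(traj$date_days) / DAYS_PER_YEAR)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = d$subject_id[1], pathology = d$pathology[1],
      rate = mean(slopes), n_pairs = length(slopes),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), pathology = logical(),
               rate = numeric(), n_pairs = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$pathology), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}

#' Moment-of-transition change rate
#'
#' For a subject whose pathology label flips exactly once, the gap slope is
#' computed across the unique consecutive recording pair spanning the flip,
#' after same-day averaging within each side.
#'
#' @param records one subject's records: `subject_id`, `date_days`,
#'   `gap_corrected`, `pathology`, sorted or unsorted.
#' @return data.frame row: subject_id, direction (`"NP->P"` or `"P->NP"`),
#'   rate, dt_years.
#' @export
transition_rate <- function(records) {
  stopifnot(all(c("subject_id", "date_days", "gap_corrected", "pathology")
                %in% names(records)))
  ord <- order(records$date_days, records$pathology)
  d <- records[ord, ]
  runs <- rle(d$pathology)
  if (length(runs$values) != 2)
    stop("pattern error: expected exactly one pathology-label flip, found ",
         length(runs$values) - 1, call. = FALSE)
  pre <- average_same_day(d[seq_len(runs$lengths[1]), ])
  post <- average_same_day(d[-seq_len(runs$lengths[1]), ])
  dt <- (post$date_days[1] - pre$date_days[nrow(pre)]) / DAYS_PER_YEAR
  if (dt <= 0)
    stop("pattern error: flip pair shares a date (elapsed time 0)",
         call. = FALSE)
  data.frame(subject_id = d$subject_id[1],
             direction = if (runs$values[2]) "NP->P" else "P->NP",
             rate = (post$gap_corrected[1] - pre$gap_corrected[nrow(pre)]) / dt,
             dt_years = dt, stringsAsFactors = FALSE)
}

#' Transition rates for all once-flipping subjects
#'
#' @param records gap records of TNPP/TPNP subjects (several subjects).
#' @return data.frame of [transition_rate()] rows.
#' @export
transition_rates <- function(records) {
  rows <- lapply(split(records, records$subject_id), transition_rate)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
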
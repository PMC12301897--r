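#' Derivative inclusion rules
#'
#' @param min_duration_s minimum recording duration, seconds (default 900,
#'   i.e. 15 minutes; the recording-selection stage uses 120 s — both are
#'   plain values of this one knob).
#' @param min_recordings_per_subject minimum retained recordings for a
#'   subject to stay in a longitudinal derivative (default 2).
#' @param max_age_source_deviation largest tolerated disagreement between
#'   the two age sources, years (default 1; strictly-greater deviations are
#'   rejected).
#' @return object of class `derivative_rules`.
#' @export
derivative_rules <- function(min_duration_s = 900,
                             min_recordings_per_subject = 2,
                             max_age_source_deviation = 1) {
  stopifnot(min_duration_s > 0, min_recordings_per_subject > 0,
            max_age_source_deviation > 0)
  structure(list(min_duration_s = min_duration_s,
                 min_recordings_per_subject = min_recordings_per_subject,
                 max_age_source_deviation = max_age_source_deviation),
            class = "derivative_rules")
}

#' Check consistency of the two age sources
#'
#' @param age_header,age_report ages in years from the two sources.
#' @param rules a [derivative_rules()].
#' @return logical: `TRUE` iff `|age_header - age_report|` does not exceed
#'   the tolerated deviation (strict inequality rejects).
#' @export
check_age_consistency <- function(age_header, age_report,
                                  rules = derivative_rules()) {
  abs(age_header - age_report) <= rules$max_age_source_deviation
}

#' Apply the inclusion/exclusion cascade
#'
#' Drops recordings that are too short, have inconsistent age sources, or
#' belong to an excluded corpus; then drops subjects left with fewer than
#' the minimum number of recordings; repeats to a fixed point (rejecting one
#' recording can strand its sibling below the subject minimum).
#'
#' @param manifest manifest data.frame (see [cohort_manifest()]); an
#'   `excluded_corpus` logical column is honored when present.
#' @param rules a [derivative_rules()].
#' @return list with `manifest` (surviving rows, original order) and
#'   `exclusions` (data.frame: recording_id, subject_id, reason).
#' @export
apply_inclusion <- function(manifest, rules = derivative_rules()) {
  log <- list()
  note <- function(rows, reason) {
    if (nrow(rows) > 0)
      log[[length(log) + 1L]] <<- data.frame(
        recording_id = rows$recording_id, subject_id = rows$subject_id,
        reason = reason, stringsAsFactors = FALSE)
  }
  keep <- manifest
  if ("excluded_corpus" %in% names(keep)) {
    bad <- keep$excluded_corpus %in% TRUE
    note(keep[bad, ], "excluded corpus")
    keep <- keep[!bad, ]
  }
  bad <- keep$duration_s < rules$min_duration_s
  note(keep[bad, ], sprintf("duration below %g s", rules$min_duration_s))
  keep <- keep[!bad, ]
  bad <- !check_age_consistency(keep$age_header, keep$age_report, rules)
  note(keep[bad, ],
       sprintf("age sources deviate by more than %g year(s)",
               rules$max_age_source_deviation))
  keep <- keep[!bad, ]
  repeat {
    counts <- table(keep$subject_id)
    low <- names(counts)[counts < rules$min_recordings_per_subject]
    if (length(low) == 0) break
    bad <- keep$subject_id %in% low
    note(keep[bad, ], sprintf("subject has fewer than %d retained recording(s)",
                              rules$min_recordings_per_subject))
    keep <- keep[!bad, ]
  }
  exclusions <- if (length(log)) do.call(rbind, log) else
    data.frame(recording_id = character(), subject_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  rownames(keep) <- NULL
  list(manifest = keep, exclusions = exclusions)
}

#' Assign a subject to a longitudinal derivative category
#'
#' @param labels logical pathology labels of one subject's recordings,
#'   sorted by date (`TRUE` = pathological).
#' @return one of `"RNP"` (all non-pathological), `"RP"` (all pathological),
#'   `"TNPP"` (non-pathological then pathological, one flip), `"TPNP"`
#'   (the opposite transition), or `"excluded"` (multiple flips).
#' @export
assign_derivative <- function(labels) {
  stopifnot(length(labels) >= 2, is.logical(labels))
  runs <- rle(labels)$values
  if (length(runs) == 1) return(if (runs) "RP" else "RNP")
  if (length(runs) == 2) return(if (runs[2]) "TNPP" else "TPNP")
  "excluded"
}

#' Categorize all subjects of a manifest
#'
#' Date-sorts each subject's recordings and applies [assign_derivative()].
#' Same-day ties are ordered non-pathological first (conservative: a same-day
#' NP/P pair cannot fabricate a P-to-NP transition) and such subjects are
#' flagged.
#'
#' @param manifest manifest data.frame with >= 2 recordings per subject.
#' @return data.frame: subject_id, category, n_recordings, tied_dates.
#' @export
derive_categories <- function(manifest) {
  split_subj <- split(manifest, manifest$subject_id)
  rows <- lapply(split_subj, function(m) {
    ord <- order(m$date_days, m$pathology)  # ties: non-pathological first
    tied <- anyDuplicated(m$date_days) > 0
    data.frame(subject_id = m$subject_id[1],
               category = assign_derivative(m$pathology[ord]),
               n_recordings = nrow(m), tied_dates = tied,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Keyword-based condition subgroups
#'
#' A subject belongs to a condition iff at least one of its report texts
#' contains the keyword as a case-insensitive substring; subjects may belong
#' to several conditions.
#'
#' @param manifest manifest data.frame with `subject_id` and `report`.
#' @param keywords named character vector of substrings (defaults: `schizo`,
#'   `depress`, `stroke`).
#' @return named list of subject-id character vectors, one per condition.
#' @export
keyword_subgroups <- function(manifest,
                              keywords = c(schizophrenia = "schizo",
                                           depression = "depress",
                                           stroke = "stroke")) {
  rep_txt <- ifelse(is.na(manifest$report), "", manifest$report)
  lapply(as.list(keywords), function(kw) {
    hit <- grepl(kw, rep_txt, ignore.case = TRUE, fixed = FALSE)
    sort(unique(manifest$subject_id[hit]))
  })
}
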
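toy_manifest <- function(subject_id, recording_id, date_days, age_header,
                         age_report, pathology, duration_s = 1000,
                         report = "", excluded_corpus = FALSE) {
  data.frame(subject_id = subject_id, recording_id = recording_id,
             date_days = date_days, age_header = age_header,
             age_report = age_report, sex = "F", pathology = pathology,
             report = report, edf_path = NA_character_,
             duration_s = duration_s, excluded_corpus = excluded_corpus,
             stringsAsFactors = FALSE)
}

test_that("age-source consistency uses a strict one-year threshold", {
  rules <- derivative_rules()
  expect_true(check_age_consistency(50, 50, rules))
  expect_true(check_age_consistency(50, 51, rules))
  expect_false(check_age_consistency(50, 52, rules))
  expect_false(check_age_consistency(50, 51.5, rules))
})

test_that("inclusion cascade: rejecting one recording strands its sibling", {
  m <- toy_manifest(subject_id = c("a", "a"), recording_id = c("r1", "r2"),
                    date_days = c(0, 100), age_header = c(40, 40.3),
                    age_report = c(40, 40.3), pathology = c(FALSE, FALSE),
                    duration_s = c(1000, 500))
  out <- apply_inclusion(m, derivative_rules(min_duration_s = 900))
  expect_equal(nrow(out$manifest), 0)
  expect_setequal(out$exclusions$recording_id, c("r1", "r2"))
  expect_match(out$exclusions$reason[out$exclusions$recording_id == "r2"],
               "duration")
  expect_match(out$exclusions$reason[out$exclusions$recording_id == "r1"],
               "fewer than")

  ok <- toy_manifest(subject_id = c("a", "a"), recording_id = c("r1", "r2"),
                     date_days = c(0, 100), age_header = c(40, 40.3),
                     age_report = c(40, 40.3), pathology = c(FALSE, TRUE))
  res <- apply_inclusion(ok, derivative_rules())
  expect_equal(res$manifest$recording_id, ok$recording_id)
  expect_equal(nrow(res$exclusions), 0)
})

test_that("inclusion cascade equals an exhaustive oracle on planted-violation toys and is row-order invariant", {
  # brute-force oracle: enumerate subjects, keep those whose individually
  # valid recordings still meet the minimum count
  oracle <- function(m, rules) {
    ok_rec <- m$duration_s >= rules$min_duration_s &
      abs(m$age_header - m$age_report) <= rules$max_age_source_deviation &
      !(m$excluded_corpus %in% TRUE)
    kept <- m[ok_rec, ]
    keep_subj <- vapply(unique(kept$subject_id), function(s)
      sum(kept$subject_id == s) >= rules$min_recordings_per_subject, TRUE)
    sort(kept$recording_id[kept$subject_id %in%
                             unique(kept$subject_id)[keep_subj]])
  }
  rules <- derivative_rules(min_duration_s = 900)
  set.seed(77)
  for (rep in 1:5) {
    n_subj <- 10
    rows <- do.call(rbind, lapply(seq_len(n_subj), function(s) {
      k <- sample(1:4, 1)
      toy_manifest(
        subject_id = rep(sprintf("s%02d", s), k),
        recording_id = sprintf("s%02d_r%d", s, seq_len(k)),
        date_days = sort(stats::runif(k, 0, 2000)),
        age_header = rep(50, k),
        age_report = 50 + sample(c(0, 0, 0, 3), k, replace = TRUE),
        pathology = sample(c(TRUE, FALSE), k, replace = TRUE),
        duration_s = sample(c(1000, 1000, 600), k, replace = TRUE),
        excluded_corpus = sample(c(FALSE, FALSE, FALSE, TRUE), k,
                                 replace = TRUE))
    }))
    got <- apply_inclusion(rows, rules)
    expect_equal(sort(got$manifest$recording_id), oracle(rows, rules))
    shuffled <- rows[sample(nrow(rows)), ]
    got2 <- apply_inclusion(shuffled, rules)
    expect_setequal(got2$manifest$recording_id, got$manifest$recording_id)
  }
})

test_that("derivative assignment matches a regular-expression oracle over all length-4 label sequences", {
  # oracle: RNP = N+, RP = P+, TNPP = N+P+, TPNP = P+N+, else excluded
  oracle <- function(labels) {
    s <- paste(ifelse(labels, "P", "N"), collapse = "")
    if (grepl("^N+$", s)) "RNP"
    else if (grepl("^P+$", s)) "RP"
    else if (grepl("^N+P+$", s)) "TNPP"
    else if (grepl("^P+N+$", s)) "TPNP"
    else "excluded"
  }
  for (i in 0:15) {
    labels <- as.logical(bitwAnd(i, c(8, 4, 2, 1)) > 0)
    expect_equal(assign_derivative(labels), oracle(labels),
                 label = paste(labels, collapse = ","))
  }
  expect_equal(assign_derivative(c(FALSE, TRUE)), "TNPP")
  expect_equal(assign_derivative(c(TRUE, FALSE)), "TPNP")
  expect_equal(assign_derivative(c(FALSE, TRUE, FALSE)), "excluded")
})

test_that("categories partition subjects and transition fraction converges to the dial", {
  cfg <- cohort_config(n_subjects = 400, transition_fraction = 0.25,
                       pathology_fraction = 0.4,
                       recordings_per_subject_mean = 2.5, seed = 99L)
  m <- cohort_manifest(generate_cohort(cfg, signals = FALSE)$recordings)
  counts <- table(m$subject_id)
  multi <- m[m$subject_id %in% names(counts)[counts >= 2], ]
  cats <- derive_categories(multi)
  expect_equal(nrow(cats), length(unique(multi$subject_id)))
  expect_true(all(cats$category %in%
                    c("RNP", "RP", "TNPP", "TPNP", "excluded")))
  trans_frac <- mean(cats$category %in% c("TNPP", "TPNP"))
  expect_gt(trans_frac, 0.20)
  expect_lt(trans_frac, 0.32)
})

test_that("keyword subgroups are case-insensitive substring matches per subject", {
  m <- toy_manifest(
    subject_id = c("a", "a", "b", "c"),
    recording_id = paste0("r", 1:4),
    date_days = 1:4, age_header = rep(50, 4), age_report = rep(50, 4),
    pathology = rep(TRUE, 4),
    report = c("Hx of STROKE in 2010", "",
               "depression, r/o schizoaffective", ""))
  g <- keyword_subgroups(m)
  expect_equal(g$stroke, "a")
  expect_equal(g$schizophrenia, "b")
  expect_equal(g$depression, "b")
  expect_false("c" %in% unlist(g))
})
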
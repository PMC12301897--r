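test_that("threshold optimizer solves separable data and never scores below chance on its own training set", {
  tp <- optimize_thresholds(c(-1, 0, 1, -10, 10),
                            c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(tp$bacc, 1)
  expect_gt(tp$lo, -10); expect_lt(tp$lo, -1)
  expect_gt(tp$hi, 1); expect_lt(tp$hi, 10)

  set.seed(3)
  for (rep in 1:5) {
    g <- stats::rnorm(200)
    l <- sample(c(TRUE, FALSE), 200, replace = TRUE)
    expect_gte(optimize_thresholds(g, l)$bacc, 0.5)
  }
  expect_error(optimize_thresholds(1:5, rep(TRUE, 5)), "class error")
})

test_that("threshold optimizer equals O(m^2) brute force on small sets", {
  brute <- function(gaps, labels) {
    cand <- c(-Inf, sort(unique(gaps)), Inf)
    # dense pairs over values themselves plus midpoints
    u <- sort(unique(gaps))
    mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric()
    cand <- c(-Inf, mids, Inf)
    best <- -Inf
    for (lo in cand) for (hi in cand[cand >= lo]) {
      pred <- gaps < lo | gaps > hi
      b <- bacc_labels(labels, pred)
      if (b > best) best <- b
    }
    best
  }
  set.seed(11)
  for (rep in 1:8) {
    g <- round(stats::rnorm(12), 2)
    l <- c(rep(TRUE, 5), rep(FALSE, 7))[sample(12)]
    got <- optimize_thresholds(g, l)
    expect_equal(got$bacc, brute(g, l))
    # round trip: applying the returned pair reproduces the achieved BACC
    expect_equal(bacc_labels(l, classify_gaps(got, g)), got$bacc)
  }
})

test_that("classification rule is a closed non-pathological interval, invariant under monotone transforms", {
  pair <- structure(list(lo = -2, hi = 3), class = "threshold_pair")
  expect_equal(classify_gaps(pair, c(-3, -2, 0, 3, 3.1)),
               c(TRUE, FALSE, FALSE, FALSE, TRUE))
  all_np <- structure(list(lo = -Inf, hi = Inf), class = "threshold_pair")
  expect_false(any(classify_gaps(all_np, stats::rnorm(50))))

  set.seed(21)
  g <- stats::rnorm(60)
  l <- g^2 + stats::rnorm(60, 0, 0.5) > 1
  b1 <- optimize_thresholds(g, l)$bacc
  b2 <- optimize_thresholds(exp(2 * g), l)$bacc  # strictly monotone map
  expect_equal(b1, b2)
})

test_that("age-threshold proxy equals the single-cut brute force and handles edge cases", {
  brute <- function(ages, labels) {
    u <- sort(unique(ages))
    mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric()
    cand <- c(-Inf, mids, Inf)
    max(vapply(cand, function(t)
      bacc_labels(labels, ages > t), 0))
  }
  set.seed(31)
  for (rep in 1:5) {
    a <- round(stats::runif(15, 20, 80))
    l <- c(rep(TRUE, 7), rep(FALSE, 8))[sample(15)]
    got <- age_threshold_proxy(a, l)
    expect_equal(got$bacc, brute(a, l))
    expect_equal(bacc_labels(l, classify_ages(got, a)), got$bacc)
  }
  sep <- age_threshold_proxy(c(20, 25, 30, 60, 65, 70),
                             c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(sep$bacc, 1)
})

test_that("change rates: slopes, same-day averaging and the hand oracle", {
  expect_equal(change_rates(data.frame(
    subject_id = "s", date_days = c(0, 2 * 365.25),
    gap_corrected = c(2, 4)))$rate, 1)

  # same-day duplicates average before the slope
  r <- change_rates(data.frame(
    subject_id = "s", date_days = c(10, 10, 10 + 365.25),
    gap_corrected = c(1, 3, 4)))
  expect_equal(r$rate, 2)

  # 5-subject toy table against a hand-computed oracle
  set.seed(41)
  rows <- list(); expected <- c()
  for (s in 1:5) {
    k <- sample(2:4, 1)
    dates <- sort(stats::runif(k, 0, 1500))
    gaps <- stats::rnorm(k)
    rows[[s]] <- data.frame(subject_id = sprintf("s%d", s),
                            date_days = dates, gap_corrected = gaps)
    expected[sprintf("s%d", s)] <-
      mean(diff(gaps) / (diff(dates) / 365.25))
  }
  got <- change_rates(do.call(rbind, rows))
  expect_equal(got$rate, unname(expected[got$subject_id]))

  skipped <- change_rates(data.frame(
    subject_id = c("a", "b", "b"), date_days = c(1, 1, 300),
    gap_corrected = c(0, 1, 2)))
  expect_equal(skipped$subject_id, "b")
  expect_equal(attr(skipped, "skipped")$subject_id, "a")
})

test_that("moment-of-transition rate spans the flip pair only", {
  expect_equal(transition_rate(data.frame(
    subject_id = "s", date_days = c(0, 2 * 365.25),
    gap_corrected = c(0, 3), pathology = c(FALSE, TRUE)))$rate, 1.5)

  # same-day averaging on each side of the flip
  tr <- transition_rate(data.frame(
    subject_id = "s", date_days = c(0, 0, 365.25, 365.25),
    gap_corrected = c(1, 3, 6, 8), pathology = c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(tr$rate, 5)
  expect_equal(tr$direction, "P->NP")

  expect_error(transition_rate(data.frame(
    subject_id = "s", date_days = c(0, 0),
    gap_corrected = c(0, 1), pathology = c(FALSE, TRUE))), "pattern error")
  expect_error(transition_rate(data.frame(
    subject_id = "s", date_days = c(0, 100, 200),
    gap_corrected = c(0, 1, 0), pathology = c(FALSE, TRUE, FALSE))),
    "pattern error")

  # TNPP toy cohort vs hand oracle
  set.seed(51)
  rows <- list(); expected <- c()
  for (s in 1:4) {
    dates <- sort(stats::runif(4, 0, 2000))
    gaps <- stats::rnorm(4)
    flip <- sample(1:3, 1)
    labels <- c(rep(FALSE, flip), rep(TRUE, 4 - flip))
    rows[[s]] <- data.frame(subject_id = sprintf("s%d", s),
                            date_days = dates, gap_corrected = gaps,
                            pathology = labels)
    expected[sprintf("s%d", s)] <- (gaps[flip + 1] - gaps[flip]) /
      ((dates[flip + 1] - dates[flip]) / 365.25)
  }
  got <- transition_rates(do.call(rbind, rows))
  expect_equal(got$rate, unname(expected[got$subject_id]))
  expect_true(all(got$direction == "NP->P"))
})
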
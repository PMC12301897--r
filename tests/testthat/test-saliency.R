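const_double <- function() {
  list(value_fn = function(crop) 0.5,
       grad_fn = function(crop) crop * 0)
}

mean_ch1_double <- function() {
  list(value_fn = function(crop) mean(crop[1, ]),
       grad_fn = function(crop) {
         g <- crop * 0
         g[1, ] <- 1 / ncol(crop)
         g
       })
}

test_that("amplitude gradients of analytic models: constant is zero, channel mean hits only DC", {
  crop <- matrix(stats::rnorm(4 * 64), 4, 64,
                 dimnames = list(c("Fp1", "C3", "O1", "O2"), NULL))
  zero <- amplitude_gradients(const_double(), crop, sfreq = 100)
  expect_true(all(zero$grad == 0))

  g <- amplitude_gradients(mean_ch1_double(), crop, sfreq = 100)
  expect_equal(unname(abs(g$grad[1, 1])), 1, tolerance = 1e-10)
  expect_lt(max(abs(g$grad[1, -1])), 1e-10)
  expect_lt(max(abs(g$grad[-1, ])), 1e-10)
  expect_equal(g$freq[1], 0)
})

test_that("gradient linearity: the gradient of a sum of models is the sum of gradients", {
  crop <- matrix(stats::rnorm(3 * 50), 3, 50)
  m1 <- mean_ch1_double()
  m2 <- list(value_fn = function(crop) 2 * mean(crop[2, ]^1),
             grad_fn = function(crop) {
               g <- crop * 0; g[2, ] <- 2 / ncol(crop); g
             })
  msum <- list(value_fn = function(crop) m1$value_fn(crop) + m2$value_fn(crop),
               grad_fn = function(crop) m1$grad_fn(crop) + m2$grad_fn(crop))
  gs <- amplitude_gradients(msum, crop, 100)$grad
  g1 <- amplitude_gradients(m1, crop, 100)$grad
  g2 <- amplitude_gradients(m2, crop, 100)$grad
  expect_equal(gs, g1 + g2, tolerance = 1e-12)
})

test_that("chain-rule amplitude gradients match central finite differences on the trained network", {
  fx <- trained_fixture()
  # identity normalization so finite perturbations live in the same space
  fit <- fx$fit
  fit$stats$mean[] <- 0
  fit$stats$sd[] <- 1
  rf <- fit$model$cfg$receptive_field
  rec <- fx$preprocessed[[fx$eval_idx[2]]]
  crop <- apply_normalization(fx$fit$stats, rec$signal[, 201:(200 + rf)])

  ag <- amplitude_gradients(fit, crop, rec$sfreq)
  n <- ncol(crop)
  set.seed(17)
  coords <- cbind(sample(nrow(crop), 5, replace = TRUE),
                  sample(2:(floor(n / 2)), 5))
  eps <- 1e-4
  out_of <- function(x) {
    fwd <- tcn_forward(fit$model, t(x), 1L)
    mean(fwd$out)
  }
  for (i in 1:5) {
    c0 <- coords[i, 1]; f0 <- coords[i, 2]
    basis <- cos(2 * pi * (f0 - 1) * (seq_len(n) - 1) / n +
                   ag$phase[c0, f0])
    xp <- crop; xp[c0, ] <- xp[c0, ] + eps * basis
    xm <- crop; xm[c0, ] <- xm[c0, ] - eps * basis
    num <- (out_of(xp) - out_of(xm)) / (2 * eps)
    expect_equal(unname(ag$grad[c0, f0]), num, tolerance = 1e-3)
  }

  # sign convention: finite perturbation at the strongest coordinate moves
  # the prediction in the direction of the gradient sign
  idx <- which(abs(ag$grad) == max(abs(ag$grad)), arr.ind = TRUE)[1, ]
  basis <- cos(2 * pi * (idx[2] - 1) * (seq_len(n) - 1) / n +
                 ag$phase[idx[1], idx[2]])
  xp <- crop; xp[idx[1], ] <- xp[idx[1], ] + 0.02 * basis
  expect_equal(unname(sign(out_of(xp) - out_of(crop))),
               unname(sign(ag$grad[idx[1], idx[2]])))
})

test_that("band aggregation equals the brute-force masked mean", {
  freq <- seq(0, 50, by = 0.5)
  flat <- matrix(0.7, 2, length(freq))
  agg <- band_aggregate(flat, freq)
  expect_true(all(agg == 0.7))

  single <- matrix(0, 2, length(freq))
  single[1, which(freq == 10)] <- 3
  agg1 <- band_aggregate(single, freq)
  expect_gt(agg1[1, "alpha"], 0)
  expect_equal(agg1[1, c("delta", "theta", "beta", "gamma")],
               c(delta = 0, theta = 0, beta = 0, gamma = 0))

  set.seed(27)
  rand <- matrix(stats::rnorm(2 * length(freq)), 2)
  agg2 <- band_aggregate(rand, freq)
  bands <- band_definitions()
  for (b in seq_len(nrow(bands))) {
    sel <- freq >= bands$lo[b] & freq < bands$hi[b]
    expect_equal(agg2[, bands$name[b]],
                 rowMeans(rand[, sel, drop = FALSE]))
  }
})

test_that("group saliency reduces correctly and recovers the planted occipital-alpha feature", {
  fx <- trained_fixture()
  recs <- fx$preprocessed[fx$eval_idx]
  labels <- vapply(recs, `[[`, TRUE, "pathology")

  # identical signal in both groups -> zero difference map
  twin_np <- recs[[1]]; twin_np$pathology <- FALSE
  twin_p <- recs[[1]]; twin_p$pathology <- TRUE
  twin_p$subject_id <- paste0(twin_p$subject_id, "_p")
  sal_twin <- group_saliency(list(fx$fit), list(twin_np, twin_p))
  expect_lt(max(abs(sal_twin$difference)), 1e-12)

  # single run, single subject per group reduces to the per-recording map
  expect_equal(sal_twin$np, sal_twin$p)

  # planted-feature recovery: age is encoded occipitally in the alpha
  # rhythm. The receptive-field-length analysis window has ~1.75 Hz bins,
  # and signed group averaging across subjects whose peaks straddle the
  # 8 Hz boundary can shift the band maximum into adjacent theta, so the
  # assertion is occipital dominance within the theta/alpha pair.
  sal <- group_saliency(list(fx$fit), recs)
  m <- abs(sal$np)
  idx <- which(m == max(m), arr.ind = TRUE)
  expect_true(rownames(m)[idx[1]] %in% c("O1", "O2"))
  expect_true(colnames(m)[idx[2]] %in% c("theta", "alpha"))
  low <- m[, "theta"] + m[, "alpha"]
  expect_true(names(which.max(low)) %in% c("O1", "O2"))
  expect_gt(max(low[c("O1", "O2")]), max(low[c("C3", "C4", "T5", "T6")]))
  expect_equal(sal$difference, sal$np - sal$p)

  expect_error(group_saliency(list(fx$fit), list(twin_np)),
               "per pathology group")
})
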
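# Trace statistics and decoding.

test_that("dF/F normalizes to the pre-stimulus baseline", {
  t_s <- seq(0, 9.9, by = 0.1)
  f <- rep(100, length(t_s))
  expect_true(all(dff(f, t_s, onset_s = 5) == 0))
  f2 <- ifelse(t_s >= 5, 150, 100)
  expect_equal(unique(dff(f2, t_s, 5)[t_s >= 5]), 0.5)
  # toy 10-frame trace with drifting baseline, hand-computed
  f3 <- c(98, 99, 100, 101, 102, 120, 130, 125, 110, 105)
  t3 <- 0:9
  f0 <- mean(c(98, 99, 100, 101, 102))
  expect_equal(dff(f3, t3, onset_s = 5, baseline_s = 5), (f3 - f0) / f0)
  expect_error(dff(c(-1, -1, 2), 0:2, onset_s = 2, baseline_s = 2), "baseline")
})

test_that("five-point mean filter averages a shrinking window at the edges", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(mean_filter5(x),
               c(mean(x[1:3]), mean(x[1:4]), mean(x[1:5]), mean(x[2:6]),
                 mean(x[3:6]), mean(x[4:6])))
})

test_that("adaptation index follows (peak - tail)/peak on the filtered trace", {
  t_s <- seq(0, 5, by = 0.05)
  # peak 1, tail 0 -> AI = 1 (complete adaptation)
  x <- ifelse(t_s >= 1 & t_s < 1.5, 1, 0)
  x <- rep(0, length(t_s)); x[t_s >= 1 & t_s <= 1.6] <- 1
  ai1 <- adaptation_index(x, t_s, c(1, 4))
  expect_equal(ai1$ai, 1)
  # tail below baseline -> AI > 1
  x2 <- rep(0, length(t_s)); x2[t_s >= 1 & t_s <= 1.6] <- 1
  x2[t_s >= 3.5 & t_s <= 4.2] <- -0.15  # covers the filter window at the tail
  ai2 <- adaptation_index(x2, t_s, c(1, 4))
  expect_equal(ai2$ai, 1.15)
  expect_error(adaptation_index(rep(-1, length(t_s)), t_s, c(1, 4)),
               "nonpositive")
})

test_that("adaptation index on an explicit 42-Hz trace matches hand filtering", {
  fs <- 42
  t_s <- (0:19) / fs
  x <- c(0, 0.1, 0.5, 1.2, 1.0, 0.9, 0.8, 0.75, 0.7, 0.6,
         0.5, 0.45, 0.4, 0.35, 0.3, 0.25, 0.2, 0.18, 0.15, 0.12)
  # hand-apply the centred 5-point mean with edge truncation
  xf <- sapply(seq_along(x), function(i)
    mean(x[max(1, i - 2):min(length(x), i + 2)]))
  win <- c(t_s[2], t_s[18])
  in_stim <- t_s >= win[1] & t_s <= win[2]
  in_tail <- t_s >= win[2] - 0.1 & t_s <= win[2]
  expected <- (max(xf[in_stim]) - mean(xf[in_tail])) / max(xf[in_stim])
  expect_equal(adaptation_index(x, t_s, win)$ai, expected)
})

test_that("SNR is the stimulus max minus baseline mean over baseline SD", {
  set.seed(42)
  t_s <- seq(0, 8, by = 1 / 42)
  x <- rnorm(length(t_s), 0, 0.1)
  x[t_s >= 3 & t_s <= 6] <- 1.0
  snr <- snr_response(x, t_s, c(3, 6), pre_s = 3)
  pre <- t_s >= 0 & t_s < 3
  expect_equal(snr, (1 - mean(x[pre])) / sd(x[pre]))
  expect_equal(snr, 10, tolerance = 0.2)
  # stimulus max equal to baseline mean -> 0
  x0 <- rep(0.5, length(t_s))
  x0[pre] <- x0[pre] + rnorm(sum(pre), 0, 0.01)
  expect_lt(abs(snr_response(x0, t_s, c(3, 6))), 3)
  expect_error(snr_response(rep(1, length(t_s)), t_s, c(3, 6)), "SD")
})

test_that("responsiveness needs SNR >= 5 at a rung and its successor", {
  expect_equal(responsive_flags(c(2, 6, 7, 8)), c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(responsive_flags(c(9, 9, 9, 9)), rep(TRUE, 4))
  # isolated single-concentration SNR spike never counts
  expect_equal(responsive_flags(c(2, 9, 2, 2)), rep(FALSE, 4))
  # the boundary is inclusive: exactly 5 counts
  expect_equal(responsive_flags(c(5, 5)), c(TRUE, TRUE))
  expect_equal(responsive_flags(c(2, 9, 2, 2), require_successor = FALSE),
               c(FALSE, TRUE, FALSE, FALSE))
})

test_that("response amplitude averages the stimulus window plus a 1-s tail", {
  t_s <- seq(0, 10, by = 0.1)
  x <- ifelse(t_s >= 3 & t_s <= 7, 0.5, 0)
  expect_equal(response_amplitude(x, t_s, c(3, 6)), 0.5)
  expect_equal(normalize_responses(c(0.2, 0.4)), c(0.5, 1.0))
  expect_equal(max(normalize_responses(c(0.1, 0.7, 0.3))), 1)
  expect_equal(normalize_responses(c(-1, -2)), c(0, 0))
})

test_that("percept labels split the ladder at 0.01 and 0.3 % sv", {
  ladder <- c(3e-5, 1e-4, 3e-3, 1e-2, 0.1, 1, 3, 10)
  lab <- label_percepts(ladder)
  expect_equal(as.character(lab[1:4]), rep("weak", 4))
  expect_true(is.na(lab[5]))  # transition range
  expect_equal(as.character(lab[6:8]), rep("strong", 3))
  expect_equal(as.character(label_percepts(3)), "strong")
})

test_that("response maps are baseline-normalized, smoothed and masked", {
  h <- w <- 24; nt <- 40
  t_s <- seq(0, length.out = nt, by = 0.1)
  movie <- array(100, c(h, w, nt))
  masks <- matrix(0L, h, w); masks[8:16, 8:16] <- 1L
  # constant movie -> zero map
  expect_true(all(response_map(movie, masks, t_s, c(2, 3.9), pre_s = 2) == 0))
  # single-pixel doubling inside a mask: smoothed bump integrating to the
  # unsmoothed response
  movie2 <- movie
  movie2[12, 12, t_s >= 2] <- 200
  mp <- response_map(movie2, matrix(1L, h, w), t_s, c(2, 3.9), pre_s = 2)
  delta <- matrix(0, h, w); delta[12, 12] <- 1
  ref <- as.matrix(EBImage::gblur(delta, sigma = 2))
  expect_equal(mp, ref, tolerance = 1e-6)
  expect_equal(sum(mp), 1, tolerance = 0.01)
  # response outside all masks -> zero map
  movie3 <- movie
  movie3[2, 2, t_s >= 2] <- 300
  mp3 <- response_map(movie3, masks, t_s, c(2, 3.9), pre_s = 2)
  expect_lt(max(abs(mp3)), 1e-3)  # only far smoothing tails can leak in
  expect_error(response_map(movie, matrix(0L, h, w), t_s, c(2, 3.9)), "mask")
})

test_that("weighted F1 averages per-class F1 by support", {
  truth <- factor(c("a", "a", "a", "b", "b"))
  pred <- factor(c("a", "a", "b", "b", "b"), levels = c("a", "b"))
  f1_a <- 2 * (2/2) * (2/3) / ((2/2) + (2/3))
  f1_b <- 2 * (2/3) * (2/2) / ((2/3) + (2/2))
  expect_equal(weighted_f1(truth, pred), (3 * f1_a + 2 * f1_b) / 5)
  expect_equal(weighted_f1(truth, truth), 1)
})

test_that("linearly separable data give F1 = 1 and shuffling gives chance", {
  set.seed(7)
  n <- 12
  x <- cbind(g1 = c(rnorm(n, 1, 0.1), rnorm(n, -1, 0.1)),
             g2 = rnorm(2 * n, 0, 0.1))
  y <- factor(rep(c("weak", "strong"), each = n))
  rep <- fit_percept_classifier(x, y)
  expect_equal(rep$f1, 1)
  set.seed(8)
  perm <- permutation_f1(x, y, n_shuffles = 100)
  # chance level for balanced two-class LOO (slightly pessimistic)
  expect_gt(perm$mean_f1, 0.25)
  expect_lt(perm$mean_f1, 0.7)
  expect_lt(perm$mean_f1, rep$f1 - 0.3)
})

test_that("a single informative glomerulus takes weight 1 and top-1 suffices", {
  set.seed(21)
  n <- 10
  x <- cbind(g1 = c(rnorm(n, 1, 0.05), rnorm(n, 0, 0.05)),
             g2 = rnorm(2 * n, 0.5, 0.3),
             g3 = rnorm(2 * n, 0.5, 0.3))
  y <- factor(rep(c("weak", "strong"), each = n))
  rep <- fit_percept_classifier(x, y, top_k = 1)
  expect_equal(names(which.max(rep$weights)), "g1")
  expect_equal(max(rep$weights), 1)
  expect_equal(sum(rep$weights == 1), 1)
  expect_equal(unname(rep$top_k["top1"]), rep$f1, tolerance = 0.1)
})

test_that("classifier report is invariant to glomerulus order and global rescaling", {
  set.seed(3)
  n <- 8
  x <- cbind(g1 = c(rnorm(n, 1, 0.2), rnorm(n, -0.5, 0.2)),
             g2 = c(rnorm(n, 0, 0.2), rnorm(n, 0.8, 0.2)),
             g3 = rnorm(2 * n, 0, 0.2))
  y <- factor(rep(c("weak", "strong"), each = n))
  r1 <- fit_percept_classifier(x, y)
  r2 <- fit_percept_classifier(x[, c(3, 1, 2)], y)
  expect_equal(r1$f1, r2$f1)
  expect_equal(r1$weights[c("g1", "g2", "g3")],
               r2$weights[c("g1", "g2", "g3")], tolerance = 1e-6)
  # soft-margin fits are only approximately scale-invariant (fixed cost C)
  r3 <- fit_percept_classifier(5 * x, y)
  expect_equal(r1$weights, r3$weights, tolerance = 0.1)
  expect_equal(names(which.max(r1$weights)), names(which.max(r3$weights)))
  expect_error(fit_percept_classifier(x, factor(rep("weak", 2 * n))), "class")
})

test_that("activation ranks order glomeruli by first supra-SNR frame", {
  t_s <- seq(0, 10, by = 1 / 42)
  base <- function() rnorm(length(t_s), 0, 0.02)
  set.seed(5)
  mk <- function(onset_s, amp = 1) {
    x <- base()
    x[t_s >= onset_s] <- x[t_s >= onset_s] + amp
    x
  }
  # one responsive glomerulus -> rank 1
  r1 <- rank_activation(list(a = mk(5.2), b = base()), t_s, c(5, 8))
  expect_equal(r1$rank[r1$glomerulus == "a"], 1)
  expect_true(is.na(r1$rank[r1$glomerulus == "b"]))
  # onsets at different frames -> ranks 1, 2; ranks are a permutation
  r2 <- rank_activation(list(a = mk(5.6), b = mk(5.1)), t_s, c(5, 8))
  expect_equal(r2$rank[r2$glomerulus == "b"], 1)
  expect_equal(sort(r2$rank), c(1, 2))
  # tie on the same frame: larger dF/F wins, then glomerulus id
  set.seed(6)
  ra <- rank_activation(list(a = mk(5.5, amp = 0.5), b = mk(5.5, amp = 2)),
                        t_s, c(5, 8))
  expect_equal(ra$rank[ra$glomerulus == "b"], 1)
  # mean rank across repeats
  expect_equal(mean_rank(c(1, 2, 1)), 4 / 3)
})

test_that("coherent activity drops flag irregular-breathing trials", {
  t_s <- seq(0, 10, by = 1 / 42)
  set.seed(11)
  clean <- replicate(5, rnorm(length(t_s), 0, 0.02), simplify = FALSE)
  expect_false(breathing_artifact(clean, t_s, onset_s = 5))
  dropped <- lapply(clean, function(x) {
    x[t_s >= 6 & t_s <= 6.8] <- x[t_s >= 6 & t_s <= 6.8] - 0.3
    x
  })
  expect_true(breathing_artifact(dropped, t_s, onset_s = 5))
  # a drop in a single glomerulus does not flag the trial
  one <- clean
  one[[1]][t_s >= 6 & t_s <= 6.8] <- -0.3
  expect_false(breathing_artifact(one, t_s, onset_s = 5))
})
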
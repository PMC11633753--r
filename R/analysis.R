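# Trace statistics and decoding for glomerular calcium imaging: dF/F,
# response maps, adaptation index, SNR-based responsiveness, response
# amplitudes, percept labelling, max-margin percept classification with
# leave-one-out weighted F1, and activation-time ranking.

#' dF/F normalization
#'
#' `(F - F0) / F0` with `F0` the mean fluorescence over a baseline window
#' immediately preceding odor onset (5 s by default).
#'
#' @param f Raw fluorescence trace.
#' @param t_s Frame time stamps (s), same length as `f`.
#' @param onset_s Odor onset (s).
#' @param baseline_s Baseline window length (s) before onset.
#' @return Numeric dF/F trace, same length as `f`.
#' @export
dff <- function(f, t_s, onset_s, baseline_s = 5) {
  stopifnot(length(f) == length(t_s))
  sel <- t_s >= onset_s - baseline_s & t_s < onset_s
  if (!any(sel)) stop("no frames in the baseline window")
  f0 <- mean(f[sel])
  if (!is.finite(f0) || f0 <= 0) stop("invalid baseline: F0 must be positive")
  (f - f0) / f0
}

#' Five-point mean filter
#'
#' Centred moving average over 5 samples, with a shrinking window at the
#' trace boundaries (edge truncation).
#'
#' @param x Numeric vector.
#' @return Filtered vector, same length.
#' @export
mean_filter5 <- function(x) {
  n <- length(x)
  if (n < 2) return(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - 2):min(n, i + 2)
    out[i] <- mean(x[j])
  }
  out
}

#' Adaptation index
#'
#' `AI = (peak - tail) / peak` where `peak` is the maximum response during
#' the stimulus and `tail` is the mean over the last 100 ms of the stimulus
#' period, both computed on the 5-point-mean-filtered trace. AI = 1 means
#' complete adaptation (tail at baseline); AI > 1 means the response falls
#' below baseline during the stimulus.
#'
#' @param x dF/F trace (or any baseline-relative response trace).
#' @param t_s Time stamps (s).
#' @param stim_window Length-2 numeric, stimulus onset/offset (s).
#' @param tail_ms Tail window length (ms); 100 per the definition.
#' @return List of class `adaptation_index`: `ai`, `peak`, `tail`.
#' @export
adaptation_index <- function(x, t_s, stim_window, tail_ms = 100) {
  stopifnot(length(x) == length(t_s), length(stim_window) == 2)
  xf <- mean_filter5(x)
  in_stim <- t_s >= stim_window[1] & t_s <= stim_window[2]
  if (!any(in_stim)) stop("no frames in the stimulus window")
  in_tail <- t_s >= stim_window[2] - tail_ms / 1000 & t_s <= stim_window[2]
  if (!any(in_tail)) stop("no frames in the last ", tail_ms, " ms of the stimulus")
  peak <- max(xf[in_stim])
  if (peak <= 0) stop("undefined AI: peak response is nonpositive")
  tail_mean <- mean(xf[in_tail])
  structure(list(ai = (peak - tail_mean) / peak, peak = peak,
                 tail = tail_mean), class = "adaptation_index")
}

#' Response signal-to-noise ratio
#'
#' `(max amplitude over the stimulus window - mean over the pre-stimulus
#' window) / SD over the pre-stimulus window`; the pre-window is the 3 s
#' preceding odor onset.
#'
#' @inheritParams adaptation_index
#' @param pre_s Pre-stimulus window length (s).
#' @return Dimensionless SNR.
#' @export
snr_response <- function(x, t_s, stim_window, pre_s = 3) {
  pre <- t_s >= stim_window[1] - pre_s & t_s < stim_window[1]
  stim <- t_s >= stim_window[1] & t_s <= stim_window[2]
  if (!any(pre)) stop("no frames in the pre-stimulus window")
  if (!any(stim)) stop("no frames in the stimulus window")
  s <- sd(x[pre])
  if (!is.finite(s) || s == 0) stop("zero baseline SD: SNR undefined")
  (max(x[stim]) - mean(x[pre])) / s
}

#' Responsiveness across a concentration ladder
#'
#' A glomerulus is responsive at a concentration iff its SNR is at or above
#' the threshold there AND at the next tested (ascending) concentration;
#' the top rung is judged on its own SNR only. The threshold is inclusive
#' (SNR exactly 5 counts).
#'
#' @param snr Numeric vector of SNR values ordered by ascending
#'   concentration.
#' @param threshold Responsiveness threshold (default 5).
#' @param require_successor Apply the successive-concentration rule
#'   (default `TRUE`); `FALSE` uses the own-SNR rule everywhere.
#' @return Logical vector, same length as `snr`.
#' @export
responsive_flags <- function(snr, threshold = 5, require_successor = TRUE) {
  own <- snr >= threshold
  if (!require_successor || length(snr) < 2) return(own)
  own & c(own[-1], TRUE)
}

#' Response amplitude
#'
#' Mean of the response over the stimulus period plus a post-offset tail
#' (1 s by default, accounting for delayed activation).
#'
#' @inheritParams adaptation_index
#' @param tail_s Post-offset tail included in the mean (s).
#' @return Mean amplitude (same units as `x`).
#' @export
response_amplitude <- function(x, t_s, stim_window, tail_s = 1) {
  sel <- t_s >= stim_window[1] & t_s <= stim_window[2] + tail_s
  if (!any(sel)) stop("no frames in the amplitude window")
  mean(x[sel])
}

#' Normalize responses to the maximum across stimuli
#'
#' @param amps Numeric vector of per-stimulus amplitudes for one glomerulus.
#' @return `amps / max(amps)`; all zero if the maximum is not positive.
#' @export
normalize_responses <- function(amps) {
  m <- max(amps, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) return(rep(0, length(amps)))
  amps / m
}

#' Percept labels for a concentration ladder
#'
#' Concentrations at or below `weak_max` map to the weak percept, at or
#' above `strong_min` to the strong percept; the transition range in
#' between is unlabeled (NA) and excluded from classification.
#'
#' @param concentration Concentrations in % saturated vapor.
#' @param weak_max Upper bound of the weak percept (% sv); default 0.01.
#' @param strong_min Lower bound of the strong percept (% sv); default 0.3.
#' @return Factor with levels `weak`, `strong`; NA in the transition range.
#' @export
label_percepts <- function(concentration, weak_max = 0.01, strong_min = 0.3) {
  lab <- rep(NA_character_, length(concentration))
  lab[concentration <= weak_max] <- "weak"
  lab[concentration >= strong_min] <- "strong"
  factor(lab, levels = c("weak", "strong"))
}

#' Response map from an imaging movie
#'
#' Per-pixel dF/F relative to the mean image over the `pre_s` seconds
#' preceding the stimulus, averaged over the stimulus window, smoothed with
#' a 2-D Gaussian (sigma = 2 px) and zeroed outside the segmented glomeruli.
#'
#' @param movie Numeric array `height x width x frames`.
#' @param masks Integer (or logical) matrix `height x width`; nonzero pixels
#'   belong to segmented glomeruli.
#' @param t_s Frame time stamps (s), length `dim(movie)[3]`.
#' @param stim_window Length-2 numeric, stimulus onset/offset (s).
#' @param pre_s Baseline window (s) preceding onset.
#' @param sigma Gaussian smoothing sigma (pixels).
#' @return Numeric matrix `height x width`.
#' @export
response_map <- function(movie, masks, t_s, stim_window, pre_s = 3, sigma = 2) {
  stopifnot(length(dim(movie)) == 3, length(t_s) == dim(movie)[3])
  masks <- masks != 0
  if (!any(masks)) stop("empty mask set")
  pre <- t_s >= stim_window[1] - pre_s & t_s < stim_window[1]
  stim <- t_s >= stim_window[1] & t_s <= stim_window[2]
  if (!any(pre) || !any(stim)) stop("movie does not cover pre and stimulus windows")
  f0 <- apply(movie[, , pre, drop = FALSE], c(1, 2), mean)
  if (any(f0 <= 0)) stop("invalid baseline image: F0 must be positive everywhere")
  fm <- apply(movie[, , stim, drop = FALSE], c(1, 2), mean)
  map <- (fm - f0) / f0
  sm <- as.matrix(EBImage::gblur(map, sigma = sigma))
  sm[!masks] <- 0
  sm
}

# ---- percept classification -------------------------------------------------

balanced_class_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  setNames(as.numeric(w), names(tab))
}

fit_linear_svm <- function(x, y) {
  e1071::svm(x = x, y = y, kernel = "linear", scale = FALSE, cost = 1,
             class.weights = balanced_class_weights(y))
}

#' Weighted F1 score
#'
#' Per-class F1 averaged with weights proportional to the true class
#' support (classes with undefined precision or recall contribute 0).
#'
#' @param truth,pred Factors with the same levels.
#' @return Weighted-average F1 in `[0, 1]`.
#' @export
weighted_f1 <- function(truth, pred) {
  truth <- factor(truth)
  pred <- factor(pred, levels = levels(truth))
  f1 <- vapply(levels(truth), function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp == 0) return(0)
    p <- tp / (tp + fp)
    r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  support <- as.numeric(table(truth))
  sum(f1 * support) / sum(support)
}

loo_f1 <- function(x, y) {
  n <- nrow(x)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (i in seq_len(n)) {
    fit <- fit_linear_svm(x[-i, , drop = FALSE], droplevels(y[-i]))
    pred[i] <- as.character(predict(fit, x[i, , drop = FALSE]))
  }
  weighted_f1(y, pred)
}

#' Percept classifier with leave-one-out evaluation
#'
#' Fits a linear maximum-margin classifier (SVM, balanced class weights) to
#' per-stimulus normalized glomerular response vectors labelled weak/strong,
#' reports the leave-one-out weighted F1, and attributes per-glomerulus
#' importance as absolute coefficients normalized to the largest. Optionally
#' refits on the top-k glomeruli only.
#'
#' @param x Numeric matrix, stimuli (rows) x glomeruli (columns).
#' @param labels Factor or character with two classes (`weak`/`strong`);
#'   rows with NA labels are dropped.
#' @param subset Optional column indices/names to restrict the features.
#' @param top_k Optional integer vector; for each k the classifier is refit
#'   using only the k highest-weight glomeruli and re-evaluated.
#' @return List of class `classifier_report`: `f1` (LOO weighted F1),
#'   `weights` (normalized absolute weights, max = 1), `raw_weights`,
#'   `top_k` (named numeric of top-k F1 scores), `n_stimuli`.
#' @export
fit_percept_classifier <- function(x, labels, subset = NULL, top_k = NULL) {
  x <- as.matrix(x)
  keep <- !is.na(labels)
  x <- x[keep, , drop = FALSE]
  y <- droplevels(factor(labels[keep]))
  if (nlevels(y) < 2) stop("need two percept classes to fit a classifier")
  if (min(table(y)) < 2) stop("need >= 2 stimuli per class")
  if (!is.null(subset)) x <- x[, subset, drop = FALSE]
  fit <- fit_linear_svm(x, y)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  names(w) <- colnames(x)
  aw <- abs(w)
  weights <- if (max(aw) > 0) aw / max(aw) else aw
  f1 <- loo_f1(x, y)
  topk_scores <- NULL
  if (!is.null(top_k)) {
    ord <- order(aw, decreasing = TRUE)
    topk_scores <- vapply(top_k, function(k) {
      loo_f1(x[, ord[seq_len(min(k, ncol(x)))], drop = FALSE], y)
    }, numeric(1))
    names(topk_scores) <- paste0("top", top_k)
  }
  structure(list(f1 = f1, weights = weights, raw_weights = w,
                 top_k = topk_scores, n_stimuli = nrow(x), labels = y),
            class = "classifier_report")
}

#' Label-permutation chance level
#'
#' Leave-one-out weighted F1 under shuffled percept labels, the chance
#' baseline for [fit_percept_classifier()].
#'
#' @inheritParams fit_percept_classifier
#' @param n_shuffles Number of label permutations.
#' @return List with `mean_f1` and the per-shuffle `f1` vector. Uses R's
#'   RNG; seed with [set.seed()].
#' @export
permutation_f1 <- function(x, labels, n_shuffles = 100) {
  x <- as.matrix(x)
  keep <- !is.na(labels)
  x <- x[keep, , drop = FALSE]
  y <- droplevels(factor(labels[keep]))
  f1 <- vapply(seq_len(n_shuffles), function(i) {
    ys <- sample(y)
    if (min(table(ys)) < 2) return(NA_real_)
    loo_f1(x, ys)
  }, numeric(1))
  list(mean_f1 = mean(f1, na.rm = TRUE), f1 = f1)
}

# ---- activation ranking -----------------------------------------------------

#' Activation-time ranking of glomeruli
#'
#' For one trial, finds each glomerulus' first frame during the stimulus
#' with a frame-wise SNR of at least `threshold` (frame amplitude minus
#' baseline mean, over baseline SD), and ranks responsive glomeruli by that
#' activation time (rank 1 = earliest). Ties are broken by the larger dF/F
#' at the tied frame, then by glomerulus id.
#'
#' @param traces Named list of dF/F traces (one per glomerulus), all on the
#'   same time base.
#' @param t_s Frame time stamps (s).
#' @param stim_window Length-2 numeric, stimulus onset/offset (s).
#' @param pre_s Baseline window (s).
#' @param threshold Frame SNR threshold (inclusive).
#' @return Data frame with `glomerulus`, `first_s` (activation time, NA if
#'   never active) and `rank` (NA for inactive glomeruli; ranks form a
#'   permutation of 1..n_active).
#' @export
rank_activation <- function(traces, t_s, stim_window, pre_s = 3, threshold = 5) {
  pre <- t_s >= stim_window[1] - pre_s & t_s < stim_window[1]
  stim_idx <- which(t_s >= stim_window[1] & t_s <= stim_window[2])
  if (!any(pre) || !length(stim_idx)) stop("trace does not cover pre and stimulus windows")
  ids <- names(traces)
  if (is.null(ids)) ids <- as.character(seq_along(traces))
  first_s <- first_amp <- rep(NA_real_, length(traces))
  for (g in seq_along(traces)) {
    x <- traces[[g]]
    mu <- mean(x[pre]); s <- sd(x[pre])
    if (!is.finite(s) || s == 0) next
    z <- (x[stim_idx] - mu) / s
    hit <- which(z >= threshold)
    if (length(hit)) {
      first_s[g] <- t_s[stim_idx[hit[1]]]
      first_amp[g] <- x[stim_idx[hit[1]]]
    }
  }
  active <- which(!is.na(first_s))
  rank_out <- rep(NA_real_, length(traces))
  if (length(active)) {
    ord <- active[order(first_s[active], -first_amp[active], active)]
    rank_out[ord] <- seq_along(ord)
  }
  data.frame(glomerulus = ids, first_s = first_s, rank = rank_out,
             stringsAsFactors = FALSE)
}

#' Mean activation rank across repeats
#'
#' @param ranks Numeric vector of per-trial ranks for one glomerulus (NAs
#'   dropped).
#' @return Arithmetic mean rank.
#' @export
mean_rank <- function(ranks) mean(ranks[!is.na(ranks)])

# ---- breathing-artifact exclusion -------------------------------------------

#' Flag irregular-breathing trials
#'
#' A trial is excluded when a coherent drop in activity appears across the
#' glomeruli: more than `frac` of them simultaneously show dF/F below
#' `-z * baseline SD` for at least `min_dur_s`.
#'
#' @param traces Named list of dF/F traces for one trial (one per
#'   glomerulus), common time base.
#' @param t_s Frame time stamps (s).
#' @param onset_s Odor onset (s); the baseline SD is estimated from the
#'   `pre_s` seconds before it.
#' @param pre_s Baseline window (s).
#' @param z Drop threshold in baseline SDs (default 2).
#' @param frac Fraction of glomeruli that must drop together (default 0.8).
#' @param min_dur_s Minimum duration of the coherent drop (s).
#' @return Logical: `TRUE` if the trial should be excluded.
#' @export
breathing_artifact <- function(traces, t_s, onset_s, pre_s = 3, z = 2,
                               frac = 0.8, min_dur_s = 0.5) {
  pre <- t_s >= onset_s - pre_s & t_s < onset_s
  if (!any(pre)) stop("no baseline frames before onset")
  below <- vapply(traces, function(x) {
    s <- sd(x[pre])
    if (!is.finite(s) || s == 0) s <- 1e-12
    x < -z * s
  }, logical(length(t_s)))
  coherent <- rowMeans(below) > frac
  if (!any(coherent)) return(FALSE)
  r <- rle(coherent)
  dt <- median(diff(t_s))
  any(r$values & r$lengths * dt >= min_dur_s)
}
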
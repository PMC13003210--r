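# Shared fixtures (built in code) and independent brute-force oracles.

# Breath plan with lognormal timing jitter around a target rate.
jittered_plan <- function(rr_bpm, duration_s, ti_ibi = 0.45,
                          jitter_cv = 0.03, noise_sd = 0.002,
                          seed = 1L, ...) {
  ibi <- 60 / rr_bpm
  nb <- ceiling(duration_s / ibi) + 2
  set.seed(seed)
  breath_plan(ti = ti_ibi * ibi * exp(stats::rnorm(nb, 0, jitter_cv)),
              te = (1 - ti_ibi) * ibi * exp(stats::rnorm(nb, 0, jitter_cv)),
              noise_sd = noise_sd, seed = seed, ...)
}

# Run the IP branch of the pipeline on a trace (detection through the
# timing-outlier filter), with the per-recording band-edge rule.
run_ip_branch <- function(trace, bp_hi = NULL) {
  tr <- resample_to_100hz(trace)
  tr <- remove_amplitude_artifacts(tr)
  if (is.null(bp_hi)) bp_hi <- dominant_freq_bp_rule(list(bioz = trace))
  ipf <- bandpass_ip(tr, 0.1, bp_hi)
  seg <- detect_breaths(ipf, raw = tr)
  seg <- assess_signal_quality(ipf, seg)
  feats <- extract_timing_features(seg)
  remove_timing_outliers(feats)
}

# Match emitted breaths to ground-truth rows by nearest inspiration
# onset.
match_truth <- function(feats, truth) {
  idx <- vapply(feats$insp_onset,
                function(t) which.min(abs(truth$insp_onset - t)), 0L)
  truth[idx, , drop = FALSE]
}

# --- exact-test oracles (independent enumeration) ---------------------

# Two-sided exact Wilcoxon signed-rank p-value and statistic by
# enumerating all 2^n sign assignments (requires no zeros/ties).
signed_rank_oracle <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  list(W = v_obs, p = min(1, p))
}

# Two-sided exact rank-sum p-value by enumerating all group
# arrangements; W is the rank sum of the first group.
rank_sum_oracle <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(r), n1)
  w_all <- colSums(matrix(seq_along(r)[combos], nrow = n1))
  # ranks of pooled sorted values are 1..N, so rank-sum enumeration is
  # over subsets of 1..N
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  list(W = w_obs, p = min(1, p))
}
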
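# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Literal rule table for the sensory taxonomy: the three single-modality
# closure patterns are written out in full.
closure_sound <- c("sound", "sound+light", "sound+whisker",
                   "sound+light+whisker")
closure_light <- c("light", "sound+light", "light+whisker",
                   "sound+light+whisker")
closure_whisker <- c("whisker", "sound+whisker", "light+whisker",
                     "sound+light+whisker")
unimodal_types <- c("sound", "light", "whisker")
multimodal_types <- c("sound+light", "sound+whisker", "light+whisker",
                      "sound+light+whisker")

taxonomy_oracle <- function(pattern) {
  pattern <- setdiff(pattern, "blank")
  if (length(pattern) == 0) {
    return(list(sensory_class = "non_responsive", modal_category = "none"))
  }
  uni <- setequal(pattern, closure_sound) ||
    setequal(pattern, closure_light) ||
    setequal(pattern, closure_whisker)
  all_multi <- all(pattern %in% multimodal_types)
  all_uni <- all(pattern %in% unimodal_types)
  list(
    sensory_class = if (uni) "unisensory" else "multisensory",
    modal_category = if (all_multi) "exclusively_multimodal"
                     else if (all_uni) "exclusively_unimodal" else "mixed"
  )
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mw_enumeration_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combos <- utils::combn(length(pooled), n)
  us <- apply(combos, 2, function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  })
  mu <- length(x) * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Step-by-step EMA recursion, written independently of ema_performance().
ema_oracle <- function(x, tau = 12, init = 0.5) {
  k <- 1 - exp(-1 / tau)
  e <- init
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    e <- (1 - k) * e + k * x[i]
    out[i] <- e
  }
  out
}

# Kruskal-Wallis H from first-principles rank arithmetic (no ties assumed).
kruskal_oracle_h <- function(groups) {
  all_v <- unlist(groups)
  r <- rank(all_v)
  n <- length(all_v)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 0
  for (g in seq_along(groups)) {
    rg <- sum(r[idx == g])
    h <- h + rg^2 / sum(idx == g)
  }
  12 / (n * (n + 1)) * h - 3 * (n + 1)
}

# A hand-built single-axon recording: transients of given amplitude at the
# listed onsets on top of seeded Gaussian noise.
make_trace <- function(onsets, n_frames, rate = 30, amplitude = 0.5,
                       decay = 0.5, baseline = 1, noise_sd = 0, seed = 1) {
  set.seed(seed)
  t_f <- (seq_len(n_frames) - 1) / rate
  tr <- baseline + rnorm(n_frames, 0, noise_sd)
  for (t0 in onsets) {
    idx <- t_f >= t0
    tr[idx] <- tr[idx] + amplitude * exp(-(t_f[idx] - t0) / decay)
  }
  tr
}

# Minimal schedule builder for hand-constructed imaging fixtures.
manual_schedule <- function(types, onsets, duration = 0.5) {
  sensint:::new_stimulus_schedule(data.frame(
    trial_index = seq_along(types), trial_type = types,
    onset_s = onsets, duration_s = rep(duration, length.out = length(types))
  ))
}

# Sweep fixture: deterministic baseline noise plus a square deflection.
deflection_sweeps <- function(n_trials = 10, rate = 10000, dur = 0.12,
                              onset = 0.05, offset = 0.054,
                              defl_start_s = NULL, defl_len_s = 0.002,
                              defl_amp = 0, noise_sd = 0.1, seed = 1,
                              clamp = "current") {
  set.seed(seed)
  n <- round(dur * rate)
  m <- matrix(rnorm(n_trials * n, 0, noise_sd), nrow = n_trials)
  if (!is.null(defl_start_s)) {
    t_s <- (seq_len(n) - 1) / rate
    idx <- t_s >= defl_start_s & t_s < defl_start_s + defl_len_s
    m[, idx] <- m[, idx] + defl_amp
  }
  sweep_set(m, rate = rate, clamp_mode = clamp, stim_onset = onset,
            stim_offset = offset)
}
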
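# Shared fixtures, built once per test run. Everything is generated in
# code (no stored data files); seeds are fixed so the suite is
# deterministic.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# 30 beats per class at 125 Hz, normalized — small general-purpose dataset
fix_dataset <- function() fixture("dataset", function() {
  generate_dataset(30, rng_seed = 101)
})

# default full model with fixed weights
fix_model <- function() fixture("model", function() {
  hctg_model(model_config(), seed = 7)
})

# 60 s synthetic record at 360 Hz, all-normal beats, mild noise
fix_record_n <- function() fixture("record_n", function() {
  generate_record(70, class_probs = c(1, 0, 0, 0, 0), fs = 360,
                  noise = noise_model(baseline_wander_amplitude = 0.05,
                                      baseline_wander_freq = 0.3,
                                      hf_noise_sd = 0.02, seed = 5),
                  rng_seed = 31, record_id = "fixn")
})

# brute-force scaled dot-product attention: explicit loops, no shortcuts
attention_oracle <- function(Q, K, V) {
  n <- nrow(Q); dk <- ncol(K)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) {
      s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    }
    w <- exp(s - max(s)); w <- w / sum(w)
    for (m in seq_len(ncol(V))) out[i, m] <- sum(w * V[, m])
  }
  out
}

# population standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
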
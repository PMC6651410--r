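# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())
.tiny_cache <- new.env(parent = emptyenv())

# one subject + one normal-speed trial, reused by several files
fixture_trial <- function() {
  if (is.null(.fixtures$trial)) {
    .fixtures$subject <- sample_subject(101)
    .fixtures$trial <- simulate_trial(.fixtures$subject, "normal", seed = 11)
  }
  .fixtures$trial
}

fixture_subject <- function() {
  fixture_trial()
  .fixtures$subject
}

# the desk-scale factorial study (2 models x 3 cutoffs x 3 folds);
# expensive, computed at most once
fixture_factorial <- function() {
  if (is.null(.fixtures$factorial))
    .fixtures$factorial <- run_study(study_config(master_seed = 1))
  .fixtures$factorial
}

# amplitude of a sinusoid at frequency f in series y sampled at rate fs,
# estimated by quadrature projection (robust to peak sampling)
sine_amplitude <- function(y, f, fs) {
  t <- seq_along(y) / fs
  2 * sqrt(mean(y * sin(2 * pi * f * t))^2 + mean(y * cos(2 * pi * f * t))^2)
}

# smooth multi-sine sequences with a running-mean target: a temporal task a
# memoryless map cannot solve
make_running_mean_cycles <- function(n, seed) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    x <- matrix(0, 100, 9)
    for (j in 1:9) {
      f <- runif(1, 0.5, 3); p <- runif(1, 0, 2 * pi)
      x[, j] <- sin(2 * pi * f * (1:100) / 100 + p) * runif(1, 0.3, 1)
    }
    y <- cumsum(x[, 2]) / (1:100)
    list(X = x, Y = cbind(y, 0.5 * y))
  }))
}
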
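# Shared fixtures: tiny pedons built in code, plus an independent
# permutation test used as an oracle for the closure check.

simple_profile <- function(stage = "S0", replicate = "r1", crack = 0,
                           top = c(0, 15), bottom = c(15, 35),
                           soc = c(60, 25), bd = c(0.85, 1.15), ...) {
  h <- data.frame(label = paste0("H", seq_along(top)),
                  top = top, bottom = bottom, soc = soc, bd = bd, ...)
  soil_profile(stage, replicate, h, crack_depth = crack)
}

# ensemble of n identical replicates of one profile spec
simple_ensemble <- function(stage, n = 2, ...) {
  stage_ensemble(lapply(seq_len(n), function(i) {
    simple_profile(stage = stage, replicate = paste0("r", i), ...)
  }))
}

# two-sided permutation test on the difference in means (independent
# oracle for the Welch-based closure check)
perm_test_p <- function(x, y, n_perm = 599) {
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  n <- length(x)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(length(pool), n)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12) {
      hits <- hits + 1L
    }
  }
  (hits + 1) / (n_perm + 1)
}
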
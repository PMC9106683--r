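test_that("total_loss subtracts mean stocks and keeps its sign convention", {
  ref <- simple_ensemble("S0", n = 2, top = 0, bottom = 30,
                         soc = 55.667, bd = 1.0)   # ~16.7 kg m-2
  deg <- simple_ensemble("S5", n = 2, crack = 0, top = 0, bottom = 30,
                         soc = 30.667, bd = 1.0)   # ~9.2 kg m-2
  tl <- total_loss(ref, deg, 30)
  expect_equal(tl$mean, 7.5, tolerance = 1e-4)

  expect_equal(total_loss(ref, ref, 30)$mean, 0)

  rich <- simple_ensemble("S1", n = 2, crack = 0, top = 0, bottom = 30,
                          soc = 70, bd = 1.0)
  expect_lt(total_loss(ref, rich, 30)$mean, 0)  # gains stay negative, unclamped
})

test_that("erosion_loss integrates reference content x BD over the crack depth", {
  ref <- simple_ensemble("S0", n = 3, top = 0, bottom = 15, soc = 60, bd = 0.85)
  zero <- erosion_loss(ref, 0)
  expect_equal(zero$mean, 0)
  expect_equal(zero$soil_mass_mean, 0)

  er <- erosion_loss(ref, 10)
  expect_equal(er$mean, 5.1)           # 60 * 0.85 * 10 * 1e-2
  expect_equal(er$soil_mass_mean, 85)  # 0.85 * 10 * 10 kg m-2

  expect_error(erosion_loss(ref, 20), "exceeds", class = "data_error")
})

test_that("erosion_loss is continuous and non-decreasing in crack depth", {
  sim <- generate_sequence(sequence_scenario(noise_cv = 0, replicates = 2))
  ref <- sim$ensembles$S0
  depths <- seq(0, 30, by = 0.25)
  losses <- vapply(depths, function(e) erosion_loss(ref, e)$mean, numeric(1))
  expect_true(all(diff(losses) >= -1e-12))
  expect_true(max(abs(diff(losses))) < 0.35)  # no jumps at horizon boundaries
})

test_that("mineralization_loss compares degraded content x BD over reference thickness", {
  ref <- simple_ensemble("S0", n = 2, top = 0, bottom = 10, soc = 60, bd = 0.8)
  same <- simple_ensemble("S1", n = 2, crack = 0, top = 0, bottom = 10,
                          soc = 60, bd = 0.8)
  expect_equal(mineralization_loss(ref, same, 10, crack_depth = 0)$mean, 0)

  deg <- simple_ensemble("S1", n = 2, crack = 0, top = 0, bottom = 10,
                         soc = 45, bd = 0.8)
  expect_equal(mineralization_loss(ref, deg, 10, crack_depth = 0)$mean, 1.2)
})

test_that("percent_loss references the mean reference stock", {
  ref <- simple_ensemble("S0", n = 2, top = 0, bottom = 30,
                         soc = 55.555, bd = 1.0)  # 16.6665 kg m-2
  expect_equal(percent_loss(0, ref, 30), 0)
  expect_equal(percent_loss(7.5, ref, 30), 45.0, tolerance = 1e-3)
  ref_stock <- 55.555 * 1.0 * 30 * 1e-2
  expect_equal(percent_loss(ref_stock, ref, 30), 100)
})

test_that("closure_check handles degenerate and clearly-open cases", {
  x <- c(5, 5, 5, 5)
  cl <- closure_check(x, x)
  expect_equal(cl$p, 1)
  expect_true(cl$ns)

  set.seed(5)
  a <- rnorm(6, 10, 0.5)
  b <- rnorm(6, 10 + 10 * 0.5, 0.5)  # offset by 10 SD
  cl2 <- closure_check(a, b)
  expect_false(cl2$ns)

  expect_error(closure_check(1, c(1, 2)), "insufficient replication",
               class = "data_error")
})

test_that("Welch closure decisions agree with a permutation oracle", {
  set.seed(99)
  agree <- 0L; n_cases <- 60L
  for (case in seq_len(n_cases)) {
    n <- sample(4:8, 1)
    shift <- sample(c(0, 0, 2, 4), 1)  # null and alternative cases
    x <- rnorm(n, 10, 1)
    y <- rnorm(n, 10 + shift, 1)
    welch_ns <- closure_check(x, y, alpha = 0.05)$ns
    perm_ns <- perm_test_p(x, y) >= 0.05
    if (welch_ns == perm_ns) agree <- agree + 1L
  }
  expect_gte(agree / n_cases, 0.95)
})

test_that("partition closes exactly on noiseless sequences and recovers truth", {
  for (seed in 1:25) {
    sim <- generate_sequence(random_scenario(seed))
    pr <- suppressWarnings(partition_sequence(sim$ensembles))
    gap <- pr$total_loss_ref_frame - pr$erosion_loss - pr$mineralization_loss
    expect_lt(max(abs(gap)), 1e-10)
    expect_equal(pr$erosion_loss, sim$truth$erosion_loss, tolerance = 1e-10)
    expect_equal(pr$mineralization_loss, sim$truth$mineralization_loss,
                 tolerance = 1e-10)
    expect_true(all(pr$closure_ns))
  }
})

test_that("single-process scenarios isolate their loss component", {
  # erosion only: all mineralization factors 1
  ero_only <- sequence_scenario(mineralization_factors = matrix(1, 5, 4),
                                noise_cv = 0, replicates = 2)
  pr <- partition_sequence(generate_sequence(ero_only)$ensembles)
  expect_equal(pr$mineralization_loss, rep(0, 5), tolerance = 1e-12)

  # mineralization only: crack depths 0
  min_only <- sequence_scenario(
    erosion_depths = c(S1 = 0, S2 = 0, S3 = 0, S4 = 0, S5 = 0),
    noise_cv = 0, replicates = 2)
  pr2 <- partition_sequence(generate_sequence(min_only)$ensembles)
  expect_identical(pr2$erosion_loss, rep(0, 5))
  expect_identical(pr2$eroded_soil_mass, rep(0, 5))
})

test_that("partition_sequence demands a reference stage", {
  sim <- generate_sequence(sequence_scenario(noise_cv = 0, replicates = 2))
  expect_error(partition_sequence(sim$ensembles[c("S1", "S5")]),
               "no reference stage", class = "data_error")
})
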
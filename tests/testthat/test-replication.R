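test_that("average copy number follows the dosage law and its edge cases", {
  expect_equal(average_copy_number(replication_params(40, 0, 40), 1), 1.0)
  expect_equal(average_copy_number(replication_params(40, 20, 60), 0), 2.0)
  expect_equal(average_copy_number(replication_params(40, 20, 60), 1), 2^(1 / 3))
  # monotone decreasing in p and in tau; always >= 1
  p <- seq(0, 1, by = 0.05)
  for (tau in c(20, 45, 120)) {
    n <- average_copy_number(replication_params(40, 20, tau), p)
    expect_true(all(diff(n) < 0))
    expect_true(all(n >= 1))
  }
  n_tau <- sapply(c(20, 40, 80), function(tau)
    average_copy_number(replication_params(40, 20, tau), 0.3))
  expect_true(all(diff(n_tau) < 0))
  expect_error(average_copy_number(replication_params(40, 20, 60), 1.2), "0, 1")
  expect_error(replication_params(-1, 0, 10))
})

test_that("log2 PTR equals C/tau and matches the ori:ter copy ratio", {
  expect_equal(log2_ptr(replication_params(40, 20, 40)), 1.0)
  expect_equal(log2_ptr(replication_params(60, 0, 20)), 3.0)
  set.seed(42)
  for (i in 1:20) {
    rp <- replication_params(runif(1, 10, 80), runif(1, 0, 40), runif(1, 15, 150))
    ratio <- average_copy_number(rp, 0) / average_copy_number(rp, 1)
    expect_equal(2^log2_ptr(rp), ratio, tolerance = 1e-12)
  }
})

test_that("growth rate conversion mu = ln2/tau", {
  expect_equal(growth_rate(20), 60 * log(2) / 20)
  expect_equal(growth_rate(40, unit = "per_minute"), log(2) / 40)
})

test_that("instantaneous copy number counts passed replication rounds", {
  expect_identical(instantaneous_copy_number(c(0.9, 0.2), 0.05), 4L)
  expect_identical(instantaneous_copy_number(c(0.9, 0.2), 0.95), 1L)
  expect_identical(instantaneous_copy_number(0.5, 0.05), 2L)
  expect_identical(instantaneous_copy_number(0.5, 0.95), 1L)
  expect_identical(instantaneous_copy_number(numeric(0), 0.5), 1L)
  # R nested rounds give 2^R at ori and 1 near ter
  prog <- c(0.9, 0.6, 0.3)
  expect_identical(instantaneous_copy_number(prog, 0), 8L)
  expect_identical(instantaneous_copy_number(prog, 0.99), 1L)
  expect_error(instantaneous_copy_number(c(0.2, 0.9), 0.5), "decreasing")
  expect_error(instantaneous_copy_number(c(1.2), 0.5), "strictly in")
})

test_that("transcript steady state couples dosage to promoter output", {
  rp <- replication_params(40, 20, 60)
  # f = gamma cancels; output is linear in f
  expect_equal(transcript_steady_state(rp, 0.4, f_y = 3, gamma = 3),
               average_copy_number(rp, 0.4))
  expect_equal(transcript_steady_state(rp, 0.4, f_y = 2, gamma = 1),
               2 * transcript_steady_state(rp, 0.4, f_y = 1, gamma = 1))
  expect_equal(transcript_steady_state(rp, 0, f_y = 2, gamma = 1), 4.0)
  expect_error(transcript_steady_state(rp, 0, f_y = 1, gamma = 0), "gamma")
})

test_that("relative abundance change has the physical sign and is reciprocal", {
  # no change in any driver
  expect_equal(relative_abundance_change(40, 20, 0.5, 60, 60), 1.0)
  # at ter with D = 0 only promoter/degradation terms remain
  expect_equal(relative_abundance_change(40, 0, 1, 60, 30, f0 = 1, fk = 3,
                                         gamma0 = 2, gammak = 1), 6.0)
  # faster growth raises dosage: 2^[60 * (1/30 - 1/60)] = 2
  expect_equal(relative_abundance_change(40, 20, 0, 60, 30), 2.0)
  # equals the explicit copy-number ratio at the two division times
  for (p in c(0, 0.3, 0.8, 1)) {
    r <- relative_abundance_change(40, 20, p, 60, 30)
    expect_equal(r, average_copy_number(replication_params(40, 20, 30), p) /
                    average_copy_number(replication_params(40, 20, 60), p))
  }
  # reciprocity: switching tau0 <-> tauk inverts the fold change
  set.seed(7)
  for (i in 1:10) {
    p <- runif(1); t0 <- runif(1, 20, 120); tk <- runif(1, 20, 120)
    expect_equal(relative_abundance_change(40, 20, p, t0, tk) *
                 relative_abundance_change(40, 20, p, tk, t0), 1.0,
                 tolerance = 1e-12)
  }
})
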
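tiny_dataset <- function() {
  rows <- expand.grid(time_s = c(10, 100), fraction = c("S1", "S2"),
                      position = 1:3, stringsAsFactors = FALSE)
  rows$intensity <- c(
    0, 500,    # pos 1, t 10:  F = 0
    30, 70,    # pos 1, t 100: F = 0.3
    50, 50,    # pos 2, t 10:  F = 0.5
    80, 20,    # pos 2, t 100: F = 0.8
    0, 0,      # pos 3, t 10:  masked (zero total)
    10, 90)    # pos 3, t 100: F = 0.1
  # expand.grid varies time fastest within (fraction, position); rebuild
  # explicitly to keep the mapping obvious
  d <- data.frame(
    time_s = rep(c(10, 100), times = 6),
    fraction = rep(rep(c("S1", "S2"), each = 2), times = 3),
    position = rep(1:3, each = 4),
    intensity = c(0, 30, 500, 70,
                  50, 80, 50, 20,
                  0, 10, 0, 90))
  gel_dataset(d)
}

test_that("fraction_unwound computes the band-ratio F and masks empties", {
  suppressMessages(traces <- fraction_unwound(tiny_dataset()))
  expect_equal(traces[["1"]]$F, c(0, 0.3))
  expect_equal(traces[["2"]]$F, c(0.5, 0.8))
  expect_true(traces[["3"]]$masked[1])
  expect_identical(traces[["3"]]$F[1], NA_real_)   # masked, not zeroed
  expect_equal(traces[["3"]]$F[2], 0.1)
  # zero-total masking announces itself
  expect_message(fraction_unwound(tiny_dataset()), "masked")
  # floor-based masking
  suppressMessages(tr_fl <- fraction_unwound(tiny_dataset(), floor = 120))
  expect_false(tr_fl[["1"]]$masked[1])  # total 500 > 120
  expect_true(tr_fl[["1"]]$masked[2])   # total 100 <= 120
  expect_true(all(tr_fl[["2"]]$masked)) # both totals 100
  # window restriction errors on absent positions
  expect_error(suppressMessages(fraction_unwound(tiny_dataset(),
                                                 positions = 2:5)),
               "absent")
})

test_that("fit_single_exponential recovers noiseless parameters exactly", {
  t <- c(5, 15, 30, 60, 120, 240)
  y <- 0.8 * (1 - exp(-0.05 * t))
  fit <- fit_single_exponential(kinetic_trace(7L, t, y))
  expect_true(fit$converged)
  expect_false(fit$low_confidence)
  expect_equal(fit$A, 0.8, tolerance = 1e-6)
  expect_equal(fit$k, 0.05, tolerance = 1e-6)
})

test_that("degenerate and under-sampled traces are flagged, not NaN", {
  z <- fit_single_exponential(kinetic_trace(1L, c(1, 2, 3, 4), rep(0, 4)))
  expect_false(z$converged)
  expect_true(z$low_confidence)
  expect_identical(z$A, 0)
  expect_true(is.na(z$k))
  # three points: fit attempted but flagged low confidence
  t3 <- c(10, 50, 200)
  f3 <- fit_single_exponential(kinetic_trace(1L, t3,
                                             0.5 * (1 - exp(-0.02 * t3))))
  expect_true(f3$low_confidence)
  # sampling that never reaches the plateau is flagged
  tr <- kinetic_trace(1L, c(2, 4, 6, 8), 0.9 * (1 - exp(-0.01 * c(2, 4, 6, 8))))
  expect_true(fit_single_exponential(tr)$low_confidence)
})

test_that("the fitted rate matches k_act for an activation-limited chain", {
  sch <- uniform_rate_scheme(20, k_act = 0.02, k_U = 50, k_D = 0)
  times <- c(5, 10, 20, 40, 80, 150, 250, 400)
  cv <- simulate_progress(sch, times)
  fit <- fit_single_exponential(kinetic_trace(1L, cv$times,
                                              cv$fraction_unwound))
  expect_lt(abs(fit$k - 0.02) / 0.02, 0.05)
  expect_equal(fit$A, total_amplitude(sch), tolerance = 0.01)
})

test_that("detect_lag distinguishes single-step from two-slow-step chains", {
  times <- c(5, 10, 20, 40, 60, 90, 130, 180, 250, 350, 500, 700)
  # pure single exponential: no lag
  y1 <- 0.7 * (1 - exp(-0.02 * times))
  expect_identical(detect_lag(kinetic_trace(1L, times, y1))$preferred,
                   "no_lag")
  # activation and one unwinding step comparably slow: a real lag phase
  sch <- rate_scheme(0.02, k_U = c(rep(50, 10), 0.02, rep(50, 9)), k_D = 0)
  cv <- simulate_progress(sch, times)
  lt <- detect_lag(kinetic_trace(1L, cv$times, cv$fraction_unwound))
  expect_identical(lt$preferred, "lag")
  expect_lt(lt$delta_aic, 0)
  # constant-zero trace: undecidable
  expect_identical(detect_lag(kinetic_trace(1L, times,
                                            rep(0, length(times))))$preferred,
                   "undecidable")
})

test_that("control_statistics summarizes replicate dispersion", {
  mk <- function(A, k) trnaip:::new_exp_fit(0L, A, k, 0.01, 0.001, 0,
                                            n = 12, converged = TRUE,
                                            low_confidence = FALSE)
  same <- control_statistics(list(mk(0.8, 0.01), mk(0.8, 0.01)))
  expect_identical(same$A_sd, 0)
  two <- control_statistics(list(mk(0.8, 0.01), mk(0.9, 0.02)))
  expect_equal(two$A_mean, 0.85)
  expect_equal(two$k_mean, 0.015)
  expect_identical(two$n_replicates, 2L)
  expect_error(control_statistics(list(mk(0.8, 0.01))), "at least 2")
})

test_that("12 simulated controls disperse as the noise model predicts", {
  sch <- uniform_rate_scheme(40)
  spec <- library_spec(40, n_molecules = 5e4)
  times <- default_times
  truth <- simulate_progress(sch, times)$fraction_unwound
  # Monte-Carlo oracle: apply the band observation model directly to the
  # true curve, fit, and measure the dispersion of the amplitude
  set.seed(321)
  oracle_A <- replicate(300, {
    f <- oracle_noisy_trace(times, truth, band_cv = 0.10)
    fit_single_exponential(kinetic_trace(0L, times, f))$A
  })
  ctl <- simulate_control_replicates(spec, sch, times, n_replicates = 12,
                                     seed = 77)
  cs <- control_statistics(lapply(ctl, fit_single_exponential))
  # a 12-sample SD is itself noisy (~21% SE), so compare within 50%
  expect_gt(cs$A_sd, 0.5 * sd(oracle_A))
  expect_lt(cs$A_sd, 1.5 * sd(oracle_A))
})

test_that("classify_positions applies the SD-band rules", {
  mk <- function(pos, A, k) trnaip:::new_exp_fit(pos, A, k, 0.01, 0.001, 0,
                                                 n = 12, converged = TRUE,
                                                 low_confidence = FALSE)
  control <- structure(list(A_mean = 0.5, A_sd = 0.02, k_mean = 0.01,
                            k_sd = 0.001, n_replicates = 12L),
                       class = "control_stats")
  fits <- list(mk(1L, 0.5, 0.01),              # at the control mean
               mk(2L, 0.5 - 3 * 0.02, 0.01),   # amplitude z = -3
               mk(3L, 0.5 + 3 * 0.02, 0.01),   # amplitude z = +3
               mk(4L, 0.5 - 1.5 * 0.02, 0.01)) # amplitude z = -1.5
  prof <- classify_positions(fits, control)
  expect_identical(prof$class,
                   c("indistinguishable", "detrimental", "favorable",
                     "slight"))
  expect_identical(prof$A_within_1sd, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(prof$A_within_2.5sd, c(TRUE, FALSE, FALSE, TRUE))
  expect_true(all(prof$k_within_1sd))
  # zero control SD is a hard error
  degenerate <- structure(list(A_mean = 0.5, A_sd = 0, k_mean = 0.01,
                               k_sd = 0.001, n_replicates = 12L),
                          class = "control_stats")
  expect_error(classify_positions(fits, degenerate), "SD")
})

test_that("the 2.5-SD rule has its nominal false-positive rate", {
  # classification-rule calibration: standard-normal nulls in, ~1.2% of
  # |z| > 2.5 flags out (the 98.8% interval's complement)
  set.seed(1234)
  n <- 2e4
  control <- structure(list(A_mean = 0.5, A_sd = 0.02, k_mean = 0.01,
                            k_sd = 0.001, n_replicates = 12L),
                       class = "control_stats")
  fits <- lapply(seq_len(n), function(i)
    trnaip:::new_exp_fit(i, 0.5 + 0.02 * rnorm(1), 0.01, 0.01, 0.001, 0,
                         n = 12, converged = TRUE, low_confidence = FALSE))
  prof <- classify_positions(fits, control)
  nominal <- 2 * (1 - pnorm(2.5))             # 0.01242
  expect_equal(mean(prof$A_outside), nominal,
               tolerance = 3 * sqrt(nominal / n) / nominal)
})

test_that("planted (A, k) grids are recovered with small median bias", {
  times <- default_times
  set.seed(555)
  for (A in c(0.3, 0.6, 0.9)) {
    for (k in c(0.005, 0.01, 0.02)) {
      rel_A <- rel_k <- numeric(20)
      for (r in 1:20) {
        f_true <- A * (1 - exp(-k * times))
        f_obs <- oracle_noisy_trace(times, f_true, band_cv = 0.10)
        fit <- fit_single_exponential(kinetic_trace(0L, times, f_obs))
        rel_A[r] <- (fit$A - A) / A
        rel_k[r] <- (fit$k - k) / k
      }
      expect_lt(abs(median(rel_A)), 0.05)
      expect_lt(abs(median(rel_k)), 0.05)
    }
  }
})
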
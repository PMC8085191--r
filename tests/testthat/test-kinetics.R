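test_that("the default frame schedule has 32 contiguous frames over 90 min", {
  fs <- frame_schedule()
  expect_equal(nrow(fs), 32)
  expect_equal(max(fs$end_s), 5400)
  expect_equal(fs$start_s[-1], fs$end_s[-32])
  expect_equal(as.vector(table(fs$end_s - fs$start_s)[
    as.character(c(10, 30, 60, 120, 240, 300))]), c(6, 4, 3, 2, 5, 12))
})

test_that("2TC simulation matches an independent ODE solver", {
  cp <- ref_cp()
  wb <- ref_wb()
  pars <- twotc_params(0.13, 0.065, 0.05, 0.05, vB = 0.05)
  tac <- simulate_2tc(cp, pars, whole_blood = wb)
  g <- (0:5400) / 60
  cpf <- stats::approxfun(g, cp$activity, rule = 2)
  rhs <- function(t, y, p) {
    list(c(p$K1 * cpf(t) - (p$k2 + p$k3) * y[1] + p$k4 * y[2],
           p$k3 * y[1] - p$k4 * y[2]))
  }
  sol <- deSolve::ode(c(0, 0), g, rhs, pars, rtol = 1e-10, atol = 1e-12)
  meas <- (1 - pars$vB) * rowSums(sol[, 2:3]) + pars$vB * wb$activity
  fs <- frame_schedule()
  frame_avg <- vapply(seq_len(32), function(i) {
    idx <- (fs$start_s[i]:fs$end_s[i]) + 1L
    pracma::trapz(fs$start_s[i]:fs$end_s[i], meas[idx]) /
      (fs$end_s[i] - fs$start_s[i])
  }, numeric(1))
  expect_equal(tac$activity_kBq_mL, frame_avg, tolerance = 1e-6)
})

test_that("2TC degenerates correctly: zero input, 1TC limit, equilibrium ratio", {
  zero_cp <- new_input_function(rep(0, 5401))
  # zero input cannot feed new_input_function peak logic; bypass via direct sim
  pars <- twotc_params(0.1, 0.05, 0.05, 0.05)
  expect_equal(simulate_2tc(zero_cp, pars)$activity_kBq_mL, rep(0, 32))
  # k3 -> 0 limit vs closed-form 1TC response to a step input:
  # C1(t) = (K1/k2)(1 - exp(-k2 t)) for Cp = 1
  step_cp <- new_input_function(c(0, rep(1, 5400)))
  p1 <- twotc_params(0.5, 0.1, 1e-10, 1, vB = 0)
  tac1 <- simulate_2tc(step_cp, p1)
  fs <- frame_schedule()
  closed <- function(t) (0.5 / 0.1) * (1 - exp(-0.1 * t))
  closed_avg <- vapply(seq_len(32), function(i) {
    a <- fs$start_s[i] / 60
    b <- fs$end_s[i] / 60
    (0.5 / 0.1) * (1 - (exp(-0.1 * a) - exp(-0.1 * b)) / (0.1 * (b - a)))
  }, numeric(1))
  expect_equal(tac1$activity_kBq_mL, closed_avg, tolerance = 1e-3)
  # long-time tissue:plasma ratio approaches VT for a sustained input
  p2 <- twotc_params(0.5, 0.5, 0.2, 0.5, vB = 0)
  tac2 <- simulate_2tc(step_cp, p2)
  expect_equal(tac2$activity_kBq_mL[32], true_vt(p2), tolerance = 1e-3)
})

test_that("blood-volume correction inverts the simulator's composition", {
  cp <- ref_cp()
  wb <- ref_wb()
  pars <- twotc_params(0.13, 0.065, 0.05, 0.05, vB = 0.05)
  tac <- simulate_2tc(cp, pars, whole_blood = wb)
  pure <- simulate_2tc(cp, twotc_params(0.13, 0.065, 0.05, 0.05, vB = 1e-12),
                       whole_blood = wb)
  corrected <- blood_volume_correct(tac, wb, vB = 0.05)
  expect_equal(corrected$activity_kBq_mL, pure$activity_kBq_mL,
               tolerance = 1e-6)
  # vB = 0 is the identity
  expect_equal(blood_volume_correct(tac, wb, vB = 0)$activity_kBq_mL,
               tac$activity_kBq_mL)
  # negative intermediates are clipped with a warning
  tiny <- tac
  tiny$activity_kBq_mL <- rep(0, 32)
  expect_warning(out <- blood_volume_correct(tiny, wb, vB = 0.05),
                 "clipped")
  expect_true(all(out$activity_kBq_mL >= 0))
  expect_error(blood_volume_correct(tac, wb, vB = 1), "vB")
})

test_that("Logan coordinates behave like the graphical transform", {
  cp <- ref_cp()
  fs <- frame_schedule()
  # identity tracer: tissue == plasma gives slope 1 (quadrature-limited)
  tid <- tibble::tibble(mid_min = fs$mid_min,
                        activity_kBq_mL = if_at(cp, fs$mid_min))
  pts <- logan_points(tid, cp)
  expect_true(all(diff(pts$x) > 0))
  fit <- fit_logan(pts, find_tstar(pts))
  expect_equal(fit$VT, 1, tolerance = 1e-2)
  # 1TC kinetics: slope recovers K1/k2 = 5 within 1%
  p1 <- twotc_params(0.5, 0.1, 1e-10, 1, vB = 0)
  tac1 <- simulate_2tc(cp, p1)
  pts1 <- logan_points(tac1, cp)
  fit1 <- fit_logan(pts1, find_tstar(pts1))
  expect_equal(fit1$VT, 5, tolerance = 0.01)
  # scaling the plasma curve by c scales VT by 1/c
  cp2 <- new_input_function(2 * cp$activity)
  pts2 <- logan_points(tac1, cp2)
  fit2 <- fit_logan(pts2, find_tstar(pts2))
  expect_equal(fit2$VT, fit1$VT / 2, tolerance = 1e-9)
})

test_that("Logan slope underestimates VT for slowly equilibrating kinetics", {
  # reversible kinetics with a slow eigenrate never reach the asymptote in a
  # 90-min scan: the estimate sits below truth, and the deficit shrinks as
  # clearance from the second compartment speeds up
  cp <- ref_cp()
  wb <- ref_wb()
  bias <- vapply(c(0.015, 0.03, 0.05), function(k4) {
    pars <- twotc_params(0.1, 0.05, 0.03 * k4 / 0.015, k4, vB = 0.05)
    tac <- simulate_2tc(cp, pars, whole_blood = wb)
    fit <- logan_vt(tac, cp, wb, vB = 0.05)
    (fit$VT - true_vt(pars)) / true_vt(pars)
  }, numeric(1))
  expect_true(all(bias < 0))
  expect_true(all(diff(bias) > 0))       # faster k4, smaller deficit
  expect_lt(abs(bias[3]), 0.02)
})

test_that("exact linear Logan points give an exact fit with diagnostics", {
  x <- seq(10, 60, by = 5)
  pts <- tibble::tibble(t_min = x, x = x, y = 5 * x + 1)
  ts <- find_tstar(pts)
  expect_equal(ts$index, 1)
  expect_false(ts$fallback)
  fit <- fit_logan(pts, ts)
  expect_equal(fit$VT, 5, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$R2, 1, tolerance = 1e-12)
  expect_equal(fit$pct_SE, 0, tolerance = 1e-4)
  expect_equal(fit$n_points, length(x))
  expect_error(fit_logan(pts[1:2, ], 1), "at least 3")
  flat <- tibble::tibble(t_min = 1:3, x = rep(1, 3), y = 1:3)
  expect_error(fit_logan(flat, 1), "degenerate")
})

test_that("t* search matches brute-force enumeration on random point sets", {
  # independent oracle: lm-based enumeration of every start index
  brute <- function(pts, thr) {
    n <- nrow(pts)
    for (s in seq_len(n - 2)) {
      f <- lm(y ~ x, data = pts[s:n, ])
      if (max(abs(residuals(f)) / abs(fitted(f))) <= thr) return(s)
    }
    n - 2L
  }
  withr::with_seed(2024, {
    for (rep in 1:100) {
      n <- sample(10:32, 1)
      x <- sort(runif(n, 1, 100))
      curve_amt <- runif(1, 0, 30)
      y <- 5 * x + 10 + curve_amt * exp(-x / 10) + rnorm(n, 0, 0.5)
      pts <- tibble::tibble(t_min = x, x = x, y = y)
      thr <- runif(1, 0.005, 0.1)
      got <- suppressWarnings(find_tstar(pts, thr))
      expect_identical(got$index, as.integer(brute(pts, thr)))
    }
  })
})

test_that("t* has its documented edge behavior and monotonicity", {
  x <- seq(5, 80, by = 5)
  pts <- tibble::tibble(t_min = x, x = x, y = 3 * x + 2)
  expect_equal(find_tstar(pts)$index, 1)   # collinear: earliest frame
  # curved head then collinear tail
  y2 <- 3 * x + 2
  y2[1:5] <- y2[1:5] - c(50, 30, 18, 10, 5)
  pts2 <- tibble::tibble(t_min = x, x = x, y = y2)
  expect_gt(find_tstar(pts2, 0.01)$index, 1)
  # zero threshold on noisy points falls back to the last three with warning
  withr::with_seed(5, {
    pts3 <- tibble::tibble(t_min = x, x = x, y = 3 * x + 2 + rnorm(16))
    expect_warning(fb <- find_tstar(pts3, 0), "last 3")
    expect_true(fb$fallback)
    expect_equal(fb$index, nrow(pts3) - 2L)
  })
  # loosening the threshold never yields a later t*
  withr::with_seed(6, {
    for (i in 1:20) {
      y4 <- 3 * x + 2 + 20 * exp(-x / 8) + rnorm(16, 0, 0.3)
      pts4 <- tibble::tibble(t_min = x, x = x, y = y4)
      idx <- vapply(c(0.02, 0.05, 0.1, 0.2),
                    function(th) suppressWarnings(find_tstar(pts4, th)$index),
                    numeric(1))
      expect_true(all(diff(idx) <= 0))
    }
  })
  expect_error(find_tstar(pts[1:2, ]), "at least 3")
})

test_that("multiplicative TAC noise biases Logan VT downward", {
  cp <- ref_cp()
  wb <- ref_wb()
  pars <- twotc_params(0.13, 0.065, 0.05, 0.05, vB = 0.05)
  tac <- simulate_2tc(cp, pars, whole_blood = wb)
  vt0 <- logan_vt(tac, cp, wb)$VT
  withr::with_seed(77, {
    vts <- vapply(1:200, function(i) {
      noisy <- tac
      noisy$activity_kBq_mL <- tac$activity_kBq_mL * exp(rnorm(32, 0, 0.1))
      suppressWarnings(logan_vt(noisy, cp, wb)$VT)
    }, numeric(1))
  })
  expect_lte(median(vts), vt0)
})
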
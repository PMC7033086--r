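test_that("the running trapezoid integral anchors at (0, 0)", {
  expect_equal(cumulative_integral(c(1, 2, 3), c(1, 1, 1)),
               c(0.5, 1.5, 2.5))
  expect_equal(cumulative_integral(c(1, 2), c(1, 2)), c(0.5, 2.0))
  tt <- seq(0, 5, by = 0.01)
  expect_lt(max(abs(cumulative_integral(tt, exp(-tt)) -
                      (1 - exp(-tt)))), 1e-4)
  expect_error(cumulative_integral(c(2, 1), c(1, 1)), "increasing")
})

test_that("the frame-aware tissue integral tracks the true running integral", {
  # frame-average a realistic organ curve and compare the running
  # integral at midpoints with a fine-grid integral of the underlying
  # curve; the frame-aware assembly must stay well inside 1%, far better
  # than a 7-point midpoint trapezoid can do on the early rise
  ns <- noiseless_study()
  sched <- default_schedule()
  mid <- frame_midpoints(sched)
  inp_par <- sim_config()$input
  rates <- rate_constants(0.188, 0.3, 0.05, 0.1)
  tac <- simulate_tissue_tac(rates, inp_par, sched, voi = "x")
  tt <- seq(0, max(mid) + 0.01, by = 0.002)
  ct <- tissue_curve(rates, inp_par, tt)
  cum <- cumsum(c(0, diff(tt) * (ct[-1] + ct[-length(ct)]) / 2))
  truth <- stats::approx(tt, cum, xout = mid)$y
  err_aware <- abs(tissue_integral(tac) - truth) / truth
  # frames from equilibration onwards are well inside 1%
  expect_lt(max(err_aware[3:7]), 0.01)
  # and the late-frame values beat the plain 7-point trapezoid clearly
  plain <- cumulative_integral(mid, tac$activity)
  err_plain <- abs(plain - truth) / truth
  expect_lt(max(err_aware[4:7]), max(err_plain[4:7]))
})

test_that("rate constants validate and give the closed-form Vt", {
  expect_equal(vt_from_rates(rate_constants(0.1, 0.2)), 0.5)
  expect_equal(vt_from_rates(rate_constants(0.1, 0.15, 0.05, 0.1)), 1.0)
  # k4 -> infinity collapses to the one-tissue value
  expect_equal(vt_from_rates(rate_constants(0.1, 0.2, 0.05, 1e9)), 0.5,
               tolerance = 1e-9)
  expect_error(rate_constants(0.1, 0), "k2")
  expect_error(rate_constants(0.1, 0.2, k3 = 0.1, k4 = 0), "k4")
})

test_that("a tissue curve equal to the plasma curve gives Vt = 1, b = 0", {
  ns <- noiseless_study()
  mid <- frame_midpoints(default_schedule())
  tac <- tissue_tac("plasma-like", default_schedule(),
                    predict(ns$input, mid))
  for (m in c("logan", "ma1")) {
    f <- fit_vt(tac, ns$input, m, t_star = mid[1])
    expect_equal(f$vt, 1)
    expect_equal(f$coef[["b"]], 0)
    expect_true("identity" %in% f$flags)
  }
})

test_that("noiseless compartment simulations are recovered by all models", {
  ns <- noiseless_study()
  sched <- default_schedule()
  inp <- sim_config()$input
  # one-tissue: Vt = K1/k2 = 0.5
  t1 <- simulate_tissue_tac(rate_constants(0.1, 0.2), inp, sched,
                            voi = "oneT")
  for (m in c("logan", "ma1", "ma2"))
    expect_equal(fit_vt(t1, ns$input, m)$vt, 0.5, tolerance = 0.02)
  # two-tissue: Vt = (K1/k2)(1 + k3/k4) = 1
  t2 <- simulate_tissue_tac(rate_constants(0.1, 0.15, 0.05, 0.1), inp,
                            sched, voi = "twoT")
  expect_equal(fit_vt(t2, ns$input, "logan", t_star = 20)$vt, 1,
               tolerance = 0.03)
  expect_equal(fit_vt(t2, ns$input, "ma1", t_star = 20)$vt, 1,
               tolerance = 0.03)
  f_ma2 <- fit_vt(t2, ns$input, "ma2")
  expect_equal(f_ma2$vt, 1, tolerance = 0.02)
  expect_equal(f_ma2$t_star, 20)
  # gamma4 estimates K1, though only roughly at 7-frame collinearity
  expect_equal(f_ma2$coef[["gamma4"]], 0.1, tolerance = 0.25)
})

test_that("degenerate designs and zero activity raise informative errors", {
  ns <- noiseless_study()
  sched <- default_schedule()
  zero <- tissue_tac("zero", sched, rep(0, 7))
  expect_error(fit_vt(zero, ns$input, "logan", t_star = 20),
               "zero in frame")
  expect_error(fit_vt(zero, ns$input, "logan"), "no feasible")
  expect_error(fit_vt(zero, ns$input, "ma2", t_star = 20), "singular")
  few <- ns$study$tacs$pancreas
  expect_error(fit_vt(few, ns$input, "ma2", t_star = 50), ">= 5 frames")
})

test_that("t* search demands linearity and flags unattainable criteria", {
  ns <- noiseless_study()
  inp_par <- sim_config()$input
  sched <- default_schedule()
  # slow second-compartment exchange needs a later t* than fast exchange
  slow <- simulate_tissue_tac(rate_constants(0.1, 0.15, 0.05, 0.02),
                              inp_par, sched, voi = "slow")
  fast <- simulate_tissue_tac(rate_constants(0.1, 0.15, 0.05, 0.2),
                              inp_par, sched, voi = "fast")
  for (m in c("logan", "ma1")) {
    ts_slow <- find_t_star(slow, ns$input, m)
    ts_fast <- find_t_star(fast, ns$input, m)
    expect_gt(ts_slow$t_star, ts_fast$t_star)
  }
  # an impossible error bound returns the latest feasible t*, flagged
  noisy <- simulate_tissue_tac(rate_constants(0.1, 0.15, 0.05, 0.1),
                               inp_par, sched, noise_cv = 0.05, seed = 7,
                               voi = "noisy")
  sel <- find_t_star(noisy, ns$input, "logan", max_rel_error = 0)
  expect_false(sel$converged)
  expect_equal(sel$t_star, frame_midpoints(sched)[5])
  f <- fit_vt(noisy, ns$input, "logan", max_rel_error = 0)
  expect_false(f$t_star_converged)
})

test_that("Logan and MA1 are algebraically identical on exactly linear data", {
  ns <- noiseless_study()
  tac <- exact_equilibrium_tac(ns$input, V = 0.8, b = -5)
  mid <- frame_midpoints(default_schedule())
  fl <- fit_vt(tac, ns$input, "logan", t_star = mid[1])
  fm <- fit_vt(tac, ns$input, "ma1", t_star = mid[1])
  expect_equal(fl$vt, 0.8, tolerance = 1e-9)
  expect_equal(fm$vt, 0.8, tolerance = 1e-9)
  expect_lt(abs(fl$vt - fm$vt) / fl$vt, 1e-6)
  expect_equal(fl$coef[["b"]], -5, tolerance = 1e-9)
})

test_that("Vt is invariant to common rescaling and unit changes", {
  ns <- noiseless_study()
  tac <- ns$study$tacs$liver
  ref <- vapply(c("logan", "ma1", "ma2"),
                function(m) fit_vt(tac, ns$input, m)$vt, numeric(1))
  for (scale in c(1000, 1 / 7)) {  # Bq vs kBq, arbitrary calibration
    blood2 <- blood_samples(ns$study$blood$time,
                            ns$study$blood$whole_blood * scale,
                            ns$study$blood$plasma * scale)
    inp2 <- fit_input_function(blood2)
    tac2 <- tissue_tac(tac$voi, tac$schedule, tac$activity * scale)
    got <- vapply(c("logan", "ma1", "ma2"),
                  function(m) fit_vt(tac2, inp2, m)$vt, numeric(1))
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("vt_fit objects expose the usual model methods", {
  ns <- noiseless_study()
  f <- fit_vt(ns$study$tacs$pancreas, ns$input, "ma2")
  expect_s3_class(f, "vt_fit")
  expect_named(coef(f)[1], "Vt")
  expect_length(residuals(f), f$n_points)
  expect_equal(fitted(f) + residuals(f), f$observed)
  expect_output(print(f), "MA2")
  s <- summary(f)
  expect_s3_class(s$gof, "gof_report")
  expect_output(print(s), "Goodness of fit")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(f))
  expect_silent(plot(fit_vt(ns$study$tacs$pancreas, ns$input, "logan")))
})
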
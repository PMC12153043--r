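test_that("Hertz force has the right limits, scaling and magnitude", {
  expect_equal(hertz_force(0, 100, 1.565), 0)
  # power-law homogeneity: doubling depth multiplies force by 2^(3/2)
  expect_equal(hertz_force(2, 80, 1.565) / hertz_force(1, 80, 1.565), 2^1.5)
  # frozen value from independent SI arithmetic: (4/3)*1e5*sqrt(1.565e-3)*(1e-3)^1.5
  expect_equal(hertz_force(1, 100, 1.565), 0.16679995, tolerance = 1e-7)
  expect_error(hertz_force(-1, 100, 1.565))
  expect_error(hertz_force(1, -5, 1.565))
})

test_that("noiseless synthetic curves satisfy the generating formulas exactly", {
  crv <- sim_indentation_curve(100, 30, tau1 = 99, tau2 = 1644,
                               cfg = sim_config(1, noise_sd_force = 0))
  truth <- attr(crv, "truth")
  load <- crv[crv$d_mm < 1, ]
  expect_equal(load$F_N, hertz_force(load$d_mm, 100, 1.565))
  hold <- crv[crv$d_mm >= 1, ]
  th <- hold$t_s - min(hold$t_s)
  expect_equal(hold$F_N,
               truth$F_inf + truth$F1 * exp(-th / 99) +
                 truth$F2 * exp(-th / 1644))
  # continuity at the ramp stop
  expect_equal(hold$F_N[1], hertz_force(1, 100, 1.565))
})

test_that("generator validates its parameters", {
  cfg <- sim_config(1)
  expect_error(sim_indentation_curve(10, 30, cfg = cfg))       # E0 < Einf
  expect_error(sim_indentation_curve(100, 30, tau1 = 200, tau2 = 100, cfg = cfg))
  expect_error(sim_indentation_curve(100, 30, d_max = 0, cfg = cfg))
  expect_error(sim_indentation_curve(100, 30, hold = -1, cfg = cfg))
})

test_that("noiseless generate-then-fit recovers every parameter", {
  crv <- sim_indentation_curve(100, 30, tau1 = 99, tau2 = 1644,
                               cfg = sim_config(7, noise_sd_force = 0))
  expect_equal(fit_initial_modulus(crv), 100, tolerance = 1e-6)
  rf <- fit_relaxation(crv)
  expect_equal(rf$tau1, 99, tolerance = 1e-4)
  expect_equal(rf$tau2, 1644, tolerance = 1e-4)
  expect_equal(residual_modulus(rf), 30, tolerance = 1e-4)
  truth <- attr(crv, "truth")
  expect_equal(rf$F_inf, truth$F_inf, tolerance = 1e-4)
  expect_equal(rf$F1, truth$F1, tolerance = 1e-3)
  expect_equal(rf$F2, truth$F2, tolerance = 1e-3)
  # tidy/glance surfaces
  td <- tidy(rf)
  expect_setequal(td$term, c("F_inf", "F1", "F2", "tau1", "tau2"))
  expect_true(glance(rf)$converged)
})

test_that("force scaling scales moduli and leaves relaxation times alone", {
  crv <- sim_indentation_curve(80, 25, cfg = sim_config(3, noise_sd_force = 0))
  crv2 <- crv
  crv2$F_N <- 3 * crv2$F_N
  expect_equal(fit_initial_modulus(crv2), 3 * fit_initial_modulus(crv),
               tolerance = 1e-8)
  rf <- fit_relaxation(crv)
  rf2 <- fit_relaxation(crv2)
  expect_equal(rf2$tau1, rf$tau1, tolerance = 1e-5)
  expect_equal(rf2$tau2, rf$tau2, tolerance = 1e-5)
  expect_equal(residual_modulus(rf2), 3 * residual_modulus(rf),
               tolerance = 1e-6)
})

test_that("noisy recovery: moduli and relaxation times across seeds", {
  seeds <- 1:20
  res <- purrr::map(seeds, function(s) {
    crv <- sim_indentation_curve(100, 30, cfg = sim_config(s))  # 1% force noise
    rf <- fit_relaxation(crv)
    tibble::tibble(E0 = fit_initial_modulus(crv),
                   Einf = residual_modulus(rf),
                   tau1 = rf$tau1, tau2 = rf$tau2)
  }) |> purrr::list_rbind()
  expect_lt(abs(mean(res$E0) - 100) / 100, 0.02)
  expect_lt(median(abs(res$tau1 - 99) / 99), 0.10)
  expect_lt(median(abs(res$tau2 - 1644) / 1644), 0.10)
  # ordering invariant holds for every fitted curve
  expect_true(all(res$Einf <= res$E0))
  expect_true(all(res$tau1 < res$tau2))
})

test_that("residual modulus inverts the Hertz worked example", {
  fake <- structure(list(F_inf = 0.16679995, R_mm = 1.565, d_max_mm = 1),
                    class = "relaxation_fit")
  expect_equal(residual_modulus(fake), 100, tolerance = 1e-6)
  fake$F_inf <- 0
  expect_equal(residual_modulus(fake), 0)
  fake$F_inf <- -0.01
  expect_error(residual_modulus(fake), "negative")
})

test_that("power-law fit recovers exact and two-point data", {
  phi <- c(1, 2, 4, 7)
  fit <- fit_power_law(phi, 10 * phi^1.9)
  expect_equal(fit$a, 10, tolerance = 1e-10)
  expect_equal(fit$b, 1.9, tolerance = 1e-10)
  # endpoints (1%, 10 kPa) and (7%, 416 kPa) pin the exponent at
  # ln(41.6)/ln(7) = 1.91586 (hand-computed closed form)
  fit2 <- fit_power_law(c(1, 7, sqrt(7)), c(10, 416, sqrt(10 * 416)))
  expect_equal(fit2$b, 1.9158645, tolerance = 1e-6)
  expect_error(fit_power_law(c(1, 2), c(1, 2)), ">= 3")
  expect_error(fit_power_law(c(1, 2, -1), c(1, 2, 3)), "positive")
})

test_that("exponent recovery under realistic modulus scatter", {
  set.seed(11)
  phi <- 1:7
  errs <- replicate(20, {
    E <- 10 * phi^1.9 * rlnorm(7, 0, 0.08)
    abs(fit_power_law(phi, E)$b - 1.9)
  })
  expect_lt(median(errs), 0.05)
})

test_that("curve CSV + sidecar round trip preserves the fit", {
  crv <- sim_indentation_curve(60, 20, cfg = sim_config(2, noise_sd_force = 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_indentation_curve(crv, path)
  back <- read_indentation_curve(path)
  expect_equal(back$F_N, crv$F_N, tolerance = 1e-12)
  expect_equal(attr(back, "R_mm"), 1.565)
  expect_equal(fit_initial_modulus(back), 60, tolerance = 1e-6)
})
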
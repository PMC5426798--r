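test_that("threshold integration matches the closed-form current-noise LIF rate", {
  cases <- list(c(0, 0, 1.0, 1), c(0, 0, sqrt(2), 1),
                c(0.05, 1.0, sqrt(2), 0.9), c(0.3, 0.6, 1.2, 1.3))
  for (cs in cases) {
    pt <- operating_point(gE_mean = cs[1], gI_mean = cs[2], sigmaE = 0,
                          sigmaI = 0, sigma = cs[3], theta = cs[4])
    ref <- siegert_rate(pt$mu, sqrt(pt$sigma_eff2), pt$tau_eff,
                        pt$theta, pt$tau_ref)
    expect_lt(abs(steady_rate(pt) - ref) / ref, 0.005)
  }
})

test_that("rates vanish for subthreshold drive and respect the refractory ceiling", {
  low <- steady_rate(operating_point(sigma = 0.05, theta = 1.4))
  expect_lt(low, 1e-4)
  high <- steady_rate(operating_point(gE_mean = 3, sigmaE = 1,
                                      sigma = 5, theta = 0.7))
  expect_lt(high, 1000 / 2) # tau_ref = 2 ms
  expect_gt(high, 100)
})

test_that("zero-frequency susceptibilities equal centered finite differences", {
  pt <- operating_point(gE_mean = 0.05, gI_mean = 1.0, sigmaE = 0.02,
                        sigmaI = 0.6, sigma = sqrt(2), theta = 1)
  sp <- cell_spectra(pt, freq = 0)
  rate_at <- function(gE = pt$gE_mean, gI = pt$gI_mean,
                      sE2 = pt$sigmaE^2, sI2 = pt$sigmaI^2) {
    steady_rate(operating_point(gE, gI, sqrt(sE2), sqrt(sI2),
                                pt$sigma, pt$theta)) / 1000
  }
  fd <- function(f, x0) {
    h <- max(abs(x0), 0.05) * 1e-3
    (f(x0 + h) - f(x0 - h)) / (2 * h)
  }
  checks <- c(
    gE_mean = fd(function(x) rate_at(gE = x), pt$gE_mean),
    gI_mean = fd(function(x) rate_at(gI = x), pt$gI_mean),
    sigmaE2 = fd(function(x) rate_at(sE2 = x), pt$sigmaE^2),
    sigmaI2 = fd(function(x) rate_at(sI2 = x), pt$sigmaI^2))
  for (p in names(checks)) {
    expect_lt(abs(sp$A0[[p]] - checks[[p]]) / abs(checks[[p]]), 0.01)
  }
  # mu susceptibility against the Siegert derivative (constant-D case)
  pt2 <- operating_point(gE_mean = 0.1, gI_mean = 0.8, sigmaE = 0,
                         sigmaI = 0, sigma = sqrt(2), theta = 1)
  a_mu <- Re(susceptibility(pt2, "mu", freq = 0))
  d <- 1e-4
  ref <- (siegert_rate(pt2$mu + d, sqrt(pt2$sigma_eff2), pt2$tau_eff, 1, 2) -
          siegert_rate(pt2$mu - d, sqrt(pt2$sigma_eff2), pt2$tau_eff, 1, 2)) /
    (2 * d) / 1000
  expect_lt(abs(a_mu - ref) / ref, 0.01)
  expect_gt(a_mu, 0) # more drive, more spikes
})

test_that("the Fokker-Planck response is linear: joint perturbations add", {
  pt <- operating_point(gE_mean = 0.05, gI_mean = 1.0, sigmaE = 0.02,
                        sigmaI = 0.6, sigma = sqrt(2), theta = 1)
  sp <- cell_spectra(pt, freq = 0)
  h <- 2e-3
  joint <- (steady_rate(operating_point(pt$gE_mean + h, pt$gI_mean + h,
                                        pt$sigmaE, pt$sigmaI, pt$sigma,
                                        pt$theta)) -
            steady_rate(operating_point(pt$gE_mean - h, pt$gI_mean - h,
                                        pt$sigmaE, pt$sigmaI, pt$sigma,
                                        pt$theta))) / (2 * h) / 1000
  expect_lt(abs(joint - (sp$A0[["gE_mean"]] + sp$A0[["gI_mean"]])) /
              abs(joint), 0.01)
})

test_that("rate, spectrum and susceptibilities converge under grid refinement", {
  pt <- operating_point(gE_mean = 0.05, gI_mean = 1.0, sigmaE = 0.02,
                        sigmaI = 0.6, sigma = sqrt(2), theta = 1)
  a <- cell_spectra(pt, freq = c(0, 10), n_v = 2048)
  b <- cell_spectra(pt, freq = c(0, 10), n_v = 4096)
  expect_lt(abs(a$nu - b$nu) / b$nu, 0.005)
  expect_lt(abs(a$C0[1] - b$C0[1]) / b$C0[1], 0.005)
  expect_lt(max(abs(a$A0 - b$A0) / abs(b$A0)), 0.005)
  expect_lt(Mod(a$A[2, "gI_mean"] - b$A[2, "gI_mean"]) /
              Mod(b$A[2, "gI_mean"]), 0.005)
})

test_that("the baseline spectrum is a valid renewal spectrum", {
  pt <- operating_point(gE_mean = 0.05, gI_mean = 1.0, sigmaE = 0.02,
                        sigmaI = 0.6, sigma = sqrt(2), theta = 1)
  sp <- cell_spectra(pt, freq = c(0, 1, 10, 100, 1000, 5000))
  expect_true(all(sp$C0 >= 0))
  # high-frequency limit -> nu
  expect_lt(abs(sp$C0[length(sp$C0)] - sp$nu) / sp$nu, 0.01)
  # 1/nu equals mean ISI from the backward moment equations
  expect_equal(1 / sp$nu, unname(sp$isi["mean"]), tolerance = 1e-4)
})

test_that("single-cell Monte Carlo agrees with threshold integration", {
  # Poisson-conductance-driven cell: map the input to moments, solve, and
  # compare with a direct Euler-Maruyama simulation of the same cell
  rateE_hz <- 150; rateI_hz <- 80; ahatE <- 0.05; ahatI <- 0.4
  mE <- conductance_moments(rateE_hz, ahatE, 1, 5)
  mI <- conductance_moments(rateI_hz, ahatI, 2, 10)
  pt <- operating_point(gE_mean = mE$mean, gI_mean = mI$mean,
                        sigmaE = sqrt(mE$variance),
                        sigmaI = sqrt(mI$variance),
                        sigma = sqrt(2), theta = 1)
  theory <- steady_rate(pt)
  res <- eicorr:::sim_poisson_cell_cpp(
    theta = 1, sigma = sqrt(2), tau_m = 20, tau_ref = 2,
    tau_r = c(1, 2), tau_d = c(5, 10), E_E = 6.5, E_I = -0.5,
    ahatE = ahatE, ahatI = ahatI, rateE = rateE_hz / 1000,
    rateI = rateI_hz / 1000, dt = 0.01, n_steps = 2e7,
    equil_steps = 1e5, bin_steps = 100, seed = 21)
  mc <- res$n_spikes / 200 # 2e7 steps * 0.01 ms = 200 s -> Hz
  se <- sqrt(res$n_spikes) / 200
  expect_lt(abs(mc - theory), max(4 * se, 0.04 * theory))
  # Fano at long windows matches the renewal prediction C0(0)/nu
  sp <- cell_spectra(pt, freq = 0)
  win <- matrix(res$counts[1:(2e5 %/% 100 * 100)], nrow = 100)
  fano_mc <- var(colSums(win)) / mean(colSums(win))
  expect_lt(abs(fano_mc - sp$C0[1] / sp$nu), 0.12)
})
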
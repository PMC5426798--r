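zero_weight_config <- function(n_E = 10, n_I = 4,
                               sigma = c(E = 1e-9, I = 1e-9)) {
  ei_network_config("custom", n_E = n_E, n_I = n_I,
                    W = matrix(0, 2, 2,
                               dimnames = list(c("E", "I"), c("E", "I"))),
                    sigma = sigma)
}

test_that("without input or noise the voltage decays and no spikes occur", {
  net <- ei_network(zero_weight_config(), heterogeneous = FALSE,
                    rng_seed = 1)
  sc <- simulate_network(net, sim_config(duration = 500, equilibration = 0,
                                         seed = 3))
  expect_true(all(sc$counts == 0L))
})

test_that("the same seed reproduces spike counts bitwise", {
  net <- fix_network("asynchronous")
  s1 <- simulate_network(net, sim_config(duration = 500, equilibration = 100,
                                         seed = 17))
  s2 <- simulate_network(net, sim_config(duration = 500, equilibration = 100,
                                         seed = 17))
  expect_identical(s1$counts, s2$counts)
  s3 <- simulate_network(net, sim_config(duration = 500, equilibration = 100,
                                         seed = 18))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("rates never exceed the refractory ceiling even under huge noise", {
  net <- ei_network(zero_weight_config(sigma = c(E = 30, I = 30)),
                    heterogeneous = FALSE, rng_seed = 1)
  sc <- simulate_network(net, sim_config(duration = 2000,
                                         equilibration = 100, seed = 5))
  expect_true(all(sc$rates$rate_hz <= 1000 / 2))
  expect_true(all(sc$rates$rate_hz > 150)) # strongly driven, not stuck
})

test_that("uncoupled Monte-Carlo rates match threshold integration", {
  net <- ei_network(zero_weight_config(n_E = 16, n_I = 4,
                                       sigma = c(E = sqrt(2),
                                                 I = 3 / sqrt(2))),
                    heterogeneous = FALSE, rng_seed = 1)
  sc <- simulate_network(net, sim_config(duration = 50000,
                                         n_realizations = 2,
                                         equilibration = 500, seed = 9))
  thE <- steady_rate(operating_point(sigma = sqrt(2), theta = 1))
  thI <- steady_rate(operating_point(sigma = 3 / sqrt(2), theta = 1))
  mcE <- mean(sc$rates$rate_hz[sc$rates$type == "E"])
  mcI <- mean(sc$rates$rate_hz[sc$rates$type == "I"])
  # Euler at dt = 0.01 carries a small positive discretization bias
  expect_lt(abs(mcE - thE) / thE, 0.07)
  expect_lt(abs(mcI - thI) / thI, 0.07)
  # halving dt moves population rates by well under 2%
  sc2 <- simulate_network(net, sim_config(duration = 50000,
                                          n_realizations = 2, dt = 0.005,
                                          equilibration = 500, seed = 9))
  mcE2 <- mean(sc2$rates$rate_hz[sc2$rates$type == "E"])
  expect_lt(abs(mcE2 - mcE) / mcE, 0.02)
})

test_that("coupled network Monte-Carlo rates match the self-consistent solution", {
  net <- fix_network("asynchronous")
  sc <- simulate_network(net, sim_config(duration = 20000,
                                         equilibration = 1000, seed = 31))
  lr <- memo("rates_asyn_11", self_consistent_rates(net))
  mcE <- mean(sc$rates$rate_hz[sc$rates$type == "E"])
  lrE <- mean(lr$rate_hz[lr$type == "E"])
  mcI <- mean(sc$rates$rate_hz[sc$rates$type == "I"])
  lrI <- mean(lr$rate_hz[lr$type == "I"])
  expect_lt(abs(mcE - lrE) / lrE, 0.06)
  expect_lt(abs(mcI - lrI) / lrI, 0.06)
})

test_that("windowed statistics recover Poisson behaviour on Poisson counts", {
  # hand-built Poisson counts: rate 10 Hz, 1 ms bins
  set.seed(44)
  n_cells <- 12
  counts <- matrix(rpois(n_cells * 2e4, 0.01), nrow = n_cells)
  obj <- structure(list(counts = counts, bin_width = 1, duration = 2e4,
                        n_realizations = 1,
                        cells = tibble::tibble(
                          id = 1:n_cells,
                          type = rep("E", n_cells),
                          theta = rep(1, n_cells)),
                        rates = NULL),
                   class = "ei_spike_counts")
  st <- spike_count_stats(obj, T = 100)
  expect_true(all(abs(st$cells$fano - 1) < 2.5 * sqrt(2 / 200)))
  expect_true(all(abs(st$pairs$rho) < 4 / sqrt(200)))
  expect_true(all(diag(st$rho) == 1)) # a cell paired with itself
  expect_lt(abs(mean(st$cells$rate_hz) - 10), 1)
})

test_that("zero-variance cells yield NA correlations, never zero", {
  counts <- rbind(matrix(rpois(2e3, 0.5), nrow = 1),
                  matrix(0L, nrow = 1, ncol = 2e3))
  obj <- structure(list(counts = counts, bin_width = 1, duration = 2e3,
                        n_realizations = 1,
                        cells = tibble::tibble(id = 1:2,
                                               type = c("E", "E"),
                                               theta = c(1, 1)),
                        rates = NULL),
                   class = "ei_spike_counts")
  expect_message(st <- spike_count_stats(obj, T = 100), "zero")
  expect_true(is.na(st$rho[1, 2]))
  expect_true(is.na(st$cells$fano[2]))
})

test_that("split-half disattenuation leaves null data alone and recovers planted structure", {
  # null: independent Poisson cells; reliability is ~0, corrected == raw
  set.seed(99)
  n_cells <- 20
  counts <- matrix(rpois(n_cells * 4e4, 0.05), nrow = n_cells)
  obj <- structure(list(counts = counts, bin_width = 5, duration = 1e5,
                        n_realizations = 2,
                        cells = tibble::tibble(
                          id = 1:n_cells, type = rep("E", n_cells),
                          theta = rep(1, n_cells)),
                        rates = NULL),
                   class = "ei_spike_counts")
  z <- corr_rate_r2(obj, T = 100)
  expect_lt(z$raw, 0.2)
  expect_true(is.na(z$reliability) || z$corrected <= 1)
  # planted: rate-correlated counts through a shared latent factor with
  # rate-proportional loading -> rho_ij grows with sqrt(rate_i rate_j)
  lam0 <- seq(0.02, 0.4, length.out = n_cells)
  nb <- 2e4
  latent <- rnorm(nb)
  counts2 <- t(vapply(lam0, function(l) {
    rpois(nb, pmax(l * (1 + 0.4 * latent * sqrt(l)), 0))
  }, numeric(nb)))
  obj$counts <- counts2
  obj$bin_width <- 5; obj$duration <- 5e4
  z2 <- corr_rate_r2(obj, T = 5)
  expect_gt(z2$reliability, 0.2)
  expect_gt(z2$corrected, z2$raw) # attenuation removed
  expect_lte(z2$corrected, 1)
})

test_that("the population spectrum finds an injected 8 Hz modulation and is flat for Poisson", {
  set.seed(7)
  tgrid <- seq_len(6e4) # ms
  lam <- 0.02 * (1 + 0.8 * sin(2 * pi * 8 * tgrid / 1000))
  counts <- rbind(rpois(length(tgrid), lam), rpois(length(tgrid), lam))
  obj <- structure(list(counts = counts, bin_width = 1, duration = 6e4,
                        n_realizations = 1,
                        cells = tibble::tibble(id = 1:2, type = c("E", "E"),
                                               theta = c(1, 1)),
                        rates = NULL),
                   class = "ei_spike_counts")
  ps <- population_power_spectrum(obj, "E", segment_ms = 2000)
  peak <- ps$freq[which.max(ps$power)]
  expect_lt(abs(peak - 8), 1)
  # homogeneous Poisson: no dominant peak
  counts0 <- rbind(rpois(length(tgrid), 0.02), rpois(length(tgrid), 0.02))
  obj$counts <- counts0
  ps0 <- population_power_spectrum(obj, "E", segment_ms = 2000)
  expect_lt(max(ps0$power) / mean(ps0$power), 3)
})

test_that("the strong asynchronous spectrum has a low-frequency maximum; the asynchronous one is flat", {
  band_ratio <- function(sc) {
    ps <- population_power_spectrum(sc, "E", segment_ms = 5000)
    lo <- mean(ps$power[ps$freq >= 3 & ps$freq <= 15])
    hi <- mean(ps$power[ps$freq >= 30 & ps$freq <= 90])
    lo / hi
  }
  sc_sa <- acc_sim("strong_asynchronous", 11, 600, n_real = 6)
  sc_a <- acc_sim("asynchronous", 11, 300)
  expect_gt(band_ratio(sc_sa), 3) # broad elevation around ~4-10 Hz
  expect_lt(band_ratio(sc_a), 2.5) # no comparable structure
  ps <- population_power_spectrum(sc_sa, "E", segment_ms = 5000)
  expect_lt(ps$freq[which.max(ps$power)], 20)
})
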
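test_that("pair susceptibility factorizes under the Poisson-variance assumption", {
  lr <- fix_lr("asynchronous")
  i0 <- match(0, lr$freq)
  A0 <- Re(lr$A$gI_mean[, i0])
  ps <- pair_susceptibility(lr, "gI", C_diag = lr$nu)
  Si <- A0 / sqrt(lr$nu)
  expect_equal(ps$susceptibility, Si[ps$i] * Si[ps$j], tolerance = 1e-12)
  expect_true(all(ps$susceptibility > 0)) # product of two negatives
})

test_that("current susceptibility rises with rate in both regimes; conductance susceptibility flips", {
  trend <- function(reg, which) {
    ps <- pair_susceptibility(fix_lr(reg), which)
    cor(ps$geom_rate, ps$susceptibility, method = "spearman")
  }
  expect_gt(trend("asynchronous", "mu"), 0.5)
  expect_gt(trend("strong_asynchronous", "mu"), 0.5)
  expect_lt(trend("asynchronous", "gI"), -0.2)
  expect_gt(trend("strong_asynchronous", "gI"), 0.2)
})

test_that("single-cell susceptibility is negative and its reductions are consistent", {
  lr <- fix_lr("asynchronous")
  full <- single_cell_susceptibility(lr, "full")
  expect_true(all(full$susceptibility < 0, na.rm = TRUE))
  avn <- memo("avn_asyn", single_cell_susceptibility(lr,
                                                     "averaged_nuisance"))
  # averaging nuisance parameters barely moves the asynchronous values
  expect_lt(mean(abs(full$susceptibility - avn$susceptibility)),
            0.05 * mean(abs(full$susceptibility)))
  # the nuisance reduction degrades more in the strong asynchronous regime
  lr_sa <- fix_lr("strong_asynchronous")
  full_sa <- single_cell_susceptibility(lr_sa, "full")
  avn_sa <- single_cell_susceptibility(lr_sa, "averaged_nuisance")
  dev_a <- mean(abs(full$susceptibility - avn$susceptibility)) /
    mean(abs(full$susceptibility))
  dev_s <- mean(abs(full_sa$susceptibility - avn_sa$susceptibility)) /
    mean(abs(full_sa$susceptibility))
  expect_lt(dev_a, dev_s)
})

test_that("with averaged inhibition, |S| falls with rate above ~5 Hz (correlations decrease)", {
  agi <- memo("agi_asyn",
              single_cell_susceptibility(fix_lr("asynchronous"),
                                         "averaged_gI"))
  hi <- subset(agi, rate_hz > 8)
  expect_lt(cor(hi$rate_hz, abs(hi$susceptibility),
                method = "spearman"), -0.8)
})

test_that("along the fixed-threshold path, |S| rises with rate below ~15 Hz (correlations increase)", {
  ft <- single_cell_susceptibility(fix_lr("asynchronous"), "fixed_theta",
                                   gI_range = c(0.1, 3.5), n_points = 25)
  lo <- subset(ft, rate_hz > 2 & rate_hz < 13)
  expect_gt(cor(lo$rate_hz, abs(lo$susceptibility),
                method = "spearman"), 0.8)
})

test_that("homogeneous populations collapse all susceptibility variants", {
  net <- ei_network("asynchronous", heterogeneous = FALSE, rng_seed = 21)
  lr <- memo("lr_hom", linear_response(net))
  full <- single_cell_susceptibility(lr, "full")
  avn <- single_cell_susceptibility(lr, "averaged_nuisance")
  agi <- single_cell_susceptibility(lr, "averaged_gI")
  expect_equal(avn$susceptibility, agi$susceptibility, tolerance = 1e-8)
  expect_equal(full$susceptibility, avn$susceptibility, tolerance = 1e-6)
})

test_that("the reduced rate surface is monotone in inhibition and threshold", {
  lr <- fix_lr("asynchronous")
  rs <- memo("surface_asyn",
             rate_surface(lr, gI_grid = seq(1.2, 2.6, length.out = 8),
                          theta_grid = seq(0.7, 1.4, length.out = 8)))
  g <- rs$grid
  for (th in unique(g$theta)) {
    r <- g$rate_hz[g$theta == th][order(g$gI_mean[g$theta == th])]
    expect_true(all(diff(r) < 0))
  }
  for (gi in unique(g$gI_mean)) {
    r <- g$rate_hz[g$gI_mean == gi][order(g$theta[g$gI_mean == gi])]
    expect_true(all(diff(r) < 0))
  }
})

test_that("surface values at cell coordinates match the per-cell reduction", {
  lr <- fix_lr("asynchronous")
  avn <- memo("avn_asyn", single_cell_susceptibility(lr,
                                                     "averaged_nuisance"))
  # direct evaluation at the exact cell coordinates (no interpolation)
  nuis <- eicorr:::e_population_means(lr)
  syn <- lr$network$config$syn
  opsE <- lr$ops[lr$network$cells$type == "E", ]
  for (k in c(1, 20, 60)) {
    v <- eicorr:::rate_and_dgi(opsE$gI_mean[k], opsE$theta[k], nuis, syn)
    expect_equal(v[["dnu"]] / sqrt(v[["nu"]]), avn$susceptibility[k],
                 tolerance = 1e-8)
  }
  # bilinear interpolation from the surface agrees to a few percent
  rs <- memo("surface_asyn",
             rate_surface(lr, gI_grid = seq(1.2, 2.6, length.out = 8),
                          theta_grid = seq(0.7, 1.4, length.out = 8)))
  g <- rs$grid
  interp <- function(gi, th) {
    gx <- sort(unique(g$gI_mean)); gy <- sort(unique(g$theta))
    i <- findInterval(gi, gx, all.inside = TRUE)
    j <- findInterval(th, gy, all.inside = TRUE)
    sub <- g[g$gI_mean %in% gx[i:(i + 1)] & g$theta %in% gy[j:(j + 1)], ]
    wx <- (gi - gx[i]) / (gx[i + 1] - gx[i])
    wy <- (th - gy[j]) / (gy[j + 1] - gy[j])
    s <- matrix(sub$susceptibility[order(sub$gI_mean, sub$theta)], 2, 2,
                byrow = TRUE)
    (1 - wx) * ((1 - wy) * s[1, 1] + wy * s[1, 2]) +
      wx * ((1 - wy) * s[2, 1] + wy * s[2, 2])
  }
  ok <- opsE$gI_mean > 1.2 & opsE$gI_mean < 2.6
  k <- which(ok)[1]
  est <- interp(opsE$gI_mean[k], opsE$theta[k])
  expect_lt(abs(est - avn$susceptibility[k]) / abs(avn$susceptibility[k]),
            0.05)
})

test_that("common-input grouping counts shared inhibitory partners correctly", {
  md <- fix_motifs("asynchronous")
  cg <- common_input_grouping(md)
  net <- md$network
  type <- net$cells$type
  # brute-force recount for a handful of pairs
  for (r in c(1, 500, 2000)) {
    i <- cg$i[r]; j <- cg$j[r]
    shared <- sum(net$adjacency[i, type == "I"] &
                    net$adjacency[j, type == "I"])
    expect_equal(cg$n_shared_I[r], shared)
  }
  expect_true(all(cg$c >= 0 & cg$c <= 1))
  expect_equal(cg$c, cg$n_shared_I / 7)
  # hypergeometric expectation N_EI^2 / n_I = 2.45 shared inputs
  expect_lt(abs(mean(cg$n_shared_I) - 49 / 20), 0.3)
  # correlation increases with the number of shared inhibitory inputs
  m <- tapply(cg$rho_I_common, cg$n_shared_I, mean)
  expect_true(all(diff(m[as.character(0:5)]) > 0))
  expect_equal(unname(m[["0"]]), 0, tolerance = 1e-15)
})
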
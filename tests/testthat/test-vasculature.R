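test_that("Hagen-Poiseuille resistance: value, quartic radius law, linear length law", {
  Z_cap <- vessel_resistance(5e-6, 75e-6, 3e-3)
  expect_equal(Z_cap, 8 * 3e-3 * 75e-6 / (pi * (5e-6)^4), tolerance = 1e-15)
  expect_equal(Z_cap, 9.17e14, tolerance = 1e-3)
  expect_equal(vessel_resistance(1e-5, 75e-6, 3e-3), Z_cap / 16)
  expect_equal(vessel_resistance(5e-6, 150e-6, 3e-3), 2 * Z_cap)
  expect_error(vessel_resistance(-1e-6, 75e-6), class = "braintherm_argument_error")
  expect_error(vessel_resistance(5e-6, 0), class = "braintherm_argument_error")
})

test_that("the unperturbed backbone follows the cube-root scaling law", {
  net <- build_network(network_spec(n_levels = 6, radius_cv = 0, length_cv = 0))
  # level counts: 2^k arterial, mirrored venous
  expect_equal(as.vector(table(net$level)), c(1, 2, 4, 8, 16, 32,
                                              32, 16, 8, 4, 2, 1))
  root <- net[net$level == 0, ]
  expect_equal(root$radius, 2^(5 / 3) * 5e-6, tolerance = 1e-12)  # ~15.87 um
  expect_equal(root$length, 2^(5 / 3) * 75e-6, tolerance = 1e-12)
  # all vessels at a level identical; venous mirrors arterial
  expect_equal(length(unique(net$radius[net$level == 3])), 1L)
  expect_equal(net$radius[net$level == 2][1], net$radius[net$level == 9][1])
  # capillaries keep the characteristic dimensions
  expect_equal(unique(net$radius[net$level == 5]), 5e-6)
  expect_equal(unique(net$length[net$level == 5]), 75e-6)
})

test_that("networks are seed-reproducible and tumour specs are more dispersed", {
  a <- build_network(tumour_vasculature_spec(), seed = 4)
  b <- build_network(tumour_vasculature_spec(), seed = 4)
  expect_identical(a$radius, b$radius)
  nor <- build_network(normal_vasculature_spec(), seed = 4)
  tum <- build_network(tumour_vasculature_spec(), seed = 4)
  rel_spread <- function(net, k) {
    r <- net$radius[net$level == k]
    sd(r) / mean(r)
  }
  expect_gt(rel_spread(tum, 4), rel_spread(nor, 4))
})

test_that("symmetric networks collapse to the closed-form total resistance", {
  Z_cap <- vessel_resistance(5e-6, 75e-6, 3e-3)
  for (N in c(1, 3, 6)) {
    net <- build_network(network_spec(n_levels = N, radius_cv = 0, length_cv = 0))
    # with cube-root scaling every one of the 2N levels contributes
    # Z_cap / 2^(N-1), arterial and venous alike
    expect_rel_equal(total_resistance(net), 2 * N * Z_cap / 2^(N - 1), 1e-12)
  }
  # N = 1: one arterial + one venous vessel in series
  net1 <- build_network(network_spec(n_levels = 1, radius_cv = 0, length_cv = 0))
  expect_rel_equal(total_resistance(net1), 2 * Z_cap, 1e-12)
})

test_that("a hand-perturbed two-level network matches the explicit path sum", {
  net <- build_network(network_spec(n_levels = 2, radius_cv = 0, length_cv = 0))
  # vessels in level order: k=0 (1), k=1 (2 capillaries), k=2 (2), k=3 (1)
  net$radius <- c(10e-6, 5e-6, 6e-6, 5.5e-6, 4.5e-6, 9e-6)
  net$length <- c(150e-6, 75e-6, 80e-6, 70e-6, 75e-6, 140e-6)
  Z <- vessel_resistance(net$radius, net$length, 3e-3)
  # two root-to-root paths, flows (1, 1/2, 1/2, 1); average of per-path drops
  drop1 <- Z[1] + Z[2] / 2 + Z[4] / 2 + Z[6]
  drop2 <- Z[1] + Z[3] / 2 + Z[5] / 2 + Z[6]
  expected <- (drop1 + drop2) / 2
  expect_rel_equal(total_resistance(net), expected, 1e-12)
  expect_rel_equal(as.numeric(total_resistance_oracle(net)), expected, 1e-12)
})

test_that("level-sum formula agrees with the path-enumeration oracle on random networks", {
  for (i in 1:100) {
    N <- 1 + (i %% 3)  # N in {1, 2, 3}
    net <- build_network(network_spec(n_levels = N, radius_cv = 0.4,
                                      length_cv = 0.4), seed = 1000 + i)
    expect_rel_equal(total_resistance(net),
                     as.numeric(total_resistance_oracle(net)), 1e-10)
  }
})

test_that("the oracle's flows conserve mass at every junction", {
  net <- build_network(tumour_vasculature_spec(n_levels = 4), seed = 9)
  flows <- attr(total_resistance_oracle(net), "flows")
  N <- 4
  for (k in 0:(N - 2)) {  # arterial bifurcations
    parents <- flows$flow[flows$level == k]
    daughters <- flows$flow[flows$level == k + 1]
    for (j in seq_along(parents)) {
      expect_equal(parents[j], daughters[2 * j - 1] + daughters[2 * j])
    }
  }
  for (k in N:(2 * N - 2)) {  # venous merges
    daughters <- flows$flow[flows$level == k]
    parents <- flows$flow[flows$level == k + 1]
    for (j in seq_along(parents)) {
      expect_equal(parents[j], daughters[2 * j - 1] + daughters[2 * j])
    }
  }
  expect_error(
    total_resistance_oracle(build_network(network_spec(n_levels = 9))),
    class = "braintherm_argument_error")
})

test_that("identical populations give a zeta distribution centred on 1", {
  zs <- estimate_zeta(normal_vasculature_spec(), normal_vasculature_spec(),
                      n_samples = 400, seed = 31)
  se <- zs$sd_zeta / sqrt(zs$n_samples)
  expect_lt(abs(zs$mean_zeta - 1), 3 * se)
})

test_that("tumour-grade variability drives zeta below 1 in most draws", {
  zs <- estimate_zeta(n_samples = 500, seed = 32)
  expect_lt(zs$mean_zeta, 1)
  expect_gt(zs$fraction_below_1, 0.5)
  expect_true(all(zs$zeta > 0))
  expect_true(all(zs$Z_normal > 0) && all(zs$Z_tumour > 0))
})

test_that("mean-one geometric noise inflates the expected resistance (convexity of l/r^4)", {
  Z_cap <- vessel_resistance(5e-6, 75e-6, 3e-3)
  Z_sym <- 2 * 6 * Z_cap / 2^5
  zs <- estimate_zeta(tumour_spec = network_spec(radius_cv = 0.2, length_cv = 0.2),
                      n_samples = 500, seed = 33)
  expect_gt(zs$mean_Z_tumour, Z_sym)
})

test_that("resistance dispersion grows with vessel variability and brackets the reported spreads", {
  rel_sd <- function(cv, seed) {
    zs <- estimate_zeta(tumour_spec = network_spec(radius_cv = cv, length_cv = cv),
                        n_samples = 400, seed = seed)
    zs$sd_Z_tumour / zs$mean_Z_tumour
  }
  spreads <- c(rel_sd(0.05, 41), rel_sd(0.15, 41), rel_sd(0.25, 41))
  expect_true(all(diff(spreads) > 0))
  # default populations: a few percent (normal) vs roughly a fifth to a
  # quarter (tumour), the ratios implied by the reported histograms
  zs <- estimate_zeta(n_samples = 500, seed = 42)
  expect_gt(zs$sd_Z_normal / zs$mean_Z_normal, 0.02)
  expect_lt(zs$sd_Z_normal / zs$mean_Z_normal, 0.06)
  expect_gt(zs$sd_Z_tumour / zs$mean_Z_tumour, 0.15)
  expect_lt(zs$sd_Z_tumour / zs$mean_Z_tumour, 0.30)
})
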
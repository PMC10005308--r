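test_that("generator parameter validation rejects bad inputs", {
  expect_error(cone_model_params(0, 0.1), "theta_c")
  expect_error(cone_model_params(181, 0.1), "theta_c")
  expect_error(cone_model_params(60, -1), "D_w")
  expect_error(cone_model_params(60, 0.1, axis = c(1, 1, 1)), "unit")
  expect_error(lateral_walk_params(-1, 4, 0.01), ">= 0")
  expect_error(lateral_walk_params(0.1, 4, 0), "dt")
  expect_error(synthetic_bilayer_spec(n_lipids_per_leaflet = 2,
                                      n_probes_per_leaflet = 3),
               "probe count")
  expect_error(gen_acf_curve(table1$tPnA_DPPC, 0:10, noise_sd = -0.1), ">= 0")
  expect_error(acf_fit_params(c(-0.1), c(1), 0.5), "amplitudes")
  expect_error(acf_fit_params(c(0.5), c(1), 1.5), "a_inf")
})

test_that("all generators are deterministic under a fixed seed", {
  p <- cone_model_params(60, 0.1)
  expect_identical(gen_hindered_rotor(p, 200, 0.01, 3, seed = 7),
                   gen_hindered_rotor(p, 200, 0.01, 3, seed = 7))
  lw <- lateral_walk_params(1e-2, 4, 0.01)
  expect_identical(gen_lateral_walk(lw, 500, seed = 7),
                   gen_lateral_walk(lw, 500, seed = 7))
  spec <- synthetic_bilayer_spec(n_lipids_per_leaflet = 6,
                                 n_probes_per_leaflet = 1, chain_length = 3)
  expect_identical(gen_bilayer_config(spec, 2, seed = 7)$xyz,
                   gen_bilayer_config(spec, 2, seed = 7)$xyz)
  pmf <- analytic_pmf("flat")
  expect_identical(gen_umbrella_samples(pmf, c(0, 0.1), n_samples = 100, seed = 7),
                   gen_umbrella_samples(pmf, c(0, 0.1), n_samples = 100, seed = 7))
  expect_identical(gen_acf_curve(table1$cPnA_POPC, 0:100, 0.01, seed = 7),
                   gen_acf_curve(table1$cPnA_POPC, 0:100, 0.01, seed = 7))
})

test_that("hindered rotor stays unit-norm and inside the cone", {
  for (thc in c(30, 60, 90)) {
    p <- cone_model_params(thc, 0.2)
    o <- gen_hindered_rotor(p, 5000, 0.005, n_molecules = 2, seed = 11)
    for (j in 1:2) {
      u <- o$u[, , j]
      expect_lt(max(abs(sqrt(rowSums(u^2)) - 1)), 1e-9)
      ang <- acos(pmin(pmax(u[, 3], -1), 1)) * 180 / pi
      expect_lte(max(ang), thc + 1e-6)
    }
  }
})

test_that("near-zero cone half-angle freezes the rotor", {
  p <- cone_model_params(0.01, 0.5)
  o <- gen_hindered_rotor(p, 2000, 0.01, n_molecules = 2, seed = 5)
  a <- compute_rotational_acf(o)
  expect_true(all(a$C > 1 - 1e-4))
})

test_that("rotor axis rotation preserves cone geometry about the new axis", {
  ax <- c(1, 0, 0)
  p <- cone_model_params(45, 0.2, axis = ax)
  o <- gen_hindered_rotor(p, 1000, 0.005, n_molecules = 1, seed = 2)
  cosang <- o$u[, , 1] %*% ax
  expect_lte(max(acos(pmin(pmax(cosang, -1), 1))) * 180 / pi, 45 + 1e-6)
})

test_that("lateral walk has the stated increment statistics", {
  # D = 0, no drift: all molecules stay put
  lw0 <- gen_lateral_walk(lateral_walk_params(0, 3, 0.01), 100, seed = 1)
  expect_equal(max(abs(lw0$pos)), 0)
  # Gaussian increments with per-axis variance 2 D dt
  D <- 5e-3; dt <- 0.01
  lw <- gen_lateral_walk(lateral_walk_params(D, 8, dt), 20000, seed = 1)
  inc <- apply(lw$pos, c(2, 3), diff)
  v <- stats::var(as.vector(inc))
  expect_lt(abs(v / (2 * D * dt) - 1), 0.05)
  # recorded drift path equals the cumulative input drift
  dr <- matrix(0.01, nrow = 49, ncol = 2)
  lwd <- gen_lateral_walk(lateral_walk_params(0, 2, dt, drift = dr), 50, seed = 1)
  expect_equal(lwd$pos[50, 1, 1], 0.49, tolerance = 1e-12)
})

test_that("synthetic bilayer honours its construction invariants", {
  # zero tilt SDs and zero mean tilt: every chain exactly along the normal
  spec0 <- synthetic_bilayer_spec(n_lipids_per_leaflet = 6, tilt_mean = 0,
                                  tilt_sd_near = 0, tilt_sd_mid = 0,
                                  tilt_sd_far = 0, n_probes_per_leaflet = 1,
                                  chain_length = 4)
  tr0 <- gen_bilayer_config(spec0, 2, seed = 1)
  td <- compute_tilt_distribution(tr0)
  expect_equal(td$mean, 0, tolerance = 1e-9)
  expect_equal(td$variance, 0, tolerance = 1e-12)
  # leaflets symmetric about z = 0 and d_PP by construction
  spec <- synthetic_bilayer_spec(n_lipids_per_leaflet = 8, d_PP_true = 3.8,
                                 n_probes_per_leaflet = 1, chain_length = 4)
  tr <- gen_bilayer_config(spec, 3, seed = 2)
  expect_equal(compute_thickness_dPP(tr)$mean, 3.8, tolerance = 1e-12)
  p_up <- select_atoms(tr, atom = "P", leaflet = "upper")
  p_lo <- select_atoms(tr, atom = "P", leaflet = "lower")
  expect_equal(mean(tr$xyz[p_up, 3, 1]), -mean(tr$xyz[p_lo, 3, 1]))
  # probe carboxylate depth as specified
  coo <- select_atoms(tr, atom = "COO")
  expect_equal(unique(abs(tr$xyz[coo, 3, 1])), spec$probe_depth)
})

test_that("umbrella sampler matches closed-form biased densities", {
  RT <- rt_kj(298.15)
  k <- 3000
  pmf <- analytic_pmf("flat")
  centers <- seq(-1, 1, by = 0.25)
  w <- gen_umbrella_samples(pmf, centers, k = k, n_samples = 4000,
                            seed = 1)
  # flat PMF: biased density is N(z0, RT/k)
  v_exp <- RT / k
  for (i in seq_along(w)) {
    se_mean <- sqrt(v_exp / 4000)
    expect_lt(abs(mean(w[[i]]$samples) - centers[i]), 3 * se_mean)
  }
  v_obs <- mean(vapply(w, function(x) stats::var(x$samples), numeric(1)))
  expect_lt(abs(v_obs / v_exp - 1), 0.05)
  # stiff-spring limit pins samples to the centre (biased density SD is
  # sqrt(RT/k) ~ 5e-4 nm; the max over 500 draws sits within ~5 sigma
  # plus one inverse-CDF grid step)
  ws <- gen_umbrella_samples(pmf, 0.3, k = 1e7, n_samples = 500, seed = 2)
  expect_lt(max(abs(ws[[1]]$samples - 0.3)), 5 * sqrt(RT / 1e7) + 1e-3)
  expect_lt(abs(mean(ws[[1]]$samples) - 0.3), 1e-4)
  # harmonic PMF: product of Gaussians, KS test against the closed form
  kappa <- 10
  pmfh <- analytic_pmf("harmonic", kappa = kappa)
  z0 <- 0.5
  wh <- gen_umbrella_samples(pmfh, z0, k = k, n_samples = 4000, seed = 3)
  mu <- k * z0 / (k + kappa)
  sg <- sqrt(RT / (k + kappa))
  ks <- stats::ks.test(wh[[1]]$samples, "pnorm", mean = mu, sd = sg)
  expect_gt(ks$p.value, 0.01)
  # per-window mean within 3 SE of the analytic biased mean
  expect_lt(abs(mean(wh[[1]]$samples) - mu), 3 * sg / sqrt(4000))
  # centres outside the grid raise a range error
  expect_error(gen_umbrella_samples(pmf, 10), "outside")
})

test_that("ACF curve generator evaluates the multiexponential model", {
  const <- gen_acf_curve(acf_fit_params(numeric(0), numeric(0), 1), 0:50)
  expect_true(all(const$C == 1))
  row <- table1$tPnA_DPPC
  cv <- gen_acf_curve(row, c(0, 1, 10))
  expect_equal(cv$C[1], sum(row$a) + row$a_inf, tolerance = 1e-12)
  expect_equal(cv$C[2],
               sum(row$a * exp(-1 / row$phi)) + row$a_inf, tolerance = 1e-12)
})
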
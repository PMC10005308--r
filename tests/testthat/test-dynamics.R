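test_that("rotational ACF satisfies its basic identities", {
  # frozen orientations: C(t) = 1 at all lags
  u <- array(rep(c(0.6, 0, 0.8), each = 50), c(50, 3, 1))
  o <- structure(list(u = u, dt = 0.1), class = "orient_series")
  a <- compute_rotational_acf(o)
  expect_true(all(abs(a$C - 1) < 1e-12))
  # C(0) = 1 and C in [-0.5, 1] for arbitrary unit-vector series
  withr::with_seed(4, {
    v <- matrix(stats::rnorm(300 * 3), ncol = 3)
  })
  v <- v / sqrt(rowSums(v^2))
  o2 <- structure(list(u = array(v, c(300, 3, 1)), dt = 0.1),
                  class = "orient_series")
  a2 <- compute_rotational_acf(o2)
  expect_equal(a2$C[1], 1, tolerance = 1e-9)
  expect_true(all(a2$C <= 1 + 1e-9 & a2$C >= -0.5 - 1e-9))
})

test_that("trajectory-based ACF matches the orientation-series ACF", {
  p <- cone_model_params(60, 0.3)
  o <- gen_hindered_rotor(p, 400, 0.01, n_molecules = 2, seed = 6)
  # build a trajectory whose per-molecule C1 -> C9 vector is the rotor axis
  nfr <- 400
  xyz <- array(NA_real_, c(4, 3, nfr))
  for (f in seq_len(nfr)) {
    xyz[1, , f] <- c(1, 1, 1)
    xyz[2, , f] <- c(1, 1, 1) + 0.7 * o$u[f, , 1]
    xyz[3, , f] <- c(3, 3, 1)
    xyz[4, , f] <- c(3, 3, 1) + 0.7 * o$u[f, , 2]
  }
  top <- data.frame(species = "PRB", molecule = c(1, 1, 2, 2),
                    atom = rep(c("C9", "C16"), 2), mass = 1,
                    leaflet = "upper")
  tr <- trajectory(xyz, c(8, 8, 8), (seq_len(nfr) - 1) * 0.01, top)
  at <- compute_rotational_acf(tr, axis_spec = list(species = "PRB",
                                                    from = "C9", to = "C16"))
  ao <- compute_rotational_acf(o)
  expect_equal(at$C, ao$C, tolerance = 1e-9)
  # zero-length axis raises a geometry error
  xyz[2, , 5] <- xyz[1, , 5]
  tr2 <- trajectory(xyz, c(8, 8, 8), (seq_len(nfr) - 1) * 0.01, top)
  expect_error(compute_rotational_acf(tr2,
                 axis_spec = list(species = "PRB", from = "C9", to = "C16")),
               "zero-length")
})

test_that("fit_acf handles degenerate and low-order models", {
  const <- gen_acf_curve(acf_fit_params(numeric(0), numeric(0), 0.5),
                         seq(0, 100, by = 1))
  f <- fit_acf(const)
  expect_equal(f$a_inf, 0.5, tolerance = 1e-6)
  expect_lt(sum(f$a), 1e-4)
  # biexponential round trip selects order 2 and recovers within 5%
  truth <- acf_fit_params(c(0.4, 0.35), c(0.8, 12), 0.25)
  cv <- gen_acf_curve(truth, seq(0, 120, by = 0.1))
  f2 <- fit_acf(cv)
  expect_equal(f2$n_exp, 2L)
  expect_equal(f2$a_inf, 0.25, tolerance = 0.0125)
  expect_equal(sort(f2$a), sort(truth$a), tolerance = 0.05)
  expect_equal(sort(f2$phi), sort(truth$phi), tolerance = 0.05)
  expect_error(fit_acf(gen_acf_curve(truth, 0:5)), "at least 10")
})

test_that("fit_acf round-trips all published parameter sets", {
  tg <- seq(0, 1000, by = 0.1)
  for (nm in names(table1)) {
    truth <- table1[[nm]]
    f <- fit_acf(gen_acf_curve(truth, tg))
    expect_equal(f$n_exp, truth$n_exp, info = nm)
    # every recovered parameter within 2% or 0.005 absolute
    ok_par <- function(est, true) abs(est - true) < pmax(0.02 * abs(true), 0.005)
    expect_true(all(ok_par(f$a, truth$a)), info = nm)
    expect_true(all(ok_par(f$phi, truth$phi)), info = nm)
    expect_true(ok_par(f$a_inf, truth$a_inf), info = nm)
  }
})

test_that("a_inf is recovered under noise for the gel-phase parameter sets", {
  tg <- seq(0, 1000, by = 0.1)  # same lag grid as the noise-free round trips
  for (nm in c("cPnA_DPPC", "tPnA_DPPC")) {
    truth <- table1[[nm]]
    cv <- gen_acf_curve(truth, tg, noise_sd = 0.01, seed = 21)
    f <- fit_acf(cv)
    expect_lt(abs(f$a_inf - truth$a_inf), 0.02)
  }
})

test_that("anisotropy estimates scale the residual amplitude by r0", {
  mk <- function(ainf) acf_fit_params(0.1, 1, ainf)
  expect_equal(anisotropy_estimate(mk(0.92))$r_inf_reported, 0.37)
  expect_equal(anisotropy_estimate(mk(0.71))$r_inf_reported, 0.28)
  expect_equal(anisotropy_estimate(mk(0))$r_inf, 0)
  expect_error(anisotropy_estimate(mk(0.5), r0 = 0.45), "2/5")
})

test_that("mean correlation time integrates the decaying part", {
  m1 <- mean_correlation_time(table1$cPnA_POPC)
  expect_equal(m1$mean_time_reported, 1.1)
  m2 <- mean_correlation_time(table1$tPnA_POPC)
  expect_equal(m2$mean_time_reported, 1.7)
  expect_equal(mean_correlation_time(acf_fit_params(1, 5, 0))$mean_time, 5)
})

test_that("MSD handles ballistic, diffusive and COM-removal regimes", {
  # constant-velocity drift, removal off: MSD = (v t)^2
  v <- 0.05; dt <- 0.1; n <- 200
  pos <- array(0, c(n, 2, 1))
  pos[, 1, 1] <- v * (seq_len(n) - 1) * dt
  lw <- structure(list(pos = pos, dt = dt), class = "lateral_walk")
  m <- compute_msd(lw, leaflet_com_removal = FALSE)
  expect_equal(m$msd, (v * m$t)^2, tolerance = 1e-9)
  # Einstein relation on a simulated walk
  D <- 5e-3
  walk <- gen_lateral_walk(lateral_walk_params(D, 16, 0.01), 2e4, seed = 1)
  est <- estimate_dlat(compute_msd(walk, leaflet_com_removal = FALSE))
  expect_lt(abs(est$D_nm2_ns / D - 1), 0.10)
  expect_gt(est$r_squared, 0.99)
  # pure noise around zero: slope ~ 0, low R^2 flagged
  withr::with_seed(2, {
    noise <- data.frame(t = seq(0, 10, by = 0.1),
                        msd = abs(stats::rnorm(101, 0, 1e-4)))
  })
  class(noise) <- c("msd_curve", "data.frame")
  en <- estimate_dlat(noise)
  expect_lt(abs(en$D_nm2_ns), 1e-4)
  expect_lt(en$r_squared, 0.5)
})

test_that("D_lat unit conversion is exact on a synthetic line", {
  D <- 5e-3
  line <- data.frame(t = seq(0, 50, by = 0.5), msd = 4 * D * seq(0, 50, by = 0.5))
  class(line) <- c("msd_curve", "data.frame")
  est <- estimate_dlat(line)
  expect_equal(est$D_lat, 5e-8, tolerance = 1e-12)
  expect_error(estimate_dlat(line, fit_window_fractions = c(0.1, 0.11)),
               "fewer than 4")
})

test_that("estimate_dlat is invariant to rigid in-plane translation", {
  walk <- gen_lateral_walk(lateral_walk_params(4e-3, 8, 0.01), 5000, seed = 3)
  est1 <- estimate_dlat(compute_msd(walk, leaflet_com_removal = FALSE))
  walk$pos[, 1, ] <- walk$pos[, 1, ] + 12.3
  walk$pos[, 2, ] <- walk$pos[, 2, ] - 4.56
  est2 <- estimate_dlat(compute_msd(walk, leaflet_com_removal = FALSE))
  # FFT round-off differs after the shift; equality is to numerical noise
  expect_equal(est1$D_lat, est2$D_lat, tolerance = 1e-6)
})

test_that("trajectory MSD groups by leaflet and detects spanning molecules", {
  # two molecules drifting at constant velocity in one leaflet
  nfr <- 60
  xyz <- array(0, c(2, 3, nfr))
  for (f in seq_len(nfr)) xyz[, , f] <- cbind(0.1 * f + c(0, 1), c(2, 3), c(1, 1))
  top <- data.frame(species = "PRB", molecule = 1:2, atom = "COO", mass = 1,
                    leaflet = "upper")
  tr <- trajectory(xyz, c(50, 50, 10), (seq_len(nfr) - 1) * 0.1, top)
  m_off <- compute_msd(tr, sel = list(species = "PRB"),
                       leaflet_com_removal = FALSE)
  expect_equal(m_off$msd, (0.1 / 0.1 * m_off$t)^2, tolerance = 1e-9)
  # identical drift is removed entirely in the leaflet COM frame
  m_on <- compute_msd(tr, sel = list(species = "PRB"))
  expect_lt(max(m_on$msd), 1e-12)
  top_bad <- top; top_bad$leaflet <- c("upper", "lower"); top_bad$molecule <- c(1, 1)
  tr_bad <- trajectory(xyz, c(50, 50, 10), (seq_len(nfr) - 1) * 0.1, top_bad)
  expect_error(compute_msd(tr_bad, sel = list(species = "PRB")), "spans")
})
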
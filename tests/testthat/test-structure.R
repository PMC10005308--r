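test_that("area per lipid is box area over leaflet lipid count", {
  tr <- make_point_traj(rbind(c(1, 1, 1)), box = c(8, 8, 5))
  expect_equal(compute_area_per_lipid(tr, 100)$mean, 0.64)
  one <- make_point_traj(rbind(c(1, 1, 1)), box = c(6.928, 6.928, 5))
  expect_equal(compute_area_per_lipid(one, 100)$mean, 0.48, tolerance = 1e-3)
  # fluctuating box: mean equals the brute-force frame average
  areas <- seq(47, 49, length.out = 25)
  boxes <- cbind(sqrt(areas), sqrt(areas), 5)
  xyz <- array(0.5, c(1, 3, 25))
  top <- data.frame(species = "A", molecule = 1, atom = "X", mass = 1,
                    leaflet = "upper")
  trf <- trajectory(xyz, boxes, seq_len(25) - 1, top)
  expect_equal(compute_area_per_lipid(trf, 100)$mean, mean(areas) / 100,
               tolerance = 1e-12)
  expect_equal(compute_area_per_lipid(trf, 100)$mean, 0.48, tolerance = 1e-3)
  expect_error(compute_area_per_lipid(tr, 0), "> 0")
})

test_that("d_PP is the leaflet P-plane separation and is translation invariant", {
  pos <- rbind(c(1, 1, 2), c(2, 2, 2), c(1, 1, -2), c(2, 2, -2))
  tr <- make_point_traj(pos, atom = "P",
                        leaflet = c("upper", "upper", "lower", "lower"))
  d <- compute_thickness_dPP(tr)
  expect_equal(d$mean, 4)
  expect_equal(d$ci, 0)
  shifted <- tr
  shifted$xyz[, 3, ] <- shifted$xyz[, 3, ] + 1
  expect_equal(compute_thickness_dPP(shifted)$mean, 4)
  solo <- make_point_traj(pos, atom = "P", leaflet = "upper")
  expect_error(compute_thickness_dPP(solo), "leaflet")
})

test_that("S_CD hits its closed-form limits", {
  expect_equal(scd_from_vectors(rbind(c(0, 0, 1))), 1)
  expect_equal(scd_from_vectors(rbind(c(0, 0, -1))), 1)
  expect_equal(scd_from_vectors(rbind(c(1, 0, 0), c(0, 1, 0))), -0.5)
  # isotropic orientations average to zero
  withr::with_seed(9, v <- matrix(stats::rnorm(3e5), ncol = 3))
  expect_lt(abs(scd_from_vectors(v)), 0.01)
  # profile on a chain trajectory stays within physical bounds
  spec <- synthetic_bilayer_spec(n_lipids_per_leaflet = 6,
                                 n_probes_per_leaflet = 1, chain_length = 5)
  tr <- gen_bilayer_config(spec, 3, seed = 1)
  p <- compute_scd_profile(tr)
  expect_true(all(p$S_CD >= -0.5 - 1e-9 & p$S_CD <= 1 + 1e-9))
})

test_that("tilt distributions are normalized and recover generator SDs", {
  spec <- synthetic_bilayer_spec(n_lipids_per_leaflet = 30,
                                 tilt_sd_near = 6, tilt_sd_mid = 6,
                                 tilt_sd_far = 6, n_probes_per_leaflet = 1,
                                 chain_length = 4)
  tr <- gen_bilayer_config(spec, 60, seed = 4)
  td <- compute_tilt_distribution(tr)
  expect_equal(sum(td$density * diff(td$edges)), 1, tolerance = 1e-9)
  expect_lt(abs(sqrt(td$variance) / 6 - 1), 0.10)
  expect_lt(abs(td$mean - 30), 1)
  expect_true(td$mean >= 0 && td$mean <= 90)
})

test_that("proximity binning partitions lipids and handles edge cases", {
  spec <- synthetic_bilayer_spec(n_lipids_per_leaflet = 16,
                                 n_probes_per_leaflet = 1, chain_length = 4)
  tr <- gen_bilayer_config(spec, 5, seed = 3)
  r <- compute_proximity_binned_tilts(tr)
  expect_equal(sum(r$counts), 5L * 2L * 16L)
  # degenerate edges empty the mid bin
  r2 <- compute_proximity_binned_tilts(tr, R_edges = c(0.7, 0.7))
  expect_equal(unname(r2$counts["mid"]), 0L)
  expect_equal(sum(r2$counts), 5L * 2L * 16L)
  # a single distant probe puts every lipid in the far bin
  pos <- rbind(c(0, 0, 1.5), c(0, 0.5, 1.5), c(5, 5, 1.5), c(5, 5, 0.5))
  tr1 <- make_point_traj(pos, box = c(12, 12, 6),
                         species = c("LIP", "LIP", "PRB", "PRB"),
                         atom = c("C1", "C3", "C1", "C3"),
                         molecule = c(1, 1, 2, 2), leaflet = "upper")
  r3 <- compute_proximity_binned_tilts(tr1, first_atom = "C1",
                                       last_atom = "C3")
  expect_equal(unname(r3$counts), c(0L, 0L, 1L))
  # no probes at all is an analysis error
  lips <- make_point_traj(pos[1:2, , drop = FALSE], species = "LIP",
                          atom = c("C1", "C3"), molecule = c(1, 1))
  expect_error(compute_proximity_binned_tilts(lips), "without probes")
})

test_that("sd_increase_percent reproduces the published gel-phase statistics", {
  v <- pna_tilt_variance_reference()
  cpna <- v[v$probe == "cPnA", ]
  tpna <- v[v$probe == "tPnA", ]
  expect_equal(sd_increase_percent(cpna$far, cpna$near), 59)
  expect_equal(sd_increase_percent(tpna$far, tpna$near), 17)
  expect_equal(sd_increase_percent(12.3, 12.3), 0)
  # strictly monotone in var_near for fixed var_far
  vals <- vapply(seq(10, 80, by = 5),
                 function(vn) sd_increase_percent(33.5, vn, round = FALSE),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(sd_increase_percent(0, 10), "> 0")
})

test_that("transverse positions measure |z - z_COM| with per-molecule CIs", {
  # a static probe atom 1.5 nm above the membrane COM (pinned at z = 0 by
  # heavy symmetric lipid atoms; the light probe is part of the bilayer COM
  # by the non-solvent convention but shifts it negligibly)
  pos <- rbind(c(1, 1, 0.5), c(1, 1, -0.5), c(1, 1, 1.5))
  tr <- make_point_traj(pos, species = c("LIP", "LIP", "PRB"),
                        atom = c("P", "P", "COO"),
                        leaflet = c("upper", "lower", "upper"),
                        mass = c(1e6, 1e6, 1))
  d <- compute_transverse_positions(tr, list(coo = list(species = "PRB")))
  expect_equal(d$mean_nm, 1.5, tolerance = 1e-5)
  expect_equal(d$ci95_nm, 0)
  # mirror-symmetric leaflets give equal upper/lower values
  pos2 <- rbind(c(0, 0, 2), c(0, 0, -2), c(1, 1, 1.2), c(1, 1, -1.2))
  tr2 <- make_point_traj(pos2, species = c("LIP", "LIP", "PRB", "PRB"),
                         atom = c("P", "P", "COO", "COO"),
                         leaflet = c("upper", "lower", "upper", "lower"))
  d2 <- compute_transverse_positions(tr2, list(
    up = list(species = "PRB", leaflet = "upper"),
    lo = list(species = "PRB", leaflet = "lower")))
  expect_lt(abs(d2$mean_nm[1] - d2$mean_nm[2]), 1e-6)
  # generator ground truth: carboxylate depth
  spec <- synthetic_bilayer_spec(n_lipids_per_leaflet = 12,
                                 n_probes_per_leaflet = 2, chain_length = 4,
                                 probe_depth = 1.9)
  tr3 <- gen_bilayer_config(spec, 20, seed = 5)
  d3 <- compute_transverse_positions(tr3,
          list(coo = list(species = "PRB", atom = "COO")))
  expect_lt(abs(d3$mean_nm - 1.9), 0.05)
  expect_error(compute_transverse_positions(tr3,
          list(x = list(species = "NOPE"))), "no atoms")
})

test_that("density profiles conserve mass, add up and locate the probe head", {
  # regular grid in z: exactly flat profile of M / (A L)
  L <- 4; nz <- 400
  z <- seq(-L / 2 + L / (2 * nz), L / 2 - L / (2 * nz), length.out = nz)
  pos <- cbind(rep(1, nz), rep(1, nz), z)
  tr <- make_point_traj(pos, box = c(3, 3, L), mass = 10)
  dp <- compute_density_profile(tr, bin_width = 0.1)
  inside <- abs(dp$z) < L / 2 - 0.1
  expect_lt(diff(range(dp$all[inside])) / mean(dp$all[inside]), 1e-9)
  amu <- 1.66053906660e-27
  expect_equal(mean(dp$all[inside]),
               nz * 10 * amu / (3 * 3 * L * 1e-27), tolerance = 1e-6)
  # species additivity
  spec <- synthetic_bilayer_spec(n_lipids_per_leaflet = 12,
                                 n_probes_per_leaflet = 2, chain_length = 4)
  tr2 <- gen_bilayer_config(spec, 10, seed = 6)
  dp2 <- compute_density_profile(tr2)
  expect_equal(dp2$all, dp2$LIP + dp2$PRB, tolerance = 1e-9)
  # carboxylate mass peak within one bin of +/- probe depth
  coo_mass <- dp2$z[which.max(dp2$PRB)]
  expect_lt(abs(abs(coo_mass) - 1.9), 0.1 + 1e-9)
  expect_error(compute_density_profile(tr2, bin_width = 0), "> 0")
})
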
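# Synthetic-data generators with known ground truth. These stand in for MD
# output: a cone-hindered rotational Brownian rotor, 2-D lateral random walks
# with common leaflet drift, a lattice bilayer with tilted segmented chains
# and probe molecules, umbrella windows drawn from an analytic PMF, and
# multiexponential ACF curves.

#' Cone-model parameters for the hindered rotor
#'
#' Describes "wobbling-in-cone" hindered rotation: a fluorophore axis
#' diffusing on the unit sphere with wobbling diffusion coefficient `D_w`,
#' confined to a cone of half-angle `theta_c` about `axis`. The associated
#' order parameter is `S = cos(theta_c) * (1 + cos(theta_c)) / 2`; the
#' long-time plateau of the rank-2 orientational ACF is `S^2`.
#'
#' @param theta_c cone half-angle in degrees, in (0, 180].
#' @param D_w wobbling diffusion coefficient in rad^2/ns, >= 0.
#' @param axis unit 3-vector for the cone axis (default bilayer normal, z).
#' @return An object of class `"cone_model_params"`.
#' @export
cone_model_params <- function(theta_c, D_w, axis = c(0, 0, 1)) {
  stopifnot_scalar(theta_c, "theta_c")
  stopifnot_scalar(D_w, "D_w", nonneg = TRUE)
  if (theta_c <= 0 || theta_c > 180) stop("theta_c must lie in (0, 180] degrees")
  if (length(axis) != 3L || !all(is.finite(axis))) stop("axis must be a finite 3-vector")
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-6) stop("axis must be a unit vector")
  structure(list(theta_c = theta_c, D_w = D_w, axis = axis / nrm),
            class = "cone_model_params")
}

#' Cone order parameter
#'
#' `S = cos(theta_c) (1 + cos(theta_c)) / 2` for a cone of half-angle
#' `theta_c` (degrees) with uniform equilibrium density.
#'
#' @param theta_c cone half-angle in degrees.
#' @return The order parameter S.
#' @export
cone_order_parameter <- function(theta_c) {
  ct <- cos(theta_c * pi / 180)
  ct * (1 + ct) / 2
}

#' Simulate cone-hindered rotational Brownian motion
#'
#' Propagates unit vectors by small tangent-plane Gaussian steps followed by
#' renormalization (spherical Brownian dynamics). The cone constraint is
#' enforced by mirror reflection of the polar angle at the cone boundary,
#' which preserves the uniform equilibrium density inside the cone. The step
#' is internally subdivided so that the RMS angular step stays below 3
#' degrees regardless of `dt`.
#'
#' @param params a [cone_model_params()] object.
#' @param n_steps number of recorded steps (>= 1).
#' @param dt time step in ns.
#' @param n_molecules number of independent rotors.
#' @param seed integer RNG seed; identical seeds give identical series.
#' @return An object of class `"orient_series"`: list with `u` (array
#'   `[n_steps, 3, n_molecules]` of unit vectors), `dt` and `time`.
#' @export
gen_hindered_rotor <- function(params, n_steps, dt, n_molecules = 1L,
                               seed = 1L) {
  if (!inherits(params, "cone_model_params")) stop("params must be cone_model_params")
  stopifnot_scalar(n_steps, "n_steps", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(n_molecules, "n_molecules", positive = TRUE)
  n_steps <- as.integer(n_steps); nm <- as.integer(n_molecules)
  thc <- params$theta_c * pi / 180
  D <- params$D_w

  # substep so RMS step angle sqrt(4 D dt_sub) < 3 deg
  max_rms <- 3 * pi / 180
  n_sub <- if (D > 0) max(1L, ceiling(4 * D * dt / max_rms^2)) else 1L
  s <- if (D > 0) sqrt(2 * D * dt / n_sub) else 0

  u <- array(NA_real_, c(n_steps, 3, nm))
  withr::with_seed(as.integer(seed), {
    # uniform initial density inside the cone: cos(theta) ~ U[cos thc, 1]
    cz <- stats::runif(nm, cos(thc), 1)
    ph <- stats::runif(nm, 0, 2 * pi)
    sz <- sqrt(pmax(0, 1 - cz^2))
    cur <- cbind(sz * cos(ph), sz * sin(ph), cz)
    u[1, , ] <- t(cur)
    if (n_steps > 1L) {
      for (i in 2:n_steps) {
        for (k in seq_len(n_sub)) {
          if (s > 0) {
            # orthonormal tangent basis at each current vector
            ref <- matrix(rep(c(0, 0, 1), each = nm), nm, 3)
            near_pole <- abs(cur[, 3]) > 0.99
            if (any(near_pole)) ref[near_pole, ] <-
                matrix(rep(c(1, 0, 0), each = sum(near_pole)), ncol = 3)
            e1 <- normalize_rows(cross_rows(cur, ref))
            e2 <- cross_rows(cur, e1)
            xi <- matrix(stats::rnorm(2L * nm, sd = s), nm, 2)
            cur <- normalize_rows(cur + xi[, 1] * e1 + xi[, 2] * e2)
            # mirror the polar angle at the cone edge
            th <- acos(clamp(cur[, 3], -1, 1))
            out <- th > thc
            if (any(out)) {
              th2 <- clamp(2 * thc - th[out], 0, thc)
              phx <- atan2(cur[out, 2], cur[out, 1])
              cur[out, ] <- cbind(sin(th2) * cos(phx), sin(th2) * sin(phx),
                                  cos(th2))
            }
          }
        }
        u[i, , ] <- t(cur)
      }
    }
  })
  if (any(abs(params$axis - c(0, 0, 1)) > 1e-12)) {
    Rm <- rotation_z_to(params$axis)
    for (j in seq_len(nm)) u[, , j] <- u[, , j] %*% t(Rm)
  }
  structure(list(u = u, dt = dt, time = (seq_len(n_steps) - 1) * dt,
                 params = params),
            class = "orient_series")
}

#' Lateral random-walk parameters
#'
#' @param D lateral diffusion coefficient, nm^2/ns, >= 0.
#' @param n_molecules number of molecules, >= 1.
#' @param dt time step, ns, > 0.
#' @param drift optional per-step common leaflet displacement: a matrix
#'   `[n_steps - 1, 2]` of (x, y) increments in nm added to every molecule.
#' @return An object of class `"lateral_walk_params"`.
#' @export
lateral_walk_params <- function(D, n_molecules, dt, drift = NULL) {
  stopifnot_scalar(D, "D")
  if (D < 0) stop("diffusion coefficient D must be >= 0")
  stopifnot_scalar(n_molecules, "n_molecules", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  if (!is.null(drift)) {
    drift <- as.matrix(drift)
    if (ncol(drift) != 2L || !all(is.finite(drift)))
      stop("drift must be a finite matrix with 2 columns")
  }
  structure(list(D = D, n_molecules = as.integer(n_molecules), dt = dt,
                 drift = drift),
            class = "lateral_walk_params")
}

#' Simulate 2-D lateral random walks with common leaflet drift
#'
#' Each molecule performs an independent Gaussian walk with per-axis increment
#' variance `2 D dt`; an optional common drift series is added identically to
#' all molecules (emulating leaflet centre-of-mass motion). All molecules are
#' labelled as one leaflet.
#'
#' @param params a [lateral_walk_params()] object.
#' @param n_steps number of recorded positions (>= 2).
#' @param seed integer RNG seed.
#' @return An object of class `"lateral_walk"`: list with `pos` (array
#'   `[n_steps, 2, n_molecules]`, nm), `dt`, `time`, and the applied
#'   cumulative `drift` path (`[n_steps, 2]`).
#' @export
gen_lateral_walk <- function(params, n_steps, seed = 1L) {
  if (!inherits(params, "lateral_walk_params")) stop("params must be lateral_walk_params")
  stopifnot_scalar(n_steps, "n_steps", positive = TRUE)
  n_steps <- as.integer(n_steps)
  if (n_steps < 2L) stop("n_steps must be >= 2")
  nm <- params$n_molecules
  s <- sqrt(2 * params$D * params$dt)
  drift_path <- matrix(0, n_steps, 2)
  if (!is.null(params$drift)) {
    if (nrow(params$drift) < n_steps - 1L)
      stop("drift series shorter than n_steps - 1")
    drift_path[-1, ] <- apply(params$drift[seq_len(n_steps - 1L), , drop = FALSE],
                              2, cumsum)
  }
  pos <- array(0, c(n_steps, 2, nm))
  withr::with_seed(as.integer(seed), {
    for (j in seq_len(nm)) {
      inc <- matrix(stats::rnorm(2L * (n_steps - 1L), sd = s), n_steps - 1L, 2)
      pos[-1, , j] <- apply(inc, 2, cumsum)
    }
  })
  for (j in seq_len(nm)) pos[, , j] <- pos[, , j] + drift_path
  structure(list(pos = pos, dt = params$dt,
                 time = (seq_len(n_steps) - 1) * params$dt,
                 drift = drift_path, params = params),
            class = "lateral_walk")
}

#' Synthetic bilayer specification
#'
#' Describes a two-leaflet lattice bilayer with tilted segmented chains and
#' probe molecules at a stated carboxylate depth. Lipids near a probe draw
#' their per-frame chain tilt from a wider distribution than distant ones
#' (near / mid / far proximity bins at centre-of-mass distances R < 0.7 nm,
#' 0.7-1.2 nm and > 1.2 nm by default).
#'
#' @param n_lipids_per_leaflet lipids per leaflet (probes are extra and
#'   occupy their own lattice sites).
#' @param lattice_spacing in-plane lattice constant, nm.
#' @param chain_length number of chain beads below the head bead.
#' @param d_PP_true separation of the two phosphate planes, nm.
#' @param tilt_mean mean chain tilt, degrees (gel-like default 30).
#' @param tilt_sd_near,tilt_sd_mid,tilt_sd_far per-proximity-bin tilt SDs,
#'   degrees.
#' @param n_probes_per_leaflet probes per leaflet (<= lipids per leaflet).
#' @param probe_depth carboxylate |z| distance from the bilayer centre, nm.
#' @param bond_length bead-to-bead distance along the chain, nm.
#' @param masses named vector of bead masses in amu (`P`, `C`, `COO`).
#' @param R_edges proximity bin edges in nm, default `c(0.7, 1.2)`.
#' @return An object of class `"bilayer_spec"`.
#' @export
synthetic_bilayer_spec <- function(n_lipids_per_leaflet = 62L,
                                   lattice_spacing = 0.65,
                                   chain_length = 8L,
                                   d_PP_true = 4.0,
                                   tilt_mean = 30,
                                   tilt_sd_near = 9.2,
                                   tilt_sd_mid = 8.0,
                                   tilt_sd_far = 5.8,
                                   n_probes_per_leaflet = 2L,
                                   probe_depth = 1.9,
                                   bond_length = 0.125,
                                   masses = c(P = 94.97, C = 14.03, COO = 44.01),
                                   R_edges = c(0.7, 1.2)) {
  stopifnot_scalar(n_lipids_per_leaflet, "n_lipids_per_leaflet", positive = TRUE)
  stopifnot_scalar(lattice_spacing, "lattice_spacing", positive = TRUE)
  stopifnot_scalar(chain_length, "chain_length", positive = TRUE)
  stopifnot_scalar(d_PP_true, "d_PP_true", positive = TRUE)
  stopifnot_scalar(probe_depth, "probe_depth", positive = TRUE)
  stopifnot_scalar(bond_length, "bond_length", positive = TRUE)
  for (nmv in c("tilt_sd_near", "tilt_sd_mid", "tilt_sd_far"))
    stopifnot_scalar(get(nmv), nmv, nonneg = TRUE)
  if (n_probes_per_leaflet > n_lipids_per_leaflet)
    stop("probe count exceeds lipids per leaflet")
  if (!all(c("P", "C", "COO") %in% names(masses)))
    stop("masses must name P, C and COO beads")
  structure(list(n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
                 lattice_spacing = lattice_spacing,
                 chain_length = as.integer(chain_length),
                 d_PP_true = d_PP_true, tilt_mean = tilt_mean,
                 tilt_sd_near = tilt_sd_near, tilt_sd_mid = tilt_sd_mid,
                 tilt_sd_far = tilt_sd_far,
                 n_probes_per_leaflet = as.integer(n_probes_per_leaflet),
                 probe_depth = probe_depth, bond_length = bond_length,
                 masses = masses, R_edges = R_edges),
            class = "bilayer_spec")
}

# fold a normal draw into [0, 90] degrees
fold_tilt <- function(x) {
  x <- abs(x)
  x <- x %% 180
  ifelse(x > 90, 180 - x, x)
}

#' Generate a synthetic bilayer trajectory
#'
#' Builds a square-lattice bilayer symmetric about z = 0: head (`P`) beads at
#' z = +/- `d_PP_true / 2`, chains of `chain_length` beads descending toward
#' the midplane at per-frame random tilt angles, and probe molecules (species
#' `"PRB"`) whose carboxylate (`COO`) bead sits at |z| = `probe_depth`. Chain
#' tilts are drawn from normal distributions (folded to [0, 90] degrees) whose
#' SD depends on the lipid's proximity bin relative to the nearest same-leaflet
#' probe; in-plane positions are fixed so the bin assignment is stable.
#'
#' @param spec a [synthetic_bilayer_spec()] object.
#' @param n_frames number of frames.
#' @param seed integer RNG seed.
#' @param dt frame spacing in ns.
#' @return A `"traj"` object; the per-lipid proximity bins used by the
#'   generator are stored in `attr(, "proximity_bin")`.
#' @export
gen_bilayer_config <- function(spec, n_frames, seed = 1L, dt = 1) {
  if (!inherits(spec, "bilayer_spec")) stop("spec must be a synthetic_bilayer_spec")
  stopifnot_scalar(n_frames, "n_frames", positive = TRUE)
  n_frames <- as.integer(n_frames)
  nl <- spec$n_lipids_per_leaflet
  np <- spec$n_probes_per_leaflet
  n_sites <- nl + np
  m <- ceiling(sqrt(n_sites))
  if (np > n_sites) stop("probe count exceeds available lattice sites")
  a <- spec$lattice_spacing
  Lx <- m * a
  sites <- expand.grid(ix = 0:(m - 1), iy = 0:(m - 1))[seq_len(n_sites), ]
  xy <- cbind((sites$ix + 0.5) * a, (sites$iy + 0.5) * a)

  # probe sites: nearest lattice sites to well-separated anchor points
  anchors <- matrix(c(0.25, 0.25, 0.75, 0.75, 0.25, 0.75, 0.75, 0.25),
                    ncol = 2, byrow = TRUE) * Lx
  probe_sites <- integer(0)
  for (k in seq_len(np)) {
    d2 <- (xy[, 1] - anchors[k, 1])^2 + (xy[, 2] - anchors[k, 2])^2
    d2[probe_sites] <- Inf
    probe_sites <- c(probe_sites, which.min(d2))
  }
  lipid_sites <- setdiff(seq_len(n_sites), probe_sites)

  zP <- spec$d_PP_true / 2
  nb <- spec$chain_length
  bl <- spec$bond_length
  ms <- spec$masses

  # proximity bin of each lipid site from in-plane minimum-image distance to
  # the nearest probe site (z offsets between lipid and probe COMs are small
  # by construction)
  bin_of <- function(sites_idx) {
    vapply(sites_idx, function(i) {
      dx <- min_image(xy[probe_sites, 1] - xy[i, 1], Lx)
      dy <- min_image(xy[probe_sites, 2] - xy[i, 2], Lx)
      r <- sqrt(min(dx^2 + dy^2))
      if (r < spec$R_edges[1]) 1L else if (r < spec$R_edges[2]) 2L else 3L
    }, integer(1))
  }
  lipid_bin <- bin_of(lipid_sites)
  sds <- c(spec$tilt_sd_near, spec$tilt_sd_mid, spec$tilt_sd_far)

  # topology: per leaflet, nl lipids (P + chain) then np probes (COO + chain)
  atoms_per_lipid <- 1L + nb
  atoms_per_probe <- 1L + nb
  n_atoms <- 2L * (nl * atoms_per_lipid + np * atoms_per_probe)
  species <- character(n_atoms); atom <- character(n_atoms)
  molecule <- integer(n_atoms); mass <- numeric(n_atoms)
  leaflet <- character(n_atoms)
  xyz <- array(NA_real_, c(n_atoms, 3, n_frames))

  build_chain <- function(x0, y0, z0, sgn, theta_deg, phi, n_beads) {
    th <- theta_deg * pi / 180
    d <- c(sin(th) * cos(phi), sin(th) * sin(phi), -sgn * cos(th))
    t(vapply(seq_len(n_beads),
             function(j) c(x0, y0, z0) + j * bl * d, numeric(3)))
  }

  withr::with_seed(as.integer(seed), {
    molid <- 0L; at <- 0L
    index <- list()
    for (lf in c(1, -1)) {
      lab <- if (lf > 0) "upper" else "lower"
      for (i in seq_len(nl)) {
        molid <- molid + 1L
        rows <- at + seq_len(atoms_per_lipid); at <- at + atoms_per_lipid
        species[rows] <- "LIP"
        atom[rows] <- c("P", paste0("C", seq_len(nb)))
        molecule[rows] <- molid
        mass[rows] <- c(ms[["P"]], rep(ms[["C"]], nb))
        leaflet[rows] <- lab
        index[[length(index) + 1L]] <-
          list(rows = rows, site = lipid_sites[i], sgn = lf,
               kind = "LIP", bin = lipid_bin[i])
      }
      for (p in seq_len(np)) {
        molid <- molid + 1L
        rows <- at + seq_len(atoms_per_probe); at <- at + atoms_per_probe
        species[rows] <- "PRB"
        atom[rows] <- c("COO", paste0("C", seq_len(nb)))
        molecule[rows] <- molid
        mass[rows] <- c(ms[["COO"]], rep(ms[["C"]], nb))
        leaflet[rows] <- lab
        index[[length(index) + 1L]] <-
          list(rows = rows, site = probe_sites[p], sgn = lf,
               kind = "PRB", bin = 3L)
      }
    }
    for (f in seq_len(n_frames)) {
      for (ent in index) {
        x0 <- xy[ent$site, 1]; y0 <- xy[ent$site, 2]
        sgn <- ent$sgn
        sd_t <- sds[ent$bin]
        theta <- fold_tilt(stats::rnorm(1, spec$tilt_mean, sd_t))
        phi <- stats::runif(1, 0, 2 * pi)
        if (ent$kind == "LIP") {
          z0 <- sgn * zP
        } else {
          z0 <- sgn * spec$probe_depth
          theta <- fold_tilt(stats::rnorm(1, spec$tilt_mean, spec$tilt_sd_far))
        }
        head <- c(x0, y0, z0)
        chain <- build_chain(x0, y0, z0, sgn, theta, phi, nb)
        xyz[ent$rows, , f] <- rbind(head, chain)
      }
    }
  })
  box <- c(Lx, Lx, spec$d_PP_true + 2)
  top <- data.frame(species = species, molecule = molecule, atom = atom,
                    mass = mass, leaflet = leaflet,
                    stringsAsFactors = FALSE)
  tr <- trajectory(xyz, box, (seq_len(n_frames) - 1) * dt, top)
  attr(tr, "proximity_bin") <- lipid_bin
  attr(tr, "spec") <- spec
  tr
}

#' Analytic PMF landscapes
#'
#' Tabulates an analytic free-energy profile G(z) on a grid, used as ground
#' truth for umbrella sampling and WHAM tests. Three functional forms:
#' * `"flat"`: G = 0 everywhere.
#' * `"harmonic"`: G = kappa z^2 / 2.
#' * `"amphiphile"`: Gaussian interfacial wells of depth `g_min` (< 0) at
#'   z = +/- `z_min` plus a Gaussian centre barrier reaching `g_barrier`
#'   above the water plateau (G = 0 far from the membrane) — the canonical
#'   shape for an amphiphile crossing a bilayer.
#'
#' @param form one of `"flat"`, `"harmonic"`, `"amphiphile"`.
#' @param z_range grid range in nm.
#' @param dz grid step in nm.
#' @param kappa harmonic constant, kJ mol^-1 nm^-2.
#' @param g_min interfacial minimum, kJ/mol (negative).
#' @param z_min location of the interfacial minimum, nm.
#' @param g_barrier centre barrier height above the water plateau, kJ/mol.
#' @param w_min,w_barrier Gaussian widths, nm.
#' @return An object of class `"analytic_pmf"`: list with `z`, `G`, `form`
#'   and the parameters.
#' @export
analytic_pmf <- function(form = c("flat", "harmonic", "amphiphile"),
                         z_range = c(-4, 4), dz = 0.01, kappa = 10,
                         g_min = -25, z_min = 1.6, g_barrier = 10,
                         w_min = 0.35, w_barrier = 0.45) {
  form <- match.arg(form)
  z <- seq(z_range[1], z_range[2], by = dz)
  G <- switch(form,
    flat = rep(0, length(z)),
    harmonic = 0.5 * kappa * z^2,
    amphiphile = {
      wells <- g_min * (exp(-(z - z_min)^2 / (2 * w_min^2)) +
                        exp(-(z + z_min)^2 / (2 * w_min^2)))
      barrier <- g_barrier * exp(-z^2 / (2 * w_barrier^2))
      wells + barrier
    })
  if (!all(is.finite(G))) stop("non-finite analytic PMF")
  structure(list(z = z, G = G, form = form,
                 params = list(kappa = kappa, g_min = g_min, z_min = z_min,
                               g_barrier = g_barrier, w_min = w_min,
                               w_barrier = w_barrier)),
            class = "analytic_pmf")
}

#' Umbrella window container
#'
#' @param center window centre z0, nm.
#' @param k harmonic force constant, kJ mol^-1 nm^-2, > 0.
#' @param samples reaction-coordinate samples, nm.
#' @param T temperature, K.
#' @return An object of class `"umbrella_window"`.
#' @export
umbrella_window <- function(center, k, samples, T = 298.15) {
  stopifnot_scalar(center, "center")
  stopifnot_scalar(k, "k", positive = TRUE)
  stopifnot_scalar(T, "T", positive = TRUE)
  samples <- as.numeric(samples)
  if (!length(samples) || !all(is.finite(samples))) stop("samples must be finite")
  structure(list(center = center, k = k, samples = samples, T = T),
            class = "umbrella_window")
}

#' Draw umbrella-window samples from an analytic PMF
#'
#' Samples each window's biased density
#' `p(z) ~ exp(-[G(z) + k (z - z0)^2 / 2] / RT)`
#' exactly by grid inverse-CDF inversion (grid step 1e-3 nm), so windows
#' contain independent samples with no autocorrelation.
#'
#' @param pmf an [analytic_pmf()] object.
#' @param window_centers window centres, nm; must lie within the PMF grid.
#' @param k force constant, kJ mol^-1 nm^-2 (default the 3000 used for
#'   0.1-nm-spaced membrane umbrella protocols).
#' @param n_samples samples per window.
#' @param T temperature, K.
#' @param seed integer RNG seed.
#' @return List of [umbrella_window()] objects.
#' @export
gen_umbrella_samples <- function(pmf, window_centers, k = 3000,
                                 n_samples = 5000, T = 298.15, seed = 1L) {
  if (!inherits(pmf, "analytic_pmf")) stop("pmf must be an analytic_pmf")
  stopifnot_scalar(k, "k", positive = TRUE)
  stopifnot_scalar(T, "T", positive = TRUE)
  stopifnot_scalar(n_samples, "n_samples", positive = TRUE)
  rng <- range(pmf$z)
  if (any(window_centers < rng[1] | window_centers > rng[2]))
    stop("window centers outside the PMF grid range")
  RT <- rt_kj(T)
  zg <- seq(rng[1], rng[2], by = 1e-3)
  Gg <- stats::approx(pmf$z, pmf$G, xout = zg)$y
  out <- vector("list", length(window_centers))
  withr::with_seed(as.integer(seed), {
    for (i in seq_along(window_centers)) {
      z0 <- window_centers[i]
      e <- Gg + 0.5 * k * (zg - z0)^2
      w <- exp(-(e - min(e)) / RT)
      # midpoint-rule CDF so that cdf[i] is the CDF *at* zg[i]; a plain
      # cumsum is the CDF half a grid step late and biases every sample
      cdf <- cumsum(w) - w / 2
      cdf <- cdf / (cdf[length(cdf)] + w[length(w)] / 2)
      u <- stats::runif(n_samples)
      # invert the CDF by monotone interpolation over unique knots
      keep <- c(TRUE, diff(cdf) > 0)
      zs <- stats::approx(cdf[keep], zg[keep], xout = u, rule = 2)$y
      out[[i]] <- umbrella_window(z0, k, zs, T)
    }
  })
  out
}

#' Multiexponential ACF model parameters
#'
#' Parameters of the hindered-rotation ACF model
#' `C(t) = sum_i a_i exp(-t / Phi_i) + a_inf`.
#'
#' @param a amplitudes, all >= 0 (up to 3).
#' @param phi correlation times in ns, > 0 wherever the amplitude is > 0.
#' @param a_inf residual amplitude in [0, 1].
#' @return An object of class `"acf_fit_params"` (fields `a`, `phi`, `a_inf`,
#'   `n_exp`; fitted objects add `ssr`, `mean_time`, `r_inf`).
#' @export
acf_fit_params <- function(a, phi, a_inf) {
  a <- unname(as.numeric(a)); phi <- unname(as.numeric(phi))
  a_inf <- unname(as.numeric(a_inf))
  if (length(a) != length(phi)) stop("a and phi must have equal length")
  if (any(a < 0)) stop("amplitudes must be >= 0")
  if (any(phi[a > 0] <= 0)) stop("correlation times must be > 0 where amplitude > 0")
  stopifnot_scalar(a_inf, "a_inf")
  if (a_inf < 0 || a_inf > 1) stop("a_inf must lie in [0, 1]")
  o <- order(phi)
  structure(list(a = a[o], phi = phi[o], a_inf = a_inf, n_exp = sum(a > 0)),
            class = "acf_fit_params")
}

# Evaluate the multiexponential model on a lag grid
eval_acf_model <- function(fit, t) {
  C <- rep(fit$a_inf, length(t))
  for (i in seq_along(fit$a))
    if (fit$a[i] > 0) C <- C + fit$a[i] * exp(-t / fit$phi[i])
  C
}

#' Generate a (noisy) multiexponential ACF curve
#'
#' Evaluates the hindered-rotation model on a lag grid and optionally adds
#' iid Gaussian noise — ground truth for fitting tests.
#'
#' @param fit an [acf_fit_params()] object.
#' @param t_grid lag times in ns.
#' @param noise_sd Gaussian noise SD (0 for a noise-free curve).
#' @param seed integer RNG seed (used only when `noise_sd > 0`).
#' @return An object of class `"acf_curve"` (fields `t`, `C`, `n_origins`).
#' @export
gen_acf_curve <- function(fit, t_grid, noise_sd = 0, seed = 1L) {
  if (!inherits(fit, "acf_fit_params")) stop("fit must be acf_fit_params")
  stopifnot_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  t_grid <- as.numeric(t_grid)
  C <- eval_acf_model(fit, t_grid)
  if (noise_sd > 0)
    withr::with_seed(as.integer(seed),
                     C <- C + stats::rnorm(length(C), sd = noise_sd))
  structure(list(t = t_grid, C = C, n_origins = rep(NA_integer_, length(t_grid)),
                 per_molecule = NULL),
            class = "acf_curve")
}
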
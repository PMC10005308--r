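# Rotational autocorrelation analysis, multiexponential hindered-rotation
# fitting, limiting-anisotropy estimation, mean squared displacement with
# leaflet-COM removal, and lateral diffusion coefficients.

# Per-series rank-2 orientational ACF via the tensor-component identity
#   P2(u(0).u(t)) = (3 sum_ij <q_ij(0) q_ij(t)> - 1)/2,  q_ij = u_i u_j,
# evaluated with FFT autocorrelations (all time origins, stride 1).
acf_p2_one <- function(u, nlag) {
  n <- nrow(u)
  comp <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  wts <- c(1, 1, 1, 2, 2, 2)
  s <- numeric(n)
  for (k in seq_along(comp)) {
    q <- u[, comp[[k]][1]] * u[, comp[[k]][2]]
    s <- s + wts[k] * acf_sums_fft(q)
  }
  lags <- seq_len(nlag)
  (1.5 * s[lags] / (n - lags + 1) - 0.5)
}

#' Rotational autocorrelation function
#'
#' `C(t) = < P2( u(xi) . u(xi + t) ) >`, the time autocorrelation of the
#' second Legendre polynomial of the reorientation angle of a unit axis,
#' averaged over all time origins `xi` and over molecules. Proportional to
#' the fluorescence anisotropy decay `r(t)` (constant `r0`) when the axis
#' tracks the transition dipole. Accepts either an orientation series from
#' [gen_hindered_rotor()] or a trajectory plus an axis specification (for a
#' fluorophore long axis such as the C9 -> C16 vector of a polyene probe).
#'
#' @param x an `"orient_series"` or `"traj"` object.
#' @param axis_spec for trajectories: list with `species`, `from`, `to`
#'   (atom names of the axis endpoints).
#' @param max_lag_fraction largest lag as a fraction of the series duration.
#' @param ... passed between methods.
#' @return An object of class `"acf_curve"`: `t` (ns), `C` (molecule
#'   average), `n_origins` per lag, and `per_molecule` (matrix of
#'   per-molecule curves).
#' @export
compute_rotational_acf <- function(x, ...) UseMethod("compute_rotational_acf")

#' @rdname compute_rotational_acf
#' @export
compute_rotational_acf.orient_series <- function(x, max_lag_fraction = 0.5,
                                                 ...) {
  n <- dim(x$u)[1]
  if (n < 2L) stop("need at least 2 frames")
  nlag <- max(2L, floor(n * max_lag_fraction))
  nm <- dim(x$u)[3]
  per <- vapply(seq_len(nm),
                function(j) acf_p2_one(x$u[, , j], nlag), numeric(nlag))
  per <- matrix(per, nrow = nlag)
  lags <- seq_len(nlag) - 1L
  structure(list(t = lags * x$dt, C = rowMeans(per),
                 n_origins = n - lags, per_molecule = per),
            class = "acf_curve")
}

#' @rdname compute_rotational_acf
#' @export
compute_rotational_acf.traj <- function(x, axis_spec, max_lag_fraction = 0.5,
                                        ...) {
  i1 <- select_atoms(x, species = axis_spec$species, atom = axis_spec$from)
  i2 <- select_atoms(x, species = axis_spec$species, atom = axis_spec$to)
  m1 <- x$top$molecule[i1]; m2 <- x$top$molecule[i2]
  common <- intersect(m1, m2)
  if (!length(common)) stop("axis atoms not found per molecule")
  i1 <- i1[match(common, m1)]; i2 <- i2[match(common, m2)]
  nf <- n_frames(x)
  u <- array(NA_real_, c(nf, 3, length(common)))
  for (f in seq_len(nf)) {
    v <- x$xyz[i2, , f, drop = FALSE][, , 1] - x$xyz[i1, , f, drop = FALSE][, , 1]
    if (is.null(dim(v))) v <- matrix(v, ncol = 3)
    if (any(row_norms(v) < 1e-12)) stop("zero-length axis vector")
    u[f, , ] <- t(normalize_rows(v))
  }
  dt <- if (nf > 1L) stats::median(diff(x$time)) else 1
  compute_rotational_acf.orient_series(
    structure(list(u = u, dt = dt), class = "orient_series"),
    max_lag_fraction = max_lag_fraction)
}

# SSR of the n-exponential + constant model for a packed parameter vector
.acf_ssr <- function(par, t, C, n) {
  a <- par[seq_len(n)]
  phi <- exp(par[n + seq_len(n)])
  ainf <- par[2L * n + 1L]
  pred <- rep(ainf, length(t))
  for (i in seq_len(n)) pred <- pred + a[i] * exp(-t / phi[i])
  sum((C - pred)^2)
}

# Analytic SSR gradient wrt (a_1..a_n, log phi_1..log phi_n, a_inf)
.acf_ssr_grad <- function(par, t, C, n) {
  a <- par[seq_len(n)]
  phi <- exp(par[n + seq_len(n)])
  ainf <- par[2L * n + 1L]
  E <- vapply(phi, function(p) exp(-t / p), numeric(length(t)))
  pred <- as.vector(E %*% a) + ainf
  r <- C - pred
  ga <- as.vector(-2 * crossprod(E, r))
  gp <- vapply(seq_len(n),
               function(i) -2 * sum(r * a[i] * E[, i] * t / phi[i]),
               numeric(1))
  c(ga, gp, -2 * sum(r))
}

# Given trial correlation times, get amplitudes by linear projection
# (clipped into bounds) and the resulting SSR - cheap start ranking.
.acf_linear_start <- function(phis, t, C) {
  X <- cbind(vapply(phis, function(p) exp(-t / p), numeric(length(t))), 1)
  cf <- tryCatch(stats::lm.fit(X, C)$coefficients, error = function(e) NULL)
  if (is.null(cf) || anyNA(cf)) cf <- c(rep(0.1, length(phis)), mean(C))
  n <- length(phis)
  a <- clamp(cf[seq_len(n)], 0, 2)
  ainf <- clamp(cf[n + 1L], 0, 1)
  list(par = c(a, log(phis), ainf))
}

fit_acf_order <- function(t, C, n) {
  tmax <- max(t)
  tpos <- min(t[t > 0])
  lo <- c(rep(0, n), rep(log(tpos / 5), n), 0)
  hi <- c(rep(2, n), rep(log(50 * tmax), n), 1)
  # deterministic multistart: log-spaced correlation-time combinations
  cand <- exp(seq(log(tpos), log(5 * tmax), length.out = 8))
  combos <- utils::combn(cand, n, simplify = FALSE)
  starts <- lapply(combos, .acf_linear_start, t = t, C = C)
  ssr0 <- vapply(starts, function(s) .acf_ssr(s$par, t, C, n), numeric(1))
  top <- order(ssr0)[seq_len(min(6L, length(starts)))]
  best <- NULL
  for (k in top) {
    fit <- tryCatch(
      stats::optim(starts[[k]]$par, .acf_ssr, gr = .acf_ssr_grad,
                   t = t, C = C, n = n,
                   method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 1000, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("multiexponential fit failed to converge from all starts")
  # polish the winner once more
  fit <- tryCatch(
    stats::optim(best$par, .acf_ssr, gr = .acf_ssr_grad, t = t, C = C, n = n,
                 method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = 2000, factr = 1e2)),
    error = function(e) best)
  if (fit$value <= best$value) best <- fit
  a <- best$par[seq_len(n)]
  phi <- exp(best$par[n + seq_len(n)])
  ainf <- best$par[2L * n + 1L]
  list(a = a, phi = phi, a_inf = ainf, ssr = best$value)
}

#' Fit the multiexponential hindered-rotation model to an ACF
#'
#' Bounded nonlinear least squares of
#' `C(t) = sum_i a_i exp(-t / Phi_i) + a_inf` with `a_i >= 0`,
#' `Phi_i > 0` and `0 <= a_inf <= 1` (no sum-to-one constraint). The model
#' order is chosen as the smallest number of exponentials such that adding
#' one more improves the SSR by less than 1%. Initialization is a fixed,
#' deterministic multistart over log-spaced correlation times, so repeated
#' fits give identical results.
#'
#' @param curve an `"acf_curve"` object.
#' @param n_exp_max maximum number of exponential terms (default 3).
#' @return An `"acf_fit_params"` object with `a`, `phi` (sorted ascending),
#'   `a_inf`, `n_exp`, `ssr`, `mean_time` (`sum a_i Phi_i`, ns) and `r_inf`
#'   (`0.4 * a_inf`).
#' @export
fit_acf <- function(curve, n_exp_max = 3L) {
  if (!inherits(curve, "acf_curve")) stop("curve must be an acf_curve")
  t <- curve$t; C <- curve$C
  ok <- is.finite(C)
  t <- t[ok]; C <- C[ok]
  if (length(t) < 10L) stop("need at least 10 lag points to fit")
  fits <- list(fit_acf_order(t, C, 1L))
  n_sel <- 1L
  floor_ssr <- 1e-12 * length(t)
  while (n_sel < n_exp_max) {
    if (fits[[n_sel]]$ssr < floor_ssr) break
    nxt <- fit_acf_order(t, C, n_sel + 1L)
    impr <- (fits[[n_sel]]$ssr - nxt$ssr) / fits[[n_sel]]$ssr
    fits[[n_sel + 1L]] <- nxt
    if (impr < 0.01) break
    n_sel <- n_sel + 1L
  }
  b <- fits[[n_sel]]
  out <- acf_fit_params(b$a, b$phi, clamp(b$a_inf, 0, 1))
  out$ssr <- b$ssr
  out$mean_time <- sum(out$a * out$phi)
  out$r_inf <- 0.4 * out$a_inf
  out
}

#' @export
print.acf_fit_params <- function(x, ...) {
  cat(sprintf("ACF fit: %d exponential term(s) + residual\n", x$n_exp))
  for (i in seq_along(x$a))
    cat(sprintf("  a%d = %.4g, Phi%d = %.4g ns\n", i, x$a[i], i, x$phi[i]))
  cat(sprintf("  a_inf = %.4g", x$a_inf))
  if (!is.null(x$ssr)) cat(sprintf("  (SSR %.3g)", x$ssr))
  cat("\n")
  invisible(x)
}

#' Limiting anisotropy from the residual ACF amplitude
#'
#' `r_inf = r0 * a_inf`, the limiting fluorescence anisotropy implied by the
#' residual ACF amplitude, with fundamental anisotropy `r0` (theoretical
#' maximum 2/5). Reported to two decimals by convention.
#'
#' @param fit an `"acf_fit_params"` object (fitted or constructed).
#' @param r0 fundamental anisotropy (default 2/5).
#' @return List with `r0`, `r_inf` (full precision) and `r_inf_reported`
#'   (two decimals).
#' @export
anisotropy_estimate <- function(fit, r0 = 2 / 5) {
  if (!inherits(fit, "acf_fit_params")) stop("fit must be acf_fit_params")
  stopifnot_scalar(r0, "r0", nonneg = TRUE)
  if (r0 > 0.4 + 1e-9) stop("r0 cannot exceed the theoretical maximum 2/5")
  r <- r0 * fit$a_inf
  list(r0 = r0, r_inf = r, r_inf_reported = round(r, 2))
}

#' Mean rotational correlation time
#'
#' Analytic time integral of the decaying part of the fitted ACF model:
#' `<Phi> = sum_i a_i Phi_i` (ns). Reported to two significant figures by
#' convention.
#'
#' @param fit an `"acf_fit_params"` object.
#' @return List with `mean_time` (ns, full precision) and
#'   `mean_time_reported` (two significant figures).
#' @export
mean_correlation_time <- function(fit) {
  if (!inherits(fit, "acf_fit_params")) stop("fit must be acf_fit_params")
  mt <- sum(fit$a * fit$phi)
  list(mean_time = mt, mean_time_reported = signif(mt, 2))
}

# FFT-based MSD of one coordinate series (vector x), all time origins.
# Standard two-sum decomposition: MSD(m) = (S1(m) - 2 S2(m)) / (n - m).
msd_one <- function(x) {
  n <- length(x)
  s2 <- acf_sums_fft(x)
  d <- x * x
  ss <- 2 * sum(d)
  s1 <- numeric(n)
  s1[1] <- ss
  for (m in 2:n) {
    ss <- ss - d[m - 1] - d[n - m + 2]
    s1[m] <- ss
  }
  (s1 - 2 * s2) / (n - seq_len(n) + 1)
}

#' In-plane mean squared displacement
#'
#' `MSD(t) = < | r_i(t0 + t) - r_i(t0) |^2 >` of the in-plane (x, y)
#' molecular centre of mass, averaged over molecules and all time origins.
#' With `leaflet_com_removal = TRUE` (default) each frame's leaflet centre of
#' mass is subtracted before differencing, removing common leaflet drift.
#' Accepts a [gen_lateral_walk()] result or a trajectory plus a molecule
#' selection.
#'
#' @param x a `"lateral_walk"` or `"traj"` object.
#' @param sel for trajectories: list with `species` (and optional `atom`).
#' @param leaflet_com_removal subtract the per-frame leaflet COM.
#' @param max_lag_fraction largest lag as a fraction of the duration.
#' @param ... passed between methods.
#' @return An object of class `"msd_curve"`: data.frame with `t` (ns) and
#'   `msd` (nm^2); attribute `"com_removed"`.
#' @export
compute_msd <- function(x, ...) UseMethod("compute_msd")

#' @rdname compute_msd
#' @export
compute_msd.lateral_walk <- function(x, leaflet_com_removal = TRUE,
                                     max_lag_fraction = 0.5, ...) {
  pos <- x$pos
  n <- dim(pos)[1]; nm <- dim(pos)[3]
  if (leaflet_com_removal) {
    com <- apply(pos, c(1, 2), mean)
    for (j in seq_len(nm)) pos[, , j] <- pos[, , j] - com
  }
  nlag <- max(2L, floor(n * max_lag_fraction))
  acc <- numeric(nlag)
  for (j in seq_len(nm))
    acc <- acc + msd_one(pos[, 1, j])[seq_len(nlag)] +
                 msd_one(pos[, 2, j])[seq_len(nlag)]
  msd <- acc / nm
  msd[1] <- 0
  out <- data.frame(t = (seq_len(nlag) - 1) * x$dt, msd = msd)
  structure(out, class = c("msd_curve", "data.frame"),
            com_removed = leaflet_com_removal)
}

#' @rdname compute_msd
#' @export
compute_msd.traj <- function(x, sel, leaflet_com_removal = TRUE,
                             max_lag_fraction = 0.5, ...) {
  idx <- do.call(select_atoms, c(list(x), sel))
  if (!length(idx)) stop("empty selection")
  lf <- unique(tapply(x$top$leaflet[idx], x$top$molecule[idx],
                      function(l) length(unique(l))))
  if (any(lf > 1L)) stop("molecule spans both leaflets; assignment ambiguous")
  nf <- n_frames(x)
  cm0 <- molecule_coms(x, idx, 1L)
  nmol <- length(cm0$mol)
  pos <- array(NA_real_, c(nf, 2, nmol))
  leaf <- cm0$leaflet
  for (f in seq_len(nf)) {
    cm <- molecule_coms(x, idx, f)
    pos[f, , ] <- t(cm$com[match(cm0$mol, cm$mol), 1:2, drop = FALSE])
  }
  if (leaflet_com_removal) {
    for (lv in unique(leaf)) {
      j <- which(leaf == lv)
      com <- apply(pos[, , j, drop = FALSE], c(1, 2), mean)
      for (jj in j) pos[, , jj] <- pos[, , jj] - com
    }
  }
  wrap <- structure(list(pos = pos,
                         dt = if (nf > 1) stats::median(diff(x$time)) else 1),
                    class = "lateral_walk")
  compute_msd.lateral_walk(wrap, leaflet_com_removal = FALSE,
                           max_lag_fraction = max_lag_fraction)
}

#' Lateral diffusion coefficient from an MSD curve
#'
#' Einstein relation for 2-D diffusion: least-squares slope of MSD(t) over
#' the fit window, divided by 4, converted from nm^2/ns to cm^2/s
#' (factor 1e-5).
#'
#' @param msd an `"msd_curve"` object.
#' @param fit_window_fractions window as fractions of the largest lag.
#' @return List with `D_lat` (cm^2/s), `D_nm2_ns`, `fit_window` (ns),
#'   `r_squared` and `n_points`.
#' @export
estimate_dlat <- function(msd, fit_window_fractions = c(0.1, 0.5)) {
  if (!inherits(msd, "msd_curve")) stop("msd must be an msd_curve")
  tmax <- max(msd$t)
  w <- fit_window_fractions * tmax
  keep <- msd$t >= w[1] & msd$t <= w[2]
  if (sum(keep) < 4L) stop("fewer than 4 points in the fit window")
  fit <- stats::lm(msd ~ t, data = msd[keep, ])
  slope <- unname(stats::coef(fit)[2])
  # R^2 by hand: summary.lm warns on exact synthetic lines
  sstot <- sum((msd$msd[keep] - mean(msd$msd[keep]))^2)
  r2 <- if (sstot > 0) 1 - sum(stats::residuals(fit)^2) / sstot else 1
  D <- slope / 4
  list(D_lat = D * 1e-5, D_nm2_ns = D, fit_window = w,
       r_squared = r2, n_points = sum(keep))
}
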
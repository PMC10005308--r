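# Structural and ordering analyses: area per lipid, P-P thickness, deuterium
# order parameters, tilt distributions (optionally conditioned on probe
# proximity), transverse positions and mass density profiles.

#' Area per lipid
#'
#' Per-frame area per lipid, `a = box_x * box_y / n_lipids_per_leaflet`,
#' plus its mean and a 95% confidence half-width over frames. Frames are
#' generally autocorrelated, so the CI is indicative only.
#'
#' @param tr a `"traj"` object.
#' @param n_lipids_per_leaflet number of phospholipids in each leaflet.
#' @return An object of class `"bilayer_summary"` with fields `series`,
#'   `mean`, `ci`, `quantity = "area_per_lipid"` (nm^2).
#' @export
compute_area_per_lipid <- function(tr, n_lipids_per_leaflet) {
  stopifnot_scalar(n_lipids_per_leaflet, "n_lipids_per_leaflet", positive = TRUE)
  a <- tr$box[, 1] * tr$box[, 2] / n_lipids_per_leaflet
  structure(list(series = a, mean = mean(a), ci = ci95(a),
                 quantity = "area_per_lipid", units = "nm^2"),
            class = "bilayer_summary")
}

#' @export
print.bilayer_summary <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.2g %s (mean over %d frames)\n",
              x$quantity, x$mean, x$ci, x$units, length(x$series)))
  invisible(x)
}

#' Bilayer thickness from phosphate planes
#'
#' Per-frame distance between the mean z of the selected atoms in the upper
#' and lower leaflets (`d_PP` when the selector picks P atoms).
#'
#' @param tr a `"traj"` object.
#' @param species,atom selection of the reference atoms (default lipid `P`).
#' @return A `"bilayer_summary"` with `quantity = "d_PP"` (nm).
#' @export
compute_thickness_dPP <- function(tr, species = NULL, atom = "P") {
  up <- select_atoms(tr, species = species, atom = atom, leaflet = "upper")
  lo <- select_atoms(tr, species = species, atom = atom, leaflet = "lower")
  if (!length(up) || !length(lo))
    stop("selector matches no atoms in one of the leaflets")
  d <- vapply(seq_len(n_frames(tr)),
              function(f) mean(tr$xyz[up, 3, f]) - mean(tr$xyz[lo, 3, f]),
              numeric(1))
  structure(list(series = d, mean = mean(d), ci = ci95(d),
                 quantity = "d_PP", units = "nm"),
            class = "bilayer_summary")
}

#' Deuterium order parameter from C-H unit vectors
#'
#' `S_CD = < 3 cos^2(theta_CH) - 1 > / 2` where `theta_CH` is the angle of
#' each C-H vector to the bilayer normal (z).
#'
#' @param v matrix of unit C-H vectors (n x 3).
#' @return The scalar S_CD in [-0.5, 1].
#' @export
scd_from_vectors <- function(v) {
  v <- as.matrix(v)
  if (ncol(v) != 3L) stop("v must have 3 columns")
  cz <- v[, 3] / row_norms(v)
  mean(p2(cz))
}

# Reconstruct the two C-H unit vectors at an interior chain carbon with
# neighbours p (previous) and n (next), assuming tetrahedral geometry.
# Degenerate (collinear) chains get the two perpendicular directions, which
# is the all-trans limit.
reconstruct_ch <- function(prev, cur, nxt) {
  a <- nxt - cur; b <- prev - cur
  n1 <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  if (sqrt(sum(n1^2)) < 1e-10) {
    # pick any direction perpendicular to the chain axis
    ref <- if (abs(a[3]) < 0.9 * sqrt(sum(a^2))) c(0, 0, 1) else c(1, 0, 0)
    n1 <- c(a[2] * ref[3] - a[3] * ref[2],
            a[3] * ref[1] - a[1] * ref[3],
            a[1] * ref[2] - a[2] * ref[1])
  }
  n1 <- n1 / sqrt(sum(n1^2))
  bis <- -(a / sqrt(sum(a^2)) + b / sqrt(sum(b^2)))
  if (sqrt(sum(bis^2)) < 1e-10) {
    bis <- c(n1[2] * a[3] - n1[3] * a[2],
             n1[3] * a[1] - n1[1] * a[3],
             n1[1] * a[2] - n1[2] * a[1])
  }
  bis <- bis / sqrt(sum(bis^2))
  half <- 0.5 * 109.47 * pi / 180
  rbind(cos(half) * bis + sin(half) * n1,
        cos(half) * bis - sin(half) * n1)
}

#' Deuterium order parameter profile along a chain
#'
#' Reconstructs C-H vectors at interior chain carbons by standard tetrahedral
#' geometry (for united-atom / bead chains without explicit hydrogens) and
#' reports one `S_CD` per carbon, averaged over frames and molecules.
#'
#' @param tr a `"traj"` object.
#' @param species chain species (default `"LIP"`).
#' @param atom_prefix chain carbons are `paste0(atom_prefix, 1:n)`.
#' @return An object of class `"scd_profile"`: data.frame with `carbon` and
#'   `S_CD`.
#' @export
compute_scd_profile <- function(tr, species = "LIP", atom_prefix = "C") {
  idx <- select_atoms(tr, species = species)
  if (!length(idx)) stop("empty chain selection")
  sub <- tr$top[idx, ]
  chain_atoms <- grep(paste0("^", atom_prefix, "[0-9]+$"), sub$atom)
  nums <- as.integer(sub("^[A-Za-z]+", "", sub$atom[chain_atoms]))
  ncarb <- max(nums)
  if (ncarb < 3L) stop("need at least 3 chain atoms to reconstruct C-H vectors")
  mols <- unique(sub$molecule)
  acc <- numeric(ncarb - 2L); cnt <- 0L
  for (f in seq_len(n_frames(tr))) {
    for (mol in mols) {
      rows <- idx[sub$molecule == mol]
      anames <- tr$top$atom[rows]
      ord <- match(paste0(atom_prefix, seq_len(ncarb)), anames)
      if (anyNA(ord)) next
      pos <- tr$xyz[rows[ord], , f]
      for (ci in 2:(ncarb - 1L)) {
        h <- reconstruct_ch(pos[ci - 1L, ], pos[ci, ], pos[ci + 1L, ])
        acc[ci - 1L] <- acc[ci - 1L] + scd_from_vectors(h)
      }
      cnt <- cnt + 1L
    }
  }
  if (cnt == 0L) stop("no complete chains found")
  structure(data.frame(carbon = 2:(ncarb - 1L), S_CD = acc / cnt),
            class = c("scd_profile", "data.frame"))
}

# tilt angles (degrees, folded to [0, 90] relative to the outward leaflet
# normal) of the terminal -> first chain vector, per molecule, one frame
tilt_angles_frame <- function(tr, f, idx_first, idx_last, sgn) {
  v <- tr$xyz[idx_first, , f, drop = FALSE][, , 1] -
       tr$xyz[idx_last, , f, drop = FALSE][, , 1]
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  nrm <- row_norms(v)
  if (any(nrm < 1e-12)) stop("zero-length chain vector")
  cz <- sgn * v[, 3] / nrm
  th <- acos(clamp(cz, -1, 1)) * 180 / pi
  ifelse(th > 90, 180 - th, th)
}

make_tilt_distribution <- function(angles, bin_width, label) {
  edges <- seq(0, 90, by = bin_width)
  if (edges[length(edges)] < 90) edges <- c(edges, 90)
  n <- length(angles)
  if (n == 0L) {
    dens <- rep(NA_real_, length(edges) - 1L)
    return(structure(list(edges = edges, density = dens, mean = NA_real_,
                          variance = NA_real_, n = 0L, label = label),
                     class = "tilt_distribution"))
  }
  h <- graphics::hist(angles, breaks = edges, plot = FALSE)
  structure(list(edges = edges, density = h$density, mean = mean(angles),
                 variance = stats::var(angles) * (n - 1) / n,
                 n = n, label = label),
            class = "tilt_distribution")
}

#' @export
print.tilt_distribution <- function(x, ...) {
  cat(sprintf("tilt distribution [%s]: n = %d, mean = %.3g deg, var = %.3g deg^2\n",
              x$label, x$n, x$mean, x$variance))
  invisible(x)
}

#' Chain tilt angle distribution
#'
#' Angle between the chain long axis (terminal -> first chain atom) and the
#' outward leaflet normal, folded to [0, 90] degrees, pooled over frames and
#' molecules. The density integrates to 1; mean and (population) variance are
#' computed from the raw pooled angles.
#'
#' @param tr a `"traj"` object.
#' @param species chain species.
#' @param first_atom,last_atom atom names of the first and terminal chain
#'   atoms.
#' @param bin_width histogram bin width in degrees.
#' @param label condition label stored in the result.
#' @return An object of class `"tilt_distribution"`.
#' @export
compute_tilt_distribution <- function(tr, species = "LIP", first_atom = "C1",
                                      last_atom = NULL, bin_width = 1,
                                      label = "all") {
  stopifnot_scalar(bin_width, "bin_width", positive = TRUE)
  if (is.null(last_atom)) last_atom <- last_chain_atom(tr, species)
  prep <- chain_ends(tr, species, first_atom, last_atom)
  angles <- unlist(lapply(seq_len(n_frames(tr)), function(f)
    tilt_angles_frame(tr, f, prep$first, prep$last, prep$sgn)))
  make_tilt_distribution(angles, bin_width, label)
}

# highest-numbered chain carbon for a species
last_chain_atom <- function(tr, species) {
  at <- tr$top$atom[tr$top$species %in% species]
  nums <- suppressWarnings(as.integer(sub("^C", "", at[grepl("^C[0-9]+$", at)])))
  if (!length(nums) || all(is.na(nums))) stop("cannot infer terminal chain atom")
  paste0("C", max(nums, na.rm = TRUE))
}

# matched first/terminal atom indices per molecule (+ outward-normal sign)
chain_ends <- function(tr, species, first_atom, last_atom) {
  i1 <- select_atoms(tr, species = species, atom = first_atom)
  i2 <- select_atoms(tr, species = species, atom = last_atom)
  if (!length(i1) || !length(i2)) stop("chain first/terminal atoms not found")
  m1 <- tr$top$molecule[i1]; m2 <- tr$top$molecule[i2]
  common <- intersect(m1, m2)
  i1 <- i1[match(common, m1)]; i2 <- i2[match(common, m2)]
  sgn <- ifelse(tr$top$leaflet[i1] == "upper", 1, -1)
  list(first = i1, last = i2, mol = common, sgn = sgn)
}

#' Proximity-conditioned tilt distributions
#'
#' Per frame, each lipid is assigned to a proximity bin by the 3-D distance
#' (minimum image in the membrane plane) between its centre of mass and that
#' of the nearest probe molecule in the same leaflet: near (`R < R_edges[1]`),
#' mid, far (`R > R_edges[2]`). Chain tilts are pooled per bin.
#'
#' @param tr a `"traj"` object.
#' @param lipid_species,probe_species species labels.
#' @param first_atom first chain atom of the lipid chain.
#' @param last_atom terminal chain atom (default: highest-numbered carbon).
#' @param R_edges proximity bin edges in nm, default `c(0.7, 1.2)`.
#' @param bin_width tilt histogram bin width, degrees.
#' @return A list with `near`, `mid`, `far` ([`tilt_distribution`] objects)
#'   and `counts` (per-frame-summed bin counts; they partition the lipids).
#' @export
compute_proximity_binned_tilts <- function(tr, lipid_species = "LIP",
                                           probe_species = "PRB",
                                           first_atom = "C1", last_atom = NULL,
                                           R_edges = c(0.7, 1.2),
                                           bin_width = 1) {
  if (length(R_edges) != 2L || R_edges[1] > R_edges[2])
    stop("R_edges must be two non-decreasing values (nm)")
  lip_idx <- select_atoms(tr, species = lipid_species)
  prb_idx <- select_atoms(tr, species = probe_species)
  if (!length(prb_idx))
    stop("proximity analysis undefined without probes")
  if (is.null(last_atom)) last_atom <- last_chain_atom(tr, lipid_species)
  prep <- chain_ends(tr, lipid_species, first_atom, last_atom)
  pools <- list(near = numeric(0), mid = numeric(0), far = numeric(0))
  counts <- c(near = 0L, mid = 0L, far = 0L)
  for (f in seq_len(n_frames(tr))) {
    lip <- molecule_coms(tr, lip_idx, f)
    prb <- molecule_coms(tr, prb_idx, f)
    ang <- tilt_angles_frame(tr, f, prep$first, prep$last, prep$sgn)
    ang <- ang[match(lip$mol, prep$mol)]
    L <- tr$box[f, ]
    for (i in seq_along(lip$mol)) {
      same <- prb$leaflet == lip$leaflet[i]
      if (!any(same)) { bin <- 3L } else {
        dx <- min_image(prb$com[same, 1] - lip$com[i, 1], L[1])
        dy <- min_image(prb$com[same, 2] - lip$com[i, 2], L[2])
        dzv <- prb$com[same, 3] - lip$com[i, 3]
        r <- sqrt(min(dx^2 + dy^2 + dzv^2))
        bin <- if (r < R_edges[1]) 1L else if (r < R_edges[2]) 2L else 3L
      }
      nmb <- c("near", "mid", "far")[bin]
      pools[[nmb]] <- c(pools[[nmb]], ang[i])
      counts[nmb] <- counts[nmb] + 1L
    }
  }
  list(near = make_tilt_distribution(pools$near, bin_width, "near"),
       mid = make_tilt_distribution(pools$mid, bin_width, "mid"),
       far = make_tilt_distribution(pools$far, bin_width, "far"),
       counts = counts)
}

#' Percent increase in tilt standard deviation
#'
#' `100 * (sqrt(var_near / var_far) - 1)`, the percentage by which the tilt
#' SD of lipids nearest a probe exceeds that of unperturbed lipids. Reported
#' rounded to the nearest integer percent by default.
#'
#' @param var_far variance of the far (R > 1.2 nm) distribution, deg^2, > 0.
#' @param var_near variance of the near (R < 0.7 nm) distribution, deg^2.
#' @param round round to the nearest integer percent (reporting convention).
#' @return Percent increase (numeric).
#' @export
sd_increase_percent <- function(var_far, var_near, round = TRUE) {
  stopifnot_scalar(var_far, "var_far")
  stopifnot_scalar(var_near, "var_near", nonneg = TRUE)
  if (var_far <= 0) stop("var_far must be > 0")
  p <- 100 * (sqrt(var_near / var_far) - 1)
  if (round) round(p) else p
}

#' Average transverse distances to the bilayer centre of mass
#'
#' For each named group (a species + atom-name selection), computes the
#' per-frame absolute distance along the normal between the group's
#' per-molecule centre of mass and the bilayer (lipid-only) centre of mass,
#' then averages over frames and molecules. The 95% CI uses the per-molecule
#' means as independent units (frames are autocorrelated).
#'
#' @param tr a `"traj"` object.
#' @param groups named list; each element a list with `species` and
#'   optionally `atom` (vector of atom names) and `leaflet`.
#' @return data.frame with `group`, `mean_nm`, `ci95_nm`, `n_molecules`.
#' @export
compute_transverse_positions <- function(tr, groups) {
  comz <- bilayer_com_z(tr)
  res <- lapply(names(groups), function(g) {
    sel <- groups[[g]]
    idx <- select_atoms(tr, species = sel$species, atom = sel$atom,
                        leaflet = sel$leaflet)
    if (!length(idx)) stop(sprintf("group '%s' selects no atoms", g))
    per_mol <- NULL
    for (f in seq_len(n_frames(tr))) {
      cm <- molecule_coms(tr, idx, f)
      d <- abs(cm$com[, 3] - comz[f])
      if (is.null(per_mol)) {
        per_mol <- matrix(NA_real_, n_frames(tr), length(cm$mol),
                          dimnames = list(NULL, cm$mol))
      }
      per_mol[f, as.character(cm$mol)] <- d
    }
    mm <- colMeans(per_mol)
    data.frame(group = g, mean_nm = mean(mm), ci95_nm = ci95(mm),
               n_molecules = length(mm))
  })
  do.call(rbind, res)
}

#' Mass density profile along the bilayer normal
#'
#' Histogram of atomic mass along z in the bilayer-COM frame, converted to
#' kg/m^3 with bin volume = box area x bin width, averaged over frames. One
#' column per requested species plus `"all"`.
#'
#' @param tr a `"traj"` object.
#' @param species species to profile (default all present).
#' @param bin_width bin width in nm.
#' @return An object of class `"density_profile"`: data.frame with `z`
#'   (bin centres, nm) and one kg/m^3 column per species.
#' @export
compute_density_profile <- function(tr, species = NULL, bin_width = 0.1) {
  stopifnot_scalar(bin_width, "bin_width", positive = TRUE)
  if (is.null(species)) species <- unique(tr$top$species)
  comz <- bilayer_com_z(tr)
  half <- max(tr$box[, 3]) / 2
  edges <- seq(-half, half, by = bin_width)
  if (edges[length(edges)] < half) edges <- c(edges, edges[length(edges)] + bin_width)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  out <- matrix(0, length(centers), length(species) + 1L,
                dimnames = list(NULL, c(species, "all")))
  nf <- n_frames(tr)
  for (f in seq_len(nf)) {
    zrel <- tr$xyz[, 3, f] - comz[f]
    area_m2 <- tr$box[f, 1] * tr$box[f, 2] * 1e-18
    vol_m3 <- area_m2 * bin_width * 1e-9
    bin <- findInterval(zrel, edges, rightmost.closed = TRUE)
    ok <- bin >= 1L & bin <= length(centers)
    for (sp in species) {
      sel <- ok & tr$top$species == sp
      if (any(sel)) {
        msum <- rowsum(tr$top$mass[sel], bin[sel])
        ib <- as.integer(rownames(msum))
        out[ib, sp] <- out[ib, sp] + msum * .AMU_KG / vol_m3 / nf
      }
    }
  }
  out[, "all"] <- rowSums(out[, species, drop = FALSE])
  structure(cbind(data.frame(z = centers), as.data.frame(out)),
            class = c("density_profile", "data.frame"))
}
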
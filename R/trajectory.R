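#' Trajectory container
#'
#' Holds an MD-style trajectory: per-frame coordinates (nm), box vectors (nm)
#' and times (ns), together with a topology mapping every atom to a species,
#' a molecule, an atom name, a mass (amu) and a leaflet label
#' (`"upper"`, `"lower"` or `"solvent"`). The membrane normal is the z axis.
#'
#' @param xyz numeric array `[n_atoms, 3, n_frames]` of positions in nm.
#' @param box numeric matrix `[n_frames, 3]` of box edge lengths in nm
#'   (a single 3-vector is recycled over frames).
#' @param time numeric vector of frame times in ns.
#' @param topology `data.frame` with columns `species`, `molecule`, `atom`,
#'   `mass`, `leaflet` (one row per atom).
#' @return An object of class `"traj"`.
#' @export
trajectory <- function(xyz, box, time, topology) {
  if (length(dim(xyz)) == 2L) xyz <- array(xyz, c(dim(xyz), 1L))
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[2] == 3L)
  nf <- dim(xyz)[3]
  na <- dim(xyz)[1]
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) == 1L && nf > 1L) box <- box[rep(1L, nf), , drop = FALSE]
  time <- as.numeric(time)
  tr <- structure(list(xyz = xyz, box = box, time = time,
                       top = as.data.frame(topology), normal = 3L),
                  class = "traj")
  validate_trajectory(tr)
}

#' Validate a trajectory's invariants
#'
#' Checks finiteness of positions, positivity of the box, consistency of
#' per-frame atom counts, presence of topology columns and legal leaflet
#' labels. Called by [trajectory()]; exported so that readers can re-validate.
#'
#' @param tr a `"traj"` object.
#' @return `tr`, invisibly usable; errors on violation.
#' @export
validate_trajectory <- function(tr) {
  if (!inherits(tr, "traj")) stop("not a 'traj' object")
  need <- c("species", "molecule", "atom", "mass", "leaflet")
  miss <- setdiff(need, names(tr$top))
  if (length(miss)) stop("topology missing columns: ", paste(miss, collapse = ", "))
  if (nrow(tr$top) != dim(tr$xyz)[1]) stop("topology/coordinate atom-count mismatch")
  if (!all(is.finite(tr$xyz))) stop("non-finite coordinates")
  if (!all(is.finite(tr$box)) || any(tr$box <= 0)) stop("box components must be > 0")
  if (nrow(tr$box) != dim(tr$xyz)[3]) stop("box/frame count mismatch")
  if (length(tr$time) != dim(tr$xyz)[3]) stop("time/frame count mismatch")
  if (!all(tr$top$leaflet %in% c("upper", "lower", "solvent")))
    stop("leaflet labels must be 'upper', 'lower' or 'solvent'")
  if (anyNA(tr$top$molecule) || anyNA(tr$top$species)) stop("every atom needs a molecule id and species")
  tr
}

#' @export
print.traj <- function(x, ...) {
  cat(sprintf("<traj> %d atoms, %d frames, %.4g-%.4g ns\n",
              dim(x$xyz)[1], dim(x$xyz)[3], min(x$time), max(x$time)))
  cat("species:", paste(unique(x$top$species), collapse = " "), "\n")
  invisible(x)
}

n_frames <- function(tr) dim(tr$xyz)[3]

#' Select atom indices by topology attributes
#'
#' @param tr a `"traj"` object.
#' @param species,atom,leaflet,molecule optional vectors of admissible values;
#'   `NULL` means no restriction.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(tr, species = NULL, atom = NULL, leaflet = NULL,
                         molecule = NULL) {
  keep <- rep(TRUE, nrow(tr$top))
  if (!is.null(species)) keep <- keep & tr$top$species %in% species
  if (!is.null(atom)) keep <- keep & tr$top$atom %in% atom
  if (!is.null(leaflet)) keep <- keep & tr$top$leaflet %in% leaflet
  if (!is.null(molecule)) keep <- keep & tr$top$molecule %in% molecule
  which(keep)
}

# Mass-weighted centres of mass per molecule for atoms `idx` in frame `f`.
# Returns list(mol = molecule ids, com = n x 3 matrix, leaflet = labels).
molecule_coms <- function(tr, idx, f) {
  if (!length(idx)) stop("empty selection")
  mol <- tr$top$molecule[idx]
  m <- tr$top$mass[idx]
  xyz <- tr$xyz[idx, , f, drop = FALSE][, , 1]
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  mw <- rowsum(xyz * m, mol)
  mt <- rowsum(m, mol)
  com <- mw / as.vector(mt)
  ids <- as.integer(rownames(mw))
  lf <- tr$top$leaflet[idx][match(ids, mol)]
  list(mol = ids, com = com, leaflet = lf)
}

# z of the bilayer centre of mass (lipid = non-solvent atoms only) per frame.
bilayer_com_z <- function(tr) {
  idx <- which(tr$top$leaflet != "solvent")
  if (!length(idx)) stop("no lipid (non-solvent) atoms; bilayer COM undefined")
  m <- tr$top$mass[idx]
  vapply(seq_len(n_frames(tr)),
         function(f) sum(tr$xyz[idx, 3, f] * m) / sum(m), numeric(1))
}

#' Discard an initial equilibration period
#'
#' Keeps exactly the frames with `time >= discard` (half-open interval
#' `[discard, end]`).
#'
#' @param tr a `"traj"` object.
#' @param discard time in ns; frames earlier than this are dropped.
#' @return A `"traj"` object restricted to the retained frames.
#' @export
subset_time <- function(tr, discard = 0) {
  stopifnot_scalar(discard, "discard", nonneg = TRUE)
  keep <- which(tr$time >= discard)
  if (!length(keep)) stop("equilibration discard removes every frame")
  trajectory(tr$xyz[, , keep, drop = FALSE], tr$box[keep, , drop = FALSE],
             tr$time[keep], tr$top)
}
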
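# Atom-atom radial distribution functions and cumulative coordination
# numbers around probe reference groups.

#' Radial distribution function and cumulative coordination number
#'
#' 3-D spherical-shell histogram of minimum-image reference-selection
#' distances, normalized by shell volume and the mean selection density
#' (the default normalization of `gmx rdf`: bin volume times density of the
#' selection group). `N(r)` is the average number of selection atoms within
#' `r` of a reference atom. Pairs within the same molecule are excluded by
#' default so that bonded-pair artifacts cannot contaminate fixtures; the
#' density normalization always uses the full selection count.
#'
#' @param tr a `"traj"` object.
#' @param ref_sel,sel lists with `species` and optionally `atom` / `leaflet`
#'   naming the reference and selection groups.
#' @param r_max maximum distance, nm; must not exceed half the smallest box
#'   dimension.
#' @param bin_width shell width, nm.
#' @param exclude_same_molecule drop intramolecular pairs (default `TRUE`).
#' @return An object of class `"rdf_curve"`: data.frame with `r` (bin
#'   centres), `g` and `N`.
#' @export
compute_rdf <- function(tr, ref_sel, sel, r_max, bin_width = 0.01,
                        exclude_same_molecule = TRUE) {
  stopifnot_scalar(r_max, "r_max", positive = TRUE)
  stopifnot_scalar(bin_width, "bin_width", positive = TRUE)
  if (r_max > min(tr$box) / 2)
    stop("r_max exceeds half the smallest box dimension")
  ir <- do.call(select_atoms, c(list(tr), ref_sel))
  is <- do.call(select_atoms, c(list(tr), sel))
  if (!length(ir) || !length(is)) stop("empty reference or selection group")
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  mol_r <- tr$top$molecule[ir]
  mol_s <- tr$top$molecule[is]
  nf <- n_frames(tr)
  g_acc <- numeric(nb); counts_acc <- numeric(nb)
  for (f in seq_len(nf)) {
    L <- tr$box[f, ]
    rho <- length(is) / prod(L)
    pr <- tr$xyz[ir, , f, drop = FALSE][, , 1, drop = TRUE]
    ps <- tr$xyz[is, , f, drop = FALSE][, , 1, drop = TRUE]
    if (is.null(dim(pr))) pr <- matrix(pr, ncol = 3)
    if (is.null(dim(ps))) ps <- matrix(ps, ncol = 3)
    cnt <- numeric(nb)
    for (i in seq_len(nrow(pr))) {
      dx <- min_image(ps[, 1] - pr[i, 1], L[1])
      dy <- min_image(ps[, 2] - pr[i, 2], L[2])
      dz <- min_image(ps[, 3] - pr[i, 3], L[3])
      d2 <- dx^2 + dy^2 + dz^2
      drop <- d2 < 1e-20
      if (exclude_same_molecule) drop <- drop | (mol_s == mol_r[i])
      d <- sqrt(d2[!drop])
      d <- d[d < r_max]
      if (length(d)) {
        b <- findInterval(d, edges, rightmost.closed = TRUE)
        tb <- tabulate(b, nbins = nb)
        cnt <- cnt + tb
      }
    }
    g_acc <- g_acc + cnt / (nrow(pr) * shell_vol * rho)
    counts_acc <- counts_acc + cnt / nrow(pr)
  }
  structure(data.frame(r = centers, g = g_acc / nf,
                       N = cumsum(counts_acc / nf)),
            class = c("rdf_curve", "data.frame"))
}
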
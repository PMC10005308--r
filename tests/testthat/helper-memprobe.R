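# Shared fixtures and helpers, all built in code at test time.

# Uniform ideal-gas configuration in a cubic box (one frame).
make_gas_traj <- function(n = 10000, L = 5, seed = 1) {
  withr::with_seed(seed, {
    xyz <- array(stats::runif(n * 3, 0, L), c(n, 3, 1))
  })
  top <- data.frame(species = "GAS", molecule = seq_len(n), atom = "X",
                    mass = 1, leaflet = "solvent", stringsAsFactors = FALSE)
  trajectory(xyz, c(L, L, L), 0, top)
}

# Minimal hand-built trajectory: atoms at given positions, one frame.
make_point_traj <- function(pos, box = c(10, 10, 10), species = "A",
                            atom = "X", leaflet = "upper", mass = 1,
                            molecule = NULL, time = 0) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (is.null(molecule)) molecule <- seq_len(n)
  top <- data.frame(species = rep_len(species, n),
                    molecule = molecule,
                    atom = rep_len(atom, n),
                    mass = rep_len(mass, n),
                    leaflet = rep_len(leaflet, n),
                    stringsAsFactors = FALSE)
  trajectory(array(pos, c(n, 3, length(time))), box, time, top)
}

# Centred RMS deviation of a reconstructed PMF from an analytic truth,
# restricted to finite bins inside the window-centre range.
pmf_rms <- function(prof, truth_fun, centers) {
  keep <- is.finite(prof$G) & prof$z >= min(centers) & prof$z <= max(centers)
  d <- prof$G[keep] - truth_fun(prof$z[keep])
  d <- d - mean(d)
  sqrt(mean(d^2))
}

table1 <- pna_acf_reference()
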
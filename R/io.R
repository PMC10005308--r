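# Format readers and writers: the internal columnar trajectory format
# (plain text with explicit units), GRO and PDB snapshots, and umbrella
# window sample files.

#' Write a trajectory in the internal columnar text format
#'
#' Plain-text container with units declared in the header (nm, ns, amu):
#' a topology block followed by one block per frame. Full `%.17g` precision,
#' so a write/read round trip is bitwise exact.
#'
#' @param tr a `"traj"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_txt <- function(tr, path) {
  validate_trajectory(tr)
  na <- dim(tr$xyz)[1]; nf <- n_frames(tr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#memprobe-traj 1",
               "#units length=nm time=ns mass=amu",
               sprintf("#natoms %d", na),
               sprintf("#nframes %d", nf),
               "#topology species molecule atom mass leaflet"), con)
  writeLines(sprintf("%s %d %s %.17g %s", tr$top$species, tr$top$molecule,
                     tr$top$atom, tr$top$mass, tr$top$leaflet), con)
  for (f in seq_len(nf)) {
    writeLines(sprintf("#frame time=%.17g box=%.17g %.17g %.17g",
                       tr$time[f], tr$box[f, 1], tr$box[f, 2], tr$box[f, 3]),
               con)
    writeLines(sprintf("%.17g %.17g %.17g",
                       tr$xyz[, 1, f], tr$xyz[, 2, f], tr$xyz[, 3, f]), con)
  }
  invisible(path)
}

read_trajectory_txt <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#memprobe-traj"))
    stop("not an internal-format trajectory file")
  hdr <- function(key) {
    ln <- grep(paste0("^#", key, " "), lines, value = TRUE)[1]
    if (is.na(ln)) stop("format error: missing header '", key, "'")
    as.integer(strsplit(ln, " ")[[1]][2])
  }
  na <- hdr("natoms"); nf <- hdr("nframes")
  itop <- grep("^#topology", lines)[1]
  if (is.na(itop) || itop + na > length(lines)) stop("format error: truncated topology")
  tp <- utils::read.table(text = lines[(itop + 1):(itop + na)],
                          col.names = c("species", "molecule", "atom",
                                        "mass", "leaflet"),
                          colClasses = c("character", "integer", "character",
                                         "numeric", "character"))
  frame_starts <- grep("^#frame ", lines)
  if (length(frame_starts) != nf) stop("format error: frame count mismatch")
  xyz <- array(NA_real_, c(na, 3, nf))
  box <- matrix(NA_real_, nf, 3)
  tm <- numeric(nf)
  for (f in seq_len(nf)) {
    st <- frame_starts[f]
    m <- regmatches(lines[st],
                    regexec("time=([^ ]+) box=([^ ]+) ([^ ]+) ([^ ]+)", lines[st]))[[1]]
    if (length(m) != 5L) stop("format error: bad frame header")
    tm[f] <- as.numeric(m[2]); box[f, ] <- as.numeric(m[3:5])
    if (st + na > length(lines)) stop("format error: truncated frame block")
    coords <- utils::read.table(text = lines[(st + 1):(st + na)])
    if (nrow(coords) != na || ncol(coords) != 3L)
      stop("format error: atom-count mismatch in frame ", f)
    xyz[, , f] <- as.matrix(coords)
  }
  trajectory(xyz, box, tm, tp)
}

#' Write a trajectory as (multi-frame) GRO
#'
#' Standard fixed-width GRO records (positions in nm, three decimals); one
#' concatenated block per frame with the time in the title line. Leaflet
#' labels are not representable in GRO and are re-inferred on read.
#'
#' @param tr a `"traj"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(tr, path) {
  validate_trajectory(tr)
  na <- dim(tr$xyz)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(tr))) {
    writeLines(sprintf("memprobe snapshot t= %.6f", tr$time[f]), con)
    writeLines(sprintf("%5d", na), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       tr$top$molecule %% 100000L,
                       substr(tr$top$species, 1, 5),
                       substr(tr$top$atom, 1, 5),
                       seq_len(na) %% 100000L,
                       tr$xyz[, 1, f], tr$xyz[, 2, f], tr$xyz[, 3, f]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f",
                       tr$box[f, 1], tr$box[f, 2], tr$box[f, 3]), con)
  }
  invisible(path)
}

read_gro <- function(path, topology = NULL) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(0); boxes <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (i + 1L > length(lines)) stop("format error: truncated GRO file")
    title <- lines[i]
    na <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(na) || na < 1L) stop("format error: bad GRO atom count")
    if (i + 1L + na + 1L > length(lines)) stop("format error: truncated GRO frame")
    atom_lines <- lines[(i + 2L):(i + 1L + na)]
    resid <- as.integer(substr(atom_lines, 1, 5))
    resnm <- trimws(substr(atom_lines, 6, 10))
    atnm <- trimws(substr(atom_lines, 11, 15))
    x <- as.numeric(substr(atom_lines, 21, 28))
    y <- as.numeric(substr(atom_lines, 29, 36))
    z <- as.numeric(substr(atom_lines, 37, 44))
    if (anyNA(x) || anyNA(y) || anyNA(z)) stop("format error: bad GRO coordinates")
    boxv <- as.numeric(strsplit(trimws(lines[i + 1L + na + 1L]), "\\s+")[[1]])[1:3]
    tm <- regmatches(title, regexec("t=\\s*([0-9eE+.-]+)", title))[[1]]
    times <- c(times, if (length(tm) == 2L) as.numeric(tm[2]) else length(times))
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
    boxes <- rbind(boxes, boxv)
    if (length(frames) == 1L) {
      first_top <- data.frame(species = resnm, molecule = resid, atom = atnm,
                              mass = 1, leaflet = "solvent",
                              stringsAsFactors = FALSE)
    } else if (nrow(frames[[length(frames)]]) != nrow(frames[[1]])) {
      stop("format error: atom-count mismatch between GRO frames")
    }
    i <- i + 1L + na + 2L
  }
  na <- nrow(frames[[1]])
  xyz <- array(NA_real_, c(na, 3, length(frames)))
  for (f in seq_along(frames)) xyz[, , f] <- frames[[f]]
  top <- if (!is.null(topology)) topology else first_top
  if (is.null(topology)) {
    # infer leaflets from first-frame z sign relative to the mean z
    z0 <- xyz[, 3, 1]
    top$leaflet <- ifelse(z0 >= mean(z0), "upper", "lower")
  }
  trajectory(xyz, boxes, times, top)
}

read_pdb <- function(path, topology = NULL) {
  lines <- readLines(path)
  cry <- grep("^CRYST1", lines, value = TRUE)[1]
  box <- if (!is.na(cry)) as.numeric(c(substr(cry, 7, 15), substr(cry, 16, 24),
                                       substr(cry, 25, 33))) / 10 else c(1, 1, 1)
  # split into MODELs; a file without MODEL records is one frame
  model_idx <- grep("^(MODEL|END|ENDMDL)", lines)
  at <- grep("^(ATOM|HETATM)", lines)
  if (!length(at)) stop("format error: no ATOM records")
  is_model <- grepl("^MODEL", lines)
  frame_id <- cumsum(is_model)[at]
  if (all(frame_id == 0)) frame_id <- frame_id + 1L
  nfr <- max(frame_id)
  per <- split(at, frame_id)
  na <- length(per[[1]])
  if (any(vapply(per, length, integer(1)) != na))
    stop("format error: atom-count mismatch between PDB frames")
  xyz <- array(NA_real_, c(na, 3, nfr))
  for (f in seq_len(nfr)) {
    ln <- lines[per[[f]]]
    xyz[, , f] <- cbind(as.numeric(substr(ln, 31, 38)),
                        as.numeric(substr(ln, 39, 46)),
                        as.numeric(substr(ln, 47, 54))) / 10  # A -> nm
  }
  ln <- lines[per[[1]]]
  top <- if (!is.null(topology)) topology else {
    tp <- data.frame(species = trimws(substr(ln, 18, 21)),
                     molecule = as.integer(substr(ln, 23, 26)),
                     atom = trimws(substr(ln, 13, 16)),
                     mass = 1, leaflet = "solvent", stringsAsFactors = FALSE)
    z0 <- xyz[, 3, 1]
    tp$leaflet <- ifelse(z0 >= mean(z0), "upper", "lower")
    tp
  }
  trajectory(xyz, box, seq_len(nfr) - 1, top)
}

#' Load a trajectory from a recognized format
#'
#' Dispatches on the file extension: `.traj`/`.txt` (internal columnar
#' format), `.gro`, `.pdb`. Binary `.xtc`/`.trr` trajectories are not
#' supported by this package and raise a format error asking for conversion.
#' When no topology is supplied, leaflet labels are inferred from the
#' initial-frame z sign relative to the mean z.
#'
#' @param path trajectory file path.
#' @param topology optional topology `data.frame` overriding the inferred one.
#' @return A validated `"traj"` object.
#' @export
load_trajectory <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    traj = , txt = {
      tr <- read_trajectory_txt(path)
      if (!is.null(topology)) tr <- trajectory(tr$xyz, tr$box, tr$time, topology)
      tr
    },
    gro = read_gro(path, topology),
    pdb = read_pdb(path, topology),
    xtc = , trr = stop("binary XTC/TRR input is not supported; convert to GRO or the internal text format"),
    stop("unknown trajectory extension: .", ext))
}

#' Write umbrella-window samples to per-window text files
#'
#' Two-column text (time index, reaction coordinate in nm) with a metadata
#' header (`center`, `k`, `T`) — the layout common WHAM drivers consume.
#'
#' @param windows list of [umbrella_window()] objects.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_umbrella_windows <- function(windows, dir, prefix = "window") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    p <- file.path(dir, sprintf("%s_%03d.txt", prefix, i))
    con <- file(p, "w")
    writeLines(c(sprintf("# center= %.17g", w$center),
                 sprintf("# k= %.17g", w$k),
                 sprintf("# T= %.17g", w$T)), con)
    writeLines(sprintf("%d %.17g", seq_along(w$samples), w$samples), con)
    close(con)
    paths[i] <- p
  }
  invisible(paths)
}

#' Read umbrella-window sample files
#'
#' @param paths character vector of files written by
#'   [write_umbrella_windows()] (or any two-column time/coordinate text with
#'   the same `# center= / # k= / # T=` header).
#' @return List of [umbrella_window()] objects.
#' @export
read_umbrella_windows <- function(paths) {
  lapply(paths, function(p) {
    lines <- readLines(p)
    get <- function(key) {
      ln <- grep(paste0("^#\\s*", key, "="), lines, value = TRUE)[1]
      if (is.na(ln)) stop("umbrella file missing header '", key, "=': ", p)
      as.numeric(sub(paste0("^#\\s*", key, "=\\s*"), "", ln))
    }
    dat <- utils::read.table(text = lines[!startsWith(lines, "#")])
    umbrella_window(get("center"), get("k"), dat[[ncol(dat)]], get("T"))
  })
}
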
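# Trajectory input: topologies from PDB/GRO, coordinates from multi-model
# PDB or DCD (CHARMM-style), plus a minimal DCD writer so that synthetic
# trajectories can be pushed through the full file-reading path. XTC/TRR
# are not readable from R in this toolchain and are not supported.

#' Load an MD trajectory
#'
#' Reads a topology (PDB or GRO) and coordinates (multi-model PDB or DCD;
#' defaults to the topology file itself when it is multi-model) into a
#' \code{trajectory_handle}.
#'
#' @param topology Path to a PDB or GRO file defining atom names/residues.
#' @param coordinates Optional path (or vector of paths, concatenated in
#'   order) to coordinate files (PDB or DCD).
#' @param dt Interval between stored steps in seconds (before striding).
#' @param stride Keep every \code{stride}-th step; the effective step
#'   interval becomes \code{dt * stride}.
#' @param skip_time Equilibration span (seconds) discarded from the start
#'   (default 0: an analysis tool should not silently drop data).
#' @return An object of class \code{trajectory_handle}: \code{atoms} data
#'   frame (\code{name}, \code{resid}, \code{resno}, \code{chain},
#'   \code{index}), \code{xyz} array (\code{n_atoms x 3 x n_steps},
#'   Angstrom), \code{dt} (seconds, stride applied), \code{n_steps}.
#' @export
load_trajectory <- function(topology, coordinates = NULL, dt = 1e-12,
                            stride = 1L, skip_time = 0) {
  if (!file.exists(topology)) stop("topology file not found: ", topology)
  stopifnot(dt > 0, stride >= 1)
  ext <- tolower(tools::file_ext(topology))
  if (ext == "gro") {
    top <- read_gro(topology)
    atoms <- top$atoms
    xyz_top <- top$xyz
  } else {
    pdb <- bio3d::read.pdb(topology, multi = TRUE, verbose = FALSE)
    atoms <- data.frame(name = trimws(pdb$atom$elety),
                        resid = pdb$atom$resid,
                        resno = pdb$atom$resno,
                        chain = ifelse(is.na(pdb$atom$chain), "",
                                       pdb$atom$chain),
                        index = seq_len(nrow(pdb$atom)),
                        stringsAsFactors = FALSE)
    xyz_top <- pdb$xyz
  }
  na <- nrow(atoms)
  if (is.null(coordinates)) {
    xyz_mat <- as.matrix(xyz_top)
    if (is.null(dim(xyz_mat))) xyz_mat <- matrix(xyz_mat, nrow = 1)
  } else {
    frames <- lapply(coordinates, function(p) {
      if (!file.exists(p)) stop("coordinate file not found: ", p)
      cext <- tolower(tools::file_ext(p))
      if (cext == "dcd") {
        m <- bio3d::read.dcd(p, verbose = FALSE)
        as.matrix(m)
      } else {
        pp <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
        as.matrix(pp$xyz)
      }
    })
    xyz_mat <- do.call(rbind, frames)
  }
  if (ncol(xyz_mat) != 3 * na) {
    stop(sprintf(
      "atom-count mismatch: topology has %d atoms, coordinates have %d",
      na, ncol(xyz_mat) / 3))
  }
  nskip <- floor(skip_time / dt + 1e-9)
  if (nskip >= nrow(xyz_mat)) stop("skip_time discards the whole trajectory")
  keep <- seq(nskip + 1L, nrow(xyz_mat), by = stride)
  xyz <- array(NA_real_, c(na, 3, length(keep)))
  for (i in seq_along(keep)) {
    xyz[, , i] <- matrix(xyz_mat[keep[i], ], ncol = 3, byrow = TRUE)
  }
  structure(list(atoms = atoms, xyz = xyz, dt = dt * stride,
                 n_steps = length(keep)),
            class = "trajectory_handle")
}

#' @export
print.trajectory_handle <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms x %d steps, dt = %.4g s\n",
              nrow(x$atoms), x$n_steps, x$dt))
  cat("  residues:", paste(utils::head(unique(x$atoms$resid), 8),
                           collapse = ", "), "\n")
  invisible(x)
}

# minimal GRO reader (topology + single frame; nm converted to Angstrom)
read_gro <- function(path) {
  ln <- readLines(path)
  na <- as.integer(trimws(ln[2]))
  body <- ln[3:(2 + na)]
  resno <- as.integer(substr(body, 1, 5))
  resid <- trimws(substr(body, 6, 10))
  name <- trimws(substr(body, 11, 15))
  x <- as.numeric(substr(body, 21, 28)) * 10
  y <- as.numeric(substr(body, 29, 36)) * 10
  z <- as.numeric(substr(body, 37, 44)) * 10
  atoms <- data.frame(name = name, resid = resid, resno = resno,
                      chain = "", index = seq_len(na),
                      stringsAsFactors = FALSE)
  list(atoms = atoms, xyz = matrix(rbind(x, y, z), nrow = 1))
}

#' Write a DCD coordinate file
#'
#' Minimal CHARMM-style DCD writer (no unit cell, no fixed atoms),
#' readable by standard DCD readers.
#'
#' @param xyz Coordinates: \code{n_atoms x 3 x n_steps} array (Angstrom).
#' @param path Output path.
#' @export
write_dcd <- function(xyz, path) {
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[2] == 3)
  na <- dim(xyz)[1]; nf <- dim(xyz)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    # Fortran unformatted record: length prefix/suffix handled per call
    writer
  }
  wint <- function(x) writeBin(as.integer(x), con, size = 4,
                               endian = "little")
  # header record (84 bytes): "CORD" + 20 control integers
  wint(84)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf      # number of frames
  icntrl[2] <- 1       # first step
  icntrl[3] <- 1       # step interval
  icntrl[4] <- nf      # total steps
  icntrl[20] <- 24     # CHARMM version stamp
  wint(icntrl)
  wint(84)
  # title record
  title <- sprintf("%-80s", "synthetic bond-vector trajectory")
  wint(4 + 80)
  wint(1)
  writeChar(title, con, nchars = 80, eos = NULL)
  wint(4 + 80)
  # natom record
  wint(4); wint(na); wint(4)
  for (f in seq_len(nf)) {
    for (d in 1:3) {
      wint(4 * na)
      writeBin(as.numeric(xyz[, d, f]), con, size = 4, endian = "little")
      wint(4 * na)
    }
  }
  invisible(path)
}

#' Export a synthetic trajectory as PDB + DCD (and a numeric table)
#'
#' Represents each molecule copy as a pseudo C-H pair: the carbon sits at
#' a fixed offset, the hydrogen at carbon + 1.09 Angstrom along the bond
#' vector, so reading the files back and forming H-C bond vectors
#' reproduces the simulated vectors.
#'
#' @param traj A \code{synthetic_trajectory}.
#' @param prefix Output prefix; writes \code{<prefix>.pdb},
#'   \code{<prefix>.dcd} and \code{<prefix>_vectors.tsv}.
#' @return Invisibly, the written paths.
#' @export
export_trajectory <- function(traj, prefix) {
  v <- traj$vectors
  nc <- dim(v)[3]; nt <- dim(v)[2]
  na <- 2L * nc
  xyz <- array(NA_real_, c(na, 3, nt))
  for (j in seq_len(nc)) {
    off <- c(10 * (j - 1), 0, 0)
    xyz[2L * j - 1L, , ] <- matrix(off, 3, nt)
    xyz[2L * j, , ] <- off + 1.09 * v[, , j]
  }
  pdbfile <- paste0(prefix, ".pdb")
  dcdfile <- paste0(prefix, ".dcd")
  tabfile <- paste0(prefix, "_vectors.tsv")
  write_pseudo_pdb(xyz[, , 1], pdbfile)
  write_dcd(xyz, dcdfile)
  df <- data.frame(step = rep(seq_len(nt) - 1L, nc),
                   copy = rep(seq_len(nc), each = nt),
                   vx = as.vector(t(v[1, , ])), vy = as.vector(t(v[2, , ])),
                   vz = as.vector(t(v[3, , ])))
  utils::write.table(df, tabfile, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(pdb = pdbfile, dcd = dcdfile, table = tabfile))
}

write_pseudo_pdb <- function(xyz1, path) {
  na2 <- nrow(xyz1)
  lines <- vapply(seq_len(na2), function(i) {
    nm <- if (i %% 2 == 1) "C" else "H"
    sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, nm, "BND", (i + 1) %/% 2, xyz1[i, 1], xyz1[i, 2], xyz1[i, 3])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Bond vectors from a trajectory
#'
#' Normalized bond vectors (from the first atom to the second) for a set
#' of atom index pairs.
#'
#' @param traj A \code{trajectory_handle}.
#' @param pairs Two-column matrix (or data frame) of atom indices
#'   (from, to), e.g. C and H indices of a [resolve_selection()] result.
#' @return A \code{3 x n_steps x n_pairs} array of unit vectors.
#' @export
bond_vectors <- function(traj, pairs) {
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  np <- nrow(pairs); nt <- traj$n_steps
  out <- array(NA_real_, c(3, nt, np))
  for (p in seq_len(np)) {
    d <- traj$xyz[pairs[p, 2], , ] - traj$xyz[pairs[p, 1], , ]
    if (is.null(dim(d))) d <- matrix(d, 3, nt)
    out[, , p] <- sweep(d, 2, sqrt(colSums(d^2)), "/")
  }
  out
}
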
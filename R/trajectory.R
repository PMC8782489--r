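#' Trajectory container
#'
#' Light container for coordinate time series: an atom table, a coordinate
#' array of dimension `n_frames x n_atoms x 3` (angstrom) and optional
#' periodic box dimensions.  Frames are 0-based in user-facing labels and
#' 1-based internally (standard R indexing).
#'
#' @param atoms Tibble with columns `serial`, `name`, `resname`, `chain`,
#'   `resid`, `element`.
#' @param coords Numeric array `n_frames x n_atoms x 3`.
#' @param box Optional numeric length-3 box dimensions (angstrom).
#' @param pairing Optional tibble describing Watson-Crick pairing with
#'   columns `level`, `watson_chain`, `watson_resid`, `crick_chain`,
#'   `crick_resid`.
#' @param metadata Optional named list of provenance values.
#' @return An object of class `dna_trajectory`.
#' @export
dna_trajectory <- function(atoms, coords, box = NULL, pairing = NULL,
                           metadata = list()) {
  atoms <- tibble::as_tibble(atoms)
  abort_if(length(dim(coords)) != 3L || dim(coords)[3L] != 3L,
           "`coords` must be an n_frames x n_atoms x 3 array")
  abort_if(dim(coords)[2L] != nrow(atoms),
           "atom count mismatch between `atoms` and `coords`")
  structure(
    list(atoms = atoms, coords = coords, box = box, pairing = pairing,
         metadata = metadata),
    class = "dna_trajectory"
  )
}

#' @export
print.dna_trajectory <- function(x, ...) {
  cat("<dna_trajectory> ", n_frames(x), " frame(s), ", n_atoms(x),
      " atoms, ", length(unique(x$atoms$chain)), " chain(s)\n", sep = "")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj A `dna_trajectory`.
#' @return Integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1L]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[2L]

#' Coordinates of one frame
#'
#' @param traj A `dna_trajectory`.
#' @param frame 1-based frame index.
#' @return `n_atoms x 3` numeric matrix.
#' @export
frame_coords <- function(traj, frame = 1L) {
  abort_if(frame < 1L || frame > n_frames(traj), "frame index out of range")
  matrix(traj$coords[frame, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Select atom indices by name / residue / chain
#'
#' @param traj A `dna_trajectory`.
#' @param name,resname,chain,resid Optional filters; NULL means no filter.
#' @return Integer atom indices (possibly empty).
#' @export
select_atoms <- function(traj, name = NULL, resname = NULL, chain = NULL,
                         resid = NULL) {
  keep <- rep(TRUE, n_atoms(traj))
  if (!is.null(name)) keep <- keep & traj$atoms$name %in% name
  if (!is.null(resname)) keep <- keep & traj$atoms$resname %in% resname
  if (!is.null(chain)) keep <- keep & traj$atoms$chain %in% chain
  if (!is.null(resid)) keep <- keep & traj$atoms$resid %in% resid
  which(keep)
}

#' Read a trajectory from PDB (+ optional DCD or multi-model PDB)
#'
#' The topology is read from a PDB file.  Coordinate series may come from
#' MODEL records in the same (or a second) PDB file, or from a binary DCD
#' file; both are read with the bio3d package.  XTC has no reader in this
#' toolchain and raises an informative error.
#'
#' @param top_path Path to the topology PDB.
#' @param traj_path Optional path to coordinates (multi-model PDB or DCD).
#' @param selection Optional named list passed to [select_atoms()]; after
#'   reading, the trajectory is subset to the matching atoms.  A selection
#'   matching zero atoms is an error.
#' @return A `dna_trajectory`.
#' @export
read_trajectory <- function(top_path, traj_path = NULL, selection = NULL) {
  abort_if(!file.exists(top_path), paste0("topology not found: ", top_path))
  pdb <- bio3d::read.pdb(top_path, multi = TRUE)
  at <- pdb$atom
  atoms <- tibble::tibble(
    serial = at$eleno,
    name = at$elety,
    resname = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resid = at$resno,
    element = ifelse(is.na(at$elesy) | at$elesy == "", substr(at$elety, 1, 1),
                     at$elesy)
  )
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)

  if (!is.null(traj_path)) {
    abort_if(!file.exists(traj_path), paste0("trajectory not found: ", traj_path))
    ext <- tolower(tools::file_ext(traj_path))
    if (ext == "dcd") {
      xyz <- bio3d::read.dcd(traj_path, verbose = FALSE)
    } else if (ext == "pdb") {
      xyz <- bio3d::read.pdb(traj_path, multi = TRUE)$xyz
      if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)
    } else if (ext == "xtc") {
      stop("XTC is not supported by this reader; convert to DCD or multi-model PDB",
           call. = FALSE)
    } else {
      stop(paste0("unknown trajectory format: .", ext), call. = FALSE)
    }
    abort_if(ncol(xyz) != 3L * nrow(atoms),
             "atom-count mismatch between topology and trajectory")
  }

  nf <- nrow(xyz)
  na_ <- nrow(atoms)
  coords <- array(0, dim = c(nf, na_, 3L))
  for (f in seq_len(nf)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  traj <- dna_trajectory(atoms, coords)

  if (!is.null(selection)) {
    idx <- do.call(select_atoms, c(list(traj), selection))
    abort_if(length(idx) == 0L, "selection matched zero atoms")
    traj <- subset_trajectory(traj, idx)
  }
  traj
}

#' Subset a trajectory to chosen atoms
#'
#' @param traj A `dna_trajectory`.
#' @param idx Integer atom indices.
#' @return A `dna_trajectory` with only the selected atoms.
#' @export
subset_trajectory <- function(traj, idx) {
  dna_trajectory(traj$atoms[idx, , drop = FALSE],
                 traj$coords[, idx, , drop = FALSE],
                 box = traj$box, pairing = traj$pairing,
                 metadata = traj$metadata)
}

#' Write a trajectory as a multi-model PDB
#'
#' Plain-text writer emitting one MODEL block per frame in fixed PDB column
#' format; round-trips through [read_trajectory()] at format precision
#' (0.001 angstrom).
#'
#' @param traj A `dna_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  at <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$serial, formatC(at$name, width = 4, flag = "-"),
      at$resname, at$chain, at$resid,
      xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, 0, at$element
    )
    writeLines(lines, con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
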
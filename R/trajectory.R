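AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")
names(AA3) <- AA1

#' Construct a trajectory set
#'
#' Container for a peptide + bilayer trajectory: a topology (one row per
#' atom) plus an ordered list of frames of Cartesian coordinates. Internal
#' units are Angstrom and picoseconds; the membrane normal is the z axis.
#'
#' @param topology data.frame with columns `atom_name`, `residue_index`
#'   (1-based within chain), `residue_name`, `chain_id`. A logical
#'   `is_peptide` column is derived from standard amino-acid residue names
#'   when absent.
#' @param frames List of frames; each a list with `time` (ps), `coords`
#'   (n_atoms x 3 numeric matrix, Angstrom) and optional `box` (three
#'   orthorhombic edge lengths, Angstrom; NULL disables periodic wrapping).
#' @param phosphate_atom_name Atom name identifying lipid phosphates
#'   (default "P").
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(topology, frames, phosphate_atom_name = "P") {
  stopifnot(is.data.frame(topology), length(frames) >= 1L)
  need <- c("atom_name", "residue_index", "residue_name", "chain_id")
  miss <- setdiff(need, names(topology))
  if (length(miss))
    stop("topology missing column(s): ", paste(miss, collapse = ", "))
  if (!"is_peptide" %in% names(topology))
    topology$is_peptide <- topology$residue_name %in% AA3
  key <- paste(topology$chain_id, topology$residue_index, topology$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom) in topology")
  n <- nrow(topology)
  times <- numeric(length(frames))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (!is.matrix(fr$coords) || nrow(fr$coords) != n)
      stop(sprintf("frame %d: coordinate count %s does not match topology (%d atoms)",
                   i, if (is.matrix(fr$coords)) nrow(fr$coords) else "?", n))
    if (!is.null(fr$box) && any(fr$box <= 0))
      stop(sprintf("frame %d: non-positive box edge", i))
    times[i] <- if (is.null(fr$time)) NA_real_ else fr$time
  }
  if (!anyNA(times) && is.unsorted(times, strictly = FALSE))
    stop("frame times must be monotone increasing")
  peptide_chains <- unique(topology$chain_id[topology$is_peptide])
  if (length(peptide_chains) < 1L)
    stop("no peptide chains identified in topology")
  if (sum(topology$atom_name == phosphate_atom_name & !topology$is_peptide) < 1L)
    warning("no lipid phosphate atoms ('", phosphate_atom_name,
            "') found; depth analyses will be unavailable")
  structure(
    list(topology = topology, frames = frames,
         peptide_chains = peptide_chains,
         phosphate_atom_name = phosphate_atom_name),
    class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d atoms, %d frames, %d peptide chain(s): %s\n",
              nrow(x$topology), length(x$frames), length(x$peptide_chains),
              paste(x$peptide_chains, collapse = " ")))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

#' Indices of atoms matching a selection
#'
#' @param traj A `trajectory_set`.
#' @param chain_id,atom_name,residue_index Optional filters; NULL = any.
#' @param peptide_only Restrict to peptide atoms.
#' @return Integer atom indices into the topology / coordinate rows.
#' @export
atom_select <- function(traj, chain_id = NULL, atom_name = NULL,
                        residue_index = NULL, peptide_only = FALSE) {
  top <- traj$topology
  keep <- rep(TRUE, nrow(top))
  if (!is.null(chain_id)) keep <- keep & top$chain_id %in% chain_id
  if (!is.null(atom_name)) keep <- keep & top$atom_name %in% atom_name
  if (!is.null(residue_index)) keep <- keep & top$residue_index %in% residue_index
  if (peptide_only) keep <- keep & top$is_peptide
  which(keep)
}

phosphate_indices <- function(traj) {
  atom_select(traj, atom_name = traj$phosphate_atom_name)[
    !traj$topology$is_peptide[atom_select(traj,
                                          atom_name = traj$phosphate_atom_name)]]
}

#' Assign lipid phosphates to bilayer leaflets
#'
#' The bilayer midplane is the mean z of all phosphate atoms in the frame;
#' phosphates with z above the midplane form the upper leaflet, the rest
#' the lower. Assignment is recomputed per frame.
#'
#' @param frame Frame index (1-based) or a frame list from `traj$frames`.
#' @param traj A `trajectory_set`.
#' @return Character vector ("upper"/"lower"), one element per phosphate
#'   atom, named by atom index; attribute `midplane` holds the midplane z.
#' @export
assign_leaflets <- function(frame, traj) {
  if (is.numeric(frame) && length(frame) == 1L) frame <- traj$frames[[frame]]
  ip <- phosphate_indices(traj)
  if (length(ip) < 1L) stop("no phosphate atoms in topology")
  z <- frame$coords[ip, 3]
  mid <- mean(z)
  lab <- ifelse(z > mid, "upper", "lower")
  if (all(lab == "lower") || all(lab == "upper")) {
    warning("all phosphates on one side of the midplane; single-leaflet mode")
    lab[] <- "lower"
  }
  names(lab) <- ip
  attr(lab, "midplane") <- mid
  lab
}

# minimum-image displacement in x,y only; z non-periodic (bilayer normal)
min_image_xy <- function(d, box) {
  if (is.null(box)) return(d)
  for (k in 1:2) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

## ---- readers / writers -----------------------------------------------------

#' Read a trajectory
#'
#' @param topology_source Path to the topology table (delimited format) or
#'   NULL when the format carries its own topology (PDB, GRO).
#' @param frames_source Path to the coordinate file.
#' @param format_tag One of `"pdb_multimodel"`, `"gro_series"`,
#'   `"delimited_frames"`.
#' @param dt Frame spacing in ps used when the format stores no times.
#' @param phosphate_atom_name Passed to [trajectory_set()].
#' @return A `trajectory_set`. GRO coordinates (nm) are converted to
#'   Angstrom.
#' @export
read_trajectory <- function(topology_source = NULL, frames_source,
                            format_tag = c("pdb_multimodel", "gro_series",
                                           "delimited_frames"),
                            dt = 1, phosphate_atom_name = "P") {
  format_tag <- match.arg(format_tag)
  switch(format_tag,
         pdb_multimodel = read_pdb_multimodel(frames_source, dt,
                                              phosphate_atom_name),
         gro_series = read_gro_series(frames_source, dt, phosphate_atom_name),
         delimited_frames = read_delimited_frames(topology_source,
                                                  frames_source,
                                                  phosphate_atom_name))
}

read_pdb_multimodel <- function(path, dt = 1, phosphate_atom_name = "P") {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  top <- data.frame(
    atom_name = pdb$atom$elety,
    residue_index = pdb$atom$resno,
    residue_name = pdb$atom$resid,
    chain_id = ifelse(is.na(pdb$atom$chain), "X", pdb$atom$chain),
    stringsAsFactors = FALSE)
  box <- NULL
  cl <- grep("^CRYST1", readLines(path, n = 50), value = TRUE)
  if (length(cl)) {
    v <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                      substr(cl[1], 25, 33)))
    if (!anyNA(v) && all(v > 0)) box <- v
  }
  nm <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  frames <- lapply(seq_len(nm), function(m) {
    xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[m, ] else as.numeric(pdb$xyz)
    list(time = (m - 1) * dt, box = box,
         coords = matrix(xyz, ncol = 3, byrow = TRUE))
  })
  trajectory_set(top, frames, phosphate_atom_name)
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame; a CRYST1 record carries the first
#' frame's box when present.
#'
#' @param traj A `trajectory_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb_multimodel <- function(traj, path) {
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  box <- traj$frames[[1]]$box
  if (!is.null(box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       box[1], box[2], box[3]), con)
  serial <- seq_len(nrow(top)) %% 100000
  for (m in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- traj$frames[[m]]$coords
    writeLines(sprintf(
      "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      serial,
      substr(top$atom_name, 1, 3),
      substr(top$residue_name, 1, 3),
      substr(top$chain_id, 1, 1),
      top$residue_index %% 10000,
      xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# GRO fixed-column format, concatenated frames; positions in nm -> Angstrom.
read_gro_series <- function(path, dt = 1, phosphate_atom_name = "P") {
  lines <- readLines(path)
  frames <- list(); top <- NULL; i <- 1L; m <- 0L
  while (i <= length(lines)) {
    title <- lines[i]
    natoms <- as.integer(trimws(lines[i + 1L]))
    if (is.na(natoms)) stop("malformed GRO frame header at line ", i + 1L)
    block <- lines[(i + 2L):(i + 1L + natoms)]
    if (length(block) < natoms)
      stop(sprintf("frame %d: truncated GRO block", m + 1L))
    resno <- as.integer(substr(block, 1, 5))
    resnm <- trimws(substr(block, 6, 10))
    atnm <- trimws(substr(block, 11, 15))
    x <- as.numeric(substr(block, 21, 28))
    y <- as.numeric(substr(block, 29, 36))
    z <- as.numeric(substr(block, 37, 44))
    boxline <- strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]]
    box <- as.numeric(boxline[1:3]) * 10
    tm <- m * dt
    tmatch <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(tmatch)) tm <- as.numeric(sub("t=\\s*", "", tmatch))
    m <- m + 1L
    if (is.null(top)) {
      # GRO has no chain column: new chain whenever residue numbering restarts
      chain <- character(natoms); cc <- 1L
      for (k in seq_len(natoms)) {
        if (k > 1L && resno[k] < resno[k - 1L]) cc <- cc + 1L
        chain[k] <- LETTERS[(cc - 1L) %% 26L + 1L]
      }
      top <- data.frame(atom_name = atnm, residue_index = resno,
                        residue_name = resnm, chain_id = chain,
                        stringsAsFactors = FALSE)
    } else if (natoms != nrow(top)) {
      stop(sprintf("frame %d: atom count %d does not match first frame (%d)",
                   m, natoms, nrow(top)))
    }
    frames[[m]] <- list(time = tm, box = if (all(box > 0)) box else NULL,
                        coords = unname(cbind(x, y, z)) * 10)
    i <- i + 3L + natoms
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  trajectory_set(top, frames, phosphate_atom_name)
}

#' Read the delimited frame format
#'
#' The topology is a tab-separated table with header columns `atom_name`,
#' `residue_index`, `residue_name`, `chain_id`. The frames file holds one
#' block per frame: a line `FRAME <time_ps> <lx> <ly> <lz>` followed by
#' `n_atoms` lines of `x y z` in Angstrom.
#'
#' @param topology_source,frames_source File paths.
#' @param phosphate_atom_name Passed to [trajectory_set()].
#' @return A `trajectory_set`.
#' @export
read_delimited_frames <- function(topology_source, frames_source,
                                  phosphate_atom_name = "P") {
  top <- utils::read.delim(topology_source, stringsAsFactors = FALSE)
  lines <- readLines(frames_source)
  heads <- grep("^FRAME\\b", lines)
  if (!length(heads)) stop("no FRAME blocks found in ", frames_source)
  n <- nrow(top)
  frames <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    hdr <- as.numeric(strsplit(trimws(lines[heads[k]]), "\\s+")[[1]][-1])
    rows <- lines[(heads[k] + 1L):(heads[k] + n)]
    if (length(rows) < n || any(grepl("^FRAME\\b", rows)))
      stop(sprintf("frame %d: expected %d coordinate rows", k, n))
    xyz <- matrix(scan(text = rows, quiet = TRUE), ncol = 3, byrow = TRUE)
    frames[[k]] <- list(time = hdr[1],
                        box = if (length(hdr) >= 4 && all(hdr[2:4] > 0))
                          hdr[2:4] else NULL,
                        coords = xyz)
  }
  trajectory_set(top, frames, phosphate_atom_name)
}

#' Write the delimited frame format
#'
#' @param traj A `trajectory_set`.
#' @param topology_path,frames_path Output file paths.
#' @return `frames_path`, invisibly.
#' @export
write_delimited_frames <- function(traj, topology_path, frames_path) {
  utils::write.table(
    traj$topology[c("atom_name", "residue_index", "residue_name", "chain_id")],
    topology_path, sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(frames_path, "w")
  on.exit(close(con))
  for (fr in traj$frames) {
    box <- if (is.null(fr$box)) c(-1, -1, -1) else fr$box
    writeLines(sprintf("FRAME %.6g %.6g %.6g %.6g", fr$time,
                       box[1], box[2], box[3]), con)
    writeLines(sprintf("%.3f %.3f %.3f",
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
  }
  invisible(frames_path)
}
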
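#' Construct a SystemTopology
#'
#' Internal-facing constructor used by the readers and the synthetic
#' generator. Validates that roles partition the atom set, that there is
#' exactly one contiguous peptide chain, and that every lipid atom carries a
#' species label.
#'
#' @param atoms Data frame with columns \code{serial}, \code{name},
#'   \code{resid}, \code{resname}, \code{role} (one of peptide, lipid,
#'   solvent, other) and \code{species} (lipid species or \code{NA}).
#' @return An object of class \code{SystemTopology}.
#' @export
new_system_topology <- function(atoms) {
  need <- c("serial", "name", "resid", "resname", "role", "species")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  ok_roles <- c("peptide", "lipid", "solvent", "other")
  bad <- setdiff(unique(atoms$role), ok_roles)
  if (length(bad)) stop("unknown atom roles: ", paste(bad, collapse = ", "))
  pep_idx <- which(atoms$role == "peptide")
  if (!length(pep_idx)) stop("no peptide residues found")
  pep_res <- unique(atoms$resid[pep_idx])
  if (!all(diff(sort(pep_res)) == 1)) {
    stop("peptide residues are not a single contiguous chain")
  }
  lip_idx <- which(atoms$role == "lipid")
  if (length(lip_idx) && anyNA(atoms$species[lip_idx])) {
    stop("lipid atoms without a species label")
  }
  structure(list(
    atoms = atoms,
    n_atoms = nrow(atoms),
    peptide_residues = sort(pep_res),
    peptide_atoms = pep_idx,
    membrane_atoms = lip_idx
  ), class = "SystemTopology")
}

#' Construct a Trajectory
#'
#' @param coords Numeric array, \code{n_atoms x 3 x n_frames}, Angstrom.
#' @param times Frame timestamps, ns, strictly increasing and uniformly
#'   spaced within 1e-6 ns.
#' @param box \code{n_frames x 3} matrix of box lengths, Angstrom.
#' @param frame_interval Frame spacing, ns.
#' @return An object of class \code{Trajectory}.
#' @export
new_trajectory <- function(coords, times, box, frame_interval) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  n_frames <- dim(coords)[3]
  stopifnot(length(times) == n_frames, nrow(box) == n_frames)
  if (n_frames > 1) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("timestamps must be strictly increasing")
    if (max(dts) - min(dts) > 1e-6) {
      stop("timestamps are not uniformly spaced")
    }
  }
  structure(list(coords = coords, times = as.numeric(times),
                 box = box, frame_interval = frame_interval,
                 n_frames = n_frames),
            class = "Trajectory")
}

#' Extract one frame from a trajectory
#'
#' @param trajectory A \code{Trajectory}.
#' @param i Frame index (1-based).
#' @return List with \code{coords} (n_atoms x 3) and \code{box} (length 3).
#' @export
get_frame <- function(trajectory, i) {
  stopifnot(i >= 1, i <= trajectory$n_frames)
  list(coords = trajectory$coords[, , i, drop = TRUE],
       box = trajectory$box[i, ])
}

# ---- GRO ------------------------------------------------------------------
# Fixed-column GROMACS coordinate format; positions stored in nm, converted
# to/from the package-internal Angstrom on the fly.

#' Write a single frame as a GRO file
#'
#' @param topology A \code{SystemTopology}.
#' @param coords n_atoms x 3 coordinates, Angstrom.
#' @param box Box lengths, Angstrom.
#' @param path Output file.
#' @param title Title line.
#' @return Invisibly, the path.
#' @export
write_gro <- function(topology, coords, box, path, title = "membind system") {
  a <- topology$atoms
  stopifnot(nrow(coords) == topology$n_atoms)
  lines <- c(title, sprintf("%5d", topology$n_atoms),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     a$resid %% 100000L, a$resname, a$name,
                     a$serial %% 100000L,
                     coords[, 1] / 10, coords[, 2] / 10, coords[, 3] / 10),
             sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10,
                     box[3] / 10))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GRO file
#'
#' @param path GRO file.
#' @return List with \code{atoms} (data frame: serial, name, resid, resname),
#'   \code{coords} (Angstrom) and \code{box} (Angstrom).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("truncated GRO file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO atom count in ", path)
  if (length(lines) < n + 3) stop("GRO file shorter than declared atom count")
  al <- lines[3:(n + 2)]
  atoms <- data.frame(
    resid = as.integer(substr(al, 1, 5)),
    resname = trimws(substr(al, 6, 10)),
    name = trimws(substr(al, 11, 15)),
    serial = as.integer(substr(al, 16, 20)),
    stringsAsFactors = FALSE
  )
  coords <- cbind(as.numeric(substr(al, 21, 28)),
                  as.numeric(substr(al, 29, 36)),
                  as.numeric(substr(al, 37, 44))) * 10
  if (anyNA(coords)) stop("malformed coordinates in GRO file ", path)
  box <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])[1:3] * 10
  list(atoms = atoms[, c("serial", "name", "resid", "resname")],
       coords = coords, box = box)
}

# ---- multi-model PDB ------------------------------------------------------

.pdb_atom_lines <- function(topology, coords) {
  a <- topology$atoms
  sprintf("ATOM  %5d %-4s %-4sA%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          a$serial %% 100000L, substr(a$name, 1, 4),
          substr(a$resname, 1, 4), a$resid %% 10000L,
          coords[, 1], coords[, 2], coords[, 3])
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame; the box goes into a CRYST1 record and
#' each model carries its timestamp in a \code{REMARK 6 TIME_NS} record
#' (readers that ignore remarks still get the coordinates).
#'
#' @param topology A \code{SystemTopology}.
#' @param trajectory A \code{Trajectory}.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_pdb_traj <- function(topology, trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(trajectory$n_frames)) {
    b <- trajectory$box[f, ]
    writeLines(c(
      sprintf("MODEL     %4d", f),
      sprintf("REMARK   6 TIME_NS %.6f", trajectory$times[f]),
      sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
              b[1], b[2], b[3], 90, 90, 90),
      .pdb_atom_lines(topology, trajectory$coords[, , f]),
      "ENDMDL"
    ), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a single frame as a PDB file
#'
#' @inheritParams write_gro
#' @return Invisibly, the path.
#' @export
write_pdb <- function(topology, coords, box, path) {
  writeLines(c(
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
            box[1], box[2], box[3], 90, 90, 90),
    .pdb_atom_lines(topology, coords),
    "END"
  ), path)
  invisible(path)
}

.parse_pdb_atoms <- function(al, where) {
  atoms <- data.frame(
    serial = as.integer(substr(al, 7, 11)),
    name = trimws(substr(al, 13, 16)),
    resname = trimws(substr(al, 18, 21)),
    resid = as.integer(substr(al, 23, 26)),
    stringsAsFactors = FALSE
  )
  coords <- cbind(as.numeric(substr(al, 31, 38)),
                  as.numeric(substr(al, 39, 46)),
                  as.numeric(substr(al, 47, 54)))
  if (anyNA(coords)) stop("malformed ATOM coordinates in ", where)
  list(atoms = atoms, coords = coords)
}

#' Read a multi-model PDB trajectory
#'
#' Parsing is strictly validating: every model must contain the same number
#' of ATOM records, and a model with a missing or malformed coordinate block
#' is an error naming the frame.
#'
#' @param path Multi-model PDB file.
#' @param frame_interval Frame spacing in ns, used when the file carries no
#'   \code{REMARK 6 TIME_NS} records.
#' @return List with \code{atoms}, \code{coords} (n_atoms x 3 x n_frames),
#'   \code{times}, \code{box} (n_frames x 3).
#' @export
read_pdb_traj <- function(path, frame_interval = 0.1) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  if (!length(model_starts)) {
    # single-model file: treat the whole file as one frame
    model_starts <- 0L
    model_ends <- length(lines) + 1L
  } else {
    model_ends <- which(rec == "ENDMDL")
    if (length(model_ends) != length(model_starts)) {
      stop("unbalanced MODEL/ENDMDL records in ", path)
    }
  }
  n_frames <- length(model_starts)
  frames <- vector("list", n_frames)
  times <- rep(NA_real_, n_frames)
  boxes <- matrix(NA_real_, n_frames, 3)
  atoms <- NULL
  for (f in seq_len(n_frames)) {
    idx <- (model_starts[f] + 1L):(model_ends[f] - 1L)
    block <- lines[idx]
    brec <- substr(block, 1, 6)
    al <- block[brec %in% c("ATOM  ", "HETATM")]
    if (!length(al)) stop("frame ", f, " of ", path, " has no ATOM records")
    parsed <- .parse_pdb_atoms(al, paste0(path, " frame ", f))
    if (is.null(atoms)) {
      atoms <- parsed$atoms
    } else if (nrow(parsed$atoms) != nrow(atoms)) {
      stop("frame ", f, " of ", path, " has ", nrow(parsed$atoms),
           " atoms; expected ", nrow(atoms))
    }
    frames[[f]] <- parsed$coords
    cl <- block[brec == "CRYST1"]
    if (length(cl)) {
      boxes[f, ] <- c(as.numeric(substr(cl[1], 7, 15)),
                      as.numeric(substr(cl[1], 16, 24)),
                      as.numeric(substr(cl[1], 25, 33)))
    }
    tl <- grep("^REMARK   6 TIME_NS", block, value = TRUE)
    if (length(tl)) times[f] <- as.numeric(sub("^REMARK   6 TIME_NS", "", tl[1]))
  }
  if (anyNA(times)) times <- (seq_len(n_frames) - 1) * frame_interval
  if (anyNA(boxes))  {
    if (all(is.na(boxes))) boxes[] <- 0 else {
      boxes[is.na(boxes[, 1]), ] <- boxes[which(!is.na(boxes[, 1]))[1], ]
    }
  }
  coords <- array(unlist(frames), dim = c(nrow(atoms), 3L, n_frames))
  list(atoms = atoms, coords = coords, times = times, box = boxes)
}

# ---- role assignment and system loading -----------------------------------

.default_solvent_names <- c("SOL", "TIP3", "TIP4", "WAT", "HOH", "SPC",
                            "NA", "CL", "K", "MG", "CA2", "POT", "SOD", "CLA")
.amino3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL", "HSD", "HSE", "HSP")

#' Assign peptide / lipid / solvent roles by residue name
#'
#' @param atoms Atom data frame (serial, name, resid, resname).
#' @param lipid_names Character vector of lipid residue names; each becomes
#'   its own species label.
#' @param solvent_names Residue names treated as solvent/ions.
#' @param peptide_pattern Extra regular expression recognised as peptide
#'   residues, in addition to the standard amino-acid three-letter codes.
#' @return The atom data frame with \code{role} and \code{species} columns.
#' @export
assign_roles <- function(atoms,
                         lipid_names = c("POPC", "POPG"),
                         solvent_names = .default_solvent_names,
                         peptide_pattern = "^PEP[0-9]+$") {
  rn <- atoms$resname
  role <- rep(NA_character_, nrow(atoms))
  role[rn %in% lipid_names] <- "lipid"
  role[rn %in% solvent_names] <- "solvent"
  is_pep <- rn %in% .amino3 | grepl(peptide_pattern, rn)
  role[is.na(role) & is_pep] <- "peptide"
  if (anyNA(role)) {
    offenders <- sort(unique(rn[is.na(role)]))
    stop("unrecognised residue names (not lipid, solvent or peptide): ",
         paste(offenders, collapse = ", "))
  }
  atoms$role <- role
  atoms$species <- ifelse(role == "lipid", rn, NA_character_)
  atoms
}

#' Load a topology/trajectory pair into the internal data model
#'
#' Reads a GRO or PDB topology and a multi-model PDB trajectory, assigns
#' roles by residue name and validates that the trajectory's atom count
#' matches the topology.
#'
#' @param topology_path GRO or PDB file defining atoms and residues.
#' @param trajectory_path Multi-model PDB trajectory. May be omitted, in
#'   which case the topology's own coordinates become a single-frame
#'   trajectory.
#' @param frame_interval Frame spacing in ns used when the trajectory carries
#'   no embedded timestamps.
#' @inheritParams assign_roles
#' @return List with \code{topology} (\code{SystemTopology}) and
#'   \code{trajectory} (\code{Trajectory}).
#' @export
load_system <- function(topology_path, trajectory_path = NULL,
                        lipid_names = c("POPC", "POPG"),
                        solvent_names = .default_solvent_names,
                        peptide_pattern = "^PEP[0-9]+$",
                        frame_interval = 0.1) {
  if (!file.exists(topology_path)) stop("no such topology: ", topology_path)
  ext <- tolower(tools::file_ext(topology_path))
  top <- switch(ext,
    gro = read_gro(topology_path),
    pdb = {
      x <- read_pdb_traj(topology_path, frame_interval)
      list(atoms = x$atoms, coords = x$coords[, , 1],
           box = x$box[1, ])
    },
    stop("unsupported topology format: .", ext)
  )
  atoms <- assign_roles(top$atoms, lipid_names, solvent_names,
                        peptide_pattern)
  topology <- new_system_topology(atoms)
  if (is.null(trajectory_path)) {
    coords <- array(top$coords, dim = c(nrow(atoms), 3L, 1L))
    trajectory <- new_trajectory(coords, times = 0,
                                 box = matrix(top$box, 1, 3),
                                 frame_interval = frame_interval)
  } else {
    if (!file.exists(trajectory_path)) {
      stop("no such trajectory: ", trajectory_path)
    }
    tr <- read_pdb_traj(trajectory_path, frame_interval)
    if (dim(tr$coords)[1] != topology$n_atoms) {
      stop("atom-count mismatch: topology has ", topology$n_atoms,
           ", trajectory has ", dim(tr$coords)[1])
    }
    dt <- if (length(tr$times) > 1) tr$times[2] - tr$times[1] else
      frame_interval
    trajectory <- new_trajectory(tr$coords, tr$times, tr$box,
                                 frame_interval = dt)
  }
  list(topology = topology, trajectory = trajectory)
}

#' Write an analysis table as TSV
#'
#' Tab-separated with a header row; floating-point columns are rendered at 6
#' significant digits so identical records always produce byte-identical
#' files.
#'
#' @param records Non-empty data frame.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("refusing to write an empty table")
  }
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(signif(out[[j]], 6), format = "g", digits = 6)
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}
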
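make_sys <- function(n_frames = 8, popg = 0.30, seed = 5) {
  p <- synthetic_params(n_frames = n_frames, popg_fraction = popg,
                        seed = seed)
  emit_trajectory(p, sample_state_path(p))
}

test_that("GRO and multi-model PDB round-trip to declared precision", {
  sys <- make_sys()
  td <- withr::local_tempdir()
  gro <- file.path(td, "s.gro")
  pdb <- file.path(td, "t.pdb")
  write_gro(sys$topology, sys$trajectory$coords[, , 1],
            sys$trajectory$box[1, ], gro)
  write_pdb_traj(sys$topology, sys$trajectory, pdb)

  g <- read_gro(gro)
  expect_equal(nrow(g$atoms), sys$topology$n_atoms)
  # GRO stores nm at 3 decimals: 0.01 A quantisation, tolerance 0.001 A on
  # the PDB (stored in A at 3 decimals)
  expect_lt(max(abs(g$coords - sys$trajectory$coords[, , 1])), 0.005 + 1e-9)

  tr <- read_pdb_traj(pdb)
  expect_equal(dim(tr$coords)[3], sys$trajectory$n_frames)
  expect_lt(max(abs(tr$coords - sys$trajectory$coords)), 0.001 + 1e-9)
  expect_equal(tr$times, sys$trajectory$times, tolerance = 1e-6)
  expect_equal(tr$box[1, ], sys$trajectory$box[1, ], tolerance = 1e-3)
})

test_that("load_system assigns roles and validates consistency", {
  sys <- make_sys(popg = 0.30)
  td <- withr::local_tempdir()
  gro <- file.path(td, "s.gro"); pdb <- file.path(td, "t.pdb")
  write_gro(sys$topology, sys$trajectory$coords[, , 1],
            sys$trajectory$box[1, ], gro)
  write_pdb_traj(sys$topology, sys$trajectory, pdb)

  ld <- load_system(gro, pdb)
  expect_equal(ld$topology$n_atoms, sys$topology$n_atoms)
  expect_equal(ld$trajectory$n_frames, sys$trajectory$n_frames)
  # membrane selection contains atoms of 18 POPG residues
  lip <- ld$topology$atoms[ld$topology$membrane_atoms, ]
  expect_equal(length(unique(lip$resid[lip$species == "POPG"])), 18L)
  expect_identical(ld$topology$atoms$role, sys$topology$atoms$role)

  # atom-count mismatch between topology and trajectory
  short <- make_sys(n_frames = 2, seed = 9)
  short$topology$atoms <- short$topology$atoms[-1, ]
  gro2 <- file.path(td, "short.gro")
  write_gro(sys$topology, sys$trajectory$coords[, , 1],
            sys$trajectory$box[1, ], gro2)
  pdb2 <- file.path(td, "short.pdb")
  tr2 <- short$trajectory
  tr2$coords <- tr2$coords[-1, , , drop = FALSE]
  topo2 <- short$topology
  topo2$n_atoms <- nrow(topo2$atoms)
  write_pdb_traj(topo2, tr2, pdb2)
  expect_error(load_system(gro2, pdb2), "atom-count mismatch")
})

test_that("malformed trajectories fail loudly, naming the frame", {
  sys <- make_sys(n_frames = 4)
  td <- withr::local_tempdir()
  pdb <- file.path(td, "t.pdb")
  write_pdb_traj(sys$topology, sys$trajectory, pdb)
  lines <- readLines(pdb)
  # drop half the ATOM records of frame 3
  starts <- which(startsWith(lines, "MODEL"))
  ends <- which(startsWith(lines, "ENDMDL"))
  atom_idx <- seq(starts[3] + 3, ends[3] - 1)
  bad <- lines[-atom_idx[1:10]]
  writeLines(bad, file.path(td, "bad.pdb"))
  expect_error(read_pdb_traj(file.path(td, "bad.pdb")), "frame 3")
})

test_that("unknown residue names are an error listing offenders", {
  sys <- make_sys(n_frames = 2)
  atoms <- sys$topology$atoms[, c("serial", "name", "resid", "resname")]
  atoms$resname[atoms$resname == "POPG"] <- "XLIP"
  expect_error(assign_roles(atoms), "XLIP")
  expect_silent(assign_roles(atoms, lipid_names = c("POPC", "XLIP")))
})

test_that("write_table is schema-stable, deterministic, refuses empties", {
  td <- withr::local_tempdir()
  p <- synthetic_params(n_frames = 120, k_on = 1, k_off = 0, seed = 2)
  sys <- emit_trajectory(p, sample_state_path(p, init = 1))
  cp <- classifier_params()
  track <- segment_states(contact_series(sys$trajectory, sys$topology, cp),
                          cp, p$frame_interval)
  summ <- summarize_binding(track, "sys1")
  f1 <- file.path(td, "a.tsv"); f2 <- file.path(td, "b.tsv")
  write_table(summ, f1)
  header <- strsplit(readLines(f1, n = 1), "\t")[[1]]
  expect_equal(header, c("system", "n_events", "t_b_ns", "t_l_ns",
                         "pct_bound", "deltaG", "status"))
  write_table(summ, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_error(write_table(summ[0, ], file.path(td, "c.tsv")), "empty")
})

test_that("truncated or malformed GRO files are rejected", {
  td <- withr::local_tempdir()
  writeLines(c("title", "5", "    1PEP1    C1    1   0.100   0.200"),
             file.path(td, "bad.gro"))
  expect_error(read_gro(file.path(td, "bad.gro")), "shorter|malformed")
})

test_that("an external PDB reader agrees on the written coordinates", {
  # MDAnalysis, from the pre-installed Python stack, as independent oracle
  sys <- make_sys(n_frames = 3, seed = 13)
  td <- withr::local_tempdir()
  pdb <- file.path(td, "t.pdb")
  write_pdb_traj(sys$topology, sys$trajectory, pdb)
  script <- file.path(td, "check.py")
  writeLines(c(
    "import sys, warnings",
    "warnings.filterwarnings('ignore')",
    "import MDAnalysis as mda",
    "import numpy as np",
    "u = mda.Universe(sys.argv[1])",
    "out = []",
    "for ts in u.trajectory:",
    "    out.append(u.atoms.positions.copy())",
    "np.savetxt(sys.argv[2], np.vstack(out), fmt='%.3f')"
  ), script)
  out <- file.path(td, "coords.txt")
  status <- system2("python", c(script, pdb, out), stdout = FALSE,
                    stderr = FALSE)
  expect_equal(status, 0L)
  ext <- as.matrix(read.table(out))
  ours <- do.call(rbind, lapply(1:3, function(f) sys$trajectory$coords[, , f]))
  expect_lt(max(abs(ext - ours)), 0.0015)
})
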
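# hand-placed micro-system: one peptide residue, membrane atoms as given
place_system <- function(pep_xyz, mem_xyz, box = c(10, 10, 10)) {
  n_pep <- nrow(pep_xyz); n_mem <- nrow(mem_xyz)
  atoms <- data.frame(
    serial = seq_len(n_pep + n_mem),
    name = c(sprintf("C%d", seq_len(n_pep)), sprintf("L%d", seq_len(n_mem))),
    resid = c(rep(1L, n_pep), 1L + seq_len(n_mem)),
    resname = c(rep("PEP1", n_pep), rep("POPC", n_mem)),
    role = c(rep("peptide", n_pep), rep("lipid", n_mem)),
    species = c(rep(NA_character_, n_pep), rep("POPC", n_mem)),
    stringsAsFactors = FALSE
  )
  topo <- new_system_topology(atoms)
  coords <- array(rbind(pep_xyz, mem_xyz), dim = c(n_pep + n_mem, 3, 1))
  traj <- new_trajectory(coords, times = 0, box = matrix(box, 1, 3),
                         frame_interval = 0.1)
  list(topology = topo, trajectory = traj)
}

test_that("min_distances: plain geometry, periodic wrap, degenerate overlap", {
  cp <- classifier_params()
  s <- place_system(matrix(c(0, 0, 5.0), 1), matrix(c(0, 0, 1.8), 1))
  d <- min_distances(get_frame(s$trajectory, 1), s$topology, cp)
  expect_equal(unname(d$atom), 3.2, tolerance = 1e-12)
  expect_equal(unname(d$residue), 3.2, tolerance = 1e-12)

  # images through the x boundary: 0.5 and box - 0.5 are 1.0 apart
  box <- c(12, 10, 10)
  s2 <- place_system(matrix(c(0.5, 3, 3), 1),
                     matrix(c(box[1] - 0.5, 3, 3), 1), box = box)
  d2 <- min_distances(get_frame(s2$trajectory, 1), s2$topology, cp)
  expect_equal(unname(d2$atom), 1.0, tolerance = 1e-12)
  expect_equal(unname(d2$atom),
               oracle_min_dist(matrix(c(0.5, 3, 3), 1),
                               matrix(c(box[1] - 0.5, 3, 3), 1), box, TRUE))
  d2off <- min_distances(get_frame(s2$trajectory, 1), s2$topology,
                         classifier_params(use_pbc = FALSE))
  expect_equal(unname(d2off$atom), 11.0, tolerance = 1e-12)

  # coincident atoms: distance 0, flagged in contact
  s3 <- place_system(matrix(c(2, 2, 2), 1), matrix(c(2, 2, 2), 1))
  series <- contact_series(s3$trajectory, s3$topology, cp)
  expect_equal(min(series$residue_min), 0)
  expect_true(series$raw_bound[1])

  # zero-size box with PBC on is an error
  s4 <- place_system(matrix(c(1, 1, 1), 1), matrix(c(2, 2, 2), 1),
                     box = c(0, 10, 10))
  expect_error(contact_series(s4$trajectory, s4$topology, cp), "zero-size")
})

test_that("bound fraction applies inclusive thresholds", {
  cp <- classifier_params()
  # 10-atom peptide: exactly 3 atoms at exactly 3.5 A -> fraction 0.30, bound
  mem <- matrix(c(5, 5, 0), 1)
  pep <- rbind(
    t(vapply(1:3, function(i) c(5, 5, 3.5), numeric(3))),
    t(vapply(1:7, function(i) c(5, 5, 20), numeric(3)))
  )
  s <- place_system(pep, mem, box = c(50, 50, 50))
  series <- contact_series(s$trajectory, s$topology, cp)
  expect_equal(series$bound_fraction[1], 0.30)
  expect_true(series$raw_bound[1])

  # 2 of 10 in contact -> 0.20, unbound
  pep2 <- pep; pep2[3, 3] <- 20
  s2 <- place_system(pep2, mem, box = c(50, 50, 50))
  series2 <- contact_series(s2$trajectory, s2$topology, cp)
  expect_equal(series2$bound_fraction[1], 0.20)
  expect_false(series2$raw_bound[1])

  # all atoms within cutoff in every frame -> fraction 1, all raw-bound
  p <- synthetic_params(n_frames = 60, k_on = 1, k_off = 0,
                        bound_fraction = 1, seed = 4)
  sys <- emit_trajectory(p, sample_state_path(p, init = 1))
  s3 <- contact_series(sys$trajectory, sys$topology, cp)
  expect_true(all(s3$bound_fraction == 1))
  expect_true(all(s3$raw_bound))
})

test_that("segmentation pins the persistence boundary", {
  mk_series <- function(raw) {
    structure(list(bound_fraction = as.numeric(raw), raw_bound = raw,
                   residue_min = matrix(0, 1, length(raw)),
                   times = (seq_along(raw) - 1) * 0.1,
                   n_frames = length(raw), params = classifier_params()),
              class = "ContactSeries")
  }
  cp <- classifier_params(persistence_frames = 50)
  raw49 <- c(rep(FALSE, 5), rep(TRUE, 49), rep(FALSE, 5))
  t49 <- segment_states(mk_series(raw49), cp, 0.1)
  expect_equal(nrow(t49$events), 0L)
  expect_equal(t49$t_b_ns, 0)

  raw50 <- c(rep(FALSE, 5), rep(TRUE, 50), rep(FALSE, 5))
  t50 <- segment_states(mk_series(raw50), cp, 0.1)
  expect_equal(nrow(t50$events), 1L)
  expect_equal(t50$events$duration_ns, 50 * 0.1)

  alt <- rep(c(TRUE, FALSE), 100)
  talt <- segment_states(mk_series(alt), cp, 0.1)
  expect_equal(nrow(talt$events), 0L)
  # oracle agreement on the same inputs
  for (raw in list(raw49, raw50, alt)) {
    o <- oracle_segment(raw, 50)
    tt <- segment_states(mk_series(raw), cp, 0.1)
    expect_identical(tt$state == "bound", o$state)
  }
})

test_that("pipeline matches brute force exactly on random small systems", {
  cp <- classifier_params(persistence_frames = 3)
  for (seed in 1:12) {
    s <- make_small_system(n_frames = 20, box = c(9, 11, 13), seed = seed)
    series <- contact_series(s$trajectory, s$topology, cp)
    dor <- vapply(seq_len(20), function(f) {
      oracle_min_dist(s$trajectory$coords[s$topology$peptide_atoms, , f],
                      s$trajectory$coords[s$topology$membrane_atoms, , f],
                      s$trajectory$box[f, ], TRUE)
    }, numeric(length(s$topology$peptide_atoms)))
    frac_or <- colMeans(dor <= cp$contact_cutoff)
    expect_equal(series$bound_fraction, frac_or, tolerance = 1e-12)
    o <- oracle_segment(frac_or >= cp$min_bound_fraction,
                        cp$persistence_frames)
    expect_identical(segment_states(series, cp, 0.1)$state == "bound",
                     o$state)
  }
})

test_that("monotonicity and time conservation hold", {
  p <- synthetic_params(n_frames = 1200, k_on = 0.1, k_off = 0.1, seed = 31)
  sys <- emit_trajectory(p, sample_state_path(p))
  cuts <- c(2, 3.5, 5, 8)
  fracs <- lapply(cuts, function(cc) {
    contact_series(sys$trajectory, sys$topology,
                   classifier_params(contact_cutoff = cc))$bound_fraction
  })
  for (i in seq_len(length(cuts) - 1)) {
    expect_true(all(fracs[[i + 1]] >= fracs[[i]]))
  }
  series <- contact_series(sys$trajectory, sys$topology, classifier_params())
  tb <- vapply(c(1, 10, 50, 200), function(pf) {
    segment_states(series, classifier_params(persistence_frames = pf),
                   p$frame_interval)$t_b_ns
  }, numeric(1))
  expect_true(all(diff(tb) <= 1e-12))
  track <- segment_states(series, classifier_params(), p$frame_interval)
  expect_equal(track$t_b_ns + track$t_l_ns, track$total_ns,
               tolerance = 1e-9)
})

test_that("bound-fraction distribution reflects the generator's target", {
  p <- synthetic_params(n_frames = 400, k_on = 1, k_off = 0,
                        bound_fraction = 0.6, seed = 8)
  sys <- emit_trajectory(p, sample_state_path(p, init = 1))
  cp <- classifier_params()
  series <- contact_series(sys$trajectory, sys$topology, cp)
  track <- segment_states(series, cp, p$frame_interval)
  dist <- bound_fraction_distribution(series, track)
  expect_equal(dist$n, 400L)
  # 17 of 28 atoms are placed in contact: fraction 0.6071...
  expect_equal(dist$median, ceiling(0.6 * 28) / 28, tolerance = 1e-9)
  # recomputed directly from the emitted coordinates
  direct <- vapply(seq_len(400), function(f) {
    d <- oracle_min_dist(sys$trajectory$coords[sys$topology$peptide_atoms, , f],
                         sys$trajectory$coords[sys$topology$membrane_atoms, , f],
                         sys$trajectory$box[f, ], TRUE)
    mean(d <= 3.5)
  }, numeric(1))
  expect_equal(unname(median(direct)), dist$median)

  # degenerate empty case
  p0 <- synthetic_params(n_frames = 50, k_on = 0, k_off = 1, seed = 8)
  sys0 <- emit_trajectory(p0, sample_state_path(p0, init = 0))
  s0 <- contact_series(sys0$trajectory, sys0$topology, cp)
  t0 <- segment_states(s0, cp, p0$frame_interval)
  d0 <- bound_fraction_distribution(s0, t0)
  expect_equal(d0$n, 0L)
  expect_true(is.na(d0$median))
})
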
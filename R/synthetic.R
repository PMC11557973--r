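#' Parameters for the synthetic peptide-membrane trajectory generator
#'
#' Defines the stated world of the generator: a 7-residue peptide above a
#' 60-lipid bilayer slab whose binding kinetics follow a two-state
#' (bound/unbound) continuous-time Markov chain with exponential dwell times.
#' The generator is geometric, not mechanical: the latent Markov state
#' dictates where the peptide is placed in each frame, so downstream
#' classification can be checked against exact ground truth.
#'
#' @param n_residues Number of peptide residues (default 7, a 7-mer host).
#' @param atoms_per_residue Pseudo-atoms per peptide residue (all heavy).
#' @param n_lipids Number of lipids in the bilayer (default 60, split evenly
#'   between two leaflets).
#' @param popg_fraction Fraction of lipids labelled POPG; the rest are POPC.
#'   Use 0 for a purely zwitterionic ("eukaryotic") membrane and 0.30 for the
#'   anionic ("prokaryotic") mixture.
#' @param atoms_per_lipid Pseudo-atoms per lipid, stacked along z from the
#'   head-group level toward the bilayer midplane.
#' @param lipid_spacing Lateral grid spacing between lipids, Angstrom.
#' @param box Box lengths (x, y, z) in Angstrom. x and y default to the grid
#'   extent; z must leave room for the slab plus the unbound clearance.
#' @param leaflet_z Half-thickness of the bilayer: head groups sit at
#'   \code{+leaflet_z} and \code{-leaflet_z}.
#' @param k_on,k_off Markov rates (per ns) for unbound->bound and
#'   bound->unbound transitions. Stationary bound occupancy is
#'   \code{k_on / (k_on + k_off)}.
#' @param frame_interval Time between saved frames, ns.
#' @param n_frames Number of frames to emit.
#' @param contact_depth How far above the head-group plane bound-state
#'   contact atoms are placed, Angstrom. Must stay within the 3.5 Angstrom
#'   contact cutoff after jitter.
#' @param unbound_margin Minimum clearance, beyond the 3.5 Angstrom cutoff,
#'   between an unbound peptide and any lipid atom (Angstrom).
#' @param bound_fraction Target fraction of peptide atoms placed in contact
#'   during bound frames (rounded up to whole atoms).
#' @param jitter_sigma Standard deviation of the Gaussian positional jitter
#'   added to peptide atoms, Angstrom. Jitter is clipped at
#'   \code{min(3 * jitter_sigma, 0.9)} per coordinate so that the raw contact
#'   criterion is never violated by noise.
#' @param seed Integer seed; one seed controls the state path, the lipid
#'   species placement and the coordinate jitter.
#' @return An object of class \code{SyntheticParams} (a validated list).
#' @examples
#' p <- synthetic_params(n_frames = 100, seed = 1)
#' p$n_lipids
#' @export
synthetic_params <- function(n_residues = 7L,
                             atoms_per_residue = 4L,
                             n_lipids = 60L,
                             popg_fraction = 0,
                             atoms_per_lipid = 5L,
                             lipid_spacing = 8,
                             box = NULL,
                             leaflet_z = 15,
                             k_on = 0.05,
                             k_off = 0.05,
                             frame_interval = 0.1,
                             n_frames = 1000L,
                             contact_depth = 2.0,
                             unbound_margin = 10.0,
                             bound_fraction = 0.6,
                             jitter_sigma = 0.3,
                             seed = 1L) {
  stopifnot(n_residues >= 1, atoms_per_residue >= 1,
            n_lipids >= 2, atoms_per_lipid >= 1,
            popg_fraction >= 0, popg_fraction <= 1,
            k_on >= 0, k_off >= 0,
            frame_interval > 0, n_frames >= 1,
            lipid_spacing > 0, leaflet_z > 0,
            contact_depth > 0, unbound_margin > 0,
            bound_fraction > 0, bound_fraction <= 1,
            jitter_sigma >= 0)
  n_upper <- ceiling(n_lipids / 2)
  nx <- ceiling(sqrt(n_upper))
  ny <- ceiling(n_upper / nx)
  if (is.null(box)) {
    box <- c(nx * lipid_spacing, ny * lipid_spacing,
             2 * (leaflet_z + 3.5 + unbound_margin + 12))
  }
  stopifnot(length(box) == 3, all(box > 0))
  clip <- min(3 * jitter_sigma, 0.9)
  # bound-state guarantee: contact atoms stay within the default 3.5 A cutoff
  if (sqrt(2 * clip^2 + (contact_depth + clip)^2) > 3.5) {
    stop("contact_depth plus jitter exceeds the 3.5 Angstrom contact cutoff")
  }
  tail_len <- 2 * (atoms_per_lipid - 1)
  z_unbound <- leaflet_z + 3.5 + unbound_margin + 1 + clip
  # clearance to the lower-leaflet image through the periodic z boundary
  image_gap <- box[3] - (z_unbound + clip) - (leaflet_z + tail_len)
  if (box[1] < nx * lipid_spacing || box[2] < ny * lipid_spacing) {
    stop("box x/y too small for the lipid grid")
  }
  if (image_gap <= 3.5 + unbound_margin) {
    stop("box z too small to hold the bilayer slab plus the unbound clearance")
  }
  structure(list(
    n_residues = as.integer(n_residues),
    atoms_per_residue = as.integer(atoms_per_residue),
    n_lipids = as.integer(n_lipids),
    popg_fraction = popg_fraction,
    atoms_per_lipid = as.integer(atoms_per_lipid),
    lipid_spacing = lipid_spacing,
    box = as.numeric(box),
    leaflet_z = leaflet_z,
    k_on = k_on, k_off = k_off,
    frame_interval = frame_interval,
    n_frames = as.integer(n_frames),
    contact_depth = contact_depth,
    unbound_margin = unbound_margin,
    bound_fraction = bound_fraction,
    jitter_sigma = jitter_sigma,
    jitter_clip = clip,
    grid = c(nx = nx, ny = ny),
    seed = as.integer(seed)
  ), class = "SyntheticParams")
}

#' Sample the latent bound/unbound state path
#'
#' Simulates the two-state continuous-time Markov chain (exponential dwell
#' times with rates \code{k_on}, \code{k_off}) and samples it at frame
#' boundaries. The initial state is drawn from the stationary distribution,
#' so the path is stationary from frame one. Dwell segments shorter than one
#' frame interval can be lost to discretisation; the default rates keep mean
#' dwells at 200 frames, far above that limit.
#'
#' @param params A [synthetic_params()] object.
#' @param init Optional forced initial state (\code{1} bound, \code{0}
#'   unbound); by default drawn from the stationary distribution.
#' @return An object of class \code{GroundTruth}: a list with
#'   \code{state_per_frame} (integer 0/1 of length \code{n_frames}),
#'   \code{dwell_segments} (data frame of state, first and last frame,
#'   1-based inclusive) and \code{stationary_occupancy}.
#' @examples
#' gt <- sample_state_path(synthetic_params(n_frames = 200, seed = 7))
#' mean(gt$state_per_frame)
#' @export
sample_state_path <- function(params, init = NULL) {
  stopifnot(inherits(params, "SyntheticParams"))
  k_on <- params$k_on; k_off <- params$k_off
  if (k_on + k_off <= 0) {
    stop("degenerate chain: k_on and k_off are both zero")
  }
  set.seed(params$seed)
  pi_b <- k_on / (k_on + k_off)
  state <- if (is.null(init)) as.integer(runif(1) < pi_b) else as.integer(init)
  n <- params$n_frames
  dt <- params$frame_interval
  total <- n * dt
  # event-driven simulation of the chain, then sample at frame start times
  t_switch <- numeric(0)
  s0 <- state
  t <- 0
  while (t < total) {
    rate <- if (state == 1L) k_off else k_on
    if (rate <= 0) break   # absorbing state
    t <- t + rexp(1, rate)
    if (t < total) t_switch <- c(t_switch, t)
    state <- 1L - state
  }
  frame_times <- (seq_len(n) - 1L) * dt
  n_switch_before <- findInterval(frame_times, t_switch)
  states <- as.integer((s0 + n_switch_before) %% 2L)
  r <- rle(states)
  ends <- cumsum(r$lengths)
  segs <- data.frame(state = r$values,
                     start = ends - r$lengths + 1L,
                     end = ends)
  structure(list(state_per_frame = states,
                 dwell_segments = segs,
                 stationary_occupancy = pi_b),
            class = "GroundTruth")
}

# static coordinates and bookkeeping shared by all frames
.synthetic_layout <- function(params) {
  p <- params
  n_upper <- ceiling(p$n_lipids / 2)
  n_lower <- p$n_lipids - n_upper
  nx <- p$grid["nx"]; ny <- p$grid["ny"]
  cell <- function(k) c(((k - 1) %% nx + 0.5) * p$lipid_spacing,
                        ((k - 1) %/% nx + 0.5) * p$lipid_spacing)
  upper_xy <- t(vapply(seq_len(n_upper), cell, numeric(2)))
  lower_xy <- t(vapply(seq_len(n_lower), cell, numeric(2)))
  apl <- p$atoms_per_lipid
  z_stack <- 2 * (seq_len(apl) - 1)
  lip_xyz <- rbind(
    do.call(rbind, lapply(seq_len(n_upper), function(i) {
      cbind(upper_xy[i, 1], upper_xy[i, 2], p$leaflet_z - z_stack)
    })),
    do.call(rbind, lapply(seq_len(n_lower), function(i) {
      cbind(lower_xy[i, 1], lower_xy[i, 2], -p$leaflet_z + z_stack)
    }))
  )
  # peptide base layout: residues along x, atoms within a residue along y
  apr <- p$atoms_per_residue
  res_x <- (seq_len(p$n_residues) - (p$n_residues + 1) / 2) * 3.5
  atom_y <- (seq_len(apr) - (apr + 1) / 2) * 1.5
  pep_base <- do.call(rbind, lapply(seq_len(p$n_residues), function(i) {
    cbind(res_x[i], atom_y, 0)
  }))
  list(n_upper = n_upper, n_lower = n_lower,
       upper_xy = upper_xy, lip_xyz = lip_xyz, pep_base = pep_base)
}

#' Emit topology and coordinates for a latent state path
#'
#' Places lipids on two lateral grids at \code{+/-leaflet_z}. In latent-bound
#' frames a fixed subset of peptide atoms (ceiling of
#' \code{bound_fraction * n_atoms}, taken from the N-terminal end) is snapped
#' onto the head-group atom of the nearest upper-leaflet lipid at height
#' \code{contact_depth}, guaranteeing the 3.5 Angstrom atom-contact criterion;
#' the remaining atoms hover out of contact. In latent-unbound frames the
#' whole peptide is lifted so every atom is strictly farther than
#' \code{3.5 + unbound_margin} from all lipid atoms. The peptide's lateral
#' position is redrawn uniformly every frame (fast lateral diffusion), so
#' bound-state contacts sample lipids uniformly and the POPG contact share
#' converges to the membrane composition.
#'
#' @param params A [synthetic_params()] object.
#' @param truth A [sample_state_path()] result of matching length.
#' @return A list with \code{topology} (a \code{SystemTopology}),
#'   \code{trajectory} (a \code{Trajectory}) and \code{truth} (the input).
#' @examples
#' p <- synthetic_params(n_frames = 50, seed = 3)
#' sys <- emit_trajectory(p, sample_state_path(p))
#' dim(sys$trajectory$coords)
#' @export
emit_trajectory <- function(params, truth) {
  stopifnot(inherits(params, "SyntheticParams"), inherits(truth, "GroundTruth"))
  p <- params
  states <- truth$state_per_frame
  if (length(states) != p$n_frames) {
    stop("ground-truth length does not match n_frames")
  }
  set.seed(p$seed + 1L)
  lay <- .synthetic_layout(p)

  # species assignment stratified per leaflet (membrane builders balance
  # leaflet composition); total POPG count is round(n_lipids * popg_fraction)
  n_popg <- round(p$n_lipids * p$popg_fraction)
  n_upper <- lay$n_upper
  popg_upper <- min(max(round(n_upper * p$popg_fraction), n_popg - lay$n_lower),
                    n_upper, n_popg)
  species <- c(
    sample(rep(c("POPG", "POPC"), c(popg_upper, n_upper - popg_upper))),
    sample(rep(c("POPG", "POPC"),
               c(n_popg - popg_upper, lay$n_lower - (n_popg - popg_upper))))
  )

  n_pep_atoms <- p$n_residues * p$atoms_per_residue
  pep_atoms <- data.frame(
    serial = seq_len(n_pep_atoms),
    name = sprintf("C%d", rep(seq_len(p$atoms_per_residue), p$n_residues)),
    resid = rep(seq_len(p$n_residues), each = p$atoms_per_residue),
    resname = sprintf("PEP%d", rep(seq_len(p$n_residues),
                                   each = p$atoms_per_residue)),
    role = "peptide", species = NA_character_,
    stringsAsFactors = FALSE
  )
  lip_atoms <- data.frame(
    serial = n_pep_atoms + seq_len(p$n_lipids * p$atoms_per_lipid),
    name = sprintf("L%d", rep(seq_len(p$atoms_per_lipid), p$n_lipids)),
    resid = p$n_residues + rep(seq_len(p$n_lipids), each = p$atoms_per_lipid),
    resname = rep(species, each = p$atoms_per_lipid),
    role = "lipid",
    species = rep(species, each = p$atoms_per_lipid),
    stringsAsFactors = FALSE
  )
  topology <- new_system_topology(rbind(pep_atoms, lip_atoms))

  n_atoms <- n_pep_atoms + nrow(lip_atoms)
  n_contact <- ceiling(p$bound_fraction * n_pep_atoms)
  clip <- p$jitter_clip
  z_unbound <- p$leaflet_z + 3.5 + p$unbound_margin + 1 + clip
  z_hover <- p$leaflet_z + 6.0

  nf <- p$n_frames
  sp <- p$lipid_spacing
  nx <- p$grid["nx"]; ny <- p$grid["ny"]
  # lateral offset redrawn per frame (fast lateral diffusion), then jitter
  off <- cbind(runif(nf, 0, p$box[1]), runif(nf, 0, p$box[2]))
  jitter <- array(rnorm(n_pep_atoms * 3 * nf, sd = p$jitter_sigma),
                  dim = c(n_pep_atoms, 3L, nf))
  jitter <- pmin(pmax(jitter, -clip), clip)

  px <- sweep(matrix(lay$pep_base[, 1], n_pep_atoms, nf), 2, off[, 1],
              "+") %% p$box[1]
  py <- sweep(matrix(lay$pep_base[, 2], n_pep_atoms, nf), 2, off[, 2],
              "+") %% p$box[2]
  pz <- matrix(z_unbound, n_pep_atoms, nf)
  bnd <- which(states == 1L)
  if (length(bnd)) {
    ci <- seq_len(n_contact)
    # snap contact atoms onto the nearest upper-leaflet head-group column
    kx <- pmin(pmax(floor(px[ci, bnd, drop = FALSE] / sp), 0), nx - 1)
    ky <- pmin(pmax(floor(py[ci, bnd, drop = FALSE] / sp), 0), ny - 1)
    k <- pmin(ky * nx + kx + 1, lay$n_upper)
    px[ci, bnd] <- lay$upper_xy[k, 1]
    py[ci, bnd] <- lay$upper_xy[k, 2]
    pz[ci, bnd] <- p$leaflet_z + p$contact_depth
    if (n_contact < n_pep_atoms) {
      pz[(n_contact + 1):n_pep_atoms, bnd] <- z_hover
    }
  }
  coords <- array(0, dim = c(n_atoms, 3L, nf))
  coords[seq_len(n_pep_atoms), 1, ] <- px
  coords[seq_len(n_pep_atoms), 2, ] <- py
  coords[seq_len(n_pep_atoms), 3, ] <- pz
  coords[seq_len(n_pep_atoms), , ] <-
    coords[seq_len(n_pep_atoms), , , drop = FALSE] + jitter
  coords[(n_pep_atoms + 1):n_atoms, , ] <- lay$lip_xyz
  trajectory <- new_trajectory(
    coords = coords,
    times = (seq_len(p$n_frames) - 1L) * p$frame_interval,
    box = matrix(rep(p$box, each = p$n_frames), ncol = 3),
    frame_interval = p$frame_interval
  )
  list(topology = topology, trajectory = trajectory, truth = truth)
}

#' Write the latent ground-truth state path as TSV
#'
#' @param truth A [sample_state_path()] result.
#' @param params The matching [synthetic_params()].
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_ground_truth <- function(truth, params, path) {
  df <- data.frame(
    frame = seq_along(truth$state_per_frame),
    time_ns = (seq_along(truth$state_per_frame) - 1) * params$frame_interval,
    latent_state = truth$state_per_frame
  )
  write_table(df, path)
}
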
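#' Bound-state classifier parameters
#'
#' The operational binding definition: a peptide atom is in contact when its
#' minimum distance to any membrane atom is 3.5 Angstrom or less (inclusive);
#' the peptide frame is raw-bound when at least \code{min_bound_fraction} of
#' its atoms are in contact (inclusive at the threshold); and the bound state
#' is assigned to maximal runs of raw-bound frames lasting at least
#' \code{persistence_frames} consecutive frames (a run of exactly the
#' persistence length counts; one frame shorter does not).
#'
#' @param contact_cutoff Contact distance cutoff, Angstrom.
#' @param min_bound_fraction Minimum fraction of peptide atoms in contact.
#' @param persistence_frames Minimum consecutive raw-bound frames for the
#'   bound state.
#' @param use_pbc Apply the minimum-image convention in all three box
#'   dimensions when computing distances.
#' @param heavy_atoms_only Drop atoms whose name starts with H from both the
#'   peptide and the membrane before computing distances and fractions.
#' @return An object of class \code{ClassifierParams}.
#' @export
classifier_params <- function(contact_cutoff = 3.5,
                              min_bound_fraction = 0.30,
                              persistence_frames = 50L,
                              use_pbc = TRUE,
                              heavy_atoms_only = FALSE) {
  stopifnot(contact_cutoff > 0,
            min_bound_fraction > 0, min_bound_fraction <= 1,
            persistence_frames >= 1)
  structure(list(contact_cutoff = contact_cutoff,
                 min_bound_fraction = min_bound_fraction,
                 persistence_frames = as.integer(persistence_frames),
                 use_pbc = isTRUE(use_pbc),
                 heavy_atoms_only = isTRUE(heavy_atoms_only)),
            class = "ClassifierParams")
}

.atom_subsets <- function(topology, params) {
  pep <- topology$peptide_atoms
  mem <- topology$membrane_atoms
  if (params$heavy_atoms_only) {
    h <- startsWith(topology$atoms$name, "H")
    pep <- pep[!h[pep]]
    mem <- mem[!h[mem]]
  }
  if (!length(mem)) stop("membrane selection is empty")
  if (!length(pep)) stop("peptide selection is empty")
  list(pep = pep, mem = mem)
}

.check_box <- function(box, params) {
  if (params$use_pbc && any(box <= 0)) {
    stop("zero-size box dimension with use_pbc enabled")
  }
}

#' Minimum peptide-membrane distances for one frame
#'
#' For every peptide atom, the minimum Euclidean distance over all membrane
#' atoms, under the minimum-image convention in x, y and z when
#' \code{use_pbc} is on; per residue, the minimum over that residue's atoms.
#'
#' @param frame A frame as returned by [get_frame()]: list with \code{coords}
#'   (n_atoms x 3, Angstrom) and \code{box} (3 lengths).
#' @param topology A \code{SystemTopology}.
#' @param params A [classifier_params()] object.
#' @return List with \code{atom} (named by peptide atom index) and
#'   \code{residue} (named by peptide residue id) distance vectors, Angstrom.
#' @examples
#' p <- synthetic_params(n_frames = 2, seed = 1)
#' sys <- emit_trajectory(p, sample_state_path(p))
#' d <- min_distances(get_frame(sys$trajectory, 1), sys$topology,
#'                    classifier_params())
#' d$residue
#' @export
min_distances <- function(frame, topology, params = classifier_params()) {
  .check_box(frame$box, params)
  sel <- .atom_subsets(topology, params)
  d <- .cpp_min_dist_frame(frame$coords[sel$pep, , drop = FALSE],
                           frame$coords[sel$mem, , drop = FALSE],
                           as.numeric(frame$box), params$use_pbc)
  resid <- topology$atoms$resid[sel$pep]
  res_min <- tapply(d, resid, min)
  list(atom = setNames(d, sel$pep),
       residue = setNames(as.numeric(res_min), names(res_min)))
}

#' Per-frame contact geometry over a whole trajectory
#'
#' @param trajectory A \code{Trajectory}.
#' @param topology A \code{SystemTopology}.
#' @param params A [classifier_params()] object.
#' @return An object of class \code{ContactSeries}: list with
#'   \code{bound_fraction} (per frame), \code{raw_bound} (logical per frame,
#'   true when the fraction is at least \code{min_bound_fraction}),
#'   \code{residue_min} (n_residues x n_frames matrix of per-residue minimum
#'   distances), \code{times} and \code{params}.
#' @export
contact_series <- function(trajectory, topology,
                           params = classifier_params()) {
  .check_box(trajectory$box[1, ], params)
  sel <- .atom_subsets(topology, params)
  dmat <- .cpp_min_dist_traj(as.numeric(trajectory$coords),
                             dim(trajectory$coords)[1],
                             as.integer(sel$pep), as.integer(sel$mem),
                             trajectory$box, params$use_pbc)
  frac <- colMeans(dmat <= params$contact_cutoff)
  resid <- topology$atoms$resid[sel$pep]
  res_ids <- sort(unique(resid))
  res_min <- do.call(rbind, lapply(res_ids, function(r) {
    apply(dmat[resid == r, , drop = FALSE], 2, min)
  }))
  rownames(res_min) <- res_ids
  structure(list(bound_fraction = frac,
                 raw_bound = frac >= params$min_bound_fraction,
                 residue_min = res_min,
                 times = trajectory$times,
                 n_frames = trajectory$n_frames,
                 params = params),
            class = "ContactSeries")
}

#' Segment a contact series into bound and unbound states
#'
#' Bound segments are maximal runs of consecutive raw-bound frames of length
#' at least \code{persistence_frames}; every other frame is unbound. Any
#' raw-unbound frame terminates a bound segment (no symmetric debounce by
#' default).
#'
#' @param series A [contact_series()] result.
#' @param params A [classifier_params()] object (persistence length).
#' @param frame_interval Frame spacing, ns.
#' @return An object of class \code{StateTrack}: list with \code{state}
#'   (character per frame, "bound"/"unbound"), \code{events} (data frame of
#'   start, end, frames, duration_ns for each bound segment), \code{t_b_ns},
#'   \code{t_l_ns}, \code{total_ns} and \code{frame_interval}.
#' @export
segment_states <- function(series, params = series$params,
                           frame_interval = NULL) {
  stopifnot(inherits(series, "ContactSeries"))
  if (is.null(frame_interval)) {
    frame_interval <- if (series$n_frames > 1) {
      series$times[2] - series$times[1]
    } else 1
  }
  raw <- series$raw_bound
  if (!length(raw)) stop("empty contact series")
  r <- rle(raw)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= params$persistence_frames
  events <- data.frame(start = starts[keep], end = ends[keep],
                       frames = r$lengths[keep])
  events$duration_ns <- events$frames * frame_interval
  state <- rep("unbound", length(raw))
  for (i in seq_len(nrow(events))) {
    state[events$start[i]:events$end[i]] <- "bound"
  }
  t_b <- sum(events$frames) * frame_interval
  total <- length(raw) * frame_interval
  structure(list(state = state, events = events,
                 t_b_ns = t_b, t_l_ns = total - t_b, total_ns = total,
                 frame_interval = frame_interval),
            class = "StateTrack")
}

#' Distribution of the bound fraction over bound-state frames
#'
#' @param series A [contact_series()] result.
#' @param track The matching [segment_states()] result.
#' @return List with \code{values} (one bound fraction per bound-state frame,
#'   possibly empty), \code{n}, \code{median} and \code{quartiles}.
#' @export
bound_fraction_distribution <- function(series, track) {
  stopifnot(inherits(series, "ContactSeries"), inherits(track, "StateTrack"))
  v <- series$bound_fraction[track$state == "bound"]
  list(values = v, n = length(v),
       median = if (length(v)) median(v) else NA_real_,
       quartiles = if (length(v)) quantile(v, c(0.25, 0.75), names = FALSE)
                   else c(NA_real_, NA_real_))
}

#' Export a state track and contact series as per-frame records
#'
#' @param series A [contact_series()] result.
#' @param track The matching [segment_states()] result.
#' @return Data frame with columns frame, time_ns, bound_fraction, raw_flag,
#'   state.
#' @export
state_records <- function(series, track) {
  data.frame(frame = seq_len(series$n_frames),
             time_ns = series$times,
             bound_fraction = series$bound_fraction,
             raw_flag = as.integer(series$raw_bound),
             state = track$state)
}
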
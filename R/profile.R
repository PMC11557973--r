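#' Peptide-membrane contact counts per residue and per lipid species
#'
#' A contact is one (peptide atom, lipid atom) pair at distance at most
#' \code{cutoff} in one frame; the same pair in consecutive frames counts
#' once per frame. Counts are aggregated over a residue's atoms and all
#' frames, and over lipid species. Per-species percentages are reported over
#' the species total and are absent when no contact was observed.
#'
#' @param trajectory A \code{Trajectory}.
#' @param topology A \code{SystemTopology}.
#' @param params A [classifier_params()] object (PBC and heavy-atom switches).
#' @param cutoff Contact cutoff, Angstrom; defaults to the classifier's
#'   binding cutoff for coherence but is independently configurable.
#' @return An object of class \code{ContactCounts}: list with
#'   \code{per_residue} (data frame: resid, resname, count),
#'   \code{per_species} (data frame: species, count, percent) and
#'   \code{total}.
#' @export
contact_counts <- function(trajectory, topology,
                           params = classifier_params(),
                           cutoff = params$contact_cutoff) {
  .check_box(trajectory$box[1, ], params)
  sel <- .atom_subsets(topology, params)
  pairs <- .cpp_contact_pairs(as.numeric(trajectory$coords),
                              dim(trajectory$coords)[1],
                              as.integer(sel$pep), as.integer(sel$mem),
                              trajectory$box, params$use_pbc, cutoff)
  resid <- topology$atoms$resid[sel$pep]
  species <- topology$atoms$species[sel$mem]
  atom_tot <- rowSums(pairs)
  res_ids <- sort(unique(resid))
  per_residue <- data.frame(
    resid = res_ids,
    resname = vapply(res_ids, function(r) {
      topology$atoms$resname[match(r, topology$atoms$resid)]
    }, character(1)),
    count = vapply(res_ids, function(r) sum(atom_tot[resid == r]),
                   numeric(1))
  )
  mem_tot <- colSums(pairs)
  sp <- sort(unique(species))
  per_species <- data.frame(
    species = sp,
    count = vapply(sp, function(s) sum(mem_tot[species == s]), numeric(1))
  )
  total <- sum(per_species$count)
  per_species$percent <- if (total > 0) 100 * per_species$count / total else
    NA_real_
  structure(list(per_residue = per_residue, per_species = per_species,
                 total = total, cutoff = cutoff),
            class = "ContactCounts")
}

#' Position of a residue along the membrane normal
#'
#' The membrane midplane is the mean z of all lipid atoms in each frame; the
#' series value is the z of the residue's atom centroid minus the midplane,
#' so the sign follows the membrane normal (positive above the midplane).
#'
#' @param trajectory A \code{Trajectory}.
#' @param topology A \code{SystemTopology}.
#' @param residue Peptide residue id.
#' @return An object of class \code{ZPositionSeries}: list with
#'   \code{values} (signed Angstrom per frame), \code{mean}, \code{sd},
#'   \code{residue}.
#' @export
z_position <- function(trajectory, topology, residue) {
  if (!residue %in% topology$peptide_residues) {
    stop("residue ", residue, " is not a peptide residue")
  }
  res_atoms <- which(topology$atoms$resid == residue &
                     topology$atoms$role == "peptide")
  mem <- topology$membrane_atoms
  if (!length(mem)) stop("membrane selection is empty")
  z_res <- apply(trajectory$coords[res_atoms, 3, , drop = FALSE], 3, mean)
  z_mid <- apply(trajectory$coords[mem, 3, , drop = FALSE], 3, mean)
  v <- as.numeric(z_res - z_mid)
  structure(list(values = v, mean = mean(v), sd = sd(v), residue = residue),
            class = "ZPositionSeries")
}
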
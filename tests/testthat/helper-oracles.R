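# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: distances enumerate all 27 periodic images explicitly,
# segmentation scans runs frame by frame.

# minimum distance from point a to point b over the 27 periodic images
oracle_pair_dist <- function(a, b, box, pbc) {
  if (!pbc) return(sqrt(sum((a - b)^2)))
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    img <- b + c(ix, iy, iz) * box
    best <- min(best, sum((a - img)^2))
  }
  sqrt(best)
}

# per-peptide-atom minimum distance to the membrane, 27-image scan
oracle_min_dist <- function(pep, mem, box, pbc) {
  apply(pep, 1, function(a) {
    min(apply(mem, 1, function(b) oracle_pair_dist(a, b, box, pbc)))
  })
}

# explicit frame-by-frame run-length scan of the persistence rule
oracle_segment <- function(raw, persistence) {
  n <- length(raw)
  state <- rep(FALSE, n)
  i <- 1
  events <- list()
  while (i <= n) {
    if (raw[i]) {
      j <- i
      while (j < n && raw[j + 1]) j <- j + 1
      if (j - i + 1 >= persistence) {
        state[i:j] <- TRUE
        events[[length(events) + 1]] <- c(start = i, end = j)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  list(state = state, events = events)
}

# brute-force atom-pair contact counting over a whole trajectory
oracle_contact_counts <- function(coords, pep_idx, mem_idx, boxes, pbc,
                                  cutoff) {
  counts <- matrix(0L, length(pep_idx), length(mem_idx))
  for (f in seq_len(dim(coords)[3])) {
    for (i in seq_along(pep_idx)) {
      for (j in seq_along(mem_idx)) {
        d <- oracle_pair_dist(coords[pep_idx[i], , f],
                              coords[mem_idx[j], , f], boxes[f, ], pbc)
        if (d <= cutoff) counts[i, j] <- counts[i, j] + 1L
      }
    }
  }
  counts
}

# independent simulation of the two-state chain (per-frame thinning of the
# embedded exponential clocks, written without reusing package code)
oracle_chain_occupancy <- function(k_on, k_off, n_frames, dt, seed) {
  set.seed(seed)
  s <- as.integer(runif(1) < k_on / (k_on + k_off))
  occ <- integer(n_frames)
  t_next <- rexp(1, if (s == 1L) k_off else k_on)
  for (f in seq_len(n_frames)) {
    occ[f] <- s
    t_left <- dt
    while (t_next <= t_left) {
      t_left <- t_left - t_next
      s <- 1L - s
      t_next <- rexp(1, if (s == 1L) k_off else k_on)
    }
    t_next <- t_next - t_left
  }
  mean(occ)
}

# a hand-built small system: arbitrary coordinates, one peptide, one lipid
# species mix; returns topology + trajectory without using the generator
make_small_system <- function(n_pep_res = 3, atoms_per_res = 2,
                              n_lip = 6, n_frames = 10,
                              box = c(20, 20, 20), seed = 1,
                              species = NULL) {
  set.seed(seed)
  n_pep <- n_pep_res * atoms_per_res
  n_mem <- n_lip
  if (is.null(species)) {
    species <- sample(c("POPC", "POPG"), n_lip, replace = TRUE)
  }
  atoms <- data.frame(
    serial = seq_len(n_pep + n_mem),
    name = c(sprintf("C%d", seq_len(n_pep)), rep("L1", n_mem)),
    resid = c(rep(seq_len(n_pep_res), each = atoms_per_res),
              n_pep_res + seq_len(n_lip)),
    resname = c(sprintf("PEP%d", rep(seq_len(n_pep_res),
                                     each = atoms_per_res)),
                species),
    role = c(rep("peptide", n_pep), rep("lipid", n_mem)),
    species = c(rep(NA_character_, n_pep), species),
    stringsAsFactors = FALSE
  )
  # wrapped coordinates: the +/-1-image oracle is exact only inside the box
  coords <- array(0, dim = c(n_pep + n_mem, 3, n_frames))
  for (d in 1:3) {
    coords[, d, ] <- runif((n_pep + n_mem) * n_frames, 0, box[d])
  }
  topo <- new_system_topology(atoms)
  traj <- new_trajectory(coords, times = (seq_len(n_frames) - 1) * 0.1,
                         box = matrix(rep(box, each = n_frames), ncol = 3),
                         frame_interval = 0.1)
  list(topology = topo, trajectory = traj)
}

# closed-form normal-equation OLS with t confidence half-widths
oracle_ols <- function(x, y, confidence = 0.95) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  se_slope <- sqrt(s2 / sxx)
  se_int <- sqrt(s2 * (1 / n + mean(x)^2 / sxx))
  tq <- qt(1 - (1 - confidence) / 2, n - 2)
  sst <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       r_squared = if (sst > 0) 1 - sum(res^2) / sst else 0,
       slope_hw = tq * se_slope, intercept_hw = tq * se_int)
}

table1_path <- function() {
  system.file("extdata", "deltag_table.tsv", package = "membind")
}
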
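#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Minimum-image displacement along one axis for an orthorhombic box.
static inline double min_image(double d, double box) {
  if (box > 0.0) d -= box * std::round(d / box);
  return d;
}

// Per-peptide-atom minimum distance to any membrane atom for a single frame.
// pep, mem: n x 3 and m x 3 coordinate matrices (Angstrom); box: 3 lengths,
// ignored when pbc is false.
// [[Rcpp::export(name = ".cpp_min_dist_frame")]]
NumericVector cpp_min_dist_frame(NumericMatrix pep, NumericMatrix mem,
                                 NumericVector box, bool pbc) {
  const int n = pep.nrow(), m = mem.nrow();
  NumericVector out(n);
  const double bx = pbc ? box[0] : 0.0;
  const double by = pbc ? box[1] : 0.0;
  const double bz = pbc ? box[2] : 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double xi = pep(i, 0), yi = pep(i, 1), zi = pep(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = min_image(xi - mem(j, 0), bx);
      double dy = min_image(yi - mem(j, 1), by);
      double dz = min_image(zi - mem(j, 2), bz);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Per-peptide-atom minimum distance over a whole trajectory.
// coords: natoms x 3 x nframes array flattened column-major; pep_idx/mem_idx
// 1-based atom indices; boxes: nframes x 3. Returns n_pep x nframes matrix.
// [[Rcpp::export(name = ".cpp_min_dist_traj")]]
NumericMatrix cpp_min_dist_traj(NumericVector coords, int natoms,
                                IntegerVector pep_idx, IntegerVector mem_idx,
                                NumericMatrix boxes, bool pbc) {
  const int n = pep_idx.size(), m = mem_idx.size();
  const R_xlen_t frame_len = (R_xlen_t)natoms * 3;
  const int nframes = boxes.nrow();
  NumericMatrix out(n, nframes);
  const double *c = coords.begin();
  for (int f = 0; f < nframes; ++f) {
    const double *fr = c + (R_xlen_t)f * frame_len;
    const double bx = pbc ? boxes(f, 0) : 0.0;
    const double by = pbc ? boxes(f, 1) : 0.0;
    const double bz = pbc ? boxes(f, 2) : 0.0;
    for (int i = 0; i < n; ++i) {
      const int ai = pep_idx[i] - 1;
      const double xi = fr[ai], yi = fr[ai + natoms], zi = fr[ai + 2 * natoms];
      double best = R_PosInf;
      for (int j = 0; j < m; ++j) {
        const int aj = mem_idx[j] - 1;
        double dx = min_image(xi - fr[aj], bx);
        double dy = min_image(yi - fr[aj + natoms], by);
        double dz = min_image(zi - fr[aj + 2 * natoms], bz);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) best = d2;
      }
      out(i, f) = std::sqrt(best);
    }
  }
  return out;
}

// Atom-pair contact counts accumulated over all frames.
// Returns an n_pep x n_mem integer matrix: entry (i, j) is the number of
// frames in which peptide atom i and membrane atom j are within cutoff.
// [[Rcpp::export(name = ".cpp_contact_pairs")]]
IntegerMatrix cpp_contact_pairs(NumericVector coords, int natoms,
                                IntegerVector pep_idx, IntegerVector mem_idx,
                                NumericMatrix boxes, bool pbc, double cutoff) {
  const int n = pep_idx.size(), m = mem_idx.size();
  const R_xlen_t frame_len = (R_xlen_t)natoms * 3;
  const int nframes = boxes.nrow();
  const double cut2 = cutoff * cutoff;
  IntegerMatrix out(n, m);
  const double *c = coords.begin();
  for (int f = 0; f < nframes; ++f) {
    const double *fr = c + (R_xlen_t)f * frame_len;
    const double bx = pbc ? boxes(f, 0) : 0.0;
    const double by = pbc ? boxes(f, 1) : 0.0;
    const double bz = pbc ? boxes(f, 2) : 0.0;
    for (int i = 0; i < n; ++i) {
      const int ai = pep_idx[i] - 1;
      const double xi = fr[ai], yi = fr[ai + natoms], zi = fr[ai + 2 * natoms];
      for (int j = 0; j < m; ++j) {
        const int aj = mem_idx[j] - 1;
        double dx = min_image(xi - fr[aj], bx);
        double dy = min_image(yi - fr[aj + natoms], by);
        double dz = min_image(zi - fr[aj + 2 * natoms], bz);
        if (dx * dx + dy * dy + dz * dz <= cut2) out(i, j) += 1;
      }
    }
  }
  return out;
}
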
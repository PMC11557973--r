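# membind

Quantifying peptide–membrane binding from molecular dynamics
trajectories — and how much a covalently attached fluorophore (e.g.
BODIPY on a tryptophan side chain) shifts it.

membind is aimed at people analysing all-atom partitioning simulations
of short membrane-active peptides against lipid bilayers (POPC,
POPC/POPG). It implements the complete analysis chain:

1. **Bound-state classification.** A peptide atom is in contact when its
   minimum distance to any membrane atom is ≤ 3.5 Å (minimum-image
   convention); a frame is raw-bound when ≥ 30 % of peptide atoms are in
   contact; the bound state is assigned over maximal runs of ≥ 50
   consecutive raw-bound frames. All thresholds are configurable.
2. **Residence-time free energy.** With t_b / t_l the total bound /
   unbound times and f = t_b/(t_b+t_l),

       ΔG = −RT · ln(1/f − 1) = RT · ln(t_b/t_l)

   positive when binding is favoured (default T = 333 K; two gas-constant
   conventions, see the methods vignette).
3. **Contact profiling.** Atom-pair contact counts per peptide residue
   and per lipid species, and the insertion depth of a chosen residue
   along the membrane normal.
4. **Labelling shift.** Ordinary least squares of labelled vs native ΔG
   with t-based 95 % confidence intervals; the intercept is the headline
   ΔΔG, with a mean-paired-difference companion estimate.
5. **Synthetic ground truth.** A generator that plants a two-state
   Markov binding process (exponential dwell times) into a geometric
   peptide + 60-lipid bilayer system, so every stage above can be
   validated against a known latent state sequence.

## Worked example

```r
library(membind)

# a synthetic system: stationary bound occupancy k_on/(k_on+k_off) = 0.5,
# 30% POPG membrane, 2000 frames at 0.1 ns
p <- synthetic_params(n_frames = 2000, k_on = 0.05, k_off = 0.05,
                      popg_fraction = 0.30, seed = 4)
truth <- sample_state_path(p)
sys <- emit_trajectory(p, truth)

cp <- classifier_params()           # 3.5 A, 30%, 50 frames, PBC on
series <- contact_series(sys$trajectory, sys$topology, cp)
track <- segment_states(series, cp, p$frame_interval)
summarize_binding(track, "demo")
#>   system n_events t_b_ns t_l_ns pct_bound    deltaG status
#> 1   demo        5   65.5  134.5     32.75 -1.992019     ok
```

Five binding events covering 65.5 of 200 ns: the peptide was bound 32.75 %
of the time (this seed drew a long unbound dwell — the latent occupancy
here is 0.3275, recovered exactly), giving ΔG = RT·ln(65.5/134.5)/1000 =
−1.99 on the paper-literal scale, i.e. binding not favoured.

```r
contact_counts(sys$trajectory, sys$topology, cp)$per_species
#>      species count  percent
#> POPC    POPC  8242 71.25443
#> POPG    POPG  3325 28.74557
```

The POPG share of atom-pair contacts (28.7 %) tracks the 30 % membrane
composition.

```r
tab <- read_deltag_table(system.file("extdata", "deltag_table.tsv",
                                     package = "membind"))
fit <- ols_fit(pair_deltag(tab, "W", "WB"))
ddg_headline(fit, pair_deltag(tab, "W", "WB"))[c("ddg", "ci_halfwidth")]
#> $ddg
#> [1] 11.13592
#>
#> $ci_halfwidth
#> [1] 2.957862
```

Feeding the shipped table of published whole-peptide ΔG values (8
tryptophan / BODIPY-tryptophan pairs) through the regression gives the
headline labelling shift ΔΔG = 11.14 ± 2.96: attaching the fluorophore
adds roughly 11 free-energy units in favour of binding regardless of
membrane — large enough to override the native sequences' selectivity.
(The originally reported fit, from unrounded inputs, is 11.146 ± 2.953; see the
methods vignette.)

## Command line

```sh
Rscript inst/cli/membind.R simulate --out sim --seed 5 --n-frames 800
Rscript inst/cli/membind.R classify --topology sim/system.gro \
    --trajectory sim/trajectory.pdb --out cls
Rscript inst/cli/membind.R thermo --states cls/states.tsv --out th
Rscript inst/cli/membind.R ddg --table inst/extdata/deltag_table.tsv --out dd
```

`run-all --config FILE` drives the whole pipeline from a flat key=value
config file (see `?parse_run_config`) and writes a manifest with content
digests.

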
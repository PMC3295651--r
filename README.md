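# sbpfam

Delineation of solute-binding protein (SBP) subfamilies and analysis of
their ligand preferences.

## What this is for

Cluster 5 SBPs — the capture subunits of bacterial ABC importers, built on
the bilobed "Venus-flytrap" dipeptide-binder (DppA) fold — have repeatedly
been re-purposed for new cargos. In the *Pasteurellaceae*, a
glutathione-binding subfamily (GbpA) evolved from DppA by gene duplication,
alongside a binding-inert group (HbpA2) that keeps the fold but breaks the
binding site. Telling such subfamilies apart, and backing the sequence-based
call with binding data, takes four kinds of analysis that this package
implements end to end for R users working on SBP families:

* **Sequence arm** — progressive multiple alignment (affine-gap Gotoh
  kernel, BLOSUM62 −11/−1, UPGMA guide tree), p-distances with the
  20-state Jukes–Cantor correction
  *d* = −(19/20)·ln(1 − (20/19)·*p*), Saitou–Nei neighbor joining, and
  column-bootstrap supports.
* **Fingerprint arm** — binding-site *signature profiles* (ligand-contact
  residues from a liganded structure, with lobe assignment and salt-bridge
  annotation), mapped through the alignment to score strict clade
  conservation and classify sequences; charge-reversing substitutions at
  salt-bridge positions veto a family call.
* **Assay arms** — thermofluor melting temperatures from the first
  derivative with sub-grid interpolation, ΔTm screening tables with a
  1.5 °C significance threshold; and a one-site perfusion-cell ITC model
  [MX] = ½[(nM + X + K_d) − √((nM + X + K_d)² − 4nMX)] fitted by
  Levenberg–Marquardt over (n, log K_a, ΔH).
* **Structure arm** — Kabsch superposition and the inter-domain
  hinge-opening angle (C-lobe superposition, then the residual N-lobe
  rotation), the measure by which an apo SBP opens ~33° relative to its
  liganded paralog.

A first-class synthetic-data module generates sequence families with
clade-diagnostic residues, two-state melt curves, one-site titration
thermograms and rigid hinge-motion structure pairs, so every arm runs and
validates with no external data.

## Worked example

```r
library(sbpfam)

# three clades, five sequences each, clade signatures planted
fam <- simulate_family_sequences(n_per_clade = 5, seed = 42)
res <- run_delineation(fam, "delin_out", B = 100, seed = 42)
res$classification
#> SBP family classification (15 sequences, threshold 0.75)
#>     seq_id        family_call match_DppA match_GbpA n_flags
#> 1   GbpA_1               GbpA          0      1.000       1
#> ...
#> 11 HbpA2_1 HbpA2-like/unknown          0      0.778       3
```

Every GbpA sequence matches the 18-position GbpA fingerprint perfectly and
every DppA sequence the 10-position DppA fingerprint; the HbpA2-clade
sequences conserve 14/18 ≈ 0.778 of the GbpA positions — above the 0.75
threshold — but carry salt-bridge-breaking substitutions (R33T, D432R) that
veto the call, so they are reported as `HbpA2-like/unknown`. The Newick
tree in `delin_out/tree.nwk` carries the bootstrap supports.

```r
# thermofluor: duplicate apo and GSSG-bound curves, true shift 16 degC
apo  <- lapply(1:2, function(r) simulate_melt_curve(Tm = 60, noise_sd = 2,
               seed = r, protein = "GbpA_Hp"))
holo <- lapply(3:4, function(r) simulate_melt_curve(Tm = 76, noise_sd = 2,
               seed = r, protein = "GbpA_Hp", ligand = "GSSG"))
build_shift_table(apo, holo)
#> delta-Tm shift table (threshold 1.5 degC; '-' = not significant)
#>      GbpA_Hp
#> GSSG    16.4

# ITC: 25 x 10 uL injections, true Kd 2.1 uM
s <- simulate_itc(Kd = 2.1e-6, dH = -1e4, M0 = 2e-5, X0 = 3e-4,
                  noise_sd = 2e-7, seed = 1)
fit_one_site(s)
#> One-site ITC fit
#>   n   = 0.997 +/- 0.005
#>   Kd  = 2.107e-06 M (2.107 uM) +/- 0.066 uM
#>   dH  = -9997 cal/mol +/- 73
#>   residual sd 1.96e-07 cal on 22 df

# hinge opening between two conformers of a bilobed structure
hp <- simulate_hinge_pair(33, seed = 1)
hinge_angle(hp$a, hp$b, hp$domains)
#> [1] 33.00135  (attributes: per-lobe RMSDs and pair counts)
```

The recovered ΔTm (16.4 °C vs the true 16 °C), Kd (2.107 µM vs 2.1 µM) and
hinge angle (33.0° vs 33°) illustrate each estimator operating at its
expected accuracy. `make_demo(dir, seed)` writes a complete synthetic
dataset (FASTA family, 30 melt CSVs, 4 ITC CSVs, a hinge PDB pair and a
config record) for exploring the file-based interfaces
(`read_melt_csv()`, `read_itc_csv()`, `read_structure()`, `run_binding()`).

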
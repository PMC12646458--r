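# abcscreen

Tools for identifying and characterizing partner complexes of Type VII ABC
transporters — the family of bacterial membrane machines (MacAB, LolCDE,
FtsEX, YbbAP) that couple cytoplasmic ATP turnover to mechanical work on
the periplasmic side of the inner membrane. The package covers the
computational stages of an "in silico pulldown" campaign and its follow-up
characterization:

1. **Complex screening** — score predicted two-chain complexes by interface
   confidence (pDockQ) and steric plausibility (a heavy-atom clashscore),
   then Pareto-rank a candidate library.
2. **Coevolution analysis** — convert an inter-protein coupling matrix
   (CCMPred plain-matrix dialect) into Z-scored residue pairs, annotate
   high-Z pairs, and map them onto a structure.
3. **Conformational metrics** — named reporter distances (e.g. the
   nucleotide-binding-domain gap) and per-residue displacement fields
   between apo and ATP-bound states.
4. **Membrane-trajectory analytics** — lipid headgroup residency grids,
   vertical extraction traces, per-residue contact propensity, RMSF/RMSD.
5. **Esterase kinetics** — initial rates from absorbance progress curves,
   Michaelis–Menten fits with a saturation (upper-bound) diagnostic, and
   wild-type-normalized relative activities.
6. **Synthetic data** — generators that plant known contacts, clashes,
   coevolving pairs, lipid occupancy schedules and kinetic parameters, so
   every stage is verifiable end to end without external downloads.

## The scores and statistics

**pDockQ** (interface confidence of a predicted complex):

    pDockQ = 0.724 / (1 + exp(-0.052 (x - 152.611))) + 0.018,
    x = <pLDDT>_interface * log10(N_contacts)

where interface residues are cross-chain pairs whose representative atoms
(Cβ, Cα for glycine) lie within 8 Å, and `<pLDDT>` is the mean per-residue
confidence over interface residues of both chains. Zero contacts give the
sigmoid floor 0.018.

**Clashscore**: serious steric overlaps (van der Waals overlap ≥ 0.4 Å
between non-bonded heavy atoms) per 1000 heavy atoms, computed with an
exact spatial-hash neighbor search. This is a hydrogen-free approximation
of the MolProbity clashscore, intended for relative ranking of predicted
models rather than absolute agreement.

**Coevolution Z-score**: each inter-chain coupling `raw_ij` is standardized
against the mean and population standard deviation of all inter-chain
cells, `z = (raw − μ)/σ`; pairs with z above a threshold (default 10) are
reported.

**Lipid residency**: a 30 × 30 histogram of headgroup xy positions
(2.5 Å bins, every 10th frame by default) for one lipid type in one
leaflet, centered on the time-averaged protein centroid and normalized to
its maximum. **Contact propensity** is the fraction of frames in which any
heavy-atom pair between a lipid and a protein residue is closer than 4 Å.

**Michaelis–Menten**: `v = Vmax·S/(Km + S)` fitted by nonlinear least
squares; when the fitted Km falls below the smallest tested concentration
the fit is flagged as an upper-bound regime (the data only bound Km from
above — the behavior expected when a nanomolar-Km enzyme is probed with
micromolar substrate).

## Worked example

Score three synthetic candidate models (planted interface quality
decreasing from `tesA` to `ygdR`), then recover planted coevolving pairs
and kinetic parameters:

```r
library(abcscreen)

dir <- file.path(tempdir(), "models"); dir.create(dir)
set <- list(tesA = c(15, 92, 0), mepM = c(6, 70, 2), ygdR = c(2, 40, 6))
for (nm in names(set)) {
  sp <- set[[nm]]   # contacts, interface pLDDT, planted clashes
  g <- gen_complex(20, 20, sp[1], sp[2], 50, sp[3], seed = 11)
  write_structure(g$model, file.path(dir, paste0(nm, ".pdb")))
}
screen_models(dir)
#>   candidate_id n_contacts mean_if_plddt pdockq clashscore pareto_rank   hit
#> 1         tesA         15            92 0.0834       0.00           1 FALSE
#> 2         mepM          6            70 0.0224       9.09           2 FALSE
#> 3         ygdR          2            40 0.0185      23.08           3 FALSE
```

The candidate with the most confident, clash-free interface lands on
Pareto front 1. (Small synthetic interfaces sit low on the pDockQ sigmoid;
the ranking, not the absolute value, carries the screen.)

```r
g <- gen_coupling(60, 40,
                  planted = data.frame(pos_a = c(5, 17), pos_b = c(8, 21),
                                       target_z = 12), seed = 7)
top_pairs(zscore_pairs(extract_interchain(g$matrix, 60, 40)), z_min = 10)
#>   pos_a pos_b   raw     z
#> 1     5     8 8.046 11.33
#> 2    17    21 8.046 11.33

gk <- gen_progress_curves(Km = 5, Vmax = 2,
                          concentrations = c(0.5, 1, 2, 5, 10, 20, 35, 50),
                          noise_sd = 0.05, seed = 3)
mm_fit(gk$rates$S, gk$rates$v)
#> Michaelis-Menten fit: Km = 5.553 (se 0.29), Vmax = 2.058 (se 0.03), rss 0.00539
```

Both planted pairs are annotated (and nothing else), and the fitted
parameters land within two standard errors of the planted truth.

A command-line wrapper exposes each stage as a subcommand
(`inst/scripts/abcscreen screen|coevo|conform|lipid|kinetics|synth`); every
run writes tab-separated tables plus a JSON run manifest, and identical
config + seed reproduce outputs byte for byte.

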
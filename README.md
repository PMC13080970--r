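# gpcrmd

Trajectory analysis for receptor-ligand complexes, built to judge
chelator-peptide radiopharmaceuticals (e.g. ²²⁵Ac-DOTA-octreotate and its
DOTP/HOPO/DFO\* variants) bound to class-A GPCRs such as somatostatin
receptor 2. Given a conformational ensemble — a multi-model PDB plus a
JSON topology sidecar with per-atom charges, Lennard-Jones parameters and
masses — the package computes the four quantities that discriminate
between candidate ligands:

* **Activation-state classification.** A frame is *active* iff the marker
  Cα-Cα distance `d` < 19.0 Å **and** the marker Cα angle `θ` > 45°
  (strict, both required; residues and thresholds are a configurable
  preset, with SSTR2 defaults 218/306 and 262/269/81 shipped in
  `inst/extdata/sstr2_criteria.json`). The *active fraction* is the
  proportion of analysed frames passing both, pooled frame-weighted over
  replicates.
* **Interaction energy.** Plain-truncated pairwise nonbonded sum over
  ligand × receptor atom pairs at minimum-image distance,
  `E = Σ k·qᵢqⱼ/r + Σ 4ε[(σ/r)¹² − (σ/r)⁶]` with
  `k = 1389.35458 kJ mol⁻¹ Å e⁻²`, Lorentz-Berthelot combination and a
  10 Å cutoff — with an exact per-residue Coulomb/LJ decomposition
  (residue contributions sum to the group total by construction).
* **Loop flexibility.** Per-residue Cα RMSF after two-pass Kabsch
  alignment, and its sum over a loop selection (ECL2 closure metric).
* **Contacts and penetration.** Census of receptor residues within 3.0 Å
  of the ligand, typed by side-chain class
  (hydrophobic/charged/polar-uncharged), plus center-of-mass distance
  series between anchor residues.

A synthetic two-state ensemble generator with planted active fraction,
noise amplitude and pocket energetics makes every stage verifiable
against closed-form ground truth — no molecular dynamics required. See
`vignettes/trajectory-analysis.Rmd` for the model details and the
reasoning behind every convention.

## Worked example

Generate three synthetic replicates with planted active fractions
0.2/0.3/0.4 and run the full pipeline:

```r
library(gpcrmd)

ens <- Map(function(f, s) generate_ensemble(synthetic_spec(2000, f, seed = s)),
           c(0.2, 0.3, 0.4), c(11, 12, 13))
rep <- run_pipeline(lapply(ens, function(e) e$trajectory),
                    ens[[1]]$topology, ens[[1]]$criteria,
                    loop_residues = 31:40,
                    com_pairs = list(pocket = list(a = list("L", 1),
                                                   b = list("A", 1))),
                    seed = 42)
rep
#> <md_report> 3 replicate(s)
#>   active fraction (pooled): 0.2970
#>   interaction energy: -70.00 kJ/mol (coulomb -70.00, LJ -0.00)
#>   loop RMSF sum (mean over replicates): 1.710 A
rep$activation$per_replicate
#> # A tibble: 3 × 4
#>   replicate fraction n_active n_frames
#>       <int>    <dbl>    <int>    <int>
#> 1         1    0.196      393     2000
#> 2         2    0.302      604     2000
#> 3         3    0.392      785     2000
```

The recovered per-replicate fractions sit on the planted 0.2/0.3/0.4
(binomial sampling scatter at n = 2000), and the pooled value 0.297 is
their frame-weighted mean. The loop RMSF sum ≈ 1.71 Å is ten residues ×
σ√3 ≈ 0.173 Å for the planted σ = 0.10 Å noise. The interaction energy
illustrates plain truncation honestly: the default synthetic pocket
places its single charged pair exactly at the 10 Å cutoff, so thermal
noise toggles the pair across the truncation boundary — the noise-free
reference frame gives exactly −138.935458 kJ mol⁻¹ Coulomb.

Single stages work the same way and return tidy objects:

```r
af <- active_fraction(ens[[2]]$trajectory, ens[[2]]$topology, ens[[2]]$criteria)
glance(af)
#> # A tibble: 1 × 3
#>   fraction n_active n_frames
#>      <dbl>    <int>    <int>
#> 1    0.302      604     2000
tidy(af)        # per-frame distance, angle, verdict
autoplot(af)    # marker series against thresholds
```

Real trajectories enter through `read_multimodel_pdb()` +
`read_topology()`, with criteria from `read_criteria()`; results are
written by `write_results()` / `write_report()` and two systems are
contrasted with `compare_systems()`.

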
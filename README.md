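# lipidsites

Lipid–protein interaction analysis for coarse-grained membrane
simulations, in R. Given a topology (GRO) and a trajectory (DCD) of a
membrane protein in a lipid bilayer, `lipidsites` quantifies *where* a
lipid species binds the protein and *how long* it stays:

1. **Contacts** — per (lipid molecule, protein residue) occupancy under a
   dual-cutoff hysteresis scheme: a contact starts when the minimum
   bead–bead minimum-image distance drops below 5 Å and ends only when it
   rises above 7 Å, suppressing cutoff rattling.
2. **Residence-time kinetics** — the survival time correlation function
   σ(t) (the fraction of contacts persisting continuously for lag t,
   averaged over start times and contacts) is fit as a biexponential
   σ(t) ≈ A·exp(−k₁t) + B·exp(−k₂t) with k₁ ≤ k₂; the slow rate is the
   dissociation constant and the residence time is reported as
   **τ = 1/k_off** in microseconds, with R², per residue and per site.
3. **Binding sites** — Louvain community detection on the residue
   co-contact network (edge weight = number of (frame, lipid) pairs in
   which one lipid bridges two residues) partitions contacted residues
   into discrete sites, ranked BS0, BS1, … by occupancy, with per-site
   kinetics and approximate bead surface areas (nm²).
4. **Membrane descriptors** — leaflet assignment, thickness (head-plane
   separation), area per lipid by exact periodic Voronoi tessellation
   with protein-footprint exclusion, and P₂ bond order parameters.

Because public reference trajectories for this kind of analysis are
rarely available, the package ships a first-class synthetic-data module:
a two-state Markov generator for raw contact series, and a 3-D toy
system — a rigid 7-helix bead bundle in a 3:1 POPE:POPG bilayer with a
minority cardiolipin analog at 0/5/10 mol % — with *planted* binding
sites whose residence times are known, so every stage of the pipeline is
testable against ground truth. The intended audience is simulators doing
lipid–protein interaction studies (and methodologists who want a
reference implementation with oracles attached).

## Worked example

Plant one binding site (residues 13–16 in 1-based numbering, true
τ = 1 µs) in a 20 µs toy trajectory with 50 minority lipids, then run
the analysis:

```r
library(lipidsites)

cfg <- synthetic_config(
  n_lipids_total = 110, mole_fraction_minority = 0.45,
  n_frames = 2000, frame_dt = 10, seed = 17,
  sites = list(planted_site(c(12, 13, 14, 15),
                            k_on = 1e-4, k_off_true = 1e-3)))
toy    <- build_toy_system(cfg)
series <- detect_contacts(toy$system, cg_selection(lipid_species = "CDL"))
per_residue_residence_times(series)
#>   residue  time_us r_squared n_events converged
#> 1      13 1.122819 0.9996485       74      TRUE
#> 2      14 1.123085 0.9996522       74      TRUE
#> 3      15 1.123085 0.9996522       74      TRUE
#> 4      16 1.122942 0.9996453       73      TRUE

binding_site_table(series, toy$system)
#>   site_id n_residues    residues  time_us r_squared area_nm2 occupancy_fraction n_events
#> 1     BS0          4 13,14,15,16 1.123085 0.9996522 4.169542               0.99       74
```

Exactly the four planted residues are reported, grouped into one site;
the planted 1 µs residence time is recovered to ~12 % from 74 pooled
contact events (1/√74 ≈ 12 % is the expected sampling error), with the
R² of the survival-curve fit alongside, mirroring the conventional
per-residue residence-time table layout (residue, time/µs, R²).

## Analysis workflow

The `analysis/` directory is a numbered end-to-end workflow over the
package functions, writing its tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_systems.R` | builds the 0/5/10 mol % systems (two planted sites at 1 and 2 µs) and writes GRO/DCD + ground truth |
| `02_contacts.R` | trims the first 2 µs, runs 5/7 Å dual-cutoff contact detection, writes event tables |
| `03_kinetics.R` | per-residue residence times with R² per condition |
| `04_binding_sites.R` | Louvain sites, per-site τ/area/occupancy, Jaccard vs planted truth |
| `05_membrane.R` | thickness, area per lipid and P₂ order parameters per mole fraction |

Run them in order with `Rscript analysis/01_simulate_systems.R`, etc.

## Documentation

The methods vignette
(`vignettes/lipid-residence-analysis.Rmd`) explains the survival-function
estimator, the identifiability gate on the biexponential's second
component, the co-contact edge definition, the Voronoi/leaflet/order
machinery, every tunable default with units, and what the synthetic
systems do and do not emulate about real CG trajectories.
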
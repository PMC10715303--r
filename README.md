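# setphen

Deep computational phenotyping of missense variants in protein domains,
built around the SET catalytic domain of the histone H3K4 methyltransferases
KMT2C and KMT2D (the genes behind Kleefstra syndrome type 2 and Kabuki
syndrome type 1). Most germline missense variants in these genes sit in
ClinVar as Variants of Uncertain Significance; `setphen` implements the
multi-tier workflow that moves them toward a mechanistic call:

1. **Catalog** — parse ClinVar-style variant tables (HGVS `p.Arg4763Gln`
   notation), summarize the five-class clinical-significance distribution,
   filter to domain regions.
2. **Paralog annotation** — map residue positions between paralogs through
   an alignment and transfer annotations, excluding targets whose residue
   already carries the substituted identity.
3. **Predictor consensus** — per-tool damaging/benign calls from a
   configurable cutoff table (20 tools shipped) and agreement statistics.
4. **Structural scores** — classify folding/binding free-energy changes
   (ΔΔG, threshold ±0.5 kcal/mol, boundary inclusive) and frustration-index
   shifts (ΔF; highly frustrated < −1.0, minimally frustrated > 0.78), and
   compute decoy Z-score frustration profiles from structure:
   F_i = (mean(E_decoy) − E_native) / sd(E_decoy).
5. **Dynamics** — Kabsch-fitted RMSD series, per-residue RMSF with the
   r-RMSF / Δ|RMSF| comparison scores, radius of gyration, Shrake–Rupley
   SASA, hydrogen-bond occupancy (2.2–3.3 Å, last-quarter window); MM-PBSA
   aggregation ΔG_bind = G_complex − G_receptor − G_ligand with
   G = E_MM + G_PB + G_SA − TS, and pairwise nonbonded (Coulomb +
   Lennard-Jones) interaction energies, e.g. Zn²⁺–protein.
6. **Molecular fitness** — integrate structural and dynamic adverse calls
   into the SV / DV / SDV / VUS classification over a 17-score panel.

Seeded synthetic generators (ideal-helix Gaussian trajectories, energy
tables, paralog alignments, variant tables) provide ground truth for every
stage, so the whole pipeline is testable offline.

## Worked example

```r
library(setphen)

# catalog: the bundled SET-domain variant table (31 variants)
recs <- read_variant_table(system.file("extdata", "table1_variants.tsv",
                                       package = "setphen"))
summarize_classifications(recs)
#> Clinical significance summary (31 variants)
#>             class count percent
#>      LikelyBenign     1     3.2
#>               VUS    23    74.2
#>  LikelyPathogenic     3     9.7
#>        Pathogenic     2     6.5
#>       Conflicting     1     3.2
#>           P_or_LP     1     3.2
```

74.2% of the domain's variants are VUS — the motivation for the rest of the
workflow. Structural scores then classify each variant:

```r
tab <- read_score_panel(system.file("extdata", "table2_scores.tsv",
                                    package = "setphen"))
structural_calls(tab[tab$variant == "C4855Y", ])$adverse_count
#> [1] 1
fitness_report(tab)   # structural-only: SV vs VUS
```

Only three variants (Q4761R, R4763Q, R4806W) come out structurally clean;
C4855Y is adverse in exactly one score (the FoldX fold energy), making it an
SV candidate pending dynamics. A dynamics panel upgrades the call:

```r
reg <- default_dynamic_registry()           # 11 dynamic scores
call_dynamic(list(r_rmsf = 0.85, delta_abs_rmsf = 0.35),
             registry = reg)$dynamic_adverse
#> [1] 2
classify_mf(structural_adverse = 1, dynamic_adverse = 2)$mf_class
#> [1] "SDV"
```

Trajectory metrics and MM-PBSA aggregation run on synthetic or external
data:

```r
helix <- build_helix(50)
tr <- gen_trajectory(helix, sigma = 0.5, n_frames = 2000, seed = 21)
mean(rmsf_profile(tr, selection = "CA")$rmsf)
#> [1] 0.8505422   # expected sigma*sqrt(3) ~ 0.866, minus the rigid-body fit share

binding_series(gen_energy_table(dg_mean = -163.4, dg_sd = 2,
                                n_frames = 150, seed = 31))
#> MM-PBSA binding free energy: -163.5 +/- 2.0 kcal/mol (n = 150 frames)
```

An end-to-end run (`run_config()` + `run_pipeline()`) writes stamped TSV
reports — catalog summary, paralog transfer, structural calls, MF report —
that are byte-identical across reruns with the same seed. A thin CLI wrapper
is shipped at `inst/scripts/setphen`.

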
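# funcarto

Functional cartography of dynamic network communities: who stays
together, who dissolves, who recruits outsiders, across a battery of
conditions.

`funcarto` is for analysts with multi-condition functional connectivity
data — typically fMRI regions × regions correlation matrices, one per
task condition or rest window — who want to quantify how network
community structure reconfigures across conditions and what dynamic
role each predefined node-set (a "cognitive system") plays in that
reconfiguration.

## The method

1. **Connectivity.** Node time series are residualized against a
   user-supplied design matrix (OLS; intercept always included),
   correlated per condition (Pearson), and Fisher-z transformed.
   Continuous rest runs are windowed into pseudo-conditions (default 11
   samples per window).
2. **Multislice community detection.** The condition matrices form the
   slices of one multilayer network with categorical interslice coupling
   ω. A generalized Louvain heuristic maximizes the multislice
   modularity

   Q = (1/2μ) Σ_ijsr [ (A_ijs − γ_s V_ijs) δ_sr + δ_ij ω ] δ(g_is, g_jr),

   with the Newman–Girvan null V_ijs = k_is k_js / (2 m_s) within each
   slice. An ensemble of seeded restarts (default 100) is retained in
   full.
3. **Allegiance and coefficients.** The module allegiance matrix P_ij is
   the fraction of (optimization, slice) pairs in which nodes i, j share
   a community. From P and a region-to-system map come recruitment
   R_S = (1/n_S²) Σ_{i,j∈S} P_ij, pairwise integration
   I_SkSl = (1/n_Sk n_Sl) Σ_{i∈Sk, j∈Sl} P_ij, total integration I_S,
   and per-node flexibility (proportion of slice transitions changing
   label).
4. **Cartography.** Each system's (R_S, I_S) is compared with a
   permutation null that reassigns nodes to systems preserving system
   count and sizes (default 1000 replicates, 2.5/97.5 percentile
   bands), yielding one of nine roles:
   {ephemeral, unstable, stable} × {loner, connector, integrator}.

A planted-partition generator (`planted_scenario()`,
`generate_planted_multilayer()`, `generate_role_scenario()`,
`generate_timeseries()`) provides ground-truth fixtures for every stage.

## Worked example

Plant four 8-node systems over 8 condition slices with a 10% chance per
(node, slice) that a node defects to another system, detect communities,
and map the systems:

```r
library(funcarto)
scen <- planted_scenario(flip_prob = 0.1, seed = 42)
gen  <- generate_planted_multilayer(scen)
gen$network
#> multilayer_network: 32 nodes x 8 slices (gamma = 1, omega = 0.1, truncate_negative)

ens <- run_ensemble(gen$network, n_runs = 100, seed = 1)
ens
#> partition_ensemble: 100 runs, 32 nodes x 8 slices, Q in [0.3172, 0.3212]

res <- cartography(ens, scen$systems, n_perm = 1000, seed = 2)
res
#> cartography_result: 4 systems, 32-node allegiance matrix
#>   S1             R = 0.773  I = 0.062  ->  stable loner
#>   S2             R = 0.945  I = 0.057  ->  stable loner
#>   S3             R = 0.848  I = 0.053  ->  stable loner
#>   S4             R = 0.867  I = 0.051  ->  stable loner
#>   mean network flexibility: 0.184
```

Every planted system is recruited well above its permutation band
(R between 0.77 and 0.95: its regions share a community in most slices
and runs) and integrated well below it (I ≈ 0.05–0.06: they rarely share
a community with outsiders), so all four are *stable loners* — the
expected signature of coherent planted blocks that only occasionally
shed a member. The mean flexibility of 0.184 reflects the 10% defection
rate (a defection changes a label on the way out and back).

The same pipeline runs from the shell via the installed script:

```sh
FUNCARTO=$(Rscript -e 'cat(system.file("cli", "funcarto.R", package = "funcarto"))')
Rscript $FUNCARTO simulate --out sim --seed 3
Rscript $FUNCARTO detect --input sim --gamma 1.0 --omega 0.45 --runs 100 --seed 42 --out det
Rscript $FUNCARTO cartography --ensemble det --systems sim/systems.tsv --nperm 1000 --seed 7 --out carto
```

Subcommands: `simulate`, `connectivity`, `detect`, `cartography`,
`gridsearch`, `pipeline`. Every output directory receives a
`run_manifest.json` (parameters, seeds, input checksums, version)
sufficient to re-run bit-identically. Matrices and tables are plain
TSV/CSV; structured results are JSON.

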
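# rangesse

Extinction-aware reconstruction of ancestral geographic ranges on
time-calibrated phylogenies.

## The problem

Historical biogeography is usually reconstructed from the ranges of
*extant* species under models (DEC, DIVA) that allow local extirpation
but ignore whole-lineage extinction. Extinction erases lineages — and
the places they lived — from the reconstructed tree, which can distort
both the inferred geographic origin of a clade and the timing of its
spread. `rangesse` is for phylogeneticists and biogeographers who want
to ask: *how do my ancestral ranges change if extinction was not zero?*

The package implements a state-dependent speciation–extinction (SSE)
model of ranges: the GeoSSE likelihood generalized to any number of
areas, with ranges as area subsets (capped, by convention, at 3 areas),
DEC- or DIVA-style cladogenesis, and whole-lineage extinction at a
user-fixed rate `mu`. Along every branch, two coupled vectors are
integrated from the tips to the root — `D_i`, the partial likelihood of
the observed subtree given range `i`, and `E_i`, the probability that a
lineage in range `i` leaves no sampled descendants:

```
dE_i/dt = mu - (L_i + Q_i + mu) E_i + sum_j q_ij E_j + sum_(i->j,k) lam_e E_j E_k
dD_i/dt = -(L_i + Q_i + mu) D_i + sum_j q_ij D_j + sum_(i->j,k) lam_e (D_j E_k + D_k E_j)
```

The `E` terms are what let extinct lineages, and the ranges they
occupied, inform the reconstruction. Free parameters are the in-situ and
vicariant speciation rates and the dispersal/extirpation rates;
`mu` is never estimated (trees are barely informative about it) but
swept over a four-level scenario grid `{0, bd_mu/10, bd_mu, 10*bd_mu}`
calibrated by the *speciation* rate of a standard birth–death fit
(`bd_mu`), bracketing the fossil-record expectation that extinction
rivals speciation.

On top of the likelihood the package provides maximum-likelihood fitting
with fixed `mu`, marginal ancestral-range probabilities at every node
(clamp-consistent, computed by an up/down pass), clade-origin summaries,
expected per-area species richness through time, an exact forward
(Gillespie) simulator of the same process, and an end-to-end scenario
pipeline. Everything is plain R objects (`ape::phylo` trees, data
frames) plus TSV/JSON/Newick writers.

## A worked example

The packaged synthetic dataset `iaa7_small` emulates the empirical
setting this analysis targets: a clade simulated over 45 Myr across 7
Indo-Australian Archipelago areas with non-zero lineage extinction, tip
ranges mostly of 1–2 areas.

```r
library(rangesse)

fx <- make_fixture("iaa7_small")
fx$sim
#> Forward simulation: 266 lineages total, 87 extant, horizon 45 Myr (1 attempt)
#> Events: dispersal=46, extirpation=12, in_situ=123, vicariance=9, extinction=47

res <- run_pipeline(fx$sim$tree, fx$sim$tip_states,
                    areas    = fx$space$areas,
                    max_range_size = 3,
                    seed     = 1,
                    settings = optimizer_settings(n_starts = 2),
                    options  = likelihood_options(rtol = 1e-6, atol = 1e-8),
                    out_dir  = "iaa7_out")

res$grid$summary[res$grid$summary$model == "DEC",
                 c("mu_level", "mu", "loglik", "lambda_is", "lambda_vic", "d", "e")]
#>      mu_level      mu loglik lambda_is lambda_vic        d        e
#>          zero 0.00000 -394.4   0.08953    0.02480 0.008741 0.040623
#>           low 0.01282 -394.4   0.09396    0.02890 0.008586 0.033749
#>  intermediate 0.12823 -397.5   0.14809    0.04370 0.008915 0.000001
#>          high 1.28232 -795.7   0.30261    0.04232 0.038264 0.014332
```

Reading the table: the zero/low cells recover the generating rates
(`lambda_is = 0.12`, `lambda_vic = 0.03`, `d = 0.01`, `e = 0.03`;
the data were simulated with `mu = 0.06`); as the assumed extinction
rises, the in-situ speciation estimate climbs to absorb the assumed
turnover while the dispersal rate stays put, until the deliberately
extreme `high` scenario (extinction ten times the birth-death speciation
rate of 0.128/Myr, on a 34-Myr clade) strains the model visibly — the
drop in likelihood and the convergence flags are how the grid reports
that. Each scenario carries an ancestral-origin summary and a
richness-through-time profile:

```r
res$reconstructions$intermediate$origin
#> Inferred ancestral origin: Sulawesi + Sumatra + Java (presence probability >= 0.50)

round(head(res$reconstructions$intermediate$richness$richness[, 1:5]), 3)
#>           Borneo Sulawesi Sumatra  Java Philippines
#> 34.301332  0.208    0.678   0.916 1.231       0.156
#> 33.954854  0.207    0.673   0.912 1.227       0.155
#> ...
```

(The generating simulation drew its crown ancestor in Sumatra; the
reconstruction under intermediate extinction places the origin on a
wider Sulawesi+Sumatra+Java range containing it — the widespread-origin
tendency of extinction-aware reconstructions discussed in the
vignette.)

`iaa7_out/` then contains `scenarios.tsv`/`.json`, per-level
`marginals_*.tsv`, `richness_*.tsv`, `origin_*.json`, annotated Newick
trees with the top-3 states per node, and a `run_record.json` capturing
the seed, options and software version needed to reproduce the run
byte-for-byte. A thin command-line wrapper over the same functions is
installed at `inst/cli/rangesse.R`
(`Rscript rangesse.R pipeline --tree T.nwk --ranges R.tsv --areas ... --seed 1 --out DIR`).

## Package tour

| Function | Purpose |
| --- | --- |
| `state_space()`, `parse_range()` | enumerate ranges, encode tip data |
| `anagenetic_table()`, `clado_table()` | DEC/DIVA event tables |
| `compute_loglik()` | pruning likelihood (compiled RK45 core) |
| `fit_bd()`, `bd_loglik()` | birth–death calibration (`bd_mu`) |
| `fit_lemad()` | ML rates with `mu` fixed |
| `run_scenarios()`, `compare_models()` | the 4x2 scenario grid |
| `node_marginals()`, `ancestral_origin()` | ancestral ranges |
| `richness_through_time()` | per-area richness profiles |
| `sim_config()`, `simulate_forward()`, `prune_extinct()` | exact forward simulator |
| `make_fixture()` | deterministic packaged synthetic datasets |
| `run_pipeline()` | validate -> calibrate -> fit -> reconstruct -> report |
| `loglik_matexp()`, `marginals_by_clamping()` | independent validation oracles |

See `vignettes/extinction-aware-ranges.Rmd` for the model, its
assumptions, every tunable default and the validation design.
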
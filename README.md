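# reefdyn

Spatially explicit diversification dynamics on shifting tropical reef
habitat grids.

`reefdyn` is for macroevolution and marine biogeography researchers who
want to ask how much of a clade's diversity pattern is explained by the
geography of its habitat alone. The package simulates the fate of a
single ancestral species on a time series of gridded shallow-reef
habitat masks (one slice per million years): ranges track habitat
through a truncated Weibull dispersal kernel, lineages split when their
range fragments (parapatric) or by per-cell chance events (sympatric),
and they die only when their habitat vanishes beyond dispersal reach.
The output is a full genealogy, per-step speciation/extinction series,
and site-by-species occupancy snapshots that can be confronted with
observed assemblages.

## The model in brief

At each 1-Myr step, for every extant species:

1. **Speciation.**
   *Parapatric*: if the range splits into `n` blocks under
   single-linkage clustering at sea-distance threshold `d_s` (degrees of
   arc), the species becomes `n` daughters (the parent closes as a
   pseudo-extinct node).
   *Sympatric*: each occupied cell founds a single-cell daughter with
   probability `P_s`, so expected events scale with range area,
   `S = P_s × A`.
2. **Dispersal.** Draw reach `r = min(x, d)`, `x ~ Weibull(2, d/2)`,
   and occupy all next-slice habitat within `r` of the current range.
   Empty new range ⇒ extinction.

Model selection across parameter sweeps uses per-cell richness maps
min–max rescaled to [0, 1] and

    BIC = n · ln(RSS / n) + k · ln(n)

with `n` compared cells, `k` parameters (2 single-mode, 3 combined) and
`RSS = Σ (obs − pred)²`; simulations are ranked by BIC summed over
comparisons. The validation stack includes among-site nestedness
(NODF_sites with a sequential-swap null model), Jaccard dissimilarity
and its turnover component β_jtu, packed-matrix rank congruence
(Spearman), and Mantel distance-decay tests.

## Worked example

```r
library(reefdyn)

# a scripted 140-Myr landscape: one shelf province undergoing eight
# split/reconnect episodes, plus a small offshore island from 100 Ma
L <- scenario_fragmentation_cycles()
L
#> paleo_landscape: 140 slices, 140 -> 1 Ma (step 1 Myr), grid 36x18 @ 1 deg

cfg <- sim_config("parapatric", d = 4, d_s = 5, seed = 1,
                  snapshot_ages = c(70, 35, 1))
res <- run_simulation(L, cfg)
res
#> sim_result: mode parapatric, 63 lineages total, 32 extant at 1 Ma, 3 snapshots
```

Thirty-one splits (63 lineages from one ancestor) were all triggered by
the scripted fragmentation episodes; richness doubles at the episodes
whose gaps exceed `d_s = 5` and is untouched by the 4°-gap episodes.
The assemblage structure right after an episode is strongly nested and
distance-structured:

```r
snap <- res$snapshots[["35"]]
set.seed(1); sites <- sort(sample(nrow(snap), 40))
m <- snap[sites, colSums(snap[sites, , drop = FALSE]) > 0, drop = FALSE]
nodf_sites(m)
#> [1] 77.77778
mantel_test(jaccard_dissimilarity(m),
            reefdyn:::cross_distance(as.integer(rownames(m)),
                                     as.integer(rownames(m)),
                                     distance_model("great_circle", L$spec)),
            n_perm = 999, seed = 1)
```

NODF_sites ≈ 77.8 says the species of poorer cells are largely subsets
of richer cells' assemblages — the classic signature of assemblages
built by episodic fragmentation and re-expansion.

A genealogy in Newick (branch lengths in Myr) and all event logs are a
call away:

```r
tr <- genealogy_tree(res, extant_only = TRUE)  # an ape "phylo"
write_outputs(res, "sim_out/")
```

A command-line front end with `make-landscape`, `simulate`, `sweep`,
`summarize` and `tag-origins` subcommands lives at
`inst/scripts/reefdyn.R`.

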
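# immunobn

Discrete Bayesian-network analysis of immune mediator panels measured in
several body compartments of a two-hit (sepsis + aspiration lung injury)
murine study design.

## The problem

When an indirect septic insult (cecal ligation and puncture, CLP) is
combined with a direct aspiration lung insult of graded severity given at
different intervals, the joint behaviour of dozens of cytokines,
chemokines and leukocyte populations across peritoneal lavage, blood and
bronchoalveolar lavage (BAL) cannot be read off one-contrast-at-a-time
statistics.  This package implements the network route: discretize every
variable into 3 states, score directed acyclic graphs over the panel with
the Bayesian-Dirichlet (BDeu) marginal likelihood, search network space by
simulated annealing, and summarise the top-scoring structures as a
consensus network in which an edge gets an arrowhead only when its
orientation is unanimous.  Collider ("V") motifs `a -> c <- b` with
non-adjacent parents, and "Y" motifs extending them by a directed child,
carry the causal interpretation — e.g. BAL neutrophils as a common child
of CLP and LungInsult, with eosinophils downstream.

The BDeu family score of a child with `r` states under `q` parent
configurations, with `α_j = ess/q` and `α_jk = ess/(q·r)`, is

```
Σ_j [ lnΓ(α_j) − lnΓ(α_j + N_j) ] + Σ_jk [ lnΓ(α_jk + N_jk) − lnΓ(α_jk) ]
```

summed over nodes (uniform structure prior, no seed edges).

Since no animal data are distributed, the package ships a calibrated
synthetic-cohort generator covering the full 12-group design (3 aspirates
without CLP + 3 aspirates × 3 intervals with CLP, 10 animals/group, three
compartments), with a "paper-like" ground-truth preset whose blood
neutrophil means are anchored at 1.9 × 10³ cells/µl (at the time of CLP)
and 0.8 × 10³ cells/µl (12 h after).  Conventional group statistics
(mean ± SEM, Student's t, ANOVA + Tukey HSD) are included for
side-by-side comparison.

## Worked example

Simulate a BAL compartment under the paper-like truth, analyse the
motif-relevant panel subset at desk-scale search effort, and inspect the
consensus:

```r
library(immunobn)
cfg <- pipeline_config(seed = 1, variables = c("NE", "EO", "KC", "MIP2a",
                                               "ALB"))
res <- run_compartment_analysis(cfg, "bal")
res$consensus
#> Consensus of 52 top-scoring network(s): 4 directed, 3 undirected edge(s)
#>   ALB -> EO
#>   NE -> ALB
#>   CLP -> NE
#>   LungInsult -> NE
#>   CLP -- InjuryInterval
#>   KC -- LungInsult
#>   LungInsult -- MIP2a
res$motifs
#> Motif report: 1 collider(s), 1 Y structure(s)
#>   CLP -> NE <- LungInsult
```

The consensus pools all 52 networks sharing the top BDeu score (within
1e-9).  CLP → NE and LungInsult → NE are unanimous orientations — the
collider encoded in the generator truth — while KC – LungInsult appears in
both orientations across top networks and is drawn without an arrowhead.
The Y reading continues from NE into the lung-injury readouts (here via
albumin).  The conventional analysis of the same table shows the graded
aspirate effect on neutrophil recruitment:

```r
s <- group_summary(res$table, "NE")
head(s[s$CLP == 0, ], 3)
#>   CLP LungInsult InjuryInterval  n  mean    sem
#> 1   0          1              0 10  17.7   2.56
#> 2   0          2              0 10 131.5  11.73
#> 3   0          3              0 10 609.9 116.59
```

A thin command-line wrapper over the same functions lives in
`inst/cli/immunobn.R` (subcommands `simulate`, `compartment`, `combined`,
`run-all`, `stats`; `--paper-scale` requests the original search effort of
100 restarts × 5 × 10⁷ proposals per compartment).

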
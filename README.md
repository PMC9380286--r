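# imepp

Identification of **essential proteins** from protein–protein interaction
networks (PINs) by **influence maximization**.

Essential proteins are those whose loss is lethal to the cell. Because
high-throughput interaction data are noisy and topology alone is an
imperfect predictor, this package (i) denoises the network by weighting
each interaction with independent biological evidence, and (ii) replaces
plain centrality ranking with a greedy influence-maximization scheme that
spreads the candidate set across the network instead of piling it into one
dense module. It is aimed at computational biologists benchmarking
essentiality predictors, and ships a synthetic-data generator so the whole
pipeline runs and is testable without any external downloads.

## Method

**1. Weighted PIN.** Each interaction (u, v) gets

&nbsp;&nbsp;&nbsp;&nbsp;w(u,v) = Sim_GO(u,v) · PCC⁺(u,v)

where PCC(u,v) = 1/(m−1) Σᵢ (pᵤ(i)−p̄ᵤ)/σᵤ · (pᵥ(i)−p̄ᵥ)/σᵥ is the Pearson
correlation of the two genes' expression profiles over m sampling points
(negatives clamped to 0 by default), and Sim_GO is the Wang-style semantic
similarity of their Gene Ontology annotation sets, computed from S-values
that decay by a factor of 0.8 per `is_a` and 0.6 per `part_of` edge up the
ontology DAG.

**2. Influence scores.** With Inf_topo(u) = Σᵥ w(u,v) the weighted degree
and OS(u) = nᵤ/N the fraction of reference species with an ortholog of u,

&nbsp;&nbsp;&nbsp;&nbsp;IS(u) = λ · IS_OS(u) + (1−λ) · IS_topo(u),

each part normalized by its maximum over the network. Default λ = 0.2,
i.e. topology dominates and conservation refines.

**3. Influence-discount selection.** Under the independent cascade model
with spread probability p (default 0.001), the expected residual influence
of a non-seed protein v with t(v) seed neighbors connected by total weight
tt(v) is

&nbsp;&nbsp;&nbsp;&nbsp;ID(v) = (Inf_topo(v) − tt(v) − (Inf_topo(v) − tt(v))·t(v)·p) · p,

the first-order expansion of (1−p)^t(v)·(Inf_topo(v)−tt(v))·p. k candidates
are selected greedily: extract the maximal-IS protein (indexed max-heap,
O(log |V|) per step), then discount its neighbors' IS_topo to ID(v)/p
normalized by the initial max Inf_topo. Degree-discount (`dd`) and
degree-centrality (`dc`) baselines are included.

## Worked example

Six proteins with hand-checkable numbers (`generate_toy_example()` is also
used by the regression tests):

```r
library(imepp)
toy <- generate_toy_example()
toy$pin$edges
#>   u v    weight
#> 1 A B 1.0000000     # same GO term, perfectly correlated expression
#> 2 A C 0.0000000     # anti-correlated: PCC clamped to 0
#> 3 A D 0.3221943     # (18/53) * 3/sqrt(10)
#> 4 B E 0.8000000
#> 5 C D 0.0000000
#> 6 D F 0.0000000     # F has a flat expression profile

st <- init_influence(toy$pin, toy$orthology, imepp_params(lambda = 0.2))
#>  protein IS_topo IS_OS     IS
#>        A  0.7346   0.9 0.7676
#>        B  1.0000   0.1 0.8200
#>        C  0.0000   0.8 0.1600
#>        D  0.1790   0.2 0.1832
#>        E  0.4444   0.5 0.4556
#>        F  0.0000   1.0 0.2000

select_seeds(toy$pin, st, 3)
#>   rank protein     score
#> 1    1       B 0.8200000
#> 2    2       A 0.3230543
#> 3    3       F 0.2000000
```

B wins round one (largest weighted degree). The discount then cuts A's
topological score from 0.7346 to 0.1788 — its strongest edge now leads to a
seed — so A is selected with IS 0.323, and by round three the discounts
have pushed every remaining neighbor of the seeds below F, which enters
purely on conservation (10/10 species). A plain weighted-degree ranking
would have returned B, A, E.

## Pipeline on synthetic data

```sh
inst/cli/imepp simulate --out bundle --n-nodes 500 --n-essential 50 --seed 1
inst/cli/imepp build --ppi bundle/ppi.tsv --expression bundle/expression.tsv \
    --obo bundle/go.obo --gaf bundle/annotations.gaf --out bundle/pin.tsv
inst/cli/imepp rank --pin bundle/pin.tsv --orthology bundle/orthology.tsv \
    --lambda 0.2 --k 50 --out bundle/ranking.tsv
inst/cli/imepp evaluate --ranking bundle/ranking.tsv \
    --gold bundle/essential.txt --k 25,50 --out bundle/eval.tsv
```

On that seed-1 bundle the ranking recovers **50/50** planted essentials in
the top 50, versus **20/50** for degree centrality and **5** expected at
random (printed by `scripts/acceptance.R`, below). The `sweep` subcommand
produces a λ × k hit-count grid as CSV.

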
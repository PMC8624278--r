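# efeunity

Expected float entropy minimisation and model unity for small discrete
systems.

## The problem

Take a system of `n` nodes, each in one of `m` discrete levels, observed
repeatedly (for example, a 2 × 3 grid of pixels sampled from hundreds of
posterized gray-scale images). A *primary relational model* for the system
is a pair of reflexive symmetric weighted relations — `R` on the nodes and
`U` on the levels, weights in `[0, 1]`. Relative to a model, a state `f`
has discontinuity `d(R, U∘f) = Σ_{a<b} |R(a,b) − U(f(a), f(b))|`, and its
*float entropy* is

```
fe(R, U, f) = log2 |{ f̃ : d(R, U∘f̃) ≤ d(R, U∘f) }|      (bits)
```

— the log-count of states at least as smooth as `f`. The *expected float
entropy* `efe(R, U, P) = Σ_f P(f) fe(R, U, f)` (or its sample version over
an observation multiset `T`) is minimised over all models to find the pair
`(R, U)` the system's bias determines: the interpretation under which the
system's probable states are as free of abrupt transitions as possible.

The package's main question is **model unity**: is one model stretched
across the whole system optimal, or does some partition `𝒳` of the nodes
into separately modelled subsystems do better? For each nontrivial
partition,

```
μ(𝒳, P) = Σ_{X∈𝒳} min efe(R_X, U_X, P_X) − min efe(R, U, P),
M(P)    = min over all B_n − 1 partitions of μ(𝒳, P),
```

and the system has model unity iff `M(P) ≥ 0`. Independent or jointly
irregular subsystems drive `M` negative, with the μ-minimising partition
identifying them; the package also verifies the supporting lemmas on every
analysis, enumerates maximal unified subsystems, surveys transitivity, and
compares datasets by the L1 distance between their full μ profiles.

Audience: researchers in mathematical consciousness science and anyone
studying relational-model inference over small discrete state spaces.

## Worked example

Generate a synthetic corpus of 410 observations of the six-node grid from
smooth image-like sources, fit the whole-system model, and ask whether the
system has model unity:

```r
library(efeunity)
obs <- gen_smooth_corpus(n_obs = 410, seed = 7)
obs
#> Observation set: |T| = 410 over 6 nodes, 4 levels (138 distinct states)

fit <- efe_fit(obs, control = efe_control(restarts = 6, seed = 7))
fit
#> EFE-minimising primary model
#>   system: 6 nodes, 4 levels
#>   efe_min: 4.77827 bits

round(fit$model$R, 3)
#>        node_1 node_2 node_3 node_4 node_5 node_6
#> node_1  1.000  0.919  0.450  0.812  0.518  0.427
#> node_2  0.919  1.000  0.902  0.476  0.874  0.518
#> node_3  0.450  0.902  1.000  0.451  0.462  0.852
#> node_4  0.812  0.476  0.451  1.000  0.938  0.434
#> node_5  0.518  0.874  0.462  0.938  1.000  0.991
#> node_6  0.427  0.518  0.852  0.434  0.991  1.000
```

The whole-system minimum is 4.78 bits out of a possible `log2 4^6 = 12`,
and the fitted `R` recovers the sampling-grid geometry: horizontally and
vertically adjacent nodes (1–2, 2–3, 4–5, 5–6) carry the strongest
weights. The unity analysis fits every subsystem (63 memoised
optimisations) and scans all 202 nontrivial partitions:

```r
rep <- unity_analysis(obs, control = efe_control(restarts = 6, seed = 7))
rep
#> Model-unity analysis: 6 nodes, 202 partitions
#>   whole-system efe_min: 4.77827 bits
#>   M = 0.501558 bits -> model unity
#>   argmin: {node_1,node_2,node_3} | {node_4,node_5,node_6}
#>   lemma-1 check: passed
```

`M = 0.50 > 0`: even the best decomposition (the two rows) loses half a
bit to the single whole-system model, so this system has model unity —
as expected for a corpus in which all six nodes sample one smooth source.
Replacing the corpus with `gen_independent_pair()` (two independent rows
combined as a Cartesian product) flips the verdict: `M < 0` with the row
split as the minimiser and each row individually unified.

How strongly the data determine the optimum:

```r
efe_histogram(obs, n_random = 200, seed = 7)
#> EFE over 200 random models: min 9.21605, mean 10.554, sd 0.4494 bits
#>   maximum-entropy reference (all-ones U): 12 bits
#>   model-determination gap (mean - min): 1.33798 bits
```

The fitted minimum (4.78 bits) sits far below anything random models reach.

A thin command-line interface wraps the same functions
(`exec/efeunity synth|sample|minimise|unity|maximal|mode-distance|histogram|example`).

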
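---
title: "Expected float entropy minimisation and model unity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expected float entropy minimisation and model unity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A *system* is a finite set of nodes $S$ ($n = |S|$), each taking one of $m$
discrete value levels $V = \{0, \dots, m-1\}$. A *system state* is a map
$f : S \to V$; the state space $\Omega_{S,V}$ has $m^n$ elements. Data
arrive either as an explicit probability distribution $P$ over
$\Omega_{S,V}$ or, in practice, as a finite multiset $T$ of numbered
observations (repetitions count).

A *primary relational model* is a pair $(R, U)$ of reflexive symmetric
weighted relations — $R$ on the nodes, $U$ on the levels, all weights in
$[0,1]$ with unit diagonal. A state $f$ induces the node relation
$U \circ f = U(f(\cdot), f(\cdot))$, and its *discontinuity* under the
model is the $d_1$ distance

$$d(R, U\circ f) \;=\; \sum_{\{a,b\}\subset S,\,a\neq b}
  \bigl|R(a,b) - U(f(a), f(b))\bigr|,$$

summed over unordered off-diagonal pairs. Small discontinuity means the
state "looks smooth" in the geometry the model encodes.

The *float entropy* of a state is the log-size of its accessible set —
the states that are at least as smooth:

$$\mathrm{fe}(R,U,f) = \log_2\bigl|\{\tilde f :
  d(R, U\circ\tilde f) \le d(R, U\circ f)\}\bigr|,$$

and the *expected float entropy* (EFE) is its mean under $P$ (or the
multiplicity-weighted mean over $T$). The model a system determines is
the EFE-minimising pair $(R, U)$. Intuitively, the optimal model is the
interpretation under which the system's probable states are as free of
abrupt transitions as possible; a model with no relational distinctions
at all (all weights equal) makes every state tie and yields the maximum
$\log_2 m^n$ instead.

For a partition $\mathcal{X}$ of $S$ into subsystems, each block $X$ gets
its own optimally fitted model on the marginal/restricted data, and

$$\mu(\mathcal{X}, P) = \sum_{X \in \mathcal{X}}
  \min \mathrm{efe}(R_X, U_X, P_X) \;-\; \min \mathrm{efe}(R, U, P), \qquad
  M(P) = \min_{\mathcal{X}} \mu(\mathcal{X}, P),$$

with the minimum over all $B_n - 1$ nontrivial partitions. The system has
*model unity* iff $M(P) \ge 0$: no decomposition into separately modelled
subsystems beats one model stretched across the whole system. Two
theorems are used as implementation oracles: every multi-node block of a
$\mu$-minimising partition itself has model unity, and (for a unique
argmin with $M<0$) no union of argmin blocks has it; `verify_lemma1()`
recomputes both on every analysis, and a violation flags optimiser
failure rather than new mathematics.

The equivalent *ratio identity* evaluates $\mu$ as
$\sum_f P(f) \log_2(|A_{\mathcal{X}}(f)| / |A_{\{S\}}(f)|)$ where
$|A_{\mathcal{X}}(f)|$ is the product of the blocks' accessible-set sizes
at the restrictions of $f$. `mu_ratio()` implements it with the same
fixed models as `mu()`; the two routes agreeing to $10^{-9}$ bits is a
standing regression test, and the product of block accessible sets never
exceeding $|\Omega_{S,V}|$ is checked exhaustively on small systems.

## Numerical design

**Tie tolerance.** The accessible-set inequality $d \le d(f)$ makes ties
first-class: analytically equal discontinuities computed in different
orders must still tie. Counts use an absolute tolerance `eps_tie`
(default `1e-9`; set 0 for strict floating-point comparison). All float
entropies are reported in bits.

**Sorted profile.** For each model the discontinuities of all $m^n$
states are computed once (in C++), sorted, and float entropies become
rank lookups. The state-space cap (default $10^6$ states) guards the
enumeration; larger systems raise an explicit error rather than
approximating.

**The objective is a step function.** Float entropies are logs of
integer counts, so EFE as a function of the $k(k-1)/2 + m(m-1)/2$ free
weights is piecewise constant, with a discrete set of attainable values.
Two consequences drive the optimiser design. First, simplex methods
stall on plateaus, so each restart of `efe_fit()` runs a full pipeline —
Nelder–Mead (clipped to the unit box) alternated with a deterministic
coordinate-descent polish on a geometric step ladder until neither
improves — and the fit is the minimum over restart pipelines. Polishing
per restart matters: which start polishes lowest is not predictable from
its pre-polish value, and the per-restart structure makes the returned
minimum monotone non-increasing in the restart count. Second,
independent runs that reach the bottom step agree *exactly*, which is
what makes invariance properties testable at $10^{-6}$ bits.

**Exact two-node solver.** With a single node pair,
$d(f) = |r - U(f_1, f_2)|$: the state space splits into level-pair groups
whose $d$ values can be ordered arbitrarily, ties never lower EFE, and
every strict order is realisable. `efe_fit()` therefore solves two-node
contexts ($m \le 4$) by enumerating the $(m(m-1)/2 + 1)!$ group orders —
the true global minimum, deterministically. This matters because
two-node blocks appear in most partitions.

**Canonical gauge.** EFE is invariant under simultaneous level
permutation (of $U$ and the data) and node relabelling (of $R$ and the
data). Fits are performed in a canonical gauge — levels ordered by
(frequency, sorted co-occurrence profile), nodes by (level distribution,
sorted agreement rates), with the fitted model conjugated back
afterwards — and the random-restart stream is seeded from the canonical
data content, not from labels. Datasets that differ only by relabelling
therefore receive the *identical* optimisation, making fitted minima
exactly invariant; this is how the value-permuted design reproduces its
unpermuted subsystem optima to machine precision. Exact ties in the
gauge statistics would fall back to input order; with realistic corpora
they do not occur.

**Budgets.** Small parameter spaces are cheap to evaluate and
proportionally more multimodal, so restarts are scaled up (×4 for
dimension ≤ 10, ×2 for ≤ 14). The default `efe_control()` uses 32
restarts; the seeded design batteries in the test suite use 3 and the
acceptance script 6 (i.e. 12–24 effective restarts for three-node
blocks), 500 Nelder–Mead iterations per simplex pass and relative
tolerance $10^{-6}$, which on the six-node, four-level systems studied
here makes a full unity analysis (63 subsystem optimisations, memoised
across the 202 partitions; singletons use the closed form $\log_2 m$)
run in well under a minute while reproducing the same discrete minima
as much larger budgets in spot checks. The iterative grid search (full factorial grid, re-centred and
shrunk by 0.5 per iteration) is kept as an independent cross-check for
low-dimensional objectives; a full grid is impractical beyond roughly
ten dimensions and `grid_search()` refuses it.

**Unity decision tolerance.** Definition-level statements ($M \ge 0$,
argmin uniqueness) are applied to computed minima, which carry optimiser
noise; `eps_unity` (default $10^{-6}$ bits) pads the decision and groups
argmin ties. Lemma-2 assertions (maximal subsystems equal the argmin
blocks) additionally require a unique argmin, matching the lemma's
hypothesis.

**Effective level sets.** A subsystem's marginal support can in
principle use fewer levels than $V$. By default blocks keep the full
level set, the usual case for comparable nodes; `strict_vx = TRUE`
recomputes each block's effective value set and shrinks its state space
accordingly. All shipped examples have $V_X = V$.

**Degenerate data.** A corpus with a single distinct state makes every
model with a strict minimum at that state optimal; the fit reports the
minimum and flags non-uniqueness rather than failing.

## The sampling protocol

Images are desaturated (ITU-R BT.601 weights — the original protocol
does not specify its desaturation), optionally contrast-stretched
(min–max to $[0,255]$; off by default since it is not needed, merely
sample-efficient), posterized to $m$ equal-width gray bins, and read at
one pixel per node on a rows × cols grid (default 2 × 3, node 1
top-left, row-major). Level labels such as physical gray values are
carried as display metadata only; the mathematics sees levels
$0..m-1$. Pixel coordinates are 0-based, x rightward, y downward; exact
anchor and spacing are configurable and nothing downstream depends on
them.

## What the synthetic generators emulate

The study conditions are corpora of photographs sampled on the six-node
grid. The generators reproduce their statistical structure with
Gaussian-blurred white noise rendered through the same
stretch–posterize–sample pipeline, at the study's sizes (410
observations for single corpora; 200 × 200 Cartesian products for the
independent pair):

* `gen_smooth_corpus()` — one smooth source per observation: spatially
  adjacent nodes correlate and adjacent gray levels co-occur, the bias
  that lets EFE minimisation recover the grid geometry in $R$ and the
  gray scale in $U$. The blur length scale defaults to twice the node
  spacing (12 px against the default 21 × 15 px field), so adjacent
  samples usually fall within one smooth region, as in photographs
  dominated by extended surfaces. As the length scale shrinks toward
  white noise the μ profile flattens toward zero.
* `gen_independent_pair()` — two independent three-node row corpora
  combined by `product_observations()`, the sample analogue of a product
  distribution: exactly zero empirical mutual information between rows.
* `gen_mismatched_pair()` — each observation pairs the top-row sample of
  one field with the bottom-row sample of another: rows are similarly
  distributed but jointly irregular, and as samples not exactly
  independent (a rare top-row state pins its paired bottom-row state).
* `gen_permuted_pair()` — the mismatched design with bottom-row values
  mapped through a derangement that is not a gray-scale automorphism
  (default the 4-cycle), making the rows differently distributed as
  well.

What they do **not** emulate: heavy-tailed luminance statistics,
occlusion edges, textures, and long-range structure of real photographs,
or anything about cortical data. Passing the analog batteries shows that
the unity machinery responds correctly to presence/absence of joint
regularity and independence — not that any particular real-world system
has or lacks model unity, and the minimised EFE values of the original
photographic corpora are properties of those corpora, not reproducible
from synthetic stand-ins.

Stochastic test thresholds (e.g. "at least 8 of 10 seeds") are artifact
policy for seeded batteries, not claims from the underlying theory.

## Diagnostics beyond M

`efe_histogram()` samples uniformly random models and reports the gap
between mean and minimum EFE — how strongly the data determine their
optimal model; structured corpora separate markedly, shuffled ones do
not. `mode_distance()` compares two datasets on the same system by the
$L_1$ distance between their full μ profiles, a probe of how a change in
the system's bias moves its unity structure. `maximal_subsystems()`
enumerates all subsystems with unity whose every strict enlargement
lacks it, and `check_transitivity()` surveys unity transitivity over
disjoint triples; both are reported as empirical surveys, with the
lemma-2 coincidence asserted only under its hypotheses (disjoint maximal
subsystems, unique argmin).

## Known limitations

* All computations enumerate the state space; systems beyond the cap are
  rejected, and partition analysis is guarded to 12 nodes
  (practically: 8).
* Global optimality of fitted models is not certified for three or more
  nodes; the exact two-node solver, multistart with polish, dual
  optimisers, and the lemma-1 oracle are mitigations, and `mu`
  comparisons inherit whatever bias a systematically under-optimised
  block would introduce.
* The optimal model is determined only up to the resolution the step
  landscape allows; analyses therefore compare EFE values, never raw
  model parameters.
* Only single (primary) relational models are implemented; hierarchies
  of higher models over features are out of scope, as is any reading of
  $M$ as a measure of consciousness.
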
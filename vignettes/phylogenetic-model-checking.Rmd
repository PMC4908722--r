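---
title: "Stochastic model checking over phylogenetic trees: models, algorithms, choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic model checking over phylogenetic trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloMC)
```

# The model

Evolution of a single alignment column is modeled as a continuous-time
Markov chain on the nucleotides: a labeled tuple $M = (S, S_0,
\mathbf{R}, L)$ where $\mathbf{R}(s,s') \ge 0$ is the transition rate,
holding times are exponential, and $L$ assigns each state its atomic
propositions (here chiefly "site $i$ carries base $\sigma$", written
`xi=sigma`). Two derived objects drive all computations:

* the **infinitesimal generator** $Q$ (off-diagonal rates, diagonal the
  negative row sums), with transient probabilities
  $P_t = e^{Qt}$;
* the **embedded jump chain** $P_{emb}(s,s') = \mathbf{R}(s,s')/E(s)$
  with exit rates $E(s) = \sum_{s'} \mathbf{R}(s,s')$; absorbing states
  ($E = 0$) get a unit self-loop.

A phylogenetic tree is the unfolding of such a mutation model: `toPTS`
converts a fully labeled tree into a transition system whose states are
tree nodes, whose edge weight from parent to child is the product over
sites of the substitution probabilities $P_{b,b'}(d)$ at the branch
length $d$ (site independence), and whose leaves receive unit self-loops
so that **all paths are infinite** — the temporal-logic semantics
requires this, and several formulas (the structural `leaf` predicate in
particular) exploit it.

## Substitution models

JC69, K80, F81 and GTR share the reversible parameterization
$Q(i,j) = s_{ij} f_j$ with symmetric exchangeabilities $s_{ij}$ and
stationary frequencies $f$. The generator is rescaled so that the
stationary substitution rate $-\sum_i f_i Q(i,i)$ equals `nu`
(substitutions per site per unit time, default 1). This is the standard
phylogenetic convention: branch lengths then read as expected
substitutions per site, and the JC closed forms
$P_{ii}(d) = \tfrac14 + \tfrac34 e^{-4\nu d/3}$,
$P_{ij}(d) = \tfrac14 - \tfrac14 e^{-4\nu d/3}$ hold exactly — the test
suite pins the numerical transient to them at $10^{-10}$.

Parameters that matter:

| parameter | meaning | default |
|---|---|---|
| `nu` | overall substitution rate (subst/site/time) | 1 |
| `kappa` (K80) | transition/transversion rate ratio (dimensionless) | 2 |
| `freqs` (F81/GTR) | stationary base frequencies | — |
| `exch` (GTR) | six symmetric exchangeabilities | — |

# The logic and its algorithms

State formulas follow the minimal grammar `true | p | !phi | phi or phi
| P~lambda[path]`; path formulas are `X phi` and `phi U_I psi` with a
closed interval $I$ ($[t,t]$ is legal). `F`, `G`, `and`, `implies` are
normalized away at construction; `G_I phi` is kept as the dual of
eventually, evaluated as $1 - \mathrm{Prob}(F_I \neg\phi)$.

`Prob(s, X phi)` sums embedded jump probabilities into the target set.
The until operator follows the interval case analysis:

* $[0,t]$: transform the chain so that target states and
  (neither-side) states are absorbing, then read the transient matrix —
  the standard bounded-until semantics. The printed boundary cases fall
  out exactly: probability 1 on target states, 0 on neither-states and
  at $t = 0$.
* $[0,\infty]$: solved on the embedded jump chain as a linear system
  $x = P_{emb} x + b$ **after** graph classification of the
  probability-0 states (backward reachability through permitted
  states). The preclassification matters twice over: it makes true
  zeros exact (so the qualitative `P>0` comparator is sound), and it
  removes the self-loop cycles — every leaf of a tree transition system
  is one — that would otherwise make $I - P_{emb}$ singular.
* $[t,t']$ and $[t,\infty]$: a first phase that must remain in
  permitted states for time $t$ (non-permitted states made absorbing,
  transient at $t$), composed with a $[0, t'-t]$ (resp. unbounded)
  continuation.

Transients use **uniformization**: with $q = \max_s |Q(s,s)|$ and $M = I
+ Q/q$, $P_t = \sum_k \mathrm{Pois}(k; qt) M^k$, truncated when the
neglected Poisson tail drops below $10^{-15}$ (well under the $10^{-12}$
structural tolerance; every term is stochastic, so the scheme is robust
for the stiff rate ratios GTR permits — the reason it was chosen over
naive series summation, whose cancellation error grows like
$e^{\|Qt\|}\epsilon$).

## Comparator tolerances

Floating-point equality at the qualitative thresholds is meaningless, so
probabilities within $10^{-9}$ of 0 or 1 are snapped to the boundary
before applying $\sim \lambda$, and `=` compares within the same
tolerance. Strict `>` is left exact: the graph preclassification
guarantees that impossible events come out as exactly 0, so `P>0` never
misfires on roundoff.

## The `leaf` predicate and a documented corner

`leaf` is defined as: for every proposition $p$ of the model, $p$ holds
now iff $p$ holds in all successors ($P_{\ge 1}[X\,p]$). On a tree
transition system this selects the self-loop leaves — and also,
literally, any internal node all of whose children carry a sequence
identical to its own. We implement the formula literally and keep the
corner: it is observable (`test-logic.R` exercises it) and collapsing it
silently would make `leaf` disagree with its definition.

## Timed patterns under race semantics

Branch traversal in a CTMC is exponential, not deterministic. A
violation two branches below the root therefore has *positive*
probability of occurring within any time bound $t > 0$, so
$P_{\ge 1}[G_{\le t}\, p]$ fails whenever the violation is reachable at
all. Time bounds separate patterns through the *probability*, not
through hard satisfaction: $\mathrm{Prob}(G_{\le t})$ decreases in $t$
toward the untimed value, and thresholds below 1 (e.g.
$P_{\ge 0.9}[G_{\le t}\,p]$) distinguish early from late violations.
The test suite asserts exactly this ordering.

# Likelihood

Felsenstein pruning computes the partial likelihoods
$$L^l_{X,i} = \prod_{c \in \mathrm{children}(X)} \sum_j
P_{ij}(d_{Xc})\, L^l_{c,j},$$
with leaf partials the 1/0 indicators of the observed base, root
combination $L^l = \sum_i f_i L^l_{\mathrm{Root},i}$ and total
$L = \prod_l L^l$. Design choices:

* **Cache contract.** Each partial is computed exactly once —
  `evalCount` equals #nodes × #sites × 4, asserted by tests. Transition
  matrices are cached per distinct branch length.
* **Underflow.** Per-site partials are rescaled when their maximum
  drops below $10^{-280}$ and the log-scale accumulates per node, so
  log-likelihoods of long alignments stay finite while short-alignment
  partials remain exact (not merely log-accurate).
* **Fixed ancestors.** Internal nodes whose sequence is supplied (e.g.
  a parsimony reconstruction) keep the 1/0 constants for their known
  base rather than being summed over — the initialization shortcut for
  precomputed ancestral states.
* **Multifurcations** are accepted: the recursion is a product over any
  number of children, a strict generalization of the binary equations.
* **Zero-length branches** are legal and yield identity transition
  matrices.

`bruteForceLikelihood` enumerates all $4^k$ assignments of bases to the
$k$ free internal nodes and sums the unfactorized product — exponential,
refused beyond 10 free nodes, and existing purely as the oracle the
recursion is checked against (200 random trees, relative $10^{-10}$, in
the test suite).

## The upper-bound heuristic

The heuristic relaxes the exact sum to per-leaf root-to-tip transitions
at distance $D_Z$ (sum of branch lengths to leaf $Z$):

* `independent` (canonical): $U^l = \prod_Z \max_i P_{i,Z(l)}(D_Z)$ —
  each leaf path maximized separately;
* `shared-root`: $U^l = \max_i f_i \prod_Z P_{i,Z(l)}(D_Z)$ — all
  leaves hang as disjoint routes from one root base.

Runtime is linear in the number of leaves. Whether either variant truly
bounds the exact likelihood is an **empirical claim, not a theorem of
this package**: the shared-root expression is a single term of the
exact root sum (hence provably *below* the exact value on star trees),
and the coverage study in the test suite and acceptance script reports,
under its fixed seeds, the independent variant above the exact
likelihood in roughly three quarters of 100 random Yule replicates
(5–10 tips, JC, one site) and the shared-root variant in well under a
quarter. The package therefore *records* coverage fractions per
replicate set instead of asserting a bound.

# Synthetic data: what it emulates and what it does not

`yuleTree` builds trees backward: starting from `nTips` present-day
lineages, a uniformly chosen pair merges after an exponential waiting
time with rate $k \cdot \mathrm{birthRate}$ for $k$ extant lineages — a
coalescent-style pure-birth construction. The default `birthRate = 1`:
only relative branch lengths matter for every demonstration in the
package, since the substitution rate `nu` sets the time unit. Waiting
times at fixed $k$ are exponential by construction, and a
Kolmogorov–Smirnov test against $\mathrm{Exp}(k\cdot b)$ (n = 5000,
$\alpha$ = 0.01) guards the implementation.

`evolveSequences` draws the root from the stationary frequencies and
each child from the parent's transition-matrix row — exactly the model
the likelihood assumes. Site-pattern frequencies on a fixed 4-taxon tree
match pruning-predicted probabilities within total-variation 0.02 at
$10^5$ sites.

What passing these tests does **not** show about real data: the
generator produces ultrametric trees, site-homogeneous evolution, no
rate variation across sites (no Gamma mixture), no indels or ambiguity
codes, and no model misspecification. Agreement between simulator and
likelihood is an internal-consistency check of both, not evidence that
any particular biological alignment follows the model.

All simulation entry points require an explicit seed; there is no hidden
global RNG state (the caller's RNG state is saved and restored).

# Problem sizes

The default test run uses: 100 random chains (≤ 6 states) for
structural/semigroup checks; 200 random Yule trees (3–8 leaves, 1–3
sites, JC and random GTR) for pruning vs enumeration; 50 instances for
site factorization; 50 chains × $10^5$ trajectories for the Monte-Carlo
until oracle (agreement within 3 binomial standard errors); 100 labeled
trees (≤ 20 tips) for the qualitative-reduction check; 100 constructed
trees for back-mutation detection; 100 replicates for the upper-bound
study plus one 1000-tip probe; 5000 Yule waiting times and $10^5$
evolved sites for simulator fidelity. These sizes keep the full suite
around half a minute while leaving each estimate's sampling error far
inside the asserted tolerances.

# Known limitations

* No steady-state analysis, reward structures, or nondeterministic
  models; intervals are closed only.
* No IUPAC ambiguity codes, gaps, or indels; unrooted trees are
  rejected, not rerooted; no branch-length or topology optimization
  (tree search is out of scope by design).
* No rate heterogeneity across sites; no codon or amino-acid models.
* The PRISM export targets semantic fidelity to the published grammar
  and round-trips through this package's own readers; byte-level
  equivalence with any particular external encoding is not claimed, and
  the PRISM tool itself is never invoked.
* The local-maximum propagation shortcut for likelihood search is
  deliberately not implemented: its propagation rule is underspecified,
  and a wrong guess would silently change results.
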
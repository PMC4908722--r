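# phyloMC

Probabilistic model checking for phylogenetics: DNA substitution models
and phylogenetic trees are treated as continuous-time Markov chains
(CTMCs), and questions about them — conservation of an alignment column,
confinement of deleterious patterns to the leaves, point and back
mutations, and the likelihood of a tree under a mutation model — are
posed as stochastic temporal-logic formulas and answered exactly.

The package is aimed at phylogeneticists who want a single, declarative
query language over trees *and* at model-checking practitioners who want
a worked stochastic-logic case study with an exact numerical back end.

## What it computes

**CTMC machinery.** A labeled CTMC `M = (S, S0, R, L)` has transient
probabilities `P_t = exp(Qt)` (computed by uniformization), an embedded
jump chain `P_emb(s,s') = R(s,s')/E(s)` with exit rates `E`, and
cylinder-set path probabilities. Substitution models (JC69, K80, F81,
GTR) are CTMCs on `{A,C,G,T}` with generator `Q(i,j) = s_ij f_j`,
normalized so branch lengths are expected substitutions per site when
the overall rate is `nu = 1`; for JC the transition probabilities have
the closed form `P_ii(d) = 1/4 + 3/4 e^{-4 nu d/3}`.

**Temporal logic.** State formulas `true | p | !phi | phi|phi |
P~lambda[path]` with path formulas `X phi` and interval-bounded
`phi U_I psi` (`F`/`G` derived). `P>=1[...]`/`P>0[...]` recover the
qualitative for-all/exists semantics on trees; `P=?[...]` returns
probabilities. Builtin macros: `leaf`, `global(p,t)`, `terminal(p,t)`,
`pointmut(i,sigma,alpha,lambda)`, `hasBM(col)`, `detectBM(n)`.

**Likelihood.** Felsenstein pruning over cached partials
`L^l_{X,i} = prod_c sum_j P_ij(d_Xc) L^l_{c,j}`, root-combined with the
stationary frequencies and multiplied across sites; a brute-force
enumeration over ancestral states as an in-package oracle; and a
linear-time per-leaf upper-bound heuristic for the likelihood.

**Simulation.** Backward (coalescent-style) Yule trees, sequence
evolution along a tree, CTMC trajectory sampling, and an experiment
harness reproducing the likelihood-scaling study design.

**PRISM export.** Substitution models as PRISM `ctmc` modules and tree
likelihood properties as `filter(...)` property files, round-trip
readable by the package's own parsers.

## Worked example

A four-taxon tree with a 4-site alignment (both shipped in
`inst/extdata`):

```r
library(phyloMC)
treeF  <- system.file("extdata", "example_tree.nwk",       package = "phyloMC")
fastaF <- system.file("extdata", "example_alignment.fasta", package = "phyloMC")

tree  <- attachAlignment(readNewick(path = treeF), readFastaAlignment(fastaF))
model <- jukesCantor()

tab <- prune(tree, model)
tab
#> LikelihoodTable: 5 nodes x 4 sites
#>   log-likelihood: -16.08238665
logReport(tab)
#>   site likelihood    logLik
#> 1    1 0.01869139 -3.979692
#> 2    2 0.01945397 -3.939704
#> 3    3 0.01945397 -3.939704
#> 4    4 0.01465042 -4.223286
upperBound(tree, model, "independent", log = TRUE)
#> [1] -14.36347
```

The per-site log-likelihoods sum to the total (sites evolve
independently); the heuristic bound `-14.36` sits above the exact
`-16.08`, as the relaxation intends.

Temporal-logic checking needs a fully labeled tree (ancestral sequences
given, e.g. by parsimony); `toPTS` converts it into a transition system
with leaf self-loops:

```r
pts <- toPTS(attachAlignment(readNewick(path = treeF),
             c(R = "CAGT", S = "CAGA", Z = "AAGT",
               X = "AAGT", Y = "CAGT")), model)
checkFormula(pts, "global(x3=G)")
#> SatResult for P>=1[G x3=G]
#>   satisfied in 5 state(s)
stateProbs(checkFormula(pts, "P=?[F<=5 x1=A]"))
#> X Y R S Z
#> 1 0 0 0 1
evalQuery(pts, "filter(min, P=?[F<=5 x1=A], x1=C)")
#> [1] 0
```

Site 3 is conserved everywhere, so the global pattern holds in all five
states. Base A at site 1 is only ever "reached" by states that already
carry it — in this labeled tree no C-state can mutate into an A-state,
so the filtered minimum probability from `x1=C` states is 0.

A command-line shim over the same functions is installed at
`inst/cli/phylomc.R`:

```sh
Rscript inst/cli/phylomc.R likelihood --tree t.nwk --fasta a.fasta \
    --model jc.json --engine exact --out out.tsv
```

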
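---
title: "Testing topological hypotheses and distance-matrix regressions against posterior tree samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing topological hypotheses and distance-matrix regressions against posterior tree samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomrm)
```

phylomrm implements the two statistical layers that turn a Bayesian
posterior sample of phylogenies plus a taxon metadata table into tests of
taxonomic hypotheses: the *Bayesian topological test* (the posterior
frequency of a topological constraint, here written P~p~) and *multiple
regression on distance matrices* (MRM) with matrix-permutation
significance tests. This vignette documents the models, the conventions
the package commits to where several were defensible, the simulators used
to validate everything, and the limits of what those validations show.

## Posterior pooling

MCMC samplers for phylogenies write thinned tree samples per independent
run. `mcmc_spec(generations, interval, burnin)` describes the sampling
design and `pool_posterior()` concatenates the post-burn-in samples across
runs. Two conventions matter:

* **The sample at exactly the burn-in generation is discarded** (the
  cutoff is inclusive on the discard side). With two runs of 10^7
  generations sampled every 1000 and a cutoff of 4×10^6, each run retains
  the 6,000 samples at generations 4,001,000…10^7 and the pool holds
  12,000 trees. Conveniently, this count is the same whether or not the
  sampler wrote out generation 0, so the convention is robust to that
  common ambiguity in tree files.
* **Trees without parseable generation indices** (plain Newick files, or
  Nexus tree names that match none of `STATE_N` / `gen.N` / `rep.N`) are
  assigned `i × interval` for the i-th sample. This matches thinned tree
  files that omit generation zero and keeps pooling deterministic.

Underscores in taxon labels are preserved verbatim, never converted to
spaces, so labels join bit-stably against the metadata table. Polytomies
are accepted everywhere: consensus and constraint trees are legitimately
multifurcating.

## The topological test

For a constraint *C* and a pooled set of *T* trees, the statistic is
P~p~ = 100·*N*/*T* where *N* counts trees consistent with *C*.

**Monophyly on unrooted trees is bipartition existence**: a group is
monophyletic when some edge splits the leaves exactly into (group | rest).
The match must be exact — a polytomy covering the group plus other taxa
does not count, which is the strict reading of "fits the hypothesis".
When an outgroup is given, the statement is the rooted one (root on the
outgroup's attachment edge, then require a node whose descendants equal
the group); because the outgroup is disjoint from the group, this
coincides with bipartition existence, which is how it is evaluated.

**Constraints** name disjoint groups and may add a backbone tree over the
group names. A tree is consistent when every group of two or more taxa is
monophyletic in the tree restricted to the grouped taxa (plus outgroup),
and every internal bipartition of the backbone — expanded to taxon sets by
group membership — exists in the restricted tree. Design choices made
here, where the requirements admitted more than one reading:

* Taxa in no group are ignored by restriction (the *soft* interpretation),
  so ungrouped outgroup taxa cannot break a backbone hypothesis about
  subgenera.
* With a single group and no outgroup there is nothing to restrict
  against, and the test reduces to plain monophyly on the full tree. (The
  literal restrict-first reading would make every single-group constraint
  trivially true.)
* With an outgroup the backbone is read as **rooted**: each of its clades,
  expanded to taxa, must be a split of the restricted tree against
  everything else including the outgroup. Without one, only the backbone's
  unrooted internal splits are testable — but triviality is judged on the
  *expanded taxon sets*, since a singleton group can still expand to a
  nontrivial split.
* Under these semantics, adding a group to a constraint is guaranteed to
  keep or decrease *N* when the added groups preserve taxon coverage
  (the property the test suite checks); changing the coverage changes the
  restriction and with it the reference set of the test.

**Display rounding.** P~p~ is reported both exactly and rounded half-up at
two decimals *on the exact rational* N/T, computed in integer arithmetic:
33/12,000 is exactly 0.275% and prints 0.28, where naive binary-float
rounding could print 0.27. This choice makes printed percentages
reproducible from printed counts.

## Multiple regression on distance matrices

The response **Y** (node distance) and each predictor are vectorized to
their n(n−1)/2 lower-triangle entries in a shared canonical taxon order
(the metadata table's row order), and ordinary least squares with an
intercept is fitted to the pairs.

* **Node distance** counts *internal nodes* on the leaf-to-leaf path, not
  edges: sister taxa in a cherry are at distance 1 (two edges, one node).
  Rooting matters — the root is an internal node on every path crossing
  it — so the matrix is computed on the tree as rooted in the input, with
  `unroot = TRUE` available to collapse a bifurcating root first. Both
  conventions are explicit because summary trees are published both ways.
* **Taxonomy**: 0 within a subgenus, 1 between. **Habitat**: 0 when the
  two taxa's habitat sets intersect (a stream+cave taxon is equally close
  to stream and to cave taxa), 1 otherwise; codes are a closed vocabulary
  validated at load, because a silent typo would corrupt the matrix.
  **Geography**: haversine great-circle distance in meters between sample
  coordinates on a sphere of radius 6,371,008.8 m (the IUGG mean; the
  radius is a parameter). Distances are between *samples*, not species
  centroids, so several samples per species are allowed.
* **Sequential (type-I) sums of squares** in the user-supplied predictor
  order, default (taxonomy, geography, habitat). Sequential SS are the
  convention under which the decomposition SST = ΣSS~k~ + SSE holds
  exactly, which is what lets a published table's footer (error SS,
  percent variance explained) be recomputed from its SST and per-predictor
  SS alone — `variance_decomposition()` does exactly that. Added-last SS
  would not sum.
* **Partial correlations** are correlations of residuals: Y on all other
  predictors versus X~k~ on all other predictors.

### The permutation test

Significance is assessed by permuting the *response matrix's* taxa: a
uniform random permutation is applied simultaneously to rows and columns
of **Y**, predictors fixed, and the model is refitted (Manly's scheme for
symmetric matrices — permuting Y preserves the joint structure among the
predictors). Conventions:

* **Add-one estimator** p = (b+1)/(R+1); with R = 10,000 the smallest
  reportable p is ≈ 0.0001. Two-sided for coefficients via |β|; upper-tail
  for sequential SS, which are nonnegative by construction.
* **The identity permutation is never drawn** (it is redrawn on the rare
  occasions Fisher–Yates produces it), so the +1 counts only genuine
  resamples and a perfect fit attains exactly p = 1/(R+1).
* One seeded generator drives the whole permutation stream, shared by the
  coefficient and SS counts of one run, so runs are bit-reproducible.
* `permutations = "exhaustive"` enumerates all n! permutations (n ≤ 8)
  and reports exact p-values; the sampled and exact estimators agree by
  construction when sampling covers the full group.
* A `permute = "predictors"` variant (all predictor matrices permuted
  jointly, response fixed) is exposed for sensitivity analysis; the
  response-permutation scheme is the default and is recorded in the
  output.

Degenerate inputs fail loudly: an all-constant predictor (e.g. the
taxonomy matrix of a single-subgenus table) raises a rank error naming the
offending predictor rather than being silently dropped; asymmetric
matrices beyond 1e-9, zero-variance responses, and mismatched label sets
are all errors. Internally each refit reuses the design's QR
factorization — only Q′y changes under a permutation of Y — which is what
makes 10^4 permutations and the simulation studies below cheap.

## The simulators and what they do (and do not) show

`simulate_yule_tree()` grows a pure-birth topology by iterative random
leaf attachment with exponential branch lengths. `simulate_tree_set()`
plants a focal clade at a controlled frequency: *consistent* trees join an
independent subtree on the clade to one on the remaining taxa (the clade's
split exists by construction); *inconsistent* trees swap one taxon across
that split and are verified to break the clade. The deterministic mode
places exactly f·T consistent trees at shuffled positions (and insists
f·T be integral); the Bernoulli mode draws each tree independently.
`simulate_metadata()` assigns subgenera either as actual clades of the
tree (taxonomy tracks phylogeny — planted signal) or as shuffled labels
(pure noise); habitats are drawn from stated probabilities with a stated
multi-habitat rate (defaults 0.5/0.3/0.2 for stream/burrow/cave and 0.15,
roughly the mix seen in burrowing-crayfish faunas), and coordinates are
uniform in a Southern-Appalachians-sized box. `simulate_mrm_dataset()`
builds Y entrywise as intercept + Σβ~k~X~k~ plus i.i.d. Gaussian pair
noise, symmetrized and clipped at zero.

These generators make the analyses *identifiable and checkable*: the
suite verifies exact P~p~ arithmetic on planted counts (484/12,000 →
4.03%; 33/12,000 → 0.28%), exact agreement of sampled permutation
p-values with exhaustive enumeration at small n, type-I error of the
coefficient test inside the exact binomial 99% band around 0.05 over
1,000 null datasets (n = 30, R = 199), unbiased coefficient recovery over
500 noisy replicates (n = 40), and ≥ 90% power for a clustered taxonomy
effect (n = 40, R = 199). Problem sizes for the simulation studies were
chosen so each study is a few CPU-minutes at most while keeping
Monte-Carlo error well below the tested margins.

What passing these tests does **not** show: real pairwise tree distances
are strongly dependent (they share paths), whereas the regression
simulator's noise is independent per pair; the permutation test's
exchangeability-on-taxa design is exactly the standard remedy for that
dependence, but power and calibration on real, correlated responses can
differ from the i.i.d.-noise figures. Likewise the pure-birth topology
model says nothing about how well a single summary topology represents a
multimodal posterior — node distance is computed on whatever summary tree
the user supplies, and consensus construction is deliberately out of
scope.

## Known limitations

* No MCMC convergence diagnostics: pooling trusts the user's burn-in
  choice.
* No likelihood-based topology tests (e.g. the approximately unbiased
  test) — only posterior frequencies.
* No Mantel simple correlations, distance GLS, or spatial autocorrelation
  corrections; the regression is OLS on pairs with permutation inference.
* Geographic distance is spherical haversine; drainage or stream-network
  distances, often more meaningful for freshwater taxa, are not modeled.
* Multiple samples per species enter as separate rows; collapsing to
  exemplars is the user's modeling decision upstream of the matrices.

## End-to-end use

```{r pipeline, eval = FALSE}
report <- run_pipeline(list(
  trees = c("run1.t", "run2.t"), # Newick or Nexus; format sniffed
  summary_tree = "consensus.nwk",
  metadata = "taxa.csv", # taxon,subgenus,habitats,lat,lon
  constraints = "hypotheses.yaml", # groups / backbone / outgroup
  mcmc = list(generations = 1e7, interval = 1000, burnin = 4e6),
  permutations = 9999,
  seed = 42,
  out_dir = "out"
))
```

The report embeds the effective configuration, artifact checksums, the
full regression table and every P~p~ row; rerunning the same configuration
byte-reproduces it, and deleting any intermediate file regenerates it
identically.
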
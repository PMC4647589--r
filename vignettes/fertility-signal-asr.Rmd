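---
title: "Reconstructing the ancestral states of fertility-linked chemical signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the ancestral states of fertility-linked chemical signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fertsig)
```

## The question and the data

Queens of eusocial bees carry cuticular compounds that signal fertility and,
in several lineages, suppress worker reproduction. A long-standing hypothesis
is that these queen pheromones were co-opted from fertility-linked cues
already present in solitary ancestors. `fertsig` implements the comparative
pipeline used to examine that hypothesis in bees: each of twelve biosynthetic
compound classes (linear alkanes, branched alkanes, alkenes, alkadienes,
aldehydes, alcohols, fatty acids, keto acids, esters, terpenes, terpene
alcohols, lactones) is coded as a binary character per species — present if
the species has at least one fertility-linked compound of the class — and the
ancestral state of each character is reconstructed by maximum likelihood on a
fixed, rooted composite phylogeny.

A compound counts as fertility-linked when it is overproduced by queens
relative to workers (eusocial species) or by mature egg-laying females
relative to virgin females (solitary species); the difference may be
qualitative (presence/absence) or quantitative.

## The model

The evolutionary model is the two-state symmetric Markov model (Mk1): a
continuous-time chain on states {absent, present} with a single rate $q$ for
both gains and losses. Over a branch of length $t$ the transition matrix has
the closed form

$$P_\text{stay}(t) = \tfrac{1}{2}\left(1 + e^{-2qt}\right), \qquad
  P_\text{switch}(t) = \tfrac{1}{2}\left(1 - e^{-2qt}\right).$$

Assumptions worth stating explicitly:

* **Unit branch lengths.** Every branch is set to length 1
  (`set_unit_branch_lengths()`), the punctuational convention: one expected
  opportunity for change per cladogenetic event. This is the pragmatic choice
  when the composite tree mixes sources without comparable branch lengths;
  it also means $q$ is a rate per speciation event, not per unit time.
* **Flat root prior.** The root state prior is $(\tfrac12, \tfrac12)$. For
  the symmetric model this equals the stationary distribution, so the choice
  is inert here, but it is explicit and configurable (`pi` arguments)
  because it would matter for any asymmetric extension.
* **Per-character rates.** $q$ is estimated separately for each compound
  class. Characters are treated as independent; correlation between classes
  is not modeled.
* **Missing states.** A `?` cell contributes the uninformative conditional
  likelihood $(1, 1)$ at its tip.
* **Multifurcations.** Polytomies are retained as such (composite supertrees
  commonly contain them); the pruning product simply runs over all children.

The likelihood is computed by Felsenstein's pruning algorithm with per-node
rescaling (the rescaling leaves the log-likelihood unchanged to well below
1e-9 even on a 200-tip tree at $q = 5$, where the unscaled computation
approaches the double-precision floor). Data of probability zero (e.g. mixed
tip states at $q = 0$) return `-Inf`.

## Rate estimation

`estimate_rate()` maximizes the pruning log-likelihood over $\log q$ with a
bounded deterministic scalar search on $[10^{-8}, 10^{3}]$ (tolerance 1e-9).
The one-dimensional profile is unimodal in practice (asserted empirically in
the test suite via agreement with an independent optimizer,
`ape::ace(model = "ER")`). Both interval endpoints are evaluated explicitly
because monomorphic characters have a likelihood that is monotone decreasing
in $q$: their estimate sits at the lower bound and is flagged
(`boundary = TRUE`) rather than hidden.

## Marginal ("proportional likelihood") reconstruction

For each internal node the reported quantities are the likelihoods of the
*full* data with that node clamped to each state — at the globally fitted
$q$, never re-optimized per node — renormalized to sum to one. This is the
definition behind Mesquite-style "trace character" pies, and it is *not* the
joint (max-product) reconstruction, which would answer a different question.
`marginal_node_proportions()` computes all nodes in one up-down pass (inside
likelihoods up, outside likelihoods down; per-node scaling factors cancel in
the normalization). The defining clamp-and-renormalize computation is kept
in the package as `marginal_node_proportions_clamp()` and the two are held
equal to 1e-10 over every rooted topology with up to six tips in the tests.

Two reporting conventions follow the published practice they reproduce:

* **Strict 50 % rule.** A state is called "likely present" at a node, and a
  branch is painted, only when the present-proportion strictly exceeds the
  threshold (default 0.5); exactly 50 % is ambiguous and not painted.
* **Half-up rounding to one decimal** in the formatted tables; all
  comparisons in code and tests use the unrounded values.

`clade_report()` evaluates the proportions at the MRCAs of named clades
(species sets), and `summarize_origins()` reads off, per character, the most
inclusive clade whose cell passes the threshold — the character's earliest
reported origin as a fertility signal.

## Coding chemical profiles into characters

`build_character_matrix()` turns per-individual abundance tables into the
binary matrix. Compound classification is deterministic: a small dictionary
of special names (mostly terpenoids, whose -ol/-ene suffixes would otherwise
be misread) is consulted first, then a suffix/keyword grammar on the name,
then descriptor rules. When descriptors conflict, the functional group wins
over hydrocarbon features (an unsaturated acid is a fatty acid, not an
alkene; a methyl-branched alkene is an alkene), mirroring biosynthetic
end-group chemistry. Unclassifiable compounds are reported as `"unknown"`
and excluded with a warning — never silently dropped, never guessed.

The default "overproduced" criterion is deliberately a configurable
stand-in, because published datasets differ in how they defined
overproduction: qualitative presence/absence (detected in at least half of
the fertile-caste individuals, zero in every non-fertile individual), OR a
one-sided Wilcoxon rank-sum test at $\alpha = 0.05$ combined with an
arithmetic fold-change of at least 2. Both parts are unit-free, so the call
is invariant to global rescaling of abundances. Groups with a single
individual only ever use the qualitative rule (flagged with a warning).
Pre-coded matrices (TSV or NEXUS `DATATYPE=STANDARD`) bypass this stage
entirely, which keeps reconstruction results independent of the statistical
choice. Note that AND-combining the fold-change gate with the rank-sum test
makes the composite rule conservative under the null: its realized
false-positive rate (about 2 % at the default settings, as measured by the
calibration in `scripts/acceptance.R`) is below the test's nominal
$\alpha = 5$ %, while the rank-sum gate alone realizes about 4 %
(the exact n = 8 test has achievable size 0.0415).

## What the synthetic data emulate — and what they do not

The generators exist so that every stage is testable without downloads:

* `simulate_yule_tree()`: pure-birth topologies. The analysis is conditional
  on a fixed tree, so only plausible shapes are needed; tips are labeled
  `sp01, ...`.
* `simulate_character()`: forward simulation of the same Mk1 process (root
  from the prior, per-edge switch probability $P_\text{switch}(q, t)$),
  returning the true internal states so reconstructions can be scored.
* `simulate_chem_profiles()`: queen/worker (or mature/virgin) abundance
  tables with a multiplicative fertile-caste excess on designated compounds
  and lognormal noise (GC--MS peak areas are positive and right-skewed).
  Defaults, chosen once as the study conditions: 16 species (11 eusocial,
  5 solitary), 8 individuals per caste group, 4-fold overproduction,
  `sigma_log = 0.75` (coefficients of variation of roughly 50--100 %),
  2 assayed compounds per class. With `fold_change = Inf` the regime is
  purely qualitative: linked compounds are absent (exactly zero) in the
  non-fertile caste, and caste-invariant compounds get identical caste
  profiles, so the regime isolates the presence/absence coding logic and
  recovery of the truth matrix is exact by construction; the statistical
  criterion itself is exercised by the finite-fold and null (fold = 1)
  regimes.

These simulations do **not** emulate: correlated evolution between compound
classes, chromatograms or spectra (compounds arrive pre-identified),
between-study heterogeneity in how abundance was quantified, or
phylogenetic signal in the chemical noise. A pipeline that passes the
synthetic tests is internally correct; that is a necessary, not sufficient,
condition for conclusions about real bees, which also depend on the accuracy
of the input tree and of the literature coding.

## Numerical and design choices

* Rooted interpretation of Newick: the outermost clade is the root, so a
  basal polytomy like `(A,B,C);` is a legal rooted tree; only an explicit
  `[&U]` marker is rejected. Ancestral nodes are meaningless without a root.
* Quoted labels (species names contain spaces) are parsed and re-quoted on
  writing; underscores are taken literally.
* Missing branch lengths are legal on input because the analysis overwrites
  them with 1.
* Rate bounds $[10^{-8}, 10^{3}]$ per unit branch: a rate at the lower bound
  is numerically "no change anywhere" and at the upper bound "fully
  saturated" on unit branches; both are far outside the informative range
  and are flagged when hit.
* The NEXUS standard-datatype matrix reader/writer is intentionally minimal
  (one `MATRIX` block, symbols 0/1, `MISSING=?`, quoted taxon labels) and
  round-trips the package's own output.
* The packaged 16-species bee supertree
  (`bee_supertree_reconstructed.nwk`) is a best-effort reconstruction from
  published clade memberships: the seven named clades (Apidae *sensu lato*
  down to Meliponini and Bombini) are correct by construction, but species
  identities beyond those named in the sources (e.g. which *Bombus* and
  *Melipona* species) are plausible stand-ins. Analyses of real data should
  supply their own tree.

## Validation problem sizes

The test suite and `scripts/acceptance.R` validate, at fixed seeds: pruning
vs exhaustive enumeration and up-down vs clamped marginals on *all* 1,068
rooted binary topologies with 3--6 tips (3 rates x 20 random tip-state
vectors each, tolerance 1e-10); the transition matrix against the numerical
matrix exponential on a 56-point $(q, t)$ grid (1e-12); pooled-likelihood
rate recovery from 500 characters on a 64-tip unit tree at $q = 0.1$;
coding calibration on 1,000 null and 500 four-fold compounds; and exact
truth recovery of the qualitative regime on a 16-species roster. Internal
node calls on self-simulated 16-tip data are reported (accuracy, not
asserted against a fixed constant, since the achievable accuracy is a
property of the process, not of the implementation).

## Limitations

* Only the symmetric one-parameter model is provided: no asymmetric
  gain/loss rates, hidden rates, model selection, stochastic mapping or
  parsimony. That restriction is the point — the package reproduces a
  specific, published analysis style.
* Unit branch lengths are an assumption, not an estimate; conclusions can
  shift under time-calibrated lengths.
* The origins summary reads a clade table; it does not search the whole
  tree, so "earliest clade" means earliest *named* clade.
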
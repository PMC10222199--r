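---
title: "Functional clustering of abundance classes: models, search, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional clustering of abundance classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcmotif)
```

# The problem

Soil organic-matter (SOM) decomposition functions — basal respiration,
mineralization of a fresh straw input, and the priming effect the input
triggers — emerge from communities of hundreds of interacting bacterial
and fungal families. Two mechanisms are usually distinguished: a
*composition effect*, in which each taxon contributes in proportion to
its relative abundance, and an *interaction effect*, which is by
definition non-linear because it depends on which taxa co-occur. Since
most soil microbes cannot be isolated and grown in monoculture, the two
effects cannot be separated experimentally; `funcmotif` separates them
statistically, by fitting the same property with a strictly linear model
and with a combinatorial, motif-based model and comparing which families
each route retains.

# The two routes

## Multi-linear composition model

`fit_ols()` regresses the property on the family relative abundances with
an intercept and no interactions. The design constraint `n > p + 1` is
enforced; when a table violates it (the motivating design has 57 samples
against 60 families), `backward_select_linear()` first drops the
lowest-abundance families until `p = n - 2`. At that limiting design the
small-sample AICc correction `2k(k+1)/(n-k-1)` diverges, so the initial
fit carries `AICc = +Inf` and the first accepted removal restores a
finite value. Model quality throughout is

$$\mathrm{AICc} = n \log(\mathrm{RSS}/n) + 2k + \frac{2k(k+1)}{n-k-1},$$

the least-squares deviance form without additive constants and without a
variance parameter in `k` — the variable count is the number of families
plus one for the intercept, and using one convention everywhere keeps the
two routes comparable. Backward selection evaluates every single-family
removal, accepts the best one if it *strictly* lowers AICc (ties stop the
loop, and among equal candidates the earliest family in input order is
taken), and repeats.

## Abundance classes and assembly motifs

`encode_all()` converts the quantitative table into a binary one. A
family observed in a fraction $f$ of samples receives
$\mathrm{clamp}(\mathrm{round}(f/0.30), 1, 3)$ relative-abundance
classes: ubiquitous families get three (noted 1/3, 2/3, 3/3), families
near one-third occupancy keep a single class, families in between get
two. The present samples are rank-ordered and cut into contiguous blocks
whose sizes differ by at most one, larger blocks at the low-abundance
end; ties in abundance are broken by sample input order, which keeps the
equal-occupancy property exact. Ranking uses depth-normalised relative
abundances; at the fixed rarefaction depth the package simulates (3000
reads) this coincides with raw-count ranking. The 30% centring constant
makes every class, whatever its family's frequency, observed in roughly
30% of samples, which equalises the information each class carries into
the clustering. A family with fewer present samples than its nominal
class count falls back to the feasible count; a family never observed is
dropped with a warning.

Given a partition of classes into functional groups, a group is *present*
in a sample when at least one member class is 1 (presence is the OR over
member classes — without this reduction motifs would not be well
defined), and the sample's *assembly motif* is the set of groups present.
The all-absent motif is legitimate and carries its own mean.
`fit_motif_means()` fits each sample by its motif's mean property, so
$R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ is exactly the inter-motif variance
fraction, and the F-ratio is the one-way ANOVA statistic across observed
motifs.

## Searching the partition space

Maximising inter-motif variance over set partitions is combinatorial
(the search space grows as Bell numbers), and the OR-presence semantics
creates a specific difficulty: a class buried in a large group is
*invisible* — its indicator no longer influences the group's presence
pattern — so single-move hill climbing stalls far from good optima, and
conversely a pure $R^2$ criterion rewards pulling weakly informative
classes out of the residual mass to chase noise. `fit_tree()` therefore
separates fitting from model choice:

1. **Levels by beam search on $R^2$.** Level $g+1$ grows from each
   assignment kept at level $g$ by seeding a new group with each of the
   best few single classes (ranked by the $R^2$ of relocating that class
   alone), refining every seed by first-improvement moves — any class to
   any group, scanned in input order, until no move strictly increases
   $R^2$ (strictness tolerance $10^{-12}$) — and carrying the best
   distinct refinements forward. The beam width defaults to 5, and to the
   class count on problems of up to 12 classes, where seeding is then
   exhaustive. Level records are $R^2$-maximal by construction, which is
   what the exhaustive-oracle audit (below) compares against.
2. **Model choice by AICc.** Each level's assignment is then *polished*
   under the selection criterion itself: first-improvement moves accepted
   when they lower AICc computed with $k$ = the number of observed
   motifs (ties resolved toward fewer motifs), which returns
   noise-chasing classes to the residual mass. The reported partition is
   the polished level with minimal AICc, ties toward fewer motifs and
   then fewer groups.

Both phases are deterministic: no random number is drawn, and all ties
break by input order. With zero residual the deviance term is $-\infty$;
perfect fits are ordered by parsimony (motif count, then group count).

`exhaustive_oracle()` enumerates every partition into at most `n_groups`
non-empty groups via restricted growth strings (refusing above $10^6$
candidates) and is the package's independent upper bound: the greedy
level $R^2$ can never exceed it, and the test suite requires equality in
at least 95 of 100 random small instances (8 classes, 3 groups, n = 30).

## Groups, ordering, and the residual

`order_groups()` relabels a fitted partition so groups read A, B, … from
most to least explanatory. The *residual* group — the default cluster of
the least significant classes — is identified as the group whose outright
deletion least changes $R^2$: the catch-all mass is present in
essentially every sample, so its presence bit carries no information and
its deletion cost is near zero. Deletion (rather than merging the group
into another) is the right probe because it is exactly the operation
family-level selection performs. Each remaining group's contribution is
the $R^2$ drop when its classes are merged into the residual group;
classes inside a group are ordered by the same single-class criterion,
and residual classes by their deletion cost. Whether the original
method's residual group may be empty, and whether classes were ordered by
the same criterion as groups, is not documented anywhere we could rely
on; both choices here are fixed as described.

## Family-level backward selection

In the clustering route a family is removable only when (a) every one of
its classes sits in the residual group, (b) removing all its classes
changes neither the non-residual groups nor any sample's motif, and
(c) AICc improves, computed with $k$ = the number of remaining families —
the level search holds groups and motifs constant, so the family count is
the honest variable count here (using motif count would make every
removal free). Because an accepted removal leaves the fit untouched, all
candidates share one RSS and AICc always improves through the penalty;
at RSS = 0 the candidates are ordered by the penalty terms alone. The
final fit reports `reported_df = p_initial - m_kept`, the bookkeeping
convention of the summary tables this mirrors, alongside the conventional
residual df.

## Group effects and the cross-route comparison

`group_anova_effects()` turns each non-residual group into a binary
presence factor and decomposes the property by a sequential (type-I)
`aov()` in group order with all pairwise interactions after the main
effects; three-way terms are not fitted. Effects are reported on the
scale the motivating analyses use: percent of the *median* property,
$100(\bar y_{G} - \tilde y)/|\tilde y|$ for a group and the double
difference for a pair. The double-difference form is one defensible
reading of "the interaction is associated with a higher effect" and is
validated against synthetic truth, not asserted as the original authors'
formula. Significance is flagged at $p < 0.001$. Factors present in no or
all samples are dropped with a warning; a zero median switches the
effects to raw units with `scaled = FALSE`.

`compare_key_families()` classifies every family as key in both routes,
one, or neither, with the linear coefficient's sign and the family's best
functional-group letter; `median_abundance_check()` runs the
Kruskal–Wallis test of per-family total abundance between key and
non-key families, guarding against selection merely tracking abundance.

# The synthetic generator

`simulate_abundance_table()` emulates the marginal regime of rarefied
amplicon family tables: per-family observation frequencies drawn
uniformly from [0.3, 1]; within present cells, heavy-tailed positive
weights (ceiling of a log-normal whose location is drawn once per family,
location mean log 5, spread 1.2, within-family dispersion 1.5 on the log
scale); and per-sample multinomial resampling to exactly 3000 reads,
mirroring rarefaction. These defaults reproduce a wide abundance range
with low medians at the study's depth. One integer seed drives a single
generator stream. Two things the generator deliberately does *not*
emulate: correlation structure between families (phylogenetic or
compositional), and community change during incubation — the analysis
attributes the property to the *initial* composition. Simulation results
therefore establish the method's behaviour under independent presences;
on real tables, correlated families can share credit in ways no test
here measures.

`plant_partition_property()` is the generative inverse of the clustering
fit: motif means come either from an explicit motif table or additively
from per-group effects, a baseline and optional pairwise increments, plus
Gaussian noise and an optional linear composition component.
`simulate_study()` bundles the full recovery design used by the tests:
60 samples, 20 families, three groups planted on the top abundance class
of nine distinct multi-class families (one class per family — planting
all classes of one family would make the group's presence equal the
family's, i.e. nearly constant and unidentifiable), additive effects
(+3, −2, +1.5) on baseline 10 so all eight motif means are distinct, and
noise of 5% of the motif-mean range.

Recovery is scored by `recovery_ari()`: the adjusted Rand index over the
planted classes plus one pseudo-member standing for the residual mass.
The pseudo-member penalises a planted group collapsing into the residual,
while noise classes — for which the truth defines nothing beyond
"residual" — do not dilute the score. The dilution is real, not a search
artefact: under noise there exist partitions with *better* AICc than the
planted truth that differ from it only in where a few noise classes sit,
so a full-partition ARI would measure the placement of classes the model
is right to consider interchangeable.

# Numerical choices and degenerate inputs

* Strict-improvement tolerance $10^{-12}$ in all searches; RSS below
  $10^{-12}\,\mathrm{TSS}$ is treated as a perfect fit.
* `aicc()` requires `n - k - 1 > 0` and positive RSS; RSS = 0 yields
  $-\infty$ (the zero-noise limit). Inside fitted objects the diverging
  correction at `k = n - 1` is recorded as $+\infty$.
* Constant properties are rejected (`TSS = 0` would make $R^2$
  undefined); a single observed motif warns and fits the grand mean.
* All result files are written with 12 significant digits, so identical
  inputs give byte-identical outputs.
* Sample alignment between tables is by identifier only; a missing
  identifier is an error, never a silent reindex.

# Problem sizes

The test suite and the acceptance script use: 100 oracle instances of 8
classes, 3 groups, n = 30; 20 recovery seeds of the `simulate_study()`
design above plus one zero-noise run; 100 backward-selection instances
with p = 6 and n = 30 against the $2^p$ exhaustive subsets; 20 null-ANOVA
runs of n = 1000 with four factors; and one full two-route pipeline on a
60 × 20 synthetic study. Together they run in a few minutes on one CPU.

# Known limitations

* The beam search carries no optimality guarantee beyond the audited
  equality rate on small instances; on large encodings the oracle is
  unavailable by construction.
* AICc with motif-count complexity is an in-sample criterion; no
  cross-validation or bootstrap of group membership is provided.
* Effects in percent of the median are undefined at median zero (reported
  raw and flagged instead).
* Unobserved motifs at prediction time would be fitted by the grand mean;
  the package flags rather than models them.
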
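---
title: "Methods and design of barcodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of barcodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodiv)
```

`barcodiv` chains the computational stages of a plant DNA-barcoding
conservation survey: evolutionary distances, barcode-gap species
delimitation, BLAST-hit taxonomic assignment, AMOVA/Fst, and
presence-only niche modeling, with seeded synthetic generators supplying
known truth for every stage. This vignette explains each model, its
assumptions, the tunable parameters, the numerical choices, and what the
synthetic validation does and does not establish about real data.

## Distances

Sequences must arrive aligned per marker; alignment itself is out of
scope and the generators emit aligned sequences (indel-free). Sites with
a gap or ambiguity code in either member of a pair are excluded
*pairwise* (pairwise deletion), the common choice in barcoding because it
retains information in unevenly trimmed sets; complete deletion can be
emulated upstream by masking columns.

Three models are provided: the uncorrected p-distance (the "simple"
distance of barcode-gap software), Jukes–Cantor
`d = -3/4 ln(1 - 4p/3)`, and Kimura's two-parameter distance

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q),$$

where $P$ and $Q$ are the transition and transversion proportions over
compared sites. K2P assumes equal base frequencies and a single
transition/transversion ratio across sites — adequate for the short,
conserved loci used as barcodes, and the de-facto standard there. When
$1-2P-Q \le 0$ or $1-2Q \le 0$ the distance is undefined (saturation);
`distance_matrix()` aborts with the offending pairs rather than emitting
`NA`, so no downstream partition is ever built on a partial matrix.

Trees are reconstructed by neighbor joining on the chosen distance matrix
(via `ape::nj`). Which agglomeration the field's GUI tools apply by
default varies, and NJ on the barcode matrix is the canonical
distance-based choice; this package makes no claim that it reproduces any
particular GUI's tree. NJ can produce small negative branch lengths on
noisy matrices; these are clamped to zero with the deficit moved to the
sister edge, preserving tip-to-tip path lengths through the parent node.
Newick output carries six-decimal branch lengths.

## Barcode-gap delimitation

The delimitation procedure assumes the classic barcode-gap structure:
intraspecific divergences concentrate below a prior ceiling $P$ while
interspecific divergences form a separated mode. `detect_gap()` scans the
intervals between consecutive *distinct* ranked distances (exact ties
collapse to one value so a run of identical distances cannot mimic an
empty region) and returns the midpoint of the first interval that

1. has its midpoint above the prior $P$ (so the returned threshold is
   always consistent with the prior), and
2. is wider than $X$ times the larger of (a) the distance at which the
   interval opens and (b) the mean width of the preceding $W$ intervals
   (window default $W = 10$).

Condition 2(a) is the load-bearing one and deserves its rationale: under
any substitution-corrected distance, distances cluster tightly around the
discrete ladder of mismatch counts, so the mean spacing just below a
candidate interval can be arbitrarily close to zero, and a rule based
only on relative local widths fires on every rung of the ladder. Requiring
the gap to dwarf the divergence level at which it opens makes detection
scale-aware: an interspecific gap must be large *relative to intraspecific
divergence itself*, which is exactly the biological definition of a
barcode gap. The relative width default $X = 1.5$ and the prior range
0.001–0.100 are the standard survey settings.

Specimens are partitioned by single linkage below the detected threshold:
groups are the connected components of the graph joining pairs with
$d <$ threshold, with deterministic group ids (the lexicographically
smallest member). The procedure recurses within each group of at least 4
specimens (smaller groups cannot show a meaningful internal gap and
pairs would always split), to depth 10. `prior_sweep()` repeats the
recursive delimitation over 10 log-spaced priors and reports the group
count per prior; the sweep — not any single partition — is the result a
survey should read, because over-tight priors legitimately over-split and
priors above the gap lump everything.

## Taxonomic assignment

Hit tables use an extended outfmt-6 dialect (`qseqid, sseqid, species,
genus, family, bitscore, qcovs, pident`), the integration contract that
replaces live database queries. Two ranking methods are provided: the
*simple* method keeps the top 10 hits by bit score; the *optimized*
method keeps the top 100 and re-ranks them by the weighted score
`bitscore * (qcovs / pident)`, which up-weights hits covering the whole
query at modest identity relative to short perfect matches. Hits are not
deduplicated by subject before re-ranking. Ties break by identity
(descending) then species name (ascending), so candidate order is total
and stable.

The published tier boundaries overlap at both cut points (High $\ge$ 95,
Medium 90–95, Low $\le$ 90); the implementation resolves the overlap
upper-bound-wins: 95 is High and 90 is Medium. The assignment ladder
then works off the best candidate's tier and the set of species within
1% of the best ranking score (the *active method's* score — bit score
for simple, weighted score for optimized):

1. High tier and exactly one species in the window → that species;
2. all window species inside one configured synonym group, tier High or
   Medium → that species group;
3. one genus, High/Medium → genus;
4. one family, High/Medium → family;
5. otherwise unassigned — except that at Low tier a family unanimous
   across *all* candidates is still reported at family rank.

Species-group membership is configuration, not code: a two-column CSV
maps species names to group labels, seeded with the six-name
*S. europaea* complex. The whole ladder lives in one function
(`assign_taxon()`) so a survey can amend it in one place.

Combination calls (core = matK+rbcL, coding, non-coding, cpDNA, total)
are built by consensus: scanning ranks from most to least specific, the
first rank at which a strict majority of the member markers project to
the same taxon wins; markers without an assignment still count in the
denominator, and no majority at any rank leaves the query unassigned.
Consensus was chosen over concatenated-query assignment because it
degrades gracefully when markers disagree; concatenation remains
available through `concatenate_markers()`.

## AMOVA, Fst, Nei distance

The AMOVA is one-level (populations within the total), matching the
within/among reporting of a single-species survey; no regional hierarchy
is modeled. From squared distances,
$SSD_{total} = \sum_{i<j} d_{ij}^2 / N$ and
$SSD_{within} = \sum_p \sum_{i<j \in p} d_{ij}^2 / n_p$, with
$\sigma^2_w = SSD_{within}/(N-P)$,
$\sigma^2_a = (SSD_{among}/(P-1) - \sigma^2_w)/\bar n$ where
$\bar n = (N - \sum_p n_p^2/N)/(P-1)$, and
$F_{st} = \sigma^2_a/(\sigma^2_a + \sigma^2_w)$. Negative
among-population components (possible by sampling noise) are clamped to
zero for the reported Fst, with the raw value preserved in the result.

The permutation test shuffles individuals among populations preserving
sizes — the standard randomization for Fst — with
$p = (1 + \#\{F^{perm} \ge F^{obs}\})/(n_{perm}+1)$ and a default of 1023
randomizations. One numerical subtlety: the *test statistic* is the
unclamped component ratio. Clamping inside the test would tie a large
fraction of null permutations with a zero observed value and pile the
p-value distribution at 1; with the raw statistic the null p-values are
uniform (verified by a KS check in the test suite).

Nei's standard genetic distance is computed on haplotype frequencies
(identical sequences after gap stripping collapse to one haplotype):
$I = \sum_i x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}$, $D = -\ln I$, with
$D = \infty$ for populations sharing no haplotype. This is the standard
1972 form; distances on shared-allele variants (Da) are not implemented.

## Niche modeling

Occurrence cleaning uses a reverse-jackknife rule per environmental
variable: with values sorted, the critical value is
$t = (0.95\sqrt n + 0.2)\,(range/50)$, and walking inward from each
extreme a value stays flagged while its gap to the remaining body
exceeds both $t$ and 1.5 times the mean of the remaining consecutive
gaps. The second condition is this package's choice: the absolute
criterion alone flags every point of any tightly and evenly spaced
sample (its threshold shrinks with the range), while requiring the gap to
also stand out against the local spacing restores the intended behavior —
a planted extreme in `{1,2,3,4,100}` is flagged, nothing in
`{1,2,3,4,5}` is. Both constants are exposed as arguments. A record is
removed when flagged in at least 3 of the (by default 19) variables.

The model is a maximum-entropy density over background cells: features
are per-variable linear and quadratic terms standardized on the
background mean/sd, and the fit maximizes the mean presence
log-likelihood $\overline{\lambda f(x)} - \ln \sum_b e^{\lambda f(b)}$
minus an L1 penalty $\sum_j \beta_j |\lambda_j|$ (default $\beta = 1$ per
feature). Hinge/product/threshold features of full MAXENT are
deliberately omitted: linear + quadratic keep the problem low-dimensional,
strictly convex in practice, and testable, at the cost of flexibility on
strongly non-Gaussian responses. The optimizer is L-BFGS-B on the
positive/negative split $\lambda = \lambda^+ - \lambda^-$ (both bounded
below by zero), which handles the non-smooth penalty exactly — at large
$\beta$ the weights are *exactly* zero — with convergence governed by an
objective tolerance (default 1e-6) and an iteration cap (default 500);
non-convergence returns the model with a warning carrying the projected
gradient norm. After every fit the raw outputs over the background are
asserted to sum to 1 within 1e-6.

Outputs are the raw relative-occurrence-rate surface and its cumulative
(0–100) transform; MAXENT's logistic output is omitted because it
requires a prevalence assumption the raw and cumulative forms avoid.
Background cells are a uniform seeded sample of valid cells (default
10,000, or all cells when fewer exist — then the background is
deterministic regardless of seed). Grid extraction uses half-open cell
intervals anchored at the lower-left corner, so a point on a shared edge
belongs to the east/north neighbor; occurrences on nodata cells or
outside the extent are dropped and reported.

Validation: a seeded 75/25 train/test split (`round(N/4)`, at least 1
test point), rank-based AUC with ties counted one half, the conventional
bands (below 0.5 random, 0.5–0.7 poor, 0.7–0.9 moderate, 0.9+ good), and
jackknife importance refitting each variable alone and excluded
(warm-started from the full fit) with ranking by the with-only AUC.

## Synthetic generators: what they emulate, and what they do not

All generators are pure functions of their parameters and a seed.

*Sequences* descend from a random root: species ancestors receive
Poisson-distributed substitutions at expected `inter/2` per site,
individuals at `intra/2`, with transition:transversion odds
$\kappa$:1 (default 2), matching the two-rate structure K2P models. The
scheme is deliberately simpler than a coalescent: no rate heterogeneity
across sites, no indels, no recombination, and each branch mutates
distinct sites. Consequently an inter-species pair carries expected
divergence `inter + intra` (two ancestor plus two individual branches) —
the validation suite checks realized K2P means against exactly that.

*Population structure* blends per-population private haplotype pools
(default size 1) with a shared pool (default size 4) under a
`migration_mix` knob: 0 yields fixation (Fst = 1), 1 yields panmixia
(Fst near 0), and mean Fst decreases monotonically in between. It
emulates variance regimes, not demography.

*Hit tables* give every query a top true-species hit plus congeneric and
confamilial decoys at lower scores; with probability `decoy_rate` a
near-top decoy lands within 1% of the best score (drawn from the query's
synonym group when configured), exercising the species-group and genus
ladder branches. Scores, not alignments, are simulated.

*Landscapes* are smoothed Gaussian random fields (separable kernel, width
1/10 of the grid extent) standardized per variable, with true suitability
$\propto \exp(c \cdot z)$ and presences sampled without replacement
proportionally to it, inside a one-cell nodata ring. The default dominant
coefficient is 5: because smooth fields concentrate suitability in a few
blobs and without-replacement sampling saturates them, that is the
signal strength at which the *generating surface itself* attains test
AUC at least 0.9 in at least 95% of seeds — the property the fitted model is
then held to. Real climate surfaces are neither isotropic nor
independent across variables; passing these checks demonstrates the
estimator recovers a known signal, not that any real landscape is this
easy.

## Problem sizes and reproducibility

The validation suite runs the delimitation recovery on 50 seeded
four-species sets (32 specimens, 600 bp), the AMOVA against a
brute-force oracle on 100 seeded instances (N $\le$ 8), the null
permutation uniformity on 500 replicates of 199 permutations, and the
niche-model properties on 50 seeded 60 x 60 landscapes with 200
presences — sizes chosen so the full suite completes in about a minute
on one core while leaving the Monte Carlo margins interpretable. The
pipeline runner derives every stage seed from one top-level seed through
fixed offsets, writes a manifest of outputs with MD5 checksums, and
reruns byte-identically; the acceptance script
(`scripts/acceptance.R --seed N --out f.json`) recomputes all headline
quantities from scratch at any seed.

## Known limitations

- No multiple sequence alignment, chromatogram handling, or primer
  logic; inputs are aligned FASTA.
- Delimitation is distance-based only (no GMYC/bPTP), and at priors far
  below the true intraspecific divergence it over-splits, as
  distance-threshold methods do.
- The taxonomy ladder trusts the hit table's taxonomy columns; synonymy
  beyond the configured groups is invisible to it.
- One-level AMOVA only; no hierarchical (region) component.
- The niche model omits hinge features and the logistic output, uses a
  single fixed extent (no projection/CRS handling), and its validation
  is entirely synthetic.
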
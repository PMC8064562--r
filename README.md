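# barcodiv

DNA-barcoding analytics for plant conservation surveys, at desk scale.
`barcodiv` implements the computational stages such a survey chains
together — from raw barcode sequences (rbcL, matK, trnH-psbA, ITS2, ycf)
to species hypotheses, taxonomic identifications, population structure,
and a presence-only distribution model — with seeded synthetic generators
providing known truth for every stage, so the whole pipeline can be
exercised and validated offline.

It is written for molecular ecologists and conservation geneticists who
want the methods of a barcode survey as reusable, tested R functions
rather than a chain of web servers and GUI tools (BLAST front-ends, ABGD's
web form, Arlequin, MAXENT, DIVA-GIS).

## Methods at the core

**Distances.** Pairwise p-distance, Jukes–Cantor and Kimura two-parameter
distances with pairwise deletion of gapped/ambiguous sites. For transition
proportion *P* and transversion proportion *Q*,

    d_K2P = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)

Saturated pairs abort with an error naming them — no silent `NA`s reach
the delimitation stage. Neighbor-joining trees (via **ape**) with newick
export round out the tree-based view.

**Barcode-gap species delimitation.** An automatic-barcode-gap procedure:
scan the ranked pairwise distances above a prior maximal intraspecific
divergence *P* for the first interval whose width exceeds *X* (default
1.5) times both the local divergence and the mean of the preceding
interval widths; partition specimens by single linkage below the gap;
recurse within groups; and sweep the prior over 0.001–0.100 to report the
number of groups per prior.

**Taxonomic assignment.** BLAST-style hit tables (extended outfmt-6 with
taxonomy columns) are classified by the *simple* method (top 10 hits by
bit score) or the *optimized* method (top 100 re-ranked by
`max_score * query_cover / identity`). Identity tiers (High >= 95%,
Medium >= 90%, Low below) combine with the number of species within 1% of
the best score in a five-rule ladder that assigns species, species group
(e.g. the *S. europaea* complex), genus, family, or leaves the query
unassigned; per-marker and combination (core / coding / non-coding /
cpDNA / total) discrimination efficiencies are summarized as percentages.

**Population structure.** One-level AMOVA on squared molecular distances
with variance components sigma2_among / sigma2_within, Fst =
sigma2_a / (sigma2_a + sigma2_w), a size-preserving permutation test
(default 1023 randomizations), and Nei's standard genetic distance
`D = -ln I` on haplotype frequencies.

**Niche modeling.** Occurrence records are cleaned by a reverse-jackknife
outlier rule (removal when flagged in >= 3 of the 19 bioclim-style
variables), split 75/25, and fed to a maximum-entropy model over
background cells with standardized linear + quadratic features and L1
regularization — a convex fit whose raw output sums to 1 over the
background. Validation uses rank-based AUC (random < 0.5, poor 0.5–0.7,
moderate 0.7–0.9, good >= 0.9) and jackknife variable importance
(each variable alone / excluded). ESRI ASCII grids are read and written
directly.

## Worked example

```r
library(barcodiv)

# a three-species barcode set with known truth
sim <- simulate_species_sequences(k = 3, n_per = 6, L = 600,
                                  intra = 0.005, inter = 0.08, seed = 42)
dm <- distance_matrix(sim$records, "K2P")
recursive_delimit(dm, prior_P = 0.01)
#> Partition: 3 group(s); prior_P = 0.01 ; threshold = 0.04191111
prior_sweep(dm, n_steps = 5)
#> Barcode-gap prior sweep (X = 1.5 )
#>      prior_P n_groups  threshold
#>  0.001000000        6 0.04191111
#>  0.003162278        6 0.04191111
#>  0.010000000        3 0.04191111
#>  0.031622777        3 0.04191111
#>  0.100000000        1         NA
```

At priors compatible with the generating intraspecific divergence the
sweep recovers exactly the three simulated species (threshold 0.042 sits
inside the barcode gap between intra ~0.005 and inter ~0.08 distances);
at an over-tight prior it over-splits and at a prior above the gap it
lumps everything, which is how the partition count is meant to be read.

```r
syn <- read_synonym_groups()
hits <- simulate_hit_table(sim$truth, seed = 42, synonym_groups = syn)
asg <- assign_all(hits, method = "optimized", synonym_groups = syn)
head(asg[, c("query_id", "rank", "taxon", "tier")], 3)
#>   query_id    rank                 taxon tier
#> 1 sp01_i01 species Salicornia species_01 High
#> 2 sp01_i02 species Salicornia species_01 High
#> 3 sp01_i03 species Salicornia species_01 High

pg <- simulate_population_structure(n_pops = 3, n_per = 6,
                                    migration_mix = 0.4, seed = 7)
dmp <- distance_matrix(pg$records, "p")
amova_one_level(dmp, pg$pops)
#> One-level AMOVA
#>              source df         SSD       sigma2       pct
#>   Among populations  2 0.003340741 8.481481e-05  6.805349
#>  Within populations 15 0.017422222 1.161481e-03 93.194651
#> Fst = 0.06805349
fst_permutation_test(dmp, pg$pops, n_perm = 1023, seed = 7)$p_value
#> [1] 0.15625
```

With substantial haplotype sharing (`migration_mix = 0.4`) most molecular
variance lies within populations and the permutation test does not reject
panmixia — the regime a survey reports as high within-population
diversity.

The full chain (simulate -> distance -> delimit -> assign -> popgen ->
sdm) runs as one reproducible command; reruns with the same config and
seed are byte-identical:

```r
run_pipeline(system.file("extdata", "survey_default.yaml",
                         package = "barcodiv"), "my_run")
```

A thin command-line wrapper is included at `inst/cli/barcodiv.R`
(`barcodiv.R run-all --config run.yaml --outdir my_run`).

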
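---
title: "From sulfur-oxidation phenotype to gene content and history: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sulfur-oxidation phenotype to gene content and history: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulfotrace)
```

`sulfotrace` connects a measured phenotype — how much sulfate a
Sulfolobaceae species produces from elemental sulfur — to the gene
clusters that track that phenotype across genomes, the genes that respond
to sulfur transcriptionally, and the gain/loss events that shaped the
trait on the family's phylogeny. This vignette records the models, the
parameters that matter, and the design decisions, so that results can be
interpreted (and distrusted) correctly.

## Phenotype: assay reduction and classification

Sulfate is quantified turbidimetrically against sodium-sulfate standards
spanning 0–10 mM. `fit_standard_curve()` is an ordinary least-squares
line (absorbance per mM); `absorbance_to_sulfate()` inverts it and scales
by the dilution factor. Blank-subtracted readings can fall slightly below
the intercept, so negative back-calculated concentrations are clamped to
zero and flagged rather than treated as errors — a judgement call that
matches how plate assays behave in practice.

Classification uses two measurements per species: total sulfate after the
72-h culturing window and *specific* production (mM per OD600 unit),
the normalization that distinguishes efficient oxidation from plain cell
growth. The class rules are:

* **weak** — total sulfate ≤ `weak_max` (default 1 mM; this boundary is
  an observed property of the assay panel, not a tunable of convenience);
* **strong** — total ≥ `strong_min` (default 20 mM) *and* specific
  production ≥ `strong_specific_min` (default 30 mM/OD);
* **moderate** — everything else. In particular a species whose total
  clears `strong_min` but whose specific production does not clear the
  floor is demoted to moderate: a large sulfate pool accumulated by a
  dense culture is not evidence of efficient oxidation.

Only the weak boundary is anchored by the assay definition; the two
strong thresholds are package defaults and should be reviewed against
each new dataset. All three live in `oxidizer_thresholds()`.

## The phenotype score

`assign_groups()` partitions species into group A (more-than-weak
oxidizers) and group B (weak). For a gene cluster with presence counts
$N_{A,gene}$ and $N_{B,gene}$,

$$\mathrm{Score} = \frac{N_{A,gene}}{N_{A,species}} -
                   \frac{N_{B,gene}}{N_{B,species}} \in [-1, 1].$$

Presence is *binary*: `score_all_clusters()` binarizes the copy-number
matrix first, so paralog expansions cannot push a score outside
$[-1, 1]$. (Counting homolog copies literally would break the score's
advertised range; the binary reading is the one consistent with every
published value.) The score is antisymmetric under swapping the groups
and monotone in single presence flips — both properties are enforced by
tests.

With 8 group-A and 2 group-B species the achievable score grid is
$\{k/8 - m/2\}$; the canonical patterns are 1.00 (present in all A, no
B), 0.875 (absent from exactly one A species) and −1.00 (present only in
B). `achievable_scores()` exposes the grid.

## Differential expression

Counts are normalized as plain counts-per-million (total-count; TMM is
deliberately not used, keeping the normalization transparent).
`filter_low_counts()` removes genes that never reach `min_cpm` in
`min_samples` samples; untestable genes are treated downstream as unable
to pass any significance criterion.

Per-gene dispersions follow the NB parameterization
$\mathrm{Var} = \mu + \phi\mu^2$, estimated by method of moments within
each condition on library-size-normalized counts, pooled by residual
degrees of freedom, and shrunk toward the common dispersion (a
10 %-trimmed mean over genes) with a prior weight of
`shrink_weight = 10` residual-df units, floored at $10^{-6}$. With
triplicates per condition the per-gene estimate carries 4 df, so the
common dispersion dominates — the intended behaviour at this replication
level.

Testing fits, per gene, a negative-binomial GLM (log link, log library
size offset) for the condition model and the intercept-only model, and
forms a quasi-likelihood F statistic: the deviance drop divided by a
moderated deviance scale. The scale is the per-gene residual deviance
per df squeezed toward its trimmed mean across genes with the same prior
weight, and the statistic is referred to $F(1, \mathrm{df_{res}} + w)$.
The moderation is essential, not cosmetic: with 4 residual df the
unmoderated F test has so little power that an 8-fold planted change in
triplicates is detected < 20 % of the time, while the moderated test is
simultaneously calibrated under the null (type-I fraction ≈ 0.05 in the
acceptance simulation) and detects essentially all 8-fold responders.
Fold changes are log2 ratios of condition mean CPM with a 0.5-count
offset, so zero-count genes have finite, stable estimates; multiplicity
is Benjamini–Hochberg FDR at `alpha = 0.05`.

## PCA candidate selection

`run_pca()` is centered (optionally unit-variance) PCA by SVD on the
sample × gene CPM matrix, with a deterministic sign convention (each
loading vector sums to a non-negative value) so that runs are
reproducible across linear-algebra backends. CPM is used unlogged by
default, as the pipeline's stated input; a `pca_log2` flag is available
because heavy-tailed CPM distributions can let a handful of highly
expressed genes dominate the rotation.

`find_condition_axis()` picks the dimension maximizing
$|\bar s_{sulfur} - \bar s_{no\_sulfur}| / s_{pooled}$, a standardized
mean-difference of replicate scores; ties resolve to the lowest
dimension. When the condition effect dominates the transcriptome this is
dimension 1 — the acceptance suite checks ≥ 95/100 seeded simulations.

A gene becomes a candidate (`select_candidates()`) when it is
significant, its fold change exceeds `fold_change_cutoff` (default 2),
and its Pearson correlation with the condition axis exceeds `r_cutoff`
in absolute value. `r_cutoff` has **no default**: two conventions are in
circulation (a permissive 0.5 screen and a stringent 0.90 filter), both
exposed via `r_cutoff_preset()`, and silently choosing between them
would change candidate sets by an order of magnitude.

## Cross-species consensus

Candidates are lifted onto homolog clusters via a gene→cluster
membership table (`genes_to_clusters()`; a gene in more than one cluster
is an error, unmapped genes are reported, never dropped silently).
`consensus_clusters()` then requires, per cluster and per species in the
consensus set, that *all* member genes pass significance and the fold
cutoff — an all-members rule, so a cluster with one responsive and one
flat paralog does not pass. Tiers:

* `all_species_concordant` — encoded in every species of the set, all
  members pass, one shared direction of regulation;
* `all_species_discordant` — as above but directions conflict;
* `subset` — missing from at least one genome of the set, passing
  wherever encoded (this is what makes strong-pair analyses fall out of
  the same operation).

Shrinking the species set can only relax the criterion; that
monotonicity is tested.

## Gain/loss reconstruction

`sankoff_reconstruct()` performs asymmetric Wagner parsimony on a rooted
tree (polytomies allowed, branch lengths ignored): post-order Sankoff
cost accumulation over states {0, 1}, root state by arg-min, pre-order
traceback. Defaults `gain_cost = 2`, `loss_cost = 1` make gains twice as
expensive as losses, encoding the asymmetry that horizontal acquisition
of a functional gene cluster is rarer than its decay; both costs are
config. All ties resolve toward absence, which biases reconstructions
toward later gains rather than deep gains followed by many losses; the
tie-break is also configurable. No event is placed above the root.

`count_parsimony_optima()` counts optimal assignments by a second DP
pass; a count of one certifies the reconstruction is the unique optimum.
The DP cost is verified against exhaustive enumeration of all ancestral
assignments on *every* rooted topology with up to six leaves and every
binary labeling (plus polytomy fixtures), and the planted-history
recovery check on a 20-leaf tree is gated on that uniqueness
certificate, because a planted history is only guaranteed recoverable
when it is the unique optimum.

## Synthetic data: what it emulates, what it does not

The generators are first-class, seeded, and emit ground truth:

* `gen_pangenome()` — 8 + 2 genomes by default (the benchmarked panel
  shape), planted clusters realizing exact target scores, uniform
  background presence (probability 1/2), geometric paralog inflation at
  rate 0.05.
* `gen_counts()` — log-normal baselines (meanlog = log 50, sdlog = 1),
  NB counts with $\mathrm{Var} = \mu + \phi\mu^2$, biological
  triplicates, expected column sums equal to the library sizes. Planted
  responders scale the sulfur-condition mean by $2^{\mathrm{lfc}}$
  *within* the relative-abundance model, so strong responders
  compositionally dilute the remaining genes exactly as deeper
  sequencing of a shifted transcriptome would. Calibration measurements
  therefore plant balanced up/down responders; one-sided planting makes
  every null gene genuinely (if slightly) differential on the CPM scale.
* `gen_tree_history()` — topology by sequential leaf attachment; each
  character gets a random root state and up to the requested number of
  state-flip events on distinct branches.
* `gen_study()` — the composed bundle: pangenome with planted scores
  (1, 0.875, −1, 0), three transcriptome species, responder clusters at
  the concordant / discordant / subset / species-private tiers
  (log2 fold ±3, dispersion 0.1), a phenotype assay table consistent
  with the grouping, and a tree over the genomes.

What the generators do **not** emulate: GC or length biases, batch
effects, TMM-relevant composition extremes, unequal replicate quality,
sequencing error, within-cluster paralog divergence, or rate variation
across lineages. Passing recovery tests on this synthetic data shows the
machinery is correct and calibrated under its stated model — not that
the model captures every property of Nanopore count data.

## Numerical and sizing choices

Problem sizes in tests were chosen to estimate each quantity stably:
2000 genes for calibration and dispersion recovery, 100 seeded
repetitions for axis detection, 30 characters on 20 leaves for history
recovery, and exhaustive enumeration (≈ 65 000 topology × labeling
combinations) for the parsimony oracle. Degenerate inputs have defined
behaviour throughout: constant genes get $r = 0$ with a flag, all-flat
count matrices give $p = 1$ and zero fold change, empty cluster sets
give empty tables, and every parser rejects ragged, non-integer or
duplicate-id input with a named error.

The pipeline (`run_pipeline()`) validates its entire configuration
before executing any stage, writes one TSV per stage plus a
`manifest.json` (parameters, seed, record counts; no timestamps), and is
a pure function of inputs, config and seed — re-running a config yields
byte-identical outputs, which the suite asserts with checksums.

## Known limitations

* The oxidizer class boundaries beyond the weak cutoff are defaults, not
  measured constants; sensitivity of the grouping (and hence every
  score) to them should be checked per dataset.
* The DE test assumes a common dispersion structure is informative for
  single genes; with many replicates the moderation is unnecessary, and
  with severe outliers a robustified variant would be preferable.
* Parsimony reconstructions depend on the cost ratio; event placements
  from a birth–death or rate-based model can differ, particularly on
  long branches.
* Consensus treats within-species paralogs strictly (all must agree); a
  cluster with one diverged, unresponsive paralog is excluded by design.
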
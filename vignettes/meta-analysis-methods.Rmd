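---
title: "Harmonising multi-omics literature data into consensus molecular features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonising multi-omics literature data into consensus molecular features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabrymeta)
options(fabrymeta.verbose = FALSE)
```

## The problem

Omics studies of Fabry disease — an X-linked lysosomal storage disorder
caused by deficient alpha-galactosidase A — are scarce and rarely deposit
raw data. What *is* available are the end-result tables of publications:
lists of detected molecules with case/control expression ratios and
statistical scores, spanning urine and blood, untreated ("naive") and
enzyme-replacement-therapy (ERT) patient groups, and four platform families
(transcriptomics, proteomics, peptidomics, metabolomics). `fabrymeta`
implements a complete meta-analysis over such tables: it harmonises
heterogeneous per-study molecule lists into non-redundant consensus
features and carries them through composition summaries, gene-set
over-representation, pathway scoring, fold-change clustering, and
disease/regulatory network overlays.

Because the underlying curated tables are not redistributable, the package
ships a synthetic-data generator with planted ground truth; every stage of
the pipeline is exercised and validated against that truth.

## Harmonisation model

**Identifier resolution.** Published identifiers are heterogeneous (gene
symbols, protein accessions, probe ids). An alias map sends each raw
identifier to a *non-redundant molecular cluster*, one identifier per
molecule across platforms, each carrying a single coarse functionality tag
(MET, CS, ENZ, TP, SIG, ...). Unmapped identifiers go to a side list, not
an error: mapping loss is a reportable part of the funnel.

**Within-study collapsing.** Repeated reports of one cluster within a
study are merged by the arithmetic mean of their expression ratios, keeping
the smallest p-value (a Fisher-combination option exists). A within-study
group whose members disagree on direction is dropped rather than averaged —
averaging across a contradiction would manufacture a direction.

**Direction and magnitude.** A ratio $r > 1$ is up-regulation, $r < 1$
down-regulation, and the fold-change magnitude is $\max(r, 1/r)$. This
reciprocal-magnitude convention keeps up- and down-regulation exactly
symmetric: a molecule halved in disease is as "changed" as one doubled. (A
literal reading of "down-regulated if below the fold-change cutoff" would
label unchanged molecules as down-regulated; we reject that reading as
internally inconsistent and state the convention in output headers.)

**Thresholds.** A feature is retained iff

* $p < 0.05$, and
* $\max(r, 1/r) \ge$ the platform threshold — 2.0 for transcriptomics, 1.3
  for proteomics/peptidomics/metabolomics — and
* $\max(r, 1/r) \ge 1.4$, the global threshold (a 40% change).

The effective threshold is the larger of the platform and global values;
filtering is monotone in every threshold. Peptidomics uses the
proteomics/metabolomics value, as peptide panels share those platforms'
effect-size scale. Studies publishing signed fold-changes (−2 meaning
halved) declare a `signed_fc` convention in the study table and are
converted on read.

**Cross-study consistency.** Within each patient group, a cluster
supported by several studies with one direction becomes a consensus feature
whose ratio is the arithmetic mean of the supporting ratios; a cluster
observed in both directions is a contradiction, excluded and reported.
Consensus and removed clusters always partition the input clusters, and
naive and ERT groups are never merged with each other. Overlap selection
then keeps clusters whose evidence spans at least two sources — body fluids
by default (urine/blood), or studies — among the consistently regulated
clusters.

## Enrichment statistics

**Two-sided hypergeometric test.** For a query of size $n$ in a universe
of size $N$, a term of size $K$ and overlap $k$, the two-sided p-value is
$\min(1,\, 2\min(P[X \ge k], P[X \le k]))$ with
$X \sim \mathrm{Hypergeom}(N, K, n)$. Doubling the smaller tail is the most
common two-sided construction; a minimum-likelihood-sum variant is
available behind a flag. The default universe is the union of all genes in
the loaded gene-set collection; an explicit background can be supplied.
Query genes outside the universe are dropped with a logged count.

**Multiple testing.** "Bonferroni step-down" is Holm's procedure:
$p^{adj}_{(i)} = \max_{j \le i} \min(1, (m - j + 1)\, p_{(j)})$ on sorted
p-values. It is computed with `stats::p.adjust(method = "holm")` after
domain validation, and tested against a hand-written step-down oracle.

**Kappa term grouping.** Two significant terms are similar when Cohen's
kappa of their binary hit-gene membership indicators reaches 0.4, computed
over the universe restricted to query hit genes. Groups are the connected
components of the resulting term graph, each represented by its member
with the smallest adjusted p (ties lexicographic). Proprietary iterative
group-merging heuristics of desktop tools are intentionally not imitated;
connected components are the simplest deterministic grouping and are stated
in the output.

**Term direction.** A term is labelled up when more hit genes are up- than
down-regulated, down in the reverse case, mixed on a tie — mirroring the
red/green/grey node convention of term-network figures.

**Pathway Z-score.** The MAPPFinder-style standardised score for a pathway
of measured size $n$ with $r$ query hits, given $R$ total hits in a
measured universe of $N$:

$$z = \frac{r - nR/N}{\sqrt{n \frac{R}{N}\left(1 - \frac{R}{N}\right)\left(1 - \frac{n - 1}{N - 1}\right)}}$$

i.e. the hypergeometric mean and variance of $r$. The significance cutoff
1.6449 is the one-sided 5% standard-normal critical value
($\Phi^{-1}(0.95)$); a degenerate variance ($R = 0$, $R = N$ or $n = N$)
returns $z = 0$ with a warning rather than NaN.

## Fold-change clustering

Overlapping features form a matrix of $\log_2$ ratios (rows clusters,
columns studies, missing where unreported; rows need at least two observed
cells). Distances are Euclidean over pairwise-complete cells, scaled to the
full dimension, with a minimum-overlap requirement of two shared cells —
any pair below it is an error naming the rows, because a distance from
fewer shared cells would be meaningless. Clustering is average-linkage
agglomeration via `stats::hclust`; the distance metric, linkage and missing
handling are package defaults (the method they emulate reports none) and
are stated in every output. The implementation is checked against a
brute-force $O(n^3)$ agglomeration oracle.

## Disease and regulatory overlays

Disease similarity is ranked purely by shared-gene count against a local
disease-gene flat file (ties alphabetical); evidence scores of the source
databases are deliberately not modelled, since the shared-gene count is the
statistic actually tabulated. The regulatory overlay keeps
regulator→target edges whose target is in the query and follows the
convention of requiring at least two loaded regulatory interaction
networks; with fewer, it returns an empty overlay with an explanatory
status rather than an error.

## The synthetic-data generator

The generator emulates *published end-result tables*, not instruments: no
spectra or reads, only molecule lists with ratios and p-values.

* **Design.** Eleven studies mirroring the curated dataspace: 7 naive and
  4 ERT, 5 urine and 6 blood, mixing proteomics, peptidomics, metabolomics
  and transcriptomics, with cohort sizes where published.
* **Signals.** 60 planted clusters, each supported by 2–4 studies of one
  group with a common direction. Because literature tables only contain
  molecules that passed each study's own detection filters, signal
  magnitudes are drawn *above* the platform's detection cutoff:
  $\mathrm{FC} = T_p \times 1.15 \times e^{|\mathcal{N}(0.15,\,0.25)|}$,
  where $T_p$ is the platform's effective threshold — so transcriptomics
  signals typically exceed FC 2 and the other platforms FC 1.4,
  reproducing the platform-dependent fold-change scales of real tables.
  Signal p-values are uniform on $(10^{-8}, 0.01)$.
* **Nulls.** 60 clusters with ratios log-normal around 1 (log-sd 0.15) and
  uniform p-values, appearing in 1–2 studies.
* **Contradictions.** A further 8% of the signal count are planted with
  their direction flipped in exactly one randomly chosen supporting study —
  precisely the failure mode the consistency check removes.
* **Redundancy.** Every cluster is published under 1–3 raw aliases with a
  small log-scale jitter (sd 0.02) between aliases within a study.
* **Gene sets.** 40 terms of 8–25 members over a universe of all generated
  clusters plus 300 never-measured background ids (real annotation
  collections mostly contain genes outside any given measured dataset —
  without this, the background would be saturated by the query and
  enrichment would be undetectable by construction). Five planted terms
  draw 75% of their members from true signal clusters; the rest draw
  uniformly.
* **Determinism.** One master seed; each study draws its measurements from
  a derived substream, so identical configuration and seed give
  byte-identical tables.

**What passing tests do and do not show.** Against this generator the
pipeline recovers ≥95% of planted consensus features with correct
direction, removes 100% of planted contradictions, and ranks every planted
term above the median non-planted term — across 20 seeds. These results
validate the *mechanics* (mapping, collapsing, thresholding, merging,
testing) under realistic effect and noise scales. They do not certify
behaviour on real literature tables, whose failure modes include mapping
ambiguity beyond a clean alias table, platform batch structure,
non-independent studies (shared cohorts), and publication bias in which
molecules get reported at all.

## Numerical and degenerate-input choices

* Percentages in tag summaries use half-up rounding to one decimal.
* `term_kappa` returns 1 for identical sets when chance agreement is 1,
  otherwise 0 in that degenerate case.
* A hypergeometric test with $K = 0$ (or any degenerate support) returns
  $p = 1$.
* Empty inputs: an empty measurement file or empty group yields empty
  outputs from merging; summarising an empty group is an error (there is
  nothing to describe).
* All outputs are sorted deterministically (descending effect or support,
  then lexicographic identifiers) so repeated runs are byte-identical.
* Problem sizes in the shipped tests and the acceptance script — 11
  studies, 120–125 clusters, 40 terms, 20 seeds — are the package's chosen
  simulation scale: large enough for stable rates, small enough to run the
  whole suite in well under a minute.

## A worked example

```{r example}
cfg <- synthetic_config()
syn <- generate_studies(cfg, seed = 42)
gs  <- generate_gene_sets(syn$truth, cfg, seed = 42)
report <- run_pipeline(run_config(syn$measurements, syn$studies,
                                  syn$alias_map, gene_sets = gs$gene_sets,
                                  seed = 42))
report
head(report$groups$naive$tags)
head(report$groups$naive$enrichment[
  c("term_id", "K", "n", "k", "p_two_sided", "p_adjusted",
    "regulation_label")])
```

## Known limitations

* The kappa grouping is connected components, not the iterative
  group-merging of desktop enrichment tools; groups can chain through
  intermediate terms.
* Gene sets are flat membership lists; pathway topology and ontology
  hierarchy (term levels, evidence codes) are out of scope.
* No meta-analytic weighting by cohort size: ratios are averaged
  unweighted, as the method this package systematises does; cohort sizes
  are carried as metadata only.
* Real-data identifier mapping is only as good as the supplied alias
  table; the package does not build or curate one.
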
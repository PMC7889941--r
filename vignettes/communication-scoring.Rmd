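---
title: "Scoring directional cell-to-cell communication from transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring directional cell-to-cell communication from transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commscore)
```

## The problem and the model

Transcriptomes let us ask which ligand–receptor channels connect two cell
populations. `commscore` anchors everything on one *central* population —
a bulk profile, or a single-cell cluster average — and pairs it against
*partner* cell types. Communication is directional: outward scores use the
central cell's ligands against partner receptors, inward scores swap the
roles.

The model is deliberately simple and transparent:

1. **Gene selection.** Only genes appearing in the ligand–receptor
   database are used; no expression filtering threshold is applied.
2. **Per-gene max-scaling.** Within a dataset, each gene is scaled so its
   ceiling is 10, where the ceiling is the mean of the top-fraction
   (default 5 %) highest values across samples; values above the ceiling
   are capped at 10. Rationale: bioactivity is not proportional to
   abundance — potent interleukins are transcribed at low levels while
   many chemokines are abundant — so each channel must be judged on its
   own scale.
3. **Per-interaction score.** `s = l · r` on the scaled values, with
   multimeric sides combined by geometric mean (`l·√(r1·r2)` for a
   two-chain receptor). The geometric mean implements the co-expression
   AND-rule: if any required subunit is not expressed (scaled value
   exactly 0), the side — and the interaction — scores 0.
4. **Global score.** `S = w · Σ s_i` over the database; `w` models a
   between-dataset technical effect as a constant factor, so it rescales
   S without changing relative differences.
5. **Views.** `S̄ = S_jk / S_0k` normalizes to a reference condition;
   a linear min–max map onto [1, 10] over all displayed scores spreads
   them for network drawing.

### Assumptions worth stating

* mRNA abundance is a usable proxy for available ligand/receptor protein;
  no secretion, trafficking or post-translational control is modeled.
* Channels are independent and additive; no downstream signaling is
  integrated (deliberately — receptor promiscuity makes pathway-level
  attribution unreliable).
* Scores are relative quantities. They are comparable within one analysis
  (same database, same scaling run), not across analyses.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `top_fraction` | 0.05 | fraction of highest values averaged into the per-gene ceiling; with n samples, k = max(1, ceil(0.05·n)) values are used, so small datasets still define one |
| `w` | 1 | technical-effect weight between datasets (dimensionless) |
| `missing` | `"exclude"` | interactions with a subunit gene absent from a platform are *excluded* from S and reported, since platform absence is not evidence of non-expression; `"zero"` switches to zero-imputation |
| `alpha_display` | 0.1 | BH-adjusted p threshold used to flag significance in plots |
| balloon `cutoff` | 10 | an interaction appears in the balloon plot if its score reaches the cutoff in at least one column |
| `n_rep` (subsampling) | 20 | random cell selections per fraction |

## Statistical comparison

Replicate-wise score distributions come in two modes: *partner comparison*
(average the central replicates, score each partner replicate separately;
n = partner replicate count) and *condition comparison* (score each
central replicate against the partner average). All pairwise comparisons
in one call are tested with a two-sided Wilcoxon rank-sum test — exact
null when both groups have ≤ 25 replicates and no ties, normal
approximation with tie correction otherwise — and adjusted with
Benjamini–Hochberg over that pairwise family. The unpaired test is the
right choice because compared replicates are independent donors/samples.
Two groups that are constant and identical get p = 1 by convention, with
a warning.

## Subsampling robustness (single-cell)

Cluster averages are the unit of analysis for single-cell input. To ask
how much a score depends on the cells that happened to be sequenced, the
focal cluster is repeatedly subsampled at a grid of fractions; each
subsample mean is re-scaled through the pipeline and re-scored against a
fixed partner, and the per-fraction SD of the scores is reported.

One numerical subtlety is decided here: scaling a *single* subsampled mean
in isolation is degenerate, because with one column the gene's own value
is its ceiling and every expressed gene maps to 10. The pipeline's
realistic behaviour is that all cluster averages are scaled jointly, so
`subsample_robustness()` requires a `context` matrix of the other cluster
means and scales the subsample mean together with it
(`scaling = "per_subsample"`). The alternative `scaling = "fixed"` reuses
the full-data ceilings for every subsample. The default re-applies scaling
each time so the whole pipeline, not just the sum, is exercised.

## What the synthetic generator emulates — and what it does not

`generate_bulk_dataset()` plants a known world: two central conditions
(default fold change 2 on ligand genes), 6 replicates per group (a
typical bulk design), partner types with type-specific receptor programs,
and multiplicative lognormal noise (default sigma 0.3, a mid-range
biological CV for expression). In noiseless mode the generator ships a
closed-form expected score matrix computed by an independent plain-loop
routine, so the pipeline can be checked to machine precision.

`generate_sc_dataset()` draws cells around planted cluster means; each
cluster expresses genes at cluster-specific levels with ~30 % of genes
silenced per cluster. That matters: no cluster is the top expresser of
every gene, so joint max-scaling leaves most scaled values strictly below
10 — the regime real multi-cluster data live in. (An earlier design that
made one cluster dominate all ligand genes pinned its scaled values at 10
and made subsampling variability vanish; it was replaced for that
reason.)

The generator does **not** emulate dropout models, batch effects, library
size variation, or count discreteness. A green test therefore establishes
the *arithmetic* of the pipeline — scaling, combination rules, sums,
tests, and their statistical calibration under lognormal noise — not
robustness to single-cell technical artifacts.

The generator's lognormal noise model is a fixture choice made once for
testability, not a biological claim.

## The shipped database

The curated interaction database this model was built around is
distributed as supplementary material under access restrictions, so the
package ships `lr_database_synthetic.tsv`: a stand-in with the same
schema (two ligand subunit columns, two receptor subunit columns, family,
cytokine subfamily, PubMed ID) and the same published counts — 380
interactions, 194 cytokines (across the 7 structural subfamilies: type 1,
type 2, IL-1, IL-17, TNF, TGF, RTK), and families Growth factor,
Cytokine, Chemokine, Checkpoint, Notch signaling, Antigen binding, plus
"other". Well-established pairs are real; padding rows use synthetic
symbols and are marked by `SYN*` prefixes. It validates cleanly and loads
through the same code path a user's curated file would.

## Numerical and design decisions

* **Small-n scaling**: k = max(1, ceil(top_fraction·n)) keeps the ceiling
  defined for datasets with fewer than 1/top_fraction samples.
* **Ligand multimers** use the same geometric mean as receptor chains;
  the database schema carries two subunit columns on both sides and the
  symmetric rule is the only consistent generalization.
* **"Not expressed" means scaled value exactly 0** — no positive
  detection threshold.
* **Missing platform genes** exclude an interaction rather than zero it
  (absence of a probe is not absence of expression); zero-imputation is
  available behind a flag and documented in the score result's
  `excluded` field either way.
* **Duplicate database pairs** are flagged by validation and must be
  deduplicated before scoring (`dedupe_lr_database()`, first occurrence
  kept) — double counting would silently inflate S.
* **Duplicate gene rows** in expression tables keep the row with the
  largest total signal: deterministic and order-independent.
* **Rescaling** is the affine map x → 1 + 9(x−min)/(max−min) over all
  displayed scores; a constant score set maps to 10 (degenerate case,
  documented rather than erroring). Normalization, when requested,
  precedes rescaling.
* **Rescaled network labels** are printed rounded to integers but stored
  at full precision.
* **Scaling scope**: central and partner datasets are scaled
  independently; any cross-platform effect then acts as the constant w.
  A `samples` argument restricts ceiling computation for sensitivity
  analysis, since pooling scope across datasets is genuinely ambiguous.
* **Seeds** are explicit arguments and recorded in reports/manifests;
  same seed, same bytes.

## Known limitations

* Scores have no absolute units; only comparisons within an analysis are
  meaningful.
* The AND-rule treats any nonzero subunit expression as sufficient for
  complex formation; stoichiometry is ignored.
* The Wilcoxon comparisons inherit low power at very small replicate
  counts (n = 3 vs 3 cannot reach p < 0.1 two-sided exact).
* Cross-platform comparisons rely on the constant-w assumption; genes
  missing from one platform are excluded pairwise, which can make S
  values non-comparable across platforms unless the shared-gene subset is
  used.
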
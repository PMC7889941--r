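# commscore

Quantify directional cell-to-cell communication from transcriptomes.

Cells coordinate through ligand–receptor signaling: a sender cell
transcribes a ligand, a receiver transcribes the cognate receptor, and the
pair forms a communication channel. Given a transcriptomic profile of one
cell population of interest (the *central cell* — from bulk RNA-seq,
microarray, or averaged single-cell clusters) and profiles of candidate
*partner* cell types, `commscore` estimates how much information flows out
of (ligands → partner receptors) or into (partner ligands → receptors) the
central cell, channel by channel and in aggregate. It is aimed at
immunologists and tumor-microenvironment researchers who want a ranked,
statistically compared map of which cell types a population can talk to.

## The model

Each gene's expression is first max-scaled per dataset: the ceiling (value
10) of gene *g* is the mean of its top 5 % of values across samples, every
value is mapped to `min(10, 10·x/ceiling)`. This stops abundant messengers
(many chemokines) from drowning out potent low-abundance ones (IL-12,
IL-4).

For interaction *i* between central condition *j* and partner *k*,

```
s_ijk = l_ij · r_ik
```

where `l` and `r` are the scaled ligand and receptor values. Multimeric
ligands and multi-chain receptors combine their subunits by geometric mean
(e.g. `l·√(r1·r2)`), so one silent subunit zeroes the side — an AND-rule
for co-expression. The global score sums the channels:

```
S_jk = w · Σ_i s_ijk
```

with `w` a technical-effect weight (default 1; it changes only the range,
never relative differences). Scores can be normalized to a reference
condition (`S̄_jk = S_jk / S_0k`) and linearly rescaled onto [1, 10] for
network display. Replicate-wise score distributions are compared with
two-sided Wilcoxon rank-sum tests, Benjamini–Hochberg adjusted, displayed
at the p ≤ 0.1 threshold.

The package ships a **synthetic** stand-in ligand–receptor database
(`inst/extdata/lr_database_synthetic.tsv`) that mirrors the published
curation's structure and counts — 380 interactions, 194 cytokine
interactions across 7 structural subfamilies, 6 named families plus
"other" — with well-known real pairs (CD86/CD28, CCL22/CCR4,
IL12A+IL12B/IL12RB1+IL12RB2, JAG1/NOTCH1, …) included verbatim and the
remainder synthetic. Supply your own curated file via
`load_lr_database()` for real analyses.

## Worked example

```r
library(commscore)

db <- load_lr_database(lr_database_path())
db
#> ligand-receptor database: 380 interactions, 863 genes
#>   Growth factor    58
#>   Cytokine         194
#>   Chemokine        52
#>   Checkpoint       42
#>   Notch signaling  12
#>   Antigen binding  12
#>   other            10

# seeded synthetic bulk dataset: 2 central conditions x 6 replicates,
# 4 partner types, noiseless so expected scores are known in closed form
cfg <- synthetic_config(noise_sigma = 0, seed = 3)
ds  <- generate_bulk_dataset(cfg)

cs <- scale_expression(ds$central)   # per-gene max-scaling to [0, 10]
ps <- scale_expression(ds$partner)
cm <- sapply(unique(ds$conditions), function(g)
  rowMeans(cs[, names(ds$conditions)[ds$conditions == g]]))
pm <- sapply(unique(ds$partner_types), function(g)
  rowMeans(ps[, names(ds$partner_types)[ds$partner_types == g]]))
rownames(cm) <- rownames(cs); rownames(pm) <- rownames(ps)

sm <- score_matrix(cm, pm, ds$db)
sm$raw
#>        partner1  partner2  partner3 partner4
#> cond1  658.3015  809.1055  680.1037  861.448
#> cond2 1316.6029 1618.2110 1360.2074 1722.896

max(abs(sm$raw - ds$expected))       # closed-form oracle agreement
#> [1] 2.273737e-13

rescale_scores(sm)$rescaled          # [1, 10] display view
#>       partner1 partner2 partner3  partner4
#> cond1 1.000000 2.274885 1.184314  2.717385
#> cond2 6.565229 9.115000 6.933858 10.000000
```

`cond2` plants a two-fold ligand effect, so its raw scores double; the
rescaled view is what the network plot encodes as edge widths. From here,
`family_contributions()` decomposes a score by molecular family,
`partner_comparison_scores()` + `compare_distributions()` test which
partners differ, and `export_network() / export_barplot() /
export_balloon() / export_pvalue_heatmap()` render the four standard
views, each with an exact companion table.

A command-line interface wraps the same pipeline:

```sh
Rscript -e 'commscore::main()' score config.json
```

with a JSON config (`validate-db`, `score`, `compare`, `subsample`
subcommands; every run writes a `manifest.json` with input hashes, seed
and parameters).

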
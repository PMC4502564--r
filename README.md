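# dupliclass

Classification of the evolutionary processes that retain duplicate genes,
from multi-tissue gene expression profiles.

## The problem

After a gene duplicates, the two copies can be retained in different ways:

* **conservation** — both copies keep the ancestral expression profile;
* **neofunctionalization** — one copy (parent or child) acquires a novel
  profile while the other keeps the ancestral one;
* **subfunctionalization** — each copy loses part of the ancestral
  expression domain, but together they reconstitute it;
* **specialization** — both copies and even their combined output diverge
  from the ancestral profile.

`dupliclass` implements a phylogenetic expression-profile test of these
hypotheses for duplicate pairs in which parent and child copies can be
distinguished (by alignment of one copy to outgroup genomes) and a
single-copy ortholog — the *outgroup gene* O, a proxy for the ancestral
gene — is available in a closely related sister species.

## The method

Expression matrices (FPKM-like, up to 11 tissues: female/male cerebrum,
cerebellum, heart, kidney, liver, plus testis) are quantile-normalized
jointly across all samples, genes are kept if expressed (FPKM ≥ 1) in at
least one tissue, and each gene's profile is its vector of **relative
expression levels** (proportions of total expression). For a trio of
parent P, child C and outgroup O, the Euclidean distances
E\_P,O, E\_C,O and E\_P+C,O (combined profile = per-tissue sum of parent
and child, renormalized) are compared against a per-species-pair
divergence cutoff derived from the distances E\_S1,S2 of single-copy
ortholog pairs between the same two species:

    cutoff = median(E_S1,S2) + SIQR(E_S1,S2),  SIQR = (Q3 − Q1) / 2

a criterion robust to outliers and to distribution-shape differences among
species pairs. The rule table (distances at the cutoff count as *not*
diverged):

| E\_P,O | E\_C,O | E\_P+C,O | class |
|-------|-------|---------|-------|
| ≤ | ≤ | – | CONSERVED |
| > | ≤ | – | NEOFUNC_PARENT |
| ≤ | > | – | NEOFUNC_CHILD |
| > | > | ≤ | SUBFUNC |
| > | > | > | SPECIALIZED |

Around the classifier the package provides parsimony dating of
duplications on a rooted species tree (single-gain placement from
copy-number patterns), parent/child designation from outgroup-alignment
flags, downstream statistics (least-squares regression of the conserved
proportion on median K_s with F and t tests, Mann–Whitney tissue-specificity
comparisons, Fisher's exact highest-tissue enrichment with Bonferroni
correction), and a fully seeded synthetic-data generator that plants
ground-truth classes so the whole pipeline is testable without external
data.

## Worked example

```r
library(dupliclass)
cfg <- generator_config(seed = 42, n_trios_per_class = 50)
bundle <- simulate_dataset(cfg)
result <- run_pipeline(bundle)
print(result)
#> dupliclass pipeline result
#> Duplicate-gene retention classification
#>   classified trios: 250  excluded: 0
#>   CONSERVED       50
#>   NEOFUNC_PARENT  50
#>   NEOFUNC_CHILD   50
#>   SUBFUNC         50
#>   SPECIALIZED     50
```

All 250 planted trios (50 per class, balanced across eight human–X species
pairs) are recovered exactly at this seed. Individual records carry the
three distances and the cutoff actually used:

```r
head(result$classification$records, 4)
#>               pair_id       e_po       e_co      e_pco cutoff_used     label
#> 1 dup_chimpanzee_0001 0.03624580 0.01338576 0.02017980   0.1006711 CONSERVED
#> 2 dup_chimpanzee_0002 0.03330154 0.05941279 0.04501970   0.1006711 CONSERVED
#> 3 dup_chimpanzee_0003 0.04472651 0.04042392 0.03868847   0.1006711 CONSERVED
#> 4 dup_chimpanzee_0004 0.03270658 0.02399407 0.02635029   0.1006711 CONSERVED

result$classification$cutoffs[["chimpanzee|human"]]
#> Divergence cutoff: 0.100671 (median 0.08484 + 1 x SIQR 0.0158311; n = 200)
```

A conserved trio's distances (~0.03) sit well below the human–chimpanzee
cutoff of 0.10, which is the median single-copy ortholog divergence plus
one semi-interquartile range over 200 baseline pairs.

To see conservation decline with evolutionary distance, let divergence
events accumulate with K_s instead of planting balanced classes:

```r
ksp <- data.frame(focal = "human",
                  outgroup = c("chimpanzee", "macaque", "mouse", "opossum", "platypus"),
                  ks = c(0.01, 0.2, 0.5, 1.0, 1.4))
cfg2 <- generator_config(seed = 9, n_trios_per_pair = 300,
                         drift_per_ks = 0.1, ks_pairs = ksp)
res2 <- run_pipeline(simulate_dataset(cfg2))
res2$regression
#>      gene_set       slope intercept   f_pvalue slope_t_pvalue n_points
#> 1   duplicate -0.53221655 0.9370387 0.00105916     0.00105916        5
#> 2 single_copy -0.01850754 0.7415117 0.35748719     0.35748719        5
```

The proportion of functionally conserved duplicates falls steeply with
K_s (slope −0.53, t-test p ≈ 0.001), while the single-copy analogue is an
order of magnitude flatter — duplicates diverge much faster than ordinary
genes.

A thin command-line wrapper (`inst/cli/dupliclass`) exposes `simulate`,
`validate` and `run` subcommands over directories of TSV/Newick inputs.

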
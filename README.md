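# vtdisorder

Comparative analysis of intrinsic structural disorder in vesicle
trafficking proteins.

Eukaryotic vesicle traffic is carried by three main routes — the
clathrin-mediated system (endocytosis and the late secretory pathway) and
the COPI and COPII systems (Golgi–ER and ER–Golgi transport). Their
proteins differ sharply in how much they rely on intrinsically disordered
regions: segments with no stable tertiary structure that act as flexible
linkers, fly-casting arms and docking sites for binding motifs.
`vtdisorder` is for structural bioinformaticians who want to quantify
that reliance: it turns per-residue disorder and binding predictions
(IUPred/ANCHOR-style score tracks) plus tabular annotations into
per-protein metrics, group and route statistics, interaction-partner
filters, tissue-specific-exon structural profiles and ortholog
comparisons — and ships a synthetic-data generator with planted ground
truth so the whole pipeline can be validated without any external data.

## The metrics

For a protein of length *L* with annotated transmembrane (TM) segments,
all metrics are computed over the *effective length* — the *L*′ residues
outside TM segments, which are excluded from every numerator and
denominator:

- **disorder content** d.c. = (residues with disorder score ≥ 0.5) / *L*′;
- **LDR residue ratio** at *k* — the fraction of effective residues lying
  in maximal runs of ≥ *k* consecutive disordered residues (long
  disordered regions; *k* = 30, 50, 100);
- **DBR residue ratio** — the same construction on the binding track
  (disordered binding regions, minimum run length 6 by default).

Cohorts are compared with the Wilcoxon rank-sum test (exact for small
tie-free samples, normal approximation with tie and continuity correction
otherwise) and against whole-proteome reference counts with Fisher's
exact (hypergeometric) test. Off-pathway interaction partners are
filtered by STRING-style confidence (≥ 0.9), sequence identity to the
pathway set (> 70 % excluded, CD-HIT-style shorter-sequence denominator),
greedy identity clustering of redundant partners and an exclusion list
standing in for manual curation. Tissue-specific exons (exon switch
score ≥ 0.25) are mapped to protein coordinates by a codon-majority rule
and scored for disorder and for DBRs overlapping the exon span or its
5-residue boundary neighbourhood.

## Worked example

Generate a two-route synthetic cohort with a planted contrast mirroring
the clathrin-vs-COPI difference (mean disorder content 0.28 vs 0.09,
n = 30 per route, track noise sd 0.08), run the metrics stage, and test
the contrast:

```r
library(vtdisorder)

groups <- data.frame(label = c("CLTR", "COPI"), n = 30,
                     target_mean_dc = c(0.28, 0.09), dc_sd = 0.08,
                     len_min = 120, len_max = 180)
out <- synth_cohort(groups, "cohort", noise_sd = 0.08, seed = 42)
res <- run_metrics(out$paths$fasta, out$paths$annotations, out$paths$track_dir)
st  <- summary_table(res$summaries)

grouping <- setNames(out$truth$group, out$truth$accession)
group_summary(st, grouping)
#>   group_label n_proteins mean_dc median_dc mean_dbr median_dbr mean_ldr30
#> 1        CLTR         30  0.2842    0.2808   0.0892      0.105     0.2626
#> 2        COPI         30  0.0959    0.0868   0.0230      0.000     0.0203

a <- st$disorder_content[grouping[st$accession] == "CLTR"]
b <- st$disorder_content[grouping[st$accession] == "COPI"]
rank_sum_test(a, b)
#> <test_result> rank_sum (two_sided): statistic 869, p = 6.111e-10 (n1=30, n2=30)

ldr_prevalence(st, grouping)
#>   group_label n_proteins frac_ldr_30 frac_ldr_50 frac_ldr_100
#> 1        CLTR         30       0.867       0.233            0
#> 2        COPI         30       0.100       0.000            0
```

The recovered group means sit on the planted 0.28/0.09 targets, the
rank-sum test flags the contrast at p ≈ 6×10⁻¹⁰, and LDRs of ≥ 30
residues are concentrated in the high-disorder route — the qualitative
signature the real trafficking routes show.

Per-protein arithmetic is exact: a 248-residue protein with 149
disordered residues has d.c. 60.08 %, and a 36-residue exon span with 16
disordered residues is 44.44 % disordered, as reported by
`summarize_protein()` and `tse_disorder()`.

## Package layout

- `R/` — domain types and IO (`protein_record`, `score_track`, readers
  for FASTA / tracks / annotation, edge, TSE and ortholog tables),
  per-protein metrics, cohort statistics, interaction filtering, TSE
  structure, ortholog comparison, synthetic-data generation.
- `inst/extdata/` — plain-text inputs: the per-protein off-pathway
  interaction report, the strongly tissue-specific exon table, and an
  example GTPase exclusion list.
- `vignettes/vesicle-trafficking-disorder.Rmd` — the methods vignette:
  model, conventions, parameter choices and limitations.
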
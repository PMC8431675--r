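# MotifSubtypes

Subtype discovery from somatic point mutations using **gene-motif**
features: every simple somatic substitution is reduced to one of the
96 pyrimidine-centred trinucleotide classes (written `CT-G.A` for
C→T with G on the 5' side and A on the 3' side) and concatenated with
its gene, e.g. `KRAS-CT-A.G`. The binary samples × gene-motif
occurrence matrix combines *which genes are hit* with *which
mutational process hit them*, and drives the whole characterisation:

* **Reading & cleaning** — ICGC-style SSM tables and VCF; non-SNV rows
  dropped and counted; records deduplicated on (sample, locus,
  alleles) with per-transcript rows retained.
* **Feature selection** — empirical top-tail rule: genes and
  gene-motifs whose occurrence counts land in the top `alpha`
  (default 0.01) of their empirical distributions, intersected so that
  every clustering feature lives in a significant gene.
* **Clustering** — diagonal Gaussian mixture fitted by EM, number of
  components by BIC (`2·logL − p·log n`), applied recursively with the
  meaningful-cluster rule (`max(7, floor(0.01·n))` samples; smaller
  clusters are outliers); leaves become subtypes `PCS1, PCS2, ...`.
* **Mutational signatures** — bootstrap NMF of the 96-channel catalog
  under the generalized KL objective, k-medoid consensus with
  silhouette diagnostics, NNLS exposures, and cosine/angular matching
  against a reference catalog at the 0.70 threshold.
* **Gene association** — two-sided Fisher exact tests calibrated by a
  permutation scheme that regenerates per-gene mutated-sample counts
  preserving subtype totals; a gene is *associated* when its p-value
  beats the permutation threshold (rank `ceiling(tail_frac·n_perm)`,
  i.e. 5 at 10,000 × 0.0005) and it is mutated in ≥ 50 % of the
  subtype.
* **Survival & clinical tables** — Kaplan–Meier with Greenwood
  log-log intervals, the weighted log-rank family (log-rank, Breslow,
  Tarone–Ware), pairwise subtype comparisons, and sex / project-code
  frequency tables.
* **Synthetic cohorts** — a fully seeded generator (reference FASTA,
  annotation, SSM, clinical, ground truth) with planted subtypes,
  signatures, driver gene-motifs and exponential survival, so every
  stage is testable offline.

## Worked example

```r
library(MotifSubtypes)

cfg <- simulationConfig(nSamples = 120L, nGenes = 120L,
                        nChromosomes = 2L, geneLengthBp = 400L,
                        driverGeneLengthBp = 650L,
                        mutationsPerSampleMean = 150, seed = 11L)
ref <- generateReference(cfg)
coh <- simulateCohort(cfg, ref$reference, ref$annotation)
cohort <- makeMutationCohort(data.frame(
  sample_id = coh$ssm$icgc_donor_id, chrom = coh$ssm$chromosome,
  pos = coh$ssm$chromosome_start,
  ref = coh$ssm$reference_genome_allele,
  alt = coh$ssm$mutated_to_allele,
  gene_id = coh$ssm$gene_affected,
  transcript_id = coh$ssm$transcript_affected,
  consequence = coh$ssm$consequence_type))
cohort
#> MutationCohort with 17545 deduplicated SNVs in 120 samples
#>   genes observed: 120
#>   transcript rows: 27061

gm  <- buildGeneMotifMatrix(cohort, ref$reference)
sel <- selectFeatures(gm, genePresenceCounts(cohort,
         sort(unique(ref$annotation$gene_id))), alpha = 0.03)
sel
#> SelectionResult (alpha = 0.03 )
#>   significant genes: 3 (count >= 97 )
#>   significant gene-motifs: 94 (count >= 9 )
#>   candidate clustering features: 27

tree <- recursiveCluster(
  t(occurrence(gm)[candidateFeatures(sel), , drop = FALSE]),
  seed = 2L)
tree
#> SubtypeTree over 120 samples, minSize = 7
#>   PCS1: 51
#>   PCS2: 35
#>   PCS3: 34
```

The three leaves are the three planted subtypes (adjusted Rand index
1.0 against the generator's truth). Survival per discovered subtype,
in months:

```r
si <- survivalInput(subtypeLabels(tree), readClinical(coh$clinical))
for (g in sort(unique(si$group))) {
  km <- kmEstimate(si$time[si$group == g], si$event[si$group == g])
  cat(sprintf("%s: n=%d median=%.1f restricted mean=%.1f\n",
              g, km@n, km@median, km@restrictedMean))
}
#> PCS1: n=51 median=19.3 restricted mean=24.4
#> PCS2: n=35 median=20.1 restricted mean=23.4
#> PCS3: n=34 median=36.0 restricted mean=46.4
pairwiseSurvivalTests(si$time, si$event, si$group, schemes = "logrank")
#>   group_a group_b  scheme        chi2          p unequal
#> 1    PCS1    PCS2 logrank 0.001409221 0.97005477   FALSE
#> 2    PCS1    PCS3 logrank 3.861819837 0.04939672    TRUE
#> 3    PCS2    PCS3 logrank 3.228859558 0.07235106   FALSE
```

PCS3 carries the planted low-hazard subtype: its median survival is
roughly 16 months longer and the log-rank test flags it against PCS1
at the 0.05 level.

`runAll(config)` (or the `inst/scripts/motifsubtypes` command-line
front end) chains all stages from a YAML config and writes every table
plus a manifest; see the vignette for the model, parameter meanings
and design choices.

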
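# cernet

Integrative competing-endogenous-RNA (ceRNA) network analysis and
biomarker evaluation for case--control transcriptomes, motivated by
studies of mitochondrial myopathy (MELAS) muscle and serum profiles.

Disease-dysregulated miRNAs, lncRNAs and mRNAs can form regulatory
circuits in which a miRNA represses both an mRNA and a lncRNA, and the
two non-miRNA partners "compete" for the shared miRNA. `cernet`
implements the full analysis a study of this design requires:

1. **Differential expression.** Microarray signal (miRNA) and FPKM
   (lncRNA/mRNA) matrices are normalised (LOWESS in MA space for paired
   intensity channels; FPKM = 10^9 *c* / (*L* *N*) from counts), tested
   per feature (Welch's t on log2 values, or exact/tie-corrected
   Mann--Whitney), and corrected by Benjamini--Hochberg. The DE screen is
   |FC| > 2 with q < 0.05; a stricter candidate screen (|log2FC| > 1.5,
   p < 0.01, abundance >= 30 copies / 500 signal in either group) selects
   features for qPCR validation.
2. **Target prediction.** Canonical miRNA seed sites (6mer, 7mer-A1,
   7mer-m8, 8mer; Watson--Crick only) scanned directly on mRNA 3'UTR and
   lncRNA sequences; lncRNA--mRNA partners by genomic proximity (cis,
   <= 100 kb) or co-expression (trans, |r| >= 0.9); optional ingestion of
   precomputed interaction tables.
3. **Network assembly.** Predicted pairs are kept only when the two
   endpoints are differentially expressed in *opposite* directions
   (repression signature). The three pairwise networks are integrated
   into the miRNA-centered (miRNA--mRNA--lncRNA) and lncRNA-centered
   (lncRNA--miRNA--mRNA) tripartite networks with triad tables, venn
   partitions of shared targets, degree-ranked hubs, and GraphML/SIF
   export for Cytoscape.
4. **Enrichment.** Hypergeometric over-representation of gene sets (GMT)
   with namespace-wise BH correction and rich factors (k/K).
5. **Biomarker evaluation.** 2^-ddCt relative quantification from
   triplicate Ct tables (U6/GAPDH/spike-in references), ROC analysis with
   exact pair-counting AUC, DeLong confidence intervals and paired AUC
   comparison, Youden-optimal cutoffs, and Spearman correlations with
   clinical covariates (lactate, NMDAS, mutation load).

Because the motivating study's patient data cannot be redistributed, the
package ships a first-class **synthetic-data generator** that emulates
the study design (20 cases vs 20 controls, planted log2 fold changes,
planted ceRNA triads whose sequences carry real seed-match sites, Ct
tables consistent with the planted effects, and a binormal serum marker
with configurable AUC and clinical correlations), together with the
ground truth needed for parameter-recovery testing.

## Worked example

```r
library(cernet)

cfg <- run_config(seed = 7, outdir = "melas-sim")
report <- run_pipeline(cfg)
str(report$counts$network)
#> List of 5
#>  $ edges       : int 42
#>  $ mirna_mrna  : int 20
#>  $ mirna_lncrna: int 20
#>  $ lncrna_mrna : int 2
#>  $ triads      : int 20

validate_run("melas-sim")   # 0 rows: every output passes its schema
```

The run directory now contains the DE tables (`de_mirna.tsv`, ...), the
predicted pairs (`pairs.tsv`), the five networks
(`network_*.graphml`, plus a `.sif`), `triads.tsv`, `venn.json`,
`enrichment.tsv` and `biomarker.json`. All 20 planted triads are
recovered, and the biomarker summary reports the empirical AUC of the
simulated serum marker with its DeLong interval and Youden cutoff:

```r
clin <- read.delim("melas-sim/clinical.tsv")
roc_curve(clin$marker, clin$group)
#> <roc_result> AUC = 0.703 (95% CI 0.537-0.868), lower-in-case
#>   optimal cutoff 1.363: sensitivity 100.0%, specificity 35.0%
```

The marker is *lower* in cases (as for a circulating miRNA depleted in
disease), so the reported orientation flag is `lower-in-case` and values
below the cutoff call a sample as a case. At the default n = 20 + 20 the
empirical AUC fluctuates around the planted 0.879; at n = 2000 + 2000 it
converges to within +/- 0.02 of it.

Single stages are available as plain functions (`de_table()`,
`find_seed_matches()`, `cis_pairs()`, `anticorrelation_filter()`,
`integrate_tripartite()`, `enrich()`, `ddct()`, `correlate()`, ...), and
`inst/cli/cernet.R` offers a thin `simulate` / `run` / `validate`
command-line wrapper.

## Vignette

`vignettes/cernet-methods.Rmd` documents the statistical models, the
synthetic-data design (what it emulates and what it deliberately does
not), all tunable parameters with their defaults, and the package's
numerical conventions.
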
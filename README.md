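# identiscape

Quantifies **loss of tissue molecular identity** from epigenomic and
transcriptomic data. The motivating biology: severe stress (e.g.
endoplasmic reticulum stress in hepatocytes) transiently represses the
identity program of a cell — the genes sitting under exceptionally broad
H3K4me3 domains, driven by densely co-bound, super-enhancer-associated
regulatory regions — and pushes the transcriptome back toward an immature
state. `identiscape` implements the full analysis chain as reusable,
tested R functions, plus a seeded synthetic-data generator so everything
runs without downloads.

For an analyst, the package answers, from standard inputs (BED peak sets,
bin-level differential ChIP tables, expression matrices):

* **Which genes carry tissue identity?** A peak is a *broad domain* when
  its length exceeds 3× the median peak length of its tissue; a broad
  domain is identity-specific (ID) when it is detected (≥ 1 bp overlap)
  in fewer than 25% of other tissues, ubiquitous (UBQ) otherwise; genes
  inherit ID/UBQ/OTHER through TSS overlap.
* **Which regulatory regions gain or lose activity?** Bins with
  genome-wide BH FDR ≤ 0.05 are signed by their log2 fold change, grouped
  under peaks (≥ 75 bp overlap), and the merged region is UP when
  #UP/#DOWN ≥ 2, DOWN when ≤ 0.5, MIXED in between.
* **Which enhancers are super-enhancers?** Peaks stitched within 12.5 kb,
  ranked by total signal; both rank and signal min–max scaled to [0, 1],
  cutoff where the discrete slope of the scaled curve first reaches 1
  (tangent rule); super iff signal > cutoff.
* **Does co-binding predict inactivation?** Enhancer × TF occupancy,
  stratified DOWN-overlap percentages (bound/unbound × 0–2, 3–5, 6–8
  additional TFs), and Fisher log-odds cistrome enrichment with ward.D2
  clustering.
* **How broad is the expression collapse?** Globally z-scaled fold
  changes after discarding the bottom 20% of genes by baseline
  expression; Tukey-depth bagplots; identity-gene enrichment across
  repression quartiles; weighted GSEA running-sum scores
  (ES = signed extremum of a sum stepping `|s|^w / Σ|s|^w` at hits,
  `-1/(N-m)` at misses); median-of-ratios size factors and per-cell
  gene-set means for single cells.
* **How far toward immaturity did the tissue move?** Mean-only,
  control-anchored batch alignment onto a developmental reference, then
  projection of every sample onto the reference's first covariance
  principal component, oriented so adult is positive.

## Worked example

Everything below runs on synthetic data from the package's own generator
(seed 42), so the numbers are exactly reproducible.

```r
library(identiscape)

cfg <- synth_config(seed = 42)      # 10 tissues, 2000 genes, 200 ID + 200 UBQ

## 1. identity genes from broad H3K4me3 domains
tp  <- gen_tissue_peaks(cfg)
res <- call_identity(tp$peaks, "liver", tp$tss)
table(res$calls$klass)
#>    ID OTHER   UBQ
#>   200  1600   200

## 2. differential H3K27ac regions from a bin table
gb <- gen_bins(cfg)
dr <- call_diff_regions(gb$bins, gb$peaks)
table(dr$regions$direction)
#>  DOWN UNCHANGED        UP
#>   109       785       106

## 3. identity genes concentrate in the deepest repression quartile
ge <- gen_expression(cfg, dediff_weights = c(0, 0.5, 1))
fc <- scale_and_fc(ge$perturbation$expr, ge$perturbation$condition, "control")
quartile_enrichment(fc[fc$scaled_fc < 0, ], res$calls)[, c("quartile", "n", "n_id", "q")]
#>   quartile   n n_id            q
#> 1       Q1 219    0           NA
#> 2       Q2 219    0           NA
#> 3       Q3 219    2 4.784941e-01
#> 4       Q4 218  163 9.495805e-58

## 4. project injured samples onto the developmental axis
expr <- cbind(ge$reference$expr, ge$injury$expr)
be <- batched_expression(expr,
  batch     = c(rep("dev", ncol(ge$reference$expr)),
                rep("inj", ncol(ge$injury$expr))),
  condition = c(ge$reference$stage, ge$injury$condition),
  reference_batch = "dev", anchor = c(dev = "adult", inj = "control"))
pr <- fit_project(align_batches(be), be)
round(tapply(pr$coords$pc1_coord[pr$coords$batch == "inj"],
             ge$injury$weight, mean), 1)
#>     0   0.5     1
#>  23.0   0.9 -21.3
```

Reading the output: the identity caller recovers exactly the 200 planted
identity and 200 ubiquitous genes; roughly 10% of peaks are called UP and
10% DOWN, matching the planted fractions; of the 163 + 2 identity genes
among repressed genes, essentially all sit in the most-repressed quartile
(Q4), the signature of identity-targeted repression; and injury samples
mixed 0%/50%/100% with the newborn profile land at descending positions
on the maturation axis (adult-anchored controls at +23, fully
dedifferentiated samples at −21, matching the newborn reference pole).

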
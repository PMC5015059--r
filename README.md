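# hetflag

Classification of per-gene cell-to-cell expression heterogeneity in
single-cell RNA-seq, with an emphasis on comparing long non-coding RNAs
(lncRNAs) to mRNAs.

## The problem

In a population of seemingly identical cells, many genes — lncRNAs in
particular — are not expressed uniformly: a gene may be silent (0 FPKM) in
most cells yet strongly expressed in a few. Bulk RNA-seq averages this away,
so a heterogeneously expressed lncRNA looks merely "lowly expressed".
`hetflag` quantifies this phenomenon per gene and classifies each gene as
having **high**, **low** or **uncertain** heterogeneity of expression, then
compares the resulting class fractions and coefficients of variation between
lncRNAs and mRNAs.

## The method

For a gene *g* in a dataset of *C* cells with FPKM values
*x<sub>g1</sub> … x<sub>gC</sub>*:

1. **Expressing-cell count.** A cell is *positive* for *g* when
   *x<sub>gc</sub>* > 3 FPKM (strict). *N<sub>g</sub>* = number of positive
   cells.
2. **Moderate-expression window.** Only genes with
   max<sub>c</sub> *x<sub>gc</sub>* ∈ (3, 30] FPKM are analysed; genes
   exceeding 30 FPKM in any cell are set aside into a highly expressed
   stratum (used in the CV comparison, not in the mixture fit).
3. **Mixture model.** Pooled over all windowed genes (lncRNAs and mRNAs
   together), the *N* values follow a two-component Gaussian mixture
   λ₁𝒩(μ₁,σ₁²) + λ₂𝒩(μ₂,σ₂²), fitted by EM (starting weights 0.5/0.5,
   starting σ 0.5, k = 2). Component 1 (smaller mean: expressed in few
   cells) is the **high-heterogeneity** population.
4. **Flags.** Each gene's posterior probability of component 1 is computed;
   a gene is flagged **H** when that posterior exceeds 0.99, **L** when the
   complementary posterior exceeds 0.99, and **U** (uncertain) otherwise.
5. **CV comparison.** For every expressed gene (max > 3 FPKM) the
   coefficient of variation sd/mean is computed across *all* cells (zeros
   included), stratified into moderate (3–30] and high (>30) expression;
   lncRNA and mRNA groups are compared with Welch's t-tests.

Supporting tools implement the surrounding conventions: union-exon gene
lengths and FPKM = reads × 10⁹ / (length × library size) from GTF and count
tables; RefSeq-prefix biotype rules (NM_/XM_/NP_/XP_ → coding, NR_/XR_ or
lincRNA → noncoding) with read-through reclassification and a >200 nt length
filter; under/over FPKM bounds for a gene overlapped by an opposite-strand
gene in non-strand-specific libraries; and a longest-ORF finder with a
Monte-Carlo null for "expected by chance" assessments.

A synthetic-data generator (`simulationSpec()` / `simulateMatrix()`) emits
FPKM matrices with planted per-gene ground truth — biotype labels, the
two-population structure in *N*, dropout zeros, maxima straddling the 3 and
30 FPKM boundaries — so the whole pipeline is testable without any external
data.

## Worked example

```r
library(hetflag)

spec <- simulationSpec(nCells = 96, nLnc = 500, nMrna = 500, seed = 42)
se   <- simulateMatrix(spec)   # SummarizedExperiment, assay "fpkm"
het  <- flagHeterogeneity(se)
het
#> HetResult: 781 genes classified
#> MixtureModel (two-component Gaussian)
#>   component 1 (high heterogeneity): lambda = 0.5455, mu = 4.9531, sigma = 1.4752
#>   component 2 (low heterogeneity):  lambda = 0.4545, mu = 72.4366, sigma = 7.1910
#>   logLik = -2512.287496 after 3 iterations (converged)
#>   lncRNA     n =  386  H  74.1%  L  25.9%  U   0.0%
#>   mRNA       n =  395  H  35.4%  L  64.6%  U   0.0%
```

781 of the 1000 simulated genes fall in the (3, 30] FPKM window. The mixture
separates a population expressed in ~5 of 96 cells from one expressed in
~72, and the recovered H fraction among lncRNAs (74.1%) matches the planted
0.74 (mRNAs: 35.4% vs planted 0.35). The CV comparison shows the same
structure:

```r
cvRec <- stratifyExpressedGenes(se)
subset(pairwiseCvComparisons(cvRec),
       group_a == "lncRNA-moderate" & group_b == "mRNA-moderate")
#>           group_a       group_b        t  df            p n_a n_b   mean_a   mean_b
#> 5 lncRNA-moderate mRNA-moderate 11.17383 779 5.444268e-27 386 395 3.820719 2.231133
```

Moderately expressed lncRNAs have a markedly higher mean CV (3.82 vs 2.23,
Welch p ≈ 5 × 10⁻²⁷): their expression is concentrated in fewer cells.

`runPipeline()` wraps these stages, reading/writing TSVs with a JSON run
manifest; `parseGtf()` + `classifyBiotype()` + `fpkmMatrix()` supply the
annotation-driven quantification path; `longestOrf()` / `orfChancePvalue()`
cover the ORF analysis.

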
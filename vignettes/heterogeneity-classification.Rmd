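---
title: "Classifying cell-to-cell expression heterogeneity with hetflag"
author: "hetflag maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cell-to-cell expression heterogeneity with hetflag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetflag)
library(SummarizedExperiment)
```

# The model

Single-cell RNA-seq of an outwardly homogeneous cell population shows that
many genes — long non-coding RNAs especially — are expressed in only a
subset of cells. `hetflag` classifies this behaviour per gene through one
statistic: the **expressing-cell count** $N_g$, the number of cells in which
gene $g$ exceeds a positivity threshold of 3 FPKM (strictly; a cell at
exactly 3 FPKM does not count). Pooled across genes, the distribution of
$N$ is bimodal: one population of genes is expressed in few cells (high
cell-to-cell heterogeneity), another in most cells (low heterogeneity). We
model the pooled $N$ values as a two-component Gaussian mixture

$$ f(n) = \lambda_1\,\mathcal{N}(n;\mu_1,\sigma_1^2)
        + \lambda_2\,\mathcal{N}(n;\mu_2,\sigma_2^2), $$

fitted by EM, with components relabelled so $\mu_1 \le \mu_2$; component 1
is by definition the high-heterogeneity population. Each gene receives the
posterior probability of component 1 at its $N$, and a flag:
**H** if that posterior exceeds 0.99, **L** if the complementary posterior
exceeds 0.99, **U** (uncertain) otherwise. Both cutoffs are strict: a
posterior of exactly 0.99 is U.

Modelling assumptions worth stating plainly:

* $N$ is treated as continuous. A Gaussian on an integer-valued, bounded
  count is an approximation; it is adequate when the two populations are
  well separated relative to their spreads and away from the boundaries
  1 and $C$ (the cell count).
* The mixture is fitted on **all windowed genes jointly** — lncRNAs and
  mRNAs together — and genes are classified against that common model.
  The pooled $N$ distribution is what is bimodal; fitting per biotype is
  available by simply subsetting the matrix, but it is not the default
  because the class definition should not depend on the biotype label.
* $N$ is fitted on the raw count scale, not normalised by $C$. Datasets of
  different sizes therefore get their own fits, and cross-dataset
  comparisons are made on flag fractions, never on raw $N$.

## The moderate-expression window

Only genes whose maximum FPKM across cells lies in $(3, 30]$ enter the
mixture analysis. The lower bound is strict, consistent with the positivity
rule (a gene never exceeding 3 FPKM is not expressed); the upper bound is
inclusive, because exclusion is defined as *exceeding* 30 FPKM in at least
one cell. The upper boundary convention is genuinely ambiguous in the usual
phrasing "3–30 FPKM"; we adopt $(3, 30]$ and expose both bounds in
`analysisConfig()`, so the choice is visible and changeable. The window
matters for two reasons: very highly expressed genes are almost always
broadly expressed (their inclusion would blur the low-$N$ component), and
restricting to a common expression band keeps the lncRNA/mRNA comparison
between genes of comparable abundance, so differences in heterogeneity are
not an artefact of abundance differences.

## Coefficient of variation

For every expressed gene (max FPKM > 3) the CV $= s/\bar x$ is computed
across **all** cells, zeros included, using the sample ($n-1$) standard
deviation. Two deliberate choices:

* *Zeros included*: dropout zeros are part of the cell-to-cell variability
  being measured; excluding them would collapse CV into a function of the
  positive cells only and conflate it with $N$.
* *Sample SD*: the convention is documented because the exact identity used
  in our tests depends on it — a gene with a single positive cell among $C$
  has CV exactly $\sqrt C$ under the $n-1$ convention. Population-SD users
  would see $\sqrt{C-1}$.

Genes are stratified by maximum FPKM into moderate $(3, 30]$ and high
$(>30)$ strata, and the four biotype-by-stratum groups are compared with
all six pairwise Welch's t-tests (unequal variances,
Welch–Satterthwaite degrees of freedom, two-sided p-values, no
multiple-testing correction — the raw p-values are reported).

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `exprThreshold` | 3 | FPKM | positivity cutoff defining $N$; strict inequality |
| `windowLow`, `windowHigh` | 3, 30 | FPKM | moderate-expression window on the per-gene maximum; $(low, high]$ |
| `posteriorCutoff` | 0.99 | probability | strict cutoff for H/L flags; between 0.5 and 1 |
| `emTolerance` | 1e-8 | relative | EM stops when the relative log-likelihood change falls below this |
| `emMaxIter` | 1000 | iterations | safety budget; non-convergence is reported, not hidden |
| `init` | "quartile" | — | deterministic mean initialisation (see below) |

# Numerical choices

**EM initialisation.** Weights start at 0.5/0.5 and both standard
deviations at 0.5. The starting means are the 25th and 75th percentiles of
the data (`init = "quartile"`), making the default fit fully deterministic;
`init = "random"` draws starting means from the data under a seed,
reproducing stochastic-restart behaviour. On well-separated bimodal data
both routes converge to the same optimum (tested against a multi-restart
reference EM and against a dense grid search on small instances).

**Degeneracy guards.** A variance floor of $10^{-6}$ and a component-weight
floor of $1/n$ are enforced during EM. Hitting either raises a
non-convergence error with diagnostics rather than returning a spike
solution — a silent $\sigma \to 0$ "fit" around a repeated value would
otherwise produce an arbitrarily high likelihood and meaningless posteriors.
Inputs with fewer than 10 points or fewer than 2 distinct values are
rejected up front.

**E-step in log space.** Responsibilities and the log-likelihood are
computed via log-densities with max-subtraction, so extreme separations do
not underflow; the log-likelihood trace is recorded and is non-decreasing on
every run (asserted in the tests).

**Flag boundaries in floating point.** The L rule is evaluated as
$(1 - p) > 0.99$, not $p < 1 - 0.99$: the two are equivalent in exact
arithmetic but differ at the representable boundary (binary `1 - 0.99` is
slightly above 0.01), and the complementary-posterior form keeps a posterior
of exactly 0.01 in the U class, symmetric with 0.99.

**Coordinates.** Gene models are held as `GRanges`/`IRanges`, i.e. 1-based
closed intervals — the native Bioconductor convention, matching GTF input
directly. All interval arithmetic (union-exon merging, overlap queries,
antisense intersections) goes through `GenomicRanges`, so no hand-rolled
interval code exists to get a convention wrong. BED export converts to
0-based half-open at the output boundary, the only place a conversion
occurs.

**FPKM.** Computed as count × 10⁹ / (union-exon length × library size) in
double precision throughout (integer inputs are promoted before the product,
which would overflow 32-bit integers). The union-exon length counts every
exonic base once across all isoforms. TSV outputs print 6 significant
digits.

**Antisense bounds.** For a gene overlapped by an opposite-strand gene in
non-strand-specific data, the under/over FPKM bounds exclude/include reads
in the shared exonic region. Both bounds divide by the *full* union-exon
length of the target gene, so the underestimate is a true lower bound under
the fixed gene model (dividing the exclusive count by the exclusive length
would instead estimate a local density, which can exceed the true FPKM).
Only exonic intersections count as ambiguous; the partition geometry is
exportable as BED so that an external counter can produce the two counts —
the package deliberately consumes counts and never parses alignments.

**Biotype rules.** Coding evidence is the RefSeq prefix set NM_/XM_/NP_/XP_;
noncoding evidence is NR_/XR_ or a lincRNA annotation. The read-through
rule — a noncoding-evidenced gene that could be the 3' continuation of a
coding transcript must not contaminate the lncRNA set — is operationalised
as *any same-strand exonic overlap with a coding-evidenced gene* (the
partner gene is recorded in the audit reason), plus the case of a single
gene id carrying both coding and noncoding transcripts. This is
deliberately conservative: it misclassifies some genuine lncRNAs as coding
rather than the reverse. Genes with neither kind of evidence are *excluded*
from both comparison sets rather than guessed. The `>200 nt` union-length
filter is strict (a 200 nt gene is removed).

**ORF conventions.** An ORF runs from ATG to the first in-frame stop on the
sense strand, stop codon *included* in the length (so lengths are multiples
of 3, minimum 6 nt); `includeStop = FALSE` gives the alternative
convention. Codons containing N never match. The by-chance null draws
i.i.d. sequences from a base composition by default — the simplest model of
"a transcript of this length and composition" — with a
dinucleotide-preserving Eulerian shuffle (`dinucShuffle()`) as the stricter
alternative that also preserves CpG content. Empirical p-values carry the
+1 correction $(1 + k)/(R + 1)$ and therefore never return 0.

# The synthetic-data generator

`simulateMatrix()` emulates the data regime the classifier is designed for:

* a gene × cell FPKM matrix with exact zeros in non-expressing cells
  (dropout); optionally sub-threshold uniform noise in $(0, 3)$ to stress
  the strict positivity boundary;
* genes labelled lncRNA or mRNA, with per-biotype planted probabilities of
  the high-heterogeneity class — defaults 0.74 and 0.35;
* $N$ drawn per gene from class-specific Gaussians (rounded, clamped to
  $[1, C]$), defaults centred at 5% of cells (high class) and 75% (low
  class), well separated at all dataset sizes used in validation
  (24–96 cells);
* positive-cell magnitudes from truncated log-normals, with a bright regime
  (default 20% of genes) whose maxima exceed 30 FPKM, so both window
  boundaries are exercised; bright genes are expressed in more cells and
  are less often high-heterogeneity (`brightHighScale`), reflecting the
  abundance–breadth coupling of real single-cell data.

The generator records the full truth table (class, regime, $N$, positive
cell identities) in `rowData`, and the emitted matrix is exactly consistent
with it: recomputing $N$ from the matrix at threshold 3 reproduces the
planted $N$, including after a 6-significant-digit TSV round trip
(magnitudes are truncated at 3.01, not 3, for this reason).

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: library-size variation and count noise
(magnitudes are drawn directly in FPKM), gene–gene correlation, cell
subpopulation structure, batch effects, skewed or overdispersed $N$
distributions (the classes are Gaussian by construction, so the mixture
model is well specified in the base tests), and transcript-level
complexities such as isoform switching. Recovery of the planted fractions
shows the pipeline is correct under its own model; it does not show the
two-component Gaussian is the right model for any particular real dataset.

# Validation problem sizes

The shipped tests and the acceptance script use: mixture recovery on 2000
points over 20 seeds; EM monotonicity over 100 seeded runs; grid-search
comparisons on instances of at most 50 points; end-to-end recovery on the
planted regime of 96 cells and 2000 genes per biotype; CV identities for
2 to 200 cells; Welch calibration over 1000 null replicates; ORF scanning
against brute-force enumeration on 1000 sequences of 50–5000 nt; and 1000
random antisense geometries for the under/over bounds. These sizes give
tight Monte-Carlo error on every recovered quantity while keeping a full
run in a few minutes.

# Known limitations

* The two-component assumption is fixed: datasets whose $N$ distribution is
  unimodal, or has more than two modes, will still be forced into two
  components; inspect the fitted model (`mixtureModel()`) and its
  separation before trusting flags.
* Flags near the window boundaries inherit the boundary conventions;
  genes with maxima hovering around 3 or 30 FPKM can enter or leave the
  window under measurement noise upstream of this package.
* The read-through rule cannot distinguish a genuine independent lncRNA that
  happens to overlap a coding gene on the same strand from actual
  read-through; such genes are conservatively called coding.
* The CV comparison reports raw Welch p-values; with four groups and six
  pairwise tests, adjust externally if your use demands it.
* `runPipeline()` provides TSV/JSON artefacts sufficient to redraw the
  standard figures (density fits, pie fractions, box plots) but does no
  plotting itself.
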
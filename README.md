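# discChIP

Tissue-context analysis of transcription-factor ChIP binding events.

## The problem

When the same transcription factor is ChIP-profiled in two tissues —
here the wing (W) and eye-antenna (EA) imaginal discs of *Drosophila*,
for the Hippo-pathway regulators Scalloped (Sd), Homothorax (Hth) and
the coactivator Yorkie (Yki) — naive peak-list comparison miscalls
events that fell just under the significance cutoff in one tissue as
"tissue-specific". `discChIP` implements the dual
false-discovery-rate threshold rule that avoids this, and the battery
of analyses used to characterize the resulting binding classes.

A stringent (1% FDR) peak in the home tissue is called

- **SPECIFIC** (W>EA or EA>W) if it overlaps *no* permissive (25% FDR)
  peak of the other tissue;
- **SHARED** (EA≈W) if it overlaps at least one.

Downstream, each class is characterized by:

- binned hypergeometric co-occurrence between interval sets
  (`N` genome bins, `n` hit by A, `K` hit by B, `k` hit by both:
  expected `nK/N`, `p = P(X ≥ k)`, `X ~ Hypergeom(N, K, n)`);
- genomic-region breakdown at peak centers (promoter = 1 kb upstream
  of a TSS; precedence PROMOTER > EXON > INTRON > INTERGENIC);
- target-gene logic classes (SHARED_ONLY / SHARED_PLUS_SPECIFIC /
  SPECIFIC_ONLY) and hypergeometric gene-set enrichment with BH
  correction;
- IUPAC consensus and spaced-dimer motif scanning (e.g. `GGAATG`,
  `TGAY{N0-2}TGAY`), per-chromatin-state containment fractions with
  Fisher exact contrasts, and Centrimo-style central enrichment
  (binomial tail; E-value = p × motif-library size, E ≤ 10
  significant);
- conservation profiles (±500 bp around peak centers),
  ultraconserved-element overlap (≥50 bp perfect-identity runs), and
  enrichment across the five-state chromatin segmentation
  (YELLOW/RED active, BLUE Polycomb, GREEN/BLACK silent);
- enhancer-catalog overlap with per-tissue activity fractions and
  unique-CRM merging.

A seeded synthetic-data generator (`generateBundle()`) produces every
input the pipeline consumes together with a ground-truth manifest, so
the whole analysis is testable against known truth; `runAll()`
orchestrates the full pipeline deterministically.

## Worked example

```r
library(discChIP)
library(GenomicRanges)

a <- DualTierPeaks("Sd", "W",
  fdr1  = GRanges("chr2L", IRanges(c(101, 1001), c(300, 1200))),
  fdr25 = GRanges("chr2L", IRanges(c(81, 981), c(320, 1220))))
b <- DualTierPeaks("Sd", "EA",
  fdr1  = GRanges("chr2L", IRanges(151, 350)),
  fdr25 = GRanges("chr2L", IRanges(131, 370)))
calls <- classifySpecificity(a, b)
specificityCounts(calls)
#>    factorName tissue shared specific total
#> W          Sd      W      1        1     2
#> EA         Sd     EA      1        0     1
```

The first wing peak overlaps the eye-antenna permissive call and is
shared; the second has no permissive support in the eye-antenna and is
wing-specific. On a synthetic bundle the full pipeline runs as:

```r
cfg <- generatorConfig(seed = 1)          # "fig-mimic" study conditions
generateBundle(cfg, "bundle")
rep <- runAll(bundleRunConfig("bundle", outDir = "out"))
rep$classify
#>   factorName tissue shared specific total
#> 1         Sd      W   1500     2000  3500
#> 2         Sd     EA   1500      150  1650
#> ...
```

i.e. the wing-rich asymmetry (2000 wing-specific vs 150
eye-antenna-specific events per sequence-specific factor) is recovered
exactly, along with the planted promoter share of shared events, the
BLUE-chromatin bias of specific events, the BLUE-vs-YELLOW motif-rate
contrast and the conservation elevation at specific peaks. Stage
outputs land in `out/` as TSVs plus `report.json`.

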
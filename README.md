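# epirhythm

Circadian rhythm detection and attribution analysis for intestinal
epithelial time-course omics, in R.

Gene expression in the gut epithelium oscillates over the 24-h day, and
those oscillations depend on upstream drivers: the commensal microbiota
(compare conventionally raised vs germ-free animals) and the histone
deacetylase HDAC3 (compare wild type vs an epithelium-specific
knockout). `epirhythm` implements the complete analysis such a study
needs, exercisable end to end on synthetic data with known ground truth:

* **Rhythm detection** — a from-scratch nonparametric scan that
  correlates each gene's temporal ranks with cosine reference waveforms
  over an 18–30 h period window via Kendall's S, using the *exact*
  Jonckheere–Terpstra null distribution for the reference's tie groups
  (computed by generating-function convolution, verified against full
  permutation enumeration). Per gene it reports the Bonferroni-adjusted
  p (adjusted by the number of rank-distinct references), BH q, best
  period and peak phase (lag), cosinor amplitude, relative amplitude
  amp/max and Kendall tau.
* **Cross-condition comparison** — shared/condition-only classification,
  the two-level A/B/C attribution funnel (A: microbiota-driven, B:
  microbiota + HDAC3, C: HDAC3-driven), signed phase differences wrapped
  into (−period/2, period/2], amplitude t-tests, elbow-selected K-means
  temporal clustering, and up/down splits between genotypes.
* **Promoter acetylation** — H3K9ac read counting in strand-oriented
  −1500..+500 TSS windows (any-overlap rule, per-million scaling),
  relative amplitude (max − min)/max, and the 0.466 amplitude cutoff
  split.
* **Enrichment** — Fisher-exact motif enrichment on the classical
  x1/x2/z1/z2 counts in −900..+100 promoter windows (with an optional
  PWM scanner at likelihood ratio > 500), hypergeometric gene-set
  over-representation on GMT collections, and Cohen's-kappa term
  networks (edges at kappa ≥ 0.4, functional groups = connected
  components).
* **Synthetic data** — generators for multi-condition cosine rhythms
  with controlled relative amplitude, phase shifts and noise, rhythmic
  promoter read pileups, planted motif maps and blocked gene-set
  collections, each a pure function of its seed.

## The statistic at the core

For reference ranks with tie groups of sizes n₁..n_g over N samples, the
scan uses S = (concordant − discordant) pairs among the M reference-untied
pairs, M = (N² − Σnᵢ²)/2. Under the null every ordering is equally
likely and the number of orderings with j cross-group inversions has
generating function ∏ᵢ [Nᵢ; nᵢ]_q (Gaussian multinomial), giving the
exact pmf of S = M − 2j. The per-gene p-value is
min(1, R · min_r P(|S| ≥ |s_r|)) over the R rank-distinct references;
amplitude is the cosine coefficient of the least-squares fit at the best
(period, lag), and relative amplitude divides by the series maximum.

## Worked example

```r
library(epirhythm)

spec <- sim_spec(n_genes = 300, conditions = c("CV", "GF"),
  blocks = list(
    list(name = "shared", n = 60, rhythmic_in = c("CV", "GF"),
         phase_shift = c(GF = 3)),              # delayed 3 h germ-free
    list(name = "CVonly", n = 40, rhythmic_in = "CV")),
  seed = 11)
sim <- simulate_expression(spec)

scan_cv <- jtk_scan(sim$matrices$CV)
scan_cv
#> Circadian rhythm scan (exact Jonckheere-Terpstra/Kendall null)
#>   300 genes, 16 samples, 33 reference waveforms
#>   rhythmic at Bonferroni p <= 0.05: 104 genes

head(as.data.frame(scan_cv), 3)
#>             gene_id        p_adj            q period  lag       tau      amp  max_expr   rel_amp rhythmic
#> gene00001 gene00001 2.651317e-05 0.0002410288     24  3.0 0.9200000 2.138630  7.999756 0.2673369     TRUE
#> gene00002 gene00002 1.046572e-05 0.0001427144     21 19.5 0.9782609 4.487585 15.662169 0.2865239     TRUE
#> gene00003 gene00003 2.909471e-04 0.0013224870     24  6.0 0.8600000 0.915851  2.944189 0.3110708     TRUE

pair <- classify_pair(scan_cv, jtk_scan(sim$matrices$GF),
                      name_a = "CV", name_b = "GF")
attr(pair, "counts")
#>   onlyA  shared   onlyB neither
#>      44      60       4     192

d <- phase_amp_diff(jtk_scan(sim$matrices$GF), scan_cv)
median(d$phase_diff[d$both_rhythmic])
#> [1] 3
```

Of 300 genes the scan calls 104 rhythmic: essentially the 100 planted
(60 shared + 40 CV-only) plus a few borderline calls. The pair
classification recovers the planted split (60 shared, 44 ≈ 40 CV-only),
and the median wrapped phase difference recovers the planted +3 h
germ-free delay exactly. `funnel_groups()` extends this to the
four-condition A/B/C attribution; `run_pipeline(pipeline_config(seed = 7,
outdir = "out"))` wires every stage — scans, funnel, clustering, promoter
signal, motif and gene-set enrichment — into one deterministic run whose
TSVs are stamped with a config hash.

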
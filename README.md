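# siteMarks

Analysis of ChIP-seq histone-mark tag patterns around transcription factor
binding sites (TFBSs), for epigenomics researchers who have mark and input
control tag libraries (BED), a site map (footprint point sites or peak
centres), and a gene annotation, and want to know **which marks are
enriched at which sites, over what distance range, with what aggregate
shape, and in which combinations**.

## The method

* **Enrichment calls.** The tag count `X` in a window `w` centred on a site
  is modelled as Poisson with a *dynamic local* rate

  `λ_local = max(λ_BG, λ_1k, λ_5k, λ_10k)`,

  where `λ_BG = N·w/G` is the uniform-scatter expectation of the control
  library and `λ_L` rescales the control count in an `L`-bp region centred
  on the site to the scoring window (regions truncated at chromosome ends
  are rescaled by their effective length).  A site is enriched iff
  `X > t`, with `t` the smallest integer such that
  `P(X > t) < α` (default `α = 1e-4`).  Repeating the call over a window
  grid yields the enrichment-proportion curve that separates short-range
  from long-range marks.
* **Aggregate profiles.** Control-subtracted per-position averages around
  sites, mirrored for sites assigned to minus-strand genes so that
  transcription-coupled asymmetry is not averaged away, smoothed with a
  200-bp moving window, and summarised into modes (bimodal/unimodal),
  inter-peak distance, asymmetry index and minimum location (NFR).
* **Stratification.** Proximal (≤ 1 kb to the nearest TSS of the
  representative, highest-RPKM transcript per gene) versus distal
  (> 10 kb) sites; activator versus repressor TFs (dual-annotated TFs
  excluded).  One-sided exact binomial tests against a decoy-site
  background and paired Wilcoxon signed-rank tests compare groups.
* **Correlation.** Spearman coefficients between marks over non-overlapping
  600-bp genome bins (5'-end counting) and over per-site window counts.
* **Synthetic data.** A seeded generator plants peaks (offsets, widths,
  fold-enrichment, orientation, NFRs) on Poisson backgrounds with a matched
  control and returns the ground truth, so every analysis step is testable
  end-to-end.

## Worked example

```r
library(siteMarks)

sim  <- simulateDataset(syntheticPreset("short_range_bimodal", seed = 1))
mark <- shiftTags(sim$tags[[1]], sim$chromSizes)
ctrl <- shiftTags(sim$control, sim$chromSizes, source = "control")
mark
#> TagIndex [mark]: 70365 events on 2 chromosome(s), 0 clamped

calls <- callEnrichment(mark, sim$sites, ctrl, window = 600)
head(calls, 3)
#>       site_id window observed lambda_local threshold enriched   tf
#> 1 site_000001    600       98         8.76        22     TRUE TF01
#> 2 site_000002    600        6         8.40        21    FALSE TF01
#> 3 site_000003    600       97         6.00        17     TRUE TF01

prof <- smoothProfile(netSignalProfile(mark, sim$sites, ctrl,
                                       flank = 2000), 200)
detectShape(prof)
#> ProfileShape: 2 mode(s) at {-205, 200}, inter-peak 405 bp, asymmetry 0.017, min at -1795 bp

enrichmentCurve(mark, sim$sites, ctrl, windows = c(200, 600, 1000, 2000))
#>   window group n_sites n_enriched proportion
#> 1    200   all    1000        430      0.430
#> 2    600   all    1000        869      0.869
#> 3   1000   all    1000        902      0.902
#> 4   2000   all    1000        950      0.950
```

Reading the output: site 1 has 98 tags in its 600-bp window against a
local expectation of 8.8 and a threshold of 22, hence enriched; the
aggregate profile has two modes at ±~200 bp — the flanking-nucleosome
signature planted by the preset — with near-zero asymmetry; and the
proportion of enriched sites rises steeply up to a 600-bp window and then
flattens, the short-range behaviour.  The slow residual climb past 600 bp
is a site-density effect (windows of several kb start to overlap
neighbouring sites at the default simulated density).

`runPipeline(config, outDir)` orchestrates
simulate → enrich → stratify → profile → correlate from a nested list or
YAML config and writes result tables plus a JSON manifest; see
`?runPipeline` and the methods vignette (`vignettes/siteMarks-methods.Rmd`).

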
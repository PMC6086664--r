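# CytoQuant

Cytonemes are signaling filopodia: thin actin-based membrane protrusions
that carry ligands such as Wnt8a at their tips and hand them to receiving
cells by direct contact. Quantifying them — how many a cell forms, how
long they are, how their frequency shapes the ligand gradient in a
target tissue, and how ligand and receptor co-diffuse in the membrane —
requires three different kinds of computation. CytoQuant provides all
three as one R package for cell biologists and image analysts:

* **Filopodia detection and tracing** — an automated pipeline for
  single-cell membrane-marker images: Gaussian smoothing, a
  Hessian-eigenvalue objectness (vesselness-family) filter that enhances
  thin bright ridges, local adaptive thresholding, morphological
  cleanup, skeleton-endpoint tip detection and livewire (shortest-path)
  tracing of each tip back to the cell body, in 2D automatically and in
  3D semi-automatically via an axial maximum-intensity projection plus a
  dynamic-programming plane assignment. Per-cell outputs are filopodium
  count, mean and cumulative length in micrometres.
* **Cytoneme transport simulation** — a Monte-Carlo direct-event model
  of ligand dissemination through a growing 2D tissue: producer cells on
  the margin of a hexagonal cell lattice form virtual cytonemes with a
  per-second probability, deposit a ligand unit when the tip lands
  within ±2 µm of a receiving cell's surface, while the receiving
  tissue grows by cell insertion, mixes by neighbour swapping and loses
  ligand by decay. The key model statement: modulating only the
  cytoneme formation frequency (wild type 1/30 s⁻¹, enhanced receptor
  activity ×1.61, kinase-dead receptor ×0.338) rescales the total
  ligand delivered to the tissue and the range of the resulting
  morphogen gradient.
* **Line-scan FCS (lsFCS)** — membrane-trace extraction from x–t
  pseudo images, multi-tau auto/cross-correlation, and fitting of the
  one-component 2D membrane diffusion model
  `G(τ) = G₀ (1 + τ/τ_D)^(-1/2) (1 + τ/(S² τ_D))^(-1/2)`
  with `D = w₀²/(4 τ_D)` and area density `C = 1/(G₀ π w₀² S)`;
  dual-colour cross-correlation amplitudes report ligand–receptor
  binding.

Every component has a synthetic ground-truth generator
(`makeCellImage()`, `makeCellStack()`, `simulateLsfcs()`,
`makeScreenTable()`), so the whole package is testable without any
external dataset. See the methods vignette
(`vignettes/cytoquant-methods.Rmd`) for models, parameters and design
choices.

## Worked example

Render a synthetic cell with five filopodia of known lengths, run the
detection pipeline, and compare:

```r
library(CytoQuant)

spec <- syntheticCellSpec(
  filopodia = data.frame(angle = c(0.3, 1.5, 2.8, 4.0, 5.3),
                         lengthPx = c(20, 30, 40, 25, 35),
                         widthPx = 2, intensity = 0.9),
  noiseSd = 0.02, seed = 7)
res <- makeCellImage(spec)          # image + ground truth
out <- analyzeCell(res$image)
out$seg
#> CellSegmentation: body 5256 px, combined 5713 px, 5 candidate tip(s)
cellMetrics(out$traces)
#>   count meanLengthUm cumLengthUm hasFilopodia
#> 1     5     5.891634    29.45817         TRUE
sort(res$truth$lengthUm)            # true lengths, um
#> [1] 4 5 6 7 8
```

All five filopodia are found and each traced length is within 2 px /
10% of its rendered truth. A kinase screen with planted hits is called
at the 85th percentile of both relative filopodia number and length
(inclusive rule, so a candidate sitting exactly on a threshold counts):

```r
scr <- makeScreenTable(nGenes = 229, nHits = 5, seed = 1)
hits <- screenHits(scr$records, percentile = 85)
round(hits$thresholds, 3)
#> percentile     number     length
#>     85.000      1.189      1.177
all(scr$records$gene[scr$truth] %in% hits$hits$gene)   # TRUE
```

A transport simulation under the wild-type preset (30 simulated
minutes shown here; the full protocol runs 180):

```r
sim <- runSimulation(simPreset("wt", seed = 1L, durationMin = 30))
sim$tissue
#> Tissue: 4464 lattice positions, 62 producer(s), 4402 receiver(s), step 1800
#>   morphogen: total 2946 (deposited 1625, duplicated 1434, decayed 113)
head(sim$profile, 4)
#>   binCenter  meanWnt nCells
#> 1      12.5 6.419355     62
#> 2      37.5 5.846774    124
#> 3      62.5 4.032258    124
#> 4      87.5 3.040323    124
```

The ledger (`deposited + duplicated - decayed`) balances the receiver
total exactly at every step, and the mean ligand content falls with
distance from the producer margin — the morphogen gradient.

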
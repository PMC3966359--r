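# msfcm

Multistage superpixel and fuzzy C-means segmentation of 2-D brain MRI
slices into cerebrospinal fluid (CSF), gray matter and white matter.

Pixel-level fuzzy C-means (FCM) classifies each pixel by its intensity
alone, so acquisition noise and slowly varying intensity inhomogeneity
(the bias field) translate directly into misclassification. `msfcm`
classifies *superpixels* instead: compact atomic regions whose mean
intensity averages the noise away and whose small spatial extent confines
the bias field to a regional offset that a neighbourhood-similarity rule
can absorb.

The pipeline:

1. **Rough segmentation** — turbopixel-style seeded narrow-band level-set
   evolution (`Ψ ← Ψ + S_I S_B ‖∇Ψ‖ Δt`) grows `L` compact superpixels
   whose fronts slow near edges (affinity `φ = exp(−E/ν)`,
   `E = ‖∇I‖ / (G_σ∗‖∇I‖ + γ)`) and freeze where regions meet.
2. **Deep segmentation** — high-variance superpixels are split at the
   exhaustive Otsu threshold; connected components above an area fraction
   `t` of the parent become regions, smaller ones are re-absorbed.
3. **Fuzzy clustering** — FCM over superpixel mean intensities,
   `u_ik ∝ (1/d_ik²)^{1/(p−1)}`, `v_i = Σ u_ik^p y_k / Σ u_ik^p`, c = 3.
4. **Broadcast labeling** — regions with confident membership
   (`max U_i > T_c`) are labelled directly; the rest iteratively adopt the
   class of their most similar labelled neighbour under the Butterworth
   similarity `S = 1 / (1 + (Δμ/η)^n)` when `S > T_s`.
5. **Merging** — adjacent same-class regions merge into the per-pixel
   class map.

The package also ships a BrainWeb-style phantom generator (three-tissue
anatomy with seeded geometry, percent-quoted Gaussian noise and a smooth
multiplicative bias field) and a Jaccard evaluation harness comparing the
multistage method against pixel-level FCM, so the whole method is testable
without downloading any data.

## Worked example

```r
library(msfcm)

pair <- make_phantom(phantom_spec(size = c(128, 128), noise_pct = 7,
                                  bias_pct = 20))
res <- msfcm_segment(pair$image, msfcm_config(), seed = 1)
print(res)
#> <msfcm_result> 64 rough -> 158 deep superpixels, FCM centers 65.9/130.8/195.6
#> <tissue_segmentation> 128 x 128, 6 merged components
#>
#> background        csf       gray      white
#>       6427       2880       3644       3433

round(evaluate_segmentation(res$segmentation$class_map, pair$truth), 3)
#>   csf   gry   wht
#> 0.977 0.983 0.991
```

The printout reads: 64 rough superpixels were refined into 158 atomic
regions by deep segmentation; the three FCM cluster centers (65.9, 130.8,
195.6) recovered the tissue means (64/128/192) despite 7% noise and a 20%
bias field; merging produced 6 connected tissue components; and the
per-class Jaccard overlap with ground truth is 0.97–0.99.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/msfcm phantom --size 128 --noise 7 --bias 20 --out-image ph.png --out-truth tr.png
Rscript inst/cli/msfcm segment --input ph.png --out seg.png --provenance prov.json
Rscript inst/cli/msfcm evaluate --size 128 --n-images 5 --out-csv report.csv
```

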
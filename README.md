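# renovasc

Quantification of kidney microvascular architecture and perfusion in 3D,
aimed at cystic kidney disease research. In autosomal dominant polycystic
kidney disease (ADPKD), epithelial cysts progressively displace kidney
parenchyma and the surrounding microvasculature — cortical peritubular
capillaries and medullary vasa recta — remodels around them. renovasc
implements the measurement chain needed to put numbers on that
remodeling, for imaging scientists working with cleared-tissue
fluorescence z-stacks and preclinical ASL MRI:

* **Segmentation** — rolling-ball background subtraction, 3D Gaussian
  smoothing, Hessian tubeness, mean/Li thresholding, morphological mask
  cleanup; cyst segmentation by hole-filling with half-maximum boundary
  refinement; cyst number/volume/fraction statistics.
* **Vessel graphs** — topology-preserving 3D thinning, junction-cluster
  merging, per-branch length (um) and radius (um, via Euclidean distance
  transform), branch density per mm^3, twig pruning.
* **Fractal measures** — box-counting fractal dimension, gliding-box
  lacunarity `var(m)/mean(m)^2 + 1`, geodesic (mass-radius) connectivity
  dimension along the skeleton.
* **Topology** — Vietoris-Rips persistent homology of the branch
  endpoint cloud (own boundary-matrix reduction, validated against a
  brute-force oracle): Betti 1, persistence entropy, average lifetime,
  plus the exact graph cycle rank `E - V + C`.
* **ASL perfusion** — voxel-wise inversion-recovery fitting of
  `M_C(TI) = M0 (1 - 2^(-TI/T1))`, perfusion-weighted signal
  `dM = mean(label) - mean(control)`, renal blood flow via the FAIR
  kinetic model `RBF = lambda * dM / (2 M0 TI exp(-TI/T1)) * 6e6`
  (ml/min/100 g), and ROI summaries (cortex, medulla, cyst-free cortex).
* **Phantoms** — synthetic vessel networks, ring-loop phantoms, cyst
  phantoms and ASL series with analytic ground truth, so the entire
  chain is testable without external data.
* **Reporting** — group comparisons (Student's t-test / ANOVA + Tukey,
  with Shapiro-Wilk and Brown-Forsythe QC), and `run_pipeline()` for
  phantom-group studies with full provenance.

## Worked example

Generate a vessel phantom with three anastomoses, push it through the
pipeline, and compare the recovered graph against the constructed truth:

```r
library(renovasc)

spec <- vessel_phantom_spec(shape = c(96, 96, 96), n_trees = 1,
                            n_branches_per_tree = 10, n_extra_loops = 3,
                            seed = 7)
ph   <- generate_vessel_phantom(spec)
ph$truth$mask
#> <binary_mask> 96 x 96 x 96 voxels, spacing (1, 1, 1) um, 19508 foreground (2.20%)

sk    <- skeletonize(ph$truth$mask)
graph <- prune_graph(extract_graph(sk, ph$truth$mask), 5)
graph
#> <vessel_graph> 8 nodes, 10 branches, total length 629.6 um, cycle rank 3

fr <- fractal_report(ph$truth$mask, skeleton = sk)
round(c(fractal = fr$fractal_dimension, lacunarity = fr$lacunarity,
        connectivity = fr$connectivity_dimension), 2)
#>      fractal   lacunarity connectivity
#>         1.86        16.68         1.02
```

The cycle rank of the re-extracted graph equals the three constructed
anastomoses exactly. The fractal dimension near 2 and high lacunarity
are what a sparse tubular network in a mostly empty volume should give.

For persistent-homology loop counting, the ring phantom gives holes of
controlled size that the endpoint diagram can resolve:

```r
lp <- generate_loop_phantom(3, seed = 13, jitter_um = 0.5)
sk2 <- skeletonize(lp$truth$mask)
tp <- topology_report(prune_graph(extract_graph(sk2, lp$truth$mask), 5))
c(cycle_rank = tp$cycle_rank, betti1_filtered = tp$betti1_filtered)
#>      cycle_rank betti1_filtered
#>               3               3
```

ASL quantification on a simulated series (true RBF 600 in cortex, 450 in
medulla, ml/min/100 g):

```r
TI <- c(30, 50, 100, 150, 200, 300, 500, 1000, 1500, 2500, 5000, 8000)
cortex <- array(FALSE, c(12, 12)); cortex[, 1:6] <- TRUE
rbf_true <- array(450, c(12, 12)); rbf_true[cortex] <- 600
ser <- generate_asl_series(array(1000, c(12, 12)), array(1500, c(12, 12)),
                           rbf_true, TI, noise_sd = 20, seed = 1)
fit <- fit_inversion_recovery(ser)
rbf <- rbf_map(perfusion_weighted_signal(ser), fit$M0, fit$T1_ms,
               ser$TI_label_ms)
roi_summary(rbf, list(cortex = cortex, medulla = !cortex))
#>       roi     mean       sd n_voxels n_excluded
#> 1  cortex 598.5308 67.60816       72          0
#> 2 medulla 448.3886 67.24326       72          0
```

The recovered ROI means sit within a few percent of the simulated truth
and preserve the cortex-above-medulla ordering.

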
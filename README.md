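# smlmq

Quantitative analysis of **labeling quality** in single-molecule
localization microscopy (dSTORM/PALM), for microscopists comparing probe
strategies — nanobodies, SNAP tags, antibodies, fluorescent proteins — on
the axes that actually determine image quality: localization precision,
labeling coverage, linkage error, completeness of labeling, and molecular
mobility.

## What it computes

**Post-processing** (shared by every imaging experiment)

* fiducial-bead drift correction (`detect_fiducials`, `estimate_drift`,
  `correct_drift`)
* NeNA localization precision from consecutive-frame nearest-neighbor
  distances, fitted with the same-molecule model
  p(d) = d/(2σ²)·exp(−d²/(4σ²)) plus background (`estimate_nena`)
* blink merging within the NeNA radius (`merge_blinks`)
* 10-nm histogram reconstruction with mass-conserving Gaussian blur
  (`reconstruct_image`)
* FIRE resolution: Fourier ring correlation between frame-parity halves,
  read at the fixed 1/7 threshold (`fire_resolution`)

**Filament morphometry** — straightened intensity profiles fitted with a
Gaussian; FWHM = 2.35·σ·pixel; lengthwise coverage of the middle 3 strip
pixels after binarization; 0.5-px wobble averaging; thin/medium/thick
width categories ([0,75), [75,150), [150,∞) nm) with a chi-square
homogeneity test.

**Cluster quantification** — classical DBSCAN (written in-package,
oracle-verified), cluster size as mean distance to the center of mass,
degree of clustering, nanobody densities per µm² (ε = 40 nm, MinPts = 6)
and cluster statistics (ε = 50 nm, MinPts = 40).

**Stoichiometry / completeness of labeling** — single-fluorophore
log-normal calibration (µ = 5.68, σ = 0.4 in log AD counts) from blink
amplitudes; the fully-labeled reference intensity distribution of an
n = 24 homo-oligomer as the binomial mixture Σₖ P(k)·f*ᵏ of k-fold
convolutions (P(k) = C(n,k)pᵏ(1−p)ⁿ⁻ᵏ, k = 0 excluded and renormalized);
completeness = 100 · median(measured) / median(mixture), with bootstrap CI
and a degree-of-labeling sensitivity band.

**Single-particle mobility** — greedy nearest-neighbor track linking,
≥ 5-step filter, MSD-based apparent diffusion coefficient (lags 1–4),
immobile/mobile split at 0.02 µm² s⁻¹.

**Synthetic data** — ground-truth-annotated generators for blinking
emitters on filaments, the 25-nm microtubule benchmark, cluster fields,
fiducial beads under drift, per-oligomer intensity traces, and Brownian
membrane trajectories. All package estimators are validated by recovering
the generators' truth.

## Worked example

```r
library(smlmq)
line <- polyline(rbind(c(500, 2000), c(9500, 2000)))
sim <- sim_filament_field(list(line), width_nm = 75, coverage = 0.8,
                          label_density = 400, sigma_loc_nm = 10,
                          n_frames = 4000, seed = 1)
nena   <- estimate_nena(sim$table)
merged <- merge_blinks(sim$table, nena$sigma_loc_nm)
img    <- reconstruct_image(merged, pixel_nm = 10,
                            extent = c(0, 10000, 1600, 2400))
meas   <- wobble_measure(img, line, thickness_px = 15)
round(c(nena_nm = nena$sigma_loc_nm, width_nm = meas$width_nm,
        coverage = meas$coverage), 3)
#>  nena_nm width_nm coverage
#>   10.159   78.256    0.766
fire_resolution(sim$table)$resolution_nm
#> 36.6
```

The simulated filament has true width 75 nm, coverage 0.8 and 10-nm
localization precision. NeNA recovers the precision (10.16 nm); the
wobble-averaged FWHM is 78.3 nm, matching the convolution law
√(75² + (2.35·10)²) ≈ 78.6 nm; the measured coverage 0.77 reflects the
0.8 ground truth; the FIRE resolution of 36.6 nm sits in the range
expected for 10-nm precision data.

A thin CLI over the same functions is installed at `exec/smlmq`
(`smlmq simulate|drift|nena|merge|render|fire|clusters|stoich|track|pipeline`).

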
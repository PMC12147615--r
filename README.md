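# dtmkit

Measurement, reliability and agreement analysis for the wrist
**dart-throwing motion (DTM)** — the functional oblique wrist motion from
radial extension (extended + radially deviated) to ulnar flexion (flexed +
ulnarly deviated) that dominates hammering, pouring and most tool use.

The package is aimed at clinicians and movement scientists validating a
simple DTM-range instrument — a mallet with a mounted bubble inclinometer,
read to 5° at the two motion extremes — against optical motion capture as
the gold standard. It implements the full analysis chain:

* **Marker kinematics.** From seven dorsal markers (forearm plate m1–m3,
  metacarpal landmarks m4–m7) it builds right-handed orthonormal forearm
  and hand frames (forearm z proximal from m2 to m1, x dorsal normal to the
  m1–m3 plane; hand z proximal from m6 to m4, x dorsal normal to the
  m4/m5/m7 plane), decomposes the relative rotation `R = Fᵀ H` in an
  intrinsic y–x–z sequence into flexion–extension and radial–ulnar
  deviation, and summarises the motion path in wrist-angle space as a
  **DTM plane**: slope `atan(Δdev/Δfe)` relative to the sagittal
  flexion-extension plane, offset (flexion-extension angle at zero
  deviation, extension positive) and range (Euclidean distance between the
  two marked extremes).
* **Instrument scoring.** DTM range = radial-extension reading +
  ulnar-flexion reading (readings negative when the motion stays short of
  the horizontal), 5° quantization with ties away from zero, and trial
  averaging in acquisition order (first trial, mean of first two, mean of
  three).
* **Reliability.** Inter-rater **ICC(2,1)** (two-way random effects,
  absolute agreement, single measure) from the two-way ANOVA mean squares,
  with the McGraw–Wong F-based 95% CI and the poor (<0.50) / moderate
  (0.50–0.75) / good (>0.75) classification.
* **Agreement.** **Bland–Altman** analysis of instrument vs motion
  capture: mean difference with t-based 95% CI (fixed bias when the CI
  excludes 0), correlation γ of difference vs mean (proportional bias when
  significant), and 95% limits of agreement `bias ± 1.96·SD`, computed on
  the percent ratio `100·d/m` whenever a proportional bias is present.
* **Synthetic studies.** Seeded generators for marker trajectories
  (sinusoidal hammering along a configured DTM plane, optional marker
  noise) and complete two-rater × two-session × three-trial studies with
  participant, rater, session and trial variance components, a fixed +
  proportional instrument bias, and 5° quantization — so every stage is
  testable end to end with known ground truth.

## Worked example

```r
library(dtmkit)

# A simulated hammering recording: plane slope 30 deg, offset 25 deg,
# range 50 deg, no marker noise.
sim <- simulate_trajectory(trajectory_config(slope = 30, offset = 25, range = 50))
ang <- wrist_angle_trajectory(sim$markers, dorsal_reference = c(0, 0, 1))
ext <- mark_extreme_positions(ang, sim$events)
dtm_plane(ext$radial_extension, ext$ulnar_flexion)
#> <dtm_plane> slope 30.00 deg, offset 25.00 deg, range 50.00 deg

# A full two-rater study under the default calibrated conditions.
study <- simulate_study(study_config(seed = 7))
tables <- run_pipeline(study)
tables$reliability
#> # A tibble: 6 x 8
#>   scheme       side          icc ci_low ci_high label    n_subjects n_raters
#> 1 first        dominant    0.529  0.150   0.747 moderate         42        2
#> 2 first        nondominant 0.700  0.467   0.835 moderate         42        2
#> 3 first-second dominant    0.600  0.280   0.783 moderate         42        2
#> 4 first-second nondominant 0.714  0.436   0.852 moderate         42        2
#> 5 first-third  dominant    0.657  0.371   0.816 moderate         42        2
#> 6 first-third  nondominant 0.765  0.466   0.888 good             42        2
```

Reliability improves as more trials are averaged (trial noise shrinks by
1/k), and the agreement table for the same study reports a proportional
bias of ≈ 33–36% with percent limits of agreement — the instrument
over-reads the motion-capture range by a scale factor, because the mallet
axis and the third-metacarpal axis are not aligned in the hand.

`bland_altman()` can also be used directly:

```r
gold <- seq(40, 110, length.out = 42)
ba <- bland_altman(1.4375 * gold, gold)
ba$bias        # 35.897  (mean percent ratio 200(c-1)/(c+1) for c = 1.4375)
ba$bias_type   # "both"  (fixed + proportional; LOA on the percent scale)
```

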
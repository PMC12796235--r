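---
title: "Motion quantification and stationary-frame selection in MS-OPUS scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion quantification and stationary-frame selection in MS-OPUS scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msopus)
```

## The data model

A handheld multispectral optoacoustic-ultrasound (MS-OPUS) probe records two
interleaved, timestamped streams: ultrasound (US) images
$I_{US}^{(j)}$, $j = 1..N_{US}$, and single-wavelength optoacoustic (OA)
images $I_{OA}^{(k)}$, $k = 1..N_{OA}$, whose illumination wavelength cycles
through a preset $\Lambda$ ($N_\Lambda = |\Lambda|$, default 700–970 nm in
10 nm steps).  Any window of $N_\Lambda$ consecutive OA images is a
multispectral (MS) frame; a frame may start at *any* OA image, so
consecutive frames overlap in $N_\Lambda - 1$ images, there are
$N_{MS} = N_{OA} - N_\Lambda + 1$ frames, and the images within a frame are
sorted by ascending wavelength before any spectral analysis.  The US images
belonging to frame $k$ are those acquired inside its closed time span,
$s^{(k)} = \{\,i : t_{OA}^{(k)} \le t_{US}^{(i)} \le
t_{OA}^{(k+N_\Lambda-1)}\,\}$, compared in double precision without
tolerance.

`msopus` indexes everything 1-based, matching both R and the mathematical
notation above; there is deliberately no hidden 0-based layer, so a frame
index in a CSV, a JSON selection, or an R vector always means the same
thing.  Scans travel as HDF5 (images stored float32, as produced by
acquisition hardware; timestamps float64 seconds), and readers ignore
unknown datasets.  Frames with fewer than two corresponding US images are
legal but unscorable: they carry `NA`, never a silent zero, and are excluded
from selection and evaluation.  The wavelength preset is inferred from the
recorded per-image wavelengths, so a truncated file reinterprets its cycle
rather than erroring; validation still enforces strictly increasing
timestamps and exact periodic cycling.

## Motion score

The central assumption is that US images look alike when probe and tissue
are still, while OA images at different wavelengths may legitimately differ
(different absorbers light up), so motion must be read from the US stream.
For a dissimilarity measure $d$ the scan-wide banded matrix

$$D^d_{ij} = d\!\left(I_{US}^{(j)}, I_{US}^{(j+i)}\right),
\qquad i + j \le N_{US},$$

is computed for lags $i \le K = \max_k |s^{(k)}|$ — larger lags can never be
needed within one frame.  Each row (one lag) is normalized to $[0,1]$:

* **ranked** (recommended): 0-based ranks within the row, average rank on
  ties, divided by the maximal rank $N_{US} - i - 1$.  Ranks are computed
  over the *whole* row, scan-wide, not per frame: a pair is judged against
  every same-lag pair in the scan.  Only the ordering of pairs survives, so
  arbitrarily scaled measures combine and a single grossly dissimilar pair
  cannot compress the rest (it just occupies the top rank).
* **normalized**: row-wise min–max.  Kept as the documented alternative and
  as the contrast case: a property test shows it is *not* invariant under
  monotone transforms of the measure, while the ranked variant is.

Conventions where the mathematics is silent: a single-entry row ranks to 0;
a constant row ranks to 0.5 everywhere (the average-tie value) and min–max
normalizes to 0.  The 0-based rank convention is what makes the normalized
ranks land exactly in $[0,1]$.

The Motion score of a frame averages, over the measure set $\Delta$ and over
*every* pair of its US images,

$$m = \frac{2}{|\Delta|\,|s|^2} \sum_{d\in\Delta} \sum_{i=1}^{|s|}
      \sum_{j=s_1}^{s_{|s|-i}} M^d_{ij},$$

with $M = R^d$ or $N^d$ and empty inner ranges contributing 0, giving values
in $[0, (|s|-1)/|s|]$.  Including all lags is the point: under steady drift
the displacement between images grows with their time separation, so
high-lag pairs rank high and the frame scores high, whereas zero-mean jitter
of the same per-step magnitude produces similar displacements at every lag.
A consecutive-pair baseline (`naive_motion_vector()`) cannot make this
distinction; it is implemented exactly as conventionally written — the sum
of the $|s|-1$ consecutive dissimilarities divided by $|s|$, not $|s|-1$ —
so that published values of the baseline are reproduced rather than
"corrected".

### Dissimilarity measures

Four measures ship with the package; each is symmetric and minimal at
identical images, and the set is user-extensible via `as_measure()` (the
intended hook for, e.g., an optical-flow magnitude — no network weights are
shipped or required).

| name | definition | range |
|---|---|---|
| `l2` | $\lVert a-b\rVert_2$ over pixels | $[0,\infty)$ |
| `xcorr` | $-\tfrac1p\sum a\!\cdot\! b$ (unnormalized, zero displacement) | $(-\infty,\infty)$ |
| `znxc` | $1 - r$, Pearson $r$ of flattened pixels | $[0,2]$ |
| `ssim` | $1 -$ mean SSIM map | $[0,2]$ |

Similarities convert to dissimilarities as $d = 1 - s$ when normalized and
$d = -s$ for the unnormalized cross-correlation; any strictly monotone
variant leaves the ranked score unchanged, which is why the poor behavior
of unnormalized correlation is qualitative, not an artifact of sign
conventions.  SSIM uses the standard Gaussian window (size 11,
$\sigma = 1.5$), stabilizers $C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$ with the
dynamic range $L$ defaulting to the per-pair intensity range, and averages
the map over the valid (un-padded) interior.  Degenerate ZNXC cases carry no
correlation information and get neutral values: two constant images → 0,
exactly one constant → 1.  All comparisons are whole-frame at zero
displacement; no template search or subpixel registration is attempted.

## Frame selection

Stationary frames are strict local minima of the motion vector, found per
contiguous non-`NA` segment with segment endpoints excluded; a plateau of
equal values lower than both neighbors is represented by its midpoint
(floored) — a declared convention, since tie-handling inside a peak finder
is genuinely underdetermined.  Minima closer than `d_min` frames are thinned
by keeping lower-valued minima first (the behavior of the standard
distance-filtered peak finders; an in-package implementation was needed for
the plateau and `NA`-segment conventions, and is cross-checked against
`pracma::findpeaks` on plateau-free vectors).  Survivors are sorted by
ascending score, ties toward the earlier frame, and the best `n_peaks` are
returned.

The two hyperparameters and their defaults: `d_min = ⌊N_MS/20⌋` (clamped to
≥ 1) — separations below the number of US images per frame would return
overlapping stationary frames, much larger ones risk skipping genuine
holds — and `n_peaks = 5`.  Both should be adapted to the scanning protocol
(scan length, expected number of holds).

## Evaluation protocol

Human reference annotations are inclusive US-index intervals per annotator.
Summing across $A$ annotators scores each US image $0..A$; a frame receives
the mean score of its US images and counts stationary when that mean is at
least $A/2$ (1.5 for the conventional three annotators).  Maximal runs of
stationary frames are *target events*.  A prediction inside any event is a
true positive; `TP1` credits at most one prediction per event, so
`precision = TP/(TP+FP)` measures how many selected frames are usable while
`recall = TP1/(TP1+FN)` measures how many holds were found.  Average
precision integrates the precision–recall curve stepwise
($\sum_n (R_n - R_{n-1}) P_n$, no interpolation) while sweeping `n_peaks`
over the pool of distance-respecting minima — the only frames the selector
can ever emit, which makes AP a property of the score's ranking and hence
invariant under monotone transforms of the vector.  mAP averages AP over
scans; scans without events have undefined AP and are excluded with a
warning.

## Spectral quality

Under the linear mixing assumption each pixel spectrum is a non-negative
combination of component spectra: $C = \arg\min_{C\ge 0}
\lVert I_{MS} - C W\rVert_F$ with $I_{MS} \in \mathbb{R}^{p\times|\Lambda|}$
the frame's pixel-spectra matrix.  The Frobenius objective separates per
pixel; for $k \le 10$ components the package solves each pixel *exactly* by
enumerating all $2^k$ active sets with one vectorized QR solve per support
(deterministic, and orders of magnitude faster in R than a per-pixel
Lawson–Hanson loop, which remains both the fallback for larger $k$ and the
independent oracle in the tests).  Blind unmixing uses multiplicative-update
NMF (Frobenius objective, non-increasing by construction) from a
deterministic NNDSVD initialization whose structural zeros are filled with
small seeded uniform values; defaults `tol = 1e-6`, `max_iter = 1000`,
and the iteration trace is returned.  Negative OA intensities
(reconstruction artifacts) are clipped to zero for NMF only; the
least-squares path consumes them as-is.  Quality is summarized by the
relative L2,1 residual

$$E = \frac{\lVert (I_{MS} - CW)^T \rVert_{2,1}}
           {\lVert I_{MS}^T \rVert_{2,1}},$$

the fraction of spectral energy (sum of per-pixel spectrum norms) the model
cannot explain: 0 for perfect reconstruction, 1 for $C = 0$, undefined for
an all-zero frame.  Motion mixes neighboring spectra and inflates $E$, which
is the package's testable link between the Motion score and spectral
usability.

The bundled chromophore table
(`inst/extdata/chromophore_spectra_synthetic.csv`) contains *synthetic*
smooth curves reproducing the qualitative near-infrared features of Hb,
HbO2, lipid and water (760 nm Hb shoulder, HbO2 rise beyond 800 nm, 930 nm
lipid peak, 970 nm water peak), linearly interpolated onto the scan's
wavelength grid with no extrapolation.  They are adequate for simulation and
testing; quantitative work on real scans should substitute a measured
compilation via the `file` argument of `chromophore_spectra()`.

## The simulator: what it emulates, and what it does not

`simulate_scan()` builds both timestamp grids at the configured rates
(defaults 25 Hz OA, 6.25 Hz US), samples one rigid 2-D pose trajectory
(dx, dy, θ) shared by both streams — mirroring the physical probe — and
renders each stream along it.  US images are a fixed seeded scatterer field,
rigid-transformed point-wise, splatted bilinearly onto a padded canvas,
blurred with a separable zero-padded Gaussian point-spread kernel and
envelope-detected; this hand-rolled renderer (rather than a generic image
`affine`) keeps integer-pixel translations *exactly* shift-equivariant away
from borders, which the test suite exploits.  OA images evaluate absorber
disks analytically at inverse-transformed pixel coordinates (1 px smoothed
edges against aliasing), scale them by the component spectrum at the
active wavelength and by an exponential fluence decay over depth — by
construction exactly the linear mixing model, so a stationary noise-free
frame unmixes to numerical zero and any residual on simulated data is
attributable to motion or noise.  All randomness flows from one root seed
through independent substreams (trajectory, scatterers, per-stream noise),
making scans bit-reproducible; rendered images are snapped to the float32
grid so that HDF5 round trips are bit-exact too.

Motion segments: `stationary` holds the pose; `drift` translates at
constant velocity; `rotation` ramps the angle at constant rate; `jitter`
draws zero-mean Gaussian per-timestamp displacements around a held pose;
`jerk` applies an instantaneous step at the segment start.  Paths are
continuous across boundaries except at jerks.

Ground truth distinguishes three granularities: stationary *time* intervals
(exactly the stationary segments), stationary *US images* (acquired inside
them), and stationary *frames*.  A frame counts stationary when **all of its
(at least two) US images** fall inside one stationary segment — motion is
only observable at US timestamps, so conditioning on the frame's full OA
span would label frames "moving" for protruding a few hundredths of a
second into a segment during which no US image was taken, a mislabel no
US-video annotator would make.  Interval comparisons carry a 1 ns epsilon
because timestamps can land exactly on accumulated segment boundaries.

The default validation corpus (`corpus_configs()`): ten scans, each with
2–3 stationary holds of 1.8–2.4 s separated by 7–10 s moving blocks drawn
from drift (6–12 px), jitter (σ = 0.75 px), rotation (10–20°) and jerky
step trains (1.5–4 px steps every ~0.7 s).  Three parameter choices deserve
their rationale, all consequences of keeping the segment-derived ground
truth *observable* at the US sampling rate and noise floor:

* **Holds of 1.8–2.4 s** — long enough for one to three complete MS frames
  (the clinically minimal hold), and shorter than the default `d_min`, so a
  true event can contain at most one distance-respecting minimum and the
  selector's budget of `n_peaks` is not silently spent twice on one hold.
* **Jerk trains, not lone jerks, flanked by 0.5 s jitter guards** — the pose
  is constant between steps, so an isolated jerk segment is physically a
  stillness the truth would mislabel; recurring steps keep motion inside
  every frame span, and the guards stop the train's edge pauses from
  merging with adjacent stationary segments.
* **Rotation of 10–20° per block** — besides being a realistic repositioning
  sweep, slower rotation accumulates sub-noise displacement for a substantial
  fraction of a second past segment edges, extending the observable
  stillness basin beyond the labelled event.

Scan lengths (~25–35 s) and 64×64 images are scaled-down study sizes chosen
so the full corpus simulates and scores in well under a minute; the
acceptance checks state their own runtimes.  What the simulator does *not*
emulate — and what passing tests therefore cannot certify on real data:
elastic tissue deformation and out-of-plane (3-D) motion, acoustic wave
propagation and reconstruction artifacts, realistic fluence spectra
("spectral coloring", a separate corruption source deliberately out of
scope), vendor file formats, and genuinely human annotation noise (the
synthetic truth is exact, so evaluation numbers on it are optimistic
relative to inter-annotator variability).

One acquisition-geometry remark: at the nominal 25 Hz / 6.25 Hz rates a
28-wavelength frame spans ~1.08 s and contains 7–8 US images; reported
hardware behavior (9–10 US images per frame at the same nominal rates)
suggests an interleaving duty cycle the public description does not
specify.  The simulator therefore treats both rates as free parameters with
the nominal values as defaults rather than hard-coding either account.

## Numerical and degenerate-input choices

* Ranks: 0-based, average ties; single-entry rows → 0; constant rows → 0.5
  (ranked) / 0 (min–max).
* Scoring: frames with $|s| < 2$ → `NA` with a warning, excluded downstream.
* Selection: strict minima only; plateau midpoints; `NA`-split segments;
  score ties break toward the earlier frame — selection is fully
  deterministic.
* NNLS enumeration: supports with rank-deficient $W_S$ are skipped (a
  smaller support represents them); feasibility tolerance $10^{-12}$;
  ties prefer smaller supports.
* NMF: seeded NNDSVD fill-in at 1 % of the data mean; $\epsilon$-guarded
  multiplicative updates; stopping on relative improvement < `tol`.
* ZNXC/SSIM degenerate images as described above; SSIM requires images at
  least the window size and `L = 0` (two identical constants) returns 0.
* Residual $E$: undefined (with warning) for zero-norm frames.

## Limitations

The Motion score is relative to its scan — it ranks frames within one
acquisition and is not a calibrated cross-scan quality unit.  It requires
complete wavelength sweeps, so it cannot provide live feedback during
acquisition.  Performance degrades for presets much shorter than 28
wavelengths (fewer US images per frame; combining adjacent frames is the
natural remedy but is not prescribed here).  The evaluation protocol
credits a single frame per hold, so it measures hold *detection*, not the
quality ranking within a hold.  And the bundled spectra are synthetic
stand-ins: conclusions about real chromophore concentrations require
measured spectra.
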
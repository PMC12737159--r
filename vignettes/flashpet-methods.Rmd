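---
title: "In-beam PET verification of FLASH proton delivery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-beam PET verification of FLASH proton delivery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A FLASH proton spill delivers its full dose in about 100 ms. Verifying where
the beam actually stopped is harder than in conventional delivery: everything
happens at once, count rates during the spill saturate the electronics, and
the activity available afterwards is whatever short-lived positron emitters
(PENs: ¹¹C, ¹⁵O, ¹³N, and the very short-lived ¹⁰C, ¹²N, ¹⁴O) the protons
created in the target. `flashpet` models this measurement end to end for a
12-panel small-animal PET scanner surrounding a solid-water cylinder: it
budgets the expected signal analytically, generates synthetic list-mode data
standing in for the experiment, sorts coincidences the way the scanner's
distributed per-panel-pair processors do, reconstructs 3D activity images
with list-mode MLEM, and extracts the beam position and range from the
images.

The synthetic generator replaces both the physical experiment and a nuclear
Monte Carlo. It is first-class, tested code: all pipeline results in this
package are computed from it, and what the tests demonstrate is therefore
internal consistency of the chain (generator → selection → reconstruction →
localization), not agreement with any measured dataset.

# Scanner geometry and geometric efficiency

Twelve square panels of side $a = 33$ mm sit on a ring, face centers at an
effective radius $r = 80$ mm (front faces at 70 mm plus a nominal 10 mm
interaction depth inside the 20 mm LYSO crystals). Each panel is modeled as a
gapless $30 \times 30$ crystal grid of pitch $a/30 = 1.1$ mm; the recorded
interaction position of a photon is the index of the crystal whose face it
crosses on the effective-radius plane. Depth of interaction is not modeled.

The geometric fraction of annihilation photons captured, for a point source
at the center, is the panel solid angle summed over the ring:

$$f_{geom} = \frac{n}{\pi}\arctan\!\left(\frac{a^2}{4r\sqrt{r^2 + a^2/2}}\right) \approx 0.156 ,$$

which the package cross-checks against brute-force isotropic ray sampling.
Because the ring has an even number of panels, a back-to-back photon pair
from the center is captured or lost as a *pair*, so $f_{geom}$ enters the
detection chain once (and the single-photon efficiency $\varepsilon_\gamma$
twice).

Coincidences are only formed between panels at ring separation ≥ 3. Of the
66 unordered pairs of 12 panels this keeps $12 \cdot 7 / 2 = 42$, matching
the scanner's 42 distributed coincidence processors; nearer pairs cannot
view the field of view. The separation threshold is configurable
(`min_panel_separation`) since the selection rule is a geometric inference,
not a published list.

# Activation and decay budget

Production is treated as instantaneous at the end of the spill: the 100 ms
spill is below 1% of the shortest budgeted half-life, so convolving
production with decay changes an 11-minute budget negligibly (the generator
can still spread creation times across the spill with `in_spill = TRUE`).
Per species, $N(0) = \text{yield} \times n_{protons}$ with per-proton yields
$2.2\times10^{-3}$ (¹¹C), $5.1\times10^{-4}$ (¹⁵O) and $9.2\times10^{-5}$
(¹³N) at $3.1\times10^{10}$ protons; activity follows
$A_i(t) = \lambda_i N_i(0) e^{-\lambda_i t}$ with $\lambda_i = \ln 2 /
T_{1/2}^{(i)}$. Expected decays in a window are exact exponential
differences, so budgets are additive over any partition of the horizon to
rounding error. The expected measured coincidences over a horizon are

$$N_{measure} = \sum_k D_k \, f_{geom} \, f_{2\gamma} \, \varepsilon_\gamma^2,$$

with $f_{2\gamma} = 0.998$ (two-photon annihilation branch) and
$\varepsilon_\gamma = 0.8$ (single-photon detection probability). ¹²N
(11 ms) is excluded from budgets; ¹⁰C and ¹⁴O participate only if the
configuration supplies yields, which the source experiment did not publish.
Note that this chain is an idealization for a *centered point* source: a
distributed source near the axial edge of the field of view is captured at a
substantially lower rate (see "Desk-scale conditions" below).

# The synthetic list-mode generator

**Activation map.** PEN production density is separable: an isotropic
lateral Gaussian with $\sigma = 7.0$ mm (the beam's intensity profile)
truncated at the phantom radius (14 mm — i.e. at $2\sigma$, so the *sample*
lateral spread inside the phantom is ≈ 5.8 mm even though the beam parameter
is 7.0 mm), times a depth profile that is flat from the entrance and falls
logistically through 50% of the plateau at `r50_depth` (default 8.3 mm,
80–20% falloff width 3 mm). The logistic distal edge is a surrogate for the
activation falloff proximal to the Bragg peak; `r50_depth` is free precisely
so that localization experiments can impose known range shifts. Depth is
measured as $z + 18$ mm on the default grid (0 at the upstream grid face).

**Sampling.** Decay counts per species are Poisson with expectation
`count_scale` × the analytic window integral; times follow the truncated
exponential; positions are i.i.d. voxel draws from the map plus uniform
in-voxel jitter. `count_scale` scales the experiment to desk size without
touching any distribution.

**Detection.** Each annihilation emits two exactly back-to-back photons with
probability $f_{2\gamma}$ (acollinearity and positron range are off by
default — both sub-voxel at 1 mm — but available as an optional Gaussian blur
of the emission point); each photon that geometrically reaches a panel is
recorded with probability $\varepsilon_\gamma$. Recorded energy is Gaussian,
FWHM 15% of 511 keV (typical LYSO; the true resolution is unpublished),
rounded to 0.1 keV; recorded times add per-single Gaussian jitter of FWHM
$3.6/\sqrt{2}$ ns so that pair time differences have the panel-pair
coincidence resolution of 3.6 ns, and are stored as integer nanoseconds so
window comparisons are exact and platform-independent.

**Dead time.** The per-pair processors cap accepted event frames at
$2.5\times10^5$/s. The model is non-paralyzable per panel pair with a
coincidence-window tolerance: a single opens a new frame on a pair only if
the pair has been idle for 1/rate since the previous frame start (inclusive
boundary), while singles within 10 ns of the last accepted single on that
pair belong to the open frame and pass. The tolerance is what lets a pair
processor ingest both photons of one coincidence; without it a literal
per-single dead time would veto every second photon and no coincidence could
ever form. A single is accepted only if all pairs containing its panel
accept it.

**Background.** Uncorrelated singles (prompt gamma and other in-room
radiation) are uniform in time and over crystals with energy uniform on
150–800 keV. No rates or spectra were published for this configuration, so
both are explicit configuration placeholders; any figure built on them
should state the rate used.

# Coincidence selection

Each of the 42 pair processors independently receives the merged, time-sorted
singles of its two panels. Singles chained by gaps ≤ 10 ns merge into one
group (transitive closure — this is how ">2 photons in the same window" is
made precise without an arbitrary anchor event); groups of exactly two
singles on opposite panels become coincidences, larger groups are ambiguous
multiples and are discarded whole, and same-panel doubles yield nothing.
Because a single is visible to seven processors, a photon claimed by
coincidences on more than one pair is globally ambiguous: all its
coincidences are dropped (with ring separation ≥ 3 a *true* pair can satisfy
only one panel pair, so this only prunes accidentals). The energy window
(360–650 keV, inclusive bounds, applied to both photons) comes after
pairing, preserving the published processing order. Histogram conventions:
left-closed right-open bins, 50 × 20 ms for the first second and 11 × 60 s
for the full acquisition; energy spectra use 40 bins up to 800 keV.

# Reconstruction

List-mode MLEM with a Siddon line-intersection system model, uniform
initialization, no subsets, no attenuation/scatter/randoms corrections
(none were applied in the source analysis; residual background shows up as
image noise), and a default of 9 full iterations on a 64 × 64 × 36 grid of
1 mm voxels. The grid is offset by half a voxel so voxel centers lie on
integer-mm world coordinates; reported lateral positions are world + 32 mm,
which makes a centered beam read (32, 32) deterministically rather than
flipping a coin between two voxels that straddle the axis.

Two numerical choices matter and were made after observing artifacts,
as the package's own design decisions:

* **Face-integrated system matrix.** Sampling every LOR at crystal face
  *centers* aliases the 1.1 mm crystal pitch against the 1 mm voxel grid and
  imprints deterministic banding on both the sensitivity image and the event
  rows. Both sides therefore integrate over the crystal face: sensitivity
  LORs and event LOR endpoints are jittered uniformly within their faces
  (seeded, reproducible). The sensitivity default enumerates the full
  42 × 900 × 900 LOR set with four jittered samples per LOR (`keep_prob = 1`,
  `n_rays = 4`), keeping the residual Monte-Carlo speckle of the face
  integration small even in the weakly-sensed axial-edge planes; Bernoulli
  thinning is available for quick work but leaves percent-level speckle in
  the denominator that MLEM faithfully inverts into the image. Event rows
  sample one jittered ray by default (`n_rays` raises that for a denser tube
  integration at proportional memory cost).
* **No sensitivity-threshold masking.** Excluding low-sensitivity voxels
  from the support looks attractive against edge-of-FOV noise
  amplification, but EM conserves each event's mass onto the support, so a
  threshold funnels the mass of shallow-depth activity into the first
  unmasked plane and fabricates a dominant artifact there. The option exists
  (`support_frac`) with default 0; the localization analysis does not use
  it.

The axial sensitivity ramps to zero at the panel edges (|z| ≳ 16.5 mm), so
the shallowest few millimeters of the activation column are measured by only
a handful of oblique LORs; their voxels are intrinsically noisy at desk-scale
counts. This is a property of the scanner geometry, not of the algorithm.

The ROI cylinder (36 mm long, 40 mm diameter — wider than the 28 mm phantom)
zeroes voxels whose *centers* fall outside it, keeping inside values bit for
bit.

# Localization

The beam center is the global argmax of the depth-summed (ROI-masked) image,
ties broken to the smallest column-major index; sub-voxel refinement is
deliberately absent by default because the reference analysis reports
integer-mm centers. Depth profiles are read along the axial column through a
center, optionally averaged over the 3 × 3 lateral neighborhood
(`average = TRUE`), which desk-scale statistics effectively require. R50 is
the *distal* (last) downward crossing of 50% of the profile's global peak,
linearly interpolated; range shift is the difference of two R50 depths.

A statistical caveat follows directly from the estimator definition: the
lateral activation blob has σ = 7 mm (truncated at the 14 mm phantom
radius), so the intensity deficit one voxel off the peak is below one
percent, while a map built from $N$ coincidences carries relative cell noise
of order $1/\sqrt{N p_{cell}}$ — a few percent at $N \sim 10^5$. The global
argmax of such a map therefore wanders by roughly a millimeter between
seeds even for a *perfect* imaging system, and the shift between two
independent irradiations inherits about 1.5 times that spread. Range (R50)
estimation does not suffer this: the distal falloff is steep, and its
recovery is stable to a fraction of a millimeter at the same counts. Users
comparing two irradiations should read integer-mm lateral shifts with a
±1–2 mm noise floor in mind.

Profile agreement uses two range-normalized metrics,
$pct = 100\sqrt{\overline{(m-s)^2}}/(\max m - \min m)$ and
$rmse_{rel} = \overline{(m-s)^2}/(\max m - \min m)^2$, computed on the
common depth support after linear resampling of the model. Normalization of
the model to the measurement is optional (`normalize = "mean"`); the default
compares profiles as given, which is the convention under which a constant
offset $c$ gives exactly $pct = 100c/R$.

# Desk-scale conditions and what the tests do (and do not) show

The default two-irradiation experiment mirrors the study design: irradiation
A centered with r50 at 8.3 mm depth; irradiation B shifted −5 mm in x with
r50 deepened by 6.0 mm. `count_scale = 0.375` makes the accepted coincidence
count per irradiation ≈ 2–4 × 10⁵, the same order as the ≈ 4.1 × 10⁵
coincidences the physical measurement collected, while keeping a full
two-irradiation run within minutes on one CPU; the single-run pipeline
default (`count_scale = 0.0026`, ≈ 10⁵ annihilations) is sized for smoke
runs. Because the activation column sits against the axial edge of the field
of view, the end-to-end pair capture fraction of the *distributed* source is
≈ 0.014 per annihilation — an order of magnitude below the centered-point
chain $f_{geom} f_{2\gamma} \varepsilon_\gamma^2 \approx 0.10$, which the
chain tests therefore verify with point sources at the center.

What passing tests show: the selection chain finds exactly the simulated
photon pairs under clean conditions, budgets conserve decays, the
reconstruction recovers point sources to the voxel and imposed lateral/range
shifts to about a millimeter, and every stage is bit-reproducible from one
master seed (stage seeds are `master * 100 + offset`). What they cannot
show: agreement with the institutional measurements (detected totals,
measured histograms, the published 3.35%/6.85% profile discrepancies) — the
real data are not public, and the generator's background and energy
resolution are placeholders, its depth profile a parametric surrogate for
nuclear transport.

# Known limitations

* No DOI or parallax error: interactions happen on a fixed effective-radius
  plane. Real oblique LORs blur millimeters; synthetic images are *sharper*
  and noisier at matched counts than measured ones.
* No scatter in the phantom, no energy-dependent yields, no washout.
* The dead-time model caps frame rates per pair; it does not emulate the
  front-end waveform pile-up that dominates true in-spill losses.
* The beam-current ramp within the spill is not modeled (optional uniform
  in-spill creation only).
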
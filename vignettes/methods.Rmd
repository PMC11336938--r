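---
title: "Methods: synthetic bioimpedance cohorts and the attention classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic bioimpedance cohorts and the attention classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the physical model behind the synthetic
measurements, every tunable parameter with units and defaults, the
numerical choices made in the hand-written network implementation, and
the limits of what the synthetic study can support.

## 1. Physical model

### Electrode–skin contact (Randles circuit)

Each of the six gel electrodes contributes a contact impedance

$$Z_c(\omega) = R_d + \frac{1}{j\omega C_{dl} + 1/R_e}, \qquad
  \omega = 2\pi f,$$

a series skin/gel resistance $R_d$ plus a double-layer capacitance
$C_{dl}$ in parallel with the charge-transfer resistance $R_e$. The
limits identify the parameters: $|Z_c| \to R_d + R_e$ at DC and
$|Z_c| \to R_d$ at infinite frequency, and $|Z_c|$ decreases
monotonically in $C_{dl}$ at fixed $f$. These limits are asserted in the
test suite.

The same symbols are sometimes typeset as the plain series sum
$R_d + 1/(j\omega C_{dl}) + 1/R_e$. That reading has no relaxation — it
diverges at DC and flattens to $R_d + 1/R_e$ at high frequency — and
does not describe a gel electrode on skin, so the Randles parallel form
is the default. `electrode_skin_impedance(..., literal = TRUE)` exposes
the series reading for comparison.

### Tissue paths (Cole dispersion)

Each tissue path is a single-dispersion Cole model

$$Z_t(f) = R_\infty + \frac{R_0 - R_\infty}{1 + (jf/f_c)^\alpha},$$

with zero-frequency resistance $R_0$, infinite-frequency resistance
$R_\infty$, characteristic frequency $f_c$, and broadening exponent
$\alpha \in (0, 1]$. Lipid droplets are insulating at low frequency, so
early fatty infiltration is modelled as a raised liver-path $R_0$ (cell
interiors only become accessible as frequency grows), a slightly
depressed $f_c$, and a slightly smaller $\alpha$ (broader dispersion
from heterogeneous droplet sizes).

### Forward model for one 15 × 30 matrix

For electrode pair $p = (e_1, e_2)$ at frequency $f$:

$$Z_p(f) = Z_c^{(e_1)}(f) + Z_c^{(e_2)}(f)
  + w_p\, Z_{\mathrm{liver}}(f) + (1 - w_p)\, Z_{\mathrm{bg}}(f),$$

and the recorded value is $|Z_p(f)|$ times a multiplicative log-normal
noise factor with median 1. The liver weight $w_p$ falls linearly with
the rank of the pair's centre-to-centre distance on a 2 × 3 electrode
grid, from 0.7 (closest pairs, most liver in the current path) to 0.3:
distant pairs sample proportionally more superficial/background tissue.
The 15 pairs are all unordered combinations of 6 electrodes; the sweep
is 30 log-spaced frequencies spanning exactly 1–100 kHz (30 points
total for the two decades — enough to resolve a single dispersion
without inflating the input width).

## 2. Generator parameters

All resistances in ohm, capacitances in farad, frequencies in hertz.
Defaults from `default_generator_config()`:

| Parameter | Healthy liver | Fatty liver | Background | Why |
|---|---|---|---|---|
| $R_0$ | 1400 | 3200 | 900 | insulating droplets raise low-f resistance |
| $R_\infty$ | 350 | 450 | 300 | high-f paths through cell interiors converge |
| $f_c$ | 25 kHz | 18 kHz | 30 kHz | larger/laden cells relax more slowly |
| $\alpha$ | 0.85 | 0.80 | 0.90 | droplet heterogeneity broadens the dispersion |

Contact defaults: $R_d = 150\ \Omega$, $C_{dl} = 0.5\ \mu F$,
$R_e = 20\ k\Omega$ — a dry-ish gel electrode whose contact impedance
dominates at the bottom of the sweep and nearly vanishes at the top,
which is exactly the regime where contact variability could mask the
tissue signal.

Between-subject spread: log-normal with coefficient of variation 0.06
on all dispersion resistances and $f_c$, 0.05 on contact parameters,
additive jitter 0.02 on $\alpha$ (clamped to $[0.4, 1]$). Measurement
noise: multiplicative log-normal, $\sigma = 0.03$ (`noise_sigma`).
These spreads leave the classes linearly inseparable in no single
frequency bin but cleanly separable from the full matrix, which is the
regime the classifier is meant to demonstrate.

What the generator emulates — and does not. It reproduces the
*structure* of an on-skin multi-frequency recording: per-pair geometry
weighting, contact overhead, dispersion shape, multiplicative noise. It
does not model anisotropy, electrode placement error, motion or
breathing artefacts, temperature drift, or inter-device calibration;
conclusions about absolute accuracy therefore apply to the synthetic
cohort, not to patients.

## 3. Network

`network_config()` defaults: `stem_channels = 16`, `n_blocks = 3` at
constant trunk width, `reduction_ratio = 4` (channel-attention
bottleneck), `spatial_kernel = 7`, two-class softmax head after global
average pooling. Each residual block is conv 1×1 → instance norm → ReLU
→ conv 3×3 → instance norm, plus identity (or 1×1-projection) shortcut.
In the attention arm, every block's pre-shortcut feature map is gated by
channel attention (sigmoid of a shared bottleneck MLP applied to both
global-average and global-max pooled vectors) and then spatial attention
(sigmoid of a `spatial_kernel`-wide convolution over the channel-mean
and channel-max maps). Attention is applied *per block* rather than once
at the top so that the re-weighting acts on progressively more abstract
features; the plain baseline (`use_attention = FALSE`) is byte-for-byte
the same network with both gates removed.

Inputs are normalised by a per-frequency (column-wise) z-score of
$\log_{10}|Z|$ fitted on the training partition only; the log makes the
multiplicative noise additive, and per-column statistics remove the
strong frequency-dependent scale so the network sees pair/frequency
*shape*, not magnitude.

Instance normalisation (per channel, per sample) is used instead of
batch normalisation because cohorts are small (40 subjects) and
evaluation must be independent of batch composition — a property the
test suite asserts directly (single-sample and permuted-batch outputs
are identical).

## 4. Numerical choices

- **Everything in base R.** Convolution is im2col + one matrix product,
  with the integer gather index memoised per input shape; the backward
  pass for inputs reuses the forward convolution with a spatially
  flipped, channel-transposed kernel.
- **Gradient checking and ReLU kinks.** At initialisation the
  instance-norm output has exactly zero spatial mean, so the
  channel-attention average-pool branch sits exactly on the ReLU kink
  and central finite differences report spurious half-slopes there.
  The gradient tests therefore perturb all parameters off the kinks
  first; after that the maximum relative error is below $10^{-5}$.
- **Optimiser.** Full-batch Adam, learning rate $10^{-3}$, up to 300
  epochs, early stopping with patience 30 on validation loss, and the
  best-validation-loss checkpoint is returned.
- **Plateau stop.** On a separable cohort the validation loss keeps
  creeping down for hundreds of epochs, so patience alone never fires.
  Training additionally stops once both partitions are perfectly
  classified *and* the training cross-entropy stays below
  `tol_loss = 0.15` for `plateau = 5` consecutive epochs — a
  convergence criterion, not an accuracy target: it only triggers after
  the fit is already perfect on both partitions.

Problem sizes used throughout: 40-subject cohorts (20 per class),
15 × 30 inputs, 20/8/12 stratified train/validation/test split
(largest-remainder apportionment per class, ties resolved
train > validation > test), roughly $10^4$ parameters in the attention
arm. One training run takes on the order of a minute on a single CPU.

## 5. Evaluation

`roc_auc()` sweeps the tie-collapsed score thresholds and integrates
the ROC by trapezoids, which equals the rank (Mann–Whitney) statistic;
the tests verify this equivalence against a brute-force rank
implementation and, when available, against the independent pROC
package. `evaluate_over_seeds()` repeats cohort generation, splitting,
training and testing across seeds and reports per-seed test accuracy
and AUC for the attention and baseline arms.

## 6. Histology pipeline

Synthetic stained sections are rendered as bright disks (lipid
droplets appear as pale vacuoles in stained tissue) on a darker noisy
background. Segmentation is Otsu thresholding plus
connected-component labelling; droplet size is the equivalent diameter
$2\sqrt{A/\pi}$ in pixels. Counts are binned half-open into diameters
$[2, 7)$ and $[7, 13)$; groups are compared per bin with one-way ANOVA
(with a zero-variance degenerate convention of $F = 0$, $p = 1$), and a
section is labelled fatty when its small-bin count exceeds a threshold
(default 40). The generator draws per-section droplet counts around
group means (healthy: 12 small / 8 large; fatty: 90 small / 25 large)
so the small-droplet surge — the defining early-NAFLD signature — is
what both the ANOVA and the labelling rule key on.

## 7. Limitations

- All results are on synthetic cohorts; the perfect test metrics state
  that the pipeline recovers the signal the generator encodes, not that
  the method achieves this on human subjects.
- The forward model is a lumped two-path circuit; no field simulation,
  electrode geometry beyond distance rank, or tissue anisotropy.
- Cohorts are small (12 test subjects), so accuracy and AUC are
  quantised in steps of 1/12 and 1/36; multi-seed means are reported
  for that reason.
- The network is CPU-bound base R: adequate for 15 × 30 inputs and
  40-subject cohorts, not for larger images or cohorts.
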
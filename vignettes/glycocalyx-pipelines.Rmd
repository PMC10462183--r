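---
title: "Models and methods: SAIM height reconstruction, phasor FLIM, and isotopologue arithmetic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoscape)
```

This vignette explains the three models the package implements, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the numerical choices behind the fitters.

## 1. SAIM: interference above a silicon mirror

A fluorophore at height $H$ above a silicon chip coated with a transparent
oxide spacer sits in a standing wave formed by the direct and
substrate-reflected excitation fields. For s-polarized (TE) light of vacuum
wavelength $\lambda$ at incidence angle $\theta_b$ in the buffer, the
excitation probability is

$$f(\theta, H) = \left|1 + r_{TE}\,e^{i\phi}\right|^2,\qquad
\phi = \frac{4\pi}{\lambda} n_b H \cos\theta_b .$$

$r_{TE}$ is the stack reflection coefficient obtained from the oxide
layer's characteristic matrix
$M = \begin{pmatrix}\cos\beta & -i\sin\beta/p_1\\ -i p_1\sin\beta & \cos\beta\end{pmatrix}$
with phase thickness $\beta = k_{ox} d_{ox}\cos\theta_{ox}$ and TE
admittances $p_0 = n_{Si}\cos\theta_{Si}$, $p_1 = n_{ox}\cos\theta_{ox}$,
$p_2 = n_b\cos\theta_b$:

$$r_{TE} = \frac{(m_{11} + m_{12}p_0)\,p_2 - (m_{21} + m_{22}p_0)}
               {(m_{11} + m_{12}p_0)\,p_2 + (m_{21} + m_{22}p_0)} .$$

Angles follow Snell's law through buffer → oxide → silicon; silicon is
complex with non-negative imaginary part, and complex cosines take the
principal square root with the branch fixed so $\mathrm{Im}(n\cos\theta)
\ge 0$ (a decaying wave into the absorbing substrate). With a lossless
oxide the matrix is unimodular, and at $d_{ox} = 0$ the expression
collapses to the two-media Fresnel coefficient — both serve as tests, along
with an independently coded Airy (recursive two-interface) summation that
must agree to $10^{-10}$ across wavelengths, angles and oxide thicknesses.

Measured intensities follow $I_j = A f(\theta_j, H) + B$ over the angle
grid (default: 32 angles evenly spaced 5–43.75°). $A$ absorbs label
density, excitation power and detection efficiency; $B$ absorbs background.

**Key parameters.** Wavelength (nm, vacuum), three refractive indices, and
oxide thickness (nm, per chip — chips vary and are measured individually,
hence the per-chip override in the config file). None of the indices are
universal constants at the needed precision, so they are configuration, not
code; every test pins its own values.

### The fitter

"Nonlinear least squares" needs care here: $f$ is oscillatory in $H$ (the
standing wave repeats with period $\lambda / (2 n_b \cos\theta_b)$, about
210 nm at these settings), so a single local start is unreliable. The
fitter exploits separability instead:

* for fixed $H$ the model is linear in $(A, B)$, solved in closed form
  (the solve matches a general linear least-squares fit to $10^{-10}$,
  which is itself a test); negative amplitudes are collapsed to the
  constant fit, since a physical pixel cannot have $A < 0$;
* the profile SSE is scanned on a 1 nm grid over the search bounds
  (default 0–300 nm);
* the best local minima (default 3) are refined by golden-section search
  in their bracketing intervals to $10^{-4}$ nm;
* the returned optimum is never worse than any coarse seed, and among
  minima tied within a $10^{-9}$ relative SSE window the smallest $H$ wins
  — this makes the fitter fully deterministic, independent of pixel order
  and worker count.

Truths beyond one interference period remain identifiable because the
period varies with angle across the sweep; the fitter reports the
in-bounds solution. Constant-intensity pixels are flagged degenerate
(`converged = FALSE`, `NA` height) rather than fitted; the quality mask
requires convergence and amplitude above a floor (default: strictly
positive). Masked pixels carry `NA` in memory and an explicit −1 sentinel
on disk, never a silent zero.

**Thickness readout.** Glycocalyx thickness is the mean dye-layer height
minus the mean fibronectin-layer height over a square subregion
(conventionally 100×100 pixels) inside each cell, means taken over
quality-masked pixels only. ROI placement is user-supplied: the original
measurement places subregions inside cells by eye, and we do not attempt
to automate a judgment the data cannot arbitrate.

## 2. Phasor FLIM and the bound-NADH fraction

Each pixel's photon-arrival histogram $I(t)$ over one laser period $T$ maps
to first-harmonic coordinates, $t$ at bin centers and
$\omega = 2\pi n / T$:

$$G = \frac{\sum_t I(t)\cos\omega t}{\sum_t I(t)},\qquad
S = \frac{\sum_t I(t)\sin\omega t}{\sum_t I(t)} .$$

A mono-exponential lifetime $\tau$ sits at
$G = 1/(1+(\omega\tau)^2)$, $S = \omega\tau/(1+(\omega\tau)^2)$ — the
universal semicircle — and this closed form is exact for a periodically
folded exponential, which is why it doubles as the calibration model.
Mixtures combine phasors linearly with intensity weights, which is the
property the bound-fraction readout rests on: after calibration, a pixel's
FB is its normalized orthogonal projection onto the chord from the
free-NADH reference phasor to the bound-NADH reference phasor, clipped to
$[0, 1]$.

Calibration treats the phasor as complex $z = G + iS$ and multiplies every
pixel by $z_{theory}(\tau_{ref}, \omega)/z_{measured}$ — one rotation plus
one modulation rescale, which removes any linear instrument response
common to sample and reference. The reference is Coumarin 6 at 2.5 ns.

**Defaults and why.** Repetition rate 80 MHz (period 12.5 ns), the standard
Ti:Sapphire value, configurable because the instrument's actual rate must
be used. Free/bound NADH endpoints default to lifetimes 0.4 and 3.4 ns
converted through the mono-exponential map — widely used values, but they
are arguments, never baked into results. Harmonic defaults to 1.
Compartment segmentation implements diffuse-background removal as
large-kernel Gaussian smoothing (sigma well above the organelle scale,
default 12 px, capped so the kernel fits the image) subtracted from the
intensity image, followed by Otsu thresholding of the residual within the
cell region; mitochondrial and cytosolic masks are disjoint by
construction. Zero-count pixels get `NA` phasors rather than errors.

## 3. Isotopologue arithmetic

For a metabolite with $n$ carbons and isotopologue areas $M_0..M_n$:
relative amount $= \sum_i M_i$; fractional contribution
$FC = \sum_i i M_i / (n \sum_i M_i)$. FC is scale invariant (so unchanged
by normalization to protein and cell number, which divides amounts
elementwise) and equals the per-carbon labeling probability exactly when
labeling is binomial — the identity $\sum_i i\,\mathrm{Bin}(i; n, p) = np$
is the module's sharpest test. Missing isotopologue columns are
zero-filled with a warning. **Caveat:** no natural-abundance ¹³C correction
is applied; inputs are assumed already corrected or the ~1.1% natural
abundance accepted as bias.

## 4. What the generators emulate — and what they do not

* `make_height_field` builds flat layers, steps, hemispherical bleb caps
  (Poisson-placed, emulating bleb-covered cell surfaces) and ridge
  networks (thresholded band-pass random fields, emulating interconnected
  membrane ridges). These capture the *height statistics* the fitter must
  handle, not cell biology: there is no point-spread function, no axial
  extent of the label layer, no registration error between channels.
* `simulate_saim_stack`'s noiseless output equals the forward model to
  machine precision by construction; Poisson noise is applied per (angle,
  pixel). Camera read noise beyond an optional Gaussian term is not
  modeled.
* `simulate_decay_image` draws multinomial photons from a two-component
  folded exponential whose bound-component intensity fraction is the FB
  field, optionally delayed by an instrument shift; a reference simulated
  with the same shift plays the calibration standard. IRF shape beyond a
  pure delay is not modeled — calibration removes any linear response, so
  a delay suffices to exercise it.
* `simulate_isotopologues` is binomial labeling with mean-one lognormal
  multiplicative noise (multiplicative being the right family for MS peak
  areas).

Every generator is a pure function of its parameters and seed; regeneration
is bitwise identical. Passing tests therefore demonstrate correctness of
the *computations* under the stated statistical models — they do not
certify performance on real images with drift, structured background, or
detector artifacts.

**Problem sizes.** The test and acceptance runs use 200 single-pixel
recovery draws, 100×100-pixel stacks for the thickness round trip (one
32-angle fit per pixel), 48×48 decay images at 256 time bins and 10⁴
photons/pixel, and 200 replicate isotopologue draws per carbon count —
sizes chosen so the full validation completes in about a minute while
keeping Monte-Carlo error well below the effect sizes being checked.

## 5. Numerical and design notes

* The reflection formula's printed term grouping is ambiguous in some
  typesettings of this model; the package uses the standard
  stratified-media form (incident medium = buffer, substrate = silicon),
  justified by the Fresnel limit at zero oxide and the Airy oracle.
* In the Snell chain the incident-side index is the buffer's, i.e.
  $\theta_{ox} = \arcsin(n_b \sin\theta_b / n_{ox})$; the invariant
  $n_b\sin\theta_b = n_{ox}\sin\theta_{ox} = n_{Si}\sin\theta_{Si}$ is
  asserted in tests.
* TIFF float storage is range-limited to $[0,1]$ in the available writer,
  so image writers apply an affine map recorded in a one-line `.scale`
  sidecar; readers undo it. Heights are always nm, FB dimensionless.
* The phasor semicircle bound holds exactly in the continuum; with finite
  time bins a short-lifetime decay can exceed it by the discretization
  error of the transform, which is why the property test carries a small
  slack.
* TM polarization, emission-side interference, vendor FLIM file formats,
  natural-abundance correction and cross-channel registration are out of
  scope.
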
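---
title: "The segclock model: a delay-differential lattice simulation of the zebrafish segmentation network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The segclock model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

Zebrafish somites bud off the anterior end of the presomitic mesoderm (PSM)
every ~30 minutes, paced by a segmentation clock: delayed autorepression of
the *her* genes (her1/her7) produces cell-autonomous transcriptional
oscillations, which Delta/Notch juxtacrine signalling keeps synchronized
between neighbours. Each nascent somite also acquires rostrocaudal
polarity: the *mesp* genes (and their target *ripply1*) mark the rostral
half, in stripes complementary to *her*/*deltaC* expression. `segclock`
implements a mechanistic tissue model that connects these two layers —
clock, Notch, and the mespa/mespb/ripply/tbx6 patterning tier — and a
harness of the time-controlled in-silico perturbations (Notch mutant, DAPT
treatment, heat-shock overexpression of *her*, *mesp*, or *ripply*) whose
timing phenotypes discriminate between candidate network topologies.

## Model structure

The tissue is a fixed 4 x 50 hexagonal lattice (even-r offset convention;
column 0 posterior, column 49 anterior, ~8 um per column). Each cell
carries 13 species: five mRNAs (`her_m`, `delta_m`, `mespa_m`, `mespb_m`,
`ripply_m`), six proteins (Her, Delta, Mespa, Mespb, Ripply, Tbx6), the
Her homodimer, and NICD (the Notch intracellular domain). Paralogs are
collapsed (`her` = her1+her7, `mespa` = mespaa/mespab, `mespb` =
mespba/mespbb), which is the granularity at which the perturbation data
constrain the network. Tbx6 is modelled at the protein level only; its
regulation in this network is post-translational (Ripply-dependent
removal).

The regulatory edges, all standard Hill kinetics with additive
multi-activator inputs and multiplicative repression:

* **Clock core** — the Her dimer represses `her` and `delta`
  transcription after a transcriptional delay; NICD activates `her`
  (`rate = tc_her * hillR(dimer) * (basal_her + w_notch_her *
  hillA(NICD))`). Translation follows the mRNA after a translational
  delay; Her monomers dimerize reversibly.
* **Coupling** — NICD is produced from the arithmetic *mean* of the
  neighbours' Delta protein (mean, not sum, so boundary cells with fewer
  neighbours are not systematically Notch-poor; an isolated cell receives
  zero), after a signalling delay.
* **mespa** — the incoherent feedforward target: strong Notch activation
  (low `K_notch_a`, weight 1) plus weak Tbx6 activation (weight 0.15,
  high `K_tbx_a`), multiplied by direct Her-dimer repression. Transcription
  is zero posterior of `anterior_gate_col` (a static stand-in for the FGF
  determination front; the gate is the only FGF representation in the
  model).
* **mespb** — strong Tbx6 activation (low `K_tbx_b`, weight 1) plus weak
  Notch activation (weight 0.2); no direct Her edge, so its clock response
  is indirect, matching its delayed perturbation kinetics.
* **ripply / tbx6** — summed Mesp proteins activate `ripply`; Ripply
  enhances Tbx6 removal (`k_rip * hillA(Ripply) * Tbx6`), closing the
  mesp -> ripply -| Tbx6 -> mespb negative feedback loop.

## Numerics

Integration is explicit fixed-step Euler at `dt = 0.1` min with a ring
buffer of past lattice states; every delayed term reads the state at
`t - tau` rounded to a fixed 0.1-min delay grid (so the effective delay is
independent of `dt`). The one deliberately non-Euler piece is the
Her/dimer exchange: the quadratic dimerization flux becomes stiff when
translation is boosted 20-fold, so that pair is updated linearly
implicitly (first-order accurate, unconditionally stable). Abundances are
clipped at zero and clip events counted; more than 0.1% clipped updates
raises a warning as a symptom of too coarse a step. Convergence is
asserted by a dt-halving test over one clock cycle (the pointwise
deviation is < 2% and halves again from `dt = 0.05` to `0.025`,
confirming first order); over longer horizons the integration error
manifests as a slowly accumulating phase shift, which a pointwise
comparison would measure instead of convergence. Simulations are
deterministic given (configuration, protocol, seed, dt); the only random
draws are the per-cell rate sampling and the initial history.

## Pseudo-stochasticity and the synthetic-data conditions

Biological noise enters as static cell-to-cell variability: every rate
constant of every cell is drawn once from a uniform distribution centred
on its nominal value with coefficient of variation `cell_cv`, truncated at
zero, and held fixed for the whole run. Delays, Hill constants and
coefficients, edge weights and geometry are shared by all cells. The
shipped `cell_cv = 0.07` was calibrated jointly with the coupling
strength so that (i) the wild-type posterior tissue stays synchronized
(Pearson synchronization index >= 0.8 over 300-900 min) and (ii) after
Notch loss the posterior clock takes more than four hours to
desynchronize while the anterior mespb field desynchronizes within the
simulated day — the two timing phenotypes the model exists to reproduce.

## The clock-slowing gradient

A static lattice with identical oscillators everywhere produces a
spatially uniform phase and hence no stripes. In the embryo the
oscillation slows as cells mature anteriorly, turning the phase profile
into kinematic waves whose frozen anterior rims are the stripes. The model
encodes this as a linear increase of the `her` transcription delay per
column (`period_grad = 0.008` per column) starting anterior of
`grad_start_col = 10`; the posterior clock zone (columns 0-9, the region
used for period and synchronization readouts) oscillates at the uniform
30-min pace. With this gradient the anterior third carries 2-4 mespa
stripes at any time from ~600 min on, and the stripe count slowly
increases over a run because the phase difference across a static tissue
grows secularly — the model trades cell advection (out of scope) for a
slow drift that is irrelevant on the 1200-min horizon analysed.

## Parameter provenance

Quantitative rate constants for this network are not published as a usable
table, so the shipped defaults are a calibrated set. The her/deltaC core
starts from the classical delay-oscillator values (transcription rate 33
molecules/min, translation 4.5 per mRNA per min, turnover 0.23-0.3 /min,
delays of a few minutes) and the delays were then tuned so the coupled
posterior period is 29-30 min. The Notch arm (`tau_p_delta = 4`,
`tau_nicd = 4`, `deg_nicd = 0.3`, `K_delta = 1000` at mid-range of the
Delta oscillation) was placed so that (a) coupling is strong enough to
synchronize tissue with 7% rate variability, (b) removing it lengthens
the period slightly and collapses the amplitude (the Notch-mutant
phenotype), and (c) NICD oscillates near antiphase to `her_m`.

Point (c) deserves a note, because it is the calibration's one
non-obvious outcome: with the NICD input saturated (temporally flat), the
Her-dimer repression arm alone places `mespa` *in phase* with `her` — the
dimer's phase lag relative to `her_m` approximately cancels the
repression inversion. The antiphase (complementary) mespa pattern is
carried by the oscillating Notch arm of the incoherent feedforward loop.
The direct Her-dimer edge on `mespa` is kept with a high half-saturation
(`K_hd_mespa = 400`): at wild-type dimer levels it contributes modest
modulation, but under a 30-min her pulse the dimer rises orders of
magnitude above it and shuts `mespa` within minutes — which is exactly
the fast-repression kinetics that motivated the direct edge.

## Perturbation protocols

Protocols are declarative lists of `{param, action (set|multiply), value,
t_on, t_off}` applied uniformly to all cells (mutants, bath-applied drug,
and heat shock are global). The presets: `notch_mutant` (`psd = 0`
always), `dapt` (`psd = 0` from 600 min), `her_oe` (30-min window),
`mespa_oe`/`mespb_oe`/`ripply_oe` (60-min windows), `her_mutant`
(`psh = 0` always). Overexpression multiplies the target's translation
rate by 20 (a heat-shock promoter drives expression far past endogenous
levels; the acceptance behaviour is insensitive to the fold above ~10).
For `her_oe` the translation boost alone is self-defeating: the flood of
Her dimer represses endogenous `her` transcription, the transcript pool
collapses within ~10 min, and repression of mespa releases before the
window ends. A heat-shock transgene is not autorepressed, so the preset
adds a transcription-independent `her` mRNA supply (`hs_her_m_supply`,
set to the nominal maximal transcription rate) for the duration of the
window — "boosted translation of pre-existing transcript plus boosted
transcription-independent supply".

## Metrics and their conventions

* **Period** — median peak-to-peak interval, peaks required to have
  topographic prominence >= 20% of the series range (rejects numerical
  ripple), peak times refined by parabolic interpolation. Affine-invariant.
* **Amplitude** — half the mean peak-to-trough excursion.
* **sync_index** — mean pairwise Pearson correlation mapped to [0, 1] via
  `(r + 1)/2`. Its fully-randomized limit is 0.5 *itself* (the expected
  pairwise correlation of phase-scrambled oscillators is a squared modulus
  and cannot be negative), so this index measures departure from
  coherence but cannot robustly cross 0.5.
* **time_to_desync** therefore defaults to a Kuramoto phase-order
  parameter: each cell's phase is interpolated between its detected
  peaks, and coherence is `|mean exp(i phi)|` within sliding
  column-window neighbourhoods of >= 6 cells, averaged over windows of
  two nominal periods. Local neighbourhoods are the faithful reading of
  the salt-and-pepper desynchronization phenotype: a kinematic wave
  (smooth phase gradient across the whole region) is an ordered pattern
  and scores coherent, intermingled high/low neighbours do not. The
  incoherent limit (~`1/sqrt(n)`) lies well below the 0.5 threshold, so
  the crossing time is well defined. The Pearson index remains available
  (`measure = "pearson"`).
* **time_to_loss** — per-cell sliding-window amplitude (window = one
  nominal period, centre convention), averaged over the region, compared
  with the mean over the 120 min before onset; "barely detectable" is
  operationalized as < 10% of baseline.
* **detect_stripes** — threshold at 50% of the profile maximum (the FWHM
  convention for effectively thresholded in situ stains), runs of >= 2
  columns; widths and anterior-edge interstripe distances in cells and um.
* **complementarity** — Pearson correlation of the row-averaged anterior
  `her` and `mespa` profiles; complementary striping gives strongly
  negative values (the wild-type run scores a median of about -0.7 over
  600-900 min).
* Regions: "posterior" = columns 0-9; "anterior" = columns >=
  `anterior_gate_col` (default 33, the anterior third; the printed
  sources place mesp expression in the anterior PSM without giving a
  fraction).

## What the synthetic fixtures do and do not show

`generate_stripe_field` and `generate_oscillators` produce rectangular
stripes of known geometry and sinusoids of known period/phase (plus
truncated Gaussian noise), and `fixture_sim` wraps them in the simulation
container so the metrics run on fixtures through exactly the code path
used for model output. Passing fixture tests therefore demonstrates that
the estimators recover known ground truth — not that the model is right,
and not that the estimators are robust to every waveform the model can
produce; the acceptance suite covers the latter on real simulations.

## Experiment readout windows

The overexpression experiments score expression "immediately after" the
induction window (amplitude over 640-700 min for a 600-660 window),
because that is when the corresponding stains were taken and because the
transient — especially for the fast-decaying Mespb and Ripply pools —
has largely relaxed two hours later. Under `ripply_oe` the mespa
reduction is real but small (a few percent): `mespa` is mostly
Notch-driven by construction, and its Tbx6 share is the weak edge.

## Problem sizes

All shipped analyses run the full 4 x 50 lattice: 900 simulated minutes
for wild-type readouts and 1200 for perturbation time courses (onset at
600 min), with five replicate tissues (seeds) for the stochastic timing
medians. A 1200-min run integrates ~12,000 Euler steps over 2,600 state
variables and takes a few seconds in plain R.

## Known limitations

No cell movement, division, ingression, or axis growth: the stripe
pattern is read on a static tissue, so stripe number grows slowly over
long runs instead of being carried away by advection. FGF/Wnt dynamics
are reduced to a fixed anterior gate. Paralog differences within the
mespa or mespb pairs, and Hes6-type heterodimer partners of earlier clock
models, are deliberately outside the network's granularity. Parameter
values are a calibrated set reproducing the timing phenotypes, not
measured constants; conclusions should rest on the phenotype directions
and their timing ranges, which are robust to the fold and threshold
choices documented above.
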
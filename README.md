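# segclock

Mechanistic simulation of the gene regulatory network that links the
zebrafish segmentation clock to rostrocaudal somite patterning.

In the zebrafish presomitic mesoderm (PSM), delayed autorepression of the
*her* genes produces ~30-min transcriptional oscillations, Delta/Notch
signalling keeps neighbouring cells in phase, and the *mesp* genes read
the clock out into stripes that prefigure the rostral somite halves —
expressed complementarily to *her*/*deltaC*. `segclock` is for systems
biologists who want to test whether a specific network topology —
Notch activating *mespa* strongly and *mespb* weakly, Tbx6 doing the
reverse, Her repressing *mespa* directly, and a mesp → ripply ⊣ Tbx6
negative feedback — reproduces the timed perturbation phenotypes that
distinguish it from the alternatives.

## The model

A 4 × 50 hexagonal cell lattice (posterior at column 0) integrated with
time-delayed differential equations (explicit Euler, `dt = 0.1` min,
ring-buffered state history). Per cell, 13 species: the mRNAs `her_m`,
`delta_m`, `mespa_m`, `mespb_m`, `ripply_m`; the proteins Her, Delta,
Mespa, Mespb, Ripply, Tbx6; the Her homodimer; and NICD. The core rate
laws (Hill kinetics):

    her_m'   = tc_her · K²/(K² + D²) · (basal + w·NICDⁿ/(Kₙⁿ + NICDⁿ)) − deg·her_m
    NICD'    = k_nicd · hill(mean neighbour Delta(t − τ)) − deg·NICD
    mespa_m' = gate · tc · [w_notch·hill(NICD) + w_tbx·hill(Tbx6)] · hillR(D) − deg·mespa_m
    Tbx6'    = basal − deg·Tbx6 − k_rip · hill(Ripply) · Tbx6

with transcription/translation delays per gene, static per-cell rate
variability (uniform, `cell_cv = 0.07`) as the pseudo-stochastic
component, and a posterior→anterior clock-slowing gradient that turns the
phase profile into the kinematic waves whose anterior rims are the mesp
stripes. Perturbations are declarative, time-windowed parameter
modifications (`psd = 0` for Notch loss; translation ×20 for heat-shock
overexpression).

## A worked example

```r
library(segclock)

cfg <- lattice_config()                       # the 4 x 50 PSM
p   <- default_parameters()
cp  <- sample_cell_parameters(p, 200, seed = 1)
sim <- integrate_lattice(cfg, cp, protocol_preset("wt"),
                         t_end = 900, seed = 1)

her <- sim_series(sim, "her_m", column_cells(0:9, cfg),
                  t_range = c(300, 900))
estimate_period(her)   # 28.9  -- posterior clock period, minutes
sync_index(her)        # 0.92  -- posterior synchronization (1 = locked)

ant <- (p$anterior_gate_col:49) + 1
detect_stripes(sim_profile(sim, "mespa_m", 750)[ant])
#> <stripe_set> 2 stripe(s)
#>   posterior_edge_col anterior_edge_col width_cells width_um
#> 1                  2                10           9       72
#> 2                 15                16           2       16
#> interstripe distances (cells): 6
complementarity(sim_profile(sim, "her_m", 750)[ant],
                sim_profile(sim, "mespa_m", 750)[ant])   # -0.86
```

The posterior tissue oscillates at the somite rhythm (~29 min) and stays
synchronized; the anterior third carries travelling mespa stripes (their
widths breathe as each kinematic wave arrives and narrows), anticorrelated
with the her pattern — the complementary striping that sets rostrocaudal
polarity.

Named in-silico experiments bundle a preset, its metrics and the expected
qualitative signature:

```r
run_experiment("dapt", seed = 1)
#> <segclock_experiment> dapt (seed 1): PASS
#>   mespa_loss_min           33
#>   her_desync_min           360
#>   mespb_desync_min         420
#>   [ok] mespa_lost_2h
#>   [ok] her_desync_after_4h
#>   [ok] mespb_desync_after_4h
```

Under simulated Notch inhibition, anterior *mespa* cycling collapses
within ~half an hour, while the posterior clock and the anterior *mespb*
field lose neighbour-level coherence only after 6 and 7 hours — the
fast-versus-slow dissociation that places Notch upstream of the clock and
*mespa* directly downstream of Notch. A command-line front end is
installed at `inst/cli/segclock.R` (`simulate`, `experiment`, `render`).

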
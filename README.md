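# endotrack

Reconstructing the dynamic architecture of yeast endocytic sites from
centroid tracks of fluorescent patches.

Endocytic events in budding yeast are stereotyped: a coat assembles on
the flat plasma membrane, actin drives a ~100 nm inward movement of the
growing invagination, BAR-domain proteins scaffold the tubule neck, and
scission releases a vesicle — all within ~10 s, below the diffraction
limit. Each event is observable only as a noisy centroid track of a
diffraction-limited spot. `endotrack` recovers nanometre-scale protein
architecture from many such tracks, for cell biologists quantifying
membrane-trafficking machinery with ordinary wide-field microscopes.

## The method

**Single-channel averaging.** Tracks
$p_i = \{p^x_i, p^y_i, p^f_i\}$ of one protein are mutually aligned over
planar isometries $T$ and integer lags $\tau$ by minimising the
fluorescence-weighted cost

$$\frac{\sum_i w_i\,\lVert q_{i+\tau} - T(p_i)\rVert^2}{\sum_i w_i},
\qquad w_i = q^f_{i+\tau}\,p^f_i,$$

with the optimal $T$ in closed form per lag (weighted 2D Procrustes).
All $n(n-1)$ pairwise alignments are combined into one transform per
track and the aligned tracks averaged per time point into an average
trajectory $P_i = \{P^x, P^y, P^f, \delta^x, \delta^y, \delta^f\}$.

**Two-colour alignment.** Pairs acquired simultaneously with a reference
protein give per-pair transforms $T = T_r (T_p)^{-1}$; components are
combined by medians with uncertainties
$1.4826 \times \mathrm{MAD}/\sqrt{M}$, and positional errors propagate as
$\zeta^x_i = \sqrt{(\delta^x_i)^2 + (P^y_i \delta T^\theta)^2 +
(\delta T^x)^2}$.

**Downstream models.** Copy-number calibration
$n_p = c\,(f/g)\,n_r$ with full error propagation; projection
foreshortening $1-\sqrt{1-(z/R)^2}$; photobleach-track alignment;
registration of electron-microscopy membrane profiles to the tracking
clock; BAR-dimer membrane coverage (13 nm × 5 nm per dimer) placed by
centre of mass on the surface of revolution; and maximum-likelihood
estimation of two-fluorophore separations from the Rice-distributed 2D
distances $p(s\mid d,\sigma) =
\tfrac{s}{\sigma^2}e^{-(s^2+d^2)/2\sigma^2} I_0(sd/\sigma^2)$.

A simulation module generates virtual ground-truth cohorts and
two-colour pairs and benchmarks the whole pipeline.

## Worked example

```r
library(endotrack)
set.seed(7)

# 20 noisy virtual tracks of one protein, averaged
tmpl   <- make_template()                       # 100 nm inward template
cohort <- lapply(1:20, function(j)
  simulate_trajectory(tmpl, sigma = 12, f_noise = 0.15))
avg <- align_and_average(cohort, cohort_config("none"))
avg
#> average trajectory: 53 time points, dt = 0.25 s

# fluorescence -> molecule numbers against a 280.6-copy reference
cal <- copy_number(target_spots, reference_spots,
                   n_r = 280.6, dn_r = 16.1)
cal
#> copy number: 136.1 +/- 10.9 molecules (f/g = 0.485, n_r = 280.6)
mc <- calibrate_curve(avg, cal)
#> molecule curve peak: 330.5 +/- 29.2 molecules at t = 8.50 s

# accuracy of the two-colour alignment under experimental noise
run_alignment_benchmark(sim_config(n_pairs = 50, n_repeats = 5, seed = 7))
#> two-colour alignment benchmark (5 repeats x 50 pairs,
#>                                 sigma_p = 16, sigma_r = 19 nm):
#>   displacement from ground truth: 1.26 +/- 0.43 nm
```

The average trajectory reproduces the template's inward movement; the
copy-number line says the target protein peaks at ~330 molecules given
the measured median intensity ratio; the benchmark line says that with
target noise of 16 nm and reference noise of 19 nm per coordinate the
aligned trajectory sits ~1 nm from its ground truth.

A thin command-line front end is installed at `exec/endotrack`
(subcommands `average`, `align2c`, `calibrate`, `simulate`, `coverage`,
`distfit`, `bleach`; every subcommand takes `--seed` and `--out` and
writes a JSON run manifest).

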
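# batnight

Movement models for the nightly dispersal and return of roosting bats.

Insectivorous bats leave a communal roost after sunset, forage within a
bounded *core sustenance zone* (CSZ) around it, and return by dawn.
Radio-tracking yields a handful of irregularly timed fixes per bat per
night. `batnight` turns such detection tables into the population-level
summary used in this field — the ensemble mean squared displacement (MSD)
from the roost,

    <r^2(t)> = (1/N(t)) * sum_i | x_i(t) - x_i(0) |^2 ,

with a standard-error ribbon — and provides the models that explain its
two phases (a linear rise with slope `4D` for ~1.5 h, then a convex
decline to zero by ~8 h):

* radially symmetric **diffusion** on a disk (zero-flux boundary), with
  closed-form short-time (`4Dt`) and uniform-limit (`R^2/2`) MSD and the
  exact boundary-trace moment identity;
* **convection–diffusion** with uniform, power-law or saturating inward
  drift, including analytic steady states;
* the **non-autonomous "pull" model** `D(t) = D_c |1 - t/t_c|`,
  `v(t) = chi_c * t` (bats increasingly attracted to the roost);
* the **"leap frog" model**: diffusion on an apically shrinking domain
  `R(t)` (only the furthest-out bat flies home), solved in the scaled
  coordinate with a moving-boundary no-flux condition;
* **piecewise linear–quadratic MSD fitting** with 95% intervals and the
  derived ecological parameters `D = a11/4`, flight speed
  `v = sqrt(D/(pi t))`, departure delay `t_d = -a10/a11`, CSZ radius
  `R(0) = sqrt(2 a20)` and radius schedule
  `R(t) = sqrt(2(a22 t^2 + a21 t + a20))`;
* the **mechanism comparison**: the proportion of the population within
  100 m of the roost over the night under each mechanism, against the
  empirical cumulative return curve;
* seeded **agent-based generators** of bat-night trajectories (dispersal,
  leap frog, pull) and of irregular detection records, for testing the
  whole pipeline end to end.

## Worked example

Simulate a leap-frog night at the survey's conditions (25 bats, 8 h,
~12 fixes per night), estimate the MSD, fit the piecewise model, derive
parameters, and compare mechanisms:

```r
library(batnight)

cfg <- sim_config(n_bats = 25, mechanism = "leapfrog", step = 4, seed = 2024)
tracks <- simulate_leapfrog_night(cfg)
detections <- sample_detections(tracks, detection_model(seed = 2024))
curve <- compute_msd(interpolate_tracks(detections, dt = 200))

fit <- fit_piecewise_msd(curve, ts = 5400)
derived_parameters(fit)
#> D   = 44.6 m2/s   [40.3, 48.9]
#> v   = 3.77 m/s    [3.58, 3.95]  (t_ref = 1 s)
#> t_d = 833 s      [482, 1.26e+03]
#> R0  = 948 m      [832, 1.05e+03]
#> R(t) collapses at t = 2.78e+04 s (7.71 h)

compare_mechanisms(fit, tracks = detections, n_cells = 400)
#> Return-curve comparison within 100 m (dawn = 7.71 h)
#>     source terminal t_half
#> 1     pull    0.644   7.56
#> 2 leapfrog    1.000   7.71
#> 3     data    0.160     NA
```

Reading the output: the phase-1 slope over the full dispersal window gives
`D = 44.6 m^2/s` — well below the generator's `100 m^2/s`, because ~12
fixes per night make the interpolated MSD a chord-like underestimate and
because the zone boundary already bends the curve before 1.5 h. The same
biases act on real survey data, which is exactly why the package ships the
generator: estimator behaviour can be measured against a known truth. The
comparison table shows the discriminating pattern between the mechanisms:
the pull model brings bats inside 100 m earlier (crossing one half at
7.56 h) but strands part of the population at dawn, while the leap-frog
domain collapse returns everyone, and the empirical curve climbs only
toward the very end of the night (its value at the fitted dawn, 7.71 h, is
still 0.16; it reaches 1 by 8 h).

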
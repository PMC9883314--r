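# ufdfmonitor

Model-based, in-line monitoring of protein **ultrafiltration/diafiltration
(UF/DF)** from Raman, density and UV sensor streams — for process-analytical
(PAT) scientists and downstream-processing engineers who want a filtered,
mechanistic estimate of buffer-exchange progress instead of raw DV counting.

## What it computes

During diafiltration at constant volume $V$ and permeate flow $F$, a solute
with sieving coefficient $\kappa$ follows the stirred-tank washout

$$\frac{dc}{dt} = c_{in}\frac{F}{V} - c\,\frac{F\kappa}{V}
  \;\Longrightarrow\;
  c(t) = \frac{c_{in}}{\kappa} - \Big(\frac{c_{in}}{\kappa}-c_0\Big)
  e^{-\kappa F t/V}.$$

Any sensor signal linearly related to such a species decays the same way. A
three-state **extended Kalman filter** tracks the remaining delta signal
$x_1$, the per-step exchange-rate exponent $x_2 = \kappa F \Delta t / V$ and
the terminal offset $x_3$ (observation $z = x_1 + x_3$), which smooths the
noisy signal and yields a running estimate of the sieving coefficient
$\kappa = x_2 V / (F\,\Delta t)$.

The chain that feeds the filter is included:

* **Raman chemometrics** — exposure normalization, mean-centered PLS
  protein-concentration models with Hotelling T²/Q outlier rejection, and a
  PCA **buffer-exchange score** (the component whose score decays
  exponentially), plus asymmetric-Whittaker baseline and Savitzky–Golay
  smoothing for visualization.
* **Density corrections** — temperature cross-multiplication against the
  Kell water reference, subtraction of the protein term
  $a_{prot}\,c_{prot}$, MAD-based bubble flagging.
* **UV** — Beer–Lambert conversion with the $R^2 > 0.97$ quality rule.
* A **synthetic UF/DF simulator** (three case-study presets: lysozyme, mAb,
  bsAb) generating ground truth plus realistic Raman/density/UV streams —
  concentration-correlated background, exposure step-downs, sapphire bands,
  bubbles, thermal drift — so the whole chain is testable end to end.

## Worked example

Simulate a lysozyme citrate→phosphate run and monitor it:

```r
library(ufdfmonitor)

ds <- simulate_dataset("lysozyme", dt = 0.5, seed = 42,
                       raman_bubble_rate = 0.01, density_bubble_rate = 0.02)
report <- run_monitor(ds)
print(report)
#> UF/DF monitor report
#>   DF window: 10.5 - 50 min
#>   EKF (Raman score): x2 = 0.04994  x3 = -0.01309
#>   terminal kappa estimate: 0.9988
#>   UV   RMSE: 0.00212 g/L  R2: 1
#>   Raman RMSE: 0.0244 g/L  R2: 1
#>   flags: density_unreliable = FALSE ; raman outliers = 0
```

Reading: the PCA buffer score decays with per-step exponent
`x2 = 0.04994`; at `F = 4.5` mL/min, `V = 45` mL and a 0.25 min step that
back-calculates to a sieving coefficient of `0.9988` — the preset's truth is
`1.0`, i.e. the citrate passes the membrane freely. The terminal offset
`x3 ≈ 0` says the normalized buffer signal ends at its floor (exchange
complete). Both concentration channels track the simulated truth, and the
density channel is usable (`density_unreliable = FALSE`). How long must a
DF run to deplete the original buffer? `residual_fraction(8, 1)` →
`0.0003354626`: eight DV at κ = 1 leave 0.034 %.

A thin CLI wraps the same functions
(`inst/cli/ufdf.R simulate|fit-pls|monitor|correct-density`).

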
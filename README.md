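# kowtools

Data reduction for octanol–water partition coefficients of ionizable and
neutral solutes.

## The problem

The octanol–water partition coefficient K_OW of a substance is defined at
the limit of zero solute concentration,

    log K_OW = log10(c_org / c_aq) |_{c -> 0}        (neutral species),

so shake-flask measurements taken at finite concentrations must be
extrapolated. For the ~95 % of active pharmaceutical ingredients that are
weak acids or bases this extrapolation is the dominant error source:
what analytics measures is the distribution coefficient

    log D = log10( (c_org,neutral + c_org,charged) / (c_aq,neutral + c_aq,charged) ),

and log D drops sharply as the solute concentration decreases, because the
aqueous pH drifts toward 7 and the degree of ionization grows — at zero
concentration an ionizable solute is fully ionized. Extrapolating log D
against concentration is therefore ill-posed, and published K_OW values for
the same drug scatter over several orders of magnitude.

`kowtools` implements two data-reduction methods that remove this error
source, for anyone reducing shake-flask partition data or curating
published partition coefficients:

* **Method 1 (pH extrapolation).** Regress the measured log D on the
  aqueous-phase pH and extrapolate to pH 7 — the pH the aqueous phase has
  at zero solute concentration. The intercept is log D_OW, converted to
  log K_OW with the Henderson–Hasselbalch ionization correction
  `log P = log D + log10(1 + 10^(pH − pKa))` (acids; exponent `pKa − pH`
  for bases) evaluated at pH 7.
* **Method 2 (conversion + concentration extrapolation).** Convert every
  measured log D to log P with that measurement's own pH, then regress
  log P on the overall solute concentration; the intercept at c = 0 is
  log K_OW. For neutral solutes (log D = log P) this plain concentration
  extrapolation is the only method needed.

The package also ships a forward simulator of the full biphasic
ionization/partition equilibrium (acid–base mass action, water
autoprotolysis, electroneutrality and phase mass balance, solved by
bracketed root finding) that serves as an independent oracle: series
generated by the simulator with a known log K_OW must be recovered by both
methods. An OECD quality-control rule (0.01 mol/L per-phase ceiling),
activity-coefficient routes to K_OW and D_OW, and screening statistics over
a curated table of published values round out the tool.

## Worked example

Simulate a four-point shake-flask series for a naproxen-like acid
(pKa 4.18, true log K_OW = 3.30, octanol:water 1:3) with 5 % concentration
noise, then reduce it with both methods:

```r
library(kowtools)
nap <- solute("naproxen", "acid", 4.18)
sys <- biphasic_system(P_neutral_0 = 10^3.3)
ser <- simulate(sys, seed = 42, solute = nap, noise = noise_model(0.05, 0.02))
summary(fit_method1(ser))
#> log K_OW estimate for naproxen by pH extrapolation to 7 (Method 1)
#>   log K_OW = 3.3294  (se 0.0434, n = 4, r^2 = 0.9901)
#>   intermediate log D_OW at pH 7 = 0.5087
#>   fitted line: slope = -0.9931, intercept = 7.461
#>   OECD QC: all phase concentrations within 0.01 mol/L
fit_method2(ser)
#> log K_OW estimate for naproxen by extrapolation to zero concentration (Method 2)
#>   log K_OW = 3.3154  (se 0.0278, n = 4, r^2 = 0.1965)
```

Both routes recover the configured value within their standard errors and
agree with each other to 0.014 log units; log D falls on a line in pH with
slope ≈ −1, the signature of the predominantly ionized regime. The
intermediate log D_OW (0.51) is the distribution coefficient at zero
concentration; adding the ionization correction at pH 7
(`log10(1 + 10^(7−4.18)) = 2.82`) yields log K_OW.

Screening the packaged curation of published values:

```r
kow_screen()$class_means
#>          class n_substances mean_spread
#> 1 nonionizable            4    1.087500
#> 2    ionizable           14    1.946429
```

— reported values for ionizable drugs scatter far more than for
nonionizable ones (glibenclamide alone spans 4.5 log units), which is the
motivation for the pH-based reduction.

A thin command-line wrapper with `convert`, `reduce`, `simulate` and
`screen` subcommands is installed at
`system.file("cli", "kowtool.R", package = "kowtools")`.

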
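# osteokin

Growth, proliferation and diffusion kinetics of osteosarcoma cell lines.

Osteosarcoma is the most common primary bone cancer and its cell lines show
strikingly different clinical behavior — some form tumors in days, others
barely at all. `osteokin` characterizes a panel of cell lines with three
minimal, few-parameter kinetic models that can be estimated from ordinary
characterization data (tumor volume curves in mice, confluence curves in
culture), and then asks how the fitted parameters relate to experimentally
measured phenotypes such as tumorigenicity.

The three models:

1. **Power-law tumor growth** (in vivo volume, mm³ vs days):
   dV/dt = α·V^β, with closed-form solution
   V(t) = [V₀^(1−β) + α(1−β)(t−t₀)]^(1/(1−β)). The growth rate α ranks
   lines into tiers; the scale exponent β (< 1: sublinear, no finite-time
   blow-up) clusters around the allometric values 2/3, 3/4, 5/6.
2. **Logistic proliferation** (in vitro confluence, % vs hours):
   dN/dt = ρ·N(1 − N/k) with k = 100 %. Each seeding condition (5 % and
   10 %) is fit independently over pooled replicates; the conditions are
   combined by the replicate-weighted average
   ρ̄ = (ρ₅n₅ + ρ₁₀n₁₀)/(n₅ + n₁₀).
3. **Point-source diffusion**: the linearized Fisher–Kolmogorov equation
   u_t = DΔu + ρu with u|₀ = C₀δ(x) gives a detectable radius growing
   asymptotically at the front speed 2√(Dρ), so each observed radius yields
   D_i = r_i²/(4ρt_i²). The mean D̄, its sd and the coefficient of
   variation CV = sd/D̄ summarize each line; CV < 50 % is the rule for "the
   front law applies".

A synthetic-data generator with known ground truth (parameterized by the
published estimates for the 17-line reference panel), a joined
parameter-vs-phenotype panel with its correlation matrix, CSV input
validation, a pipeline runner, and a small CLI complete the package.

## Worked example

Simulate one line at realistic noise, refit every stage, and inspect:

```r
library(osteokin)

tr <- reference_ground_truth()[["HOS"]]   # alpha 2.1797, beta 0.53, D 1.19e-2

vol <- simulate_volume_series(tr, seq(11, 28, by = 1.5),
                              noise_spec(volume_sigma = 0.05, seed = 42))
fit_power_law(vol$time_days, vol$volume_mm3)
#> Power-law growth fit
#>   alpha = 1.9553  beta = 0.5595  R^2 = 0.9930
#>   tier: High   beta cluster: 2/3   n = 12   converged: TRUE

conf <- simulate_confluence_series(tr, 5, seq(0, 96, by = 4),
                                   noise_spec(confluence_sigma = 2, seed = 42))
fit_logistic(conf$time_hours / 24, conf$confluence_pct, N0 = 5,
             cell_line = "HOS", condition = "5%")
#> Logistic proliferation fit (HOS, 5%)
#>   rho = 1.4880 /day  N0 = 5.00%  k = 100%  R^2 = 0.9963  (n = 1, 25 pts)

weighted_average_rate(1.48, 8, 1.58, 2)
#> Weighted proliferation rate: (1.48 x 8 + 1.58 x 2)/10 = 1.50 /day [Medium high]

estimate_diffusion(vol$time_days, volume_to_radius(vol$volume_mm3),
                   rho = 1.50, cell_line = "HOS")
#> Diffusion estimate (HOS)
#>   D_bar = 0.0126 mm^2/day  sd = 0.00215  CV = 17%  [model applies, High]
#>   over days 11-27.5 (12 timepoints)
```

The noisy refits land close to the generating truth (α 2.18 → 1.96 at 5 %
lognormal noise on 12 points; ρ 1.48 → 1.49; D 1.19×10⁻² → 1.26×10⁻² with
CV well under the 50 % validity cutoff). On the reference panel itself, the
weighted proliferation rate correlates with the experimental proliferation
level at 0.86:

```r
ref <- reference_estimates("panel")
panel <- build_panel(
  data.frame(cell_line = ref$cell_line, alpha = ref$alpha, beta = ref$beta),
  data.frame(cell_line = ref$cell_line, weighted_average = ref$rho),
  data.frame(cell_line = ref$cell_line, D_bar = ref$D_bar),
  ref[, c("cell_line", "TL", "CL", "IL", "ML", "PL")])
round(correlation_matrix(panel)["rho_weighted", "PL"], 2)
#> [1] 0.86
```

Whole-panel runs go through `run_pipeline(volumes, confluence, levels)` or
the CLI (`inst/cli/osteokin`), which writes `growth_fits.csv`,
`proliferation_fits.csv`, `diffusion.csv`, `panel.csv`, `correlation.csv`
and a run log.

## Package layout

- `R/power-law.R`, `R/logistic.R`, `R/diffusion.R` — the three models:
  closed forms, fits, tiers, clusters, the CV validity rule.
- `R/synthetic.R` — ground-truth generator (`simulate_panel()` and friends).
- `R/panel.R` — phenotype join and correlation matrix.
- `R/io.R`, `R/pipeline.R` — validated CSV schemas, config, run log,
  `run_pipeline()`.
- `R/reference.R`, `inst/extdata/` — the published reference estimates for
  the Lauvrak et al. (2013) osteosarcoma panel.
- `vignettes/osteokin-methods.Rmd` — models, assumptions, numerical
  choices, limitations.
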
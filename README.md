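# prefsolv

Preferential solvation analysis of solvatochromic indicators in binary
solvent mixtures.

When a solvatochromic dye is dissolved in a mixture of two solvents, the
composition of its first solvation shell (the cybotactic region) usually
differs from the bulk: one component, or a 1:1 solvent–solvent complex,
is enriched around the solute. Because the dye's charge-transfer band
position tracks the polarity it actually experiences, a titration of the
absorption maximum against bulk composition encodes the shell
composition. `prefsolv` implements the standard analysis chain for such
titrations, for spectroscopists and physical chemists studying
solute–solvent interactions:

- **Spectroscopic conversion** — molar transition energies from band
  maxima, `E_T (kcal/mol) = 28590 / λ_max (nm)`.
- **Kamlet–Abboud–Taft LSER** — ordinary least squares of
  `E_T = E_T⁰ + a·π* + b·α + c·β` on a panel of solvent descriptors
  (π* dipolarity/polarizability, α H-bond donor acidity, β H-bond
  acceptor basicity), separating the interaction types driving the
  solvatochromism.
- **Model-free shell composition** — the two-state inversion
  `x₂ˢ = (E_T − E_T1)/(E_T2 − E_T1)` and the preferential solvation
  parameter `δ_s,2 = x₂ˢ − x₂` (positive: the cosolvent S2 is enriched
  in the shell).
- **Two-step solvent-exchange model** (Bosch–Rosés /
  Skwierczynski–Connors) — the solute is solvated by S1, S2 or the S12
  complex with shell weights
  `(1−x₂)^m : f₂/₁·x₂^m : f₁₂/₁·(x₂(1−x₂))^{m/2}`, giving

      E_T(x₂) = [E_T1·(1−x₂)^m + E_T2·f₂/₁·x₂^m + E_T12·f₁₂/₁·(x₂(1−x₂))^{m/2}]
                / [(1−x₂)^m + f₂/₁·x₂^m + f₁₂/₁·(x₂(1−x₂))^{m/2}]

  optionally plus a water-structure correction term `ΔE_T` with constant
  `k` (the "corrected" variant, m = 2). Parameters are estimated by
  seeded multi-start bounded Levenberg–Marquardt; model variants
  (general m = 2, m = 3, corrected) are fitted side by side and ranked.
- **Statistical cell model** — linear regression of the shell log-odds
  `ln(x₂ˢ/(1−x₂ˢ))` on the bulk log-ratio `ln(x₂/x₁)`, whose intercept
  gives the solute–solvent interaction-energy difference `ω₁ − ω₂` in
  units of k_B·T.
- **Synthetic-data generators** — seeded titration series and LSER
  panels with known ground truth, so the whole pipeline is verifiable
  without raw spectra.

## Worked example

Simulate a strongly cosolvent-preferring mixture (a benzene + methanol
type system, f₂/₁ = 2.17) and analyze it end to end:

```r
library(prefsolv)

params <- scenario_library()[["Benzene + MeOH"]]
series <- simulate_exchange_series(params, grid = seq(0, 1, by = 0.1),
                                   noise = noise_spec(sigma = 0.05, seed = 42),
                                   mixture_name = "Benzene + MeOH")
report <- run_pipeline(series, pipeline_config(seed = 1, n_starts = 16))
report
#> <analysis_report> Benzene + MeOH (11 points)
#> variant comparison (best first):
#>   rank   variant m converged stability_flag         sd
#> 1    1   general 2      TRUE          FALSE 0.04717336
#> 2    2 corrected 2      TRUE          FALSE 0.04886813
#> 3    3   general 3      TRUE          FALSE 0.05737105
#> <exchange_fit> Benzene + MeOH (general, m = 2): 11 points
#> <exchange_params> variant = general, m = 2
#>   E_T1 = 60.74  E_T2 = 68.76  E_T12 = 62.94 kcal/mol
#>   f2/1 = 2.504  f12/1 = 1.502
#>   rss = 0.01335 (kcal/mol)^2, R^2 = 0.9998, sd = 0.04717 kcal/mol
#>   17/17 starts converged; best start 1
#> <cell_model_fit> slope = 1.3000, intercept = 0.3047 (n = 9, R^2 = 0.9976)
#>   omega1 - omega2 = 1.242e-21 J (1.242 x 10^-21 J) at T = 295.15 K
```

Reading the output: the variant comparison correctly prefers the
generating model (general, m = 2) on residual standard deviation; the
refitted `f2/1 = 2.504` sits within one standard error of the generating
2.17 at this noise level (the residual sd ≈ 0.047 kcal/mol matches the
injected σ = 0.05); and the cell-model intercept is positive, i.e. the
shell is enriched in methanol relative to the bulk, with an
interaction-energy difference of about 1.2 × 10⁻²¹ J. With `sigma = 0`
all generating parameters are recovered to machine precision.

Measured data enter the same way via `read_series("my_mixture.csv")`
(columns `x2,et` or `x2,lambda_nm`; `x2` is always the bulk mole
fraction of the polar/protic cosolvent), and `write_report()` serializes
the full analysis as JSON.

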
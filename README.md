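# pikaDemog

Life-history demography of the plateau pika (*Ochotona curzoniae*) — and of
mark-recaptured small-mammal populations generally — in R.

The plateau pika is a burrowing lagomorph endemic to the Qinghai–Tibet
alpine meadow. Its vital rates (survival, fertility, growth, abundance)
determine whether populations stay sparse and stable or irrupt to densities
that damage the grassland, so its demography matters to both evolutionary
ecologists and rangeland managers. `pikaDemog` implements the full analysis
chain for a three-year enclosure mark–recapture study of such a population,
with every stage reusable on other datasets and a seeded individual-based
simulator so the whole pipeline can be validated without field data.

## What it computes

* **Cohort (dynamic) life tables** from known-age individuals: survivorship
  `l_x`, deaths `d_x`, mortality `q_x`, person-time `L_x` (midpoint rule),
  `T_x`, and life expectancy `e_x = T_x / l_x`.
* **Triple-catch survival** between trapping sessions:
  `Ŝ = (B₂·R₁₃) / (B₁·(R₂₃ − 1))`,
  from counts caught in sessions I and II and recaptured in session III.
* **Fertility and Fisherian reproductive value**:
  `m_x = Σn · ½ / n_x` and
  `V_x = m_x + Σ_{t>x} l_t m_t / l_x`, with residual reproductive value
  `V_x − m_x` and net reproductive rate `R₀ = Σ l_x m_x` (the identity
  `V₀ = R₀` is asserted on every schedule).
* **A composite fitness index** over a 12-month mortality horizon,

  `r = b·(1 − 2Z + Z¹³)/(1 − Z) − M·(1 − M¹²)/(1 − M)`,

  where `b` is annual fecundity and `Z`, `M` monthly juvenile and adult
  mortality; plus the fast–slow tempo statistic `T = F/α`
  (fast > 0.60, slow < 0.15).
* **Charnov's dimensionless invariants** `E/α`, `C·E`, `I/m` and the
  `2R₀ = S·C·E·m/I` identity.
* **Ontogenetic growth** `dm/dt = a·m^0.75 − b·m` with its exact solution
  `m(t) = (a/b + (m₀^¼ − a/b)e^{−bt/4})⁴`, least-squares parameter fitting,
  and precision scoring.
* **Model-Mh jackknife abundance** (Burnham–Overton, orders 1–5 with
  sequential order selection) for closed populations with heterogeneous
  capture probabilities.

The published demographic tables of the study population ship as plain TSV
under `inst/extdata/` (see `pikaExtdata()`), including the 65-species
comparative vital-rates table used for the fitness ranking.

## Worked example

```r
library(pikaDemog)

report <- runPipeline()
round(report$summary, 4)
#>      q0_male      V_21_24    q0_female mean_S_adult           R0
#>       0.4912       4.7658       0.5156       0.6841       1.3985
#>       r_pika    rank_pika      tempo_T
#>       0.1125      43.0000       2.1275
```

Reading the numbers: about 49% of male pikas die in their first three
months (`q0_male`); a female entering the 21–24 month class is still worth
≈ 4.77 future daughters (`V_21_24`); mean adult female monthly survival
from the triple-catch table is 0.684; a newborn female produces ≈ 1.40
daughters over her lifetime (`R0`); and the pika's fitness index 0.1125
ranks 43rd of the 46 mammal species with complete vital rates — a
slow-growing, stable population despite a "fast" reproductive tempo.

Individual stages are one-liners:

```r
lt <- buildLifeTable(CohortCounts(c(228, 116, 51, 35, 22, 11, 5, 3, 2, 1),
                                  sex = "male"))
qx(lt)[1]                                   # 0.4912
tripleCatchSurvival(B1 = 10, R13 = 5, B2 = 85, R23 = 79)   # 0.5449
fitnessIndex(b = 2.10, Z = 0.418, M = 0.324)               # 0.1125

cfg <- simConfig(seed = 1)
pop <- simulatePopulation(cfg)
ch  <- simulateTrapping(pop, cfg, months = 1:3)
jackknifeMh(frequencyCounts(ch, session = 1))$Nhat
```

## Vignette

`vignettes/pika-demography.Rmd` documents the models, their assumptions,
the numerical choices (midpoint rule, trapezoid discretisation, order
selection), what the simulator does and does not emulate, and the known
inconsistencies in the published tables that the package treats as
errata.
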
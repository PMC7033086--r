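# fbpakin

Kinetic modeling of dynamic ¹⁸F-FBPA PET for estimating tissue boron-10
concentration in boron neutron capture therapy (BNCT) planning.

## What it does and for whom

BNCT efficacy and safety hinge on the boron-10 concentration in the
tumor *and* in the surrounding normal organs.  When
4-borono-L-phenylalanine (¹⁰B-BPA) is the boron carrier, its PET
analogue ¹⁸F-FBPA traces the same amino-acid transport, and the
tracer's **total distribution volume**

&nbsp;&nbsp;&nbsp;&nbsp;Vt = C\_tissue / C\_plasma (ml/ml, at equilibrium)

ties plasma boron to organ boron: `H_tissue = Vt x H_plasma`.
`fbpakin` is for physicists and pharmacokineticists working with
dynamic whole-body FBPA protocols (7 frames of 455 s) who need organ
Vt values and therapeutic-dose boron estimates from frame-wise
time-activity curves (TACs) and manual blood samples.

The package estimates Vt per organ with three linearizations for
reversible tracers, fitted over frames at/after an equilibration time
t\* (selected automatically so the maximum relative regression error is
at most 1%):

- **Logan plot**: `int C / C(T) = Vt * int Cp / C(T) + b`
- **Ichise MA1**: `C(T) = -(Vt/b) int Cp + (1/b) int C`
- **Ichise MA2**: `C(T) = g1 iint Cp + g2 iint C + g3 int C + g4 int Cp`,
  `Vt = -g1/g2` (no equilibration needed; restricted to frames from
  20 min by convention)

with AIC / reduced chi-square / Sy.x / R² model comparison, a
metabolite-corrected bi-exponential plasma input function, a
two-tissue-compartment study simulator for validation, and the
activity-to-boron chain `T = P*Vt`, `M = T/S`, `B = MW_B * M * 1e6`,
`H = B * (dose/I) * (MW_FBPA/MW_BPA-fr)`.

## Worked example

Printed organ boron from published mean Vt values and the 1 h plasma
boron level:

```r
library(fbpakin)
estimate_boron(c(pancreas = 0.94, liver = 0.81, brain = 0.39, lung = 0.16),
               plasma = 14.9, time = 60)
#> Estimated tissue boron-10 at the therapeutic dose (ppm):
#>       voi time_min   vt boron_ppm
#>  pancreas       60 0.94      14.0
#>     liver       60 0.81      12.1
#>     brain       60 0.39       5.8
#>      lung       60 0.16       2.4
```

Each row multiplies the organ's distribution volume by the plasma boron
level: a pancreas carrying 0.94 ml plasma-equivalent per ml of tissue
reaches 14.0 ppm boron-10 when plasma sits at 14.9 ppm after a 30 g
¹⁰B-BPA-fructose dose.

A full synthetic study (11 organs whose true Vt values span
0.94-0.16 ml/ml), end to end:

```r
study  <- make_study_fixture(sim_config(noise_cv = 0), seed = 1)
report <- run_study(study$tacs, study$blood)
report
#> Study report: 11 VOIs, models logan/ma1/ma2; selected ma2
#> Mean AIC by model:
#>  logan    ma1    ma2
#> -31.73 -43.03 -54.15
#> Vt (ml/ml):
#>              voi vt_logan vt_ma1 vt_ma2
#>         pancreas    0.924  0.924  0.925
#>            liver    0.796  0.796  0.795
#>  ...
#>            brain    0.381  0.381  0.382
#>             lung    0.157  0.157  0.157
```

All three estimators land within ~2% of the generating truth (the
small deficit is the documented sampling-design bias of the sparse
blood grid), MA2 shows the lowest AIC, and `report_tables(report, dir)`
writes `vt.csv`, `gof.csv`, `boron.csv`, `run.log` and a manifest.

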
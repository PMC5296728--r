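# PulseDecode

Cells encode environmental signals in the *dynamics* of transcription
factors — as amplitude-modulated (AM) pulses whose level fluctuates, or
frequency-modulated (FM) pulses whose timing fluctuates — and downstream
genes must decode them.  PulseDecode is a simulation and analysis toolkit
for the canonical decoding model: a single gene

```
∅ --k_b(t)--> mRNA --k_d(t)·m--> ∅
```

whose transcription rate `k_b(t)` *or* degradation rate `k_d(t)` is driven
by a noisy two-level pulsatile signal.  It quantifies how much the mRNA
output reveals about the input (mutual information, MI), what the
transmission costs thermodynamically (the entropy production rate of the
chain, "energetic cost" EC), and when input noise shifts the mean output
(stochastic focusing, SF).  It is aimed at people studying information
transmission and nonequilibrium costs in stochastic gene expression.

## What is inside

* **Signal generation** — AM/FM square waves with moment-matched log-normal
  or gamma noise: amplitude variance `Var`, refresh interval ("duration")
  `D`, or width noise `Noise` = CV² (`signalParams()`, `makeSignal()`).
* **Exact stochastic simulation** of the non-homogeneous birth–death
  process under piecewise-constant rates, in compiled code
  (`simulateTrajectory()`, `simulateEnsemble()`).
* **Closed-form master-equation solution** — for realized rate paths the
  copy-number law is Poisson(μ(t)) with `μ' = k_b(t) − k_d(t) μ`, solved
  exactly per segment (`muPath()`, `analyticPmf()`, `mixturePmf()`), plus a
  direct master-equation integrator as an independent oracle
  (`masterEquationPmf()`).
* **Mutual information** — plug-in estimator on (binned input level,
  output count) pairs, in bits (`binInput()`, `estimateMI()`).
* **Energetic cost** — Schnakenberg entropy production of the birth–death
  chain, σ = Σ (k_b P(m) − k_d (m+1) P(m+1)) ln[k_b P(m) / (k_d (m+1)
  P(m+1))] ≥ 0, zero exactly at detailed balance (`instantaneousEC()`,
  `timeAveragedEC()`, `ecFromRates()`).
* **Experiment pipelines** — ON/OFF-time sweeps at fixed period, duration
  sweeps, MI–EC correlation and stochastic-focusing curves, with output
  mean calibration and batch error bars (`sweepOnOff()`, `sweepDuration()`,
  `sfCurve()`, `miEcCorrelation()`, `calibrateMeanOutput()`).
* **Config-driven runs** — YAML experiment files (shipped under
  `inst/extdata/`), CSV results with a checksummed JSON manifest, and a
  thin CLI (`inst/cli/pulsedecode`) with subcommands `simulate`,
  `mi-sweep`, `ec-sweep`, `duration-sweep`, `sf-curve`, `validate`.

## Worked example

An amplitude-modulated signal on the transcription rate (levels 0.8/0.1,
period 200 s, variance 0.01, refresh 3 s), decay rate calibrated so the
mean output is 15 copies:

```r
library(PulseDecode)

p  <- signalParams(amplitudeVar = 0.01, totalTime = 1800)
kd <- calibrateMeanOutput(p, 15)      # 0.03 = <k_b>/15
sig <- makeSignal(p, seed = 1)
ens <- simulateEnsemble(modelConfig(sig, kd), 200, seed = 2)

times <- sampleTimes(ens)
x  <- binInput(signalValueAt(sig, times), "quantile", 8)$symbols
mi <- estimateMI(rep(x, each = 200), as.vector(countsMatrix(ens)))
ec <- ecTimeAverage(ecFromRates(sig, kd, times))
cat(sprintf("MI = %.3f bits   EC = %.3f   mean output = %.2f\n",
            mi, ec, mean(countsMatrix(ens))))
#> MI = 0.218 bits   EC = 0.333   mean output = 14.38
```

The mRNA carries about 0.22 bits about the instantaneous input level, at an
entropy production of about 0.33 per second.  The same quantities over an
ON-time grid:

```r
sw <- sweepOnOff(seq(40, 160, 40), c(0, 0.01), nReplicates = 200, seed = 1)
sw[, c("on_time", "off_time", "noise", "mi", "mi_se", "ec", "mean_output")]
#>   on_time off_time noise    mi mi_se    ec mean_output
#> 1      40      160  0.00 0.059 0.001 0.211      14.922
#> 2      80      120  0.00 0.199 0.004 0.245      15.077
#> 3     120       80  0.00 0.278 0.005 0.200      14.983
#> 4     160       40  0.00 0.167 0.003 0.142      14.960
#> 5      40      160  0.01 0.088 0.004 0.299      14.930
#> 6      80      120  0.01 0.214 0.006 0.335      15.046
#> 7     120       80  0.01 0.286 0.006 0.262      15.072
#> 8     160       40  0.01 0.167 0.006 0.189      15.028
```

MI has an interior optimum in the ON-time, and at long OFF-times the extra
amplitude noise *raises* MI (0.059 → 0.088 bits at ON = 40) while also
raising the energetic cost — information gain is paid for in entropy
production.  The methods vignette (`vignettes/pulse-decoding.Rmd`) explains
the estimators, defaults and design choices in detail.

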
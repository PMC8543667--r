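# fpetdopa

Quantification of **task-specific dopamine synthesis** from dynamic
6-[18F]FDOPA PET acquired with a functional-PET (fPET) protocol: a 20:80
bolus + constant infusion over a 50-min scan, monetary incentive delay
(MID) task blocks embedded in the acquisition, and within-scan separation
of task-induced from baseline tracer uptake.

The package is aimed at PET methodologists who want a complete, testable
reference implementation of the fPET-FDOPA analysis chain, and at anyone
who needs a ground-truth simulator for functional PET kinetics.

## The model in brief

6-FDOPA is trapped after decarboxylation by AADC, so its net influx
constant indexes dopamine synthesis. For the irreversible two-tissue
compartment model

K<sub>i</sub> = K<sub>1</sub> k<sub>3</sub> / (k<sub>2</sub> + k<sub>3</sub>)  [1/min],

the Patlak slope of the tissue curve against normalized time
x(t) = &int;C<sub>p</sub>d&tau; / C<sub>p</sub>(t) from t* = 25 min.
Task blocks transiently raise AADC activity (k<sub>3</sub>); the package's
GLM separates each TAC into per-block ramp-and-hold task components (slope
1 kBq/mL per frame inside a block), a gray-matter baseline component and a
motion component, after zero-phase low-pass filtering (2.5-min cutoff).
Ramp coefficients convert to task-specific K<sub>i</sub> via
&beta;<sub>j</sub> / (&Delta;t &middot; C&#773;<sub>p,j</sub>); the
baseline component is Patlak-fitted for baseline K<sub>i</sub>; per-block
values are averaged per condition with task-performance weights, and
percent signal change is PSC = K<sub>i,task</sub>/K<sub>i,baseline</sub> × 100.

Before the GLM, brain curves are corrected for the blood-brain-barrier-
crossing radiometabolite 3-OMFD: a one-tissue model fitted on the
occipital reference region (task/motion nuisance terms estimated jointly)
is convolved with the metabolite input function and subtracted everywhere,
together with a fixed 5% whole-blood component. Arterial input functions
are assembled from blood samples as whole blood × plasma ratio line ×
parent fraction, with the literature bolus 3-OMFD fraction adapted to
bolus + infusion by superposition.

A fully parameterised synthetic generator (kinetics, blood curves, motion,
adaptive-staircase MID behavior) records its ground truth, so every
reported quantity is validated by parameter recovery. See the vignette
`vignettes/fpet-dopamine-quantification.Rmd` for the model, the numerical
choices and their rationale.

## Worked example

Simulate a session whose striatal baseline K<sub>i</sub> is 0.009/min with
task increases of 0.014 (gain blocks) and 0.009/min (loss blocks), then
run the full pipeline:

```r
library(fpetdopa)

cfg   <- fpetConfig(seed = 1L)
scene <- kineticScene(baselineKi = 0.009,
                      taskDeltaKi = c(0.014, 0.009, 0.014, 0.009))
ses <- simulateSession(cfg, scene)
res <- runQuantification(cfg, ses$tacs, ses$bloodSamples, ses$motion,
                         ses$trialLog)
print(res)
#> fPET quantification results
#>    region Ki_baseline patlak_r2 Ki_gain Ki_gain_unweighted PSC_gain  Ki_loss
#>  striatum    0.009063         1 0.01399            0.01399    154.4 0.008971
#>  Ki_loss_unweighted PSC_loss Ki_gain_minus_loss PSC_gain_minus_loss
#>            0.008971    98.99           0.005019               55.39
#> reference fit: K1=0.05998, k2=0.04998 (RMS 0.000415 kBq/mL)
```

The generative constants are recovered within 1%: baseline K<sub>i</sub>
0.00906 vs 0.009, gain 0.01399 vs 0.014, loss 0.00897 vs 0.009/min. The
PSC columns express the task conditions relative to baseline (154% for
gain), and `Ki_gain_minus_loss` is the within-subject condition contrast.
The reference-region one-tissue fit reproduces the generative occipital
constants (0.06, 0.05) to four digits.

Behavioral side — reaction times simulated from a linear amount
sensitivity of −2.36 ms/€ (18 subjects, 10 trials per amount level,
10 ms noise) and modelled by stepwise polynomial regression:

```r
set.seed(1)
a <- rep(c(-3, -2, -1, 1, 2, 3), each = 10)
rts <- do.call(rbind, lapply(1:18, function(s) {
  rt <- -0.18 - 2.36 * a + rnorm(length(a), 0, 10)
  data.frame(amount = a, rt = rt - mean(rt))
}))
m <- stepwisePolyfit(rts$amount, rts$rt)
print(m)
#> RtModel (stepwise polynomial, RT vs amount):
#>   included: linear
#>  intercept     linear  quadratic
#>  6.909e-17 -2.228e+00         NA
```

Only the linear term enters (the quadratic stays above the 0.05 entry
threshold) and its coefficient, −2.23 ms/€, matches the generative slope
within sampling error.

A thin command-line wrapper is installed at `inst/scripts/fpetdopa`:

```sh
Rscript inst/scripts/fpetdopa simulate --out-dir session --seed 1
Rscript inst/scripts/fpetdopa quantify --tacs session/tacs.tsv \
    --blood session/blood.tsv --motion session/motion.tsv \
    --trials session/trials.csv --out-dir results
```

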
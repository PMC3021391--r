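# dcmnet

Bilinear dynamic causal modelling (DCM) of a four-region frontal motor
network, with free-energy model inversion, group Bayesian model selection
and a test-retest reliability battery — everything needed to ask, on
synthetic cohorts with known ground truth, the two questions that decide
whether DCM is usable in clinical and pharmacological fMRI: *is model
selection reproducible?* and *are the parameter estimates reliable?*

The network links left dorsolateral prefrontal cortex (PFC), lateral
premotor cortex (PM), pre-supplementary motor area (preSMA) and primary
motor cortex (M1) during an action-selection task (externally *specified*
vs freely *chosen* button presses). Neural dynamics follow the bilinear
state equation

    dz/dt = (A + u2 * B) z + C u

with intrinsic couplings `A` (Hz), context-dependent coupling changes `B`
(the psychophysiological interaction of the chosen-vs-specified context
`u2`), and driving inputs `C` (trial onsets `u1` into PFC, plus `u2` in
half of the models). Region activity maps to BOLD through the balloon
model, and each (session, model) pair is inverted by variational Laplace,
yielding a posterior over couplings and a free-energy bound `F` on the log
model evidence (`F = accuracy - complexity`, the complexity being the KL
divergence of posterior from prior). Forty-eight models — six intrinsic
structures x eight contextual-modulation patterns — are compared by
fixed-effects (summed `F`, Group Bayes Factors) and random-effects
(hierarchical Dirichlet, exceedance probabilities) procedures.

Who this is for: methodologists studying the reproducibility of effective
connectivity estimates, and anyone who needs a transparent, fully
synthetic DCM test bed where the generating model and parameters are known
exactly.

## Worked example

Three healthy older controls, two sessions each, generating model E2
(context modulates PFC<->preSMA); compare E2 against E1 (context modulates
PFC<->PM):

```r
library(dcmnet)

e2 <- buildModel("E", 2)
e2
#> DcmModel E2 (set E, pattern 2): 10 intrinsic, 2 bilinear, 1 driving

cfg <- defaultStudyConfig(nYoung = 0, nOC = 3, nPD = 0)
coh <- generateCohort(cfg, seed = 42)

ms <- buildModelSpace()
fits <- list(); so <- integer(0)
for (k in seq_along(coh$sessions)) for (mid in c("E2", "E1")) {
  fits <- c(fits, invertSession(ms[[mid]], coh$sessions[[k]])); so <- c(so, k)
}
tab <- evidenceTable(fits, coh$roster, so)

fixedEffects(tab)
#> Fixed-effects group model comparison
#>  model     sumF deltaF postProb
#>     E2 -1590.14   0.00   0.9994
#>     E1 -1597.57  -7.43   0.0006

randomEffects(tab, seed = 1)
#> Random-effects (hierarchical Dirichlet) group model comparison
#>  model alpha expectedProb exceedance
#>     E2  6.67       0.8341      0.982
#>     E1  1.33       0.1659      0.018
```

The generating model wins by both procedures: the summed log-evidence
margin of 7.4 nats is "very strong" evidence (Bayes factor > 150), and the
exceedance probability — the belief that E2 is more likely than any other
model in the set for a random subject of this group — is 0.98. Reliability
statistics work the same way from the posterior panels, e.g. the
sign-consistency test for a bilinear term preserved in 11 of 15 subjects:

```r
st <- signConsistencyTest(11, 15)
cat(sprintf("chi-squared = %.1f, df %d, p = %.2f\n", st$chiSqReported, st$df, st$p))
#> chi-squared = 3.3, df 1, p = 0.07
```

A command-line pipeline (`inst/scripts/dcm-pipeline.R`) wraps the same
functions as `simulate` / `invert` / `bms` / `reliability` /
`reproduce-study` subcommands with resumable inversion runs.

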
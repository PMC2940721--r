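# thermocrm

Thermodynamics-based modeling of transcriptional regulation by enhancers
(cis-regulatory modules, CRMs). Given a CRM sequence, the binding motifs
(PWMs) of a set of transcription factors, and the TFs' concentration
profiles over spatial or temporal bins, `thermocrm` predicts the expression
profile the CRM drives, and trains the model's free parameters against
observed readouts. It is aimed at regulatory genomicists studying how
activators and repressors combine — synergistically, cooperatively, or
through short-range quenching — to encode an expression pattern in sequence.

## The model

Expression is the equilibrium fractional occupancy of the basal
transcriptional machinery (BTM) at the promoter. Summing the statistical
weights of all binding-site configurations σ,

    Z_ON  = Σ_σ W(σ) Q(σ)        Z_OFF = Σ_σ W(σ)
    E     = q_btm Z_ON / (q_btm Z_ON + Z_OFF)

where a bound site contributes `q(S) = K·[TF]_rel·exp(LLR(S) − LLR(S_max))`
to W, adjacent bound partner sites multiply W by a cooperativity weight ω
(within a distance cutoff), and Q collects the TF–BTM interaction weights α.
Repression is modeled either by direct BTM interaction (α < 1) or by
short-range repression: three-state repressor sites whose bound-effective
state (weight β_R) makes all activator sites within d_R unbindable. The
number of simultaneous activator–BTM contacts is capped by N_MA: 1 gives the
additive model `Q = Σ α_i`, ∞ the multiplicative (synergistic) model
`Q = Π α_i`. All partition functions are computed exactly by dynamic
programming (linear in site count for bounded cooperativity range) and are
verified against brute-force enumeration oracles in the test suite.

Sites are annotated by scanning both strands with each PWM and keeping
windows whose log-likelihood-ratio score exceeds 0.4 of the optimal site's
score. Training maximizes the average per-CRM Pearson correlation (CC),
alternated with a per-CRM-rescaled sum of squared errors, using Nelder–Mead
and BFGS stages with random restarts; assessment includes CC > 0.65 counts,
k-fold cross-validation (CVCC), permuted-PWM negative controls, in-silico
TF knock-downs, best-K curves, and bootstrap model comparison. Conservation
filters restrict the annotation to sites conserved across orthologous
sequences, strictly or tolerating lineage-specific turnover.

## A worked example

```r
library(thermocrm)

# a synthetic patterning study: 10 CRMs, 2 activators on opposing gradients,
# 2 repressors on stripes, observed profiles generated by the model itself
sim   <- simulate_dataset(n_crms = 10, noise_sd = 0, rng_seed = 1)
sites <- annotate_dataset(sim$dataset, sim$pwms)

fit <- fit_model(sim$dataset, sites,
                 options = fit_options(restarts = 5, rng_seed = 1))
fit
#> Fit result: train avg CC 1.0000 (SSE 0.0000), 10 CRMs
#> Thermodynamic model parameters (mode=direct, n_ma=Inf)
#>   binding_k: actA=10 actP=10 repS1=10 repS2=10
#>   alpha:     actA=6 actP=6 repS1=0.2 repS2=0.25
#>   q_btm: 0.05 (basal expression 0.04762)

report <- evaluate_model(fit$params, sim$dataset, sites)
report
#> Model report: avg CC 1.0000 over 10 CRMs; 10 with CC > 0.65

# contribution of one repressor: re-predict with its concentration zeroed
knockdown(fit$params, sim$dataset, sites, "repS1")$avg_cc
#> [1] 0.7777532

# negative control: the same protocol with randomly permuted PWMs
perm  <- lapply(seq_along(sim$pwms), function(i) permute_pwm(sim$pwms[[i]], 1000 + i))
fit0  <- fit_model(sim$dataset, annotate_dataset(sim$dataset, perm),
                   options = fit_options(restarts = 5, rng_seed = 1))
fit0$train_cc
#> [1] 0.4705784
```

On this noiseless dataset the optimizer lands on the generating parameters
themselves (training average CC 1.0), while the permuted-motif control
plateaus around 0.47 — the ~0.5-CC gap is the sequence signal. In general
several (K, α) combinations can predict near-identical profiles, so only
predictive recovery, not parameter identifiability, is guaranteed. The
knock-down CC (0.78 after zeroing the repressor `repS1`) quantifies how much
of the fit that repressor carries.

A command-line front end wrapping the same functions is installed at
`inst/cli/thermocrm.R` with subcommands `annotate`, `predict`, `fit`,
`eval`, `knockdown`, `compare`, `simulate` and `conserve`; every run writes
a log with its seed and input checksums beside its outputs.

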
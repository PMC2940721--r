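---
title: "Thermodynamic models of enhancer readout: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic models of enhancer readout: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermocrm)
```

## The model

`thermocrm` predicts the expression readout of a cis-regulatory module (CRM,
enhancer) from its sequence, the binding specificities (PWMs) of a set of
transcription factors (TFs), and the TFs' concentration profiles across a set
of spatial or temporal bins. The model is an equilibrium statistical-mechanics
description of the CRM, in the Shea–Ackers tradition: gene expression is
equated with the fractional occupancy of the basal transcriptional machinery
(BTM) at the promoter.

A *configuration* $\sigma$ assigns a bound/unbound state to every annotated
binding site. Its statistical weight factors into a TF–DNA part $W(\sigma)$
and, when the BTM is bound, a TF–BTM part $Q(\sigma)$. With

$$Z_\mathrm{ON} = \sum_\sigma W(\sigma)\,Q(\sigma), \qquad
  Z_\mathrm{OFF} = \sum_\sigma W(\sigma),$$

the predicted expression is

$$E \;=\; \frac{q_\mathrm{btm}\, Z_\mathrm{ON}}
              {q_\mathrm{btm}\, Z_\mathrm{ON} + Z_\mathrm{OFF}},$$

where $q_\mathrm{btm}$ is the statistical weight of BTM binding at the
promoter; the empty configuration contributes weight 1 to both sums, so the
expression of a site-free sequence is the basal level
$q_\mathrm{btm}/(1+q_\mathrm{btm})$.

A bound site $S$ of TF $f$ contributes

$$q(S) \;=\; K_f \,[\mathrm{TF}]_\mathrm{rel}\,
             e^{\,\mathrm{LLR}(S) - \mathrm{LLR}(S_\mathrm{max})},$$

the Berg–von Hippel mismatch form: $K_f$ is a lumped constant (association
constant of the optimal site times the concentration scale; the two are not
separately identifiable and are fitted as one free parameter per TF),
$[\mathrm{TF}]_\mathrm{rel}$ the bin's relative concentration, and the
exponential the affinity penalty of the site relative to the optimal word
$S_\mathrm{max}$. Adjacent bound sites (no bound site in between) of declared
partner TFs multiply $W$ by a cooperativity weight $\omega$ when their
edge-to-edge gap $d$ satisfies $0 < d \le d_c$ (default $d_c = 50$ bp). The
distance profile of cooperativity is not observable at the resolution we
target, so a piecewise-constant form was chosen; both $\omega$ and $d_c$ are
configurable per pair.

### Repression

Two mechanisms are implemented:

* **Direct interaction** (`mode = "direct"`): every bound TF contacts the
  BTM; activators with weight $\alpha > 1$, repressors with $\alpha < 1$.
  $Q(\sigma)$ is the product of the $\alpha$'s of bound TFs.
* **Short-range repression** (`mode = "srr"`): a bound repressor never
  contacts the BTM. Each repressor site instead has three states — unbound,
  *bound-only* (weight $q$), and *bound-effective* (weight $\beta_R\, q$).
  A bound-effective repressor closes the surrounding chromatin: no activator
  site within $d_R$ (edge-to-edge; default 250 bp) may be bound in the same
  configuration. $\beta_R$ is interpretable as the equilibrium constant of
  the chromatin-closing reaction: $\beta_R \to 0$ removes repression,
  $\beta_R \to \infty$ deletes every activator site in range. Setting
  $d_R \approx 10$ bp (`competition_mode()`) reduces the mechanism to
  competitive binding at overlapping sites, which is how the
  competitive-repression hypothesis is tested. Overlapping repression zones
  combine as a simple union, and by default a bound-effective repressor does
  not block other repressor sites (`block_repressors` switches this).

### Activator synergy

How the $\alpha$'s of several bound activators combine is controlled by
$N_{MA}$, the maximum number of activators that may simultaneously contact
the BTM:

* $N_{MA} = \infty$ (default): the **multiplicative** model,
  $Q = \prod \alpha_i$, which produces transcriptional synergy even without
  cooperative DNA binding.
* $N_{MA} = 1$: the **additive** model, $Q = \sum \alpha_i$ over bound
  activators — each configuration has at most one activator–BTM contact.
* $1 < N_{MA} < \infty$: the **limited-contact** model. Each bound activator
  either contacts the BTM (factor $\alpha$) or does not (factor 1); $Q$ sums
  over all non-empty contact subsets of size at most $N_{MA}$ (an empty
  activator set has $Q = 1$). With $N_{MA} = 1$ this reduces exactly to
  $\sum \alpha_i$. The multiplicative model is implemented as forced full
  contact rather than the $N_{MA}\to\infty$ subset-sum limit, matching the
  product form above; both conventions are exposed through
  `partition_direct()` and `partition_limited_contact()`.

The two extremes are distinguishable in principle by their saturation
behavior: with $n$ identical strong sites at saturating concentration,
expression approaches $q_\mathrm{btm}\alpha^n/(q_\mathrm{btm}\alpha^n+1)$
under the multiplicative model but only
$q_\mathrm{btm}\,n\alpha/(q_\mathrm{btm}\,n\alpha+1)$ under the additive
model — cooperative DNA binding cannot rescue the difference because binding
is already saturated. The acceptance suite verifies both closed forms
numerically at $q = 10^6$.

## Exact computation

$Z_\mathrm{ON}$ and $Z_\mathrm{OFF}$ sum over $2^n$ (DirectInt) or up to
$3^n$ (SRR) configurations; the package computes them exactly by dynamic
programming over sites sorted by start coordinate, summing over the nearest
occupied site to the left:

$$Z_\mathrm{OFF}(i) = q(i)\Big(1 + \sum_{j \in \Phi(i)} \omega(i,j)\,
Z_\mathrm{OFF}(j)\Big),$$

with $\Phi(i)$ the non-overlapping sites left of $i$, and the analogous
recurrence with $\alpha_{f(i)}$ for $Z_\mathrm{ON}$. Because adjacent bound
sites cannot overlap, site ends increase along any configuration, which makes
the nearest-left-neighbor sum exact. With cooperativity restricted to a
bounded range the non-cooperative mass is kept in prefix sums and only the
sites within $d_c$ are rescanned, so the DP is linear in site count (the
acceptance suite times three doublings). The limited-contact DP carries an
extra contact-count dimension and removes the all-no-contact term of
configurations with at least one bound activator by subtracting two plain
weight-sum DPs. The SRR DP sweeps left to right with a merged state
(last bound site, last bound activator, last bound-effective repressor),
which is all a future site's legitimacy can depend on.

Every DP is checked against an independent brute-force enumerator
(`brute_force_partition()`, `brute_force_srr()`) that loops over all
configurations — and, for limited contact, over all activator contact
subsets — on hundreds of random instances with overlapping sites, mixed
roles, and anti-cooperative as well as cooperative $\omega$; agreement is
required to a relative $10^{-9}$ (observed: $\sim 10^{-15}$). The DPs are
implemented in C++ (Rcpp) for the direct and limited-contact models, which
sit in the training hot path, and in R for SRR, which the package exercises
at evaluation scale.

Weights are carried in double precision and the partition functions validate
finiteness, stopping with an informative error on overflow. The study-regime
inputs (site weights up to $10^6$, of order 100 sites) stay far below
overflow; a log-space DP was considered and rejected because it would
complicate the exact-equality contract with the enumeration oracle.

### Degenerate inputs and tie-breaks

A sequence shorter than every PWM yields an empty site list (not an error);
an empty site list yields basal expression in every bin. Strand ties at a
window keep the `+` strand. Windows containing an ambiguous base are
skipped. Site-calling uses a strict `>` threshold at
`threshold_frac * llr_max` (default 0.4, the weak threshold that admits
low-affinity sites while bounding run time). Abutting sites (gap 0) are not
treated as cooperative under the $0 < d \le d_c$ rule. The correlation of a
constant profile is defined as 0, which penalizes flat predictions without
aborting training.

## Parameter training

Free parameters are mapped to an unconstrained space — $\log K$,
$\log(\alpha - 1)$ for activators, $\mathrm{logit}(\alpha)$ for repressors,
$\log(\omega - 1)$, $\log \beta$, $\log q_\mathrm{btm}$ — so role bounds
(activator $\alpha > 1$, repressor $0 < \alpha < 1$, $\omega \ge 1$) hold by
construction for every optimizer iterate. From each random start (log-uniform
within documented bounds: $K \in [10^{-3}, 10^3]$, activator
$\alpha \in (1, 100]$, repressor $\alpha \in [10^{-3}, 1)$,
$\omega \in [1, 100]$, $\beta \in [0, 100]$,
$q_\mathrm{btm} \in [10^{-4}, 1]$), training runs two cycles of a
Nelder–Mead simplex stage followed by a BFGS quasi-Newton stage with central
numerical gradients (step $10^{-4}$ in transformed space), alternating the
average-CC objective with the scaled-SSE objective; 5 restarts by default,
best result by the primary objective kept. The alternation schedule and
restart count are this package's choices; both are configurable through
`fit_options()`.

Two objectives are provided: the mean over CRMs of the Pearson correlation
between predicted and observed profiles, and a sum of squared errors in
which each CRM first receives a free non-negative scale with the closed form
$s = \max(0, \langle p,o\rangle/\langle p,p\rangle)$ — observed profiles are
on an arbitrary 0-to-1 scale, so only shapes are compared. `cross_validate()`
shuffles CRMs into folds deterministically under the seed, fits on each
training split and averages the held-out CCs (the CVCC); the partition is
recorded because the CVCC depends on it.

Evaluation reports per-CRM CC, the average, and the number of CRMs with CC
strictly above 0.65. `knockdown()` rescores the model with one TF's
concentration zeroed, without refitting. `best_k_curve()` averages each
model's top-K CRMs, with companion (e.g. knock-down) curves averaged over
the *same* K CRMs as their parent. `compare_models()` estimates per-CRM
significance of a CC improvement by a seeded bootstrap over bins and
combines CRMs by Fisher's method — the per-CRM test is this package's
convention, reported as such — alongside the descriptive better/worse counts
(winner CC $\ge$ 0.65 and $|\Delta CC| \ge 0.05$).

## Conservation filters

`filter_strict()` keeps a reference-species site only if the aligned window
scores above the same LLR threshold in each of the first $n$ species of a
supplied alignment; `filter_turnover()` tolerates lineage-specific loss by
requiring only $m$ of $n$ species (default
$m = \lceil n/2\rceil + 1$), an m-of-k rule chosen as a transparent
stand-in for a turnover-significance test. Any gap inside the aligned window
counts as non-conserved in that species; both filters reduce to the
unfiltered annotation at $n = 1$, and strict filtering is nested in $n$.
On a planted-turnover fixture, where functional activator sites are ablated
in one lineage, the strict filter removes them and the average CC drops
while the turnover filter retains them — the qualitative behavior expected
when enhancer function is carried partly by sites that are deeply conserved
yet lost in single lineages.

## The synthetic test bed

All tests and the acceptance script run on data from `simulate_dataset()`,
which emulates a spatial-patterning study at a deliberately modest scale:
10 CRMs of 1 kb, four TFs (two activators on opposing sigmoid gradients, two
repressors on stripe gradients), PWMs of width 8 with consensus-base
probability 0.85, 4–8 planted sites per CRM at 0.6–1.0 of the optimal LLR,
and 60-bin profiles — the analysis window of a 100-bin axis modeled
directly. Each CRM is driven mainly by one of the two activators so profiles
are spatially patterned rather than uniformly saturated. Generating
parameters are $K = 10$ for every TF, activator $\alpha = 6$, repressor
$\alpha = 0.2/0.25$, $q_\mathrm{btm} = 0.05$; observed profiles are the
model's own predictions rescaled to a per-CRM maximum of 1, with optional
truncated Gaussian noise. Everything is a pure function of its seed.

What passing on this bed does and does not show: recovery of noiseless
self-generated data (training average CC $\ge 0.95$, 10-fold CVCC
$\ge 0.85$, permuted-PWM control at least 0.3 lower) demonstrates that the
pipeline — annotation, partition function, optimizer, cross-validation — is
internally consistent and that predictions carry real sequence signal, not
that the model explains any real enhancer; real expression data add
measurement noise, unmodeled TFs, chromatin context, and mis-specified
motifs, none of which the generator emulates. Individual parameters are not
asserted to be identifiable (several $(K, \alpha)$ combinations predict
nearly identical profiles); only predictive recovery is.

## Known limitations

* Monotonicity of expression in TF dose holds in the plain setting only:
  a repressor that cooperates with an activator ($\omega > 1$ across roles)
  can *raise* expression as its occupancy grows, and a weak activator whose
  site overlaps a strong activator's site can lower it. The monotonicity
  test suites therefore use homotypic, non-overlapping instances; the
  general-instance suites cover the full setting via enumeration equality.
* Repression strength does not decay with distance within $d_R$, and two
  overlapping repression zones combine as a union.
* Heterotypic cooperativity is supported by the engine but not exercised in
  fitting defaults, where the parameter count would grow quadratically in
  the number of TFs.
* Equating expression with equilibrium BTM occupancy ignores transcription
  initiation/elongation dynamics and chromatin state.
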
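---
title: "Models and methods behind mignet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mignet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`mignet` synthesises networks of randomized trials of prophylactic
migraine medications in two steps: conventional pairwise random-effects
meta-analysis of the direct evidence, then a Bayesian random-effects
network meta-analysis (NMA) that combines direct and indirect evidence,
followed by ranking, consistency and publication-bias diagnostics. This
vignette records the models, the defaults, and the design decisions that
were genuinely open.

## Data model

The unit of input is the *arm record*: one treatment arm of one study for
one endpoint, in a long-format CSV
(`study_id, year, design, blinding, endpoint, treatment, n, events, mean,
sd, follow_up_weeks`). Binary endpoints carry event counts; continuous
endpoints carry the arm mean and SD. Endpoints 1–2 (monthly migraine
headache days, headache frequency) are continuous and analysed as raw
mean differences — the trials in this literature report them on a common
scale, so no standardisation is applied. Endpoints 3–9 are binary and
analysed as odds ratios. Endpoint 3 (≥50% reduction in attacks) is the
only outcome where a larger effect is better; every other endpoint is a
harm or a withdrawal, ranked lower-is-better. These directions are
attached to the endpoint registry rather than inferred, because ranking
output is meaningless if the direction is implicit.

Treatment names are case-folded and validated against the seven-treatment
registry (placebo is always the reference); unknown names are rejected
unless explicitly allowed, so typos cannot silently grow the network.
Studies reporting an endpoint in only one arm cannot contribute a
comparison and are dropped *per endpoint* with a warning. A network that
is not connected for an endpoint is an error, not a silent subnetwork
fit: treatments outside a closed network cannot be compared at all, which
mirrors the exclusion rule used when assembling the evidence base.

## Pairwise meta-analysis

Study effects are the raw mean difference
(`se = sqrt(sd_a^2/n_a + sd_r^2/n_r)`) or the log odds ratio from the 2×2
table (`se = sqrt(1/a + 1/b + 1/c + 1/d)`). When any cell of the table is
zero, 0.5 is added to all four cells of that table — the conventional
continuity correction; studies with zero events in *both* arms carry no
information about the odds ratio and are excluded from that endpoint with
a warning. Pooling uses the DerSimonian–Laird moment estimator
(`tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`) with Wald 95%
intervals (`z = 1.96`) and no Hartung–Knapp adjustment — the era-standard
choice for this literature; the estimator is verified in the tests
against `metafor::rma(method = "DL")` on random inputs. Crossover trials
report period-pooled arm summaries and are pooled as parallel-group data
by default; a sensitivity option (`crossover_rho`) shrinks the SE of
continuous crossover contrasts by `sqrt(1 - rho)` to acknowledge the
within-subject correlation.

## The Bayesian NMA model

For binary endpoints the arm counts are modelled directly:

    r_ik ~ Binomial(n_ik, p_ik)
    logit(p_ik) = mu_i + delta_ik

and for continuous endpoints the arm means:

    ybar_ik ~ Normal(mu_i + delta_ik, sd_ik^2 / n_ik)

with `delta` of each study's baseline arm fixed at zero. Non-baseline
study effects are exchangeable around the basic-parameter contrasts,
`delta_ik ~ Normal(d_{t_ik} - d_{t_i1}, tau^2)`, with the sequential
conditional-normal construction (between-arm covariance `tau^2/2`) for
multi-arm trials — the simulator can emit them even though the packaged
evidence base is all two-arm. Every relative effect is a deterministic
contrast of the basic parameters, so consistency holds by construction
draw-for-draw; the tests assert the additivity identity at machine
precision.

Priors are deliberately vague and fully exposed in `nma_config()`:
`d_k ~ Normal(0, 100^2)`, `mu_i ~ Normal(0, 100^2)`, and
`tau ~ Uniform(0, U)` with `U = 5` on the log-odds scale and `U = 10` for
mean differences — bounds far above any plausible between-trial SD in
this application. The posterior point estimate is the median, which is
robust and conventional for league tables. No software, priors or chain
settings are inherited from elsewhere; the defaults (4 chains, 50 000
iterations including 10 000 burn-in, thinning 10) are this package's own
choices, and all calibration experiments state the reduced sizes they
use.

### The sampler

Sampling is Metropolis-within-Gibbs, implemented in C++: random-walk
updates for each baseline `mu_i`, study effect `delta_ik` and basic
parameter `d_k`, with per-parameter proposal scales adapted in batches of
50 iterations during burn-in (target acceptance ≈ 0.3) and frozen
afterwards, so the post-burn-in chain is a fixed Markov kernel. Two
additions matter in practice:

* a **joint translation move** that shifts `d_k` together with every
  study effect coupled to it (adding the shift to `delta` of arms with
  treatment `k` and subtracting it for arms whose study baseline is
  `k`). This leaves the random-effect density exactly invariant and is
  accepted on the arm likelihood alone, so the sampler mixes even when
  `tau` approaches zero — the regime where `d` and `delta` are otherwise
  glued together and a componentwise walk diffuses at speed `tau`;
* a **shrinkage slice sampler** for `tau` on its bounded prior support,
  which is rejection-free and needs no tuning; the random walk it
  replaces mixed poorly through the heterogeneity scale.

Chains start from overdispersed random points (`d ~ N(0,1)`,
`mu ~ N(0,0.5^2)`, `tau` uniform over a sub-interval) so that split-chain
R̂ has power to detect non-convergence. All randomness flows through R's
RNG; a fit is bit-reproducible from `(data, config, seed)`, with chain
`c` seeded at `seed + c - 1`. Convergence is summarised by split-chain R̂
and a Geyer initial-positive-sequence effective sample size for every
`d_k` and `tau`; any R̂ above 1.05 flags the posterior (a warning, not an
exception — the draws remain inspectable).

## Ranking

For each posterior draw the treatments are sorted with the endpoint's
better direction first; exact ties (possible only in degenerate
posteriors) break by canonical treatment order, which makes the rank
matrix deterministic. SUCRA is the normalised area under the cumulative
rank curve, `sum_{j<K} cum_k(j) / (K-1)`; rank matrices are doubly
stochastic and mean SUCRA is exactly 0.5, both asserted in tests, and the
formula is checked against exhaustive rank counting for small networks.
The two-endpoint cluster analysis runs k-means with 50 seeded restarts on
the treatments' SUCRA pairs; when the number of clusters is not given it
is chosen in {2, 3, 4} by mean silhouette width. If all points coincide
the silhouette is undefined; the function returns a single flagged
degenerate cluster rather than failing.

## Consistency diagnostics

**Node splitting** refits the NMA giving the split comparison's two-arm
direct studies their own direct-evidence parameter while the rest of the
network informs the basic parameters; the indirect estimate is the usual
contrast `d_b - d_a` from that refit and
`p = 2 min(P(diff > 0), P(diff < 0))` over draws of
`direct - indirect`. A comparison is splittable only if it has direct
evidence *and* an indirect path survives removal of its direct studies;
otherwise the comparison is skipped with a message (a two-treatment
network has nothing to split). Multi-arm studies containing the split
pair — absent from the packaged geometry but possible via the
simulator — stay on the network side, a standard simplification.
Simulation shows the p-values are approximately uniform under consistency
(Kolmogorov–Smirnov over 200 consistent replicates) and reject reliably
when a 1.0 log-odds offset is injected on one edge. Raw p-values are
reported; multiplicity adjustment across comparisons is left to the
caller.

**The net-heat construction** is deliberately frequentist, because that
is the machinery the plot presumes: studies are reduced to contrasts
versus their baseline arm (with the covariance adjustment for shared
baselines), pooled within *designs* — a design is a distinct treatment
set within a study-design stratum, so parallel and crossover trials of
the same comparison form separate designs — and the pooled design
contrasts are regressed on the basic-parameter design matrix by weighted
least squares. `Q_total` (studies vs network estimates) decomposes
exactly into within-design heterogeneity `Q_het` plus design
inconsistency `Q_inc`, because within-design pooling is the weighted
projection; the identity is asserted to 1e-9. The contribution matrix is
the row-normalised absolute hat matrix aggregated to designs. Detaching a
design means granting it its own parameter (implemented as refitting
without its rows, which is equivalent and keeps the Q bookkeeping): the
delta-inconsistency entry is the *decrease* in a design's Q contribution
after detachment, positive where detaching helps (warm colours in the
conventional display). Refits that disconnect the network fall back to
the Moore–Penrose pseudoinverse so the remaining estimable contrasts are
still projected.

**Funnel data** centre each study effect on its own comparison's pooled
direct effect, so studies of different comparisons share a common null;
the Egger regression of `centered/se` on `1/se` quantifies asymmetry
(intercept ≈ small-study effect) and is only fitted with at least three
studies. One caveat is worth recording: for binary outcomes the estimated
log odds ratio and its estimated SE are functions of the same counts, so
Egger-type tests are intrinsically anti-conservative on sparse odds-ratio
data; the calibration tests therefore use continuous effects with varying
precision, where the null behaviour is clean.

## The simulator

`simulation_scenario()` / `simulate_network()` generate what the analysis
model assumes: per trial on edge (a, b), a true effect
`theta ~ Normal(d_b - d_a + offset_ab, tau^2)` around study baselines
drawn `Normal(b0, b_sd^2)` (logit scale for binary endpoints, defaults
`b0 = logit(0.3)`, `b_sd = 0.3`, a plausible adverse-event range;
`logit(0.15)` for withdrawal endpoints; outcome mean 5 with SD 2 for the
continuous endpoints, roughly monthly migraine days). Binary arms draw
binomial events; continuous arms draw the arm mean with the common
outcome SD reported as the arm SD. Offsets on chosen edges inject loop
inconsistency; `crossover_fraction` flags designs; everything is
reproducible from the scenario seed. `make_paper_like_scenario()`
reproduces the packaged 32-study geometry — sizes, designs, the ten
comparisons and each study's endpoint set — with true effects defaulting
to zero.

The simulator emulates the statistical structure the methods assume; it
does **not** emulate dose titration, washout effects in crossover trials,
correlated endpoints within a study, informative dropout, or selective
reporting. Passing calibration tests therefore demonstrates internal
correctness of the machinery under its own assumptions, not robustness of
the published conclusions to violations of them. Study-level outcome data
for the 32 trials were never published in aggregate form, so numeric
league-table entries of the original analysis are not reproduction
targets; the packaged fixture carries geometry and metadata only.

## Problem sizes and numerical choices

The calibration experiments use a consistent three-treatment triangle
(true effects 0/−0.5/−1.0 on the log-odds scale, `tau = 0.1`, 10 trials
per edge): 50 replicates at n = 200/arm with 4 chains × 10 000 iterations
for bias and coverage of the basic parameters, and 50 replicates at
n = 500/arm with 2 chains × 8 000 iterations for node-splitting error
rates — sizes at which the Monte-Carlo error of the reported rates is a
few percent while a full run stays comfortably interactive. Determinism
is checked end-to-end by hashing every artifact of two pipeline runs on
the paper-like network. Degenerate inputs are handled explicitly: empty
effect lists, all-zero 2×2 tables, single-chain posteriors, identical
cluster points and unsplittable comparisons each produce a typed error,
warning or flagged result rather than silent output.

## Known limitations

* The NMA likelihood treats crossover trials as parallel-group data
  (their period-pooled summaries are what the evidence base reports); the
  crossover SE adjustment is available only as a pairwise sensitivity
  analysis.
* Node splitting requires two-arm direct studies for the split edge.
* No meta-regression, informative priors, or model-selection criteria;
  dose levels are out of scope.
* The net-heat WLS backbone uses fixed-effect weights at the design
  level, the standard construction; it is a diagnostic, not a substitute
  for the Bayesian model.
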
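---
title: "Modelling and analysing the CAA decision-making circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing the CAA decision-making circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caadyn)
```

## The circuit and the questions

The cross-antagonism-with-autoregulation (CAA) motif consists of two
transcription factors, A and B, each activating its own promoter and
repressing the other's. It is the canonical decision-making topology: when
cross-repression is strong the population splits into mutually exclusive
"decided" states (A high / B low, or the reverse), with a possible third
state in which both factors are co-expressed. `caadyn` implements a
stochastic and a deterministic model of this circuit, and asks how three
topology-preserving perturbations change decision-making behaviour:
repression strength, the number of operator sites per promoter, and gene
(promoter) copy number. It also implements the downstream data-analysis
methods such an experiment needs: clustering of two-channel flow-cytometry
response profiles, and digital-PCR copy-number estimation.

## The reaction model

The stochastic model represents, per side $i \in \{A, B\}$ with opposite
side $j$:

* three aggregate promoter-state counts — free, activator-bound,
  repressor-bound — summing to the side's copy number $n_i$;
* an mRNA pool and a protein pool.

The reactions per promoter copy are activator binding at
$k_\text{act,on} P_i^2$ and unbinding at $k_\text{act,off}$; repressor
binding at $k_\text{rep,on} P_j^2$ and unbinding at $k_\text{rep,off}$;
transcription at $\alpha_\text{active}$, $\alpha_\text{basal}$ or
$\alpha_\text{repressed}$ depending on the promoter state; translation at
$\beta$ per mRNA; and first-order degradation at $\delta_m$ and $\delta_p$.
Binding is competitive (one operator, occupied by either factor) and
non-sequestering: protein counts are not decremented on binding, which is
accurate when proteins vastly outnumber promoter copies and keeps the
promoter-conservation invariant trivial to verify.

Two modelling choices deserve emphasis.

**Binding is second order in protein.** TetR-family regulators — the
natural implementation of this circuit — bind their operators as
homodimers, so the binding propensity is $k_\text{on} P^2$ per free
promoter copy. This is not merely biochemical fidelity: a mean-field
analysis of the first-order variant (occupancy fractions that are
fractional-linear in $P$) shows its nullclines are strictly monotone with
at most three intersections whose middle point is always a saddle, so
first-order binding can be at most bistable. The tristability that
motivates the circuit — two exclusive states *plus* a stable co-expression
state — requires the quadratic (dimeric) propensity.

**Bursting by slow promoter switching.** The defaults put
$k_\text{act,off}, k_\text{rep,off} \ll \alpha_\text{active}$, so a
promoter transcribes in bursts of tens of mRNAs between switching events.
This is the regime in which stochastic fate decisions are made: early
bursts decide which side activates first.

`build_network()` materializes the scheme as a 10-species mass-action
network; reactions whose rate constant is exactly zero (e.g. repressed
transcription under strong repression) are pruned, so the strong defaults
give 18 reactions and leaky parameter sets 20.

## Default parameters

Units are hours throughout; all rates are per hour. The symmetric defaults
(`default_parameters()`):

| parameter | strong | weak | meaning |
|---|---|---|---|
| `k_act_on` | 0.02 | 0.02 | activator dimer binding (per molecule² h⁻¹) |
| `k_act_off` | 2 | 2 | activator unbinding |
| `k_rep_on` | 6.25e-4 | 6.25e-4 | repressor dimer binding |
| `k_rep_off` | 1 | 10 | repressor unbinding |
| `alpha_active` | 60 | 60 | mRNA h⁻¹ per activated copy |
| `alpha_basal` | 1.5 | 1.5 | mRNA h⁻¹ per free copy |
| `alpha_repressed` | 0 | 0.45 | mRNA h⁻¹ per repressed copy |
| `beta` | 7 | 7 | protein per mRNA h⁻¹ |
| `delta_m` | 3.5 | 3.5 | mRNA half-life ≈ 12 min |
| `delta_p` | 0.7 | 0.7 | protein half-life ≈ 1 h |

These were chosen, once, by the package's own fixed-point finder to realize
the qualitative regimes the circuit is meant to exhibit: the strong set is
tristable and the weak set — a 30% basal leak through the repressor-bound
promoter plus a ten-fold faster repressor off-rate, i.e. occlusion rather
than active silencing — is monostable. In scaled terms the activation
threshold is $K_\text{act} = \sqrt{k_\text{act,off}/k_\text{act,on}} = 10$
molecules and the strong repression threshold $K_\text{rep} = 40$; the
tristable window at these settings spans roughly $K_\text{rep} \in
[30, 80]$, so the defaults sit comfortably inside it rather than at its
edge. The magnitudes (basal protein ≈ 4, activated protein ≈ 170 per copy;
turnover on the hour scale) are typical of a budding-yeast reporter
circuit.

```{r fixed-points}
find_fixed_points(default_parameters("strong"))
count_stable_fixed_points(default_parameters("weak"))
```

The default horizon is 16 h from an all-free, zero-expression initial
state. That is both the experimental endpoint the package mirrors and past
the burn-in heuristic $10/\min(\delta_m, \delta_p) \approx 14.3$ h, so an
endpoint sample (state at $t_\text{end}$, not a time average) reads out
the committed fate.

## Deterministic reduction

`mean_field_rates()` eliminates promoter states by quasi-steady-state:
occupancy fractions proportional to $1 : (k_\text{act,on}/k_\text{act,off})
P_i^2 : (k_\text{rep,on}/k_\text{rep,off}) P_j^2$, leaving a smooth field
on $(m_A, P_A, m_B, P_B)$. The stochastic model deliberately violates the
fast-switching assumption (bursting needs slow switching); the reduction is
still the right object for counting and classifying steady states, which is
what it is used for. Roots are found by damped Newton iteration from 50+
log-spaced and seeded starts on the protein plane, de-duplicated at 1e-6
relative tolerance, then classified by the eigenvalues of a central-
difference Jacobian of the full 4-D field (stable iff the leading real part
is below −1e-9). With symmetric parameters the stable set is the two
exclusive states plus a symmetric co-expression state; the "intermediate"
label goes to the stable point minimizing $|P_A - P_B|$.

Weakening repression collapses the structure. The packaged slice
`repression_slice(s)` raises the leak $\alpha_\text{repressed} = s\,
\alpha_\text{basal}$ while loosening binding geometrically
($k_\text{rep,off} = 10^s$): the stable-state count falls monotonically
from 3 to 1 and never re-enters. The slice couples both knobs because
occlusion alone (leak without loosening) preserves exclusivity: a promoter
that is never free cannot fire regardless of how much a *free* repressed
state would leak.

## Dosage sweeps and quadrant classification

`dosage_sweep()` runs endpoint ensembles over a copy-number grid and
classifies each endpoint into one of four expression quadrants. Thresholds
are self-calibrating: the geometric mean of the lowest and highest stable
fixed-point protein level at single copy (≈ 6.2 for the strong defaults),
falling back to ten times basal expression for monostable sets. Ties count
as "high". The classification is applied with one common threshold across
all grid cells so that dosage effects are not confounded by a moving
cutoff.

The headline phenomenology, computed by `scripts/acceptance.R` and the test
suite: at single copy the strong circuit decides (≈ 80% exclusive
endpoints), and co-expression rises monotonically with copy number (≈ 20%
at (1,1) to ≈ 67% at (5,5), 1000 runs/cell). The mechanism is averaging:
with five copies a side, basal output is less noisy, both sides reliably
activate, and repressing *all five* opposing promoters simultaneously —
which is what maintaining exclusivity requires — becomes combinatorially
unlikely. Weak repression at single copy co-expresses (≈ 63%) where strong
repression decides.

## The multi-operator promoter

A single operator site is in one of three states — unbound,
activator-bound, repressor-bound — so an $m$-site promoter has $3^m$
configurations. With independent, identical sites (tandem repeats, no
cooperativity) the per-site probabilities are proportional to $1 :
[\text{act}]/K_\text{act} : [\text{rep}]/K_\text{rep}$ and joint counts
are multinomial (`occupancy_distribution()`, validated against explicit
$3^m$ enumeration).

The biological question — why do many-operator promoters lose
decision-making exclusivity? — needs a map from configuration to activity,
which the underlying experiments do not constrain. The package's
formalization (`promoter_activity_fn()`) is activation linear in the bound-
activator fraction times a repression factor interpolating between graded
($(1 - n_\text{rep}/m)$, `strength = 0`) and dominant (silence if any
repressor is bound, `strength = 1`). The default is `strength = 0.3`,
partial dominance, and it is a considered choice: at `strength = 1` *every*
promoter is all-or-none in repressor occupancy, so adding sites makes the
dose response steeper and the configurational variance larger — there is no
averaging to be had. At partial dominance the averaging effect appears and
is robust (checked across total concentrations 3–50× $K$): the normalized
activity variance at balanced input falls monotonically (1.86 at $m = 1$ to
0.55 at $m = 7$) and the maximum slope of expected activity versus
$\log_{10}([\text{act}]/[\text{rep}])$ is lower at $m = 7$ than at
$m = 2$ — many sites read the *average* regulator balance, few sites flip.

The stochastic engine always uses the three-state aggregate promoter; the
multi-site model is an equilibrium-level analysis layer. This keeps the SSA
state space independent of $m$ and is exact for $m = 1$.

## Response-profile clustering

The flow-cytometry pipeline mirrors standard practice for two-channel
endpoint data:

1. **Trim** events outside per-channel percentile bounds (default
   0.5–99.5); both channels must pass. Trimming a single-event profile, or
   everything, is a degenerate-profile error.
2. **Bin** on the log10 scale (floor-clamped at 1 a.u.; non-positive values
   are an error) into an $n \times n$ grid with half-open bins, last bin
   closed, out-of-range events clamped to edge bins. Axis ranges are
   computed once from the pooled dataset (0.1–99.9 percentiles) so all
   profiles share a grid; $n = 10$ for clustering, $n = 100$ for display.
3. **Distance**: Manhattan (L1) on the normalized grids, so distances live
   in $[0, 2]$.
4. **Cluster** with PAM — implemented from scratch as greedy BUILD followed
   by best-improvement SWAP, with all ties broken to the lowest index.
   Because BUILD+SWAP alone stalls in local optima on a nontrivial fraction
   of small instances (as does the reference implementation in `cluster`),
   the SWAP descent is restarted from seeded random medoid sets (8 starts
   total) and the cheapest solution kept; on 100 random instances with
   $N \le 10$ this attains the exhaustive-search optimum every time and can
   never beat it.
5. **Select** $n$ and $k$ by mean silhouette (`silhouette_scan()`);
   singleton clusters score 0 by convention, ties resolve to smaller $k$
   then smaller $n$, and an all-identical input is flagged degenerate
   rather than scored.
6. **Summarize** clusters as archetype masks: unweighted means of the
   members' normalized grids, so each clone carries the same weight.

## Digital-PCR copy numbers

Template molecules distribute over partitions as a Poisson law, so the
positive fraction $p$ gives $\hat\lambda = -\ln(1 - p)$
(`lambda_from_partitions()`; saturated reactions are an error, empty ones a
zero-information warning). The copy number of a target relative to the
endogenous single-copy reference is $\hat\lambda_t/\hat\lambda_r$ (times
`reference_copies`, default 1 for a haploid host). The 95% interval is a
delta-method interval on the log scale — the log-ratio variance is the sum
of the two log-$\lambda$ variances, each $p/\big((1-p) N \lambda^2\big)$ —
which keeps bounds positive and achieves ≈ 96% empirical coverage for true
copies 1–5 at 20,000 partitions (the packaged simulation check requires
≥ 90%).

## Synthetic data

No raw flow or dPCR data accompany the experiments this package models, so
`synthetic_data` generators produce every input the analysis consumes, and
they are first-class, tested code:

* `generate_clone_profile()` draws events from a mixture of up to four
  log-normal populations at the canonical quadrant centers (low $10^2$,
  high $10^4$ a.u.; spread 0.15 log10 units — tight, decade-separated
  populations).
* `generate_archetype_dataset()` builds clone sets from the 15 non-empty
  presence/absence patterns of the four populations (singletons first, then
  pairs, triples, the full pattern; patterns are reused with skewed weights
  beyond 15), with per-clone center jitter. Defaults — 20,000 events/clone,
  jitter 0.05 — are assumptions documented here, not measured values.
* `generate_dpcr_partitions()` draws binomial partition counts at a known
  copy ratio.

Everything is seed-deterministic and round-trips through the same
delimited-text formats the readers consume. What these generators do *not*
emulate: instrument artifacts (spillover, autofluorescence, doublets),
heavy-tailed event noise, correlated channels, or any mechanistic link
between copy number and profile shape. Passing the recovery tests therefore
shows the pipeline identifies well-separated mixture archetypes — not that
it would partition noisy instrument data equally cleanly.

## Numerical choices and limitations

* **Problem sizes.** The packaged checks use 1000 runs per sweep cell
  (binomial error ≈ 1.6 points on a fraction), 200-run ensembles against
  closed forms (3-SE bands), 20 recovery replicates, and 1000 coverage
  simulations — sizes at which every qualitative claim is comfortably
  resolved.
* **RNG.** R's Mersenne-Twister throughout, including inside the C++ SSA
  core (`unif_rand`); per-run seeds are `base_seed + index`, so any single
  run of an ensemble can be reproduced in isolation.
* **SSA.** Exact direct method; no tau-leaping. Propensities are
  recomputed per event (the network has ≤ 20 reactions); a `max_events`
  guard aborts runaway simulations; non-finite propensities abort with the
  reaction named.
* **Root finding.** Newton steps are damped to one log10 unit; convergence
  is declared below 1e-11 relative residual and verified at 1e-8 on the
  4-D field. Degenerate inputs (zero unbinding rates) are rejected before
  the reduction divides by them.
* **Known limitations.** The deterministic layer assumes fast promoter
  switching that the stochastic layer deliberately violates, so the
  fixed-point count describes the mean-field skeleton, not burst-driven
  occupancy of the states. The multi-site activity family is a
  formalization choice, not a measured dose-response. PAM with restarts is
  a heuristic; optimality is only guaranteed where the tests enumerate.
  The dosage classification depends on a threshold convention (geometric
  mean of extreme stable states) that the underlying experiments leave
  unspecified.
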
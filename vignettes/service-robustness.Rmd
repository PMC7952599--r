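---
title: "Robustness of food webs and the ecosystem services they provide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robustness of food webs and the ecosystem services they provide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(servweb)
```

## The model

Ecosystem services — water filtration, shoreline stabilization, fisheries,
birdwatching — are delivered by particular species, but those providers sit
inside food webs. A threat that removes species can therefore erode a
service indirectly, by starving the providers' resource base, even when no
provider is targeted. servweb quantifies this indirect risk by coupling two
node types in one directed network:

* **trophic links**, stored resource → consumer, so that a species with
  trophic in-degree 0 literally has no resources;
* **provision links**, stored provider → service, so that a service's
  in-degree is its *redundancy* (number of providers).

Extinctions are simulated topologically and bottom-up. Species from a
target sequence are removed one at a time; after every removal, any
non-basal species whose last remaining resource (self-loops excluded — a
cannibal cannot sustain itself) has died goes *secondarily* extinct, and
the rule is iterated to its least fixed point. A service is lost the
instant its last living provider dies, whether by primary removal or by
cascade. Basal species (producers) have no resources to lose and are never
secondarily extinct; they form the complement of the *susceptible* set.

Each trajectory records, after every realized removal, the proportion of
targets removed (x), the proportion of susceptible species not secondarily
extinct (y for the food web) and the proportion of initially provided
services still present (y for services). A target that has already died
secondarily is skipped and does not advance x, so sequences truncated by
their own cascades never reach x = 1. Robustness is the area under the
step curve normalised by the realized sequence length:

R = Σ y(x) · (1/L_seq) / max(x),

evaluated after each realized removal (right Riemann sum; with this rule R
is the mean of y over realized steps). The normalisation by max(x) makes
sequences of different realized length comparable. Three metrics share
this form: food-web robustness R_F, aggregate service robustness R_ES, and
individual service robustness R_indiv, which tracks a single service and
is *not* normalised by max(x) — a service that survives the whole sequence
scores exactly max(x). Both conventions are exposed
(`robustness_indiv(..., normalize = TRUE)`, and
`rule = "trapezoid"` anchors the curve at (0, 1) for users who prefer the
trapezoidal reading of the sum); the defaults follow the discrete-sum
reading of the formulas above, which matches the step-curve illustrations
the method is usually presented with.

Because service nodes have no outgoing links, the species dynamics are
identical whether or not services are attached; R_F computed on the full
network equals R_F on the species-only web, and the package exploits this
by deriving all three metrics from a single cascade run.

### Weighted contributions

The unweighted R_ES treats all providers of a service as equivalent: y
falls only when a service loses its *last* provider. The weighted
extension assumes service output is proportional to provider biomass, so
the aggregate y becomes the mean over services of the living-provider
biomass fraction. The mean is taken across services (not pooled biomass),
keeping services equally weighted exactly as in the unweighted proportion.
Services whose value is not biomass-proportional (birdwatching: rare birds
are valued disproportionately) can be flagged *weight-exempt* and
contribute their binary indicator inside the weighted mean. Zero-biomass
providers contribute nothing to the fraction but still keep a service
"present" in the unweighted sense. Weighted y never exceeds unweighted y
pointwise, so weighted robustness is always ≤ its unweighted counterpart.

## The twelve removal scenarios

Sequence order is the threat model. The standard report runs, per system:

| entries | construction |
|---|---|
| providers, high→low / low→high biomass | union of all providers, sorted by biomass |
| providers, random (mean of 100) | permutations of the provider union |
| most-to-least connected | descending total trophic degree (self-loop counted once; provision links excluded — they are not species–species links) |
| random max / mean / min | 1000 uniform permutations of all species, summarised as best/average/worst case |
| rarity | all species, ascending abundance |
| supporting species, most→least / least→most important, random (mean of 100) | see below |
| vulnerable | flagged species only, ascending abundance |

All deterministic orders break ties by ascending species id, so results
are invariant to node-table row order. Random-family entries report the
max/mean/min of R_F and of R_ES summarised independently over the
replicate ensemble (the pairing of, say, "random max" R_F with "random
max" R_ES follows the reporting convention of per-metric summaries).

**Supporting species** are ranked by personalized PageRank on the
*reversed* network: provision links point service → provider and trophic
links consumer → prey, so a random walk started at a service flows down
the energy channels that sustain it. The walk terminates (returns to the
restart service) with probability α = 0.15 and continues along a uniform
out-link otherwise; dangling nodes return their mass to the restart node.
One walk is run per service on the intact reversed graph; a service's own
providers are then masked out of its score list (direct provision is not
"support"), and each species is ranked by the mean of its remaining
per-service scores. Species providing every service have no defined mean
and drop out of the supporting target set.

Two conventions here are genuinely ambiguous and both are exposed as
flags. First, α can be read as the termination probability (our default:
continuation = 0.85) or passed directly as a damping factor
(`alpha_is_damping = TRUE`). Second, provider exclusion can be applied to
the finished score lists (default, matching "removed from the link list
before averaging") or by rebuilding the reversed graph without the
providers before each walk (`rebuild_graph = TRUE`).

## Trophic levels and service metrics

Species trophic level is prey-averaged: TL = 1 for basal species, else
1 + mean TL of the diet, with uniform weights (the link data are binary)
and self-loops removed first. Cycles are handled by solving the linear
system (I − Q)·TL = 1 directly; a consumer cycle with no basal input makes
the system singular and is reported as an error naming the species — such
a configuration has no energy source and the synthetic generator rejects
it. Trophic levels are computed on the species-only web (the default for
the open question of whether service nodes participate: they do not, as
they are not prey). A service's trophic level is the unweighted mean of
its providers' levels; its redundancy is its in-degree.

## The synthetic generator

The empirical webs the method was developed on are three estuarine salt
marshes of roughly 107–136 species, 1015–1680 trophic links (connectance
≈ 0.09) and 6–7 services, analysed after filtering to adult, living,
free-living nodes (`filter_network()` reproduces that filtering given
`group`/`life_stage` attributes). The species–service link data are not
freely redistributable, so the package ships a generator that emulates the
study conditions end to end and makes every stage testable offline:

* **Web**: the niche model at S = 120, C = 0.08 (defaults), rejected and
  redrawn until it has ≥ 1 basal species, no isolated species, every
  consumer reachable from a basal species, and a realized link count
  within 20% of C·S² (±S links for very small webs, where the 20% band may
  contain no integer). The rejection budget is 100 draws.
* **Traits**: lognormal biomass (meanlog log 100, sdlog 2) and abundance
  (meanlog log 1000, sdlog 2.5) per hectare — heavy-tailed density spans
  typical of community data; abundance is assigned against noisy niche
  ranks so that higher-trophic species tend rarer (Spearman ρ ≤ 0
  enforced). A random 10% of species is flagged vulnerable, mirroring the
  deliberately conservative, much-shorter vulnerable list of the study
  systems.
* **Services**: seven services spanning redundancy 1–40. Provider sampling
  is weighted by trophic level to reproduce the observed spread of service
  trophic levels (≈ 1 for the plant-based shoreline/wave services, ≈ 1.5–2.5
  for carbon sequestration and filtration, ≈ 3–3.5 for fishery, hunting and
  birdwatching). An early draft biased most provision onto pure basal
  species; because basal species can never be lost secondarily, that made
  aggregate service robustness nearly independent of the cascade, which
  contradicts the qualitative behaviour of the empirical systems (provider
  removal and supporting-species removal both collapse services there).
  The Gaussian TL-targeted weights fix that fidelity defect and are now
  frozen defaults.

What the generator does *not* emulate: parasite links and ontogenetic
stage structure, empirical degree correlations, body-size allometry, and
any real provider identity. Passing tests on synthetic ensembles therefore
demonstrate correctness of the algorithms and reproduction of the
*directional* findings (hub removal harsher than random; R_F–R_ES
positively correlated; R_indiv rising with redundancy, falling with
trophic level), not the study's numerical correlation coefficients, which
depend on the on-request species–service data.

## Numerical choices

* Cascade propagation is event-driven (each species death decrements its
  consumers' resource counts), so a full trajectory costs O(S + L).
* PageRank uses dense power iteration to an L1 tolerance of 1e-12
  (iteration budget 10 000); the webs involved have at most a few hundred
  nodes, and the implementation is cross-checked in the tests against a
  direct linear solve and against igraph.
* The trophic-level system is solved by LAPACK (`solve`), with exact
  singularity reported, never patched.
* Spearman tests use average ranks; p-values are exact (permutation null)
  for n ≤ 10 without ties and t-approximate otherwise. p-values are
  reported, never used for gating, and not multiplicity-corrected.
* All randomness flows through explicit integer seeds; every ensemble
  derives per-stage sub-seeds from one master seed, so reruns are
  byte-identical.

## A worked run

```{r, eval = FALSE}
nets <- lapply(1:3, function(s) synth_system(seed = s))
names(nets) <- c("synthA", "synthB", "synthC")
fit <- service_robustness(nets, seed = 11)
summary(fit)
plot(fit)
coef(fit)          # all-sequence R_indiv model
fit$correlations   # R_F vs R_ES by sequence class, n = 36/12/6/18
```

The problem sizes used throughout the test suite (webs of 20–40 species
for property checks, 30 systems of 120 species for the ensemble
reproduction, 1000-replicate random ensembles) were chosen so the whole
analysis runs in minutes on one core while keeping the ensemble estimates
stable across seeds.

## Known limitations

The model is purely topological: no top-down effects, competition, prey
switching/rewiring, recolonisation, or interaction strengths, each of
which can raise or lower secondary-extinction estimates. Services are
binary-or-biomass-linear functions of provider presence; real
service-biodiversity relationships are rarely linear. The individual
robustness of a service that is never lost equals max(x), so comparing
R_indiv across sequences of very different realized lengths should use
`normalize = TRUE`. Isolated species are retained by `filter_network()`
and treated as basal, a documented convention rather than an empirical
claim.
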
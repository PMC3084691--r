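---
title: "Models and methods behind coherentunits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coherentunits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`coherentunits` asks a question that comes up whenever a set of
presence/absence characters is scored for a handful of related groups:
did all the characters travel together down one history, or do
different character classes carry different histories?  The motivating
application is a comparative study of tribal textile assemblages — six
Iranian nomad tribes plus an archaeological outgroup, scored for 122
binary characters in three classes (42 weaving techniques, 56
flat-weave designs, 24 pile-weave designs) — but every piece of the
package works on any binary matrix with a partition map.

Two competing transmission models frame the analyses.  Under a
*hierarchically integrated system*, one core tradition descends
tree-like and peripheral characters are exchanged sideways between
contemporaneous groups; on a single tree this predicts *rate*
differences between character classes.  Under *many coherent units*,
character classes travel as packages with genuinely different descent
histories; this predicts different *topologies* for different
partitions.  Both predictions are testable with Bayes factors between
partitioned Bayesian tree models.

## The character-evolution model

Characters are two-state (0 = absent, 1 = present) continuous-time
Markov chains on a rooted tree.  The transition matrix is normalised so
one unit of branch length equals one expected change at stationarity:

$$P_{ij}(t) = \pi_j + (\delta_{ij} - \pi_j)\,e^{-\beta t},
\qquad \beta = \frac{1}{2\pi_0\pi_1}.$$

Likelihoods come from Felsenstein's pruning algorithm, vectorised over
compressed site patterns (at most $2^{N}$ patterns exist for $N$ taxa,
so pattern compression caps the cost of large matrices).  A
brute-force enumerator over all internal-state assignments
(`brute_force_loglik()`) serves as the independent oracle; the test
suite holds the two routes together to $10^{-10}$ over random trees,
models and patterns.

Model structure is factored into a `model_spec()`:

* **Rate asymmetry.**  Rather than one shared gain/loss asymmetry, the
  frequency of the present state is drawn per character from a
  symmetric Beta$(\alpha,\alpha)$, discretised into 5 equal-weight
  categories at their category means.  This is the standard morphology
  treatment for data where no single mechanism drives asymmetry; as
  $\alpha\to\infty$ it collapses to the symmetric model (checked at
  $\alpha = 10^6$ to $10^{-6}$).  The category count is a modelling
  choice; 5 keeps the mixture cheap while resolving the Beta shape.
* **Rate heterogeneity.**  The usual discrete-gamma approximation with
  4 equal-probability categories at category means (cross-checked
  against `phangorn::discrete.gamma`).
* **Ascertainment.**  Observational presence/absence matrices never
  contain characters absent everywhere, so the likelihood can be
  conditioned on "not all-absent":
  $\log L' = \log L - \log(1 - L_{\text{all-0}})$.  The correction is
  applied to the *mixture* likelihood — that is the generative
  probability of observing a non-all-absent character — not per
  category.  The corrected pattern probabilities over the $2^N - 1$
  allowed patterns sum to one (enumerated at $N = 4$ in the tests).
* **Partitioning.**  Partition rates may be unlinked (per-partition
  branch-length multipliers constrained to character-weighted mean 1)
  and partition topologies may be unlinked (an independent tree per
  partition).  With multipliers at 1, or identical trees, the
  unlinked models reduce exactly to the linked one; both reductions
  are asserted in the tests.

Missing entries (`?` on disk) contribute partial likelihood 1 to both
states: legal everywhere, uninformative, and exercised in the tests
even though the motivating data have none.

## MCMC

`run_mcmc()` is a Metropolis-coupled sampler over topologies, branch
lengths and the continuous parameters.  Defaults mirror the study
protocol: 6 independent runs of 100,000 generations, sampled every 100,
4 chains per run (chain $i$ at inverse temperature $1/(1+0.2i)$), one
attempted swap per generation between a random adjacent pair, and the
final 900 samples per run retained (a 5400-record pooled posterior).
`detect_burnin()` implements that retention convention plus a
stationarity flag (first- vs second-half mean of the retained window
beyond two standard errors).

The proposal cycle is a minimal standard mixture, adequate for the
small taxon sets this design targets (weights in parentheses): rooted
NNI (3), rooted SPR with explicit root-regraft case (1), log-window
branch-length multipliers (4), log-window gamma-shape and
Beta-concentration multipliers (1 each), and a mean-preserving shift of
the partition rate multipliers (1).  Priors: i.i.d. exponential branch
lengths (mean 0.1), uniform rooted topologies, uniform gamma shape on
[0.05, 50], exponential(1) Beta concentration, flat multipliers.
Constraints are enforced by rejecting violating topology proposals.

Correctness is established two ways.  Sampling with zero characters
recovers the priors (topology frequencies uniform over all 15 rooted
4-taxon trees; branch-length mean and variance at their exponential
values) — this is the check that catches Hastings-ratio errors, and it
is what motivated the explicit root-regraft bookkeeping in the SPR
move.  Sampling with data is compared against an *exact* posterior:
with i.i.d. exponential branch priors the marginal likelihood of a
rooted topology is available in closed form by expanding the per-edge
expectations $E[e^{-2kt}] = \lambda/(\lambda + 2k)$ over joint
internal-state assignments, so for a 5-character, 4-taxon matrix the
posterior over all 15 rooted topologies is computable exactly and the
sampler must match it within Monte-Carlo error.

## Marginal likelihoods and Bayes factors

Model comparison uses the harmonic-mean estimator of the log marginal
likelihood, computed in log space
($-(\mathrm{logSumExp}(-\ell_i) - \log n)$) so chains at
$\ell \approx -10^4$ are safe.  Bayes factors follow the
$2\Delta\ln L$ convention with the Kass–Raftery reading: up to 2
barely worth mentioning, 2–5 positive, 5–10 strong, beyond 10 very
strong.  The estimator is famously unstable — it is dominated by the
smallest sampled likelihood — so estimates are reported pooled *and*
per run, with a warning when per-run values spread beyond 2 log units
(`hm_stability()`).  Two consequences matter for interpretation:

* the estimator barely penalises extra diffuse parameters near the
  posterior mode, which is why it can favour a topology-unlinked model
  on genuinely incongruent data despite the added tree;
* conversely, a weakly informed partition lets its tree wander through
  low-likelihood topologies, which *lowers* the harmonic mean.  On
  congruent synthetic data the topology-unlinked model therefore tends
  to lose by several log units rather than tying — the linked model is
  favoured under the null, which is the directionally correct
  behaviour even though the magnitude is estimator-driven.

## The synthetic-data generator

No character matrix was published for the motivating study, so the
generator *is* the data source, and its defaults are the study
conditions: 7 taxa, 122 characters in the 42/56/24 class layout,
simulated at 0.123 expected changes per unit branch length on the
Grafen transform of a fixed reference topology.  The Grafen transform
(`grafen_transform()`) sets each node's age to its descendant-tip count
minus one (tips at zero), giving root age $N-1$; ages are used as-is,
with no rescaling.

The reference topology is a reconstruction from the published figure
descriptions, not a machine-read tree: Pazyryk outgroup, a
Shahsevan–Yomut cherry, and a ladder Qashqai → BoyerAhmad →
(Bakhtiari, Papi).  Two constraints pin down the ladder section.
First, the all-character history must hold Papi sister to Bakhtiari
while the pile-weave history moves Papi basal to a
Qashqai/BoyerAhmad/Bakhtiari clade (`textile_reference_tree("pile")`).
Second, the anti-local borrowing regime requires taxa separated by
exactly two internal nodes to exist: on a fully balanced 6-tribe tree
(three cherries) every inter-cherry pair is three nodes apart and the
regime would be empty, so the generating tree cannot have been fully
balanced.  No 6- or 7-taxon topology gives every tribe both a sister
and a two-node partner; under the chosen tree, local borrowing is
available to the four cherry tribes and anti-local to the four ladder
tribes, and taxa with empty donor sets are skipped with a warning.

Borrowing (`apply_transfers()`) happens at the tips after vertical
evolution: per character, each eligible tribe adopts, with probability
0.30, the state of a donor drawn uniformly from its mode-specific
donor set.  Updates are simultaneous (donors' pre-transfer states), so
mutual adoption in a cherry swaps states; the sequential alternative
would make the result order-dependent.  The outgroup — an
archaeological assemblage — neither borrows nor donates, but its tip
still evolves and enters the rate estimation.  Invariant characters
are dropped from transfer sets only; the no-transfer baseline keeps
all 100 characters, matching the study's asymmetric filtering.

What the generator does *not* emulate: rate variation among characters
within a set, borrowing along interior branches or through time,
selective (biased) adoption, and any correlation between characters.
Passing tests therefore speak to the machinery and to this idealised
generative process, not to the full complexity of real assemblages.

## Per-character ML rates and the distribution tests

`ml_rate()` maximises the symmetric-model likelihood per character over
the rate in $[10^{-8}, 100]$, in log-rate space.  The likelihood in the
rate can be *bimodal* — a finite mode plus a saturation plateau where
every pattern probability approaches $2^{-N}$ — so a pure line search
is unsafe; the implementation scans a 60-point log grid (vectorised
over site patterns) and then refines the best bracket with Brent's
combined golden-section/parabolic search (`stats::optimize`).
Invariant characters return the lower bound, flagged.  On the
saturation plateau the rate is unidentifiable (the tests compare
achieved log-likelihoods there instead of argmax locations); these
plateau characters are why mean inferred rates vastly exceed medians,
and why the median is the headline summary throughout.

The distribution comparisons are deliberately boring implementations:
Mann–Whitney U from rank sums with midrank ties, exact enumeration up
to 12 combined observations and a tie-corrected,
continuity-corrected normal approximation beyond (cross-checked
against `stats::wilcox.test`); the variance F test and Fligner–Killeen
test call `stats::var.test` and `stats::fligner.test` directly, with
the Fligner–Killeen statistic re-derived by hand in the tests.

## Numerical and design choices

* Likelihoods are computed in linear space per pattern (safe to ~50
  taxa for binary states) and logged at the end; the harmonic mean and
  all mixture sums are in log space.
* Consensus trees (`majority_consensus()`) use strict-majority clades
  (> 0.5, mutually compatible by construction), annotated with clade
  credibilities and mean subtending branch lengths over the trees
  containing each clade; clade counts are verified against
  `ape::prop.part`.
* The all-absent pattern is appended (weight zero) to every compressed
  pattern block so one pruning pass per mixture component yields both
  the data likelihood and the ascertainment term.
* Every stochastic entry point takes a seed and fans it out
  deterministically (run $r$ seeds with `seed + r`), so each
  experiment is a pure function of (inputs, configuration, seed).

## Problem sizes

Default configurations reproduce the study protocol (6 × 100,000
generations).  The test suite and the analysis scripts run reduced but
converged configurations chosen by inspection of likelihood traces and
of agreement with the exact 4-taxon posterior: 12,000–30,000
generations with two chains for 7-taxon problems, and the full
100-set × 3-regime simulation study at its native size (it needs no
MCMC).  The vignette-level scripts state their sizes inline.

## Known limitations

* The harmonic-mean estimator's heavy tail makes single-dataset Bayes
  factors noisy at any affordable chain length; replicate-level
  behaviour is the meaningful summary.
* Binary symmetric characters at the study's rate carry little
  topological information: posteriors over 7-taxon topologies remain
  diffuse even at several hundred characters (confirmed independently
  with ML bootstrap), so consensus-tree resolution on synthetic data
  is much lower than on the study's empirical matrix.
* Tip-copy borrowing homogenises close relatives; copying a cherry
  sister's state can only erase or relocate apparent changes, never
  create homoplasy, so the local regime *reduces* median inferred
  rates more often than it inflates them.  The global regime, whose
  donors are distant, is the one that reliably manufactures homoplasy.
  This asymmetry is intrinsic to the copy process, not to the
  estimator.
* Multistate characters, polymorphic codings, covarion-style models
  and reticulate (network) representations are out of scope.
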
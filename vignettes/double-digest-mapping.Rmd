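---
title: "Reconstructing restriction maps from double digest fragment lengths"
author: "digestmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing restriction maps from double digest fragment lengths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digestmap)
```

## The problem

Digesting a DNA molecule with restriction enzyme A partitions it into
fragments whose lengths (but not order) can be measured by gel
electrophoresis; digesting with enzyme B gives a second multiset of
lengths, and digesting with both enzymes together a third. The double
digest problem (DDP) asks for orderings of the A-fragments and B-fragments
along the molecule that are consistent with all three measurements. The
decision problem is strongly NP-complete, and the number of candidate
orderings grows as $m!\,n!$ for $m$ A-fragments and $n$ B-fragments, so
practical solvers are heuristic.

`digestmap` works entirely on fragment-length vectors. For a vector
$\vec a = (a_1, \dots, a_m)$ the *accumulative sum* vector
$\mathrm{AS}(\vec a)$ holds the cut positions implied by that ordering, and
the *step difference* $\mathrm{SD}(\cdot)$ inverts it. Overlaying the cut
positions of an A-ordering and a B-ordering — concatenating
$\mathrm{AS}(\vec a)$ with the interior entries of $\mathrm{AS}(\vec b)$,
sorting, and taking step differences — yields the *double digest sequence*
$\mathrm{DDS}(\vec a, \vec b)$ of $m + n - 1$ fragment lengths. A pair of
permutations $(\mu, \nu) \in S_m \times S_n$ solves the instance
$(\vec a, \vec b, \vec c)$ when $\mathrm{DDS}(\vec a^\mu, \vec b^\nu)$
equals $\vec c$ up to reordering. Permutations act by gathering,
$\vec a^\mu_i = a_{\mu(i)}$, and the alignment $\pi$ of $\vec c$ to the
realized double digest is recovered afterwards in $O(k \log k)$ by stable
sorting (`extractPi()`), so the search space is $S_m \times S_n$ rather
than $S_m \times S_n \times S_k$.

An instance is *valid* only if the three totals agree
($\sum \vec a = \sum \vec b = \sum \vec c = L$); `validateInstance()`
reports the three sums without raising, because defective lab inputs should
load and be diagnosable. When the two enzymes share cut sites the double
digest has $k < m + n - 1$ observable fragments; `padToCanonical()` appends
$\delta = (m + n - 1) - k$ zero-length fragments to $\vec c$ (or, in the
opposite direction, to the shorter single digest, to $\vec a$ on ties — an
arbitrary but documented and deterministic choice). Zero-length fragments
are retained everywhere downstream and drawn as radial ticks in the pie
charts.

## The genetic algorithm

A chromosome is a permutation pair $(\mu, \nu)$ with fitness

$$ f(\mu, \nu) = \frac{1}{1 + \left|\mathrm{DDS}(\vec a^\mu, \vec b^\nu)
   \oplus \vec c\right|} $$

where $\oplus$ is the multiset symmetric difference (element-wise exact
integer comparison; no measurement-noise model). Fitness is 1 exactly at
solutions, and strictly positive, which roulette-wheel selection requires.

Operators:

* **RWS** — roulette-wheel selection, fitness-proportional with
  replacement.
* **PCC** — permutation-composition crossover: offspring
  $(\mu^{(1)} \circ \mu^{(2)}, \nu^{(1)} \circ \nu^{(2)})$ and the reverse
  composition, with $(p \circ q)(i) = p(q(i))$.
* **RSC** — referenced-sorting (order-preserving) crossover: the offspring
  keeps one parent's prefix and rearranges the suffix into the other
  parent's order. The referenced sort resolves ambiguity among repeated
  elements by greedy right-to-left matching (rightmost occurrences); that
  is the unique simple deterministic rule that reproduces both published
  worked offspring of this operator, where leftmost-greedy reproduces
  neither. Crossover points are drawn independently for $\mu$ and $\nu$,
  uniformly on $1..\mathrm{degree}-1$.
* **P4X** — one transposition in $\mu$ and one in $\nu$ (positions drawn
  without replacement, so the mutation never degenerates to a no-op).
* **FLP** — reversal of a contiguous segment, endpoints uniform over all
  $i < j$.
* **CSH** — left rotation by one of a contiguous segment.

FLP and CSH are applied to $\mu$ and $\nu$ independently, each with the
scheduled mutation probability; when several crossovers or mutations are
enabled, one is drawn uniformly per application (no per-operator weights).

The evolution strategy is elitist and generational: population 50; the
best chromosome (configurable `eliteCount`) is copied unchanged; the rest
of the next generation comes from RWS-selected parent pairs crossed with
probability 0.85 (otherwise cloned) and then mutated. The mutation
probability climbs linearly within 200-generation cycles from $2/(m+n)$ to
0.55 and resets; the 0.55 ceiling keeps the increment non-negative down to
$m = n = 2$ (start 0.5). For $m + n < 4$ the start value $2/(m+n)$ would
exceed the ceiling, so the floor is clamped at the ceiling and the
schedule is constant there — those degrees are below any instance where
the schedule matters. The run stops at fitness 1 or at 10,000 generations
(generation 0 is the initial population, sampled uniformly from
$S_m \times S_n$).

Every reported solution is re-verifiable: the cached fitness equals a
from-scratch recomputation, and for exact solutions the mirror chromosome
$(\mathrm{rev}(\mu), \mathrm{rev}(\nu))$ — the map read right-to-left — is
also exact.

```{r ins2prime}
ins2 <- ddpFixtures()$ins2prime
validateInstance(ins2)$sums
res <- evolveDDP(ins2, GAConfig(seed = 11))
res@success
res@best@generationFound
```

## Hard instances: scaling-rounding-adjusting

Some instances with large fragment lengths have extremely sparse solution
sets and defeat the GA within any reasonable budget. `scaleRoundAdjust()`
multiplies all lengths by a factor (by default the power of ten that brings
the smallest double-digest fragment to at least 1, e.g. 0.001 for a
smallest fragment of 1120) and rounds half-away-from-zero. Rounding
usually breaks the equal-totals restriction, so two adjusted candidates
are formed by rounding $x + t$ and $x - t$ with $t = 0.1$ by default
(admissible range $[0.0001, 0.4999]$). The first valid candidate in the
order plain, up, down is selected (the order is configurable; all three
sum triples are always reported for audit). A solution of the scaled
surrogate is then read back as an approximate map of the original
molecule. `mapDistance()` quantifies the approximation as the L1
displacement of sorted interior cut positions divided by $L$ — a
documented formalization chosen here because the verbal description it
operationalizes ("total length of gaps between mis-aligned fragments")
admits no unique arithmetic reading.

## The instance generator and what it emulates

`randomInstance(m, n, L, rhoCMax)` samples $m-1$ and $n-1$ interior cut
positions uniformly without replacement from $1..L-1$ (per enzyme;
cross-enzyme coincidences are allowed), reads $\vec c$ off the overlaid
cut sites with zero-length fragments dropped — as an experiment would drop
them — and emits $\vec a, \vec b$ in shuffled order together with the
generating orderings as a ground-truth certificate (fitness 1 after
padding). Cut-position sampling guarantees validity and a known solution,
which fragment-length sampling would not.

The generator emulates *noiseless* digests: integer lengths, no
measurement error, no missing or partial cleavage. Passing tests
therefore certify combinatorial correctness of the solver, not robustness
to gel measurement noise.

The cap `rhoCMax` on the largest double-digest fragment is enforced by
rejection (resample cap, then an error): small $\rho_C$ means many evenly
spread cut sites, dense solution sets, and easy instances; large $\rho_C$
sparse solutions and hard ones. `benchRhoSweep()` measures exactly this.
Note that a cap below $\lceil L / (m+n-1) \rceil$ is arithmetically
impossible and caps slightly above it are unreachable by rejection (at
$m = n = 6$, $L = 300$ the probability that all 11 gaps are $\le 30$ is
about $10^{-10}$); the sweep reports such points as unsampled (NA) and
trend statistics are computed over the sampled points.

## Numerical and design choices

* All sorts are stable; `extractPi()` breaks ties among equal fragment
  lengths by ascending original index, making $\pi$ deterministic even
  though it is not unique under ties.
* Rounding in the scaling transform is half-away-from-zero on positive
  reals (`floor(x + 0.5)`), the common engineering convention.
* Per-trial seeds derive from the base seed as
  $(\mathrm{seed} + 7919\,i) \bmod (2^{31}-1)$, so trials are independent
  and each experiment replays exactly from its configuration.
* The brute-force oracle (`solveExhaustive()`) enumerates
  lexicographically with a hard guard on $m!\,n!$ (default $10^7$); it
  exists for certainty on small instances, not speed, and certifies GA
  solutions in the test-suite (every GA success on a small instance is a
  member of the enumerated solution set).
* Operator sets: a runnable benchmark configuration pairs at least one
  crossover with at least one mutation; the standard combination list is
  the six single-crossover + single-mutation pairs plus the full set
  (`benchmarkCombos()`). Crossover-only or mutation-only sets are accepted
  at run time but are not benchmarked — a crossover-only RSC population
  has no diversity source and converges prematurely.
* Problem sizes in the shipped tests and the reproduction script are
  chosen at desk scale: 20 seeded trials per operator combination on the
  packaged hard instance, 20 trials per point in the $\rho_C$ sweep with
  a 1,500-generation budget, and property checks over a few hundred
  generated instances with $m, n \le 6$.

## Limitations

* No model of measurement noise or partial digestion; mismatch is exact
  multiset difference.
* The GA carries no optimality certificate for failures: a run that stops
  at the generation cap reports its best chromosome, nothing more.
* `mapDistance()` is one formalization of map disagreement among several
  defensible ones; values are comparable within this package only.
* Wall-clock runtimes are recorded as information and never asserted:
  they are hardware-dependent.
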
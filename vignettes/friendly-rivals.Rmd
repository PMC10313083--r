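---
title: "Friendly rivals in the iterated donation game: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Friendly rivals in the iterated donation game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frsim)
```

## The model

frsim studies the repeated **donation game**: in each round a player who
cooperates pays a cost of 1 so that the co-player receives a benefit
$b > 1$; a defector does nothing.  Intended actions are flipped with a
small implementation-error probability $e$.  Strategies are
deterministic lookup tables over joint histories: a
**memory-$(m_1, m_2)$ strategy** prescribes C or D from the player's own
last $m_1$ moves and the co-player's last $m_2$ moves.  The package caps
memory at $m \le 3$, so a strategy is at most a 64-entry table.

When both players have finite memory the game is a Markov chain over the
joint full-memory states.  For $e > 0$ the chain has a unique stationary
distribution $v$ (Perron–Frobenius), from which the package reads off
cooperation levels $\gamma_{p,q}$ (the stationary probability that $p$'s
most recent action is C) and long-term payoffs
$\pi_{p,q} = b\,\gamma_{q,p} - \gamma_{p,q}$.

Three strategy classes organize the analysis:

* **efficient** (self-cooperators): $\gamma_{p,p} \to 1$ as $e \to 0$.
  Win-Stay-Lose-Shift recovers mutual cooperation after an error, so it
  is efficient; Tit-for-Tat locks into retaliation, so it is not.
* **rival** (unbeatable): no co-player, of any memory length and from
  any initial state, can secure a strictly higher long-term payoff at
  $e = 0$.  AllD, TFT and Grim Trigger are rivals.
* **friendly rival (FR)**: both at once.  FRs cooperate fully with
  themselves yet never fall behind; they exist only when
  $m_1 + m_2 \ge 4$ and are extremely rare (8 strategies, a fraction
  $1.2\times10^{-4}$, among the $2^{16}$ memory-2 tables).

## Numerical decisions

**Stationary distributions** are computed by a dense LU solve of
$(T^\top - I)v = 0$ with one equation replaced by the normalization row;
the dimension is at most 64.  For very small $e$ the system can be
ill-conditioned, so the solution is accepted only if it satisfies
$v^\top T = v^\top$ to $10^{-9}$ and is nonnegative to the same
tolerance; otherwise the solver falls back to least squares on the full
stacked system.  The returned vector is clamped to $[0, 1]$ and
renormalized, so `sum(v) == 1` holds to machine precision.

**Efficiency** is judged numerically: $\gamma_{p,p} > 0.99$ at
$e = 10^{-4}$.  A strategy whose recovery from an error takes $k$ rounds
has $\gamma_{p,p} \approx 1 - k\,e$, so at $e = 10^{-4}$ the 0.99
threshold admits recovery times up to $k \approx 100$.  A much stricter
threshold (0.999) would misread slow recoverers at this $e$; pushing $e$
down to $10^{-5}$ makes both thresholds agree with the standard setting,
which is the sense in which the judgement is threshold-insensitive.  The
test suite checks exactly this stability, and the FR census is identical
under every setting.

**Rivalry** is decided exactly at $e = 0$ with a graph test.  Nodes are
the $2^{2m}$ full-memory joint states; from each node the focal action
is the deterministic prescription while the co-player's action is free,
giving two outgoing edges; an edge carries weight $0$ if the new round's
actions coincide, $-1$ if the focal player cooperates unilaterally and
$+1$ in the opposite case (the sign of the per-round payoff difference —
rescaling by $1/(b+1)$ shows the classification is independent of the
payoff values).  Long-term payoff differences are sums over cycles, so
the strategy is a rival iff no cycle has negative total weight, which
Floyd–Warshall detects in $O(n^3)$ with an early exit on a negative
diagonal.  The whole graph is scanned, including states unreachable from
mutual cooperation, because rivalry must hold from any initial state.
The graph is built at the strategy's capacity; the test suite verifies
that the verdict is invariant under lifting the representation.

**Memory lengths** are determined by a wildcard cascade: $m_1$ is the
deepest own-history round the table depends on, found by testing depth
$m, m-1, \dots, 1$; once the table is known to be independent of all
deeper rounds, the wildcarded prescriptions are well defined and the
test reduces to flipping a single history bit.  A brute-force oracle in
the test suite confirms the cascade on random strategies.

**Fixation probabilities** under the pairwise Fermi comparison,

$$\rho_{X\to Y} = \left\{\sum_{j=0}^{N-1}\exp\!\left[\sigma_{\mathrm{in}}\,
j\,\frac{(2N-j-3)\pi_{XX} + (j+1)\pi_{XY} - (2N-j-1)\pi_{YX} -
(j-1)\pi_{YY}}{2(N-1)}\right]\right\}^{-1},$$

are evaluated in log-sum-exp form, which is overflow-proof at any
selection strength and makes the neutral case ($\rho = 1/N$) exact.  The
grouping of the exponent — $j$ multiplying the whole bracket — is forced
by two checks: the $j = 0$ term must equal 1, and equal payoffs must
give exactly $1/N$.  A stochastic oracle (direct simulation of the
within-group imitation process) confirms the formula in the tests.

## Evolutionary simulations

Both population models operate in the small-mutation limit, where a
resident strategy (per group) is challenged by one mutant lineage at a
time.

* **Well-mixed** (`run_well_mixed`): one resident; each time step a
  mutant is drawn and fixes with probability $\rho_{X \to Y}$.
* **Group-structured** (`run_group_structured`): $M$ groups of size $N$,
  each homogeneous.  Per step a focal group is picked uniformly; with
  probability $r$ a mutant invades it (fixing with $\rho$), otherwise
  the group imitates a random other group with probability
  $T_{X\to Y} = f^{\mathrm{out}}_{X\to Y}\,\rho_{X\to Y}$, where the
  Fermi factor compares the homogeneous-group self-payoffs (members of
  different groups never play each other).

Mutants come from a **two-step sampler**: $m_1, m_2$ uniform on
$\{0,\dots,m\}$, then a uniform draw from the exact class
$S(m_1, m_2)$ by rejection.  Sampling uniformly from the full table
space instead would almost never produce short-memory strategies such as
AllD or TFT; the two-step scheme gives every memory class equal weight
and neutral mean memory lengths $(m/2, m/2)$.  The exact classes are
disjoint, so rejection (accept iff the drawn table really depends on its
deepest own and co-player rounds) samples the intended distribution; the
worst acceptance rate over classes is 1/2.

Observables — the residents' self-cooperation $\gamma_{p,p}$ at the
run's error rate, the fractions of FR / non-FR efficient / non-FR rival
residents, and the mean exact memory lengths — are streamed as running
means after burn-in, with an optional thinned time series.  Per-strategy
quantities are memoized; pair payoffs are cached only where the key set
stays bounded (the 16-strategy memory-one space, and resident–resident
pairs in the group model), while mutant-versus-resident payoffs in the
large spaces are computed fresh each step to keep memory bounded over
$10^7$-step runs.

### Default parameters

| parameter | default | meaning |
|---|---|---|
| $b$ | 3 (group), user-set (well-mixed) | benefit of cooperation; cost fixed at 1 |
| $e$ | $10^{-6}$ | implementation-error probability per action |
| $\sigma_{\mathrm{in}}$, $\sigma_{\mathrm{out}}$ | $30/(b-1)$ | selection strengths; the denominator keeps the effective selection pressure comparable across $b$ |
| $N$ | 2 (group) | group size |
| $M$ | 100 | number of groups |
| $r$ | $10^{-2}$ | mutation frequency relative to out-group imitation |
| steps / burn-in | $10^6$/$10^5$ (well-mixed), $10^7$/$10^6$ (group) | Monte Carlo length |

## Problem sizes and what the desk-scale runs show

The package's standard study conditions are desk-scale surrogates of
much longer simulations:

* Well-mixed memory-1 runs use $10^6$ steps ($10^5$ discarded) — the
  full protocol.  Memory-3 runs are reduced to $2\times10^5$ steps
  ($2\times10^4$ discarded), averaged over several seeds; at $b = 6$,
  $N = 8$ they give a mean cooperation of about 0.76–0.80.
* Group-structured memory-3 runs use $M = 100$ groups and $10^7$ steps
  ($10^6$ discarded) rather than $M = 10^3$ and $10^9$ steps.

The scale matters for one qualitative conclusion.  With the two-step
sampler the probability that a mutant is an FR is about $2\times10^{-5}$
(measured over $2\times10^5$ draws), so a $10^7$-step group run at
$r = 10^{-2}$ contains only $O(1)$ successful FR entries; moreover
$r = 10^{-2}$ coincides with the crossover scale $r \sim 1/M$ at
$M = 100$, where non-FR efficient strategies can replace FRs by neutral
drift.  Consequently, whether FRs dominate a single desk-scale run is
seed-dependent: cooperation is robustly high (0.82–0.91 across seeds),
but the FR fraction ranges from 0 to about 0.5.  Demonstrating stable FR
dominance requires either more groups, longer runs, or $r$ clearly above
$1/M$.

## What the generator emulates — and what it does not

All inputs are generated in code: enumerated or sampled strategy tables
and seeded Monte Carlo runs.  The model idealizes away much of what real
repeated interactions contain: payoffs are exact long-term averages (no
sampling noise from finitely many rounds), groups are always homogeneous
(the small-mutation limit), mutants are drawn independently of the
resident (no local mutation structure), strategies are pure (mixed
strategies cannot be FRs, since partnership and rivalry pin down some
prescriptions deterministically), and there is no discounting, no
population viscosity beyond the island structure, and no cost of memory.
Passing tests therefore validate the model's internal logic and its
documented quantities, not predictions about behavioral data.

## Known limitations

* Memory capacity is capped at $m = 3$ (64-entry tables); exhaustive
  classification is limited to classes with $m_1 + m_2 \le 4$, and
  larger classes are censused by Monte Carlo with Wilson intervals — the
  FR fraction estimate there is unreliable precisely because FRs are
  rare.
* `count_exact_memory` returns doubles; values are exact only up to
  $2^{53}$ (i.e. $m_1 + m_2 \le 5$).
* Evolutionary robustness of FRs ($\rho \le 1/N$ for every mutant) is a
  vanishing-error statement; at finite $e$ the fixation probability can
  exceed $1/N$ by $O(\sigma e)$, which the tests bound explicitly.
* The group model assumes fully separated intra-group time scales; the
  variant with completely separated mutation and imitation time scales
  is not implemented.
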
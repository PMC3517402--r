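---
title: "Methods: continuous-time Markov dynamics on Boolean networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuous-time Markov dynamics on Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A network of $n$ Boolean nodes defines a state space $\Sigma = \{0,1\}^n$.
Every node $i$ carries two rate expressions, an activation rate
$R_i^{\uparrow}(\mathbf S)$ and an inactivation rate
$R_i^{\downarrow}(\mathbf S)$, each a function of the full network state
(units: 1/time).  The dynamics is the continuous-time Markov jump process
with transition rates

$$\rho(\mathbf S \to \mathbf S') =
\begin{cases} R_i^{\uparrow}(\mathbf S) & S_i = 0\\
              R_i^{\downarrow}(\mathbf S) & S_i = 1 \end{cases}$$

whenever $\mathbf S$ and $\mathbf S'$ differ in exactly the node $i$, and 0
otherwise.  This is the natural continuous-time generalization of
asynchronous Boolean updating: with all non-zero rates equal, the embedded
jump chain selects among the $\gamma(\mathbf S)$ asynchronous successors
uniformly (probability $1/\gamma$), which the test suite checks both through
the normalized generator rows and empirically.

Assumptions: rates depend on the state only (time-independent Markov
process); at most one node flips at a time; rates are finite and
non-negative (a violation at evaluation time is a hard error, not a
warning).  Multi-level species are a modeling *pattern*, not engine
machinery: a two-level node B is encoded by an auxiliary node `B_h` whose
rules maintain `B_h <= B`; the engine never enforces the constraint itself.

## Simulation

Trajectories are generated by the kinetic Monte-Carlo (Gillespie) iteration:
with total exit rate $\rho_{tot}(\mathbf S) = \sum_{S'} \rho(S \to S')$ and
two uniform variates $u, u' \in (0,1]$,

1. $\delta t = -\log(u) / \rho_{tot}$;
2. the $k$-th candidate (in node declaration order) is selected where
   $\sum_{j<k}\rho_j < u'\rho_{tot} \le \sum_{j\le k}\rho_j$.

Numerical choices:

* $u$ is never 0 (R's uniform generator excludes the endpoints), so
  $\delta t$ is finite and positive.
* Candidate order is the node declaration index.  Any fixed order is
  distributionally equivalent; fixing it makes runs bit-reproducible.
* The boundary $u'\rho_{tot}$ exactly equal to a cumulative sum selects the
  earlier candidate ("$\le$" in step 2).
* Absorbing states ($\rho_{tot} = 0$) simply persist to the horizon; no
  pseudo-transition is inserted.
* A jump that would pass `max_time` is discarded and the trajectory is
  truncated at the horizon in the pre-jump state.
* Transition sets are memoized per state (rates depend only on the state, so
  memoization is exact, not an approximation).
* Trajectory $j$ draws from an RNG substream seeded by a fixed odd-multiplier
  hash of `(seed, j)` (Mersenne-Twister).  The ensemble is therefore
  bit-identical for any `parallel_degree`; base R has no counter-based
  generator, and the hash is bijective in $j$ modulo $2^{31}$, so substreams
  cannot collide within a run.
* States are carried as exact doubles (id $= \sum_i S_i 2^{i-1}$), which
  limits models to 52 nodes.  All bundled models have $n \le 10$.

## Windowed observables

Estimators average occupancy over windows $[\tau\Delta t, (\tau+1)\Delta t]$.
Per trajectory, the occupancy fraction of each state in each window is
computed exactly from the jump times; the ensemble estimate is the mean over
trajectories and its error is $\sqrt{\widehat{\mathrm{Var}}/N}$.  With a
single trajectory the error is reported as `NA` — the variance of one draw
carries no information.  The horizon is truncated down to an integer number
of windows; a trailing partial window is discarded with a warning, because
the window estimate is defined as an average over a *full* window.

The entropy $H(\tau)$ is the plug-in estimate $-\sum \hat p \log_2 \hat p$
applied to the estimated window distribution, with no bias correction — the
plug-in form is what the windowed definition prescribes, and a correction
would shift comparisons against the exact solution.

The transition entropy uses the jump-chain probabilities
$P_{S\to S'} = \rho_{S\to S'} / \sum_{S''} \rho_{S \to S''}$.  The printed
form of that denominator is ambiguous in places in the literature; the only
reading consistent with the jump-process definition — normalization over all
outgoing candidates of $S$ — is implemented.  $TH(S)$ is the entropy of that
distribution (0 for absorbing states), and $TH(\tau)$ weights $TH(S)$ by
window occupancy.

**Internal nodes** are marginalized out of all observables by summation.
For $TH$ two rules apply: if every transition out of $S$ flips an internal
node, $TH(S) = 0$; otherwise only output-flipping candidates enter the
normalization.  With internal nodes the observed process is no longer
Markovian, so this $TH$ is a generalization; results flag it
(`generalized_th`) and the run report records the warning.

**Input nodes** have fixed initial values; all other nodes start 0/1 with
probability 1/2.  **Reference nodes** define the Hamming distance
$HD(\mathbf S, \mathbf S_{ref})$ (count of disagreeing reference nodes),
whose windowed distribution is estimated exactly like the probabilities.

## Stationary distributions and clustering

Each trajectory yields the time-average occupancy over its whole horizon
$[0, T]$.  Transient (pre-attractor) occupancy is *not* removed: the
estimate is intentionally the plain whole-trajectory average, and its
quality is controlled by choosing $T$ large relative to the mixing time.
Supports are thresholded at strictly positive occupancy with no epsilon
floor — occupancies are exact rational fractions of $T$, so "visited" is
unambiguous.

Two estimates are compared by the support-overlap similarity
$D(a,b) = (\sum_{S \in \mathrm{shared}} \hat P_a[S])
(\sum_{S \in \mathrm{shared}} \hat P_b[S]) \in [0,1]$; indecomposable
stationary distributions are identical iff they share their support, so
$D \to 1$ for estimates of the same distribution as $T$ grows.  The cluster
definition "every member is $\alpha$-similar to some member" is an implicit
fixed point; its minimal deterministic closure is single-linkage: connected
components of the graph with edges $D \ge \alpha$.  Per cluster, the
averaged distribution is the plain mean of member probabilities and the
per-state error $\sqrt{\mathrm{Var}/|C|}$; cluster *proportions* (members /
estimates) estimate the probability of reaching each attractor.

Clustering refuses to run when any node is internal: marginalized
time-averages no longer estimate stationary distributions of a Markov
process.  The driver downgrades the refusal to a recorded warning and skips
the computation.

The first `statdist_traj_count` trajectories of the ensemble are used —
a subset, because stationary estimation costs memory per trajectory while
window estimates stream.

## The exact oracle

For $n \le 12$ (4096 states; the dense matrix exponential is the binding
cost) the generator $Q$ with rows summing to zero is built explicitly, and:

* instantaneous probabilities are $P(t) = P(0)e^{tQ}$;
* window averages are computed *exactly* via the block identity
  $\exp\!\big(\begin{smallmatrix}Q & I\\ 0 & 0\end{smallmatrix}\big)\Delta t
  = \big(\begin{smallmatrix}A & J\\ 0 & I\end{smallmatrix}\big)$ with
  $J = \int_0^{\Delta t} e^{Qs}ds$ — this matches the estimator's target
  without quadrature error, which keeps the engine-vs-oracle comparison a
  pure Monte-Carlo-error test;
* indecomposable stationary distributions are computed per terminal strongly
  connected component (null space of $Q$ restricted to the component),
  rather than from the global null space, which disambiguates degenerate
  eigenspaces;
* eigenvalue reality uses the tolerance $|\mathrm{Im}\,\lambda| >
  10^{-9}\max(1, |\lambda|)$, sized for floating-point spectra of defective
  matrices.

### Spectra and damped oscillations

A non-real generator eigenvalue is necessary for damped oscillations of
instantaneous probabilities, and when present there is always an initial
condition that produces them.  For the bundled single-cycle toy model this
criterion turns out to be structurally insensitive to the escape rate: with
the three in-cycle rates equal to 1 and escape rate $\varepsilon$ on the
leaving transition, the cycle block's characteristic polynomial is
$y^3(y + \varepsilon - 1) = 1$ with $y = \lambda + 1$, which has a complex
pair for *every* $\varepsilon > 0$ (as $\varepsilon \to \infty$ the roots
approach $-1 + \varepsilon^{-1/3}\cdot$ cube roots of unity).  The presence
of a non-real eigenvalue therefore cannot by itself separate the fast- and
slow-escape regimes, whose simulated behavior differs visibly.

What does separate them is *which* mode dominates: the package additionally
reports the **dominant decaying mode** — the eigenvalue of largest real part
among genuinely decaying modes, after excluding quasi-stationary modes
($\mathrm{Re}\,\lambda \ge -10^{-3}$ by default, sized to the slow-escape
leak rate).  For the toy model this mode is real ($-0.543$) in the fast
regime — late-time relaxation is monotone — and complex ($-1 \pm i$) in the
slow regime, matching the observed damped oscillation.  Tests assert both
the raw spectral facts and this diagnostic.

## The model language and configuration dialect

The printed examples of the BND-style language do not amount to a grammar,
so this package fixes one: `node NAME { rate_up = expr; rate_down = expr; }`
blocks, parameters written `$name`, C operator precedence
(`?:` < `||` < `&&` < `|` < `^` < `&` < comparisons < `+ -` < `* /` < unary),
`//` and `#` line comments, numeric truthiness (non-zero is true) and 1/0
coercion of Boolean results in arithmetic.  The ternary conditional
short-circuits, so an unbound parameter in a dead branch is not an error.

The configuration dialect is likewise this package's own: statements
`key = value;` with `timetick`, `max_time`, `sample_count`,
`statdist_traj_count`, `statdist_cluster_threshold`, `seed`,
`parallel_degree`, parameter assignments `$k = 0.5;`, and node-scoped
settings `NODE.is_internal`, `NODE.istate` (`0`, `1` or `random`; a fixed
value makes the node an input node) and `NODE.refstate`.  `timetick` and
`max_time` have no safe universal default and must be given explicitly;
`sample_count` defaults to 1000, `statdist_traj_count` to
`min(sample_count, 100)`, `statdist_cluster_threshold` to 0.8 (high
thresholds are preferable but a threshold too close to 1 makes finite-$T$
estimates of the same distribution fall into separate clusters).

## The example models

The fixtures are generated in code and define the study conditions.

**Toy** (3 nodes): A activated by C and inhibited by B, B activated by A,
C activated by A or B; every rate 1 except the escape transition
$[001] \to [000]$, the inactivation of C with both inputs off, exposed as
`$escape` (10 fast, $10^{-5}$ slow).  The published description labels this
escape parameter `rate_up`, although the transition is an inactivation; the
fixture implements it as C's `rate_down` in the `A = B = 0` context.
Defaults: `timetick 0.1`, `max_time 4`, 50,000 trajectories.  At that
horizon the exact final-window probability of the fixed point is 0.882 (the
slowest decaying mode is $-0.543$, so $\sim 11\%$ of the cycle mass remains
at $t=4$); convergence to 1 is reached around $t \approx 20$, which a test
verifies at the longer horizon.

**p53–Mdm2 damage response** (5 Boolean nodes; p53 two-level via `p53_h`).
The exact published rules are not machine-readable in the source text, so
the fixture is a documented *reconstruction* from the narrative: nuclear
Mdm2 degrades p53; only high p53 transcribes cytoplasmic Mdm2; Mdm2 enters
the nucleus from the cytoplasm with basal entry when p53 is off (p53
inhibits the translocation); DNA damage accelerates nuclear Mdm2
degradation; p53 promotes damage repair; damage is only set by the initial
condition.  The structural check — one fixed point
[p53 Mdm2C Mdm2N Dam] = [0010] and exactly two transition-graph cycles on
the consistent subspace `p53_h <= p53` — validates the reconstruction, and a
mismatch there would indict the reconstruction, not the engine.

**Mammalian cell cycle** (10 nodes): the published logical rules, two rate
classes (slow 1, fast 10).  The published per-transition class assignment is
not printed either; candidate assignments were compared against the exact
master-equation solution, and mappings that make the regulatory switches
fast destroy the oscillatory dominant mode entirely (all-real spectrum).
The fixture assigns the fast class to the purely phosphorylation-driven
inactivations of the CDK substrates Rb and p27 and keeps synthesis- and
degradation-driven events slow, consistent with the priority-class reasoning
of the source and yielding a complex dominant mode — hence damped
population-level cyclin oscillations from a G1 start with growth factors.
Stationary clustering from random initial conditions yields two clusters
(cycling with CycD on; G1 arrest with CycD off); the cluster *count* is
rate-independent, being fixed by the attractor structure.

**Random models** (property testing): each node receives a random logic over
up to three regulators in the canonical form
`rate_up = L ? r : 0; rate_down = L ? 0 : r'` with rates in
$\{0.5, 1, 2\}$ (or all 1), deterministically from a seed.

What the fixtures emulate — and what they do not: they reproduce published
*logical structure* and rate *classes*, not measured kinetic constants; real
signaling data have unequal, uncertain rates, time-dependent inputs and
non-Markovian memory, none of which these tests exercise.  Passing tests
demonstrate correctness of the simulator and estimators under the model
assumptions, not biological validity of any particular parameterization.

## Study sizes used in tests

Unit tests use hundreds to a few thousand trajectories; the study-level
checks use the fixture defaults (50,000 trajectories for the toy regimes;
500 stationary estimates over horizon 100 and 4,000 trajectories over
horizon 30 for the cell cycle; 20 random 5-node models at 1,500 trajectories
for the oracle sweep).  These sizes put Monte-Carlo errors well below the
assertion margins (e.g. state-probability errors $\sim 2\cdot10^{-3}$ at
$N = 50{,}000$).

## Known limitations

* $n \le 52$ (exact double state ids); exact analysis $n \le 12$ by default.
* Stationary estimates include transient occupancy; choose `max_time` large.
* Plug-in entropies are biased low by $O(\#states/N)$ at small $N$.
* Rates must be time-independent; no tau-leaping or other approximate
  accelerations are provided.
* The similarity threshold trades resolution for robustness: $\alpha$ close
  to 1 can split finite-$T$ estimates of one distribution; the 0.8 default
  suits the bundled models.
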
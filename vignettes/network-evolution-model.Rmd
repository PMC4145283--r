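---
title: "Complex networks as solutions of a constrained bi-objective optimisation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complex networks as solutions of a constrained bi-objective optimisation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(paretonet)
```

## The model

Three measures suffice to describe a surprising amount of network structure:
the node degree $x_i$, the edge degree, and the average shortest path length
$y$. `paretonet` treats a connected undirected simple network on $N$ nodes as
an evolving solution of a bi-objective optimisation problem:

$$
\min F_1 = \sum_i x_i, \qquad
\max F_2 = \sum_{i,j} \delta_{ij}\, x_i^a x_j^b, \qquad
\text{s.t. } y = c,\; x_i \ge x_{min},
$$

where $\delta_{ij} = 1$ iff nodes $i$ and $j$ are linked, the sum for $F_2$
runs over *ordered* adjacent pairs, and $a, b, c, x_{min}$ are non-negative
constants. The generalised edge degree $x_i^a x_j^b$ contains three familiar
special cases: a constant ($a=b=0$), the neighbour's degree ($a=0, b=1$) and
the degree product ($a=b=1$).

The two objectives oppose each other — fewer edges mean lower $F_1$ but also
lower $F_2$ — so "best" means Pareto-optimal: no feasible network improves
both at once. Sampling the Pareto front at different $(a, b, c, x_{min})$
produces networks of very different familiar types from one mechanism:
complete ($c = 1$), Delta-distribution (star-like, small $c$), compact
(onion-like hub cores), community-structure, fractal (large $c$), linear
regular ($c = (N+1)/3$), small-world ($c \approx \ln N$) and random
($a = b = 0$) networks.

### The ordered-pair convention

$F_2$ sums both orientations of every edge. This is normative in the package
because it is the only convention under which the degenerate case $a = b = 0$
collapses $F_2$ to exactly $F_1$ (each edge contributes
$x_i^0 x_j^0 + x_j^0 x_i^0 = 2$, and $F_1 = 2m$), which in turn is what makes
the degenerate model produce *random* networks: every feasible solution is
Pareto-optimal, so the constrained rewiring chain performs an unbiased walk.
Run reports carry both conventions (`f2_ordered`, `f2_unordered = f2/2`).

### The predicted exponent

Treating the degrees as i.i.d. samples of a random variable $X$ and relaxing
the bi-objective problem with a Lagrange multiplier, the Pareto-front degree
distribution is a truncated power law
$p(x) = C x^{-\gamma}$ on $[x_{min}, x_{max}]$ with

$$ \gamma(a, b) = \frac{a + b + 1}{a + b}, $$

implemented in `predicted_exponent()`. Anchors worth remembering:
$\gamma(0,1) = 2$ (the configuration exercised throughout the experiments),
$\gamma(1,1) = 1.5$, and $\gamma \to 1^+$ as $a+b \to \infty$ (the exponent-1
limit where scale-freeness degrades into randomness). At $a = b = 0$ no power
law is predicted and the function refuses to answer. The relation is
injectable (`relation` argument) so a refined formula can be swapped in
without touching callers. Normalisation is the discrete truncated zeta sum —
degrees are integers capped at $N - 1$ — with the continuous-integral variant
available for comparison (`powerlaw_model(..., normalization = "continuous")`).

```{r}
predicted_exponent(0, 1)
expected_mean_degree(powerlaw_model(gamma = 2, xmin = 2, xmax = 36))
```

## The solver

$F_1$ is discrete, so the bi-objective problem is reduced to a
single-objective one by the histogram method: fix $F_1$ through a fixed edge
budget $m$, then optimise $F_2$ alone. `optimise_network()` implements the
greedy constrained rewiring chain:

1. **Initial network** — a uniform random spanning tree (Prüfer decoding)
   plus uniformly random extra edges up to $m$, followed by degree-repair
   swaps until the floor $x_{min}$ holds. Connected and feasible by
   construction.
2. **Phase 1 (constrain)** — random single-edge rewires (remove one edge,
   add one absent pair), accepted iff $|y - c|$ strictly decreases. $F_2$ is
   ignored; this phase exists because a conjunctive rule cannot move a random
   start whose $y$ is far from $c$.
3. **Phase 2 (optimise)** — entered once $|y - c| \le$ `tol`; the greedy
   conjunctive rule: accept iff $F_2$ strictly improves *and* $|y - c|$ does
   not increase. Connectivity and the degree floor are enforced on every
   proposal; the edge count — hence $F_1$ — never changes.

### Why the conjunctive gap guard matters

A tempting relaxation of phase 2 is to accept any $F_2$ improvement that
keeps $y$ inside the tolerance band. That variant does not stop at scale-free
structure: with $F_2$ improvements re-admitted anywhere in the band, the
chain keeps funnelling edges into one node and converges to a condensed
state — a single hub holding a large fraction of all endpoints, with a
fitted exponent near 2.7 at the `n = 300, m = 762` configuration — which is
*not* what the theory's typical Pareto-front solution looks like. Under the
conjunctive rule the gap ratchets monotonically to (essentially) zero and
further hub growth is only possible along moves that preserve the total
distance sum exactly; that manifold exhausts itself at a multi-hub
scale-free local optimum. At `n = 300, m = 762, xmin = 2, c = 3.9` the chain
then stops (via the patience criterion) at a fitted exponent of about 2.1,
with $y = c$ to five decimals — the regime the analytic theory predicts with
$\gamma(0,1) = 2$ plus finite-size bias. The condensed endpoint of the
relaxed rule is a real and instructive failure mode of greedy $F_2$
maximisation; the conjunctive guard is the model's own brake on it.

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `tol` | 0.05 hops | success band for the final exact $|y - c|$; matches reporting $y$ to one decimal |
| `max_iters` | $3000\,m$ | candidate budget; sized so runs stop via `patience`, not the budget |
| `patience` | $20\,m$ | consecutive rejections that end the run (the greedy's fixed point) |
| `retry_limit` | 100 | redraws per iteration for illegal proposals (self-pair, existing edge, floor or connectivity violations) |
| `restarts` | 1 | independent restarts; best feasible $F_2$ wins |
| `aspl_sample_k` | 0 (exact) | optional landmark-sampled screen; acceptances and the reported $y$ are always re-verified exactly |

All distance evaluations are exact BFS hop counts. The all-pairs evaluation
runs 64 sources per pass with bitset frontiers and aborts as soon as the
partial distance sum exceeds the largest total an acceptable move could
have; the abort can only fire on moves that would be rejected anyway, so
results are bit-for-bit identical to full evaluation. The final reported $y$
is additionally cross-checked against an independent from-scratch BFS to
$10^{-12}$ on every run.

Determinism: a run is a pure function of (`params`, `config`); the seed
drives both the initial network (R's RNG) and the rewiring chain (a
Mersenne-Twister in the compiled core).

```{r}
p <- model_params(n = 100, m = 254, a = 0, b = 1, xmin = 2, c = 3.3)
res <- optimise_network(p, optimiser_config(seed = 1))
res
fit_powerlaw_mle(degree_sequence(res$final), xmin = 2)
```

## The community revision

Plain $F_2$ maximisation links hubs to each other: community structure is
*non*-optimal under the base model. In real systems, communities track
similarity distances — geographic, cultural, cognitive. The revision folds
such distances into the objective: each ordered edge term is divided by the
pair's similarity distance, here the minimal block-structured form
(`similarity_model()`: distance 1 within a block, $\delta > 1$ across
blocks). Cross-community hub links then buy less $F_2$, so hub formation
proceeds within blocks and the planted partition becomes visible in the
optimised network. This penalty form is this package's concrete
reconstruction of the revised model — the mechanism (biasing $F_2$ against
cross-community hub linking) is what matters, and the interface isolates the
functional form so alternatives can be swapped in. With $\delta = 1$ the
revision reduces exactly to the plain model, move for move under the same
seed. Newman–Girvan modularity over the planted partition
(`partition_modularity()`) is included purely as a verification metric.

```{r}
blocks <- planted_blocks(100, 2)
resc <- optimise_community(p, similarity_model(blocks, delta = 4),
                           optimiser_config(seed = 1))
c(community = partition_modularity(resc$final, blocks),
  plain = partition_modularity(res$final, blocks))
```

## The measurement layer

* `fit_powerlaw_mle()` — discrete truncated power-law MLE with the
  truncated-zeta normalisation on $[x_{min}, \max x]$, plus the KS distance
  of the tail. The fit floor defaults to the model's own $x_{min}$ (known by
  construction); a Clauset-style KS-minimising floor scan is available via
  `scan_xmin = TRUE`. The two protocols can disagree substantially on
  optimised networks, which concentrate extra mass at the floor: on an
  `xmin = 3` run the fixed-floor estimate was ~2.5 while the scanned-floor
  tail estimate was ~1.8. Comparisons should therefore always state the
  protocol; at $N = 300$ the fixed-floor estimate has seed-to-seed spread of
  a few hundredths, so means over ten seeded runs are used in all
  reproductions.
* `box_covering()` / `fractal_scaling()` — Song-style box covering (a box
  holds nodes at pairwise distance $< l_B$) by greedy colouring, minimised
  over `orders` random node orders, and the log–log fit of
  $N_B \propto l_B^{-d_B}$. The default box-diameter grid is log-spaced (a
  uniform $1..\mathrm{diam}$ grid oversamples the near-diameter plateau and
  biases the slope); the fractal verdict ($r^2 \ge 0.95$ over $\ge 4$
  scales) is reported, never asserted. Greedy covering overshoots the
  optimal count more at large $l_B$, so path graphs measure $d_B \approx
  0.9$ rather than exactly 1.
* `small_world_indices()` — $y / \ln N$ and $y / \ln \ln N$.
* `classify_regime()` — the spectrum of types along $c$ for given
  $(N, x_{min})$: complete at $c = 1$ and linear regular at the maximum
  $c = (N+1)/3$ are exact anchors, as is the small-world tag at
  $c \approx \ln N$; the inner Delta/compact/community/fractal breakpoints
  are *not* sharply defined by the model, so the defaults
  ($0.5, 0.9, 1.3 \times L$ with $L = \ln(N)/\sqrt{x_{min}}$) are labelled
  heuristics and fully configurable. The $\sqrt{x_{min}}$ scale realises the
  leftward shift of the whole spectrum as the degree floor grows — e.g.
  $c = \ln N$ is small-world at $x_{min} = 1$ but already fractal at
  $x_{min} = 3$. `check_proper_c()` warns when $c$ itself would distort the
  degree distribution (outside the compact–fractal band); it is advisory
  only.

```{r}
classify_regime(log(300), 300, xmin = 1)
classify_regime(log(300), 300, xmin = 3)
```

## What the generator emulates, and what it does not

The experimental protocol this package reproduces fixes $N = 300$,
$a = 0, b = 1$ (theoretical $\gamma = 2$) and sweeps the edge budget
($m \in \{762, 1157\}$), the floor ($x_{min} \in \{2, 3\}$) and the
constraint $c$. Generated networks are *ideal model networks*: simple,
undirected, exactly feasible, with every structural trait an emergent
consequence of the optimisation. They emulate the statistical traits of real
systems (scale-free tails, small-world path lengths, community blocks,
fractal stretching) but none of their measurement noise: there is no degree
measurement error, no missing edges, no disassortativity imposed by data
collection. Passing tests therefore validate the model's internal claims —
they do not certify that any particular real network is a sample of this
model.

Two known limitations deserve emphasis:

* **Stopping-state sensitivity of the fitted exponent.** The greedy chain's
  fitted exponent rises slowly through phase 2 toward its patience fixed
  point. At the sparser configurations ($x_{min} = 2$) the fixed point
  matches the reference exponents (2.10–2.13); at the
  denser ones ($x_{min} = 3$) the fixed point overshoots to ≈ 2.5 and the
  printed 2.16–2.28 corresponds to intermediate states of the chain. The
  package always runs to the fixed point — a principled, reproducible
  stopping state — rather than tuning budgets per configuration, and
  documents the discrepancy instead of hiding it.
* **Greedy, not global.** Results are local optima by design; simulated
  annealing or population methods would find higher $F_2$ at the same
  constraint but are out of scope. The 6-node exhaustive-search test shows
  the greedy-with-restarts reaching the global optimum at toy scale.

## Problem sizes used in the shipped checks

The test suite runs the experimental protocol at half scale
($N = 150$, three seeds per configuration, exact evaluation throughout) plus
toy-scale exhaustive oracles; `scripts/acceptance.R` recomputes the
full-scale protocol ($N = 300$, ten seeds per configuration) from scratch.
These sizes are the package's own choices: large enough for the fitted
exponents to be meaningful, small enough to re-run routinely.
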
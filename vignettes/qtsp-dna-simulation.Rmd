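---
title: "Simulating a DNA-computing algorithm for the Quota TSP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a DNA-computing algorithm for the Quota TSP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtspdna)
```

## The problem and the model

The Quota Traveling Salesman Problem (QTSP) asks, on a complete undirected
graph with positive integer edge distances $d_{ij}$, non-negative integer
vertex quotas $w_i$ and a threshold $Q$: find the cheapest cycle that starts
and ends at the origin vertex $v_1$ and whose visited vertices collect at
least $Q$ of quota. It is the zero-penalty special case of the
Prize-Collecting TSP and is NP-hard.

This package simulates a DNA-computing solution in the Adleman–Lipton model.
Data are single DNA strands in virtual test tubes; computation is a short
sequence of laboratory operations (merge, annealing/ligation, denaturation,
separation by probe, discard, append-head/tail, length selection by gel
electrophoresis, cutting, sort, read). The "algorithm" is massive parallel
filtering: first every candidate route materialises at once as a strand pool,
then each constraint is enforced by a physical filter, and the survivors'
lengths encode their cost so that a gel pulls out the optimum.

### The encoding

Each symbol is a DNA code word of $t$ nucleotides ($t$-mer, default
$t = 4$). A codebook for $n$ vertices holds $2n + 4$ words:

* $A_i\,B_i$ — the two-part block encoding vertex $v_i$;
* `#` — the strand terminator at both ends;
* `Y` — the pad appended (twice) for every vertex a route does *not* visit,
  so that simple cycles all measure the same length;
* $\psi$ — the quota unit: a route visiting $v_j$ gains $w_j$ copies;
* `X` — the distance unit: a route traversing edge $(i,j)$ gains $d_{ij}$
  copies.

A route $1 \to k_1 \to \dots \to k_r \to 1$ is the strand
$\#\,A_1B_1\,A_{k_1}B_{k_1}\cdots A_{k_r}B_{k_r}\,A_1B_1\,\#$. Edges exist in
the tube as complement-sense *linkers* $\overline{B_iA_j}$ which bridge the
junction $\dots B_i\,|\,A_j \dots$ during annealing.

Two deliberate conventions, both documented on the functions:

* **Complementation is position-wise** (A↔T, G↔C) with no 5′/3′ reversal:
  linkers are written in the same left-to-right order as the blocks they
  bridge, and the printed orientation labels are treated as decoration. This
  only affects rendering, never matching.
* **All tube logic operates on symbol lists, never on rendered
  nucleotides.** Random $t$-mers are not a comma-free code — a probe sequence
  can occur as a substring straddling a block boundary — so nucleotide-level
  matching would be unsound. Rendering (`render_strand()`, FASTA export) is
  presentation and interop only.

Cross-hybridisation safety is handled at the codebook level: random
generation rejects a word equal to another word's complement, while explicit
tables (including the published example table, itself unvalidated random
4-mers) only warn, since no matching ever depends on it.

### The five filtering stages

`solve_dna()` composes five stages, each built only from the eleven
operations:

1. **Generate.** Merge the vertex fragments with all edge linkers, anneal,
   denature, and keep by two separations the strands that begin `# A1` and
   end `A1 B1 #`. Annealing is exhaustive and deterministic — the model's
   premise is that all products form in parallel — and emits every
   *complete* (both-end-terminated) ligation product up to a cap of
   $2n + 4$ symbols. The cap is needed because closed walks are unbounded,
   and it provably cannot change the final answer: stage 2 discards
   anything longer anyway. The result is one strand per closed walk from
   $v_1$ with at most $n - 1$ intermediate steps.
2. **Uniquify.** For each $j = 2..n$, separate the strands visiting $v_j$
   and append `Y Y` to the others; a route visiting $r$ distinct vertices
   then measures exactly $(2r + 6) + 2(n - 1 - r) = 2n + 4$ symbols, while
   any revisit inflates the strand beyond that. One exact-length selection
   at $(2n+4)t$ leaves precisely the simple cycles through $v_1$.
3. **Quota.** Attach $w_j$ copies of $\psi$ at the head per visited vertex,
   then run $Q$ exact-length selection+discard rounds at
   $(2n+4)t + kt,\ k = 0..Q-1$, removing every strand with fewer than $Q$
   quota units (the $k = 0$ round covers routes whose visited vertices all
   have zero weight). Cut survivors at the $(\psi, \#)$ boundary and discard
   the $\psi$ fragments.
4. **Costs.** For every ordered pair $(i, j)$, separate the strands
   containing the adjacent symbols $B_i A_j$ — the routes traversing the
   edge in that direction — and append $d_{ij}$ copies of `X`. A two-cycle
   $1 \to j \to 1$ (a legal tour here, as in the arc-based formulation) is
   charged $d_{1j}$ once per direction.
5. **Select.** Sort out the shortest strands and read them. Cost is
   recovered as $(L - (2n+4)t)/t$. *All* co-minimal strands are reported —
   the problem may have several optimal tours, and at minimum both
   directions of each survive, so ties are never canonicalised away.

Strand pools are sets of species, not multisets: the pipeline only ever asks
existence and length questions, never abundance, so duplicates collapse.

## Worked example

A six-city fixture ships with the package. The full data of the published
example graph were never printed; `fig2_like_fixture()` is a synthetic
instance pinned to every printed fragment ($Q = 7$; $w_3, w_4, w_5 = 3, 2,
2$; optimal route $v_1 \to v_2 \to v_5 \to v_3 \to v_1$ with quota sum 9; the
route through $v_4, v_5$ alone infeasible since $2 + 2 < 7$), with the
remaining weights ($w_2 = 4$, $w_6 = 1$) and the distance matrix chosen once
so that the pinned optimum is unique up to direction — the exact oracle
verifies that in the test suite.

```{r worked}
fix <- fig2_like_fixture()
book <- build_codebook(6, source = "table5")
sol <- solve_dna(fix, codebook = book)
sol
tidy(sol)
glance(sol)
```

Both optimal strands decode to the published tour (in its two directions),
and `exact_solve(fix)` — full enumeration — returns the same cost and route
set.

## The exact oracle

`exact_solve()` is the package's ground truth, with two independent modes
that are cross-checked against each other in the tests: explicit permutation
enumeration (refused above $n = 10$) and a Held–Karp subset dynamic program
(per-state minimum path cost, quota checked per subset, every co-minimal
route recovered by backtracking tied predecessors). Subtour elimination is
structural — only simple cycles through the origin are enumerated — which
realises the same feasible set as the flow-based mixed-integer formulation
without materialising flow variables or requiring a MIP solver.

## Accounting: operations and strand lengths

Every operation increments exactly one ledger counter. `check_theorems()`
asserts the per-stage budgets (stage 1 ≤ 7 operations; stage 2 ≤
$4(n-1)+1$; stage 3 ≤ $4(n-1) + 2(Q-1) + 2$; stage 4 ≤ $4n^2$; stage 5 ≤ 2 —
an $O(n^2 + Q)$ total) and the final strand-length window
$(2n+4)t \le L \le (2n+4)t + lt$ with $l$ the total edge weight counted in
both directions.

```{r ledger}
rep <- check_theorems(sol$ledger, fix, sol, error_on_fail = FALSE)
rep
```

One accounting note: the stage-3 mechanism used here spends
$3(n-1) + 2(Q-1) + 5$ operations (weight loop, $Q$ selection/discard rounds,
cut, and two operations disposing of the $\psi$ fragments). That sits inside
the printed constant $4(n-1) + 2(Q-1) + 2$ exactly when $n \ge 4$; for
$n \in \{2, 3\}$ the printed constant — which is an $O(1)$-per-stage budget,
not a tight count — can be exceeded by up to two operations. The validation
suites therefore exercise $n \ge 4$, where the literal bound is asserted.

## The random-instance generator

`gen_random_instance()` defines the study conditions for all property
checks: symmetric integer distances uniform on 1..9, vertex quotas uniform
on 1..9 for $v_2..v_n$, the origin quota fixed at 0 (the depot carries no
prize, as in rooted prize-collecting instances), and
$Q = \lceil \sigma \sum_i w_i \rceil$ with $\sigma \in \{0.2, 0.5, 0.8\}$ —
the same conversion rule used for deriving QTSP instances from
Prize-Collecting TSP data (`convert_pctsp()`; the ceiling is this package's
choice, made so the collected quota genuinely meets the $\sigma$ fraction).
Setting $w_1 = 0$ makes every generated instance feasible for
$\sigma \le 1$, so the oracle-equivalence suite compares costs rather than
infeasibility signals; infeasible instances are still first-class
(`Q > collectible_quota()` raises a dedicated condition in both engines).

What the generator does *not* emulate: real PCTSP benchmark geometry
(clustered or metric distances — draws here are uniform and generally
non-metric), large prizes, or $n$ beyond desk scale. Passing tests therefore
certify the *mechanism* — that the strand pipeline computes exactly what the
enumeration oracle computes under these conditions — not solver performance
on benchmark files, which are external and out of scope.

## Numerical and design choices

* **Distances must be positive integers** — `X` is a unit chain. Non-integer
  input is rejected with a pre-scaling hint; nothing is silently rounded.
* **Quota rounds run $k = 0..Q-1$** (that is, $Q$ selection/discard rounds,
  one more than the minimum): the extra $k = 0$ round is required when all
  visited vertices could carry zero weight.
* **$Q = 0$ is accepted** and makes the quota vacuous; the filter loop then
  runs zero rounds and every simple cycle survives.
* **The origin's quota never counts toward $Q$**: the worked example sums
  only the visited non-origin weights, and the weight-attachment loop ranges
  over $j = 2..n$.
* **Sort ties**: all strands tied for the minimum length are returned; if
  the tube holds a single length, everything goes to the "shortest" side and
  the "longest" tube is empty.
* **Degenerate inputs**: empty tubes propagate through every operation
  without error; infeasibility surfaces only at the final read, as in the
  physical protocol.
* **Problem sizes.** The strand pool is inherently exponential
  ($\sum_{r \le n-1} (n-1) \cdot (n-2)^{r-1}$ closed walks before
  filtering — about 392,000 species at $n = 8$). The validation suites run
  $n \in 4..8$ for pipeline/oracle equivalence (50 seeded instances) and
  $n \le 7$ for the simple-cycle bijection, sizes at which a full run takes
  seconds; the solver refuses nothing, but the command-line wrapper guards
  at $n > 10$ by default with a message about the growth.

## Limitations

This is a faithful *simulator* of the symbolic content of the protocol, not
of its chemistry: hybridisation thermodynamics, melting temperatures,
mismatch tolerance, reaction yields and error rates are out of scope, and
strands either match exactly at symbol level or not at all. It is also not a
competitive QTSP solver — the exact oracle inside this same package
outperforms the tube simulation at every size; the point of the tube
pipeline is to certify the algorithm design, operation counts and length
bounds of the DNA protocol itself.
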
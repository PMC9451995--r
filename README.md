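# qtspdna

A deterministic, desk-scale simulator of a DNA-computing algorithm for the
**Quota Traveling Salesman Problem** (QTSP), in the Adleman–Lipton model.

Given a complete undirected graph with positive integer distances *d[i,j]*,
non-negative integer vertex quotas *w[i]* and a threshold *Q*, the QTSP asks
for the cheapest cycle from vertex 1 whose visited vertices collect at least
*Q*. The package is for readers and researchers of biomolecular computing
who want to *execute* such a protocol symbolically: every candidate route
materialises as a DNA strand in a virtual test tube, and the problem's
constraints are enforced one by one with the model's eleven laboratory
operations (merge, annealing/ligation, denaturation, separation, discard,
append-head/tail, length selection, cutting, sort, read).

The encoding uses one *t*-mer code word per symbol (default *t* = 4):
vertex blocks `Ai Bi`, the terminator `#`, the pad `Y` (two per unvisited
vertex, so simple cycles share one length), the quota unit `ψ` (*w[j]*
copies per visited vertex) and the distance unit `X` (*d[i,j]* copies per
traversed edge). The pipeline then reads:

1. anneal fragments with edge linkers `B̄iĀj` → all closed walks from v1;
2. pad with `Y Y` and length-select at `(2n+4)t` → exactly the simple cycles;
3. prepend `ψ` quota units, discard lengths below `(2n+4)t + Qt`, cut the
   prefix back off → the quota-feasible cycles;
4. append `X` distance units per traversed edge → length encodes cost;
5. gel-sort and read the shortest strands → all co-minimal optimal tours.

Every run is certified against an exact enumeration oracle (permutation
mode and a Held–Karp subset dynamic program), and an operation ledger checks
the protocol's complexity budget (an O(n² + Q) operation total) and the
final strand-length window `(2n+4)t ≤ L ≤ (2n+4)t + lt`.

## Worked example

A six-city example instance ships with the package (`fig2_like_fixture()`,
a synthetic instance consistent with the published worked example: Q = 7,
quotas (0, 4, 3, 2, 2, 1)):

```r
library(qtspdna)
fix  <- fig2_like_fixture()
book <- build_codebook(6, source = "table5")   # the published code words
sol  <- solve_dna(fix, codebook = book)
sol
#> <qtsp_solution engine=dna> cost = 8, 2 optimal route(s)
#>   1-2-5-3-1  (quota 9)
#>   1-3-5-2-1  (quota 9)
```

The two strands are the same optimal tour in its two traversal directions:
visiting vertices 2, 5, 3 collects quota 4 + 2 + 3 = 9 ≥ 7 at total
distance 8, and no quota-feasible cycle is cheaper (`exact_solve(fix)`
returns the identical cost and route set). Rendering the winning strand
with the published codebook reproduces the published sequence byte for
byte:

```r
render_strand(encode_route(c(1, 2, 5, 3, 1)), book, "vertex-blocks-only")
#> [1] "GTTTGATGGTTAAGTTTATTCTAGTACGACTGGTTTGATG"
tidy(sol)        # one tibble row per optimal route
glance(sol)      # engine, cost, number of routes, total bio-operations
check_theorems(sol$ledger, fix, sol)   # operation budget + length window
```

A thin command-line wrapper covers generation, solving and conversion of
Prize-Collecting TSP instances (quotas = prizes, penalties dropped,
`Q = ⌈σ·Σp⌉`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli/qtspdna.R", package="qtspdna"))') \
    solve inst/extdata/fig2_like_synthetic.qtsp --engine both --codebook table5
```

## Scope

The simulator is faithful to the symbolic content of the protocol, not its
chemistry: no hybridisation thermodynamics, melting temperatures or error
rates, and no ambition to compete with conventional QTSP solvers — the
strand pool grows exponentially (~4 × 10⁵ species at n = 8), which is the
protocol's premise of massive parallelism, not a performance bug. See the
methods vignette (`vignettes/qtsp-dna-simulation.Rmd`) for the model,
design decisions and limitations.
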
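# Independent oracles used to certify the simulator. These deliberately share
# no code with the package internals: routes are plain integer vectors and
# enumeration is by direct recursion / permutation, so agreement between a
# tube computation and these helpers is a genuine cross-check.

# All closed walks 1 -> v2 -> ... -> 1 on the complete graph with interior
# vertices drawn from 2..n, consecutive vertices distinct, and between 1 and
# max_interior interior steps. This is the semantic content of the annealing
# data pool (revisits allowed, immediate repeats impossible).
oracle_closed_walks <- function(n, max_interior = n - 1L) {
  walks <- list()
  grow <- function(path) {
    walks[[length(walks) + 1L]] <<- c(1L, path, 1L)
    if (length(path) < max_interior) {
      for (v in setdiff(2:n, path[length(path)])) grow(c(path, v))
    }
  }
  for (v in 2:n) grow(v)
  walks
}

# All permutations of a vector, by straightforward insertion.
oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in oracle_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# All simple cycles through vertex 1: permutations of every non-empty subset.
oracle_simple_cycles <- function(n) {
  cycles <- list()
  for (r in 1:(n - 1L)) {
    for (S in utils::combn(2:n, r, simplify = FALSE)) {
      for (p in oracle_perms(S)) cycles[[length(cycles) + 1L]] <- c(1L, p, 1L)
    }
  }
  cycles
}

oracle_cost <- function(d, route) {
  sum(d[cbind(route[-length(route)], route[-1L])])
}

oracle_quota <- function(w, route) sum(w[setdiff(unique(route), 1L)])

# Brute-force QTSP optimum: filter simple cycles by quota, minimise cost.
oracle_best <- function(inst) {
  cycles <- oracle_simple_cycles(inst$n)
  keep <- vapply(cycles, function(r) oracle_quota(inst$quotas, r) >= inst$Q, NA)
  cycles <- cycles[keep]
  if (length(cycles) == 0L) return(NULL)
  costs <- vapply(cycles, function(r) oracle_cost(inst$distances, r), 0L)
  list(cost = min(costs), routes = cycles[costs == min(costs)])
}

route_strings <- function(routes) {
  sort(vapply(routes, paste, "", collapse = "-"))
}

# A tiny 4-city instance with a hand-verifiable optimum: quota-feasible
# vertex sets are {2,3}, {2,4} (cost 6 each) and {2,3,4} whose cheapest order
# 1-2-3-4-1 costs 1+1+1+2 = 5, the overall optimum (with its reversal).
four_city <- function() {
  d <- matrix(0L, 4L, 4L)
  d[1, 2] <- 1L; d[1, 3] <- 4L; d[1, 4] <- 2L
  d[2, 3] <- 1L; d[2, 4] <- 3L; d[3, 4] <- 1L
  d <- d + t(d)
  qtsp_instance(d, quotas = c(0L, 3L, 2L, 2L), Q = 5L)
}

table5_book <- function() build_codebook(6L, source = "table5")
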
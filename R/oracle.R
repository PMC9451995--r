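# Exact QTSP solving by explicit enumeration: the ground truth every DNA
# pipeline run is checked against. Subtour elimination is structural -- only
# simple cycles through the origin are enumerated -- which realises the same
# feasible set as the flow-based mixed-integer formulation without
# materialising flow variables.

#' Enumerate all simple cycles through the origin
#'
#' Lists every cycle `c(1, pi(S), 1)` for each non-empty subset
#' `S` of vertices 2..n and each ordering `pi` of it; both traversal
#' directions appear as separate cycles. Two-vertex cycles `1 -> j -> 1` are
#' included (they are legal tours; their cost counts `d[1, j]` twice).
#'
#' @param inst A `qtsp_instance` (only `n` is used).
#' @param max_n Refusal bound: enumeration is factorial, so instances with
#'   `n > max_n` (default 10) are rejected with a size error.
#' @return List of integer cycles.
#' @examples
#' length(enumerate_simple_cycles(fig2_like_fixture()))  # 325 for n = 6
#' @export
enumerate_simple_cycles <- function(inst, max_n = 10L) {
  n <- inst$n
  if (n > max_n) {
    qtsp_error(sprintf("n = %d exceeds the enumeration bound %d", n, max_n),
               "qtspdna_size_error")
  }
  cycles <- vector("list", 0L)
  path <- integer(0)
  recurse <- function(path) {
    avail <- setdiff(2:n, path)
    for (v in avail) {
      p <- c(path, v)
      cycles[[length(cycles) + 1L]] <<- c(1L, p, 1L)
      recurse(p)
    }
  }
  recurse(integer(0))
  cycles
}

#' Solve a QTSP instance exactly
#'
#' Two independent modes:
#' \describe{
#'   \item{`"permutation"`}{Enumerates every simple cycle through vertex 1
#'     ([enumerate_simple_cycles()]), filters by quota, minimises cost.
#'     Factorial; refused above `max_n = 10`.}
#'   \item{`"subset-dp"`}{Held-Karp dynamic programming: minimum path cost per
#'     (visited-subset, last-vertex) state, quota checked per subset, all
#'     co-minimal cycles recovered by backtracking every tied predecessor.
#'     Practical to n of about 16.}
#' }
#' Both modes agree wherever both run, and both report all co-minimal routes
#' (ties are meaningful: at minimum the two directions of each optimal tour).
#'
#' @param inst A `qtsp_instance`.
#' @param mode `"subset-dp"` (default) or `"permutation"`.
#' @return A `qtsp_solution` with `routes`, `cost`, `quota_collected`,
#'   `engine = "exact"`.
#' @examples
#' exact_solve(fig2_like_fixture())$cost  # 8
#' @export
exact_solve <- function(inst, mode = c("subset-dp", "permutation")) {
  mode <- match.arg(mode)
  if (inst$Q > collectible_quota(inst)) {
    abort_infeasible(sprintf(
      "Q = %d exceeds the collectible quota %d", inst$Q, collectible_quota(inst)))
  }
  routes <- if (mode == "permutation") exact_permutation(inst) else exact_dp(inst)
  if (length(routes) == 0L) abort_infeasible()
  new_solution(inst, routes, engine = "exact")
}

exact_permutation <- function(inst) {
  cycles <- enumerate_simple_cycles(inst)
  ok <- vapply(cycles, function(r) route_quota(inst, r) >= inst$Q, NA)
  cycles <- cycles[ok]
  if (length(cycles) == 0L) return(list())
  costs <- vapply(cycles, function(r) route_cost(inst, r), 0)
  cycles[costs == min(costs)]
}

exact_dp <- function(inst) {
  n <- inst$n; d <- inst$distances; w <- inst$quotas; Q <- inst$Q
  m <- n - 1L                      # interior vertices 2..n, bit v-1
  nmask <- bitwShiftL(1L, m)
  INF <- .Machine$integer.max %/% 4L
  dp <- matrix(INF, nrow = nmask, ncol = m)  # dp[mask+1, last-1]
  for (v in 2:n) dp[bitwShiftL(1L, v - 2L) + 1L, v - 1L] <- d[1L, v]
  masks <- seq_len(nmask - 1L)
  quota_of <- vapply(masks, function(mask) {
    sum(w[which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))) != 0L) + 1L])
  }, 0L)
  for (mask in masks) {
    for (last in 2:n) {
      bit <- bitwShiftL(1L, last - 2L)
      if (bitwAnd(mask, bit) == 0L) next
      cur <- dp[mask + 1L, last - 1L]
      if (cur >= INF) next
      rest <- bitwAnd(nmask - 1L, bitwNot(mask))
      for (nxt in 2:n) {
        nbit <- bitwShiftL(1L, nxt - 2L)
        if (bitwAnd(rest, nbit) == 0L) next
        nm <- bitwOr(mask, nbit)
        cand <- cur + d[last, nxt]
        if (cand < dp[nm + 1L, nxt - 1L]) dp[nm + 1L, nxt - 1L] <- cand
      }
    }
  }
  feas <- masks[quota_of >= Q]
  if (length(feas) == 0L) return(list())
  best <- INF
  for (mask in feas) {
    for (last in 2:n) {
      if (bitwAnd(mask, bitwShiftL(1L, last - 2L)) == 0L) next
      tot <- dp[mask + 1L, last - 1L] + d[last, 1L]
      if (tot < best) best <- tot
    }
  }
  if (best >= INF) return(list())
  # recover every co-minimal route by backtracking all tied predecessors
  routes <- list()
  backtrack <- function(mask, last, suffix) {
    prev_mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, last - 2L)))
    if (prev_mask == 0L) {
      if (dp[mask + 1L, last - 1L] == d[1L, last]) {
        routes[[length(routes) + 1L]] <<- c(1L, last, suffix, 1L)
      }
      return(invisible(NULL))
    }
    for (prev in 2:n) {
      if (bitwAnd(prev_mask, bitwShiftL(1L, prev - 2L)) == 0L) next
      if (dp[prev_mask + 1L, prev - 1L] + d[prev, last] ==
          dp[mask + 1L, last - 1L]) {
        backtrack(prev_mask, prev, c(last, suffix))
      }
    }
  }
  for (mask in feas) {
    for (last in 2:n) {
      if (bitwAnd(mask, bitwShiftL(1L, last - 2L)) == 0L) next
      if (dp[mask + 1L, last - 1L] + d[last, 1L] == best) {
        backtrack(mask, last, integer(0))
      }
    }
  }
  unique(routes)
}

#' Validate a route against a QTSP instance
#'
#' A total function reporting, per constraint, whether the route is a simple
#' cycle through vertex 1, whether its collected quota reaches Q, and its
#' cost. Never throws.
#'
#' @param inst A `qtsp_instance`.
#' @param route Integer vector.
#' @return A tibble with columns `check`, `pass`, `value`.
#' @export
validate_solution <- function(inst, route) {
  route <- as.integer(route)
  interior <- route[-c(1L, length(route))]
  simple <- length(route) >= 3L &&
    route[1L] == 1L && route[length(route)] == 1L &&
    !anyDuplicated(interior) && !any(interior == 1L) &&
    all(route >= 1L & route <= inst$n)
  quota <- if (simple) route_quota(inst, route) else NA_integer_
  cost <- if (simple) route_cost(inst, route) else NA_integer_
  tibble::tibble(
    check = c("simple_cycle", "quota", "cost"),
    pass = c(simple, isTRUE(quota >= inst$Q), simple),
    value = c(NA_integer_, quota, cost)
  )
}
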
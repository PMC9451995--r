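# The five composed filtering algorithms and the end-to-end solver.

tube_route_set <- function(tube) {
  rep <- tube_read(tube)
  sort(rep$route[!rep$malformed])
}

test_that("the data pool holds exactly the capped closed walks from vertex 1", {
  book2 <- build_codebook(2, seed = 1)
  inst2 <- qtsp_instance(matrix(c(0, 1, 1, 0), 2), c(0, 1), 1)
  t4 <- algorithm1_generate(inst2, book2)
  expect_identical(tube_route_set(t4), "1-2-1")

  inst4 <- four_city()
  book4 <- build_codebook(4, seed = 1)
  t4 <- algorithm1_generate(inst4, book4)
  want <- vapply(oracle_closed_walks(4L, 3L), paste, "", collapse = "-")
  expect_setequal(tube_route_set(t4), want)

  fix <- fig2_like_fixture()
  t4 <- algorithm1_generate(fix, table5_book())
  expect_true("1-4-5-1" %in% tube_route_set(t4))
})

test_that("uniquification leaves the simple cycles at one exact length", {
  for (n in 4:6) {
    inst <- gen_random_instance(n, sigma = 0.5, seed = 40 + n)
    book <- build_codebook(n, seed = 1)
    lg <- new_ledger()
    t4 <- algorithm1_generate(inst, book, lg)
    simp <- algorithm2_uniquify(t4, inst, book, lg)
    expect_true(all(simp$nsym * book$t == (2L * n + 4L) * book$t))
    expect_setequal(tube_route_set(simp),
                    route_strings(oracle_simple_cycles(n)))
  }
  # a revisiting walk is padded past the target length and eliminated
  fix <- fig2_like_fixture()
  book <- table5_book()
  walk <- c(encode_route(c(1, 2, 3, 2, 4, 1)))
  out <- algorithm2_uniquify(new_tube("T4", list(walk)), fix, book)
  expect_identical(tube_size(out), 0L)
  # the published example survivor carries its YYYYYY pad
  t4 <- algorithm1_generate(fix, book)
  simp <- algorithm2_uniquify(t4, fix, book)
  rep <- tube_read(simp)
  expect_true(paste(c(encode_route(c(1, 4, 5, 1)), rep("Y", 6)), collapse = " ")
              %in% rep$symbols)
})

test_that("the quota filter keeps exactly the feasible visited-vertex sets", {
  for (n in 5:6) {
    inst <- gen_random_instance(n, sigma = 0.5, seed = 50 + n)
    book <- build_codebook(n, seed = 1)
    feas <- algorithm3_quota_filter(
      algorithm2_uniquify(algorithm1_generate(inst, book), inst, book),
      inst, book)
    got <- unique(vapply(strsplit(tube_route_set(feas), "-"), function(r) {
      paste(sort(unique(setdiff(as.integer(r), 1L))), collapse = ",")
    }, ""))
    all_sets <- unlist(lapply(1:(n - 1), function(r) {
      utils::combn(2:n, r, simplify = FALSE)
    }), recursive = FALSE)
    want <- vapply(
      Filter(function(S) sum(inst$quotas[S]) >= inst$Q, all_sets),
      function(S) paste(S, collapse = ","), "")
    expect_setequal(got, want)
    # the psi prefixes are cut back off: uniform length again
    expect_true(all(feas$nsym == 2L * n + 4L))
  }
  # the published infeasible route is eliminated (2 + 2 < 7)
  fix <- fig2_like_fixture()
  book <- table5_book()
  feas <- algorithm3_quota_filter(
    algorithm2_uniquify(algorithm1_generate(fix, book), fix, book), fix, book)
  routes <- tube_route_set(feas)
  expect_false("1-4-5-1" %in% routes)
  expect_true("1-3-4-5-1" %in% routes)   # 3 + 2 + 2 = 7 >= Q
})

test_that("a vacuous quota keeps every simple cycle", {
  inst <- four_city()
  inst0 <- qtsp_instance(inst$distances, inst$quotas, Q = 0L)
  book <- build_codebook(4, seed = 1)
  feas <- algorithm3_quota_filter(
    algorithm2_uniquify(algorithm1_generate(inst0, book), inst0, book),
    inst0, book)
  expect_setequal(tube_route_set(feas), route_strings(oracle_simple_cycles(4L)))
})

test_that("cost tails carry exactly the route distance as X symbols", {
  inst <- four_city()
  book <- build_codebook(4, seed = 1)
  feas <- algorithm3_quota_filter(
    algorithm2_uniquify(algorithm1_generate(inst, book), inst, book),
    inst, book)
  costed <- algorithm4_append_costs(feas, inst, book)
  rep <- tube_read(costed)
  for (i in seq_len(nrow(rep))) {
    syms <- strsplit(rep$symbols[i], " ", fixed = TRUE)[[1]]
    route <- as.integer(strsplit(rep$route[i], "-", fixed = TRUE)[[1]])
    expect_identical(sum(syms == "X"), as.integer(route_cost(inst, route)))
  }
  # a two-cycle is charged once in each traversal direction
  two <- c(encode_route(c(1, 2, 1)), rep("Y", 4))
  out <- algorithm4_append_costs(new_tube("T9", list(two)), inst, book)
  syms <- strsplit(tube_read(out)$symbols, " ", fixed = TRUE)[[1]]
  expect_identical(sum(syms == "X"), as.integer(2L * inst$distances[1, 2]))
})

test_that("selection reads all co-minimal strands", {
  inst <- four_city()
  book <- build_codebook(4, seed = 1)
  sol <- solve_dna(inst, codebook = book)
  expect_identical(sol$cost, 5L)
  expect_setequal(route_strings(sol$routes), c("1-2-3-4-1", "1-4-3-2-1"))
  # a symmetric 5-city instance with two cost-tied optimal tours
  d <- matrix(5L, 5L, 5L); diag(d) <- 0L
  d[1, 2] <- d[2, 1] <- 1L; d[1, 3] <- d[3, 1] <- 1L
  d[2, 4] <- d[4, 2] <- 1L; d[3, 5] <- d[5, 3] <- 1L
  d[4, 5] <- d[5, 4] <- 6L
  tied <- qtsp_instance(d, quotas = c(0L, 1L, 1L, 2L, 2L), Q = 3L)
  sol2 <- solve_dna(tied, codebook = build_codebook(5, seed = 2))
  ex2 <- exact_solve(tied)
  expect_identical(sol2$cost, ex2$cost)
  expect_setequal(route_strings(sol2$routes), route_strings(ex2$routes))
  expect_gte(length(unique(lapply(sol2$routes, function(r) {
    sort(unique(r))
  }))), 2L)  # genuinely different vertex sets, not just directions
})

test_that("solve_dna matches the exact oracle on seeded instances", {
  for (n in 4:6) {
    for (k in 1:3) {
      inst <- gen_random_instance(n, sigma = c(0.2, 0.5, 0.8)[k],
                                  seed = 600 + 10 * n + k)
      sol <- solve_dna(inst)
      ex <- exact_solve(inst)
      expect_identical(sol$cost, ex$cost)
      expect_setequal(route_strings(sol$routes), route_strings(ex$routes))
    }
  }
})

test_that("an unreachable quota raises the infeasibility condition", {
  inst <- four_city()
  hard <- qtsp_instance(inst$distances, inst$quotas, Q = 50L)
  expect_error(solve_dna(hard), class = "qtspdna_infeasible")
})

test_that("solution invariants hold: simple cycles, quota met, X equals cost", {
  fix <- fig2_like_fixture()
  sol <- solve_dna(fix, codebook = table5_book())
  for (i in seq_along(sol$routes)) {
    r <- sol$routes[[i]]
    expect_true(all(validate_solution(fix, r)$pass))
    syms <- strsplit(sol$strands[i], " ", fixed = TRUE)[[1]]
    expect_identical(sum(syms == "X"), as.integer(sol$cost))
  }
  expect_true(all(sol$quota_collected >= fix$Q))
})

test_that("check_theorems passes on honest runs and catches violations", {
  fix <- fig2_like_fixture()
  sol <- solve_dna(fix, codebook = table5_book())
  rep <- check_theorems(sol$ledger, fix, sol)
  expect_true(all(rep$pass))
  # inflate a stage count artificially and expect the violation error
  bad <- new_ledger()
  ledger_stage(bad, "alg1")
  for (i in 1:20) tube_merge(new_tube("A"), new_tube("B"), bad)
  expect_error(check_theorems(bad, fix, sol), class = "qtspdna_theorem_violation")
})

test_that("the trace log carries one line per counted operation", {
  fix <- fig2_like_fixture()
  sol <- solve_dna(fix, codebook = table5_book(), trace = TRUE)
  expect_length(ledger_trace(sol$ledger), sum(ledger_tally(sol$ledger)$count))
  expect_match(ledger_trace(sol$ledger)[1], "^alg1\tmerge\t")
})
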
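# The eleven tube operations as contracts, including the annealing oracle.

frag_set <- function(n) {
  c(list(c("#", "A1", "B1")),
    lapply(2:n, function(j) c(paste0("A", j), paste0("B", j))),
    list(c("A1", "B1", "#")))
}

linker_set <- function(n) {
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  pairs <- pairs[pairs$i != pairs$j, ]
  Map(function(i, j) c(paste0("B", i), paste0("A", j)), pairs$i, pairs$j)
}

tube_routes <- function(tube) {
  rep <- tube_read(tube)
  sort(rep$route[!rep$malformed])
}

test_that("merge unions species and collapses duplicates", {
  a <- new_tube("T1", list(c("A1", "B1")))
  b <- new_tube("T2", list(c("A2", "B2")))
  expect_identical(tube_size(tube_merge(a, b)), 2L)
  expect_identical(tube_size(tube_merge(a, a)), 1L)
  expect_identical(tube_size(tube_merge(new_tube("T1"), new_tube("T2"))), 0L)
})

test_that("annealing generates exactly the capped closed-walk products", {
  n <- 3L
  t <- tube_merge(new_tube("T1", frag_set(n)),
                  new_tube("T2", linker_set(n), sense = "-"))
  out <- tube_denature(tube_anneal(t, cap_symbols = 10L))
  # independent enumeration: closed walks from vertex 1, <= 2 interior steps
  want <- vapply(oracle_closed_walks(n, 2L), paste, "", collapse = "-")
  expect_setequal(tube_routes(out), want)
  expect_identical(tube_size(out), 4L)
})

test_that("annealing with no linkers passes fragments through, capped", {
  t <- new_tube("T1", frag_set(3L))
  out <- tube_anneal(t, cap_symbols = 10L)
  expect_identical(tube_size(out), tube_size(t))
  # cap below the smallest fragment empties the tube (not an error)
  expect_identical(tube_size(tube_anneal(t, cap_symbols = 1L)), 0L)
})

test_that("annealing at the pipeline cap matches the walk oracle at n = 6", {
  n <- 6L
  t <- tube_merge(new_tube("T1", frag_set(n)),
                  new_tube("T2", linker_set(n), sense = "-"))
  out <- tube_denature(tube_anneal(t, cap_symbols = 2L * n + 4L))
  want <- vapply(oracle_closed_walks(n, n - 1L), paste, "", collapse = "-")
  expect_setequal(tube_routes(out), want)
  expect_true("1-4-5-1" %in% tube_routes(out))
})

test_that("denaturation drops linker species and nothing else", {
  t <- tube_merge(
    new_tube("T", list(c("#", "A1", "B1", "A2", "B2", "A1", "B1", "#"))),
    new_tube("L", list(c("B1", "A2")), sense = "-"))
  out <- tube_denature(t)
  expect_identical(tube_size(out), 1L)
  expect_identical(out$sense, "+")
  expect_identical(tube_size(tube_denature(new_tube("T"))), 0L)
})

test_that("separation splits on contiguous symbol patterns", {
  t <- new_tube("T", list(
    c("#", "A1", "B1", "A4", "B4", "A5", "B5", "A1", "B1", "#"),
    c("#", "A1", "B1", "A5", "B5", "A1", "B1", "#")))
  sep <- tube_separate(t, c("A4", "B4"))
  expect_identical(tube_size(sep$matched), 1L)
  expect_identical(tube_size(sep$rest), 1L)
  # edge-traversal pattern: B3 A5 matches a route using edge (3, 5)
  t2 <- new_tube("T", list(encode_route(c(1, 3, 5, 1)), encode_route(c(1, 5, 3, 1))))
  sep2 <- tube_separate(t2, c("B3", "A5"))
  expect_identical(tube_read(sep2$matched)$route, "1-3-5-1")
  # a pattern longer than any strand never matches
  sep3 <- tube_separate(t2, rep(c("A2", "B2"), 10))
  expect_identical(tube_size(sep3$matched), 0L)
  expect_error(tube_separate(t2, character(0)), class = "qtspdna_invalid_pattern")
})

test_that("separation partitions the tube", {
  set.seed(7)
  for (i in 1:20) {
    routes <- lapply(1:8, function(.) {
      n <- 6L; c(1L, sample(2:n, sample(1:(n - 1), 1)), 1L)
    })
    t <- new_tube("T", lapply(routes, encode_route))
    j <- sample(2:6, 1)
    sep <- tube_separate(t, c(paste0("A", j), paste0("B", j)))
    expect_identical(tube_size(sep$matched) + tube_size(sep$rest), tube_size(t))
    expect_length(intersect(sep$matched$key, sep$rest$key), 0L)
    expect_setequal(c(sep$matched$key, sep$rest$key), t$key)
  }
})

test_that("discard empties any tube and counts as one operation", {
  lg <- new_ledger()
  expect_identical(tube_size(tube_discard(new_tube("T", frag_set(4L)), lg)), 0L)
  expect_identical(tube_size(tube_discard(new_tube("T"), lg)), 0L)
  tal <- ledger_tally(lg)
  expect_identical(tal$count[tal$op == "discard"], 2L)
})

test_that("append operations extend every strand at the requested end", {
  t <- new_tube("T", list(encode_route(c(1, 4, 5, 1))))
  tail2 <- tube_append_tail(t, c("Y", "Y"))
  expect_match(tube_read(tail2)$symbols, "# Y Y$")
  head3 <- tube_append_head(t, rep("psi", 3))
  expect_match(tube_read(head3)$symbols, "^psi psi psi #")
  expect_identical(tube_size(tube_append_tail(new_tube("T"), "Y")), 0L)
  expect_error(tube_append_head(t, character(0)), class = "qtspdna_invalid_pattern")
})

test_that("length selection moves exactly the strands of length L", {
  t <- new_tube("T", list(
    encode_route(c(1, 2, 1)),                 # 8 symbols  = 32 nt at t = 4
    c(encode_route(c(1, 2, 1)), "Y", "Y"),    # 10 symbols = 40 nt
    encode_route(c(1, 2, 3, 4, 5, 6, 1)) ))   # 16 symbols = 64 nt
  sel <- tube_select_length(t, 64L, 4L)
  expect_identical(tube_size(sel$selected), 1L)
  expect_identical(tube_read(sel$selected)$route, "1-2-3-4-5-6-1")
  expect_identical(tube_size(sel$rest), 2L)
  expect_error(tube_select_length(t, 63L, 4L), class = "qtspdna_invalid_length")
  both <- tube_select_length(new_tube("T"), 0L, 4L)
  expect_identical(tube_size(both$selected) + tube_size(both$rest), 0L)
})

test_that("cutting splits at the first boundary pair and conserves symbols", {
  s <- c(rep("psi", 7), encode_route(c(1, 3, 4, 5, 1)), rep("Y", 4))
  t <- new_tube("T", list(s, encode_route(c(1, 2, 1))))
  before <- sum(t$nsym)
  out <- tube_cut(t, c("psi", "#"))
  expect_identical(sum(out$nsym), before)
  rep <- tube_read(out)
  expect_setequal(rep$symbols, c(
    paste(rep("psi", 7), collapse = " "),
    paste(c(encode_route(c(1, 3, 4, 5, 1)), rep("Y", 4)), collapse = " "),
    paste(encode_route(c(1, 2, 1)), collapse = " ")))
})

test_that("sorting pulls all co-minimal and co-maximal strands", {
  short1 <- encode_route(c(1, 2, 1))
  short2 <- encode_route(c(1, 3, 1))
  mid <- encode_route(c(1, 2, 3, 1))
  long <- encode_route(c(1, 2, 3, 4, 1))
  srt <- tube_sort_extremes(new_tube("T", list(short1, mid, long)))
  expect_identical(tube_read(srt$shortest)$route, "1-2-1")
  expect_identical(tube_read(srt$longest)$route, "1-2-3-4-1")
  expect_identical(tube_read(srt$rest)$route, "1-2-3-1")
  # ties: both co-minimal strands are kept
  srt2 <- tube_sort_extremes(new_tube("T", list(short1, short2, long)))
  expect_setequal(tube_read(srt2$shortest)$route, c("1-2-1", "1-3-1"))
  # a single shared length goes entirely to `shortest`
  srt3 <- tube_sort_extremes(new_tube("T", list(short1, short2)))
  expect_identical(tube_size(srt3$shortest), 2L)
  expect_identical(tube_size(srt3$longest), 0L)
  srt4 <- tube_sort_extremes(new_tube("T"))
  expect_identical(tube_size(srt4$shortest), 0L)
})

test_that("read is total: malformed strands are flagged, not thrown", {
  book <- table5_book()
  t <- new_tube("T", list(encode_route(c(1, 2, 5, 3, 1)),
                          c("A2", "B2", "A3")))
  rep <- tube_read(t, book)
  expect_identical(rep$route[1], "1-2-5-3-1")
  expect_true(rep$malformed[2])
  expect_identical(rep$length_nt[1], 4L * 12L)
  expect_identical(rep$sequence[1],
                   render_strand(encode_route(c(1, 2, 5, 3, 1)), book))
  expect_identical(nrow(tube_read(new_tube("T"))), 0L)
})

test_that("every operation increments exactly its own counter by one", {
  lg <- new_ledger()
  t <- new_tube("T", frag_set(3L))
  l <- new_tube("L", linker_set(3L), sense = "-")
  m <- tube_merge(t, l, lg)
  m <- tube_anneal(m, 10L, lg)
  m <- tube_denature(m, lg)
  sep <- tube_separate(m, c("#", "A1"), lg)
  m <- tube_append_tail(sep$matched, c("Y", "Y"), lg)
  m <- tube_append_head(m, "psi", lg)
  sel <- tube_select_length(m, 48L, 4L, lg)
  m <- tube_cut(tube_merge(sel$selected, sel$rest, lg), c("psi", "#"), lg)
  srt <- tube_sort_extremes(m, lg)
  tube_read(srt$shortest, ledger = lg)
  tube_discard(srt$rest, lg)
  tal <- ledger_tally(lg)
  want <- c(merge = 2L, anneal = 1L, denature = 1L, separate = 1L,
            append_tail = 1L, append_head = 1L, selection = 1L, cutting = 1L,
            sort = 1L, read = 1L, discard = 1L)
  got <- stats::setNames(tal$count, tal$op)
  expect_mapequal(as.list(got), as.list(want))
})

test_that("operations are pure: rerunning on equal inputs gives equal tubes", {
  t <- tube_merge(new_tube("T1", frag_set(4L)),
                  new_tube("T2", linker_set(4L), sense = "-"))
  a <- tube_denature(tube_anneal(t, 12L))
  b <- tube_denature(tube_anneal(t, 12L))
  expect_identical(sort(a$key), sort(b$key))
})
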
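# The virtual test tube and the eleven Adleman-Lipton operations.
#
# A tube holds a finite set of strand species: duplicates collapse (the
# algorithm only ever asks existence and length questions, never abundance).
# Each species has a sense: "+" for plain coding strands, "-" for
# complement-sense linker strands (the two-symbol bridges "Bi Aj" that embody
# edge (i, j) during annealing).
#
# Every operation optionally takes a ledger and increments exactly one
# counter by exactly 1 per invocation; the ledger also carries an optional
# machine-parsable trace (one line per operation).

new_tube_raw <- function(name, key = character(), sense = character(),
                         nsym = integer()) {
  keep <- if (length(unique(sense)) <= 1L) !duplicated(key)
          else !duplicated(paste0(sense, key))
  structure(list(name = name, key = key[keep], sense = sense[keep],
                 nsym = as.integer(nsym[keep])),
            class = "qtsp_tube")
}

#' Create a test tube
#'
#' @param name Tube label (`"T1"`, `"T2"`, ...).
#' @param strands List of strands, each a character vector of symbols.
#' @param sense Character vector (recycled): `"+"` for plain strands, `"-"`
#'   for complement-sense linkers.
#' @return A `qtsp_tube`: a named finite set of strand species.
#' @examples
#' new_tube("T1", list(c("#", "A1", "B1"), c("A2", "B2")))
#' @export
new_tube <- function(name = "T", strands = list(), sense = "+") {
  key <- vapply(strands, .key, "")
  sense <- rep_len(sense, length(strands))
  new_tube_raw(name, key, sense, lengths(strands))
}

#' @export
print.qtsp_tube <- function(x, ...) {
  cat(sprintf("<qtsp_tube %s> %d species\n", x$name, length(x$key)))
  show <- utils::head(seq_along(x$key), 6L)
  for (i in show) {
    cat(sprintf("  [%s] %s\n", x$sense[i], paste(.syms(x$key[i]), collapse = " ")))
  }
  if (length(x$key) > 6L) cat(sprintf("  ... and %d more\n", length(x$key) - 6L))
  invisible(x)
}

#' Number of strand species in a tube
#' @param tube A `qtsp_tube`.
#' @return Integer count.
#' @export
tube_size <- function(tube) length(tube$key)

#' Strands of a tube as symbol lists
#' @param tube A `qtsp_tube`.
#' @return List of character vectors.
#' @export
tube_strands <- function(tube) lapply(tube$key, .syms)

# Ledger --------------------------------------------------------------------

#' Create an operation ledger
#'
#' Counts every biological operation, grouped by pipeline stage, for the
#' complexity accounting of [check_theorems()]. Counters only ever increase.
#' With `trace = TRUE` each operation also appends one tab-separated line
#' (stage, operation, tubes, argument, resulting species count).
#'
#' @param trace Record a per-operation trace log?
#' @return A `qtsp_ledger` (an environment).
#' @export
new_ledger <- function(trace = FALSE) {
  lg <- new.env(parent = emptyenv())
  lg$counts <- list()
  lg$stage <- "global"
  lg$trace <- isTRUE(trace)
  lg$log <- character()
  class(lg) <- "qtsp_ledger"
  lg
}

#' Set the pipeline stage a ledger attributes operations to
#' @param ledger A `qtsp_ledger`.
#' @param stage Stage label (e.g. `"alg1"`).
#' @return The ledger, invisibly.
#' @export
ledger_stage <- function(ledger, stage) {
  ledger$stage <- stage
  invisible(ledger)
}

bump <- function(ledger, op, tubes = "", arg = "", nspecies = NA_integer_) {
  if (is.null(ledger)) return(invisible(NULL))
  st <- ledger$stage
  if (is.null(ledger$counts[[st]])) ledger$counts[[st]] <- integer()
  ledger$counts[[st]][[op]] <- (if (is.na(ledger$counts[[st]][op])) 0L
                                else ledger$counts[[st]][[op]]) + 1L
  if (ledger$trace) {
    ledger$log <- c(ledger$log,
                    sprintf("%s\t%s\t%s\t%s\t%d", st, op, tubes, arg, nspecies))
  }
  invisible(NULL)
}

#' Tally a ledger
#' @param ledger A `qtsp_ledger`.
#' @return A tibble with columns `stage`, `op`, `count`.
#' @export
ledger_tally <- function(ledger) {
  rows <- lapply(names(ledger$counts), function(st) {
    cnt <- ledger$counts[[st]]
    tibble::tibble(stage = st, op = names(cnt), count = unname(cnt))
  })
  do.call(rbind, c(rows, list(tibble::tibble(stage = character(),
                                             op = character(),
                                             count = integer()))))
}

#' Trace log of a ledger
#' @param ledger A `qtsp_ledger` created with `trace = TRUE`.
#' @return Character vector, one tab-separated line per operation.
#' @export
ledger_trace <- function(ledger) ledger$log

# The eleven operations ------------------------------------------------------

#' Merge: pour one tube into another
#'
#' The union of the two tubes' species, under set semantics. The second tube
#' is conceptually empty afterwards (drop the value you passed in).
#'
#' @param t1,t2 Tubes.
#' @param ledger Optional `qtsp_ledger`.
#' @return The merged tube (named after `t1`).
#' @export
tube_merge <- function(t1, t2, ledger = NULL) {
  out <- new_tube_raw(t1$name, c(t1$key, t2$key), c(t1$sense, t2$sense),
                      c(t1$nsym, t2$nsym))
  bump(ledger, "merge", paste(t1$name, t2$name), "", tube_size(out))
  out
}

#' Annealing/ligation: generate all complete double-stranded products
#'
#' Models exhaustive, deterministic hybridisation: plain-sense fragments chain
#' head-to-tail wherever the junction `... Bi | Aj ...` is bridged by a
#' present complement-sense linker `Bi Aj`, and a chain counts as a complete
#' product only when both of its ends carry the `#` terminator (the cap
#' fragments). All complete products of at most `cap_symbols` symbols are
#' produced; linker species remain (as duplex scaffolding) until
#' [tube_denature()] drops them. If the tube holds no linkers, the fragments
#' pass through unchanged (subject to the cap).
#'
#' The cap exists because closed walks are unbounded; the pipeline's length
#' filter discards anything longer than `(2n+4)t` anyway, so a cap of `2n+4`
#' symbols provably does not change the final output.
#'
#' @param tube A tube of plain-sense fragments and complement-sense linkers.
#' @param cap_symbols Maximum product length in symbols.
#' @param ledger Optional ledger.
#' @return The tube after annealing.
#' @export
tube_anneal <- function(tube, cap_symbols, ledger = NULL) {
  cap_symbols <- as.integer(cap_symbols)
  is_linker <- tube$sense == "-"
  frag_key <- tube$key[!is_linker]
  frag_nsym <- tube$nsym[!is_linker]
  if (!any(is_linker)) {
    keep <- frag_nsym <= cap_symbols
    out <- new_tube_raw(tube$name, frag_key[keep], rep("+", sum(keep)),
                        frag_nsym[keep])
    bump(ledger, "anneal", tube$name, sprintf("cap=%d", cap_symbols),
         tube_size(out))
    return(out)
  }
  # linker (first, second) symbol pairs
  lsyms <- lapply(tube$key[is_linker], .syms)
  lsyms <- lsyms[lengths(lsyms) == 2L]
  link_from <- vapply(lsyms, `[[`, "", 1L)
  link_to <- vapply(lsyms, `[[`, "", 2L)

  fsyms <- lapply(frag_key, .syms)
  f_first <- vapply(fsyms, `[[`, "", 1L)
  f_last <- vapply(fsyms, function(s) s[[length(s)]], "")
  left_capped <- f_first == "#"
  right_capped <- f_last == "#"

  # Breadth-first extension of chains. A chain is a sequence of fragment ids;
  # chains of the same level form an integer matrix (one column per position)
  # so the whole frontier advances with integer operations, and keys are only
  # materialised at the end, one vectorised paste per chain length.
  nf <- length(fsyms)
  can_follow <- matrix(FALSE, nf, nf)  # can_follow[a, b]: fragment b may extend a
  for (a in seq_len(nf)) {
    for (b in seq_len(nf)) {
      can_follow[a, b] <- any(link_from == f_last[a] & link_to == f_first[b])
    }
  }
  start <- which(left_capped & frag_nsym <= cap_symbols)
  product_mats <- list()
  done <- right_capped[start]
  if (any(done)) product_mats[[1L]] <- matrix(start[done], ncol = 1L)
  cur <- matrix(start[!done], ncol = 1L)
  cur_nsym <- frag_nsym[start[!done]]
  while (nrow(cur) > 0L) {
    lastcol <- cur[, ncol(cur)]
    idx <- integer(); add <- integer()
    for (g in seq_len(nf)) {
      sel <- which(can_follow[lastcol, g] & cur_nsym + frag_nsym[g] <= cap_symbols)
      if (length(sel) == 0L) next
      if (right_capped[g]) {
        product_mats[[length(product_mats) + 1L]] <-
          cbind(cur[sel, , drop = FALSE], g, deparse.level = 0L)
      } else {
        idx <- c(idx, sel)
        add <- c(add, rep.int(g, length(sel)))
      }
    }
    cur <- cbind(cur[idx, , drop = FALSE], add, deparse.level = 0L)
    cur_nsym <- cur_nsym[idx] + frag_nsym[add]
  }
  products_key <- character(); products_nsym <- integer()
  for (m in product_mats) {
    cols <- lapply(seq_len(ncol(m)), function(cc) frag_key[m[, cc]])
    products_key <- c(products_key, do.call(paste0, cols))
    products_nsym <- c(products_nsym,
                       rowSums(matrix(frag_nsym[m], nrow = nrow(m))))
  }
  out <- new_tube_raw(tube$name,
                      c(products_key, tube$key[is_linker]),
                      c(rep("+", length(products_key)), tube$sense[is_linker]),
                      c(products_nsym, tube$nsym[is_linker]))
  bump(ledger, "anneal", tube$name, sprintf("cap=%d", cap_symbols), tube_size(out))
  out
}

#' Denaturation: separate duplexes into single strands
#'
#' In this symbolic simulator the ligated product is already recorded as a
#' single plain-sense strand, so denaturation reduces to dropping the
#' complement-sense linker species that served as scaffolding.
#'
#' @param tube A tube.
#' @param ledger Optional ledger.
#' @return The tube with only plain-sense strands.
#' @export
tube_denature <- function(tube, ledger = NULL) {
  keep <- tube$sense != "-"
  out <- new_tube_raw(tube$name, tube$key[keep], tube$sense[keep], tube$nsym[keep])
  bump(ledger, "denature", tube$name, "", tube_size(out))
  out
}

#' Separation: split a tube on a contiguous symbol pattern
#'
#' Strands whose symbol list contains `pattern` as a contiguous run move to
#' the `matched` tube; the rest stay. Matching is at symbol level, never on
#' rendered nucleotides.
#'
#' @param tube A tube.
#' @param pattern Non-empty character vector of symbols.
#' @param ledger Optional ledger.
#' @return `list(matched = , rest = )` of two tubes.
#' @export
tube_separate <- function(tube, pattern, ledger = NULL) {
  if (length(pattern) == 0L) {
    qtsp_error("separation pattern must be non-empty", "qtspdna_invalid_pattern")
  }
  pat <- .key(pattern)
  hit <- grepl(pat, tube$key, fixed = TRUE)
  matched <- new_tube_raw(paste0(tube$name, "+"), tube$key[hit],
                          tube$sense[hit], tube$nsym[hit])
  rest <- new_tube_raw(tube$name, tube$key[!hit], tube$sense[!hit],
                       tube$nsym[!hit])
  bump(ledger, "separate", tube$name, paste(pattern, collapse = " "),
       tube_size(matched))
  list(matched = matched, rest = rest)
}

#' Discard: empty a tube
#' @param tube A tube.
#' @param ledger Optional ledger.
#' @return The emptied tube.
#' @export
tube_discard <- function(tube, ledger = NULL) {
  bump(ledger, "discard", tube$name, "", 0L)
  new_tube_raw(tube$name)
}

append_impl <- function(tube, symbols, where, op, ledger) {
  if (length(symbols) == 0L) {
    qtsp_error("append symbols must be non-empty", "qtspdna_invalid_pattern")
  }
  piece <- .key(symbols)
  key <- if (length(tube$key) == 0L) character(0)
         else if (where == "head") paste0(piece, tube$key)
         else paste0(tube$key, piece)
  out <- new_tube_raw(tube$name, key, tube$sense, tube$nsym + length(symbols))
  bump(ledger, op, tube$name, paste(symbols, collapse = " "), tube_size(out))
  out
}

#' Append-head / append-tail: attach symbols to every strand
#'
#' @param tube A tube.
#' @param symbols Non-empty character vector of symbols to attach.
#' @param ledger Optional ledger.
#' @return The tube with every strand extended.
#' @export
tube_append_head <- function(tube, symbols, ledger = NULL) {
  append_impl(tube, symbols, "head", "append_head", ledger)
}

#' @rdname tube_append_head
#' @export
tube_append_tail <- function(tube, symbols, ledger = NULL) {
  append_impl(tube, symbols, "tail", "append_tail", ledger)
}

#' Selection (gel electrophoresis): move strands of an exact length
#'
#' Moves every strand whose rendered nucleotide length equals `L` to the
#' selected tube. `L` must be a multiple of the code-word length `t` (the
#' pipeline only ever asks for such lengths).
#'
#' @param tube A tube.
#' @param L Target length in nucleotides (>= 0).
#' @param t Code-word length of the governing codebook.
#' @param ledger Optional ledger.
#' @return `list(selected = , rest = )`.
#' @export
tube_select_length <- function(tube, L, t, ledger = NULL) {
  L <- as.integer(L); t <- as.integer(t)
  if (L < 0L || L %% t != 0L) {
    qtsp_error(sprintf("invalid length: L = %d is not a non-negative multiple of t = %d", L, t),
               "qtspdna_invalid_length")
  }
  hit <- tube$nsym * t == L
  selected <- new_tube_raw(paste0(tube$name, "+"), tube$key[hit],
                           tube$sense[hit], tube$nsym[hit])
  rest <- new_tube_raw(tube$name, tube$key[!hit], tube$sense[!hit],
                       tube$nsym[!hit])
  bump(ledger, "selection", tube$name, sprintf("L=%d", L), tube_size(selected))
  list(selected = selected, rest = rest)
}

#' Cutting: split strands at a two-symbol boundary
#'
#' Every strand containing the adjacent pair `(w1, w2)` is replaced by the
#' two fragments obtained by splitting at the first such occurrence
#' (`... w1 | w2 ...`); other strands are untouched. Total symbol count over
#' the tube is conserved.
#'
#' @param tube A tube.
#' @param boundary Character vector `c(w1, w2)` of two distinct symbols.
#' @param ledger Optional ledger.
#' @return The tube after cutting.
#' @export
tube_cut <- function(tube, boundary, ledger = NULL) {
  stopifnot(length(boundary) == 2L)
  pat <- .key(boundary)
  at <- regexpr(pat, tube$key, fixed = TRUE)  # split index: w1 ends at `at`
  hit <- at > 0L
  key <- tube$key; sense <- tube$sense; nsym <- tube$nsym
  if (any(hit)) {
    lkey <- substr(key[hit], 1L, at[hit])
    rkey <- substr(key[hit], at[hit] + 1L, nsym[hit])
    key <- c(key[!hit], lkey, rkey)
    sense <- c(sense[!hit], rep(tube$sense[hit], 2L))
    nsym <- c(nsym[!hit], at[hit], nsym[hit] - at[hit])
  }
  out <- new_tube_raw(tube$name, key, sense, nsym)
  bump(ledger, "cutting", tube$name, paste(boundary, collapse = " "),
       tube_size(out))
  out
}

#' Sort: pull out the shortest and the longest strands
#'
#' All strands tied for the minimum rendered length move to the `shortest`
#' tube and all tied for the maximum to the `longest` tube; the remainder
#' stays. If every strand shares one length, they all go to `shortest` and
#' `longest` is empty (ties are kept because the problem may have several
#' optimal tours).
#'
#' @param tube A tube.
#' @param ledger Optional ledger.
#' @return `list(rest = , shortest = , longest = )`.
#' @export
tube_sort_extremes <- function(tube, ledger = NULL) {
  if (tube_size(tube) == 0L) {
    bump(ledger, "sort", tube$name, "", 0L)
    return(list(rest = tube, shortest = new_tube_raw(paste0(tube$name, "_min")),
                longest = new_tube_raw(paste0(tube$name, "_max"))))
  }
  lo <- tube$nsym == min(tube$nsym)
  hi <- tube$nsym == max(tube$nsym) & !lo
  mid <- !lo & !hi
  mk <- function(suffix, sel) new_tube_raw(paste0(tube$name, suffix),
                                           tube$key[sel], tube$sense[sel],
                                           tube$nsym[sel])
  bump(ledger, "sort", tube$name, "", sum(lo))
  list(rest = mk("", mid), shortest = mk("_min", lo), longest = mk("_max", hi))
}

#' Read: report the composition of a tube
#'
#' A total function: malformed strands are reported with a flag, never an
#' exception.
#'
#' @param tube A tube.
#' @param codebook Optional `qtsp_codebook`; when supplied the rendering and
#'   nucleotide length are included.
#' @param ledger Optional ledger.
#' @return A tibble with columns `symbols` (space-separated), `sense`,
#'   `n_symbols`, `route` (`"1-2-5-3-1"` form, `NA` if malformed),
#'   `malformed`, and -- with a codebook -- `length_nt` and `sequence`.
#' @export
tube_read <- function(tube, codebook = NULL, ledger = NULL) {
  bump(ledger, "read", tube$name, "", tube_size(tube))
  syms <- lapply(tube$key, .syms)
  routes <- vapply(syms, function(s) {
    r <- tryCatch(decode_route(s), error = function(e) NULL)
    if (is.null(r)) NA_character_ else paste(r, collapse = "-")
  }, "")
  out <- tibble::tibble(
    symbols = vapply(syms, paste, "", collapse = " "),
    sense = tube$sense,
    n_symbols = tube$nsym,
    route = routes,
    malformed = is.na(routes)
  )
  if (!is.null(codebook)) {
    out$length_nt <- out$n_symbols * codebook$t
    out$sequence <- vapply(syms, render_strand, "", codebook = codebook)
  }
  out
}
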
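# Code words and codebooks: the symbol -> DNA-word table grounding every
# strand in nucleotides. A codebook for n vertices holds 2n + 4 words, one per
# symbol in {A_1..A_n, B_1..B_n, #, Y, X, psi}, all of the same length t
# ("t mer"). A_iB_i encodes vertex v_i; # terminates strands; Y pads unvisited
# vertices; psi repeats encode vertex quotas; X repeats encode edge distances.

#' Watson-Crick complement of a nucleotide sequence
#'
#' Position-wise base-pairing map A<->T, G<->C. No reversal is applied: all
#' strand matching in this simulator happens at symbol level, so the
#' complement only matters for rendering linker strands, which are written in
#' the same left-to-right order as the blocks they bridge.
#'
#' @param sequence Character vector of sequences over the alphabet A, C, G, T
#'   (empty strings allowed).
#' @return Character vector of the same length: the position-wise complements.
#' @examples
#' wc_complement("GATG")              # "CTAC"
#' wc_complement(wc_complement("GTTTGATG"))  # involution
#' @export
wc_complement <- function(sequence) {
  if (!is.character(sequence)) {
    qtsp_error("`sequence` must be a character vector", "qtspdna_invalid_alphabet")
  }
  bad <- grepl("[^ACGT]", sequence)
  if (any(bad)) {
    qtsp_error(
      sprintf("non-ACGT character in sequence(s): %s",
              paste(utils::head(sequence[bad], 3L), collapse = ", ")),
      "qtspdna_invalid_alphabet"
    )
  }
  chartr("ACGT", "TGCA", sequence)
}

#' Symbols required by a codebook for n vertices
#'
#' @param n Vertex count.
#' @return Character vector of the 2n + 4 symbol labels: `A1..An`, `B1..Bn`,
#'   `#`, `Y`, `X`, `psi`.
#' @export
codebook_symbols <- function(n) {
  c(paste0("A", seq_len(n)), paste0("B", seq_len(n)), "#", "Y", "X", "psi")
}

# The published example table: six vertices, 4-mer words (3'-5' as printed).
.table5_words <- c(
  A1 = "GTTT", A2 = "GTTA", A3 = "TACG", A4 = "GGAA", A5 = "TATT", A6 = "TCCC",
  B1 = "GATG", B2 = "AGTT", B3 = "ACTG", B4 = "GCGG", B5 = "CTAG", B6 = "GCCG",
  "#" = "GTAA", psi = "AGGC", X = "CGAG", Y = "TATA"
)

new_codebook <- function(n, t, words, source) {
  structure(list(n = as.integer(n), t = as.integer(t),
                 words = words, source = source),
            class = "qtsp_codebook")
}

# Invariant checks shared by every construction path. Complement collisions
# (one word equal to the position-wise complement of another) are a warning
# for explicit tables -- the published table is itself unvalidated random
# 4-mers -- but a rejection criterion during random generation.
validate_codebook_words <- function(words, n, t, complement_action = c("warn", "error", "none")) {
  complement_action <- match.arg(complement_action)
  req <- codebook_symbols(n)
  missing <- setdiff(req, names(words))
  if (length(missing) > 0L) {
    qtsp_error(sprintf("codebook-invalid: missing symbol(s) %s",
                       paste(missing, collapse = ", ")), "qtspdna_codebook_invalid")
  }
  words <- words[req]
  if (any(nchar(words) != t)) {
    qtsp_error(sprintf("codebook-invalid: word length != t = %d for %s", t,
                       paste(req[nchar(words) != t], collapse = ", ")),
               "qtspdna_codebook_invalid")
  }
  if (any(grepl("[^ACGT]", words))) {
    qtsp_error("codebook-invalid: non-ACGT character in code word",
               "qtspdna_codebook_invalid")
  }
  if (anyDuplicated(words)) {
    qtsp_error("codebook-invalid: duplicate sequences across symbols",
               "qtspdna_codebook_invalid")
  }
  collide <- words %in% wc_complement(words)
  if (any(collide) && complement_action != "none") {
    msg <- sprintf("code word(s) equal to the complement of another word: %s",
                   paste(req[collide], collapse = ", "))
    if (complement_action == "error") {
      qtsp_error(paste("codebook-invalid:", msg), "qtspdna_codebook_invalid")
    }
    warning(msg, call. = FALSE)
  }
  words
}

#' Build a codebook mapping symbols to DNA code words
#'
#' A codebook for `n` vertices assigns a distinct `t`-mer over \{A,C,G,T\} to
#' each of the 2n + 4 symbols `A1..An`, `B1..Bn`, `#`, `Y`, `X`, `psi`.
#'
#' Sources:
#' \describe{
#'   \item{`"random"`}{Seeded rejection sampling: words are drawn uniformly
#'     and redrawn until all are pairwise distinct and no word equals the
#'     position-wise complement of another. Reproducible given `(n, t, seed)`.}
#'   \item{`"table5"`}{The published six-vertex example table (t = 4); valid
#'     for `n <= 6`, truncated to the first `n` vertex pairs.}
#'   \item{`"explicit"`}{A user-supplied named character vector `words`
#'     covering every required symbol. Complement collisions only warn.}
#' }
#'
#' @param n Vertex count (>= 2).
#' @param t Code-word length in nucleotides (default 4).
#' @param source One of `"random"`, `"table5"`, `"explicit"`.
#' @param words Named character vector of sequences (for `source = "explicit"`).
#' @param seed Integer seed for `source = "random"`; `NULL` uses the current
#'   RNG state.
#' @return An object of class `qtsp_codebook` with fields `n`, `t`, `words`.
#' @examples
#' book <- build_codebook(6, source = "table5")
#' book$words[["A1"]]  # "GTTT"
#' @export
build_codebook <- function(n, t = 4L, source = c("random", "table5", "explicit"),
                           words = NULL, seed = NULL) {
  source <- match.arg(source)
  n <- as.integer(n); t <- as.integer(t)
  if (n < 2L) qtsp_error("n must be >= 2", "qtspdna_codebook_invalid")
  if (t < 1L) qtsp_error("t must be >= 1", "qtspdna_codebook_invalid")
  k <- 2L * n + 4L
  if (source == "table5") {
    if (n > 6L || t != 4L) {
      qtsp_error("the built-in example table covers n <= 6 at t = 4",
                 "qtspdna_codebook_invalid")
    }
    w <- validate_codebook_words(.table5_words[codebook_symbols(n)], n, t, "none")
    return(new_codebook(n, t, w, "table5"))
  }
  if (source == "explicit") {
    if (is.null(words)) qtsp_error("explicit source requires `words`",
                                   "qtspdna_codebook_invalid")
    w <- validate_codebook_words(words, n, t, "warn")
    return(new_codebook(n, t, w, "explicit"))
  }
  # random: capacity check first. Complements pair up the 4^t t-mers (a word
  # never equals its own position-wise complement), so at most 4^t / 2 words
  # can avoid both duplication and complement collision.
  if (k > 4^t / 2) {
    qtsp_error(sprintf(
      "codebook-invalid: %d distinct, complement-free %d-mers requested but only %d are available",
      k, t, as.integer(4^t / 2)), "qtspdna_codebook_invalid")
  }
  draw <- function() {
    chosen <- character(0)
    blocked <- character(0)
    while (length(chosen) < k) {
      w <- paste(sample(c("A", "C", "G", "T"), t, replace = TRUE), collapse = "")
      if (w %in% blocked) next
      chosen <- c(chosen, w)
      blocked <- c(blocked, w, wc_complement(w))
    }
    stats::setNames(chosen, codebook_symbols(n))
  }
  w <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  w <- validate_codebook_words(w, n, t, "error")
  new_codebook(n, t, w, "random")
}

#' @export
print.qtsp_codebook <- function(x, ...) {
  cat(sprintf("<qtsp_codebook> n = %d, t = %d mer, source = %s\n",
              x$n, x$t, x$source))
  cat(sprintf("  %d code words, e.g. A1 = %s, # = %s\n",
              length(x$words), x$words[["A1"]], x$words[["#"]]))
  invisible(x)
}

#' Write / read a codebook
#'
#' Two on-disk forms: a two-column tab-separated table `symbol<TAB>sequence`
#' (the dialect of the published table) and a JSON form carrying `n`, `t` and
#' the word table. Round-trips are bit-exact.
#'
#' @param book A `qtsp_codebook`.
#' @param path Output file; format inferred from the extension (`.json` means
#'   JSON, anything else the tab-separated dialect) unless `format` is given.
#' @param format `"auto"`, `"tsv"` or `"json"`.
#' @return `write_codebook` returns `path` invisibly; `read_codebook` returns
#'   a `qtsp_codebook`.
#' @export
write_codebook <- function(book, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.json$", path)) "json" else "tsv"
  if (format == "json") {
    jsonlite::write_json(
      list(format = "qtsp_codebook", n = book$n, t = book$t,
           words = as.list(book$words)),
      path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    writeLines(paste(names(book$words), book$words, sep = "\t"), path)
  }
  invisible(path)
}

#' @param n,t Dimensions for the tab-separated form (which carries only the
#'   word table); inferred from the content when `NULL`.
#' @rdname write_codebook
#' @export
read_codebook <- function(path, format = c("auto", "tsv", "json"),
                          n = NULL, t = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.json$", path)) "json" else "tsv"
  if (format == "json") {
    x <- jsonlite::read_json(path)
    words <- vapply(x$words, as.character, "")
    return(build_codebook(as.integer(x$n), as.integer(x$t),
                          source = "explicit", words = words))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    qtsp_error("codebook file: expected two tab-separated columns",
               "qtspdna_parse_error")
  }
  words <- vapply(parts, `[[`, "", 2L)
  names(words) <- vapply(parts, `[[`, "", 1L)
  if (is.null(n)) n <- (length(words) - 4L) %/% 2L
  if (is.null(t)) t <- nchar(words[[1L]])
  build_codebook(n, t, source = "explicit", words = words)
}
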
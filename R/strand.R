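# Strands are ordered lists of code-word symbols. All tube logic operates on
# symbol lists, never on rendered nucleotide strings: randomly drawn t-mers
# are not a comma-free code, so sequence-level substring matching across block
# boundaries would be unsound. Rendering is presentation/interop only.
#
# Internally a strand is stored as a compact key: one ASCII character per
# symbol, assigned on demand from a session-local registry. A contiguous
# symbol pattern is then exactly a fixed-substring match of its own key form,
# and a strand's symbol count is nchar(key) -- this keeps every tube
# operation vectorised over hundreds of thousands of species. Keys never
# leave the package: every public surface speaks symbol vectors.

.symreg <- new.env(parent = emptyenv())
.symreg$pool <- setdiff(strsplit(rawToChar(as.raw(33:126)), "")[[1L]],
                        c("\\", "\"", "'"))
.symreg$fwd <- character()  # symbol -> char
.symreg$rev <- character()  # char -> symbol

.sym_chars <- function(symbols) {
  out <- .symreg$fwd[symbols]
  new <- unique(symbols[is.na(out)])
  if (length(new) > 0L) {
    avail <- setdiff(.symreg$pool, unname(.symreg$fwd))
    if (length(new) > length(avail)) {
      qtsp_error("symbol registry exhausted (too many distinct code-word symbols)",
                 "qtspdna_size_error")
    }
    ch <- avail[seq_along(new)]
    .symreg$fwd[new] <- ch
    .symreg$rev[ch] <- new
    out <- .symreg$fwd[symbols]
  }
  unname(out)
}

.key <- function(symbols) paste(.sym_chars(symbols), collapse = "")

.syms <- function(key) unname(.symreg$rev[strsplit(key, "", fixed = TRUE)[[1L]]])

.vertex_of <- function(symbols) {
  # A7 -> 7 for A/B block symbols, NA for #, Y, X, psi
  ifelse(grepl("^[AB][0-9]+$", symbols),
         as.integer(sub("^[AB]", "", symbols)), NA_integer_)
}

#' Encode a route as a strand symbol list
#'
#' A cycle `c(1, k1, ..., kr, 1)` from the origin becomes the symbol list
#' `#  A1 B1  Ak1 Bk1 ... Akr Bkr  A1 B1  #`: each visited vertex contributes
#' its two-part block, and `#` terminates both ends.
#'
#' @param route Integer vector starting and ending at 1.
#' @return Character vector of symbols.
#' @examples
#' encode_route(c(1, 2, 5, 3, 1))
#' @export
encode_route <- function(route) {
  route <- as.integer(route)
  if (length(route) < 2L || route[1L] != 1L || route[length(route)] != 1L) {
    qtsp_error("route must start and end at vertex 1", "qtspdna_malformed_strand")
  }
  blocks <- as.vector(rbind(paste0("A", route), paste0("B", route)))
  c("#", blocks, "#")
}

#' Decode a strand back to its route
#'
#' Ignores the auxiliary symbols `#`, `Y`, `X`, `psi` and reads the remaining
#' vertex blocks, which must form complete `Ai Bi` pairs with the first and
#' last pair equal to `A1 B1`. The inverse of [encode_route()].
#'
#' @param strand Character vector of symbols (a strand's symbol list).
#' @return Integer vector `c(1, k1, ..., kr, 1)`.
#' @examples
#' decode_route(encode_route(c(1, 4, 5, 1)))  # c(1, 4, 5, 1)
#' @export
decode_route <- function(strand) {
  keep <- grepl("^[AB][0-9]+$", strand)
  blocks <- strand[keep]
  if (length(blocks) < 4L || length(blocks) %% 2L != 0L) {
    qtsp_error("malformed strand: vertex blocks do not pair up",
               "qtspdna_malformed_strand")
  }
  a <- blocks[seq(1L, length(blocks), by = 2L)]
  b <- blocks[seq(2L, length(blocks), by = 2L)]
  ia <- .vertex_of(a); ib <- .vertex_of(b)
  if (any(!startsWith(a, "A")) || any(!startsWith(b, "B")) || any(ia != ib)) {
    qtsp_error("malformed strand: dangling half-block (Ai without matching Bi)",
               "qtspdna_malformed_strand")
  }
  if (ia[1L] != 1L || ia[length(ia)] != 1L) {
    qtsp_error("malformed strand: route does not start and end at vertex 1",
               "qtspdna_malformed_strand")
  }
  ia
}

#' Render a strand as nucleotides
#'
#' Concatenates the code words of the strand's symbols in order. With
#' `scope = "vertex-blocks-only"` the auxiliary symbols `#`, `Y`, `X`, `psi`
#' are dropped first -- the display convention used for route strands in the
#' published worked example.
#'
#' @param strand Character vector of symbols.
#' @param codebook A `qtsp_codebook` covering every symbol of the strand.
#' @param scope `"full"` or `"vertex-blocks-only"`.
#' @return A single nucleotide string.
#' @examples
#' book <- build_codebook(6, source = "table5")
#' render_strand(c("A1", "B1"), book)  # "GTTTGATG"
#' @export
render_strand <- function(strand, codebook,
                          scope = c("full", "vertex-blocks-only")) {
  scope <- match.arg(scope)
  if (scope == "vertex-blocks-only") {
    strand <- strand[!strand %in% c("#", "Y", "X", "psi")]
  }
  unknown <- setdiff(strand, names(codebook$words))
  if (length(unknown) > 0L) {
    qtsp_error(sprintf("codebook-mismatch: unknown symbol(s) %s",
                       paste(unknown, collapse = ", ")),
               "qtspdna_codebook_mismatch")
  }
  paste(codebook$words[strand], collapse = "")
}

#' Export route strands to FASTA
#'
#' Writes one FASTA record per strand: the id is the decoded route in the form
#' `"1-2-5-3-1"` (or `strand<k>` for strands that do not decode), the sequence
#' the full nucleotide rendering. Uses Biostrings for the file format.
#'
#' @param strands List of symbol vectors, or a `qtsp_tube`.
#' @param codebook A `qtsp_codebook`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_strand_fasta <- function(strands, codebook, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    qtsp_error("Biostrings is required for FASTA export", "qtspdna_io_error")
  }
  if (inherits(strands, "qtsp_tube")) {
    strands <- lapply(strands$key, .syms)
  }
  ids <- vapply(seq_along(strands), function(i) {
    r <- tryCatch(decode_route(strands[[i]]), error = function(e) NULL)
    if (is.null(r)) sprintf("strand%d", i) else paste(r, collapse = "-")
  }, "")
  seqs <- vapply(strands, render_strand, "", codebook = codebook)
  x <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
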
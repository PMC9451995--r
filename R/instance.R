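# QTSP and PCTSP instances, plain-text formats, the PCTSP -> QTSP conversion
# and the seeded random-instance generator. Vertex ids are 1-based throughout
# and the origin is fixed at vertex 1.

#' Construct a QTSP instance
#'
#' A QTSP instance is a complete undirected graph on `n` vertices with
#' symmetric positive integer distances `d[i, j]`, non-negative integer
#' per-vertex quotas `w`, and a positive integer quota threshold `Q`. The
#' salesman starts and ends at vertex 1 and must collect at least `Q` quota
#' from the vertices visited. Distances must be integers because edge weight
#' is encoded as a unit chain of `X` symbols; rescale non-integer data before
#' constructing (no silent rounding is done).
#'
#' Feasibility (`Q` at most the collectible quota) is not assumed here; the
#' solvers detect and report infeasible instances.
#'
#' @param distances Symmetric `n x n` matrix of positive integers (diagonal
#'   unused).
#' @param quotas Integer vector of length `n`, non-negative.
#' @param Q Non-negative integer quota threshold (0 makes the quota
#'   constraint vacuous).
#' @param name Optional instance name.
#' @return A `qtsp_instance`.
#' @export
qtsp_instance <- function(distances, quotas, Q, name = NULL) {
  distances <- as.matrix(distances)
  n <- nrow(distances)
  if (n < 2L || ncol(distances) != n) {
    qtsp_error("distances must be a square matrix with n >= 2", "qtspdna_invalid_instance")
  }
  off <- distances[row(distances) != col(distances)]
  if (any(off != round(off)) || any(quotas != round(quotas)) || Q != round(Q)) {
    qtsp_error("distances, quotas and Q must be integers (pre-scale non-integer data)",
               "qtspdna_invalid_instance")
  }
  if (!isTRUE(all.equal(distances, t(distances)))) {
    qtsp_error("distance matrix must be symmetric", "qtspdna_invalid_instance")
  }
  if (any(off <= 0)) {
    qtsp_error("off-diagonal distances must be positive (complete graph)",
               "qtspdna_invalid_instance")
  }
  if (length(quotas) != n || any(quotas < 0)) {
    qtsp_error("quotas must be length n and non-negative", "qtspdna_invalid_instance")
  }
  if (Q < 0) {
    qtsp_error("Q must be a non-negative integer (0 makes the quota vacuous)",
               "qtspdna_invalid_instance")
  }
  storage.mode(distances) <- "integer"
  diag(distances) <- 0L
  structure(list(n = as.integer(n), distances = distances,
                 quotas = as.integer(quotas), Q = as.integer(Q),
                 name = name),
            class = "qtsp_instance")
}

#' @export
print.qtsp_instance <- function(x, ...) {
  cat(sprintf("<qtsp_instance%s> n = %d, Q = %d, quotas = (%s)\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$n, x$Q, paste(x$quotas, collapse = ", ")))
  invisible(x)
}

#' Total quota collectible away from the origin
#' @param inst A `qtsp_instance`.
#' @return Integer: sum of quotas over vertices 2..n (the origin's quota is
#'   never collected; the tour starts there).
#' @export
collectible_quota <- function(inst) sum(inst$quotas[-1L])

#' Cost and quota of a route
#'
#' @param inst A `qtsp_instance`.
#' @param route Integer cycle `c(1, ..., 1)`.
#' @return `route_cost`: total distance; `route_quota`: quota collected over
#'   the distinct non-origin vertices visited.
#' @export
route_cost <- function(inst, route) {
  sum(inst$distances[cbind(route[-length(route)], route[-1L])])
}

#' @rdname route_cost
#' @export
route_quota <- function(inst, route) {
  sum(inst$quotas[setdiff(unique(route), 1L)])
}

#' Construct a PCTSP instance
#'
#' Prize-Collecting TSP data: per-vertex prizes and penalties plus a distance
#' matrix. Only the pieces needed for conversion to QTSP are modelled. The
#' text dialect read and written here (see [read_pctsp()]) is this package's
#' own documented format; the converter is independent of any dialect.
#'
#' @param distances Symmetric matrix.
#' @param prizes Non-negative numeric vector of length n.
#' @param penalties Numeric vector of length n (ignored by the conversion).
#' @param name Optional name.
#' @return A `pctsp_instance`.
#' @export
pctsp_instance <- function(distances, prizes, penalties = rep(0, length(prizes)),
                           name = NULL) {
  distances <- as.matrix(distances)
  n <- nrow(distances)
  if (ncol(distances) != n || !isTRUE(all.equal(distances, t(distances)))) {
    qtsp_error("PCTSP distances must be square and symmetric", "qtspdna_invalid_instance")
  }
  if (length(prizes) != n || any(prizes < 0)) {
    qtsp_error("prizes must be length n and non-negative", "qtspdna_invalid_instance")
  }
  structure(list(n = n, distances = distances, prizes = as.numeric(prizes),
                 penalties = as.numeric(penalties), name = name),
            class = "pctsp_instance")
}

#' Convert a PCTSP instance to a QTSP instance
#'
#' The conversion drops the penalty mechanism entirely (penalties are treated
#' as zero), takes the prizes as vertex quotas, keeps the distances, and sets
#' the quota threshold to `Q = ceiling(sigma * sum(prizes))` for a fraction
#' `sigma`. The ceiling guarantees the collected quota genuinely meets the
#' `sigma` fraction (the rounding rule is this package's choice).
#'
#' @param pctsp A `pctsp_instance`.
#' @param sigma Fraction in (0, 1]; the conventional values are 0.2, 0.5, 0.8.
#' @return A `qtsp_instance`.
#' @export
convert_pctsp <- function(pctsp, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0 || sigma > 1) {
    qtsp_error("sigma must be a single fraction in (0, 1]", "qtspdna_invalid_parameter")
  }
  Q <- as.integer(ceiling(sigma * sum(pctsp$prizes)))
  nm <- if (is.null(pctsp$name)) NULL else name_instance(pctsp$name, sigma)
  qtsp_instance(pctsp$distances, pctsp$prizes, Q, name = nm)
}

#' Name a converted QTSP instance
#'
#' Splices the decimal digit of `sigma` onto the PCTSP base name:
#' `("problem_20_100_100_1000", 0.2)` becomes
#' `"problem_20_100_100_1000_2.qtsp"`. A `.pctsp` extension on the base name
#' is stripped first.
#'
#' @param base_name PCTSP instance name.
#' @param sigma Fraction with a single decimal digit (0.2, 0.5, 0.8, ...).
#' @return The QTSP instance file name.
#' @export
name_instance <- function(base_name, sigma) {
  d <- sigma * 10
  if (abs(d - round(d)) > 1e-9) {
    qtsp_error("sigma must have a single decimal digit", "qtspdna_invalid_parameter")
  }
  base <- sub("\\.pctsp$", "", base_name)
  sprintf("%s_%d.qtsp", base, as.integer(round(d)))
}

#' Generate a seeded random QTSP instance
#'
#' Draws symmetric integer distances uniformly from `distance_range` and
#' vertex quotas uniformly from `weight_range` for vertices 2..n; the origin
#' quota is 0 (the depot carries no prize, as in rooted prize-collecting
#' instances), so `Q = ceiling(sigma * sum(w))` is always collectible for
#' `sigma <= 1`. Reproducible given the seed.
#'
#' @param n Vertex count (>= 2).
#' @param weight_range,distance_range Integer `c(lo, hi)` with `0 < lo <= hi`
#'   (`weight_range` may start at 0).
#' @param sigma Fraction in (0, 1] determining Q.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `qtsp_instance`.
#' @export
gen_random_instance <- function(n, weight_range = c(1L, 9L),
                                distance_range = c(1L, 9L),
                                sigma = 0.5, seed = NULL) {
  n <- as.integer(n)
  if (n < 2L) qtsp_error("n must be >= 2", "qtspdna_invalid_parameter")
  if (length(weight_range) != 2L || length(distance_range) != 2L ||
      weight_range[1L] > weight_range[2L] || weight_range[1L] < 0L ||
      distance_range[1L] > distance_range[2L] || distance_range[1L] < 1L) {
    qtsp_error("degenerate weight/distance range", "qtspdna_invalid_parameter")
  }
  if (sigma <= 0 || sigma > 1) {
    qtsp_error("sigma must be in (0, 1]", "qtspdna_invalid_parameter")
  }
  draw <- function() {
    d <- matrix(0L, n, n)
    up <- upper.tri(d)
    d[up] <- sample(seq.int(distance_range[1L], distance_range[2L]),
                    sum(up), replace = TRUE)
    d <- d + t(d)
    w <- c(0L, sample(seq.int(weight_range[1L], weight_range[2L]),
                      n - 1L, replace = TRUE))
    list(d = d, w = w)
  }
  x <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  qtsp_instance(x$d, x$w, max(1L, as.integer(ceiling(sigma * sum(x$w)))),
                name = sprintf("random_n%d_seed%s", n,
                               if (is.null(seed)) "NA" else seed))
}

#' A six-city fixture consistent with the published worked example
#'
#' The worked example's full data is never printed; only fragments are: the
#' quota threshold Q = 7, the quotas w3 = 3, w4 = 2, w5 = 2, the optimal route
#' v1 -> v2 -> v5 -> v3 -> v1 with quota sum 9, and the infeasibility of
#' v1 -> v4 -> v5 -> v1 (2 + 2 < 7). This synthetic fixture pins all of those
#' and fills the remaining weights (w2 = 4, w6 = 1) and the distance matrix
#' with documented choices under which the pinned optimum is unique up to
#' direction (verified by the exact oracle in the test suite).
#'
#' @return A `qtsp_instance` named `"fig2_like_synthetic"`.
#' @export
fig2_like_fixture <- function() {
  d <- matrix(6L, 6L, 6L)
  d[1, 2] <- d[2, 1] <- 1L
  d[1, 3] <- d[3, 1] <- 3L
  d[1, 5] <- d[5, 1] <- 8L
  d[2, 3] <- d[3, 2] <- 9L
  d[2, 5] <- d[5, 2] <- 2L
  d[3, 5] <- d[5, 3] <- 2L
  diag(d) <- 0L
  qtsp_instance(d, quotas = c(0L, 4L, 3L, 2L, 2L, 1L), Q = 7L,
                name = "fig2_like_synthetic")
}

# File formats ---------------------------------------------------------------

#' Read and write QTSP instances (JSON `.qtsp` schema)
#'
#' The schema (version 1) is a JSON object with fields `format` (`"qtsp"`),
#' `version`, `n`, `origin` (always 1; vertex ids are 1-based), `quotas`
#' (length n), `Q`, and `distances` (n rows of n integers). `read_qtsp` and
#' `write_qtsp` are exact inverses.
#'
#' @param inst A `qtsp_instance`.
#' @param path File path.
#' @return `write_qtsp`: `path` invisibly; `read_qtsp`: a `qtsp_instance`.
#' @export
write_qtsp <- function(inst, path) {
  jsonlite::write_json(
    list(format = "qtsp", version = 1L, name = inst$name, n = inst$n,
         origin = 1L, quotas = inst$quotas, Q = inst$Q,
         distances = inst$distances),
    path, auto_unbox = TRUE, pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_qtsp
#' @export
read_qtsp <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) {
                  qtsp_error(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
                             "qtspdna_parse_error")
                })
  for (f in c("n", "quotas", "Q", "distances")) {
    if (is.null(x[[f]])) {
      qtsp_error(sprintf("%s: missing required field '%s'", path, f),
                 "qtspdna_parse_error")
    }
  }
  qtsp_instance(x$distances, x$quotas, x$Q,
                name = if (is.null(x$name)) NULL else x$name)
}

#' Read and write PCTSP instances (plain-text dialect)
#'
#' This package's own documented dialect: `#` comment lines; a line `n <int>`;
#' `prizes <n ints>`; `penalties <n ints>`; a line `matrix` followed by n rows
#' of n integers. The converter ([convert_pctsp()]) is independent of this
#' dialect.
#'
#' @param pctsp A `pctsp_instance`.
#' @param path File path.
#' @return `write_pctsp`: `path` invisibly; `read_pctsp`: a `pctsp_instance`.
#' @export
write_pctsp <- function(pctsp, path) {
  rows <- apply(pctsp$distances, 1L, paste, collapse = " ")
  writeLines(c(sprintf("n %d", pctsp$n),
               paste("prizes", paste(pctsp$prizes, collapse = " ")),
               paste("penalties", paste(pctsp$penalties, collapse = " ")),
               "matrix", rows), path)
  invisible(path)
}

#' @rdname write_pctsp
#' @export
read_pctsp <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  field <- function(tag) {
    i <- which(startsWith(lines, paste0(tag, " ")) | lines == tag)
    if (length(i) != 1L) {
      qtsp_error(sprintf("%s: expected exactly one '%s' line", path, tag),
                 "qtspdna_parse_error")
    }
    i
  }
  n <- as.integer(sub("^n ", "", lines[field("n")]))
  num <- function(tag) {
    v <- as.numeric(strsplit(sub(paste0("^", tag, " "), "", lines[field(tag)]),
                             "\\s+")[[1L]])
    if (length(v) != n || anyNA(v)) {
      qtsp_error(sprintf("%s: '%s' must list %d numbers", path, tag, n),
                 "qtspdna_parse_error")
    }
    v
  }
  prizes <- num("prizes")
  penalties <- num("penalties")
  im <- field("matrix")
  if (length(lines) < im + n) {
    qtsp_error(sprintf("%s: matrix must have %d rows", path, n), "qtspdna_parse_error")
  }
  m <- t(vapply(lines[(im + 1L):(im + n)], function(l) {
    as.numeric(strsplit(l, "\\s+")[[1L]])
  }, numeric(n), USE.NAMES = FALSE))
  base <- sub("\\.pctsp$", "", basename(path))
  pctsp_instance(m, prizes, penalties, name = base)
}
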
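# broom-style accessors and plotting for solutions.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a QTSP solution
#'
#' One row per co-minimal optimal route.
#'
#' @param x A `qtsp_solution`.
#' @param ... Unused.
#' @return A tibble with columns `route`, `cost`, `quota_collected`,
#'   `n_vertices_visited`, `strand` (symbol list, or `NA` for the exact
#'   engine).
#' @export
tidy.qtsp_solution <- function(x, ...) {
  tibble::tibble(
    route = vapply(x$routes, paste, "", collapse = "-"),
    cost = x$cost,
    quota_collected = x$quota_collected,
    n_vertices_visited = vapply(x$routes, function(r) length(r) - 2L, 0L),
    strand = if (is.null(x$strands)) NA_character_ else x$strands
  )
}

#' Glance at a QTSP solution
#'
#' @param x A `qtsp_solution`.
#' @param ... Unused.
#' @return A one-row tibble: `engine`, `n`, `Q`, `cost`, `n_routes`,
#'   `total_ops` (`NA` for the exact engine).
#' @export
glance.qtsp_solution <- function(x, ...) {
  tibble::tibble(
    engine = x$engine,
    n = x$instance$n,
    Q = x$instance$Q,
    cost = x$cost,
    n_routes = length(x$routes),
    total_ops = if (is.null(x$ledger)) NA_integer_
                else sum(ledger_tally(x$ledger)$count)
  )
}

#' Plot an optimal route
#'
#' Draws the instance's vertices on a circle (no coordinates exist beyond the
#' distance matrix) with the first optimal route's edges highlighted and the
#' vertex quotas as labels.
#'
#' @param object A `qtsp_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qtsp_solution <- function(object, ...) {
  inst <- object$instance
  n <- inst$n
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  pts <- tibble::tibble(v = seq_len(n), x = cos(ang), y = sin(ang),
                        label = sprintf("v%d (w=%d)", seq_len(n), inst$quotas))
  r <- object$routes[[1L]]
  segs <- tibble::tibble(
    x = pts$x[r[-length(r)]], y = pts$y[r[-length(r)]],
    xend = pts$x[r[-1L]], yend = pts$y[r[-1L]]
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(xend = .data$xend, yend = .data$yend),
                          colour = "steelblue", linewidth = 0.8) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -1, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("Optimal route %s  (cost %d, quota %d ≥ Q = %d)",
                                  paste(r, collapse = "-"), object$cost,
                                  object$quota_collected[[1L]], inst$Q))
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot

#' Plot the per-stage operation tally of a run
#'
#' @param sol A `qtsp_solution` from [solve_dna()].
#' @return A ggplot bar chart of operation counts by stage.
#' @export
plot_ledger <- function(sol) {
  stopifnot(!is.null(sol$ledger))
  tal <- ledger_tally(sol$ledger)
  ggplot2::ggplot(tal, ggplot2::aes(x = .data$stage, y = .data$count,
                                    fill = .data$op)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "pipeline stage", y = "biological operations",
                  fill = "operation") +
    ggplot2::theme_minimal()
}
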
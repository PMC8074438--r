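#' Saltelli design row count
#'
#' The cross-sampling scheme evaluates `N(D+2)` parameterizations for
#' first-order plus total-effect estimation (blocks A, B and the D
#' column-swapped hybrids A_B^(i)), or `N(2D+2)` when the mirrored hybrids
#' B_A^(i) needed by second-order indices are added.
#'
#' @param n base sample count N.
#' @param d number of factors D.
#' @param second_order include the B_A^(i) blocks?
#' @return Total number of design rows, as a double (counts at genome scale
#'   exceed integer range comfort).
#' @export
#' @examples
#' design_row_count(2^15, 693)  # 22773760
design_row_count <- function(n, d, second_order = FALSE) {
  n <- assert_scalar_count(n, "n")
  d <- assert_scalar_count(d, "d")
  as.numeric(n) * (if (second_order) 2 * d + 2 else d + 2)
}

#' Map unit-hypercube points to factor bounds
#'
#' Columnwise affine map `low + u * (high - low)`. With the default
#' perturbation interval `[-10, 0]` mM/h this turns quasi-random unit
#' coordinates into intake lower bounds.
#'
#' @param unit_points numeric matrix with entries in `[0, 1]`.
#' @param bounds 2-column matrix (or 2-vector recycled to all columns):
#'   column 1 = low, column 2 = high.
#' @return Matrix of the same shape as `unit_points`.
#' @export
#' @examples
#' scale_to_bounds(matrix(c(0, 0.5, 1)), c(-10, 0))
scale_to_bounds <- function(unit_points, bounds) {
  unit_points <- as.matrix(unit_points)
  bounds <- normalize_bounds(bounds, ncol(unit_points))
  if (any(unit_points < 0 | unit_points > 1)) {
    abort("Unit points must lie in [0, 1].",
          class = "fluxsens_argument_error")
  }
  low <- bounds[, 1]
  high <- bounds[, 2]
  sweep(sweep(unit_points, 2, high - low, `*`), 2, low, `+`)
}

normalize_bounds <- function(bounds, d) {
  if (is.null(dim(bounds))) {
    stopifnot(length(bounds) == 2)
    bounds <- matrix(rep(as.numeric(bounds), each = d), ncol = 2)
  }
  bounds <- as.matrix(bounds)
  stopifnot(ncol(bounds) == 2, nrow(bounds) == d)
  if (any(bounds[, 1] > bounds[, 2])) {
    abort("Factor bounds must satisfy low <= high.",
          class = "fluxsens_bounds_error")
  }
  bounds
}

#' Generate a Saltelli cross-sampling design
#'
#' Draws N points of a 2D-dimensional Sobol' sequence, splits them
#' column-wise into the independent blocks A (first D columns) and B (last
#' D columns), and forms the hybrid blocks A_B^(i) — A with column i
#' replaced by B's column i — which the Sobol index estimators difference
#' against A and B. Rows are laid out block-contiguously
#' (A, B, A_B^(1..D)[, B_A^(1..D)]) with a provenance label per row.
#'
#' @param n base sample count N. Powers of two preserve the balance
#'   properties of the underlying sequence; other values are accepted with
#'   a warning.
#' @param factor_names character vector of D factor identifiers.
#' @param bounds per-factor `(low, high)` pairs as for [scale_to_bounds()];
#'   default the common intake perturbation interval `c(-10, 0)` mM/h.
#' @param second_order also generate the B_A^(i) blocks (doubles the hybrid
#'   rows; enables second-order index estimation).
#' @param skip number of initial sequence points to drop (default 1: the
#'   all-zeros point would put every intake at its most negative bound in
#'   the first A row). Recorded in the design so runs are reproducible.
#' @return A `saltelli_design` object: fields `matrix` (R x D, on the
#'   factor scale), `unit_matrix`, `row_blocks`, `factor_names`, `bounds`,
#'   `n`, `d`, `second_order`, `skip`.
#' @export
#' @examples
#' des <- saltelli_design(8, c("EX_A", "EX_B"))
#' nrow(des$matrix)  # 8 * (2 + 2)
saltelli_design <- function(n, factor_names, bounds = c(-10, 0),
                            second_order = FALSE, skip = 1) {
  n <- assert_scalar_count(n, "n")
  factor_names <- as.character(factor_names)
  d <- length(factor_names)
  stopifnot(d >= 1)
  bounds <- normalize_bounds(bounds, d)
  if (bitwAnd(n, n - 1L) != 0L) {
    warn(sprintf(
      "n = %d is not a power of two; balance properties of the quasi-random design degrade.",
      n))
  }
  base <- sobol_sequence(n, 2L * d, skip = skip)
  A <- base[, seq_len(d), drop = FALSE]
  B <- base[, d + seq_len(d), drop = FALSE]

  blocks <- vector("list", 2L + d * (1L + second_order))
  labels <- character(length(blocks))
  blocks[[1]] <- A; labels[1] <- "A"
  blocks[[2]] <- B; labels[2] <- "B"
  for (i in seq_len(d)) {
    AB <- A
    AB[, i] <- B[, i]
    blocks[[2L + i]] <- AB
    labels[2L + i] <- paste0("AB", i)
  }
  if (second_order) {
    for (i in seq_len(d)) {
      BA <- B
      BA[, i] <- A[, i]
      blocks[[2L + d + i]] <- BA
      labels[2L + d + i] <- paste0("BA", i)
    }
  }
  unit <- do.call(rbind, blocks)
  structure(
    list(
      factor_names = factor_names,
      bounds = bounds,
      n = n,
      d = d,
      second_order = isTRUE(second_order),
      skip = skip,
      unit_matrix = unit,
      matrix = scale_to_bounds(unit, bounds),
      row_blocks = rep(labels, each = n)
    ),
    class = "saltelli_design")
}

#' @export
print.saltelli_design <- function(x, ...) {
  cat(sprintf(
    "<saltelli_design> N = %d, D = %d, %s: %d rows (blocks %s), skip = %d\n",
    x$n, x$d,
    if (x$second_order) "second order" else "first/total order",
    nrow(x$matrix),
    paste(unique(x$row_blocks), collapse = " "), x$skip))
  invisible(x)
}

#' @describeIn saltelli_design rows of the scaled design as a tibble with a
#'   `block` column, the exchange format for out-of-process evaluation.
#' @param x a `saltelli_design`.
#' @param ... unused.
#' @export
as_tibble.saltelli_design <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$matrix, col.names = x$factor_names))
  names(out) <- x$factor_names
  dplyr::mutate(out, block = x$row_blocks, .before = 1)
}

#' Write / read a design as a tab-separated table
#'
#' One row per parameterization, columns = factor names plus a leading
#' `block` label, with the design header (`n`, `skip`, bounds) carried in
#' `#`-prefixed comment lines so a design can be regenerated, resumed or
#' evaluated out of process.
#'
#' @param design a `saltelli_design`.
#' @param path output (input) file path.
#' @return `path` invisibly; `read_design()` returns a `saltelli_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "saltelli_design"))
  hdr <- c(
    sprintf("# n=%d d=%d second_order=%s skip=%d", design$n, design$d,
            design$second_order, design$skip),
    sprintf("# bounds %s %g %g", design$factor_names,
            design$bounds[, 1], design$bounds[, 2]))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    as_tibble(design), path, sep = "\t", quote = FALSE,
    row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  hdr <- grep("^#", readLines(path, n = 200), value = TRUE)
  meta <- regmatches(hdr[1], regexec(
    "n=(\\d+) d=(\\d+) second_order=(\\w+) skip=(\\d+)", hdr[1]))[[1]]
  if (length(meta) != 5) {
    abort("Design file lacks the expected header line.",
          class = "fluxsens_format_error")
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", check.names = FALSE)
  bound_lines <- do.call(rbind, strsplit(sub("^# bounds ", "",
                                             hdr[-1]), " "))
  bounds <- cbind(as.numeric(bound_lines[, 2]), as.numeric(bound_lines[, 3]))
  design <- saltelli_design(
    n = as.integer(meta[2]),
    factor_names = bound_lines[, 1],
    bounds = bounds,
    second_order = identical(meta[4], "TRUE"),
    skip = as.integer(meta[5]))
  # regenerated design must agree with the stored rows
  stored <- as.matrix(tab[, design$factor_names, drop = FALSE])
  if (max(abs(stored - design$matrix)) > 1e-8) {
    abort("Stored design rows disagree with regenerated design.",
          class = "fluxsens_format_error")
  }
  design
}
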
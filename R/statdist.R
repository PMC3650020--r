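# Integrated distributions of matrix elements and ingoing sums, and
# power-law exponent fits (mu, nu, and the PageRank decay exponent beta).

.element_view <- function(M) {
  if (inherits(M, "google_matrix") || inherits(M, "column_stochastic"))
    return(as.matrix(M))
  as.matrix(M)
}

#' Integrated distribution of matrix elements
#'
#' fraction(g) = #\{(j,i): M\[j,i\] > g\} / N^2, evaluated on a threshold
#' grid. The inequality is strict, making the curve right-continuous. The
#' default grid is 64 log-spaced points from the smallest positive element
#' to the largest element.
#'
#' @param M Matrix (or `column_stochastic` / `google_matrix` element view).
#' @param grid Strictly increasing positive thresholds; `NULL` for default.
#' @return Object of class `integrated_distribution`: `grid`, `fraction`,
#'   `n_total`.
#' @export
element_distribution <- function(M, grid = NULL) {
  v <- sort(as.vector(.element_view(M)))
  .integrated_distribution(v, grid)
}

#' Integrated distribution of ingoing element sums
#'
#' fraction(g) = #\{j: gtilde\[j\] > g\} / N for the vector of row sums
#' gtilde (see [ingoing_sums()]).
#'
#' @param gt Numeric vector of ingoing sums, or a matrix-like object from
#'   which they are computed.
#' @param grid As in [element_distribution()].
#' @return An `integrated_distribution`.
#' @export
ingoing_distribution <- function(gt, grid = NULL) {
  if (!is.numeric(gt)) gt <- ingoing_sums(gt)
  .integrated_distribution(sort(gt), grid)
}

.integrated_distribution <- function(v_sorted, grid) {
  if (is.null(grid)) {
    pos <- v_sorted[v_sorted > 0]
    if (!length(pos)) stop("no positive values to build a default grid")
    lo <- min(pos)
    hi <- max(v_sorted)
    if (hi <= lo) hi <- lo * 1.0001
    grid <- 10^seq(log10(lo), log10(hi), length.out = 64L)
  }
  if (!length(grid)) stop("empty threshold grid")
  if (any(grid <= 0) || any(diff(grid) <= 0))
    stop("grid must be strictly increasing and positive")
  frac <- (length(v_sorted) - findInterval(grid, v_sorted)) / length(v_sorted)
  structure(list(grid = grid, fraction = frac, n_total = length(v_sorted)),
            class = "integrated_distribution")
}

#' @export
print.integrated_distribution <- function(x, ...) {
  cat(sprintf("<integrated_distribution> %d thresholds over [%.3g, %.3g], %d values\n",
              length(x$grid), min(x$grid), max(x$grid), x$n_total))
  invisible(x)
}

#' Fit a power law to an integrated distribution
#'
#' Ordinary least squares of log10(fraction) on log10(g) over thresholds in
#' \[gmin, gmax\] with positive fraction. If the integrated curve decays as
#' g^-(exp-1), the differential element distribution decays as g^-exp, so
#' the reported `exponent` is 1 - slope (mu for element values, nu for
#' ingoing sums).
#'
#' @param dist An `integrated_distribution`.
#' @param gmin,gmax Fit range; the algebraic-decay window must be chosen by
#'   the user (default: the full positive-fraction range of the grid).
#' @return Object of class `power_law_fit`: `slope`, `exponent`,
#'   `amplitude`, `gmin`, `gmax`, `stderr`, `n_points`.
#' @export
fit_power_law <- function(dist, gmin = NULL, gmax = NULL) {
  stopifnot(inherits(dist, "integrated_distribution"))
  if (is.null(gmin)) gmin <- min(dist$grid)
  if (is.null(gmax)) gmax <- max(dist$grid)
  use <- dist$grid >= gmin & dist$grid <= gmax & dist$fraction > 0
  if (sum(use) < 3L)
    stop("fewer than 3 usable grid points in the fit range")
  lx <- log10(dist$grid[use])
  ly <- log10(dist$fraction[use])
  fit <- stats::lm(ly ~ lx)
  cf <- stats::coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients["lx", "Std. Error"]),
                 error = function(e) NA_real_)
  structure(list(
    slope = unname(cf[2L]),
    exponent = 1 - unname(cf[2L]),
    amplitude = 10^unname(cf[1L]),
    gmin = gmin, gmax = gmax,
    stderr = se, n_points = sum(use)
  ), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> slope %.4f (se %.2g) over [%.3g, %.3g] (%d points); differential exponent %.4f\n",
              x$slope, x$stderr, x$gmin, x$gmax, x$n_points, x$exponent))
  invisible(x)
}

#' PageRank decay exponent beta
#'
#' Least-squares slope of log10 P(K) vs log10 K over a rank range; the
#' decay P(K) ~ K^-beta gives `beta = -slope`.
#'
#' @param P A `rank_vector`, or a numeric vector of probabilities already
#'   sorted by rank (largest first).
#' @param k_range Integer vector `c(kmin, kmax)` within \[1, N\].
#' @return List with `beta`, `slope`, `stderr`, `k_range`.
#' @export
fit_pagerank_decay <- function(P, k_range = NULL) {
  if (inherits(P, "rank_vector")) P <- sort(P$P, decreasing = TRUE)
  N <- length(P)
  if (is.null(k_range)) k_range <- c(1L, N)
  if (k_range[1L] < 1L || k_range[2L] > N || k_range[1L] >= k_range[2L])
    stop("invalid rank range")
  ks <- k_range[1L]:k_range[2L]
  pk <- P[ks]
  if (any(pk <= 0)) stop("zero probabilities in the fit range")
  fit <- stats::lm(log10(pk) ~ log10(ks))
  cf <- stats::coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[2L, "Std. Error"]),
                 error = function(e) NA_real_)
  list(beta = -unname(cf[2L]), slope = unname(cf[2L]),
       stderr = se, k_range = k_range)
}

#' PageRank exponent predicted from the ingoing exponent
#'
#' For scale-free networks the PageRank decay exponent follows the ingoing
#' distribution exponent nu through beta = 1/(nu - 1) (the classic WWW case
#' nu ~ 2.1 gives beta ~ 0.9).
#'
#' @param nu Differential ingoing-sum exponent, must exceed 1.
#' @return beta = 1/(nu - 1).
#' @export
predicted_beta <- function(nu) {
  if (!is.numeric(nu) || any(nu <= 1)) stop("`nu` must exceed 1")
  1 / (nu - 1)
}
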
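#' Construct a spheroid-area grid
#'
#' End-point and day-zero spheroid areas over a drug-by-bacteria plate.
#' Rows are bacteria inoculum levels (high to low), columns are doses
#' (high to low with the zero-dose column last), matching the plate
#' layout of a 1.6-fold serial dilution across columns.
#'
#' @param area_end,area_t0 positive matrices of identical dimension
#'   (um^2); `NA` marks missing wells.
#' @param doses dose per column (uM), optional.
#' @param bacteria inoculum level per row, optional.
#' @return object of class `spheroid_grid`.
#' @export
spheroid_grid <- function(area_end, area_t0, doses = NULL, bacteria = NULL) {
  area_end <- as.matrix(area_end); area_t0 <- as.matrix(area_t0)
  gs_assert(all(dim(area_end) == dim(area_t0)), "grid dimensions differ")
  gs_assert(all(area_end > 0, na.rm = TRUE) &&
              all(area_t0 > 0, na.rm = TRUE), "areas must be positive")
  if (!is.null(doses))
    gs_assert(length(doses) == ncol(area_end), "one dose per column")
  if (!is.null(bacteria))
    gs_assert(length(bacteria) == nrow(area_end), "one level per row")
  structure(list(area_end = area_end, area_t0 = area_t0,
                 doses = doses, bacteria = bacteria, normalized = NULL),
            class = "spheroid_grid")
}

#' Two-step normalisation of spheroid areas
#'
#' Step 1 divides each well's end-point area by its day-zero area. Step 2
#' rescales over the plate: subtract the plate minimum and divide by the
#' second-largest value minus the minimum, so the minimum maps to 0, the
#' second-largest value to 1, and the largest value may exceed 1 (it is
#' not clipped).
#'
#' @param grid a `spheroid_grid`.
#' @return the grid with `normalized` filled in.
#' @export
normalize_spheroids <- function(grid) {
  gs_assert(inherits(grid, "spheroid_grid"), "`grid` must be a spheroid_grid")
  gs_assert(all(grid$area_t0 > 0, na.rm = TRUE), "day-zero areas must be > 0")
  v <- grid$area_end / grid$area_t0
  vals <- sort(v[is.finite(v)], decreasing = TRUE)
  gs_assert(length(unique(vals)) >= 3,
            "degenerate plate: fewer than 3 distinct values",
            "gemscreen_degenerate_plate_error")
  mn <- min(vals); secondmax <- vals[2]
  gs_assert(secondmax > mn,
            "degenerate plate: second-largest equals minimum",
            "gemscreen_degenerate_plate_error")
  grid$normalized <- (v - mn) / (secondmax - mn)
  grid
}

# 15 monomial exponents of the bivariate quartic, in fixed order
poly44_terms <- function() {
  ex <- expand.grid(m = 0:4, n = 0:4)
  ex <- ex[ex$m + ex$n <= 4, ]
  ex[order(ex$m + ex$n, ex$m), ]
}

poly44_design <- function(x, y) {
  ex <- poly44_terms()
  X <- mapply(function(m, n) x^m * y^n, ex$m, ex$n)
  if (!is.matrix(X)) X <- matrix(X, nrow = length(x))
  colnames(X) <- paste0("x", ex$m, "y", ex$n)
  X
}

#' Fit a bivariate quartic ("poly44") fitness surface
#'
#' Ordinary least squares over the 15 monomials \eqn{x^m y^n},
#' \eqn{m+n \le 4}, with the dose axis as x and the bacteria axis as y,
#' both mapped to [0, 1] dilution-index coordinates (column/row index
#' rescaled; serial dilutions are uniform in log concentration, so index
#' space is log-dose space, with the zero-dose column at index 0 of the
#' reversed axis).
#'
#' @param grid a normalised `spheroid_grid`, or a bare numeric matrix of
#'   normalised values.
#' @return object of class `surface_fit`: `coefficients` (15, named),
#'   `rss`, grid dimensions, and the index ranges used.
#' @export
fit_poly44 <- function(grid) {
  z <- if (inherits(grid, "spheroid_grid")) {
    gs_assert(!is.null(grid$normalized),
              "run normalize_spheroids() first")
    grid$normalized
  } else as.matrix(grid)
  nr <- nrow(z); nc <- ncol(z)
  # x: dose index 0..nc-1 rescaled, column nc (zero dose) at x = 0
  xg <- rev(seq(0, 1, length.out = nc))
  yg <- rev(seq(0, 1, length.out = nr))   # row 1 = highest bacteria -> y = 1
  pts <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  pts$x <- xg[pts$col]; pts$y <- yg[pts$row]
  pts$z <- z[cbind(pts$row, pts$col)]
  pts <- pts[is.finite(pts$z), ]
  gs_assert(nrow(pts) >= 15, "need >= 15 wells for the 15 coefficients")
  X <- poly44_design(pts$x, pts$y)
  qr_X <- qr(X)
  gs_assert(qr_X$rank == 15, "rank-deficient design (degenerate grid)",
            "gemscreen_fit_error")
  fit <- lm.fit(X, pts$z)
  structure(list(coefficients = stats::setNames(fit$coefficients,
                                                colnames(X)),
                 rss = sum(fit$residuals^2),
                 nrow = nr, ncol = nc, level = 0.5),
            class = "surface_fit")
}

#' Evaluate a fitted poly44 surface
#'
#' @param fit a `surface_fit`.
#' @param x,y coordinates in the fit's [0, 1] index space (vectors of
#'   equal length, or a grid when `outer = TRUE`).
#' @param outer if TRUE, evaluate on the outer product grid and return a
#'   length(x) by length(y) matrix.
#' @return fitted values.
#' @export
poly44_eval <- function(fit, x, y, outer = FALSE) {
  if (outer) {
    g <- expand.grid(x = x, y = y)
    return(matrix(poly44_eval(fit, g$x, g$y), nrow = length(x)))
  }
  drop(poly44_design(x, y) %*% fit$coefficients)
}

#' Extract the EC50 front of a fitted surface
#'
#' The level set where the fitted surface equals `level` (0.5: the
#' mid-response) is traced by marching-squares contouring on a dense
#' evaluation grid; in addition, the per-bacteria-row crossing dose is
#' located by sign-change bracketing and bisection along the dose axis at
#' each of the original grid's row coordinates (taking, where the surface
#' crosses several times, the crossing at the highest dose with the
#' surface decreasing through the level).
#'
#' @param fit a `surface_fit`.
#' @param level contour level (default 0.5).
#' @param n evaluation grid resolution per axis (default 500).
#' @return object of class `ec50_front`: `polylines` (list of data.frames
#'   x, y), `crossings` (data.frame row, y, x_cross; `NA` where the row
#'   never crosses), `level`. An empty front (no polyline, all crossings
#'   `NA`) is a valid result.
#' @export
extract_front <- function(fit, level = 0.5, n = 500) {
  gs_assert(inherits(fit, "surface_fit"), "`fit` must be a surface_fit")
  xs <- seq(0, 1, length.out = n)
  ys <- seq(0, 1, length.out = n)
  z <- poly44_eval(fit, xs, ys, outer = TRUE)
  cl <- grDevices::contourLines(xs, ys, z, levels = level)
  polylines <- lapply(cl, function(s) data.frame(x = s$x, y = s$y))

  yrows <- rev(seq(0, 1, length.out = fit$nrow))
  cross_one <- function(yr) {
    f <- function(x) poly44_eval(fit, x, rep(yr, length(x))) - level
    fx <- f(xs)
    sgn <- which(fx[-n] > 0 & fx[-1] <= 0)   # decreasing crossings
    if (!length(sgn)) sgn <- which(diff(sign(fx)) != 0)
    if (!length(sgn)) return(NA_real_)
    i <- max(sgn)
    stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-9)$root
  }
  crossings <- data.frame(row = seq_len(fit$nrow), y = yrows,
                          x_cross = vapply(yrows, cross_one, numeric(1)))
  structure(list(polylines = polylines, crossings = crossings,
                 level = level),
            class = "ec50_front")
}

#' @export
print.ec50_front <- function(x, ...) {
  cat("ec50_front at level", x$level, ":", length(x$polylines),
      "polyline(s),", sum(!is.na(x$crossings$x_cross)), "of",
      nrow(x$crossings), "rows crossing\n")
  invisible(x)
}

#' Compare two EC50 fronts row by row
#'
#' Signed shift of the crossing dose, `b - a`, per shared bacteria level,
#' in index (log-dose) units; positive shifts mean strain b tolerates
#' more drug at that bacteria level. Rows where either front is absent
#' are excluded. A sign test (exact binomial on the nonzero shift signs)
#' summarises the direction.
#'
#' @param a,b `ec50_front`s sharing the bacteria axis.
#' @return list with `shifts` (data.frame row, y, shift), `mean_shift`,
#'   `sign_test_p`.
#' @export
compare_fronts <- function(a, b) {
  gs_assert(inherits(a, "ec50_front") && inherits(b, "ec50_front"),
            "inputs must be ec50_fronts")
  gs_assert(nrow(a$crossings) == nrow(b$crossings) &&
              isTRUE(all.equal(a$crossings$y, b$crossings$y)),
            "fronts must share the bacteria axis",
            "gemscreen_comparison_error")
  ok <- !is.na(a$crossings$x_cross) & !is.na(b$crossings$x_cross)
  gs_assert(any(ok), "no bacteria level crossed by both fronts",
            "gemscreen_comparison_error")
  shifts <- data.frame(row = a$crossings$row[ok], y = a$crossings$y[ok],
                       shift = b$crossings$x_cross[ok] -
                         a$crossings$x_cross[ok])
  nz <- shifts$shift[abs(shifts$shift) > 1e-12]
  p <- if (!length(nz)) 1 else
    stats::binom.test(sum(nz > 0), length(nz))$p.value
  list(shifts = shifts, mean_shift = mean(shifts$shift), sign_test_p = p)
}
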
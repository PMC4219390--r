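#' Restricted cubic spline knot placement
#'
#' Places boundary knots at the minimum and maximum of the (optionally
#' log-transformed) values and `df - 1` interior knots at equally spaced
#' centiles, the Royston-Parmar convention. With `df = 1` there are no
#' interior knots and the basis reduces to a single linear column.
#'
#' @param values numeric vector the knots are derived from (e.g. measurement
#'   times, or event times for a survival baseline).
#' @param df positive integer; number of basis columns. Total knots = df + 1.
#' @param scale `"identity"` or `"log"`; knots are placed on the transformed
#'   axis and the basis is evaluated on that axis.
#' @return an object of class `"rcs_knots"`: list with `interior`, `boundary`,
#'   `df`, `scale`.
#' @examples
#' rcs_knots(1:100, df = 2)
#' @export
rcs_knots <- function(values, df, scale = c("identity", "log")) {
  scale <- match.arg(scale)
  if (length(values) == 0L) stop("'values' must be non-empty")
  if (!is.numeric(df) || length(df) != 1L || df < 1 || df != round(df))
    stop("'df' must be a positive integer")
  df <- as.integer(df)
  x <- if (scale == "log") {
    if (any(values <= 0)) stop("all values must be positive on the log scale")
    log(values)
  } else as.numeric(values)
  if (length(unique(x)) <= df)
    stop("knot degeneracy: 'df' (", df, ") must be smaller than the number of distinct values (",
         length(unique(x)), ")")
  bnd <- range(x)
  interior <- if (df > 1L) {
    p <- seq_len(df - 1L) / df
    # linear-interpolation empirical quantiles (type 7)
    as.numeric(stats::quantile(x, probs = p, type = 7, names = FALSE))
  } else numeric(0)
  new_rcs_knots(interior, bnd, scale)
}

new_rcs_knots <- function(interior, boundary, scale = "identity") {
  interior <- as.numeric(interior)
  boundary <- as.numeric(boundary)
  if (length(boundary) != 2L || boundary[1] >= boundary[2])
    stop("boundary knots must be two increasing values")
  if (length(interior) &&
      (any(diff(interior) <= 0) || any(interior <= boundary[1]) ||
       any(interior >= boundary[2])))
    stop("interior knots must be strictly increasing and strictly inside the boundary knots")
  structure(list(interior = interior, boundary = boundary,
                 df = length(interior) + 1L, scale = scale),
            class = "rcs_knots")
}

#' @export
print.rcs_knots <- function(x, ...) {
  cat("Restricted cubic spline knots (", x$scale, " scale), df = ", x$df, "\n",
      "  boundary: ", paste(signif(x$boundary, 6), collapse = ", "), "\n", sep = "")
  if (length(x$interior))
    cat("  interior: ", paste(signif(x$interior, 6), collapse = ", "), "\n", sep = "")
  invisible(x)
}

all_knots <- function(knots) c(knots$boundary[1], knots$interior, knots$boundary[2])

#' Restricted cubic spline basis
#'
#' Evaluates the restricted (natural) cubic basis: column 1 is `x` itself,
#' columns `2..df` are truncated-cubic terms constrained so any linear
#' combination is linear beyond both boundary knots. The basis is unscaled
#' (raw), so coefficient values depend on this parameterisation.
#'
#' @param x numeric vector, already on the knots' scale (pass `log(t)` for
#'   knots placed on log time).
#' @param knots an [rcs_knots] object.
#' @return numeric matrix, `length(x)` by `knots$df`.
#' @export
rcs_basis <- function(x, knots) {
  stopifnot(inherits(knots, "rcs_knots"))
  x <- as.numeric(x)
  k <- all_knots(knots)
  K <- length(k)
  out <- matrix(0, length(x), knots$df)
  out[, 1] <- x
  if (K > 2L) {
    kmin <- k[1]; kmax <- k[K]
    for (m in 2:(K - 1L)) {
      lam <- (kmax - k[m]) / (kmax - kmin)
      out[, m] <- pmax(x - k[m], 0)^3 - lam * pmax(x - kmin, 0)^3 -
        (1 - lam) * pmax(x - kmax, 0)^3
    }
  }
  colnames(out) <- paste0("rcs", seq_len(knots$df))
  out
}

#' Derivative of the restricted cubic spline basis
#'
#' Element-wise derivative of [rcs_basis] with respect to `x`; used to obtain
#' the hazard from a spline-modelled log cumulative hazard.
#'
#' @inheritParams rcs_basis
#' @return numeric matrix matching [rcs_basis] in shape.
#' @export
rcs_deriv <- function(x, knots) {
  stopifnot(inherits(knots, "rcs_knots"))
  x <- as.numeric(x)
  k <- all_knots(knots)
  K <- length(k)
  out <- matrix(0, length(x), knots$df)
  out[, 1] <- 1
  if (K > 2L) {
    kmin <- k[1]; kmax <- k[K]
    for (m in 2:(K - 1L)) {
      lam <- (kmax - k[m]) / (kmax - kmin)
      out[, m] <- 3 * pmax(x - k[m], 0)^2 - 3 * lam * pmax(x - kmin, 0)^2 -
        3 * (1 - lam) * pmax(x - kmax, 0)^2
    }
  }
  colnames(out) <- paste0("rcs", seq_len(knots$df))
  out
}

# serialisable plain-list form, reconstructible with rcs_knots_from_list()
rcs_knots_to_list <- function(knots) {
  list(interior = knots$interior, boundary = knots$boundary, scale = knots$scale)
}

rcs_knots_from_list <- function(x) {
  new_rcs_knots(unlist(x$interior), unlist(x$boundary),
                if (is.null(x$scale)) "identity" else x$scale)
}
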
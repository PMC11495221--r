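#' Restricted cubic spline basis over EYO
#'
#' Knots sit at empirical quantiles of the pooled EYO sample (default 0.1,
#' 0.5, 0.9). The basis uses the restricted truncated-power construction
#' (Harrell normalization, dividing the nonlinear terms by the squared knot
#' span): one linear column plus one nonlinear column per interior knot, so
#' 3 knots give exactly 2 columns. The represented function is linear beyond
#' the boundary knots.
#'
#' @param x Numeric sample (EYO values) from which knots are placed.
#' @param quantiles Knot quantiles.
#' @param knots Optional explicit knot locations, overriding `quantiles`.
#' @return An object of class `rcs_basis` holding the knots; evaluate it on
#'   any grid with [rcs_eval()].
#' @export
rcs_basis <- function(x, quantiles = c(0.1, 0.5, 0.9), knots = NULL) {
  if (is.null(knots)) {
    x <- x[is.finite(x)]
    if (length(unique(x)) < 10) stop("need at least 10 distinct values to place knots")
    knots <- stats::quantile(x, probs = quantiles, names = FALSE, type = 7)
  }
  knots <- sort(as.numeric(knots))
  if (length(knots) < 3) stop("need at least 3 knots")
  if (any(diff(knots) <= 0)) stop("coincident knots: ", paste(knots, collapse = ", "))
  structure(list(knots = knots), class = "rcs_basis")
}

#' Evaluate a restricted cubic spline basis
#'
#' @param basis An [rcs_basis()].
#' @param x Points at which to evaluate.
#' @return Matrix with `length(knots) - 1` columns named `eyo_1`,
#'   `eyo_2`, ... (`eyo_1` is the linear term).
#' @export
rcs_eval <- function(basis, x) {
  stopifnot(inherits(basis, "rcs_basis"))
  t <- basis$knots
  k <- length(t)
  pp3 <- function(u) pmax(u, 0)^3
  out <- matrix(x, ncol = 1)
  norm <- (t[k] - t[1])^2
  for (j in seq_len(k - 2)) {
    col <- (pp3(x - t[j]) -
              pp3(x - t[k - 1]) * (t[k] - t[j]) / (t[k] - t[k - 1]) +
              pp3(x - t[k]) * (t[k - 1] - t[j]) / (t[k] - t[k - 1])) / norm
    out <- cbind(out, col)
  }
  colnames(out) <- paste0("eyo_", seq_len(ncol(out)))
  out
}
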
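#' Penalized B-spline basis for one smooth term
#'
#' Each smooth function in the additive predictors is represented by a
#' cubic B-spline basis with knots at covariate quantiles and a
#' second-order difference penalty on the coefficients (a P-spline).
#' Columns are centered on their training means so the intercept is carried
#' separately; outside the training range the basis is extended linearly,
#' so extrapolated predictions degrade gracefully instead of oscillating.
#' A covariate with too few distinct values degrades to a plain linear term
#' with zero penalty (with a warning for a constant covariate).
#'
#' @param x Numeric covariate values observed at training time.
#' @param name Covariate name (used in messages and serialization).
#' @param df Basis dimension (number of columns before centering).
#' @param degree Spline degree; 3 gives cubic B-splines.
#' @param penalty_order Order of the difference penalty.
#' @return An object of class `"spline_term"` describing the basis;
#'   evaluate it with [spline_basis()].
#' @export
spline_term <- function(x, name = "x", df = 10L, degree = 3L,
                        penalty_order = 2L) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L) {
    warning("covariate '", name,
            "' is constant; degrading to a linear term with zero penalty")
    return(structure(list(name = name, type = "linear",
                          center = if (length(x)) mean(x) else 0),
                     class = "spline_term"))
  }
  if (length(unique(x)) < df + 2L)
    return(structure(list(name = name, type = "linear", center = mean(x)),
                     class = "spline_term"))
  n_interior <- df - degree - 1L
  probs <- seq_len(n_interior) / (n_interior + 1)
  interior <- unique(as.numeric(stats::quantile(x, probs, names = FALSE)))
  boundary <- range(x)
  interior <- interior[interior > boundary[1] & interior < boundary[2]]
  if (!length(interior))
    return(structure(list(name = name, type = "linear", center = mean(x)),
                     class = "spline_term"))
  knots <- c(rep(boundary[1], degree + 1L), interior,
             rep(boundary[2], degree + 1L))
  k <- length(interior) + degree + 1L         # basis dimension
  term <- structure(list(name = name, type = "spline", knots = knots,
                         degree = degree, boundary = boundary,
                         penalty_order = penalty_order,
                         penalty = divided_diff_penalty(knots, degree,
                                                        penalty_order),
                         colmeans = rep(0, k)),
                    class = "spline_term")
  term$colmeans <- colMeans(spline_basis(term, x, center = FALSE))
  term
}

#' Evaluate a spline term's basis
#'
#' @param term A [spline_term()].
#' @param x Points at which to evaluate.
#' @param center Subtract the stored training column means?
#' @return Matrix with one row per element of `x`. For a linear fallback
#'   term the matrix has a single centered column.
#' @export
spline_basis <- function(term, x, center = TRUE) {
  stopifnot(inherits(term, "spline_term"))
  if (term$type == "linear")
    return(matrix(x - if (center) term$center else 0, ncol = 1,
                  dimnames = list(NULL, term$name)))
  lo <- term$boundary[1]; hi <- term$boundary[2]
  xc <- pmin(pmax(x, lo), hi)
  B <- splines::splineDesign(term$knots, xc, ord = term$degree + 1L)
  for (side in list(list(out = x < lo, at = lo), list(out = x > hi, at = hi))) {
    if (any(side$out)) {
      d1 <- splines::splineDesign(term$knots, side$at, ord = term$degree + 1L,
                                  derivs = 1L)
      B[side$out, ] <- B[side$out, , drop = FALSE] +
        (x[side$out] - side$at) %o% drop(d1)
    }
  }
  if (center) B <- sweep(B, 2L, term$colmeans)
  colnames(B) <- paste0(term$name, ".", seq_len(ncol(B)))
  B
}

# Difference penalty on the spline coefficients, taken as divided
# differences over the Greville abscissae so that the null space is
# exactly the polynomials of degree < penalty_order in x (for order 2:
# constant and linear functions) even with non-uniform quantile knots.
divided_diff_penalty <- function(knots, degree, penalty_order) {
  k <- length(knots) - degree - 1L
  g <- vapply(seq_len(k), function(i) mean(knots[(i + 1L):(i + degree)]),
              numeric(1))
  D <- diag(k)
  for (o in seq_len(penalty_order)) {
    m <- length(g)
    D <- diag(1 / diff(g), m - 1L, m - 1L) %*% diff(diag(m)) %*% D
    g <- (g[-1L] + g[-m]) / 2
  }
  # scale by the average spacing so the penalty has the units of an
  # integrated squared derivative and is comparable across covariates
  crossprod(D) * (diff(range(knots)) / (k - 1))^(2 * penalty_order - 1)
}

term_penalty <- function(term) {
  if (term$type == "linear") matrix(0, 1, 1) else term$penalty
}

# Assemble design matrix (intercept + centered bases) and the block
# penalty for a list of terms at a shared smoothing parameter.
assemble_design <- function(terms, data, lambda_pen) {
  blocks <- lapply(terms, function(tm) spline_basis(tm, data[[tm$name]]))
  X <- cbind(`(Intercept)` = 1, do.call(cbind, blocks))
  p <- ncol(X)
  S <- matrix(0, p, p)
  off <- 1L
  for (tm in terms) {
    P <- term_penalty(tm)
    k <- ncol(P)
    idx <- off + seq_len(k)
    if (tm$type == "spline") S[idx, idx] <- lambda_pen * P
    off <- off + k
  }
  list(X = X, S = S)
}
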
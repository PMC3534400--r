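#' @title Penalized IRLS fitting of the hurdle submodels
#'
#' @description
#' Both submodels — the logistic model for the probability of a productive
#' flow and the zero-truncated weighted Poisson model for the positive
#' homopolymer counts — are additive models on cubic B-spline bases,
#' fitted by maximizing a penalized log-likelihood with iteratively
#' reweighted least squares (IRLS). Each iteration solves a penalized
#' weighted least-squares problem on the working response
#' \eqn{z = \eta + u/w} with score \eqn{u} and curvature weight \eqn{w};
#' steps are halved whenever the penalized deviance would increase, so the
#' penalized deviance is non-increasing across iterations. Convergence is
#' declared when the relative change in penalized deviance falls below
#' `1e-6` (at most 100 iterations). The shared smoothing parameter is
#' chosen by approximate GCV on the working model over a log-spaced grid,
#' and the dispersion weight `theta` by profile likelihood over a grid
#' with golden-section refinement.
#' @name hurdle-fitting
NULL

ETA_CLIP <- c(-10, 5)  # log-rate bounds for the Poisson submodel

# --- generic penalized IRLS -------------------------------------------------

pirls <- function(X, S, llfun, start, max_iter = 100L, tol = 1e-6) {
  beta <- start
  eta <- drop(X %*% beta)
  st <- llfun(eta)
  pen <- function(b) drop(crossprod(b, S %*% b))
  pen_dev <- -2 * sum(st$ll) + pen(beta)
  dev_trace <- pen_dev
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    w <- pmax(st$w, 1e-8)
    z <- eta + st$u / w
    A <- crossprod(X * sqrt(w)) + S
    rhs <- crossprod(X, w * z)
    # escalating scaled ridge keeps the solve stable when the penalty
    # dwarfs the data information (e.g. smoothing parameter -> infinity)
    beta_prop <- NULL
    for (eps in c(0, 1e-12, 1e-9, 1e-6)) {
      beta_prop <- tryCatch(
        drop(solve(A + diag(eps * mean(diag(A)), ncol(X)), rhs)),
        error = function(e) NULL)
      if (!is.null(beta_prop)) break
    }
    if (is.null(beta_prop)) break
    step <- beta_prop - beta
    accepted <- FALSE
    for (half in 0:30) {
      beta_new <- beta + step * 0.5^half
      eta_new <- drop(X %*% beta_new)
      ll_new <- sum(llfun(eta_new, deriv = FALSE)$ll)
      pen_dev_new <- -2 * ll_new + pen(beta_new)
      if (is.finite(pen_dev_new) && pen_dev_new <= pen_dev + 1e-10) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break  # cannot improve: treat as converged at current point
    rel <- abs(pen_dev - pen_dev_new) / (abs(pen_dev_new) + 0.1)
    beta <- beta_new
    eta <- eta_new
    st <- llfun(eta)
    pen_dev <- pen_dev_new
    dev_trace <- c(dev_trace, pen_dev)
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  w <- pmax(st$w, 1e-8)
  XtWX <- crossprod(X * sqrt(w))
  Ainv <- tryCatch(solve(XtWX + S), error = function(e) NULL)
  edf <- if (is.null(Ainv)) ncol(X) else sum(Ainv * t(XtWX))
  dev <- -2 * sum(st$ll)
  n <- nrow(X)
  gcv <- n * dev / max(n - edf, 1)^2
  list(coef = beta, eta = eta, converged = converged, iterations = iters,
       penalized_loglik = sum(st$ll) - 0.5 * pen(beta),
       loglik = sum(st$ll), edf = edf, gcv = gcv, dev_trace = dev_trace)
}

# Design-matrix cache: bases are independent of the smoothing parameter,
# only the block penalty is rescaled.
make_design <- function(terms, data) {
  if (!length(terms)) {
    n <- nrow(data)
    return(list(X = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
                blocks = list()))
  }
  blocks <- lapply(terms, function(tm) spline_basis(tm, data[[tm$name]]))
  X <- cbind(`(Intercept)` = 1, do.call(cbind, blocks))
  pen_blocks <- list()
  off <- 1L
  for (i in seq_along(terms)) {
    P <- term_penalty(terms[[i]])
    pen_blocks[[i]] <- list(idx = off + seq_len(ncol(P)), P = P,
                            penalized = terms[[i]]$type == "spline")
    off <- off + ncol(P)
  }
  list(X = X, blocks = pen_blocks)
}

design_penalty <- function(design, lambda_pen, ridge = 0) {
  p <- ncol(design$X)
  S <- diag(ridge, p)
  for (b in design$blocks)
    if (b$penalized) S[b$idx, b$idx] <- S[b$idx, b$idx] + lambda_pen * b$P
  S
}

fit_gam_engine <- function(data, covariates, llfun, start0, df,
                           penalty_grid, link, ridge = 0, start = NULL) {
  terms <- lapply(covariates, function(nm) spline_term(data[[nm]], nm, df = df))
  design <- make_design(terms, data)
  if (is.null(start) || length(start) != ncol(design$X))
    start <- c(start0, rep(0, ncol(design$X) - 1L))
  best <- NULL
  grid_tab <- data.frame(lambda_pen = penalty_grid, gcv = NA_real_)
  for (i in seq_along(penalty_grid)) {
    S <- design_penalty(design, penalty_grid[i], ridge)
    fit <- pirls(design$X, S, llfun, start)
    grid_tab$gcv[i] <- fit$gcv
    if (is.null(best) || fit$gcv < best$fit$gcv)
      best <- list(fit = fit, lambda_pen = penalty_grid[i])
    start <- fit$coef  # warm start along the grid
  }
  structure(list(coef = best$fit$coef, terms = terms, link = link,
                 lambda_pen = best$lambda_pen,
                 converged = best$fit$converged,
                 iterations = best$fit$iterations,
                 penalized_loglik = best$fit$penalized_loglik,
                 loglik = best$fit$loglik, edf = best$fit$edf,
                 dev_trace = best$fit$dev_trace, gcv_table = grid_tab,
                 n = nrow(data)),
            class = "hurdle_gam")
}

#' Linear predictor of a fitted submodel
#' @param fit A `"hurdle_gam"` submodel fit.
#' @param data Data frame holding the submodel's covariates.
#' @return Numeric vector of linear-predictor values.
#' @export
submodel_eta <- function(fit, data) {
  stopifnot(inherits(fit, "hurdle_gam"))
  X <- make_design(fit$terms, data)$X
  drop(X %*% fit$coef)
}

#' @export
print.hurdle_gam <- function(x, ...) {
  cat("Penalized additive submodel (", x$link, " link)\n", sep = "")
  cat("  terms:", if (length(x$terms))
    paste(vapply(x$terms, `[[`, "", "name"), collapse = ", ")
    else "intercept only", "\n")
  cat(sprintf("  n = %d, edf = %.2f, smoothing parameter = %g\n",
              x$n, x$edf, x$lambda_pen))
  cat(sprintf("  penalized log-likelihood = %.3f (%s in %d iterations)\n",
              x$penalized_loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

# --- binomial submodel ------------------------------------------------------

#' Fit the logistic submodel for productive flows
#'
#' Maximizes the penalized Bernoulli log-likelihood for
#' \eqn{\mathrm{logit}(\Pi) = \beta_0 + \sum_j f_j(x_j)} by penalized
#' IRLS. If the optimum shows signs of complete separation (unbounded
#' linear predictor) the model is refitted with a small ridge (`1e-6`)
#' added to the penalty, with a warning.
#'
#' @param data Data frame of covariates (e.g. from [build_features()]).
#' @param z Binary vector: 1 for flows with positive homopolymer length.
#' @param covariates Names of columns of `data` to use as smooth terms;
#'   empty for an intercept-only model.
#' @param df Basis dimension per smooth.
#' @param penalty_grid Candidate shared smoothing parameters; the one with
#'   the smallest approximate GCV score is kept.
#' @return A `"hurdle_gam"` fit.
#' @export
fit_binomial_gam <- function(data, z, covariates = character(),
                             df = 10L, penalty_grid = 10^seq(-4, 4)) {
  z <- as.integer(z)
  if (length(unique(z)) < 2L)
    stop("both zero and positive flows are required to fit the hurdle ",
         "binomial component", call. = FALSE)
  llfun <- function(eta, deriv = TRUE) {
    mu <- stats::plogis(pmin(pmax(eta, -30), 30))
    out <- list(ll = stats::dbinom(z, 1L, mu, log = TRUE))
    if (deriv) {
      out$u <- z - mu
      out$w <- mu * (1 - mu)
    }
    out
  }
  fit <- fit_gam_engine(data, covariates, llfun, stats::qlogis(mean(z)),
                        df, penalty_grid, link = "logit")
  eta <- submodel_eta(fit, data)
  if (max(abs(eta)) > 30) {
    warning("possible separation in the binomial submodel; ",
            "refitting with a small ridge penalty")
    fit <- fit_gam_engine(data, covariates, llfun, stats::qlogis(mean(z)),
                          df, penalty_grid, link = "logit", ridge = 1e-6)
  }
  fit
}

# --- zero-truncated weighted Poisson submodel -------------------------------

#' Zero-truncated weighted Poisson log-likelihood
#'
#' @param counts Positive integer homopolymer lengths.
#' @param lam Per-flow rates (recycled).
#' @param theta Dispersion weight parameter.
#' @return The summed log-likelihood.
#' @export
ztwp_loglik <- function(counts, lam, theta) {
  if (any(counts < 1))
    stop("all counts must be >= 1 for the zero-truncated likelihood",
         call. = FALSE)
  sum(dztwpois(counts, lam, theta, log = TRUE))
}

# Per-observation ZTWP log-likelihood as a function of eta = log(lambda),
# vectorized over observations. A(lambda) = sum_{m>=1} raw terms is the
# truncated-series normalizer of the positive part.
ztwp_ll_eta <- function(counts, eta, theta) {
  lam <- exp(pmin(pmax(eta, ETA_CLIP[1]), ETA_CLIP[2]))
  A <- wpois_series(lam, theta, drop_zero = TRUE)
  -theta * (lam - counts)^2 + counts * log(lam) - lam -
    lgamma(counts + 1) - log(A)
}

#' Fit the zero-truncated weighted Poisson submodel
#'
#' Maximizes the penalized zero-truncated weighted Poisson log-likelihood
#' for \eqn{\log(\lambda) = \gamma_0 + \sum_j g_j(y_j)} at a fixed
#' dispersion weight `theta`, by IRLS with working score and curvature
#' obtained from central finite differences of the per-flow log-likelihood
#' in \eqn{\eta = \log\lambda}. The linear predictor is clipped to
#' \eqn{[-10, 5]} as an overflow guard; a warning is issued if the clip is
#' active at the optimum.
#'
#' @inheritParams fit_binomial_gam
#' @param counts Positive integer homopolymer lengths, one per row of
#'   `data`.
#' @param theta Fixed dispersion weight parameter (see
#'   [estimate_theta()]).
#' @param start Optional full coefficient start (warm start).
#' @return A `"hurdle_gam"` fit.
#' @export
fit_ztwp_gam <- function(data, counts, theta = 0, covariates = character(),
                         df = 10L, penalty_grid = 10^seq(-4, 4),
                         start = NULL) {
  if (any(counts < 1))
    stop("all counts must be >= 1 in the zero-truncated submodel",
         call. = FALSE)
  h <- 1e-3
  llfun <- function(eta, deriv = TRUE) {
    ll <- ztwp_ll_eta(counts, eta, theta)
    out <- list(ll = ll)
    if (deriv) {
      llp <- ztwp_ll_eta(counts, eta + h, theta)
      llm <- ztwp_ll_eta(counts, eta - h, theta)
      out$u <- (llp - llm) / (2 * h)
      out$w <- pmax(-(llp - 2 * ll + llm) / h^2, 1e-8)
    }
    out
  }
  fit <- fit_gam_engine(data, covariates, llfun, log(mean(counts)),
                        df, penalty_grid, link = "log", start = start)
  eta <- submodel_eta(fit, data)
  if (any(eta < ETA_CLIP[1] | eta > ETA_CLIP[2]))
    warning("linear predictor clipped to [", ETA_CLIP[1], ", ", ETA_CLIP[2],
            "] at the optimum of the Poisson submodel")
  fit
}

# --- profile estimation of theta --------------------------------------------

#' Profile-likelihood estimation of the dispersion weight
#'
#' Refits the zero-truncated weighted Poisson submodel for every `theta`
#' on a grid, records the penalized log-likelihood, and refines the grid
#' argmax by golden-section search between its neighbours (tolerance
#' `1e-3` on the log-theta scale). A boundary argmax is returned as is;
#' a flat profile (range below `1e-6`) returns the smallest grid value
#' with a warning.
#'
#' @inheritParams fit_ztwp_gam
#' @param grid Non-empty vector of candidate `theta` values (non-negative,
#'   increasing).
#' @param penalty_grid Smoothing parameter(s) passed to [fit_ztwp_gam()];
#'   typically a single pre-selected value so the profile varies only in
#'   `theta`.
#' @return A list with `theta` (the estimate) and `profile` (a data frame
#'   of grid values and penalized log-likelihoods).
#' @export
estimate_theta <- function(data, counts, covariates = character(),
                           grid = c(0, 0.05, 0.1, 0.2, 0.4, 0.8, 1.6),
                           df = 10L, penalty_grid = 1) {
  if (!length(grid)) stop("'grid' must be non-empty", call. = FALSE)
  grid <- sort(grid)
  pll <- numeric(length(grid))
  start <- NULL
  fits <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    fits[[i]] <- fit_ztwp_gam(data, counts, theta = grid[i],
                              covariates = covariates, df = df,
                              penalty_grid = penalty_grid, start = start)
    pll[i] <- fits[[i]]$penalized_loglik
    start <- fits[[i]]$coef
  }
  profile <- data.frame(theta = grid, penalized_loglik = pll)
  if (length(grid) == 1L)
    return(list(theta = grid, profile = profile))
  if (diff(range(pll)) < 1e-6) {
    warning("flat theta profile; returning the smallest grid value")
    return(list(theta = grid[1], profile = profile))
  }
  i_best <- which.max(pll)
  if (i_best == 1L)
    return(list(theta = grid[1L], profile = profile))
  if (i_best == length(grid)) {
    # Profile still rising at the top of the grid: expand geometrically
    # until it turns over, then refine inside the bracket. The expansion
    # stops at theta = -log(prob floor): past that point the weight of a
    # count one away from lambda is below the 1e-15 floor applied to all
    # reported probabilities, so larger theta cannot change any output
    # (it only drives the positive part to a degenerate point mass).
    theta_max <- -log(PROB_FLOOR)
    th <- grid[i_best]
    best_pll <- pll[i_best]
    start_exp <- fits[[i_best]]$coef
    while (2 * th <= theta_max) {
      th_next <- 2 * th
      fit_next <- fit_ztwp_gam(data, counts, theta = th_next,
                               covariates = covariates, df = df,
                               penalty_grid = penalty_grid,
                               start = start_exp)
      profile <- rbind(profile,
                       data.frame(theta = th_next,
                                  penalized_loglik = fit_next$penalized_loglik))
      if (fit_next$penalized_loglik <= best_pll) break
      th <- th_next
      best_pll <- fit_next$penalized_loglik
      start_exp <- fit_next$coef
    }
    o <- order(profile$theta)
    profile <- profile[o, ]
    rownames(profile) <- NULL
    pll <- profile$penalized_loglik
    grid <- profile$theta
    i_best <- which.max(pll)
    fits <- vector("list", length(grid))
    fits[[i_best]] <- list(coef = start_exp)
    if (i_best == length(grid))
      return(list(theta = grid[i_best], profile = profile))
  }
  # golden-section refinement on log(theta) between the neighbours
  lo <- max(grid[i_best - 1L], grid[i_best] / 16)
  hi <- grid[i_best + 1L]
  f <- function(lth) {
    fit <- fit_ztwp_gam(data, counts, theta = exp(lth),
                        covariates = covariates, df = df,
                        penalty_grid = penalty_grid, start = fits[[i_best]]$coef)
    fit$penalized_loglik
  }
  gr <- (sqrt(5) - 1) / 2
  a <- log(lo); b <- log(hi)
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > 1e-3) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  theta_hat <- exp((a + b) / 2)
  if (f((a + b) / 2) < pll[i_best]) theta_hat <- grid[i_best]
  list(theta = theta_hat, profile = profile)
}
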
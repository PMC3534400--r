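#' Train the full hurdle base-calling model
#'
#' Builds covariates from a training flow table carrying reference
#' homopolymer lengths (`ref_hpl`), fits the logistic submodel on the
#' zero/positive indicator, fits the zero-truncated weighted Poisson
#' submodel on the positive flows, and estimates the dispersion weight
#' `theta` by profile likelihood. Smoothing-parameter selection (GCV over
#' `penalty_grid`) and the `theta` profile are alternated once: the
#' smoothing parameter is first chosen at `theta = 0`, `theta` is profiled
#' at that smoothing parameter, and the smoothing parameter is then
#' re-selected at the estimated `theta`.
#'
#' @param flows Training flow table (see [read_flow_table()]) with a
#'   `ref_hpl` column.
#' @param config A [feature_config()] naming the covariates of each
#'   submodel.
#' @param df Basis dimension per smooth term.
#' @param penalty_grid Candidate shared smoothing parameters (approximate
#'   GCV selection).
#' @param theta_grid Grid for the profile-likelihood estimation of
#'   `theta`.
#' @param min_positive Minimum number of positive flows required.
#' @param n_max Largest homopolymer length carried in reported probability
#'   vectors; defaults to `max(ref_hpl) + 3` with a floor of 12.
#' @return An object of class `"hurdle_model"`.
#' @seealso [predict.hurdle_model()], [call_reads()], [write_model()]
#' @export
fit_hurdle_model <- function(flows, config = feature_config(), df = 10L,
                             penalty_grid = 10^seq(-4, 4),
                             theta_grid = c(0, 0.05, 0.1, 0.2, 0.4, 0.8, 1.6),
                             min_positive = 50L, n_max = NULL) {
  if (!"ref_hpl" %in% names(flows) || all(is.na(flows$ref_hpl)))
    stop("training requires the 'ref_hpl' column (reference homopolymer ",
         "lengths)", call. = FALSE)
  keep <- !is.na(flows$ref_hpl)
  flows <- flows[keep, , drop = FALSE]
  feats <- build_features(flows, config)
  ref <- as.integer(flows$ref_hpl)
  z <- as.integer(ref > 0L)
  if (sum(z) < min_positive)
    stop("only ", sum(z), " positive flows; at least ", min_positive,
         " are required", call. = FALSE)
  binom <- fit_binomial_gam(feats, z, covariates = config$binomial, df = df,
                            penalty_grid = penalty_grid)

  pos <- z == 1L
  feats_pos <- feats[pos, , drop = FALSE]
  counts <- ref[pos]
  # smoothing selection at theta = 0
  pois0 <- fit_ztwp_gam(feats_pos, counts, theta = 0,
                        covariates = config$poisson, df = df,
                        penalty_grid = penalty_grid)
  prof <- estimate_theta(feats_pos, counts, covariates = config$poisson,
                         grid = theta_grid, df = df,
                         penalty_grid = pois0$lambda_pen)
  # one alternation: re-select the smoothing parameter at theta-hat
  pois <- fit_ztwp_gam(feats_pos, counts, theta = prof$theta,
                       covariates = config$poisson, df = df,
                       penalty_grid = penalty_grid, start = pois0$coef)

  if (is.null(n_max)) n_max <- max(12L, max(ref) + 3L)
  feat_cols <- setdiff(names(feats), c("read_id", "flow_index"))
  ranges <- lapply(feats[feat_cols], range)
  structure(list(binomial = binom, poisson = pois, theta = prof$theta,
                 theta_profile = prof$profile, n_max = as.integer(n_max),
                 feature_config = config,
                 training_summary = list(
                   n_flows = nrow(flows),
                   n_reads = length(unique(flows$read_id)),
                   n_positive = sum(z),
                   max_ref_hpl = max(ref),
                   covariate_ranges = ranges)),
            class = "hurdle_model")
}

#' @export
print.hurdle_model <- function(x, ...) {
  cat("Hurdle base-calling model\n")
  cat(sprintf("  trained on %d flows / %d reads (%d positive)\n",
              x$training_summary$n_flows, x$training_summary$n_reads,
              x$training_summary$n_positive))
  cat(sprintf("  theta = %.4f, n_max = %d\n", x$theta, x$n_max))
  cat("  binomial submodel: "); print(x$binomial)
  cat("  Poisson submodel: "); print(x$poisson)
  invisible(x)
}

#' Per-flow hurdle parameters for new reads
#'
#' Builds features with the model's own feature configuration and returns
#' the estimated probability of a productive flow and the weighted Poisson
#' rate for every flow, plus a flag for flows whose covariates fall outside
#' three times the span observed in training (extrapolation).
#'
#' @param object A fitted [fit_hurdle_model()].
#' @param flows Flow table for the reads to be called.
#' @param config Optional [feature_config()]; it must be identical to the
#'   one used in training (supplying a different one is an error).
#' @param ... Unused.
#' @return Data frame with `read_id`, `flow_index`, `pi`, `lambda`,
#'   `extrapolated`.
#' @export
predict.hurdle_model <- function(object, flows, config = NULL, ...) {
  if (!is.null(config) && !identical(unclass(config),
                                     unclass(object$feature_config)))
    stop("feature configuration differs from the one used to train the ",
         "model; prediction refuses mismatched configurations",
         call. = FALSE)
  feats <- build_features(flows, object$feature_config)
  eta_b <- submodel_eta(object$binomial, feats)
  eta_p <- submodel_eta(object$poisson, feats)
  extrapolated <- rep(FALSE, nrow(feats))
  for (nm in names(object$training_summary$covariate_ranges)) {
    if (!nm %in% names(feats)) next
    r <- object$training_summary$covariate_ranges[[nm]]
    mid <- mean(r); half <- diff(r) / 2
    extrapolated <- extrapolated |
      feats[[nm]] < mid - 3 * half | feats[[nm]] > mid + 3 * half
  }
  data.frame(read_id = feats$read_id, flow_index = feats$flow_index,
             pi = stats::plogis(eta_b),
             lambda = exp(pmin(pmax(eta_p, ETA_CLIP[1]), ETA_CLIP[2])),
             extrapolated = extrapolated,
             stringsAsFactors = FALSE)
}
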
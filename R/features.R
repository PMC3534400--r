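#' Feature configuration for the hurdle base-calling model
#'
#' The two submodels use covariates derived from the ordered flow signals of
#' each read: the current flowgram value (`fg0`), the (optionally
#' read-normalized) log2 raw intensity (`lraw0`), cumulative sums of both
#' over strictly earlier flows (`cum_fg`, `cum_lraw`), and flowgram values
#' 1, 4 and 8 flows before/after the current flow (`fg_lag1`, ...,
#' `fg_lead8`). Lags and leads beyond the read ends are filled with 0, the
#' natural background flowgram value.
#'
#' @param binomial Character vector of covariates entering the logistic
#'   (zero vs positive) submodel.
#' @param poisson Character vector of covariates entering the
#'   zero-truncated weighted Poisson submodel.
#' @param normalize_raw Apply the read-specific normalization of
#'   [normalize_raw()] to log2 raw intensities?
#' @param flow_order Four-letter nucleotide flow order (a permutation of
#'   TACG).
#' @return A list of class `"feature_config"`.
#' @export
feature_config <- function(binomial = c("fg0", "lraw0", "cum_fg", "fg_lag1", "fg_lead1"),
                           poisson = c("fg0", "lraw0", "cum_fg",
                                       "fg_lag1", "fg_lag4", "fg_lag8",
                                       "fg_lead1", "fg_lead4", "fg_lead8"),
                           normalize_raw = TRUE,
                           flow_order = "TACG") {
  all_feats <- c("fg0", "lraw0", "cum_fg", "cum_lraw",
                 paste0("fg_lag", c(1, 4, 8)), paste0("fg_lead", c(1, 4, 8)))
  bad <- setdiff(c(binomial, poisson), all_feats)
  if (length(bad))
    stop("unknown feature(s): ", paste(bad, collapse = ", "), call. = FALSE)
  check_flow_order(flow_order)
  structure(list(binomial = binomial, poisson = poisson,
                 normalize_raw = isTRUE(normalize_raw),
                 flow_order = toupper(flow_order)),
            class = "feature_config")
}

check_flow_order <- function(flow_order) {
  if (!is.character(flow_order) || length(flow_order) != 1L ||
      nchar(flow_order) != 4L ||
      !setequal(strsplit(toupper(flow_order), "")[[1]], c("T", "A", "C", "G")))
    stop("'flow_order' must be a permutation of TACG", call. = FALSE)
  invisible(TRUE)
}

# split a flow table into per-read chunks, preserving first-appearance order
split_reads <- function(flows) {
  split(flows, factor(flows$read_id, levels = unique(flows$read_id)))
}

check_read_sorted <- function(fl) {
  idx <- fl$flow_index
  if (anyDuplicated(idx))
    stop("duplicated flow_index within read ", fl$read_id[1], call. = FALSE)
  if (is.unsorted(idx, strictly = TRUE))
    stop("flows of read ", fl$read_id[1], " are not sorted by flow_index",
         call. = FALSE)
  invisible(TRUE)
}

#' Read-specific normalization of log2 raw intensities
#'
#' Centers the log2 raw intensities of each read on a read-specific
#' baseline: the median log2 raw intensity over the read's presumed zero
#' flows (flowgram value < 0.5). If a read has fewer than 4 such flows the
#' median over all its flows is used instead.
#'
#' @param flows Flow table (data frame with at least `read_id`,
#'   `flow_index`, `flowgram`, `raw_intensity`), sorted by flow within
#'   read.
#' @return Numeric vector of centered log2 raw intensities, aligned with
#'   the rows of `flows`.
#' @export
normalize_raw <- function(flows) {
  if (nrow(flows) == 0L) return(numeric(0))
  unlist(lapply(split_reads(flows), function(fl) {
    l <- log2(fl$raw_intensity)
    zero <- fl$flowgram < 0.5
    baseline <- if (sum(zero) >= 4L) stats::median(l[zero]) else stats::median(l)
    l - baseline
  }), use.names = FALSE)
}

shift_fill0 <- function(x, by) {
  # by > 0: lag (values from 'by' positions earlier); by < 0: lead
  n <- length(x)
  out <- numeric(n)
  if (by >= n || -by >= n) return(out)
  if (by > 0) out[(by + 1):n] <- x[1:(n - by)]
  else if (by < 0) out[1:(n + by)] <- x[(1 - by):n]
  else out <- x
  out
}

#' Build model covariates from ordered flow signals
#'
#' Computes one row of covariates per flow: the current flowgram and log2
#' raw intensity, cumulative sums over strictly earlier flows, and lag/lead
#' flowgram values at offsets 1, 4 and 8. All covariates are computed
#' within read; positions beyond the read boundaries are filled with 0.
#'
#' @inheritParams normalize_raw
#' @param config A [feature_config()].
#' @return A data frame with `read_id`, `flow_index` and one column per
#'   covariate, in the row order of `flows`.
#' @export
build_features <- function(flows, config = feature_config()) {
  stopifnot(inherits(config, "feature_config"))
  need <- c("read_id", "flow_index", "flowgram", "raw_intensity")
  miss <- setdiff(need, names(flows))
  if (length(miss))
    stop("flow table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  reads <- split_reads(flows)
  lapply(reads, check_read_sorted)
  lraw_all <- if (config$normalize_raw) normalize_raw(flows)
              else log2(flows$raw_intensity)
  flows$.lraw <- lraw_all
  out <- lapply(split_reads(flows), function(fl) {
    fg <- fl$flowgram
    lr <- fl$.lraw
    n <- length(fg)
    data.frame(
      read_id = fl$read_id, flow_index = fl$flow_index,
      fg0 = fg, lraw0 = lr,
      cum_fg = c(0, cumsum(fg))[seq_len(n)],
      cum_lraw = c(0, cumsum(lr))[seq_len(n)],
      fg_lag1 = shift_fill0(fg, 1L), fg_lag4 = shift_fill0(fg, 4L),
      fg_lag8 = shift_fill0(fg, 8L),
      fg_lead1 = shift_fill0(fg, -1L), fg_lead4 = shift_fill0(fg, -4L),
      fg_lead8 = shift_fill0(fg, -8L),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
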
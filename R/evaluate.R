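#' Base-calling accuracy by homopolymer length
#'
#' Classifies every flow as correct, undercall (called < reference) or
#' overcall (called > reference) and tabulates counts and error
#' percentages per reference homopolymer length, with overall totals in
#' the last row.
#'
#' @param called_hpls Integer vector of called homopolymer lengths.
#' @param ref_hpls Integer vector of reference homopolymer lengths (same
#'   length).
#' @return Data frame with columns `ref_hpl` (`"all"` for the totals
#'   row), `n_flows`, `n_correct`, `n_undercall`, `n_overcall`,
#'   `pct_error`.
#' @export
error_by_hpl <- function(called_hpls, ref_hpls) {
  if (length(called_hpls) != length(ref_hpls))
    stop("'called_hpls' and 'ref_hpls' must have equal length",
         call. = FALSE)
  cls <- ifelse(called_hpls < ref_hpls, "undercall",
                ifelse(called_hpls > ref_hpls, "overcall", "correct"))
  lv <- sort(unique(ref_hpls))
  rows <- lapply(lv, function(h) {
    sel <- ref_hpls == h
    data.frame(ref_hpl = as.character(h), n_flows = sum(sel),
               n_correct = sum(cls[sel] == "correct"),
               n_undercall = sum(cls[sel] == "undercall"),
               n_overcall = sum(cls[sel] == "overcall"))
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(ref_hpl = "all", n_flows = length(cls),
                               n_correct = sum(cls == "correct"),
                               n_undercall = sum(cls == "undercall"),
                               n_overcall = sum(cls == "overcall")))
  tab$pct_error <- 100 * (tab$n_undercall + tab$n_overcall) / tab$n_flows
  tab
}

#' Observed versus predicted quality-score calibration
#'
#' Groups called bases by their integer predicted Phred score and
#' computes for each group the observed score
#' \eqn{-10\log_{10}(\text{overcall rate})}. Groups with zero observed
#' overcalls are reported at the cap (40) and flagged; observed scores
#' above the cap are trimmed to it, mirroring the trimming of the
#' predicted scores.
#'
#' @param predicted_qs Integer predicted Phred score per called base.
#' @param overcall Logical (or 0/1) indicator per called base: was the
#'   base an overcall (its within-homopolymer position exceeds the
#'   reference homopolymer length)?
#' @return Data frame with `predicted_qs`, `observed_qs`, `n`,
#'   `n_overcall`, `zero_errors`.
#' @export
qs_calibration <- function(predicted_qs, overcall) {
  stopifnot(length(predicted_qs) == length(overcall))
  overcall <- as.logical(overcall)
  qs <- round_half_away(predicted_qs)
  groups <- sort(unique(qs))
  rows <- lapply(groups, function(g) {
    sel <- qs == g
    n <- sum(sel)
    k <- sum(overcall[sel])
    obs <- if (k == 0L) QS_CAP else min(-10 * log10(k / n), QS_CAP)
    data.frame(predicted_qs = g, observed_qs = obs, n = n, n_overcall = k,
               zero_errors = k == 0L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cumulative distribution of assigned quality scores
#'
#' @param predicted_qs Integer Phred score per called base.
#' @param t_max Largest threshold reported.
#' @return Data frame with `t` (0..`t_max`) and `fraction`, the fraction
#'   of bases with score `>= t` (non-increasing in `t`; 1 at `t = 0`).
#' @export
cumulative_qs <- function(predicted_qs, t_max = QS_CAP) {
  t <- 0:t_max
  frac <- vapply(t, function(th) mean(predicted_qs >= th), numeric(1))
  data.frame(t = t, fraction = frac)
}

#' Flow-aligned evaluation of called reads against reference truth
#'
#' Pairs every called flow with its reference homopolymer length (flow
#' alignment via the simulator truth; no sequence aligner involved) and
#' derives the error table, the per-base overcall indicators and the
#' quality-score calibration.
#'
#' @param called_reads A [call_reads()] result.
#' @param flows The flow table that was called, carrying `ref_hpl`.
#' @return List with `error_table`, `calibration`, `cumulative`, and the
#'   per-base data frame `bases` (`predicted_qs`, `overcall`).
#' @export
evaluate_calls <- function(called_reads, flows) {
  key <- paste(flows$read_id, flows$flow_index)
  ref_of <- stats::setNames(flows$ref_hpl, key)
  called_all <- integer(0); ref_all <- integer(0)
  pred_qs <- integer(0); over <- logical(0)
  for (rd in called_reads) {
    ref <- ref_of[paste(rd$read_id, rd$flow_index)]
    called_all <- c(called_all, rd$called_hpls)
    ref_all <- c(ref_all, ref)
    if (nrow(rd$base_to_flow)) {
      ref_base <- ref_of[paste(rd$read_id, rd$base_to_flow$flow_index)]
      pred_qs <- c(pred_qs, rd$phred)
      over <- c(over, rd$base_to_flow$k > ref_base)
    }
  }
  if (anyNA(ref_all))
    stop("evaluation requires 'ref_hpl' for every called flow",
         call. = FALSE)
  list(error_table = error_by_hpl(called_all, ref_all),
       calibration = qs_calibration(pred_qs, over),
       cumulative = cumulative_qs(pred_qs),
       bases = data.frame(predicted_qs = pred_qs, overcall = over))
}
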
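#' Quality scores from homopolymer-length probabilities
#'
#' For the `k`-th base of a called homopolymer the two error tails of the
#' flow's probability vector are
#' \deqn{P(\mathrm{overcall}_k) = P(N < k), \qquad
#'       P(\mathrm{undercall}_k) = P(N > k),}
#' i.e. the probability that the `k`-th called base should not exist, and
#' the probability that at least one base beyond position `k` is missing.
#' Both are turned into Phred-like scores \eqn{-10\log_{10}} after
#' flooring the tail probability at `1e-15`. The signed combined score is
#' \deqn{QS_k = I_{dir} \times \mathrm{round}(\min(QS_{k,under},
#'       QS_{k,over})),}
#' with \eqn{I_{dir} = -1} when the undercall score is strictly smaller
#' (an undercall is the likelier error) and \eqn{+1} otherwise. Reported
#' integer scores are rounded half away from zero and their magnitude is
#' capped at 40; per-base Phred scores are the capped rounded overcall
#' scores.
#'
#' @param probs Probability vector over homopolymer lengths `0..n_max`
#'   (element `i` is the probability of length `i - 1`).
#' @param k Within-homopolymer position: `k >= 1` for called bases, `k = 0`
#'   for the no-base position of a zero call (`qs_overcall` requires
#'   `k >= 1`).
#' @return `qs_overcall` and `qs_undercall` return raw (uncapped) scores;
#'   `qs_signed` returns the signed rounded integer score.
#' @examples
#' p <- c(0.75, 0.25, 2.9e-8)        # a likely 0-1 undercall flow
#' call_hpl(p)                        # called length 0
#' qs_signed(p, 0)                    # -6: an undercall is likelier
#' @name quality-scores
NULL

PROB_FLOOR <- 1e-15
QS_CAP <- 40L

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @rdname quality-scores
#' @export
qs_overcall <- function(probs, k) {
  if (k < 1) stop("'k' must be >= 1 for overcall scores", call. = FALSE)
  tail_p <- sum(probs[seq_len(min(k, length(probs)))])
  -10 * log10(max(tail_p, PROB_FLOOR))
}

#' @rdname quality-scores
#' @export
qs_undercall <- function(probs, k) {
  if (k < 0) stop("'k' must be >= 0", call. = FALSE)
  L <- length(probs)
  tail_p <- if (k + 2L <= L) sum(probs[(k + 2L):L]) else 0
  -10 * log10(max(tail_p, PROB_FLOOR))
}

#' @rdname quality-scores
#' @export
qs_signed <- function(probs, k) {
  qu <- qs_undercall(probs, k)
  qo <- if (k >= 1) qs_overcall(probs, k) else -10 * log10(PROB_FLOOR)
  dir <- if (qu < qo) -1L else 1L
  mag <- min(round_half_away(min(qu, qo)), QS_CAP)
  if (mag <= 0L) return(0L)
  as.integer(dir * mag)
}

#' Per-base Phred-like scores of a called read
#'
#' The `k`-th base of each called homopolymer receives the rounded
#' overcall score of its flow, capped at 40 and floored at 0 — a
#' Phred-like score for the probability that the base is not an overcall.
#'
#' @param called_read A [assemble_read()] result.
#' @param prob_matrix Matrix of per-flow probability vectors (rows in flow
#'   order, as in the read).
#' @return Integer vector, one score per called base, in sequence order.
#' @export
phred_scores <- function(called_read, prob_matrix) {
  btf <- called_read$base_to_flow
  if (nrow(btf) == 0L) return(integer(0))
  L <- ncol(prob_matrix)
  C <- matrixStats_rowCumsums(prob_matrix)
  rows <- match(btf$flow_index, called_read$flow_index)
  over_tail <- C[cbind(rows, pmin(btf$k, L))]
  q <- -10 * log10(pmax(over_tail, PROB_FLOOR))
  as.integer(pmax(pmin(round_half_away(q), QS_CAP), 0L))
}

# row-wise cumulative sums (kept in base R; apply() would transpose)
matrixStats_rowCumsums <- function(m) {
  out <- m
  if (ncol(m) >= 2L)
    for (j in 2:ncol(m)) out[, j] <- out[, j - 1L] + m[, j]
  out
}

#' Per-position quality-score table of a called read
#'
#' For every flow, scores the within-homopolymer positions
#' `k = 0..min(called + window, n_max)` (position 0 is the no-base
#' position of a zero call, scored on the undercall side only).
#'
#' @inheritParams phred_scores
#' @param n_max Largest homopolymer length of the probability vectors.
#' @param window Number of positions beyond the called length to report.
#' @return Data frame with `read_id`, `flow_index`, `k`, `qs_overcall`,
#'   `qs_undercall`, `qs_signed`.
#' @export
position_quality <- function(called_read, prob_matrix, n_max, window = 2L) {
  called <- called_read$called_hpls
  L <- ncol(prob_matrix)
  C <- matrixStats_rowCumsums(prob_matrix)
  n_pos <- pmin(called + window, n_max) + 1L  # positions k = 0..
  rows <- rep(seq_along(called), n_pos)
  k <- sequence(n_pos) - 1L
  over_tail <- ifelse(k >= 1L, C[cbind(rows, pmax(pmin(k, L), 1L))], NA)
  under_tail <- C[cbind(rows, L)] - C[cbind(rows, pmin(k + 1L, L))]
  under_tail[k + 1L >= L] <- 0
  qo <- -10 * log10(pmax(over_tail, PROB_FLOOR))
  qu <- -10 * log10(pmax(under_tail, PROB_FLOOR))
  qo_eff <- ifelse(is.na(qo), -10 * log10(PROB_FLOOR), qo)
  dir <- ifelse(qu < qo_eff, -1L, 1L)
  mag <- pmin(round_half_away(pmin(qu, qo_eff)), QS_CAP)
  data.frame(
    read_id = called_read$read_id,
    flow_index = called_read$flow_index[rows],
    k = k,
    qs_overcall = qo,
    qs_undercall = qu,
    qs_signed = as.integer(ifelse(mag <= 0, 0L, dir * mag)),
    stringsAsFactors = FALSE)
}
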
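#' Per-flow homopolymer-length probabilities
#'
#' Given the hurdle parameters of one flow, returns the discrete
#' distribution over homopolymer lengths `0..n_max`: the zero class gets
#' `1 - pi` exactly, and the positive classes share `pi` according to the
#' zero-truncated weighted Poisson probabilities renormalized over
#' `1..n_max` (the truncated tail mass beyond `n_max` is negligible for
#' flow-data rates).
#'
#' @param pi Probability of a productive flow.
#' @param lambda Weighted Poisson rate.
#' @param theta Dispersion weight parameter.
#' @param n_max Largest reported homopolymer length.
#' @return Numeric vector of length `n_max + 1`; element `i` is the
#'   probability of homopolymer length `i - 1`.
#' @export
hpl_probabilities <- function(pi, lambda, theta, n_max) {
  probs <- numeric(n_max + 1L)
  probs[1] <- 1 - pi
  if (pi > 0) {
    p_pos <- dztwpois(seq_len(n_max), lambda, theta)
    probs[-1] <- pi * p_pos / sum(p_pos)
  }
  probs
}

#' Probability matrix for a set of flows
#'
#' Applies a fitted hurdle model to a flow table and returns the
#' homopolymer-length probability distribution of every flow.
#'
#' @param model A fitted [fit_hurdle_model()].
#' @param flows Flow table of the reads to call.
#' @return A list with `pred` (the data frame from
#'   [predict.hurdle_model()]) and `probs`, a numeric matrix with one row
#'   per flow and columns `p0..p<n_max>`.
#' @export
predict_probabilities <- function(model, flows) {
  pred <- stats::predict(model, flows)
  n_max <- model$n_max
  # vectorized over flows: ZTWP probabilities for all rates at once
  lam <- pred$lambda
  P <- ztwp_matrix(lam, model$theta, n_max)
  P <- P / rowSums(P)
  probs <- cbind(1 - pred$pi, pred$pi * P)
  colnames(probs) <- paste0("p", 0:n_max)
  list(pred = pred, probs = probs)
}

#' Call a homopolymer length from a probability vector
#'
#' Returns the homopolymer length with maximal probability; exact ties are
#' broken toward the smaller length (conservative against overcalls).
#'
#' @param probs Probability vector over homopolymer lengths `0..n_max`.
#' @return A single integer homopolymer length.
#' @export
call_hpl <- function(probs) {
  which.max(probs) - 1L
}

#' Assemble a called read from per-flow homopolymer lengths
#'
#' Concatenates each flow's nucleotide repeated by its called homopolymer
#' length, and records the mapping from base positions to flows together
#' with the within-homopolymer index `k` (1-based).
#'
#' @param called_hpls Integer vector of called homopolymer lengths, in
#'   flow order.
#' @param nucleotides Character vector of the flowed nucleotides (same
#'   length), e.g. recycled from the flow order.
#' @param flow_index Optional flow indices (defaults to `0:(n-1)`).
#' @param read_id Read identifier carried through to the output.
#' @return An object of class `"called_read"`: list with `read_id`,
#'   `sequence`, `called_hpls`, and `base_to_flow` (data frame with
#'   0-based `base_pos`, `flow_index`, and `k`).
#' @export
assemble_read <- function(called_hpls, nucleotides,
                          flow_index = seq_along(called_hpls) - 1L,
                          read_id = "read") {
  called_hpls <- as.integer(called_hpls)
  stopifnot(length(nucleotides) == length(called_hpls),
            all(called_hpls >= 0L))
  pos <- called_hpls > 0L
  sequence <- paste(rep(nucleotides[pos], called_hpls[pos]), collapse = "")
  n_bases <- sum(called_hpls)
  base_to_flow <- data.frame(
    base_pos = seq_len(n_bases) - 1L,
    flow_index = rep(flow_index[pos], called_hpls[pos]),
    k = sequence(called_hpls[pos]),
    stringsAsFactors = FALSE)
  if (n_bases == 0L)
    base_to_flow <- data.frame(base_pos = integer(0), flow_index = integer(0),
                               k = integer(0))
  structure(list(read_id = read_id, sequence = sequence,
                 called_hpls = called_hpls, flow_index = flow_index,
                 nucleotides = nucleotides, base_to_flow = base_to_flow),
            class = "called_read")
}

#' @export
print.called_read <- function(x, ...) {
  cat(sprintf("Called read '%s': %d flows, %d bases\n", x$read_id,
              length(x$called_hpls), sum(x$called_hpls)))
  seq_show <- if (nchar(x$sequence) > 60)
    paste0(substr(x$sequence, 1, 57), "...") else x$sequence
  cat("  ", seq_show, "\n", sep = "")
  invisible(x)
}

#' Call, score and assemble all reads of a flow table
#'
#' The end-to-end calling step: predicts per-flow homopolymer-length
#' probabilities, calls each flow by maximum probability, assembles the
#' read sequences, and attaches per-base Phred-like scores plus the
#' per-position signed quality-score table.
#'
#' @param model A fitted [fit_hurdle_model()].
#' @param flows Flow table of the reads to call.
#' @return A list of class `"called_reads"`: one element per read, each a
#'   `"called_read"` augmented with `probs` (per-flow probability matrix),
#'   `phred` (integer per called base) and `qs_table` (per-position
#'   overcall/undercall/signed scores).
#' @export
call_reads <- function(model, flows) {
  pp <- predict_probabilities(model, flows)
  ids <- factor(pp$pred$read_id, levels = unique(pp$pred$read_id))
  rows <- split(seq_len(nrow(pp$probs)), ids)
  nuc <- flows$nucleotide
  out <- lapply(names(rows), function(id) {
    idx <- rows[[id]]
    probs <- pp$probs[idx, , drop = FALSE]
    called <- max.col(probs, ties.method = "first") - 1L
    rd <- assemble_read(called, nuc[idx],
                        flow_index = pp$pred$flow_index[idx], read_id = id)
    rd$probs <- probs
    rd$extrapolated <- pp$pred$extrapolated[idx]
    rd$phred <- phred_scores(rd, probs)
    rd$qs_table <- position_quality(rd, probs, n_max = model$n_max)
    rd
  })
  names(out) <- names(rows)
  class(out) <- "called_reads"
  out
}
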
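#' Configuration of the flow-data simulator
#'
#' The simulator emulates the noise structure of flow-cycle
#' pyrosequencing: a large excess of zero flows (a flow whose nucleotide
#' does not match the template yields only background optical noise),
#' approximately homopolymer-length-scaled flowgram values whose noise
#' grows with the length, and raw light intensities whose increase
#' attenuates at higher homopolymer lengths — which is what makes long
#' homopolymers progressively harder to call.
#'
#' Signal model: for a flow with true homopolymer length `n = 0`, the raw
#' intensity is `2^Normal(background_log2_mean, background_log2_sd)` and
#' the flowgram value is `|Normal(0, flowgram_noise_sd)|`; for `n >= 1`
#' the raw intensity is `signal_scale * n^attenuation * LogNormal(0,
#' signal_cv)` and the flowgram value is `n + Normal(0, flowgram_noise_sd
#' * sqrt(n))`, floored at 0.
#'
#' @param n_reads Number of reads.
#' @param read_length Template length in bases.
#' @param hpl_geometric_p Geometric parameter of the homopolymer-length
#'   law (support >= 1, mean `1/p`).
#' @param flow_order Four-letter nucleotide flow order.
#' @param signal_scale Raw-intensity scale `a` of a single incorporated
#'   nucleotide.
#' @param attenuation Exponent `gamma` in `(0, 1]`: raw signal grows as
#'   `a * n^gamma`, so the per-length increments shrink as `n` grows.
#' @param signal_cv Log-scale SD of the multiplicative noise on positive
#'   raw intensities.
#' @param background_log2_mean,background_log2_sd Location and SD of the
#'   log2 raw intensity of zero flows.
#' @param flowgram_noise_sd Flowgram noise SD at homopolymer length 1
#'   (scales with `sqrt(n)`).
#' @param max_flows Maximum number of flows per read (default: enough to
#'   sequence the whole template).
#' @param seed Integer seed; every read derives its own substream from it
#'   by counter, so simulated reads do not depend on generation order.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_reads = 100L, read_length = 60L,
                       hpl_geometric_p = 0.7, flow_order = "TACG",
                       signal_scale = 64, attenuation = 0.8,
                       signal_cv = 0.25, background_log2_mean = 5,
                       background_log2_sd = 0.7, flowgram_noise_sd = 0.1,
                       max_flows = NULL, seed = 1L) {
  stopifnot(n_reads >= 1, read_length >= 1,
            hpl_geometric_p > 0, hpl_geometric_p <= 1,
            signal_scale > 0, attenuation > 0, attenuation <= 1,
            signal_cv > 0, background_log2_sd > 0, flowgram_noise_sd > 0)
  check_flow_order(flow_order)
  structure(list(n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 hpl_geometric_p = hpl_geometric_p,
                 flow_order = toupper(flow_order),
                 signal_scale = signal_scale, attenuation = attenuation,
                 signal_cv = signal_cv,
                 background_log2_mean = background_log2_mean,
                 background_log2_sd = background_log2_sd,
                 flowgram_noise_sd = flowgram_noise_sd,
                 max_flows = max_flows, seed = as.integer(seed)),
            class = "sim_config")
}

# per-read RNG substream: derived by counter so read i is reproducible
# independently of how many reads are generated
read_seed <- function(seed, i, offset = 0L) {
  as.integer((as.double(seed) * 48271 + i * 16807 + offset) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Simulate reference sequences
#'
#' Homopolymer run lengths are i.i.d. geometric with support >= 1 and
#' parameter `hpl_geometric_p`; each run's nucleotide is drawn uniformly
#' among the three nucleotides different from the previous run. The
#' sequence is truncated to `read_length` bases.
#'
#' @param config A [sim_config()].
#' @return Character vector of `n_reads` sequences, named
#'   `read_00001, ...`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nucs <- c("T", "A", "C", "G")
  seqs <- vapply(seq_len(config$n_reads), function(i) {
    with_seed(read_seed(config$seed, i), {
      bases <- character(0)
      prev <- ""
      while (length(bases) < config$read_length) {
        len <- stats::rgeom(1, config$hpl_geometric_p) + 1L
        nuc <- sample(setdiff(nucs, prev), 1L)
        bases <- c(bases, rep(nuc, len))
        prev <- nuc
      }
      paste(bases[seq_len(config$read_length)], collapse = "")
    })
  }, character(1))
  names(seqs) <- sprintf("read_%05d", seq_len(config$n_reads))
  seqs
}

#' True homopolymer length per flow of a template
#'
#' Walks the flow order over the template: each flow consumes the maximal
#' run of its nucleotide at the template cursor (possibly of length 0) and
#' stops at the template end or after `max_flows` flows.
#'
#' @param sequence Template nucleotide string.
#' @param flow_order Four-letter flow order.
#' @param max_flows Maximum number of flows to emit.
#' @return Integer vector of true homopolymer lengths, one per flow.
#' @export
sequence_to_flows <- function(sequence, flow_order = "TACG",
                              max_flows = Inf) {
  check_flow_order(flow_order)
  stopifnot(nchar(sequence) > 0)
  runs <- rle(strsplit(toupper(sequence), "")[[1]])
  order4 <- strsplit(toupper(flow_order), "")[[1]]
  hpls <- integer(0)
  fi <- 0L
  for (r in seq_along(runs$lengths)) {
    while (order4[fi %% 4L + 1L] != runs$values[r]) {
      if (length(hpls) >= max_flows) return(hpls)
      hpls <- c(hpls, 0L)
      fi <- fi + 1L
    }
    if (length(hpls) >= max_flows) return(hpls)
    hpls <- c(hpls, runs$lengths[r])
    fi <- fi + 1L
  }
  hpls
}

#' Simulate flow signals for known homopolymer lengths
#'
#' @param true_hpls Integer vector of true homopolymer lengths.
#' @param config A [sim_config()] (signal parameters).
#' @param seed Seed for this call (defaults to the config seed).
#' @return Data frame with `flowgram` and `raw_intensity`, one row per
#'   flow.
#' @export
simulate_signals <- function(true_hpls, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), all(true_hpls >= 0))
  n <- length(true_hpls)
  with_seed(seed, {
    flowgram <- numeric(n)
    raw <- numeric(n)
    zero <- true_hpls == 0L
    n0 <- sum(zero)
    if (n0) {
      raw[zero] <- 2^stats::rnorm(n0, config$background_log2_mean,
                                  config$background_log2_sd)
      flowgram[zero] <- abs(stats::rnorm(n0, 0, config$flowgram_noise_sd))
    }
    if (n0 < n) {
      h <- true_hpls[!zero]
      raw[!zero] <- config$signal_scale * h^config$attenuation *
        exp(stats::rnorm(n - n0, 0, config$signal_cv))
      flowgram[!zero] <- pmax(h + stats::rnorm(n - n0, 0,
        config$flowgram_noise_sd * sqrt(h)), 0)
    }
    data.frame(flowgram = flowgram, raw_intensity = raw)
  })
}

#' Simulate a complete flow table with ground truth
#'
#' Draws reference sequences, converts them to per-flow true homopolymer
#' lengths, and attaches noisy flowgram and raw-intensity signals. The
#' result is a training- or evaluation-ready flow table.
#'
#' @param config A [sim_config()].
#' @return List with `flows` (a flow table data frame with `read_id`,
#'   `flow_index`, `cycle`, `nucleotide`, `flowgram`, `raw_intensity`,
#'   `ref_hpl`) and `truth` (the named reference sequences).
#' @export
simulate_flow_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seqs <- simulate_reference(config)
  order4 <- strsplit(config$flow_order, "")[[1]]
  max_flows <- if (is.null(config$max_flows)) Inf else config$max_flows
  tabs <- lapply(seq_along(seqs), function(i) {
    hpls <- sequence_to_flows(seqs[i], config$flow_order, max_flows)
    sig <- simulate_signals(hpls, config,
                            seed = read_seed(config$seed, i, offset = 1000000L))
    fi <- seq_along(hpls) - 1L
    data.frame(read_id = names(seqs)[i], flow_index = fi,
               cycle = fi %/% 4L, nucleotide = order4[fi %% 4L + 1L],
               flowgram = sig$flowgram, raw_intensity = sig$raw_intensity,
               ref_hpl = hpls, stringsAsFactors = FALSE)
  })
  flows <- do.call(rbind, tabs)
  rownames(flows) <- NULL
  list(flows = flows, truth = seqs)
}

#' Draw homopolymer counts from a specified hurdle model
#'
#' Model-based simulation for parameter-recovery experiments: draws the
#' zero/positive indicator from Bernoulli(`pi_fn(x)`) and positive counts
#' from the zero-truncated weighted Poisson by inverse-CDF on the
#' truncated probability table.
#'
#' @param pi_fn Function mapping the covariate vector to probabilities in
#'   (0, 1).
#' @param lambda_fn Function mapping the covariate vector to positive
#'   rates.
#' @param theta Dispersion weight parameter of the generative model.
#' @param covariates Numeric covariate vector (one value per flow).
#' @param seed Integer seed.
#' @param n_max Truncation bound of the inverse-CDF table.
#' @return Integer vector of simulated homopolymer counts.
#' @export
simulate_from_model <- function(pi_fn, lambda_fn, theta, covariates,
                                seed = 1L, n_max = 30L) {
  pi <- pi_fn(covariates)
  lam <- lambda_fn(covariates)
  stopifnot(all(pi >= 0 & pi <= 1), all(lam > 0))
  with_seed(seed, {
    n <- length(covariates)
    z <- stats::rbinom(n, 1L, pi)
    counts <- integer(n)
    pos <- z == 1L
    if (any(pos)) {
      lam_p <- lam[pos]
      P <- ztwp_matrix(lam_p, theta, n_max)
      P <- P / rowSums(P)
      cum <- t(apply(P, 1L, cumsum))
      cum <- cum / cum[, n_max]
      u <- stats::runif(sum(pos))
      counts[pos] <- 1L + rowSums(cum < u)
    }
    counts
  })
}
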
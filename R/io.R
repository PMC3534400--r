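#' Flow-table, model and read output files
#'
#' The ingestion format is a documented tab-separated flow table: one row
#' per flow with columns `read_id`, `flow_index` (0-based within read),
#' `cycle`, `nucleotide`, `flowgram`, `raw_intensity`, `ref_hpl` (`-1`
#' when unknown), preceded by `#`-comment header lines, one of which
#' declares the flow order (`#flow_order=TACG`). Vendor binary formats are
#' deliberately unsupported. Called reads are written as FASTA plus FASTQ
#' (Sanger Phred+33, scores clamped to `[0, 40]`), a per-flow probability
#' sidecar and a per-position quality-score sidecar (signed scores cannot
#' be carried by FASTQ).
#'
#' @name flow-io
NULL

PKG_VERSION <- function() as.character(utils::packageVersion("hurdlecall"))

# small FNV-1a hash so emitted files can carry a config fingerprint
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

file_header <- function(seed = NULL, config = NULL, extra = character()) {
  c(paste0("#tool=hurdlecall ", PKG_VERSION()),
    if (!is.null(seed)) paste0("#seed=", seed),
    if (!is.null(config)) paste0("#config_hash=", config_hash(config)),
    extra)
}

#' @describeIn flow-io Write a flow table (TSV with comment header).
#' @param flows Flow-table data frame.
#' @param path Output file path.
#' @param flow_order Flow order recorded in the header.
#' @param seed,config Optional provenance recorded in the header.
#' @export
write_flow_table <- function(flows, path, flow_order = "TACG",
                             seed = NULL, config = NULL) {
  check_flow_order(flow_order)
  cols <- c("read_id", "flow_index", "cycle", "nucleotide", "flowgram",
            "raw_intensity", "ref_hpl")
  if (!"ref_hpl" %in% names(flows)) flows$ref_hpl <- -1L
  flows$ref_hpl[is.na(flows$ref_hpl)] <- -1L
  miss <- setdiff(cols, names(flows))
  if (length(miss))
    stop("flow table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(file_header(seed, config),
               paste0("#flow_order=", toupper(flow_order))), con)
  utils::write.table(flows[cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @describeIn flow-io Read and validate a flow table.
#' @return `read_flow_table` returns the validated flow table (data
#'   frame, `ref_hpl = -1` mapped to `NA`) with the declared flow order in
#'   `attr(, "flow_order")`.
#' @export
read_flow_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  n_header <- match(FALSE, is_comment) - 1L
  if (is.na(n_header)) n_header <- length(lines)
  flow_order <- "TACG"
  fo_line <- grep("^#flow_order=", lines[seq_len(n_header)], value = TRUE)
  if (length(fo_line)) flow_order <- sub("^#flow_order=", "", fo_line[1])
  check_flow_order(flow_order)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  cols <- c("read_id", "flow_index", "cycle", "nucleotide", "flowgram",
            "raw_intensity", "ref_hpl")
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop("flow table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  # data row i sits on file line n_header + 1 (column header) + i
  line_no <- function(i) n_header + 1L + i
  order4 <- strsplit(toupper(flow_order), "")[[1]]
  expected <- order4[tab$flow_index %% 4L + 1L]
  bad <- which(toupper(tab$nucleotide) != expected)
  if (length(bad))
    stop("nucleotide/flow-order mismatch at line ", line_no(bad[1]),
         ": flow ", tab$flow_index[bad[1]], " should be ",
         expected[bad[1]], call. = FALSE)
  dup <- which(duplicated(tab[c("read_id", "flow_index")]))
  if (length(dup))
    stop("duplicate flow_index within read at line ", line_no(dup[1]),
         call. = FALSE)
  if (any(tab$flowgram < 0) || any(tab$raw_intensity <= 0))
    stop("flowgram must be >= 0 and raw_intensity > 0", call. = FALSE)
  tab$ref_hpl[tab$ref_hpl < 0] <- NA_integer_
  tab <- tab[order(match(tab$read_id, unique(tab$read_id)),
                   tab$flow_index), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "flow_order") <- toupper(flow_order)
  tab
}

format_prob <- function(p) sprintf("%.5e", pmax(p, PROB_FLOOR))

#' @describeIn flow-io Write called reads: `<prefix>.fasta`,
#'   `<prefix>.fastq`, `<prefix>.probs.tsv` (per-flow probability matrix,
#'   6 significant digits, floored at `1e-15`) and `<prefix>.qs.tsv`
#'   (per-position overcall/undercall/signed scores).
#' @param called_reads A [call_reads()] result.
#' @param prefix Output path prefix.
#' @export
write_outputs <- function(called_reads, prefix, seed = NULL, config = NULL) {
  seqs <- vapply(called_reads, `[[`, "", "sequence")
  ids <- vapply(called_reads, `[[`, "", "read_id")
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  Biostrings::writeXStringSet(dna, paste0(prefix, ".fasta"))
  quals <- lapply(called_reads, function(rd)
    pmin(pmax(rd$phred, 0L), QS_CAP))
  qual_strings <- vapply(quals, function(q)
    paste(intToUtf8(q + 33L, multiple = TRUE), collapse = ""), character(1))
  # suppress Biostrings' benign note about dropped metadata columns
  fq <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    dna, Biostrings::PhredQuality(unname(qual_strings))))
  Biostrings::writeQualityScaledXStringSet(fq, paste0(prefix, ".fastq"))

  header <- file_header(seed, config)
  # probability sidecar
  con <- file(paste0(prefix, ".probs.tsv"), "w")
  writeLines(header, con)
  n_max <- if (length(called_reads)) ncol(called_reads[[1]]$probs) - 1L else 0L
  writeLines(paste(c("read_id", "flow_index", "nucleotide", "called_hpl",
                     paste0("p", 0:n_max)), collapse = "\t"), con)
  for (rd in called_reads) {
    pm <- apply(rd$probs, 2L, format_prob)
    pm <- matrix(pm, nrow = nrow(rd$probs))
    writeLines(paste(rd$read_id, rd$flow_index, rd$nucleotides,
                     rd$called_hpls,
                     apply(pm, 1L, paste, collapse = "\t"),
                     sep = "\t"), con)
  }
  close(con)
  # quality-score sidecar
  con <- file(paste0(prefix, ".qs.tsv"), "w")
  writeLines(header, con)
  writeLines(paste(c("read_id", "flow_index", "k", "qs_overcall",
                     "qs_undercall", "qs_signed"), collapse = "\t"), con)
  for (rd in called_reads) {
    qt <- rd$qs_table
    writeLines(paste(qt$read_id, qt$flow_index, qt$k,
                     ifelse(is.na(qt$qs_overcall), "NA",
                            sprintf("%.3f", qt$qs_overcall)),
                     sprintf("%.3f", qt$qs_undercall), qt$qs_signed,
                     sep = "\t"), con)
  }
  close(con)
  invisible(paste0(prefix, c(".fasta", ".fastq", ".probs.tsv", ".qs.tsv")))
}

# --- model serialization ----------------------------------------------------

serialize_term <- function(tm) {
  out <- unclass(tm)
  out$penalty <- NULL  # reconstructed from penalty_order on read
  out
}

deserialize_term <- function(lst) {
  tm <- list(name = lst$name[[1]], type = lst$type[[1]])
  if (tm$type == "linear") {
    tm$center <- as.numeric(lst$center)
  } else {
    tm$knots <- as.numeric(unlist(lst$knots))
    tm$degree <- as.integer(lst$degree[[1]])
    tm$boundary <- as.numeric(unlist(lst$boundary))
    tm$penalty_order <- as.integer(lst$penalty_order[[1]])
    tm$colmeans <- as.numeric(unlist(lst$colmeans))
    k <- length(tm$colmeans)
    D <- diff(diag(k), differences = tm$penalty_order)
    tm$penalty <- crossprod(D)
  }
  structure(tm, class = "spline_term")
}

serialize_submodel <- function(fit) {
  list(coef = as.list(fit$coef), terms = lapply(fit$terms, serialize_term),
       link = fit$link, lambda_pen = fit$lambda_pen,
       converged = fit$converged, iterations = fit$iterations,
       penalized_loglik = fit$penalized_loglik, edf = fit$edf, n = fit$n)
}

deserialize_submodel <- function(lst) {
  coef <- vapply(lst$coef, as.numeric, numeric(1))
  structure(list(coef = coef,
                 terms = lapply(lst$terms, deserialize_term),
                 link = lst$link[[1]],
                 lambda_pen = as.numeric(lst$lambda_pen),
                 converged = isTRUE(lst$converged[[1]]),
                 iterations = as.integer(lst$iterations[[1]]),
                 penalized_loglik = as.numeric(lst$penalized_loglik),
                 edf = as.numeric(lst$edf), n = as.integer(lst$n[[1]])),
            class = "hurdle_gam")
}

#' @describeIn flow-io Serialize a fitted model to a versioned JSON
#'   document (full double precision; round-trips bit-exactly).
#' @param model A fitted [fit_hurdle_model()].
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "hurdle_model"))
  doc <- list(format = "hurdlecall-model", version = 1L,
              tool_version = PKG_VERSION(),
              theta = model$theta, n_max = model$n_max,
              feature_config = unclass(model$feature_config),
              binomial = serialize_submodel(model$binomial),
              poisson = serialize_submodel(model$poisson),
              theta_profile = model$theta_profile,
              training_summary = model$training_summary)
  # I(17) significant digits: IEEE doubles survive the text round trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @describeIn flow-io Read a serialized model back.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "hurdlecall-model"))
    stop("not a hurdlecall model file: ", path, call. = FALSE)
  fc <- doc$feature_config
  config <- feature_config(binomial = unlist(fc$binomial),
                           poisson = unlist(fc$poisson),
                           normalize_raw = isTRUE(fc$normalize_raw[[1]]),
                           flow_order = fc$flow_order[[1]])
  ts <- doc$training_summary
  ts <- list(n_flows = as.integer(ts$n_flows[[1]]),
             n_reads = as.integer(ts$n_reads[[1]]),
             n_positive = as.integer(ts$n_positive[[1]]),
             max_ref_hpl = as.integer(ts$max_ref_hpl[[1]]),
             covariate_ranges = lapply(ts$covariate_ranges,
                                       function(r) as.numeric(unlist(r))))
  profile <- data.frame(
    theta = vapply(doc$theta_profile, function(r) as.numeric(r$theta),
                   numeric(1)),
    penalized_loglik = vapply(doc$theta_profile,
                              function(r) as.numeric(r$penalized_loglik),
                              numeric(1)))
  structure(list(binomial = deserialize_submodel(doc$binomial),
                 poisson = deserialize_submodel(doc$poisson),
                 theta = as.numeric(doc$theta),
                 theta_profile = profile,
                 n_max = as.integer(doc$n_max[[1]]), feature_config = config,
                 training_summary = ts),
            class = "hurdle_model")
}
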
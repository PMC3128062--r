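# Information-profile post-processing: low-pass smoothing for display and
# TSV / bedGraph / JSON export.

#' Smooth an information profile
#'
#' Moving average of odd window `window`. Away from the edges this is the
#' plain centred moving average; at the edges each observation's unit weight
#' is renormalised over the positions whose windows reach it
#' (a column-stochastic smoother), so the global mean of the profile is
#' preserved exactly -- the smoothed track integrates to the same total bits
#' as the raw one. `window = 1` is the identity.
#'
#' @param bits Numeric vector of per-base bits.
#' @param window Odd positive window length.
#' @return Numeric vector, same length as `bits`.
#' @export
smooth_profile <- function(bits, window = 2001L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  n <- length(bits)
  if (window == 1L || n == 0L) return(as.numeric(bits))
  h <- (window - 1L) %/% 2L
  idx <- seq_len(n)
  # c[j] = number of positions whose window covers j (truncated at the edges)
  cov <- pmin(idx + h, n) - pmax(idx - h, 1L) + 1L
  y <- bits / cov
  cs <- c(0, cumsum(y))
  cs[pmin(idx + h, n) + 1L] - cs[pmax(idx - h, 1L)]
}

#' Write a per-base profile as TSV
#'
#' Columns: `position` (1-based original coordinate), `bits`, `chosen_depth`.
#' With several records a leading `record_id` column is added.
#'
#' @param results A `RunResult` or list of them.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_profile_tsv <- function(results, file) {
  if (inherits(results, "RunResult")) results <- list(results)
  tabs <- lapply(results, function(r)
    cbind(record_id = r$record_id, r$profile))
  out <- do.call(rbind, tabs)
  if (length(results) == 1L) out$record_id <- NULL
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a smoothed profile as bedGraph
#'
#' Standard 0-based half-open intervals, one line per base, value = smoothed
#' bits. Coordinates refer to the original (unfiltered) sequence.
#'
#' @param result A `RunResult`.
#' @param file Output path.
#' @param window Smoothing window passed to [smooth_profile()].
#' @param track_name Track name written in the header line.
#' @return `file`, invisibly.
#' @export
write_bedgraph <- function(result, file, window = 2001L,
                           track_name = "information_bpb") {
  stopifnot(inherits(result, "RunResult"))
  sm <- smooth_profile(result$profile$bits, window)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', track_name), con)
  pos <- result$profile$position
  chrom <- if (nzchar(result$record_id)) result$record_id else "seq"
  chrom <- strsplit(chrom, "[[:space:]]+")[[1]][1]
  writeLines(sprintf("%s\t%d\t%d\t%.6f", chrom, pos - 1L, pos, sm), con)
  invisible(file)
}

#' Summarise one or more runs as a JSON-ready list
#'
#' @param results A `RunResult` or list of them.
#' @param cfg The [competition_config()] the runs used (embedded verbatim for
#'   reproducibility).
#' @return A list with per-record entries and overall totals
#'   (`symbol_bits`, `side_bits`, `modeled_bases`, `bpb`, depth histogram).
#' @export
run_summary <- function(results, cfg = NULL) {
  if (inherits(results, "RunResult")) results <- list(results)
  per_record <- lapply(results, function(r) {
    hist <- table(factor(r$blocks$chosen_depth,
                         levels = sort(unique(r$profile$chosen_depth))))
    list(record_id = r$record_id,
         modeled_bases = r$modeled_bases,
         symbol_bits = r$symbol_bits,
         side_bits = r$side_bits,
         bpb = r$bpb,
         depth_histogram = as.list(hist))
  })
  tot_sym <- sum(vapply(results, `[[`, 0, "symbol_bits"))
  tot_side <- sum(vapply(results, `[[`, 0, "side_bits"))
  tot_n <- sum(vapply(results, `[[`, 0, "modeled_bases"))
  out <- list(
    records = per_record,
    totals = list(symbol_bits = tot_sym, side_bits = tot_side,
                  modeled_bases = tot_n,
                  bpb = if (tot_n > 0) (tot_sym + tot_side) / tot_n else 0))
  if (!is.null(cfg)) out$config <- unclass(cfg)
  out
}
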
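# Block-wise competition among finite-context models of different orders.
# All models scan the sequence in one pass and all of them update their
# counters at every symbol (direct + inverted-repeat); selection is purely an
# accounting decision per fixed-size block, so it never alters the counts.

#' Configuration for the multi-model engine
#'
#' Defaults follow the whole-genome setup: eight competing models with orders
#' up to 16, 200-base blocks, Laplace pseudocounts for shallow models and
#' `alpha = 1/16` for deep ones, and an adaptive order-4 side model coding
#' the per-block depth indices.
#'
#' @param depths Strictly increasing model orders.
#' @param block_size Block length in retained bases.
#' @param alpha_low Pseudocount for orders below `alpha_threshold`.
#' @param alpha_high Pseudocount for orders at or above `alpha_threshold`.
#' @param alpha_threshold Smallest order treated as "high".
#' @param side_order Context order of the depth-index side model.
#' @param side_alpha Pseudocount of the side model.
#' @param use_ir Apply inverted-repeat count updates.
#' @param hash_threshold Largest order stored densely (see [fcm_model()]).
#' @return A `CompetitionConfig`.
#' @export
competition_config <- function(depths = c(2L, 4L, 6L, 8L, 10L, 12L, 14L, 16L),
                               block_size = 200L,
                               alpha_low = 1,
                               alpha_high = 1 / 16,
                               alpha_threshold = 12L,
                               side_order = 4L,
                               side_alpha = 1,
                               use_ir = TRUE,
                               hash_threshold = 10L) {
  depths <- as.integer(depths)
  if (length(depths) == 0L || any(diff(depths) <= 0L) || any(depths < 1L))
    stop("depths must be a non-empty strictly increasing vector of orders >= 1")
  if (block_size < 1L) stop("block_size must be >= 1")
  if (alpha_low <= 0 || alpha_high <= 0 || side_alpha <= 0)
    stop("pseudocounts must be > 0")
  structure(
    list(depths = depths, block_size = as.integer(block_size),
         alpha_low = alpha_low, alpha_high = alpha_high,
         alpha_threshold = as.integer(alpha_threshold),
         side_order = as.integer(side_order), side_alpha = side_alpha,
         use_ir = isTRUE(use_ir), hash_threshold = as.integer(hash_threshold)),
    class = "CompetitionConfig")
}

#' @export
print.CompetitionConfig <- function(x, ...) {
  cat("CompetitionConfig\n")
  cat("  depths:        ", paste(x$depths, collapse = " "), "\n")
  cat("  block size:    ", x$block_size, "bases\n")
  cat(sprintf("  alpha:          %g below order %d, %g from it up\n",
              x$alpha_low, x$alpha_threshold, x$alpha_high))
  cat(sprintf("  side model:     order %d, alpha %g\n", x$side_order, x$side_alpha))
  cat("  inverted reps: ", if (x$use_ir) "on" else "off", "\n")
  invisible(x)
}

#' Pseudocount assigned to a model order under a configuration's policy
#'
#' @param depth Model order.
#' @param cfg A [competition_config()].
#' @return The pseudocount value.
#' @export
alpha_for_depth <- function(depth, cfg = competition_config()) {
  ifelse(depth >= cfg$alpha_threshold, cfg$alpha_high, cfg$alpha_low)
}

result_of <- function(seq, profile, chosen_depth_per_base, blocks,
                      symbol_bits, side_bits) {
  n <- length(seq$codes)
  bpb <- if (n > 0L) (symbol_bits + side_bits) / n else 0
  structure(
    list(record_id = seq$record_id,
         profile = data.frame(position = seq$positions,
                              bits = profile,
                              chosen_depth = chosen_depth_per_base),
         blocks = blocks,
         symbol_bits = symbol_bits, side_bits = side_bits,
         modeled_bases = n, bpb = bpb),
    class = "RunResult")
}

#' @export
print.RunResult <- function(x, ...) {
  cat(sprintf("RunResult '%s': %d bases, %.1f symbol bits + %.1f side bits = %.4f bpb\n",
              x$record_id, x$modeled_bases, x$symbol_bits, x$side_bits, x$bpb))
  invisible(x)
}

#' Run the multiple competing models over one sequence
#'
#' Performs a single left-to-right pass. At every symbol each configured
#' model emits `-log2 p` from its own adaptively updated counts, then every
#' model's counters advance (direct and inverted-repeat updates) regardless
#' of which model wins. At each block boundary the accumulated per-model
#' block costs pick the winner (ties go to the lowest order); the winner's
#' per-symbol bits become the block's slice of the information profile. The
#' final partial block competes like any other. The depth-index sequence is
#' priced by the adaptive side model and included in `bpb`.
#'
#' @param seq A `FilteredSequence` (or DNA string / code vector).
#' @param cfg A [competition_config()].
#' @return A `RunResult` with elements `profile` (position, bits,
#'   chosen_depth), `blocks` (per-block chosen depth, block length, cost of
#'   every model), `symbol_bits`, `side_bits`, `modeled_bases`, and
#'   `bpb = (symbol_bits + side_bits) / modeled_bases`.
#' @examples
#' run_multi("ACGTACGTACGTACGT", competition_config(depths = c(1, 2), block_size = 8))
#' @export
run_multi <- function(seq, cfg = competition_config()) {
  seq <- as_filtered(seq)
  if (length(seq$codes) == 0L) {
    blocks <- data.frame(block_index = integer(), chosen = integer(),
                         chosen_depth = integer(), block_len = integer(),
                         symbol_bits = numeric())
    return(result_of(seq, numeric(), integer(), blocks, 0, 0))
  }
  alphas <- alpha_for_depth(cfg$depths, cfg)
  r <- cpp_run_multi(seq$codes, cfg$depths, alphas, cfg$block_size,
                     cfg$side_order, cfg$side_alpha, cfg$use_ir,
                     cfg$hash_threshold, TRUE)
  chosen <- r$chosen + 1L  # 1-based index into depths
  costs <- r$block_costs
  colnames(costs) <- paste0("k", cfg$depths)
  blocks <- data.frame(block_index = seq_along(chosen),
                       chosen = chosen,
                       chosen_depth = cfg$depths[chosen],
                       block_len = r$block_len,
                       symbol_bits = costs[cbind(seq_along(chosen), chosen)])
  blocks <- cbind(blocks, as.data.frame(costs))
  depth_track <- rep(cfg$depths[chosen], times = r$block_len)
  result_of(seq, r$profile, depth_track, blocks, r$symbol_bits, r$side_bits)
}

#' Run a single finite-context model over one sequence
#'
#' One model, no blocks, no side channel; `bpb` is the plain per-base average
#' of the information contents.
#'
#' @param seq A `FilteredSequence` (or DNA string / code vector).
#' @param depth Model order.
#' @param alpha Pseudocount; defaults to the standard policy for `depth`.
#' @param use_ir Apply inverted-repeat updates.
#' @param hash_threshold See [fcm_model()].
#' @return A `RunResult` (with `side_bits = 0` and a single pseudo-block).
#' @export
run_single <- function(seq, depth, alpha = NULL, use_ir = TRUE,
                       hash_threshold = 10L) {
  seq <- as_filtered(seq)
  depth <- as.integer(depth)
  if (is.null(alpha)) alpha <- alpha_for_depth(depth, competition_config())
  if (length(seq$codes) == 0L) {
    blocks <- data.frame(block_index = integer(), chosen = integer(),
                         chosen_depth = integer(), block_len = integer(),
                         symbol_bits = numeric())
    return(result_of(seq, numeric(), integer(), blocks, 0, 0))
  }
  r <- cpp_run_single(seq$codes, depth, alpha, isTRUE(use_ir),
                      as.integer(hash_threshold))
  n <- length(seq$codes)
  blocks <- data.frame(block_index = 1L, chosen = 1L, chosen_depth = depth,
                       block_len = n, symbol_bits = r$symbol_bits)
  result_of(seq, r$profile, rep(depth, n), blocks, r$symbol_bits, 0)
}

#' Best single model for one sequence
#'
#' Runs [run_single()] for every configured depth, with each depth's
#' pseudocount from the configuration's policy, and returns the minimum-bpb
#' run (ties go to the lowest order). This is the per-record "single model,
#' best order" baseline against which the competing-models engine is judged.
#'
#' @param seq A `FilteredSequence` (or DNA string / code vector).
#' @param cfg A [competition_config()].
#' @return A list with `depth`, `result` (the winning `RunResult`), and
#'   `bpb_by_depth` (named numeric vector over all configured depths).
#' @export
best_single <- function(seq, cfg = competition_config()) {
  seq <- as_filtered(seq)
  runs <- lapply(cfg$depths, function(d)
    run_single(seq, d, alpha = alpha_for_depth(d, cfg), use_ir = cfg$use_ir,
               hash_threshold = cfg$hash_threshold))
  bpbs <- vapply(runs, function(r) r$bpb, numeric(1))
  names(bpbs) <- paste0("k", cfg$depths)
  best <- which.min(bpbs)  # which.min takes the first minimum: lowest depth
  list(depth = cfg$depths[best], result = runs[[best]], bpb_by_depth = bpbs)
}

#' Code length of a depth-choice sequence under the side model
#'
#' Prices a sequence of per-block model choices with the adaptive
#' order-`side_order` finite-context model over the index alphabet
#' (pseudocount `side_alpha`, warm-up context of index 1). The first choice,
#' with no history, costs exactly `log2(length(depths))` bits.
#'
#' @param choices Integer vector of 1-based indices into `cfg$depths`.
#' @param cfg A [competition_config()].
#' @return Total code length in bits.
#' @export
side_channel_bits <- function(choices, cfg = competition_config()) {
  choices <- as.integer(choices)
  D <- length(cfg$depths)
  if (length(choices) && (min(choices) < 1L || max(choices) > D))
    stop("choice indices must lie in 1..", D)
  cpp_side_bits(choices - 1L, D, cfg$side_order, cfg$side_alpha)
}
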
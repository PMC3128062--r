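# The order-k finite-context model: count storage, pseudocount estimator,
# direct and inverted-repeat updates, per-symbol information content.
#
# Count storage is dense (4^k rows) up to `hash_threshold` and hash-backed
# above it; both give bit-identical estimates. Counters are 64-bit and never
# rescaled: genome-scale counts cannot overflow them.

#' Create a finite-context model
#'
#' An order-`k` Markov model over the DNA alphabet. Probabilities follow the
#' pseudocount estimator `p(s|c) = (n(s|c) + alpha) / (N(c) + 4 alpha)`,
#' a linear interpolation between the maximum-likelihood estimate and the
#' uniform distribution with weight `lambda = N / (N + 4 alpha)`.
#'
#' @param k Model order (number of conditioning bases), `>= 1`.
#' @param alpha Pseudocount, `> 0`. `alpha = 1` is Laplace's rule; small
#'   values sharpen deep-context estimates.
#' @param hash_threshold Largest order stored as a dense table; deeper models
#'   use a hash map keyed by the packed context.
#' @return An object of class `FCModel`.
#' @examples
#' m <- fcm_model(5, alpha = 1)
#' fcm_estimate(m, "ATAGA")
#' @export
fcm_model <- function(k, alpha = 1, hash_threshold = 10L) {
  stopifnot(k >= 1, alpha > 0)
  structure(
    list(ptr = cpp_fcm_create(as.integer(k), alpha, as.integer(hash_threshold)),
         k = as.integer(k), alpha = alpha,
         dense = k <= hash_threshold),
    class = "FCModel")
}

#' @export
print.FCModel <- function(x, ...) {
  cat(sprintf("FCModel: order %d, alpha %g, %s storage\n",
              x$k, x$alpha, if (x$dense) "dense" else "hash"))
  invisible(x)
}

as_context <- function(model, context) {
  ctx <- if (is.character(context)) dna_to_codes(context) else as.integer(context)
  if (length(ctx) != model$k)
    stop("context length must equal the model order (", model$k, ")")
  ctx
}

#' Probability estimates for the next symbol
#'
#' @param model An `FCModel`.
#' @param context The conditioning context: a DNA string of length `k` or an
#'   integer vector of symbol codes (oldest base first).
#' @return Named numeric vector of four probabilities (A, C, G, T) summing
#'   to 1; unseen contexts give the uniform distribution.
#' @export
fcm_estimate <- function(model, context) {
  p <- cpp_fcm_probs(model$ptr, as_context(model, context))
  names(p) <- DNA_LETTERS
  p
}

#' Read the counters of one context row
#'
#' @inheritParams fcm_estimate
#' @return Named numeric vector `n(s|c)` for A, C, G, T.
#' @export
fcm_counts <- function(model, context) {
  n <- cpp_fcm_counts(model$ptr, as_context(model, context))
  names(n) <- DNA_LETTERS
  n
}

#' Overwrite the counters of one context row
#'
#' Mainly used to reproduce worked examples and to seed models in tests.
#'
#' @inheritParams fcm_estimate
#' @param counts Numeric vector of four non-negative counts (A, C, G, T).
#' @export
fcm_set_counts <- function(model, context, counts) {
  cpp_fcm_set_counts(model$ptr, as_context(model, context), as.numeric(counts))
  invisible(model)
}

#' Record one observed symbol
#'
#' Increments `n(s|c)`. With `use_ir = TRUE` the counter addressed by
#' [ir_counterpart()] is incremented too, so inverted repeats reinforce the
#' same table; when the two addresses coincide (reverse-complement
#' palindromes) the row is incremented twice, by design.
#'
#' @inheritParams fcm_estimate
#' @param symbol The observed symbol: one of `"A","C","G","T"` or a code 0..3.
#' @param use_ir Also apply the inverted-repeat update.
#' @export
fcm_update <- function(model, context, symbol, use_ir = TRUE) {
  s <- if (is.character(symbol)) dna_to_codes(symbol) else as.integer(symbol)
  stopifnot(length(s) == 1L)
  cpp_fcm_update(model$ptr, as_context(model, context), s, isTRUE(use_ir))
  invisible(model)
}

#' Inverted-repeat counterpart of a (context, symbol) pair
#'
#' Appends `symbol` to `context`, reverse-complements the resulting
#' `(k+1)`-mer, and splits it back into a length-`k` context and a final
#' symbol. Applying the map twice returns the original pair.
#'
#' @param context DNA string or integer codes (oldest base first).
#' @param symbol Single base or code.
#' @return A list with elements `context` and `symbol`, in the same
#'   representation (string or codes) as the input.
#' @examples
#' ir_counterpart("ATAGA", "C")  # context "GTCTA", symbol "T"
#' @export
ir_counterpart <- function(context, symbol) {
  str_in <- is.character(context)
  ctx <- if (str_in) dna_to_codes(context) else as.integer(context)
  s <- if (is.character(symbol)) dna_to_codes(symbol) else as.integer(symbol)
  r <- cpp_ir_counterpart(ctx, s)
  if (str_in)
    list(context = codes_to_dna(r$context), symbol = codes_to_dna(r$symbol))
  else r
}

#' Shift a context register
#'
#' Drops the oldest symbol and appends a new one, as the model does while
#' scanning a sequence.
#'
#' @param context DNA string or integer codes (oldest first).
#' @param symbol Base or code to push.
#' @return The new context, same representation as the input.
#' @export
shift_context <- function(context, symbol) {
  if (is.character(context)) {
    s <- if (is.character(symbol)) symbol else codes_to_dna(symbol)
    return(paste0(substr(context, 2L, nchar(context)), s))
  }
  s <- if (is.character(symbol)) dna_to_codes(symbol) else as.integer(symbol)
  c(context[-1L], s)
}

#' Pack a context into its integer register value
#'
#' Two bits per symbol, most recent symbol in the lowest bits. Exact for
#' orders up to 24 (the value is returned as a double).
#'
#' @param context DNA string or integer codes (oldest first).
#' @return The packed value, in `[0, 4^k)`.
#' @export
pack_context <- function(context) {
  ctx <- if (is.character(context)) dna_to_codes(context) else as.integer(context)
  cpp_pack_context(ctx)
}

#' Information content of an observed symbol
#'
#' `-log2 p(s)`, in bits. Accumulated over a sequence and divided by its
#' length this is the model's bits-per-base (bpb) figure; 2 bpb is the
#' uniform-model baseline on a four-letter alphabet.
#'
#' @param p Probability vector as returned by [fcm_estimate()].
#' @param symbol Observed base or code.
#' @return Code length in bits.
#' @export
info_content <- function(p, symbol) {
  s <- if (is.character(symbol)) dna_to_codes(symbol) else as.integer(symbol)
  stopifnot(length(s) == 1L, s %in% 0:3)
  -log2(p[[s + 1L]])
}
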
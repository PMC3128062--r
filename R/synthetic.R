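# Seeded fixture generator. Emulates the statistical structure the method
# exploits -- alternation of high-entropy (iid / Markov) stretches with
# low-entropy material (exact and inverted repeats) -- without pretending to
# be a genome simulator.

#' Segment descriptors for synthetic fixtures
#'
#' Building blocks for [fixture_spec()]. `seg_iid` draws independent bases
#' from `probs`; `seg_markov` draws from an order-`order` chain with the
#' given transition table (rows indexed by packed context, columns A,C,G,T);
#' `seg_repeat` copies an earlier segment verbatim and
#' `seg_inverted_repeat` copies its reverse complement. Copy segments recycle
#' or truncate the source to the requested length.
#'
#' @param length Segment length in bases.
#' @param probs Base probabilities (A, C, G, T), summing to 1.
#' @param order Markov order of the segment's generator.
#' @param table `4^order x 4` stochastic matrix of conditional probabilities.
#' @param of 1-based index of the segment being copied (must precede).
#' @name segments
NULL

#' @rdname segments
#' @export
seg_iid <- function(length, probs = rep(0.25, 4)) {
  stopifnot(length >= 1, length(probs) == 4, all(probs >= 0),
            abs(sum(probs) - 1) < 1e-9)
  list(kind = "iid", length = as.integer(length), probs = probs)
}

#' @rdname segments
#' @export
seg_markov <- function(length, order, table) {
  stopifnot(length >= 1, order >= 1)
  table <- as.matrix(table)
  if (nrow(table) != 4^order || ncol(table) != 4)
    stop("transition table must be 4^order x 4")
  if (any(table < 0) || any(abs(rowSums(table) - 1) > 1e-9))
    stop("transition table rows must be probability distributions")
  list(kind = "markov", length = as.integer(length), order = as.integer(order),
       table = table)
}

#' @rdname segments
#' @export
seg_repeat <- function(length, of) {
  stopifnot(length >= 1, of >= 1)
  list(kind = "repeat_copy", length = as.integer(length), of = as.integer(of))
}

#' @rdname segments
#' @export
seg_inverted_repeat <- function(length, of) {
  stopifnot(length >= 1, of >= 1)
  list(kind = "inverted_repeat_copy", length = as.integer(length),
       of = as.integer(of))
}

#' Specify a synthetic fixture
#'
#' @param segments List of segment descriptors (see [segments]).
#' @param seed Integer seed; the same spec always yields the same sequence.
#' @return A `FixtureSpec`.
#' @export
fixture_spec <- function(segments, seed) {
  stopifnot(is.list(segments), length(segments) >= 1)
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    if (!is.list(s) || is.null(s$kind))
      stop("segment ", i, " is not a segment descriptor")
    if (s$kind %in% c("repeat_copy", "inverted_repeat_copy") && s$of >= i)
      stop("segment ", i, " must reference an earlier segment")
  }
  structure(list(segments = segments, seed = as.integer(seed)),
            class = "FixtureSpec")
}

#' Random stochastic transition table
#'
#' Rows are independent symmetric-Dirichlet draws; small `concentration`
#' gives skewed (low-entropy) rows, large gives near-uniform rows.
#'
#' @param order Markov order (rows are the `4^order` packed contexts).
#' @param concentration Dirichlet concentration parameter per cell.
#' @return A `4^order x 4` stochastic matrix.
#' @export
random_transition_table <- function(order, concentration = 0.5) {
  g <- matrix(rgamma(4^order * 4, shape = concentration), ncol = 4)
  g / rowSums(g)
}

#' Analytic entropy rate of an order-k Markov source
#'
#' Computes the stationary distribution over packed contexts (power iteration
#' on the lazy chain, which converges for periodic chains too) and returns
#' `sum_c pi(c) H(p(. | c))` in bits per symbol. Used as the independent
#' oracle for model-recovery tests.
#'
#' @param table `4^order x 4` stochastic matrix.
#' @param order Markov order.
#' @return Entropy rate in bits per symbol.
#' @examples
#' entropy_rate(matrix(0.25, 4, 4), 1)  # exactly 2
#' @export
entropy_rate <- function(table, order) {
  table <- as.matrix(table)
  S <- 4^order
  if (nrow(table) != S || ncol(table) != 4)
    stop("transition table must be 4^order x 4")
  if (any(table < 0) || any(abs(rowSums(table) - 1) > 1e-9))
    stop("transition table rows must be probability distributions")
  # next packed state when symbol s is emitted from state c: (4c + s) mod 4^k
  states <- 0:(S - 1)
  ns <- outer(states, 0:3, function(c, s) (4 * c + s) %% S) + 1L
  pi_ <- rep(1 / S, S)
  for (it in 1:20000) {
    step <- numeric(S)
    for (s in 1:4) {
      contrib <- pi_ * table[, s]
      add <- rowsum(contrib, ns[, s])
      idx <- as.integer(rownames(add))
      step[idx] <- step[idx] + add[, 1]
    }
    pin <- 0.5 * pi_ + 0.5 * step  # lazy chain: same stationary distribution
    if (max(abs(pin - pi_)) < 1e-13) { pi_ <- pin; break }
    pi_ <- pin
  }
  hrow <- -rowSums(ifelse(table > 0, table * log2(table), 0))
  sum(pi_ * hrow)
}

rc_codes <- function(codes) rev(3L - codes)

recycle_to <- function(codes, n) {
  if (length(codes) == 0L) stop("copy segment references an empty segment")
  rep_len(codes, n)
}

#' Generate a synthetic fixture
#'
#' Deterministic given the spec's seed (the caller's RNG state is saved and
#' restored). Markov segments start from the last `order` emitted bases
#' (A-padded at the very start, matching the engine's warm-up convention).
#'
#' @param spec A [fixture_spec()].
#' @return A list with `seq` (a `FilteredSequence`) and `annotation`, a
#'   BED-like data frame with one row per segment: `segment`, `kind`,
#'   `start`, `end` (1-based, inclusive) and `entropy` (bits/symbol where
#'   analytically defined, `NA` for copy segments).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  parts <- vector("list", length(spec$segments))
  entropies <- rep(NA_real_, length(spec$segments))
  emitted <- integer(0)
  for (i in seq_along(spec$segments)) {
    s <- spec$segments[[i]]
    seg <- switch(s$kind,
      iid = {
        entropies[i] <- -sum(ifelse(s$probs > 0, s$probs * log2(s$probs), 0))
        sample.int(4L, s$length, replace = TRUE, prob = s$probs) - 1L
      },
      markov = {
        entropies[i] <- entropy_rate(s$table, s$order)
        gen_markov(s$length, s$order, s$table, emitted)
      },
      repeat_copy = recycle_to(parts[[s$of]], s$length),
      inverted_repeat_copy = recycle_to(rc_codes(parts[[s$of]]), s$length),
      stop("unknown segment kind: ", s$kind))
    parts[[i]] <- seg
    emitted <- c(emitted, seg)
  }
  lens <- lengths(parts)
  ends <- cumsum(lens)
  annotation <- data.frame(
    segment = seq_along(parts),
    kind = vapply(spec$segments, `[[`, "", "kind"),
    start = ends - lens + 1L,
    end = ends,
    entropy = entropies)
  list(seq = as_filtered(unlist(parts), record_id = sprintf("fixture_seed%d", spec$seed)),
       annotation = annotation)
}

gen_markov <- function(n, order, table, history) {
  S <- 4^order
  cum <- t(apply(table, 1L, cumsum))
  ctx <- 0L
  warm <- c(rep(0L, max(0L, order - length(history))), tail(history, order))
  for (b in warm) ctx <- (4L * ctx + b) %% S
  out <- integer(n)
  u <- runif(n)
  for (i in seq_len(n)) {
    s <- findInterval(u[i], cum[ctx + 1L, ], left.open = TRUE)  # in 0..3
    if (s > 3L) s <- 3L  # guard against rounding at the top edge
    out[i] <- s
    ctx <- (4L * ctx + s) %% S
  }
  out
}
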
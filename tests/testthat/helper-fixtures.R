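# Shared fixture builders and independent oracles. All fixtures are generated
# in code under fixed seeds; nothing is read from disk.

fx_iid <- function(n, seed) {
  generate_fixture(fixture_spec(list(seg_iid(n)), seed = seed))$seq
}

fx_markov <- function(n, order, seed, concentration = 0.5) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  tab <- random_transition_table(order, concentration)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  fx <- generate_fixture(fixture_spec(list(seg_markov(n, order, tab)),
                                      seed = seed + 1L))
  list(seq = fx$seq, table = tab, order = order,
       entropy = fx$annotation$entropy[1])
}

# iid background with an exact late copy of its start (direct repeat)
fx_repeat <- function(n_bg = 50000L, n_rep = 20000L, seed = 11L) {
  generate_fixture(fixture_spec(list(seg_iid(n_bg), seg_repeat(n_rep, of = 1L)),
                                seed = seed))
}

# first half iid, second half the reverse complement of the first
fx_ircopy <- function(n_half = 20000L, seed = 12L) {
  generate_fixture(fixture_spec(
    list(seg_iid(n_half), seg_inverted_repeat(n_half, of = 1L)), seed = seed))
}

# independent string-level reverse-complement oracle (no packed arithmetic)
rc_string <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

random_codes <- function(n) sample.int(4L, n, replace = TRUE) - 1L

write_temp_fasta <- function(lines) {
  fa <- tempfile(fileext = ".fa")
  writeLines(lines, fa)
  fa
}
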
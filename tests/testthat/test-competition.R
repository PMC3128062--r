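# Block-wise competition engine, side channel, single-model baseline.

test_that("competition with a single depth degenerates to the single model", {
  seq <- fx_iid(5000, 3)
  cfg <- competition_config(depths = 6L, block_size = 200L)
  multi <- run_multi(seq, cfg)
  single <- run_single(seq, 6L, alpha = alpha_for_depth(6L, cfg))
  expect_true(all(multi$blocks$chosen_depth == 6L))
  expect_equal(multi$symbol_bits, single$symbol_bits, tolerance = 1e-12)
  expect_equal(multi$side_bits, 0)  # one-symbol index alphabet costs nothing
})

test_that("blocks partition the sequence, final partial block included", {
  seq <- fx_iid(450, 4)
  r <- run_multi(seq, competition_config(depths = c(2L, 4L), block_size = 200L))
  expect_equal(r$blocks$block_len, c(200L, 200L, 50L))
  expect_equal(sum(r$blocks$block_len), r$modeled_bases)
})

test_that("empty sequence yields an empty result with zero totals", {
  r <- run_multi(filter_sequence(""))
  expect_equal(r$modeled_bases, 0L)
  expect_equal(r$symbol_bits, 0)
  expect_equal(r$side_bits, 0)
  expect_equal(nrow(r$blocks), 0L)
  expect_equal(r$bpb, 0)
})

test_that("iid uniform sequences cost about 2 bpb under the default engine", {
  for (seed in 1:5) {
    r <- run_multi(fx_iid(100000, seed), competition_config())
    expect_gt(r$symbol_bits / r$modeled_bases, 1.95)
    expect_lt(r$symbol_bits / r$modeled_bases, 2.05)
  }
})

test_that("side channel prices choice streams as an adaptive model should", {
  cfg <- competition_config()  # 8 depths
  expect_equal(side_channel_bits(1L, cfg), 3)       # log2(8) with no history
  expect_lt(side_channel_bits(rep(4L, 1000), cfg), 100)  # constant stream
  set.seed(9)
  rnd <- sample.int(8L, 10000, replace = TRUE)
  expect_equal(side_channel_bits(rnd, cfg) / 10000, 3, tolerance = 0.02)
  expect_error(side_channel_bits(c(1L, 9L), cfg), "1..8")
})

test_that("run_single handles sequences shorter than the order", {
  r <- run_single("ACG", 10L)
  expect_equal(r$modeled_bases, 3L)
  expect_true(is.finite(r$bpb))
  # the first symbol sees a never-visited warm-up context: exactly uniform
  expect_equal(r$profile$bits[1], 2, tolerance = 1e-12)
})

test_that("run_single recovers the entropy of simple sources", {
  r <- run_single(fx_iid(100000, 21), 2L, alpha = 1)
  expect_equal(r$bpb, 2, tolerance = 0.05 / 2)
  expect_equal(sum(r$profile$bits), r$symbol_bits, tolerance = 1e-9)
})

test_that("best_single picks deep models on repeats, any model on noise", {
  rep_fx <- fx_repeat(30000L, 15000L, seed = 6)
  cfg <- competition_config()
  b <- best_single(rep_fx$seq, cfg)
  expect_gte(b$depth, 10L)

  iid <- fx_iid(30000, 8)
  cfg1 <- competition_config(depths = 4L)
  expect_equal(best_single(iid, cfg1)$depth, 4L)
})

# Exact expected bpb of an adaptive order-k Laplace model on an iid uniform
# source of length n (no IR updates): each of the 4^k contexts accumulates a
# Binomial(n, 4^-k) number of visits; the t-th visit of a context costs
# log2(t+4) - E[log2(B+1)] with B ~ Binomial(t, 1/4). Overlapping-context
# correlations are neglected (second-order at these sizes).
laplace_iid_bpb <- function(k, n) {
  S <- 4^k
  M <- qbinom(1 - 1e-12, n, 1 / S) + 2L
  ct <- vapply(0:(M - 1), function(t)
    log2(t + 4) - sum(dbinom(0:t, t, 0.25) * log2(0:t + 1)), numeric(1))
  cost_m <- c(0, cumsum(ct))
  pm <- dbinom(0:M, n, 1 / S)
  S * sum(pm * cost_m[seq_len(M + 1L)]) / n
}

test_that("single-model bpb on iid data matches the expected-redundancy oracle", {
  n <- 30000L
  iid <- fx_iid(n, 8)
  cfg <- competition_config(use_ir = FALSE)
  b <- best_single(iid, cfg)
  for (i in seq_along(cfg$depths)) {
    k <- cfg$depths[i]
    if (alpha_for_depth(k, cfg) != 1) next  # oracle models Laplace (alpha = 1)
    expect_equal(unname(b$bpb_by_depth[i]), laplace_iid_bpb(k, n),
                 tolerance = 0.02 / 2)
    # cross-entropy of any estimate against the uniform source is >= 2 bpb
    expect_gt(unname(b$bpb_by_depth[i]), 2 - 0.005)
  }
})

test_that("multi-model symbol bits dominate every fixed single depth", {
  cfg <- competition_config(depths = c(2L, 5L, 9L, 12L), block_size = 100L)
  fixtures <- list(
    fx_iid(20000, 31),
    fx_markov(20000, 3, 32)$seq,
    fx_repeat(15000L, 8000L, seed = 33)$seq,
    fx_ircopy(8000L, seed = 34)$seq)
  for (fx in fixtures) {
    multi <- run_multi(fx, cfg)
    singles <- vapply(cfg$depths, function(d)
      run_single(fx, d, alpha = alpha_for_depth(d, cfg),
                 use_ir = cfg$use_ir)$symbol_bits, numeric(1))
    expect_true(all(multi$symbol_bits <= singles + 1e-6))
  }
})

test_that("profile bits add up to block and total symbol bits", {
  fx <- fx_markov(20000, 2, 55)$seq
  r <- run_multi(fx, competition_config(depths = c(2L, 6L, 10L)))
  expect_equal(sum(r$profile$bits), r$symbol_bits, tolerance = 1e-6)
  expect_equal(sum(r$blocks$symbol_bits), r$symbol_bits, tolerance = 1e-6)
  # per-block winner is the argmin of the cost columns, ties to lowest depth
  costs <- as.matrix(r$blocks[, paste0("k", c(2, 6, 10))])
  expect_equal(r$blocks$chosen, unname(apply(costs, 1, which.min)))
})

test_that("identical input and config give bit-identical results", {
  fx <- fx_iid(10000, 61)
  a <- run_multi(fx, competition_config())
  b <- run_multi(fx, competition_config())
  expect_identical(a$profile, b$profile)
  expect_identical(a$symbol_bits, b$symbol_bits)
  expect_identical(a$side_bits, b$side_bits)
})

test_that("depth track switches to deeper models inside a repeated region", {
  fx <- fx_repeat(30000L, 20000L, seed = 71)
  r <- run_multi(fx$seq, competition_config())
  ann <- fx$annotation
  in_rep <- r$profile$position >= ann$start[2]
  modal <- function(x) as.integer(names(sort(table(x), decreasing = TRUE))[1])
  expect_gt(modal(r$profile$chosen_depth[in_rep]),
            modal(r$profile$chosen_depth[!in_rep]))
  # valley: the copy is far cheaper than the iid background
  expect_lt(mean(r$profile$bits[in_rep]), mean(r$profile$bits[!in_rep]))
})
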
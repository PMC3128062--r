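# Count-table model, pseudocount estimator, inverted-repeat updates.

table1_model <- function(alpha = 1, ...) {
  m <- fcm_model(5, alpha, ...)
  fcm_set_counts(m, "AAAAA", c(23, 41, 3, 12))
  fcm_set_counts(m, "ATAGA", c(16, 6, 21, 15))
  fcm_set_counts(m, "GTCTA", c(19, 30, 0, 4))
  fcm_set_counts(m, "TTTTT", c(8, 2, 18, 11))
  m
}

test_that("estimator reproduces the worked count-table example", {
  m <- table1_model(alpha = 1)
  p <- fcm_estimate(m, "ATAGA")
  expect_equal(unname(p["C"]), 7 / 62, tolerance = 1e-15)
  expect_equal(unname(p), c(17, 7, 22, 16) / 62, tolerance = 1e-15)
})

test_that("unseen context gives the uniform distribution for every alpha", {
  for (a in c(1e-6, 1 / 16, 1, 7, 1e6)) {
    m <- fcm_model(4, a)
    expect_equal(unname(fcm_estimate(m, "ACGT")), rep(0.25, 4), tolerance = 1e-15)
  }
})

test_that("alpha interpolates between ML and uniform limits", {
  # evaluate the estimator directly at extreme alphas with counts (10,0,0,0)
  m_small <- fcm_model(2, 1e-6)
  fcm_set_counts(m_small, "AC", c(10, 0, 0, 0))
  expect_equal(unname(fcm_estimate(m_small, "AC")), c(1, 0, 0, 0), tolerance = 1e-6)

  m_big <- fcm_model(2, 1e6)
  fcm_set_counts(m_big, "AC", c(10, 0, 0, 0))
  expect_equal(unname(fcm_estimate(m_big, "AC")), rep(0.25, 4), tolerance = 1e-5)
})

test_that("estimator is normalised and equals the interpolation identity", {
  set.seed(17)
  m <- fcm_model(3, 1)
  for (i in 1:2000) {
    ctx <- random_codes(3)
    counts <- sample(0:200, 4, replace = TRUE)
    alpha <- exp(runif(1, log(1e-3), log(1e3)))
    mm <- fcm_model(3, alpha)
    fcm_set_counts(mm, ctx, counts)
    p <- unname(fcm_estimate(mm, ctx))
    expect_lt(abs(sum(p) - 1), 1e-12)
    N <- sum(counts)
    lambda <- N / (N + 4 * alpha)
    ml <- if (N > 0) counts / N else rep(0.25, 4)
    expect_equal(p, lambda * ml + (1 - lambda) / 4, tolerance = 1e-12)
    # unseen-symbol probability per the closed form
    zero <- which(counts == 0)
    if (length(zero))
      expect_equal(p[zero[1]], alpha / (N + 4 * alpha), tolerance = 1e-12)
  }
})

test_that("incrementing a counter raises its probability and lowers the rest", {
  m <- fcm_model(2, 0.5)
  fcm_set_counts(m, "AC", c(3, 1, 4, 1))
  before <- fcm_estimate(m, "AC")
  fcm_update(m, "AC", "G", use_ir = FALSE)
  after <- fcm_estimate(m, "AC")
  expect_gt(after["G"], before["G"])
  expect_true(all(after[c("A", "C", "T")] < before[c("A", "C", "T")]))
})

test_that("estimator converges to maximum likelihood for large N", {
  m <- fcm_model(1, 1)
  props <- c(0.5, 0.3, 0.15, 0.05)
  fcm_set_counts(m, "A", props * 1e6)
  expect_equal(unname(fcm_estimate(m, "A")), props, tolerance = 1e-5)
})

test_that("unseen-symbol probability decays in N and grows in alpha", {
  f <- function(N, a) a / (N + 4 * a)
  Ns <- c(1, 5, 50, 500, 5000)
  expect_true(all(diff(f(Ns, 1 / 16)) < 0))
  alphas <- c(1 / 64, 1 / 16, 1 / 4, 1, 4)
  expect_true(all(diff(f(100, alphas)) > 0))
})

test_that("ir_counterpart matches the worked example and homopolymers", {
  expect_equal(ir_counterpart("ATAGA", "C"), list(context = "GTCTA", symbol = "T"))
  expect_equal(ir_counterpart("AAAAA", "A"), list(context = "TTTTT", symbol = "T"))
})

test_that("ir_counterpart is an involution and agrees with the string oracle", {
  set.seed(23)
  for (i in 1:1000) {
    k <- sample(2:16, 1)
    ctx <- random_codes(k)
    s <- random_codes(1)
    r <- ir_counterpart(ctx, s)
    # brute-force oracle: reverse-complement the (k+1)-mer as a string
    w <- codes_to_dna(c(ctx, s))
    rc <- rc_string(w)
    expect_equal(codes_to_dna(r$context), substr(rc, 1, k))
    expect_equal(codes_to_dna(r$symbol), substr(rc, k + 1, k + 1))
    back <- ir_counterpart(r$context, r$symbol)
    expect_equal(back$context, ctx)
    expect_equal(back$symbol, s)
  }
})

test_that("inverted-repeat update modifies exactly the two worked-example cells", {
  m <- table1_model()
  fcm_update(m, "ATAGA", "C", use_ir = TRUE)
  expect_equal(unname(fcm_counts(m, "ATAGA")), c(16, 7, 21, 15))  # N = 59
  expect_equal(unname(fcm_counts(m, "GTCTA")), c(19, 30, 0, 5))   # N = 54
  expect_equal(unname(fcm_counts(m, "AAAAA")), c(23, 41, 3, 12))
  expect_equal(unname(fcm_counts(m, "TTTTT")), c(8, 2, 18, 11))

  m2 <- table1_model()
  fcm_update(m2, "ATAGA", "C", use_ir = FALSE)
  expect_equal(unname(fcm_counts(m2, "ATAGA")), c(16, 7, 21, 15))
  expect_equal(unname(fcm_counts(m2, "GTCTA")), c(19, 30, 0, 4))  # untouched
})

test_that("palindromic coincidence double-increments", {
  # k=1: context A, symbol T reverse-complements onto itself
  m <- fcm_model(1, 1)
  fcm_update(m, "A", "T", use_ir = TRUE)
  expect_equal(unname(fcm_counts(m, "A")), c(0, 0, 0, 2))
})

test_that("info_content matches closed forms", {
  expect_equal(info_content(rep(0.25, 4), "A"), 2)
  m <- table1_model()
  expect_equal(info_content(fcm_estimate(m, "ATAGA"), "C"), -log2(7 / 62))
  expect_equal(-log2(7 / 62), 3.1469, tolerance = 1e-4)
  eps <- 1e-12
  expect_lt(info_content(c(1 - 3 * eps, eps, eps, eps), "A"), 1e-11)
})

test_that("shift_context drops the oldest symbol and packing stays bounded", {
  expect_equal(shift_context("AC", "G"), "CG")
  expect_equal(shift_context(c(0L, 1L), 2L), c(1L, 2L))
  # pushing k symbols fully determines the state
  ctx <- "ACGT"
  for (s in c("T", "T", "G", "A")) ctx <- shift_context(ctx, s)
  expect_equal(ctx, "TTGA")
  expect_lt(pack_context(strrep("T", 16)), 4^16)
  expect_equal(pack_context(strrep("T", 16)), 4^16 - 1)
  expect_equal(pack_context("ACGT"), 0 * 64 + 1 * 16 + 2 * 4 + 3)
})

test_that("dense and hash storage give bit-identical model output", {
  set.seed(41)
  seq <- fx_iid(10000, 77)
  for (k in c(2L, 8L)) {
    dense <- run_single(seq, k, alpha = 1, hash_threshold = 16L)
    hashed <- run_single(seq, k, alpha = 1, hash_threshold = 0L)
    expect_identical(dense$profile$bits, hashed$profile$bits)
    expect_identical(dense$symbol_bits, hashed$symbol_bits)
  }
})
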
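test_that("ASCII codec round-trips, MSB first", {
  expect_equal(ascii_to_bits("M"), c(0L, 1L, 0L, 0L, 1L, 1L, 0L, 1L))  # 77
  bits <- ascii_to_bits("MISL")
  expect_length(bits, 32)
  expect_equal(bits_to_ascii(bits), "MISL")
  for (txt in c("A", "hello", "Tag42!"))
    expect_equal(bits_to_ascii(ascii_to_bits(txt)), txt)
  expect_error(ascii_to_bits("café"), "non-ASCII")
})

test_that("code_spec enforces the distance/radius relation", {
  sp <- code_spec()
  expect_equal(sp$required_min_distance, 19)
  expect_equal(sp$t, 9)
  expect_error(code_spec(t = 8, required_min_distance = 19), "floor")
  expect_error(code_spec(n = 10, k = 10), "k must be < n")
})

test_that("encoding is linear and dimension-correct", {
  sp <- code_spec(n = 20, k = 8, t = 2, required_min_distance = 5)
  G <- make_generator_matrix(sp, seed = 3)
  expect_equal(encode_message(rep(0, 8), G), rep(0L, 20))
  set.seed(50)
  for (i in 1:20) {
    m1 <- sample(0:1, 8, TRUE)
    m2 <- sample(0:1, 8, TRUE)
    lhs <- encode_message(as.integer(xor(m1, m2)), G)
    rhs <- as.integer(xor(encode_message(m1, G), encode_message(m2, G)))
    expect_equal(lhs, rhs)
    # matrix-arithmetic oracle
    expect_equal(encode_message(m1, G), encode_oracle(m1, G$bits))
  }
  expect_error(encode_message(c(1, 0), G), "length")
})

test_that("degenerate [3,1] code behaves like repetition", {
  G <- structure(list(bits = matrix(c(1L, 1L, 1L), 1, 3), seed = 0,
                      verified_weight_floor = 3,
                      spec = code_spec(3, 1, 1, 3)),
                 class = "generator_matrix")
  expect_equal(min_weight_search(G), 3)
  r <- decode_nearest(c(1, 1, 0), G)
  expect_equal(r$message, 1L)
  expect_equal(r$distance, 1)
  expect_equal(r$status, "unique")
})

test_that("ISD low-weight search agrees with exhaustive enumeration", {
  for (seed in 1:5) {
    sp <- code_spec(n = 16, k = 5, t = 1, required_min_distance = 3)
    G <- make_generator_matrix(sp, seed = seed)
    exact <- min_weight_search(G, exhaustive = TRUE)
    isd <- min_weight_search(G, iters = 3000, seed = seed + 100,
                             exhaustive = FALSE)
    expect_equal(isd, exact)
    expect_gte(exact, 3)
  }
  # more search never raises the found minimum
  sp <- code_spec(n = 24, k = 10, t = 1, required_min_distance = 3)
  G <- make_generator_matrix(sp, seed = 9)
  w1 <- min_weight_search(G, iters = 50, seed = 1, exhaustive = FALSE)
  w2 <- min_weight_search(G, iters = 2000, seed = 1, exhaustive = FALSE)
  expect_lte(w2, w1)
})

test_that("generator construction emits full-rank verified matrices", {
  sp <- code_spec(n = 20, k = 6, t = 2, required_min_distance = 5)
  G <- make_generator_matrix(sp, seed = 11)
  expect_equal(nrow(G$bits), 6)
  expect_equal(ncol(G$bits), 20)
  expect_gte(min_weight_search(G, exhaustive = TRUE), 5)
  # determinism
  G2 <- make_generator_matrix(sp, seed = 11)
  expect_identical(G$bits, G2$bits)
  # an impossible distance demand fails with advice
  expect_error(make_generator_matrix(
    code_spec(n = 10, k = 8, t = 2, required_min_distance = 5),
    seed = 1, max_matrices = 50), "lowering")
})

test_that("exhaustive decoding corrects every pattern within radius t", {
  sp <- code_spec(n = 12, k = 4, t = 1, required_min_distance = 3)
  G <- make_generator_matrix(sp, seed = 13)
  d <- min_weight_search(G, exhaustive = TRUE)
  t_true <- (d - 1) %/% 2
  expect_gte(t_true, 1)
  messages <- as.matrix(expand.grid(rep(list(0:1), 4)))
  patterns <- list(integer(0))
  for (w in seq_len(t_true))
    patterns <- c(patterns,
                  lapply(asplit(utils::combn(12, w), 2), as.integer))
  for (i in seq_len(nrow(messages))) {
    m <- as.integer(messages[i, ])
    cw <- encode_message(m, G)
    for (e in patterns) {
      res <- decode_nearest(flip_bits(cw, e), G, sp)
      expect_equal(res$message, m)
      expect_equal(res$distance, length(e))
      expect_equal(res$status, "unique")
    }
  }
})

test_that("ISD decoding matches the exhaustive decoder on [20,8] codes", {
  sp <- code_spec(n = 20, k = 8, t = 2, required_min_distance = 5)
  G <- make_generator_matrix(sp, seed = 29)
  set.seed(61)
  n_checked <- 0
  for (trial in 1:200) {
    r <- sample(0:1, 20, TRUE)
    ex <- decode_nearest(r, G, sp, strategy = "exhaustive")
    isd <- decode_nearest(r, G, sp, strategy = "isd", iters = 3000)
    if (ex$status == "unique") {
      expect_equal(isd$message, ex$message)
      expect_equal(isd$distance, ex$distance)
      n_checked <- n_checked + 1
    } else {
      expect_equal(isd$status, "failure")
    }
  }
  expect_gt(n_checked, 10)
})

test_that("scaling vector fitting matches its construction", {
  # uniform counts -> unit factors
  cal <- list(rep(10, 8), rep(3, 8))
  pres <- list(rep(1, 8), rep(1, 8))
  f <- fit_scaling_vector(cal, pres)
  expect_equal(as.numeric(f), rep(1, 8))

  # a molbit with twice the average abundance gets factor ~0.5
  ab <- c(2, rep(1, 7))
  cal <- list(ab * 100, ab * 50)
  f <- fit_scaling_vector(cal, pres)
  expect_equal(as.numeric(f)[1] / mean(as.numeric(f)[-1]), 0.5,
               tolerance = 1e-9)

  # molbits absent from a run are ignored in that run's normalization
  pres2 <- list(c(1, 1, 1, 1, 0, 0, 0, 0), c(0, 0, 0, 0, 1, 1, 1, 1))
  cal2 <- list(c(4, 4, 4, 4, 0, 0, 0, 0), c(0, 0, 0, 0, 5, 5, 5, 5))
  f2 <- fit_scaling_vector(cal2, pres2)
  expect_equal(as.numeric(f2), rep(1, 8))

  # never-present molbit falls back to factor 1 with a warning
  pres3 <- list(c(1, 1, 1, 1, 1, 1, 1, 0))
  expect_warning(f3 <- fit_scaling_vector(list(rep(2, 8)), pres3),
                 "never present")
  expect_equal(as.numeric(f3)[8], 1)
})

test_that("rescaling reduces count dispersion on a seeded fixture", {
  set.seed(71)
  sp <- code_spec()
  ab <- rlnorm(96, 0, 0.67)
  cfg <- run_model_config(misassign_rate = 0)
  ones <- rep(1L, 96)
  cal <- lapply(1:3, function(i)
    count_values(simulate_counts(ones, 20000, cfg, abundance = ab)))
  f <- fit_scaling_vector(cal, list(ones, ones, ones))
  test_run <- count_values(simulate_counts(ones, 20000, cfg, abundance = ab))
  cv_raw <- sd(test_run) / mean(test_run)
  scaled <- test_run * as.numeric(f)
  cv_scaled <- sd(scaled) / mean(scaled)
  expect_lte(cv_scaled, cv_raw)
})

test_that("tag decoding sweeps thresholds and is scale invariant", {
  G <- molbit_generator_matrix()
  msg <- ascii_to_bits("MISL")
  cw <- encode_message(msg, G)
  counts <- cw * 100
  res <- decode_tag(counts, G)
  expect_equal(res$status, "unique")
  expect_equal(res$distance, 0)
  expect_equal(bits_to_ascii(res$message), "MISL")

  # uniform scaling of counts cannot change the decoding
  res2 <- decode_tag(counts * 7.3, G)
  expect_equal(res2$message, res$message)
  expect_equal(res2$distance, res$distance)

  # all-zero counts cannot be binarized -> failure
  res3 <- decode_tag(rep(0, 96), G)
  expect_equal(res3$status, "failure")
  expect_false(identical(res3$message, msg))

  # presence flipped on 9 molbits at a threshold-consistent level still
  # decodes correctly (within the correction radius)
  set.seed(95)
  corrupted <- counts
  idx <- sample(96, 9)
  corrupted[idx] <- ifelse(corrupted[idx] > 0, 0, 100)
  res4 <- decode_tag(corrupted, G, seed = 6)
  expect_equal(res4$status, "unique")
  expect_equal(res4$distance, 9)
  expect_equal(bits_to_ascii(res4$message), "MISL")
})

test_that("noisy counts with realistic structure still decode", {
  G <- molbit_generator_matrix()
  msg <- ascii_to_bits("MISL")
  cw <- encode_message(msg, G)
  set.seed(81)
  # dispersed counts for present molbits, background for absent ones
  counts <- ifelse(cw == 1, rpois(96, rlnorm(96, 5, 0.67)), rpois(96, 0.5))
  res <- decode_tag(counts, G, iters = 1000, seed = 5)
  expect_equal(res$status, "unique")
  expect_equal(bits_to_ascii(res$message), "MISL")
})

test_that("length channel splits at the documented cutoff", {
  expect_equal(classify_by_length(5768), "short")
  expect_equal(classify_by_length(16968), "long")
  expect_equal(classify_by_length(9800), "short")  # boundary convention
  expect_equal(classify_by_length(9801), "long")
  expect_error(classify_by_length(0), "positive")
})

test_that("error probability estimators agree with enumeration", {
  sp <- code_spec(n = 12, k = 4, t = 1, required_min_distance = 3)
  G <- make_generator_matrix(sp, seed = 13)
  expect_equal(estimate_error_probability(0, sp), 0)
  # monotone in p
  ps <- c(0.01, 0.05, 0.1, 0.2)
  tails <- vapply(ps, estimate_error_probability, numeric(1), spec = sp)
  expect_true(all(diff(tails) > 0))

  # exact failure probability by full error-pattern enumeration: by
  # linearity it does not depend on the transmitted message
  p <- 0.08
  m0 <- c(1L, 0L, 1L, 1L)
  cw <- encode_message(m0, G)
  all_e <- as.matrix(expand.grid(rep(list(0:1), 12)))
  fails <- vapply(seq_len(nrow(all_e)), function(i) {
    e <- as.integer(all_e[i, ])
    res <- decode_nearest(as.integer(xor(cw, e)), G, sp)
    bad <- res$status != "unique" || !identical(res$message, m0)
    w <- sum(e)
    if (bad) p^w * (1 - p)^(12 - w) else 0
  }, numeric(1))
  exact <- sum(fails)
  mc <- estimate_error_probability(p, sp, G, method = "monte_carlo",
                                   trials = 800, seed = 91)
  expect_gte(exact, mc$ci[1] - 1e-12)
  expect_lte(exact, mc$ci[2] + 0.02)
  # the binomial tail upper-bounds the exact failure probability
  expect_gte(estimate_error_probability(p, sp), exact - 1e-12)
})

test_that("generator matrices round-trip through hex JSON", {
  sp <- code_spec(n = 20, k = 6, t = 2, required_min_distance = 5)
  G <- make_generator_matrix(sp, seed = 31)
  path <- tempfile(fileext = ".json")
  write_generator_matrix(G, path)
  G2 <- read_generator_matrix(path)
  expect_identical(G2$bits, G$bits)
  expect_equal(G2$spec$n, 20)

  # counts TSV round-trip
  cnt <- count_vector(c(5, 0, 3, 0, 0, 9), run_id = "r1")
  cpath <- tempfile(fileext = ".tsv")
  write_counts_tsv(cnt, cpath)
  back <- read_counts_tsv(cpath, n = 6)
  expect_equal(back$counts, cnt$counts)
})
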
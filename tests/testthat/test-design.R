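test_that("independent constraints report every violation", {
  cfg <- design_config(barcode_length = 40)

  # 6-A homopolymer violates the A/T limit of 5
  s <- paste0("AAAAAA", strrep("CGT", 12), "CG")
  stopifnot(nchar(s) == 44)
  s <- substr(s, 1, 40)
  rep <- check_independent_constraints(s, cfg)
  expect_true("homopolymer_AT" %in% rep$failures$constraint)
  expect_equal(rep$failures$value[rep$failures$constraint == "homopolymer_AT"],
               "6")

  # BsaI site, either strand
  set.seed(40)
  s <- paste0("GGTCTC", random_dna(34))
  rep <- check_independent_constraints(s, cfg)
  expect_true("forbidden_motif" %in% rep$failures$constraint)
  s <- paste0("GAGACC", random_dna(34))
  rep <- check_independent_constraints(s, cfg)
  expect_true("forbidden_motif" %in% rep$failures$constraint)

  # all-GC fails the GC window (and likely others; all are reported)
  rep <- check_independent_constraints(strrep("GC", 20), cfg)
  expect_true("gc_content" %in% rep$failures$constraint)
  expect_false(rep$passed)

  # wrong length is an error, not a failure report
  expect_error(check_independent_constraints("ACGT", cfg), "length")
})

test_that("a compliant sequence passes all constraints", {
  st <- fix_design()
  for (s in st$sequences)
    expect_true(check_independent_constraints(s, st$config)$passed)
})

test_that("mutation changes exactly two adjacent positions", {
  set.seed(41)
  s <- random_dna(40)
  for (i in 1:500) {
    m <- mutate_sequence(s)
    diff <- which(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
    expect_length(diff, 2)
    expect_equal(diff[2] - diff[1], 1)
    expect_equal(nchar(m), nchar(s))
  }
  expect_identical(mutate_sequence(s, seed = 3), mutate_sequence(s, seed = 3))
  # length-2 input mutates both positions
  m2 <- mutate_sequence("AC", seed = 1)
  expect_equal(nchar(m2), 2)
  expect_false(substr(m2, 1, 1) == "A" || substr(m2, 2, 2) == "C")
  expect_error(mutate_sequence("A"), "length >= 2")
})

test_that("random initialization satisfies all postconditions", {
  st <- fix_design()
  n <- length(st$sequences)
  expect_equal(n, 6)
  expect_equal(anyDuplicated(st$sequences), 0)
  off <- st$sw_matrix[upper.tri(st$sw_matrix)]
  expect_true(all(off <= st$config$sw_max_score))
  expect_true(all(diag(st$sw_matrix) == 40))
  expect_true(all(diag(st$dtw_matrix) == 0))
  expect_equal(st$dtw_matrix, t(st$dtw_matrix))
  expect_true(all(st$dtw_matrix[upper.tri(st$dtw_matrix)] > 0))
  # squiggles consistent with sequences
  expect_equal(vapply(st$squiggles, function(s) s$seq_id, character(1)),
               st$sequences)
})

test_that("warm start beats random init on minimum DTW in expectation", {
  model <- fix_model()
  cfg <- design_config(n_barcodes = 5, barcode_length = 40)
  diffs <- vapply(1:8, function(seed) {
    r <- init_barcodes(cfg, model, "random", seed = seed)
    w <- init_barcodes(cfg, model, "warm_start", seed = seed,
                       candidate_factor = 8)
    min(w$dtw_matrix[upper.tri(w$dtw_matrix)]) -
      min(r$dtw_matrix[upper.tri(r$dtw_matrix)])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("evolution is monotone and keeps the set feasible", {
  model <- fix_model()
  cfg <- design_config(n_barcodes = 6, barcode_length = 40, max_rounds = 4)
  st0 <- init_barcodes(cfg, model, "random", seed = 17)
  st <- evolve_barcodes(st0, seed = 18)
  h <- st$history
  expect_gt(nrow(h), 0)
  # global min DTW never decreases (acceptance rule forbids decreases)
  mins <- c(min(st0$dtw_matrix[upper.tri(st0$dtw_matrix)]), h$min_dtw)
  expect_true(all(diff(mins) >= 0))
  # every final sequence passes all constraints
  for (s in st$sequences)
    expect_true(check_independent_constraints(s, cfg)$passed)
  off_sw <- st$sw_matrix[upper.tri(st$sw_matrix)]
  expect_true(all(off_sw <= cfg$sw_max_score))
  expect_true(all(st$dtw_matrix[upper.tri(st$dtw_matrix)] >= st$dtw_floor))
  # matrices stay consistent with a fresh recomputation
  lev <- lapply(st$sequences, function(s)
    simulate_squiggle(s, model, "noiseless", "fixed")$event_levels)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(st$dtw_matrix[i, j], dtw_distance(lev[[i]], lev[[j]]),
                 tolerance = 1e-9)
})

test_that("partitioning covers every barcode once with good separation", {
  st <- fix_design()
  sets <- partition_sets(st, 3)
  expect_length(sets, 3)
  expect_equal(sort(unlist(sets)), 1:6)
  expect_true(all(lengths(sets) == 2))
  # within-set min DTW can never fall below the global min
  gmin <- min(st$dtw_matrix[upper.tri(st$dtw_matrix)])
  for (s in sets)
    if (length(s) > 1) {
      sub <- st$dtw_matrix[s, s]
      expect_gte(min(sub[upper.tri(sub)]), gmin)
    }
  expect_error(partition_sets(st, 4), "divisible")
})

test_that("greedy partition separates better than random on average", {
  model <- fix_model()
  cfg <- design_config(n_barcodes = 8, barcode_length = 40)
  st <- init_barcodes(cfg, model, "random", seed = 23)
  d <- st$dtw_matrix
  within_min <- function(sets) {
    min(vapply(sets, function(s) {
      sub <- d[s, s]
      min(sub[upper.tri(sub)])
    }, numeric(1)))
  }
  greedy <- within_min(partition_sets(st, 2))
  set.seed(24)
  rand <- mean(replicate(40, {
    perm <- sample(8)
    within_min(list(perm[1:4], perm[5:8]))
  }))
  expect_gte(greedy, rand)
})

test_that("barcode FASTA round-trips with molbit ids", {
  st <- fix_design()
  path <- tempfile(fileext = ".fa")
  write_barcodes_fasta(st, path)
  back <- read_barcodes_fasta(path)
  expect_equal(unname(back), st$sequences)
  expect_equal(names(back), paste0("molbit_", 0:5))
})
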
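# small shared training fixture: barcodes, noisy reads, a trained model
clf_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    model <- fix_model()
    st <- fix_design()   # 6 barcodes
    st$config$max_rounds <- 5
    st <- evolve_barcodes(st, seed = 8)
    set.seed(99)
    sig <- list(); lab <- c()
    for (i in seq_along(st$sequences)) {
      for (r in 1:150) {
        sig[[length(sig) + 1]] <- simulate_squiggle(
          st$sequences[i], model, "noisy", "geometric")
        lab <- c(lab, i)
      }
    }
    pc <- preprocess_config(truncate_to = 400, fixed_skip = 0)
    cfg <- classifier_config(
      n_classes = 6, input_length = 400,
      conv_blocks = cbind(c(16L, 32L, 64L, 64L, 64L), rep(7L, 5), rep(2L, 5)),
      fc_sizes = c(128L, 64L), epochs = 6, batch_size = 16,
      learning_rate = 3e-3, seed = 33)
    ds <- build_training_dataset(sig, lab, cfg, pre_config = pc, seed = 34)
    clf <- train_classifier(ds, cfg)
    cache <<- list(model = model, st = st, sig = sig, lab = lab,
                   pc = pc, cfg = cfg, ds = ds, clf = clf)
    cache
  }
})

test_that("alignment labeling finds embedded barcodes and honors ties", {
  st <- fix_design()
  bcs <- setNames(st$sequences, paste0("bc", seq_along(st$sequences)))
  set.seed(51)
  adapter <- random_dna(30)
  spacer <- random_dna(60)
  read <- paste0(adapter, bcs[3], spacer)
  expect_equal(label_read_by_alignment(read, bcs), "bc3")
  # reverse-complement orientation is found too
  expect_equal(label_read_by_alignment(reverse_complement(read), bcs), "bc3")
  # a read containing two distinct barcodes at equal top score -> none
  read2 <- paste0(bcs[1], spacer, bcs[2])
  expect_true(is.na(label_read_by_alignment(read2, bcs)))
  expect_error(label_read_by_alignment(read, character(0)), "empty")
})

test_that("random reads score below the labeling threshold", {
  st <- fix_design()
  bcs <- st$sequences
  set.seed(52)
  n_labeled <- 0
  for (i in 1:20) {
    lbl <- label_read_by_alignment(random_dna(500), bcs)
    if (!is.na(lbl)) n_labeled <- n_labeled + 1
  }
  # 500-nt uniform reads essentially never contain a 15+-scoring match
  expect_lte(n_labeled, 1)
})

test_that("dataset assembly caps classes and splits 85/15", {
  cfg <- classifier_config(n_classes = 2, input_length = 50,
                           conv_blocks = cbind(4L, 5L, 2L),
                           fc_sizes = c(8L, 8L))
  set.seed(53)
  sig <- lapply(1:1000, function(i) rnorm(60))
  lab <- rep(c("a", "b"), c(700, 300))
  ds <- build_training_dataset(sig, lab, cfg, per_class_cap = 500,
                               split_fraction = c(0.85, 0.15), seed = 54)
  # class a capped at 500, class b kept at 300
  expect_equal(sum(ds$y == 0), 500)
  expect_equal(sum(ds$y == 1), 300)
  expect_equal(dim(ds$x), c(50, 800))
  # split sizes within 1 of the stratified target
  expect_lte(abs(sum(ds$train) - round(0.85 * 800)), 1)
  # per-class stratification
  for (cl in 0:1) {
    idx <- ds$y == cl
    expect_lte(abs(sum(ds$train[idx]) - 0.85 * sum(idx)), 1)
  }
})

test_that("training learns the synthetic classes and records history", {
  f <- clf_fixture()
  h <- f$clf$history
  expect_equal(nrow(h), 6)
  # loss decreases over the first epochs on this fixture
  expect_lt(h$train_loss[3], h$train_loss[1])
  expect_gte(tail(h$val_accuracy, 1), 0.8)
  # single-class dataset is rejected
  ds1 <- f$ds
  keep <- ds1$y == 0
  ds1$x <- ds1$x[, keep]
  ds1$y <- ds1$y[keep]
  ds1$classes <- ds1$classes[1]
  ds1$train <- ds1$train[keep]
  expect_error(train_classifier(ds1, f$cfg), "2 classes")
})

test_that("prediction yields proper probabilities and threshold calls", {
  f <- clf_fixture()
  pre <- lapply(f$sig[1:40], function(s) preprocess_signal(s, f$pc))
  probs <- predict(f$clf, pre, type = "prob")
  expect_equal(dim(probs), c(40, 6))
  expect_equal(rowSums(probs), rep(1, 40), tolerance = 1e-6)

  res <- classify_signal(f$clf, pre[[1]])
  expect_s3_class(res, "classification_result")
  expect_equal(sum(res$probabilities), 1, tolerance = 1e-6)
  expect_true(is.na(res$molbit_id) ||
              res$confidence >= f$cfg$confidence_threshold)

  # the confidence threshold rule: a sub-threshold maximum is unclassified
  fake <- f$clf
  fake$config$confidence_threshold <- 1.01
  res2 <- classify_signal(fake, pre[[1]])
  expect_true(is.na(res2$molbit_id))
})

test_that("classified fraction is non-increasing in the threshold", {
  f <- clf_fixture()
  pre <- lapply(f$sig[seq(1, 480, by = 4)],
                function(s) preprocess_signal(s, f$pc))
  probs <- predict(f$clf, pre, type = "prob")
  conf <- apply(probs, 1, max)
  fracs <- vapply(c(0.5, 0.7, 0.9, 0.95, 0.99),
                  function(th) mean(conf >= th), numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("evaluation matches an independent recount", {
  f <- clf_fixture()
  idx <- seq(2, 480, by = 3)
  pre <- lapply(f$sig[idx], function(s) preprocess_signal(s, f$pc))
  labs <- as.character(f$lab[idx])
  ev <- evaluate_classifier(f$clf, pre, labs)
  # confusion rows sum to per-class counts
  expect_equal(unname(rowSums(ev$confusion)),
               unname(as.vector(table(factor(labs, levels = f$clf$classes)))))
  # accuracy equals recount over prediction pairs
  probs <- predict(f$clf, pre, type = "prob")
  pred <- f$clf$classes[apply(probs, 1, which.max)]
  expect_equal(ev$accuracy, mean(pred == labs))
  expect_equal(sum(diag(ev$confusion)) / sum(ev$confusion), ev$accuracy)
})

test_that("training and prediction are deterministic given the seed", {
  f <- clf_fixture()
  clf2 <- train_classifier(f$ds, f$cfg)
  pre <- lapply(f$sig[1:10], function(s) preprocess_signal(s, f$pc))
  expect_equal(predict(f$clf, pre), predict(clf2, pre), tolerance = 1e-12)
})
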
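test_that("a separable 1-D problem is classified with correct score signs", {
  x <- matrix(c(0, 0.1, 0.9, 1), ncol = 1)
  y <- c(-1, -1, 1, 1)
  m <- svm_train(x, y, C = 10, w_ratio = 1)
  s <- decision_scores(m, x)
  expect_true(all(sign(s) == y))
  # zero vector scores exactly the bias
  expect_equal(decision_scores(m, matrix(0, 1, 1)), m$b)
  expect_error(decision_scores(m, matrix(0, 1, 2)), "width mismatch")
  expect_error(svm_train(x, rep(1, 4)), "both classes")
})

test_that("duplicating the dataset is equivalent to doubling the cost", {
  # the hinge-loss term doubles under duplication while the margin term is
  # unchanged, so training the doubled data at C must equal the original
  # data at 2C
  set.seed(31)
  x <- rbind(matrix(rnorm(40, -1), 20, 2), matrix(rnorm(40, 1), 20, 2))
  y <- rep(c(-1, 1), each = 20)
  m1 <- svm_train(x, y, C = 2, w_ratio = 1)
  m2 <- svm_train(rbind(x, x), c(y, y), C = 1, w_ratio = 1)
  expect_equal(m1$w, m2$w, tolerance = 1e-3)
  expect_equal(m1$b, m2$b, tolerance = 1e-3)
  # in the separable hard-margin regime duplication changes nothing at all
  xs <- rbind(matrix(rnorm(40, -3), 20, 2), matrix(rnorm(40, 3), 20, 2))
  h1 <- svm_train(xs, y, C = 100, w_ratio = 1)
  h2 <- svm_train(rbind(xs, xs), c(y, y), C = 100, w_ratio = 1)
  expect_equal(h1$w, h2$w, tolerance = 1e-3)
})

test_that("raising w_ratio does not increase false positives", {
  set.seed(32)
  x <- rbind(matrix(rnorm(200, -0.5), 100, 2), matrix(rnorm(200, 0.5), 100, 2))
  y <- rep(c(-1, 1), each = 100)
  fp <- vapply(c(1, 16), function(w) {
    m <- svm_train(x, y, C = 1, w_ratio = w)
    sum(decision_scores(m, x) > 0 & y == -1)
  }, numeric(1))
  expect_lte(fp[2], fp[1])
})

test_that("solver results are stable across termination tolerances", {
  set.seed(33)
  x <- rbind(matrix(rnorm(100, -0.8), 50, 2), matrix(rnorm(100, 0.8), 50, 2))
  y <- rep(c(-1, 1), each = 50)
  m4 <- svm_train(x, y, tolerance = 1e-4)
  m5 <- svm_train(x, y, tolerance = 1e-5)
  expect_equal(decision_scores(m4, x), decision_scores(m5, x),
               tolerance = 1e-3)
})

test_that("evaluate reproduces its defining identities on fuzzed tables", {
  pr <- evaluate(TP = 1, FN = 0, TN = 1, FP = 0)
  expect_equal(c(pr$Sn, pr$Sp, pr$accuracy), c(100, 100, 100))
  pr <- evaluate(TP = 0, FN = 1, TN = 1, FP = 0)
  expect_equal(c(pr$Sn, pr$Sp, pr$accuracy), c(0, 100, 50))
  set.seed(34)
  for (i in 1:50) {
    counts <- rpois(4, 50) + c(1, 0, 1, 0)
    pr <- evaluate(counts[1], counts[2], counts[3], counts[4])
    expect_identical(pr$TP + pr$FN, counts[1] + counts[2])
    expect_identical(pr$TN + pr$FP, counts[3] + counts[4])
    expect_equal(pr$Sn, 100 * counts[1] / (counts[1] + counts[2]))
    expect_equal(pr$Sp, 100 * counts[3] / (counts[3] + counts[4]))
    expect_equal(pr$accuracy, (pr$Sn + pr$Sp) / 2)
  }
  expect_error(evaluate(0, 0, 1, 0), "no positive")
  expect_error(evaluate(1, 0, 0, 0), "no negative")
})

test_that("cross-validation separates planted classes and is reproducible", {
  ds <- tiny_benchmark(n = 40, seed = 41, signal = "strong")
  cv1 <- cross_validate(ds, selection = c(1, 3), k = 5, seed = 7)
  expect_equal(cv1$accuracy, 100)
  expect_equal(cv1$Sn_sd, 0)
  cv2 <- cross_validate(ds, selection = c(1, 3), k = 5, seed = 7)
  expect_identical(cv1$per_fold, cv2$per_fold)  # bit-reproducible
  cv3 <- cross_validate(ds, selection = c(1, 3), k = 5, seed = 8)
  expect_identical(nrow(cv3$per_fold), 5L)
})

test_that("k equal to the sample count reduces to leave-one-out", {
  ds <- tiny_benchmark(n = 8, seed = 42, signal = "strong")
  cv <- cross_validate(ds, selection = 3, k = nrow(ds), seed = 1)
  # every non-empty fold holds exactly one sample
  sizes <- rowSums(cv$per_fold[, c("TP", "FN", "TN", "FP")])
  expect_true(all(sizes == 1))
  expect_equal(sum(sizes), nrow(ds))
  expect_equal(cv$accuracy, 100)
})

test_that("the 63-combination screen is ordered and complete", {
  ds <- tiny_benchmark(n = 25, seed = 43, signal = "strong")
  scr <- screen_combinations(ds, k = 3, seed = 2)
  expect_identical(nrow(scr), 63L)
  expect_identical(scr$measurements[1:6], as.character(1:6))
  expect_identical(scr$measurements[63], "1, 2, 3, 4, 5, 6")
  sizes <- lengths(strsplit(scr$measurements, ", "))
  expect_true(!is.unsorted(sizes))  # singletons, pairs, ..., full set
  expect_true(all(is.finite(scr$accuracy)))
})

test_that("grid search is deterministic and breaks ties toward simplicity", {
  ds <- tiny_benchmark(n = 20, seed = 44, signal = "strong")
  single <- grid_search(ds, selection = 3, log2C_grid = 0, log2w_grid = 0,
                        k = 3, seed = 3)
  expect_identical(nrow(single$grid), 1L)
  expect_equal(single$best$log2C, 0)

  dup <- grid_search(ds, selection = 3, log2C_grid = c(-1, -1),
                     log2w_grid = 0.4, k = 3, seed = 3)
  expect_equal(dup$grid$accuracy[1], dup$grid$accuracy[2])

  # separable data: every cell ties at 100%; the smallest C and the
  # |log2 w| closest to zero must win
  g <- grid_search(ds, selection = 3, log2C_grid = c(2, 4),
                   log2w_grid = c(-1, 0, 1), k = 3, seed = 3)
  if (length(unique(g$grid$accuracy)) == 1L) {
    expect_equal(g$best$log2C, 2)
    expect_equal(g$best$log2w, 0)
  }
})

test_that("threshold sweep reproduces t = 0 and is monotone in the offset", {
  ds <- tiny_benchmark(n = 50, seed = 45)
  x <- encode_features(setNames(ds$sequence, ds$seq_id), c(1, 3))
  sc <- fit_scaler(x)
  xs <- apply_scaler(sc, x)
  m <- svm_train(xs, ds$label)
  sw <- threshold_sweep(m, xs, ds$label, offsets = seq(-2, 2, length.out = 41))
  expect_true(all(diff(sw$Sn) <= 1e-12))   # Sn non-increasing
  expect_true(all(diff(sw$Sp) >= -1e-12))  # Sp non-decreasing

  at0 <- threshold_sweep(m, xs, ds$label, offsets = 0)
  pred <- decision_scores(m, xs) > 0
  expect_identical(at0$TP, sum(pred & ds$label == 1))
  expect_identical(at0$FP, sum(pred & ds$label == -1))

  low <- threshold_sweep(m, xs, ds$label, offsets = -1e6)
  expect_equal(low$Sn, 100)  # everything predicted coding
})

test_that("ORF prediction keeps input order and flags unscorable sequences", {
  ds <- tiny_benchmark(n = 40, seed = 46)
  m <- train_orf_model(ds, selection = c(1, 3))
  seqs <- setNames(ds$sequence, ds$seq_id)
  pred <- predict_orfs(m, seqs)
  expect_identical(pred$orf_id, ds$seq_id)
  # resubstitution: nearly all training positives re-score as coding
  pos <- pred$label[ds$label == 1]
  expect_gte(mean(pos == "coding"), 0.99)

  expect_identical(nrow(predict_orfs(m, character(0))), 0L)
  expect_identical(predict_orfs(m, seqs), pred)  # deterministic

  mixed <- c(seqs[1], short = "AT", seqs[2])
  pm <- predict_orfs(m, mixed)
  expect_identical(pm$label[2], "unscorable")
  expect_true(is.na(pm$score[2]))
  expect_identical(pm$orf_id, names(mixed))
})

test_that("persisted models reload and reproduce scores to 1e-10", {
  ds <- tiny_benchmark(n = 30, seed = 47)
  m <- train_orf_model(ds, selection = c(1, 2, 5))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_identical(m2$selection, m$selection)
  expect_equal(m2$C, m$C)
  seqs <- setNames(ds$sequence, ds$seq_id)
  expect_lt(max(abs(predict_orfs(m, seqs)$score -
                    predict_orfs(m2, seqs)$score)), 1e-10)
})

test_that("cross-validation recovers the Bayes accuracy of a calibrated task", {
  # two fixed-length codon-table classes; the log-likelihood ratio is an
  # exact Bayes rule and is linear in the codon-frequency block, so the
  # linear SVM can represent it
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  sense <- sort(sense)
  eps <- 0.39  # tilt giving ~97% Bayes accuracy at 100 codons
  s <- rep(c(1, -1), length.out = 61)
  p <- setNames(exp(eps * s) / sum(exp(eps * s)), sense)
  q <- setNames(rep(1 / 61, 61), sense)
  a <- sample_coding(coding_model(codon_probs = p, len_range = c(100L, 100L)),
                     800, seed = 21, prefix = "A")
  b <- sample_coding(coding_model(codon_probs = q, len_range = c(100L, 100L)),
                     800, seed = 22, prefix = "B")
  b$label <- -1L
  ds <- rbind(a, b)

  lr <- log(p / q)
  llr <- vapply(ds$sequence, function(sq) {
    cod <- substring(sq, seq(4, by = 3, length.out = 100),
                     seq(6, by = 3, length.out = 100))
    sum(lr[cod])
  }, numeric(1), USE.NAMES = FALSE)
  bayes <- 100 * (mean(llr[ds$label == 1] > 0) +
                  mean(llr[ds$label == -1] <= 0)) / 2
  expect_gt(bayes, 94)  # calibration sanity

  cv <- cross_validate(ds, selection = 3, k = 10, C = 1, w_ratio = 1, seed = 5)
  expect_lt(abs(cv$accuracy - bayes), 3)
})
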
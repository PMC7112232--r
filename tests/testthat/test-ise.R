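# Core ISE machinery: discretisation, MCC, filter evaluation, range
# selection, sampling, elimination, fold runs, MBI scoring and serialization.

test_that("sub-range enumeration matches the n(n-1)/2 combinatorics", {
  expect_equal(nrow(enumerate_subranges(2)), 1)
  expect_equal(nrow(enumerate_subranges(100)), 4950)
  # brute-force index pairs for a small grid
  n <- 5
  pairs <- expand.grid(lo = 1:n, hi = 1:n)
  pairs <- pairs[pairs$lo < pairs$hi, ]
  got <- enumerate_subranges(n)
  expect_equal(nrow(got), nrow(pairs))           # 10
  expect_setequal(paste(got$lo_idx, got$hi_idx),
                  paste(pairs$lo, pairs$hi))
  expect_true(all(got$lo_idx < got$hi_idx))
  expect_error(enumerate_subranges(1), "n_divisions")
})

test_that("filter space size reproduces the published combinatorics scale", {
  expect_equal(filter_space_size(180, 5), choose(180, 5))
  expect_equal(filter_space_size(10, c(4, 5)),
               choose(10, 4) + choose(10, 5))
})

test_that("confusion-count MCC matches hand arithmetic and conventions", {
  expect_equal(mcc(10, 0, 100, 0), 1)
  expect_equal(mcc(0, 10, 0, 100), -1)
  expect_equal(mcc(3, 1, 5, 1), 14 / 24)
  # zero denominator factor -> 0 by convention
  expect_equal(mcc(5, 5, 0, 0), 0)
  expect_error(mcc(0, 0, 0, 0), "zero")
  # vectorised path agrees with scalar oracle on random cases
  set.seed(11)
  for (i in 1:50) {
    cts <- rpois(4, 8)
    if (sum(cts) == 0) next
    expect_equal(mcc(cts[1], cts[2], cts[3], cts[4]),
                 oracle_mcc_counts(cts[1], cts[2], cts[3], cts[4]))
    expect_true(abs(mcc(cts[1], cts[2], cts[3], cts[4])) <= 1)
  }
})

test_that("proportion MCC equalises classes and agrees with its oracle", {
  set.seed(12)
  for (i in 1:50) {
    nA <- sample(5:50, 1); nI <- sample(5:5000, 1)
    tp <- sample(0:nA, 1); fp <- sample(0:nI, 1)
    expect_equal(mcc_proportions(tp, fp, nI - fp, nA - tp),
                 oracle_mcc_props(tp, fp, nI - fp, nA - tp))
  }
  # scale invariance in class sizes
  expect_equal(mcc_proportions(8, 10, 90, 2),
               mcc_proportions(80, 100, 900, 20))
})

test_that("filter evaluation reproduces the hand-constructed 6-molecule case", {
  d <- data.frame(a = c(0.2, 0.3, 0.9, 0.25, 0.1, 0.95),
                  b = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  f <- list(descriptors = c("a", "b"), lo = c(0.15, 0), hi = c(0.4, 1))
  got <- evaluate_filter(f, d, lab)
  expect_equal(got[c("tp", "fn", "fp", "tn")],
               list(tp = 2, fn = 1, fp = 1, tn = 2))
  expect_equal(got$mcc, 1 / 3)
  # whole-space filter: all pass, tn + fn = 0 -> mcc 0
  g <- list(descriptors = "a", lo = 0, hi = 1)
  all_pass <- evaluate_filter(g, d, lab)
  expect_equal(all_pass$tp, 3)
  expect_equal(all_pass$fp, 3)
  expect_equal(all_pass$mcc, 0)
  # perfect filter
  h <- list(descriptors = "a", lo = 0.85, hi = 1)
  expect_equal(evaluate_filter(h, d, c(FALSE, FALSE, TRUE,
                                       FALSE, FALSE, TRUE))$mcc, 1)
  expect_error(evaluate_filter(list(descriptors = "zz", lo = 0, hi = 1),
                               d, lab), "missing descriptor")
})

test_that("best single range equals the exhaustive brute-force scan", {
  set.seed(21)
  for (case in 1:4) {
    n_div <- c(20, 35, 50, 30)[case]
    v <- c(runif(15, 0.4, 0.6), runif(120))
    lab <- rep(c(TRUE, FALSE), c(15, 120))
    for (comp in c("proportions", "counts")) {
      br <- best_range_per_descriptor(v, lab, n_div, comp)
      oracle <- oracle_best_range(v, lab, n_div,
                                  if (comp == "proportions")
                                    oracle_mcc_props else oracle_mcc_counts)
      expect_equal(br$mcc, oracle, tolerance = 1e-12)
    }
  }
})

test_that("best range recovers a planted window and behaves at the edges", {
  set.seed(22)
  v <- c(runif(1000, 0.4, 0.6), runif(1000))
  lab <- rep(c(TRUE, FALSE), c(1000, 1000))
  br <- best_range_per_descriptor(v, lab, 100)
  jacc <- (min(br$hi, 0.6) - max(br$lo, 0.4)) /
    (max(br$hi, 0.6) - min(br$lo, 0.4))
  expect_gte(jacc, 0.8)
  # perfectly separated classes
  v2 <- c(runif(50, 0, 0.3), runif(50, 0.6, 1))
  br2 <- best_range_per_descriptor(v2, rep(c(TRUE, FALSE), each = 50), 50)
  expect_equal(br2$mcc, 1)
  # labels independent of values -> small score
  set.seed(23)
  v3 <- runif(500); lab3 <- sample(rep(c(TRUE, FALSE), c(50, 450)))
  br3 <- best_range_per_descriptor(v3, lab3, 100, "counts")
  expect_lt(abs(br3$mcc), 0.3)
  # constant descriptor flagged
  br4 <- best_range_per_descriptor(rep(1, 10),
                                   rep(c(TRUE, FALSE), 5), 100)
  expect_false(br4$ok)
  expect_equal(br4$mcc, 0)
})

test_that("filter sampling is seed-deterministic, structural and unbiased", {
  set.seed(5)
  a <- sample_filters(20, c(4, 5), 500)
  set.seed(5)
  b <- sample_filters(20, c(4, 5), 500)
  expect_identical(a, b)
  sizes <- rowSums(!is.na(a))
  expect_true(all(sizes %in% c(4, 5)))
  expect_true(all(apply(a, 1, function(r)
    !anyDuplicated(r[!is.na(r)]))))
  # descriptor frequencies ~ uniform across a large sample
  set.seed(6)
  big <- sample_filters(20, c(4, 5), 20000)
  freq <- tabulate(big[!is.na(big)], nbins = 20)
  p <- chisq.test(freq)$p.value
  expect_gt(p, 0.001)
  expect_error(sample_filters(3, c(4, 5), 10), "pool too small")
})

test_that("range elimination follows the biased-decile rule arithmetic", {
  # pool of 10 ranges; 1000 filters of size 4; range 1 appears 100 times:
  # 40 among the worst decile, 0 among the best; everything else uniform.
  pool <- data.frame(descriptor = paste0("d", 1:10), lo = 0, hi = 1,
                     lo_idx = 1, hi_idx = 2, mcc = 0.1)
  set.seed(31)
  n <- 1000
  combos <- t(vapply(seq_len(n), function(i)
    sort(sample(2:10, 4)), integer(4)))
  # rows 1..100 ordered by mcc rank: worst decile = rows 1..100 after sort;
  # craft mcc so that row i has rank i
  mccs <- seq(-1, 1, length.out = n)
  rows_with_1 <- c(1:40, 301:360)              # 40 worst-decile, 60 mid
  for (r in rows_with_1) combos[r, 1] <- 1L
  cfg <- ise_config(decile_fraction = 0.1, alpha = 2, beta = 0.5,
                    min_expected = 5)
  res <- eliminate_ranges(combos, mccs, pool, cfg)
  expect_false(res$skipped)
  # range 1: total 100, expected 10; worst 40 > 20, best 0 < 5 -> out
  expect_true("d1" %in% res$eliminated)
  # uniformly spread ranges stay
  expect_true(all(paste0("d", 2:10) %in% res$pool$descriptor))
  # a range only in the best decile is kept
  combos2 <- combos
  best_rows <- which(rank(mccs) > n - 100)
  for (r in best_rows[1:60]) combos2[r, 1] <- 1L
  combos2[setdiff(rows_with_1, best_rows), 1] <- 2L
  res2 <- eliminate_ranges(combos2, mccs, pool, cfg)
  expect_false("d1" %in% res2$eliminated)
  # too-small sample -> skipped with warning
  expect_warning(
    res3 <- eliminate_ranges(combos[1:20, ], mccs[1:20], pool, cfg),
    "skipped")
  expect_true(res3$skipped)
  expect_equal(nrow(res3$pool), 10)
})

test_that("fold run equals the independent exhaustive oracle on small pools", {
  for (seed in c(1, 2, 3)) {
    tp <- tiny_planted(n_act = 10, n_inact = 60, n_desc = 6, seed = seed)
    cfg <- ise_config(n_divisions = 12)
    set.seed(seed)
    ens <- run_ise_fold(tp$data, tp$labels, cfg)
    pool <- attr(ens, "pool")
    oracle <- oracle_top_filter_mcc(tp$data, tp$labels, pool, c(4, 5))
    expect_equal(max(ens$mcc), oracle, tolerance = 1e-12)
    # every stored filter's MCC is reproducible from its stored counts
    recomputed <- mcc_proportions(ens$tp, ens$fp, ens$tn, ens$fn)
    expect_equal(ens$mcc, recomputed, tolerance = 1e-12)
    # and its counts are reproducible from its ranges
    for (i in seq_len(min(5, nrow(ens)))) {
      r <- ens$ranges[[i]]
      ev <- evaluate_filter(list(descriptors = r$descriptor, lo = r$lo,
                                 hi = r$hi), tp$data, tp$labels)
      expect_equal(unlist(ev[c("tp", "fp", "tn", "fn")]),
                   c(tp = ens$tp[i], fp = ens$fp[i], tn = ens$tn[i],
                     fn = ens$fn[i]))
    }
  }
})

test_that("fold run recovers planted descriptors and rejects empty classes", {
  gd <- gen_descriptor_dataset(planted_descriptor_spec(
    n_inactives = 2000, seed = 99))
  d <- gd$data
  X <- d[, grep("^sig|^noise", names(d))]
  set.seed(99)
  ens <- run_ise_fold(X, d$label == 1)
  top_desc <- ens$ranges[[1]]$descriptor
  expect_gte(sum(top_desc %in% gd$truth$signal), 2)
  expect_error(run_ise_fold(X, rep(FALSE, nrow(X))), "no actives")
  expect_error(run_ise_fold(X, rep(TRUE, nrow(X))), "no inactives")
})

test_that("stochastic elimination converges and shrinks the pool monotonely", {
  # sensitive bias thresholds so that the mild worst-decile enrichment of
  # noise ranges in a 12-descriptor pool is enough to trigger eliminations
  tp <- tiny_planted(n_act = 20, n_inact = 150, n_desc = 12, seed = 7)
  cfg <- ise_config(n_divisions = 10, sample_size = 4000,
                    alpha = 1.2, beta = 0.95,
                    exhaustive_threshold = 400, max_iterations = 30)
  set.seed(7)
  ens <- run_ise_fold(tp$data, tp$labels, cfg)
  hist <- attr(ens, "history")
  expect_gt(length(hist), 0)
  pool_sizes <- vapply(hist, `[[`, numeric(1), "pool_size")
  expect_true(all(diff(pool_sizes) <= 0))
  final_pool <- attr(ens, "pool")
  expect_lt(filter_space_size(nrow(final_pool), cfg$filter_sizes),
            cfg$exhaustive_threshold)
  expect_gte(nrow(final_pool), max(cfg$filter_sizes))
})

test_that("cross-validated build gives one held-out score per molecule", {
  gd <- gen_descriptor_dataset(planted_descriptor_spec(
    n_actives = 20, n_inactives = 600, seed = 5))
  d <- gd$data
  X <- d[, grep("^sig|^noise", names(d))]
  m <- build_model(X, d$label == 1, seed = 5, ids = d$id)
  expect_setequal(m$holdout$id, d$id)
  expect_equal(anyDuplicated(m$holdout$id), 0)
  expect_equal(sort(unique(m$folds)), 1:5)
  # fold stratification: every fold holds both classes
  for (k in 1:5) {
    expect_gt(sum(d$label[m$folds == k] == 1), 0)
    expect_gt(sum(d$label[m$folds == k] == 0), 0)
  }
  # planted signal separates held-out classes far better than chance
  expect_gt(rank_auc(m$holdout$mbi, m$holdout$label), 0.9)
})

test_that("label-permuted data yields chance-level held-out discrimination", {
  gd <- gen_descriptor_dataset(planted_descriptor_spec(
    n_actives = 25, n_inactives = 3000, seed = 8))
  d <- gd$data
  X <- d[, grep("^sig|^noise", names(d))]
  set.seed(80)
  perm <- sample(d$label)
  m <- build_model(X, perm == 1, seed = 8, ids = d$id)
  auc <- rank_auc(m$holdout$mbi, m$holdout$label)
  expect_gte(auc, 0.4)
  expect_lte(auc, 0.6)
})

test_that("MBI follows the efficiency/inefficiency arithmetic and bounds", {
  mk_model <- function(stats, ranges, mode = "proportion") {
    ens <- stats
    ens$ranges <- ranges
    class(ens) <- c("ise_ensemble", "data.frame")
    structure(list(filters = ens, descriptors = "a",
                   config = ise_config(mbi_mode = mode)),
              class = "ise_model")
  }
  r1 <- data.frame(descriptor = "a", lo = 0, hi = 0.5)
  r2 <- data.frame(descriptor = "a", lo = 0.9, hi = 1)
  # single filter with efficiency 0.8 (tp 4, fp 1), molecule passes
  m1 <- mk_model(data.frame(size = 1, tp = 4, fp = 1, tn = 9, fn = 1,
                            mcc = 0.5), list(r1))
  expect_equal(mbi_score(m1, data.frame(a = 0.2))$mbi, 0.8)
  # add a filter the molecule fails, inefficiency 0.9 (tn 9, fn 1)
  m2 <- mk_model(data.frame(size = 1, tp = c(4, 4), fp = c(1, 1),
                            tn = c(9, 9), fn = c(1, 1), mcc = 0.5),
                 list(r1, r2))
  expect_equal(mbi_score(m2, data.frame(a = 0.2))$mbi, (0.8 - 0.9) / 2)
  # failing every filter of an all-inefficiency-1 model -> exactly -1
  m3 <- mk_model(data.frame(size = 1, tp = c(2, 2), fp = c(3, 3),
                            tn = c(7, 7), fn = c(0, 0), mcc = 0.5),
                 list(r2, r2))
  expect_equal(mbi_score(m3, data.frame(a = 0.2))$mbi, -1)
  # proportion-mode bounds on random models and molecules
  gd <- gen_descriptor_dataset(planted_descriptor_spec(
    n_actives = 15, n_inactives = 300, seed = 17))
  X <- gd$data[, grep("^sig|^noise", names(gd$data))]
  m <- build_model(X, gd$data$label == 1, seed = 17)
  sc <- mbi_score(m, X)
  expect_true(all(sc$mbi >= -1 & sc$mbi <= 1))
  # raw mode is unbounded above but finite
  m_raw <- m; m_raw$config$mbi_mode <- "raw"
  sc_raw <- mbi_score(m_raw, X)
  expect_true(all(is.finite(sc_raw$mbi)))
  # missing descriptor value -> NA with warning; absent column -> error
  Xna <- X[1:3, ]; Xna[2, 1] <- NA
  expect_warning(sc_na <- mbi_score(m, Xna), "missing descriptor values")
  expect_true(is.na(sc_na$mbi[2]) && !is.na(sc_na$mbi[1]))
  expect_error(mbi_score(m, X[, 1:3]), "missing descriptor column")
})

test_that("score table counts strictly-above cutoffs and ranks AUC", {
  sc <- c(0.9, 0.8, 0.7, 0.1)
  lab <- c(TRUE, FALSE, TRUE, FALSE)
  tab <- score_table(sc, lab, cutoffs = c(0.85, 0.5, 0))
  expect_equal(tab$tp, c(1, 2, 2))
  expect_equal(tab$fp, c(0, 1, 2))
  expect_equal(attr(tab, "auc"), 0.75)
  expect_equal(rank_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(rank_auc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE)), 0)
  expect_message(a <- rank_auc(1:3, c(TRUE, TRUE, TRUE)), "one class")
  expect_true(is.na(a))
})

test_that("rank AUC agrees with the pROC reference on tied, noisy scores", {
  skip_if_not_installed("pROC")
  set.seed(41)
  sc <- round(rnorm(300), 1)                      # ties on purpose
  lab <- runif(300) < 0.3
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rank_auc(sc, lab), ref, tolerance = 1e-12)
})

test_that("models serialize to byte-identical JSON and round-trip scores", {
  gd <- gen_descriptor_dataset(planted_descriptor_spec(
    n_actives = 15, n_inactives = 400, seed = 13))
  d <- gd$data
  X <- d[, grep("^sig|^noise", names(d))]
  m1 <- build_model(X, d$label == 1, seed = 13, ids = d$id)
  m2 <- build_model(X, d$label == 1, seed = 13, ids = d$id)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_ise_model(m1, f1); write_ise_model(m2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_ise_model(f1)
  expect_equal(back$filters$mcc, m1$filters$mcc)
  expect_equal(mbi_score(back, X[1:20, ])$mbi,
               mbi_score(m1, X[1:20, ])$mbi)
  # re-serialising the read model is also byte-stable
  f3 <- tempfile(fileext = ".json")
  write_ise_model(back, f3)
  expect_identical(readLines(f1), readLines(f3))
})
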
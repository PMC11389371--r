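test_that("Bray-Curtis similarity matches its closed forms", {
  expect_equal(brayCurtisSimilarity(c(0.2, 0.8), c(0.2, 0.8)), 1)
  expect_equal(brayCurtisSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(brayCurtisSimilarity(c(0.5, 0.5, 0), c(1, 0, 0)), 0.5)
  # symmetry and the sum-min identity on random simplex vectors
  set.seed(4)
  for (i in 1:25) {
    x <- normalizeComposition(rgamma(6, 1))
    y <- normalizeComposition(rgamma(6, 1))
    expect_equal(brayCurtisSimilarity(x, y), brayCurtisSimilarity(y, x))
    expect_equal(brayCurtisSimilarity(x, y), sum(pmin(x, y)))
  }
})

test_that("Bray-Curtis agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(5)
  x <- normalizeComposition(rgamma(10, 1))
  y <- normalizeComposition(rgamma(10, 1))
  expect_equal(brayCurtisSimilarity(x, y),
               1 - as.numeric(vegan::vegdist(rbind(x, y), method = "bray")))
})

test_that("relative error follows the elementwise definition with NaN at zero truth", {
  expect_equal(relativeError(c(0.2, 0.5), c(0.2, 0.5)), c(0, 0))
  expect_equal(relativeError(c(0.2), c(0.1)), 0.5)
  got <- relativeError(c(0, 0.5), c(0.2, 0.4))
  expect_true(is.nan(got[1]))
  expect_equal(got[2], 0.2)
  expect_equal(mean(got, na.rm = TRUE), 0.2)
})

test_that("leave-one-out covers exactly the interior samples", {
  p <- randomProfile(10, 4, seed = 31)
  ev <- looEvaluate(p, "knn")
  r <- records(ev)
  expect_equal(nrow(r), 8L)
  expect_equal(r$target_index, 2:9)
  expect_true(all(r$gap_prev > 0 & r$gap_next > 0))
  expect_equal(r$n_samples_available, rep(9L, 8))
  expect_true(all(!r$failed))
  # predictions live on the simplex
  expect_true(all(abs(rowSums(ev@predicted) - 1) < 1e-9))
})

test_that("'last' scores perfectly on a constant profile and 'equal' matches its identity", {
  m <- matrix(rep(c(0.5, 0.3, 0.2), 6), 6, byrow = TRUE,
              dimnames = list(NULL, c("A", "B", "C")))
  p <- LongitudinalProfile(m, times = cumsum(c(0, runif(5, 0.5, 2))),
                           individualId = "c")
  expect_true(all(records(looEvaluate(p, "last"))$bc_similarity == 1))

  p2 <- randomProfile(8, 5, seed = 17)
  ev <- looEvaluate(p2, "equal")
  ab <- abundanceMatrix(p2)
  oracle <- vapply(2:7, function(i) sum(pmin(ab[i, ], 1 / 5)), numeric(1))
  expect_equal(records(ev)$bc_similarity, oracle)
})

test_that("method failures are flagged records, not dropped", {
  # DBN fitting needs 3 remaining samples; a 3-sample profile leaves 2
  p <- subsetSamples(randomProfile(6, 4, seed = 8), c(1, 3, 5))
  ev <- looEvaluate(p, "dbn_dense")
  r <- records(ev)
  expect_equal(nrow(r), 1L)
  expect_true(r$failed)
  expect_match(r$message, "at least 3")
  expect_true(is.na(r$bc_similarity))
})

test_that("summaries aggregate, rank, and keep failures visible", {
  r1 <- data.frame(individual_id = "a", dataset = NA, method = "m1",
                   target_index = 2:4, target_time = 1:3,
                   bc_similarity = c(0.8, 0.9, 1.0), gap_prev = 1,
                   gap_next = 1, n_samples_available = 9,
                   failed = FALSE, message = "")
  single <- summarizeAccuracy(r1[1, ], groupBy = "method")
  expect_equal(single$mean_bc, 0.8)
  expect_equal(single$n, 1L)

  r2 <- r1
  r2$method <- "m2"
  r2$bc_similarity <- c(0.5, 0.6, 0.7)
  r2$failed <- c(FALSE, FALSE, TRUE)
  s <- summarizeAccuracy(rbind(r1, r2), groupBy = "method")
  expect_equal(s$mean_bc[s$method == "m1"], 0.9)
  expect_equal(s$mean_bc[s$method == "m2"], 0.55)   # failed row excluded
  expect_equal(s$n_failed[s$method == "m2"], 1L)
  expect_equal(s$rank, c(1, 2))
})

test_that("subsampling yields the promised design and is seed-stable", {
  p <- randomProfile(14, 4, seed = 41)
  res <- subsampleExperiment(p, "knn", sizes = c(5, 10), replicates = 3,
                             seed = 2)
  expect_equal(nrow(res), 6L)
  expect_equal(res$sample_size, rep(c(5, 10), each = 3))
  again <- subsampleExperiment(p, "knn", sizes = c(5, 10), replicates = 3,
                               seed = 2)
  expect_identical(res, again)
  expect_warning(subsampleExperiment(p, "knn", sizes = c(5, 99),
                                     replicates = 2, seed = 1),
                 "skipping")
})

test_that("full-size subsampling coincides with the LOO record of its target", {
  p <- randomProfile(9, 4, seed = 51)
  res <- subsampleExperiment(p, "knn", sizes = nSamples(p), replicates = 5,
                             seed = 3)
  loo <- records(looEvaluate(p, "knn"))
  for (k in seq_len(nrow(res))) {
    match <- loo[abs(loo$target_time - res$target_time[k]) < 1e-12, ]
    expect_equal(res$bc_similarity[k], match$bc_similarity)
    expect_equal(res$gap_prev[k], match$gap_prev)
  }
})

test_that("stratified effects recover a constructed monotone gap trend", {
  set.seed(6)
  fake <- data.frame(sample_size = rep(c(5, 10), each = 60),
                     gap_prev = runif(120, 0, 10))
  fake$bc_similarity <- 1 - 0.01 * fake$gap_prev
  fake$failed <- FALSE
  out <- stratifiedEffects(fake, fix = "sample_size", bins = c(0, 3.3, 6.6, 10))
  for (s in unique(out$stratum)) {
    col <- out$mean_bc[out$stratum == s]
    expect_true(all(diff(col) < 0))
  }
  expect_equal(sum(out$n), 120L)

  # a single stratum reproduces the overall mean
  one <- stratifiedEffects(fake[fake$sample_size == 5, ],
                           fix = "sample_size", bins = c(0, 10))
  expect_equal(one$mean_bc, mean(fake$bc_similarity[fake$sample_size == 5]))
})

test_that("accuracy autocorrelation decays for an AR(1) series and conserves pairs", {
  set.seed(9)
  n <- 40
  acc <- numeric(n)
  acc[1] <- 0
  for (i in 2:n) acc[i] <- 0.9 * acc[i - 1] + rnorm(1, 0, 0.2)
  fake <- data.frame(individual_id = "a", dataset = NA, method = "knn",
                     target_index = seq_len(n) + 1, target_time = seq_len(n),
                     bc_similarity = 0.5 + 0.1 * acc, gap_prev = 1,
                     gap_next = 1, n_samples_available = n + 1,
                     failed = FALSE, message = "")
  out <- accuracyAutocorrelation(fake, lagBins = c(0, 3, 40))
  expect_equal(sum(out$n_pairs), choose(n, 2))
  expect_gt(out$r[1], out$r[2])

  # constant accuracy: zero variance, correlation undefined
  fake$bc_similarity <- 0.7
  flat <- accuracyAutocorrelation(fake, lagBins = c(0, 3, 40))
  expect_true(all(is.nan(flat$r)))
  expect_error(accuracyAutocorrelation(fake[1:4, ], c(0, 40)), "at least 10")
})

test_that("neighbour-context correlations order as constructed and are seeded", {
  set.seed(12)
  mk <- function(id, ds, base) {
    n <- 30
    acc <- base + cumsum(rnorm(n, 0, 0.02))
    data.frame(individual_id = id, dataset = ds, method = "knn",
               target_index = seq_len(n) + 1, target_time = seq_len(n),
               bc_similarity = pmin(pmax(acc, 0.01), 0.99),
               gap_prev = 1, gap_next = 1, n_samples_available = n + 1,
               failed = FALSE, message = "")
  }
  recs <- rbind(mk("a1", "d1", 0.9), mk("a2", "d1", 0.6),
                mk("b1", "d2", 0.75), mk("b2", "d2", 0.45))
  out <- neighborContextCorrelation(recs, seed = 7, nDraws = 5)
  expect_identical(out, neighborContextCorrelation(recs, seed = 7, nDraws = 5))
  r <- setNames(out$r, out$context)
  expect_gt(r[["adjacent"]], r[["other_dataset"]])

  # identical accuracies everywhere: no variance, correlations undefined
  recs$bc_similarity <- 0.5
  flat <- neighborContextCorrelation(recs, seed = 7)
  expect_true(all(is.nan(flat$r)))
})

test_that("diversity-accuracy correlation matches the closed-form Pearson", {
  div <- c(1.2, 1.5, 1.9, 2.3, 2.8)
  acc <- c(0.52, 0.60, 0.71, 0.68, 0.90)
  actual <- t(vapply(div, function(d) {
    # two-taxon composition with the requested Shannon diversity is not
    # attainable above ln 2, so use a direct 3-taxon construction
    p <- exp(-d)
    c(p, (1 - p) * 0.6, (1 - p) * 0.4)
  }, numeric(3)))
  # recompute the true diversities of the constructed compositions
  div2 <- apply(actual, 1, shannonDiversity)
  recs <- data.frame(individual_id = "a", dataset = NA, method = "knn",
                     target_index = 2:6, target_time = 1:5,
                     bc_similarity = acc, gap_prev = 1, gap_next = 1,
                     n_samples_available = 7, failed = FALSE, message = "")
  ev <- new("LooEvaluation", records = recs, predicted = actual,
            actual = actual, relativeErrors = actual * 0,
            taxa = c("A", "B", "C"))
  out <- diversityAccuracyCorrelation(list(ev))
  num <- sum((div2 - mean(div2)) * (acc - mean(acc)))
  den <- sqrt(sum((div2 - mean(div2))^2) * sum((acc - mean(acc))^2))
  expect_equal(out$r, num / den, tolerance = 1e-12)
})

test_that("method agreement is a unit-diagonal symmetric matrix with exact extremes", {
  mk <- function(m, accs) {
    do.call(rbind, lapply(seq_along(accs), function(i)
      data.frame(individual_id = paste0("i", i), dataset = NA, method = m,
                 target_index = 2:4, target_time = 1:3,
                 bc_similarity = accs[i] + c(-0.01, 0, 0.01),
                 gap_prev = 1, gap_next = 1, n_samples_available = 9,
                 failed = FALSE, message = "")))
  }
  a <- c(0.5, 0.7, 0.9)
  recs <- rbind(mk("m1", a), mk("m2", a), mk("m3", 1 - a))
  cc <- methodAgreement(recs)
  expect_equal(diag(cc), setNames(rep(1, 3), c("m1", "m2", "m3")))
  expect_equal(cc, t(cc))
  expect_equal(cc["m1", "m2"], 1)
  expect_equal(cc["m1", "m3"], -1)
  # hand-computed Pearson for a 3-individual table
  b <- c(0.6, 0.65, 0.95)
  cc2 <- methodAgreement(rbind(mk("m1", a), mk("m4", b)))
  expect_equal(cc2["m1", "m4"], cor(a, b), tolerance = 1e-12)
})
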
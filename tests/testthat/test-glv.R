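test_that("regression matrices have the documented shape and zero F on constants", {
  m <- matrix(rep(c(0.5, 0.3, 0.2), 6), 6, byrow = TRUE,
              dimnames = list(NULL, c("A", "B", "C")))
  p <- LongitudinalProfile(m, times = cumsum(c(0, runif(5, 0.5, 2))),
                           individualId = "x")
  mats <- buildGLVRegression(p)
  expect_equal(dim(mats@F), c(3L, 5L))
  expect_equal(dim(mats@Y), c(4L, 5L))
  expect_true(all(mats@Y[4L, ] == 1))
  expect_true(all(mats@F == 0))
  expect_equal(mats@pairDeltas, diff(sampleTimes(p)))
  expect_true(validObject(mats))
  expect_error(buildGLVRegression(m[1, , drop = FALSE], times = 0), "at least 2")
})

test_that("exponential growth of a single taxon gives F identically beta", {
  beta <- 0.37
  tms <- cumsum(c(0, runif(9, 0.3, 2.1)))
  x <- matrix(0.2 * exp(beta * tms), ncol = 1,
              dimnames = list(NULL, "t1"))
  mats <- buildGLVRegression(x, times = tms)
  # F = beta + alpha * x; with alpha unknown the pure-growth check needs
  # alpha = 0, i.e. F - beta must vanish identically
  expect_lt(max(abs(mats@F - beta)), 1e-10)
})

test_that("least-squares estimator recovers noise-free gLV parameters", {
  sys <- oscillatorSystem()
  sim <- simulateGLVProfile(sys$model, sys$x0, sys$times, noiseSd = 0,
                            closure = FALSE)
  mats <- buildGLVRegression(sim)
  fit <- fitGLVMSE(mats)
  expect_lt(max(abs(fit@A - sys$A)), 1e-6)
  expect_lt(max(abs(fit@B - sys$B)), 1e-6)
})

test_that("zero F yields zero parameters and duplicates give the minimum norm fit", {
  mats <- new("GLVRegression",
              F = matrix(0, 2, 5),
              Y = rbind(matrix(runif(10), 2, 5), 1),
              pairDeltas = rep(1, 5), taxa = c("A", "B"))
  fit <- fitGLVMSE(mats)
  expect_true(all(fit@A == 0) && all(fit@B == 0))

  # duplicated design columns with consistent responses: residual must be
  # zero and the solution must match the pseudoinverse oracle
  Y <- cbind(c(0.4, 0.6, 1), c(0.4, 0.6, 1), c(0.7, 0.3, 1))
  theta0 <- rbind(c(0.2, -0.1, 0.05), c(0.0, 0.3, -0.2))
  F <- theta0 %*% Y
  mats2 <- new("GLVRegression", F = F, Y = Y, pairDeltas = rep(1, 3),
               taxa = c("A", "B"))
  fit2 <- fitGLVMSE(mats2)
  theta <- cbind(fit2@A, fit2@B)
  expect_lt(max(abs(F - theta %*% Y)), 1e-9)
  oracle <- F %*% MASS::ginv(Y)
  expect_lt(max(abs(theta - oracle)), 1e-9)
  expect_error(fitGLVMSE(mats2, strict = TRUE), "rank-deficient")
})

test_that("no small perturbation of the least-squares solution lowers the residual", {
  set.seed(8)
  Y <- rbind(matrix(runif(2 * 8), 2, 8), 1)
  F <- matrix(rnorm(2 * 8), 2, 8)
  fit <- fitGLVMSE(new("GLVRegression", F = F, Y = Y,
                       pairDeltas = rep(1, 8), taxa = c("A", "B")))
  theta <- cbind(fit@A, fit@B)
  base <- sum((F - theta %*% Y)^2)
  for (i in seq_len(nrow(theta))) for (j in seq_len(ncol(theta)))
    for (d in c(-1e-3, 1e-3)) {
      pert <- theta
      pert[i, j] <- pert[i, j] + d
      expect_gte(sum((F - pert %*% Y)^2), base)
    }
})

test_that("ridge estimator matches least squares at lambda 0 and shrinks monotonically", {
  sys <- oscillatorSystem(nTaxa = 3, seed = 5)
  sim <- simulateGLVProfile(sys$model, sys$x0, sys$times[1:20], noiseSd = 0.05,
                            seed = 2, closure = FALSE)
  mats <- buildGLVRegression(sim)
  mse <- fitGLVMSE(mats)
  r0 <- fitGLVMLRR(mats, lambda = 0)
  expect_lt(max(abs(cbind(r0@A, r0@B) - cbind(mse@A, mse@B))), 1e-9)

  norms <- vapply(10^seq(-4, 4), function(l) {
    f <- fitGLVMLRR(mats, lambda = l)
    sqrt(sum(cbind(f@A, f@B)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))

  # ridge residual dominates the least-squares residual, with equality at 0
  resid <- function(fit) sum((mats@F - cbind(fit@A, fit@B) %*% mats@Y)^2)
  expect_gte(resid(fitGLVMLRR(mats, lambda = 3)), resid(mse))
  expect_equal(resid(r0), resid(mse), tolerance = 1e-9)
})

test_that("ridge at a tiny penalty still recovers noise-free parameters", {
  sys <- oscillatorSystem()
  sim <- simulateGLVProfile(sys$model, sys$x0, sys$times, noiseSd = 0,
                            closure = FALSE)
  fit <- fitGLVMLRR(buildGLVRegression(sim), lambda = 1e-8)
  expect_lt(max(abs(fit@A - sys$A)), 1e-4)
  expect_lt(max(abs(fit@B - sys$B)), 1e-4)
})

limitsOracleR <- function(mats, splits, thresh) {
  # naive R reimplementation of the bootstrap forward selection
  Yt <- t(mats@Y)
  q <- ncol(Yt)
  n <- nrow(mats@F)
  theta <- matrix(0, n, q)
  for (i in seq_len(n)) {
    boots <- matrix(0, q, ncol(splits))
    for (b in seq_len(ncol(splits))) {
      tr <- which(splits[, b] == 1)
      te <- which(splits[, b] == 0)
      active <- unique(c(q, i))
      fitErr <- function(act) {
        cf <- qr.coef(qr(Yt[tr, act, drop = FALSE]), mats@F[i, tr])
        cf[is.na(cf)] <- 0
        list(cf = cf,
             err = mean((mats@F[i, te] - Yt[te, act, drop = FALSE] %*% cf)^2))
      }
      cur <- fitErr(active)
      repeat {
        if (length(active) >= min(q, length(tr)) || cur$err <= 0) break
        cands <- setdiff(seq_len(q), active)
        trials <- lapply(cands, function(c) fitErr(c(active, c)))
        errs <- vapply(trials, `[[`, numeric(1), "err")
        best <- which.min(errs)
        if ((cur$err - errs[best]) / cur$err < thresh) break
        active <- c(active, cands[best])
        cur <- trials[[best]]
      }
      # coefficients re-estimated on all pairs over the selected support
      cfAll <- qr.coef(qr(Yt[, active, drop = FALSE]), mats@F[i, ])
      cfAll[is.na(cfAll)] <- 0
      boots[active, b] <- cfAll
    }
    theta[i, ] <- apply(boots, 1, median)
  }
  theta
}

test_that("the compiled LIMITS search matches a naive R implementation", {
  sys <- oscillatorSystem(nTaxa = 3, seed = 17)
  sim <- simulateGLVProfile(sys$model, sys$x0, sys$times[1:15], noiseSd = 0.1,
                            seed = 4, closure = FALSE)
  mats <- buildGLVRegression(sim)
  p <- ncol(mats@Y)
  set.seed(99)
  splits <- matrix(0L, p, 5)
  for (b in 1:5) splits[sample.int(p, floor(p / 2)), b] <- 1L
  got <- micropolate:::cpp_limits_fit(t(mats@Y), mats@F, splits, 1e-3)
  want <- limitsOracleR(mats, splits, 1e-3)
  expect_lt(max(abs(got - want)), 1e-8)
})

test_that("LIMITS keeps a diagonal system sparse and is seed-reproducible", {
  set.seed(21)
  nt <- 5
  A <- diag(-1, nt)
  xstar <- runif(nt, 0.6, 1.4)
  gen <- new("GLVModel", A = A, B = -drop(A %*% xstar),
             taxa = paste0("t", 1:nt), estimator = "mse")
  sim <- simulateGLVProfile(gen, xstar * exp(runif(nt, -0.4, 0.4)),
                            cumsum(c(0, runif(60, 0.3, 0.9))),
                            noiseSd = 0.01, seed = 4, closure = FALSE)
  mats <- buildGLVRegression(sim)
  fit <- fitGLVLIMITS(mats, seed = 31)
  off <- fit@A[row(fit@A) != col(fit@A)]
  expect_gte(mean(off == 0), 0.9)

  again <- fitGLVLIMITS(mats, seed = 31)
  expect_identical(cbind(fit@A, fit@B), cbind(again@A, again@B))
  one <- fitGLVLIMITS(mats, nBootstrap = 1, seed = 12)
  expect_identical(one@A, fitGLVLIMITS(mats, nBootstrap = 1, seed = 12)@A)
})

test_that("LIMITS detects a strong pairwise interaction with the right sign", {
  hits <- 0
  for (s in 1:20) {
    set.seed(300 + s)
    nt <- 4
    A <- diag(-1, nt)
    A[1, 2] <- 2    # strong positive effect of taxon 2 on taxon 1
    xstar <- runif(nt, 0.6, 1.2)
    gen <- new("GLVModel", A = A, B = -drop(A %*% xstar),
               taxa = paste0("t", 1:nt), estimator = "mse")
    sim <- try(simulateGLVProfile(gen, xstar * exp(runif(nt, -0.3, 0.3)),
                                  cumsum(c(0, runif(50, 0.3, 0.9))),
                                  noiseSd = 0.05, seed = s, closure = FALSE),
               silent = TRUE)
    if (inherits(sim, "try-error")) next
    fit <- fitGLVLIMITS(buildGLVRegression(sim), seed = s)
    if (fit@A[1, 2] > 0) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.9)
})

test_that("LIMITS support size does not grow with the improvement threshold", {
  sys <- oscillatorSystem(nTaxa = 4, seed = 23)
  sim <- simulateGLVProfile(sys$model, sys$x0, sys$times[1:25], noiseSd = 0.1,
                            seed = 9, closure = FALSE)
  mats <- buildGLVRegression(sim)
  sizes <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1), function(th) {
    f <- fitGLVLIMITS(mats, improvementThreshold = th, seed = 44)
    sum(cbind(f@A, f@B) != 0)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("one-step forecasts behave analytically and reproduce held-out samples", {
  # A = 0, B = 0: the previous composition is returned unchanged
  id <- new("GLVModel", A = matrix(0, 2, 2), B = c(0, 0),
            taxa = c("A", "B"), estimator = "mse")
  expect_equal(unname(predictGLV(id, c(0.3, 0.7), 2)), c(0.3, 0.7),
               ignore_attr = TRUE)

  # pure growth: the log-ratio between taxa moves by exactly beta * dt
  gr <- new("GLVModel", A = matrix(0, 2, 2), B = c(0.4, 0),
            taxa = c("A", "B"), estimator = "mse")
  out <- predictGLV(gr, c(0.5, 0.5), deltaT = 3)
  expect_equal(log(out[["A"]] / out[["B"]]), 0.4 * 3)

  # self-consistency on the noise-free oracle series
  sys <- oscillatorSystem()
  sim <- simulateGLVProfile(sys$model, sys$x0, sys$times, noiseSd = 0,
                            closure = FALSE)
  fit <- fitGLVMSE(buildGLVRegression(sim))
  for (i in c(5, 17, 33)) {
    pred <- predictGLV(fit, sim$abundances[i, ],
                       sys$times[i + 1] - sys$times[i])
    truth <- sim$abundances[i + 1, ] / sum(sim$abundances[i + 1, ])
    expect_lt(max(abs(pred - truth)), 1e-6)
  }

  # explosive parameters are clamped and flagged rather than overflowing
  boom <- new("GLVModel", A = matrix(0, 2, 2), B = c(1e4, 0),
              taxa = c("A", "B"), estimator = "mse")
  out2 <- predictGLV(boom, c(0.5, 0.5), 10)
  expect_true(attr(out2, "clamped"))
  expect_true(all(is.finite(out2)))
  expect_error(predictGLV(id, c(0.2, 0.3, 0.5), 1), "mismatch")
})

test_that("gLV parameters serialize to a labelled delimited table", {
  sys <- oscillatorSystem(nTaxa = 3, seed = 2)
  path <- tempfile(fileext = ".tsv")
  writeGLVModel(sys$model, path)
  tab <- read.delim(path)
  expect_equal(tab$taxon, sys$model@taxa)
  expect_equal(as.numeric(tab$growth_rate), sys$B, tolerance = 1e-12)
  unlink(path)
})
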
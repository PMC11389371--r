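# shared fixtures: all built in code, nothing on disk

# small hand profile: 3 taxa, 5 samples, strictly on the simplex
handProfile <- function() {
  m <- rbind(c(0.5, 0.3, 0.2),
             c(0.6, 0.2, 0.2),
             c(0.4, 0.4, 0.2),
             c(0.3, 0.5, 0.2),
             c(0.5, 0.25, 0.25))
  colnames(m) <- c("A", "B", "C")
  LongitudinalProfile(m, times = c(0, 2, 5, 9, 12), individualId = "hand")
}

# random simplex profile with given dims
randomProfile <- function(nSamples, nTaxa, seed, id = "rand") {
  set.seed(seed)
  m <- matrix(rgamma(nSamples * nTaxa, shape = 0.8), nSamples, nTaxa)
  colnames(m) <- sprintf("t%02d", seq_len(nTaxa))
  LongitudinalProfile(m, times = cumsum(c(0, runif(nSamples - 1, 0.5, 2))),
                      individualId = id)
}

# noise-free gLV oracle system: damped rotation around a positive
# equilibrium keeps abundances O(1) and the design well conditioned
oscillatorSystem <- function(nTaxa = 5, seed = 42) {
  set.seed(seed)
  M <- matrix(rnorm(nTaxa^2, 0, 0.25), nTaxa, nTaxa)
  A <- M - t(M)
  diag(A) <- -0.4
  xstar <- runif(nTaxa, 0.6, 1.4)
  B <- -drop(A %*% xstar)
  taxa <- paste0("t", seq_len(nTaxa))
  dimnames(A) <- list(taxa, taxa)
  list(model = new("GLVModel", A = A, B = B, taxa = taxa, estimator = "mse"),
       A = A, B = B, xstar = xstar,
       x0 = xstar * exp(runif(nTaxa, -0.5, 0.5)),
       times = cumsum(c(0, runif(39, 0.3, 0.8))))
}

# memoised default synthetic cohort + per-method LOO (shared by the
# qualitative acceptance checks so the heavy fits run once per session)
.cohortCache <- new.env(parent = emptyenv())

cachedCohort <- function() {
  if (is.null(.cohortCache$cohort))
    .cohortCache$cohort <- simulateCohort(syntheticConfig())
  .cohortCache$cohort
}

cachedLoo <- function(method, params = list()) {
  key <- paste0("loo_", method)
  if (is.null(.cohortCache[[key]])) {
    co <- cachedCohort()
    .cohortCache[[key]] <- lapply(co$profiles, looEvaluate, method = method,
                                  params = params, seed = 707)
  }
  .cohortCache[[key]]
}

meanAccuracyByRegime <- function(evals, cohort) {
  acc <- vapply(evals, function(e) {
    r <- records(e)
    mean(r$bc_similarity[!r$failed], na.rm = TRUE)
  }, numeric(1))
  reg <- vapply(cohort$profiles, datasetLabel, "")
  list(adult = mean(acc[reg == "adult_stable"]),
       infant = mean(acc[reg == "infant_successional"]),
       pooled = mean(acc), perIndividual = acc)
}
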
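#' Configuration for the synthetic cohort generator
#'
#' Returns the default study conditions emulated by [simulateCohort()]:
#' a cohort of 31-taxon profiles (30 named taxa plus an `"others"`
#' stand-in), irregular near-daily sampling, two dynamic regimes (densely
#' sampled stable adults vs successional infants), and a set of
#' conditionally present taxa that switch on and off and are bimodal by
#' construction. All values can be overridden by name.
#'
#' @param nIndividuals individuals per regime, as
#'   `c(adult_stable = , infant_successional = )`.
#' @param nTaxa total taxon count including the `"others"` stand-in.
#' @param nSamplesRange inclusive range of per-individual sample counts.
#' @param meanInterval mean sampling interval (days); intervals are drawn
#'   from a Gamma distribution (shape `intervalShape`) with this mean, so
#'   sampling is irregular.
#' @param intervalShape Gamma shape of the interval distribution (larger =
#'   more regular sampling).
#' @param selfInteraction strength of the stabilizing self-interaction
#'   (per day, per unit abundance); the diagonal of the interaction matrix
#'   is `-selfInteraction`.
#' @param interactionScale standard deviation of the off-diagonal
#'   interactions.
#' @param processNoiseSd per-day standard deviation of the log-scale
#'   process noise, as `c(adult_stable = , infant_successional = )`.
#' @param nConditionalTaxa number of conditionally present (on/off) taxa.
#' @param conditionalSwitchRate per-day on/off switching rate of the
#'   conditional taxa.
#' @param successionStrength infant regime: scale of the logistic hand-off
#'   between the early and late equilibrium communities (fraction of the
#'   sampling span used as the transition width).
#' @param composition log-normal sd of the equilibrium composition draw,
#'   per regime (larger = more uneven, lower-diversity communities; infant
#'   guts are typically dominated by fewer taxa than adult guts).
#' @param seed integer seed.
#' @return named list of generator settings.
#' @export
syntheticConfig <- function(nIndividuals = c(adult_stable = 10, infant_successional = 10),
                            nTaxa = 31,
                            nSamplesRange = c(20, 30),
                            meanInterval = 1.5,
                            intervalShape = 3,
                            selfInteraction = 10,
                            interactionScale = 1,
                            processNoiseSd = c(adult_stable = 0.12,
                                               infant_successional = 0.4),
                            nConditionalTaxa = 6,
                            conditionalSwitchRate = 0.12,
                            successionStrength = 0.12,
                            composition = c(adult_stable = 1,
                                            infant_successional = 1.6),
                            seed = 20260101) {
  cfg <- list(nIndividuals = nIndividuals, nTaxa = nTaxa,
              nSamplesRange = nSamplesRange, meanInterval = meanInterval,
              intervalShape = intervalShape,
              selfInteraction = selfInteraction,
              interactionScale = interactionScale,
              processNoiseSd = processNoiseSd,
              nConditionalTaxa = nConditionalTaxa,
              conditionalSwitchRate = conditionalSwitchRate,
              successionStrength = successionStrength,
              composition = composition, seed = seed)
  stopifnot(all(cfg$nIndividuals >= 0), sum(cfg$nIndividuals) >= 1,
            cfg$nTaxa >= 3,
            all(cfg$nSamplesRange >= 4), cfg$meanInterval > 0,
            all(cfg$processNoiseSd >= 0), cfg$nConditionalTaxa >= 0,
            cfg$nConditionalTaxa <= cfg$nTaxa - 2)
  cfg
}

# core stepper: forward Euler on log-abundances; B may be a matrix with one
# row per step for time-varying growth rates
glvStep <- function(A, B, x, dt, noise) {
  lx <- log(x) + dt * (B + drop(A %*% x)) + noise
  if (any(!is.finite(lx)) || any(abs(lx) > 500))
    stop("numerical blow-up in gLV simulation step")
  exp(lx)
}

#' Simulate a longitudinal profile from gLV dynamics
#'
#' Forward Euler integration of the discretized generalized Lotka-Volterra
#' model on the log scale over the given sampling times, with Gaussian
#' process noise of per-step variance `noiseSd^2 * dt` (a diffusion
#' scaling, so longer gaps accumulate more drift). With `closure = TRUE`
#' (the default, mirroring what 16S feature tables provide) every state is
#' renormalized to the simplex and a [LongitudinalProfile-class] is
#' returned. `closure = FALSE` is an absolute-abundance test mode for
#' analytic validation of the estimators: the raw (unnormalized) series
#' and times are returned as a list, and the regression built from it by
#' [buildGLVRegression()] reproduces the generating parameters exactly at
#' zero noise.
#'
#' @param params a [GLVModel-class] holding the generating `A` and `B`.
#' @param x0 initial composition (positive entries).
#' @param times strictly increasing sampling days.
#' @param noiseSd per-day log-scale process noise (0 = deterministic).
#' @param seed optional integer seed.
#' @param closure renormalize every state to the simplex (default `TRUE`).
#' @param individualId,dataset labels for the returned profile.
#' @return a `LongitudinalProfile`, or (with `closure = FALSE`) a list with
#'   elements `abundances` and `times`.
#' @export
simulateGLVProfile <- function(params, x0, times, noiseSd = 0, seed = NULL,
                               closure = TRUE, individualId = "sim",
                               dataset = NA_character_) {
  stopifnot(is(params, "GLVModel"), all(diff(times) > 0), noiseSd >= 0,
            all(x0 > 0), length(x0) == length(params@taxa))
  if (!is.null(seed)) set.seed(seed)
  n <- length(times)
  nt <- length(x0)
  out <- matrix(NA_real_, n, nt, dimnames = list(NULL, params@taxa))
  x <- if (closure) x0 / sum(x0) else x0
  out[1L, ] <- x
  for (k in seq_len(n - 1L)) {
    dt <- times[k + 1L] - times[k]
    noise <- if (noiseSd > 0) stats::rnorm(nt, 0, noiseSd * sqrt(dt)) else 0
    x <- tryCatch(glvStep(params@A, params@B, x, dt, noise),
                  error = function(e)
                    stop("simulation failed at step ", k, " (t = ",
                         format(times[k + 1L]), "): ", conditionMessage(e)))
    if (closure) x <- x / sum(x)
    out[k + 1L, ] <- x
  }
  if (!closure) return(list(abundances = out, times = times))
  LongitudinalProfile(out, times = times, individualId = individualId,
                      dataset = dataset)
}

# draw a random equilibrium composition and the interaction matrix pinned
# to it (B = -A x* makes x* a fixed point of the log-rates)
glvSystemForEquilibrium <- function(nTaxa, selfInteraction, interactionScale,
                                    compositionSd, taxaNames) {
  xstar <- exp(stats::rnorm(nTaxa, 0, compositionSd))
  xstar <- xstar / sum(xstar)
  A <- matrix(stats::rnorm(nTaxa^2, 0, interactionScale), nTaxa, nTaxa)
  diag(A) <- -selfInteraction
  dimnames(A) <- list(taxaNames, taxaNames)
  B <- -drop(A %*% xstar)
  list(A = A, B = B, xstar = xstar)
}

#' Simulate a synthetic longitudinal cohort
#'
#' Generates one [LongitudinalProfile-class] per individual under the study
#' conditions of [syntheticConfig()]. Adult-regime individuals follow
#' stable gLV dynamics around a fixed equilibrium community with low
#' process noise; infant-regime individuals undergo a monotone successional
#' hand-off between an "early" and a "late" equilibrium community (logistic
#' in time) with higher noise. A subset of taxa is conditionally present:
#' a two-state Markov process switches them on and off, and their abundance
#' is zeroed while off, producing bimodal, hard-to-interpolate behaviour.
#' Each state is closed to the simplex, as in real 16S feature tables.
#'
#' @param config a list from [syntheticConfig()].
#' @return list with `profiles` (list of `LongitudinalProfile`) and
#'   `truth`, a per-individual ledger of generating parameters (regime,
#'   `A`, `B`, equilibria, conditional taxa, noise level, seed).
#' @export
simulateCohort <- function(config = syntheticConfig()) {
  set.seed(config$seed)
  nt <- config$nTaxa
  taxaNames <- c(sprintf("taxon_%02d", seq_len(nt - 1L)), "others")
  profiles <- list()
  truth <- list()
  regimes <- rep(names(config$nIndividuals), config$nIndividuals)
  for (ix in seq_along(regimes)) {
    regime <- regimes[ix]
    id <- sprintf("%s_%02d", ifelse(regime == "adult_stable", "adult", "infant"),
                  sum(regimes[seq_len(ix)] == regime))
    nChoices <- seq(config$nSamplesRange[1L], config$nSamplesRange[2L])
    n <- nChoices[sample.int(length(nChoices), 1L)]
    gaps <- stats::rgamma(n - 1L, shape = config$intervalShape,
                          scale = config$meanInterval / config$intervalShape)
    times <- cumsum(c(0, pmax(gaps, 0.05)))
    noiseSd <- config$processNoiseSd[[regime]]

    compSd <- if (length(config$composition) > 1L)
      config$composition[[regime]] else config$composition
    sys <- glvSystemForEquilibrium(nt, config$selfInteraction,
                                   config$interactionScale,
                                   compSd, taxaNames)
    late <- NULL
    x <- sys$xstar
    ab <- matrix(NA_real_, n, nt, dimnames = list(NULL, taxaNames))
    if (regime == "infant_successional") {
      late <- glvSystemForEquilibrium(nt, config$selfInteraction,
                                      config$interactionScale,
                                      compSd, taxaNames)
      span <- max(times)
      midpoint <- span / 2
      width <- max(config$successionStrength * span, 1e-6)
    }
    # conditional (on/off) taxa: drawn from the lower-abundance half so
    # rarity and bimodality co-occur, never the "others" stand-in
    pool <- order(sys$xstar[seq_len(nt - 1L)])[seq_len(ceiling((nt - 1L) / 2))]
    conditional <- sort(sample(pool, min(config$nConditionalTaxa, length(pool))))
    on <- stats::runif(length(conditional)) < 0.5

    mask <- function(xrow, on) {
      if (length(conditional)) xrow[conditional][!on] <- 0
      xrow / sum(xrow)
    }
    ab[1L, ] <- mask(x, on)
    for (k in seq_len(n - 1L)) {
      dt <- times[k + 1L] - times[k]
      B <- sys$B
      if (regime == "infant_successional") {
        w <- 1 / (1 + exp(-(times[k] - midpoint) / width))
        B <- -drop(sys$A %*% ((1 - w) * sys$xstar + w * late$xstar))
      }
      noise <- stats::rnorm(nt, 0, noiseSd * sqrt(dt))
      x <- glvStep(sys$A, B, x, dt, noise)
      x <- x / sum(x)
      if (length(conditional)) {
        pSwitch <- 1 - exp(-config$conditionalSwitchRate * dt)
        flip <- stats::runif(length(conditional)) < pSwitch
        on <- xor(on, flip)
      }
      ab[k + 1L, ] <- mask(x, on)
    }
    profiles[[id]] <- LongitudinalProfile(ab, times = times, individualId = id,
                                          dataset = regime)
    truth[[id]] <- list(regime = regime, A = sys$A, B = sys$B,
                        equilibrium = sys$xstar,
                        lateEquilibrium = if (is.null(late)) NULL else late$xstar,
                        conditionalTaxa = taxaNames[conditional],
                        noiseSd = noiseSd, nSamples = n)
  }
  list(profiles = profiles, truth = truth)
}

#' Remove a random fraction of interior samples
#'
#' The two endpoint samples are always retained. Returns the reduced
#' profile together with a ledger of the removed times and their true
#' compositions, for scoring imputations.
#'
#' @param profile a [LongitudinalProfile-class].
#' @param fraction fraction of interior samples to remove, in `[0, 1)`.
#' @param seed optional integer seed.
#' @return list with `profile` (reduced) and `removed` (data.frame of
#'   `index`, `time` plus the true composition columns).
#' @export
injectMissingness <- function(profile, fraction, seed = NULL) {
  stopifnot(is(profile, "LongitudinalProfile"),
            fraction >= 0, fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nSamples(profile)
  interior <- seq(2L, n - 1L)
  nRemove <- floor(fraction * length(interior))
  if (n - nRemove < 3L)
    stop("removal would leave fewer than 3 samples")
  removed <- sort(interior[sample.int(length(interior), nRemove)])
  ab <- abundanceMatrix(profile)
  ledger <- data.frame(index = removed, time = sampleTimes(profile)[removed])
  ledger <- cbind(ledger, as.data.frame(ab[removed, , drop = FALSE]))
  reduced <- if (nRemove) subsetSamples(profile, setdiff(seq_len(n), removed))
             else profile
  list(profile = reduced, removed = ledger)
}

#' Simulate feature tables from a known accuracy model
#'
#' Draws covariates and a logit-scale response from the accuracy model's
#' own generative form (`logit_bc = intercept + X beta + b_i + e`), for
#' parameter-recovery and Wald-calibration checks of [fitAccuracyLMM()].
#' Columns not named in `coefficients` receive a zero (null) effect.
#'
#' @param nIndividuals number of individuals (random-intercept groups).
#' @param nPerIndividual feature rows per individual.
#' @param coefficients named vector over
#'   `c("(Intercept)", "gap_prev", "gap_next", "logit_bc_prev",
#'   "logit_bc_next", "n_samples")` (missing names default to 0).
#' @param reSd standard deviation of the random intercepts.
#' @param residSd residual standard deviation.
#' @param seed integer seed.
#' @return a feature data.frame compatible with [fitAccuracyLMM()].
#' @export
simulateAccuracyData <- function(nIndividuals = 20, nPerIndividual = 30,
                                 coefficients = c("(Intercept)" = 1,
                                                  gap_prev = -0.15,
                                                  gap_next = -0.1,
                                                  logit_bc_prev = 0.3,
                                                  logit_bc_next = 0.25),
                                 reSd = 0.4, residSd = 0.5, seed = 1L) {
  set.seed(seed)
  full <- c("(Intercept)" = 0, gap_prev = 0, gap_next = 0,
            logit_bc_prev = 0, logit_bc_next = 0, n_samples = 0)
  full[names(coefficients)] <- coefficients
  rows <- lapply(seq_len(nIndividuals), function(i) {
    b <- stats::rnorm(1, 0, reSd)
    nsamp <- sample(20:60, 1L)
    d <- data.frame(
      individual_id = sprintf("ind_%02d", i),
      target_time = seq_len(nPerIndividual),
      n_samples = nsamp,
      gap_prev = stats::rgamma(nPerIndividual, 3, 2),
      gap_next = stats::rgamma(nPerIndividual, 3, 2),
      logit_bc_prev = stats::rnorm(nPerIndividual, 1.5, 1),
      logit_bc_next = stats::rnorm(nPerIndividual, 1.5, 1),
      stringsAsFactors = FALSE)
    eta <- full[["(Intercept)"]] +
      full[["gap_prev"]] * d$gap_prev + full[["gap_next"]] * d$gap_next +
      full[["logit_bc_prev"]] * d$logit_bc_prev +
      full[["logit_bc_next"]] * d$logit_bc_next +
      full[["n_samples"]] * d$n_samples
    d$logit_bc <- eta + b + stats::rnorm(nPerIndividual, 0, residSd)
    d$bc_similarity <- 1 / (1 + exp(-d$logit_bc))
    d
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "clipEpsilon") <- 1e-3
  out
}
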
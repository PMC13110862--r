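# Benchmark-concentration estimation: BMC at a benchmark response of 1
# residual SD, profile-likelihood confidence limits, nested-LRT + AIC model
# selection, reliability filters, and distribution summaries.

.CHI2_PROFILE <- stats::qchisq(0.90, df = 1)  # one-sided 95% limits

#' Benchmark concentration from a fitted model
#'
#' Smallest d > 0 within the dose range where the fitted mean response
#' departs from the control response by `bmrSd` residual SDs:
#' `|f(d) - f(0)| = bmrSd * sigmaHat`. Linear and Hill are inverted in
#' closed form; the other models use bracketed root-finding on a dense
#' monotone-segment-aware grid (log- and linearly-spaced), taking the
#' smallest positive root. The residual SD is floored at 1e-6 so noiseless
#' fixtures do not collapse to BMC = 0.
#'
#' @param fit a converged [DoseResponseFit-class].
#' @param bmrSd benchmark response in residual-SD units (default 1).
#' @param doseRange numeric length 2; defaults to (0, max fitted dose\].
#' @return positive numeric (nM), or `NA_real_` when the response never
#'   reaches the benchmark within range (the endpoint is then dropped).
#' @examples
#' d <- rep(c(0, 10, 100, 1000), each = 4)
#' f <- fitModel("Linear", d, 8 + 0.01 * d)
#' bmcFromFit(f)  # ~ sigmaHat / 0.01
#' @export
bmcFromFit <- function(fit, bmrSd = 1, doseRange = NULL) {
  stopifnot(is(fit, "DoseResponseFit"))
  if (!fit@converged) stop("bmcFromFit needs a converged fit")
  if (is.null(doseRange)) doseRange <- c(0, max(fit@doses))
  maxd <- doseRange[2L]
  target <- bmrSd * max(fit@sigmaHat, 1e-6)
  p <- as.list(fit@params)
  d <- switch(fit@modelId,
    Linear = if (p$beta1 == 0) NA_real_ else target / abs(p$beta1),
    Hill = {
      x <- target / abs(p$v)
      if (x >= 1) NA_real_ else p$k * (x / (1 - x))^(1 / p$n)
    },
    { # Poly2/Poly3/Exp3/Exp5: first crossing of |f(d) - f(0)| = target
      f0 <- evaluateModel(fit@modelId, p, 0)
      g <- function(dd) abs(evaluateModel(fit@modelId, p, dd) - f0) - target
      grid <- sort(unique(c(
        exp(seq(log(maxd * 1e-8), log(maxd), length.out = 1200L)),
        seq(maxd / 1200, maxd, length.out = 1200L))))
      gv <- g(grid)
      idx <- which(gv >= 0)
      if (!length(idx)) NA_real_
      else {
        i <- idx[1L]
        if (i == 1L) grid[1L]
        else stats::uniroot(g, c(grid[i - 1L], grid[i]),
                            tol = maxd * 1e-10)$root
      }
    })
  if (!is.na(d) && (d <= 0 || d > maxd)) d <- NA_real_
  d
}

# ---------------------------------------------------------------------------
# Profile likelihood: re-parameterize each model so the BMC is a free
# parameter b. One amplitude-like parameter is eliminated by the benchmark
# constraint |f(b) - f(0)| = bmrSd * sigma; the remaining mean parameters
# plus sigma are profiled out numerically.
# ---------------------------------------------------------------------------

# free-theta layout per model: all on optimization scale (log where noted)
.profileSetup <- function(fit, bmrSd) {
  p <- as.list(fit@params)
  sig0 <- max(fit@sigmaHat, 1e-6)
  f0 <- evaluateModel(fit@modelId, p, 0)
  mid <- fit@doses[fit@doses > 0]
  bmcHat <- bmcFromFit(fit, bmrSd)
  dirSign <- sign(evaluateModel(fit@modelId, p,
                                if (is.na(bmcHat)) max(fit@doses) else bmcHat)
                  - f0)
  if (dirSign == 0) dirSign <- 1
  switch(fit@modelId,
    Linear = list(
      theta0 = c(p$beta0, log(sig0)),
      lower = c(-Inf, log(1e-8)), upper = c(Inf, log(1e3)),
      toParams = function(th, b, sigma)
        list(beta0 = th[1L], beta1 = dirSign * bmrSd * sigma / b)),
    Poly2 = list(
      theta0 = c(p$beta0, p$beta2, log(sig0)),
      lower = c(-Inf, -Inf, log(1e-8)), upper = c(Inf, Inf, log(1e3)),
      toParams = function(th, b, sigma)
        list(beta0 = th[1L],
             beta1 = (dirSign * bmrSd * sigma - th[2L] * b^2) / b,
             beta2 = th[2L])),
    Poly3 = list(
      theta0 = c(p$beta0, p$beta2, p$beta3, log(sig0)),
      lower = c(-Inf, -Inf, -Inf, log(1e-8)),
      upper = c(Inf, Inf, Inf, log(1e3)),
      toParams = function(th, b, sigma)
        list(beta0 = th[1L],
             beta1 = (dirSign * bmrSd * sigma - th[2L] * b^2 -
                      th[3L] * b^3) / b,
             beta2 = th[2L], beta3 = th[3L])),
    Hill = list(
      theta0 = c(p$gamma, log(p$k), p$n, log(sig0)),
      lower = c(-Inf, log(max(fit@doses) * 1e-6),
                min(1, p$n, na.rm = TRUE) * 0.99, log(1e-8)),
      upper = c(Inf, log(max(fit@doses) * 1e3), 18, log(1e3)),
      toParams = function(th, b, sigma) {
        k <- exp(th[2L]); n <- th[3L]
        list(gamma = th[1L],
             v = dirSign * bmrSd * sigma * (k^n + b^n) / b^n,
             k = k, n = n)
      }),
    Exp3 = list(
      theta0 = c(log(p$a), p$g, log(sig0)),
      lower = c(log(1e-6), min(1, p$g) * 0.99, log(1e-8)),
      upper = c(log(1e6), 18, log(1e3)),
      toParams = function(th, b, sigma) {
        a <- exp(th[1L]); g <- th[2L]; tgt <- bmrSd * sigma
        if (p$s > 0) {
          bp <- (log(1 + tgt / a))^(1 / g) / b
        } else {
          if (tgt >= a) return(NULL)
          bp <- (-log(1 - tgt / a))^(1 / g) / b
        }
        list(a = a, b = bp, g = g, s = p$s)
      }),
    Exp5 = list(
      theta0 = c(log(p$a), log(p$c), p$g, log(sig0)),
      lower = c(log(1e-6), log(1e-6), min(1, p$g) * 0.99, log(1e-8)),
      upper = c(log(1e6), log(1e6), 18, log(1e3)),
      toParams = function(th, b, sigma) {
        a <- exp(th[1L]); cpar <- exp(th[2L]); g <- th[3L]
        amp <- a * abs(cpar - 1); tgt <- bmrSd * sigma
        if (tgt >= amp) return(NULL)
        bp <- (-log(1 - tgt / amp))^(1 / g) / b
        list(a = a, b = bp, c = cpar, g = g)
      })
  )
}

# profiled negative log-likelihood at BMC = b (lower is better)
.profileNLL <- function(b, fit, setup, warmEnv, bmrSd) {
  n <- length(fit@responses)
  obj <- function(th) {
    sigma <- exp(th[length(th)])
    pars <- setup$toParams(th[-length(th)], b, sigma)
    if (is.null(pars)) return(1e300)
    mu <- tryCatch(evaluateModel(fit@modelId, pars, fit@doses),
                   error = function(e) NULL)
    if (is.null(mu) || any(!is.finite(mu))) return(1e300)
    sse <- sum((fit@responses - mu)^2)
    n / 2 * log(2 * pi * sigma^2) + sse / (2 * sigma^2)
  }
  starts <- list(setup$theta0)
  if (!is.null(warmEnv$theta)) starts <- c(list(warmEnv$theta), starts)
  best <- NULL
  for (th0 in starts) {
    th0 <- pmin(pmax(th0, setup$lower), setup$upper)
    opt <- tryCatch(
      stats::nlminb(th0, obj, lower = setup$lower, upper = setup$upper,
                    control = list(iter.max = 300L, eval.max = 500L)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) return(1e300)
  warmEnv$theta <- best$par
  best$objective
}

#' Profile-likelihood confidence limits for the BMC
#'
#' Re-parameterizes the fitted model so the BMC is a free parameter and
#' finds the values where the profile deviance `2 (LL_max - LL_profile)`
#' reaches the chi-square(1) 90th percentile, giving one-sided 95% lower and
#' upper bounds (BMCL, BMCU). The profile is scanned outward from the
#' estimate with warm-started re-optimization, and each crossing is refined
#' by root-finding. When the profile never crosses the threshold inside
#' `[dose_min / 1e3, 10 * dose_max]` the limit is reported at that boundary
#' and flagged.
#'
#' @param fit a converged [DoseResponseFit-class] with a defined BMC.
#' @param bmrSd benchmark response in residual-SD units (default 1).
#' @param level kept at 0.95 (each limit a one-sided 95% bound).
#' @return list with `bmcl`, `bmcu`, `lowerAtBoundary`, `upperAtBoundary`.
#' @export
profileCI <- function(fit, bmrSd = 1, level = 0.95) {
  stopifnot(is(fit, "DoseResponseFit"), fit@converged)
  bmcHat <- bmcFromFit(fit, bmrSd)
  if (is.na(bmcHat)) stop("profileCI needs a defined BMC")
  setup <- .profileSetup(fit, bmrSd)
  nllMin <- -fit@logLik
  thr <- .CHI2_PROFILE
  dev <- function(b, warmEnv)
    max(2 * (.profileNLL(b, fit, setup, warmEnv, bmrSd) - nllMin), 0)

  minPos <- min(fit@doses[fit@doses > 0])
  lb <- minPos / 1e3
  ub <- 10 * max(fit@doses)

  scanLimit <- function(fromB, step, bound, lowerSide) {
    warm <- new.env(parent = emptyenv())
    bPrev <- fromB
    dPrev <- dev(bPrev, warm)
    repeat {
      bNext <- bPrev * step
      atBound <- if (lowerSide) bNext <= bound else bNext >= bound
      if (atBound) bNext <- bound
      dNext <- dev(bNext, warm)
      if (dNext >= thr) {
        root <- tryCatch(
          stats::uniroot(function(b) dev(b, warm) - thr,
                         lower = min(bPrev, bNext),
                         upper = max(bPrev, bNext),
                         tol = bmcHat * 1e-4)$root,
          error = function(e) bNext)
        return(list(limit = root, atBoundary = FALSE))
      }
      if (atBound) return(list(limit = bound, atBoundary = TRUE))
      bPrev <- bNext
      dPrev <- dNext
    }
  }
  lo <- scanLimit(bmcHat, 0.75, lb, lowerSide = TRUE)
  hi <- scanLimit(bmcHat, 1.30, ub, lowerSide = FALSE)
  list(bmcl = min(lo$limit, bmcHat), bmcu = max(hi$limit, bmcHat),
       lowerAtBoundary = lo$atBoundary, upperAtBoundary = hi$atBoundary)
}

#' Select the best model by nested likelihood-ratio tests and AIC
#'
#' Within the nested polynomial family (Linear in Poly2 in Poly3) and the
#' nested exponential family (Exp3 in Exp5), likelihood-ratio chi-square
#' tests at `pNested` promote a higher-order member only when it fits
#' significantly better, yielding the simplest adequate member of each
#' family. The family winners plus Hill are then compared by lowest AIC.
#' Exact AIC ties go to the model with fewer parameters, then to a fixed
#' model-id order (Linear, Poly2, Poly3, Exp3, Exp5, Hill). Non-converged
#' candidates are ignored, so adding one never changes the selection.
#'
#' @param fits named list of [DoseResponseFit-class] objects (as returned by
#'   [fitAllModels()]).
#' @param pNested significance cutoff of the nested chi-square test
#'   (default 0.05).
#' @return the selected [DoseResponseFit-class].
#' @export
selectBestModel <- function(fits, pNested = 0.05) {
  fits <- Filter(function(f) isTRUE(f@converged), fits)
  if (!length(fits)) stop("no converged fit to select from")

  familyWinner <- function(members) {
    members <- members[members %in% names(fits)]
    if (!length(members)) return(NULL)
    winner <- members[1L]
    # step up the nesting ladder; stop at the first non-significant
    # promotion (higher orders are not retested against a lower winner)
    for (cand in members[-1L]) {
      dfDiff <- .MODEL_NPAR[[cand]] - .MODEL_NPAR[[winner]]
      lrt <- 2 * (fits[[cand]]@logLik - fits[[winner]]@logLik)
      pval <- stats::pchisq(max(lrt, 0), df = dfDiff, lower.tail = FALSE)
      if (pval >= pNested) break
      winner <- cand
    }
    winner
  }
  candidates <- c(familyWinner(c("Linear", "Poly2", "Poly3")),
                  familyWinner(c("Exp3", "Exp5")),
                  intersect("Hill", names(fits)))
  cf <- fits[candidates]
  aics <- vapply(cf, function(f) f@aic, numeric(1))
  npars <- .MODEL_NPAR[candidates]
  ord <- order(aics, npars, match(candidates, .MODEL_ORDER))
  cf[[ord[1L]]]
}

# ---------------------------------------------------------------------------
# Record-level operations
# ---------------------------------------------------------------------------

#' Fit one endpoint end-to-end to a BMC record
#'
#' Fits the model suite, selects the best model, computes the BMC at
#' `bmrSd` residual SDs and its profile-likelihood limits.
#'
#' @inheritParams fitModel
#' @param endpointId identifier carried into the record.
#' @param models model identifiers to fit.
#' @param bmrSd benchmark response in residual-SD units.
#' @param week exposure week annotation (6 or 12; default NA).
#' @param endpointClass "transcriptomic" or "apical".
#' @return one-row [S4Vectors::DataFrame]: endpoint_id, model_id, bmc, bmcl,
#'   bmcu, loglik, aic, passes_filters (NA until [filterBMCRecords()]),
#'   week, endpoint_class, provenance. `bmc` is `NA` when no converged model
#'   reaches the benchmark within the tested range.
#' @export
fitEndpoint <- function(doses, responses, endpointId = "endpoint",
                        models = .MODEL_ORDER, bmrSd = 1,
                        restricted = TRUE, week = NA_integer_,
                        endpointClass = "transcriptomic") {
  rec <- DataFrame(endpoint_id = endpointId, model_id = NA_character_,
                   bmc = NA_real_, bmcl = NA_real_, bmcu = NA_real_,
                   loglik = NA_real_, aic = NA_real_,
                   passes_filters = NA, week = as.integer(week),
                   endpoint_class = endpointClass, provenance = "uncorrected")
  fits <- fitAllModels(doses, responses, models = models,
                       restricted = restricted)
  best <- tryCatch(selectBestModel(fits), error = function(e) NULL)
  if (is.null(best)) return(rec)
  rec$model_id <- best@modelId
  rec$loglik <- best@logLik
  rec$aic <- best@aic
  b <- bmcFromFit(best, bmrSd)
  if (is.na(b)) return(rec)
  ci <- profileCI(best, bmrSd)
  rec$bmc <- b
  rec$bmcl <- ci$bmcl
  rec$bmcu <- ci$bmcu
  rec
}

#' Fit BMCs for all screened probes of an experiment
#'
#' @param x a [DoseResponseExperiment-class].
#' @param screen optional result of [screenProbes()]; when given only probes
#'   with `passes == TRUE` are fit.
#' @param ... forwarded to [fitEndpoint()] (models, bmrSd, restricted, week,
#'   endpointClass).
#' @return [S4Vectors::DataFrame] of BMC records, one row per fitted probe.
#' @export
fitBMCs <- function(x, screen = NULL, ...) {
  stopifnot(is(x, "DoseResponseExperiment"))
  ids <- rownames(x)
  if (!is.null(screen)) ids <- screen$gene_id[screen$passes]
  doses <- concentrations(x)
  mat <- assay(x)
  recs <- lapply(ids, function(g)
    fitEndpoint(doses, mat[g, ], endpointId = g, ...))
  if (!length(recs)) {
    return(DataFrame(endpoint_id = character(), model_id = character(),
                     bmc = numeric(), bmcl = numeric(), bmcu = numeric(),
                     loglik = numeric(), aic = numeric(),
                     passes_filters = logical(), week = integer(),
                     endpoint_class = character(), provenance = character()))
  }
  do.call(rbind, recs)
}

#' Apply the BMC reliability filters
#'
#' A record is retained iff its BMC does not exceed the tested concentration
#' range (`bmc <= maxDose`) and its confidence-limit ratio is below the
#' cutoff (`bmcu / bmcl < ratioMax`, strict). Sets `passes_filters`; records
#' with undefined BMC fail. Never adds records.
#'
#' @param records [S4Vectors::DataFrame] of BMC records.
#' @param maxDose highest tested concentration (nM).
#' @param ratioMax BMCU/BMCL cutoff (default 40).
#' @return the records with `passes_filters` set.
#' @export
filterBMCRecords <- function(records, maxDose, ratioMax = 40) {
  ok <- !is.na(records$bmc) & records$bmc <= maxDose &
        !is.na(records$bmcl) & !is.na(records$bmcu) &
        records$bmcu / records$bmcl < ratioMax
  records$passes_filters <- ok
  records
}

#' Summarize a BMC (or HED) distribution with a bootstrap CI
#'
#' Point estimate is the median or the 5th percentile (linear interpolation
#' between order statistics, `stats::quantile` type 7; the median of two
#' values is their mean), with a seeded percentile bootstrap 95% CI over
#' records. A single record gives a degenerate CI at its value.
#'
#' @param values numeric vector, or a BMC record [S4Vectors::DataFrame]
#'   (its retained `bmc` column is used).
#' @param stat "median" or "p5".
#' @param bootstrapB bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return list with `estimate`, `ciLow`, `ciHigh`.
#' @examples
#' summarizeBMCs(c(0.8417, 427.1))$estimate  # 213.97 ~ the 214 nM median
#' @export
summarizeBMCs <- function(values, stat = c("median", "p5"),
                          bootstrapB = 1000L, seed = 1L) {
  stat <- match.arg(stat)
  if (is(values, "DataFrame") || is.data.frame(values)) {
    keep <- if (!all(is.na(values$passes_filters)))
      isTRUE_v(values$passes_filters) else !is.na(values$bmc)
    values <- values$bmc[keep]
  }
  values <- sort(as.numeric(values))  # bootstrap is record-order invariant
  if (!length(values)) stop("no records to summarize")
  p <- if (stat == "median") 0.5 else 0.05
  est <- unname(stats::quantile(values, p, type = 7))
  if (length(values) == 1L)
    return(list(estimate = est, ciLow = est, ciHigh = est))
  boot <- withr::with_seed(seed, {
    vapply(seq_len(bootstrapB), function(i)
      unname(stats::quantile(sample(values, replace = TRUE), p, type = 7)),
      numeric(1))
  })
  ci <- unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
  list(estimate = est, ciLow = min(ci[1L], est), ciHigh = max(ci[2L], est))
}

# vectorized isTRUE
isTRUE_v <- function(x) !is.na(x) & x
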
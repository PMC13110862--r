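# The continuous benchmark-dose model suite. Standard forms:
#   Linear  beta0 + beta1 d
#   Poly2   beta0 + beta1 d + beta2 d^2
#   Poly3   beta0 + beta1 d + beta2 d^2 + beta3 d^3
#   Exp3    a * exp(s * (b d)^g),            s in {-1, +1}
#   Exp5    a * (c - (c - 1) exp(-(b d)^g))
#   Hill    gamma + v d^n / (k^n + d^n)
# Nested families used by model selection: Linear < Poly2 < Poly3 and
# Exp3 < Exp5; Hill stands alone.

.MODEL_ORDER <- c("Linear", "Poly2", "Poly3", "Exp3", "Exp5", "Hill")

# mean-model parameter counts (sign s of Exp3 is fixed by the data, not free)
.MODEL_NPAR <- c(Linear = 2L, Poly2 = 3L, Poly3 = 4L,
                 Exp3 = 3L, Exp5 = 4L, Hill = 4L)

.modelFamily <- function(modelId) {
  switch(modelId,
    Linear = , Poly2 = , Poly3 = "poly",
    Exp3 = , Exp5 = "exp",
    Hill = "hill")
}

#' Evaluate a dose-response model
#'
#' Deterministic mean response of one model of the continuous suite at the
#' given doses.
#'
#' @param modelId "Linear", "Poly2", "Poly3", "Exp3", "Exp5" or "Hill".
#' @param params named list or numeric vector of parameters: Linear/Poly use
#'   `beta0..beta3`; Exp3 uses `a, b, g, s` (sign s = +/-1); Exp5 uses
#'   `a, b, c, g`; Hill uses `gamma, v, k, n`. Scale parameters must satisfy
#'   `k > 0`, `n > 0`, `b > 0`, `g > 0`, `a > 0`, `c > 0`.
#' @param dose numeric vector of doses (>= 0).
#' @return numeric vector of mean responses.
#' @examples
#' evaluateModel("Hill", list(gamma = 8, v = 2, k = 100, n = 1), 100) # 9
#' evaluateModel("Poly3", list(beta0 = 1, beta1 = 2, beta2 = 0,
#'                             beta3 = 0), 3)                         # 7
#' @export
evaluateModel <- function(modelId, params, dose) {
  p <- as.list(params)
  chk <- function(cond, what)
    if (!isTRUE(cond)) stop("parameter constraint violated: ", what)
  switch(modelId,
    Linear = p$beta0 + p$beta1 * dose,
    Poly2 = p$beta0 + p$beta1 * dose + p$beta2 * dose^2,
    Poly3 = p$beta0 + p$beta1 * dose + p$beta2 * dose^2 + p$beta3 * dose^3,
    Exp3 = {
      chk(p$a > 0, "Exp3 a > 0"); chk(p$b > 0, "Exp3 b > 0")
      chk(p$g > 0, "Exp3 g > 0"); chk(abs(p$s) == 1, "Exp3 s in {-1, 1}")
      p$a * exp(p$s * (p$b * dose)^p$g)
    },
    Exp5 = {
      chk(p$a > 0, "Exp5 a > 0"); chk(p$b > 0, "Exp5 b > 0")
      chk(p$c > 0, "Exp5 c > 0"); chk(p$g > 0, "Exp5 g > 0")
      p$a * (p$c - (p$c - 1) * exp(-(p$b * dose)^p$g))
    },
    Hill = {
      chk(p$k > 0, "Hill k > 0"); chk(p$n > 0, "Hill n > 0")
      ifelse(dose == 0, p$gamma,
             p$gamma + p$v * dose^p$n / (p$k^p$n + dose^p$n))
    },
    stop("unknown model: ", modelId)
  )
}

# log-likelihood of an i.i.d. normal constant-variance fit given SSE
.normLogLik <- function(sse, n, sigma = NULL) {
  sigma2 <- if (is.null(sigma)) max(sse / n, 1e-12) else max(sigma^2, 1e-12)
  -n / 2 * log(2 * pi * sigma2) - sse / (2 * sigma2)
}

# ---------------------------------------------------------------------------
# Transformed-parameter machinery for the nonlinear fits: optimization works
# on an unconstrained-ish vector theta, mapped to natural parameters. Shape
# parameters (Hill n, Exp g) have box bounds: >= 1 under the restricted
# convention, >= 0.1 otherwise.
# ---------------------------------------------------------------------------

.shapeLower <- function(restricted) if (restricted) 1 else 0.1

# theta -> named natural parameter list
.thetaToParams <- function(modelId, theta, sign = 1L) {
  switch(modelId,
    Hill = list(gamma = theta[1L], v = theta[2L], k = exp(theta[3L]),
                n = theta[4L]),
    Exp3 = list(a = exp(theta[1L]), b = exp(theta[2L]), g = theta[3L],
                s = sign),
    Exp5 = list(a = exp(theta[1L]), b = exp(theta[2L]), c = exp(theta[3L]),
                g = theta[4L])
  )
}

.nonlinearStarts <- function(modelId, doses, responses, restricted) {
  lev <- sort(unique(doses))
  m0 <- mean(responses[doses == lev[1L]])
  mtop <- mean(responses[doses == max(lev)])
  amp <- mtop - m0
  if (amp == 0) amp <- 1e-3
  dpos <- lev[lev > 0]
  kGrid <- sort(unique(c(dpos, sqrt(dpos[-length(dpos)] * dpos[-1L]))))
  gLo <- .shapeLower(restricted)
  shapeStarts <- unique(pmax(c(1, 2, 4), gLo))
  switch(modelId,
    Hill = {
      st <- expand.grid(k = kGrid, n = shapeStarts)
      lapply(seq_len(nrow(st)), function(i)
        c(m0, amp, log(st$k[i]), st$n[i]))
    },
    Exp3 = {
      if (m0 <= 0.05) return(list())
      st <- expand.grid(b = 1 / kGrid, g = shapeStarts)
      lapply(seq_len(nrow(st)), function(i)
        c(log(m0), log(st$b[i]), st$g[i]))
    },
    Exp5 = {
      if (m0 <= 0.05 || mtop <= 0) return(list())
      cstart <- mtop / m0
      if (cstart <= 0 || abs(cstart - 1) < 1e-4)
        cstart <- 1 + sign(amp) * 0.05
      st <- expand.grid(b = 1 / kGrid, g = shapeStarts)
      lapply(seq_len(nrow(st)), function(i)
        c(log(m0), log(st$b[i]), log(cstart), st$g[i]))
    }
  )
}

.nonlinearBounds <- function(modelId, doses, responses, restricted) {
  maxd <- max(doses)
  gLo <- .shapeLower(restricted)
  ry <- range(responses)
  pad <- diff(ry) + 1
  switch(modelId,
    Hill = list(
      lower = c(ry[1L] - pad, -4 * pad, log(maxd * 1e-4), gLo),
      upper = c(ry[2L] + pad, 4 * pad, log(maxd * 1e2), 18)),
    Exp3 = list(
      lower = c(log(1e-4), log(1e-4 / maxd), gLo),
      upper = c(log(max(responses) + pad), log(1e2 / maxd), 18)),
    Exp5 = list(
      lower = c(log(1e-4), log(1e-4 / maxd), log(1e-4), gLo),
      upper = c(log(max(responses) + pad), log(1e2 / maxd), log(1e4), 18))
  )
}

.sseFun <- function(modelId, doses, responses, sign = 1L) {
  force(modelId); force(doses); force(responses); force(sign)
  function(theta) {
    p <- .thetaToParams(modelId, theta, sign)
    mu <- tryCatch(evaluateModel(modelId, p, doses), error = function(e) NULL)
    if (is.null(mu) || any(!is.finite(mu))) return(1e300)
    sum((responses - mu)^2)
  }
}

#' Maximum-likelihood fit of one dose-response model
#'
#' Fits the model by ML under i.i.d. normal errors with constant variance
#' (equivalently least squares; `sigmaHat^2 = SSE/n`). Linear and polynomial
#' models are solved exactly by ordinary least squares; the nonlinear models
#' (Exp3, Exp5, Hill) use deterministic multi-start bounded
#' quasi-Newton optimization over a fixed grid of starting values, so
#' repeated fits are identical. The convergence flag is honest: fits where
#' no start converged are flagged and excluded from model selection.
#'
#' @param modelId one of the six model identifiers.
#' @param doses numeric doses (nM), >= 2 distinct values.
#' @param responses numeric responses (log2 units), one per dose entry.
#' @param restricted logical; Hill `n >= 1` and Exp `g >= 1` (the
#'   restricted convention, default) or a relaxed lower bound of 0.1.
#' @return A [DoseResponseFit-class].
#' @examples
#' d <- rep(c(0, 10, 100, 1000), each = 4)
#' y <- 8 + 0.001 * d + rnorm(16, sd = 0.1)
#' fitModel("Linear", d, y)
#' @export
fitModel <- function(modelId, doses, responses, restricted = TRUE) {
  modelId <- match.arg(modelId, .MODEL_ORDER)
  stopifnot(length(doses) == length(responses),
            length(unique(doses)) >= 2L)
  n <- length(responses)
  npar <- .MODEL_NPAR[[modelId]]
  if (n < npar + 1L)
    stop("need at least ", npar + 1L, " observations for ", modelId)

  if (.modelFamily(modelId) == "poly") {
    deg <- npar - 1L
    X <- cbind(1, stats::poly(doses, degree = deg, raw = TRUE))
    ols <- stats::lm.fit(X, responses)
    coefs <- ols$coefficients
    coefs[is.na(coefs)] <- 0
    if (restricted && deg > 1L) {
      # restricted polynomial convention: non-intercept coefficients share
      # the trend direction, so the fitted curve is monotone on d >= 0
      lev <- sort(unique(doses))
      s <- sign(mean(responses[doses == max(lev)]) -
                mean(responses[doses == lev[1L]]))
      if (s == 0) s <- 1
      sse <- function(th) {
        b <- c(th[1L], s * th[-1L])
        sum((responses - X %*% b)^2)
      }
      th0 <- c(coefs[1L], pmax(s * coefs[-1L], 0))
      opt <- stats::nlminb(th0, sse,
                           lower = c(-Inf, rep(0, deg)),
                           control = list(iter.max = 400L))
      coefs <- c(opt$par[1L], s * opt$par[-1L])
    }
    params <- stats::setNames(coefs, paste0("beta", 0:deg))
    sse <- sum((responses - X %*% coefs)^2)
    sigma <- max(sqrt(sse / n), 1e-6)
    ll <- .normLogLik(sse, n)
    return(new("DoseResponseFit", modelId = modelId, params = params,
               sigmaHat = sigma, logLik = ll,
               aic = 2 * (npar + 1) - 2 * ll, converged = TRUE,
               doses = as.numeric(doses), responses = as.numeric(responses)))
  }

  sgn <- {
    lev <- sort(unique(doses))
    d <- mean(responses[doses == max(lev)]) -
         mean(responses[doses == lev[1L]])
    if (d >= 0) 1L else -1L
  }
  starts <- .nonlinearStarts(modelId, doses, responses, restricted)
  bounds <- .nonlinearBounds(modelId, doses, responses, restricted)
  obj <- .sseFun(modelId, doses, responses, sgn)
  best <- NULL
  for (th0 in starts) {
    th0 <- pmin(pmax(th0, bounds$lower), bounds$upper)
    opt <- tryCatch(
      stats::nlminb(th0, obj, lower = bounds$lower, upper = bounds$upper,
                    control = list(iter.max = 400L, eval.max = 600L)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    ok <- opt$convergence == 0L && opt$objective < 1e200
    if (is.null(best) || opt$objective < best$objective - 1e-12)
      best <- c(opt, list(ok = ok))
  }
  if (is.null(best)) {
    return(new("DoseResponseFit", modelId = modelId,
               params = stats::setNames(numeric(0), character(0)),
               sigmaHat = 1e-6, logLik = -Inf, aic = Inf, converged = FALSE,
               doses = as.numeric(doses), responses = as.numeric(responses)))
  }
  params <- unlist(.thetaToParams(modelId, best$par, sgn))
  sse <- best$objective
  sigma <- max(sqrt(sse / n), 1e-6)
  ll <- .normLogLik(sse, n)
  new("DoseResponseFit", modelId = modelId, params = params,
      sigmaHat = sigma, logLik = ll, aic = 2 * (npar + 1) - 2 * ll,
      converged = isTRUE(best$ok) && sse < 1e200,
      doses = as.numeric(doses), responses = as.numeric(responses))
}

#' Fit the whole model suite to one endpoint
#'
#' @inheritParams fitModel
#' @param models model identifiers to fit (default: all six).
#' @return named list of [DoseResponseFit-class] objects.
#' @export
fitAllModels <- function(doses, responses, models = .MODEL_ORDER,
                         restricted = TRUE) {
  models <- match.arg(models, .MODEL_ORDER, several.ok = TRUE)
  stats::setNames(
    lapply(models, fitModel, doses = doses, responses = responses,
           restricted = restricted),
    models)
}
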
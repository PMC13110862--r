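# Synthetic concentration-response data with known ground truth. The
# generator defines the study conditions every downstream stage is tested
# under: 4 concentrations spanning 0/10/100/1000 nM, 4 biological
# replicates, additive Gaussian noise on the log2 scale, and a minority of
# monotone responder probes drawn from the same curve families the fitting
# stage uses.

#' Mean response of a planted curve at a set of doses
#'
#' @param model "Hill", "Exp5" or "Linear".
#' @param params named list/vector of curve parameters (see
#'   [evaluateModel()]; planted curves use the same forms).
#' @param dose numeric vector of doses (nM).
#' @return numeric vector of mean log2 responses.
#' @keywords internal
.plantedCurve <- function(model, params, dose) {
  evaluateModel(model, params, dose)
}

# Draw the truth table for one design. Called inside the seeded block.
.drawTruth <- function(design) {
  nG <- design@nGenes
  nResp <- round(design@responderFraction * nG)
  isResp <- rep(FALSE, nG)
  if (nResp > 0) isResp[sample.int(nG, nResp)] <- TRUE
  baseline <- stats::runif(nG, design@baselineRange[1], design@baselineRange[2])
  modelId <- rep(NA_character_, nG)
  direction <- integer(nG)
  params <- vector("list", nG)
  maxDose <- max(design@concentrations)
  trueBmc <- rep(NA_real_, nG)
  for (i in seq_len(nG)) {
    if (!isResp[i]) {
      params[[i]] <- list(beta0 = baseline[i], beta1 = 0)
      next
    }
    m <- if (length(design@responderModels) == 1L) design@responderModels
         else sample(design@responderModels, 1L)
    dir <- sample(c(-1L, 1L), 1L)
    amp <- stats::runif(1, design@amplitudeRange[1], design@amplitudeRange[2])
    ec50 <- exp(stats::runif(1, log(design@ec50Range[1]),
                             log(design@ec50Range[2])))
    p <- switch(m,
      Hill = list(gamma = baseline[i], v = dir * amp, k = ec50,
                  n = stats::runif(1, design@hillCoefRange[1],
                                   design@hillCoefRange[2])),
      Exp5 = {
        a <- baseline[i]
        # asymptotic amplitude a|c-1| = amp, direction via c >< 1
        cpar <- 1 + dir * amp / a
        if (cpar <= 0) cpar <- 1e-3  # guard: down-amplitude beyond baseline
        list(a = a, b = 1 / ec50, c = cpar,
             g = stats::runif(1, design@expShapeRange[1],
                              design@expShapeRange[2]))
      },
      Linear = list(beta0 = baseline[i], beta1 = dir * amp / maxDose)
    )
    modelId[i] <- m
    direction[i] <- dir
    params[[i]] <- p
  }
  truth <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(nG)),
    is_responder = isResp,
    model_id = modelId,
    direction = direction,
    stringsAsFactors = FALSE
  )
  truth$params <- params
  truth$true_bmc <- trueBmc
  for (i in which(isResp)) {
    rec <- list(model_id = modelId[i], params = params[[i]],
                is_responder = TRUE)
    truth$true_bmc[i] <- trueBMC(rec, bmrSd = 1, noiseSd = design@noiseSd,
                                 maxDose = maxDose)
  }
  truth
}

#' Generate a synthetic probe x sample expression matrix
#'
#' Responder rows follow their planted curve plus i.i.d. Gaussian noise of
#' SD `noiseSd`; non-responders are flat at their baseline plus the same
#' noise. The planted truth (curve family, parameters, direction and the
#' analytic benchmark concentration at a benchmark response of 1 noise SD)
#' is stored in `rowData` and retrievable with [truthRecords()]. Generation
#' is bit-identical under a fixed design seed.
#'
#' @param design a [SyntheticDesign-class].
#' @return A [DoseResponseExperiment-class] with planted truth in `rowData`.
#' @examples
#' dre <- generateExpressionMatrix(syntheticDesign(nGenes = 20))
#' head(truthRecords(dre))
#' @export
generateExpressionMatrix <- function(design) {
  stopifnot(is(design, "SyntheticDesign"))
  validObject(design)
  conc <- rep(design@concentrations, each = design@nReplicates)
  repl <- rep(seq_len(design@nReplicates), times = length(design@concentrations))
  withr::with_seed(design@seed, {
    truth <- .drawTruth(design)
    mu <- t(vapply(seq_len(design@nGenes), function(i) {
      if (truth$is_responder[i])
        .plantedCurve(truth$model_id[i], truth$params[[i]], conc)
      else
        rep(truth$params[[i]]$beta0, length(conc))
    }, numeric(length(conc))))
    values <- mu + matrix(stats::rnorm(length(mu), sd = design@noiseSd),
                          nrow = nrow(mu))
  })
  rownames(values) <- truth$gene_id
  dre <- DoseResponseExperiment(values, conc, repl, geneIds = truth$gene_id)
  rd <- DataFrame(
    is_responder = truth$is_responder,
    model_id = truth$model_id,
    direction = truth$direction,
    true_bmc = truth$true_bmc,
    row.names = truth$gene_id
  )
  rd$params <- truth$params
  SummarizedExperiment::rowData(dre) <- rd
  metadata(dre)$design <- design
  dre
}

#' Analytic benchmark concentration of a planted curve
#'
#' Smallest d > 0 with |f(d) - f(0)| = `bmrSd * noiseSd` for the planted
#' curve f, inverted in closed form. Returns `NA` when the response never
#' reaches the benchmark within the dose range (the endpoint is then absent
#' from the truth, mirroring the range filter applied to fitted BMCs).
#'
#' @param truth a truth record: list with `is_responder`, `model_id` and
#'   `params` (as one row of [truthRecords()] provides).
#' @param bmrSd benchmark response in noise-SD units (default 1).
#' @param noiseSd the design noise SD (log2 units).
#' @param maxDose upper end of the dose range (nM); responses first reaching
#'   the benchmark beyond it count as absent. `Inf` disables the cap.
#' @return positive numeric (nM) or `NA_real_`.
#' @examples
#' rec <- list(is_responder = TRUE, model_id = "Hill",
#'             params = list(gamma = 8, v = 2, k = 100, n = 1))
#' trueBMC(rec, noiseSd = 0.25)  # 100 * 0.125/0.875 = 14.29 nM
#' @export
trueBMC <- function(truth, bmrSd = 1, noiseSd, maxDose = Inf) {
  stopifnot(bmrSd > 0, noiseSd > 0)
  if (!isTRUE(truth$is_responder))
    stop("trueBMC is defined for responder records only")
  target <- bmrSd * noiseSd
  p <- truth$params
  d <- switch(truth$model_id,
    Linear = if (p$beta1 == 0) NA_real_ else target / abs(p$beta1),
    Hill = {
      x <- target / abs(p$v)
      if (x >= 1) NA_real_ else p$k * (x / (1 - x))^(1 / p$n)
    },
    Exp5 = {
      amp <- p$a * abs(p$c - 1)
      if (target >= amp) NA_real_
      else (-log(1 - target / amp))^(1 / p$g) / p$b
    },
    Exp3 = {
      a <- p$a
      if (p$s > 0) (log(1 + target / a))^(1 / p$g) / p$b
      else if (target >= a) NA_real_
      else (-log(1 - target / a))^(1 / p$g) / p$b
    },
    stop("unknown planted model: ", truth$model_id)
  )
  if (!is.na(d) && d > maxDose) d <- NA_real_
  d
}

#' Generate a synthetic apical-endpoint table
#'
#' Emulates endpoint x concentration x replicate summaries (hormone
#' secretion, cell-cycle fractions, ...) with a known curve per endpoint.
#'
#' @param design a [SyntheticDesign-class] (supplies the concentration grid,
#'   replicate count and seed).
#' @param endpointSpecs non-empty list; each element a list with `name`,
#'   `model` ("flat", "Linear", "Hill", "Exp5"), `params` (curve parameters;
#'   ignored for "flat" beyond `baseline`), and optional `noiseSd`
#'   (defaults to the design noise SD).
#' @return `data.frame` with columns endpoint, concentration_nM, replicate,
#'   value; deterministic under the design seed.
#' @examples
#' tab <- generateApicalTable(syntheticDesign(), list(
#'   list(name = "estradiol", model = "Hill",
#'        params = list(gamma = 10, v = 3, k = 150, n = 1.5))))
#' head(tab)
#' @export
generateApicalTable <- function(design, endpointSpecs) {
  stopifnot(is(design, "SyntheticDesign"))
  if (length(endpointSpecs) == 0L)
    stop("endpointSpecs must name at least one endpoint")
  conc <- rep(design@concentrations, each = design@nReplicates)
  repl <- rep(seq_len(design@nReplicates), times = length(design@concentrations))
  withr::with_seed(design@seed, {
    rows <- lapply(endpointSpecs, function(sp) {
      noiseSd <- if (is.null(sp$noiseSd)) design@noiseSd else sp$noiseSd
      mu <- if (identical(sp$model, "flat")) {
        rep(if (is.null(sp$params$baseline)) 0 else sp$params$baseline,
            length(conc))
      } else {
        .plantedCurve(sp$model, sp$params, conc)
      }
      data.frame(endpoint = sp$name, concentration_nM = conc,
                 replicate = repl,
                 value = mu + stats::rnorm(length(conc), sd = noiseSd),
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

#' Convert an apical-endpoint table to a DoseResponseExperiment
#'
#' Reshapes the long endpoint table into an endpoint x sample matrix so the
#' trend screen and BMC fitting apply unchanged.
#'
#' @param table output of [generateApicalTable()] (or a TSV read into the
#'   same shape).
#' @return A [DoseResponseExperiment-class] with endpoints as rows.
#' @export
apicalToExperiment <- function(table) {
  stopifnot(all(c("endpoint", "concentration_nM", "replicate", "value")
                %in% colnames(table)))
  table <- table[order(table$endpoint, table$concentration_nM,
                       table$replicate), ]
  first <- table[table$endpoint == table$endpoint[1L], ]
  values <- do.call(rbind, lapply(split(table, table$endpoint),
                                  function(d) d$value))
  DoseResponseExperiment(values, first$concentration_nM, first$replicate,
                         geneIds = rownames(values))
}

#' Printed reference constants for the desk-reproducible chain
#'
#' Returns the published summary constants the acceptance checks replay:
#' median BMCs, median/5th-percentile HEDs before and after albumin
#' correction, pathway- and apical-endpoint HED extremes, reference
#' exposures for ART and occupational populations, the plasma free fraction
#' and the blood-to-follicular-fluid transfer efficiency. Units: BMCs in nM,
#' HEDs in ng/kg bw/day, concentrations in ng/ml.
#'
#' @param file optional path; when given, the fixture is also written as
#'   JSON.
#' @return named list of constants.
#' @examples
#' fx <- printedValuesFixture()
#' fx$ART_ref_median   # 3.5 ng/kg bw/day
#' fx$fu_plasma        # 0.0033
#' @export
printedValuesFixture <- function(file = NULL) {
  fx <- list(
    # median BMCs (nM)
    bmc_median_transcriptomic_6wk = 38.1,
    bmc_median_low = 36.5,
    bmc_median_apical_6wk = 214,
    # median and 5th-percentile HEDs (ng/kg bw/day), uncorrected
    hed_median_transcriptomic_6wk = 18.1,
    hed_median_transcriptomic_12wk = 17.5,
    hed_median_apical_12wk = 17.3,
    hed_median_apical_6wk = 101.7,
    hed_p5_transcriptomic_6wk = 3.7,
    hed_p5_transcriptomic_12wk = 1.4,
    # pathway-level HED range and apical extremes
    hed_pathway_eicosanoid = 2.8,
    hed_pathway_il6 = 24.1,
    hed_apical_subg1 = 0.4,
    hed_apical_estradiol = 203,
    # albumin-corrected medians / percentiles
    hed_corrected = c(
      transcriptomic_6wk = 302, transcriptomic_12wk = 291.8,
      p5_6wk = 61.7, p5_12wk = 22.6,
      pathway_eicosanoid = 45.8, pathway_il6 = 401.6,
      apical_6wk = 1694.7, apical_12wk = 289
    ),
    # reference exposures (HEDs, ng/kg bw/day)
    ART_ref_min = 0.1,
    ART_ref_median = 3.5,
    ART_ref_max = 172,
    occupational_ref = c(min = 303.6, median = 877.3, max = 13942.7),
    occupational_serum = c(min = 426, median = 1231, max = 19564),
    # binding / transfer constants
    fu_plasma = 0.0033,
    bfte = 0.75,
    follicular_fluid_range_ng_ml = c(min = 0.1, max = 181)
  )
  if (!is.null(file))
    jsonlite::write_json(fx, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  fx
}
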
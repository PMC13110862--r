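#' @import methods
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

# ---------------------------------------------------------------------------
# SyntheticDesign
# ---------------------------------------------------------------------------

#' Design of a synthetic concentration-response experiment
#'
#' Describes the layout and signal structure of a simulated probe x sample
#' log2-expression matrix: the concentration grid (nM), the number of
#' biological replicates per concentration, how many probes are simulated,
#' which fraction of them are planted responders, and the residual noise on
#' the log2 scale. The defaults mirror a chronic low-level exposure design:
#' vehicle control plus three concentrations spanning three decades
#' (0/10/100/1000 nM, i.e. 0/0.01/0.1/1 uM), four biological replicates.
#'
#' @slot concentrations numeric, strictly increasing, first element 0 (nM).
#' @slot nReplicates integer >= 2, biological replicates per concentration.
#' @slot nGenes integer >= 1, number of simulated probes.
#' @slot responderFraction numeric in \[0, 1\], fraction of probes planted
#'   with a monotone concentration-response.
#' @slot noiseSd numeric > 0, i.i.d. Gaussian residual SD (log2 units).
#' @slot seed integer, RNG seed; regeneration is bit-identical.
#' @slot responderModels character, curve families drawn for responders
#'   (subset of "Hill", "Exp5", "Linear").
#' @slot baselineRange numeric length 2, uniform range of baseline log2
#'   expression for every probe.
#' @slot amplitudeRange numeric length 2, uniform range of absolute response
#'   amplitude (log2 units).
#' @slot ec50Range numeric length 2, log-uniform range of the half-maximal
#'   concentration (nM).
#' @slot hillCoefRange numeric length 2, uniform range of the Hill
#'   coefficient.
#' @slot expShapeRange numeric length 2, uniform range of the exponential
#'   shape parameter g.
#' @seealso [syntheticDesign()], [generateExpressionMatrix()]
#' @exportClass SyntheticDesign
setClass("SyntheticDesign",
  slots = c(
    concentrations    = "numeric",
    nReplicates       = "integer",
    nGenes            = "integer",
    responderFraction = "numeric",
    noiseSd           = "numeric",
    seed              = "integer",
    responderModels   = "character",
    baselineRange     = "numeric",
    amplitudeRange    = "numeric",
    ec50Range         = "numeric",
    hillCoefRange     = "numeric",
    expShapeRange     = "numeric"
  )
)

setValidity("SyntheticDesign", function(object) {
  msg <- character()
  cc <- object@concentrations
  if (length(cc) < 2L || any(diff(cc) <= 0))
    msg <- c(msg, "concentrations must be strictly increasing")
  if (length(cc) && (cc[1L] != 0 || any(cc < 0)))
    msg <- c(msg, "concentrations must be >= 0 and include 0 (first element)")
  if (object@nReplicates < 2L)
    msg <- c(msg, "nReplicates must be >= 2")
  if (object@nGenes < 1L)
    msg <- c(msg, "nGenes must be >= 1")
  rf <- object@responderFraction
  if (length(rf) != 1L || is.na(rf) || rf < 0 || rf > 1)
    msg <- c(msg, "responderFraction must lie in [0, 1]")
  if (object@noiseSd <= 0)
    msg <- c(msg, "noiseSd must be > 0")
  if (!all(object@responderModels %in% c("Hill", "Exp5", "Linear")))
    msg <- c(msg, "responderModels must be a subset of Hill/Exp5/Linear")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic concentration-response design
#'
#' @param concentrations dose grid; strictly increasing, must include 0.
#'   Interpreted in nM unless `units = "uM"`, in which case values are
#'   converted to nM at the boundary (the package works in nM internally).
#' @param nReplicates biological replicates per concentration (>= 2).
#' @param nGenes number of probes to simulate.
#' @param responderFraction fraction of probes planted as responders.
#' @param noiseSd residual SD on the log2 scale.
#' @param seed RNG seed.
#' @param responderModels curve families sampled for responders.
#' @param baselineRange,amplitudeRange,ec50Range,hillCoefRange,expShapeRange
#'   ranges of the planted curve parameters; see [SyntheticDesign-class].
#' @param units `"nM"` (default) or `"uM"` for the concentration grid.
#' @return A validated [SyntheticDesign-class] object.
#' @examples
#' syntheticDesign(nGenes = 50, responderFraction = 0.2)
#' syntheticDesign(concentrations = c(0, 0.01, 0.1, 1), units = "uM")
#' @export
syntheticDesign <- function(concentrations = c(0, 10, 100, 1000),
                            nReplicates = 4L,
                            nGenes = 500L,
                            responderFraction = 0.1,
                            noiseSd = 0.25,
                            seed = 1L,
                            responderModels = c("Hill", "Exp5"),
                            baselineRange = c(6, 10),
                            amplitudeRange = c(1, 2.5),
                            ec50Range = c(20, 500),
                            hillCoefRange = c(1, 3),
                            expShapeRange = c(1, 2),
                            units = c("nM", "uM")) {
  units <- match.arg(units)
  if (units == "uM") concentrations <- concentrations * 1000
  new("SyntheticDesign",
    concentrations = as.numeric(concentrations),
    nReplicates = as.integer(nReplicates),
    nGenes = as.integer(nGenes),
    responderFraction = as.numeric(responderFraction),
    noiseSd = as.numeric(noiseSd),
    seed = as.integer(seed),
    responderModels = responderModels,
    baselineRange = baselineRange,
    amplitudeRange = amplitudeRange,
    ec50Range = ec50Range,
    hillCoefRange = hillCoefRange,
    expShapeRange = expShapeRange
  )
}

setMethod("show", "SyntheticDesign", function(object) {
  cat("SyntheticDesign:", object@nGenes, "genes x",
      length(object@concentrations), "concentrations x",
      object@nReplicates, "replicates\n")
  cat("  concentrations (nM):", paste(object@concentrations, collapse = ", "), "\n")
  cat("  responder fraction:", object@responderFraction,
      " noise SD (log2):", object@noiseSd, " seed:", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# DoseResponseExperiment
# ---------------------------------------------------------------------------

#' Probe x sample log2 expression with a concentration design
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] whose
#' `colData` carries the concentration (nM) and replicate label of each
#' sample. Validity requires at least two distinct concentrations including
#' a 0 (vehicle control) group, at least two replicates per concentration,
#' and finite assay values.
#'
#' @seealso [DoseResponseExperiment()], [screenProbes()], [fitBMCs()]
#' @exportClass DoseResponseExperiment
setClass("DoseResponseExperiment", contains = "SummarizedExperiment")

setValidity("DoseResponseExperiment", function(object) {
  msg <- character()
  cd <- colData(object)
  if (!"concentration" %in% colnames(cd))
    return("colData must contain a 'concentration' column (nM)")
  conc <- cd$concentration
  if (!is.numeric(conc) || anyNA(conc) || any(conc < 0))
    msg <- c(msg, "concentrations must be non-negative numbers")
  tab <- table(conc)
  if (length(tab) < 2L)
    msg <- c(msg, "need >= 2 distinct concentrations")
  if (!any(conc == 0))
    msg <- c(msg, "a 0-concentration (control) group is required")
  if (any(tab < 2L))
    msg <- c(msg, "every concentration needs >= 2 replicates")
  if (length(SummarizedExperiment::assays(object)) &&
      !all(is.finite(assay(object))))
    msg <- c(msg, "assay values must all be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a DoseResponseExperiment
#'
#' @param values numeric matrix of log2 expression, probes in rows, samples
#'   in columns.
#' @param concentration numeric vector (length `ncol(values)`) of sample
#'   concentrations in nM.
#' @param replicate optional replicate labels; defaults to a within-group
#'   counter.
#' @param geneIds optional probe identifiers; default taken from row names.
#' @return A [DoseResponseExperiment-class].
#' @examples
#' m <- matrix(rnorm(40, 8), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), NULL))
#' dre <- DoseResponseExperiment(m, rep(c(0, 10, 100, 1000), each = 2))
#' doseLevels(dre)
#' @export
DoseResponseExperiment <- function(values, concentration, replicate = NULL,
                                   geneIds = rownames(values)) {
  values <- as.matrix(values)
  if (length(concentration) != ncol(values))
    stop("length(concentration) must equal ncol(values)")
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(concentration), concentration,
                            FUN = seq_along)
  }
  if (is.null(geneIds)) geneIds <- paste0("gene_", seq_len(nrow(values)))
  if (nrow(values) > 0L) rownames(values) <- geneIds
  colnames(values) <- sprintf("conc_%g_rep%d", concentration,
                              as.integer(replicate))
  se <- SummarizedExperiment(
    assays = list(log2expr = values),
    colData = DataFrame(concentration = as.numeric(concentration),
                        replicate = as.integer(replicate),
                        row.names = colnames(values))
  )
  new("DoseResponseExperiment", se)
}

setMethod("show", "DoseResponseExperiment", function(object) {
  cat("DoseResponseExperiment:", nrow(object), "probes x", ncol(object),
      "samples\n")
  cat("  concentrations (nM):",
      paste(doseLevels(object), collapse = ", "), "\n")
  tr <- truthRecords(object)
  if (!is.null(tr))
    cat("  planted responders:", sum(tr$is_responder), "of", nrow(tr), "\n")
})

# ---------------------------------------------------------------------------
# DoseResponseFit
# ---------------------------------------------------------------------------

#' A fitted continuous dose-response model
#'
#' Maximum-likelihood fit of one member of the continuous benchmark-dose
#' model suite (Linear, Poly2, Poly3, Exp3, Exp5, Hill) under i.i.d. normal
#' errors with constant variance. `sigmaHat` is the ML residual SD (log2
#' units) used as the benchmark-response unit; `aic = 2k - 2 logLik` where k
#' counts mean-model parameters plus one for the variance.
#'
#' @slot modelId one of "Linear", "Poly2", "Poly3", "Exp3", "Exp5", "Hill".
#' @slot params named numeric vector of mean-model parameters.
#' @slot sigmaHat ML residual SD (floored at 1e-6).
#' @slot logLik maximized log-likelihood.
#' @slot aic Akaike information criterion.
#' @slot converged logical convergence flag; non-converged fits are excluded
#'   from model selection.
#' @slot doses,responses the fitted data (kept for profiling).
#' @exportClass DoseResponseFit
setClass("DoseResponseFit",
  slots = c(
    modelId   = "character",
    params    = "numeric",
    sigmaHat  = "numeric",
    logLik    = "numeric",
    aic       = "numeric",
    converged = "logical",
    doses     = "numeric",
    responses = "numeric"
  )
)

setMethod("show", "DoseResponseFit", function(object) {
  cat("DoseResponseFit [", object@modelId, "]",
      if (!object@converged) "(NOT converged)", "\n")
  print(round(object@params, 5))
  cat("  sigmaHat:", signif(object@sigmaHat, 5),
      " logLik:", signif(object@logLik, 6),
      " AIC:", signif(object@aic, 6), "\n")
})

# ---------------------------------------------------------------------------
# Binding correction parameters
# ---------------------------------------------------------------------------

#' Plasma-protein-binding correction parameters
#'
#' Holds the free fraction of PFOS in human plasma and in the in vitro
#' exposure system (medium with 10% FBS). Equal free concentrations in both
#' systems imply that the total in vivo concentration matching an in vitro
#' total concentration is larger by `fuInvitro / fuPlasma`. When albumin
#' concentrations are supplied the in vitro free fraction is computed from
#' single-site linear binding-capacity scaling rather than set directly.
#'
#' @slot fuPlasma free fraction in plasma, default 0.0033 (0.33%).
#' @slot fuInvitro free fraction in the culture system, default 0.05506
#'   (gives a correction factor of ~16.7, matching the ~17-fold shift the
#'   corrected results display).
#' @slot albuminPlasma,albuminInvitro optional albumin concentrations (g/l);
#'   `NA` when the direct free-fraction route is used.
#' @seealso [correctionParams()], [correctionFactor()], [fuFromAlbumin()]
#' @exportClass CorrectionParams
setClass("CorrectionParams",
  slots = c(
    fuPlasma       = "numeric",
    fuInvitro      = "numeric",
    albuminPlasma  = "numeric",
    albuminInvitro = "numeric"
  )
)

setValidity("CorrectionParams", function(object) {
  msg <- character()
  for (nm in c("fuPlasma", "fuInvitro")) {
    v <- slot(object, nm)
    if (length(v) != 1L || is.na(v) || v <= 0 || v > 1)
      msg <- c(msg, paste(nm, "must lie in (0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct binding-correction parameters
#'
#' @param fuPlasma free fraction in human plasma (default 0.0033).
#' @param fuInvitro free fraction in the in vitro system; ignored when the
#'   albumin route is used. Default 0.05506.
#' @param albuminPlasma,albuminInvitro optional albumin concentrations (g/l).
#'   When both are given, `fuInvitro` is computed via [fuFromAlbumin()] with
#'   plasma as the reference system.
#' @return A [CorrectionParams-class].
#' @examples
#' correctionFactor(correctionParams())                     # ~16.68
#' correctionParams(albuminPlasma = 45, albuminInvitro = 2.3)
#' @export
correctionParams <- function(fuPlasma = 0.0033, fuInvitro = 0.05506,
                             albuminPlasma = NULL, albuminInvitro = NULL) {
  if (!is.null(albuminPlasma) || !is.null(albuminInvitro)) {
    if (is.null(albuminPlasma) || is.null(albuminInvitro))
      stop("the albumin route needs both albuminPlasma and albuminInvitro")
    fuInvitro <- fuFromAlbumin(fuPlasma, albuminPlasma, albuminInvitro)
  } else {
    albuminPlasma <- NA_real_
    albuminInvitro <- NA_real_
  }
  new("CorrectionParams", fuPlasma = fuPlasma, fuInvitro = fuInvitro,
      albuminPlasma = as.numeric(albuminPlasma),
      albuminInvitro = as.numeric(albuminInvitro))
}

setMethod("show", "CorrectionParams", function(object) {
  cat("CorrectionParams: fu(plasma) =", object@fuPlasma,
      " fu(in vitro) =", signif(object@fuInvitro, 5),
      " factor =", signif(correctionFactor(object), 5), "\n")
})

# ---------------------------------------------------------------------------
# PBTK
# ---------------------------------------------------------------------------

#' Reduced PBTK model parameters
#'
#' Parameters of a reduced toxicokinetic model for chronic daily oral PFOS
#' dosing in a 70-kg adult female: a gut depot with first-order absorption, a
#' central (plasma) compartment with first-order elimination set by the
#' serum half-life (~5.4 years), and a small flow-limited ovarian
#' interstitial-fluid sub-compartment whose total concentration tends to
#' `ovaryInterstitialPartition` times the total plasma concentration at
#' quasi-steady state. The partition coefficient is the single calibration
#' knob for reverse dosimetry (see [calibrateToAnchor()]).
#'
#' @slot bodyWeight kg, default 70.
#' @slot fuPlasma plasma free fraction, default 0.0033 (recorded for
#'   provenance; kinetics are expressed on total concentrations).
#' @slot absorptionRate 1/day, first-order oral absorption, default 1.
#' @slot volumeCentral l/kg, central distribution volume, default 0.23.
#' @slot halfLife days, elimination half-life, default 1971 (~5.4 y);
#'   elimination rate k = ln(2)/halfLife.
#' @slot ovaryPlasmaFlow l/day plasma flow to the ovary sub-compartment,
#'   default 28.8.
#' @slot ovaryVolume l, interstitial-fluid volume, default 0.011.
#' @slot ovaryInterstitialPartition total ovarian-interstitial : total plasma
#'   concentration ratio at steady state.
#' @exportClass PBTKParameters
setClass("PBTKParameters",
  slots = c(
    bodyWeight                 = "numeric",
    fuPlasma                   = "numeric",
    absorptionRate             = "numeric",
    volumeCentral              = "numeric",
    halfLife                   = "numeric",
    ovaryPlasmaFlow            = "numeric",
    ovaryVolume                = "numeric",
    ovaryInterstitialPartition = "numeric"
  )
)

setValidity("PBTKParameters", function(object) {
  vals <- c(object@bodyWeight, object@fuPlasma, object@absorptionRate,
            object@volumeCentral, object@halfLife, object@ovaryPlasmaFlow,
            object@ovaryVolume, object@ovaryInterstitialPartition)
  if (any(!is.finite(vals)) || any(vals <= 0))
    "all PBTK parameters must be positive and finite"
  else TRUE
})

#' Construct PBTK parameters
#'
#' @param bodyWeight,fuPlasma,absorptionRate,volumeCentral,halfLife
#'   see [PBTKParameters-class].
#' @param ovaryPlasmaFlow,ovaryVolume,ovaryInterstitialPartition
#'   ovary sub-compartment; the partition defaults to 0.38088, which the
#'   anchor calibration (181 ng/ml at 172 ng/kg bw/day over 720 days)
#'   reproduces.
#' @return A [PBTKParameters-class].
#' @examples
#' p <- pbtkParameters()
#' eliminationRate(p) * p@halfLife / log(2)  # 1
#' @export
pbtkParameters <- function(bodyWeight = 70, fuPlasma = 0.0033,
                           absorptionRate = 1, volumeCentral = 0.23,
                           halfLife = 1971, ovaryPlasmaFlow = 28.8,
                           ovaryVolume = 0.011,
                           ovaryInterstitialPartition = 0.38088) {
  new("PBTKParameters", bodyWeight = bodyWeight, fuPlasma = fuPlasma,
      absorptionRate = absorptionRate, volumeCentral = volumeCentral,
      halfLife = halfLife, ovaryPlasmaFlow = ovaryPlasmaFlow,
      ovaryVolume = ovaryVolume,
      ovaryInterstitialPartition = ovaryInterstitialPartition)
}

setMethod("show", "PBTKParameters", function(object) {
  cat("PBTKParameters: BW", object@bodyWeight, "kg, t1/2",
      object@halfLife, "d (k =", signif(eliminationRate(object), 4),
      "/d), Vc", object@volumeCentral, "l/kg\n")
  cat("  ovary: flow", object@ovaryPlasmaFlow, "l/d, volume",
      object@ovaryVolume, "l, partition",
      signif(object@ovaryInterstitialPartition, 5), "\n")
})

#' Chronic oral dosing regimen
#'
#' @slot doseRate ng/kg bw/day, >= 0.
#' @slot duration days, default 720 (two years).
#' @slot interval days between doses, default 1.
#' @exportClass DosingRegimen
setClass("DosingRegimen",
  slots = c(doseRate = "numeric", duration = "numeric", interval = "numeric")
)

setValidity("DosingRegimen", function(object) {
  msg <- character()
  if (object@doseRate < 0) msg <- c(msg, "doseRate must be >= 0")
  if (object@interval <= 0) msg <- c(msg, "interval must be > 0")
  if (object@duration < object@interval)
    msg <- c(msg, "duration must be >= interval")
  if (length(msg)) msg else TRUE
})

#' Construct a dosing regimen
#'
#' @param doseRate daily oral dose, ng/kg bw/day.
#' @param duration total simulated time in days (default 720).
#' @param interval dosing interval in days (default 1).
#' @return A [DosingRegimen-class].
#' @export
dosingRegimen <- function(doseRate, duration = 720, interval = 1) {
  new("DosingRegimen", doseRate = as.numeric(doseRate),
      duration = as.numeric(duration), interval = as.numeric(interval))
}

setMethod("show", "DosingRegimen", function(object) {
  cat("DosingRegimen:", object@doseRate, "ng/kg bw/day every",
      object@interval, "d for", object@duration, "d\n")
})

# ---------------------------------------------------------------------------
# ReferenceExposure
# ---------------------------------------------------------------------------

#' Population reference exposure
#'
#' Follicular-fluid PFOS concentrations (min/median/max, ng/ml) for a
#' reference population together with the human-equivalent doses they map to
#' (ng/kg bw/day). For occupational cohorts only serum concentrations are
#' reported; follicular fluid is predicted as serum x BFTE (blood-to-
#' follicular-fluid transfer efficiency, default 0.75).
#'
#' @slot population "ART" or "occupational".
#' @slot conc follicular-fluid concentrations, named min/median/max (ng/ml);
#'   may be `NA` when the reference is consumed directly as HEDs.
#' @slot serum serum concentrations (ng/ml), occupational only, else `NA`.
#' @slot bfte blood-to-follicular-fluid transfer efficiency in (0, 1].
#' @slot hed reference HEDs, named min/median/max (ng/kg bw/day).
#' @seealso [artReference()], [occupationalReference()], [berInterval()]
#' @exportClass ReferenceExposure
setClass("ReferenceExposure",
  slots = c(population = "character", conc = "numeric", serum = "numeric",
            bfte = "numeric", hed = "numeric")
)

setValidity("ReferenceExposure", function(object) {
  msg <- character()
  h <- object@hed
  if (length(h) != 3L || anyNA(h) || any(h < 0))
    msg <- c(msg, "hed must be three non-negative values (min/median/max)")
  else if (is.unsorted(h))
    msg <- c(msg, "hed must be ordered min <= median <= max")
  if (object@bfte <= 0 || object@bfte > 1)
    msg <- c(msg, "bfte must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReferenceExposure", function(object) {
  cat("ReferenceExposure [", object@population, "] HED (ng/kg bw/day):",
      paste(signif(object@hed, 5), collapse = " / "), "(min/median/max)\n")
})
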
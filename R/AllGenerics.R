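# Accessor generics. Slot access from user code goes through these.

#' Per-sample concentrations (nM)
#' @param x a `DoseResponseExperiment`.
#' @return numeric vector, one concentration per sample.
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname concentrations
#' @export
setMethod("concentrations", "DoseResponseExperiment",
          function(x) colData(x)$concentration)

#' Distinct concentrations of the design, sorted (nM)
#' @param x a `DoseResponseExperiment`.
#' @return sorted numeric vector of dose levels.
#' @export
setGeneric("doseLevels", function(x) standardGeneric("doseLevels"))

#' @rdname doseLevels
#' @export
setMethod("doseLevels", "DoseResponseExperiment",
          function(x) sort(unique(concentrations(x))))

#' Planted ground truth of a synthetic experiment
#'
#' @param x a `DoseResponseExperiment` produced by
#'   [generateExpressionMatrix()].
#' @return a `data.frame` with one row per probe (gene_id, is_responder,
#'   model_id, direction, true_bmc and a `params` list column), or `NULL`
#'   for experiments without planted truth.
#' @export
setGeneric("truthRecords", function(x) standardGeneric("truthRecords"))

#' @rdname truthRecords
#' @export
setMethod("truthRecords", "DoseResponseExperiment", function(x) {
  rd <- rowData(x)
  if (!"is_responder" %in% colnames(rd)) return(NULL)
  out <- as.data.frame(rd[, setdiff(colnames(rd), "params"), drop = FALSE])
  out <- cbind(gene_id = rownames(x), out)
  out$params <- as.list(rd$params)
  out
})

#' Identifier of the fitted model
#' @param x a `DoseResponseFit`.
#' @return character scalar.
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))

#' @rdname modelId
#' @export
setMethod("modelId", "DoseResponseFit", function(x) x@modelId)

#' Mean-model parameters of a fit
#' @param x a `DoseResponseFit`.
#' @return named numeric vector.
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' @rdname modelParams
#' @export
setMethod("modelParams", "DoseResponseFit", function(x) x@params)

#' ML residual standard deviation of a fit (log2 units)
#' @param x a `DoseResponseFit`.
#' @return numeric scalar.
#' @export
setGeneric("sigmaHat", function(x) standardGeneric("sigmaHat"))

#' @rdname sigmaHat
#' @export
setMethod("sigmaHat", "DoseResponseFit", function(x) x@sigmaHat)

#' Convergence flag of a fit
#' @param x a `DoseResponseFit`.
#' @return logical scalar.
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname converged
#' @export
setMethod("converged", "DoseResponseFit", function(x) x@converged)

#' First-order elimination rate, ln(2)/halfLife (1/day)
#' @param x a `PBTKParameters`.
#' @return numeric scalar.
#' @export
setGeneric("eliminationRate", function(x) standardGeneric("eliminationRate"))

#' @rdname eliminationRate
#' @export
setMethod("eliminationRate", "PBTKParameters",
          function(x) log(2) / x@halfLife)

#' Reference HEDs (min/median/max, ng/kg bw/day)
#' @param x a `ReferenceExposure`.
#' @return named numeric vector of length 3.
#' @export
setGeneric("referenceHEDs", function(x) standardGeneric("referenceHEDs"))

#' @rdname referenceHEDs
#' @export
setMethod("referenceHEDs", "ReferenceExposure", function(x) x@hed)
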
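# HED and BER chain: unit bridge nM <-> ng/ml, BMC -> HED conversion via the
# reverse-dosimetry factor, reference exposures (ART follicular fluid;
# occupational serum x BFTE), bioactivity exposure ratios with intervals,
# low-BER gene flagging and pathway-level aggregation.

#' Molecular weights of PFOS (g/mol)
#'
#' Free acid (500.13, the default — the only choice consistent with the
#' nM <-> ng/ml <-> ng/kg bw/day chain of the published summary values) and
#' potassium salt (538.22, selectable).
#' @export
MW_PFOS_ACID <- 500.13

#' @rdname MW_PFOS_ACID
#' @export
MW_PFOS_K <- 538.22

#' Default reverse-dosimetry dose factor (ng/kg bw/day per ng/ml)
#'
#' The exact ratio of the anchor pair: a 172 ng/kg bw/day daily oral dose
#' produces 181 ng/ml in ovarian interstitial fluid at day 720, so
#' `172 / 181 = 0.950276...`. The mechanistic route
#' (`1 / doseToConcFactor(calibrateToAnchor(...))`) reproduces it.
#' @return numeric scalar.
#' @export
defaultDoseFactor <- function() 172 / 181

#' Convert nM to ng/ml
#'
#' `ng/ml = nM * MW / 1000`; exact inverse available via [ngPerMlToNM()].
#'
#' @param c concentration in nM, >= 0.
#' @param mw molecular weight (g/mol), default PFOS free acid.
#' @return concentration in ng/ml.
#' @examples
#' nMToNgPerMl(1000)  # 500.13
#' @export
nMToNgPerMl <- function(c, mw = MW_PFOS_ACID) {
  stopifnot(mw > 0)
  if (any(c < 0)) stop("concentration must be >= 0")
  c * mw / 1000
}

#' @rdname nMToNgPerMl
#' @export
ngPerMlToNM <- function(c, mw = MW_PFOS_ACID) {
  stopifnot(mw > 0)
  if (any(c < 0)) stop("concentration must be >= 0")
  c * 1000 / mw
}

#' Convert a BMC (nM) to a human-equivalent dose (ng/kg bw/day)
#'
#' `HED = nMToNgPerMl(bmc) * doseFactor`, the daily oral intake whose
#' end-of-regimen ovarian interstitial-fluid concentration equals the BMC.
#'
#' @param bmcNM benchmark concentration(s) in nM.
#' @param mw molecular weight (g/mol).
#' @param doseFactor dose per unit concentration (ng/kg bw/day per ng/ml);
#'   the reciprocal of [doseToConcFactor()]. Default [defaultDoseFactor()].
#' @return HED(s) in ng/kg bw/day.
#' @examples
#' bmcToHED(38.1)  # 18.1 ng/kg bw/day
#' @export
bmcToHED <- function(bmcNM, mw = MW_PFOS_ACID,
                     doseFactor = defaultDoseFactor()) {
  stopifnot(doseFactor > 0)
  nMToNgPerMl(bmcNM, mw) * doseFactor
}

#' @rdname bmcToHED
#' @export
hedToBMC <- function(hed, mw = MW_PFOS_ACID,
                     doseFactor = defaultDoseFactor()) {
  stopifnot(doseFactor > 0)
  ngPerMlToNM(hed / doseFactor, mw)
}

#' ART reference exposure from follicular-fluid HEDs
#'
#' The assisted-reproduction reference is consumed directly as HEDs
#' (min / median-of-study-medians / max; defaults 0.1 / 3.5 / 172 ng/kg
#' bw/day), or rebuilt from follicular-fluid concentrations when `conc` is
#' given.
#'
#' @param heds numeric length 3 (min, median, max), ng/kg bw/day.
#' @param conc optional follicular-fluid concentrations (ng/ml, length 3);
#'   converted with `doseFactor` and overriding `heds`.
#' @param doseFactor ng/kg bw/day per ng/ml.
#' @return A [ReferenceExposure-class].
#' @examples
#' referenceHEDs(artReference())
#' @export
artReference <- function(heds = c(min = 0.1, median = 3.5, max = 172),
                         conc = NULL, doseFactor = defaultDoseFactor()) {
  if (!is.null(conc)) {
    heds <- conc * doseFactor
  } else {
    conc <- rep(NA_real_, 3L)
  }
  new("ReferenceExposure", population = "ART",
      conc = stats::setNames(as.numeric(conc), c("min", "median", "max")),
      serum = stats::setNames(rep(NA_real_, 3L), c("min", "median", "max")),
      bfte = 1,
      hed = stats::setNames(as.numeric(heds), c("min", "median", "max")))
}

#' Occupational reference exposure from serum concentrations
#'
#' Follicular-fluid concentrations are predicted from serum as
#' `C_ff = C_serum * BFTE` (blood-to-follicular-fluid transfer efficiency,
#' default 0.75) and converted to HEDs with the reverse-dosimetry factor.
#' Defaults are the biomonitoring serum values of a fluorochemical
#' production cohort (426 / 1231 / 19564 ng/ml), which map to reference
#' HEDs of about 303.6 / 877.3 / 13943 ng/kg bw/day.
#'
#' @param serum numeric length 3 (min, median, max), ng/ml.
#' @param bfte transfer efficiency in (0, 1\].
#' @param doseFactor ng/kg bw/day per ng/ml.
#' @return A [ReferenceExposure-class].
#' @export
occupationalReference <- function(serum = c(min = 426, median = 1231,
                                            max = 19564),
                                  bfte = 0.75,
                                  doseFactor = defaultDoseFactor()) {
  if (bfte <= 0 || bfte > 1) stop("bfte must lie in (0, 1]")
  if (any(serum < 0)) stop("serum concentrations must be >= 0")
  conc <- serum * bfte
  new("ReferenceExposure", population = "occupational",
      conc = stats::setNames(as.numeric(conc), c("min", "median", "max")),
      serum = stats::setNames(as.numeric(serum), c("min", "median", "max")),
      bfte = bfte,
      hed = stats::setNames(as.numeric(conc * doseFactor),
                            c("min", "median", "max")))
}

#' Bioactivity exposure ratio
#'
#' `BER = HED_bioactive / HED_reference`; values below 1 mean the reference
#' exposure reaches bioactive levels. Summary outputs report BERs rounded to
#' one decimal ([berReport()]); full precision is kept internally.
#'
#' @param hedBioactive bioactive HED (ng/kg bw/day), > 0.
#' @param hedReference reference HED (ng/kg bw/day), > 0.
#' @return numeric ratio.
#' @examples
#' berReport(ber(1.4, 3.5))  # 0.4
#' @export
ber <- function(hedBioactive, hedReference) {
  if (any(hedReference <= 0)) stop("reference HED must be > 0")
  hedBioactive / hedReference
}

#' @rdname ber
#' @param x numeric BER value(s).
#' @export
berReport <- function(x) round(x, 1)

#' BER interval against a reference exposure
#'
#' Divides one bioactive HED by the minimum, median and maximum reference
#' HEDs. Dividing by a larger reference gives a smaller BER, so the interval
#' runs from `hed / hed_max_ref` up to `hed / hed_min_ref` and brackets the
#' median-based BER. Two below-1 flags are kept: against the median
#' reference (median-based claims) and against the minimum reference (the
#' whole interval below 1).
#'
#' @param hedBioactive bioactive HED (ng/kg bw/day).
#' @param reference a [ReferenceExposure-class] with positive HEDs.
#' @param endpointId identifier carried into the record.
#' @return one-row [S4Vectors::DataFrame]: endpoint_id, hed_bioactive,
#'   reference_id, ber_at_min_ref, ber_at_median_ref, ber_at_max_ref,
#'   below_one_median, below_one_min.
#' @export
berInterval <- function(hedBioactive, reference, endpointId = "endpoint") {
  stopifnot(is(reference, "ReferenceExposure"))
  h <- referenceHEDs(reference)
  if (any(h <= 0)) stop("all reference HEDs must be > 0")
  DataFrame(
    endpoint_id = endpointId,
    hed_bioactive = hedBioactive,
    reference_id = reference@population,
    ber_at_min_ref = hedBioactive / h[["min"]],
    ber_at_median_ref = hedBioactive / h[["median"]],
    ber_at_max_ref = hedBioactive / h[["max"]],
    below_one_median = hedBioactive / h[["median"]] < 1,
    below_one_min = hedBioactive / h[["min"]] < 1
  )
}

#' Flag genes with low BERs
#'
#' Genes whose HED falls below `threshold` times the reference HED, sorted
#' by ascending BER (most at-risk first).
#'
#' @param geneHeds named numeric vector, gene -> HED (ng/kg bw/day).
#' @param referenceHed reference HED, > 0.
#' @param threshold BER cutoff (default 1).
#' @return character vector of gene identifiers.
#' @export
flagLowBERGenes <- function(geneHeds, referenceHed, threshold = 1) {
  stopifnot(referenceHed > 0)
  if (!length(geneHeds)) return(character())
  bers <- geneHeds / referenceHed
  flagged <- bers[bers < threshold]
  names(flagged)[order(flagged)]
}

#' Pathway-level HED by median aggregation
#'
#' Median HED over the member genes of a gene set that have an HED (the
#' median of two values is their mean). Returns `NA` when no member gene
#' overlaps the HED map.
#'
#' @param geneHeds named numeric vector, gene -> HED.
#' @param geneSet character vector of member gene identifiers.
#' @return numeric scalar or `NA_real_`.
#' @examples
#' aggregatePathwayHED(c(a = 2.0, b = 3.6, c = 9), c("a", "b"))  # 2.8
#' @export
aggregatePathwayHED <- function(geneHeds, geneSet) {
  members <- geneHeds[names(geneHeds) %in% geneSet]
  if (!length(members)) return(NA_real_)
  unname(stats::quantile(members, 0.5, type = 7))
}

#' Summarize an HED distribution
#'
#' Same semantics as [summarizeBMCs()] on the HED scale: median or 5th
#' percentile (linear interpolation between order statistics) with a seeded
#' percentile-bootstrap 95% CI.
#'
#' @inheritParams summarizeBMCs
#' @param heds numeric HED values (ng/kg bw/day).
#' @return list with `estimate`, `ciLow`, `ciHigh`.
#' @export
summarizeHEDs <- function(heds, stat = c("median", "p5"),
                          bootstrapB = 1000L, seed = 1L) {
  summarizeBMCs(as.numeric(heds), stat = match.arg(stat),
                bootstrapB = bootstrapB, seed = seed)
}

#' Read gene sets from a GMT file
#'
#' @param file path to a GMT file (one set per line: name, description,
#'   member genes, tab-separated).
#' @return named list of character vectors.
#' @export
readGeneSets <- function(file) {
  fgsea::gmtPathways(file)
}
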
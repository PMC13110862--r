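# Albumin-binding correction: in vitro BMCs are total concentrations in
# medium with 10% FBS, where the PFOS free fraction is much higher than in
# human plasma (fu ~ 0.33%). Matching the free concentration across the two
# systems scales the equivalent total in vivo concentration up by
# fu_invitro / fu_plasma (~17-fold with the defaults).

#' Binding correction factor
#'
#' Factor by which a total in vitro concentration must be scaled so the
#' free concentration in plasma matches the free concentration in the
#' culture system: `fu_invitro / fu_plasma`.
#'
#' @param params a [CorrectionParams-class].
#' @return numeric factor >= 1 for the defaults (~16.68).
#' @examples
#' correctionFactor(correctionParams())  # 16.68
#' correctionFactor(correctionParams(fuPlasma = 0.05, fuInvitro = 0.05))  # 1
#' @export
correctionFactor <- function(params) {
  stopifnot(is(params, "CorrectionParams"))
  validObject(params)
  params@fuInvitro / params@fuPlasma
}

#' Free fraction under a different albumin concentration
#'
#' Single-site equilibrium binding far from saturation: bound/free scales
#' linearly with binding capacity, so
#' `fu = 1 / (1 + (1/fu_ref - 1) * albumin / albumin_ref)`.
#' A reference free fraction of 1 (no binding) stays 1 at any albumin level.
#'
#' @param fuRef free fraction at the reference albumin concentration.
#' @param albuminRef reference albumin concentration (g/l), e.g. 45 for
#'   plasma.
#' @param albumin albumin concentration of the target system (g/l).
#' @return free fraction in (0, 1\].
#' @examples
#' fuFromAlbumin(0.0033, 45, 45)   # 0.0033
#' fuFromAlbumin(0.0033, 45, 2.3)  # ~0.0609 (10% FBS medium)
#' @export
fuFromAlbumin <- function(fuRef, albuminRef, albumin) {
  stopifnot(fuRef > 0, fuRef <= 1, albuminRef > 0, albumin >= 0)
  if (fuRef == 1) return(1)
  1 / (1 + (1 / fuRef - 1) * albumin / albuminRef)
}

#' Apply the binding correction to BMC records
#'
#' Multiplies bmc, bmcl and bmcu by the factor and marks the provenance as
#' "albumin_corrected". The BMCU/BMCL ratio — hence the reliability filter —
#' is unchanged, and the correction commutes with the downstream HED
#' conversion (the whole chain is linear).
#'
#' @param records a BMC record [S4Vectors::DataFrame] (see [fitEndpoint()]),
#'   or a plain numeric vector of concentrations.
#' @param factor positive scale factor, typically [correctionFactor()].
#' @return records of the same shape, scaled.
#' @export
applyCorrection <- function(records, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("factor must be a positive scalar")
  if (is.numeric(records)) return(records * factor)
  records$bmc <- records$bmc * factor
  records$bmcl <- records$bmcl * factor
  records$bmcu <- records$bmcu * factor
  records$provenance <- "albumin_corrected"
  records
}
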
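# Williams trend screen: monotone concentration-response detection via the
# amalgamated (isotonic) highest-dose vs control contrast, with a
# permutation null and a fold-change prefilter. Defaults reproduce the
# screening stage applied upstream of BMC modeling: 500 permutations,
# 1.5-fold change, P < 0.05.

#' Weighted isotonic fit of group means (pool-adjacent-violators)
#'
#' Computes the weighted least-squares monotone fit of a sequence of group
#' means, the amalgamation step of Williams' trend procedure. Preserves the
#' weighted mean, is idempotent, and leaves already-monotone input
#' unchanged.
#'
#' @param means numeric vector of group means (dose order).
#' @param ns positive integer group sizes (weights); default equal.
#' @param direction "increasing" (non-decreasing fit) or "decreasing".
#' @return numeric vector of amalgamated means, monotone in `direction`.
#' @examples
#' pavaMonotoneMeans(c(0, 1.0, 0.4, 0.8))  # 0, 0.7, 0.7, 0.8
#' @export
pavaMonotoneMeans <- function(means, ns = rep(1L, length(means)),
                              direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  if (length(means) == 0L) stop("means must be non-empty")
  if (length(ns) != length(means)) stop("means and ns lengths differ")
  if (any(ns <= 0)) stop("group sizes must be positive")
  .pavaCpp(as.numeric(means), as.numeric(ns),
           direction == "increasing")
}

.groupIndex <- function(concentration) {
  lev <- sort(unique(concentration))
  list(index = match(concentration, lev) - 1L, nGroups = length(lev),
       levels = lev)
}

#' Williams trend statistic for one endpoint
#'
#' The statistic is the amalgamated mean of the highest-concentration group
#' minus the control mean, standardized by the pooled within-group variance:
#' `t = (mu~_top - mu^_0) / sqrt(s^2 (1/n_top + 1/n_0))`, maximized over the
#' increasing and decreasing orderings and signed by the winning direction.
#' Flat data give t = 0; screening uses |t|.
#'
#' @param row numeric response vector (one value per sample).
#' @param concentration numeric concentrations per sample (nM); needs >= 2
#'   groups with >= 2 replicates each.
#' @return list with `tBar` (signed statistic) and `pooledSd` (pooled
#'   within-group SD).
#' @examples
#' conc <- rep(c(0, 10, 100, 1000), each = 4)
#' williamsStatistic(rep(c(0, .5, 1, 1.5), each = 4) +
#'                   rnorm(16, sd = .1), conc)
#' @export
williamsStatistic <- function(row, concentration) {
  gi <- .groupIndex(concentration)
  if (gi$nGroups < 2L) stop("need >= 2 concentration groups")
  if (any(table(concentration) < 2L))
    stop("every concentration group needs >= 2 replicates")
  res <- .williamsStatCpp(matrix(as.numeric(row), nrow = 1L),
                          gi$index, gi$nGroups)
  list(tBar = res[1L, 1L], pooledSd = res[1L, 2L])
}

.permutationMatrix <- function(groupIndex, B, seed) {
  withr::with_seed(seed, {
    t(vapply(seq_len(B), function(b) sample(groupIndex),
             integer(length(groupIndex))))
  })
}

#' Permutation p-value of the Williams statistic
#'
#' Permutations shuffle the sample-to-concentration assignment; the p-value
#' uses the add-one estimator `p = (1 + #{|t*| >= |t_obs|}) / (B + 1)`, so
#' `p >= 1/(B+1)` always, and ties count as exceedances.
#'
#' @param row numeric response vector.
#' @param concentration sample concentrations (nM).
#' @param B number of permutations (default 500).
#' @param seed RNG seed; results are deterministic given it.
#' @return p-value in (0, 1\].
#' @export
permutationPvalue <- function(row, concentration, B = 500L, seed = 1L) {
  stopifnot(B >= 1L)
  gi <- .groupIndex(concentration)
  perms <- .permutationMatrix(gi$index, B, seed)
  cnt <- .williamsPermCountCpp(matrix(as.numeric(row), nrow = 1L),
                               gi$index, perms, gi$nGroups)
  (1 + cnt[1L]) / (B + 1)
}

#' Screen probes for monotone concentration-response
#'
#' Runs the Williams trend test with a permutation null on every probe and
#' applies the fold-change prefilter. A probe passes iff its permutation
#' p-value is below `alpha` and its largest absolute log2 difference from
#' control reaches `log2(fcThreshold)`. One shared set of permuted
#' assignments is used for all probes (the permutation distribution depends
#' only on the design), which keeps the screen O(genes x B) and
#' reproducible.
#'
#' @param x a [DoseResponseExperiment-class].
#' @param alpha significance level of the permutation test (default 0.05).
#' @param fcThreshold fold-change threshold on the natural scale (default
#'   1.5; applied as |delta log2 mean| >= log2(1.5)).
#' @param B number of permutations (default 500).
#' @param seed RNG seed for the permutations.
#' @return [S4Vectors::DataFrame] with one row per probe: gene_id, t_bar,
#'   pooled_sd, perm_p, max_abs_log2fc, passes.
#' @examples
#' dre <- generateExpressionMatrix(syntheticDesign(nGenes = 40))
#' res <- screenProbes(dre, B = 100)
#' table(res$passes)
#' @export
screenProbes <- function(x, alpha = 0.05, fcThreshold = 1.5, B = 500L,
                         seed = 1L) {
  stopifnot(is(x, "DoseResponseExperiment"))
  validObject(x)
  mat <- assay(x)
  conc <- concentrations(x)
  gi <- .groupIndex(conc)
  if (nrow(mat) == 0L) {
    return(DataFrame(gene_id = character(), t_bar = numeric(),
                     pooled_sd = numeric(), perm_p = numeric(),
                     max_abs_log2fc = numeric(), passes = logical()))
  }
  obs <- .williamsStatCpp(mat, gi$index, gi$nGroups)
  perms <- .permutationMatrix(gi$index, B, seed)
  cnt <- .williamsPermCountCpp(mat, gi$index, perms, gi$nGroups)
  permP <- (1 + cnt) / (B + 1)
  # max |group mean - control mean| over non-control concentrations
  groupMeans <- vapply(gi$levels, function(g)
    rowMeans(mat[, conc == g, drop = FALSE]), numeric(nrow(mat)))
  if (is.null(dim(groupMeans)))
    groupMeans <- matrix(groupMeans, nrow = 1L)
  fc <- apply(abs(groupMeans[, -1L, drop = FALSE] - groupMeans[, 1L]),
              1L, max)
  DataFrame(
    gene_id = rownames(mat),
    t_bar = obs[, 1L],
    pooled_sd = obs[, 2L],
    perm_p = permP,
    max_abs_log2fc = fc,
    passes = permP < alpha & fc >= log2(fcThreshold),
    row.names = rownames(mat)
  )
}
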
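# Plain-text interchange: every stage reads and writes TSV/JSON so each is
# independently re-runnable.

#' Write / read an expression matrix as TSV
#'
#' The TSV dialect used throughout: first column `gene_id`, one column per
#' sample named `conc_<nM>_rep<j>`, log2 values.
#'
#' @param x a [DoseResponseExperiment-class].
#' @param file path.
#' @return `writeExpressionMatrix` returns `file` invisibly;
#'   `readExpressionMatrix` returns a [DoseResponseExperiment-class].
#' @export
writeExpressionMatrix <- function(x, file) {
  stopifnot(is(x, "DoseResponseExperiment"))
  df <- data.frame(gene_id = rownames(x), assay(x), check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeExpressionMatrix
#' @export
readExpressionMatrix <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  stopifnot("gene_id" %in% colnames(df))
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df$gene_id
  hdr <- colnames(values)
  m <- regmatches(hdr, regexec("^conc_([0-9.eE+-]+)_rep([0-9]+)$", hdr))
  bad <- lengths(m) != 3L
  if (any(bad))
    stop("malformed sample headers: ", paste(hdr[bad], collapse = ", "))
  conc <- vapply(m, function(g) as.numeric(g[2L]), numeric(1))
  repl <- vapply(m, function(g) as.integer(g[3L]), integer(1))
  DoseResponseExperiment(values, conc, repl, geneIds = df$gene_id)
}

#' Write the planted truth table as TSV
#'
#' Curve parameters are serialized as `name=value` pairs in one column.
#'
#' @param x a synthetic [DoseResponseExperiment-class].
#' @param file path.
#' @return `file`, invisibly.
#' @export
writeTruthTable <- function(x, file) {
  tr <- truthRecords(x)
  if (is.null(tr)) stop("experiment carries no planted truth")
  tr$params <- vapply(tr$params, function(p)
    paste(sprintf("%s=%g", names(p), unlist(p)), collapse = ";"),
    character(1))
  utils::write.table(tr, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a result table (screen results, BMC records, BER report) as TSV
#'
#' @param records a [S4Vectors::DataFrame] or data.frame.
#' @param file path.
#' @return `file`, invisibly.
#' @export
writeResultTable <- function(records, file) {
  utils::write.table(as.data.frame(records), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a reference-exposure table
#'
#' TSV with columns `population`, `statistic` (min/median/max) and either
#' `hed` (ng/kg bw/day) or `serum_ng_ml`; occupational serum rows are
#' converted through BFTE and the dose factor.
#'
#' @param file path.
#' @param bfte blood-to-follicular-fluid transfer efficiency.
#' @param doseFactor ng/kg bw/day per ng/ml.
#' @return named list of [ReferenceExposure-class] objects.
#' @export
readReferenceTable <- function(file, bfte = 0.75,
                               doseFactor = defaultDoseFactor()) {
  df <- utils::read.delim(file)
  stopifnot(all(c("population", "statistic") %in% colnames(df)))
  out <- list()
  for (pop in unique(df$population)) {
    sub <- df[df$population == pop, ]
    g <- function(col) {
      v <- sub[[col]][match(c("min", "median", "max"), sub$statistic)]
      stats::setNames(as.numeric(v), c("min", "median", "max"))
    }
    ref <- if ("hed" %in% colnames(sub) && !anyNA(g("hed"))) {
      artReference(heds = g("hed"), doseFactor = doseFactor)
    } else {
      occupationalReference(serum = g("serum_ng_ml"), bfte = bfte,
                            doseFactor = doseFactor)
    }
    ref@population <- pop
    out[[pop]] <- ref
  }
  out
}
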
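# End-to-end orchestration: screen -> fit -> filter -> (optional albumin
# correction) -> HED -> BER, driven by a single structured config with
# explicit seeds, writing plain TSV/JSON stage outputs plus a run manifest.

#' Default pipeline configuration
#'
#' A complete config list, suitable as-is for a synthetic demonstration run
#' or as a template. Sections: `data` (synthetic design or a TSV path),
#' `screen` (alpha, fc_threshold, permutations, seed), `fit` (models,
#' restricted, bmr_sd, bootstrap, seed), `filters` (ratio_max), `correction`
#' (enabled, fu_plasma, fu_invitro), `pbtk` (use_model, anchor_conc,
#' anchor_dose and the physiological parameters), `units`
#' (molecular_weight), `references` (art_heds, occupational_serum, bfte,
#' optional gmt path), `output` (dir).
#'
#' @param outputDir output directory.
#' @return nested named list.
#' @export
defaultPipelineConfig <- function(outputDir = tempfile("bmcber_run_")) {
  list(
    data = list(
      source = "synthetic",
      synthetic = list(n_genes = 200L, responder_fraction = 0.15,
                       noise_sd = 0.25, seed = 101L),
      tsv = NULL
    ),
    screen = list(alpha = 0.05, fc_threshold = 1.5, permutations = 500L,
                  seed = 202L),
    fit = list(models = .MODEL_ORDER, restricted = TRUE, bmr_sd = 1,
               bootstrap = 1000L, seed = 303L),
    filters = list(ratio_max = 40),
    correction = list(enabled = FALSE, fu_plasma = 0.0033,
                      fu_invitro = 0.05506),
    pbtk = list(use_model = FALSE, anchor_conc = 181, anchor_dose = 172,
                body_weight = 70, half_life_days = 1971,
                absorption_rate = 1, volume_central = 0.23,
                ovary_plasma_flow = 28.8, ovary_volume = 0.011,
                ovary_partition = 0.38088, duration_days = 720),
    units = list(molecular_weight = MW_PFOS_ACID),
    references = list(art_heds = c(0.1, 3.5, 172),
                      occupational_serum = c(426, 1231, 19564),
                      bfte = 0.75, gmt = NULL),
    output = list(dir = outputDir)
  )
}

.loadConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- defaultPipelineConfig()
  mergeLists <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        mergeLists(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  mergeLists(base, config)
}

.pipelineDoseFactor <- function(cfg) {
  pb <- cfg$pbtk
  if (isTRUE(pb$use_model)) {
    params <- pbtkParameters(
      bodyWeight = pb$body_weight, absorptionRate = pb$absorption_rate,
      volumeCentral = pb$volume_central, halfLife = pb$half_life_days,
      ovaryPlasmaFlow = pb$ovary_plasma_flow, ovaryVolume = pb$ovary_volume,
      ovaryInterstitialPartition = pb$ovary_partition)
    params <- calibrateToAnchor(params, pb$anchor_conc, pb$anchor_dose,
                                regimen = dosingRegimen(1, pb$duration_days))
    1 / doseToConcFactor(params,
                         regimen = dosingRegimen(1, pb$duration_days))
  } else {
    pb$anchor_dose / pb$anchor_conc
  }
}

#' Run the whole pipeline
#'
#' Executes screen -> fit -> filter -> (optional correction) -> HED -> BER
#' on the configured input, writes per-stage TSV/JSON outputs to the output
#' directory, and returns a manifest recording package version, seeds,
#' parameters, per-stage record counts and every file written. Re-running
#' with the same config is bit-identical (the manifest timestamp aside).
#'
#' @param config a config list (see [defaultPipelineConfig()]) or the path
#'   to a YAML file with the same structure; missing entries fall back to
#'   the defaults.
#' @return the manifest, invisibly.
#' @examples
#' \donttest{
#' cfg <- defaultPipelineConfig()
#' cfg$data$synthetic$n_genes <- 50L
#' cfg$screen$permutations <- 100L
#' manifest <- runPipeline(cfg)
#' manifest$counts
#' }
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  cfg <- .loadConfig(config)
  dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(name) file.path(cfg$output$dir, name)
  files <- character()
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("[", name, "] stage failed: ", conditionMessage(e), call. = FALSE))
  }

  dre <- stage("data", {
    if (identical(cfg$data$source, "synthetic")) {
      sy <- cfg$data$synthetic
      generateExpressionMatrix(syntheticDesign(
        nGenes = sy$n_genes, responderFraction = sy$responder_fraction,
        noiseSd = sy$noise_sd, seed = sy$seed))
    } else {
      readExpressionMatrix(cfg$data$tsv)
    }
  })

  screen <- stage("screen", {
    sc <- cfg$screen
    res <- screenProbes(dre, alpha = sc$alpha,
                        fcThreshold = sc$fc_threshold,
                        B = sc$permutations, seed = sc$seed)
    files["screen"] <- writeResultTable(res, outfile("screen_results.tsv"))
    res
  })

  maxDose <- max(doseLevels(dre))
  records <- stage("fit", {
    recs <- fitBMCs(dre, screen, models = cfg$fit$models,
                    bmrSd = cfg$fit$bmr_sd,
                    restricted = cfg$fit$restricted)
    recs <- filterBMCRecords(recs, maxDose,
                             ratioMax = cfg$filters$ratio_max)
    files["bmc"] <- writeResultTable(recs, outfile("bmc_records.tsv"))
    recs
  })
  retained <- records[isTRUE_v(records$passes_filters), ]

  if (isTRUE(cfg$correction$enabled)) {
    retained <- stage("correction", {
      cp <- correctionParams(fuPlasma = cfg$correction$fu_plasma,
                             fuInvitro = cfg$correction$fu_invitro)
      out <- applyCorrection(retained, correctionFactor(cp))
      files["corrected"] <- writeResultTable(
        out, outfile("bmc_records_corrected.tsv"))
      out
    })
  }

  doseFactor <- stage("pbtk", .pipelineDoseFactor(cfg))

  heds <- stage("hed", {
    h <- if (nrow(retained))
      stats::setNames(bmcToHED(retained$bmc, cfg$units$molecular_weight,
                               doseFactor),
                      retained$endpoint_id)
    else stats::setNames(numeric(), character())
    files["hed"] <- writeResultTable(
      data.frame(endpoint_id = names(h), hed_ng_kg_day = unname(h)),
      outfile("heds.tsv"))
    h
  })

  berOut <- stage("ber", {
    refs <- list(
      ART = artReference(heds = cfg$references$art_heds,
                         doseFactor = doseFactor),
      occupational = occupationalReference(
        serum = cfg$references$occupational_serum,
        bfte = cfg$references$bfte, doseFactor = doseFactor))
    summary <- list(doseFactor = doseFactor)
    rows <- list()
    if (length(heds)) {
      med <- summarizeHEDs(heds, "median", cfg$fit$bootstrap, cfg$fit$seed)
      p5 <- summarizeHEDs(heds, "p5", cfg$fit$bootstrap, cfg$fit$seed)
      summary$hed_median <- med
      summary$hed_p5 <- p5
      for (nm in names(refs)) {
        rows[[paste0("median_", nm)]] <-
          berInterval(med$estimate, refs[[nm]], "hed_median")
        rows[[paste0("p5_", nm)]] <-
          berInterval(p5$estimate, refs[[nm]], "hed_p5")
      }
      summary$low_ber_genes <-
        flagLowBERGenes(heds, referenceHEDs(refs$ART)[["median"]])
      if (!is.null(cfg$references$gmt)) {
        sets <- readGeneSets(cfg$references$gmt)
        summary$pathway_heds <- vapply(sets, aggregatePathwayHED,
                                       numeric(1), geneHeds = heds)
      }
    }
    report <- if (length(rows)) do.call(rbind, rows)
              else berInterval(1, refs$ART)[0L, ]
    files["ber"] <- writeResultTable(report, outfile("ber_report.tsv"))
    files["summary"] <- outfile("summary.json")
    jsonlite::write_json(summary, files["summary"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    report
  })

  manifest <- list(
    package = as.character(utils::packageVersion("bmcber")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = cfg,
    counts = list(
      genes = nrow(dre),
      screen_passed = sum(screen$passes),
      bmc_fitted = sum(!is.na(records$bmc)),
      bmc_retained = nrow(retained),
      ber_rows = nrow(berOut)
    ),
    files = as.list(files)
  )
  mpath <- outfile("manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}

#' Replay the desk-reproducible printed-value chain
#'
#' Recomputes, through the package's own conversion chain, every published
#' summary value that is derivable without the deposited expression data,
#' and compares each with its printed counterpart at the printed precision.
#'
#' @param fixture constants from [printedValuesFixture()].
#' @return `data.frame` with columns check, computed, printed, rel_error,
#'   pass (one row per replayed value); empty fixture gives zero rows.
#' @examples
#' acceptanceReport()
#' @export
acceptanceReport <- function(fixture = printedValuesFixture()) {
  empty <- data.frame(check = character(), computed = numeric(),
                      printed = numeric(), rel_error = numeric(),
                      pass = logical(), stringsAsFactors = FALSE)
  if (!length(fixture)) return(empty)
  f <- defaultDoseFactor()
  occ <- occupationalReference(serum = fixture$occupational_serum)
  rows <- list(
    list("hed_median_transcriptomic_6wk",
         bmcToHED(fixture$bmc_median_transcriptomic_6wk),
         fixture$hed_median_transcriptomic_6wk),
    list("bmc_median_apical_6wk",
         summarizeBMCs(hedToBMC(c(fixture$hed_apical_subg1,
                                  fixture$hed_apical_estradiol)))$estimate,
         fixture$bmc_median_apical_6wk),
    list("occupational_ref_hed_median",
         referenceHEDs(occ)[["median"]],
         unname(fixture$occupational_ref["median"])),
    list("occupational_ref_hed_min",
         referenceHEDs(occ)[["min"]],
         unname(fixture$occupational_ref["min"])),
    list("ber_p5_transcriptomic_12wk",
         berReport(ber(fixture$hed_p5_transcriptomic_12wk,
                       fixture$ART_ref_median)), 0.4),
    list("ber_pathway_eicosanoid",
         berReport(ber(fixture$hed_pathway_eicosanoid,
                       fixture$ART_ref_median)), 0.8),
    list("ber_apical_subg1",
         berReport(ber(fixture$hed_apical_subg1,
                       fixture$ART_ref_median)), 0.1),
    list("occupational_ber_max",
         max(ber(c(fixture$hed_median_transcriptomic_6wk,
                   fixture$hed_median_transcriptomic_12wk,
                   fixture$hed_median_apical_12wk,
                   fixture$hed_median_apical_6wk,
                   fixture$hed_pathway_eicosanoid,
                   fixture$hed_pathway_il6,
                   fixture$hed_apical_subg1,
                   fixture$hed_apical_estradiol),
                 referenceHEDs(occ)[["min"]])),
         1),  # all occupational BERs below 1
    list("albumin_correction_fold",
         round(correctionFactor(correctionParams())),
         17),
    list("ART_ref_hed_min",
         round(fixture$follicular_fluid_range_ng_ml[["min"]] * f, 1),
         fixture$ART_ref_min)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    printed <- as.numeric(r[[3L]])
    computed <- as.numeric(r[[2L]])
    digits <- max(0L, nchar(sub("^[^.]*\\.?", "", format(printed))))
    pass <- if (identical(r[[1L]], "occupational_ber_max"))
      computed < printed
    else round(computed, digits) == printed
    data.frame(check = r[[1L]], computed = computed, printed = printed,
               rel_error = abs(computed - printed) / max(abs(printed),
                                                         .Machine$double.eps),
               pass = pass, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
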
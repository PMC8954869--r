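# Replicate harness: runs the association methods over seeded simulation
# replicates and tallies empirical power and false positive rates across a
# significance grid, mirroring the study's table layouts.

#' Default smoothing/compression parameters by layout and method
#'
#' Homogeneous SLoS defaults: 0.1/0.1 for common-variant layouts, 0.01/0.01
#' for rare-variant layouts, 0.05/0.05 for the hybrid layouts, and
#' 0.001/0.001 for the loci-weighted (mixed10) study. W-SLoS uses per-region
#' values from [wslosConfig] according to each region's type.
#'
#' @param layout a design layout string.
#' @param method method name.
#' @param dataset the assembled dataset (needed by "w-slos" to read region
#'   types off the region ids).
#' @return a [SLoSConfig-class].
#' @export
defaultSLoSConfig <- function(layout, method = "multi-slos",
                              dataset = NULL) {
  if (method == "w-slos") {
    ids <- regionIds(dataset)
    commonIdx <- grep("^(common|hybrid2|mixed)", ids)
    rareIdx <- grep("^rare", ids)
    return(wslosConfig(commonIdx, rareIdx))
  }
  if (method == "lw-slos") return(slosConfig(0.001, 0.001))
  v <- switch(layout, common25 = 0.1, rare25 = 0.01,
              hybridI = 0.05, hybridII = 0.05, mixed10 = 0.001, 0.1)
  slosConfig(v, v)
}

# Dispatch one method on a dataset; returns the per-region result table.
applyMethod <- function(method, dataset, layout, K = 25L, params = list()) {
  lw <- params$weights
  if (is.null(lw)) lw <- locusWeightScheme(1, 10)
  cfg <- params$config
  if (is.null(cfg) && grepl("slos", method))
    cfg <- defaultSLoSConfig(layout, method, dataset)
  switch(method,
    "step" = stepTest(dataset, K = K),
    "lw-step" = stepTest(dataset, K = K, weights = lw),
    "forward-step" = stepTest(dataset, K = K, direction = "forward"),
    "multi-slos" = slosTest(dataset, K = K, config = cfg),
    "w-slos" = slosTest(dataset, K = K, config = cfg),
    "lw-slos" = slosTest(dataset, K = K, config = cfg, weights = lw),
    "slos" = singleRegionSLoSTest(dataset, K = K, config = cfg),
    "flm" = singleRegionFTest(dataset, K = K),
    stop("unknown method '", method, "'"))
}

#' Experiment configuration
#'
#' @param design a [SimulationDesign-class].
#' @param methods character subset of "step", "lw-step", "forward-step",
#'   "multi-slos", "w-slos", "lw-slos", "slos" (single-region SLoS), "flm"
#'   (single-region F baseline).
#' @param alphas significance grid (default the study's six levels).
#' @param replicates number of seeded replicates (default 100).
#' @param baseSeed replicate r uses seed `baseSeed + r`.
#' @param K Fourier basis count for the genotype stage.
#' @param methodParams named list of per-method parameter lists (entries
#'   `config` for a [SLoSConfig-class], `weights` for a [LocusWeightScheme]).
#' @param includeNull also run every method on a separate pure-noise
#'   phenotype (N(0, sd 0.1)) per replicate and report its rejection rate.
#' @param verbose emit progress messages.
#' @return list of class `ExperimentConfig`.
#' @export
experimentConfig <- function(design, methods = "step",
                             alphas = c(0.05, 0.01, 1e-3, 1e-4, 1e-6, 1e-8),
                             replicates = 100L, baseSeed = 1L, K = 25L,
                             methodParams = list(), includeNull = FALSE,
                             verbose = FALSE) {
  stopifnot(replicates >= 1L, all(alphas > 0), all(alphas <= 1))
  structure(list(design = design, methods = methods, alphas = alphas,
                 replicates = as.integer(replicates),
                 baseSeed = as.integer(baseSeed), K = as.integer(K),
                 methodParams = methodParams, includeNull = includeNull,
                 verbose = verbose),
            class = "ExperimentConfig")
}

#' Run a power / false-positive-rate experiment
#'
#' For each replicate: assemble the layout, assign effects, simulate the
#' trait, apply every configured method, and tally per-region significance
#' at each alpha. Power is significant-and-truly-associated region tests
#' over all associated region tests; the false positive rate is the same
#' fraction among unassociated regions of the same runs. With
#' `includeNull = TRUE` each method is additionally run on a separate
#' pure-noise phenotype and that rejection rate is reported as `fprNull`.
#' A method failure in a replicate is recorded and excluded from that
#' method's denominators. Deterministic given `baseSeed`.
#'
#' @param config an `ExperimentConfig` from [experimentConfig].
#' @return `PowerTable`: data.frame with one row per (method, alpha) carrying
#'   `power`, `fpr`, optionally `fprNull`, Monte-Carlo standard errors and
#'   tally counts. Per-region rates are attached as
#'   `attr(, "regionRates")`; failures as `attr(, "failures")`.
#' @export
runExperiment <- function(config) {
  des <- config$design
  P <- if (des@layout == "mixed10") 10L else 25L
  nm <- length(config$methods)
  na <- length(config$alphas)
  dimn <- list(config$methods, paste0("a", seq_len(na)), NULL)
  hitA <- array(0L, c(nm, na, P), dimnames = dimn)   # significant & assoc
  hitU <- array(0L, c(nm, na, P), dimnames = dimn)   # significant & unassoc
  hitN <- array(0L, c(nm, na, P), dimnames = dimn)   # significant, null trait
  runsA <- matrix(0L, nm, P)   # associated region tests attempted
  runsU <- matrix(0L, nm, P)
  runsN <- matrix(0L, nm, P)
  failures <- data.frame(method = character(0), replicate = integer(0),
                         message = character(0), stringsAsFactors = FALSE)
  for (r in seq_len(config$replicates)) {
    study <- simulateStudy(des, seed = config$baseSeed + r)
    assocMask <- seq_len(P) %in% study$assoc
    ynull <- if (config$includeNull) nullTrait(nIndividuals(study$dataset))
             else NULL
    for (mi in seq_len(nm)) {
      m <- config$methods[mi]
      res <- tryCatch(
        applyMethod(m, study$dataset, des@layout, config$K,
                    config$methodParams[[m]]),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures <- rbind(failures,
                          data.frame(method = m, replicate = r,
                                     message = conditionMessage(res),
                                     stringsAsFactors = FALSE))
      } else {
        runsA[mi, assocMask] <- runsA[mi, assocMask] + 1L
        runsU[mi, !assocMask] <- runsU[mi, !assocMask] + 1L
        for (ai in seq_len(na)) {
          s <- res$p_value < config$alphas[ai]
          hitA[mi, ai, ] <- hitA[mi, ai, ] + (s & assocMask)
          hitU[mi, ai, ] <- hitU[mi, ai, ] + (s & !assocMask)
        }
      }
      if (!is.null(ynull)) {
        dn <- study$dataset
        trait(dn) <- ynull
        resN <- tryCatch(
          applyMethod(m, dn, des@layout, config$K,
                      config$methodParams[[m]]),
          error = function(e) e)
        if (!inherits(resN, "error")) {
          runsN[mi, ] <- runsN[mi, ] + 1L
          for (ai in seq_len(na))
            hitN[mi, ai, ] <- hitN[mi, ai, ] +
              (resN$p_value < config$alphas[ai])
        }
      }
    }
    if (config$verbose)
      message("replicate ", r, "/", config$replicates, " done")
  }
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  rows <- do.call(rbind, lapply(seq_len(nm), function(mi) {
    do.call(rbind, lapply(seq_len(na), function(ai) {
      nA <- sum(runsA[mi, ]); nU <- sum(runsU[mi, ]); nN <- sum(runsN[mi, ])
      pw <- rate(sum(hitA[mi, ai, ]), nA)
      fp <- rate(sum(hitU[mi, ai, ]), nU)
      fn <- rate(sum(hitN[mi, ai, ]), nN)
      data.frame(method = config$methods[mi], scenario = des@scenario,
                 alpha = config$alphas[ai], power = pw, fpr = fp,
                 fprNull = fn,
                 powerSE = if (is.na(pw)) NA_real_
                           else sqrt(pw * (1 - pw) / max(nA, 1)),
                 fprSE = if (is.na(fp)) NA_real_
                         else sqrt(fp * (1 - fp) / max(nU, 1)),
                 nAssoc = nA, nUnassoc = nU, nNull = nN,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  regionRates <- do.call(rbind, lapply(seq_len(nm), function(mi) {
    do.call(rbind, lapply(seq_len(na), function(ai) {
      data.frame(method = config$methods[mi], alpha = config$alphas[ai],
                 region = seq_len(P),
                 powerRegion = ifelse(runsA[mi, ] > 0,
                                      hitA[mi, ai, ] / pmax(runsA[mi, ], 1),
                                      NA_real_),
                 fprRegion = ifelse(runsU[mi, ] > 0,
                                    hitU[mi, ai, ] / pmax(runsU[mi, ], 1),
                                    NA_real_),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (!config$includeNull) rows$fprNull <- NULL
  structure(rows, class = c("PowerTable", "data.frame"),
            regionRates = regionRates, failures = failures,
            config = config)
}

#' Write a PowerTable to TSV/JSON artifacts
#'
#' Emits `power.tsv` and `fpr.tsv` (rows = (scenario, alpha), columns =
#' methods), `subregion.tsv` with the per-region rates (the per-subregion
#' power/FPR sheets of the mixed layout), and `results.json` with the whole
#' table; returns the file paths invisibly.
#'
#' @param table a `PowerTable` from [runExperiment].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
tabulateResults <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide <- function(col) {
    out <- unique(table[, c("scenario", "alpha")])
    for (m in unique(table$method))
      out[[m]] <- table[[col]][table$method == m][
        match(paste(out$scenario, out$alpha),
              paste(table$scenario[table$method == m],
                    table$alpha[table$method == m]))]
    out
  }
  paths <- c(power = file.path(dir, "power.tsv"),
             fpr = file.path(dir, "fpr.tsv"),
             subregion = file.path(dir, "subregion.tsv"),
             json = file.path(dir, "results.json"))
  utils::write.table(wide("power"), paths["power"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(wide("fpr"), paths["fpr"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(attr(table, "regionRates"), paths["subregion"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(rates = as.data.frame(table),
                            regionRates = attr(table, "regionRates"),
                            failures = attr(table, "failures")),
                       paths["json"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
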
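#' @include AllClasses.R synthetic.R inference.R effector.R diagnostics.R io.R
NULL

#' Default pipeline configuration
#'
#' Every pipeline setting with its default: the global seed, output
#' directory, model constants (assay and in vivo complex concentration,
#' crosslinking constant, in vivo valency), sampler settings, behavioral
#' flags, and the synthetic-design parameters used when no measurement
#' files are supplied. The configuration round-trips losslessly through
#' YAML ([writeRunConfig()] / [readRunConfig()]).
#'
#' @return Nested list of settings.
#' @export
defaultRunConfig <- function() {
    list(
        seed = 1L,
        out = "fcbindmix-run",
        simulate = TRUE,
        inputs = list(measurements = NULL, documented = NULL, se = NULL,
                      expression = NULL, profiles = NULL, depletion = NULL),
        model = list(L0 = 1e-9, kxStar = 6.31e-13,
                     invivoL0 = 1e-9, invivoValency = 4),
        sampler = list(chains = 4L, warmup = 1000L, draws = 1000L),
        flags = list(fixAffinities = FALSE, useMixtures = FALSE,
                     centerPca = TRUE, dedupePure = FALSE),
        synthetic = list(receptors = panelReceptors(),
                         subclasses = panelSubclasses(),
                         replicates = 3L, micePerCondition = 6L,
                         depletionNoiseSd = 0.05,
                         documentedSeFraction = 0.25,
                         expressionReplicates = 3L,
                         expressionNoiseSd = 0.1))
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file path.
#' @param config configuration list (missing fields are filled from
#'   [defaultRunConfig()] on read).
#' @return \code{readRunConfig}: complete configuration list;
#'   \code{writeRunConfig}: the path, invisibly.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    mergeCfg <- function(base, upd) {
        for (nm in names(upd)) {
            base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
                mergeCfg(base[[nm]], upd[[nm]]) else upd[[nm]]
        }
        base
    }
    mergeCfg(defaultRunConfig(), user)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

.requireInput <- function(path, what) {
    if (is.null(path)) stop("no input path configured for ", what)
    if (!file.exists(path)) stop(what, " input not found: ", path)
    path
}

## Simulated "documented" affinity knowledge: the generating truth plus a
## relative standard error, mimicking a literature affinity table.
.syntheticDocumented <- function(truth, seFraction) {
    ka <- truth$affinities@.Data
    list(documented = truth$affinities, se = ka * seFraction)
}

.simulateExpressionTable <- function(truth, replicates, noiseSd, seed) {
    set.seed(as.integer(seed))
    rec <- names(truth$receptorExpression)
    d <- expand.grid(receptor = rec, replicate = seq_len(replicates),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    d$sites_per_cell <- truth$receptorExpression[d$receptor] *
        exp(stats::rnorm(nrow(d), 0, noiseSd))
    d$replicate <- as.character(d$replicate)
    d
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages end to end: (1) simulate or load the
#' replicated binding panel, documented affinities, and receptor
#' expression; (2) build priors and fit the binding model by MAP + MCMC on
#' single-composition records; (3) predict the held-out mixture conditions
#' from posterior medians; (4) simulate or load a depletion study and fit
#' effector cell-type weights; (5) write descriptive diagnostics; (6) write
#' a machine-readable run manifest (seed, versions, file checksums). Any
#' stage failure aborts with the stage name.
#'
#' @param config configuration list, see [defaultRunConfig()].
#' @return Invisibly, a list with the artifact directory, per-stage
#'   results, and the manifest.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
    cfg <- config
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    stage <- "setup"
    res <- list()
    runStage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    ## --- stage: data ----------------------------------------------------
    truth <- NULL
    if (isTRUE(cfg$simulate)) {
        res$data <- runStage("simulate", {
            truth <- sampleGroundTruth(
                seed = cfg$seed,
                receptors = cfg$synthetic$receptors,
                subclasses = cfg$synthetic$subclasses)
            design <- factorialDesign(receptors = cfg$synthetic$receptors,
                                      subclasses = cfg$synthetic$subclasses,
                                      dedupePure = isTRUE(cfg$flags$dedupePure))
            panel <- simulateBindingPanel(truth, design,
                                          replicates = cfg$synthetic$replicates,
                                          seed = cfg$seed + 1L,
                                          L0 = cfg$model$L0)
            doc <- .syntheticDocumented(truth,
                                        cfg$synthetic$documentedSeFraction)
            expr <- .simulateExpressionTable(
                truth, cfg$synthetic$expressionReplicates,
                cfg$synthetic$expressionNoiseSd, cfg$seed + 2L)
            panelOut <- panel
            panelOut$replicate <- as.character(panelOut$replicate)
            writeTable(panelOut, file.path(cfg$out, "measurements.csv"),
                       "measurements")
            writeAffinityCsv(doc$documented,
                             file.path(cfg$out, "documented_affinities.csv"))
            writeAffinityCsv(doc$se,
                             file.path(cfg$out, "documented_se.csv"))
            writeTable(expr, file.path(cfg$out, "receptor_expression.csv"),
                       "receptor_expression")
            jsonlite::write_json(
                list(affinities = as.data.frame(truth$affinities@.Data),
                     receptorExpression = as.list(truth$receptorExpression),
                     kxStar = truth$kxStar, f4 = truth$f4, f33 = truth$f33,
                     sigmaObs = truth$sigmaObs,
                     cellWeights = as.list(truth$cellWeights)),
                file.path(cfg$out, "ground_truth.json"),
                auto_unbox = TRUE, digits = NA)
            list(panel = panel, documented = doc$documented, se = doc$se,
                 expression = expr, truth = truth)
        })
        truth <- res$data$truth
    } else {
        res$data <- runStage("load", {
            panel <- readTable(.requireInput(cfg$inputs$measurements,
                                             "measurements"), "measurements")
            panel$replicate <- as.character(panel$replicate)
            list(panel = panel,
                 documented = readAffinityCsv(
                     .requireInput(cfg$inputs$documented,
                                   "documented affinities")),
                 se = as.matrix(readAffinityCsv(
                     .requireInput(cfg$inputs$se,
                                   "affinity standard errors"))@.Data),
                 expression = readTable(
                     .requireInput(cfg$inputs$expression,
                                   "receptor expression"),
                     "receptor_expression"))
        })
    }

    ## --- stage: priors + fit -------------------------------------------
    res$fit <- runStage("fit-affinities", {
        priors <- priorSet(
            buildAffinityPriors(res$data$documented, res$data$se),
            buildReceptorPriors(receptorExpressionList(res$data$expression)))
        ps <- runMcmc(res$data$panel, priors,
                      config = list(chains = cfg$sampler$chains,
                                    warmup = cfg$sampler$warmup,
                                    draws = cfg$sampler$draws,
                                    seed = cfg$seed),
                      fixedAffinities = if (isTRUE(cfg$flags$fixAffinities))
                          res$data$documented else NULL,
                      useMixtures = isTRUE(cfg$flags$useMixtures),
                      L0 = cfg$model$L0)
        summ <- posteriorSummary(ps)
        writeTable(summ, file.path(cfg$out, "posterior_summary.csv"),
                   "posterior_summary")
        list(priors = priors, posterior = ps, summary = summ)
    })

    ## --- stage: predict held-out mixtures ------------------------------
    res$predict <- runStage("predict-binding", {
        med <- stats::setNames(res$fit$summary$median,
                               res$fit$summary$parameter)
        mix <- res$data$panel[!(res$data$panel$frac_a %in% c(0, 1)), ,
                              drop = FALSE]
        pred <- predictMeasurement(med, mix, res$fit$priors,
                                   L0 = cfg$model$L0)
        ## 90% posterior-predictive interval per held-out record: thinned
        ## posterior draws pushed through the binding model plus one
        ## observation-noise draw each.
        dr <- posteriorDraws(res$fit$posterior)
        nIter <- dim(dr)[1]; nCh <- dim(dr)[2]
        flat <- matrix(aperm(dr, c(1, 2, 3)), nIter * nCh, dim(dr)[3],
                       dimnames = list(NULL, dimnames(dr)[[3]]))
        keep <- unique(round(seq(1, nrow(flat), length.out = 200)))
        set.seed(cfg$seed + 5L)
        ppd <- vapply(keep, function(d) {
            params <- flat[d, ]
            log(predictMeasurement(params, mix, res$fit$priors,
                                   L0 = cfg$model$L0)) +
                stats::rnorm(nrow(mix), 0, params[["sigmaObs"]])
        }, numeric(nrow(mix)))
        qs <- apply(ppd, 1L, stats::quantile, probs = c(0.05, 0.95))
        out <- mix
        out$predicted_rfu <- pred
        out$pi_lower <- exp(qs[1L, ])
        out$pi_upper <- exp(qs[2L, ])
        utils::write.csv(out, file.path(cfg$out, "mixture_predictions.csv"),
                         row.names = FALSE)
        within <- mean(mix$rfu >= out$pi_lower & mix$rfu <= out$pi_upper)
        logErr <- abs(log(pmax(mix$rfu, 1e-300)) - log(pmax(pred, 1e-300)))
        list(predictions = out, sigmaObs = med[["sigmaObs"]],
             withinNoise = within, medianLogErr = stats::median(logErr))
    })

    ## --- stage: depletion regression ------------------------------------
    res$depletion <- runStage("fit-depletion", {
        med <- stats::setNames(res$fit$summary$median,
                               res$fit$summary$parameter)
        lay <- .panelLayout(res$fit$priors)
        kaMed <- matrix(med[lay$idxKa], length(lay$ligands),
                        length(lay$receptors),
                        dimnames = list(lay$ligands, lay$receptors))
        affinUpd <- affinityMatrix(kaMed)
        profiles <- if (!is.null(cfg$inputs$profiles)) {
            tab <- readTable(cfg$inputs$profiles, "effector_profiles")
            lapply(split(tab, tab$cell_type), function(d)
                cellSurface(stats::setNames(
                    d$sites_per_cell, d$receptor)[lay$receptors]))
        } else defaultEffectorProfiles(lay$receptors)
        signs <- defaultReceptorSigns(lay$receptors)
        if (isTRUE(cfg$simulate)) {
            study <- simulateDepletionStudy(
                truth, profiles = profiles,
                micePerCondition = cfg$synthetic$micePerCondition,
                noiseSd = cfg$synthetic$depletionNoiseSd,
                seed = cfg$seed + 3L, signs = signs)
            dep <- study$data
        } else {
            dep <- readTable(.requireInput(cfg$inputs$depletion, "depletion"),
                             "depletion")
            study <- NULL
        }
        conditions <- lapply(unique(dep$condition), function(s)
            stats::setNames(as.numeric(lay$ligands == s), lay$ligands))
        names(conditions) <- unique(dep$condition)
        X <- do.call(rbind, lapply(conditions, function(comp)
            activitiesForCondition(comp, profiles, affinUpd,
                                   med[["KxStar"]], signs,
                                   L0 = cfg$model$invivoL0,
                                   f = cfg$model$invivoValency)))
        rownames(X) <- names(conditions)
        colnames(X) <- names(profiles)
        ps <- fitDepletion(dep, X,
                           config = list(chains = cfg$sampler$chains,
                                         warmup = cfg$sampler$warmup,
                                         draws = cfg$sampler$draws,
                                         seed = cfg$seed + 4L))
        summ <- posteriorSummary(ps)
        writeTable(summ, file.path(cfg$out, "depletion_weights.csv"),
                   "posterior_summary")
        list(posterior = ps, summary = summ, activities = X, study = study)
    })

    ## --- stage: diagnostics ---------------------------------------------
    res$diagnostics <- runStage("diagnostics", {
        summ <- conditionSummaries(res$data$panel)
        ratios <- suppressWarnings(intervalencyRatio(summ))
        medMat <- stats::xtabs(
            median_rfu ~ paste(valency, igg_a, igg_b, frac_a, sep = "|") +
                receptor, data = summ)
        medMat <- matrix(as.numeric(medMat), nrow(medMat),
                         dimnames = dimnames(medMat))
        anova <- anovaConditionVariance(
            res$data$panel$rfu,
            paste(res$data$panel$receptor, res$data$panel$valency,
                  res$data$panel$igg_a, res$data$panel$igg_b,
                  res$data$panel$frac_a))
        k12 <- vapply(1:2, function(k)
            pcaVarianceExplained(medMat, k,
                                 center = isTRUE(cfg$flags$centerPca)), 0)
        utils::write.csv(summ, file.path(cfg$out, "condition_summaries.csv"),
                         row.names = FALSE)
        utils::write.csv(ratios, file.path(cfg$out, "intervalency_ratios.csv"),
                         row.names = FALSE)
        list(summaries = summ, ratios = ratios,
             anovaFraction = anova, pcaVariance = k12)
    })

    ## --- stage: manifest -------------------------------------------------
    res$manifest <- runStage("manifest", {
        files <- list.files(cfg$out, pattern = "\\.(csv|json)$",
                            full.names = TRUE)
        manifest <- list(
            seed = cfg$seed,
            package = "FcBindMix",
            packageVersion = as.character(utils::packageVersion("FcBindMix")),
            rVersion = R.version.string,
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
            config = cfg,
            checksums = as.list(tools::md5sum(files))
        )
        jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        manifest
    })
    invisible(c(list(out = cfg$out), res))
}
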
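#' Configuration for the end-to-end syndrome-pattern pipeline
#'
#' Collects every tunable of the workflow with the study's settings as
#' defaults: top-12 key symptoms per syndrome, wMI threshold 0.1 (base-2
#' logarithm), 10000 permutations with p-value cutoff 0.1, Tanimoto
#' cutoff 0.5, and 5-fold cross-validation repeated 10 times.
#'
#' @param cohortPath path to a cohort file (see [readCohort()]); `NULL` to
#'   generate a synthetic cohort from `spec` instead.
#' @param spec a [cohortSpec()] used when `cohortPath` is `NULL`; default
#'   [defaultDepressionSpec()].
#' @param kTop key symptoms per syndrome (default 12).
#' @param theta wMI edge threshold (default 0.1).
#' @param logBase wMI logarithm base (default 2).
#' @param nPermutations permutation-test iterations (default 10000).
#' @param pCutoff dynamic-interaction p-value cutoff (default 0.1).
#' @param tanimotoCutoff syndrome-network similarity cutoff (default 0.5).
#' @param folds,repeats cross-validation geometry (default 5 x 10).
#' @param classifierMethods methods to evaluate (default all four).
#' @param seed master integer seed for the whole run.
#' @param outputDir directory for the result files.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(cohortPath = NULL, spec = defaultDepressionSpec(),
                           kTop = 12L, theta = 0.1, logBase = 2,
                           nPermutations = 10000L, pCutoff = 0.1,
                           tanimotoCutoff = 0.5, folds = 5L, repeats = 10L,
                           classifierMethods = c("nb", "tan", "svm", "tree"),
                           seed = 1L, outputDir = "zhengnet-results") {
    stopifnot(kTop >= 1, theta >= 0, nPermutations >= 1,
              pCutoff > 0, pCutoff < 1, tanimotoCutoff >= 0,
              folds >= 2, repeats >= 1)
    structure(list(cohortPath = cohortPath, spec = spec,
                   kTop = as.integer(kTop), theta = theta, logBase = logBase,
                   nPermutations = as.integer(nPermutations),
                   pCutoff = pCutoff, tanimotoCutoff = tanimotoCutoff,
                   folds = as.integer(folds), repeats = as.integer(repeats),
                   classifierMethods = classifierMethods,
                   seed = as.integer(seed), outputDir = outputDir),
              class = "PipelineConfig")
}

.stage <- function(name, expr) {
    message("[zhengnet] stage: ", name)
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full syndrome-pattern analysis
#'
#' Executes the workflow end to end and writes delimited-text artifacts to
#' the output directory: (1) classifier evaluation under repeated CV with
#' pairwise paired t-tests; (2) per-syndrome Fisher-score rankings and
#' top-k tables; (3) the global depression symptom network (all 36
#' symptoms, whole cohort) and 7 per-syndrome networks (top-k nodes on the
#' positive sets), as edge lists and GraphML; (4) the topology summary
#' table; (5) permutation-test results with dynamic-interaction classes
#' and NDI/NII counts; (6) the Tanimoto syndrome network with
#' co-occurrence p-values. A JSON manifest records every setting, seed and
#' produced file, so a run is self-describing and reproducible.
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly) a list with the in-memory results and the manifest.
#' @export
runPipeline <- function(config = pipelineConfig()) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outputDir, f)
    produced <- character()
    emit <- function(f) produced <<- c(produced, f)

    cohort <- .stage("cohort", {
        if (!is.null(config$cohortPath)) readCohort(config$cohortPath)
        else {
            co <- generateCohort(config$spec, seed = config$seed)
            writeCohort(co, out("cohort.csv")); emit("cohort.csv")
            truth <- S4Vectors::metadata(co)$truth
            jsonlite::write_json(
                list(key_symptoms = truth$key_symptoms,
                     coupled_pairs = truth$coupled_pairs),
                out("cohort_ground_truth.json"), dataframe = "rows")
            emit("cohort_ground_truth.json")
            co
        }
    })

    evals <- .stage("classification", {
        rows <- list(); comps <- list()
        for (s in syndromeIds(cohort)) {
            es <- lapply(config$classifierMethods, function(m)
                repeatedCV(cohort, s, m, folds = config$folds,
                           repeats = config$repeats, seed = config$seed))
            names(es) <- config$classifierMethods
            for (m in names(es))
                rows[[paste(s, m)]] <- data.frame(
                    syndrome = s, method = m,
                    repeat_ = seq_len(config$repeats),
                    accuracy = accuracies(es[[m]]))
            if (length(es) > 1L) {
                prs <- utils::combn(names(es), 2L)
                for (k in seq_len(ncol(prs))) {
                    cmp <- compareMethods(es[[prs[1L, k]]], es[[prs[2L, k]]])
                    comps[[paste(s, k)]] <- data.frame(
                        syndrome = s, method_a = prs[1L, k],
                        method_b = prs[2L, k], mean_diff = cmp$mean_diff,
                        p_value = cmp$p.value)
                }
            }
        }
        perTrial <- do.call(rbind, rows)
        names(perTrial)[3L] <- "repeat"
        write.table(perTrial, out("classifier_eval.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        emit("classifier_eval.tsv")
        if (length(comps)) {
            write.table(do.call(rbind, comps), out("classifier_ttests.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            emit("classifier_ttests.tsv")
        }
        perTrial
    })

    rankings <- .stage("feature ranking", {
        tabs <- lapply(syndromeIds(cohort), function(s)
            rankSymptoms(cohort, s))
        names(tabs) <- syndromeIds(cohort)
        allRanks <- do.call(rbind, tabs)
        write.table(allRanks, out("fisher_rankings.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        emit("fisher_rankings.tsv")
        topk <- do.call(rbind, lapply(tabs, utils::head, config$kTop))
        write.table(topk, out("key_symptoms.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        emit("key_symptoms.tsv")
        tabs
    })

    networks <- .stage("symptom networks", {
        nets <- list(depression = buildSymptomNetwork(
            cohort, theta = config$theta, logBase = config$logBase,
            networkId = "depression"))
        for (s in syndromeIds(cohort)) {
            nodes <- topK(rankings[[s]], config$kTop)
            nets[[s]] <- buildSymptomNetwork(
                positiveSet(cohort, s), nodes = nodes, theta = config$theta,
                logBase = config$logBase, networkId = s)
        }
        for (id in names(nets)) {
            writeEdgeList(nets[[id]], out(paste0("network_", id, ".tsv")))
            emit(paste0("network_", id, ".tsv"))
            rk <- if (id == "depression") NULL else
                rankings[[id]][, c("symptom_id", "rank")]
            writeGraphML(nets[[id]], out(paste0("network_", id, ".graphml")),
                         nodeAttributes = rk)
            emit(paste0("network_", id, ".graphml"))
        }
        nets
    })

    permutations <- .stage("permutation test", {
        res <- list()
        for (s in syndromeIds(cohort)) {
            pr <- permutationTest(cohort, s, networks[[s]],
                                  N = config$nPermutations,
                                  seed = config$seed)
            res[[s]] <- classifyDynamic(pr, cutoff = config$pCutoff)
        }
        flat <- do.call(rbind, Map(function(s, r)
            if (nrow(r)) cbind(syndrome = s, r) else NULL,
            names(res), res))
        write.table(flat, out("dynamic_interactions.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        emit("dynamic_interactions.tsv")
        res
    })

    topology <- .stage("topology summary", {
        tab <- do.call(rbind, lapply(names(networks), function(id)
            summarizeTopology(networks[[id]],
                permutation = permutations[[id]])))
        tab$CC <- round(tab$CC, 3L)
        tab$ND <- round(tab$ND, 3L)
        write.table(tab, out("topology_summary.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        emit("topology_summary.tsv")
        tab
    })

    syndromeNet <- .stage("syndrome network", {
        sn <- buildSyndromeNetwork(cohort, cutoff = config$tanimotoCutoff)
        write.table(sn@allPairs, out("syndrome_pairs.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        emit("syndrome_pairs.tsv")
        writeEdgeList(sn, out("syndrome_network.tsv"))
        emit("syndrome_network.tsv")
        writeGraphML(sn, out("syndrome_network.graphml"))
        emit("syndrome_network.graphml")
        sn
    })

    manifest <- list(
        settings = config[setdiff(names(config), "spec")],
        synthetic = is.null(config$cohortPath),
        n_patients = ncol(cohort),
        conventions = list(
            wmi_log_base = config$logBase,
            wmi_smoothing = "none (raw empirical frequencies)",
            fisher_variance = "population (divide by n_i)",
            fisher_prior = "empirical class proportions",
            clustering_low_degree = "counted as 0",
            cv_stratified = TRUE,
            bayes_pseudocount = 1,
            permutation_ties = "count toward n_g",
            multiple_testing = "none (raw p-value cutoff)"),
        files = produced)
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         null = "null")
    message("[zhengnet] done: ", length(produced) + 1L, " files in ",
            config$outputDir)
    invisible(list(cohort = cohort, classifierEval = evals,
                   rankings = rankings, networks = networks,
                   permutations = permutations, topology = topology,
                   syndromeNetwork = syndromeNet, manifest = manifest))
}
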
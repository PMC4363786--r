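## Canonical identifiers: 36 inquiry symptoms and 7 syndromes (ZHENG).
.SYMPTOM_IDS <- paste0("PS", 1:36)
.SYNDROME_IDS <- c("BD", "BS", "FH", "PH", "QD", "QS", "YD")
.FEMALE_ONLY <- c("PS13", "PS22")
.GRADES <- 0:3

#' SymptomCohort: ordinal symptom grades with binary syndrome labels
#'
#' A \linkS4class{SummarizedExperiment} holding one cohort of clinical
#' inquiry data: a `grades` assay (36 symptoms in rows, patients in columns,
#' integer risk degrees 0 = none, 1 = low, 2 = median, 3 = high), the
#' symptom catalog as `rowData` (`symptom_id`, `description`, `female_only`)
#' and per-patient metadata as `colData` (`patient_id`, `sex`, and one 0/1
#' column per syndrome: BD, BS, FH, PH, QD, QS, YD).
#'
#' Two symptoms (PS13, PS22) concern menses and are female-only; when a
#' patient's sex is recorded as male their grades must be 0. Records with
#' `sex = "unknown"` are exempt from that check.
#'
#' @seealso [SymptomCohort()] for construction, [readCohort()] /
#'   [writeCohort()] for delimited-text I/O, [positiveSet()] for
#'   syndrome subsetting.
#' @export
setClass("SymptomCohort", contains = "SummarizedExperiment")

setValidity("SymptomCohort", function(object) {
    msg <- character()
    if (!"grades" %in% assayNames(object))
        return("assay 'grades' is missing")
    g <- assay(object, "grades")
    if (!identical(rownames(object), .SYMPTOM_IDS))
        msg <- c(msg, "rows must be the 36 symptoms PS1..PS36, in order")
    if (anyNA(g) || !all(g %in% .GRADES))
        msg <- c(msg, "grades must all be integers in {0,1,2,3}")
    cd <- colData(object)
    need <- c("patient_id", "sex", .SYNDROME_IDS)
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(c(msg, paste0("colData misses column(s): ",
                             paste(miss, collapse = ", "))))
    if (!all(cd$sex %in% c("female", "male", "unknown")))
        msg <- c(msg, "sex must be 'female', 'male' or 'unknown'")
    lab <- as.matrix(cd[, .SYNDROME_IDS, drop = FALSE])
    if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
        msg <- c(msg, "syndrome labels must all be 0 or 1")
    rd <- rowData(object)
    if (!all(c("description", "female_only") %in% colnames(rd))) {
        msg <- c(msg, "rowData needs 'description' and 'female_only'")
    } else if (!identical(which(rd$female_only), match(.FEMALE_ONLY, rownames(object)))) {
        msg <- c(msg, "female_only must be TRUE exactly for PS13 and PS22")
    }
    male <- cd$sex == "male"
    if (any(male) && ncol(object) &&
        any(g[.FEMALE_ONLY, male, drop = FALSE] != 0L))
        msg <- c(msg, "male patients must have grade 0 for PS13 and PS22")
    if (length(msg)) msg else TRUE
})

#' SymptomNetwork: a weighted-mutual-information symptom graph
#'
#' An undirected simple graph over symptoms. Edges connect symptom pairs
#' whose weighted mutual information (wMI), computed on a positive set,
#' reached the selection threshold; edge weights are the wMI values.
#'
#' @slot networkId the syndrome the network belongs to, or `"depression"`
#'   for the global network built on the whole cohort.
#' @slot nodes character vector of symptom ids (isolated nodes retained).
#' @slot edges data.frame with columns `u`, `v`, `wMI`; each weight is
#'   `>=` the threshold, `u` precedes `v` in catalog order.
#' @slot threshold the wMI cutoff theta used for edge selection.
#' @slot logBase base of the logarithm in the wMI (2 = bits).
#' @seealso [buildSymptomNetwork()], [summarizeTopology()],
#'   [permutationTest()]
#' @export
setClass("SymptomNetwork",
    representation(networkId = "character", nodes = "character",
                   edges = "data.frame", threshold = "numeric",
                   logBase = "numeric"))

setValidity("SymptomNetwork", function(object) {
    e <- object@edges
    if (!all(c("u", "v", "wMI") %in% colnames(e)))
        return("edges must have columns u, v, wMI")
    if (nrow(e)) {
        if (any(e$u == e$v)) return("self-loops are not allowed")
        if (!all(c(e$u, e$v) %in% object@nodes))
            return("edge endpoints must be network nodes")
        key <- paste(pmin(e$u, e$v), pmax(e$u, e$v))
        if (anyDuplicated(key)) return("duplicate edges are not allowed")
        if (any(e$wMI < object@threshold - 1e-12))
            return("every edge weight must be >= the threshold")
    }
    TRUE
})

#' SyndromeNetwork: Tanimoto co-occurrence graph over the 7 syndromes
#'
#' Nodes are the syndromes with their cohort prevalence; edges connect
#' syndrome pairs whose Tanimoto similarity reached the cutoff, annotated
#' with a one-sided Fisher's exact test p-value for co-occurrence
#' enrichment. All 21 pair statistics are retained in `allPairs`.
#'
#' @slot nodes data.frame with columns `syndrome`, `prevalence`.
#' @slot edges data.frame with columns `s1`, `s2`, `similarity`, `p_value`
#'   (only pairs with similarity `>=` cutoff).
#' @slot allPairs data.frame of the same shape covering all 21 pairs.
#' @slot cutoff the similarity cutoff used for edge selection.
#' @seealso [buildSyndromeNetwork()], [tanimotoSimilarity()]
#' @export
setClass("SyndromeNetwork",
    representation(nodes = "data.frame", edges = "data.frame",
                   allPairs = "data.frame", cutoff = "numeric"))

setValidity("SyndromeNetwork", function(object) {
    e <- object@edges
    if (nrow(e)) {
        if (any(e$similarity < 0 | e$similarity > 1))
            return("similarities must lie in [0,1]")
        if (any(e$similarity < object@cutoff - 1e-12))
            return("every edge similarity must be >= the cutoff")
    }
    TRUE
})

#' Naive Bayes classifier for one syndrome
#'
#' Multinomial naive Bayes over the ordinal grades, trained by smoothed
#' maximum likelihood; prediction is by the maximum a posteriori rule on
#' `P(C) * prod_i P(F_i | C)`.
#'
#' @slot syndrome the syndrome the model classifies.
#' @slot prior named numeric(2), empirical class prior for classes "0","1".
#' @slot tables numeric array `[feature, grade, class]` of conditional
#'   probabilities `P(F_i = f | C = c)`; each `[i, , c]` slice sums to 1.
#' @slot features character vector of feature (symptom) ids.
#' @slot pseudocount Laplace smoothing pseudocount used for the tables.
#' @seealso [trainNaiveBayes()], [predict,NaiveBayesModel-method]
#' @export
setClass("NaiveBayesModel",
    representation(syndrome = "character", prior = "numeric",
                   tables = "array", features = "character",
                   pseudocount = "numeric"))

#' Tree-augmented naive Bayes classifier for one syndrome
#'
#' Extends naive Bayes by a Chow-Liu tree over the features: each feature's
#' parents are the class plus at most one other feature, the feature tree
#' being a maximum spanning tree of class-conditional mutual information.
#'
#' @slot syndrome the syndrome the model classifies.
#' @slot prior named numeric(2), empirical class prior for classes "0","1".
#' @slot features character vector of feature ids.
#' @slot parent integer vector: index of each feature's feature-parent in
#'   `features`, `NA` for the root (class-only parent).
#' @slot tables list, one per feature: array `[grade, parent grade, class]`
#'   of `P(F_i | Pa_i, C)` (parent dimension 1 for the root).
#' @slot pseudocount Laplace smoothing pseudocount.
#' @seealso [trainTAN()], [predict,TANModel-method]
#' @export
setClass("TANModel",
    representation(syndrome = "character", prior = "numeric",
                   features = "character", parent = "integer",
                   tables = "list", pseudocount = "numeric"))

#' Repeated cross-validation result for one classifier on one syndrome
#'
#' @slot syndrome syndrome id.
#' @slot method one of "nb", "tan", "svm", "tree".
#' @slot accuracies numeric vector, one pooled accuracy per repeat.
#' @slot folds,repeats cross-validation geometry (default 5-fold x 10).
#' @slot seed integer seed that fixed the fold assignments.
#' @seealso [repeatedCV()], [compareMethods()]
#' @export
setClass("ClassifierEval",
    representation(syndrome = "character", method = "character",
                   accuracies = "numeric", folds = "integer",
                   repeats = "integer", seed = "integer"))

setValidity("ClassifierEval", function(object) {
    a <- object@accuracies
    if (length(a) != object@repeats)
        return("one accuracy per repeat is required")
    if (any(a < 0 | a > 1)) return("accuracies must lie in [0,1]")
    TRUE
})

## ---- accessors & show -----------------------------------------------------

#' @rdname grades
#' @export
setMethod("grades", "SymptomCohort", function(x) assay(x, "grades"))

#' @rdname grades
#' @export
setMethod("syndromeLabels", "SymptomCohort", function(x) {
    m <- as.matrix(colData(x)[, .SYNDROME_IDS, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- colData(x)$patient_id
    m
})

#' @rdname grades
#' @export
setMethod("symptomIds", "SymptomCohort", function(x) rownames(x))

#' @rdname grades
#' @export
setMethod("syndromeIds", "SymptomCohort", function(x) .SYNDROME_IDS)

#' @rdname positiveSet
#' @export
setMethod("positiveSet", "SymptomCohort", function(x, syndrome) {
    syndrome <- match.arg(syndrome, .SYNDROME_IDS)
    keep <- colData(x)[[syndrome]] == 1L
    if (!any(keep))
        stop("positive set of ", syndrome, " is empty: no patient has ",
             "label 1 and downstream analyses need at least one record")
    x[, keep]
})

setMethod("show", "SymptomCohort", function(object) {
    cat("SymptomCohort with", ncol(object), "patients x", nrow(object),
        "symptoms\n")
    lab <- syndromeLabels(object)
    cat("syndrome positives:",
        paste(colnames(lab), colSums(lab), sep = "=", collapse = " "), "\n")
})

#' @rdname networkNodes
#' @export
setMethod("networkNodes", "SymptomNetwork", function(x) x@nodes)

#' @rdname networkNodes
#' @export
setMethod("networkEdges", "SymptomNetwork", function(x) x@edges)

#' @rdname networkNodes
#' @export
setMethod("networkThreshold", "SymptomNetwork", function(x) x@threshold)

#' @rdname networkNodes
#' @export
setMethod("networkNodes", "SyndromeNetwork", function(x) x@nodes)

#' @rdname networkNodes
#' @export
setMethod("networkEdges", "SyndromeNetwork", function(x) x@edges)

#' @rdname networkNodes
#' @export
setMethod("networkThreshold", "SyndromeNetwork", function(x) x@cutoff)

setMethod("show", "SymptomNetwork", function(object) {
    cat("SymptomNetwork '", object@networkId, "': ",
        length(object@nodes), " nodes, ", nrow(object@edges),
        " edges (wMI >= ", object@threshold, ", log base ",
        object@logBase, ")\n", sep = "")
})

setMethod("show", "SyndromeNetwork", function(object) {
    cat("SyndromeNetwork:", nrow(object@nodes), "syndromes,",
        nrow(object@edges), "edges (Tanimoto >=", object@cutoff, ")\n")
})

setMethod("show", "NaiveBayesModel", function(object) {
    cat("NaiveBayesModel for", object@syndrome, "-",
        length(object@features), "features, prior P(1) =",
        signif(object@prior[["1"]], 3), "\n")
})

setMethod("show", "TANModel", function(object) {
    cat("TANModel for", object@syndrome, "-", length(object@features),
        "features,", sum(!is.na(object@parent)), "augmenting tree edges\n")
})

#' @rdname accuracies
#' @export
setMethod("accuracies", "ClassifierEval", function(x) x@accuracies)

setMethod("show", "ClassifierEval", function(object) {
    cat(sprintf("ClassifierEval %s/%s: mean accuracy %.4f (sd %.4f) over %d x %d-fold CV\n",
        object@syndrome, object@method, mean(object@accuracies),
        sd(object@accuracies), object@repeats, object@folds))
})
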
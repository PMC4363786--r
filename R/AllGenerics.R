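#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats fisher.test predict rbinom runif sd setNames t.test var
#' @importFrom utils read.csv read.delim write.table
NULL

#' Extract the grade matrix of a cohort
#'
#' @param x a \linkS4class{SymptomCohort}.
#' @return For `grades`, an integer matrix (symptoms in rows, patients in
#'   columns) of risk degrees in 0..3.
#' @export
setGeneric("grades", function(x) standardGeneric("grades"))

#' @rdname grades
#' @return For `syndromeLabels`, an integer matrix (patients in rows, the 7
#'   syndromes in columns) of 0/1 diagnosis labels.
#' @export
setGeneric("syndromeLabels", function(x) standardGeneric("syndromeLabels"))

#' @rdname grades
#' @return For `symptomIds`, the character vector of symptom identifiers.
#' @export
setGeneric("symptomIds", function(x) standardGeneric("symptomIds"))

#' @rdname grades
#' @return For `syndromeIds`, the character vector of syndrome identifiers.
#' @export
setGeneric("syndromeIds", function(x) standardGeneric("syndromeIds"))

#' Subset a cohort to the positive set of one syndrome
#'
#' The positive set of a syndrome is the sub-cohort of all patients labelled
#' 1 for that syndrome; it is the data on which that syndrome's symptom
#' network is built.
#'
#' @param x a \linkS4class{SymptomCohort}.
#' @param syndrome one of the cohort's syndrome ids.
#' @return a `SymptomCohort` containing exactly the label-1 patients, in
#'   their original order.
#' @export
setGeneric("positiveSet", function(x, syndrome) standardGeneric("positiveSet"))

#' Network accessors
#'
#' @param x a \linkS4class{SymptomNetwork} or \linkS4class{SyndromeNetwork}.
#' @return `networkNodes`: node identifiers (with attributes for syndrome
#'   networks); `networkEdges`: a data.frame of edges with weights;
#'   `networkThreshold`: the edge-selection cutoff used.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname networkNodes
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname networkNodes
#' @export
setGeneric("networkThreshold", function(x) standardGeneric("networkThreshold"))

#' @rdname networkNodes
#' @return `asIgraph`: the network as an \pkg{igraph} undirected graph with
#'   edge attribute `weight`.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Per-trial accuracies of a cross-validated classifier
#'
#' @param x a \linkS4class{ClassifierEval}.
#' @return numeric vector of per-repeat accuracies (each the pooled accuracy
#'   over the k folds of one repeat).
#' @export
setGeneric("accuracies", function(x) standardGeneric("accuracies"))
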
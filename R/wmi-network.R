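#' Grade-pair weight matrix for weighted mutual information
#'
#' The default weight of a grade pair (x, y) is `1 - 0.2 * |x - y|`
#' (1.0 on the diagonal down to 0.4 for the 0/3 pair), down-weighting the
#' contribution of discordant grade combinations to the dependence score.
#'
#' @return symmetric 4x4 numeric matrix, rows/columns named "0".."3".
#' @examples
#' gradeWeightMatrix()
#' @export
gradeWeightMatrix <- function() {
    w <- 1 - 0.2 * abs(outer(0:3, 0:3, "-"))
    dimnames(w) <- list(0:3, 0:3)
    w
}

#' Empirical joint grade distribution of two symptoms
#'
#' Raw relative frequencies over the 4x4 grade grid, no smoothing.
#'
#' @param x,y equal-length integer vectors of grades in 0..3.
#' @return list of class `JointDistribution`: `p` (4x4 joint), `px`, `py`
#'   (marginals by summation).
#' @examples
#' empiricalJoint(c(0, 3), c(0, 3))$p
#' @export
empiricalJoint <- function(x, y) {
    if (length(x) == 0L) stop("cannot estimate a joint from empty input")
    if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
    if (!all(x %in% .GRADES) || !all(y %in% .GRADES))
        stop("grades must lie in {0,1,2,3}")
    counts <- tabulate(x * 4L + y + 1L, nbins = 16L)
    p <- matrix(counts / length(x), 4L, 4L, byrow = TRUE,
                dimnames = list(0:3, 0:3))
    structure(list(p = p, px = rowSums(p), py = colSums(p)),
              class = "JointDistribution")
}

## wMI from a plain 4x4 joint matrix; log base configurable (2 = bits).
.wmiFromJoint <- function(p, w, logBase = 2) {
    px <- rowSums(p)
    py <- colSums(p)
    nz <- which(p > 0)
    if (!length(nz)) return(0)
    pij <- p[nz]
    prod <- outer(px, py)[nz]
    sum(w[nz] * pij * (log(pij / prod) / log(logBase)))
}

#' Weighted mutual information of a joint grade distribution
#'
#' `wMI(X; Y) = sum_xy w(x,y) P(x,y) log( P(x,y) / (P(x) P(y)) )`, with
#' `0 log 0 := 0` so absent grade combinations contribute nothing. With an
#' all-ones weight matrix this is the ordinary mutual information; with
#' the default grade-distance weights, discordant pairs are down-weighted
#' and the sum is no longer guaranteed non-negative.
#'
#' @param joint a [empiricalJoint()] result, or a bare 4x4 joint matrix.
#' @param w 4x4 weight matrix, default [gradeWeightMatrix()].
#' @param logBase logarithm base; 2 (bits, the default) or `exp(1)`.
#' @return a single numeric wMI value.
#' @examples
#' j <- empiricalJoint(c(0, 0, 3, 3), c(0, 0, 3, 3))
#' weightedMutualInformation(j)  # 1 bit
#' @export
weightedMutualInformation <- function(joint, w = gradeWeightMatrix(),
                                      logBase = 2) {
    p <- if (inherits(joint, "JointDistribution")) joint$p else as.matrix(joint)
    stopifnot(identical(dim(p), c(4L, 4L)), identical(dim(w), c(4L, 4L)),
              all(p >= 0), abs(sum(p) - 1) < 1e-9)
    .wmiFromJoint(p, w, logBase)
}

## fast path used by network construction and the permutation test:
## per-pair 16-bin grade-pair codes -> counts -> wMI
.wmiFromCodes <- function(codes, w, logBase = 2) {
    counts <- tabulate(codes, nbins = 16L)
    p <- matrix(counts / length(codes), 4L, 4L, byrow = TRUE)
    .wmiFromJoint(p, w, logBase)
}

#' Build a symptom network from a positive set
#'
#' Computes the weighted mutual information of every unordered pair of the
#' requested nodes on the given cohort (pass the syndrome's positive set,
#' or the whole cohort for the global depression network) and keeps the
#' pairs with `wMI >= theta` as edges.
#'
#' @param cohort the \linkS4class{SymptomCohort} to estimate joints on.
#' @param nodes symptom ids to use as nodes (e.g. the top-12 key symptoms);
#'   default all 36.
#' @param w grade-pair weight matrix.
#' @param theta edge-selection threshold on the wMI (default 0.1).
#' @param logBase wMI logarithm base (default 2, bits).
#' @param networkId identifier stored on the network (syndrome id or
#'   "depression").
#' @return a \linkS4class{SymptomNetwork}.
#' @examples
#' co <- generateCohort(defaultDepressionSpec(), seed = 1)
#' buildSymptomNetwork(positiveSet(co, "QS"),
#'                     nodes = topK(rankSymptoms(co, "QS")),
#'                     networkId = "QS")
#' @export
buildSymptomNetwork <- function(cohort, nodes = symptomIds(cohort),
                                w = gradeWeightMatrix(), theta = 0.1,
                                logBase = 2, networkId = "depression") {
    stopifnot(is(cohort, "SymptomCohort"), theta >= 0)
    if (ncol(cohort) == 0L)
        stop("cannot build a network from an empty cohort")
    bad <- setdiff(nodes, symptomIds(cohort))
    if (length(bad))
        stop("unknown node symptom(s): ", paste(bad, collapse = ", "))
    g <- grades(cohort)[nodes, , drop = FALSE]
    np <- length(nodes)
    pairs <- which(upper.tri(matrix(0, np, np)), arr.ind = TRUE)
    wmi <- vapply(seq_len(nrow(pairs)), function(r) {
        i <- pairs[r, 1L]; j <- pairs[r, 2L]
        .wmiFromCodes(g[i, ] * 4L + g[j, ] + 1L, w, logBase)
    }, numeric(1))
    keep <- wmi >= theta
    edges <- data.frame(u = nodes[pairs[keep, 1L]],
                        v = nodes[pairs[keep, 2L]],
                        wMI = wmi[keep], row.names = NULL)
    new("SymptomNetwork", networkId = networkId, nodes = nodes,
        edges = edges, threshold = theta, logBase = logBase)
}

#' Tanimoto similarity of two syndrome label vectors
#'
#' `c / (a + b - c)` where `a` and `b` are the positive counts of the two
#' syndromes and `c` the count of patients positive for both (the Jaccard
#' index of the two positive sets).
#'
#' @param labels1,labels2 equal-length 0/1 vectors.
#' @return similarity in \[0, 1\].
#' @examples
#' tanimotoSimilarity(c(1,1,1,1,1,0,0,0,0), c(1,1,0,0,0,1,1,0,0))  # 2/7
#' @export
tanimotoSimilarity <- function(labels1, labels2) {
    stopifnot(length(labels1) == length(labels2),
              all(labels1 %in% 0:1), all(labels2 %in% 0:1))
    a <- sum(labels1)
    b <- sum(labels2)
    cc <- sum(labels1 == 1L & labels2 == 1L)
    if (a + b - cc == 0)
        stop("Tanimoto similarity is undefined when both syndromes have ",
             "no positives")
    cc / (a + b - cc)
}

#' Build the syndrome co-occurrence network
#'
#' Scores all 21 syndrome pairs by Tanimoto similarity of their positive
#' sets and keeps pairs with similarity `>=` the cutoff as edges. Every
#' pair is also annotated with a one-sided Fisher's exact test p-value
#' (alternative: co-occurrence enrichment) on its 2x2 contingency table.
#'
#' @param cohort a \linkS4class{SymptomCohort}.
#' @param cutoff similarity cutoff for edge selection (default 0.5).
#' @return a \linkS4class{SyndromeNetwork}; nodes carry each syndrome's
#'   cohort prevalence.
#' @export
buildSyndromeNetwork <- function(cohort, cutoff = 0.5) {
    stopifnot(is(cohort, "SymptomCohort"))
    lab <- syndromeLabels(cohort)
    n <- nrow(lab)
    ids <- colnames(lab)
    pairs <- utils::combn(ids, 2L)
    allPairs <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
        s1 <- pairs[1L, k]; s2 <- pairs[2L, k]
        l1 <- lab[, s1]; l2 <- lab[, s2]
        a <- sum(l1); b <- sum(l2); cc <- sum(l1 & l2)
        sim <- if (a + b - cc == 0) NA_real_ else cc / (a + b - cc)
        tab <- matrix(c(cc, a - cc, b - cc, n - a - b + cc), 2L, 2L)
        p <- fisher.test(tab, alternative = "greater")$p.value
        data.frame(s1 = s1, s2 = s2, similarity = sim, p_value = p)
    }))
    edges <- allPairs[!is.na(allPairs$similarity) &
                      allPairs$similarity >= cutoff, , drop = FALSE]
    rownames(edges) <- NULL
    new("SyndromeNetwork",
        nodes = data.frame(syndrome = ids, prevalence = colMeans(lab)),
        edges = edges, allPairs = allPairs, cutoff = cutoff)
}

#' @rdname networkNodes
#' @export
setMethod("asIgraph", "SymptomNetwork", function(x) {
    e <- x@edges
    igraph::graph_from_data_frame(
        data.frame(from = e$u, to = e$v, weight = e$wMI),
        directed = FALSE, vertices = data.frame(name = x@nodes))
})

#' @rdname networkNodes
#' @export
setMethod("asIgraph", "SyndromeNetwork", function(x) {
    e <- x@edges
    igraph::graph_from_data_frame(
        data.frame(from = e$s1, to = e$s2, weight = e$similarity,
                   p_value = e$p_value),
        directed = FALSE,
        vertices = data.frame(name = x@nodes$syndrome,
                              prevalence = x@nodes$prevalence))
})

#' Export a network as a weighted edge list or GraphML
#'
#' @param network a \linkS4class{SymptomNetwork} or
#'   \linkS4class{SyndromeNetwork}.
#' @param path output file path.
#' @param delim delimiter for the edge list (default tab).
#' @param nodeAttributes optional data.frame of extra node attributes for
#'   GraphML (first column must be the node id), e.g. syndrome membership
#'   or Fisher rank.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(network, path, delim = "\t") {
    e <- networkEdges(network)
    write.table(e, path, sep = delim, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeEdgeList
#' @export
writeGraphML <- function(network, path, nodeAttributes = NULL) {
    g <- asIgraph(network)
    if (!is.null(nodeAttributes)) {
        idx <- match(igraph::V(g)$name, nodeAttributes[[1L]])
        for (col in colnames(nodeAttributes)[-1L])
            g <- igraph::set_vertex_attr(g, col, value = nodeAttributes[[col]][idx])
    }
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}
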
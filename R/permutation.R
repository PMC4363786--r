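#' Uniform random shuffle of a syndrome label vector
#'
#' Permutes the 0/1 labels uniformly at random, preserving the positive
#' count; only the one syndrome's label column is touched.
#'
#' @param labels 0/1 vector with at least one member of each class.
#' @return a permutation of `labels`.
#' @export
permuteLabels <- function(labels) {
    stopifnot(all(labels %in% 0:1))
    if (length(unique(labels)) < 2L)
        stop("labels are degenerate (a single class); shuffling them ",
             "cannot form a meaningful null")
    sample(labels)
}

#' Label-shuffling permutation test for dynamic symptom interactions
#'
#' The self-contained permutation test: in each of `N` iterations the
#' syndrome's label column is shuffled across the whole cohort, the
#' shuffled positive set is formed, and the wMI of every edge of the
#' ORIGINAL network is recomputed on it (node set and edge list are kept
#' fixed; no re-selection). For an edge, `n_g` counts iterations whose
#' permuted wMI is equal to or greater than the original edge weight;
#' `P_g = n_g / N` and `P_l = 1 - P_g`. Small `P_g` marks an interaction
#' stronger under the syndrome than under random labelling (increased);
#' small `P_l` a weaker one (decreased). The raw `n/N` estimator is used,
#' so `P_g = 0` is possible at finite `N`; ties count toward `n_g`.
#'
#' @param cohort the full \linkS4class{SymptomCohort} (not the positive
#'   set) whose labels are shuffled.
#' @param syndrome the syndrome whose label column is shuffled.
#' @param network the original \linkS4class{SymptomNetwork}, built from the
#'   true positive set of `syndrome`.
#' @param w grade-pair weight matrix (must match the one used for
#'   `network`).
#' @param N number of permutations (default 10000).
#' @param seed optional integer seed for the shuffles.
#' @return data.frame of class `PermutationEdgeResult` with columns `u`,
#'   `v`, `original_wMI`, `n_g`, `N`, `P_g`, `P_l`, one row per edge.
#' @seealso [classifyDynamic()] to call increased/decreased edges.
#' @export
permutationTest <- function(cohort, syndrome, network,
                            w = gradeWeightMatrix(), N = 10000L,
                            seed = NULL) {
    stopifnot(is(cohort, "SymptomCohort"), is(network, "SymptomNetwork"))
    syndrome <- match.arg(syndrome, syndromeIds(cohort))
    if (N < 1L) stop("'N' must be at least 1")
    lab <- colData(cohort)[[syndrome]]
    if (length(unique(lab)) < 2L)
        stop("labels for ", syndrome, " are degenerate (single class)")
    if (!is.null(seed)) set.seed(as.integer(seed))
    edges <- networkEdges(network)
    nE <- nrow(edges)
    out <- data.frame(u = edges$u, v = edges$v, original_wMI = edges$wMI,
                      n_g = integer(nE), N = as.integer(N),
                      P_g = numeric(nE), P_l = numeric(nE))
    class(out) <- c("PermutationEdgeResult", class(out))
    if (!nE) return(out)
    g <- grades(cohort)
    ## per-edge grade-pair codes over the whole cohort, subset per shuffle
    codes <- matrix(0L, ncol(cohort), nE)
    for (k in seq_len(nE))
        codes[, k] <- g[edges$u[k], ] * 4L + g[edges$v[k], ] + 1L
    logBase <- network@logBase
    orig <- edges$wMI
    ng <- integer(nE)
    for (it in seq_len(N)) {
        pos <- which(sample(lab) == 1L)
        permWMI <- vapply(seq_len(nE), function(k)
            .wmiFromCodes(codes[pos, k], w, logBase), numeric(1))
        ng <- ng + (permWMI >= orig)
    }
    out$n_g <- ng
    out$P_g <- ng / N
    out$P_l <- 1 - out$P_g
    out
}

#' Classify dynamic symptom interactions
#'
#' An edge is an increased interaction when `P_g < cutoff` (its wMI under
#' the syndrome exceeds the shuffled-label null), a decreased interaction
#' when `P_l < cutoff`, and neutral otherwise. With `cutoff < 0.5` the
#' classes are mutually exclusive. P-values are used raw (no
#' multiple-testing correction, matching the 0.1 screening cutoff);
#' set `adjust = "BH"` for Benjamini-Hochberg adjusted calls instead.
#'
#' @param results a [permutationTest()] result.
#' @param cutoff p-value cutoff in (0, 1), default 0.1.
#' @param adjust "none" (default) or "BH".
#' @return `results` with an added `dynamic_class` factor column
#'   (increased/decreased/neutral).
#' @export
classifyDynamic <- function(results, cutoff = 0.1, adjust = c("none", "BH")) {
    stopifnot(inherits(results, "PermutationEdgeResult") ||
              all(c("P_g", "P_l") %in% colnames(results)),
              cutoff > 0, cutoff < 1)
    adjust <- match.arg(adjust)
    pg <- results$P_g
    pl <- results$P_l
    if (adjust == "BH") {
        pg <- stats::p.adjust(pg, "BH")
        pl <- stats::p.adjust(pl, "BH")
    }
    cls <- rep("neutral", nrow(results))
    cls[pg < cutoff] <- "increased"
    cls[pl < cutoff & !(pg < cutoff)] <- "decreased"
    results$dynamic_class <- factor(cls,
        levels = c("increased", "decreased", "neutral"))
    results
}

#' Count decreased and increased interactions
#'
#' @param results a classified [classifyDynamic()] result.
#' @return named integer vector `c(NDI = ..., NII = ...)`.
#' @export
dynamicCounts <- function(results) {
    stopifnot("dynamic_class" %in% colnames(results))
    c(NDI = sum(results$dynamic_class == "decreased"),
      NII = sum(results$dynamic_class == "increased"))
}
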
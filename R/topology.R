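#' Density of an undirected simple graph
#'
#' `2 * NE / (NN * (NN - 1))`: the fraction of realised edges.
#'
#' @param nn node count (>= 2).
#' @param ne edge count.
#' @return density in \[0, 1\].
#' @examples
#' networkDensity(36, 176)  # 0.279...
#' @export
networkDensity <- function(nn, ne) {
    if (nn < 2) stop("density is undefined for fewer than 2 nodes")
    if (ne < 0 || ne > nn * (nn - 1) / 2)
        stop("edge count out of range for a simple graph on ", nn, " nodes")
    2 * ne / (nn * (nn - 1))
}

#' Average clustering coefficient of a symptom network
#'
#' Unweighted average of the local clustering coefficients over all nodes.
#' Nodes of degree < 2 have no potential triangles; by default they count
#' as 0 in the average (set `excludeLowDegree = TRUE` to drop them
#' instead, the other common convention).
#'
#' @param network a \linkS4class{SymptomNetwork}.
#' @param excludeLowDegree drop degree-<2 nodes from the average rather
#'   than counting them as 0.
#' @return clustering coefficient in \[0, 1\] (0 for an empty average).
#' @export
clusteringCoefficient <- function(network, excludeLowDegree = FALSE) {
    g <- asIgraph(network)
    if (igraph::vcount(g) == 0L) return(0)
    local <- igraph::transitivity(g, type = "local", isolates = "zero")
    deg <- igraph::degree(g)
    local[deg < 2L] <- 0
    if (excludeLowDegree) {
        local <- local[deg >= 2L]
        if (!length(local)) return(0)
    }
    mean(local)
}

#' Topological summary of a symptom network
#'
#' One-row data.frame shaped like the study's network characteristics
#' table: node count (NN), edge count (NE), number of connected
#' components (NCC), average clustering coefficient (CC), density (ND),
#' and the decreased/increased dynamic interaction counts (NDI/NII, `NA`
#' until permutation results are supplied). Average shortest path length,
#' diameter and radius are additionally reported for fully connected
#' networks and are `NA` otherwise.
#'
#' @param network a \linkS4class{SymptomNetwork}.
#' @param permutation optional classified permutation results from
#'   [classifyDynamic()], used to fill NDI/NII.
#' @param excludeLowDegree passed to [clusteringCoefficient()].
#' @return one-row data.frame with columns `network`, `NN`, `NE`, `NCC`,
#'   `CC`, `ND`, `NDI`, `NII`, `ASP`, `diameter`, `radius`.
#' @export
summarizeTopology <- function(network, permutation = NULL,
                              excludeLowDegree = FALSE) {
    g <- asIgraph(network)
    nn <- igraph::vcount(g)
    ne <- igraph::ecount(g)
    ncc <- igraph::components(g)$no
    cc <- clusteringCoefficient(network, excludeLowDegree)
    nd <- if (nn >= 2) networkDensity(nn, ne) else NA_real_
    connected <- ncc == 1L && nn >= 1L
    asp <- diam <- rad <- NA_real_
    if (connected) {
        asp <- igraph::mean_distance(g, weights = NA)
        diam <- igraph::diameter(g, weights = NA)
        rad <- igraph::radius(g)
    }
    ndi <- nii <- NA_integer_
    if (!is.null(permutation)) {
        counts <- dynamicCounts(permutation)
        ndi <- counts[["NDI"]]
        nii <- counts[["NII"]]
    }
    data.frame(network = network@networkId, NN = nn, NE = ne, NCC = ncc,
               CC = cc, ND = nd, NDI = ndi, NII = nii,
               ASP = asp, diameter = diam, radius = rad)
}
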
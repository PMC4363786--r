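## Shared fixtures and independent oracles for the test suite.

ALL_SYNDROMES <- c("BD", "BS", "FH", "PH", "QD", "QS", "YD")
ALL_SYMPTOMS <- paste0("PS", 1:36)

## syndromes that carry no signal (shift 0, no couplings)
inertSyndromeSpecs <- function(active, prevalence = 0.3) {
    lapply(setdiff(ALL_SYNDROMES, active), function(s)
        syndromeSpec(s, prevalence,
                     keySymptoms = data.frame(symptom_id = "PS36",
                                              grade_shift = 0L)))
}

## one informative syndrome (QS), everything else inert; female-only
## symptoms avoided by using an all-female cohort
singleSyndromeSpec <- function(n = 364, prevalence = 0.5,
                               keys = paste0("PS", 1:12), shift = 2L,
                               coupledPairs = NULL,
                               baseline = c(0.4, 0.3, 0.2, 0.1)) {
    qs <- syndromeSpec("QS", prevalence,
        keySymptoms = data.frame(symptom_id = keys, grade_shift = shift),
        coupledPairs = if (is.null(coupledPairs))
            data.frame(u = character(), v = character(), coupling = numeric())
        else coupledPairs)
    cohortSpec(n, baseline, c(list(qs), inertSyndromeSpecs("QS")),
               femaleFraction = 1)
}

## labels carry no information about grades at all
nullLabelSpec <- function(n = 364, prevalence = 0.5,
                          baseline = c(0.4, 0.3, 0.2, 0.1)) {
    syn <- lapply(ALL_SYNDROMES, function(s)
        syndromeSpec(s, prevalence,
                     keySymptoms = data.frame(symptom_id = "PS36",
                                              grade_shift = 0L)))
    cohortSpec(n, baseline, syn, femaleFraction = 1)
}

## a small valid cohort with arbitrary content
randomCohort <- function(n = 10, seed = 1) {
    set.seed(seed)
    g <- matrix(sample(0:3, n * 36, replace = TRUE), n, 36)
    l <- matrix(0L, n, 7)
    while (any(colSums(l) == 0) || any(colSums(l) == n))
        l <- matrix(rbinom(n * 7, 1, 0.5), n, 7)
    SymptomCohort(g, l)
}

## assemble a SymptomNetwork from explicit edges (unit weight, theta 0)
makeTestNetwork <- function(nodes, u, v, w = 1) {
    new("SymptomNetwork", networkId = "test", nodes = nodes,
        edges = data.frame(u = u, v = v, wMI = rep_len(w, length(u))),
        threshold = 0, logBase = 2)
}

## ---- independent oracles --------------------------------------------------

## textbook mutual information of a joint matrix, direct double loop
bruteMI <- function(p, logBase = 2) {
    px <- rowSums(p); py <- colSums(p)
    s <- 0
    for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
        if (p[i, j] > 0)
            s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]), base = logBase)
    }
    s
}

## two-pass Fisher score: explicit class means/population variances
bruteFisher <- function(x, y) {
    mu <- sum(x) / length(x)
    num <- den <- 0
    for (cl in unique(y)) {
        xi <- x[y == cl]
        Pi <- length(xi) / length(x)
        mui <- sum(xi) / length(xi)
        vari <- sum((xi - mui)^2) / length(xi)
        num <- num + Pi * (mui - mu)^2
        den <- den + Pi * vari
    }
    if (den == 0) { if (num == 0) 0 else Inf } else num / den
}

## average local clustering coefficient by triangle counting over all
## node triples on an adjacency matrix; degree-<2 nodes count as 0
bruteCC <- function(adj) {
    nn <- nrow(adj)
    local <- numeric(nn)
    for (i in seq_len(nn)) {
        nb <- which(adj[i, ] == 1)
        k <- length(nb)
        if (k < 2) next
        tri <- 0
        for (a in seq_len(k - 1)) for (b in (a + 1):k)
            tri <- tri + adj[nb[a], nb[b]]
        local[i] <- 2 * tri / (k * (k - 1))
    }
    mean(local)
}

## number of connected components via breadth-first flood fill
bruteNCC <- function(adj) {
    nn <- nrow(adj)
    seen <- logical(nn)
    ncc <- 0
    for (s in seq_len(nn)) {
        if (seen[s]) next
        ncc <- ncc + 1
        queue <- s
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            if (seen[v]) next
            seen[v] <- TRUE
            queue <- c(queue, which(adj[v, ] == 1 & !seen))
        }
    }
    ncc
}

## exact permutation-null P_g of one edge by enumerating all positive
## sets of the given size (label arrangements are uniform over these)
exactPermPg <- function(gradesU, gradesV, nPos, origWMI,
                        w = gradeWeightMatrix()) {
    sets <- utils::combn(length(gradesU), nPos)
    hits <- 0
    for (k in seq_len(ncol(sets))) {
        idx <- sets[, k]
        j <- empiricalJoint(gradesU[idx], gradesV[idx])
        if (weightedMutualInformation(j, w) >= origWMI - 1e-12)
            hits <- hits + 1
    }
    hits / ncol(sets)
}
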
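test_that("empiricalJoint counts without smoothing", {
    j <- empiricalJoint(c(0, 3), c(0, 3))
    expect_equal(j$p["0", "0"], 0.5)
    expect_equal(j$p["3", "3"], 0.5)
    expect_equal(sum(j$p), 1)
    j1 <- empiricalJoint(2, 1)
    expect_equal(j1$p["2", "1"], 1)
    expect_error(empiricalJoint(integer(), integer()), "empty")
    expect_error(empiricalJoint(c(0, 4), c(0, 1)))
    ## marginals derive from the joint
    set.seed(30)
    x <- sample(0:3, 40, TRUE); y <- sample(0:3, 40, TRUE)
    j2 <- empiricalJoint(x, y)
    expect_equal(sum(j2$px), 1)
    expect_equal(j2$px, rowSums(j2$p))
    expect_equal(j2$py, colSums(j2$p))
})

test_that("the default weight matrix is 1 - 0.2|x - y|", {
    w <- gradeWeightMatrix()
    expect_equal(diag(w), rep(1, 4), ignore_attr = TRUE)
    expect_identical(w, t(w))
    expect_equal(w["0", "3"], 0.4)
    expect_equal(w["1", "2"], 0.8)
})

test_that("wMI reproduces hand-derived coupling values", {
    ## deterministic 2-symbol coupling on the diagonal: 1 bit, weights 1
    expect_equal(weightedMutualInformation(
        empiricalJoint(c(0, 0, 3, 3), c(0, 0, 3, 3))), 1.0)
    ## same coupling through w = 0.8 cells: 0.8 bit (plain MI would be 1)
    j <- empiricalJoint(c(0, 0, 3, 3), c(1, 1, 2, 2))
    expect_equal(weightedMutualInformation(j), 0.8)
    expect_equal(weightedMutualInformation(j, matrix(1, 4, 4)), 1.0)
    ## independence: every log term vanishes
    p <- outer(c(.1, .2, .3, .4), c(.4, .3, .2, .1))
    expect_equal(weightedMutualInformation(p, gradeWeightMatrix()), 0)
})

test_that("wMI with unit weights equals textbook MI on random joints", {
    set.seed(31)
    ones <- matrix(1, 4, 4)
    for (i in 1:1000) {
        p <- matrix(rexp(16), 4, 4)
        p <- p / sum(p)
        expect_equal(weightedMutualInformation(p, ones), bruteMI(p),
                     tolerance = 1e-12)
    }
})

test_that("wMI is symmetric under transposition of the joint", {
    set.seed(32)
    w <- gradeWeightMatrix()
    for (i in 1:1000) {
        p <- matrix(rexp(16), 4, 4)
        p <- p / sum(p)
        expect_equal(weightedMutualInformation(p, w),
                     weightedMutualInformation(t(p), w), tolerance = 1e-12)
    }
})

test_that("natural-log base rescales the wMI by log(2)", {
    j <- empiricalJoint(c(0, 0, 3, 3), c(0, 0, 3, 3))
    expect_equal(weightedMutualInformation(j, logBase = exp(1)), log(2))
})

test_that("network thresholding is monotone and uses >=", {
    co <- generateCohort(defaultDepressionSpec(), seed = 33)
    ps <- positiveSet(co, "QD")
    nodes <- paste0("PS", 1:12)
    edgeKey <- function(net) {
        e <- networkEdges(net)
        paste(e$u, e$v)
    }
    n0 <- buildSymptomNetwork(ps, nodes, theta = 0)
    n1 <- buildSymptomNetwork(ps, nodes, theta = 0.05)
    n2 <- buildSymptomNetwork(ps, nodes, theta = 0.1)
    expect_true(all(edgeKey(n2) %in% edgeKey(n1)))
    expect_true(all(edgeKey(n1) %in% edgeKey(n0)))
    ## theta = 0 keeps exactly the pairs with non-negative wMI
    expect_true(all(networkEdges(n0)$wMI >= 0))
    ## an edge sitting exactly at theta is kept ("equal to or larger")
    wmax <- max(networkEdges(n0)$wMI)
    nAt <- buildSymptomNetwork(ps, nodes, theta = wmax)
    expect_gte(nrow(networkEdges(nAt)), 1)
    ## theta above the maximum leaves the network edgeless
    nAbove <- buildSymptomNetwork(ps, nodes, theta = wmax + 1e-6)
    expect_equal(nrow(networkEdges(nAbove)), 0)
    expect_length(networkNodes(nAbove), 12)
})

test_that("a planted coupled pair survives thresholding at theta = 0.1", {
    pairs <- data.frame(u = "PS1", v = "PS2", coupling = 0.9)
    spec <- singleSyndromeSpec(shift = 0L, coupledPairs = pairs)
    found <- vapply(1:20, function(s) {
        co <- generateCohort(spec, seed = s)
        e <- networkEdges(buildSymptomNetwork(positiveSet(co, "QS"),
                                              paste0("PS", 1:12),
                                              theta = 0.1))
        any(e$u == "PS1" & e$v == "PS2")
    }, logical(1))
    expect_gte(mean(found), 0.9)
})

test_that("tanimotoSimilarity implements c / (a + b - c)", {
    expect_equal(tanimotoSimilarity(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
    expect_equal(tanimotoSimilarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
    ## a = 5, b = 4, c = 2
    l1 <- c(1, 1, 1, 1, 1, 0, 0, 0, 0)
    l2 <- c(1, 1, 0, 0, 0, 1, 1, 0, 0)
    expect_equal(tanimotoSimilarity(l1, l2), 2 / 7)
    expect_equal(tanimotoSimilarity(l2, l1), 2 / 7)
    expect_error(tanimotoSimilarity(c(0, 0), c(0, 0)), "undefined")
})

test_that("syndrome network scores all 21 pairs and keeps cutoff edges", {
    co <- randomCohort(n = 40, seed = 34)
    sn <- buildSyndromeNetwork(co, cutoff = 0.5)
    expect_equal(nrow(sn@allPairs), 21L)
    expect_true(all(networkEdges(sn)$similarity >= 0.5))
    ## impossible cutoff -> edgeless
    expect_equal(nrow(networkEdges(buildSyndromeNetwork(co, 1.01))), 0L)
    ## identical label columns -> similarity-1 edge
    l <- syndromeLabels(co)
    l[, "QD"] <- l[, "QS"]
    co2 <- SymptomCohort(t(grades(co)), l)
    e <- networkEdges(buildSyndromeNetwork(co2))
    expect_equal(e$similarity[e$s1 == "QD" & e$s2 == "QS"], 1)
})

test_that("planted co-occurrence is detected by Fisher's exact test", {
    base <- nullLabelSpec(n = 5000, prevalence = 0.3)
    tilted <- cohortSpec(5000, base$baseline_grade_probs, base$syndromes,
        cooccurrence = data.frame(s1 = "QS", s2 = "QD", multiplier = 4),
        femaleFraction = 1)
    hits <- vapply(1:20, function(s) {
        co <- generateCohort(tilted, seed = s)
        sn <- buildSyndromeNetwork(co)
        p <- sn@allPairs
        p$p_value[p$s1 == "QD" & p$s2 == "QS"] < 0.01
    }, logical(1))
    expect_gte(mean(hits), 0.9)
})

test_that("networks export as edge lists and GraphML", {
    co <- generateCohort(defaultDepressionSpec(), seed = 35)
    net <- buildSymptomNetwork(positiveSet(co, "QS"), paste0("PS", 1:12),
                               networkId = "QS")
    f <- withr::local_tempfile(fileext = ".tsv")
    writeEdgeList(net, f)
    tab <- read.delim(f)
    expect_identical(colnames(tab), c("u", "v", "wMI"))
    expect_equal(nrow(tab), nrow(networkEdges(net)))
    gml <- withr::local_tempfile(fileext = ".graphml")
    writeGraphML(net, gml,
                 nodeAttributes = data.frame(id = paste0("PS", 1:12),
                                             fisher_rank = 1:12))
    g <- igraph::read_graph(gml, format = "graphml")
    expect_equal(igraph::vcount(g), 12)
    expect_equal(igraph::ecount(g), nrow(networkEdges(net)))
    expect_true("fisher_rank" %in% igraph::vertex_attr_names(g))
})
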
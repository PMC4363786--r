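## small helper: a cohort whose QS label is a deterministic function of PS1
separableCohort <- function(n = 40) {
    g <- matrix(0L, n, 36)
    l <- matrix(0L, n, 7, dimnames = list(NULL, ALL_SYNDROMES))
    l[seq_len(n / 2), ] <- 1L
    g[l[, "QS"] == 1L, 1] <- 3L
    SymptomCohort(g, l)
}

test_that("naive Bayes separates a deterministic feature", {
    co <- separableCohort()
    m <- trainNaiveBayes(co, "QS", pseudocount = 0)
    pred <- predict(m, co)
    expect_equal(pred, as.integer(colData(co)$QS))
    post <- predict(m, co, type = "posterior")
    expect_equal(rowSums(post), rep(1, ncol(co)))
})

test_that("uninformative features fall back to the majority class", {
    l <- matrix(0L, 60, 7)
    l[1:15, ] <- 1L  # 75% negatives
    ## constant features carry no evidence, so the prior must dominate
    co2 <- SymptomCohort(matrix(2L, 60, 36), l)
    m <- trainNaiveBayes(co2, "QS")
    expect_true(all(predict(m, co2) == 0L))
})

test_that("the naive Bayes posterior matches hand multiplication", {
    ## 2-feature toy: class-conditional tables known exactly
    g <- matrix(0L, 8, 36)
    g[, 1] <- c(3, 3, 3, 0, 0, 0, 0, 3)
    g[, 2] <- c(2, 2, 0, 0, 2, 0, 0, 0)
    l <- matrix(0L, 8, 7)
    l[1:4, ] <- 1L
    co <- SymptomCohort(g, l)
    m <- trainNaiveBayes(co, "QS", pseudocount = 1,
                         features = c("PS1", "PS2"))
    ## hand-computed smoothed tables (4 samples per class, 4 grades):
    ## P(PS1=3|C=1) = (3+1)/(4+4) = 0.5 ; P(PS1=3|C=0) = (1+1)/8 = 0.25
    ## P(PS2=2|C=1) = (2+1)/8 = 0.375  ; P(PS2=2|C=0) = (1+1)/8 = 0.25
    ## priors 0.5/0.5
    up1 <- 0.5 * 0.5 * 0.375
    up0 <- 0.5 * 0.25 * 0.25
    post <- predict(m, matrix(c(3L, 2L, rep(0L, 34)), 1, 36,
                              dimnames = list(NULL, ALL_SYMPTOMS)),
                    type = "posterior")
    expect_equal(unname(post[1, "1"]), up1 / (up1 + up0),
                 tolerance = 1e-12)
})

test_that("TAN recovers a feature dependence in its tree", {
    ## PS2 copies PS1 given the class, other features independent
    set.seed(61)
    n <- 400
    g <- matrix(sample(0:3, n * 36, TRUE), n, 36)
    l <- matrix(rbinom(n * 7, 1, 0.5), n, 7)
    g[, 2] <- g[, 1]
    co <- SymptomCohort(g, l)
    m <- trainTAN(co, "QS", features = paste0("PS", 1:5))
    ## the F1-F2 edge must be in the augmenting tree (as parenthood
    ## either way)
    expect_true(identical(m@parent[2], 1L) || identical(m@parent[1], 2L))
})

test_that("TAN structure learning is deterministic", {
    co <- generateCohort(defaultDepressionSpec(), seed = 62)
    m1 <- trainTAN(co, "QD")
    m2 <- trainTAN(co, "QD")
    expect_identical(m1@parent, m2@parent)
    ## exactly one root; the feature edges form a spanning tree
    expect_equal(sum(is.na(m1@parent)), 1L)
    expect_true(is.na(m1@parent[1]))
})

test_that("TAN approaches naive Bayes when features are independent", {
    spec <- singleSyndromeSpec(n = 5000, keys = paste0("PS", 1:6),
                               shift = 1L)
    co <- generateCohort(spec, seed = 63)
    feats <- paste0("PS", 1:8)
    nb <- trainNaiveBayes(co, "QS", features = feats)
    tan <- trainTAN(co, "QS", features = feats)
    dPost <- abs(predict(nb, co, type = "posterior")[, "1"] -
                 predict(tan, co, type = "posterior")[, "1"])
    expect_lt(mean(dPost), 0.02)
})

test_that("repeated CV is deterministic, stratified and validated", {
    co <- generateCohort(defaultDepressionSpec(), seed = 64)
    e1 <- repeatedCV(co, "QS", "nb", repeats = 3, seed = 9)
    e2 <- repeatedCV(co, "QS", "nb", repeats = 3, seed = 9)
    expect_identical(accuracies(e1), accuracies(e2))
    ## a class smaller than the fold count is refused by name
    g <- matrix(sample(0:3, 20 * 36, TRUE), 20, 36)
    l <- matrix(0L, 20, 7)
    l[1:2, ] <- 1L
    tiny <- SymptomCohort(g, l)
    expect_error(repeatedCV(tiny, "QS", "nb"), "class 1")
})

test_that("all four methods ace a perfectly separable cohort", {
    co <- separableCohort(n = 60)
    for (m in c("nb", "tan", "svm", "tree")) {
        ev <- repeatedCV(co, "QS", m, repeats = 2, seed = 3,
                         features = paste0("PS", 1:4))
        expect_equal(mean(accuracies(ev)), 1.0)
    }
})

test_that("naive Bayes predictions agree with an independent implementation", {
    ## same smoothing, same prior: predictions must coincide exactly with
    ## e1071::naiveBayes on a held-out split
    co <- generateCohort(nullLabelSpec(n = 364, prevalence = 0.15),
                         seed = 65)
    g <- t(grades(co))
    y <- as.integer(colData(co)$QS)
    df <- as.data.frame(lapply(as.data.frame(g),
                               function(col) factor(col, levels = 0:3)))
    tr <- seq_len(250); te <- 251:364
    mine <- predict(trainNaiveBayes(co[, tr], "QS", pseudocount = 1),
                    g[te, , drop = FALSE])
    ref <- e1071::naiveBayes(df[tr, ], factor(y[tr], 0:1), laplace = 1)
    theirs <- as.integer(as.character(predict(ref, df[te, ])))
    expect_identical(mine, theirs)
})

test_that("null-label accuracy converges to the majority rate", {
    ## labels independent of grades, 85% negative; at a cohort size where
    ## per-feature table noise is negligible the classifier must fall
    ## back to the majority class rate
    spec <- nullLabelSpec(n = 2000, prevalence = 0.15)
    co <- generateCohort(spec, seed = 65)
    ev <- repeatedCV(co, "QS", "nb", repeats = 3, seed = 66)
    maj <- max(mean(colData(co)$QS), 1 - mean(colData(co)$QS))
    expect_lt(abs(mean(accuracies(ev)) - maj), 0.03)
})

test_that("compareMethods is a paired t-test with degenerate handling", {
    mkEval <- function(acc, method = "nb")
        new("ClassifierEval", syndrome = "QS", method = method,
            accuracies = acc, folds = 5L, repeats = length(acc),
            seed = 1L)
    a <- mkEval(c(0.8, 0.9, 0.85))
    expect_equal(compareMethods(a, mkEval(c(0.8, 0.9, 0.85), "tan"))$p.value, 1)
    shifted <- mkEval(c(0.7, 0.8, 0.75), "tan")
    expect_lt(compareMethods(a, shifted)$p.value, 1e-6)
    ## hand-computed paired t on a 3-pair toy:
    ## diffs 0.10, 0.05, 0.05; mean 0.0666..; sd = sqrt(oneliner below)
    b <- mkEval(c(0.70, 0.85, 0.80), "tan")
    d <- c(0.10, 0.05, 0.05)
    tHand <- mean(d) / (sqrt(sum((d - mean(d))^2) / 2) / sqrt(3))
    expect_equal(compareMethods(a, b)$statistic, tHand, tolerance = 1e-12)
    ## unpaired settings are refused
    expect_error(compareMethods(a, mkEval(c(0.7, 0.8), "tan")), "paired")
})
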
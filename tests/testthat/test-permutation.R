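test_that("permuteLabels conserves counts and rejects degenerate input", {
    set.seed(50)
    l <- c(1, 1, 0, 0)
    for (i in 1:20) expect_equal(sum(permuteLabels(l)), 2)
    expect_error(permuteLabels(c(1, 1, 1)), "single class")
    ## uniformity: each position holds the single 1 about N/4 times
    N <- 10000
    pos <- vapply(seq_len(N), function(i) which(permuteLabels(c(1, 0, 0, 0)) == 1),
                  integer(1))
    counts <- tabulate(pos, 4)
    expect_true(all(abs(counts - 2500) <= 150))  # 3 sigma binomial bound
})

test_that("shuffles are reproducible for a fixed seed", {
    co <- generateCohort(defaultDepressionSpec(), seed = 51)
    net <- buildSymptomNetwork(positiveSet(co, "QS"), paste0("PS", 1:8),
                               networkId = "QS")
    r1 <- permutationTest(co, "QS", net, N = 50, seed = 7)
    r2 <- permutationTest(co, "QS", net, N = 50, seed = 7)
    expect_identical(r1$n_g, r2$n_g)
})

test_that("P_g and P_l satisfy the counting identities", {
    co <- generateCohort(defaultDepressionSpec(), seed = 52)
    net <- buildSymptomNetwork(positiveSet(co, "QD"), paste0("PS", 1:10),
                               theta = 0, networkId = "QD")
    res <- permutationTest(co, "QD", net, N = 200, seed = 1)
    expect_equal(res$P_g + res$P_l, rep(1, nrow(res)))
    expect_equal(res$P_g, res$n_g / res$N)
    expect_true(all(res$n_g >= 0 & res$n_g <= res$N))
})

test_that("ties count toward n_g (constant grades give P_g = 1)", {
    ## identical grade columns: every permuted wMI equals the original
    g <- matrix(1L, 12, 36)
    l <- matrix(rep(c(1L, 0L), 6 * 7), 12, 7)
    co <- SymptomCohort(g, l)
    net <- makeTestNetwork(c("PS1", "PS2"), "PS1", "PS2", w = 0)
    res <- permutationTest(co, "QS", net, N = 100, seed = 3)
    expect_equal(res$n_g, 100L)
    expect_equal(res$P_g, 1)
    expect_equal(res$P_l, 0)
})

test_that("Monte-Carlo P_g matches exhaustive enumeration on toy cohorts", {
    ## 6 patients, 3 positives: the shuffle distribution is uniform over
    ## the choose(6,3) = 20 positive sets, so P_g can be enumerated
    set.seed(53)
    for (rep in 1:3) {
        g <- matrix(sample(0:3, 6 * 36, replace = TRUE), 6, 36)
        l <- matrix(rbinom(6 * 7, 1, 0.5), 6, 7)
        l[1:2, ] <- rep(c(1L, 0L), each = 1L)  # both classes everywhere
        l[, 6] <- c(1L, 1L, 1L, 0L, 0L, 0L)  # QS: 3 positives
        co <- SymptomCohort(g, l)
        net <- buildSymptomNetwork(positiveSet(co, "QS"),
                                   nodes = paste0("PS", 1:5),
                                   theta = 0, networkId = "QS")
        res <- permutationTest(co, "QS", net, N = 20000, seed = rep)
        gr <- grades(co)
        for (k in seq_len(nrow(res))) {
            exact <- exactPermPg(gr[res$u[k], ], gr[res$v[k], ], nPos = 3,
                                 origWMI = res$original_wMI[k])
            se <- sqrt(max(exact * (1 - exact), 1 / 20000) / 20000)
            expect_lt(abs(res$P_g[k] - exact), 3 * se + 1e-9)
        }
    }
})

test_that("classifyDynamic applies the cutoff rule exclusively", {
    res <- data.frame(u = paste0("PS", 1:3), v = paste0("PS", 4:6),
                      original_wMI = 1, n_g = c(500L, 9500L, 2500L),
                      N = 10000L)
    res$P_g <- res$n_g / res$N
    res$P_l <- 1 - res$P_g
    class(res) <- c("PermutationEdgeResult", class(res))
    cls <- classifyDynamic(res, cutoff = 0.1)$dynamic_class
    expect_equal(as.character(cls), c("increased", "decreased", "neutral"))
    ## exactly one class per edge for any cutoff below 0.5
    set.seed(54)
    for (i in 1:50) {
        r1 <- res[1, ]
        r1$P_g <- runif(1); r1$P_l <- 1 - r1$P_g
        cls1 <- classifyDynamic(r1, cutoff = runif(1, 0.01, 0.49))$dynamic_class
        expect_length(cls1, 1)
        expect_false(is.na(cls1))
    }
    cnt <- dynamicCounts(classifyDynamic(res))
    expect_equal(cnt, c(NDI = 1L, NII = 1L))
})

test_that("doubling N leaves P_g estimates within Monte-Carlo error", {
    co <- generateCohort(defaultDepressionSpec(), seed = 55)
    net <- buildSymptomNetwork(positiveSet(co, "QS"), paste0("PS", 14:18),
                               theta = 0, networkId = "QS")
    expect_gt(nrow(networkEdges(net)), 0)
    rA <- permutationTest(co, "QS", net, N = 1000, seed = 10)
    rB <- permutationTest(co, "QS", net, N = 2000, seed = 11)
    expect_true(all(abs(rA$P_g - rB$P_g) <= 4 * sqrt(0.25 / 1000)))
})

test_that("a coupled pair present only in positives is called increased", {
    pairs <- data.frame(u = "PS1", v = "PS2", coupling = 0.9)
    spec <- singleSyndromeSpec(shift = 0L, coupledPairs = pairs)
    calls <- vapply(1:10, function(s) {
        co <- generateCohort(spec, seed = s)
        net <- buildSymptomNetwork(positiveSet(co, "QS"),
                                   paste0("PS", 1:6), networkId = "QS")
        e <- networkEdges(net)
        if (!any(e$u == "PS1" & e$v == "PS2")) return(FALSE)
        cd <- classifyDynamic(permutationTest(co, "QS", net, N = 500,
                                              seed = s + 100))
        as.character(cd$dynamic_class[cd$u == "PS1" & cd$v == "PS2"]) ==
            "increased"
    }, logical(1))
    expect_gte(mean(calls), 0.8)
})
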
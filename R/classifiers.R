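## grade matrix (features x n) and 0/1 label vector for one syndrome
.classData <- function(cohort, syndrome, features) {
    g <- grades(cohort)[features, , drop = FALSE]
    y <- as.integer(colData(cohort)[[syndrome]])
    if (length(unique(y)) < 2L)
        stop("cannot train on a single class for ", syndrome)
    list(g = g, y = y)
}

#' Train a naive Bayes classifier for one syndrome
#'
#' Multinomial naive Bayes over the ordinal grades: the class posterior is
#' proportional to `P(C) * prod_i P(F_i | C)` under the conditional
#' independence assumption, and prediction takes the maximum a posteriori
#' class. Conditional tables are smoothed maximum likelihood (Laplace
#' pseudocount, default 1, over the 4 grades); the class prior is the
#' empirical class proportion.
#'
#' @param cohort a \linkS4class{SymptomCohort} with both classes present
#'   for the syndrome.
#' @param syndrome syndrome id.
#' @param pseudocount Laplace smoothing pseudocount (0 disables smoothing;
#'   zero cells then produce zero posteriors).
#' @param features feature symptom ids (default all 36).
#' @return a \linkS4class{NaiveBayesModel}.
#' @export
trainNaiveBayes <- function(cohort, syndrome, pseudocount = 1,
                            features = symptomIds(cohort)) {
    syndrome <- match.arg(syndrome, syndromeIds(cohort))
    d <- .classData(cohort, syndrome, features)
    k <- length(features)
    tables <- array(NA_real_, c(k, 4L, 2L),
                    dimnames = list(features, 0:3, 0:1))
    for (cl in 0:1) {
        gc <- d$g[, d$y == cl, drop = FALSE]
        nc <- ncol(gc)
        for (i in seq_len(k)) {
            cnt <- tabulate(gc[i, ] + 1L, nbins = 4L)
            tables[i, , cl + 1L] <- (cnt + pseudocount) /
                (nc + 4 * pseudocount)
        }
    }
    prior <- c("0" = mean(d$y == 0L), "1" = mean(d$y == 1L))
    new("NaiveBayesModel", syndrome = syndrome, prior = prior,
        tables = tables, features = features,
        pseudocount = as.numeric(pseudocount))
}

## class-conditional mutual information between all feature pairs
## (natural-log units; only relative order matters for the spanning tree)
.condMI <- function(g, y) {
    k <- nrow(g)
    cmi <- matrix(0, k, k)
    for (cl in 0:1) {
        gc <- g[, y == cl, drop = FALSE]
        pc <- mean(y == cl)
        for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
            counts <- tabulate(gc[i, ] * 4L + gc[j, ] + 1L, nbins = 16L)
            p <- matrix(counts / ncol(gc), 4L, 4L, byrow = TRUE)
            mi <- .wmiFromJoint(p, matrix(1, 4L, 4L), logBase = exp(1))
            cmi[i, j] <- cmi[i, j] + pc * mi
        }
    }
    cmi + t(cmi)
}

## deterministic Prim maximum spanning tree; ties broken by lowest node
## index; returns parent index per node with the tree rooted at node 1
.maxSpanningTreeParents <- function(weights) {
    k <- nrow(weights)
    parent <- rep(NA_integer_, k)
    inTree <- c(TRUE, rep(FALSE, k - 1L))
    best <- weights[1L, ]      # best link weight into the tree
    bestFrom <- rep(1L, k)
    for (step in seq_len(k - 1L)) {
        cand <- which(!inTree)
        nxt <- cand[order(-best[cand], cand)][1L]
        parent[nxt] <- bestFrom[nxt]
        inTree[nxt] <- TRUE
        upd <- !inTree & weights[nxt, ] > best
        best[upd] <- weights[nxt, upd]
        bestFrom[upd] <- nxt
    }
    parent
}

#' Train a tree-augmented naive Bayes (TAN) classifier
#'
#' Chow-Liu augmentation of naive Bayes: the feature tree is the maximum
#' spanning tree of pairwise class-conditional mutual information, rooted
#' at the lowest-index feature, so every feature's parents are the class
#' plus at most one other feature. Parameters `P(F_i | Pa_i, C)` are
#' smoothed maximum likelihood; prediction is maximum a posteriori on
#' `P(C) * prod_i P(F_i | Pa_i, C)`. Structure learning is deterministic
#' (ties broken by feature index).
#'
#' @inheritParams trainNaiveBayes
#' @return a \linkS4class{TANModel}.
#' @export
trainTAN <- function(cohort, syndrome, pseudocount = 1,
                     features = symptomIds(cohort)) {
    syndrome <- match.arg(syndrome, syndromeIds(cohort))
    if (length(features) < 2L) stop("TAN needs at least 2 features")
    d <- .classData(cohort, syndrome, features)
    k <- length(features)
    parent <- .maxSpanningTreeParents(.condMI(d$g, d$y))
    tables <- vector("list", k)
    for (i in seq_len(k)) {
        npa <- if (is.na(parent[i])) 1L else 4L
        tab <- array(NA_real_, c(4L, npa, 2L))
        for (cl in 0:1) {
            gc <- d$g[, d$y == cl, drop = FALSE]
            for (pa in seq_len(npa)) {
                sel <- if (npa == 1L) rep(TRUE, ncol(gc))
                       else gc[parent[i], ] == pa - 1L
                cnt <- tabulate(gc[i, sel] + 1L, nbins = 4L)
                tab[, pa, cl + 1L] <- (cnt + pseudocount) /
                    (sum(cnt) + 4 * pseudocount)
            }
        }
        tables[[i]] <- tab
    }
    prior <- c("0" = mean(d$y == 0L), "1" = mean(d$y == 1L))
    new("TANModel", syndrome = syndrome, prior = prior, features = features,
        parent = parent, tables = tables,
        pseudocount = as.numeric(pseudocount))
}

.newdataGrades <- function(object, newdata) {
    g <- if (is(newdata, "SymptomCohort")) grades(newdata) else {
        m <- as.matrix(newdata)
        if (!is.null(colnames(m)) &&
            all(object@features %in% colnames(m))) t(m) else m
    }
    g[object@features, , drop = FALSE]
}

.mapPredict <- function(logpost, type) {
    ## normalized posteriors via log-sum-exp; MAP ties go to class 0
    mx <- pmax(logpost[, 1L], logpost[, 2L])
    post <- exp(logpost - mx)
    post <- post / rowSums(post)
    colnames(post) <- c("0", "1")
    if (type == "posterior") post
    else as.integer(post[, 2L] > post[, 1L])
}

#' Predict syndrome membership with a trained Bayes classifier
#'
#' @param object a \linkS4class{NaiveBayesModel} or \linkS4class{TANModel}.
#' @param newdata a \linkS4class{SymptomCohort}, or a matrix of grades
#'   (patients in rows with named feature columns, or features x patients).
#' @param type `"class"` (0/1 vector, maximum a posteriori with ties to
#'   the negative class) or `"posterior"` (n x 2 matrix of class
#'   posteriors summing to 1).
#' @return predictions as described under `type`.
#' @export
setMethod("predict", "NaiveBayesModel",
    function(object, newdata, type = c("class", "posterior")) {
    type <- match.arg(type)
    g <- .newdataGrades(object, newdata)
    n <- ncol(g)
    logpost <- matrix(rep(log(object@prior), each = n), n, 2L)
    for (i in seq_along(object@features)) {
        gi <- g[i, ] + 1L
        logpost[, 1L] <- logpost[, 1L] + log(object@tables[i, , 1L][gi])
        logpost[, 2L] <- logpost[, 2L] + log(object@tables[i, , 2L][gi])
    }
    .mapPredict(logpost, type)
})

#' @rdname predict-NaiveBayesModel-method
#' @export
setMethod("predict", "TANModel",
    function(object, newdata, type = c("class", "posterior")) {
    type <- match.arg(type)
    g <- .newdataGrades(object, newdata)
    n <- ncol(g)
    logpost <- matrix(rep(log(object@prior), each = n), n, 2L)
    for (i in seq_along(object@features)) {
        gi <- g[i, ] + 1L
        pa <- if (is.na(object@parent[i])) rep(1L, n)
              else g[object@parent[i], ] + 1L
        for (cl in 1:2) {
            tab <- object@tables[[i]][, , cl]
            if (is.na(object@parent[i]))
                logpost[, cl] <- logpost[, cl] + log(tab[gi])
            else
                logpost[, cl] <- logpost[, cl] +
                    log(tab[cbind(gi, pa)])
        }
    }
    .mapPredict(logpost, type)
})

## delegate fits: linear-kernel soft-margin SVM (libsvm via e1071) and an
## information-gain decision tree with cost-complexity pruning (rpart)
.fitDelegate <- function(method, trainX, trainY, testX) {
    y <- factor(trainY, levels = 0:1)
    if (method == "svm") {
        fit <- e1071::svm(trainX, y, kernel = "linear", scale = FALSE)
        as.integer(as.character(predict(fit, testX)))
    } else {
        df <- data.frame(.y = y, trainX, check.names = FALSE)
        fit <- rpart::rpart(.y ~ ., df, method = "class",
                            parms = list(split = "information"),
                            control = rpart::rpart.control(xval = 0L))
        pred <- predict(fit, data.frame(testX, check.names = FALSE),
                        type = "class")
        as.integer(as.character(pred))
    }
}

#' Repeated stratified cross-validation of a syndrome classifier
#'
#' Evaluates one method on one syndrome by k-fold cross-validation
#' repeated `repeats` times (default 5-fold x 10). Folds are stratified by
#' class and fixed by the seed, identically across methods, so evaluations
#' with the same seed are paired. The per-repeat accuracy pools the
#' correctly classified held-out patients over the k folds.
#'
#' @param cohort a \linkS4class{SymptomCohort}.
#' @param syndrome syndrome id; each class must have at least `folds`
#'   members.
#' @param method `"nb"` (naive Bayes), `"tan"` (tree-augmented naive
#'   Bayes), `"svm"` (linear-kernel soft-margin SVM) or `"tree"`
#'   (information-gain decision tree).
#' @param folds,repeats cross-validation geometry.
#' @param seed integer seed fixing the fold assignments.
#' @param pseudocount smoothing for the Bayes classifiers.
#' @param features feature symptom ids (default all 36).
#' @return a \linkS4class{ClassifierEval}.
#' @seealso [compareMethods()] for the paired t-test between two methods.
#' @export
repeatedCV <- function(cohort, syndrome,
                       method = c("nb", "tan", "svm", "tree"),
                       folds = 5L, repeats = 10L, seed = 1L,
                       pseudocount = 1, features = symptomIds(cohort)) {
    method <- match.arg(method)
    syndrome <- match.arg(syndrome, syndromeIds(cohort))
    y <- as.integer(colData(cohort)[[syndrome]])
    for (cl in 0:1)
        if (sum(y == cl) < folds)
            stop("class ", cl, " of ", syndrome, " has fewer than ", folds,
                 " members; stratified ", folds, "-fold CV is impossible")
    n <- length(y)
    set.seed(as.integer(seed))
    ## all fold assignments drawn up front so they are identical across
    ## methods for a given seed (paired comparisons)
    foldAssign <- lapply(seq_len(repeats), function(r) {
        f <- integer(n)
        for (cl in 0:1) {
            idx <- sample(which(y == cl))
            f[idx] <- rep_len(seq_len(folds), length(idx))
        }
        f
    })
    g <- grades(cohort)[features, , drop = FALSE]
    X <- t(g)  # patients x features, for the delegate methods
    acc <- vapply(seq_len(repeats), function(r) {
        f <- foldAssign[[r]]
        correct <- 0L
        for (k in seq_len(folds)) {
            test <- f == k
            pred <- if (method %in% c("nb", "tan")) {
                train <- cohort[, !test]
                model <- if (method == "nb")
                    trainNaiveBayes(train, syndrome, pseudocount, features)
                else trainTAN(train, syndrome, pseudocount, features)
                predict(model, g[, test, drop = FALSE])
            } else {
                .fitDelegate(method, X[!test, , drop = FALSE], y[!test],
                             X[test, , drop = FALSE])
            }
            correct <- correct + sum(pred == y[test])
        }
        correct / n
    }, numeric(1))
    new("ClassifierEval", syndrome = syndrome, method = method,
        accuracies = acc, folds = as.integer(folds),
        repeats = as.integer(repeats), seed = as.integer(seed))
}

#' Paired t-test between two classifier evaluations
#'
#' Two-sided paired t-test over the per-repeat accuracy pairs of two
#' methods evaluated on the same syndrome with the same fold geometry and
#' seed (so the pairs share fold assignments).
#'
#' @param evalA,evalB \linkS4class{ClassifierEval} objects.
#' @return list with `statistic`, `p.value`, `mean_diff` (A minus B) and
#'   `note` ("zero-variance" when the accuracy differences are constant:
#'   identical vectors give p = 1, a constant non-zero shift p = 0).
#' @export
compareMethods <- function(evalA, evalB) {
    if (evalA@syndrome != evalB@syndrome ||
        evalA@folds != evalB@folds || evalA@repeats != evalB@repeats ||
        evalA@seed != evalB@seed)
        stop("evaluations are not paired: syndrome, folds, repeats and ",
             "seed must all match")
    d <- accuracies(evalA) - accuracies(evalB)
    if (sd(d) < 1e-12) {
        return(list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                    p.value = if (mean(d) == 0) 1 else 0,
                    mean_diff = mean(d), note = "zero-variance"))
    }
    tt <- t.test(accuracies(evalA), accuracies(evalB), paired = TRUE)
    list(statistic = unname(tt$statistic), p.value = tt$p.value,
         mean_diff = mean(d), note = "")
}
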
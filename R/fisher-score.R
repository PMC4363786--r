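#' Fisher's score of one feature against a class label
#'
#' Ratio of between-class to within-class variance:
#' `sum_i P_i (mu_i - mu)^2 / sum_i P_i sigma_i^2`, where `P_i` is the
#' empirical proportion of class `i`, `mu_i` and `sigma_i^2` the class mean
#' and population (divide-by-n_i) variance of the feature, and `mu` the
#' overall mean. Features with small within-class and large between-class
#' variance score high; scores are invariant to affine rescaling of the
#' feature. The general multi-class form is implemented; syndrome ranking
#' uses it with two classes (positive/negative).
#'
#' Degenerate cases: a zero denominator with zero numerator (feature
#' constant overall) scores 0; a zero denominator with positive numerator
#' (classes perfectly separated, zero within-class spread) scores `Inf`.
#'
#' @param x numeric feature vector (here: grades 0..3).
#' @param y class label vector, at least two distinct classes.
#' @return a single non-negative score (possibly `Inf`).
#' @examples
#' fisherScore(c(0, 2, 1, 3), c(0, 0, 1, 1))  # 0.25
#' @export
fisherScore <- function(x, y) {
    if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
    if (length(x) < 2L) stop("need at least two observations")
    cls <- unique(y)
    if (length(cls) < 2L)
        stop("only one class present; Fisher's score needs both classes")
    n <- length(x)
    mu <- mean(x)
    num <- 0
    den <- 0
    for (ci in cls) {
        xi <- x[y == ci]
        Pi <- length(xi) / n
        mui <- mean(xi)
        vari <- mean((xi - mui)^2)  # population variance
        num <- num + Pi * (mui - mu)^2
        den <- den + Pi * vari
    }
    if (den == 0) {
        if (num == 0) 0 else Inf
    } else num / den
}

#' Rank symptoms for one syndrome by Fisher's score
#'
#' Scores every symptom of the cohort against the syndrome's 0/1 label and
#' ranks them in decreasing score order; ties are broken by ascending
#' catalog index so the ranking is deterministic.
#'
#' @param cohort a \linkS4class{SymptomCohort} (both label classes must be
#'   present for the syndrome).
#' @param syndrome syndrome id.
#' @return data.frame of class `FisherScoreTable` with columns `syndrome`,
#'   `rank`, `symptom_id`, `score`, one row per symptom, ordered by rank.
#' @seealso [topK()] to take the leading k symptoms.
#' @export
rankSymptoms <- function(cohort, syndrome) {
    stopifnot(is(cohort, "SymptomCohort"))
    syndrome <- match.arg(syndrome, syndromeIds(cohort))
    lab <- colData(cohort)[[syndrome]]
    g <- grades(cohort)
    scores <- vapply(rownames(g), function(s) fisherScore(g[s, ], lab),
                     numeric(1))
    ord <- order(-scores, seq_along(scores))
    out <- data.frame(syndrome = syndrome,
                      rank = seq_along(scores),
                      symptom_id = rownames(g)[ord],
                      score = scores[ord],
                      row.names = NULL)
    class(out) <- c("FisherScoreTable", class(out))
    out
}

#' Top-k symptoms of a Fisher-score ranking
#'
#' @param table a ranking from [rankSymptoms()].
#' @param k how many leading symptoms to keep (default 12, the brief
#'   per-syndrome representation used for symptom networks).
#' @return character vector of the first `k` symptom ids.
#' @export
topK <- function(table, k = 12L) {
    stopifnot(is.data.frame(table), "symptom_id" %in% colnames(table))
    if (k < 1L || k > nrow(table))
        stop("'k' must be between 1 and ", nrow(table))
    table$symptom_id[seq_len(k)]
}
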
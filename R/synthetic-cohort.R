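#' Specify one syndrome of a synthetic cohort
#'
#' @param syndrome syndrome id (BD, BS, FH, PH, QD, QS, YD).
#' @param prevalence marginal probability of the syndrome label, in (0,1)
#'   (before any co-occurrence tilt).
#' @param keySymptoms data.frame with columns `symptom_id`, `grade_shift`
#'   (non-negative integer <= 3): symptoms whose grade distribution is
#'   shifted upward among this syndrome's positives.
#' @param coupledPairs data.frame with columns `u`, `v`, `coupling`
#'   (probability): symptom pairs whose grades are forced equal with the
#'   given probability among this syndrome's positives. May have 0 rows.
#' @return a list of class `SyndromeSpec`.
#' @export
syndromeSpec <- function(syndrome, prevalence, keySymptoms,
                         coupledPairs = data.frame(u = character(),
                                                   v = character(),
                                                   coupling = numeric())) {
    syndrome <- match.arg(syndrome, .SYNDROME_IDS)
    stopifnot(is.numeric(prevalence), prevalence > 0, prevalence < 1)
    keySymptoms <- as.data.frame(keySymptoms)
    if (!nrow(keySymptoms))
        stop("keySymptoms must name at least one symptom")
    stopifnot(all(c("symptom_id", "grade_shift") %in% colnames(keySymptoms)),
              all(keySymptoms$symptom_id %in% .SYMPTOM_IDS),
              all(keySymptoms$grade_shift >= 0),
              all(keySymptoms$grade_shift <= 3))
    coupledPairs <- as.data.frame(coupledPairs)
    if (nrow(coupledPairs)) {
        stopifnot(all(c("u", "v", "coupling") %in% colnames(coupledPairs)),
                  all(coupledPairs$u %in% .SYMPTOM_IDS),
                  all(coupledPairs$v %in% .SYMPTOM_IDS),
                  all(coupledPairs$u != coupledPairs$v),
                  all(coupledPairs$coupling >= 0),
                  all(coupledPairs$coupling <= 1))
    }
    structure(list(syndrome = syndrome, prevalence = prevalence,
                   key_symptoms = keySymptoms, coupled_pairs = coupledPairs),
              class = "SyndromeSpec")
}

#' Specify a synthetic cohort
#'
#' @param nPatients number of patients.
#' @param baselineGradeProbs length-4 probability vector over grades 0..3
#'   for background (non-key) symptoms.
#' @param syndromes list of exactly 7 [syndromeSpec()]s covering the
#'   canonical syndrome ids.
#' @param cooccurrence data.frame with columns `s1`, `s2`, `multiplier`
#'   (>= 0): pairwise odds multipliers tilting the joint label
#'   distribution toward (multiplier > 1) or away from (< 1) co-occurrence.
#' @param femaleFraction probability that a patient is female.
#' @param seed default integer seed for [generateCohort()].
#' @return a list of class `CohortSpec`.
#' @seealso [defaultDepressionSpec()] for the depression study conditions.
#' @export
cohortSpec <- function(nPatients, baselineGradeProbs, syndromes,
                       cooccurrence = data.frame(s1 = character(),
                                                 s2 = character(),
                                                 multiplier = numeric()),
                       femaleFraction = 0.5, seed = 1L) {
    stopifnot(nPatients >= 1,
              length(baselineGradeProbs) == 4L,
              all(baselineGradeProbs >= 0),
              abs(sum(baselineGradeProbs) - 1) < 1e-9,
              femaleFraction >= 0, femaleFraction <= 1)
    ids <- vapply(syndromes, function(s) s$syndrome, character(1))
    if (!setequal(ids, .SYNDROME_IDS) || length(ids) != 7L)
        stop("'syndromes' must contain exactly one spec per canonical ",
             "syndrome (", paste(.SYNDROME_IDS, collapse = ", "), ")")
    names(syndromes) <- ids
    syndromes <- syndromes[.SYNDROME_IDS]
    cooccurrence <- as.data.frame(cooccurrence)
    if (nrow(cooccurrence))
        stopifnot(all(c("s1", "s2", "multiplier") %in% colnames(cooccurrence)),
                  all(cooccurrence$s1 %in% .SYNDROME_IDS),
                  all(cooccurrence$s2 %in% .SYNDROME_IDS),
                  all(cooccurrence$s1 != cooccurrence$s2),
                  all(cooccurrence$multiplier >= 0))
    structure(list(n_patients = as.integer(nPatients),
                   baseline_grade_probs = as.numeric(baselineGradeProbs),
                   syndromes = syndromes, cooccurrence = cooccurrence,
                   female_fraction = femaleFraction, seed = as.integer(seed)),
              class = "CohortSpec")
}

## Top-12 key symptoms per syndrome, in rank order, used by the default spec.
.DEFAULT_KEYS <- list(
    BD = c("PS10", "PS9", "PS11", "PS12", "PS27", "PS19",
           "PS18", "PS26", "PS25", "PS5", "PS13", "PS36"),
    BS = c("PS19", "PS22", "PS20", "PS28", "PS21", "PS16",
           "PS24", "PS11", "PS18", "PS26", "PS36", "PS9"),
    FH = c("PS36", "PS31", "PS35", "PS30", "PS34", "PS33",
           "PS32", "PS29", "PS4", "PS18", "PS9", "PS12"),
    PH = c("PS25", "PS26", "PS27", "PS24", "PS17", "PS19",
           "PS23", "PS5", "PS9", "PS36", "PS30", "PS11"),
    QD = c("PS5", "PS6", "PS8", "PS15", "PS14", "PS7",
           "PS27", "PS25", "PS26", "PS17", "PS10", "PS4"),
    QS = c("PS15", "PS14", "PS17", "PS18", "PS27", "PS16",
           "PS6", "PS10", "PS30", "PS5", "PS9", "PS4"),
    YD = c("PS2", "PS3", "PS4", "PS1", "PS7", "PS30",
           "PS10", "PS29", "PS25", "PS5", "PS15", "PS11"))

## Clinically plausible coupled symptom pairs, one per syndrome, drawn from
## that syndrome's key set (e.g. the two dizziness items, the two
## epigastric-obstruction items).
.DEFAULT_COUPLES <- list(
    BD = c("PS25", "PS26"), BS = c("PS19", "PS20"), FH = c("PS31", "PS34"),
    PH = c("PS25", "PS26"), QD = c("PS5", "PS8"), QS = c("PS17", "PS18"),
    YD = c("PS2", "PS3"))

#' Default synthetic depression cohort specification
#'
#' Encodes the study conditions the analysis assumes: 364 patients; Qi
#' stagnation (QS), Qi deficiency (QD) and fire hot (FH) the most prevalent
#' of the 7 syndromes, blood stasis (BS) the rarest; QS-QD and FH-QS
#' labels tilted toward co-occurrence (with milder tilts among the
#' BD/PH/QD cluster); each syndrome's 12 key symptoms taken from its
#' clinical ranking, the top 6 with grade shift 2 and the rest with shift
#' 1; one clinically coupled symptom pair per syndrome at coupling 0.8;
#' 70% female patients (depression inquiry cohorts skew female), with the
#' two menses symptoms zeroed for males.
#'
#' @return a `CohortSpec` ready for [generateCohort()].
#' @examples
#' spec <- defaultDepressionSpec()
#' spec$n_patients
#' @export
defaultDepressionSpec <- function() {
    prev <- c(BD = 0.28, BS = 0.12, FH = 0.48, PH = 0.33,
              QD = 0.55, QS = 0.62, YD = 0.25)
    syn <- lapply(.SYNDROME_IDS, function(s) {
        keys <- .DEFAULT_KEYS[[s]]
        syndromeSpec(s, prev[[s]],
            keySymptoms = data.frame(symptom_id = keys,
                                     grade_shift = rep(c(2L, 1L), each = 6L)),
            coupledPairs = data.frame(u = .DEFAULT_COUPLES[[s]][1L],
                                      v = .DEFAULT_COUPLES[[s]][2L],
                                      coupling = 0.8))
    })
    cooc <- data.frame(
        s1 = c("QS", "FH", "BD", "PH", "BD"),
        s2 = c("QD", "QS", "QD", "QD", "PH"),
        multiplier = c(4, 4, 2, 2, 2))
    cohortSpec(nPatients = 364L,
               baselineGradeProbs = c(0.45, 0.30, 0.17, 0.08),
               syndromes = syn, cooccurrence = cooc,
               femaleFraction = 0.7, seed = 1L)
}

## Gibbs sampling of the 0/1 label matrix under pairwise odds multipliers:
## P(L_s = 1 | rest) has odds  b_s * prod_t mult(s,t)^L_t.  Positive
## multipliers would inflate the marginals away from the requested
## prevalences, so the base odds b_s are calibrated by a short damped
## fixed-point iteration until the empirical marginals match.
.sampleLabels <- function(spec, n, sweeps = 20L, calibration = 6L) {
    prev <- vapply(spec$syndromes, function(s) s$prevalence, numeric(1))
    L <- matrix(rbinom(n * 7L, 1L, rep(prev, each = n)), n, 7L,
                dimnames = list(NULL, .SYNDROME_IDS))
    co <- spec$cooccurrence
    if (!nrow(co)) return(L)
    logm <- matrix(0, 7L, 7L, dimnames = list(.SYNDROME_IDS, .SYNDROME_IDS))
    for (i in seq_len(nrow(co))) {
        if (co$multiplier[i] <= 0)
            stop("zero co-occurrence multipliers are not supported by the ",
                 "Gibbs label sampler")
        logm[co$s1[i], co$s2[i]] <- logm[co$s1[i], co$s2[i]] + log(co$multiplier[i])
        logm[co$s2[i], co$s1[i]] <- logm[co$s2[i], co$s1[i]] + log(co$multiplier[i])
    }
    target <- log(prev / (1 - prev))
    logodds0 <- target
    gibbs <- function(L, logodds0) {
        for (sweep in seq_len(sweeps)) {
            for (s in seq_len(7L)) {
                lo <- logodds0[s] + L %*% logm[, s]
                p <- 1 / (1 + exp(-lo))
                L[, s] <- as.integer(runif(n) < p)
            }
        }
        L
    }
    for (round in seq_len(calibration)) {
        L <- gibbs(L, logodds0)
        emp <- pmin(pmax(colMeans(L), 1 / (n + 1)), n / (n + 1))
        logodds0 <- logodds0 - 0.8 * (log(emp / (1 - emp)) - target)
    }
    gibbs(L, logodds0)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws syndrome labels first (independent Bernoulli prevalences, tilted
#' by pairwise co-occurrence odds multipliers through a fixed-burn-in Gibbs
#' sweep over the 7-label vector), then grades: background symptoms i.i.d.
#' from the baseline grade distribution; for each active syndrome its key
#' symptoms are shifted upward by `grade_shift` (grade + shift, clipped at
#' 3; the largest shift wins when key sets overlap); each coupled pair is
#' forced equal with its coupling probability among that syndrome's
#' positives; finally the female-only symptoms are zeroed for male
#' patients. Everything is deterministic for a fixed seed.
#'
#' The planted truth (key symptoms and coupled pairs per syndrome) is kept
#' in `metadata(cohort)$truth` for recovery tests.
#'
#' @param spec a [cohortSpec()].
#' @param seed integer seed; defaults to the seed recorded in `spec`.
#' @return a \linkS4class{SymptomCohort}.
#' @examples
#' co <- generateCohort(defaultDepressionSpec(), seed = 7)
#' co
#' @export
generateCohort <- function(spec, seed = spec$seed) {
    if (!inherits(spec, "CohortSpec"))
        stop("'spec' must be a CohortSpec (see cohortSpec())")
    set.seed(as.integer(seed))
    n <- spec$n_patients
    L <- .sampleLabels(spec, n)

    ## per-patient, per-symptom upward shift: max over active syndromes
    shift <- matrix(0L, n, 36L, dimnames = list(NULL, .SYMPTOM_IDS))
    for (s in .SYNDROME_IDS) {
        pos <- L[, s] == 1L
        if (!any(pos)) next
        ks <- spec$syndromes[[s]]$key_symptoms
        for (i in seq_len(nrow(ks))) {
            j <- ks$symptom_id[i]
            shift[pos, j] <- pmax(shift[pos, j], as.integer(ks$grade_shift[i]))
        }
    }
    base <- sample(0:3, n * 36L, replace = TRUE,
                   prob = spec$baseline_grade_probs)
    g <- matrix(as.integer(base), n, 36L, dimnames = list(NULL, .SYMPTOM_IDS))
    g <- pmin(g + shift, 3L)

    for (s in .SYNDROME_IDS) {
        cp <- spec$syndromes[[s]]$coupled_pairs
        if (!nrow(cp)) next
        pos <- which(L[, s] == 1L)
        for (i in seq_len(nrow(cp))) {
            hit <- pos[runif(length(pos)) < cp$coupling[i]]
            g[hit, cp$v[i]] <- g[hit, cp$u[i]]
        }
    }

    sex <- ifelse(runif(n) < spec$female_fraction, "female", "male")
    g[sex == "male", .FEMALE_ONLY] <- 0L

    cohort <- SymptomCohort(grades = g, labels = L, sex = sex)
    S4Vectors::metadata(cohort)$truth <- list(
        key_symptoms = lapply(spec$syndromes, `[[`, "key_symptoms"),
        coupled_pairs = lapply(spec$syndromes, `[[`, "coupled_pairs"),
        seed = as.integer(seed))
    cohort
}

#' Serialize / deserialize a CohortSpec as YAML
#'
#' @param spec a [cohortSpec()].
#' @param path file path.
#' @return `readCohortSpec`: a `CohortSpec`; `writeCohortSpec`: `path`,
#'   invisibly.
#' @export
writeCohortSpec <- function(spec, path) {
    stopifnot(inherits(spec, "CohortSpec"))
    x <- list(n_patients = spec$n_patients,
              baseline_grade_probs = spec$baseline_grade_probs,
              female_fraction = spec$female_fraction,
              seed = spec$seed,
              cooccurrence = lapply(seq_len(nrow(spec$cooccurrence)),
                  function(i) as.list(spec$cooccurrence[i, ])),
              syndromes = lapply(spec$syndromes, function(s) list(
                  syndrome = s$syndrome, prevalence = s$prevalence,
                  key_symptoms = lapply(seq_len(nrow(s$key_symptoms)),
                      function(i) as.list(s$key_symptoms[i, ])),
                  coupled_pairs = lapply(seq_len(nrow(s$coupled_pairs)),
                      function(i) as.list(s$coupled_pairs[i, ])))))
    yaml::write_yaml(x, path)
    invisible(path)
}

#' @rdname writeCohortSpec
#' @export
readCohortSpec <- function(path) {
    x <- yaml::read_yaml(path)
    bindRows <- function(lst, cols) {
        if (!length(lst)) {
            out <- lapply(cols, function(.) character())
            names(out) <- cols
            return(as.data.frame(out))
        }
        do.call(rbind, lapply(lst, function(r) as.data.frame(r[cols])))
    }
    syn <- lapply(x$syndromes, function(s)
        syndromeSpec(s$syndrome, s$prevalence,
                     keySymptoms = bindRows(s$key_symptoms,
                                            c("symptom_id", "grade_shift")),
                     coupledPairs = bindRows(s$coupled_pairs,
                                             c("u", "v", "coupling"))))
    cohortSpec(nPatients = x$n_patients,
               baselineGradeProbs = x$baseline_grade_probs,
               syndromes = syn,
               cooccurrence = bindRows(x$cooccurrence,
                                       c("s1", "s2", "multiplier")),
               femaleFraction = x$female_fraction, seed = x$seed)
}
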
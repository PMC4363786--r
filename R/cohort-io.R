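#' The 36-symptom inquiry catalog
#'
#' Returns the fixed catalog of the 36 depression inquiry symptoms: id
#' (PS1..PS36), a free-text description, and whether the symptom is
#' female-only (TRUE exactly for the two menses items PS13 and PS22).
#'
#' @return data.frame with columns `symptom_id`, `description`,
#'   `female_only`, one row per symptom in catalog order.
#' @examples
#' cat36 <- symptomCatalog()
#' cat36$symptom_id[cat36$female_only]
#' @export
symptomCatalog <- function() {
    path <- system.file("extdata", "symptom_catalog.tsv", package = "zhengnet",
                        mustWork = TRUE)
    cat36 <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(identical(cat36$symptom_id, .SYMPTOM_IDS))
    cat36
}

#' Construct a SymptomCohort from patient-per-row tables
#'
#' @param grades matrix or data.frame, one row per patient and 36 columns of
#'   integer risk degrees in 0..3. Columns may be named PS1..PS36 (any
#'   order) or unnamed in catalog order.
#' @param labels matrix or data.frame, one row per patient and one 0/1
#'   column per syndrome (BD, BS, FH, PH, QD, QS, YD).
#' @param sex optional character vector ("female"/"male"/"unknown");
#'   defaults to "unknown", in which case the female-only zero constraint
#'   is not enforced.
#' @param patientId optional character vector of unique patient ids;
#'   defaults to P1..Pn.
#' @return a validated \linkS4class{SymptomCohort}.
#' @examples
#' g <- matrix(sample(0:3, 5 * 36, TRUE), 5, 36)
#' l <- matrix(rbinom(5 * 7, 1, 0.4), 5, 7)
#' SymptomCohort(g, l)
#' @export
SymptomCohort <- function(grades, labels, sex = NULL, patientId = NULL) {
    grades <- as.matrix(grades)
    if (ncol(grades) != 36L)
        stop("'grades' must have 36 columns, got ", ncol(grades))
    if (!is.null(colnames(grades))) {
        miss <- setdiff(.SYMPTOM_IDS, colnames(grades))
        if (length(miss))
            stop("'grades' misses symptom column(s): ",
                 paste(miss, collapse = ", "))
        grades <- grades[, .SYMPTOM_IDS, drop = FALSE]
    } else colnames(grades) <- .SYMPTOM_IDS
    labels <- as.matrix(labels)
    if (is.null(colnames(labels))) {
        if (ncol(labels) != 7L)
            stop("'labels' must have 7 columns, got ", ncol(labels))
        colnames(labels) <- .SYNDROME_IDS
    }
    miss <- setdiff(.SYNDROME_IDS, colnames(labels))
    if (length(miss))
        stop("'labels' misses syndrome column(s): ",
             paste(miss, collapse = ", "))
    labels <- labels[, .SYNDROME_IDS, drop = FALSE]
    n <- nrow(grades)
    if (n < 1L) stop("a cohort needs at least one patient record")
    if (nrow(labels) != n)
        stop("'grades' and 'labels' disagree on the number of patients")
    if (is.null(sex)) sex <- rep("unknown", n)
    if (is.null(patientId)) patientId <- paste0("P", seq_len(n))
    storage.mode(grades) <- "integer"
    storage.mode(labels) <- "integer"
    cat36 <- symptomCatalog()
    cd <- S4Vectors::DataFrame(patient_id = as.character(patientId),
                               sex = as.character(sex), labels,
                               row.names = as.character(patientId))
    se <- SummarizedExperiment(
        assays = list(grades = t(grades)),
        rowData = S4Vectors::DataFrame(cat36[, c("description", "female_only")],
                                       row.names = cat36$symptom_id),
        colData = cd)
    new("SymptomCohort", se)
}

.detectSep <- function(path, delim = NULL) {
    if (!is.null(delim)) return(delim)
    if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read / write a cohort as delimited text
#'
#' The on-disk format is one row per patient with header
#' `patient_id[,sex],PS1..PS36,BD,BS,FH,PH,QD,QS,YD`; grades and labels are
#' bare integers. The delimiter is taken from the file extension (`.tsv`
#' tab, otherwise comma) unless `delim` is given. `writeCohort` emits the
#' canonical column order and `readCohort` inverts it exactly
#' (read-after-write is the identity).
#'
#' @param path file path.
#' @param delim field delimiter; `NULL` to auto-detect from the extension.
#' @return `readCohort`: a validated \linkS4class{SymptomCohort};
#'   `writeCohort`: `path`, invisibly.
#' @examples
#' g <- matrix(sample(0:3, 3 * 36, TRUE), 3, 36)
#' l <- matrix(rbinom(3 * 7, 1, 0.5), 3, 7)
#' co <- SymptomCohort(g, l)
#' f <- tempfile(fileext = ".csv")
#' writeCohort(co, f)
#' identical(grades(readCohort(f)), grades(co))
#' @export
readCohort <- function(path, delim = NULL) {
    if (!file.exists(path)) stop("cohort file not found: ", path)
    sep <- .detectSep(path, delim)
    df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                     check.names = FALSE)
    need <- c("patient_id", .SYMPTOM_IDS, .SYNDROME_IDS)
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("cohort file schema error, missing column(s): ",
             paste(miss, collapse = ", "))
    for (col in .SYMPTOM_IDS) {
        bad <- which(!(df[[col]] %in% .GRADES))
        if (length(bad))
            stop("invalid grade in column ", col, ", row ", bad[1L], ": ",
                 df[[col]][bad[1L]], " (grades must be 0, 1, 2 or 3)")
    }
    for (col in .SYNDROME_IDS) {
        bad <- which(!(df[[col]] %in% c(0L, 1L)))
        if (length(bad))
            stop("invalid label in column ", col, ", row ", bad[1L], ": ",
                 df[[col]][bad[1L]], " (labels must be 0 or 1)")
    }
    sex <- if ("sex" %in% colnames(df)) df$sex else NULL
    SymptomCohort(grades = df[, .SYMPTOM_IDS], labels = df[, .SYNDROME_IDS],
                  sex = sex, patientId = df$patient_id)
}

#' @rdname readCohort
#' @param cohort a \linkS4class{SymptomCohort}.
#' @export
writeCohort <- function(cohort, path, delim = NULL) {
    stopifnot(is(cohort, "SymptomCohort"))
    sep <- .detectSep(path, delim)
    cd <- colData(cohort)
    df <- data.frame(patient_id = cd$patient_id, sex = cd$sex,
                     t(grades(cohort)),
                     as.data.frame(cd[, .SYNDROME_IDS, drop = FALSE]),
                     check.names = FALSE, row.names = NULL)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}
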
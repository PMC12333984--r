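#' Read a wide-format Ct table
#'
#' Reads a CSV/TSV table with samples in rows and miRNA assays in columns
#' (first column \code{sample_id}). Blank cells, the token
#' \code{"Undetermined"} and Ct values at or above the 40-cycle run ceiling
#' are parsed as missing. Sample metadata is read from a companion table or
#' supplied directly.
#'
#' @param path CSV or TSV file (delimiter sniffed from the extension / first
#'   line); samples in rows, first column \code{sample_id}
#' @param sampleData data.frame of sample metadata with a \code{sample_id}
#'   column, or a path to a CSV holding one; when \code{NULL} minimal
#'   metadata with \code{NA} entries is created
#' @param controls named list mapping roles (\code{reference},
#'   \code{hemolysis}, \code{spikein}) to assay names; roles absent from the
#'   table are flagged in \code{metadata(x)$controls_absent} and downstream
#'   QC degrades gracefully
#' @param ceiling Ct values at or above this are sentinel "no detection"
#'   readings and parsed as missing (default 40, the run length)
#' @return a \linkS4class{CtExperiment}; the number of sentinel cells parsed
#'   as missing is recorded in \code{metadata(x)$parse_log}
#' @export
readCtTable <- function(path, sampleData = NULL,
                        controls = list(reference = "miR-23a-3p",
                                        hemolysis = "miR-451a",
                                        spikein   = "cel-miR-39"),
                        ceiling = 40) {
    raw <- .readDelim(path)
    if (anyDuplicated(raw[[1L]]))
        stop("duplicate sample identifiers in ", path)
    if (anyDuplicated(names(raw)[-1L]))
        stop("duplicate assay identifiers in ", path)
    ids <- as.character(raw[[1L]])
    vals <- raw[-1L]
    n_sentinel <- 0L
    for (j in seq_along(vals)) {
        v <- vals[[j]]
        if (is.character(v)) {
            v <- trimws(v)
            v[v %in% c("", "NA")] <- NA
            und <- !is.na(v) & tolower(v) == "undetermined"
            n_sentinel <- n_sentinel + sum(und)
            v[und] <- NA
            suppressWarnings(num <- as.numeric(v))
            bad <- !is.na(v) & is.na(num)
            if (any(bad))
                stop(sprintf("non-numeric Ct at row %s, column '%s': '%s'",
                             paste(ids[which(bad)], collapse = ","),
                             names(vals)[j], v[which(bad)[1L]]))
            v <- num
        }
        hi <- !is.na(v) & v >= ceiling
        n_sentinel <- n_sentinel + sum(hi)
        v[hi] <- NA
        vals[[j]] <- v
    }
    ct <- t(as.matrix(as.data.frame(vals, check.names = FALSE)))
    colnames(ct) <- ids
    if (is.character(sampleData) && length(sampleData) == 1L)
        sampleData <- utils::read.csv(sampleData, check.names = FALSE)
    if (is.null(sampleData)) {
        sampleData <- data.frame(sample_id = ids, cohort = NA_character_,
                                 timepoint = NA_character_,
                                 dose_gy = NA_real_)
    } else {
        sampleData <- as.data.frame(sampleData)
        if (!"sample_id" %in% names(sampleData))
            stop("sampleData needs a 'sample_id' column")
        m <- match(ids, sampleData$sample_id)
        if (anyNA(m))
            stop("samples without metadata: ",
                 paste(ids[is.na(m)], collapse = ", "))
        sampleData <- sampleData[m, , drop = FALSE]
    }
    x <- ctExperiment(ct, sampleData, controls = controls)
    metadata(x)$parse_log <- list(n_sentinel_missing = n_sentinel,
                                  source = path)
    x
}

.readDelim <- function(path) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      colClasses = "character", na.strings = NULL,
                      quote = "\"", comment.char = "")
}

#' Write a CtExperiment to CSV
#'
#' Writes the Ct matrix (samples in rows, assays in columns, first column
#' \code{sample_id}) and, optionally, the sample metadata. Missing Ct values
#' are written as empty cells; a \code{\link{readCtTable}} round trip
#' preserves values, missingness and metadata.
#'
#' @param x a \linkS4class{CtExperiment}
#' @param path output CSV for the Ct table
#' @param metaPath optional output CSV for the sample metadata
#' @return \code{path}, invisibly
#' @export
writeCtTable <- function(x, path, metaPath = NULL) {
    ct <- t(ctValues(x))
    df <- data.frame(sample_id = rownames(ct), ct, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    if (!is.null(metaPath)) {
        md <- as.data.frame(colData(x))
        md <- data.frame(sample_id = colnames(x), md, check.names = FALSE)
        utils::write.csv(md, metaPath, row.names = FALSE, na = "")
    }
    invisible(path)
}

#' Read a clinical table
#'
#' One sample per row; a \code{sample_id} column plus numeric clinical
#' fields (CBC, CRP, TEWL difference, perfusion ratio, injury score).
#'
#' @param path CSV file
#' @return data.frame with validated fields
#' @export
readClinicalTable <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    if (!"sample_id" %in% names(df))
        stop("clinical table needs a 'sample_id' column")
    if ("perfusion_ratio" %in% names(df)) {
        pr <- df$perfusion_ratio
        if (any(!is.na(pr) & pr <= 0))
            stop("perfusion_ratio must be > 0 where present")
    }
    df
}

#' Write the selected-signature report
#'
#' One row per selected feature per component with its stability score and
#' loading, ordered deterministically: component ascending, stability
#' descending, name ascending. Writing the same model twice produces
#' byte-identical files.
#'
#' @param model a fitted \linkS4class{SplsdaModel} with stability scores
#' @param path output CSV
#' @return \code{path}, invisibly
#' @export
writeSignatureReport <- function(model, path) {
    if (!is(model, "SplsdaModel") || !length(model@loadings))
        stop("a fitted SplsdaModel is required")
    sig <- model@signature
    if (!nrow(sig)) {
        cols <- c("component", "miRNA", "stability", "loading")
        utils::write.csv(
            stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 4)), cols),
            path, row.names = FALSE)
        return(invisible(path))
    }
    ord <- order(sig$component, -sig$stability, sig$miRNA)
    sig <- sig[ord, , drop = FALSE]
    utils::write.csv(sig, path, row.names = FALSE, na = "")
    invisible(path)
}

#' Write a QC report
#'
#' Per-sample and per-assay sections as CSV plus a JSON summary.
#'
#' @param x a \linkS4class{QCReport}
#' @param prefix path prefix; writes \code{<prefix>_samples.csv},
#'   \code{<prefix>_assays.csv} and \code{<prefix>_summary.json}
#' @return character vector of the files written, invisibly
#' @export
writeQCReport <- function(x, prefix) {
    stopifnot(is(x, "QCReport"))
    fs <- paste0(prefix, c("_samples.csv", "_assays.csv", "_summary.json"))
    utils::write.csv(x@sampleQC, fs[1], row.names = FALSE, na = "")
    utils::write.csv(x@assayQC, fs[2], row.names = FALSE, na = "")
    jsonlite::write_json(list(
        n_discarded_high_ct = x@nDiscardedHighCt,
        ct_limit = x@ctLimit,
        n_samples_excluded = sum(x@sampleQC$excluded, na.rm = TRUE),
        n_assays_retained = sum(x@assayQC$retained)),
        fs[3], auto_unbox = TRUE, digits = NA)
    invisible(fs)
}
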
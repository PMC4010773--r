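#' Read a plain-text EEG sample matrix
#'
#' The ASCII interchange format is a tab-separated table of samples x channels
#' with a single header row of channel labels -- the format clinical review
#' software commonly exports epochs to.
#'
#' @param path File to read.
#' @param fs Sampling rate in Hz (the format does not carry it).
#' @return An [eeg_record()].
#' @seealso [write_ascii_eeg()]
#' @export
read_ascii_eeg <- function(path, fs) {
  if (!file.exists(path)) stop("no such EEG file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (!ncol(tab)) stop("empty EEG file: ", path)
  m <- t(as.matrix(tab))
  eeg_record(m, colnames(tab), fs)
}

#' Write a record as a plain-text sample matrix
#'
#' @param record An [eeg_record()].
#' @param path Destination file.
#' @param digits Decimal places written (default 6; microvolt-scale signals
#'   lose nothing of analytic relevance).
#' @return `path`, invisibly.
#' @export
write_ascii_eeg <- function(record, path, digits = 6L) {
  stopifnot(inherits(record, "eeg_record"))
  tab <- as.data.frame(round(t(record$data), digits))
  names(tab) <- record$labels
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with columns `subject_id`, `group` (patient/control),
#' `condition` (routine/sleep_deprived), `file` (path to the ASCII sample
#' matrix, relative to the manifest's directory) and `added_value` (logical;
#' whether the sleep-deprived recording contributed new diagnostic
#' information -- consumed only as a subset flag).
#'
#' @param path Manifest CSV.
#' @return A data.frame with the columns above and `file` resolved to paths
#'   relative to the manifest location.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "condition", "file", "added_value")
  missing <- setdiff(need, names(man))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  man$group <- match_levels(man$group, c("patient", "control"), "group")
  man$condition <- match_levels(man$condition, c("routine", "sleep_deprived"),
                                "condition")
  man$added_value <- as.logical(man$added_value)
  man$file <- file.path(dirname(path), man$file)
  bad <- !file.exists(man$file)
  if (any(bad))
    stop("manifest references missing file(s) for subject(s): ",
         paste(unique(man$subject_id[bad]), collapse = ", "))
  # every subject must appear under both conditions exactly once
  tabs <- table(man$subject_id, man$condition)
  if (any(tabs != 1L))
    stop("every subject needs exactly one record per condition; offending: ",
         paste(rownames(tabs)[apply(tabs != 1L, 1L, any)], collapse = ", "))
  man
}

match_levels <- function(x, levels, what) {
  x <- as.character(x)
  bad <- !(x %in% levels)
  if (any(bad))
    stop("invalid ", what, " value(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected ", paste(levels, collapse = "/"), ")")
  x
}
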
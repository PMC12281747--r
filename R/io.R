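#' Read a taxa-by-samples count table
#'
#' Reads a count matrix with taxa as rows and samples as columns.  The TSV
#' dialect is the common OTU-table export: first column taxon identifiers,
#' header row of sample identifiers, integer cells.  BIOM (JSON, format 1.0)
#' tables are supported read-only via the biomformat package.
#'
#' @param path Path to the file.
#' @param format Either `"tsv"` (default) or `"biom"`.
#' @return An integer matrix (taxa x samples) with unique row and column
#'   names, validated by [validate_counts()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("taxon\ts1\ts2", "otu1\t0\t5", "otu2\t2\t0"), tf)
#' read_count_table(tf)
#' @export
read_count_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("count table file does not exist: ", path)
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM tables requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    storage.mode(m) <- "double"
    return(validate_counts(m))
  }
  if (file.size(path) == 0L) {
    stop("count table format error: file is empty")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("count table format error: need a taxon-id column plus >=1 sample")
  }
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(m, 2L, function(col) {
      suppressWarnings(!anyNA(as.numeric(col)) | all(is.na(col)))
    }))
    stop("count table validation error: non-numeric cells in column(s) ",
         paste(colnames(m)[bad], collapse = ", "))
  }
  rownames(m) <- ids
  validate_counts(m)
}

#' Validate a count matrix
#'
#' Checks the invariants of the count-table data model: a numeric matrix of
#' non-negative integers with unique, non-empty taxon (row) and sample
#' (column) identifiers.
#'
#' @param counts A matrix, taxa in rows and samples in columns.
#' @return The validated matrix (invisibly identical to the input).
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("count table validation error: counts must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count table validation error: taxon and sample ids are required")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("count table format error: duplicate taxon ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("count table format error: duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  }
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop("count table validation error: negative, missing or non-integer ",
         "count at taxon '", rownames(counts)[bad[1L, 1L]], "', sample '",
         colnames(counts)[bad[1L, 2L]], "'")
  }
  counts
}

#' Read a sample metadata table
#'
#' Reads the sample design frame: columns `sample_id`, `subject_id`, `group`
#' and (optionally) `occasion`.  A missing `occasion` column yields a
#' single-occasion (cross-sectional) design.  Factor levels are recorded in
#' first-appearance order unless a reference level is supplied.
#'
#' @param path Path to a TSV file.
#' @param counts Optional count matrix; if given, the metadata are validated
#'   against it with [validate_metadata()].
#' @param group_ref,occasion_ref Optional reference levels for the group and
#'   occasion factors.
#' @return A data.frame with columns `sample_id`, `subject_id`, `group`
#'   (factor) and `occasion` (ordered-coded factor).
#' @export
read_metadata <- function(path, counts = NULL, group_ref = NULL,
                          occasion_ref = NULL) {
  if (!file.exists(path)) stop("metadata file does not exist: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  as_sample_frame(df, counts = counts, group_ref = group_ref,
                  occasion_ref = occasion_ref)
}

#' Build and validate a sample frame
#'
#' @param df A data.frame with columns `sample_id`, `subject_id`, `group`,
#'   and optionally `occasion`.
#' @inheritParams read_metadata
#' @return A validated sample frame (see [read_metadata()]).
#' @export
as_sample_frame <- function(df, counts = NULL, group_ref = NULL,
                            occasion_ref = NULL) {
  need <- c("sample_id", "subject_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("metadata validation error: missing column(s) ",
         paste(miss, collapse = ", "))
  }
  out <- data.frame(
    sample_id  = as.character(df$sample_id),
    subject_id = as.character(df$subject_id),
    stringsAsFactors = FALSE
  )
  g <- as.character(df$group)
  glev <- unique(g)
  if (!is.null(group_ref)) {
    if (!group_ref %in% glev) {
      stop("metadata validation error: group reference level '", group_ref,
           "' not present")
    }
    glev <- c(group_ref, setdiff(glev, group_ref))
  }
  out$group <- factor(g, levels = glev)
  if ("occasion" %in% names(df)) {
    o <- as.character(df$occasion)
    # earliest occasion is the baseline: sort levels, numerically when possible
    olev <- unique(o)
    onum <- suppressWarnings(as.numeric(olev))
    olev <- if (!anyNA(onum)) olev[order(onum)] else sort(olev)
    if (!is.null(occasion_ref)) {
      olev <- c(occasion_ref, setdiff(olev, occasion_ref))
    }
    out$occasion <- factor(o, levels = olev)
  } else {
    out$occasion <- factor(rep("1", nrow(out)))
  }
  validate_metadata(out, counts)
}

#' Validate sample metadata against a count table
#'
#' Enforces the sample-frame invariants: every count-table sample appears
#' exactly once, each (subject, occasion) pair appears at most once, and
#' group is constant within subject.
#'
#' @param meta A sample frame as returned by [as_sample_frame()].
#' @param counts Optional count matrix to cross-validate sample ids.
#' @return The validated sample frame.
#' @export
validate_metadata <- function(meta, counts = NULL) {
  if (anyDuplicated(meta$sample_id)) {
    stop("metadata validation error: duplicate sample_id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  }
  key <- paste(meta$subject_id, meta$occasion, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- meta$subject_id[duplicated(key)][1L]
    stop("metadata validation error: subject '", dup,
         "' observed more than once at the same occasion")
  }
  gps <- tapply(as.character(meta$group), meta$subject_id,
                function(x) length(unique(x)))
  if (any(gps > 1L)) {
    stop("metadata validation error: subject(s) assigned to multiple ",
         "groups: ", paste(names(gps)[gps > 1L], collapse = ", "))
  }
  if (!is.null(counts)) {
    missing_meta <- setdiff(colnames(counts), meta$sample_id)
    if (length(missing_meta)) {
      stop("metadata validation error: sample(s) in counts missing from ",
           "metadata: ", paste(missing_meta, collapse = ", "))
    }
  }
  meta
}

#' Write a count table as TSV
#'
#' Inverse of [read_count_table()]; integer values round-trip bit-exactly.
#'
#' @param counts Count matrix (taxa x samples).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(taxon = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal TSV writer for result tables (10 significant digits for floats)
write_result_table <- function(df, path) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x) signif(x, 10L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
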
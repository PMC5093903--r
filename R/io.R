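#' Canonical developmental time points
#'
#' The eight postnatal time points of the two-population mammary time course,
#' in developmental order: nulliparous week 10 (W10), pregnancy days 3.5 and
#' 14.5 (P3.5, P14.5), lactation days 3 and 10 (L3, L10), involution day 2 and
#' week 4 (Id2, Iw4), and the 4-month parous gland (M4).
#'
#' @return Character vector of the eight canonical time-point labels, ordered.
#' @export
time_points <- function() {
  c("W10", "P3.5", "P14.5", "L3", "L10", "Id2", "Iw4", "M4")
}

#' Population labels
#' @return Character vector `c("luminal", "basal")`.
#' @export
populations <- function() c("luminal", "basal")

#' Default stage groupings of time points
#'
#' Stages pool developmentally related time points: lactogenesis spans late
#' pregnancy through lactation; lact-invo spans lactation into early
#' involution; lacto-invo covers both; NP (non-pregnant) and P (pregnancy)
#' cover the remaining figure abbreviations. Memberships are overridable in
#' every function that accepts a `stages` argument.
#'
#' @return Named list mapping stage name to a character vector of time points.
#' @export
default_stages <- function() {
  list(
    lactogenesis = c("P14.5", "L3", "L10"),
    `lact-invo`  = c("L3", "L10", "Id2"),
    `lacto-invo` = c("P14.5", "L3", "L10", "Id2"),
    NP           = c("W10", "M4"),
    P            = c("P3.5", "P14.5")
  )
}

check_stages <- function(stages) {
  stopifnot(is.list(stages), length(names(stages)) == length(stages))
  for (nm in names(stages)) {
    bad <- setdiff(stages[[nm]], time_points())
    if (length(bad) > 0)
      stop("stage '", nm, "' contains unknown time points: ",
           paste(bad, collapse = ", "))
  }
  stages
}

# Map loosely styled labels ("id2", " L3 ", "Involution day 2") onto the
# canonical eight tokens; unknown labels pass through for the caller to reject.
normalize_time_point <- function(x) {
  x <- trimws(as.character(x))
  canon <- time_points()
  idx <- match(toupper(x), toupper(canon))
  alias <- c(
    "involution day 2"  = "Id2",
    "involution week 4" = "Iw4",
    "week 10"           = "W10",
    "month 4"           = "M4"
  )
  a <- match(tolower(x), names(alias))
  out <- ifelse(!is.na(idx), canon[idx],
                ifelse(!is.na(a), alias[a], x))
  unname(out)
}

#' Validate a count matrix
#'
#' @param counts Numeric matrix, genes as rows, samples as columns, with
#'   unique non-empty `rownames` (gene ids) and `colnames` (sample ids).
#' @return The matrix, invisibly, after validation.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids in counts")
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts contain negative values")
  invisible(counts)
}

#' Read a gene-by-sample count matrix
#'
#' TSV layout: header row of sample ids, first column of gene ids. MTX layout:
#' MatrixMarket file with sidecar `genes.txt` and `samples.txt` (one id per
#' line) in the same directory.
#'
#' @param path Path to the counts TSV or MTX file.
#' @param format `"tsv"` (default) or `"mtx"`.
#' @return Validated numeric matrix (genes x samples).
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("counts file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = NA)
    if (ncol(tab) < 2) stop("counts TSV needs a gene-id column plus samples")
    ids <- as.character(tab[[1]])
    if (anyDuplicated(ids)) stop("duplicate gene ids in counts")
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric count entries")
    rownames(m) <- ids
  } else {
    mm <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    gpath <- file.path(dir, "genes.txt")
    spath <- file.path(dir, "samples.txt")
    if (!file.exists(gpath) || !file.exists(spath))
      stop("MTX counts require sidecar genes.txt and samples.txt")
    rownames(mm) <- readLines(gpath)
    colnames(mm) <- readLines(spath)
    m <- mm
  }
  storage.mode(m) <- "double"
  validate_counts(m)
  m
}

#' Write a count matrix
#'
#' @param counts Validated count matrix.
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"` (writes sidecar genes.txt/samples.txt).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  validate_counts(counts)
  if (format == "tsv") {
    tab <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(rownames(counts), file.path(dir, "genes.txt"))
    writeLines(colnames(counts), file.path(dir, "samples.txt"))
  }
  invisible(path)
}

#' Validate sample metadata, optionally against a count matrix
#'
#' Metadata is a data.frame with columns `sample`, `population`, `time_point`,
#' `replicate` and any number of categorical technical covariates (`batch`,
#' `lane`, `rna_amp_batch`, `sorting_time`, ...). Time points are normalised
#' to the canonical eight tokens; unknown labels are rejected.
#'
#' @param meta Data frame of per-sample metadata.
#' @param counts Optional count matrix; sample ids must match bijectively.
#' @return The validated (normalised) metadata, rows ordered as in `counts`
#'   when supplied.
#' @export
validate_metadata <- function(meta, counts = NULL) {
  req <- c("sample", "population", "time_point", "replicate")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols) > 0)
    stop("metadata missing required columns: ",
         paste(missing_cols, collapse = ", "))
  meta$sample <- as.character(meta$sample)
  if (anyDuplicated(meta$sample)) stop("duplicate sample ids in metadata")
  meta$population <- tolower(trimws(as.character(meta$population)))
  bad_pop <- setdiff(unique(meta$population), populations())
  if (length(bad_pop) > 0)
    stop("unknown population label(s): ", paste(bad_pop, collapse = ", "))
  meta$time_point <- normalize_time_point(meta$time_point)
  bad_tp <- setdiff(unique(meta$time_point), time_points())
  if (length(bad_tp) > 0)
    stop("unknown time_point label(s): ", paste(bad_tp, collapse = ", "))
  meta$replicate <- as.integer(meta$replicate)
  if (!is.null(counts)) {
    if (!setequal(colnames(counts), meta$sample))
      stop("metadata samples do not match count matrix samples")
    meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
    rownames(meta) <- NULL
  }
  meta
}

#' Read sample metadata from TSV
#'
#' @param path Path to a tab-delimited file with columns `sample`,
#'   `population`, `time_point`, `replicate` and optional covariates.
#' @param counts Optional count matrix to validate against.
#' @return Validated metadata data frame.
#' @export
read_metadata <- function(path, counts = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE,
                            colClasses = "character")
  validate_metadata(meta, counts)
}

#' Write sample metadata to TSV
#' @param meta Metadata data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Broad-dialect GMT: each line is `name TAB description TAB member TAB ...`.
#' Member order is preserved; duplicate members within a set are dropped.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors with a `"description"` attribute
#'   (named character vector) on the list.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short) > 0)
    stop("GMT line ", short[1], " has fewer than 3 fields")
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms)) stop("duplicate set names in GMT")
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  if (any(lengths(sets) == 0)) stop("GMT contains an empty set")
  names(sets) <- nms
  names(desc) <- nms
  attr(sets, "description") <- desc
  sets
}

#' Write a gene-set collection to GMT
#' @param sets Named list of character vectors; optional `"description"`
#'   attribute as produced by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
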
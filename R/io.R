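#' @include accessors.R
NULL

## Auto-detect comma vs tab delimiter from the header line.
.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) >=
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

#' Read a regional uptake table from delimited text
#'
#' Expects UTF-8 delimited text (comma or tab, auto-detected): first row
#' region labels, first column animal ids, body the SUVR values. Missing
#' or non-positive cells, duplicate region labels and groups of fewer than
#' 3 animals are hard errors.
#'
#' @param path file path.
#' @param group_id,genotype,sex,age_months group descriptors for the table.
#' @return an \linkS4class{UptakeTable}.
#' @seealso [writeUptakeTable()]
#' @export
readUptakeTable <- function(path, group_id = basename(path), genotype = "WT",
                            sex = "M", age_months = 4) {
  sep <- .detect_sep(path)
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  animal_ids <- as.character(df[[1L]])
  region_labels <- colnames(df)[-1L]   # before subsetting: [.data.frame
                                       # silently repairs duplicated names
  values <- as.matrix(df[, -1L, drop = FALSE])
  colnames(values) <- region_labels
  if (anyDuplicated(region_labels))
    stop("duplicate region label(s): ",
         paste(unique(region_labels[duplicated(region_labels)]),
               collapse = ", "))
  if (anyDuplicated(animal_ids))
    stop("duplicate animal id(s): ",
         paste(unique(animal_ids[duplicated(animal_ids)]), collapse = ", "))
  bad <- which(is.na(values) | !is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("missing or non-numeric SUVR value at row '%s', column '%s'",
                 animal_ids[bad[1L, 1L]], region_labels[bad[1L, 2L]]))
  if (nrow(values) < 3L)
    stop("at least 3 animals are required (got ", nrow(values), ")")
  uptakeTable(values, region_labels = region_labels, animal_ids = animal_ids,
              group_id = group_id, genotype = genotype, sex = sex,
              age_months = age_months)
}

#' Write a regional uptake table as CSV
#'
#' @param table an \linkS4class{UptakeTable}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeUptakeTable <- function(table, path) {
  v <- suvrMatrix(table)
  body <- apply(v, 2L, function(col) sprintf("%.17g", col))
  if (nrow(v) == 1L) body <- matrix(body, 1L)
  df <- data.frame(animal_id = rownames(v), body,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("animal_id", colnames(v))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a labelled square matrix as CSV
#'
#' Delimited text with a header row and a header column of region labels;
#' values are written with enough digits that a read-back reproduces them
#' to at least 12 significant digits.
#'
#' @param matrix square numeric matrix with (identical) row/column labels.
#' @param path output file path.
#' @return the path, invisibly.
#' @seealso [readMatrix()]
#' @export
writeMatrix <- function(matrix, path) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("input must be a square matrix (got ",
         paste(dim(matrix), collapse = " x "), ")")
  labs <- rownames(matrix)
  if (is.null(labs)) labs <- paste0("R", seq_len(nrow(matrix)))
  body <- apply(matrix, 2L, function(col) sprintf("%.15g", col))
  if (nrow(matrix) == 1L) body <- matrix(body, 1L)
  df <- data.frame(region = labs, body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("region", labs)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labelled square matrix written by [writeMatrix()]
#'
#' @param path file path.
#' @return square numeric matrix with dimnames.
#' @export
readMatrix <- function(path) {
  sep <- .detect_sep(path)
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  if (nrow(m) != ncol(m))
    stop("file does not contain a square labelled matrix")
  m
}

#' Write a partition as two-column CSV (region, label)
#'
#' @param partition a \linkS4class{Partition}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writePartition <- function(partition, path) {
  stopifnot(is(partition, "Partition"))
  df <- data.frame(region = partition@regionLabels,
                   label = partition@labels, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a partition written by [writePartition()]
#'
#' @param path file path.
#' @return a \linkS4class{Partition}.
#' @export
readPartition <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  partition(df$label, df$region)
}
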
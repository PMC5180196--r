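#' Construct an OTU count table
#'
#' The central container of the package: an integer count matrix with samples
#' as rows and OTUs as columns, plus a taxonomy label per OTU. Identifiers
#' must be unique; counts must be non-negative integers.
#'
#' @param counts numeric matrix, samples x OTUs, with unique row and column
#'   names. All entries must be non-negative and integer-valued.
#' @param taxonomy named character vector mapping every OTU id to a taxonomy
#'   string (free text; \code{"Unclassified"} is allowed). \code{NULL} fills
#'   \code{"Unclassified"} for all OTUs.
#' @return An object of class \code{"otu_table"}: a list with elements
#'   \code{counts} (integer matrix) and \code{taxonomy}.
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix (samples x OTUs)")
  if (nrow(counts) == 0L) stop("no samples in OTU table")
  if (ncol(counts) == 0L) stop("no OTUs in OTU table")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have sample ids as rownames and OTU ids as colnames")
  dup_s <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  dup_o <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_o))
    stop("duplicate OTU ids: ", paste(dup_o, collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 |
                 abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("counts must be non-negative integers; offending cell: sample '",
         rownames(counts)[bad[1, 1]], "', OTU '", colnames(counts)[bad[1, 2]],
         "' (value ", counts[bad[1, 1], bad[1, 2]], ")")
  }
  storage.mode(counts) <- "integer"
  if (is.null(taxonomy)) {
    taxonomy <- setNames(rep("Unclassified", ncol(counts)), colnames(counts))
  }
  missing_tax <- setdiff(colnames(counts), names(taxonomy))
  if (length(missing_tax))
    stop("OTUs without taxonomy entry: ",
         paste(utils::head(missing_tax, 5), collapse = ", "))
  structure(list(counts = counts,
                 taxonomy = as.character(taxonomy[colnames(counts)])),
            class = "otu_table")
}

#' @rdname otu_table
#' @param x object to test.
#' @export
is_otu_table <- function(x) inherits(x, "otu_table")

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table:", nrow(x$counts), "samples x", ncol(x$counts), "OTUs;",
      "total reads", sum(x$counts), "\n")
  invisible(x)
}

#' Sample and OTU identifiers of an OTU table
#' @param t an \code{otu_table}.
#' @return character vector of ids.
#' @export
sample_ids <- function(t) rownames(t$counts)

#' @rdname sample_ids
#' @export
otu_ids <- function(t) colnames(t$counts)

#' Read an OTU count table from a tab-separated file
#'
#' The canonical layout has OTUs as rows (first column = OTU id), one column
#' per sample and one taxonomy column. \code{samples_as = "rows"} reads the
#' transposed layout (samples as rows, no taxonomy column; taxonomy is then
#' filled with \code{"Unclassified"}).
#'
#' @param path path to a TSV file with a header row.
#' @param taxonomy_column name of the taxonomy column (default
#'   \code{"taxonomy"}); required for the OTUs-as-rows layout.
#' @param samples_as \code{"columns"} (default) or \code{"rows"}.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, taxonomy_column = "taxonomy",
                           samples_as = c("columns", "rows")) {
  samples_as <- match.arg(samples_as)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = NA)
  if (nrow(df) == 0L)
    stop("no ", if (samples_as == "columns") "OTUs" else "samples",
         " in '", path, "' (header only)")
  ids <- as.character(df[[1]])
  if (samples_as == "columns") {
    if (!taxonomy_column %in% names(df))
      stop("taxonomy column '", taxonomy_column, "' not found in '", path, "'")
    tax <- setNames(as.character(df[[taxonomy_column]]), ids)
    tax[is.na(tax) | tax == ""] <- "Unclassified"
    keep <- setdiff(names(df)[-1], taxonomy_column)
    if (length(keep) == 0L) stop("no samples in '", path, "'")
    m <- .numeric_matrix(df[keep], ids, path)
    counts <- t(m)  # samples x OTUs
    otu_table(counts, tax)
  } else {
    keep <- names(df)[-1]
    if (length(keep) == 0L) stop("no OTUs in '", path, "'")
    counts <- .numeric_matrix(df[keep], ids, path)
    otu_table(counts, NULL)
  }
}

# data.frame block -> numeric matrix with row ids; errors name the bad cell
.numeric_matrix <- function(block, ids, path) {
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(block),
              dimnames = list(ids, names(block)))
  for (j in seq_along(block)) {
    v <- block[[j]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("unparseable numeric in '", path, "': row '", ids[bad[1]],
             "', column '", names(block)[j], "' (value '", v[bad[1]], "')")
      v <- vn
    }
    m[, j] <- v
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("missing value in '", path, "': row '", ids[bad[1, 1]],
         "', column '", colnames(m)[bad[1, 2]], "'")
  }
  m
}
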
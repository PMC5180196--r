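#' Labeled symmetric distance matrix
#'
#' A thin validated wrapper around a base matrix: symmetric within 1e-12,
#' exactly zero diagonal, non-negative entries, unique ids on both margins.
#' All distance matrices exchanged between modules are of this class.
#'
#' @param values square numeric matrix with matching row/column names, or a
#'   \code{stats::dist} object.
#' @param ids optional character vector of ids overriding the dimnames.
#' @return A matrix of class \code{c("dist_matrix", "matrix")}.
#' @export
dist_matrix <- function(values, ids = NULL) {
  if (inherits(values, "dist")) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix or dist object")
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (!is.null(ids)) dimnames(values) <- list(ids, ids)
  ids <- rownames(values)
  if (is.null(ids) || length(ids) != nrow(values))
    stop("distance matrix needs ids (dimnames)")
  if (anyDuplicated(ids)) stop("duplicate ids in distance matrix")
  if (!identical(ids, colnames(values)))
    stop("row and column ids differ")
  if (any(!is.finite(values)))
    stop("distance matrix contains non-finite values")
  if (max(abs(values - t(values))) > 1e-12)
    stop("distance matrix not symmetric within 1e-12")
  if (any(diag(values) != 0)) stop("distance matrix diagonal must be 0")
  if (any(values < 0)) stop("distance matrix entries must be >= 0")
  values <- (values + t(values)) / 2
  class(values) <- c("dist_matrix", "matrix")
  values
}

#' @rdname dist_matrix
#' @param x object to test.
#' @export
is_dist_matrix <- function(x) inherits(x, "dist_matrix")

# strip class for plain-matrix math
.dm <- function(x) {
  m <- unclass(x)
  attr(m, "class") <- NULL
  m
}

#' Write / read a distance matrix as a square TSV
#'
#' The file has an id header row and an id first column; values round-trip
#' within 1e-12.
#'
#' @param m a [dist_matrix()].
#' @param path output path.
#' @return \code{write_distance_matrix} returns \code{invisible(path)};
#'   \code{read_distance_matrix} returns a [dist_matrix()].
#' @export
write_distance_matrix <- function(m, path) {
  m <- dist_matrix(m)  # re-validate (catches NaN off-diagonal etc.)
  df <- data.frame(id = rownames(m), .dm(m), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[-1])
  dimnames(m) <- list(ids, ids)
  dist_matrix(m)
}

#' Write a results table as TSV
#'
#' Plain lossless TSV writer used for every tabular output of the pipeline.
#' An empty data.frame yields a header-only file.
#'
#' @param rows data.frame of results.
#' @param path output path.
#' @return \code{invisible(path)}.
#' @export
write_results_table <- function(rows, path) {
  if (!is.data.frame(rows)) stop("`rows` must be a data.frame")
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

# align a second distance matrix onto the id order of the first
.align_dist <- function(dx, dy, what = "distance matrices") {
  dx <- .dm(dist_matrix(dx)); dy0 <- dist_matrix(dy)
  if (!setequal(rownames(dx), rownames(dy0)))
    stop(what, " have different id sets; symmetric difference: ",
         paste(c(setdiff(rownames(dx), rownames(dy0)),
                 setdiff(rownames(dy0), rownames(dx))), collapse = ", "))
  list(x = dx, y = .dm(dy0)[rownames(dx), rownames(dx)])
}
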
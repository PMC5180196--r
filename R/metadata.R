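#' Construct a sample metadata table
#'
#' One row per sample: identifier, month label, decimal-degree coordinates
#' and a fixed set of environmental variables (salinity, temperature,
#' chlorophyll a, inorganic nutrients, ...).
#'
#' @param df data.frame with columns \code{sample_id}, \code{month},
#'   \code{latitude}, \code{longitude} and one numeric column per
#'   environmental variable.
#' @param env_variables character, names of the environmental variable
#'   columns.
#' @param months ordered character vector of admissible month labels
#'   (default [default_months()]). Month values outside this set are an
#'   error.
#' @return A data.frame of class \code{"sample_metadata"} with attributes
#'   \code{env_variables} and \code{months}.
#' @export
sample_metadata <- function(df, env_variables,
                            months = default_months()) {
  req <- c("sample_id", "month", "latitude", "longitude")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  miss_env <- setdiff(env_variables, names(df))
  if (length(miss_env)) stop("metadata missing environmental variables: ",
                             paste(miss_env, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  df$month <- as.character(df$month)
  bad_m <- setdiff(unique(df$month), months)
  if (length(bad_m))
    stop("month label(s) outside configured set: ",
         paste(bad_m, collapse = ", "),
         " (allowed: ", paste(months, collapse = ", "), ")")
  for (v in c("latitude", "longitude", env_variables)) {
    if (!is.numeric(df[[v]])) stop("column '", v, "' must be numeric")
    if (anyNA(df[[v]]))
      stop("missing value in column '", v, "', sample '",
           df$sample_id[which(is.na(df[[v]]))[1]], "'")
  }
  if (anyNA(df$month)) stop("missing month label")
  out <- df[c(req, env_variables)]
  rownames(out) <- out$sample_id
  structure(out, env_variables = env_variables, months = months,
            class = c("sample_metadata", "data.frame"))
}

#' Read sample metadata from a tab-separated file
#'
#' @param path path to a TSV with a header that includes \code{sample_id},
#'   \code{month}, \code{latitude}, \code{longitude} and every requested
#'   environmental variable.
#' @param env_variables character, environmental variable columns to load.
#' @param months admissible month labels; see [sample_metadata()].
#' @return A \code{sample_metadata} data.frame.
#' @export
read_sample_metadata <- function(path,
                                 env_variables = c("salinity", "temperature",
                                                   "chla", "nh4", "no3",
                                                   "po4", "sio4"),
                                 months = default_months()) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  num_cols <- intersect(c("latitude", "longitude", env_variables), names(df))
  for (v in num_cols) {
    if (!is.numeric(df[[v]])) {
      vn <- suppressWarnings(as.numeric(df[[v]]))
      bad <- which(is.na(vn) & !is.na(df[[v]]))
      if (length(bad))
        stop("unparseable numeric in '", path, "': row ", bad[1],
             ", column '", v, "' (value '", df[[v]][bad[1]], "')")
      df[[v]] <- vn
    }
  }
  sample_metadata(df, env_variables, months)
}

#' @export
print.sample_metadata <- function(x, ...) {
  cat("sample_metadata:", nrow(x), "samples;",
      length(attr(x, "env_variables")), "environmental variables (",
      paste(attr(x, "env_variables"), collapse = ", "), ")\n")
  invisible(as.data.frame(x))
}

#' Environmental variable names of a metadata table
#' @param md a \code{sample_metadata} object.
#' @return character vector.
#' @export
env_variables <- function(md) attr(md, "env_variables")
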
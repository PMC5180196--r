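#' Rarefy an OTU table to a common sequencing depth
#'
#' Each sample's reads are subsampled WITHOUT replacement (multivariate
#' hypergeometric) to exactly \code{depth} reads, under a fixed seed so the
#' result is reproducible bit-for-bit. Samples with fewer than \code{depth}
#' total reads are dropped (reported via \code{message()}); OTUs left with
#' zero reads across all retained samples are removed.
#'
#' @param t an [otu_table()].
#' @param depth target reads per sample (the standard survey depth here is
#'   2500).
#' @param seed integer seed controlling the subsampling.
#' @return A rarefied [otu_table()].
#' @export
rarefy <- function(t, depth, seed = 1L) {
  stopifnot(is_otu_table(t), depth >= 1)
  totals <- rowSums(t$counts)
  keep <- totals >= depth
  if (!any(keep)) stop("no samples survive rarefaction at depth ", depth)
  if (any(!keep))
    message("rarefy: dropping ", sum(!keep), " sample(s) below depth ",
            depth, ": ", paste(rownames(t$counts)[!keep], collapse = ", "))
  counts <- t$counts[keep, , drop = FALSE]
  n_otu <- ncol(counts)
  out <- with_seed(seed, {
    res <- matrix(0L, nrow(counts), n_otu, dimnames = dimnames(counts))
    for (i in seq_len(nrow(counts))) {
      reads <- rep.int(seq_len(n_otu), counts[i, ])
      picked <- if (length(reads) == depth) reads else sample(reads, depth)
      res[i, ] <- tabulate(picked, nbins = n_otu)
    }
    res
  })
  nonzero <- colSums(out) > 0L
  otu_table(out[, nonzero, drop = FALSE],
            setNames(t$taxonomy, colnames(t$counts))[nonzero])
}

#' Per-sample relative abundances
#'
#' @param t an [otu_table()].
#' @return numeric matrix (samples x OTUs) whose rows sum to 1.
#' @export
relative_abundance <- function(t) {
  stopifnot(is_otu_table(t))
  totals <- rowSums(t$counts)
  if (any(totals == 0))
    stop("zero-sum sample(s): ",
         paste(rownames(t$counts)[totals == 0], collapse = ", "))
  sweep(t$counts, 1, totals, "/")
}

#' Subset an OTU table to one taxonomic group
#'
#' OTUs are retained when their taxonomy string contains \code{group_label}
#' (fixed substring match; the seven standard groups are phylum labels except
#' the proteobacterial classes). Samples with zero remaining reads are kept;
#' downstream analyses drop them where their methods require. A label that
#' matches no OTU returns an [nf_marker()], which the Mantel battery and
#' classifier report as \code{"NF"}.
#'
#' @param t an [otu_table()].
#' @param group_label taxonomy substring, e.g. \code{"Cyanobacteria"}.
#' @return An [otu_table()] or an [nf_marker()].
#' @export
subset_by_taxon <- function(t, group_label) {
  stopifnot(is_otu_table(t))
  hit <- grepl(group_label, t$taxonomy, fixed = TRUE)
  if (!any(hit))
    return(nf_marker(paste0("no OTUs match taxon '", group_label, "'")))
  otu_table(t$counts[, hit, drop = FALSE],
            setNames(t$taxonomy, colnames(t$counts))[hit])
}

#' Bray-Curtis community dissimilarity
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} on the (typically
#' rarefied) counts; values lie in \[0, 1\].
#'
#' @param t an [otu_table()] with at least two samples.
#' @return A [dist_matrix()] over samples.
#' @export
bray_curtis <- function(t) {
  stopifnot(is_otu_table(t))
  if (nrow(t$counts) < 2) stop("need >= 2 samples for Bray-Curtis")
  zero <- rowSums(t$counts) == 0
  if (sum(zero) >= 2)
    stop("two or more all-zero samples (Bray-Curtis 0/0 undefined): ",
         paste(rownames(t$counts)[zero], collapse = ", "))
  dist_matrix(vegan::vegdist(t$counts, method = "bray"))
}

#' Environmental distance between samples
#'
#' Euclidean distance over the chosen environmental variables. With
#' \code{standardize = TRUE} (default) each variable is z-scored across the
#' included samples first, so variables with incommensurable units (PSU,
#' degrees C, uM) contribute comparably.
#'
#' @param md a [sample_metadata()] collection.
#' @param variables environmental variables to use (default: all declared).
#' @param standardize z-score variables before the distance (default TRUE).
#' @return A [dist_matrix()] over samples.
#' @export
env_distance <- function(md, variables = env_variables(md),
                         standardize = TRUE) {
  miss <- setdiff(variables, names(md))
  if (length(miss)) stop("missing environmental variables: ",
                         paste(miss, collapse = ", "))
  x <- as.matrix(as.data.frame(md)[variables])
  rownames(x) <- md$sample_id
  if (standardize) {
    sds <- apply(x, 2, sd)
    if (any(sds == 0))
      stop("zero-variance variable(s) under standardization: ",
           paste(variables[sds == 0], collapse = ", "))
    x <- scale(x)
  }
  dist_matrix(dist(x))
}

#' Spatial distance between samples
#'
#' Default is Euclidean distance on raw (latitude, longitude) in decimal
#' degrees; \code{mode = "great-circle"} gives haversine distances in km
#' (Earth radius 6371 km).
#'
#' @param md a [sample_metadata()] collection.
#' @param mode \code{"euclidean-degrees"} (default) or \code{"great-circle"}.
#' @return A [dist_matrix()] over samples.
#' @export
spatial_distance <- function(md, mode = c("euclidean-degrees",
                                          "great-circle")) {
  mode <- match.arg(mode)
  lat <- md$latitude; lon <- md$longitude
  if (mode == "euclidean-degrees") {
    x <- cbind(lat, lon)
    rownames(x) <- md$sample_id
    return(dist_matrix(dist(x)))
  }
  n <- length(lat)
  phi <- lat * pi / 180; lam <- lon * pi / 180
  m <- matrix(0, n, n, dimnames = list(md$sample_id, md$sample_id))
  for (i in seq_len(n)) {
    dphi <- phi - phi[i]; dlam <- lam - lam[i]
    a <- sin(dphi / 2)^2 + cos(phi[i]) * cos(phi) * sin(dlam / 2)^2
    m[i, ] <- 2 * 6371 * asin(pmin(1, sqrt(a)))
  }
  diag(m) <- 0
  dist_matrix((m + t(m)) / 2)
}

#' Per-OTU occupancy
#'
#' Fraction of samples in which each OTU is detected (count > 0). Reported
#' as a percentage in the pipeline's tables.
#'
#' @param t an [otu_table()].
#' @return named numeric vector in \[0, 1\].
#' @export
occupancy <- function(t) {
  stopifnot(is_otu_table(t))
  colMeans(t$counts > 0)
}
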
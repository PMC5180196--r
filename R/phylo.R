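#' Patristic (tip-to-tip branch length) distance matrix
#'
#' @param tree a rooted \code{"phylo"} tree with branch lengths.
#' @param tips tip subset to return (default: all tips).
#' @return A [dist_matrix()] over the requested tips, in branch-length
#'   units.
#' @export
patristic_matrix <- function(tree, tips = tree$tip.label) {
  tree <- validate_tree(tree)
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing))
    stop("tips absent from tree: ", paste(missing, collapse = ", "))
  d <- stats::cophenetic(tree)
  dist_matrix(d[tips, tips, drop = FALSE])
}

#' Mean pairwise phylogenetic distance (MPD)
#'
#' Unweighted mean of patristic distances over all unordered pairs of the
#' community's members; with \code{weights}, the abundance-weighted form
#' \eqn{\sum_{i<j} w_i w_j d_{ij} / \sum_{i<j} w_i w_j}.
#'
#' @param members character vector of taxon ids (>= 2).
#' @param d a [dist_matrix()] over taxa containing all members.
#' @param weights optional non-negative abundance weights, named by or
#'   ordered as \code{members}.
#' @return scalar MPD.
#' @export
mpd <- function(members, d, weights = NULL) {
  members <- as.character(members)
  if (length(members) < 2) stop("MPD undefined for fewer than 2 members")
  m <- .dm(dist_matrix(d))
  missing <- setdiff(members, rownames(m))
  if (length(missing))
    stop("members absent from distance matrix: ",
         paste(missing, collapse = ", "))
  sub <- m[members, members]
  lt <- lower.tri(sub)
  if (is.null(weights)) return(mean(sub[lt]))
  if (!is.null(names(weights))) weights <- weights[members]
  w <- outer(weights, weights)
  sum((w * sub)[lt]) / sum(w[lt])
}

#' Net relatedness index (NRI) of a community against a randomization null
#'
#' The null distribution is the MPD of richness-matched random draws from a
#' species pool: \code{n_null} uniform subsets of size
#' \code{length(members)} (or, with \code{exhaustive = TRUE} and a feasible
#' pool, every such subset). The index is the negated standardized effect
#' size \eqn{NRI = -(MPD_{obs} - \bar{MPD}_{null}) / sd(MPD_{null})}: positive
#' values mean the community is phylogenetically clustered (habitat
#' filtering), negative values overdispersed (competitive exclusion).
#' Significance is two-tailed at rank level 0.025 per tail with the
#' \eqn{(r + 1)/(n + 1)} correction.
#'
#' @param members community taxon ids (subset of \code{pool}).
#' @param pool species-pool taxon ids (subset of the matrix ids).
#' @param d a [dist_matrix()] over taxa.
#' @param n_null number of null draws (default 999).
#' @param seed integer seed for the null draws.
#' @param exhaustive enumerate all subsets instead of sampling when
#'   \code{choose(|pool|, |members|) <= exhaustive_cap}.
#' @param exhaustive_cap cap on the enumeration size (default 10000).
#' @param weights optional abundance weights over \code{pool} taxa; when
#'   given, observed and null MPDs are abundance-weighted.
#' @return An object of class \code{"nri_result"}: a list with
#'   \code{mpd_obs}, \code{null_mean}, \code{null_sd}, \code{nri},
#'   \code{n_null}, \code{p_low}, \code{p_high}, \code{significant},
#'   \code{direction}, \code{degenerate}.
#' @export
nri <- function(members, pool, d, n_null = 999, seed = NULL,
                exhaustive = FALSE, exhaustive_cap = 10000, weights = NULL) {
  members <- as.character(members); pool <- as.character(pool)
  m <- .dm(dist_matrix(d))
  if (length(setdiff(pool, rownames(m))))
    stop("pool taxa absent from distance matrix")
  if (length(setdiff(members, pool)))
    stop("members must be a subset of the pool")
  k <- length(members)
  if (k < 2) stop("MPD undefined for fewer than 2 members")
  one_mpd <- function(ids) {
    sub <- m[ids, ids]
    lt <- lower.tri(sub)
    if (is.null(weights)) return(mean(sub[lt]))
    w <- outer(weights[ids], weights[ids])
    sum((w * sub)[lt]) / sum(w[lt])
  }
  obs <- one_mpd(members)
  use_exhaustive <- FALSE
  if (exhaustive) {
    n_comb <- choose(length(pool), k)
    if (n_comb <= exhaustive_cap) use_exhaustive <- TRUE
    else warning("choose(|pool|, k) = ", n_comb, " exceeds cap ",
                 exhaustive_cap, "; falling back to sampling")
  }
  null <- if (use_exhaustive) {
    combn(pool, k, one_mpd)
  } else {
    with_seed(seed,
      vapply(seq_len(n_null), function(i) one_mpd(sample(pool, k)),
             numeric(1)))
  }
  mu <- mean(null); s <- sd(null)
  n <- length(null)
  p_low <- (sum(null <= obs) + 1) / (n + 1)
  p_high <- (sum(null >= obs) + 1) / (n + 1)
  degenerate <- !is.finite(s) || s == 0
  structure(list(
    mpd_obs = obs, null_mean = mu, null_sd = s,
    nri = if (degenerate) NaN else -(obs - mu) / s,
    n_null = n, p_low = p_low, p_high = p_high,
    significant = !degenerate && (p_low <= 0.025 || p_high <= 0.025),
    direction = if (obs < mu) "positive" else "negative",
    degenerate = degenerate,
    exhaustive = use_exhaustive
  ), class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("NRI = %.3f (MPD obs %.4g, null %.4g +/- %.4g, n_null %d)%s\n",
              x$nri, x$mpd_obs, x$null_mean, x$null_sd, x$n_null,
              if (x$degenerate) " [degenerate null]"
              else if (x$significant) " *" else ""))
  invisible(x)
}

#' NRI for every sample of an OTU table
#'
#' Members of each sample are its detected OTUs (count > 0); the pool is all
#' OTUs of the table (intersected with the distance matrix ids). Samples
#' with fewer than two detected OTUs are skipped with a message.
#'
#' @param t a (rarefied) [otu_table()].
#' @param d patristic [dist_matrix()] over (at least) the table's OTUs.
#' @param n_null,seed,weights see [nri()]; per-sample seeds are derived as
#'   \code{seed + sample index}.
#' @param abundance_weighted use each sample's counts as MPD weights.
#' @return data.frame with one row per analyzed sample (NRI fields as in
#'   [nri()]).
#' @export
nri_samples <- function(t, d, n_null = 999, seed = NULL,
                        abundance_weighted = FALSE, weights = NULL) {
  stopifnot(is_otu_table(t))
  pool <- intersect(colnames(t$counts), rownames(.dm(dist_matrix(d))))
  if (length(pool) < 2) stop("pool has fewer than 2 taxa on the tree")
  rows <- vector("list", nrow(t$counts))
  for (i in seq_len(nrow(t$counts))) {
    sid <- rownames(t$counts)[i]
    members <- intersect(colnames(t$counts)[t$counts[i, ] > 0], pool)
    if (length(members) < 2) {
      message("nri_samples: skipping sample '", sid,
              "' (fewer than 2 OTUs on tree)")
      next
    }
    w <- if (abundance_weighted)
      setNames(as.numeric(t$counts[i, pool]), pool) else weights
    r <- nri(members, pool, d, n_null = n_null,
             seed = if (is.null(seed)) NULL else seed + i, weights = w)
    rows[[i]] <- data.frame(sample_id = sid, mpd_obs = r$mpd_obs,
                            null_mean = r$null_mean, null_sd = r$null_sd,
                            nri = r$nri, n_null = r$n_null,
                            p_low = r$p_low, p_high = r$p_high,
                            significant = r$significant,
                            direction = r$direction,
                            degenerate = r$degenerate)
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Summarize per-sample NRI by month
#'
#' Counts and percentages of positive / negative and significantly positive
#' / negative NRI values per month, in the conventional 8-column layout.
#'
#' @param results data.frame from [nri_samples()].
#' @param metadata a [sample_metadata()] collection with the same samples.
#' @return data.frame with columns \code{month}, \code{"+ (n)"},
#'   \code{"- (n)"}, \code{"+ (\%)"}, \code{"- (\%)"}, \code{"Sig + (n)"},
#'   \code{"Sig - (n)"}, \code{"Sig + (\%)"}, \code{"Sig - (\%)"}.
#' @export
nri_month_summary <- function(results, metadata) {
  month <- setNames(as.character(metadata$month), metadata$sample_id)
  res <- results[!results$degenerate & is.finite(results$nri), , drop = FALSE]
  res$month <- month[res$sample_id]
  out <- list()
  for (m in attr(metadata, "months")) {
    sub <- res[res$month %in% m, , drop = FALSE]
    n <- nrow(sub)
    if (n == 0) {
      if (m %in% month) warning("month ", m, " omitted: no usable NRI values")
      next
    }
    pos <- sum(sub$nri > 0); neg <- sum(sub$nri < 0)
    sig_pos <- sum(sub$significant & sub$direction == "positive")
    sig_neg <- sum(sub$significant & sub$direction == "negative")
    row <- data.frame(month = m, check.names = FALSE)
    row[["+ (n)"]] <- pos;            row[["- (n)"]] <- neg
    row[["+ (%)"]] <- round(100 * pos / n, 1)
    row[["- (%)"]] <- round(100 * neg / n, 1)
    row[["Sig + (n)"]] <- sig_pos;    row[["Sig - (n)"]] <- sig_neg
    row[["Sig + (%)"]] <- round(100 * sig_pos / n, 1)
    row[["Sig - (%)"]] <- round(100 * sig_neg / n, 1)
    out[[m]] <- row
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
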
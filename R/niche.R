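#' Levins' niche breadth per OTU
#'
#' For OTU j with counts \eqn{c_{ij}} across the N samples,
#' \eqn{p_{ij} = c_{ij} / \sum_i c_{ij}} is the proportion of OTU j's reads
#' found in sample i, and \eqn{B_j = 1 / \sum_i p_{ij}^2}. B ranges from 1
#' (all reads in a single sample: an extreme habitat specialist) to N
#' (perfectly even across all samples: an extreme generalist). Occupancy
#' (percent of samples occupied) and mean relative abundance (percent of
#' total sequences) are profiled alongside.
#'
#' @param t a (rarefied) [otu_table()] with every OTU total > 0.
#' @return A data.frame of class \code{"niche_breadth_profile"}: columns
#'   \code{otu_id}, \code{taxonomy}, \code{B}, \code{occupancy_pct},
#'   \code{mean_rel_abund_pct}; attribute \code{n_samples}.
#' @export
levins_b <- function(t) {
  stopifnot(is_otu_table(t))
  totals <- colSums(t$counts)
  if (any(totals == 0))
    stop("zero-total OTU(s) (prune before computing niche breadth): ",
         paste(utils::head(colnames(t$counts)[totals == 0], 5),
               collapse = ", "))
  p <- sweep(t$counts, 2, totals, "/")
  B <- 1 / colSums(p^2)
  structure(data.frame(otu_id = colnames(t$counts),
                       taxonomy = t$taxonomy,
                       B = as.numeric(B),
                       occupancy_pct = 100 * as.numeric(occupancy(t)),
                       mean_rel_abund_pct =
                         100 * as.numeric(colMeans(relative_abundance(t))),
                       stringsAsFactors = FALSE, row.names = NULL),
            n_samples = nrow(t$counts),
            class = c("niche_breadth_profile", "data.frame"))
}

#' Bin OTUs by niche breadth
#'
#' Default bins follow the conventional generalist/specialist partition:
#' \code{"<3"} = \[1, 3), \code{"3-6"} = \[3, 6), \code{"6-10"} = \[6, 10\],
#' \code{">10"} = (10, Inf). Boundary values 3 and 6 fall in the upper bin,
#' 10 in \code{"6-10"}.
#'
#' @param profiles a [levins_b()] profile data.frame.
#' @param edges three increasing breakpoints (default \code{c(3, 6, 10)}).
#' @param t optional [otu_table()] used to add each bin's share of total
#'   sequences to the summary.
#' @return A list: \code{profiles} (input with a \code{bin} column) and
#'   \code{summary} (per bin: OTU count, mean/sd B, mean/sd occupancy, and
#'   percent of total sequences when \code{t} is given).
#' @export
bin_by_breadth <- function(profiles, edges = c(3, 6, 10), t = NULL) {
  stopifnot(length(edges) == 3, !is.unsorted(edges))
  labels <- c(paste0("<", edges[1]),
              paste0(edges[1], "-", edges[2]),
              paste0(edges[2], "-", edges[3]),
              paste0(">", edges[3]))
  assign_bin <- function(B) {
    ifelse(B < edges[1], labels[1],
      ifelse(B < edges[2], labels[2],
        ifelse(B <= edges[3], labels[3], labels[4])))
  }
  profiles$bin <- factor(assign_bin(profiles$B), levels = labels)
  seq_share <- NULL
  if (!is.null(t)) {
    tot <- sum(t$counts)
    per_otu <- colSums(t$counts)[profiles$otu_id]
    seq_share <- vapply(labels, function(l)
      100 * sum(per_otu[profiles$bin == l]) / tot, numeric(1))
  }
  summ <- do.call(rbind, lapply(labels, function(l) {
    sub <- profiles[profiles$bin == l, , drop = FALSE]
    data.frame(bin = l, n_otus = nrow(sub),
               mean_B = mean(sub$B), sd_B = sd(sub$B),
               mean_occupancy_pct = mean(sub$occupancy_pct),
               sd_occupancy_pct = sd(sub$occupancy_pct),
               pct_total_sequences =
                 if (is.null(seq_share)) NA_real_ else seq_share[[l]],
               stringsAsFactors = FALSE)
  }))
  list(profiles = profiles, summary = summ)
}

#' Environmental and spatial explained variance per niche-breadth bin
#'
#' For each bin the OTU table is subset to the bin's OTUs, Bray-Curtis
#' distances are computed over the samples with nonzero bin reads, and
#' simple Mantel tests against the environmental and spatial distances are
#' run. Explained variance is reported as \eqn{100 r^2} (the signed r and p
#' are emitted alongside). Bins with no OTUs or fewer than
#' \code{min_samples} usable samples yield an NF row.
#'
#' @param t a (rarefied) [otu_table()].
#' @param md a [sample_metadata()] collection.
#' @param binned output of [bin_by_breadth()] (or a profile data.frame with
#'   a \code{bin} column).
#' @param n_perm,seed permutation settings per Mantel test.
#' @param min_samples minimum usable samples per bin (default 4).
#' @param env_vars environmental variables (default: all declared).
#' @param spatial_mode passed to [spatial_distance()].
#' @return data.frame, one row per bin: \code{bin}, \code{n_otus},
#'   \code{n_samples}, \code{mean_B}, \code{r_E}, \code{p_E},
#'   \code{var_expl_E_pct}, \code{r_S}, \code{p_S}, \code{var_expl_S_pct},
#'   \code{status}.
#' @export
breadth_partition_analysis <- function(t, md, binned, n_perm = 999,
                                       seed = NULL, min_samples = 4,
                                       env_vars = env_variables(md),
                                       spatial_mode = "euclidean-degrees") {
  profiles <- if (is.data.frame(binned)) binned else binned$profiles
  stopifnot(is_otu_table(t), "bin" %in% names(profiles))
  common <- intersect(rownames(t$counts), md$sample_id)
  rows <- list()
  for (bi in seq_along(levels(profiles$bin))) {
    b <- levels(profiles$bin)[bi]
    otus <- intersect(profiles$otu_id[profiles$bin == b], colnames(t$counts))
    nf <- function(reason, n_s = 0) data.frame(
      bin = b, n_otus = length(otus), n_samples = n_s,
      mean_B = if (length(otus)) mean(profiles$B[profiles$bin == b])
               else NA_real_,
      r_E = NA_real_, p_E = NA_real_, var_expl_E_pct = NA_real_,
      r_S = NA_real_, p_S = NA_real_, var_expl_S_pct = NA_real_,
      status = paste0("NF: ", reason), stringsAsFactors = FALSE)
    if (length(otus) == 0) { rows[[b]] <- nf("no OTUs in bin"); next }
    sub <- t$counts[common, otus, drop = FALSE]
    usable <- rownames(sub)[rowSums(sub) > 0]
    if (length(usable) < min_samples) {
      rows[[b]] <- nf(paste0("only ", length(usable), " usable samples"),
                      length(usable))
      next
    }
    tt <- otu_table(sub[usable, , drop = FALSE],
                    setNames(profiles$taxonomy[match(otus, profiles$otu_id)],
                             otus))
    mds <- md[match(usable, md$sample_id), , drop = FALSE]
    rows[[b]] <- tryCatch({
      bc <- bray_curtis(tt)
      E <- mantel_test(bc, env_distance(mds, env_vars), n_perm,
                       if (is.null(seed)) NULL else seed + bi)
      S <- mantel_test(bc, spatial_distance(mds, spatial_mode), n_perm,
                       if (is.null(seed)) NULL else seed + 100L + bi)
      data.frame(bin = b, n_otus = length(otus), n_samples = length(usable),
                 mean_B = mean(profiles$B[profiles$bin == b]),
                 r_E = E$r, p_E = E$p, var_expl_E_pct = 100 * E$r^2,
                 r_S = S$r, p_S = S$p, var_expl_S_pct = 100 * S$r^2,
                 status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) nf(conditionMessage(e), length(usable)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Regression of explained variance on mean niche breadth
#'
#' Ordinary least squares of the per-bin environmental explained variance
#' (percent) on the per-bin mean Levins' B; the slope's p-value is the
#' usual two-sided t-test. Requires at least 3 non-NF bins.
#'
#' @param bin_variance output of [breadth_partition_analysis()].
#' @param response which explained-variance column to regress (default
#'   environmental).
#' @return list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{p_value}, \code{n} and the fitted \code{lm} object.
#' @export
breadth_regression <- function(bin_variance,
                               response = "var_expl_E_pct") {
  ok <- bin_variance$status == "ok" & is.finite(bin_variance[[response]])
  d <- bin_variance[ok, , drop = FALSE]
  if (nrow(d) < 3) stop("insufficient bins for regression (need >= 3 non-NF)")
  fit <- lm(d[[response]] ~ d$mean_B)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared,
       p_value = unname(s$coefficients[2, 4]),
       n = nrow(d), fit = fit)
}
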
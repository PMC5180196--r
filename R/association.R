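#' Simple Mantel permutation test
#'
#' The statistic is Pearson's r between the lower-triangle entries of the
#' two distance matrices. The permutation null simultaneously permutes rows
#' and columns of \code{dx} \code{n_perm} times; the p-value is one-sided
#' (greater), \eqn{p = (\#\{r_{perm} \ge r_{obs}\} + 1) / (n_{perm} + 1)},
#' positive distance correlation being the ecologically meaningful
#' direction.
#'
#' @param dx,dy [dist_matrix()] objects over the same ids (\code{dy} is
#'   aligned to \code{dx}'s order); at least 4 samples.
#' @param n_perm number of permutations (default 999; 0 skips the test and
#'   returns \code{p = NA}).
#' @param seed integer seed for the permutation stream.
#' @return An object of class \code{"mantel_result"}: list with \code{r},
#'   \code{p}, \code{n_perm}, \code{kind = "simple"}, \code{partial_r = NA},
#'   \code{n_samples}.
#' @export
mantel_test <- function(dx, dy, n_perm = 999, seed = NULL) {
  a <- .align_dist(dx, dy)
  n <- nrow(a$x)
  if (n < 4) stop("need >= 4 samples for a Mantel test")
  lt <- lower.tri(a$x)
  xv <- a$x[lt]; yv <- a$y[lt]
  if (sd(xv) == 0 || sd(yv) == 0) stop("constant distances")
  r_obs <- cor(xv, yv)
  p <- NA_real_
  if (n_perm > 0) {
    perm_r <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      p_idx <- sample.int(n)
      cor(a$x[p_idx, p_idx][lt], yv)
    }, numeric(1)))
    p <- (sum(perm_r >= r_obs) + 1) / (n_perm + 1)
  }
  structure(list(r = r_obs, p = p, n_perm = n_perm, kind = "simple",
                 partial_r = NA_real_, n_samples = n),
            class = "mantel_result")
}

#' Partial Mantel permutation test
#'
#' First-order partial Pearson correlation of \code{dx} and \code{dy}
#' controlling for \code{dz} over lower-triangle entries,
#' \eqn{r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) /
#' \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}. The permutation null permutes
#' rows/columns of the raw \code{dx} (Legendre-style) and recomputes the
#' partial statistic; one-sided (greater).
#'
#' @inheritParams mantel_test
#' @param dz covariate [dist_matrix()] to partial out.
#' @return A \code{"mantel_result"} with \code{kind = "partial"};
#'   \code{partial_r} holds the statistic, \code{r} the simple
#'   \eqn{r_{xy}}.
#' @export
partial_mantel <- function(dx, dy, dz, n_perm = 999, seed = NULL) {
  a <- .align_dist(dx, dy)
  az <- .align_dist(dx, dz)
  n <- nrow(a$x)
  if (n < 4) stop("need >= 4 samples for a partial Mantel test")
  lt <- lower.tri(a$x)
  xv <- a$x[lt]; yv <- a$y[lt]; zv <- az$y[lt]
  if (sd(xv) == 0 || sd(yv) == 0 || sd(zv) == 0) stop("constant distances")
  r_xy <- cor(xv, yv); r_xz <- cor(xv, zv); r_yz <- cor(yv, zv)
  if (1 - r_xz^2 < 1e-12 || 1 - r_yz^2 < 1e-12)
    stop("covariate collinear with a primary matrix (|r| = 1)")
  pcor <- function(rxy, rxz, ryz)
    (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  pr_obs <- pcor(r_xy, r_xz, r_yz)
  p <- NA_real_
  if (n_perm > 0) {
    perm_pr <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      p_idx <- sample.int(n)
      xp <- a$x[p_idx, p_idx][lt]
      pcor(cor(xp, yv), cor(xp, zv), r_yz)
    }, numeric(1)))
    p <- (sum(perm_pr >= pr_obs) + 1) / (n_perm + 1)
  }
  structure(list(r = r_xy, p = p, n_perm = n_perm, kind = "partial",
                 partial_r = pr_obs, n_samples = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  stat <- if (x$kind == "partial") x$partial_r else x$r
  cat(sprintf("%s Mantel: r = %.4f, p = %s (n = %d, %d permutations)\n",
              x$kind, stat,
              if (is.na(x$p)) "NA" else format(x$p, digits = 4),
              x$n_samples, x$n_perm))
  invisible(x)
}

#' Classify the metacommunity paradigm from four Mantel outcomes
#'
#' Rule-based assignment from the significance pattern of the two partial
#' tests at level \code{alpha}:
#' \itemize{
#'   \item \code{[E|S]} significant, \code{[S|E]} not: \code{"SS"}
#'     (species sorting -- environment acts independently of space);
#'   \item both significant: \code{"SS+ME"} (sorting plus mass effect);
#'   \item \code{[S|E]} significant only: \code{"NM/PD"} (space-only
#'     signature; neutral model and patch dynamics are not separable from
#'     these tests);
#'   \item neither: \code{"UD"} (undetermined);
#'   \item any input an [nf_marker()]: \code{"NF"}.
#' }
#'
#' @param E,S simple Mantel results for community~environment and
#'   community~space (carried along for reporting).
#' @param E_given_S,S_given_E partial Mantel results.
#' @param alpha significance level (default 0.05).
#' @return An object of class \code{"metacommunity_class"} with elements
#'   \code{label}, \code{alpha} and the four inputs.
#' @export
classify_metacommunity <- function(E, S, E_given_S, S_given_E,
                                   alpha = 0.05) {
  inputs <- list(E = E, S = S, E_given_S = E_given_S, S_given_E = S_given_E)
  if (any(vapply(inputs, is_nf, logical(1)))) {
    return(structure(list(label = "NF", alpha = alpha, inputs = inputs),
                     class = "metacommunity_class"))
  }
  ns <- vapply(inputs, function(x) x$n_samples, numeric(1))
  if (length(unique(ns)) != 1)
    stop("mismatched sample sets among the four Mantel results")
  if (is.na(E_given_S$p) || is.na(S_given_E$p))
    stop("partial Mantel p-value missing (was n_perm = 0?)")
  sig_es <- E_given_S$p <= alpha
  sig_se <- S_given_E$p <= alpha
  label <- if (sig_es && sig_se) "SS+ME"
           else if (sig_es) "SS"
           else if (sig_se) "NM/PD"
           else "UD"
  structure(list(label = label, alpha = alpha, inputs = inputs),
            class = "metacommunity_class")
}

#' @export
print.metacommunity_class <- function(x, ...) {
  cat("metacommunity class:", x$label, "(alpha =", x$alpha, ")\n")
  invisible(x)
}

#' Run the full Mantel test battery over months x taxonomic groups
#'
#' For every cell of \{All, each month\} x \{All, each group\} the battery
#' computes \code{[E]} = Mantel(Bray-Curtis, environment), \code{[S]} =
#' Mantel(Bray-Curtis, space), \code{[E|S]} and \code{[S|E]} partial tests
#' on the cell's samples and OTUs, and classifies the cell's metacommunity
#' paradigm. Cells with fewer than \code{min_samples} usable samples, a
#' taxon matching no OTU, or otherwise degenerate distances are reported as
#' \code{"NF"} with the reason. With 7 months and 7 groups the grid has
#' \eqn{(1+7) \times (1+7) = 64} cells: 1 all-by-all, 7 month-by-all,
#' 7 all-by-group and 49 month-by-group.
#'
#' @param t a (rarefied) [otu_table()].
#' @param md a [sample_metadata()] collection covering the table's samples.
#' @param months month labels to analyze separately (default: those present
#'   in \code{md}, in configured order).
#' @param groups taxonomic group labels (default [default_taxon_groups()]).
#' @param n_perm permutations per test (default 999).
#' @param seed top-level seed; per-cell seeds are derived by cell index.
#' @param alpha significance level for classification.
#' @param min_samples minimum usable samples per cell (default 4).
#' @param env_vars environmental variables (default: all declared in
#'   \code{md}).
#' @param spatial_mode passed to [spatial_distance()].
#' @return An object of class \code{"mantel_battery"}: list with
#'   \code{results} (one row per cell: r/p for the four tests plus label)
#'   and \code{manifest} (every cell with its definition and status).
#' @export
mantel_battery <- function(t, md, months = NULL, groups = default_taxon_groups(),
                           n_perm = 999, seed = NULL, alpha = 0.05,
                           min_samples = 4, env_vars = env_variables(md),
                           spatial_mode = "euclidean-degrees") {
  stopifnot(is_otu_table(t))
  common <- intersect(rownames(t$counts), md$sample_id)
  extra <- c(setdiff(rownames(t$counts), md$sample_id),
             setdiff(md$sample_id, rownames(t$counts)))
  if (length(extra))
    message("mantel_battery: ", length(extra),
            " sample id(s) not shared between table and metadata: ",
            paste(extra, collapse = ", "))
  if (length(common) < min_samples)
    stop("fewer than min_samples shared samples")
  if (is.null(months))
    months <- intersect(attr(md, "months"), unique(as.character(md$month)))
  month_of <- setNames(as.character(md$month), md$sample_id)
  cells <- expand.grid(month = c("All", months), group = c("All", groups),
                       stringsAsFactors = FALSE)
  res_rows <- vector("list", nrow(cells))
  man_rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    mo <- cells$month[ci]; gr <- cells$group[ci]
    cell_seed <- if (is.null(seed)) NULL else seed + ci
    samp <- if (mo == "All") common else common[month_of[common] == mo]
    out <- .battery_cell(t, md, samp, gr, n_perm, cell_seed, alpha,
                         min_samples, env_vars, spatial_mode)
    res_rows[[ci]] <- data.frame(month = mo, group = gr, out$row,
                                 stringsAsFactors = FALSE)
    man_rows[[ci]] <- data.frame(month = mo, group = gr,
                                 n_samples = out$row$n_samples,
                                 status = out$status, reason = out$reason,
                                 stringsAsFactors = FALSE)
  }
  structure(list(results = do.call(rbind, res_rows),
                 manifest = do.call(rbind, man_rows),
                 alpha = alpha, n_perm = n_perm),
            class = "mantel_battery")
}

.battery_cell <- function(t, md, samp, group, n_perm, seed, alpha,
                          min_samples, env_vars, spatial_mode) {
  nf_row <- function(reason, n = length(samp)) {
    list(row = data.frame(n_samples = n, r_E = NA_real_, p_E = NA_real_,
                          r_S = NA_real_, p_S = NA_real_,
                          r_ES = NA_real_, p_ES = NA_real_,
                          r_SE = NA_real_, p_SE = NA_real_,
                          label = "NF", stringsAsFactors = FALSE),
         status = "NF", reason = reason)
  }
  tt <- otu_table(t$counts[samp, , drop = FALSE],
                  setNames(t$taxonomy, colnames(t$counts)))
  if (group != "All") {
    tt <- subset_by_taxon(tt, group)
    if (is_nf(tt)) return(nf_row(tt$reason))
  }
  usable <- rownames(tt$counts)[rowSums(tt$counts) > 0]
  if (length(usable) < min_samples)
    return(nf_row(paste0("only ", length(usable), " usable samples")))
  tt <- otu_table(tt$counts[usable, , drop = FALSE],
                  setNames(tt$taxonomy, colnames(tt$counts)))
  mds <- md[match(usable, md$sample_id), , drop = FALSE]
  out <- tryCatch({
    bc <- bray_curtis(tt)
    de <- env_distance(mds, env_vars, standardize = TRUE)
    ds <- spatial_distance(mds, spatial_mode)
    E  <- mantel_test(bc, de, n_perm, seed)
    S  <- mantel_test(bc, ds, n_perm,
                      if (is.null(seed)) NULL else seed + 100000L)
    ES <- partial_mantel(bc, de, ds, n_perm,
                         if (is.null(seed)) NULL else seed + 200000L)
    SE <- partial_mantel(bc, ds, de, n_perm,
                         if (is.null(seed)) NULL else seed + 300000L)
    cls <- classify_metacommunity(E, S, ES, SE, alpha)
    list(row = data.frame(n_samples = length(usable),
                          r_E = E$r, p_E = E$p, r_S = S$r, p_S = S$p,
                          r_ES = ES$partial_r, p_ES = ES$p,
                          r_SE = SE$partial_r, p_SE = SE$p,
                          label = cls$label, stringsAsFactors = FALSE),
         status = "ok", reason = "")
  }, error = function(e) nf_row(conditionMessage(e), length(usable)))
  out
}

#' @export
print.mantel_battery <- function(x, ...) {
  cat("mantel_battery:", nrow(x$results), "cells (",
      sum(x$manifest$status == "ok"), "computed,",
      sum(x$manifest$status == "NF"), "NF );",
      x$n_perm, "permutations per test\n")
  print(table(x$results$label))
  invisible(x)
}
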
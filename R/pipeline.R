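#' Default pipeline configuration
#'
#' @param ... overrides of the defaults shown in the function definition.
#' @return named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    otu = NULL, meta = NULL, tree = NULL,          # input paths, or ...
    simulate = NULL,                               # ... a scenario_config
    taxonomy_column = "taxonomy",
    env_variables = c("salinity", "temperature", "chla", "nh4", "no3",
                      "po4", "sio4"),
    months = NULL, groups = default_taxon_groups(),
    depth = 2500, n_perm = 999, n_null = 999, alpha = 0.05,
    min_samples = 4, spatial_mode = "euclidean-degrees",
    seed = 1L, out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the full assembly-inference pipeline
#'
#' rarefy -> NRI (per sample and by month) -> Mantel battery and
#' metacommunity classification -> Levins' niche breadth, bins, per-bin
#' explained variance and the breadth regression. Deterministic given the
#' config: every stage's seed is derived from \code{seed} by a fixed
#' offset, so stages can be rerun in isolation.
#'
#' @param config a [pipeline_config()] list, or a path to a JSON file with
#'   the same fields (a \code{simulate} entry is passed to
#'   [scenario_config()]).
#' @return Invisibly, a list with every intermediate and final result. When
#'   \code{out_dir} is set, writes \code{nri.tsv}, \code{nri_by_month.tsv},
#'   \code{battery.tsv}, \code{classes.tsv}, \code{niche_breadth.tsv},
#'   \code{bins_summary.tsv}, \code{bin_variance.tsv},
#'   \code{regression.tsv}, \code{manifest.json} and \code{run_log.txt}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    raw <- jsonlite::read_json(config, simplifyVector = TRUE)
    sim <- raw$simulate
    raw$simulate <- NULL
    config <- do.call(pipeline_config, raw)
    if (!is.null(sim)) config$simulate <- do.call(scenario_config, sim)
  }
  cfg <- config
  log_lines <- c(paste0("metacomm ", as.character(utils::packageVersion("metacomm")),
                        " | R ", R.version.string),
                 paste0("seed: ", cfg$seed))
  logit <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  # -- inputs ----------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim <- simulate_metacommunity(cfg$simulate)
    t_raw <- sim$otu; md <- sim$metadata; tree <- sim$tree
    logit("simulated scenario: regime ", cfg$simulate$regime,
          ", seed ", cfg$simulate$seed)
  } else {
    t_raw <- read_otu_table(cfg$otu, cfg$taxonomy_column)
    md <- read_sample_metadata(cfg$meta, cfg$env_variables,
                               months = cfg$months %||% default_months())
    tree <- read_tree(cfg$tree)
    sim <- NULL
  }
  sdiff <- c(setdiff(rownames(t_raw$counts), md$sample_id),
             setdiff(md$sample_id, rownames(t_raw$counts)))
  if (length(sdiff))
    stop("sample id mismatch between OTU table and metadata; ",
         "symmetric difference: ", paste(sdiff, collapse = ", "))

  # -- rarefaction -----------------------------------------------------
  t <- withCallingHandlers(
    rarefy(t_raw, cfg$depth, seed = cfg$seed + 1L),
    message = function(m) {
      log_lines <<- c(log_lines, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  md <- sample_metadata(
    as.data.frame(md)[md$sample_id %in% rownames(t$counts), , drop = FALSE],
    env_variables(md), attr(md, "months"))
  logit("rarefied to depth ", cfg$depth, ": ", nrow(t$counts),
        " samples x ", ncol(t$counts), " OTUs")

  # -- NRI -------------------------------------------------------------
  d_phylo <- patristic_matrix(tree,
                              intersect(colnames(t$counts), tree$tip.label))
  nri_res <- suppressMessages(
    nri_samples(t, d_phylo, n_null = cfg$n_null, seed = cfg$seed + 1000L))
  nri_month <- suppressWarnings(nri_month_summary(nri_res, md))
  logit("NRI: ", nrow(nri_res), " samples, ",
        sum(nri_res$significant), " significant")

  # -- Mantel battery and classification -------------------------------
  battery <- suppressMessages(mantel_battery(
    t, md, months = cfg$months, groups = cfg$groups, n_perm = cfg$n_perm,
    seed = cfg$seed + 2000L, alpha = cfg$alpha,
    min_samples = cfg$min_samples, env_vars = cfg$env_variables,
    spatial_mode = cfg$spatial_mode))
  nf_cells <- battery$manifest[battery$manifest$status == "NF", , drop = FALSE]
  for (i in seq_len(nrow(nf_cells)))
    logit("NF cell ", nf_cells$month[i], " x ", nf_cells$group[i], ": ",
          nf_cells$reason[i])

  # -- niche breadth ---------------------------------------------------
  profiles <- levins_b(t)
  binned <- bin_by_breadth(profiles, t = t)
  bin_var <- breadth_partition_analysis(
    t, md, binned, n_perm = cfg$n_perm, seed = cfg$seed + 3000L,
    min_samples = cfg$min_samples, env_vars = cfg$env_variables,
    spatial_mode = cfg$spatial_mode)
  regression <- tryCatch(breadth_regression(bin_var), error = function(e) {
    logit("breadth regression skipped: ", conditionMessage(e)); NULL
  })

  out <- list(config = cfg, otu = t, metadata = md, tree = tree,
              simulation = sim, nri = nri_res, nri_by_month = nri_month,
              battery = battery, niche_profiles = binned$profiles,
              bins_summary = binned$summary, bin_variance = bin_var,
              regression = regression, log = log_lines)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) write_results_table(x, file.path(cfg$out_dir, f))
    w(nri_res, "nri.tsv"); w(nri_month, "nri_by_month.tsv")
    w(battery$results, "battery.tsv")
    w(battery$results[c("month", "group", "n_samples", "label")],
      "classes.tsv")
    w(binned$profiles, "niche_breadth.tsv")
    w(binned$summary, "bins_summary.tsv")
    w(bin_var, "bin_variance.tsv")
    if (!is.null(regression))
      w(data.frame(slope = regression$slope,
                   intercept = regression$intercept,
                   r_squared = regression$r_squared,
                   p_value = regression$p_value, n = regression$n),
        "regression.tsv")
    jsonlite::write_json(
      list(cells = battery$manifest,
           n_perm = cfg$n_perm, n_null = cfg$n_null, alpha = cfg$alpha,
           depth = cfg$depth, seed = cfg$seed),
      file.path(cfg$out_dir, "manifest.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  }
  invisible(out)
}
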
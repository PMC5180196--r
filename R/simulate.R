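#' Scenario configuration for the synthetic metacommunity generator
#'
#' The stated world mimics a monthly transect campaign: 13 stations sampled
#' April through October (91 sample slots; the real campaign retained 63),
#' 2500 reads per sample after rarefaction, and OTUs whose niche optima
#' evolve on a phylogeny. Defaults are chosen once and documented in the
#' methods vignette; \code{regime} selects the assembly process that
#' generated the data.
#'
#' @param regime one of \code{"SS"} (species sorting: Gaussian niche
#'   response to a latent environmental axis), \code{"ME"} (mass effect:
#'   the SS response blended with immigration from neighboring persistent
#'   source populations -- the time-averaged SS field convolved with an
#'   exponential dispersal kernel along the transect), \code{"PD"} (patch
#'   dynamics: dispersal kernels around random source stations, no
#'   environmental dependence), \code{"NM"} (neutral: one lognormal
#'   species-abundance distribution everywhere).
#' @param n_stations stations along the transect (default 13).
#' @param months ordered month labels (default [default_months()]).
#' @param n_otus number of OTUs simulated (default 200; desk-scale stand-in
#'   for the thousands in a real survey).
#' @param depth reads per sample (default 2500).
#' @param niche_width_generalist,niche_width_specialist Gaussian niche
#'   widths on the latent axis (latent units; defaults 3 and 0.4 -- the
#'   latent axis spans about \[-2, 2\] plus season).
#' @param frac_generalists fraction of OTUs that are generalists
#'   (default 0.3).
#' @param generalist_boost multiplicative abundance advantage of
#'   generalists (default 20; generalists are the common "core" taxa).
#' @param dispersal_length exponential kernel scale in station units
#'   (default 1.5).
#' @param mass_effect_strength in \[0, 1\]: under \code{"ME"}, the share of
#'   expected abundance contributed by kernel-weighted immigration from the
#'   time-averaged neighboring source populations (default 0.5).
#' @param phylo_signal in \[0, 1\]: share of niche-optimum variance from
#'   Brownian evolution on the tree vs. independent noise (default 0.8).
#' @param season_amplitude seasonal swing of the latent axis (default 1.5).
#' @param gradient_amplitude peak-to-peak spatial swing of the latent axis
#'   along the transect (default 1.0).
#' @param env_noise_sd station-by-month latent noise sd (default 0.8):
#'   local environmental patchiness that species sorting tracks and
#'   dispersal smooths over.
#' @param obs_noise_sd measurement noise sd, as a fraction of each
#'   environmental variable's latent-driven sd (default 0.05).
#' @param n_samples optional subsample of sample slots (e.g. 63), drawn
#'   uniformly without replacement.
#' @param seed integer master seed; all randomness derives from it.
#' @return A list of class \code{"scenario_config"}.
#' @export
scenario_config <- function(regime = c("SS", "ME", "PD", "NM"),
                            n_stations = 13, months = default_months(),
                            n_otus = 200, depth = 2500,
                            niche_width_generalist = 3,
                            niche_width_specialist = 0.4,
                            frac_generalists = 0.3,
                            generalist_boost = 20,
                            dispersal_length = 1.5,
                            mass_effect_strength = 0.5,
                            phylo_signal = 0.8,
                            season_amplitude = 1.5,
                            gradient_amplitude = 1.0,
                            env_noise_sd = 0.8,
                            obs_noise_sd = 0.05,
                            n_samples = NULL,
                            seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(n_stations >= 2, length(months) >= 1, n_otus >= 2, depth >= 1,
            niche_width_generalist > 0, niche_width_specialist > 0,
            frac_generalists >= 0, frac_generalists <= 1,
            dispersal_length > 0, phylo_signal >= 0, phylo_signal <= 1,
            mass_effect_strength >= 0, mass_effect_strength <= 1)
  structure(list(regime = regime, n_stations = n_stations, months = months,
                 n_otus = n_otus, depth = depth,
                 niche_width_generalist = niche_width_generalist,
                 niche_width_specialist = niche_width_specialist,
                 frac_generalists = frac_generalists,
                 generalist_boost = generalist_boost,
                 dispersal_length = dispersal_length,
                 mass_effect_strength = mass_effect_strength,
                 phylo_signal = phylo_signal,
                 season_amplitude = season_amplitude,
                 gradient_amplitude = gradient_amplitude,
                 env_noise_sd = env_noise_sd, obs_noise_sd = obs_noise_sd,
                 n_samples = n_samples, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a random phylogeny for the OTU pool
#'
#' A random coalescent tree ([ape::rcoal()]): ultrametric, with long shared
#' interior branches, so Brownian traits evolved on it carry clear
#' clade-level structure (which is what gives the NRI something to detect).
#' Tips are labeled \code{OTU_1 .. OTU_n}; deterministic given the seed.
#'
#' @param n_otus number of tips (>= 2).
#' @param seed integer seed.
#' @return A \code{"phylo"} tree.
#' @export
simulate_tree <- function(n_otus, seed = 1L) {
  stopifnot(n_otus >= 2)
  tree <- with_seed(seed, ape::rcoal(n_otus))
  tree$tip.label <- paste0("OTU_", seq_len(n_otus))
  tree
}

#' Simulate transect sample metadata
#'
#' Stations sit on a 1-D south-north transect (about 0.9 degrees of
#' latitude, mirroring a ~100 km campaign). A latent environmental axis is
#' the sum of a linear spatial gradient, a seasonal offset peaking in
#' mid-summer, and station-by-month noise; the seven emitted variables
#' (salinity, temperature, chla, nh4, no3, po4, sio4) are noisy linear maps
#' of that axis. The latent axis is attached as attribute \code{"latent"}
#' (one value per sample row) for ground-truth checks.
#'
#' @param cfg a [scenario_config()].
#' @return A [sample_metadata()] collection with one row per station x
#'   month slot and attributes \code{latent}, \code{station},
#'   \code{station_pos}.
#' @export
simulate_environment <- function(cfg) {
  S <- cfg$n_stations; M <- length(cfg$months)
  pos <- seq_len(S) - 1
  spatial <- cfg$gradient_amplitude * (pos / max(pos, 1) - 0.5)
  seasonal <- if (M > 1)
    cfg$season_amplitude * sin(pi * (seq_len(M) - 1) / (M - 1)) else 0
  with_seed(cfg$seed + 2L, {
    latent <- outer(spatial, seasonal, "+") +
      matrix(rnorm(S * M, sd = cfg$env_noise_sd), S, M)
    # variable = intercept + slope * latent + measurement noise
    spec <- list(salinity    = c(6.5, -1.2), temperature = c(10, 3.0),
                 chla        = c(3.0,  1.0), nh4         = c(0.5, -0.3),
                 no3         = c(2.0, -0.8), po4         = c(0.6, -0.2),
                 sio4        = c(12,   2.0))
    lat <- 56.2 + 0.075 * pos
    lon <- 16.5 + 0.020 * pos
    rows <- expand.grid(station = seq_len(S), month_i = seq_len(M))
    lv <- latent[cbind(rows$station, rows$month_i)]
    df <- data.frame(
      sample_id = sprintf("S%02d_%s", rows$station, cfg$months[rows$month_i]),
      month = cfg$months[rows$month_i],
      latitude = lat[rows$station], longitude = lon[rows$station],
      stringsAsFactors = FALSE)
    for (v in names(spec)) {
      drive <- spec[[v]][1] + spec[[v]][2] * lv
      noise_sd <- cfg$obs_noise_sd * abs(spec[[v]][2]) *
        max(sd(lv), .Machine$double.eps)
      df[[v]] <- drive + rnorm(nrow(df), sd = noise_sd)
    }
    md <- sample_metadata(df, names(spec), months = cfg$months)
    attr(md, "latent") <- lv
    attr(md, "station") <- rows$station
    attr(md, "station_pos") <- pos
    md
  })
}

#' Simulate a metacommunity dataset with known assembly regime
#'
#' Produces an OTU count table, matching metadata, the phylogeny and a
#' ground-truth record. Expected relative abundances follow the configured
#' regime (see [scenario_config()]); reads are then drawn multinomially at
#' \code{depth} per sample. OTUs receiving zero reads everywhere are pruned
#' from the table (their tips remain on the tree). Byte-identical for a
#' given configuration.
#'
#' @param cfg a [scenario_config()].
#' @return list with elements \code{otu} ([otu_table()]), \code{metadata},
#'   \code{tree}, \code{truth} (regime, per-OTU niche optima/widths,
#'   generalist flags, base abundances, latent axis).
#' @export
simulate_metacommunity <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  tree <- simulate_tree(cfg$n_otus, cfg$seed + 1L)
  md <- simulate_environment(cfg)
  n <- cfg$n_otus
  S <- cfg$n_stations; M <- length(cfg$months)
  station <- attr(md, "station")
  pos <- attr(md, "station_pos")
  lv <- attr(md, "latent")
  sim <- with_seed(cfg$seed + 3L, {
    # niche optima: Brownian on the tree blended with independent noise
    bm <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    bm <- (bm - mean(bm)) / max(sd(bm), .Machine$double.eps)
    eps <- rnorm(n)
    opt <- 1.6 * (sqrt(cfg$phylo_signal) * bm[paste0("OTU_", seq_len(n))] +
                    sqrt(1 - cfg$phylo_signal) * eps)
    generalist <- runif(n) < cfg$frac_generalists
    width <- ifelse(generalist, cfg$niche_width_generalist,
                    cfg$niche_width_specialist)
    base <- rlnorm(n, meanlog = 0, sdlog = 1)
    base[generalist] <- base[generalist] * cfg$generalist_boost
    n_slots <- nrow(md)
    expected <- matrix(0, n_slots, n)
    sources <- NULL
    if (cfg$regime %in% c("SS", "ME")) {
      for (j in seq_len(n))
        expected[, j] <- base[j] *
          exp(-(lv - opt[j])^2 / (2 * width[j]^2))
      if (cfg$regime == "ME") {
        # immigration from persistent source populations: the kernel acts on
        # each station's time-averaged local field, blended with local sorting
        K <- exp(-abs(outer(pos, pos, "-")) / cfg$dispersal_length)
        K <- K / rowSums(K)
        mean_field <- apply(expected, 2, function(col) tapply(col, station, mean))
        immigrants <- K %*% mean_field
        rho <- cfg$mass_effect_strength
        expected <- (1 - rho) * expected + rho * immigrants[station, ]
      }
    } else if (cfg$regime == "PD") {
      sources <- sample.int(S, n, replace = TRUE)
      for (j in seq_len(n))
        expected[, j] <- base[j] *
          exp(-abs(pos[station] - pos[sources[j]]) / cfg$dispersal_length)
    } else {                                       # NM
      expected <- matrix(base, n_slots, n, byrow = TRUE)
    }
    keep <- seq_len(n_slots)
    if (!is.null(cfg$n_samples) && cfg$n_samples < n_slots)
      keep <- sort(sample.int(n_slots, cfg$n_samples))
    counts <- matrix(0L, length(keep), n,
                     dimnames = list(md$sample_id[keep],
                                     paste0("OTU_", seq_len(n))))
    for (si in seq_along(keep)) {
      pr <- expected[keep[si], ]
      pr <- pr / sum(pr)
      counts[si, ] <- as.integer(rmultinom(1, cfg$depth, pr))
    }
    groups <- c(default_taxon_groups(), "Unclassified")
    gsel <- sample(groups, n, replace = TRUE,
                   prob = c(rep(0.13, 7), 0.09))
    tax <- ifelse(grepl("proteobacteria", gsel),
                  paste0("Bacteria;Proteobacteria;", gsel),
                  ifelse(gsel == "Unclassified", "Unclassified",
                         paste0("Bacteria;", gsel)))
    list(counts = counts, tax = setNames(tax, colnames(counts)),
         opt = opt, width = width, generalist = generalist, base = base,
         sources = sources, keep = keep)
  })
  nonzero <- colSums(sim$counts) > 0L
  t <- otu_table(sim$counts[, nonzero, drop = FALSE], sim$tax[nonzero])
  md_keep <- md[sim$keep, , drop = FALSE]
  md_keep <- sample_metadata(as.data.frame(md_keep), env_variables(md),
                             months = cfg$months)
  truth <- list(regime = cfg$regime, opt = sim$opt, width = sim$width,
                generalist = sim$generalist, base = sim$base,
                sources = sim$sources, latent = lv[sim$keep],
                config = cfg)
  list(otu = t, metadata = md_keep, tree = tree, truth = truth)
}
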
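#' Configuration for the synthetic community generator
#'
#' Defaults encode the field design being emulated: a five-site regional
#' survey (plots per site 4,4,3,4,4 after one decommissioned block, two
#' N-treatment subplots per plot, three cores per subplot, one collection)
#' and a single-site growing season (four plots, 15 biweekly soil
#' collections with roots on every second collection from the fifth, so 6
#' root dates), with 10,000 reads per sample.
#'
#' @param design `"mle"` (regional), `"lux_arbor"` (growing season) or
#'   `"custom"`.
#' @param n_taxa taxon pool size.
#' @param depth reads per sample.
#' @param site_sigma SD of per-site log-scale offsets for structured taxa.
#' @param date_amplitude amplitude of the seasonal log-scale curve.
#' @param spatial_range range (m) of the exponential spatial covariance;
#'   0 disables the spatial field.
#' @param spatial_sigma SD of the spatial field.
#' @param n_effect log-scale shift applied in N-addition subplots to a
#'   random 10% of structured taxa (weak by design).
#' @param core_fraction fraction of taxa forced to full occupancy at high
#'   abundance.
#' @param neutral_fraction fraction of taxa assembled by the Sloan neutral
#'   process.
#' @param m neutral migration probability.
#' @param root_lag_days lag with which root communities track soil.
#' @param root_mix_weight weight of the lagged soil community in root
#'   samples (the rest is niche-specific).
#' @param sites,plots_per_site,n_dates design overrides for
#'   `design = "custom"`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(design = c("mle", "lux_arbor", "custom"),
                       n_taxa = 400, depth = 10000,
                       site_sigma = 0.5, date_amplitude = 0.5,
                       spatial_range = 30, spatial_sigma = 0.25,
                       n_effect = 0.1,
                       core_fraction = 0.05, neutral_fraction = 0.3,
                       m = 0.1, root_lag_days = 14, root_mix_weight = 0.7,
                       sites = NULL, plots_per_site = NULL, n_dates = NULL) {
  design <- match.arg(design)
  stopifnot(core_fraction >= 0, neutral_fraction >= 0,
            core_fraction + neutral_fraction <= 1,
            site_sigma >= 0, date_amplitude >= 0, spatial_range >= 0,
            n_effect >= 0, m > 0, m <= 1)
  structure(as.list(environment()), class = "sim_config")
}

iso <- function(x) format(x, "%Y-%m-%d")

#' Generate the sampling scaffold (metadata) for a design
#'
#' The regional scaffold has 5 sites with plots (4,4,3,4,4) — one block
#' decommissioned at one site — two N subplots per plot and three cores
#' per subplot on a single date; the growing-season scaffold has 4 plots
#' sampled over 15 biweekly soil dates with roots collected on 6 of them
#' (every second date from the fifth). Both niches share core points, so
#' root and soil samples are spatially paired. UTM coordinates are drawn
#' within 19.5 m plot rectangles; sites are spaced tens of kilometres
#' apart.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for coordinates.
#' @return validated metadata data.frame with a `core` column.
#' @export
simulate_design <- function(config, seed = 1L) {
  set.seed(seed)
  plot_w <- 19.5
  if (config$design == "mle") {
    sites <- c("LUX", "LC", "ESC", "HAN", "RHN")
    pps <- c(4, 4, 4, 3, 4)
    dates <- list(soil = as.Date("2018-07-30"), root = as.Date("2018-07-30"))
  } else if (config$design == "lux_arbor") {
    sites <- "LUX"
    pps <- 4
    soil_dates <- as.Date("2018-03-19") + 14 * (0:14)
    root_dates <- soil_dates[seq(5, 15, by = 2)]
    dates <- list(soil = soil_dates, root = root_dates)
  } else {
    sites <- config$sites
    pps <- config$plots_per_site
    dates <- list(soil = as.Date("2018-07-30"), root = as.Date("2018-07-30"))
    if (!is.null(config$n_dates))
      dates <- list(soil = as.Date("2018-03-19") + 14 * seq_len(config$n_dates) - 14,
                    root = as.Date("2018-03-19") + 14 * seq_len(config$n_dates) - 14)
  }
  site_xy <- cbind(runif(length(sites), 0, 4e5), runif(length(sites), 0, 4e5))
  rows <- list()
  for (s in seq_along(sites)) {
    for (p in seq_len(pps[s])) {
      plot_xy <- site_xy[s, ] + c((p - 1) * 50, 0)
      for (trt in c("control", "N")) {
        # one subplot rectangle = half the plot
        off_x <- if (trt == "N") plot_w / 2 else 0
        for (core in 1:3) {
          xy <- plot_xy + c(off_x + runif(1, 0, plot_w / 2),
                            runif(1, 0, plot_w))
          for (niche in c("soil", "root")) {
            for (dt in seq_along(dates[[niche]])) {
              rows[[length(rows) + 1]] <- data.frame(
                niche = niche, site = sites[s], plot = paste0("p", p),
                subplot = trt, n_treatment = trt,
                collection_date = iso(dates[[niche]][dt]),
                easting = xy[1], northing = xy[2],
                core = paste0("c", core))
            }
          }
        }
      }
    }
  }
  meta <- do.call(rbind, rows)
  meta$sample_id <- sprintf("%s_%s_%s_%s_%s_%s", substr(meta$niche, 1, 1),
                            meta$site, meta$plot, meta$n_treatment,
                            meta$core, gsub("-", "", meta$collection_date))
  meta <- meta[, c("sample_id", "niche", "site", "plot", "subplot",
                   "n_treatment", "collection_date", "easting", "northing",
                   "core")]
  validate_metadata(meta)
}

# exponential-covariance Gaussian field over sample coordinates
spatial_field <- function(xy, range_m, sigma) {
  n <- nrow(xy)
  if (range_m <= 0 || sigma <= 0) return(rep(0, n))
  D <- as.matrix(stats::dist(xy))
  S <- sigma^2 * exp(-D / range_m)
  L <- chol(S + diag(1e-8, n))
  drop(t(L) %*% stats::rnorm(n))
}

#' Simulate OTU tables with known ground truth
#'
#' Taxa are partitioned into core (forced to full occupancy at high
#' abundance), neutral (per-sample relative abundances drawn from the
#' Sloan Beta process at migration rate m) and structured taxa. Structured
#' taxa start from a log-normal abundance pool and receive multiplicative
#' log-scale effects: per-site offsets (SD `site_sigma`), smooth seasonal
#' curves (amplitude `date_amplitude`, random phase per taxon), a
#' spatially autocorrelated field with exponential covariance (range
#' `spatial_range` m, one independent field per taxon), and an N-addition
#' shift (`n_effect`) on a random 10% of structured taxa. Root samples
#' are a convex mixture of the soil expectation of the same subplot
#' lagged by `root_lag_days` (weight `root_mix_weight`) and root-specific
#' taxa. Counts are multinomial at `depth` reads.
#'
#' @param config a [sim_config()].
#' @param meta scaffold from [simulate_design()].
#' @param seed integer seed.
#' @return list: `table` ([otu_table()] over all samples of both niches),
#'   `meta`, `truth` (taxon membership, m, N-responsive taxa, per-site
#'   offsets, seed).
#' @export
simulate_community <- function(config, meta, seed = 1L) {
  set.seed(seed)
  nt <- config$n_taxa
  n_core <- round(config$core_fraction * nt)
  n_neut <- round(config$neutral_fraction * nt)
  membership <- rep("structured", nt)
  if (n_core > 0) membership[seq_len(n_core)] <- "core"
  if (n_neut > 0) membership[n_core + seq_len(n_neut)] <- "neutral"
  taxon_id <- sprintf("OTU%04d", seq_len(nt))

  # baseline log-normal pool; core taxa at the top so occupancy is 1
  base <- stats::rnorm(nt, 0, 1.5)
  base[membership == "core"] <- stats::rnorm(n_core, 4, 0.5)
  neut <- membership == "neutral"
  p_neut <- {   # neutral taxa mean relative abundances from the same pool
    w <- exp(stats::rnorm(n_neut, 0, 1.5))
    w / sum(w)
  }

  ns <- nrow(meta)
  sites <- factor(meta$site)
  site_off <- matrix(stats::rnorm(nlevels(sites) * nt, 0, config$site_sigma),
                     nlevels(sites), nt)
  phase <- stats::runif(nt, 0, 2 * pi)
  doy <- as.integer(format(as.Date(meta$collection_date), "%j"))
  n_struct <- sum(membership == "structured")
  n_resp <- if (n_struct > 0)
    sample(which(membership == "structured"),
           max(1, round(0.1 * n_struct)))
  else integer(0)

  struct_ix <- which(membership != "neutral")  # core + structured share the
  # multiplicative-effects model; core taxa just sit higher in the pool
  loglam <- matrix(rep(base[struct_ix], each = ns), ns, length(struct_ix))
  loglam <- loglam + site_off[as.integer(sites), struct_ix, drop = FALSE]
  if (config$date_amplitude > 0)
    loglam <- loglam + config$date_amplitude *
      sin(outer(2 * pi * doy / 365, rep(1, length(struct_ix))) +
            matrix(rep(phase[struct_ix], each = ns), ns))
  if (config$spatial_range > 0 && config$spatial_sigma > 0) {
    xy <- cbind(meta$easting, meta$northing)
    for (k in seq_along(struct_ix))
      loglam[, k] <- loglam[, k] +
        spatial_field(xy, config$spatial_range, config$spatial_sigma)
  }
  isN <- meta$n_treatment == "N"
  respk <- match(intersect(n_resp, struct_ix), struct_ix)
  loglam[isN, respk] <- loglam[isN, respk] + config$n_effect

  # per-sample expected proportions: structured share scaled to 1 - neutral
  P <- matrix(0, ns, nt, dimnames = list(meta$sample_id, taxon_id))
  w_neut <- if (n_neut > 0) config$neutral_fraction else 0
  lam <- exp(loglam)
  P[, struct_ix] <- (1 - w_neut) * lam / rowSums(lam)
  if (n_neut > 0) {
    a <- config$depth * config$m
    nb <- matrix(stats::rbeta(ns * n_neut,
                              rep(a * p_neut, each = ns),
                              rep(a * (1 - p_neut), each = ns)), ns, n_neut)
    P[, neut] <- w_neut * nb / pmax(rowSums(nb), 1e-12)
  }

  # root samples track the soil expectation of their subplot, lagged
  is_root <- meta$niche == "root"
  if (any(is_root)) {
    skey <- paste(meta$site, meta$plot, meta$subplot, meta$collection_date)
    soil_ix <- which(!is_root)
    for (i in which(is_root)) {
      lag_date <- iso(as.Date(meta$collection_date[i]) - config$root_lag_days)
      key <- paste(meta$site[i], meta$plot[i], meta$subplot[i], lag_date)
      src <- soil_ix[skey[soil_ix] == key]
      if (length(src) == 0) {  # no lagged collection: use same-day soil
        key <- paste(meta$site[i], meta$plot[i], meta$subplot[i],
                     as.character(meta$collection_date[i]))
        src <- soil_ix[skey[soil_ix] == key]
      }
      if (length(src) > 0) {
        soil_mean <- colMeans(P[src, , drop = FALSE])
        P[i, ] <- config$root_mix_weight * soil_mean +
          (1 - config$root_mix_weight) * P[i, ]
      }
    }
  }

  counts <- t(vapply(seq_len(ns), function(i)
    stats::rmultinom(1, config$depth, P[i, ])[, 1], integer(nt)))
  dimnames(counts) <- list(meta$sample_id, taxon_id)

  truth <- list(membership = stats::setNames(membership, taxon_id),
                m = config$m, depth = config$depth,
                n_responsive = taxon_id[n_resp],
                site_offsets = site_off, seed = seed)
  list(table = otu_table(counts), meta = meta, truth = truth)
}
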
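#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the regional (multi-site, single date) analysis end to end
#'
#' rarefy -> Bray-Curtis -> nested PERMANOVA (site / N design) -> beta
#' dispersion -> PROTEST between niches -> GDM with deviance partition ->
#' core community across sites. Each stage writes its outputs under
#' `out_dir`, plus a JSON manifest recording inputs, seeds and package
#' version, so any stage can be re-run from files.
#'
#' @param table [otu_table()] covering both niches (e.g. from
#'   [simulate_community()]).
#' @param meta validated metadata.
#' @param out_dir output directory (created).
#' @param depth rarefaction depth.
#' @param predictors optional per-sample predictor data.frame for the GDM
#'   (beyond the spatial distance).
#' @param gdm_groups named list of predictor groups for deviance
#'   partitioning (defaults to spatial only, or spatial + each predictor
#'   group supplied).
#' @param n_perm permutations for PERMANOVA/PROTEST/dispersion.
#' @param core_threshold Bray-Curtis change threshold for core selection.
#' @param seed master seed; stage seeds are derived from it.
#' @return list of stage results (also written to `out_dir`).
#' @export
run_regional <- function(table, meta, out_dir, depth = 10000,
                         predictors = NULL, gdm_groups = NULL,
                         n_perm = 999, core_threshold = 0.05, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- seed + 0:9
  res <- list()

  rar <- run_stage("rarefy", {
    r <- rarefy(table, depth = depth, seed = seeds[1])
    write_tsv(r$dropped, file.path(out_dir, "dropped_samples.tsv"))
    r
  })
  meta <- meta[meta$sample_id %in% rownames(rar$table), ]
  niches <- split(meta$sample_id, meta$niche)
  if (length(niches) < 2) stop("need both root and soil samples")

  res$permanova <- list()
  res$dispersion <- list()
  dms <- list()
  for (ni in names(niches)) {
    sub <- rar$table[niches[[ni]], ]
    sub <- sub[, colSums(sub) > 0]
    dm <- run_stage("bray_curtis", bray_curtis(sub))
    dms[[ni]] <- dm
    nm <- meta[match(niches[[ni]], meta$sample_id), ]
    pt <- run_stage("permanova",
                    permanova(dm, nm, design_regional(), n_perm = n_perm,
                              seed = seeds[2]))
    write_tsv(pt$table, file.path(out_dir, paste0("permanova_", ni, ".tsv")))
    res$permanova[[ni]] <- pt
    bd <- run_stage("beta_dispersion",
                    beta_dispersion(dm, nm$site, n_perm = n_perm,
                                    seed = seeds[3]))
    write_tsv(data.frame(sample_id = names(bd$distances),
                         distance_to_median = bd$distances),
              file.path(out_dir, paste0("dispersion_", ni, ".tsv")))
    res$dispersion[[ni]] <- bd
  }

  res$protest <- run_stage("protest", {
    ords <- lapply(dms, ordinate, k = 2, seed = seeds[4])
    # shared core points: compare niches on matched sampling positions
    key <- function(ids) {
      i <- match(ids, meta$sample_id)
      paste(meta$site[i], meta$plot[i], meta$subplot[i], meta$core[i],
            meta$collection_date[i])
    }
    a <- ords[[1]]$points
    b <- ords[[2]]$points
    rownames(a) <- key(rownames(a))
    rownames(b) <- key(rownames(b))
    pr <- protest(a, b, n_perm = n_perm, seed = seeds[5])
    write_tsv(data.frame(position = names(pr$residuals),
                         residual = pr$residuals),
              file.path(out_dir, "protest_residuals.tsv"))
    pr
  })

  res$gdm <- run_stage("gdm", {
    out <- list()
    for (ni in names(niches)) {
      nm <- meta[match(niches[[ni]], meta$sample_id), ]
      pairs <- build_pair_table(dms[[ni]], nm, predictors)
      preds <- c("geo", if (!is.null(predictors))
        setdiff(names(predictors), "sample_id"))
      fit <- fit_gdm(pairs, preds)
      groups <- if (!is.null(gdm_groups)) gdm_groups else
        c(list(spatial = "geo"),
          if (!is.null(predictors))
            list(env = setdiff(names(predictors), "sample_id")))
      part <- partition_deviance(pairs, groups)
      write_tsv(part$partition,
                file.path(out_dir, paste0("gdm_partition_", ni, ".tsv")))
      out[[ni]] <- list(model = fit, partition = part)
    }
    out
  })

  res$core <- run_stage("core", {
    out <- list()
    for (ni in names(niches)) {
      sub <- rar$table[niches[[ni]], ]
      sub <- sub[, colSums(sub) > 0]
      nm <- meta[match(niches[[ni]], meta$sample_id), ]
      st <- occupancy_abundance(sub, nm, group_by = "site")
      rk <- rank_taxa(st)
      cv <- bc_contribution_curve(sub, rk)
      cr <- select_core(cv, sub, threshold = core_threshold)
      nf <- fit_neutral(st, N = depth, n_samples = nrow(sub))
      write_tsv(cr$curve, file.path(out_dir, paste0("core_curve_", ni, ".tsv")))
      write_tsv(nf$taxa, file.path(out_dir, paste0("neutral_", ni, ".tsv")))
      out[[ni]] <- list(stats = st, core = cr, neutral = nf)
    }
    out
  })

  manifest <- list(analysis = "regional", seed = seed, seeds = seeds,
                   depth = depth, n_perm = n_perm,
                   core_threshold = core_threshold,
                   n_samples = nrow(rar$table),
                   dropped = rar$dropped$sample_id,
                   version = as.character(utils::packageVersion("spatiomic")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

#' Run the growing-season (single-site time series) analysis end to end
#'
#' rarefy -> Bray-Curtis -> nested PERMANOVA (date / N design) -> PROTEST
#' between niches on shared dates -> GDM (spatial + temporal, soil runs
#' restricted to root dates) -> lagged root-soil similarity (14 days) ->
#' core community across dates.
#'
#' @inheritParams run_regional
#' @param lag_days root-soil comparison lag.
#' @return list of stage results (also written to `out_dir`).
#' @export
run_growing_season <- function(table, meta, out_dir, depth = 10000,
                               predictors = NULL, n_perm = 999,
                               core_threshold = 0.05, lag_days = 14,
                               seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- seed + 0:9
  res <- list()

  rar <- run_stage("rarefy", rarefy(table, depth = depth, seed = seeds[1]))
  meta <- meta[meta$sample_id %in% rownames(rar$table), ]
  niches <- split(meta$sample_id, meta$niche)
  if (length(niches) < 2) stop("need both root and soil samples")
  root_dates <- unique(meta$collection_date[meta$niche == "root"])
  shared <- intersect(as.character(root_dates),
                      as.character(meta$collection_date[meta$niche == "soil"]))
  if (length(shared) == 0) stop("no shared collection dates between niches")

  res$permanova <- list()
  dms <- list()
  for (ni in names(niches)) {
    sub <- rar$table[niches[[ni]], ]
    sub <- sub[, colSums(sub) > 0]
    dm <- run_stage("bray_curtis", bray_curtis(sub))
    dms[[ni]] <- dm
    nm <- meta[match(niches[[ni]], meta$sample_id), ]
    pt <- run_stage("permanova",
                    permanova(dm, nm, design_season(), n_perm = n_perm,
                              seed = seeds[2]))
    write_tsv(pt$table, file.path(out_dir, paste0("permanova_", ni, ".tsv")))
    res$permanova[[ni]] <- pt
  }

  res$gdm <- run_stage("gdm", {
    out <- list()
    for (ni in names(niches)) {
      nm <- meta[match(niches[[ni]], meta$sample_id), ]
      restrict <- if (ni == "soil") root_dates else NULL
      pairs <- build_pair_table(dms[[ni]], nm, predictors,
                                restrict_dates = restrict)
      preds <- c("geo", "days", if (!is.null(predictors))
        setdiff(names(predictors), "sample_id"))
      fit <- fit_gdm(pairs, preds)
      groups <- c(list(spatial = "geo", temporal = "days"),
                  if (!is.null(predictors))
                    list(env = setdiff(names(predictors), "sample_id")))
      part <- partition_deviance(pairs, groups)
      write_tsv(part$partition,
                file.path(out_dir, paste0("gdm_partition_", ni, ".tsv")))
      out[[ni]] <- list(model = fit, partition = part)
    }
    out
  })

  res$lagged <- run_stage("lagged_similarity", {
    root <- rar$table[niches$root, ]
    soil <- rar$table[niches$soil, ]
    ls <- lagged_similarity(root, soil, meta, lag_days = lag_days)
    write_tsv(ls, file.path(out_dir, "lagged_similarity.tsv"))
    ls
  })

  res$core <- run_stage("core", {
    out <- list()
    for (ni in names(niches)) {
      sub <- rar$table[niches[[ni]], ]
      sub <- sub[, colSums(sub) > 0]
      nm <- meta[match(niches[[ni]], meta$sample_id), ]
      st <- occupancy_abundance(sub, nm, group_by = "collection_date")
      rk <- rank_taxa(st)
      cv <- bc_contribution_curve(sub, rk)
      cr <- select_core(cv, sub, threshold = core_threshold)
      nf <- fit_neutral(st, N = depth, n_samples = nrow(sub))
      write_tsv(cr$curve, file.path(out_dir, paste0("core_curve_", ni, ".tsv")))
      out[[ni]] <- list(stats = st, core = cr, neutral = nf)
    }
    out
  })

  manifest <- list(analysis = "growing_season", seed = seed, seeds = seeds,
                   depth = depth, n_perm = n_perm, lag_days = lag_days,
                   core_threshold = core_threshold,
                   n_samples = nrow(rar$table),
                   version = as.character(utils::packageVersion("spatiomic")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
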
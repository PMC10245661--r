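#' Per-taxon occupancy and abundance statistics
#'
#' For each taxon: overall occupancy (proportion of samples where
#' detected), mean relative abundance, per-group occupancy (sites or
#' collection dates), and replicate consistency (proportion of groups in
#' which the taxon is detected in every sample of the group).
#'
#' @param table rarefied [otu_table()].
#' @param meta validated metadata.
#' @param group_by metadata column defining groups (`"site"` or
#'   `"collection_date"`).
#' @return data.frame: `taxon_id`, `occupancy`, `mean_rel_abund`,
#'   `replicate_consistency`, `mean_group_occupancy`, plus one
#'   `occ_<group>` column per group.
#' @export
occupancy_abundance <- function(table, meta, group_by = "site") {
  m <- unclass(table)
  meta <- meta[match(rownames(m), meta$sample_id), ]
  if (anyNA(meta$sample_id)) stop("samples missing from metadata")
  g <- factor(meta[[group_by]])
  if (any(table(g) == 0)) stop("empty group")
  rel <- m / rowSums(m)
  pres <- m > 0
  gocc <- vapply(levels(g), function(l)
    colMeans(pres[g == l, , drop = FALSE]), numeric(ncol(m)))
  out <- data.frame(taxon_id = colnames(m),
                    occupancy = colMeans(pres),
                    mean_rel_abund = colMeans(rel),
                    replicate_consistency = rowMeans(gocc == 1),
                    mean_group_occupancy = rowMeans(gocc),
                    row.names = NULL)
  colnames(gocc) <- paste0("occ_", levels(g))
  cbind(out, gocc)
}

#' Rank taxa for core-community selection
#'
#' The rank index is the mean of (i) the mean per-group occupancy and
#' (ii) the replicate consistency; taxa are ordered by decreasing index,
#' breaking ties by higher mean relative abundance and then taxon id, so
#' the ranking is a total order invariant to input order.
#'
#' @param stats output of [occupancy_abundance()].
#' @return the stats rows with a `rank_index` column, sorted by rank.
#' @export
rank_taxa <- function(stats) {
  if (nrow(stats) == 0) stop("no taxa to rank")
  stats$rank_index <- (stats$mean_group_occupancy +
                         stats$replicate_consistency) / 2
  ord <- order(-stats$rank_index, -stats$mean_rel_abund, stats$taxon_id)
  out <- stats[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cumulative Bray-Curtis contribution of the ranked taxa
#'
#' For each prefix of the ranking, the partial Bray-Curtis of a sample
#' pair keeps the full-table denominator
#' (\eqn{\sum_t (x_{it} + x_{jt})} over all taxa) so per-taxon
#' contributions are additive and the curve is non-decreasing, reaching 1
#' at full richness. `bc_contribution[i]` is the mean partial BC over all
#' pairs divided by the mean full BC.
#'
#' @param table rarefied [otu_table()].
#' @param ranking ranked stats from [rank_taxa()] (must cover all taxa).
#' @return data.frame: `rank`, `taxon_id`, `bc_contribution`.
#' @export
bc_contribution_curve <- function(table, ranking) {
  m <- unclass(table)
  if (!setequal(ranking$taxon_id, colnames(m)))
    stop("ranking must cover exactly the table's taxa")
  m <- m[, ranking$taxon_id, drop = FALSE]
  n <- nrow(m)
  pr <- t(utils::combn(n, 2))
  den <- rowSums(m)[pr[, 1]] + rowSums(m)[pr[, 2]]
  # per-taxon mean pairwise |difference| / pair denominator
  contrib <- vapply(seq_len(ncol(m)), function(t)
    mean(abs(m[pr[, 1], t] - m[pr[, 2], t]) / den), 0)
  cum <- cumsum(contrib)
  data.frame(rank = seq_len(ncol(m)), taxon_id = colnames(m),
             bc_contribution = cum / cum[length(cum)])
}

#' Select the core community from the contribution curve
#'
#' The "last 5% increase" rule: the core extends to the largest rank i
#' whose inclusion increased the cumulative Bray-Curtis contribution by at
#' least `threshold` relative to the previous prefix,
#' \eqn{(c_i - c_{i-1})/c_{i-1} \ge} `threshold`. An absolute-change
#' variant \eqn{c_i - c_{i-1} \ge} `threshold` is available. If no step
#' meets the threshold the core is the first-ranked taxon, with a warning.
#'
#' @param curve output of [bc_contribution_curve()].
#' @param table the same [otu_table()] (for richness/read shares).
#' @param threshold change threshold (study convention 0.05).
#' @param mode `"relative"` (default) or `"absolute"` change.
#' @return list of class `core_result`: `curve` with a `core` flag,
#'   `threshold_index`, `core_taxa`, `richness_share` and `read_share`
#'   (percent of OTUs / of reads in the core).
#' @export
select_core <- function(curve, table, threshold = 0.05,
                        mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  c_i <- curve$bc_contribution
  n <- length(c_i)
  step <- if (mode == "relative")
    (c_i[-1] - c_i[-n]) / c_i[-n]
  else c_i[-1] - c_i[-n]
  hits <- which(step >= threshold - 1e-12) + 1L
  if (length(hits) == 0) {
    warning("no rank step meets the threshold; core set to the top taxon")
    idx <- 1L
  } else idx <- max(hits)
  core_taxa <- curve$taxon_id[seq_len(idx)]
  m <- unclass(table)
  structure(list(curve = transform(curve, core = rank <= idx),
                 threshold_index = idx,
                 threshold = threshold, mode = mode,
                 core_taxa = core_taxa,
                 richness_share = 100 * idx / n,
                 read_share = 100 * sum(m[, core_taxa, drop = FALSE]) /
                   sum(m)),
            class = "core_result")
}

#' @export
print.core_result <- function(x, ...) {
  cat("Core community: ", x$threshold_index, " taxa (",
      signif(x$richness_share, 3), "% of OTUs, ",
      signif(x$read_share, 3), "% of reads) at threshold ",
      x$threshold, " (", x$mode, ")\n", sep = "")
  invisible(x)
}

#' Scan core selection across thresholds
#'
#' Exports core richness share, read share and the neutral-model fit of
#' the resulting partition for a grid of thresholds, supporting the choice
#' of a Bray-Curtis change threshold.
#'
#' @param curve contribution curve.
#' @param table the [otu_table()].
#' @param stats [occupancy_abundance()] output.
#' @param thresholds grid of thresholds.
#' @return data.frame per threshold: core size/shares and neutral R2.
#' @export
core_threshold_scan <- function(curve, table, stats,
                                thresholds = seq(0.01, 0.2, by = 0.01)) {
  n_samp <- nrow(table)
  depth <- sum(table) / n_samp
  do.call(rbind, lapply(thresholds, function(th) {
    cr <- suppressWarnings(select_core(curve, table, threshold = th))
    nf <- tryCatch(fit_neutral(stats, N = round(depth), n_samples = n_samp),
                   error = function(e) NULL)
    data.frame(threshold = th, core_size = cr$threshold_index,
               richness_share = cr$richness_share,
               read_share = cr$read_share,
               neutral_r2 = if (is.null(nf)) NA_real_ else nf$r2)
  }))
}

#' Fit the Sloan neutral community model
#'
#' Predicted occupancy for a taxon of mean relative abundance \eqn{\bar p}
#' is \eqn{1 - \mathrm{BetaCDF}(d;\; N m \bar p,\; N m (1 - \bar p))}
#' with detection limit \eqn{d = 1/N}; the migration probability m is fit
#' by unweighted least squares over taxa. 95% Wilson binomial intervals at
#' the realized sample count classify each taxon as above, within
#' (neutral), or below the neutral expectation.
#'
#' @param stats [occupancy_abundance()] output (>= 10 taxa).
#' @param N reads per sample (study convention 10,000).
#' @param n_samples number of samples behind the occupancy estimates.
#' @return object of class `neutral_fit`: `m`, `r2`, `taxa` (data.frame
#'   with observed/predicted occupancy, CI bounds, class), `failed` flag
#'   (non-convergence or R2 <= 0), `N`, `n_samples`.
#' @export
fit_neutral <- function(stats, N = 10000, n_samples) {
  if (nrow(stats) < 10) stop("need >= 10 taxa")
  p <- stats$mean_rel_abund
  occ <- stats$occupancy
  d <- 1 / N
  pred_occ <- function(m) 1 - stats::pbeta(d, N * m * p, N * m * (1 - p))
  sse <- function(m) sum((occ - pred_occ(m))^2)
  opt <- stats::optimize(sse, interval = c(1e-8, 1))
  m_hat <- opt$minimum
  pred <- pred_occ(m_hat)
  sst <- sum((occ - mean(occ))^2)
  r2 <- if (sst <= 0) NA_real_ else 1 - opt$objective / sst
  # Wilson 95% interval around the predicted occupancy at n_samples
  z <- stats::qnorm(0.975)
  nn <- n_samples
  centre <- (pred + z^2 / (2 * nn)) / (1 + z^2 / nn)
  half <- z * sqrt(pred * (1 - pred) / nn + z^2 / (4 * nn^2)) / (1 + z^2 / nn)
  lo <- pmax(centre - half, 0)
  hi <- pmin(centre + half, 1)
  cls <- ifelse(occ > hi, "above", ifelse(occ < lo, "below", "neutral"))
  structure(list(m = m_hat, r2 = r2, N = N, n_samples = n_samples,
                 failed = is.na(r2) || r2 <= 0,
                 taxa = data.frame(taxon_id = stats$taxon_id,
                                   mean_rel_abund = p, occupancy = occ,
                                   predicted = pred, lower = lo, upper = hi,
                                   class = cls)),
            class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat("Sloan neutral model: m = ", signif(x$m, 4), ", R2 = ",
      signif(x$r2, 4), " (N = ", x$N, ", ", x$n_samples, " samples",
      if (x$failed) "; FAILED fit" else "", ")\n", sep = "")
  print(table(x$taxa$class))
  invisible(x)
}

#' Root-vs-soil differential family abundance
#'
#' Aggregates taxa to families, computes per-sample family proportions in
#' each niche, and reports the log2 ratio of median proportions
#' (root / soil) with a two-sided Wilcoxon rank-sum test across samples
#' and Benjamini-Hochberg FDR. When a median is zero, a pseudo-proportion
#' of 1/(2N) (N = reads per sample) is added to both medians and the row
#' is flagged.
#'
#' @param root,soil rarefied [otu_table()]s.
#' @param annotations data.frame with `taxon_id` and `family` columns.
#' @return data.frame per family: medians, `log2_ratio`, `p_value`,
#'   `p_adjust`, `pseudo` flag; families absent from both niches are
#'   excluded.
#' @export
differential_family_abundance <- function(root, soil, annotations) {
  fam_prop <- function(tab) {
    m <- unclass(tab)
    rel <- m / rowSums(m)
    fam <- annotations$family[match(colnames(m), annotations$taxon_id)]
    keep <- !is.na(fam) & fam != ""
    rel <- rel[, keep, drop = FALSE]
    t(rowsum(t(rel), fam[keep]))  # samples x families
  }
  pr <- fam_prop(root)
  ps <- fam_prop(soil)
  fams <- union(colnames(pr), colnames(ps))
  Nr <- sum(root) / nrow(root)
  pseudo <- 1 / (2 * Nr)
  out <- lapply(fams, function(f) {
    a <- if (f %in% colnames(pr)) pr[, f] else rep(0, nrow(pr))
    b <- if (f %in% colnames(ps)) ps[, f] else rep(0, nrow(ps))
    if (all(a == 0) && all(b == 0)) return(NULL)
    ma <- stats::median(a)
    mb <- stats::median(b)
    zero <- ma == 0 || mb == 0
    if (zero) {
      ma <- ma + pseudo
      mb <- mb + pseudo
    }
    w <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    data.frame(family = f, median_root = stats::median(a),
               median_soil = stats::median(b),
               log2_ratio = log2(ma / mb), p_value = w$p.value,
               pseudo = zero)
  })
  out <- do.call(rbind, out)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Collapse fungal guild labels to grouped categories
#'
#' Maps (possibly multi-)guild labels to grouped categories
#' (symbiotroph / pathogen / saprotroph style groups) via a user-supplied
#' mapping table. Annotations with confidence below "Probable" have their
#' guild dropped; unmapped multi-guild labels are retained verbatim with a
#' warning; empty guilds become "unknown".
#'
#' @param annotations data.frame with `taxon_id`, `guild_label` and
#'   optionally `confidence` columns.
#' @param guild_map data.frame with `guild_label` and `guild_group`.
#' @return annotations with a `guild_group` column.
#' @export
group_guilds <- function(annotations, guild_map) {
  g <- annotations$guild_label
  if (!is.null(annotations$confidence)) {
    ok <- annotations$confidence %in% c("Probable", "Highly Probable")
    g[!ok] <- NA_character_
  }
  grp <- guild_map$guild_group[match(g, guild_map$guild_label)]
  unmapped <- !is.na(g) & g != "" & is.na(grp)
  if (any(unmapped)) {
    warning("unmapped guild labels retained verbatim: ",
            paste(unique(g[unmapped]), collapse = ", "))
    grp[unmapped] <- g[unmapped]
  }
  grp[is.na(g) | g == ""] <- "unknown"
  annotations$guild_group <- grp
  annotations
}
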
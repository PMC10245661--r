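#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d_{ij} = \sum_t |x_{it} - x_{jt}| / \sum_t (x_{it} + x_{jt})},
#' computed on counts (equivalent to relative abundances at equal depth,
#' so rarefied tables are the expected input).
#'
#' @param table an [otu_table()] or numeric matrix, samples x taxa.
#' @return a `dist` object with sample ids as labels.
#' @export
bray_curtis <- function(table) {
  m <- unclass(table)
  if (any(rowSums(m) == 0)) stop("all-zero samples make Bray-Curtis undefined")
  stats::as.dist(vegan::vegdist(m, method = "bray"))
}

#' Geographic distance between samples
#'
#' Euclidean distance in meters on (easting, northing) UTM coordinates;
#' all samples are assumed to share a UTM zone.
#'
#' @param meta validated metadata (see [validate_metadata()]).
#' @return a `dist` in meters, labelled by sample id.
#' @export
geo_distance <- function(meta) {
  bad <- !is.finite(meta$easting) | !is.finite(meta$northing)
  if (any(bad)) stop("missing coordinates for: ",
                     paste(meta$sample_id[bad], collapse = ", "))
  xy <- cbind(meta$easting, meta$northing)
  rownames(xy) <- meta$sample_id
  stats::dist(xy)
}

#' Temporal distance between samples
#'
#' Absolute difference of collection dates in whole days.
#'
#' @param meta validated metadata.
#' @return a `dist` in days, labelled by sample id.
#' @export
time_distance <- function(meta) {
  d <- as.Date(meta$collection_date)
  if (anyNA(d)) stop("unparseable collection_date")
  x <- matrix(as.numeric(d), dimnames = list(meta$sample_id, NULL))
  stats::dist(x, method = "manhattan")
}

#' Lagged root-vs-soil community similarity
#'
#' For each root sample two similarities (1 - Bray-Curtis) are computed:
#' `same_day`, against the spatially paired soil core (same plot, subplot
#' and core point on the same date), and `two_week_prior`, the mean
#' similarity against all soil samples of the same subplot collected
#' `lag_days` earlier. Because field collections drift from exact spacing,
#' the soil collection nearest to (root date - lag_days) within
#' `tolerance_days` is used; root samples with no such collection are
#' returned flagged as missing rather than fabricated.
#'
#' @param root,soil [otu_table()]s rarefied to the same depth and sharing a
#'   taxon set.
#' @param meta validated metadata covering both tables, with a `core`
#'   column identifying the spatial sampling point within subplot.
#' @param lag_days lag between soil and root collection (days; default 14).
#' @param tolerance_days allowed drift around the lag target (default 4).
#' @return data.frame of records: `root_sample_id`, `soil_reference`
#'   (`same_day` / `two_week_prior`), `similarity` (NA when flagged
#'   `missing`), `collection_date`, `site`, `plot`, `subplot`,
#'   `n_treatment`, `n_soil` (soil samples averaged), `missing`.
#' @export
lagged_similarity <- function(root, soil, meta, lag_days = 14,
                              tolerance_days = 4) {
  if (!"core" %in% names(meta))
    stop("metadata must carry a 'core' column naming the sampling point")
  if (!identical(sort(colnames(root)), sort(colnames(soil))))
    stop("root and soil tables must share a taxon set")
  soilm <- unclass(soil)[, colnames(root), drop = FALSE]
  rootm <- unclass(root)
  meta$collection_date <- as.Date(meta$collection_date)
  rmeta <- meta[match(rownames(rootm), meta$sample_id), ]
  smeta <- meta[match(rownames(soilm), meta$sample_id), ]
  if (anyNA(rmeta$sample_id) || anyNA(smeta$sample_id))
    stop("samples missing from metadata")

  sim <- function(a, b) 1 - sum(abs(a - b)) / sum(a + b)
  skey <- paste(smeta$site, smeta$plot, smeta$subplot, sep = "/")
  rkey <- paste(rmeta$site, rmeta$plot, rmeta$subplot, sep = "/")

  rec <- function(i, ref, value, n_soil, missing) {
    data.frame(root_sample_id = rmeta$sample_id[i], soil_reference = ref,
               similarity = value, collection_date = rmeta$collection_date[i],
               site = rmeta$site[i], plot = rmeta$plot[i],
               subplot = rmeta$subplot[i], n_treatment = rmeta$n_treatment[i],
               n_soil = n_soil, missing = missing)
  }

  out <- vector("list", 2L * nrow(rmeta))
  for (i in seq_len(nrow(rmeta))) {
    # same-day spatial pair: same subplot, same core point, same date
    j <- which(skey == rkey[i] & smeta$core == rmeta$core[i] &
                 smeta$collection_date == rmeta$collection_date[i])
    out[[2 * i - 1]] <- if (length(j) >= 1)
      rec(i, "same_day", sim(rootm[i, ], soilm[j[1], ]), 1L, FALSE)
    else rec(i, "same_day", NA_real_, 0L, TRUE)

    # lagged: subplot mean at the nearest collection to (date - lag)
    target <- rmeta$collection_date[i] - lag_days
    cand <- which(skey == rkey[i])
    if (length(cand)) {
      off <- abs(as.numeric(smeta$collection_date[cand] - target))
      cand <- cand[off <= tolerance_days & off == min(off)]
    }
    out[[2 * i]] <- if (length(cand))
      rec(i, "two_week_prior",
          mean(vapply(cand, function(j) sim(rootm[i, ], soilm[j, ]), 0)),
          length(cand), FALSE)
    else rec(i, "two_week_prior", NA_real_, 0L, TRUE)
  }
  do.call(rbind, out)
}

#' Write a distance matrix as square TSV
#' @param d a `dist` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square TSV distance matrix
#' @param path TSV written by [write_distance()].
#' @return a `dist` object.
#' @export
read_distance <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (max(abs(m - t(m))) > 1e-12) stop("matrix is not symmetric")
  stats::as.dist(m)
}
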
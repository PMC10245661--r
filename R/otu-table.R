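#' Construct an OTU table
#'
#' An OTU table is a non-negative integer count matrix with samples as rows
#' and taxa (OTUs) as columns, the object every downstream stage consumes.
#' Construction validates identifiers and counts; taxa whose total count is
#' zero are retained but flagged in the `"zero_taxa"` attribute so matrices
#' stay alignable across niches.
#'
#' @param counts numeric matrix of read counts, samples x taxa, with unique
#'   non-empty dimnames.
#' @return An object of class `otu_table`: the validated integer matrix with
#'   attributes `zero_taxa` (character vector of all-zero taxon ids).
#' @examples
#' m <- matrix(c(5, 0, 3, 2, 1, 0), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
#' otu_table(m)
#' @export
otu_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts)) {
    bad <- which(!apply(counts, 2, is.numeric))
    stop("non-numeric values in columns: ", paste(colnames(counts)[bad], collapse = ", "))
  }
  if (anyNA(counts)) {
    bad <- which(apply(is.na(counts), 1, any))
    stop("missing counts in samples: ", paste(rownames(counts)[bad], collapse = ", "))
  }
  if (any(counts < 0)) {
    bad <- which(apply(counts < 0, 1, any))
    stop("negative counts in samples: ", paste(rownames(counts)[bad], collapse = ", "))
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(apply(abs(counts - round(counts)) > 1e-8, 1, any))
    stop("non-integer counts in samples: ", paste(rownames(counts)[bad], collapse = ", "))
  }
  storage.mode(counts) <- "integer"
  rs <- rowSums(counts)
  if (any(rs == 0))
    stop("samples with zero total reads: ",
         paste(rownames(counts)[rs == 0], collapse = ", "))
  structure(counts,
            zero_taxa = colnames(counts)[colSums(counts) == 0],
            class = c("otu_table", "matrix", "array"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table: ", nrow(x), " samples x ", ncol(x), " taxa, ",
      sum(x), " reads", sep = "")
  zt <- attr(x, "zero_taxa")
  if (length(zt)) cat(" (", length(zt), " all-zero taxa flagged)", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
`[.otu_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  structure(out,
            zero_taxa = colnames(out)[colSums(out) == 0],
            class = c("otu_table", "matrix", "array"))
}

#' Read an OTU table from TSV or BIOM
#'
#' TSV tables carry taxa as columns with a header row of taxon ids and sample
#' ids in the first column; set `orientation = "taxa_rows"` for transposed
#' files. BIOM input is the JSON serialization read through
#' \pkg{biomformat} (BIOM stores taxa as rows; orientation is normalized to
#' samples x taxa on read).
#'
#' @param path input file.
#' @param format `"tsv"` or `"biom"`; defaults from the file extension.
#' @param orientation for TSV only: `"samples_rows"` (default) or
#'   `"taxa_rows"`.
#' @return validated [otu_table()].
#' @export
read_otu_table <- function(path, format = c("auto", "tsv", "biom"),
                           orientation = c("samples_rows", "taxa_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))  # biom is taxa x samples
  } else {
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
    m <- as.matrix(df)
    if (!is.numeric(m)) {
      bad <- colnames(m)[!apply(m, 2, function(v) all(grepl("^\\s*-?[0-9.eE+-]+\\s*$", v)))]
      stop("non-numeric cells in columns: ", paste(bad, collapse = ", "))
    }
    if (orientation == "taxa_rows") m <- t(m)
  }
  otu_table(m)
}

#' Write an OTU table to TSV or BIOM
#'
#' @param table an [otu_table()].
#' @param path output file.
#' @param format `"tsv"` or `"biom"` (JSON); defaults from the extension.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  if (format == "biom") {
    b <- biomformat::make_biom(t(unclass(table)))
    biomformat::write_biom(b, path)
  } else {
    df <- data.frame(sample_id = rownames(table), unclass(table),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Rarefy an OTU table to even depth
#'
#' Samples with fewer than `depth` total reads are removed and reported;
#' the rest are subsampled without replacement to exactly `depth` reads.
#' One seed governs all samples so the result is reproducible.
#'
#' @param table an [otu_table()].
#' @param depth target reads per sample (the study convention is 10,000).
#' @param seed integer seed for the subsampling.
#' @return list with `table` (rarefied [otu_table()]), `dropped`
#'   (data.frame of removed sample ids and their totals), `depth`, `seed`.
#' @export
rarefy <- function(table, depth = 10000, seed = 1L) {
  stopifnot(depth >= 1)
  totals <- rowSums(table)
  keep <- totals >= depth
  dropped <- data.frame(sample_id = rownames(table)[!keep],
                        total_reads = unname(totals[!keep]))
  if (!any(keep))
    stop("all samples have fewer than ", depth, " reads; nothing to rarefy")
  m <- unclass(table)[keep, , drop = FALSE]
  set.seed(seed)
  r <- withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      # muffle vegan's "smallest count" heuristic; counts are validated
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(table = otu_table(r), dropped = dropped, depth = depth, seed = seed)
}

#' Per-sample richness and inverse Simpson diversity
#'
#' Richness counts taxa with nonzero reads; inverse Simpson is
#' \eqn{1/\sum_i p_i^2} on each sample's relative abundances, so it ranges
#' from 1 (single dominant taxon) to the richness (perfectly even sample).
#'
#' @param table an [otu_table()].
#' @return data.frame with `sample_id`, `richness`, `inverse_simpson`.
#' @export
alpha_diversity <- function(table) {
  m <- unclass(table)
  data.frame(sample_id = rownames(m),
             richness = rowSums(m > 0),
             inverse_simpson = vegan::diversity(m, index = "invsimpson"),
             row.names = NULL)
}

#' Flag extreme values by the 3x inter-quartile rule
#'
#' A value is flagged when it falls outside
#' \eqn{[Q1 - 3\,\mathrm{IQR},\; Q3 + 3\,\mathrm{IQR}]}, with quartiles by
#' linear interpolation between order statistics (`stats::quantile`
#' type 7). Missing values are never flagged.
#'
#' @param values numeric vector with at least 4 finite entries.
#' @return logical mask, same length as `values`.
#' @export
flag_extreme <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 4) stop("need at least 4 finite values")
  q <- stats::quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  out <- values < q[1] - 3 * iqr | values > q[2] + 3 * iqr
  out[!ok] <- FALSE
  out
}

#' Validate sample metadata
#'
#' Checks the mandated design columns (sample_id, niche, site, plot,
#' subplot, n_treatment, collection_date, easting, northing), id uniqueness,
#' niche/treatment levels, date parseability (ISO-8601) and finite UTM
#' coordinates; subplot labels are disambiguated within plot within site.
#'
#' @param meta data.frame of per-sample metadata.
#' @return the metadata with `collection_date` as `Date`, invisibly checked.
#' @export
validate_metadata <- function(meta) {
  need <- c("sample_id", "niche", "site", "plot", "subplot", "n_treatment",
            "collection_date", "easting", "northing")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata")
  if (!all(meta$niche %in% c("root", "soil")))
    stop("niche must be 'root' or 'soil'")
  if (!all(meta$n_treatment %in% c("N", "control")))
    stop("n_treatment must be 'N' or 'control'")
  d <- as.Date(as.character(meta$collection_date), format = "%Y-%m-%d")
  if (anyNA(d)) stop("unparseable collection_date for: ",
                     paste(meta$sample_id[is.na(d)], collapse = ", "))
  meta$collection_date <- d
  if (!all(is.finite(meta$easting)) || !all(is.finite(meta$northing)))
    stop("non-finite coordinates for: ",
         paste(meta$sample_id[!is.finite(meta$easting) | !is.finite(meta$northing)],
               collapse = ", "))
  meta
}

#' Read sample metadata from TSV
#' @param path TSV file with the mandated metadata columns.
#' @return validated metadata data.frame.
#' @export
read_metadata <- function(path) {
  validate_metadata(utils::read.delim(path, check.names = FALSE,
                                      colClasses = "character",
                                      stringsAsFactors = FALSE) |>
                      transform(easting = as.numeric(easting),
                                northing = as.numeric(northing)))
}
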
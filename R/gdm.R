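#' Monotone I-spline basis
#'
#' Quadratic I-splines (integrated M-splines) with knots at chosen
#' quantiles of the predictor (default min/median/max, giving 3 basis
#' functions). Each basis function is monotone non-decreasing from 0 to 1,
#' so any non-negative combination is a monotone transfer function.
#'
#' @param x numeric values at which to evaluate.
#' @param knots increasing knot locations (length `n_basis`); values of `x`
#'   outside the knot range are clamped.
#' @return matrix `length(x)` x `n_basis` of basis values in [0, 1].
#' @export
ispline_basis <- function(x, knots) {
  knots <- sort(unique(knots))
  if (length(knots) < 2) {
    # degenerate predictor: single pseudo-basis, constant 0
    return(matrix(0, length(x), 1))
  }
  lo <- knots[1]
  hi <- knots[length(knots)]
  x <- pmin(pmax(x, lo), hi)
  # I-splines of order 2 = reversed cumulative sums of order-3 B-splines
  aug <- c(rep(lo, 3), knots[-c(1, length(knots))], rep(hi, 3))
  B <- splines::splineDesign(aug, x, ord = 3)
  p <- ncol(B)
  I <- sapply(seq_len(p - 1), function(i)
    rowSums(B[, (i + 1):p, drop = FALSE]))
  matrix(I, nrow = length(x))
}

knots_for <- function(v, n_basis = 3) {
  q <- stats::quantile(v, probs = seq(0, 1, length.out = n_basis),
                       type = 7, names = FALSE)
  if (length(unique(q)) < 2) q <- c(q[1], q[1] + 1)  # constant predictor
  q
}

#' Build the site-pair table for generalized dissimilarity modelling
#'
#' Expands samples to all unordered pairs, attaching the observed
#' Bray-Curtis dissimilarity, the pairwise geographic (m) and temporal
#' (days) distances, and the per-sample values of each environmental or
#' plant predictor at both ends of the pair.
#'
#' @param d community `dist` (response).
#' @param meta validated metadata (for coordinates and dates).
#' @param predictors data.frame of per-sample predictor values with a
#'   `sample_id` column (may be omitted for distance-only models).
#' @param restrict_dates optional vector of dates; samples collected on
#'   other dates are excluded (used to restrict soil runs to root-sampling
#'   dates).
#' @return data.frame of class `site_pair_table`: `s1`, `s2`, `distance`
#'   (response in [0,1]), `geo`, `days`, and `<var>_s1`/`<var>_s2` columns.
#' @export
build_pair_table <- function(d, meta, predictors = NULL,
                             restrict_dates = NULL) {
  ids <- attr(d, "Labels")
  meta <- meta[match(ids, meta$sample_id), ]
  if (anyNA(meta$sample_id)) stop("distance labels missing from metadata")
  if (!is.null(restrict_dates)) {
    keep <- as.Date(meta$collection_date) %in% as.Date(restrict_dates)
    d <- stats::as.dist(as.matrix(d)[keep, keep])
    meta <- meta[keep, ]
    ids <- ids[keep]
  }
  n <- length(ids)
  pr <- t(utils::combn(n, 2))
  i <- pr[, 1]; j <- pr[, 2]
  dm <- as.matrix(d)
  geo <- sqrt((meta$easting[i] - meta$easting[j])^2 +
                (meta$northing[i] - meta$northing[j])^2)
  days <- abs(as.numeric(as.Date(meta$collection_date[i]) -
                           as.Date(meta$collection_date[j])))
  out <- data.frame(s1 = ids[i], s2 = ids[j],
                    distance = dm[cbind(i, j)], geo = geo, days = days)
  if (!is.null(predictors)) {
    pv <- predictors[match(ids, predictors$sample_id), , drop = FALSE]
    if (anyNA(pv$sample_id)) stop("predictors missing for some samples")
    for (v in setdiff(names(predictors), "sample_id")) {
      if (anyNA(pv[[v]])) stop("missing values in predictor '", v, "'")
      out[[paste0(v, "_s1")]] <- pv[[v]][i]
      out[[paste0(v, "_s2")]] <- pv[[v]][j]
    }
  }
  class(out) <- c("site_pair_table", "data.frame")
  out
}

# design matrix of |I-spline| differences for the chosen predictors;
# "geo" and "days" enter as splines of the pairwise distance itself
gdm_design <- function(pairs, predictors, n_basis = 3, knots = NULL) {
  cols <- list()
  kn <- list()
  for (p in predictors) {
    if (p %in% c("geo", "days")) {
      v <- pairs[[p]]
      k <- if (!is.null(knots[[p]])) knots[[p]] else knots_for(v, n_basis)
      cols[[p]] <- ispline_basis(v, k)
    } else {
      v1 <- pairs[[paste0(p, "_s1")]]
      v2 <- pairs[[paste0(p, "_s2")]]
      if (is.null(v1)) stop("predictor '", p, "' not in pair table")
      k <- if (!is.null(knots[[p]])) knots[[p]] else
        knots_for(c(v1, v2), n_basis)
      cols[[p]] <- abs(ispline_basis(v1, k) - ispline_basis(v2, k))
    }
    kn[[p]] <- if (!is.null(knots[[p]])) knots[[p]] else k
    colnames(cols[[p]]) <- paste0(p, "_b", seq_len(ncol(cols[[p]])))
  }
  list(X = do.call(cbind, cols), knots = kn,
       index = rep(predictors, vapply(cols, ncol, 0L)))
}

# binomial-type deviance for dissimilarities; y = 1 shrunk for the log limit
gdm_deviance <- function(y, mu) {
  y <- pmin(pmax(y, 1e-9), 1 - 1e-9)
  mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
  sum(2 * (y * log(y / mu) + (1 - y) * log((1 - y) / (1 - mu))))
}

fit_link <- function(y, X) {
  # minimize deviance of mu = 1 - exp(-(a + X b)) subject to a, b >= 0
  nb <- ncol(X)
  obj <- function(par) {
    eta <- par[1] + drop(X %*% par[-1])
    gdm_deviance(y, 1 - exp(-eta))
  }
  grad <- function(par) {
    eta <- pmax(par[1] + drop(X %*% par[-1]), 1e-12)
    mu <- pmin(1 - exp(-eta), 1 - 1e-9)
    yc <- pmin(pmax(y, 1e-9), 1 - 1e-9)
    # d dev / d eta = 2 (mu - y)/(1 - mu) * dmu/deta / mu ... use chain rule:
    dmu <- exp(-eta)
    ddev <- 2 * (-yc / mu + (1 - yc) / (1 - mu)) * dmu
    c(sum(ddev), drop(crossprod(X, ddev)))
  }
  starts <- list(rep(0.01, nb + 1),
                 c(max(-log(1 - min(mean(y), 0.99)), 0.01), rep(0.1, nb)))
  best <- NULL
  for (s in starts) {
    f <- try(stats::optim(s, obj, grad, method = "L-BFGS-B",
                          lower = rep(0, nb + 1),
                          control = list(maxit = 500)), silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || f$value < best$value) best <- f
  }
  if (is.null(best)) stop("GDM optimizer failed to converge")
  best
}

#' Fit a generalized dissimilarity model
#'
#' Models compositional dissimilarity as
#' \eqn{\hat d = 1 - \exp(-\eta)}, \eqn{\eta = \alpha + \sum_p f_p}, where
#' each \eqn{f_p} is a non-negative combination of monotone I-spline basis
#' functions of the predictor difference (or of the pairwise distance for
#' the `geo`/`days` predictors). Coefficients are constrained non-negative
#' so fitted turnover is monotone; the fit minimizes the binomial-type
#' deviance and reports percent deviance explained relative to the
#' intercept-only model.
#'
#' @param pairs a [build_pair_table()] result.
#' @param predictors character vector of predictor names (`"geo"`,
#'   `"days"`, or environmental variable names in the pair table). May be
#'   empty for the intercept-only (null) model.
#' @param n_basis I-spline basis functions per predictor (default 3, knots
#'   at min/median/max).
#' @param knots optional named list of fixed knot vectors (used internally
#'   by permutation and bootstrap refits).
#' @return object of class `gdm_model`: intercept, per-basis coefficients,
#'   knots, null and fitted deviance, `deviance_explained` (percent),
#'   predictor list.
#' @export
fit_gdm <- function(pairs, predictors, n_basis = 3, knots = NULL) {
  y <- pairs$distance
  if (length(y) < 10) stop("need at least 10 pairs")
  null_dev <- fit_link(y, matrix(0, length(y), 0))$value
  if (length(predictors) == 0) {
    return(structure(list(intercept = NA_real_, coefficients = numeric(0),
                          index = character(0), knots = list(),
                          null_deviance = null_dev, deviance = null_dev,
                          deviance_explained = 0, predictors = character(0),
                          n_basis = n_basis),
                     class = "gdm_model"))
  }
  des <- gdm_design(pairs, predictors, n_basis, knots)
  fit <- fit_link(y, des$X)
  dev <- fit$value
  structure(list(intercept = fit$par[1],
                 coefficients = stats::setNames(fit$par[-1],
                                                colnames(des$X)),
                 index = des$index, knots = des$knots,
                 null_deviance = null_dev, deviance = dev,
                 deviance_explained = 100 * (null_dev - dev) / null_dev,
                 predictors = predictors, n_basis = n_basis),
            class = "gdm_model")
}

#' @export
print.gdm_model <- function(x, ...) {
  cat("GDM:", length(x$predictors), "predictors,",
      signif(x$deviance_explained, 4), "% deviance explained\n")
  if (length(x$predictors)) {
    cs <- vapply(x$predictors, function(p)
      sum(x$coefficients[x$index == p]), 0)
    print(signif(cs, 4))
  }
  invisible(x)
}

#' Predict dissimilarities from a fitted GDM
#' @param object a `gdm_model`.
#' @param pairs a pair table with the model's predictors.
#' @param ... unused.
#' @return predicted dissimilarities in [0, 1).
#' @export
predict.gdm_model <- function(object, pairs, ...) {
  if (length(object$predictors) == 0)
    stop("intercept-only model has no usable intercept for prediction")
  des <- gdm_design(pairs, object$predictors, object$n_basis, object$knots)
  eta <- object$intercept + drop(des$X %*% object$coefficients)
  1 - exp(-eta)
}

#' Evaluate a fitted predictor transfer function f_p on a grid
#' @param model a `gdm_model`.
#' @param predictor predictor name.
#' @param grid values at which to evaluate (default 200 points across the
#'   knot range).
#' @return data.frame with `x` and `f` (partial turnover, monotone).
#' @export
gdm_spline <- function(model, predictor, grid = NULL) {
  k <- model$knots[[predictor]]
  if (is.null(k)) stop("predictor not in model: ", predictor)
  if (is.null(grid)) grid <- seq(min(k), max(k), length.out = 200)
  B <- ispline_basis(grid, k)
  beta <- model$coefficients[model$index == predictor]
  data.frame(x = grid, f = drop(B %*% beta))
}

#' Permutation importance and backward selection of GDM predictors
#'
#' Importance of a predictor is the percent decrease in deviance explained
#' when its per-sample values (or the pairwise distance column for
#' `geo`/`days`) are permuted across samples; its p-value is the
#' proportion of permutations whose refitted deviance explained is at
#' least the observed. Backward elimination repeatedly drops the least
#' important non-significant predictor and refits until every retained
#' predictor is significant at `alpha`; ties are broken by the smaller
#' coefficient sum, then name.
#'
#' @param pairs pair table.
#' @param predictors starting predictor set.
#' @param n_perm permutations per predictor (study convention 100).
#' @param alpha retention threshold (default 0.05).
#' @param n_basis spline basis size.
#' @param seed integer seed.
#' @return list with `importance` (data.frame per elimination step),
#'   `model` (final refitted `gdm_model`), `retained`.
#' @export
variable_importance <- function(pairs, predictors, n_perm = 100,
                                alpha = 0.05, n_basis = 3, seed = 1L) {
  set.seed(seed)
  ids <- unique(c(pairs$s1, pairs$s2))
  i1 <- match(pairs$s1, ids)
  i2 <- match(pairs$s2, ids)

  permute_pred <- function(pairs, p) {
    # permute sample-level values and rebuild the pair columns
    if (p %in% c("geo", "days")) {
      # distance predictor has no sample decomposition: permute the column
      pairs[[p]] <- sample(pairs[[p]])
    } else {
      v <- numeric(length(ids))
      v[i1] <- pairs[[paste0(p, "_s1")]]
      v[i2] <- pairs[[paste0(p, "_s2")]]
      v <- sample(v)
      pairs[[paste0(p, "_s1")]] <- v[i1]
      pairs[[paste0(p, "_s2")]] <- v[i2]
    }
    pairs
  }

  steps <- list()
  current <- predictors
  repeat {
    full <- fit_gdm(pairs, current, n_basis)
    imp <- data.frame(predictor = current, importance = NA_real_,
                      p_value = NA_real_)
    for (pi in seq_along(current)) {
      p <- current[pi]
      de_perm <- numeric(n_perm)
      for (b in seq_len(n_perm)) {
        pp <- permute_pred(pairs, p)
        de_perm[b] <- fit_gdm(pp, current, n_basis,
                              knots = full$knots)$deviance_explained
      }
      imp$importance[pi] <- 100 *
        (full$deviance_explained - mean(de_perm)) /
        max(full$deviance_explained, 1e-12)
      imp$p_value[pi] <- mean(de_perm >= full$deviance_explained - 1e-12)
    }
    steps[[length(steps) + 1]] <- cbind(step = length(steps) + 1, imp)
    nonsig <- imp[imp$p_value > alpha, , drop = FALSE]
    if (nrow(nonsig) == 0) break
    cs <- vapply(nonsig$predictor, function(p)
      sum(full$coefficients[full$index == p]), 0)
    ord <- order(nonsig$importance, cs, nonsig$predictor)
    drop_p <- nonsig$predictor[ord[1]]
    current <- setdiff(current, drop_p)
    if (length(current) == 0) {
      warning("backward selection removed all predictors; returning null model")
      return(list(importance = do.call(rbind, steps),
                  model = fit_gdm(pairs, character(0), n_basis),
                  retained = character(0)))
    }
  }
  list(importance = do.call(rbind, steps),
       model = fit_gdm(pairs, current, n_basis),
       retained = current)
}

#' Partition GDM deviance explained among predictor groups
#'
#' Fits a GDM on every non-empty subset of the predictor groups and
#' decomposes the full model's deviance explained into unique and shared
#' components by inclusion-exclusion, as in variation partitioning.
#' Negative shared components are reported as computed, not clipped.
#'
#' @param pairs pair table.
#' @param groups named list mapping group name (e.g. `spatial`, `soil`,
#'   `MET`, `plant`, `temporal`) to its predictors.
#' @param n_basis spline basis size.
#' @return list with `subsets` (deviance explained per group subset) and
#'   `partition` (data.frame: component groups, fraction); fractions sum to
#'   the full model's deviance explained.
#' @export
partition_deviance <- function(pairs, groups, n_basis = 3) {
  stopifnot(length(groups) >= 1, all(lengths(groups) > 0))
  gn <- names(groups)
  k <- length(gn)
  subsets <- lapply(seq_len(2^k - 1), function(mask)
    gn[bitwAnd(mask, 2^(seq_len(k) - 1)) != 0])
  de <- vapply(subsets, function(s) {
    preds <- unique(unlist(groups[s]))
    m <- tryCatch(fit_gdm(pairs, preds, n_basis),
                  error = function(e) stop("subset {",
                                           paste(s, collapse = ","),
                                           "} failed: ", conditionMessage(e)))
    m$deviance_explained
  }, 0)
  names(de) <- vapply(subsets, paste, "", collapse = "+")
  R <- function(s) {  # deviance explained of a union of groups
    if (length(s) == 0) return(0)
    de[[paste(gn[sort(match(s, gn))], collapse = "+")]]
  }
  full <- R(gn)
  part <- lapply(subsets, function(Tset) {
    x <- 0
    u_sub <- lapply(seq_len(2^length(Tset)) - 1, function(mask)
      Tset[bitwAnd(mask, 2^(seq_along(Tset) - 1)) != 0])
    for (U in u_sub)
      x <- x + (-1)^(length(Tset) - length(U)) * (full - R(setdiff(gn, U)))
    data.frame(component = paste(Tset, collapse = "&"),
               n_groups = length(Tset), fraction = x)
  })
  part <- do.call(rbind, part)
  list(subsets = de, partition = part, full = full)
}

#' Bootstrap uncertainty bands for GDM splines
#'
#' Refits the model `n_boot` times on random subsets of the samples
#' (withholding `withhold` of them; pairs are induced from the retained
#' samples) and returns 95% pointwise bands for each predictor's fitted
#' transfer function, evaluated on the full-data knot range.
#'
#' @param pairs pair table.
#' @param model fitted `gdm_model`.
#' @param withhold fraction of samples withheld per iteration (study
#'   convention 0.30).
#' @param n_boot iterations (study convention 100).
#' @param seed integer seed.
#' @param grid_n grid points per predictor.
#' @return list per predictor: data.frame `x`, `lower`, `upper`, `fit`
#'   (full-data spline). Errors if more than 20% of refits fail.
#' @export
bootstrap_splines <- function(pairs, model, withhold = 0.30, n_boot = 100,
                              seed = 1L, grid_n = 50) {
  set.seed(seed)
  ids <- unique(c(pairs$s1, pairs$s2))
  preds <- model$predictors
  grids <- lapply(preds, function(p) {
    k <- model$knots[[p]]
    seq(min(k), max(k), length.out = grid_n)
  })
  names(grids) <- preds
  curves <- lapply(preds, function(p) matrix(NA_real_, n_boot, grid_n))
  names(curves) <- preds
  fails <- 0L
  for (b in seq_len(n_boot)) {
    keep <- sample(ids, ceiling((1 - withhold) * length(ids)))
    sub <- pairs[pairs$s1 %in% keep & pairs$s2 %in% keep, , drop = FALSE]
    fit <- try(fit_gdm(sub, preds, model$n_basis, knots = model$knots),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      fails <- fails + 1L
      next
    }
    for (p in preds)
      curves[[p]][b, ] <- gdm_spline(fit, p, grids[[p]])$f
  }
  if (fails > 0.2 * n_boot)
    stop("bootstrap refits failed in ", fails, "/", n_boot, " iterations")
  out <- lapply(preds, function(p) {
    qs <- apply(curves[[p]], 2, stats::quantile,
                probs = c(0.025, 0.975), na.rm = TRUE)
    data.frame(x = grids[[p]], lower = qs[1, ], upper = qs[2, ],
               fit = gdm_spline(model, p, grids[[p]])$f)
  })
  names(out) <- preds
  out
}
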
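#' Ordinate a dissimilarity matrix
#'
#' Non-metric multidimensional scaling (stress majorization with monotone
#' regression, 20 random restarts, best-stress solution kept) through
#' \pkg{vegan}'s `metaMDS` engine, or metric principal coordinates as a
#' fallback. The configuration is centered at the origin.
#'
#' @param d a `dist`.
#' @param k number of dimensions (default 2).
#' @param seed integer seed controlling the random restarts.
#' @param method `"nmds"` or `"pcoa"`.
#' @param trymax random restarts for NMDS.
#' @return object of class `ordination`: list with `ids`, `points`
#'   (n x k, centered), `stress` (Kruskal stress-1 in [0,1]; `NA` for
#'   PCoA), `method`, `seed`.
#' @export
ordinate <- function(d, k = 2, seed = 1L, method = c("nmds", "pcoa"),
                     trymax = 20) {
  method <- match.arg(method)
  ids <- attr(d, "Labels")
  if (method == "nmds") {
    set.seed(seed)
    fit <- vegan::metaMDS(d, k = k, trymax = trymax, trace = 0,
                          autotransform = FALSE, wascores = FALSE)
    if (!fit$converged && fit$stress > 0.3)
      stop("NMDS failed to converge in ", trymax,
           " restarts (stress ", signif(fit$stress, 3), ")")
    pts <- fit$points
    stress <- fit$stress
  } else {
    fit <- stats::cmdscale(d, k = k, eig = TRUE, add = TRUE)
    pts <- fit$points
    stress <- NA_real_
  }
  pts <- scale(pts, center = TRUE, scale = FALSE)
  dimnames(pts) <- list(ids, paste0("axis", seq_len(ncol(pts))))
  structure(list(ids = ids, points = pts, stress = stress,
                 method = method, seed = seed),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("Ordination (", x$method, "): ", length(x$ids), " samples x ",
      ncol(x$points), " axes", sep = "")
  if (!is.na(x$stress)) cat(", stress ", signif(x$stress, 4), sep = "")
  cat("\n")
  invisible(x)
}

# optimal superimposition of Y onto X (both already centered):
# translation + uniform scale + orthogonal rotation minimizing residual SS,
# with X normalized to unit sum of squares so m2 is target-scaled
procrustes_fit <- function(X, Y) {
  X <- scale(X, center = TRUE, scale = FALSE)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  sx <- sqrt(sum(X^2))
  sy <- sqrt(sum(Y^2))
  X <- X / sx
  Y <- Y / sy
  sv <- svd(crossprod(X, Y))
  R <- sv$v %*% t(sv$u)        # rotation applied to Y
  scl <- sum(sv$d)             # optimal dilation for unit-SS inputs
  Yrot <- scl * Y %*% R
  resid <- sqrt(rowSums((X - Yrot)^2))
  m2 <- 1 - scl^2              # = residual SS after optimal scaling
  list(m2 = max(m2, 0), t = sqrt(max(1 - m2, 0)), rotation = R,
       scale = scl * sx / sy, residuals = resid, yrot = Yrot * sx)
}

#' Procrustes concordance with permutation test (PROTEST)
#'
#' Fits configuration `y` onto `x` by translation, uniform scaling and
#' orthogonal rotation, minimizing the sum of squared deviations m2
#' (target-scaled so m2 is in [0, 1]); the correlation statistic is
#' t = sqrt(1 - m2). Significance is assessed by permuting the sample
#' identities of `y` `n_perm` times; p = (b + 1)/(n_perm + 1). The fit is
#' asymmetric (y onto x), so the per-sample residuals depend on which
#' community is the target; the m2 statistic itself does not.
#'
#' @param x,y [ordinate()] results (or plain coordinate matrices with row
#'   names); the id intersection is used and logged via message.
#' @param n_perm permutations (study convention 9999).
#' @param seed integer seed.
#' @return object of class `protest_result`: list with `m2`, `t`, `p_perm`,
#'   `residuals` (named per-sample lengths, sum of squares = m2),
#'   `rotation`, `scale`, `n_shared`.
#' @export
protest <- function(x, y, n_perm = 999, seed = 1L) {
  px <- if (inherits(x, "ordination")) x$points else as.matrix(x)
  py <- if (inherits(y, "ordination")) y$points else as.matrix(y)
  shared <- intersect(rownames(px), rownames(py))
  if (length(shared) < 3) stop("need >= 3 shared samples")
  if (length(shared) < nrow(px) || length(shared) < nrow(py))
    message("protest: using ", length(shared), " shared samples")
  px <- px[shared, , drop = FALSE]
  py <- py[shared, , drop = FALSE]
  fit <- procrustes_fit(px, py)
  set.seed(seed)
  n <- nrow(py)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    tb <- procrustes_fit(px, py[sample.int(n), , drop = FALSE])$t
    if (tb >= fit$t - 1e-12) hits <- hits + 1L
  }
  res <- fit$residuals
  names(res) <- shared
  structure(list(m2 = fit$m2, t = fit$t,
                 p_perm = (hits + 1) / (n_perm + 1),
                 residuals = res, rotation = fit$rotation,
                 scale = fit$scale, n_shared = length(shared),
                 n_perm = n_perm, seed = seed),
            class = "protest_result")
}

#' @export
print.protest_result <- function(x, ...) {
  cat("PROTEST: m2 = ", signif(x$m2, 4), ", t = ", signif(x$t, 4),
      ", p = ", signif(x$p_perm, 4), " (", x$n_perm, " permutations, ",
      x$n_shared, " samples)\n", sep = "")
  invisible(x)
}
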
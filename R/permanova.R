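#' Describe one term of a split-plot PERMANOVA design
#'
#' @param name display name for the output table (e.g. `"Plot(Site*N)"`).
#' @param vars metadata columns whose interaction defines the term.
#' @param type `"main"` (sum-to-zero contrasts of one factor),
#'   `"interaction"` (interaction contrasts of several factors), or
#'   `"nested"` (full cell indicators, for a random factor nested in the
#'   crossed terms above it).
#' @param denominator name of the term whose mean square is the error for
#'   this term's pseudo-F, or `"Residual"`.
#' @param exchange permutation scheme for the term's test: `"free"`, or
#'   `list(blocks = vars)` to permute intact equal-sized blocks defined by
#'   the interaction of `vars`, or `list(within = vars)` to permute samples
#'   within each level of that interaction.
#' @return a `design_term` list, consumed by [design_spec()].
#' @export
design_term <- function(name, vars, type = c("main", "interaction", "nested"),
                        denominator = "Residual", exchange = "free") {
  type <- match.arg(type)
  structure(list(name = name, vars = vars, type = type,
                 denominator = denominator, exchange = exchange),
            class = "design_term")
}

#' Assemble a PERMANOVA design specification
#'
#' @param ... [design_term()]s in display order.
#' @return a `design_spec` object.
#' @export
design_spec <- function(...) {
  terms <- list(...)
  nm <- vapply(terms, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate term names")
  for (t in terms)
    if (t$denominator != "Residual" && !t$denominator %in% nm)
      stop("denominator '", t$denominator, "' of term '", t$name,
           "' is not a design term")
  structure(terms, names = nm, class = "design_spec")
}

#' Regional (multi-site) split-plot design
#'
#' Site, N addition and their interaction are tested over the mean square of
#' the random plot term nested in site x N; the plot term is tested over the
#' residual. Whole-plot terms permute intact subplot cells (site/plot/N
#' blocks of cores); the plot term permutes cores within site x N cells.
#'
#' @return a [design_spec()].
#' @export
design_regional <- function() {
  plotv <- c("site", "plot", "n_treatment")
  design_spec(
    design_term("Site", "site", "main", denominator = "Plot(Site*N)",
                exchange = list(blocks = plotv)),
    design_term("N add", "n_treatment", "main", denominator = "Plot(Site*N)",
                exchange = list(blocks = plotv)),
    design_term("Site*N add", c("site", "n_treatment"), "interaction",
                denominator = "Plot(Site*N)", exchange = list(blocks = plotv)),
    design_term("Plot(Site*N)", plotv, "nested",
                exchange = list(within = c("site", "n_treatment"))))
}

#' Growing-season (single-site time series) split-plot design
#'
#' Collection date, N addition and their interaction tested over the random
#' plot term nested in date x N; plot term over the residual.
#'
#' @return a [design_spec()].
#' @export
design_season <- function() {
  plotv <- c("collection_date", "plot", "n_treatment")
  design_spec(
    design_term("Collection Date", "collection_date", "main",
                denominator = "Plot(Date*N)", exchange = list(blocks = plotv)),
    design_term("N add", "n_treatment", "main", denominator = "Plot(Date*N)",
                exchange = list(blocks = plotv)),
    design_term("Date*N add", c("collection_date", "n_treatment"),
                "interaction", denominator = "Plot(Date*N)",
                exchange = list(blocks = plotv)),
    design_term("Plot(Date*N)", plotv, "nested",
                exchange = list(within = c("collection_date", "n_treatment"))))
}

#' One-way design (single factor over the residual, free permutation)
#' @param var metadata column holding the factor.
#' @param name display name (defaults to `var`).
#' @return a [design_spec()].
#' @export
design_oneway <- function(var, name = var) {
  design_spec(design_term(name, var, "main"))
}

# model matrix for one design term (no intercept column)
term_matrix <- function(term, meta) {
  fac <- lapply(term$vars, function(v) factor(meta[[v]]))
  if (term$type == "nested") {
    cell <- droplevels(interaction(fac, drop = TRUE))
    X <- stats::model.matrix(~ 0 + cell)
  } else {
    cs <- lapply(fac, function(f) {
      stats::contr.sum(nlevels(f))[as.integer(f), , drop = FALSE]
    })
    X <- Reduce(function(a, b) {
      # row-wise Kronecker: interaction contrast columns
      out <- matrix(0, nrow(a), ncol(a) * ncol(b))
      k <- 0L
      for (i in seq_len(ncol(a))) for (j in seq_len(ncol(b))) {
        k <- k + 1L
        out[, k] <- a[, i] * b[, j]
      }
      out
    }, cs)
  }
  unname(as.matrix(X))
}

proj <- function(X) {
  # projection onto the column space of [1, X]
  Z <- cbind(1, X)
  q <- qr(Z)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

rank_of <- function(X) qr(cbind(1, X))$rank

# does span([1, X_container]) contain the columns of X?
spans <- function(container, X) {
  rank_of(container) == rank_of(cbind(container, X))
}

gower_matrix <- function(d) {
  m <- as.matrix(d)
  A <- -0.5 * m^2
  n <- nrow(A)
  C <- diag(n) - matrix(1 / n, n, n)
  C %*% A %*% C
}

perm_indices <- function(term, meta, n) {
  ex <- term$exchange
  if (identical(ex, "free")) return(sample.int(n))
  if (!is.null(ex$blocks)) {
    f <- droplevels(interaction(meta[ex$blocks], drop = TRUE))
    idx <- split(seq_len(n), f)
    sz <- lengths(idx)
    if (length(unique(sz)) != 1)
      stop("block permutation requires equal-sized blocks")
    unlist(idx[sample.int(length(idx))], use.names = FALSE)
  } else if (!is.null(ex$within)) {
    f <- droplevels(interaction(meta[ex$within], drop = TRUE))
    pi <- seq_len(n)
    for (idx in split(seq_len(n), f)) pi[idx] <- idx[sample.int(length(idx))]
    pi
  } else stop("unknown exchange scheme")
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' Distance-based PERMANOVA for nested split-plot designs
#'
#' Partitions a dissimilarity matrix by the terms of a [design_spec()] using
#' the Gower-centered inner-product decomposition. Sums of squares are
#' type III (marginal): each term is adjusted for every other term whose
#' column space does not contain it, which reproduces the split-plot scheme
#' where fixed whole-plot terms are adjusted among themselves and the nested
#' random plot term absorbs the remaining between-cell variation. Pseudo-F
#' uses each term's designated denominator mean square. P-values come from
#' Freedman-Lane permutation of reduced-model residuals, with permutations
#' restricted to each term's exchangeable units, reported as
#' \eqn{(b + 1)/(n_{perm} + 1)}. Omega-squared is
#' \eqn{(SS - df\,MS_{denom}) / (SS_{total} + MS_{denom})}.
#'
#' @param d a `dist` of pairwise dissimilarities.
#' @param meta metadata with the design columns; rows are matched to the
#'   labels of `d`.
#' @param design a [design_spec()].
#' @param n_perm number of permutations (study convention 9999).
#' @param seed integer seed for the permutation stream.
#' @param exact if `TRUE`, enumerate all n! sample permutations instead of
#'   Monte-Carlo sampling (one free-permutation term, n <= 8 only).
#' @return object of class `permanova`: list with `table` (term rows plus
#'   Residual and Total) and the design.
#' @export
permanova <- function(d, meta, design, n_perm = 999, seed = NULL,
                      exact = FALSE) {
  stopifnot(inherits(design, "design_spec"))
  labs <- attr(d, "Labels")
  if (!is.null(labs)) {
    if (!all(labs %in% meta$sample_id))
      stop("distance labels missing from metadata")
    meta <- meta[match(labs, meta$sample_id), ]
  }
  n <- attr(d, "Size")
  if (nrow(meta) != n) stop("metadata rows do not match distance size")

  G <- gower_matrix(d)
  ss_total <- sum(diag(G))
  Xs <- lapply(design, term_matrix, meta = meta)
  nm <- names(design)
  k <- length(Xs)

  # mutual containment = aliased (confounded) terms
  if (k > 1) for (i in seq_len(k - 1)) for (j in (i + 1):k)
    if (spans(Xs[[i]], Xs[[j]]) && spans(Xs[[j]], Xs[[i]]))
      stop("aliased (confounded) terms: ", nm[i], ", ", nm[j])

  # adjustment sets by the containment rule
  adj <- lapply(seq_len(k), function(i) {
    keep <- vapply(seq_len(k), function(j)
      j != i && !spans(Xs[[j]], Xs[[i]]), TRUE)
    which(keep)
  })

  Xcat <- function(ix) if (length(ix)) do.call(cbind, Xs[ix]) else
    matrix(0, n, 0)
  H_red <- lapply(seq_len(k), function(i) proj(Xcat(adj[[i]])))
  H_aug <- lapply(seq_len(k), function(i) proj(Xcat(c(adj[[i]], i))))
  H_all <- proj(Xcat(seq_len(k)))

  df <- vapply(seq_len(k), function(i)
    rank_of(Xcat(c(adj[[i]], i))) - rank_of(Xcat(adj[[i]])), 0L)
  if (any(df == 0))
    stop("aliased (confounded) terms: ", paste(nm[df == 0], collapse = ", "))
  df_res <- n - rank_of(Xcat(seq_len(k)))  # rank_of includes the intercept

  ss_of <- function(Gm) {
    s <- vapply(seq_len(k), function(i)
      sum(H_aug[[i]] * Gm) - sum(H_red[[i]] * Gm), 0)
    res <- sum(diag(Gm)) - sum(H_all * Gm)
    c(s, res)
  }
  obs <- ss_of(G)
  SS <- obs[seq_len(k)]
  ss_res <- obs[k + 1L]
  MS <- SS / df
  ms_res <- ss_res / df_res

  den_ix <- vapply(design, function(t)
    if (t$denominator == "Residual") 0L else match(t$denominator, nm), 0L)
  ms_den <- ifelse(den_ix == 0L, ms_res, MS[pmax(den_ix, 1L)])
  Fobs <- MS / ms_den

  omega2 <- vapply(seq_len(k), function(i)
    omega_squared(SS[i], df[i], ms_den[i], ss_total), 0)

  # permutation p-values (Freedman-Lane on reduced-model residuals)
  p <- rep(NA_real_, k)
  if (n_perm >= 1 || exact) {
    if (!is.null(seed)) set.seed(seed)
    Id <- diag(n)
    perm_F <- function(i, pi) {
      M <- H_red[[i]] + (Id - H_red[[i]])[pi, , drop = FALSE]
      Gp <- M %*% G %*% t(M)
      s <- sum(H_aug[[i]] * Gp) - sum(H_red[[i]] * Gp)
      den <- if (den_ix[i] == 0L)
        (sum(diag(Gp)) - sum(H_all * Gp)) / df_res
      else {
        j <- den_ix[i]
        (sum(H_aug[[j]] * Gp) - sum(H_red[[j]] * Gp)) / df[j]
      }
      (s / df[i]) / den
    }
    if (exact) {
      if (n > 8) stop("exact enumeration limited to n <= 8")
      perms <- all_perms(n)
      for (i in seq_len(k)) {
        Fstar <- vapply(perms, function(pi) perm_F(i, pi), 0)
        p[i] <- mean(Fstar >= Fobs[i] - 1e-12)
      }
    } else {
      for (i in seq_len(k)) {
        hits <- 0L
        for (b in seq_len(n_perm)) {
          pi <- perm_indices(design[[i]], meta, n)
          if (perm_F(i, pi) >= Fobs[i] - 1e-12) hits <- hits + 1L
        }
        p[i] <- (hits + 1) / (n_perm + 1)
      }
    }
  }

  tab <- data.frame(
    term = c(nm, "Residual", "Total"),
    df = c(df, df_res, n - 1L),
    SS = c(SS, ss_res, ss_total),
    MS = c(MS, ms_res, NA),
    pseudo_F = c(Fobs, NA, NA),
    R2 = c(SS, ss_res, ss_total) / ss_total,
    omega2 = c(omega2, NA, NA),
    p_perm = c(p, NA, NA),
    row.names = NULL)
  structure(list(table = tab, design = design, n_perm = n_perm,
                 exact = exact, seed = seed),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (type III marginal SS,",
      if (x$exact) "exact enumeration" else paste(x$n_perm, "permutations"),
      ")\n")
  print(transform(x$table,
                  SS = signif(SS, 5), MS = signif(MS, 4),
                  pseudo_F = signif(pseudo_F, 4), R2 = signif(R2, 4),
                  omega2 = signif(omega2, 4)), row.names = FALSE)
  invisible(x)
}

#' Omega-squared effect size for a distance-based ANOVA term
#'
#' \eqn{\omega^2 = (SS - df\,MS_{denom}) / (SS_{total} + MS_{denom})};
#' zero when the term's mean square equals its error mean square, and
#' possibly negative (reported as computed).
#'
#' @param ss_effect,df_effect term sum of squares and degrees of freedom.
#' @param ms_denom mean square of the term's designated error stratum.
#' @param ss_total total sum of squares.
#' @return omega-squared value.
#' @export
omega_squared <- function(ss_effect, df_effect, ms_denom, ss_total) {
  stopifnot(df_effect > 0)
  if (ss_total + ms_denom <= 0) stop("ss_total + ms_denom must be positive")
  (ss_effect - df_effect * ms_denom) / (ss_total + ms_denom)
}

#' Beta dispersion: distances to group spatial medians, with permutation test
#'
#' Principal-coordinate embedding with negative-eigenvalue correction,
#' per-sample distance to the group spatial median, and a permutation F-test
#' of group differences on those distances (via \pkg{vegan}'s
#' `betadisper`/`permutest`). Groups of size 1 are excluded with a warning.
#'
#' @param d a `dist`.
#' @param groups factor of group membership aligned to `d`'s labels.
#' @param n_perm permutations for the F-test.
#' @param seed integer seed.
#' @return list with `distances` (named per-sample), `F`, `p`, and the
#'   underlying `betadisper` fit.
#' @export
beta_dispersion <- function(d, groups, n_perm = 999, seed = NULL) {
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    drop <- names(sizes)[sizes < 2]
    warning("excluding size-1 groups: ", paste(drop, collapse = ", "))
    keep <- !groups %in% drop
    d <- stats::as.dist(as.matrix(d)[keep, keep])
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need >= 2 groups with >= 2 members")
  fit <- vegan::betadisper(d, groups, type = "median")
  if (!is.null(seed)) set.seed(seed)
  pt <- vegan::permutest(fit, permutations = n_perm)
  dist_out <- fit$distances
  names(dist_out) <- attr(d, "Labels")
  list(distances = dist_out,
       F = pt$tab[1, "F"],
       p = pt$tab[1, "Pr(>F)"],
       fit = fit)
}
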
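test_that("pseudo-F on univariate Euclidean data equals classical ANOVA F", {
  set.seed(1)
  for (rep in 1:5) {
    g <- factor(rep(letters[1:3], each = 5))
    y <- rnorm(15) + as.numeric(g)
    meta <- flat_meta(paste0("s", 1:15), as.character(g))
    d <- dist(setNames(y, meta$sample_id))
    attr(d, "Labels") <- meta$sample_id
    pt <- permanova(d, meta, design_oneway("site"), n_perm = 0)
    f_aov <- summary(aov(y ~ g))[[1]]$`F value`[1]
    expect_equal(pt$table$pseudo_F[1], f_aov, tolerance = 1e-8)
    expect_equal(pt$table$df[1:2], c(2L, 12L))
  }
})

test_that("Gower identity: SS_total equals sum of squared deviations", {
  set.seed(5)
  x <- matrix(rnorm(12 * 4), 12)
  d <- dist(x)
  g <- spatiomic:::gower_matrix(d)
  expect_equal(sum(diag(g)),
               sum(scale(x, scale = FALSE)^2), tolerance = 1e-8)
})

test_that("marginal SS agree with adonis2 on a crossed two-factor design", {
  set.seed(8)
  n <- 24
  a <- factor(rep(c("a1", "a2"), each = 12))
  b <- factor(rep(rep(c("b1", "b2", "b3"), each = 4), 2))
  x <- matrix(rpois(n * 8, 20 + 5 * as.numeric(a)), n)
  rownames(x) <- paste0("s", 1:n)
  d <- vegan::vegdist(x)
  meta <- flat_meta(rownames(x), as.character(a))
  meta$plot <- as.character(b)
  des <- design_spec(
    design_term("A", "site", "main"),
    design_term("B", "plot", "main"),
    design_term("A:B", c("site", "plot"), "interaction"))
  pt <- permanova(d, meta, des, n_perm = 0)
  ref <- vegan::adonis2(d ~ site * plot, data = meta, by = "margin",
                        permutations = 19)
  # adonis2 margins cover main effects only when the interaction is absent;
  # compare the interaction row directly and totals
  expect_equal(pt$table$SS[pt$table$term == "A:B"],
               ref["site:plot", "SumOfSqs"], tolerance = 1e-8)
  expect_equal(pt$table$SS[pt$table$term == "Residual"],
               ref["Residual", "SumOfSqs"], tolerance = 1e-8)
  expect_equal(sum(pt$table$df[1:4]) + 0, 23)
})

test_that("regional scaffold reproduces the nested split-plot df column", {
  cfg <- sim_config("mle", n_taxa = 30, depth = 300)
  meta <- simulate_design(cfg, seed = 1)
  soil <- meta[meta$niche == "soil", ]
  sim <- simulate_community(cfg, meta, seed = 1)
  d <- bray_curtis(sim$table[soil$sample_id, ])
  pt <- permanova(d, soil, design_regional(), n_perm = 0)
  expect_equal(pt$table$term[1:4],
               c("Site", "N add", "Site*N add", "Plot(Site*N)"))
  expect_equal(pt$table$df, c(4L, 1L, 4L, 28L, 76L, 113L))
  # marginal SS nearly decompose the total (one site lost a block)
  expect_equal(sum(pt$table$SS[1:5]), pt$table$SS[6], tolerance = 1e-2)
  expect_true(all(pt$table$R2 >= 0 & pt$table$R2 <= 1))

  # on a fully balanced design the decomposition is exact
  cfgb <- sim_config("custom", n_taxa = 30, depth = 300,
                     sites = c("A", "B"), plots_per_site = c(4, 4))
  metab <- simulate_design(cfgb, seed = 3)
  soilb <- metab[metab$niche == "soil", ]
  simb <- simulate_community(cfgb, metab, seed = 3)
  db <- bray_curtis(simb$table[soilb$sample_id, ])
  ptb <- permanova(db, soilb, design_regional(), n_perm = 0)
  expect_equal(sum(ptb$table$SS[1:5]), ptb$table$SS[6], tolerance = 1e-8)
})

test_that("aliased designs are reported as confounded", {
  meta <- flat_meta(paste0("s", 1:6), rep(c("x", "y"), each = 3))
  meta$plot <- meta$site  # plot aliased with site
  d <- dist(1:6)
  attr(d, "Labels") <- meta$sample_id
  des <- design_spec(design_term("Site", "site", "main"),
                     design_term("Plot", "plot", "main"))
  expect_error(permanova(d, meta, des, n_perm = 0), "aliased")
})

test_that("exact permutation p equals a brute-force enumeration oracle", {
  set.seed(3)
  y <- c(0.1, 0.5, 0.9, 1.4, 2.2, 3.1)
  g <- rep(c("a", "b"), each = 3)
  meta <- flat_meta(paste0("s", 1:6), g)
  d <- dist(y)
  attr(d, "Labels") <- meta$sample_id
  pt <- permanova(d, meta, design_oneway("site"), exact = TRUE)

  # oracle: F statistic over all 720 relabelings, computed by classical ANOVA
  perms <- spatiomic:::all_perms(6)
  f_of <- function(yy) {
    fit <- summary(aov(yy ~ factor(g)))[[1]]
    fit$`F value`[1]
  }
  f_obs <- f_of(y)
  f_all <- vapply(perms, function(p) f_of(y[p]), 0)
  expect_equal(pt$table$p_perm[1], mean(f_all >= f_obs - 1e-12),
               tolerance = 1e-12)
})

test_that("Monte-Carlo p converges to the exact p at large n_perm", {
  y <- c(0.1, 0.5, 0.9, 1.4, 2.2, 3.1)
  meta <- flat_meta(paste0("s", 1:6), rep(c("a", "b"), each = 3))
  d <- dist(y)
  attr(d, "Labels") <- meta$sample_id
  exact <- permanova(d, meta, design_oneway("site"), exact = TRUE)
  mc <- permanova(d, meta, design_oneway("site"), n_perm = 1999, seed = 4)
  expect_lt(abs(mc$table$p_perm[1] - exact$table$p_perm[1]), 0.025)
})

test_that("omega-squared follows the formula and is bounded by R2", {
  expect_equal(omega_squared(10, 2, 1, 20), 8 / 21)
  expect_equal(omega_squared(2 * 1.5, 2, 1.5, 10), 0)  # SS = df * MS_denom
  expect_error(omega_squared(1, 1, -5, 2), "positive")
  expect_error(omega_squared(1, 0, 1, 2))

  set.seed(11)
  for (i in 1:50) {
    n <- sample(9:18, 1)
    g <- factor(sample(letters[1:3], n, replace = TRUE))
    while (nlevels(droplevels(g)) < 3) g <- factor(sample(letters[1:3], n, TRUE))
    x <- matrix(rnorm(n * 3), n)
    rownames(x) <- paste0("s", 1:n)
    meta <- flat_meta(rownames(x), as.character(g))
    pt <- permanova(dist(x), meta, design_oneway("site"), n_perm = 0)
    expect_lte(pt$table$omega2[1], pt$table$R2[1] + 1e-12)
  }
})

test_that("whole-plot effects use the plot mean square as denominator", {
  cfg <- sim_config("mle", n_taxa = 20, depth = 200, site_sigma = 0)
  meta <- simulate_design(cfg, seed = 2)
  soil <- meta[meta$niche == "soil", ]
  sim <- simulate_community(cfg, meta, seed = 2)
  d <- bray_curtis(sim$table[soil$sample_id, ])
  pt <- permanova(d, soil, design_regional(), n_perm = 0)
  tab <- pt$table
  ms_plot <- tab$MS[tab$term == "Plot(Site*N)"]
  expect_equal(tab$pseudo_F[tab$term == "Site"],
               tab$MS[tab$term == "Site"] / ms_plot, tolerance = 1e-12)
  ms_res <- tab$MS[tab$term == "Residual"]
  expect_equal(tab$pseudo_F[tab$term == "Plot(Site*N)"],
               ms_plot / ms_res, tolerance = 1e-12)
})

test_that("beta dispersion recovers closed-form distances in 1-D", {
  x <- c(1, 2, 3, 10, 20, 26)
  g <- rep(c("a", "b"), each = 3)
  d <- dist(x)
  attr(d, "Labels") <- paste0("s", 1:6)
  bd <- beta_dispersion(d, g, n_perm = 99, seed = 1)
  med <- c(rep(median(x[1:3]), 3), rep(median(x[4:6]), 3))
  expect_equal(unname(bd$distances), abs(x - med), tolerance = 1e-8)
})

test_that("beta dispersion detects a scaled group and excludes singletons", {
  set.seed(21)
  a <- matrix(rnorm(20 * 2), 20)
  b <- matrix(rnorm(20 * 2, sd = 3), 20)
  x <- rbind(a, b)
  rownames(x) <- paste0("s", 1:40)
  d <- dist(x)
  bd <- beta_dispersion(d, rep(c("a", "b"), each = 20), n_perm = 999, seed = 2)
  expect_lt(bd$p, 0.05)

  g <- c(rep("a", 20), rep("b", 19), "c")
  expect_warning(beta_dispersion(d, g, n_perm = 19), "size-1")
})
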
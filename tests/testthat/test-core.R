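core_meta <- function(tab, groups) {
  m <- flat_meta(rownames(tab), groups)
  m
}

test_that("occupancy statistics match a brute-force per-taxon loop", {
  for (seed in 1:3) {
    tab <- random_table(8, 10, depth = 60, seed = seed)
    groups <- rep(c("A", "B"), each = 4)
    st <- occupancy_abundance(tab, core_meta(tab, groups), group_by = "site")
    m <- unclass(tab)
    rel <- m / rowSums(m)
    for (t in seq_len(ncol(m))) {
      expect_equal(st$occupancy[t], mean(m[, t] > 0))
      expect_equal(st$mean_rel_abund[t], mean(rel[, t]))
      ga <- mean(m[groups == "A", t] > 0)
      gb <- mean(m[groups == "B", t] > 0)
      expect_equal(st$mean_group_occupancy[t], mean(c(ga, gb)))
      expect_equal(st$replicate_consistency[t], mean(c(ga == 1, gb == 1)))
    }
  }
})

test_that("ranking is a total order with the documented tie rules", {
  tab <- toy_table(rbind(c(10L, 10L, 1L, 0L),
                         c(10L, 20L, 1L, 5L),
                         c(10L, 30L, 0L, 5L),
                         c(10L, 40L, 0L, 5L)))
  st <- occupancy_abundance(tab, core_meta(tab, rep(c("A", "B"), each = 2)))
  rk <- rank_taxa(st)
  # t2 is everywhere and more abundant than t1 (also everywhere)
  expect_equal(rk$taxon_id[1:2], c("t2", "t1"))
  expect_equal(rk$rank_index[1:2], c(1, 1))
  # permutation invariance of the ranking
  for (s in 1:5) {
    set.seed(s)
    rk2 <- rank_taxa(st[sample(nrow(st)), ])
    expect_equal(rk2$taxon_id, rk$taxon_id)
  }
})

test_that("contribution curve equals an exhaustive pairwise oracle", {
  set.seed(13)
  tab <- random_table(4, 5, depth = 50, seed = 13)
  st <- occupancy_abundance(tab, core_meta(tab, rep(c("A", "B"), each = 2)))
  rk <- rank_taxa(st)
  cv <- bc_contribution_curve(tab, rk)
  m <- unclass(tab)[, rk$taxon_id]
  # oracle: partial BC with full-table denominator, averaged over all pairs
  oracle <- sapply(seq_len(ncol(m)), function(i) {
    vals <- c()
    for (a in 1:3) for (b in (a + 1):4) {
      num <- sum(abs(m[a, seq_len(i)] - m[b, seq_len(i)]))
      den <- sum(m[a, ] + m[b, ])
      vals <- c(vals, num / den)
    }
    mean(vals)
  })
  expect_equal(cv$bc_contribution, oracle / oracle[5], tolerance = 1e-12)
  expect_true(all(diff(cv$bc_contribution) >= -1e-12))
  expect_equal(cv$bc_contribution[5], 1, tolerance = 1e-9)

  # a taxon absent everywhere contributes nothing
  m2 <- cbind(m, t6 = 0L)
  tab2 <- otu_table(m2)
  st2 <- occupancy_abundance(tab2, core_meta(tab2, rep(c("A", "B"), each = 2)))
  cv2 <- bc_contribution_curve(tab2, rank_taxa(st2))
  expect_equal(cv2$bc_contribution[5:6], c(1, 1), tolerance = 1e-9)
})

test_that("the last-5%-increase rule picks the documented threshold index", {
  curve <- data.frame(rank = 1:4, taxon_id = paste0("t", 1:4),
                      bc_contribution = c(0.40, 0.60, 0.62, 0.624))
  tab <- toy_table(matrix(c(10L, 10L, 10L, 10L, 10L, 10L, 10L, 10L), 2),
                   taxa = paste0("t", 1:4))
  cr <- select_core(curve, tab, threshold = 0.05)
  expect_equal(cr$threshold_index, 2L)  # 0.6/0.4 - 1 = 50%; later steps < 5%
  expect_equal(cr$core_taxa, c("t1", "t2"))
  expect_equal(cr$richness_share, 50)

  # raising the threshold never enlarges the core
  sizes <- sapply(c(0.01, 0.05, 0.1, 0.3, 0.6),
                  function(th) suppressWarnings(
                    select_core(curve, tab, threshold = th)$threshold_index))
  expect_true(all(diff(sizes) <= 0))

  # no qualifying step: top taxon with warning
  flat <- transform(curve, bc_contribution = c(0.97, 0.98, 0.99, 1))
  expect_warning(cr2 <- select_core(flat, tab, threshold = 0.05), "top taxon")
  expect_equal(cr2$threshold_index, 1L)
})

test_that("core selection matches brute force on all small fixtures", {
  # exhaustive re-evaluation of the rule on random <= 12-taxon tables
  for (seed in 1:10) {
    nt <- sample(2:12, 1)
    tab <- random_table(6, nt, depth = 40, seed = seed + 100)
    st <- occupancy_abundance(tab, core_meta(tab, rep(c("A", "B", "C"), 2)))
    rk <- rank_taxa(st)
    cv <- bc_contribution_curve(tab, rk)
    cr <- suppressWarnings(select_core(cv, tab, threshold = 0.05))
    c_i <- cv$bc_contribution
    ok <- which(c_i[-1] / c_i[-nt] - 1 >= 0.05 - 1e-12) + 1L
    expected <- if (length(ok)) max(ok) else 1L
    expect_equal(cr$threshold_index, expected)
    expect_equal(cr$core_taxa, cv$taxon_id[seq_len(expected)])
  }
})

test_that("Sloan model limits behave and perfect fits give R2 = 1", {
  # occupancy generated exactly from the model's own prediction
  N <- 1000
  m_true <- 0.2
  p <- exp(seq(log(1e-4), log(0.05), length.out = 40))
  p <- p / sum(p) * 0.5
  occ <- 1 - pbeta(1 / N, N * m_true * p, N * m_true * (1 - p))
  st <- data.frame(taxon_id = paste0("t", 1:40), mean_rel_abund = p,
                   occupancy = occ)
  fit <- fit_neutral(st, N = N, n_samples = 50)
  expect_equal(fit$m, m_true, tolerance = 1e-3)
  expect_gt(fit$r2, 0.9999)
  expect_false(fit$failed)
  # predicted occupancy is monotone in mean abundance and -> 1 as p -> 1
  expect_true(all(diff(fit$taxa$predicted[order(p)]) >= -1e-12))
  big <- 1 - pbeta(1 / N, N * fit$m * 0.999, N * fit$m * 0.001)
  expect_gt(big, 0.999)
})

test_that("taxa are classified against the Wilson band", {
  N <- 1000
  p <- seq(0.001, 0.02, length.out = 20)
  occ <- 1 - pbeta(1 / N, N * 0.1 * p, N * 0.1 * (1 - p))
  occ[1] <- 1      # far above neutral expectation at tiny abundance
  occ[20] <- 0.05  # far below
  st <- data.frame(taxon_id = paste0("t", 1:20), mean_rel_abund = p,
                   occupancy = occ)
  fit <- fit_neutral(st, N = N, n_samples = 100)
  expect_equal(fit$taxa$class[1], "above")
  expect_equal(fit$taxa$class[20], "below")
  expect_true(all(fit$taxa$class %in% c("above", "neutral", "below")))
  expect_true(all(fit$taxa$lower >= 0 & fit$taxa$upper <= 1))
})

test_that("differential family abundance reports log2 median ratios", {
  ann <- data.frame(taxon_id = paste0("t", 1:4),
                    family = c("F1", "F1", "F2", "F3"))
  # root: F1 at 40% of reads; soil: F1 at 10%; F3 absent in root
  root <- toy_table(rbind(c(20L, 20L, 60L, 0L), c(20L, 20L, 60L, 0L),
                          c(20L, 20L, 60L, 0L)))
  soil <- toy_table(rbind(c(5L, 5L, 70L, 20L), c(5L, 5L, 70L, 20L),
                          c(5L, 5L, 70L, 20L)))
  res <- differential_family_abundance(root, soil, ann)
  f1 <- res[res$family == "F1", ]
  expect_equal(f1$log2_ratio, 2)  # 0.4 vs 0.1
  expect_false(f1$pseudo)
  f3 <- res[res$family == "F3", ]
  expect_true(f3$pseudo)
  expect_lt(f3$log2_ratio, 0)
  expect_true(all(res$p_adjust >= res$p_value - 1e-12))
})

test_that("Wilcoxon p-values match the exact test at tiny n", {
  set.seed(14)
  a <- c(0.01, 0.02, 0.03, 0.09, 0.11)
  b <- c(0.04, 0.05, 0.06, 0.07, 0.12)
  ann <- data.frame(taxon_id = "t1", family = "F1")
  root <- toy_table(cbind(t1 = as.integer(a * 1000),
                          t2 = as.integer((1 - a) * 1000)))
  soil <- toy_table(cbind(t1 = as.integer(b * 1000),
                          t2 = as.integer((1 - b) * 1000)))
  ann <- data.frame(taxon_id = c("t1", "t2"), family = c("F1", ""))
  res <- differential_family_abundance(root, soil, ann)
  pr <- unclass(root)[, "t1"] / rowSums(root)
  ps <- unclass(soil)[, "t1"] / rowSums(soil)
  exact <- stats::wilcox.test(pr, ps, exact = TRUE)$p.value
  approx <- res$p_value[res$family == "F1"]
  expect_lt(abs(approx - exact), 0.15)  # normal approximation at n = 5
})

test_that("guild grouping honors confidence and flags unmapped labels", {
  ann <- data.frame(
    taxon_id = paste0("t", 1:5),
    guild_label = c("Arbuscular Mycorrhizal", "Plant Pathogen",
                    "Wood Saprotroph", "Weird-Multi-Guild", ""),
    confidence = c("Highly Probable", "Probable", "Possible",
                   "Probable", "Probable"))
  gm <- data.frame(
    guild_label = c("Arbuscular Mycorrhizal", "Plant Pathogen",
                    "Wood Saprotroph"),
    guild_group = c("symbiotroph", "pathogen", "saprotroph"))
  expect_warning(out <- group_guilds(ann, gm), "Weird-Multi-Guild")
  expect_equal(out$guild_group,
               c("symbiotroph", "pathogen", "unknown",  # Possible dropped
                 "Weird-Multi-Guild", "unknown"))
})

test_that("threshold scan reports shares and neutral fit across thresholds", {
  tab <- random_table(10, 30, depth = 500, seed = 15)
  meta <- core_meta(tab, rep(c("A", "B"), each = 5))
  st <- occupancy_abundance(tab, meta)
  cv <- bc_contribution_curve(tab, rank_taxa(st))
  scan <- core_threshold_scan(cv, tab, st, thresholds = c(0.02, 0.05, 0.1))
  expect_equal(nrow(scan), 3L)
  expect_true(all(diff(scan$core_size) <= 0))
  expect_true(all(scan$richness_share >= 0 & scan$richness_share <= 100))
})
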
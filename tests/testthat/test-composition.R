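test_that("composition profiles count bases and derive skews correctly", {
  m <- rbind(t1 = c("A", "A", "T", "T"), t2 = c("A", "A", "A", "A"),
             t3 = c("A", "A", "C", "G"), t4 = c("-", "N", "?", "R"))
  a <- rad_alignment(m)
  pr <- composition_profile(a)
  expect_equal(pr$at_skew[1], 0)           # AATT
  expect_equal(pr$gc_percent[1], 0)
  expect_equal(pr$at_skew[2], 1)           # AAAA
  expect_equal(pr$gc_percent[3], 50)       # AACG
  expect_equal(pr$at_skew[3], 1)
  expect_equal(pr$gc_skew[3], 0)
  expect_equal(pr$n_obs[4], 0)             # only gaps/ambiguities
  expect_true(is.na(pr$at_skew[4]))
  # per-gene mode splits counts by partition
  a2 <- rad_alignment(m, partition = c("g1", "g1", "g2", "g2"))
  pg <- composition_profile(a2, per_gene = TRUE)
  expect_equal(nrow(pg), 8L)
  expect_equal(pg$A[pg$taxon == "t1" & pg$gene == "g1"], 2)
  expect_equal(pg$T[pg$taxon == "t1" & pg$gene == "g2"], 2)
  # invariance to site and taxon order
  pr_shuf <- composition_profile(
    rad_alignment(m[c(3, 1, 4, 2), c(4, 2, 1, 3)]))
  for (tx in rownames(m))
    expect_equal(pr_shuf$A[pr_shuf$taxon == tx], pr$A[pr$taxon == tx])
})

test_that("chi-square homogeneity matches hand arithmetic and chisq.test", {
  pr <- data.frame(taxon = c("x", "y"),
                   A = c(90, 10), C = c(10, 90), G = c(0, 0), T = c(0, 0))
  res <- suppressWarnings(chi_square_homogeneity(pr))
  # hand computation: 2x2 effective table, all expected = 50
  expect_equal(res$statistic, 4 * (40^2 / 50))
  expect_equal(res$df, 3L)
  tab <- rbind(c(90, 10, 5, 20), c(30, 40, 25, 30), c(60, 20, 10, 35))
  pr2 <- data.frame(taxon = c("a", "b", "c"), A = tab[, 1], C = tab[, 2],
                    G = tab[, 3], T = tab[, 4])
  res2 <- chi_square_homogeneity(pr2)
  ref <- suppressWarnings(stats::chisq.test(tab))
  expect_equal(res2$statistic, unname(ref$statistic))
  expect_equal(res2$df, unname(ref$parameter))
  expect_equal(res2$p_value, unname(ref$p.value))
  # identical frequencies: statistic 0, p 1
  same <- data.frame(taxon = c("u", "v"), A = c(10, 20), C = c(10, 20),
                     G = c(10, 20), T = c(10, 20))
  res3 <- chi_square_homogeneity(same)
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p_value, 1)
  expect_warning(chi_square_homogeneity(
    data.frame(taxon = c("u", "v"), A = c(1, 1), C = c(1, 0),
               G = c(0, 1), T = c(2, 1))), "below 1")
})

test_that("stationary simulated data reject at roughly the nominal rate", {
  set.seed(121)
  n_rep <- 200
  rej <- 0
  for (i in seq_len(n_rep)) {
    counts <- stats::rmultinom(6, 400, c(.3, .2, .2, .3))
    pr <- data.frame(taxon = paste0("t", 1:6), A = counts[1, ],
                     C = counts[2, ], G = counts[3, ], T = counts[4, ])
    rej <- rej + (chi_square_homogeneity(pr)$p_value < 0.05)
  }
  expect_equal(rej / n_rep, 0.05, tolerance = 0.03 / 0.05)
})

test_that("AT-skew clustering merges identical taxa first", {
  pr <- data.frame(taxon = rep(c("a", "b", "c", "d"), each = 3),
                   gene = rep(c("g1", "g2", "g3"), 4),
                   at_skew = c(0.1, 0.2, 0.3,
                               0.1, 0.2, 0.3,
                               -0.5, -0.4, -0.2,
                               0.6, 0.7, 0.8))
  hc <- skew_clustering(pr)
  expect_equal(hc$height[1], 0)            # identical vectors merge at 0
  first <- rownames(attr(hc, "matrix"))[-hc$merge[1, ]]
  expect_setequal(first, c("a", "b"))
  expect_true(all(diff(hc$height) >= -1e-12))  # monotone merges
  expect_error(skew_clustering(pr[pr$taxon %in% c("a", "b"), ]), "3 taxa")
  # missing taxon-gene cells are imputed and flagged
  pr2 <- pr[-2, ]
  hc2 <- skew_clustering(pr2)
  expect_equal(sum(attr(hc2, "imputed")), 1L)
})

test_that("phylogenetic ANOVA: observed F is the textbook statistic", {
  tr <- ape::read.tree(
    text = "((a:1,b:1):1,((c:1,d:1):0.5,(e:1,f:1):0.5):0.5);")
  trait <- c(a = 1.2, b = 0.8, c = 3.1, d = 2.9, e = 3.3, f = 2.7)
  grp <- c("low", "low", "high", "high", "high", "high")
  res <- phylo_anova(trait, grp, tr, n_sim = 200, seed = 5)
  ref <- stats::anova(stats::lm(trait ~ grp))
  expect_equal(res$F, ref$`F value`[1])
  expect_equal(res$p_parametric, ref$`Pr(>F)`[1])
  expect_gte(res$p_phylo, 0)
  expect_lte(res$p_phylo, 1)
  expect_error(phylo_anova(trait, grp, tr, n_sim = 0), "n_sim")
  expect_error(phylo_anova(trait, rep("one", 6), tr), "2 groups")
  # zero variance: nothing to test
  flat <- phylo_anova(stats::setNames(rep(1, 6), names(trait)), grp, tr,
                      n_sim = 10)
  expect_equal(flat$p_phylo, 1)
})

test_that("phylogenetic ANOVA is calibrated on a star tree", {
  # on a star tree the Brownian null is an iid null: rejection ~ alpha and
  # the phylogenetic p approaches the parametric p
  set.seed(123)
  n_tax <- 24
  star <- ape::read.tree(text = paste0(
    "(", paste0("t", 1:n_tax, ":1", collapse = ","), ");"))
  grp <- rep(c("g1", "g2", "g3"), each = 8)
  rej <- 0; n_rep <- 60; gap <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    trait <- stats::setNames(rnorm(n_tax), paste0("t", 1:n_tax))
    res <- phylo_anova(trait, grp, star, n_sim = 400)
    rej <- rej + (res$p_phylo < 0.05)
    gap[i] <- abs(res$p_phylo - res$p_parametric)
  }
  expect_lte(rej / n_rep, 0.12)
  expect_gte(rej / n_rep, 0.0)
  expect_lt(stats::median(gap), 0.05)
})

test_that("phylogenetic ANOVA agrees with the phytools implementation", {
  skip_if_not_installed("phytools")
  set.seed(125)
  tr <- ape::rcoal(12)
  trait <- stats::setNames(rnorm(12) + rep(c(0, 1.5), each = 6),
                           tr$tip.label)
  grp <- stats::setNames(rep(c("A", "B"), each = 6), tr$tip.label)
  mine <- phylo_anova(trait, grp, tr, n_sim = 2000, seed = 1)
  ref <- phytools::phylANOVA(tr, grp, trait, nsim = 2000, posthoc = FALSE)
  expect_equal(mine$F, ref$F, tolerance = 1e-8)
  expect_equal(mine$p_phylo, ref$Pf, tolerance = 0.07)
})

test_that("clade rate summaries: single tree, identity subsample, recovery", {
  cfg <- radiation_config(seed = 77, n_genes = 2, n_per_clade = 3)
  ti <- generate_radiation_tree(cfg)
  # ultrametric chronogram: every clade has the same root-to-tip depth
  s1 <- clade_rate_comparison(list(ti$chronogram), ti$clade_map,
                              subsample_fraction = 1)
  expect_lt(diff(range(s1$mean)), 1e-6)
  expect_true(all(attr(s1, "overlap")))
  # subsample_fraction = 1 reproduces the full-sample summary
  trees <- replicate(10, {
    t2 <- ti$rate_tree
    t2$edge.length <- t2$edge.length * stats::runif(1, 0.9, 1.1)
    t2
  }, simplify = FALSE)
  full <- clade_rate_comparison(trees, ti$clade_map, subsample_fraction = 1)
  again <- clade_rate_comparison(trees, ti$clade_map,
                                 subsample_fraction = 1, seed = 9)
  expect_equal(full$mean, again$mean)
  # the rate-multiplied clades sit above the background clades
  fast <- full$clade %in% cfg$fast_clades
  expect_gt(min(full$mean[fast]), max(full$mean[!fast]))
})
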
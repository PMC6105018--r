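test_that("model construction enforces the rate-matrix invariants", {
  m <- substitution_model("GTR", frequencies = c(.1, .2, .3, .4),
                          exchangeabilities = c(1, 2, 3, 4, 5, 6),
                          gamma_shape = 0.5)
  expect_equal(rowSums(m$Q), rep(0, 4), tolerance = 1e-12)
  expect_equal(-sum(m$frequencies * diag(m$Q)), 1, tolerance = 1e-12)
  # stationarity: pi Q = 0 and P(t) rows sum to 1
  expect_equal(as.numeric(m$frequencies %*% m$Q), rep(0, 4),
               tolerance = 1e-12)
  P <- radsignal:::.pmat(m, 0.37)
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-10)
  expect_equal(as.numeric(m$frequencies %*% P), m$frequencies,
               tolerance = 1e-10)
  # discrete gamma categories average to 1
  expect_equal(mean(radsignal:::.discrete_gamma(0.3, 4)), 1,
               tolerance = 1e-10)
  expect_equal(mean(m$cat_rates), 1, tolerance = 1e-10)
  expect_error(substitution_model("GTR"), "exchangeabilities")
  expect_error(substitution_model("JC", prop_invariant = 1), "prop_invariant")
  expect_error(substitution_model("Mk", n_states = 1), "at least 2")
})

test_that("two-taxon JC limits match the closed forms", {
  a <- aln_from_strings("AC", "AC", taxa = c("x", "y"))
  jc <- substitution_model("JC")
  near0 <- ape::read.tree(text = "(x:0.00000001,y:0.00000001);")
  ll <- site_log_likelihoods(a, near0, jc)
  expect_equal(as.numeric(ll), rep(log(0.25), 2), tolerance = 1e-6)
  far <- ape::read.tree(text = "(x:80,y:80);")
  expect_equal(as.numeric(site_log_likelihoods(a, far, jc)),
               rep(log(1 / 16), 2), tolerance = 1e-8)
  expect_equal(attr(ll, "total"), sum(ll))
})

test_that("pruning equals exhaustive state summation on small trees", {
  set.seed(41)
  models <- list(
    substitution_model("JC"),
    substitution_model("HKY", frequencies = c(.35, .15, .2, .3), kappa = 4,
                       gamma_shape = 0.6, n_cat = 3),
    substitution_model("GTR", frequencies = c(.3, .2, .3, .2),
                       exchangeabilities = c(2, 6, 1, 1.5, 5, 1),
                       gamma_shape = 1.2, prop_invariant = 0.2, n_cat = 2))
  for (rep in 1:6) {
    n <- sample(3:5, 1)
    tr <- random_tree(n)
    m <- matrix(sample(c("A", "C", "G", "T", "-", "R", "N"), n * 3, TRUE,
                       prob = c(rep(0.2, 4), .1, .05, .05)), n, 3,
                dimnames = list(tr$tip.label, NULL))
    a <- rad_alignment(m)
    for (mod in models) {
      mine <- as.numeric(site_log_likelihoods(a, tr, mod))
      expect_equal(mine, oracle_loglik(a, tr, mod), tolerance = 1e-8)
    }
  }
  # Mk model too
  tr <- random_tree(4)
  m <- matrix(sample(c("0", "1", "?"), 8, TRUE), 4, 2,
              dimnames = list(tr$tip.label, NULL))
  a <- rad_alignment(m, alphabet = "standard")
  mk <- substitution_model("Mk", n_states = 2)
  expect_equal(as.numeric(site_log_likelihoods(a, tr, mk)),
               oracle_loglik(a, tr, mk), tolerance = 1e-8)
})

test_that("site-pattern probabilities sum to one over all patterns", {
  set.seed(43)
  mod <- substitution_model("HKY", frequencies = c(.3, .25, .25, .2),
                            kappa = 3, gamma_shape = 0.8)
  for (n in 3:4) {
    tr <- random_tree(n)
    pats <- do.call(expand.grid,
                    rep(list(c("A", "C", "G", "T")), n))
    m <- t(as.matrix(pats))
    rownames(m) <- tr$tip.label
    a <- rad_alignment(m)
    ll <- site_log_likelihoods(a, tr, mod)
    expect_equal(sum(exp(ll)), 1, tolerance = 1e-10)
  }
})

test_that("gamma mixture converges to the single-rate likelihood", {
  set.seed(44)
  tr <- random_tree(5)
  a <- sim_jc_alignment(tr, 50)
  single <- substitution_model("JC")
  nearly <- substitution_model("JC", gamma_shape = 1e6)
  l1 <- attr(site_log_likelihoods(a, tr, single), "total")
  l2 <- attr(site_log_likelihoods(a, tr, nearly), "total")
  expect_lt(abs(l1 - l2) / abs(l1), 1e-4)
})

test_that("branch-length optimization is monotone and recovers truth", {
  jc <- substitution_model("JC")
  # identical sequences drive branches to the lower bound
  a0 <- aln_from_strings("ACGT", "ACGT", "ACGT", taxa = c("x", "y", "z"))
  t0 <- ape::read.tree(text = "((x:0.3,y:0.2):0.1,z:0.4);")
  fit0 <- optimize_branch_lengths(a0, t0, jc)
  expect_true(all(fit0$edge.length < 1e-6))
  # monotone improvement on noisy data
  set.seed(47)
  tr <- random_tree(6)
  a <- sim_jc_alignment(tr, 300)
  start <- tr; start$edge.length <- rep(0.3, nrow(tr$edge))
  l_start <- attr(site_log_likelihoods(a, start, jc), "total")
  fit <- optimize_branch_lengths(a, start, jc)
  expect_gte(attr(fit, "logL"), l_start)
  expect_equal(attr(fit, "logL"),
               attr(site_log_likelihoods(a, fit, jc), "total"),
               tolerance = 1e-9)
  # recovery within 15% on a long simulated alignment
  set.seed(48)
  truth <- random_tree(6)
  truth$edge.length <- stats::runif(nrow(truth$edge), 0.05, 0.4)
  big <- sim_jc_alignment(truth, 5000)
  fit2 <- optimize_branch_lengths(big, truth, jc)
  rel <- abs(fit2$edge.length - truth$edge.length) / truth$edge.length
  expect_lt(stats::median(rel), 0.15)
  expect_lt(max(rel), 0.5)
})

test_that("per-site rate estimation: invariant sites, ratios, rescaling", {
  jc <- substitution_model("JC")
  chron <- ape::read.tree(
    text = "(((a:5,b:5):5,(c:5,d:5):5):5,e:15);")
  # constant columns get rate zero
  m <- rbind(a = c("A", "A", "C"), b = c("A", "A", "C"),
             c = c("A", "G", "C"), d = c("A", "-", "C"),
             e = c("A", "G", "A"))
  aln <- rad_alignment(m)
  r <- per_site_rates(aln, chron, jc)
  expect_equal(r[1], 0)            # constant
  expect_equal(r[3] == 0, FALSE)   # variable site needs change
  # two batches of sites simulated at rates differing 2x: mean ratio ~ 2
  # (larger tree keeps pathological saturated patterns out of the draw)
  set.seed(60)
  big_chron <- ape::rcoal(8)
  big_chron$edge.length <- big_chron$edge.length * 10 /
    max(ape::node.depth.edgelength(big_chron))
  set.seed(51)
  rate1 <- 0.004; rate2 <- 0.008
  t1 <- big_chron; t1$edge.length <- big_chron$edge.length * rate1
  t2 <- big_chron; t2$edge.length <- big_chron$edge.length * rate2
  s1 <- sim_jc_alignment(t1, 1000)
  s2 <- sim_jc_alignment(t2, 1000)
  r1 <- per_site_rates(s1, big_chron, jc)
  r2 <- per_site_rates(s2, big_chron, jc)
  expect_equal(mean(r2) / mean(r1), 2, tolerance = 0.1)
  # reparameterization: doubling depths halves the rates
  chron2 <- big_chron; chron2$edge.length <- big_chron$edge.length * 2
  r_half <- per_site_rates(s1, chron2, jc)
  expect_equal(r_half, r1 / 2, tolerance = 1e-4)
})

test_that("grafting and class maxima behave deterministically", {
  jc <- substitution_model("JC")
  subtrees <- list(X = "(X_1,X_2)", Y = "Y_1", Z = "Z_1", W = "W_1")
  full <- graft_backbone("((X,Y),(Z,W));", subtrees)
  expect_setequal(full$tip.label, c("X_1", "X_2", "Y_1", "Z_1", "W_1"))
  expect_true(ape::is.monophyletic(full, c("X_1", "X_2")))
  expect_error(graft_backbone("((X,Y),(Z,W));", list(Q = "q")), "not found")
  # simulate on a known backbone; its class should win
  set.seed(53)
  truth <- graft_backbone("(((X,Y),Z),W);", subtrees)
  truth$edge.length <- rep(0.08, nrow(truth$edge))
  truth$edge.length[ape::which.edge(truth, c("X_1", "X_2", "Y_1"))] <- 0.15
  a <- sim_jc_alignment(truth, 2000)
  bb <- enumerate_backbones(c("X", "Y", "Z", "W"))
  cls <- classify_backbone(bb, list(xy = c("X", "Y")))
  in_class <- bb[cls == "xy"]
  out_class <- bb[cls == "neither"]
  best_in <- suppressWarnings(
    best_tree_in_class(a, in_class, subtrees, jc, max_rounds = 5))
  best_out <- suppressWarnings(
    best_tree_in_class(a, out_class, subtrees, jc, max_rounds = 5))
  expect_gt(best_in$logL, best_out$logL)
  # single-topology class returns that topology; order invariance
  single <- suppressWarnings(
    best_tree_in_class(a, in_class[1], subtrees, jc, max_rounds = 5))
  expect_equal(single$index, 1L)
  perm <- sample(length(in_class))
  best_perm <- suppressWarnings(
    best_tree_in_class(a, in_class[perm], subtrees, jc, max_rounds = 5))
  expect_equal(best_perm$logL, best_in$logL, tolerance = 1e-6)
  expect_error(best_tree_in_class(a, character(0), subtrees, jc), "empty")
})
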
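test_that("radiation configs validate their study conditions", {
  expect_error(radiation_config(), "seed is mandatory")
  expect_error(radiation_config(seed = 1, internode_range = c(-1, 2)),
               "positive")
  expect_error(radiation_config(seed = 1, root_age = 20), "root age")
  expect_error(radiation_config(seed = 1, fast_clades = "Dinosauria"),
               "ingroup clades")
  expect_error(radiation_config(seed = 1, at_shift = 0.9), "simplex")
  cfg <- radiation_config(seed = 1)
  expect_equal(length(cfg$clades), 6L)
  expect_equal(cfg$internode_range, c(4.6, 8.7))
  expect_equal(cfg$rate_multiplier, 1.6)
  expect_equal(cfg$at_shift, 0.013)
})

test_that("generated chronograms are ultrametric with short deep internodes", {
  cfg <- radiation_config(seed = 19)
  ti <- generate_radiation_tree(cfg)
  d <- root_to_tip_distances(ti$chronogram)
  expect_lt(max(d) - min(d), 1e-9)
  expect_equal(unname(max(d)), cfg$root_age + cfg$outgroup_stem,
               tolerance = 1e-9)
  # the realized backbone is the configured true backbone
  bb <- backbone_of(ti$chronogram, ti$clade_map)
  expect_equal(bb$newick, ti$backbone)
  cls <- classify_backbone(ti$backbone)
  expect_equal(as.character(cls), "scleroglossa")
  tox <- generate_radiation_tree(
    radiation_config(seed = 19, true_backbone = "toxicofera"))
  expect_equal(as.character(classify_backbone(tox$backbone)), "toxicofera")
  # backbone internode durations fall in the configured range: recover the
  # inter-divergence gaps from the ingroup node ages
  depths <- ape::node.depth.edgelength(ti$chronogram)
  ages <- max(depths) - depths
  ig_nodes <- sort(unique(ages[ages > 100 & ages < cfg$root_age + 1e-6]),
                   decreasing = TRUE)
  gaps <- -diff(ig_nodes[1:5])
  expect_true(all(gaps >= cfg$internode_range[1] - 1e-9 &
                  gaps <= cfg$internode_range[2] + 1e-9))
})

test_that("rate tree scales the chronogram by lineage multipliers", {
  cfg1 <- radiation_config(seed = 23, rate_multiplier = 1)
  t1 <- generate_radiation_tree(cfg1)
  expect_equal(t1$rate_tree$edge.length,
               t1$chronogram$edge.length * cfg1$base_rate)
  cfg2 <- radiation_config(seed = 23)
  t2 <- generate_radiation_tree(cfg2)
  r <- t2$rate_tree$edge.length / t2$chronogram$edge.length
  expect_setequal(round(unique(r), 10),
                  round(cfg2$base_rate * c(1, cfg2$rate_multiplier), 10))
  # multiplied edges are exactly the fast-clade subtrees + stems
  fast_tips <- unlist(lapply(cfg2$fast_clades, clade_terminals,
                             map = t2$clade_map))
  for (e in which(r > cfg2$base_rate * 1.0001)) {
    below <- radsignal:::.clade_sets(t2$chronogram)[[t2$chronogram$edge[e, 2]]]
    expect_true(all(below %in% fast_tips))
  }
})

test_that("identical config and seed give bit-identical datasets", {
  cfg <- radiation_config(seed = 29, n_genes = 3, n_per_clade = 2)
  a <- simulate_radiation(cfg)
  b <- simulate_radiation(cfg)
  expect_identical(a$alignment$matrix, b$alignment$matrix)
  expect_identical(a$site_rates, b$site_rates)
  expect_identical(ape::write.tree(a$chronogram),
                   ape::write.tree(b$chronogram))
  c2 <- simulate_radiation(radiation_config(seed = 30, n_genes = 3,
                                            n_per_clade = 2))
  expect_false(identical(a$alignment$matrix, c2$alignment$matrix))
})

test_that("stationary simulation converges to its equilibrium composition", {
  # long background-only simulation: tip base frequencies within 1% of the
  # model equilibrium (law of large numbers)
  cfg <- radiation_config(seed = 31, n_genes = 1, n_per_clade = 1,
                          gene_length_meanlog = log(50000),
                          gene_length_sdlog = 1e-6,
                          rate_multiplier = 1, at_shift = 0,
                          prop_invariant = 0, missing_fraction = 0)
  sim <- simulate_radiation(cfg)
  pr <- composition_profile(sim$alignment)
  fr <- as.matrix(pr[, c("A", "C", "G", "T")]) / pr$n_obs
  eq <- cfg$base_freqs / sum(cfg$base_freqs)
  for (i in seq_len(nrow(fr)))
    expect_true(all(abs(fr[i, ] - eq) < 0.01))
})

test_that("a rate multiplier doubles observed change on the fast branch", {
  # two sister tips, one with a 2x lineage multiplier: the fast tip should
  # accumulate about twice the substitutions of its sister (vs the outgroup
  # consensus), counted over many sites
  cfg <- radiation_config(clades = c("Fast", "Slow", "Ref"),
                          fast_clades = "Fast", rate_multiplier = 2,
                          at_shift = 0, n_per_clade = 1, n_genes = 1,
                          gene_length_meanlog = log(20000),
                          gene_length_sdlog = 1e-6, prop_invariant = 0,
                          gamma_shape = 100, missing_fraction = 0,
                          root_age = 40, internode_range = c(4.6, 8.7),
                          seed = 37)
  sim <- simulate_radiation(cfg)
  m <- sim$alignment$matrix
  d_fast <- mean(m["Fast_1", ] != m["Ref_1", ])
  d_slow <- mean(m["Slow_1", ] != m["Ref_1", ])
  # JC-correct the raw mismatch proportions before taking the ratio
  jc <- function(p) -3 / 4 * log(1 - 4 * p / 3)
  expect_gt(jc(d_fast) / jc(d_slow), 1.2)
  # direct branch counting against the recorded truth
  expect_equal(sum(sim$edge_rates > cfg$base_rate * 1.5), 1L)
})

test_that("AT shift enriches the fast clades in both content and skew", {
  cfg <- radiation_config(seed = 41, n_genes = 8, n_per_clade = 2,
                          missing_fraction = 0)
  sim <- simulate_radiation(cfg)
  pr <- composition_profile(sim$alignment)
  fast_tips <- unlist(lapply(cfg$fast_clades, clade_terminals,
                             map = sim$clade_map))
  fast <- pr$taxon %in% fast_tips
  og <- pr$taxon %in% clade_terminals(sim$clade_map, "Outgroup")
  at <- 100 - pr$gc_percent
  expect_gt(mean(at[fast]), mean(at[!fast & !og]))
  expect_gt(mean(pr$at_skew[fast]), mean(pr$at_skew[!fast & !og]))
})

test_that("Mk morphology: closed-form difference probability, independence", {
  two <- ape::read.tree(text = "(x:50,y:50);")
  set.seed(43)
  mo <- simulate_morphology(two, n_chars = 10000, mk_rate = 0.004,
                            n_states = 2)
  p_diff <- mean(mo$matrix["x", ] != mo$matrix["y", ])
  t_tot <- 100
  expected <- (1 - exp(-2 * 0.004 * t_tot)) / 2
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(p_diff - expected), 3 * se)
  # characters are independent: adjacent-site pattern correlation ~ 0
  x <- as.integer(mo$matrix["x", ] == mo$matrix["y", ])
  expect_lt(abs(stats::cor(x[-1], x[-length(x)])), 0.03)
  # near-zero rate: characters almost all constant
  mo0 <- simulate_morphology(two, n_chars = 500, mk_rate = 1e-9, seed = 7)
  expect_true(all(mo0$matrix["x", ] == mo0$matrix["y", ]))
  expect_error(simulate_morphology(two, mk_rate = 0), "positive")
  expect_error(simulate_morphology(two, n_states = 1), "at least 2")
})

test_that("morphology evolves slowly enough to peak deeper than sequences", {
  # default Mk rate against the default molecular base rate: the single-rate
  # informativeness peak 1/(4 lambda) lies deeper in time for morphology
  mol_peak <- 1 / (4 * radiation_config(seed = 1)$base_rate)
  mor_peak <- 1 / (4 * 5e-4)
  expect_gt(mor_peak, mol_peak)
})

test_that("dataset export writes truth and provenance that round trip", {
  cfg <- radiation_config(seed = 53, n_genes = 2, n_per_clade = 1,
                          gene_length_meanlog = log(120),
                          gene_length_sdlog = 0.1)
  sim <- simulate_radiation(cfg, morphology = TRUE, n_morph = 20)
  d <- tempfile()
  write_synthetic_dataset(sim, d)
  back <- read_alignment(file.path(d, "alignment.nex"), "nexus")
  expect_identical(back$matrix, sim$alignment$matrix)
  expect_identical(back$partition, sim$alignment$partition)
  chron <- read_tree(file.path(d, "chronogram.nwk"))
  expect_equal(rf_distance(chron, sim$chronogram), 0)
  rates <- utils::read.delim(file.path(d, "site_rates.tsv"))
  expect_equal(rates$rate, sim$site_rates, tolerance = 1e-9)
  skip_if_not_installed("jsonlite")
  prov <- jsonlite::read_json(file.path(d, "provenance.json"))
  expect_equal(prov$seed, 53L)
  expect_equal(prov$true_backbone_newick, sim$backbone)
})
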
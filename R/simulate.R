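#' Configuration of a synthetic ancient rapid radiation
#'
#' Defines the study conditions the generator emulates: six backbone clades
#' plus an outgroup diverging in rapid succession deep in time (backbone
#' internodes of a few Ma at a root age of ~190 Ma), tens of genes of
#' varying length, elevated substitution rates on two designated non-sister
#' clades, and an AT-ward equilibrium-frequency shift on those same clades.
#'
#' @param clades ingroup clade labels, in backbone ladder order.
#' @param outgroup outgroup label.
#' @param n_per_clade terminals sampled per ingroup clade.
#' @param root_age ingroup crown age (Ma).
#' @param internode_range backbone internode durations are drawn uniformly
#'   from this interval (Ma).
#' @param true_backbone \code{"scleroglossa"} (first clade sister to all
#'   others -- so the two biased clades are non-sister) or
#'   \code{"toxicofera"} (first clade nested next to the last two).
#' @param n_genes number of genes.
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene-length
#'   parameters (defaults span roughly 400-3000 bp).
#' @param base_rate background substitution rate (substitutions/site/Ma).
#' @param fast_clades clades carrying the rate multiplier and the AT shift;
#'   non-sister under the default backbone.
#' @param rate_multiplier lineage rate multiplier on the fast clades
#'   (applies to their stem and all internal branches).
#' @param at_shift increase in total AT equilibrium frequency on the fast
#'   clades (proportion; 0.013 = 1.3 percentage points), split equally
#'   between A and T and taken equally from C and G.
#' @param base_freqs background equilibrium frequencies (A, C, G, T).
#' @param kappa HKY transition/transversion rate ratio.
#' @param gamma_shape shape of the gamma distribution of per-site rates.
#' @param prop_invariant proportion of invariant sites per gene.
#' @param missing_fraction probability that a taxon is entirely missing for
#'   a gene (whole-gene absence, as in phylogenomic supermatrices).
#' @param outgroup_stem time (Ma) between the outgroup divergence and the
#'   ingroup crown.
#' @param seed mandatory integer seed.
#' @return list of class \code{radiation_config}.
#' @export
radiation_config <- function(clades = squamate_clades(),
                             outgroup = "Outgroup",
                             n_per_clade = 4L,
                             root_age = 190,
                             internode_range = c(4.6, 8.7),
                             true_backbone = c("scleroglossa", "toxicofera"),
                             n_genes = 46L,
                             gene_length_meanlog = log(900),
                             gene_length_sdlog = 0.45,
                             base_rate = 0.002,
                             fast_clades = c("Iguania", "Serpentes"),
                             rate_multiplier = 1.6,
                             at_shift = 0.013,
                             base_freqs = c(A = 0.28, C = 0.22,
                                            G = 0.22, T = 0.28),
                             kappa = 2.5,
                             gamma_shape = 0.7,
                             prop_invariant = 0.25,
                             missing_fraction = 0.10,
                             outgroup_stem = 30,
                             seed) {
  true_backbone <- match.arg(true_backbone)
  if (missing(seed)) stop("a seed is mandatory")
  if (length(clades) < 3L) stop("need at least 3 ingroup clades")
  if (any(internode_range <= 0) || diff(internode_range) < 0)
    stop("internode_range must be positive and ordered")
  if ((length(clades) - 1L) * internode_range[2] >= root_age)
    stop("backbone internodes cannot exceed the root age")
  if (rate_multiplier <= 0) stop("rate multiplier must be positive")
  if (!all(fast_clades %in% clades))
    stop("fast_clades must be ingroup clades")
  if (any(.shift_at(base_freqs / sum(base_freqs), at_shift) <= 0))
    stop("at_shift pushes frequencies off the simplex")
  structure(as.list(environment()), class = "radiation_config")
}

# Move `shift` total equilibrium mass AT-ward. The whole shift lands on A
# (with C and G each giving up half), so the biased clades acquire both an
# elevated AT content and a distinctive positive AT skew -- the two
# compositional signatures the diagnostic stages are meant to detect; a
# symmetric A/T split would leave the skew statistics blind to the bias.
#' @noRd
.shift_at <- function(freqs, shift) {
  f <- freqs
  f[1] <- f[1] + shift
  f[c(2, 3)] <- f[c(2, 3)] - shift / 2
  f
}

#' Generate the chronogram and rate tree of a synthetic radiation
#'
#' Builds an ultrametric chronogram: a ladder backbone whose successive
#' divergences are separated by the configured short internode draws,
#' Yule-process subtrees within each clade (crown ages a uniform 0.3-0.6
#' fraction of each clade's stem age), and the outgroup attached above the
#' ingroup crown. The companion rate tree multiplies every branch duration
#' by its lineage rate: the background rate everywhere, times the
#' rate multiplier on the designated fast clades (stem included).
#'
#' @param config a [radiation_config()].
#' @param .reseed set the RNG from \code{config$seed} first (disabled when
#'   called from [simulate_radiation()], which manages the stream).
#' @return list with \code{chronogram} (Ma), \code{rate_tree}
#'   (substitutions/site), \code{edge_rates} (per-edge rates of the
#'   chronogram), \code{backbone} (true backbone newick on clade labels)
#'   and \code{clade_map}.
#' @export
generate_radiation_tree <- function(config, .reseed = TRUE) {
  if (.reseed) set.seed(config$seed)
  cl <- config$clades
  n_cl <- length(cl)
  # divergence times of the ladder: t1 = root age, then short internodes
  d <- stats::runif(n_cl - 1L, config$internode_range[1],
                    config$internode_range[2])
  tt <- config$root_age - c(0, cumsum(d[-(n_cl - 1L)]))   # t1..t_{n-1}
  # ladder orders: who splits off at t1, t2, ...; the final split at
  # t_{n-1} separates the last two entries
  ladder <- switch(config$true_backbone,
    scleroglossa = cl,
    toxicofera = c(cl[-c(1L, n_cl - 1L, n_cl)], cl[n_cl - 1L], cl[n_cl],
                   cl[1L]))
  # clade subtrees (newick fragments) and stem attachment ages
  stem_age <- stats::setNames(numeric(n_cl), ladder)
  stem_age[ladder[seq_len(n_cl - 1L)]] <- tt
  stem_age[ladder[n_cl]] <- tt[n_cl - 1L]
  frag <- stats::setNames(character(n_cl), ladder)
  for (nm in ladder) {
    tips <- paste0(nm, "_", seq_len(config$n_per_clade))
    if (config$n_per_clade == 1L) {
      frag[nm] <- sprintf("%s:%.15g", tips, stem_age[nm])
    } else {
      crown <- stats::runif(1, 0.3, 0.6) * stem_age[nm]
      sub <- .yule_subtree(tips, crown)
      frag[nm] <- sprintf("%s:%.15g", sub, stem_age[nm] - crown)
    }
  }
  chron <- ape::read.tree(text = .assemble_root(frag, ladder, tt, config))
  chron <- ape::reorder.phylo(chron, "cladewise")
  edge_rates <- .edge_rates(chron, config)
  rate_tree <- chron
  rate_tree$edge.length <- chron$edge.length * edge_rates
  terms <- chron$tip.label
  cmap <- clade_map(stats::setNames(sub("_[0-9]+$", "", terms), terms),
                    outgroup = config$outgroup, clade_order = cl)
  bb <- backbone_of(chron, cmap)
  list(chronogram = chron, rate_tree = rate_tree, edge_rates = edge_rates,
       backbone = bb$newick, clade_map = cmap)
}

# root assembly as a clean recursive build (avoids string bracket juggling)
#' @noRd
.assemble_root <- function(frag, ladder, tt, config) {
  n_cl <- length(ladder)
  nw <- sprintf("(%s,%s)", frag[ladder[n_cl - 1L]], frag[ladder[n_cl]])
  for (i in rev(seq_len(n_cl - 2L))) {
    stem <- tt[i] - tt[i + 1L]
    nw <- sprintf("(%s:%.15g,%s)", nw, stem, frag[ladder[i]])
  }
  og_age <- config$root_age + config$outgroup_stem
  sprintf("(%s:%.15g,%s_1:%.15g);", nw, config$outgroup_stem,
          config$outgroup, og_age)
}

# Yule (pure-birth) ultrametric subtree on given tip labels, rescaled to a
# target crown age, returned as a newick fragment without the root length
#' @noRd
.yule_subtree <- function(tips, crown_age) {
  n <- length(tips)
  tr <- ape::rphylo(n, birth = 0.1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * crown_age / depth
  tr$tip.label <- tips
  sub(";$", "", ape::write.tree(tr, digits = 15))
}

# edges whose descendant tips all belong to one designated clade (stem
# included): where the rate multiplier and the AT shift act
#' @noRd
.clade_edges <- function(chron, clades) {
  labs <- chron$tip.label
  cl_of <- sub("_[0-9]+$", "", labs)
  desc <- .clade_sets(chron)
  vapply(seq_len(nrow(chron$edge)), function(e) {
    tips_below <- desc[[chron$edge[e, 2L]]]
    cls <- unique(cl_of[match(tips_below, labs)])
    length(cls) == 1L && cls %in% clades
  }, logical(1))
}

# per-edge lineage rates of the chronogram
#' @noRd
.edge_rates <- function(chron, config) {
  ifelse(.clade_edges(chron, config$fast_clades),
         config$base_rate * config$rate_multiplier, config$base_rate)
}

#' Simulate the multi-gene alignment of a synthetic radiation
#'
#' Evolves each gene site by site along the chronogram with a continuous-
#' time HKY Markov chain. Branch-specific equilibrium frequencies make the
#' process nonstationary: branches inside the designated fast clades (stems
#' included) use the AT-shifted frequencies, all others the background
#' frequencies. Per-site rates are drawn from a gamma distribution with an
#' invariant-site class; whole genes are masked per taxon with the
#' configured missing fraction (at least four taxa are always retained).
#'
#' @param tree_info output of [generate_radiation_tree()].
#' @param config the same [radiation_config()].
#' @param .reseed set the RNG from \code{config$seed + 1} first (disabled
#'   by [simulate_radiation()]).
#' @return list with \code{alignment} (partitioned [rad_alignment()]),
#'   \code{site_rates} (true per-site rates, substitutions/site/Ma on
#'   background lineages), \code{gene_lengths}.
#' @export
simulate_alignment <- function(tree_info, config, .reseed = TRUE) {
  if (.reseed) set.seed(config$seed + 1L)
  chron <- tree_info$chronogram
  edge_rates <- tree_info$edge_rates
  fast <- .clade_edges(chron, config$fast_clades)
  freq_bg <- config$base_freqs / sum(config$base_freqs)
  freq_fast <- .shift_at(freq_bg, config$at_shift)
  states <- c("A", "C", "G", "T")
  mod_bg <- substitution_model("HKY", frequencies = freq_bg,
                               kappa = config$kappa)
  mod_fast <- substitution_model("HKY", frequencies = freq_fast,
                                 kappa = config$kappa)
  labs <- chron$tip.label
  ntax <- length(labs)
  glen <- pmax(100L, round(stats::rlnorm(config$n_genes,
                                         config$gene_length_meanlog,
                                         config$gene_length_sdlog)))
  total <- sum(glen)
  aln <- matrix(NA_character_, ntax, total, dimnames = list(labs, NULL))
  part <- rep(sprintf("gene_%02d", seq_len(config$n_genes)), glen)
  site_rates <- numeric(total)
  tr <- stats::reorder(chron, "postorder")
  # preorder edge sequence: reverse postorder
  eord <- rev(seq_len(nrow(tr$edge)))
  root <- tr$edge[nrow(tr$edge), 1L]
  emap <- match(.edge_key(tr), .edge_key(chron))
  erates <- edge_rates[emap]
  efast <- fast[emap]
  off <- 0L
  for (g in seq_len(config$n_genes)) {
    L <- glen[g]
    inv <- stats::runif(L) < config$prop_invariant
    r_site <- ifelse(inv, 0, stats::rgamma(L, config$gamma_shape,
                                           config$gamma_shape))
    site_rates[off + seq_len(L)] <- r_site * config$base_rate
    node_states <- matrix(NA_integer_, ntax + tr$Nnode, L)
    node_states[root, ] <- sample.int(4L, L, replace = TRUE, prob = freq_bg)
    for (e in eord) {
      p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
      mod <- if (efast[e]) mod_fast else mod_bg
      b <- tr$edge.length[e] * erates[e]      # subst/site on this branch
      node_states[ch, ] <- .evolve_branch(node_states[p, ], b * r_site, mod)
    }
    aln[, off + seq_len(L)] <-
      matrix(states[node_states[seq_len(ntax), ]], ntax, L)
    off <- off + L
  }
  # whole-gene missing mask
  for (g in seq_len(config$n_genes)) {
    drop <- stats::runif(ntax) < config$missing_fraction
    if (sum(!drop) < 4L) drop[order(drop)[seq_len(4L)]] <- FALSE
    if (any(drop))
      aln[drop, part == sprintf("gene_%02d", g)] <- "-"
  }
  list(alignment = rad_alignment(aln, alphabet = "DNA", partition = part),
       site_rates = site_rates, gene_lengths = glen)
}

# stable identification of chronogram edges across reorderings
#' @noRd
.edge_key <- function(tree) paste(tree$edge[, 1], tree$edge[, 2])

# evolve one branch: parent states (integer 1..k) to child states, with a
# per-site branch length (expected substitutions); eigen-based transition
# probabilities vectorized over sites
#' @noRd
.evolve_branch <- function(parent, b_site, model) {
  k <- model$k
  e <- model$eigen
  out <- integer(length(parent))
  E <- exp(outer(b_site, e$values))           # n x k
  for (s in unique(parent)) {
    rows <- which(parent == s)
    A <- e$U[s, ] * e$Uinv                    # k x k  (A[m, j])
    pr <- E[rows, , drop = FALSE] %*% A       # n_s x k
    pr[pr < 0] <- 0
    pr <- pr / rowSums(pr)
    cs <- pr %*% upper.tri(diag(k), diag = TRUE)
    u <- stats::runif(length(rows))
    out[rows] <- 1L + as.integer(rowSums(cs < u))
  }
  out
}

#' Simulate Mk-type discrete morphological characters
#'
#' Symmetric k-state Markov simulation on a chronogram at a single (slow)
#' rate, emulating a morphological partition whose informativeness peaks
#' deeper in time than the molecular data.
#'
#' @param chronogram ultrametric \code{phylo} (Ma).
#' @param n_chars number of characters.
#' @param mk_rate substitution rate (changes/character/Ma); must be > 0.
#' @param n_states number of states (>= 2).
#' @param seed optional integer seed.
#' @return a \code{rad_alignment} with the \code{"standard"} alphabet.
#' @export
simulate_morphology <- function(chronogram, n_chars = 100L, mk_rate = 5e-4,
                                n_states = 2L, seed = NULL) {
  if (mk_rate <= 0) stop("mk_rate must be positive")
  if (n_states < 2L) stop("need at least 2 states")
  if (!is.null(seed)) set.seed(seed)
  mod <- substitution_model("Mk", n_states = n_states)
  tr <- stats::reorder(chronogram, "postorder")
  ntax <- length(tr$tip.label)
  root <- tr$edge[nrow(tr$edge), 1L]
  node_states <- matrix(NA_integer_, ntax + tr$Nnode, n_chars)
  node_states[root, ] <- sample.int(n_states, n_chars, replace = TRUE)
  for (e in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    b <- rep(tr$edge.length[e] * mk_rate, n_chars)
    node_states[ch, ] <- .evolve_branch(node_states[p, ], b, mod)
  }
  m <- matrix(as.character(node_states[seq_len(ntax), ] - 1L), ntax,
              n_chars, dimnames = list(tr$tip.label, NULL))
  rad_alignment(m, alphabet = "standard")
}

#' Simulate a complete synthetic radiation dataset
#'
#' One call producing the chronogram, rate tree, multi-gene alignment and
#' (optionally) a morphological matrix under a single seeded RNG stream, so
#' identical configurations give bit-identical datasets.
#'
#' @param config a [radiation_config()].
#' @param morphology also simulate \code{n_morph} Mk characters.
#' @param n_morph number of morphological characters.
#' @return list of class \code{synthetic_radiation}: everything from
#'   [generate_radiation_tree()] and [simulate_alignment()], plus
#'   \code{morphology} (or \code{NULL}) and the \code{config}.
#' @export
simulate_radiation <- function(config, morphology = FALSE, n_morph = 100L) {
  set.seed(config$seed)
  ti <- generate_radiation_tree(config, .reseed = FALSE)
  al <- simulate_alignment(ti, config, .reseed = FALSE)
  mo <- if (morphology)
    simulate_morphology(ti$chronogram, n_chars = n_morph, seed = NULL)
  else NULL
  structure(c(ti, al, list(morphology = mo, config = config)),
            class = "synthetic_radiation")
}

#' Write a synthetic dataset with its truth and provenance
#'
#' Writes the alignment (NEXUS with charsets, plus FASTA), the true
#' chronogram and rate tree (newick), the clade map (TSV), the true
#' per-site rates (TSV) and a JSON provenance block holding the full
#' configuration including the seed, so any dataset can be regenerated
#' bit-identically.
#'
#' @param sim a [simulate_radiation()] result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_alignment(sim$alignment, file.path(dir, "alignment.nex"), "nexus")
  write_alignment(sim$alignment, file.path(dir, "alignment.fasta"), "fasta")
  write_tree(sim$chronogram, file.path(dir, "chronogram.nwk"))
  write_tree(sim$rate_tree, file.path(dir, "rate_tree.nwk"))
  write_clade_map(sim$clade_map, file.path(dir, "clade_map.tsv"))
  utils::write.table(
    data.frame(site = seq_along(sim$site_rates), rate = sim$site_rates,
               gene = sim$alignment$partition),
    file.path(dir, "site_rates.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(sim$morphology))
    write_alignment(sim$morphology, file.path(dir, "morphology.nex"),
                    "nexus")
  cfg <- unclass(sim$config)
  cfg$true_backbone_newick <- sim$backbone
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(cfg, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    dput(cfg, file.path(dir, "provenance.R"))
  }
  invisible(dir)
}

#' @export
print.synthetic_radiation <- function(x, ...) {
  cat(sprintf(paste0("synthetic_radiation: %d taxa, %d genes, %d sites ",
                     "(true backbone: %s)\n"),
              length(x$chronogram$tip.label), x$config$n_genes,
              n_sites(x$alignment), x$config$true_backbone))
  invisible(x)
}
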
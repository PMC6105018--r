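#' Per-taxon nucleotide composition profile
#'
#' Counts of A, C, G, T per taxon (and per gene when requested), with GC
#' content, AT skew (A - T)/(A + T) and GC skew (G - C)/(G + C). Gaps and
#' ambiguity codes are not counted. Taxa (or taxon-gene cells) with zero
#' observed bases are flagged via \code{n_obs = 0} and skews of \code{NA}.
#'
#' @param alignment a DNA [rad_alignment()].
#' @param per_gene compute one row per taxon x gene (requires a partition).
#' @return data frame of class \code{composition_profile} with columns
#'   \code{taxon} (, \code{gene}), \code{A}, \code{C}, \code{G}, \code{T},
#'   \code{n_obs}, \code{gc_percent}, \code{at_skew}, \code{gc_skew}.
#' @export
composition_profile <- function(alignment, per_gene = FALSE) {
  if (alignment$alphabet != "DNA") stop("composition needs a DNA alignment")
  count_block <- function(m) {
    t(apply(m, 1, function(row)
      table(factor(row[row %in% c("A", "C", "G", "T")],
                   levels = c("A", "C", "G", "T")))))
  }
  derive <- function(cnt, extra) {
    a <- cnt[, 1]; c_ <- cnt[, 2]; g <- cnt[, 3]; t_ <- cnt[, 4]
    n <- a + c_ + g + t_
    out <- data.frame(extra, A = a, C = c_, G = g, T = t_, n_obs = n,
                      gc_percent = ifelse(n > 0, 100 * (g + c_) / n, NA),
                      at_skew = ifelse(a + t_ > 0, (a - t_) / (a + t_), NA),
                      gc_skew = ifelse(g + c_ > 0, (g - c_) / (g + c_), NA),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  }
  if (per_gene) {
    if (is.null(alignment$partition)) stop("per-gene mode needs a partition")
    res <- do.call(rbind, lapply(gene_names(alignment), function(g) {
      m <- gene_alignment(alignment, g)$matrix
      derive(count_block(m), data.frame(taxon = rownames(m), gene = g,
                                        stringsAsFactors = FALSE))
    }))
  } else {
    m <- alignment$matrix
    res <- derive(count_block(m), data.frame(taxon = rownames(m),
                                             stringsAsFactors = FALSE))
  }
  class(res) <- c("composition_profile", "data.frame")
  res
}

#' Chi-square test of base-frequency homogeneity across taxa
#'
#' Standard contingency test on the taxa-by-bases count table: expected
#' counts from the row and column margins, statistic sum((O - E)^2 / E),
#' df = (n_taxa - 1) * 3. Taxa with zero observed bases are excluded. A
#' warning is raised (but the test still computed) when any expected count
#' falls below 1.
#'
#' @param profile a [composition_profile()] (per-gene profiles are pooled by
#'   taxon).
#' @return list with \code{statistic}, \code{df}, \code{p_value} and the
#'   pooled count \code{table}.
#' @export
chi_square_homogeneity <- function(profile) {
  tab <- rowsum(as.matrix(profile[, c("A", "C", "G", "T")]), profile$taxon)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L) stop("need at least 2 taxa with observed bases")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(E < 1))
    warning("expected counts below 1; chi-square approximation is poor")
  use <- E > 0
  stat <- sum((tab[use] - E[use])^2 / E[use])
  df <- (nrow(tab) - 1L) * 3L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), table = tab)
}

#' Hierarchical clustering of taxa by per-gene AT skew
#'
#' Builds the taxa-by-genes matrix of AT skews from a per-gene composition
#' profile and clusters taxa on Euclidean distances. Cells that are missing
#' (gene absent for a taxon) are imputed with that taxon's across-gene mean
#' skew so distances stay defined; imputed cells are reported.
#'
#' @param profile a per-gene [composition_profile()].
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   \code{"average"}).
#' @return an \code{hclust} object with attributes \code{"matrix"} (the skew
#'   matrix used) and \code{"imputed"} (logical matrix of imputed cells).
#' @export
skew_clustering <- function(profile, linkage = "average") {
  if (!"gene" %in% names(profile))
    stop("need a per-gene composition profile")
  taxa <- unique(profile$taxon)
  if (length(taxa) < 3L) stop("need at least 3 taxa to cluster")
  genes <- unique(profile$gene)
  m <- matrix(NA_real_, length(taxa), length(genes),
              dimnames = list(taxa, genes))
  m[cbind(match(profile$taxon, taxa), match(profile$gene, genes))] <-
    profile$at_skew
  imputed <- is.na(m)
  if (any(imputed)) {
    rm <- rowMeans(m, na.rm = TRUE)
    if (anyNA(rm)) stop("taxon with no observed skew in any gene: ",
                        paste(taxa[is.na(rm)], collapse = ", "))
    m[imputed] <- rm[row(m)[imputed]]
  }
  hc <- stats::hclust(stats::dist(m), method = linkage)
  attr(hc, "matrix") <- m
  attr(hc, "imputed") <- imputed
  hc
}

#' Simulation-based phylogenetic ANOVA
#'
#' The observed F statistic is the ordinary one-way ANOVA ratio of the trait
#' across groups; its null distribution is generated by simulating Brownian
#' motion on the phylogeny, with the Brownian rate estimated from the
#' observed trait by phylogenetically independent contrasts, and the
#' phylogenetic p-value is the proportion of simulated F statistics at least
#' as large as the observed one.
#'
#' @param trait named numeric vector (names = tree leaves).
#' @param groups group labels, same order/names as \code{trait}.
#' @param tree a \code{phylo} with branch lengths covering the trait taxa.
#' @param n_sim number of Brownian simulations (>= 1).
#' @param seed optional integer seed.
#' @return list with \code{F}, \code{p_phylo}, \code{p_parametric} (the
#'   ordinary ANOVA p, for reference), \code{sigma2} and \code{n_sim}.
#' @export
phylo_anova <- function(trait, groups, tree, n_sim = 1000L, seed = NULL) {
  if (n_sim < 1L) stop("n_sim must be >= 1")
  if (is.null(names(trait))) stop("'trait' must be named by taxa")
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  miss <- setdiff(names(trait), tree$tip.label)
  if (length(miss)) stop("taxa not in the tree: ", paste(miss, collapse = ", "))
  if (length(tree$tip.label) > length(trait))
    tree <- ape::keep.tip(tree, names(trait))
  orig_names <- names(trait)
  trait <- trait[tree$tip.label]
  groups <- groups[match(tree$tip.label, orig_names)]
  g <- factor(groups)
  fstat <- function(y) {
    gm <- tapply(y, g, mean)
    ng <- tabulate(g)
    ssb <- sum(ng * (gm - mean(y))^2)
    ssw <- sum((y - gm[g])^2)
    dfb <- nlevels(g) - 1L
    dfw <- length(y) - nlevels(g)
    (ssb / dfb) / (ssw / dfw)
  }
  if (stats::var(trait) == 0)
    return(list(F = NA_real_, p_phylo = 1, p_parametric = 1,
                sigma2 = 0, n_sim = n_sim))
  f_obs <- fstat(trait)
  btree <- ape::multi2di(tree)
  pic <- ape::pic(trait, btree)
  sigma2 <- mean(pic^2)
  if (!is.null(seed)) set.seed(seed)
  C <- ape::vcv(tree)[names(trait), names(trait)]
  L <- chol(sigma2 * C)
  Z <- matrix(stats::rnorm(length(trait) * n_sim), ncol = n_sim)
  sims <- crossprod(L, Z)                      # taxa x n_sim
  f_sim <- apply(sims, 2, fstat)
  dfb <- nlevels(g) - 1L
  dfw <- length(trait) - nlevels(g)
  list(F = f_obs, p_phylo = mean(f_sim >= f_obs),
       p_parametric = stats::pf(f_obs, dfb, dfw, lower.tail = FALSE),
       sigma2 = sigma2, n_sim = n_sim)
}

#' Root-to-tip rate comparison across clades
#'
#' Pools root-to-tip path lengths over a random subsample of a tree set
#' (e.g. a posterior sample) and over the member terminals of each ingroup
#' clade, summarizing each clade by its mean, median and central 95%
#' interval. Two clades differ "significantly" in rate when their intervals
#' do not overlap.
#'
#' @param trees list or \code{multiPhylo} of trees with branch lengths,
#'   rooted or rootable on the outgroup of \code{map}.
#' @param map a [clade_map()].
#' @param subsample_fraction fraction of trees used (1 = all).
#' @param seed optional integer seed for the subsample.
#' @return data frame of class \code{clade_rate_summary} with columns
#'   \code{clade}, \code{mean}, \code{median}, \code{lower}, \code{upper},
#'   \code{n}; the pairwise interval-overlap matrix is in attribute
#'   \code{"overlap"}, skipped tree-clade combinations in \code{"skipped"}.
#' @export
clade_rate_comparison <- function(trees, map, subsample_fraction = 0.10,
                                  seed = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  ntr <- length(trees)
  if (ntr < 1L) stop("no trees supplied")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  m <- max(1L, round(subsample_fraction * ntr))
  pick <- if (m == ntr) seq_len(ntr) else sort(sample.int(ntr, m))
  vals <- stats::setNames(vector("list", length(map$clades)), map$clades)
  skipped <- character(0)
  for (i in pick) {
    tr <- trees[[i]]
    og <- intersect(clade_terminals(map, map$outgroup), tr$tip.label)
    if (length(og) && !ape::is.rooted(tr))
      tr <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    d <- root_to_tip_distances(tr)
    for (cl in map$clades) {
      members <- intersect(clade_terminals(map, cl), names(d))
      if (!length(members)) {
        skipped <- c(skipped, paste0("tree_", i, ":", cl))
        next
      }
      vals[[cl]] <- c(vals[[cl]], d[members])
    }
  }
  out <- do.call(rbind, lapply(map$clades, function(cl) {
    v <- vals[[cl]]
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    data.frame(clade = cl, mean = mean(v), median = stats::median(v),
               lower = q[1], upper = q[2], n = length(v),
               stringsAsFactors = FALSE)
  }))
  eps <- 1e-9 * max(abs(out$upper), 1)
  ov <- outer(seq_len(nrow(out)), seq_len(nrow(out)), function(i, j)
    !(out$upper[i] < out$lower[j] - eps | out$upper[j] < out$lower[i] - eps))
  dimnames(ov) <- list(out$clade, out$clade)
  attr(out, "overlap") <- ov
  attr(out, "skipped") <- skipped
  class(out) <- c("clade_rate_summary", "data.frame")
  out
}
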
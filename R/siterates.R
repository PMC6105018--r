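#' Observed variability (OV) site scores
#'
#' Tree-independent per-site rate proxy: the proportion of unordered taxon
#' pairs whose (unambiguously observed) states differ at the site. Constant
#' sites score 0, sites where every observed state is unique score 1; gaps
#' and ambiguity codes are excluded from the pair counts. Sites with fewer
#' than two observed states are unscoreable and return \code{NA}.
#'
#' @param alignment a [rad_alignment()].
#' @return numeric vector of per-site scores in [0, 1] (or \code{NA}).
#' @export
ov_scores <- function(alignment) {
  m <- alignment$matrix
  apply(m, 2, function(col) {
    obs <- col[.is_observed(col, alignment$alphabet)]
    n <- length(obs)
    if (n < 2L) return(NA_real_)
    tb <- table(obs)
    total <- n * (n - 1) / 2
    match_pairs <- sum(tb * (tb - 1) / 2)
    (total - match_pairs) / total
  })
}

#' TIGER site agreement scores
#'
#' Tree-independent rate proxy based on character compatibility: each
#' observed state of a site defines a taxon set; the partition agreement of
#' site j with site i is the fraction of j's state sets that are subsets of
#' some state set of i, and site i's score is the mean agreement of all
#' other sites with it. Slow sites partition taxa consistently with the rest
#' of the matrix and score near 1 (a constant site scores exactly 1); fast,
#' noisy sites score low. Taxa with gaps or ambiguities at a site are absent
#' from that site's sets.
#'
#' @param alignment a [rad_alignment()] with at least two sites.
#' @return numeric vector of per-site scores in [0, 1]; \code{NA} for sites
#'   with no observed states.
#' @export
tiger_scores <- function(alignment) {
  m <- alignment$matrix
  nsit <- ncol(m)
  if (nsit < 2L) stop("TIGER needs at least 2 sites")
  ntax <- nrow(m)
  # per site: list of logical taxon-membership vectors, one per state
  sets <- lapply(seq_len(nsit), function(j) {
    col <- m[, j]
    ok <- .is_observed(col, alignment$alphabet)
    if (!any(ok)) return(NULL)
    lapply(unique(col[ok]), function(s) ok & col == s)
  })
  pa <- function(from, to) {
    # fraction of `from`'s sets that nest within some set of `to`
    mean(vapply(from, function(s)
      any(vapply(to, function(t) !any(s & !t), logical(1))), logical(1)))
  }
  vapply(seq_len(nsit), function(i) {
    if (is.null(sets[[i]])) return(NA_real_)
    others <- setdiff(seq_len(nsit), i)
    others <- others[!vapply(sets[others], is.null, logical(1))]
    if (!length(others)) return(NA_real_)
    mean(vapply(others, function(j) pa(sets[[j]], sets[[i]]), numeric(1)))
  }, numeric(1))
}

#' Rank sites from fastest to slowest
#'
#' @param scores per-site scores.
#' @param higher_is_faster \code{TRUE} for OV (high score = fast),
#'   \code{FALSE} for TIGER (high score = slow).
#' @return integer permutation of the site indices, fastest first; ties and
#'   unscoreable (\code{NA}) sites are broken by original site index, with
#'   \code{NA} sites ranked slowest.
#' @export
rank_sites <- function(scores, higher_is_faster = TRUE) {
  key <- if (higher_is_faster) -scores else scores
  key[is.na(key)] <- Inf
  order(key, seq_along(scores))
}

#' Site-rate ranking of an alignment
#'
#' Convenience wrapper producing scores and a fastest-first ranking under one
#' of the tree-independent methods.
#'
#' @param alignment a [rad_alignment()].
#' @param method \code{"ov"} or \code{"tiger"}.
#' @return list of class \code{site_ranking}: \code{method}, \code{scores},
#'   \code{order} (fastest first).
#' @export
site_rate_ranking <- function(alignment, method = c("ov", "tiger")) {
  method <- match.arg(method)
  sc <- if (method == "ov") ov_scores(alignment) else tiger_scores(alignment)
  structure(list(method = method, scores = sc,
                 order = rank_sites(sc, higher_is_faster = method == "ov")),
            class = "site_ranking")
}

#' Neighbor-joining tree on ML distances
#'
#' Built-in re-inference used by the removal series: pairwise
#' Jukes-Cantor-corrected distances (pairwise deletion of unobserved cells)
#' followed by neighbor joining. Saturated or undefined pairwise distances
#' are replaced by slightly more than the largest finite distance.
#'
#' @param alignment a DNA [rad_alignment()] with >= 4 taxa.
#' @return an unrooted \code{phylo}.
#' @export
nj_tree <- function(alignment) {
  if (alignment$alphabet != "DNA") stop("nj_tree expects a DNA alignment")
  if (nrow(alignment$matrix) < 4L) stop("need at least 4 taxa")
  dna <- ape::as.DNAbin(tolower(alignment$matrix))
  d <- ape::dist.dna(dna, model = "JC69", pairwise.deletion = TRUE)
  dm <- as.matrix(d)
  bad <- !is.finite(dm)
  if (any(bad)) {
    mx <- max(dm[!bad & row(dm) != col(dm)], 0)
    dm[bad] <- mx * 1.25 + 0.5
    diag(dm) <- 0
    warning("saturated or undefined pairwise distances replaced by ",
            signif(mx * 1.25 + 0.5, 3))
  }
  ape::nj(as.dist(dm))
}

#' Pairwise maximum-likelihood distances under a substitution model
#'
#' For every taxon pair, the expected number of substitutions per site is
#' estimated by 1-D ML from the 4 x 4 table of jointly observed states,
#' under any reversible [substitution_model()] including gamma rate
#' categories and an invariant class (heterogeneity corrections matter:
#' uncorrected distances compress fast lineages). Pairs with no jointly
#' observed site, or saturated beyond the search bound, get the bound.
#'
#' @param alignment a DNA [rad_alignment()].
#' @param model a [substitution_model()].
#' @param t_max upper bound of the distance search.
#' @return symmetric matrix of ML distances.
#' @export
ml_distances <- function(alignment, model, t_max = 10) {
  m <- alignment$matrix
  code <- match(m, model$states)          # ambiguities/gaps -> NA
  dim(code) <- dim(m)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  lf <- log(model$frequencies)
  pinv <- model$prop_invariant
  wc <- (1 - pinv) / length(model$cat_rates)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(code[i, ]) & !is.na(code[j, ])
    if (!any(ok)) { D[i, j] <- D[j, i] <- t_max; next }
    idx <- (code[i, ok] - 1L) * model$k + code[j, ok]
    cnt <- tabulate(idx, nbins = model$k^2)
    nz <- which(cnt > 0)
    f <- function(t) {
      P <- Reduce(`+`, lapply(model$cat_rates, function(r)
        wc * .pmat(model, r * t)))
      if (pinv > 0) P <- P + pinv * diag(model$k)
      sum(cnt[nz] * (lf[(nz - 1L) %/% model$k + 1L] +
                     log(P[cbind((nz - 1L) %/% model$k + 1L,
                               (nz - 1L) %% model$k + 1L)])))
    }
    op <- stats::optimize(f, c(1e-8, t_max), maximum = TRUE, tol = 1e-7)
    D[i, j] <- D[j, i] <- op$maximum
  }
  D
}

#' Neighbor joining on model-corrected ML distances
#'
#' @param alignment a DNA [rad_alignment()] with >= 4 taxa.
#' @param model a [substitution_model()] passed to [ml_distances()].
#' @return an unrooted \code{phylo} with non-negative branch lengths.
#' @export
nj_ml_tree <- function(alignment, model) {
  if (nrow(alignment$matrix) < 4L) stop("need at least 4 taxa")
  tr <- ape::nj(stats::as.dist(ml_distances(alignment, model)))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Progressive fast-site removal with re-inference
#'
#' Starting from the full alignment, the next \code{step} fastest sites
#' (according to a fastest-first ranking) are removed at each step, a tree
#' is re-inferred from the remaining sites, and the presence of each
#' nontrivial backbone split of a reference tree in the re-inferred tree is
#' recorded. The built-in inference is neighbor joining on Jukes-Cantor
#' distances ([nj_tree()]); any function alignment -> \code{phylo} can be
#' substituted. The series truncates (with a warning) once no variable site
#' remains.
#'
#' @param alignment a [rad_alignment()].
#' @param ranking a \code{site_ranking} (or a bare fastest-first index
#'   permutation covering all sites).
#' @param reference_tree \code{phylo} whose nontrivial splits are tracked.
#' @param step sites removed per step (default 500).
#' @param infer function used to re-infer a tree; default [nj_tree()].
#' @param keep_alignments also retain each step's alignment (attribute
#'   \code{"alignments"}) for export with [write_alignment()].
#' @return object of class \code{removal_series}: a data frame
#'   (\code{step}, \code{sites_remaining}, \code{split_id}, \code{present})
#'   with the per-step trees in attribute \code{"trees"} and the tracked
#'   splits in attribute \code{"splits"}. Step 0 is the full alignment.
#' @export
removal_series <- function(alignment, ranking, reference_tree, step = 500L,
                           infer = nj_tree, keep_alignments = FALSE) {
  idx <- if (inherits(ranking, "site_ranking")) ranking$order else ranking
  nsit <- n_sites(alignment)
  if (step < 1L) stop("step must be >= 1")
  if (step >= nsit)
    stop("step (", step, ") is not smaller than the alignment (", nsit,
         " sites): the first removal would empty it")
  if (!setequal(idx, seq_len(nsit)))
    stop("ranking must be a permutation of all site indices")
  ref_splits <- nontrivial_splits(reference_tree)
  split_ids <- vapply(ref_splits, function(s) paste(s, collapse = "+"),
                      character(1))
  rows <- list(); trees <- list(); alns <- list()
  k <- 0L
  repeat {
    keep <- sort(idx[seq.int(k * step + 1L, nsit)])
    aln <- subset_alignment(alignment, sites = keep)
    nvar <- sum(apply(aln$matrix, 2, function(col) {
      obs <- col[.is_observed(col, aln$alphabet)]
      length(unique(obs)) > 1L
    }))
    if (k > 0L && nvar == 0L) {
      warning("series truncated at step ", k,
              ": no variable sites remain")
      break
    }
    tr <- infer(aln)
    present <- vapply(ref_splits, function(s) {
      shared <- intersect(reference_tree$tip.label, tr$tip.label)
      s <- intersect(s, shared)
      other <- setdiff(shared, s)
      if (length(s) < 2L || length(other) < 2L) return(TRUE)  # trivial
      is_monophyletic(tr, s)
    }, logical(1))
    rows[[k + 1L]] <- data.frame(step = k,
                                 sites_remaining = length(keep),
                                 split_id = split_ids, present = present,
                                 stringsAsFactors = FALSE)
    trees[[k + 1L]] <- tr
    if (keep_alignments) alns[[k + 1L]] <- aln
    if (nsit - (k + 1L) * step < 1L) break
    k <- k + 1L
  }
  out <- do.call(rbind, rows)
  attr(out, "trees") <- trees
  if (keep_alignments) attr(out, "alignments") <- alns
  attr(out, "splits") <- ref_splits
  class(out) <- c("removal_series", "data.frame")
  out
}

#' Rank accuracy against known simulation rates
#'
#' Spearman correlation between a method's per-site scores and the true
#' simulated rates, with the sign convention folded in so that a perfect
#' method scores +1 regardless of its score orientation.
#'
#' @param scores per-site scores (or a \code{site_ranking}, whose
#'   orientation is then known).
#' @param true_rates simulated per-site rates.
#' @param higher_is_faster orientation of bare scores (ignored for a
#'   \code{site_ranking}).
#' @return Spearman's rho (\code{NA} with a warning if the scores are
#'   constant).
#' @export
rank_vs_truth <- function(scores, true_rates, higher_is_faster = TRUE) {
  if (inherits(scores, "site_ranking")) {
    higher_is_faster <- scores$method == "ov"
    scores <- scores$scores
  }
  ok <- !is.na(scores) & !is.na(true_rates)
  s <- scores[ok]
  if (length(unique(s)) < 2L) {
    warning("scores are constant; rank correlation undefined")
    return(NA_real_)
  }
  rho <- stats::cor(s, true_rates[ok], method = "spearman")
  if (higher_is_faster) rho else -rho
}
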
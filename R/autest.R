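#' Multiscale RELL bootstrap of site log-likelihoods
#'
#' Resampling of estimated log-likelihoods: at each scale r, \code{ceiling(r
#' * n_sites)} site columns are drawn with replacement, per-topology
#' log-likelihoods are summed, and the winning topology recorded. No
#' re-optimization is performed. Ties for the winner split the count equally
#' among the tied topologies, so the proportions sum to 1 at every scale.
#'
#' @param site_loglik matrix of per-site log-likelihoods, one row per
#'   topology, one column per site.
#' @param scales bootstrap scale factors (default the 10 conventional values
#'   0.5 to 1.4).
#' @param replicates bootstrap replicates per scale (>= 100).
#' @param seed optional integer seed for the resampling stream.
#' @return matrix of winning proportions, \code{length(scales)} rows by
#'   \code{nrow(site_loglik)} columns, with attributes \code{"scales"} and
#'   \code{"replicates"}.
#' @export
rell_bootstrap <- function(site_loglik, scales = seq(0.5, 1.4, by = 0.1),
                           replicates = 10000L, seed = NULL) {
  if (!is.matrix(site_loglik)) site_loglik <- rbind(site_loglik)
  ntop <- nrow(site_loglik)
  nsit <- ncol(site_loglik)
  if (any(scales <= 0)) stop("scales must be positive")
  if (replicates < 100L) stop("use at least 100 replicates")
  if (!is.null(seed)) set.seed(seed)
  bp <- matrix(0, length(scales), ntop,
               dimnames = list(NULL, rownames(site_loglik)))
  for (si in seq_along(scales)) {
    if (ntop == 1L) { bp[si, ] <- 1; next }
    m <- ceiling(scales[si] * nsit)
    counts <- stats::rmultinom(replicates, m, rep(1 / nsit, nsit))
    tot <- site_loglik %*% counts                     # ntop x replicates
    mx <- do.call(pmax, lapply(seq_len(ntop), function(i) tot[i, ]))
    win <- tot >= rep(mx, each = ntop) - 1e-9 * abs(rep(mx, each = ntop))
    nt <- colSums(win)
    bp[si, ] <- rowSums(win / rep(nt, each = ntop)) / replicates
  }
  attr(bp, "scales") <- scales
  attr(bp, "replicates") <- replicates
  bp
}

#' Approximately unbiased p-values from multiscale bootstrap proportions
#'
#' For each topology, the bootstrap proportions bp(r) are modelled as
#' \eqn{\Phi(-(d\sqrt{r} + c/\sqrt{r}))} and (d, c) -- the signed distance
#' and curvature of the log-likelihood boundary -- are fitted by weighted
#' least squares on the probit scale; the AU p-value is
#' \eqn{\Phi(-(d - c))}. Topologies with proportions of 0 (or 1) at every
#' scale short-circuit to p = 0 (or 1). If fewer than three scales are
#' non-degenerate the scale-1 proportion is returned with a fallback flag.
#'
#' @param bp proportion matrix from [rell_bootstrap()] (scales x topologies).
#' @param scales,replicates taken from \code{bp}'s attributes when absent.
#' @return object of class \code{au_result}: a data frame with one row per
#'   topology and columns \code{topology}, \code{p_au}, \code{d}, \code{c},
#'   \code{fallback}; the proportions are kept in attribute \code{"bp"}.
#' @export
au_pvalues <- function(bp, scales = attr(bp, "scales"),
                       replicates = attr(bp, "replicates")) {
  if (is.null(scales)) stop("scales not supplied")
  if (is.null(replicates)) replicates <- 10000L
  ntop <- ncol(bp)
  nm <- colnames(bp)
  if (is.null(nm)) nm <- paste0("topology_", seq_len(ntop))
  out <- data.frame(topology = nm, p_au = NA_real_, d = NA_real_,
                    c = NA_real_, fallback = FALSE,
                    stringsAsFactors = FALSE)
  eps <- 0.5 / replicates
  for (j in seq_len(ntop)) {
    x <- bp[, j]
    if (all(x >= 1 - eps)) { out$p_au[j] <- 1; next }
    if (all(x <= eps)) { out$p_au[j] <- 0; next }
    ok <- x > eps & x < 1 - eps
    if (sum(ok) < 3L) {
      out$p_au[j] <- x[which.min(abs(scales - 1))]
      out$fallback[j] <- TRUE
      next
    }
    r <- scales[ok]
    z <- stats::qnorm(1 - x[ok])
    wt <- replicates * stats::dnorm(z)^2 / (x[ok] * (1 - x[ok]))
    X <- cbind(sqrt(r), 1 / sqrt(r))
    fit <- tryCatch(stats::lm.wfit(X, z, wt), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      out$p_au[j] <- x[which.min(abs(scales - 1))]
      out$fallback[j] <- TRUE
      next
    }
    d <- fit$coefficients[1]; cc <- fit$coefficients[2]
    out$p_au[j] <- stats::pnorm(-(d - cc))
    out$d[j] <- d; out$c[j] <- cc
  }
  attr(out, "bp") <- bp
  class(out) <- c("au_result", "data.frame")
  out
}

#' Write per-site log-likelihoods as a long TSV
#'
#' One row per topology x site (columns \code{site}, \code{tree_id},
#' \code{lnL}), the layout per-site topology-test tools consume.
#'
#' @param site_loglik topologies-by-sites matrix.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_site_likelihoods <- function(site_loglik, path) {
  if (!is.matrix(site_loglik)) site_loglik <- rbind(site_loglik)
  ids <- rownames(site_loglik)
  if (is.null(ids)) ids <- paste0("topology_", seq_len(nrow(site_loglik)))
  df <- data.frame(site = rep(seq_len(ncol(site_loglik)),
                              each = nrow(site_loglik)),
                   tree_id = rep(ids, ncol(site_loglik)),
                   lnL = as.vector(site_loglik))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Confidence set of an AU result
#' @param au an \code{au_result}.
#' @param threshold p-value threshold (default 0.05).
#' @return character vector of topology names with p above the threshold;
#'   always contains the highest-p topology so the set is never empty.
#' @export
confidence_set <- function(au, threshold = 0.05) {
  keep <- au$topology[au$p_au > threshold]
  if (!length(keep)) keep <- au$topology[which.max(au$p_au)]
  keep
}

#' Per-gene AU tests over backbone hypothesis classes
#'
#' For every gene of a partitioned alignment: the best tree within each
#' hypothesis class is found (grafting fixed within-clade subtrees onto
#' every backbone of the class and optimizing branch lengths), per-site
#' log-likelihoods of the class representatives are computed, and an AU test
#' over the class maxima assigns each class a p-value. Classes with p above
#' the threshold form the gene's confidence set; a gene is \code{ambiguous}
#' when at least two classes remain in the set, otherwise it supports the
#' single remaining class.
#'
#' @param alignment a partitioned [rad_alignment()] (or a single gene).
#' @param classes named list of character vectors of backbone newicks, e.g.
#'   the enumeration split by [classify_backbone()].
#' @param subtrees named list mapping clade labels to fixed subtree newicks
#'   or single terminal names (see [graft_backbone()]).
#' @param model a [substitution_model()].
#' @param threshold confidence-set p-value threshold.
#' @param scales,replicates,seed passed to [rell_bootstrap()]; the seed is
#'   advanced per gene so genes are independent but reproducible.
#' @param ... passed to [optimize_branch_lengths()].
#' @return data frame with one row per gene: p-value per class, the
#'   confidence set (comma-collapsed), \code{verdict}, \code{n_variable} and
#'   \code{low_power} (fewer than 50 variable sites). The proportion of
#'   ambiguous genes is stored in attribute \code{"prop_ambiguous"}.
#' @export
gene_confidence_sets <- function(alignment, classes, subtrees, model,
                                 threshold = 0.05,
                                 scales = seq(0.5, 1.4, by = 0.1),
                                 replicates = 10000L, seed = 1L, ...) {
  genes <- gene_names(alignment)
  if (is.null(genes)) genes <- "gene_1"
  rows <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    aln <- if (is.null(alignment$partition)) alignment
           else gene_alignment(alignment, g)
    nvar <- sum(apply(aln$matrix, 2, function(col) {
      obs <- col[.is_observed(col, aln$alphabet)]
      length(unique(obs)) > 1L
    }))
    reps <- lapply(classes, function(cl)
      best_tree_in_class(aln, cl, subtrees, model, ...))
    L <- do.call(rbind, lapply(reps, function(r)
      as.numeric(site_log_likelihoods(aln, r$tree, model))))
    rownames(L) <- names(classes)
    bp <- rell_bootstrap(L, scales = scales, replicates = replicates,
                         seed = if (is.null(seed)) NULL else seed + gi - 1L)
    au <- au_pvalues(bp)
    cs <- confidence_set(au, threshold)
    verdict <- if (length(cs) >= 2L) "ambiguous"
               else paste0("supports_", cs, "_only")
    p <- stats::setNames(au$p_au, au$topology)
    rows[[gi]] <- data.frame(gene = g, t(p), n_variable = nvar,
                             low_power = nvar < 50L,
                             confidence_set = paste(cs, collapse = ","),
                             verdict = verdict, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[2:(1 + length(classes))] <- paste0("p_", names(classes))
  attr(out, "prop_ambiguous") <- mean(out$verdict == "ambiguous")
  out
}
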
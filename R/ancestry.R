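#' Standardize genotypes for PCA
#'
#' Each SNP column is centred and scaled by its estimated allele frequency:
#' entry \eqn{(g - 2\hat p)/\sqrt{2\hat p(1-\hat p)}} with \eqn{\hat p} the
#' minor-allele frequency over non-missing genotypes (the usual convention
#' for genotype PCA).  Missing genotypes become 0 after centring, i.e. are
#' imputed at the column mean.  Monomorphic SNP carry no information and
#' are dropped with a warning.
#'
#' @param dataset a [genotype_dataset()] or a genotype matrix coded 0/1/2.
#' @return numeric matrix (animals x polymorphic SNP) with attributes
#'   `p_hat` (frequencies of the retained SNP) and `dropped` (ids of
#'   monomorphic SNP removed).
#' @export
standardize_genotypes <- function(dataset) {
  G <- if (inherits(dataset, "genotype_dataset")) dataset$genotypes else dataset
  stopifnot(is.matrix(G))
  if (nrow(G) < 2L) stop("need at least 2 animals", call. = FALSE)
  p <- colMeans(G, na.rm = TRUE) / 2
  mono <- is.na(p) | p <= 0 | p >= 1
  if (all(mono)) stop("all SNP are monomorphic", call. = FALSE)
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP dropped before PCA")
  }
  dropped <- if (is.null(colnames(G))) character() else colnames(G)[mono]
  G <- G[, !mono, drop = FALSE]
  p <- p[!mono]
  X <- sweep(G, 2L, 2 * p, `-`)
  X <- sweep(X, 2L, sqrt(2 * p * (1 - p)), `/`)
  X[is.na(X)] <- 0
  attr(X, "p_hat") <- p
  attr(X, "dropped") <- dropped
  X
}

#' Principal component analysis of standardized genotypes
#'
#' Exact eigendecomposition of the animal-by-animal covariance of the
#' standardized matrix, which is the cheap side when animals are far fewer
#' than SNP.  SNP loadings (the "weights" of each component) are recovered
#' by back-projection and unit-normalized.  PC1 is oriented so that the
#' mean score of the animals in `orient_negative` (typically the pure
#' indicine lineage) is negative; the remaining components get a canonical
#' sign (largest-magnitude loading positive) so results are reproducible.
#'
#' @param X standardized matrix from [standardize_genotypes()].
#' @param k number of components (at most `min(animals - 1, n SNP)`).
#' @param orient_negative optional row indices (or logical vector) of
#'   animals whose mean PC1 score should be negative.
#' @return object of class `pca_result`: `scores` (animals x k),
#'   `loadings` (SNP x k, unit columns), `var_explained` (fraction of
#'   total variance per component).
#' @export
run_pca <- function(X, k = 10, orient_negative = NULL) {
  stopifnot(is.matrix(X))
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L || k > min(n - 1L, ncol(X))) {
    stop("k must be between 1 and min(animals - 1, SNP)", call. = FALSE)
  }
  M <- tcrossprod(X)
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  total <- sum(vals)
  d <- sqrt(vals[seq_len(k)])
  U <- e$vectors[, seq_len(k), drop = FALSE]
  scores <- U * rep(d, each = n)
  loadings <- crossprod(X, U)
  for (j in seq_len(k)) {
    if (d[j] > 0) loadings[, j] <- loadings[, j] / d[j]
    # canonical sign: strongest loading positive
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  if (!is.null(orient_negative)) {
    if (mean(scores[orient_negative, 1]) > 0) {
      scores[, 1] <- -scores[, 1]
      loadings[, 1] <- -loadings[, 1]
    }
  }
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  structure(list(scores = scores, loadings = loadings,
                 var_explained = vals[seq_len(k)] / total),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " animals, ", nrow(x$loadings),
      " SNP, k = ", ncol(x$scores), "; var explained: ",
      paste(sprintf("%.1f%%", 100 * x$var_explained[seq_len(min(3, length(x$var_explained)))]),
            collapse = ", "), " ...\n", sep = "")
  invisible(x)
}

#' Fit a two-component Normal mixture to PC1 loadings
#'
#' Maximum-likelihood EM for a univariate two-component Gaussian mixture.
#' The empirical distribution of PC1 SNP loadings in an admixed panel is
#' bimodal: one mode per ancestral component.  After fitting, the
#' component with the smaller mean is labelled *indicine* (the pure
#' indicine lineage sits at the negative end of PC1 under the orientation
#' applied by [run_pca()]) and the per-SNP posterior membership of that
#' component is `m1`, with `m2 = 1 - m1` for the taurine component.
#'
#' Initialization is deterministic: the data are split at their median and
#' component moments taken from the two halves, with equal mixing
#' proportions.  EM stops when the relative log-likelihood change drops
#' below `tol` or after `max_iter` iterations; component variances are
#' floored at 1e-12 to prevent collapse.
#'
#' @param x numeric vector of loadings (names, if any, are kept as SNP
#'   ids); at least two distinct values.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return object of class `mixture_ancestry`: `pi`, `mu`, `sigma2`
#'   (length-2, component 1 = indicine), `posterior` (n x 2 matrix with
#'   columns `m1`, `m2`), `loglik` (trace over iterations), `n_iter`,
#'   `converged`.
#' @export
fit_mixture <- function(x, tol = 1e-8, max_iter = 1000L) {
  ids <- names(x)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L || length(unique(x)) < 2L) {
    stop("need at least two distinct values to fit a mixture", call. = FALSE)
  }
  var_floor <- 1e-12
  med <- median(x)
  lo <- x <= med
  if (all(lo) || !any(lo)) lo <- x < med
  mu <- c(mean(x[lo]), mean(x[!lo]))
  s2 <- pmax(c(var(x[lo]), var(x[!lo])), var_floor)
  s2[is.na(s2)] <- var_floor
  pi <- c(0.5, 0.5)
  loglik <- numeric(0)
  converged <- FALSE
  post <- NULL
  for (it in seq_len(max_iter)) {
    # E step on the log scale for numerical stability
    l1 <- log(pi[1]) + dnorm(x, mu[1], sqrt(s2[1]), log = TRUE)
    l2 <- log(pi[2]) + dnorm(x, mu[2], sqrt(s2[2]), log = TRUE)
    m <- pmax(l1, l2)
    ll <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
    loglik <- c(loglik, ll)
    w1 <- 1 / (1 + exp(l2 - l1))
    post <- cbind(m1 = w1, m2 = 1 - w1)
    if (it > 1L) {
      prev <- loglik[it - 1L]
      if (abs(ll - prev) < tol * abs(prev)) { converged <- TRUE; break }
    }
    # M step
    n1 <- sum(w1); n2 <- n - n1
    if (n1 < 1e-10 || n2 < 1e-10) break  # a component emptied out
    pi <- c(n1, n2) / n
    mu <- c(sum(w1 * x) / n1, sum((1 - w1) * x) / n2)
    s2 <- pmax(c(sum(w1 * (x - mu[1])^2) / n1,
                 sum((1 - w1) * (x - mu[2])^2) / n2), var_floor)
  }
  # label: smaller mean = component 1 = indicine
  if (mu[1] > mu[2]) {
    mu <- rev(mu); s2 <- rev(s2); pi <- rev(pi)
    post <- post[, 2:1, drop = FALSE]
    colnames(post) <- c("m1", "m2")
  }
  rownames(post) <- ids
  structure(list(pi = pi, mu = mu, sigma2 = s2, posterior = post,
                 loglik = loglik, n_iter = length(loglik),
                 converged = converged),
            class = "mixture_ancestry")
}

#' @export
print.mixture_ancestry <- function(x, ...) {
  cat("<mixture_ancestry> two-component Normal mixture (EM, ",
      x$n_iter, " iterations", if (!x$converged) ", NOT converged", ")\n",
      sprintf("  indicine: pi = %.3f, mu = %+.4f, sd = %.4f\n",
              x$pi[1], x$mu[1], sqrt(x$sigma2[1])),
      sprintf("  taurine:  pi = %.3f, mu = %+.4f, sd = %.4f\n",
              x$pi[2], x$mu[2], sqrt(x$sigma2[2])), sep = "")
  invisible(x)
}

#' Posterior membership for new values under a fitted mixture
#'
#' @param object a `mixture_ancestry`.
#' @param newdata numeric vector.
#' @param ... unused.
#' @return matrix with columns `m1` (indicine) and `m2` (taurine).
#' @export
predict.mixture_ancestry <- function(object, newdata, ...) {
  l1 <- log(object$pi[1]) +
    dnorm(newdata, object$mu[1], sqrt(object$sigma2[1]), log = TRUE)
  l2 <- log(object$pi[2]) +
    dnorm(newdata, object$mu[2], sqrt(object$sigma2[2]), log = TRUE)
  w1 <- 1 / (1 + exp(l2 - l1))
  cbind(m1 = w1, m2 = 1 - w1)
}

#' Collapse SNP posteriors to gene-level ancestry
#'
#' A gene's indicine membership is the unweighted mean of the `m1`
#' posteriors of its assigned SNP; `pr_taurine = 1 - pr_indicine`.  Genes
#' none of whose SNP carry a posterior (e.g. all monomorphic) are excluded
#' with a warning.
#'
#' @param mixture a [fit_mixture()] result whose posterior rows are named
#'   by SNP id.
#' @param gmap a [gene_map()].
#' @return data frame `gene_id`, `n_snp`, `pr_indicine`, `pr_taurine`,
#'   ordered by gene id.
#' @export
gene_ancestry <- function(mixture, gmap) {
  stopifnot(inherits(mixture, "mixture_ancestry"), inherits(gmap, "gene_map"))
  m1 <- mixture$posterior[, "m1"]
  a <- gmap$assignment
  a$m1 <- m1[a$snp_id]
  known <- !is.na(a$m1)
  lost <- setdiff(unique(a$gene_id), unique(a$gene_id[known]))
  if (length(lost)) {
    warning(length(lost), " gene(s) had no SNP with a posterior and were excluded")
  }
  a <- a[known, , drop = FALSE]
  agg <- tapply(a$m1, a$gene_id, mean)
  cnt <- tapply(a$m1, a$gene_id, length)
  ids <- sort_c(names(agg))
  data.frame(gene_id = ids,
             n_snp = as.integer(cnt[ids]),
             pr_indicine = as.numeric(agg[ids]),
             pr_taurine = 1 - as.numeric(agg[ids]),
             stringsAsFactors = FALSE)
}

#' Select genes by component membership
#'
#' @param ga gene ancestry table from [gene_ancestry()].
#' @param cutoff membership threshold in (0.5, 1]; the two lists are
#'   disjoint by construction.
#' @return list with sorted character vectors `indicine`
#'   (`pr_indicine >= cutoff`) and `taurine` (`pr_taurine >= cutoff`).
#' @export
select_by_membership <- function(ga, cutoff = 0.95) {
  if (!(cutoff > 0.5 && cutoff <= 1)) {
    stop("cutoff must lie in (0.5, 1]", call. = FALSE)
  }
  list(indicine = sort_c(ga$gene_id[ga$pr_indicine >= cutoff]),
       taurine = sort_c(ga$gene_id[ga$pr_taurine >= cutoff]))
}

#' Negative-log posterior profiles
#'
#' For genome-wide profile plots, each gene's evidence for one component
#' is summarised as the negative log of the *opposing* component's
#' posterior: a gene with very low taurine membership scores high on the
#' indicine profile and vice versa.  Posteriors are floored at 1e-300
#' before taking logs; genes exceeding `flag_threshold` are flagged as
#' significant contributors.
#'
#' @param ga gene ancestry table from [gene_ancestry()].
#' @param base logarithm base (default 10).
#' @param flag_threshold flag genes with `-log` value above this (default 4).
#' @return data frame `gene_id`, `neglogp_indicine`, `flag_indicine`,
#'   `neglogp_taurine`, `flag_taurine`.
#' @export
neglogp_profile <- function(ga, base = 10, flag_threshold = 4) {
  eps <- 1e-300
  nl <- function(p) -log(pmax(p, eps), base = base)
  ind <- nl(ga$pr_taurine)   # low taurine membership = high indicine content
  tau <- nl(ga$pr_indicine)
  data.frame(gene_id = ga$gene_id,
             neglogp_indicine = ind, flag_indicine = ind > flag_threshold,
             neglogp_taurine = tau, flag_taurine = tau > flag_threshold,
             stringsAsFactors = FALSE)
}

#' Chromosome-level ancestry
#'
#' A chromosome's indicine content is the unweighted mean of the posterior
#' memberships of its genes.
#'
#' @param ga gene ancestry table from [gene_ancestry()].
#' @param gmap a [gene_map()] providing each gene's chromosome.
#' @return data frame `chrom`, `n_genes`, `pr_indicine`, `pr_taurine`.
#' @export
chromosome_ancestry <- function(ga, gmap) {
  stopifnot(inherits(gmap, "gene_map"))
  chrom <- gmap$genes$chrom[match(ga$gene_id, gmap$genes$gene_id)]
  keep <- !is.na(chrom)
  mi <- tapply(ga$pr_indicine[keep], chrom[keep], mean)
  cnt <- tapply(ga$pr_indicine[keep], chrom[keep], length)
  out <- data.frame(chrom = type.convert(names(mi), as.is = TRUE),
                    n_genes = as.integer(cnt),
                    pr_indicine = as.numeric(mi),
                    pr_taurine = 1 - as.numeric(mi),
                    stringsAsFactors = FALSE)
  out[order(out$chrom), , drop = FALSE]
}
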
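#' Correlation of gene heterozygosity profiles
#'
#' Pearson correlation between the per-breed HET profiles of gene pairs.
#' The breed axis is the only axis along which gene-level HET varies, so
#' "co-heterozygosity" is correlation across breeds.  Profiles with zero
#' variance are excluded with a warning; off-diagonal values are clipped
#' to +/- (1 - 1e-12) so downstream partial correlations stay finite.
#'
#' @param gene_het gene x breed HET matrix.
#' @param genes optional character vector restricting the genes used.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(gene_het, genes = NULL) {
  stopifnot(is.matrix(gene_het))
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(gene_het))
    if (length(missing)) {
      warning(length(missing), " requested gene(s) have no HET profile")
    }
    gene_het <- gene_het[intersect(genes, rownames(gene_het)), , drop = FALSE]
  }
  if (ncol(gene_het) < 3L) {
    stop("need HET profiles across at least 3 breeds", call. = FALSE)
  }
  v <- apply(gene_het, 1, var)
  flat <- is.na(v) | v == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance HET profile(s) excluded")
    gene_het <- gene_het[!flat, , drop = FALSE]
  }
  r <- cor(t(gene_het))
  lim <- 1 - 1e-12
  r[r > lim] <- lim
  r[r < -lim] <- -lim
  diag(r) <- 1
  r
}

#' First-order partial correlation
#'
#' Correlation between x and y after removing the linear effect of z:
#' \eqn{r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) /
#' \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}.
#'
#' @param r_xy,r_xz,r_yz raw correlations, strictly inside (-1, 1).
#' @return the partial correlation (vectorized).
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz) {
  if (any(abs(c(r_xy, r_xz, r_yz)) >= 1)) {
    stop("correlations must lie strictly in (-1, 1); clip inputs first",
         call. = FALSE)
  }
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' PCIT edge significance
#'
#' Partial correlation and information theory scan: for every unordered
#' gene trio the three first-order partial correlations are computed and a
#' trio-specific tolerance \eqn{\varepsilon} is set to the mean of the
#' signed partial/raw ratios (ratios with a zero raw correlation are
#' skipped).  An edge is discarded by a trio when its absolute raw
#' correlation is at most \eqn{|\varepsilon|} times both other absolute
#' raw correlations of the trio (non-strict comparison), and an edge is
#' significant iff no trio discards it.  The result is symmetric,
#' deterministic and invariant under simultaneous row/column permutation.
#'
#' @param correlations symmetric correlation matrix with unit diagonal and
#'   off-diagonal entries strictly inside (-1, 1) (see
#'   [correlation_matrix()]).
#' @return logical matrix, `TRUE` where the edge is PCIT-significant;
#'   diagonal `FALSE`.
#' @export
pcit <- function(correlations) {
  stopifnot(is.matrix(correlations))
  n <- nrow(correlations)
  if (n < 3L || n != ncol(correlations)) {
    stop("need a square correlation matrix of at least 3 genes", call. = FALSE)
  }
  if (max(abs(correlations - t(correlations))) > 1e-8) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  off <- correlations[upper.tri(correlations)]
  if (any(abs(off) >= 1)) {
    stop("off-diagonal correlations must lie strictly in (-1, 1)",
         call. = FALSE)
  }
  sig <- .pcit_cpp(correlations)
  dimnames(sig) <- dimnames(correlations)
  sig
}

#' Build the co-heterozygosity network
#'
#' Retains the edges that are PCIT-significant and whose absolute
#' correlation reaches the threshold; genes left without any edge are
#' dropped from the sub-network.
#'
#' @param correlations correlation matrix.
#' @param significance logical matrix from [pcit()].
#' @param threshold absolute-correlation threshold (default 0.95).
#' @param node_attrs optional data frame keyed by `gene_id` whose columns
#'   are attached to the nodes (e.g. `pr_indicine`, attribute flags).
#' @return object of class `cohet_network`: `nodes` (data frame),
#'   `edges` (`gene_a`, `gene_b`, `r`), `threshold` and `graph` (an
#'   [igraph][igraph::graph_from_data_frame] object).
#' @export
build_network <- function(correlations, significance, threshold = 0.95,
                          node_attrs = NULL) {
  stopifnot(identical(dim(correlations), dim(significance)))
  ids <- rownames(correlations) %||% as.character(seq_len(nrow(correlations)))
  keep <- significance & abs(correlations) >= threshold
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(gene_a = ids[idx[, 1]], gene_b = ids[idx[, 2]],
                      r = correlations[idx], stringsAsFactors = FALSE)
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  node_ids <- sort_c(unique(c(edges$gene_a, edges$gene_b)))
  nodes <- data.frame(gene_id = node_ids, stringsAsFactors = FALSE)
  if (!is.null(node_attrs)) {
    nodes <- cbind(nodes, node_attrs[match(node_ids, node_attrs$gene_id),
                                     setdiff(names(node_attrs), "gene_id"),
                                     drop = FALSE])
    rownames(nodes) <- NULL
  }
  graph <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = nodes)
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 graph = graph),
            class = "cohet_network")
}

#' @export
print.cohet_network <- function(x, ...) {
  cat("<cohet_network> ", nrow(x$nodes), " genes, ", nrow(x$edges),
      " edges (|r| >= ", x$threshold, ", PCIT-significant)\n", sep = "")
  invisible(x)
}

#' Log-log regression of a degree distribution
#'
#' Regresses `log10(frequency of degree k)` on `log10(k)` over the
#' observed degrees `k >= 1` (zero-frequency degrees are undefined on the
#' log scale and excluded).  An approximately linear fit with negative
#' slope is the classic scale-free diagnostic.
#'
#' @param degrees integer vector of node degrees.
#' @return list `slope`, `r` (Pearson correlation on the log-log scale),
#'   `p_value`, `n_points`, or `NULL` with a warning when fewer than two
#'   distinct positive degrees are observed.
#' @export
scale_free_fit <- function(degrees) {
  tab <- table(degrees[degrees >= 1])
  k <- as.numeric(names(tab))
  f <- as.numeric(tab)
  if (length(k) < 2L) {
    warning("fewer than two distinct positive degrees; no scale-free fit")
    return(NULL)
  }
  lx <- log10(k); ly <- log10(f)
  fit <- lm(ly ~ lx)
  # summary.lm warns on an exactly collinear (perfect power-law) fit
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(coef(fit)[2]),
       r = cor(lx, ly),
       p_value = sm$coefficients[2, 4],
       n_points = length(k))
}

#' Degree table, scale-free diagnostic and hub genes
#'
#' @param network a [build_network()] result.
#' @return list `degrees` (data frame `gene_id`, `degree`, sorted by
#'   decreasing degree), `fit` (see [scale_free_fit()]) and `hubs`
#'   (gene ids attaining the maximum degree).
#' @export
degree_diagnostics <- function(network) {
  stopifnot(inherits(network, "cohet_network"))
  deg <- igraph::degree(network$graph)
  df <- data.frame(gene_id = names(deg), degree = as.integer(deg),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$degree, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  list(degrees = df,
       fit = scale_free_fit(df$degree),
       hubs = df$gene_id[df$degree == max(df$degree)])
}

#' Search for the fertility-gene trio spanning the network
#'
#' Coverage of a trio is the size of its closed neighbourhood (the three
#' genes plus all their direct neighbours) divided by the number of
#' network nodes.  With at most `max_exhaustive` candidate trios every
#' trio of fertility genes is scored exhaustively (ties resolved to the
#' lexicographically smallest trio); beyond that a greedy best-first
#' build-up with pairwise swap refinement is used, with the same
#' lexicographic tie-break.
#'
#' @param network a [build_network()] result or an igraph graph.
#' @param fe_genes character vector of fertility-related gene ids; at
#'   least three must be present in the network.
#' @param method `"auto"`, `"exhaustive"` or `"greedy"`.
#' @param max_exhaustive trio-count limit for the exhaustive search under
#'   `"auto"` (default 1e5).
#' @return list `trio` (sorted gene ids), `coverage` (fraction of nodes
#'   covered), `covered` (sorted covered node ids), `method`.
#' @export
trio_span_search <- function(network, fe_genes,
                             method = c("auto", "exhaustive", "greedy"),
                             max_exhaustive = 1e5) {
  method <- match.arg(method)
  g <- if (inherits(network, "cohet_network")) network$graph else network
  ids <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  if (is.null(igraph::V(g)$name)) g <- igraph::set_vertex_attr(g, "name", value = ids)
  fe <- sort_c(intersect(fe_genes, ids))
  if (length(fe) < 3L) {
    stop("need at least 3 fertility genes present in the network",
         call. = FALSE)
  }
  n <- length(ids)
  # closed neighbourhood of each FE gene as a logical membership vector
  nb <- lapply(fe, function(v) {
    out <- rep(FALSE, n)
    out[match(c(v, igraph::neighbors(g, v)$name), ids)] <- TRUE
    out
  })
  names(nb) <- fe
  cover_size <- function(trio_idx) {
    sum(nb[[trio_idx[1]]] | nb[[trio_idx[2]]] | nb[[trio_idx[3]]])
  }
  if (method == "auto") {
    method <- if (choose(length(fe), 3) <= max_exhaustive) "exhaustive"
    else "greedy"
  }
  if (method == "exhaustive") {
    trios <- combn(length(fe), 3)
    best <- 0L; best_trio <- trios[, 1]
    for (j in seq_len(ncol(trios))) {
      s <- cover_size(trios[, j])
      if (s > best) { best <- s; best_trio <- trios[, j] }
    }
  } else {
    # best-first build-up restarted from every possible seed gene, each
    # followed by swap refinement; best refined trio wins, lexicographic
    # tie-break (fe is sorted, so index order is lexicographic)
    refine <- function(cur) {
      repeat {
        improved <- FALSE
        for (slot in 1:3) {
          others <- cur[-slot]
          base <- nb[[others[1]]] | nb[[others[2]]]
          cand <- setdiff(seq_along(fe), others)
          gain <- vapply(cand, function(i) sum(base | nb[[i]]), 0L)
          if (max(gain) > sum(base | nb[[cur[slot]]])) {
            cur[slot] <- cand[which.max(gain)]
            improved <- TRUE
          }
        }
        if (!improved) break
      }
      cur
    }
    best <- -1L; best_trio <- NULL
    for (seed_i in seq_along(fe)) {
      cur <- seed_i
      acc <- nb[[seed_i]]
      for (step in 1:2) {
        cand <- setdiff(seq_along(fe), cur)
        gain <- vapply(cand, function(i) sum(acc | nb[[i]]), 0L)
        pick <- cand[which.max(gain)]  # first max = lexicographic tie-break
        cur <- c(cur, pick)
        acc <- acc | nb[[pick]]
      }
      cur <- sort(refine(cur))
      s <- cover_size(cur)
      lex_less <- !is.null(best_trio) && {
        d <- cur - best_trio
        any(d != 0) && d[which(d != 0)[1]] < 0
      }
      if (s > best || (s == best && lex_less)) { best <- s; best_trio <- cur }
    }
  }
  covered <- nb[[best_trio[1]]] | nb[[best_trio[2]]] | nb[[best_trio[3]]]
  list(trio = fe[best_trio], coverage = best / n,
       covered = sort_c(ids[covered]), method = method)
}

#' Write a network as edge list, node table and GraphML
#'
#' @param network a [build_network()] result.
#' @param dir output directory (created if needed).
#' @param prefix file basename (default `"network"`).
#' @return `dir`, invisibly.
#' @export
write_network <- function(network, dir, prefix = "network") {
  stopifnot(inherits(network, "cohet_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(network$edges, file.path(dir, paste0(prefix, "_edges.tsv")))
  write_tsv(network$nodes, file.path(dir, paste0(prefix, "_nodes.tsv")))
  igraph::write_graph(network$graph,
                      file.path(dir, paste0(prefix, ".graphml")),
                      format = "graphml")
  invisible(dir)
}
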
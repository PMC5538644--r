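#' Permutation test of gene-set ancestry skew
#'
#' Counts how many genes of a set have taurine membership at or above
#' `threshold`, then compares that count with its null distribution
#' obtained by repeatedly sampling sets of the same size without
#' replacement from the background.  The reported percentile uses the
#' strict-less convention: trials tying the observed count are not
#' counted, so a set in a degenerate background where every trial ties
#' scores percentile 0.  A high percentile indicates taurine skew, a low
#' one indicine skew.
#'
#' @param ga gene ancestry table ([gene_ancestry()]); its `gene_id` column
#'   is the background.
#' @param gene_set character vector of gene ids, a subset of the
#'   background.
#' @param n_perm number of permutation trials (default 10000).
#' @param threshold taurine membership threshold (default 0.5).
#' @param seed optional seed making the trial stream reproducible without
#'   touching the caller's RNG.
#' @return object of class `geneset_result` (also a list): `set_size`,
#'   `n_background`, `observed`, `n_perm`, `perm_counts`, `percentile`.
#' @export
ancestry_permutation_test <- function(ga, gene_set, n_perm = 10000,
                                      threshold = 0.5, seed = NULL) {
  background <- ga$gene_id
  missing <- setdiff(gene_set, background)
  if (length(missing)) {
    stop("gene_set contains genes absent from the background: ",
         paste(head(missing, 3), collapse = ", "), call. = FALSE)
  }
  if (length(gene_set) > length(background)) {
    stop("gene_set larger than background", call. = FALSE)
  }
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  taur <- ga$pr_taurine >= threshold
  observed <- sum(taur[match(gene_set, background)])
  size <- length(gene_set)
  N <- length(background)
  counts <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sum(taur[sample.int(N, size)]), integer(1))
  })
  structure(
    list(set_size = size, n_background = N, observed = observed,
         n_perm = as.integer(n_perm), perm_counts = counts,
         percentile = 100 * sum(counts < observed) / n_perm),
    class = "geneset_result"
  )
}

#' @export
print.geneset_result <- function(x, ...) {
  cat("<geneset_result> ", x$observed, "/", x$set_size,
      " genes taurine-skewed; percentile ", sprintf("%.1f", x$percentile),
      " of ", x$n_perm, " trials (background ", x$n_background, ")\n",
      sep = "")
  invisible(x)
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric p-value per term: the probability
#' of observing at least the seen overlap between the target list and the
#' term's genes when drawing `|target|` genes from the background at
#' random.  Term genes outside the background are ignored.
#'
#' @param target_genes character vector, a subset of `background`.
#' @param term_map named list: term id -> character vector of gene ids.
#' @param background character vector of background gene ids.
#' @param p_cutoff report only terms with p-value at or below this
#'   (default 1 = all).
#' @return data frame `term`, `n_term`, `n_target`, `overlap`, `p_value`,
#'   ordered by p-value.
#' @export
overrepresentation_test <- function(target_genes, term_map, background,
                                    p_cutoff = 1) {
  if (!length(background)) stop("background is empty", call. = FALSE)
  bad <- setdiff(target_genes, background)
  if (length(bad)) {
    stop("target contains genes absent from the background: ",
         paste(head(bad, 3), collapse = ", "), call. = FALSE)
  }
  N <- length(background)
  n <- length(target_genes)
  rows <- lapply(names(term_map), function(tm) {
    term_bg <- intersect(term_map[[tm]], background)
    K <- length(term_bg)
    k <- length(intersect(term_bg, target_genes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, n_term = K, n_target = n, overlap = k,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$p_value <= p_cutoff, , drop = FALSE]
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Union of candidate gene lists for network inference
#'
#' Deduplicated, sorted union of the Hardy-Weinberg deviation list, the
#' high-membership ancestry lists and the fertility-related list (any of
#' which may be empty).
#'
#' @param ... character vectors of gene ids.
#' @return sorted character vector.
#' @export
select_network_genes <- function(...) {
  sort_c(unique(unlist(list(...), use.names = FALSE)))
}

#' Annotate genes with functional attribute flags
#'
#' Marks each gene's membership of user-supplied attribute tables
#' (typically transcription factors TF, tissue-specific TS, secreted SE,
#' kinases KI, fertility FE).  Unknown genes get all flags `FALSE`.
#'
#' @param genes character vector of gene ids.
#' @param attribute_tables named list: attribute name -> character vector
#'   of gene ids (or path to a one-column TSV, see [read_gene_list()]).
#' @return data frame with `gene_id` and one logical column per attribute.
#' @export
annotate_attributes <- function(genes, attribute_tables) {
  stopifnot(length(names(attribute_tables)) == length(attribute_tables))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (nm in names(attribute_tables)) {
    tab <- attribute_tables[[nm]]
    if (is.character(tab) && length(tab) == 1L && file.exists(tab)) {
      tab <- read_gene_list(tab)
    }
    out[[nm]] <- genes %in% tab
  }
  out
}

#' Query attribute flags with a logical expression
#'
#' Evaluates a logical expression over the flag columns of an
#' [annotate_attributes()] table, e.g.
#' `query_attributes(flags, "TF & FE & (TS | SE | KI)")`.
#'
#' @param flags data frame from [annotate_attributes()].
#' @param expr character scalar with a logical expression over the
#'   attribute column names.
#' @return character vector of gene ids satisfying the expression.
#' @export
query_attributes <- function(flags, expr) {
  sel <- eval(parse(text = expr)[[1]], envir = flags,
              enclos = baseenv())
  if (!is.logical(sel) || length(sel) != nrow(flags)) {
    stop("expression did not evaluate to one logical per gene", call. = FALSE)
  }
  flags$gene_id[sel & !is.na(sel)]
}
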
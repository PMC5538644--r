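#' Percentage heterozygosity per SNP, gene, lineage and chromosome
#'
#' Percentage heterozygosity (HET) of a SNP in a breed is 100 times the
#' proportion of that breed's non-missing animals carrying a heterozygous
#' genotype.  Gene-level HET is the unweighted mean over the gene's SNP,
#' lineage-level HET the unweighted mean over the breeds of a lineage
#' (equal breed weights), and chromosome-level HET the unweighted mean
#' over a chromosome's genes.
#'
#' @param dataset a [genotype_dataset()].
#' @param gmap optional [gene_map()]; without it only `snp_het` is
#'   computed.
#' @return object of class `het_table` with components `snp_het`
#'   (SNP x breed), `gene_het` (gene x breed), `lineage_het`
#'   (gene x lineage) and `chrom_het` (chromosome x lineage), all in
#'   percent.  Cells with no non-missing genotypes are `NA`.
#' @export
compute_het <- function(dataset, gmap = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  G <- dataset$genotypes
  rows <- breed_rows(dataset)
  snp_het <- vapply(rows, function(idx) {
    g <- G[idx, , drop = FALSE]
    100 * colMeans(g == 1L, na.rm = TRUE)
  }, numeric(ncol(G)))
  snp_het <- matrix(snp_het, nrow = ncol(G),
                    dimnames = list(colnames(G), names(rows)))
  snp_het[is.nan(snp_het)] <- NA_real_
  n_empty <- sum(is.na(snp_het))
  if (n_empty > 0) {
    message(n_empty, " (SNP, breed) cells had no non-missing genotypes")
  }
  out <- list(snp_het = snp_het, gene_het = NULL, lineage_het = NULL,
              chrom_het = NULL)
  if (!is.null(gmap)) {
    stopifnot(inherits(gmap, "gene_map"))
    a <- gmap$assignment[gmap$assignment$snp_id %in% rownames(snp_het), ,
                         drop = FALSE]
    gid <- sort_c(unique(a$gene_id))
    gene_het <- matrix(NA_real_, length(gid), ncol(snp_het),
                       dimnames = list(gid, colnames(snp_het)))
    idx <- split(match(a$snp_id, rownames(snp_het)), a$gene_id)
    for (g in gid) {
      gene_het[g, ] <- colMeans(snp_het[idx[[g]], , drop = FALSE], na.rm = TRUE)
    }
    gene_het[is.nan(gene_het)] <- NA_real_
    lineages <- intersect(c("BI", "BTI", "BT"),
                          unique(dataset$breed_table$lineage))
    lineage_het <- vapply(lineages, function(l) {
      b <- dataset$breed_table$breed_id[dataset$breed_table$lineage == l]
      rowMeans(gene_het[, b, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(gene_het)))
    lineage_het <- matrix(lineage_het, nrow = nrow(gene_het),
                          dimnames = list(gid, lineages))
    lineage_het[is.nan(lineage_het)] <- NA_real_
    chrom <- gmap$genes$chrom[match(gid, gmap$genes$gene_id)]
    chroms <- unique(chrom[order(chrom)])
    chrom_het <- vapply(chroms, function(ch) {
      colMeans(lineage_het[chrom == ch, , drop = FALSE], na.rm = TRUE)
    }, numeric(ncol(lineage_het)))
    chrom_het <- t(matrix(chrom_het, nrow = ncol(lineage_het),
                          dimnames = list(lineages, as.character(chroms))))
    out$gene_het <- gene_het
    out$lineage_het <- lineage_het
    out$chrom_het <- chrom_het
  }
  structure(out, class = "het_table")
}

#' @export
print.het_table <- function(x, ...) {
  cat("<het_table> ", nrow(x$snp_het), " SNP x ", ncol(x$snp_het),
      " breeds", if (!is.null(x$gene_het))
        paste0("; ", nrow(x$gene_het), " genes"), "\n", sep = "")
  invisible(x)
}

#' Hardy-Weinberg chi-square test from genotype counts
#'
#' Classic one-degree-of-freedom Pearson chi-square against the expected
#' genotype proportions \eqn{\hat p^2, 2\hat p\hat q, \hat q^2} with the
#' allele frequency estimated from the counts; no continuity correction.
#' Monomorphic counts give statistic 0 and p-value 1.
#'
#' @param n_hom1 count of animals homozygous for one allele.
#' @param n_het heterozygote count.
#' @param n_hom2 count homozygous for the other allele.  All three may be
#'   vectors.
#' @return data frame with `chisq` and `p_value`.
#' @export
hwe_chisq <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  p <- (2 * n_hom2 + n_het) / (2 * n)
  q <- 1 - p
  e0 <- n * q^2; e1 <- 2 * n * p * q; e2 <- n * p^2
  chisq <- ifelse(p <= 0 | p >= 1 | n == 0, 0,
                  (n_hom1 - e0)^2 / e0 + (n_het - e1)^2 / e1 +
                    (n_hom2 - e2)^2 / e2)
  pv <- ifelse(n == 0, NA_real_, pchisq(chisq, df = 1, lower.tail = FALSE))
  pv[!is.na(p) & (p <= 0 | p >= 1)] <- 1
  data.frame(chisq = chisq, p_value = pv)
}

#' Per-SNP, per-breed Hardy-Weinberg screening
#'
#' Applies [hwe_chisq()] to the genotype counts of every (SNP, breed)
#' pair.  Admixed breeds are expected to show an excess of homozygotes at
#' SNP with divergent subspecies frequencies (the Wahlund effect), so
#' their deviating SNP mark ancestry-informative regions.
#'
#' @param dataset a [genotype_dataset()].
#' @return data frame with columns `snp_id`, `breed_id`, `n_hom_major`,
#'   `n_het`, `n_hom_minor`, `p_hat` (minor-allele frequency), `chisq`,
#'   `p_value`.
#' @export
hwe_test <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  G <- dataset$genotypes
  rows <- breed_rows(dataset)
  pieces <- lapply(names(rows), function(b) {
    g <- G[rows[[b]], , drop = FALSE]
    n0 <- colSums(g == 0L, na.rm = TRUE)
    n1 <- colSums(g == 1L, na.rm = TRUE)
    n2 <- colSums(g == 2L, na.rm = TRUE)
    ht <- hwe_chisq(n0, n1, n2)
    data.frame(snp_id = colnames(G), breed_id = b,
               n_hom_major = n0, n_het = n1, n_hom_minor = n2,
               p_hat = (2 * n2 + n1) / (2 * pmax(n0 + n1 + n2, 1L)),
               chisq = ht$chisq, p_value = ht$p_value,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, pieces)
}

#' Gene lists deviating from Hardy-Weinberg equilibrium
#'
#' A gene is flagged for a breed when at least one of its SNP deviates at
#' the nominal level `alpha` in that breed (no multiple-testing
#' correction, by design: the lists are permissive candidate pools).  A
#' stricter fraction-based rule is available through `min_frac`: the
#' significant SNP must additionally make up at least that fraction of the
#' gene's tested SNP.
#'
#' @param hwe result of [hwe_test()].
#' @param gmap a [gene_map()].
#' @param alpha nominal significance threshold (default 0.01).
#' @param min_frac minimal fraction of significant SNP per gene
#'   (default 0 = any SNP).
#' @return list with `per_breed` (named list of sorted gene-id vectors)
#'   and `union` (sorted union across breeds).
#' @export
genes_deviating_hwe <- function(hwe, gmap, alpha = 0.01, min_frac = 0) {
  stopifnot(inherits(gmap, "gene_map"))
  a <- gmap$assignment
  breeds <- unique(hwe$breed_id)
  per_breed <- lapply(breeds, function(b) {
    h <- hwe[hwe$breed_id == b, , drop = FALSE]
    pv <- h$p_value[match(a$snp_id, h$snp_id)]
    sig <- !is.na(pv) & pv < alpha
    n_sig <- tapply(sig, a$gene_id, sum)
    n_tot <- tapply(!is.na(pv), a$gene_id, sum)
    flagged <- names(n_sig)[n_sig >= 1L & n_sig >= min_frac * pmax(n_tot, 1L)]
    sort_c(flagged)
  })
  names(per_breed) <- breeds
  list(per_breed = per_breed,
       union = sort_c(unique(unlist(per_breed, use.names = FALSE))))
}

#' Hierarchical clustering of breeds by gene heterozygosity
#'
#' Agglomerative clustering of breed columns of the gene-level HET matrix
#' with Euclidean distance and average (UPGMA) linkage.  Columns are
#' processed in breed-id order so the leaf order is deterministic.
#'
#' @param gene_het gene x breed matrix (the `gene_het` component of a
#'   [compute_het()] result).
#' @return list with `hclust` (the dendrogram), `cophenetic` (breed x
#'   breed cophenetic distance matrix) and `newick` (the dendrogram as a
#'   Newick string).
#' @export
cluster_breeds <- function(gene_het) {
  stopifnot(is.matrix(gene_het))
  if (ncol(gene_het) < 2L) stop("need at least 2 breeds", call. = FALSE)
  gene_het <- gene_het[, order(colnames(gene_het)), drop = FALSE]
  cc <- stats::complete.cases(gene_het)
  d <- dist(t(gene_het[cc, , drop = FALSE]))
  hc <- hclust(d, method = "average")
  list(hclust = hc,
       cophenetic = as.matrix(cophenetic(hc)),
       newick = ape::write.tree(ape::as.phylo(hc)))
}
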
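#' Gene map container
#'
#' A many-to-many assignment of SNP to genes together with the gene spans
#' it was derived from.  Coordinates are 1-based inclusive (the MAP
#' convention); BED input is converted on read.
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @param assignment data frame with columns `gene_id`, `snp_id`.
#' @return object of class `gene_map`.
#' @export
gene_map <- function(genes, assignment) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)),
            all(c("gene_id", "snp_id") %in% names(assignment)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id", call. = FALSE)
  bad <- setdiff(assignment$gene_id, genes$gene_id)
  if (length(bad)) {
    stop("assignment references unknown genes: ",
         paste(head(bad, 3), collapse = ", "), call. = FALSE)
  }
  structure(list(genes = as.data.frame(genes),
                 assignment = as.data.frame(assignment)),
            class = "gene_map")
}

#' @export
print.gene_map <- function(x, ...) {
  n_assigned <- length(unique(x$assignment$gene_id))
  cat("<gene_map> ", nrow(x$genes), " genes (", n_assigned,
      " with SNP), ", nrow(x$assignment), " SNP-gene assignments\n", sep = "")
  invisible(x)
}

#' Per-gene SNP counts
#'
#' @param gmap a [gene_map()].
#' @return named integer vector of SNP counts for genes with at least one
#'   assigned SNP.
#' @export
snp_counts <- function(gmap) {
  stopifnot(inherits(gmap, "gene_map"))
  tab <- table(gmap$assignment$gene_id)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Keep only SNP on the listed autosomes
#'
#' Sex-chromosome SNP behave differently with respect to Hardy-Weinberg
#' equilibrium in mixed-sex panels and are removed before any analysis.
#'
#' @param dataset a [genotype_dataset()].
#' @param autosomes vector of chromosome names to keep.
#' @return filtered [genotype_dataset()]; the animal set is unchanged.
#' @export
filter_autosomal <- function(dataset, autosomes) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  keep <- dataset$snp_table$chrom %in% autosomes
  if (!any(keep)) stop("no SNP left after autosome filter", call. = FALSE)
  subset_snps(dataset, which(keep))
}

#' Assign SNP to genes within a window
#'
#' A SNP is assigned to every gene whose span, extended by `window_bp` on
#' both sides, contains its map position (boundaries inclusive).  SNP
#' matching no gene are excluded from gene-level analyses; a SNP inside
#' two overlapping windows is assigned to both genes.
#'
#' @param dataset a [genotype_dataset()].
#' @param annotation gene spans as returned by [read_bed_annotation()]
#'   (columns `gene_id`, `chrom`, `start`, `end`, 1-based inclusive).
#' @param window_bp window size in base pairs around each gene span
#'   (default 1000).
#' @return a [gene_map()].
#' @export
map_snp_to_genes <- function(dataset, annotation, window_bp = 1000) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  annotation <- as.data.frame(annotation)
  if (!nrow(annotation)) stop("annotation is empty", call. = FALSE)
  snp <- dataset$snp_table
  pieces <- list()
  for (ch in unique(annotation$chrom)) {
    g <- annotation[annotation$chrom == ch, , drop = FALSE]
    s <- snp[snp$chrom == ch, , drop = FALSE]
    if (!nrow(s)) next
    win <- IRanges::IRanges(start = g$start - window_bp,
                            end = g$end + window_bp)
    pts <- IRanges::IRanges(start = s$pos, width = 1L)
    hits <- IRanges::findOverlaps(pts, win)
    if (length(hits)) {
      pieces[[length(pieces) + 1L]] <- data.frame(
        gene_id = g$gene_id[S4Vectors::subjectHits(hits)],
        snp_id = s$snp_id[S4Vectors::queryHits(hits)],
        stringsAsFactors = FALSE
      )
    }
  }
  assignment <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(gene_id = character(), snp_id = character())
  assignment <- assignment[order(assignment$gene_id, assignment$snp_id), ,
                           drop = FALSE]
  rownames(assignment) <- NULL
  gene_map(annotation[, c("gene_id", "chrom", "start", "end")], assignment)
}

#' Drop genes with too few SNP
#'
#' With the default `min_snp = "median"`, the threshold is the median
#' per-gene SNP count over genes with at least one SNP (for an even number
#' of genes the lower of the two central values, so the threshold is an
#' attainable integer); genes below the threshold are removed.  A fixed
#' integer threshold can be given instead.
#'
#' @param gmap a [gene_map()].
#' @param min_snp `"median"` or a positive integer.
#' @return filtered [gene_map()] containing only genes whose SNP count
#'   reaches the threshold, with attribute `"threshold"` recording the
#'   value used.
#' @export
filter_genes_by_snp_count <- function(gmap, min_snp = "median") {
  stopifnot(inherits(gmap, "gene_map"))
  counts <- snp_counts(gmap)
  if (!length(counts)) stop("gene map has no assigned SNP", call. = FALSE)
  thr <- if (identical(min_snp, "median")) {
    s <- sort(counts)
    s[[floor((length(s) + 1) / 2)]]  # lower median, always attained
  } else {
    as.integer(min_snp)
  }
  keep <- names(counts)[counts >= thr]
  genes <- gmap$genes[gmap$genes$gene_id %in% keep, , drop = FALSE]
  assignment <- gmap$assignment[gmap$assignment$gene_id %in% keep, ,
                                drop = FALSE]
  rownames(genes) <- rownames(assignment) <- NULL
  out <- gene_map(genes, assignment)
  attr(out, "threshold") <- thr
  out
}
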
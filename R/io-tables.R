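#' Read gene annotation from BED
#'
#' Expects BED3+ with the gene id in column 4.  BED intervals are 0-based
#' half-open; they are converted to the package's 1-based inclusive
#' convention (`start = bed_start + 1`, `end = bed_end`), matching MAP
#' positions.
#'
#' @param path BED file.
#' @return data frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_bed_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty annotation file: ", path)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 4L)) {
    bad <- which(lengths(fields) < 4L)[1]
    stop("line ", bad, " in ", path, ": BED3+ with a name column required",
         call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:4))
  start0 <- as.integer(m[, 2]); end0 <- as.integer(m[, 3])
  if (any(is.na(start0)) || any(is.na(end0))) {
    stop("non-numeric coordinates in ", path, call. = FALSE)
  }
  if (any(start0 >= end0)) {
    bad <- which(start0 >= end0)[1]
    stop("line ", bad, " in ", path, ": start >= end", call. = FALSE)
  }
  ids <- m[, 4]
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))],
               collapse = ", "), call. = FALSE)
  }
  data.frame(gene_id = ids, chrom = type.convert(m[, 1], as.is = TRUE),
             start = start0 + 1L, end = end0, stringsAsFactors = FALSE)
}

#' Write gene annotation as BED
#'
#' Converts the internal 1-based inclusive spans back to 0-based half-open
#' BED coordinates.
#'
#' @param genes data frame with `gene_id`, `chrom`, `start`, `end`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed_annotation <- function(genes, path) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  out <- data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read and write the breed/lineage table
#'
#' Headered TSV with columns `breed_id` and `lineage` (`BI`, `BT` or
#' `BTI`); extra columns such as the simulator's true ancestry proportion
#' are preserved.
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_breed_table <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("breed_id", "lineage") %in% names(x))) {
    stop(path, " must have columns breed_id and lineage", call. = FALSE)
  }
  x
}

#' @rdname read_breed_table
#' @param breed_table data frame to write.
#' @export
write_breed_table <- function(breed_table, path) {
  write_tsv(breed_table, path)
}

#' Read and write one-column gene lists
#'
#' Headered single-column TSV (column `gene_id`).
#'
#' @param path TSV file.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  as.character(x[[1]])
}

#' @rdname read_gene_list
#' @param genes character vector of gene ids.
#' @export
write_gene_list <- function(genes, path) {
  write_tsv(data.frame(gene_id = genes, stringsAsFactors = FALSE), path)
}

#' Write the per-gene ancestry summary table
#'
#' One row per gene with its SNP count, percentage heterozygosity by
#' lineage and posterior membership of the two ancestral components
#' (columns `gene_id`, `n_snp`, `het_BI`, `het_BTI`, `het_BT`,
#' `pr_indicine`, `pr_taurine`).  Rows are ordered by gene id and floats
#' printed at 4 decimals, so re-running on identical inputs is
#' byte-identical.
#'
#' @param ga gene ancestry table from [gene_ancestry()].
#' @param het a `het_table` from [compute_het()] (its `lineage_het`
#'   component is used); lineages absent from the panel yield `NA`
#'   columns.
#' @param path output TSV.
#' @return the assembled data frame, invisibly.
#' @export
write_gene_ancestry_table <- function(ga, het, path) {
  lin <- het$lineage_het
  pick <- function(l) {
    if (!is.null(lin) && l %in% colnames(lin)) {
      lin[match(ga$gene_id, rownames(lin)), l]
    } else rep(NA_real_, nrow(ga))
  }
  out <- data.frame(gene_id = ga$gene_id,
                    n_snp = ga$n_snp,
                    het_BI = pick("BI"),
                    het_BTI = pick("BTI"),
                    het_BT = pick("BT"),
                    pr_indicine = ga$pr_indicine,
                    pr_taurine = ga$pr_taurine,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  write_tsv(out, path)
  invisible(out)
}
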
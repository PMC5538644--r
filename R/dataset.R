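#' Genotype dataset container
#'
#' Bundles an animals x SNP genotype matrix with its SNP map, animal table
#' and breed table.  Genotypes are coded as counts of the panel-wide minor
#' allele (0, 1, 2) with `NA` marking missing calls; all downstream
#' statistics exclude missing entries.
#'
#' @param genotypes integer matrix, animals in rows, SNP in columns.  Row
#'   names are animal ids and column names SNP ids (set from the tables if
#'   absent).
#' @param snp_table data frame with columns `snp_id`, `chrom`, `pos`
#'   (1-based), `allele_minor`, `allele_major`.  One row per genotype
#'   column, in column order.
#' @param animal_table data frame with columns `animal_id`, `breed_id`, one
#'   row per genotype row.
#' @param breed_table data frame with columns `breed_id`, `lineage`;
#'   lineage is one of `"BI"` (pure indicine), `"BT"` (pure taurine) or
#'   `"BTI"` (admixed/composite).  Extra columns (e.g. the simulator's true
#'   ancestry proportion) are kept.
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, snp_table, animal_table, breed_table) {
  stopifnot(is.matrix(genotypes))
  if (!all(c("snp_id", "chrom", "pos") %in% names(snp_table))) {
    stop("snp_table needs columns snp_id, chrom, pos", call. = FALSE)
  }
  if (!all(c("animal_id", "breed_id") %in% names(animal_table))) {
    stop("animal_table needs columns animal_id, breed_id", call. = FALSE)
  }
  if (!all(c("breed_id", "lineage") %in% names(breed_table))) {
    stop("breed_table needs columns breed_id, lineage", call. = FALSE)
  }
  if (nrow(genotypes) != nrow(animal_table)) {
    stop("genotype rows (", nrow(genotypes), ") != animals (",
         nrow(animal_table), ")", call. = FALSE)
  }
  if (ncol(genotypes) != nrow(snp_table)) {
    stop("genotype columns (", ncol(genotypes), ") != SNP (",
         nrow(snp_table), ")", call. = FALSE)
  }
  if (any(snp_table$pos <= 0)) stop("SNP positions must be positive", call. = FALSE)
  miss <- setdiff(unique(animal_table$breed_id), breed_table$breed_id)
  if (length(miss)) {
    stop("breeds missing from breed_table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_lin <- setdiff(unique(breed_table$lineage), c("BI", "BT", "BTI"))
  if (length(bad_lin)) {
    stop("unknown lineage: ", paste(bad_lin, collapse = ", "), call. = FALSE)
  }
  ok <- is.na(genotypes) | genotypes %in% 0:2
  if (!all(ok)) stop("genotypes must be 0, 1, 2 or NA", call. = FALSE)
  rownames(genotypes) <- as.character(animal_table$animal_id)
  colnames(genotypes) <- as.character(snp_table$snp_id)
  structure(
    list(genotypes = genotypes,
         snp_table = as.data.frame(snp_table),
         animal_table = as.data.frame(animal_table),
         breed_table = as.data.frame(breed_table)),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("<genotype_dataset> ", nrow(x$genotypes), " animals x ",
      ncol(x$genotypes), " SNP, ", nrow(x$breed_table), " breeds (",
      paste(sprintf("%s:%d", c("BI", "BT", "BTI"),
                    vapply(c("BI", "BT", "BTI"), function(l)
                      sum(x$breed_table$lineage == l), 0L)),
            collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

# Subset a dataset by SNP (logical/integer/character index over columns).
subset_snps <- function(dataset, idx) {
  geno <- dataset$genotypes[, idx, drop = FALSE]
  snp <- dataset$snp_table[match(colnames(geno), dataset$snp_table$snp_id), ,
                           drop = FALSE]
  rownames(snp) <- NULL
  genotype_dataset(geno, snp, dataset$animal_table, dataset$breed_table)
}

# Named list of animal-row indices per breed, in breed_table order.
breed_rows <- function(dataset) {
  ids <- dataset$breed_table$breed_id
  out <- lapply(ids, function(b) which(dataset$animal_table$breed_id == b))
  names(out) <- ids
  out
}
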
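#' Read PLINK-style text genotypes
#'
#' Supports the PED/MAP (one line per animal) and TPED/TFAM (one line per
#' SNP) text dialects.  Alleles are recoded to counts of the panel-wide
#' minor allele; the less frequent allele over all animals is minor, with
#' ties broken toward the first-listed allele (order of appearance in the
#' file).  The unknown-genotype token `0` maps to missing.  The PED/TFAM
#' family-id column is taken as the breed id; breed-to-lineage mapping is
#' never inferred and must be supplied.
#'
#' @param prefix path prefix; `<prefix>.ped`/`<prefix>.map` or
#'   `<prefix>.tped`/`<prefix>.tfam` must exist.
#' @param breed_table data frame with columns `breed_id`, `lineage`, or a
#'   path to such a TSV (see [read_breed_table()]).
#' @param dialect `"ped"` or `"tped"`.
#' @return a [genotype_dataset()].
#' @export
read_plink <- function(prefix, breed_table, dialect = c("ped", "tped")) {
  dialect <- match.arg(dialect)
  if (is.character(breed_table)) breed_table <- read_breed_table(breed_table)
  if (dialect == "ped") {
    map_file <- paste0(prefix, ".map")
    ped_file <- paste0(prefix, ".ped")
    map <- read.table(map_file, header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("chrom", "snp_id", "cm", "pos"))
    n_snp <- nrow(map)
    lines <- readLines(ped_file)
    fields <- strsplit(trimws(lines), "[ \t]+")
    want <- 6L + 2L * n_snp
    len <- lengths(fields)
    if (any(len != want)) {
      bad <- which(len != want)[1]
      stop("malformed line ", bad, " in ", ped_file, ": expected ", want,
           " fields, found ", len[bad], call. = FALSE)
    }
    m <- do.call(rbind, fields)
    fam <- m[, 1]; iid <- m[, 2]
    a1 <- m[, 6L + 2L * seq_len(n_snp) - 1L, drop = FALSE]
    a2 <- m[, 6L + 2L * seq_len(n_snp), drop = FALSE]
  } else {
    tped_file <- paste0(prefix, ".tped")
    tfam_file <- paste0(prefix, ".tfam")
    tfam <- read.table(tfam_file, header = FALSE, stringsAsFactors = FALSE)
    fam <- tfam[[1]]; iid <- tfam[[2]]
    n_animal <- length(iid)
    lines <- readLines(tped_file)
    fields <- strsplit(trimws(lines), "[ \t]+")
    want <- 4L + 2L * n_animal
    len <- lengths(fields)
    if (any(len != want)) {
      bad <- which(len != want)[1]
      stop("malformed line ", bad, " in ", tped_file, ": expected ", want,
           " fields, found ", len[bad], call. = FALSE)
    }
    m <- do.call(rbind, fields)
    map <- data.frame(chrom = m[, 1], snp_id = m[, 2], cm = m[, 3],
                      pos = m[, 4], stringsAsFactors = FALSE)
    a1 <- t(m[, 4L + 2L * seq_len(n_animal) - 1L, drop = FALSE])
    a2 <- t(m[, 4L + 2L * seq_len(n_animal), drop = FALSE])
    n_snp <- nrow(map)
  }
  n_animal <- length(iid)
  src <- if (dialect == "ped") paste0(prefix, ".ped") else paste0(prefix, ".tped")
  geno <- matrix(NA_integer_, n_animal, n_snp)
  allele_minor <- character(n_snp)
  allele_major <- character(n_snp)
  for (j in seq_len(n_snp)) {
    # interleave copies in file order so "first listed" is well defined
    v <- as.vector(t(cbind(a1[, j], a2[, j])))
    seen <- unique(v[v != "0"])
    if (length(seen) > 2L) {
      stop("SNP ", map$snp_id[j], " in ", src, " has ", length(seen),
           " alleles (", paste(seen, collapse = "/"),
           "); only biallelic SNP are supported", call. = FALSE)
    }
    if (length(seen) == 0L) {            # fully missing SNP
      allele_minor[j] <- allele_major[j] <- NA_character_
      next
    }
    if (length(seen) == 1L) {            # monomorphic: minor allele unseen
      g <- rep(0L, n_animal)
      g[a1[, j] == "0" | a2[, j] == "0"] <- NA_integer_
      geno[, j] <- g
      allele_minor[j] <- NA_character_
      allele_major[j] <- seen[1]
      next
    }
    n1 <- sum(v == seen[1], na.rm = TRUE)
    n2 <- sum(v == seen[2], na.rm = TRUE)
    minor <- if (n1 <= n2) seen[1] else seen[2]
    major <- if (n1 <= n2) seen[2] else seen[1]
    g <- (a1[, j] == minor) + (a2[, j] == minor)
    g[a1[, j] == "0" | a2[, j] == "0"] <- NA_integer_
    geno[, j] <- as.integer(g)
    allele_minor[j] <- minor
    allele_major[j] <- if (is.na(major)) "0" else major
  }
  snp_table <- data.frame(snp_id = map$snp_id,
                          chrom = type.convert(map$chrom, as.is = TRUE),
                          pos = as.integer(map$pos),
                          allele_minor = allele_minor,
                          allele_major = allele_major,
                          stringsAsFactors = FALSE)
  animal_table <- data.frame(animal_id = iid, breed_id = fam,
                             stringsAsFactors = FALSE)
  genotype_dataset(geno, snp_table, animal_table, breed_table)
}

#' Write PLINK-style text genotypes
#'
#' Inverse of [read_plink()]: genotype 2 becomes a homozygous minor-allele
#' pair, 1 a minor/major pair (minor listed first), 0 a homozygous major
#' pair and missing the `0 0` token.  The breed id is written as the
#' family id.
#'
#' @param dataset a [genotype_dataset()].
#' @param prefix output path prefix.
#' @param dialect `"ped"` (writes `.ped` + `.map`) or `"tped"` (writes
#'   `.tped` + `.tfam`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(dataset, prefix, dialect = c("ped", "tped")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(dataset, "genotype_dataset"))
  G <- dataset$genotypes
  st <- dataset$snp_table
  n <- nrow(G); S <- ncol(G)
  minor <- st$allele_minor %||% rep("B", S)
  major <- st$allele_major %||% rep("A", S)
  minor[is.na(minor)] <- "B"; major[is.na(major)] <- "A"
  Mm <- matrix(rep(minor, each = n), n, S)
  MM <- matrix(rep(major, each = n), n, S)
  c1 <- ifelse(!is.na(G) & G >= 1L, Mm, MM)
  c2 <- ifelse(!is.na(G) & G == 2L, Mm, MM)
  c1[is.na(G)] <- "0"; c2[is.na(G)] <- "0"
  inter <- matrix("", n, 2L * S)
  inter[, 2L * seq_len(S) - 1L] <- c1
  inter[, 2L * seq_len(S)] <- c2
  if (dialect == "ped") {
    lead <- cbind(dataset$animal_table$breed_id, dataset$animal_table$animal_id,
                  "0", "0", "0", "-9")
    lines <- apply(cbind(lead, inter), 1, paste, collapse = " ")
    writeLines(lines, paste0(prefix, ".ped"))
    map <- cbind(st$chrom, st$snp_id, "0", st$pos)
    writeLines(apply(map, 1, paste, collapse = "\t"), paste0(prefix, ".map"))
  } else {
    tinter <- matrix("", S, 2L * n)
    tinter[, 2L * seq_len(n) - 1L] <- t(c1)
    tinter[, 2L * seq_len(n)] <- t(c2)
    lead <- cbind(st$chrom, st$snp_id, "0", st$pos)
    writeLines(apply(cbind(lead, tinter), 1, paste, collapse = " "),
               paste0(prefix, ".tped"))
    tfam <- cbind(dataset$animal_table$breed_id,
                  dataset$animal_table$animal_id, "0", "0", "0", "-9")
    writeLines(apply(tfam, 1, paste, collapse = " "), paste0(prefix, ".tfam"))
  }
  invisible(prefix)
}
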
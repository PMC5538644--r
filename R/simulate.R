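#' Simulation configuration for admixed genotype panels
#'
#' Defines the conditions under which a synthetic panel is generated: two
#' ancestral subspecies (called *indicine* and *taurine*) diverged at a
#' given \eqn{F_{ST}}, a set of pure and admixed breeds with per-breed
#' indicine ancestry proportions, SNP organised into gene blocks of at
#' least six SNP, and optional gene sets whose allele frequencies are made
#' deliberately informative for one ancestral component.
#'
#' The default breed panel is a scaled-down multi-breed design: two pure
#' indicine breeds (ancestry 1), four pure taurine breeds (ancestry 0) and
#' three composites with indicine proportions 0.375, 0.5 and 0.625, 150
#' animals each.  The default divergence `fst = 0.2` is of the order seen
#' between the two cattle subspecies, and the ancestral minor-allele
#' frequency range `[0.05, 0.5]` mimics the common-variant ascertainment of
#' commercial SNP arrays.
#'
#' @param n_snp total number of SNP; must be at least `6 * n_genes`.
#' @param n_genes number of genes; each receives a contiguous block of at
#'   least six SNP.
#' @param n_chromosomes number of autosomes the genes are spread over.
#' @param breeds data frame with columns `breed_id`, `lineage` (`"BI"`,
#'   `"BT"` or `"BTI"`), `ancestry` (indicine proportion; must be 1 for BI,
#'   0 for BT and strictly between 0 and 1 for BTI) and `n_animals`.
#' @param fst divergence between the two subspecies, in (0, 1).
#' @param ancestral_maf_range interval within (0, 0.5] from which ancestral
#'   minor-allele frequencies are drawn.
#' @param skewed_sets data frame (possibly empty) with columns `set_name`,
#'   `n_genes`, `target` (`"indicine"` or `"taurine"`): gene sets whose SNP
#'   frequencies are rewritten to be strongly differentiated with the
#'   common allele in the matching pure lineage.
#' @param ancestry_dispersion concentration `nu` of the Beta distribution
#'   from which each admixed animal's individual indicine proportion is
#'   drawn (`Beta(alpha * nu, (1 - alpha) * nu)`, mean `alpha`, variance
#'   `alpha (1 - alpha) / (nu + 1)`).  Individual-level ancestry variation
#'   is what spreads composite animals along PC1 and produces the Wahlund
#'   homozygote excess their HWE tests detect.  The default 4 gives a
#'   broad crossbred-like spread (sd 0.22 at alpha = 0.5); `Inf` makes
#'   every animal's proportion exactly the breed value, in which case
#'   admixed breeds are in exact Hardy-Weinberg equilibrium.
#' @param missing_rate proportion of genotype calls set missing completely
#'   at random (default 0).
#' @param seed integer seed; the full panel is reproducible from the
#'   configuration alone.
#' @return an object of class `sim_config`.
#' @seealso [simulate_panel()]
#' @export
sim_config <- function(n_snp = 6000,
                       n_genes = 750,
                       n_chromosomes = 29,
                       breeds = default_breeds(),
                       fst = 0.2,
                       ancestral_maf_range = c(0.05, 0.5),
                       skewed_sets = empty_skewed_sets(),
                       ancestry_dispersion = 4,
                       missing_rate = 0,
                       seed = 1L) {
  breeds <- as.data.frame(breeds)
  skewed_sets <- as.data.frame(skewed_sets)
  if (!all(c("breed_id", "lineage", "ancestry", "n_animals") %in% names(breeds))) {
    stop("breeds needs columns breed_id, lineage, ancestry, n_animals",
         call. = FALSE)
  }
  if (anyDuplicated(breeds$breed_id)) stop("duplicate breed_id", call. = FALSE)
  if (!(is.numeric(fst) && length(fst) == 1L && fst > 0 && fst < 1)) {
    stop("fst must lie strictly in (0, 1)", call. = FALSE)
  }
  if (n_snp < 6 * n_genes) {
    stop("n_snp must be at least 6 * n_genes", call. = FALSE)
  }
  r <- ancestral_maf_range
  if (length(r) != 2L || r[1] > r[2] || r[1] <= 0 || r[2] > 0.5) {
    stop("ancestral_maf_range must be an interval within (0, 0.5]", call. = FALSE)
  }
  for (i in seq_len(nrow(breeds))) {
    lin <- breeds$lineage[i]; a <- breeds$ancestry[i]
    ok <- switch(lin,
                 BI = isTRUE(a == 1),
                 BT = isTRUE(a == 0),
                 BTI = isTRUE(a > 0 && a < 1),
                 FALSE)
    if (!ok) {
      stop("breed ", breeds$breed_id[i], ": ancestry ", a,
           " inconsistent with lineage ", lin,
           " (BI needs 1, BT needs 0, BTI needs (0,1))", call. = FALSE)
    }
  }
  if (nrow(skewed_sets)) {
    if (!all(c("set_name", "n_genes", "target") %in% names(skewed_sets))) {
      stop("skewed_sets needs columns set_name, n_genes, target", call. = FALSE)
    }
    if (!all(skewed_sets$target %in% c("indicine", "taurine"))) {
      stop("skewed_sets$target must be 'indicine' or 'taurine'", call. = FALSE)
    }
    if (sum(skewed_sets$n_genes) > n_genes) {
      stop("skewed_sets request more genes (", sum(skewed_sets$n_genes),
           ") than available (", n_genes, ")", call. = FALSE)
    }
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  if (!(is.numeric(ancestry_dispersion) && length(ancestry_dispersion) == 1L &&
        ancestry_dispersion > 0)) {
    stop("ancestry_dispersion must be a positive number (Inf allowed)",
         call. = FALSE)
  }
  structure(
    list(n_snp = as.integer(n_snp), n_genes = as.integer(n_genes),
         n_chromosomes = as.integer(n_chromosomes), breeds = breeds,
         fst = fst, ancestral_maf_range = r, skewed_sets = skewed_sets,
         ancestry_dispersion = ancestry_dispersion,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_breeds <- function() {
  data.frame(
    breed_id  = c("BI1", "BI2", "BT1", "BT2", "BT3", "BT4",
                  "XC1", "XC2", "XC3"),
    lineage   = c("BI", "BI", "BT", "BT", "BT", "BT", "BTI", "BTI", "BTI"),
    ancestry  = c(1, 1, 0, 0, 0, 0, 0.375, 0.5, 0.625),
    n_animals = rep(150L, 9L),
    stringsAsFactors = FALSE
  )
}

#' @rdname sim_config
#' @export
empty_skewed_sets <- function() {
  data.frame(set_name = character(), n_genes = integer(),
             target = character(), stringsAsFactors = FALSE)
}

#' Draw subspecies allele frequencies under the Balding-Nichols model
#'
#' For each SNP an ancestral frequency `p` is drawn uniformly from the
#' configured minor-allele range or its mirror image (so the simulated
#' allele is the minor one only about half the time), and the indicine and
#' taurine frequencies are drawn independently from
#' \eqn{\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)}, which has mean `p` and
#' variance \eqn{p(1-p)F} with `F` the configured `fst`.  Frequencies are
#' clamped away from 0 and 1 by 1e-6.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `p_ancestral`, `p_indicine`,
#'   `p_taurine`, one row per SNP.  Frequencies refer to the simulated "B"
#'   allele (recoded to minor-allele counts later).
#' @export
simulate_allele_freqs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_snp
  F <- config$fst
  r <- config$ancestral_maf_range
  with_seed(config$seed, {
    maf <- runif(n, r[1], r[2])
    p <- ifelse(runif(n) < 0.5, maf, 1 - maf)
    shape1 <- p * (1 - F) / F
    shape2 <- (1 - p) * (1 - F) / F
    pi <- rbeta(n, shape1, shape2)
    pt <- rbeta(n, shape1, shape2)
    clamp <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
    data.frame(p_ancestral = p, p_indicine = clamp(pi), p_taurine = clamp(pt))
  })
}

#' Lay SNP out in gene blocks along chromosomes
#'
#' Genes are distributed evenly across chromosomes; each gene receives a
#' contiguous block of at least six SNP spaced 200 bp apart, with the gene
#' span running from its first to its last SNP.  Consecutive genes are
#' separated by 4 kb so that 1 kb windows never overlap.  SNP left over
#' after the per-gene blocks are placed as decoys at least 3 kb beyond the
#' last gene of a chromosome, hence more than 1 kb from any gene.  The
#' layout is a deterministic function of the configuration.
#'
#' @param config a [sim_config()].
#' @return list with `snp_table` (snp_id, chrom, pos, gene_id or NA),
#'   `genes` (gene_id, chrom, start, end) and `gene_map` (a [gene_map()]
#'   built from the layout).
#' @export
assign_gene_blocks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_genes <- config$n_genes
  n_snp <- config$n_snp
  n_chr <- config$n_chromosomes
  slack <- n_snp - 6L * n_genes
  n_decoy <- if (slack > 0L) as.integer(ceiling(slack / 3)) else 0L
  extra <- slack - n_decoy
  # per-gene SNP counts: 6 plus round-robin share of the extra SNP
  sizes <- rep(6L, n_genes)
  if (extra > 0L) {
    add <- tabulate(((seq_len(extra) - 1L) %% n_genes) + 1L, nbins = n_genes)
    sizes <- sizes + add
  }
  gene_chrom <- rep(seq_len(n_chr), length.out = n_genes)
  gene_chrom <- sort(gene_chrom)
  decoy_chrom <- if (n_decoy > 0L) {
    sort(rep(seq_len(n_chr), length.out = n_decoy))
  } else integer()

  gid <- sprintf("gene%05d", seq_len(n_genes))
  snp_chrom <- integer(n_snp); snp_pos <- integer(n_snp)
  snp_gene <- rep(NA_character_, n_snp)
  gene_start <- integer(n_genes); gene_end <- integer(n_genes)
  k <- 0L
  for (ch in seq_len(n_chr)) {
    cursor <- 5000L
    for (g in which(gene_chrom == ch)) {
      pos <- cursor + 200L * (seq_len(sizes[g]) - 1L)
      idx <- k + seq_len(sizes[g])
      snp_chrom[idx] <- ch
      snp_pos[idx] <- pos
      snp_gene[idx] <- gid[g]
      gene_start[g] <- pos[1]
      gene_end[g] <- pos[sizes[g]]
      cursor <- pos[sizes[g]] + 4000L
      k <- k + sizes[g]
    }
    nd <- sum(decoy_chrom == ch)
    if (nd > 0L) {
      pos <- cursor + 3000L + 500L * (seq_len(nd) - 1L)
      idx <- k + seq_len(nd)
      snp_chrom[idx] <- ch
      snp_pos[idx] <- pos
      k <- k + nd
    }
  }
  stopifnot(k == n_snp)
  ord <- order(snp_chrom, snp_pos)
  snp_table <- data.frame(
    snp_id = sprintf("snp%06d", seq_len(n_snp)),
    chrom = snp_chrom[ord], pos = snp_pos[ord],
    gene_id = snp_gene[ord], stringsAsFactors = FALSE
  )
  genes <- data.frame(gene_id = gid, chrom = gene_chrom,
                      start = gene_start, end = gene_end,
                      stringsAsFactors = FALSE)
  assign <- snp_table[!is.na(snp_table$gene_id), c("gene_id", "snp_id")]
  rownames(assign) <- NULL
  list(snp_table = snp_table, genes = genes,
       gene_map = gene_map(genes, assign))
}

#' Designate ancestry-informative gene sets
#'
#' Marks disjoint gene sets as deliberately skewed towards one ancestral
#' component and rewrites the subspecies frequencies of their SNP so that
#' the sets are strongly informative: SNP in a taurine-targeted set get a
#' common-in-taurine, rare-in-indicine simulated allele
#' (\eqn{p_{taurine} \sim U(0.35, 0.5)}, \eqn{p_{indicine} \sim U(0.005,
#' 0.05)}) and vice versa.  Such SNP carry large frequency differences, so
#' their PC1 loadings fall in the matching mixture mode and the set scores
#' at the corresponding extreme of the gene-set permutation test.
#'
#' @param config a [sim_config()] with a non-empty `skewed_sets` table.
#' @param gene_map the layout's gene map (see [assign_gene_blocks()]).
#' @param freqs frequencies from [simulate_allele_freqs()].
#' @return list with `sets` (named list of gene-id vectors, possibly
#'   empty) and `freqs` (the frequency table with skewed SNP rewritten).
#'   Genes are drawn without replacement so sets are disjoint.
#' @export
designate_skewed_sets <- function(config, gene_map, freqs) {
  stopifnot(inherits(config, "sim_config"), inherits(gene_map, "gene_map"))
  spec <- config$skewed_sets
  if (!nrow(spec)) return(list(sets = list(), freqs = freqs))
  if (sum(spec$n_genes) > nrow(gene_map$genes)) {
    stop("skewed sets oversubscribe the available genes", call. = FALSE)
  }
  snp_of <- split(gene_map$assignment$snp_id, gene_map$assignment$gene_id)
  snp_index <- match(gene_map$assignment$snp_id,
                     sprintf("snp%06d", seq_len(config$n_snp)))
  names(snp_index) <- gene_map$assignment$snp_id
  with_seed(config$seed + 2L, {
    pool <- gene_map$genes$gene_id
    sets <- list()
    for (i in seq_len(nrow(spec))) {
      chosen <- sample(pool, spec$n_genes[i])
      pool <- setdiff(pool, chosen)
      snps <- unlist(snp_of[chosen], use.names = FALSE)
      j <- snp_index[snps]
      hi <- runif(length(j), 0.35, 0.50)
      lo <- runif(length(j), 0.005, 0.05)
      if (spec$target[i] == "taurine") {
        freqs$p_taurine[j] <- hi
        freqs$p_indicine[j] <- lo
      } else {
        freqs$p_indicine[j] <- hi
        freqs$p_taurine[j] <- lo
      }
      sets[[spec$set_name[i]]] <- sort_c(chosen)
    }
    list(sets = sets, freqs = freqs)
  })
}

#' Simulate genotypes for all breeds
#'
#' Each admixed animal first receives an individual indicine proportion
#' drawn from a Beta distribution centred on its breed's ancestry (see
#' `ancestry_dispersion` in [sim_config()]); pure-lineage animals have
#' proportion exactly 0 or 1.  Every allele copy at every SNP is then
#' independently of indicine origin with the animal's individual
#' probability and drawn Bernoulli from the matching subspecies frequency
#' (SNP are unlinked and no LD is generated).  Genotypes are recoded as
#' counts of the panel-wide minor allele; if the simulated allele's
#' overall frequency exceeds 0.5 the coding is flipped (ties keep the
#' first-listed allele as minor).  The realised individual proportions
#' are recorded in the animal table as `ancestry_true`.
#'
#' @param config a [sim_config()].
#' @param freqs per-SNP frequencies ([simulate_allele_freqs()], possibly
#'   rewritten by [designate_skewed_sets()]).
#' @param snp_table SNP layout from [assign_gene_blocks()]; defaults to
#'   generating the layout from `config`.
#' @return a [genotype_dataset()].  The breed table keeps the true
#'   `ancestry` proportion as an extra column.
#' @export
simulate_genotypes <- function(config, freqs, snp_table = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(snp_table)) snp_table <- assign_gene_blocks(config)$snp_table
  n_snp <- config$n_snp
  stopifnot(nrow(freqs) == n_snp, nrow(snp_table) == n_snp)
  # freqs rows are indexed by snp number; reorder to snp_table order
  ord <- match(snp_table$snp_id, sprintf("snp%06d", seq_len(n_snp)))
  pI <- freqs$p_indicine[ord]
  pT <- freqs$p_taurine[ord]
  breeds <- config$breeds
  nu <- config$ancestry_dispersion
  with_seed(config$seed + 1L, {
    blocks <- vector("list", nrow(breeds))
    alpha_true <- vector("list", nrow(breeds))
    for (b in seq_len(nrow(breeds))) {
      nb <- breeds$n_animals[b]
      alpha <- breeds$ancestry[b]
      ai <- if (alpha %in% c(0, 1) || !is.finite(nu)) rep(alpha, nb)
            else rbeta(nb, alpha * nu, (1 - alpha) * nu)
      alpha_true[[b]] <- ai
      g <- matrix(0L, nb, n_snp)
      for (copy in 1:2) {
        # ai recycles down columns: one ancestry probability per animal
        anc <- matrix(runif(nb * n_snp), nb, n_snp) < ai
        pm <- matrix(rep(pT, each = nb), nb, n_snp)
        pm[anc] <- matrix(rep(pI, each = nb), nb, n_snp)[anc]
        g <- g + (matrix(runif(nb * n_snp), nb, n_snp) < pm)
      }
      blocks[[b]] <- g
    }
    G <- do.call(rbind, blocks)
    if (config$missing_rate > 0) {
      G[matrix(runif(length(G)) < config$missing_rate,
               nrow(G), ncol(G))] <- NA_integer_
    }
    # recode to panel-wide minor-allele counts; allele "B" is the simulated
    # allele, "A" its alternative; ties keep "A" (first listed) as minor
    freqB <- colMeans(G, na.rm = TRUE) / 2
    flip <- freqB >= 0.5
    G[, flip] <- 2L - G[, flip]
    allele_minor <- ifelse(flip, "A", "B")
    allele_major <- ifelse(flip, "B", "A")
    st <- data.frame(snp_id = snp_table$snp_id, chrom = snp_table$chrom,
                     pos = snp_table$pos, allele_minor = allele_minor,
                     allele_major = allele_major, stringsAsFactors = FALSE)
    animal_table <- data.frame(
      animal_id = sprintf("%s_%03d",
                          rep(breeds$breed_id, breeds$n_animals),
                          unlist(lapply(breeds$n_animals, seq_len))),
      breed_id = rep(breeds$breed_id, breeds$n_animals),
      ancestry_true = unlist(alpha_true, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    breed_table <- data.frame(breed_id = breeds$breed_id,
                              lineage = breeds$lineage,
                              ancestry = breeds$ancestry,
                              stringsAsFactors = FALSE)
    genotype_dataset(G, st, animal_table, breed_table)
  })
}

#' Simulate a complete admixed panel
#'
#' Convenience wrapper running [simulate_allele_freqs()],
#' [assign_gene_blocks()], [designate_skewed_sets()] and
#' [simulate_genotypes()] in order, so that skewed-set frequency rewrites
#' are reflected in the genotypes.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_panel` with elements `dataset`
#'   (a [genotype_dataset()]), `gene_map`, `genes` (annotation table),
#'   `freqs` (final frequencies) and `gene_sets` (named list of skewed
#'   gene-id sets, possibly empty).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- assign_gene_blocks(config)
  freqs <- simulate_allele_freqs(config)
  sk <- designate_skewed_sets(config, layout$gene_map, freqs)
  dataset <- simulate_genotypes(config, sk$freqs, layout$snp_table)
  structure(
    list(dataset = dataset, gene_map = layout$gene_map,
         genes = layout$genes, freqs = sk$freqs, gene_sets = sk$sets,
         config = config),
    class = "sim_panel"
  )
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("<sim_panel> ", nrow(x$dataset$genotypes), " animals, ",
      ncol(x$dataset$genotypes), " SNP, ", nrow(x$genes), " genes",
      if (length(x$gene_sets))
        paste0("; skewed sets: ", paste(names(x$gene_sets), collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Write a simulated panel to disk
#'
#' Writes PLINK text genotypes (both PED/MAP and TPED/TFAM dialects), the
#' gene annotation as BED, the breed/lineage table and one gene-list TSV
#' per skewed set, so the panel can be re-read through the package's
#' standard readers.
#'
#' @param panel a [simulate_panel()] result.
#' @param dir output directory (created if needed).
#' @param prefix basename for the PLINK files.
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir, prefix = "panel") {
  stopifnot(inherits(panel, "sim_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_plink(panel$dataset, file.path(dir, prefix), dialect = "ped")
  write_plink(panel$dataset, file.path(dir, prefix), dialect = "tped")
  write_bed_annotation(panel$genes, file.path(dir, paste0(prefix, "_genes.bed")))
  write_breed_table(panel$dataset$breed_table,
                    file.path(dir, paste0(prefix, "_breeds.tsv")))
  for (nm in names(panel$gene_sets)) {
    write_gene_list(panel$gene_sets[[nm]],
                    file.path(dir, paste0(prefix, "_set_", nm, ".tsv")))
  }
  invisible(dir)
}
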
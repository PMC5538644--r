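# Shared synthetic panels and cached per-seed summary metrics.  Panels are
# generated once per test run and reused across test files.

.panel_cache <- new.env(parent = emptyenv())

# Six-breed structure panel: 2 pure indicine, 2 pure taurine, 2 half-and-
# half composites, 200 animals each.
breeds6 <- function(n_animals = 200L) {
  data.frame(
    breed_id  = c("BI1", "BI2", "BT1", "BT2", "XC1", "XC2"),
    lineage   = c("BI", "BI", "BT", "BT", "BTI", "BTI"),
    ancestry  = c(1, 1, 0, 0, 0.5, 0.5),
    n_animals = n_animals,
    stringsAsFactors = FALSE
  )
}

structure_panel <- function(seed, n_animals = 200L, fst = 0.2) {
  simulate_panel(sim_config(n_snp = 3600, n_genes = 500, fst = fst,
                            breeds = breeds6(n_animals), seed = seed))
}

# Per-seed structure-recovery metrics used by several tests: PC1-ancestry
# correlation, lineage ARI of the breed dendrogram, inverted-V indicator
# and the gene-level HET vs indicine-content correlation within BT.
structure_metrics <- function(seeds = 1:10) {
  key <- paste0("metrics_", paste(range(seeds), collapse = "_"))
  if (!is.null(.panel_cache[[key]])) return(.panel_cache[[key]])
  rows <- lapply(seeds, function(s) {
    panel <- structure_panel(s)
    ds <- panel$dataset
    gmap <- filter_genes_by_snp_count(
      map_snp_to_genes(ds, panel$genes), "median")
    X <- suppressWarnings(standardize_genotypes(ds))
    lin <- ds$breed_table$lineage[match(ds$animal_table$breed_id,
                                        ds$breed_table$breed_id)]
    pca <- run_pca(X, k = 2, orient_negative = which(lin == "BI"))
    r_pc1 <- abs(cor(pca$scores[, 1], ds$animal_table$ancestry_true))
    ht <- compute_het(ds, gmap)
    cl <- cluster_breeds(ht$gene_het)
    k3 <- cutree(cl$hclust, k = 3)
    truth <- ds$breed_table$lineage[match(names(k3),
                                          ds$breed_table$breed_id)]
    ari <- mclust::adjustedRandIndex(k3, truth)
    bm <- colMeans(ht$gene_het, na.rm = TRUE)
    inv_v <- min(bm[c("XC1", "XC2")]) >
      max(bm[c("BI1", "BI2", "BT1", "BT2")])
    mix <- fit_mixture(pca$loadings[, 1])
    ga <- gene_ancestry(mix, gmap)
    bt <- ht$lineage_het[match(ga$gene_id, rownames(ht$lineage_het)), "BT"]
    data.frame(seed = s, r_pc1 = r_pc1, ari = ari, inv_v = inv_v,
               cor_bt = cor(bt, ga$pr_indicine, use = "complete.obs"))
  })
  out <- do.call(rbind, rows)
  .panel_cache[[key]] <- out
  out
}

# Minimal hand-written dataset: 4 animals, 2 breeds, 3 SNP.
tiny_dataset <- function() {
  geno <- rbind(c(0L, 1L, 2L),
                c(1L, 1L, 2L),
                c(2L, 0L, 1L),
                c(1L, 0L, 0L))
  snp <- data.frame(snp_id = c("s1", "s2", "s3"), chrom = c(1L, 1L, 2L),
                    pos = c(100L, 5000L, 200L),
                    allele_minor = "B", allele_major = "A",
                    stringsAsFactors = FALSE)
  animals <- data.frame(animal_id = c("a1", "a2", "b1", "b2"),
                        breed_id = c("X", "X", "Y", "Y"),
                        stringsAsFactors = FALSE)
  breeds <- data.frame(breed_id = c("X", "Y"), lineage = c("BI", "BT"),
                       stringsAsFactors = FALSE)
  genotype_dataset(geno, snp, animals, breeds)
}
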
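test_that("configuration invariants are enforced", {
  expect_error(sim_config(fst = 0), "fst")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(n_snp = 100, n_genes = 100), "6 \\* n_genes")
  expect_error(sim_config(ancestral_maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(ancestral_maf_range = c(0.1, 0.6)), "maf_range")
  bad <- default_breeds()
  bad$ancestry[bad$lineage == "BT"][1] <- 0.2
  expect_error(sim_config(breeds = bad), "inconsistent with lineage")
  expect_error(
    sim_config(n_genes = 100,
               skewed_sets = data.frame(set_name = "s", n_genes = 101L,
                                        target = "taurine")),
    "more genes")
})

test_that("allele frequencies follow the divergence model", {
  # degenerate maf range pins the ancestral frequency at 0.5
  cfg <- sim_config(n_snp = 600, n_genes = 100,
                    ancestral_maf_range = c(0.5, 0.5), seed = 1)
  fr <- simulate_allele_freqs(cfg)
  expect_true(all(fr$p_ancestral == 0.5))

  # vanishing divergence: subspecies frequencies collapse onto the
  # ancestral value
  cfg0 <- sim_config(n_snp = 2000, n_genes = 300, fst = 1e-4, seed = 2)
  fr0 <- simulate_allele_freqs(cfg0)
  expect_lt(max(abs(fr0$p_indicine - fr0$p_ancestral)), 0.05)
  expect_lt(max(abs(fr0$p_taurine - fr0$p_ancestral)), 0.05)

  # frequencies stay clamped inside (0, 1)
  cfgb <- sim_config(n_snp = 2000, n_genes = 300, fst = 0.9, seed = 3)
  frb <- simulate_allele_freqs(cfgb)
  expect_true(all(frb$p_indicine > 0 & frb$p_indicine < 1))
  expect_true(all(frb$p_taurine > 0 & frb$p_taurine < 1))
})

test_that("realised divergence matches the Weir-Cockerham estimate", {
  cfg <- sim_config(n_snp = 10000, n_genes = 1000, fst = 0.2,
                    breeds = data.frame(breed_id = c("P1", "P2"),
                                        lineage = c("BI", "BT"),
                                        ancestry = c(1, 0),
                                        n_animals = 500L),
                    seed = 11)
  panel <- simulate_panel(cfg)
  G <- panel$dataset$genotypes
  b <- panel$dataset$animal_table$breed_id
  g1 <- G[b == "P1", ]; g2 <- G[b == "P2", ]
  est <- wc_fst(colMeans(g1) / 2, colMeans(g2) / 2,
                colMeans(g1 == 1), colMeans(g2 == 1), 500, 500)
  expect_lt(abs(est - 0.2), 0.03)

  # pure-breed sample frequencies recover the subspecies frequencies;
  # account for the panel-wide minor-allele recoding
  fr <- panel$freqs[match(panel$dataset$snp_table$snp_id,
                          sprintf("snp%06d", seq_len(cfg$n_snp))), ]
  flipped <- panel$dataset$snp_table$allele_minor == "A"
  pI <- ifelse(flipped, 1 - fr$p_indicine, fr$p_indicine)
  pT <- ifelse(flipped, 1 - fr$p_taurine, fr$p_taurine)
  expect_lt(max(abs(colMeans(g1) / 2 - pI)), 0.08)  # worst single SNP
  expect_lt(mean(abs(colMeans(g1) / 2 - pI)), 0.03)
  expect_lt(mean(abs(colMeans(g2) / 2 - pT)), 0.03)
})

test_that("gene block layout has the required structure", {
  cfg <- sim_config(n_snp = 100, n_genes = 10, n_chromosomes = 3, seed = 1)
  lay <- assign_gene_blocks(cfg)
  counts <- snp_counts(lay$gene_map)
  expect_length(counts, 10L)
  expect_true(all(counts >= 6L))
  expect_gt(sum(is.na(lay$snp_table$gene_id)), 0)   # decoys exist
  # positions strictly increasing within each chromosome
  for (ch in unique(lay$snp_table$chrom)) {
    pos <- lay$snp_table$pos[lay$snp_table$chrom == ch]
    expect_true(all(diff(pos) > 0))
  }
  # decoys are more than 1 kb from every gene span
  dec <- lay$snp_table[is.na(lay$snp_table$gene_id), ]
  for (i in seq_len(nrow(dec))) {
    g <- lay$genes[lay$genes$chrom == dec$chrom[i], ]
    expect_true(all(dec$pos[i] < g$start - 1000 | dec$pos[i] > g$end + 1000))
  }
  # layout is deterministic (no RNG involved)
  expect_identical(lay$snp_table, assign_gene_blocks(cfg)$snp_table)
})

test_that("gene spans survive a BED round trip", {
  cfg <- sim_config(n_snp = 120, n_genes = 15, seed = 5)
  lay <- assign_gene_blocks(cfg)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed_annotation(lay$genes, path)
  back <- read_bed_annotation(path)
  expect_equal(back[, c("gene_id", "chrom", "start", "end")],
               lay$genes[, c("gene_id", "chrom", "start", "end")])
})

test_that("skewed sets are disjoint and rewrite the right frequencies", {
  sk <- data.frame(set_name = c("a", "b"), n_genes = c(20L, 30L),
                   target = c("taurine", "indicine"))
  cfg <- sim_config(n_snp = 700, n_genes = 100, skewed_sets = sk, seed = 4)
  lay <- assign_gene_blocks(cfg)
  fr <- simulate_allele_freqs(cfg)
  res <- designate_skewed_sets(cfg, lay$gene_map, fr)
  expect_named(res$sets, c("a", "b"))
  expect_length(res$sets$a, 20L)
  expect_length(intersect(res$sets$a, res$sets$b), 0L)
  snp_of <- split(lay$gene_map$assignment$snp_id,
                  lay$gene_map$assignment$gene_id)
  idx_a <- as.integer(sub("snp", "", unlist(snp_of[res$sets$a])))
  expect_true(all(res$freqs$p_taurine[idx_a] >= 0.35))
  expect_true(all(res$freqs$p_indicine[idx_a] <= 0.05))
  idx_b <- as.integer(sub("snp", "", unlist(snp_of[res$sets$b])))
  expect_true(all(res$freqs$p_indicine[idx_b] >= 0.35))

  # no sets requested -> nothing emitted, frequencies untouched
  cfg0 <- sim_config(n_snp = 700, n_genes = 100, seed = 4)
  res0 <- designate_skewed_sets(cfg0, lay$gene_map, fr)
  expect_length(res0$sets, 0L)
  expect_identical(res0$freqs, fr)
})

test_that("genotype simulation is reproducible and correctly coded", {
  cfg <- sim_config(n_snp = 400, n_genes = 60, seed = 9,
                    breeds = breeds6(30L))
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$dataset$genotypes, p2$dataset$genotypes)
  G <- p1$dataset$genotypes
  expect_true(all(G %in% 0:2))
  # minor-allele coding: no SNP has coded frequency above one half
  expect_true(all(colMeans(G) / 2 <= 0.5 + 1e-12))
})

test_that("a fixed difference at alpha 0.5 yields 50% heterozygosity under per-allele sampling", {
  # ancestry_dispersion = Inf gives every animal exactly alpha = 0.5 and
  # independent allele copies: one indicine + one taurine allele each with
  # probability 1/2 at a fixed difference, hence HET 50%
  cfg <- sim_config(n_snp = 600, n_genes = 100, fst = 0.5,
                    breeds = data.frame(breed_id = "X", lineage = "BTI",
                                        ancestry = 0.5, n_animals = 400L),
                    ancestry_dispersion = Inf, seed = 12)
  lay <- assign_gene_blocks(cfg)
  fr <- simulate_allele_freqs(cfg)
  fr$p_indicine <- rep(1 - 1e-9, nrow(fr))
  fr$p_taurine <- rep(1e-9, nrow(fr))
  ds <- simulate_genotypes(cfg, fr, lay$snp_table)
  expect_lt(abs(mean(ds$genotypes == 1L) - 0.5), 0.01)
})

test_that("missingness is applied at the configured MCAR rate", {
  cfg <- sim_config(n_snp = 600, n_genes = 100, missing_rate = 0.1,
                    breeds = breeds6(25L), seed = 6)
  G <- simulate_panel(cfg)$dataset$genotypes
  expect_lt(abs(mean(is.na(G)) - 0.1), 0.01)
})

test_that("admixture raises heterozygosity above both pure lineages", {
  # inverted-V analogue, asserted at moderate divergence
  for (s in 1:3) {
    panel <- structure_panel(s, n_animals = 100L, fst = 0.15)
    ht <- compute_het(panel$dataset, panel$gene_map)
    bm <- colMeans(ht$gene_het, na.rm = TRUE)
    expect_gt(min(bm[c("XC1", "XC2")]),
              max(bm[c("BI1", "BI2", "BT1", "BT2")]))
  }
})
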
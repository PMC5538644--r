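test_that("standardization matches the closed form and centres columns", {
  # p = 0.5: genotypes {0,1,2} map to {-sqrt(2)/1, 0, +sqrt(2)}/... = -2/sqrt(2), 0, 2/sqrt(2)
  G <- matrix(c(0L, 1L, 2L, 2L, 1L, 0L), 3, 2,
              dimnames = list(NULL, c("s1", "s2")))
  X <- standardize_genotypes(G)
  expect_equal(X[, "s1"], c(-1, 0, 1) * 2 / sqrt(2), tolerance = 1e-12)
  expect_lt(max(abs(colMeans(X))), 1e-10)

  # monomorphic SNP are dropped with a warning naming the count
  Gm <- cbind(G, s3 = c(0L, 0L, 0L))
  expect_warning(Xm <- standardize_genotypes(Gm), "1 monomorphic")
  expect_identical(colnames(Xm), c("s1", "s2"))
  expect_identical(attr(Xm, "dropped"), "s3")
  expect_error(standardize_genotypes(matrix(2L, 3, 2)), "monomorphic")
})

test_that("PCA contracts hold and duplicate animals coincide", {
  panel <- structure_panel(3, n_animals = 30L)
  X <- suppressWarnings(standardize_genotypes(panel$dataset))
  pca <- run_pca(X, k = 5)
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  expect_lte(sum(pca$var_explained), 1 + 1e-8)
  # component scores are uncorrelated
  cv <- crossprod(pca$scores)
  off <- abs(cv[upper.tri(cv)])
  expect_lt(max(off / max(diag(cv))), 1e-8)
  # loadings are unit-normalized
  expect_equal(unname(colSums(pca$loadings^2)), rep(1, 5), tolerance = 1e-8)

  # duplicated animal rows receive identical scores
  Xd <- rbind(X, X[7, ])
  pcad <- run_pca(Xd, k = 2)
  expect_equal(unname(pcad$scores[nrow(Xd), ]), unname(pcad$scores[7, ]),
               tolerance = 1e-8)

  expect_error(run_pca(X, k = nrow(X) + 1), "k must be")
})

test_that("PC1 tracks true ancestry and is oriented indicine-negative", {
  panel <- structure_panel(1, n_animals = 100L)
  ds <- panel$dataset
  X <- suppressWarnings(standardize_genotypes(ds))
  lin <- ds$breed_table$lineage[match(ds$animal_table$breed_id,
                                      ds$breed_table$breed_id)]
  pca <- run_pca(X, k = 2, orient_negative = which(lin == "BI"))
  expect_gte(abs(cor(pca$scores[, 1], ds$animal_table$ancestry_true)), 0.99)
  expect_lt(mean(pca$scores[lin == "BI", 1]), 0)
  expect_gt(mean(pca$scores[lin == "BT", 1]), 0)
})

test_that("EM recovers a well-separated two-component mixture", {
  set.seed(101)
  n <- 20000
  z <- runif(n) < 0.31
  x <- ifelse(z, rnorm(n, -1, 0.2), rnorm(n, 1, 0.2))
  f <- fit_mixture(x)
  expect_lt(max(abs(f$pi - c(0.31, 0.69))), 0.02)
  expect_lt(max(abs(f$mu - c(-1, 1))), 0.02)
  expect_true(f$converged)
  # log-likelihood trace is non-decreasing (EM guarantee)
  expect_true(all(diff(f$loglik) >= -1e-6 * abs(f$loglik[-1])))
  # cross-check the attained log-likelihood against an independent fitter
  suppressMessages(library(mclust))
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(abs(f$loglik[f$n_iter] - mc$loglik) / abs(mc$loglik), 1e-4)
})

test_that("mixture posteriors respect symmetry and labelling conventions", {
  # equal-variance symmetric mixture: posterior at the mean midpoint is
  # exactly 1/2
  sym <- structure(list(pi = c(0.5, 0.5), mu = c(-1, 1),
                        sigma2 = c(0.04, 0.04)),
                   class = "mixture_ancestry")
  expect_equal(unname(predict(sym, 0)[, "m1"]), 0.5, tolerance = 1e-12)

  set.seed(7)
  x <- c(rnorm(4000, -1, 0.3), rnorm(4000, 1, 0.3))
  f <- fit_mixture(x)
  # component 1 is the smaller-mean (indicine) component
  expect_lt(f$mu[1], f$mu[2])
  # posteriors sum to one
  expect_lt(max(abs(rowSums(f$posterior) - 1)), 1e-12)

  # permutation invariance of the fit
  set.seed(8)
  f2 <- fit_mixture(sample(x))
  expect_equal(f$mu, f2$mu, tolerance = 1e-6)
  expect_equal(f$pi, f2$pi, tolerance = 1e-6)

  # sign flip relabels the components consistently
  f3 <- fit_mixture(-x)
  expect_equal(f3$mu, -rev(f$mu), tolerance = 1e-6)
  expect_equal(f3$pi, rev(f$pi), tolerance = 1e-6)

  expect_error(fit_mixture(rep(1, 10)), "distinct")
})

test_that("gene ancestry is the mean of SNP posteriors", {
  gm <- gene_map(
    data.frame(gene_id = c("g1", "g2"), chrom = 1L,
               start = c(1L, 100L), end = c(10L, 110L)),
    data.frame(gene_id = c("g1", "g1", "g2"),
               snp_id = c("s1", "s2", "s3")))
  mix <- structure(list(posterior = cbind(m1 = c(s1 = 0.9, s2 = 0.7, s3 = 1),
                                          m2 = c(0.1, 0.3, 0))),
                   class = "mixture_ancestry")
  ga <- gene_ancestry(mix, gm)
  expect_equal(ga$pr_indicine[ga$gene_id == "g1"], 0.8)
  # a gene whose every SNP is fully indicine reaches membership 1
  expect_equal(ga$pr_indicine[ga$gene_id == "g2"], 1)
  expect_equal(ga$pr_indicine + ga$pr_taurine, rep(1, 2))

  # genes with no scored SNP are dropped with a warning
  gm2 <- gene_map(rbind(gm$genes,
                        data.frame(gene_id = "g3", chrom = 1L,
                                   start = 200L, end = 210L)),
                  rbind(gm$assignment,
                        data.frame(gene_id = "g3", snp_id = "s9")))
  expect_warning(ga2 <- gene_ancestry(mix, gm2), "no SNP with a posterior")
  expect_false("g3" %in% ga2$gene_id)
})

test_that("membership selection produces disjoint extreme lists", {
  ga <- data.frame(gene_id = c("a", "b", "c"),
                   pr_indicine = c(0.96, 0.94, 0.50),
                   pr_taurine = c(0.04, 0.06, 0.50))
  sel <- select_by_membership(ga, 0.95)
  expect_identical(sel$indicine, "a")
  expect_identical(sel$taurine, character(0))
  expect_length(intersect(sel$indicine, sel$taurine), 0L)
  # cutoff 1 keeps exact members only
  ga$pr_indicine[1] <- 1; ga$pr_taurine[1] <- 0
  expect_identical(select_by_membership(ga, 1)$indicine, "a")
  expect_error(select_by_membership(ga, 0.5), "cutoff")
})

test_that("negative-log profiles flag the opposing component", {
  ga <- data.frame(gene_id = c("a", "b", "c"),
                   pr_indicine = c(1 - 1e-5, 0.5, 0),
                   pr_taurine = c(1e-5, 0.5, 1))
  nlp <- neglogp_profile(ga, base = 10, flag_threshold = 4)
  expect_equal(nlp$neglogp_indicine[1], 5, tolerance = 1e-9)
  expect_true(nlp$flag_indicine[1])
  expect_equal(nlp$neglogp_indicine[2], log10(2), tolerance = 1e-12)
  expect_false(nlp$flag_indicine[2])
  expect_equal(nlp$neglogp_indicine[3], 0)
  # a zero posterior is floored, not infinite
  expect_true(is.finite(nlp$neglogp_taurine[3]))
})

test_that("chromosome ancestry averages genes and preserves the genome mean", {
  gm <- gene_map(
    data.frame(gene_id = c("g1", "g2", "g3"), chrom = c(1L, 1L, 2L),
               start = 1L, end = 2L),
    data.frame(gene_id = c("g1", "g2", "g3"),
               snp_id = c("s1", "s2", "s3")))
  ga <- data.frame(gene_id = c("g1", "g2", "g3"),
                   pr_indicine = c(0.2, 0.4, 0.9),
                   pr_taurine = c(0.8, 0.6, 0.1))
  ca <- chromosome_ancestry(ga, gm)
  expect_equal(ca$pr_indicine[ca$chrom == 1], 0.3)
  expect_equal(ca$pr_indicine[ca$chrom == 2], 0.9)
  # gene-count weighted chromosome mean equals the genome-wide mean
  expect_equal(sum(ca$pr_indicine * ca$n_genes) / sum(ca$n_genes),
               mean(ga$pr_indicine))
})

test_that("designed fixed-difference genes are assigned the right component", {
  # genes built on strongly differentiated SNP must come out with
  # membership near 0 or 1, concordant with which allele is common in
  # which subspecies
  sk <- data.frame(set_name = c("tset", "iset"), n_genes = c(40L, 40L),
                   target = c("taurine", "indicine"))
  panel <- simulate_panel(sim_config(n_snp = 2500, n_genes = 350,
                                     fst = 0.2, breeds = breeds6(80L),
                                     skewed_sets = sk, seed = 31))
  ds <- panel$dataset
  X <- suppressWarnings(standardize_genotypes(ds))
  lin <- ds$breed_table$lineage[match(ds$animal_table$breed_id,
                                      ds$breed_table$breed_id)]
  pca <- run_pca(X, k = 2, orient_negative = which(lin == "BI"))
  ga <- gene_ancestry(fit_mixture(pca$loadings[, 1]), panel$gene_map)
  tau <- ga$pr_taurine[ga$gene_id %in% panel$gene_sets$tset]
  ind <- ga$pr_indicine[ga$gene_id %in% panel$gene_sets$iset]
  expect_gte(mean(tau > 0.5), 0.95)
  expect_gte(mean(ind > 0.5), 0.95)
})
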
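test_that("HET profile correlations match the closed form", {
  m <- rbind(gx = c(1, 2, 3), gy = c(1, 2, 4), gz = c(3, 2, 1))
  colnames(m) <- c("B1", "B2", "B3")
  r <- correlation_matrix(m)
  expect_equal(r["gx", "gy"], 0.9820, tolerance = 5e-5)
  expect_equal(r["gx", "gz"], -(1 - 1e-12), tolerance = 1e-13)
  expect_equal(unname(diag(r)), rep(1, 3))
  # identical profiles hit the clip bound just inside 1
  m2 <- rbind(m, gw = c(1, 2, 3))
  r2 <- correlation_matrix(m2)
  expect_lt(r2["gx", "gw"], 1)
  expect_gt(r2["gx", "gw"], 1 - 1e-10)

  expect_error(correlation_matrix(m[, 1:2]), "3 breeds")
  m3 <- rbind(m, flat = c(2, 2, 2))
  expect_warning(r3 <- correlation_matrix(m3), "zero-variance")
  expect_false("flat" %in% rownames(r3))
})

test_that("first-order partial correlation follows its formula", {
  expect_equal(partial_correlation(0.5, 0.5, 0.5), 1 / 3)
  expect_equal(partial_correlation(0.9, 0.9, 0.9), 0.09 / 0.19)
  # independent third variable leaves the correlation unchanged
  expect_equal(partial_correlation(0.42, 0, 0), 0.42)
  expect_error(partial_correlation(1, 0.5, 0.5), "strictly")
})

test_that("PCIT agrees with the naive triple-loop oracle", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(5:20, 1)
    X <- matrix(rnorm(30 * n), 30, n)
    r <- cor(X)
    lim <- 1 - 1e-12
    r[r > lim] <- lim; r[r < -lim] <- -lim; diag(r) <- 1
    expect_identical(unname(pcit(r)), unname(pcit_oracle(r)))
  }
})

test_that("PCIT hand examples and invariances hold", {
  # equicorrelated trio at 0.9: eps*0.9 = 0.4737 < 0.9, all edges kept
  r <- matrix(0.9, 3, 3); diag(r) <- 1
  sig <- pcit(r)
  expect_identical(sum(sig), 6L)
  # independent third gene: edge (x, y) trivially kept
  r2 <- diag(3); r2[1, 2] <- r2[2, 1] <- 0.6
  expect_true(pcit(r2)[1, 2])
  # symmetry and permutation invariance
  set.seed(1)
  X <- matrix(rnorm(200), 20, 10)
  rr <- cor(X); diag(rr) <- 1
  s <- pcit(rr)
  expect_identical(s, t(s))
  perm <- sample(10)
  expect_identical(unname(pcit(rr[perm, perm])), unname(s[perm, perm]))
  expect_error(pcit(rr[1:2, 1:2]), "at least 3")
})

test_that("PCIT prunes the indirect edge of an averaged profile", {
  # gene A's profile is the average of B and C plus small noise: over
  # repeated draws the B-C edge (the indirect one) must be pruned more
  # often than the direct A-B / A-C edges
  set.seed(77)
  drop_bc <- 0L; drop_direct <- 0L
  for (i in 1:100) {
    b <- rnorm(10); c <- rnorm(10)
    a <- (b + c) / 2 + rnorm(10, sd = 0.05)
    prof <- rbind(A = a, B = b, C = c)
    r <- suppressWarnings(correlation_matrix(prof))
    s <- pcit(r)
    drop_bc <- drop_bc + !s["B", "C"]
    drop_direct <- drop_direct + !s["A", "B"] + !s["A", "C"]
  }
  expect_gt(drop_bc, drop_direct / 2)
})

test_that("network assembly applies the absolute threshold and drops isolates", {
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- 0.96
  r[1, 3] <- r[3, 1] <- 0.90
  r[2, 3] <- r[3, 2] <- -0.97
  dimnames(r) <- list(letters[1:4], letters[1:4])
  sig <- matrix(TRUE, 4, 4); diag(sig) <- FALSE
  net <- build_network(r, sig, threshold = 0.95)
  expect_identical(nrow(net$edges), 2L)           # |r| rule keeps -0.97
  expect_false("d" %in% net$nodes$gene_id)        # isolated node dropped
  # threshold 0 reduces to the significance graph
  net0 <- build_network(r, sig, threshold = 0)
  expect_identical(nrow(net0$edges), 6L)
  # monotonicity: raising the threshold never adds edges
  for (thr in c(0, 0.5, 0.9, 0.95, 0.99)) {
    expect_lte(nrow(build_network(r, sig, thr)$edges), nrow(net0$edges))
  }
})

test_that("degree diagnostics identify hubs and exact power laws", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "a", "b", "c", "d")
  net <- structure(list(nodes = data.frame(gene_id = igraph::V(star)$name),
                        edges = NULL, threshold = 0, graph = star),
                   class = "cohet_network")
  dd <- degree_diagnostics(net)
  expect_identical(dd$hubs, "hub")
  expect_identical(dd$degrees$degree[1], 4L)

  # exact power law freq(k) = 64 k^-2 over k in {1,2,4,8}
  degs <- rep(c(1L, 2L, 4L, 8L), times = c(64L, 16L, 4L, 1L))
  fit <- scale_free_fit(degs)
  expect_equal(fit$r, -1)
  expect_equal(fit$slope, -2, tolerance = 1e-12)

  expect_warning(out <- scale_free_fit(rep(3L, 5)), "distinct")
  expect_null(out)
})

test_that("trio coverage is exact on the star and two-triangle fixtures", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("h", "a", "b", "c", "d")
  res <- trio_span_search(star, c("h", "a", "b"), method = "exhaustive")
  expect_equal(res$coverage, 1)
  expect_identical(sort(res$trio), c("a", "b", "h"))

  tt <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("b", "c"), c("a", "c"),
          c("d", "e"), c("e", "f"), c("d", "f")), directed = FALSE)
  res2 <- trio_span_search(tt, c("a", "b", "c"), method = "exhaustive")
  expect_equal(res2$coverage, 3 / 6)

  expect_error(trio_span_search(star, c("h", "a")), "at least 3")
})

test_that("greedy and exhaustive trio searches agree on random graphs", {
  set.seed(9)
  for (i in 1:30) {
    g <- igraph::sample_gnp(25, 0.15)
    igraph::V(g)$name <- sprintf("g%02d", 1:25)
    fe <- sample(igraph::V(g)$name, 8)
    ex <- trio_span_search(g, fe, method = "exhaustive")
    gr <- trio_span_search(g, fe, method = "greedy")
    expect_equal(gr$coverage, ex$coverage)
    # and both agree with the independent enumeration oracle
    or <- trio_oracle(g, fe)
    expect_equal(ex$coverage, or$coverage)
  }
})
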
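#' Default pipeline configuration
#'
#' Nested list with one block per stage; values mirror the method's
#' standard settings: 1 kb gene window, median SNP-count gene filter, HWE
#' alpha 0.01, membership cutoff 0.95, 10,000 permutation trials, network
#' correlation threshold 0.95, `-log10` profiles flagged above 4.  The
#' `simulate` block holds [sim_config()] arguments; replace it with an
#' `input` block (`plink_prefix`, `dialect`, `breed_table`, `bed`,
#' optional `gene_sets` name->path list) to run on genotypes read from
#' disk.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(),
    input = NULL,
    preprocess = list(autosomes = NULL, window_bp = 1000, min_snp = "median"),
    ancestry = list(k = 10, cutoff = 0.95, log_base = 10, flag_threshold = 4),
    het = list(alpha = 0.01, min_frac = 0),
    geneset = list(n_perm = 10000, threshold = 0.5),
    network = list(threshold = 0.95, fe_set = NULL)
  )
}

# Deep-merge user config over defaults.
merge_config <- function(user, defaults = default_config()) {
  if (is.null(user)) return(defaults)
  utils::modifyList(defaults, user)
}

# YAML represents tables as lists of records; rebuild data frames.
records_to_df <- function(x) {
  if (is.data.frame(x) || !is.list(x) || !length(x)) return(x)
  if (!all(vapply(x, is.list, TRUE))) return(x)
  do.call(rbind, lapply(x, as.data.frame, stringsAsFactors = FALSE))
}

#' Run the full co-heterozygosity pipeline
#'
#' Executes the six analysis stages in order -- input (simulated or read
#' from disk), preprocessing, ancestry, heterozygosity/HWE, gene-set
#' testing and network inference -- writing each stage's tables under
#' `out_dir` together with a deterministic `manifest.json`.  All
#' randomness derives from `seed`, so re-running with the same
#' configuration and seed reproduces every output byte for byte.
#'
#' @param config configuration list (see [default_config()]) or path to a
#'   YAML file with the same structure; missing entries fall back to the
#'   defaults.
#' @param out_dir output directory, created if needed.
#' @param seed integer seed; overrides `config$seed` when given.
#' @param resume if `TRUE`, stages whose cached state (saved under
#'   `out_dir/state/`) matches the current configuration and seed are
#'   reloaded instead of recomputed.
#' @return (invisibly) list of class `cohet_run` with the main in-memory
#'   results: `dataset`, `gene_map`, `pca`, `mixture`, `gene_ancestry`,
#'   `selection`, `het`, `hwe_genes`, `clustering`, `geneset_results`,
#'   `network`, `degree`, `trio`, `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL,
                         resume = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("stage input: config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  config <- merge_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  config$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state_dir <- file.path(out_dir, "state")
  dir.create(state_dir, showWarnings = FALSE)
  cfg_key <- digest_config(config)

  stage <- function(name, code) {
    cache <- file.path(state_dir, paste0(name, ".rds"))
    if (resume && file.exists(cache)) {
      st <- readRDS(cache)
      if (identical(st$key, cfg_key)) return(st$value)
    }
    value <- tryCatch(force(code), error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
    saveRDS(list(key = cfg_key, value = value), cache)
    value
  }

  ## stage 1: input
  inp <- stage("input", {
    if (!is.null(config$input)) {
      i <- config$input
      for (f in c(paste0(i$plink_prefix, ".",
                         if ((i$dialect %||% "ped") == "ped") c("ped", "map")
                         else c("tped", "tfam")),
                  i$bed,
                  if (is.character(i$breed_table)) i$breed_table)) {
        if (!file.exists(f)) stop("input file not found: ", f)
      }
      dataset <- read_plink(i$plink_prefix, i$breed_table,
                            dialect = i$dialect %||% "ped")
      annotation <- read_bed_annotation(i$bed)
      gene_sets <- lapply(i$gene_sets %||% list(), read_gene_list)
      checks <- tools::md5sum(c(paste0(i$plink_prefix, ".",
                                       if ((i$dialect %||% "ped") == "ped")
                                         c("ped", "map") else c("tped", "tfam")),
                                i$bed))
      list(dataset = dataset, annotation = annotation,
           gene_sets = gene_sets, checksums = as.list(checks))
    } else {
      sim <- config$simulate
      sim$breeds <- records_to_df(sim$breeds %||% NULL) %||% default_breeds()
      sim$skewed_sets <- records_to_df(sim$skewed_sets %||% NULL) %||%
        empty_skewed_sets()
      sim$seed <- seed
      panel <- simulate_panel(do.call(sim_config, sim))
      list(dataset = panel$dataset, annotation = panel$genes,
           gene_sets = panel$gene_sets, checksums = list())
    }
  })

  ## stage 2: preprocess
  pp <- stage("preprocess", {
    autos <- config$preprocess$autosomes %||%
      unique(inp$dataset$snp_table$chrom)
    ds <- filter_autosomal(inp$dataset, autos)
    gmap <- map_snp_to_genes(ds, inp$annotation,
                             window_bp = config$preprocess$window_bp)
    gmap <- filter_genes_by_snp_count(gmap, config$preprocess$min_snp)
    list(dataset = ds, gene_map = gmap)
  })
  ds <- pp$dataset; gmap <- pp$gene_map

  ## stage 3: ancestry
  anc <- stage("ancestry", {
    X <- standardize_genotypes(ds)
    k <- min(config$ancestry$k, nrow(X) - 1L, ncol(X))
    lin <- ds$breed_table$lineage[match(ds$animal_table$breed_id,
                                        ds$breed_table$breed_id)]
    bi <- which(lin == "BI")
    pca <- run_pca(X, k = k,
                   orient_negative = if (length(bi)) bi else NULL)
    mixture <- fit_mixture(pca$loadings[, 1])
    ga <- gene_ancestry(mixture, gmap)
    sel <- select_by_membership(ga, config$ancestry$cutoff)
    nlp <- neglogp_profile(ga, base = config$ancestry$log_base,
                           flag_threshold = config$ancestry$flag_threshold)
    ca <- chromosome_ancestry(ga, gmap)
    list(pca = pca, mixture = mixture, gene_ancestry = ga, selection = sel,
         neglogp = nlp, chrom_ancestry = ca)
  })

  ## stage 4: heterozygosity / HWE / clustering
  het <- stage("het", {
    ht <- compute_het(ds, gmap)
    hwe <- hwe_test(ds)
    dev <- genes_deviating_hwe(hwe, gmap, alpha = config$het$alpha,
                               min_frac = config$het$min_frac)
    clus <- cluster_breeds(ht$gene_het)
    list(het = ht, hwe = hwe, deviating = dev, clustering = clus)
  })

  ## stage 5: gene sets
  gs <- stage("geneset", {
    res <- list()
    sets <- inp$gene_sets
    for (i in seq_along(sets)) {
      nm <- names(sets)[i]
      set_in_bg <- intersect(sets[[i]], anc$gene_ancestry$gene_id)
      if (!length(set_in_bg)) next
      res[[nm]] <- ancestry_permutation_test(
        anc$gene_ancestry, set_in_bg,
        n_perm = config$geneset$n_perm,
        threshold = config$geneset$threshold,
        seed = seed + 100L + i)
    }
    res
  })

  ## stage 6: network
  net <- stage("network", {
    fe <- if (!is.null(config$network$fe_set)) {
      inp$gene_sets[[config$network$fe_set]] %||% character()
    } else character()
    genes <- select_network_genes(het$deviating$union, anc$selection$indicine,
                                  anc$selection$taurine, fe)
    genes <- intersect(genes, rownames(het$het$gene_het))
    if (length(genes) < 3L) stop("fewer than 3 candidate network genes")
    R <- suppressWarnings(correlation_matrix(het$het$gene_het, genes))
    sig <- pcit(R)
    ga <- anc$gene_ancestry
    network <- build_network(R, sig, threshold = config$network$threshold,
                             node_attrs = ga[, c("gene_id", "pr_indicine")])
    dd <- degree_diagnostics(network)
    trio <- if (length(intersect(fe, network$nodes$gene_id)) >= 3L) {
      trio_span_search(network, fe)
    } else NULL
    list(candidates = genes, network = network, degree = dd, trio = trio)
  })

  write_pipeline_outputs(out_dir, config, inp, ds, gmap, anc, het, gs, net)

  invisible(structure(
    list(dataset = ds, gene_map = gmap, pca = anc$pca,
         mixture = anc$mixture, gene_ancestry = anc$gene_ancestry,
         selection = anc$selection, het = het$het,
         hwe_genes = het$deviating, clustering = het$clustering,
         geneset_results = gs, network = net$network, degree = net$degree,
         trio = net$trio, config = config, out_dir = out_dir),
    class = "cohet_run"
  ))
}

#' @export
print.cohet_run <- function(x, ...) {
  cat("<cohet_run> ", nrow(x$dataset$genotypes), " animals, ",
      length(unique(x$gene_ancestry$gene_id)), " genes analysed; network: ",
      nrow(x$network$nodes), " nodes / ", nrow(x$network$edges),
      " edges; outputs in ", x$out_dir, "\n", sep = "")
  invisible(x)
}

# Stable short fingerprint of the effective configuration (used by resume).
digest_config <- function(config) {
  paste(deparse(config), collapse = "")
}

write_pipeline_outputs <- function(out_dir, config, inp, ds, gmap, anc, het,
                                   gs, net) {
  j <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  adir <- file.path(out_dir, "ancestry")
  hdir <- file.path(out_dir, "het")
  gdir <- file.path(out_dir, "geneset")
  ndir <- file.path(out_dir, "network")
  for (d in c(adir, hdir, gdir, ndir)) {
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  }

  write_gene_ancestry_table(anc$gene_ancestry, het$het,
                            file.path(adir, "gene_ancestry.tsv"))
  j(list(pi = anc$mixture$pi, mu = anc$mixture$mu,
         sigma2 = anc$mixture$sigma2, n_iter = anc$mixture$n_iter,
         converged = anc$mixture$converged,
         loglik = anc$mixture$loglik[anc$mixture$n_iter],
         var_explained = anc$pca$var_explained),
    file.path(adir, "mixture.json"))
  write_tsv(anc$chrom_ancestry, file.path(adir, "chromosome_ancestry.tsv"))
  write_tsv(anc$neglogp, file.path(adir, "neglogp_profile.tsv"))
  write_gene_list(anc$selection$indicine,
                  file.path(adir, "selected_indicine.tsv"))
  write_gene_list(anc$selection$taurine,
                  file.path(adir, "selected_taurine.tsv"))

  gh <- het$het$gene_het
  write_tsv(data.frame(gene_id = rownames(gh), as.data.frame(gh),
                       check.names = FALSE, stringsAsFactors = FALSE),
            file.path(hdir, "gene_het.tsv"))
  lh <- het$het$lineage_het
  write_tsv(data.frame(gene_id = rownames(lh), as.data.frame(lh),
                       check.names = FALSE, stringsAsFactors = FALSE),
            file.path(hdir, "lineage_het.tsv"))
  ch <- het$het$chrom_het
  write_tsv(data.frame(chrom = rownames(ch), as.data.frame(ch),
                       check.names = FALSE, stringsAsFactors = FALSE),
            file.path(hdir, "chrom_het.tsv"))
  write_tsv(het$hwe, file.path(hdir, "hwe.tsv"))
  write_gene_list(het$deviating$union, file.path(hdir, "hwe_genes_union.tsv"))
  writeLines(het$clustering$newick, file.path(hdir, "breed_dendrogram.nwk"))

  if (length(gs)) {
    summ <- do.call(rbind, lapply(names(gs), function(nm) {
      r <- gs[[nm]]
      data.frame(set_name = nm, set_size = r$set_size,
                 n_background = r$n_background, observed = r$observed,
                 n_perm = r$n_perm, percentile = r$percentile,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(summ, file.path(gdir, "geneset_results.tsv"))
    j(lapply(gs, function(r) r[c("set_size", "n_background", "observed",
                                 "n_perm", "percentile")]),
      file.path(gdir, "geneset_results.json"))
  }

  write_network(net$network, ndir)
  write_tsv(net$degree$degrees, file.path(ndir, "degree.tsv"))
  j(list(n_nodes = nrow(net$network$nodes),
         n_edges = nrow(net$network$edges),
         threshold = net$network$threshold,
         n_candidates = length(net$candidates),
         scale_free = net$degree$fit,
         hubs = net$degree$hubs,
         trio = if (!is.null(net$trio))
           net$trio[c("trio", "coverage", "method")]),
    file.path(ndir, "network_summary.json"))

  j(list(package = "cohet",
         version = as.character(utils::packageVersion("cohet")),
         seed = config$seed,
         config = config,
         input_checksums = inp$checksums,
         n_animals = nrow(ds$genotypes),
         n_snp = ncol(ds$genotypes),
         n_genes = nrow(gmap$genes)),
    file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
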
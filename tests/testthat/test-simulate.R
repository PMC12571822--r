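small_pops <- function(n_lan = 60, n_mv = 30) {
  tibble::tibble(population = c("Xian", "Xian", "Geng", "Geng"),
                 variety_class = c("LAN", "MV", "LAN", "MV"),
                 n = c(n_lan, n_mv, n_lan, n_mv))
}

test_that("mutation trees are feasible, bounded and reproducible", {
  cfg <- sim_config(seed = 1, n_genes = 1, sites_per_gene = 3,
                    n_haps_per_gene = 4)
  hs <- simulate_haplotypes(cfg)$gene_1
  expect_equal(nrow(hs$tree), 3)
  expect_true(all(pairwise_steps(hs$vectors) <= 3))
  expect_equal(simulate_haplotypes(cfg)$gene_1, hs)      # same seed, same tree
  expect_error(sim_config(sites_per_gene = 3, n_haps_per_gene = 5),
               "infeasible")
})

test_that("tree path lengths equal Hamming distances (each site mutates once)", {
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, n_genes = 1, sites_per_gene = 10,
                      n_haps_per_gene = 8)
    hs <- simulate_haplotypes(cfg)$gene_1
    ## oracle: path length on the tree via BFS over the edge list
    adj <- lapply(1:8, function(i) integer())
    for (r in seq_len(nrow(hs$tree))) {
      a <- hs$tree$parent[r]; b <- hs$tree$child[r]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
    path_len <- function(a, b) {
      dist <- rep(NA_integer_, 8); dist[a] <- 0L; q <- a
      while (length(q)) {
        v <- q[1]; q <- q[-1]
        for (w in adj[[v]]) if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L; q <- c(q, w)
        }
      }
      dist[b]
    }
    d <- pairwise_steps(hs$vectors)
    for (i in 1:7) for (j in (i + 1):8) {
      expect_equal(d[i, j], path_len(i, j))
    }
    ## allele vectors are pairwise distinct by construction
    expect_equal(nrow(unique(hs$vectors)), 8)
  }
})

test_that("simulated fixtures parse with the package readers and match the truth", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 7, n_genes = 2, sites_per_gene = 6,
                    n_haps_per_gene = 5, populations = small_pops())
  sim <- simulate_panel(cfg, dir)
  v <- read_vcf(sim$paths$vcf)
  g <- read_gff3(sim$paths$gff)
  p <- read_panel(sim$paths$panel)
  tr <- read_traits(sim$paths$traits)
  expect_equal(nrow(v$sites), 12)
  expect_equal(v$samples, sim$panel$accession)
  expect_equal(dplyr::n_distinct(g$gene_id), 2)
  expect_equal(p, sim$panel)
  expect_equal(names(tr), c("accession", gchap_traits()$trait))
  ## site positions land inside the CDS models of their gene
  for (gi in 1:2) {
    gm <- g[g$gene_id == paste0("gene_", gi), ]
    pos <- sim$truth$site_positions[[gi]]
    expect_true(all(vapply(pos, function(x) any(x >= gm$start & x <= gm$end),
                           logical(1))))
  }
  ## the manifest is valid JSON holding the assignment
  man <- jsonlite::read_json(sim$paths$manifest, simplifyVector = TRUE)
  expect_equal(nrow(man$truth$assignment), nrow(sim$panel))
})

test_that("zero-noise simulations are recovered exactly by the caller", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 13, n_genes = 2, sites_per_gene = 7,
                    n_haps_per_gene = 6, populations = small_pops(),
                    het_rate = 0, missing_rate = 0)
  sim <- simulate_panel(cfg, dir)
  v <- read_vcf(sim$paths$vcf)
  g <- read_gff3(sim$paths$gff)
  p <- read_panel(sim$paths$panel)
  tabs <- call_gchap_tables(v, g, p)
  for (gi in 1:2) {
    x <- tabs[[paste0("gene_", gi)]]
    expect_equal(x$excluded_count, 0L)
    truth <- sim$truth$assignment[[paste0("gene_", gi)]]
    expect_true(same_partition(truth, x$assignment$hap_id))
  }
})

test_that("injected het/missing noise causes exclusions at the expected scale", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 5, n_genes = 1, sites_per_gene = 6,
                    n_haps_per_gene = 4, populations = small_pops(),
                    het_rate = 0.02, missing_rate = 0.02)
  sim <- simulate_panel(cfg, dir)
  tabs <- call_gchap_tables(read_vcf(sim$paths$vcf),
                            read_gff3(sim$paths$gff),
                            read_panel(sim$paths$panel))
  x <- tabs$gene_1
  expect_gt(x$excluded_count, 0)
  ## P(clean accession) = 0.96^6 ~ 0.78: exclusions stay near 22%
  expect_lt(x$excluded_count, nrow(sim$panel) * 0.45)
  expect_equal(sum(x$haps$count) + x$excluded_count, nrow(sim$panel))
})

test_that("per-gene streams are stable when the gene count changes", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg1 <- sim_config(seed = 3, n_genes = 1, populations = small_pops())
  cfg3 <- sim_config(seed = 3, n_genes = 3, populations = small_pops())
  s1 <- simulate_panel(cfg1, dir1)
  s3 <- simulate_panel(cfg3, dir2)
  expect_equal(s1$truth$assignment$gene_1, s3$truth$assignment$gene_1)
  expect_equal(s1$truth$haplotypes$gene_1, s3$truth$haplotypes$gene_1)
})

test_that("planted trait effects shift the affected haplotype group", {
  dir <- withr::local_tempdir()
  eff <- tibble::tibble(gene = 1L, hap = 1L, trait = "TGW", effect = 3)
  cfg <- sim_config(seed = 11, n_genes = 1, populations = small_pops(),
                    trait_effects = eff, trait_sd = 1)
  sim <- simulate_panel(cfg, dir)
  carriers <- sim$truth$assignment$gene_1 == 1L
  expect_gt(mean(sim$traits$TGW[carriers]) - mean(sim$traits$TGW[!carriers]),
            1.5)
})

test_that("strong drift reduces the modern-variety haplotype count", {
  ## direction check at one seed batch; the full-rate property runs in the
  ## acceptance suite
  hits <- 0L
  for (seed in 1:15) {
    dir <- withr::local_tempdir()
    cfg <- sim_config(seed = seed, n_genes = 1, sites_per_gene = 12,
                      n_haps_per_gene = 12, drift_strength = 0.8,
                      populations = small_pops(300, 150))
    sim <- simulate_panel(cfg, dir)
    tabs <- call_gchap_tables(read_vcf(sim$paths$vcf),
                              read_gff3(sim$paths$gff),
                              read_panel(sim$paths$panel))
    s_lan <- hap_spectrum(tabs$gene_1, "Xian", "LAN")
    s_mv <- hap_spectrum(tabs$gene_1, "Xian", "MV")
    hits <- hits + (length(s_mv) < length(s_lan))
  }
  expect_gte(hits, 13)
})
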
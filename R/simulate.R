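#' Configuration for the synthetic gcHap data generator
#'
#' Defines the study conditions the generator emulates: K populations with
#' distinct, skewed haplotype-frequency spectra; haplotypes related by a
#' mutation tree over CDS SNPs; landrace/modern-variety frequency drift;
#' and trait values with additive per-haplotype effects plus Gaussian
#' noise. The default panel composition mirrors the landrace/modern split
#' of the 3,010-accession rice panel: 732 Xian landraces, 358 modern Xian
#' varieties, 328 Geng landraces, 139 modern Geng varieties.
#'
#' @param seed Master RNG seed; each gene uses a derived stream so per-gene
#'   output is stable when `n_genes` changes.
#' @param n_genes Number of genes.
#' @param sites_per_gene CDS SNP sites per gene.
#' @param n_haps_per_gene Haplotypes per gene; the mutation tree mutates
#'   one new site per haplotype, so at most `sites_per_gene + 1`.
#' @param populations Tibble `population`, `variety_class`, `n` giving the
#'   panel composition.
#' @param dirichlet_alpha Dirichlet concentration for haplotype
#'   frequencies; the default 0.5 produces skewed spectra with a dominant
#'   Hap1, the structure seen in real panels.
#' @param drift_strength In \[0, 1\): how far MV frequencies are pulled from
#'   the LAN spectrum toward its dominant haplotype (mixture
#'   re-weighting), emulating the haplotype-count reduction of modern
#'   breeding. 0 means MV and LAN share a spectrum in expectation.
#' @param trait_effects Optional tibble `gene`, `hap`, `trait`, `effect`:
#'   additive effect (in trait units) of carrying haplotype `hap`
#'   (generation index, 1 = root) at gene `gene`.
#' @param trait_sd Residual standard deviation of the simulated traits.
#' @param het_rate,missing_rate Per-genotype-call noise rates in \[0, 1).
#' @param chromosome Chromosome name used for all genes.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_genes = 3, sites_per_gene = 8,
                       n_haps_per_gene = 6,
                       populations = default_sim_populations(),
                       dirichlet_alpha = 0.5, drift_strength = 0.3,
                       trait_effects = NULL, trait_sd = 1,
                       het_rate = 0, missing_rate = 0,
                       chromosome = "chr1") {
  stopifnot(is.data.frame(populations),
            all(c("population", "variety_class", "n") %in% names(populations)))
  check_vocab(populations$population, .POPULATIONS, .POP_ALIASES, "population")
  check_vocab(populations$variety_class, .CLASSES, .CLASS_ALIASES,
              "variety_class")
  if (any(populations$n < 0)) abort("population sizes must be >= 0")
  for (r in c(het_rate, missing_rate, drift_strength)) {
    if (r < 0 || r >= 1) abort("rates must lie in [0, 1)")
  }
  if (trait_sd <= 0) abort("trait_sd must be > 0")
  if (n_haps_per_gene < 1) abort("need at least one haplotype per gene")
  if (n_haps_per_gene > sites_per_gene + 1) {
    abort(paste0("infeasible config: the mutation tree mutates one new ",
                 "site per haplotype, so n_haps_per_gene (",
                 n_haps_per_gene, ") must be <= sites_per_gene + 1 (",
                 sites_per_gene + 1, ")"))
  }
  if (!is.null(trait_effects)) {
    stopifnot(all(c("gene", "hap", "trait", "effect") %in%
                    names(trait_effects)))
    check_vocab(trait_effects$trait, .TRAITS$trait, character(), "trait")
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         sites_per_gene = as.integer(sites_per_gene),
         n_haps_per_gene = as.integer(n_haps_per_gene),
         populations = as_tibble(populations),
         dirichlet_alpha = dirichlet_alpha,
         drift_strength = drift_strength,
         trait_effects = trait_effects, trait_sd = trait_sd,
         het_rate = het_rate, missing_rate = missing_rate,
         chromosome = chromosome),
    class = "sim_config")
}

#' @rdname sim_config
#' @export
default_sim_populations <- function() {
  tibble(
    population = c("Xian", "Xian", "Geng", "Geng"),
    variety_class = c("LAN", "MV", "LAN", "MV"),
    n = c(732L, 358L, 328L, 139L)
  )
}

#' Simulate haplotypes on a random mutation tree
#'
#' Per gene: the root haplotype is all-reference; each subsequent
#' haplotype copies a random existing parent and mutates one previously
#' unmutated site. Every site mutates exactly once, so allele vectors are
#' unique and the Hamming distance between any two haplotypes equals the
#' number of tree edges on the path between them — an exact ground truth
#' for the network builder.
#'
#' @param config A [sim_config()].
#' @return Named list (gene_1, ...); per gene a list with `vectors`
#'   (0/1 matrix, haplotypes x sites, rows in generation order) and `tree`
#'   (tibble `parent`, `child`, `site` of generation indices).
#' @export
simulate_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set_names(map(seq_len(config$n_genes), function(g) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_seed(old), add = TRUE)
    set.seed(derive_seed(config$seed, g))
    simulate_gene_tree(config$n_haps_per_gene, config$sites_per_gene)
  }), paste0("gene_", seq_len(config$n_genes)))
}

simulate_gene_tree <- function(n_haps, n_sites) {
  vectors <- matrix(0L, nrow = n_haps, ncol = n_sites)
  free_sites <- sample.int(n_sites)       # each site mutates once
  parent <- integer(0); child <- integer(0); site <- integer(0)
  for (h in seq_len(n_haps)[-1]) {
    p <- if (h == 2) 1L else sample.int(h - 1, 1)
    s <- free_sites[h - 1]
    vectors[h, ] <- vectors[p, ]
    vectors[h, s] <- 1L
    parent <- c(parent, p); child <- c(child, h); site <- c(site, s)
  }
  rownames(vectors) <- paste0("H", seq_len(n_haps))
  list(vectors = vectors,
       tree = tibble(parent = parent, child = child, site = site))
}

#' Simulate a complete input fixture on disk
#'
#' Writes a VCF 4.2, a GFF3 with gene/mRNA/CDS features (two CDS exons per
#' gene), a panel TSV, a phenotype TSV, and a JSON manifest holding the
#' resolved configuration and the ground truth (per-gene haplotype
#' frequencies, mutation trees, and the accession-to-haplotype
#' assignment) for test assertions.
#'
#' Per population, landrace haplotype frequencies are drawn from a
#' Dirichlet(`dirichlet_alpha`) distribution; modern-variety frequencies
#' are `(1 - d) * p_LAN + d * e_top` where `e_top` points at the dominant
#' landrace haplotype and `d = drift_strength`. Accessions draw their
#' haplotype multinomially; genotypes are written as homozygous diploid
#' calls with heterozygous/missing noise injected at the configured rates.
#' Trait values are the trait baseline plus the summed per-haplotype
#' effects plus Normal(0, `trait_sd`) noise.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file `paths` and the ground `truth`
#'   (assignment tibble, haplotype structures, frequency tables).
#' @export
simulate_panel <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  pops <- config$populations[config$populations$n > 0, , drop = FALSE]
  acc_n <- sum(pops$n)
  panel <- tibble(
    accession = sprintf("ACC%05d", seq_len(acc_n)),
    population = rep(pops$population, pops$n),
    variety_class = rep(pops$variety_class, pops$n)
  )

  haps <- simulate_haplotypes(config)
  genes <- map(seq_len(config$n_genes), function(g) {
    off <- 100000L * g
    tibble(gene_id = sprintf("gene_%d", g),
           chromosome = config$chromosome,
           strand = if (g %% 2 == 1) "+" else "-",
           start = c(off + 101L, off + 901L),
           end = c(off + 700L, off + 1500L))
  }) |> list_rbind()

  ## per-gene: site positions, per-population-class frequencies, assignment
  truth_assign <- matrix(NA_integer_, nrow = acc_n,
                         ncol = config$n_genes,
                         dimnames = list(panel$accession,
                                         names(haps)))
  site_pos <- list(); freq_tables <- list()
  gt_blocks <- list()
  for (g in seq_len(config$n_genes)) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(derive_seed(config$seed, 1000L + g))
    gm <- genes[genes$gene_id == sprintf("gene_%d", g), ]
    cds_pos <- unlist(map2(gm$start, gm$end, seq))
    pos <- sort(sample(cds_pos, config$sites_per_gene))
    site_pos[[g]] <- pos

    h <- config$n_haps_per_gene
    freqs <- list()
    for (p in unique(pops$population)) {
      base <- rgamma(h, shape = config$dirichlet_alpha)
      base <- base / sum(base)
      freqs[[paste0(p, ".LAN")]] <- base
      mv <- (1 - config$drift_strength) * base
      mv[which.max(base)] <- mv[which.max(base)] + config$drift_strength
      freqs[[paste0(p, ".MV")]] <- mv
      freqs[[paste0(p, ".other")]] <- base
    }
    freq_tables[[g]] <- freqs

    key <- paste(panel$population, panel$variety_class, sep = ".")
    hap_of <- integer(acc_n)
    for (kk in unique(key)) {
      idx <- which(key == kk)
      hap_of[idx] <- sample.int(h, length(idx), replace = TRUE,
                                prob = freqs[[kk]])
    }
    truth_assign[, g] <- hap_of

    ## genotypes: sites x accessions allele indices with injected noise
    gmat <- t(haps[[g]]$vectors[hap_of, , drop = FALSE])
    noise <- matrix(runif(length(gmat)), nrow = nrow(gmat))
    gt_chr <- matrix(paste0(gmat, "/", gmat), nrow = nrow(gmat))
    gt_chr[noise < config$het_rate] <- "0/1"
    gt_chr[noise >= config$het_rate &
             noise < config$het_rate + config$missing_rate] <- "./."
    gt_blocks[[g]] <- list(pos = pos, gt = gt_chr)
    restore_seed(old)
  }

  ## traits
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(derive_seed(config$seed, 999999L))
  traits <- tibble(accession = panel$accession)
  for (k in seq_len(nrow(.TRAITS))) {
    tr <- .TRAITS$trait[k]
    v <- rep(.TRAITS$baseline[k], acc_n) + rnorm(acc_n, 0, config$trait_sd)
    if (!is.null(config$trait_effects)) {
      eff <- config$trait_effects[config$trait_effects$trait == tr, ,
                                  drop = FALSE]
      for (r in seq_len(nrow(eff))) {
        gi <- eff$gene[r]
        v <- v + eff$effect[r] * (truth_assign[, gi] == eff$hap[r])
      }
    }
    traits[[tr]] <- v
  }
  restore_seed(old)

  paths <- list(
    vcf = file.path(dir, "panel.vcf"),
    gff = file.path(dir, "genes.gff3"),
    panel = file.path(dir, "panel.tsv"),
    traits = file.path(dir, "traits.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_sim_vcf(paths$vcf, config$chromosome, gt_blocks, panel$accession)
  write_sim_gff3(paths$gff, genes)
  write_panel(panel, paths$panel)
  write_traits(traits, paths$traits)

  truth <- list(
    assignment = as_tibble(truth_assign, rownames = "accession"),
    haplotypes = map(haps, function(hh) {
      list(vectors = apply(hh$vectors, 1, paste, collapse = ""),
           tree = hh$tree)
    }),
    frequencies = set_names(freq_tables, names(haps)),
    site_positions = set_names(site_pos, names(haps))
  )
  manifest <- list(
    config = config[setdiff(names(config), "trait_effects")],
    trait_effects = config$trait_effects,
    truth = truth
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(paths = paths, truth = truth, panel = panel,
                 genes = genes, traits = traits))
}

write_sim_vcf <- function(path, chromosome, gt_blocks, accessions) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=gchapr-simulate",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", accessions), collapse = "\t")
  ), con)
  bases <- c("A", "C", "G", "T")
  for (blk in gt_blocks) {
    for (i in seq_along(blk$pos)) {
      ref <- bases[(blk$pos[i] %% 4) + 1]
      alt <- bases[((blk$pos[i] + 1) %% 4) + 1]
      writeLines(paste(c(chromosome, blk$pos[i],
                         paste0("snp_", blk$pos[i]), ref, alt, ".", "PASS",
                         ".", "GT", blk$gt[i, ]), collapse = "\t"), con)
    }
  }
}

write_sim_gff3 <- function(path, genes) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (gid in unique(genes$gene_id)) {
    gm <- genes[genes$gene_id == gid, ]
    span <- c(min(gm$start), max(gm$end))
    writeLines(c(
      gff_line(gm$chromosome[1], "gene", span[1], span[2], gm$strand[1],
               paste0("ID=", gid)),
      gff_line(gm$chromosome[1], "mRNA", span[1], span[2], gm$strand[1],
               paste0("ID=", gid, ".1;Parent=", gid)),
      vapply(seq_len(nrow(gm)), function(i) {
        gff_line(gm$chromosome[1], "CDS", gm$start[i], gm$end[i],
                 gm$strand[1],
                 paste0("ID=", gid, ".1.cds", i, ";Parent=", gid, ".1"))
      }, character(1))
    ), con)
  }
}

gff_line <- function(chrom, type, start, end, strand, attrs) {
  paste(chrom, "gchapr_sim", type, start, end, ".", strand,
        if (type == "CDS") "0" else ".", attrs, sep = "\t")
}
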
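## Shared in-code fixtures and independent oracles for the suite.

## A one-gene variant set + models + panel built from explicit per-accession
## allele vectors (accessions x sites matrix).
fixture_from_vectors <- function(vectors, population = NULL,
                                 variety_class = NULL, chrom = "chr1",
                                 pos = NULL) {
  vectors <- as.matrix(vectors)
  n_acc <- nrow(vectors)
  n_sites <- ncol(vectors)
  pos <- pos %||% (100L + seq_len(n_sites))
  samples <- sprintf("S%03d", seq_len(n_acc))
  v <- gchap_variants(
    chrom = rep(chrom, n_sites), pos = pos,
    ref = rep("A", n_sites),
    alt = rep(list(c("T", "G", "C")), n_sites),
    gt = t(vectors), samples = samples
  )
  g <- gene_models("geneA", chrom, "+",
                   start = min(pos), end = max(pos))
  p <- accession_panel(
    samples,
    population %||% rep("Xian", n_acc),
    variety_class %||% rep("LAN", n_acc)
  )
  list(variants = v, genes = g, panel = p, samples = samples)
}

## gchap_table from a haplotype-index assignment: encodes hap k as allele
## k-1 at a single multiallelic site, so calling reproduces the partition.
table_from_assignment <- function(hap_idx, population = NULL,
                                  variety_class = NULL) {
  fx <- fixture_from_vectors(matrix(hap_idx - 1L, ncol = 1),
                             population = population,
                             variety_class = variety_class)
  call_gchaps(fx$variants, fx$genes, fx$panel)
}

## gchap_table whose Hap ranks follow `counts` (descending), with the
## given allele vectors (haplotypes x sites).
table_from_vectors_ranked <- function(vectors, counts) {
  stopifnot(nrow(vectors) == length(counts))
  acc_vectors <- vectors[rep(seq_len(nrow(vectors)), counts), , drop = FALSE]
  fx <- fixture_from_vectors(acc_vectors)
  call_gchaps(fx$variants, fx$genes, fx$panel)
}

## one gene, two haplotype groups, one trait column (TGW)
two_group_fixture <- function(y1, y2) {
  n1 <- length(y1); n2 <- length(y2)
  x <- table_from_assignment(rep(1:2, c(n1, n2)))
  traits <- tibble::tibble(accession = x$assignment$accession,
                           TGW = c(y1, y2))
  list(table = x, traits = traits)
}

## Write a VCF text fixture.
write_vcf_fixture <- function(records, samples, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records
  ), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

## Brute-force minimum-spanning-tree weight by enumerating spanning trees
## (feasible for <= 8 nodes); the independent oracle for build_network.
brute_mst_weight <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  best <- Inf
  for (combo in utils::combn(nrow(pairs), n - 1, simplify = FALSE)) {
    sel <- pairs[combo, , drop = FALSE]
    parent <- seq_len(n)
    find <- function(v) { while (parent[v] != v) v <- parent[v]; v }
    acyclic <- TRUE
    for (r in seq_len(nrow(sel))) {
      a <- find(sel[r, 1]); b <- find(sel[r, 2])
      if (a == b) { acyclic <- FALSE; break }
      parent[a] <- b
    }
    if (acyclic &&
        length(unique(vapply(seq_len(n), find, integer(1)))) == 1) {
      w <- sum(d[sel])
      if (w < best) best <- w
    }
  }
  best
}

## Check that two partitions of the same items are identical up to
## relabeling: the cross-tabulation must have one non-zero cell per row
## and per column.
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
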
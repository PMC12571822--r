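#' Select the CDS SNP sites of a gene
#'
#' Returns exactly the SNPs whose 1-based position lies inside any CDS
#' interval of the gene (boundaries inclusive), in genomic order regardless
#' of strand.
#'
#' @param variants A `gchap_variants` object ([read_vcf()]).
#' @param genes A `gene_models` tibble ([read_gff3()]).
#' @param gene_id Gene to select; may be omitted when `genes` holds a
#'   single gene.
#' @return Integer vector of row indices into `variants$sites` (possibly
#'   empty), named by position.
#' @export
select_cds_sites <- function(variants, genes, gene_id = NULL) {
  model <- one_gene(genes, gene_id)
  chrom <- model$chromosome[1]
  on_chrom <- which(variants$sites$chrom == chrom)
  if (length(on_chrom) == 0) return(integer())
  pos <- variants$sites$pos[on_chrom]
  inside <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(model))) {
    inside <- inside | (pos >= model$start[i] & pos <= model$end[i])
  }
  idx <- on_chrom[inside]
  idx <- idx[order(variants$sites$pos[idx])]
  set_names(idx, variants$sites$pos[idx])
}

one_gene <- function(genes, gene_id = NULL) {
  if (is.null(gene_id)) {
    ids <- unique(genes$gene_id)
    if (length(ids) != 1) {
      abort("gene_id must be given when `genes` holds more than one gene")
    }
    gene_id <- ids
  }
  model <- genes[genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(model) == 0) abort(paste0("gene not found in models: ", gene_id))
  model
}

#' Call gene-CDS-haplotypes (gcHaps) for one gene
#'
#' Groups accessions by their exact allele vector over the gene's CDS SNP
#' sites. Under the default `"exclude"` policy, any accession with a
#' missing or heterozygous genotype at a selected site is excluded from the
#' gene (rice accessions are predominantly inbred, so this is the strictest
#' reproducible rule); the `"ref_fill"` policy instead replaces such calls
#' with the reference allele and excludes nobody. Haplotypes are ranked by
#' descending global count — ties broken by first occurrence in accession
#' order — and named `Hap1`, `Hap2`, ... A gene with zero CDS SNPs yields a
#' single haplotype holding every accession.
#'
#' @inheritParams select_cds_sites
#' @param panel Accession panel ([read_panel()]); must cover every VCF sample.
#' @param policy Missing/heterozygote policy, `"exclude"` (default) or
#'   `"ref_fill"`.
#' @return A `gchap_table` object; see [tidy.gchap_table()] and
#'   [glance.gchap_table()] for tabular views.
#' @export
call_gchaps <- function(variants, genes, panel, gene_id = NULL,
                        policy = c("exclude", "ref_fill")) {
  policy <- match.arg(policy)
  model <- one_gene(genes, gene_id)
  gene_id <- model$gene_id[1]
  chrom <- model$chromosome[1]
  if (nrow(variants$sites) > 0 && chrom %notin% unique(variants$sites$chrom)) {
    abort(paste0("chromosome mismatch: gene ", gene_id, " is on ", chrom,
                 " but the variant set has no sites on that chromosome"))
  }
  missing_acc <- setdiff(variants$samples, panel$accession)
  if (length(missing_acc)) {
    abort(paste0("panel does not cover VCF sample(s): ",
                 paste(head(missing_acc, 5), collapse = ", ")))
  }

  idx <- select_cds_sites(variants, model)
  samples <- variants$samples
  n_total <- length(samples)
  mat <- variants$gt[idx, , drop = FALSE]   # sites x samples

  if (policy == "ref_fill") {
    mat[is.na(mat) | mat == GT_HET] <- 0L
  }
  bad <- if (nrow(mat)) {
    colSums(is.na(mat) | mat == GT_HET) > 0
  } else {
    rep(FALSE, n_total)
  }

  keys <- if (nrow(mat)) {
    apply(mat, 2, paste, collapse = ",")
  } else {
    rep("", n_total)
  }
  keys[bad] <- NA_character_

  keys <- unname(keys)
  kept_keys <- keys[!bad]
  first_seen <- !duplicated(kept_keys)
  uniq <- kept_keys[first_seen]
  counts <- as.integer(table(factor(kept_keys, levels = uniq)))
  rank_order <- order(-counts, seq_along(uniq))
  uniq <- uniq[rank_order]
  counts <- counts[rank_order]
  hap_ids <- paste0("Hap", seq_along(uniq))

  n_kept <- sum(!bad)
  alleles <- map(uniq, function(k) {
    if (nzchar(k)) as.integer(strsplit(k, ",", fixed = TRUE)[[1]]) else integer()
  })
  haps <- tibble(
    hap_id = hap_ids,
    alleles = alleles,
    allele_str = uniq,
    count = counts,
    freq = if (n_kept > 0) counts / n_kept else rep(NA_real_, length(counts))
  )

  assignment <- tibble(
    accession = samples,
    hap_id = hap_ids[match(keys, uniq)]
  ) |>
    left_join(panel, by = "accession") |>
    mutate(excluded = is.na(.data$hap_id))

  structure(
    list(
      gene_id = gene_id,
      chromosome = chrom,
      strand = model$strand[1],
      sites = variants$sites[idx, , drop = FALSE],
      haps = haps,
      assignment = assignment,
      excluded_count = as.integer(sum(bad)),
      n = as.integer(n_kept),
      policy = policy
    ),
    class = "gchap_table"
  )
}

#' Call gcHap tables for every gene in a model set
#'
#' @inheritParams call_gchaps
#' @return Named list of `gchap_table` objects, one per gene.
#' @export
call_gchap_tables <- function(variants, genes, panel,
                              policy = c("exclude", "ref_fill")) {
  policy <- match.arg(policy)
  ids <- unique(genes$gene_id)
  set_names(
    map(ids, function(g) call_gchaps(variants, genes, panel, g, policy)),
    ids
  )
}

#' @export
print.gchap_table <- function(x, ...) {
  cat("<gchap_table> gene ", x$gene_id, " (", x$chromosome, x$strand, "), ",
      nrow(x$sites), " CDS SNP site(s)\n", sep = "")
  cat("  ", nrow(x$haps), " haplotype(s) over ", x$n,
      " accession(s); ", x$excluded_count, " excluded [policy: ", x$policy,
      "]\n", sep = "")
  print(head(select(x$haps, -"alleles"), 5))
  invisible(x)
}

#' Tabular views of a gcHap table
#'
#' `tidy()` returns one row per haplotype with its allele string, global
#' count and frequency; with `by` set it appends per-group counts in wide
#' columns. `glance()` returns a one-row gene summary.
#'
#' @param x A `gchap_table`.
#' @param by Optional grouping columns of the panel to append counts for
#'   (subset of `c("population", "variety_class")`).
#' @param ... Unused.
#' @export
tidy.gchap_table <- function(x, by = NULL, ...) {
  out <- select(x$haps, "hap_id", "allele_str", "count", "freq")
  out <- mutate(out, gene_id = x$gene_id, .before = 1)
  if (!is.null(by)) {
    wide <- hap_counts(x, by = by) |>
      tidyr::unite("group", all_of(by), sep = ".") |>
      pivot_wider(names_from = "group", values_from = "count",
                  values_fill = 0L, names_prefix = "n_")
    out <- left_join(out, wide, by = "hap_id")
  }
  out
}

#' @rdname tidy.gchap_table
#' @export
glance.gchap_table <- function(x, ...) {
  tibble(
    gene_id = x$gene_id,
    n_sites = nrow(x$sites),
    n_haps = nrow(x$haps),
    n_major = length(major_gchaps(x)),
    n = x$n,
    excluded = x$excluded_count,
    policy = x$policy
  )
}

#' Per-group haplotype counts
#'
#' Counts non-excluded accessions per haplotype within panel groups.
#'
#' @param x A `gchap_table`.
#' @param by Panel grouping columns, subset of
#'   `c("population", "variety_class")`.
#' @return Long tibble `hap_id` x groups x `count`.
#' @export
hap_counts <- function(x, by = "population") {
  stopifnot(all(by %in% c("population", "variety_class")))
  x$assignment |>
    filter(!.data$excluded) |>
    count(across(all_of(c("hap_id", by))), name = "count")
}

#' Major haplotypes of a gene
#'
#' Haplotypes whose global frequency among non-excluded accessions is at
#' least `threshold` (default 1%, boundary included), in rank order.
#'
#' @param x A `gchap_table`.
#' @param threshold Frequency threshold in `(0, 1]`.
#' @return Character vector of haplotype ids.
#' @export
major_gchaps <- function(x, threshold = 0.01) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  if (nrow(x$haps) == 0 || x$n == 0) return(character())
  ## compare counts, not ratios, to keep the >= boundary exact
  x$haps$hap_id[x$haps$count >= threshold * x$n - 1e-9]
}

#' Favorable and unfavorable major haplotypes
#'
#' The highest-frequency major haplotype is taken as the selection-favored
#' allele and the lowest-frequency major haplotype as the disfavored one.
#' Frequency ties are resolved by haplotype rank (favorable takes the lower
#' rank, unfavorable the higher). Genes with fewer than two major
#' haplotypes cannot be analyzed and are flagged rather than erroring.
#'
#' @inheritParams major_gchaps
#' @return One-row tibble: `gene_id`, `favorable`, `unfavorable`,
#'   `analyzable`.
#' @export
favorable_unfavorable <- function(x, threshold = 0.01) {
  majors <- major_gchaps(x, threshold)
  if (length(majors) < 2) {
    return(tibble(gene_id = x$gene_id, favorable = NA_character_,
                  unfavorable = NA_character_, analyzable = FALSE))
  }
  h <- x$haps[x$haps$hap_id %in% majors, , drop = FALSE]
  o <- order(-h$count, seq_len(nrow(h)))   # freq desc, then rank
  tibble(gene_id = x$gene_id,
         favorable = h$hap_id[o[1]],
         unfavorable = h$hap_id[o[length(o)]],
         analyzable = TRUE)
}

#' Write / read gcHap tables as TSV pairs
#'
#' `write_gchap_tables()` writes an assignment TSV (accession, gene,
#' hap_id, excluded flag) and a summary TSV (gene, hap, allele vector,
#' counts). `read_gchap_tables()` rebuilds the `gchap_table` list from the
#' pair together with the panel; site metadata is restored from the summary
#' (positions are recorded as a comma list).
#'
#' @param tables Named list of `gchap_table` objects.
#' @param assignment_path,summary_path Output/input TSV paths.
#' @return `write_gchap_tables()` the input invisibly;
#'   `read_gchap_tables()` a named list of `gchap_table` objects.
#' @export
write_gchap_tables <- function(tables, assignment_path, summary_path) {
  assign_tbl <- map(tables, function(x) {
    tibble(accession = x$assignment$accession,
           gene_id = x$gene_id,
           hap_id = ifelse(x$assignment$excluded, "",
                           x$assignment$hap_id))
  }) |> list_rbind()
  summary_tbl <- map(tables, function(x) {
    tidy(x, by = c("population", "variety_class")) |>
      mutate(chromosome = x$chromosome, strand = x$strand,
             positions = paste(x$sites$pos, collapse = ","),
             policy = x$policy, n = x$n, excluded = x$excluded_count)
  }) |> list_rbind()
  write_tsv(assign_tbl, assignment_path, na = "")
  write_tsv(summary_tbl, summary_path, na = "")
  invisible(tables)
}

#' @rdname write_gchap_tables
#' @param panel Accession panel used when the tables were called.
#' @export
read_gchap_tables <- function(assignment_path, summary_path, panel) {
  if (!file.exists(assignment_path)) {
    abort(paste0("missing gcHap assignment file: ", assignment_path,
                 " (run the `call` stage first)"))
  }
  if (!file.exists(summary_path)) {
    abort(paste0("missing gcHap summary file: ", summary_path,
                 " (run the `call` stage first)"))
  }
  assign_tbl <- read_tsv(assignment_path,
                         col_types = cols(.default = col_character()),
                         progress = FALSE, na = character())
  summary_tbl <- read_tsv(summary_path, col_types = cols(
    gene_id = col_character(), hap_id = col_character(),
    allele_str = col_character(), count = col_integer(),
    freq = col_double(), chromosome = col_character(),
    strand = col_character(), positions = col_character(),
    policy = col_character(), n = col_integer(), excluded = col_integer(),
    .default = col_integer()), progress = FALSE, na = character())

  ids <- unique(summary_tbl$gene_id)
  set_names(map(ids, function(g) {
    s <- summary_tbl[summary_tbl$gene_id == g, , drop = FALSE]
    a <- assign_tbl[assign_tbl$gene_id == g, , drop = FALSE]
    pos <- if (nzchar(s$positions[1])) {
      as.integer(strsplit(s$positions[1], ",", fixed = TRUE)[[1]])
    } else integer()
    haps <- tibble(
      hap_id = s$hap_id,
      alleles = map(s$allele_str, function(k) {
        if (is.na(k) || !nzchar(k)) integer()
        else as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
      }),
      allele_str = ifelse(is.na(s$allele_str), "", s$allele_str),
      count = s$count,
      freq = s$freq
    )
    assignment <- tibble(accession = a$accession,
                         hap_id = ifelse(nzchar(a$hap_id), a$hap_id,
                                         NA_character_)) |>
      left_join(panel, by = "accession") |>
      mutate(excluded = is.na(.data$hap_id))
    structure(list(
      gene_id = g, chromosome = s$chromosome[1], strand = s$strand[1],
      sites = tibble(chrom = rep(s$chromosome[1], length(pos)), pos = pos,
                     id = rep(".", length(pos)),
                     ref = rep(NA_character_, length(pos)),
                     alt = rep(list(NA_character_), length(pos))),
      haps = haps, assignment = assignment,
      excluded_count = s$excluded[1], n = s$n[1], policy = s$policy[1]
    ), class = "gchap_table")
  }), ids)
}
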
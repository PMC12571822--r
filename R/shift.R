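#' Landrace vs modern-variety diversity shift per gene
#'
#' For each gene, computes Shannon equitability and haplotype counts on the
#' landrace (LAN) and modern-variety (MV) subsets of one population group,
#' their differences, a label-permutation p-value for the equitability
#' difference, a significance code (`**` for p < 1e-4, `*` for p < 0.05,
#' `ns` otherwise), and an artificial-selection label: `"up"` exactly when
#' the shift is significant (the sign of the difference is not part of the
#' label). A `(mean)` row averages the per-gene values; the delta columns of
#' that row are kept at full precision.
#'
#' @param tables Named list of `gchap_table` objects.
#' @param group Population group, `"Xian"` or `"Geng"` (any panel
#'   population with both classes works).
#' @param reps Number of label permutations per gene (default 10000).
#' @param seed Base RNG seed; gene `i` uses a stream derived from
#'   `seed + i` so the table is reproducible and order-stable.
#' @param include_mean Append the `(mean)` row?
#' @return Tibble with columns `gene_id`, `EH_LAN`, `gcHapN_LAN`, `EH_MV`,
#'   `gcHapN_MV`, `delta_EH`, `delta_gcHapN`, `p_value`, `significance`,
#'   `selection_label`.
#' @export
shift_table <- function(tables, group, reps = 10000, seed = 1,
                        include_mean = TRUE) {
  rows <- imap(tables, function(x, nm) {
    i <- match(nm, names(tables))
    s_lan <- hap_spectrum(x, population = group, variety_class = "LAN")
    s_mv <- hap_spectrum(x, population = group, variety_class = "MV")
    if (attr(s_lan, "n") == 0) {
      abort(paste0("no LAN accessions in group ", group, " for gene ",
                   x$gene_id))
    }
    if (attr(s_mv, "n") == 0) {
      abort(paste0("no MV accessions in group ", group, " for gene ",
                   x$gene_id))
    }
    p <- eh_permutation_test(x, group, reps = reps,
                             seed = derive_seed(seed, i))
    eh_lan <- eh_from_counts(s_lan)
    eh_mv <- eh_from_counts(s_mv)
    sig <- significance_code(p)
    tibble(
      gene_id = x$gene_id,
      EH_LAN = eh_lan, gcHapN_LAN = length(s_lan),
      EH_MV = eh_mv, gcHapN_MV = length(s_mv),
      delta_EH = eh_mv - eh_lan,
      delta_gcHapN = length(s_mv) - length(s_lan),
      p_value = p,
      significance = sig,
      selection_label = if (sig == "ns") "down" else "up"
    )
  }) |> list_rbind()
  if (include_mean) rows <- bind_rows(rows, shift_summary(rows))
  rows
}

#' Aggregate a shift table into its mean row
#'
#' Arithmetic means of the per-gene equitability and haplotype-count
#' columns and of their differences; the aggregation used for the `(mean)`
#' row of [shift_table()] and for reproducing published per-gene summary
#' tables.
#'
#' @param rows Tibble with columns `EH_LAN`, `gcHapN_LAN`, `EH_MV`,
#'   `gcHapN_MV` (and optionally the delta columns, which are recomputed).
#' @return One-row tibble with `gene_id = "(mean)"` and the same numeric
#'   columns at full precision.
#' @export
shift_summary <- function(rows) {
  rows <- filter(rows, is.na(.data$gene_id) | .data$gene_id != "(mean)")
  tibble(
    gene_id = "(mean)",
    EH_LAN = mean(rows$EH_LAN), gcHapN_LAN = mean(rows$gcHapN_LAN),
    EH_MV = mean(rows$EH_MV), gcHapN_MV = mean(rows$gcHapN_MV),
    delta_EH = mean(rows$EH_MV - rows$EH_LAN),
    delta_gcHapN = mean(rows$gcHapN_MV - rows$gcHapN_LAN)
  )
}

significance_code <- function(p) {
  if (is.na(p)) return("ns")
  if (p < 1e-4) "**" else if (p < 0.05) "*" else "ns"
}

#' Permutation test for the LAN/MV equitability difference
#'
#' Two-sided permutation p-value for \eqn{|\Delta E_H|} under random
#' reshuffling of the LAN/MV labels among the group's non-excluded
#' accessions, holding subset sizes fixed:
#' \eqn{p = (1 + \#\{perm \ge obs\}) / (1 + reps)}. The null of no
#' landrace/modern structuring corresponds exactly to label
#' exchangeability, which is why a permutation test (rather than a
#' bootstrap) is used. A gene that is monomorphic over the combined subset
#' returns p = 1.
#'
#' @param x A `gchap_table`.
#' @param group Population group.
#' @param reps Number of permutations (>= 1).
#' @param seed RNG seed; fixed seed implies an identical p-value.
#' @return Permutation p-value in (0, 1].
#' @export
eh_permutation_test <- function(x, group, reps = 10000, seed = 1) {
  if (reps < 1) abort("reps must be >= 1")
  a <- filter(x$assignment, !.data$excluded,
              .data$population == group,
              .data$variety_class %in% c("LAN", "MV"))
  if (nrow(a) == 0) abort(paste0("no LAN/MV accessions in group ", group))
  ## canonical order: the p-value depends only on the (hap, class) multiset
  a <- a[order(a$hap_id, a$variety_class), ]
  hap <- as.integer(factor(a$hap_id))
  is_mv <- a$variety_class == "MV"
  n <- length(hap)
  n_mv <- sum(is_mv)
  if (n_mv == 0 || n_mv == n) {
    abort(paste0("group ", group, " lacks one of the LAN/MV classes"))
  }
  k <- max(hap)
  if (k == 1) return(1)
  total <- tabulate(hap, k)
  obs <- abs(eh_from_counts(tabulate(hap[is_mv], k)) -
               eh_from_counts(tabulate(hap[!is_mv], k)))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  exceed <- 0L
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n_mv)
    c_mv <- tabulate(hap[idx], k)
    stat <- abs(eh_from_counts(c_mv) - eh_from_counts(total - c_mv))
    if (stat >= obs - 1e-12) exceed <- exceed + 1L
  }
  (1 + exceed) / (1 + reps)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Major-haplotype frequency drift between landraces and modern varieties
#'
#' 2x2 chi-square test (haplotype vs all others, LAN vs MV), without
#' continuity correction, on the counts of one major haplotype within a
#' population group. Results with any expected cell below 1, or with a
#' degenerate margin, are flagged `low_count` (the p-value is `NA` when the
#' statistic is undefined).
#'
#' @param x A `gchap_table`.
#' @param group Population group.
#' @param hap_id A major haplotype of the gene (error otherwise).
#' @param threshold Major-haplotype threshold used for the check.
#' @return One-row tibble: `gene_id`, `hap_id`, `n_LAN`, `n_MV`,
#'   `freq_LAN`, `freq_MV`, `chi2`, `p`, `low_count`.
#' @export
drift_chi2 <- function(x, group, hap_id, threshold = 0.01) {
  if (hap_id %notin% major_gchaps(x, threshold)) {
    abort(paste0(hap_id, " is not a major haplotype of gene ", x$gene_id))
  }
  a <- filter(x$assignment, !.data$excluded,
              .data$population == group,
              .data$variety_class %in% c("LAN", "MV"))
  n_lan <- sum(a$variety_class == "LAN")
  n_mv <- sum(a$variety_class == "MV")
  if (n_lan == 0 || n_mv == 0) {
    abort(paste0("both LAN and MV subsets must be non-empty in group ",
                 group))
  }
  k_lan <- sum(a$variety_class == "LAN" & a$hap_id == hap_id)
  k_mv <- sum(a$variety_class == "MV" & a$hap_id == hap_id)
  m <- rbind(LAN = c(hap = k_lan, other = n_lan - k_lan),
             MV = c(hap = k_mv, other = n_mv - k_mv))
  res <- tryCatch(suppressWarnings(chisq.test(m, correct = FALSE)),
                  error = function(e) NULL)
  low <- is.null(res) || any(res$expected < 1)
  tibble(
    gene_id = x$gene_id, hap_id = hap_id,
    n_LAN = n_lan, n_MV = n_mv,
    freq_LAN = k_lan / n_lan, freq_MV = k_mv / n_mv,
    chi2 = if (is.null(res) || !is.finite(res$statistic)) NA_real_
           else unname(res$statistic),
    p = if (is.null(res) || !is.finite(res$p.value)) NA_real_
        else res$p.value,
    low_count = low
  )
}

#' Drift table over all major haplotypes of a set of genes
#'
#' @param tables Named list of `gchap_table` objects.
#' @inheritParams drift_chi2
#' @return Tibble with one [drift_chi2()] row per gene x major haplotype.
#' @export
drift_table <- function(tables, group, threshold = 0.01) {
  map(tables, function(x) {
    majors <- major_gchaps(x, threshold)
    map(majors, function(h) drift_chi2(x, group, h, threshold)) |>
      list_rbind()
  }) |> list_rbind()
}
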
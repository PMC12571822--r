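#' Associate major haplotypes of a gene with a quantitative trait
#'
#' Classical one-way ANOVA of the trait over the gene's major haplotypes
#' (only one factor — haplotype — is involved), followed by Tukey HSD over
#' all retained haplotype pairs (studentized-range distribution) and a
#' compact letter display computed with the insert-absorb algorithm: two
#' haplotypes share a letter exactly when their Tukey-adjusted p-value is
#' >= `alpha`. Haplotype groups need at least `min_n` phenotyped
#' accessions; missing trait values are dropped per accession. Associations
#' with ANOVA p below `strong_p` (default 1e-7) are flagged `strong` — a
#' fixed threshold is used rather than FDR control, and the raw p-value is
#' always reported alongside.
#'
#' @param x A `gchap_table`.
#' @param traits Phenotype tibble ([read_traits()]).
#' @param trait Trait column to analyse.
#' @param min_n Minimum phenotyped accessions per haplotype group
#'   (default 10).
#' @param threshold Major-haplotype frequency threshold (default 1%).
#' @param alpha Pairwise significance level for the letter display.
#' @param strong_p Threshold for the `strong` flag.
#' @return A `hap_assoc` object; genes with fewer than two eligible groups
#'   return one with `analyzable = FALSE`. See [tidy.hap_assoc()] /
#'   [glance.hap_assoc()].
#' @export
anova_by_hap <- function(x, traits, trait, min_n = 10, threshold = 0.01,
                         alpha = 0.05, strong_p = 1e-7) {
  if (trait %notin% names(traits)) {
    abort(paste0("trait column not found: ", trait))
  }
  majors <- major_gchaps(x, threshold)
  df <- x$assignment |>
    filter(!.data$excluded, .data$hap_id %in% majors) |>
    inner_join(select(traits, "accession", value = all_of(trait)),
               by = "accession") |>
    filter(!is.na(.data$value))
  sizes <- count(df, .data$hap_id)
  eligible <- sizes$hap_id[sizes$n >= min_n]
  df <- filter(df, .data$hap_id %in% eligible)

  not_analyzable <- structure(
    list(gene_id = x$gene_id, trait = trait, analyzable = FALSE,
         groups = tibble(hap_id = character(), n = integer(),
                         mean = numeric(), sd = numeric(),
                         letter = character()),
         F = NA_real_, p = NA_real_, strong = NA,
         min_n = min_n, threshold = threshold, alpha = alpha,
         strong_p = strong_p, data = df),
    class = "hap_assoc")
  if (length(eligible) < 2) return(not_analyzable)

  ## keep haplotype rank order as factor order
  lev <- majors[majors %in% eligible]
  df$hap <- factor(df$hap_id, levels = lev)
  fit <- suppressWarnings(aov(value ~ hap, data = df))
  at <- suppressWarnings(anova(fit))
  ss <- at$`Sum Sq`
  eps <- 1e-10 * (sum(df$value^2) + 1)   # guards numerically-zero fits
  if (!is.finite(ss[1]) || ss[1] <= eps) {
    f <- 0; p <- 1
  } else if (!is.finite(ss[2]) || ss[2] <= eps) {
    f <- Inf; p <- 0
  } else {
    f <- unname(at$`F value`[1])
    p <- unname(at$`Pr(>F)`[1])
  }

  pmat <- tukey_p_matrix(fit, lev, df)
  letters <- cld_insert_absorb(pmat < alpha,
                               order_by = tapply(df$value, df$hap, mean))

  groups <- df |>
    group_by(hap_id = .data$hap) |>
    summarise(n = n(), mean = mean(.data$value), sd = sd(.data$value),
              .groups = "drop") |>
    mutate(hap_id = as.character(.data$hap_id),
           letter = letters[.data$hap_id])

  structure(
    list(gene_id = x$gene_id, trait = trait, analyzable = TRUE,
         groups = groups, F = f, p = p, strong = is.finite(p) && p < strong_p,
         tukey_p = pmat, min_n = min_n, threshold = threshold,
         alpha = alpha, strong_p = strong_p, data = df),
    class = "hap_assoc")
}

## Pairwise Tukey-adjusted p-values as a symmetric matrix. Degenerate fits
## (zero within-group variance) fall back to 0/1 p-values by mean equality.
tukey_p_matrix <- function(fit, lev, df) {
  k <- length(lev)
  pmat <- matrix(1, k, k, dimnames = list(lev, lev))
  at <- suppressWarnings(anova(fit))
  ssw <- at$`Sum Sq`[2]
  if (!is.finite(ssw) || ssw <= 1e-10 * (sum(df$value^2) + 1)) {
    mns <- tapply(df$value, df$hap, mean)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      pij <- if (isTRUE(all.equal(unname(mns[i]), unname(mns[j])))) 1 else 0
      pmat[i, j] <- pmat[j, i] <- pij
    }
    return(pmat)
  }
  tk <- TukeyHSD(fit)$hap
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (r in seq_along(pairs)) {
    a <- pairs[[r]][1]; b <- pairs[[r]][2]
    pmat[a, b] <- pmat[b, a] <- tk[r, "p adj"]
  }
  pmat
}

#' Compact letter display by insert-absorb
#'
#' Assigns letter strings to groups from a logical matrix of pairwise
#' significant differences so that two groups share a letter if and only
#' if they are not significantly different. This is the insert-absorb
#' algorithm: start from one set holding all groups; for each significant
#' pair, split every set containing both; then absorb sets contained in
#' others. Letters are ordered by decreasing group mean when `order_by` is
#' given, so the "a" group has the largest mean.
#'
#' @param sig Logical symmetric matrix with dimnames; `TRUE` marks a
#'   significantly different pair.
#' @param order_by Optional numeric vector (named like `sig`'s rows) used
#'   to order letters.
#' @return Named character vector of letter strings.
#' @export
cld_insert_absorb <- function(sig, order_by = NULL) {
  groups <- rownames(sig)
  if (is.null(groups)) abort("sig matrix must have dimnames")
  ord <- if (!is.null(order_by)) {
    groups[order(-order_by[groups])]
  } else groups
  sets <- list(ord)
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    a <- groups[pairs[r, 1]]; b <- groups[pairs[r, 2]]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    ## absorb: drop sets that are subsets of another set, and duplicates
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      for (j in seq_along(new_sets)) {
        if (i != j && keep[j] &&
            all(new_sets[[i]] %in% new_sets[[j]]) &&
            (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    sets <- new_sets[keep]
  }
  ## order letter sets by the best-ranked member, then label a, b, c, ...
  rank_of <- setNames(seq_along(ord), ord)
  sets <- sets[order(map_dbl(sets, function(s) min(rank_of[s])))]
  out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    l <- letters[(i - 1) %% 26 + 1]
    if (i > 26) l <- paste0(l, (i - 1) %/% 26)
    for (g in sets[[i]]) out[g] <- paste0(out[g], l)
  }
  out
}

#' @export
print.hap_assoc <- function(x, ...) {
  cat("<hap_assoc> gene ", x$gene_id, " x trait ", x$trait, "\n", sep = "")
  if (!x$analyzable) {
    cat("  not analyzable: fewer than two major haplotype groups with n >= ",
        x$min_n, "\n", sep = "")
    return(invisible(x))
  }
  cat("  one-way ANOVA F = ", signif(x$F, 4), ", p = ", signif(x$p, 3),
      if (x$strong) "  [strong]" else "", "\n", sep = "")
  print(x$groups)
  invisible(x)
}

#' Tabular views of a haplotype-trait association
#'
#' `tidy()` returns one row per haplotype group (n, mean, sd, letter);
#' `glance()` a one-row model summary (F, p, strong flag).
#'
#' @param x A `hap_assoc` object.
#' @param ... Unused.
#' @export
tidy.hap_assoc <- function(x, ...) {
  mutate(x$groups, gene_id = x$gene_id, trait = x$trait, .before = 1)
}

#' @rdname tidy.hap_assoc
#' @export
glance.hap_assoc <- function(x, ...) {
  tibble(gene_id = x$gene_id, trait = x$trait, analyzable = x$analyzable,
         n_groups = nrow(x$groups), F = x$F, p = x$p, strong = x$strong,
         min_n = x$min_n)
}

#' Scan all gene x trait associations
#'
#' Runs [anova_by_hap()] over every combination of gene table and trait
#' column, returning the tidied group rows with the model summary columns
#' attached.
#'
#' @param tables Named list of `gchap_table` objects.
#' @param traits Phenotype tibble.
#' @param trait_names Traits to scan; defaults to every trait column.
#' @inheritParams anova_by_hap
#' @return Tibble of per-group rows with `F`, `p`, `strong` per
#'   gene x trait; non-analyzable combinations contribute one row with
#'   `analyzable = FALSE`.
#' @export
assoc_scan <- function(tables, traits, trait_names = NULL, min_n = 10,
                       threshold = 0.01, alpha = 0.05, strong_p = 1e-7) {
  trait_names <- trait_names %||% setdiff(names(traits), "accession")
  map(tables, function(x) {
    map(trait_names, function(tr) {
      res <- anova_by_hap(x, traits, tr, min_n, threshold, alpha, strong_p)
      if (!res$analyzable) {
        return(tibble(gene_id = x$gene_id, trait = tr,
                      hap_id = NA_character_, n = NA_integer_,
                      mean = NA_real_, sd = NA_real_, letter = NA_character_,
                      F = NA_real_, p = NA_real_, strong = NA,
                      analyzable = FALSE))
      }
      tidy(res) |>
        mutate(F = res$F, p = res$p, strong = res$strong, analyzable = TRUE)
    }) |> list_rbind()
  }) |> list_rbind()
}

#' Favorable vs unfavorable haplotype trait comparison
#'
#' For each gene with a resolvable favorable/unfavorable major-haplotype
#' pair ([favorable_unfavorable()]), compares every trait between the two
#' haplotype groups with Welch's unequal-variance two-sample t-test (the
#' group sizes are wildly unbalanced by construction — highest vs lowest
#' frequency). A comparison is `different` at `p < alpha`. Comparisons
#' where either group has fewer than two non-missing values are skipped
#' with a reason. Genes without an analyzable pair contribute no
#' comparisons.
#'
#' @param tables Named list of `gchap_table` objects.
#' @param traits Phenotype tibble.
#' @param trait_names Traits to compare (default: all trait columns).
#' @param threshold Major-haplotype threshold.
#' @param alpha Significance level for `different`.
#' @return A tibble of class `fav_unfav_scan`, one row per attempted
#'   gene x trait comparison; `glance()` gives the summary counts
#'   (attempted, detected, skipped).
#' @export
fav_unfav_scan <- function(tables, traits, trait_names = NULL,
                           threshold = 0.01, alpha = 0.05) {
  trait_names <- trait_names %||% setdiff(names(traits), "accession")
  rows <- map(tables, function(x) {
    fu <- favorable_unfavorable(x, threshold)
    if (!fu$analyzable) return(NULL)
    a <- filter(x$assignment, !.data$excluded)
    map(trait_names, function(tr) {
      vals <- inner_join(a, select(traits, "accession", value = all_of(tr)),
                         by = "accession")
      v_fav <- vals$value[vals$hap_id == fu$favorable & !is.na(vals$value)]
      v_unf <- vals$value[vals$hap_id == fu$unfavorable & !is.na(vals$value)]
      base <- tibble(gene_id = x$gene_id, trait = tr,
                     favorable = fu$favorable, unfavorable = fu$unfavorable,
                     n_fav = length(v_fav), n_unfav = length(v_unf),
                     mean_fav = if (length(v_fav)) mean(v_fav) else NA_real_,
                     mean_unfav = if (length(v_unf)) mean(v_unf) else NA_real_)
      if (length(v_fav) < 2 || length(v_unf) < 2) {
        return(mutate(base, p = NA_real_, different = NA,
                      skipped = "fewer than 2 phenotyped accessions in a group"))
      }
      if (sd(v_fav) == 0 && sd(v_unf) == 0) {
        same <- isTRUE(all.equal(mean(v_fav), mean(v_unf)))
        return(mutate(base, p = if (same) 1 else 0, different = !same,
                      skipped = NA_character_))
      }
      tt <- t.test(v_fav, v_unf)
      mutate(base, p = tt$p.value, different = tt$p.value < alpha,
             skipped = NA_character_)
    }) |> list_rbind()
  }) |> compact() |> list_rbind()
  class(rows) <- unique(c("fav_unfav_scan", class(rows)))
  rows
}

#' @export
glance.fav_unfav_scan <- function(x, ...) {
  tibble(
    attempted = nrow(x),
    detected = sum(x$different, na.rm = TRUE),
    skipped = sum(!is.na(x$skipped))
  )
}
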
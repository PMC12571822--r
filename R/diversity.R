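#' Haplotype frequency spectrum of a (sub)population
#'
#' @param x A `gchap_table`.
#' @param population,variety_class Optional filters on the panel columns;
#'   `NULL` keeps everything.
#' @return Named numeric vector of haplotype frequencies (names are hap
#'   ids, entries sum to 1) with attribute `n`, the number of non-excluded
#'   accessions in the subset. Zero accessions yield an empty spectrum with
#'   `n = 0`.
#' @export
hap_spectrum <- function(x, population = NULL, variety_class = NULL) {
  a <- filter(x$assignment, !.data$excluded)
  if (!is.null(population)) a <- filter(a, .data$population %in% !!population)
  if (!is.null(variety_class)) {
    a <- filter(a, .data$variety_class %in% !!variety_class)
  }
  if (nrow(a) == 0) {
    return(structure(setNames(numeric(), character()), n = 0L))
  }
  counts <- table(a$hap_id)
  freqs <- as.numeric(counts) / sum(counts)
  structure(setNames(freqs, names(counts)), n = as.integer(sum(counts)))
}

#' Shannon equitability of a haplotype spectrum
#'
#' \eqn{E_H = -\sum_i p_i \ln p_i / \ln S}, where `S` is the number of
#' haplotypes with positive frequency (natural log; the base cancels in the
#' ratio). Defined as 0 for a monomorphic spectrum (`S = 1`); always in
#' \[0, 1\], with 1 for a perfectly even spectrum. Invariant to haplotype
#' relabeling and to zero-frequency entries.
#'
#' @param p Numeric vector of haplotype frequencies or counts (need not be
#'   normalised); zero entries are ignored.
#' @return `E_H` in \[0, 1\].
#' @export
shannon_equitability <- function(p) {
  if (length(p) == 0 || sum(p) <= 0) {
    abort("shannon_equitability: undefined for an empty spectrum (n = 0)")
  }
  if (any(p < 0)) abort("frequencies must be non-negative")
  eh_from_counts(p)
}

#' Nei's genetic identity between two populations
#'
#' \eqn{I = \sum_i x_i y_i / \sqrt{(\sum_i x_i^2)(\sum_i y_i^2)}} over the
#' union of the two haplotype sets (absent haplotypes enter as 0).
#' Symmetric, bounded in \[0, 1\], and equal to 1 exactly when the two
#' frequency vectors are proportional (hence, for frequencies, equal).
#' Low identity indicates strong between-population differentiation.
#'
#' @param x,y Named numeric vectors of haplotype frequencies (names are
#'   haplotype ids), e.g. from [hap_spectrum()]. Unnamed vectors of equal
#'   length are compared position-wise.
#' @return `I_Nei` in \[0, 1\].
#' @export
nei_identity <- function(x, y) {
  if (length(x) == 0 || length(y) == 0 || sum(x) <= 0 || sum(y) <= 0) {
    abort("nei_identity: undefined when either spectrum is empty (n = 0)")
  }
  if (!is.null(names(x)) && !is.null(names(y))) {
    ids <- union(names(x), names(y))
    xv <- setNames(numeric(length(ids)), ids)
    yv <- xv
    xv[names(x)] <- x
    yv[names(y)] <- y
  } else {
    if (length(x) != length(y)) {
      abort("unnamed spectra must have equal length")
    }
    xv <- x; yv <- y
  }
  sum(xv * yv) / sqrt(sum(xv^2) * sum(yv^2))
}

#' Fst (Nei's G_ST) from haplotype frequencies
#'
#' Multi-population fixation index computed from haplotype frequency
#' spectra with sample-size weights \eqn{w_k = n_k / \sum n}:
#' \eqn{H_S = \sum_k w_k (1 - \sum_i p_{ki}^2)},
#' \eqn{H_T = 1 - \sum_i \bar p_i^2} with
#' \eqn{\bar p_i = \sum_k w_k p_{ki}}, and
#' \eqn{F_{ST} = (H_T - H_S) / H_T} (0 when \eqn{H_T = 0}).
#'
#' @param spectra List of K >= 2 named frequency vectors (e.g. from
#'   [hap_spectrum()]).
#' @param n Sample sizes per population; defaults to the `n` attributes of
#'   the spectra, else equal weights.
#' @return `F_ST` in \[0, 1\].
#' @export
fst_haplotype <- function(spectra, n = NULL) {
  if (length(spectra) < 2) abort("fst_haplotype needs K >= 2 populations")
  if (is.null(n)) {
    n <- map_dbl(spectra, function(s) as.numeric(attr(s, "n") %||% 1))
  }
  if (any(n < 1)) abort("every population must have n >= 1")
  ids <- unique(unlist(map(spectra, names)))
  if (is.null(ids)) abort("spectra must be named by haplotype id")
  P <- matrix(0, nrow = length(spectra), ncol = length(ids),
              dimnames = list(NULL, ids))
  for (k in seq_along(spectra)) P[k, names(spectra[[k]])] <- spectra[[k]]
  w <- n / sum(n)
  hs <- sum(w * (1 - rowSums(P^2)))
  pbar <- colSums(w * P)
  ht <- 1 - sum(pbar^2)
  if (ht <= 0) return(0)
  (ht - hs) / ht
}

#' Per-gene, per-population diversity table
#'
#' One row per gene x population with Shannon equitability (`EH`), the
#' number of distinct haplotypes observed in the population (`gcHapN`) and
#' the number of globally major haplotypes (frequency >= `threshold` in
#' the whole panel) present in the population (`major_gcHapN`), plus a
#' `(mean)` row per population averaging over genes.
#'
#' @param tables Named list of `gchap_table` objects.
#' @param populations Populations to report; default all present in the
#'   panel. A requested population absent from the panel is an error.
#' @param threshold Major-haplotype frequency threshold (default 1%).
#' @param include_mean Append per-population mean rows (gene_id `"(mean)"`)?
#' @return Tibble `gene_id`, `population`, `EH`, `gcHapN`, `major_gcHapN`,
#'   `n`.
#' @export
diversity_table <- function(tables, populations = NULL, threshold = 0.01,
                            include_mean = TRUE) {
  stopifnot(length(tables) > 0)
  present <- unique(tables[[1]]$assignment$population)
  if (is.null(populations)) {
    populations <- intersect(.POPULATIONS, present)
  } else {
    absent <- setdiff(populations, present)
    if (length(absent)) {
      abort(paste0("population(s) absent from panel: ",
                   paste(absent, collapse = ", ")))
    }
  }
  rows <- map(tables, function(x) {
    majors <- major_gchaps(x, threshold)
    map(populations, function(p) {
      s <- hap_spectrum(x, population = p)
      tibble(gene_id = x$gene_id, population = p,
             EH = if (attr(s, "n") > 0) eh_from_counts(s) else NA_real_,
             gcHapN = length(s),
             major_gcHapN = sum(names(s) %in% majors),
             n = attr(s, "n"))
    }) |> list_rbind()
  }) |> list_rbind()
  if (include_mean) {
    means <- rows |>
      group_by(.data$population) |>
      summarise(gene_id = "(mean)", EH = mean(.data$EH),
                gcHapN = mean(.data$gcHapN),
                major_gcHapN = mean(.data$major_gcHapN),
                n = mean(.data$n), .groups = "drop") |>
      relocate("gene_id")
    rows <- bind_rows(rows, means)
  }
  rows
}

#' Pairwise Nei identity table across populations
#'
#' Mirrors a gene x population-pair identity matrix: one row per gene and
#' unordered population pair.
#'
#' @inheritParams diversity_table
#' @return Tibble `gene_id`, `pop_a`, `pop_b`, `INei`.
#' @export
nei_table <- function(tables, populations = NULL) {
  stopifnot(length(tables) > 0)
  present <- unique(tables[[1]]$assignment$population)
  populations <- populations %||% intersect(.POPULATIONS, present)
  if (length(populations) < 2) abort("need at least two populations")
  pairs <- utils::combn(populations, 2, simplify = FALSE)
  map(tables, function(x) {
    map(pairs, function(pr) {
      sx <- hap_spectrum(x, population = pr[1])
      sy <- hap_spectrum(x, population = pr[2])
      tibble(gene_id = x$gene_id, pop_a = pr[1], pop_b = pr[2],
             INei = if (attr(sx, "n") > 0 && attr(sy, "n") > 0) {
               nei_identity(sx, sy)
             } else NA_real_)
    }) |> list_rbind()
  }) |> list_rbind()
}

#' Per-gene Fst table across populations
#'
#' @inheritParams diversity_table
#' @return Tibble `gene_id`, `Fst`, `K`, `n`, `estimator`.
#' @export
fst_table <- function(tables, populations = NULL) {
  stopifnot(length(tables) > 0)
  present <- unique(tables[[1]]$assignment$population)
  populations <- populations %||% intersect(.POPULATIONS, present)
  if (length(populations) < 2) abort("need at least two populations")
  map(tables, function(x) {
    spectra <- map(populations, function(p) hap_spectrum(x, population = p))
    keep <- map_int(spectra, function(s) attr(s, "n")) >= 1
    tibble(gene_id = x$gene_id,
           Fst = if (sum(keep) >= 2) fst_haplotype(spectra[keep]) else NA_real_,
           K = sum(keep),
           n = sum(map_int(spectra, function(s) attr(s, "n"))),
           estimator = "Nei_GST_weighted")
  }) |> list_rbind()
}
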
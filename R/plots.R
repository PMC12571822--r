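#' Plot a gcHap frequency spectrum
#'
#' Bar chart of haplotype frequencies, optionally faceted by population.
#'
#' @param object A `gchap_table`.
#' @param by_population Facet the counts by population?
#' @param top Show at most this many top-ranked haplotypes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gchap_table <- function(object, by_population = FALSE, top = 10,
                                 ...) {
  keep <- head(object$haps$hap_id, top)
  if (by_population) {
    df <- hap_counts(object, by = "population") |>
      filter(.data$hap_id %in% keep) |>
      group_by(.data$population) |>
      mutate(freq = .data$count / sum(.data$count)) |>
      ungroup()
    p <- ggplot(df, aes(x = factor(.data$hap_id, levels = keep),
                        y = .data$freq)) +
      geom_col(fill = "steelblue") +
      facet_wrap(~population)
  } else {
    df <- filter(object$haps, .data$hap_id %in% keep)
    p <- ggplot(df, aes(x = factor(.data$hap_id, levels = keep),
                        y = .data$freq)) +
      geom_col(fill = "steelblue")
  }
  p + labs(x = NULL, y = "frequency",
           title = paste0(object$gene_id, ": gcHap spectrum")) +
    theme_minimal()
}

#' Plot per-gene, per-population diversity
#'
#' Tile map of Shannon equitability by gene and population from a
#' [diversity_table()] result.
#'
#' @param div Tibble from [diversity_table()].
#' @return A ggplot object.
#' @export
plot_diversity <- function(div) {
  df <- filter(div, .data$gene_id != "(mean)")
  ggplot(df, aes(x = .data$population, y = .data$gene_id,
                 fill = .data$EH)) +
    geom_tile() +
    labs(x = NULL, y = NULL, fill = expression(E[H])) +
    theme_minimal()
}

#' Plot landrace vs modern-variety equitability shifts
#'
#' Dumbbell plot: one segment per gene from the landrace to the
#' modern-variety equitability, annotated with the significance code.
#'
#' @param st Tibble from [shift_table()].
#' @return A ggplot object.
#' @export
plot_shift <- function(st) {
  df <- filter(st, .data$gene_id != "(mean)")
  ggplot(df, aes(y = .data$gene_id)) +
    geom_segment(aes(x = .data$EH_LAN, xend = .data$EH_MV,
                     yend = .data$gene_id), color = "grey50") +
    geom_point(aes(x = .data$EH_LAN), color = "darkorange", size = 2) +
    geom_point(aes(x = .data$EH_MV), color = "steelblue", size = 2) +
    geom_text(aes(x = pmax(.data$EH_LAN, .data$EH_MV),
                  label = .data$significance),
              hjust = -0.4, size = 3) +
    labs(x = expression(E[H]~"(orange = LAN, blue = MV)"), y = NULL) +
    theme_minimal()
}

#' Plot a haplotype-trait association
#'
#' Box plots of the trait by major haplotype with the compact letter
#' display above each box; haplotypes sharing a letter do not differ at
#' the pairwise level.
#'
#' @param object A `hap_assoc` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hap_assoc <- function(object, ...) {
  if (!object$analyzable) abort("association is not analyzable")
  df <- object$data
  lab <- object$groups
  ypos <- tapply(df$value, df$hap, max)
  lab$y <- as.numeric(ypos[lab$hap_id])
  ggplot(df, aes(x = .data$hap, y = .data$value)) +
    geom_boxplot(fill = "grey90", outlier.size = 0.6) +
    geom_text(data = lab, aes(x = .data$hap_id, y = .data$y,
                              label = .data$letter),
              vjust = -0.7, size = 3.5) +
    labs(x = NULL, y = object$trait,
         title = paste0(object$gene_id, " ~ ", object$trait,
                        "  (F = ", signif(object$F, 3),
                        ", p = ", signif(object$p, 2), ")")) +
    theme_minimal()
}

#' Plot a haplotype network
#'
#' Force-directed layout (Fruchterman-Reingold, fixed seed) of the
#' minimum-mutation network: node area proportional to haplotype count,
#' spanning edges solid, alternative links dashed, edges labelled with
#' their mutation steps.
#'
#' @param object A `hap_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hap_network <- function(object, seed = 1, ...) {
  nodes <- object$nodes
  if (nrow(object$edges)) {
    g <- igraph::graph_from_data_frame(
      object$edges[, c("from", "to")], directed = FALSE,
      vertices = nodes$hap_id)
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    xy <- igraph::layout_with_fr(g, weights = 1 / object$edges$steps)
    restore_seed(old)
  } else {
    xy <- cbind(seq_len(nrow(nodes)), 0)
  }
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  ed <- object$edges |>
    left_join(select(nodes, "hap_id", x0 = "x", y0 = "y"),
              by = c(from = "hap_id")) |>
    left_join(select(nodes, "hap_id", x1 = "x", y1 = "y"),
              by = c(to = "hap_id"))
  p <- ggplot(nodes, aes(x = .data$x, y = .data$y))
  if (nrow(ed)) {
    p <- p + geom_segment(
      data = ed,
      aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
          linetype = !.data$in_msn), color = "grey40") +
      geom_text(data = ed, aes(x = (.data$x0 + .data$x1) / 2,
                               y = (.data$y0 + .data$y1) / 2,
                               label = .data$steps),
                size = 3, color = "grey30")
  }
  p + geom_point(aes(size = .data$count), color = "steelblue",
                 alpha = 0.85) +
    geom_text(aes(label = .data$hap_id), vjust = -1.1, size = 3) +
    scale_size_area(max_size = 12) +
    labs(title = paste0(object$gene_id, ": gcHap network"),
         size = "count") +
    theme_minimal() +
    theme(axis.title = element_blank(), axis.text = element_blank(),
          panel.grid = element_blank()) +
    ggplot2::guides(linetype = "none")
}
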
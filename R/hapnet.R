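#' Pairwise mutation steps between the haplotypes of a gene
#'
#' Hamming distance between allele vectors: the minimum number of
#' single-site mutations separating two CDS haplotypes.
#'
#' @param x A `gchap_table`, or a list/matrix of equal-length allele
#'   vectors (rows = haplotypes).
#' @return Symmetric integer matrix with zero diagonal, dimnames = hap ids.
#' @export
pairwise_steps <- function(x) {
  if (inherits(x, "gchap_table")) {
    vecs <- x$haps$alleles
    ids <- x$haps$hap_id
  } else if (is.matrix(x)) {
    vecs <- asplit(x, 1)
    ids <- rownames(x) %||% paste0("Hap", seq_len(nrow(x)))
  } else {
    vecs <- x
    ids <- names(x) %||% paste0("Hap", seq_along(x))
  }
  if (length(vecs) > 1 && length(unique(lengths(vecs))) > 1) {
    abort("allele vectors must all have the same length")
  }
  h <- length(vecs)
  d <- matrix(0L, h, h, dimnames = list(ids, ids))
  if (h < 2) return(d)
  for (i in seq_len(h - 1)) {
    for (j in (i + 1):h) {
      d[i, j] <- d[j, i] <- sum(vecs[[i]] != vecs[[j]])
    }
  }
  d
}

#' Build a minimum-mutation haplotype network
#'
#' Statistical-parsimony-style network: candidate edges (all haplotype
#' pairs with `steps <= limit`) are processed in Kruskal order — ascending
#' mutation steps, ties by haplotype rank pair. An edge joining two
#' components enters the spanning network (`in_msn = TRUE`). An edge inside
#' one component is retained as an alternative link (`in_msn = FALSE`)
#' when its step count equals the step at which its two endpoints'
#' components merged (equivalently, the bottleneck weight on the spanning
#' path), which keeps reticulations among equally parsimonious
#' connections. Unsampled intermediate (median) haplotypes are never
#' inserted. With an unlimited `limit` the network is connected; a finite
#' limit may split it into components.
#'
#' @param x A `gchap_table` with at least one haplotype.
#' @param limit Connection limit in mutation steps (default `Inf`,
#'   unlimited).
#' @return A `hap_network` object: `nodes` (hap_id, count, freq, one
#'   `n_<population>` column per population), `edges` (`from`, `to`,
#'   `steps`, `in_msn`), plus `gene_id` and `limit`.
#' @export
build_network <- function(x, limit = Inf) {
  if (nrow(x$haps) == 0) abort("cannot build a network with no haplotypes")
  ids <- x$haps$hap_id
  h <- length(ids)
  d <- pairwise_steps(x)

  pop_counts <- hap_counts(x, by = "population") |>
    pivot_wider(names_from = "population", values_from = "count",
                values_fill = 0L, names_prefix = "n_")
  nodes <- select(x$haps, "hap_id", "count", "freq") |>
    left_join(pop_counts, by = "hap_id") |>
    mutate(across(dplyr::starts_with("n_"), function(v) replace_na(v, 0L)))

  if (h < 2) {
    return(new_hap_network(x$gene_id, nodes,
                           tibble(from = character(), to = character(),
                                  steps = integer(), in_msn = logical()),
                           limit))
  }

  cand <- which(upper.tri(d), arr.ind = TRUE)
  cand <- tibble(i = cand[, 1], j = cand[, 2],
                 steps = d[upper.tri(d)]) |>
    filter(.data$steps <= !!limit) |>
    arrange(.data$steps, .data$i, .data$j)

  parent <- seq_len(h)
  find <- function(v) {
    while (parent[v] != v) v <- parent[v]
    v
  }
  in_msn <- logical(nrow(cand))
  keep <- logical(nrow(cand))
  mst_adj <- vector("list", h)          # adjacency of accepted tree edges
  mst_w <- vector("list", h)
  for (r in seq_len(nrow(cand))) {
    a <- cand$i[r]; b <- cand$j[r]
    ra <- find(a); rb <- find(b)
    if (ra != rb) {
      parent[ra] <- rb
      in_msn[r] <- TRUE
      keep[r] <- TRUE
      mst_adj[[a]] <- c(mst_adj[[a]], b); mst_w[[a]] <- c(mst_w[[a]], cand$steps[r])
      mst_adj[[b]] <- c(mst_adj[[b]], a); mst_w[[b]] <- c(mst_w[[b]], cand$steps[r])
    } else {
      ## bottleneck weight on the spanning path a..b
      if (cand$steps[r] == path_bottleneck(mst_adj, mst_w, a, b)) {
        keep[r] <- TRUE
      }
    }
  }
  edges <- cand[keep, , drop = FALSE] |>
    mutate(from = ids[.data$i], to = ids[.data$j],
           in_msn = in_msn[keep]) |>
    select("from", "to", "steps", "in_msn")
  new_hap_network(x$gene_id, nodes, edges, limit)
}

## Maximum edge weight on the unique tree path between a and b
## (Inf if disconnected). Graphs are small; plain DFS.
path_bottleneck <- function(adj, w, a, b) {
  seen <- logical(length(adj))
  stack <- list(list(v = a, mx = 0L))
  seen[a] <- TRUE
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (top$v == b) return(top$mx)
    nb <- adj[[top$v]]
    for (k in seq_along(nb)) {
      if (!seen[nb[k]]) {
        seen[nb[k]] <- TRUE
        stack <- c(stack, list(list(v = nb[k], mx = max(top$mx, w[[top$v]][k]))))
      }
    }
  }
  Inf
}

new_hap_network <- function(gene_id, nodes, edges, limit) {
  structure(list(gene_id = gene_id, nodes = nodes, edges = edges,
                 limit = limit),
            class = "hap_network")
}

#' @export
print.hap_network <- function(x, ...) {
  cat("<hap_network> gene ", x$gene_id, ": ", nrow(x$nodes), " node(s), ",
      nrow(x$edges), " edge(s) (", sum(x$edges$in_msn),
      " spanning), limit = ",
      if (is.finite(x$limit)) x$limit else "unlimited", "\n", sep = "")
  invisible(x)
}

#' @describeIn build_network one-row summary: node/edge counts, total
#'   spanning weight, number of connected components.
#' @param ... Unused.
#' @export
glance.hap_network <- function(x, ...) {
  tibble(
    gene_id = x$gene_id,
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_msn_edges = sum(x$edges$in_msn),
    msn_weight = sum(x$edges$steps[x$edges$in_msn]),
    n_components = network_components(x)
  )
}

network_components <- function(x) {
  ids <- x$nodes$hap_id
  parent <- seq_along(ids)
  find <- function(v) { while (parent[v] != v) v <- parent[v]; v }
  for (r in seq_len(nrow(x$edges))) {
    a <- match(x$edges$from[r], ids); b <- match(x$edges$to[r], ids)
    parent[find(a)] <- find(b)
  }
  length(unique(vapply(seq_along(ids), find, integer(1))))
}

#' Export / import a haplotype network as a node + edge TSV pair
#'
#' The node table carries per-population counts (for pie-style
#' annotation downstream); the edge table carries `steps` and `in_msn`.
#' `read_network()` restores an equivalent `hap_network`.
#'
#' @param net A `hap_network`.
#' @param node_path,edge_path TSV paths.
#' @return `export_network()` the network invisibly; `read_network()` a
#'   `hap_network`.
#' @export
export_network <- function(net, node_path, edge_path) {
  write_tsv(mutate(net$nodes, gene_id = net$gene_id,
                   limit = if (is.finite(net$limit)) as.character(net$limit)
                           else "unlimited", .before = 1),
            node_path, na = "")
  write_tsv(mutate(net$edges, gene_id = net$gene_id, .before = 1),
            edge_path, na = "")
  invisible(net)
}

#' @rdname export_network
#' @export
read_network <- function(node_path, edge_path) {
  nodes <- read_tsv(node_path, col_types = cols(
    gene_id = col_character(), limit = col_character(),
    hap_id = col_character(), count = col_integer(), freq = col_double(),
    .default = col_integer()), progress = FALSE)
  edges <- read_tsv(edge_path, col_types = cols(
    gene_id = col_character(), from = col_character(), to = col_character(),
    steps = col_integer(), in_msn = readr::col_logical()), progress = FALSE)
  limit <- if (nrow(nodes) && nodes$limit[1] != "unlimited") {
    as.numeric(nodes$limit[1])
  } else Inf
  new_hap_network(
    gene_id = if (nrow(nodes)) nodes$gene_id[1] else NA_character_,
    nodes = select(nodes, -"gene_id", -"limit"),
    edges = select(edges, -"gene_id"),
    limit = limit
  )
}
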
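#' Read gene models (CDS intervals) from a GFF3 file
#'
#' Extracts one gene model per gene from the CDS features of a GFF3 file.
#' The gene identifier of each CDS is resolved by following the
#' `Parent`/`ID` attribute chain (CDS -> mRNA -> gene); a `gene_id`
#' attribute or a bare `Parent` pointing at an undeclared feature is also
#' accepted. Intervals of a gene are sorted and merged when they overlap or
#' are book-ended (adjacent). Coordinates are kept 1-based inclusive, the
#' native GFF3/VCF convention, end to end.
#'
#' @param path Path to a GFF3 file.
#' @param feature Feature type carrying the coding intervals (default `"CDS"`).
#' @return A `gene_models` tibble with one row per (merged) interval:
#'   columns `gene_id`, `chromosome`, `strand`, `start`, `end`, sorted by
#'   gene then start. An empty file yields an empty tibble with a warning.
#' @export
read_gff3 <- function(path, feature = "CDS") {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  data_lines <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(data_lines) == 0) {
    warn(paste0("read_gff3: no feature lines in ", basename(path)))
    return(empty_gene_models())
  }

  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  if (nrow(g) == 0 || !any(g$type == feature)) {
    warn(paste0("read_gff3: no ", feature, " features in ", basename(path)))
    return(empty_gene_models())
  }

  ids <- if ("ID" %in% names(g)) as.character(g$ID) else rep(NA_character_, nrow(g))
  parents <- first_attr(g, "Parent")
  gene_attr <- first_attr(g, "gene_id")
  type_of <- setNames(as.character(g$type), ids)
  parent_of <- setNames(parents, ids)

  is_cds <- which(g$type == feature)
  ## File line numbers of the feature's rows, for error reporting
  ## (readGFF preserves file order of feature lines).
  cds_lines <- data_lines[which(
    vapply(strsplit(lines[data_lines], "\t", fixed = TRUE),
           function(f) length(f) >= 3 && f[3] == feature, logical(1)))]

  gene_id <- character(length(is_cds))
  for (k in seq_along(is_cds)) {
    i <- is_cds[k]
    gid <- resolve_gene_id(ids[i], parents[i], gene_attr[i], type_of, parent_of)
    if (is.na(gid)) {
      line_no <- if (k <= length(cds_lines)) cds_lines[k] else NA_integer_
      abort(paste0(
        "read_gff3: ", feature, " feature with no resolvable gene id",
        if (!is.na(line_no)) paste0(" at line ", line_no, ": ",
                                    lines[line_no])
        else paste0(" (", g$seqid[i], ":", g$start[i], "-", g$end[i], ")")
      ))
    }
    gene_id[k] <- gid
  }

  raw <- tibble(
    gene_id = gene_id,
    chromosome = as.character(g$seqid[is_cds]),
    strand = as.character(g$strand[is_cds]),
    start = as.integer(g$start[is_cds]),
    end = as.integer(g$end[is_cds])
  )
  models <- raw |>
    group_by(.data$gene_id, .data$chromosome) |>
    summarise(intervals = list(merge_intervals(.data$start, .data$end)),
              strand = resolve_strand(.data$strand, .data$gene_id[1]),
              .groups = "drop") |>
    tidyr::unnest("intervals") |>
    select("gene_id", "chromosome", "strand", "start", "end") |>
    arrange(.data$gene_id, .data$start)
  new_gene_models(models)
}

first_attr <- function(g, name) {
  if (!name %in% names(g)) return(rep(NA_character_, nrow(g)))
  col <- g[[name]]
  if (is.list(col)) {
    vapply(col, function(x) if (length(x)) as.character(x[[1]]) else NA_character_,
           character(1))
  } else {
    as.character(col)
  }
}

resolve_gene_id <- function(id, parent, gene_attr, type_of, parent_of) {
  if (!is.na(gene_attr) && nzchar(gene_attr)) return(gene_attr)
  cur <- parent
  if (is.na(cur) || !nzchar(cur)) {
    ## no Parent: a CDS whose own ID is a declared gene, else unresolvable
    if (!is.na(id) && identical(unname(type_of[id]), "gene")) return(id)
    return(NA_character_)
  }
  for (depth in 1:10) {   # bounded walk; GFF3 chains are shallow
    ty <- unname(type_of[cur])
    if (is.na(ty)) return(cur)      # Parent points at an undeclared feature
    if (ty == "gene") return(cur)
    nxt <- unname(parent_of[cur])
    if (is.na(nxt) || !nzchar(nxt)) return(cur)  # topmost ancestor
    cur <- nxt
  }
  cur
}

resolve_strand <- function(strand, gene_id) {
  s <- unique(strand)
  s <- s[s %in% c("+", "-")]
  if (length(s) == 0) return("+")
  if (length(s) > 1) {
    warn(paste0("read_gff3: conflicting strands for gene ", gene_id,
                "; keeping ", s[1]))
  }
  s[1]
}

## Merge sorted 1-based inclusive intervals that overlap or are book-ended.
merge_intervals <- function(start, end) {
  if (any(end < start)) abort("interval end < start in gene model")
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1L) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  tibble(start = c(out_s, ms), end = c(out_e, me))
}

new_gene_models <- function(df) {
  stopifnot(all(c("gene_id", "chromosome", "strand", "start", "end") %in%
                  names(df)))
  class(df) <- unique(c("gene_models", class(df)))
  df
}

empty_gene_models <- function() {
  new_gene_models(tibble(gene_id = character(), chromosome = character(),
                         strand = character(), start = integer(),
                         end = integer()))
}

#' Construct gene models from vectors
#'
#' Programmatic counterpart of [read_gff3()]: validates, sorts, and merges
#' book-ended intervals.
#'
#' @param gene_id,chromosome,strand,start,end Parallel vectors, one entry
#'   per CDS interval; `strand` in `{"+", "-"}`.
#' @return A `gene_models` tibble.
#' @export
gene_models <- function(gene_id, chromosome, strand, start, end) {
  if (any(strand %notin% c("+", "-"))) abort('strand must be "+" or "-"')
  if (any(end < start)) abort("interval end < start")
  raw <- tibble(gene_id = as.character(gene_id),
                chromosome = as.character(chromosome),
                strand = as.character(strand),
                start = as.integer(start), end = as.integer(end))
  out <- raw |>
    group_by(.data$gene_id, .data$chromosome, .data$strand) |>
    summarise(intervals = list(merge_intervals(.data$start, .data$end)),
              .groups = "drop") |>
    tidyr::unnest("intervals") |>
    select("gene_id", "chromosome", "strand", "start", "end") |>
    arrange(.data$gene_id, .data$start)
  new_gene_models(out)
}
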
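#' Resolved run configuration for the analysis pipeline
#'
#' Bundles input paths and thresholds; validated once, written as JSON next
#' to the outputs of every run so results are self-describing.
#'
#' @param vcf,gff,panel,traits Input file paths (`traits` may be `NULL` to
#'   skip the association stage).
#' @param out_dir Output directory.
#' @param major_threshold Major-haplotype frequency threshold in (0, 1].
#' @param strong_p "Strong association" p-value threshold.
#' @param alpha Significance level for pairwise comparisons.
#' @param min_n Minimum phenotyped accessions per haplotype group.
#' @param reps Permutation replicates for the shift test.
#' @param seed RNG seed.
#' @param limit Network connection limit in mutation steps (`Inf` =
#'   unlimited).
#' @param groups Population groups for the landrace/modern shift stage.
#' @param policy Missing/het policy for the caller.
#' @return A validated list of class `run_config`.
#' @export
pipeline_config <- function(vcf, gff, panel, traits = NULL, out_dir,
                            major_threshold = 0.01, strong_p = 1e-7,
                            alpha = 0.05, min_n = 10, reps = 10000,
                            seed = 1, limit = Inf,
                            groups = c("Xian", "Geng"),
                            policy = "exclude") {
  if (major_threshold <= 0 || major_threshold > 1) {
    abort("major_threshold must be in (0, 1]")
  }
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (strong_p <= 0 || strong_p >= 1) abort("strong_p must be in (0, 1)")
  if (min_n < 1) abort("min_n must be >= 1")
  if (reps < 1) abort("reps must be >= 1")
  if (is.finite(limit) && limit < 1) abort("limit must be >= 1 or Inf")
  check_vocab(groups, .POPULATIONS, .POP_ALIASES, "population")
  structure(
    list(vcf = vcf, gff = gff, panel = panel, traits = traits,
         out_dir = out_dir, major_threshold = major_threshold,
         strong_p = strong_p, alpha = alpha, min_n = as.integer(min_n),
         reps = as.integer(reps), seed = as.integer(seed), limit = limit,
         groups = groups, policy = policy),
    class = "run_config")
}

#' Run the gcHap analysis pipeline
#'
#' Executes the requested stages and writes all result tables as TSV under
#' `config$out_dir`, plus the resolved configuration as
#' `run_config.json`. Stages after `call` read the caller's TSV outputs,
#' so each stage can also be run on its own once `call` has run; a stage
#' whose inputs are missing fails naming the missing file. A structured
#' log (via `message()`) reports record counts at every filter.
#'
#' Stage outputs: `call` writes `gchap_assignments.tsv` +
#' `gchap_summary.tsv`; `diversity` writes `diversity.tsv`, `nei.tsv`,
#' `fst.tsv`; `shift` writes `shift_<group>.tsv` and `drift_<group>.tsv`
#' per group with both classes; `assoc` writes `assoc.tsv`,
#' `fav_unfav.tsv`, `fav_unfav_summary.tsv`; `network` writes
#' `network_<gene>_nodes.tsv` / `_edges.tsv` per gene.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages to run, subset of
#'   `c("call", "diversity", "shift", "assoc", "network")`, or `"all"`.
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config, stages = "all") {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("call", "diversity", "shift", "assoc", "network")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  results <- list()

  panel <- read_panel(config$panel)
  inform(paste0("panel: ", nrow(panel), " accessions (",
                paste0(names(table(panel$population)), "=",
                       table(panel$population), collapse = ", "), ")"))

  if ("call" %in% stages) {
    variants <- read_vcf(config$vcf)
    inform(paste0("vcf: ", nrow(variants$sites), " SNP sites, ",
                  length(variants$samples), " samples, ",
                  variants$skipped, " non-SNP records skipped"))
    genes <- read_gff3(config$gff)
    inform(paste0("gff3: ", n_distinct(genes$gene_id), " genes, ",
                  nrow(genes), " CDS intervals"))
    tables <- call_gchap_tables(variants, genes, panel,
                                policy = config$policy)
    for (x in tables) {
      inform(paste0("call ", x$gene_id, ": ", nrow(x$sites),
                    " CDS sites, ", nrow(x$haps), " haplotypes (",
                    length(major_gchaps(x, config$major_threshold)),
                    " major), ", x$excluded_count, " accessions excluded"))
    }
    write_gchap_tables(tables, out("gchap_assignments.tsv"),
                       out("gchap_summary.tsv"))
    results$tables <- tables
  } else {
    tables <- read_gchap_tables(out("gchap_assignments.tsv"),
                                out("gchap_summary.tsv"), panel)
    results$tables <- tables
  }

  if ("diversity" %in% stages) {
    div <- diversity_table(tables, threshold = config$major_threshold)
    write_tsv(div, out("diversity.tsv"), na = "")
    pops <- intersect(.POPULATIONS, unique(panel$population))
    if (length(pops) >= 2) {
      write_tsv(nei_table(tables, pops), out("nei.tsv"), na = "")
      write_tsv(fst_table(tables, pops), out("fst.tsv"), na = "")
    }
    inform(paste0("diversity: ", nrow(div), " gene x population rows"))
    results$diversity <- div
  }

  if ("shift" %in% stages) {
    for (grp in config$groups) {
      cls <- table(panel$variety_class[panel$population == grp])
      if (!all(c("LAN", "MV") %in% names(cls))) {
        inform(paste0("shift: skipping group ", grp,
                      " (needs both LAN and MV accessions)"))
        next
      }
      st <- shift_table(tables, grp, reps = config$reps, seed = config$seed)
      write_shift_tsv(st, out(paste0("shift_", grp, ".tsv")))
      dr <- drift_table(tables, grp, config$major_threshold)
      write_tsv(dr, out(paste0("drift_", grp, ".tsv")), na = "")
      inform(paste0("shift ", grp, ": ", sum(st$gene_id != "(mean)"),
                    " genes, ",
                    sum(st$selection_label == "up", na.rm = TRUE),
                    " significant"))
      results$shift[[grp]] <- st
      results$drift[[grp]] <- dr
    }
  }

  if ("assoc" %in% stages) {
    if (is.null(config$traits)) {
      inform("assoc: no trait table configured; stage skipped")
    } else {
      traits <- read_traits(config$traits)
      assoc <- assoc_scan(tables, traits, min_n = config$min_n,
                          threshold = config$major_threshold,
                          alpha = config$alpha, strong_p = config$strong_p)
      write_tsv(assoc, out("assoc.tsv"), na = "")
      fu <- fav_unfav_scan(tables, traits,
                           threshold = config$major_threshold,
                           alpha = config$alpha)
      write_tsv(as_tibble(fu), out("fav_unfav.tsv"), na = "")
      write_tsv(glance(fu), out("fav_unfav_summary.tsv"), na = "")
      inform(paste0("assoc: ",
                    sum(assoc$analyzable & !duplicated(
                      paste(assoc$gene_id, assoc$trait))),
                    " analyzable gene x trait cases; fav/unfav: ",
                    glance(fu)$detected, " of ", glance(fu)$attempted,
                    " comparisons different"))
      results$assoc <- assoc
      results$fav_unfav <- fu
    }
  }

  if ("network" %in% stages) {
    for (x in tables) {
      net <- build_network(x, limit = config$limit)
      export_network(net,
                     out(paste0("network_", x$gene_id, "_nodes.tsv")),
                     out(paste0("network_", x$gene_id, "_edges.tsv")))
      results$networks[[x$gene_id]] <- net
    }
    inform(paste0("network: ", length(tables), " gene networks written"))
  }

  cfg <- unclass(config)
  cfg$limit <- if (is.finite(cfg$limit)) cfg$limit else "unlimited"
  jsonlite::write_json(cfg, out("run_config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(results)
}

## Shift TSV mirrors the published table style: equitability columns at
## 3 decimals for display, delta columns kept at full precision alongside.
write_shift_tsv <- function(st, path) {
  disp <- st |>
    mutate(EH_LAN = round(.data$EH_LAN, 3), EH_MV = round(.data$EH_MV, 3),
           delta_EH_display = round(.data$delta_EH, 3)) |>
    relocate("delta_EH_display", .after = "delta_EH")
  write_tsv(disp, path, na = "")
  invisible(st)
}
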
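#' Read and validate an accession panel table
#'
#' The panel TSV must carry a header with columns `accession`, `population`
#' (one of `r paste(gchap_populations(), collapse = ", ")`) and
#' `variety_class` (`LAN`, `MV`, `other`). Unknown tokens are rejected with
#' a suggestion where a common alias is recognised; accessions must be
#' unique.
#'
#' @param path Path to a tab-separated panel file with header.
#' @return A validated tibble with columns `accession`, `population`,
#'   `variety_class`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("panel file not found: ", path))
  df <- read_tsv(path, col_types = cols(.default = col_character()),
                 progress = FALSE)
  need <- c("accession", "population", "variety_class")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("panel file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  accession_panel(df$accession, df$population, df$variety_class)
}

#' Construct an accession panel
#'
#' @param accession Character vector of unique accession ids.
#' @param population Population label per accession.
#' @param variety_class Variety class per accession.
#' @return A validated tibble (`accession`, `population`, `variety_class`).
#' @export
accession_panel <- function(accession, population, variety_class) {
  accession <- as.character(accession)
  dup <- accession[duplicated(accession)]
  if (length(dup)) {
    abort(paste0("duplicate accession id(s) in panel: ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (anyNA(accession) || any(!nzchar(accession))) {
    abort("accession ids must be non-missing and non-empty")
  }
  if (anyNA(population) || anyNA(variety_class)) {
    abort("population and variety_class must be defined for every accession")
  }
  check_vocab(population, .POPULATIONS, .POP_ALIASES, "population")
  check_vocab(variety_class, .CLASSES, .CLASS_ALIASES, "variety_class")
  tibble(accession = accession,
         population = as.character(population),
         variety_class = as.character(variety_class))
}

#' Read a phenotype table
#'
#' Wide TSV: one `accession` column plus one numeric column per trait.
#' Trait names must belong to the declared vocabulary ([gchap_traits()]).
#' Blank cells are preserved as missing values, never imputed.
#'
#' @param path Path to the phenotype TSV.
#' @return A tibble with `accession` and one numeric column per trait.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) abort(paste0("trait file not found: ", path))
  df <- read_tsv(path, col_types = cols(accession = col_character(),
                                        .default = col_double()),
                 progress = FALSE, na = c("", "NA"))
  if ("accession" %notin% names(df)) {
    abort("trait file lacks an 'accession' column")
  }
  validate_traits(df)
}

validate_traits <- function(df) {
  bad <- setdiff(names(df), c("accession", .TRAITS$trait))
  if (length(bad)) {
    abort(paste0("unknown trait column(s): ", paste(bad, collapse = ", "),
                 "; declared traits are: ",
                 paste(.TRAITS$trait, collapse = ", ")))
  }
  dup <- df$accession[duplicated(df$accession)]
  if (length(dup)) {
    abort(paste0("duplicate accession id(s) in trait table: ",
                 paste(unique(dup), collapse = ", ")))
  }
  df
}

#' Write panel / phenotype tables
#'
#' Writers paired with [read_panel()] and [read_traits()]; a write-then-read
#' round trip reproduces the input exactly (missing trait cells stay blank).
#'
#' @param panel,traits Tibbles as returned by the paired readers.
#' @param path Output TSV path.
#' @return The input, invisibly.
#' @export
write_panel <- function(panel, path) {
  accession_panel(panel$accession, panel$population, panel$variety_class)
  write_tsv(panel, path, na = "")
  invisible(panel)
}

#' @rdname write_panel
#' @export
write_traits <- function(traits, path) {
  validate_traits(traits)
  write_tsv(traits, path, na = "")
  invisible(traits)
}
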
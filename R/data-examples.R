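#' Published OsDLH landrace/modern-variety diversity summaries
#'
#' Per-gene Shannon equitability and gcHap counts reported for the 11
#' OsDLH (1,3-1,4-beta-D-glucanase) genes of rice in the 3,010-accession
#' panel, comparing landraces (LAN) with modern varieties (MV) within the
#' Xian (indica) and Geng (japonica) populations, together with the
#' reported significance codes and artificial-selection labels. Bundled as
#' plain TSV so the package's aggregation path ([shift_summary()]) can be
#' exercised against published numbers without any download.
#'
#' @param group `"Xian"` or `"Geng"`.
#' @return Tibble with columns `gene_id`, `EH_LAN`, `gcHapN_LAN`,
#'   `EH_MV`, `gcHapN_MV`, `significance`, `selection_label`.
#' @examples
#' shift_summary(osdlh_shift_example("Xian"))
#' @export
osdlh_shift_example <- function(group = c("Xian", "Geng")) {
  group <- match.arg(group)
  path <- system.file("extdata",
                      paste0("osdlh_shift_", tolower(group), ".tsv"),
                      package = "gchapr", mustWork = TRUE)
  read_tsv(path, col_types = cols(
    gene_id = col_character(), EH_LAN = col_double(),
    gcHapN_LAN = col_double(), EH_MV = col_double(),
    gcHapN_MV = col_double(), significance = col_character(),
    selection_label = col_character()), progress = FALSE)
}
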
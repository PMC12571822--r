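## Controlled vocabularies shared by the whole pipeline.

.POPULATIONS <- c("Xian", "Geng", "Aus", "Bas", "Admix")
.CLASSES <- c("LAN", "MV", "other")

## Aliases only used to make vocabulary errors actionable; never applied
## silently.
.POP_ALIASES <- c(
  Indica = "Xian", indica = "Xian", XI = "Xian",
  Japonica = "Geng", japonica = "Geng", GJ = "Geng",
  Basmati = "Bas", Admixed = "Admix", Mixed = "Admix", admix = "Admix"
)
.CLASS_ALIASES <- c(
  landrace = "LAN", Landrace = "LAN", TRJ = "LAN",
  modern = "MV", improved = "MV", Other = "other"
)

## The 15 agronomic traits of the 3KRG phenotype tables, with units and a
## plausible panel-level baseline used by the synthetic generator.
.TRAITS <- data.frame(
  trait = c("DTH", "PH", "FLL", "FLW", "PN", "PL", "CN", "CL",
            "GL", "GW", "GLWR", "TGW", "LRI", "SH", "LL"),
  unit = c("day", "cm", "cm", "cm", "count", "cm", "count", "cm",
           "mm", "mm", "ratio", "g", "%", "cm", "mm"),
  description = c(
    "days to heading", "plant height", "flag leaf length", "flag leaf width",
    "panicle number", "panicle length", "culm number", "culm length",
    "grain length", "grain width", "grain length-to-width ratio",
    "1000-grain weight", "leaf rolling index", "seedling height",
    "lemma length"),
  baseline = c(95, 115, 30, 1.5, 10, 23, 11, 90, 8.5, 2.8, 3.1, 25, 20, 18, 8),
  stringsAsFactors = FALSE
)

#' Controlled vocabularies of the pipeline
#'
#' `gchap_populations()` returns the recognised population labels of the
#' 3,010-accession rice panel structure (Xian = indica, Geng = japonica,
#' Aus, Bas = basmati-like, Admix). `gchap_classes()` returns the variety
#' classes (LAN = landrace, MV = modern variety, other).
#' `gchap_traits()` returns the 15 agronomic traits with their units.
#'
#' @return A character vector (`gchap_populations()`, `gchap_classes()`)
#'   or a tibble with columns `trait`, `unit`, `description`, `baseline`
#'   (`gchap_traits()`).
#' @examples
#' gchap_populations()
#' gchap_traits()
#' @export
gchap_populations <- function() .POPULATIONS

#' @rdname gchap_populations
#' @export
gchap_classes <- function() .CLASSES

#' @rdname gchap_populations
#' @export
gchap_traits <- function() as_tibble(.TRAITS)

## Genotype codes used throughout: non-negative integer = allele index
## (0 = REF), -1 = heterozygous call, NA = missing call.
GT_HET <- -1L

check_vocab <- function(x, vocab, aliases, what) {
  bad <- setdiff(unique(x[!is.na(x)]), vocab)
  if (length(bad) == 0) return(invisible(TRUE))
  hints <- aliases[bad]
  hint_txt <- if (any(!is.na(hints))) {
    known <- bad[!is.na(hints)]
    paste0(" (did you mean ", paste0('"', hints[!is.na(hints)], '" for "',
                                     known, '"', collapse = ", "), "?)")
  } else ""
  abort(paste0(
    "unknown ", what, " token(s): ", paste0('"', bad, '"', collapse = ", "),
    hint_txt, "; valid tokens are: ", paste(vocab, collapse = ", ")
  ))
}

## Derive a per-stream 32-bit seed from a master seed; stable in k so that
## per-gene streams do not move when the number of genes changes.
derive_seed <- function(master, k) {
  v <- ((as.numeric(master) %% 1000003) * 2053 + as.numeric(k) * 7919) %%
    2147483587
  as.integer(v) + 1L
}

## Shannon equitability from a count (or frequency) vector; the numerical
## core shared by the diversity and shift modules.
eh_from_counts <- function(counts) {
  p <- counts[counts > 0]
  s <- length(p)
  if (s == 0) return(NA_real_)
  if (s == 1) return(0)
  p <- p / sum(p)
  -sum(p * log(p)) / log(s)
}

`%notin%` <- function(x, table) !(x %in% table)
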
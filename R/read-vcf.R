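#' Read SNP genotypes from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and retains SNP records only:
#' `REF` and every `ALT` allele must be a single base. Indel/MNP records are
#' skipped and counted. Genotypes are decoded to integer allele indices
#' (0 = REF, 1..k = ALT), with two special codes: `NA` for missing calls
#' (any `.` in the genotype) and `-1` for heterozygous calls. Phased and
#' unphased genotypes are treated identically, as are haploid-style single
#' allele calls ("1" equals "1/1").
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @return An object of class `gchap_variants`: a list with
#'   \describe{
#'     \item{sites}{tibble with one row per retained SNP: `chrom`, `pos`,
#'       `id`, `ref`, `alt` (list column of ALT alleles).}
#'     \item{gt}{integer matrix, sites x accessions, coded as above.}
#'     \item{samples}{accession ids in VCF column order.}
#'     \item{skipped}{number of non-SNP records dropped.}
#'   }
#' @seealso [gchap_variants()] to build the same structure programmatically,
#'   [call_gchaps()] for the downstream haplotype caller.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))

  ## Structural pre-validation so that malformed files fail with a line
  ## number instead of a downstream parser message.
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^#CHROM\t", lines)
  if (length(hdr_idx) != 1) {
    abort(paste0("malformed VCF header in ", path,
                 ": expected exactly one #CHROM column line, found ",
                 length(hdr_idx)))
  }
  n_hdr <- length(strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]])
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(body)) {
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    bad <- which(nf != n_hdr)
    if (length(bad)) {
      abort(paste0("VCF parse error at line ", body[bad[1]], ": record has ",
                   nf[bad[1]], " fields but the header declares ", n_hdr))
    }
  }

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fm <- vcfR::getFIX(v)
  if (is.null(dim(fm))) {   # single-record files come back as a bare vector
    fm <- matrix(fm, nrow = 1,
                 dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                         "QUAL", "FILTER")))
  }
  fix <- as.data.frame(fm, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(gchap_variants(character(), integer(), character(), list(),
                          gt = matrix(integer(), 0, max(0, n_hdr - 9)),
                          samples = vcf_sample_names(lines[hdr_idx]),
                          skipped = 0L))
  }

  alts <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  is_snp <- nchar(fix$REF) == 1 &
    vapply(alts, function(a) all(nchar(a) == 1), logical(1))
  skipped <- sum(!is_snp)

  samples <- if (!is.null(v@gt)) colnames(v@gt)[-1] else character()
  if (length(samples)) {
    gt_raw <- vcfR::extract.gt(v, element = "GT")
    gt <- decode_gt_matrix(gt_raw)[is_snp, , drop = FALSE]
  } else {
    gt <- matrix(integer(), sum(is_snp), 0)
  }

  fix <- fix[is_snp, , drop = FALSE]
  out <- gchap_variants(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID), ".", fix$ID),
    ref = fix$REF, alt = alts[is_snp],
    gt = gt, samples = samples, skipped = as.integer(skipped)
  )
  if (skipped > 0) {
    inform(paste0("read_vcf: skipped ", skipped, " non-SNP record(s) in ",
                  basename(path)))
  }
  out
}

vcf_sample_names <- function(header_line) {
  f <- strsplit(header_line, "\t", fixed = TRUE)[[1]]
  if (length(f) > 9) f[-(1:9)] else character()
}

#' Construct a SNP genotype set programmatically
#'
#' Low-level constructor behind [read_vcf()], exported so that tests and
#' simulations can build variant sets without touching the file system.
#'
#' @param chrom,pos,ref Character/integer/character vectors, one entry per site.
#' @param id Site identifiers (defaults to `"."`).
#' @param alt List of character vectors of ALT alleles per site.
#' @param gt Integer matrix, sites x accessions; `NA` = missing, `-1` = het,
#'   otherwise the allele index.
#' @param samples Accession ids, one per genotype column.
#' @param skipped Count of records dropped upstream (bookkeeping only).
#' @return A `gchap_variants` object.
#' @export
gchap_variants <- function(chrom, pos, ref, alt, gt, samples,
                           id = rep(".", length(chrom)), skipped = 0L) {
  pos <- as.integer(pos)
  if (length(pos) && any(pos < 1)) abort("variant positions must be >= 1")
  if (length(ref) && any(!nzchar(ref))) abort("REF alleles must be non-empty")
  if (!is.matrix(gt)) gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  if (nrow(gt) != length(chrom) || ncol(gt) != length(samples)) {
    abort("genotype matrix must be sites x samples")
  }
  dimnames(gt) <- list(NULL, samples)
  structure(
    list(
      sites = tibble(chrom = as.character(chrom), pos = pos,
                     id = as.character(id), ref = as.character(ref),
                     alt = alt),
      gt = gt,
      samples = as.character(samples),
      skipped = as.integer(skipped)
    ),
    class = "gchap_variants"
  )
}

#' @export
print.gchap_variants <- function(x, ...) {
  cat("<gchap_variants> ", nrow(x$sites), " SNP site(s) x ",
      length(x$samples), " accession(s)", sep = "")
  if (x$skipped > 0) cat(" [", x$skipped, " non-SNP record(s) skipped]", sep = "")
  cat("\n")
  if (nrow(x$sites)) print(head(x$sites, 5))
  invisible(x)
}

#' @describeIn read_vcf long-format view: one row per site x accession with
#'   the decoded genotype code.
#' @param x A `gchap_variants` object.
#' @param ... Unused.
#' @export
tidy.gchap_variants <- function(x, ...) {
  if (length(x$samples) == 0 || nrow(x$sites) == 0) {
    return(tibble(chrom = character(), pos = integer(),
                  accession = character(), genotype = integer()))
  }
  g <- x$gt
  tibble(
    chrom = rep(x$sites$chrom, times = ncol(g)),
    pos = rep(x$sites$pos, times = ncol(g)),
    accession = rep(colnames(g), each = nrow(g)),
    genotype = as.integer(g)
  )
}

## Decode a matrix of raw GT strings to integer codes. Few unique strings
## occur, so decode the unique set and index back.
decode_gt_matrix <- function(gt_raw) {
  u <- unique(as.vector(gt_raw))
  codes <- vapply(u, decode_gt_one, integer(1))
  out <- matrix(codes[match(as.vector(gt_raw), u)],
                nrow = nrow(gt_raw), dimnames = dimnames(gt_raw))
  storage.mode(out) <- "integer"
  out
}

decode_gt_one <- function(s) {
  if (is.na(s)) return(NA_integer_)
  s <- sub(":.*$", "", s)
  s <- gsub("|", "/", s, fixed = TRUE)
  parts <- strsplit(s, "/", fixed = TRUE)[[1]]
  if (length(parts) == 0 || any(parts == ".") || any(!nzchar(parts))) {
    return(NA_integer_)
  }
  al <- suppressWarnings(as.integer(parts))
  if (anyNA(al)) return(NA_integer_)
  if (length(unique(al)) > 1) return(GT_HET)
  al[1]
}
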
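test_that("CDS site selection is boundary-inclusive and excludes intron gaps", {
  v <- gchap_variants(chrom = rep("chr1", 5),
                      pos = c(99L, 100L, 150L, 200L, 201L),
                      ref = rep("A", 5), alt = rep(list("T"), 5),
                      gt = matrix(0L, 5, 2), samples = c("s1", "s2"))
  g <- gene_models("gA", "chr1", "+", start = 100, end = 200)
  expect_equal(unname(select_cds_sites(v, g)), c(2L, 3L, 4L))

  g2 <- gene_models(rep("gB", 2), "chr1", "+",
                    start = c(90, 190), end = c(110, 210))
  expect_equal(unname(select_cds_sites(v, g2)), c(1L, 2L, 4L, 5L))  # 150 in gap
})

test_that("CDS site selection equals a brute-force membership test", {
  set.seed(7)
  for (rep in 1:5) {
    pos <- sort(sample.int(1000, 50))
    v <- gchap_variants(chrom = rep("chr1", 50), pos = pos,
                        ref = rep("A", 50), alt = rep(list("T"), 50),
                        gt = matrix(0L, 50, 1), samples = "s1")
    starts <- sort(sample.int(1000, 3))
    ends <- pmin(starts + sample.int(120, 3), 1000L)
    g <- gene_models(rep("gR", 3), "chr1", "+", start = starts, end = ends)
    ## oracle: exhaustive per-position membership against the merged model
    expected <- which(vapply(pos, function(p) {
      any(p >= g$start & p <= g$end)
    }, logical(1)))
    expect_equal(unname(select_cds_sites(v, g)), expected)
  }
})

test_that("haplotypes are grouped, ranked and named by global frequency", {
  vectors <- rbind(c(0, 0), c(0, 0), c(0, 1), c(0, 1), c(0, 0))
  fx <- fixture_from_vectors(vectors)
  x <- call_gchaps(fx$variants, fx$genes, fx$panel)
  expect_equal(x$haps$hap_id, c("Hap1", "Hap2"))
  expect_equal(x$haps$count, c(3L, 2L))
  expect_equal(x$haps$alleles[[1]], c(0L, 0L))
  expect_equal(x$assignment$hap_id,
               c("Hap1", "Hap1", "Hap2", "Hap2", "Hap1"))
  ## count ties: first-occurrence order decides the rank deterministically
  fx2 <- fixture_from_vectors(rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1)))
  x2 <- call_gchaps(fx2$variants, fx2$genes, fx2$panel)
  expect_equal(x2$haps$count, c(2L, 2L))
  expect_equal(x2$haps$alleles[[1]], c(1L, 0L))   # seen first
})

test_that("missing and heterozygous calls follow the declared policy", {
  vectors <- rbind(c(0, 0), c(0, 0), c(1, 1))
  fx <- fixture_from_vectors(vectors)
  fx$variants$gt[1, 3] <- NA_integer_          # S003 missing at site 1
  x <- call_gchaps(fx$variants, fx$genes, fx$panel)
  expect_equal(x$excluded_count, 1L)
  expect_equal(x$n, 2L)
  expect_true(x$assignment$excluded[3])

  x_fill <- call_gchaps(fx$variants, fx$genes, fx$panel, policy = "ref_fill")
  expect_equal(x_fill$excluded_count, 0L)
  ## the missing call becomes reference: S003 carries (0, 1)
  expect_equal(x_fill$haps$count, c(2L, 1L))

  fx$variants$gt[2, 2] <- -1L                  # S002 heterozygous
  x2 <- call_gchaps(fx$variants, fx$genes, fx$panel)
  expect_equal(x2$excluded_count, 2L)
})

test_that("a gene with zero CDS SNPs yields one haplotype holding everyone", {
  fx <- fixture_from_vectors(matrix(0L, 10, 1))
  g <- gene_models("gEmpty", "chr1", "+", start = 5000, end = 5100)
  x <- call_gchaps(fx$variants, g, fx$panel)
  expect_equal(nrow(x$haps), 1)
  expect_equal(x$haps$count, 10L)
  expect_equal(x$haps$alleles[[1]], integer())
  expect_equal(x$excluded_count, 0L)
})

test_that("counts are conserved and calling is permutation-invariant", {
  set.seed(11)
  for (policy in c("exclude", "ref_fill")) {
    vectors <- matrix(sample(0:1, 40 * 4, replace = TRUE), 40, 4)
    fx <- fixture_from_vectors(vectors)
    fx$variants$gt[sample(length(fx$variants$gt), 10)] <- NA_integer_
    fx$variants$gt[sample(length(fx$variants$gt), 5)] <- -1L
    x <- call_gchaps(fx$variants, fx$genes, fx$panel, policy = policy)
    ## conservation: haplotype counts plus exclusions cover the panel
    expect_equal(sum(x$haps$count) + x$excluded_count, 40L)

    perm <- sample.int(40)
    v2 <- gchap_variants(chrom = fx$variants$sites$chrom,
                         pos = fx$variants$sites$pos,
                         ref = fx$variants$sites$ref,
                         alt = fx$variants$sites$alt,
                         gt = fx$variants$gt[, perm],
                         samples = fx$samples[perm])
    x2 <- call_gchaps(v2, fx$genes, fx$panel, policy = policy)
    expect_equal(sort(x2$haps$count), sort(x$haps$count))
    ## same accession -> same haplotype membership (up to hap renaming)
    a1 <- setNames(x$assignment$hap_id, x$assignment$accession)
    a2 <- setNames(x2$assignment$hap_id, x2$assignment$accession)
    keep <- !is.na(a1)
    expect_true(same_partition(a1[keep], a2[names(a1)[keep]]))
  }
})

test_that("a gene on an absent chromosome is a hard error", {
  fx <- fixture_from_vectors(matrix(0L, 3, 2))
  g <- gene_models("gZ", "chr9", "+", start = 1, end = 10)
  expect_error(call_gchaps(fx$variants, g, fx$panel), "chromosome mismatch")
})

test_that("the major-haplotype rule includes the >= 1% boundary", {
  counts <- c(600L, 300L, 50L, 41L, 9L)   # n = 1000
  x <- table_from_assignment(rep(seq_along(counts), counts))
  expect_equal(major_gchaps(x), c("Hap1", "Hap2", "Hap3", "Hap4"))

  ## frequency exactly 1%: 2 of 200 is major
  x2 <- table_from_assignment(rep(c(1L, 2L), c(198L, 2L)))
  expect_equal(major_gchaps(x2), c("Hap1", "Hap2"))

  ## threshold 1 on a monomorphic gene still returns the single haplotype
  x3 <- table_from_assignment(rep(1L, 10))
  expect_equal(major_gchaps(x3, threshold = 1), "Hap1")
  expect_error(major_gchaps(x3, threshold = 0), "threshold")
})

test_that("favorable/unfavorable picks the frequency extremes among majors", {
  x <- table_from_assignment(rep(1:3, c(60L, 30L, 10L)))
  fu <- favorable_unfavorable(x)
  expect_true(fu$analyzable)
  expect_equal(fu$favorable, "Hap1")
  expect_equal(fu$unfavorable, "Hap3")

  ## equal-frequency majors: ties resolved by haplotype rank
  x2 <- table_from_assignment(rep(1:2, c(50L, 50L)))
  fu2 <- favorable_unfavorable(x2)
  expect_equal(fu2$favorable, "Hap1")
  expect_equal(fu2$unfavorable, "Hap2")

  ## single-haplotype genes cannot be analyzed
  x3 <- table_from_assignment(rep(1L, 100))
  expect_false(favorable_unfavorable(x3)$analyzable)
})

test_that("gcHap tables round-trip through the TSV writer/reader pair", {
  set.seed(3)
  vectors <- matrix(sample(0:1, 30 * 3, replace = TRUE), 30, 3)
  fx <- fixture_from_vectors(vectors,
                             population = rep(c("Xian", "Geng"), 15),
                             variety_class = rep(c("LAN", "MV", "other"), 10))
  fx$variants$gt[2, 5] <- NA_integer_
  x <- call_gchaps(fx$variants, fx$genes, fx$panel)
  a <- tempfile(fileext = ".tsv"); s <- tempfile(fileext = ".tsv")
  write_gchap_tables(list(geneA = x), a, s)
  back <- read_gchap_tables(a, s, fx$panel)$geneA
  expect_equal(back$haps$hap_id, x$haps$hap_id)
  expect_equal(back$haps$count, x$haps$count)
  expect_equal(back$haps$alleles, x$haps$alleles)
  expect_equal(back$assignment$hap_id, x$assignment$hap_id)
  expect_equal(back$excluded_count, x$excluded_count)
  expect_equal(back$sites$pos, x$sites$pos)
})
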
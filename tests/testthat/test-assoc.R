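test_that("two-group ANOVA F equals the squared pooled-variance t statistic", {
  set.seed(8)
  for (i in 1:10) {
    y1 <- rnorm(sample(12:40, 1)); y2 <- rnorm(sample(12:40, 1), mean = 0.3)
    fx <- two_group_fixture(y1, y2)
    a <- anova_by_hap(fx$table, fx$traits, "TGW")
    tt <- t.test(y1, y2, var.equal = TRUE)
    expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(a$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate and strongly separated groups get the right letters", {
  fx <- two_group_fixture(rep(5, 15), rep(5, 15))
  a <- anova_by_hap(fx$table, fx$traits, "TGW")
  expect_equal(a$F, 0)
  expect_equal(unique(a$groups$letter), "a")

  set.seed(42)
  fx2 <- two_group_fixture(rnorm(50, 0), rnorm(50, 3))
  a2 <- anova_by_hap(fx2$table, fx2$traits, "TGW")
  expect_lt(a2$p, 1e-7)
  expect_true(a2$strong)
  expect_setequal(a2$groups$letter, c("a", "b"))
})

test_that("three-group Tukey p-values match the studentized-range CDF directly", {
  set.seed(2)
  y <- c(rnorm(20, 0), rnorm(20, 0), rnorm(20, 5))
  x <- table_from_assignment(rep(1:3, each = 20))
  traits <- tibble::tibble(accession = x$assignment$accession, PL = y)
  a <- anova_by_hap(x, traits, "PL", min_n = 5)

  ## oracle: p = 1 - ptukey(|diff| / se, k, df) from the group summaries
  mns <- tapply(y, rep(1:3, each = 20), mean)
  mse <- sum((y - ave(y, rep(1:3, each = 20)))^2) / (60 - 3)
  se <- sqrt(mse / 2 * (1 / 20 + 1 / 20))
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    q <- abs(mns[pair[1]] - mns[pair[2]]) / se
    p_oracle <- 1 - ptukey(q, nmeans = 3, df = 57)
    ## hap ranks: all groups n=20, so rank follows first occurrence 1,2,3
    expect_equal(a$tukey_p[paste0("Hap", pair[1]), paste0("Hap", pair[2])],
                 unname(p_oracle), tolerance = 1e-10)
  }
  ## the two null groups share a letter; the shifted one differs
  g <- setNames(a$groups$letter, a$groups$hap_id)
  expect_equal(g[["Hap1"]], g[["Hap2"]])
  expect_false(g[["Hap3"]] %in% c(g[["Hap1"]]))
})

test_that("compact letters satisfy the sharing property and match multcomp", {
  ## property: share a letter <=> pair not significantly different
  set.seed(23)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    ids <- paste0("G", seq_len(k))
    sig <- matrix(FALSE, k, k, dimnames = list(ids, ids))
    for (r in seq_len(k - 1)) for (cc in (r + 1):k) {
      sig[r, cc] <- sig[cc, r] <- runif(1) < 0.4
    }
    lt <- cld_insert_absorb(sig)
    for (r in seq_len(k - 1)) for (cc in (r + 1):k) {
      share <- any(strsplit(lt[r], "")[[1]] %in% strsplit(lt[cc], "")[[1]])
      expect_equal(share, !sig[r, cc])
    }
  }

  ## order invariance: permuting the matrix yields the same sharing structure
  k <- 5; ids <- paste0("G", 1:k)
  sig <- matrix(FALSE, k, k, dimnames = list(ids, ids))
  sig["G1", "G4"] <- sig["G4", "G1"] <- TRUE
  sig["G2", "G5"] <- sig["G5", "G2"] <- TRUE
  lt <- cld_insert_absorb(sig)
  perm <- c(3, 5, 1, 2, 4)
  lt_p <- cld_insert_absorb(sig[perm, perm])
  shares <- function(l, a, b) any(strsplit(l[a], "")[[1]] %in%
                                    strsplit(l[b], "")[[1]])
  for (a in ids) for (b in ids) {
    if (a != b) expect_equal(shares(lt_p, a, b), shares(lt, a, b))
  }

  ## independent oracle: multcomp's cld on a clearly separated fit
  set.seed(4)
  y <- c(rnorm(30, 0), rnorm(30, 0.2), rnorm(30, 6))
  df <- data.frame(y = y, g = factor(rep(c("a1", "a2", "a3"), each = 30)))
  glht_fit <- multcomp::glht(aov(y ~ g, df), multcomp::mcp(g = "Tukey"))
  letters_mc <- multcomp::cld(glht_fit)$mcletters$Letters
  x <- table_from_assignment(rep(1:3, each = 30))
  traits <- tibble::tibble(accession = x$assignment$accession, GW = y)
  a <- anova_by_hap(x, traits, "GW")
  ours <- setNames(a$groups$letter, a$groups$hap_id)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    share_mc <- shares(letters_mc, paste0("a", pair[1]), paste0("a", pair[2]))
    share_us <- shares(ours, paste0("Hap", pair[1]), paste0("Hap", pair[2]))
    expect_equal(share_us, share_mc)
  }
})

test_that("small haplotype groups are dropped by min_n and signalled when <2 remain", {
  set.seed(3)
  x <- table_from_assignment(rep(1:3, c(40, 30, 5)))
  traits <- tibble::tibble(accession = x$assignment$accession,
                           DTH = rnorm(75, 90))
  a <- anova_by_hap(x, traits, "DTH", min_n = 10)
  expect_true(a$analyzable)
  expect_setequal(a$groups$hap_id, c("Hap1", "Hap2"))   # Hap3 n=5 dropped

  x2 <- table_from_assignment(rep(1:2, c(40, 5)))
  traits2 <- tibble::tibble(accession = x2$assignment$accession,
                            DTH = rnorm(45, 90))
  a2 <- anova_by_hap(x2, traits2, "DTH", min_n = 10)
  expect_false(a2$analyzable)
  expect_true(is.na(glance(a2)$p))
  expect_error(anova_by_hap(x2, traits2, "PH"), "trait column")
})

test_that("the favorable/unfavorable scan attempts the full gene x trait grid", {
  set.seed(77)
  tables <- list()
  for (g in 1:11) {
    tables[[paste0("g", g)]] <- if (g <= 8) {
      table_from_assignment(sample(1:3, 120, replace = TRUE,
                                   prob = c(0.6, 0.3, 0.1)))
    } else {
      table_from_assignment(rep(1L, 120))   # single-gcHap genes drop out
    }
  }
  acc <- tables[[1]]$assignment$accession
  traits <- tibble::tibble(accession = acc)
  for (tr in gchap_traits()$trait) traits[[tr]] <- rnorm(120)
  fu <- fav_unfav_scan(tables, traits)
  expect_equal(nrow(fu), 8 * 15)
  expect_equal(glance(fu)$attempted, 120)
  expect_true(all(fu$favorable == "Hap1"))

  ## a group with one phenotyped accession is skipped, not tested
  x <- table_from_assignment(rep(1:2, c(99, 1)))
  tr1 <- tibble::tibble(accession = x$assignment$accession, TGW = rnorm(100))
  fu2 <- fav_unfav_scan(list(g = x), tr1, trait_names = "TGW")
  expect_true(is.na(fu2$p))
  expect_match(fu2$skipped, "fewer than 2")
})

test_that("the favorable/unfavorable test is calibrated under the null", {
  set.seed(101)
  flags <- vapply(1:200, function(i) {
    x <- table_from_assignment(rep(1:2, c(70, 30)))
    tr <- tibble::tibble(accession = x$assignment$accession, GL = rnorm(100))
    fav_unfav_scan(list(g = x), tr, trait_names = "GL")$different
  }, logical(1))
  expect_gt(mean(flags), 0.005)
  expect_lt(mean(flags), 0.115)
})
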
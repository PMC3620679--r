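test_that("common-gene exclusion follows both stated modes", {
  out <- excludeCommon(list(A = c("g1", "g2", "g3"), B = c("g2", "g4")),
                       mode = "pairwise_vs_reference")
  expect_equal(sort(out$A), c("G1", "G3"))
  expect_equal(out$B, "G4")
  disjoint <- excludeCommon(list(A = c("a", "b"), B = c("c", "d")),
                            mode = "unique_only")
  expect_equal(sort(unlist(disjoint, use.names = FALSE)),
               c("A", "B", "C", "D"))
  expect_error(excludeCommon(list(A = "g1", B = "g1")), "emptied")

  # unique_only equals set difference against the union of the others
  set.seed(15)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j) sample(sprintf("g%02d", 1:40),
                                           sample(10:30, 1)))
    names(sets) <- c("X", "Y", "Z")
    got <- tryCatch(excludeCommon(sets, mode = "unique_only"),
                    error = function(e) NULL)
    want <- lapply(1:3, function(j)
      setdiff(toupper(sets[[j]]),
              toupper(unlist(sets[-j], use.names = FALSE))))
    if (is.null(got)) {
      expect_true(any(lengths(want) == 0L))
    } else {
      for (j in 1:3) expect_setequal(got[[j]], want[[j]])
    }
  }
  # order independence of the pairwise rule
  ab <- excludeCommon(list(A = c("g1", "g2"), B = c("g2", "g3")))
  ba <- excludeCommon(list(B = c("g2", "g3"), A = c("g1", "g2")))
  expect_equal(ab$A, ba$A)
  expect_equal(ab$B, ba$B)
})

test_that("rank-sum test is exact for small untied samples, symmetric, and rank-based", {
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))$p, 1.0)
  expect_error(wilcoxonRankSum(c(1, NA), c(2, 3)), "finite")
  set.seed(31)
  x <- rnorm(30); y <- rnorm(30, 0.4)
  expect_equal(wilcoxonRankSum(x, y)$p, wilcoxonRankSum(y, x)$p)
  # invariance under a strictly monotone transform of the pooled values
  expect_equal(wilcoxonRankSum(exp(x), exp(y))$p, wilcoxonRankSum(x, y)$p)
})

test_that("rank-sum normal approximation agrees with a permutation oracle", {
  set.seed(52)
  x <- rnorm(30); y <- rnorm(30, 0.5)
  got <- wilcoxonRankSum(x, y)$p
  pooled <- c(x, y)
  wobs <- sum(rank(pooled)[1:30]) - 30 * 31 / 2
  perms <- replicate(40000, {
    idx <- sample.int(60, 30)
    sum(rank(pooled)[idx]) - 30 * 31 / 2
  })
  # two-sided permutation p from the distance to the null mean
  p_perm <- mean(abs(perms - 450) >= abs(wobs - 450) - 1e-9)
  expect_lt(abs(got - p_perm) / p_perm, 0.1)
})

test_that("rate comparisons recover planted shifts and report direction", {
  set.seed(66)
  bg <- sprintf("G%04d", 1:1000)
  hits <- 0L
  for (s in 1:60) {
    a <- sample(bg, 200); b <- sample(setdiff(bg, a), 200)
    rates <- data.frame(gene_symbol = bg,
                        dn = rlnorm(1000, log(0.07), 0.5) +
                          ifelse(bg %in% a, 0.05, 0),
                        ds = rlnorm(1000, log(0.5), 0.4),
                        dnds = NA_real_)
    rates$dnds <- rates$dn / rates$ds
    cmp <- compareRates(a, b, rates, exclusionMode = "none")
    dn <- cmp[cmp$metric == "dn", ]
    if (dn$direction == -1L && dn$p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 57)  # >= 95% of seeds recover the planted direction

  # identical contents: no direction, p in the null region
  rates <- data.frame(gene_symbol = sprintf("G%04d", 1:50),
                      dn = rlnorm(50, log(0.07), 0.5),
                      ds = rlnorm(50, log(0.5), 0.4), dnds = runif(50))
  same <- compareRates(rates$gene_symbol, rates$gene_symbol, rates,
                       exclusionMode = "none")
  expect_true(all(same$direction == 0L))
  expect_true(all(same$p > 0.9))
})

test_that("rate comparisons drop missing values per metric and flag tiny sets", {
  rates <- data.frame(gene_symbol = c("A", "B", "C", "D"),
                      dn = c(0.1, 0.2, NA, 0.4),
                      ds = c(NA, NA, NA, 0.5),
                      dnds = c(0.2, 0.4, 0.1, 0.8))
  cmp <- compareRates(c("A", "B"), c("C", "D"), rates,
                      exclusionMode = "none")
  expect_equal(cmp$note[cmp$metric == "ds"], "insufficient data")
  expect_true(is.na(cmp$p[cmp$metric == "ds"]))
  expect_equal(cmp$n_a[cmp$metric == "dnds"], 2L)
})

test_that("generator defaults reproduce the expected rate sign pattern", {
  # housekeeping-like genes slower (-) and tissue/secreted-like faster (+)
  # than the hotspot-intersected set, on all three metrics
  set.seed(19)
  bg <- sprintf("G%04d", 1:2000)
  hi <- sample(bg, 300)
  hk <- c(sample(hi, 30), sample(setdiff(bg, hi), 170))
  tiger <- c(sample(setdiff(hi, hk), 80),
             sample(setdiff(bg, c(hi, hk)), 320))
  rates <- genRateTable(bg, sets = list(HK = hk, TiGER = tiger, HI = hi),
                        rateShifts = c(TiGER = 0.015, HK = -0.02,
                                       HI = 0.01), seed = 19)
  hkCmp <- compareRates(hi, hk, rates, "pairwise_vs_reference",
                        setNames = c("HI", "HK"))
  expect_true(all(hkCmp$direction == -1L))
  tgCmp <- compareRates(hi, tiger, rates, "pairwise_vs_reference",
                        setNames = c("HI", "TiGER"))
  expect_true(all(tgCmp$direction == 1L))
})

test_that("proportion comparisons delegate to the exact 2x2 test", {
  flat <- proportionTest(10, 100, 10, 100)
  expect_equal(flat$p, 1)
  expect_equal(flat$fe, 1)
  # duplicated-gene proportions as printed: 20.1% vs 9.1%
  dgd <- proportionTest(413, 2054, 50, 550)
  expect_equal(round(100 * dgd$prop_a, 1), 20.1)
  expect_equal(round(100 * dgd$prop_b, 1), 9.1)
  expect_lt(dgd$p, 1e-4)
  expect_equal(dgd$p,
               stats::fisher.test(rbind(c(413, 2054 - 413),
                                        c(50, 500)))$p.value,
               tolerance = 1e-6)
  set.seed(2)
  for (i in 1:25) {
    at <- sample(5:60, 1); bt <- sample(5:60, 1)
    am <- sample.int(at, 1); bm <- sample.int(bt, 1)
    expect_equal(proportionTest(am, at, bm, bt)$p,
                 fisherExact2x2(am, at - am, bm, bt - bm))
  }
})

test_that("branch enrichment is calibrated under the null and recovers planting", {
  set.seed(41)
  bg <- sprintf("G%04d", 1:2000)
  branches <- setNames(sample(0:12, 2000, replace = TRUE,
                              prob = c(0.5, 0.6^(1:12) / sum(0.6^(1:12)) * 0.5)),
                       bg)
  anySig <- 0L
  for (s in 1:40) {
    q <- sample(bg, 300)
    res <- branchEnrichment(q, branches, bg)
    if (any(res$table$q < 0.05)) anySig <- anySig + 1L
  }
  expect_lte(anySig, 4L)  # null query: findings in <= 10% of seeds

  # degenerate planting: the query IS branch 0
  b0 <- names(branches)[branches == 0L]
  res <- branchEnrichment(b0, branches, bg)
  tab <- res$table
  expect_equal(tab$fe[tab$branch == 0L], max(tab$fe, na.rm = TRUE))
  expect_true(all(tab$fe[tab$branch != 0L] < 0 | is.na(tab$fe[tab$branch != 0L])))
  expect_equal(res$branch0_fraction, 1.0)

  # planted 80% branch-0 query against a ~50% background
  fr <- replicate(40, {
    inB0 <- runif(300) < 0.8
    q <- c(sample(b0, sum(inB0)),
           sample(names(branches)[branches != 0L], sum(!inB0)))
    branchEnrichment(q, branches, bg)$branch0_fraction
  })
  expect_lt(abs(mean(fr) - 0.8), 0.03)
  expect_error(branchEnrichment("G0001", c(OTHER = 3L), bg), "not in the background")
})
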
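test_that("single-SNP regression equals the closed-form OLS oracle", {
  debv <- data.frame(animal = sprintf("a%d", 1:6),
                     debv = c(0.1, -0.1, 0.2, 0.0, 0.4, 0.2))
  G <- matrix(c(0, 0, 1, 1, 2, 2), ncol = 1,
              dimnames = list(debv$animal, "m1"))
  res <- snp_association(debv, G, threshold = 6)
  orc <- ols_oracle(debv$debv, G[, 1])
  expect_equal(res$effect, orc$effect, tolerance = 1e-10)
  expect_equal(res$se, orc$se, tolerance = 1e-10)
  expect_equal(res$t, orc$t, tolerance = 1e-10)
  expect_equal(res$p, orc$p, tolerance = 1e-10)
  expect_false(res$significant)

  # random fixtures, several markers at once
  set.seed(5)
  n <- 40
  G <- matrix(sample(0:2, n * 8, replace = TRUE), n,
              dimnames = list(sprintf("a%d", 1:n), sprintf("m%d", 1:8)))
  debv <- data.frame(animal = rownames(G), debv = rnorm(n))
  res <- snp_association(debv, G)
  for (j in 1:8) {
    orc <- ols_oracle(debv$debv, G[, j])
    expect_equal(res$effect[j], orc$effect, tolerance = 1e-10)
    expect_equal(res$p[j], orc$p, tolerance = 1e-10)
  }
})

test_that("monomorphic markers are flagged not testable", {
  debv <- data.frame(animal = sprintf("a%d", 1:10), debv = rnorm(10))
  G <- cbind(mono = rep(2, 10), poly = rep(0:1, 5))
  rownames(G) <- debv$animal
  res <- snp_association(debv, G)
  expect_false(res$testable[1])
  expect_true(is.na(res$p[1]))
  expect_false(res$significant[1])
  expect_true(res$testable[2])
})

test_that("p-values are monotone in |t| and the significance flag is consistent", {
  set.seed(9)
  n <- 60
  G <- matrix(sample(0:2, n * 50, replace = TRUE), n,
              dimnames = list(sprintf("a%d", 1:n), NULL))
  debv <- data.frame(animal = rownames(G),
                     debv = 0.8 * G[, 1] + rnorm(n))
  res <- snp_association(debv, G, threshold = 2)
  ok <- res$testable
  expect_equal(order(res$p[ok]), order(-abs(res$t[ok])))
  expect_equal(res$significant[ok], res$minus_log10_p[ok] > 2)
})

test_that("haplotype association handles carrier dosage and degenerate input", {
  set.seed(13)
  ids <- sprintf("a%d", 1:200)
  carriers <- sample(ids, 40)
  debv <- data.frame(animal = ids,
                     debv = 0.5 * (ids %in% carriers) + rnorm(200))
  res <- haplotype_association(debv, carriers, threshold = 2)
  expect_true(res$testable)
  expect_gt(res$effect, 0)
  orc <- ols_oracle(debv$debv, as.numeric(ids %in% carriers))
  expect_equal(res$effect, orc$effect, tolerance = 1e-10)
  expect_equal(res$p, orc$p, tolerance = 1e-10)

  expect_false(haplotype_association(debv, ids)$testable)          # all carriers
  expect_false(haplotype_association(debv, character(0))$testable) # none
  flat <- data.frame(animal = ids, debv = 0)
  expect_false(haplotype_association(flat, carriers)$testable)     # no variance
})

test_that("permutation of labels gives the nominal type-I rate", {
  set.seed(17)
  ids <- sprintf("a%d", 1:150)
  carriers <- sample(ids, 30)
  hits <- 0L
  B <- 400
  for (b in seq_len(B)) {
    debv <- data.frame(animal = ids, debv = rnorm(150))
    if (haplotype_association(debv, carriers)$p < 0.05) hits <- hits + 1L
  }
  expect_lt(abs(hits / B - 0.05), 3 * sqrt(0.05 * 0.95 / B))
})

test_that("gene-window annotation: exact boundary and quadratic oracle", {
  res <- data.frame(marker = c("m1", "m2"), chrom = "5",
                    pos = c(500000L, 900000L),
                    significant = c(TRUE, TRUE), testable = TRUE)
  genes <- data.frame(chrom = "5",
                      start = c(600000L, 600001L, 250000L),
                      end = c(650000L, 650001L, 400000L),
                      gene_id = c("exact_right", "far", "exact_left"))
  hits <- annotate_windows(res, genes, window = 100000)
  h1 <- hits[hits$marker == "m1", ]
  # genes exactly 100,000 bp away included on both sides, 100,001 excluded
  expect_setequal(h1$gene_id, c("exact_right", "exact_left"))
  expect_equal(h1$distance[h1$gene_id == "exact_right"], 100000L)
  expect_equal(h1$distance[h1$gene_id == "exact_left"], 100000L)

  # marker inside a gene has distance 0
  res2 <- data.frame(marker = "m3", chrom = "5", pos = 620000L,
                     significant = TRUE, testable = TRUE)
  h3 <- annotate_windows(res2, genes, 100000)
  expect_equal(h3$distance[h3$gene_id == "exact_right"], 0L)

  # random fixture vs all-pairs scan
  set.seed(21)
  mk <- data.frame(marker = sprintf("s%d", 1:50),
                   chrom = sample(c("1", "2"), 50, replace = TRUE),
                   pos = sample.int(5e6, 50), significant = TRUE,
                   testable = TRUE)
  gn <- data.frame(chrom = sample(c("1", "2"), 1000, replace = TRUE),
                   start = sample.int(5e6, 1000))
  gn$end <- gn$start + sample.int(50000, 1000)
  gn$gene_id <- sprintf("g%d", 1:1000)
  got <- annotate_windows(mk, gn, window = 100000)
  want <- window_hits_brute(mk, gn, 100000)
  key <- function(d) sort(paste(d$marker, d$gene_id, d$distance))
  expect_identical(key(got), key(want))
})

test_that("annotation errors on chromosome-name mismatch, harmonizes prefixes", {
  res <- data.frame(marker = "m1", chrom = "chr5", pos = 1000L,
                    significant = TRUE, testable = TRUE)
  genes <- data.frame(chrom = "BTA5", start = 500L, end = 2000L,
                      gene_id = "g1")
  expect_equal(annotate_windows(res, genes, 1000)$gene_id, "g1")
  genes2 <- data.frame(chrom = "7", start = 500L, end = 2000L,
                       gene_id = "g1")
  expect_error(annotate_windows(res, genes2, 1000), "absent")
})

test_that("cross-trait overlap equals brute-force set algebra", {
  mk <- function(ids, sig) data.frame(marker = ids,
                                      significant = sig, testable = TRUE)
  a <- mk(c("x", "y", "z"), TRUE)
  ov <- cross_trait_overlap(list(HR = a, STAY = a))
  expect_equal(unname(ov$counts["HR+STAY"]), 3L)
  expect_null(ov$sets[["HR"]])

  b <- mk(c("p", "q"), TRUE)
  ov <- cross_trait_overlap(list(HR = a, STAY = b))
  expect_setequal(ov$sets[["HR"]], c("x", "y", "z"))
  expect_setequal(ov$sets[["STAY"]], c("p", "q"))

  set.seed(25)
  pool <- sprintf("m%d", 1:40)
  lists <- lapply(1:3, function(i) mk(sample(pool, 20), TRUE))
  names(lists) <- c("HR", "PNM", "STAY")
  ov <- cross_trait_overlap(lists)
  sig <- lapply(lists, function(d) d$marker)
  for (m in pool) {
    pat <- paste(names(sig)[vapply(sig, function(s) m %in% s, logical(1))],
                 collapse = "+")
    if (pat == "") next
    expect_true(m %in% ov$sets[[pat]])
  }
})
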
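# Frozen oracle values below were computed once with exact rational
# arithmetic at 25 significant digits (sympy), independently of the
# log-space implementation they check.

test_that("simple-method expectation reproduces published arithmetic", {
  expect_equal(expected_hom_simple(6189, 62022), 154, tolerance = 0.005)
  expect_equal(expected_hom_simple(0, 62022), 0)
  expect_equal(expected_hom_simple(15145, 62022), 924.6, tolerance = 0.001)
  # N * C^2 / 4 and N * f^2 are the same number
  expect_equal(expected_hom_simple(4000, 50000),
               50000 * (4000 / 50000)^2 / 4)
  expect_error(expected_hom_simple(5, 0), "positive")
  # Monte-Carlo oracle: random union of two haplotypes per animal
  set.seed(99)
  N <- 62022; f <- 15145 / (2 * N)
  hom <- sum(rbinom(N, 1, f) & rbinom(N, 1, f))
  expect_lt(abs(hom - expected_hom_simple(15145, N)),
            4 * sqrt(N * f^2 * (1 - f^2)))
})

test_that("zero-homozygote probabilities match exact-arithmetic oracles", {
  expect_equal(as.numeric(phh_simple(6958 / 124044, 62022)),
               6.364832020894174e-22, tolerance = 1e-12)
  expect_equal(as.numeric(phh_simple(5929 / 124044, 62022)),
               4.084821109374573e-16, tolerance = 1e-12)
  expect_equal(as.numeric(phh_simple(15145 / 124044, 62022)),
               2.692720371189006e-101, tolerance = 1e-12)
  expect_equal(as.numeric(phh_simple(0, 1000)), 1.0)
  expect_equal(as.numeric(phh_simple(0.3, 0)), 1.0)  # empty product
  expect_identical(attr(phh_simple(0.05, 10), "convention"), "haplotype")
  expect_identical(attr(phh_simple(0.05, 10, "carrier"), "convention"),
                   "carrier")
})

test_that("mating-method probability is exact in log space without underflow", {
  expect_equal(phh_mating(2), 0.5625)
  expect_equal(phh_mating(69), 2.394567997517306e-9, tolerance = 1e-12)
  expect_equal(phh_mating(0), 1.0)
  expect_equal(phh_mating(1028), 3.655769175523772e-129, tolerance = 1e-12)
  expect_gt(phh_mating(1028), 0)   # no underflow to zero
})

test_that("carrier-mating count: hand pedigree and exhaustive oracle", {
  # one carrier sire S also serving as MGS of one genotyped animal
  ped <- as_pedigree(data.frame(
    id = c("S", "D1", "D2", "X", "Y", "Z"),
    sire = c(NA, "S", NA, "S", "S", NA),
    dam = c(NA, NA, NA, "D1", "D2", NA)))
  expect_equal(count_carrier_matings(ped, character(0), ped$id), 0L)
  expect_equal(count_carrier_matings(ped, "S", ped$id), 1L)   # only X
  expect_equal(count_carrier_matings(ped, c("S", "D2"), ped$id), 1L)

  pop <- small_sim(seed = 23)
  carriers <- pop$truth$true_carrier_ids
  expect_equal(count_carrier_matings(pop$pedigree, carriers, pop$panel$ids),
               carrier_matings_brute(pop$pedigree, carriers, pop$panel$ids))
})

test_that("candidate filter matches a brute-force predicate on boundary sweeps", {
  grid <- expand.grid(n_homozygotes = c(0L, 1L),
                      hap_pct = c(1.99, 2.0, 2.01, 3),
                      exp_hom_simple = c(0.99, 1.0, 1.01, 5),
                      phh_simple = c(0.59, 0.6, 0.61),
                      phh_mating = c(0.59, 0.6, 0.61))
  grid$hap_id <- sprintf("h%d", seq_len(nrow(grid)))
  grid$chrom <- "1"; grid$start_bp <- seq_len(nrow(grid))
  kept <- filter_candidates(grid)
  brute <- grid[grid$n_homozygotes == 0 & grid$hap_pct > 2 &
                  grid$exp_hom_simple > 1 & grid$phh_simple < 0.6 &
                  grid$phh_mating < 0.6, ]
  expect_setequal(kept$hap_id, brute$hap_id)
  expect_false(any(filter_candidates(grid)$n_homozygotes == 1))
})

test_that("all thirty published candidates pass the filter from raw counts", {
  fx <- fixture_candidates()
  N <- 62022
  rec <- data.frame(
    hap_id = fx$hap_id, chrom = fx$bta, start_bp = fx$start_bp,
    n_homozygotes = 0L,
    hap_pct = 100 * fx$n_carriers / (2 * N),
    exp_hom_simple = expected_hom_simple(fx$n_carriers, N),
    phh_simple = as.numeric(phh_simple(fx$n_carriers / (2 * N), N)),
    phh_mating = phh_mating(fx$n_matings))
  kept <- filter_candidates(rec)
  expect_equal(nrow(kept), 30L)
})

test_that("depletion report is invariant to animal ordering", {
  pop <- small_sim(seed = 29)
  plan <- plan_segments(pop$panel$map, max_len = 20)
  r1 <- depletion_report(enumerate_haplotypes(pop$panel, plan),
                         pop$pedigree, pop$panel$ids, min_hap_pct = 1)
  n <- length(pop$panel$ids)
  set.seed(1)
  perm <- sample(n)
  rows <- as.vector(rbind(2L * perm - 1L, 2L * perm))
  panel2 <- phased_panel(pop$panel$H[rows, , drop = FALSE], pop$panel$map,
                         pop$panel$ids[perm])
  r2 <- depletion_report(enumerate_haplotypes(panel2, plan),
                         pop$pedigree, panel2$ids, min_hap_pct = 1)
  expect_equal(r1[, setdiff(names(r1), "carriers")],
               r2[, setdiff(names(r2), "carriers")])
})

test_that("mating and simple expectations agree under random mating with full pedigree", {
  # no masking, no lethality, many sires: exposure noise only
  pop <- simulate_population(sim_config(
    n_founders = 500, n_generations = 3, n_sires_per_gen = 150,
    offspring_per_mating = 2, n_chromosomes = 1,
    markers_per_chromosome = 12, lethal_marker_window = c(0L, 4L),
    lethal_founder_frequency = 0, prob_unknown_sire = 0,
    prob_unknown_dam = 0, seed = 12))
  plan <- plan_segments(pop$panel$map, max_len = 4)
  cat_ <- enumerate_haplotypes(pop$panel, plan)
  N <- length(pop$panel$ids)
  common <- cat_[cat_$copies / (2 * N) > 0.08, ]
  tot_simple <- 0; tot_mating <- 0
  for (k in seq_len(nrow(common))) {
    carr <- common$carriers[[k]]
    tot_simple <- tot_simple + expected_hom_simple(length(carr), N)
    tot_mating <- tot_mating +
      count_carrier_matings(pop$pedigree, carr, pop$panel$ids) / 4
  }
  expect_gt(tot_simple, 20)
  # aggregate ratio: binomial exposure noise plus carrier-share sampling
  # keeps individual haplotypes noisy, the total within a factor of ~2
  expect_gt(tot_mating / tot_simple, 0.5)
  expect_lt(tot_mating / tot_simple, 2.0)
})

test_that("empty catalog yields an empty report", {
  pop <- small_sim(seed = 3)
  cat_ <- enumerate_haplotypes(pop$panel, plan_segments(pop$panel$map, 20))
  empty <- cat_[0, ]
  attr(empty, "n_genotyped") <- length(pop$panel$ids)
  rep_ <- depletion_report(empty, pop$pedigree, pop$panel$ids)
  expect_equal(nrow(rep_), 0L)
  expect_true(all(c("phh_simple", "phh_mating", "passes_filter") %in%
                    names(rep_)))
})
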
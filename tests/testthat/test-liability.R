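make_gibbs_result <- function(ids, ebv, rel, sig2a = 0.45) {
  structure(list(
    ebv = data.frame(animal = ids, ebv = ebv, pev = (1 - rel) * sig2a,
                     reliability = rel, stringsAsFactors = FALSE),
    sig2a = c(mean = sig2a, sd = 0.05),
    h2 = c(mean = sig2a / (1 + sig2a), sd = 0.02),
    diagnostics = list()), class = "gibbs_result")
}

test_that("contemporary-group editing drops small and invariant groups", {
  raw <- data.frame(
    animal = sprintf("a%02d", 1:24),
    value = c(rep(0:1, 5),        # cg 1: 10 records, mixed  -> kept
              rep(1L, 4),         # cg 2: 4 records          -> small
              rep(1L, 10)),       # cg 3: 10 records, all 1  -> no variance
    cg = rep(1:3, c(10, 4, 10)))
  out <- prepare_traits(raw)
  expect_setequal(unique(out$cg), 1L)
  rep_ <- attr(out, "edit_report")
  expect_equal(rep_$cg_removed_small, 1L)
  expect_equal(rep_$cg_removed_novar, 1L)
  expect_error(prepare_traits(raw[raw$cg != 1, ]), "no records survive")

  set.seed(31)
  rnd <- data.frame(animal = sprintf("r%03d", 1:400),
                    value = rbinom(400, 1, 0.3),
                    cg = sample(1:60, 400, replace = TRUE))
  out <- prepare_traits(rnd)
  keep_brute <- unlist(lapply(split(rnd, rnd$cg), function(g)
    if (nrow(g) >= 5 && length(unique(g$value)) == 2) g$animal else NULL))
  expect_setequal(out$animal, keep_brute)
})

test_that("Gaussian limit of the sampler matches the mixed-model equations", {
  ped <- random_pedigree(150, seed = 41)
  n <- nrow(ped)
  set.seed(42)
  cg <- sample(1:5, n, replace = TRUE)
  y <- rnorm(n, mean = c(-0.5, 0, 0.3, 0.8, -0.2)[cg])
  dat <- data.frame(animal = ped$id, value = y, cg = cg)
  s2a <- 0.5
  fit <- gibbs_threshold_model(dat, ped, n_iter = 12000, burn_in = 2000,
                               thin = 2, seed = 7, liability_observed = TRUE,
                               fix_sig2a = s2a)
  # closed-form MME solution with the same A-inverse and variance
  Ainv <- a_inverse(ped)$Ainv
  X <- Matrix::sparseMatrix(i = seq_len(n), j = cg, x = 1,
                            dims = c(n, 5))
  Z <- Matrix::Diagonal(n)
  C <- rbind(cbind(Matrix::t(X) %*% X, Matrix::t(X) %*% Z),
             cbind(Matrix::t(Z) %*% X, Matrix::t(Z) %*% Z + Ainv / s2a))
  sol <- Matrix::solve(C, c(as.vector(Matrix::t(X) %*% y),
                            as.vector(Matrix::t(Z) %*% y)))
  sol <- as.vector(sol)
  beta_mme <- sol[1:5]; a_mme <- sol[-(1:5)]
  expect_lt(max(abs(unname(fit$beta) - beta_mme)), 0.15)
  expect_lt(max(abs(fit$ebv$ebv - a_mme)), 0.15)
  expect_gt(cor(fit$ebv$ebv, a_mme), 0.99)
})

test_that("chains are reproducible for a fixed seed", {
  pop <- small_sim(seed = 51)
  dat <- prepare_traits(pop$traits[pop$traits$trait == "HR", ])
  f1 <- gibbs_threshold_model(dat, pop$pedigree, n_iter = 800, burn_in = 200,
                              thin = 2, seed = 99)
  f2 <- gibbs_threshold_model(dat, pop$pedigree, n_iter = 800, burn_in = 200,
                              thin = 2, seed = 99)
  expect_identical(f1$ebv$ebv, f2$ebv$ebv)
  expect_identical(f1$h2_samples, f2$h2_samples)
  f3 <- gibbs_threshold_model(dat, pop$pedigree, n_iter = 800, burn_in = 200,
                              thin = 2, seed = 100)
  expect_false(identical(f1$h2_samples, f3$h2_samples))
})

test_that("with unrelated animals and no genetic signal, h2 concentrates near 0", {
  # repeated records per animal identify the animal effect under A = I;
  # independent records mean its variance is truly zero
  hits <- 0L
  for (seed in 1:8) {
    set.seed(seed)
    n <- 150
    ped <- as_pedigree(data.frame(id = sprintf("u%03d", 1:n),
                                  sire = NA, dam = NA))   # A = I
    dat <- data.frame(animal = rep(ped$id, each = 4),
                      value = rbinom(4 * n, 1, 0.4), cg = 1L)
    fit <- gibbs_threshold_model(dat, ped, n_iter = 3000, burn_in = 500,
                                 thin = 5, seed = seed)
    if (unname(quantile(fit$h2_samples, 0.1)) < 0.12) hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})

test_that("heritability is recovered within 3 posterior SD on simulated data", {
  pop <- simulate_population(sim_config(
    n_founders = 700, n_generations = 3, n_sires_per_gen = 60,
    offspring_per_mating = 2, n_chromosomes = 1,
    markers_per_chromosome = 10, lethal_marker_window = c(0L, 5L),
    lethal_founder_frequency = 0, n_contemporary_groups = 50, seed = 61))
  dat <- prepare_traits(pop$traits[pop$traits$trait == "HR", ])  # h2 = 0.31
  fit <- gibbs_threshold_model(dat, pop$pedigree, n_iter = 6000,
                               burn_in = 1500, thin = 5, seed = 2)
  expect_lt(abs(fit$h2["mean"] - 0.31), 3 * fit$h2["sd"])
  expect_false(fit$diagnostics$divergent)
  # EBVs track the simulated breeding values, better for proven sires
  bv <- pop$truth$true_breeding_values[, "HR"]
  m <- match(names(bv), fit$ebv$animal)
  r_all <- cor(fit$ebv$ebv[m], bv)
  expect_gt(r_all, 0.25)
  prog <- table(c(pop$truth$true_sire))
  rich <- names(prog)[prog >= 10]
  r_rich <- cor(fit$ebv$ebv[m[names(bv) %in% rich]], bv[names(bv) %in% rich])
  expect_gt(r_rich, r_all)
})

test_that("deregression boundary and degenerate cases follow the stated rules", {
  ped <- as_pedigree(data.frame(id = c("f1", "f2"), sire = NA, dam = NA))
  res <- make_gibbs_result(c("f1", "f2"), ebv = c(0.2, 0.3),
                           rel = c(0.16, 0.1))
  out <- deregress(res, ped, h2 = 0.31, min_acc = 0.40)
  # accuracy exactly 0.40 (r2 = 0.16) is retained; r2 = 0.10 is not
  expect_identical(out$animal, "f1")
  expect_equal(out$accuracy, 0.4)
  # unknown parents reduce to the EBV / r2 scaling
  expect_equal(out$debv, 0.2 / 0.16)

  # animal whose reliability does not exceed the parent average is skipped
  ped2 <- as_pedigree(data.frame(id = c("s", "d", "o"),
                                 sire = c(NA, NA, "s"), dam = c(NA, NA, "d")))
  res2 <- make_gibbs_result(c("s", "d", "o"), ebv = c(0.5, 0.1, 0.3),
                            rel = c(0.9, 0.9, 0.05))
  expect_message(out2 <- deregress(res2, ped2, h2 = 0.31, min_acc = 0),
                 "skipped")
  expect_false("o" %in% out2$animal)
})

test_that("deregressed EBVs are calibrated against true breeding values", {
  # Gaussian-records variant gives enough information for the slope check
  pop <- simulate_population(sim_config(
    n_founders = 500, n_generations = 3, n_sires_per_gen = 50,
    offspring_per_mating = 2, n_chromosomes = 1,
    markers_per_chromosome = 10, lethal_marker_window = c(0L, 5L),
    lethal_founder_frequency = 0, n_contemporary_groups = 10, seed = 71))
  bv <- pop$truth$true_breeding_values[, "HR"]
  ped <- pop$pedigree
  set.seed(72)
  cg <- sample(1:10, nrow(ped), replace = TRUE)
  dat <- data.frame(animal = ped$id,
                    value = rnorm(nrow(ped), bv[ped$id] + 0.3 * cg), cg = cg)
  fit <- gibbs_threshold_model(dat, ped, n_iter = 6000, burn_in = 1500,
                               thin = 5, seed = 73, liability_observed = TRUE)
  db <- deregress(fit, ped, min_acc = 0.40)
  expect_gt(nrow(db), 100)
  slope <- coef(lm(db$debv ~ bv[db$animal]))[2]
  expect_lt(abs(slope - 1), 0.35)
  expect_true(all(db$accuracy >= 0.40))
  expect_true(all(db$weight > 0))
})
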
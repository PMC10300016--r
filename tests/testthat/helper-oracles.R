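# Independent brute-force oracles the implementation is checked against.

# dense tabular numerator relationship matrix (recursive, O(n^2))
tabular_A <- function(ped) {
  n <- nrow(ped)
  s <- attr(ped, "sire_idx")
  d <- attr(ped, "dam_idx")
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    asd <- if (s[i] > 0 && d[i] > 0) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * asd
    for (j in seq_len(i - 1L)) {
      aij <- 0
      if (s[i] > 0) aij <- aij + 0.5 * A[j, s[i]]
      if (d[i] > 0) aij <- aij + 0.5 * A[j, d[i]]
      A[i, j] <- A[j, i] <- aij
    }
  }
  A
}

# two-step pedigree lookup, per animal
mgs_brute <- function(ped, animal) {
  vapply(animal, function(a) {
    row <- ped[ped$id == a, ]
    if (nrow(row) == 0L || is.na(row$dam)) return(NA_character_)
    drow <- ped[ped$id == row$dam, ]
    if (nrow(drow) == 0L) return(NA_character_)
    drow$sire
  }, character(1), USE.NAMES = FALSE)
}

# carrier-sire x carrier-MGS progeny, one explicit loop
carrier_matings_brute <- function(ped, carriers, genotyped) {
  ct <- 0L
  for (a in genotyped) {
    row <- ped[ped$id == a, ]
    if (nrow(row) == 0L || is.na(row$sire) || is.na(row$dam)) next
    mgs <- ped$sire[ped$id == row$dam]
    if (length(mgs) == 0L || is.na(mgs)) next
    if (row$sire %in% carriers && mgs %in% carriers) ct <- ct + 1L
  }
  ct
}

# closed-form OLS with intercept via lm(), the textbook reference
ols_oracle <- function(y, x) {
  fit <- summary(lm(y ~ x))
  co <- coef(fit)["x", ]
  p <- unname(co["Pr(>|t|)"])
  list(effect = unname(co["Estimate"]), se = unname(co["Std. Error"]),
       t = unname(co["t value"]), p = p)
}

# all-pairs interval scan for gene-window annotation
window_hits_brute <- function(markers, genes, window) {
  out <- list()
  for (i in seq_len(nrow(markers))) {
    for (j in seq_len(nrow(genes))) {
      if (markers$chrom[i] != genes$chrom[j]) next
      dist <- max(genes$start[j] - markers$pos[i],
                  markers$pos[i] - genes$end[j], 0)
      if (dist <= window)
        out[[length(out) + 1L]] <- data.frame(
          marker = markers$marker[i], gene_id = genes$gene_id[j],
          distance = dist)
    }
  }
  if (!length(out)) return(data.frame(marker = character(0),
                                      gene_id = character(0),
                                      distance = integer(0)))
  do.call(rbind, out)
}

# random pedigree generator for property tests (topologically valid)
random_pedigree <- function(n, p_known = 0.8, seed = 1) {
  set.seed(seed)
  id <- sprintf("P%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  for (i in seq_len(n)) {
    if (i <= 10L) next
    prev_m <- which(sex[seq_len(i - 1L)] == "M")
    prev_f <- which(sex[seq_len(i - 1L)] == "F")
    if (length(prev_m) && runif(1) < p_known) sire[i] <- id[sample(prev_m, 1)]
    if (length(prev_f) && runif(1) < p_known) dam[i] <- id[sample(prev_f, 1)]
  }
  as_pedigree(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                         stringsAsFactors = FALSE))
}

fixture_candidates <- function() {
  path <- system.file("extdata", "nellore_candidate_counts.tsv",
                      package = "lethalscan")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             colClasses = c(hap_id = "character", bta = "character"))
}

small_sim <- function(seed = 11, lethal = 0.08, ...) {
  simulate_population(sim_config(
    n_founders = 150, n_generations = 3, n_sires_per_gen = 12,
    offspring_per_mating = 2, n_chromosomes = 2,
    markers_per_chromosome = 60, lethal_marker_window = c(20L, 40L),
    lethal_founder_frequency = lethal, seed = seed, ...))
}
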
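# Gene-drop simulator: pedigreed population with a planted recessive
# lethal haplotype, phased marker panel, and binary traits generated under
# a liability threshold model. The generated data have the statistical
# structure the downstream screen assumes (heavy sire reuse through AI,
# partially unknown parents, zero homozygotes at the lethal window), so
# every stage of the pipeline can be exercised without external data.

#' Simulation configuration
#'
#' Defaults emulate the structure of a large commercial beef population:
#' heavy sire reuse across discrete generations, 40.4% unknown sires and
#' 18.7% unknown dams in the reported pedigree, a recessive lethal
#' haplotype segregating at a founder frequency of 5% (about 10% carriers),
#' and binary reproductive/survival traits (heifer rebreeding HR,
#' stayability STAY, post-natal mortality PNM) with liability-scale
#' heritabilities 0.31/0.33/0.41 and incidences 59.3%/47.4%/2.1%.
#'
#' @param n_founders number of base-population animals (half female)
#' @param n_generations number of discrete descendant generations
#' @param n_sires_per_gen sires in service per generation (AI-style reuse)
#' @param offspring_per_mating conceptions per dam per generation
#' @param n_chromosomes,markers_per_chromosome,chromosome_length_bp panel
#'   geometry; markers are evenly spaced along each chromosome
#' @param lethal_chromosome chromosome carrying the planted lethal
#' @param lethal_marker_window half-open 0-based marker index range of the
#'   lethal allele's background haplotype on that chromosome
#' @param lethal_founder_frequency frequency of lethal-bearing founder
#'   haplotype copies, in `[0, 0.5]`; 0 disables the lethal
#' @param prob_unknown_sire,prob_unknown_dam masking probabilities applied
#'   to the reported pedigree of non-founders (true parentage is still used
#'   for transmission)
#' @param n_contemporary_groups,cg_effect_sd contemporary-group structure
#'   of the traits (liability-scale SD of CG effects)
#' @param heritabilities,trait_incidences named per-trait vectors
#' @param pnm_carrier_penalty liability-scale penalty added to the PNM
#'   liability of calves whose (true) sire and dam are both carriers;
#'   default 0 (the lethal itself acts purely before genotyping)
#' @param seed integer seed; the whole population is a deterministic
#'   function of the configuration
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_founders = 400L,
                       n_generations = 4L,
                       n_sires_per_gen = 20L,
                       offspring_per_mating = 2L,
                       n_chromosomes = 2L,
                       markers_per_chromosome = 300L,
                       chromosome_length_bp = 1e8,
                       lethal_chromosome = 1L,
                       lethal_marker_window = c(150L, 160L),
                       lethal_founder_frequency = 0.05,
                       prob_unknown_sire = 0.404,
                       prob_unknown_dam = 0.187,
                       n_contemporary_groups = 20L,
                       cg_effect_sd = 0.5,
                       heritabilities = c(HR = 0.31, STAY = 0.33, PNM = 0.41),
                       trait_incidences = c(HR = 0.593, STAY = 0.4738, PNM = 0.0212),
                       pnm_carrier_penalty = 0,
                       seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              n_sires_per_gen = as.integer(n_sires_per_gen),
              offspring_per_mating = as.integer(offspring_per_mating),
              n_chromosomes = as.integer(n_chromosomes),
              markers_per_chromosome = as.integer(markers_per_chromosome),
              chromosome_length_bp = chromosome_length_bp,
              lethal_chromosome = as.integer(lethal_chromosome),
              lethal_marker_window = as.integer(lethal_marker_window),
              lethal_founder_frequency = lethal_founder_frequency,
              prob_unknown_sire = prob_unknown_sire,
              prob_unknown_dam = prob_unknown_dam,
              n_contemporary_groups = as.integer(n_contemporary_groups),
              cg_effect_sd = cg_effect_sd,
              heritabilities = heritabilities,
              trait_incidences = trait_incidences,
              pnm_carrier_penalty = pnm_carrier_penalty,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$prob_unknown_sire, cfg$prob_unknown_dam,
             cfg$trait_incidences, cfg$lethal_founder_frequency)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$lethal_founder_frequency > 0.5)
    stop("lethal_founder_frequency must be <= 0.5")
  w <- cfg$lethal_marker_window
  if (length(w) != 2L || w[1] < 0L || w[2] <= w[1] ||
      w[2] > cfg$markers_per_chromosome)
    stop("lethal_marker_window must be a half-open range within the chromosome")
  if (cfg$lethal_chromosome < 1L || cfg$lethal_chromosome > cfg$n_chromosomes)
    stop("lethal_chromosome out of range")
  if (any(cfg$heritabilities <= 0 | cfg$heritabilities >= 1))
    stop("heritabilities must lie in (0, 1)")
  stopifnot(cfg$n_founders >= 2L, cfg$n_generations >= 1L,
            cfg$n_sires_per_gen >= 1L, cfg$offspring_per_mating >= 1L,
            length(cfg$seed) == 1L)
  if (!identical(sort(names(cfg$heritabilities)), sort(names(cfg$trait_incidences))))
    stop("heritabilities and trait_incidences must name the same traits")
  invisible(cfg)
}

# one gamete: free recombination between chromosomes, Poisson(1) crossovers
# per chromosome at uniform positions, recombination-free transmission
# within resulting blocks
.gamete <- function(h1, h2, chrom_cols, chrom_pos, chrom_len) {
  g <- integer(length(h1))
  for (cc in seq_along(chrom_cols)) {
    cols <- chrom_cols[[cc]]
    ncx <- stats::rpois(1L, 1)
    first <- sample.int(2L, 1L)
    if (ncx == 0L) {
      g[cols] <- if (first == 1L) h1[cols] else h2[cols]
    } else {
      br <- sort(stats::runif(ncx, 0, chrom_len))
      seg <- findInterval(chrom_pos[[cc]], br)
      take1 <- (seg + first) %% 2L == 1L
      g[cols] <- ifelse(take1, h1[cols], h2[cols])
    }
  }
  g
}

#' Simulate a pedigreed population with a planted lethal haplotype
#'
#' Founder haplotypes are drawn marker-by-marker with allele frequencies
#' uniform on `[0.05, 0.95]`. A fixed allele string over the configured
#' marker window is written onto the chosen fraction of founder haplotype
#' copies (never two copies in one founder); an individual is a carrier
#' when exactly one of its haplotypes matches that string over the window.
#' Descent is simulated generation by generation with heavy sire reuse;
#' any conceptus whose two haplotypes both match the lethal string dies
#' before entering the genotyped set. After mating, sire and dam fields of
#' the reported pedigree are masked to unknown with the configured
#' probabilities (true parentage drives transmission and breeding values).
#' Binary trait records arise from liabilities l = cg + a + e with the
#' additive value a following the true pedigree (founders N(0, sigma2_a),
#' offspring midparent plus Mendelian sampling), e standard normal, and
#' the threshold set to match the configured incidence.
#'
#' @param config a [sim_config()]
#' @return object of class `sim_population`: list with `pedigree` (masked,
#'   [as_pedigree()]), `panel` ([phased_panel()]), `traits` (data.frame
#'   animal/trait/value/cg) and `truth` (lethal window, allele string,
#'   carrier ids, true parents, CG effects, true breeding values)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  M <- cfg$n_chromosomes * cfg$markers_per_chromosome
  map <- data.frame(
    chrom = as.character(rep(seq_len(cfg$n_chromosomes),
                             each = cfg$markers_per_chromosome)),
    pos = rep(round(seq(1, cfg$chromosome_length_bp,
                        length.out = cfg$markers_per_chromosome)),
              times = cfg$n_chromosomes),
    id = sprintf("snp_%d_%d", rep(seq_len(cfg$n_chromosomes),
                                  each = cfg$markers_per_chromosome),
                 rep(seq_len(cfg$markers_per_chromosome), cfg$n_chromosomes)),
    stringsAsFactors = FALSE)
  chrom_cols <- split(seq_len(M), map$chrom)[as.character(seq_len(cfg$n_chromosomes))]
  chrom_pos <- lapply(chrom_cols, function(j) map$pos[j])

  freqs <- stats::runif(M, 0.05, 0.95)
  nf <- cfg$n_founders
  Hf <- matrix(stats::rbinom(2L * nf * M, 1L, rep(freqs, each = 2L * nf)),
               nrow = 2L * nf, ncol = M)

  lw <- cfg$lethal_marker_window
  lcols <- chrom_cols[[cfg$lethal_chromosome]][(lw[1] + 1L):lw[2]]
  lethal_str <- NULL
  if (cfg$lethal_founder_frequency > 0) {
    lethal_vec <- stats::rbinom(length(lcols), 1L, freqs[lcols])
    lethal_str <- paste(lethal_vec, collapse = "")
    n_copies <- max(1L, round(2L * nf * cfg$lethal_founder_frequency))
    n_copies <- min(n_copies, nf)         # at most one copy per founder
    chosen <- sample.int(nf, n_copies)
    planted_rows <- 2L * chosen - 2L + sample(c(1L, 2L), n_copies,
                                              replace = TRUE)
    # the planted copies are the only founder copies carrying the string:
    # flip one window marker in every coincidental match so the lethal
    # segregates at exactly the configured founder frequency
    match_row <- apply(Hf[, lcols, drop = FALSE], 1L, paste,
                       collapse = "") == lethal_str
    for (r in setdiff(which(match_row), planted_rows)) {
      j <- if (length(lcols) == 1L) lcols else sample(lcols, 1L)
      Hf[r, j] <- 1L - Hf[r, j]
    }
    for (r in planted_rows) Hf[r, lcols] <- lethal_vec
  }

  is_lethal_hap <- function(h) {
    !is.null(lethal_str) && paste(h[lcols], collapse = "") == lethal_str
  }

  # discrete-generation gene drop; panel matrix grows on demand
  cap <- 4L * nf
  H <- matrix(0L, nrow = 2L * cap, ncol = M)
  H[seq_len(2L * nf), ] <- Hf
  ensure_cap <- function(n_needed) {
    if (2L * n_needed > nrow(H)) {
      H2 <- matrix(0L, nrow = 2L * nrow(H), ncol = M)
      H2[seq_len(nrow(H)), ] <- H
      H <<- H2
    }
  }
  id <- sprintf("A%06d", seq_len(nf))
  sire <- rep(NA_character_, nf)
  dam <- rep(NA_character_, nf)
  sex <- sample(rep(c("M", "F"), length.out = nf))
  gen <- rep(0L, nf)
  n_anim <- nf
  prev <- seq_len(nf)

  for (g in seq_len(cfg$n_generations)) {
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (!length(males) || !length(females))
      stop("generation ", g, " has no available sires or dams")
    sires_g <- if (length(males) <= cfg$n_sires_per_gen) males else
      sample(males, cfg$n_sires_per_gen)
    born <- integer(0)
    for (dm in females) {
      for (k in seq_len(cfg$offspring_per_mating)) {
        sr <- if (length(sires_g) == 1L) sires_g else sample(sires_g, 1L)
        g1 <- .gamete(H[2L * sr - 1L, ], H[2L * sr, ], chrom_cols, chrom_pos,
                      cfg$chromosome_length_bp)
        g2 <- .gamete(H[2L * dm - 1L, ], H[2L * dm, ], chrom_cols, chrom_pos,
                      cfg$chromosome_length_bp)
        if (is_lethal_hap(g1) && is_lethal_hap(g2)) next  # dies in utero
        n_anim <- n_anim + 1L
        ensure_cap(n_anim)
        H[2L * n_anim - 1L, ] <- g1
        H[2L * n_anim, ] <- g2
        id[n_anim] <- sprintf("A%06d", n_anim)
        sire[n_anim] <- id[sr]
        dam[n_anim] <- id[dm]
        sex[n_anim] <- sample(c("M", "F"), 1L)
        gen[n_anim] <- g
        born <- c(born, n_anim)
      }
    }
    prev <- born
  }
  H <- H[seq_len(2L * n_anim), , drop = FALSE]
  id <- id[seq_len(n_anim)]; sire <- sire[seq_len(n_anim)]
  dam <- dam[seq_len(n_anim)]; sex <- sex[seq_len(n_anim)]
  gen <- gen[seq_len(n_anim)]

  # carrier truth: exactly one haplotype matching the lethal string
  if (!is.null(lethal_str)) {
    s1 <- apply(H[seq(1L, 2L * n_anim, by = 2L), lcols, drop = FALSE], 1L,
                paste, collapse = "") == lethal_str
    s2 <- apply(H[seq(2L, 2L * n_anim, by = 2L), lcols, drop = FALSE], 1L,
                paste, collapse = "") == lethal_str
    carriers <- id[xor(s1, s2)]
    stopifnot(!any(s1 & s2))
  } else {
    carriers <- character(0)
  }

  # contemporary groups and liability traits
  cgs <- sample.int(cfg$n_contemporary_groups, n_anim, replace = TRUE)
  traits <- names(cfg$heritabilities)
  cg_eff <- matrix(stats::rnorm(cfg$n_contemporary_groups * length(traits),
                                0, cfg$cg_effect_sd),
                   ncol = length(traits), dimnames = list(NULL, traits))
  sidx <- match(sire, id); didx <- match(dam, id)
  bv <- matrix(0, n_anim, length(traits), dimnames = list(id, traits))
  rec <- vector("list", length(traits)); names(rec) <- traits
  both_carrier <- !is.na(sidx) & !is.na(didx) &
    id[pmax(sidx, 1L)] %in% carriers & id[pmax(didx, 1L)] %in% carriers
  for (tr in traits) {
    h2 <- cfg$heritabilities[[tr]]
    s2a <- h2 / (1 - h2)                 # residual variance 1
    a <- numeric(n_anim)
    for (i in seq_len(n_anim)) {
      if (is.na(sidx[i]) && is.na(didx[i])) {
        a[i] <- stats::rnorm(1, 0, sqrt(s2a))
      } else {
        pa <- mean(c(if (!is.na(sidx[i])) a[sidx[i]] else 0,
                     if (!is.na(didx[i])) a[didx[i]] else 0))
        a[i] <- pa + stats::rnorm(1, 0, sqrt(s2a / 2))
      }
    }
    bv[, tr] <- a
    l <- cg_eff[cgs, tr] + a + stats::rnorm(n_anim)
    if (tr == "PNM" && cfg$pnm_carrier_penalty != 0)
      l[both_carrier] <- l[both_carrier] + cfg$pnm_carrier_penalty
    thr <- stats::qnorm(1 - cfg$trait_incidences[[tr]], 0,
                        sqrt(s2a + 1 + cfg$cg_effect_sd^2))
    rec[[tr]] <- data.frame(animal = id, trait = tr,
                            value = as.integer(l > thr), cg = cgs,
                            stringsAsFactors = FALSE)
  }
  trait_df <- do.call(rbind, rec)
  rownames(trait_df) <- NULL

  # masked (reported) pedigree; founders keep unknown parents
  nonf <- gen > 0L
  mask_s <- nonf & stats::runif(n_anim) < cfg$prob_unknown_sire
  mask_d <- nonf & stats::runif(n_anim) < cfg$prob_unknown_dam
  ped_df <- data.frame(id = id,
                       sire = ifelse(mask_s, NA_character_, sire),
                       dam = ifelse(mask_d, NA_character_, dam),
                       sex = sex, generation = gen,
                       birth_year = 2000L + gen, season = 1L, herd = 1L,
                       cg = cgs, stringsAsFactors = FALSE)

  truth <- list(lethal_chromosome = as.character(cfg$lethal_chromosome),
                lethal_marker_window = lw,
                lethal_haplotype_allele_string = lethal_str,
                true_carrier_ids = carriers,
                true_sire = stats::setNames(sire, id),
                true_dam = stats::setNames(dam, id),
                true_cg_effects = cg_eff,
                true_breeding_values = bv)

  pop <- list(pedigree = as_pedigree(ped_df),
              panel = phased_panel(H, map, id),
              traits = trait_df,
              truth = truth,
              config = cfg)
  class(pop) <- "sim_population"
  pop
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("Simulated population: %d genotyped animals, %d markers, %d carriers of the planted lethal\n",
              length(x$panel$ids), nrow(x$panel$map),
              length(x$truth$true_carrier_ids)))
  invisible(x)
}

#' Write a simulated population to disk
#'
#' Emits a phased VCF, pedigree CSV, traits CSV, marker-map TSV and a truth
#' JSON, in the formats the readers in this package expect; a write/read
#' cycle is lossless.
#'
#' @param pop a [simulate_population()] result
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of file paths written
#' @export
write_population <- function(pop, dir) {
  stopifnot(inherits(pop, "sim_population"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             ped = file.path(dir, "pedigree.csv"),
             traits = file.path(dir, "traits.csv"),
             map = file.path(dir, "map.tsv"),
             truth = file.path(dir, "truth.json"))
  write_phased_vcf(pop$panel, paths["vcf"])
  write.csv(as.data.frame(pop$pedigree), paths["ped"], row.names = FALSE,
            quote = FALSE, na = "")
  write.csv(pop$traits, paths["traits"], row.names = FALSE, quote = FALSE)
  write.table(pop$panel$map, paths["map"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  tr <- pop$truth
  tr$true_cg_effects <- as.data.frame(tr$true_cg_effects)
  tr$true_breeding_values <- cbind(data.frame(animal = rownames(tr$true_breeding_values)),
                                   as.data.frame(tr$true_breeding_values))
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(paths)
}

#' Read a population written by [write_population()]
#'
#' @param dir directory containing the files
#' @return a `sim_population`-like list (without the generating config)
#' @export
read_population <- function(dir) {
  ped <- as_pedigree(read.csv(file.path(dir, "pedigree.csv"),
                              colClasses = "character"))
  ped$generation <- as.integer(ped$generation)
  ped$birth_year <- as.integer(ped$birth_year)
  ped$season <- as.integer(ped$season)
  ped$herd <- as.integer(ped$herd)
  ped$cg <- as.integer(ped$cg)
  traits <- read.csv(file.path(dir, "traits.csv"),
                     colClasses = c(animal = "character", trait = "character",
                                    value = "integer", cg = "integer"))
  panel <- read_phased_vcf(file.path(dir, "genotypes.vcf"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  if (!is.null(truth$true_breeding_values)) {
    bv <- truth$true_breeding_values
    rn <- bv$animal
    bv <- as.matrix(bv[setdiff(names(bv), "animal")])
    rownames(bv) <- rn
    truth$true_breeding_values <- bv
  }
  structure(list(pedigree = ped, panel = panel, traits = traits,
                 truth = truth), class = "sim_population")
}
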
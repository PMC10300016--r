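# Umbrella driver: simulate (or load) -> marker QC -> haplotype scan ->
# depletion test -> threshold-model EBVs -> deregression -> association ->
# gene-window annotation, writing every intermediate as TSV/JSON so the
# analysis scripts stay thin.

.pipeline_keys <- c("out_dir", "seed", "stages", "sim", "vcf", "pedigree",
                    "traits", "genes", "max_len", "min_hap_pct",
                    "min_exp_hom", "max_phh", "min_acc", "sig_threshold",
                    "window_bp", "gibbs", "traits_to_fit", "qc",
                    "log_level")

.pipeline_stages <- c("simulate", "qc", "scan", "depletion", "ebv",
                      "deregress", "gwas", "annotate")

#' Validate a pipeline configuration
#'
#' Unknown keys are rejected before any stage executes; thresholds are
#' checked against their domains. A seed is mandatory because several
#' stages are stochastic.
#'
#' @param config named list (or path to a YAML file with the same keys)
#' @return the validated config, with defaults filled in
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .pipeline_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$out_dir)) stop("out_dir is required")
  if (is.null(config$seed)) stop("seed is required for stochastic stages")
  defaults <- list(stages = .pipeline_stages, max_len = 200L,
                   min_hap_pct = 2, min_exp_hom = 1, max_phh = 0.6,
                   min_acc = 0.40, sig_threshold = 6, window_bp = 100000,
                   gibbs = list(n_iter = 20000L, burn_in = 4000L, thin = 10L),
                   qc = TRUE, log_level = "info")
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  bad <- setdiff(config$stages, .pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stopifnot(config$min_hap_pct >= 0, config$min_exp_hom >= 0,
            config$max_phh > 0, config$max_phh <= 1,
            config$min_acc >= 0, config$min_acc <= 1,
            config$window_bp >= 0, config$sig_threshold > 0)
  config
}

.plog <- function(config, ...) {
  if (!identical(config$log_level, "quiet"))
    message(sprintf("[lethalscan] %s", sprintf(...)))
}

#' Run the full screen end to end
#'
#' Executes the enabled stages in order and writes every intermediate
#' under `out_dir`. Re-running with an identical configuration (including
#' the seed) reproduces identical outputs.
#'
#' @param config see [validate_run_config()]; either a simulated input
#'   (`sim` = list of [sim_config()] arguments) or paths `vcf`,
#'   `pedigree`, `traits` (and optionally `genes` for annotation)
#' @return invisibly, a list with the in-memory stage results
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  res <- list(config = config)

  if ("simulate" %in% st) {
    cfg <- do.call(sim_config, c(config$sim %||% list(),
                                 if (is.null(config$sim$seed))
                                   list(seed = config$seed)))
    pop <- simulate_population(cfg)
    write_population(pop, file.path(out, "simdata"))
    .plog(config, "simulated %d animals (%d lethal carriers)",
          length(pop$panel$ids), length(pop$truth$true_carrier_ids))
  } else {
    if (is.null(config$vcf) || is.null(config$pedigree))
      stop("without the simulate stage, vcf and pedigree paths are required")
    panel <- read_phased_vcf(config$vcf)
    ped <- as_pedigree(read.csv(config$pedigree, colClasses = "character"))
    traits <- if (!is.null(config$traits))
      read.csv(config$traits, colClasses = c(animal = "character")) else NULL
    pop <- list(panel = panel, pedigree = ped, traits = traits)
  }
  res$population <- pop

  panel <- pop$panel
  if ("qc" %in% st && isTRUE(config$qc)) {
    chroms <- unique(harmonize_chrom(panel$map$chrom))
    panel <- qc_markers(panel, autosomes = chroms)  # keep sim chromosomes
    rep_qc <- attr(panel, "qc_report")
    .plog(config, "marker QC: %d -> %d markers", rep_qc$n_in, rep_qc$n_out)
    res$qc_report <- rep_qc
  }

  if ("scan" %in% st) {
    plan <- plan_segments(panel$map, max_len = config$max_len)
    catalog <- enumerate_haplotypes(panel, plan)
    write_catalog(catalog, file.path(out, "catalog.tsv"))
    .plog(config, "scan: %d segments, %d distinct haplotypes",
          nrow(plan), nrow(catalog))
    res$plan <- plan; res$catalog <- catalog
  }

  if ("depletion" %in% st) {
    report <- depletion_report(res$catalog, pop$pedigree, panel$ids,
                               min_hap_pct = config$min_hap_pct,
                               min_exp_hom = config$min_exp_hom,
                               max_phh = config$max_phh)
    write_tsv_report(report[, setdiff(names(report), c("carriers"))],
                     file.path(out, "depletion.tsv"), seed = config$seed)
    candidates <- filter_candidates(report, config$min_hap_pct,
                                    config$min_exp_hom, config$max_phh)
    write_candidate_table(candidates, file.path(out, "candidates.tsv"))
    .plog(config, "depletion: %d zero-homozygote haplotypes, %d candidates",
          nrow(report), nrow(candidates))
    res$depletion <- report; res$candidates <- candidates
  }

  trait_names <- config$traits_to_fit %||% unique(pop$traits$trait)
  if (any(c("ebv", "deregress", "gwas") %in% st) && length(trait_names)) {
    res$fits <- list(); res$debv <- list(); res$assoc <- list()
    res$hap_assoc <- list()
    dose <- panel_dosages(panel)
    for (k in seq_along(trait_names)) {
      tr <- trait_names[k]
      dat <- prepare_traits(pop$traits[pop$traits$trait == tr, , drop = FALSE])
      if (!("ebv" %in% st)) next
      fit <- gibbs_threshold_model(dat, pop$pedigree,
                                   n_iter = config$gibbs$n_iter,
                                   burn_in = config$gibbs$burn_in,
                                   thin = config$gibbs$thin,
                                   seed = config$seed + 1000L * k)
      write_tsv_report(fit$ebv, file.path(out, sprintf("ebv_%s.tsv", tr)),
                       seed = config$seed)
      jsonlite::write_json(list(trait = tr,
                                sig2a = as.list(fit$sig2a),
                                h2 = as.list(fit$h2)),
                           file.path(out, sprintf("varcomp_%s.json", tr)),
                           auto_unbox = TRUE, digits = NA)
      .plog(config, "%s: h2 = %.3f (SD %.3f)", tr, fit$h2["mean"], fit$h2["sd"])
      res$fits[[tr]] <- fit
      if (!("deregress" %in% st)) next
      db <- deregress(fit, pop$pedigree, min_acc = config$min_acc)
      write_tsv_report(db, file.path(out, sprintf("debv_%s.tsv", tr)),
                       seed = config$seed)
      res$debv[[tr]] <- db
      if (!("gwas" %in% st)) next
      assoc <- snp_association(db, dose, map = panel$map,
                               threshold = config$sig_threshold)
      write_tsv_report(assoc, file.path(out, sprintf("assoc_%s.tsv", tr)),
                       seed = config$seed)
      res$assoc[[tr]] <- assoc
      if (!is.null(res$candidates) && nrow(res$candidates)) {
        carr <- attr(res$depletion, "carriers")
        ha <- do.call(rbind, lapply(seq_len(nrow(res$candidates)), function(r) {
          hid <- res$candidates$hap_id[r]
          haplotype_association(db,
                                carr[[match(hid, res$depletion$hap_id)]],
                                threshold = config$sig_threshold, id = hid)
        }))
        write_tsv_report(ha, file.path(out, sprintf("hapassoc_%s.tsv", tr)),
                         seed = config$seed)
        res$hap_assoc[[tr]] <- ha
      }
    }
    if ("gwas" %in% st && length(res$assoc) >= 2L) {
      ov <- cross_trait_overlap(res$assoc)
      jsonlite::write_json(ov, file.path(out, "overlap.json"),
                           auto_unbox = TRUE, digits = NA)
      res$overlap <- ov
    }
  }

  if ("annotate" %in% st && !is.null(config$genes) && length(res$assoc)) {
    genes <- read_genes(config$genes)
    res$gene_hits <- lapply(res$assoc, annotate_windows, genes = genes,
                            window = config$window_bp)
    for (tr in names(res$gene_hits))
      write_tsv_report(res$gene_hits[[tr]],
                       file.path(out, sprintf("gene_hits_%s.tsv", tr)),
                       seed = config$seed)
  }

  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
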
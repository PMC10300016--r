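# Liability threshold animal model and deregression of breeding values.
#
# The model is l = X beta + Z a + e on the latent liability scale, with
# contemporary-group fixed effects, a pedigree additive effect
# a ~ N(0, A sig2a) and e ~ N(0, I). For identifiability the residual
# variance is fixed at 1 and the threshold at 0; the reported heritability
# h2 = sig2a / (sig2a + 1) is scale-free. Fitting is by single-site Gibbs
# sampling (compiled core in src/gibbs.cpp).

#' Contemporary-group editing of binary trait records
#'
#' Removes contemporary groups with fewer than `min_cg` records or without
#' variability (all 0 or all 1), the standard edit for categorical-trait
#' evaluations.
#'
#' @param raw data.frame with columns `animal`, `value` (0/1), `cg`
#'   (a `trait` column, if present, is preserved; editing is within trait)
#' @param min_cg minimum records per contemporary group (default 5)
#' @return the surviving records; attribute `edit_report` counts removals
#' @export
prepare_traits <- function(raw, min_cg = 5L) {
  stopifnot(all(c("animal", "value", "cg") %in% names(raw)))
  if (!all(raw$value %in% c(0L, 1L))) stop("trait values must be 0/1")
  key <- if ("trait" %in% names(raw)) paste(raw$trait, raw$cg) else
    as.character(raw$cg)
  n_by <- tapply(raw$value, key, length)
  v_by <- tapply(raw$value, key, function(v) length(unique(v)))
  small <- names(n_by)[n_by < min_cg]
  novar <- names(v_by)[v_by < 2L]
  keep <- !(key %in% union(small, novar))
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) stop("no records survive contemporary-group editing")
  attr(out, "edit_report") <- list(
    n_in = nrow(raw), n_out = nrow(out),
    cg_removed_small = length(small),
    cg_removed_novar = length(setdiff(novar, small)))
  out
}

#' Fit the liability threshold animal model by Gibbs sampling
#'
#' Each cycle samples (1) a latent liability per record from a unit-variance
#' normal centred at the CG effect plus animal effect, truncated below or
#' above 0 according to the binary record, (2) CG and animal effects
#' single-site from their mixed-model conditionals using the sparse
#' A-inverse, and (3) the additive variance from its scaled inverse
#' chi-square conditional. Reliabilities come from the posterior
#' prediction-error variance: r2 = 1 - PEV / sig2a.
#'
#' @param data record data.frame (`animal`, `value`, `cg`), typically a
#'   single trait after [prepare_traits()]
#' @param ped a [as_pedigree()] containing every recorded animal
#' @param n_iter,burn_in,thin chain settings (defaults 20000 / 4000 / 10)
#' @param nu,s2 scaled inverse chi-square prior for the additive variance
#'   (defaults nu = 4, s2 = 0.25: weakly informative around h2 ~ 0.3)
#' @param seed integer seed; the chain is reproducible for a fixed seed
#'   and record order
#' @param use_inbreeding pass through to [a_inverse()]
#' @param liability_observed treat `value` as the observed (continuous)
#'   liability itself: the Gaussian limit used for validation
#' @param fix_sig2a fix the additive variance instead of sampling it
#' @param sig2a_cap divergence guard: chains exceeding this additive
#'   variance are flagged in `diagnostics`
#' @return object of class `gibbs_result`: `ebv` data.frame (animal, ebv,
#'   pev, reliability), `beta` (posterior-mean CG effects), `sig2a` and
#'   `h2` posterior mean/SD, `h2_samples`, `diagnostics`
#' @export
gibbs_threshold_model <- function(data, ped, n_iter = 20000L,
                                  burn_in = 4000L, thin = 10L,
                                  nu = 4, s2 = 0.25, seed = NULL,
                                  use_inbreeding = TRUE,
                                  liability_observed = FALSE,
                                  fix_sig2a = NULL, sig2a_cap = 50) {
  stopifnot(inherits(ped, "pedigree"),
            all(c("animal", "value", "cg") %in% names(data)),
            n_iter > burn_in, thin >= 1L)
  if (!liability_observed && !all(data$value %in% c(0L, 1L)))
    stop("binary records required (or set liability_observed = TRUE)")
  if (!is.null(seed)) set.seed(seed)

  anim_idx <- .ped_lookup(ped, as.character(data$animal)) - 1L
  cg_lev <- sort(unique(data$cg))
  cg_idx <- match(data$cg, cg_lev) - 1L

  fac <- a_inverse(ped, use_inbreeding = use_inbreeding)
  Ai <- fac$Ainv  # dgCMatrix; symmetric, so CSC columns double as CSR rows

  fit <- gibbs_threshold_cpp(
    rec_anim = anim_idx, rec_cg = cg_idx, y = as.numeric(data$value),
    n_anim = nrow(ped), n_cg = length(cg_lev),
    ai_p = Ai@p, ai_j = Ai@i, ai_x = Ai@x,
    n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
    thin = as.integer(thin), nu = nu, s2 = s2,
    liability_observed = liability_observed,
    fix_sig2a = if (is.null(fix_sig2a)) -1 else fix_sig2a,
    sig2a_cap = sig2a_cap)

  sig2a_hat <- mean(fit$sig2a)
  rel <- pmin(pmax(1 - fit$a_var / sig2a_hat, 0), 1)
  res <- list(
    ebv = data.frame(animal = ped$id, ebv = fit$a_mean, pev = fit$a_var,
                     reliability = rel, stringsAsFactors = FALSE),
    beta = stats::setNames(fit$beta_mean, cg_lev),
    sig2a = c(mean = sig2a_hat, sd = stats::sd(fit$sig2a)),
    h2 = c(mean = mean(fit$h2), sd = stats::sd(fit$h2)),
    h2_samples = fit$h2,
    sig2a_samples = fit$sig2a,
    diagnostics = list(n_samples = fit$n_samples,
                       divergent = fit$divergent,
                       n_records = nrow(data), n_cg = length(cg_lev)))
  class(res) <- "gibbs_result"
  res
}

#' @export
print.gibbs_result <- function(x, ...) {
  cat(sprintf("Threshold-model fit: %d records, %d CGs, %d posterior samples\n",
              x$diagnostics$n_records, x$diagnostics$n_cg,
              x$diagnostics$n_samples))
  cat(sprintf("  sig2a = %.3f (SD %.3f), h2 = %.3f (SD %.3f)%s\n",
              x$sig2a["mean"], x$sig2a["sd"], x$h2["mean"], x$h2["sd"],
              if (isTRUE(x$diagnostics$divergent)) "  [divergent]" else ""))
  invisible(x)
}

# Deregression of one animal's EBV given its parent-average EBV and the
# two reliabilities, after Garrick, Taylor & Fernando (2009). The 2x2
# animal/parent-average mixed-model equations
#     [ Zpa'Zpa + 4*lambda   -2*lambda        ] [g_pa]   [y_pa]
#     [ -2*lambda             Zi'Zi + 2*lambda] [g_i ] = [y_i ]
# with lambda = (1 - h2)/h2 imply reliabilities r2 = 1 - lambda * C^jj.
# Inverting those two relations gives (writing B = Zi'Zi + 2*lambda,
# A = Zpa'Zpa + 4*lambda, q_pa = 1 - r2_pa, q_i = 1 - r2_i):
#     B = lambda * (1 + sqrt(1 + 16 * q_pa * q_i)) / (2 * q_i)
#     A = B * q_i / q_pa
# The deregressed information is y_i / Zi'Zi with y_i from the equations'
# right-hand side, its reliability Zi'Zi / (Zi'Zi + lambda), and the GWAS
# weight (1 - h2) / ((c + (1 - r2_debv) / r2_debv) * h2) with c the
# fraction of genetic variance not captured by markers.
.garrick_one <- function(ebv, ebv_pa, r2, r2_pa, h2, cpar) {
  lambda <- (1 - h2) / h2
  qi <- max(1 - r2, 1e-8)
  qpa <- max(1 - r2_pa, 1e-8)
  B <- lambda * (1 + sqrt(1 + 16 * qpa * qi)) / (2 * qi)
  A <- B * qi / qpa
  zi <- B - 2 * lambda
  zpa <- A - 4 * lambda
  if (zi <= 0 || zpa < 0) return(NULL)  # reliability artifact
  yi <- -2 * lambda * ebv_pa + B * ebv
  debv <- yi / zi
  r2_debv <- zi / (zi + lambda)
  w <- (1 - h2) / ((cpar + (1 - r2_debv) / r2_debv) * h2)
  c(debv = debv, r2_debv = r2_debv, weight = w)
}

#' Deregress EBVs for use as a GWAS response
#'
#' Removes the parent-average contribution from each animal's EBV
#' (Garrick-style deregression) and attaches the per-animal weight used in
#' weighted analyses. Animals whose deregressed-EBV accuracy
#' (square root of the deregressed reliability) falls below `min_acc` are
#' dropped; animals with both parents unknown reduce to the simple
#' EBV / r2 scaling. Animals with reliability artifacts (animal
#' reliability not above what the parent average alone provides) are
#' skipped with a message.
#'
#' @param res a [gibbs_threshold_model()] result
#' @param ped the pedigree used in the fit
#' @param h2 heritability used for the deregression (typically the
#'   posterior mean from `res`)
#' @param min_acc minimum accuracy retained, inclusive (default 0.40)
#' @param cpar fraction of genetic variance not explained by markers for
#'   the weight (default 0.5)
#' @return data.frame `animal`, `debv`, `accuracy`, `weight`
#' @export
deregress <- function(res, ped, h2 = unname(res$h2["mean"]),
                      min_acc = 0.40, cpar = 0.5) {
  stopifnot(inherits(res, "gibbs_result"), inherits(ped, "pedigree"),
            h2 > 0, h2 < 1)
  ebv <- res$ebv
  i <- match(ped$id, ebv$animal)
  e <- ebv$ebv[i]; r2 <- ebv$reliability[i]
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  out <- vector("list", nrow(ped))
  skipped <- 0L
  for (k in seq_len(nrow(ped))) {
    if (si[k] == 0L && di[k] == 0L) {
      if (r2[k] <= 0) next
      v <- c(debv = e[k] / r2[k], r2_debv = r2[k],
             weight = (1 - h2) / ((cpar + (1 - r2[k]) / r2[k]) * h2))
    } else {
      ebv_pa <- mean(c(if (si[k] > 0L) e[si[k]] else 0,
                       if (di[k] > 0L) e[di[k]] else 0))
      r2_pa <- ((if (si[k] > 0L) r2[si[k]] else 0) +
                  (if (di[k] > 0L) r2[di[k]] else 0)) / 4
      v <- .garrick_one(e[k], ebv_pa, r2[k], r2_pa, h2, cpar)
      if (is.null(v)) { skipped <- skipped + 1L; next }
    }
    acc <- sqrt(v[["r2_debv"]])
    if (acc < min_acc) next
    out[[k]] <- data.frame(animal = ped$id[k], debv = v[["debv"]],
                           accuracy = acc, weight = v[["weight"]],
                           stringsAsFactors = FALSE)
  }
  if (skipped > 0L)
    message("deregression: skipped ", skipped,
            " animals with reliability <= parent-average reliability")
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(animal = character(0), debv = numeric(0),
                      accuracy = numeric(0), weight = numeric(0))
  rownames(out) <- NULL
  out
}
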
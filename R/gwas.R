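# Association of deregressed breeding values with SNP dosages or
# carrier status, and annotation of significant markers with genes within
# a +/-100 kb window.
#
# The per-marker model is the fixed-effect regression y* = mu + b x + e
# with x the count of the alternate allele (0/1/2), t = b_hat / SE(b_hat),
# and a two-sided p-value from the t distribution with n - 2 degrees of
# freedom. Genome-wide significance uses the fixed rule -log10(p) > 6.

.assoc_core <- function(y, x, df_resid, tail = c("t", "normal")) {
  tail <- match.arg(tail)
  n <- length(y)
  vx <- stats::var(x)
  if (n < 3L || vx == 0 || stats::var(y) == 0) {
    return(data.frame(effect = NA_real_, se = NA_real_, t = NA_real_,
                      p = NA_real_, minus_log10_p = NA_real_,
                      significant = FALSE, testable = FALSE))
  }
  sxx <- vx * (n - 1)
  b <- stats::cov(x, y) * (n - 1) / sxx
  syy <- stats::var(y) * (n - 1)
  rss <- syy - b^2 * sxx
  s2 <- max(rss, 0) / df_resid
  se <- sqrt(s2 / sxx)
  tv <- b / se
  if (tail == "t") {
    logp <- log(2) + stats::pt(-abs(tv), df_resid, log.p = TRUE)
  } else {
    logp <- log(2) + stats::pnorm(-abs(tv), log.p = TRUE)
  }
  p <- exp(logp)
  mlp <- -logp / log(10)
  data.frame(effect = b, se = se, t = tv, p = p, minus_log10_p = mlp,
             significant = FALSE, testable = TRUE)
}

#' Single-SNP association on deregressed breeding values
#'
#' Simple regression with intercept of the dEBV on the 0/1/2 alternate
#' allele dosage, one marker at a time. Monomorphic markers (in the
#' analysed animal set) are flagged not testable rather than dividing by
#' zero.
#'
#' @param debv data.frame `animal`, `debv` (e.g. from [deregress()])
#' @param dosages numeric matrix, animals in rows (rownames = animal ids)
#'   and markers in columns, entries in `{0, 1, 2}`
#' @param map optional marker map (`chrom`, `pos`, `id`) aligned with the
#'   dosage columns, copied onto the results
#' @param threshold genome-wide significance on the -log10(p) scale
#'   (default 6)
#' @param tail `"t"` (default, n - 2 df) or `"normal"`
#' @return data.frame, one row per marker: `marker`, `chrom`, `pos`,
#'   `effect`, `se`, `t`, `p`, `minus_log10_p`, `significant`, `testable`
#' @export
snp_association <- function(debv, dosages, map = NULL, threshold = 6,
                            tail = c("t", "normal")) {
  tail <- match.arg(tail)
  stopifnot(all(c("animal", "debv") %in% names(debv)), is.matrix(dosages))
  if (is.null(rownames(dosages)))
    stop("dosage matrix needs animal ids as rownames")
  common <- intersect(debv$animal, rownames(dosages))
  if (length(common) < 3L) stop("fewer than 3 animals with both dEBV and genotypes")
  y <- debv$debv[match(common, debv$animal)]
  G <- dosages[common, , drop = FALSE]
  if (!all(G %in% c(0, 1, 2))) stop("dosages must be 0, 1 or 2")
  n <- length(y)
  df_resid <- n - 2L
  ym <- mean(y)
  syy <- sum((y - ym)^2)
  xm <- colMeans(G)
  sxx <- colSums(G^2) - n * xm^2
  sxy <- as.vector(crossprod(G, y)) - n * xm * ym
  testable <- sxx > 0 & syy > 0
  b <- ifelse(testable, sxy / sxx, NA_real_)
  rss <- pmax(syy - b^2 * sxx, 0)
  se <- sqrt(rss / df_resid / sxx)
  tv <- b / se
  logp <- if (tail == "t") log(2) + stats::pt(-abs(tv), df_resid, log.p = TRUE)
          else log(2) + stats::pnorm(-abs(tv), log.p = TRUE)
  res <- data.frame(effect = b, se = se, t = tv, p = exp(logp),
                    minus_log10_p = -logp / log(10), significant = FALSE,
                    testable = testable)
  res[!testable, c("effect", "se", "t", "p", "minus_log10_p")] <- NA_real_
  res$marker <- if (!is.null(colnames(G))) colnames(G) else
    sprintf("m%d", seq_len(ncol(G)))
  if (!is.null(map)) {
    stopifnot(nrow(map) == ncol(G))
    res$chrom <- as.character(map$chrom)
    res$pos <- map$pos
  } else {
    res$chrom <- NA_character_; res$pos <- NA_integer_
  }
  res$significant <- res$testable & !is.na(res$minus_log10_p) &
    res$minus_log10_p > threshold
  res$n <- length(y)
  rownames(res) <- NULL
  res[, c("marker", "chrom", "pos", "effect", "se", "t", "p",
          "minus_log10_p", "significant", "testable", "n")]
}

#' Haplotype-carrier association on deregressed breeding values
#'
#' Same regression machinery with the carrier dosage (0 or 1 copies;
#' homozygotes are absent for a lethal haplotype by construction).
#' Positive effect = carrying one copy increases the dEBV.
#'
#' @param debv data.frame `animal`, `debv`
#' @param carriers character vector of carrier animal ids (1 copy)
#' @param threshold,tail see [snp_association()]
#' @param id label for the tested haplotype
#' @return one-row data.frame as in [snp_association()]
#' @export
haplotype_association <- function(debv, carriers, threshold = 6,
                                  tail = c("t", "normal"),
                                  id = "haplotype") {
  tail <- match.arg(tail)
  y <- debv$debv
  x <- as.numeric(debv$animal %in% carriers)
  res <- .assoc_core(y, x, length(y) - 2L, tail)
  res$marker <- id
  res$chrom <- NA_character_; res$pos <- NA_integer_
  res$significant <- res$testable & !is.na(res$minus_log10_p) &
    res$minus_log10_p > threshold
  res$n <- length(y)
  res[, c("marker", "chrom", "pos", "effect", "se", "t", "p",
          "minus_log10_p", "significant", "testable", "n")]
}

#' Genes within a window of significant markers
#'
#' Interval overlap of `[pos - window, pos + window]` (clamped at 1)
#' against gene spans; a gene exactly `window` bp away is included. Only
#' markers flagged significant are annotated. Chromosome names on both
#' sides are harmonised by stripping an optional `chr`/`BTA` prefix; a
#' significant marker whose chromosome is absent from the gene table
#' raises an error listing the offenders.
#'
#' @param results a [snp_association()]-style data.frame
#' @param genes data.frame `chrom`, `start`, `end`, `gene_id` (and
#'   optionally `gene_name`), 1-based inclusive coordinates (see
#'   [read_genes()])
#' @param window half-width in bp (default 100000)
#' @return data.frame `marker`, `chrom`, `pos`, `gene_id`, `gene_name`,
#'   `gene_start`, `gene_end`, `distance` (0 if the marker lies inside
#'   the gene)
#' @export
annotate_windows <- function(results, genes, window = 100000) {
  sig <- results[results$significant %in% TRUE, , drop = FALSE]
  empty <- data.frame(marker = character(0), chrom = character(0),
                      pos = integer(0), gene_id = character(0),
                      gene_name = character(0), gene_start = integer(0),
                      gene_end = integer(0), distance = integer(0))
  if (!nrow(sig)) return(empty)
  sig$chrom <- harmonize_chrom(sig$chrom)
  genes$chrom <- harmonize_chrom(genes$chrom)
  missing <- setdiff(unique(sig$chrom), unique(genes$chrom))
  if (length(missing))
    stop("chromosomes of significant markers absent from gene table: ",
         paste(missing, collapse = ", "))
  if (!("gene_name" %in% names(genes))) genes$gene_name <- genes$gene_id
  hits <- lapply(unique(sig$chrom), function(ch) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    q <- IRanges::IRanges(start = pmax(s$pos - window, 1),
                          end = s$pos + window)
    subj <- IRanges::IRanges(start = g$start, end = g$end)
    ov <- IRanges::findOverlaps(q, subj)
    if (!length(ov)) return(NULL)
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    dist <- pmax(g$start[si] - s$pos[qi], s$pos[qi] - g$end[si], 0)
    data.frame(marker = s$marker[qi], chrom = ch, pos = s$pos[qi],
               gene_id = g$gene_id[si], gene_name = g$gene_name[si],
               gene_start = g$start[si], gene_end = g$end[si],
               distance = dist, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Shared and trait-specific significant markers
#'
#' Set algebra over per-trait significant marker ids: every non-empty
#' intersection pattern is reported, the per-trait specific sets included.
#'
#' @param per_trait named list of [snp_association()]-style data.frames
#' @return list with `sets` (named list of marker id vectors, names like
#'   `"HR"`, `"HR+STAY"`) and `counts` (named integer vector)
#' @export
cross_trait_overlap <- function(per_trait) {
  stopifnot(is.list(per_trait), length(per_trait) >= 2L,
            !is.null(names(per_trait)))
  sig <- lapply(per_trait, function(r) unique(r$marker[r$significant %in% TRUE]))
  traits <- names(sig)
  all_ids <- unique(unlist(sig))
  member <- vapply(sig, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1L) member <- matrix(member, nrow = 1L,
                                              dimnames = list(NULL, traits))
  pattern <- apply(member, 1L, function(row) paste(traits[row], collapse = "+"))
  sets <- split(all_ids, pattern)
  counts <- vapply(sets, length, integer(1))
  list(sets = sets, counts = counts)
}
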
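# Readers and writers for the external formats: phased VCF 4.2, haplotype
# matrix TSV, pedigree/trait CSV, marker-map TSV, BED6/GFF3 gene spans.
# VCF is the canonical genotype interchange; the TSV haplotype matrix is
# accepted to keep small fixtures readable.

#' Strip chr/BTA prefixes from chromosome names
#'
#' @param x character vector of chromosome names
#' @return harmonised names (`"chr5"`, `"BTA5"` and `"5"` all map to `"5"`)
#' @export
harmonize_chrom <- function(x) {
  sub("^(chr|BTA)", "", as.character(x), ignore.case = TRUE)
}

#' Write a phased panel as VCF 4.2
#'
#' Biallelic sites, GT-only FORMAT, `|`-separated phased genotypes.
#'
#' @param panel a [phased_panel()]
#' @param path output path
#' @export
write_phased_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "phased_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=lethalscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", panel$ids), collapse = "\t"), con)
  n <- length(panel$ids)
  if (n && nrow(panel$map)) {
    odd <- seq(1L, 2L * n, by = 2L)
    gt <- matrix(paste0(t(panel$H[odd, , drop = FALSE]), "|",
                        t(panel$H[odd + 1L, , drop = FALSE])),
                 nrow = nrow(panel$map))
    fixed <- paste(panel$map$chrom, panel$map$pos, panel$map$id, "A", "C",
                   ".", ".", ".", "GT", sep = "\t")
    writeLines(paste(fixed, apply(gt, 1L, paste, collapse = "\t"),
                     sep = "\t"), con)
  } else if (nrow(panel$map)) {
    writeLines(paste(panel$map$chrom, panel$map$pos, panel$map$id, "A", "C",
                     ".", ".", ".", "GT", sep = "\t"), con)
  }
  invisible(path)
}

#' Read a phased VCF into a panel
#'
#' Requires fully phased biallelic GT fields; any missing or unphased
#' genotype is an error (this pipeline requires complete phased input).
#'
#' @param path VCF path (plain or bgzipped, as supported by vcfR)
#' @return a [phased_panel()]
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  map <- data.frame(chrom = as.character(v@fix[, "CHROM"]),
                    pos = as.integer(v@fix[, "POS"]),
                    id = as.character(v@fix[, "ID"]),
                    stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v)
  if (is.null(gt) || ncol(gt) == 0L) {
    return(phased_panel(matrix(0L, 0L, nrow(map)), map, character(0)))
  }
  if (anyNA(gt) || any(grepl("/", gt, fixed = TRUE)))
    stop("panel is not fully phased: missing or unphased genotypes in ", path)
  ids <- colnames(gt)
  M <- nrow(map); n <- length(ids)
  a1 <- substr(gt, 1L, 1L); a2 <- substr(gt, 3L, 3L)
  H <- matrix(0L, nrow = 2L * n, ncol = M)
  H[seq(1L, 2L * n, by = 2L), ] <- t(matrix(as.integer(a1), nrow = M))
  H[seq(2L, 2L * n, by = 2L), ] <- t(matrix(as.integer(a2), nrow = M))
  phased_panel(H, map, ids)
}

#' Read a haplotype-matrix TSV
#'
#' One row per haplotype copy (two consecutive rows per animal, column
#' `animal` repeated), marker columns named as in the map.
#'
#' @param path TSV path with an `animal` column followed by marker columns
#' @param map marker map matching the marker columns
#' @return a [phased_panel()]
#' @export
read_hap_matrix <- function(path, map) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- unique(df$animal)
  H <- as.matrix(df[, setdiff(names(df), "animal"), drop = FALSE])
  storage.mode(H) <- "integer"
  phased_panel(H, map, ids)
}

#' Extract alternate-allele dosages from a panel
#'
#' @param panel a [phased_panel()]
#' @return integer matrix animals x markers with entries 0/1/2, rownames =
#'   animal ids, colnames = marker ids
#' @export
panel_dosages <- function(panel) {
  n <- length(panel$ids)
  odd <- seq(1L, 2L * n, by = 2L)
  D <- panel$H[odd, , drop = FALSE] + panel$H[odd + 1L, , drop = FALSE]
  dimnames(D) <- list(panel$ids, panel$map$id)
  D
}

#' Read gene spans from BED6 or GFF3
#'
#' BED is 0-based half-open on disk and converted to 1-based inclusive;
#' GFF3 is used as-is with only `gene`-type features retained.
#'
#' @param path file ending in `.bed`, `.gff`, `.gff3` (or `.gtf`)
#' @return data.frame `chrom`, `start`, `end`, `gene_id`, `gene_name`
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path)
  if (grepl("\\.(gff3?|gtf)$", path, ignore.case = TRUE)) {
    keep <- if (!is.null(gr$type)) tolower(as.character(gr$type)) == "gene"
            else rep(TRUE, length(gr))
    gr <- gr[keep]
    gid <- if (!is.null(gr$ID)) as.character(gr$ID) else
      if (!is.null(gr$gene_id)) as.character(gr$gene_id) else
        sprintf("gene%d", seq_along(gr))
    gname <- if (!is.null(gr$Name)) as.character(gr$Name) else gid
  } else {
    gid <- if (!is.null(gr$name)) as.character(gr$name) else
      sprintf("gene%d", seq_along(gr))
    gname <- gid
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             gene_id = gid, gene_name = gname, stringsAsFactors = FALSE)
}

#' Marker quality control
#'
#' Drops non-autosomal markers, markers with a GenCall score lower than
#' 0.90 (when scores are supplied; a score of exactly 0.90 is retained),
#' duplicate-position markers (first by id order kept) and monomorphic
#' markers.
#'
#' @param panel a [phased_panel()]
#' @param gencall optional numeric per-marker score vector
#' @param autosomes chromosome names considered autosomal after
#'   [harmonize_chrom()] (default `"1"`..`"29"`, the cattle autosomes)
#' @param min_gencall score floor (default 0.90)
#' @return the filtered panel; attribute `qc_report` counts removals per
#'   rule
#' @export
qc_markers <- function(panel, gencall = NULL, autosomes = as.character(1:29),
                       min_gencall = 0.90) {
  stopifnot(inherits(panel, "phased_panel"))
  M <- nrow(panel$map)
  chrom <- harmonize_chrom(panel$map$chrom)
  drop_auto <- !(chrom %in% autosomes)
  drop_gc <- if (is.null(gencall)) rep(FALSE, M) else {
    stopifnot(length(gencall) == M)
    gencall < min_gencall
  }
  pos_key <- paste(chrom, panel$map$pos)
  drop_dup <- duplicated(pos_key)
  n <- length(panel$ids)
  mono <- if (n > 0L) {
    cs <- colSums(panel$H)
    cs == 0L | cs == 2L * n
  } else rep(FALSE, M)
  drop <- drop_auto | drop_gc | drop_dup | mono
  if (all(drop)) stop("marker QC removed every marker")
  out <- phased_panel(panel$H[, !drop, drop = FALSE],
                      panel$map[!drop, , drop = FALSE], panel$ids)
  attr(out, "qc_report") <- list(
    n_in = M, n_out = sum(!drop),
    non_autosomal = sum(drop_auto),
    low_gencall = sum(drop_gc & !drop_auto),
    duplicate_position = sum(drop_dup & !drop_auto & !drop_gc),
    monomorphic = sum(mono & !drop_auto & !drop_gc & !drop_dup))
  out
}

# 32-bit FNV-1a over a deparsed object, for config provenance lines
.config_hash <- function(x) {
  if (is.null(x)) return("none")
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^32
  sprintf("%08x", h)
}

#' Write a TSV with a provenance comment block
#'
#' Prepends `#` comment lines recording the package version, seed and a
#' hash of the configuration, then the table with a header line.
#'
#' @param df data.frame to write
#' @param path output path
#' @param seed seed to record
#' @param config optional configuration object to hash into the header
#' @export
write_tsv_report <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# lethalscan %s",
                       as.character(utils::packageVersion("lethalscan"))),
               sprintf("# seed: %s", seed),
               sprintf("# config_hash: %s", .config_hash(config))), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read a TSV written with a comment header
#'
#' @param path TSV path; `#`-prefixed lines are skipped
#' @return data.frame
#' @export
read_tsv_report <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
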
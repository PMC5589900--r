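#' Construct a beta-value matrix
#'
#' Probe-level methylation fractions (beta values, 0 = unmethylated,
#' 1 = fully methylated) for a cohort, optionally with per-probe detection
#' p-values.
#'
#' @param beta numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids); values in \[0,1\] or `NA`.
#' @param detection_p optional matrix of detection p-values with the same
#'   dimnames.
#' @return An object of class `"beta_matrix"`.
#' @export
beta_matrix <- function(beta, detection_p = NULL) {
  stopifnot(is.matrix(beta), is.numeric(beta))
  .stop_if(is.null(rownames(beta)) || is.null(colnames(beta)),
           "beta must have probe rownames and sample colnames")
  .stop_if(anyDuplicated(rownames(beta)) > 0, "duplicate probe_id in beta")
  .stop_if(anyDuplicated(colnames(beta)) > 0, "duplicate sample_id in beta")
  rng <- range(beta, na.rm = TRUE)
  .stop_if(is.finite(rng[1L]) && (rng[1L] < 0 || rng[2L] > 1),
           "beta values must lie in [0, 1]")
  if (!is.null(detection_p)) {
    stopifnot(is.matrix(detection_p),
              identical(dim(detection_p), dim(beta)))
    dimnames(detection_p) <- dimnames(beta)
  }
  structure(list(beta = beta, detection_p = detection_p),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix:", nrow(x$beta), "probes x", ncol(x$beta), "samples;",
      sum(is.na(x$beta)), "missing;",
      if (is.null(x$detection_p)) "no" else "with", "detection p-values\n")
  invisible(x)
}

#' Read a beta-value matrix from a delimited file
#'
#' First column `probe_id`, one further column per sample. Empty cells are
#' recorded as missing (never as zero); column order is preserved.
#' Gzip-compressed files are read transparently.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           colClasses = "character",
                           check.names = FALSE, na.strings = c("", "NA"))
  .stop_if(ncol(raw) < 2L, "expected a probe_id column plus sample columns")
  probes <- raw[[1L]]
  dup <- probes[duplicated(probes)]
  .stop_if(length(dup) > 0, "duplicate probe_id: ", dup[1L])
  m <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
              dimnames = list(probes, colnames(raw)[-1L]))
  for (j in seq_len(ncol(m))) {
    cell <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    .stop_if(length(bad) > 0, "malformed numeric cell at probe '",
             probes[bad[1L]], "', sample '", colnames(m)[j], "'")
    bad <- which(!is.na(num) & (num < 0 | num > 1))
    .stop_if(length(bad) > 0, "beta out of [0,1] at probe '",
             probes[bad[1L]], "', sample '", colnames(m)[j], "'")
    m[, j] <- num
  }
  beta_matrix(m)
}

#' Write a beta-value matrix
#'
#' @param bm a [beta_matrix()].
#' @param path output path (`.gz` suffix compresses).
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_beta_matrix <- function(bm, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  df <- data.frame(probe_id = rownames(bm$beta), bm$beta,
                   check.names = FALSE)
  .write_tsv(df, path, sep = if (dialect == "tsv") "\t" else ",")
  invisible(path)
}

.write_tsv <- function(df, path, sep = "\t") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
}

#' Read allele-specific copy-number segments
#'
#' SEG-like TSV with columns `sample`, `chrom`, `start`, `end`, `total_cn`,
#' `minor_cn`; file coordinates are 1-based inclusive and are converted to
#' 0-based half-open internally. The minor allele must be the smaller
#' parental count, and segments may not overlap within a sample/chromosome.
#'
#' @param path file path.
#' @return data.frame with columns `sample_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `total_cn`, `minor_cn`.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  need <- c("sample", "chrom", "start", "end", "total_cn", "minor_cn")
  .stop_if(!all(need %in% colnames(df)),
           "segment table must have columns: ", paste(need, collapse = ", "))
  seg <- data.frame(sample_id = as.character(df$sample),
                    chrom = as.character(df$chrom),
                    start = as.integer(df$start) - 1L,
                    end = as.integer(df$end),
                    total_cn = as.integer(df$total_cn),
                    minor_cn = as.integer(df$minor_cn),
                    stringsAsFactors = FALSE)
  validate_segments(seg)
}

#' Validate a segment table (internal coordinates)
#'
#' @param seg data.frame as returned by [read_segments()].
#' @return `seg`, invisibly validated.
#' @export
validate_segments <- function(seg) {
  .stop_if(any(seg$start >= seg$end), "segment with start >= end")
  .stop_if(any(seg$total_cn < 0 | seg$minor_cn < 0), "negative copy count")
  bad <- seg$minor_cn > seg$total_cn - seg$minor_cn
  .stop_if(any(bad),
           "minor_cn must be the smaller allele count (minor <= total - minor); ",
           "offending row: sample ", seg$sample_id[which(bad)[1L]])
  # overlap check within sample/chrom
  key <- split(seq_len(nrow(seg)), paste(seg$sample_id, seg$chrom))
  for (idx in key) {
    if (length(idx) < 2L) next
    o <- idx[order(seg$start[idx])]
    ov <- seg$start[o][-1L] < seg$end[o][-length(o)]
    .stop_if(any(ov), "overlapping segments for sample ",
             seg$sample_id[o[1L]], " on ", seg$chrom[o[1L]])
  }
  seg
}

#' Write a segment table (1-based inclusive on disk)
#' @param seg internal segment data.frame.
#' @param path output path.
#' @export
write_segments <- function(seg, path) {
  out <- data.frame(sample = seg$sample_id, chrom = seg$chrom,
                    start = seg$start + 1L, end = seg$end,
                    total_cn = seg$total_cn, minor_cn = seg$minor_cn)
  .write_tsv(out, path)
  invisible(path)
}

#' Read a region set from extended BED
#'
#' BED (0-based half-open) with columns chrom, start, end, region_id, klass
#' (`imprinted_dmr`, `cimp`, `bivalent`, `dmv`) and methylated_parent
#' (`maternal`, `paternal`, `none`). `methylated_parent` must be `none`
#' exactly for non-imprinted classes.
#'
#' @param path BED path (no header).
#' @return data.frame with columns `region_id`, `chrom`, `start`, `end`,
#'   `klass`, `methylated_parent`.
#' @export
read_regions <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = FALSE,
                          check.names = FALSE)
  .stop_if(ncol(df) < 4L, "region BED needs at least 4 columns")
  reg <- data.frame(region_id = as.character(df[[4L]]),
                    chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]),
                    klass = if (ncol(df) >= 5L) as.character(df[[5L]])
                            else "imprinted_dmr",
                    methylated_parent = if (ncol(df) >= 6L)
                            as.character(df[[6L]]) else "none",
                    stringsAsFactors = FALSE)
  validate_regions(reg)
}

#' Validate a region set
#' @param reg region data.frame.
#' @return `reg`.
#' @export
validate_regions <- function(reg) {
  .stop_if(anyDuplicated(reg$region_id) > 0, "duplicate region_id")
  .stop_if(any(reg$start >= reg$end), "region with start >= end")
  .stop_if(!all(reg$klass %in% c("imprinted_dmr", "cimp", "bivalent", "dmv")),
           "unknown region klass")
  .stop_if(!all(reg$methylated_parent %in% c("maternal", "paternal", "none")),
           "unknown methylated_parent")
  bad <- (reg$klass == "imprinted_dmr") == (reg$methylated_parent == "none")
  .stop_if(any(bad),
           "methylated_parent must be maternal/paternal for imprinted DMRs ",
           "and none otherwise; offending region: ",
           reg$region_id[which(bad)[1L]])
  reg
}

#' Write a region set as extended BED
#' @param reg region data.frame.
#' @param path output path.
#' @export
write_regions <- function(reg, path) {
  out <- data.frame(reg$chrom, reg$start, reg$end, reg$region_id,
                    reg$klass, reg$methylated_parent)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read chromosome anatomy (lengths and centromeres)
#'
#' TSV with columns `chrom`, `length_bp`, `centromere_start`,
#' `centromere_end` (0-based half-open centromere interval).
#' @param path file path.
#' @return data.frame keyed by `chrom`.
#' @export
read_anatomy <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE)
  need <- c("chrom", "length_bp", "centromere_start", "centromere_end")
  .stop_if(!all(need %in% colnames(df)),
           "anatomy table must have columns: ", paste(need, collapse = ", "))
  .stop_if(!all(df$centromere_start > 0 &
                df$centromere_end > df$centromere_start &
                df$length_bp > df$centromere_end),
           "anatomy must satisfy 0 < centromere_start < centromere_end < length_bp")
  df
}

#' Read an RRBS site table
#'
#' TSV with columns `chrom`, `pos` (0-based), `meth_count` (C reads) and
#' `total_count` (C + T reads).
#' @param path file path.
#' @return data.frame of sites; a `sample` column is carried through when
#'   present.
#' @export
read_rrbs_sites <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE)
  need <- c("chrom", "pos", "meth_count", "total_count")
  .stop_if(!all(need %in% colnames(df)),
           "RRBS table must have columns: ", paste(need, collapse = ", "))
  .stop_if(any(df$total_count < 1), "total_count must be positive")
  .stop_if(any(df$meth_count > df$total_count),
           "meth_count exceeds total_count")
  df
}

#' Apply probe-level quality control
#'
#' Removes, in order: probes whose detection p-value exceeds
#' `detection_p` in strictly more than `detection_frac` of samples; probes
#' with a missing beta in any sample; probes with a common SNP
#' (MAF >= `snp_maf`) within `snp_dist_bp` of the interrogated CpG; and
#' probes on chrX/chrY. Each probe is attributed to the first rule that
#' removes it, so rule counts plus retained probes always sum to the input
#' probe count.
#'
#' @param bm a [beta_matrix()].
#' @param manifest data.frame with columns `probe_id`, `chrom`, `pos` and
#'   optionally `nearest_snp_distance_bp`, `nearest_snp_maf` (NA when no
#'   SNP is near).
#' @param thresholds an [imprint_thresholds()].
#' @return The filtered `beta_matrix`, with attribute `"removal"`: a named
#'   integer vector `(detection, missing, snp, sex_chrom, retained)`.
#' @export
filter_probes <- function(bm, manifest, thresholds = imprint_thresholds()) {
  stopifnot(inherits(bm, "beta_matrix"))
  .stop_if(anyDuplicated(manifest$probe_id) > 0,
           "duplicate probe_id in manifest")
  probes <- rownames(bm$beta)
  miss <- setdiff(probes, manifest$probe_id)
  .stop_if(length(miss) > 0, "probes absent from manifest: ", miss[1L])
  man <- manifest[match(probes, manifest$probe_id), , drop = FALSE]
  th <- thresholds
  n_samp <- ncol(bm$beta)
  removed_by <- rep(NA_character_, length(probes))

  if (!is.null(bm$detection_p)) {
    n_fail <- rowSums(bm$detection_p > th$detection_p, na.rm = TRUE)
    removed_by[n_fail > th$detection_frac * n_samp] <- "detection"
  }
  alive <- is.na(removed_by)
  has_na <- rowSums(is.na(bm$beta)) > 0
  removed_by[alive & has_na] <- "missing"
  alive <- is.na(removed_by)
  if (all(c("nearest_snp_distance_bp", "nearest_snp_maf") %in% colnames(man))) {
    snp <- !is.na(man$nearest_snp_distance_bp) &
      man$nearest_snp_distance_bp <= th$snp_dist_bp &
      !is.na(man$nearest_snp_maf) & man$nearest_snp_maf >= th$snp_maf
    removed_by[alive & snp] <- "snp"
    alive <- is.na(removed_by)
  }
  sexchr <- man$chrom %in% c("chrX", "chrY", "X", "Y")
  removed_by[alive & sexchr] <- "sex_chrom"

  keep <- is.na(removed_by)
  counts <- c(detection = sum(removed_by == "detection", na.rm = TRUE),
              missing = sum(removed_by == "missing", na.rm = TRUE),
              snp = sum(removed_by == "snp", na.rm = TRUE),
              sex_chrom = sum(removed_by == "sex_chrom", na.rm = TRUE),
              retained = sum(keep))
  out <- beta_matrix(bm$beta[keep, , drop = FALSE],
                     if (is.null(bm$detection_p)) NULL
                     else bm$detection_p[keep, , drop = FALSE])
  attr(out, "removal") <- counts
  out
}

#' Aggregate RRBS sites over regions
#'
#' Site methylation is `meth_count / total_count`; sites covered by fewer
#' than `min_coverage` reads are excluded and the region value is the
#' unweighted mean of the surviving site fractions. A site belongs to a
#' region when `start <= pos < end`. Regions with no surviving site are
#' returned as `NA`.
#'
#' @param sites RRBS site data.frame (see [read_rrbs_sites()]).
#' @param regions region data.frame.
#' @param min_coverage minimum total read count per site (kept when
#'   `total_count >= min_coverage`).
#' @return Named numeric vector of per-region methylation fractions.
#' @export
aggregate_rrbs_regions <- function(sites, regions, min_coverage = 10L) {
  out <- setNames(rep(NA_real_, nrow(regions)), regions$region_id)
  keep <- sites$total_count >= min_coverage
  if (any(keep)) {
    s <- sites[keep, , drop = FALSE]
    hits <- GenomicRanges::findOverlaps(
      .granges_pos(s$chrom, s$pos),
      .granges0(regions$chrom, regions$start, regions$end))
    if (length(hits) > 0) {
      frac <- s$meth_count[S4Vectors::queryHits(hits)] /
        s$total_count[S4Vectors::queryHits(hits)]
      agg <- tapply(frac, S4Vectors::subjectHits(hits), mean)
      out[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  out
}
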
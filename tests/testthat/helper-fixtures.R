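# small in-code fixtures shared across tests

make_bm <- function(beta, detection_p = NULL) {
  if (is.null(rownames(beta)))
    rownames(beta) <- sprintf("cg%03d", seq_len(nrow(beta)))
  if (is.null(colnames(beta)))
    colnames(beta) <- sprintf("S%02d", seq_len(ncol(beta)))
  beta_matrix(beta, detection_p)
}

make_manifest <- function(probe_ids, chrom = "chr1", pos = NULL,
                          snp_dist = NA_integer_, snp_maf = NA_real_) {
  n <- length(probe_ids)
  data.frame(probe_id = probe_ids,
             chrom = rep_len(chrom, n),
             pos = if (is.null(pos)) seq(100L, by = 50L, length.out = n)
                   else rep_len(pos, n),
             nearest_snp_distance_bp = rep_len(snp_dist, n),
             nearest_snp_maf = rep_len(snp_maf, n),
             stringsAsFactors = FALSE)
}

make_regions <- function(n = 2L, chrom = "chr1", start = 0L,
                         width = 1000L, gap = 1000L,
                         klass = "imprinted_dmr",
                         methylated_parent = "maternal") {
  s <- start + (seq_len(n) - 1L) * (width + gap)
  validate_regions(data.frame(
    region_id = sprintf("R%02d", seq_len(n)), chrom = rep_len(chrom, n),
    start = s, end = s + width, klass = rep_len(klass, n),
    methylated_parent = rep_len(methylated_parent, n),
    stringsAsFactors = FALSE))
}

make_anatomy <- function(chrom = "chr1", length_bp = 100e6,
                         cen = c(45e6, 50e6)) {
  data.frame(chrom = chrom, length_bp = length_bp,
             centromere_start = cen[1L], centromere_end = cen[2L],
             stringsAsFactors = FALSE)
}

make_segments <- function(sample_id, chrom, start, end, total_cn,
                          minor_cn) {
  validate_segments(data.frame(
    sample_id = sample_id, chrom = chrom, start = start, end = end,
    total_cn = as.integer(total_cn), minor_cn = as.integer(minor_cn),
    stringsAsFactors = FALSE))
}
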
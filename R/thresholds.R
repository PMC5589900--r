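#' Analysis thresholds
#'
#' Bundles every tunable cutoff of the pipeline, with defaults matching the
#' canonical analysis: hyper/hypomethylation at beta > 0.8 / < 0.2,
#' intermediate defects at +/- 0.2 beta relative to controls, the epimutation
#' band at 3 control standard deviations, context severity at > 0.75 (highly),
#' > 0.5 (mildly) and control mean + 0.2 (lowly), context-region selection at
#' control mean < 0.2, the internal-CNA rule at > 1 Mb from the nearer
#' telomere/centromere, RRBS site coverage >= 10 reads, probe detection
#' p > 0.01 in > 10% of samples, and SNP exclusion at MAF >= 0.01 within 5 bp.
#'
#' @param hyper,hypo absolute beta cutoffs for hyper/hypomethylated calls.
#' @param intermediate_delta beta offset from the control mean for
#'   intermediate gain/loss calls.
#' @param sd_mult width of the epimutation band in control s.d. units.
#' @param severity_high,severity_mid absolute beta cutoffs for highly/mildly
#'   methylated context regions.
#' @param severity_low_delta offset above the control mean for lowly
#'   methylated context regions.
#' @param ctrl_unmeth control-mean cutoff below which a context region counts
#'   as uniformly unmethylated in normals (region selection).
#' @param internal_dist_bp minimum distance (bp) from telomere/centromere for
#'   a CNA to be called internal (strictly greater than).
#' @param min_coverage minimum RRBS read count for a site to be used.
#' @param detection_p,detection_frac probe detection p-value cutoff and the
#'   fraction of samples that may exceed it (strictly more than
#'   `detection_frac` failing samples removes the probe).
#' @param snp_dist_bp,snp_maf flanking distance (bp) and minor-allele
#'   frequency defining SNP-confounded probes.
#' @return A named list of class `"imprint_thresholds"`.
#' @export
imprint_thresholds <- function(hyper = 0.8, hypo = 0.2,
                               intermediate_delta = 0.2, sd_mult = 3,
                               severity_high = 0.75, severity_mid = 0.5,
                               severity_low_delta = 0.2, ctrl_unmeth = 0.2,
                               internal_dist_bp = 1e6, min_coverage = 10L,
                               detection_p = 0.01, detection_frac = 0.10,
                               snp_dist_bp = 5L, snp_maf = 0.01) {
  th <- list(hyper = hyper, hypo = hypo,
             intermediate_delta = intermediate_delta, sd_mult = sd_mult,
             severity_high = severity_high, severity_mid = severity_mid,
             severity_low_delta = severity_low_delta,
             ctrl_unmeth = ctrl_unmeth,
             internal_dist_bp = internal_dist_bp,
             min_coverage = as.integer(min_coverage),
             detection_p = detection_p, detection_frac = detection_frac,
             snp_dist_bp = as.integer(snp_dist_bp), snp_maf = snp_maf)
  stopifnot(all(vapply(th, is.numeric, logical(1L))),
            all(unlist(th) >= 0))
  class(th) <- "imprint_thresholds"
  th
}
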
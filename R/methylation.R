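#' Map probes to regions by position
#'
#' A probe belongs to a region when `start <= pos < end`.
#'
#' @param manifest data.frame with `probe_id`, `chrom`, `pos`.
#' @param regions region data.frame.
#' @return Named character vector: region_id per probe (`NA` when outside
#'   every region).
#' @export
map_probes_to_regions <- function(manifest, regions) {
  hits <- GenomicRanges::findOverlaps(
    .granges_pos(manifest$chrom, manifest$pos),
    .granges0(regions$chrom, regions$start, regions$end))
  out <- setNames(rep(NA_character_, nrow(manifest)), manifest$probe_id)
  out[S4Vectors::queryHits(hits)] <-
    regions$region_id[S4Vectors::subjectHits(hits)]
  out
}

#' Average methylation per region and sample
#'
#' Unweighted mean of non-missing probe betas per sample for each region.
#' Regions with fewer than `min_probes` mapped probes (default 2) are
#' excluded with a warning: a single-probe region cannot be averaged
#' robustly.
#'
#' @param bm a [beta_matrix()].
#' @param regions region data.frame.
#' @param probe_region named region assignment per probe, as from
#'   [map_probes_to_regions()]; defaults to mapping `manifest`.
#' @param manifest probe manifest (used when `probe_region` is missing).
#' @param min_probes minimum mapped probes per region.
#' @return Numeric matrix, regions x samples.
#' @export
dmr_average <- function(bm, regions, probe_region = NULL, manifest = NULL,
                        min_probes = 2L) {
  if (is.null(probe_region)) {
    .stop_if(is.null(manifest), "need probe_region or manifest")
    probe_region <- map_probes_to_regions(manifest, regions)
  }
  pr <- probe_region[rownames(bm$beta)]
  counts <- table(factor(pr, levels = regions$region_id))
  drop <- names(counts)[counts < min_probes]
  if (length(drop) > 0)
    warning(length(drop), " region(s) with fewer than ", min_probes,
            " probes excluded: ", paste(utils::head(drop, 5L), collapse = ", "),
            call. = FALSE)
  keep <- setdiff(regions$region_id, drop)
  out <- matrix(NA_real_, length(keep), ncol(bm$beta),
                dimnames = list(keep, colnames(bm$beta)))
  for (r in keep) {
    rows <- which(!is.na(pr) & pr == r)
    sub <- bm$beta[rows, , drop = FALSE]
    v <- colMeans(sub, na.rm = TRUE)
    v[colSums(!is.na(sub)) == 0L] <- NA_real_
    out[r, ] <- v
  }
  out
}

#' Per-region mean and s.d. of control methylation
#'
#' Sample standard deviation (n - 1 denominator) of the per-sample region
#' averages across normal-tissue controls; these define the +/- 3 s.d.
#' epimutation band.
#'
#' @param region_avg regions x samples matrix from [dmr_average()].
#' @param controls character vector of control sample ids (>= 2).
#' @param tissue label used in error messages.
#' @return data.frame `(region_id, n_controls, mean, sd)`.
#' @export
compute_control_stats <- function(region_avg, controls, tissue = "cohort") {
  controls <- intersect(controls, colnames(region_avg))
  .stop_if(length(controls) < 2L,
           "need at least 2 control samples for tissue '", tissue, "'")
  sub <- region_avg[, controls, drop = FALSE]
  data.frame(region_id = rownames(region_avg),
             n_controls = rowSums(!is.na(sub)),
             mean = rowMeans(sub, na.rm = TRUE),
             sd = apply(sub, 1L, stats::sd, na.rm = TRUE),
             stringsAsFactors = FALSE)
}

#' CNA-predicted methylation
#'
#' The minor methylation value is the ratio of the minor to the total
#' allele count, m = minor/total. If the observed beta is below 0.5 the
#' methylated allele is assumed to be the minor one and m is the predicted
#' methylation; if above 0.5 the methylated allele is assumed to be the
#' major one and 1 - m is returned. An observed value of exactly 0.5 is
#' broken toward 1 - m (a tie only matters when m < 0.5; tie counts are
#' returned in attribute `"ties"`). A locus with total copy number 0
#' (homozygous deletion) has no prediction and returns `NA`.
#'
#' For a normal 2:1 complement this gives 0.5 (one methylated, one
#' unmethylated allele); a 4:1 locus gives 0.75 or 0.25 depending on the
#' parental origin of the minor allele; any cnnLOH locus (minor = 0) gives
#' 0 or 1.
#'
#' @param total_cn,minor_cn integer vectors of allele counts
#'   (minor <= total - minor).
#' @param observed observed beta values in \[0,1\] (chooses the parental
#'   branch).
#' @return Numeric vector of predicted fractions in \[0,1\] (`NA` where
#'   total is 0 or observed is missing).
#' @export
predicted_methylation <- function(total_cn, minor_cn, observed) {
  n <- max(length(total_cn), length(minor_cn), length(observed))
  total_cn <- rep_len(total_cn, n)
  minor_cn <- rep_len(minor_cn, n)
  observed <- rep_len(observed, n)
  .stop_if(any(minor_cn > total_cn - minor_cn, na.rm = TRUE),
           "minor_cn must satisfy minor <= total - minor")
  m <- ifelse(total_cn > 0L, minor_cn / total_cn, NA_real_)
  pred <- ifelse(observed < 0.5, m, 1 - m)
  pred[is.na(observed)] <- NA_real_
  attr(pred, "ties") <- sum(observed == 0.5 & m < 0.5, na.rm = TRUE)
  pred
}

#' Is a methylation profile independent of copy number?
#'
#' TRUE when the observed region average deviates from the CNA-predicted
#' value by strictly more than `sd_mult` (default 3) control standard
#' deviations: such loci are deemed genuine epimutations rather than
#' copy-number effects. A deviation of exactly 3 s.d. is not called. With a
#' control s.d. of zero any nonzero deviation is independent (an absolute
#' fuzz of 1e-12 guards against floating-point noise).
#'
#' @param observed,predicted numeric vectors of fractions.
#' @param ctrl_sd per-region control standard deviation (recycled).
#' @param sd_mult band width in s.d. units.
#' @return Logical vector (`NA` where observed or predicted is missing).
#' @export
call_cna_independent <- function(observed, predicted, ctrl_sd,
                                 sd_mult = 3) {
  abs(observed - predicted) > sd_mult * ctrl_sd + .EPS
}

#' Classify the methylation state of a region average
#'
#' Hypermethylated when the observed beta exceeds `hyper` (0.8);
#' hypomethylated below `hypo` (0.2); otherwise an intermediate gain/loss
#' when at least `intermediate_delta` (0.2) above/below the control mean;
#' otherwise normal. Every (observed, control) pair maps to exactly one
#' state. Comparison to the diploid control mean is deliberate; CNA
#' awareness lives in [call_cna_independent()].
#'
#' @param observed numeric vector of region averages.
#' @param ctrl_mean control means (recycled).
#' @param thresholds an [imprint_thresholds()].
#' @return Character vector of states.
#' @export
classify_state <- function(observed, ctrl_mean,
                           thresholds = imprint_thresholds()) {
  th <- thresholds
  out <- ifelse(observed > th$hyper, "hypermethylated",
         ifelse(observed < th$hypo, "hypomethylated",
         ifelse(observed >= ctrl_mean + th$intermediate_delta,
                "intermediate_gain",
         ifelse(observed <= ctrl_mean - th$intermediate_delta,
                "intermediate_loss", "normal"))))
  out[is.na(observed)] <- NA_character_
  out
}

#' Infer the parental allele retained through copy-neutral LOH
#'
#' At a cnnLOH locus only one parental allele remains, so the methylation
#' profile reveals it: an imprinted DMR methylated in, say, the maternal
#' germline that reads near-fully methylated (> 0.8) retained the maternal
#' allele; near-zero (< 0.2) means the paternal allele was retained.
#' Anything in between is ambiguous. The 0.8/0.2 bands are reused for
#' internal consistency with the state classifier.
#'
#' @param observed numeric vector of region averages at cnnLOH loci.
#' @param methylated_parent `"maternal"` or `"paternal"` (the
#'   germline-methylated parent of the DMR; recycled).
#' @param thresholds an [imprint_thresholds()].
#' @return Character vector: `"maternal"`, `"paternal"` or `"ambiguous"`.
#' @export
infer_cnnloh_parent <- function(observed, methylated_parent,
                                thresholds = imprint_thresholds()) {
  n <- max(length(observed), length(methylated_parent))
  observed <- rep_len(observed, n)
  methylated_parent <- rep_len(methylated_parent, n)
  .stop_if(any(!methylated_parent %in% c("maternal", "paternal")),
           "methylated_parent must be maternal or paternal")
  other <- ifelse(methylated_parent == "maternal", "paternal", "maternal")
  out <- ifelse(observed > thresholds$hyper, methylated_parent,
         ifelse(observed < thresholds$hypo, other, "ambiguous"))
  out[is.na(observed)] <- NA_character_
  out
}

#' Proportion of methylation variance explained by copy number
#'
#' Ordinary least squares of the observed region averages on the
#' CNA-predicted values across samples; returns the coefficient of
#' determination (R^2). A constant predictor is degenerate: R^2 is reported
#' as 0 with attribute `"degenerate" = TRUE`.
#'
#' @param observed,predicted paired numeric vectors (>= 3 complete pairs).
#' @return R^2 in \[0,1\].
#' @export
variance_explained <- function(observed, predicted) {
  ok <- stats::complete.cases(observed, predicted)
  .stop_if(sum(ok) < 3L, "need at least 3 paired non-missing values")
  x <- predicted[ok]; y <- observed[ok]
  if (stats::sd(x) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  fit <- stats::lm(y ~ x)
  # R^2 computed directly; summary.lm warns on numerically perfect fits
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  structure(min(1, max(0, r2)), degenerate = FALSE)
}
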
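#' Is a copy state copy-neutral LOH?
#'
#' Copy-neutral loss of heterozygosity: one parental allele lost entirely
#' while the other is present in two or more copies, i.e. total copy number
#' >= 2 with a minor allele count of zero (the state can reach 14:0).
#'
#' @param total_cn,minor_cn integer vectors of allele counts.
#' @return logical vector.
#' @export
is_cnnloh <- function(total_cn, minor_cn) {
  minor_cn == 0L & total_cn >= 2L
}

#' Estimate a sample's baseline ploidy
#'
#' Length-weighted median of the total copy number across all segments,
#' rounded half-up, minimum 1. The median resists focal amplification
#' outliers, so a genome that is mostly 4:2 yields baseline 4 even with a
#' few 14-copy segments.
#'
#' @param seg segment data.frame for one sample (columns `start`, `end`,
#'   `total_cn`).
#' @return positive integer.
#' @export
estimate_baseline_ploidy <- function(seg) {
  .stop_if(nrow(seg) == 0L, "no segments: cannot estimate ploidy")
  w <- as.numeric(seg$end - seg$start)
  o <- order(seg$total_cn)
  cw <- cumsum(w[o])
  med <- seg$total_cn[o][which(cw >= sum(w) / 2)[1L]]
  max(1L, as.integer(floor(med + 0.5)))
}

#' Classify a segment as internal or telomere/centromere-bound
#'
#' A CNA is internal when it lies strictly more than `internal_dist_bp`
#' (default 1 Mb) from the nearer of the telomere and the centromere;
#' otherwise it takes the bound class of the nearer anchor (a tie goes to
#' the telomere). A segment overlapping the centromere has centromere
#' distance 0. Depends only on coordinates, never on strand.
#'
#' @param start,end segment coordinates, 0-based half-open.
#' @param anatomy one anatomy row (or data.frame keyed by `chrom`) with
#'   `length_bp`, `centromere_start`, `centromere_end`.
#' @param chrom chromosome of the segment (used to index `anatomy` when it
#'   has several rows).
#' @param internal_dist_bp distance threshold in bp (strictly greater than).
#' @return one of `"internal"`, `"telomere_bound"`, `"centromere_bound"`.
#' @export
classify_boundedness <- function(start, end, anatomy, chrom = NULL,
                                 internal_dist_bp = 1e6) {
  if (!is.null(chrom))
    anatomy <- anatomy[match(chrom, anatomy$chrom), , drop = FALSE]
  .stop_if(nrow(anatomy) != 1L || anyNA(anatomy$length_bp),
           "chromosome absent from anatomy")
  d_tel <- min(start, anatomy$length_bp - end)
  d_cen <- if (end <= anatomy$centromere_start)
    anatomy$centromere_start - end
  else if (start >= anatomy$centromere_end)
    start - anatomy$centromere_end
  else 0
  if (min(d_tel, d_cen) > internal_dist_bp) return("internal")
  if (d_tel <= d_cen) "telomere_bound" else "centromere_bound"
}

#' Assign an allele-specific copy state to every (sample, region) pair
#'
#' A segment is eligible when it overlaps the region by at least 1 bp. When
#' several segments overlap a region, the one with the largest overlap
#' length supplies the copy state, ties broken toward the larger total copy
#' number. Regions without any covering segment default to the diploid 2:1
#' state and are flagged `assumed`. Each state carries the ploidy-baseline
#' ratio (total copies / baseline ploidy), the cnnLOH flag, an aberration
#' call relative to the diploid 2:1 state, and the boundedness class of the
#' supplying segment (aberrant states only).
#'
#' @param seg segment data.frame (all samples; see [read_segments()]).
#' @param regions region data.frame.
#' @param anatomy chromosome anatomy data.frame; every region chromosome
#'   must be present.
#' @param samples sample ids to emit states for (default: those in `seg`).
#' @param thresholds an [imprint_thresholds()] (internal-distance rule).
#' @return data.frame with one row per (sample, region): `sample_id`,
#'   `region_id`, `total_cn`, `minor_cn`, `ploidy`, `ploidy_ratio`,
#'   `cnnloh`, `aberration`, `boundedness`, `assumed`, `seg_length`.
#' @export
overlap_locus_state <- function(seg, regions, anatomy,
                                samples = unique(seg$sample_id),
                                thresholds = imprint_thresholds()) {
  miss <- setdiff(unique(regions$chrom), anatomy$chrom)
  .stop_if(length(miss) > 0, "region chromosome absent from anatomy: ",
           miss[1L])
  empty <- data.frame(sample_id = character(), region_id = character(),
                      total_cn = integer(), minor_cn = integer(),
                      ploidy = integer(), ploidy_ratio = numeric(),
                      cnnloh = logical(), aberration = character(),
                      boundedness = character(), assumed = logical(),
                      seg_length = numeric(), stringsAsFactors = FALSE)
  if (length(samples) == 0L) return(empty)
  reg_gr <- .granges0(regions$chrom, regions$start, regions$end)
  out <- vector("list", length(samples))
  for (k in seq_along(samples)) {
    s <- samples[k]
    sseg <- seg[seg$sample_id == s, , drop = FALSE]
    ploidy <- if (nrow(sseg) > 0) estimate_baseline_ploidy(sseg) else 2L
    total <- rep(2L, nrow(regions))
    minor <- rep(1L, nrow(regions))
    assumed <- rep(TRUE, nrow(regions))
    seg_len <- rep(NA_real_, nrow(regions))
    seg_row <- rep(NA_integer_, nrow(regions))
    if (nrow(sseg) > 0) {
      hits <- GenomicRanges::findOverlaps(
        .granges0(sseg$chrom, sseg$start, sseg$end), reg_gr,
        minoverlap = 1L)
      if (length(hits) > 0) {
        qh <- S4Vectors::queryHits(hits)
        sh <- S4Vectors::subjectHits(hits)
        ov <- pmin(sseg$end[qh], regions$end[sh]) -
          pmax(sseg$start[qh], regions$start[sh])
        # largest overlap wins; ties toward larger total_cn
        o <- order(sh, -ov, -sseg$total_cn[qh])
        first <- !duplicated(sh[o])
        win_reg <- sh[o][first]
        win_seg <- qh[o][first]
        total[win_reg] <- sseg$total_cn[win_seg]
        minor[win_reg] <- sseg$minor_cn[win_seg]
        assumed[win_reg] <- FALSE
        seg_len[win_reg] <- sseg$end[win_seg] - sseg$start[win_seg]
        seg_row[win_reg] <- win_seg
      }
    }
    aberr <- ifelse(is_cnnloh(total, minor), "cnnloh",
             ifelse(total > 2L, "amplification",
             ifelse(total < 2L, "deletion", "normal")))
    bound <- rep("not_applicable", nrow(regions))
    idx <- which(aberr != "normal" & !assumed)
    for (i in idx) {
      bound[i] <- classify_boundedness(
        sseg$start[seg_row[i]], sseg$end[seg_row[i]], anatomy,
        chrom = sseg$chrom[seg_row[i]],
        internal_dist_bp = thresholds$internal_dist_bp)
    }
    out[[k]] <- data.frame(sample_id = s, region_id = regions$region_id,
                           total_cn = total, minor_cn = minor,
                           ploidy = ploidy, ploidy_ratio = total / ploidy,
                           cnnloh = is_cnnloh(total, minor),
                           aberration = aberr, boundedness = bound,
                           assumed = assumed, seg_length = seg_len,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Summarize CNA size and copy number by region and boundedness
#'
#' Per (region, boundedness) class over aberrant, non-assumed states: count,
#' mean supplying-segment length and mean total copy number. Also reports,
#' over regions having both internal and bound aberrations, the fraction
#' where the internal mean length is smaller than the bound mean length
#' (attribute `"fraction_internal_smaller"`). Averages are over segments.
#'
#' @param states output of [overlap_locus_state()].
#' @return data.frame `(region_id, boundedness, n, mean_length_bp,
#'   mean_total_cn)`.
#' @export
cna_size_summary <- function(states) {
  ab <- states[states$aberration != "normal" & !states$assumed, ,
               drop = FALSE]
  .stop_if(nrow(ab) == 0L, "no aberrant states to summarize")
  key <- paste(ab$region_id, ab$boundedness, sep = "\r")
  tab <- do.call(rbind, lapply(split(seq_len(nrow(ab)), key), function(i) {
    data.frame(region_id = ab$region_id[i[1L]],
               boundedness = ab$boundedness[i[1L]],
               n = length(i),
               mean_length_bp = mean(ab$seg_length[i]),
               mean_total_cn = mean(ab$total_cn[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  frac <- NA_real_
  both <- intersect(
    tab$region_id[tab$boundedness == "internal"],
    tab$region_id[tab$boundedness %in% c("telomere_bound", "centromere_bound")])
  if (length(both) > 0) {
    smaller <- vapply(both, function(r) {
      int <- tab$mean_length_bp[tab$region_id == r &
                                tab$boundedness == "internal"]
      bnd <- tab$mean_length_bp[tab$region_id == r &
                                tab$boundedness != "internal"]
      mean(int) < mean(bnd)
    }, logical(1L))
    frac <- mean(smaller)
  }
  attr(tab, "fraction_internal_smaller") <- frac
  tab
}
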
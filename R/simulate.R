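#' Default synthetic chromosome anatomy
#'
#' Eight synthetic chromosomes: chr1-chr4 (150 Mb, centromere 60-65 Mb)
#' carry the imprinted DMRs, chr5-chr8 (160 Mb, centromere 120-125 Mb)
#' carry the context regions.
#'
#' @return Anatomy data.frame (see [read_anatomy()]).
#' @export
default_anatomy <- function() {
  data.frame(
    chrom = paste0("chr", 1:8),
    length_bp = c(rep(150e6, 4L), rep(160e6, 4L)),
    centromere_start = c(rep(60e6, 4L), rep(120e6, 4L)),
    centromere_end = c(rep(65e6, 4L), rep(125e6, 4L)),
    stringsAsFactors = FALSE)
}

#' Default synthetic region set
#'
#' 37 imprinted DMRs (2 kb wide, 10 Mb apart on chr1-chr4; roughly
#' two-thirds maternally methylated, as in the human imprintome) plus
#' 30 CIMP, 442 bivalent-domain and 166 DMV context regions (2 kb wide,
#' 50 kb apart on chr5-chr8).
#'
#' @param n_dmr,n_cimp,n_bivalent,n_dmv region counts per class.
#' @return Region data.frame.
#' @export
default_regions <- function(n_dmr = 37L, n_cimp = 30L, n_bivalent = 442L,
                            n_dmv = 166L) {
  dmr_chrom <- paste0("chr", ((seq_len(n_dmr) - 1L) %% 4L) + 1L)
  dmr_start <- 10e6 + ((seq_len(n_dmr) - 1L) %/% 4L) * 10e6
  dmr <- data.frame(
    region_id = sprintf("DMR%02d", seq_len(n_dmr)),
    chrom = dmr_chrom, start = as.integer(dmr_start),
    end = as.integer(dmr_start + 2000L), klass = "imprinted_dmr",
    methylated_parent = ifelse(seq_len(n_dmr) %% 3L == 0L,
                               "paternal", "maternal"),
    stringsAsFactors = FALSE)
  ctx <- function(n, klass, prefix) {
    if (n == 0L) return(NULL)
    chrom <- paste0("chr", ((seq_len(n) - 1L) %% 4L) + 5L)
    start <- switch(prefix, CIMP = 5e6, BIV = 20e6, DMV = 60e6) +
      ((seq_len(n) - 1L) %/% 4L) * 50e3
    data.frame(region_id = sprintf("%s%03d", prefix, seq_len(n)),
               chrom = chrom, start = as.integer(start),
               end = as.integer(start + 2000L), klass = rep(klass, n),
               methylated_parent = rep("none", n),
               stringsAsFactors = FALSE)
  }
  validate_regions(rbind(dmr, ctx(n_cimp, "cimp", "CIMP"),
                         ctx(n_bivalent, "bivalent", "BIV"),
                         ctx(n_dmv, "dmv", "DMV")))
}

#' Simulation configuration
#'
#' Parameters of the allele-resolved tumor-methylome generator. Defaults
#' emulate a primary-tumor-like cohort: most imprinted loci copy-normal
#' (`cna_rate` 0.1 per tumor and DMR), cnnLOH making up 10% of aberrations,
#' single-copy deletions 15% of the remainder, amplification totals
#' concentrated at 3-4 with a tail up to 14 copies; epimutations injected
#' at 10% of (tumor, DMR) pairs; per-probe measurement noise s.d. 0.02 on
#' the beta scale; inter-individual biological variation of normal controls
#' 0.01 at the region scale; full tumor purity (cell-line-like).
#'
#' @param n_tumors,n_normals cohort sizes.
#' @param regions region data.frame ([default_regions()]).
#' @param anatomy chromosome anatomy ([default_anatomy()]).
#' @param probes_per_region probes simulated per region (>= 2).
#' @param cna_rate probability a (tumor, DMR) pair is copy-aberrant.
#' @param cnnloh_rate share of aberrations that are copy-neutral LOH.
#' @param del_rate share of non-cnnLOH aberrations that are single-copy
#'   deletions (1:0).
#' @param max_total_cn largest total copy number (>= 2).
#' @param epimutation_rate probability of an injected epimutation per
#'   (tumor, DMR) pair.
#' @param epimutation_kinds named weights over `hyper`, `hypo`,
#'   `intermediate`.
#' @param noise_sd per-probe beta measurement noise s.d.
#' @param biovar_sd inter-individual biological s.d. of normal controls at
#'   the region scale.
#' @param context_baseline unmethylated context-region beta in normals.
#' @param purity_mean,purity_sd tumor purity distribution (clipped to
#'   \[0,1\]).
#' @param rrbs_mean_coverage mean Poisson read coverage for simulated RRBS.
#' @param seed integer master seed; every (sample, region) pair derives its
#'   own stream from it, so adding samples never perturbs existing ones.
#' @return Validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_tumors = 50L, n_normals = 10L,
                       regions = default_regions(),
                       anatomy = default_anatomy(),
                       probes_per_region = 5L,
                       cna_rate = 0.1, cnnloh_rate = 0.1, del_rate = 0.15,
                       max_total_cn = 14L, epimutation_rate = 0.1,
                       epimutation_kinds = c(hyper = 0.4, hypo = 0.3,
                                             intermediate = 0.3),
                       noise_sd = 0.02, biovar_sd = 0.01,
                       context_baseline = 0.05,
                       purity_mean = 1, purity_sd = 0,
                       rrbs_mean_coverage = 30, seed = 1L) {
  cfg <- list(n_tumors = as.integer(n_tumors),
              n_normals = as.integer(n_normals),
              regions = validate_regions(regions), anatomy = anatomy,
              probes_per_region = as.integer(probes_per_region),
              cna_rate = cna_rate, cnnloh_rate = cnnloh_rate,
              del_rate = del_rate, max_total_cn = as.integer(max_total_cn),
              epimutation_rate = epimutation_rate,
              epimutation_kinds = epimutation_kinds,
              noise_sd = noise_sd, biovar_sd = biovar_sd,
              context_baseline = context_baseline,
              purity_mean = purity_mean, purity_sd = purity_sd,
              rrbs_mean_coverage = rrbs_mean_coverage,
              seed = as.integer(seed))
  rates <- c(cfg$cna_rate, cfg$cnnloh_rate, cfg$del_rate,
             cfg$epimutation_rate, cfg$purity_mean)
  .stop_if(any(rates < 0 | rates > 1), "rates must lie in [0, 1]")
  .stop_if(cfg$max_total_cn < 2L, "max_total_cn must be >= 2")
  .stop_if(cfg$probes_per_region < 2L, "probes_per_region must be >= 2")
  .stop_if(cfg$rrbs_mean_coverage <= 0, "rrbs_mean_coverage must be > 0")
  .stop_if(!all(c("hyper", "hypo", "intermediate") %in%
                names(cfg$epimutation_kinds)),
           "epimutation_kinds needs hyper, hypo, intermediate weights")
  class(cfg) <- "sim_config"
  cfg
}

# amplification total-copy prior: mass at 3-4, geometric tail to max
.amp_weights <- function(max_total_cn) {
  tot <- 3:max_total_cn
  w <- c(0.45, 0.30, 0.25 * 0.6^(seq_len(max(0L, max_total_cn - 4L)) - 1L))
  w <- w[seq_along(tot)]
  w / sum(w)
}

#' Draw copy-number and parental-phase ground truth
#'
#' Internal first stage of [simulate_cohort()]: copy states, parental
#' phase, context latent factors and purity, without epimutations.
#'
#' @param cfg a [sim_config()].
#' @return TruthTable data.frame.
#' @export
draw_copy_truth <- function(cfg) {
  reg <- cfg$regions
  n_reg <- nrow(reg)
  tumors <- sprintf("T%03d", seq_len(cfg$n_tumors))
  normals <- sprintf("N%02d", seq_len(cfg$n_normals))
  is_dmr <- reg$klass == "imprinted_dmr"
  amp_w <- .amp_weights(cfg$max_total_cn)
  cn_tot <- 2:cfg$max_total_cn
  cn_wfull <- c(0.6, 0.2, 0.1, rep(0.1 / max(1L, cfg$max_total_cn - 4L),
                                   max(0L, cfg$max_total_cn - 4L)))
  cn_wfull <- cn_wfull[seq_along(cn_tot)]
  chrom_len <- cfg$anatomy$length_bp[match(reg$chrom, cfg$anatomy$chrom)]

  n <- (cfg$n_tumors + cfg$n_normals) * n_reg
  sample_id <- character(n); is_tumor <- logical(n)
  region_id <- character(n); klass <- character(n)
  total_cn <- integer(n); minor_cn <- integer(n)
  minor_parent <- rep(NA_character_, n); meth_copies <- rep(NA_integer_, n)
  true_beta <- numeric(n); epimutation <- rep("none", n)
  purity_v <- numeric(n); latent_v <- rep(NA_real_, n)
  seg_start <- rep(NA_real_, n); seg_end <- rep(NA_real_, n)

  ri <- 0L
  for (i in seq_len(cfg$n_tumors)) {
    set.seed(.pair_seed(cfg$seed, i, 0L, stream = 1L))
    latent <- stats::runif(1L)
    purity <- if (cfg$purity_sd > 0)
      .clip01(stats::rnorm(1L, cfg$purity_mean, cfg$purity_sd))
    else cfg$purity_mean
    for (j in seq_len(n_reg)) {
      set.seed(.pair_seed(cfg$seed, i, j, stream = 0L))
      ri <- ri + 1L
      sample_id[ri] <- tumors[i]; is_tumor[ri] <- TRUE
      region_id[ri] <- reg$region_id[j]; klass[ri] <- reg$klass[j]
      purity_v[ri] <- purity; latent_v[ri] <- latent
      if (is_dmr[j]) {
        total <- 2L; minor <- 1L
        if (stats::runif(1L) < cfg$cna_rate) {
          u <- stats::runif(1L)
          if (u < cfg$cnnloh_rate) {
            total <- sample(cn_tot, 1L, prob = cn_wfull); minor <- 0L
          } else if (u < cfg$cnnloh_rate +
                     (1 - cfg$cnnloh_rate) * cfg$del_rate) {
            total <- 1L; minor <- 0L
          } else {
            total <- sample(3:cfg$max_total_cn, 1L, prob = amp_w)
            minor <- sample.int(total %/% 2L, 1L)
          }
          hw <- stats::runif(2L, 0.5e6, 4e6)
          seg_start[ri] <- max(0, reg$start[j] - hw[1L])
          seg_end[ri] <- min(chrom_len[j], reg$end[j] + hw[2L])
        }
        mp <- sample(c("maternal", "paternal"), 1L)
        meth <- if (mp == reg$methylated_parent[j]) minor else total - minor
        minor_parent[ri] <- mp
        total_cn[ri] <- total; minor_cn[ri] <- minor
        meth_copies[ri] <- meth; true_beta[ri] <- meth / total
      } else {
        total_cn[ri] <- 2L; minor_cn[ri] <- 1L
        hyper <- stats::runif(1L) < latent
        true_beta[ri] <- if (hyper) stats::runif(1L, 0.3, 0.95)
                         else cfg$context_baseline
      }
    }
  }
  for (k in seq_len(cfg$n_normals)) {
    idx <- ri + seq_len(n_reg)
    sample_id[idx] <- normals[k]
    region_id[idx] <- reg$region_id; klass[idx] <- reg$klass
    total_cn[idx] <- 2L; minor_cn[idx] <- 1L
    meth_copies[idx] <- ifelse(is_dmr, 1L, NA_integer_)
    true_beta[idx] <- ifelse(is_dmr, 0.5, cfg$context_baseline)
    purity_v[idx] <- 1
    ri <- ri + n_reg
  }
  data.frame(sample_id = sample_id, is_tumor = is_tumor,
             region_id = region_id, klass = klass, total_cn = total_cn,
             minor_cn = minor_cn, minor_parent = minor_parent,
             meth_copies = meth_copies, true_beta = true_beta,
             epimutation = epimutation, purity = purity_v,
             latent = latent_v, seg_start = seg_start, seg_end = seg_end,
             stringsAsFactors = FALSE)
}

#' Inject epimutations into a truth table
#'
#' Per (tumor, imprinted DMR) pair, with probability
#' `cfg$epimutation_rate`, rewrites the per-copy methylation states:
#' `hyper` methylates all copies, `hypo` unmethylates all, `intermediate`
#' flips exactly one randomly chosen copy (so at a 2:1 locus the average
#' moves to 0 or 1, at 4:1 it shifts by 0.25). Labels are recorded in the
#' `epimutation` column.
#'
#' @param truth TruthTable from [draw_copy_truth()].
#' @param cfg the [sim_config()] used to draw it.
#' @return Updated TruthTable.
#' @export
inject_epimutations <- function(truth, cfg) {
  if (cfg$epimutation_rate == 0) return(truth)
  reg_idx <- match(truth$region_id, cfg$regions$region_id)
  tum_idx <- match(truth$sample_id,
                   sprintf("T%03d", seq_len(cfg$n_tumors)))
  kinds <- names(cfg$epimutation_kinds)
  w <- as.numeric(cfg$epimutation_kinds)
  for (r in which(truth$is_tumor & truth$klass == "imprinted_dmr")) {
    set.seed(.pair_seed(cfg$seed, tum_idx[r], reg_idx[r], stream = 3L))
    if (stats::runif(1L) >= cfg$epimutation_rate) next
    kind <- sample(kinds, 1L, prob = w)
    tot <- truth$total_cn[r]
    if (tot == 0L) next
    meth <- truth$meth_copies[r]
    meth <- switch(kind,
      hyper = tot,
      hypo = 0L,
      intermediate = if (stats::runif(1L) < meth / tot) meth - 1L
                     else meth + 1L)
    truth$meth_copies[r] <- meth
    truth$true_beta[r] <- meth / tot
    truth$epimutation[r] <- kind
  }
  truth
}

#' Mix tumor and normal methylation by purity
#'
#' The measured beta of an impure tumor sample is the purity-weighted
#' average of the tumor-cell and infiltrating-normal values.
#'
#' @param beta_tumor,beta_normal fractions in \[0,1\].
#' @param purity tumor-cell fraction in \[0,1\].
#' @return `purity * beta_tumor + (1 - purity) * beta_normal`.
#' @export
mix_purity <- function(beta_tumor, beta_normal, purity) {
  stopifnot(all(purity >= 0 & purity <= 1, na.rm = TRUE))
  purity * beta_tumor + (1 - purity) * beta_normal
}

#' Simulate an allele-resolved tumor methylome cohort
#'
#' Generates a beta-value matrix, allele-specific copy-number segments, the
#' region set and a ground-truth table. Normals are diploid 2:1 everywhere
#' with DMR averages near 0.5; tumors draw per-DMR copy states with known
#' parental phase, so probe betas equal methylated copies / total copies
#' plus clipped Gaussian noise; epimutations are injected at
#' `epimutation_rate`; purity dilutes the tumor signal toward the normal
#' profile; context regions gain methylation through a shared per-sample
#' latent burden factor, independent of imprinted epimutations. Everything
#' is deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return Object of class `"imprint_sim"`: list with `config`, `beta`
#'   ([beta_matrix()]), `manifest`, `segments`, `regions`, `anatomy`,
#'   `truth`, `normals`, `tumors`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- inject_epimutations(draw_copy_truth(cfg), cfg)
  reg <- cfg$regions
  ppr <- cfg$probes_per_region
  n_reg <- nrow(reg)

  manifest <- data.frame(
    probe_id = sprintf("p_%s_%02d", rep(reg$region_id, each = ppr),
                       rep(seq_len(ppr), n_reg)),
    chrom = rep(reg$chrom, each = ppr),
    pos = as.integer(rep(reg$start, each = ppr) +
      round((rep(seq_len(ppr), n_reg) - 0.5) / ppr *
            rep(reg$end - reg$start, each = ppr))),
    nearest_snp_distance_bp = NA_integer_, nearest_snp_maf = NA_real_,
    region_id = rep(reg$region_id, each = ppr),
    stringsAsFactors = FALSE)

  samples <- unique(truth$sample_id)
  normals <- samples[!samples %in% truth$sample_id[truth$is_tumor]]
  tumors <- setdiff(samples, normals)
  beta <- matrix(NA_real_, nrow(manifest), length(samples),
                 dimnames = list(manifest$probe_id, samples))
  signal_v <- rep(NA_real_, nrow(truth))

  tum_idx <- match(truth$sample_id, tumors)
  nor_idx <- match(truth$sample_id, normals)
  reg_idx <- match(truth$region_id, reg$region_id)
  col_idx <- match(truth$sample_id, samples)
  normal_base <- ifelse(truth$klass == "imprinted_dmr", 0.5,
                        cfg$context_baseline)
  sig <- truth$true_beta
  is_tum <- truth$is_tumor
  for (r in seq_len(nrow(truth))) {
    j <- reg_idx[r]
    rows <- ((j - 1L) * ppr + 1L):(j * ppr)
    if (is_tum[r]) {
      set.seed(.pair_seed(cfg$seed, tum_idx[r], j, stream = 4L))
      signal <- mix_purity(sig[r], normal_base[r], truth$purity[r])
    } else {
      set.seed(.pair_seed(cfg$seed, nor_idx[r], j, stream = 2L))
      biovar <- if (cfg$biovar_sd > 0)
        stats::rnorm(1L, 0, cfg$biovar_sd) else 0
      signal <- .clip01(normal_base[r] + biovar)
    }
    signal_v[r] <- signal
    noise <- if (cfg$noise_sd > 0) stats::rnorm(ppr, 0, cfg$noise_sd)
             else 0
    beta[rows, col_idx[r]] <- .clip01(signal + noise)
  }
  truth$signal <- signal_v

  has_seg <- !is.na(truth$seg_start)
  segments <- data.frame(
    sample_id = truth$sample_id[has_seg],
    chrom = reg$chrom[reg_idx[has_seg]],
    start = as.integer(truth$seg_start[has_seg]),
    end = as.integer(truth$seg_end[has_seg]),
    total_cn = truth$total_cn[has_seg],
    minor_cn = truth$minor_cn[has_seg], stringsAsFactors = FALSE)
  if (nrow(segments) > 0) segments <- validate_segments(segments)

  structure(list(config = cfg, beta = beta_matrix(beta),
                 manifest = manifest, segments = segments, regions = reg,
                 anatomy = cfg$anatomy, truth = truth,
                 normals = normals, tumors = tumors),
            class = "imprint_sim")
}

#' @export
print.imprint_sim <- function(x, ...) {
  cat("imprint_sim:", length(x$tumors), "tumors,", length(x$normals),
      "normals,", nrow(x$regions), "regions,", nrow(x$beta$beta),
      "probes; seed", x$config$seed, "\n")
  invisible(x)
}

#' Simulate RRBS read counts for the imprinted DMR sites
#'
#' One site per simulated DMR probe position. Coverage is Poisson with mean
#' `cfg$rrbs_mean_coverage` (zero-coverage sites are dropped) and the
#' methylated read count is Binomial(coverage, site methylation), where the
#' site methylation is the sample's purity-mixed region signal.
#'
#' @param sim an [simulate_cohort()] result.
#' @param samples sample ids to emit (default: all).
#' @return data.frame `(sample, chrom, pos, meth_count, total_count)`.
#' @export
simulate_rrbs_counts <- function(sim, samples = NULL) {
  cfg <- sim$config
  ppr <- cfg$probes_per_region
  truth <- sim$truth[sim$truth$klass == "imprinted_dmr", , drop = FALSE]
  if (!is.null(samples))
    truth <- truth[truth$sample_id %in% samples, , drop = FALSE]
  reg_idx <- match(truth$region_id, sim$regions$region_id)
  all_idx <- match(truth$sample_id, c(sim$tumors, sim$normals))
  out <- vector("list", nrow(truth))
  for (r in seq_len(nrow(truth))) {
    set.seed(.pair_seed(cfg$seed, all_idx[r], reg_idx[r], stream = 5L))
    cov <- stats::rpois(ppr, cfg$rrbs_mean_coverage)
    keep <- cov > 0L
    if (!any(keep)) next
    p <- truth$signal[r]
    rows <- ((reg_idx[r] - 1L) * ppr + 1L):(reg_idx[r] * ppr)
    out[[r]] <- data.frame(
      sample = truth$sample_id[r],
      chrom = sim$manifest$chrom[rows][keep],
      pos = sim$manifest$pos[rows][keep],
      meth_count = stats::rbinom(sum(keep), cov[keep], p),
      total_count = cov[keep], stringsAsFactors = FALSE)
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1L))])
}

#' Write a simulated cohort to disk in pipeline dialects
#'
#' Emits `beta.tsv`, `segments.tsv`, `regions.bed`, `anatomy.tsv`,
#' `manifest.tsv`, `truth.tsv`, `controls.txt` and `config.yaml` under
#' `dir`. Refuses to overwrite an existing non-empty directory unless
#' `force` is TRUE.
#'
#' @param sim an [simulate_cohort()] result.
#' @param dir output directory.
#' @param force overwrite existing files.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force)
    stop("output directory not empty (use force = TRUE): ", dir,
         call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(sim$beta, file.path(dir, "beta.tsv"))
  write_segments(sim$segments, file.path(dir, "segments.tsv"))
  write_regions(sim$regions, file.path(dir, "regions.bed"))
  .write_tsv(sim$anatomy, file.path(dir, "anatomy.tsv"))
  .write_tsv(sim$manifest, file.path(dir, "manifest.tsv"))
  .write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  writeLines(sim$normals, file.path(dir, "controls.txt"))
  cfg <- sim$config
  scalars <- cfg[!names(cfg) %in% c("regions", "anatomy")]
  scalars$epimutation_kinds <- as.list(cfg$epimutation_kinds)
  yaml::write_yaml(scalars, file.path(dir, "config.yaml"))
  invisible(dir)
}
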
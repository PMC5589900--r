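#' Fit the copy-number-predicted methylation model to a cohort
#'
#' The analysis core. For every tumor sample and imprinted DMR the observed
#' methylation (average beta over the DMR's probes) is compared with the
#' value implied by the locus's allele-specific copy state: with total t
#' and minor m copies the expected methylation is m/t or 1 - m/t depending
#' on which parental allele carries the germline methylation, the branch
#' being chosen by whether the observed beta lies below or above 0.5. A
#' sample deviating from its predicted value by more than three standard
#' deviations of the normal-tissue controls carries a methylation profile
#' independent of copy number - a genuine epimutation. The fit also
#' classifies methylation states (0.8/0.2 absolute and +/- 0.2 relative
#' cutoffs), infers the parental allele retained through copy-neutral LOH,
#' estimates per-region variance explained by copy number (R^2 of observed
#' on predicted), and, when CIMP/bivalent/DMV context regions are supplied,
#' scores per-sample hypermethylation burden and its correlation structure.
#'
#' @param beta a [beta_matrix()] (or plain probes x samples matrix) that
#'   has already passed probe QC ([filter_probes()]).
#' @param segments allele-specific segment data.frame
#'   ([read_segments()]).
#' @param regions region data.frame ([read_regions()]); imprinted DMRs
#'   drive the model, other classes feed the context burden.
#' @param anatomy chromosome anatomy ([read_anatomy()]).
#' @param controls character vector of normal-control sample ids (>= 2);
#'   all other columns of `beta` are treated as tumors.
#' @param manifest probe manifest with `probe_id`, `chrom`, `pos` (used to
#'   map probes into regions).
#' @param tissue cohort label carried into reports.
#' @param thresholds an [imprint_thresholds()].
#' @param min_probes minimum probes per region for averaging.
#' @return An object of class `"imprint_cna"` with components `calls` (one
#'   row per (tumor, DMR): observed, predicted, deviation, state,
#'   cna_independent, retained_parent and the copy state), `control_stats`,
#'   `region_avg`, `r_squared`, `coefficients`, `context`, `cohort`
#'   summaries, and the inputs needed by the methods.
#' @seealso [predict.imprint_cna()], [residuals.imprint_cna()],
#'   [plot.imprint_cna()], [simulate.imprint_cna()]
#' @export
imprint_cna <- function(beta, segments, regions, anatomy, controls,
                        manifest, tissue = "cohort",
                        thresholds = imprint_thresholds(),
                        min_probes = 2L) {
  bm <- if (inherits(beta, "beta_matrix")) beta else beta_matrix(beta)
  regions <- validate_regions(regions)
  th <- thresholds
  samples <- colnames(bm$beta)
  controls <- intersect(controls, samples)
  .stop_if(length(controls) < 2L,
           "need at least 2 control samples for tissue '", tissue, "'")
  tumors <- setdiff(samples, controls)  # may be empty: normals-only run

  probe_region <- map_probes_to_regions(manifest, regions)
  region_avg <- dmr_average(bm, regions, probe_region = probe_region,
                            min_probes = min_probes)
  ctrl <- compute_control_stats(region_avg, controls, tissue)

  dmrs <- regions[regions$klass == "imprinted_dmr" &
                  regions$region_id %in% rownames(region_avg), ,
                  drop = FALSE]
  .stop_if(nrow(dmrs) == 0L, "no imprinted DMRs with enough probes")
  states <- overlap_locus_state(segments, dmrs, anatomy,
                                samples = tumors, thresholds = th)

  calls <- states
  calls$observed <- region_avg[cbind(match(calls$region_id,
                                           rownames(region_avg)),
                                     match(calls$sample_id,
                                           colnames(region_avg)))]
  calls$predicted <- as.numeric(
    predicted_methylation(calls$total_cn, calls$minor_cn, calls$observed))
  calls$deviation <- calls$observed - calls$predicted
  cs <- match(calls$region_id, ctrl$region_id)
  calls$ctrl_mean <- ctrl$mean[cs]
  calls$ctrl_sd <- ctrl$sd[cs]
  calls$evaluable <- !is.na(calls$observed) & calls$total_cn > 0L
  calls$cna_independent <- ifelse(
    calls$evaluable,
    call_cna_independent(calls$observed, calls$predicted, calls$ctrl_sd,
                         sd_mult = th$sd_mult),
    NA)
  calls$state <- classify_state(calls$observed, calls$ctrl_mean, th)
  calls$retained_parent <- rep(NA_character_, nrow(calls))
  loh <- which(calls$cnnloh & calls$evaluable)
  if (length(loh) > 0) {
    mp <- dmrs$methylated_parent[match(calls$region_id[loh],
                                       dmrs$region_id)]
    calls$retained_parent[loh] <-
      infer_cnnloh_parent(calls$observed[loh], mp, th)
  }

  # per-region variance explained by copy number, and OLS coefficients
  r2 <- data.frame(region_id = dmrs$region_id, r_squared = NA_real_,
                   degenerate = NA, n = NA_integer_,
                   stringsAsFactors = FALSE)
  coefs <- matrix(NA_real_, nrow(dmrs), 2L,
                  dimnames = list(dmrs$region_id, c("intercept", "slope")))
  for (i in seq_len(nrow(dmrs))) {
    sub <- calls[calls$region_id == dmrs$region_id[i] & calls$evaluable, ]
    if (nrow(sub) < 3L) next
    v <- variance_explained(sub$observed, sub$predicted)
    r2$r_squared[i] <- as.numeric(v)
    r2$degenerate[i] <- attr(v, "degenerate")
    r2$n[i] <- nrow(sub)
    if (!attr(v, "degenerate"))
      coefs[i, ] <- coef(stats::lm(observed ~ predicted, data = sub))
  }

  context <- .fit_context(region_avg, regions, ctrl, calls, tumors, th)

  ev <- calls[calls$evaluable, , drop = FALSE]
  per_sample <- tapply(ev$cna_independent, ev$sample_id, mean)
  cohort <- list(
    tissue = tissue,
    n_tumors = length(tumors), n_controls = length(controls),
    n_dmrs = nrow(dmrs), n_pairs_evaluable = nrow(ev),
    pct_pairs_cna_independent = 100 * mean(ev$cna_independent),
    mean_pct_dmrs_affected_per_sample = 100 * mean(per_sample),
    per_region_pct_independent =
      100 * tapply(ev$cna_independent, ev$region_id, mean),
    state_counts = table(ev$state))

  structure(list(calls = calls, control_stats = ctrl,
                 region_avg = region_avg, r_squared = r2,
                 coefficients = coefs, context = context, cohort = cohort,
                 regions = regions, dmrs = dmrs, thresholds = th,
                 tissue = tissue, controls = controls, tumors = tumors),
            class = "imprint_cna")
}

# context-region severity, burden and correlation structure
.fit_context <- function(region_avg, regions, ctrl, calls, tumors, th) {
  ctx_reg <- regions[regions$klass != "imprinted_dmr" &
                     regions$region_id %in% rownames(region_avg), ,
                     drop = FALSE]
  if (nrow(ctx_reg) == 0L || length(tumors) == 0L) return(NULL)
  selected <- select_analysis_regions(ctrl, ctx_reg, thresholds = th)
  if (nrow(selected) == 0L) return(NULL)
  vals <- region_avg[selected$region_id, tumors, drop = FALSE]
  cm <- ctrl$mean[match(selected$region_id, ctrl$region_id)]
  sev <- matrix(severity_class(as.vector(vals), rep(cm, ncol(vals)), th),
                nrow(vals), ncol(vals), dimnames = dimnames(vals))
  burdens <- list(); scores <- list()
  for (kl in unique(selected$klass)) {
    rows <- selected$region_id[selected$klass == kl]
    bp <- burden_profile(t(sev[rows, , drop = FALSE]))
    burdens[[kl]] <- bp
    scores[[kl]] <- setNames(bp$score, bp$sample_id)[tumors]
  }
  # imprinted burden: number of DMRs with a methylation defect per sample,
  # irrespective of CNA status
  ev <- calls[calls$evaluable, , drop = FALSE]
  imp <- tapply(ev$state != "normal", ev$sample_id, sum)
  scores[["imprinted"]] <- as.numeric(imp[tumors])
  names(scores[["imprinted"]]) <- tumors
  corr <- if (length(scores) >= 2L) burden_correlation_matrix(scores)
          else NULL
  list(selected = selected, severity = sev, burdens = burdens,
       scores = scores, correlations = corr)
}

#' @export
print.imprint_cna <- function(x, ...) {
  cat("Copy-number-predicted methylation fit ('", x$tissue, "')\n",
      sep = "")
  cat("  ", x$cohort$n_tumors, " tumors vs ", x$cohort$n_controls,
      " controls over ", x$cohort$n_dmrs, " imprinted DMRs\n", sep = "")
  cat(sprintf("  %.1f%% of evaluable (sample, DMR) pairs CNA-independent\n",
              x$cohort$pct_pairs_cna_independent))
  r2 <- x$r_squared$r_squared[!is.na(x$r_squared$r_squared) &
                              !x$r_squared$degenerate]
  if (length(r2) > 0)
    cat(sprintf("  median per-region R^2 (observed ~ predicted): %.3f\n",
                stats::median(r2)))
  invisible(x)
}

#' @export
summary.imprint_cna <- function(object, ...) {
  structure(list(fit = object), class = "summary.imprint_cna")
}

#' @export
print.summary.imprint_cna <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nMethylation states (evaluable pairs):\n")
  print(f$cohort$state_counts)
  cat(sprintf("\nMean %% of DMRs affected per sample: %.1f%%\n",
              f$cohort$mean_pct_dmrs_affected_per_sample))
  top <- sort(f$cohort$per_region_pct_independent, decreasing = TRUE)
  cat("Most frequently epimutated regions (% of samples):\n")
  print(round(utils::head(top, 5L), 1))
  if (!is.null(f$context$correlations)) {
    cat("\nBurden correlations:\n")
    print(round(f$context$correlations$coefficient, 2))
  }
  invisible(x)
}

#' Model coefficients: per-region OLS of observed on predicted methylation
#'
#' @param object an [imprint_cna()] fit.
#' @param ... unused.
#' @return Matrix with columns `intercept`, `slope`, `r_squared`.
#' @export
coef.imprint_cna <- function(object, ...) {
  cbind(object$coefficients,
        r_squared = object$r_squared$r_squared[
          match(rownames(object$coefficients),
                object$r_squared$region_id)])
}

#' Predicted methylation from the fitted model
#'
#' Without `newdata`, returns the fitted CNA-predicted values, one per
#' (tumor, DMR) call. With `newdata` (columns `total_cn`, `minor_cn`,
#' `observed`), evaluates the allele-counting prediction on new copy
#' states.
#'
#' @param object an [imprint_cna()] fit.
#' @param newdata optional data.frame of new copy states.
#' @param ... unused.
#' @return Numeric vector of predicted fractions.
#' @export
predict.imprint_cna <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    p <- object$calls$predicted
    names(p) <- paste(object$calls$sample_id, object$calls$region_id,
                      sep = ".")
    return(p)
  }
  as.numeric(predicted_methylation(newdata$total_cn, newdata$minor_cn,
                                   newdata$observed))
}

#' Residuals: observed minus CNA-predicted methylation
#'
#' These are the deviations the epimutation call thresholds at
#' `sd_mult * ctrl_sd`.
#'
#' @param object an [imprint_cna()] fit.
#' @param ... unused.
#' @return Named numeric vector.
#' @export
residuals.imprint_cna <- function(object, ...) {
  r <- object$calls$deviation
  names(r) <- paste(object$calls$sample_id, object$calls$region_id,
                    sep = ".")
  r
}

#' Observed-vs-expected scatter table
#'
#' Plain-table export of the observed-vs-expected methylation plot:
#' x = predicted, y = observed, band = predicted +/- `sd_mult` control
#' s.d.
#'
#' @param fit an [imprint_cna()] fit.
#' @param region optional region_id subset.
#' @return data.frame `(sample_id, region_id, predicted, observed,
#'   band_lo, band_hi, cna_independent)`.
#' @export
scatter_table <- function(fit, region = NULL) {
  stopifnot(inherits(fit, "imprint_cna"))
  d <- fit$calls
  if (!is.null(region)) d <- d[d$region_id %in% region, , drop = FALSE]
  w <- fit$thresholds$sd_mult * d$ctrl_sd
  data.frame(sample_id = d$sample_id, region_id = d$region_id,
             predicted = d$predicted, observed = d$observed,
             band_lo = d$predicted - w, band_hi = d$predicted + w,
             cna_independent = d$cna_independent,
             stringsAsFactors = FALSE)
}

#' Plot observed versus CNA-predicted methylation for one region
#'
#' Points outside the dashed +/- 3 s.d. control band have methylation
#' profiles independent of copy number.
#'
#' @param x an [imprint_cna()] fit.
#' @param region region_id to plot (default: first DMR).
#' @param ... passed to [graphics::plot()].
#' @export
plot.imprint_cna <- function(x, region = NULL, ...) {
  if (is.null(region)) region <- x$dmrs$region_id[1L]
  d <- scatter_table(x, region)
  d <- d[!is.na(d$observed), , drop = FALSE]
  graphics::plot(d$predicted, d$observed, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "CNA-predicted methylation",
                 ylab = "observed methylation", main = region,
                 col = ifelse(d$cna_independent, "red", "black"), ...)
  graphics::abline(0, 1, col = "grey40")
  w <- x$thresholds$sd_mult *
    x$control_stats$sd[match(region, x$control_stats$region_id)]
  graphics::abline(w, 1, lty = 2)
  graphics::abline(-w, 1, lty = 2)
  invisible(x)
}

#' Simulate observed methylation from a fitted model
#'
#' Draws region averages around the fitted CNA-predicted values with the
#' control standard deviation as noise scale (clipped to \[0,1\]) - the
#' no-epimutation null of the fitted cohort.
#'
#' @param object an [imprint_cna()] fit.
#' @param nsim number of replicate cohorts.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame with `sample_id`, `region_id` and one `sim_k` column
#'   per replicate.
#' @export
simulate.imprint_cna <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$calls
  out <- data.frame(sample_id = d$sample_id, region_id = d$region_id,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nsim))
    out[[paste0("sim_", k)]] <-
      .clip01(stats::rnorm(nrow(d), d$predicted, d$ctrl_sd))
  out
}
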
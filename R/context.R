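#' Select context regions analysable for hypermethylation
#'
#' Keeps regions that are uniformly unmethylated in normal tissue
#' (control mean strictly below `ctrl_unmeth`, default 0.2); only such
#' regions can gain methylation informatively.
#'
#' @param ctrl_stats data.frame from [compute_control_stats()].
#' @param regions region data.frame (matched on `region_id`).
#' @param klass optional subset of region classes to consider.
#' @param thresholds an [imprint_thresholds()].
#' @return The selected subset of `regions`, with attribute
#'   `"counts_per_klass"`.
#' @export
select_analysis_regions <- function(ctrl_stats, regions, klass = NULL,
                                    thresholds = imprint_thresholds()) {
  if (!is.null(klass)) regions <- regions[regions$klass %in% klass, ,
                                          drop = FALSE]
  m <- ctrl_stats$mean[match(regions$region_id, ctrl_stats$region_id)]
  keep <- !is.na(m) & m < thresholds$ctrl_unmeth
  out <- regions[keep, , drop = FALSE]
  attr(out, "counts_per_klass") <- table(out$klass)
  out
}

#' Severity of hypermethylation at one region
#'
#' `highly` when the region average exceeds 0.75, else `mildly` above 0.5,
#' else `lowly` when at or above the control mean + 0.2, else `unaffected`.
#' Monotone in the value for a fixed control mean.
#'
#' @param value region-average beta values.
#' @param ctrl_mean control means (recycled).
#' @param thresholds an [imprint_thresholds()].
#' @return Character vector of severities.
#' @export
severity_class <- function(value, ctrl_mean,
                           thresholds = imprint_thresholds()) {
  th <- thresholds
  out <- ifelse(value > th$severity_high, "highly",
         ifelse(value > th$severity_mid, "mildly",
         ifelse(value >= ctrl_mean + th$severity_low_delta, "lowly",
                "unaffected")))
  out[is.na(value)] <- NA_character_
  out
}

#' Per-sample hypermethylation burden and cohort ranking
#'
#' Counts regions per severity level for each sample and scores the burden
#' as `3*highly + 2*mildly + 1*lowly` (weights configurable). Samples are
#' ranked by descending score, ties broken by the number of highly
#' methylated regions and then by sample id, mirroring stacked-histogram
#' rankings by severity and number of affected loci.
#'
#' @param severity sample x region character matrix of severities (or a
#'   long data.frame with `sample_id`, `severity`).
#' @param weights named numeric weights for `highly`, `mildly`, `lowly`.
#' @return data.frame `(sample_id, n_highly, n_mildly, n_lowly,
#'   n_unaffected, score, rank)`, ordered by rank.
#' @export
burden_profile <- function(severity,
                           weights = c(highly = 3, mildly = 2, lowly = 1)) {
  if (is.data.frame(severity)) {
    sam <- severity$sample_id
    sev <- severity$severity
  } else {
    sam <- rep(rownames(severity), ncol(severity))
    sev <- as.vector(severity)
  }
  lev <- c("highly", "mildly", "lowly", "unaffected")
  tab <- table(factor(sam, levels = unique(sam)),
               factor(sev, levels = lev))
  out <- data.frame(sample_id = rownames(tab),
                    n_highly = as.integer(tab[, "highly"]),
                    n_mildly = as.integer(tab[, "mildly"]),
                    n_lowly = as.integer(tab[, "lowly"]),
                    n_unaffected = as.integer(tab[, "unaffected"]),
                    stringsAsFactors = FALSE)
  out$score <- weights[["highly"]] * out$n_highly +
    weights[["mildly"]] * out$n_mildly + weights[["lowly"]] * out$n_lowly
  o <- order(-out$score, -out$n_highly, out$sample_id)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Correlate two per-sample burden vectors
#'
#' Uses Pearson's correlation when both vectors look normal
#' (Shapiro-Wilk, alpha = 0.05) and Spearman's rank correlation otherwise.
#' Zero-variance input yields an `NA` coefficient flagged as degenerate.
#'
#' @param x,y paired numeric vectors (>= 5 samples).
#' @param alpha normality-test level.
#' @return list `(coefficient, method, degenerate)`.
#' @export
correlate_burdens <- function(x, y, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  .stop_if(length(x) < 5L, "need at least 5 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(coefficient = NA_real_, method = NA_character_,
                degenerate = TRUE))
  normal <- vapply(list(x, y), function(v) {
    v <- if (length(v) > 5000L) v[seq_len(5000L)] else v
    stats::shapiro.test(v)$p.value >= alpha
  }, logical(1L))
  method <- if (all(normal)) "pearson" else "spearman"
  list(coefficient = stats::cor(x, y, method = method), method = method,
       degenerate = FALSE)
}

#' Pairwise burden correlation matrix
#'
#' @param scores named list (or data.frame) of per-sample score vectors,
#'   one element per region class.
#' @return list of matrices: `coefficient` and `method`.
#' @export
burden_correlation_matrix <- function(scores) {
  scores <- as.list(scores)
  k <- length(scores)
  nm <- names(scores)
  co <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  me <- matrix(NA_character_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    r <- correlate_burdens(scores[[i]], scores[[j]])
    co[i, j] <- r$coefficient
    me[i, j] <- if (is.na(r$method)) NA_character_ else r$method
  }
  list(coefficient = co, method = me)
}
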
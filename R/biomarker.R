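# qRT-PCR relative quantification (2^-ddCt) and diagnostic evaluation:
# ROC/AUC with DeLong confidence intervals and paired comparisons, Youden
# cutoffs, and rank correlations with clinical covariates.

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged (arithmetic mean of Ct; replicate SD
#' above 0.5 cycles is flagged), then per sample
#' `dCt = Ct_target - Ct_reference`,
#' `ddCt = dCt - mean(dCt in the calibrator group)`, and
#' `rq = 2^-ddCt`.  The amplification efficiency is fixed at 2 (the
#' 2^-ddCt assumption).
#'
#' @param ct a `CtTable` data frame with columns `sample`, `group`,
#'   `gene`, `replicate`, `ct` (cycles, in (0, 45]).
#' @param target_gene,reference_gene gene ids; the reference must be
#'   present for every sample assaying the target.
#' @param calibrator_group group whose mean dCt anchors ddCt
#'   (default `"control"`).
#' @param qc_sd_flag replicate-SD threshold (cycles) for the QC flag.
#' @return Data frame with one row per sample: `sample`, `group`, `dct`,
#'   `ddct`, `rq`, `replicate_sd_flag`; the group mean/SD summary of `rq`
#'   is attached as attribute `"summary"`.
#' @export
ddct <- function(ct, target_gene, reference_gene, calibrator_group = "control",
                 qc_sd_flag = 0.5) {
  needed <- c("sample", "group", "gene", "replicate", "ct")
  if (!all(needed %in% names(ct)))
    stopf("Ct table must have columns: %s", paste(needed, collapse = ", "))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0 | ct$ct > 45))
    stopf("Ct values must lie in (0, 45]")
  tgt <- ct[ct$gene == target_gene, , drop = FALSE]
  ref <- ct[ct$gene == reference_gene, , drop = FALSE]
  if (!nrow(tgt)) stopf("target gene '%s' not found", target_gene)
  missing_ref <- setdiff(unique(tgt$sample), unique(ref$sample))
  if (length(missing_ref))
    stopf("reference gene '%s' missing for sample(s): %s", reference_gene,
          paste(head(missing_ref, 5), collapse = ", "))
  agg <- function(df) {
    m <- tapply(df$ct, df$sample, mean)
    s <- tapply(df$ct, df$sample, sd)
    list(mean = m, sd = s)
  }
  at <- agg(tgt); ar <- agg(ref)
  samples <- sort_c(unique(tgt$sample))
  group <- tgt$group[match(samples, tgt$sample)]
  if (!calibrator_group %in% group)
    stopf("calibrator group '%s' has no samples", calibrator_group)
  dct <- unname(at$mean[samples] - ar$mean[samples])
  ddct_v <- dct - mean(dct[group == calibrator_group])
  rq <- 2^(-ddct_v)
  sd_flag <- pmax(at$sd[samples], ar$sd[samples], na.rm = TRUE)
  sd_flag[is.na(sd_flag)] <- 0
  out <- data.frame(sample = samples, group = group, dct = dct,
                    ddct = ddct_v, rq = rq,
                    replicate_sd_flag = unname(sd_flag) > qc_sd_flag,
                    stringsAsFactors = FALSE)
  if (any(out$replicate_sd_flag))
    message(sprintf("%d sample(s) with replicate SD > %.2f cycles",
                    sum(out$replicate_sd_flag), qc_sd_flag))
  summ <- do.call(rbind, lapply(split(out$rq, out$group), function(v)
    data.frame(mean_rq = mean(v), sd_rq = sd(v))))
  summ$group <- rownames(summ); rownames(summ) <- NULL
  attr(out, "summary") <- summ[, c("group", "mean_rq", "sd_rq")]
  out
}

# DeLong placement values for oriented scores (higher score = more
# case-like): V10 per case, V01 per control.
delong_placements <- function(case_scores, control_scores) {
  n1 <- length(case_scores); n0 <- length(control_scores)
  r_all <- rank(c(case_scores, control_scores))
  r_case <- rank(case_scores)
  r_control <- rank(control_scores)
  v10 <- (r_all[seq_len(n1)] - r_case) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_control) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' ROC analysis of a diagnostic marker
#'
#' The AUC is the tie-corrected pair-counting (Mann-Whitney) statistic
#' `(concordant + 0.5 * tied) / (n_case * n_control)`, oriented so that
#' AUC >= 0.5: when cases tend to have *lower* values the marker is
#' flipped and the orientation flag records `"lower-in-case"`.  Candidate
#' cutoffs are the midpoints between consecutive sorted unique values
#' (plus sentinels beyond the range); the optimal cutoff maximises the
#' Youden index `J = sensitivity + specificity - 1`, ties broken toward
#' higher sensitivity.  The confidence interval uses the DeLong variance
#' with a normal approximation, truncated to `[0, 1]`.
#'
#' @param values numeric marker values, one per sample.
#' @param labels group labels (`positive` marks the case class).
#' @param positive label treated as the case class.
#' @param conf_level confidence level of the AUC interval.
#' @return An object of class `roc_result`: list with `auc`,
#'   `orientation`, `ci` (lo, hi), `se`, `thresholds` (cutoff,
#'   sensitivity, specificity, youden on the original value scale),
#'   `optimal` (cutoff, sensitivity, specificity, youden), `n_case`,
#'   `n_control`, plus the oriented scores and labels for paired
#'   comparisons.
#' @export
roc_curve <- function(values, labels, positive = "case", conf_level = 0.95) {
  if (length(values) != length(labels)) stopf("one label per value required")
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  is_case <- labels == positive
  if (!any(is_case) || all(is_case))
    stopf("both classes must be non-empty")
  x <- values[is_case]; y <- values[!is_case]
  pl <- delong_placements(x, y)
  orientation <- "higher-in-case"
  if (pl$auc < 0.5) {
    orientation <- "lower-in-case"
    pl <- delong_placements(-x, -y)
  }
  auc <- pl$auc
  n1 <- length(x); n0 <- length(y)
  v <- (if (n1 > 1) var(pl$v10) else 0) / n1 +
       (if (n0 > 1) var(pl$v01) else 0) / n0
  se <- sqrt(v)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - zq * se), min(1, auc + zq * se))

  # thresholds on the original value scale
  sign_mult <- if (orientation == "higher-in-case") 1 else -1
  sc <- sign_mult * values
  su <- sort(unique(sc))
  cuts <- if (length(su) > 1)
    c(su[1] - 1, (su[-1] + su[-length(su)]) / 2, su[length(su)] + 1)
  else c(su - 1, su + 1)
  sens <- vapply(cuts, function(cc) mean(sign_mult * x >= cc), numeric(1))
  spec <- vapply(cuts, function(cc) mean(sign_mult * y < cc), numeric(1))
  thresholds <- data.frame(cutoff = sign_mult * cuts, sensitivity = sens,
                           specificity = spec, youden = sens + spec - 1)
  best <- order(-thresholds$youden, -thresholds$sensitivity)[1]
  structure(list(auc = auc, orientation = orientation, ci = ci, se = se,
                 conf_level = conf_level, thresholds = thresholds,
                 optimal = thresholds[best, , drop = FALSE],
                 n_case = n1, n_control = n0,
                 scores_case = sign_mult * x, scores_control = sign_mult * y),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0("<roc_result> AUC = %.3f (%d%% CI %.3f-%.3f), %s\n",
                     "  optimal cutoff %.4g: sensitivity %.1f%%, specificity %.1f%%\n"),
              x$auc, round(100 * x$conf_level), x$ci[1], x$ci[2],
              x$orientation, x$optimal$cutoff, 100 * x$optimal$sensitivity,
              100 * x$optimal$specificity))
  invisible(x)
}

#' Compare two ROC analyses on the same samples (paired DeLong)
#'
#' @param roc_a,roc_b `roc_result` objects computed on the same samples in
#'   the same order.
#' @return List with `delta_auc` (`auc_a - auc_b`), `se`, `z`, `p`
#'   (two-sided).
#' @export
compare_roc <- function(roc_a, roc_b) {
  stopifnot(inherits(roc_a, "roc_result"), inherits(roc_b, "roc_result"))
  if (roc_a$n_case != roc_b$n_case || roc_a$n_control != roc_b$n_control)
    stopf("ROC results were not computed on the same samples")
  pa <- delong_placements(roc_a$scores_case, roc_a$scores_control)
  pb <- delong_placements(roc_b$scores_case, roc_b$scores_control)
  n1 <- roc_a$n_case; n0 <- roc_a$n_control
  s10 <- if (n1 > 1) cov(cbind(pa$v10, pb$v10)) else matrix(0, 2, 2)
  s01 <- if (n0 > 1) cov(cbind(pa$v01, pb$v01)) else matrix(0, 2, 2)
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- roc_a$auc - roc_b$auc
  if (v <= 1e-16) {
    z <- 0; p <- if (abs(delta) < 1e-12) 1 else 0
  } else {
    z <- delta / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  list(delta_auc = delta, se = sqrt(max(v, 0)), z = z, p = p)
}

# All permutations of 1..n as a matrix (n! rows), built iteratively.
all_permutations <- function(n) {
  p <- matrix(1L, 1, 1)
  for (k in 2:n) {
    m <- nrow(p)
    out <- matrix(0L, m * k, k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1L) * m + seq_len(m)
      if (pos == 1L) out[rows, ] <- cbind(k, p)
      else if (pos == k) out[rows, ] <- cbind(p, k)
      else out[rows, ] <- cbind(p[, seq_len(pos - 1L), drop = FALSE], k,
                                p[, pos:(k - 1L), drop = FALSE])
    }
    p <- out
  }
  p
}

#' Correlation of a marker with a clinical covariate
#'
#' Spearman (default; Pearson on average-tie ranks) or Pearson.  Missing
#' pairs are dropped; at least 3 complete pairs and non-degenerate
#' variance are required.  The two-sided p-value uses the t approximation
#' `t = r sqrt((n-2)/(1-r^2))` for n > 10 and exact enumeration of all n!
#' permutations for n <= 10.
#'
#' @param marker,covariate paired numeric vectors.
#' @param method `"spearman"` or `"pearson"`.
#' @param covariate_name label carried into the result.
#' @return List of class `correlation_result`: `covariate`, `method`, `r`,
#'   `p`, `n`.
#' @export
correlate <- function(marker, covariate, method = c("spearman", "pearson"),
                      covariate_name = deparse(substitute(covariate))) {
  method <- match.arg(method)
  if (length(marker) != length(covariate)) stopf("paired vectors required")
  ok <- is.finite(marker) & is.finite(covariate)
  x <- marker[ok]; y <- covariate[ok]
  n <- length(x)
  if (n < 3) stopf("at least 3 complete pairs required")
  if (sd(x) == 0 || sd(y) == 0) stopf("zero-variance input")
  stat <- function(a, b) {
    if (method == "spearman") cor(rank(a), rank(b)) else cor(a, b)
  }
  r <- stat(x, y)
  if (n <= 10) {
    perms <- all_permutations(n)
    if (method == "spearman") {
      rx <- rank(x)
      ry_mat <- matrix(rank(y)[perms], nrow(perms), n)
      r_all <- as.numeric(cor(t(ry_mat), rx))
    } else {
      yp <- matrix(y[perms], nrow(perms), n)
      r_all <- as.numeric(cor(t(yp), x))
    }
    p <- mean(abs(r_all) >= abs(r) - 1e-12)
  } else {
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * pt(-abs(tt), n - 2)
    }
  }
  structure(list(covariate = covariate_name, method = method, r = r,
                 p = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s: %s r = %.3f, p = %.3g, n = %d\n",
              x$covariate, x$method, x$r, x$p, x$n))
  invisible(x)
}
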
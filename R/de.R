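# Differential expression: LOWESS MA normalisation, per-feature tests,
# multiple-testing correction, and the two-level screen (DE call, then the
# stricter qPCR-candidate filter).

#' LOWESS normalisation of paired intensity vectors
#'
#' Removes intensity-dependent bias between a case and a control signal
#' vector in MA space: with `M = log2(case/control)` and
#' `A = (log2 case + log2 control)/2`, the locally weighted regression of M
#' on A is subtracted from M, and the corrected positive intensities are
#' returned.  Feature order is preserved.
#'
#' @param case_signal,control_signal equal-length positive vectors
#'   (at least 10 features; the local fit is unstable below that).
#' @param span LOWESS smoother span (fraction of points).
#' @return A list with normalised `case` and `control` vectors.
#' @export
lowess_normalize <- function(case_signal, control_signal, span = 0.4) {
  if (length(case_signal) != length(control_signal))
    stopf("paired vectors must have equal length")
  if (length(case_signal) < 10)
    stopf("at least 10 features required for a stable LOWESS fit")
  if (any(!is.finite(case_signal)) || any(!is.finite(control_signal)) ||
      any(case_signal <= 0) || any(control_signal <= 0))
    stopf("signals must be finite and strictly positive")
  assert_scalar_number(span, "span", 0, 1, strict = TRUE)
  M <- log2(case_signal) - log2(control_signal)
  A <- (log2(case_signal) + log2(control_signal)) / 2
  fit <- lowess(A, M, f = span)
  trend <- approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
  M2 <- M - trend
  list(case = 2^(A + M2 / 2), control = 2^(A - M2 / 2))
}

# Exact two-sided Mann-Whitney p by enumeration of all C(n1+n2, n1)
# group assignments of the pooled (tie-averaged) ranks.
mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  p <- 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps))
  min(p, 1)
}

# Tie-corrected normal approximation (no continuity correction).
mw_normal_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  2 * pnorm(-abs(u - n1 * n2 / 2) / sqrt(sigma2))
}

mann_whitney_p <- function(x, y) {
  if (max(length(x), length(y)) <= 8) mw_exact_p(x, y) else mw_normal_p(x, y)
}

welch_p <- function(x, y) {
  out <- tryCatch(t.test(x, y, var.equal = FALSE)$p.value, error = function(e) NA_real_)
  if (is.na(out)) mann_whitney_p(x, y) else out
}

#' Per-feature two-group test
#'
#' Welch's t on log2 values (default when both groups have >= 3 samples) or
#' the Mann-Whitney U test.  The Mann-Whitney p-value is computed by exact
#' enumeration of all group assignments when both groups have <= 8 samples
#' and by a tie-corrected normal approximation otherwise; all-tie features
#' give p = 1.  Degenerate constant features for which the t statistic is
#' undefined fall back to the exact Mann-Whitney path (their count is
#' reported via a message).
#'
#' @param em an `expr_matrix`.
#' @param method `"auto"`, `"welch_t"` or `"mann_whitney"`.
#' @return Named vector of raw two-sided p-values, one per feature.
#' @export
de_test <- function(em, method = c("auto", "welch_t", "mann_whitney")) {
  stopifnot(inherits(em, "expr_matrix"))
  method <- match.arg(method)
  xc <- case_values(em); xo <- control_values(em)
  n1 <- ncol(xc); n2 <- ncol(xo)
  if (n1 < 1 || n2 < 1) stopf("both groups must be non-empty")
  if (method == "auto")
    method <- if (min(n1, n2) >= 3) "welch_t" else "mann_whitney"
  if (method == "welch_t" && min(n1, n2) < 2)
    stopf("welch_t requires at least 2 samples per group")
  pc <- pseudocount(em$values)
  p <- vapply(seq_len(nrow(em$values)), function(i) {
    if (method == "welch_t")
      welch_p(log2(xc[i, ] + pc), log2(xo[i, ] + pc))
    else mann_whitney_p(xc[i, ], xo[i, ])
  }, numeric(1))
  n_degenerate <- sum(vapply(seq_len(nrow(em$values)), function(i)
    length(unique(c(xc[i, ], xo[i, ]))) == 1L, logical(1)))
  if (n_degenerate > 0)
    message(sprintf("%d all-tie feature(s) with degenerate tests", n_degenerate))
  setNames(p, rownames(em$values))
}

# Half the smallest positive value: keeps fold changes finite and
# symmetric when a group mean is zero.
pseudocount <- function(values) {
  pos <- values[values > 0]
  if (!length(pos)) return(0.5)
  min(pos) / 2
}

#' Benjamini-Hochberg (or Bonferroni) adjustment
#'
#' Standard step-up FDR control: sort p ascending, take running minima of
#' `p * m / rank` from the largest rank down, cap at 1, and return values
#' in the input order.
#'
#' @param p vector of p-values in `[0, 1]`; `NA` is rejected.
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (anyNA(p)) stopf("p-values must not be NA")
  if (any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' Differential expression table
#'
#' Per-feature group means (linear scale), fold change (case/control, with
#' a half-minimum pseudocount guarding zero means), log2 fold change, raw
#' and adjusted p-values, the larger of the two group means
#' (`max_group_signal`, the abundance used by the candidate screen), and
#' flags/directions filled in by [call_de()] and [candidate_filter()] at
#' their default thresholds.
#'
#' @param em an `expr_matrix`.
#' @param method test passed to [de_test()].
#' @param adjust correction passed to [bh_adjust()].
#' @return A data frame of class `de_table` with columns `feature`,
#'   `class`, `mean_case`, `mean_control`, `fc`, `log2fc`, `p`, `q`,
#'   `direction`, `max_group_signal`, `passes_de`, `passes_candidate`.
#' @export
de_table <- function(em, method = "auto", adjust = "BH") {
  stopifnot(inherits(em, "expr_matrix"))
  mean_case <- rowMeans(case_values(em))
  mean_control <- rowMeans(control_values(em))
  pc <- pseudocount(em$values)
  fc <- (mean_case + pc) / (mean_control + pc)
  p <- de_test(em, method)
  det <- data.frame(feature = rownames(em$values),
                    class = em$feature_class,
                    mean_case = unname(mean_case),
                    mean_control = unname(mean_control),
                    fc = unname(fc), log2fc = unname(log2(fc)),
                    p = unname(p), q = unname(bh_adjust(p, adjust)),
                    direction = "ns",
                    max_group_signal = unname(pmax(mean_case, mean_control)),
                    passes_de = FALSE, passes_candidate = FALSE,
                    stringsAsFactors = FALSE)
  class(det) <- c("de_table", "data.frame")
  det <- call_de(det)$table
  cand <- candidate_filter(det)
  det$passes_candidate <- det$feature %in% cand
  det
}

#' Call up/down differential features
#'
#' A feature is up-regulated when `log2FC > log2(fc_threshold)` and
#' `q < q_threshold` (both strict), down-regulated symmetrically.
#'
#' @param det a [de_table()].
#' @param fc_threshold linear fold-change threshold (default 2).
#' @param q_threshold adjusted-p threshold (default 0.05).
#' @return A list with `up` and `down` feature-id vectors and `table`, the
#'   input with `direction` and `passes_de` refreshed.
#' @export
call_de <- function(det, fc_threshold = 2, q_threshold = 0.05) {
  stopifnot(inherits(det, "data.frame"))
  lf <- log2(fc_threshold)
  up <- det$log2fc > lf & det$q < q_threshold
  down <- det$log2fc < -lf & det$q < q_threshold
  det$direction <- ifelse(up, "up", ifelse(down, "down", "ns"))
  det$passes_de <- up | down
  list(up = det$feature[up], down = det$feature[down], table = det)
}

#' Candidate screen for qPCR validation
#'
#' Keeps features with `|log2FC| > log2fc_floor` (strict), `p < p_floor`
#' (strict, and p computable and nonzero), and abundant expression in
#' either group: `max_group_signal >= signal_floor` for microarray-class
#' (miRNA) features or `>= copy_floor` for sequencing-class (lncRNA/mRNA)
#' features.
#'
#' @param det a [de_table()].
#' @param log2fc_floor log2 fold-change floor (default 1.5).
#' @param p_floor raw-p ceiling (default 0.01).
#' @param copy_floor minimum FPKM-scale abundance (default 30).
#' @param signal_floor minimum microarray signal (default 500).
#' @return Character vector of candidate feature ids.
#' @export
candidate_filter <- function(det, log2fc_floor = 1.5, p_floor = 0.01,
                             copy_floor = 30, signal_floor = 500) {
  stopifnot(inherits(det, "data.frame"))
  floor_per_class <- ifelse(det$class == "mirna", signal_floor, copy_floor)
  keep <- abs(det$log2fc) > log2fc_floor &
    is.finite(det$p) & det$p > 0 & det$p < p_floor &
    det$max_group_signal >= floor_per_class
  det$feature[keep]
}

#' Write / read a DE table as TSV
#' @param det a [de_table()].
#' @param path file path.
#' @return `write_de_table` returns `path` invisibly; `read_de_table` a
#'   `de_table`.
#' @export
write_de_table <- function(det, path) {
  write_tsv(det, path)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  det <- read_tsv(path)
  needed <- c("feature", "class", "mean_case", "mean_control", "fc",
              "log2fc", "p", "q", "direction", "max_group_signal",
              "passes_de", "passes_candidate")
  if (!all(needed %in% names(det)))
    stopf("DE table is missing columns: %s",
          paste(setdiff(needed, names(det)), collapse = ", "))
  class(det) <- c("de_table", "data.frame")
  det
}
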
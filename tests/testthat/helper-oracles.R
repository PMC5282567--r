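# Independent brute-force oracles used across the suite.  These deliberately
# re-derive each quantity from first principles (character loops, explicit
# enumeration, naive formulas) rather than calling package internals.

rand_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Naive seed-site scan: walk the target base by base, classify each 6mer-core
# occurrence by direct character comparison.
naive_seed_scan <- function(mirna, target) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  mch <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  tch <- strsplit(chartr("T", "U", toupper(target)), "")[[1]]
  core <- paste(rev(unname(comp[mch[2:7]])), collapse = "")
  rows <- list()
  for (i in seq_len(length(tch) - 5L)) {
    if (paste(tch[i:(i + 5L)], collapse = "") != core) next
    m8 <- i > 1L && tch[i - 1L] == comp[[mch[8]]]
    a1 <- (i + 6L) <= length(tch) && tch[i + 6L] == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8" else
      if (a1) "7mer-A1" else "6mer"
    rows[[length(rows) + 1L]] <- data.frame(
      type = type,
      start = if (m8) i - 2L else i - 1L,
      end = if (a1) i + 6L else i + 5L,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(type = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Naive quadratic Benjamini-Hochberg definition.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    qi <- 1
    for (j in i:m) qi <- min(qi, p[o[j]] * m / j)
    q[o[i]] <- qi
  }
  q
}

# Hypergeometric upper tail by direct summation of the pmf.
enum_hyper_tail <- function(N, K, n, k) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
}

# AUC by exhaustive pair counting (before orientation).
pair_count_auc <- function(cases, controls) {
  s <- 0
  for (x in cases) for (y in controls)
    s <- s + (x > y) + 0.5 * (x == y)
  s / (length(cases) * length(controls))
}

# Mann-Whitney two-sided p by enumerating all group assignments, with U
# computed by direct pair counting (not via ranks).
enum_mw_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) {
    s <- 0
    for (xi in a) for (yj in b) s <- s + (xi > yj) + 0.5 * (xi == yj)
    s
  }
  u_obs <- u_of(x, y)
  combs <- combn(length(pool), n1)
  u_all <- apply(combs, 2, function(idx) u_of(pool[idx], pool[-idx]))
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# Brute-force triad enumeration: triple loop over candidate node ids.
brute_force_triads <- function(mm_edges, ml_edges) {
  mirnas <- unique(c(mm_edges$regulator, ml_edges$regulator))
  lncs <- unique(ml_edges$target)
  genes <- unique(mm_edges$target)
  rows <- list()
  for (l in lncs) for (m in mirnas) for (g in genes) {
    has_ml <- any(ml_edges$regulator == m & ml_edges$target == l)
    has_mg <- any(mm_edges$regulator == m & mm_edges$target == g)
    if (has_ml && has_mg)
      rows[[length(rows) + 1L]] <- data.frame(lncrna = l, mirna = m, mrna = g,
                                              stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(lncrna = character(0), mirna = character(0),
                      mrna = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$lncrna, out$mirna, out$mrna), , drop = FALSE]
}

# A small DE-table fixture with full schema.
make_de_table <- function(feature, class, log2fc, p, q = p,
                          max_group_signal = 1000,
                          direction = NULL, passes_de = NULL,
                          passes_candidate = NULL) {
  n <- length(feature)
  fc <- 2^log2fc
  det <- data.frame(feature = feature, class = class,
                    mean_case = fc, mean_control = 1, fc = fc,
                    log2fc = log2fc, p = p, q = q,
                    direction = "ns",
                    max_group_signal = rep_len(max_group_signal, n),
                    passes_de = FALSE, passes_candidate = FALSE,
                    stringsAsFactors = FALSE)
  det <- call_de(det)$table
  if (!is.null(direction)) det$direction <- direction
  if (!is.null(passes_de)) det$passes_de <- passes_de
  det$passes_candidate <- if (is.null(passes_candidate)) det$passes_de
                          else passes_candidate
  det
}

# Small simulation config for fast tests.
tiny_config <- function(seed = 42, ...) {
  defaults <- list(seed = seed, n_case = 6L, n_control = 6L, n_mirna = 8L,
                   n_lncrna = 10L, n_mrna = 14L, frac_de = 0.4,
                   n_triads = 3L, utr_length = 200L, lnc_length = 260L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}
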
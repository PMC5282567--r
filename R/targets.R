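# Candidate regulator-target pairs: canonical miRNA seed-site scanning,
# ingestion of precomputed interaction tables, genomic cis proximity, and
# co-expression (trans) pairing.

PAIR_COLUMNS <- c("source", "source_class", "target", "target_class",
                  "evidence", "score")

empty_pairs <- function() {
  data.frame(source = character(0), source_class = character(0),
             target = character(0), target_class = character(0),
             evidence = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

as_seq_string <- function(x, what) {
  if (inherits(x, "XString") || inherits(x, "XStringSet"))
    x <- as.character(x)
  if (!is_string(x)) stopf("'%s' must be a single sequence string", what)
  normalize_rna(x, what)
}

#' Scan a transcript for canonical miRNA seed sites
#'
#' Classifies target sites by seed complementarity on the target's 5'->3'
#' strand (Watson-Crick only, no G:U wobble).  With the miRNA seed being
#' positions 2--8 (1-based on the miRNA):
#' * `8mer`: reverse complement of positions 2--8 followed by A;
#' * `7mer-m8`: reverse complement of positions 2--8;
#' * `7mer-A1`: reverse complement of positions 2--7 followed by A;
#' * `6mer`: reverse complement of positions 2--7.
#' Each occurrence of the 6mer core is reported once, at the strongest type
#' it supports (8mer > 7mer-m8 > 7mer-A1 > 6mer).  Intervals are 0-based
#' half-open on the target.  T is accepted and treated as U.
#'
#' @param mirna mature miRNA sequence (>= 16 nt), character or
#'   [Biostrings::RNAString].
#' @param transcript target sequence (>= 30 nt).
#' @param mirna_id,target_id ids used in the output.
#' @return Data frame with columns `mirna`, `target`, `type`, `start`,
#'   `end`, ordered by `start`.
#' @export
find_seed_matches <- function(mirna, transcript, mirna_id = "mirna",
                              target_id = "target") {
  m <- as_seq_string(mirna, "mirna")
  tg <- as_seq_string(transcript, "transcript")
  if (nchar(m) < 16) stopf("miRNA must be at least 16 nt")
  if (nchar(tg) < 30) stopf("transcript must be at least 30 nt")
  core6 <- revcomp_rna(substr(m, 2, 7))
  m8_comp <- unname(RNA_COMPLEMENT[substr(m, 8, 8)])
  hits <- find_all_occurrences(tg, core6)
  if (!length(hits))
    return(data.frame(mirna = character(0), target = character(0),
                      type = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  n <- nchar(tg)
  has_m8 <- hits > 1L & substr(rep(tg, length(hits)), hits - 1L, hits - 1L) == m8_comp
  a1_pos <- hits + 6L
  has_a1 <- a1_pos <= n & substring(tg, a1_pos, a1_pos) == "A"
  type <- ifelse(has_m8 & has_a1, "8mer",
          ifelse(has_m8, "7mer-m8",
          ifelse(has_a1, "7mer-A1", "6mer")))
  start0 <- ifelse(has_m8, hits - 2L, hits - 1L)
  end0 <- ifelse(has_a1, hits + 6L, hits + 5L)
  out <- data.frame(mirna = mirna_id, target = target_id, type = type,
                    start = as.integer(start0), end = as.integer(end0),
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Scan many miRNAs against many transcripts
#'
#' @param mirnas named character vector or [Biostrings::RNAStringSet] of
#'   mature miRNA sequences.
#' @param transcripts named character vector or RNAStringSet of targets.
#' @param min_type weakest site type to keep (default `"7mer-m8"`, i.e.
#'   7mer-m8 and 8mer sites only).
#' @return `scan_targets`: all retained [find_seed_matches()] rows bound
#'   together; `seed_pairs`: one `InteractionPair` row per (miRNA, target)
#'   with at least one retained site, `evidence = "seed"`, score = site
#'   count.
#' @export
scan_targets <- function(mirnas, transcripts,
                         min_type = c("7mer-m8", "8mer", "7mer-A1", "6mer")) {
  min_type <- match.arg(min_type)
  strength <- c("6mer" = 1, "7mer-A1" = 2, "7mer-m8" = 3, "8mer" = 4)
  if (inherits(mirnas, "XStringSet")) mirnas <- as.character(mirnas)
  if (inherits(transcripts, "XStringSet")) transcripts <- as.character(transcripts)
  if (is.null(names(mirnas)) || is.null(names(transcripts)))
    stopf("sequences must be named")
  res <- vector("list", length(mirnas) * length(transcripts))
  k <- 0L
  for (mi in names(mirnas)) {
    for (ti in names(transcripts)) {
      hits <- find_seed_matches(mirnas[[mi]], transcripts[[ti]], mi, ti)
      hits <- hits[strength[hits$type] >= strength[min_type], , drop = FALSE]
      if (nrow(hits)) { k <- k + 1L; res[[k]] <- hits }
    }
  }
  if (k == 0L)
    return(data.frame(mirna = character(0), target = character(0),
                      type = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, res[seq_len(k)])
}

#' @rdname scan_targets
#' @param target_class class recorded for the targets (`"mrna"` or
#'   `"lncrna"`).
#' @export
seed_pairs <- function(mirnas, transcripts, target_class = c("mrna", "lncrna"),
                       min_type = "7mer-m8") {
  target_class <- match.arg(target_class)
  sites <- scan_targets(mirnas, transcripts, min_type)
  if (!nrow(sites)) return(empty_pairs())
  key <- paste(sites$mirna, sites$target, sep = "\r")
  counts <- table(key)
  parts <- do.call(rbind, strsplit(names(counts), "\r", fixed = TRUE))
  out <- data.frame(source = parts[, 1], source_class = "mirna",
                    target = parts[, 2], target_class = target_class,
                    evidence = "seed", score = as.numeric(counts),
                    stringsAsFactors = FALSE)
  out[order_c(out$source, out$target), , drop = FALSE]
}

#' Load a precomputed interaction table
#'
#' TSV with columns `source`, `source_class`, `target`, `target_class`,
#' `score` (e.g. an export from an external target database).  Rows are
#' validated (classes among miRNA/lncRNA/mRNA, source class a regulator,
#' no self-pairs, numeric score) and malformed rows are reported with their
#' line numbers; duplicates collapse to one pair.
#'
#' @param path TSV path.
#' @return An `InteractionPair` data frame with `evidence = "table"`.
#' @export
load_interaction_table <- function(path) {
  df <- read_tsv(path)
  needed <- c("source", "source_class", "target", "target_class", "score")
  if (!all(needed %in% names(df)))
    stopf("interaction table must have columns: %s", paste(needed, collapse = ", "))
  if (nrow(df) == 0) return(empty_pairs())
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  problems <- character(0)
  classes <- c("mirna", "lncrna", "mrna")
  bad_src <- !(tolower(df$source_class) %in% c("mirna", "lncrna"))
  bad_tgt <- !(tolower(df$target_class) %in% classes)
  self <- df$source == df$target
  bad_score <- !is.finite(suppressWarnings(as.numeric(df$score)))
  if (any(bad_src))
    problems <- c(problems, sprintf("line %d: source_class must be mirna or lncrna",
                                    line[bad_src]))
  if (any(bad_tgt))
    problems <- c(problems, sprintf("line %d: unknown target_class", line[bad_tgt]))
  if (any(self))
    problems <- c(problems, sprintf("line %d: self-pair", line[self]))
  if (any(bad_score))
    problems <- c(problems, sprintf("line %d: non-numeric score", line[bad_score]))
  if (length(problems))
    stopf("malformed interaction table:\n%s", paste(problems, collapse = "\n"))
  out <- data.frame(source = df$source, source_class = tolower(df$source_class),
                    target = df$target, target_class = tolower(df$target_class),
                    evidence = "table", score = as.numeric(df$score),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("source", "target", "evidence")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

loci_to_df <- function(gr, what) {
  if (inherits(gr, "GRanges")) {
    if (is.null(names(gr))) stopf("'%s' GRanges must be named by feature id", what)
    data.frame(id = names(gr),
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("id", "chrom", "start", "end") %in% names(gr)))
    as.data.frame(gr, stringsAsFactors = FALSE)
  }
}

#' Pair lncRNA and mRNA loci by genomic proximity (cis)
#'
#' Two loci pair when they lie on the same chromosome with an interval gap
#' of at most `window` nucleotides (gap 0 for overlapping or adjacent
#' intervals); strand is ignored.  Symmetric in its arguments.
#'
#' @param lnc_loci,mrna_loci named [GenomicRanges::GRanges] (or data frames
#'   with `id`, `chrom`, `start`, `end`, 0-based half-open).
#' @param window maximum gap in nucleotides (default 100 kb).
#' @return An `InteractionPair` data frame with `evidence = "cis"` and
#'   score = gap in nucleotides.
#' @export
cis_pairs <- function(lnc_loci, mrna_loci, window = 1e5) {
  assert_scalar_number(window, "window", 0, Inf)
  l <- loci_to_df(lnc_loci, "lnc_loci")
  g <- loci_to_df(mrna_loci, "mrna_loci")
  if (any(l$start >= l$end) || any(g$start >= g$end))
    stopf("loci must satisfy start < end")
  out <- empty_pairs()
  for (chrom in intersect(unique(l$chrom), unique(g$chrom))) {
    li <- l[l$chrom == chrom, , drop = FALSE]
    gi <- g[g$chrom == chrom, , drop = FALSE]
    idx <- expand.grid(a = seq_len(nrow(li)), b = seq_len(nrow(gi)))
    gap <- pmax(0, pmax(li$start[idx$a], gi$start[idx$b]) -
                   pmin(li$end[idx$a], gi$end[idx$b]))
    keep <- gap <= window & li$id[idx$a] != gi$id[idx$b]
    if (any(keep))
      out <- rbind(out, data.frame(
        source = li$id[idx$a[keep]], source_class = "lncrna",
        target = gi$id[idx$b[keep]], target_class = "mrna",
        evidence = "cis", score = as.numeric(gap[keep]),
        stringsAsFactors = FALSE))
  }
  out <- out[order_c(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair lncRNAs and mRNAs by co-expression (trans)
#'
#' Computes the correlation of each lncRNA-mRNA pair across shared samples
#' and keeps pairs with `|r| >= r_threshold`.
#'
#' @param lnc_expr,mrna_expr `expr_matrix` objects sharing sample ids
#'   (at least 3 shared samples required).
#' @param r_threshold absolute-correlation threshold (default 0.9).
#' @param method `"pearson"` or `"spearman"`.
#' @return An `InteractionPair` data frame with `evidence = "trans"` and
#'   score = the signed correlation.
#' @export
trans_pairs <- function(lnc_expr, mrna_expr, r_threshold = 0.9,
                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(lnc_expr, "expr_matrix"), inherits(mrna_expr, "expr_matrix"))
  assert_scalar_number(r_threshold, "r_threshold", 0, 1)
  shared <- intersect(colnames(lnc_expr$values), colnames(mrna_expr$values))
  if (length(shared) < 3) stopf("at least 3 shared samples required")
  r <- cor(t(lnc_expr$values[, shared, drop = FALSE]),
           t(mrna_expr$values[, shared, drop = FALSE]), method = method)
  hit <- which(abs(r) >= r_threshold & is.finite(r), arr.ind = TRUE)
  if (!nrow(hit)) return(empty_pairs())
  out <- data.frame(source = rownames(r)[hit[, 1]], source_class = "lncrna",
                    target = colnames(r)[hit[, 2]], target_class = "mrna",
                    evidence = "trans", score = r[hit],
                    stringsAsFactors = FALSE)
  out <- out[out$source != out$target, , drop = FALSE]
  out <- out[order_c(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write interaction pairs as TSV
#' @param pairs an `InteractionPair` data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  stopifnot(all(PAIR_COLUMNS %in% names(pairs)))
  write_tsv(pairs[, PAIR_COLUMNS], path)
  invisible(path)
}
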
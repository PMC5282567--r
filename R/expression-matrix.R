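#' Feature-by-sample expression matrix with group labels
#'
#' The substrate for differential expression and co-expression analysis:
#' a non-negative numeric matrix (microarray signal intensity or FPKM) with
#' unique feature ids in rows, unique sample ids in columns, a case/control
#' label per sample, and the feature class (miRNA, lncRNA or mRNA).  lncRNA
#' matrices may additionally carry a per-feature category (antisense,
#' intergenic, intronic, processed_transcript).
#'
#' @param values numeric matrix, features x samples, finite and >= 0, with
#'   rownames (feature ids) and colnames (sample ids).
#' @param groups character/factor of length `ncol(values)` with levels
#'   `"case"` and `"control"`; both groups must be non-empty.
#' @param feature_class one of `"mirna"`, `"lncrna"`, `"mrna"`.
#' @param lnc_category optional character per feature (lncRNA class only).
#'
#' @return An object of class `expr_matrix`: a list with elements
#'   `values`, `groups` (named character), `feature_class`, `lnc_category`.
#' @export
expression_matrix <- function(values, groups, feature_class = c("mirna", "lncrna", "mrna"),
                              lnc_category = NULL) {
  feature_class <- match.arg(feature_class)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("'values' must have feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values))) stopf("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stopf("duplicate sample ids")
  if (any(!is.finite(values)) || any(values < 0))
    stopf("expression values must be finite and non-negative")
  groups <- as.character(groups)
  if (length(groups) != ncol(values))
    stopf("'groups' must have one label per sample")
  if (!all(groups %in% c("case", "control")))
    stopf("group labels must be 'case' or 'control'")
  if (!all(c("case", "control") %in% groups))
    stopf("both 'case' and 'control' groups must be non-empty")
  names(groups) <- colnames(values)
  if (!is.null(lnc_category)) {
    if (feature_class != "lncrna")
      stopf("'lnc_category' is only meaningful for lncRNA matrices")
    if (length(lnc_category) != nrow(values))
      stopf("'lnc_category' must have one entry per feature")
    cats <- c("antisense", "intergenic", "intronic", "processed_transcript")
    if (!all(lnc_category %in% cats))
      stopf("unknown lncRNA category; expected one of %s",
            paste(cats, collapse = ", "))
    names(lnc_category) <- rownames(values)
  }
  structure(list(values = values, groups = groups,
                 feature_class = feature_class,
                 lnc_category = lnc_category),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s: %d features x %d samples (%d case, %d control)\n",
              x$feature_class, nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

case_values <- function(em) em$values[, em$groups == "case", drop = FALSE]
control_values <- function(em) em$values[, em$groups == "control", drop = FALSE]

#' Compute FPKM from fragment counts
#'
#' Fragments per kilobase of exon per million mapped fragments:
#' `1e9 * count / (effective_length * library_size)`.
#'
#' @param counts integer matrix of fragment counts (features x samples).
#' @param effective_lengths positive lengths in nucleotides, one per feature.
#' @param library_sizes positive mapped-fragment totals, one per sample.
#' @param groups,feature_class optional; when `groups` is given the result is
#'   wrapped in an [expression_matrix()].
#' @return A numeric FPKM matrix, or an `expr_matrix` when `groups` is given.
#' @export
fpkm <- function(counts, effective_lengths, library_sizes, groups = NULL,
                 feature_class = "mrna") {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stopf("counts must be finite and non-negative")
  if (length(effective_lengths) != nrow(counts))
    stopf("one effective length per feature required")
  if (length(library_sizes) != ncol(counts))
    stopf("one library size per sample required")
  if (any(!is.finite(effective_lengths)) || any(effective_lengths <= 0))
    stopf("effective lengths must be positive")
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0))
    stopf("library sizes must be positive")
  vals <- 1e9 * sweep(counts / effective_lengths, 2, library_sizes, "/")
  dimnames(vals) <- dimnames(counts)
  if (is.null(groups)) return(vals)
  expression_matrix(vals, groups, feature_class)
}

#' Read / write expression matrices as TSV
#'
#' Layout: header row of sample ids, first column `feature` holding feature
#' ids, remaining columns numeric.  Group labels travel in a two-column
#' companion table (`sample`, `group`).
#'
#' @param em an `expr_matrix`.
#' @param path,groups_path file paths.
#' @param feature_class,lnc_category passed to [expression_matrix()] on read.
#' @return `write_expression` returns `path` invisibly; `read_expression`
#'   returns an `expr_matrix`.
#' @export
write_expression <- function(em, path, groups_path = NULL) {
  df <- data.frame(feature = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  if (!is.null(groups_path))
    write_tsv(data.frame(sample = names(em$groups), group = unname(em$groups),
                         stringsAsFactors = FALSE), groups_path)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path, groups_path, feature_class = "mrna",
                            lnc_category = NULL) {
  df <- read_tsv(path)
  if (names(df)[1] != "feature") stopf("first column must be 'feature'")
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$feature
  gr <- read_tsv(groups_path)
  if (!all(c("sample", "group") %in% names(gr)))
    stopf("groups table must have columns 'sample' and 'group'")
  groups <- setNames(gr$group, gr$sample)[colnames(vals)]
  if (anyNA(groups)) stopf("groups table is missing some samples")
  expression_matrix(vals, groups, feature_class, lnc_category)
}
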
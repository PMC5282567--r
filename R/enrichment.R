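# Hypergeometric over-representation of gene sets (GO/KEGG-style GMT
# collections) with namespace-wise BH correction and rich factors.

#' Gene-set collection
#'
#' Terms (named list of member gene ids) with a gene universe and an
#' optional namespace per term (e.g. BP/MF/CC/pathway).  Members are
#' intersected with the universe on construction; empty terms are dropped.
#'
#' @param sets named list of character vectors of gene ids.
#' @param universe gene universe; defaults to the union of all members.
#' @param namespace optional named character vector, one entry per term
#'   (default: a single `"default"` namespace).
#' @return A list of class `gene_set_collection` with elements `sets`,
#'   `universe`, `namespace`.
#' @export
gene_set_collection <- function(sets, universe = NULL, namespace = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("'sets' must be a named list of gene-id vectors")
  if (anyDuplicated(names(sets))) stopf("duplicate term ids")
  universe <- unique(universe %||% unlist(sets, use.names = FALSE))
  sets <- lapply(sets, function(s) unique(intersect(s, universe)))
  keep <- lengths(sets) > 0
  sets <- sets[keep]
  if (is.null(namespace)) {
    namespace <- setNames(rep("default", length(sets)), names(sets))
  } else {
    if (is.null(names(namespace)) || !all(names(sets) %in% names(namespace)))
      stopf("'namespace' must be named with one entry per term")
    namespace <- namespace[names(sets)]
  }
  structure(list(sets = sets, universe = universe, namespace = namespace),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d terms over %d genes (%d namespace(s))\n",
              length(x$sets), length(x$universe),
              length(unique(x$namespace))))
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' Reading delegates to [fgsea::gmtPathways()] (the description column of
#' the GMT is not retained; the term id doubles as its name).  Writing
#' emits `term<TAB>description<TAB>member...` lines.
#'
#' @param path GMT path.
#' @param universe,namespace passed to [gene_set_collection()].
#' @return `read_gmt` returns a [gene_set_collection()]; `write_gmt`
#'   returns `path` invisibly.
#' @export
read_gmt <- function(path, universe = NULL, namespace = NULL) {
  sets <- fgsea::gmtPathways(path)
  gene_set_collection(sets, universe = universe, namespace = namespace)
}

#' @rdname read_gmt
#' @param collection a [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(tid)
    paste(c(tid, unname(collection$namespace[tid]), collection$sets[[tid]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric upper-tail probability
#'
#' Probability of drawing at least `k` members of a `K`-gene term when
#' sampling `n` genes without replacement from a universe of `N`:
#' `sum_{i=k}^{min(K,n)} C(K,i) C(N-K, n-i) / C(N,n)`, evaluated in log
#' space for stability.
#'
#' @param N universe size.
#' @param K term size.
#' @param n query size.
#' @param k overlap.
#' @return The upper-tail p-value (1 when `k = 0`).
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  N <- assert_count(N, "N", min = 0L)
  K <- assert_count(K, "K", min = 0L)
  n <- assert_count(n, "n", min = 0L)
  k <- assert_count(k, "k", min = 0L)
  if (K > N || n > N) stopf("K and n must not exceed N")
  if (k > min(K, n)) stopf("k must not exceed min(K, n)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' Tests every term of at least `min_term_size` (post-intersection)
#' members for enrichment in the query set, with BH correction applied
#' within each namespace (mirroring the convention of reporting the GO
#' divisions separately).  The rich factor is `k / K`: the fraction of the
#' term covered by the query.
#'
#' @param query character vector of gene ids; genes outside the universe
#'   are dropped (their count is reported via a message) and the query
#'   must be non-empty afterwards.
#' @param collection a [gene_set_collection()].
#' @param min_term_size smallest term tested (default 3).
#' @param q_threshold threshold stored in the `significant` column.
#' @return Data frame with one row per tested term: `term`, `namespace`,
#'   `N`, `K`, `n`, `k`, `p`, `q`, `rich_factor`, `significant`; ranked by
#'   `q`, then `p`, then descending `rich_factor`.
#' @export
enrich <- function(query, collection, min_term_size = 3L, q_threshold = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  min_term_size <- assert_count(min_term_size, "min_term_size")
  query <- unique(query)
  dropped <- sum(!(query %in% collection$universe))
  if (dropped > 0)
    message(sprintf("%d query gene(s) outside the universe dropped", dropped))
  query <- intersect(query, collection$universe)
  if (!length(query)) stopf("query is empty after intersection with the universe")
  sets <- collection$sets[lengths(collection$sets) >= min_term_size]
  if (!length(sets)) stopf("no terms of size >= %d to test", min_term_size)
  N <- length(collection$universe)
  n <- length(query)
  K <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, query)), integer(1))
  p <- vapply(seq_along(sets), function(i)
    hypergeom_upper_tail(N, K[[i]], n, k[[i]]), numeric(1))
  ns <- collection$namespace[names(sets)]
  q <- numeric(length(p))
  for (nsp in unique(ns)) q[ns == nsp] <- bh_adjust(p[ns == nsp])
  out <- data.frame(term = names(sets), namespace = unname(ns),
                    N = N, K = unname(K), n = n, k = unname(k),
                    p = p, q = q, rich_factor = unname(k / K),
                    significant = q < q_threshold, stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, -out$rich_factor, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
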
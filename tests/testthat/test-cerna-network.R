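# Network assembly: the opposite-direction filter, pairwise networks,
# tripartite integration with triads and venn partitions, hubs, export.

pair_row <- function(source, s_class, target, t_class, evidence = "seed",
                     score = 1) {
  data.frame(source = source, source_class = s_class, target = target,
             target_class = t_class, evidence = evidence, score = score,
             stringsAsFactors = FALSE)
}

two_class_tables <- function() {
  list(
    mirna = make_de_table(c("m_up", "m_down", "m_ns"), "mirna",
                          log2fc = c(2, -2, 0.1),
                          p = c(0.001, 0.001, 0.9), q = c(0.01, 0.01, 0.9)),
    mrna = make_de_table(c("g_up", "g_down", "g_ns"), "mrna",
                         log2fc = c(2, -2, 0.1),
                         p = c(0.001, 0.001, 0.9), q = c(0.01, 0.01, 0.9)),
    lncrna = make_de_table(c("l_up", "l_down"), "lncrna",
                           log2fc = c(2, -2),
                           p = c(0.001, 0.001), q = c(0.01, 0.01)))
}

test_that("anticorrelation filter keeps only opposite-direction DE pairs", {
  det <- two_class_tables()
  pairs <- rbind(
    pair_row("m_up", "mirna", "g_down", "mrna"),   # retained
    pair_row("m_up", "mirna", "g_up", "mrna"),     # same direction
    pair_row("m_down", "mirna", "g_up", "mrna"),   # retained
    pair_row("m_up", "mirna", "g_ns", "mrna"),     # target not DE
    pair_row("m_ns", "mirna", "g_down", "mrna"))   # regulator not DE
  edges <- anticorrelation_filter(pairs, det)
  expect_identical(nrow(edges), 2L)
  expect_setequal(paste(edges$regulator, edges$target),
                  c("m_up g_down", "m_down g_up"))
  expect_true(all(edges$regulator_direction != edges$target_direction))
  # missing endpoint is an error
  expect_error(
    anticorrelation_filter(pair_row("m_up", "mirna", "nope", "mrna"), det),
    "missing")
  # no DE features at all gives an empty edge list
  det_null <- det
  for (cl in names(det_null)) {
    det_null[[cl]]$passes_de <- FALSE
    det_null[[cl]]$direction <- "ns"
  }
  expect_identical(nrow(anticorrelation_filter(pairs, det_null)), 0L)
})

test_that("the sample-level correlation gate removes positively coupled pairs", {
  det <- two_class_tables()
  n <- 10
  v <- seq_len(n)
  vals_m <- rbind(m_up = v, m_down = rev(v))
  vals_g <- rbind(g_down = rev(v), g_up = v)
  colnames(vals_m) <- colnames(vals_g) <- paste0("s", 1:n)
  groups <- rep(c("case", "control"), each = 5)
  expr <- list(mirna = expression_matrix(vals_m, groups, "mirna"),
               mrna = expression_matrix(vals_g, groups, "mrna"))
  pairs <- rbind(pair_row("m_up", "mirna", "g_down", "mrna"),   # r = -1
                 pair_row("m_down", "mirna", "g_up", "mrna"))   # r = -1
  pairs_pos <- pair_row("m_up", "mirna", "g_up", "mrna")        # r = +1 (also same dir)
  edges <- anticorrelation_filter(pairs, det, require_r = 0.9, expr = expr)
  expect_identical(nrow(edges), 2L)
  # a pair anticorrelated in direction but positively coupled in samples drops
  expr2 <- expr
  expr2$mrna$values["g_down", ] <- v  # now r(m_up, g_down) = +1
  edges2 <- anticorrelation_filter(pairs, det, require_r = 0.9, expr = expr2)
  expect_identical(paste(edges2$regulator, edges2$target), "m_down g_up")
})

test_that("pairwise networks compute degrees and reject bad input", {
  det <- two_class_tables()
  pairs <- rbind(
    pair_row("m_up", "mirna", "g_down", "mrna"),
    pair_row("m_up", "mirna", "g_down", "mrna", evidence = "table"),
    pair_row("m_down", "mirna", "g_up", "mrna"))
  edges <- anticorrelation_filter(pairs, det)
  net <- build_pair_network(edges, "mirna_mrna")
  expect_identical(nrow(net$edges), 3L)  # two evidence classes kept distinct
  expect_identical(net$nodes$degree[net$nodes$id == "m_up"], 2L)
  expect_identical(sum(net$nodes$degree), 2L * nrow(net$edges))
  expect_identical(net$nodes$id, sort(net$nodes$id, method = "radix"))
  # fully crossed 2x2 toy with valid signs: 4 edges, 4 nodes
  det2 <- list(
    mirna = make_de_table(c("mA", "mB"), "mirna", c(2, 2),
                          p = c(0.001, 0.001), q = c(0.01, 0.01)),
    mrna = make_de_table(c("gA", "gB"), "mrna", c(-2, -2),
                         p = c(0.001, 0.001), q = c(0.01, 0.01)))
  cross <- do.call(rbind, lapply(c("mA", "mB"), function(m)
    rbind(pair_row(m, "mirna", "gA", "mrna"), pair_row(m, "mirna", "gB", "mrna"))))
  net2 <- build_pair_network(anticorrelation_filter(cross, det2), "mirna_mrna")
  expect_identical(nrow(net2$edges), 4L)
  expect_identical(nrow(net2$nodes), 4L)
  # empty edges give an empty network
  net0 <- build_pair_network(anticorrelation_filter(pairs[0, ], det), "mirna_mrna")
  expect_identical(nrow(net0$nodes), 0L)
  # mixed-kind edges are rejected
  expect_error(build_pair_network(edges, "mirna_lncrna"), "classes")
})

integrate_from_pairs <- function(mm, ml, lm, det) {
  integrate_tripartite(
    build_pair_network(anticorrelation_filter(mm, det), "mirna_mrna"),
    build_pair_network(anticorrelation_filter(ml, det), "mirna_lncrna"),
    build_pair_network(anticorrelation_filter(lm, det), "lncrna_mrna"))
}

test_that("tripartite integration enumerates triads correctly", {
  det <- two_class_tables()
  mm <- rbind(pair_row("m_up", "mirna", "g_down", "mrna"),
              pair_row("m_down", "mirna", "g_up", "mrna"))
  ml <- pair_row("m_up", "mirna", "l_down", "lncrna")
  lm <- pair_row("l_down", "lncrna", "g_up", "mrna")
  tri <- integrate_from_pairs(mm, ml, lm, det)
  triads <- tri$lncrna_centered$summary$triads
  # only m_up has both an mRNA target and an lncRNA partner
  expect_identical(nrow(triads), 1L)
  expect_identical(triads$lncrna, "l_down")
  expect_identical(triads$mirna, "m_up")
  expect_identical(triads$mrna, "g_down")
  expect_identical(triads$mirna_direction, "up")
  expect_identical(triads$partner_direction, "down")
  # miRNA-centered network drops m_down (no lncRNA partner)
  expect_false("m_down" %in% tri$mirna_centered$network$nodes$id)
  expect_identical(nrow(tri$mirna_centered$network$nodes), 3L)
  expect_identical(nrow(tri$mirna_centered$network$edges), 2L)
  # venn counts sum to the union
  for (vn in list(tri$mirna_centered$summary$venn,
                  tri$lncrna_centered$summary$venn))
    expect_identical(vn$shared + vn$first_only + vn$second_only, vn$union)
})

test_that("triad enumeration equals the brute-force triple loop", {
  set.seed(77)
  for (rep in 1:20) {
    n_m <- sample(3:8, 1); n_l <- sample(3:8, 1); n_g <- sample(3:8, 1)
    m_ids <- paste0("m", 1:n_m); l_ids <- paste0("l", 1:n_l)
    g_ids <- paste0("g", 1:n_g)
    m_dir <- sample(c("up", "down"), n_m, replace = TRUE)
    det <- list(
      mirna = make_de_table(m_ids, "mirna", ifelse(m_dir == "up", 2, -2),
                            p = 0.001, q = 0.01),
      lncrna = make_de_table(l_ids, "lncrna",
                             sample(c(2, -2), n_l, replace = TRUE),
                             p = 0.001, q = 0.01),
      mrna = make_de_table(g_ids, "mrna",
                           sample(c(2, -2), n_g, replace = TRUE),
                           p = 0.001, q = 0.01))
    rand_pairs <- function(src, s_class, tgt, t_class, n_pairs) {
      grid <- expand.grid(s = src, t = tgt, stringsAsFactors = FALSE)
      grid <- grid[sample(nrow(grid), min(n_pairs, nrow(grid))), ]
      pair_row(grid$s, s_class, grid$t, t_class)
    }
    mm <- rand_pairs(m_ids, "mirna", g_ids, "mrna", 12)
    ml <- rand_pairs(m_ids, "mirna", l_ids, "lncrna", 10)
    lm <- rand_pairs(l_ids, "lncrna", g_ids, "mrna", 8)
    tri <- integrate_from_pairs(mm, ml, lm, det)
    got <- tri$lncrna_centered$summary$triads[, c("lncrna", "mirna", "mrna")]
    mm_e <- anticorrelation_filter(mm, det)
    ml_e <- anticorrelation_filter(ml, det)
    want <- brute_force_triads(mm_e, ml_e)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("direction conflicts across inputs are rejected", {
  det <- two_class_tables()
  det_flip <- det
  det_flip$mirna$direction[det_flip$mirna$feature == "m_up"] <- "down"
  mm <- pair_row("m_up", "mirna", "g_down", "mrna")
  ml <- pair_row("m_up", "mirna", "l_up", "lncrna")
  net_mm <- build_pair_network(anticorrelation_filter(mm, det), "mirna_mrna")
  net_ml <- build_pair_network(anticorrelation_filter(ml, det_flip), "mirna_lncrna")
  net_lm <- build_pair_network(
    anticorrelation_filter(pair_row("l_up", "lncrna", "g_down", "mrna"), det),
    "lncrna_mrna")
  expect_error(integrate_tripartite(net_mm, net_ml, net_lm), "conflict")
})

test_that("hub ranking uses degree with lexicographic tie-break", {
  det2 <- list(
    mirna = make_de_table(c("hub", "zz", "aa"), "mirna", c(2, 2, 2),
                          p = 0.001, q = 0.01),
    mrna = make_de_table(c("g1", "g2", "g3"), "mrna", c(-2, -2, -2),
                         p = 0.001, q = 0.01))
  star <- do.call(rbind, lapply(c("g1", "g2", "g3"), function(g)
    pair_row("hub", "mirna", g, "mrna")))
  net <- build_pair_network(anticorrelation_filter(star, det2), "mirna_mrna")
  expect_identical(hub_nodes(net, 1)$id, "hub")
  # all-degree-one graph ranks lexicographically
  flat <- rbind(pair_row("zz", "mirna", "g1", "mrna"),
                pair_row("aa", "mirna", "g2", "mrna"))
  net_flat <- build_pair_network(anticorrelation_filter(flat, det2), "mirna_mrna")
  expect_identical(hub_nodes(net_flat, 10)$id, c("aa", "g1", "g2", "zz"))
  expect_identical(nrow(hub_nodes(net_flat, 100)), 4L)
})

test_that("GraphML and SIF exports round-trip and count edges", {
  det <- two_class_tables()
  pairs <- rbind(pair_row("m_up", "mirna", "g_down", "mrna"),
                 pair_row("m_down", "mirna", "g_up", "mrna"))
  net <- build_pair_network(anticorrelation_filter(pairs, det), "mirna_mrna")
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, "graphml", gml)
  back <- read_network(gml)
  expect_identical(back$nodes, net$nodes)
  expect_identical(back$edges$regulator, net$edges$regulator)
  expect_identical(back$edges$evidence, net$edges$evidence)
  expect_identical(back$kind, net$kind)
  # write -> read -> write is byte-identical
  gml2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(back, "graphml", gml2)
  expect_identical(readLines(gml), readLines(gml2))
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, "sif", sif)
  lines <- readLines(sif)
  expect_length(lines, nrow(net$edges))
  expect_true(all(grepl("\trepresses\t", lines)))
  # empty network exports a valid document
  net0 <- build_pair_network(anticorrelation_filter(pairs[0, ], det), "mirna_mrna")
  gml0 <- withr::local_tempfile(fileext = ".graphml")
  export_network(net0, "graphml", gml0)
  expect_identical(nrow(read_network(gml0)$nodes), 0L)
})

test_that("a truth-free simulation yields zero triads", {
  cfg <- tiny_config(seed = 29, frac_de = 0, n_triads = 0L)
  sim <- generate_expression(cfg)
  seqs <- generate_sequences(cfg, sim$truth)
  det <- list(mirna = de_table(sim$mirna),
              lncrna = de_table(sim$lncrna),
              mrna = de_table(sim$mrna))
  pairs <- rbind(seed_pairs(seqs$mirna, seqs$utr3, "mrna"),
                 seed_pairs(seqs$mirna, seqs$lncrna, "lncrna"))
  edges <- anticorrelation_filter(pairs, det)
  net_mm <- build_pair_network(
    edges[edges$target_class == "mrna", , drop = FALSE], "mirna_mrna")
  net_ml <- build_pair_network(
    edges[edges$target_class == "lncrna", , drop = FALSE], "mirna_lncrna")
  net_lm <- build_pair_network(
    edges[edges$regulator_class == "lncrna", , drop = FALSE], "lncrna_mrna")
  tri <- integrate_tripartite(net_mm, net_ml, net_lm)
  expect_identical(nrow(tri$lncrna_centered$summary$triads), 0L)
})
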
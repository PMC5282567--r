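# Target prediction: seed-site scanning, table ingestion, cis and trans
# pairing.

test_that("the constructed 8mer example is found at [3, 11)", {
  hits <- find_seed_matches("UACGGAUGCAUAAGCUU", "GGGCATCCGTAGGGCATGCATGCATGCATG",
                            "mir", "tgt")
  eight <- hits[hits$type == "8mer", ]
  expect_identical(nrow(eight), 1L)
  expect_identical(eight$start, 3L)
  expect_identical(eight$end, 11L)
})

test_that("a homopolymer target yields no strong sites", {
  hits <- find_seed_matches("UACGGAUGCAUAAGCUU", strrep("A", 60))
  expect_false(any(hits$type %in% c("7mer-m8", "8mer")))
})

test_that("scanner agrees with the naive character-walk oracle", {
  set.seed(7)
  for (i in 1:300) {
    m <- rand_rna(sample(16:24, 1))
    tg <- rand_rna(sample(30:120, 1))
    got <- find_seed_matches(m, tg)
    want <- naive_seed_scan(m, tg)
    expect_identical(nrow(got), nrow(want))
    if (nrow(got)) {
      ord <- order(want$start)
      expect_identical(got$type, want$type[ord])
      expect_identical(got$start, as.integer(want$start[ord]))
      expect_identical(got$end, as.integer(want$end[ord]))
    }
  }
})

test_that("site counts are non-increasing under target truncation", {
  set.seed(8)
  for (i in 1:20) {
    m <- rand_rna(20)
    tg <- rand_rna(100)
    full <- nrow(find_seed_matches(m, tg))
    trunc <- nrow(find_seed_matches(m, substr(tg, 1, 60)))
    expect_lte(trunc, full)
  }
})

test_that("alphabet handling maps T to U and rejects junk", {
  dna <- find_seed_matches("TACGGATGCATAAGCTT", "GGGCATCCGTAGGGCATGCATGCATGCATG")
  rna <- find_seed_matches("UACGGAUGCAUAAGCUU", "GGGCATCCGTAGGGCATGCATGCATGCATG")
  expect_identical(dna, rna)
  expect_error(find_seed_matches("UACGGAUGCAUAAGCNN", strrep("A", 40)), "A/C/G/U")
  expect_error(find_seed_matches("UACGG", strrep("A", 40)), "16 nt")
  expect_error(find_seed_matches("UACGGAUGCAUAAGCUU", "ACGU"), "30 nt")
})

test_that("interaction tables are validated, deduplicated and line-numbered", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\tsource_class\ttarget\ttarget_class\tscore",
               "miR-1\tmirna\tGENE1\tmrna\t2",
               "miR-1\tmirna\tGENE1\tmrna\t2",
               "lnc-1\tlncrna\tGENE2\tmrna\t0.5"), path)
  pairs <- load_interaction_table(path)
  expect_identical(nrow(pairs), 2L)
  expect_identical(unique(pairs$evidence), "table")
  # self pair rejected with its line number
  writeLines(c("source\tsource_class\ttarget\ttarget_class\tscore",
               "GENE1\tlncrna\tGENE1\tmrna\t1"), path)
  expect_error(load_interaction_table(path), "line 2.*self-pair")
  # mRNA can not be a regulator
  writeLines(c("source\tsource_class\ttarget\ttarget_class\tscore",
               "GENE1\tmrna\tmiR-1\tmirna\t1"), path)
  expect_error(load_interaction_table(path), "source_class")
  # empty file gives an empty pair list
  writeLines("source\tsource_class\ttarget\ttarget_class\tscore", path)
  expect_identical(nrow(load_interaction_table(path)), 0L)
})

test_that("cis pairing respects the window boundary exactly", {
  loci <- function(id, chrom, start, end)
    data.frame(id = id, chrom = chrom, start = start, end = end,
               stringsAsFactors = FALSE)
  lnc <- loci(c("l1", "l2", "l3"), c("chr1", "chr1", "chr2"),
              c(0, 0, 0), c(1000, 1000, 1000))
  # overlap, exact-window gap, window+1 gap
  g <- loci(c("g1", "g2", "g3"),
            c("chr1", "chr1", "chr1"),
            c(500, 1000 + 100000, 1000 + 100001),
            c(1500, 2000 + 100000, 2000 + 100001))
  pairs <- cis_pairs(lnc, g, window = 100000)
  key <- paste(pairs$source, pairs$target)
  expect_true("l1 g1" %in% key)   # overlapping
  expect_true("l1 g2" %in% key)   # gap == window
  expect_false("l1 g3" %in% key)  # gap == window + 1
  expect_false(any(pairs$source == "l3"))  # different chromosome never pairs
  expect_equal(pairs$score[key == "l1 g1"], 0)
  # symmetric in argument order
  swapped <- cis_pairs(g, lnc, window = 100000)
  expect_setequal(paste(swapped$target, swapped$source), key)
})

test_that("trans pairing thresholds correlation and matches the formula oracle", {
  set.seed(10)
  n <- 12
  base <- rnorm(n)
  lv <- rbind(l1 = base, l2 = rnorm(n))
  gv <- rbind(g1 = base * 2 + 5, g2 = rnorm(n))
  colnames(lv) <- colnames(gv) <- paste0("s", 1:n)
  groups <- rep(c("case", "control"), each = n / 2)
  lnc <- expression_matrix(abs(lv) + 1, groups, "lncrna")
  mrna <- expression_matrix(abs(gv) + 1, groups, "mrna")
  pairs <- trans_pairs(lnc, mrna, r_threshold = 0.99)
  # r computed on the stored (absolute-shifted) values
  naive_r <- function(x, y) {
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in seq_len(nrow(pairs)))
    expect_equal(pairs$score[i],
                 naive_r(lnc$values[pairs$source[i], ],
                         mrna$values[pairs$target[i], ]),
                 tolerance = 1e-12)
  # identical vectors always pair; independent ones at r ~ 0 never do
  lv2 <- rbind(l1 = abs(base) + 1)
  gv2 <- rbind(g1 = abs(base) + 1)
  colnames(lv2) <- colnames(gv2) <- paste0("s", 1:n)
  p2 <- trans_pairs(expression_matrix(lv2, groups, "lncrna"),
                    expression_matrix(gv2, groups, "mrna"), r_threshold = 0.9)
  expect_identical(nrow(p2), 1L)
  expect_equal(p2$score, 1)
  expect_error(trans_pairs(
    expression_matrix(lv2[, 1:2, drop = FALSE], c("case", "control"), "lncrna"),
    expression_matrix(gv2[, 1:2, drop = FALSE], c("case", "control"), "mrna")),
    "3 shared samples")
  # full formula oracle over random pairs
  set.seed(11)
  lv3 <- matrix(abs(rnorm(50 * 10)) + 0.1, 50, 10,
                dimnames = list(paste0("l", 1:50), paste0("s", 1:10)))
  gv3 <- matrix(abs(rnorm(50 * 10)) + 0.1, 50, 10,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
  gr3 <- rep(c("case", "control"), each = 5)
  p3 <- trans_pairs(expression_matrix(lv3, gr3, "lncrna"),
                    expression_matrix(gv3, gr3, "mrna"), r_threshold = 0.6)
  for (i in seq_len(nrow(p3)))
    expect_equal(p3$score[i],
                 naive_r(lv3[p3$source[i], ], gv3[p3$target[i], ]),
                 tolerance = 1e-12)
})

test_that("synthetic planted edges are recovered by the scanner, no extras", {
  cfg <- tiny_config(seed = 19, n_triads = 4L)
  sim <- generate_expression(cfg)
  seqs <- generate_sequences(cfg, sim$truth)
  pairs <- rbind(seed_pairs(seqs$mirna, seqs$utr3, "mrna"),
                 seed_pairs(seqs$mirna, seqs$lncrna, "lncrna"))
  got <- paste(pairs$source, pairs$target)
  planted <- unique(c(paste(sim$truth$triads$mirna, sim$truth$triads$mrna),
                      paste(sim$truth$triads$mirna, sim$truth$triads$lncrna)))
  expect_setequal(got, planted)
})
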
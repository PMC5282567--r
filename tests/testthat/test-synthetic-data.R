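# Synthetic-data generator: determinism, planted effects, sequence/site
# fidelity, annotation geometry, qPCR and clinical structure.

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(seed = 1, frac_de = 1.2), "frac_de")
  expect_error(simulation_config(seed = 1, biomarker_auc = 0.4), "biomarker_auc")
  expect_error(simulation_config(seed = 1, biomarker_auc = 1), "biomarker_auc")
  expect_error(simulation_config(seed = 1, clinical_r = c(lactate = 1.1)),
               "clinical_r")
  expect_error(simulation_config(seed = 1, n_mirna = 0), "n_mirna")
  expect_error(simulation_config(seed = 1, noise_sd = NaN), "noise_sd")
  expect_error(simulation_config(seed = 1, n_mirna = 3, n_triads = 5),
               "n_triads")
})

test_that("identical configs give bit-identical outputs", {
  cfg <- tiny_config(seed = 7)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$expression$mirna$values, b$expression$mirna$values)
  expect_identical(a$expression$mrna$values, b$expression$mrna$values)
  expect_identical(as.character(a$sequences$utr3), as.character(b$sequences$utr3))
  expect_identical(a$qpcr, b$qpcr)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$triads, b$truth$triads)
  # a different seed changes the data
  c <- simulate_dataset(tiny_config(seed = 8))
  expect_false(identical(a$expression$mirna$values, c$expression$mirna$values))
})

test_that("planted effects set the case/control mean ratio", {
  cfg <- tiny_config(seed = 3, noise_sd = 0, frac_de = 0.5,
                     planted_log2fc = 1, n_triads = 0L)
  sim <- generate_expression(cfg)
  de <- sim$truth$de_features$mrna
  up <- names(de)[de == "up"][1]
  em <- sim$mrna
  ratio <- mean(em$values[up, em$groups == "case"]) /
    mean(em$values[up, em$groups == "control"])
  expect_equal(ratio, 2, tolerance = 1e-12)
  down <- names(de)[de == "down"][1]
  ratio_dn <- mean(em$values[down, em$groups == "case"]) /
    mean(em$values[down, em$groups == "control"])
  expect_equal(ratio_dn, 0.5, tolerance = 1e-12)
})

test_that("frac_de = 0 plants nothing and group means differ only by noise", {
  cfg <- tiny_config(seed = 5, frac_de = 0, n_triads = 0L, noise_sd = 0)
  sim <- generate_expression(cfg)
  expect_length(sim$truth$de_features$mrna, 0)
  expect_length(sim$truth$de_features$mirna, 0)
  expect_equal(rowMeans(sim$mrna$values[, sim$mrna$groups == "case"]),
               rowMeans(sim$mrna$values[, sim$mrna$groups == "control"]),
               tolerance = 1e-12)
})

test_that("planted triads have opposing miRNA and partner directions", {
  for (seed in c(1, 11, 21)) {
    truth <- generate_expression(tiny_config(seed = seed))$truth
    expect_true(all(truth$triads$mirna_direction != truth$triads$partner_direction))
    for (cl in c("mirna", "lncrna", "mrna")) {
      col <- if (cl == "mirna") "mirna_direction" else "partner_direction"
      expect_identical(
        unname(truth$de_features[[cl]][truth$triads[[cl]]]),
        truth$triads[[col]])
    }
  }
})

test_that("planted edges carry seed sites and non-edges carry none", {
  cfg <- tiny_config(seed = 13, n_mrna = 12L, n_triads = 4L)
  sim <- generate_expression(cfg)
  seqs <- generate_sequences(cfg, sim$truth)
  mir <- as.character(seqs$mirna)
  targets <- c(as.character(seqs$utr3), as.character(seqs$lncrna))
  edges <- unique(rbind(
    data.frame(m = sim$truth$triads$mirna, t = sim$truth$triads$mrna),
    data.frame(m = sim$truth$triads$mirna, t = sim$truth$triads$lncrna)))
  edge_key <- paste(edges$m, edges$t)
  for (m in names(mir)) {
    for (tg in names(targets)) {
      hits <- naive_seed_scan(mir[[m]], targets[[tg]])
      strong <- hits[hits$type %in% c("7mer-m8", "8mer"), , drop = FALSE]
      if (paste(m, tg) %in% edge_key) {
        expect_gte(nrow(strong), 1)
      } else {
        expect_identical(nrow(strong), 0L)
      }
    }
  }
  # planted site records point at exact 8mer intervals
  ps <- seqs$truth$planted_sites
  expect_identical(nrow(ps), 2L * cfg$n_triads)
  for (i in seq_len(nrow(ps))) {
    tg <- targets[[ps$target[i]]]
    site <- substr(tg, ps$start[i] + 1, ps$end[i])
    m <- mir[[ps$mirna[i]]]
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    expected <- paste0(paste(rev(unname(comp[strsplit(substr(m, 2, 8), "")[[1]]])),
                             collapse = ""), "A")
    expect_identical(site, expected)
  }
})

test_that("with no triads sequences are unconstrained and sites unrecorded", {
  cfg <- tiny_config(seed = 2, n_triads = 0L)
  sim <- generate_expression(cfg)
  seqs <- generate_sequences(cfg, sim$truth)
  expect_identical(nrow(seqs$truth$planted_sites), 0L)
  expect_identical(length(seqs$utr3), as.integer(cfg$n_mrna))
})

test_that("annotation respects the cis fraction at both extremes", {
  cfg1 <- tiny_config(seed = 9, cis_fraction = 1)
  truth <- generate_expression(cfg1)$truth
  anno <- generate_annotation(truth, cfg1)
  for (i in seq_len(nrow(truth$triads))) {
    l <- anno$lncrna[truth$triads$lncrna[i]]
    g <- anno$mrna[truth$triads$mrna[i]]
    expect_identical(as.character(GenomicRanges::seqnames(l)),
                     as.character(GenomicRanges::seqnames(g)))
    gap <- max(0, max(GenomicRanges::start(l), GenomicRanges::start(g)) -
                  min(GenomicRanges::end(l), GenomicRanges::end(g)) - 1)
    expect_lte(gap, cfg1$cis_window)
  }
  cfg0 <- tiny_config(seed = 9, cis_fraction = 0)
  truth0 <- generate_expression(cfg0)$truth
  anno0 <- generate_annotation(truth0, cfg0)
  for (i in seq_len(nrow(truth0$triads))) {
    expect_false(identical(
      as.character(GenomicRanges::seqnames(anno0$lncrna[truth0$triads$lncrna[i]])),
      as.character(GenomicRanges::seqnames(anno0$mrna[truth0$triads$mrna[i]]))))
  }
  expect_error(generate_annotation(truth, tiny_config(seed = 9, cis_window = 9e6)),
               "chromosome")
})

test_that("BED round-trip is the identity", {
  cfg <- tiny_config(seed = 4)
  anno <- generate_annotation(generate_expression(cfg)$truth, cfg)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(anno$mrna, path)
  back <- read_bed(path)
  expect_identical(names(back), names(anno$mrna))
  expect_identical(GenomicRanges::start(back), GenomicRanges::start(anno$mrna))
  expect_identical(GenomicRanges::end(back), GenomicRanges::end(anno$mrna))
  expect_identical(as.character(GenomicRanges::seqnames(back)),
                   as.character(GenomicRanges::seqnames(anno$mrna)))
  expect_identical(as.character(GenomicRanges::strand(back)),
                   as.character(GenomicRanges::strand(anno$mrna)))
  # write -> read -> write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("noise-free qPCR reproduces the planted fold change", {
  cfg <- tiny_config(seed = 6, ct_noise_sd = 0, planted_log2fc = 2)
  sim <- generate_expression(cfg)
  ct <- generate_qpcr(sim$truth, cfg)
  dirs <- sim$truth$de_features$mrna[sim$truth$triads$mrna]
  gene <- sim$truth$triads$mrna[1]
  expected <- if (unname(dirs[1]) == "down") 0.25 else 4
  rq <- ddct(ct, gene, "GAPDH-ref", "control")
  ratio <- mean(rq$rq[rq$group == "case"]) / mean(rq$rq[rq$group == "control"])
  expect_equal(ratio, expected, tolerance = 1e-9)
})

test_that("reference genes are group-invariant in expectation", {
  cfg <- tiny_config(seed = 6, ct_noise_sd = 0)
  sim <- generate_expression(cfg)
  ct <- generate_qpcr(sim$truth, cfg)
  for (ref in c("U6-ref", "GAPDH-ref", "cel-miR-39-ref")) {
    sub <- ct[ct$gene == ref, ]
    expect_equal(mean(sub$ct[sub$group == "case"]),
                 mean(sub$ct[sub$group == "control"]), tolerance = 1e-9)
  }
})

test_that("replicate Ct spread matches the configured noise", {
  cfg <- tiny_config(seed = 31, n_case = 50L, n_control = 50L,
                     n_triads = 3L, ct_noise_sd = 0.3)
  sim <- generate_expression(cfg)
  ct <- generate_qpcr(sim$truth, cfg)
  # pooled within-(sample, gene) standard deviation across all triplicates
  ss <- tapply(ct$ct, paste(ct$sample, ct$gene), function(v)
    c(sum((v - mean(v))^2), length(v) - 1))
  pooled <- sqrt(sum(vapply(ss, `[`, numeric(1), 1)) /
                 sum(vapply(ss, `[`, numeric(1), 2)))
  expect_equal(pooled, 0.3, tolerance = 0.05)
})

test_that("binormal separation matches the target AUC", {
  cfg <- tiny_config(seed = 1, biomarker_auc = 0.879)
  clin <- generate_clinical(cfg)
  expect_equal(clin$params$delta, 1.653, tolerance = 1e-3)
  expect_identical(clin$params$orientation, "lower-in-case")
  # AUC 0.5 means identical group distributions
  cfg0 <- tiny_config(seed = 1, biomarker_auc = 0.5)
  expect_equal(generate_clinical(cfg0)$params$delta, 0, tolerance = 1e-12)
})

test_that("null clinical correlation stays near zero", {
  cfg <- tiny_config(seed = 17, n_case = 400L, n_control = 10L,
                     clinical_r = c(lactate = 0))
  clin <- generate_clinical(cfg)$clinical
  cases <- clin[clin$group == "case", ]
  r <- cor(cases$marker, cases$lactate, method = "spearman")
  expect_lt(abs(r), 3 / sqrt(nrow(cases)))
})

test_that("pooling collapses each group to its mean profile", {
  sim <- generate_expression(tiny_config(seed = 23))
  pooled <- pool_samples(sim$mrna)
  expect_identical(colnames(pooled$values), c("case-pool", "control-pool"))
  expect_equal(pooled$values[, "case-pool"],
               rowMeans(sim$mrna$values[, sim$mrna$groups == "case"]))
})
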
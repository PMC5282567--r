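# Synthetic-data generator: emulates a pooled case-control muscle/serum
# study (expression matrices with planted differential expression, ceRNA
# triads backed by real seed-match sites, qPCR Ct tables, and a binormal
# serum biomarker tied to clinical covariates), together with the ground
# truth needed for recovery tests.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator under one seed.
#' Defaults emulate the study design the package targets: 20 cases vs 20
#' controls, moderate transcriptome sizes, planted |log2FC| = 2 effects on
#' a log-normal expression scale, 20 planted ceRNA triads, a serum
#' biomarker with binormal AUC 0.879 that is *lower* in cases, and negative
#' rank correlations of the marker with lactate (-0.43), NMDAS (-0.644) and
#' muscle mutation load (-0.709).
#'
#' @param seed integer root seed; every generator derives its own stream
#'   from it, so identical configs give bit-identical outputs.
#' @param n_case,n_control samples per group.
#' @param n_mirna,n_lncrna,n_mrna feature counts per class.
#' @param frac_de fraction of features per class planted as differentially
#'   expressed (triad members are always DE when `frac_de > 0`).
#' @param planted_log2fc magnitude of the planted group effect (log2 units).
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param n_triads number of planted lncRNA--miRNA--mRNA ceRNA triads.
#' @param utr_length,lnc_length lengths (nt) of simulated mRNA 3'UTRs and
#'   lncRNA transcripts.
#' @param cis_fraction fraction of triad lncRNA--mRNA pairs placed within
#'   `cis_window` on one chromosome; the rest land on distinct chromosomes.
#' @param cis_window genomic window (nt) defining cis proximity.
#' @param biomarker_auc target binormal AUC of the serum marker, in
#'   `[0.5, 1)`.
#' @param clinical_r named vector of target Spearman correlations between
#'   the marker and clinical covariates within cases; `|r| < 1`.
#' @param ct_noise_sd qPCR replicate/sample noise (Ct cycles).
#'
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(seed,
                              n_case = 20L, n_control = 20L,
                              n_mirna = 60L, n_lncrna = 150L, n_mrna = 300L,
                              frac_de = 0.2, planted_log2fc = 2,
                              noise_sd = 0.5, n_triads = 20L,
                              utr_length = 500L, lnc_length = 800L,
                              cis_fraction = 0.5, cis_window = 1e5,
                              biomarker_auc = 0.879,
                              clinical_r = c(lactate = -0.43,
                                             nmdas = -0.644,
                                             mutation_load = -0.709),
                              ct_noise_sd = 0.25) {
  cfg <- list(
    seed = assert_count(seed, "seed", min = 0L),
    n_case = assert_count(n_case, "n_case"),
    n_control = assert_count(n_control, "n_control"),
    n_mirna = assert_count(n_mirna, "n_mirna"),
    n_lncrna = assert_count(n_lncrna, "n_lncrna"),
    n_mrna = assert_count(n_mrna, "n_mrna"),
    frac_de = assert_scalar_number(frac_de, "frac_de", 0, 1),
    planted_log2fc = assert_scalar_number(planted_log2fc, "planted_log2fc", 0, Inf),
    noise_sd = assert_scalar_number(noise_sd, "noise_sd", 0, Inf),
    n_triads = assert_count(n_triads, "n_triads", min = 0L),
    utr_length = assert_count(utr_length, "utr_length", min = 30L),
    lnc_length = assert_count(lnc_length, "lnc_length", min = 30L),
    cis_fraction = assert_scalar_number(cis_fraction, "cis_fraction", 0, 1),
    cis_window = assert_scalar_number(cis_window, "cis_window", 1, Inf),
    biomarker_auc = assert_scalar_number(biomarker_auc, "biomarker_auc", 0.5, 1 - 1e-12),
    clinical_r = clinical_r,
    ct_noise_sd = assert_scalar_number(ct_noise_sd, "ct_noise_sd", 0, Inf)
  )
  if (length(clinical_r) < 1 || is.null(names(clinical_r)) ||
      any(!nzchar(names(clinical_r))))
    stopf("'clinical_r' must be a named numeric vector")
  if (any(!is.finite(clinical_r)) || any(abs(clinical_r) >= 1))
    stopf("'clinical_r' entries must be finite with |r| < 1")
  if (cfg$n_triads > min(cfg$n_mirna, cfg$n_lncrna, cfg$n_mrna))
    stopf("n_triads exceeds the smallest feature class")
  class(cfg) <- "sim_config"
  cfg
}

sim_sample_ids <- function(config) {
  c(sprintf("case-%02d", seq_len(config$n_case)),
    sprintf("control-%02d", seq_len(config$n_control)))
}

sim_groups <- function(config) {
  ids <- sim_sample_ids(config)
  setNames(rep(c("case", "control"), c(config$n_case, config$n_control)), ids)
}

sim_feature_ids <- function(config) {
  list(mirna = sprintf("miR-sim-%04d", seq_len(config$n_mirna)),
       lncrna = sprintf("lnc-sim-%04d", seq_len(config$n_lncrna)),
       mrna = sprintf("gene-sim-%04d", seq_len(config$n_mrna)))
}

#' Generate expression matrices with planted effects
#'
#' Log2 expression is baseline + group effect (+/- `planted_log2fc` for
#' planted DE features, applied to cases) + a shared latent factor within
#' each planted triad (loading -1 on the miRNA, +1 on its lncRNA/mRNA
#' partners, scale `noise_sd`) + Gaussian noise, then exponentiated, so
#' values are strictly positive and log-normal -- emulating microarray
#' signal (miRNA, baseline around 2^10) and FPKM (lncRNA/mRNA, baseline
#' around 2^6).
#'
#' In every planted triad the miRNA's DE direction is opposite to both
#' partners'.  With `frac_de = 0` no feature is planted DE and the truth
#' record is empty.
#'
#' @param config a [simulation_config()].
#' @return A list with `expr_matrix` elements `mirna`, `lncrna`, `mrna` and
#'   a `truth` record (class `cernet_truth`) holding `de_features`,
#'   `triads`, and placeholders for planted sites and biomarker parameters.
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sim_feature_ids(config)
  groups <- sim_groups(config)
  with_seed(derive_seed(config$seed, 1L), {
    n_tr <- config$n_triads
    triads <- data.frame(lncrna = character(0), mirna = character(0),
                         mrna = character(0), mirna_direction = character(0),
                         partner_direction = character(0),
                         stringsAsFactors = FALSE)
    if (n_tr > 0) {
      mdir <- sample(c("up", "down"), n_tr, replace = TRUE)
      triads <- data.frame(
        lncrna = sample(ids$lncrna, n_tr),
        mirna = sample(ids$mirna, n_tr),
        mrna = sample(ids$mrna, n_tr),
        mirna_direction = mdir,
        partner_direction = ifelse(mdir == "up", "down", "up"),
        stringsAsFactors = FALSE)
    }

    de_features <- list(mirna = character(0), lncrna = character(0),
                        mrna = character(0))
    if (config$frac_de > 0) {
      pick_de <- function(all_ids, forced, forced_dir) {
        n_de <- max(round(config$frac_de * length(all_ids)), length(forced))
        extra <- setdiff(all_ids, forced)
        extra <- sample(extra, n_de - length(forced))
        dirs <- c(forced_dir, sample(c("up", "down"), length(extra),
                                     replace = TRUE))
        setNames(dirs, c(forced, extra))
      }
      de_features <- list(
        mirna = pick_de(ids$mirna, triads$mirna, triads$mirna_direction),
        lncrna = pick_de(ids$lncrna, triads$lncrna, triads$partner_direction),
        mrna = pick_de(ids$mrna, triads$mrna, triads$partner_direction))
    }

    n_s <- config$n_case + config$n_control
    is_case <- unname(groups == "case")
    latent <- if (n_tr > 0)
      matrix(rnorm(n_tr * n_s, sd = config$noise_sd), n_tr, n_s)
    else matrix(0, 0, n_s)

    build_class <- function(class, baseline_mean) {
      f <- ids[[class]]
      base <- rnorm(length(f), baseline_mean, 1.5)
      x <- matrix(base, length(f), n_s)
      de <- de_features[[class]]
      if (length(de)) {
        sgn <- ifelse(unname(de) == "up", 1, -1)
        idx <- match(names(de), f)
        x[idx, is_case] <- x[idx, is_case] + sgn * config$planted_log2fc
      }
      if (n_tr > 0) {
        col <- if (class == "mirna") "mirna" else class
        loading <- if (class == "mirna") -1 else 1
        idx <- match(triads[[col]], f)
        x[idx, ] <- x[idx, ] + loading * latent
      }
      x <- x + matrix(rnorm(length(f) * n_s, sd = config$noise_sd),
                      length(f), n_s)
      dimnames(x) <- list(f, names(groups))
      x
    }

    m_mirna <- build_class("mirna", 10)
    m_lncrna <- build_class("lncrna", 6)
    m_mrna <- build_class("mrna", 6)
    lnc_cat <- sample(c("antisense", "intergenic", "intronic",
                        "processed_transcript"),
                      config$n_lncrna, replace = TRUE,
                      prob = c(0.35, 0.35, 0.15, 0.15))

    truth <- structure(list(de_features = de_features, triads = triads,
                            planted_sites = NULL, biomarker_params = NULL,
                            planted_correlations = NULL),
                       class = "cernet_truth")
    list(mirna = expression_matrix(2^m_mirna, groups, "mirna"),
         lncrna = expression_matrix(2^m_lncrna, groups, "lncrna", lnc_cat),
         mrna = expression_matrix(2^m_mrna, groups, "mrna"),
         truth = truth)
  })
}

# Planted regulator edges implied by the triads: miRNA -> mRNA 3'UTR and
# miRNA -> lncRNA transcript.
truth_edges <- function(truth) {
  if (nrow(truth$triads) == 0)
    return(data.frame(mirna = character(0), target = character(0),
                      target_kind = character(0), stringsAsFactors = FALSE))
  rbind(
    data.frame(mirna = truth$triads$mirna, target = truth$triads$mrna,
               target_kind = "utr3", stringsAsFactors = FALSE),
    data.frame(mirna = truth$triads$mirna, target = truth$triads$lncrna,
               target_kind = "lncRNA", stringsAsFactors = FALSE))
}

random_rna <- function(n_seq, len) {
  vapply(seq_len(n_seq), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate miRNA, 3'UTR and lncRNA sequences with planted seed sites
#'
#' Mature miRNA sequences (22 nt) are drawn so that no miRNA's 7mer-m8 site
#' sequence occurs inside another's 8mer site.  Each planted
#' (miRNA, target) edge receives at least one exact 8mer site (reverse
#' complement of miRNA positions 2--8 followed by A) at a random position of
#' the target; every non-edge (miRNA, target) pair is scrubbed of 7mer-m8 /
#' 8mer sites by rejection-style repair (6mer and 7mer-A1 sites may remain
#' by chance, which downstream truth evaluation tolerates).  With
#' `n_triads = 0` sequences are unconstrained random.
#'
#' @param config a [simulation_config()].
#' @param truth truth record from [generate_expression()].
#' @param max_iter repair iterations per transcript before giving up.
#' @return A list of [Biostrings::RNAStringSet] objects `mirna`, `utr3`,
#'   `lncrna`, and the `truth` updated with `planted_sites` (0-based
#'   half-open intervals of the inserted 8mers).
#' @export
generate_sequences <- function(config, truth, max_iter = 100L) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "cernet_truth"))
  ids <- sim_feature_ids(config)
  with_seed(derive_seed(config$seed, 2L), {
    # miRNAs with mutually compatible seeds
    mirna_seq <- character(config$n_mirna)
    site7 <- character(config$n_mirna)
    for (i in seq_len(config$n_mirna)) {
      for (try in seq_len(200L)) {
        s <- random_rna(1, 22)
        s7 <- revcomp_rna(substr(s, 2, 8))
        prev <- site7[seq_len(i - 1L)]
        clash <- any(vapply(prev, function(p)
          grepl(s7, paste0(p, "A"), fixed = TRUE) ||
            grepl(p, paste0(s7, "A"), fixed = TRUE), logical(1)))
        if (!clash) break
        s <- NA_character_
      }
      if (is.na(s)) stopf("could not draw compatible miRNA seeds")
      mirna_seq[i] <- s
      site7[i] <- s7
    }
    names(mirna_seq) <- ids$mirna
    names(site7) <- ids$mirna

    edges <- truth_edges(truth)
    constrain <- nrow(edges) > 0

    make_target <- function(id, len, kind) {
      seqs <- random_rna(1, len)
      regulators <- edges$mirna[edges$target == id]
      locked <- logical(len)
      sites <- NULL
      if (length(regulators)) {
        for (m in regulators) {
          s8 <- paste0(site7[m], "A")
          placed <- FALSE
          for (try in seq_len(max_iter)) {
            pos <- sample.int(len - 8L + 1L, 1L)
            if (!any(locked[pos:(pos + 7L)])) {
              substr(seqs, pos, pos + 7L) <- s8
              locked[pos:(pos + 7L)] <- TRUE
              sites <- rbind(sites, data.frame(
                mirna = m, target = id, start = pos - 1L, end = pos + 7L,
                stringsAsFactors = FALSE))
              placed <- TRUE
              break
            }
          }
          if (!placed) stopf("could not place seed site for %s on %s", m, id)
        }
      }
      if (constrain) {
        forbidden <- site7[setdiff(ids$mirna, regulators)]
        for (iter in seq_len(max_iter)) {
          starts <- seq_len(len - 7L + 1L)
          hits <- starts[substring(seqs, starts, starts + 6L) %in% forbidden]
          if (!length(hits)) break
          for (h in hits) {
            span <- h:(h + 6L)
            free <- span[!locked[span]]
            if (!length(free)) next
            p <- free[sample.int(length(free), 1L)]
            old <- substr(seqs, p, p)
            substr(seqs, p, p) <- sample(setdiff(c("A", "C", "G", "U"), old), 1L)
          }
        }
        starts <- seq_len(len - 7L + 1L)
        if (any(substring(seqs, starts, starts + 6L) %in% forbidden))
          stopf("failed to scrub unintended seed sites from %s after %d iterations",
                id, max_iter)
      }
      list(seq = seqs, sites = sites)
    }

    utr <- lapply(ids$mrna, make_target, len = config$utr_length, kind = "utr3")
    lnc <- lapply(ids$lncrna, make_target, len = config$lnc_length,
                  kind = "lncRNA")
    sites <- do.call(rbind, c(lapply(utr, `[[`, "sites"),
                              lapply(lnc, `[[`, "sites")))
    if (is.null(sites))
      sites <- data.frame(mirna = character(0), target = character(0),
                          start = integer(0), end = integer(0),
                          stringsAsFactors = FALSE)
    truth$planted_sites <- sites[order_c(sites$mirna, sites$target, sites$start), ,
                                 drop = FALSE]
    rownames(truth$planted_sites) <- NULL

    list(
      mirna = Biostrings::RNAStringSet(mirna_seq),
      utr3 = Biostrings::RNAStringSet(
        setNames(vapply(utr, `[[`, character(1), "seq"), ids$mrna)),
      lncrna = Biostrings::RNAStringSet(
        setNames(vapply(lnc, `[[`, character(1), "seq"), ids$lncrna)),
      truth = truth)
  })
}

SIM_GENOME <- list(n_chrom = 10L, chrom_len = 1e7)

#' Generate genomic loci (BED-style) for lncRNAs and mRNAs
#'
#' Places features on a pseudo-genome of 10 chromosomes x 10 Mb.  A
#' `cis_fraction` share of the planted triad lncRNA--mRNA pairs is placed on
#' one chromosome with an intergenic gap drawn uniformly in
#' `[0, cis_window]`; the remaining triad pairs land on distinct
#' chromosomes.  All other features are placed uniformly at random.
#' Intervals are 0-based half-open with `start < end`.
#'
#' @param truth truth record from [generate_expression()].
#' @param config a [simulation_config()].
#' @return A list of two [GenomicRanges::GRanges] (`lncrna`, `mrna`), with
#'   feature ids as names.
#' @export
generate_annotation <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "cernet_truth"))
  if (config$cis_window >= SIM_GENOME$chrom_len / 2)
    stopf("cis_window must be well below the %g nt chromosome model",
          SIM_GENOME$chrom_len)
  ids <- sim_feature_ids(config)
  chroms <- sprintf("chr%d", seq_len(SIM_GENOME$n_chrom))
  with_seed(derive_seed(config$seed, 3L), {
    gene_len <- function(n) as.integer(round(runif(n, 2000, 10000)))
    loci <- list(
      lncrna = data.frame(id = ids$lncrna,
                          chrom = sample(chroms, config$n_lncrna, TRUE),
                          start = NA_integer_, width = config$lnc_length,
                          strand = sample(c("+", "-"), config$n_lncrna, TRUE),
                          stringsAsFactors = FALSE),
      mrna = data.frame(id = ids$mrna,
                        chrom = sample(chroms, config$n_mrna, TRUE),
                        start = NA_integer_, width = gene_len(config$n_mrna),
                        strand = sample(c("+", "-"), config$n_mrna, TRUE),
                        stringsAsFactors = FALSE))
    for (k in names(loci)) {
      n <- nrow(loci[[k]])
      loci[[k]]$start <- as.integer(floor(runif(
        n, 0, SIM_GENOME$chrom_len - loci[[k]]$width)))
    }

    n_tr <- nrow(truth$triads)
    if (n_tr > 0) {
      ord <- sample.int(n_tr)
      n_cis <- round(config$cis_fraction * n_tr)
      cis_idx <- ord[seq_len(n_cis)]
      for (t in seq_len(n_tr)) {
        li <- match(truth$triads$lncrna[t], loci$lncrna$id)
        gi <- match(truth$triads$mrna[t], loci$mrna$id)
        if (t %in% cis_idx) {
          chrom <- sample(chroms, 1)
          gap <- round(runif(1, 0, config$cis_window))
          lw <- loci$lncrna$width[li]; gw <- loci$mrna$width[gi]
          s <- floor(runif(1, 0, SIM_GENOME$chrom_len - lw - gap - gw))
          loci$lncrna$chrom[li] <- chrom
          loci$lncrna$start[li] <- as.integer(s)
          loci$mrna$chrom[gi] <- chrom
          loci$mrna$start[gi] <- as.integer(s + lw + gap)
        } else {
          two <- sample(chroms, 2)
          loci$lncrna$chrom[li] <- two[1]
          loci$mrna$chrom[gi] <- two[2]
        }
      }
    }

    as_granges <- function(df) {
      gr <- GenomicRanges::GRanges(
        seqnames = df$chrom,
        ranges = IRanges::IRanges(start = df$start + 1L,
                                  end = df$start + df$width),
        strand = df$strand)
      names(gr) <- df$id
      gr
    }
    list(lncrna = as_granges(loci$lncrna), mrna = as_granges(loci$mrna))
  })
}

#' Write / read gene loci as 6-column BED
#'
#' @param gr a named [GenomicRanges::GRanges].
#' @param path BED file path.
#' @return `write_bed` returns `path` invisibly; `read_bed` a named GRanges.
#' @export
write_bed <- function(gr, path) {
  score <- S4Vectors::mcols(gr)$score
  if (is.null(score)) S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  names(gr) <- S4Vectors::mcols(gr)$name
  gr
}

#' Generate a qPCR Ct table consistent with planted fold changes
#'
#' Emits triplicate threshold-cycle values for the planted triad members
#' (or an explicit gene list) plus three group-invariant reference genes:
#' `U6-ref` (miRNA normaliser), `GAPDH-ref` (lncRNA/mRNA normaliser) and
#' `cel-miR-39-ref` (serum spike-in analogue).  An up-regulated feature's
#' case Ct is lowered by its planted log2 fold change, so
#' `2^-ddCt` recovers the planted effect as noise vanishes.
#'
#' @param truth truth record from [generate_expression()].
#' @param config a [simulation_config()].
#' @param genes target genes to assay; defaults to all triad members, or all
#'   planted DE features (capped at 12) when there are no triads.
#' @param n_replicates technical replicates per (sample, gene).
#' @return A data frame (`CtTable`) with columns `sample`, `group`, `gene`,
#'   `replicate`, `ct`.
#' @export
generate_qpcr <- function(truth, config, genes = NULL, n_replicates = 3L) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "cernet_truth"))
  if (is.null(genes)) {
    genes <- if (nrow(truth$triads) > 0)
      unique(c(truth$triads$mirna, truth$triads$lncrna, truth$triads$mrna))
    else head(sort_c(unlist(lapply(truth$de_features, names))), 12L)
  }
  refs <- c("U6-ref", "GAPDH-ref", "cel-miR-39-ref")
  de_dir <- unlist(unname(truth$de_features))
  if (is.null(de_dir)) de_dir <- character(0)
  groups <- sim_groups(config)
  with_seed(derive_seed(config$seed, 4L), {
    all_genes <- c(genes, refs)
    base_ct <- setNames(c(runif(length(genes), 18, 30), 18.5, 20.5, 22.5),
                        all_genes)
    rows <- expand.grid(replicate = seq_len(n_replicates), gene = all_genes,
                        sample = names(groups), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    rows <- rows[, c("sample", "gene", "replicate")]
    rows$group <- unname(groups[rows$sample])
    lfc <- vapply(rows$gene, function(g) {
      d <- unname(de_dir[g])
      if (is.na(d) || g %in% refs) 0 else
        if (d == "up") config$planted_log2fc else -config$planted_log2fc
    }, numeric(1))
    sample_eff <- rnorm(nrow(unique(rows[, c("sample", "gene")])),
                        sd = config$ct_noise_sd)
    names(sample_eff) <- with(unique(rows[, c("sample", "gene")]),
                              paste(sample, gene, sep = "\r"))
    ct <- base_ct[rows$gene] -
      ifelse(rows$group == "case", lfc, 0) +
      sample_eff[paste(rows$sample, rows$gene, sep = "\r")] +
      rnorm(nrow(rows), sd = config$ct_noise_sd)
    data.frame(sample = rows$sample, group = rows$group, gene = rows$gene,
               replicate = rows$replicate,
               ct = pmin(pmax(ct, 1), 45), stringsAsFactors = FALSE)
  })
}

# Latent-normal correlation that yields a target Spearman correlation
# under a Gaussian copula.
rho_from_spearman <- function(r_s) 2 * sin(pi * r_s / 6)

#' Generate a serum biomarker and clinical covariates
#'
#' The marker is binormal on the log2 scale with the case mean *below* the
#' control mean (emulating a circulating miRNA reduced in disease), with
#' group separation `delta/sigma = sqrt(2) * qnorm(auc)` so the theoretical
#' AUC equals `biomarker_auc`.  Clinical covariates (by default lactate,
#' NMDAS and muscle mutation load) are generated within cases via a
#' single-factor Gaussian copula on the marker's latent normal, targeting
#' the configured Spearman correlations; controls receive covariates from
#' an independent healthy distribution (mutation load `NA`).
#'
#' @param config a [simulation_config()].
#' @return A list: `clinical` data frame (`sample`, `group`, `marker`, one
#'   column per covariate) and `params` (binormal means/sds, `delta`,
#'   latent correlations actually used).
#' @export
generate_clinical <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  r_s <- config$clinical_r
  rho <- rho_from_spearman(r_s)
  k <- length(rho)
  R <- diag(k + 1)
  R[1, -1] <- rho; R[-1, 1] <- rho
  R[-1, -1][upper.tri(diag(k))] <- (rho %o% rho)[upper.tri(diag(k))]
  R[-1, -1][lower.tri(diag(k))] <- (rho %o% rho)[lower.tri(diag(k))]
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stopf("implied covariate correlation matrix is not positive semi-definite")

  groups <- sim_groups(config)
  delta <- sqrt(2) * qnorm(config$biomarker_auc)
  with_seed(derive_seed(config$seed, 5L), {
    n_case <- config$n_case; n_control <- config$n_control
    z_case <- rnorm(n_case)
    log2_marker <- c(-delta + z_case, rnorm(n_control))
    marker <- 2^log2_marker

    covar_case <- vapply(rho, function(p)
      p * z_case + sqrt(1 - p^2) * rnorm(n_case), numeric(n_case))
    if (n_case == 1L) covar_case <- matrix(covar_case, nrow = 1L)
    colnames(covar_case) <- names(r_s)

    transform_cov <- function(name, z, case) {
      switch(name,
             lactate = if (case) exp(1.6 + 0.35 * z) else exp(0.55 + 0.25 * z),
             nmdas = if (case) 35 + 15 * z else abs(z) * 1.5,
             mutation_load = if (case) 100 * stats::plogis(0.9 + 0.8 * z)
                             else rep(NA_real_, length(z)),
             z)
    }
    clin_case <- vapply(names(r_s), function(nm)
      transform_cov(nm, covar_case[, nm], TRUE), numeric(n_case))
    if (n_case == 1L) clin_case <- matrix(clin_case, nrow = 1L,
                                          dimnames = list(NULL, names(r_s)))
    clin_control <- vapply(names(r_s), function(nm)
      transform_cov(nm, rnorm(n_control), FALSE), numeric(n_control))
    if (n_control == 1L) clin_control <- matrix(clin_control, nrow = 1L,
                                                dimnames = list(NULL, names(r_s)))

    clinical <- data.frame(sample = names(groups), group = unname(groups),
                           marker = marker, stringsAsFactors = FALSE)
    for (nm in names(r_s))
      clinical[[nm]] <- c(clin_case[, nm], clin_control[, nm])
    params <- list(mu_case_log2 = -delta, mu_control_log2 = 0, sigma_log2 = 1,
                   delta = delta, target_auc = config$biomarker_auc,
                   orientation = "lower-in-case",
                   rho_latent = setNames(as.numeric(rho), names(r_s)),
                   target_spearman = r_s)
    list(clinical = clinical, params = params)
  })
}

#' Pool samples within each group
#'
#' Emulates the equal-amount RNA pooling used in discovery-phase profiling:
#' collapses each group to a single pooled sample (the mean of its
#' members' values).
#'
#' @param em an `expr_matrix`.
#' @return An `expr_matrix` with two samples, `case-pool` and
#'   `control-pool`.
#' @export
pool_samples <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  vals <- cbind(`case-pool` = rowMeans(case_values(em)),
                `control-pool` = rowMeans(control_values(em)))
  expression_matrix(vals, c("case", "control"), em$feature_class,
                    em$lnc_category)
}

#' Generate a synthetic gene-set collection
#'
#' Random terms over the simulated mRNA universe, with a few "signal" terms
#' concentrated in the planted DE mRNAs so that over-representation
#' analysis of recovered targets has something to find.  Namespaces cycle
#' through BP/MF/CC/pathway to exercise namespace-wise correction.
#'
#' @param truth truth record from [generate_expression()].
#' @param config a [simulation_config()].
#' @param n_terms number of terms.
#' @param n_signal_terms number of DE-enriched terms among them.
#' @return A [gene_set_collection()].
#' @export
generate_gene_sets <- function(truth, config, n_terms = 40L,
                               n_signal_terms = 3L) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "cernet_truth"))
  universe <- sim_feature_ids(config)$mrna
  de_mrna <- names(truth$de_features$mrna)
  with_seed(derive_seed(config$seed, 6L), {
    sets <- vector("list", n_terms)
    names(sets) <- sprintf("TERM:%04d", seq_len(n_terms))
    lo <- min(5L, length(universe))
    hi <- min(50L, length(universe))
    for (i in seq_len(n_terms)) {
      size <- sample(lo:hi, 1)
      if (i <= n_signal_terms && length(de_mrna) >= 3) {
        n_sig <- min(length(de_mrna), ceiling(0.7 * size))
        sets[[i]] <- unique(c(sample(de_mrna, n_sig),
                              sample(universe, size - n_sig)))
      } else {
        sets[[i]] <- sample(universe, size)
      }
    }
    ns <- setNames(rep(c("BP", "MF", "CC", "pathway"), length.out = n_terms),
                   names(sets))
    gene_set_collection(sets, universe = universe, namespace = ns)
  })
}

#' Run every generator under one configuration
#'
#' @param config a [simulation_config()].
#' @return A list with `expression` (three `expr_matrix`), `sequences`
#'   (three `RNAStringSet`), `annotation` (two `GRanges`), `qpcr`
#'   (`CtTable`), `clinical`, `gene_sets`, the completed `truth`, and the
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  expr <- generate_expression(config)
  seqs <- generate_sequences(config, expr$truth)
  truth <- seqs$truth
  anno <- generate_annotation(truth, config)
  qpcr <- generate_qpcr(truth, config)
  clin <- generate_clinical(config)
  truth$biomarker_params <- clin$params
  truth$planted_correlations <- clin$params$target_spearman
  gene_sets <- generate_gene_sets(truth, config)
  list(expression = expr[c("mirna", "lncrna", "mrna")],
       sequences = seqs[c("mirna", "utr3", "lncrna")],
       annotation = anno, qpcr = qpcr, clinical = clin$clinical,
       gene_sets = gene_sets, truth = truth, config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits the pipeline's on-disk input formats: expression TSVs plus a group
#' table, FASTA sequence files, 6-column BED loci, a Ct TSV, a clinical
#' TSV, a GMT gene-set file and a JSON ground-truth record.
#'
#' @param sim result of [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  paths <- c(expr_mirna = p("expr_mirna.tsv"), expr_lncrna = p("expr_lncrna.tsv"),
             expr_mrna = p("expr_mrna.tsv"), groups = p("groups.tsv"),
             mirna_fa = p("mirna.fa"), utr3_fa = p("utr3.fa"),
             lncrna_fa = p("lncrna.fa"), lncrna_bed = p("lncrna.bed"),
             mrna_bed = p("mrna.bed"), qpcr = p("qpcr_ct.tsv"),
             clinical = p("clinical.tsv"), gene_sets = p("gene_sets.gmt"),
             truth = p("truth.json"))
  write_expression(sim$expression$mirna, paths["expr_mirna"], paths["groups"])
  write_expression(sim$expression$lncrna, paths["expr_lncrna"])
  write_expression(sim$expression$mrna, paths["expr_mrna"])
  Biostrings::writeXStringSet(sim$sequences$mirna, paths["mirna_fa"])
  Biostrings::writeXStringSet(sim$sequences$utr3, paths["utr3_fa"])
  Biostrings::writeXStringSet(sim$sequences$lncrna, paths["lncrna_fa"])
  write_bed(sim$annotation$lncrna, paths["lncrna_bed"])
  write_bed(sim$annotation$mrna, paths["mrna_bed"])
  write_tsv(sim$qpcr, paths["qpcr"])
  write_tsv(sim$clinical, paths["clinical"])
  write_gmt(sim$gene_sets, paths["gene_sets"])
  truth <- sim$truth
  truth$de_features <- lapply(truth$de_features, as.list)
  jsonlite::write_json(unclass(truth), paths["truth"], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}
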
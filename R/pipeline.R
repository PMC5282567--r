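# Pipeline orchestration: simulate -> DE -> targets -> network ->
# enrichment -> biomarker as one reproducible, seeded run with
# machine-parseable logging and schema validation of outputs.

#' Pipeline run configuration
#'
#' Bundles every stage's parameters.  All randomness flows from the single
#' root seed (per-stage streams are derived deterministically), so a rerun
#' with the same configuration is byte-identical apart from timestamps
#' (which live in `run.log` and the report's `timestamps` field only).
#'
#' @param seed integer root seed (mandatory when simulation is enabled).
#' @param outdir output directory.
#' @param sim named list of overrides for [simulation_config()].
#' @param de list: `method`, `adjust`, `fc_threshold`, `q_threshold`.
#' @param candidate list: `log2fc_floor`, `p_floor`, `copy_floor`,
#'   `signal_floor`.
#' @param targets list: `min_type`, `cis_window`, `trans_r`,
#'   `trans_method`.
#' @param network list: `gate` (`"de"` or `"candidate"`), `require_r`
#'   (optional sample-level correlation gate).
#' @param enrichment list: `min_term_size`, `q_threshold`.
#' @param biomarker list: `calibrator`.
#' @param stages character vector of stages to run (dependency order is
#'   enforced); omitted stages must be fed via `inputs`.
#' @param inputs named list of user-supplied file paths that replace
#'   simulated/derived ones: `expr_mirna`, `expr_lncrna`, `expr_mrna`,
#'   `groups`, `mirna_fa`, `utr3_fa`, `lncrna_fa`, `lncrna_bed`,
#'   `mrna_bed`, `qpcr`, `clinical`, `gene_sets`, `de_mirna`,
#'   `de_lncrna`, `de_mrna`, `pairs`, `interaction_table`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = NULL, outdir,
                       sim = list(), de = list(), candidate = list(),
                       targets = list(), network = list(),
                       enrichment = list(), biomarker = list(),
                       stages = c("simulate", "de", "targets", "network",
                                  "enrich", "biomarker"),
                       inputs = list()) {
  all_stages <- c("simulate", "de", "targets", "network", "enrich", "biomarker")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if ("simulate" %in% stages && is.null(seed))
    stopf("a seed is mandatory when the simulate stage is enabled")
  merge_defaults <- function(user, defaults) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stopf("unknown option(s): %s", paste(bad, collapse = ", "))
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    seed = if (is.null(seed)) NULL else assert_count(seed, "seed", min = 0L),
    outdir = outdir,
    sim = sim,
    de = merge_defaults(de, list(method = "auto", adjust = "BH",
                                 fc_threshold = 2, q_threshold = 0.05)),
    candidate = merge_defaults(candidate, list(log2fc_floor = 1.5,
                                               p_floor = 0.01, copy_floor = 30,
                                               signal_floor = 500)),
    targets = merge_defaults(targets, list(min_type = "7mer-m8",
                                           cis_window = 1e5, trans_r = 0.9,
                                           trans_method = "pearson")),
    network = merge_defaults(network, list(gate = "de", require_r = NULL)),
    enrichment = merge_defaults(enrichment, list(min_term_size = 3,
                                                 q_threshold = 0.05)),
    biomarker = merge_defaults(biomarker, list(calibrator = "control")),
    stages = stages,
    inputs = inputs)
  for (f in unlist(inputs))
    if (!file.exists(f)) stopf("input file does not exist: %s", f)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors the arguments of [run_config()] (top-level keys
#' `seed`, `outdir`, `sim`, `de`, `candidate`, `targets`, `network`,
#' `enrichment`, `biomarker`, `stages`, `inputs`).
#'
#' @param path YAML file.
#' @param outdir optional override of the configured output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(outdir)) y$outdir <- outdir
  if (is.null(y$outdir)) stopf("config must provide 'outdir'")
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

# Hash of the semantic configuration (outdir excluded): md5 of the
# canonical JSON serialisation.
config_hash <- function(config) {
  semantic <- config[setdiff(names(config), "outdir")]
  canon <- jsonlite::toJSON(semantic[sort_c(names(semantic))],
                            auto_unbox = TRUE, digits = NA, null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(canon), tmp)
  unname(tools::md5sum(tmp))
}

run_log <- function(state, stage, ...) {
  kv <- c(...)
  line <- paste0("ts=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 " stage=", stage,
                 if (length(kv)) paste0(" ", paste(names(kv), kv, sep = "=",
                                                   collapse = " ")) else "")
  cat(line, "\n", file = state$log, sep = "", append = TRUE)
  invisible(line)
}

#' Run the full ceRNA pipeline
#'
#' Executes the enabled stages in dependency order
#' (simulate -> de -> targets -> network -> enrich -> biomarker), writing
#' each stage's tables under `config$outdir` and a machine-parseable
#' `run.log`.  Any stage can instead consume user-supplied files listed in
#' `config$inputs`.  A failing stage aborts with the stage named and
#' leaves a `FAILED` marker file alongside the partial outputs.
#'
#' @param config a [run_config()].
#' @return The run report (also written to `report.json`): per-stage
#'   record counts, package version, config hash and timestamps.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(outdir, "FAILED"))
  state <- list(log = file.path(outdir, "run.log"))
  cat("", file = state$log)  # truncate
  report <- list(tool = "cernet",
                 version = as.character(packageVersion("cernet")),
                 config_hash = config_hash(config),
                 seed = config$seed, counts = list(),
                 timestamps = list(started = format(Sys.time(),
                                                    "%Y-%m-%dT%H:%M:%S%z")))
  current_stage <- "setup"
  res <- tryCatch({
    p <- function(f) file.path(outdir, f)
    inp <- function(key, default) config$inputs[[key]] %||% p(default)

    ## ---- simulate ----
    if ("simulate" %in% config$stages) {
      current_stage <- "simulate"
      sim_cfg <- do.call(simulation_config,
                         c(list(seed = config$seed), config$sim))
      sim <- simulate_dataset(sim_cfg)
      write_simulation(sim, outdir)
      run_log(state, "simulate",
              n_mirna = nrow(sim$expression$mirna$values),
              n_lncrna = nrow(sim$expression$lncrna$values),
              n_mrna = nrow(sim$expression$mrna$values),
              n_triads = nrow(sim$truth$triads))
      report$counts$simulate <- list(
        n_mirna = nrow(sim$expression$mirna$values),
        n_lncrna = nrow(sim$expression$lncrna$values),
        n_mrna = nrow(sim$expression$mrna$values),
        n_triads = nrow(sim$truth$triads),
        n_planted_sites = nrow(sim$truth$planted_sites))
    }

    ## ---- de ----
    classes <- c("mirna", "lncrna", "mrna")
    expr <- NULL
    load_expr <- function() {
      if (is.null(expr)) {
        expr <<- list(
          mirna = read_expression(inp("expr_mirna", "expr_mirna.tsv"),
                                  inp("groups", "groups.tsv"), "mirna"),
          lncrna = read_expression(inp("expr_lncrna", "expr_lncrna.tsv"),
                                   inp("groups", "groups.tsv"), "lncrna"),
          mrna = read_expression(inp("expr_mrna", "expr_mrna.tsv"),
                                 inp("groups", "groups.tsv"), "mrna"))
      }
      expr
    }
    de_tables <- NULL
    if ("de" %in% config$stages) {
      current_stage <- "de"
      load_expr()
      de_tables <- list()
      for (cl in classes) {
        det <- de_table(expr[[cl]], method = config$de$method,
                        adjust = config$de$adjust)
        called <- call_de(det, config$de$fc_threshold, config$de$q_threshold)
        det <- called$table
        det$passes_candidate <- det$feature %in%
          do.call(candidate_filter, c(list(det), config$candidate))
        de_tables[[cl]] <- det
        write_de_table(det, p(sprintf("de_%s.tsv", cl)))
        run_log(state, "de", class = cl, n_up = length(called$up),
                n_down = length(called$down),
                n_candidate = sum(det$passes_candidate))
        report$counts$de[[cl]] <- list(up = length(called$up),
                                       down = length(called$down),
                                       candidate = sum(det$passes_candidate))
      }
    } else {
      de_paths <- c(mirna = inp("de_mirna", "de_mirna.tsv"),
                    lncrna = inp("de_lncrna", "de_lncrna.tsv"),
                    mrna = inp("de_mrna", "de_mrna.tsv"))
      if (all(file.exists(de_paths)))
        de_tables <- lapply(de_paths, read_de_table)
    }

    ## ---- targets ----
    pairs <- NULL
    if ("targets" %in% config$stages) {
      current_stage <- "targets"
      if (is.null(de_tables)) stopf("targets stage requires DE tables")
      de_ids <- lapply(de_tables, function(d) d$feature[d$passes_de])
      mirna_fa <- as.character(Biostrings::readRNAStringSet(
        inp("mirna_fa", "mirna.fa")))
      utr_fa <- as.character(Biostrings::readRNAStringSet(
        inp("utr3_fa", "utr3.fa")))
      lnc_fa <- as.character(Biostrings::readRNAStringSet(
        inp("lncrna_fa", "lncrna.fa")))
      mirna_fa <- mirna_fa[names(mirna_fa) %in% de_ids$mirna]
      utr_fa <- utr_fa[names(utr_fa) %in% de_ids$mrna]
      lnc_fa <- lnc_fa[names(lnc_fa) %in% de_ids$lncrna]
      pairs <- rbind(
        if (length(mirna_fa) && length(utr_fa))
          seed_pairs(mirna_fa, utr_fa, "mrna", config$targets$min_type)
        else empty_pairs(),
        if (length(mirna_fa) && length(lnc_fa))
          seed_pairs(mirna_fa, lnc_fa, "lncrna", config$targets$min_type)
        else empty_pairs())
      lnc_bed <- read_bed(inp("lncrna_bed", "lncrna.bed"))
      mrna_bed <- read_bed(inp("mrna_bed", "mrna.bed"))
      lnc_bed <- lnc_bed[names(lnc_bed) %in% de_ids$lncrna]
      mrna_bed <- mrna_bed[names(mrna_bed) %in% de_ids$mrna]
      if (length(lnc_bed) && length(mrna_bed))
        pairs <- rbind(pairs, cis_pairs(lnc_bed, mrna_bed,
                                        config$targets$cis_window))
      load_expr()
      lnc_sub <- expr$lncrna$values[rownames(expr$lncrna$values) %in% de_ids$lncrna, ,
                                    drop = FALSE]
      mrna_sub <- expr$mrna$values[rownames(expr$mrna$values) %in% de_ids$mrna, ,
                                   drop = FALSE]
      if (nrow(lnc_sub) && nrow(mrna_sub))
        pairs <- rbind(pairs, trans_pairs(
          expression_matrix(lnc_sub, expr$lncrna$groups[colnames(lnc_sub)], "lncrna"),
          expression_matrix(mrna_sub, expr$mrna$groups[colnames(mrna_sub)], "mrna"),
          config$targets$trans_r, config$targets$trans_method))
      if (!is.null(config$inputs$interaction_table))
        pairs <- rbind(pairs,
                       load_interaction_table(config$inputs$interaction_table))
      write_pairs(pairs, p("pairs.tsv"))
      ev <- table(pairs$evidence)
      run_log(state, "targets", n_pairs = nrow(pairs),
              n_seed = sum(pairs$evidence == "seed"),
              n_cis = sum(pairs$evidence == "cis"),
              n_trans = sum(pairs$evidence == "trans"))
      report$counts$targets <- c(list(total = nrow(pairs)), as.list(ev))
    } else if (file.exists(inp("pairs", "pairs.tsv"))) {
      pairs <- read_tsv(inp("pairs", "pairs.tsv"))
    }

    ## ---- network ----
    integrated <- NULL
    if ("network" %in% config$stages) {
      current_stage <- "network"
      if (is.null(pairs) || is.null(de_tables))
        stopf("network stage requires pairs and DE tables")
      edges <- anticorrelation_filter(pairs, de_tables,
                                      gate = config$network$gate,
                                      require_r = config$network$require_r,
                                      expr = if (!is.null(config$network$require_r))
                                        load_expr() else NULL)
      split_edges <- function(sc, tc)
        edges[edges$regulator_class == sc & edges$target_class == tc, ,
              drop = FALSE]
      net_mm <- build_pair_network(split_edges("mirna", "mrna"), "mirna_mrna")
      net_ml <- build_pair_network(split_edges("mirna", "lncrna"), "mirna_lncrna")
      net_lm <- build_pair_network(split_edges("lncrna", "mrna"), "lncrna_mrna")
      integrated <- integrate_tripartite(net_mm, net_ml, net_lm)
      export_network(net_mm, "graphml", p("network_mirna_mrna.graphml"))
      export_network(net_ml, "graphml", p("network_mirna_lncrna.graphml"))
      export_network(net_lm, "graphml", p("network_lncrna_mrna.graphml"))
      export_network(integrated$mirna_centered$network, "graphml",
                     p("network_mirna_centered.graphml"))
      export_network(integrated$lncrna_centered$network, "graphml",
                     p("network_lncrna_centered.graphml"))
      export_network(integrated$lncrna_centered$network, "sif",
                     p("network_lncrna_centered.sif"))
      write_tsv(integrated$mirna_centered$summary$triads, p("triads.tsv"))
      jsonlite::write_json(
        list(mirna_centered = integrated$mirna_centered$summary$venn,
             lncrna_centered = integrated$lncrna_centered$summary$venn),
        p("venn.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
      run_log(state, "network", n_edges = nrow(edges),
              n_mm = nrow(net_mm$edges), n_ml = nrow(net_ml$edges),
              n_lm = nrow(net_lm$edges),
              n_triads = nrow(integrated$mirna_centered$summary$triads))
      report$counts$network <- list(
        edges = nrow(edges), mirna_mrna = nrow(net_mm$edges),
        mirna_lncrna = nrow(net_ml$edges), lncrna_mrna = nrow(net_lm$edges),
        triads = nrow(integrated$mirna_centered$summary$triads))
    }

    ## ---- enrich ----
    if ("enrich" %in% config$stages) {
      current_stage <- "enrich"
      if (is.null(de_tables)) stopf("enrich stage requires DE tables")
      collection <- read_gmt(inp("gene_sets", "gene_sets.gmt"))
      query <- de_tables$mrna$feature[de_tables$mrna$passes_de]
      enr <- enrich(query, collection,
                    min_term_size = config$enrichment$min_term_size,
                    q_threshold = config$enrichment$q_threshold)
      write_tsv(enr, p("enrichment.tsv"))
      write_tsv(enr[, c("term", "rich_factor", "q", "k")],
                p("enrichment_scatter.tsv"))
      run_log(state, "enrich", n_terms = nrow(enr),
              n_significant = sum(enr$significant))
      report$counts$enrich <- list(terms = nrow(enr),
                                   significant = sum(enr$significant))
    }

    ## ---- biomarker ----
    if ("biomarker" %in% config$stages) {
      current_stage <- "biomarker"
      ct <- read_tsv(inp("qpcr", "qpcr_ct.tsv"))
      clinical <- read_tsv(inp("clinical", "clinical.tsv"))
      refs <- c(mirna = "U6-ref", lncrna = "GAPDH-ref", mrna = "GAPDH-ref")
      assayed <- setdiff(sort_c(unique(ct$gene)),
                         c("U6-ref", "GAPDH-ref", "cel-miR-39-ref"))
      rq_all <- do.call(rbind, lapply(assayed, function(g) {
        cl <- if (grepl("^miR", g)) "mirna" else
          if (grepl("^lnc", g)) "lncrna" else "mrna"
        out <- ddct(ct, g, refs[[cl]], config$biomarker$calibrator)
        out$gene <- g
        out
      }))
      write_tsv(rq_all[, c("sample", "group", "gene", "dct", "ddct", "rq")],
                p("rq.tsv"))
      roc_marker <- roc_curve(clinical$marker, clinical$group)
      covariates <- setdiff(names(clinical), c("sample", "group", "marker"))
      rocs <- list(marker = roc_marker)
      if ("lactate" %in% covariates)
        rocs$lactate <- roc_curve(clinical$lactate, clinical$group)
      comparison <- if (!is.null(rocs$lactate))
        compare_roc(rocs$marker, rocs$lactate) else NULL
      cases <- clinical[clinical$group == "case", , drop = FALSE]
      correlations <- lapply(covariates, function(cv)
        tryCatch(unclass(correlate(cases$marker, cases[[cv]],
                                   covariate_name = cv)),
                 error = function(e) NULL))
      correlations <- Filter(Negate(is.null), correlations)
      write_tsv(roc_marker$thresholds, p("roc_thresholds.tsv"))
      summary <- list(
        marker = list(auc = roc_marker$auc, orientation = roc_marker$orientation,
                      ci = roc_marker$ci, cutoff = roc_marker$optimal$cutoff,
                      sensitivity = roc_marker$optimal$sensitivity,
                      specificity = roc_marker$optimal$specificity),
        lactate = if (!is.null(rocs$lactate))
          list(auc = rocs$lactate$auc, ci = rocs$lactate$ci) else NULL,
        comparison = comparison,
        correlations = correlations)
      jsonlite::write_json(summary, p("biomarker.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, null = "null")
      run_log(state, "biomarker", auc = sprintf("%.4f", roc_marker$auc),
              n_genes = length(assayed))
      report$counts$biomarker <- list(
        genes_assayed = length(assayed), auc = roc_marker$auc,
        n_correlations = length(correlations))
    }

    report$timestamps$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    run_log(state, "done")
    report
  }, error = function(e) {
    writeLines(sprintf("stage=%s error=%s", current_stage, conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stopf("pipeline failed at stage '%s': %s", current_stage,
          conditionMessage(e))
  })
  invisible(res)
}

violation <- function(file, check, message) {
  data.frame(file = file, check = check, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a completed run directory
#'
#' Checks every pipeline output against its documented schema and verifies
#' cross-file referential integrity (network edge endpoints must exist in
#' the DE tables, triad edges in the exported networks).
#'
#' @param outdir a run directory produced by [run_pipeline()].
#' @return A data frame of violations (zero rows when the directory is
#'   valid) with columns `file`, `check`, `message`.
#' @export
validate_run <- function(outdir) {
  v <- violation(character(0), character(0), character(0))
  p <- function(f) file.path(outdir, f)
  need <- function(f) {
    if (!file.exists(p(f))) {
      v <<- rbind(v, violation(f, "exists", "file is missing"))
      FALSE
    } else TRUE
  }
  if (file.exists(p("FAILED")))
    v <- rbind(v, violation("FAILED", "marker", "run directory is marked failed"))

  if (need("report.json")) {
    rep <- tryCatch(jsonlite::read_json(p("report.json")), error = function(e) NULL)
    if (is.null(rep))
      v <- rbind(v, violation("report.json", "parse", "invalid JSON"))
    else if (is.null(rep$config_hash))
      v <- rbind(v, violation("report.json", "schema", "missing config_hash"))
  }

  de_tables <- list()
  for (cl in c("mirna", "lncrna", "mrna")) {
    f <- sprintf("de_%s.tsv", cl)
    if (!need(f)) next
    det <- tryCatch(read_de_table(p(f)), error = function(e) e)
    if (inherits(det, "error")) {
      v <- rbind(v, violation(f, "schema", conditionMessage(det)))
      next
    }
    de_tables[[cl]] <- det
    if (any(abs(det$fc - 2^det$log2fc) > 1e-9 * pmax(det$fc, 1)))
      v <- rbind(v, violation(f, "invariant", "fc != 2^log2fc"))
    if (any(det$q < det$p - 1e-12) || any(det$q > 1 + 1e-12))
      v <- rbind(v, violation(f, "invariant", "q out of range"))
    if (any(det$direction == "up" & det$log2fc <= 0))
      v <- rbind(v, violation(f, "invariant", "up-called feature with log2fc <= 0"))
  }

  if (need("pairs.tsv")) {
    pr <- read_tsv(p("pairs.tsv"))
    if (!all(PAIR_COLUMNS %in% names(pr)))
      v <- rbind(v, violation("pairs.tsv", "schema", "missing columns"))
    else {
      if (any(pr$source == pr$target))
        v <- rbind(v, violation("pairs.tsv", "invariant", "self-pair present"))
      if (!all(pr$source_class %in% c("mirna", "lncrna")))
        v <- rbind(v, violation("pairs.tsv", "invariant", "invalid source class"))
    }
  }

  nets <- list()
  for (f in c("network_mirna_mrna.graphml", "network_mirna_lncrna.graphml",
              "network_lncrna_mrna.graphml", "network_mirna_centered.graphml",
              "network_lncrna_centered.graphml")) {
    if (!need(f)) next
    net <- tryCatch(read_network(p(f)), error = function(e) e)
    if (inherits(net, "error")) {
      v <- rbind(v, violation(f, "parse", conditionMessage(net)))
      next
    }
    nets[[f]] <- net
    if (nrow(net$edges) &&
        any(net$edges$regulator_direction == net$edges$target_direction))
      v <- rbind(v, violation(f, "invariant", "same-direction edge"))
    if (length(de_tables) == 3 && nrow(net$edges)) {
      for (cl in c("mirna", "lncrna", "mrna")) {
        ids <- unique(c(net$edges$regulator[net$edges$regulator_class == cl],
                        net$edges$target[net$edges$target_class == cl]))
        missing <- setdiff(ids, de_tables[[cl]]$feature)
        if (length(missing))
          v <- rbind(v, violation(f, "referential",
                                  sprintf("%d %s node(s) absent from DE table",
                                          length(missing), cl)))
      }
    }
  }

  if (need("triads.tsv")) {
    tr <- read_tsv(p("triads.tsv"))
    lnet <- nets[["network_lncrna_centered.graphml"]]
    if (!is.null(lnet) && nrow(tr)) {
      ek <- paste(lnet$edges$regulator, lnet$edges$target)
      bad <- !(paste(tr$mirna, tr$lncrna) %in% ek &
                 paste(tr$mirna, tr$mrna) %in% ek)
      if (any(bad))
        v <- rbind(v, violation("triads.tsv", "referential",
                                sprintf("%d triad(s) without both edges", sum(bad))))
    }
  }

  if (need("enrichment.tsv")) {
    en <- read_tsv(p("enrichment.tsv"))
    if (!all(c("term", "N", "K", "n", "k", "p", "q", "rich_factor") %in% names(en)))
      v <- rbind(v, violation("enrichment.tsv", "schema", "missing columns"))
    else if (nrow(en) &&
             (any(en$k > pmin(en$K, en$n)) ||
              any(en$rich_factor < 0 | en$rich_factor > 1)))
      v <- rbind(v, violation("enrichment.tsv", "invariant", "k or rich_factor out of range"))
  }

  if (need("biomarker.json")) {
    bm <- tryCatch(jsonlite::read_json(p("biomarker.json")), error = function(e) NULL)
    if (is.null(bm))
      v <- rbind(v, violation("biomarker.json", "parse", "invalid JSON"))
    else {
      auc <- bm$marker$auc
      ci <- unlist(bm$marker$ci)
      if (is.null(auc) || auc < 0.5 - 1e-12 || auc > 1 + 1e-12)
        v <- rbind(v, violation("biomarker.json", "invariant", "AUC out of [0.5, 1]"))
      else if (length(ci) == 2 && (ci[1] > auc + 1e-12 || ci[2] < auc - 1e-12))
        v <- rbind(v, violation("biomarker.json", "invariant", "CI does not cover AUC"))
    }
  }

  for (f in c("expr_mirna.tsv", "expr_lncrna.tsv", "expr_mrna.tsv", "groups.tsv",
              "qpcr_ct.tsv", "clinical.tsv")) need(f)
  if (file.exists(p("qpcr_ct.tsv"))) {
    qc <- read_tsv(p("qpcr_ct.tsv"))
    if (!all(c("sample", "group", "gene", "replicate", "ct") %in% names(qc)))
      v <- rbind(v, violation("qpcr_ct.tsv", "schema", "missing columns"))
    else if (any(!is.finite(qc$ct)) || any(qc$ct <= 0 | qc$ct > 45))
      v <- rbind(v, violation("qpcr_ct.tsv", "invariant", "Ct outside (0, 45]"))
  }
  rownames(v) <- NULL
  v
}
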
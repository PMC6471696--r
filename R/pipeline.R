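#' Pipeline configuration
#'
#' Collects every input path and threshold of the end-to-end workflow.
#' All inputs are validated before any stage runs; thresholds default to
#' the conventional values of the workflow (differential expression at
#' |logFC| > 1.5 and adjusted p < 0.05; differential methylation at beta
#' fold change 1.5 / 0.67 and adjusted p < 1e-4; CpG-gene correlation
#' regions at |rho| > 0.4 and the composite-module set at |rho| > 0.18;
#' 200 bp enrichment and 500 bp composite-module windows; key-node radius
#' 10 with context discount 0.5; marker-correlation threshold 0.8 and 100
#' random splits).
#'
#' @param inputs Named list of input file paths: `expression_case`,
#'   `expression_control`, `methylation_case`, `methylation_control`,
#'   `probe_annotation` (TSV: probe, chrom, pos, gene),
#'   `gene_annotation` (TSV: gene, chrom, start, end),
#'   `sequences_enrichment` (FASTA of enrichment windows per probe),
#'   `sequences_model` (FASTA of composite-module windows per probe),
#'   `background_sequences` (FASTA No-set), `pwms`, `network`,
#'   `tf_gene_map` (TSV: tf, gene), `labels` (TSV: sample, class).
#' @param thresholds Named list overriding the defaults listed above.
#' @param ga A [cma_ga_config()] for the composite-module stage.
#' @param pwm_dialect `"jaspar"` or `"transfac"`.
#' @param seed Master seed for all stochastic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs, thresholds = list(),
                            ga = cma_ga_config(), pwm_dialect = "jaspar",
                            seed = 1) {
  defaults <- list(
    deg_lfc = 1.5, deg_alpha = 0.05,
    meth_lfc = log2(1.5), meth_alpha = 1e-4,
    corr_alpha = 0.05, corr_region = 0.4, corr_model = 0.18,
    window_enrichment = 200, window_model = 500,
    fmatch_alpha = 0.05, fmatch_criterion = "sequence", fmatch_floor = 0.5,
    context_lfc = 1.0, radius = 10, discount = 0.5, max_path_cost = Inf,
    panel_threshold = 0.8, n_splits = 100, train_fraction = 0.5,
    model_max_regions = 200
  )
  bad <- setdiff(names(thresholds), names(defaults))
  if (length(bad) > 0) {
    abort(paste0("Unknown threshold(s): ", paste(bad, collapse = ", ")))
  }
  th <- modifyList(defaults, thresholds)
  if (th$deg_alpha <= 0 || th$deg_alpha > 1 || th$meth_alpha <= 0 ||
      th$corr_alpha <= 0 || th$corr_alpha > 1) {
    abort("Alpha thresholds must lie in (0, 1].")
  }
  required <- c("expression_case", "expression_control",
                "methylation_case", "methylation_control",
                "probe_annotation", "gene_annotation",
                "sequences_enrichment", "sequences_model",
                "background_sequences", "pwms", "network",
                "tf_gene_map", "labels")
  missing <- setdiff(required, names(inputs))
  if (length(missing) > 0) {
    abort(paste0("Missing input path(s): ", paste(missing, collapse = ", ")))
  }
  # network_nodes (node kinds + gene mapping) is optional
  keep <- c(required, intersect("network_nodes", names(inputs)))
  structure(
    list(inputs = inputs[keep], thresholds = th, ga = ga,
         pwm_dialect = pwm_dialect, seed = seed),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file mirrors [pipeline_config()]: top-level keys `inputs`,
#' `thresholds`, `ga`, `pwm_dialect`, `seed`. Relative input paths are
#' resolved against the YAML file's directory.
#'
#' @param path Path to the YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  inputs <- lapply(y$inputs, function(p) {
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  })
  ga <- do.call(cma_ga_config, y$ga %||% list())
  pipeline_config(
    inputs = inputs, thresholds = y$thresholds %||% list(), ga = ga,
    pwm_dialect = y$pwm_dialect %||% "jaspar", seed = y$seed %||% 1
  )
}

stage_log <- function(log_path, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  cat(line, "\n", file = log_path, append = TRUE)
}

#' Run the full biomarker-discovery workflow
#'
#' Executes, in order: differential expression; differential methylation;
#' CpG-gene Spearman correlation (split into negatively and positively
#' correlated loci); merged-window construction around the selected CpGs;
#' F-Match enrichment of the negative and positive window sets against
#' the background; the composite-module correlation model over the wider
#' windows of all correlated loci; assembly of the candidate TF table
#' (enriched in at least one method, joined with differential evidence);
#' context-weighted key-node search over the signalling network with
#' feedback-loop detection and omics prioritisation; assembly of the
#' candidate biomarker CpG table (loci whose windows carry sites of
#' selected TFs and/or map to master-regulator genes); marker
#' decorrelation; and panel evaluation by repeated random splits. Every
#' stage writes a TSV under `out_dir` plus a run log; any stage failure
#' aborts with the stage name while retaining partial outputs.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of class `pipeline_result` with every stage
#'   table, the fitted model, the final panel and its evaluation.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  # validate every input before any stage runs
  paths <- unlist(config$inputs)
  absent <- paths[!file.exists(paths)]
  if (length(absent) > 0) {
    abort(paste0("Input file(s) not found: ", paste(absent, collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("pipeline seed=%d  %s\n", config$seed,
              format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      file = log_path)
  th <- config$thresholds
  stage_log(log_path, "config", paste0(
    "thresholds: ", paste(names(th), unlist(lapply(th, format)),
                          sep = "=", collapse = " ")
  ))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stage_log(log_path, stage, paste0("FAILED: ", conditionMessage(e)))
      abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
  }

  # -- stage 1: differential expression ------------------------------------
  deg <- run_stage("differential_expression", {
    ec <- read_matrix_tsv(config$inputs$expression_case, "expression")
    en <- read_matrix_tsv(config$inputs$expression_control, "expression")
    d <- diff_stats(ec, en, kind = "expression")
    write_matrix_tsv(d, file.path(out_dir, "differential_expression.tsv"))
    d
  })
  deg_sets <- filter_features(deg, th$deg_lfc, -th$deg_lfc, th$deg_alpha)
  stage_log(log_path, "differential_expression",
            sprintf("%d up, %d down (|logFC|>%g, adj p<%g)",
                    nrow(deg_sets$up), nrow(deg_sets$down),
                    th$deg_lfc, th$deg_alpha))

  # -- stage 2: differential methylation -----------------------------------
  dm <- run_stage("differential_methylation", {
    mc <- read_matrix_tsv(config$inputs$methylation_case, "beta")
    mn <- read_matrix_tsv(config$inputs$methylation_control, "beta")
    d <- diff_stats(mc, mn, kind = "beta")
    write_matrix_tsv(d, file.path(out_dir, "differential_methylation.tsv"))
    d
  })
  dm_sets <- filter_features(dm, th$meth_lfc, -th$meth_lfc, th$meth_alpha)
  dm_probes <- c(dm_sets$up$feature, dm_sets$down$feature)
  stage_log(log_path, "differential_methylation",
            sprintf("%d differential CpGs", length(dm_probes)))

  # -- stage 3: CpG-gene correlation ---------------------------------------
  corr <- run_stage("cpg_gene_correlation", {
    mc <- read_matrix_tsv(config$inputs$methylation_case, "beta")
    mn <- read_matrix_tsv(config$inputs$methylation_control, "beta")
    ec <- read_matrix_tsv(config$inputs$expression_case, "expression")
    en <- read_matrix_tsv(config$inputs$expression_control, "expression")
    meth <- cbind(mc, mn[rownames(mc), , drop = FALSE])
    expr <- cbind(ec, en[rownames(ec), , drop = FALSE])
    ann <- read.delim(config$inputs$probe_annotation)
    gann <- read.delim(config$inputs$gene_annotation)
    pairs <- pair_by_distance(ann, gann)
    pairs <- pairs[pairs$probe %in% dm_probes, , drop = FALSE]
    cc <- cpg_gene_correlation(meth, expr, pairs, alpha = th$corr_alpha)
    # per probe, keep the strongest-correlated gene
    cc <- cc |>
      dplyr::arrange(dplyr::desc(abs(.data$rho))) |>
      dplyr::distinct(.data$probe, .keep_all = TRUE)
    write_matrix_tsv(cc, file.path(out_dir, "cpg_gene_correlation.tsv"))
    cc
  })
  neg <- corr$probe[corr$rho < -th$corr_region]
  pos <- corr$probe[corr$rho > th$corr_region]
  model_set <- corr[abs(corr$rho) > th$corr_model, ]
  stage_log(log_path, "cpg_gene_correlation",
            sprintf("%d NEG, %d POS loci (|rho|>%g); %d model loci (|rho|>%g)",
                    length(neg), length(pos), th$corr_region,
                    nrow(model_set), th$corr_model))

  # -- stage 4: window construction ----------------------------------------
  run_stage("regions", {
    ann <- read.delim(config$inputs$probe_annotation)
    for (set in list(list(ids = neg, tag = "neg"),
                     list(ids = pos, tag = "pos"))) {
      sub <- ann[ann$probe %in% set$ids, , drop = FALSE]
      if (nrow(sub) > 0) {
        bed <- regions_around(sub, window = th$window_enrichment)
        write_bed(bed, file.path(out_dir,
                                 paste0("regions_", set$tag, ".bed")))
      }
    }
    sub <- ann[ann$probe %in% model_set$probe, , drop = FALSE]
    if (nrow(sub) > 0) {
      bed <- regions_around(sub, window = th$window_model)
      write_bed(bed, file.path(out_dir, "regions_model.bed"))
    }
    NULL
  })

  # -- stage 5: F-Match enrichment -----------------------------------------
  pwms <- read_pwms(config$inputs$pwms, dialect = config$pwm_dialect)
  enr <- run_stage("fmatch", {
    yes_all <- read_fasta(config$inputs$sequences_enrichment)
    no_set <- read_fasta(config$inputs$background_sequences)
    res <- list()
    for (set in list(list(ids = neg, tag = "neg"),
                     list(ids = pos, tag = "pos"))) {
      yes <- yes_all[yes_all$id %in% set$ids, ]
      if (nrow(yes) == 0) next
      r <- fmatch(pwms, yes, no_set,
                  criterion = th$fmatch_criterion,
                  alpha = th$fmatch_alpha, min_score = th$fmatch_floor)
      r$set <- set$tag
      res[[set$tag]] <- r
    }
    out <- dplyr::bind_rows(res)
    write_matrix_tsv(out, file.path(out_dir, "fmatch.tsv"))
    out
  })
  enriched_tfs <- unique(enr$pwm_id[enr$significant &
                                      enr$p_adjusted < th$fmatch_alpha])
  stage_log(log_path, "fmatch",
            sprintf("%d enriched matrices", length(enriched_tfs)))

  # -- stage 6: composite-module model -------------------------------------
  fit <- run_stage("composite_model", {
    seqs_all <- read_fasta(config$inputs$sequences_model)
    ms <- model_set[model_set$probe %in% seqs_all$id, ]
    if (nrow(ms) > th$model_max_regions) {
      set.seed(config$seed)
      ms <- ms[sort(sample.int(nrow(ms), th$model_max_regions)), ]
    }
    seqs <- seqs_all[match(ms$probe, seqs_all$id), ]
    ga <- config$ga
    ga$seed <- config$seed
    f <- cma_fit(seqs, tibble(seq_id = ms$probe, value = ms$rho),
                 pwms, config = ga)
    jsonlite::write_json(
      list(modules = tidy(f), fitness = f$fitness, rho = f$rho,
           seed = config$seed),
      file.path(out_dir, "composite_model.json"), auto_unbox = TRUE,
      digits = NA
    )
    write_matrix_tsv(f$scores, file.path(out_dir, "composite_scores.tsv"))
    f
  })
  model_tfs <- unique(tidy(fit)$pwm_id)
  stage_log(log_path, "composite_model",
            sprintf("rho=%.3f fitness=%.3f model PWMs: %s", fit$rho,
                    fit$fitness, paste(model_tfs, collapse = ",")))

  # -- stage 7: candidate TF table -----------------------------------------
  tf_map <- read.delim(config$inputs$tf_gene_map)
  tf_table <- run_stage("tf_candidates", {
    tfs <- union(enriched_tfs, model_tfs)
    tab <- tibble(
      tf = tfs,
      gene = tf_map$gene[match(tfs, tf_map$tf)],
      enriched_fmatch = tfs %in% enriched_tfs,
      in_model = tfs %in% model_tfs
    )
    tab$expression_logFC <- deg$logFC[match(tab$gene, deg$feature)]
    write_matrix_tsv(tab, file.path(out_dir, "tf_candidates.tsv"))
    tab
  })

  # -- stage 8: key-node search with context and loops ---------------------
  keynodes <- run_stage("keynodes", {
    graph <- read_network(config$inputs$network)
    if (!is.null(config$inputs$network_nodes)) {
      nd <- as_tibble(read.delim(config$inputs$network_nodes))
      graph <- signaling_graph(graph$edges, nd)
    }
    node_gene <- setNames(graph$nodes$gene, graph$nodes$id)
    up_genes <- deg$feature[deg$p_adjusted < th$deg_alpha &
                              deg$logFC > th$context_lfc]
    context <- graph$nodes$id[!is.na(node_gene) & node_gene %in% up_genes]
    g2 <- apply_context(graph, context, discount = th$discount)
    inputs_in_graph <- intersect(tf_table$tf, graph$nodes$id)
    if (length(inputs_in_graph) == 0) {
      abort("No candidate TF maps to a network node.")
    }
    kn <- keynode_search(g2, inputs_in_graph, radius = th$radius,
                         max_path_cost = th$max_path_cost)
    write_matrix_tsv(tidy(kn), file.path(out_dir, "keynodes.tsv"))
    loops <- list()
    for (node in utils::head(kn$node, 5)) {
      fl <- find_feedback_loops(graph, node, max_len = th$radius,
                                context_nodes = context)
      if (nrow(fl) > 0) {
        fl$keynode <- node
        fl$nodes <- vapply(fl$nodes, paste, "", collapse = ">")
        loops[[node]] <- fl
      }
    }
    loop_tab <- dplyr::bind_rows(loops)
    if (nrow(loop_tab) > 0) {
      write_matrix_tsv(loop_tab, file.path(out_dir, "feedback_loops.tsv"))
    }
    list(ranking = kn, loops = loop_tab, context = context,
         gene_of = node_gene[!is.na(node_gene)])
  })
  masters <- run_stage("prioritize", {
    # methylation evidence lifted from probes to their paired genes;
    # genes without a probe carry zero methylation change
    dm_gene <- tibble(feature = deg$feature, logFC = 0)
    idx <- match(dm_gene$feature, corr$gene)
    has <- !is.na(idx)
    dm_gene$logFC[has] <- dm$logFC[match(corr$probe[idx[has]], dm$feature)]
    pr <- prioritize_regulators(
      keynodes$ranking, deg, dm_gene, gene_of = keynodes$gene_of,
      lfc_expression = th$context_lfc, lfc_methylation = 0
    )
    write_matrix_tsv(pr, file.path(out_dir, "master_regulators.tsv"))
    pr
  })
  stage_log(log_path, "keynodes",
            sprintf("%d ranked nodes, %d loops, %d prioritised masters",
                    nrow(keynodes$ranking), nrow(keynodes$loops),
                    nrow(masters)))

  # -- stage 9: candidate biomarker CpGs -----------------------------------
  selected_tfs <- intersect(union(enriched_tfs, model_tfs),
                            c(tf_table$tf[tf_table$enriched_fmatch |
                                            tf_table$in_model]))
  candidates <- run_stage("biomarker_candidates", {
    seqs_all <- read_fasta(config$inputs$sequences_enrichment)
    cand_probes <- model_set$probe
    seqs <- seqs_all[seqs_all$id %in% cand_probes, ]
    sel_pwms <- pwms[selected_tfs]
    cut_of <- setNames(enr$cutoff[match(selected_tfs, enr$pwm_id)],
                       selected_tfs)
    cut_of[is.na(cut_of)] <- 0.85
    hits <- dplyr::bind_rows(lapply(selected_tfs, function(tf) {
      m <- scan_pwm(sel_pwms[[tf]], seqs, cutoff = cut_of[[tf]])
      if (nrow(m) == 0) return(NULL)
      tibble(probe = unique(m$seq_id), tf = tf)
    }))
    master_genes <- masters$gene
    tab <- model_set
    tab$has_tf_site <- tab$probe %in% hits$probe
    tab$master_gene <- tab$gene %in% master_genes
    tab$methylation_logFC <- dm$logFC[match(tab$probe, dm$feature)]
    tab <- tab[tab$has_tf_site | tab$master_gene, ]
    write_matrix_tsv(tab, file.path(out_dir, "biomarker_candidates.tsv"))
    tab
  })
  stage_log(log_path, "biomarker_candidates",
            sprintf("%d candidate CpGs", nrow(candidates)))

  # -- stage 10: decorrelation + panel evaluation --------------------------
  panel <- run_stage("panel", {
    mc <- read_matrix_tsv(config$inputs$methylation_case, "beta")
    mn <- read_matrix_tsv(config$inputs$methylation_control, "beta")
    beta <- cbind(mc, mn[rownames(mc), , drop = FALSE])
    labels <- read.delim(config$inputs$labels)
    cand <- intersect(candidates$probe, rownames(beta))
    if (length(cand) < 2) abort("Fewer than 2 candidate markers.")
    cm <- marker_correlation(beta, cand)
    effect <- setNames(abs(candidates$methylation_logFC),
                       candidates$probe)[cand]
    kept <- decorrelate_markers(cand, cm, effect,
                                threshold = th$panel_threshold)
    beta <- beta[, labels$sample, drop = FALSE]
    ev <- evaluate_panel(beta[kept, , drop = FALSE], labels$class,
                         n_splits = th$n_splits,
                         train_fraction = th$train_fraction,
                         seed = config$seed)
    write_matrix_tsv(
      tibble(probe = kept), file.path(out_dir, "panel_markers.tsv")
    )
    write_matrix_tsv(tidy(ev), file.path(out_dir, "panel_accuracy.tsv"))
    list(markers = kept, evaluation = ev)
  })
  stage_log(log_path, "panel",
            sprintf("%d markers, mean accuracy %.3f",
                    length(panel$markers), panel$evaluation$mean_accuracy))

  summary <- list(
    seed = config$seed,
    n_deg_up = nrow(deg_sets$up), n_deg_down = nrow(deg_sets$down),
    n_diff_cpgs = length(dm_probes),
    n_neg = length(neg), n_pos = length(pos),
    n_model_loci = nrow(model_set),
    model_rho = fit$rho,
    enriched_tfs = enriched_tfs, model_tfs = model_tfs,
    top_keynode = if (nrow(keynodes$ranking) > 0) {
      keynodes$ranking$node[1]
    } else NA,
    n_candidates = nrow(candidates),
    panel = panel$markers,
    panel_accuracy = panel$evaluation$mean_accuracy
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  res <- structure(
    list(deg = deg, dm = dm, correlation = corr, enrichment = enr,
         model = fit, tf_candidates = tf_table, keynodes = keynodes,
         masters = masters, candidates = candidates, panel = panel,
         summary = summary, out_dir = out_dir),
    class = "pipeline_result"
  )
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  model rho: %.3f\n", x$summary$model_rho))
  cat(sprintf("  panel: %s\n", paste(x$summary$panel, collapse = ", ")))
  cat(sprintf("  mean accuracy: %.3f\n", x$summary$panel_accuracy))
  invisible(x)
}

# consensus-heavy count matrix for a given consensus word
consensus_counts <- function(word, depth = 12) {
  enc <- encode_dna(word)
  counts <- matrix(0, length(enc), 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[cbind(seq_along(enc), enc + 1L)] <- depth
  counts
}

write_jaspar <- function(pwms_counts, path) {
  lines <- unlist(lapply(names(pwms_counts), function(id) {
    m <- t(pwms_counts[[id]]) # 4 x L
    c(paste0(">", id),
      vapply(1:4, function(b) {
        paste0(c("A", "C", "G", "T")[b], " [ ",
               paste(m[b, ], collapse = " "), " ]")
      }, ""))
  }))
  writeLines(lines, path)
}

#' Write a coherent synthetic input bundle for the pipeline
#'
#' Generates, under one directory, every input the pipeline needs with a
#' known planted signal: a PWM pool with two planted matrices; per-CpG
#' window sequences in which half the loci carry the planted composite
#' module at the window centre; case/control methylation (planted loci
#' hypermethylated in cases) and expression (each locus's paired gene
#' anti-correlated with its methylation; TF and regulator genes
#' up-regulated in cases for the network context); probe and gene
#' annotations; a signalling network with a planted master regulator on a
#' positive feedback loop whose input TFs are the planted matrices; and
#' sample labels. Truth (planted probes, matrices, regulator) is saved to
#' `truth.json`.
#'
#' @param dir Output directory.
#' @param n_probes Number of CpG loci (default 400).
#' @param n_case,n_control Samples per class (defaults 12).
#' @param seed RNG seed.
#' @return A [pipeline_config()] pointing at the generated files, with
#'   attribute `truth`.
#' @export
sim_pipeline_bundle <- function(dir, n_probes = 400, n_case = 12,
                                n_control = 12, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  planted_words <- c(P1 = "TGACTCAGC", P2 = "CCGGAAGTG")
  decoy_ids <- sprintf("D%d", 1:6)
  words <- c(planted_words,
             setNames(vapply(decoy_ids, function(i) {
               paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE),
                     collapse = "")
             }, ""), decoy_ids))
  counts <- lapply(words, consensus_counts)
  names(counts) <- c(names(planted_words), decoy_ids)
  pwm_path <- file.path(dir, "pwms.jaspar")
  write_jaspar(counts, pwm_path)
  pwms <- read_pwms(pwm_path, "jaspar")

  # 500 bp windows, module planted at the centre of half the loci
  seqs500 <- sim_background(n_probes, 500, seed = seed + 1, prefix = "cg")
  planted <- sim_planted_module(seqs500, pwms[names(planted_words)],
                                sigma = 15, fraction = 0.5,
                                seed = seed + 2, center = 250)
  seqs500 <- planted$seqs
  # 200 bp windows are the central slice of the 500 bp windows
  seqs200 <- seq_set(seqs500$id, substr(seqs500$seq, 151, 350))
  write_fasta(seqs500, file.path(dir, "windows_500.fasta"))
  write_fasta(seqs200, file.path(dir, "windows_200.fasta"))
  bg <- sim_background(150, 200, seed = seed + 3, prefix = "bg")
  write_fasta(bg, file.path(dir, "background_200.fasta"))

  probes <- seqs500$id
  is_planted <- planted$labels$present
  n <- n_case + n_control
  cls <- c(rep("case", n_case), rep("control", n_control))
  samples <- sprintf("s%02d", seq_len(n))

  # methylation: planted loci hypermethylated in cases
  base <- matrix(rnorm(n_probes * n, 0.15, 0.04), n_probes, n)
  shift <- outer(as.numeric(is_planted) * 0.45,
                 as.numeric(cls == "case"))
  beta <- pmin(pmax(base + shift, 0.01), 0.99)
  dimnames(beta) <- list(probes, samples)

  # expression: one gene per probe, anti-correlated with its beta
  genes <- paste0("g_", probes)
  expr <- 8 - 5 * beta + matrix(rnorm(n_probes * n, 0, 0.3), n_probes, n)
  dimnames(expr) <- list(genes, samples)
  # TF genes expressed flat; the regulator's own gene up-regulated in
  # cases (the self-amplifying loop), making it the context molecule
  extra_genes <- c(paste0("gene_", names(planted_words)), "gene_REG")
  extra <- matrix(rnorm(length(extra_genes) * n, 2, 0.2),
                  length(extra_genes), n)
  dimnames(extra) <- list(extra_genes, samples)
  extra["gene_REG", cls == "case"] <- extra["gene_REG", cls == "case"] * 4
  expr <- rbind(expr, extra)
  expr <- pmax(expr, 0.01)

  case_idx <- cls == "case"
  write_matrix_tsv(beta[, case_idx], file.path(dir, "meth_case.tsv"))
  write_matrix_tsv(beta[, !case_idx], file.path(dir, "meth_control.tsv"))
  write_matrix_tsv(expr[, case_idx], file.path(dir, "expr_case.tsv"))
  write_matrix_tsv(expr[, !case_idx], file.path(dir, "expr_control.tsv"))

  # annotations: probes spaced far apart; paired gene span adjacent
  ann <- tibble(probe = probes, chrom = "chr1",
                pos = 10000L + seq_len(n_probes) * 10000L)
  gann <- tibble(gene = genes, chrom = "chr1",
                 start = ann$pos + 500L, end = ann$pos + 1500L)
  write_matrix_tsv(ann, file.path(dir, "probes.tsv"))
  write_matrix_tsv(gann, file.path(dir, "genes.tsv"))

  # network: inputs are the planted TFs; regulator on a positive loop
  net <- sim_network(n_nodes = 40, planted = TRUE, feedback = TRUE,
                     n_inputs = length(planted_words), seed = seed + 4,
                     input_ids = names(planted_words))
  # annotate TF nodes with their genes so context mapping works
  net$graph$nodes$gene[match(names(planted_words), net$graph$nodes$id)] <-
    paste0("gene_", names(planted_words))
  write_network(net$graph, file.path(dir, "network.tsv"))
  # regulatory edge flags are not part of the edge-list format; gene-kind
  # nodes drive loop detection instead
  nodes_path <- file.path(dir, "network_nodes.tsv")
  write_matrix_tsv(net$graph$nodes, nodes_path)

  tf_map <- tibble(tf = c(names(planted_words), decoy_ids),
                   gene = paste0("gene_", c(names(planted_words), decoy_ids)))
  write_matrix_tsv(tf_map, file.path(dir, "tf_gene_map.tsv"))
  write_matrix_tsv(tibble(sample = samples, class = cls),
                   file.path(dir, "labels.tsv"))

  truth <- list(planted_probes = probes[is_planted],
                planted_pwms = names(planted_words),
                regulator = net$truth$regulator,
                seed = seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg <- pipeline_config(
    inputs = list(
      expression_case = file.path(dir, "expr_case.tsv"),
      expression_control = file.path(dir, "expr_control.tsv"),
      methylation_case = file.path(dir, "meth_case.tsv"),
      methylation_control = file.path(dir, "meth_control.tsv"),
      probe_annotation = file.path(dir, "probes.tsv"),
      gene_annotation = file.path(dir, "genes.tsv"),
      sequences_enrichment = file.path(dir, "windows_200.fasta"),
      sequences_model = file.path(dir, "windows_500.fasta"),
      background_sequences = file.path(dir, "background_200.fasta"),
      pwms = pwm_path,
      network = file.path(dir, "network.tsv"),
      network_nodes = nodes_path,
      tf_gene_map = file.path(dir, "tf_gene_map.tsv"),
      labels = file.path(dir, "labels.tsv")
    ),
    ga = cma_ga_config(population = 20, generations = 15, n_modules = 2,
                       max_pwms = 3, seed = seed),
    seed = seed
  )
  attr(cfg, "truth") <- truth
  cfg
}
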
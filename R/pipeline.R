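# Command-line style front end: configuration, subcommand dispatch,
# provenance records and report assembly.  Results are written as TSV/JSON
# pairs so runs can be diffed; all stages are deterministic given the
# configured seeds.

#' Build a pipeline configuration
#'
#' Defaults mirror the analysis parameters used throughout the package:
#' 3000 bp promoter and downstream windows, 1000 bp overlap gap, 200 bp
#' state bins, 10000 bootstrap trials, DE thresholds adjusted p < 0.05 and
#' |log2FC| > 1.5, gene-set size bounds 5-500.  Values from a YAML config
#' file override the defaults, and arguments in `...` override the file.
#'
#' @param config_file Optional YAML file with configuration keys.
#' @param ... Named overrides (highest precedence).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(config_file = NULL, ...) {
  cfg <- list(
    out_dir = "peaksets_out",
    genome = NULL,               # BED12 gene models
    peaks = NULL,                # named list: sample id -> peak file
    segmentation = NULL,         # 4-column state BED
    gene_sets = NULL,            # named list: set name -> id list file
    expression = NULL,           # expression TSV
    expression_sets = NULL,      # named list of id list files for set tests
    groups = NULL,               # two group sizes, e.g. c(3, 3)
    promoter_window = 3000,
    downstream_window = 3000,
    max_gap = 1000,
    bin_size = 200,
    bootstrap_B = 10000,
    seed = 1,
    alpha = 0.05,
    lfc_threshold = 1.5,
    set_min = 5,
    set_max = 500,
    quiet = FALSE,
    sim = list(n_genes = 500, n_chromosomes = 1, n_peaks = 2000, rho = 3,
               set_sizes = c(45, 54), n_samples = 6, n_de_genes = 20,
               n_null_genes = 500, de_effect = 2, de_sigma = 0.25))
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) stop("config file not found: ", config_file)
    file_cfg <- yaml::read_yaml(config_file)
    for (k in names(file_cfg)) {
      if (k == "sim" && is.list(file_cfg$sim)) {
        cfg$sim[names(file_cfg$sim)] <- file_cfg$sim
      } else {
        cfg[[k]] <- file_cfg[[k]]
      }
    }
  }
  dots <- list(...)
  for (k in names(dots)) {
    if (k == "sim" && is.list(dots$sim)) {
      cfg$sim[names(dots$sim)] <- dots$sim
    } else {
      cfg[[k]] <- dots[[k]]
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

.SUBCOMMANDS <- c("annotate-peaks", "venn", "feature-test", "state-profile",
                  "bootstrap-enrich", "expr-cluster", "diff-expr",
                  "geneset-test", "simulate", "run-all")

log_stage <- function(cfg, fmt, ...) {
  if (!isTRUE(cfg$quiet)) message(sprintf(paste0("[peaksets] ", fmt), ...))
}

# validate that every input file a subcommand needs exists; enumerate all
# failures before any computation or output
validate_inputs <- function(cfg, need) {
  problems <- character(0)
  for (field in need) {
    paths <- cfg[[field]]
    if (is.null(paths)) {
      problems <- c(problems, sprintf("config field '%s' is required", field))
      next
    }
    for (p in unlist(paths)) {
      if (!file.exists(p)) {
        problems <- c(problems, sprintf("%s: file not found: %s", field, p))
      }
    }
  }
  if (cfg$bootstrap_B < 100) {
    problems <- c(problems, "bootstrap_B must be >= 100 for reporting runs")
  }
  if (length(problems)) {
    stop("configuration invalid:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(TRUE)
}

write_provenance <- function(cfg, subcommand, out_dir, extra = list()) {
  keep <- cfg[setdiff(names(cfg), "quiet")]
  rec <- c(list(subcommand = subcommand,
                package = "peaksets",
                version = as.character(utils::packageVersion("peaksets")),
                seed = cfg$seed),
           list(config = keep), extra)
  jsonlite::write_json(rec, file.path(out_dir, paste0(subcommand, ".provenance.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

#' Run a pipeline subcommand
#'
#' Dispatches one of the pipeline stages: `simulate` (write synthetic
#' inputs), `annotate-peaks`, `venn`, `feature-test`, `state-profile`,
#' `bootstrap-enrich`, `expr-cluster`, `diff-expr`, `geneset-test`, or
#' `run-all` (the whole downstream workflow).  Every run validates its
#' inputs up front, writes results plus a machine-readable provenance
#' record into the output directory, and is deterministic given the
#' configured seeds.
#'
#' @param name Subcommand name.
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the files written.
#' @export
run_subcommand <- function(name, config = pipeline_config()) {
  if (!name %in% .SUBCOMMANDS) {
    stop("unknown subcommand '", name, "'; available: ",
         paste(.SUBCOMMANDS, collapse = ", "))
  }
  t0 <- Sys.time()
  out <- switch(name,
    "simulate" = stage_simulate(config),
    "annotate-peaks" = stage_annotate(config),
    "venn" = stage_venn(config),
    "feature-test" = stage_feature_test(config),
    "state-profile" = stage_state_profile(config),
    "bootstrap-enrich" = stage_bootstrap(config),
    "expr-cluster" = stage_expr_cluster(config),
    "diff-expr" = stage_diff_expr(config),
    "geneset-test" = stage_geneset_test(config),
    "run-all" = stage_run_all(config))
  log_stage(config, "%s finished in %.1f s", name,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(out)
}

stage_simulate <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- cfg$sim
  seed <- as.integer(cfg$seed)
  log_stage(cfg, "simulate: %d genes, %d peaks/sample", s$n_genes, s$n_peaks)
  genome <- generate_genome(n_genes = s$n_genes,
                            n_chromosomes = s$n_chromosomes, seed = seed)
  gene_ids <- genome$annotation$genes$gene_id
  sets <- with_seed(seed + 1L, list(
    setA = gene_set("setA", sample(gene_ids, s$set_sizes[1])),
    setB = gene_set("setB", sample(gene_ids, s$set_sizes[2]))))
  pk <- list(
    sampleA = generate_peaks(genome$annotation, n_peaks = s$n_peaks,
                             rho = s$rho, gene_set = sets$setA,
                             sample_id = "sampleA", seed = seed + 2L),
    sampleB = generate_peaks(genome$annotation, n_peaks = s$n_peaks,
                             rho = s$rho, gene_set = sets$setA,
                             sample_id = "sampleB", seed = seed + 3L))
  seg <- generate_segmentation(genome$annotation, bin_size = cfg$bin_size,
                               seed = seed + 4L)
  expr <- generate_expression(n_samples = s$n_samples,
                              n_de_genes = s$n_de_genes,
                              n_null_genes = s$n_null_genes,
                              de_effect = s$de_effect, de_sigma = s$de_sigma,
                              groups = NULL, seed = seed + 5L)
  files <- list(
    genome = file.path(cfg$out_dir, "genome.bed"),
    peaks_sampleA = file.path(cfg$out_dir, "peaks_sampleA.narrowPeak"),
    peaks_sampleB = file.path(cfg$out_dir, "peaks_sampleB.narrowPeak"),
    segmentation = file.path(cfg$out_dir, "segmentation.bed"),
    expression = file.path(cfg$out_dir, "expression.tsv"),
    geneset_setA = file.path(cfg$out_dir, "geneset_setA.txt"),
    geneset_setB = file.path(cfg$out_dir, "geneset_setB.txt"),
    expr_set_epithelial = file.path(cfg$out_dir, "expr_set_epithelial.txt"),
    expr_set_mesenchymal = file.path(cfg$out_dir, "expr_set_mesenchymal.txt"),
    groups = file.path(cfg$out_dir, "groups.txt"),
    truth = file.path(cfg$out_dir, "truth.json"))
  write_bed12(genome$annotation, files$genome)
  write_narrowpeak(pk$sampleA$peaks, files$peaks_sampleA)
  write_narrowpeak(pk$sampleB$peaks, files$peaks_sampleB)
  write_segmentation(seg$segmentation, files$segmentation)
  write_expression(expr$matrix, files$expression)
  write_gene_set(sets$setA, files$geneset_setA)
  write_gene_set(sets$setB, files$geneset_setB)
  blocks <- expr$truth$blocks
  writeLines(names(blocks)[blocks == "epithelial-like"],
             files$expr_set_epithelial)
  writeLines(names(blocks)[blocks == "mesenchymal-like"],
             files$expr_set_mesenchymal)
  writeLines(expr$truth$group_labels, files$groups)
  jsonlite::write_json(
    list(seed = seed, enriched_set = "setA", rho = s$rho,
         set_sizes = s$set_sizes,
         peak_truth = lapply(pk, function(p) p$truth$peaks),
         de_genes = expr$truth$de_genes,
         blocks = as.list(expr$truth$blocks),
         group_labels = expr$truth$group_labels),
    files$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(cfg, "simulate", cfg$out_dir)
  files
}

# shared loaders ------------------------------------------------------------

load_annotation <- function(cfg) read_gene_models(cfg$genome)

load_annotated_sets <- function(cfg, annotation) {
  params <- annotation_params(cfg$promoter_window, cfg$downstream_window)
  lapply(stats::setNames(names(cfg$peaks), names(cfg$peaks)), function(sid) {
    ps <- read_narrowpeak(cfg$peaks[[sid]], sample_id = sid)
    classify_peaks(ps, annotation, params)
  })
}

stage_annotate <- function(cfg) {
  validate_inputs(cfg, c("genome", "peaks"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  annotation <- load_annotation(cfg)
  ann_sets <- load_annotated_sets(cfg, annotation)
  files <- list()
  for (sid in names(ann_sets)) {
    f <- file.path(cfg$out_dir, sprintf("annotated_%s.tsv", sid))
    write_annotated_peaks(ann_sets[[sid]], f)
    fd <- feature_distribution(ann_sets[[sid]])
    fdf <- data.frame(feature = names(fd$counts), count = fd$counts,
                      fraction = fd$fractions, row.names = NULL)
    f2 <- file.path(cfg$out_dir, sprintf("feature_distribution_%s.tsv", sid))
    utils::write.table(fdf, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[sid]] <- f
    files[[paste0(sid, "_distribution")]] <- f2
  }
  write_provenance(cfg, "annotate-peaks", cfg$out_dir)
  files
}

stage_venn <- function(cfg) {
  validate_inputs(cfg, "peaks")
  if (length(cfg$peaks) < 2) stop("venn needs at least two peak files")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  sets <- lapply(names(cfg$peaks), function(sid) {
    read_narrowpeak(cfg$peaks[[sid]], sample_id = sid)
  })
  ov <- cluster_overlapping(sets, max_gap = cfg$max_gap)
  f <- file.path(cfg$out_dir, "venn.tsv")
  write_overlap_table(ov, f, json_path = file.path(cfg$out_dir, "venn.json"))
  write_provenance(cfg, "venn", cfg$out_dir)
  list(venn = f)
}

stage_feature_test <- function(cfg) {
  validate_inputs(cfg, c("genome", "peaks", "gene_sets"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  annotation <- load_annotation(cfg)
  ann_sets <- load_annotated_sets(cfg, annotation)
  files <- list()
  for (sid in names(ann_sets)) {
    bg <- feature_distribution(ann_sets[[sid]])
    for (sname in names(cfg$gene_sets)) {
      gs <- read_gene_set(cfg$gene_sets[[sname]], name = sname)
      sd <- feature_distribution(ann_sets[[sid]], restrict_to = gs)
      tab <- hypergeom_feature_tests(sd, bg)
      f <- file.path(cfg$out_dir, sprintf("feature_test_%s_%s.tsv", sid, sname))
      utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
      files[[paste(sid, sname, sep = "_")]] <- f
    }
  }
  write_provenance(cfg, "feature-test", cfg$out_dir)
  files
}

stage_state_profile <- function(cfg) {
  validate_inputs(cfg, c("genome", "peaks", "segmentation"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  annotation <- load_annotation(cfg)
  seg <- read_segmentation(cfg$segmentation, bin_size = cfg$bin_size)
  ann_sets <- load_annotated_sets(cfg, annotation)
  gsets <- if (!is.null(cfg$gene_sets)) {
    lapply(stats::setNames(names(cfg$gene_sets), names(cfg$gene_sets)),
           function(sname) read_gene_set(cfg$gene_sets[[sname]], name = sname))
  } else NULL
  files <- list()
  for (sid in names(ann_sets)) {
    prof <- state_abundance(ann_sets[[sid]], seg)
    f <- file.path(cfg$out_dir, sprintf("state_profile_%s.tsv", sid))
    write_state_profile(prof, f)
    files[[sid]] <- f
    for (sname in names(gsets)) {
      # distal intergenic peaks of the set, as in the state-abundance
      # comparison between gene groups
      prof_s <- tryCatch(
        state_abundance(ann_sets[[sid]], seg,
                        feature_filter = "DistalIntergenic",
                        gene_set = gsets[[sname]]),
        error = function(e) NULL)
      if (is.null(prof_s)) next
      f2 <- file.path(cfg$out_dir,
                      sprintf("state_profile_%s_%s_distal.tsv", sid, sname))
      write_state_profile(prof_s, f2)
      files[[paste(sid, sname, sep = "_")]] <- f2
    }
  }
  write_provenance(cfg, "state-profile", cfg$out_dir)
  files
}

stage_bootstrap <- function(cfg) {
  validate_inputs(cfg, c("genome", "peaks", "gene_sets"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  annotation <- load_annotation(cfg)
  ann_sets <- load_annotated_sets(cfg, annotation)
  files <- list()
  for (sid in names(ann_sets)) {
    assoc <- associate_peaks(ann_sets[[sid]], annotation)
    for (sname in names(cfg$gene_sets)) {
      gs <- read_gene_set(cfg$gene_sets[[sname]], name = sname)
      res <- bootstrap_enrichment(assoc, gs, B = cfg$bootstrap_B,
                                  seed = as.integer(cfg$seed))
      f <- file.path(cfg$out_dir, sprintf("bootstrap_%s_%s.json", sid, sname))
      jsonlite::write_json(
        list(sample = sid, set = sname, set_size = res$set_size,
             observed = res$observed, B = res$B, seed = res$seed,
             fit = res$fit[c("xi", "omega", "alpha", "degenerate")],
             p_high = res$p_high, p_low = res$p_low,
             p_high_emp = res$p_high_emp, p_low_emp = res$p_low_emp,
             null_mean = mean(res$null_counts),
             null_sd = stats::sd(res$null_counts)),
        f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files[[paste(sid, sname, sep = "_")]] <- f
    }
  }
  write_provenance(cfg, "bootstrap-enrich", cfg$out_dir)
  files
}

stage_expr_cluster <- function(cfg) {
  validate_inputs(cfg, "expression")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- read_expression(cfg$expression)
  cl <- hier_cluster(m, input = "expression", k = 2)
  df <- data.frame(gene_id = rownames(m), cluster = unname(cl$clusters),
                   leaf_position = match(seq_len(nrow(m)), cl$order),
                   stringsAsFactors = FALSE)
  f <- file.path(cfg$out_dir, "expr_clusters.tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(cfg, "expr-cluster", cfg$out_dir)
  list(clusters = f)
}

read_groups <- function(cfg, n_samples) {
  g <- cfg$groups
  if (is.character(g) && length(g) == 1 && file.exists(g)) {
    g <- readLines(g)
  }
  if (is.null(g)) stop("config field 'groups' is required")
  if (length(g) == 2 && is.numeric(as.numeric(g)) &&
      !anyNA(suppressWarnings(as.numeric(g))) && length(g) != n_samples) {
    g <- rep(c("g1", "g2"), as.numeric(g))
  }
  if (length(g) != n_samples) {
    stop("group labels do not match the number of samples")
  }
  g
}

stage_diff_expr <- function(cfg) {
  validate_inputs(cfg, "expression")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- read_expression(cfg$expression)
  groups <- read_groups(cfg, ncol(m))
  de <- differential_expression(m, groups, alpha = cfg$alpha,
                                lfc_threshold = cfg$lfc_threshold)
  f <- file.path(cfg$out_dir, "diff_expr.tsv")
  write_de_table(de, f)
  log_stage(cfg, "diff-expr: %d significant of %d genes",
            sum(de$significant), nrow(de))
  write_provenance(cfg, "diff-expr", cfg$out_dir)
  list(de = f)
}

stage_geneset_test <- function(cfg) {
  validate_inputs(cfg, c("expression", "expression_sets"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- read_expression(cfg$expression)
  groups <- read_groups(cfg, ncol(m))
  de <- differential_expression(m, groups, alpha = cfg$alpha,
                                lfc_threshold = cfg$lfc_threshold)
  rows <- list()
  for (sname in names(cfg$expression_sets)) {
    gs <- read_gene_set(cfg$expression_sets[[sname]], name = sname)
    for (mode in c("directed", "undirected")) {
      r <- tryCatch(geneset_perturbation_test(de, gs, mode = mode,
                                              min_size = cfg$set_min,
                                              max_size = cfg$set_max),
                    error = function(e) NULL)
      if (is.null(r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        set = sname, mode = mode, n_set = r$n_set, t = r$t, df = r$df,
        p_value = r$p_value, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no gene set passed the size bounds")
  tab <- do.call(rbind, rows)
  f <- file.path(cfg$out_dir, "geneset_test.tsv")
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(cfg, "geneset-test", cfg$out_dir)
  list(geneset_test = f)
}

stage_run_all <- function(cfg) {
  validate_inputs(cfg, c("genome", "peaks", "segmentation", "gene_sets",
                         "expression", "expression_sets"))
  out <- list()
  out$annotate <- stage_annotate(cfg)
  out$venn <- stage_venn(cfg)
  out$feature_test <- stage_feature_test(cfg)
  out$state_profile <- stage_state_profile(cfg)
  out$bootstrap <- stage_bootstrap(cfg)
  out$expr_cluster <- stage_expr_cluster(cfg)
  out$diff_expr <- stage_diff_expr(cfg)
  out$geneset_test <- stage_geneset_test(cfg)
  write_provenance(cfg, "run-all", cfg$out_dir)
  out
}

#' Configuration pointing run-all at the files written by simulate
#'
#' Convenience helper for the simulate-then-analyse workflow: returns the
#' given config with the input fields set to the paths `simulate` writes
#' under its output directory.
#'
#' @param config A [pipeline_config()] whose `out_dir` holds simulate output.
#' @return A modified [pipeline_config()].
#' @export
config_for_simulated <- function(config) {
  d <- config$out_dir
  config$genome <- file.path(d, "genome.bed")
  config$peaks <- list(sampleA = file.path(d, "peaks_sampleA.narrowPeak"),
                       sampleB = file.path(d, "peaks_sampleB.narrowPeak"))
  config$segmentation <- file.path(d, "segmentation.bed")
  config$gene_sets <- list(setA = file.path(d, "geneset_setA.txt"),
                           setB = file.path(d, "geneset_setB.txt"))
  config$expression <- file.path(d, "expression.tsv")
  config$expression_sets <- list(
    epithelial = file.path(d, "expr_set_epithelial.txt"),
    mesenchymal = file.path(d, "expr_set_mesenchymal.txt"))
  config$groups <- file.path(d, "groups.txt")
  config
}
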
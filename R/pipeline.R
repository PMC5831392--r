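## End-to-end orchestration: simulate -> qc -> identify -> diffexp ->
## targets -> enrich -> network, with per-stage TSV reports and a run log.

.PIPELINE_KEYS <- c(
  "output_dir", "seed", "min_len", "min_reads", "mfe_threshold", "min_fold",
  "alpha", "energy_cutoff", "fdr", "score_cutoff", "hub_fraction",
  "pseudocount", "seed_mode", "sim"
)

#' Pipeline configuration
#'
#' Every stage threshold defaults to the analysis' canonical printed value:
#' minimum insert length 18, per-library read floor 10, hairpin MFE cutoff
#' -18 kcal/mol, fold-change 2, corrected alpha 0.01, canonical (>= 7 base)
#' seed matching, duplex energy cutoff -20 kcal/mol, enrichment FDR 0.1,
#' interaction combined score 0.4, hub fraction 0.05. A default run is
#' therefore the published analysis protocol applied to synthetic data.
#'
#' @param output_dir Directory for per-stage reports.
#' @param seed Integer seed driving every stage.
#' @param min_len,min_reads,mfe_threshold,min_fold,alpha,energy_cutoff,fdr,score_cutoff,hub_fraction,pseudocount
#'   Stage thresholds (see the stage functions).
#' @param seed_mode Seed matching mode, see [seed_scan()].
#' @param sim Named list of overrides passed to [sim_config()].
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(output_dir = tempfile("mirnaflow-run"),
                            seed = 1L, min_len = 18L, min_reads = 10L,
                            mfe_threshold = -18, min_fold = 2, alpha = 0.01,
                            energy_cutoff = -20, fdr = 0.1,
                            score_cutoff = 0.4, hub_fraction = 0.05,
                            pseudocount = 0.01, seed_mode = "canonical",
                            sim = list()) {
  allowed_sim <- setdiff(names(formals(sim_config)), "seed")
  unknown <- setdiff(names(sim), allowed_sim)
  if (length(unknown)) {
    stop("unknown simulation key(s): ", paste(unknown, collapse = ", "))
  }
  structure(
    list(output_dir = output_dir, seed = as.integer(seed),
         min_len = min_len, min_reads = min_reads,
         mfe_threshold = mfe_threshold, min_fold = min_fold, alpha = alpha,
         energy_cutoff = energy_cutoff, fdr = fdr,
         score_cutoff = score_cutoff, hub_fraction = hub_fraction,
         pseudocount = pseudocount, seed_mode = seed_mode, sim = sim),
    class = "pipeline_config"
  )
}

#' Serialize / deserialize a pipeline configuration
#'
#' Single human-readable YAML file; unknown keys are rejected on read.
#'
#' @param config A [pipeline_config()].
#' @param path YAML path.
#' @return `path` (write) or the configuration (read).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .PIPELINE_KEYS)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$sim)) raw$sim <- as.list(raw$sim)
  do.call(pipeline_config, raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline on a synthetic study
#'
#' Generates a synthetic study under the configured seed, then runs read
#' filtering and accounting, genome mapping, known-miRNA quantification,
#' novel-miRNA prediction, pairwise differential expression, target
#' prediction, term enrichment, and regulatory-network construction. Per-stage
#' TSVs, a YAML summary and a parameter log (with the configuration hash) are
#' written under `config$output_dir`; repeated runs with the same
#' configuration are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return The summary list (invisibly): accounting reports, count matrix,
#'   differential results per pair, target sets, enrichment table, network
#'   and hubs, plus the simulation ground truth.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  gen <- .stage("simulate", simulate_genome(scfg))
  sim <- .stage("simulate", simulate_reads(scfg, gen$annotation,
                                           gen$novel_truth))

  # qc: write FASTQ, read back, filter
  libs <- names(sim$reads)
  clean <- list()
  reports <- list()
  for (lib in libs) {
    fq <- file.path(out, paste0(lib, ".fastq"))
    write_fastq(sim$reads[[lib]], fq)
    reads <- .stage("qc", read_fastq(fq))
    res <- .stage("qc", filter_reads(reads, scfg$adapter3, scfg$adapter5,
                                     min_len = config$min_len, library = lib))
    clean[[lib]] <- res$clean
    reports[[lib]] <- res$report
    write_collapsed_fasta(res$clean, file.path(out, paste0(lib, "_clean.fa")))
  }

  # mapping
  for (lib in libs) {
    mp <- .stage("map", map_reads(clean[[lib]], gen$genome))
    reports[[lib]]$mapped_reads <- mp$mapped_reads
    reports[[lib]]$mapped_percent <- mp$mapped_percent
  }
  write_accounting_tsv(reports, file.path(out, "accounting.tsv"))
  for (lib in libs) {
    v <- validate_accounting(reports[[lib]])
    if (!v$pass) stop("pipeline stage 'qc' failed: accounting inconsistent in ",
                      lib, call. = FALSE)
  }

  # known miRNA quantification
  known <- .stage("identify", assign_known(clean, gen$annotation,
                                           min_reads = config$min_reads))
  cm <- known$counts
  utils::write.table(
    data.frame(mirna_id = rownames(cm$counts), cm$counts,
               check.names = FALSE),
    file.path(out, "counts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  # novel prediction from pooled unassigned reads
  assigned_seqs <- unique(known$assignments$seq)
  pooled <- do.call(rbind, lapply(libs, function(lib)
    as.data.frame(clean[[lib]])))
  pooled <- pooled[!pooled$seq %in% assigned_seqs, , drop = FALSE]
  novel <- if (nrow(pooled)) {
    .stage("identify", predict_novel(
      clean_read_set(pooled$seq, pooled$count), gen$genome,
      mfe_threshold = config$mfe_threshold))
  } else {
    .empty_candidates()
  }
  utils::write.table(novel, file.path(out, "novel_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # differential expression over all library pairs
  pairs <- utils::combn(libs, 2, simplify = FALSE)
  de <- list()
  de_summary <- list()
  for (p in pairs) {
    key <- paste(p, collapse = "_vs_")
    res <- .stage("diffexp", call_differential(
      cm, p, min_fold = config$min_fold, alpha = config$alpha,
      pseudocount = config$pseudocount))
    de[[key]] <- res
    de_summary[[key]] <- summary(res)
    utils::write.table(as.data.frame(res),
                       file.path(out, paste0("de_", key, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # target prediction for differentially expressed miRNAs
  de_ids <- sort(unique(unlist(lapply(de, function(r)
    r$mirna_id[r$significant]))))
  mat <- gen$annotation$matures
  de_seqs <- stats::setNames(mat$seq, mat$mature_id)[de_ids]
  de_seqs <- de_seqs[!is.na(de_seqs)]
  genes <- sprintf("gene%03d", seq_len(100L))
  tx <- .stage("targets", simulate_transcripts(scfg, de_seqs, genes))
  targets <- .stage("targets", predict_targets(
    de_seqs, tx$transcripts, energy_cutoff = config$energy_cutoff,
    mode = config$seed_mode))
  utils::write.table(targets$sites, file.path(out, "target_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # enrichment of candidate targets
  tables <- .stage("enrich", simulate_annotation_tables(
    scfg, genes,
    candidates = if (length(targets$union) >= 4) targets$union else NULL))
  background <- tables$fpkm$gene_id[tables$fpkm$fpkm > 1]
  candidates <- tables$truth$candidates
  enr <- .stage("enrich", enrich(candidates, tables$go, background,
                                 fdr_cutoff = config$fdr))
  utils::write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # regulatory network over predicted targets and the interaction table
  target_sets <- if (length(targets$targets)) targets$targets else
    stats::setNames(list(tables$truth$candidates), "mirna-set")
  net <- .stage("network", build_network(target_sets, tables$ppi,
                                         score_cutoff = config$score_cutoff))
  hubs <- if (nrow(net$nodes)) {
    .stage("network", find_hubs(net, fraction = config$hub_fraction))
  } else {
    list(hub_genes = character(), hub_mirnas = character())
  }
  export_network(net, file.path(out, "network"))

  summary <- list(
    libraries = libs,
    clean_reads = vapply(reports, function(r) r$clean_reads, numeric(1)),
    de = lapply(de_summary, function(s)
      list(tested = s$tested, significant = s$significant,
           up_in_a = s$up_in_a, up_in_b = s$up_in_b)),
    n_novel_candidates = nrow(novel),
    n_candidate_targets = length(targets$union),
    n_enriched_terms = sum(enr$significant),
    network_nodes = nrow(net$nodes),
    hub_genes = hubs$hub_genes,
    hub_mirnas = hubs$hub_mirnas
  )
  yaml::write_yaml(summary, file.path(out, "summary.yaml"))

  cfg_path <- file.path(out, "config.yaml")
  write_pipeline_config(config, cfg_path)
  log_lines <- c(
    "mirnaflow run log",
    paste0("config_hash: ", unname(tools::md5sum(cfg_path))),
    paste0("seed: ", config$seed),
    paste0(
      vapply(setdiff(.PIPELINE_KEYS, c("sim", "output_dir")), function(k)
        paste0(k, ": ", format(config[[k]])), character(1))
    )
  )
  writeLines(log_lines, file.path(out, "run.log"))

  invisible(c(summary, list(
    reports = reports, counts = cm, differential = de, novel = novel,
    targets = targets, enrichment = enr, network = net, hubs = hubs,
    ground_truth = sim$ground_truth, genome = gen$genome,
    annotation = gen$annotation, novel_truth = gen$novel_truth
  )))
}
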
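## End-to-end orchestration: clean -> map -> mask -> discover -> DE ->
## targets -> anti-correlation -> TF layer -> network -> enrichment
## (-> qPCR when a Ct table is provided), from a single config.

#' Default run configuration
#'
#' Builds a RunConfig pointing at the files written by [simulate_all()]
#' (or any directory laid out the same way), with every stage threshold at
#' its default: 18-30 nt length window, 10% N, Q20 tail, expectation <= 3,
#' |FC| >= 2, P <= 0.05, r <= -0.8.
#'
#' @param datadir directory holding the input files
#' @param outdir output directory for stage tables and the run report
#' @param adapter 3' adapter sequence
#' @param samples sample IDs; default: FASTQ file stems found in `datadir`
#' @param ... overrides for any config element
#' @return a `run_config` list
#' @export
run_config <- function(datadir, outdir = file.path(datadir, "out"),
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       samples = NULL, ...) {
  if (is.null(samples)) {
    samples <- sort(sub("\\.fastq$", "",
                        basename(list.files(datadir,
                                            pattern = "\\.fastq$"))))
  }
  cfg <- list(
    datadir = datadir, outdir = outdir, samples = samples,
    fastq = stats::setNames(file.path(datadir,
                                      paste0(samples, ".fastq")), samples),
    genome = file.path(datadir, "genome.fasta"),
    reference = file.path(datadir, "mirna_reference.fasta"),
    mask = file.path(datadir, "annotation.gff3"),
    transcriptome = file.path(datadir, "transcriptome.fasta"),
    expression = file.path(datadir, "expression.tsv"),
    tf_table = file.path(datadir, "tf_table.tsv"),
    pathway_map = file.path(datadir, "pathway_map.tsv"),
    ct_table = file.path(datadir, "ct_table.tsv"),
    adapter = adapter, min_len = 18L, max_len = 30L, max_n_frac = 0.10,
    min_tail_q = 20L, flank = 80L, expectation_cutoff = 3.0,
    fc_min = 2, de_p_max = 0.05, r_max = -0.8, cor_p_max = 0.05,
    tf_r_min = 0.8, qpcr_calibrator = "NW", seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Returns problems instead of raising: threshold range checks, input-file
#' existence, and sample-column consistency are all reported together.
#'
#' @param cfg a `run_config`
#' @return character vector of problems (empty when valid)
#' @export
validate_config <- function(cfg) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (!(cfg$r_max >= -1 && cfg$r_max < 0)) {
    add("r_max must lie in [-1, 0)")
  }
  if (cfg$expectation_cutoff < 0) add("expectation_cutoff must be >= 0")
  if (cfg$fc_min < 1) add("fc_min must be >= 1")
  if (cfg$de_p_max <= 0 || cfg$de_p_max > 1) add("de_p_max out of (0, 1]")
  if (cfg$min_len < 1 || cfg$max_len < cfg$min_len) {
    add("invalid length window")
  }
  for (f in c("genome", "reference", "mask", "transcriptome",
              "expression", "tf_table", "pathway_map")) {
    if (!file.exists(cfg[[f]])) add(paste0("missing file: ", f))
  }
  for (fq in cfg$fastq) {
    if (!file.exists(fq)) add(paste0("missing FASTQ: ", fq))
  }
  if (file.exists(cfg$expression)) {
    em <- read_expression(cfg$expression)
    missing <- setdiff(cfg$samples, colnames(em))
    if (length(missing)) {
      add(paste0("expression matrix lacks sample column(s): ",
                 paste(missing, collapse = ", ")))
    }
  }
  problems
}

#' Load a run configuration from a YAML file
#' @param path YAML file with `datadir` plus any overrides
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Read a gene x sample expression matrix TSV
#' @param path TSV with a `gene_id` column and one column per sample
#' @return numeric matrix with gene rownames
#' @export
read_expression <- function(path) {
  d <- read_tsv(path)
  m <- as.matrix(d[, setdiff(names(d), "gene_id"), drop = FALSE])
  rownames(m) <- d$gene_id
  m
}

tissue_from_sample <- function(samples) {
  stats::setNames(sub("[0-9]+$", "", samples), samples)
}

#' Run the full pipeline
#'
#' Executes every stage in order, writes stage TSVs, the network exports
#' and a JSON run report (per-stage record counts, parameters, file
#' checksums) under `cfg$outdir`. Any stage failure propagates with the
#' stage name prepended.
#'
#' @param cfg a `run_config` (see [run_config()], [read_run_config()])
#' @return invisibly, a list with every stage result and the `report`
#' @export
run_all <- function(cfg) {
  problems <- validate_config(cfg)
  if (length(problems)) {
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = cfg[c("adapter", "min_len", "max_len",
                                    "max_n_frac", "min_tail_q", "flank",
                                    "expectation_cutoff", "fc_min",
                                    "de_p_max", "r_max", "cor_p_max",
                                    "tf_r_min", "seed")],
                 stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log_stage <- function(name, ...) {
    report$stages[[name]] <<- list(...)
  }

  ## clean
  cleaned <- list(); stats_rows <- list()
  stage("clean", {
    for (s in cfg$samples) {
      raw <- read_fastq(cfg$fastq[[s]], sample_id = s)
      cl <- clean_reads(raw, cfg$adapter, cfg$min_len, cfg$max_len,
                        cfg$max_n_frac, cfg$min_tail_q)
      cleaned[[s]] <- cl$reads
      stats_rows[[s]] <- cl$stats
    }
  })
  stats <- do.call(rbind, stats_rows)
  log_stage("clean", n_samples = length(cleaned),
            raw_reads = sum(stats$raw_reads),
            clean_reads = sum(stats$clean_reads),
            total_srna = sum(stats$total_srna))

  ## map
  genome <- stage("map", read_genome(cfg$genome))
  catalog <- stage("map", collapse_and_map(cleaned, genome, stats))
  write_tsv(catalog$stats, file.path(cfg$outdir, "read_stats.tsv"))
  log_stage("map", n_tags = nrow(catalog$tags),
            n_mapped_tags = sum(!catalog$tags$unmapped),
            mapped_srna = sum(catalog$stats$mapped_srna))

  ## mask
  mask <- stage("mask", read_mask(cfg$mask))
  masked <- stage("mask", mask_annotated(catalog, mask))
  write_tsv(masked$tags, file.path(cfg$outdir, "tag_catalog.tsv"))
  log_stage("mask", n_tags = nrow(masked$tags))

  ## discover
  reference <- stage("discover", read_mirna_reference(cfg$reference))
  known <- stage("discover", match_known(masked, reference))
  novel <- stage("discover", call_novel(masked, genome, known,
                                        flank = cfg$flank))
  novel$records <- assign_family(novel$records, reference)
  records <- rbind(known, novel$records)
  write_tsv(records, file.path(cfg$outdir, "mirna_table.tsv"))
  write_tsv(novel$candidates, file.path(cfg$outdir, "hairpin_report.tsv"))
  log_stage("discover", n_known = nrow(known),
            n_novel = nrow(novel$records))

  ## differential abundance
  tissue_of_sample <- tissue_from_sample(cfg$samples)
  counts <- as.matrix(records[, cfg$samples, drop = FALSE])
  rownames(counts) <- records$mirna_id
  totals <- stats::setNames(catalog$stats$mapped_srna,
                            catalog$stats$sample)[cfg$samples]
  abund <- stage("de", normalize_abundance(counts, totals))
  de <- stage("de", de_table(abund, tissue_of_sample,
                             pseudocount = 1.0, fc_min = cfg$fc_min,
                             p_max = cfg$de_p_max))
  write_tsv(de, file.path(cfg$outdir, "de_table.tsv"))
  desum <- de_summary(de)
  log_stage("de", n_tests = nrow(de), n_significant = sum(de$significant))

  ## targets
  transcripts <- stage("targets", read_genome(cfg$transcriptome))
  hits <- stage("targets", predict_targets(
    records, transcripts, cutoff = cfg$expectation_cutoff))
  write_tsv(hits, file.path(cfg$outdir, "target_hits.tsv"))
  log_stage("targets", n_hits = nrow(hits),
            n_pairs = sum(hits$best))

  ## network: anti-correlation + TF layer + assembly
  expr <- stage("network", read_expression(cfg$expression))
  validated <- stage("network", anticorrelation_filter(
    hits, abund$values, expr, r_max = cfg$r_max, p_max = cfg$cor_p_max))
  write_tsv(validated, file.path(cfg$outdir, "validated_pairs.tsv"))
  tf_table <- read_tsv(cfg$tf_table)
  tf_edges <- stage("network", tf_layer(
    intersect(tf_table$gene_id, rownames(expr)), expr,
    r_min = cfg$tf_r_min, p_max = cfg$cor_p_max))
  net <- stage("network", build_network(validated, tf_edges,
                                        tf_table$gene_id))
  export_network(net, file.path(cfg$outdir, "network"))
  log_stage("network", n_validated = sum(validated$validated),
            n_tf_edges = nrow(tf_edges), n_nodes = nrow(net$nodes),
            n_edges = nrow(net$edges))

  ## enrichment
  pathway_map <- read_tsv(cfg$pathway_map)
  network_genes <- setdiff(net$nodes$id,
                           net$nodes$id[net$nodes$type == "miRNA"])
  enr <- stage("enrich", if (length(network_genes))
    enrich_pathways(network_genes, rownames(expr), pathway_map) else
      data.frame())
  write_tsv(enr, file.path(cfg$outdir, "enrichment.tsv"))
  log_stage("enrich", n_pathways = nrow(enr),
            n_network_genes = length(network_genes))

  ## qPCR (optional)
  qpcr <- NULL
  if (!is.null(cfg$ct_table) && file.exists(cfg$ct_table)) {
    ct <- read_tsv(cfg$ct_table)
    rel <- stage("qpcr", relative_expression(
      ct, tissue_of_sample, calibrator = cfg$qpcr_calibrator))
    qpcr <- summarize_qpcr(rel, calibrator = cfg$qpcr_calibrator)
    write_tsv(qpcr, file.path(cfg$outdir, "qpcr_summary.tsv"))
    log_stage("qpcr", n_genes = length(unique(qpcr$gene_id)))
  }

  report$checksums <- vapply(
    list.files(cfg$outdir, full.names = TRUE, pattern = "\\.(tsv|sif)$"),
    function(f) unname(tools::md5sum(f)), character(1))
  names(report$checksums) <- basename(names(report$checksums))
  jsonlite::write_json(report, file.path(cfg$outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(stats = catalog$stats, catalog = masked, known = known,
                 novel = novel, records = records, abund = abund, de = de,
                 de_summary = desum, hits = hits, validated = validated,
                 tf_edges = tf_edges, network = net, enrichment = enr,
                 qpcr = qpcr, report = report))
}

#' Simulate a synthetic study and run the pipeline on it
#'
#' @param seed integer seed for the generator
#' @param dir working directory (created); data under `dir`, outputs under
#'   `dir/out`
#' @param cfg optional `synthetic_config` (its seed is overridden)
#' @param ... overrides passed to [run_config()]
#' @return list with `sim` (generator output incl. truth) and `run`
#'   (pipeline results)
#' @export
simulate_and_run <- function(seed, dir = tempfile("mirwoodnet"),
                             cfg = NULL, ...) {
  if (is.null(cfg)) cfg <- synthetic_config(seed = seed)
  cfg$seed <- as.integer(seed)
  sim <- simulate_all(cfg, dir)
  rc <- run_config(dir, adapter = cfg$adapter_seq, ...)
  run <- run_all(rc)
  list(sim = sim, run = run, config = rc)
}
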
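# End-to-end benchmark pipeline: ontology + annotations + lists in,
# enrichment, metrics, and clusters out, with a JSON summary mirroring every
# table. All randomness flows from the single config seed.

#' Run the full benchmark pipeline
#'
#' Loads (or synthesizes) an ontology and annotations, loads or generates
#' gene lists, obtains one enrichment result per list (reference ORA, or
#' ingested foreign tables), and for each result emits: significant-term
#' counts, the semantic-similarity confusion matrix with accuracy/FPR,
#' the target identification/rank report, top-20 and top-100 specificity
#' profiles, and MCL clusters of the significant terms. Every table is
#' written as TSV under `out_dir` and mirrored in a single
#' `summary.json`. Identical config + seed reproduces byte-identical
#' outputs. When no targets are supplied for a list the confusion/rank
#' stages are skipped with a notice while specificity and clustering still
#' run. Any stage error aborts with the stage name and the offending label.
#'
#' @param config a named list, or path to a JSON file holding one. Keys:
#'   \describe{
#'     \item{out_dir}{output directory (required).}
#'     \item{seed}{integer seed for every random stage (default 1).}
#'     \item{ontology}{path to an OBO file; omit to use `synthetic`.}
#'     \item{namespace}{optional namespace filter for the OBO.}
#'     \item{synthetic}{list of [synthetic_ontology_spec()] arguments used
#'       when no `ontology` path is given.}
#'     \item{annotations}{list with `path` and `format` ("gaf"/"gmt");
#'       required with `ontology`, ignored with `synthetic`.}
#'     \item{lists}{named list label -> gene-list file path, or a directory
#'       of `*.txt` lists.}
#'     \item{make_lists}{alternative generator spec: list with optional
#'       `random` (= list(sizes, replicates)) and/or `target`
#'       (= list(targets, sizes)) entries.}
#'     \item{results}{optional named list label -> list(path, term_id,
#'       p_raw, p_adj, delimiter): foreign tables ingested instead of
#'       running the reference ORA for those labels.}
#'     \item{targets}{named list label -> character vector of target term
#'       ids (merged over targets from `make_lists$target`).}
#'     \item{alpha, hi, lo, cutoff, inflation, min_count, top_n,
#'       min_cluster_size, ks}{thresholds; defaults 0.05, 0.7, 0.3, 0.5,
#'       5.0, 2, 15, 3, c(20, 100).}
#'     \item{statistic}{"hypergeometric" (default) or "ease".}
#'   }
#' @return invisibly, a list with the summary data.frame, per-label results,
#'   cluster tables, and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config), !is.null(config$out_dir))
  cfg <- utils::modifyList(
    list(seed = 1L, alpha = 0.05, hi = 0.7, lo = 0.3, cutoff = 0.5,
         inflation = 5.0, min_count = 2L, top_n = 15L, min_cluster_size = 3L,
         ks = c(20L, 100L), statistic = "hypergeometric",
         is_a_weight = 0.8, part_of_weight = 0.6),
    config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  weights <- wang_weights(cfg$is_a_weight, cfg$part_of_weight)
  log_lines <- c(sprintf("seed: %d", as.integer(cfg$seed)))

  stage <- function(name, label, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for '", label, "': ",
           conditionMessage(e), call. = FALSE))
  }

  # --- ontology + annotations ------------------------------------------
  if (!is.null(cfg$ontology)) {
    graph <- stage("ontology", cfg$ontology,
                   parse_obo(cfg$ontology, namespace = cfg$namespace))
    if (is.null(cfg$annotations))
      stop("stage 'annotations' failed for 'config': annotations required with an OBO path")
    annset <- stage("annotations", cfg$annotations$path,
                    load_annotations(cfg$annotations$path,
                                     format = cfg$annotations$format,
                                     graph = graph))
    obo_path <- cfg$ontology
  } else {
    synth_args <- c(cfg$synthetic, list(seed = as.integer(cfg$seed)))
    synth_args <- synth_args[!duplicated(names(synth_args))]
    synth <- stage("synthesize", "synthetic",
                   synthesize_ontology(do.call(synthetic_ontology_spec,
                                               synth_args)))
    graph <- synth$graph; annset <- synth$annset
    obo_path <- file.path(out_dir, "ontology.obo")
    write_obo(graph, obo_path)
    write_gaf(annset, file.path(out_dir, "annotations.gaf"))
  }
  log_lines <- c(log_lines,
                 sprintf("ontology_md5: %s", unname(tools::md5sum(obo_path))),
                 sprintf("terms: %d", nrow(graph$terms)),
                 sprintf("annotated_terms: %d", length(annset$genes_by_term)),
                 sprintf("background_genes: %d", length(annset$background)))

  # --- gene lists -------------------------------------------------------
  gene_lists <- list()
  targets <- as.list(cfg$targets %||% list())
  targets <- lapply(targets, unlist)
  if (!is.null(cfg$lists)) {
    paths <- cfg$lists
    if (length(paths) == 1L && is.null(names(paths)) && dir.exists(paths[[1]])) {
      files <- sort(list.files(paths[[1]], pattern = "\\.txt$",
                               full.names = TRUE))
      paths <- stats::setNames(as.list(files),
                               sub("\\.txt$", "", basename(files)))
    }
    for (lab in names(paths))
      gene_lists[[lab]] <- stage("read-list", lab,
                                 read_gene_list(paths[[lab]], label = lab))
  }
  if (!is.null(cfg$make_lists)) {
    ml <- cfg$make_lists
    if (!is.null(ml$random)) {
      b <- stage("make-lists", "random",
                 make_random_lists(annset$background,
                                   sizes = ml$random$sizes %||% c(500L, 200L, 100L, 50L),
                                   replicates = ml$random$replicates %||% 5L,
                                   seed = as.integer(cfg$seed)))
      gene_lists <- c(gene_lists, b$gene_lists)
    }
    if (!is.null(ml$target)) {
      b <- stage("make-lists", "target",
                 make_target_lists(annset, graph,
                                   targets = unlist(ml$target$targets),
                                   sizes = ml$target$sizes %||% c(100L, 50L),
                                   seed = as.integer(cfg$seed)))
      gene_lists <- c(gene_lists, b$gene_lists)
      targets <- utils::modifyList(targets, b$targets)
    }
  }
  if (!length(gene_lists))
    stop("stage 'lists' failed for 'config': no gene lists configured")

  # --- enrichment per list ---------------------------------------------
  results <- list()
  for (lab in names(gene_lists)) {
    fr <- cfg$results[[lab]]
    results[[lab]] <- if (!is.null(fr)) {
      schema <- result_table_schema(term_id = fr$term_id %||% "term_id",
                                    p_raw = fr$p_raw %||% "p_raw",
                                    p_adj = fr$p_adj,
                                    delimiter = fr$delimiter %||% "\t")
      stage("ingest", lab,
            read_result_table(fr$path, schema, graph, label = lab,
                              alpha = cfg$alpha))
    } else {
      stage("ora", lab,
            run_ora(gene_lists[[lab]], annset, graph,
                    min_count = cfg$min_count, statistic = cfg$statistic,
                    alpha = cfg$alpha))
    }
    write_enrichment(results[[lab]],
                     file.path(out_dir, paste0(lab, "_result.tsv")))
  }

  # --- metrics ----------------------------------------------------------
  summary_rows <- list(); rank_rows <- list(); cluster_tables <- list()
  for (lab in names(results)) {
    r <- results[[lab]]
    tg <- targets[[lab]]
    if (is.null(tg)) message("no targets for '", lab,
                             "': confusion/rank stages skipped")
    summary_rows[[lab]] <- stage("evaluate", lab,
      evaluate_results(stats::setNames(list(r), lab), tg, annset, graph,
                       weights, cfg$alpha, cfg$hi, cfg$lo, cfg$ks))
    if (!is.null(tg)) {
      tr <- target_report(r, tg, graph, cfg$alpha)
      rank_rows[[lab]] <- data.frame(
        label = lab, target = tg,
        rank = unname(ifelse(tg %in% names(tr$ranks), tr$ranks[tg], NA_real_)))
    }
    sig_terms <- r$term_id[r$p_adj < cfg$alpha]
    if (length(sig_terms)) {
      net <- stage("cluster", lab,
                   build_network(sig_terms, graph, weights, cfg$cutoff))
      cl <- stage("cluster", lab, mcl(net, inflation = cfg$inflation))
      write_network(net, file.path(out_dir, paste0(lab, "_network.tsv")))
      write_clusters(cl, graph, file.path(out_dir, paste0(lab, "_clusters.tsv")),
                     annset)
      major <- select_major_clusters(cl, cfg$top_n, cfg$min_cluster_size)
      cluster_tables[[lab]] <- annotate_clusters(cl, graph, annset)
      write_tsv_plain(cluster_tables[[lab]],
                      file.path(out_dir, paste0(lab, "_cluster_summary.tsv")))
      summary_rows[[lab]]$n_clusters <- length(cl$clusters)
      summary_rows[[lab]]$n_major_clusters <- length(major)
    } else {
      summary_rows[[lab]]$n_clusters <- 0L
      summary_rows[[lab]]$n_major_clusters <- 0L
    }
  }
  # harmonise columns (lists without targets lack the confusion columns)
  all_cols <- Reduce(union, lapply(summary_rows, names))
  summary_rows <- lapply(summary_rows, function(df) {
    for (cc in setdiff(all_cols, names(df))) df[[cc]] <- NA
    df[, all_cols, drop = FALSE]
  })
  summary_df <- do.call(rbind, summary_rows)
  rownames(summary_df) <- NULL
  write_tsv_plain(summary_df, file.path(out_dir, "summary.tsv"))
  if (length(rank_rows)) {
    ranks_df <- do.call(rbind, rank_rows); rownames(ranks_df) <- NULL
    write_tsv_plain(ranks_df, file.path(out_dir, "target_ranks.tsv"))
  } else ranks_df <- NULL

  mirror <- list(summary = summary_df,
                 target_ranks = ranks_df,
                 clusters = cluster_tables,
                 log = log_lines)
  jsonlite::write_json(mirror, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(summary = summary_df, results = results,
                 clusters = cluster_tables, targets = targets,
                 out_dir = out_dir))
}
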
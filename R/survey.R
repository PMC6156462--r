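#' Build a survey run configuration
#'
#' Flat key-value configuration for [run_survey()]; all thresholds are
#' validated here, before any work starts.
#'
#' @param out_dir Output directory (created if needed).
#' @param catalog_path Catalog TSV (defaults to the packaged fixture).
#' @param seed Integer seed for the synthetic stages.
#' @param simulate Also run the sequence-level stages (duplications,
#'   Ka/Ks, expression) on synthetic inputs generated from `seed`;
#'   without it the run is fixture-only (classification, tallies,
#'   chromosome map).
#' @param max_mature_len,min_identity,min_coverage,max_orfs,max_span
#'   Cascade and duplication thresholds.
#' @param fc_threshold,alpha,pseudocount,k_trends Expression thresholds.
#' @return Object of class `run_config` (a named list).
#' @export
survey_config <- function(out_dir, catalog_path = NULL, seed = 1L,
                          simulate = TRUE, max_mature_len = 120L,
                          min_identity = 0.8, min_coverage = 0.8,
                          max_orfs = 15L, max_span = 30000L,
                          fc_threshold = 2, alpha = 0.05, pseudocount = 1,
                          k_trends = 4L) {
  if (is.null(catalog_path))
    catalog_path <- system.file("extdata", "ghltp_table1.tsv",
                                package = "nsltp")
  stopifnot(max_mature_len > 0L, min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1, max_orfs >= 0L,
            max_span >= 0L, fc_threshold >= 1, alpha > 0, alpha < 1,
            pseudocount >= 0, k_trends >= 2L)
  structure(list(out_dir = out_dir, catalog_path = catalog_path,
                 seed = as.integer(seed), simulate = simulate,
                 max_mature_len = max_mature_len,
                 min_identity = min_identity, min_coverage = min_coverage,
                 max_orfs = max_orfs, max_span = max_span,
                 fc_threshold = fc_threshold, alpha = alpha,
                 pseudocount = pseudocount, k_trends = k_trends),
            class = "run_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Type tally report
#'
#' @param assignments Character vector of type labels (or a list of
#'   `type_assignment` objects).
#' @return List: `table` (counts by type, decreasing), `n_groups`
#'   (distinct non-unknown labels), `largest` (label of the largest
#'   group, `NA` when empty).
#' @export
report_type_tally <- function(assignments) {
  if (is.list(assignments))
    assignments <- vapply(assignments, `[[`, "", "type_label")
  tab <- sort(table(assignments), decreasing = TRUE)
  tab <- setNames(as.integer(tab), names(tab))
  groups <- setdiff(names(tab), "unknown")
  list(table = tab, n_groups = length(groups),
       largest = if (length(tab)) names(tab)[[1L]] else NA_character_)
}

#' Run the full family survey and write a report bundle
#'
#' Orchestrates the survey in the published order — identify (on a
#' synthetic candidate pool), classify, map to chromosomes, call
#' duplications with Ka/Ks, analyse expression — and writes
#' tab-separated reports plus a checksum manifest.  Deterministic for a
#' fixed config.
#'
#' @param config A [survey_config()].
#' @return Invisibly, the manifest data frame (`file`, `md5`).
#' @export
run_survey <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$catalog_path))
    stop("missing input: ", config$catalog_path)
  catalog <- read_catalog(config$catalog_path)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) files <<- c(files, write_tsv(
    df, file.path(config$out_dir, name)))

  # classification from catalog patterns
  labels <- vapply(catalog$ecm_pattern,
                   function(p) classify_type(p)$type_label, "")
  emit(data.frame(gene_name = catalog$gene_name, gene_id = catalog$gene_id,
                  ecm_pattern = catalog$ecm_pattern, type = unname(labels),
                  stringsAsFactors = FALSE), "classification.tsv")
  tally <- report_type_tally(unname(labels))
  emit(data.frame(type = names(tally$table), n = tally$table,
                  row.names = NULL), "type_tally.tsv")

  dist <- chromosome_distribution(catalog)
  emit(data.frame(chromosome = names(dist$counts), n = dist$counts,
                  row.names = NULL), "chromosome_distribution.tsv")
  emit(data.frame(gene_name = dist$unplaced), "unplaced.tsv")

  if (isTRUE(config$simulate)) {
    spec <- simulation_spec(seed = config$seed)
    pool <- gen_candidate_pool(spec)
    rep_ <- filter_candidates(pool$records,
                              max_mature_len = config$max_mature_len)
    emit(data.frame(
      stage = c("input", "no_signal", "long_mature", "missing_cys",
                "no_start_met", "no_domain", "survivors"),
      n = c(rep_$n_input, rep_$removed_no_signal, rep_$removed_long_mature,
            rep_$removed_missing_cys, rep_$removed_no_start_met,
            rep_$removed_no_domain, length(rep_$survivors))),
      "filter_report.tsv")

    layout <- gen_genome_layout(spec)
    events <- call_duplications(layout$catalog, layout$cds_by_gene,
                                min_identity = config$min_identity,
                                min_coverage = config$min_coverage,
                                max_orfs = config$max_orfs,
                                max_span = config$max_span,
                                all_orfs = layout$all_orfs)
    if (nrow(events)) {
      kaks <- lapply(strsplit(events$members, ","), function(ms) {
        a <- layout$cds_by_gene[[ms[[1L]]]]
        b <- layout$cds_by_gene[[ms[[2L]]]]
        if (nchar(a) == nchar(b)) ng86_kaks(a, b)
        else list(ka = NA_real_, ks = NA_real_, ratio = NA_real_)
      })
      events$ka <- vapply(kaks, function(x) x$ka, 1)
      events$ks <- vapply(kaks, function(x) x$ks, 1)
      events$ka_ks <- vapply(kaks, function(x) x$ratio, 1)
    }
    emit(events, "duplications.tsv")

    expr <- gen_expression(spec)
    clusters <- trend_cluster(expr$em, k = config$k_trends,
                              seed = config$seed,
                              cultivar = spec$expression_plan$cultivars[[2L]])
    emit(data.frame(gene_id = names(clusters), cluster = unname(clusters),
                    stringsAsFactors = FALSE), "trend_clusters.tsv")
    de <- differential(expr$em, spec$expression_plan$cultivars[[1L]],
                       spec$expression_plan$cultivars[[2L]],
                       fc_threshold = config$fc_threshold,
                       alpha = config$alpha,
                       pseudocount = config$pseudocount)
    emit(de, "differential.tsv")
  }

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  invisible(manifest)
}
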
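#' Pipeline configuration
#'
#' Collects every threshold of the analysis in one place, with the
#' published protocol's values as defaults: 1000 nt contig filter, two
#' detection profiles with >= 2 spacers, 70% RMS hit coverage, 4-gene RMS
#' pairing/merging windows, 1.5-fold enrichment, spacer search at word
#' size 7 / E-value 0.1, repeat-reference matching at E-value 0.01,
#' 5-gene cas adjacency window, LCA top-score fraction 0.1.
#'
#' @param min_contig_len Contig length filter.
#' @param profiles Detection profiles ([default_profiles()]).
#' @param scheme Spacer-search [scoring_scheme()].
#' @param rms_min_coverage RMS hit coverage cutoff.
#' @param rms_max_gene_distance REase-MTase pairing window.
#' @param rms_merge_window Cluster merge window.
#' @param enrichment_factor Fold-change for enrichment calls.
#' @param cas_max_gene_gap Array-cas adjacency window.
#' @param repeat_ref_max_evalue Repeat-reference match cutoff.
#' @param lca_top_score_fraction LCA bit-score retention band.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_contig_len = 1000L,
                            profiles = default_profiles(),
                            scheme = scoring_scheme(),
                            rms_min_coverage = 0.70,
                            rms_max_gene_distance = 4L,
                            rms_merge_window = 4L,
                            enrichment_factor = 1.5,
                            cas_max_gene_gap = 5L,
                            repeat_ref_max_evalue = 0.01,
                            lca_top_score_fraction = 0.1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Analyze one sample
#'
#' Runs contig filtering, cas identification, consensus CRISPR detection,
#' spacer/repeat collection, RMS calling and cpm normalization for one
#' sample's inputs (in-memory objects, as produced by [simulate_sample()]
#' or the readers in this package).
#'
#' @param contigs Named character vector of contig sequences.
#' @param genes Gene table ([read_gene_table()] layout).
#' @param domain_hits Domain-hit table.
#' @param depths Named list of depth vectors.
#' @param total_mapped_bp Total mapped basepairs (default: sum of depths).
#' @param config A [pipeline_config()].
#' @param sample_id Sample label.
#' @return List of class `sample_result`: arrays, spacers, repeats,
#'   cas_genes, cas_loci, rms_genes, rms_systems, rms_clusters,
#'   contig_cpm, feature_cpm, gc, sample_id.
#' @export
analyze_sample <- function(contigs, genes, domain_hits, depths,
                           total_mapped_bp = NULL,
                           config = pipeline_config(),
                           sample_id = "sample") {
  contigs <- filter_contigs(contigs, config$min_contig_len)

  cas_genes <- identify_cas_genes(domain_hits)
  cas_loci <- call_cas_loci(cas_genes, genes,
                            max_gene_gap = config$cas_max_gene_gap)
  cas_contigs <- unique(cas_loci$contig_id)

  arrays <- detect_consensus(contigs, config$profiles, cas_contigs)
  arrays <- link_arrays_to_cas(arrays, cas_loci, genes,
                               max_gene_gap = config$cas_max_gene_gap)
  fa <- write_array_fastas(arrays, sample_id)

  rms_genes <- filter_rms_hits(domain_hits[!is.na(role) & role != ""],
                               genes, config$rms_min_coverage)
  rms_systems <- pair_complete_systems(rms_genes,
                                       config$rms_max_gene_distance)
  rms_clusters <- merge_into_clusters(rms_systems, config$rms_merge_window)

  cc <- contig_cpm_table(depths, total_mapped_bp)
  feats <- list()
  if (length(arrays)) {
    feats$crispr <- data.table::data.table(
      feature_id = "CRISPR",
      contig = vapply(arrays, `[[`, character(1), "contig_id"))
  }
  if (nrow(rms_clusters)) {
    feats$rms <- data.table::data.table(
      feature_id = paste0("RMS_", rms_clusters$rms_type),
      contig = rms_clusters$contig_id)
  }
  if (nrow(cas_genes)) {
    cg <- merge(cas_genes, genes[, list(gene_id, contig_id)], by = "gene_id")
    feats$cas <- data.table::data.table(feature_id = cg$cas_name,
                                        contig = cg$contig_id)
  }
  feature_cpm <- aggregate_feature_cpm(
    data.table::rbindlist(feats), cc)

  gc <- gc_distribution(contigs)

  structure(list(sample_id = sample_id, arrays = arrays,
                 spacers = fa$spacers, repeats = fa$repeats,
                 cas_genes = cas_genes, cas_loci = cas_loci,
                 rms_genes = rms_genes, rms_systems = rms_systems,
                 rms_clusters = rms_clusters, contig_cpm = cc,
                 feature_cpm = feature_cpm, gc = gc,
                 total_mapped_bp = if (is.null(total_mapped_bp))
                   sum(cc$coverage * cc$length) else total_mapped_bp),
            class = "sample_result")
}

#' Run the full pipeline over a sample manifest
#'
#' The manifest is a data.frame with one row per sample and columns
#' `sample_id`, `role` ("sponge" or "seawater") and the input paths
#' `contigs`, `genes`, `domain_hits`, `depth`, and optionally
#' `total_mapped_bp` (single-number text file). All referenced files must
#' exist before any computation starts. Results are written under
#' `outdir/<sample_id>/` plus combined summary tables; the run log
#' records every threshold used.
#'
#' @param manifest Manifest data.frame (see above).
#' @param outdir Output directory.
#' @param config A [pipeline_config()].
#' @return Invisibly, the list of `sample_result` objects (named by
#'   sample).
#' @export
run_pipeline <- function(manifest, outdir, config = pipeline_config()) {
  manifest <- data.table::as.data.table(manifest)
  req <- c("sample_id", "role", "contigs", "genes", "domain_hits", "depth")
  if (!all(req %in% names(manifest))) {
    stop("manifest needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(manifest$sample_id)) stop("duplicate sample_id")
  if (nrow(manifest) < 1L) stop("manifest is empty")
  paths <- unlist(manifest[, req[-(1:2)], with = FALSE])
  paths <- c(paths, if ("total_mapped_bp" %in% names(manifest))
    stats::na.omit(manifest$total_mapped_bp))
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    stop("missing input file(s): ", paste(missing_files, collapse = ", "))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    contigs <- read_fasta(manifest$contigs[i])
    genes <- read_gene_table(manifest$genes[i])
    hits <- read_domain_hits(manifest$domain_hits[i])
    contigs_f <- filter_contigs(contigs, config$min_contig_len)
    depths <- read_depth_table(manifest$depth[i],
                               stats::setNames(nchar(contigs_f),
                                               names(contigs_f)))
    tmb <- NULL
    if ("total_mapped_bp" %in% names(manifest) &&
        !is.na(manifest$total_mapped_bp[i])) {
      tmb <- as.numeric(readLines(manifest$total_mapped_bp[i])[1L])
    }
    res <- analyze_sample(contigs, genes, hits, depths, tmb, config, sid)
    results[[sid]] <- res

    sdir <- file.path(outdir, sid)
    dir.create(sdir, showWarnings = FALSE)
    data.table::fwrite(arrays_to_table(res$arrays),
                       file.path(sdir, "arrays.tsv"), sep = "\t")
    if (length(res$spacers)) {
      write_fasta(res$spacers, file.path(sdir, "spacers.fasta"))
    }
    if (length(res$repeats)) {
      write_fasta(res$repeats, file.path(sdir, "repeats.fasta"))
    }
    data.table::fwrite(res$cas_loci, file.path(sdir, "cas_loci.tsv"),
                       sep = "\t")
    data.table::fwrite(res$rms_clusters,
                       file.path(sdir, "rms_clusters.tsv"), sep = "\t")
    data.table::fwrite(res$contig_cpm, file.path(sdir, "contig_cpm.tsv"),
                       sep = "\t")
    data.table::fwrite(res$feature_cpm, file.path(sdir, "feature_cpm.tsv"),
                       sep = "\t")
    data.table::fwrite(res$gc$histogram, file.path(sdir, "gc_hist.tsv"),
                       sep = "\t")
  }

  summary_dt <- summarize_crispr(results)
  data.table::fwrite(summary_dt, file.path(outdir, "summary_crispr.tsv"),
                     sep = "\t")
  t2 <- summarize_assembly(results)
  data.table::fwrite(t2, file.path(outdir, "summary_assembly.tsv"),
                     sep = "\t")
  enr <- summarize_enrichment(results, manifest,
                              factor = config$enrichment_factor)
  if (!is.null(enr)) {
    data.table::fwrite(enr, file.path(outdir, "enrichment.tsv"), sep = "\t")
  }

  log_lines <- c(
    sprintf("min_contig_len\t%d", config$min_contig_len),
    sprintf("profiles\t%s",
            paste(vapply(config$profiles, `[[`, character(1), "name"),
                  collapse = ",")),
    sprintf("min_spacers\t%d", config$profiles[[1]]$min_spacers),
    sprintf("rms_min_coverage\t%g", config$rms_min_coverage),
    sprintf("rms_max_gene_distance\t%d", config$rms_max_gene_distance),
    sprintf("rms_merge_window\t%d", config$rms_merge_window),
    sprintf("enrichment_factor\t%g", config$enrichment_factor),
    sprintf("word_size\t%d", config$scheme$word_size),
    sprintf("evalue_max\t%g", config$scheme$evalue_max),
    sprintf("cas_max_gene_gap\t%d", config$cas_max_gene_gap),
    sprintf("repeat_ref_max_evalue\t%g", config$repeat_ref_max_evalue),
    sprintf("lca_top_score_fraction\t%g", config$lca_top_score_fraction))
  writeLines(log_lines, file.path(outdir, "run_log.tsv"))
  invisible(results)
}

#' Summary table of CRISPR statistics per sample
#'
#' One row per sample: array counts, summed array cpm, cas adjacency with
#' percentage, per-type tallies, largest array, spacer counts
#' (total/distinct/singleton) and repeat counts (total/distinct). All
#' percentages use [percentage()] (half-up, two decimals).
#'
#' @param results Named list of `sample_result` objects.
#' @return A `data.table`, one row per sample.
#' @export
summarize_crispr <- function(results) {
  rows <- lapply(results, function(res) {
    arrays <- res$arrays
    n_arr <- length(arrays)
    n_cas <- sum(vapply(arrays, `[[`, logical(1), "cas_adjacent"))
    types <- table(factor(
      vapply(arrays, function(a) {
        loci <- res$cas_loci[contig_id == a$contig_id]
        if (a$cas_adjacent && nrow(loci)) loci$assigned_type[1L]
        else "unknown"
      }, character(1)),
      levels = c("I", "II", "III", "unknown")))
    sp <- collect_spacers(arrays)
    reps <- vapply(arrays, `[[`, character(1), "consensus_repeat")
    crispr_cpm <- res$feature_cpm[feature_id == "CRISPR"]$cpm
    data.table::data.table(
      sample = res$sample_id,
      n_arrays = n_arr,
      crispr_cpm = if (length(crispr_cpm)) crispr_cpm else 0,
      n_cas_adjacent = n_cas,
      pct_cas_adjacent = if (n_arr > 0) percentage(n_cas, n_arr) else NA_real_,
      type_I = as.integer(types[["I"]]),
      type_II = as.integer(types[["II"]]),
      type_III = as.integer(types[["III"]]),
      type_unknown = if (n_arr > 0) as.integer(types[["unknown"]]) else 0L,
      largest_array = if (n_arr > 0) {
        max(vapply(arrays, `[[`, integer(1), "n_spacers"))
      } else 0L,
      spacers_total = sp$n_total,
      spacers_distinct = sp$n_distinct,
      spacers_singleton = sp$n_singleton,
      repeats_total = length(reps),
      repeats_distinct = length(unique(reps)))
  })
  data.table::rbindlist(rows)
}

#' Assembly-level summary (contig counts, size, coverage, GC)
#'
#' @param results Named list of `sample_result` objects.
#' @return `data.table`: sample, n_contigs, assembly_bp, mapped_bp,
#'   mean_coverage (mapped bp / assembly bp, half-up 2 decimals),
#'   mean_gc_pct.
#' @export
summarize_assembly <- function(results) {
  data.table::rbindlist(lapply(results, function(res) {
    asm <- sum(res$contig_cpm$length)
    data.table::data.table(
      sample = res$sample_id,
      n_contigs = nrow(res$contig_cpm),
      assembly_bp = asm,
      mapped_bp = res$total_mapped_bp,
      mean_coverage = round_half_up(res$total_mapped_bp / asm, 2),
      mean_gc_pct = round_half_up(100 * mean(res$gc$gc), 2))
  }))
}

#' Feature-wise enrichment calls between sponge and seawater samples
#'
#' Builds the feature x sample cpm matrix from per-sample results and
#' flags each feature via [enrichment_call()]. Returns NULL when the
#' manifest lacks either a sponge or a seawater sample.
#'
#' @param results Named list of `sample_result` objects.
#' @param manifest Manifest with sample_id and role.
#' @param factor Fold-change threshold.
#' @return `data.table`: feature_id, mean_sponge_cpm, seawater_cpm, flag;
#'   or NULL.
#' @export
summarize_enrichment <- function(results, manifest, factor = 1.5) {
  manifest <- data.table::as.data.table(manifest)
  sponge_ids <- manifest$sample_id[manifest$role == "sponge"]
  sea_ids <- manifest$sample_id[manifest$role == "seawater"]
  if (!length(sponge_ids) || length(sea_ids) != 1L) return(NULL)
  feats <- unique(unlist(lapply(results, function(r) r$feature_cpm$feature_id)))
  if (!length(feats)) return(NULL)
  get_cpm <- function(res, f) {
    v <- res$feature_cpm[feature_id == f]$cpm
    if (length(v)) v else 0
  }
  data.table::rbindlist(lapply(sort(feats), function(f) {
    sponge <- vapply(results[sponge_ids], get_cpm, numeric(1), f = f)
    sea <- get_cpm(results[[sea_ids]], f)
    data.table::data.table(
      feature_id = f,
      mean_sponge_cpm = mean(sponge),
      seawater_cpm = sea,
      flag = enrichment_call(sponge, sea, factor))
  }))
}
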
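#' Filter REBASE-role hits into RMS gene calls
#'
#' Keeps hits with query coverage at or above `min_coverage` (inclusive
#' boundary). Per gene and RMS type, the best (lowest) e-value hit defines
#' the role; ties are broken in favor of the role listed first in the
#' table order after a stable sort, making the call deterministic.
#'
#' @param hits Domain-hit `data.table` with columns gene_id, role
#'   (REase / MTase / Specificity), rms_type (I / II / III), evalue,
#'   query_coverage.
#' @param genes Gene coordinate table (adds contig_id and index).
#' @param min_coverage Minimum query coverage (default 0.70).
#' @return `data.table` of RMS genes: gene_id, contig_id, index, role,
#'   rms_type, query_coverage, evalue. A gene may appear once per rms_type.
#' @export
filter_rms_hits <- function(hits, genes, min_coverage = 0.70) {
  req <- c("gene_id", "role", "rms_type", "evalue", "query_coverage")
  if (!all(req %in% names(hits))) {
    stop("RMS hits need columns: ", paste(req, collapse = ", "))
  }
  sub <- hits[query_coverage >= min_coverage]
  if (nrow(sub)) {
    bad <- sub$role == "Specificity" & sub$rms_type != "I"
    if (any(bad)) stop("Specificity role only admissible for type I")
  }
  if (nrow(sub) == 0L) {
    return(data.table::data.table(
      gene_id = character(0), contig_id = character(0), index = integer(0),
      role = character(0), rms_type = character(0),
      query_coverage = numeric(0), evalue = numeric(0)))
  }
  sub <- sub[order(gene_id, rms_type, evalue)]
  best <- sub[, .SD[1L], by = list(gene_id, rms_type)]
  out <- merge(best, genes[, list(gene_id, contig_id, index)],
               by = "gene_id", sort = FALSE)
  out[order(contig_id, index),
      list(gene_id, contig_id, index, role, rms_type, query_coverage, evalue)]
}

#' Pair REases with MTases into complete RMS
#'
#' A complete system is an REase and an MTase of the same type within
#' `max_gene_distance` gene ordinals of each other; each REase pairs with
#' its nearest qualifying MTase (leftmost on tie). For type I a
#' Specificity gene within the same window is recorded when present but
#' not required. A single gene carrying both REase and MTase roles of one
#' type (fused type II architecture) counts as a complete system of span
#' zero.
#'
#' The distance rule follows the completeness convention of proximity
#' pairing ("within four genes"); it is measured in gene ordinals, not
#' basepairs, and is configurable.
#'
#' @param rms_genes Output of [filter_rms_hits()].
#' @param max_gene_distance Maximum index distance (default 4).
#' @return `data.table` of systems: contig_id, rms_type, rease_gene,
#'   mtase_gene, spec_gene, index_min, index_max, complete.
#' @export
pair_complete_systems <- function(rms_genes, max_gene_distance = 4L) {
  empty <- data.table::data.table(
    contig_id = character(0), rms_type = character(0),
    rease_gene = character(0), mtase_gene = character(0),
    spec_gene = character(0), index_min = integer(0),
    index_max = integer(0), complete = logical(0))
  if (nrow(rms_genes) == 0L) return(empty)
  out <- list()
  combos <- unique(rms_genes[, list(contig_id, rms_type)])
  for (i in seq_len(nrow(combos))) {
    cid <- combos$contig_id[i]; ty <- combos$rms_type[i]
    sub <- rms_genes[contig_id == cid & rms_type == ty][order(index)]
    # fused genes: same gene called as both roles cannot happen (one row per
    # gene per type), so a fused architecture is flagged via role "REase+MTase"
    fused <- sub[role == "REase+MTase"]
    for (j in seq_len(nrow(fused))) {
      out[[length(out) + 1L]] <- data.table::data.table(
        contig_id = cid, rms_type = ty,
        rease_gene = fused$gene_id[j], mtase_gene = fused$gene_id[j],
        spec_gene = NA_character_, index_min = fused$index[j],
        index_max = fused$index[j], complete = TRUE)
    }
    re <- sub[role == "REase"]
    mt <- sub[role == "MTase"]
    sp <- sub[role == "Specificity"]
    for (j in seq_len(nrow(re))) {
      if (!nrow(mt)) break
      d <- abs(mt$index - re$index[j])
      if (min(d) > max_gene_distance) next
      # nearest qualifying MTase, leftmost on tie
      cand <- which(d == min(d))
      pick <- cand[which.min(mt$index[cand])]
      imin <- min(re$index[j], mt$index[pick])
      imax <- max(re$index[j], mt$index[pick])
      spg <- NA_character_
      if (ty == "I" && nrow(sp)) {
        ds <- pmin(abs(sp$index - re$index[j]), abs(sp$index - mt$index[pick]))
        if (min(ds) <= max_gene_distance) {
          k <- which.min(ds)
          spg <- sp$gene_id[k]
          imin <- min(imin, sp$index[k]); imax <- max(imax, sp$index[k])
        }
      }
      out[[length(out) + 1L]] <- data.table::data.table(
        contig_id = cid, rms_type = ty,
        rease_gene = re$gene_id[j], mtase_gene = mt$gene_id[pick],
        spec_gene = spg, index_min = imin, index_max = imax,
        complete = TRUE)
    }
  }
  if (!length(out)) return(empty)
  data.table::rbindlist(out)[order(contig_id, rms_type, index_min)]
}

#' Merge complete systems into non-redundant clusters
#'
#' Same-type systems on one contig whose gene-index spans overlap or lie
#' within `window` gene indices merge transitively into one cluster;
#' different types never merge. The cluster count is the reported RMS
#' count (avoids double counting of shared genes).
#'
#' @param systems Output of [pair_complete_systems()].
#' @param window Maximum gap between spans (default 4).
#' @return `data.table` of clusters: contig_id, rms_type, index_min,
#'   index_max, n_systems, genes.
#' @export
merge_into_clusters <- function(systems, window = 4L) {
  empty <- data.table::data.table(
    contig_id = character(0), rms_type = character(0),
    index_min = integer(0), index_max = integer(0),
    n_systems = integer(0), genes = character(0))
  if (nrow(systems) == 0L) return(empty)
  out <- list()
  combos <- unique(systems[, list(contig_id, rms_type)])
  for (i in seq_len(nrow(combos))) {
    cid <- combos$contig_id[i]; ty <- combos$rms_type[i]
    sub <- systems[contig_id == cid & rms_type == ty][order(index_min)]
    cur_min <- sub$index_min[1L]; cur_max <- sub$index_max[1L]
    members <- list(1L)
    cur_members <- 1L
    if (nrow(sub) >= 2L) {
      for (j in 2L:nrow(sub)) {
        gap <- sub$index_min[j] - cur_max - 1L
        if (gap <= window) {
          cur_max <- max(cur_max, sub$index_max[j])
          cur_members <- c(cur_members, j)
        } else {
          out[[length(out) + 1L]] <- .cluster_row(cid, ty, cur_min, cur_max,
                                                  sub[cur_members])
          cur_min <- sub$index_min[j]; cur_max <- sub$index_max[j]
          cur_members <- j
        }
      }
    }
    out[[length(out) + 1L]] <- .cluster_row(cid, ty, cur_min, cur_max,
                                            sub[cur_members])
  }
  data.table::rbindlist(out)[order(contig_id, rms_type, index_min)]
}

.cluster_row <- function(cid, ty, imin, imax, members) {
  genes <- unique(stats::na.omit(c(members$rease_gene, members$mtase_gene,
                                   members$spec_gene)))
  data.table::data.table(contig_id = cid, rms_type = ty,
                         index_min = imin, index_max = imax,
                         n_systems = nrow(members),
                         genes = paste(sort(genes), collapse = ","))
}
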
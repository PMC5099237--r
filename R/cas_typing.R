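#' Load the shipped accession-to-cas-gene mapping
#'
#' The mapping from TIGRFAM/Pfam/COG accessions to cas gene names ships as
#' an editable two-column TSV (`accession`, `cas_name`) in `extdata`; the
#' published classification scheme names only example accessions, so the
#' table is a curated, replaceable config rather than an exhaustive
#' database.
#'
#' @param path Optional path to a custom mapping TSV.
#' @return Named character vector: accession -> cas gene name.
#' @export
load_cas_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cas_gene_map.tsv",
                        package = "defenseprofiler")
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  stats::setNames(dt$cas_name, dt$accession)
}

#' Load the shipped subtype-signature mapping (accession -> subtype)
#' @param path Optional path to a custom mapping TSV.
#' @return Named character vector: accession -> subtype (e.g. "I-E").
#' @export
load_cas_subtype_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cas_subtype_map.tsv",
                        package = "defenseprofiler")
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  stats::setNames(dt$subtype, dt$accession)
}

#' Identify cas genes from a domain-hit table
#'
#' A gene is a cas gene iff at least one of its hit accessions is in the
#' mapping; among mapped hits, the best (lowest) e-value hit names it.
#'
#' @param hits `data.table` of domain hits (see [read_domain_hits()]).
#' @param mapping Named character vector accession -> cas name
#'   (default: [load_cas_map()]).
#' @return A `data.table` with columns gene_id, cas_name, accession,
#'   evalue; one row per cas gene.
#' @export
identify_cas_genes <- function(hits, mapping = load_cas_map()) {
  if (length(mapping) == 0L) stop("cas mapping must be non-empty")
  sub <- hits[accession %in% names(mapping)]
  if (nrow(sub) == 0L) {
    return(data.table::data.table(gene_id = character(0),
                                  cas_name = character(0),
                                  accession = character(0),
                                  evalue = numeric(0)))
  }
  sub <- sub[order(evalue)]
  best <- sub[, .SD[1L], by = gene_id]
  accs <- sub[, list(accessions = paste(unique(accession), collapse = ",")),
              by = gene_id]
  out <- best[, list(gene_id, cas_name = unname(mapping[accession]),
                     accession, evalue)]
  merge(out, accs, by = "gene_id", sort = TRUE)
}

#' Group cas genes on a contig into loci
#'
#' Consecutive cas genes (gene-index gap <= `max_gene_gap`) on one contig
#' form a locus, which is then typed with [assign_cas_type()].
#'
#' @param cas_genes Output of [identify_cas_genes()].
#' @param genes Gene coordinate table (see [read_gene_table()]).
#' @param max_gene_gap Maximum index gap between members of one locus.
#' @param subtype_map Named vector accession -> subtype.
#' @return A `data.table` of loci: contig_id, index_min, index_max,
#'   genes (comma list), cas_names, assigned_type, subtype.
#' @export
call_cas_loci <- function(cas_genes, genes, max_gene_gap = 5L,
                          subtype_map = load_cas_subtype_map()) {
  if (nrow(cas_genes) == 0L) {
    return(data.table::data.table(
      contig_id = character(0), index_min = integer(0),
      index_max = integer(0), genes = character(0), cas_names = character(0),
      assigned_type = character(0), subtype = character(0)))
  }
  g <- merge(cas_genes, genes[, list(gene_id, contig_id, index)],
             by = "gene_id")
  g <- g[order(contig_id, index)]
  out <- list()
  for (cid in unique(g$contig_id)) {
    sub <- g[contig_id == cid]
    brk <- c(0L, which(diff(sub$index) > max_gene_gap), nrow(sub))
    for (i in seq_len(length(brk) - 1L)) {
      mem <- sub[(brk[i] + 1L):brk[i + 1L]]
      ty <- assign_cas_type(mem$cas_name)
      subt <- NA_character_
      sig_accs <- unlist(strsplit(mem$accessions, ","))
      hits_sub <- stats::na.omit(unname(subtype_map[sig_accs]))
      if (length(unique(hits_sub)) == 1L &&
          startsWith(hits_sub[1L], paste0(ty$type, "-"))) {
        subt <- hits_sub[1L]
      }
      out[[length(out) + 1L]] <- data.table::data.table(
        contig_id = cid, index_min = min(mem$index),
        index_max = max(mem$index),
        genes = paste(mem$gene_id, collapse = ","),
        cas_names = paste(mem$cas_name, collapse = ","),
        assigned_type = ty$type, subtype = subt)
    }
  }
  data.table::rbindlist(out)
}

#' Assign a CRISPR-Cas type from the cas genes at a locus
#'
#' Signature genes define the type: cas3 -> I, cas9 -> II, cas10 -> III.
#' Conflicting signatures or no signature give "unknown". The assignment is
#' invariant to gene order.
#'
#' @param cas_names Character vector of cas gene names at one locus.
#' @return List with elements `type` ("I", "II", "III" or "unknown") and
#'   `signatures` (the signature genes present).
#' @export
assign_cas_type <- function(cas_names) {
  if (length(cas_names) == 0L) stop("at least one cas gene required")
  sig <- c(cas3 = "I", cas9 = "II", cas10 = "III")
  present <- intersect(names(sig), cas_names)
  type <- if (length(present) == 1L) unname(sig[present]) else "unknown"
  list(type = type, signatures = present)
}

#' Flag arrays adjacent to cas loci
#'
#' `cas_adjacent` is set iff a cas locus exists on the array's contig whose
#' gene-index range is within `max_gene_gap` gene indices of the genes
#' flanking the array (the last gene ending before the array and the first
#' gene starting after it).
#'
#' @param arrays List of `crispr_array` objects.
#' @param loci Locus table from [call_cas_loci()].
#' @param genes Gene coordinate table.
#' @param max_gene_gap Adjacency window in gene ordinals (default 5; the
#'   notion of "adjacent" is not quantified in the field's protocols).
#' @return The arrays with `cas_adjacent` set.
#' @export
link_arrays_to_cas <- function(arrays, loci, genes, max_gene_gap = 5L) {
  lapply(arrays, function(a) {
    a$cas_adjacent <- FALSE
    lsub <- loci[contig_id == a$contig_id]
    if (nrow(lsub) == 0L) return(a)
    gsub <- genes[contig_id == a$contig_id]
    left <- gsub[end < a$start]
    right <- gsub[start > a$end]
    flank <- c(if (nrow(left)) max(left$index),
               if (nrow(right)) min(right$index))
    if (!length(flank)) return(a)
    for (i in seq_len(nrow(lsub))) {
      d <- min(vapply(flank, function(f) {
        if (f >= lsub$index_min[i] && f <= lsub$index_max[i]) return(0L)
        min(abs(f - lsub$index_min[i]), abs(f - lsub$index_max[i]))
      }, integer(1)))
      if (d <= max_gene_gap) { a$cas_adjacent <- TRUE; break }
    }
    a
  })
}
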
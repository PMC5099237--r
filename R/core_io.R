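#' @useDynLib defenseprofiler, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# Silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  "contig", "pos", "depth", "contig_id", "gene_id", "accession", "evalue",
  "start", "end", "index", "role", "rms_type", "query_coverage",
  "index_min", "index_max", "feature_id", "cas_name", "accessions",
  "query_id", "sequence", "count", "source", "taxid", ".", ":="
))

#' Read a FASTA file into sequence records
#'
#' Sequences are uppercased and validated against the DNA alphabet
#' `{A,C,G,T,N}`. Record ids must be unique and sequences non-empty;
#' violations raise an error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of uppercase DNA sequences; names are
#'   record ids (first whitespace-delimited token of the header). The full
#'   headers are kept in the `"description"` attribute.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    out <- character(0)
    attr(out, "description") <- character(0)
    return(out)
  }
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[ \t]"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  empty <- !nzchar(seqs)
  if (any(empty)) stop("empty sequence for record: ", ids[empty][1L])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN character in record: ", ids[bad][1L])
  }
  names(seqs) <- ids
  attr(seqs, "description") <- headers
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Filter contigs by minimum length
#'
#' Contigs shorter than `min_len` are discarded (keep length >= `min_len`,
#' matching the "contigs > 1000 bp" convention used for assembled
#' metagenomes; the boundary is configurable).
#'
#' @param seqs Named character vector of contig sequences.
#' @param min_len Minimum retained length (default 1000).
#' @return Filtered named character vector. The number of removed records is
#'   reported via `message()`.
#' @export
filter_contigs <- function(seqs, min_len = 1000L) {
  stopifnot(min_len >= 1)
  keep <- nchar(seqs) >= min_len
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(n_removed, " contig(s) below ", min_len, " nt discarded")
  }
  out <- seqs[keep]
  attr(out, "description") <- attr(seqs, "description")[keep]
  out
}

#' Read a samtools-depth-style per-base depth table
#'
#' Expects a TSV with three columns: contig id, 1-based position, depth.
#' Positions absent from the file are depth 0 when the contig length is
#' known from `contig_lengths`.
#'
#' @param path Path to the TSV (no header).
#' @param contig_lengths Named integer vector of contig lengths. Contigs
#'   named here but absent from the file get all-zero vectors.
#' @return A named list of integer depth vectors (one per contig, length =
#'   contig length when known, otherwise max observed position).
#' @export
read_depth_table <- function(path, contig_lengths = NULL) {
  if (!file.exists(path)) stop("depth table not found: ", path)
  if (file.size(path) == 0L) {
    dt <- data.table::data.table(contig = character(0), pos = integer(0),
                                 depth = integer(0))
  } else {
    dt <- tryCatch(
      data.table::fread(path, header = FALSE, sep = "\t",
                        col.names = c("contig", "pos", "depth"),
                        colClasses = list(character = 1)),
      error = function(e) stop("malformed depth table: ", conditionMessage(e))
    )
  }
  if (nrow(dt) > 0) {
    if (!is.numeric(dt$pos) || !is.numeric(dt$depth) ||
        any(dt$pos != as.integer(dt$pos)) || any(dt$depth != as.integer(dt$depth))) {
      stop("depth table positions and depths must be integers")
    }
    if (any(dt$pos <= 0)) stop("depth table positions must be 1-based (> 0)")
    if (any(dt$depth < 0)) stop("negative depth in depth table")
  }
  ids <- union(names(contig_lengths), unique(dt$contig))
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    sub <- dt[contig == id]
    len <- if (!is.null(contig_lengths) && id %in% names(contig_lengths)) {
      as.integer(contig_lengths[[id]])
    } else if (nrow(sub)) max(sub$pos) else 0L
    v <- integer(len)
    if (nrow(sub)) {
      if (any(sub$pos > len)) {
        stop("depth position beyond contig length for ", id)
      }
      v[sub$pos] <- as.integer(sub$depth)
    }
    out[[id]] <- v
  }
  out
}

#' Write a depth table (positions with zero depth are omitted)
#' @param depths Named list of integer vectors.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(depths, path) {
  dts <- lapply(names(depths), function(id) {
    v <- depths[[id]]
    nz <- which(v > 0L)
    if (!length(nz)) return(NULL)
    data.table::data.table(contig = id, pos = nz, depth = v[nz])
  })
  dt <- data.table::rbindlist(dts)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a gene coordinate table
#'
#' TSV with header columns: gene_id, contig_id, index, start, end, strand.
#' Coordinates are 1-based inclusive; `index` is the 0-based ordinal of the
#' gene along its contig in coordinate order.
#'
#' @param path Path to TSV.
#' @return A `data.table` with columns gene_id, contig_id, index, start,
#'   end, strand.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("gene table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c(1, 2)))
  req <- c("gene_id", "contig_id", "index", "start", "end", "strand")
  if (!all(req %in% names(dt))) {
    stop("gene table must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(dt) && any(dt$start > dt$end)) stop("gene with start > end")
  dt
}

#' Read a domain/annotation hit table
#'
#' TSV with header columns gene_id, accession, source_db, evalue,
#' query_coverage and optional role, rms_type (REBASE-role hits).
#'
#' @param path Path to TSV.
#' @return A `data.table`.
#' @export
read_domain_hits <- function(path) {
  if (!file.exists(path)) stop("domain hit table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  req <- c("gene_id", "accession", "source_db", "evalue", "query_coverage")
  if (!all(req %in% names(dt))) {
    stop("domain hit table must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(dt)) {
    if (any(dt$evalue < 0)) stop("negative e-value in domain hits")
    if (any(dt$query_coverage < 0 | dt$query_coverage > 1)) {
      stop("query_coverage outside [0,1]")
    }
  }
  dt
}

#' Read a 12-column BLAST tabular (outfmt 6) file with subject taxids
#'
#' Standard outfmt-6 column order, with the subject taxid appended as a
#' 13th column (qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore staxid).
#'
#' @param path Path to tabular file (no header).
#' @return A `data.table` with named columns.
#' @export
read_alignment_hits <- function(path) {
  if (!file.exists(path)) stop("alignment hit table not found: ", path)
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "evalue", "bit_score", "subject_taxid")
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) != length(cols)) {
    stop("expected ", length(cols), " columns (outfmt 6 + staxid), got ",
         ncol(dt))
  }
  data.table::setnames(dt, cols)
  if (nrow(dt)) {
    if (any(dt$bit_score < 0)) stop("negative bit score")
    if (any(dt$percent_identity < 0 | dt$percent_identity > 100)) {
      stop("percent identity outside [0,100]")
    }
  }
  dt
}

#' Read a taxonomy table (taxid, parent, rank, name)
#'
#' The tree must have exactly one root (parent == taxid) and parent
#' pointers must form a tree (no cycles).
#'
#' @param path Path to TSV with header taxid, parent, rank, name.
#' @return A `data.table` keyed by taxid.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  req <- c("taxid", "parent", "rank", "name")
  if (!all(req %in% names(dt))) {
    stop("taxonomy table must have columns: ", paste(req, collapse = ", "))
  }
  validate_taxonomy(dt)
  data.table::setkey(dt, taxid)
  dt
}

validate_taxonomy <- function(dt) {
  roots <- dt$taxid[dt$taxid == dt$parent]
  if (length(roots) != 1L) {
    stop("taxonomy must have exactly one root, found ", length(roots))
  }
  parent <- stats::setNames(dt$parent, as.character(dt$taxid))
  for (t in dt$taxid) {
    seen <- character(0)
    cur <- as.character(t)
    while (parent[[cur]] != as.numeric(cur)) {
      if (cur %in% seen) stop("cycle in taxonomy at taxid ", t)
      seen <- c(seen, cur)
      nxt <- as.character(parent[[cur]])
      if (!nxt %in% names(parent)) stop("dangling parent taxid ", nxt)
      cur <- nxt
    }
  }
  invisible(TRUE)
}
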
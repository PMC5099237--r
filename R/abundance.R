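#' Mean coverage of a contig
#'
#' Arithmetic mean of per-position depth over all positions, zeros
#' included.
#'
#' @param depth Integer vector of per-position depths.
#' @return Mean coverage.
#' @export
contig_coverage <- function(depth) {
  if (!length(depth)) stop("empty depth vector")
  if (any(depth < 0)) stop("negative depth")
  mean(depth)
}

#' Copies per megabase (cpm)
#'
#' Contig coverage divided by the sample's total mapped basepairs, times
#' 1e6. Summing `cpm * length` over all contigs of one mapping returns
#' exactly 1e6 (conservation identity used as a pipeline self-check).
#'
#' @param coverage Mean contig coverage.
#' @param total_mapped_bp Total mapped basepairs of the sample (> 0).
#' @return cpm value.
#' @export
cpm <- function(coverage, total_mapped_bp) {
  if (total_mapped_bp <= 0) stop("total_mapped_bp must be > 0")
  coverage / total_mapped_bp * 1e6
}

#' Per-contig cpm table from a depth list
#'
#' @param depths Named list of depth vectors (see [read_depth_table()]).
#' @param total_mapped_bp Total mapped bp; default `sum(all depths)`, which
#'   makes the conservation identity exact.
#' @return `data.table`: contig, length, coverage, cpm.
#' @export
contig_cpm_table <- function(depths, total_mapped_bp = NULL) {
  if (is.null(total_mapped_bp)) {
    total_mapped_bp <- sum(vapply(depths, function(v) sum(as.numeric(v)),
                                  numeric(1)))
  }
  data.table::data.table(
    contig = names(depths),
    length = lengths(depths),
    coverage = vapply(depths, contig_coverage, numeric(1)),
    cpm = vapply(depths, function(v) cpm(contig_coverage(v), total_mapped_bp),
                 numeric(1)))
}

#' Aggregate feature abundance in cpm
#'
#' A feature instance contributes its host contig's cpm; the feature's cpm
#' is the sum over instances (and its raw count the number of instances).
#'
#' @param features `data.frame`/`data.table` with columns feature_id,
#'   contig.
#' @param contig_cpm `data.table` from [contig_cpm_table()].
#' @return `data.table`: feature_id, raw_count, cpm.
#' @export
aggregate_feature_cpm <- function(features, contig_cpm) {
  features <- data.table::as.data.table(features)
  if (nrow(features)) {
    unknown <- setdiff(features$contig, contig_cpm$contig)
    if (length(unknown)) {
      bad <- features[contig %in% unknown][1L]
      stop("feature ", bad$feature_id, " on unknown contig ", bad$contig)
    }
  }
  if (!nrow(features)) {
    return(data.table::data.table(feature_id = character(0),
                                  raw_count = integer(0), cpm = numeric(0)))
  }
  m <- merge(features, contig_cpm[, list(contig, cpm)], by = "contig")
  m[, list(raw_count = .N, cpm = sum(cpm)), by = feature_id][order(feature_id)]
}

#' Enrichment call between sponge and seawater samples
#'
#' Compares the arithmetic mean cpm over sponge samples against the
#' seawater cpm; a side is flagged enriched when strictly greater than
#' `factor` times the other. A zero denominator with a positive numerator
#' is enriched on the positive side; both zero gives "none". Flags are
#' mutually exclusive and invariant to sponge-sample order.
#'
#' @param sponge_cpm Numeric vector of per-sponge-sample cpm (>= 1 value).
#' @param seawater_cpm Single seawater cpm.
#' @param factor Fold-change threshold (default 1.5).
#' @return One of "sponge", "seawater", "none".
#' @export
enrichment_call <- function(sponge_cpm, seawater_cpm, factor = 1.5) {
  stopifnot(length(sponge_cpm) >= 1, length(seawater_cpm) == 1)
  m <- mean(sponge_cpm)
  if (m == 0 && seawater_cpm == 0) return("none")
  if (seawater_cpm == 0 && m > 0) return("sponge")
  if (m == 0 && seawater_cpm > 0) return("seawater")
  if (m > factor * seawater_cpm) return("sponge")
  if (seawater_cpm > factor * m) return("seawater")
  "none"
}

#' Bray-Curtis dissimilarity between two abundance profiles
#'
#' `BC = 1 - 2 * sum(min(a, b)) / (sum(a) + sum(b))` over the union of
#' taxa (missing taxa count as 0).
#'
#' @param a,b Named (or plain, equal-length) non-negative numeric vectors.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(a, b) {
  if (!is.null(names(a)) || !is.null(names(b))) {
    taxa <- union(names(a), names(b))
    a <- stats::setNames(ifelse(taxa %in% names(a), a[taxa], 0), taxa)
    b <- stats::setNames(ifelse(taxa %in% names(b), b[taxa], 0), taxa)
    a[is.na(a)] <- 0; b[is.na(b)] <- 0
  }
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0))
  tot <- sum(a) + sum(b)
  if (tot == 0) stop("both profiles are all-zero")
  1 - 2 * sum(pmin(a, b)) / tot
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' @param profiles Named list of abundance profiles (named numeric
#'   vectors).
#' @return Symmetric matrix of dissimilarities.
#' @export
bray_curtis_matrix <- function(profiles) {
  n <- length(profiles)
  m <- matrix(0, n, n, dimnames = list(names(profiles), names(profiles)))
  if (n < 2) return(m)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- bray_curtis(profiles[[i]], profiles[[j]])
    m[i, j] <- d; m[j, i] <- d
  }
  m
}

#' Complete-linkage hierarchical clustering of a dissimilarity matrix
#'
#' Standard agglomerative clustering with maximum linkage
#' (`stats::hclust(method = "complete")`), which is deterministic for a
#' fixed input ordering.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @return An `hclust` object.
#' @export
complete_linkage <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d))) stop("dissimilarity matrix must be symmetric")
  if (any(diag(d) != 0)) stop("dissimilarity matrix must have zero diagonal")
  stats::hclust(stats::as.dist(d), method = "complete")
}

#' Export a dendrogram as a Newick string
#'
#' @param hc An `hclust` object.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if written to file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

.tax_path <- function(taxid, parent) {
  path <- integer(0)
  cur <- taxid
  repeat {
    path <- c(cur, path)
    p <- parent[[as.character(cur)]]
    if (is.null(p)) stop("taxid absent from taxonomy: ", cur)
    if (p == cur) break
    cur <- p
  }
  path  # root ... taxid
}

#' Lowest-common-ancestor taxonomic assignment
#'
#' Retains the hits whose bit score is at least
#' `(1 - top_score_fraction) * best` and answers with the lowest common
#' ancestor of the retained taxids; queries with no hits are unassigned
#' (NA). The retention rule mirrors the common top-percent default of
#' LCA-based metagenome classifiers.
#'
#' @param hits `data.table` of alignment hits for ONE query (columns
#'   subject_taxid, bit_score).
#' @param taxonomy Taxonomy `data.table` (see [read_taxonomy()]).
#' @param top_score_fraction Retention band below the best score
#'   (default 0.1).
#' @param min_hits Minimum retained hits for an assignment (default 1).
#' @return The assigned taxid, or `NA` when unassigned.
#' @export
lca_assign <- function(hits, taxonomy, top_score_fraction = 0.1,
                       min_hits = 1L) {
  if (is.null(hits) || nrow(hits) == 0L) return(NA_integer_)
  best <- max(hits$bit_score)
  keep <- hits$subject_taxid[hits$bit_score >= (1 - top_score_fraction) * best]
  if (length(keep) < min_hits) return(NA_integer_)
  parent <- stats::setNames(as.list(taxonomy$parent),
                            as.character(taxonomy$taxid))
  paths <- lapply(unique(keep), .tax_path, parent = parent)
  common <- paths[[1L]]
  for (p in paths[-1L]) {
    n <- min(length(common), length(p))
    eq <- which(common[seq_len(n)] == p[seq_len(n)])
    if (!length(eq)) stop("taxa share no root; invalid taxonomy")
    common <- common[seq_len(max(eq))]
  }
  common[length(common)]
}

#' Assign taxonomy to many queries at once
#'
#' @param hits Full alignment-hit `data.table` (see
#'   [read_alignment_hits()]).
#' @param taxonomy Taxonomy table.
#' @param ... Passed to [lca_assign()].
#' @return `data.table`: query_id, taxid.
#' @export
lca_assign_all <- function(hits, taxonomy, ...) {
  ids <- unique(hits$query_id)
  data.table::data.table(
    query_id = ids,
    taxid = vapply(ids, function(q) {
      as.integer(lca_assign(hits[query_id == q], taxonomy, ...))
    }, integer(1)))
}

#' Build a community profile from taxon counts
#'
#' @param counts Named numeric vector of per-taxon counts.
#' @param min_fraction Taxa below this relative abundance are pooled into
#'   `"other"` (default 0 = keep all).
#' @return Named numeric vector of relative abundances summing to 1.
#' @export
community_profile <- function(counts, min_fraction = 0) {
  stopifnot(all(counts >= 0), sum(counts) > 0)
  p <- counts / sum(counts)
  if (min_fraction > 0) {
    small <- p < min_fraction
    if (any(small)) {
      p <- c(p[!small], other = sum(p[small]))
    }
  }
  p
}

#' GC content per record and binned distribution
#'
#' GC is `(G + C) / (A + C + G + T)`; N bases are excluded from both
#' numerator and denominator. Errors on a record with zero non-N bases.
#'
#' @param seqs Named character vector of sequences.
#' @param bin_width Histogram bin width as a fraction (default 0.01).
#' @return List with `gc` (named per-record fractions) and `histogram`
#'   (`data.table`: bin_start, bin_end, count, density).
#' @export
gc_distribution <- function(seqs, bin_width = 0.01) {
  counts <- lapply(seqs, function(s) {
    tab <- table(strsplit(s, NULL)[[1]])
    g <- sum(tab[names(tab) %in% c("G", "C")])
    acgt <- sum(tab[names(tab) %in% c("A", "C", "G", "T")])
    c(g = g, acgt = acgt)
  })
  bad <- vapply(counts, function(x) x[["acgt"]] == 0, logical(1))
  if (any(bad)) stop("record with zero non-N bases: ", names(seqs)[bad][1L])
  gc <- vapply(counts, function(x) x[["g"]] / x[["acgt"]], numeric(1))
  names(gc) <- names(seqs)
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  h <- graphics::hist(gc, breaks = breaks, plot = FALSE)
  list(gc = gc,
       histogram = data.table::data.table(
         bin_start = h$breaks[-length(h$breaks)],
         bin_end = h$breaks[-1L],
         count = h$counts,
         density = h$density))
}

#' Round half up
#'
#' Decimal rounding with ties away from zero (0.005 -> 0.01), matching the
#' convention of printed summary tables, unlike R's banker's rounding.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded value.
#' @export
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

#' Percentage with half-up rounding to two decimals
#'
#' @param numerator,denominator Integers; denominator > 0.
#' @return `100 * numerator / denominator` rounded half-up to 2 decimals.
#' @export
percentage <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be > 0")
  round_half_up(100 * numerator / denominator, 2)
}

#' Pearson correlation with two-sided p-value
#'
#' `r` computed by direct summation of the covariance over the product of
#' standard deviations; the p-value comes from the t distribution with
#' `n - 2` degrees of freedom.
#'
#' @param a,b Equal-length numeric vectors (length >= 3, nonzero
#'   variance).
#' @return List with `r` and `p_value`.
#' @export
pearson_correlation <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero variance")
  n <- length(a)
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p_value = p)
}
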
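#' Scoring scheme for the seeded spacer-target aligner
#'
#' Defaults follow the published protospacer-search parameters: nucleotide
#' match +1, mismatch -1, gap open -5, gap extend -2, word size 7, E-value
#' cutoff 0.1.
#'
#' @param match,mismatch Match/mismatch scores.
#' @param gap_open,gap_extend Affine gap penalties (a gap of length L
#'   scores `gap_open + L * gap_extend`).
#' @param word_size Exact seed length required before alignment.
#' @param evalue_max Maximum reported E-value.
#' @param K Karlin-Altschul K constant (approximate calibration; see
#'   [karlin_altschul_lambda()]).
#' @return Object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1,
                           gap_open = -5, gap_extend = -2,
                           word_size = 7L, evalue_max = 0.1, K = 0.35) {
  stopifnot(word_size >= 1, evalue_max > 0, match > 0, mismatch < 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, word_size = as.integer(word_size),
                 evalue_max = evalue_max, K = K,
                 lambda = karlin_altschul_lambda(match, mismatch)),
            class = "scoring_scheme")
}

#' Karlin-Altschul lambda for a match/mismatch scheme
#'
#' Solves `p * exp(lambda * match) + (1 - p) * exp(lambda * mismatch) = 1`
#' numerically, with `p` the match probability under uniform base
#' composition (1/4). For +1/-1 the root is `log(3)`.
#'
#' @param match,mismatch Scores.
#' @param p_match Background match probability (default 0.25).
#' @return lambda > 0.
#' @export
karlin_altschul_lambda <- function(match, mismatch, p_match = 0.25) {
  f <- function(l) p_match * exp(l * match) + (1 - p_match) * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

#' E-value for a local alignment score
#'
#' Gumbel form `E = K * m * n * exp(-lambda * S)`; gapped parameters are
#' approximated by the ungapped pair, as the alignment scores in scope are
#' dominated by near-exact matches.
#'
#' @param score Alignment score.
#' @param m,n Query and subject (database) lengths.
#' @param scheme A [scoring_scheme()].
#' @return E-value.
#' @export
alignment_evalue <- function(score, m, n, scheme = scoring_scheme()) {
  scheme$K * m * n * exp(-scheme$lambda * score)
}

reverse_complement <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(lapply(strsplit(s, NULL), rev),
                                  paste, character(1), collapse = ""))
}

.kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Seeded local alignment of one query against one subject
#'
#' Reports a hit only when the two sequences share an exact `word_size`-mer
#' on the examined strand; the alignment itself is a full local
#' (Smith-Waterman) dynamic program with affine gaps, so whenever a seed
#' exists the score equals the exhaustive-DP optimum.
#'
#' @param query,subject DNA strings.
#' @param scheme A [scoring_scheme()].
#' @param both_strands Also scan the reverse complement of the subject.
#' @return NULL if unseeded; else a list with score, strand, q_start,
#'   q_end, s_start, s_end, evalue (coordinates 1-based on the forward
#'   subject for strand "+", on the reverse complement for strand "-").
#' @export
seeded_align <- function(query, subject, scheme = scoring_scheme(),
                         both_strands = TRUE) {
  qk <- .kmer_set(query, scheme$word_size)
  if (!length(qk)) return(NULL)
  best <- NULL
  subjects <- list(`+` = subject)
  if (both_strands) subjects$`-` <- reverse_complement(subject)
  for (strand in names(subjects)) {
    s <- subjects[[strand]]
    sk <- .kmer_set(s, scheme$word_size)
    if (!any(qk %in% sk)) next
    al <- .sw_align_cpp(query, s, scheme$match, scheme$mismatch,
                        scheme$gap_open, scheme$gap_extend)
    if (is.null(best) || al$score > best$score) {
      best <- c(al, list(strand = strand))
    }
  }
  if (is.null(best)) return(NULL)
  best$evalue <- alignment_evalue(best$score, nchar(query), nchar(subject),
                                  scheme)
  best
}

#' Build a spacer catalogue with per-sequence multiplicity
#'
#' Maps each distinct spacer sequence (exact string identity) to its
#' occurrence count and source arrays. Reports both the distinct count and
#' the singleton count (sequences occurring exactly once), since published
#' "unique spacer" tallies are ambiguous between the two.
#'
#' @param arrays List of validated `crispr_array` objects.
#' @return List with `catalogue` (data.table: sequence, count, sources),
#'   `n_total`, `n_distinct`, `n_singleton`, `n_multi`.
#' @export
collect_spacers <- function(arrays) {
  seqs <- character(0); src <- character(0)
  for (ai in seq_along(arrays)) {
    a <- arrays[[ai]]
    for (si in seq_along(a$spacers)) {
      seqs <- c(seqs, a$spacers[[si]]$seq)
      src <- c(src, sprintf("%s:%d:%d", a$contig_id, ai, si))
    }
  }
  if (!length(seqs)) {
    cat_dt <- data.table::data.table(sequence = character(0),
                                     count = integer(0),
                                     sources = character(0))
    return(list(catalogue = cat_dt, n_total = 0L, n_distinct = 0L,
                n_singleton = 0L, n_multi = 0L))
  }
  dt <- data.table::data.table(sequence = seqs, source = src)
  cat_dt <- dt[, list(count = .N, sources = paste(source, collapse = ",")),
               by = sequence]
  list(catalogue = cat_dt,
       n_total = length(seqs),
       n_distinct = nrow(cat_dt),
       n_singleton = sum(cat_dt$count == 1L),
       n_multi = sum(cat_dt$count > 1L))
}

#' Sequences shared between two catalogues
#'
#' Exact string identity; each sequence counts once regardless of
#' multiplicity. Symmetric. Reverse-complement matching is off by default.
#'
#' @param a,b Character vectors of sequences, or catalogue lists from
#'   [collect_spacers()].
#' @param revcomp Also match reverse complements.
#' @return List with `count` and `shared` (the shared sequences).
#' @export
shared_sequences <- function(a, b, revcomp = FALSE) {
  if (is.list(a) && !is.null(a$catalogue)) a <- a$catalogue$sequence
  if (is.list(b) && !is.null(b$catalogue)) b <- b$catalogue$sequence
  a <- unique(a); b <- unique(b)
  shared <- intersect(a, b)
  if (revcomp) {
    shared <- union(shared, a[reverse_complement(a) %in% b])
  }
  list(count = length(shared), shared = sort(shared))
}

#' Search spacers against a labelled target database
#'
#' Every target record must carry a category label (phage, virus or
#' plasmid), either via `categories` or encoded in the FASTA description
#' after a space (e.g. `>recA phage`). Hits are seeded local alignments on
#' both strands; per spacer and target only the best-scoring hit is kept,
#' and hits are reported iff `evalue <= scheme$evalue_max`.
#'
#' @param spacers Named character vector of spacer sequences.
#' @param targets Named character vector of target sequences.
#' @param categories Named character vector target id -> category; if NULL,
#'   taken from the `description` attribute of `targets`.
#' @param scheme A [scoring_scheme()].
#' @return `data.table` of hits: spacer_id, target_id, category, score,
#'   evalue, strand, q_start, q_end, s_start, s_end.
#' @export
search_targets <- function(spacers, targets, categories = NULL,
                           scheme = scoring_scheme()) {
  if (is.null(categories)) {
    desc <- attr(targets, "description")
    if (is.null(desc)) stop("target records need category labels")
    toks <- strsplit(desc, "[ \t]+")
    categories <- stats::setNames(
      vapply(toks, function(t) if (length(t) >= 2L) t[2L] else NA_character_,
             character(1)),
      vapply(toks, `[[`, character(1), 1L))
  }
  miss <- setdiff(names(targets), names(categories))
  miss <- union(miss, names(targets)[is.na(categories[names(targets)])])
  if (length(miss)) {
    stop("target without category label: ", miss[1L])
  }
  ok_cat <- c("phage", "virus", "plasmid")
  bad <- setdiff(unique(categories[names(targets)]), ok_cat)
  if (length(bad)) stop("unknown target category: ", bad[1L])
  short <- nchar(spacers) < scheme$word_size
  if (any(short)) {
    stop("spacer shorter than word size: ", names(spacers)[short][1L])
  }
  rows <- list()
  for (sp in names(spacers)) {
    for (tg in names(targets)) {
      al <- seeded_align(spacers[[sp]], targets[[tg]], scheme)
      if (is.null(al) || al$evalue > scheme$evalue_max) next
      rows[[length(rows) + 1L]] <- data.table::data.table(
        spacer_id = sp, target_id = tg,
        category = unname(categories[[tg]]),
        score = al$score, evalue = al$evalue, strand = al$strand,
        q_start = al$q_start, q_end = al$q_end,
        s_start = al$s_start, s_end = al$s_end)
    }
  }
  if (!length(rows)) {
    return(data.table::data.table(
      spacer_id = character(0), target_id = character(0),
      category = character(0), score = numeric(0), evalue = numeric(0),
      strand = character(0), q_start = integer(0), q_end = integer(0),
      s_start = integer(0), s_end = integer(0)))
  }
  data.table::rbindlist(rows)
}

#' Categorize spacers by their target hits
#'
#' A spacer with no hit is "unknown"; a spacer with hits in several
#' categories is counted once per category (published per-category tallies
#' overlap, so category sums may exceed the number of spacers with a
#' target).
#'
#' @param hits Hit table from [search_targets()].
#' @param spacer_ids All spacer ids that were searched.
#' @return List with `per_spacer` (data.table: spacer_id, categories) and
#'   `tally` (named counts for phage, virus, plasmid, unknown, and
#'   `with_target`).
#' @export
categorize_targets <- function(hits, spacer_ids) {
  per <- lapply(spacer_ids, function(sp) {
    cats <- sort(unique(hits$category[hits$spacer_id == sp]))
    if (!length(cats)) cats <- "unknown"
    data.table::data.table(spacer_id = sp,
                           categories = paste(cats, collapse = ","))
  })
  per <- data.table::rbindlist(per)
  tally <- c(
    phage = sum(grepl("\\bphage\\b", per$categories)),
    virus = sum(grepl("\\bvirus\\b", per$categories)),
    plasmid = sum(grepl("\\bplasmid\\b", per$categories)),
    unknown = sum(per$categories == "unknown"),
    with_target = sum(per$categories != "unknown"))
  list(per_spacer = per, tally = tally)
}

#' Partition direct repeats into known/unknown against a reference FASTA
#'
#' A repeat is "known" iff it has at least one seeded alignment to the
#' reference at `evalue <= max_evalue`.
#'
#' @param repeats Named character vector of repeat sequences.
#' @param reference Named character vector of reference repeat sequences
#'   (user-supplied; an empty reference yields all-unknown with a warning).
#' @param max_evalue E-value cutoff (default 0.01).
#' @param scheme A [scoring_scheme()].
#' @return List with `known` and `unknown` (character vectors of repeat
#'   ids).
#' @export
match_repeats_to_reference <- function(repeats, reference,
                                       max_evalue = 0.01,
                                       scheme = scoring_scheme()) {
  if (!length(reference)) {
    warning("empty reference: all repeats unmatched")
    return(list(known = character(0), unknown = names(repeats)))
  }
  known <- vapply(names(repeats), function(rid) {
    for (ref in reference) {
      al <- seeded_align(repeats[[rid]], ref, scheme)
      if (!is.null(al) && al$evalue <= max_evalue) return(TRUE)
    }
    FALSE
  }, logical(1))
  list(known = names(repeats)[known], unknown = names(repeats)[!known])
}
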
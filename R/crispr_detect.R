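#' Detection parameter profile for the CRISPR array detector
#'
#' A profile bundles the seed length and the structural bounds a
#' repeat-spacer array must satisfy. Two built-in profiles ("strict" and
#' "lenient") stand in for the multi-tool consensus used in metagenome
#' CRISPR surveys: an array is trusted when independent parameterizations
#' agree, or when a single profile hit lies on a contig that also carries
#' cas genes.
#'
#' @param name Profile name.
#' @param seed_k Exact seed k-mer length (default 8).
#' @param repeat_len_min,repeat_len_max Direct-repeat length bounds
#'   (defaults 19/48, spanning the common detector defaults).
#' @param spacer_len_min,spacer_len_max Spacer length bounds (19/72).
#' @param max_repeat_divergence Maximum mismatch fraction of any repeat
#'   copy against the array consensus (default 0.2).
#' @param max_spacer_pair_identity Maximum positional identity allowed
#'   between adjacent spacers (default 0.6); higher means a tandem repeat,
#'   not a CRISPR.
#' @param min_spacers Minimum spacer count for a validated array
#'   (default 2).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(name = "strict",
                             seed_k = 8L,
                             repeat_len_min = 19L, repeat_len_max = 48L,
                             spacer_len_min = 19L, spacer_len_max = 72L,
                             max_repeat_divergence = 0.2,
                             max_spacer_pair_identity = 0.6,
                             min_spacers = 2L) {
  stopifnot(seed_k >= 1,
            repeat_len_min <= repeat_len_max,
            spacer_len_min <= spacer_len_max,
            max_repeat_divergence >= 0, max_repeat_divergence <= 1,
            max_spacer_pair_identity >= 0, max_spacer_pair_identity <= 1,
            min_spacers >= 1)
  structure(list(name = name, seed_k = as.integer(seed_k),
                 repeat_len_min = as.integer(repeat_len_min),
                 repeat_len_max = as.integer(repeat_len_max),
                 spacer_len_min = as.integer(spacer_len_min),
                 spacer_len_max = as.integer(spacer_len_max),
                 max_repeat_divergence = max_repeat_divergence,
                 max_spacer_pair_identity = max_spacer_pair_identity,
                 min_spacers = as.integer(min_spacers)),
            class = "detection_params")
}

#' Default detection profiles
#' @return Named list of two `detection_params`: strict and lenient.
#' @export
default_profiles <- function() {
  list(
    strict = detection_params("strict"),
    lenient = detection_params("lenient", seed_k = 7L,
                               repeat_len_min = 17L, repeat_len_max = 50L,
                               spacer_len_min = 15L, spacer_len_max = 80L,
                               max_repeat_divergence = 0.25,
                               max_spacer_pair_identity = 0.7)
  )
}

new_crispr_array <- function(contig_id, repeats, spacers, params_name) {
  consensus <- .consensus_cpp(vapply(repeats, `[[`, character(1), "seq"))
  structure(list(
    contig_id = contig_id,
    start = repeats[[1]]$start,
    end = repeats[[length(repeats)]]$end,
    repeats = repeats,
    spacers = spacers,
    consensus_repeat = consensus,
    n_repeats = length(repeats),
    n_spacers = length(spacers),
    profiles_hit = params_name,
    cas_adjacent = FALSE,
    validated = FALSE,
    crispr_type = NA_character_
  ), class = "crispr_array")
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("<crispr_array> %s:%d-%d  %d repeats / %d spacers  repeat=%s\n",
              x$contig_id, x$start, x$end, x$n_repeats, x$n_spacers,
              x$consensus_repeat))
  cat(sprintf("  profiles: %s  validated: %s  cas_adjacent: %s\n",
              paste(x$profiles_hit, collapse = ","), x$validated,
              x$cas_adjacent))
  invisible(x)
}

# positional identity between two strings: matches at aligned positions
# (no gaps) divided by the longer length
positional_identity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la == 0 || lb == 0) return(0)
  n <- min(la, lb)
  va <- strsplit(substr(a, 1, n), "")[[1]]
  vb <- strsplit(substr(b, 1, n), "")[[1]]
  sum(va == vb) / max(la, lb)
}

# Extend a chain of seed occurrence starts into maximal identical repeat
# copies; enforces the repeat/spacer length bounds during extension.
.extend_chain <- function(seq, starts, k, params) {
  n <- nchar(seq)
  m <- length(starts)
  len <- k
  off <- 0L  # left extension amount; copy i spans [starts[i]-off, +len-1]
  gaps <- function(off, len) {
    s <- starts - off
    e <- s + len - 1L
    if (m < 2) return(integer(0))
    s[-1L] - e[-m] - 1L
  }
  all_eq <- function(positions) {
    ch <- substring(seq, positions, positions)
    all(ch == ch[1L]) && all(positions >= 1L) && all(positions <= n)
  }
  # left extension
  repeat {
    cand <- starts - off - 1L
    if (len >= params$repeat_len_max) break
    if (any(cand < 1L)) break
    if (m >= 2 && any(gaps(off + 1L, len + 1L) < params$spacer_len_min)) break
    if (!all_eq(cand)) break
    off <- off + 1L
    len <- len + 1L
  }
  # right extension
  repeat {
    cand <- starts - off + len
    if (len >= params$repeat_len_max) break
    if (any(cand > n)) break
    if (m >= 2 && any(gaps(off, len + 1L) < params$spacer_len_min)) break
    if (!all_eq(cand)) break
    len <- len + 1L
  }
  s <- starts - off
  list(starts = s, len = len, gaps = gaps(off, len))
}

#' Find candidate CRISPR arrays on one contig
#'
#' Seed-and-extend detector: exact `seed_k`-mers occurring at least twice
#' with inter-occurrence periods compatible with one repeat plus one spacer
#' form chains; each chain is extended to the maximal exactly matching
#' repeat copies, then checked against the repeat/spacer length bounds.
#' Candidates are unvalidated (use [validate_array()]); overlapping
#' candidates are resolved in favor of more repeat copies, then longer
#' repeats, then leftmost start.
#'
#' @param seq Contig sequence (single string) or a length-1 named character
#'   vector as returned by [read_fasta()].
#' @param contig_id Contig id; defaults to `names(seq)`.
#' @param params A [detection_params()] profile.
#' @return A list of `crispr_array` objects sorted by start; empty list if
#'   none.
#' @export
find_candidate_arrays <- function(seq, contig_id = names(seq),
                                  params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  seq <- unname(seq[[1]])
  if (is.null(contig_id)) contig_id <- "contig"
  n <- nchar(seq)
  k <- params$seed_k
  if (n < 2L * params$repeat_len_min + params$spacer_len_min) return(list())
  pmin_ <- params$repeat_len_min + params$spacer_len_min
  pmax_ <- params$repeat_len_max + params$spacer_len_max

  pos <- seq_len(n - k + 1L)
  kmers <- substring(seq, pos, pos + k - 1L)
  grps <- split(pos, kmers)
  sizes <- lengths(grps)
  grps <- grps[sizes >= 2L & sizes <= 2000L]
  if (!length(grps)) return(list())

  candidates <- list()
  seen_keys <- character(0)
  for (p in grps) {
    if (length(p) < 2L) next
    d <- diff(p)
    ok <- d >= pmin_ & d <= pmax_
    # maximal runs of consecutive in-range periods
    r <- rle(ok)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (ri in seq_along(r$values)) {
      if (!r$values[ri]) next
      starts <- p[idx_start[ri]:(idx_end[ri] + 1L)]
      ext <- .extend_chain(seq, starts, k, params)
      if (ext$len < params$repeat_len_min) next
      # split at gaps outside the spacer range
      bad <- which(ext$gaps < params$spacer_len_min |
                     ext$gaps > params$spacer_len_max)
      seg_bounds <- c(0L, bad, length(ext$starts))
      for (si in seq_len(length(seg_bounds) - 1L)) {
        i1 <- seg_bounds[si] + 1L
        i2 <- seg_bounds[si + 1L]
        if (i2 - i1 + 1L < 2L) next
        st <- ext$starts[i1:i2]
        key <- paste(st, collapse = ",")
        key <- paste0(key, ":", ext$len)
        if (key %in% seen_keys) next
        seen_keys <- c(seen_keys, key)
        reps <- lapply(st, function(s0) {
          list(start = s0, end = s0 + ext$len - 1L,
               seq = substr(seq, s0, s0 + ext$len - 1L))
        })
        sps <- lapply(seq_len(length(st) - 1L), function(i) {
          s0 <- st[i] + ext$len
          e0 <- st[i + 1L] - 1L
          list(start = s0, end = e0, seq = substr(seq, s0, e0))
        })
        candidates[[length(candidates) + 1L]] <-
          new_crispr_array(contig_id, reps, sps, params$name)
      }
    }
  }
  if (!length(candidates)) return(list())
  # resolve overlaps: more repeats > longer repeat > leftmost
  ord <- order(-vapply(candidates, `[[`, integer(1), "n_repeats"),
               -vapply(candidates, function(a) nchar(a$consensus_repeat),
                       integer(1)),
               vapply(candidates, `[[`, integer(1), "start"))
  chosen <- list()
  for (i in ord) {
    a <- candidates[[i]]
    clash <- any(vapply(chosen, function(b) {
      a$start <= b$end && b$start <= a$end
    }, logical(1)))
    if (!clash) chosen[[length(chosen) + 1L]] <- a
  }
  chosen[order(vapply(chosen, `[[`, integer(1), "start"))]
}

#' Validate a candidate CRISPR array
#'
#' An array is validated iff it has at least `min_spacers` spacers, every
#' repeat copy is within `max_repeat_divergence` of the consensus, every
#' adjacent spacer pair has positional identity at most
#' `max_spacer_pair_identity`, and all repeat and spacer lengths fall in
#' the configured ranges.
#'
#' @param array A `crispr_array`.
#' @param params A [detection_params()] profile.
#' @return The array with its `validated` flag set.
#' @export
validate_array <- function(array, params = detection_params()) {
  ok <- array$n_spacers >= params$min_spacers
  if (ok) {
    cons <- array$consensus_repeat
    div <- vapply(array$repeats, function(r) {
      1 - positional_identity(r$seq, cons)
    }, numeric(1))
    ok <- all(div <= params$max_repeat_divergence)
  }
  if (ok) {
    rl <- vapply(array$repeats, function(r) nchar(r$seq), integer(1))
    sl <- vapply(array$spacers, function(s) nchar(s$seq), integer(1))
    ok <- all(rl >= params$repeat_len_min & rl <= params$repeat_len_max) &&
      all(sl >= params$spacer_len_min & sl <= params$spacer_len_max)
  }
  if (ok && array$n_spacers >= 2L) {
    for (i in seq_len(array$n_spacers - 1L)) {
      id <- positional_identity(array$spacers[[i]]$seq,
                                array$spacers[[i + 1L]]$seq)
      if (id > params$max_spacer_pair_identity) { ok <- FALSE; break }
    }
  }
  array$validated <- isTRUE(ok)
  array
}

#' Multi-profile consensus CRISPR detection
#'
#' Runs the detector once per profile on every contig and retains arrays
#' detected by at least two profiles, or by at least one profile on a
#' contig known to carry cas genes. Arrays from different profiles whose
#' coordinates overlap are merged (union span; the repeat/spacer structure
#' of the hit with most repeats is kept). Every retained array must pass
#' [validate_array()] under at least one of its detecting profiles.
#'
#' @param contigs Named character vector of contig sequences.
#' @param profiles List of [detection_params()] (>= 1; the consensus rule
#'   needs >= 2 to be meaningful).
#' @param cas_contig_ids Character vector of contig ids carrying cas genes.
#' @return List of validated `crispr_array` objects, ordered by contig then
#'   start.
#' @export
detect_consensus <- function(contigs, profiles = default_profiles(),
                             cas_contig_ids = character(0)) {
  if (length(profiles) < 1L) stop("at least one detection profile required")
  per_profile <- lapply(profiles, function(p) {
    hits <- lapply(names(contigs), function(id) {
      find_candidate_arrays(contigs[[id]], id, p)
    })
    unlist(hits, recursive = FALSE)
  })
  # merge across profiles by coordinate overlap on the same contig
  all_hits <- unlist(per_profile, recursive = FALSE)
  if (!length(all_hits)) return(list())
  merged <- list()
  for (a in all_hits) {
    placed <- FALSE
    for (i in seq_along(merged)) {
      b <- merged[[i]]
      if (a$contig_id == b$contig_id && a$start <= b$end && b$start <= a$end) {
        # union span; keep structure of the richer hit
        keep <- if (a$n_repeats > b$n_repeats) a else b
        keep$start <- min(a$start, b$start)
        keep$end <- max(a$end, b$end)
        keep$profiles_hit <- sort(unique(c(a$profiles_hit, b$profiles_hit)))
        merged[[i]] <- keep
        placed <- TRUE
        break
      }
    }
    if (!placed) merged[[length(merged) + 1L]] <- a
  }
  prof_by_name <- stats::setNames(profiles,
                                  vapply(profiles, `[[`, character(1), "name"))
  out <- list()
  for (a in merged) {
    retained <- length(a$profiles_hit) >= 2L ||
      a$contig_id %in% cas_contig_ids
    if (!retained) next
    ok <- FALSE
    for (pn in a$profiles_hit) {
      v <- validate_array(a, prof_by_name[[pn]])
      if (v$validated) { ok <- TRUE; a <- v; break }
    }
    if (ok) out[[length(out) + 1L]] <- a
  }
  if (!length(out)) return(list())
  out[order(vapply(out, `[[`, character(1), "contig_id"),
            vapply(out, `[[`, integer(1), "start"))]
}

#' Tabulate CRISPR arrays
#'
#' @param arrays List of `crispr_array` objects.
#' @return A `data.table` (contig, start, end, n_repeats, n_spacers,
#'   consensus_repeat, profiles, validated, cas_adjacent).
#' @export
arrays_to_table <- function(arrays) {
  if (!length(arrays)) {
    return(data.table::data.table(
      contig = character(0), start = integer(0), end = integer(0),
      n_repeats = integer(0), n_spacers = integer(0),
      consensus_repeat = character(0), profiles = character(0),
      validated = logical(0), cas_adjacent = logical(0)))
  }
  data.table::rbindlist(lapply(arrays, function(a) {
    data.table::data.table(
      contig = a$contig_id, start = a$start, end = a$end,
      n_repeats = a$n_repeats, n_spacers = a$n_spacers,
      consensus_repeat = a$consensus_repeat,
      profiles = paste(a$profiles_hit, collapse = ","),
      validated = a$validated, cas_adjacent = a$cas_adjacent)
  }))
}

#' Write spacer and repeat FASTA files for a set of arrays
#'
#' Ids encode sample, array ordinal and segment ordinal, e.g.
#' `s1_array3_spacer2`.
#'
#' @param arrays List of `crispr_array` objects.
#' @param sample_id Sample identifier used in FASTA ids.
#' @param spacer_path,repeat_path Output FASTA paths (NULL to skip).
#' @return Invisibly, a list with the spacer and repeat named vectors.
#' @export
write_array_fastas <- function(arrays, sample_id,
                               spacer_path = NULL, repeat_path = NULL) {
  spacers <- character(0); repeats <- character(0)
  for (ai in seq_along(arrays)) {
    a <- arrays[[ai]]
    for (si in seq_along(a$spacers)) {
      spacers[sprintf("%s_array%d_spacer%d", sample_id, ai, si)] <-
        a$spacers[[si]]$seq
    }
    for (ri in seq_along(a$repeats)) {
      repeats[sprintf("%s_array%d_repeat%d", sample_id, ai, ri)] <-
        a$repeats[[ri]]$seq
    }
  }
  if (!is.null(spacer_path) && length(spacers)) write_fasta(spacers, spacer_path)
  if (!is.null(repeat_path) && length(repeats)) write_fasta(repeats, repeat_path)
  invisible(list(spacers = spacers, repeats = repeats))
}
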
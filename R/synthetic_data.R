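#' Configuration for the synthetic metagenome generator
#'
#' The defaults describe a sponge-like, defense-rich sample at desk scale:
#' 20 contigs of 20-50 kb, GC 0.60, 10 planted repeat-spacer arrays
#' (repeat 32 nt, spacer 36 nt, 3-6 spacers, mutation rate 0), half of the
#' arrays with an adjacent cas operon, 5 single-spacer decoy loci, 8
#' complete RMS pairs (REase-MTase within 4 gene ordinals; 3 type I, 3
#' type II, 2 type III) plus 6 isolated decoy singletons, and per-position
#' Poisson depth around per-contig targets of 5-50x. A seawater-like
#' sample is the same world with zero planted defense features and GC
#' 0.41.
#'
#' @param n_contigs Number of contigs.
#' @param contig_len_min,contig_len_max Contig length bounds (nt).
#' @param gc Background GC fraction.
#' @param n_arrays Number of planted CRISPR arrays.
#' @param repeat_len,spacer_len Planted repeat/spacer lengths.
#' @param n_spacers_min,n_spacers_max Spacer count range per array.
#' @param mutation_rate Per-base substitution rate applied to repeat
#'   copies.
#' @param cas_fraction Fraction of arrays given an adjacent cas operon.
#' @param n_decoy_arrays Single-spacer decoy loci (must be rejected by the
#'   validator).
#' @param n_rms Named integer vector of complete RMS per type
#'   (`c(I=, II=, III=)`).
#' @param rms_distance_max Maximum REase-MTase gene distance for planted
#'   systems.
#' @param n_decoy_rms Isolated singleton REase/MTase genes (no partner
#'   within the pairing window).
#' @param n_lowcov_hits RMS hits emitted below the 70% coverage cutoff
#'   (filter exercise).
#' @param coverage_min,coverage_max Per-contig target coverage range.
#' @param depth_model "poisson" or "constant".
#' @param gene_len,gene_gap Gene grid geometry (nt).
#' @param taxa Taxon label pool for contigs.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_contigs = 20L,
                              contig_len_min = 20000L,
                              contig_len_max = 50000L,
                              gc = 0.60,
                              n_arrays = 10L,
                              repeat_len = 32L, spacer_len = 36L,
                              n_spacers_min = 3L, n_spacers_max = 6L,
                              mutation_rate = 0,
                              cas_fraction = 0.5,
                              n_decoy_arrays = 5L,
                              n_rms = c(I = 3L, II = 3L, III = 2L),
                              rms_distance_max = 4L,
                              n_decoy_rms = 6L,
                              n_lowcov_hits = 3L,
                              coverage_min = 5, coverage_max = 50,
                              depth_model = c("poisson", "constant"),
                              gene_len = 900L, gene_gap = 100L,
                              taxa = c("Proteobacteria", "Actinobacteria",
                                       "Chloroflexi", "Firmicutes",
                                       "Bacteroidetes", "Cyanobacteria")) {
  depth_model <- match.arg(depth_model)
  stopifnot(n_contigs >= 1, contig_len_min <= contig_len_max,
            gc >= 0, gc <= 1, mutation_rate >= 0, mutation_rate <= 1,
            cas_fraction >= 0, cas_fraction <= 1,
            all(n_rms >= 0), n_decoy_arrays >= 0, n_decoy_rms >= 0,
            coverage_min >= 0, coverage_min <= coverage_max)
  structure(as.list(environment()), class = "simulation_config")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- strsplit(s, NULL)[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) {
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  }
  paste(v, collapse = "")
}

# Longest run of positionally identical bases between two equal-length
# strings; used for the detectability expectation (an exact seed k-mer
# must survive in adjacent repeat copies).
.longest_common_run <- function(a, b) {
  va <- strsplit(a, NULL)[[1]]; vb <- strsplit(b, NULL)[[1]]
  eq <- va == vb
  if (!any(eq)) return(0L)
  max(rle(eq)$lengths[rle(eq)$values])
}

#' Plant one CRISPR array into a contig sequence
#'
#' Overwrites the region starting at `position` with the block
#' `repeat, spacer1, repeat, spacer2, ..., repeat` (length
#' `(n+1) * repeat_len + n * spacer_len`). Each repeat copy is mutated
#' independently at `mutation_rate`. Spacers must be pairwise dissimilar
#' (positional identity <= 0.6); callers generate them, this function
#' enforces the precondition.
#'
#' @param seq Contig sequence.
#' @param position 1-based insertion start.
#' @param repeat_seq Template repeat.
#' @param spacers Character vector of spacers (>= 1).
#' @param mutation_rate Per-base substitution rate on repeat copies.
#' @param detect_params [detection_params()] used for the detectability
#'   expectation (default strict profile).
#' @return List: `seq` (modified contig), `truth` (data.table row with
#'   coordinates, n_spacers, max divergence, expected_detectable).
#' @export
plant_crispr <- function(seq, position, repeat_seq, spacers,
                         mutation_rate = 0,
                         detect_params = detection_params()) {
  stopifnot(length(spacers) >= 1)
  if (length(spacers) >= 2) {
    for (i in 1:(length(spacers) - 1)) for (j in (i + 1):length(spacers)) {
      if (positional_identity(spacers[i], spacers[j]) > 0.6) {
        stop("spacers too similar (identity > 0.6): regenerate them")
      }
    }
  }
  n_rep <- length(spacers) + 1L
  copies <- vapply(seq_len(n_rep), function(i) {
    mutate_seq(repeat_seq, mutation_rate)
  }, character(1))
  parts <- character(0)
  for (i in seq_along(spacers)) parts <- c(parts, copies[i], spacers[i])
  parts <- c(parts, copies[n_rep])
  block <- paste(parts, collapse = "")
  if (position < 1 || position + nchar(block) - 1L > nchar(seq)) {
    stop("planted array does not fit in contig (position ", position,
         ", block length ", nchar(block), ", contig ", nchar(seq), ")")
  }
  newseq <- paste0(substr(seq, 1, position - 1L), block,
                   substr(seq, position + nchar(block), nchar(seq)))
  # keep the planted block maximal: if the characters preceding every
  # repeat copy (or following every copy) happen to agree, a seed-extend
  # detector would rightly extend the repeat one base past the planted
  # boundary; break such ties in the flanking background so truth
  # coordinates equal the maximal extension
  bases <- c("A", "C", "G", "T")
  end_pos <- position + nchar(block) - 1L
  if (position > 1L) {
    before <- c(substr(newseq, position - 1L, position - 1L),
                substring(spacers, nchar(spacers), nchar(spacers)))
    if (length(unique(before)) == 1L) {
      substr(newseq, position - 1L, position - 1L) <-
        setdiff(bases, before[1L])[1L]
    }
  }
  if (end_pos < nchar(newseq)) {
    after <- c(substring(spacers, 1L, 1L),
               substr(newseq, end_pos + 1L, end_pos + 1L))
    if (length(unique(after)) == 1L) {
      substr(newseq, end_pos + 1L, end_pos + 1L) <-
        setdiff(bases, after[1L])[1L]
    }
  }
  div <- vapply(copies, function(cp) {
    1 - positional_identity(cp, repeat_seq)
  }, numeric(1))
  runs <- if (n_rep >= 2) {
    vapply(1:(n_rep - 1), function(i) {
      .longest_common_run(copies[i], copies[i + 1L])
    }, integer(1))
  } else integer(0)
  detectable <- all(div <= detect_params$max_repeat_divergence) &&
    (length(runs) == 0 || all(runs >= detect_params$seed_k)) &&
    length(spacers) >= detect_params$min_spacers
  list(seq = newseq,
       truth = data.table::data.table(
         start = position, end = position + nchar(block) - 1L,
         n_repeats = n_rep, n_spacers = length(spacers),
         repeat_seq = repeat_seq, max_divergence = max(div),
         expected_detectable = detectable))
}

#' Simulate per-position depth
#'
#' Per-position depths are Poisson around the contig's target coverage
#' (or exactly the rounded target under the "constant" model, for exact
#' arithmetic tests). The total mapped basepairs is the exact sum of the
#' emitted depths, so cpm conservation holds by construction.
#'
#' @param lengths Named integer vector of contig lengths.
#' @param targets Numeric vector of target coverages (recycled).
#' @param model "poisson" or "constant".
#' @return List: `depths` (named list of integer vectors),
#'   `total_mapped_bp`.
#' @export
simulate_depth <- function(lengths, targets,
                           model = c("poisson", "constant")) {
  model <- match.arg(model)
  stopifnot(all(targets >= 0))
  targets <- rep_len(targets, length(lengths))
  depths <- stats::setNames(vector("list", length(lengths)), names(lengths))
  for (i in seq_along(lengths)) {
    depths[[i]] <- if (model == "poisson") {
      stats::rpois(lengths[[i]], targets[[i]])
    } else {
      rep(as.integer(round(targets[[i]])), lengths[[i]])
    }
  }
  total <- sum(vapply(depths, function(v) sum(as.numeric(v)), numeric(1)))
  list(depths = depths, total_mapped_bp = total)
}

.gen_distinct_spacers <- function(n, len, gc, max_tries = 200L) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    cand <- random_dna(len, gc)
    ok <- all(vapply(out, function(s) {
      positional_identity(s, cand) <= 0.6
    }, logical(1)))
    if (ok) out <- c(out, cand) else {
      tries <- tries + 1L
      if (tries > max_tries) stop("cannot generate dissimilar spacers")
    }
  }
  out
}

#' Simulate one synthetic metagenome sample
#'
#' Deterministic for a fixed seed. Returns all inputs the analysis
#' pipeline consumes (contigs, gene table, domain hits, depth) plus the
#' ground-truth ledger of every planted feature.
#'
#' @param config A [simulation_config()].
#' @param seed Mandatory integer seed.
#' @param sample_id Sample identifier used in record ids.
#' @return List of class `synthetic_sample` with elements `contigs`,
#'   `genes`, `domain_hits`, `depths`, `total_mapped_bp`, `truth` (list of
#'   data.tables: arrays, decoy_arrays, cas_operons, rms, decoy_rms,
#'   contigs), `config`, `seed`.
#' @export
simulate_sample <- function(config = simulation_config(), seed,
                            sample_id = "s1") {
  stopifnot(inherits(config, "simulation_config"))
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  cfg <- config

  lens <- sample(cfg$contig_len_min:cfg$contig_len_max, cfg$n_contigs,
                 replace = TRUE)
  ids <- sprintf("%s_c%03d", sample_id, seq_len(cfg$n_contigs))
  names(lens) <- ids
  contigs <- stats::setNames(
    vapply(lens, random_dna, character(1), gc = cfg$gc), ids)

  # --- plant arrays (real + single-spacer decoys), round-robin on contigs
  block_len <- function(n_sp) {
    (n_sp + 1L) * cfg$repeat_len + n_sp * cfg$spacer_len
  }
  max_block <- block_len(cfg$n_spacers_max)
  margin <- 600L
  occupied <- stats::setNames(rep(list(data.frame(s = integer(0),
                                                  e = integer(0))), length(ids)),
                              ids)
  place_block <- function(cid, blen) {
    len <- lens[[cid]]
    for (try in 1:100) {
      pos <- sample.int(len - blen - 2L * margin, 1L) + margin
      occ <- occupied[[cid]]
      if (!any(pos <= occ$e + margin & occ$s - margin <= pos + blen - 1L)) {
        occupied[[cid]] <<- rbind(occ, data.frame(s = pos, e = pos + blen - 1L))
        return(pos)
      }
    }
    stop("cannot place feature on contig ", cid)
  }
  min_needed <- max_block + 2L * margin + 2L
  if (any(lens < min_needed) && (cfg$n_arrays > 0 || cfg$n_decoy_arrays > 0)) {
    stop("contig too short to host a planted array: need >= ", min_needed)
  }

  truth_arrays <- list(); truth_decoys <- list()
  arr_contigs <- character(0)
  n_total_arr <- cfg$n_arrays + cfg$n_decoy_arrays
  host_cycle <- rep_len(ids, max(n_total_arr, 1L))
  for (ai in seq_len(cfg$n_arrays)) {
    cid <- host_cycle[ai]
    n_sp <- sample(cfg$n_spacers_min:cfg$n_spacers_max, 1L)
    pos <- place_block(cid, block_len(n_sp))
    rep_seq <- random_dna(cfg$repeat_len, 0.5)
    spacers <- .gen_distinct_spacers(n_sp, cfg$spacer_len, 0.5)
    pl <- plant_crispr(contigs[[cid]], pos, rep_seq, spacers,
                       cfg$mutation_rate)
    contigs[[cid]] <- pl$seq
    tr <- pl$truth
    tr[, `:=`(feature = "array", array_id = sprintf("arr%02d", ai),
              contig = cid)]
    truth_arrays[[ai]] <- tr
    arr_contigs <- c(arr_contigs, cid)
  }
  for (di in seq_len(cfg$n_decoy_arrays)) {
    cid <- host_cycle[cfg$n_arrays + di]
    pos <- place_block(cid, block_len(1L))
    rep_seq <- random_dna(cfg$repeat_len, 0.5)
    spacers <- .gen_distinct_spacers(1L, cfg$spacer_len, 0.5)
    pl <- plant_crispr(contigs[[cid]], pos, rep_seq, spacers,
                       cfg$mutation_rate)
    contigs[[cid]] <- pl$seq
    tr <- pl$truth
    tr[, `:=`(feature = "decoy_array", array_id = sprintf("dec%02d", di),
              contig = cid)]
    truth_decoys[[di]] <- tr
  }
  empty_truth <- data.table::data.table(
    start = integer(0), end = integer(0), n_repeats = integer(0),
    n_spacers = integer(0), repeat_seq = character(0),
    max_divergence = numeric(0), expected_detectable = logical(0),
    feature = character(0), array_id = character(0), contig = character(0))
  truth_arrays <- if (length(truth_arrays))
    data.table::rbindlist(truth_arrays) else empty_truth
  truth_decoys <- if (length(truth_decoys))
    data.table::rbindlist(truth_decoys) else empty_truth

  # --- gene grid: tile each contig, drop genes overlapping planted loci,
  # reindex consecutively from 0 in coordinate order
  gene_rows <- list()
  for (cid in ids) {
    starts <- seq(1L, lens[[cid]] - cfg$gene_len,
                  by = cfg$gene_len + cfg$gene_gap)
    ends <- starts + cfg$gene_len - 1L
    occ <- occupied[[cid]]
    keep <- !vapply(seq_along(starts), function(i) {
      any(starts[i] <= occ$e & occ$s <= ends[i])
    }, logical(1))
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) next
    gene_rows[[cid]] <- data.table::data.table(
      gene_id = sprintf("%s_g%04d", cid, seq_along(starts)),
      contig_id = cid, index = seq_along(starts) - 1L,
      start = starts, end = ends,
      strand = sample(c("+", "-"), length(starts), replace = TRUE))
  }
  genes <- data.table::rbindlist(gene_rows)

  # --- cas operons adjacent to a fraction of the arrays
  cas_map <- load_cas_map()
  operon_templates <- list(
    I = c(cas1 = "COG1518", cas2 = "COG1343", cas3 = "COG1203"),
    II = c(cas1 = "COG1518", cas2 = "COG1343", cas9 = "TIGR01865"),
    III = c(cas1 = "COG1518", cas2 = "COG1343", cas10 = "COG1353"))
  hit_rows <- list()
  truth_cas <- list()
  used_idx <- stats::setNames(rep(list(integer(0)), length(ids)), ids)
  n_cas <- round(cfg$cas_fraction * cfg$n_arrays)
  cas_arrays <- if (n_cas > 0) seq_len(n_cas) else integer(0)
  for (ai in cas_arrays) {
    tr <- truth_arrays[ai]
    cid <- tr$contig
    # the three genes nearest the array (either side); adjacency linking
    # groups them as long as their index span stays within the gap window
    gsub <- genes[contig_id == cid]
    if (nrow(gsub) < 3L) {
      stop("no room for a cas operon next to array on ", cid)
    }
    dist_to_array <- pmax(0L, pmax(tr$start - gsub$end,
                                   gsub$start - tr$end))
    slot <- gsub[order(dist_to_array, index)][1:3][order(index)]
    ty <- sample(names(operon_templates), 1L)
    tmpl <- operon_templates[[ty]]
    for (k in seq_along(tmpl)) {
      hit_rows[[length(hit_rows) + 1L]] <- data.table::data.table(
        gene_id = slot$gene_id[k], accession = unname(tmpl[k]),
        source_db = if (startsWith(tmpl[[k]], "COG")) "COG" else "TIGRFAM",
        evalue = 10^-stats::runif(1, 20, 60), query_coverage = stats::runif(1, .8, 1),
        role = NA_character_, rms_type = NA_character_)
    }
    used_idx[[cid]] <- c(used_idx[[cid]], slot$index)
    truth_cas[[length(truth_cas) + 1L]] <- data.table::data.table(
      array_id = tr$array_id, contig = cid, cas_type = ty,
      gene_ids = paste(slot$gene_id, collapse = ","),
      index_min = min(slot$index), index_max = max(slot$index))
  }
  truth_cas <- if (length(truth_cas)) data.table::rbindlist(truth_cas) else
    data.table::data.table(array_id = character(0), contig = character(0),
                           cas_type = character(0), gene_ids = character(0),
                           index_min = integer(0), index_max = integer(0))

  # --- RMS systems and decoy singletons on the gene grid.
  # Same-category features stay > rms_distance_max gene ordinals apart so
  # planted systems never merge and decoys never acquire a partner; cas
  # genes only block direct overlap (they carry no REBASE role, so
  # proximity to them is harmless).
  rms_sep <- cfg$rms_distance_max + 1L
  used_rms <- stats::setNames(rep(list(integer(0)), length(ids)), ids)
  take_slot <- function(width, isolate = TRUE) {
    for (cid in sample(ids)) {
      gsub <- genes[contig_id == cid]
      if (nrow(gsub) < width) next
      max_idx <- max(gsub$index)
      for (i0 in 0:(max_idx - width + 1L)) {
        i1 <- i0 + width - 1L
        idxs <- i0:i1
        if (any(idxs %in% used_idx[[cid]])) next
        if (isolate) {
          guard <- (i0 - rms_sep):(i1 + rms_sep)
          if (any(guard %in% used_rms[[cid]])) next
        }
        used_idx[[cid]] <<- c(used_idx[[cid]], idxs)
        if (isolate) used_rms[[cid]] <<- c(used_rms[[cid]], idxs)
        return(gsub[order(index)][index %in% idxs])
      }
    }
    stop("no gene-grid slot available for RMS placement")
  }
  truth_rms <- list(); truth_decoy_rms <- list()
  rms_counter <- 0L
  for (ty in names(cfg$n_rms)) {
    for (k in seq_len(cfg$n_rms[[ty]])) {
      rms_counter <- rms_counter + 1L
      d <- sample(seq_len(cfg$rms_distance_max), 1L)
      slot <- take_slot(d + 1L)
      re_first <- sample(c(TRUE, FALSE), 1L)
      g_re <- if (re_first) slot[1L] else slot[nrow(slot)]
      g_mt <- if (re_first) slot[nrow(slot)] else slot[1L]
      for (g in list(list(row = g_re, role = "REase"),
                     list(row = g_mt, role = "MTase"))) {
        hit_rows[[length(hit_rows) + 1L]] <- data.table::data.table(
          gene_id = g$row$gene_id, accession = paste0("REBASE_", g$role),
          source_db = "REBASE", evalue = 10^-stats::runif(1, 10, 40),
          query_coverage = stats::runif(1, 0.75, 1),
          role = g$role, rms_type = ty)
      }
      truth_rms[[rms_counter]] <- data.table::data.table(
        rms_id = sprintf("rms%02d", rms_counter), contig = g_re$contig_id,
        rms_type = ty, rease_gene = g_re$gene_id, mtase_gene = g_mt$gene_id,
        index_min = min(slot$index), index_max = max(slot$index),
        distance = d)
    }
  }
  for (k in seq_len(cfg$n_decoy_rms)) {
    role <- if (k %% 2L == 0L) "REase" else "MTase"
    ty <- sample(c("I", "II", "III"), 1L)
    slot <- take_slot(1L)
    hit_rows[[length(hit_rows) + 1L]] <- data.table::data.table(
      gene_id = slot$gene_id, accession = paste0("REBASE_", role),
      source_db = "REBASE", evalue = 10^-stats::runif(1, 10, 40),
      query_coverage = stats::runif(1, 0.75, 1),
      role = role, rms_type = ty)
    truth_decoy_rms[[k]] <- data.table::data.table(
      decoy_id = sprintf("drms%02d", k), contig = slot$contig_id,
      rms_type = ty, role = role, gene_id = slot$gene_id,
      index = slot$index)
  }
  # sub-threshold coverage hits (exercise the >= 70% filter); they are
  # discarded by the coverage filter, so they need no isolation
  for (k in seq_len(cfg$n_lowcov_hits)) {
    slot <- take_slot(1L, isolate = FALSE)
    hit_rows[[length(hit_rows) + 1L]] <- data.table::data.table(
      gene_id = slot$gene_id, accession = "REBASE_REase",
      source_db = "REBASE", evalue = 10^-stats::runif(1, 10, 40),
      query_coverage = stats::runif(1, 0.3, 0.69),
      role = "REase", rms_type = sample(c("I", "II", "III"), 1L))
  }
  domain_hits <- if (length(hit_rows)) data.table::rbindlist(hit_rows) else
    data.table::data.table(gene_id = character(0), accession = character(0),
                           source_db = character(0), evalue = numeric(0),
                           query_coverage = numeric(0), role = character(0),
                           rms_type = character(0))
  truth_rms <- if (length(truth_rms)) data.table::rbindlist(truth_rms) else
    data.table::data.table(rms_id = character(0), contig = character(0),
                           rms_type = character(0), rease_gene = character(0),
                           mtase_gene = character(0), index_min = integer(0),
                           index_max = integer(0), distance = integer(0))
  truth_decoy_rms <- if (length(truth_decoy_rms))
    data.table::rbindlist(truth_decoy_rms) else
      data.table::data.table(decoy_id = character(0), contig = character(0),
                             rms_type = character(0), role = character(0),
                             gene_id = character(0), index = integer(0))

  # --- coverage and taxonomy
  targets <- stats::runif(length(lens), cfg$coverage_min, cfg$coverage_max)
  dep <- simulate_depth(lens, targets, cfg$depth_model)
  contig_truth <- data.table::data.table(
    contig = ids, length = as.integer(lens),
    target_coverage = targets,
    taxon = sample(cfg$taxa, length(ids), replace = TRUE))

  structure(list(
    sample_id = sample_id,
    contigs = contigs,
    genes = genes,
    domain_hits = domain_hits,
    depths = dep$depths,
    total_mapped_bp = dep$total_mapped_bp,
    truth = list(arrays = truth_arrays, decoy_arrays = truth_decoys,
                 cas_operons = truth_cas, rms = truth_rms,
                 decoy_rms = truth_decoy_rms, contigs = contig_truth),
    config = cfg, seed = seed), class = "synthetic_sample")
}

#' Write a synthetic sample to disk in the pipeline's input formats
#'
#' Emits contigs.fasta, genes.tsv, domain_hits.tsv, depth.tsv,
#' total_mapped_bp.txt, and the truth ledger as both TSV files and one
#' JSON document.
#'
#' @param sim A `synthetic_sample`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sample <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$contigs, file.path(dir, "contigs.fasta"))
  data.table::fwrite(sim$genes, file.path(dir, "genes.tsv"), sep = "\t")
  data.table::fwrite(sim$domain_hits, file.path(dir, "domain_hits.tsv"),
                     sep = "\t")
  write_depth_table(sim$depths, file.path(dir, "depth.tsv"))
  writeLines(format(sim$total_mapped_bp, scientific = FALSE),
             file.path(dir, "total_mapped_bp.txt"))
  for (nm in names(sim$truth)) {
    data.table::fwrite(sim$truth[[nm]],
                       file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t")
  }
  jsonlite::write_json(lapply(sim$truth, as.data.frame),
                       file.path(dir, "truth.json"), dataframe = "rows",
                       digits = NA)
  invisible(dir)
}
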
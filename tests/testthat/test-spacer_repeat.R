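test_that("collect_spacers reports multiplicities, distinct and singleton counts", {
  mk <- function(contig, spacer_seqs) {
    structure(list(contig_id = contig, start = 1L, end = 100L,
                   repeats = list(), consensus_repeat = "",
                   spacers = lapply(spacer_seqs, function(s) {
                     list(start = 1L, end = nchar(s), seq = s)
                   }),
                   n_repeats = length(spacer_seqs) + 1L,
                   n_spacers = length(spacer_seqs),
                   profiles_hit = "strict", cas_adjacent = FALSE,
                   validated = TRUE, crispr_type = NA_character_),
              class = "crispr_array")
  }
  got <- collect_spacers(list(mk("c1", c("AAA", "CCC")), mk("c2", "AAA")))
  expect_equal(got$n_total, 3)
  expect_equal(got$n_distinct, 2)
  expect_equal(got$n_singleton, 1)
  expect_equal(got$n_multi, 1)
  expect_equal(got$catalogue[sequence == "AAA"]$count, 2)

  empty <- collect_spacers(list())
  expect_equal(empty$n_total, 0)
  expect_equal(nrow(empty$catalogue), 0)

  set.seed(31)
  ten <- vapply(1:10, function(i) rnd_dna(36), character(1))
  got10 <- collect_spacers(lapply(seq_along(ten), function(i) {
    mk(paste0("c", i), ten[i])
  }))
  expect_equal(got10$n_distinct, 10)
  expect_equal(got10$n_singleton, 10)
})

test_that("shared_sequences is symmetric and counts sequences once", {
  a <- c("X1" = "ACGTACGT", "X2" = "GGGGCCCC")
  b <- c("Y1" = "GGGGCCCC", "Y2" = "TTTTAAAA")
  expect_equal(shared_sequences(a, b)$count, 1)
  expect_equal(shared_sequences(a, b)$shared,
               shared_sequences(b, a)$shared)
  expect_equal(shared_sequences(a, c("Z" = "ACACACAC"))$count, 0)
  expect_equal(shared_sequences(a, a)$count, 2)
  # multiplicity does not inflate the count
  expect_equal(shared_sequences(c(a, "X3" = "GGGGCCCC"), b)$count, 1)
})

test_that("search_targets scores verbatim and mutated embeddings exactly", {
  set.seed(32)
  sp <- rnd_dna(25)
  tgt <- rnd_dna(900)
  tgt <- paste0(substr(tgt, 1, 399), sp, substr(tgt, 425, 900))
  targets <- c(t1 = tgt)
  hits <- search_targets(c(sp1 = sp), targets,
                         categories = c(t1 = "phage"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$score, 25)     # 25 matches x +1
  expect_equal(hits$category, "phage")

  sp_mut <- sp
  substr(sp_mut, 13, 13) <- chartr("ACGT", "TGCA", substr(sp, 13, 13))
  hits2 <- search_targets(c(sp1 = sp_mut), targets,
                          categories = c(t1 = "phage"))
  expect_equal(hits2$score, 23)    # 24 * (+1) + 1 * (-1)
})

test_that("search_targets requires a shared 7-mer and category labels", {
  # spacer and target sharing no 7-mer on either strand
  sp <- paste(rep("AC", 15), collapse = "")   # (AC)15
  tgt <- paste(rep("G", 200), collapse = "")
  expect_equal(nrow(search_targets(c(s = sp), c(t = tgt),
                                   categories = c(t = "virus"))), 0)
  expect_error(search_targets(c(s = sp), c(t = tgt)), "category")
  expect_error(search_targets(c(s = sp), c(t = tgt),
                              categories = c(t = "weird")), "unknown target")
  expect_error(search_targets(c(s = "ACG"), c(t = tgt),
                              categories = c(t = "virus")), "word size")
})

test_that("reverse-strand protospacers are found", {
  set.seed(33)
  sp <- rnd_dna(30)
  tgt <- rnd_dna(500)
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(sp, NULL)[[1]]), collapse = ""))
  tgt <- paste0(substr(tgt, 1, 99), rc, substr(tgt, 130, 500))
  hits <- search_targets(c(s = sp), c(t = tgt), categories = c(t = "plasmid"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "-")
  expect_equal(hits$score, 30)
})

test_that("seeded aligner equals exhaustive Smith-Waterman when seeded", {
  set.seed(34)
  scheme <- scoring_scheme()
  submat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
  n_checked <- 0
  for (i in 1:20) {
    q <- rnd_dna(sample(20:60, 1))
    s <- rnd_dna(sample(200:600, 1))
    if (i %% 2 == 0) {  # embed with one substitution to force a seed
      p <- sample(nchar(s) - nchar(q), 1)
      qq <- q
      substr(qq, 5, 5) <- "T"
      s <- paste0(substr(s, 1, p - 1), qq, substr(s, p + nchar(q), nchar(s)))
    }
    al <- seeded_align(q, s, scheme, both_strands = FALSE)
    if (is.null(al)) next
    oracle <- Biostrings::pairwiseAlignment(
      q, s, type = "local", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
    expect_equal(al$score, oracle)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 10)
})

test_that("E-values decrease in score and raising the cutoff never loses hits", {
  scheme <- scoring_scheme()
  expect_equal(scheme$lambda, log(3), tolerance = 1e-9)
  ev <- vapply(20:30, alignment_evalue, numeric(1), m = 36, n = 1000,
               scheme = scheme)
  expect_true(all(diff(ev) < 0))

  set.seed(35)
  spacers <- setNames(vapply(1:5, function(i) rnd_dna(30), character(1)),
                      paste0("s", 1:5))
  tgt <- rnd_dna(800)
  tgt <- paste0(substr(tgt, 1, 50), spacers[["s1"]],
                substr(tgt, 81, 800))
  targets <- c(t = tgt)
  cats <- c(t = "phage")
  n_tight <- nrow(search_targets(spacers, targets, cats,
                                 scoring_scheme(evalue_max = 1e-6)))
  n_loose <- nrow(search_targets(spacers, targets, cats,
                                 scoring_scheme(evalue_max = 0.5)))
  expect_gte(n_loose, n_tight)
})

test_that("categorize_targets multi-counts categories and defaults to unknown", {
  hits <- data.table::data.table(
    spacer_id = c("s1", "s1", "s2"),
    target_id = c("t1", "t2", "t3"),
    category = c("phage", "plasmid", "plasmid"),
    score = 25, evalue = 1e-8, strand = "+",
    q_start = 1L, q_end = 25L, s_start = 1L, s_end = 25L)
  got <- categorize_targets(hits, c("s1", "s2", "s3"))
  expect_equal(unname(got$tally["phage"]), 1)
  expect_equal(unname(got$tally["plasmid"]), 2)
  expect_equal(unname(got$tally["unknown"]), 1)
  expect_equal(unname(got$tally["with_target"]), 2)
  # category sums can exceed the number of spacers with a target
  expect_gt(sum(got$tally[c("phage", "virus", "plasmid")]),
            got$tally[["with_target"]] - 1)
})

test_that("repeat-reference matching partitions known from unknown", {
  set.seed(36)
  ref_rep <- rnd_dna(32)
  reference <- c(ref1 = ref_rep)
  reps <- c(known1 = ref_rep, novel1 = rnd_dna(32))
  got <- match_repeats_to_reference(reps, reference)
  expect_identical(got$known, "known1")
  expect_identical(got$unknown, "novel1")
  expect_warning(out <- match_repeats_to_reference(reps, character(0)),
                 "empty reference")
  expect_length(out$known, 0)
})
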
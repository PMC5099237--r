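test_that("a planted array is recovered with exact structure", {
  set.seed(21)
  R <- rnd_dna(32)
  S <- c(rnd_dna(36), rnd_dna(36))
  pl <- make_array_contig(R, S)
  cand <- find_candidate_arrays(pl$seq, "c1", detection_params())
  expect_length(cand, 1)
  a <- cand[[1]]
  expect_equal(a$n_repeats, 3)
  expect_equal(a$n_spacers, 2)
  expect_equal(a$consensus_repeat, R)
  expect_equal(a$start, pl$truth$start)
  expect_equal(a$end, pl$truth$end)
  expect_identical(vapply(a$spacers, `[[`, character(1), "seq"), S)
})

test_that("a single-spacer locus is found but rejected by validation", {
  set.seed(22)
  pl <- make_array_contig(rnd_dna(32), rnd_dna(36))
  cand <- find_candidate_arrays(pl$seq, "c1")
  expect_length(cand, 1)
  expect_equal(cand[[1]]$n_spacers, 1)
  expect_false(validate_array(cand[[1]])$validated)
})

test_that("random sequence with no qualifying repeat yields no candidates", {
  set.seed(23)
  seq <- rnd_dna(5000)
  # brute-force oracle: no exact 19-mer pair at a period in [38, 120]
  # (any strict-profile candidate needs repeat >= 19 and period
  #  = repeat + spacer in [19+19, 48+72])
  n <- nchar(seq)
  k19 <- substring(seq, 1:(n - 18), 19:n)
  clash <- FALSE
  for (d in 38:120) {
    m <- length(k19) - d
    if (m < 1) break
    if (any(k19[1:m] == k19[(1 + d):(m + d)])) { clash <- TRUE; break }
  }
  expect_false(clash)  # fixture sanity: oracle confirms no repeat pair
  expect_length(find_candidate_arrays(seq, "c1", detection_params()), 0)
})

test_that("validation enforces spacer dissimilarity and repeat divergence", {
  set.seed(24)
  R <- rnd_dna(32)
  s1 <- rnd_dna(36)
  # identical adjacent spacers = tandem repeat, not CRISPR
  flank <- rnd_dna(500)
  seqlen <- 1000 + 3 * 32 + 2 * 36
  ctg <- rnd_dna(seqlen)
  block <- paste0(R, s1, R, s1, R)
  ctg <- paste0(substr(ctg, 1, 500), block,
                substr(ctg, 501 + nchar(block), seqlen))
  cand <- find_candidate_arrays(ctg, "c1")
  # tandem block may be detected as one candidate; it must never validate
  for (a in cand) expect_false(validate_array(a)$validated)

  # distinct spacers validate
  pl <- make_array_contig(R, c(s1, rnd_dna(36)))
  a <- find_candidate_arrays(pl$seq, "c1")[[1]]
  expect_true(validate_array(a)$validated)

  # divergence gate: inject a heavily mutated repeat copy
  a2 <- a
  a2$repeats[[2]]$seq <- rnd_dna(32)
  a2$consensus_repeat <- R
  strictest <- detection_params(max_repeat_divergence = 0.05)
  expect_false(validate_array(a2, strictest)$validated)
})

test_that("relaxing max_repeat_divergence never decreases validated count", {
  set.seed(25)
  n_valid <- function(div) {
    sum(vapply(arrays, function(a) {
      validate_array(a, detection_params(max_repeat_divergence = div))$validated
    }, logical(1)))
  }
  arrays <- list()
  for (i in 1:8) {
    pl <- make_array_contig(rnd_dna(32),
                            c(rnd_dna(36), rnd_dna(36), rnd_dna(36)))
    a <- find_candidate_arrays(pl$seq, paste0("c", i))[[1]]
    # perturb one repeat copy a little
    s <- a$repeats[[1]]$seq
    substr(s, i, i) <- setdiff(c("A", "C", "G", "T"),
                               substr(s, i, i))[sample(3, 1)]
    a$repeats[[1]]$seq <- s
    arrays[[i]] <- a
  }
  counts <- vapply(c(0, 0.05, 0.1, 0.2, 0.5), n_valid, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("consensus rule: two profiles or cas contig required", {
  set.seed(26)
  # standard array: found by strict and lenient -> retained
  pl <- make_array_contig(rnd_dna(32), c(rnd_dna(36), rnd_dna(36)))
  got <- detect_consensus(c(c1 = pl$seq))
  expect_length(got, 1)
  expect_setequal(got[[1]]$profiles_hit, c("strict", "lenient"))

  # short repeat (18 nt) and short spacers (15 nt): the repeat-plus-spacer
  # period (33) is below the strict profile's minimum (19 + 19), so only
  # the lenient profile can see it
  pl2 <- make_array_contig(rnd_dna(18), c(rnd_dna(15), rnd_dna(15)))
  expect_length(detect_consensus(c(c2 = pl2$seq)), 0)
  got2 <- detect_consensus(c(c2 = pl2$seq), cas_contig_ids = "c2")
  expect_length(got2, 1)
  expect_identical(got2[[1]]$profiles_hit, "lenient")

  expect_error(detect_consensus(c(c1 = pl$seq), profiles = list()),
               "at least one")
})

test_that("detection is deterministic and consensus majority breaks ties alphabetically", {
  set.seed(27)
  pl <- make_array_contig(rnd_dna(32), c(rnd_dna(36), rnd_dna(36)))
  a1 <- detect_consensus(c(c1 = pl$seq))
  a2 <- detect_consensus(c(c1 = pl$seq))
  expect_identical(arrays_to_table(a1), arrays_to_table(a2))

  # 2-way tie at a column: alphabetically smaller base wins
  expect_identical(.consensus_cpp(c("AT", "AG")), "AG")
  expect_identical(.consensus_cpp(c("CA", "CA", "CT")), "CA")
})

test_that("validated arrays always satisfy the min-spacer postcondition", {
  set.seed(28)
  for (i in 1:5) {
    n_sp <- sample(1:4, 1)
    pl <- make_array_contig(rnd_dna(32),
                            vapply(seq_len(n_sp), function(j) rnd_dna(36),
                                   character(1)))
    got <- detect_consensus(c(c1 = pl$seq))
    for (a in got) expect_gte(a$n_spacers, 2)
  }
})
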
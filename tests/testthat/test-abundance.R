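test_that("contig coverage is the zero-included positional mean", {
  expect_equal(contig_coverage(c(2, 2, 2, 2)), 2.0)
  expect_equal(contig_coverage(c(10, 0, 0, 0)), 2.5)
  expect_error(contig_coverage(numeric(0)), "empty")
})

test_that("cpm arithmetic and conservation identity", {
  expect_equal(cpm(0, 1e9), 0)
  expect_equal(cpm(20, 2e9), 0.01)
  expect_error(cpm(5, 0), "> 0")

  set.seed(51)
  lens <- setNames(sample(500:2000, 6), paste0("c", 1:6))
  sim <- simulate_depth(lens, runif(6, 1, 30))
  tab <- contig_cpm_table(sim$depths)
  expect_equal(sum(tab$cpm * tab$length), 1e6, tolerance = 1e-9)
})

test_that("feature cpm sums host-contig cpm per instance", {
  cc <- data.table::data.table(contig = c("c1", "c2"), length = c(10L, 10L),
                               coverage = c(1, 2), cpm = c(0.1, 0.2))
  feats <- data.table::data.table(
    feature_id = c("CRISPR", "CRISPR", "RMS_II"),
    contig = c("c1", "c2", "c2"))
  got <- aggregate_feature_cpm(feats, cc)
  expect_equal(got[feature_id == "CRISPR"]$cpm, 0.3)
  expect_equal(got[feature_id == "CRISPR"]$raw_count, 2L)
  expect_equal(got[feature_id == "RMS_II"]$cpm, 0.2)
  bad <- data.table::data.table(feature_id = "x", contig = "nope")
  expect_error(aggregate_feature_cpm(bad, cc), "x.*nope")
  expect_equal(nrow(aggregate_feature_cpm(feats[0], cc)), 0)
})

test_that("enrichment calls follow the 1.5-fold rule with zero handling", {
  expect_equal(enrichment_call(c(2, 2, 2), 1), "sponge")
  expect_equal(enrichment_call(c(1, 1, 1), 1), "none")
  expect_equal(enrichment_call(c(0, 0, 0), 0.2), "seawater")
  expect_equal(enrichment_call(c(0.5, 0.5), 0), "sponge")
  expect_equal(enrichment_call(c(0, 0), 0), "none")
  # order invariance and mutual exclusivity on random tables
  set.seed(52)
  for (i in 1:20) {
    sponge <- runif(3, 0, 2)
    sea <- runif(1, 0, 2)
    f1 <- enrichment_call(sponge, sea)
    expect_identical(f1, enrichment_call(rev(sponge), sea))
    expect_true(f1 %in% c("sponge", "seawater", "none"))
  }
})

test_that("bray_curtis matches closed forms and vegan on random profiles", {
  expect_equal(bray_curtis(c(a = .5, b = .5), c(a = .5, b = .5)), 0)
  expect_equal(bray_curtis(c(a = 1), c(b = 1)), 1)
  expect_equal(bray_curtis(c(0.7, 0.3), c(0.3, 0.7)), 0.4)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")

  skip_if_not_installed("vegan")
  set.seed(53)
  for (i in 1:10) {
    x <- runif(5); y <- runif(5)
    expect_equal(bray_curtis(x, y),
                 as.numeric(vegan::vegdist(rbind(x, y), "bray")),
                 tolerance = 1e-12)
    expect_equal(bray_curtis(x, y), bray_curtis(y, x))
    expect_gte(bray_curtis(x, y), 0)
    expect_lte(bray_curtis(x, y), 1)
    expect_equal(bray_curtis(x, x), 0)
  }
})

test_that("complete linkage reproduces the hand-traced merge order", {
  d <- matrix(c(0, .1, .4,
                .1, 0, .4,
                .4, .4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- complete_linkage(d)
  expect_equal(hc$height, c(0.1, 0.4))
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("A", "B"))

  two <- matrix(c(0, .3, .3, 0), 2, 2,
                dimnames = list(c("X", "Y"), c("X", "Y")))
  expect_equal(complete_linkage(two)$height, 0.3)

  dup <- matrix(0, 2, 2, dimnames = list(c("X", "X2"), c("X", "X2")))
  expect_equal(complete_linkage(dup)$height, 0)

  asym <- matrix(c(0, .2, .3, 0), 2, 2)
  expect_error(complete_linkage(asym), "symmetric")
  nwk <- dendrogram_newick(complete_linkage(d))
  expect_match(nwk, "^\\(.*\\);$")
})

test_that("LCA assignment walks the hand-built tree correctly", {
  tax <- tiny_taxonomy()
  mk_hits <- function(taxids, scores) {
    data.table::data.table(subject_taxid = taxids, bit_score = scores)
  }
  # all hits to one species
  expect_equal(lca_assign(mk_hits(c(101, 101), c(100, 99)), tax), 101)
  # sister species of one genus -> genus node
  expect_equal(lca_assign(mk_hits(c(101, 102), c(100, 95)), tax), 10)
  # hits across genera -> Bacteria; root only via the root node itself
  expect_equal(lca_assign(mk_hits(c(101, 201), c(100, 100)), tax), 2)
  # retention band: the weak hit (below 90% of best) is ignored
  expect_equal(lca_assign(mk_hits(c(101, 201), c(100, 80)), tax), 101)
  # no hits -> unassigned
  expect_true(is.na(lca_assign(mk_hits(integer(0), numeric(0)), tax)))
  expect_error(lca_assign(mk_hits(999, 50), tax), "absent")
})

test_that("LCA result is an ancestor of every retained taxon and shrinking the band never moves it rootward", {
  tax <- tiny_taxonomy()
  parent <- setNames(tax$parent, as.character(tax$taxid))
  ancestors <- function(t) {
    path <- t
    while (parent[[as.character(t)]] != t) {
      t <- parent[[as.character(t)]]
      path <- c(path, t)
    }
    path
  }
  set.seed(54)
  leaves <- c(101L, 102L, 201L)
  for (i in 1:25) {
    n <- sample(1:4, 1)
    hits <- data.table::data.table(
      subject_taxid = sample(leaves, n, replace = TRUE),
      bit_score = runif(n, 50, 100))
    wide <- lca_assign(hits, tax, top_score_fraction = 0.5)
    narrow <- lca_assign(hits, tax, top_score_fraction = 0.05)
    best <- max(hits$bit_score)
    retained <- hits$subject_taxid[hits$bit_score >= 0.5 * best]
    for (t in retained) expect_true(wide %in% ancestors(t))
    # narrow retains a subset, so its LCA is equal or deeper
    expect_true(wide %in% ancestors(narrow))
  }
})

test_that("GC content excludes N and the histogram integrates to one", {
  gc <- gc_distribution(c(a = "GGCC", b = "ATAT", c = "ACGTN"))
  expect_equal(unname(gc$gc), c(1, 0, 0.5))
  expect_error(gc_distribution(c(x = "NNN")), "zero non-N")
  expect_equal(sum(gc$histogram$density * 0.01), 1, tolerance = 1e-9)
})

test_that("percentage uses half-up rounding at two decimals", {
  expect_equal(percentage(53, 77), 68.83)
  expect_equal(percentage(21, 40), 52.50)
  expect_equal(percentage(0, 7), 0)
  expect_equal(percentage(1, 800), 0.13)  # 0.125 rounds up, not to even
  expect_error(percentage(1, 0), "> 0")
  expect_equal(round_half_up(2.675, 2), 2.68)
  expect_equal(round_half_up(-2.675, 2), -2.68)
})

test_that("pearson correlation matches the direct formula and cor.test", {
  expect_equal(pearson_correlation(1:5, 1:5)$r, 1)
  expect_equal(pearson_correlation(1:5, -(1:5))$r, -1)
  a <- c(1, 2, 3); b <- c(2, 4, 7)
  got <- pearson_correlation(a, b)
  ct <- stats::cor.test(a, b)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ct$p.value, tolerance = 1e-12)
  expect_error(pearson_correlation(c(1, 1, 1), 1:3), "zero variance")
})

test_that("community profiles are normalized and pool rare taxa", {
  p <- community_profile(c(A = 70, B = 25, C = 5))
  expect_equal(sum(p), 1)
  p2 <- community_profile(c(A = 70, B = 25, C = 5), min_fraction = 0.10)
  expect_true("other" %in% names(p2))
  expect_equal(sum(p2), 1)
  expect_equal(unname(p2["other"]), 0.05)
})
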
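genes20 <- make_gene_table("c1", 20)
gid <- function(i) genes20$gene_id[i + 1L]  # by 0-based index

test_that("filter_rms_hits applies the inclusive 70% coverage cutoff", {
  hits <- rbind(rms_hit(gid(1), "REase", "II", coverage = 0.70),
                rms_hit(gid(2), "MTase", "II", coverage = 0.69),
                rms_hit(gid(3), "MTase", "II", coverage = 0.90))
  got <- filter_rms_hits(hits, genes20)
  expect_setequal(got$gene_id, c(gid(1), gid(3)))

  # role decided by best e-value when a gene hits both roles
  both <- rbind(rms_hit(gid(5), "REase", "II", evalue = 1e-30),
                rms_hit(gid(5), "MTase", "II", evalue = 1e-10))
  expect_equal(filter_rms_hits(both, genes20)$role, "REase")

  # Specificity only valid for type I
  expect_error(filter_rms_hits(rms_hit(gid(1), "Specificity", "II"), genes20),
               "type I")
})

test_that("pair_complete_systems enforces the distance rule", {
  hits <- rbind(rms_hit(gid(3), "MTase", "II"),
                rms_hit(gid(5), "REase", "II"))
  sys <- pair_complete_systems(filter_rms_hits(hits, genes20))
  expect_equal(nrow(sys), 1)
  expect_equal(sys$index_min, 3L)
  expect_equal(sys$index_max, 5L)

  far <- rbind(rms_hit(gid(3), "MTase", "II"),
               rms_hit(gid(9), "REase", "II"))
  expect_equal(nrow(pair_complete_systems(filter_rms_hits(far, genes20))), 0)

  lone <- rms_hit(gid(3), "MTase", "II")
  expect_equal(nrow(pair_complete_systems(filter_rms_hits(lone, genes20))), 0)

  # types never pair across
  cross <- rbind(rms_hit(gid(3), "MTase", "I"),
                 rms_hit(gid(5), "REase", "II"))
  expect_equal(nrow(pair_complete_systems(filter_rms_hits(cross, genes20))), 0)
})

test_that("type I records a nearby specificity gene without requiring it", {
  hits <- rbind(rms_hit(gid(3), "REase", "I"),
                rms_hit(gid(5), "MTase", "I"),
                rms_hit(gid(6), "Specificity", "I"))
  sys <- pair_complete_systems(filter_rms_hits(hits, genes20))
  expect_equal(nrow(sys), 1)
  expect_equal(sys$spec_gene, gid(6))
  no_spec <- pair_complete_systems(
    filter_rms_hits(hits[1:2], genes20))
  expect_equal(nrow(no_spec), 1)
  expect_true(is.na(no_spec$spec_gene))
})

test_that("merge_into_clusters merges same-type neighbors transitively", {
  mk_sys <- function(imin, imax, type = "II") {
    data.table::data.table(contig_id = "c1", rms_type = type,
                           rease_gene = paste0("re", imin),
                           mtase_gene = paste0("mt", imax),
                           spec_gene = NA_character_,
                           index_min = imin, index_max = imax,
                           complete = TRUE)
  }
  near <- rbind(mk_sys(3L, 5L), mk_sys(6L, 8L))     # gap 0 -> merge
  expect_equal(nrow(merge_into_clusters(near)), 1)

  far <- rbind(mk_sys(3L, 5L), mk_sys(12L, 14L))    # gap 6 -> keep apart
  expect_equal(nrow(merge_into_clusters(far)), 2)

  mixed <- rbind(mk_sys(3L, 5L, "I"), mk_sys(4L, 6L, "II"))
  expect_equal(nrow(merge_into_clusters(mixed)), 2)  # types never merge

  # transitive chain
  chain <- rbind(mk_sys(0L, 2L), mk_sys(5L, 7L), mk_sys(10L, 12L))
  expect_equal(nrow(merge_into_clusters(chain)), 1)
})

test_that("cluster merging is idempotent, order-invariant, and bounded", {
  set.seed(41)
  mk_sys <- function(imin, imax, type) {
    data.table::data.table(contig_id = "c1", rms_type = type,
                           rease_gene = paste0("re", imin, type),
                           mtase_gene = paste0("mt", imax, type),
                           spec_gene = NA_character_,
                           index_min = imin, index_max = imax,
                           complete = TRUE)
  }
  sys <- data.table::rbindlist(lapply(1:10, function(i) {
    s <- sample(0:60, 1)
    mk_sys(s, s + sample(0:4, 1), sample(c("I", "II"), 1))
  }))
  cl <- merge_into_clusters(sys)
  shuffled <- sys[sample(nrow(sys))]
  expect_identical(merge_into_clusters(shuffled), cl)
  # idempotence: reclustering the clusters changes nothing
  as_sys <- cl[, list(contig_id, rms_type, rease_gene = "x",
                      mtase_gene = "y", spec_gene = NA_character_,
                      index_min, index_max, complete = TRUE)]
  expect_equal(nrow(merge_into_clusters(as_sys)), nrow(cl))
  # cluster count <= system count
  expect_lte(nrow(cl), nrow(sys))
})

test_that("planted pairs are recovered and decoy singletons rejected", {
  set.seed(42)
  sim <- simulate_sample(simulation_config(n_arrays = 0L,
                                           n_decoy_arrays = 0L),
                         seed = 77, sample_id = "s")
  rg <- filter_rms_hits(sim$domain_hits[!is.na(role) & role != ""],
                        sim$genes)
  cl <- merge_into_clusters(pair_complete_systems(rg))
  expect_equal(nrow(cl), sum(sim$config$n_rms))
  # every cluster corresponds to one planted system; no decoy genes appear
  decoy_genes <- sim$truth$decoy_rms$gene_id
  expect_false(any(decoy_genes %in% unlist(strsplit(cl$genes, ","))))
  # type tallies match the plan
  expect_equal(as.integer(table(factor(cl$rms_type,
                                       levels = c("I", "II", "III")))),
               as.integer(sim$config$n_rms))
})
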
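# shared fixtures, all generated in code

rnd_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# contig with one planted array: flank + R S1 R S2 ... R + flank
make_array_contig <- function(repeat_seq, spacers, flank = 500L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ctg <- rnd_dna(2L * flank +
                   nchar(repeat_seq) * (length(spacers) + 1L) +
                   sum(nchar(spacers)))
  pl <- plant_crispr(ctg, flank + 1L, repeat_seq, spacers, 0)
  pl
}

# six-node taxonomy: root(1) > Bacteria(2) > genusA(10) > spA1(101), spA2(102)
#                                     \> genusB(20) > spB1(201)
tiny_taxonomy <- function() {
  data.table::data.table(
    taxid  = c(1L, 2L, 10L, 101L, 102L, 20L, 201L),
    parent = c(1L, 1L, 2L, 10L, 10L, 2L, 20L),
    rank   = c("root", "domain", "genus", "species", "species",
               "genus", "species"),
    name   = c("root", "Bacteria", "GenusA", "spA1", "spA2",
               "GenusB", "spB1"))
}

make_gene_table <- function(contig_id, n, gene_len = 900L, gap = 100L) {
  starts <- seq(1L, by = gene_len + gap, length.out = n)
  data.table::data.table(
    gene_id = sprintf("%s_g%03d", contig_id, seq_len(n)),
    contig_id = contig_id, index = seq_len(n) - 1L,
    start = starts, end = starts + gene_len - 1L, strand = "+")
}

rms_hit <- function(gene_id, role, type, coverage = 0.9, evalue = 1e-20) {
  data.table::data.table(gene_id = gene_id, accession = paste0("REBASE_", role),
                         source_db = "REBASE", evalue = evalue,
                         query_coverage = coverage, role = role,
                         rms_type = type)
}
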
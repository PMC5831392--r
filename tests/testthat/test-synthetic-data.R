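# Generator contracts: determinism, planted structure, exact ledgers.

test_that("configuration invariants are enforced", {
  expect_error(sim_config(contamination_rates = c(
    no_3_adapter = 0.5, insert_null = 0.3, adapter5_contaminant = 0.1,
    short_lt18 = 0.1, polyA = 0.1)))
  expect_error(sim_config(de_fraction = 0.5, de_fold = 1.5), "de_fold")
  expect_error(sim_config(contamination_rates = c(bogus = 0.1)))
  expect_s3_class(sim_config(), "sim_config")
})

test_that("genomes are deterministic and precursors extractable verbatim", {
  scfg <- small_sim_config(seed = 61, n_known_mirnas = 5, n_novel_loci = 2)
  g1 <- simulate_genome(scfg)
  g2 <- simulate_genome(scfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$annotation$precursors, g2$annotation$precursors)
  # seven extractable loci, each returning the planted sequence exactly
  all_loci <- rbind(
    g1$annotation$precursors[, c("chrom", "start", "end", "strand", "seq")],
    setNames(g1$novel_truth[, c("chrom", "start", "end", "strand",
                                "precursor_seq")],
             c("chrom", "start", "end", "strand", "seq")))
  expect_identical(nrow(all_loci), 7L)
  for (i in seq_len(nrow(all_loci))) {
    row <- all_loci[i, ]
    dna <- as.character(Biostrings::subseq(g1$genome[[row$chrom]],
                                           row$start, row$end))
    if (row$strand == "-") {
      dna <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(dna)))
    }
    expect_identical(chartr("T", "U", dna), row$seq)
  }
  # same seed twice writes byte-identical FASTA
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(g1$genome, f1)
  Biostrings::writeXStringSet(simulate_genome(scfg)$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("oversized locus sets are rejected", {
  expect_error(
    simulate_genome(small_sim_config(n_known_mirnas = 50,
                                     genome_length = 1000)),
    "genome length")
})

test_that("planted novel loci fold below the MFE acceptance threshold", {
  gen <- simulate_genome(small_sim_config(seed = 62, n_novel_loci = 3))
  for (s in gen$novel_truth$precursor_seq) {
    expect_lte(fold_rna(s)$mfe, -18)
  }
})

test_that("the per-category ledger equals the filter tallies exactly", {
  scfg <- small_sim_config(seed = 63)
  gen <- simulate_genome(scfg)
  sim <- simulate_reads(scfg, gen$annotation, gen$novel_truth)
  for (lib in names(sim$reads)) {
    rep <- filter_reads(sim$reads[[lib]], scfg$adapter3, scfg$adapter5,
                        library = lib)$report
    expect_identical(unname(rep$removed),
                     unname(sim$ground_truth$per_category_counts[, lib]),
                     label = lib)
    expect_identical(rep$clean_reads,
                     unname(sim$ground_truth$clean_totals[lib]))
  }
})

test_that("zero contamination keeps every read", {
  scfg <- small_sim_config(
    seed = 64,
    contamination_rates = c(no_3_adapter = 0, insert_null = 0,
                            adapter5_contaminant = 0, short_lt18 = 0,
                            polyA = 0))
  gen <- simulate_genome(scfg)
  sim <- simulate_reads(scfg, gen$annotation, gen$novel_truth)
  res <- filter_reads(sim$reads$DU, scfg$adapter3, scfg$adapter5)
  expect_identical(res$report$clean_reads, res$report$high_quality_reads)
  expect_identical(res$report$clean_percent, 100)
})

test_that("reads are reproducible under a fixed seed", {
  scfg <- small_sim_config(seed = 65)
  gen <- simulate_genome(scfg)
  s1 <- simulate_reads(scfg, gen$annotation, gen$novel_truth)
  s2 <- simulate_reads(scfg, gen$annotation, gen$novel_truth)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$ground_truth, s2$ground_truth)
})

test_that("planted fold-changes are realised in expectation", {
  ratios <- vapply(1:6, function(s) {
    scfg <- small_sim_config(seed = 70 + s, n_known_mirnas = 30,
                             de_fraction = 0.1, de_fold = 4,
                             mean_count = 200)
    sim <- simulate_counts(scfg)
    de <- sim$planted_de
    mean(vapply(seq_len(nrow(de)), function(i) {
      up <- de$up_library[i]
      other <- setdiff(colnames(sim$counts), up)[1]
      sim$counts[de$mirna_id[i], up] /
        max(1, sim$counts[de$mirna_id[i], other])
    }, numeric(1)))
  }, numeric(1))
  expect_gte(mean(ratios), 2)
})

test_that("annotations export to GFF3 with genomic mature coordinates", {
  skip_if_not_installed("rtracklayer")
  gen <- simulate_genome(small_sim_config(seed = 67, n_known_mirnas = 4,
                                          n_novel_loci = 0))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(gen$annotation, path)
  gr <- rtracklayer::import(path)
  pre <- gr[gr$type == "miRNA_primary_transcript"]
  mat <- gr[gr$type == "miRNA"]
  expect_length(pre, 4)
  expect_length(mat, 4)
  ann <- gen$annotation
  for (i in seq_along(mat)) {
    m <- mat[i]
    row <- ann$matures[ann$matures$mature_id == m$ID, ]
    p <- ann$precursors[ann$precursors$precursor_id == row$precursor_id, ]
    # extracting the mature's genomic interval returns its sequence
    dna <- as.character(Biostrings::subseq(
      gen$genome[[as.character(GenomicRanges::seqnames(m))]],
      GenomicRanges::start(m), GenomicRanges::end(m)))
    if (p$strand == "-") {
      dna <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(dna)))
    }
    expect_identical(chartr("T", "U", dna), row$seq)
  }
})

test_that("the mature length mode matches the clean-read length mode", {
  scfg <- small_sim_config(seed = 66, n_known_mirnas = 40)
  gen <- simulate_genome(scfg)
  sim <- simulate_reads(scfg, gen$annotation, gen$novel_truth)
  clean <- filter_reads(sim$reads$DU, scfg$adapter3, scfg$adapter5)$clean
  ld <- length_distribution(clean)
  expect_identical(ld$length[which.max(ld$count)], 22L)
})
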
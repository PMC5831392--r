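# Filter cascade, accounting arithmetic, length distribution, exact mapping.

A3 <- "TGGAATTCTCGGGTGCCAAGG"
A5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

test_that("each read lands in its first-failing category", {
  reads <- c(
    none = "ACGTACGTACGTACGTACGTAC",             # no 3' adapter anywhere
    null = A3,                                    # adapter alone: empty insert
    five = paste0(A5, "ACGTACGTACGTACGT", A3),    # 5' contaminant
    short = paste0("ACGTACGTAC", A3),             # 10 nt insert
    polya = paste0(strrep("A", 20), A3),          # 100% A insert
    clean = paste0("TCGTACCGTGAGTAATAATGCG", A3)
  )
  res <- filter_reads(reads, A3, A5)
  expect_equal(unname(res$report$removed),
               c(1, 1, 1, 1, 1))
  expect_identical(res$report$clean_reads, 1)
  expect_identical(res$clean$seq, "TCGTACCGTGAGTAATAATGCG")
})

test_that("polyA is called at 70% adenine after trimming", {
  insert_69 <- paste0(strrep("A", 16), "CGTCGTC")  # 16/23 = 69.6%
  insert_70 <- paste0(strrep("A", 14), "CGTCGT")   # 14/20 = 70%
  res <- filter_reads(paste0(c(insert_69, insert_70), A3), A3, A5)
  expect_equal(unname(res$report$removed[["polyA"]]), 1)
  expect_identical(res$clean$seq, insert_69)
})

test_that("accounting conserves reads and is order-stable", {
  set.seed(9)
  pool <- c(
    replicate(40, paste0(paste(sample(c("A", "C", "G", "T"), 22,
                                      replace = TRUE), collapse = ""), A3)),
    replicate(10, paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
                        collapse = "")),
    rep(A3, 5),
    replicate(8, paste0(paste(sample(c("A", "C", "G", "T"), 10,
                                     replace = TRUE), collapse = ""), A3))
  )
  r1 <- filter_reads(pool, A3, A5)
  r2 <- filter_reads(rev(pool), A3, A5)
  expect_identical(r1$report$high_quality_reads,
                   r1$report$clean_reads + sum(r1$report$removed))
  expect_identical(r1$report$removed, r2$report$removed)
  expect_identical(r1$report$clean_reads, r2$report$clean_reads)
  expect_identical(as.data.frame(r1$clean), as.data.frame(r2$clean))
})

test_that("report arithmetic matches the published duodenum column", {
  rep_du <- accounting_report(
    high_quality_reads = 28493897,
    removed = c(no_3_adapter = 268000, insert_null = 19580,
                adapter5_contaminant = 9650, short_lt18 = 697631,
                polyA = 145),
    raw_reads = 28536048
  )
  expect_identical(rep_du$clean_reads, 27498891)
  expect_identical(rep_du$clean_percent, 96.51)
})

test_that("length distribution tallies and percentages close", {
  all22 <- clean_read_set(replicate(100, paste(
    sample(c("A", "C", "G", "T"), 22, replace = TRUE), collapse = "")))
  ld <- length_distribution(all22)
  expect_identical(ld$length, 22L)
  expect_identical(ld$percent, 100)

  mix <- clean_read_set(c(rep(strrep("C", 21), 50), rep(strrep("G", 22), 50)))
  ld2 <- length_distribution(mix)
  expect_equal(ld2$percent, c(50, 50))
  expect_equal(sum(ld2$percent), 100)
})

test_that("exact mapping finds both strands and counts multi-mappers once", {
  genome <- c(chr1 = paste0(strrep("T", 30), "ACCGGTTACCAGTGCAATGCAG",
                            strrep("T", 30)),
              chr2 = paste0(strrep("C", 10), "ACCGGTTACCAGTGCAATGCAG",
                            strrep("G", 10)))
  read <- "ACCGGTTACCAGTGCAATGCAG"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  clean <- clean_read_set(c(rep(read, 3), rc))
  res <- map_reads(clean, genome)
  plus <- res$assignments[res$assignments$strand == "+", ]
  expect_setequal(plus$chrom, c("chr1", "chr2"))
  expect_identical(sort(plus$start), c(11L, 31L))
  minus <- res$assignments[res$assignments$strand == "-", ]
  expect_identical(sort(unique(minus$seq)), rc)
  # both unique reads map (multi-mapping counted once per read)
  expect_identical(res$mapped_reads, 4)
  expect_identical(res$mapped_percent, 100)
  expect_error(map_reads(clean, character(0)), "empty genome")
})

test_that("mapping percentages reproduce the published report arithmetic", {
  r <- accounting_report(
    high_quality_reads = 28493897,
    removed = c(no_3_adapter = 268000, insert_null = 19580,
                adapter5_contaminant = 9650, short_lt18 = 697631,
                polyA = 145),
    mapped_reads = 16733785
  )
  expect_identical(r$mapped_percent, 60.85)
})

test_that("FASTQ round-trips and malformed records abort with their number", {
  reads <- Biostrings::DNAStringSet(c(r1 = "ACGTACGT", r2 = "GGGTTTAA"))
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_identical(as.character(back), as.character(reads))

  lines <- readLines(path)
  lines[6] <- "ACG" # sequence/quality length mismatch in record 2
  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(lines, bad)
  expect_error(read_fastq(bad), "record 2")
})

test_that("collapsed FASTA preserves sequences and counts", {
  cs <- clean_read_set(c(rep("ACGTACGTACGTACGTAA", 7), "TTTTGGGGCCCCAAAATT"))
  path <- withr::local_tempfile(fileext = ".fa")
  write_collapsed_fasta(cs, path)
  back <- read_collapsed_fasta(path)
  expect_identical(as.data.frame(back), as.data.frame(cs))
})
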
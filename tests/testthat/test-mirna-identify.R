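# Known-miRNA assignment rules, RNA class priorities, novel prediction,
# cross-study comparison.

make_annotation <- function() {
  pre <- paste0("UGAGGUAGUAGGUUGUAUAGUU", "GCUAAGCU",
                "AACUAUACAACCUACUACCUCA")
  mirna_annotation(
    precursors = data.frame(precursor_id = "pre-1", chrom = "chr1",
                            start = 101, end = 100 + nchar(pre),
                            strand = "+", seq = pre,
                            stringsAsFactors = FALSE),
    matures = data.frame(mature_id = "miR-1", precursor_id = "pre-1",
                         start = 1, end = 22,
                         seq = "UGAGGUAGUAGGUUGUAUAGUU",
                         stringsAsFactors = FALSE)
  )
}

test_that("annotation construction validates mature/precursor consistency", {
  expect_s3_class(make_annotation(), "mirna_annotation")
  expect_error(
    mirna_annotation(
      data.frame(precursor_id = "p", chrom = "c", start = 1, end = 30,
                 strand = "+", seq = strrep("ACGU", 10)),
      data.frame(mature_id = "m", precursor_id = "p", start = 30, end = 55,
                 seq = strrep("ACGU", 6))),
    "m")
})

test_that("reads need a 16-base identical overlap with the mature", {
  ann <- make_annotation()
  pre <- ann$precursors$seq
  exact <- chartr("U", "T", ann$matures$seq)           # the mature itself
  ov15 <- chartr("U", "T", substr(pre, 8, 29))         # overlap 15 with 1-22
  ov16 <- chartr("U", "T", substr(pre, 7, 28))         # overlap 16
  clean <- clean_read_set(c(rep(exact, 20), rep(ov15, 20), rep(ov16, 20)))
  res <- assign_known(clean, ann, min_reads = 10)
  expect_equal(unname(res$counts$counts["miR-1", 1]), 40)
  expect_false(ov15 %in% res$assignments$seq)
  expect_true(ov16 %in% res$assignments$seq)
})

test_that("the per-library read floor zeroes sparse miRNAs", {
  ann <- make_annotation()
  read <- chartr("U", "T", ann$matures$seq)
  libs <- list(L1 = clean_read_set(rep(read, 9)),
               L2 = clean_read_set(rep(read, 10)))
  res <- assign_known(libs, ann, min_reads = 10)
  expect_equal(unname(res$counts$counts["miR-1", ]), c(0, 10))
})

test_that("multi-mature reads are shared fractionally or fully by policy", {
  pre <- paste0("GCGCAUAUGCGCAUAUGCGCAUAU", "AAGGAAGG")
  ann <- mirna_annotation(
    data.frame(precursor_id = "p", chrom = "c", start = 1,
               end = nchar(pre), strand = "+", seq = pre,
               stringsAsFactors = FALSE),
    data.frame(mature_id = c("m-5p", "m-3p"), precursor_id = "p",
               start = c(1, 5), end = c(20, 24),
               seq = c(substr(pre, 1, 20), substr(pre, 5, 24)),
               stringsAsFactors = FALSE)
  )
  read <- chartr("U", "T", substr(pre, 3, 22)) # overlaps both matures by >=16
  clean <- clean_read_set(rep(read, 30))
  frac <- assign_known(clean, ann, min_reads = 0)
  expect_equal(unname(frac$counts$counts[, 1]), c(15, 15))
  expect_equal(sum(frac$counts$counts), 30) # conservation
  expect_warning(
    each <- assign_known(clean, ann, min_reads = 0, multi = "each"),
    "exceed library totals")
  expect_equal(unname(each$counts$counts[, 1]), c(30, 30))
})

test_that("assignment is independent of read input order", {
  ann <- make_annotation()
  read <- chartr("U", "T", ann$matures$seq)
  other <- "ACGGCATTCAGGACTTAGGC"
  a <- assign_known(clean_read_set(c(rep(read, 12), rep(other, 3))), ann)
  b <- assign_known(clean_read_set(c(rep(other, 3), rep(read, 12))), ann)
  expect_identical(a$counts$counts, b$counts$counts)
})

test_that("RNA classes follow the fixed priority and conserve totals", {
  ncrna <- data.frame(
    id = c("r1", "t1"),
    class = c("rRNA", "tRNA"),
    sequence = c(strrep("GCAU", 20), strrep("GCAU", 15)),
    stringsAsFactors = FALSE
  )
  ann <- make_annotation()
  both <- chartr("U", "T", strrep("GCAU", 5)) # substring of rRNA and tRNA
  mir <- chartr("U", "T", ann$matures$seq)
  unk <- "TTACGGATCCATTACGGACC"
  clean <- clean_read_set(c(rep(both, 7), rep(mir, 11), rep(unk, 5)))
  tally <- classify_ncrna(clean, ncrna, ann)
  expect_equal(unname(tally["rRNA"]), 7)
  expect_equal(unname(tally["tRNA"]), 0)
  expect_equal(unname(tally["miRNA"]), 11)
  expect_equal(unname(tally["unannotated"]), 5)
  expect_equal(sum(tally), attr(clean, "total"))
})

test_that("cross-study comparison agrees with a brute-force matcher", {
  set.seed(7)
  a <- replicate(8, random_rna(sample(18:24, 1)))
  b <- replicate(8, random_rna(sample(18:24, 1)))
  b[1] <- a[1]                                      # identical pair
  sub <- substr(a[2], 1, 18)                        # 18-mer with 1 mismatch
  substr(sub, 9, 9) <- if (substr(sub, 9, 9) == "A") "C" else "A"
  b[2] <- paste0(sub, "GCGCGA")
  names(a) <- paste0("a", 1:8)
  names(b) <- paste0("b", 1:8)
  got <- compare_novel_sets(a, b, min_cov = 18, max_mismatch = 1)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      expect_identical(
        any(got$id_a == names(a)[i] & got$id_b == names(b)[j]),
        brute_ungapped_match(a[[i]], b[[j]], 18, 1),
        label = paste("pair", i, j))
    }
  }
  expect_true(any(got$id_a == "a1" & got$id_b == "b1"))
  expect_true(any(got$id_a == "a2" & got$id_b == "b2"))
})

test_that("two mismatches inside every 18-window prevent a match", {
  # 22-mers differing at positions 5 and 18: every ungapped 18-base window
  # of any offset alignment carries both mismatches (verified by the brute
  # oracle below)
  a <- "UAUCCAGCCCUCUAUUGUACUC"
  b <- "UAUCAAGCCCUCUAUUGAACUC"
  expect_false(brute_ungapped_match(a, b, 18, 1))
  got <- compare_novel_sets(c(x = a), c(y = b))
  expect_identical(nrow(got), 0L)
})

test_that("planted hairpin loci are recovered and imposters rejected", {
  scfg <- small_sim_config(seed = 31, n_novel_loci = 3)
  gen <- simulate_genome(scfg)
  sim <- simulate_reads(scfg, gen$annotation, gen$novel_truth)
  clean <- lapply(sim$reads, function(r)
    filter_reads(r, scfg$adapter3, scfg$adapter5)$clean)
  assigned <- unique(assign_known(clean, gen$annotation)$assignments$seq)
  pooled <- do.call(rbind, lapply(clean, as.data.frame))
  pooled <- pooled[!pooled$seq %in% assigned, , drop = FALSE]
  cs <- clean_read_set(pooled$seq, pooled$count)

  nv <- predict_novel(cs, gen$genome)
  truth <- gen$novel_truth
  # every planted locus is recovered by an overlapping candidate...
  hit <- vapply(seq_len(nrow(truth)), function(i)
    any(nv$chrom == truth$chrom[i] & nv$start <= truth$end[i] &
          nv$end >= truth$start[i]), logical(1))
  expect_true(all(hit))
  # ...and no candidate falls outside the planted loci
  spurious <- vapply(seq_len(nrow(nv)), function(i)
    !any(truth$chrom == nv$chrom[i] & truth$start <= nv$end[i] &
           truth$end >= nv$start[i]), logical(1))
  expect_identical(sum(spurious), 0L)
  expect_true(all(nv$mfe <= -18))
  expect_true(all(nv$label == "novel"))

  # an unreachable threshold rejects everything
  none <- predict_novel(cs, gen$genome, mfe_threshold = -200)
  expect_identical(nrow(none), 0L)

  # a cross-species reference containing a planted mature flips its label
  ref <- c(known_sheep_mir = truth$mature_seq[1])
  nv2 <- predict_novel(cs, gen$genome, cross_reference = ref)
  lab <- nv2$label[nv2$chrom == truth$chrom[1] &
                     nv2$start <= truth$end[1] & nv2$end >= truth$start[1]]
  expect_identical(lab, "conserved")
})
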
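## Known-miRNA assignment, small RNA classification, novel miRNA prediction.

.to_rna <- function(x) chartr("Tt", "Uu", toupper(x))
.to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

.revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(toupper(.to_dna(x)), "")[[1]]),
                               collapse = ""))
}

#' miRNA annotation (precursor + mature)
#'
#' @param precursors data.frame with columns `precursor_id`, `chrom`, `start`,
#'   `end`, `strand`, `seq` (precursor sequence, RNA alphabet, 5'->3').
#' @param matures data.frame with columns `mature_id`, `precursor_id`,
#'   `start`, `end` (1-based inclusive position on the precursor), `seq`,
#'   and optionally `family`.
#' @return A `mirna_annotation` object. Errors name the offending record when
#'   a mature interval is inconsistent with its precursor.
#' @export
mirna_annotation <- function(precursors, matures) {
  precursors$seq <- .to_rna(precursors$seq)
  matures$seq <- .to_rna(matures$seq)
  if (is.null(matures$family)) {
    matures$family <- sub("-[35]p$", "", matures$mature_id)
  }
  for (i in seq_len(nrow(matures))) {
    m <- matures[i, ]
    p <- precursors[precursors$precursor_id == m$precursor_id, ]
    if (nrow(p) != 1L) {
      stop("mature ", m$mature_id, ": unknown precursor ", m$precursor_id)
    }
    if (m$start < 1L || m$end > nchar(p$seq) || m$start > m$end) {
      stop("mature ", m$mature_id, ": interval outside precursor ",
           m$precursor_id)
    }
    if (substr(p$seq, m$start, m$end) != m$seq) {
      stop("mature ", m$mature_id,
           ": sequence does not match its precursor interval")
    }
  }
  structure(list(precursors = precursors, matures = matures),
            class = "mirna_annotation")
}

#' @export
print.mirna_annotation <- function(x, ...) {
  cat("miRNA annotation:", nrow(x$precursors), "precursors,",
      nrow(x$matures), "matures\n")
  invisible(x)
}

# For one read sequence, the mature ids it supports: the read must occur in
# the precursor with 0 mismatches and its precursor interval must overlap the
# mature interval by >= min_overlap identical bases (any offset permitted).
.matures_for_read <- function(seq_rna, annotation, min_overlap = 16L) {
  hits <- character(0)
  L <- nchar(seq_rna)
  for (i in seq_len(nrow(annotation$precursors))) {
    p <- annotation$precursors[i, ]
    occ <- gregexpr(seq_rna, p$seq, fixed = TRUE)[[1]]
    if (occ[1] == -1L) next
    mats <- annotation$matures[
      annotation$matures$precursor_id == p$precursor_id, , drop = FALSE]
    for (s in as.integer(occ)) {
      e <- s + L - 1L
      ov <- pmin(e, mats$end) - pmax(s, mats$start) + 1L
      hits <- c(hits, mats$mature_id[ov >= min_overlap])
    }
  }
  unique(hits)
}

#' Assign clean reads to known mature miRNAs
#'
#' A read counts toward a mature miRNA if and only if it aligns to the
#' precursor with no mismatch and its interval on the precursor overlaps the
#' mature interval by at least `min_overlap` identical bases (offsets
#' permitted). miRNAs with fewer than `min_reads` reads in a library are
#' zeroed in that library (false-positive floor, applied per library). A read
#' satisfying the rule for several matures contributes fractionally (1/k) by
#' default, which conserves total counts; `multi = "each"` counts it fully
#' toward every mature.
#'
#' @param clean A [clean_read_set()] or a named list of them (one per library).
#' @param annotation A [mirna_annotation()].
#' @param min_reads Per-library read floor (default 10).
#' @param min_overlap Minimum identical overlap with the mature (default 16).
#' @param multi Multi-assignment policy: `"fractional"` (default) or `"each"`.
#' @return A list with `counts` (a [count_matrix()]; rows all annotated
#'   matures) and `assignments` (data.frame seq, mature_id, weight).
#' @export
assign_known <- function(clean, annotation, min_reads = 10L,
                         min_overlap = 16L,
                         multi = c("fractional", "each")) {
  multi <- match.arg(multi)
  stopifnot(inherits(annotation, "mirna_annotation"),
            nrow(annotation$matures) > 0)
  if (inherits(clean, "clean_reads")) clean <- list(library1 = clean)
  libs <- names(clean)
  mat_ids <- sort(annotation$matures$mature_id)
  counts <- matrix(0, nrow = length(mat_ids), ncol = length(libs),
                   dimnames = list(mat_ids, libs))

  all_seqs <- sort(unique(unlist(lapply(clean, function(x) x$seq))))
  assign_map <- lapply(all_seqs, function(s)
    .matures_for_read(.to_rna(s), annotation, min_overlap))
  names(assign_map) <- all_seqs

  rows <- list()
  for (lib in libs) {
    cs <- clean[[lib]]
    for (i in seq_len(nrow(cs))) {
      hits <- assign_map[[cs$seq[i]]]
      k <- length(hits)
      if (k == 0L) next
      w <- if (multi == "fractional") cs$count[i] / k else cs$count[i]
      counts[hits, lib] <- counts[hits, lib] + w
      rows[[length(rows) + 1L]] <- data.frame(
        library = lib, seq = cs$seq[i], mature_id = hits,
        weight = w, stringsAsFactors = FALSE
      )
    }
  }
  counts[counts < min_reads] <- 0
  totals <- vapply(clean, function(x) attr(x, "total"), numeric(1))
  list(
    counts = count_matrix(counts, totals),
    assignments = if (length(rows)) do.call(rbind, rows) else
      data.frame(library = character(), seq = character(),
                 mature_id = character(), weight = numeric())
  )
}

#' Classify clean reads into small RNA categories
#'
#' Each unique read is assigned to exactly one category by a fixed priority:
#' known miRNA, then rRNA, tRNA, snRNA, snoRNA, repeat, and finally
#' unannotated. A read matches a non-miRNA class when it is an exact
#' substring of any reference sequence of that class. Tallies (in reads)
#' always sum to the total clean reads.
#'
#' @param clean A [clean_read_set()].
#' @param ncrna_table data.frame with columns `id`, `class` (one of rRNA,
#'   tRNA, snRNA, snoRNA, repeat) and `sequence`.
#' @param annotation Optional [mirna_annotation()] for the miRNA class.
#' @param min_overlap Overlap rule for the miRNA class (default 16).
#' @return Named numeric vector of read tallies over the seven categories.
#' @export
classify_ncrna <- function(clean, ncrna_table, annotation = NULL,
                           min_overlap = 16L) {
  stopifnot(inherits(clean, "clean_reads"))
  classes <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "repeat",
               "unannotated")
  tally <- stats::setNames(numeric(length(classes)), classes)
  ncrna_table$sequence <- .to_rna(ncrna_table$sequence)
  by_class <- split(ncrna_table$sequence, ncrna_table$class)
  for (i in seq_len(nrow(clean))) {
    s <- .to_rna(clean$seq[i])
    cat_ <- "unannotated"
    if (!is.null(annotation) &&
        length(.matures_for_read(s, annotation, min_overlap))) {
      cat_ <- "miRNA"
    } else {
      for (cl in c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat")) {
        refs <- by_class[[cl]]
        if (!is.null(refs) && any(grepl(s, refs, fixed = TRUE))) {
          cat_ <- cl
          break
        }
      }
    }
    tally[cat_] <- tally[cat_] + clean$count[i]
  }
  tally
}

# Ungapped alignment test: TRUE when some ungapped alignment window of a
# against b covers >= min_cov bases with <= max_mismatch mismatches (windows
# of exactly min_cov suffice: longer windows are never easier).
.ungapped_match <- function(a, b, min_cov, max_mismatch) {
  ac <- strsplit(.to_rna(a), "")[[1]]
  bc <- strsplit(.to_rna(b), "")[[1]]
  la <- length(ac)
  lb <- length(bc)
  for (off in -(la - 1L):(lb - 1L)) {
    i0 <- max(1L, 1L - off)
    i1 <- min(la, lb - off)
    ov <- i1 - i0 + 1L
    if (ov < min_cov) next
    mm <- ac[i0:i1] != bc[(i0 + off):(i1 + off)]
    # sliding mismatch counts over windows of length min_cov
    cs <- c(0L, cumsum(mm))
    wins <- cs[(min_cov + 1L):(ov + 1L)] - cs[seq_len(ov - min_cov + 1L)]
    if (any(wins <= max_mismatch)) return(TRUE)
  }
  FALSE
}

#' Cross-study comparison of novel mature miRNA sets
#'
#' Reports a pair when some ungapped alignment of one mature against the
#' other covers at least `min_cov` bases with at most `max_mismatch`
#' mismatches. Symmetric in its arguments.
#'
#' @param set_a,set_b Named character vectors of mature sequences.
#' @param min_cov Minimum aligned coverage (default 18).
#' @param max_mismatch Maximum mismatches (default 1).
#' @return data.frame of matched pairs (`id_a`, `id_b`).
#' @export
compare_novel_sets <- function(set_a, set_b, min_cov = 18L,
                               max_mismatch = 1L) {
  stopifnot(length(set_a) > 0, length(set_b) > 0)
  if (is.null(names(set_a))) names(set_a) <- paste0("a", seq_along(set_a))
  if (is.null(names(set_b))) names(set_b) <- paste0("b", seq_along(set_b))
  rows <- list()
  for (i in seq_along(set_a)) {
    for (j in seq_along(set_b)) {
      if (.ungapped_match(set_a[[i]], set_b[[j]], min_cov, max_mismatch)) {
        rows[[length(rows) + 1L]] <- data.frame(
          id_a = names(set_a)[i], id_b = names(set_b)[j],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(id_a = character(), id_b = character())
}

#' Predict novel miRNA precursor hairpins from unannotated mapped reads
#'
#' Unassigned mapped reads are clustered along the genome (gap at most
#' `cluster_gap`), each cluster is excised with `flank` nt on both sides and
#' folded with [fold_rna()]. A candidate is accepted when its minimum free
#' energy is at most `mfe_threshold` and its candidate mature (the most
#' abundant supporting read) lies wholly on one hairpin arm with at least 16
#' bases inside that arm's paired span. Accepted candidates whose mature
#' matches a cross-species reference mature (16 identical bases, no
#' mismatch) are labelled `conserved`; the rest are `novel`. Read support is
#' re-counted against accepted precursors with the known-miRNA rule.
#'
#' @param clean A [clean_read_set()] of the unannotated clean reads (reads
#'   already assigned to known miRNAs or other RNA classes should be
#'   excluded by the caller).
#' @param genome Named `DNAStringSet` or character vector.
#' @param cross_reference Optional named character vector of cross-species
#'   mature sequences.
#' @param mfe_threshold MFE acceptance cutoff in kcal/mol (default -18).
#' @param cluster_gap Maximum genomic gap joining reads into one cluster
#'   (default 10).
#' @param flank Flanking bases excised on each side of a cluster (default 20).
#' @param max_precursor Maximum excised precursor length (default 300).
#' @param mature_range Admissible candidate mature length (default 18-26).
#' @param min_overlap Identical-overlap rule shared with [assign_known()].
#' @return data.frame of accepted candidates: locus, sequence, dot-bracket
#'   structure, MFE, candidate mature and its interval, supporting read
#'   count, and label (`conserved`/`novel`).
#' @export
predict_novel <- function(clean, genome, cross_reference = NULL,
                          mfe_threshold = -18, cluster_gap = 10L,
                          flank = 20L, max_precursor = 300L,
                          mature_range = c(18L, 26L), min_overlap = 16L) {
  stopifnot(inherits(clean, "clean_reads"))
  if (!inherits(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  mapped <- map_reads(clean, genome)$assignments
  if (!nrow(mapped)) return(.empty_candidates())

  out <- list()
  for (key in unique(paste(mapped$chrom, mapped$strand))) {
    parts <- strsplit(key, " ")[[1]]
    sub <- mapped[mapped$chrom == parts[1] & mapped$strand == parts[2], ,
                  drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    gap_break <- c(TRUE, sub$start[-1] > cummax(sub$end)[-nrow(sub)] +
                     cluster_gap + 1L)
    cluster <- cumsum(gap_break)
    for (cl in unique(cluster)) {
      reads <- sub[cluster == cl, , drop = FALSE]
      cand <- .evaluate_cluster(reads, genome, flank, max_precursor,
                                mfe_threshold, mature_range, min_overlap,
                                cross_reference, clean)
      if (!is.null(cand)) out[[length(out) + 1L]] <- cand
    }
  }
  if (!length(out)) return(.empty_candidates())
  res <- do.call(rbind, out)
  # a hairpin is its own reverse complement's hairpin: collapse candidates
  # whose genomic intervals overlap (keep the best-supported, then lowest MFE)
  res <- res[order(-res$supporting_reads, res$mfe, res$chrom, res$start), ,
             drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))[-1]) {
    prev <- which(keep[seq_len(i - 1L)])
    overlaps <- res$chrom[prev] == res$chrom[i] &
      res$start[prev] <= res$end[i] & res$end[prev] >= res$start[i]
    if (any(overlaps)) keep[i] <- FALSE
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res$precursor_id <- sprintf("novel-pre-%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

.empty_candidates <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), seq = character(), structure = character(),
             mfe = numeric(), mature_seq = character(),
             mature_start = integer(), mature_end = integer(),
             supporting_reads = numeric(), label = character(),
             precursor_id = character(), stringsAsFactors = FALSE)
}

.evaluate_cluster <- function(reads, genome, flank, max_precursor,
                              mfe_threshold, mature_range, min_overlap,
                              cross_reference, clean) {
  chrom <- reads$chrom[1]
  strand <- reads$strand[1]
  chrom_len <- Biostrings::width(genome)[names(genome) == chrom]
  start <- max(1L, min(reads$start) - flank)
  end <- min(chrom_len, max(reads$end) + flank)
  if (end - start + 1L > max_precursor) return(NULL)
  dna <- as.character(Biostrings::subseq(genome[[chrom]], start, end))
  if (strand == "-") dna <- .revcomp(dna)
  rna <- .to_rna(dna)

  fold <- fold_rna(rna)
  if (fold$mfe > mfe_threshold) return(NULL)

  # candidate mature: most abundant supporting read (ties by sequence)
  reads <- reads[order(-reads$count, reads$seq), , drop = FALSE]
  mature <- .to_rna(reads$seq[1])
  if (nchar(mature) < mature_range[1] || nchar(mature) > mature_range[2]) {
    return(NULL)
  }
  mpos <- regexpr(mature, rna, fixed = TRUE)
  if (mpos == -1L) return(NULL)
  ms <- as.integer(mpos)
  me <- ms + nchar(mature) - 1L

  # arm rule: at least min_overlap mature bases paired, all in one stem
  # orientation (the mature must not straddle a terminal loop)
  chars <- strsplit(fold$structure, "")[[1]]
  mchars <- chars[ms:me]
  n_open <- sum(mchars == "(")
  n_close <- sum(mchars == ")")
  on_arm <- (n_open >= min_overlap && n_close == 0L) ||
    (n_close >= min_overlap && n_open == 0L)
  if (!on_arm) return(NULL)

  label <- "novel"
  if (!is.null(cross_reference) && length(cross_reference)) {
    hit <- any(vapply(cross_reference, function(ref)
      .ungapped_match(mature, ref, min_cov = 16L, max_mismatch = 0L),
      logical(1)))
    if (hit) label <- "conserved"
  }

  # re-count support with the known-miRNA rule against this precursor
  cand_ann <- mirna_annotation(
    precursors = data.frame(precursor_id = "cand", chrom = chrom,
                            start = start, end = end, strand = strand,
                            seq = rna, stringsAsFactors = FALSE),
    matures = data.frame(mature_id = "cand-mature", precursor_id = "cand",
                         start = ms, end = me, seq = mature,
                         stringsAsFactors = FALSE)
  )
  support <- assign_known(clean, cand_ann, min_reads = 0L,
                          min_overlap = min_overlap)$counts
  data.frame(
    chrom = chrom, start = start, end = end, strand = strand,
    seq = rna, structure = fold$structure, mfe = fold$mfe,
    mature_seq = mature, mature_start = ms, mature_end = me,
    supporting_reads = sum(support$counts),
    label = label, stringsAsFactors = FALSE
  )
}
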
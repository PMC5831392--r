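## Read cleaning: adapter detection, contamination categories, accounting.

# Fixed filter cascade order; each read is assigned to the first failing test.
.FILTER_CATEGORIES <- c(
  "no_3_adapter", "insert_null", "adapter5_contaminant", "short_lt18", "polyA"
)
.CATEGORY_LABELS <- c(
  no_3_adapter = "3' adapter null",
  insert_null = "Insert null",
  adapter5_contaminant = "5' adapter contaminants",
  short_lt18 = "Smaller than 18 nt",
  polyA = "PolyA"
)

#' Locate the 3' adapter in a read
#'
#' Finds the leftmost position at which a prefix of the adapter (at least
#' `min_overlap` bases, at most `max_mismatch` mismatches) occurs in the read.
#'
#' @param seq Read sequence (character scalar).
#' @param adapter Adapter sequence.
#' @param min_overlap Minimum matched adapter prefix length (default 6).
#' @param max_mismatch Maximum mismatches tolerated (default 1).
#' @return 1-based start position of the adapter in the read, or `NA` if the
#'   adapter is not found.
#' @keywords internal
find_adapter_start <- function(seq, adapter, min_overlap = 6L, max_mismatch = 1L) {
  rc <- strsplit(seq, "")[[1]]
  ac <- strsplit(adapter, "")[[1]]
  n <- length(rc)
  for (p in seq_len(max(0L, n - min_overlap + 1L))) {
    L <- min(length(ac), n - p + 1L)
    if (L < min_overlap) break
    if (sum(rc[p:(p + L - 1L)] != ac[seq_len(L)]) <= max_mismatch) return(p)
  }
  NA_integer_
}

.contains_adapter <- function(seq, adapter, min_overlap = 6L, max_mismatch = 1L) {
  !is.na(find_adapter_start(seq, adapter, min_overlap, max_mismatch))
}

.polya_fraction <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  mean(chars == "A")
}

# One read through the filter cascade; first failing test wins.
.categorize_read <- function(s, adapter3, adapter5, min_len = 18L,
                             polya_frac = 0.7) {
  p <- find_adapter_start(s, adapter3)
  if (is.na(p)) return(list(category = "no_3_adapter", insert = ""))
  ins <- substr(s, 1L, p - 1L)
  if (nchar(ins) == 0L) return(list(category = "insert_null", insert = ""))
  if (.contains_adapter(ins, adapter5)) {
    return(list(category = "adapter5_contaminant", insert = ""))
  }
  if (nchar(ins) < min_len) return(list(category = "short_lt18", insert = ""))
  if (.polya_fraction(ins) >= polya_frac) {
    return(list(category = "polyA", insert = ""))
  }
  list(category = "clean", insert = ins)
}

.as_read_sequences <- function(reads) {
  if (inherits(reads, "DNAStringSet")) as.character(reads) else as.character(reads)
}

#' Collapsed clean-read set
#'
#' @param seqs Character vector of insert sequences (possibly repeated).
#' @param counts Optional counts parallel to `seqs`; default 1 each.
#' @return A `clean_reads` object: data.frame with columns `seq` and `count`
#'   (unique sequences, descending count) and attribute `total`.
#' @export
clean_read_set <- function(seqs, counts = NULL) {
  if (is.null(counts)) counts <- rep(1L, length(seqs))
  agg <- tapply(counts, seqs, sum)
  df <- data.frame(seq = names(agg), count = as.numeric(agg),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$seq), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, total = sum(df$count), class = c("clean_reads", "data.frame"))
}

#' @export
print.clean_reads <- function(x, ...) {
  cat("Clean read set:", attr(x, "total"), "reads,", nrow(x),
      "unique sequences\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Filter raw small-RNA reads into clean reads with full accounting
#'
#' Applies the contamination filter cascade in a fixed order; every read is
#' assigned to exactly one category by its first failing test:
#' 3' adapter absent, then empty insert, then 5' adapter contamination, then
#' insert shorter than `min_len`, then polyA (at least `polya_frac` adenines
#' after adapter removal); reads passing all tests are clean and are reported
#' as adapter-trimmed inserts.
#'
#' @param reads Character vector of read sequences or a `DNAStringSet`.
#' @param adapter3,adapter5 3' and 5' adapter sequences (non-empty).
#' @param min_len Minimum insert length to keep (default 18).
#' @param polya_frac polyA threshold: fraction of A in the insert (default 0.7).
#' @param raw_reads Optional raw read count before base-quality filtering; the
#'   input is treated as the high-quality read set.
#' @param library Optional library label carried into the report.
#' @return A list with `clean` (a [clean_read_set()] of trimmed inserts) and
#'   `report` (an [accounting_report()]).
#' @export
filter_reads <- function(reads, adapter3, adapter5, min_len = 18L,
                         polya_frac = 0.7, raw_reads = NULL, library = NULL) {
  stopifnot(nchar(adapter3) > 0, nchar(adapter5) > 0)
  seqs <- .as_read_sequences(reads)
  n_total <- length(seqs)
  tab <- table(seqs)
  uniq <- names(tab)
  counts <- as.numeric(tab)

  category <- character(length(uniq))
  insert <- character(length(uniq))
  for (i in seq_along(uniq)) {
    res <- .categorize_read(uniq[i], adapter3, adapter5, min_len, polya_frac)
    category[i] <- res$category
    insert[i] <- res$insert
  }

  removed <- vapply(.FILTER_CATEGORIES, function(cat)
    sum(counts[category == cat]), numeric(1))
  keep <- category == "clean"
  clean <- clean_read_set(insert[keep], counts[keep])
  report <- accounting_report(
    high_quality_reads = n_total,
    removed = removed,
    raw_reads = if (is.null(raw_reads)) n_total else raw_reads,
    library = library
  )
  list(clean = clean, report = report)
}

#' Read-accounting report
#'
#' Per-library accounting of the filter cascade, mirroring the standard
#' published layout (raw reads, high-quality reads, one row per removal
#' category, clean reads with percent of high-quality reads, and mapped reads
#' with percent of clean reads). When `clean_reads` or the percentages are
#' supplied (e.g. transcribed from a published table) they are stored as
#' reported; [validate_accounting()] checks them against recomputation.
#'
#' @param high_quality_reads High-quality read count (the filter input).
#' @param removed Named numeric vector of per-category removal counts; names
#'   must be the five cascade categories.
#' @param clean_reads,clean_percent,mapped_reads,mapped_percent Optional
#'   reported values; clean values are computed when missing.
#' @param raw_reads Raw read count (defaults to `high_quality_reads`).
#' @param library Optional library label.
#' @return An `accounting_report` object.
#' @export
accounting_report <- function(high_quality_reads, removed,
                              clean_reads = NULL, clean_percent = NULL,
                              mapped_reads = NA_real_, mapped_percent = NULL,
                              raw_reads = high_quality_reads, library = NULL) {
  stopifnot(setequal(names(removed), .FILTER_CATEGORIES))
  removed <- vapply(removed[.FILTER_CATEGORIES], as.numeric, numeric(1))
  high_quality_reads <- as.numeric(high_quality_reads)
  raw_reads <- as.numeric(raw_reads)
  if (!is.null(clean_reads)) clean_reads <- as.numeric(clean_reads)
  mapped_reads <- as.numeric(mapped_reads)
  if (is.null(clean_reads)) clean_reads <- high_quality_reads - sum(removed)
  if (is.null(clean_percent)) {
    clean_percent <- round(100 * clean_reads / high_quality_reads, 2)
  }
  if (is.null(mapped_percent)) {
    mapped_percent <- if (is.na(mapped_reads)) NA_real_ else
      round(100 * mapped_reads / clean_reads, 2)
  }
  structure(
    list(
      library = library,
      raw_reads = raw_reads,
      high_quality_reads = high_quality_reads,
      removed = removed,
      clean_reads = clean_reads,
      clean_percent = clean_percent,
      mapped_reads = mapped_reads,
      mapped_percent = mapped_percent
    ),
    class = "accounting_report"
  )
}

#' @export
print.accounting_report <- function(x, ...) {
  cat("Read accounting", if (!is.null(x$library)) paste0("(", x$library, ")"),
      "\n")
  cat(sprintf("  %-28s %12.0f\n", "Raw reads", x$raw_reads))
  cat(sprintf("  %-28s %12.0f\n", "High quality reads", x$high_quality_reads))
  for (cat_ in .FILTER_CATEGORIES) {
    cat(sprintf("  %-28s %12.0f\n", .CATEGORY_LABELS[[cat_]],
                x$removed[[cat_]]))
  }
  cat(sprintf("  %-28s %12.0f  (%.2f%%)\n", "Clean reads", x$clean_reads,
              x$clean_percent))
  if (!is.na(x$mapped_reads)) {
    cat(sprintf("  %-28s %12.0f  (%.2f%%)\n", "Mapping on genome",
                x$mapped_reads, x$mapped_percent))
  }
  invisible(x)
}

#' Validate the internal arithmetic of an accounting report
#'
#' Checks the exact integer identity `clean = high_quality - sum(removed)` and
#' that the stored percentages match recomputation at two decimals
#' (round-half-even). Inconsistent columns in published tables are flagged
#' rather than silently accepted.
#'
#' @param report An [accounting_report()].
#' @return A list with logical fields `clean_ok`, `clean_percent_ok`,
#'   `mapped_percent_ok` and the overall `pass`.
#' @export
validate_accounting <- function(report) {
  stopifnot(inherits(report, "accounting_report"))
  expected_clean <- report$high_quality_reads - sum(report$removed)
  clean_ok <- isTRUE(expected_clean == report$clean_reads)
  clean_percent_ok <- isTRUE(
    round(100 * report$clean_reads / report$high_quality_reads, 2) ==
      round(report$clean_percent, 2)
  )
  mapped_percent_ok <- if (is.na(report$mapped_reads)) TRUE else isTRUE(
    round(100 * report$mapped_reads / report$clean_reads, 2) ==
      round(report$mapped_percent, 2)
  )
  list(
    clean_ok = clean_ok,
    clean_percent_ok = clean_percent_ok,
    mapped_percent_ok = mapped_percent_ok,
    pass = clean_ok && clean_percent_ok && mapped_percent_ok
  )
}

#' Write / read accounting reports as TSV
#'
#' The TSV mirrors the published row layout: one row per accounting category,
#' one `<library>_total` and `<library>_percent` column pair per library.
#'
#' @param reports A list of [accounting_report()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_accounting_tsv <- function(reports, path) {
  if (inherits(reports, "accounting_report")) reports <- list(reports)
  labs <- vapply(seq_along(reports), function(i) {
    lib <- reports[[i]]$library
    if (is.null(lib)) paste0("lib", i) else lib
  }, character(1))
  rows <- c("raw_reads", "high_quality_reads", .FILTER_CATEGORIES,
            "clean_reads", "mapped_reads")
  df <- data.frame(category = rows, stringsAsFactors = FALSE)
  for (i in seq_along(reports)) {
    r <- reports[[i]]
    tot <- c(r$raw_reads, r$high_quality_reads, unname(r$removed),
             r$clean_reads, r$mapped_reads)
    pct <- c(NA, 100, unname(round(100 * r$removed / r$high_quality_reads, 2)),
             r$clean_percent, r$mapped_percent)
    df[[paste0(labs[i], "_total")]] <- tot
    df[[paste0(labs[i], "_percent")]] <- pct
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_accounting_tsv
#' @param path TSV path to read.
#' @return For `read_accounting_tsv`: a named list of [accounting_report()]s.
#' @export
read_accounting_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  tot_cols <- grep("_total$", names(df), value = TRUE)
  libs <- sub("_total$", "", tot_cols)
  get <- function(lib, row, what) {
    df[df$category == row, paste0(lib, "_", what)]
  }
  out <- lapply(libs, function(lib) {
    removed <- vapply(.FILTER_CATEGORIES, function(cat)
      get(lib, cat, "total"), numeric(1))
    accounting_report(
      high_quality_reads = get(lib, "high_quality_reads", "total"),
      removed = removed,
      clean_reads = get(lib, "clean_reads", "total"),
      clean_percent = get(lib, "clean_reads", "percent"),
      mapped_reads = get(lib, "mapped_reads", "total"),
      mapped_percent = get(lib, "mapped_reads", "percent"),
      raw_reads = get(lib, "raw_reads", "total"),
      library = lib
    )
  })
  names(out) <- libs
  out
}

#' Length distribution of clean reads
#'
#' @param clean A [clean_read_set()].
#' @return data.frame with columns `length`, `count` and `percent`
#'   (percentages sum to 100 up to rounding).
#' @export
length_distribution <- function(clean) {
  stopifnot(inherits(clean, "clean_reads"), nrow(clean) > 0)
  lens <- nchar(clean$seq)
  agg <- tapply(clean$count, lens, sum)
  df <- data.frame(
    length = as.integer(names(agg)),
    count = as.numeric(agg)
  )
  df <- df[order(df$length), , drop = FALSE]
  df$percent <- 100 * df$count / sum(df$count)
  rownames(df) <- NULL
  df
}

#' Map clean reads to a genome by exact match
#'
#' A read maps if its sequence occurs exactly (0 mismatches) on either strand
#' of the genome. Multi-mapping reads are recorded at all loci but counted
#' once in `mapped_reads`. Coordinates are reported 1-based inclusive on the
#' plus strand of the reference.
#'
#' @param clean A [clean_read_set()].
#' @param genome A named `DNAStringSet` (or a named character vector of
#'   chromosome sequences).
#' @return A list with `assignments` (data.frame: seq, count, chrom, start,
#'   end, strand), `mapped_reads`, `mapped_percent` and `per_chromosome`
#'   (locus-level read tallies).
#' @export
map_reads <- function(clean, genome) {
  stopifnot(inherits(clean, "clean_reads"))
  if (!inherits(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0) {
    stop("empty genome")
  }
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))

  hits <- vector("list", nrow(clean))
  for (i in seq_len(nrow(clean))) {
    s <- clean$seq[i]
    pat <- Biostrings::DNAString(s)
    rcp <- Biostrings::reverseComplement(pat)
    rows <- list()
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else rcp
      m <- Biostrings::vmatchPattern(p, genome)
      for (ci in seq_along(m)) {
        ir <- m[[ci]]
        if (length(ir)) {
          rows[[length(rows) + 1L]] <- data.frame(
            seq = s, count = clean$count[i],
            chrom = names(genome)[ci],
            start = IRanges::start(ir), end = IRanges::end(ir),
            strand = strand, stringsAsFactors = FALSE
          )
        }
      }
    }
    if (length(rows)) hits[[i]] <- do.call(rbind, rows)
  }
  assignments <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(assignments)) {
    assignments <- data.frame(seq = character(), count = numeric(),
                              chrom = character(), start = integer(),
                              end = integer(), strand = character())
  }
  mapped <- sum(clean$count[clean$seq %in% assignments$seq])
  per_chrom <- if (nrow(assignments)) {
    agg <- tapply(assignments$count, assignments$chrom, sum)
    data.frame(chrom = names(agg), reads = as.numeric(agg))
  } else {
    data.frame(chrom = character(), reads = numeric())
  }
  list(
    assignments = assignments,
    mapped_reads = mapped,
    mapped_percent = round(100 * mapped / attr(clean, "total"), 2),
    per_chromosome = per_chrom
  )
}
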
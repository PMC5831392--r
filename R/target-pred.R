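## miRNA target prediction: canonical seed sites + duplex hybridization energy.

.rna_complement <- function(chars) {
  chartr("ACGU", "UGCA", chars)
}

# reverse complement of an RNA string
.rna_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", .to_rna(x)), "")[[1]]),
        collapse = "")
}

#' Scan a transcript for canonical miRNA seed sites
#'
#' Reports every position where the transcript Watson-Crick pairs the miRNA
#' seed: positions 2-8 (`7mer-m8`), positions 2-7 with an `A` in the
#' transcript opposite miRNA position 1 (`7mer-A1`), or both (`8mer`).
#' Scanning is along the transcript 5'->3'; the miRNA is reversed for
#' complementarity, so a site is the reverse complement of the seed. The
#' permissive mode instead accepts any 7 contiguous complementary bases
#' within miRNA positions 1-8.
#'
#' @param mirna miRNA sequence, 5'->3' (length >= 8).
#' @param transcript Transcript sequence, 5'->3'.
#' @param mode `"canonical"` (default) or `"permissive"`.
#' @return data.frame of sites: `position` (1-based start of the site on the
#'   transcript) and `site_type` (`8mer`, `7mer-m8`, `7mer-A1`, or `7mer` in
#'   permissive mode).
#' @export
seed_scan <- function(mirna, transcript, mode = c("canonical", "permissive")) {
  mode <- match.arg(mode)
  mirna <- .to_rna(mirna)
  transcript <- .to_rna(transcript)
  stopifnot(nchar(mirna) >= 8)
  n <- nchar(transcript)
  sites <- data.frame(position = integer(), site_type = character(),
                      stringsAsFactors = FALSE)
  add <- function(pos, type) {
    sites[nrow(sites) + 1L, ] <<- list(pos, type)
  }

  if (mode == "canonical") {
    m8_site <- .rna_revcomp(substr(mirna, 2L, 8L)) # 7 nt, pairs miRNA 2-8
    m7_site <- .rna_revcomp(substr(mirna, 2L, 7L)) # 6 nt, pairs miRNA 2-7
    # 7mer-m8 / 8mer: match to the 7-nt site; A opposite position 1 is the
    # transcript base immediately 3' of the match
    occ <- gregexpr(m8_site, transcript, fixed = TRUE)[[1]]
    if (occ[1] != -1L) {
      for (p in as.integer(occ)) {
        a1 <- if (p + 7L <= n) substr(transcript, p + 7L, p + 7L) else ""
        add(p, if (a1 == "A") "8mer" else "7mer-m8")
      }
    }
    # 7mer-A1: 6-nt match (miRNA 2-7) + A opposite position 1, not already an
    # m8 match at the same site
    occ6 <- gregexpr(m7_site, transcript, fixed = TRUE)[[1]]
    if (occ6[1] != -1L) {
      for (p in as.integer(occ6)) {
        a1_pos <- p + 6L
        if (a1_pos > n || substr(transcript, a1_pos, a1_pos) != "A") next
        # position 8 pairing would make this an m8 site found above
        m8_pairs <- p > 1L &&
          substr(transcript, p - 1L, p - 1L) ==
            .rna_complement(substr(mirna, 8L, 8L))
        if (!m8_pairs) add(p, "7mer-A1")
      }
    }
  } else {
    region <- substr(mirna, 1L, 8L)
    rc <- .rna_revcomp(region) # 8 nt
    tc <- strsplit(transcript, "")[[1]]
    rcc <- strsplit(rc, "")[[1]]
    for (p in seq_len(max(0L, n - 7L))) {
      match_run <- tc[p:(p + 7L)] == rcc
      runs <- rle(match_run)
      if (any(runs$lengths[runs$values] >= 7L)) add(p, "7mer")
    }
  }
  sites <- sites[order(sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Predict candidate target genes of differentially expressed miRNAs
#'
#' Two routes are intersected: a gene is a candidate target of a miRNA if
#' and only if it carries at least one canonical seed site and at least one
#' seed-anchored duplex with hybridization energy at or below
#' `energy_cutoff`. The duplex window for a seed site at transcript position
#' `p` spans the site plus the miRNA length and a 4-nt allowance upstream
#' (the 3'-pairing region of the duplex).
#'
#' @param de_mirnas Named character vector of miRNA sequences (5'->3').
#' @param transcripts Named character vector or `DNAStringSet` of transcript
#'   sequences.
#' @param energy_cutoff Duplex energy cutoff in kcal/mol (default -20).
#' @param mode Seed-matching mode, see [seed_scan()].
#' @return A list with `sites` (data.frame: mirna_id, gene_id, position,
#'   site_type, duplex_energy), `seed_targets` and `energy_targets` (the
#'   per-route gene sets), `targets` (per-miRNA intersection gene sets) and
#'   `union` (the non-redundant union of candidate genes).
#' @export
predict_targets <- function(de_mirnas, transcripts, energy_cutoff = -20,
                            mode = "canonical") {
  if (inherits(transcripts, "DNAStringSet") ||
      inherits(transcripts, "RNAStringSet")) {
    transcripts <- as.character(transcripts)
  }
  stopifnot(length(transcripts) > 0, !is.null(names(transcripts)))
  if (is.null(names(de_mirnas))) {
    names(de_mirnas) <- paste0("mirna", seq_along(de_mirnas))
  }
  transcripts <- vapply(transcripts, .to_rna, character(1))
  rows <- list()
  for (mi in names(de_mirnas)) {
    mseq <- .to_rna(de_mirnas[[mi]])
    mlen <- nchar(mseq)
    for (g in names(transcripts)) {
      tx <- transcripts[[g]]
      sites <- seed_scan(mseq, tx, mode = mode)
      if (!nrow(sites)) next
      energy <- vapply(sites$position, function(p) {
        w_end <- min(nchar(tx), p + 7L)      # covers the seed + A1 position
        w_start <- max(1L, w_end - (mlen + 4L) + 1L)
        duplex_energy(mseq, substr(tx, w_start, w_end))
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mi, gene_id = g, position = sites$position,
        site_type = sites$site_type, duplex_energy = energy,
        stringsAsFactors = FALSE
      )
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(), gene_id = character(),
               position = integer(), site_type = character(),
               duplex_energy = numeric())
  seed_targets <- lapply(split(sites$gene_id, sites$mirna_id), unique)
  keep <- sites[sites$duplex_energy <= energy_cutoff, , drop = FALSE]
  energy_targets <- lapply(split(keep$gene_id, keep$mirna_id), unique)
  targets <- lapply(names(seed_targets), function(mi)
    intersect(seed_targets[[mi]], energy_targets[[mi]]))
  names(targets) <- names(seed_targets)
  targets <- targets[vapply(targets, length, integer(1)) > 0]
  list(
    sites = sites,
    seed_targets = seed_targets,
    energy_targets = energy_targets,
    targets = targets,
    union = sort(unique(unlist(targets)))
  )
}
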
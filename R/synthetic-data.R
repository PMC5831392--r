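## Synthetic-data generator: every input the pipeline consumes, with ground
## truth. Emulates adaptered ~19-24 nt miRNA reads, the five contamination
## categories of the published accounting layout, three tissue libraries with
## Poisson counts and planted fold-changes, genomic loci that fold into valid
## hairpins, and annotation/interaction tables with planted enriched terms
## and hub genes.

.DEFAULT_ADAPTER3 <- "TGGAATTCTCGGGTGCCAAGG"      # TruSeq small RNA 3'
.DEFAULT_ADAPTER5 <- "GTTCAGAGTTCTACAGTCCGACGATC" # TruSeq small RNA 5'

#' Simulation configuration
#'
#' Defaults describe a desk-scale version of a three-tissue small RNA
#' sequencing study: three libraries, Poisson-distributed counts with mean
#' `mean_count` per expressed miRNA, a fraction `de_fraction` of miRNAs
#' planted at `de_fold`-fold higher expression in one designated library, and
#' contamination categories at rates matching the published per-category
#' proportions (fractions of emitted reads).
#'
#' @param seed Integer RNG seed.
#' @param n_libraries Number of libraries (default 3, named `DU`, `CE`, `CO`).
#' @param n_known_mirnas Number of known miRNA precursors (one mature each).
#' @param n_novel_loci Number of planted novel hairpin loci.
#' @param n_reads_per_library Nominal reads emitted per library (sets the
#'   expected contamination counts).
#' @param adapter3,adapter5 Adapter sequences appended to / contaminating
#'   reads.
#' @param contamination_rates Named fractions for the five categories
#'   `no_3_adapter`, `insert_null`, `adapter5_contaminant`, `short_lt18`,
#'   `polyA`; must sum to < 1 (the remainder is the clean fraction).
#' @param de_fraction Fraction of known miRNAs planted as differential.
#' @param de_fold Planted fold-change (>= 2 whenever `de_fraction > 0`).
#' @param mean_count Expected clean reads per expressed miRNA per library.
#' @param overdispersion Negative-binomial overdispersion (variance
#'   `mu + overdispersion * mu^2`); 0 (default) gives pure Poisson sampling,
#'   matching the assumption of the differential test.
#' @param genome_length Total genome length; computed from the locus count
#'   when `NULL`.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(seed = 1L,
                       n_libraries = 3L,
                       n_known_mirnas = 20L,
                       n_novel_loci = 3L,
                       n_reads_per_library = 20000L,
                       adapter3 = .DEFAULT_ADAPTER3,
                       adapter5 = .DEFAULT_ADAPTER5,
                       contamination_rates = c(
                         no_3_adapter = 0.0094,
                         insert_null = 0.0007,
                         adapter5_contaminant = 0.0003,
                         short_lt18 = 0.0245,
                         polyA = 0.0001
                       ),
                       de_fraction = 0.2,
                       de_fold = 4,
                       mean_count = 200,
                       overdispersion = 0,
                       genome_length = NULL) {
  stopifnot(
    setequal(names(contamination_rates),
             c("no_3_adapter", "insert_null", "adapter5_contaminant",
               "short_lt18", "polyA")),
    all(contamination_rates >= 0), sum(contamination_rates) < 1,
    n_libraries >= 2, n_known_mirnas >= 1, n_reads_per_library >= 1,
    nchar(adapter3) >= 6, nchar(adapter5) >= 6,
    de_fraction >= 0, de_fraction <= 1, mean_count > 0, overdispersion >= 0
  )
  if (de_fraction > 0 && de_fold < 2) {
    stop("de_fold must be >= 2 when de_fraction > 0")
  }
  lib_names <- c("DU", "CE", "CO", paste0("L", seq_len(max(0, n_libraries - 3))))
  cfg <- list(
    seed = as.integer(seed), n_libraries = as.integer(n_libraries),
    library_names = lib_names[seq_len(n_libraries)],
    n_known_mirnas = as.integer(n_known_mirnas),
    n_novel_loci = as.integer(n_novel_loci),
    n_reads_per_library = as.integer(n_reads_per_library),
    adapter3 = adapter3, adapter5 = adapter5,
    contamination_rates = contamination_rates[
      c("no_3_adapter", "insert_null", "adapter5_contaminant", "short_lt18",
        "polyA")],
    de_fraction = de_fraction, de_fold = de_fold, mean_count = mean_count,
    overdispersion = overdispersion, genome_length = genome_length
  )
  structure(cfg, class = "sim_config")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A sequence is "adapter-safe" when neither adapter would be detected inside
# it, it is below the polyA threshold, and it carries no run confusable with
# the categories applied before the clean test.
.adapter_safe <- function(seq, adapter3, adapter5) {
  !.contains_adapter(seq, adapter3) && !.contains_adapter(seq, adapter5) &&
    .polya_fraction(seq) < 0.7
}

.random_safe_dna <- function(n, adapter3, adapter5, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    s <- .random_dna(n)
    if (.adapter_safe(s, adapter3, adapter5)) return(s)
  }
  stop("could not draw an adapter-safe sequence")
}

# An insert emitted as a clean read must come back from the filter cascade as
# that exact insert (junction windows between insert and adapter can
# otherwise fake an earlier adapter hit).
.clean_read_ok <- function(insert, adapter3, adapter5) {
  res <- .categorize_read(paste0(insert, adapter3), adapter3, adapter5)
  res$category == "clean" && res$insert == insert
}

.draw_categorized <- function(n, adapter3, adapter5, target, build,
                              max_tries = 200L) {
  vapply(seq_len(n), function(i) {
    for (t in seq_len(max_tries)) {
      s <- build()
      if (.categorize_read(s, adapter3, adapter5)$category == target) return(s)
    }
    stop("could not draw a read of category ", target)
  }, character(1))
}

#' Simulate a genome with planted miRNA loci
#'
#' Builds a random background genome and plants `n_known_mirnas` known
#' precursors (mature + loop + reverse complement of the mature, so each
#' precursor folds into a hairpin; the mature occupies the 5' arm) and
#' `n_novel_loci` unannotated inverted-repeat loci (stem >= 18 bp, loop >= 3
#' nt), alternating chromosome and strand. Each precursor occurs verbatim at
#' its annotated locus; annotation coordinates are 1-based inclusive on the
#' declared strand. Mature and locus sequences are drawn adapter-safe so
#' that downstream filtering never truncates them.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (named `DNAStringSet`), `annotation` (a
#'   [mirna_annotation()] of the known miRNAs) and `novel_truth` (data.frame
#'   of the planted novel loci: coordinates, precursor and mature sequence).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_genome_impl(config))
}

.simulate_genome_impl <- function(config) {
  n_loci <- config$n_known_mirnas + config$n_novel_loci
  slot <- 220L
  g_len <- if (is.null(config$genome_length)) {
    max(2000L, as.integer(ceiling(n_loci / 2) * slot + 500L))
  } else {
    as.integer(config$genome_length)
  }
  chroms <- c("chr1", "chr2")
  per_chrom <- ceiling(n_loci / 2)
  if (per_chrom * slot + 100L > g_len) {
    stop("precursors exceed genome length; increase genome_length")
  }
  genome <- stats::setNames(
    vapply(chroms, function(ch) .random_dna(g_len), character(1)), chroms)

  mature_lens <- sample(20:24, config$n_known_mirnas, replace = TRUE,
                        prob = c(0.1, 0.2, 0.4, 0.2, 0.1))
  pre_rows <- list()
  mat_rows <- list()
  novel_rows <- list()
  plant <- function(locus_idx, pre_dna) {
    ch <- chroms[(locus_idx - 1L) %% 2L + 1L]
    strand <- if (((locus_idx - 1L) %/% 2L) %% 2L == 0L) "+" else "-"
    slot_idx <- (locus_idx - 1L) %/% 2L
    start <- 60L + slot_idx * slot
    end <- start + nchar(pre_dna) - 1L
    if (end > g_len) stop("precursors exceed genome length")
    planted <- if (strand == "+") pre_dna else .revcomp(pre_dna)
    substr(genome[[ch]], start, end) <<- planted
    list(chrom = ch, start = start, end = end, strand = strand)
  }

  for (i in seq_len(config$n_known_mirnas)) {
    repeat {
      mat <- .random_safe_dna(mature_lens[i], config$adapter3, config$adapter5)
      loop <- .random_dna(sample(8:12, 1))
      pre_dna <- paste0(mat, loop, .revcomp(mat))
      if (.adapter_safe(pre_dna, config$adapter3, config$adapter5) &&
          .clean_read_ok(mat, config$adapter3, config$adapter5)) break
    }
    loc <- plant(i, pre_dna)
    pid <- sprintf("sim-mir-%03d", i)
    pre_rows[[i]] <- data.frame(
      precursor_id = pid, chrom = loc$chrom, start = loc$start,
      end = loc$end, strand = loc$strand, seq = .to_rna(pre_dna),
      stringsAsFactors = FALSE
    )
    mat_rows[[i]] <- data.frame(
      mature_id = sprintf("sim-miR-%03d", i), precursor_id = pid,
      start = 1L, end = nchar(mat), seq = .to_rna(mat),
      family = sprintf("sim-miR-%03d", i), stringsAsFactors = FALSE
    )
  }

  # novel loci: perfect inverted repeats; mature on the 5' arm, star read on
  # the 3' arm, so a read cluster spans the whole hairpin within the default
  # cluster gap
  for (j in seq_len(config$n_novel_loci)) {
    repeat {
      arm <- .random_safe_dna(22L, config$adapter3, config$adapter5)
      star <- .revcomp(arm)
      loop <- .random_dna(sample(6:8, 1))
      pre_dna <- paste0(arm, loop, star)
      if (.adapter_safe(pre_dna, config$adapter3, config$adapter5) &&
          .clean_read_ok(arm, config$adapter3, config$adapter5) &&
          .clean_read_ok(star, config$adapter3, config$adapter5)) break
    }
    loc <- plant(config$n_known_mirnas + j, pre_dna)
    novel_rows[[j]] <- data.frame(
      locus_id = sprintf("sim-novel-%03d", j), chrom = loc$chrom,
      start = loc$start, end = loc$end, strand = loc$strand,
      precursor_seq = .to_rna(pre_dna),
      mature_seq = .to_rna(arm), star_seq = .to_rna(star),
      stringsAsFactors = FALSE
    )
  }

  annotation <- mirna_annotation(do.call(rbind, pre_rows),
                                 do.call(rbind, mat_rows))
  list(
    genome = Biostrings::DNAStringSet(genome),
    annotation = annotation,
    novel_truth = if (length(novel_rows)) do.call(rbind, novel_rows) else
      data.frame()
  )
}

# Per-miRNA expected counts with planted differential miRNAs; DE miRNAs are
# upregulated by de_fold in one designated library (round-robin).
.plant_de <- function(config, mirna_ids) {
  n_de <- round(config$de_fraction * length(mirna_ids))
  de_ids <- if (n_de > 0) mirna_ids[seq_len(n_de)] else character(0)
  up_lib <- config$library_names[(seq_along(de_ids) - 1L) %%
                                   config$n_libraries + 1L]
  data.frame(mirna_id = de_ids, up_library = up_lib,
             stringsAsFactors = FALSE)
}

.draw_count <- function(n, mu, overdispersion) {
  if (overdispersion > 0) {
    stats::rnbinom(n, mu = mu, size = 1 / overdispersion)
  } else {
    stats::rpois(n, mu)
  }
}

#' Simulate a true count matrix with planted fold-changes
#'
#' Count-level core of the read simulator: per-miRNA counts are Poisson (or
#' negative binomial when `overdispersion > 0`) with mean `mean_count`,
#' multiplied by `de_fold` for each planted differential miRNA in its
#' designated library.
#'
#' @param config A [sim_config()].
#' @param mirna_ids Optional miRNA ids (defaults to the configured number of
#'   known miRNAs).
#' @return A list with `counts` (matrix miRNA x library) and `planted_de`
#'   (data.frame `mirna_id`, `up_library`).
#' @export
simulate_counts <- function(config, mirna_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(mirna_ids)) {
    mirna_ids <- sprintf("sim-miR-%03d", seq_len(config$n_known_mirnas))
  }
  withr::with_seed(config$seed + 1L, {
    de <- .plant_de(config, mirna_ids)
    counts <- matrix(0, length(mirna_ids), config$n_libraries,
                     dimnames = list(mirna_ids, config$library_names))
    for (lib in config$library_names) {
      mu <- rep(config$mean_count, length(mirna_ids))
      up <- de$mirna_id[de$up_library == lib]
      mu[mirna_ids %in% up] <- mu[mirna_ids %in% up] * config$de_fold
      counts[, lib] <- .draw_count(length(mirna_ids), mu,
                                   config$overdispersion)
    }
    list(counts = counts, planted_de = de)
  })
}

#' Simulate per-library FASTQ reads with ground truth
#'
#' Clean reads are mature miRNA sequences (known matures plus the planted
#' novel-locus matures) with the 3' adapter appended; per-miRNA counts come
#' from [simulate_counts()]. Each contamination category is emitted at its
#' configured rate (expected `rate * n_reads_per_library` reads, Poisson).
#' Categories are mutually exclusive - each contaminated read carries exactly
#' one defect - so the generator ledger and the filter tallies must agree
#' read-for-read.
#'
#' @param config A [sim_config()].
#' @param annotation A [mirna_annotation()] from [simulate_genome()].
#' @param novel_truth Optional `novel_truth` table from [simulate_genome()];
#'   planted novel matures are expressed at `mean_count` in every library.
#' @return A list with `reads` (named list of character vectors of read
#'   sequences per library) and `ground_truth`: `per_category_counts`
#'   (matrix category x library), `true_counts` (emitted clean reads per
#'   mature per library), `planted_de`, `clean_totals`.
#' @export
simulate_reads <- function(config, annotation, novel_truth = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(annotation, "mirna_annotation"),
            nrow(annotation$matures) > 0)
  mat <- annotation$matures
  mature_seqs <- stats::setNames(.to_dna(mat$seq), mat$mature_id)
  if (!is.null(novel_truth) && nrow(novel_truth)) {
    nv <- stats::setNames(.to_dna(novel_truth$mature_seq),
                          novel_truth$locus_id)
    star <- stats::setNames(.to_dna(novel_truth$star_seq),
                            paste0(novel_truth$locus_id, "-star"))
    mature_seqs <- c(mature_seqs, nv, star)
  }
  cm <- simulate_counts(config, mirna_ids = names(mature_seqs))
  # star reads are emitted at roughly half the mature abundance
  star_ids <- grep("-star$", rownames(cm$counts), value = TRUE)
  if (length(star_ids)) {
    cm$counts[star_ids, ] <- ceiling(cm$counts[star_ids, ] / 2)
    cm$planted_de <- cm$planted_de[
      !cm$planted_de$mirna_id %in% star_ids, , drop = FALSE]
  }
  withr::with_seed(config$seed + 2L, {
    libs <- config$library_names
    cats <- names(config$contamination_rates)
    per_cat <- matrix(0, length(cats), length(libs),
                      dimnames = list(cats, libs))
    reads <- vector("list", length(libs))
    names(reads) <- libs
    a3 <- config$adapter3
    a5 <- config$adapter5
    for (lib in libs) {
      clean <- rep(paste0(mature_seqs, a3), cm$counts[, lib])
      contam <- character(0)
      for (cat_ in cats) {
        n_cat <- stats::rpois(1, config$n_reads_per_library *
                                config$contamination_rates[[cat_]])
        per_cat[cat_, lib] <- n_cat
        if (n_cat == 0) next
        emitted <- switch(
          cat_,
          no_3_adapter = .draw_categorized(n_cat, a3, a5, "no_3_adapter",
                                           function() .random_dna(22L)),
          insert_null = rep(a3, n_cat),
          adapter5_contaminant = .draw_categorized(
            n_cat, a3, a5, "adapter5_contaminant",
            function() paste0(a5, .random_dna(16L), a3)),
          short_lt18 = .draw_categorized(
            n_cat, a3, a5, "short_lt18",
            function() paste0(.random_dna(sample(8:17, 1)), a3)),
          polyA = .draw_categorized(
            n_cat, a3, a5, "polyA",
            function() paste0(strrep("A", 22L), a3))
        )
        contam <- c(contam, emitted)
      }
      all_reads <- sample(c(clean, contam))
      names(all_reads) <- sprintf("%s_read_%06d", lib, seq_along(all_reads))
      reads[[lib]] <- all_reads
    }
    list(
      reads = reads,
      ground_truth = list(
        per_category_counts = per_cat,
        true_counts = cm$counts,
        planted_de = cm$planted_de,
        clean_totals = colSums(cm$counts)
      )
    )
  })
}

#' Simulate annotation, interaction and expression-background tables
#'
#' Plants enriched terms (over-represented among the designated candidate
#' genes) in a GO-style table, hub genes of top-5% degree in an interaction
#' table with combined scores, and an FPKM background in which all genes are
#' expressed.
#'
#' @param config A [sim_config()].
#' @param genes Character vector of at least 50 gene ids.
#' @param candidates Designated candidate target genes (default: the first
#'   `n_candidates` ids). Interaction edges are planted among them so the
#'   downstream network is non-trivial, as in a real study where candidate
#'   targets share pathways.
#' @param n_candidates Number of designated candidates when `candidates` is
#'   `NULL`.
#' @return A list with `go` (gene_id, term_id, term_name, namespace), `ppi`
#'   (gene_a, gene_b, combined_score), `fpkm` (gene_id, fpkm) and `truth`
#'   (`enriched_terms`, `hubs`, `candidates`).
#' @export
simulate_annotation_tables <- function(config, genes, candidates = NULL,
                                       n_candidates = 10L) {
  stopifnot(inherits(config, "sim_config"), length(genes) >= 50)
  withr::with_seed(config$seed + 3L, {
    genes <- as.character(genes)
    if (is.null(candidates)) candidates <- genes[seq_len(n_candidates)]
    candidates <- intersect(genes, candidates)
    n_candidates <- length(candidates)
    stopifnot(n_candidates >= 4)
    namespaces <- c("biological_process", "cellular_component",
                    "molecular_function")
    rows <- list()
    planted <- character(0)
    for (ns in namespaces[1:2]) {
      term <- paste0("TERM:planted_", ns)
      planted <- c(planted, term)
      in_cand <- candidates[seq_len(ceiling(0.8 * n_candidates))]
      in_bg <- sample(setdiff(genes, candidates), 20L)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = c(in_cand, in_bg), term_id = term, term_name = term,
        namespace = ns, stringsAsFactors = FALSE
      )
    }
    for (t in seq_len(12L)) {
      ns <- namespaces[(t - 1L) %% 3L + 1L]
      members <- sample(genes, sample(10:40, 1))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = members, term_id = sprintf("TERM:%04d", t),
        term_name = sprintf("TERM:%04d", t), namespace = ns,
        stringsAsFactors = FALSE
      )
    }
    go <- do.call(rbind, rows)

    # hubs: candidate genes of top degree among the candidate interactions
    hubs <- utils::tail(candidates, 2L)
    others <- setdiff(candidates, hubs)
    ppi_rows <- list()
    for (h in hubs) {
      partners <- c(others,
                    sample(setdiff(genes, candidates),
                           max(0L, min(30L, length(genes) - n_candidates) -
                                 length(others))))
      ppi_rows[[length(ppi_rows) + 1L]] <- data.frame(
        gene_a = h, gene_b = partners,
        combined_score = stats::runif(length(partners), 0.4, 1),
        stringsAsFactors = FALSE
      )
    }
    # ring over the remaining candidates so each keeps an interaction edge
    if (length(others) >= 2) {
      ppi_rows[[length(ppi_rows) + 1L]] <- data.frame(
        gene_a = others, gene_b = c(others[-1], others[1]),
        combined_score = stats::runif(length(others), 0.4, 1),
        stringsAsFactors = FALSE
      )
    }
    # background edges across all genes, scores over the full [0, 1]
    ppi_rows[[length(ppi_rows) + 1L]] <- data.frame(
      gene_a = sample(genes, 60L, replace = TRUE),
      gene_b = sample(genes, 60L, replace = TRUE),
      combined_score = stats::runif(60L), stringsAsFactors = FALSE
    )
    ppi <- do.call(rbind, ppi_rows)
    ppi <- ppi[ppi$gene_a != ppi$gene_b, , drop = FALSE]

    fpkm <- data.frame(gene_id = genes,
                       fpkm = stats::rlnorm(length(genes), 2, 1) + 1.01,
                       stringsAsFactors = FALSE)
    list(go = go, ppi = ppi, fpkm = fpkm,
         truth = list(enriched_terms = planted, hubs = hubs,
                      candidates = candidates))
  })
}

#' Simulate a transcriptome with planted target sites
#'
#' For each designated miRNA-gene pair, the transcript carries one planted
#' site: the reverse complement of miRNA positions 2..L followed by an `A`
#' (an 8mer seed site whose full-length duplex hybridizes far below the
#' energy cutoff). Non-target transcripts are drawn with no seed site for
#' any query miRNA (rejection sampling).
#'
#' @param config A [sim_config()].
#' @param mirnas Named character vector of miRNA sequences.
#' @param genes Character vector of gene ids.
#' @param targets Named list (miRNA id -> gene ids) of planted target
#'   relations; default plants each miRNA into two genes round-robin.
#' @param transcript_length Transcript length (default 300).
#' @return A list with `transcripts` (named character vector) and `truth`
#'   (the planted target sets).
#' @export
simulate_transcripts <- function(config, mirnas, genes, targets = NULL,
                                 transcript_length = 300L) {
  stopifnot(inherits(config, "sim_config"), length(genes) >= 1)
  withr::with_seed(config$seed + 4L, {
    if (is.null(targets)) {
      targets <- stats::setNames(vector("list", length(mirnas)),
                                 names(mirnas))
      gi <- 0L
      for (mi in names(mirnas)) {
        targets[[mi]] <- genes[(gi + seq_len(2L) - 1L) %% length(genes) + 1L]
        gi <- gi + 2L
      }
    }
    seeds <- lapply(mirnas, function(m) {
      m <- .to_rna(m)
      c(.rna_revcomp(substr(m, 2L, 8L)), .rna_revcomp(substr(m, 2L, 7L)))
    })
    has_any_seed <- function(tx) {
      any(vapply(seeds, function(s)
        grepl(s[1], tx, fixed = TRUE) ||
          grepl(paste0(s[2], "A"), tx, fixed = TRUE), logical(1)))
    }
    draw_background <- function(n) {
      repeat {
        tx <- .to_rna(.random_dna(n))
        if (!has_any_seed(tx)) return(tx)
      }
    }
    transcripts <- stats::setNames(
      vapply(genes, function(g) draw_background(transcript_length),
             character(1)), genes)
    for (mi in names(targets)) {
      m <- .to_rna(mirnas[[mi]])
      site <- paste0(.rna_revcomp(substr(m, 2L, nchar(m))), "A")
      for (g in targets[[mi]]) {
        pos <- sample(seq(30L, transcript_length - nchar(site) - 10L), 1)
        tx <- transcripts[[g]]
        substr(tx, pos, pos + nchar(site) - 1L) <- site
        transcripts[[g]] <- tx
      }
    }
    list(transcripts = transcripts, truth = targets)
  })
}

#' Deterministic regulatory-network fixture at a published scale
#'
#' Constructs an interaction table and per-miRNA target sets with a planted
#' topology: `length(hub_regulator_counts)` hub genes of strictly highest
#' interaction degree, regulated by the given numbers of distinct miRNAs
#' (all other miRNAs regulate non-hub genes), every gene holding at least
#' one interaction edge so that [build_network()] keeps all
#' `n_genes + n_mirnas` nodes.
#'
#' @param n_genes,n_mirnas Node counts (defaults 92 genes, 65 miRNAs).
#' @param hub_regulator_counts Distinct regulators per hub gene (default
#'   `c(2, 2, 1, 1, 1)`, i.e. 7 distinct hub miRNAs over 5 hub genes).
#' @param seed RNG seed.
#' @return A list with `target_sets`, `ppi` and `truth` (`hubs`,
#'   `hub_mirnas`).
#' @export
simulate_regulatory_fixture <- function(n_genes = 92L, n_mirnas = 65L,
                                        hub_regulator_counts = c(2, 2, 1, 1, 1),
                                        seed = 1L) {
  n_hubs <- length(hub_regulator_counts)
  stopifnot(n_genes > 4 * n_hubs, n_mirnas >= sum(hub_regulator_counts))
  withr::with_seed(seed, {
    genes <- sprintf("gene%03d", seq_len(n_genes))
    mirnas <- sprintf("mir%03d", seq_len(n_mirnas))
    hubs <- genes[seq_len(n_hubs)]
    others <- setdiff(genes, hubs)

    ppi_rows <- list()
    # hubs: strictly decreasing high degrees
    for (i in seq_len(n_hubs)) {
      k <- 2L * n_hubs + 8L - i
      partners <- others[((i - 1L) * 3L + seq_len(k) - 1L) %% length(others) + 1L]
      ppi_rows[[length(ppi_rows) + 1L]] <- data.frame(
        gene_a = hubs[i], gene_b = unique(partners),
        combined_score = 0.9, stringsAsFactors = FALSE
      )
    }
    # ring over the remaining genes so every gene keeps an interaction edge
    ppi_rows[[length(ppi_rows) + 1L]] <- data.frame(
      gene_a = others,
      gene_b = c(others[-1], others[1]),
      combined_score = 0.5, stringsAsFactors = FALSE
    )
    ppi <- do.call(rbind, ppi_rows)

    target_sets <- stats::setNames(vector("list", n_mirnas), mirnas)
    hub_regulators <- mirnas[seq_len(sum(hub_regulator_counts))]
    idx <- 0L
    for (i in seq_len(n_hubs)) {
      regs <- hub_regulators[idx + seq_len(hub_regulator_counts[i])]
      idx <- idx + hub_regulator_counts[i]
      for (r in regs) target_sets[[r]] <- c(target_sets[[r]], hubs[i])
    }
    # every remaining gene is regulated by at least one remaining miRNA, and
    # every remaining miRNA regulates at least one gene
    rest <- setdiff(mirnas, hub_regulators)
    for (j in seq_along(others)) {
      mi <- rest[(j - 1L) %% length(rest) + 1L]
      target_sets[[mi]] <- c(target_sets[[mi]], others[j])
    }
    for (j in seq_along(rest)) {
      if (is.null(target_sets[[rest[j]]])) {
        target_sets[[rest[j]]] <- others[(j - 1L) %% length(others) + 1L]
      }
    }
    list(target_sets = target_sets, ppi = ppi,
         truth = list(hubs = hubs, hub_mirnas = hub_regulators))
  })
}
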
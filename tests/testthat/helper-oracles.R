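# Independent oracles used to cross-check the package implementations.
# Deliberately written as direct enumerations / closed forms, sharing no code
# with the routines under test.

# Exhaustive minimum-free-energy oracle: enumerates every pseudoknot-free
# secondary structure (hairpin loops >= 3 nt) and scores it as the sum of
# pair energies (GC -3, AU -2, GU -1) plus 0.5 per hairpin loop. Memoised
# enumeration over subintervals; feasible up to ~15 nt.
enum_fold_mfe <- function(seq) {
  chars <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(chars)
  pair_e <- function(i, j) {
    p <- paste0(chars[i], chars[j])
    if (p %in% c("GC", "CG")) return(-3)
    if (p %in% c("AU", "UA")) return(-2)
    if (p %in% c("GU", "UG")) return(-1)
    0
  }
  memo <- new.env(parent = emptyenv())
  # returns list(energy = numeric vector, haspair = logical vector) over all
  # structures on [i..j]
  enum <- function(i, j) {
    if (i > j) return(list(energy = 0, haspair = FALSE))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res_e <- numeric(0)
    res_h <- logical(0)
    left <- enum(i + 1L, j) # i unpaired
    res_e <- c(res_e, left$energy)
    res_h <- c(res_h, left$haspair)
    if (j - i >= 4L) {
      for (k in (i + 4L):j) {
        e <- pair_e(i, k)
        if (e == 0) next
        inner <- enum(i + 1L, k - 1L)
        right <- if (k < j) enum(k + 1L, j) else
          list(energy = 0, haspair = FALSE)
        inner_e <- ifelse(inner$haspair, inner$energy, 0.5) # hairpin penalty
        comb <- outer(inner_e, right$energy, "+") + e
        res_e <- c(res_e, as.vector(comb))
        res_h <- c(res_h, rep(TRUE, length(comb)))
      }
    }
    out <- list(energy = res_e, haspair = res_h)
    memo[[key]] <- out
    out
  }
  min(0, min(enum(1L, n)$energy))
}

# Brute-force canonical seed-site oracle: position-by-position Watson-Crick
# complementarity of the transcript against miRNA positions 2-8 / 2-7 + A1.
brute_seed_sites <- function(mirna, transcript) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  m <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  t_ <- strsplit(chartr("T", "U", toupper(transcript)), "")[[1]]
  n <- length(t_)
  out <- data.frame(position = integer(), site_type = character(),
                    stringsAsFactors = FALSE)
  # transcript position p..p+6 pairs miRNA 8..2 (antiparallel)
  for (p in seq_len(max(0, n - 6L))) {
    pairs_m8 <- all(t_[p:(p + 6L)] == comp[m[8:2]])
    a1 <- p + 7L <= n && t_[p + 7L] == "A"
    if (pairs_m8) {
      out[nrow(out) + 1L, ] <- list(p, if (a1) "8mer" else "7mer-m8")
    }
  }
  for (p in seq_len(max(0, n - 5L))) {
    pairs_m7 <- all(t_[p:(p + 5L)] == comp[m[7:2]])
    a1_pos <- p + 6L
    if (!pairs_m7 || a1_pos > n || t_[a1_pos] != "A") next
    m8_pairs <- p > 1L && t_[p - 1L] == comp[m[8]]
    if (!m8_pairs) out[nrow(out) + 1L, ] <- list(p, "7mer-A1")
  }
  out[order(out$position), , drop = FALSE]
}

# Brute-force ungapped coverage/mismatch matcher over all window placements.
brute_ungapped_match <- function(a, b, min_cov, max_mismatch) {
  ac <- strsplit(chartr("T", "U", toupper(a)), "")[[1]]
  bc <- strsplit(chartr("T", "U", toupper(b)), "")[[1]]
  for (ia in seq_along(ac)) {
    for (ib in seq_along(bc)) {
      L <- min(length(ac) - ia, length(bc) - ib) + 1L
      if (L < min_cov) next
      for (cov in min_cov:L) {
        mm <- sum(ac[ia:(ia + cov - 1L)] != bc[ib:(ib + cov - 1L)])
        if (mm <= max_mismatch) return(TRUE)
      }
    }
  }
  FALSE
}

# Shared small simulation fixture (kept modest so the suite stays fast).
small_sim_config <- function(seed = 11L, ...) {
  args <- list(seed = seed, n_known_mirnas = 12L, n_novel_loci = 2L,
               n_reads_per_library = 5000L, mean_count = 150)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
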
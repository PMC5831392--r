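## Shared thermodynamic constants for hairpin folding and duplex hybridization.
## Deliberately simple and fully documented so every result is reproducible
## without an external folding engine: each admissible base pair contributes a
## fixed stabilising energy and every terminal (hairpin) loop costs a fixed
## entropic penalty. Energies in kcal/mol.

.PAIR_ENERGY <- c(
  "GC" = -3.0, "CG" = -3.0,
  "AU" = -2.0, "UA" = -2.0,
  "GU" = -1.0, "UG" = -1.0
)
.LOOP_PENALTY <- 0.5   # per hairpin loop
.MIN_HAIRPIN_LOOP <- 3 # minimum unpaired bases closed by a pair

#' Energy of a single base pair
#'
#' @param a,b Single RNA bases (`A`, `C`, `G`, `U`).
#' @return Pair energy in kcal/mol, or `0` if the two bases cannot pair.
#'   Watson-Crick pairs and the G:U wobble are admissible.
#' @keywords internal
pair_energy <- function(a, b) {
  e <- .PAIR_ENERGY[paste0(a, b)]
  ifelse(is.na(e), 0, unname(e))
}

.as_rna_chars <- function(seq) {
  seq <- toupper(seq)
  seq <- chartr("T", "U", seq)
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) && !all(chars %in% c("A", "C", "G", "U"))) {
    bad <- setdiff(unique(chars), c("A", "C", "G", "U"))
    stop("invalid RNA alphabet: found ", paste(bad, collapse = ", "))
  }
  chars
}

#' Fold an RNA sequence to its minimum free energy structure
#'
#' Computes the minimum free energy (MFE) pseudoknot-free secondary structure
#' of a short RNA under the package energy model: every admissible base pair
#' (GC -3.0, AU -2.0, GU -1.0 kcal/mol) contributes its pair energy and every
#' hairpin loop adds an entropic penalty of +0.5 kcal/mol; hairpin loops span
#' at least 3 unpaired bases. The minimisation is an exact Nussinov-style
#' dynamic programme over all admissible structures, so on any input the
#' returned energy equals the minimum over exhaustive structure enumeration.
#'
#' @param seq RNA sequence (character scalar, `ACGU`; `T` tolerated and read
#'   as `U`).
#' @return A list with `structure` (dot-bracket string, same length as `seq`)
#'   and `mfe` (kcal/mol, always `<= 0`; the open structure has energy 0).
#' @examples
#' fold_rna("GGGGGAAAACCCCC")
#' @export
fold_rna <- function(seq) {
  chars <- .as_rna_chars(seq)
  n <- length(chars)
  if (n == 0L) stop("empty sequence")

  min_span <- .MIN_HAIRPIN_LOOP + 1L # j - i for the closest admissible pair
  # pair energy matrix (0 where unpairable)
  pe <- outer(chars, chars, FUN = pair_energy)

  INF <- Inf
  # V[i,j]: min energy over structures on [i,j] with (i,j) paired
  # W1[i,j]: min energy over structures on [i,j] containing >= 1 pair
  V <- matrix(INF, n, n)
  W1 <- matrix(INF, n, n)
  W <- matrix(0, n, n) # min(0, W1)

  if (n > min_span) {
    for (span in min_span:(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        if (pe[i, j] < 0) {
          inner <- if (span >= min_span + 2L) W1[i + 1L, j - 1L] else INF
          V[i, j] <- pe[i, j] + min(.LOOP_PENALTY, inner)
        }
        # W1 decomposition: i unpaired, or i paired to some k
        best <- W1[i + 1L, j]
        ks <- (i + min_span):j
        cand <- V[i, ks] + c(W[ks[-length(ks)] + 1L, j], 0)
        best <- min(best, cand)
        W1[i, j] <- best
        W[i, j] <- min(0, best)
      }
    }
  }

  structure_chars <- rep(".", n)
  # traceback
  trace_w <- function(i, j) {
    if (i >= j || W[i, j] >= 0) return(invisible())
    trace_w1(i, j)
  }
  trace_w1 <- function(i, j) {
    if (i >= j) return(invisible())
    target <- W1[i, j]
    if (!is.finite(target)) return(invisible())
    if (isTRUE(all.equal(W1[i + 1L, j], target)) && i + 1L <= j) {
      return(trace_w1(i + 1L, j))
    }
    if (j < i + min_span) return(invisible())
    for (k in (i + min_span):j) {
      right <- if (k < j) W[k + 1L, j] else 0
      if (is.finite(V[i, k]) && abs(V[i, k] + right - target) < 1e-9) {
        trace_v(i, k)
        if (k < j) trace_w(k + 1L, j)
        return(invisible())
      }
    }
    invisible()
  }
  trace_v <- function(i, j) {
    structure_chars[i] <<- "("
    structure_chars[j] <<- ")"
    inner <- if (j - i >= min_span + 2L) W1[i + 1L, j - 1L] else INF
    if (is.finite(inner) && inner < .LOOP_PENALTY) trace_w1(i + 1L, j - 1L)
    invisible()
  }

  mfe <- if (n >= 2) min(0, W1[1L, n]) else 0
  if (mfe < 0) trace_w1(1L, n)
  list(structure = paste(structure_chars, collapse = ""), mfe = mfe)
}

#' Hybridization energy of a miRNA/target duplex
#'
#' Minimum hybridization energy over all ungapped alignments, optionally with
#' a single 1-nt bulge on either strand, of the miRNA (read 3'->5') against a
#' target site region (read 5'->3'). Aligned complementary positions
#' contribute the shared pair constants (GC -3.0, AU -2.0, GU -1.0 kcal/mol)
#' when they sit in a stacked helix of at least two consecutive pairs
#' (isolated single pairs do not stack and score 0); a duplex with at least
#' one helix pays a single +0.5 kcal/mol initiation penalty. With no stacked
#' complementary run in any alignment the energy is 0.
#'
#' @param mirna miRNA sequence, 5'->3' (`ACGU`).
#' @param site_region Target region sequence, 5'->3'; typically the miRNA
#'   length up to the miRNA length plus 10 nt.
#' @return Duplex energy in kcal/mol (`<= 0`).
#' @export
duplex_energy <- function(mirna, site_region) {
  m <- rev(.as_rna_chars(mirna)) # 3'->5' against site 5'->3'
  s <- .as_rna_chars(site_region)
  score_alignment <- function(a, b) {
    L <- min(length(a), length(b))
    if (L == 0L) return(0)
    e_pos <- pair_energy(a[seq_len(L)], b[seq_len(L)])
    runs <- rle(e_pos < 0)
    # only stacked runs (>= 2 consecutive pairs) contribute
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values & runs$lengths >= 2L
    e <- sum(unlist(lapply(which(keep), function(i)
      e_pos[starts[i]:ends[i]])))
    if (e < 0) e + .LOOP_PENALTY else 0
  }
  best <- 0
  # ungapped: all relative offsets
  for (off in -(length(m) - 1L):(length(s) - 1L)) {
    a <- if (off >= 0) m else m[(-off + 1L):length(m)]
    b <- if (off >= 0) s[(off + 1L):length(s)] else s
    best <- min(best, score_alignment(a, b))
  }
  # single 1-nt bulge on either strand, duplex anchored at each offset
  for (off in 0:(length(s) - 1L)) {
    b <- s[(off + 1L):length(s)]
    for (pos in seq_len(min(length(m), length(b)) - 1L)) {
      a_b <- m[-(pos + 1L)] # bulged base on the miRNA strand
      best <- min(best, score_alignment(a_b, b))
      if (length(b) > 1L) {
        b_b <- b[-(pos + 1L)] # bulged base on the target strand
        best <- min(best, score_alignment(m, b_b))
      }
    }
  }
  best
}
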
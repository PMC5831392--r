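# TPM normalisation, fold-changes and the Audic-Claverie exact test.

test_that("TPM follows the count / total * 1e6 identity", {
  cm <- count_matrix(matrix(c(5, 0, 4606500), ncol = 1,
                            dimnames = list(c("a", "b", "mir143"), "DU")),
                     c(DU = 27498891))
  tpm <- tpm_normalize(cm)
  expect_equal(tpm["a", "DU"], 5 / 27498891 * 1e6)
  expect_equal(tpm["b", "DU"], 0)
  # the most abundant miRNA of the published duodenum library
  expect_equal(tpm["mir143", "DU"], 167516, tolerance = 1e-5)

  cm2 <- count_matrix(matrix(5, 1, 1, dimnames = list("a", "L")),
                      c(L = 1e6))
  expect_equal(unname(tpm_normalize(cm2)[1, 1]), 5)
})

test_that("log2 fold-change handles zeros via the pseudocount", {
  expect_equal(log2_fold_change(40, 10, pseudocount = 0), 2)
  expect_equal(log2_fold_change(7, 7, pseudocount = 0), 0)
  expect_equal(log2_fold_change(0, 10, pseudocount = 0.01),
               log2(0.01 / 10.01))
})

test_that("ac_probability matches closed forms and normalises", {
  expect_equal(ac_probability(0, 0, 1e6, 1e6), 0.5)
  # hand-computed exact rational: C(7,5)/2^8 = 21/256
  expect_equal(ac_probability(5, 2, 1e6, 1e6), 21 / 256, tolerance = 1e-12)
  for (r in c(0.5, 1, 2)) {
    expect_equal(sum(ac_probability(0:2000, 10, 1e6, 1e6 * r)), 1,
                 tolerance = 1e-9)
  }
})

test_that("ac_probability equals the negative-binomial closed form", {
  # under the conditional Poisson model, y | x ~ NB(size = x+1,
  # prob = n1/(n1+n2)) - an independent route through R's C implementation
  for (r in c(1 / 3, 1 / 2, 1, 2, 3)) {
    n1 <- 2.4e6
    n2 <- n1 * r
    for (x in c(0, 3, 17)) {
      ys <- 0:60
      expect_equal(ac_probability(ys, x, n1, n2),
                   dnbinom(ys, size = x + 1, prob = n1 / (n1 + n2)),
                   tolerance = 1e-12)
    }
  }
})

test_that("ac_test tails behave as an exact conditional test", {
  expect_gte(ac_test(50, 50, 1e6, 1e6), 0.5)
  expect_lt(ac_test(100, 0, 1e6, 1e6), 1e-20)
  # tail duality: P(Y <= y | x; N1,N2) = P(X >= x+1 | y; N2,N1)
  n1 <- 1.2e6
  n2 <- 2.5e6
  for (xy in list(c(7, 19), c(0, 3), c(40, 22))) {
    lhs <- sum(ac_probability(0:xy[2], xy[1], n1, n2))
    rhs <- mirnaflow:::.ac_upper_tail(xy[2], xy[1] + 1, n2, n1)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  # exchange symmetry of the two-sided rule, up to the observed point mass
  for (xy in list(c(7, 19), c(200, 260), c(1000, 1150))) {
    d <- abs(ac_test(xy[1], xy[2], n1, n2) - ac_test(xy[2], xy[1], n2, n1))
    bound <- 2 * max(ac_probability(xy[2], xy[1], n1, n2),
                     ac_probability(xy[1], xy[2], n2, n1))
    expect_lte(d, bound + 1e-12)
  }
})

test_that("the upper tail is non-increasing in the observed count", {
  for (r in c(0.5, 2)) {
    ds <- vapply(0:120, function(y)
      mirnaflow:::.ac_upper_tail(30, y, 1e6, 1e6 * r), numeric(1))
    expect_true(all(diff(ds) <= 1e-12))
  }
})

test_that("Bonferroni never drops below raw p and shrinks calls as m grows", {
  set.seed(5)
  counts <- matrix(rpois(40, 100), ncol = 2,
                   dimnames = list(sprintf("m%02d", 1:20), c("A", "B")))
  counts[1, ] <- c(100, 420)
  cm <- count_matrix(counts, c(A = 1e5, B = 1e5))
  res <- call_differential(cm, c("A", "B"))
  expect_true(all(res$p_bonferroni >= res$p_raw - 1e-15))
  expect_true(all(res$p_bonferroni <= 1))
  # same counts embedded among many more tested rows: calls cannot grow
  big <- rbind(counts, matrix(rpois(360, 100), ncol = 2,
                              dimnames = list(sprintf("x%03d", 1:180),
                                              c("A", "B"))))
  cm_big <- count_matrix(big, c(A = 1e5, B = 1e5))
  res_big <- call_differential(cm_big, c("A", "B"))
  sig_small <- res$mirna_id[res$significant]
  sig_big <- res_big$mirna_id[res_big$significant & res_big$mirna_id %in%
                                rownames(counts)]
  expect_true(all(sig_big %in% sig_small))
})

test_that("identical libraries yield no differential calls", {
  counts <- matrix(rep(c(50, 200, 1000), 2), ncol = 2,
                   dimnames = list(c("a", "b", "c"), c("A", "B")))
  cm <- count_matrix(counts, c(A = 1e5, B = 1e5))
  res <- call_differential(cm, c("A", "B"))
  expect_identical(sum(res$significant), 0L)
})

test_that("a planted four-fold miRNA is called with the right direction", {
  scfg <- small_sim_config(seed = 21, n_known_mirnas = 30, de_fraction = 0.2,
                           de_fold = 4, mean_count = 200)
  sim <- simulate_counts(scfg)
  cm <- count_matrix(sim$counts, colSums(sim$counts))
  planted <- sim$planted_de
  up_du <- planted$mirna_id[planted$up_library == "DU"]
  res <- call_differential(cm, c("DU", "CE"))
  sig_up_a <- res$mirna_id[res$significant & res$direction == "up_in_a"]
  expect_true(all(up_du %in% sig_up_a))
  s <- summary(res)
  expect_identical(s$up_in_a + s$up_in_b, s$significant)
})

test_that("2^-ddCt relative expression follows the definition", {
  expect_equal(relative_expression_ddct(20, 20, 20, 20), 1)
  expect_equal(relative_expression_ddct(19, 20, 20, 20), 2)
  expect_equal(relative_expression_ddct(23.32, 20, 20, 20), 2^-3.32)
  expect_equal(relative_expression_ddct(23.32, 20, 20, 20), 0.1,
               tolerance = 0.01)
})
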
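pi_eq <- setNames(rep(1 / 61, 61), concertr:::CODONS61)

test_that("the GY94 rate matrix has the required structure", {
  q <- codon_Q_matrix(2.5, 0, pi_eq)
  type <- concertr:::.codon_tables$type
  # omega = 0 silences every nonsynonymous rate
  expect_true(all(q$Q[type %in% c(3L, 4L)] == 0))
  expect_true(any(q$Q[type %in% c(1L, 2L)] > 0))

  q2 <- codon_Q_matrix(3, 0.7, pi_eq)
  expect_equal(max(abs(rowSums(q2$Q))), 0, tolerance = 1e-12)
  # detailed balance (reversibility)
  flux <- q2$Q * pi_eq
  expect_equal(flux, t(flux), tolerance = 1e-12)
  # multi-nucleotide changes are forbidden
  expect_true(all(q2$Q[type == 0L & row(q2$Q) != col(q2$Q)] == 0))
})

test_that("the long-time transition distribution converges to the stationary frequencies", {
  sim <- quick_sim(TREE_3SP, n_codons = 120, seed = 1)
  pif <- codon_frequencies(sim$alignment, "F3x4")
  q <- codon_Q_matrix(2, 0.4, pif)
  e <- concertr:::eigen_reversible(q$Q, pif)
  P <- e$V %*% diag(exp(e$eval * 5000)) %*% e$Vinv
  for (i in c(1, 30, 61))
    expect_equal(unname(P[i, ]), unname(pif), tolerance = 1e-8)
})

test_that("codon frequency models are normalized and reflect composition", {
  sim <- quick_sim(TREE_3SP, n_codons = 150, seed = 2)
  for (mdl in c("F3x4", "F61", "equal")) {
    p <- codon_frequencies(sim$alignment, mdl)
    expect_length(p, 61L)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p > 0))
  }
})

test_that("pruning likelihood equals brute-force enumeration over ancestral states", {
  a <- toy_codon_aln()[1:3, ]
  tr <- ape::read.tree(text = "(s1:0.2,s2:0.3,s3:0.15);")
  pif <- codon_frequencies(a, "F3x4")
  # single class (M0)
  lnl <- site_mixture_lnL(a, tr, "M0", list(omega = 0.5), kappa = 2,
                          scale = 1, pi = pif)
  bf <- brute_force_codon_lnL(a, tr, 2, 0.5, 1, pif)
  expect_equal(lnl, bf, tolerance = 1e-8)
  # two-class mixture (M1a)
  lnl2 <- site_mixture_lnL(a, tr, "M1a", list(p0 = 0.6, omega0 = 0.2),
                           kappa = 2, scale = 1, pi = pif)
  bf2 <- brute_force_codon_lnL(a, tr, 2, c(0.2, 1), c(0.6, 0.4), pif)
  expect_equal(lnl2, bf2, tolerance = 1e-8)
})

test_that("four-taxon pruning likelihood matches enumeration over two internal nodes", {
  a <- toy_codon_aln()
  tr <- ape::unroot(ape::read.tree(
    text = "((s1:0.2,s2:0.3):0.1,(s3:0.15,s4:0.25):0.05);"))
  pif <- codon_frequencies(a, "F3x4")
  lnl <- site_mixture_lnL(a, tr, "M0", list(omega = 0.8), kappa = 1.5,
                          scale = 1, pi = pif)
  bf <- brute_force_codon_lnL(a, tr, 1.5, 0.8, 1, pif)
  expect_equal(lnl, bf, tolerance = 1e-8)
})

test_that("site independence: duplicating the alignment doubles the log-likelihood", {
  sim <- quick_sim(TREE_3SP, n_codons = 40, seed = 3)
  a <- sim$alignment
  tr <- neighbor_joining(distance_matrix(a, "F84"))
  par <- list(p0 = 0.7, omega0 = 0.3)
  l1 <- site_mixture_lnL(a, tr, "M1a", par, kappa = 2)
  l2 <- site_mixture_lnL(concat_alignments(a, a), tr, "M1a", par, kappa = 2)
  expect_equal(2 * l1, l2, tolerance = 1e-6)
})

test_that("likelihood is invariant to re-rooting under the reversible model", {
  sim <- quick_sim(TREE_3SP, n_codons = 40, seed = 4)
  a <- sim$alignment
  tr <- neighbor_joining(distance_matrix(a, "F84"))
  par <- list(omega = 0.5)
  l1 <- site_mixture_lnL(a, tr, "M0", par, kappa = 2)
  rot <- ape::root(tr, outgroup = "c_A", resolve.root = FALSE)
  l2 <- site_mixture_lnL(a, ape::unroot(rot), "M0", par, kappa = 2)
  expect_equal(l1, l2, tolerance = 1e-6)
})

test_that("beta discretization produces valid equal-probability class means", {
  for (pq in list(c(0.5, 1.5), c(2, 2), c(0.1, 0.12), c(8, 40))) {
    m <- concertr:::discrete_beta(pq[1], pq[2], 10)
    expect_length(m, 10L)
    expect_true(all(m > 0 & m < 1))
    expect_true(all(diff(m) >= 0))
    expect_equal(mean(m), pq[1] / sum(pq), tolerance = 0.05)
  }
})

test_that("M0 recovers the simulated omega", {
  sim <- quick_sim(TREE_4SP, n_codons = 500, rate = 1.2e-3,
                   omega = 0.2, props = 1, seed = 6)
  tr <- neighbor_joining(distance_matrix(sim$alignment, "F84"))
  fit <- fit_site_model(sim$alignment, tr, "M0")
  expect_true(fit$convergence)
  expect_gt(fit$par$omega, 0.15)
  expect_lt(fit$par$omega, 0.26)
  expect_gt(fit$kappa, 1.5)
  expect_lt(fit$kappa, 4.5)
})

test_that("an M8a fit keeps its positive-selection class omega fixed at 1", {
  sim <- quick_sim(TREE_3SP, n_codons = 60, seed = 7)
  tr <- neighbor_joining(distance_matrix(sim$alignment, "F84"))
  fit <- fit_site_model(sim$alignment, tr, "M8a")
  expect_equal(fit$classes$omega[length(fit$classes$omega)], 1)
  expect_equal(sum(fit$classes$w), 1, tolerance = 1e-9)
})

test_that("likelihood-ratio tests follow the nesting table and clamp at zero", {
  sim <- quick_sim(TREE_3SP, n_codons = 80, seed = 8)
  tr <- neighbor_joining(distance_matrix(sim$alignment, "F84"))
  f1 <- fit_site_model(sim$alignment, tr, "M1a")
  same <- lrt(f1, structure(
    modifyList(unclass(f1), list(model = "M2a")), class = "site_model_fit"))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  f7 <- fit_site_model(sim$alignment, tr, "M7")
  expect_error(lrt(f7, structure(modifyList(unclass(f1), list(model = "M2a")),
                                 class = "site_model_fit")),
               "nested")
  # boundary-corrected option for M8a vs M8
  f8a <- structure(modifyList(unclass(f7), list(model = "M8a")),
                   class = "site_model_fit")
  f8 <- structure(modifyList(unclass(f7),
                             list(model = "M8", lnL = f7$lnL + 2)),
                  class = "site_model_fit")
  res <- lrt(f8a, f8)
  expect_equal(res$df, 1L)
  expect_equal(res$p_value_boundary, 0.5 * pchisq(4, 1, lower.tail = FALSE))
})

test_that("empirical Bayes site posteriors are proper and reference labels skip gaps", {
  sim <- quick_sim(TREE_4SP, n_codons = 120,
                   omega = c(0.1, 0.6, 4), props = c(0.6, 0.3, 0.1), seed = 9)
  tr <- neighbor_joining(distance_matrix(sim$alignment, "F84"))
  f8 <- fit_site_model(sim$alignment, tr, "M8")
  tab <- positively_selected_sites(f8, sim$alignment, "a_A")
  expect_equal(nrow(tab), 120L)
  expect_true(all(tab$p_positive >= 0 & tab$p_positive <= 1))
  expect_match(tab$label[1L], "^1[A-Z]$")
  expect_error(positively_selected_sites(f8, sim$alignment, "nope"),
               "reference")

  # a model with no omega > 1 class yields an empty list
  f1 <- fit_site_model(sim$alignment, tr, "M1a")
  expect_equal(nrow(positively_selected_sites(f1, sim$alignment, "a_A")), 0L)
})

test_that("gapped reference rows are labeled by ungapped position", {
  prot <- alignment(c(r = "M-KL", s = "MAKL"), "protein")
  cds <- c(r = "ATGAAACTG", s = "ATGGCTAAGCTT")
  ca <- backtranslate_alignment(prot, cds)
  mp <- concertr:::translate_matrix(ca)["r", ]
  pos <- cumsum(mp != "-"); pos[mp == "-"] <- NA
  expect_equal(pos, c(1, NA, 2, 3), ignore_attr = TRUE)
})
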
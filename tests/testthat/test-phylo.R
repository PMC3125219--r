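test_that("F84 distance handles identical pairs and matches the reference implementation", {
  a <- alignment(c(x = "ACGTACGT", y = "ACGTACGT"), "dna")
  expect_equal(unname(f84_distance(a, "x", "y")), c(0, 0, 0))

  sim <- quick_sim(TREE_4SP, n_codons = 200, seed = 8)
  bin <- ape::as.DNAbin(strsplit(tolower(
    apply(unclass(sim$alignment), 1L, paste, collapse = "")), ""))
  Dref <- as.matrix(ape::dist.dna(bin, model = "F84"))
  ids <- rownames(sim$alignment)
  for (p in list(c(1, 2), c(1, 5), c(3, 8))) {
    d <- f84_distance(sim$alignment, ids[p[1]], ids[p[2]])["d"]
    # ape pools base frequencies across the alignment; this package
    # uses the pair's own frequencies, hence agreement only to ~1e-4
    expect_equal(unname(d), Dref[ids[p[1]], ids[p[2]]], tolerance = 1e-4)
  }
})

test_that("F84 reduces to the Jukes-Cantor form for balanced changes", {
  base <- strsplit(paste(rep("ACGT", 75), collapse = ""), "")[[1L]]
  y <- base
  # 10 transitions + 20 transversions in balanced pairs keeps base
  # frequencies equal and the 1:2 ts:tv ratio of the JC expectation
  ts_pos <- seq(1, 40, by = 4)                   # A -> G (10x)
  y[ts_pos] <- "G"
  tv1 <- seq(2, 40, by = 4)                      # C -> A (10x)
  y[tv1] <- "A"
  tv2 <- seq(43, 80, by = 4)                     # G -> C (10x)
  y[tv2] <- "C"
  a <- alignment(c(x = paste(base, collapse = ""),
                   y = paste(y, collapse = "")), "dna")
  fv <- f84_distance(a, "x", "y")
  p <- fv[["s"]] + fv[["v"]]
  jc <- -3 / 4 * log(1 - 4 * p / 3)
  expect_equal(fv[["d"]], jc, tolerance = 0.01)
})

test_that("saturated pairs are flagged as infinite, not clamped", {
  a <- alignment(c(x = paste(rep("AC", 30), collapse = ""),
                   y = paste(rep("GT", 30), collapse = "")), "dna")
  expect_warning(fv <- f84_distance(a, "x", "y"), "saturated")
  expect_true(is.infinite(fv[["d"]]))
})

test_that("pairwise ML distance agrees with the JC closed form when kappa = 1", {
  base <- strsplit(paste(rep("ACGT", 75), collapse = ""), "")[[1L]]
  y <- base
  # composition-preserving swaps: 4x A<->C and 4x G<->T
  sw <- function(v, i, j) { t <- v[i]; v[i] <- v[j]; v[j] <- t; v }
  for (k in 0:3) y <- sw(y, 1 + 8 * k, 2 + 8 * k)   # A<->C
  for (k in 0:3) y <- sw(y, 35 + 8 * k, 36 + 8 * k) # G<->T
  a <- alignment(c(x = paste(base, collapse = ""),
                   y = paste(y, collapse = "")), "dna")
  phat <- 16 / 300
  jc <- -3 / 4 * log(1 - 4 * phat / 3)
  expect_equal(ml_pair_distance(a, "x", "y", kappa = 1), jc,
               tolerance = 1e-6)
  same <- alignment(c(x = "ACGTACGT", y = "ACGTACGT"), "dna")
  expect_equal(ml_pair_distance(same, "x", "y"), 0)
})

test_that("pairwise ML distance recovers the simulated divergence", {
  # simulate a pair at true distance 0.3 under HKY85 kappa = 4
  set.seed(2)
  pi <- c(0.3, 0.2, 0.2, 0.3)
  hk <- concertr:::hky_Q(4, pi)
  e <- concertr:::eigen_reversible(hk$Q, pi)
  P <- e$V %*% diag(exp(e$eval * 0.3)) %*% e$Vinv
  n <- 10000L
  xs <- sample.int(4, n, TRUE, prob = pi)
  ys <- vapply(xs, function(x) sample.int(4, 1, prob = P[x, ]), 0L)
  nuc <- c("A", "C", "G", "T")
  a <- alignment(c(x = paste(nuc[xs], collapse = ""),
                   y = paste(nuc[ys], collapse = "")), "dna")
  dhat <- ml_pair_distance(a, "x", "y")
  expect_gt(dhat, 0.27); expect_lt(dhat, 0.33)
})

test_that("neighbor joining is exact on an additive 4-taxon matrix", {
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):0);")
  D <- cophenetic(tr)
  nj <- neighbor_joining(D)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj)), 0)
  expect_equal(cophenetic(nj)[rownames(D), colnames(D)], D,
               tolerance = 1e-10)
})

test_that("neighbor joining handles 2 taxa, rejects asymmetry, excludes saturated taxa", {
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr2 <- neighbor_joining(D2)
  expect_equal(unname(cophenetic(tr2)["a", "b"]), 0.4)

  Dbad <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(Dbad), "symmetric")

  D <- cophenetic(ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):0);"))
  D["a", "b"] <- D["b", "a"] <- Inf
  expect_warning(tr <- neighbor_joining(D), "saturated")
  expect_lt(length(tr$tip.label), 4L)
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
    D <- cophenetic(tr)
    nj <- neighbor_joining(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj)), 0)
  }
})

test_that("phangorn-backed tree likelihood matches an independent pruning engine", {
  # fixed tree + JC: phangorn's pml vs this package's own pruning code
  sim <- quick_sim(TREE_3SP, n_codons = 30, seed = 17)
  a <- sim$alignment
  tr <- ape::unroot(ape::read.tree(
    text = "((a_A:0.1,b_A:0.2):0.05,(a_B:0.15,b_B:0.1):0.1,(c_A:0.3,c_B:0.2):0.02);"))
  pd <- concertr:::aln_to_phyDat(a)
  fitp <- phangorn::pml(tr, pd)  # JC69, single rate
  Q <- matrix(1 / 4, 4, 4); diag(Q) <- -3 / 4
  pi4 <- rep(1 / 4, 4)
  e <- concertr:::eigen_reversible(Q / (3 / 4), pi4)
  eg <- list(V = array(e$V, c(4, 4, 1)), Vi = array(e$Vinv, c(4, 4, 1)),
             ev = matrix(e$eval, 4, 1))
  pat <- concertr:::nuc_patterns(a, tr$tip.label)
  post <- ape::reorder.phylo(tr, "postorder")
  lm <- concertr:::prune_loglik_cpp(post$edge, post$edge.length,
                                    pat$states, eg$V, eg$Vi, eg$ev, pi4)
  own <- sum(lm[1, ] * pat$weights)
  expect_equal(own, as.numeric(fitp$logLik), tolerance = 1e-6)
})

test_that("duplicating the alignment doubles the tree log-likelihood", {
  sim <- quick_sim(TREE_3SP, n_codons = 40, seed = 19)
  a <- sim$alignment
  a2 <- concat_alignments(a, a)
  tr <- neighbor_joining(distance_matrix(a, "F84"))
  f1 <- phangorn::pml(tr, concertr:::aln_to_phyDat(a))
  f2 <- phangorn::pml(tr, concertr:::aln_to_phyDat(a2))
  expect_equal(2 * as.numeric(f1$logLik), as.numeric(f2$logLik),
               tolerance = 1e-8)
})

test_that("ML branch lengths support the two-round protocol and recover the gamma shape", {
  set.seed(5)
  tr <- ape::rtree(6, br = function(k) runif(k, 0.05, 0.4))
  rates <- concertr:::discrete_gamma_rates(0.5, 4)
  pd <- NULL
  chunks <- lapply(rates, function(r) {
    tr2 <- tr; tr2$edge.length <- tr$edge.length * r
    as.character(phangorn::simSeq(tr2, l = 1250))
  })
  m <- toupper(do.call(cbind, chunks))
  a <- alignment(m, "dna")
  fit <- ml_branch_lengths(ape::unroot(tr), a, fixed = list(p_inv = 0))
  expect_gt(fit$alpha, 0.35); expect_lt(fit$alpha, 0.8)
  expect_true(is.finite(fit$lnL))
  # round 2: fixed parameters
  fit2 <- ml_branch_lengths(ape::unroot(tr), a,
                            fixed = list(alpha = fit$alpha, p_inv = 0,
                                         kappa = fit$kappa))
  expect_equal(fit2$alpha, fit$alpha)
  expect_error(ml_branch_lengths(tr, a[, 0]), "zero-length|equal length|only of gaps")
})

test_that("bootstrap support is total for two well-separated identical clades", {
  a <- alignment(c(w = paste(rep("A", 60), collapse = ""),
                   x = paste(rep("A", 60), collapse = ""),
                   y = paste(rep("T", 60), collapse = ""),
                   z = paste(rep("T", 60), collapse = "")), "dna")
  tree <- neighbor_joining(distance_matrix(a, "raw"))
  bs <- bootstrap_support(a, tree,
                          tree_builder = function(x)
                            neighbor_joining(distance_matrix(x, "raw")),
                          replicates = 100L, seed = 2)
  # the single internal split is present in every replicate
  expect_true(any(bs$support == 100L))
  expect_error(bootstrap_support(a, tree, replicates = 50L), "100")
})

test_that("bootstrap support grows with alignment length for a short internal branch", {
  tr <- ape::read.tree(
    text = "(((a:0.1,b:0.1):0.02,(c:0.1,d:0.1):0.02):0.05,(e:0.15,f:0.15):0.05);")
  sup_at <- function(len, seed) {
    set.seed(seed)
    m <- toupper(as.character(phangorn::simSeq(tr, l = len)))
    a <- alignment(m, "dna")
    point <- neighbor_joining(distance_matrix(a, "F84"))
    bs <- bootstrap_support(a, point, replicates = 100L, seed = seed)
    mean(bs$support)
  }
  expect_gt(sup_at(5000L, 3), sup_at(300L, 3))
})

test_that("quartet likelihood mapping separates resolved from star-like signal", {
  # strongly resolved quartet
  sim <- quick_sim(TREE_4SP, n_codons = 250, seed = 23)
  res <- likelihood_mapping(sim$alignment[c("a_A", "b_A", "c_A", "d_A"), ],
                            n_quartets = 1, seed = 1)
  expect_equal(res$resolved, 1)
  expect_equal(sum(res$regions), 1)

  # star topology: four lineages radiating from one point
  star <- ape::read.tree(text = "(a:0.3,b:0.3,c:0.3,d:0.3);")
  set.seed(9)
  m <- toupper(as.character(phangorn::simSeq(star, l = 120)))
  astar <- alignment(m, "dna")
  res2 <- likelihood_mapping(astar, n_quartets = 1, seed = 1)
  expect_lt(res2$resolved, 1)
  expect_error(likelihood_mapping(astar[1:3, ]), ">= 4")
})
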
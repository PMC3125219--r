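test_that("polymorphic sites are enumerated excluding gapped and N columns", {
  a <- alignment(c(x = "AAAA", y = "AATA"), "dna")
  expect_equal(as.integer(find_polymorphic_sites(a)), 3L)

  same <- alignment(c(x = "ACGT", y = "ACGT"), "dna")
  expect_length(find_polymorphic_sites(same), 0L)

  gp <- alignment(c(x = "A-GTN", y = "ACGAN"), "dna")
  expect_equal(as.integer(find_polymorphic_sites(gp)), 4L)

  one <- alignment(c(x = "ACGT"), "dna")
  expect_error(find_polymorphic_sites(one), ">= 2 sequences")
})

test_that("polymorphism count bounds per-pair total differences", {
  sim <- quick_sim(TREE_4SP, n_codons = 200, seed = 5)
  a <- sim$alignment
  poly <- find_polymorphic_sites(a)
  ids <- rownames(a)
  prs <- t(combn(ids, 2L))
  difs <- apply(prs, 1L, function(p)
    concertr:::pair_mismatch_stats(a, p[1L], p[2L])$tot_difs)
  expect_true(length(poly) >= max(difs))
})

test_that("longest-run tail probability matches exhaustive enumeration", {
  # tiny instance: enumerate all arrangements of M matches / D mismatches
  exhaustive <- function(L, M, D) {
    pos <- combn(M + D, D)
    hits <- 0L
    for (j in seq_len(ncol(pos))) {
      v <- rep(TRUE, M + D); v[pos[, j]] <- FALSE
      r <- rle(v); mx <- max(c(0L, r$lengths[r$values]))
      if (mx >= L) hits <- hits + 1L
    }
    hits / ncol(pos)
  }
  for (cc in list(c(3, 8, 4), c(4, 8, 4), c(5, 9, 3), c(2, 6, 6))) {
    expect_equal(exp(concertr:::run_tail_logp(cc[1], cc[2], cc[3])),
                 exhaustive(cc[1], cc[2], cc[3]), tolerance = 1e-10,
                 info = paste(cc, collapse = ","))
  }
})

test_that("tail probability is calibrated against Monte Carlo in the moderate regime", {
  set.seed(42)
  M <- 300L; D <- 60L
  maxrun <- function(v) { r <- rle(v); max(c(0L, r$lengths[r$values])) }
  sims <- replicate(2000, maxrun(sample(c(rep(TRUE, M), rep(FALSE, D)))))
  for (L in c(20L, 25L, 30L)) {
    mc <- mean(sims >= L)
    an <- exp(concertr:::run_tail_logp(L, M, D))
    expect_lt(abs(mc - an), 0.03)
  }
})

test_that("tail probability decreases in run length and increases with matches", {
  lp <- vapply(5:40, function(L) concertr:::run_tail_logp(L, 200, 100), 0)
  expect_true(all(diff(lp) <= 1e-12))
})

test_that("fragments degenerate as the spec's edge cases require", {
  # pair differing at every polymorphic site -> no fragment
  a <- alignment(c(x = "AAAAAAAA", y = "TTTTTTTT"), "dna")
  fr <- global_inner_fragments(a, "x", "y")
  expect_equal(nrow(fr), 0L)
  expect_equal(attr(fr, "status"), "no_fragment")

  # pair identical at all polymorphic sites -> uninformative
  b <- alignment(c(x = "ACGTACGT", y = "ACGTACGT", z = "ACGTTTTT"), "dna")
  frb <- global_inner_fragments(b, "x", "y")
  expect_equal(nrow(frb), 0L)
  expect_equal(attr(frb, "status"), "uninformative")
})

test_that("a copied tract is recovered as the dominant fragment", {
  ev <- data.frame(species = "a", donor_copy = "A", time = 0,
                   begin_codon = 101L, end_codon = 250L)
  sim <- quick_sim(TREE_4SP, n_codons = 400, events = ev, seed = 9)
  fr <- global_inner_fragments(sim$alignment, "a_A", "a_B")
  expect_gt(nrow(fr), 0L)
  expect_gt(interval_jaccard(fr$begin[1L], fr$end[1L], 301L, 750L), 0.8)
  # the tract at time 0 leaves the paralogues identical inside it
  expect_identical(unclass(sim$alignment)["a_A", 301:750],
                   unclass(sim$alignment)["a_B", 301:750])
})

test_that("fragment detection is invariant to permuting non-polymorphic columns", {
  sim <- quick_sim(TREE_4SP, n_codons = 150, seed = 13)
  a <- sim$alignment
  poly <- as.integer(find_polymorphic_sites(a))
  nonpoly <- setdiff(seq_len(ncol(a)), poly)
  set.seed(1)
  m <- unclass(a)
  m[, nonpoly] <- m[, sample(nonpoly)]
  b <- alignment(m, "dna")
  fa <- global_inner_fragments(a, "a_A", "b_A")
  fb <- global_inner_fragments(b, "a_A", "b_A")
  expect_equal(fa$begin, fb$begin)
  expect_equal(fa$end, fb$end)
  expect_equal(fa$score, fb$score)
})

test_that("permutation p-value is extreme for engineered conversion and demands R >= 100", {
  # matches clustered in one block of 40, mismatches scattered elsewhere
  set.seed(3)
  n <- 90
  x <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  xv <- strsplit(x, "")[[1L]]
  yv <- xv
  flip <- c("A" = "C", "C" = "A", "G" = "T", "T" = "G")
  yv[c(1:25, 66:90)] <- flip[yv[c(1:25, 66:90)]]
  zv <- flip[xv]  # third row makes every column polymorphic
  a <- alignment(c(x = paste(xv, collapse = ""),
                   y = paste(yv, collapse = ""),
                   z = paste(zv, collapse = "")), "dna")
  p <- permutation_pvalue(a, "x", "y", R = 400, seed = 5)
  expect_lt(p, 0.02)
  expect_error(permutation_pvalue(a, "x", "y", R = 50), ">= 100")
  # deterministic given seed
  expect_equal(p, permutation_pvalue(a, "x", "y", R = 400, seed = 5))
})

test_that("analytic and permutation p-values agree in rank over synthetic instances", {
  set.seed(11)
  stats <- t(sapply(1:50, function(i) {
    M <- sample(40:120, 1); D <- sample(10:60, 1)
    v <- sample(c(rep(TRUE, M), rep(FALSE, D)))
    r <- rle(v); L <- max(c(2L, r$lengths[r$values]))
    lp <- concertr:::run_tail_logp(L, M, D)
    # permutation oracle on the same statistic
    hits <- sum(replicate(300, {
      vv <- sample(v); rr <- rle(vv)
      max(c(0L, rr$lengths[rr$values])) >= L
    }))
    c(analytic = lp, sim = (1 + hits) / 301)
  }))
  rho <- cor(stats[, "analytic"], log(stats[, "sim"]), method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("group scans report Bonferroni-corrected p-values and region tables", {
  ev <- data.frame(species = "a", donor_copy = "A", time = 0.2,
                   begin_codon = 134L, end_codon = 200L)
  sim <- quick_sim(TREE_4SP, n_codons = 200, events = ev, seed = 21)
  fr <- scan_gene_conversion(sim$alignment, permutations = 200, seed = 2)
  expect_s3_class(fr, "conversion_fragments")
  expect_true(all(fr$bcka_p > 0 & fr$bcka_p <= 1))
  expect_true(all(fr$n_dif <= fr$tot_difs))
  top <- fr[1L, ]
  expect_setequal(c(top$idA, top$idB), c("a_A", "a_B"))
  expect_false(is.na(top$sim_p))

  regions <- conversion_regions(top$begin, top$end, ncol(sim$alignment))
  expect_s3_class(regions, "region_spec")
  expect_equal(sum(regions$converted), 1L)
  expect_equal(regions$start[1L], 1L)
  expect_equal(regions$end[nrow(regions)], ncol(sim$alignment))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_fragments_tsv(fr, f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(fr))
})

test_that("degenerate pairs raise the documented errors", {
  frag <- data.frame(n_match = 5, score = 5)
  expect_error(bcka_pvalue(frag, 0, 0), "degenerate")
})

test_that("penalized scoring recovers older tracts that contain internal mismatches", {
  ev <- data.frame(species = "a", donor_copy = "A", time = 8,
                   begin_codon = 201L, end_codon = 400L)
  sim <- quick_sim(TREE_4SP, n_codons = 600, events = ev, seed = 31)
  fr <- global_inner_fragments(sim$alignment, "a_A", "a_B",
                               mismatch_penalty = "auto")
  expect_gt(interval_jaccard(fr$begin[1L], fr$end[1L], 601L, 1200L), 0.8)
  expect_gte(fr$n_dif[1L], 0L)
})
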
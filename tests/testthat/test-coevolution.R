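test_that("site substitution vectors follow the scoring definition", {
  # two-state column with equal-diagonal residues and equal pair times:
  # exactly two distinct theta values
  b80 <- concertr:::blosum80
  a <- alignment(c(s1 = "RRAA", s2 = "RRAA", s3 = "NRAA", s4 = "NRAA"),
                 "protein")
  expect_equal(b80["R", "R"], b80["N", "N"])  # chosen for equal diagonal
  tm <- matrix(1, 4, 4)
  v <- site_substitution_vector(a, 1, times = tm)
  expect_length(v, 6L)
  expect_equal(length(unique(round(v + mean(v), 9))), 2L)
  expect_equal(mean(v), 0, tolerance = 1e-12)

  # invariant column -> uninformative
  expect_message(v2 <- site_substitution_vector(a, 2, times = tm),
                 "uninformative")
  expect_null(v2)

  # doubling the time proxies halves every (uncentered) score
  v1 <- site_substitution_vector(a, 1, times = tm)
  v2x <- site_substitution_vector(a, 1, times = 2 * tm)
  expect_equal(v1, 2 * v2x, ignore_attr = TRUE)
})

test_that("a constant alignment yields no co-evolution output", {
  a <- alignment(c(s1 = "MKLV", s2 = "MKLV", s3 = "MKLV", s4 = "MKLV"),
                 "protein")
  cv <- coevolution_scan(a, n_samplings = 500, seed = 1)
  expect_equal(nrow(cv), 0L)
})

test_that("engineered coupled sites are detected with high correlation", {
  pairs <- data.frame(siteA = 20L, siteB = 60L, coupling = 1.0,
                      residues = "KRDE", rate_boost = 3)
  sim <- quick_sim(TREE_12SP, dup = 130, n_codons = 150, rate = 3e-3,
                   omega = c(0.3, 1), props = c(0.6, 0.4),
                   pairs = pairs, seed = 5)
  prot <- translate_alignment(sim$alignment)
  protA <- prot[paste0(letters[1:12], "_A"), ]
  cv <- coevolution_scan(protA, n_samplings = 5000, alpha = 0.001,
                         seed = 2)
  hit <- cv[(cv$siteA == 20 & cv$siteB == 60) |
              (cv$siteA == 60 & cv$siteB == 20), ]
  expect_equal(nrow(hit), 1L)
  expect_gt(hit$r, 0.8)
  expect_lt(hit$p, 0.001)
})

test_that("scan output is independent of site order and symmetric in r", {
  pairs <- data.frame(siteA = 10L, siteB = 40L, coupling = 1.0,
                      residues = "KRDE", rate_boost = 3)
  sim <- quick_sim(TREE_12SP, dup = 130, n_codons = 80, rate = 3e-3,
                   pairs = pairs, seed = 6)
  prot <- translate_alignment(sim$alignment)[paste0(letters[1:12], "_A"), ]
  cv1 <- coevolution_scan(prot, n_samplings = 3000, seed = 3)
  rev_cols <- prot[, rev(seq_len(ncol(prot)))]
  cv2 <- coevolution_scan(rev_cols, n_samplings = 3000, seed = 3)
  key1 <- sort(paste(pmin(cv1$siteA, cv1$siteB),
                     pmax(cv1$siteA, cv1$siteB)))
  n <- ncol(prot)
  key2 <- sort(paste(pmin(n + 1 - cv2$siteA, n + 1 - cv2$siteB),
                     pmax(n + 1 - cv2$siteA, n + 1 - cv2$siteB)))
  expect_identical(key1, key2)
  expect_equal(sort(cv1$r), sort(cv2$r), tolerance = 1e-12)
})

test_that("inter-molecular mode pairs taxa across two alignments", {
  pairs <- data.frame(siteA = c(15L, 45L), siteB = c(30L, 70L),
                      coupling = 1.0, residues = "KRDE", rate_boost = 3)
  sim <- quick_sim(TREE_12SP, dup = 130, n_codons = 100, rate = 3e-3,
                   pairs = pairs, seed = 7)
  prot <- translate_alignment(sim$alignment)
  alnA <- prot[paste0(letters[1:12], "_A"), ]
  alnB <- prot[paste0(letters[1:12], "_B"), ]
  pm <- data.frame(idA = rownames(alnA), idB = rownames(alnB))
  cv <- coevolution_scan(alnA, alnB, pair_map = pm, n_samplings = 5000,
                         alpha = 0.001, seed = 4)
  expect_true(all(cv$mode == "inter"))
  # the coupled sites evolve concertedly in both paralogues, so the
  # cross-protein scan finds at least one of the injected positions
  expect_gt(nrow(cv), 0L)
  expect_error(coevolution_scan(alnA, alnB, pair_map = NULL), "pair_map")
})

test_that("compartment filtering labels pairs and tabulates combinations", {
  ann <- compartment_annotation(
    protein = rep("TLRX", 3),
    compartment = c("extracellular", "transmembrane", "cytoplasmic"),
    start = c(1, 51, 61), end = c(50, 60, 120),
    domain = c("LRR", "TM", "TIR"))
  pairs <- data.frame(siteA = c(5L, 55L), siteB = c(20L, 70L),
                      posA = c(5L, 55L), posB = c(20L, 70L),
                      labelA = c("5A", "55L"), labelB = c("20V", "70K"),
                      r = c(0.9, 0.8), p = c(1e-4, 5e-4),
                      mode = "intra", group = c(1L, 2L))
  out <- compartment_filter(pairs, ann, "TLRX")
  expect_equal(out$pairs$compartmentA, c("extracellular", "transmembrane"))
  expect_equal(out$pairs$compartmentB, c("extracellular", "cytoplasmic"))
  tm_row <- out$summary[out$summary$compartmentA == "transmembrane" &
                          out$summary$compartmentB == "cytoplasmic", ]
  expect_equal(tm_row$Freq, 1L)
  # unannotated site -> unknown with a warning
  pairs2 <- pairs; pairs2$posB[1L] <- 999L
  expect_warning(out2 <- compartment_filter(pairs2, ann, "TLRX"),
                 "unknown")
  expect_equal(out2$pairs$compartmentB[1L], "unknown")
  expect_error(compartment_annotation("P", c("extracellular", "cytoplasmic"),
                                      c(1, 40), c(50, 80)),
               "overlap")
})

test_that("network export writes GraphML and SIF with residue nodes and r-weighted edges", {
  pairs <- data.frame(siteA = c(1L, 1L, 1L), siteB = c(2L, 3L, 4L),
                      posA = 1L, posB = c(2L, 3L, 4L),
                      labelA = "1K", labelB = c("2R", "3D", "4E"),
                      r = c(0.9, 0.85, 0.8), p = 1e-4, mode = "intra",
                      group = 1L)
  g <- withr::local_tempfile(fileext = ".graphml")
  s <- withr::local_tempfile(fileext = ".sif")
  net <- export_network(pairs, graphml = g, sif = s, proteinA = "TLR1")
  # a hub of degree 3: 4 nodes, 3 edges
  expect_length(net$nodes, 4L)
  expect_equal(nrow(net$edges), 3L)
  gl <- readLines(g)
  expect_true(any(grepl("graphml", gl)))
  expect_equal(sum(grepl("<edge ", gl)), 3L)
  expect_equal(sum(grepl("<node ", gl)), 4L)
  expect_equal(length(readLines(s)), 3L)
  one <- export_network(pairs[1L, ], proteinA = "TLR1")
  expect_length(one$nodes, 2L)
  expect_error(export_network(pairs[0L, ]), "no pairs")
})
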
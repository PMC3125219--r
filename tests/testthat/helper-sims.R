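# Shared fixtures: small species trees (branch lengths in My) and
# simulation shortcuts used across the suite.

TREE_3SP <- "((a:40,b:40):40,c:80);"                      # 6-tip gene tree
TREE_4SP <- "((a:40,b:40):40,(c:60,d:60):20);"            # 8-tip gene tree
TREE_6SP <- "(((a:20,b:20):20,(c:30,d:30):10):20,(e:50,f:50):10);"
TREE_12SP <- paste0("(((((a:20,b:20):20,(c:30,d:30):10):20,(e:50,f:50):10):40,",
                    "(((g:25,h:25):15,i:40):30,(j:45,k:45):25):30):20,l:120);")

quick_sim <- function(tree = TREE_4SP, dup = 150, n_codons = 300,
                      rate = 1.5e-3, omega = c(0.2, 1), props = c(0.7, 0.3),
                      events = NULL, pairs = NULL, seed = 1) {
  simulate_gene_family(sim_config(
    tree, duplication_time = dup, n_codons = n_codons,
    mutation_rate = rate, omega_classes = omega, omega_props = props,
    conversion_events = events, coevolving_pairs = pairs, seed = seed))
}

# tiny in-frame codon alignment (no stops), 4 sequences x 5 codons
toy_codon_aln <- function() {
  codon_alignment(alignment(c(
    s1 = "ATGAAATTTGGGCCC",
    s2 = "ATGAAGTTTGGACCC",
    s3 = "ATGAAATTCGGGCCA",
    s4 = "ATAAAATTTGGGCCC"), "dna"))
}

# jaccard overlap of two 1-based inclusive intervals
interval_jaccard <- function(b1, e1, b2, e2) {
  inter <- max(0, min(e1, e2) - max(b1, b2) + 1)
  inter / (max(e1, e2) - min(b1, b2) + 1)
}

# brute-force mixture log-likelihood for <= 4 taxa on an unrooted
# 3-leaf star or 4-leaf tree, by enumerating internal-node codon states
brute_force_codon_lnL <- function(a, tree, kappa, omegas, weights, pi) {
  e_of <- function(om) {
    q <- codon_Q_matrix(kappa, om, pi)
    concertr:::eigen_reversible(q$Q, pi)
  }
  rates <- vapply(omegas, function(om) codon_Q_matrix(kappa, om, pi)$rate, 0)
  mean_rate <- sum(weights * rates)
  tr <- ape::reorder.phylo(tree, "postorder")
  cs <- concertr:::codon_strings(a)
  idx <- matrix(match(cs, concertr:::CODONS61), nrow = nrow(cs))
  rownames(idx) <- rownames(cs)
  idx <- idx[tr$tip.label, , drop = FALSE]
  ntip <- nrow(idx)
  lnl <- 0
  for (s in seq_len(ncol(idx))) {
    site_l <- 0
    for (k in seq_along(omegas)) {
      e <- e_of(omegas[k])
      P <- function(t) {
        M <- e$V %*% diag(exp(e$eval * t / mean_rate)) %*% e$Vinv
        pmax(M, 0)
      }
      Ps <- lapply(seq_len(nrow(tr$edge)), function(i) P(tr$edge.length[i]))
      if (ntip == 3L) {
        tot <- 0
        for (x in 1:61) {
          pr <- pi[x]
          for (ei in seq_len(nrow(tr$edge)))
            pr <- pr * Ps[[ei]][x, idx[tr$edge[ei, 2L], s]]
          tot <- tot + pr
        }
      } else {
        ## unrooted 4-taxon: two internal nodes
        in1 <- ntip + 1L; in2 <- ntip + 2L
        tot <- 0
        for (x in 1:61) for (y in 1:61) {
          pr <- pi[x]
          for (ei in seq_len(nrow(tr$edge))) {
            par <- tr$edge[ei, 1L]; ch <- tr$edge[ei, 2L]
            from <- if (par == in1) x else y
            to <- if (ch <= ntip) idx[ch, s] else (if (ch == in1) x else y)
            pr <- pr * Ps[[ei]][from, to]
          }
          tot <- tot + pr
        }
      }
      site_l <- site_l + weights[k] * tot
    }
    lnl <- lnl + log(unname(site_l))
  }
  lnl
}
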
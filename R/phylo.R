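## Distances (F84 closed form, HKY/JTT maximum likelihood), neighbor
## joining, ML branch lengths with invariant sites + discrete gamma
## (via phangorn's pruning engine), nonparametric bootstrap and quartet
## likelihood mapping.

#' F84 pairwise distance
#'
#' Closed-form F84 distance with empirical base frequencies of the pair,
#' together with the observed per-site transition (`s`) and transversion
#' (`v`) proportions over gap-free shared columns. Saturated pairs (log
#' domain violated) are returned as `Inf` with a warning.
#'
#' @param a DNA `aln`.
#' @param idA,idB row ids.
#' @return named numeric vector `c(d, s, v)`.
#' @export
f84_distance <- function(a, idA, idB) {
  m <- unclass(a)
  x <- m[idA, ]; y <- m[idB, ]
  keep <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  if (!any(keep)) stop("no comparable columns", call. = FALSE)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  ts_pair <- function(a1, a2) (a1 %in% c("A", "G") & a2 %in% c("A", "G")) |
                              (a1 %in% c("C", "T") & a2 %in% c("C", "T"))
  dif <- x != y
  P <- sum(dif & ts_pair(x, y)) / n
  Q <- sum(dif & !ts_pair(x, y)) / n
  f <- table(factor(c(x, y), levels = c("A", "C", "G", "T"))) / (2 * n)
  piA <- f[["A"]]; piC <- f[["C"]]; piG <- f[["G"]]; piT <- f[["T"]]
  piR <- piA + piG; piY <- piC + piT
  A <- piC * piT / piY + piA * piG / piR
  B <- piC * piT + piA * piG
  C <- piR * piY
  t1 <- 1 - P / (2 * A) - (A - B) * Q / (2 * A * C)
  t2 <- 1 - Q / (2 * C)
  if (t1 <= 0 || t2 <= 0) {
    warning(sprintf("saturated pair %s:%s, F84 distance undefined",
                    idA, idB))
    return(c(d = Inf, s = P, v = Q))
  }
  d <- -2 * A * log(t1) + 2 * (A - B - C) * log(t2)
  c(d = d, s = P, v = Q)
}

## 4-state HKY85 rate matrix and its spectral decomposition
hky_Q <- function(kappa, pi) {
  ## state order A C G T
  Q <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ts <- (i %in% c(1, 3) && j %in% c(1, 3)) ||
          (i %in% c(2, 4) && j %in% c(2, 4))
    Q[i, j] <- pi[j] * if (ts) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  list(Q = Q / rate, rate = rate)
}

#' Maximum-likelihood pairwise distance
#'
#' For DNA, the two-sequence likelihood under HKY85 (empirical base
#' frequencies of the pair; `kappa` estimated jointly unless given) is
#' maximized over the distance. For proteins, the ML distance under the
#' JTT model is delegated to phangorn's pairwise ML machinery.
#'
#' @param a an `aln`.
#' @param idA,idB row ids.
#' @param kappa fixed transition/transversion ratio, or `NULL` to
#'   estimate (DNA only).
#' @return distance in substitutions/site.
#' @export
ml_pair_distance <- function(a, idA, idB, kappa = NULL) {
  m <- unclass(a)
  if (attr(a, "moltype") == "protein") {
    pd <- aln_to_phyDat(a[c(idA, idB), , drop = FALSE])
    D <- phangorn::dist.ml(pd, model = "JTT")
    return(as.matrix(D)[idA, idB])
  }
  x <- m[idA, ]; y <- m[idB, ]
  keep <- x %in% c("A","C","G","T") & y %in% c("A","C","G","T")
  if (!any(keep)) stop("no comparable columns", call. = FALSE)
  x <- x[keep]; y <- y[keep]
  if (all(x == y)) return(0)
  f <- as.numeric(table(factor(c(x, y), levels = c("A","C","G","T")))) /
    (2 * length(x))
  f <- pmax(f, 1e-6); f <- f / sum(f)
  cnt <- table(factor(x, levels = c("A","C","G","T")),
               factor(y, levels = c("A","C","G","T")))
  negll <- function(d, k) {
    hk <- hky_Q(k, f)
    e <- eigen_reversible(hk$Q, f)
    P <- e$V %*% diag(exp(e$eval * d)) %*% e$Vinv
    P[P < 1e-12] <- 1e-12
    L <- log(f * P)  # pi_i * P_ij, symmetric under reversibility
    -sum(cnt * L)
  }
  if (is.null(kappa)) {
    opt <- optim(c(log(0.2), log(2)),
                 function(v) negll(exp(v[1L]), exp(v[2L])),
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 500))
    d <- exp(opt$par[1L])
  } else {
    opt <- optimize(function(d) negll(d, kappa), c(1e-8, 20), tol = 1e-9)
    d <- opt$minimum
  }
  if (d > 19) stop("ML distance did not converge (saturation?) for ",
                   idA, ":", idB, call. = FALSE)
  d
}

#' All-pairs distance matrix
#'
#' @param a an `aln`.
#' @param method `"F84"` (closed form), `"ML"` (HKY or JTT pairwise ML)
#'   or `"raw"` (p-distance).
#' @return symmetric matrix with the alignment's ids.
#' @export
distance_matrix <- function(a, method = c("F84", "ML", "raw")) {
  method <- match.arg(method)
  ids <- rownames(a)
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- switch(method,
      F84 = unname(f84_distance(a, ids[i], ids[j])["d"]),
      ML  = ml_pair_distance(a, ids[i], ids[j]),
      raw = 1 - pairwise_identity(a, ids[i], ids[j]))
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor joining
#'
#' Standard NJ agglomeration (exact on additive matrices). Taxa involved
#' in non-finite (saturated) distances are excluded with a warning rather
#' than clamped.
#'
#' @param D symmetric distance matrix with dimnames.
#' @return `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix not symmetric", call. = FALSE)
  while (any(!is.finite(D))) {
    bad <- which.max(rowSums(!is.finite(D)))
    warning("excluding taxon with saturated distances: ", rownames(D)[bad])
    D <- D[-bad, -bad, drop = FALSE]
  }
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 taxa after exclusions", call. = FALSE)
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2L),
               edge.length = c(D[1, 2] / 2, D[1, 2] / 2),
               tip.label = rownames(D), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  ape::nj(as.dist(D))
}

aln_to_phyDat <- function(a) {
  m <- unclass(a)
  if (attr(a, "moltype") == "dna")
    phangorn::phyDat(m, type = "DNA")
  else
    phangorn::phyDat(m, type = "AA")
}

#' ML branch lengths and model parameters on a fixed topology
#'
#' Optimizes branch lengths, the gamma shape, the proportion of
#' invariable sites and (for DNA) the transition/transversion ratio by
#' pruning-algorithm likelihood (phangorn), under HKY85 + I + Gamma(4)
#' for DNA or JTT + I + Gamma(4) for proteins. The two-round protocol is
#' supported through `fixed`: passing the first round's `alpha`, `p_inv`
#' (and `kappa`) freezes them, as done when bootstrapping.
#'
#' @param tree starting `phylo` (leaf set = alignment ids).
#' @param a an `aln`.
#' @param rate_classes discrete gamma categories.
#' @param fixed optional list with `alpha`, `p_inv`, `kappa` to hold
#'   fixed.
#' @param optimize_topology also perform NNI rearrangements.
#' @return list: `tree` (optimized branch lengths), `lnL`, `alpha`,
#'   `p_inv`, `kappa`, `fit` (the underlying phangorn fit).
#' @export
ml_branch_lengths <- function(tree, a, rate_classes = 4L, fixed = NULL,
                              optimize_topology = FALSE) {
  if (ncol(a) == 0L) stop("zero-length alignment", call. = FALSE)
  if (!setequal(tree$tip.label, rownames(a)))
    stop("tree taxa do not match alignment", call. = FALSE)
  pd <- aln_to_phyDat(a)
  dna <- attr(a, "moltype") == "dna"
  fit <- phangorn::pml(tree, pd, k = rate_classes,
                       shape = if (!is.null(fixed$alpha)) fixed$alpha else 1,
                       inv = if (!is.null(fixed$p_inv)) fixed$p_inv else 0,
                       model = if (dna) "HKY" else "JTT")
  fit <- suppressWarnings(phangorn::optim.pml(
    fit, model = if (dna) "HKY" else "JTT",
    optEdge = TRUE, optGamma = is.null(fixed$alpha),
    optInv = is.null(fixed$p_inv),
    optQ = dna && is.null(fixed$kappa), optBf = dna && is.null(fixed$kappa),
    optNni = optimize_topology,
    control = phangorn::pml.control(trace = 0)))
  kappa <- if (dna) fit$Q[5L] / fit$Q[1L] else NA_real_
  list(tree = fit$tree, lnL = fit$logLik, alpha = fit$shape,
       p_inv = fit$inv, kappa = kappa, fit = fit)
}

#' Nonparametric bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with `tree_builder`, and counts how many replicates contain
#' each bipartition of `tree` (unordered leaf splits).
#'
#' @param a an `aln`.
#' @param tree the point-estimate `phylo` whose splits are scored.
#' @param tree_builder function(aln) -> `phylo`; default NJ on F84 (DNA)
#'   or JTT ML (protein) distances.
#' @param replicates bootstrap replicates (>= 100).
#' @param seed RNG seed (deterministic output).
#' @return list: `tree` with `node.label` support counts, `support`
#'   (named per internal node), `replicates`.
#' @export
bootstrap_support <- function(a, tree, tree_builder = NULL,
                              replicates = 1000L, seed = 1L) {
  if (replicates < 100L) stop("use at least 100 replicates", call. = FALSE)
  if (is.null(tree_builder))
    tree_builder <- function(x) neighbor_joining(distance_matrix(
      x, if (attr(x, "moltype") == "dna") "F84" else "ML"))
  set.seed(seed)
  trees <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    idx <- sample.int(ncol(a), replace = TRUE)
    ar <- unclass(a)[, idx, drop = FALSE]
    ar <- alignment(ar, attr(a, "moltype"))
    trees[[r]] <- tree_builder(ar)
  }
  class(trees) <- "multiPhylo"
  cnt <- ape::prop.clades(tree, trees, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  tree$node.label <- cnt
  list(tree = tree, support = cnt, replicates = replicates)
}

## the seven typical points of the quartet-weight simplex: three corners
## (fully resolved), three edge midpoints (partly resolved), the center
## (star-like); each quartet is assigned to its nearest typical point
quartet_region <- function(w) {
  pts <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5),
               c(1, 1, 1) / 3)
  which.min(rowSums(sweep(pts, 2L, w)^2))
}

#' Quartet likelihood mapping
#'
#' Samples quartets of taxa, computes the ML log-likelihood of the three
#' resolved quartet topologies (branch lengths optimized; HKY for DNA,
#' JTT for protein) and maps the posterior weights onto the simplex'
#' seven regions. The proportion landing in the three corner regions is
#' the fraction of fully resolved quartets, the usual summary of
#' phylogenetic signal.
#'
#' @param a an `aln` with >= 4 sequences.
#' @param n_quartets number of quartets to sample (all distinct quartets
#'   if fewer exist).
#' @param seed RNG seed.
#' @return list: `n`, `resolved` (proportion in corner regions),
#'   `regions` (7 proportions summing to 1), `weights` (n x 3 matrix).
#' @export
likelihood_mapping <- function(a, n_quartets = 100L, seed = 1L) {
  ids <- rownames(a)
  if (length(ids) < 4L) stop("need >= 4 sequences", call. = FALSE)
  all_q <- combn(ids, 4L)
  set.seed(seed)
  take <- if (ncol(all_q) <= n_quartets) seq_len(ncol(all_q))
          else sample.int(ncol(all_q), n_quartets)
  dna <- attr(a, "moltype") == "dna"
  W <- matrix(0, length(take), 3L)
  for (qi in seq_along(take)) {
    q <- all_q[, take[qi]]
    sub <- alignment(unclass(a)[q, , drop = FALSE], attr(a, "moltype"))
    pd <- aln_to_phyDat(sub)
    tops <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
    lnl <- vapply(tops, function(o) {
      tr <- ape::read.tree(text = sprintf("((%s,%s),(%s,%s));",
                                          q[o[1]], q[o[2]], q[o[3]], q[o[4]]))
      tr <- ape::unroot(tr)
      tr$edge.length <- rep(0.1, nrow(tr$edge))
      fit <- phangorn::pml(tr, pd, model = if (dna) "HKY" else "JTT")
      fit <- suppressWarnings(phangorn::optim.pml(
        fit, model = if (dna) "HKY" else "JTT", optEdge = TRUE,
        optQ = dna, control = phangorn::pml.control(trace = 0)))
      as.numeric(fit$logLik)
    }, 0)
    w <- exp(lnl - max(lnl)); W[qi, ] <- w / sum(w)
  }
  reg <- apply(W, 1L, quartet_region)
  regions <- tabulate(reg, 7L) / length(reg)
  list(n = length(take), resolved = sum(regions[1:3]), regions = regions,
       weights = W)
}
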
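## Goldman-Yang codon substitution model: 61 sense codons (standard code),
## transition/transversion ratio kappa, nonsynonymous/synonymous ratio
## omega, target-codon frequencies pi.

NUC <- c("T", "C", "A", "G")

.codon_tables <- local({
  all_cod <- as.vector(outer(outer(NUC, NUC, paste0), NUC,
                             function(ab, c) paste0(ab, c)))
  all_cod <- sort(all_cod)
  aa <- vapply(all_cod, function(cd) unname(GENETIC_CODE_DNA[cd]), "")
  sense <- all_cod[aa != "*"]
  aa <- aa[match(sense, all_cod)]
  n <- length(sense)  # 61
  cm <- do.call(rbind, strsplit(sense, ""))
  ## substitution type: 0 none/multi-nt, 1 syn tv, 2 syn ts, 3 nonsyn tv,
  ## 4 nonsyn ts
  type <- matrix(0L, n, n)
  is_ts <- function(a, b) (a %in% c("A", "G") && b %in% c("A", "G")) ||
                          (a %in% c("C", "T") && b %in% c("C", "T"))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dif <- which(cm[i, ] != cm[j, ])
    if (length(dif) != 1L) next
    ts <- is_ts(cm[i, dif], cm[j, dif])
    syn <- aa[i] == aa[j]
    type[i, j] <- if (syn) (if (ts) 2L else 1L) else (if (ts) 4L else 3L)
  }
  list(codons = sense, aa = aa, type = type, cm = cm)
})

CODONS61 <- .codon_tables$codons
CODON_AA <- .codon_tables$aa

#' Codon equilibrium frequencies
#'
#' `F3x4` builds sense-codon frequencies from position-specific nucleotide
#' frequencies of the alignment; `F61` uses empirical codon counts (with a
#' pseudo-count); `equal` is uniform over the 61 sense codons.
#'
#' @param a codon alignment.
#' @param model `"F3x4"`, `"F61"` or `"equal"`.
#' @return numeric vector of length 61 summing to 1, named by codon.
#' @export
codon_frequencies <- function(a, model = c("F3x4", "F61", "equal")) {
  model <- match.arg(model)
  if (model == "equal")
    return(setNames(rep(1 / 61, 61), CODONS61))
  cs <- codon_strings(a)
  cs <- cs[!grepl("[^ACGT]", cs)]
  if (model == "F61") {
    cnt <- table(factor(cs, levels = CODONS61)) + 0.5
    p <- as.numeric(cnt / sum(cnt))
    return(setNames(p, CODONS61))
  }
  chars <- do.call(rbind, strsplit(cs, ""))
  f <- vapply(1:3, function(pos)
    as.numeric(table(factor(chars[, pos], levels = NUC))) /
      length(cs), numeric(4))
  cm <- .codon_tables$cm
  p <- f[match(cm[, 1], NUC), 1] * f[match(cm[, 2], NUC), 2] *
       f[match(cm[, 3], NUC), 3]
  p <- pmax(p, 1e-10)
  setNames(p / sum(p), CODONS61)
}

#' GY94 instantaneous rate matrix
#'
#' Rates are 0 for multi-nucleotide changes, `pi_j` for synonymous
#' transversions, `kappa * pi_j` for synonymous transitions, and the same
#' multiplied by `omega` for nonsynonymous changes; the diagonal makes
#' rows sum to zero. The matrix is returned unscaled together with its
#' mean rate under `pi`; mixtures are rescaled jointly at the mixture
#' level so one unit of branch length is one expected codon substitution.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi sense-codon frequencies (length 61).
#' @return list with `Q` (61 x 61) and `rate` (mean substitution rate).
#' @export
codon_Q_matrix <- function(kappa, omega, pi) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61)
  type <- .codon_tables$type
  mult <- c(0, 1, kappa, omega, omega * kappa)[type + 1L]
  Q <- matrix(mult, 61, 61) * rep(pi, each = 61)
  diag(Q) <- -rowSums(Q)
  list(Q = Q, rate = -sum(pi * diag(Q)))
}

## spectral decomposition of a reversible Q via symmetrization
eigen_reversible <- function(Q, pi) {
  sp <- sqrt(pi)
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(V = diag(1 / sp) %*% e$vectors,
       Vinv = t(e$vectors) %*% diag(sp),
       eval = e$values)
}

## discrete beta: K equal-probability categories represented by their
## conditional means (same convention as the usual codeml discretization
## by mean)
discrete_beta <- function(p, q, K) {
  br <- suppressWarnings(qbeta(seq(0, 1, length.out = K + 1), p, q))
  m <- p / (p + q) * (pbeta(br[-1], p + 1, q) - pbeta(br[-(K + 1)], p + 1, q)) * K
  pmin(pmax(m, 1e-8), 1 - 1e-8)
}

## site classes (weights, omegas) for each site model
site_classes <- function(model, par, ncat = 10) {
  switch(model,
    M0  = list(w = 1, omega = par$omega),
    M1a = list(w = c(par$p0, 1 - par$p0), omega = c(par$omega0, 1)),
    M2a = list(w = c(par$p0, par$p1, 1 - par$p0 - par$p1),
               omega = c(par$omega0, 1, par$omega2)),
    M7  = list(w = rep(1 / ncat, ncat),
               omega = discrete_beta(par$p, par$q, ncat)),
    M8  = list(w = c(rep(par$p0 / ncat, ncat), 1 - par$p0),
               omega = c(discrete_beta(par$p, par$q, ncat), par$omega_s)),
    M8a = list(w = c(rep(par$p0 / ncat, ncat), 1 - par$p0),
               omega = c(discrete_beta(par$p, par$q, ncat), 1)),
    stop("unknown site model ", model, call. = FALSE))
}

## tip codon states (1..61, 0 = gap/ambiguous) with pattern compression
codon_patterns <- function(a, tip_order) {
  cs <- codon_strings(a)[match(tip_order, rownames(a)), , drop = FALSE]
  st <- matrix(match(cs, CODONS61), nrow = nrow(cs))
  st[is.na(st)] <- 0L
  key <- apply(st, 2L, paste, collapse = ",")
  ux <- !duplicated(key)
  list(states = st[, ux, drop = FALSE],
       weights = as.numeric(table(key)[key[ux]]),
       map = match(key, key[ux]))
}

tree_postorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, blen = tr$edge.length, tip = tr$tip.label)
}

## log-likelihood of a site-class mixture; returns per-pattern matrix
## too (rate-matrix construction, eigendecomposition, mixture-level rate
## normalization and pruning all happen in compiled code)
mixture_lnL <- function(pat, post, scale, kappa, classes, pi) {
  lm <- gy94_mixture_loglik_cpp(post$edge, post$blen * scale, pat$states,
                                kappa, classes$omega, classes$w, pi,
                                .codon_tables$type)
  mx <- apply(lm, 2L, max)
  sitel <- log(colSums(classes$w * exp(sweep(lm, 2L, mx)))) + mx
  list(lnL = sum(sitel * pat$weights), logmat = lm, site_lnL = sitel)
}

#' Log-likelihood of a codon site-class mixture
#'
#' Per-site likelihood is the class-weighted average of GY94 pruning
#' likelihoods; the total is the weighted sum over site patterns.
#' Branch lengths of `tree` are multiplied by `scale` and normalized so
#' that one unit is one expected codon substitution at the mixture level.
#'
#' @param a codon alignment.
#' @param tree `phylo` over the same taxa.
#' @param model site model name (`M0`, `M1a`, `M2a`, `M7`, `M8`, `M8a`).
#' @param par named list of model parameters (see [fit_site_model()]).
#' @param kappa transition/transversion ratio.
#' @param scale tree scale factor.
#' @param pi codon frequencies (default F3x4 from `a`).
#' @param ncat beta discretization categories.
#' @return log-likelihood (numeric scalar).
#' @export
site_mixture_lnL <- function(a, tree, model, par, kappa, scale = 1,
                             pi = codon_frequencies(a), ncat = 10) {
  po <- tree_postorder(tree)
  stopifnot(setequal(po$tip, rownames(a)))
  pat <- codon_patterns(a, po$tip)
  cls <- site_classes(model, par, ncat)
  mixture_lnL(pat, po, scale, kappa, cls, pi)$lnL
}
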
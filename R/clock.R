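## Divergence-time estimation under global and local molecular clocks.
## Two-phase protocol: substitution parameters (kappa and omega for codon
## data, kappa and gamma shape for nucleotide data) are estimated first
## without the clock; relative node heights are then fitted by
## clock-constrained maximum likelihood with those parameters fixed, and
## fossil calibrations map heights onto absolute ages (Mya).

## equal-probability discrete gamma categories represented by their means
discrete_gamma_rates <- function(alpha, K = 4L) {
  br <- stats::qgamma(seq(0, 1, length.out = K + 1), alpha, alpha)
  m <- vapply(seq_len(K), function(k)
    (stats::pgamma(br[k + 1], alpha + 1, alpha) -
     stats::pgamma(br[k], alpha + 1, alpha)) * K, 0)
  m / mean(m)
}

## nucleotide patterns (A C G T -> 1..4, else 0) for the pruning engine
nuc_patterns <- function(a, tip_order) {
  m <- unclass(a)[match(tip_order, rownames(a)), , drop = FALSE]
  st <- matrix(match(m, c("A", "C", "G", "T")), nrow = nrow(m))
  st[is.na(st)] <- 0L
  key <- apply(st, 2L, paste, collapse = ",")
  ux <- !duplicated(key)
  list(states = st[, ux, drop = FALSE],
       weights = as.numeric(table(key)[key[ux]]),
       map = match(key, key[ux]))
}

## mixture eigendecompositions: either a list of (Q, pi) per class or one
## Q with per-class rate multipliers
mixture_eigen <- function(Qs, pis, rate_mult = NULL) {
  K <- if (is.null(rate_mult)) length(Qs) else length(rate_mult)
  ns <- nrow(if (is.null(rate_mult)) Qs[[1L]] else Qs)
  V <- array(0, c(ns, ns, K)); Vi <- array(0, c(ns, ns, K))
  ev <- matrix(0, ns, K)
  if (is.null(rate_mult)) {
    for (k in seq_len(K)) {
      e <- eigen_reversible(Qs[[k]], pis[[k]])
      V[, , k] <- e$V; Vi[, , k] <- e$Vinv; ev[, k] <- e$eval
    }
  } else {
    e <- eigen_reversible(Qs, pis)
    for (k in seq_len(K)) {
      V[, , k] <- e$V; Vi[, , k] <- e$Vinv
      ev[, k] <- e$eval * rate_mult[k]
    }
  }
  list(V = V, Vi = Vi, ev = ev)
}

## log-likelihood of a rooted tree with given node heights (tips at 0)
clock_lnL <- function(pat, tree, heights, eg, rootfreq, weights_mix,
                      rate_mult_edges = NULL) {
  tr <- ape::reorder.phylo(tree, "postorder")
  blen <- heights[tr$edge[, 1L]] - heights[tr$edge[, 2L]]
  if (any(!is.finite(blen)) || any(blen < 0)) return(-Inf)
  if (!is.null(rate_mult_edges)) blen <- blen * rate_mult_edges
  lm <- prune_loglik_cpp(tr$edge, blen, pat$states, eg$V, eg$Vi, eg$ev,
                         rootfreq)
  mx <- apply(lm, 2L, max)
  sitel <- log(colSums(weights_mix * exp(sweep(lm, 2L, mx)))) + mx
  sum(sitel * pat$weights)
}

## heights from transformed parameters: root height exp(v[1]); each
## further internal node (preorder) a logistic fraction of its parent
heights_from_par <- function(v, tree) {
  ntip <- length(tree$tip.label)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  h <- numeric(ntip + tree$Nnode)
  root <- ntip + 1L
  h[root] <- exp(clamp(v[1L], -20, 6))
  k <- 1L
  for (e in seq_len(nrow(pre))) {
    ch <- pre[e, 2L]
    if (ch <= ntip) next
    k <- k + 1L
    h[ch] <- h[pre[e, 1L]] * ilogit(v[k])
  }
  h
}

par_from_heights <- function(h, tree) {
  ntip <- length(tree$tip.label)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  v <- log(h[ntip + 1L])
  for (e in seq_len(nrow(pre))) {
    ch <- pre[e, 2L]
    if (ch <= ntip) next
    frac <- clamp(h[ch] / h[pre[e, 1L]], 1e-6, 1 - 1e-6)
    v <- c(v, qlogis(frac))
  }
  v
}

#' Calibration set
#'
#' @param clades list of character vectors of leaf names; each
#'   calibration constrains the age of the MRCA of its leaves.
#' @param min_age,max_age bounds in Mya (equal for a point calibration).
#' @return data.frame of class `calibration_set`.
#' @export
calibration_set <- function(clades, min_age, max_age = min_age) {
  stopifnot(length(clades) == length(min_age),
            length(min_age) == length(max_age),
            all(min_age > 0), all(max_age >= min_age))
  df <- data.frame(min_age = min_age, max_age = max_age)
  df$clade <- if (is.list(clades)) clades else list(clades)
  class(df) <- c("calibration_set", "data.frame")
  df
}

#' @rdname calibration_set
#' @param path TSV with columns `leaves` (semicolon-separated),
#'   `min_age`, `max_age`.
#' @export
read_calibration_set <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("leaves", "min_age", "max_age") %in% names(df)))
  calibration_set(strsplit(df$leaves, ";"), df$min_age, df$max_age)
}

#' Fit a molecular clock and date nodes
#'
#' Phase 1 estimates the substitution nuisance parameters without a
#' clock (kappa and omega by an M0 fit for codon data; kappa and the
#' gamma shape via phangorn for nucleotide data). Phase 2 fixes them and
#' maximizes the clock-constrained likelihood over relative node heights
#' (and, for the local model, one extra rate multiplier on user-flagged
#' branches). Calibrations then scale relative heights to absolute ages:
#' the overall rate is chosen so calibrated nodes fall inside their age
#' intervals (least-squares against interval midpoints if the feasible
#' intersection is empty).
#'
#' @param a codon alignment (`data_type = "codon"`) or DNA `aln`.
#' @param rooted_tree rooted binary `phylo` over the alignment's taxa.
#' @param calibrations a [calibration_set()].
#' @param model `"global"` or `"local"`.
#' @param data_type `"codon"` or `"nucleotide"`.
#' @param local_branches for the local model: a character vector of tip
#'   labels; the terminal branches of these tips (and edges of the MRCA
#'   clade) get the second rate.
#' @return object of class `clock_fit`: `ages` (Mya per node),
#'   `rate` (substitutions/site/My), `rate_interval`, `lnL`, `heights`
#'   (substitutions/site), nuisance parameters, `tree`, `data_type`.
#' @export
fit_clock <- function(a, rooted_tree, calibrations,
                      model = c("global", "local"),
                      data_type = c("codon", "nucleotide"),
                      local_branches = NULL) {
  model <- match.arg(model)
  data_type <- match.arg(data_type)
  tree <- rooted_tree
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  if (!setequal(tree$tip.label, rownames(a)))
    stop("tree taxa do not match alignment", call. = FALSE)
  if (nrow(calibrations) < 1L) stop("need >= 1 calibration", call. = FALSE)
  ntip <- length(tree$tip.label)

  ## calibration nodes + contradiction check (child older than parent)
  cal_nodes <- vapply(calibrations$clade, function(cl) {
    if (length(cl) == ntip) return(ntip + 1L)
    as.integer(ape::getMRCA(tree, cl))
  }, 0L)
  if (anyNA(cal_nodes)) stop("calibration clade not in tree", call. = FALSE)
  anc <- lapply(seq_len(nrow(calibrations)), function(i)
    c(cal_nodes[i], phangorn::Ancestors(tree, cal_nodes[i])))
  for (i in seq_len(nrow(calibrations)))
    for (j in seq_len(nrow(calibrations)))
      if (i != j && cal_nodes[j] %in% anc[[i]][-1L] &&
          calibrations$min_age[i] > calibrations$max_age[j])
        stop("contradictory calibrations: descendant older than ancestor",
             call. = FALSE)

  ## phase 1: nuisance parameters, no clock
  if (data_type == "codon") {
    m0 <- fit_site_model(a, ape::unroot(tree), "M0")
    kappa <- m0$kappa; omega <- m0$par$omega; alpha <- NA_real_
    pi <- m0$pi
    q <- codon_Q_matrix(kappa, omega, pi)
    eg <- mixture_eigen(q$Q / q$rate, pi, rate_mult = 1)
    wmix <- 1
    pat <- codon_patterns(a, tree$tip.label)
    nuis <- list(kappa = kappa, omega = omega)
  } else {
    ml <- ml_branch_lengths(ape::unroot(tree), a)
    kappa <- ml$kappa; alpha <- ml$alpha
    f <- as.numeric(table(factor(unclass(a), levels = c("A","C","G","T"))))
    pi <- f / sum(f)
    hk <- hky_Q(kappa, pi)
    rates <- discrete_gamma_rates(alpha, 4L)
    eg <- mixture_eigen(hk$Q, pi, rate_mult = rates)
    wmix <- rep(1 / 4, 4)
    pat <- nuc_patterns(a, tree$tip.label)
    nuis <- list(kappa = kappa, alpha = alpha)
  }

  ## local-model edge rate multipliers
  edge_mult_fn <- function(mult) NULL
  if (model == "local") {
    if (is.null(local_branches))
      stop("local model needs local_branches", call. = FALSE)
    tr_post <- ape::reorder.phylo(tree, "postorder")
    flag_node <- if (length(local_branches) == 1L)
      match(local_branches, tree$tip.label)
    else ape::getMRCA(tree, local_branches)
    in_clade <- c(flag_node,
                  unlist(phangorn::Descendants(tree, flag_node, "all")))
    flagged_edges <- tr_post$edge[, 2L] %in% in_clade
    edge_mult_fn <- function(mult) ifelse(flagged_edges, mult, 1)
  }

  ## phase 2: clock-constrained heights (+ optional local rate)
  start_tree <- tree
  if (is.null(start_tree$edge.length))
    start_tree$edge.length <- rep(0.05, nrow(start_tree$edge))
  h0 <- clock_start_heights(start_tree)
  v0 <- par_from_heights(h0, tree)
  if (model == "local") v0 <- c(v0, 0)
  nh <- tree$Nnode
  obj <- function(v) {
    h <- heights_from_par(v[seq_len(nh)], tree)
    em <- if (model == "local") edge_mult_fn(exp(v[nh + 1L])) else NULL
    val <- clock_lnL(pat, tree, h, eg, pi, wmix, em)
    if (!is.finite(val)) 1e10 else -val
  }
  opt <- optim(v0, obj, method = "BFGS",
               control = list(reltol = 1e-10, maxit = 500))
  h <- heights_from_par(opt$par[seq_len(nh)], tree)
  rate_mult <- if (model == "local") exp(opt$par[nh + 1L]) else NA_real_

  ## calibration: overall rate rho (height = rho * age)
  ch <- h[cal_nodes]
  lo <- ch / calibrations$max_age
  hi <- ch / pmax(calibrations$min_age, 1e-9)
  feas_lo <- max(lo); feas_hi <- min(hi)
  if (feas_lo <= feas_hi) {
    rho <- sqrt(feas_lo * feas_hi)
    rho_int <- c(feas_lo, feas_hi)
  } else {
    mid <- (calibrations$min_age + calibrations$max_age) / 2
    rho <- sum(ch^2) / sum(ch * mid)  # LS of age = h/rho on midpoints
    rho_int <- range(lo, hi)
  }
  ages <- h / rho
  names(ages) <- as.character(seq_along(ages))
  structure(list(model = model, data_type = data_type,
                 ages = ages[(ntip + 1L):(ntip + tree$Nnode)],
                 heights = h, rate = rho,
                 rate_interval = sort(c(ch[1L] / calibrations$max_age[1L],
                                        ch[1L] / pmax(calibrations$min_age[1L], 1e-9))),
                 local_rate_multiplier = rate_mult,
                 lnL = -opt$value, nuisance = nuis, pi = pi,
                 tree = tree, cal_nodes = cal_nodes),
            class = "clock_fit")
}

## crude starting heights: node depths from the tree's own branch
## lengths, forced strictly positive and monotone
clock_start_heights <- function(tree) {
  ntip <- length(tree$tip.label)
  h <- node_ages_from_blen(tree)
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(post))) {
    par <- post[e, 1L]; ch <- post[e, 2L]
    h[par] <- max(h[par], h[ch] * 1.05 + 1e-4)
  }
  h[seq_len(ntip)] <- 0
  h
}

node_ages_from_blen <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  max(d) - d
}

#' @export
print.clock_fit <- function(x, ...) {
  cat(sprintf("%s clock (%s data): lnL = %.3f, rate = %.4g subs/site/My\n",
              x$model, x$data_type, x$lnL, x$rate))
  cat("node ages (Mya):", paste(signif(x$ages, 4), collapse = " "), "\n")
  invisible(x)
}

#' Age of the MRCA of a set of taxa under a clock fit
#' @param fit a [fit_clock()] result.
#' @param taxa tip labels.
#' @return age in Mya.
#' @export
mrca_age <- function(fit, taxa) {
  node <- ape::getMRCA(fit$tree, taxa)
  ntip <- length(fit$tree$tip.label)
  unname(fit$ages[node - ntip])
}

## pairwise ML distance under the clock fit's substitution model, in the
## same units as fit$rate
clock_pair_distance <- function(a, idA, idB, fit) {
  if (fit$data_type == "nucleotide")
    return(ml_pair_distance(a, idA, idB, kappa = fit$nuisance$kappa))
  pi <- fit$pi
  q <- codon_Q_matrix(fit$nuisance$kappa, fit$nuisance$omega, pi)
  e <- eigen_reversible(q$Q / q$rate, pi)
  xs <- match(codon_strings(a[idA, ])[1L, ], CODONS61)
  ys <- match(codon_strings(a[idB, ])[1L, ], CODONS61)
  keep <- !is.na(xs) & !is.na(ys)
  xs <- xs[keep]; ys <- ys[keep]
  if (all(xs == ys)) return(0)
  negll <- function(t) {
    P <- e$V %*% diag(exp(e$eval * t)) %*% e$Vinv
    P[P < 1e-12] <- 1e-12
    -sum(log(pi[xs] * P[cbind(xs, ys)]))
  }
  optimize(negll, c(1e-9, 20), tol = 1e-9)$minimum
}

#' Date a gene-conversion event from its homogenized tract
#'
#' A converted tract shared by two paralogues has a star-like two-lineage
#' history since the conversion, so its age is the tract's pairwise
#' divergence divided by twice the substitution rate. The rate (and its
#' interval) normally comes from a [fit_clock()] on the conversion-free
#' region.
#'
#' @param a alignment restricted to the converted region.
#' @param idA,idB the paralogue pair.
#' @param rate substitutions/site/My, or a `clock_fit` whose rate and
#'   model are used.
#' @param rate_interval optional c(lo, hi) rate interval for an age
#'   interval.
#' @return list: `age` (Mya), `age_interval`, `divergence`, `flag`
#'   (`"recent_or_ongoing"` when divergence is 0).
#' @export
date_conversion_event <- function(a, idA, idB, rate, rate_interval = NULL) {
  if (inherits(rate, "clock_fit")) {
    fit <- rate
    d <- clock_pair_distance(a, idA, idB, fit)
    rate_interval <- fit$rate_interval
    rate <- fit$rate
  } else {
    d <- unname(f84_distance(a, idA, idB)["d"])
  }
  stopifnot(rate > 0)
  age <- d / (2 * rate)
  ai <- if (!is.null(rate_interval) && all(rate_interval > 0))
    sort(d / (2 * rate_interval)) else c(age, age)
  list(age = age, age_interval = ai, divergence = d,
       flag = if (d == 0) "recent_or_ongoing" else "ok")
}
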
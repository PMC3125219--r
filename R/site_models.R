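## Fitting codon site-class mixture models (M0, M1a, M2a, M7, M8, M8a),
## likelihood-ratio tests between nested pairs, and naive empirical Bayes
## identification of positively selected sites.

ilogit <- function(x) 1 / (1 + exp(-x))
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## parameter transforms: all site-model parameters are optimized on an
## unconstrained scale (log for rates, logistic/stick-breaking for
## proportions, log(omega - 1) for the positive-selection class)
sm_pack <- function(model, kappa, scale, par) {
  v <- c(log(kappa), log(scale))
  v <- c(v, switch(model,
    M0  = log(par$omega),
    M1a = c(qlogis(par$p0), qlogis(par$omega0)),
    M2a = c(qlogis(par$p0), qlogis(par$p1 / (1 - par$p0)),
            qlogis(par$omega0), log(par$omega2 - 1)),
    M7  = c(log(par$p), log(par$q)),
    M8  = c(qlogis(par$p0), log(par$p), log(par$q), log(par$omega_s - 1)),
    M8a = c(qlogis(par$p0), log(par$p), log(par$q))))
  v
}

sm_unpack <- function(model, v) {
  kappa <- clamp(exp(v[1L]), 0.02, 99)
  scale <- clamp(exp(v[2L]), 1e-4, 1e4)
  r <- v[-(1:2)]
  pe <- function(x) clamp(ilogit(x), 1e-6, 1 - 1e-6)
  bq <- function(x) clamp(exp(x), 0.005, 99)
  par <- switch(model,
    M0  = list(omega = clamp(exp(r[1L]), 1e-6, 50)),
    M1a = list(p0 = pe(r[1L]), omega0 = pe(r[2L])),
    M2a = {
      a1 <- pe(r[1L]); a2 <- pe(r[2L])
      list(p0 = a1, p1 = a2 * (1 - a1), omega0 = pe(r[3L]),
           omega2 = 1 + clamp(exp(r[4L]), 1e-6, 49))
    },
    M7  = list(p = bq(r[1L]), q = bq(r[2L])),
    M8  = list(p0 = pe(r[1L]), p = bq(r[2L]), q = bq(r[3L]),
               omega_s = 1 + clamp(exp(r[4L]), 1e-6, 49)),
    M8a = list(p0 = pe(r[1L]), p = bq(r[2L]), q = bq(r[3L])))
  list(kappa = kappa, scale = scale, par = par)
}

sm_starts <- function(model) {
  ## two starting points per the low/high-omega convention (0.5 and 2.0
  ## on the free omega where one exists)
  base <- list(kappa = 2, scale = 1)
  s <- switch(model,
    M0  = list(list(omega = 0.5), list(omega = 2.0)),
    M1a = list(list(p0 = 0.7, omega0 = 0.2), list(p0 = 0.4, omega0 = 0.8)),
    M2a = list(list(p0 = 0.6, p1 = 0.3, omega0 = 0.2, omega2 = 2.0),
               list(p0 = 0.5, p1 = 0.3, omega0 = 0.5, omega2 = 4.0)),
    M7  = list(list(p = 0.5, q = 1.5), list(p = 2, q = 2)),
    M8  = list(list(p0 = 0.9, p = 0.5, q = 1.5, omega_s = 2.0),
               list(p0 = 0.8, p = 2, q = 2, omega_s = 1.3)),
    M8a = list(list(p0 = 0.9, p = 0.5, q = 1.5), list(p0 = 0.8, p = 2, q = 2)))
  lapply(s, function(p) c(base, list(par = p)))
}

#' Fit a codon site-class mixture model
#'
#' Maximum-likelihood fit of one of the standard site models by bounded
#' quasi-Newton optimization on transformed parameters from multiple
#' starting points (the best local optimum is retained). Branch lengths
#' enter through the supplied tree; by default a single tree-scale factor
#' is re-optimized per model over the tree's relative branch lengths
#' (`branches = "all"` frees every branch length instead).
#'
#' @param a codon alignment.
#' @param tree `phylo` with branch lengths over the alignment's taxa.
#' @param model `"M0"`, `"M1a"`, `"M2a"`, `"M7"`, `"M8"` or `"M8a"`.
#' @param freq_model codon frequency model, see [codon_frequencies()].
#' @param ncat beta discretization categories (equal-probability, by
#'   mean).
#' @param branches `"scale"` (default) or `"all"`.
#' @param starts list of starting parameter sets; default two per model.
#' @param control passed to [stats::optim()] (method `"BFGS"`).
#' @return object of class `site_model_fit`: `model`, `lnL`, `kappa`,
#'   `scale`, `par`, `classes` (weights and omega per class), `pi`,
#'   `convergence`, plus the pattern map and per-class site
#'   log-likelihoods needed for empirical Bayes site identification.
#' @export
fit_site_model <- function(a, tree, model = c("M0", "M1a", "M2a", "M7",
                                              "M8", "M8a"),
                           freq_model = "F3x4", ncat = 10,
                           branches = c("scale", "all"),
                           starts = NULL, control = list()) {
  model <- match.arg(model)
  branches <- match.arg(branches)
  stopifnot(inherits(a, "codon_aln"), nrow(a) >= 3L)
  po <- tree_postorder(tree)
  if (!setequal(po$tip, rownames(a)))
    stop("tree taxa do not match alignment ids", call. = FALSE)
  pat <- codon_patterns(a, po$tip)
  pi <- codon_frequencies(a, freq_model)
  if (is.null(starts)) starts <- sm_starts(model)
  ## relative branch lengths from the supplied tree; the per-model scale
  ## factor absorbs unit differences (nucleotide vs codon substitutions)
  rel_blen <- pmax(po$blen, 1e-6)

  obj <- function(v) {
    up <- sm_unpack(model, v[1:npar_core])
    po2 <- po
    if (branches == "all") {
      po2$blen <- clamp(exp(v[-(1:npar_core)]), 1e-8, 50)
      sc <- up$scale <- 1
    }
    if (branches == "scale") po2$blen <- rel_blen
    cls <- site_classes(model, up$par, ncat)
    val <- tryCatch(
      mixture_lnL(pat, po2, up$scale, up$kappa, cls, pi)$lnL,
      error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else -val
  }

  best <- NULL
  ctrl <- modifyList(list(reltol = 1e-9, maxit = 300), control)
  for (st in starts) {
    v0 <- sm_pack(model, st$kappa, st$scale, st$par)
    npar_core <- length(v0)
    if (branches == "all") v0 <- c(v0, log(pmax(po$blen, 1e-4)))
    opt <- tryCatch(optim(v0, obj, method = "BFGS", control = ctrl),
                    error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimization starts failed for ", model,
                          call. = FALSE)
  npar_core <- length(sm_pack(model, 2, 1, sm_starts(model)[[1L]]$par))
  up <- sm_unpack(model, best$par[1:npar_core])
  po2 <- po
  if (branches == "all") {
    po2$blen <- clamp(exp(best$par[-(1:npar_core)]), 1e-8, 50)
    up$scale <- 1
  } else po2$blen <- rel_blen
  cls <- site_classes(model, up$par, ncat)
  ml <- mixture_lnL(pat, po2, up$scale, up$kappa, cls, pi)
  structure(list(model = model, lnL = ml$lnL, kappa = up$kappa,
                 scale = up$scale, par = up$par, classes = cls, pi = pi,
                 ncat = ncat, convergence = best$convergence == 0L,
                 logmat = ml$logmat, pattern_map = pat$map,
                 tree = tree, n_codons = length(pat$map)),
            class = "site_model_fit")
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat(sprintf("site model %s: lnL = %.4f, kappa = %.3f%s\n", x$model,
              x$lnL, x$kappa,
              if (!x$convergence) " (NOT converged)" else ""))
  pv <- paste(sprintf("%s=%.4g", names(x$par), unlist(x$par)),
              collapse = ", ")
  cat("  parameters:", pv, "\n")
  invisible(x)
}

NESTED_PAIRS <- list("M1a/M2a" = 2L, "M7/M8" = 2L, "M8a/M8" = 1L,
                     "M0/M1a" = 1L, "M0/M2a" = 3L)

#' Likelihood-ratio test between nested site models
#'
#' Statistic `2 * (lnL_alt - lnL_null)` (clamped at zero against optimizer
#' noise) against a chi-squared with the nesting's degrees of freedom.
#' For M8a vs M8, where omega_s = 1 sits on the boundary, a mixture
#' `0.5 chi2_0 + 0.5 chi2_1` p-value is additionally reported.
#'
#' @param null_fit,alt_fit `site_model_fit` objects of a nested pair.
#' @return object of class `lrt_result` with `statistic`, `df`,
#'   `p_value` and (where applicable) `p_value_boundary`.
#' @export
lrt <- function(null_fit, alt_fit) {
  key <- paste0(null_fit$model, "/", alt_fit$model)
  if (!key %in% names(NESTED_PAIRS))
    stop("models not a supported nested pair: ", key, call. = FALSE)
  df <- NESTED_PAIRS[[key]]
  stat <- max(0, 2 * (alt_fit$lnL - null_fit$lnL))
  p <- pchisq(stat, df, lower.tail = FALSE)
  pb <- if (key == "M8a/M8")
    if (stat == 0) 1 else 0.5 * pchisq(stat, 1, lower.tail = FALSE)
  else NA_real_
  structure(list(null = null_fit$model, alt = alt_fit$model,
                 statistic = stat, df = df, p_value = min(p, 1),
                 p_value_boundary = pb),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("%s vs %s: -2(ln lambda) = %.3f, df = %d, p = %.3g\n",
              x$null, x$alt, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Naive empirical Bayes site identification
#'
#' Posterior probability of each omega class per codon site, computed
#' from the maximum-likelihood estimates (naive empirical Bayes). Sites
#' with posterior probability of omega > 1 above `threshold` are flagged
#' and labeled by their ungapped position and residue in the designated
#' reference sequence (the "286Q" convention).
#'
#' @param fit a `site_model_fit`.
#' @param a the codon alignment the fit was made on.
#' @param reference_id row id used for site labels.
#' @param threshold posterior probability cut-off.
#' @return data.frame (class `site_posterior_table`) with one row per
#'   codon site: `codon`, `ref_pos`, `ref_aa`, `label`, `p_positive`,
#'   `selected`; empty when the fit has no omega > 1 class.
#' @export
positively_selected_sites <- function(fit, a, reference_id,
                                      threshold = 0.9) {
  stopifnot(inherits(fit, "site_model_fit"), inherits(a, "codon_aln"))
  if (!reference_id %in% rownames(a))
    stop("reference id not in alignment: ", reference_id, call. = FALSE)
  pos_class <- fit$classes$omega > 1
  empty <- data.frame(codon = integer(), ref_pos = integer(),
                      ref_aa = character(), label = character(),
                      p_positive = numeric(), selected = logical())
  class(empty) <- c("site_posterior_table", "data.frame")
  if (!any(pos_class)) return(empty)
  lm <- fit$logmat[, fit$pattern_map, drop = FALSE]
  lw <- sweep(lm, 1L, log(fit$classes$w), "+")
  mx <- apply(lw, 2L, max)
  pw <- exp(sweep(lw, 2L, mx))
  post <- sweep(pw, 2L, colSums(pw), "/")
  p_pos <- colSums(post[pos_class, , drop = FALSE])
  refaa <- translate_matrix(a)[reference_id, ]
  ref_pos <- cumsum(refaa != "-")
  ref_pos[refaa == "-"] <- NA_integer_
  lab <- ifelse(is.na(ref_pos), NA_character_,
                paste0(ref_pos, refaa))
  out <- data.frame(codon = seq_along(p_pos), ref_pos = ref_pos,
                    ref_aa = refaa, label = lab, p_positive = p_pos,
                    selected = p_pos > threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("site_posterior_table", "data.frame")
  out
}

#' Run the standard positive-selection test battery on one group
#'
#' Fits M1a, M2a, M7, M8 and M8a and reports the three nested LRTs
#' (M1a vs M2a, M7 vs M8, M8a vs M8) in the shape of a per-group results
#' table, plus the M8 site list.
#'
#' @inheritParams fit_site_model
#' @param reference_id reference sequence for site labels (default first
#'   row).
#' @param threshold posterior threshold for the site list.
#' @param models which site models to fit (nested tests are reported
#'   for whichever pairs are available).
#' @param control optimizer control passed to every fit.
#' @return list with `fits`, `tests` (data.frame), `sites`
#'   (`site_posterior_table` under M8, or M2a when M8 is not fitted).
#' @export
selection_scan <- function(a, tree, freq_model = "F3x4", ncat = 10,
                           reference_id = rownames(a)[1L],
                           threshold = 0.9,
                           models = c("M1a", "M2a", "M7", "M8", "M8a"),
                           control = list()) {
  fit1 <- function(m, starts = NULL)
    fit_site_model(a, tree, m, freq_model = freq_model, ncat = ncat,
                   starts = starts, control = control)
  fits <- list()
  if ("M1a" %in% models)
    fits$M1a <- fit1("M1a")
  ## warm-start each alternative from its null (plus a dispersed start)
  f1 <- fits$M1a
  if ("M2a" %in% models)
    fits$M2a <- fit1("M2a", starts = list(
      list(kappa = f1$kappa, scale = f1$scale,
           par = list(p0 = f1$par$p0 * 0.95,
                      p1 = (1 - f1$par$p0) * 0.95,
                      omega0 = max(f1$par$omega0, 1e-4), omega2 = 2.0)),
      list(kappa = f1$kappa, scale = f1$scale,
           par = list(p0 = 0.6, p1 = 0.3, omega0 = 0.3, omega2 = 4.0))))
  if (any(c("M7", "M8", "M8a") %in% models))
    fits$M7 <- fit1("M7")
  f7 <- fits$M7
  if ("M8" %in% models)
    fits$M8 <- fit1("M8", starts = list(
      list(kappa = f7$kappa, scale = f7$scale,
           par = list(p0 = 0.95, p = f7$par$p, q = f7$par$q,
                      omega_s = 2.0)),
      list(kappa = f7$kappa, scale = f7$scale,
           par = list(p0 = 0.75, p = f7$par$p, q = f7$par$q,
                      omega_s = 1.2))))
  if ("M8a" %in% models)
    fits$M8a <- fit1("M8a", starts = list(
      list(kappa = f7$kappa, scale = f7$scale,
           par = list(p0 = 0.97, p = f7$par$p, q = f7$par$q)),
      list(kappa = f7$kappa, scale = f7$scale,
           par = list(p0 = 0.8, p = f7$par$p, q = f7$par$q))))
  tests <- list()
  if (all(c("M1a", "M2a") %in% names(fits)))
    tests$m1a_m2a <- lrt(fits$M1a, fits$M2a)
  if (all(c("M7", "M8") %in% names(fits)))
    tests$m7_m8 <- lrt(fits$M7, fits$M8)
  if (all(c("M8a", "M8") %in% names(fits)))
    tests$m8a_m8 <- lrt(fits$M8a, fits$M8)
  td <- do.call(rbind, lapply(tests, function(t)
    data.frame(test = paste(t$null, "vs.", t$alt),
               statistic = t$statistic, df = t$df, p_value = t$p_value)))
  if (!is.null(td)) {
    td$omega_positive <- NA_real_; td$prop_positive <- NA_real_
    if ("m1a_m2a" %in% names(tests)) {
      i <- which(names(tests) == "m1a_m2a")
      td$omega_positive[i] <- fits$M2a$par$omega2
      td$prop_positive[i] <- 1 - fits$M2a$par$p0 - fits$M2a$par$p1
    }
    if ("m7_m8" %in% names(tests)) {
      i <- which(names(tests) == "m7_m8")
      td$omega_positive[i] <- fits$M8$par$omega_s
      td$prop_positive[i] <- 1 - fits$M8$par$p0
    }
    rownames(td) <- NULL
  }
  site_fit <- if ("M8" %in% names(fits)) fits$M8
              else if ("M2a" %in% names(fits)) fits$M2a else NULL
  sites <- if (is.null(site_fit)) NULL
           else positively_selected_sites(site_fit, a, reference_id,
                                          threshold)
  list(fits = fits, tests = td, sites = sites)
}
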
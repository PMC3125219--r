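## Sawyer-style detection of gene-conversion fragments between sequence
## pairs: maximal runs of consecutive matching polymorphic sites, scored
## by the exact tail probability of the longest match run, with
## permutation and Bonferroni-corrected analytic p-values.

#' Polymorphic sites of an alignment
#'
#' Columns with at least two distinct non-gap states across the
#' alignment; columns containing any gap or `N` are excluded so that
#' alignment artifacts cannot seed fragments.
#'
#' @param a DNA `aln` with >= 2 sequences.
#' @return integer vector of 1-based polymorphic columns (ascending),
#'   with the column states as a character matrix attribute `states`.
#' @export
find_polymorphic_sites <- function(a) {
  stopifnot(inherits(a, "aln"))
  if (nrow(a) < 2L) stop("need >= 2 sequences", call. = FALSE)
  m <- unclass(a)
  clean <- colSums(m == "-" | m == "N") == 0L
  nstates <- apply(m, 2L, function(col) length(unique(col)))
  cols <- which(clean & nstates >= 2L)
  structure(cols, states = m[, cols, drop = FALSE])
}

## log upper-tail probability that the longest run of matches is >= L
## when M matches and D mismatches are arranged uniformly at random.
## Exact inclusion-exclusion over compositions where it is numerically
## stable (small instances, or the small-p regime where the alternating
## series has sharply decreasing terms); Poisson clump approximation
## from the expected number of qualifying runs in the moderate-tail
## regime, where cancellation would destroy the exact series.
run_tail_logp <- function(L, M, D) {
  if (L > M) return(-Inf)
  if (D == 0L) return(0)           # the single run has length M >= L
  jmax <- floor(M / L)
  lt <- vapply(seq_len(jmax), function(j)
    lchoose(D + 1, j) + lchoose(M - j * L + D, D) - lchoose(M + D, D),
    0)
  if (M + D <= 50) {               # exact, safely within double range
    s <- sum(rep_len(c(1, -1), jmax) * exp(lt))
    return(log(min(max(s, 1e-300), 1)))
  }
  if (jmax == 1L || (all(diff(lt) < 0) && lt[2L] - lt[1L] < log(0.99))) {
    r <- exp(lt - lt[1L])
    s <- sum(r * rep_len(c(1, -1), length(r)))
    if (s <= 0) s <- .Machine$double.xmin
    return(min(lt[1L] + log(s), 0))
  }
  E <- exp(min(lt[1L], 700))       # expected number of runs >= L
  log(max(1 - exp(-E), 1e-300))
}

## Karlin-Altschul decay rate for match/mismatch scores (+1 / -penalty)
## at background match probability p: solves E[exp(lambda X)] = 1
ka_lambda <- function(p, penalty) {
  f <- function(l) p * exp(l) + (1 - p) * exp(-l * penalty) - 1
  if (f(20) < 0) return(20)
  stats::uniroot(f, c(1e-8, 20), tol = 1e-10)$root
}

## all positive-scoring maximal segments of a score vector (iterated
## Kadane on disjoint sub-ranges), returned as (begin, end, score) rows
max_scoring_segments <- function(x, max_segments = 10L) {
  kadane <- function(lo, hi) {
    best <- c(0, lo, lo); cur <- 0; start <- lo
    for (i in lo:hi) {
      cur <- cur + x[i]
      if (cur > best[1L]) best <- c(cur, start, i)
      if (cur < 0) { cur <- 0; start <- i + 1L }
    }
    best
  }
  out <- NULL
  stack <- list(c(1L, length(x)))
  while (length(stack) && (is.null(out) || nrow(out) < max_segments)) {
    rng <- stack[[1L]]; stack <- stack[-1L]
    if (rng[1L] > rng[2L]) next
    b <- kadane(rng[1L], rng[2L])
    if (b[1L] <= 0) next
    out <- rbind(out, b)
    if (b[2L] > rng[1L]) stack <- c(stack, list(c(rng[1L], b[2L] - 1L)))
    if (b[3L] < rng[2L]) stack <- c(stack, list(c(b[3L] + 1L, rng[2L])))
  }
  out
}

pair_mismatch_stats <- function(a, idA, idB, poly = NULL) {
  m <- unclass(a)
  if (is.null(poly)) poly <- find_polymorphic_sites(a)
  match_vec <- m[idA, poly] == m[idB, poly]
  cmp <- m[idA, ] != "-" & m[idB, ] != "-" &
         m[idA, ] != "N" & m[idB, ] != "N"
  tot_difs <- sum(m[idA, cmp] != m[idB, cmp])
  list(poly = as.integer(poly), match = unname(match_vec),
       tot_difs = tot_difs)
}

#' Global inner conversion fragments for a sequence pair
#'
#' With the default scoring (no mismatches allowed inside a fragment),
#' fragments are maximal runs of consecutive polymorphic sites at which
#' the pair matches, delimited by the outermost matching polymorphic
#' columns. Each fragment is scored by `-log10` of the exact tail
#' probability of a match run at least that long given the pair's
#' matches and mismatches over polymorphic sites, so longer runs and
#' more diverged pairs score higher. Fragments are returned in
#' descending score order.
#'
#' @param a DNA `aln` (the group alignment being scanned).
#' @param idA,idB the pair.
#' @param mismatch_penalty `NULL` (default: no mismatches allowed inside
#'   a fragment), `"auto"` (penalty `max(1, 2p/(1-p))` from the pair's
#'   match proportion `p`), or a positive number: per-mismatch penalty
#'   of the maximal-scoring-segment scoring (match = +1).
#' @param min_sites drop fragments spanning fewer matching polymorphic
#'   sites.
#' @return data.frame of class `conversion_fragments` with columns
#'   `idA`, `idB`, `begin`, `end`, `n_match`, `score`, `n_poly`,
#'   `n_dif`, `tot_difs`; zero rows when no informative fragment exists
#'   (attribute `status` is `"uninformative"` when the pair matches at
#'   every polymorphic site).
#' @export
global_inner_fragments <- function(a, idA, idB, mismatch_penalty = NULL,
                                   min_sites = 2L) {
  st <- pair_mismatch_stats(a, idA, idB)
  empty <- data.frame(idA = character(), idB = character(),
                      begin = integer(), end = integer(),
                      n_match = integer(), score = numeric(),
                      n_poly = integer(), n_dif = integer(),
                      tot_difs = integer())
  class(empty) <- c("conversion_fragments", "data.frame")
  if (length(st$poly) == 0L) {
    attr(empty, "status") <- "uninformative"
    return(empty)
  }
  M <- sum(st$match); D <- sum(!st$match)
  if (D == 0L) {
    attr(empty, "status") <- "uninformative"
    return(empty)
  }
  if (M == 0L) {
    attr(empty, "status") <- "no_fragment"
    return(empty)
  }
  p <- M / (M + D)
  if (identical(mismatch_penalty, "auto"))
    mismatch_penalty <- max(1, 2 * p / (1 - p))
  if (is.null(mismatch_penalty)) {
    ## fragments = maximal runs of matching polymorphic sites; scored by
    ## the exact tail of the longest-run null (-log10 p)
    r <- rle(st$match)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_sites
    if (!any(keep)) {
      attr(empty, "status") <- "no_fragment"
      return(empty)
    }
    out <- data.frame(
      idA = idA, idB = idB,
      begin = st$poly[starts[keep]], end = st$poly[ends[keep]],
      n_match = r$lengths[keep],
      score = vapply(r$lengths[keep],
                     function(L) -run_tail_logp(L, M, D) / log(10), 0),
      n_poly = r$lengths[keep], n_dif = 0L, tot_difs = st$tot_difs)
  } else {
    stopifnot(mismatch_penalty > 0)
    x <- ifelse(st$match, 1, -mismatch_penalty)
    segs <- max_scoring_segments(x)
    if (is.null(segs)) {
      attr(empty, "status") <- "no_fragment"
      return(empty)
    }
    nm <- vapply(seq_len(nrow(segs)), function(i)
      sum(st$match[segs[i, 2L]:segs[i, 3L]]), 0)
    keep <- nm >= min_sites
    if (!any(keep)) {
      attr(empty, "status") <- "no_fragment"
      return(empty)
    }
    segs <- segs[keep, , drop = FALSE]; nm <- nm[keep]
    out <- data.frame(
      idA = idA, idB = idB,
      begin = st$poly[segs[, 2L]], end = st$poly[segs[, 3L]],
      n_match = as.integer(nm),
      score = segs[, 1L],
      n_poly = as.integer(segs[, 3L] - segs[, 2L] + 1L),
      n_dif = as.integer(segs[, 3L] - segs[, 2L] + 1L - nm),
      tot_difs = st$tot_difs)
  }
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("conversion_fragments", "data.frame")
  attr(out, "status") <- "ok"
  attr(out, "n_poly_total") <- length(st$poly)
  attr(out, "mismatch_penalty") <- mismatch_penalty
  out
}

#' Permutation p-value for the best fragment of a pair
#'
#' Permutes the order of the pair's match/mismatch pattern over
#' polymorphic columns and compares the best permuted fragment (longest
#' match run) against the observed one:
#' `sim_p = (1 + #\{permutation max >= observed\}) / (R + 1)`.
#'
#' @param a DNA `aln`.
#' @param idA,idB the pair.
#' @param R permutation replicates (>= 100).
#' @param seed RNG seed (deterministic).
#' @param mismatch_penalty as in [global_inner_fragments()]; the
#'   permuted statistic matches the scoring in use (longest match run,
#'   or best segment score).
#' @return `sim_p` in `[1/(R+1), 1]`.
#' @export
permutation_pvalue <- function(a, idA, idB, R = 10000L, seed = 1L,
                               mismatch_penalty = NULL) {
  if (R < 100L) stop("R must be >= 100", call. = FALSE)
  st <- pair_mismatch_stats(a, idA, idB)
  if (length(st$poly) == 0L || all(st$match) || !any(st$match))
    stop("pair uninformative for permutation test", call. = FALSE)
  if (identical(mismatch_penalty, "auto")) {
    pm <- mean(st$match)
    mismatch_penalty <- max(1, 2 * pm / (1 - pm))
  }
  stat <- if (is.null(mismatch_penalty)) {
    function(v) { r <- rle(v); m <- r$lengths[r$values]
                  if (length(m)) max(m) else 0L }
  } else {
    function(v) {
      best <- 0; cur <- 0
      for (xi in ifelse(v, 1, -mismatch_penalty)) {
        cur <- max(cur + xi, 0)
        if (cur > best) best <- cur
      }
      best
    }
  }
  obs <- stat(st$match)
  set.seed(seed)
  n <- length(st$match)
  hits <- 0L
  for (i in seq_len(R))
    if (stat(st$match[sample.int(n)]) >= obs) hits <- hits + 1L
  (1 + hits) / (R + 1)
}

#' Bonferroni-corrected analytic fragment p-value
#'
#' Exact tail probability of the fragment's match-run length under
#' random arrangement of the pair's matches and mismatches over
#' polymorphic sites (the same null the permutation test samples),
#' multiplied by the number of pairwise comparisons in the scan and
#' capped at 1.
#'
#' @param fragment one row of [global_inner_fragments()] output.
#' @param n_match_total,n_dif_total matches/mismatches of the pair over
#'   all polymorphic sites.
#' @param n_comparisons Bonferroni factor (number of ordered-pair
#'   comparisons scanned).
#' @param mismatch_penalty the penalty the fragment was scored with
#'   (`NULL` = no-mismatch runs; then the exact run-length tail is
#'   used). With a penalty, the Karlin-Altschul asymptotic tail for the
#'   maximal segment score applies.
#' @return corrected p-value in (0, 1].
#' @export
bcka_pvalue <- function(fragment, n_match_total, n_dif_total,
                        n_comparisons = 1L, mismatch_penalty = NULL) {
  if (n_match_total + n_dif_total == 0L)
    stop("degenerate pair: no polymorphic sites", call. = FALSE)
  p <- n_match_total / (n_match_total + n_dif_total)
  if (is.null(mismatch_penalty)) {
    lp <- run_tail_logp(fragment$n_match, n_match_total, n_dif_total)
  } else {
    lam <- ka_lambda(p, mismatch_penalty)
    lE <- log(n_dif_total + 1) - lam * fragment$score
    lp <- if (lE > log(0.01)) log(max(1 - exp(-exp(min(lE, 700))), 1e-300))
          else lE
  }
  min(exp(lp + log(n_comparisons)), 1)
}

#' Scan a group alignment for gene conversion
#'
#' Runs the pairwise inner-fragment scan over all (or selected)
#' sequence pairs of a group alignment, attaching the Bonferroni-
#' corrected analytic p-value (`bcka_p`) and, optionally, the
#' permutation p-value (`sim_p`) to each pair's fragments.
#'
#' @param a DNA `aln` (group alignment).
#' @param pairs optional 2-column matrix of id pairs; default all
#'   unordered pairs.
#' @param permutations permutation replicates for `sim_p`
#'   (0 = skip permutations).
#' @param seed RNG seed.
#' @param mismatch_penalty as in [global_inner_fragments()].
#' @param max_fragments_per_pair keep the top-scoring fragments.
#' @return `conversion_fragments` data.frame over all pairs, with
#'   `bcka_p` (and `sim_p`) columns, sorted by `bcka_p`.
#' @export
scan_gene_conversion <- function(a, pairs = NULL, permutations = 0L,
                                 seed = 1L, mismatch_penalty = NULL,
                                 max_fragments_per_pair = 3L) {
  ids <- rownames(a)
  if (is.null(pairs)) pairs <- t(combn(ids, 2L))
  n_comp <- nrow(pairs) * 2L  # ordered-pair Bonferroni factor
  res <- list()
  for (i in seq_len(nrow(pairs))) {
    idA <- pairs[i, 1L]; idB <- pairs[i, 2L]
    fr <- global_inner_fragments(a, idA, idB, mismatch_penalty)
    if (nrow(fr) == 0L) next
    pen <- attr(fr, "mismatch_penalty")
    fr <- head(fr, max_fragments_per_pair)
    st <- pair_mismatch_stats(a, idA, idB)
    M <- sum(st$match); D <- sum(!st$match)
    fr$bcka_p <- vapply(seq_len(nrow(fr)), function(j)
      bcka_pvalue(fr[j, ], M, D, n_comp, pen), 0)
    if (permutations > 0L) {
      sp <- permutation_pvalue(a, idA, idB, permutations, seed + i,
                               mismatch_penalty)
      fr$sim_p <- c(sp, rep(NA_real_, nrow(fr) - 1L))
    }
    res[[length(res) + 1L]] <- fr
  }
  if (!length(res)) {
    out <- data.frame()
  } else {
    out <- do.call(rbind, res)
    out <- out[order(out$bcka_p), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("conversion_fragments", "data.frame")
  out
}

#' Tile an alignment into converted / conversion-free regions
#'
#' Given one detected tract per group (the top fragment), produces the
#' familiar N / Central / C partition: segments before, inside and after
#' the tract, flagged as converted or not.
#'
#' @param begin,end tract bounds (1-based inclusive columns).
#' @param aln_length alignment length.
#' @return [region_spec()] with an extra `converted` column.
#' @export
conversion_regions <- function(begin, end, aln_length) {
  stopifnot(begin >= 1L, end >= begin, end <= aln_length)
  nm <- character(); s <- integer(); e <- integer(); conv <- logical()
  if (begin > 1L) { nm <- c(nm, "N"); s <- c(s, 1L); e <- c(e, begin - 1L)
                    conv <- c(conv, FALSE) }
  ## positional naming: a tract reaching the alignment end is called C,
  ## one starting at column 1 is called N, matching the region-report
  ## convention; an internal tract is Central
  tract_name <- if (end == aln_length && begin > 1L) "C"
                else if (begin == 1L && end < aln_length) "N"
                else "Central"
  nm <- c(nm, tract_name); s <- c(s, begin); e <- c(e, end)
  conv <- c(conv, TRUE)
  if (end < aln_length) { nm <- c(nm, "C"); s <- c(s, end + 1L)
                          e <- c(e, aln_length); conv <- c(conv, FALSE) }
  rs <- region_spec(nm, s, e, aln_length)
  rs$converted <- conv[match(rs$name, nm)]
  rs
}

#' Write a Table-1-shaped fragments report
#' @param fragments output of [scan_gene_conversion()].
#' @param path TSV path.
#' @export
write_fragments_tsv <- function(fragments, path) {
  df <- as.data.frame(fragments)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
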
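## Sliding-window bootstrap phylogeny profiling (bootscan): per window,
## columns are resampled with replacement, an NJ tree is built on
## ML-corrected (F84) distances, and the support for the query grouping
## with each reference is the fraction of replicate trees in which the
## two form a cherry.

.nuc_codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)

encode_dna <- function(a) {
  m <- matrix(.nuc_codes[unclass(a)], nrow(a), ncol(a))
  rownames(m) <- rownames(a)
  m
}

## F84 distance from integer-coded vectors; saturated pairs -> `cap`
f84_codes <- function(x, y, cap = 5) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n == 0L) return(cap)
  dif <- x != y
  ts <- dif & ((x == 1L | x == 3L) & (y == 1L | y == 3L) |
               (x == 2L | x == 4L) & (y == 2L | y == 4L))
  P <- sum(ts) / n
  Q <- (sum(dif) - sum(ts)) / n
  f <- tabulate(c(x, y), 4L) / (2 * n)
  f <- pmax(f, 1e-4)
  piR <- f[1L] + f[3L]; piY <- f[2L] + f[4L]
  A <- f[2L] * f[4L] / piY + f[1L] * f[3L] / piR
  B <- f[2L] * f[4L] + f[1L] * f[3L]
  C <- piR * piY
  t1 <- 1 - P / (2 * A) - (A - B) * Q / (2 * A * C)
  t2 <- 1 - Q / (2 * C)
  if (t1 <= 0 || t2 <= 0) return(cap)
  min(-2 * A * log(t1) + 2 * (A - B - C) * log(t2), cap)
}

dist_f84_codes <- function(M) {
  ids <- rownames(M); n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- f84_codes(M[i, ], M[j, ])
  D
}

is_cherry <- function(tree, a, b) {
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  pa <- tree$edge[tree$edge[, 2L] == ia, 1L]
  pb <- tree$edge[tree$edge[, 2L] == ib, 1L]
  length(pa) == 1L && length(pb) == 1L && pa == pb
}

#' Bootscan profile of a query sequence
#'
#' @param a DNA `aln` with >= 4 sequences.
#' @param query query id; all other rows are references.
#' @param window window width in columns.
#' @param step step between window starts.
#' @param replicates bootstrap replicates per window.
#' @param seed RNG seed (deterministic output).
#' @return data.frame of class `bootscan_profile`: `window_center` plus
#'   one support column per reference (fraction of replicate NJ trees in
#'   which the query and that reference are sisters).
#' @export
bootscan <- function(a, query, window = 200L, step = 20L,
                     replicates = 1000L, seed = 1L) {
  stopifnot(inherits(a, "aln"), attr(a, "moltype") == "dna")
  if (nrow(a) < 4L) stop("bootscan needs >= 4 sequences", call. = FALSE)
  if (window > ncol(a)) stop("window exceeds alignment length",
                             call. = FALSE)
  if (!query %in% rownames(a)) stop("query not in alignment", call. = FALSE)
  refs <- setdiff(rownames(a), query)
  M <- encode_dna(a)
  starts <- seq(1L, ncol(a) - window + 1L, by = step)
  set.seed(seed)
  sup <- matrix(0, length(starts), length(refs),
                dimnames = list(NULL, refs))
  for (wi in seq_along(starts)) {
    cols <- starts[wi]:(starts[wi] + window - 1L)
    Mw <- M[, cols, drop = FALSE]
    for (r in seq_len(replicates)) {
      Mb <- Mw[, sample.int(window, replace = TRUE), drop = FALSE]
      D <- dist_f84_codes(Mb)
      tr <- ape::nj(as.dist(D))
      for (rf in refs)
        if (is_cherry(tr, query, rf))
          sup[wi, rf] <- sup[wi, rf] + 1
    }
  }
  out <- data.frame(window_center = starts + (window - 1L) / 2,
                    sup / replicates, check.names = FALSE)
  attr(out, "query") <- query
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "replicates") <- replicates
  class(out) <- c("bootscan_profile", "data.frame")
  out
}

#' Locate the tract where the query's bootscan partner switches
#'
#' Convenience summary: per window, the best-supported reference; runs
#' of windows whose best partner differs from the global majority
#' partner delimit candidate conversion tracts.
#'
#' @param profile a [bootscan()] result.
#' @param min_support only count windows whose best support exceeds this.
#' @return data.frame with `begin`, `end` (columns) and `partner` per
#'   switched run (zero rows if the partner never switches).
#' @export
bootscan_switches <- function(profile, min_support = 0.5) {
  refs <- setdiff(names(profile), "window_center")
  sup <- as.matrix(profile[refs])
  best <- refs[max.col(sup, ties.method = "first")]
  best[apply(sup, 1L, max) < min_support] <- NA
  maj <- names(sort(table(best), decreasing = TRUE))[1L]
  half <- (attr(profile, "window") - 1L) / 2
  switched <- !is.na(best) & best != maj
  r <- rle(switched)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep))
    return(data.frame(begin = integer(), end = integer(),
                      partner = character()))
  data.frame(
    begin = as.integer(floor(profile$window_center[starts[keep]] - half)),
    end = as.integer(ceiling(profile$window_center[ends[keep]] + half)),
    partner = vapply(keep, function(k)
      names(sort(table(best[starts[k]:ends[k]]), decreasing = TRUE))[1L],
      ""))
}

#' Write a bootscan profile TSV
#' @param profile a [bootscan()] result.
#' @param path TSV path.
#' @export
write_bootscan_tsv <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
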
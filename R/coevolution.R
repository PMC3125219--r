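## CAPS-style detection of correlated amino-acid evolution: per site,
## BLOSUM80 transition scores of every sequence pair, corrected by the
## pair's divergence-time proxy (Poisson-corrected protein distance),
## centered and correlated between sites. Significance comes from a
## large resampling of random site pairs with a step-down (monotone)
## correction; significant pairs are grouped into connected components.

blosum80 <- local({
  e <- new.env()
  utils::data("BLOSUM80", package = "Biostrings", envir = e)
  e$BLOSUM80
})

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
          "S","T","W","Y","V")

## Poisson-corrected pairwise protein distances (divergence-time proxy)
poisson_distances <- function(a) {
  m <- unclass(a)
  ids <- rownames(m); n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    keep <- m[i, ] %in% AA20 & m[j, ] %in% AA20
    p <- mean(m[i, keep] != m[j, keep])
    d <- if (p >= 0.95) 3 else -log(1 - p)
    D[i, j] <- D[j, i] <- max(d, 0.01)  # floor: identical pairs still usable
  }
  D
}

## informative sites: gap-free columns with >= 2 residue states and a
## minor-residue count of at least `min_minor` sequences. Columns whose
## variation rests on a single sequence carry one substitution at most;
## their pair vectors collapse to a two-valued pattern that collides
## exactly with every other such column, flooding the null with perfect
## correlations, so scanning excludes them by default.
informative_sites <- function(a, min_minor = 1L) {
  m <- unclass(a)
  ok <- apply(m, 2L, function(col) {
    if (!all(col %in% AA20)) return(FALSE)
    tb <- table(col)
    length(tb) >= 2L && sum(tb) - max(tb) >= min_minor
  })
  which(ok)
}

#' Per-site substitution vector
#'
#' For one alignment column, the vector over unordered sequence pairs of
#' BLOSUM80 transition scores of the pair's residues divided by the
#' pair's divergence-time proxy, centered by its mean. Invariant or
#' gapped columns are uninformative and excluded from scanning.
#'
#' @param a protein `aln`.
#' @param site 1-based column.
#' @param times optional symmetric matrix of pair time proxies (default
#'   Poisson-corrected distances of `a`).
#' @return centered numeric vector over pairs (attribute `pairs` gives
#'   the id pairs), or `NULL` with a message for uninformative sites.
#' @export
site_substitution_vector <- function(a, site, times = NULL) {
  m <- unclass(a)
  col <- m[, site]
  if (!(all(col %in% AA20) && length(unique(col)) >= 2L)) {
    message("site ", site, " is uninformative (invariant or gapped)")
    return(NULL)
  }
  if (is.null(times)) times <- poisson_distances(a)
  pr <- combn(nrow(m), 2L)
  th <- blosum80[cbind(col[pr[1L, ]], col[pr[2L, ]])] /
    times[cbind(pr[1L, ], pr[2L, ])]
  v <- th - mean(th)
  attr(v, "pairs") <- rbind(rownames(m)[pr[1L, ]], rownames(m)[pr[2L, ]])
  v
}

## matrix of centered, unit-norm substitution vectors for all
## informative sites (pairs x sites); correlation = crossprod
theta_matrix <- function(a, sites, times) {
  m <- unclass(a)
  pr <- combn(nrow(m), 2L)
  tt <- times[cbind(pr[1L, ], pr[2L, ])]
  TH <- matrix(0, ncol(pr), length(sites))
  for (k in seq_along(sites)) {
    col <- m[, sites[k]]
    TH[, k] <- blosum80[cbind(col[pr[1L, ]], col[pr[2L, ]])] / tt
  }
  TH <- sweep(TH, 2L, colMeans(TH))
  nrm <- sqrt(colSums(TH^2))
  ## degenerate (zero-variance) site vectors are dropped by the caller
  list(M = sweep(TH, 2L, pmax(nrm, 1e-12), "/"), norm = nrm)
}

ref_position_map <- function(a, reference_id) {
  row <- unclass(a)[reference_id, ]
  pos <- cumsum(row != "-")
  pos[row == "-"] <- NA_integer_
  list(pos = pos, aa = row)
}

#' Scan for co-evolving site pairs
#'
#' Intra-molecular mode correlates all informative site pairs of one
#' protein alignment; inter-molecular mode correlates sites of two
#' alignments whose rows are paired by taxon. The null distribution of
#' the correlation is built from `n_samplings` random site pairs, raw
#' one-sided p-values are read off it, and a step-down pass enforces
#' monotonicity of p along decreasing correlation. Pairs with corrected
#' p below `alpha` are returned, grouped into connected components.
#'
#' @param alnA protein `aln`.
#' @param alnB optional second protein `aln` (inter mode).
#' @param pair_map for inter mode: data.frame with columns `idA`, `idB`
#'   pairing rows of the two alignments by taxon.
#' @param n_samplings null resamplings.
#' @param alpha significance level on the corrected p-value.
#' @param seed RNG seed.
#' @param min_minor minimum minor-residue count for a site to enter the
#'   scan (see `informative_sites`).
#' @param refA,refB reference row ids for site labels (default first
#'   row of each alignment).
#' @return data.frame of class `coevolution_pairs`: `siteA`, `siteB`
#'   (alignment columns), `posA`, `posB` + `labelA`, `labelB`
#'   (reference positions/residues), `r`, `p`, `group`, `mode`.
#'   Attribute `n_tested` records the number of scanned pairs.
#' @export
coevolution_scan <- function(alnA, alnB = NULL, pair_map = NULL,
                             n_samplings = 10000L, alpha = 0.001,
                             seed = 1L, min_minor = 2L,
                             refA = rownames(alnA)[1L],
                             refB = NULL) {
  stopifnot(attr(alnA, "moltype") == "protein")
  inter <- !is.null(alnB)
  set.seed(seed)
  if (inter) {
    stopifnot(attr(alnB, "moltype") == "protein", !is.null(pair_map))
    if (is.null(refB)) refB <- rownames(alnB)[1L]
    alnA <- alnA[pair_map$idA, ]
    alnB <- alnB[pair_map$idB, ]
    if (nrow(alnA) < 4L) stop("need >= 4 paired taxa", call. = FALSE)
    sA <- informative_sites(alnA, min_minor)
    sB <- informative_sites(alnB, min_minor)
    if (!length(sA) || !length(sB))
      return(empty_coevolution(if (inter) "inter" else "intra"))
    tA <- poisson_distances(alnA); tB <- poisson_distances(alnB)
    thA <- theta_matrix(alnA, sA, tA); thB <- theta_matrix(alnB, sB, tB)
    okA <- thA$norm > 1e-9; okB <- thB$norm > 1e-9
    sA <- sA[okA]; sB <- sB[okB]
    MA <- thA$M[, okA, drop = FALSE]; MB <- thB$M[, okB, drop = FALSE]
    if (!length(sA) || !length(sB))
      return(empty_coevolution("inter"))
    R <- crossprod(MA, MB)                     # |sA| x |sB| correlations
    cand <- cbind(as.vector(row(R)), as.vector(col(R)))
    robs <- as.vector(R)
    null_r <- R[cbind(sample.int(nrow(R), n_samplings, TRUE),
                      sample.int(ncol(R), n_samplings, TRUE))]
    pairs_df <- data.frame(siteA = sA[cand[, 1L]], siteB = sB[cand[, 2L]])
  } else {
    if (nrow(alnA) < 4L) stop("need >= 4 sequences", call. = FALSE)
    sA <- informative_sites(alnA, min_minor)
    if (length(sA) < 2L) return(empty_coevolution("intra"))
    tA <- poisson_distances(alnA)
    thA <- theta_matrix(alnA, sA, tA)
    ok <- thA$norm > 1e-9
    sA <- sA[ok]; MA <- thA$M[, ok, drop = FALSE]
    if (length(sA) < 2L) return(empty_coevolution("intra"))
    R <- crossprod(MA)
    iu <- which(upper.tri(R), arr.ind = TRUE)
    robs <- R[iu]
    null_idx <- cbind(sample.int(length(sA), n_samplings, TRUE),
                      sample.int(length(sA), n_samplings, TRUE))
    null_idx <- null_idx[null_idx[, 1L] != null_idx[, 2L], , drop = FALSE]
    null_r <- R[null_idx]
    pairs_df <- data.frame(siteA = sA[iu[, 1L]], siteB = sA[iu[, 2L]])
    alnB <- alnA; refB <- refA; sB <- sA
  }
  ## one-sided p against the resampled null, then a step-down monotone
  ## pass. Strict exceedance: null draws tied with the candidate (same
  ## correlation to numerical resolution) are patterns identical to it,
  ## typically the co-evolving pairs themselves re-sampled into the
  ## null, and do not count as more extreme; the null-calibration suite
  ## verifies the significant fraction stays at the nominal level on
  ## conversion-free, coupling-free data.
  ns <- sort(null_r)
  praw <- (1 + length(ns) - findInterval(robs + 1e-9, ns)) /
    (length(ns) + 1)
  ord <- order(-robs)
  padj <- cummax(praw[ord])[order(ord)]
  keep <- padj < alpha
  mode <- if (inter) "inter" else "intra"
  if (!any(keep)) {
    out <- empty_coevolution(mode)
    attr(out, "n_tested") <- length(robs)
    attr(out, "alpha") <- alpha
    return(out)
  }
  out <- pairs_df[keep, , drop = FALSE]
  out$r <- robs[keep]
  out$p <- padj[keep]
  out$mode <- mode
  mpA <- ref_position_map(alnA, refA); mpB <- ref_position_map(alnB, refB)
  out$posA <- mpA$pos[out$siteA]; out$posB <- mpB$pos[out$siteB]
  out$labelA <- ifelse(is.na(out$posA), NA,
                       paste0(out$posA, mpA$aa[out$siteA]))
  out$labelB <- ifelse(is.na(out$posB), NA,
                       paste0(out$posB, mpB$aa[out$siteB]))
  out <- out[order(-out$r), , drop = FALSE]
  rownames(out) <- NULL
  out$group <- pair_groups(out, inter)
  class(out) <- c("coevolution_pairs", "data.frame")
  attr(out, "n_tested") <- length(robs)
  attr(out, "alpha") <- alpha
  attr(out, "refA") <- refA; attr(out, "refB") <- refB
  out
}

empty_coevolution <- function(mode) {
  out <- data.frame(siteA = integer(), siteB = integer(), r = numeric(),
                    p = numeric(), mode = character(), posA = integer(),
                    posB = integer(), labelA = character(),
                    labelB = character(), group = integer())
  class(out) <- c("coevolution_pairs", "data.frame")
  attr(out, "n_tested") <- 0L
  out
}

## connected components of the significant-pair graph (union-find);
## inter-mode sites of the two proteins live in disjoint namespaces
pair_groups <- function(pairs, inter) {
  if (!nrow(pairs)) return(integer())
  na <- paste0("A", pairs$siteA)
  nb <- paste0(if (inter) "B" else "A", pairs$siteB)
  nodes <- unique(c(na, nb))
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  ia <- match(na, nodes); ib <- match(nb, nodes)
  for (k in seq_len(nrow(pairs))) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(ia, find, 0L)
  as.integer(factor(roots, levels = unique(roots)))
}

#' Compartment annotations
#'
#' @param protein protein name per interval.
#' @param compartment `extracellular`, `transmembrane` or `cytoplasmic`.
#' @param start,end 1-based positions in the reference protein.
#' @param domain optional domain names (LRRn, TIR, ...).
#' @return data.frame of class `compartment_annotation`.
#' @export
compartment_annotation <- function(protein, compartment, start, end,
                                   domain = NA_character_) {
  df <- data.frame(protein = protein, compartment = compartment,
                   start = as.integer(start), end = as.integer(end),
                   domain = domain, stringsAsFactors = FALSE)
  sp <- split(df, df$protein)
  for (d in sp) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)]))
      stop("overlapping intervals for ", d$protein[1L], call. = FALSE)
  }
  class(df) <- c("compartment_annotation", "data.frame")
  df
}

#' @rdname compartment_annotation
#' @param path TSV with columns `protein`, `compartment`, `start`,
#'   `end` (optional `domain`).
#' @export
read_compartment_annotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  compartment_annotation(df$protein, df$compartment, df$start, df$end,
                         if ("domain" %in% names(df)) df$domain else NA)
}

lookup_compartment <- function(ann, protein, pos) {
  vapply(pos, function(p) {
    if (is.na(p)) return("unknown")
    hit <- ann$protein == protein & ann$start <= p & ann$end >= p
    if (any(hit)) ann$compartment[which(hit)[1L]] else "unknown"
  }, "")
}

#' Label co-evolving pairs with cellular compartments
#'
#' @param pairs a [coevolution_scan()] result.
#' @param annotations a [compartment_annotation()].
#' @param proteinA,proteinB annotation protein names for the two sides.
#' @return list: `pairs` (with `compartmentA`/`compartmentB` columns),
#'   `summary` (cross-tabulated counts per compartment combination).
#' @export
compartment_filter <- function(pairs, annotations, proteinA,
                               proteinB = proteinA) {
  pairs$compartmentA <- lookup_compartment(annotations, proteinA,
                                           pairs$posA)
  pairs$compartmentB <- lookup_compartment(annotations, proteinB,
                                           pairs$posB)
  if (any(pairs$compartmentA == "unknown" |
          pairs$compartmentB == "unknown"))
    warning("unannotated site(s) labeled 'unknown'")
  lv <- c("extracellular", "transmembrane", "cytoplasmic", "unknown")
  summary <- as.data.frame(table(
    compartmentA = factor(pairs$compartmentA, lv),
    compartmentB = factor(pairs$compartmentB, lv)))
  summary <- summary[summary$Freq > 0L | TRUE, ]
  list(pairs = pairs, summary = summary)
}

#' Export a co-evolution network
#'
#' Nodes are residues (`protein:position:residue`), edges carry the
#' correlation coefficient. Writes GraphML and/or SIF files loadable by
#' standard graph viewers.
#'
#' @param pairs a [coevolution_scan()] result (non-empty).
#' @param graphml,sif output paths (`NULL` to skip either).
#' @param proteinA,proteinB node name prefixes.
#' @return invisible list of node and edge tables.
#' @export
export_network <- function(pairs, graphml = NULL, sif = NULL,
                           proteinA = "A", proteinB = proteinA) {
  if (!nrow(pairs)) stop("no pairs to export", call. = FALSE)
  inter <- any(pairs$mode == "inter")
  nodeA <- paste0(proteinA, ":", pairs$labelA)
  nodeB <- paste0(if (inter) proteinB else proteinA, ":", pairs$labelB)
  edges <- data.frame(from = nodeA, to = nodeB, r = pairs$r)
  nodes <- unique(c(nodeA, nodeB))
  if (!is.null(graphml)) {
    con <- file(graphml, "w")
    writeLines(c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="r" for="edge" attr.name="correlation" attr.type="double"/>',
      '  <graph id="coevolution" edgedefault="undirected">'), con)
    for (n in nodes)
      writeLines(sprintf('    <node id="%s"/>', n), con)
    for (i in seq_len(nrow(edges)))
      writeLines(sprintf(
        '    <edge source="%s" target="%s"><data key="r">%.4f</data></edge>',
        edges$from[i], edges$to[i], edges$r[i]), con)
    writeLines(c("  </graph>", "</graphml>"), con)
    close(con)
  }
  if (!is.null(sif))
    writeLines(paste(edges$from, "coevolves", edges$to), sif)
  invisible(list(nodes = nodes, edges = edges))
}
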
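## Discriminating gene conversion from convergent evolution by codon
## usage, and screening alignments for substitution saturation.

#' Codon-usage concordance of conserved residues
#'
#' Residues that stayed identical through purifying selection or became
#' identical by convergence are less likely to use the same codon than
#' residues homogenized by gene conversion. For each region, over
#' columns where the pair's amino acids are identical and gap-free, the
#' fraction whose codons are also nucleotide-identical is reported.
#'
#' @param a codon alignment.
#' @param idA,idB the pair.
#' @param regions a [region_spec()] in alignment (nucleotide) columns.
#' @return data.frame of class `codon_concordance`: `region`,
#'   `n_conserved`, `n_identical_codon`, `fraction` (NA when a region
#'   has no conserved column).
#' @export
codon_usage_concordance <- function(a, idA, idB, regions) {
  stopifnot(inherits(a, "codon_aln"), inherits(regions, "region_spec"))
  parts <- partition_regions(a, regions)
  rows <- lapply(names(parts), function(nm) {
    sub <- parts[[nm]]
    aa <- translate_matrix(sub)
    cs <- codon_strings(sub)
    cons <- aa[idA, ] == aa[idB, ] & aa[idA, ] != "-" & aa[idA, ] != "X" &
            aa[idB, ] != "-" & aa[idB, ] != "X"
    n_cons <- sum(cons)
    n_id <- sum(cons & cs[match(idA, rownames(sub)), ] ==
                       cs[match(idB, rownames(sub)), ])
    data.frame(region = nm, n_conserved = n_cons,
               n_identical_codon = n_id,
               fraction = if (n_cons > 0L) n_id / n_cons else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$idA <- idA; out$idB <- idB
  class(out) <- c("codon_concordance", "data.frame")
  out
}

#' Aggregate concordance over several pairs of a group
#'
#' @param a codon alignment.
#' @param pairs 2-column matrix of id pairs.
#' @param regions a [region_spec()].
#' @return per-region pooled counts and fractions across pairs.
#' @export
codon_usage_concordance_group <- function(a, pairs, regions) {
  per <- lapply(seq_len(nrow(pairs)), function(i)
    codon_usage_concordance(a, pairs[i, 1L], pairs[i, 2L], regions))
  all <- do.call(rbind, per)
  agg <- do.call(rbind, lapply(split(all, all$region), function(d)
    data.frame(region = d$region[1L],
               n_conserved = sum(d$n_conserved),
               n_identical_codon = sum(d$n_identical_codon),
               fraction = if (sum(d$n_conserved) > 0L)
                 sum(d$n_identical_codon) / sum(d$n_conserved)
               else NA_real_)))
  rownames(agg) <- NULL
  list(per_pair = all, aggregate = agg)
}

#' Conversion versus convergence verdict
#'
#' A candidate (converted) region whose identical-codon fraction exceeds
#' the non-candidate regions' fraction by at least `margin` supports
#' gene conversion; comparable fractions are inconclusive, and a
#' candidate fraction clearly below the background suggests convergent
#' or independent evolution of the amino-acid identity.
#'
#' @param report a [codon_usage_concordance()] result.
#' @param candidate region name(s) of the putative conversion tract.
#' @param margin required absolute excess of the candidate fraction.
#' @return list: `verdict` (`"conversion"`, `"convergence"` or
#'   `"inconclusive"`), `candidate_fraction`, `background_fraction`.
#' @export
conversion_vs_convergence_verdict <- function(report, candidate,
                                              margin = 0.2) {
  stopifnot(inherits(report, "codon_concordance"))
  ## pooled fractions, so small regions do not dominate
  pool <- function(d) if (sum(d$n_conserved) > 0L)
    sum(d$n_identical_codon) / sum(d$n_conserved) else NA_real_
  cand <- pool(report[report$region %in% candidate, , drop = FALSE])
  bg <- pool(report[!report$region %in% candidate, , drop = FALSE])
  if (is.na(cand) || is.na(bg))
    return(list(verdict = "inconclusive", candidate_fraction = cand,
                background_fraction = bg))
  verdict <- if (cand - bg >= margin) "conversion"
             else if (bg - cand >= margin) "convergence"
             else "inconclusive"
  list(verdict = verdict, candidate_fraction = cand,
       background_fraction = bg)
}

#' Transition/transversion saturation table
#'
#' All unordered pairs with their per-site transition (`s`) and
#' transversion (`v`) proportions and F84 distance. The plateau flag is
#' set when the fitted slope of `s` against `d` beyond `d_break` drops
#' to at most 10 percent of the slope below it, the signature of
#' transition saturation.
#'
#' @param a DNA `aln` with >= 2 sequences.
#' @param d_break distance splitting the near/far regimes.
#' @return list: `table` (data.frame `idA`, `idB`, `s`, `v`, `d`),
#'   `plateau` (logical), `slope_near`, `slope_far`.
#' @export
saturation_table <- function(a, d_break = 0.7) {
  stopifnot(inherits(a, "aln"), attr(a, "moltype") == "dna",
            nrow(a) >= 2L)
  ids <- rownames(a)
  pr <- t(combn(ids, 2L))
  rec <- do.call(rbind, lapply(seq_len(nrow(pr)), function(i) {
    fv <- suppressWarnings(f84_distance(a, pr[i, 1L], pr[i, 2L]))
    data.frame(idA = pr[i, 1L], idB = pr[i, 2L],
               s = unname(fv["s"]), v = unname(fv["v"]),
               d = unname(fv["d"]))
  }))
  fin <- rec[is.finite(rec$d), , drop = FALSE]
  near <- fin[fin$d <= d_break, , drop = FALSE]
  far <- fin[fin$d > d_break, , drop = FALSE]
  slope <- function(dd) if (nrow(dd) >= 2L && stats::var(dd$d) > 0)
    unname(stats::coef(stats::lm(s ~ d, dd))[2L]) else NA_real_
  sn <- slope(near); sf <- slope(far)
  plateau <- !is.na(sn) && !is.na(sf) && sn > 0 && sf <= 0.1 * sn
  list(table = rec, plateau = plateau, slope_near = sn, slope_far = sf)
}
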
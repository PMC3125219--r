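## End-to-end orchestration: conversion scan -> region partition ->
## trees -> clock dating -> positive selection -> co-evolution ->
## codon-usage diagnostics, from one config, with deterministic seeds
## and a structured run report.

#' Pipeline configuration
#'
#' @param alignment a `codon_aln` or a FASTA path (aligned CDS).
#' @param pairs 2-column matrix of paralogue id pairs to scan (default
#'   all unordered pairs).
#' @param stages character vector of stages to run, a subset of
#'   `c("scan", "partition", "trees", "dating", "selection",
#'   "coevolution", "diagnostics")`.
#' @param calibrations optional [calibration_set()] for dating.
#' @param reference_id reference row for site labels.
#' @param out_dir output directory (`NULL` = no files written).
#' @param seed master RNG seed; every stochastic stage derives its seed
#'   from it.
#' @param scan_permutations permutation replicates for the conversion
#'   scan (0 = analytic p-values only).
#' @param bootstrap_replicates tree bootstrap replicates.
#' @param coevolution_samplings null resamplings of the co-evolution
#'   scan.
#' @param coevolution_alpha significance level of the co-evolution scan.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(alignment, pairs = NULL,
                            stages = c("scan", "partition", "trees",
                                       "dating", "selection",
                                       "coevolution", "diagnostics"),
                            calibrations = NULL,
                            reference_id = NULL, out_dir = NULL,
                            seed = 1L, scan_permutations = 0L,
                            bootstrap_replicates = 100L,
                            coevolution_samplings = 2000L,
                            coevolution_alpha = 0.001) {
  a <- if (inherits(alignment, "aln")) alignment
       else codon_alignment(read_fasta(alignment, "dna"))
  if (!inherits(a, "codon_aln")) a <- codon_alignment(a)
  known <- c("scan", "partition", "trees", "dating", "selection",
             "coevolution", "diagnostics")
  stopifnot(all(stages %in% known))
  if (is.null(reference_id)) reference_id <- rownames(a)[1L]
  structure(list(alignment = a, pairs = pairs, stages = stages,
                 calibrations = calibrations,
                 reference_id = reference_id, out_dir = out_dir,
                 seed = as.integer(seed),
                 scan_permutations = scan_permutations,
                 bootstrap_replicates = bootstrap_replicates,
                 coevolution_samplings = coevolution_samplings,
                 coevolution_alpha = coevolution_alpha),
            class = "pipeline_config")
}

#' Run the conversion-aware analysis pipeline
#'
#' Stages run in dependency order: the conversion scan's top tract
#' defines converted / conversion-free regions; conversion-free regions
#' feed tree building and clock dating; the full-length alignment feeds
#' the codon selection models; the translated alignment feeds the
#' co-evolution scan; the codon-usage diagnostic compares regions.
#' A failed stage marks its dependents skipped. Rerunning with the same
#' config reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report`: per-stage `status`
#'   (`ok`/`skipped`/`failed` + reason), `results` (in-memory stage
#'   outputs), `files` (manifest), `seed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  a <- config$alignment
  want <- function(s) s %in% config$stages
  status <- list(); results <- list(); files <- character()
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  emit <- function(obj, name, writer) {
    if (is.null(out)) return(invisible())
    p <- file.path(out, name)
    writer(obj, p)
    files <<- c(files, p)
  }
  fail <- function(stage, e) {
    status[[stage]] <<- list(status = "failed",
                             reason = conditionMessage(e))
  }
  skip <- function(stage, why) {
    status[[stage]] <<- list(status = "skipped", reason = why)
  }
  okay <- function(stage) status[[stage]] <<- list(status = "ok")

  ## scan
  if (want("scan")) {
    tryCatch({
      fr <- scan_gene_conversion(a, pairs = config$pairs,
                                 permutations = config$scan_permutations,
                                 seed = config$seed)
      results$fragments <- fr
      emit(fr, "conversion_fragments.tsv", write_fragments_tsv)
      okay("scan")
    }, error = function(e) fail("scan", e))
  } else skip("scan", "disabled")

  ## partition
  if (want("partition")) {
    if (is.null(results$fragments) || !nrow(results$fragments)) {
      skip("partition", if (want("scan")) "no fragments detected"
                        else "scan disabled")
    } else tryCatch({
      top <- results$fragments[1L, ]
      regions <- conversion_regions(top$begin, top$end, ncol(a))
      results$regions <- regions
      parts <- suppressWarnings(partition_regions(a, regions))
      results$parts <- parts
      free <- parts[!regions$converted[match(names(parts), regions$name)]]
      results$conversion_free <- concat_alignments(free)
      results$converted <- concat_alignments(
        parts[regions$converted[match(names(parts), regions$name)]])
      emit(regions, "regions.tsv", function(r, p)
        write.table(as.data.frame(r), p, sep = "\t", quote = FALSE,
                    row.names = FALSE))
      okay("partition")
    }, error = function(e) fail("partition", e))
  } else skip("partition", "disabled")

  ## trees (on the conversion-free region when available)
  if (want("trees")) {
    tryCatch({
      ta <- if (!is.null(results$conversion_free))
        results$conversion_free else a
      D <- distance_matrix(ta, "F84")
      nj <- neighbor_joining(D)
      ml <- ml_branch_lengths(nj, ta)
      bs <- bootstrap_support(ta, ml$tree,
                              replicates = config$bootstrap_replicates,
                              seed = config$seed + 1L)
      results$tree <- bs$tree
      results$tree_lnL <- ml$lnL
      results$bootstrap <- bs$support
      emit(bs$tree, "tree.nwk", function(t, p) ape::write.tree(t, p))
      okay("trees")
    }, error = function(e) fail("trees", e))
  } else skip("trees", "disabled")

  ## dating
  if (want("dating")) {
    if (!want("trees") || is.null(results$tree)) {
      skip("dating", if (!want("trees")) "trees stage disabled"
                     else "no tree available")
    } else if (is.null(config$calibrations)) {
      skip("dating", "no calibrations supplied")
    } else tryCatch({
      ta <- if (!is.null(results$conversion_free))
        results$conversion_free else a
      rooted <- root_at_midpoint(results$tree)
      cf <- fit_clock(ta, rooted, config$calibrations,
                      model = "global", data_type = "codon")
      results$clock <- cf
      if (!is.null(results$converted)) {
        pairs <- if (is.null(config$pairs))
          t(combn(rownames(a), 2L)) else config$pairs
        results$conversion_dates <- do.call(rbind, lapply(
          seq_len(nrow(pairs)), function(i) {
            dc <- date_conversion_event(results$converted,
                                        pairs[i, 1L], pairs[i, 2L], cf)
            data.frame(idA = pairs[i, 1L], idB = pairs[i, 2L],
                       age = dc$age, lo = dc$age_interval[1L],
                       hi = dc$age_interval[2L], flag = dc$flag)
          }))
        emit(results$conversion_dates, "conversion_dates.tsv",
             function(d, p) write.table(d, p, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
      }
      ages <- data.frame(node = names(cf$ages), age_mya = cf$ages)
      emit(ages, "node_ages.tsv", function(d, p)
        write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE))
      okay("dating")
    }, error = function(e) fail("dating", e))
  } else skip("dating", "disabled")

  ## selection (full-length alignment, tree from the trees stage)
  if (want("selection")) {
    if (is.null(results$tree)) {
      skip("selection", "no tree available")
    } else tryCatch({
      sel <- selection_scan(a, results$tree,
                            reference_id = config$reference_id)
      results$selection <- sel
      emit(sel$tests, "selection_tests.tsv", function(d, p)
        write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE))
      emit(sel$sites, "selected_sites.tsv", function(d, p)
        write.table(as.data.frame(d), p, sep = "\t", quote = FALSE,
                    row.names = FALSE))
      okay("selection")
    }, error = function(e) fail("selection", e))
  } else skip("selection", "disabled")

  ## co-evolution (intra-molecular on the translated alignment)
  if (want("coevolution")) {
    tryCatch({
      prot <- translate_alignment(a)
      cv <- coevolution_scan(prot,
                             n_samplings = config$coevolution_samplings,
                             alpha = config$coevolution_alpha,
                             seed = config$seed + 2L,
                             refA = config$reference_id)
      results$coevolution <- cv
      emit(cv, "coevolution_pairs.tsv", function(d, p)
        write.table(as.data.frame(d), p, sep = "\t", quote = FALSE,
                    row.names = FALSE))
      if (nrow(cv) > 0L && !is.null(out))
        export_network(cv, graphml = file.path(out, "coevolution.graphml"),
                       sif = file.path(out, "coevolution.sif"))
      okay("coevolution")
    }, error = function(e) fail("coevolution", e))
  } else skip("coevolution", "disabled")

  ## diagnostics
  if (want("diagnostics")) {
    if (is.null(results$regions)) {
      skip("diagnostics", "no region partition available")
    } else tryCatch({
      pairs <- if (is.null(config$pairs))
        matrix(rownames(a)[1:2], 1L) else config$pairs
      cc <- codon_usage_concordance_group(a, pairs, results$regions)
      cand <- results$regions$name[results$regions$converted]
      verdicts <- lapply(split(cc$per_pair,
                               paste(cc$per_pair$idA, cc$per_pair$idB)),
                         function(d) {
                           class(d) <- c("codon_concordance", "data.frame")
                           conversion_vs_convergence_verdict(d, cand)
                         })
      results$concordance <- cc
      results$verdicts <- verdicts
      results$saturation <- saturation_table(a)
      emit(cc$aggregate, "codon_concordance.tsv", function(d, p)
        write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE))
      emit(results$saturation$table, "saturation.tsv", function(d, p)
        write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE))
      okay("diagnostics")
    }, error = function(e) fail("diagnostics", e))
  } else skip("diagnostics", "disabled")

  structure(list(status = status, results = results, files = files,
                 seed = config$seed,
                 params = config[setdiff(names(config), "alignment")]),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  for (s in names(x$status)) {
    st <- x$status[[s]]
    cat(sprintf("%-12s %s%s\n", s, st$status,
                if (!is.null(st$reason)) paste0(" (", st$reason, ")")
                else ""))
  }
  invisible(x)
}

## midpoint rooting without extra dependencies
root_at_midpoint <- function(tree) {
  phangorn::midpoint(tree)
}
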
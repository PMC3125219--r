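## Gillespie simulation of codon sequences along a duplicated gene tree,
## with interval gene conversion between paralogues, discrete omega site
## classes and branch-synchronous coupled (co-evolving) site pairs.
## Every emitted dataset carries its ground truth, so detection, dating,
## selection and co-evolution stages are all testable by recovery.

#' Simulation configuration
#'
#' Defines the study conditions for one simulated gene family: an
#' ultrametric species tree (branch lengths in My), a duplication time
#' predating its root, per-species conversion events on terminal
#' branches, a GY94 codon model with discrete omega site classes, and
#' optional coupled site pairs.
#'
#' @param species_tree newick string or ultrametric `phylo`, branch
#'   lengths in My.
#' @param duplication_time age (Mya) of the duplication; must be >= the
#'   species-tree root age.
#' @param n_codons alignment length in codons.
#' @param mutation_rate expected codon substitutions per codon site per
#'   My at the mixture level.
#' @param kappa transition/transversion rate ratio.
#' @param pi codon frequencies (`"equal"` or a length-61 vector).
#' @param omega_classes,omega_props discrete omega classes and their
#'   proportions (sites are assigned classes i.i.d.).
#' @param conversion_events data.frame with columns `species`,
#'   `donor_copy` (`"A"` or `"B"`), `time` (Mya, on the terminal
#'   branches of both copies), `begin_codon`, `end_codon`.
#' @param coevolving_pairs data.frame with columns `siteA`, `siteB`
#'   (codon positions), `coupling` (probability), `residues` (string of
#'   allowed amino acids, e.g. `"KRED"`), optional `rate_boost`
#'   (substitution-rate multiplier of the coupled sites; default 3,
#'   mimicking the elevated exchange rate of interacting interface
#'   residues).
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(species_tree, duplication_time, n_codons = 500L,
                       mutation_rate = 1e-3, kappa = 2.5, pi = "equal",
                       omega_classes = c(0.1, 0.5),
                       omega_props = c(0.6, 0.4),
                       conversion_events = NULL,
                       coevolving_pairs = NULL, seed = 1L) {
  tr <- if (inherits(species_tree, "phylo")) species_tree
        else ape::read.tree(text = species_tree)
  ages <- node_ages(tr)
  root_age <- max(ages)
  if (duplication_time < root_age - 1e-9)
    stop("duplication_time must be >= species-tree root age (",
         signif(root_age, 4), ")", call. = FALSE)
  stopifnot(length(omega_classes) == length(omega_props),
            abs(sum(omega_props) - 1) < 1e-8, all(omega_props >= 0),
            mutation_rate > 0, kappa > 0, n_codons >= 1L)
  if (identical(pi, "equal")) pi <- setNames(rep(1 / 61, 61), CODONS61)
  stopifnot(length(pi) == 61, abs(sum(pi) - 1) < 1e-6)
  if (!is.null(conversion_events)) {
    ce <- conversion_events
    need <- c("species", "donor_copy", "time", "begin_codon", "end_codon")
    stopifnot(all(need %in% names(ce)))
    tip_age <- terminal_branch_age(tr)
    for (i in seq_len(nrow(ce))) {
      sp <- ce$species[i]
      if (!sp %in% tr$tip.label)
        stop("conversion species not in tree: ", sp, call. = FALSE)
      if (ce$time[i] > tip_age[sp] + 1e-9)
        stop("conversion time ", ce$time[i], " older than the terminal ",
             "branch of ", sp, " (", signif(tip_age[sp], 4), " My)",
             call. = FALSE)
      if (ce$begin_codon[i] < 1L || ce$end_codon[i] > n_codons ||
          ce$begin_codon[i] > ce$end_codon[i])
        stop("conversion region out of range", call. = FALSE)
      if (!ce$donor_copy[i] %in% c("A", "B"))
        stop("donor_copy must be 'A' or 'B'", call. = FALSE)
    }
  }
  if (!is.null(coevolving_pairs)) {
    cp <- coevolving_pairs
    stopifnot(all(c("siteA", "siteB", "coupling", "residues") %in% names(cp)),
              all(cp$coupling >= 0 & cp$coupling <= 1),
              all(c(cp$siteA, cp$siteB) >= 1),
              all(c(cp$siteA, cp$siteB) <= n_codons))
    if (is.null(cp$rate_boost)) cp$rate_boost <- 3
    coevolving_pairs <- cp
  }
  structure(list(species_tree = tr, duplication_time = duplication_time,
                 n_codons = as.integer(n_codons),
                 mutation_rate = mutation_rate, kappa = kappa, pi = pi,
                 omega_classes = omega_classes, omega_props = omega_props,
                 conversion_events = conversion_events,
                 coevolving_pairs = coevolving_pairs, seed = seed),
            class = "sim_config")
}

## node ages (Mya) of an ultrametric phylo: tips at 0
node_ages <- function(tr) {
  h <- ape::node.depth.edgelength(tr)
  max(h) - h
}

## age of the speciation node above each tip
terminal_branch_age <- function(tr) {
  ages <- node_ages(tr)
  setNames(vapply(seq_along(tr$tip.label), function(i)
    ages[tr$edge[tr$edge[, 2L] == i, 1L]], 0), tr$tip.label)
}

## recursive node structure of the duplicated gene tree: each node has
## an age, tips carry labels <species>_<copy>
gene_tree_nodes <- function(config) {
  tr <- config$species_tree
  ages <- node_ages(tr)
  build <- function(idx, copy) {
    if (idx <= length(tr$tip.label))
      return(list(age = 0, label = paste0(tr$tip.label[idx], "_", copy)))
    ch <- tr$edge[tr$edge[, 1L] == idx, 2L]
    list(age = ages[idx], children = lapply(ch, build, copy = copy))
  }
  root_idx <- length(tr$tip.label) + 1L
  list(age = config$duplication_time,
       children = list(build(root_idx, "A"), build(root_idx, "B")))
}

## substitution machinery for the omega classes: leaving rates and jump
## distributions, normalized so the mixture mean rate is 1
class_machinery <- function(kappa, pi, omegas, props) {
  Qs <- lapply(omegas, function(w) codon_Q_matrix(kappa, w, pi))
  mean_rate <- sum(props * vapply(Qs, `[[`, 0, "rate"))
  lapply(Qs, function(q) {
    Q <- q$Q / mean_rate
    leave <- -diag(Q)
    P <- Q; diag(P) <- 0
    P <- P / pmax(rowSums(P), 1e-300)
    list(leave = leave, jump_cum = t(apply(P, 1L, cumsum)))
  })
}

evolve_site <- function(state, mach_k, dur) {
  t <- 0
  repeat {
    rate <- mach_k$leave[state]
    if (rate <= 0) break
    t <- t + rexp(1L, rate)
    if (t >= dur) break
    state <- findInterval(runif(1L), mach_k$jump_cum[state, ]) + 1L
    if (state > 61L) state <- 61L
  }
  state
}

## evolve a whole sequence (integer codon states) for `dur` expected
## substitutions per site, honoring coupled pairs branch-synchronously;
## `boost` is the per-site rate multiplier (coupled sites only)
evolve_seq <- function(seq, site_class, mach, dur, pairs, pi,
                       boost = NULL) {
  if (dur <= 0) return(seq)
  new <- seq
  if (is.null(boost)) {
    for (s in seq_along(seq))
      new[s] <- evolve_site(seq[s], mach[[site_class[s]]], dur)
  } else {
    for (s in seq_along(seq))
      new[s] <- evolve_site(seq[s], mach[[site_class[s]]], dur * boost[s])
  }
  if (!is.null(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      aS <- pairs$siteA[i]; bS <- pairs$siteB[i]
      cp <- pairs$coupling[i]
      if (cp <= 0) next
      allowed <- strsplit(pairs$residues[i], "")[[1L]]
      cand <- which(CODON_AA %in% allowed)
      ## branch-synchronous coupling: if either partner changed its
      ## residue on this branch, both land on the same compatible
      ## residue (fully concerted replacement at the coupled pair)
      if (CODON_AA[new[aS]] != CODON_AA[seq[aS]] ||
          CODON_AA[new[bS]] != CODON_AA[seq[bS]]) {
        if (runif(1L) < cp) {
          cod <- sample(cand, 1L, prob = pi[cand])
          new[aS] <- cod
          new[bS] <- cod
        }
      }
    }
  }
  new
}

#' Simulate a duplicated gene family with known truth
#'
#' Evolves codon sequences along the duplicated gene tree by per-site
#' Gillespie simulation under GY94 with per-site omega classes. At each
#' conversion event the donor paralogue's tract (its lineage state at
#' the event time) overwrites the acceptor's tract, after which both
#' evolve independently to the present. Coupled pairs substitute
#' branch-synchronously with the configured probability, restricted to
#' the allowed residues. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return list: `alignment` (a `codon_aln`, tips named
#'   `<species>_<copy>`), `truth` (site classes, conversion tracts in
#'   codons and columns, node ages, coupled pairs, seed).
#' @export
simulate_gene_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_codons
  site_class <- sample.int(length(config$omega_classes), n, replace = TRUE,
                           prob = config$omega_props)
  mach <- class_machinery(config$kappa, config$pi, config$omega_classes,
                          config$omega_props)
  pairs <- config$coevolving_pairs
  boost <- NULL
  if (!is.null(pairs)) {
    ## coupled sites evolve in the fastest class with a rate boost (so
    ## coupled substitutions actually occur) and start from compatible
    ## residues
    fast <- which.max(config$omega_classes)
    boost <- rep(1, n)
    for (i in seq_len(nrow(pairs))) {
      if (pairs$coupling[i] <= 0) next
      idx <- c(pairs$siteA[i], pairs$siteB[i])
      site_class[idx] <- fast
      boost[idx] <- pairs$rate_boost[i]
    }
    if (all(boost == 1)) boost <- NULL
  }
  r <- config$mutation_rate
  gt <- gene_tree_nodes(config)
  root_seq <- sample.int(61L, n, replace = TRUE, prob = config$pi)
  if (!is.null(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      if (pairs$coupling[i] <= 0) next
      cand <- which(CODON_AA %in% strsplit(pairs$residues[i], "")[[1L]])
      cod <- sample(cand, 1L, prob = config$pi[cand])
      root_seq[pairs$siteA[i]] <- cod
      root_seq[pairs$siteB[i]] <- cod
    }
  }

  ## donor intermediate states needed by conversion events
  ce <- config$conversion_events
  donor_need <- list()
  if (!is.null(ce)) for (i in seq_len(nrow(ce))) {
    dtip <- paste0(ce$species[i], "_", ce$donor_copy[i])
    donor_need[[dtip]] <- sort(unique(c(donor_need[[dtip]], ce$time[i])),
                               decreasing = TRUE)
  }
  tips <- new.env(parent = emptyenv())
  donor_states <- new.env(parent = emptyenv())

  descend <- function(node, seq) {
    if (is.null(node$children)) {
      assign(node$label, seq, envir = tips)
      return(invisible())
    }
    for (ch in node$children) {
      dur_my <- node$age - ch$age
      lbl <- if (is.null(ch$children)) ch$label else NULL
      if (!is.null(lbl) && !is.null(donor_need[[lbl]])) {
        ## split the terminal branch at each required event age
        cur_age <- node$age; s <- seq
        for (tau in donor_need[[lbl]]) {
          s <- evolve_seq(s, site_class, mach, (cur_age - tau) * r,
                          pairs, config$pi, boost)
          assign(paste0(lbl, "@", tau), s, envir = donor_states)
          cur_age <- tau
        }
        s <- evolve_seq(s, site_class, mach, cur_age * r, pairs,
                        config$pi, boost)
        assign(lbl, s, envir = tips)
      } else {
        descend(ch, evolve_seq(seq, site_class, mach, dur_my * r,
                               pairs, config$pi, boost))
      }
    }
  }
  descend(gt, root_seq)

  tracts <- NULL
  if (!is.null(ce)) {
    tracts <- ce
    tracts$acceptor <- paste0(ce$species, "_",
                              ifelse(ce$donor_copy == "A", "B", "A"))
    tracts$donor <- paste0(ce$species, "_", ce$donor_copy)
    tracts$begin_col <- 3L * (ce$begin_codon - 1L) + 1L
    tracts$end_col <- 3L * ce$end_codon
    for (i in seq_len(nrow(ce))) {
      reg <- ce$begin_codon[i]:ce$end_codon[i]
      s0 <- get(paste0(tracts$donor[i], "@", ce$time[i]),
                envir = donor_states)[reg]
      s1 <- s0
      for (k in seq_along(reg))
        s1[k] <- evolve_site(s0[k], mach[[site_class[reg[k]]]],
                             ce$time[i] * r)
      acc <- get(tracts$acceptor[i], envir = tips)
      acc[reg] <- s1
      assign(tracts$acceptor[i], acc, envir = tips)
    }
  }

  tip_labels <- character()
  collect <- function(node) {
    if (is.null(node$children)) tip_labels <<- c(tip_labels, node$label)
    else for (ch in node$children) collect(ch)
  }
  collect(gt)
  seqs <- vapply(tip_labels, function(l)
    paste(CODONS61[get(l, envir = tips)], collapse = ""), "")
  aln <- codon_alignment(alignment(seqs, "dna"),
                         strip_terminal_stop = FALSE)
  truth <- list(site_class = site_class,
                omega = config$omega_classes[site_class],
                tracts = tracts,
                duplication_time = config$duplication_time,
                species_ages = node_ages(config$species_tree),
                coevolving_pairs = pairs, seed = config$seed)
  list(alignment = aln, truth = truth)
}

#' Null dataset: same conditions, no conversion, no positive selection,
#' no coupling
#'
#' @param config a [sim_config()]; conversion events and coupled pairs
#'   are stripped and omega classes above 1 are truncated to 1.
#' @return as [simulate_gene_family()], with empty event truth.
#' @export
null_dataset <- function(config) {
  config$conversion_events <- NULL
  config$coevolving_pairs <- NULL
  config$omega_classes <- pmin(config$omega_classes, 1)
  simulate_gene_family(config)
}

#' Study-shaped simulation preset
#'
#' Four bird and four mammal species (bird-mammal split at 317.5 Mya), a
#' duplication at 359 Mya giving two paralogues per species, 800 codons,
#' and species-specific recent conversion tracts in the C-terminal third
#' (0-20 Mya in birds, 5-45 Mya in mammals).
#'
#' @param seed RNG seed.
#' @return a [sim_config()].
#' @export
tlr1_family_preset <- function(seed = 1L) {
  nwk <- paste0("(((birdW:35,birdX:35):55,(birdY:60,birdZ:60):30):227.5,",
                "((mamW:90,mamX:90):5,(mamY:94,mamZ:94):1):222.5);")
  events <- data.frame(
    species = c("birdW", "birdX", "birdY", "birdZ",
                "mamW", "mamX", "mamY", "mamZ"),
    donor_copy = c("A", "A", "B", "A", "A", "B", "A", "A"),
    time = c(2, 8, 14, 20, 5, 18, 30, 45),
    begin_codon = 534L, end_codon = 800L)
  sim_config(nwk, duplication_time = 359, n_codons = 800L,
             mutation_rate = 1.25e-3, kappa = 2.5,
             omega_classes = c(0.05, 0.4, 2.5),
             omega_props = c(0.55, 0.40, 0.05),
             conversion_events = events, seed = seed)
}

#' Round-trippable config serialization
#'
#' Writes/reads the full simulation configuration as plain text (newick
#' plus key = value lines and TSV blocks), so an emitted dataset can be
#' regenerated exactly.
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  con <- file(path, "w"); on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("tree\t", ape::write.tree(config$species_tree))
  wl("duplication_time\t", config$duplication_time)
  wl("n_codons\t", config$n_codons)
  wl("mutation_rate\t", config$mutation_rate)
  wl("kappa\t", config$kappa)
  wl("omega_classes\t", paste(config$omega_classes, collapse = ","))
  wl("omega_props\t", paste(config$omega_props, collapse = ","))
  wl("seed\t", config$seed)
  if (!is.null(config$conversion_events))
    for (i in seq_len(nrow(config$conversion_events)))
      wl("conversion\t", paste(unlist(
        config$conversion_events[i, c("species", "donor_copy", "time",
                                      "begin_codon", "end_codon")]),
        collapse = ","))
  if (!is.null(config$coevolving_pairs))
    for (i in seq_len(nrow(config$coevolving_pairs)))
      wl("pair\t", paste(unlist(
        config$coevolving_pairs[i, c("siteA", "siteB", "coupling",
                                     "residues")]), collapse = ","))
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  ln <- readLines(path)
  kv <- strsplit(ln, "\t")
  key <- vapply(kv, `[[`, "", 1L)
  val <- vapply(kv, function(x) paste(x[-1L], collapse = "\t"), "")
  g <- function(k) val[key == k][1L]
  ce <- NULL
  if (any(key == "conversion")) {
    parts <- strsplit(val[key == "conversion"], ",")
    ce <- data.frame(species = vapply(parts, `[[`, "", 1L),
                     donor_copy = vapply(parts, `[[`, "", 2L),
                     time = as.numeric(vapply(parts, `[[`, "", 3L)),
                     begin_codon = as.integer(vapply(parts, `[[`, "", 4L)),
                     end_codon = as.integer(vapply(parts, `[[`, "", 5L)))
  }
  cp <- NULL
  if (any(key == "pair")) {
    parts <- strsplit(val[key == "pair"], ",")
    cp <- data.frame(siteA = as.integer(vapply(parts, `[[`, "", 1L)),
                     siteB = as.integer(vapply(parts, `[[`, "", 2L)),
                     coupling = as.numeric(vapply(parts, `[[`, "", 3L)),
                     residues = vapply(parts, `[[`, "", 4L))
  }
  sim_config(g("tree"), as.numeric(g("duplication_time")),
             n_codons = as.integer(g("n_codons")),
             mutation_rate = as.numeric(g("mutation_rate")),
             kappa = as.numeric(g("kappa")),
             omega_classes = as.numeric(strsplit(g("omega_classes"), ",")[[1L]]),
             omega_props = as.numeric(strsplit(g("omega_props"), ",")[[1L]]),
             conversion_events = ce, coevolving_pairs = cp,
             seed = as.integer(g("seed")))
}
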
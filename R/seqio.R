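#' @useDynLib concertr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim optimize pchisq pbeta qbeta runif rexp cor sd
#'   setNames quantile as.dist qlogis
#' @importFrom utils combn read.delim write.table head modifyList data
NULL

DNA_CHARS  <- c("A", "C", "G", "T", "N", "-")
AA_CHARS   <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                "P","S","T","W","Y","V","X","-","*")

#' Alignment container
#'
#' An alignment is stored as a character matrix with one row per sequence
#' (single upper-case characters, gaps as `-`), rownames holding the
#' sequence ids and a `moltype` attribute (`"dna"` or `"protein"`).
#' [codon_alignment()] additionally enforces codon structure: a length
#' divisible by 3, frame anchored at column 1, and no internal stop codons.
#'
#' @param x named character vector of aligned sequences, or a character
#'   matrix (rows = sequences, single characters).
#' @param moltype `"dna"` or `"protein"`.
#' @return An object of class `aln` (and `codon_aln` for
#'   [codon_alignment()]).
#' @export
alignment <- function(x, moltype = c("dna", "protein")) {
  moltype <- match.arg(moltype)
  if (is.matrix(x)) {
    m <- x
  } else {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("sequences must be named", call. = FALSE)
    x <- toupper(x)
    lens <- nchar(x)
    if (length(unique(lens)) != 1L)
      stop("alignment rows must have equal length", call. = FALSE)
    m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    rownames(m) <- names(x)
  }
  mode(m) <- "character"
  m[] <- toupper(m)
  ids <- rownames(m)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequence ids must be unique and non-empty", call. = FALSE)
  allowed <- if (moltype == "dna") DNA_CHARS else AA_CHARS
  bad <- setdiff(unique(as.vector(m)), allowed)
  if (length(bad))
    stop(sprintf("illegal %s character(s): %s", moltype,
                 paste(bad, collapse = " ")), call. = FALSE)
  if (any(apply(m, 1L, function(r) all(r == "-"))))
    stop("a row consists only of gaps", call. = FALSE)
  structure(m, class = "aln", moltype = moltype)
}

#' @export
`[.aln` <- function(x, i, j, ...) {
  m <- unclass(x)[i, j, drop = FALSE]
  out <- alignment(m, attr(x, "moltype"))
  if (inherits(x, "codon_aln") && ncol(out) %% 3L == 0L)
    class(out) <- c("codon_aln", "aln")
  out
}

#' @export
print.aln <- function(x, ...) {
  cat(sprintf("<%s alignment: %d sequences x %d columns>\n",
              attr(x, "moltype"), nrow(x), ncol(x)))
  invisible(x)
}

aln_strings <- function(a) apply(unclass(a), 1L, paste, collapse = "")

#' @rdname alignment
#' @param strip_terminal_stop drop a final stop codon shared by the rows
#'   (with a message).
#' @export
codon_alignment <- function(x, strip_terminal_stop = TRUE) {
  a <- if (inherits(x, "aln")) x else alignment(x, "dna")
  if (attr(a, "moltype") != "dna")
    stop("codon alignments must be DNA", call. = FALSE)
  if (ncol(a) %% 3L != 0L)
    stop("alignment length not divisible by 3", call. = FALSE)
  ncod <- ncol(a) %/% 3L
  aam <- translate_matrix(a)
  if (strip_terminal_stop && ncod > 1L && any(aam[, ncod] == "*")) {
    if (!all(aam[, ncod] %in% c("*", "-", "X")))
      stop("terminal column mixes stop and sense codons", call. = FALSE)
    message("stripping terminal stop codon column")
    a <- a[, seq_len(3L * (ncod - 1L)), drop = FALSE]
    class(a) <- "aln"; attr(a, "moltype") <- "dna"
    aam <- aam[, -ncod, drop = FALSE]
  }
  if (any(aam == "*")) {
    w <- which(aam == "*", arr.ind = TRUE)[1L, ]
    stop(sprintf("in-frame stop codon in %s at codon %d",
                 rownames(a)[w[1L]], w[2L]), call. = FALSE)
  }
  class(a) <- c("codon_aln", "aln")
  a
}

#' Read and write FASTA
#'
#' Thin wrappers around Biostrings' FASTA reader that enforce the
#' package's alignment invariants (unique ids, legal alphabet). Gaps are
#' retained, order preserved.
#'
#' @param path FASTA file.
#' @param moltype `"dna"` or `"protein"`.
#' @return [read_fasta()]: an `aln`; [write_fasta()]: `path`, invisibly.
#' @export
read_fasta <- function(path, moltype = c("dna", "protein")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("FASTA parse error in ", path,
                                          ": ", conditionMessage(e),
                                          call. = FALSE))
  if (length(ss) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = " "), call. = FALSE)
  seqs <- setNames(as.character(ss), ids)
  alignment(seqs, moltype)
}

#' @rdname read_fasta
#' @param a an `aln`.
#' @param width line-wrap width.
#' @export
write_fasta <- function(a, path, width = 70L) {
  stopifnot(inherits(a, "aln"))
  s <- aln_strings(a)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(s)) {
    writeLines(paste0(">", names(s)[i]), con)
    writeLines(substring(s[i], seq(1L, nchar(s[i]), width),
                         pmin(nchar(s[i]), seq(1L, nchar(s[i]), width) + width - 1L)),
               con)
  }
  invisible(path)
}

translate_codon <- function(cod) {
  if (cod == "---") return("-")
  if (grepl("[^ACGT]", cod)) return("X")
  unname(GENETIC_CODE_DNA[cod])
}

codon_strings <- function(a) {
  ncod <- ncol(a) %/% 3L
  idx <- 3L * (seq_len(ncod) - 1L)
  m <- matrix("", nrow(a), ncod, dimnames = list(rownames(a), NULL))
  for (i in seq_len(nrow(a))) {
    r <- unclass(a)[i, ]
    m[i, ] <- vapply(idx, function(j) paste(r[j + 1:3], collapse = ""), "")
  }
  m
}

translate_matrix <- function(a) {
  cs <- codon_strings(a)
  m <- matrix(vapply(as.vector(cs), translate_codon, ""), nrow = nrow(a))
  rownames(m) <- rownames(a)
  m
}

#' Translate a codon alignment to protein
#'
#' @param a a codon alignment (DNA `aln`, length divisible by 3).
#' @return a protein `aln`; codon gaps become `-`, ambiguous codons `X`.
#' @export
translate_alignment <- function(a) {
  stopifnot(inherits(a, "aln"), attr(a, "moltype") == "dna",
            ncol(a) %% 3L == 0L)
  m <- translate_matrix(a)
  m[m == "*"] <- "X"  # caller should have handled stops; keep alphabet legal
  alignment(m, "protein")
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Expands every amino-acid column of `protein_alignment` to the codon
#' triplet of the matching (ungapped) coding sequence; protein gaps become
#' `---`. Each protein row must be the translation of its CDS under the
#' standard genetic code; a terminal stop codon on the CDS is stripped.
#'
#' @param protein_alignment protein `aln`.
#' @param cds named character vector (or DNA `aln`) of unaligned coding
#'   sequences, ids matching the protein rows.
#' @return a `codon_aln` of length `3 * ncol(protein_alignment)`.
#' @export
backtranslate_alignment <- function(protein_alignment, cds) {
  stopifnot(inherits(protein_alignment, "aln"),
            attr(protein_alignment, "moltype") == "protein")
  if (inherits(cds, "aln")) cds <- aln_strings(cds)
  cds <- toupper(gsub("-", "", cds))
  ids <- rownames(protein_alignment)
  miss <- setdiff(ids, names(cds))
  if (length(miss)) stop("missing CDS for: ", paste(miss, collapse = " "),
                         call. = FALSE)
  out <- matrix("", nrow(protein_alignment), 3L * ncol(protein_alignment))
  rownames(out) <- ids
  for (id in ids) {
    s <- cds[[id]]
    if (nchar(s) %% 3L != 0L)
      stop("CDS length of ", id, " not divisible by 3", call. = FALSE)
    cods <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    aas <- vapply(cods, translate_codon, "")
    if (length(aas) && aas[length(aas)] == "*") {
      cods <- cods[-length(cods)]; aas <- aas[-length(aas)]
    }
    prow <- unclass(protein_alignment)[id, ]
    k <- 0L
    for (j in seq_along(prow)) {
      if (prow[j] == "-") {
        cod <- "---"
      } else {
        k <- k + 1L
        if (k > length(cods))
          stop("CDS of ", id, " shorter than its protein row", call. = FALSE)
        if (aas[k] == "*")
          stop("internal stop codon in CDS of ", id, " at codon ", k,
               call. = FALSE)
        if (aas[k] != prow[j] && prow[j] != "X" && aas[k] != "X")
          stop(sprintf("translation mismatch for %s at protein position %d: CDS gives %s, alignment has %s",
                       id, j, aas[k], prow[j]), call. = FALSE)
        cod <- cods[k]
      }
      out[id, (3L * (j - 1L) + 1L):(3L * j)] <- strsplit(cod, "")[[1L]]
    }
    if (k != length(cods))
      stop("CDS of ", id, " longer than its protein row", call. = FALSE)
  }
  codon_alignment(alignment(out, "dna"), strip_terminal_stop = FALSE)
}

#' Pairwise identity
#'
#' Fraction of identical characters between two rows over columns where
#' neither row has a gap; `N`/`X` count as mismatches.
#'
#' @param a an `aln`.
#' @param idA,idB row ids.
#' @return fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, idA, idB) {
  stopifnot(inherits(a, "aln"))
  m <- unclass(a)
  if (!all(c(idA, idB) %in% rownames(m)))
    stop("id not in alignment", call. = FALSE)
  x <- m[idA, ]; y <- m[idB, ]
  keep <- x != "-" & y != "-"
  if (!any(keep)) stop("no gap-free shared columns", call. = FALSE)
  amb <- if (attr(a, "moltype") == "dna") "N" else "X"
  mean(x[keep] == y[keep] & x[keep] != amb)
}

#' Mean and SD of pairwise identities over a set of id pairs
#'
#' @param a an `aln`.
#' @param pairs 2-column matrix (or list of length-2 vectors) of id pairs.
#' @return list with `identities`, `mean`, `sd` (identities as fractions).
#' @export
identity_summary <- function(a, pairs) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  v <- apply(pairs, 1L, function(p) pairwise_identity(a, p[1L], p[2L]))
  list(identities = v, mean = mean(v), sd = if (length(v) > 1L) sd(v) else NA_real_)
}

#' Region specifications
#'
#' Regions are named 1-based inclusive alignment column intervals, the
#' reporting convention used throughout (`N`, `Central`, `C` or custom
#' names). Internally all slicing is 0-based half-open; [region_spec()]
#' is the single conversion point.
#'
#' @param name character vector of region names.
#' @param start,end 1-based inclusive columns.
#' @param aln_length optional alignment length to validate against.
#' @return data.frame of class `region_spec`.
#' @export
region_spec <- function(name, start, end, aln_length = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L) || any(end < start))
    stop("invalid region bounds", call. = FALSE)
  if (!is.null(aln_length) && any(end > aln_length))
    stop("region out of range for alignment of length ", aln_length,
         call. = FALSE)
  df <- data.frame(name = as.character(name), start = start, end = end,
                   stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  if (nrow(df) > 1L && any(df$start[-1L] <= df$end[-nrow(df)]))
    stop("regions overlap", call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("region_spec", "data.frame")
  df
}

#' @rdname region_spec
#' @param path TSV with columns `group`, `name`, `start`, `end`.
#' @return [read_region_spec()]: named list of `region_spec` by group.
#' @export
read_region_spec <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("group", "name", "start", "end")
  if (!all(need %in% names(df)))
    stop("region TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$group),
         function(d) region_spec(d$name, d$start, d$end))
}

#' Partition an alignment into named regions
#'
#' Concatenating the returned sub-alignments in coordinate order
#' reproduces the covered columns exactly. For codon alignments a region
#' boundary falling inside a codon is trimmed inward to the enclosing
#' codon boundary with a warning, so every piece stays in frame.
#'
#' @param a an `aln` or `codon_aln`.
#' @param regions a [region_spec()].
#' @return named list of sub-alignments.
#' @export
partition_regions <- function(a, regions) {
  stopifnot(inherits(a, "aln"), inherits(regions, "region_spec"))
  if (any(regions$end > ncol(a)))
    stop("region out of range for alignment of length ", ncol(a),
         call. = FALSE)
  codon <- inherits(a, "codon_aln")
  out <- list()
  for (i in seq_len(nrow(regions))) {
    s <- regions$start[i]; e <- regions$end[i]
    if (codon) {
      s2 <- s + (3L - (s - 1L) %% 3L) %% 3L      # next codon start >= s
      e2 <- e - e %% 3L                          # last codon end <= e
      if (s2 != s || e2 != e) {
        warning(sprintf("region %s trimmed to codon frame: %d-%d -> %d-%d",
                        regions$name[i], s, e, s2, e2))
        s <- s2; e <- e2
      }
      if (e < s) stop("region ", regions$name[i],
                      " empty after codon trimming", call. = FALSE)
    }
    sub <- unclass(a)[, s:e, drop = FALSE]
    sub <- alignment(sub, attr(a, "moltype"))
    if (codon) class(sub) <- c("codon_aln", "aln")
    out[[regions$name[i]]] <- sub
  }
  out
}

#' Concatenate alignments column-wise
#' @param ... alignments with identical row ids (in order).
#' @return an `aln` (codon class kept if all inputs are codon alignments).
#' @export
concat_alignments <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !inherits(parts[[1L]], "aln")) parts <- parts[[1L]]
  ids <- rownames(parts[[1L]])
  stopifnot(all(vapply(parts, function(p) identical(rownames(p), ids), TRUE)))
  m <- do.call(cbind, lapply(parts, unclass))
  out <- alignment(m, attr(parts[[1L]], "moltype"))
  if (all(vapply(parts, inherits, TRUE, "codon_aln")))
    class(out) <- c("codon_aln", "aln")
  out
}
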
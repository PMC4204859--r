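# Translation-initiation (Kozak-like) context analysis: position frequency
# matrix over the 10 nt upstream of the start codon, threshold consensus,
# context scoring and start selection.

context_positions <- as.character(-10:-1)

normalize_rna <- function(x) {
  x <- toupper(x)
  gsub("T", "U", x, fixed = TRUE)
}

#' Build a position frequency matrix from start-codon context windows
#'
#' Each window is the 10 nt immediately upstream of a start codon
#' (positions -10..-1). U and T are identified.
#'
#' @param windows Character vector of length-10 windows over {A,C,G,U/T}.
#' @return A 4 x 10 percentage matrix (rows A, U, G, C; columns -10..-1)
#'   with attribute `n_sequences`, of class `context_pfm`.
#' @export
build_pfm <- function(windows) {
  stopifnot(length(windows) >= 1L)
  windows <- normalize_rna(windows)
  bad <- which(nchar(windows) != 10L)
  if (length(bad))
    stop("window(s) not 10 nt long at index: ", paste(bad, collapse = ", "))
  mat <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  if (!all(mat %in% c("A", "U", "G", "C")))
    stop("windows must contain only A, C, G and U/T")
  pfm <- vapply(seq_len(10L), function(j) {
    tab <- table(factor(mat[, j], levels = c("A", "U", "G", "C")))
    100 * as.numeric(tab) / nrow(mat)
  }, numeric(4))
  dimnames(pfm) <- list(c("A", "U", "G", "C"), context_positions)
  structure(pfm, n_sequences = length(windows), class = "context_pfm")
}

#' Read a context PFM from TSV
#'
#' Expected layout: a `nt` column (A/U/G/C) and one column per upstream
#' position -10..-1 holding percentages.
#'
#' @param path TSV file path.
#' @return A `context_pfm` as from [build_pfm()].
#' @export
read_pfm_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("nt" %in% names(df))
  pos <- setdiff(names(df), c("nt", "n_sequences"))
  m <- as.matrix(df[, pos])
  rownames(m) <- normalize_rna(df$nt)
  m <- m[c("A", "U", "G", "C"), , drop = FALSE]
  colnames(m) <- pos
  n <- if ("n_sequences" %in% names(df)) df$n_sequences[1] else NA_integer_
  structure(m, n_sequences = n, class = "context_pfm")
}

#' Derive a threshold consensus from a context PFM
#'
#' Position by position, every nucleotide whose frequency reaches the
#' threshold enters the consensus set. The default threshold of 27% is the
#' value that reproduces the published Sf9 consensus row cell by cell.
#'
#' @param pfm A `context_pfm`.
#' @param threshold Percentage in (0, 100].
#' @return Named list (positions -10..-1) of character vectors, class
#'   `context_consensus`.
#' @export
derive_consensus <- function(pfm, threshold = 27) {
  stopifnot(inherits(pfm, "context_pfm") || (is.matrix(pfm) &&
            all(c("A", "U", "G", "C") %in% rownames(pfm))))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 100)
    stop("threshold must be a percentage in (0, 100]")
  sets <- lapply(seq_len(ncol(pfm)), function(j)
    rownames(pfm)[pfm[, j] >= threshold])
  names(sets) <- colnames(pfm)
  structure(sets, class = "context_consensus")
}

#' @export
print.context_consensus <- function(x, ...) {
  cat("<context_consensus> ",
      paste(vapply(x, function(s)
        if (length(s)) paste(s, collapse = "/") else "-", character(1)),
        collapse = " "), "\n")
  invisible(x)
}

#' Score a start-codon context against a consensus
#'
#' The score is the number of the 10 upstream positions whose nucleotide
#' belongs to the consensus set at that position (what bolded cells encode
#' in published context tables). Invariant under U/T relabelling.
#'
#' @param context Length-10 character scalar (or 10-vector) of nucleotides
#'   at positions -10..-1.
#' @param consensus A `context_consensus`.
#' @return Integer match count in 0..10.
#' @export
score_context <- function(context, consensus) {
  if (length(context) == 10L) context <- paste(context, collapse = "")
  context <- normalize_rna(context)
  stopifnot(nchar(context) == 10L, length(consensus) == 10L)
  nts <- strsplit(context, "", fixed = TRUE)[[1]]
  sum(vapply(seq_len(10L), function(j) nts[j] %in% consensus[[j]],
             logical(1)))
}

#' Log2-odds PWM score of a context (secondary statistic)
#'
#' Sum over positions of `log2(f / 25)` where `f` is the PFM percentage of
#' the observed nucleotide (pseudocount 1%); offered alongside the
#' consensus match count, not used for start selection.
#'
#' @inheritParams score_context
#' @param pfm A `context_pfm`.
#' @return Numeric log2-odds score.
#' @export
score_context_pwm <- function(context, pfm) {
  if (length(context) == 10L) context <- paste(context, collapse = "")
  context <- normalize_rna(context)
  stopifnot(nchar(context) == 10L)
  nts <- strsplit(context, "", fixed = TRUE)[[1]]
  sum(vapply(seq_len(10L), function(j)
    log2((pfm[nts[j], j] + 1) / 25), numeric(1)))
}

#' Select the most favourable in-frame start codon
#'
#' Scans the annotated reading frame for AUG codons from `orf_start` up to
#' (not including) the first in-frame stop, scores the 10-nt upstream
#' context of each against the consensus, and returns the highest-scoring
#' candidate (ties resolved in favour of the 5'-most). Candidates with
#' fewer than 10 nt of upstream sequence are skipped with a warning.
#'
#' @param cdna Character scalar: cDNA (or mRNA) sequence, T or U.
#' @param consensus A `context_consensus`.
#' @param orf_start 0-based offset of the annotated ORF's first nucleotide
#'   (default 0: frame of the sequence start).
#' @return List with `cds_offset` (0-based AUG position), `context`,
#'   `score`, and `candidates` (data frame of all scored AUGs).
#' @export
select_start <- function(cdna, consensus, orf_start = 0L) {
  seq <- normalize_rna(as.character(cdna))
  stopifnot(length(seq) == 1L)
  orf_start <- as.integer(orf_start)
  stopifnot(orf_start >= 0L)
  nts <- strsplit(seq, "", fixed = TRUE)[[1]]
  stops <- c("UAA", "UAG", "UGA")
  starts <- integer(); pos <- orf_start
  while (pos + 3L <= length(nts)) {
    codon <- paste(nts[(pos + 1L):(pos + 3L)], collapse = "")
    if (codon %in% stops && pos > orf_start) break
    if (codon == "AUG") starts <- c(starts, pos)
    pos <- pos + 3L
  }
  if (length(starts) == 0L)
    stop("no in-frame AUG found in the annotated reading frame")
  ok <- starts >= 10L
  if (any(!ok))
    warning(sum(!ok), " candidate AUG(s) with < 10 nt of upstream ",
            "sequence skipped")
  starts <- starts[ok]
  if (length(starts) == 0L)
    stop("no candidate AUG has a full 10-nt upstream context")
  ctx <- vapply(starts, function(s)
    paste(nts[(s - 9L):s], collapse = ""), character(1))
  sc <- vapply(ctx, score_context, integer(1), consensus = consensus)
  candidates <- data.frame(cds_offset = starts, context = ctx, score = sc,
                           row.names = NULL)
  best <- which(sc == max(sc))[1]  # 5'-most on ties (starts are ascending)
  list(cds_offset = starts[best], context = ctx[best],
       score = unname(sc[best]), candidates = candidates)
}
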
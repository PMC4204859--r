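# Coding gene models: intron phases, exon phase/size notation, splice sites.

#' Construct a coding gene model
#'
#' A gene model holds the ordered coding exons of one gene in one species,
#' in 0-based half-open coordinates on the coding strand, together with the
#' lengths of the introns separating them. The coordinate origin is the
#' first coding base; the stop codon is included in the CDS.
#'
#' @param species_id Character scalar naming the species (or gene).
#' @param exon_lengths Integer vector of exon lengths in nt, 5' to 3'.
#' @param intron_lengths Integer vector of intron lengths in nt, one per
#'   exon junction (`length(exon_lengths) - 1` values).
#' @return An object of class `gene_model` with fields `species_id`,
#'   `exons` (two-column matrix of genomic start/end, half-open),
#'   `intron_lengths` and `cds_length`.
#' @examples
#' gm <- gene_model("toy", exon_lengths = c(99, 120), intron_lengths = 500)
#' summarize_gene(gm)
#' @export
gene_model <- function(species_id, exon_lengths, intron_lengths = integer()) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  exon_lengths <- as.integer(exon_lengths)
  intron_lengths <- as.integer(intron_lengths)
  if (length(exon_lengths) < 1L || any(exon_lengths < 1L))
    stop("every exon must be at least 1 nt long")
  if (length(intron_lengths) != length(exon_lengths) - 1L)
    stop("need exactly one intron length per exon junction: ",
         length(exon_lengths) - 1L, " expected, got ", length(intron_lengths))
  if (length(intron_lengths) && any(intron_lengths < 1L))
    stop("intron lengths must be positive")
  starts <- integer(length(exon_lengths))
  ends <- integer(length(exon_lengths))
  pos <- 0L
  for (i in seq_along(exon_lengths)) {
    starts[i] <- pos
    ends[i] <- pos + exon_lengths[i]
    pos <- ends[i] + if (i < length(exon_lengths)) intron_lengths[i] else 0L
  }
  structure(
    list(species_id = species_id,
         exons = cbind(start = starts, end = ends),
         intron_lengths = intron_lengths,
         cds_length = sum(exon_lengths)),
    class = "gene_model")
}

#' Validate a gene model's invariants
#'
#' Checks that exons are strictly increasing, non-overlapping, at least 1 nt
#' each, that there is one intron length per junction, and that exon lengths
#' sum to the CDS length.
#'
#' @param model A `gene_model`.
#' @return The model, invisibly; errors describe the violated invariant.
#' @export
validate_gene_model <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  len <- ex[, "end"] - ex[, "start"]
  if (any(len < 1L)) stop("exon of length < 1 nt")
  if (nrow(ex) > 1L) {
    if (any(ex[-1L, "start"] < ex[-nrow(ex), "end"]))
      stop("exons overlap or are not strictly increasing")
  }
  if (length(model$intron_lengths) != nrow(ex) - 1L)
    stop("intron count must be exon count - 1")
  if (sum(len) != model$cds_length)
    stop("exon lengths do not sum to cds_length")
  invisible(model)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: %d exons, %d introns, CDS %d nt\n",
              x$species_id, nrow(x$exons), length(x$intron_lengths),
              x$cds_length))
  invisible(x)
}

#' Exon lengths of a gene model
#' @param model A `gene_model`.
#' @return Integer vector of exon lengths in nt.
#' @export
exon_lengths <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  as.integer(model$exons[, "end"] - model$exons[, "start"])
}

#' Intron phase at a CDS offset
#'
#' The phase of an intron is determined by the amount of coding sequence
#' preceding it: phase 0 introns fall between two codons, phase 1 introns
#' after the first nucleotide of a codon, and phase 2 introns between the
#' second and third nucleotide.
#'
#' @param cds_offset Non-negative integer (vectorised): nt of CDS upstream
#'   of the intron.
#' @return Integer in 0..2, `cds_offset mod 3`.
#' @examples
#' intron_phase(c(153, 154, 155))  # 0 1 2
#' @export
intron_phase <- function(cds_offset) {
  cds_offset <- as.integer(cds_offset)
  if (any(is.na(cds_offset)) || any(cds_offset < 0L))
    stop("cds_offset must be a non-negative integer")
  cds_offset %% 3L
}

#' Infer intron insertion sites from a gene model
#'
#' One site per exon junction, ordered 5' to 3'. The CDS offset of a site is
#' the cumulative exon length upstream of the junction; its phase follows
#' from [intron_phase()].
#'
#' @param model A `gene_model`.
#' @return A data frame with columns `species_id`, `site`, `cds_offset`,
#'   `phase`, `intron_length`. Zero rows for an intronless gene.
#' @export
infer_intron_sites <- function(model) {
  validate_gene_model(model)
  n <- length(model$intron_lengths)
  if (n == 0L)
    return(data.frame(species_id = character(), site = integer(),
                      cds_offset = integer(), phase = integer(),
                      intron_length = integer()))
  offs <- cumsum(exon_lengths(model))[seq_len(n)]
  data.frame(species_id = model$species_id,
             site = seq_len(n),
             cds_offset = offs,
             phase = intron_phase(offs),
             intron_length = model$intron_lengths)
}

#' Summarise a gene model
#'
#' @param model A `gene_model`.
#' @return A list with `n_exons`, `n_introns`, `total_intronic_bp`
#'   (the "total IS" of the comparative tables) and `exon_nt_lengths`.
#' @export
summarize_gene <- function(model) {
  validate_gene_model(model)
  list(n_exons = nrow(model$exons),
       n_introns = length(model$intron_lengths),
       total_intronic_bp = as.integer(sum(model$intron_lengths)),
       exon_nt_lengths = exon_lengths(model))
}

# ---- exon phase/size notation ----------------------------------------------

#' Exon phase/size notation
#'
#' An exon is written `u-c-d` where `c` (bold in structure diagrams) is the
#' number of codons having at least one nucleotide in the exon and `u`, `d`
#' (italic) are the numbers of nucleotides of the flanking split codons that
#' lie inside the exon. `u` therefore equals `(3 - upstream intron phase)
#' mod 3`, and `d` equals the downstream intron phase. For example, an exon
#' written 1-51-0 lies downstream of a phase-2 intron (carrying the single
#' nucleotide that completes the split codon) and upstream of a phase-0
#' intron.
#'
#' @param u Integer 0..2, nt of the upstream split codon inside the exon.
#' @param codons Positive integer, codons with >= 1 nt in the exon.
#' @param d Integer 0..2, nt of the downstream split codon inside the exon.
#' @return An object of class `exon_notation`.
#' @examples
#' notation_to_length(exon_notation(1, 51, 0))  # 151
#' @export
exon_notation <- function(u, codons, d) {
  u <- as.integer(u); codons <- as.integer(codons); d <- as.integer(d)
  stopifnot(length(u) == 1L, length(codons) == 1L, length(d) == 1L)
  if (u < 0L || u > 2L || d < 0L || d > 2L)
    stop("flank counts u and d must be in 0..2")
  full <- codons - (u > 0L) - (d > 0L)
  if (codons < 1L || full < 0L)
    stop("codon count ", codons, " too small to admit the flanking fragments")
  if (3L * full + u + d < 1L)
    stop("notation describes an empty exon")
  structure(list(u = u, codons = codons, d = d), class = "exon_notation")
}

#' @export
print.exon_notation <- function(x, ...) {
  cat(sprintf("<exon_notation> %d-%d-%d (%d nt)\n",
              x$u, x$codons, x$d, notation_to_length(x)))
  invisible(x)
}

#' @export
format.exon_notation <- function(x, ...) {
  sprintf("%d-%d-%d", x$u, x$codons, x$d)
}

#' Nucleotide length of an exon from its notation
#'
#' `L = u + 3 * (codons - [u>0] - [d>0]) + d`: the flanking split-codon
#' fragments contribute their own nucleotide counts and every other counted
#' codon lies fully inside the exon.
#'
#' @param n An `exon_notation`.
#' @return Integer nt length.
#' @export
notation_to_length <- function(n) {
  stopifnot(inherits(n, "exon_notation"))
  as.integer(n$u + 3L * (n$codons - (n$u > 0L) - (n$d > 0L)) + n$d)
}

#' Phase of the intron upstream/downstream of a notated exon
#' @param n An `exon_notation`.
#' @return Named integer vector `c(upstream =, downstream =)` of intron
#'   phases.
#' @export
notation_phases <- function(n) {
  stopifnot(inherits(n, "exon_notation"))
  c(upstream = (3L - n$u) %% 3L, downstream = n$d)
}

#' Merge two exons across a lost intron
#'
#' The two exons must flank the same intron: the downstream fragment of the
#' split codon carried by `a` and the upstream fragment carried by `b` must
#' complete one codon (`b$u == (3 - a$d) mod 3`, both zero for a phase-0
#' boundary). The merged codon count is `a$codons + b$codons` minus 1 when
#' the boundary codon was split (it was counted in both exons).
#'
#' @param a,b `exon_notation` objects, `a` upstream of `b`.
#' @return The merged `exon_notation`; its nt length is the sum of the two
#'   input lengths.
#' @examples
#' merge_exons(exon_notation(1, 51, 0), exon_notation(0, 58, 0))  # 1-109-0
#' @export
merge_exons <- function(a, b) {
  stopifnot(inherits(a, "exon_notation"), inherits(b, "exon_notation"))
  if (b$u != (3L - a$d) %% 3L)
    stop("boundary fragments are incompatible: downstream exon must carry (3 - ",
         a$d, ") mod 3 nt of the split codon, has ", b$u)
  out <- exon_notation(a$u, a$codons + b$codons - (a$d > 0L), b$d)
  stopifnot(notation_to_length(out) ==
              notation_to_length(a) + notation_to_length(b))
  out
}

#' Split an exon at an internal offset (inverse of merge)
#'
#' The new intron falls `internal_offset` nt into the exon; its phase is
#' computed on the codon frame implied by the exon's upstream flank. Offsets
#' that would place the boundary inside an already-split flanking codon
#' (so that one fragment cannot be written in `u-c-d` notation) are
#' rejected.
#'
#' @param n An `exon_notation`.
#' @param internal_offset Integer nt, `0 < internal_offset < length(n)`.
#' @return List of two `exon_notation` objects; `merge_exons()` of the pair
#'   returns `n`.
#' @export
split_exon <- function(n, internal_offset) {
  stopifnot(inherits(n, "exon_notation"))
  k <- as.integer(internal_offset)
  L <- notation_to_length(n)
  if (k <= 0L || k >= L)
    stop("internal_offset must lie strictly inside the exon (1..", L - 1L, ")")
  up_phase <- (3L - n$u) %% 3L
  p <- (up_phase + k) %% 3L          # phase of the new intron
  d_left <- p
  u_right <- (3L - p) %% 3L
  full_left <- (k - n$u - d_left) / 3L
  full_right <- ((L - k) - u_right - n$d) / 3L
  if (full_left < 0L || full_right < 0L)
    stop("offset ", k, " would split a codon that is already split by a ",
         "flanking intron; the fragment cannot be notated")
  left <- exon_notation(n$u, (n$u > 0L) + full_left + (d_left > 0L), d_left)
  right <- exon_notation(u_right, (u_right > 0L) + full_right + (n$d > 0L),
                         n$d)
  stopifnot(notation_to_length(left) == k,
            notation_to_length(right) == L - k)
  list(left, right)
}

#' Exon notations of all exons in a gene model
#'
#' The first exon has `u = 0` and the last `d = 0` (no flanking intron).
#'
#' @param model A `gene_model`.
#' @return List of `exon_notation`, one per exon.
#' @export
model_exon_notations <- function(model) {
  sites <- infer_intron_sites(model)
  phases <- sites$phase
  lens <- exon_lengths(model)
  up <- c(0L, (3L - phases) %% 3L)
  dn <- c(phases, 0L)
  lapply(seq_along(lens), function(i) {
    full <- (lens[i] - up[i] - dn[i]) / 3L
    exon_notation(up[i], (up[i] > 0L) + full + (dn[i] > 0L), dn[i])
  })
}

# ---- splice sites -----------------------------------------------------------

#' Check canonical GT..AG splice sites
#'
#' For each intron of the model, reports whether the genomic sequence begins
#' with GT at its first two positions and ends with AG at its last two
#' (the canonical spliceosomal donor/acceptor dinucleotides). Non-canonical
#' classes (GC-AG, AT-AC) are reported only through the boolean flag.
#'
#' @param model A `gene_model`.
#' @param genomic_seq Character scalar (or `Biostrings::DNAString`): the
#'   gene's sequence on the coding strand, starting at the first coding
#'   base, covering all exons and introns.
#' @return Data frame with columns `intron`, `donor`, `acceptor`,
#'   `canonical`. Zero rows for an intronless gene.
#' @export
validate_splice_sites <- function(model, genomic_seq) {
  validate_gene_model(model)
  seq <- toupper(as.character(genomic_seq))
  stopifnot(length(seq) == 1L)
  span <- model$exons[nrow(model$exons), "end"]
  if (nchar(seq) < span)
    stop("genomic sequence (", nchar(seq), " nt) shorter than the gene span (",
         span, " nt)")
  n <- length(model$intron_lengths)
  if (n == 0L)
    return(data.frame(intron = integer(), donor = character(),
                      acceptor = character(), canonical = logical()))
  donor <- acceptor <- character(n)
  for (i in seq_len(n)) {
    istart <- model$exons[i, "end"]          # 0-based start of intron i
    iend <- istart + model$intron_lengths[i] # 0-based half-open end
    donor[i] <- substr(seq, istart + 1L, istart + 2L)
    acceptor[i] <- substr(seq, iend - 1L, iend)
  }
  data.frame(intron = seq_len(n), donor = donor, acceptor = acceptor,
             canonical = donor == "GT" & acceptor == "AG")
}

# ---- construction from printed site tables ---------------------------------

#' Build a gene model from intron phases and lengths alone
#'
#' Comparative tables print, per species, the phase and length of each
#' intron but not the exon boundaries. Any exon boundaries consistent with
#' the printed phases give the same intron count, total intronic size and
#' per-site phases, so this constructor places junctions at evenly spaced
#' offsets adjusted to the required phase.
#'
#' @param species_id Character scalar.
#' @param phases Integer vector of intron phases (0..2), 5' to 3'.
#' @param intron_lengths Integer vector of intron lengths, same length.
#' @param spacing Approximate exon size used to place the synthetic
#'   boundaries (default 90 nt).
#' @param cds_length Optional CDS length (incl. stop); defaults to one
#'   spacing beyond the last junction, rounded to a codon boundary.
#' @return A `gene_model` whose [infer_intron_sites()] phases equal
#'   `phases` and whose intron lengths equal `intron_lengths`.
#' @export
gene_model_from_sites <- function(species_id, phases, intron_lengths,
                                  spacing = 90L, cds_length = NULL) {
  phases <- as.integer(phases)
  intron_lengths <- as.integer(intron_lengths)
  stopifnot(length(phases) == length(intron_lengths),
            all(phases %in% 0:2))
  n <- length(phases)
  if (n == 0L) {
    if (is.null(cds_length)) cds_length <- as.integer(spacing) * 3L %/% 3L * 3L
    return(gene_model(species_id, exon_lengths = cds_length))
  }
  base <- as.integer(spacing) * seq_len(n)
  offs <- base + (phases - base) %% 3L
  if (any(diff(offs) <= 0L))
    stop("spacing too small to separate ", n, " junctions")
  if (is.null(cds_length))
    cds_length <- offs[n] + as.integer(spacing) +
      (3L - (offs[n] + as.integer(spacing)) %% 3L) %% 3L
  if (cds_length <= offs[n] || cds_length %% 3L != 0L)
    stop("cds_length must exceed the last junction and be a codon multiple")
  gene_model(species_id, exon_lengths = diff(c(0L, offs, cds_length)),
             intron_lengths = intron_lengths)
}
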
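# Readers and writers for gene models, alignments, site tables and trees.

#' Read gene models from the simple TSV gene-structure format
#'
#' Three tab-separated columns: `species_id`, `exon_lengths` (comma-joined
#' nt), `intron_lengths` (comma-joined nt, empty for intronless genes).
#'
#' @param path File path.
#' @return Named list of `gene_model` objects.
#' @export
read_gene_models_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("species_id", "exon_lengths", "intron_lengths")
  if (!all(need %in% names(df)))
    stop("gene-model TSV needs columns: ", paste(need, collapse = ", "))
  parse_num <- function(s) {
    s <- gsub("[[:space:]]", "", s)
    if (!nzchar(s)) return(integer())
    as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  }
  models <- lapply(seq_len(nrow(df)), function(i)
    gene_model(df$species_id[i],
               exon_lengths = parse_num(df$exon_lengths[i]),
               intron_lengths = parse_num(df$intron_lengths[i])))
  names(models) <- df$species_id
  models
}

#' Write gene models to the simple TSV gene-structure format
#' @param models List of `gene_model` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models_tsv <- function(models, path) {
  df <- data.frame(
    species_id = vapply(models, function(m) m$species_id, character(1)),
    exon_lengths = vapply(models, function(m)
      paste(exon_lengths(m), collapse = ","), character(1)),
    intron_lengths = vapply(models, function(m)
      paste(m$intron_lengths, collapse = ","), character(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' CDS features are grouped by their `Parent` (or `ID` when no parent is
#' present), ordered along the transcript, and normalised to the coding
#' strand: minus-strand genes are re-ordered so exon 1 is 5' in the mRNA.
#' The GFF3 `phase` column, where present, is cross-checked against the
#' phases computed from cumulative exon lengths and any mismatch triggers a
#' warning (the computed phases win).
#'
#' @param path GFF3 file path.
#' @param species_from Attribute used as the model id: `"parent"` (default)
#'   or `"seqid"`.
#' @return Named list of `gene_model` objects.
#' @export
read_gene_models_gff3 <- function(path, species_from = c("parent", "seqid")) {
  species_from <- match.arg(species_from)
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) stop("no CDS features in ", path)
  # Parent is a CharacterList; take the first parent of each feature
  p <- gr$Parent
  parent <- vapply(seq_along(gr), function(i) {
    pi <- p[[i]]
    if (length(pi)) as.character(pi[1]) else as.character(gr$ID[i])
  }, character(1))
  key <- if (species_from == "seqid")
    as.character(GenomicRanges::seqnames(gr)) else parent
  out <- list()
  for (k in unique(key)) {
    sub <- gr[key == k]
    minus <- as.character(BiocGenerics::strand(sub))[1] == "-"
    ord <- order(BiocGenerics::start(sub), decreasing = minus)
    sub <- sub[ord]
    exlen <- BiocGenerics::width(sub)
    if (length(sub) > 1L) {
      st <- BiocGenerics::start(sub); en <- BiocGenerics::end(sub)
      inlen <- if (minus) st[-length(st)] - en[-1L] - 1L
               else st[-1L] - en[-length(en)] - 1L
    } else inlen <- integer()
    m <- gene_model(k, exon_lengths = exlen, intron_lengths = inlen)
    gff_phase <- suppressWarnings(as.integer(as.character(sub$phase)))
    if (!all(is.na(gff_phase))) {
      cum <- c(0L, cumsum(exlen)[-length(exlen)])
      expect <- (3L - cum %% 3L) %% 3L  # GFF3 phase: nt to skip to a codon start
      bad <- which(!is.na(gff_phase) & gff_phase != expect)
      if (length(bad))
        warning("GFF3 phase mismatch for ", k, " at CDS segment(s) ",
                paste(bad, collapse = ", "), "; computed phases used")
    }
    out[[k]] <- m
  }
  out
}

#' Read a protein multiple alignment from aligned FASTA
#'
#' @param path Aligned FASTA file; all records must have equal width.
#' @return Named character vector of aligned sequences (upper case).
#' @export
read_alignment_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(aa))
  if (length(unique(nchar(out))) != 1L)
    stop("alignment rows differ in width; is ", path, " really aligned?")
  out
}

#' Write a protein alignment to FASTA
#' @param msa Named character vector of equal-width aligned sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(msa, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(msa), path, width = 60L)
  invisible(path)
}

#' Read an intron-site table fixture
#'
#' The packaged site tables reproduce the layout of the comparative-table
#' figures: one row per species, one column per labelled insertion site
#' holding `phase/length` (or a bare presence mark `X`/`+`), plus columns
#' `total_is`, `nb_introns` and optional `truncated`, `flag` metadata.
#'
#' @param path TSV file path.
#' @return A list with elements `cells` (long data frame: `species`,
#'   `label`, `phase`, `intron_length`, `present`), `species` (per-species
#'   data frame with `total_is`, `nb_introns`, `truncated`, `flag`) and
#'   `labels` (site labels in 5'-to-3' order).
#' @export
read_site_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  meta_cols <- intersect(c("lineage", "group", "species", "total_is",
                           "nb_introns", "truncated", "flag"), names(df))
  labels <- setdiff(names(df), meta_cols)
  cells <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    vals <- as.character(df[i, labels])
    present <- nzchar(vals) & !is.na(vals)
    phase <- rep(NA_integer_, length(vals))
    ilen <- rep(NA_integer_, length(vals))
    has_pl <- grepl("/", vals, fixed = TRUE)
    phase[has_pl] <- as.integer(sub("/.*", "", vals[has_pl]))
    ilen[has_pl] <- as.integer(gsub(",", "", sub(".*/", "", vals[has_pl])))
    data.frame(species = df$species[i], label = labels, phase = phase,
               intron_length = ilen, present = present,
               stringsAsFactors = FALSE)
  }))
  species <- data.frame(
    species = df$species,
    lineage = if ("lineage" %in% names(df)) df$lineage else NA_character_,
    total_is = if ("total_is" %in% names(df))
      as.integer(gsub("[^0-9]", "", df$total_is)) else NA_integer_,
    nb_introns = if ("nb_introns" %in% names(df))
      as.integer(gsub("[^0-9]", "", df$nb_introns)) else NA_integer_,
    truncated = if ("truncated" %in% names(df))
      df$truncated %in% c("TRUE", "yes", "1") else FALSE,
    flag = if ("flag" %in% names(df)) df$flag else "",
    stringsAsFactors = FALSE)
  list(cells = cells, species = species, labels = labels)
}

#' Path to a packaged fixture file
#' @param ... Path components under the package's `extdata` directory; with
#'   no arguments, lists the available fixtures.
#' @return File path(s).
#' @export
intronarch_extdata <- function(...) {
  if (nargs() == 0L)
    return(dir(system.file("extdata", package = "intronarch")))
  system.file("extdata", ..., package = "intronarch", mustWork = TRUE)
}

#' Site clusters from a published-style site table
#'
#' Reconstructs labelled [cluster_sites()]-style clusters directly from a
#' site table ([read_site_table()]): one cluster per table column, members
#' = species with a filled cell. Because the table already assigns sites
#' to homologous columns, no alignment is needed; cluster columns are the
#' table's ordinal positions (or a supplied map of true alignment
#' columns), phases the modal printed phase per column.
#'
#' @param tbl A list from [read_site_table()].
#' @param column_map Optional named integer vector label -> alignment
#'   column (defaults to ordinal positions).
#' @return Labelled cluster list.
#' @export
clusters_from_site_table <- function(tbl, column_map = NULL) {
  lapply(seq_along(tbl$labels), function(j) {
    lab <- tbl$labels[j]
    rows <- tbl$cells[tbl$cells$label == lab & tbl$cells$present, ,
                      drop = FALSE]
    ph <- rows$phase[!is.na(rows$phase)]
    phase <- if (length(ph)) as.integer(names(sort(table(ph),
                                                   decreasing = TRUE))[1])
             else NA_integer_
    col <- if (!is.null(column_map)) unname(column_map[lab]) else j
    sites <- if (nrow(rows)) {
      data.frame(species_id = rows$species,
                 alignment_column = col,
                 phase = ifelse(is.na(rows$phase), phase, rows$phase),
                 intron_length = rows$intron_length)
    } else {
      data.frame(species_id = character(), alignment_column = integer(),
                 phase = integer(), intron_length = integer())
    }
    list(column = col, phase = phase, members = unique(rows$species),
         sites = sites, labels = lab)
  })
}

#' Presence/absence matrix straight from a site table
#'
#' Filled cells are `present`, blanks `absent`, except that for a species
#' flagged as 5'-truncated every blank upstream of its first filled cell is
#' `unknown` (the region is missing, not intron-free).
#'
#' @param tbl A list from [read_site_table()].
#' @return Character matrix species x labels with entries
#'   "present"/"absent"/"unknown".
#' @export
site_table_presence <- function(tbl) {
  species <- tbl$species$species
  m <- matrix("absent", nrow = length(species), ncol = length(tbl$labels),
              dimnames = list(species, tbl$labels))
  for (i in seq_along(species)) {
    cells <- tbl$cells[tbl$cells$species == species[i], ]
    cells <- cells[match(tbl$labels, cells$label), ]
    m[i, cells$present] <- "present"
    if (tbl$species$truncated[i] && any(cells$present)) {
      first <- which(cells$present)[1]
      if (first > 1L) m[i, seq_len(first - 1L)] <- "unknown"
    }
  }
  m
}

#' Read a node-age table
#'
#' @param path TSV with columns `node` (leaf or internal node label) and
#'   `age_mya`.
#' @return Named numeric vector of ages in MYA.
#' @export
read_node_ages <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("node", "age_mya") %in% names(df)))
    stop("node-age TSV needs columns node, age_mya")
  stats::setNames(as.numeric(df$age_mya), df$node)
}
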
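# Projection of intron insertion sites onto a protein alignment, clustering
# of homologous sites, lineage labelling, near intron pairs.

#' Convert a CDS offset to a protein residue and phase
#'
#' A phase-0 site at residue `r` lies between residues `r - 1` and `r`;
#' phase 1/2 sites fall inside residue `r`'s codon. This convention makes
#' `3 * delta(residue) + delta(phase)` an exact nucleotide distance between
#' insertion points.
#'
#' @param cds_offset Non-negative integer nt offset(s).
#' @return Data frame with columns `residue_index` (0-based) and `phase`.
#' @examples
#' cds_to_residue(152)  # residue 50, phase 2
#' @export
cds_to_residue <- function(cds_offset) {
  cds_offset <- as.integer(cds_offset)
  if (any(is.na(cds_offset)) || any(cds_offset < 0L))
    stop("cds_offset must be a non-negative integer")
  data.frame(residue_index = cds_offset %/% 3L, phase = cds_offset %% 3L)
}

gap_chars <- c("-", ".")

# 0-based alignment columns of the non-gap positions of one aligned row
ungapped_columns <- function(row) {
  chars <- strsplit(row, "", fixed = TRUE)[[1]]
  which(!(chars %in% gap_chars)) - 1L
}

#' Project intron sites onto a protein multiple alignment
#'
#' Maps each site's CDS offset to the residue containing (or, for phase 0,
#' following) the insertion point, then to the alignment column of that
#' residue in the species' row, skipping gap columns.
#'
#' @param sites Data frame with columns `species_id`, `cds_offset` (as
#'   returned by [infer_intron_sites()]; extra columns such as
#'   `intron_length` are carried through).
#' @param msa Named character vector of aligned protein sequences (names =
#'   species ids), or a path readable by [read_alignment_fasta()].
#' @return Data frame of aligned sites: `species_id`, `residue_index`,
#'   `alignment_column` (0-based), `phase`, plus carried columns.
#' @export
project_sites <- function(sites, msa) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa))
    msa <- read_alignment_fasta(msa)
  stopifnot(is.data.frame(sites),
            all(c("species_id", "cds_offset") %in% names(sites)))
  cols <- lapply(msa, ungapped_columns)
  res <- cds_to_residue(sites$cds_offset)
  out <- cbind(sites, res)
  out$alignment_column <- NA_integer_
  for (i in seq_len(nrow(out))) {
    sp <- out$species_id[i]
    if (!sp %in% names(cols))
      stop("species ", sp, " is not in the alignment")
    uc <- cols[[sp]]
    ri <- out$residue_index[i]
    if (ri >= length(uc))
      stop("site at CDS offset ", out$cds_offset[i], " maps to residue ",
           ri, " beyond the aligned sequence of ", sp,
           " (", length(uc), " residues)")
    out$alignment_column[i] <- uc[ri + 1L]
  }
  out
}

#' Project a single intron site
#' @param site One-row data frame or list with `species_id`, `cds_offset`.
#' @inheritParams project_sites
#' @return One-row data frame as from [project_sites()].
#' @export
project_site <- function(site, msa) {
  project_sites(as.data.frame(site[c("species_id", "cds_offset")]), msa)
}

#' Cluster homologous insertion sites across taxa
#'
#' Sites are grouped by single linkage: two sites join the same cluster when
#' their alignment columns differ by at most `column_tolerance` *and* their
#' phases are identical (a conserved insertion site conserves its phase;
#' equal column with differing phase is treated as non-homologous). The
#' default tolerance 0 requires exact column identity.
#'
#' @param sites Data frame of aligned sites from [project_sites()].
#' @param column_tolerance Non-negative integer, maximum column gap joined
#'   by single linkage (default 0).
#' @return List of clusters ordered by column; each cluster is a list with
#'   `column` (minimum member column), `phase`, `members` (species ids),
#'   `sites` (the member rows) and `labels` (filled by [label_clusters()]).
#' @export
cluster_sites <- function(sites, column_tolerance = 0L) {
  stopifnot(is.data.frame(sites),
            all(c("species_id", "alignment_column", "phase") %in% names(sites)))
  column_tolerance <- as.integer(column_tolerance)
  stopifnot(column_tolerance >= 0L)
  if (nrow(sites) == 0L) return(list())
  clusters <- list()
  for (ph in sort(unique(sites$phase))) {
    sub <- sites[sites$phase == ph, , drop = FALSE]
    sub <- sub[order(sub$alignment_column), , drop = FALSE]
    brk <- c(0L, which(diff(sub$alignment_column) > column_tolerance),
             nrow(sub))
    for (g in seq_len(length(brk) - 1L)) {
      rows <- sub[(brk[g] + 1L):brk[g + 1L], , drop = FALSE]
      clusters[[length(clusters) + 1L]] <- list(
        column = min(rows$alignment_column),
        phase = ph,
        members = unique(rows$species_id),
        sites = rows,
        labels = character())
    }
  }
  ord <- order(vapply(clusters, `[[`, integer(1), "column"),
               vapply(clusters, `[[`, integer(1), "phase"))
  clusters[ord]
}

cluster_label <- function(cl) {
  if (length(cl$labels)) cl$labels[1] else
    sprintf("col%d.p%d", cl$column, cl$phase)
}

#' Label site clusters by reference lineage
#'
#' Clusters containing at least one of the reference species are numbered
#' 1..n in 5'-to-3' column order and labelled `i<n><suffix>`. Passing all
#' species of a lineage as the reference reproduces the published
#' numbering when the primary reference species lacks one of the lineage's
#' sites (e.g. a site restricted to one family still occupies its ordinal).
#' Clusters already labelled by an earlier pass keep their first label as
#' primary; later passes append secondary labels.
#'
#' @param clusters List of clusters from [cluster_sites()].
#' @param reference Character vector of reference species ids (a single
#'   species or a whole lineage).
#' @param suffix Single-letter lineage suffix (e.g. "l", "h", "c").
#' @return The cluster list with `labels` extended.
#' @export
label_clusters <- function(clusters, reference, suffix) {
  stopifnot(is.character(reference), length(reference) >= 1L,
            is.character(suffix), nchar(suffix) == 1L)
  known <- unique(unlist(lapply(clusters, `[[`, "members")))
  if (!any(reference %in% known))
    stop("reference species not found in any cluster: ",
         paste(reference, collapse = ", "))
  eligible <- which(vapply(clusters, function(cl)
    any(cl$members %in% reference), logical(1)))
  # clusters are already in column order; number sequentially
  for (k in seq_along(eligible)) {
    i <- eligible[k]
    clusters[[i]]$labels <- c(clusters[[i]]$labels,
                              sprintf("i%d%s", k, suffix))
  }
  clusters
}

#' Retrieve a cluster by label
#' @param clusters Labelled cluster list.
#' @param label Label to look up (primary or secondary).
#' @return The matching cluster, or an error.
#' @export
get_cluster <- function(clusters, label) {
  hit <- which(vapply(clusters, function(cl) label %in% cl$labels,
                      logical(1)))
  if (length(hit) != 1L)
    stop("label ", label, " matches ", length(hit), " clusters")
  clusters[[hit]]
}

#' Detect near intron pairs
#'
#' Two distinct insertion-site clusters form a near intron pair when their
#' insertion points are separated by at most `max_nt_distance` coding
#' nucleotides, a configuration suggestive of intron sliding rather than
#' independent gain. The distance is measured on a species carried by both
#' clusters (the `scaffold` species if it belongs to both, else any common
#' member) as the difference of `3 * residue + phase`; when the clusters
#' share no species it falls back to `3 * delta(column) + delta(phase)`.
#' Pairs at distance 0 sharing a member species are the same site and are
#' not reported.
#'
#' @param clusters Labelled cluster list from [label_clusters()].
#' @param max_nt_distance Maximum separation in nt (default 32).
#' @param scaffold Optional species id preferred for gap-aware distances.
#' @return Data frame with `label_a`, `label_b`, `nt_distance`,
#'   `measured_on` (species id or "columns").
#' @export
near_intron_pairs <- function(clusters, max_nt_distance = 32L,
                              scaffold = NULL) {
  max_nt_distance <- as.integer(max_nt_distance)
  out <- data.frame(label_a = character(), label_b = character(),
                    nt_distance = integer(), measured_on = character(),
                    stringsAsFactors = FALSE)
  n <- length(clusters)
  if (n < 2L) return(out)
  point <- function(cl, sp) {
    row <- cl$sites[cl$sites$species_id == sp, , drop = FALSE][1, ]
    3L * row$residue_index + row$phase
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- clusters[[i]]; b <- clusters[[j]]
    common <- intersect(a$members, b$members)
    if (length(common)) {
      sp <- if (!is.null(scaffold) && scaffold %in% common) scaffold
            else common[1]
      d <- abs(point(a, sp) - point(b, sp))
      on <- sp
    } else {
      d <- abs(3L * (b$column - a$column) + (b$phase - a$phase))
      on <- "columns"
    }
    if (d == 0L && length(common)) next  # same site, not a pair
    if (d <= max_nt_distance)
      out[nrow(out) + 1L, ] <- list(cluster_label(a), cluster_label(b),
                                    as.integer(d), on)
  }
  out
}

#' Presence/absence matrix of sites across species
#'
#' @param clusters Labelled cluster list.
#' @param species Character vector of species (matrix rows).
#' @param truncation_columns Optional named integer vector: for a species
#'   with a 5'-truncated gene, all clusters at alignment columns strictly
#'   below the given column are scored `unknown` rather than `absent`.
#' @return Character matrix (`species` x cluster labels) with entries
#'   "present", "absent" or "unknown".
#' @export
presence_absence <- function(clusters, species, truncation_columns = NULL) {
  labs <- vapply(clusters, cluster_label, character(1))
  m <- matrix("absent", nrow = length(species), ncol = length(clusters),
              dimnames = list(species, labs))
  if (length(species) == 0L || length(clusters) == 0L)
    return(m)
  for (j in seq_along(clusters)) {
    cl <- clusters[[j]]
    m[intersect(cl$members, species), j] <- "present"
    if (!is.null(truncation_columns)) {
      for (sp in intersect(names(truncation_columns), species)) {
        if (m[sp, j] == "absent" && cl$column < truncation_columns[[sp]])
          m[sp, j] <- "unknown"
      }
    }
  }
  m
}

#' Per-column residue frequencies and information content
#'
#' Frequencies are computed over the 20 standard amino acids, excluding
#' gaps (recorded separately as `gap_fraction`). Information content is
#' `log2(20) + sum(f * log2 f)` bits, the height of a sequence-logo stack.
#' All-gap columns have undefined information, reported as `NA`.
#'
#' @param msa Named character vector of aligned sequences, or a FASTA path.
#' @param columns Optional integer vector of 0-based columns (default all).
#' @return List with `frequencies` (20 x k matrix), `gap_fraction` and
#'   `information` (numeric vectors, one entry per requested column).
#' @export
column_profile <- function(msa, columns = NULL) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa))
    msa <- read_alignment_fasta(msa)
  stopifnot(length(msa) >= 1L)
  mat <- do.call(rbind, strsplit(toupper(unname(msa)), "", fixed = TRUE))
  if (is.null(columns)) columns <- seq_len(ncol(mat)) - 1L
  columns <- as.integer(columns)
  stopifnot(all(columns >= 0L), all(columns < ncol(mat)))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  freq <- matrix(0, nrow = 20L, ncol = length(columns),
                 dimnames = list(aa, columns))
  gapf <- info <- numeric(length(columns))
  for (k in seq_along(columns)) {
    col <- mat[, columns[k] + 1L]
    isgap <- col %in% gap_chars
    gapf[k] <- mean(isgap)
    col <- col[!isgap]
    if (length(col) == 0L) { info[k] <- NA_real_; next }
    tab <- table(factor(col, levels = aa))
    f <- as.numeric(tab) / length(col)
    freq[, k] <- f
    nz <- f[f > 0]
    info[k] <- log2(20) + sum(nz * log2(nz))
  }
  list(frequencies = freq, gap_fraction = gapf, information = info)
}
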
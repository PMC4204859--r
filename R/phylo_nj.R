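# Distance-based tree reconstruction: p-distances on a protein alignment,
# neighbor-joining with a fixed tie-break, bootstrap support.

msa_matrix <- function(msa) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa))
    msa <- read_alignment_fasta(msa)
  stopifnot(length(msa) >= 2L, !is.null(names(msa)))
  mat <- do.call(rbind, strsplit(toupper(unname(msa)), "", fixed = TRUE))
  rownames(mat) <- names(msa)
  mat
}

#' Pairwise p-distances from a protein alignment
#'
#' The p-distance between two sequences is the fraction of retained aligned
#' positions at which they differ. Under complete deletion (the default)
#' every column containing a gap or missing character in *any* sequence is
#' eliminated before comparison; under pairwise deletion only the columns
#' gapped in one of the two sequences being compared are dropped.
#'
#' @param msa Named character vector of aligned sequences, or a FASTA path.
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @param missing_chars Characters treated as gaps/missing data.
#' @return Symmetric numeric matrix of distances in `[0, 1]` with a zero
#'   diagonal, taxa as dimnames.
#' @export
p_distance <- function(msa, deletion = c("complete", "pairwise"),
                       missing_chars = c("-", ".", "?", "X")) {
  deletion <- match.arg(deletion)
  mat <- msa_matrix(msa)
  miss <- mat %in% missing_chars
  dim(miss) <- dim(mat)
  n <- nrow(mat)
  if (deletion == "complete") {
    keep <- !apply(miss, 2L, any)
    if (!any(keep))
      stop("no columns retained under complete deletion")
    mat <- mat[, keep, drop = FALSE]
    miss <- miss[, keep, drop = FALSE]
  }
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !(miss[i, ] | miss[j, ])
    if (!any(ok))
      stop("no columns retained under pairwise deletion for ",
           rownames(mat)[i], " vs ", rownames(mat)[j])
    d[i, j] <- d[j, i] <- mean(mat[i, ok] != mat[j, ok])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomeration on the Q criterion. Ties in Q are broken by the
#' lexicographically lowest pair of current taxon indices, making the
#' topology deterministic on degenerate inputs. Negative branch-length
#' estimates are clamped to zero with a warning.
#'
#' @param dm Symmetric numeric matrix with taxa dimnames (>= 3 taxa) and a
#'   zero diagonal.
#' @return An unrooted `ape::phylo` tree with branch lengths; the total
#'   branch length is attached as attribute `total_branch_length`.
#' @export
nj_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (nrow(dm) < 3L) stop("neighbor-joining needs at least 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-12)
    stop("distance matrix is not symmetric")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <-
      paste0("t", seq_len(nrow(dm)))
  d <- dm
  # each active node is represented by its newick subtree string
  node <- rownames(d)
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  fmt <- function(lab, len) sprintf("%s:%.10g", lab, len)
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    best <- c(NA_integer_, NA_integer_); bq <- Inf
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (q[i, j] < bq - 1e-12) { bq <- q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    vi <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    vj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    newlab <- sprintf("(%s,%s)", fmt(node[i], vi), fmt(node[j], vj))
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    node <- c(node[keep], newlab)
    rownames(d2) <- colnames(d2) <- paste0("n", seq_len(nrow(d2)))
    d <- d2
  }
  # final three-point resolution
  va <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  vb <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  vc <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- sprintf("(%s,%s,%s);", fmt(node[1], va), fmt(node[2], vb),
                 fmt(node[3], vc))
  if (clamped)
    warning("negative neighbor-joining branch length(s) clamped to 0")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "total_branch_length") <- sum(tree$edge.length)
  tree
}

# Canonical keys for the non-trivial bipartitions of an unrooted tree:
# each internal edge splits the taxa; the key is the sorted side that does
# not contain the alphabetically first taxon.
bipartition_keys <- function(tree) {
  taxa <- sort(tree$tip.label)
  anchor <- taxa[1]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  keys <- vapply(parts, function(idx) {
    side <- labs[idx]
    if (anchor %in% side) side <- setdiff(taxa, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  n <- length(taxa)
  keep <- vapply(strsplit(keys, "|", fixed = TRUE), function(s)
    length(s) >= 2L && length(s) <= n - 2L, logical(1))
  unique(keys[keep])
}

#' Bootstrap support for the bipartitions of an alignment's NJ tree
#'
#' Alignment columns are resampled with replacement; each replicate is run
#' through [p_distance()] and [nj_tree()], and the support of a bipartition
#' of the original tree is the percentage of replicate trees containing it.
#' Supports are reported on the original tree's internal bipartitions (no
#' majority-rule consensus is built).
#'
#' @param msa Named character vector of aligned sequences, or a FASTA path.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the same seed reproduces the same supports.
#' @param deletion Deletion mode passed to [p_distance()].
#' @return List with `tree` (the original NJ tree), `support` (named
#'   percentage vector, one entry per internal bipartition, names are
#'   `|`-joined taxon sets) and `replicates`.
#' @export
bootstrap_support <- function(msa, replicates, seed = 1L,
                              deletion = "complete") {
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L)
  if (is.character(msa) && length(msa) == 1L && file.exists(msa))
    msa <- read_alignment_fasta(msa)
  mat <- msa_matrix(msa)
  to_msa <- function(m) stats::setNames(apply(m, 1L, paste, collapse = ""),
                                        rownames(m))
  ref_tree <- nj_tree(p_distance(to_msa(mat), deletion = deletion))
  ref_keys <- bipartition_keys(ref_tree)
  counts <- stats::setNames(numeric(length(ref_keys)), ref_keys)
  if (deletion == "complete") {
    # resample from the retained (gap-free) columns, as the original
    # distances were computed on exactly those
    miss <- mat %in% c("-", ".", "?", "X"); dim(miss) <- dim(mat)
    mat <- mat[, !apply(miss, 2L, any), drop = FALSE]
  }
  set.seed(as.integer(seed))
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol(mat), replace = TRUE)
    rep_tree <- suppressWarnings(
      nj_tree(p_distance(to_msa(mat[, cols, drop = FALSE]),
                         deletion = "pairwise")))
    hit <- intersect(ref_keys, bipartition_keys(rep_tree))
    counts[hit] <- counts[hit] + 1
  }
  list(tree = ref_tree, support = 100 * counts / replicates,
       replicates = replicates)
}
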
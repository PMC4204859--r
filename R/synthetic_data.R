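# Synthetic data with known ground truth: species trees, intron gain/loss
# histories, gene models, protein alignments and start-context windows.

#' Configuration for a synthetic intron-evolution history
#'
#' @param seed Integer seed; all outputs are reproducible from it.
#' @param tree Optional rooted `ape::phylo`; when `NULL` a random rooted
#'   tree with `n_leaves` tips (labelled sp1..spN) is drawn.
#' @param n_leaves Number of tips for the random tree (default 8).
#' @param n_ancestral_sites Number of intron sites present at the root
#'   (default 11, the lepidopteran complement).
#' @param gain_rate Expected number of new sites gained per branch
#'   (Poisson; default 0.2).
#' @param loss_rate Expected number of site losses per branch (Poisson;
#'   default 0.3).
#' @param protein_length Protein length in residues (default 561).
#' @param substitution_rate Per-site, per-branch substitution probability
#'   for the protein sequences (default 0.05).
#' @param intron_meanlog,intron_sdlog Log-normal intron-length parameters.
#'   `intron_meanlog` may be a single value or a named vector of per-clade
#'   scales combined with `clades`; clade-dependent intron sizes emulate
#'   the order-of-magnitude spread seen between insect orders.
#' @param clades Optional named list mapping clade name to tip labels (for
#'   per-clade intron lengths).
#' @param indel_rate Expected number of deletion events per branch
#'   (default 0: gapless alignment, exact site-to-column map). Deletions
#'   only hit residues carrying no site, so the ground-truth map stays
#'   exact while projection must skip gaps.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, tree = NULL, n_leaves = 8L,
                              n_ancestral_sites = 11L, gain_rate = 0.2,
                              loss_rate = 0.3, protein_length = 561L,
                              substitution_rate = 0.05,
                              intron_meanlog = log(500), intron_sdlog = 0.8,
                              clades = NULL, indel_rate = 0) {
  stopifnot(gain_rate >= 0, loss_rate >= 0, substitution_rate >= 0,
            substitution_rate <= 1, n_ancestral_sites >= 0,
            protein_length >= 2L, indel_rate >= 0)
  if (!is.null(tree)) {
    stopifnot(inherits(tree, "phylo"))
    if (!ape::is.rooted(tree)) stop("config tree must be rooted")
  }
  structure(list(seed = as.integer(seed), tree = tree,
                 n_leaves = as.integer(n_leaves),
                 n_ancestral_sites = as.integer(n_ancestral_sites),
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 protein_length = as.integer(protein_length),
                 substitution_rate = substitution_rate,
                 intron_meanlog = intron_meanlog,
                 intron_sdlog = intron_sdlog, clades = clades,
                 indel_rate = indel_rate),
            class = "simulation_config")
}

aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

clade_of <- function(config, tip) {
  if (is.null(config$clades)) return(NA_character_)
  for (nm in names(config$clades))
    if (tip %in% config$clades[[nm]]) return(nm)
  NA_character_
}

draw_intron_length <- function(config, tip) {
  ml <- config$intron_meanlog
  if (length(ml) > 1L) {
    cl <- clade_of(config, tip)
    ml <- if (!is.na(cl) && cl %in% names(ml)) ml[[cl]] else ml[[1]]
  }
  max(60L, as.integer(round(stats::rlnorm(1, ml, config$intron_sdlog))))
}

#' Simulate an intron gain/loss history with ground truth
#'
#' Sites evolve along a rooted tree under a Dollo-consistent model: each
#' site is gained exactly once (ancestral sites on the root, later gains on
#' a random branch) and lost independently on descendant branches. Each
#' site occupies a distinct residue of a simulated protein, with a random
#' phase; leaf gene models place the surviving sites at their CDS offsets
#' and draw intron lengths from a (per-clade) log-normal. Protein
#' sequences evolve by independent substitutions without indels (unless
#' `indel_rate > 0`, which adds site-free deletions rendered as gaps), so
#' the site-to-column map is exact and emitted alongside.
#'
#' @param config A [simulation_config()].
#' @return List with `tree`, `models` (named list of `gene_model`, tips
#'   with zero surviving sites included as intronless), `msa` (named
#'   character vector), and `truth`: `ledger` (per site: `gain_node`,
#'   `gain_branch`, `loss_nodes`, `loss_branches`), `site_map` (data frame
#'   `label`, `residue_index`, `phase`, `alignment_column`), and
#'   `presence` (logical matrix species x site).
#' @export
simulate_history <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rtree(config$n_leaves,
                       tip.label = paste0("sp", seq_len(config$n_leaves)))
  }
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  children <- tree_children(tree)
  parents <- tree_parents(tree)
  # preorder over non-root nodes (every branch, identified by child node)
  preorder <- integer()
  stack <- children[[root]]
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    preorder <- c(preorder, v)
    if (v > ntip) stack <- c(children[[v]], stack)
  }
  n_sites_max <- config$n_ancestral_sites +
    stats::qpois(1 - 1e-9, config$gain_rate * length(preorder)) + 8L
  if (n_sites_max > config$protein_length - 1L)
    stop("protein_length too small for the expected number of sites")
  # 0-based residue indices excluding residue 0, so every CDS offset is
  # strictly inside the CDS
  residues <- sample(seq_len(config$protein_length - 1L), n_sites_max)
  phases <- sample(0:2, n_sites_max, replace = TRUE)
  site_gain <- integer()   # gain node per allocated site
  next_site <- 0L
  new_site <- function(node) {
    next_site <<- next_site + 1L
    if (next_site > n_sites_max)
      stop("more gains drawn than allocated site slots; increase ",
           "protein_length")
    site_gain[next_site] <<- node
    next_site
  }
  for (k in seq_len(config$n_ancestral_sites)) new_site(root)
  present_at <- vector("list", ntip + tree$Nnode)
  present_at[[root]] <- seq_len(config$n_ancestral_sites)
  loss_events <- list()  # site -> loss nodes
  for (v in preorder) {
    inherited <- present_at[[parents[v]]]
    n_lost <- min(stats::rpois(1, config$loss_rate), length(inherited))
    lost <- if (n_lost > 0L) sample(inherited, n_lost) else integer()
    for (s in lost)
      loss_events[[as.character(s)]] <- c(loss_events[[as.character(s)]], v)
    surviving <- setdiff(inherited, lost)
    n_gain <- stats::rpois(1, config$gain_rate)
    gained <- if (n_gain > 0L) vapply(seq_len(n_gain), function(i)
      new_site(v), integer(1)) else integer()
    present_at[[v]] <- c(surviving, gained)
  }
  n_sites <- next_site
  labels <- paste0("s", seq_len(n_sites))
  # order sites by residue for readable gene models
  site_res <- residues[seq_len(n_sites)]
  site_ph <- phases[seq_len(n_sites)]
  presence <- matrix(FALSE, nrow = ntip, ncol = n_sites,
                     dimnames = list(tree$tip.label, labels))
  for (t_ in seq_len(ntip))
    presence[t_, present_at[[t_]]] <- TRUE
  # protein sequences: substitutions along branches
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sample(aa_alphabet, config$protein_length, replace = TRUE)
  for (v in preorder) {
    s <- seqs[[parents[v]]]
    hit <- which(stats::runif(length(s)) < config$substitution_rate)
    for (h in hit) s[h] <- sample(setdiff(aa_alphabet, s[h]), 1)
    seqs[[v]] <- s
  }
  # optional deletions at site-free residues, rendered as gaps in all
  # tips below the deletion branch
  gapped <- matrix(FALSE, nrow = ntip, ncol = config$protein_length)
  if (config$indel_rate > 0) {
    # 1-based columns carrying no site (site_res are 0-based residues)
    free <- setdiff(seq_len(config$protein_length), site_res + 1L)
    tips_below <- function(v) {
      if (v <= ntip) return(v)
      unlist(lapply(children[[v]], tips_below))
    }
    for (v in preorder) {
      n_del <- stats::rpois(1, config$indel_rate)
      for (k in seq_len(n_del)) {
        if (!length(free)) break
        start <- sample(free, 1)
        len <- 1L + stats::rgeom(1, 0.5)
        run <- intersect(start:(start + len - 1L), free)
        gapped[tips_below(v), run] <- TRUE
      }
    }
  }
  msa <- vapply(seq_len(ntip), function(t_) {
    s <- seqs[[t_]]
    s[gapped[t_, ]] <- "-"
    paste(s, collapse = "")
  }, character(1))
  names(msa) <- tree$tip.label
  # leaf gene models; with deletions, a tip's CDS shrinks and its sites
  # shift to the tip's own (ungapped) residue indices, so projection back
  # onto the alignment recovers the ground-truth columns exactly
  models <- lapply(seq_len(ntip), function(t_) {
    tip <- tree$tip.label[t_]
    kept <- !gapped[t_, ]
    cds_length <- 3L * (sum(kept) + 1L)  # + stop codon
    idx <- which(presence[t_, ])
    if (length(idx) == 0L)
      return(gene_model(tip, exon_lengths = cds_length))
    local_res <- cumsum(kept) - 1L       # 0-based residue per column
    offs <- sort(3L * local_res[site_res[idx] + 1L] + site_ph[idx])
    ilen <- vapply(seq_along(offs), function(i)
      draw_intron_length(config, tip), integer(1))
    gene_model(tip, exon_lengths = diff(c(0L, offs, cds_length)),
               intron_lengths = ilen)
  })
  names(models) <- tree$tip.label
  ledger <- lapply(seq_len(n_sites), function(s) {
    ln <- sort(loss_events[[as.character(s)]])
    if (is.null(ln)) ln <- integer()
    list(gain_node = site_gain[s],
         gain_branch = node_name(tree, site_gain[s]),
         loss_nodes = as.integer(ln),
         loss_branches = node_names(tree, ln))
  })
  names(ledger) <- labels
  site_map <- data.frame(label = labels, residue_index = site_res,
                         phase = site_ph, alignment_column = site_res,
                         row.names = NULL)
  list(tree = tree, models = models, msa = msa,
       truth = list(ledger = ledger, site_map = site_map,
                    presence = presence))
}

#' Simulate start-codon context windows from a PFM
#'
#' Windows are drawn position-independently from the PFM's percentage
#' columns; rebuilding a PFM from the sample recovers the input within
#' multinomial error.
#'
#' @param pfm A `context_pfm` (see [build_pfm()]).
#' @param n Number of windows.
#' @param seed Integer seed.
#' @return Character vector of `n` 10-nt windows.
#' @export
simulate_contexts <- function(pfm, n, seed = 1L) {
  stopifnot(ncol(pfm) == 10L, n >= 1L)
  set.seed(as.integer(seed))
  nts <- rownames(pfm)
  vapply(seq_len(n), function(i)
    paste(vapply(seq_len(10L), function(j)
      sample(nts, 1, prob = pfm[, j]), character(1)), collapse = ""),
    character(1))
}
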
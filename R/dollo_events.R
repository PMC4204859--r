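# Dollo parsimony reconstruction of intron gain/loss events on a rooted
# species tree, event dating by node ages, and ledger summaries.

# children[[v]] = integer vector of child node ids (ape numbering)
tree_children <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge)))
    ch[[tree$edge[e, 1]]] <- c(ch[[tree$edge[e, 1]]], tree$edge[e, 2])
  ch
}

tree_parents <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  par <- rep(NA_integer_, n_nodes)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

# human-readable identifier of a node: tip label, node label, or "node<k>"
node_name <- function(tree, v) {
  ntip <- ape::Ntip(tree)
  if (v <= ntip) return(tree$tip.label[v])
  lab <- tree$node.label[v - ntip]
  if (!is.null(lab) && !is.na(lab) && nzchar(lab)) lab else paste0("node", v)
}

node_names <- function(tree, v) vapply(v, function(x) node_name(tree, x),
                                       character(1))

#' Dollo reconstruction of one presence/absence character
#'
#' Under Dollo parsimony a character (here: one intron insertion site) is
#' gained exactly once and may subsequently be lost any number of times.
#' The gain is placed on the branch into the most recent common ancestor of
#' all taxa carrying the site; losses are the minimal set of branches
#' explaining every absence inside that clade, found by subtree
#' aggregation: a branch is a loss branch when its subtree contains at
#' least one absent taxon and no present taxon, while its parent's subtree
#' contains a present taxon. Taxa with unknown state (e.g. truncated
#' genes) never force a loss.
#'
#' @param presence Named logical vector over the tree's tips: `TRUE` =
#'   present, `FALSE` = absent, `NA` = unknown. (Character vectors with
#'   values "present"/"absent"/"unknown" are also accepted.)
#' @param tree A rooted `ape::phylo` tree whose tip labels cover
#'   `names(presence)`.
#' @return List with `gain_branch` (name of the child node of the gain
#'   branch, `NA` if the site is present nowhere), `gain_node` (its ape
#'   node id), `loss_branches`, `loss_nodes`, and `n_losses`.
#' @export
dollo_reconstruct <- function(presence, tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree))
    stop("Dollo reconstruction requires a rooted tree")
  if (is.character(presence)) {
    map <- c(present = TRUE, absent = FALSE, unknown = NA)
    presence <- stats::setNames(unname(map[presence]), names(presence))
  }
  stopifnot(is.logical(presence), !is.null(names(presence)))
  miss <- setdiff(names(presence), tree$tip.label)
  if (length(miss))
    stop("taxa not in the tree: ", paste(miss, collapse = ", "))
  ntip <- ape::Ntip(tree)
  state <- rep(NA, ntip)
  state[match(names(presence), tree$tip.label)] <- presence
  empty <- list(gain_branch = NA_character_, gain_node = NA_integer_,
                loss_branches = character(), loss_nodes = integer(),
                n_losses = 0L)
  present_tips <- which(!is.na(state) & state)
  if (length(present_tips) == 0L) return(empty)
  gain <- if (length(present_tips) == 1L) present_tips else
    ape::getMRCA(tree, present_tips)
  children <- tree_children(tree)
  has_present <- has_absent <- rep(FALSE, ntip + tree$Nnode)
  # per-node flags, computed bottom-up
  flags <- function(v) {
    if (v <= ntip) {
      has_present[v] <<- !is.na(state[v]) && state[v]
      has_absent[v] <<- !is.na(state[v]) && !state[v]
    } else {
      for (c_ in children[[v]]) flags(c_)
      has_present[v] <<- any(has_present[children[[v]]])
      has_absent[v] <<- any(has_absent[children[[v]]])
    }
  }
  root <- ntip + 1L
  flags(root)
  # losses: maximal absent-only subtrees within the gain clade
  losses <- integer()
  walk <- function(v) {
    for (c_ in children[[v]]) {
      if (!has_present[c_]) {
        if (has_absent[c_]) losses <<- c(losses, c_)
        # all-unknown subtree: neither loss nor recursion needed
      } else walk(c_)
    }
  }
  walk(gain)
  list(gain_branch = node_name(tree, gain), gain_node = as.integer(gain),
       loss_branches = node_names(tree, sort(losses)),
       loss_nodes = as.integer(sort(losses)),
       n_losses = length(losses))
}

#' Dollo event ledger for a presence/absence matrix
#'
#' Runs [dollo_reconstruct()] for every site column of a presence/absence
#' matrix (species x site labels).
#'
#' @param pa Character or logical matrix: rows = species, columns = site
#'   labels; character entries "present"/"absent"/"unknown" or logical with
#'   `NA` = unknown.
#' @param tree Rooted `ape::phylo`.
#' @return An object of class `event_ledger`: a named list (one element per
#'   site label) of [dollo_reconstruct()] results.
#' @export
dollo_ledger <- function(pa, tree) {
  stopifnot(is.matrix(pa), !is.null(rownames(pa)),
            ncol(pa) == 0L || !is.null(colnames(pa)))
  out <- lapply(colnames(pa), function(lab)
    dollo_reconstruct(stats::setNames(pa[, lab], rownames(pa)), tree))
  names(out) <- colnames(pa)
  structure(out, class = "event_ledger", tree = tree)
}

#' @export
print.event_ledger <- function(x, ...) {
  cat(sprintf("<event_ledger> %d sites, %d losses in total\n", length(x),
              sum(vapply(x, `[[`, integer(1), "n_losses"))))
  invisible(x)
}

#' Date ledger events with node ages
#'
#' An event assigned to a branch is dated by the age of the branch's
#' *parent* node: the divergence that opens the branch. Published gain/loss
#' dates cite divergence times, so this convention reproduces them.
#'
#' @param ledger An `event_ledger` from [dollo_ledger()].
#' @param node_ages Named numeric vector of ages in MYA; names are tip or
#'   internal node labels (see [read_node_ages()]). Every node parent to an
#'   event branch must be present.
#' @return The ledger with `gain_age` and `loss_ages` added per site.
#' @export
annotate_ages <- function(ledger, node_ages) {
  stopifnot(inherits(ledger, "event_ledger"), is.numeric(node_ages),
            !is.null(names(node_ages)))
  tree <- attr(ledger, "tree")
  parents <- tree_parents(tree)
  age_of_parent <- function(v) {
    p <- parents[v]
    if (is.na(p)) return(NA_real_)  # event on the root branch: undatable
    node_name(tree, p)
  }
  missing_nodes <- character()
  dated <- lapply(ledger, function(ev) {
    if (is.na(ev$gain_node)) {
      ev$gain_age <- NA_real_; ev$loss_ages <- numeric(); return(ev)
    }
    gp <- age_of_parent(ev$gain_node)
    lp <- vapply(ev$loss_nodes, age_of_parent, character(1))
    for (nm in c(gp, lp)) if (!is.na(nm) && !(nm %in% names(node_ages)))
      missing_nodes <<- c(missing_nodes, nm)
    ev$gain_age <- if (is.na(gp)) NA_real_ else unname(node_ages[gp])
    ev$loss_ages <- stats::setNames(
      vapply(lp, function(nm) if (is.na(nm)) NA_real_ else
        unname(node_ages[nm]), numeric(1)),
      ev$loss_branches)
    ev
  })
  if (length(missing_nodes))
    stop("no age for node(s): ", paste(unique(missing_nodes), collapse = ", "))
  structure(dated, class = "event_ledger", tree = attr(ledger, "tree"))
}

#' Summarise an event ledger
#'
#' @param ledger An `event_ledger`.
#' @param membership Optional named character vector mapping species to an
#'   order/family; used to count sites private to each species' group.
#' @return List with `per_branch` (data frame: branch, gains, losses),
#'   `per_taxon` (data frame: species, n_sites, n_private) where
#'   `n_private` (requires `membership`) counts sites whose carriers all
#'   belong to the species' own group.
#' @export
event_summary <- function(ledger, membership = NULL) {
  stopifnot(inherits(ledger, "event_ledger"))
  tree <- attr(ledger, "tree")
  gains <- table(unlist(lapply(ledger, function(ev)
    if (!is.na(ev$gain_branch)) ev$gain_branch else NULL)))
  losses <- table(unlist(lapply(ledger, `[[`, "loss_branches")))
  branches <- sort(unique(c(names(gains), names(losses))))
  per_branch <- data.frame(
    branch = branches,
    gains = as.integer(gains[branches]),
    losses = as.integer(losses[branches]))
  per_branch$gains[is.na(per_branch$gains)] <- 0L
  per_branch$losses[is.na(per_branch$losses)] <- 0L
  # presence of each site at each tip, replayed from the events
  ntip <- ape::Ntip(tree)
  parents <- tree_parents(tree)
  ancestors <- function(v) {
    out <- integer()
    while (!is.na(parents[v])) { out <- c(out, v); v <- parents[v] }
    c(out, v)
  }
  anc <- lapply(seq_len(ntip), ancestors)
  carriers <- lapply(ledger, function(ev) {
    if (is.na(ev$gain_node)) return(character())
    tips <- which(vapply(anc, function(a)
      ev$gain_node %in% a && !any(ev$loss_nodes %in% a), logical(1)))
    tree$tip.label[tips]
  })
  n_sites <- vapply(tree$tip.label, function(sp)
    sum(vapply(carriers, function(cc) sp %in% cc, logical(1))), integer(1))
  if (!is.null(membership)) {
    n_private <- vapply(tree$tip.label, function(sp) {
      grp <- membership[sp]
      if (is.na(grp)) return(NA_integer_)
      sum(vapply(carriers, function(cc)
        sp %in% cc && all(membership[cc] %in% grp), logical(1)))
    }, integer(1))
  } else n_private <- rep(NA_integer_, ntip)
  per_taxon <- data.frame(species = tree$tip.label, n_sites = n_sites,
                          n_private = n_private, row.names = NULL)
  list(per_branch = per_branch, per_taxon = per_taxon)
}

#' Write an event ledger as TSV
#'
#' One row per event: `site`, `event` (gain/loss), `branch`, `age_mya`
#' (NA when the ledger is undated).
#'
#' @param ledger An `event_ledger`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_ledger_tsv <- function(ledger, path) {
  rows <- list()
  for (lab in names(ledger)) {
    ev <- ledger[[lab]]
    if (!is.na(ev$gain_branch))
      rows[[length(rows) + 1L]] <- data.frame(
        site = lab, event = "gain", branch = ev$gain_branch,
        age_mya = if (!is.null(ev$gain_age)) ev$gain_age else NA_real_)
    for (k in seq_along(ev$loss_branches))
      rows[[length(rows) + 1L]] <- data.frame(
        site = lab, event = "loss", branch = ev$loss_branches[k],
        age_mya = if (!is.null(ev$loss_ages)) unname(ev$loss_ages[k])
                  else NA_real_)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = character(), event = character(),
               branch = character(), age_mya = numeric())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
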
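# Pipeline driver: configuration, staged execution, report writers, log.

#' Build and validate a pipeline run configuration
#'
#' @param gene_models Path to a gene-model TSV ([read_gene_models_tsv()])
#'   or GFF3 file, or a named list of `gene_model` objects.
#' @param msa Path to an aligned protein FASTA, or a named character
#'   vector of aligned sequences.
#' @param out_dir Output directory (created if absent).
#' @param references Named list: lineage suffix -> character vector of
#'   reference species for [label_clusters()] (e.g.
#'   `list(l = c("S_frugiperda"), c = c("H_sapiens"))`). Must be
#'   non-empty.
#' @param tree Optional path to a rooted newick tree (or `phylo`) for the
#'   Dollo stage.
#' @param ages Optional path to a node-age TSV (or named numeric vector).
#' @param cdna Optional cDNA FASTA path (or character scalar) for the
#'   start-codon stage.
#' @param start_pfm Optional PFM TSV path (or `context_pfm`); required
#'   when `cdna` is given.
#' @param consensus_threshold Consensus threshold in percent (default 27).
#' @param nearpair_nt Near-intron-pair distance threshold in nt
#'   (default 32).
#' @param column_tolerance Cluster column tolerance (default 0).
#' @param bootstrap Bootstrap replicate count for the NJ stage (default 0:
#'   NJ tree without supports; set `NA` to skip the NJ stage).
#' @param seed Integer seed for all stochastic stages.
#' @return A validated `run_config` list.
#' @export
run_config <- function(gene_models, msa, out_dir,
                       references,
                       tree = NULL, ages = NULL, cdna = NULL,
                       start_pfm = NULL,
                       consensus_threshold = 27, nearpair_nt = 32L,
                       column_tolerance = 0L, bootstrap = 0L, seed = 1L) {
  chk_path <- function(x, what) {
    if (is.character(x) && length(x) == 1L && !file.exists(x))
      stop("config error: ", what, " file does not exist: ", x)
    x
  }
  if (!is.list(references) || length(references) == 0L ||
      is.null(names(references)) || any(!nzchar(names(references))))
    stop("config error: references must be a non-empty named list ",
         "(suffix -> species vector)")
  for (s in names(references))
    if (length(references[[s]]) == 0L)
      stop("config error: empty species set for reference suffix '", s, "'")
  if (!is.numeric(consensus_threshold) || consensus_threshold <= 0 ||
      consensus_threshold > 100)
    stop("config error: consensus_threshold must be in (0, 100]")
  if (!is.na(bootstrap) && bootstrap < 0)
    stop("config error: bootstrap must be >= 0 (or NA to skip NJ)")
  if (column_tolerance < 0) stop("config error: column_tolerance < 0")
  if (nearpair_nt < 0) stop("config error: nearpair_nt < 0")
  structure(list(gene_models = chk_path(gene_models, "gene model"),
                 msa = chk_path(msa, "alignment"),
                 out_dir = out_dir, references = references,
                 tree = chk_path(tree, "tree"),
                 ages = chk_path(ages, "node-age"),
                 cdna = chk_path(cdna, "cDNA"),
                 start_pfm = chk_path(start_pfm, "PFM"),
                 consensus_threshold = consensus_threshold,
                 nearpair_nt = as.integer(nearpair_nt),
                 column_tolerance = as.integer(column_tolerance),
                 bootstrap = bootstrap, seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full comparative-architecture pipeline
#'
#' Stages: load gene models and alignment; per-gene summaries; site
#' inference and projection; clustering and lineage labelling;
#' presence/absence matrix; near-intron-pair scan; optional NJ tree (with
#' bootstrap supports); optional Dollo reconstruction on a supplied rooted
#' tree, dated when node ages are given; optional start-codon context
#' scan. Reports are written as TSV/newick under `out_dir` together with a
#' plain-text log recording versions, seed and thresholds. Re-running an
#' identical configuration reproduces the reports byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`summaries`,
#'   `clusters`, `presence`, `near_pairs`, `nj`, `ledger`, `start`,
#'   `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log_lines <- c(
    sprintf("%s intronarch %s | R %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
            as.character(utils::packageVersion("intronarch")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed=%d consensus_threshold=%g nearpair_nt=%d column_tolerance=%d bootstrap=%s",
            config$seed, config$consensus_threshold, config$nearpair_nt,
            config$column_tolerance, as.character(config$bootstrap)))
  note <- function(fmt, ...) log_lines <<- c(log_lines, sprintf(fmt, ...))
  files <- character()
  emit <- function(name) files <<- c(files, file.path(config$out_dir, name))

  models <- stage("load_gene_models", {
    gm <- config$gene_models
    if (is.character(gm)) {
      if (grepl("\\.gff3?$", gm, ignore.case = TRUE))
        gm <- read_gene_models_gff3(gm)
      else gm <- read_gene_models_tsv(gm)
    }
    if (length(gm) == 0L) stop("no gene models given")
    lapply(gm, validate_gene_model)
    gm
  })
  msa <- stage("load_alignment", {
    m <- config$msa
    if (is.character(m) && length(m) == 1L && file.exists(m))
      m <- read_alignment_fasta(m)
    m
  })
  note("loaded %d gene models, %d aligned sequences", length(models),
       length(msa))

  summaries <- stage("summarize", {
    df <- do.call(rbind, lapply(models, function(m) {
      s <- summarize_gene(m)
      data.frame(species = m$species_id, n_exons = s$n_exons,
                 n_introns = s$n_introns,
                 total_intronic_bp = s$total_intronic_bp)
    }))
    rownames(df) <- NULL
    utils::write.table(df, file.path(config$out_dir, "gene_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("gene_summary.tsv")
    df
  })

  clusters <- stage("project_and_cluster", {
    sites <- do.call(rbind, lapply(models, infer_intron_sites))
    sites <- sites[sites$species_id %in% names(msa), , drop = FALSE]
    aligned <- project_sites(sites, msa)
    cl <- cluster_sites(aligned, column_tolerance = config$column_tolerance)
    for (sfx in names(config$references))
      cl <- label_clusters(cl, config$references[[sfx]], sfx)
    cl
  })
  note("%d site clusters", length(clusters))

  presence <- stage("presence_absence", {
    pa <- presence_absence(clusters, species = names(models))
    out <- data.frame(species = rownames(pa), pa, check.names = FALSE)
    utils::write.table(out, file.path(config$out_dir, "presence_absence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("presence_absence.tsv")
    pa
  })

  near_pairs <- stage("near_intron_pairs", {
    np <- near_intron_pairs(clusters, max_nt_distance = config$nearpair_nt)
    utils::write.table(np, file.path(config$out_dir, "near_intron_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("near_intron_pairs.tsv")
    np
  })
  note("%d near intron pair(s) within %d nt", nrow(near_pairs),
       config$nearpair_nt)

  nj <- NULL
  if (!is.na(config$bootstrap) && length(msa) >= 3L) {
    nj <- stage("nj", {
      if (config$bootstrap > 0L) {
        bs <- bootstrap_support(msa, replicates = config$bootstrap,
                                seed = config$seed)
        tr <- bs$tree
        ape::write.tree(tr, file.path(config$out_dir, "nj_tree.nwk"))
        sup <- data.frame(bipartition = names(bs$support),
                          support_pct = unname(bs$support))
        utils::write.table(sup,
                           file.path(config$out_dir, "nj_bootstrap.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        emit("nj_bootstrap.tsv")
        bs
      } else {
        tr <- nj_tree(p_distance(msa))
        ape::write.tree(tr, file.path(config$out_dir, "nj_tree.nwk"))
        list(tree = tr)
      }
    })
    emit("nj_tree.nwk")
  }

  ledger <- NULL
  if (!is.null(config$tree)) {
    ledger <- stage("dollo", {
      tr <- config$tree
      if (is.character(tr)) tr <- ape::read.tree(tr)
      pa <- ifelse(presence == "unknown", NA, presence == "present")
      dimnames(pa) <- dimnames(presence)
      lg <- dollo_ledger(pa, tr)
      if (!is.null(config$ages)) {
        ages <- config$ages
        if (is.character(ages)) ages <- read_node_ages(ages)
        lg <- annotate_ages(lg, ages)
      }
      write_event_ledger_tsv(lg, file.path(config$out_dir,
                                           "event_ledger.tsv"))
      emit("event_ledger.tsv")
      lg
    })
  }

  start <- NULL
  if (!is.null(config$cdna)) {
    start <- stage("start_scan", {
      if (is.null(config$start_pfm))
        stop("start-codon stage needs start_pfm")
      pfm <- config$start_pfm
      if (is.character(pfm)) pfm <- read_pfm_tsv(pfm)
      cdna <- config$cdna
      if (is.character(cdna) && length(cdna) == 1L && file.exists(cdna))
        cdna <- as.character(Biostrings::readDNAStringSet(cdna)[[1]])
      cons <- derive_consensus(pfm, threshold = config$consensus_threshold)
      sel <- select_start(cdna, cons)
      utils::write.table(sel$candidates,
                         file.path(config$out_dir, "start_candidates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit("start_candidates.tsv")
      sel
    })
  }

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  emit("run_log.txt")
  invisible(list(summaries = summaries, clusters = clusters,
                 presence = presence, near_pairs = near_pairs, nj = nj,
                 ledger = ledger, start = start, files = files))
}

#' Write a comparative site table (published-table layout)
#'
#' Rows are species, columns are labelled sites holding `phase/length`
#' cells (blank when absent), followed by `total_is` and `nb_introns`.
#'
#' @param clusters Labelled cluster list (with `intron_length` carried in
#'   the member site rows).
#' @param models Named list of `gene_model` (for the per-species totals).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(clusters, models, path) {
  labs <- vapply(clusters, cluster_label, character(1))
  species <- vapply(models, function(m) m$species_id, character(1))
  cells <- matrix("", nrow = length(species), ncol = length(clusters),
                  dimnames = list(species, labs))
  for (j in seq_along(clusters)) {
    s <- clusters[[j]]$sites
    for (i in seq_len(nrow(s))) {
      if (!s$species_id[i] %in% species) next
      len <- if ("intron_length" %in% names(s)) s$intron_length[i]
             else NA_integer_
      cells[s$species_id[i], j] <-
        if (is.na(len)) "X" else sprintf("%d/%d", s$phase[i], len)
    }
  }
  sums <- lapply(models, summarize_gene)
  df <- data.frame(species = species, cells,
                   total_is = vapply(sums, `[[`, integer(1),
                                     "total_intronic_bp"),
                   nb_introns = vapply(sums, `[[`, integer(1), "n_introns"),
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
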
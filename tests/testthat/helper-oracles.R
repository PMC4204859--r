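# Independent oracles and small builders used across the test files.

# Enumerative oracle for the nt length of an exon written u-c-d: walk CDS
# offsets downstream of a boundary with the implied upstream intron phase
# until the count of touched codons reaches c and the end offset has the
# required downstream phase; never uses the closed-form length formula.
oracle_notation_length <- function(u, c_, d) {
  phase_up <- (3L - u) %% 3L
  o1 <- 300L + phase_up           # any CDS offset with that phase
  o2 <- o1 + 1L
  repeat {
    codons <- length(unique((o1:(o2 - 1L)) %/% 3L))
    if (codons == c_ && o2 %% 3L == d) return(o2 - o1)
    if (codons > c_) stop("no layout for ", u, "-", c_, "-", d)
    o2 <- o2 + 1L
  }
}

# ---- brute-force Dollo oracle ----------------------------------------------

oracle_tree_index <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  parent <- rep(NA_integer_, nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  anc <- lapply(seq_len(ntip), function(v) {
    out <- v
    while (!is.na(parent[v])) { v <- parent[v]; out <- c(out, v) }
    out                              # leaf .. root, inclusive
  })
  list(ntip = ntip, nn = nn, parent = parent, anc = anc)
}

# leaf states implied by a single gain at `gain` and losses on `losses`
oracle_simulate <- function(idx, gain, losses) {
  vapply(seq_len(idx$ntip), function(leaf) {
    a <- idx$anc[[leaf]]
    (gain %in% a) && !any(losses %in% a)
  }, logical(1))
}

# all minimum-loss single-gain explanations of a presence pattern
# (states: TRUE/FALSE/NA over tips, in tree tip order)
oracle_dollo <- function(tree, states, max_losses = 8L) {
  idx <- oracle_tree_index(tree)
  known <- which(!is.na(states))
  matches <- function(sim) all(sim[known] == states[known])
  if (!any(states[known])) {
    return(list(min_losses = 0L,
                solutions = list(list(gain = NA_integer_,
                                      losses = integer()))))
  }
  present <- which(!is.na(states) & states)
  gains <- Filter(function(g) all(vapply(present, function(p)
    g %in% idx$anc[[p]], logical(1))), seq_len(idx$nn))
  below_of <- lapply(seq_len(idx$nn), function(g)
    setdiff(which(vapply(seq_len(idx$nn), function(v) {
      a <- v
      while (!is.na(idx$parent[a]) && a != g) a <- idx$parent[a]
      a == g
    }, logical(1))), g))
  for (m in 0:max_losses) {
    sols <- list()
    for (g in gains) {
      below <- below_of[[g]]
      if (m > length(below)) next
      subsets <- if (m == 0L) list(integer()) else
        utils::combn(below, m, simplify = FALSE)
      for (ls in subsets)
        if (matches(oracle_simulate(idx, g, ls)))
          sols[[length(sols) + 1L]] <- list(gain = g, losses = sort(ls))
    }
    if (length(sols)) return(list(min_losses = m, solutions = sols))
  }
  stop("oracle exceeded max_losses")
}

# deduplicated solutions keyed by gain + losses
oracle_solution_keys <- function(sol)
  unique(vapply(sol$solutions, function(s)
    paste(s$gain, paste(s$losses, collapse = ","), sep = "|"),
    character(1)))

# ---- misc builders ----------------------------------------------------------

random_notation <- function() {
  u <- sample(0:2, 1); d <- sample(0:2, 1)
  c_ <- sample(2:120, 1)
  exon_notation(u, max(c_, (u > 0) + (d > 0) + 1L), d)
}

# a random rooted tree with distinct tip labels
random_rooted_tree <- function(n) {
  tr <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
  tr
}

fixture <- function(...) intronarch_extdata(...)

# frozen presence patterns of the published arthropod/chordate tables
# (transcribed from the printed rows, independent of the fixture files)
expected_arthropod_presence <- list(
  S_frugiperda = paste0("i", 1:11, "l"),
  B_mori = paste0("i", 1:11, "l"),
  D_plexippus = paste0("i", 1:11, "l"),
  H_melpomene = paste0("i", c(1:8, 10, 11), "l"),
  T_castaneum = c("i4l", "i5l", "i7l", "i9l"),
  A_pisum = c("i4l", "i5l", "i7l", "i9l"),
  P_humanus = c("i3l", "i4l", "i5l", "i7l"),
  D_melanogaster = c("i4l", "i7l"),
  C_pipiens = c("i7l", "i8l"),
  L_longipalpis = c("i7l", "i8l"),
  M_occidentallis = "i9l",
  T_urticae = character(),
  D_pulex = c("i3l", "i4l", "i5l", "i7l"),
  L_salmonis = character(),
  S_maritima = c("i7l", "i9l"),
  C_intestinalis_A = c("i3l", "i5l", "i7l", "i9l", "i10l"),
  H_sapiens = c("i3l", "i5l", "i7l", "i9l"),
  R_norvegicus = c("i3l", "i5l", "i7l", "i9l"),
  B_taurus = c("i3l", "i5l", "i7l", "i9l"))

chordate_six <- c("i3l", "i4c", "i5l", "i7l", "i7c", "i9l")
expected_chordate_presence <- c(
  stats::setNames(rep(list(chordate_six), 12),
                  c("H_sapiens", "G_gallus", "M_gallopavo", "T_guttata",
                    "A_carolinensis", "X_tropicalis", "D_rerio_B",
                    "T_rubipres", "O_latipes", "O_niloticus",
                    "S_purpuratus", "S_kowalevskii_A")),
  list(T_spiralis = c("i6l", "i7l", "i9l"),
       C_brenneri = c("i7c", "i9l"),
       L_loa = "i7c", B_malayi = "i7c", W_bancrofti = "i7c",
       A_suum = "i7c",
       C_teleta = c("i3l", "i4c", "i7l", "i7c", "i9l"),
       T_adhaerens = c("i7l", "i7c", "i9l"),
       H_magnipapillata = c("i7l", "i7c", "i9l"),
       N_vectensis = c("i7l", "i7c", "i9l")))
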
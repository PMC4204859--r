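# intronarch

Comparative analysis of intron–exon architecture evolution in orthologous
genes.

Deeply conserved single-copy genes — the motivating case is the core
α1,6-fucosyltransferase gene *fut8*, present from the earliest metazoans to
vertebrates — accumulate intron gains and losses that leave a readable
record: the positions and codon phases at which introns interrupt the
coding sequence. `intronarch` is for molecular evolutionists who want to
turn that record into explicit characters and events. It:

* computes **intron phases** (`cds_offset mod 3`: phase 0 between codons,
  1 after the first nucleotide, 2 after the second) and the **exon
  notation** `u-c-d` (codon count `c` flanked by the split-codon
  nucleotides inside the exon), with exact merge/split algebra for exon
  fusion and fission, e.g. `1-51-0 + 0-58-0 → 1-109-0`;
* **projects insertion sites onto a protein alignment** (a phase-0 site at
  residue *r* lies between *r−1* and *r*, so `3·Δresidue + Δphase` is an
  exact nt distance), clusters sites requiring identical phase, and labels
  them `i<n>l / i<n>h / i<n>c` per reference lineage;
* detects **near intron pairs** (distinct sites within a configurable
  ≤ 32 nt window, suggestive of intron sliding);
* reconstructs **gain/loss events by Dollo parsimony** (single gain at the
  carriers' MRCA, provably minimal losses by subtree aggregation) on a
  rooted species tree, dated by the parent node's divergence age in MYA;
* builds **neighbor-joining trees from p-distances** with column-resampling
  bootstrap supports, with fixed tie-break and branch-clamping contracts;
* scores **translation-initiation (Kozak-like) contexts**: a position
  frequency matrix over the 10 nt upstream of the start codon, a threshold
  consensus (default 27%), and consensus-match scoring of candidate AUGs;
* ships a **synthetic-data generator** with exact ground truth (event
  ledger, site-to-column map) so every stage is testable end to end.

Published comparative tables for the *fut8* ortholog set (arthropod,
hymenopteran and chordate site tables, the start-context frequency table)
are included as plain-text fixtures, together with a schematic dated
metazoan tree; files with synthetic content are marked `_synthetic`.

## Worked example

```r
library(intronarch)

# per-gene architecture summaries
models <- read_gene_models_tsv(
  intronarch_extdata("fut8_gene_models_synthetic.tsv"))
summarize_gene(models$S_frugiperda)[c("n_introns", "total_intronic_bp")]
#> $n_introns
#> [1] 11
#> $total_intronic_bp
#> [1] 22071

# project sites onto the alignment, cluster, label by lineage
msa <- read_alignment_fasta(intronarch_extdata("fut8_msa_synthetic.fasta"))
sites <- do.call(rbind, lapply(models, infer_intron_sites))
cl <- cluster_sites(project_sites(sites, msa))
cl <- label_clusters(cl, c("S_frugiperda", "B_mori"), "l")
cl <- label_clusters(cl, c("H_sapiens", "B_taurus"), "c")
near_intron_pairs(cl, max_nt_distance = 32)
#>   label_a label_b nt_distance measured_on
#> 1     i8l     i7c          24     columns

# dated Dollo ledger on the schematic metazoan tree
tr <- ape::read.tree(intronarch_extdata("metazoa_schematic_tree.nwk"))
pa <- ifelse(site_table_presence(read_site_table(
  intronarch_extdata("metazoa_site_presence.tsv"))) == "present", TRUE, FALSE)
dated <- annotate_ages(dollo_ledger(pa, tr),
                       read_node_ages(intronarch_extdata("metazoa_node_ages.tsv")))
dated$i7l$gain_age       # 855  (MYA; gain on the branch into metazoa)
dated$i3l$loss_ages      # cladeII: 372  (single arthropod loss)

# start-codon context consensus at the default 27% threshold
pfm <- read_pfm_tsv(intronarch_extdata("sf9_start_pfm.tsv"))
derive_consensus(pfm, 27)
#> <context_consensus>  A A/U A/U/C A/U/C A/U/G U A/C A A A
```

The 11 introns / 22,071 bp summary, the single 24-nt `i8l`–`i7c` near
pair, the 855 and 372 MYA events and the consensus row are the published
values for this ortholog set. A full staged run (summaries → projection →
clustering → presence/absence → near pairs → NJ → Dollo) is available as
`run_pipeline()`; `inst/exec/intronarch-run` wraps it for the shell.

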
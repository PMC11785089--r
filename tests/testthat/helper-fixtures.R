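# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept tiny so the whole suite runs in well under a minute apart
# from the simulation-heavy recovery checks.

tiny_genome <- function(seed = 42, n_genes = 6L) {
  sim_genome(n_contigs = 1L, contig_length = 40000L, n_genes = n_genes,
             isg_fraction = 0.5, repeat_density = 1, seed = seed)
}

tiny_model <- function(wt_sites = 60L) {
  edit_model(wt_sites = wt_sites, shared_fraction = 0.5,
             gene_shared_fraction = 0.6,
             gene_private = c(WT = 0.2, Adar_het = 0.1, RdRp_tg = 0.1,
                              RdRp_Adar_het = 0.2))
}

# a hand-built genome with known coordinates, for deterministic annotation
# and orientation cases:
#   geneP (+, 101..400): exons 101-200 and 301-400; 5'UTR 101-130,
#     CDS 131-200 + 301-340, 3'UTR 341-400; intron 201-300
#   geneM (-, 601..900): exons 601-700 and 801-900; transcript runs
#     right-to-left so 5'UTR 871-900, CDS 631-700 + 801-870, 3'UTR 601-630
#   repeats: SINE 250-270 (inside geneP intron), LINE 240-260 (overlaps)
toy_genome <- function(seq_override = NULL) {
  seq <- seq_override %||% paste(rep("A", 1000), collapse = "")
  genes <- data.frame(
    gene_id = c("geneP", "geneM"), contig = "chr1",
    strand = c("+", "-"), start = c(101L, 601L), end = c(400L, 900L),
    is_isg = c(TRUE, FALSE), stringsAsFactors = FALSE)
  features <- rbind(
    data.frame(gene_id = "geneP", contig = "chr1", strand = "+",
               type = c("exon", "exon", "five_prime_UTR", "CDS", "CDS",
                        "three_prime_UTR"),
               start = c(101L, 301L, 101L, 131L, 301L, 341L),
               end = c(200L, 400L, 130L, 200L, 340L, 400L)),
    data.frame(gene_id = "geneM", contig = "chr1", strand = "-",
               type = c("exon", "exon", "three_prime_UTR", "CDS", "CDS",
                        "five_prime_UTR"),
               start = c(601L, 801L, 601L, 631L, 801L, 871L),
               end = c(700L, 900L, 630L, 700L, 870L, 900L)))
  repeats <- data.frame(contig = "chr1",
                        start = c(250L, 240L), end = c(270L, 260L),
                        repeat_class = c("SINE", "LINE"),
                        stringsAsFactors = FALSE)
  structure(list(seq = Biostrings::DNAStringSet(c(chr1 = seq)),
                 genes = genes, features = features, repeats = repeats),
            class = "editome_genome")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# literal brute-force re-statement of the calling thresholds, used as the
# oracle for call_edit_sites()
brute_force_calls <- function(pileup, th) {
  hits <- list()
  for (i in seq_len(nrow(pileup))) {
    ref <- pileup$ref[i]
    cov <- pileup$A[i] + pileup$C[i] + pileup$G[i] + pileup$T[i]
    edited <- if (ref == "A") pileup$G[i] else if (ref == "T") pileup$C[i]
              else next
    if (cov == 0) next
    frac <- edited / cov
    if (edited >= th$min_edited && cov >= th$min_coverage &&
        frac >= th$min_fraction && frac < th$max_fraction) {
      hits[[length(hits) + 1L]] <- data.frame(
        contig = pileup$contig[i], pos = pileup$pos[i], ref = ref,
        change = if (ref == "A") "A>G" else "T>C",
        coverage = cov, edited = edited, fraction = frac,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(contig = character(), pos = integer(), ref = character(),
               change = character(), coverage = integer(),
               edited = integer(), fraction = numeric())
}

random_pileup <- function(n, contig = "chr1") {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  data.frame(contig = contig, pos = seq_len(n), ref = ref,
             A = rpois(n, 4), C = rpois(n, 2), G = rpois(n, 3),
             T = rpois(n, 2), stringsAsFactors = FALSE)
}

# linear-scan oracle for point annotation: checks every feature interval of
# every gene, applies the priority ladder and the smallest-repeat rule
linear_scan_annotate <- function(genome, contig, pos) {
  f <- genome$features
  ladder <- c(three_prime_UTR = "three_prime_utr",
              five_prime_UTR = "five_prime_utr", CDS = "exon_cds")
  category <- "intergenic"; gene <- NA_character_
  found <- FALSE
  for (type in names(ladder)) {
    rows <- which(f$type == type & f$contig == contig &
                  f$start <= pos & pos <= f$end)
    if (length(rows)) {
      gids <- sort(f$gene_id[rows])
      category <- ladder[[type]]; gene <- gids[1L]; found <- TRUE
      break
    }
  }
  if (!found) {
    # intron: inside some gene's body but in no exon of that gene
    g <- genome$genes
    for (gi in order(g$gene_id)) {
      if (g$contig[gi] != contig || pos < g$start[gi] || pos > g$end[gi])
        next
      ex <- f[f$gene_id == g$gene_id[gi] & f$type == "exon", ]
      if (!any(ex$start <= pos & pos <= ex$end)) {
        category <- "intron"; gene <- g$gene_id[gi]; found <- TRUE
        break
      }
    }
  }
  r <- genome$repeats
  rows <- which(r$contig == contig & r$start <= pos & pos <= r$end)
  repeat_class <- NA_character_
  if (length(rows)) {
    w <- r$end[rows] - r$start[rows] + 1L
    ord <- order(w, match(r$repeat_class[rows], REPEAT_CLASSES),
                 r$start[rows])
    repeat_class <- r$repeat_class[rows][ord[1L]]
  }
  list(category = category, gene_id = gene, repeat_class = repeat_class)
}
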
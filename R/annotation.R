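#' Build a queryable interval index over genes and repeats
#'
#' Wraps the gene features and repeat intervals of a genome (or plain data
#' frames in the same layout) in [GenomicRanges::GRanges] objects so that
#' point queries resolve by overlap. Introns are derived as the gaps between
#' consecutive exons of each gene. Construction is order-independent;
#' overlapping repeats of different classes are accepted and resolved at
#' query time (smallest interval wins, ties broken by class priority
#' LINE > SINE > DNA_transposon > other_retroelement, then leftmost start).
#'
#' @param genes gene table (`gene_id`, `contig`, `strand`, `start`, `end`),
#'   or an `editome_genome`, in which case `features`/`repeats` are taken
#'   from it.
#' @param features per-gene feature table (`gene_id`, `contig`, `strand`,
#'   `type` in exon/CDS/five_prime_UTR/three_prime_UTR, `start`, `end`).
#' @param repeats repeat table (`contig`, `start`, `end`, `repeat_class`).
#' @return an object of class `feature_index`.
#' @export
feature_index <- function(genes, features = NULL, repeats = NULL) {
  if (inherits(genes, "editome_genome")) {
    features <- genes$features
    repeats <- genes$repeats
    genes <- genes$genes
  }
  features <- features %||% genes[0, ]
  repeats <- repeats %||% data.frame(contig = character(), start = integer(),
                                     end = integer(),
                                     repeat_class = character())
  as_gr <- function(df, ...) {
    if (nrow(df) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(df$contig,
                           IRanges::IRanges(df$start, df$end), ...)
  }
  pick <- function(type) features[features$type == type, , drop = FALSE]
  u3 <- pick("three_prime_UTR"); u5 <- pick("five_prime_UTR")
  cds <- pick("CDS"); ex <- pick("exon")

  ## introns: per-gene gaps between sorted exons
  introns <- do.call(rbind, lapply(split(ex, ex$gene_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2L) return(NULL)
    data.frame(gene_id = e$gene_id[1L], contig = e$contig[1L],
               strand = e$strand[1L],
               start = e$end[-nrow(e)] + 1L, end = e$start[-1L] - 1L,
               stringsAsFactors = FALSE)
  }))
  introns <- introns %||% ex[0, c("gene_id", "contig", "strand", "start", "end")]
  introns <- introns[introns$end >= introns$start, , drop = FALSE]

  gr_with_gene <- function(df) {
    gr <- as_gr(df)
    if (length(gr)) S4Vectors::mcols(gr)$gene_id <- df$gene_id
    gr
  }
  gr_genes <- as_gr(genes, strand = genes$strand)
  if (length(gr_genes)) S4Vectors::mcols(gr_genes)$gene_id <- genes$gene_id
  gr_rep <- as_gr(repeats)
  if (length(gr_rep)) S4Vectors::mcols(gr_rep)$repeat_class <- repeats$repeat_class

  structure(list(
    genes = gr_genes,
    regions = list(three_prime_utr = gr_with_gene(u3),
                   five_prime_utr = gr_with_gene(u5),
                   exon_cds = gr_with_gene(cds),
                   intron = gr_with_gene(introns)),
    repeats = gr_rep,
    gene_strand = setNames(genes$strand, genes$gene_id),
    is_isg = if ("is_isg" %in% names(genes))
      setNames(genes$is_isg, genes$gene_id) else NULL
  ), class = "feature_index")
}

# Core point-annotation kernel: vectors of contig/pos -> category, gene_id,
# repeat_class by the priority ladder. Used by annotate_sites() and by the
# truth planter.
annotate_positions <- function(index, contig, pos) {
  n <- length(pos)
  category <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  if (n == 0L) {
    return(data.frame(category = character(), gene_id = character(),
                      repeat_class = character(), stringsAsFactors = FALSE))
  }
  pts <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
  unassigned <- rep(TRUE, n)
  for (cat in names(index$regions)) {
    gr <- index$regions[[cat]]
    if (!length(gr)) next
    hits <- GenomicRanges::findOverlaps(pts, gr, ignore.strand = TRUE)
    if (!length(hits)) next
    q <- S4Vectors::queryHits(hits)
    g <- S4Vectors::mcols(gr)$gene_id[S4Vectors::subjectHits(hits)]
    # deterministic multi-gene tie-break: lexicographically smallest gene_id
    ord <- order(q, g)
    q <- q[ord]; g <- g[ord]
    first <- !duplicated(q)
    sel <- q[first][unassigned[q[first]]]
    gsel <- g[first][unassigned[q[first]]]
    if (length(sel)) {
      category[sel] <- cat
      gene_id[sel] <- gsel
      unassigned[sel] <- FALSE
    }
  }
  repeat_class <- rep(NA_character_, n)
  if (length(index$repeats)) {
    hits <- GenomicRanges::findOverlaps(pts, index$repeats,
                                        ignore.strand = TRUE)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      w <- GenomicRanges::width(index$repeats)[s]
      cl <- S4Vectors::mcols(index$repeats)$repeat_class[s]
      st <- GenomicRanges::start(index$repeats)[s]
      ord <- order(q, w, match(cl, REPEAT_CLASSES), st)
      q <- q[ord]; cl <- cl[ord]
      first <- !duplicated(q)
      repeat_class[q[first]] <- cl[first]
    }
  }
  data.frame(category = category, gene_id = gene_id,
             repeat_class = repeat_class, stringsAsFactors = FALSE)
}

#' Attribute edit sites to RNA elements and repeat classes
#'
#' Each site receives exactly one region category by the priority ladder
#' 3'UTR > 5'UTR > CDS exon > intron > intergenic, evaluated over all genes
#' overlapping the position, and independently at most one repeat class
#' (smallest overlapping repeat interval; ties by class priority). Region
#' and repeat attribution are orthogonal: a 3'UTR site inside a SINE carries
#' both labels.
#'
#' @param sites data frame of edit calls with `contig` and `pos` columns.
#' @param index a [feature_index()].
#' @return `sites` with `category`, `gene_id` and `repeat_class` columns
#'   appended.
#' @export
annotate_sites <- function(sites, index) {
  stopifnot(inherits(index, "feature_index"))
  ann <- annotate_positions(index, sites$contig, sites$pos)
  cbind(sites, ann)
}

#' Region distribution of annotated sites
#'
#' Counts and proportions of sites per RNA-element category. With no sites,
#' counts are 0 and proportions are `NA` (undefined, not silently 0/0).
#'
#' @param sites annotated site data frame (needs a `category` column).
#' @param collapse_utr5 merge the 5'UTR category into `exon_cds`, for a
#'   four-category breakdown where 5'UTRs are not reported separately.
#' @return data frame with `category`, `count`, `proportion`; proportions
#'   sum to 1 when `sites` is non-empty.
#' @export
region_distribution <- function(sites, collapse_utr5 = FALSE) {
  cat <- sites$category
  levels <- REGION_CATEGORIES
  if (collapse_utr5) {
    cat[cat == "five_prime_utr"] <- "exon_cds"
    levels <- setdiff(levels, "five_prime_utr")
  }
  counts <- table(factor(cat, levels = levels))
  n <- sum(counts)
  data.frame(category = levels,
             count = as.integer(counts),
             proportion = if (n == 0L) NA_real_ else as.integer(counts) / n,
             stringsAsFactors = FALSE)
}
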
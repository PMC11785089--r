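#' Simulate a miniature annotated genome
#'
#' Builds a small random genome with protein-coding gene models (exons, CDS,
#' UTRs, implicit introns), an ISG subset, and repeat intervals of the four
#' retroelement classes. The scale defaults to two 100 kb contigs carrying 40
#' genes: large enough that every RNA-element category and repeat class is
#' represented, small enough to simulate and analyse in seconds.
#'
#' Gene spans are placed left to right with random intergenic gaps; each gene
#' has 3-6 exons whose exonic span is partitioned, in transcript order, into
#' a 5'UTR (~10%), CDS, and a long 3'UTR (~30%). ISG 3'UTRs are seeded with a
#' SINE each, mirroring the retroelement-rich 3'UTRs of interferon-stimulated
#' transcripts; further repeats are scattered uniformly.
#'
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig in bp.
#' @param n_genes total number of genes to place.
#' @param isg_fraction fraction of genes flagged as ISGs (count is
#'   `round(n_genes * isg_fraction)`).
#' @param repeat_density expected scattered repeats per kb of genome
#'   (0 disables repeats entirely, including the ISG 3'UTR SINEs).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return an object of class `editome_genome`: a list with `seq`
#'   (a [Biostrings::DNAStringSet]), `genes`, `features` and `repeats`
#'   data frames. All intervals are 1-based closed.
#' @export
sim_genome <- function(n_contigs = 2L, contig_length = 100000L,
                       n_genes = 40L, isg_fraction = 0.25,
                       repeat_density = 1, seed) {
  stopifnot(n_contigs >= 1L, contig_length >= 1000L, n_genes >= 1L,
            isg_fraction >= 0, isg_fraction <= 1, repeat_density >= 0)
  if (missing(seed)) stop("'seed' is required: the genome is seed-determined")
  set.seed(stage_seed(seed, "genome"))

  contig_names <- paste0("ctg", seq_len(n_contigs))
  seqs <- vapply(contig_names, function(nm) {
    paste(sample(c("A", "C", "G", "T"), contig_length, replace = TRUE),
          collapse = "")
  }, character(1))

  ## draw gene structures first, then check they fit
  structures <- lapply(seq_len(n_genes), function(i) {
    k <- sample(3:6, 1L)
    exon_len <- sample(150:500, k, replace = TRUE)
    intron_len <- if (k > 1L) sample(200:900, k - 1L, replace = TRUE) else integer()
    list(exon_len = exon_len, intron_len = intron_len,
         span = sum(exon_len) + sum(intron_len))
  })
  spans <- vapply(structures, `[[`, numeric(1), "span")
  min_gap <- 300L
  if (any(spans > contig_length)) {
    stop("gene span (", max(spans), " bp) exceeds contig length (",
         contig_length, " bp); enlarge contigs or shorten genes")
  }
  if (sum(spans) + (n_genes + n_contigs) * min_gap > n_contigs * contig_length) {
    stop("cannot place ", n_genes, " genes totalling ", sum(spans),
         " bp on ", n_contigs, " x ", contig_length, " bp contigs")
  }

  ## greedy left-to-right placement, round-robin across contigs
  genes <- vector("list", n_genes)
  features <- vector("list", n_genes)
  cursor <- setNames(rep(1L, n_contigs), contig_names)
  ci <- 1L
  for (i in seq_len(n_genes)) {
    st <- structures[[i]]
    placed <- FALSE
    for (gap in c(sample(min_gap:1500L, 1L), min_gap)) {
      for (try in seq_len(n_contigs)) {
        ctg <- contig_names[ci]
        start <- cursor[ctg] + gap
        end <- start + st$span - 1L
        ci <- ci %% n_contigs + 1L
        if (end <= contig_length) {
          cursor[ctg] <- end + 1L
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) stop("ran out of contig space placing gene ", i)
    gid <- sprintf("gene%03d", i)
    strand <- sample(c("+", "-"), 1L)
    ex <- exon_layout(start, st$exon_len, st$intron_len)
    part <- partition_exons(ex, strand)
    genes[[i]] <- data.frame(gene_id = gid, contig = ctg, strand = strand,
                             start = start, end = end, is_isg = FALSE,
                             stringsAsFactors = FALSE)
    feat <- rbind(
      data.frame(type = "exon", start = ex$start, end = ex$end,
                 stringsAsFactors = FALSE),
      part
    )
    feat$gene_id <- gid
    feat$contig <- ctg
    feat$strand <- strand
    features[[i]] <- feat
  }
  genes <- do.call(rbind, genes)
  features <- do.call(rbind, features)[, c("gene_id", "contig", "strand",
                                           "type", "start", "end")]

  n_isg <- round(n_genes * isg_fraction)
  if (n_isg > 0L) genes$is_isg[sample(n_genes, n_isg)] <- TRUE

  repeats <- sim_repeats(genes, features, contig_names, contig_length,
                         repeat_density)

  structure(list(seq = Biostrings::DNAStringSet(seqs),
                 genes = genes, features = features, repeats = repeats),
            class = "editome_genome")
}

# exon intervals (1-based closed) from a start position and length vectors
exon_layout <- function(start, exon_len, intron_len) {
  k <- length(exon_len)
  starts <- integer(k); ends <- integer(k)
  pos <- start
  for (j in seq_len(k)) {
    starts[j] <- pos
    ends[j] <- pos + exon_len[j] - 1L
    pos <- ends[j] + 1L + if (j < k) intron_len[j] else 0L
  }
  data.frame(start = starts, end = ends)
}

# Split the exonic span (in transcript order) into five_prime_UTR / CDS /
# three_prime_UTR sub-intervals of the exons. UTR sizes: ~10% and ~30% of
# exonic bp, at least 30 bp each.
partition_exons <- function(exons, strand) {
  total <- sum(exons$end - exons$start + 1L)
  u5 <- max(30L, round(0.10 * total))
  u3 <- max(30L, round(0.30 * total))
  stopifnot(u5 + u3 < total)
  breaks <- c(u5, total - u5 - u3, u3)  # transcript-order lengths
  types <- c("five_prime_UTR", "CDS", "three_prime_UTR")
  ex <- exons[order(exons$start), , drop = FALSE]
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  out <- list(); oi <- 1L
  ti <- 1L; remaining <- breaks[1L]
  for (j in seq_len(nrow(ex))) {
    # walk this exon in transcript order, slicing off pieces
    w <- ex$end[j] - ex$start[j] + 1L
    lo <- ex$start[j]; hi <- ex$end[j]
    while (w > 0L) {
      take <- min(w, remaining)
      if (strand == "+") {
        piece <- c(lo, lo + take - 1L); lo <- lo + take
      } else {
        piece <- c(hi - take + 1L, hi); hi <- hi - take
      }
      out[[oi]] <- data.frame(type = types[ti], start = piece[1L],
                              end = piece[2L], stringsAsFactors = FALSE)
      oi <- oi + 1L
      w <- w - take
      remaining <- remaining - take
      if (remaining == 0L && ti < 3L) {
        ti <- ti + 1L
        remaining <- breaks[ti]
      }
    }
  }
  do.call(rbind, out)
}

sim_repeats <- function(genes, features, contig_names, contig_length,
                        repeat_density) {
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), repeat_class = character(),
                      stringsAsFactors = FALSE)
  if (repeat_density == 0) return(empty)
  len_range <- list(LINE = c(500L, 3000L), SINE = c(100L, 300L),
                    DNA_transposon = c(200L, 1000L),
                    other_retroelement = c(300L, 800L))
  n_scatter <- round(repeat_density * length(contig_names) *
                     contig_length / 1000)
  cls <- sample(REPEAT_CLASSES, n_scatter, replace = TRUE,
                prob = c(0.3, 0.4, 0.2, 0.1))
  # guarantee each class appears at least once
  missing_cls <- setdiff(REPEAT_CLASSES, unique(cls))
  cls <- c(cls, missing_cls)
  reps <- lapply(cls, function(cl) {
    rng <- len_range[[cl]]
    w <- sample(rng[1L]:rng[2L], 1L)
    ctg <- sample(contig_names, 1L)
    s <- sample(contig_length - w, 1L)
    data.frame(contig = ctg, start = as.integer(s),
               end = as.integer(s + w - 1L),
               repeat_class = cl, stringsAsFactors = FALSE)
  })
  # one SINE inside each ISG 3'UTR segment that can hold it
  isg <- genes$gene_id[genes$is_isg]
  u3 <- features[features$type == "three_prime_UTR" &
                 features$gene_id %in% isg, , drop = FALSE]
  sines <- lapply(which(u3$end - u3$start + 1L >= 120L), function(j) {
    w <- sample(80L:min(250L, u3$end[j] - u3$start[j] + 1L), 1L)
    s <- u3$start[j] + sample(0:(u3$end[j] - u3$start[j] + 1L - w), 1L)
    data.frame(contig = u3$contig[j], start = as.integer(s),
               end = as.integer(s + w - 1L),
               repeat_class = "SINE", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(reps, sines))
  if (is.null(out)) empty else out[order(out$contig, out$start), ]
}

#' @export
print.editome_genome <- function(x, ...) {
  cat("Synthetic annotated genome\n")
  cat("  contigs:", length(x$seq), "totalling",
      sum(Biostrings::width(x$seq)), "bp\n")
  cat("  genes:  ", nrow(x$genes), "(", sum(x$genes$is_isg), "ISGs )\n")
  cat("  repeats:", nrow(x$repeats), "\n")
  invisible(x)
}

# base at 1-based positions of one contig, as a character vector
contig_bases <- function(genome, contig) {
  strsplit(as.character(genome$seq[[contig]]), "", fixed = TRUE)[[1L]]
}
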
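#' Write and read the simulated genome and annotation
#'
#' Fixture writers for the synthetic genome: FASTA for sequences, GFF3
#' (1-based closed, gene/mRNA/exon/CDS/five_prime_UTR/three_prime_UTR) for
#' gene models, BED (0-based half-open, name = repeat class) for repeats.
#' Coordinates are converted at the file boundary only; in memory
#' everything is 1-based closed.
#'
#' @param genome an `editome_genome`.
#' @param path output file path.
#' @name genome_io
NULL

#' @rdname genome_io
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seq, path)
  invisible(path)
}

#' @rdname genome_io
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname genome_io
#' @export
write_annotation_gff3 <- function(genome, path) {
  g <- genome$genes
  f <- genome$features
  rows <- list(
    data.frame(contig = g$contig, type = "gene", start = g$start,
               end = g$end, strand = g$strand,
               attr = sprintf("ID=%s;is_isg=%s", g$gene_id,
                              ifelse(g$is_isg, "true", "false")),
               stringsAsFactors = FALSE),
    data.frame(contig = g$contig, type = "mRNA", start = g$start,
               end = g$end, strand = g$strand,
               attr = sprintf("ID=%s.t1;Parent=%s", g$gene_id, g$gene_id),
               stringsAsFactors = FALSE),
    data.frame(contig = f$contig, type = f$type, start = f$start,
               end = f$end, strand = f$strand,
               attr = sprintf("Parent=%s.t1", f$gene_id),
               stringsAsFactors = FALSE)
  )
  df <- do.call(rbind, rows)
  gff <- data.frame(df$contig, "editomer", df$type, df$start, df$end, ".",
                    df$strand, ".", df$attr, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(gff, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname genome_io
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", , drop = FALSE]
  feats <- df[df$type %in% c("exon", "CDS", "five_prime_UTR",
                             "three_prime_UTR"), , drop = FALSE]
  parent <- sub("\\.t1$", "", vapply(feats$Parent, `[`, character(1), 1L))
  list(
    genes = data.frame(gene_id = genes$ID, contig = as.character(genes$seqnames),
                       strand = as.character(genes$strand),
                       start = genes$start, end = genes$end,
                       is_isg = if ("is_isg" %in% names(genes))
                         genes$is_isg == "true" else FALSE,
                       stringsAsFactors = FALSE),
    features = data.frame(gene_id = parent,
                          contig = as.character(feats$seqnames),
                          strand = as.character(feats$strand),
                          type = as.character(feats$type),
                          start = feats$start, end = feats$end,
                          stringsAsFactors = FALSE)
  )
}

#' @rdname genome_io
#' @export
write_repeats_bed <- function(genome, path) {
  r <- genome$repeats
  bed <- data.frame(r$contig, r$start - 1L, r$end, r$repeat_class,
                    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname genome_io
#' @export
read_repeats_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             repeat_class = gr$name, stringsAsFactors = FALSE)
}

#' Write a minimal exome variant VCF (v4.2)
#'
#' One mouse line's germline variants as a small VCF: CHROM/POS/REF/ALT
#' with a single sample column carrying a 0/1 (heterozygous) or 1/1
#' genotype. Positions are 1-based per VCF.
#'
#' @param snps data frame with `contig`, `pos`, `ref`, `alt`, `het`.
#' @param path output path.
#' @param sample sample column name.
#' @export
write_exome_vcf <- function(snps, path, sample = "line") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      sample)), con)
  if (nrow(snps)) {
    gt <- ifelse(snps$het %||% TRUE, "0/1", "1/1")
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                    snps$contig, snps$pos, snps$ref, snps$alt, gt)
    writeLines(body, con)
  }
  invisible(path)
}

#' Read germline SNP positions from a VCF
#'
#' @param path a VCF file (plain text or bgzipped).
#' @return data frame with `contig`, `pos`, `ref`, `alt`.
#' @export
read_exome_snps <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("VariantAnnotation is required to read VCF files")
  }
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  data.frame(contig = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = as.character(rr$REF),
             alt = vapply(rr$ALT, function(a) as.character(a)[1L],
                          character(1)),
             stringsAsFactors = FALSE)
}

#' Pileup, counts, design and truth table I/O
#'
#' Plain TSVs. Pileups have the header `contig pos ref A C G T` with
#' 1-based positions.
#'
#' @param pileup,counts,design,truth,calls objects to write.
#' @param path file path.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_pileup <- function(pileup, path) {
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_pileup <- function(path) {
  read.delim(path, colClasses = c(contig = "character", ref = "character"))
}

#' @rdname table_io
#' @export
write_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_calls <- function(path) {
  read.delim(path, colClasses = c(contig = "character", ref = "character",
                                  change = "character", strand = "character"))
}

#' @rdname table_io
#' @export
write_counts <- function(counts, path) {
  write.table(data.frame(gene = rownames(counts), counts,
                         check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' @rdname table_io
#' @export
write_design <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_design <- function(path) {
  read.delim(path, colClasses = "character")
}

#' @rdname table_io
#' @export
write_truth <- function(truth, path) {
  write.table(truth$edit_sites, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an ISG reference list (one gene per line)
#'
#' @param path text file, one gene identifier per line; blank lines and
#'   lines starting with `#` are skipped.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
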
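#' Thresholds for candidate A-to-I site calling
#'
#' The study's editome was built from all A-to-G changes; no explicit
#' thresholds were part of that description, so these follow standard
#' editing-caller practice and are fully configurable. The fraction ceiling
#' guards against unfiltered homozygous variants (an edit fraction of 1 in
#' every read is a genotype, not editing).
#'
#' @param min_coverage minimum total read depth at the position.
#' @param min_edited minimum edited (A-to-G / T-to-C) read count.
#' @param min_fraction,max_fraction allowed edit-fraction window; a call
#'   requires `min_fraction <= fraction < max_fraction` (half-open at the
#'   top).
#' @param error_rate assumed per-base sequencing error rate (carried as
#'   metadata; not used to filter).
#' @export
edit_thresholds <- function(min_coverage = 10L, min_edited = 2L,
                            min_fraction = 0.05, max_fraction = 0.95,
                            error_rate = 0.003) {
  stopifnot(min_fraction >= 0, min_fraction < max_fraction,
            max_fraction <= 1, min_edited >= 1L,
            min_coverage >= min_edited)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_edited = as.integer(min_edited),
                 min_fraction = min_fraction, max_fraction = max_fraction,
                 error_rate = error_rate),
            class = "edit_thresholds")
}

#' Call candidate A-to-I editing sites from a pileup
#'
#' Scans one sample's pileup for RNA-DNA differences of the A-to-I
#' signature: reference A with G reads (or reference T with C reads, the
#' minus-strand image). All other mismatch classes are never emitted. A
#' position is called iff the edited-read count, total coverage and edit
#' fraction satisfy `thresholds`. Transcript strand is not resolved here
#' (see [orient_edits()]); germline SNPs are not yet excluded (see
#' [exclude_snps()]).
#'
#' @param pileup data frame with `contig`, `pos` (1-based), `ref`, and
#'   `A`/`C`/`G`/`T` count columns.
#' @param genome an `editome_genome` (or any object whose `seq` is a named
#'   DNAStringSet) used to verify the pileup's reference bases; pass `NULL`
#'   to skip the check.
#' @param thresholds an [edit_thresholds()].
#' @param sample_id label attached to the calls.
#' @return data frame of calls: `contig`, `pos`, `ref`, `change` (`A>G` or
#'   `T>C` on the reference strand), `strand` (`NA` until oriented),
#'   `coverage`, `edited`, `fraction`, `sample_id`.
#' @export
call_edit_sites <- function(pileup, genome = NULL,
                            thresholds = edit_thresholds(),
                            sample_id = NA_character_) {
  stopifnot(inherits(thresholds, "edit_thresholds"),
            all(c("contig", "pos", "ref", "A", "C", "G", "T") %in%
                names(pileup)))
  if (any(pileup$A < 0 | pileup$C < 0 | pileup$G < 0 | pileup$T < 0)) {
    stop("negative base counts in pileup")
  }
  if (!is.null(genome)) {
    for (ctg in unique(pileup$contig)) {
      rows <- pileup$contig == ctg
      bases <- contig_bases(genome, ctg)
      if (any(pileup$pos[rows] < 1L | pileup$pos[rows] > length(bases))) {
        stop("pileup position outside reference on ", ctg)
      }
      bad <- which(pileup$ref[rows] != bases[pileup$pos[rows]])
      if (length(bad)) {
        p <- pileup$pos[rows][bad[1L]]
        stop("pileup reference base disagrees with genome at ",
             ctg, ":", p, " (pileup ", pileup$ref[rows][bad[1L]],
             ", genome ", bases[p], ")")
      }
    }
  }
  coverage <- pileup$A + pileup$C + pileup$G + pileup$T
  edited <- ifelse(pileup$ref == "A", pileup$G,
                   ifelse(pileup$ref == "T", pileup$C, 0L))
  fraction <- ifelse(coverage > 0, edited / coverage, 0)
  keep <- pileup$ref %in% c("A", "T") &
    edited >= thresholds$min_edited &
    coverage >= thresholds$min_coverage &
    fraction >= thresholds$min_fraction &
    fraction < thresholds$max_fraction
  out <- data.frame(
    contig = pileup$contig[keep], pos = pileup$pos[keep],
    ref = pileup$ref[keep],
    change = ifelse(pileup$ref[keep] == "A", "A>G", "T>C"),
    strand = NA_character_,
    coverage = coverage[keep], edited = edited[keep],
    fraction = fraction[keep],
    sample_id = sample_id, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Exclude germline SNP positions from candidate calls
#'
#' Removes every candidate whose (contig, position) appears in the line's
#' exome variant set. Exclusion keys on position only, not allele: the
#' conservative reading of purging any colony-specific SNP from the
#' editome. Order and all other fields of the surviving calls are
#' preserved; an empty SNP set returns the input unchanged.
#'
#' @param calls candidate call data frame.
#' @param snps data frame with `contig` and `pos` (1-based) columns, e.g.
#'   from [read_exome_snps()] or a truth set.
#' @return `calls` minus the SNP-coincident rows.
#' @export
exclude_snps <- function(calls, snps) {
  if (is.null(snps) || nrow(snps) == 0L || nrow(calls) == 0L) return(calls)
  drop <- paste(calls$contig, calls$pos) %in% paste(snps$contig, snps$pos)
  out <- calls[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve transcript strand of candidate calls
#'
#' A-to-I editing happens on the transcribed strand, so a reference-strand
#' A>G change is a genuine edit only where a + strand gene is transcribed
#' (and T>C only under a - strand gene). Calls whose change is inconsistent
#' with every overlapping gene's strand are discarded; calls in unannotated
#' (intergenic) space cannot be oriented and are retained with strand
#' `"ambiguous"` (set `drop_ambiguous = TRUE` to drop them instead).
#'
#' @param calls candidate call data frame.
#' @param genome an `editome_genome`, or a gene table with `gene_id`,
#'   `contig`, `strand`, `start`, `end`.
#' @param drop_ambiguous drop calls outside any annotated gene?
#' @return the oriented calls with `strand` set to `+`, `-` or
#'   `"ambiguous"`.
#' @export
orient_edits <- function(calls, genome, drop_ambiguous = FALSE) {
  genes <- if (inherits(genome, "editome_genome")) genome$genes else genome
  if (nrow(calls) == 0L) return(calls)
  has_plus <- has_minus <- rep(FALSE, nrow(calls))
  if (nrow(genes)) {
    pts <- GenomicRanges::GRanges(calls$contig,
                                  IRanges::IRanges(calls$pos, calls$pos))
    gb <- GenomicRanges::GRanges(genes$contig,
                                 IRanges::IRanges(genes$start, genes$end))
    hits <- GenomicRanges::findOverlaps(pts, gb)
    q <- S4Vectors::queryHits(hits)
    s <- genes$strand[S4Vectors::subjectHits(hits)]
    has_plus[unique(q[s == "+"])] <- TRUE
    has_minus[unique(q[s == "-"])] <- TRUE
  }
  genic <- has_plus | has_minus
  consistent <- (calls$change == "A>G" & has_plus) |
                (calls$change == "T>C" & has_minus)
  strand <- ifelse(!genic, "ambiguous",
                   ifelse(calls$change == "A>G", "+", "-"))
  keep <- consistent | !genic
  if (drop_ambiguous) keep <- keep & genic
  out <- calls[keep, , drop = FALSE]
  out$strand <- strand[keep]
  rownames(out) <- NULL
  out
}

#' One-sample editome: call, SNP-filter, orient, annotate
#'
#' Convenience wrapper running the per-sample pipeline in the canonical
#' order: candidate calling, germline SNP exclusion, transcript-strand
#' orientation, and feature/repeat annotation.
#'
#' @inheritParams call_edit_sites
#' @inheritParams exclude_snps
#' @inheritParams orient_edits
#' @param index a [feature_index()]; built from `genome` if omitted.
#' @return annotated, oriented, SNP-filtered call data frame.
#' @export
sample_editome <- function(pileup, genome, snps,
                           thresholds = edit_thresholds(),
                           index = feature_index(genome),
                           sample_id = NA_character_,
                           drop_ambiguous = FALSE) {
  calls <- call_edit_sites(pileup, genome, thresholds, sample_id)
  calls <- exclude_snps(calls, snps)
  calls <- orient_edits(calls, genome, drop_ambiguous)
  annotate_sites(calls, index)
}
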
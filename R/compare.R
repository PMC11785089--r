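#' Consensus edited sites across replicates
#'
#' A site belongs to a genotype's consensus editome iff the identical
#' (contig, position, change) triple is called in every replicate — the
#' n-fold set intersection, generalising the study's all-four-animals rule
#' to n replicates. Edit fraction is not part of site identity. Use
#' `min_replicates` to relax the rule (defaults to all).
#'
#' @param calls_list list of per-replicate call data frames (already
#'   SNP-filtered and oriented).
#' @param min_replicates number of replicates a site must appear in
#'   (default: all of them).
#' @return data frame of consensus sites (`contig`, `pos`, `change`).
#' @export
consensus_sites <- function(calls_list, min_replicates = length(calls_list)) {
  stopifnot(length(calls_list) >= 1L,
            min_replicates >= 1L, min_replicates <= length(calls_list))
  keysets <- lapply(calls_list, function(df)
    unique(site_key(df$contig, df$pos, df$change)))
  tab <- table(unlist(keysets))
  keys <- as.character(names(tab)[tab >= min_replicates])
  out <- split_site_key(sort(keys))
  rownames(out) <- NULL
  out
}

#' Consensus edited genes across replicates
#'
#' A gene belongs to the consensus iff every replicate has at least one
#' filtered call annotated to it — editing can occur anywhere in the gene
#' and at different sites in different replicates, so this set always
#' contains the genes of the consensus sites but is typically larger.
#'
#' @param annotated_calls_list list of per-replicate annotated call data
#'   frames (need a `gene_id` column; intergenic calls, `gene_id` `NA`,
#'   never contribute).
#' @inheritParams consensus_sites
#' @return character vector of consensus gene ids (sorted).
#' @export
consensus_genes <- function(annotated_calls_list,
                            min_replicates = length(annotated_calls_list)) {
  stopifnot(length(annotated_calls_list) >= 1L)
  genesets <- lapply(annotated_calls_list, function(df)
    unique(df$gene_id[!is.na(df$gene_id)]))
  tab <- table(unlist(genesets))
  sort(as.character(names(tab)[tab >= min_replicates]))
}

#' Four-set Venn partition
#'
#' Partitions the union of four named sets into the 15 disjoint membership
#' cells (every non-empty subset of the four names). The four singleton
#' cells are each set's unique elements.
#'
#' @param sets named list of exactly four character vectors.
#' @return data frame with one row per cell: a logical column per set name,
#'   `cell` (names joined by `&`), and `n`; `attr(, "members")` holds the
#'   element lists. Cell counts sum to the union size.
#' @export
venn_partition <- function(sets) {
  stopifnot(is.list(sets), length(sets) == 4L, !is.null(names(sets)),
            !anyDuplicated(names(sets)))
  nm <- names(sets)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, nm))
  ## all 15 non-empty subsets, singletons first, then by size
  masks <- expand.grid(rep(list(c(TRUE, FALSE)), 4L))[-16L, 4:1]
  names(masks) <- nm
  masks <- masks[order(rowSums(masks)), , drop = FALSE]
  sig <- apply(masks, 1L, function(m) paste(nm[as.logical(m)], collapse = "&"))
  member_sig <- if (length(universe)) {
    apply(member, 1L, function(m) paste(nm[m], collapse = "&"))
  } else character()
  members <- lapply(sig, function(s) universe[member_sig == s])
  out <- cbind(masks, data.frame(cell = sig,
                                 n = lengths(members),
                                 stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "members") <- setNames(members, sig)
  out
}

#' Compare consensus editomes across the four genotypes
#'
#' Runs the full comparison: per-genotype consensus sites and genes, a
#' counts table with RNA-element and repeat-class breakdowns, region
#' distributions, four-set Venn partitions of sites and genes, per-genotype
#' uniquely edited sites/genes (the singleton Venn cells), and the
#' double-het / WT consensus-site ratio — the statistic behind the
#' dysregulated-editing excess.
#'
#' @param calls_by_sample named list (by `sample_id`) of SNP-filtered,
#'   oriented call data frames.
#' @param design data frame mapping `sample_id` to `genotype` (all four
#'   genotypes required).
#' @param index a [feature_index()] over the shared genome annotation;
#'   consensus sites are annotated against it (replicate-invariant by
#'   construction).
#' @param ratio_genotypes length-2 character: numerator and denominator
#'   genotypes of the reported site-count ratio.
#' @param min_replicates consensus rule (default: all replicates).
#' @return an object of class `editome_comparison`.
#' @export
compare_editomes <- function(calls_by_sample, design, index,
                             ratio_genotypes = c("RdRp_Adar_het", "WT"),
                             min_replicates = NULL) {
  stopifnot(inherits(index, "feature_index"),
            all(design$sample_id %in% names(calls_by_sample)))
  genotypes <- unique(design$genotype)
  if (length(genotypes) != 4L) stop("exactly four genotypes required")

  per_geno <- lapply(setNames(genotypes, genotypes), function(g) {
    sids <- design$sample_id[design$genotype == g]
    reps <- lapply(calls_by_sample[sids], function(df)
      annotate_sites(df, index))
    k <- min_replicates %||% length(reps)
    sites <- consensus_sites(reps, min_replicates = k)
    sites <- annotate_sites(sites, index)
    genes <- consensus_genes(reps, min_replicates = k)
    list(sites = sites, genes = genes)
  })

  counts <- do.call(rbind, lapply(genotypes, function(g) {
    s <- per_geno[[g]]$sites
    rc <- table(factor(s$repeat_class, levels = REPEAT_CLASSES))
    cc <- table(factor(s$category, levels = REGION_CATEGORIES))
    cbind(data.frame(genotype = g, n_genes = length(per_geno[[g]]$genes),
                     n_sites = nrow(s), stringsAsFactors = FALSE),
          as.data.frame.matrix(t(as.matrix(cc))),
          as.data.frame.matrix(t(as.matrix(rc))))
  }))
  rownames(counts) <- NULL

  region <- do.call(rbind, lapply(genotypes, function(g) {
    d <- region_distribution(per_geno[[g]]$sites)
    cbind(genotype = g, d)
  }))

  site_sets <- lapply(per_geno, function(x)
    site_key(x$sites$contig, x$sites$pos, x$sites$change))
  gene_sets <- lapply(per_geno, `[[`, "genes")
  venn_sites <- venn_partition(site_sets)
  venn_genes <- venn_partition(gene_sets)

  singleton <- function(venn, g) {
    m <- attr(venn, "members")
    m[[g]]
  }
  unique_sites <- lapply(setNames(genotypes, genotypes), function(g) {
    df <- split_site_key(singleton(venn_sites, g))
    annotate_sites(df, index)
  })
  unique_genes <- lapply(setNames(genotypes, genotypes), function(g)
    singleton(venn_genes, g))

  num <- counts$n_sites[counts$genotype == ratio_genotypes[1L]]
  den <- counts$n_sites[counts$genotype == ratio_genotypes[2L]]
  ratio <- if (length(num) && length(den) && den > 0) num / den else NA_real_

  structure(list(consensus = per_geno, counts = counts, region = region,
                 venn_sites = venn_sites, venn_genes = venn_genes,
                 unique_sites = unique_sites, unique_genes = unique_genes,
                 site_ratio = ratio, ratio_genotypes = ratio_genotypes),
            class = "editome_comparison")
}

#' @export
print.editome_comparison <- function(x, ...) {
  cat("Consensus editome comparison (all-replicates rule)\n\n")
  print(x$counts[, c("genotype", "n_genes", "n_sites")], row.names = FALSE)
  cat("\nuniquely edited:",
      paste(sprintf("%s %d sites / %d genes", names(x$unique_sites),
                    vapply(x$unique_sites, nrow, integer(1)),
                    lengths(x$unique_genes)), collapse = "; "), "\n")
  cat(sprintf("site-count ratio %s / %s = %.3f\n",
              x$ratio_genotypes[1L], x$ratio_genotypes[2L], x$site_ratio))
  invisible(x)
}

#' @export
summary.editome_comparison <- function(object, ...) {
  cat("Counts table (consensus sites by RNA element and repeat class):\n")
  print(object$counts, row.names = FALSE)
  cat("\nRegion distribution:\n")
  print(object$region, row.names = FALSE)
  cat("\nVenn cells (sites):\n")
  print(object$venn_sites[, c("cell", "n")], row.names = FALSE)
  cat("\nVenn cells (genes):\n")
  print(object$venn_genes[, c("cell", "n")], row.names = FALSE)
  invisible(object)
}
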
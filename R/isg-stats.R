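#' Log-normalized expression with one pseudocount
#'
#' Counts-per-million (or FPKM-like when gene lengths are supplied),
#' log2-transformed with 1 pseudocount: `log2(normalized + 1)`.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param gene_lengths optional per-gene lengths in bp (named or in row
#'   order); when given, normalization is per-kilobase per-million
#'   (FPKM-like) instead of CPM.
#' @return numeric matrix of the same shape.
#' @export
normalize_log <- function(counts, gene_lengths = NULL) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[libsize == 0], collapse = ", "),
         " (normalization undefined)")
  }
  norm <- sweep(counts, 2L, libsize, "/") * 1e6
  if (!is.null(gene_lengths)) {
    if (!is.null(names(gene_lengths))) {
      gene_lengths <- gene_lengths[rownames(counts)]
    }
    stopifnot(length(gene_lengths) == nrow(counts), all(gene_lengths > 0))
    norm <- norm / (gene_lengths / 1e3)
  }
  log2(norm + 1)
}

#' Per-gene log2 fold changes versus the reference genotype
#'
#' Mean difference on the log scale: `mean(genotype) - mean(reference)` of
#' the log-normalized values, per gene. The reference-vs-reference column is
#' identically 0.
#'
#' @param norm log-normalized matrix from [normalize_log()].
#' @param design data frame with `sample_id`, `genotype`.
#' @param reference reference genotype (default `"WT"`).
#' @return matrix genes x genotypes of log2 fold changes.
#' @export
fold_changes <- function(norm, design, reference = "WT") {
  stopifnot(reference %in% design$genotype,
            all(design$sample_id %in% colnames(norm)))
  genotypes <- unique(design$genotype)
  means <- vapply(genotypes, function(g) {
    rowMeans(norm[, design$sample_id[design$genotype == g], drop = FALSE])
  }, numeric(nrow(norm)))
  means - means[, reference]
}

#' Welch tests with Benjamini-Hochberg correction for one contrast
#'
#' Per-gene two-sided unequal-variance (Welch) t-test on log-normalized
#' values between two groups, with BH q-values over all tested genes. A
#' gene with zero variance in both groups gets p = 1 when the means are
#' equal (no evidence) and p = 0 when they differ (infinite t, a
#' degenerate-input convention).
#'
#' @param norm log-normalized matrix.
#' @param design data frame with `sample_id`, `genotype`.
#' @param contrast length-2 character, `c(group, reference)`; each needs
#'   >= 2 replicates.
#' @return data frame: `gene`, `log2fc` (group minus reference mean), `t`,
#'   `p`, `q`.
#' @export
test_differential <- function(norm, design, contrast = c("RdRp_Adar_het", "WT")) {
  stopifnot(length(contrast) == 2L, all(contrast %in% design$genotype))
  a <- norm[, design$sample_id[design$genotype == contrast[1L]], drop = FALSE]
  b <- norm[, design$sample_id[design$genotype == contrast[2L]], drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2L || n2 < 2L) stop(">= 2 replicates per group required")
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1L)
  v2 <- rowSums((b - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  q <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(norm), log2fc = m1 - m2, t = tstat,
             p = p, q = q, row.names = NULL, stringsAsFactors = FALSE)
}

#' Expression summary with DEG and ISG flags
#'
#' One-stop wrapper: normalizes, computes the per-gene fold change and
#' Welch/BH statistics for a contrast, and flags differentially expressed
#' genes (`|log2FC| >= fc_threshold` and `q <= q_threshold`) and ISG
#' membership.
#'
#' @param counts genes x samples count matrix.
#' @param design data frame with `sample_id`, `genotype`.
#' @param isg_genes character vector of ISG identifiers (the reference
#'   list; supplied, not bundled).
#' @param contrast `c(group, reference)` passed to [test_differential()].
#' @param fc_threshold,q_threshold DEG thresholds.
#' @param gene_lengths optional, for FPKM-like normalization.
#' @return data frame per gene: statistics plus `is_deg`, `is_isg`.
#' @export
expression_summary <- function(counts, design, isg_genes,
                               contrast = c("RdRp_Adar_het", "WT"),
                               fc_threshold = 1, q_threshold = 0.05,
                               gene_lengths = NULL) {
  norm <- normalize_log(counts, gene_lengths)
  res <- test_differential(norm, design, contrast)
  res$is_deg <- abs(res$log2fc) >= fc_threshold & res$q <= q_threshold
  res$is_isg <- res$gene %in% isg_genes
  res
}

#' ISG fraction among differentially expressed genes
#'
#' The "N out of M" summary: how many DEGs are known ISGs.
#'
#' @param deg_genes character vector of DEG identifiers.
#' @param isg_genes ISG reference list (non-empty).
#' @param universe optional full gene universe; used only to detect an
#'   identifier-namespace mismatch (zero overlap between universe and ISG
#'   list raises a warning rather than a silent zero).
#' @return list: `n_deg`, `n_deg_isg`, `fraction` (`NA` when no DEGs), and
#'   a `summary` string.
#' @export
classify_isg_fraction <- function(deg_genes, isg_genes, universe = NULL) {
  stopifnot(length(isg_genes) >= 1L)
  check <- universe %||% deg_genes
  if (length(check) && !length(intersect(check, isg_genes))) {
    warning("no overlap between gene identifiers and the ISG list; ",
            "check identifier namespaces")
  }
  n <- length(unique(deg_genes))
  k <- length(intersect(deg_genes, isg_genes))
  list(n_deg = n, n_deg_isg = k,
       fraction = if (n == 0L) NA_real_ else k / n,
       summary = sprintf("%d out of %d DEGs are known ISGs", k, n))
}

#' Two-sided exact test for a 2x2 table
#'
#' Conditional (hypergeometric) exact test: with margins fixed, the p-value
#' is the sum of probabilities of all tables whose probability does not
#' exceed that of the observed table — the common two-sided convention.
#'
#' @param a,b,c,d the 2x2 cell counts (row 1: a, b; row 2: c, d).
#' @return two-sided p-value.
#' @export
exact_test_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' ISG enrichment among uniquely edited sites
#'
#' Builds the 2x2 table of uniquely edited genic sites (in-ISG vs in-other
#' genes) for two genotypes and applies the two-sided exact test.
#' Intergenic sites carry no gene and are excluded. The odds ratio is
#' `ad/bc`, with 0.5 added to every cell when any cell is zero (Haldane
#' continuity fallback); a zero margin (no genic sites in a genotype, or no
#' sites in one ISG class at all) makes the table untestable and is
#' flagged rather than tested.
#'
#' @param unique_sites_a,unique_sites_b annotated unique-site data frames
#'   for the two genotypes (need `gene_id`).
#' @param isg_map named logical vector: gene_id -> is this gene an ISG?
#' @param labels genotype labels for the table dimnames.
#' @param intergenic `"exclude"` (default) drops intergenic sites from the
#'   table; `"nearest"` assigns each one the nearest gene on its contig
#'   (requires `index`).
#' @param index a [feature_index()], needed only for the nearest-gene mode.
#' @return list of class `isg_proportion_test`: `table`, `odds_ratio`,
#'   `p`, `untestable`.
#' @export
isg_proportion_test <- function(unique_sites_a, unique_sites_b, isg_map,
                                labels = c("A", "B"),
                                intergenic = c("exclude", "nearest"),
                                index = NULL) {
  intergenic <- match.arg(intergenic)
  if (intergenic == "nearest") {
    stopifnot(inherits(index, "feature_index"))
    unique_sites_a <- assign_nearest_gene(unique_sites_a, index)
    unique_sites_b <- assign_nearest_gene(unique_sites_b, index)
  }
  count_row <- function(sites) {
    g <- sites$gene_id[!is.na(sites$gene_id)]
    isg <- isg_map[g]
    isg[is.na(isg)] <- FALSE
    c(in_isg = sum(isg), in_other = sum(!isg))
  }
  tab <- rbind(count_row(unique_sites_a), count_row(unique_sites_b))
  rownames(tab) <- labels
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  untestable <- (a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0
  or <- if (any(tab == 0)) {
    (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5))
  } else {
    a * d / (b * c)
  }
  p <- if (untestable) NA_real_ else exact_test_2x2(a, b, c, d)
  structure(list(table = tab, odds_ratio = or, p = p,
                 untestable = untestable),
            class = "isg_proportion_test")
}

# fill NA gene_id with the nearest annotated gene on the same contig
assign_nearest_gene <- function(sites, index) {
  na <- which(is.na(sites$gene_id))
  if (!length(na) || !length(index$genes)) return(sites)
  pts <- GenomicRanges::GRanges(sites$contig[na],
                                IRanges::IRanges(sites$pos[na],
                                                 sites$pos[na]))
  hit <- GenomicRanges::nearest(pts, index$genes, ignore.strand = TRUE)
  ok <- !is.na(hit)
  sites$gene_id[na[ok]] <-
    S4Vectors::mcols(index$genes)$gene_id[hit[ok]]
  sites
}

#' @export
print.isg_proportion_test <- function(x, ...) {
  cat("ISG proportion test on uniquely edited genic sites\n")
  print(x$table)
  if (x$untestable) {
    cat("untestable: a table margin is zero\n")
  } else {
    cat(sprintf("odds ratio %.3f, two-sided exact p = %.4g\n",
                x$odds_ratio, x$p))
  }
  invisible(x)
}
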
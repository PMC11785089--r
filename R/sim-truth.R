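#' Per-genotype edit model for the truth planter
#'
#' Describes how many editing sites each genotype carries and where they
#' fall. Genotype site sets share a common core (present in all four) plus
#' genotype-private extras, so four-set Venn overlap structure exists by
#' construction. The double heterozygote's total is `wt_sites * dhet_ratio`
#' exactly (sites are planted, not sampled into existence); its private
#' extras are drawn with extra weight on 3'UTR positions, repeat
#' (LINE/SINE)-overlapping positions, and ISG genes, emulating the 3'UTR /
#' retroelement shift of the dysregulated editome.
#'
#' @param wt_sites number of active sites in the wild type.
#' @param dhet_ratio double-het / WT active-site ratio (default 1.6, the
#'   middle of the observed 50-65% excess).
#' @param adar_het_ratio,rdrp_ratio active-site ratios for the single
#'   mutants relative to WT (site numbers largely unchanged).
#' @param shared_fraction fraction of WT sites shared by all four genotypes.
#' @param fraction_range range of per-site edit fractions (uniform draw; a
#'   length-1 value fixes all fractions).
#' @param base_weights category sampling weights for core and single-mutant
#'   sites (majority intergenic and 3'UTR).
#' @param dhet_weights category weights for the double-het private extras.
#' @param repeat_boost multiplicative weight for LINE/SINE-overlapping
#'   candidate positions among double-het extras.
#' @param isg_boost multiplicative weight for positions in ISG genes among
#'   double-het extras.
#' @param gene_shared_fraction fraction of genes editable in every
#'   genotype. Editing is gene-targeted: each genotype's genic sites fall
#'   only in this shared gene set plus its private set, so genotypes differ
#'   in edited genes, not just sites.
#' @param gene_private per-genotype fractions of genes privately editable
#'   (the singles lose, and the double het gains, edited genes relative to
#'   WT).
#' @param isg_fc ranges of ISG expression multipliers per genotype
#'   (low / large / largest tiers).
#' @return a list of class `edit_model` with the per-genotype site counts in
#'   `$n_sites`.
#' @export
edit_model <- function(wt_sites = 500L, dhet_ratio = 1.6,
                       adar_het_ratio = 0.94, rdrp_ratio = 1.0,
                       shared_fraction = 0.6,
                       fraction_range = c(0.2, 0.8),
                       base_weights = c(three_prime_utr = 0.30,
                                        five_prime_utr = 0.05,
                                        exon_cds = 0.12, intron = 0.13,
                                        intergenic = 0.40),
                       dhet_weights = c(three_prime_utr = 0.55,
                                        five_prime_utr = 0.05,
                                        exon_cds = 0.10, intron = 0.10,
                                        intergenic = 0.20),
                       repeat_boost = 3, isg_boost = 3,
                       gene_shared_fraction = 0.5,
                       gene_private = c(WT = 0.10, Adar_het = 0.05,
                                        RdRp_tg = 0.075,
                                        RdRp_Adar_het = 0.20),
                       isg_fc = list(WT = c(1, 1), Adar_het = c(2, 5),
                                     RdRp_tg = c(20, 100),
                                     RdRp_Adar_het = c(200, 600))) {
  n_sites <- c(WT = as.integer(wt_sites),
               Adar_het = as.integer(round(wt_sites * adar_het_ratio)),
               RdRp_tg = as.integer(round(wt_sites * rdrp_ratio)),
               RdRp_Adar_het = as.integer(round(wt_sites * dhet_ratio)))
  n_core <- as.integer(round(wt_sites * shared_fraction))
  if (any(n_sites < n_core)) {
    stop("shared core (", n_core, " sites) exceeds a genotype's total")
  }
  if (length(fraction_range) == 1L) fraction_range <- rep(fraction_range, 2L)
  stopifnot(fraction_range[1] >= 0, fraction_range[2] <= 1,
            fraction_range[1] <= fraction_range[2])
  stopifnot(gene_shared_fraction >= 0, gene_shared_fraction <= 1,
            all(GENOTYPES %in% names(gene_private)))
  structure(list(n_sites = n_sites, n_core = n_core,
                 fraction_range = fraction_range,
                 base_weights = base_weights, dhet_weights = dhet_weights,
                 repeat_boost = repeat_boost, isg_boost = isg_boost,
                 gene_shared_fraction = gene_shared_fraction,
                 gene_private = gene_private,
                 isg_fc = isg_fc),
            class = "edit_model")
}

#' Plant ground-truth edits, SNPs and ISG expression effects
#'
#' Selects real genomic positions for the per-genotype editing-site sets
#' (reference A on the transcript strand: A in + genes, T in - genes, either
#' in intergenic space), assigns each site a per-genotype edit fraction
#' (0 where the genotype does not edit it), places heterozygous germline
#' A>G / T>C SNPs in exonic (exome-captured) space disjoint from the edit
#' sites, and draws per-gene ISG expression multipliers for each genotype.
#'
#' @param genome an `editome_genome`.
#' @param model an [edit_model()].
#' @param snp_count number of heterozygous germline SNPs to plant.
#' @param seed integer seed.
#' @return an object of class `editome_truth`: list with `edit_sites`
#'   (one row per site; `f_<genotype>` columns hold edit fractions),
#'   `snps`, and `isg_fc` (gene x genotype multiplier matrix).
#' @export
plant_truth <- function(genome, model = edit_model(), snp_count = 60L, seed) {
  stopifnot(inherits(genome, "editome_genome"), inherits(model, "edit_model"))
  if (missing(seed)) stop("'seed' is required")
  set.seed(stage_seed(seed, "truth"))
  idx <- feature_index(genome)

  pool <- candidate_pool(genome, idx)

  ## gene-targeted editing: a shared editable gene set plus per-genotype
  ## private sets; remaining genes carry no planted edits at all
  gid <- genome$genes$gene_id
  shuffled <- sample(gid)
  n_shared <- round(length(gid) * model$gene_shared_fraction)
  shared_genes <- shuffled[seq_len(n_shared)]
  rest <- shuffled[-seq_len(n_shared)]
  private <- list()
  off <- 0L
  for (g in GENOTYPES) {
    k <- min(round(length(gid) * model$gene_private[[g]]),
             max(0L, length(rest) - off))
    private[[g]] <- rest[seq_len(k) + off]
    off <- off + k
  }

  pick <- function(n, cat_weights, repeat_boost, isg_boost, allowed_genes,
                   exclude) {
    ok <- (is.na(pool$gene_id) | pool$gene_id %in% allowed_genes) &
      !(seq_len(nrow(pool)) %in% exclude)
    avail <- which(ok)
    if (n > length(avail)) {
      stop("requested ", n, " edit sites but only ", length(avail),
           " candidate A positions remain (shortfall ", n - length(avail), ")")
    }
    w <- position_weights(pool[avail, , drop = FALSE], cat_weights,
                          repeat_boost, isg_boost, idx)
    avail[sample.int(length(avail), n, prob = w)]
  }

  core <- pick(model$n_core, model$base_weights, 1, 1, shared_genes,
               integer())
  used <- core
  extras <- list()
  for (g in GENOTYPES) {
    n_extra <- model$n_sites[[g]] - model$n_core
    allowed <- c(shared_genes, private[[g]])
    extras[[g]] <- if (g == "RdRp_Adar_het") {
      pick(n_extra, model$dhet_weights, model$repeat_boost,
           model$isg_boost, allowed, used)
    } else {
      pick(n_extra, model$base_weights, 1, 1, allowed, used)
    }
    used <- c(used, extras[[g]])
  }

  all_idx <- sort(unique(used))
  sites <- pool[all_idx, , drop = FALSE]
  rownames(sites) <- NULL
  fr <- model$fraction_range
  f <- runif(nrow(sites), fr[1], fr[2])
  for (g in GENOTYPES) {
    active <- all_idx %in% c(core, extras[[g]])
    sites[[paste0("f_", g)]] <- ifelse(active, f, 0)
  }

  snps <- plant_snps(pool, sites, snp_count)
  isg_fc <- draw_isg_fc(genome, model$isg_fc)

  structure(list(edit_sites = sites, snps = snps, isg_fc = isg_fc,
                 model = model),
            class = "editome_truth")
}

# All positions where an A-to-I edit can be planted: transcript-strand A.
candidate_pool <- function(genome, idx) {
  pools <- lapply(names(genome$seq), function(ctg) {
    bases <- contig_bases(genome, ctg)
    pos <- which(bases %in% c("A", "T"))
    data.frame(contig = ctg, pos = pos, ref = bases[pos],
               stringsAsFactors = FALSE)
  })
  pool <- do.call(rbind, pools)
  ann <- annotate_positions(idx, pool$contig, pool$pos)
  pool <- cbind(pool, ann)
  gstrand <- idx$gene_strand[pool$gene_id]
  genic <- !is.na(pool$gene_id)
  # transcript-strand A: ref A in + genes, ref T in - genes; intergenic both
  keep <- !genic | (gstrand == "+" & pool$ref == "A") |
          (gstrand == "-" & pool$ref == "T")
  pool <- pool[keep, , drop = FALSE]
  pool$change <- ifelse(pool$ref == "A", "A>G", "T>C")
  pool$strand <- ifelse(is.na(pool$gene_id), NA_character_,
                        unname(idx$gene_strand[pool$gene_id]))
  rownames(pool) <- NULL
  pool
}

position_weights <- function(pool, cat_weights, repeat_boost, isg_boost, idx) {
  # weight per position = category target share / category pool size, so
  # sampled category proportions track the configured weights
  pool_n <- table(pool$category)
  w <- unname(cat_weights[pool$category]) /
    as.numeric(pool_n[pool$category])
  w[is.na(w)] <- min(cat_weights) / nrow(pool)
  if (repeat_boost != 1) {
    in_rep <- !is.na(pool$repeat_class) &
      pool$repeat_class %in% c("LINE", "SINE")
    w[in_rep] <- w[in_rep] * repeat_boost
  }
  if (isg_boost != 1 && !is.null(idx$is_isg)) {
    in_isg <- !is.na(pool$gene_id) & idx$is_isg[pool$gene_id]
    w[in_isg] <- w[in_isg] * isg_boost
  }
  w
}

plant_snps <- function(pool, sites, snp_count) {
  # exome-captured: exonic categories only, disjoint from edit sites
  exonic <- pool$category %in% c("three_prime_utr", "five_prime_utr",
                                 "exon_cds")
  free <- exonic & !(site_key(pool$contig, pool$pos, pool$change) %in%
                     site_key(sites$contig, sites$pos, sites$change))
  cand <- which(free)
  if (snp_count > length(cand)) {
    stop("requested ", snp_count, " SNPs but only ", length(cand),
         " exonic positions remain")
  }
  sel <- sort(sample(cand, snp_count))
  data.frame(contig = pool$contig[sel], pos = pool$pos[sel],
             ref = pool$ref[sel],
             alt = ifelse(pool$ref[sel] == "A", "G", "C"),
             het = rep(TRUE, length(sel)), stringsAsFactors = FALSE)
}

draw_isg_fc <- function(genome, tiers) {
  genes <- c(genome$genes$gene_id, "RdRp_transgene")
  fc <- matrix(1, nrow = length(genes), ncol = length(GENOTYPES),
               dimnames = list(genes, GENOTYPES))
  isg <- genome$genes$gene_id[genome$genes$is_isg]
  for (g in GENOTYPES) {
    rng <- tiers[[g]]
    fc[isg, g] <- runif(length(isg), rng[1], rng[2])
  }
  fc
}

#' @export
print.editome_truth <- function(x, ...) {
  cat("Planted editome truth\n")
  n <- vapply(GENOTYPES, function(g) sum(x$edit_sites[[paste0("f_", g)]] > 0),
              numeric(1))
  cat("  active sites:",
      paste(sprintf("%s=%d", GENOTYPES, n), collapse = ", "), "\n")
  cat("  germline SNPs:", nrow(x$snps), "\n")
  invisible(x)
}
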
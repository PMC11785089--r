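#' Sample design table for the four-genotype cross
#'
#' @param replicates biological replicates per genotype (>= 2; the study
#'   design is 4 animals per genotype).
#' @return data frame with `sample_id`, `genotype`, `replicate`.
#' @export
sample_design <- function(replicates = 4L) {
  stopifnot(replicates >= 2L)
  data.frame(
    sample_id = paste(rep(GENOTYPES, each = replicates),
                      seq_len(replicates), sep = "_"),
    genotype = rep(GENOTYPES, each = replicates),
    replicate = rep(seq_len(replicates), times = length(GENOTYPES)),
    stringsAsFactors = FALSE
  )
}

#' Read-depth model for pileup simulation
#'
#' Per-position coverage is negative binomial around `mean_depth` times a
#' per-gene log-normal expression multiplier, so edit calling is exercised
#' under realistic depth variance. `size = Inf` makes coverage exactly
#' `round(mean_depth * multiplier)` (useful for analytic checks);
#' `gene_log_sd = 0` removes the gene-level variation.
#'
#' @param mean_depth mean read depth.
#' @param size negative-binomial size (dispersion) parameter.
#' @param gene_log_sd sd of the per-gene log-normal depth multiplier.
#' @export
coverage_model <- function(mean_depth = 30, size = 8, gene_log_sd = 0.3) {
  stopifnot(mean_depth >= 1, size > 0, gene_log_sd >= 0)
  structure(list(mean_depth = mean_depth, size = size,
                 gene_log_sd = gene_log_sd), class = "coverage_model")
}

#' Simulate per-sample RNA pileups
#'
#' Produces one pileup table per sample (every position of the genome:
#' `contig`, 1-based `pos`, `ref`, and A/C/G/T read counts). At a truth edit
#' site with fraction f and realised coverage c, the edited-base count is
#' Binomial(c, f(1-e) + (1-f)e/3) where e is the per-base error rate; at a
#' heterozygous SNP the alt fraction is centred at 0.5; all other positions
#' acquire mismatches only through sequencing error (uniform substitution to
#' each of the three non-reference bases).
#'
#' @param genome an `editome_genome`.
#' @param truth an `editome_truth` (or `NULL` for a variant-free genome).
#' @param design a [sample_design()]-style data frame.
#' @param coverage a [coverage_model()].
#' @param error_rate per-base substitution error rate, in [0, 0.05].
#' @param seed integer seed; per-sample sub-seeds are derived from it, so a
#'   sample's pileup does not depend on the order of `design` rows.
#' @return named list of pileup data frames, one per `sample_id`.
#' @export
sim_pileups <- function(genome, truth, design, coverage = coverage_model(),
                        error_rate = 0.003, seed) {
  stopifnot(inherits(genome, "editome_genome"),
            inherits(coverage, "coverage_model"),
            error_rate >= 0, error_rate <= 0.05)
  if (missing(seed)) stop("'seed' is required")
  if (!is.null(truth)) {
    fcols <- paste0("f_", unique(design$genotype))
    missing_g <- setdiff(fcols, names(truth$edit_sites))
    if (length(missing_g)) {
      stop("design genotype(s) absent from truth: ",
           paste(sub("^f_", "", missing_g), collapse = ", "))
    }
  }

  ## position scaffold shared by all samples
  scaffold <- do.call(rbind, lapply(names(genome$seq), function(ctg) {
    bases <- contig_bases(genome, ctg)
    data.frame(contig = ctg, pos = seq_along(bases), ref = bases,
               stringsAsFactors = FALSE)
  }))
  pos_key <- paste(scaffold$contig, scaffold$pos)
  ## map positions to gene row (gene body, introns included) for the
  ## depth multiplier
  gene_of <- rep(NA_integer_, nrow(scaffold))
  if (nrow(genome$genes)) {
    pts <- GenomicRanges::GRanges(scaffold$contig,
                                  IRanges::IRanges(scaffold$pos, scaffold$pos))
    gb <- GenomicRanges::GRanges(genome$genes$contig,
                                 IRanges::IRanges(genome$genes$start,
                                                  genome$genes$end))
    hits <- GenomicRanges::findOverlaps(pts, gb)
    gene_of[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  }

  out <- lapply(design$sample_id, function(sid) {
    set.seed(stage_seed(seed, paste0("pileup:", sid)))
    genotype <- design$genotype[design$sample_id == sid][1L]
    mult <- rep(1, nrow(genome$genes))
    if (coverage$gene_log_sd > 0 && length(mult)) {
      mult <- rlnorm(length(mult), 0, coverage$gene_log_sd)
    }
    mu <- coverage$mean_depth * ifelse(is.na(gene_of), 1, mult[gene_of])
    cvg <- if (is.infinite(coverage$size)) as.integer(round(mu))
           else rnbinom(length(mu), size = coverage$size, mu = mu)

    counts <- error_counts(scaffold$ref, cvg, error_rate)

    if (!is.null(truth)) {
      f <- truth$edit_sites[[paste0("f_", genotype)]]
      counts <- overlay_variants(counts, pos_key, cvg, error_rate,
                                 truth$edit_sites, f)
      counts <- overlay_variants(counts, pos_key, cvg, error_rate,
                                 truth$snps, rep(0.5, nrow(truth$snps)))
    }
    storage.mode(counts) <- "integer"
    cbind(scaffold, as.data.frame(counts))
  })
  setNames(out, design$sample_id)
}

# Multinomial error split: total errors ~ Binom(c, e), divided uniformly
# among the three non-reference bases by conditional binomials.
error_counts <- function(ref, cvg, error_rate) {
  n <- length(ref)
  counts <- matrix(0L, nrow = n, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  k_err <- if (error_rate > 0) rbinom(n, cvg, error_rate) else integer(n)
  k1 <- rbinom(n, k_err, 1 / 3)
  k2 <- rbinom(n, k_err - k1, 1 / 2)
  k3 <- k_err - k1 - k2
  bases <- c("A", "C", "G", "T")
  ref_i <- match(ref, bases)
  for (j in 1:4) {
    rows <- ref_i == j
    counts[rows, j] <- cvg[rows] - k_err[rows]
    alt <- setdiff(1:4, j)
    counts[rows, alt[1L]] <- counts[rows, alt[1L]] + k1[rows]
    counts[rows, alt[2L]] <- counts[rows, alt[2L]] + k2[rows]
    counts[rows, alt[3L]] <- counts[rows, alt[3L]] + k3[rows]
  }
  counts
}

# Replace counts at variant positions: alt-base count ~ Binom(c, p_alt) with
# p_alt = f(1-e) + (1-f)e/3; remaining reads are reference except residual
# errors to the other two bases.
overlay_variants <- function(counts, pos_key, cvg, error_rate, var_df, f) {
  if (is.null(var_df) || nrow(var_df) == 0L) return(counts)
  active <- f > 0
  if (!any(active)) return(counts)
  var_df <- var_df[active, , drop = FALSE]
  f <- f[active]
  idx <- match(paste(var_df$contig, var_df$pos), pos_key)
  stopifnot(!anyNA(idx))
  bases <- c("A", "C", "G", "T")
  ref <- var_df$ref
  alt <- ifelse(ref == "A", "G", "C")  # A>G / T>C variants only
  c_i <- cvg[idx]
  p_alt <- f * (1 - error_rate) + (1 - f) * error_rate / 3
  k_alt <- rbinom(length(idx), c_i, p_alt)
  rest <- c_i - k_alt
  k_err <- rbinom(length(idx), rest, 2 * error_rate / 3)
  k_e1 <- rbinom(length(idx), k_err, 1 / 2)
  k_e2 <- k_err - k_e1
  newc <- matrix(0L, nrow = length(idx), ncol = 4L,
                 dimnames = list(NULL, bases))
  for (i in seq_along(idx)) {
    r <- match(ref[i], bases); a <- match(alt[i], bases)
    oth <- setdiff(1:4, c(r, a))
    newc[i, r] <- rest[i] - k_err[i]
    newc[i, a] <- k_alt[i]
    newc[i, oth[1L]] <- k_e1[i]
    newc[i, oth[2L]] <- k_e2[i]
  }
  counts[idx, ] <- newc
  counts
}

#' Negative-binomial expression model
#'
#' ISG genes start from a low (quiescent) baseline — interferon-stimulated
#' genes are near-silent without stimulation — so a several-hundred-fold
#' induction lands them at plausibly high, not absurd, expression. The
#' matrix also carries `n_background` inert transcriptome rows (multiplier
#' 1 in every genotype, named `bg####`) besides the editome genes, so
#' library-size normalization sees a realistic mass of unchanged genes and
#' massive ISG induction does not masquerade as global downregulation.
#'
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of per-gene
#'   baseline mean expression.
#' @param isg_baseline_meanlog log-normal mean of the ISG baseline.
#' @param size negative-binomial size (dispersion) of counts.
#' @param transgene_mean mean count of the `RdRp_transgene` pseudo-gene row
#'   in RdRp-bearing genotypes (exactly 0 elsewhere).
#' @param n_background inert background genes appended to the matrix.
#' @export
expression_model <- function(baseline_meanlog = log(200),
                             baseline_sdlog = 1,
                             isg_baseline_meanlog = log(10), size = 10,
                             transgene_mean = 500, n_background = 3000L) {
  structure(list(baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 isg_baseline_meanlog = isg_baseline_meanlog, size = size,
                 transgene_mean = transgene_mean,
                 n_background = as.integer(n_background)),
            class = "expression_model")
}

#' Simulate a gene-level expression count matrix
#'
#' Counts are negative binomial around baseline x genotype multiplier. ISG
#' genes carry the per-genotype multipliers of `truth$isg_fc` (tiers: low in
#' the Adar het, large with the RdRp transgene, largest in the double het);
#' non-ISG genes have multiplier 1 in every genotype. A pseudo-gene row
#' `RdRp_transgene` gets nonzero counts only in RdRp-bearing genotypes.
#'
#' @param genome an `editome_genome`.
#' @param design a [sample_design()]-style data frame.
#' @param truth an `editome_truth` carrying `isg_fc`, or a gene x genotype
#'   multiplier matrix.
#' @param model an [expression_model()].
#' @param seed integer seed.
#' @return integer matrix, genes (rows, including `RdRp_transgene`) x
#'   samples.
#' @export
sim_expression <- function(genome, design, truth, model = expression_model(),
                           seed) {
  stopifnot(inherits(genome, "editome_genome"))
  if (missing(seed)) stop("'seed' is required")
  set.seed(stage_seed(seed, "expression"))
  fc <- if (inherits(truth, "editome_truth")) truth$isg_fc else truth
  stopifnot("RdRp_transgene" %in% rownames(fc),
            all(design$genotype %in% colnames(fc)))
  if (model$n_background > 0L) {
    bg <- matrix(1, nrow = model$n_background, ncol = ncol(fc),
                 dimnames = list(sprintf("bg%04d", seq_len(model$n_background)),
                                 colnames(fc)))
    fc <- rbind(fc, bg)
  }
  genes <- rownames(fc)
  is_isg_gene <- genes %in%
    genome$genes$gene_id[genome$genes$is_isg]
  baseline <- rlnorm(length(genes),
                     ifelse(is_isg_gene, model$isg_baseline_meanlog,
                            model$baseline_meanlog),
                     model$baseline_sdlog)
  names(baseline) <- genes
  baseline["RdRp_transgene"] <- model$transgene_mean
  counts <- matrix(0L, nrow = length(genes), ncol = nrow(design),
                   dimnames = list(genes, design$sample_id))
  for (j in seq_len(nrow(design))) {
    g <- design$genotype[j]
    mu <- baseline * fc[, g]
    mu["RdRp_transgene"] <- if (g %in% c("RdRp_tg", "RdRp_Adar_het"))
      model$transgene_mean else 0
    k <- integer(length(mu))
    nz <- mu > 0
    k[nz] <- as.integer(rnbinom(sum(nz), size = model$size, mu = mu[nz]))
    counts[, j] <- k
  }
  counts
}
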
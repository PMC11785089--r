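#' @importFrom stats rbinom rnbinom rlnorm runif dhyper pt p.adjust setNames
#' @importFrom utils read.delim write.table
NULL

#' The four genotypes of the cross
#'
#' Genotype labels used throughout: wild type, Adar heterozygote, RdRp
#' transgene carrier, and the double heterozygote carrying both.
#'
#' @export
GENOTYPES <- c("WT", "Adar_het", "RdRp_tg", "RdRp_Adar_het")

#' RNA-element categories
#'
#' The disjoint region categories a site is attributed to, in ladder
#' priority order (highest first).
#'
#' @export
REGION_CATEGORIES <- c("three_prime_utr", "five_prime_utr", "exon_cds",
                       "intron", "intergenic")

#' Retroelement classes
#'
#' Repeat classes in tie-break priority order.
#'
#' @export
REPEAT_CLASSES <- c("LINE", "SINE", "DNA_transposon", "other_retroelement")

# Derive a reproducible per-stage seed from one top-level seed, so each
# simulation stage can be re-run independently. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629L)
}

# Composite site key used for set operations: identity is position plus
# reference-strand change; edit fraction is deliberately not part of it.
site_key <- function(contig, pos, change) {
  paste(contig, pos, change, sep = ":")
}

split_site_key <- function(keys) {
  if (length(keys) == 0L) {
    return(data.frame(contig = character(), pos = integer(),
                      change = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(
    contig = vapply(parts, `[[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[[`, character(1), 2L)),
    change = vapply(parts, `[[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
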
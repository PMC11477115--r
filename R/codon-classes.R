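#' High-frequency (HF) codon classification
#'
#' A codon is HF if its RFSC exceeds 0.60 (`abs60` rule) or exceeds 1.5 times
#' the family mean RFSC, which is `1/n_i` (`rel50` rule). Undefined families
#' are excluded.
#'
#' @param rfsc_values Named numeric vector from [rfsc()] on species-pooled
#'   counts.
#' @return data.frame of class `"hf_codons"` with columns `codon`, `aa`,
#'   `rfsc`, `rule` (`"abs60"`, `"rel50"` or `"both"`), sorted by codon.
#' @export
high_frequency_codons <- function(rfsc_values) {
  v <- rfsc_values[INFORMATIVE_CODONS]
  ni <- .codon_ni[INFORMATIVE_CODONS]
  abs60 <- !is.na(v) & v > 0.60
  rel50 <- !is.na(v) & v > 1.5 / ni
  hit <- abs60 | rel50
  out <- data.frame(
    codon = INFORMATIVE_CODONS[hit],
    aa = unname(.codon_aa[INFORMATIVE_CODONS[hit]]),
    rfsc = unname(v[hit]),
    rule = ifelse(abs60[hit] & rel50[hit], "both",
                  ifelse(abs60[hit], "abs60", "rel50")),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$codon), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hf_codons", "data.frame")
  out
}

#' Codons classed as high-frequency in every species
#'
#' @param sets List of `"hf_codons"` tables (or plain codon character
#'   vectors), one per species; must be non-empty.
#' @return Sorted character vector: the intersection across species.
#' @export
shared_hf <- function(sets) {
  if (!length(sets)) stop("no HF sets supplied")
  codons <- lapply(sets, function(s)
    if (is.data.frame(s)) s$codon else as.character(s))
  sort(Reduce(intersect, codons))
}

#' ENC-decile expression datasets
#'
#' Sorts genes by ENC and takes the lowest-ENC decile as the putative
#' high-expression set and the highest-ENC decile as the low-expression set;
#' the decile size is `ceiling(fraction * n)` and ENC ties are broken by
#' gene id (lexicographic) for determinism.
#'
#' @param set A [cds_set()].
#' @param enc_values Named numeric vector of per-gene ENC (names = gene ids
#'   of `set`); `NA` entries are dropped.
#' @param fraction Decile fraction (default 0.10).
#' @return List with [cds_set()] elements `high_expr` (lowest ENC) and
#'   `low_expr` (highest ENC).
#' @export
expression_datasets_by_enc <- function(set, enc_values, fraction = 0.10) {
  stopifnot(inherits(set, "cds_set"))
  enc_values <- enc_values[!is.na(enc_values)]
  ids <- intersect(names(set$seq), names(enc_values))
  if (length(ids) < 10L)
    stop("need at least 10 genes with defined ENC, have ", length(ids))
  k <- ceiling(fraction * length(ids))
  ord <- ids[order(enc_values[ids], ids)]
  lo <- ord[seq_len(k)]                          # lowest ENC -> high expression
  hi <- ord[seq.int(length(ord) - k + 1L, length(ord))]
  list(high_expr = cds_set(set$seq[lo], set$species, set$provenance),
       low_expr = cds_set(set$seq[hi], set$species, set$provenance))
}

#' Optimal codon detection from expression deciles
#'
#' A codon is optimal when its RSCU in the pooled high-expression set exceeds
#' 1, its RSCU in the pooled low-expression set is below 1, and the
#' difference exceeds `delta_min`. Codons whose family is unobserved in
#' either pool are skipped.
#'
#' @param high Pooled codon counts of the high-expression set.
#' @param low Pooled codon counts of the low-expression set.
#' @param delta_min Minimum RSCU difference (default 0.08).
#' @return data.frame with columns `codon`, `aa`, `rscu_high`, `rscu_low`,
#'   `delta_rscu`, sorted by codon.
#' @export
optimal_codons <- function(high, low, delta_min = 0.08) {
  rh <- rscu(high)
  rl <- rscu(low)
  ok <- !is.na(rh) & !is.na(rl) & rh > 1 & rl < 1 & (rh - rl) > delta_min
  out <- data.frame(
    codon = INFORMATIVE_CODONS[ok],
    aa = unname(.codon_aa[INFORMATIVE_CODONS[ok]]),
    rscu_high = unname(rh[ok]),
    rscu_low = unname(rl[ok]),
    delta_rscu = unname(rh[ok] - rl[ok]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$codon), , drop = FALSE]
  rownames(out) <- NULL
  out
}
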
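#' Codon counts for a gene or a pooled set
#'
#' Reads codons in frame from position 1 and tabulates them over the fixed
#' 64-codon domain. For a `cds_set` the per-gene tables are summed.
#'
#' @param x A single sequence, a named character vector of sequences, or a
#'   [cds_set()]. Every sequence length must be divisible by three.
#' @return Named integer vector over the 64 codons (class `"codon_counts"`),
#'   with attributes `total_codons` and `scope` (`"gene"` or
#'   `"species_pooled"`).
#' @export
codon_counts <- function(x) {
  seqs <- .as_seqs(x)
  if (!length(seqs)) stop("no sequences")
  bad <- nchar(seqs) %% 3L != 0L
  if (any(bad))
    stop("sequence length not a multiple of 3: ",
         paste(names(seqs)[bad], collapse = ", "))
  codons <- unlist(lapply(unname(seqs), .split_codons), use.names = FALSE)
  counts <- table(factor(codons, levels = CODONS))
  out <- setNames(as.integer(counts), CODONS)
  structure(out, total_codons = sum(out),
            scope = if (length(seqs) > 1L) "species_pooled" else "gene",
            class = "codon_counts")
}

#' Nucleotide and positional GC composition
#'
#' Overall base fractions, third-position base fractions, GC content at each
#' codon position, their combinations, and GC3s (the G+C fraction at third
#' positions of synonymous codons only, excluding ATG, TGG and stop codons).
#'
#' @inheritParams codon_counts
#' @return Named numeric vector with elements `frac_A`, `frac_T`, `frac_G`,
#'   `frac_C`, `A3`, `T3`, `G3`, `C3`, `GC1`, `GC2`, `GC3`, `GC`, `GC12`,
#'   `GC3s`.
#' @export
composition_profile <- function(x) {
  seqs <- .as_seqs(x)
  if (!length(seqs) || sum(nchar(seqs)) == 0L) stop("zero-length input")
  counts <- codon_counts(x)
  .composition_from_counts(counts)
}

.composition_from_counts <- function(counts) {
  codons <- names(counts)
  n <- as.numeric(counts)
  base_at <- function(pos, base)
    sum(n[substr(codons, pos, pos) == base])
  tot <- sum(n) # codons
  pos_gc <- vapply(1:3, function(p)
    (base_at(p, "G") + base_at(p, "C")) / tot, numeric(1))
  all_base <- vapply(c("A", "T", "G", "C"), function(b)
    sum(vapply(1:3, base_at, numeric(1), base = b)), numeric(1))
  third <- vapply(c("A", "T", "G", "C"), base_at, numeric(1), pos = 3L)

  syn <- setdiff(codons, c("ATG", "TGG", .STOP_CODONS))
  n_syn <- n[match(syn, codons)]
  third_syn <- substr(syn, 3L, 3L)
  gc3s_den <- sum(n_syn)
  gc3s <- if (gc3s_den > 0)
    sum(n_syn[third_syn %in% c("G", "C")]) / gc3s_den else NA_real_

  c(frac_A = unname(all_base["A"]) / (3 * tot),
    frac_T = unname(all_base["T"]) / (3 * tot),
    frac_G = unname(all_base["G"]) / (3 * tot),
    frac_C = unname(all_base["C"]) / (3 * tot),
    A3 = unname(third["A"]) / tot, T3 = unname(third["T"]) / tot,
    G3 = unname(third["G"]) / tot, C3 = unname(third["C"]) / tot,
    GC1 = pos_gc[1], GC2 = pos_gc[2], GC3 = pos_gc[3],
    GC = mean(pos_gc), GC12 = (pos_gc[1] + pos_gc[2]) / 2,
    GC3s = gc3s)
}

#' The six pairwise nucleotide skews
#'
#' Each skew is `(X - Y)/(X + Y)` on whole-gene nucleotide counts: AT skew
#' (A,T), GC skew (G,C), purine skew (A,G), pyrimidine skew (C,T), keto skew
#' (G,T) and amino skew (A,C). A skew whose denominator is zero is returned
#' as `NA` and excluded pairwise from downstream correlations.
#'
#' @param x A sequence / vector of sequences / [cds_set()], or a named
#'   numeric vector of nucleotide counts `c(A=, C=, G=, T=)`.
#' @return Named numeric vector `at_skew`, `gc_skew`, `purine_skew`,
#'   `pyrimidine_skew`, `keto_skew`, `amino_skew`, each in `[-1, 1]` or `NA`.
#' @export
nucleotide_skews <- function(x) {
  if (is.numeric(x)) {
    stopifnot(all(c("A", "C", "G", "T") %in% names(x)))
    cnt <- x[c("A", "C", "G", "T")]
  } else {
    seqs <- .as_seqs(x)
    all <- paste(seqs, collapse = "")
    cnt <- vapply(c("A", "C", "G", "T"), function(b)
      sum(strsplit(all, "")[[1]] == b), numeric(1))
  }
  sk <- function(p, q) {
    d <- cnt[[p]] + cnt[[q]]
    if (d == 0) NA_real_ else (cnt[[p]] - cnt[[q]]) / d
  }
  c(at_skew = sk("A", "T"), gc_skew = sk("G", "C"),
    purine_skew = sk("A", "G"), pyrimidine_skew = sk("C", "T"),
    keto_skew = sk("G", "T"), amino_skew = sk("A", "C"))
}
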
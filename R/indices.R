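#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of codon j in a synonymous family of size n_i is its observed count
#' divided by the family mean count: 1 means no bias, above 1 a preferred
#' codon. Computed over the 59 informative codons; families with zero
#' occurrences yield `NA` (undefined, not 0).
#'
#' @param counts A `"codon_counts"` table from [codon_counts()] (any named
#'   vector covering the 64 codons works).
#' @return Named numeric vector over [INFORMATIVE_CODONS].
#' @export
rscu <- function(counts) {
  x <- as.numeric(counts[INFORMATIVE_CODONS])
  out <- setNames(rep(NA_real_, length(x)), INFORMATIVE_CODONS)
  for (aa in names(.syn_families)) {
    fam <- .syn_families[[aa]]
    if (length(fam) < 1L) next
    xi <- x[match(fam, INFORMATIVE_CODONS)]
    tot <- sum(xi)
    if (!is.na(tot) && tot > 0) out[fam] <- xi / (tot / length(fam))
  }
  out
}

#' Relative frequency of synonymous codons (RFSC)
#'
#' Observed count divided by the family total; values of an observed family
#' sum to 1. `RFSC = RSCU / n_i` wherever both are defined.
#'
#' @inheritParams rscu
#' @return Named numeric vector over [INFORMATIVE_CODONS].
#' @export
rfsc <- function(counts) {
  rscu(counts) / .codon_ni[INFORMATIVE_CODONS]
}

#' Wright's effective number of codons (ENC)
#'
#' Per amino acid observed at least twice, the homozygosity estimate is
#' `F = (n * sum(p^2) - 1) / (n - 1)` with `p` the within-family codon
#' fractions; F is averaged within degeneracy classes {2, 3, 4, 6} and
#' `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, capped at 61. If the 3-fold class
#' (Ile) is missing it is imputed as `(F2 + F4)/2`; if class 2, 4 or 6 is
#' missing (or has zero mean homozygosity) ENC is undefined (`NA`).
#'
#' @param counts Codon counts of a single gene.
#' @return ENC in `[2, 61]`, or `NA`.
#' @export
enc <- function(counts) {
  x <- as.numeric(counts[INFORMATIVE_CODONS])
  names(x) <- INFORMATIVE_CODONS
  fhat <- ni <- numeric(0)
  for (aa in .degenerate_aas) {
    fam <- .syn_families[[aa]]
    xi <- x[fam]
    n <- sum(xi)
    if (n >= 2) {
      p <- xi / n
      fhat <- c(fhat, (n * sum(p^2) - 1) / (n - 1))
      ni <- c(ni, length(fam))
    }
  }
  fbar <- vapply(c(2, 3, 4, 6), function(k) {
    v <- fhat[ni == k]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  if (is.na(fbar[2]) && !is.na(fbar[1]) && !is.na(fbar[3]))
    fbar[2] <- (fbar[1] + fbar[3]) / 2
  if (anyNA(fbar) || any(fbar <= 0)) return(NA_real_)
  min(61, 2 + 9 / fbar[1] + 1 / fbar[2] + 5 / fbar[3] + 3 / fbar[4])
}

#' Expected ENC under mutation pressure alone
#'
#' Wright's null curve `2 + s + 29/(s^2 + (1-s)^2)` evaluated at the
#' synonymous third-position G+C fraction `s` (GC3s).
#'
#' @param gc3s Numeric vector with values in `[0, 1]`.
#' @return Expected ENC, same length as `gc3s`.
#' @export
expected_enc <- function(gc3s) {
  if (any(!is.na(gc3s) & (gc3s < 0 | gc3s > 1)))
    stop("gc3s must lie in [0, 1]")
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Synonymous codon usage order (SCUO)
#'
#' Information-theoretic bias measure: per degenerate amino acid i the
#' normalized entropy deficit `O_i = (log2 n_i - H_i)/log2 n_i` is weighted
#' by the amino acid's share of degenerate-codon occurrences. 0 means
#' uniform synonymous usage, 1 one codon per family.
#'
#' @inheritParams enc
#' @return SCUO in `[0, 1]`, `NA` if no degenerate amino acid is observed.
#' @export
scuo <- function(counts) {
  x <- as.numeric(counts[INFORMATIVE_CODONS])
  names(x) <- INFORMATIVE_CODONS
  wsum <- osum <- 0
  for (aa in .degenerate_aas) {
    fam <- .syn_families[[aa]]
    xi <- x[fam]
    n <- sum(xi)
    if (n > 0) {
      p <- xi[xi > 0] / n
      h <- -sum(p * log2(p))
      o <- (log2(length(fam)) - h) / log2(length(fam))
      wsum <- wsum + n
      osum <- osum + n * o
    }
  }
  if (wsum == 0) return(NA_real_)
  osum / wsum
}

#' MILC: measure independent of length and composition
#'
#' Goodness-of-fit distance between a gene's synonymous codon usage and a
#' reference usage (here typically the species' pooled filtered CDSs):
#' `MILC = sum_a M_a / L - C`, where `M_a = 2 * sum_c O_c ln(f_c/g_c)` over
#' the codons of amino acid a (O observed counts, f gene and g reference
#' within-family fractions), L is the gene's scored codon count and
#' `C = sum_a (r_a - 1)/L` over amino acids present (r_a = family size).
#'
#' If the reference has a zero count for a codon observed in the gene, 0.5 is
#' added to every codon of that family in the reference.
#'
#' @param counts Codon counts of the gene.
#' @param reference Codon counts of the reference distribution.
#' @return MILC value (numeric).
#' @export
milc <- function(counts, reference) {
  x <- as.numeric(counts[INFORMATIVE_CODONS])
  g <- as.numeric(reference[INFORMATIVE_CODONS])
  names(x) <- names(g) <- INFORMATIVE_CODONS
  L <- sum(x)
  if (L == 0) stop("gene has no scored codons")
  msum <- 0
  cterm <- 0
  # single-codon families (Met, Trp) contribute 0 to both terms
  for (aa in .degenerate_aas) {
    fam <- .syn_families[[aa]]
    xi <- x[fam]
    n <- sum(xi)
    if (n == 0) next
    gi <- g[fam]
    if (any(gi == 0 & xi > 0)) gi <- gi + 0.5
    f <- xi / n
    gg <- gi / sum(gi)
    pos <- xi > 0
    msum <- msum + 2 * sum(xi[pos] * log(f[pos] / gg[pos]))
    cterm <- cterm + (length(fam) - 1) / L
  }
  msum / L - cterm
}

#' CAI fitness weights from a reference gene set
#'
#' `w_j = RSCU_j / max RSCU` within each family, computed on the reference
#' counts; codons unobserved in the reference are floored at 0.01. Families
#' entirely absent from the reference get `NA` weights and are excluded from
#' CAI scoring.
#'
#' @param reference Pooled codon counts of the reference (e.g. high-
#'   expression) gene set.
#' @return Named numeric vector of weights in `(0, 1]` over
#'   [INFORMATIVE_CODONS].
#' @export
cai_weights <- function(reference) {
  if (sum(as.numeric(reference[INFORMATIVE_CODONS]), na.rm = TRUE) == 0)
    stop("empty reference set")
  r <- rscu(reference)
  w <- setNames(rep(NA_real_, length(r)), names(r))
  for (aa in names(.syn_families)) {
    fam <- .syn_families[[aa]]
    ri <- r[fam]
    if (all(is.na(ri))) next
    wi <- ri / max(ri)
    wi[wi == 0] <- 0.01
    w[fam] <- wi
  }
  w
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of the reference weights over all codon occurrences of the
#' gene, excluding ATG, TGG and stops (and codons with undefined weight).
#'
#' @param counts Codon counts of the gene.
#' @param weights Weights from [cai_weights()].
#' @return CAI in `(0, 1]`, or `NA` if no codon is scorable.
#' @export
cai <- function(counts, weights) {
  x <- as.numeric(counts[INFORMATIVE_CODONS])
  w <- weights[INFORMATIVE_CODONS]
  use <- x > 0 & !is.na(w)
  if (!any(use)) return(NA_real_)
  exp(sum(x[use] * log(w[use])) / sum(x[use]))
}

#' Frequency of optimal codons (Fop) and codon bias index (CBI)
#'
#' Over the occurrences of degenerate-family codons (`N_tot`):
#' `Fop = N_opt / N_tot`; `CBI = (N_opt - N_ran) / (N_tot - N_ran)` where
#' `N_ran` is the count expected if usage were uniform within each family
#' (`sum x_i * k_i / n_i`, with `k_i` optimal codons in family i).
#'
#' @param counts Codon counts of the gene.
#' @param optimal Character vector of optimal codons (at most one per family
#'   in normal use; an empty set gives `Fop = 0`).
#' @return Named numeric vector `c(Fop =, CBI =)`; CBI is `NA` when
#'   `N_tot == N_ran`.
#' @export
fop_cbi <- function(counts, optimal) {
  x <- as.numeric(counts[INFORMATIVE_CODONS])
  names(x) <- INFORMATIVE_CODONS
  n_tot <- n_opt <- n_ran <- 0
  for (aa in .degenerate_aas) {
    fam <- .syn_families[[aa]]
    xi <- x[fam]
    n <- sum(xi)
    if (n == 0) next
    k <- sum(fam %in% optimal)
    n_tot <- n_tot + n
    n_opt <- n_opt + sum(xi[fam %in% optimal])
    n_ran <- n_ran + n * k / length(fam)
  }
  if (n_tot == 0) return(c(Fop = NA_real_, CBI = NA_real_))
  cbi <- if (abs(n_tot - n_ran) < .Machine$double.eps^0.5) NA_real_
         else (n_opt - n_ran) / (n_tot - n_ran)
  c(Fop = n_opt / n_tot, CBI = cbi)
}

#' Translate a coding sequence
#'
#' @param seq In-frame CDS string (A/C/G/T). The terminal stop codon, if
#'   present, is dropped; an internal stop is an error.
#' @return Amino-acid string (one-letter codes).
#' @export
translate_cds <- function(seq) {
  codons <- .split_codons(.norm_seq(seq))
  if (length(codons) && codons[length(codons)] %in% .STOP_CODONS)
    codons <- codons[-length(codons)]
  aa <- .genetic_code[codons]
  if (anyNA(aa)) stop("unknown codon(s): ",
                      paste(codons[is.na(aa)], collapse = ", "))
  if (any(aa == "*")) stop("internal stop codon")
  paste(aa, collapse = "")
}

#' Properties of the encoded protein
#'
#' Translates the CDS (dropping the terminal stop) and reports the protein
#' length, the Kyte-Doolittle grand average of hydropathicity (GRAVY), the
#' aromatic-residue fraction (Phe/Tyr/Trp) and the isoelectric point (pI),
#' solved by bisection of the Henderson-Hasselbalch net charge with the
#' EMBOSS pKa set to |charge| < 1e-4.
#'
#' @param seq In-frame CDS string.
#' @return Named numeric vector `c(L_aa =, GRAVY =, aromaticity =, pI =)`.
#' @export
protein_properties <- function(seq) {
  prot <- strsplit(translate_cds(seq), "")[[1]]
  if (!length(prot)) stop("empty protein")
  gravy <- mean(.kd_hydropathy[prot])
  arom <- mean(prot %in% c("F", "Y", "W"))
  c(L_aa = length(prot), GRAVY = gravy, aromaticity = arom,
    pI = .isoelectric_point(prot))
}

.net_charge <- function(prot_counts, ph) {
  pos <- 1 / (1 + 10^(ph - .pka$nterm))
  for (aa in names(.pka$positive))
    pos <- pos + prot_counts[[aa]] / (1 + 10^(ph - .pka$positive[[aa]]))
  neg <- 1 / (1 + 10^(.pka$cterm - ph))
  for (aa in names(.pka$negative))
    neg <- neg + prot_counts[[aa]] / (1 + 10^(.pka$negative[[aa]] - ph))
  pos - neg
}

.isoelectric_point <- function(prot, tol = 1e-4) {
  cnt <- as.list(table(factor(prot, levels = names(.kd_hydropathy))))
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- .net_charge(cnt, mid)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
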
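#' @importFrom stats setNames
NULL

# Fixed codon order used by every table in the package: first base slowest,
# T < C < A < G (the classical codon-table order).
.codon_bases <- c("T", "C", "A", "G")

#' The 64 codons in canonical table order
#'
#' @format Character vector of length 64 (DNA alphabet, e.g. `"TTT"`).
#' @export
CODONS <- as.vector(vapply(.codon_bases, function(b1)
  vapply(.codon_bases, function(b2)
    paste0(b1, b2, .codon_bases), character(4)),
  matrix("", 4, 4)))

# Bacterial/plastid translation table (NCBI table 11). Its codon -> amino acid
# map is identical to the standard code over all 64 codons, so it is taken
# from Biostrings and re-ordered. Stops are "*".
.genetic_code <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc[CODONS]), CODONS)
})

#' Genetic code used throughout (plastid, NCBI table 11)
#'
#' Named character vector mapping each of the 64 codons to a one-letter amino
#' acid code, `"*"` for the three stop codons.
#'
#' @export
GENETIC_CODE_PLASTID <- .genetic_code

.STOP_CODONS <- names(.genetic_code)[.genetic_code == "*"]
.START_CODON <- "ATG"

# Synonymous families, keyed by amino acid; stops excluded.
.syn_families <- local({
  aa <- .genetic_code[.genetic_code != "*"]
  split(names(aa), aa)
})

.family_size <- vapply(.syn_families, length, integer(1))

# The 59 informative codons: 64 minus ATG, TGG and the three stops.
#' The 59 synonymous (informative) codons
#'
#' All codons except ATG (Met), TGG (Trp) and the three stop codons; the
#' domain of RSCU, RFSC, correspondence analysis and RSCU clustering.
#'
#' @export
INFORMATIVE_CODONS <- setdiff(CODONS, c("ATG", "TGG", .STOP_CODONS))

# Degenerate families only (size >= 2), used by SCUO, Fop/CBI, GC3s.
.degenerate_aas <- names(.family_size)[.family_size >= 2]

# codon -> amino acid for informative codons, and codon -> family size
.codon_aa <- .genetic_code[INFORMATIVE_CODONS]
.codon_ni <- .family_size[.codon_aa]
names(.codon_ni) <- INFORMATIVE_CODONS

# Kyte-Doolittle hydropathy scale.
.kd_hydropathy <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# EMBOSS pKa set for isoelectric-point bisection.
.pka <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

# --- tiny shared helpers -----------------------------------------------------

.norm_seq <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Coerce the various accepted inputs to a named character vector of sequences.
.as_seqs <- function(x) {
  if (inherits(x, "cds_set")) return(x$seq)
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop("expected a character vector of sequences or a 'cds_set'")
}
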
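#' Codon frequency per thousand codons
#'
#' @param counts Codon counts with positive total.
#' @return Named numeric vector over all 64 codons summing to 1000.
#' @export
per_thousand_frequency <- function(counts) {
  x <- as.numeric(counts[CODONS])
  names(x) <- CODONS
  tot <- sum(x)
  if (tot <= 0) stop("zero total codon count")
  1000 * x / tot
}

#' Read a host codon-frequency table
#'
#' Expects tab-separated text with comment lines starting with `#` and
#' columns `codon` and `freq_per_thousand` over all 64 codons (DNA or RNA
#' alphabet). The packaged tables under `inst/extdata/` are synthetic
#' stand-ins for the public codon-usage tables of the four common
#' heterologous hosts (see [host_frequency()]).
#'
#' @param path Path to the table.
#' @return Named numeric vector over the 64 codons, rescaled to sum to 1000.
#' @export
read_host_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("codon", "freq_per_thousand") %in% names(df)))
  codon <- .norm_seq(df$codon)
  if (!setequal(codon, CODONS))
    stop("host table must cover exactly the 64 codons: ", path)
  v <- setNames(df$freq_per_thousand[match(CODONS, codon)], CODONS)
  1000 * v / sum(v)
}

#' Packaged heterologous-host codon-frequency tables
#'
#' Per-thousand codon frequencies for the four standard expression hosts.
#' These are synthetic stand-in tables (shaped by well-known qualitative
#' preferences such as the E. coli CTG bias and the AT-richness of the plant
#' tables), not snapshots of the public codon-usage database; replace them
#' via [read_host_table()] for real comparisons.
#'
#' @param host One of `"e_coli"`, `"s_cerevisiae"`, `"n_tabacum"`,
#'   `"a_thaliana"`.
#' @return Named numeric vector over the 64 codons summing to 1000.
#' @export
host_frequency <- function(host = c("e_coli", "s_cerevisiae", "n_tabacum",
                                    "a_thaliana")) {
  host <- match.arg(host)
  path <- system.file("extdata", paste0("host_", host, "_synthetic.tsv"),
                      package = "cubtools", mustWork = TRUE)
  read_host_table(path)
}

#' Codon-frequency divergence from a heterologous host
#'
#' Per codon, the ratio of the species frequency to the host frequency. A
#' ratio strictly between 0.5 and 2 marks negligible disparity; ratios at or
#' beyond either boundary mark the codon as divergent. A host frequency of 0
#' with positive species usage gives an undefined ratio counted as
#' divergent; codons absent from both are excluded.
#'
#' @param species_freq,host_freq Per-thousand frequency vectors over the 64
#'   codons ([per_thousand_frequency()] / [host_frequency()]).
#' @param host Host label for reporting.
#' @return List of class `"host_comparison"`: `host`, `table` (codon,
#'   species_freq, host_freq, ratio, divergent), `n_divergent`,
#'   `pct_of_64`.
#' @export
host_divergence <- function(species_freq, host_freq, host = "host") {
  s <- as.numeric(species_freq[CODONS])
  h <- as.numeric(host_freq[CODONS])
  ratio <- ifelse(h > 0, s / h, ifelse(s > 0, NA_real_, NaN))
  excluded <- s == 0 & h == 0
  divergent <- !excluded & (is.na(ratio) | ratio <= 0.5 | ratio >= 2)
  tab <- data.frame(codon = CODONS, species_freq = s, host_freq = h,
                    ratio = ratio, divergent = divergent,
                    stringsAsFactors = FALSE)[!excluded, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(host = host, table = tab,
                 n_divergent = sum(divergent),
                 pct_of_64 = 100 * sum(divergent) / 64),
            class = "host_comparison")
}

#' @export
print.host_comparison <- function(x, ...) {
  cat(sprintf("Host comparison vs %s: %d/64 divergent codons (%.2f%%)\n",
              x$host, x$n_divergent, x$pct_of_64))
  invisible(x)
}

#' RSCU-based hierarchical clustering of species
#'
#' Squared Euclidean distances between species over the 59 informative-codon
#' RSCU values, agglomerated by between-groups average linkage (UPGMA).
#' Species rows are sorted lexicographically before clustering so the result
#' is invariant to input order; undefined RSCU entries are imputed as 0 with
#' a message.
#'
#' @param mat Numeric matrix, one row per species (rownames = unique species
#'   labels), columns = codons.
#' @return List of class `"rscu_cluster"`: `hclust`, `phylo` (an
#'   [ape::as.phylo()] tree), `newick` (serialized tree text), `labels`.
#' @export
rscu_cluster <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 species")
  if (is.null(rownames(mat))) stop("species labels required as rownames")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate species labels: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  if (anyNA(mat)) {
    message("imputing ", sum(is.na(mat)), " undefined RSCU entr(ies) as 0")
    mat[is.na(mat)] <- 0
  }
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  d <- stats::dist(mat, method = "euclidean")^2
  hc <- stats::hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = phy,
                 newick = ape::write.tree(phy),
                 labels = rownames(mat)),
            class = "rscu_cluster")
}

#' @export
print.rscu_cluster <- function(x, ...) {
  cat("RSCU cluster tree over", length(x$labels), "species\n")
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' @export
plot.rscu_cluster <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "",
       main = "RSCU squared-Euclidean average-linkage clustering", ...)
  invisible(x)
}
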
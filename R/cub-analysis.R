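#' Full codon-usage-bias analysis of one species
#'
#' The package's central fitting function: takes a species' coding
#' sequences, optionally applies the CDS quality filter, and computes every
#' per-gene and pooled statistic — composition and skews, RSCU/RFSC, ENC and
#' its mutation-only expectation, SCUO, MILC (reference = the species'
#' pooled usage), CAI (reference = the lowest-ENC decile), Fop/CBI (optimal
#' codons from the ENC-decile contrast), protein properties, high-frequency
#' and optimal codon classifications, the neutrality regression, ENC-plot,
#' PR2-plot, correspondence analysis of the gene-by-codon RSCU matrix, and
#' the standard correlation suite.
#'
#' @param x A [cds_set()] or a named character vector of candidate CDSs.
#' @param species Species label (defaults to the set's label).
#' @param filter Apply [filter_cds()] first (default TRUE).
#' @param min_len,dedupe Passed to [filter_cds()].
#' @param fraction ENC-decile fraction for the expression datasets.
#' @param cor_method `"spearman"` (default) or `"pearson"`.
#' @return Object of class `"cub"`; see Details. Key elements: `genes` (the
#'   master per-gene index table), `rscu_pooled`, `rfsc_pooled`, `hf`,
#'   `optimal`, `neutrality`, `encplot`, `pr2`, `coa`, `correlations`,
#'   `pooled_counts`, `set`, `filter_report`.
#' @examples
#' sim <- simulate_cds_set(20, c(150, 300), seed = 42, species = "demo")
#' fit <- cub_analysis(sim$set)
#' fit
#' head(summary(fit)$index_means)
#' @export
cub_analysis <- function(x, species = NULL, filter = TRUE, min_len = 300L,
                         dedupe = TRUE, fraction = 0.10,
                         cor_method = c("spearman", "pearson")) {
  cor_method <- match.arg(cor_method)
  if (inherits(x, "cds_set")) {
    if (is.null(species)) species <- x$species
    cand <- structure(x$seq, gene = names(x$seq))
  } else {
    if (is.null(species)) species <- "unknown"
    cand <- x
  }
  if (filter) {
    fl <- filter_cds(cand, min_len = min_len, species = species,
                     dedupe = dedupe)
    set <- fl$set
    report <- fl$report
  } else {
    set <- cds_set(.norm_seq(unclass(c(cand))), species)
    report <- NULL
  }
  if (length(set) < 2L)
    stop("[", species, "] fewer than 2 CDSs survive filtering")

  ids <- names(set$seq)
  counts <- lapply(set$seq, function(s) codon_counts(s))
  pooled <- codon_counts(set)

  comp <- t(vapply(set$seq, composition_profile, numeric(14)))
  skews <- t(vapply(set$seq, nucleotide_skews, numeric(6)))
  enc_v <- setNames(vapply(counts, enc, numeric(1)), ids)
  scuo_v <- vapply(counts, scuo, numeric(1))
  milc_v <- vapply(counts, milc, numeric(1), reference = pooled)
  prot <- t(vapply(set$seq, protein_properties, numeric(4)))

  # expression deciles -> CAI reference and optimal codons
  expr <- tryCatch(expression_datasets_by_enc(set, enc_v, fraction),
                   error = function(e) {
                     warning("[", species, "] ", conditionMessage(e),
                             "; CAI and optimal codons undefined")
                     NULL
                   })
  if (!is.null(expr)) {
    high_counts <- codon_counts(expr$high_expr)
    low_counts <- codon_counts(expr$low_expr)
    w <- cai_weights(high_counts)
    cai_v <- vapply(counts, cai, numeric(1), weights = w)
    opt <- optimal_codons(high_counts, low_counts)
  } else {
    w <- NULL
    cai_v <- rep(NA_real_, length(ids))
    opt <- optimal_codons(pooled, pooled)[0, ]
  }
  fc <- t(vapply(counts, fop_cbi, numeric(2), optimal = opt$codon))

  genes <- data.frame(gene_id = ids, species = species,
                      length_nt = unname(nchar(set$seq)),
                      comp, skews, prot,
                      ENC = unname(enc_v),
                      ENC_expected = expected_enc(comp[, "GC3s"]),
                      SCUO = unname(scuo_v), MILC = unname(milc_v),
                      CAI = unname(cai_v), Fop = unname(fc[, "Fop"]),
                      CBI = unname(fc[, "CBI"]),
                      stringsAsFactors = FALSE, row.names = NULL)
  genes$ENC_ratio <- (genes$ENC_expected - genes$ENC) / genes$ENC_expected

  rscu_mat <- t(vapply(counts, rscu, numeric(length(INFORMATIVE_CODONS))))
  rownames(rscu_mat) <- ids

  hf <- high_frequency_codons(rfsc(pooled))
  neut <- neutrality_regression(genes$GC12, genes$GC3)
  ep <- enc_plot(genes$GC3s, setNames(genes$ENC, ids))
  pr2 <- pr2_plot(set)
  coa <- correspondence_analysis(rscu_mat)
  ax <- coa$row_coords
  genes$Axis1 <- if (coa$n_axes >= 1) ax[match(ids, rownames(ax)), 1] else NA_real_
  genes$Axis2 <- if (coa$n_axes >= 2) ax[match(ids, rownames(ax)), 2] else NA_real_

  pairs <- rbind(
    cbind("Axis1", c("GC3s", "ENC", "L_aa", "CAI", "CBI", "Fop", "GC3", "GC")),
    cbind("SCUO", c("at_skew", "gc_skew", "purine_skew", "pyrimidine_skew",
                    "keto_skew", "amino_skew")),
    cbind("SCUO", c("GRAVY", "L_aa", "aromaticity", "pI", "MILC"))
  )
  corr <- correlation_suite(genes, pairs, method = cor_method)
  corr$species <- species

  structure(list(species = species, set = set, filter_report = report,
                 genes = genes, pooled_counts = pooled,
                 rscu_pooled = rscu(pooled), rfsc_pooled = rfsc(pooled),
                 rscu_matrix = rscu_mat, cai_weights = w,
                 expression = expr, hf = hf, optimal = opt,
                 neutrality = neut, encplot = ep, pr2 = pr2, coa = coa,
                 correlations = corr,
                 params = list(min_len = min_len, dedupe = dedupe,
                               fraction = fraction, cor_method = cor_method)),
            class = "cub")
}

#' @export
print.cub <- function(x, ...) {
  g <- x$genes
  cat("Codon usage analysis:", x$species, "\n")
  cat(sprintf("  %d genes (%s-%s nt), GC %.3f, GC3 %.3f\n", nrow(g),
              min(g$length_nt), max(g$length_nt), mean(g$GC), mean(g$GC3)))
  cat(sprintf("  mean ENC %.2f, SCUO %.3f, MILC %.3f\n",
              mean(g$ENC, na.rm = TRUE), mean(g$SCUO, na.rm = TRUE),
              mean(g$MILC, na.rm = TRUE)))
  cat(sprintf("  %d high-frequency codons, %d optimal codons\n",
              nrow(x$hf), nrow(x$optimal)))
  cat(sprintf("  neutrality slope %.3f (r %.3f); ENC-plot band fraction %.2f\n",
              x$neutrality$slope, x$neutrality$r, x$encplot$frac_in_band))
  if (x$coa$n_axes >= 1)
    cat(sprintf("  COA axis 1: %.2f%% of inertia\n", x$coa$inertia_pct[1]))
  invisible(x)
}

#' @export
summary.cub <- function(object, ...) {
  g <- object$genes
  idx <- c("GC", "GC1", "GC2", "GC3", "GC3s", "ENC", "ENC_ratio", "SCUO",
           "MILC", "CAI", "Fop", "CBI", "GRAVY", "aromaticity", "pI", "L_aa")
  out <- list(
    species = object$species,
    n_genes = nrow(g),
    index_means = vapply(g[idx], mean, numeric(1), na.rm = TRUE),
    hf_codons = object$hf$codon,
    optimal_codons = object$optimal$codon,
    neutrality = object$neutrality,
    frac_in_band = object$encplot$frac_in_band,
    coa_inertia_pct = utils::head(object$coa$inertia_pct, 4),
    correlations = object$correlations
  )
  class(out) <- "summary.cub"
  out
}

#' @export
print.summary.cub <- function(x, ...) {
  cat("Codon usage analysis summary:", x$species, "(", x$n_genes, "genes )\n")
  cat("\nIndex means:\n")
  print(round(x$index_means, 4))
  cat("\nHigh-frequency codons:", paste(x$hf_codons, collapse = " "), "\n")
  cat("Optimal codons:", if (length(x$optimal_codons))
    paste(x$optimal_codons, collapse = " ") else "(none)", "\n\n")
  print(x$neutrality)
  cat(sprintf("ENC-plot: %.1f%% of genes within enc_ratio [-0.05, 0.10]\n",
              100 * x$frac_in_band))
  cat("COA inertia % (first axes):",
      paste(sprintf("%.2f", x$coa_inertia_pct), collapse = ", "), "\n")
  invisible(x)
}

#' Diagnostic plots for a codon-usage analysis
#'
#' @param x A `"cub"` object.
#' @param type `"enc"` (ENC vs GC3s with Wright's curve), `"neutrality"`
#'   (GC12 vs GC3 with the fitted line), `"pr2"` (PR2-plot) or `"coa"`
#'   (gene and codon scores on the first two axes).
#' @param ... Passed to the underlying plot calls.
#' @export
plot.cub <- function(x, type = c("enc", "neutrality", "pr2", "coa"), ...) {
  type <- match.arg(type)
  g <- x$genes
  if (type == "enc") {
    plot(g$GC3s, g$ENC, xlim = c(0, 1), ylim = c(0, 62), pch = 19,
         col = "grey30", xlab = "GC3s", ylab = "ENC",
         main = paste("ENC-plot:", x$species), ...)
    s <- seq(0.01, 0.99, by = 0.01)
    graphics::lines(s, expected_enc(s), col = "red", lwd = 2)
  } else if (type == "neutrality") {
    plot(g$GC3, g$GC12, pch = 19, col = "grey30", xlab = "GC3",
         ylab = "GC12", main = paste("Neutrality plot:", x$species), ...)
    if (!is.na(x$neutrality$slope))
      graphics::abline(x$neutrality$intercept, x$neutrality$slope,
                       col = "red", lwd = 2)
  } else if (type == "pr2") {
    d <- x$pr2$data
    plot(d$x, d$y, xlim = c(0, 1), ylim = c(0, 1), pch = 19, col = "grey30",
         xlab = "G3/(G3+C3)", ylab = "A3/(A3+T3)",
         main = paste("PR2-plot:", x$species), ...)
    graphics::abline(h = 0.5, v = 0.5, lty = 2)
  } else {
    stopifnot(x$coa$n_axes >= 2)
    rc <- x$coa$row_coords; cc <- x$coa$col_coords
    plot(rc[, 1], rc[, 2], pch = 19, col = "grey30",
         xlab = sprintf("Axis 1 (%.1f%%)", x$coa$inertia_pct[1]),
         ylab = sprintf("Axis 2 (%.1f%%)", x$coa$inertia_pct[2]),
         main = paste("COA of RSCU:", x$species), ...)
    graphics::text(cc[, 1], cc[, 2], rownames(cc), cex = 0.5, col = "red")
  }
  invisible(x)
}

#' Cross-species comparison of codon-usage analyses
#'
#' Intersects the per-species high-frequency codon sets, clusters the
#' species by their pooled RSCU profiles (squared Euclidean distance,
#' between-groups average linkage), and compares each species'
#' per-thousand codon frequencies against heterologous-host tables.
#'
#' @param analyses List of `"cub"` objects (unique species labels).
#' @param hosts Named list of host frequency vectors over the 64 codons, or
#'   `NULL` (default) for the four packaged synthetic host tables.
#' @return Object of class `"cub_comparison"`: `shared_hf`, `cluster` (an
#'   [rscu_cluster()] result, `NULL` for a single species),
#'   `host_comparisons` (species x host list), `divergence_summary`
#'   (data.frame: species, host, n_divergent, pct_of_64), `rscu_species`
#'   (species x 59 pooled RSCU matrix).
#' @export
cub_compare <- function(analyses, hosts = NULL) {
  stopifnot(length(analyses) >= 1L,
            all(vapply(analyses, inherits, logical(1), "cub")))
  sp <- vapply(analyses, `[[`, character(1), "species")
  if (anyDuplicated(sp)) stop("duplicate species labels")
  names(analyses) <- sp
  if (is.null(hosts))
    hosts <- sapply(c("e_coli", "s_cerevisiae", "n_tabacum", "a_thaliana"),
                    host_frequency, simplify = FALSE)

  rscu_sp <- t(vapply(analyses, `[[`, numeric(length(INFORMATIVE_CODONS)),
                      "rscu_pooled"))
  rownames(rscu_sp) <- sp
  tree <- if (length(sp) >= 2L) rscu_cluster(rscu_sp) else NULL

  hostcmp <- lapply(analyses, function(a) {
    freq <- per_thousand_frequency(a$pooled_counts)
    lapply(names(hosts), function(h)
      host_divergence(freq, hosts[[h]], host = h))
  })
  hostcmp <- lapply(hostcmp, function(l) setNames(l, names(hosts)))
  summ <- do.call(rbind, lapply(sp, function(s)
    do.call(rbind, lapply(names(hosts), function(h) {
      hc <- hostcmp[[s]][[h]]
      data.frame(species = s, host = h, n_divergent = hc$n_divergent,
                 pct_of_64 = hc$pct_of_64, stringsAsFactors = FALSE)
    }))))
  structure(list(shared_hf = shared_hf(lapply(analyses, `[[`, "hf")),
                 cluster = tree, host_comparisons = hostcmp,
                 divergence_summary = summ, rscu_species = rscu_sp,
                 species = sp),
            class = "cub_comparison")
}

#' @export
print.cub_comparison <- function(x, ...) {
  cat("Codon usage comparison over", length(x$species), "species\n")
  cat("  shared HF codons (", length(x$shared_hf), "):",
      paste(x$shared_hf, collapse = " "), "\n")
  if (!is.null(x$cluster)) cat("  cluster:", x$cluster$newick, "\n")
  cat("  host divergence (codons of 64):\n")
  print(stats::reshape(x$divergence_summary[c("species", "host", "n_divergent")],
                       direction = "wide", idvar = "species",
                       timevar = "host"), row.names = FALSE)
  invisible(x)
}
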
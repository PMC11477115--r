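#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least squares of the mean GC content at codon positions 1-2 on
#' the GC content at position 3. A slope near 1 with a strong correlation
#' indicates mutation pressure as the dominant force; a slope near 0,
#' selection.
#'
#' @param gc12,gc3 Numeric vectors of per-gene values (pairwise-complete
#'   cases are used; at least 3 required).
#' @return List of class `"cub_regression"`: `slope`, `intercept`, `r`
#'   (Pearson), `p` (two-sided t-test on r), `n`. A zero-variance `gc3`
#'   yields `NA` slope with a warning.
#' @export
neutrality_regression <- function(gc12, gc3) {
  ok <- !is.na(gc12) & !is.na(gc3)
  gc12 <- gc12[ok]; gc3 <- gc3[ok]
  n <- length(gc3)
  if (n < 3L) stop("need at least 3 genes, have ", n)
  if (stats::var(gc3) == 0) {
    warning("GC3 has zero variance; slope undefined")
    return(structure(list(slope = NA_real_, intercept = mean(gc12),
                          r = NA_real_, p = NA_real_, n = n),
                     class = "cub_regression"))
  }
  fit <- stats::lm(gc12 ~ gc3)
  if (stats::var(gc12) == 0) {
    r <- p <- NA_real_
  } else {
    ct <- stats::cor.test(gc3, gc12, method = "pearson")
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = r, p = p, n = n),
            class = "cub_regression")
}

#' @export
print.cub_regression <- function(x, ...) {
  cat(sprintf("GC12 ~ GC3: slope %.4f, intercept %.4f, r %.3f (p %.3g, n %d)\n",
              x$slope, x$intercept, x$r, x$p, x$n))
  invisible(x)
}

#' ENC-plot statistics
#'
#' For each gene, the expected ENC on Wright's mutation-only curve at its
#' GC3s, the signed relative deviation `enc_ratio = (exp - obs)/exp`
#' (positive below the curve, i.e. more bias than mutation alone explains),
#' a 0.05-wide histogram of the ratios aligned to multiples of 0.05
#' (left-closed, right-open), and the fraction of genes with ratio in
#' `[-0.05, 0.10]`.
#'
#' @param gc3s,enc_obs Numeric per-gene vectors (equal length; entries with
#'   either value missing are dropped).
#' @param gene_id Optional gene identifiers.
#' @return List of class `"enc_plot"`: `data` (gene_id, gc3s, enc_obs,
#'   enc_exp, enc_ratio), `histogram` (bin_left, bin_right, count),
#'   `frac_in_band`.
#' @export
enc_plot <- function(gc3s, enc_obs, gene_id = NULL) {
  if (is.null(gene_id)) gene_id <- if (!is.null(names(enc_obs)))
    names(enc_obs) else paste0("gene", seq_along(enc_obs))
  ok <- !is.na(gc3s) & !is.na(enc_obs)
  d <- data.frame(gene_id = gene_id[ok], gc3s = gc3s[ok],
                  enc_obs = enc_obs[ok], stringsAsFactors = FALSE)
  d$enc_exp <- expected_enc(d$gc3s)
  d$enc_ratio <- (d$enc_exp - d$enc_obs) / d$enc_exp
  lo <- min(-0.25, floor(min(d$enc_ratio) / 0.05) * 0.05)
  hi <- max(0.30, ceiling(max(d$enc_ratio) / 0.05) * 0.05)
  edges <- seq(lo, hi, by = 0.05)
  bin <- findInterval(d$enc_ratio, edges, rightmost.closed = FALSE)
  histo <- data.frame(bin_left = edges[-length(edges)],
                      bin_right = edges[-1],
                      count = tabulate(bin, nbins = length(edges) - 1L))
  structure(list(data = d, histogram = histo,
                 frac_in_band = mean(d$enc_ratio >= -0.05 &
                                       d$enc_ratio <= 0.10)),
            class = "enc_plot")
}

#' @export
print.enc_plot <- function(x, ...) {
  cat(sprintf("ENC-plot: %d genes, enc_ratio in [%.3f, %.3f], %.1f%% in band [-0.05, 0.10]\n",
              nrow(x$data), min(x$data$enc_ratio), max(x$data$enc_ratio),
              100 * x$frac_in_band))
  invisible(x)
}

#' PR2-plot coordinates and quadrant summary
#'
#' Per gene, `x = G3/(G3 + C3)` and `y = A3/(A3 + T3)` from third-position
#' base counts. Under mutation pressure alone both coordinates sit at 0.5
#' (A = T and G = C at the third position); deviations indicate selection.
#'
#' @param x A [cds_set()], a named character vector of sequences, or a
#'   matrix/data.frame with columns `A3`, `T3`, `G3`, `C3` of third-position
#'   counts (one row per gene).
#' @return List of class `"pr2_plot"`: `data` (gene_id, x, y; genes with a
#'   zero denominator are dropped with a warning) and `quadrants` (counts
#'   relative to (0.5, 0.5); points on a boundary are counted toward the
#'   lower/left quadrant).
#' @export
pr2_plot <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) {
    m <- as.data.frame(x)
    stopifnot(all(c("A3", "T3", "G3", "C3") %in% names(m)))
    ids <- if (!is.null(rownames(x))) rownames(x) else paste0("gene", seq_len(nrow(m)))
  } else {
    seqs <- .as_seqs(x)
    ids <- names(seqs)
    m <- do.call(rbind, lapply(seqs, function(s) {
      third <- substr(.split_codons(s), 3L, 3L)
      data.frame(A3 = sum(third == "A"), T3 = sum(third == "T"),
                 G3 = sum(third == "G"), C3 = sum(third == "C"))
    }))
  }
  den_x <- m$G3 + m$C3
  den_y <- m$A3 + m$T3
  drop <- den_x == 0 | den_y == 0
  if (any(drop))
    warning(sum(drop), " gene(s) dropped from PR2-plot (zero denominator)")
  d <- data.frame(gene_id = ids[!drop],
                  x = (m$G3 / den_x)[!drop],
                  y = (m$A3 / den_y)[!drop],
                  stringsAsFactors = FALSE)
  quad <- table(factor(ifelse(d$x > 0.5, "right", "left"),
                       levels = c("left", "right")),
                factor(ifelse(d$y > 0.5, "top", "bottom"),
                       levels = c("bottom", "top")))
  structure(list(data = d, quadrants = quad), class = "pr2_plot")
}

#' @export
print.pr2_plot <- function(x, ...) {
  cat("PR2-plot:", nrow(x$data), "genes; quadrant counts (x vs 0.5, y vs 0.5):\n")
  print(x$quadrants)
  invisible(x)
}

#' Correspondence analysis of a gene-by-codon RSCU matrix
#'
#' Standard CA: with `P` the matrix scaled to sum 1 and `r`, `c` its margins,
#' the standardized residuals `S = Dr^-1/2 (P - r c') Dc^-1/2` are decomposed
#' by SVD; row (gene) and column (codon) principal coordinates are the
#' singular vectors rescaled by the margins and singular values, and the
#' per-axis inertia percentages come from the squared singular values.
#' Undefined entries are treated as 0; all-zero columns (and rows) are
#' dropped with a message.
#'
#' @param mat Non-negative matrix, genes in rows (typically gene x 59 RSCU).
#' @return List of class `"cub_ca"`: `row_coords`, `col_coords`,
#'   `inertia` (squared singular values), `inertia_pct`, `n_axes`,
#'   `total_inertia`.
#' @export
correspondence_analysis <- function(mat) {
  mat <- as.matrix(mat)
  mat[is.na(mat)] <- 0
  if (any(mat < 0)) stop("matrix must be non-negative")
  if (nrow(mat) < 2L) stop("need at least 2 rows")
  keep_col <- colSums(mat) > 0
  keep_row <- rowSums(mat) > 0
  if (!all(keep_col))
    message("dropping ", sum(!keep_col), " all-zero column(s)")
  if (!all(keep_row))
    message("dropping ", sum(!keep_row), " all-zero row(s)")
  mat <- mat[keep_row, keep_col, drop = FALSE]

  P <- mat / sum(mat)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  nontrivial <- sv$d > 1e-12
  n_axes <- sum(nontrivial)
  if (n_axes == 0L) {
    return(structure(list(
      row_coords = matrix(0, nrow(mat), 0, dimnames = list(rownames(mat), NULL)),
      col_coords = matrix(0, ncol(mat), 0, dimnames = list(colnames(mat), NULL)),
      inertia = numeric(0), inertia_pct = numeric(0),
      n_axes = 0L, total_inertia = 0), class = "cub_ca"))
  }
  d <- sv$d[nontrivial]
  row_coords <- diag(1 / sqrt(r)) %*% sv$u[, nontrivial, drop = FALSE] %*% diag(d, n_axes)
  col_coords <- diag(1 / sqrt(cc)) %*% sv$v[, nontrivial, drop = FALSE] %*% diag(d, n_axes)
  dimnames(row_coords) <- list(rownames(mat), paste0("Axis", seq_len(n_axes)))
  dimnames(col_coords) <- list(colnames(mat), paste0("Axis", seq_len(n_axes)))
  structure(list(row_coords = row_coords, col_coords = col_coords,
                 inertia = d^2, inertia_pct = 100 * d^2 / sum(d^2),
                 n_axes = n_axes, total_inertia = sum(d^2)),
            class = "cub_ca")
}

#' @export
print.cub_ca <- function(x, ...) {
  cat("Correspondence analysis:", nrow(x$row_coords), "rows x",
      nrow(x$col_coords), "columns,", x$n_axes, "axes\n")
  if (x$n_axes)
    cat("  inertia %:", paste(sprintf("%.2f", utils::head(x$inertia_pct, 4)),
                              collapse = ", "),
        if (x$n_axes > 4) "..." else "", "\n")
  invisible(x)
}

#' Correlation suite over an index table
#'
#' Computes rank (Spearman, the default) or Pearson correlations for a
#' declared list of variable pairs, excluding missing values pairwise.
#'
#' @param index_table data.frame of per-gene statistics.
#' @param pairs Two-column character matrix/data.frame (or list of length-2
#'   vectors) naming the variable pairs.
#' @param method `"spearman"` or `"pearson"`.
#' @return data.frame with columns `x`, `y`, `rho`, `p`, `n`; a constant
#'   variable yields `NA` rho with a warning.
#' @export
correlation_suite <- function(index_table, pairs,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  out <- data.frame(x = character(0), y = character(0), rho = numeric(0),
                    p = numeric(0), n = integer(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    vx <- index_table[[pairs[i, 1]]]
    vy <- index_table[[pairs[i, 2]]]
    if (is.null(vx) || is.null(vy))
      stop("unknown variable in pair: ", paste(pairs[i, ], collapse = ", "))
    ok <- !is.na(vx) & !is.na(vy)
    n <- sum(ok)
    if (n < 4L) {
      warning("fewer than 4 complete pairs for ", pairs[i, 1], " vs ",
              pairs[i, 2])
      rho <- p <- NA_real_
    } else if (stats::var(vx[ok]) == 0 || stats::var(vy[ok]) == 0) {
      warning("constant variable in pair ", pairs[i, 1], " vs ", pairs[i, 2])
      rho <- p <- NA_real_
    } else {
      ct <- suppressWarnings(stats::cor.test(vx[ok], vy[ok], method = method,
                                             exact = FALSE))
      rho <- unname(ct$estimate)
      p <- ct$p.value
    }
    out[nrow(out) + 1L, ] <- list(pairs[i, 1], pairs[i, 2], rho, p, n)
  }
  out
}
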
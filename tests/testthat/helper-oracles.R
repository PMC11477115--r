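# Independent oracles and small fixture builders used across the suite.

# All 64 codons / informative codons in the package's fixed order.
codons64 <- cubtools::CODONS
inf59 <- cubtools::INFORMATIVE_CODONS

# codon -> amino acid and synonymous families, rebuilt here independently
# from Biostrings so the oracles do not lean on package internals.
oracle_code <- Biostrings::GENETIC_CODE[codons64]
oracle_fams <- split(names(oracle_code)[oracle_code != "*"],
                     oracle_code[oracle_code != "*"])

# named 64-long count vector from a partial specification
count_table <- function(...) {
  spec <- c(...)
  out <- stats::setNames(rep(0, 64), codons64)
  out[names(spec)] <- spec
  out
}

# brute-force Wright ENC straight from the formula (loop, no shared code path)
brute_enc <- function(counts) {
  fs <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (aa in names(oracle_fams)) {
    fam <- oracle_fams[[aa]]
    if (length(fam) < 2) next
    n <- sum(counts[fam])
    if (n < 2) next
    p <- counts[fam] / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    k <- as.character(length(fam))
    fs[[k]] <- c(fs[[k]], f)
  }
  fbar <- vapply(fs, function(v) if (length(v)) mean(v) else NA_real_,
                 numeric(1))
  if (is.na(fbar["3"]) && !is.na(fbar["2"]) && !is.na(fbar["4"]))
    fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
  if (anyNA(fbar[c("2", "4", "6")]) || any(fbar <= 0, na.rm = TRUE))
    return(NA_real_)
  min(61, 2 + 9 / fbar["2"] + 1 / fbar["3"] + 5 / fbar["4"] + 3 / fbar["6"])
}

# chi-square-residual cross-product eigen oracle for CA inertias
brute_ca_inertia <- function(mat) {
  mat <- mat[rowSums(mat) > 0, colSums(mat) > 0, drop = FALSE]
  P <- mat / sum(mat)
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  ev <- eigen(S %*% t(S), symmetric = TRUE)$values
  sort(ev[ev > 1e-12], decreasing = TRUE)
}

# brute-force between-groups average-linkage agglomeration on a point matrix
# using squared Euclidean distances; returns merge heights and the member
# sets created at each step (sorted label strings for comparability)
brute_average_linkage <- function(mat) {
  labs <- rownames(mat)
  d <- as.matrix(stats::dist(mat))^2
  clusters <- as.list(labs)
  heights <- numeric(0)
  merged <- character(0)
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      key <- paste(sort(c(paste(sort(clusters[[i]]), collapse = ","),
                          paste(sort(clusters[[j]]), collapse = ","))),
                   collapse = "|")
      if (dij < best_d - 1e-12 ||
          (abs(dij - best_d) <= 1e-12 && !is.null(best) && key < best$key)) {
        best_d <- dij
        best <- list(i = i, j = j, key = key)
      }
    }
    newc <- c(clusters[[best$i]], clusters[[best$j]])
    clusters <- c(clusters[-c(best$i, best$j)], list(newc))
    heights <- c(heights, best_d)
    merged <- c(merged, paste(sort(newc), collapse = ","))
  }
  list(heights = heights, merged = merged)
}

# hclust merge steps in the same representation as the brute-force oracle
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  out <- character(nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[k, ], function(m)
      if (m < 0) hc$labels[-m] else sets[[m]]))
    sets[[k]] <- members
    out[k] <- paste(sort(members), collapse = ",")
  }
  out
}

# write a tiny FASTA file, return its path
tmp_fasta <- function(headers, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}
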
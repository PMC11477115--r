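#' Default planted preferred-codon set
#'
#' One codon per degenerate family: the C-ending codon where the family has
#' one, otherwise the G-ending codon. Used as the planted selection target
#' when a simulation regime requires a preferred set and none is given.
#'
#' @return Character vector of 18 codons (one per degenerate family).
#' @export
default_preferred_codons <- function() {
  vapply(.degenerate_aas, function(aa) {
    fam <- .syn_families[[aa]]
    third <- substr(fam, 3L, 3L)
    if (any(third == "C")) fam[third == "C"][1] else fam[third == "G"][1]
  }, character(1), USE.NAMES = FALSE)
}

# Per-family codon sampling probabilities for mutation target t and
# selection strength s toward `preferred`. The third-position pull is split
# so that P(G/C-ending) = t exactly in every family (incl. the asymmetric
# Ile family); single-codon families are emitted as-is elsewhere.
.family_probs <- function(fam, t, s, preferred) {
  gc_end <- substr(fam, 3L, 3L) %in% c("G", "C")
  w <- ifelse(gc_end, t / sum(gc_end), (1 - t) / sum(!gc_end))
  w <- w * exp(s * (fam %in% preferred))
  w / sum(w)
}

#' Simulate a CDS set with known codon-usage structure
#'
#' Each gene is built codon by codon: a length is drawn, amino acids are
#' sampled from `aa_profile` (the first codon is always Met, a uniformly
#' drawn stop is appended), and each synonymous codon is drawn from its
#' family with probability proportional to `m(c) * exp(s * [c in
#' preferred_set])`, where the mutational weight `m` makes the G/C-ending
#' probability of every family equal to the gene's GC3 target. Generated
#' genes pass [filter_cds()] by construction, and per-gene random substreams
#' make the output prefix-stable: extending `n_genes` never changes earlier
#' genes.
#'
#' @param n_genes Number of genes.
#' @param length_codons Length range in codons (including start and stop),
#'   default `c(100, 1500)` (300-4500 nt, chloroplast-CDS scale); a single
#'   value fixes the length.
#' @param aa_profile Named amino-acid frequency vector (default uniform over
#'   the 20); need not be normalized.
#' @param gc3_target Per-gene synonymous-GC3 target: a single value, a range
#'   `c(lo, hi)` sampled per gene, or a length-`n_genes` vector.
#' @param s Selection strength (>= 0); single value or length-`n_genes`.
#' @param preferred_set Planted preferred codons, at most one per family;
#'   defaults to [default_preferred_codons()] when a selection regime needs
#'   one.
#' @param regime `"mutation_only"` (forces s = 0), `"selection"` (forces
#'   gc3_target = 0.5) or `"mixed"`.
#' @param seed Integer root seed.
#' @param species Species label of the emitted set.
#' @return List with `set` (a [cds_set()]) and `truth` (data.frame:
#'   `gene_id`, `length_codons`, `gc3_target`, `realized_gc3s`, `s`,
#'   `regime`) plus attribute `preferred_set`.
#' @export
simulate_cds_set <- function(n_genes, length_codons = c(100L, 1500L),
                             aa_profile = NULL, gc3_target = 0.37, s = 0,
                             preferred_set = NULL,
                             regime = c("mixed", "mutation_only", "selection"),
                             seed = 1L, species = "synthetic") {
  regime <- match.arg(regime)
  if (regime == "mutation_only") s <- 0
  if (regime == "selection") gc3_target <- 0.5
  if (regime != "mutation_only" && any(s > 0) && is.null(preferred_set))
    preferred_set <- default_preferred_codons()
  if (regime == "selection" && !length(preferred_set))
    stop("selection regime requires a non-empty preferred_set")
  if (!is.null(preferred_set)) {
    fam_of <- .codon_aa[preferred_set]
    if (anyNA(fam_of) || anyDuplicated(fam_of))
      stop("preferred_set must contain informative codons, at most one per family")
  }
  if (any(gc3_target < 0 | gc3_target > 1)) stop("gc3_target must be in [0, 1]")
  if (any(s < 0)) stop("selection strength s must be >= 0")

  aas <- names(.kd_hydropathy)
  if (is.null(aa_profile)) aa_profile <- setNames(rep(1, 20), aas)
  stopifnot(all(names(aa_profile) %in% aas))
  prof <- setNames(numeric(20), aas)
  prof[names(aa_profile)] <- aa_profile
  prof <- prof / sum(prof)

  # per-gene parameter resolution
  gc3 <- if (length(gc3_target) == n_genes) gc3_target
         else if (length(gc3_target) == 2L && n_genes != 2L) NULL
         else rep_len(gc3_target, n_genes)
  sg <- rep_len(s, n_genes)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  gene_seeds <- sample.int(.Machine$integer.max - 1L, n_genes)

  seqs <- character(n_genes)
  truth <- data.frame(gene_id = sprintf("%s_g%03d", species, seq_len(n_genes)),
                      length_codons = 0L, gc3_target = NA_real_,
                      realized_gc3s = NA_real_, s = sg, regime = regime,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_genes)) {
    set.seed(gene_seeds[i])
    L <- if (length(length_codons) == 1L) length_codons
         else sample(length_codons[1]:length_codons[2], 1L)
    t <- if (is.null(gc3)) stats::runif(1, gc3_target[1], gc3_target[2]) else gc3[i]
    body_aa <- sample(aas, L - 2L, replace = TRUE, prob = prof)
    codons <- character(L - 2L)
    for (aa in unique(body_aa)) {
      idx <- which(body_aa == aa)
      fam <- .syn_families[[aa]]
      codons[idx] <- if (length(fam) == 1L) fam else
        sample(fam, length(idx), replace = TRUE,
               prob = .family_probs(fam, t, sg[i], preferred_set))
    }
    seqs[i] <- paste(c("ATG", codons, sample(.STOP_CODONS, 1L)), collapse = "")
    ni <- .codon_ni[codons]
    syn <- codons[!is.na(ni) & ni >= 2]
    truth$length_codons[i] <- L
    truth$gc3_target[i] <- t
    truth$realized_gc3s[i] <- mean(substr(syn, 3L, 3L) %in% c("G", "C"))
  }
  names(seqs) <- truth$gene_id
  res <- list(set = cds_set(seqs, species), truth = truth)
  attr(res, "preferred_set") <- preferred_set
  res
}

#' Fixed scenario battery for calibration and acceptance checks
#'
#' Emits the deterministic scenario grid the package's calibration tests
#' run on: mutation-only sets at GC3s targets 0.2/0.35/0.5/0.65/0.8,
#' selection sets (GC3s 0.5, planted [default_preferred_codons()]) at
#' s = 0/0.5/1/2/5, two planted clustering regimes (GC3s 0.30 vs 0.60, three
#' species each), and one "recovery" set on an AT-rich background (GC3s
#' 0.25, where every planted G/C-ending codon is a true mutational minority
#' with null RSCU below 1) in which half the genes carry strong selection
#' (s = 4) toward the planted set — the scenario for planted optimal-codon
#' recovery.
#'
#' @param seed Integer root seed; the same seed reproduces every set
#'   byte-identically.
#' @param n_genes Genes per set (default 40, the chloroplast scale).
#' @param length_codons Length range in codons (default `c(300, 600)`, long
#'   enough for stable per-gene ENC estimation).
#' @return Named list of simulation results (each `list(set, truth)`), with
#'   attribute `scenarios` (data.frame describing the grid) and
#'   `preferred_set`.
#' @export
regime_battery <- function(seed = 1L, n_genes = 40L,
                           length_codons = c(300L, 600L)) {
  pref <- default_preferred_codons()
  scen <- rbind(
    data.frame(name = sprintf("mut_gc%02.0f", 100 * c(.2, .35, .5, .65, .8)),
               regime = "mutation_only", gc3 = c(.2, .35, .5, .65, .8), s = 0),
    data.frame(name = sprintf("sel_s%s", c("0", "0.5", "1", "2", "5")),
               regime = "selection", gc3 = 0.5, s = c(0, .5, 1, 2, 5)),
    data.frame(name = c(paste0("clustA_", 1:3), paste0("clustB_", 1:3)),
               regime = "mutation_only", gc3 = rep(c(.30, .60), each = 3), s = 0),
    data.frame(name = "recovery", regime = "mixed", gc3 = 0.25, s = NA)
  )
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, nrow(scen))
  out <- vector("list", nrow(scen))
  names(out) <- scen$name
  for (i in seq_len(nrow(scen))) {
    sc <- scen[i, ]
    if (sc$name == "recovery") {
      out[[i]] <- simulate_cds_set(
        n_genes, length_codons, gc3_target = sc$gc3,
        s = rep(c(4, 0), each = ceiling(n_genes / 2))[seq_len(n_genes)],
        preferred_set = pref, regime = "mixed", seed = seeds[i],
        species = sc$name)
    } else {
      out[[i]] <- simulate_cds_set(
        n_genes, length_codons, gc3_target = sc$gc3, s = sc$s,
        preferred_set = if (sc$regime == "selection") pref else NULL,
        regime = sc$regime, seed = seeds[i], species = sc$name)
    }
  }
  attr(out, "scenarios") <- scen
  attr(out, "preferred_set") <- pref
  out
}

#' Write a simulated set and its truth table
#'
#' @param sim Result of [simulate_cds_set()].
#' @param fasta_path,truth_path Output paths (FASTA and tab-separated truth).
#' @return Invisibly, the two paths.
#' @export
write_simulation <- function(sim, fasta_path, truth_path) {
  write_cds_fasta(sim$set, fasta_path)
  .write_tsv(sim$truth, truth_path,
             comment = paste("synthetic truth table; regime =",
                             sim$truth$regime[1]))
  invisible(c(fasta_path, truth_path))
}
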
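#' Construct a per-species CDS set
#'
#' The container every downstream stage consumes: an ordered, uniquely named
#' collection of in-frame coding sequences from one species.
#'
#' @param seq Named character vector of uppercase DNA sequences (names are
#'   gene/CDS identifiers, unique within the set).
#' @param species Single species label.
#' @param provenance Character vector of source file paths (may be empty).
#' @return An object of class `"cds_set"` with elements `species`, `seq`,
#'   `provenance`.
#' @export
cds_set <- function(seq, species, provenance = character()) {
  stopifnot(is.character(seq), length(species) == 1L)
  if (length(seq) &&
      (is.null(names(seq)) || anyNA(names(seq)) || any(names(seq) == "")))
    stop("all sequences must be named")
  if (anyDuplicated(names(seq)))
    stop("duplicate sequence ids in cds_set: ",
         paste(unique(names(seq)[duplicated(names(seq))]), collapse = ", "))
  structure(list(species = as.character(species), seq = seq,
                 provenance = as.character(provenance)),
            class = "cds_set")
}

#' @export
print.cds_set <- function(x, ...) {
  cat("CDS set:", x$species, "-", length(x$seq), "sequences\n")
  if (length(x$seq)) {
    len <- nchar(x$seq)
    cat("  length (nt): min", min(len), "/ median", stats::median(len),
        "/ max", max(len), "\n")
  }
  invisible(x)
}

#' @export
length.cds_set <- function(x) length(x$seq)

#' Read coding sequences from FASTA or GenBank
#'
#' FASTA files yield one sequence per record (id = first whitespace-delimited
#' token of the header). GenBank flat files yield one sequence per CDS
#' feature: join locations are spliced and minus-strand features are
#' reverse-complemented so every returned sequence reads 5'->3'. All
#' sequences are uppercased and U is mapped to T.
#'
#' @param path Path to the input file.
#' @param format `"fasta"` or `"genbank"`.
#' @return Named character vector of sequences. For GenBank input the names
#'   are the `/gene` qualifier where present (falling back to `/locus_tag`,
#'   then a positional id); an attribute `"gene"` carries the same names for
#'   use by duplicate-gene removal.
#' @seealso [filter_cds()]
#' @export
read_cds <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    recs <- tryCatch(Biostrings::readBStringSet(path),
                     error = function(e) stop("cannot parse FASTA file '",
                                              path, "': ", conditionMessage(e)))
    seqs <- .norm_seq(as.character(recs))
    ids <- vapply(strsplit(names(recs), "[ \t]+"), `[`, character(1), 1L)
    ids[is.na(ids) | ids == ""] <- paste0("record", which(is.na(ids) | ids == ""))
    names(seqs) <- make.unique(ids)
    attr(seqs, "gene") <- names(seqs)
    return(seqs)
  }
  .read_genbank_cds(path)
}

# Minimal GenBank flat-file CDS extractor (LOCUS/FEATURES/ORIGIN). Handles
# multi-line locations, join()/order(), complement() wrapping a join and
# per-element complement(); start..end coordinates are 1-based inclusive.
.read_genbank_cds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(grep("^LOCUS", lines)))
    stop("cannot parse GenBank file '", path, "': no LOCUS line")
  rec_start <- grep("^LOCUS", lines)
  rec_end <- c(rec_start[-1] - 1L, length(lines))
  out <- character(0)
  genes <- character(0)
  for (r in seq_along(rec_start)) {
    rl <- lines[rec_start[r]:rec_end[r]]
    ori <- grep("^ORIGIN", rl)
    if (!length(ori)) next
    seq_lines <- rl[(ori[1] + 1L):length(rl)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    genome <- .norm_seq(paste(gsub("[^A-Za-z]", "", seq_lines), collapse = ""))

    feat <- grep("^FEATURES", rl)
    if (!length(feat)) next
    fl <- rl[(feat[1] + 1L):(ori[1] - 1L)]
    # feature keys start at column 6; qualifier/continuation lines at column 22
    is_key <- grepl("^ {5}\\S", fl)
    key_idx <- which(is_key)
    keys <- sub("^ {5}(\\S+).*$", "\\1", fl[key_idx])
    cds_pos <- which(keys == "CDS")
    if (!length(cds_pos)) {
      warning("GenBank record ", r, " in '", path, "' has no CDS features")
      next
    }
    for (k in cds_pos) {
      from <- key_idx[k]
      to <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(fl)
      block <- fl[from:to]
      # location = feature line remainder plus continuation lines before the
      # first qualifier
      qual_at <- grep("^ +/", block)
      loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(block)
      loc <- paste(gsub("\\s+", "", c(sub("^ {5}\\S+\\s+", "", block[1]),
                                      if (loc_end >= 2) block[2:loc_end])),
                   collapse = "")
      seq <- tryCatch(.extract_location(loc, genome), error = function(e)
        stop("bad CDS location '", loc, "' in '", path, "': ",
             conditionMessage(e)))
      quals <- block[grep("^ +/", block)]
      gene <- sub('^.*/gene="([^"]*)".*$', "\\1",
                  grep('/gene="', quals, value = TRUE)[1])
      if (is.na(gene))
        gene <- sub('^.*/locus_tag="([^"]*)".*$', "\\1",
                    grep('/locus_tag="', quals, value = TRUE)[1])
      if (is.na(gene)) gene <- paste0("CDS_", length(out) + 1L)
      out <- c(out, seq)
      genes <- c(genes, gene)
    }
  }
  names(out) <- make.unique(genes)
  attr(out, "gene") <- genes
  out
}

# Resolve a GenBank location string against the full genome sequence.
.extract_location <- function(loc, genome) {
  loc <- gsub("[<>]", "", loc)
  outer_comp <- FALSE
  if (grepl("^complement\\(", loc) && grepl("^complement\\((join|order)\\(", loc)) {
    outer_comp <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  } else if (grepl("^complement\\([0-9]", loc)) {
    outer_comp <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  pieces <- vapply(parts, function(p) {
    comp <- grepl("^complement\\(", p)
    p <- sub("^complement\\((.*)\\)$", "\\1", p)
    m <- regmatches(p, regexec("^([0-9]+)\\.\\.([0-9]+)$", p))[[1]]
    if (length(m) == 3) {
      a <- as.integer(m[2]); b <- as.integer(m[3])
    } else if (grepl("^[0-9]+$", p)) {
      a <- b <- as.integer(p)
    } else stop("unsupported location element: ", p)
    if (a > b || b > nchar(genome)) stop("coordinates out of range: ", p)
    s <- substr(genome, a, b)
    if (comp) .revcomp(s) else s
  }, character(1))
  seq <- paste(pieces, collapse = "")
  if (outer_comp) seq <- .revcomp(seq)
  seq
}

#' Filter candidate coding sequences
#'
#' Applies the canonical chloroplast-CDS quality rules: a retained gene must
#' start with ATG, end with TAA/TAG/TGA, contain no internal in-frame stop,
#' have length divisible by three and at least `min_len` nucleotides, and
#' contain only A/C/G/T. Optionally, duplicated gene names (e.g.
#' inverted-repeat copies) are collapsed to their first occurrence.
#'
#' @param candidates Named character vector as returned by [read_cds()].
#' @param min_len Minimum length in nucleotides (default 300).
#' @param species Species label for the resulting set.
#' @param dedupe Drop later copies of an already-seen gene name (default TRUE).
#' @return List with elements `set` (a [cds_set()]) and `report` (a
#'   `"filter_report"`: data.frame of `gene_id`, `status`, `reason` with
#'   attributes `accepted` and `rejected`).
#' @export
filter_cds <- function(candidates, min_len = 300L, species = "unknown",
                       dedupe = TRUE) {
  seqs <- .norm_seq(unclass(c(candidates)))
  if (length(seqs) && (is.null(names(seqs)) || any(names(seqs) == "")))
    names(seqs) <- paste0("cds", seq_along(seqs))
  gene <- attr(candidates, "gene")
  if (is.null(gene)) gene <- names(seqs)

  reason <- character(length(seqs))
  seen <- character(0)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    reason[i] <-
      if (grepl("[^ACGT]", s)) "ambiguous_base"
      else if (n %% 3L != 0L) "frame"
      else if (n < min_len) "length"
      else if (substr(s, 1L, 3L) != .START_CODON) "start"
      else if (!(substr(s, n - 2L, n) %in% .STOP_CODONS)) "stop"
      else {
        body <- .split_codons(substr(s, 1L, n - 3L))
        if (any(body %in% .STOP_CODONS)) "internal_stop"
        else if (dedupe && gene[i] %in% seen) "duplicate"
        else ""
      }
    if (reason[i] == "") seen <- c(seen, gene[i])
  }
  ok <- reason == ""
  report <- data.frame(
    gene_id = if (length(seqs)) names(seqs) else character(0),
    status = ifelse(ok, "accepted", "rejected"),
    reason = ifelse(ok, "", reason),
    stringsAsFactors = FALSE
  )
  attr(report, "accepted") <- sum(ok)
  attr(report, "rejected") <- sum(!ok)
  class(report) <- c("filter_report", "data.frame")
  prov <- attr(candidates, "provenance")
  list(set = cds_set(seqs[ok], species,
                     provenance = if (is.null(prov)) character() else prov),
       report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("CDS filter report:", attr(x, "accepted"), "accepted,",
      attr(x, "rejected"), "rejected\n")
  if (attr(x, "rejected") > 0)
    print(table(x$reason[x$reason != ""]))
  invisible(x)
}

#' Write a CDS set as wrapped FASTA
#'
#' Headers are `">id species=<label>"`; sequence lines wrap at 60 columns.
#' `read_cds()` on the written file reproduces the set.
#'
#' @param set A [cds_set()]; must be non-empty.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(set, path) {
  stopifnot(inherits(set, "cds_set"))
  if (!length(set$seq)) stop("refusing to write an empty cds_set")
  x <- Biostrings::BStringSet(set$seq)
  names(x) <- paste0(names(set$seq), " species=", set$species)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Write a filter report as tab-separated text
#'
#' @param report A `"filter_report"` from [filter_cds()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  .write_tsv(as.data.frame(report), path,
             comment = sprintf("filter_cds: accepted=%d rejected=%d",
                               attr(report, "accepted"),
                               attr(report, "rejected")))
}

# shared TSV writer: optional '#' comment header then tab-separated body
.write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
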
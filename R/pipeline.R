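#' Read a pipeline configuration
#'
#' Configurations are declarative YAML. Recognised keys: `species` (list of
#' entries with `label` plus either `path`/`format` or a `simulate` block of
#' [simulate_cds_set()] arguments), `min_len`, `dedupe`, `fraction`,
#' `cor_method`, `hosts` (named map host -> table path; omit for the
#' packaged synthetic tables), `outdir`, `seed`.
#'
#' @param path YAML file path.
#' @return Config list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  .fill_config(cfg)
}

.fill_config <- function(cfg) {
  defaults <- list(min_len = 300L, dedupe = TRUE, fraction = 0.10,
                   cor_method = "spearman", hosts = NULL, outdir = "cub_out",
                   seed = 1L)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg$species) || !length(cfg$species))
    stop("config error: no species entries")
  labels <- vapply(cfg$species, function(s) as.character(s$label %||% ""),
                   character(1))
  if (any(labels == "")) stop("config error: every species needs a label")
  if (anyDuplicated(labels))
    stop("config error: duplicate species labels")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_species <- function(entry, seed) {
  if (!is.null(entry$simulate)) {
    args <- entry$simulate
    args$species <- entry$label
    if (is.null(args$seed)) args$seed <- seed
    sim <- do.call(simulate_cds_set, args)
    structure(sim$set$seq, gene = names(sim$set$seq))
  } else {
    if (is.null(entry$path) || !file.exists(entry$path %||% ""))
      stop("input path missing or not found: ", entry$path %||% "<unset>")
    read_cds(entry$path, format = entry$format %||% "fasta")
  }
}

#' Run the complete codon-usage pipeline
#'
#' For each configured species: read or simulate the CDSs, filter, run
#' [cub_analysis()], and write the filtered FASTA plus every per-species
#' table (filter report, gene index table, pooled RSCU/RFSC, HF and optimal
#' codons, neutrality/ENC-plot/PR2 tables, COA coordinates and inertia,
#' correlation table, host divergence). Across species it writes the
#' shared-HF set, the species-by-codon RSCU matrix, the cluster tree in
#' newick form, the host-divergence summary, and a run manifest. Any stage
#' failure aborts with a stage-tagged error; outputs already written are
#' retained.
#'
#' @param config A config list or a YAML path ([read_pipeline_config()]).
#' @return A `"cub_comparison"` object, invisibly; attribute `"analyses"`
#'   holds the per-species `"cub"` objects and `"outdir"` the output
#'   directory.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else .fill_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, label, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s:%s] %s", name, label, conditionMessage(e)),
           call. = FALSE))
  }

  hosts <- NULL
  if (!is.null(cfg$hosts))
    hosts <- stage("hosts", "config",
                   sapply(names(cfg$hosts), function(h)
                     read_host_table(cfg$hosts[[h]]), simplify = FALSE))

  analyses <- list()
  for (entry in cfg$species) {
    lab <- entry$label
    cand <- stage("read", lab, .load_species(entry, cfg$seed))
    fit <- stage("analyse", lab,
                 cub_analysis(cand, species = lab, min_len = cfg$min_len,
                              dedupe = cfg$dedupe, fraction = cfg$fraction,
                              cor_method = cfg$cor_method))
    stage("write", lab, .write_species_bundle(fit, file.path(outdir, lab)))
    analyses[[lab]] <- fit
  }

  cmp <- stage("compare", "all", cub_compare(analyses, hosts = hosts))
  stage("write", "all", .write_comparison_bundle(cmp, outdir))
  .write_manifest(cfg, file.path(outdir, "manifest.txt"))
  attr(cmp, "analyses") <- analyses
  attr(cmp, "outdir") <- outdir
  invisible(cmp)
}

.write_species_bundle <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  sp <- fit$species
  hdr <- function(stg) sprintf("stage=%s species=%s min_len=%d fraction=%.2f",
                               stg, sp, fit$params$min_len, fit$params$fraction)
  write_cds_fasta(fit$set, p("filtered.fasta"))
  if (!is.null(fit$filter_report))
    write_filter_report(fit$filter_report, p("filter_report.tsv"))
  .write_tsv(fit$genes, p("gene_indices.tsv"), comment = hdr("indices"))
  .write_tsv(data.frame(codon = names(fit$rscu_pooled),
                        aa = unname(.codon_aa[names(fit$rscu_pooled)]),
                        rscu = unname(fit$rscu_pooled),
                        rfsc = unname(fit$rfsc_pooled)),
             p("rscu_pooled.tsv"), comment = hdr("rscu"))
  .write_tsv(as.data.frame(fit$hf), p("hf_codons.tsv"), comment = hdr("hf"))
  .write_tsv(fit$optimal, p("optimal_codons.tsv"), comment = hdr("optimal"))
  .write_tsv(data.frame(gene_id = fit$genes$gene_id, GC12 = fit$genes$GC12,
                        GC3 = fit$genes$GC3),
             p("neutrality.tsv"),
             comment = sprintf("%s slope=%.6g intercept=%.6g r=%.6g p=%.6g n=%d",
                               hdr("neutrality"), fit$neutrality$slope,
                               fit$neutrality$intercept, fit$neutrality$r,
                               fit$neutrality$p, fit$neutrality$n))
  .write_tsv(fit$encplot$data, p("encplot.tsv"),
             comment = sprintf("%s frac_in_band=%.6g", hdr("encplot"),
                               fit$encplot$frac_in_band))
  .write_tsv(fit$encplot$histogram, p("enc_histogram.tsv"),
             comment = hdr("encplot"))
  .write_tsv(fit$pr2$data, p("pr2.tsv"), comment = hdr("pr2"))
  if (fit$coa$n_axes) {
    .write_tsv(data.frame(gene_id = rownames(fit$coa$row_coords),
                          fit$coa$row_coords, row.names = NULL),
               p("coa_genes.tsv"), comment = hdr("coa"))
    .write_tsv(data.frame(codon = rownames(fit$coa$col_coords),
                          fit$coa$col_coords, row.names = NULL),
               p("coa_codons.tsv"), comment = hdr("coa"))
    .write_tsv(data.frame(axis = seq_len(fit$coa$n_axes),
                          inertia = fit$coa$inertia,
                          inertia_pct = fit$coa$inertia_pct),
               p("coa_inertia.tsv"), comment = hdr("coa"))
  }
  .write_tsv(fit$correlations, p("correlations.tsv"),
             comment = paste(hdr("correlate"), "method =",
                             fit$params$cor_method))
  invisible(dir)
}

.write_comparison_bundle <- function(cmp, outdir) {
  p <- function(f) file.path(outdir, f)
  writeLines(cmp$shared_hf, p("shared_hf_codons.txt"))
  .write_tsv(data.frame(species = rownames(cmp$rscu_species),
                        cmp$rscu_species, row.names = NULL, check.names = FALSE),
             p("rscu_species_matrix.tsv"), comment = "stage=cluster")
  if (!is.null(cmp$cluster))
    writeLines(cmp$cluster$newick, p("rscu_cluster.nwk"))
  .write_tsv(cmp$divergence_summary, p("host_divergence_summary.tsv"),
             comment = "stage=hosts ratio divergent iff <=0.5 or >=2")
  div <- do.call(rbind, lapply(names(cmp$host_comparisons), function(s)
    do.call(rbind, lapply(cmp$host_comparisons[[s]], function(hc)
      cbind(species = s, host = hc$host, hc$table)))))
  rownames(div) <- NULL
  .write_tsv(div, p("host_divergence_full.tsv"), comment = "stage=hosts")
  invisible(outdir)
}

.write_manifest <- function(cfg, path) {
  tmp <- tempfile()
  yaml::write_yaml(cfg, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  writeLines(c(
    sprintf("cubtools version: %s",
            as.character(utils::packageVersion("cubtools"))),
    sprintf("R version: %s", R.version.string),
    sprintf("seed: %s", cfg$seed),
    sprintf("config md5: %s", hash),
    "", "config:", vapply(utils::capture.output(utils::str(cfg)),
                          function(l) paste0("  ", l), character(1))
  ), path)
  invisible(path)
}
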
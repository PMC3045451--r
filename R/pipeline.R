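# End-to-end orchestration on synthetic (or user-supplied) inputs,
# with deterministic per-stage seeds, audit logging and TSV reports.

#' Default pipeline configuration
#'
#' All stage parameters in one structure.  Every stochastic stage
#' derives its own seed deterministically from \code{master_seed}, so a
#' run is a pure function of its configuration.  The default problem
#' size (one 200 kb chromosome, 20 islands, 40 genes, seven samples)
#' keeps a full run under a minute while exercising every stage.
#'
#' @param master_seed integer master seed.
#' @return nested list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(master_seed = 1L) {
  structure(list(
    master_seed = as.integer(master_seed),
    design = default_design(),
    reference_sample = "ref",
    genome = genome_config(chr_lengths = c(chr1 = 2e5), n_genes = 40L,
                           n_islands = 20L),
    truth = list(de_frac = 0.15, inverse_frac = 0.9, dispersion = 0.05),
    expression = list(min_mean = 50, min_each = 5, p_cut = 0.05,
                      fc_cut = 1.5, k = 2L, robustness_iter = 100L),
    rrbs = list(coverage = 30, read_len = 50L, conversion = 1.0,
                min_cov = 10L, dm_p_cut = 0.05, tss_window = 5000L),
    cna = list(depth = 2e4, min_tags_per_window = 30,
               p_split = 1e-4, min_points = 10L, min_sn = 0.3,
               t_del = -1, t_amp = 0.59, p_call = 1e-4,
               min_samples = 2L)),
    class = "pipeline_config")
}

#' Window size giving a target expected reference tag count
#'
#' @param genome_size genome length (bp).
#' @param depth total tags.
#' @param min_tags target expected tags per window (default 30).
#' @return window size in bp.
#' @export
choose_window_size <- function(genome_size, depth, min_tags = 30) {
  ceiling(min_tags * genome_size / depth)
}

#' Run the full integrated pipeline on synthetic data
#'
#' Generates a toy genome and planted truth, simulates the three
#' assays, runs each layer's analysis and the cross-layer integration,
#' and writes every result table (TSV), the audit log and the
#' serialized configuration into \code{dir}.  Re-running with the same
#' configuration reproduces byte-identical outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param dir output directory (created).
#' @return list of in-memory results (invisible components mirror the
#'   files on disk).
#' @export
run_pipeline <- function(config = pipeline_config(), dir = tempfile("run")) {
  design <- config$design
  lev <- tryCatch(check_two_groups(design),
                  error = function(e) stop("invalid design: ",
                                           conditionMessage(e), call. = FALSE))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ms <- config$master_seed
  audit <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- synthetic inputs -------------------------------------------------
  genome <- stage("genome",
    generate_genome(config$genome, seed = derive_seed(ms, "genome")))
  truth <- stage("truth", do.call(synthetic_truth, c(
    list(genome = genome, design = design,
         seed = derive_seed(ms, "truth")), config$truth)))
  counts <- stage("mrnaseq",
    simulate_mrnaseq(genome, truth, design,
                     seed = derive_seed(ms, "mrnaseq")))
  write_tsv(data.frame(gene = rownames(counts), counts,
                       check.names = FALSE),
            file.path(dir, "counts.tsv"))

  # --- expression -------------------------------------------------------
  ex <- config$expression
  flt <- stage("filter", filter_genes(counts, design,
                                      min_mean = ex$min_mean,
                                      min_each = ex$min_each))
  audit$expression_filter <- as.list(flt$audit)
  expr <- stage("normalize", normalize_rpm(flt$counts))
  de <- stage("de", moderated_t_test(expr, design))
  de$q <- estimate_qvalues(de$p)
  de_genes <- select_de(de, p_cut = ex$p_cut, fc_cut = ex$fc_cut)
  write_tsv(de[, c("gene", "log2fc", "t", "p", "q")],
            file.path(dir, "de_table.tsv"))
  cl <- stage("cluster", hierarchical_cluster(expr, k = ex$k))
  rb <- stage("robustness",
    cluster_robustness(expr, k = ex$k, n_iter = ex$robustness_iter,
                       seed = derive_seed(ms, "robustness")))
  write_tsv(data.frame(sample = names(cl$membership),
                       cluster = unname(cl$membership),
                       group = unname(design[names(cl$membership)])),
            file.path(dir, "cluster_membership.tsv"))
  hist <- report_pvalue_histogram(de$p)
  write_tsv(data.frame(bin = names(hist$counts), count = hist$counts,
                       expected = hist$expected, row.names = NULL),
            file.path(dir, "pvalue_histogram.tsv"))

  # --- methylation ------------------------------------------------------
  rr <- config$rrbs
  frags <- stage("digest", digest_reference(genome, read_len = rr$read_len))
  index <- stage("index", build_converted_reference(frags))
  samples <- names(design)
  site_calls <- list()
  read_audit <- list()
  for (s in samples) {
    reads <- stage(paste0("rrbs_", s),
      simulate_rrbs_reads(genome, truth, s,
                          config = list(coverage = rr$coverage,
                                        read_len = rr$read_len,
                                        conversion = rr$conversion),
                          seed = derive_seed(ms, paste0("rrbs_", s))))
    aln <- stage(paste0("align_", s),
                 align_bisulfite_reads(reads, index))
    read_audit[[s]] <- as.list(aln$audit)
    site_calls[[s]] <- stage(paste0("call_", s),
                             call_methylation(aln, frags, genome))
  }
  audit$rrbs_reads <- read_audit
  isl <- stage("islands", summarize_islands(site_calls, genome$islands,
                                            min_cov = rr$min_cov))
  audit$island_retention <- as.list(isl$audit)
  write_tsv(data.frame(island = rownames(isl$percent), isl$percent,
                       check.names = FALSE),
            file.path(dir, "island_methylation.tsv"))
  dm <- stage("dm", differential_methylation(isl$percent, design,
                                             p_cut = rr$dm_p_cut))
  write_tsv(dm, file.path(dir, "dm_table.tsv"))
  assoc <- map_islands_to_genes(genome$islands, genome$genes,
                                window = rr$tss_window)

  # --- copy number ------------------------------------------------------
  cn <- config$cna
  gsize <- sum(nchar(genome$chromosomes))
  wsize <- choose_window_size(gsize, cn$depth, cn$min_tags_per_window)
  ref_tags <- stage("dnaseq_ref",
    simulate_dnaseq(genome, truth, config$reference_sample,
                    depth = cn$depth,
                    seed = derive_seed(ms, "dnaseq_ref")))
  ref_counts <- count_windows(ref_tags, genome, wsize)
  seglists <- list()
  for (s in samples) {
    tags <- stage(paste0("dnaseq_", s),
      simulate_dnaseq(genome, truth, s, depth = cn$depth,
                      seed = derive_seed(ms, paste0("dnaseq_", s))))
    tw <- count_windows(tags, genome, wsize)
    track <- stage(paste0("ratio_", s), compute_log2_ratios(tw, ref_counts))
    segs <- stage(paste0("segment_", s),
                  segment_genome(track, p_split = cn$p_split,
                                 min_points = cn$min_points,
                                 min_sn = cn$min_sn))
    seglists[[s]] <- classify_segments(segs, track, t_del = cn$t_del,
                                       t_amp = cn$t_amp,
                                       p_call = cn$p_call)
  }
  catalog <- stage("recurrent", merge_and_overlap(seglists,
                                                  min_samples = cn$min_samples))
  write_tsv(catalog$regions, file.path(dir, "cna_regions.tsv"))
  write_tsv(do.call(rbind, lapply(names(catalog$per_sample), function(s)
    cbind(sample = s, catalog$per_sample[[s]]))),
    file.path(dir, "cna_segments.tsv"))
  cna_genes <- stage("cna_genes", assign_genes_to_cna(catalog, genome$genes))

  # --- integration ------------------------------------------------------
  records <- stage("join", join_layers(de, dm, assoc, de_genes = de_genes,
                                       dm_p_cut = rr$dm_p_cut))
  write_tsv(records, file.path(dir, "integrated_records.tsv"))
  linked <- records[records$de_sig & records$dm_sig, , drop = FALSE]
  meth_cor <- if (nrow(linked) >= 3L)
    tryCatch(correlate_methylation_expression(linked),
             error = function(e) NULL) else NULL
  outl <- if (nrow(linked)) flag_outliers(linked) else NULL
  dist <- if (any(records$inverse))
    distance_analysis(records[records$inverse, , drop = FALSE]) else NULL
  cna_cor <- tryCatch(
    correlate_cna_expression(de[de$gene %in% de_genes, , drop = FALSE],
                             cna_genes$values, design),
    error = function(e) NULL)
  sigs <- stage("signatures",
                build_signatures(records, cna_genes$values, design, de = de))
  write_tsv(sigs$methylation$table, file.path(dir, "signature_methylation.tsv"))
  if (!is.null(sigs$cna))
    write_tsv(sigs$cna$table, file.path(dir, "signature_cna.tsv"))
  write_gmt(list(methylation_signature = sigs$methylation$all,
                 cna_signature = sigs$cna$genes %||% character(0)),
            file.path(dir, "signatures.gmt"))

  audit$integration <- list(
    records = nrow(records),
    de_and_dm_linked = nrow(linked),
    outliers = length(outl$outliers %||% character(0)),
    inverse = sum(records$inverse))

  yaml::write_yaml(unclass_recursive(config), file.path(dir, "config.yaml"))
  yaml::write_yaml(audit, file.path(dir, "audit.yaml"))

  invisible(list(dir = dir, genome = genome, truth = truth,
                 counts = counts, filter = flt, expr = expr, de = de,
                 de_genes = de_genes, cluster = cl, robustness = rb,
                 islands = isl, dm = dm, assoc = assoc,
                 seglists = seglists, catalog = catalog,
                 cna_genes = cna_genes, records = records,
                 meth_cor = meth_cor, outliers = outl, distance = dist,
                 cna_cor = cna_cor, signatures = sigs, audit = audit))
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive)
  else if (!is.null(attributes(x)) && !is.null(names(x)))
    as.list(stats::setNames(as.vector(x), names(x)))
  else unclass(x)
}
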
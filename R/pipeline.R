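#' Build a pipeline configuration
#'
#' Collects every tunable of the transcriptomic pipeline, with the
#' field-standard defaults used throughout the package (count filter 5
#' counts in 3 samples, |log2 ratio| > 0.58, selection and
#' signature-summary alpha 0.1, 7 expression clusters, discrimination
#' margin 0.5, and the synthetic study conditions: 3 cell types with 50
#' markers each at a 4:1 effect-to-noise ratio, 3 replicates per region).
#'
#' @param seed global seed; all generator substreams derive from it.
#' @param ... overrides for any default field (unknown fields are an error).
#' @return a validated `wm_config` list.
#' @export
wm_config <- function(seed = 0, ...) {
  cfg <- list(
    seed = seed,
    # atlas generation + signature derivation
    n_cell_types = 3, n_markers_per_type = 50, n_background_genes = 500,
    n_atlas_replicates = 3, marker_effect = 2, noise_sd = 0.5,
    low_coverage_min = 1, cv_cutoff = 0.3, k_atlas = NULL, margin = 0.5,
    # region counts + differential expression
    n_genes = 2000, n_per_region = 3, dispersion = 0.05,
    planted_signature = "TYPE1", n_planted_signature = 40,
    planted_log2fc = 2, n_planted_other = 260,
    min_count = 5, min_samples = 3,
    lfc_min = 0.58, alpha_select = 0.1, alpha_signature = 0.1,
    k_de = 7, correction = "bh",
    # quantification defaults (recorded for provenance)
    decompaction_threshold = 0.15, contact_distance = 1.5,
    disruption_fraction = 0.25, tier_probs = c(0.25, 0.75),
    threshold_z = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$n_cell_types >= 2, cfg$n_per_region >= 2,
            cfg$lfc_min >= 0, cfg$alpha_select > 0, cfg$alpha_select <= 1,
            cfg$k_de >= 2, cfg$correction %in% c("bh", "bonferroni"))
  structure(cfg, class = "wm_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic transcriptomic pipeline
#'
#' Executes, in order: atlas simulation, signature derivation, region-count
#' simulation with effects planted inside one signature's markers, count
#' filtering, differential expression for CC vs Bulk and ST vs Bulk,
#' selection and K-means clustering of regulated genes, cluster-by-signature
#' Fisher enrichment, per-signature regulation summaries and sample PCA.
#' Every stage is seeded from `config$seed`, all tables plus a config
#' snapshot and a stage log are written to `out_dir`, and the returned MD5
#' hashes make byte-level reproducibility checkable: re-running the same
#' config reproduces identical hashes.
#'
#' @param config a [wm_config()] object.
#' @param out_dir output directory (created if missing).
#' @return (invisibly) a list with all in-memory results (`atlas`,
#'   `signatures`, `counts`, `filtered`, `de_cc`, `de_st`, `clusters`,
#'   `enrichment`, `regulation_cc`, `pca`, `truth`), the written `files`
#'   and their `hashes`.
#' @export
run_pipeline <- function(config = wm_config(), out_dir = tempfile("wmrun")) {
  stopifnot(inherits(config, "wm_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # --- atlas and signatures ---------------------------------------------
  atlas <- stage("simulate_atlas", simulate_atlas(
    n_cell_types = config$n_cell_types,
    n_markers_per_type = config$n_markers_per_type,
    n_background_genes = config$n_background_genes,
    n_replicates = config$n_atlas_replicates,
    marker_effect = config$marker_effect,
    noise_sd = config$noise_sd,
    seed = config$seed
  ))
  say("atlas: %d genes x %d samples", nrow(atlas$expression),
      ncol(atlas$expression) - 1)

  centred <- stage("preprocess_atlas",
                   preprocess_atlas(atlas$expression, config$low_coverage_min))
  variable <- stage("select_variable_genes",
                    select_variable_genes(atlas$expression, config$cv_cutoff))
  k_atlas <- if (is.null(config$k_atlas)) config$n_cell_types else config$k_atlas
  signatures <- stage("derive_signatures", derive_signatures(
    centred, variable, k = k_atlas, margin = config$margin, seed = config$seed
  ))
  say("signatures: %d variable genes -> %d signatures (%s)",
      length(variable), length(signatures),
      paste(sprintf("%s:%d", names(signatures), lengths(signatures)),
            collapse = ", "))

  # --- region counts with planted effects --------------------------------
  sig_genes <- signatures[[config$planted_signature]]
  if (is.null(sig_genes)) {
    abort(sprintf("no derived signature for planted type '%s'",
                  config$planted_signature))
  }
  planted_sig <- head(sig_genes, config$n_planted_signature)
  genes <- atlas$truth$gene
  if (config$n_genes > length(genes)) {
    genes <- c(genes, sprintf("XGENE%04d", seq_len(config$n_genes - length(genes))))
  }
  background <- setdiff(genes, unlist(unclass(signatures)))
  other <- with_seed(substream_seed(config$seed, "counts"), {
    sample(background, config$n_planted_other)
  })
  half <- length(other) %/% 2
  de_plan <- dplyr::bind_rows(
    tibble::tibble(gene = planted_sig, region = "CC",
                   log2fc = config$planted_log2fc),
    tibble::tibble(gene = other[seq_len(half)], region = "ST",
                   log2fc = config$planted_log2fc),
    tibble::tibble(gene = other[-seq_len(half)], region = "CC",
                   log2fc = -config$planted_log2fc)
  )
  sim <- stage("simulate_region_counts", simulate_region_counts(
    genes = genes, n_per_region = config$n_per_region, de = de_plan,
    dispersion = config$dispersion, seed = config$seed
  ))
  say("counts: %d genes, %d planted DE (%d inside signature %s)",
      length(genes), nrow(de_plan), length(planted_sig),
      config$planted_signature)

  # --- differential expression ------------------------------------------
  filtered <- stage("filter_counts", filter_counts(
    sim$counts, config$min_count, config$min_samples
  ))
  say("filter: %d of %d genes retained (>= %d counts in >= %d samples)",
      nrow(filtered), nrow(sim$counts), config$min_count, config$min_samples)
  sf <- stage("estimate_size_factors", estimate_size_factors(filtered))
  de_cc <- stage("test_differential_expression",
                 test_differential_expression(filtered, "CC", "Bulk",
                                              size_factors = sf))
  de_st <- stage("test_differential_expression",
                 test_differential_expression(filtered, "ST", "Bulk",
                                              size_factors = sf))
  say("DE: CC vs Bulk %d regulated; ST vs Bulk %d regulated",
      glance(de_cc, config$alpha_select, config$lfc_min)$n_regulated,
      glance(de_st, config$alpha_select, config$lfc_min)$n_regulated)

  clusters <- stage("select_and_cluster", select_and_cluster(
    de_cc, de_st, lfc_min = config$lfc_min, alpha = config$alpha_select,
    k = config$k_de, seed = config$seed
  ))
  say("clusters: %d selected genes in %d clusters", nrow(clusters), config$k_de)

  enrichment <- stage("enrich", enrich(
    clusters, signatures, universe = filtered$gene,
    correction = config$correction
  ))
  top <- glance(enrichment)
  say("enrichment: top cell (%s, %s)", top$top_group, top$top_signature)

  regulation_cc <- stage("signature_regulation_summary",
                         signature_regulation_summary(de_cc, signatures,
                                                      config$alpha_signature))
  pca <- stage("pca_samples", pca_samples(filtered, size_factors = sf))

  # --- outputs -----------------------------------------------------------
  paths <- list(
    atlas = file.path(out_dir, "atlas.tsv"),
    counts = file.path(out_dir, "counts.tsv"),
    signatures = file.path(out_dir, "signatures.gmt"),
    de_cc = file.path(out_dir, "de_cc_vs_bulk.tsv"),
    de_st = file.path(out_dir, "de_st_vs_bulk.tsv"),
    clusters = file.path(out_dir, "clusters.tsv"),
    enrichment = file.path(out_dir, "enrichment.tsv"),
    regulation_cc = file.path(out_dir, "signature_regulation_cc.tsv"),
    pca = file.path(out_dir, "pca.tsv"),
    config = file.path(out_dir, "config.json"),
    log = file.path(out_dir, "log.txt")
  )
  write_expression_tsv(atlas$expression, paths$atlas)
  write_expression_tsv(sim$counts, paths$counts)
  write_gmt(signatures, paths$signatures)
  readr::write_tsv(tibble::as_tibble(de_cc), paths$de_cc, progress = FALSE)
  readr::write_tsv(tibble::as_tibble(de_st), paths$de_st, progress = FALSE)
  readr::write_tsv(clusters, paths$clusters, progress = FALSE)
  readr::write_tsv(tibble::as_tibble(enrichment), paths$enrichment,
                   progress = FALSE)
  readr::write_tsv(regulation_cc, paths$regulation_cc, progress = FALSE)
  readr::write_tsv(tibble::as_tibble(pca), paths$pca, progress = FALSE)
  jsonlite::write_json(c(unclass(config), list(config_hash = config_hash(config))),
                       paths$config, auto_unbox = TRUE, digits = NA, null = "null")
  readr::write_lines(log_lines, paths$log)

  hashes <- tools::md5sum(unlist(paths))
  names(hashes) <- names(paths)

  invisible(list(
    atlas = atlas, signatures = signatures, counts = sim$counts,
    filtered = filtered, de_cc = de_cc, de_st = de_st,
    clusters = clusters, enrichment = enrichment,
    regulation_cc = regulation_cc, pca = pca,
    truth = list(atlas = atlas$truth, de = sim$truth$de,
                 planted_signature_genes = planted_sig),
    files = paths, hashes = hashes
  ))
}
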
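#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its documented default. Unknown keys
#' are rejected by [validate_config()], and the configuration serializes
#' losslessly through JSON ([write_config()] / [read_config()]).
#'
#' Sections: `simulate` (synthetic-study generation; disable and fill
#' `inputs` to run on real tables), `inputs` (file paths), `calling` (SNV
#' depth/frequency thresholds), `clustering` (trajectory clustering),
#' `deconvolution` (restarts and maximum strain count), `enrichment`
#' (burden normalization, sidedness, multiplicity), `chemistry_constants`
#' (ammonia pKa parameterization), `diversity` (Chao1 pseudo-depth,
#' Shannon log base).
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    simulate = list(
      enabled = TRUE, n_strains = 3L, n_timepoints = 8L,
      sweep_pattern = "serial_replacement", n_sites = 100L, n_genes = 10L,
      gene_length = 900L, gc_fraction = 0.5, target_nonsyn_fraction = 0.5,
      mean_depth = 50, noise_sd = 0, dispersion = 0, error_rate = 0,
      min_hamming = 2L
    ),
    inputs = list(
      pileup = NULL, dialect = "tsv_pileup", sample_order = NULL,
      fasta = NULL, gff3 = NULL, translation_table = "11",
      coverage = NULL, chemistry = NULL, pathway_map = NULL, mag_ra = NULL
    ),
    calling = list(min_depth = 5, min_freq = 0.05),
    clustering = list(linkage = "average", distance = "correlation",
                      cut_threshold = 0.25, min_cluster_size = 2L),
    deconvolution = list(s_max = 5L, n_restarts = 20L),
    enrichment = list(per_kb = TRUE, alternative = "greater",
                      p_adjust = "none"),
    chemistry_constants = list(pka_a = 0.09018, pka_b = 2729.92),
    diversity = list(pseudo_depth = 1000, log_base = "e")
  )
}

#' Validate a pipeline configuration
#'
#' Checks the configuration against [default_config()]: unknown keys are
#' rejected, missing keys filled with defaults.
#'
#' @param config Nested list.
#' @return The completed configuration.
#' @export
validate_config <- function(config) {
  merge_checked <- function(user, def, path = "") {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown)) {
      stopf("unknown configuration key(s): %s",
            paste0(path, unknown, collapse = ", "))
    }
    out <- def
    for (k in names(user)) {
      if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
        out[[k]] <- merge_checked(user[[k]] %||% list(), def[[k]],
                                  paste0(path, k, "."))
      } else {
        out[k] <- user[k]
      }
    }
    out
  }
  merge_checked(config %||% list(), default_config())
}

#' @rdname default_config
#' @param config Configuration list.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE,
                                      simplifyMatrix = FALSE))
}

#' Run the full strain-resolution pipeline
#'
#' Executes the stage sequence call-annotate -> cluster -> deconvolve ->
#' selection -> community on simulated or file-based inputs, writing each
#' stage's tables to `config$outdir` and a JSON run manifest (tool version,
#' configuration hash, input checksums, per-stage timings and record
#' counts) at the end. A stage failure halts downstream stages; completed
#' outputs are left in place together with an error manifest.
#'
#' All randomness derives from `config$seed`; identical configuration and
#' inputs produce byte-identical stage outputs.
#'
#' @param config Configuration (see [default_config()]); `outdir` must be
#'   set.
#' @return Invisibly, the manifest list (with `results` attached in-memory:
#'   snvs, clustering, model, pnps, enrichment, community).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  if (is.null(config$outdir)) stopf("config$outdir must be set")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)

  manifest <- list(
    tool = "strainsweep",
    version = as.character(packageVersion("strainsweep")),
    config = config,
    config_hash = config_hash(config),
    inputs = list(),
    stages = list()
  )
  results <- list()
  t_all <- proc.time()[["elapsed"]]

  record_stage <- function(name, t0, counts) {
    manifest$stages[[name]] <<- c(
      list(elapsed_s = round(proc.time()[["elapsed"]] - t0, 3)), counts)
  }
  fail <- function(name, e) {
    manifest$error <<- list(stage = name, message = conditionMessage(e))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE, force = TRUE)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  }

  # ---- inputs / simulate ----
  t0 <- proc.time()[["elapsed"]]
  stage <- "inputs"
  res <- tryCatch({
    if (isTRUE(config$simulate$enabled)) {
      sim <- config$simulate
      study <- simulate_study(
        n_strains = sim$n_strains, n_timepoints = sim$n_timepoints,
        sweep_pattern = sim$sweep_pattern, n_sites = sim$n_sites,
        n_genes = sim$n_genes, gene_length = sim$gene_length,
        gc_fraction = sim$gc_fraction,
        target_nonsyn_fraction = sim$target_nonsyn_fraction,
        mean_depth = sim$mean_depth, noise_sd = sim$noise_sd,
        dispersion = sim$dispersion, error_rate = sim$error_rate,
        min_hamming = sim$min_hamming, seed = config$seed)
      write_genome(study$genome, out("genome.fasta"), out("genes.gff3"))
      write_pileup_tsv(study$pileup, out("pileup.tsv"))
      write_matrix_tsv(study$truth$genotypes, out("truth_genotypes.tsv"), "site")
      write_matrix_tsv(study$truth$abundances, out("truth_abundances.tsv"), "strain")
      list(pileup = study$pileup, genome = study$genome, truth = study$truth)
    } else {
      inp <- config$inputs
      if (is.null(inp$fasta) || is.null(inp$gff3)) {
        stopf("inputs$fasta and inputs$gff3 are required when simulation is disabled")
      }
      genome <- read_genome(inp$fasta, inp$gff3, inp$translation_table)
      if (is.null(inp$pileup)) stopf("inputs$pileup is required")
      pileup <- read_variant_table(inp$pileup, inp$dialect, inp$sample_order)
      for (f in c(inp$pileup, inp$fasta, inp$gff3, inp$coverage,
                  inp$chemistry, inp$pathway_map)) {
        manifest$inputs[[basename(f)]] <- unname(tools::md5sum(f))
      }
      list(pileup = pileup, genome = genome, truth = NULL)
    }
  }, error = function(e) fail(stage, e))
  record_stage(stage, t0, list(n_sites = nrow(res$pileup$total_counts)))

  # ---- call-annotate ----
  t0 <- proc.time()[["elapsed"]]
  stage <- "call_annotate"
  snvs <- tryCatch({
    called <- call_snvs(res$pileup, config$calling$min_depth,
                        config$calling$min_freq)
    ann <- annotate_effect(called, res$genome)
    write_snv_table(ann, out("snv_table.tsv"), out("snv_table_wide.tsv"))
    ann
  }, error = function(e) fail(stage, e))
  record_stage(stage, t0, list(n_called = nrow(snvs$records)))

  # ---- cluster ----
  t0 <- proc.time()[["elapsed"]]
  stage <- "cluster"
  clustering <- tryCatch({
    f <- frequency_matrix(snvs)
    cl <- cluster_trajectories(
      f, linkage = config$clustering$linkage,
      distance = config$clustering$distance,
      cut_threshold = config$clustering$cut_threshold,
      min_cluster_size = config$clustering$min_cluster_size)
    write_tsv(data.frame(snv = names(cl$assignment),
                         cluster = cl$assignment, row.names = NULL),
              out("cluster_assignments.tsv"))
    if (nrow(cl$mean_profiles)) {
      write_matrix_tsv(cl$mean_profiles, out("cluster_mean_profiles.tsv"),
                       "cluster")
    }
    cl
  }, error = function(e) fail(stage, e))
  record_stage(stage, t0, list(n_clusters = length(clustering$clusters)))

  # ---- deconvolve ----
  t0 <- proc.time()[["elapsed"]]
  stage <- "deconvolve"
  model <- tryCatch({
    f <- frequency_matrix(snvs)
    w <- snvs$total
    rownames(w) <- rownames(f)
    m <- select_strain_number(
      f, weights = w, s_max = config$deconvolution$s_max,
      n_restarts = config$deconvolution$n_restarts,
      seed = derive_seed(config$seed, "pipeline", "deconv"),
      init_profiles = clustering$mean_profiles)
    write_matrix_tsv(m$genotypes, out("genotypes.tsv"), "site")
    write_matrix_tsv(m$abundances, out("abundances.tsv"), "strain")
    write_tsv(m$score_path, out("score_path.tsv"))
    if (!is.null(config$inputs$mag_ra) && !isTRUE(config$simulate$enabled)) {
      mag_ra <- read_tsv(config$inputs$mag_ra)
      wA <- weight_by_mag_abundance(m, mag_ra$ra)
      write_matrix_tsv(wA, out("weighted_abundances.tsv"), "strain")
    }
    m
  }, error = function(e) fail(stage, e))
  record_stage(stage, t0, list(n_strains = model$n_strains))

  # ---- selection ----
  t0 <- proc.time()[["elapsed"]]
  stage <- "selection"
  sel <- tryCatch({
    pnps <- pnps_table(snvs, res$genome)
    pnps$selected <- pnps$gene_id %in% flag_selected(pnps)
    write_tsv(pnps, out("pnps.tsv"))
    enr <- NULL
    if (!is.null(config$inputs$pathway_map)) {
      pm <- read_pathway_map(config$inputs$pathway_map)
      burden <- nsnv_burden(snvs, res$genome,
                            per_kb = isTRUE(config$enrichment$per_kb))
      enr <- enrichment_table(burden, pm,
                              p_adjust = config$enrichment$p_adjust,
                              alternative = config$enrichment$alternative)
      if (!is.null(enr)) write_tsv(enr, out("enrichment.tsv"))
    }
    list(pnps = pnps, enrichment = enr)
  }, error = function(e) fail(stage, e))
  record_stage(stage, t0, list(n_genes = nrow(sel$pnps)))

  # ---- community ----
  t0 <- proc.time()[["elapsed"]]
  stage <- "community"
  comm <- tryCatch({
    outc <- list()
    if (!is.null(config$inputs$coverage)) {
      cov <- read_coverage_tsv(config$inputs$coverage)
      ra <- relative_abundance(cov)
      write_matrix_tsv(ra, out("relative_abundance.tsv"), "mag")
      base <- if (identical(config$diversity$log_base, "e")) exp(1)
      else as.numeric(config$diversity$log_base)
      div <- diversity_table(ra, depth = config$diversity$pseudo_depth,
                             base = base)
      write_tsv(div, out("diversity.tsv"))
      outc$ra <- ra
      outc$diversity <- div
    }
    if (!is.null(config$inputs$chemistry)) {
      chem <- read_chemistry_csv(config$inputs$chemistry)
      chem <- chemistry_with_fan(chem,
                                 a = config$chemistry_constants$pka_a,
                                 b = config$chemistry_constants$pka_b)
      write_tsv(chem, out("chemistry_fan.tsv"))
      outc$chemistry <- chem
    }
    outc
  }, error = function(e) fail(stage, e))
  record_stage(stage, t0, list(n_tables = length(comm)))

  manifest$total_elapsed_s <- round(proc.time()[["elapsed"]] - t_all, 3)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE, force = TRUE)
  results <- list(snvs = snvs, clustering = clustering, model = model,
                  pnps = sel$pnps, enrichment = sel$enrichment,
                  community = comm)
  manifest$results <- results
  invisible(manifest)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Domain composition report
#'
#' Per-domain MAG counts and percentages (half-up rounding to two
#' decimals), e.g. the bacterial/archaeal split of a genome catalogue.
#'
#' @param taxonomy Named character vector (names = MAG ids, values =
#'   domain labels) or data.frame with columns `mag`, `domain`.
#' @return data.frame: domain, n, percent (sorted by count, descending).
#' @examples
#' summarize_taxonomy(c(rep("Bacteria", 172), rep("Archaea", 7)))
#' @export
summarize_taxonomy <- function(taxonomy) {
  labels <- if (is.data.frame(taxonomy)) {
    if (!all(c("mag", "domain") %in% names(taxonomy))) {
      stopf("taxonomy data.frame needs columns `mag` and `domain`")
    }
    setNames(taxonomy$domain, taxonomy$mag)
  } else taxonomy
  if (any(is.na(labels) | labels == "")) {
    bad <- which(is.na(labels) | labels == "")[1]
    stopf("unlabeled MAG: %s", names(labels)[bad] %||% bad)
  }
  tb <- sort(table(labels), decreasing = TRUE)
  data.frame(
    domain = names(tb),
    n = as.integer(tb),
    percent = round_half_up(100 * as.integer(tb) / sum(tb), 2),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
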
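# End-to-end orchestration: simulate -> load -> discover -> map -> profile
# -> markers, with deterministic seeding and a machine-readable run report.

#' Pipeline configuration
#'
#' Collects every path and parameter of [run_pipeline()]. Either a
#' [synthetic_config()] (`simulate`) or the four input paths
#' (`sample_sheet`, `data_dir`, `antigen_fasta`, `epitope_csv`) must be
#' supplied. Unknown arguments are errors.
#'
#' @param out_dir Output directory.
#' @param simulate Optional [synthetic_config()]; when given, the cohort,
#'   antigens and linear epitope table are generated and written under
#'   `out_dir/cohort` first.
#' @param sample_sheet,data_dir,antigen_fasta,epitope_csv Input paths (used
#'   when `simulate` is `NULL`).
#' @param discovery A [discovery_params()] object.
#' @param top_n Top-peptide list size for CSI (default 2500).
#' @param top_k Immunodominant epitope count per patient (default 50).
#' @param cap_percentile Z-score cap percentile (default 97.5).
#' @param min_sens,min_spec Marker performance floors (defaults 0.72, 0.67).
#' @param n_markers Maximum markers kept (default 15).
#' @param max_subset Maximum combined-model subset size (default 3).
#' @param seed Master seed; every stochastic stage derives a named
#'   sub-stream from it.
#' @param n_antigens,antigen_length Synthetic antigen parameters (simulate
#'   mode).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, simulate = NULL, sample_sheet = NULL,
                       data_dir = NULL, antigen_fasta = NULL,
                       epitope_csv = NULL, discovery = discovery_params(),
                       top_n = 2500L, top_k = 50L, cap_percentile = 97.5,
                       min_sens = 0.72, min_spec = 0.67, n_markers = 15L,
                       max_subset = 3L, seed = 1L, n_antigens = 8L,
                       antigen_length = 300L) {
  if (is.null(simulate) &&
      (is.null(sample_sheet) || is.null(data_dir) ||
       is.null(antigen_fasta) || is.null(epitope_csv)))
    stop_("supply either `simulate` or all four input paths")
  if (!is.null(simulate)) stopifnot(inherits(simulate, "synthetic_config"))
  stopifnot(inherits(discovery, "discovery_params"),
            top_n >= 1, top_k >= 1, cap_percentile > 0, cap_percentile <= 100,
            min_sens >= 0, min_sens <= 1, min_spec >= 0, min_spec <= 1,
            n_markers >= 1, max_subset >= 1)
  structure(list(out_dir = out_dir, simulate = simulate,
                 sample_sheet = sample_sheet, data_dir = data_dir,
                 antigen_fasta = antigen_fasta, epitope_csv = epitope_csv,
                 discovery = discovery, top_n = as.integer(top_n),
                 top_k = as.integer(top_k), cap_percentile = cap_percentile,
                 min_sens = min_sens, min_spec = min_spec,
                 n_markers = as.integer(n_markers),
                 max_subset = as.integer(max_subset), seed = as.integer(seed),
                 n_antigens = as.integer(n_antigens),
                 antigen_length = as.integer(antigen_length)),
            class = "run_config")
}

pipe_log <- function(level, fmt, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), level,
                  sprintf(fmt, ...)))
}

write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- data.frame(rn = rownames(x), as.data.frame(x), check.names = FALSE,
                    stringsAsFactors = FALSE)
    names(x)[1L] <- rownames_as
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate (optional), load, discover, map,
#' profile, markers — writing every intermediate table under
#' `config$out_dir` and a machine-readable `report.json` recording
#' parameters, seed, input digests and per-stage record counts. Paired
#' samples are compared discriminatively (query vs its paired
#' pre-treatment sample); unpaired treated samples are compared against a
#' randomly generated reference set. Any stage failure aborts with the
#' stage name and leaves a `FAILED` marker file next to the partial
#' outputs.
#'
#' @param config A [run_config()].
#' @return The run report (list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out, "FAILED"))
  report <- list(schema_version = "1.0",
                 package_version = as.character(utils::packageVersion("epitopescan")),
                 seed = config$seed,
                 parameters = list(
                   discovery = unclass(config$discovery),
                   top_n = config$top_n, top_k = config$top_k,
                   cap_percentile = config$cap_percentile,
                   min_sens = config$min_sens, min_spec = config$min_spec,
                   n_markers = config$n_markers,
                   max_subset = config$max_subset,
                   abundance_log_offset = 1),
                 stages = list())
  stage <- function(name, code) {
    pipe_log("INFO", "stage %s", name)
    tryCatch(code, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  ## stage 1: simulate (optional)
  paths <- config[c("sample_sheet", "data_dir", "antigen_fasta",
                    "epitope_csv")]
  if (!is.null(config$simulate)) {
    stage("simulate", {
      sim <- generate_cohort(config$simulate)
      ant <- generate_antigens(config$simulate, n_antigens = config$n_antigens,
                               length = config$antigen_length,
                               seed = seed_stream(config$seed, "antigens"))
      cdir <- file.path(out, "cohort")
      write_cohort(sim, cdir, antigens = ant)
      # linear epitope table: the embedded regions of the antigens
      epi <- data.frame(epitope_sequence = substring(
                          ant$antigens$sequence[match(ant$truth$accession,
                                                      ant$antigens$accession)],
                          ant$truth$start,
                          ant$truth$start + nchar(ant$truth$pattern) - 1L),
                        parent_accession = ant$truth$accession,
                        parent_name = "synthetic",
                        stringsAsFactors = FALSE)
      utils::write.csv(epi, file.path(cdir, "linear_epitopes.csv"),
                       row.names = FALSE, quote = FALSE)
      paths <- list(sample_sheet = file.path(cdir, "samples.csv"),
                     data_dir = cdir,
                     antigen_fasta = file.path(cdir, "antigens.fasta"),
                     epitope_csv = file.path(cdir, "linear_epitopes.csv"))
      report$stages$simulate <- list(samples = nrow(sim$cohort$meta),
                                      antigens = nrow(ant$antigens),
                                      planted_motifs = nrow(sim$truth$motifs))
    })
  }
  report$inputs <- lapply(paths[c("sample_sheet", "antigen_fasta",
                                  "epitope_csv")], function(p)
    list(file = basename(p), md5 = unname(tools::md5sum(p))))

  ## stage 2: load
  co <- stage("load", load_cohort(paths$sample_sheet, paths$data_dir))
  report$stages$load <- list(samples = nrow(co$meta),
                             groups = as.list(table(co$meta$group)))

  ## stage 3: discover
  disc <- stage("discover", {
    meta <- co$meta
    vac <- list()   # paired, discriminative: post vs pre
    mel <- list()   # unpaired treated, vs random reference
    for (i in which(meta$group == "MelVac" & !nzchar(meta$competition_of))) {
      pre_id <- meta$paired_with[i]
      if (!nzchar(pre_id)) next
      res <- discover(co$repertoires[[meta$sample_id[i]]],
                      co$repertoires[[pre_id]],
                      params = config$discovery, mode = "discriminative")
      vac[[meta$sample_id[i]]] <- reduce_to_core(
        res, co$repertoires[[meta$sample_id[i]]])
    }
    for (i in which(meta$group == "PEM-Mel")) {
      q <- co$repertoires[[meta$sample_id[i]]]
      ref <- generate_random_reference(
        length(q$counts), freqs = NULL,
        seed = seed_stream(config$seed, paste0("ref_", meta$sample_id[i])))
      res <- discover(q, ref, params = config$discovery, mode = "vs_random")
      mel[[meta$sample_id[i]]] <- reduce_to_core(res, q)
    }
    vac_all <- if (length(vac)) do.call(rbind, c(vac, make.row.names = FALSE))
               else NULL
    mel_all <- if (length(mel)) do.call(rbind, c(mel, make.row.names = FALSE))
               else NULL
    if (!is.null(vac_all))
      write_enrichment(vac_all, file.path(out, "epitopes_vaccination.tsv"))
    if (!is.null(mel_all))
      write_enrichment(mel_all, file.path(out, "epitopes_melanoma.tsv"))
    list(per_sample_vac = vac, per_sample_mel = mel,
         vac_patterns = unique(vac_all$pattern %||% character(0)),
         mel_patterns = unique(mel_all$pattern %||% character(0)))
  })
  report$stages$discover <- list(
    vaccination_epitopes = length(disc$vac_patterns),
    melanoma_epitopes = length(disc$mel_patterns))

  ## stage 4: map
  map <- stage("map", {
    antigens <- read_antigen_fasta(paths$antigen_fasta)
    epitopes <- read_linear_epitopes(paths$epitope_csv)
    hit_vac <- match_patterns_to_linear_epitopes(disc$vac_patterns, epitopes)
    hit_mel <- match_patterns_to_linear_epitopes(disc$mel_patterns, epitopes)
    recruited <- recruit_antigens(hit_mel$parent_accession,
                                  hit_vac$parent_accession)
    hits <- align_patterns_to_antigens(
      unique(c(disc$vac_patterns, disc$mel_patterns)),
      antigens[antigens$accession %in% recruited, , drop = FALSE])
    write_tsv(hits, file.path(out, "antigen_hits.tsv"))
    scores <- antigen_score_matrix(hits, co)
    write_tsv(scores, file.path(out, "antigen_scores.tsv"),
              rownames_as = "accession")
    list(recruited = recruited, hits = hits,
         antigen_patterns = unique(hits$pattern))
  })
  report$stages$map <- list(recruited_antigens = length(map$recruited),
                            alignment_hits = nrow(map$hits),
                            antigen_associated_epitopes =
                              length(map$antigen_patterns))

  ## stage 5: profile
  prof <- stage("profile", {
    csi <- csi_matrix(co, n = config$top_n)
    write_tsv(csi, file.path(out, "csi.tsv"), rownames_as = "sample_id")
    n_z <- 0L
    for (id in names(disc$per_sample_vac)) {
      res <- disc$per_sample_vac[[id]]
      if (!nrow(res)) next
      meta_i <- co$meta[co$meta$sample_id == id, ]
      pre_id <- meta_i$paired_with
      top <- top_k_epitopes(res$pattern, co$repertoires[[id]],
                            k = config$top_k)
      sub <- build_abundance_matrix(
        top$pattern, cohort(co$repertoires[c(pre_id, id)],
                            co$meta[co$meta$sample_id %in% c(pre_id, id), ]))
      if (stats::sd(as.vector(sub)) > 0) {
        z <- zscore_map(sub, cap_percentile = config$cap_percentile)
        write_tsv(z, file.path(out, sprintf("zscores_%s.tsv",
                                            meta_i$subject_id)),
                  rownames_as = "pattern")
        n_z <- n_z + 1L
      }
    }
    # pre/post abundance ratios of antigen-associated epitopes
    ratios <- list()
    for (id in names(disc$per_sample_vac)) {
      meta_i <- co$meta[co$meta$sample_id == id, ]
      pre_id <- meta_i$paired_with
      for (p in map$antigen_patterns) {
        post_ab <- pattern_abundance(p, co$repertoires[[id]])
        pre_ab <- pattern_abundance(p, co$repertoires[[pre_id]])
        ratios[[length(ratios) + 1L]] <- data.frame(
          marker = p, subject = meta_i$subject_id,
          log10_ratio = abundance_ratio(post_ab, pre_ab),
          stringsAsFactors = FALSE)
      }
    }
    ratios <- if (length(ratios)) do.call(rbind, ratios)
              else data.frame(marker = character(0), subject = character(0),
                              log10_ratio = numeric(0))
    write_tsv(ratios, file.path(out, "abundance_ratios.tsv"))
    # competition relative abundance, when competition samples exist
    comp_rows <- list()
    for (i in which(nzchar(co$meta$competition_of))) {
      parent <- co$meta$competition_of[i]
      for (p in map$antigen_patterns) {
        un <- pattern_abundance(p, co$repertoires[[parent]])
        if (un <= 0) next
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          marker = p, sample_id = co$meta$sample_id[i],
          relative_abundance = competition_relative_abundance(
            pattern_abundance(p, co$repertoires[[co$meta$sample_id[i]]]), un),
          stringsAsFactors = FALSE)
      }
    }
    if (length(comp_rows))
      write_tsv(do.call(rbind, comp_rows),
                file.path(out, "competition_relative_abundance.tsv"))
    list(csi_pairs = sum(upper.tri(csi)), zscore_maps = n_z,
         ratios = nrow(ratios), competition_rows = length(comp_rows))
  })
  report$stages$profile <- prof

  ## stage 6: markers
  mk <- stage("markers", {
    meta <- co$meta
    use <- (meta$group %in% c("MelVac", "PEM-Mel", "CTRL-Mel", "CTRL-NSCLC")) &
      !nzchar(meta$competition_of)
    labels <- meta$group[use] %in% c("MelVac", "PEM-Mel")
    sub <- subset_cohort(co, meta$sample_id[use])
    if (!length(map$antigen_patterns))
      stop_("no antigen-associated epitopes to rank")
    mat <- build_abundance_matrix(map$antigen_patterns, sub)
    markers <- rank_markers(mat, labels, min_sens = config$min_sens,
                            min_spec = config$min_spec, k = config$n_markers)
    write_tsv(markers, file.path(out, "markers.tsv"))
    model <- NULL
    if (nrow(markers) >= 1) {
      feats <- t(log10(mat[markers$pattern, , drop = FALSE] + 1))
      model <- best_subset(feats, labels, candidates = markers$pattern,
                           max_size = config$max_subset)
      model_json <- list(markers = model$subset,
                         coefficients = as.list(model$coefficients),
                         auc = model$auc, sensitivity = model$sensitivity,
                         specificity = model$specificity,
                         converged = model$converged,
                         transform = "log10(x+1)",
                         cross_validation = "none: apparent performance only",
                         warnings = model$warnings)
      jsonlite::write_json(model_json, file.path(out, "model.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(markers = markers, model = model)
  })
  report$stages$markers <- list(
    markers_passing_floors = nrow(mk$markers),
    model_markers = if (!is.null(mk$model)) length(mk$model$subset) else 0L,
    model_auc = if (!is.null(mk$model)) mk$model$auc else NA)

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipe_log("INFO", "pipeline complete: %s", out)
  invisible(report)
}
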
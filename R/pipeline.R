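# pipeline: configuration, end-to-end run, and artifact writing.

#' Pipeline configuration
#'
#' One flat document of every tunable threshold in the pipeline; unknown
#' arguments are rejected. Defaults follow the standard EST-comparison
#' settings: 800-nt prefix and 100-nt minimum for cleaning, 50-nt/95 %
#' clustering overlaps, 96 % identity / 1e-10 E-value / 33-column HSP
#' filters for matching, 5-nt slop and 23-nt minimum for large-indel
#' topology, 10-nt flank windows.
#'
#' @param max_prefix_len,min_len,adapters Cleaning (see [clean_sequences()]).
#' @param min_overlap,min_overlap_identity Clustering (see
#'   [cluster_unigenes()]).
#' @param min_identity,max_evalue,min_hsp_len,prefilter Matching (see
#'   [match_sets()]).
#' @param slop,min_large,flank_width Variant calling (see
#'   [detect_large_indels()]).
#' @param flank_window,max_motif,min_motif Classification (see
#'   [classify_indels()]).
#' @param scoring Alignment scoring scheme ([alignment_scoring()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(max_prefix_len = 800L, min_len = 100L,
                            adapters = character(),
                            min_overlap = 50L, min_overlap_identity = 0.95,
                            min_identity = 0.96, max_evalue = 1e-10,
                            min_hsp_len = 33L, prefilter = TRUE,
                            slop = 5L, min_large = 23L, flank_width = 10L,
                            flank_window = 10L, max_motif = 51L,
                            min_motif = 1L,
                            scoring = alignment_scoring()) {
  cfg <- list(max_prefix_len = max_prefix_len, min_len = min_len,
              adapters = adapters, min_overlap = min_overlap,
              min_overlap_identity = min_overlap_identity,
              min_identity = min_identity, max_evalue = max_evalue,
              min_hsp_len = min_hsp_len, prefilter = prefilter, slop = slop,
              min_large = min_large, flank_width = flank_width,
              flank_window = flank_window, max_motif = max_motif,
              min_motif = min_motif, scoring = scoring)
  structure(cfg, class = "pipeline_config")
}

# Build a pipeline_config from a plain list (e.g. parsed YAML), rejecting
# unknown keys.
as_pipeline_config <- function(x) {
  if (inherits(x, "pipeline_config")) return(x)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(x$scoring)) x$scoring <- do.call(alignment_scoring, x$scoring)
  do.call(pipeline_config, x)
}

#' Run the full comparison pipeline
#'
#' Chains clean, cluster, match, variant calling, statistics and large-indel
#' classification over two sequence libraries. Library A provides the
#' queries, library B the subjects, so insertions are sequence present in A
#' and absent in B.
#'
#' @param lib_a,lib_b Sequence tables (e.g. from [read_fasta()] or
#'   [simulate_pair()]).
#' @param config A [pipeline_config()].
#' @return A list of class `est_pipeline`: cleaning results (`clean_a`,
#'   `clean_b`), unigene sets (`unigenes_a`, `unigenes_b`), `match`,
#'   `variants`, `summary` (a `polymorphism_summary`), `spectrum_small`,
#'   `spectrum_large`, `flanks`, `classes`, `config`.
#' @export
run_pipeline <- function(lib_a, lib_b, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  clean_a <- clean_sequences(lib_a, config$max_prefix_len, config$min_len,
                             config$adapters)
  clean_b <- clean_sequences(lib_b, config$max_prefix_len, config$min_len,
                             config$adapters)
  uni_a <- cluster_unigenes(clean_a$kept, config$min_overlap,
                            config$min_overlap_identity)
  uni_b <- cluster_unigenes(clean_b$kept, config$min_overlap,
                            config$min_overlap_identity)
  match <- match_sets(uni_a$unigenes, uni_b$unigenes,
                      min_identity = config$min_identity,
                      max_evalue = config$max_evalue,
                      min_hsp_len = config$min_hsp_len,
                      scoring = config$scoring,
                      max_gap_run = config$min_large,
                      prefilter = config$prefilter)
  variants <- call_variants(match, slop = config$slop,
                            min_large = config$min_large,
                            flank_width = config$flank_width)
  summary <- if (match$summary$matched_columns > 0)
    summarize_polymorphism(variants, match) else NULL
  classes <- classify_indels(
    variants %>% filter(!is.na(.data$size_class),
                        .data$size_class == "large"),
    match, flank_window = config$flank_window,
    max_motif = config$max_motif, min_motif = config$min_motif)
  structure(list(
    clean_a = clean_a, clean_b = clean_b,
    unigenes_a = uni_a, unigenes_b = uni_b,
    match = match, variants = variants, summary = summary,
    spectrum_small = ratio_spectrum(variants, "small"),
    spectrum_large = ratio_spectrum(variants, "large"),
    flanks = flank_profile(variants, config$flank_width),
    classes = classes, config = config
  ), class = "est_pipeline")
}

#' @export
glance.est_pipeline <- function(x, ...) {
  bind_cols(
    glance(x$match),
    if (!is.null(x$summary)) glance(x$summary) %>%
      select(-"matched_length") else NULL
  )
}

#' @export
print.est_pipeline <- function(x, ...) {
  cat("<est_pipeline>\n")
  print(x$match)
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Emits the stage TSVs (cleaning reports, unigene membership, match table,
#' variant table, classification, per-length and per-pattern tables), a JSON
#' bundle of summary statistics, and a manifest with input descriptions, the
#' effective config and its hash, and row counts.
#'
#' @param result An `est_pipeline`.
#' @param outdir Output directory (created if needed).
#' @param inputs Optional named character vector describing the inputs,
#'   echoed into the manifest.
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, outdir, inputs = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(outdir, f)
  readr::write_tsv(result$clean_a$report, pth("cleaning_report_a.tsv"))
  readr::write_tsv(result$clean_b$report, pth("cleaning_report_b.tsv"))
  readr::write_tsv(result$unigenes_a$members, pth("members_a.tsv"))
  readr::write_tsv(result$unigenes_b$members, pth("members_b.tsv"))
  write_fasta(result$unigenes_a$unigenes, pth("unigenes_a.fasta"))
  write_fasta(result$unigenes_b$unigenes, pth("unigenes_b.fasta"))
  write_match_tsv(result$match, pth("match.tsv"))
  write_variants_tsv(result$variants, pth("variants.tsv"))
  readr::write_tsv(result$classes, pth("large_indel_classes.tsv"))
  if (!is.null(result$summary)) {
    readr::write_tsv(result$summary$per_pattern, pth("snp_patterns.tsv"))
    readr::write_tsv(result$summary$per_length, pth("indel_lengths.tsv"))
  }
  readr::write_tsv(tidy(result$flanks), pth("flank_profile.tsv"))
  stats_bundle <- list(
    match = as.list(glance(result$match)),
    polymorphism = if (!is.null(result$summary))
      as.list(glance(result$summary)) else NULL,
    spectrum_small = as.list(glance(result$spectrum_small)),
    spectrum_large = as.list(glance(result$spectrum_large)),
    mechanism = if (nrow(result$classes) > 0)
      mechanism_summary(result$classes) else NULL
  )
  jsonlite::write_json(stats_bundle, pth("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  cfg <- unclass(result$config)
  manifest <- list(
    package = "estpoly",
    version = as.character(utils::packageVersion("estpoly")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(inputs),
    config = cfg,
    config_hash = rlang::hash(cfg),
    counts = list(
      input_a = nrow(result$clean_a$report),
      input_b = nrow(result$clean_b$report),
      kept_a = nrow(result$clean_a$kept),
      kept_b = nrow(result$clean_b$kept),
      unigenes_a = nrow(result$unigenes_a$unigenes),
      unigenes_b = nrow(result$unigenes_b$unigenes),
      matched = result$match$summary$matched_unigene_count,
      hsps = nrow(result$match$hsps),
      variants = nrow(result$variants),
      large_indels = nrow(result$classes)
    )
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(outdir)
}
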
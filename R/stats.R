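# stats: per-1000-nt polymorphism frequencies, indel spectra, flanking-GC
# profiles and per-functional-category summaries.

all_snp_patterns <- function() {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(subject_base = bases, query_base = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$subject_base != grid$query_base, ]
  tibble(
    pattern = paste0(grid$subject_base, "->", grid$query_base),
    cls = ifelse(paste0(pmin(grid$subject_base, grid$query_base),
                        pmax(grid$subject_base, grid$query_base)) %in%
                   c("AG", "CT"), "transition", "transversion")
  ) %>% arrange(desc(.data$cls == "transition"), .data$pattern)
}

# Core counting shared by summarize_polymorphism() and functional_bins().
poly_counts <- function(variants, matched_length) {
  snps <- variants %>% filter(.data$type == "SNP")
  small <- variants %>%
    filter(.data$type %in% c("INS", "DEL"), .data$size_class == "small")
  per_kb <- function(n) 1000 * n / matched_length
  tibble(
    matched_length = matched_length,
    snp_total = nrow(snps),
    transitions = sum(snps$cls == "transition"),
    transversions = sum(snps$cls == "transversion"),
    small_insertions = sum(small$type == "INS"),
    small_deletions = sum(small$type == "DEL"),
    small_indels = nrow(small),
    snp_per_kb = per_kb(nrow(snps)),
    transition_per_kb = per_kb(sum(snps$cls == "transition")),
    transversion_per_kb = per_kb(sum(snps$cls == "transversion")),
    insertion_per_kb = per_kb(sum(small$type == "INS")),
    deletion_per_kb = per_kb(sum(small$type == "DEL")),
    indel_per_kb = per_kb(nrow(small))
  )
}

#' Summarise polymorphism between two matched libraries
#'
#' Counts SNPs and small indels and converts them to per-1000-nt frequencies.
#' The denominator is the total number of alignment columns of qualifying
#' HSPs over the retained best-hit pairs (gap columns included, consistent
#' with the identity definition). Only small indels enter the indel
#' frequencies; large indels are tabulated by the spectrum and classification
#' functions.
#'
#' @param variants Variant tibble from [call_variants()].
#' @param match The `est_match` object the variants were derived from, used
#'   for the matched-length denominator. Alternatively pass `matched_length`
#'   directly.
#' @param matched_length Denominator in alignment columns (overrides
#'   `match`).
#' @return An object of class `polymorphism_summary`. `glance()` gives the
#'   one-row count/frequency summary; `tidy()` the 12-pattern SNP table and
#'   per-length (1-10 nt) small-indel table in long form.
#' @export
summarize_polymorphism <- function(variants, match = NULL,
                                   matched_length = NULL) {
  if (is.null(matched_length)) {
    if (is.null(match)) abort("supply `match` or `matched_length`")
    matched_length <- match$summary$matched_columns
  }
  if (is.null(matched_length) || matched_length <= 0) {
    abort("matched_length is zero: no qualifying matched regions")
  }
  snps <- variants %>% filter(.data$type == "SNP")
  per_pattern <- all_snp_patterns() %>%
    left_join(count(snps, .data$pattern), by = "pattern") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L),
           per_kb = 1000 * .data$n / matched_length)
  small <- variants %>%
    filter(.data$type %in% c("INS", "DEL"), .data$size_class == "small")
  per_length <- tibble(length = 1:10) %>%
    left_join(small %>% filter(.data$length <= 10) %>%
                count(.data$length, .data$type) %>%
                tidyr::pivot_wider(names_from = "type", values_from = "n"),
              by = "length")
  for (col in c("INS", "DEL")) {
    if (!col %in% names(per_length)) per_length[[col]] <- NA_integer_
  }
  per_length <- per_length %>%
    mutate(n_ins = dplyr::coalesce(.data$INS, 0L),
           n_del = dplyr::coalesce(.data$DEL, 0L),
           n = .data$n_ins + .data$n_del,
           per_kb = 1000 * .data$n / matched_length) %>%
    select("length", "n_ins", "n_del", "n", "per_kb")
  structure(list(
    totals = poly_counts(variants, matched_length),
    per_pattern = per_pattern,
    per_length = per_length,
    matched_length = matched_length
  ), class = "polymorphism_summary")
}

#' @export
glance.polymorphism_summary <- function(x, ...) x$totals

#' @export
tidy.polymorphism_summary <- function(x, ...) {
  bind_rows(
    x$per_pattern %>%
      mutate(statistic = paste0("snp_", .data$pattern), group = .data$cls) %>%
      select("statistic", "group", "n", "per_kb"),
    x$per_length %>%
      mutate(statistic = paste0("indel_len_", .data$length),
             group = "small_indel") %>%
      select("statistic", "group", "n", "per_kb")
  )
}

#' @export
print.polymorphism_summary <- function(x, ...) {
  t <- x$totals
  cat(sprintf(paste0(
    "<polymorphism_summary> %d columns matched\n",
    "  SNPs: %d (%.3f/kb; transitions %.3f, transversions %.3f)\n",
    "  small indels: %d (%.3f/kb; insertions %.3f, deletions %.3f)\n"),
    t$matched_length, t$snp_total, t$snp_per_kb, t$transition_per_kb,
    t$transversion_per_kb, t$small_indels, t$indel_per_kb,
    t$insertion_per_kb, t$deletion_per_kb))
  invisible(x)
}

#' Insertion/deletion ratio spectrum
#'
#' Bins indels by length, computes the insertion:deletion count ratio per
#' bin, and the Pearson correlation between bin length and ratio. Bins with
#' zero deletions have an undefined ratio and are excluded from the
#' correlation. With fewer than three defined bins the correlation is
#' undefined (`NA`); with zero variance among ratios it is reported as 0 and
#' flagged.
#'
#' @param variants Variant tibble.
#' @param size_class `"small"` or `"large"`.
#' @param bins For `"small"`, an integer vector of lengths (default 1:10);
#'   for `"large"`, a list of `c(lo, hi)` ranges (default 23-70, 71-200,
#'   >200). A range with `Inf` upper edge uses its lower edge as the
#'   correlation abscissa.
#' @return An object of class `ratio_spectrum`; `tidy()` returns the bin
#'   table, `glance()` the correlation summary (`r_squared`, `direction`,
#'   `n_defined`, `zero_variance`).
#' @export
ratio_spectrum <- function(variants, size_class = c("small", "large"),
                           bins = NULL) {
  size_class <- match.arg(size_class)
  if (is.null(bins)) {
    bins <- if (size_class == "small") 1:10 else
      list(c(23, 70), c(71, 200), c(201, Inf))
  }
  ind <- variants %>%
    filter(.data$type %in% c("INS", "DEL"),
           .data$size_class == !!size_class)
  if (is.list(bins)) {
    bin_tbl <- bind_rows(lapply(bins, function(b) {
      tibble(label = if (is.finite(b[2])) sprintf("%g-%g", b[1], b[2])
             else sprintf(">%g", b[1] - 1),
             lo = b[1], hi = b[2],
             midpoint = if (is.finite(b[2])) mean(b) else b[1])
    }))
  } else {
    bin_tbl <- tibble(label = as.character(bins), lo = bins, hi = bins,
                      midpoint = as.numeric(bins))
  }
  bin_tbl$n_ins <- map_int(seq_len(nrow(bin_tbl)), function(i) {
    sum(ind$type == "INS" & ind$length >= bin_tbl$lo[i] &
          ind$length <= bin_tbl$hi[i])
  })
  bin_tbl$n_del <- map_int(seq_len(nrow(bin_tbl)), function(i) {
    sum(ind$type == "DEL" & ind$length >= bin_tbl$lo[i] &
          ind$length <= bin_tbl$hi[i])
  })
  bin_tbl <- bin_tbl %>%
    mutate(ratio = ifelse(.data$n_del > 0, .data$n_ins / .data$n_del,
                          NA_real_),
           defined = .data$n_del > 0)
  def <- bin_tbl %>% filter(.data$defined)
  zero_var <- FALSE
  if (nrow(def) < 3) {
    r2 <- NA_real_; dir <- NA_real_
  } else if (stats::sd(def$ratio) == 0 || stats::sd(def$midpoint) == 0) {
    r2 <- 0; dir <- 0; zero_var <- TRUE
  } else {
    r <- cor(def$midpoint, def$ratio)
    r2 <- r^2; dir <- sign(r)
  }
  structure(list(bins = bin_tbl, r_squared = r2, direction = dir,
                 n_defined = nrow(def), zero_variance = zero_var,
                 size_class = size_class),
            class = "ratio_spectrum")
}

#' @export
tidy.ratio_spectrum <- function(x, ...) x$bins

#' @export
glance.ratio_spectrum <- function(x, ...) {
  tibble(size_class = x$size_class, r_squared = x$r_squared,
         direction = x$direction, n_defined = x$n_defined,
         zero_variance = x$zero_variance)
}

#' @export
print.ratio_spectrum <- function(x, ...) {
  cat(sprintf("<ratio_spectrum> %s indels, %d bins (%d defined), r2 = %s\n",
              x$size_class, nrow(x$bins), x$n_defined,
              ifelse(is.na(x$r_squared), "NA",
                     sprintf("%.3f (%s)", x$r_squared,
                             ifelse(x$direction < 0, "negative",
                                    "non-negative")))))
  invisible(x)
}

#' GC profile of indel flanking sequence
#'
#' For each of the ten positions on either side of an indel (-10..-1 and
#' 1..10, position -1 and 1 immediately adjacent to the event), the GC
#' fraction across indels carrying a base at that offset, for insertions,
#' deletions and all indels together. Indels with truncated flanks
#' contribute only to the positions they cover; `N` bases are excluded.
#'
#' @param variants Variant tibble (indel rows must carry `flank5`/`flank3`).
#' @param flank_width Positions profiled on each side (default 10).
#' @return An object of class `flank_profile`; `tidy()` gives the long table
#'   (`position`, `category`, `n`, `gc`), `glance()` the per-category
#'   full-flank mean GC.
#' @export
flank_profile <- function(variants, flank_width = 10L) {
  ind <- variants %>%
    filter(.data$type %in% c("INS", "DEL"), !is.na(.data$flank5))
  base_at <- function(flank, k, side) {
    # side 5: position -k is the k-th base counting back from the event
    len <- nchar(flank)
    pos <- if (side == 5) len - k + 1L else k
    b <- substr(flank, pos, pos)
    ifelse(pos >= 1 & pos <= len & b != "N", b, NA_character_)
  }
  rows <- list()
  for (k in seq_len(flank_width)) {
    rows[[length(rows) + 1L]] <- tibble(
      position = -k, type = ind$type, base = base_at(ind$flank5, k, 5))
    rows[[length(rows) + 1L]] <- tibble(
      position = k, type = ind$type, base = base_at(ind$flank3, k, 3))
  }
  long <- bind_rows(rows) %>% filter(!is.na(.data$base))
  per_cat <- long %>%
    mutate(category = if_else(.data$type == "INS", "insertion",
                              "deletion")) %>%
    group_by(.data$position, .data$category) %>%
    summarise(n = n(), gc = mean(.data$base %in% c("G", "C")),
              .groups = "drop")
  all_cat <- long %>%
    group_by(.data$position) %>%
    summarise(n = n(), gc = mean(.data$base %in% c("G", "C")),
              .groups = "drop") %>%
    mutate(category = "all")
  profile <- bind_rows(per_cat, all_cat) %>%
    select("position", "category", "n", "gc") %>%
    arrange(.data$category, .data$position)
  means <- profile %>%
    group_by(.data$category) %>%
    summarise(mean_gc = sum(.data$gc * .data$n) / sum(.data$n),
              n_bases = sum(.data$n), .groups = "drop")
  structure(list(profile = profile, means = means,
                 flank_width = flank_width),
            class = "flank_profile")
}

#' @export
tidy.flank_profile <- function(x, ...) x$profile

#' @export
glance.flank_profile <- function(x, ...) {
  tidyr::pivot_wider(x$means %>% select("category", "mean_gc"),
                     names_from = "category", values_from = "mean_gc",
                     names_prefix = "mean_gc_")
}

#' Per-functional-category polymorphism summaries
#'
#' Restricts the summary to each category of a user-supplied unigene-to-
#' category map (a unigene may carry several categories and is counted in
#' each). Categories whose unigenes have no matched length are emitted with
#' zero counts and flagged, not dropped.
#'
#' @param variants Variant tibble.
#' @param match The `est_match` object.
#' @param category_map Data frame with columns `unigene_id` (query ids) and
#'   `category`.
#' @return Tibble: one row per category with `n_unigenes`, the count and
#'   per-kb columns of [glance.polymorphism_summary()], and
#'   `zero_matched_length`.
#' @export
functional_bins <- function(variants, match, category_map) {
  if (!all(c("unigene_id", "category") %in% names(category_map))) {
    abort("category_map needs columns `unigene_id` and `category`")
  }
  cats <- unique(category_map$category)
  bind_rows(lapply(cats, function(cat) {
    ids <- category_map$unigene_id[category_map$category == cat]
    pairs_sub <- match$pairs %>% filter(.data$query_id %in% ids)
    ml <- sum(pairs_sub$matched_columns)
    vars_sub <- variants %>% filter(.data$query_id %in% ids)
    if (ml == 0) {
      row <- poly_counts(vars_sub[0, ], 1)   # all-zero counts and rates
      row$matched_length <- 0L
    } else {
      row <- poly_counts(vars_sub, ml)
    }
    bind_cols(tibble(category = cat, n_unigenes = length(ids)), row,
              tibble(zero_matched_length = ml == 0))
  }))
}
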
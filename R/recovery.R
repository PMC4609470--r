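# recovery: planted-vs-estimated comparison for simulator-driven validation.

#' Compare planted truth with pipeline estimates
#'
#' Runs the comparison behind simulator-based validation: for each
#' polymorphism statistic, the planted (ground-truth) value from a
#' [simulate_pair()] truth table against the value estimated by a full
#' [run_pipeline()] pass over the simulated libraries. Counts are compared
#' directly; per-kb rates share the pipeline's matched-length denominator so
#' the comparison isolates variant recovery from denominator convention.
#' The boundary-repeat fraction is compared on motifs of at least 3 nt,
#' since shorter motifs arise by chance at rates comparable to their planted
#' frequency.
#'
#' @param sim A `synth_pair` from [simulate_pair()].
#' @param result An `est_pipeline` from [run_pipeline()] on `sim`'s
#'   libraries.
#' @param tolerance Maximum relative error counted as a pass (default 0.1).
#' @return Tibble: `parameter`, `planted`, `estimated`, `relative_error`,
#'   `pass`, plus per-kb columns for the count rows.
#' @export
recovery_report <- function(sim, result, tolerance = 0.1) {
  truth <- sim$truth
  vars <- result$variants
  ml <- result$match$summary$matched_columns
  t_small <- truth %>% filter(.data$size_class == "small")
  t_large <- truth %>% filter(.data$size_class == "large")
  v_small <- vars %>% filter(.data$size_class == "small")
  v_large <- vars %>% filter(.data$size_class == "large")

  planted_repeat <- if (nrow(t_large) > 0)
    mean(t_large$mechanism == "repeat" & t_large$motif_len >= 3,
         na.rm = FALSE) else NA_real_
  est_repeat <- if (!is.null(result$classes) && nrow(result$classes) > 0)
    mean(result$classes$group == "boundary_repeat" &
           result$classes$motif_len >= 3) else NA_real_

  rows <- tibble(
    parameter = c("snp", "transition", "transversion", "small_insertion",
                  "small_deletion", "small_indel", "large_indel",
                  "ins_del_ratio", "boundary_repeat_fraction"),
    planted = c(
      sum(truth$type == "SNP"),
      sum(truth$type == "SNP" & truth$cls == "transition"),
      sum(truth$type == "SNP" & truth$cls == "transversion"),
      sum(t_small$type == "INS"), sum(t_small$type == "DEL"),
      nrow(t_small), nrow(t_large),
      if (sum(t_small$type == "DEL") > 0)
        sum(t_small$type == "INS") / sum(t_small$type == "DEL") else NA_real_,
      planted_repeat),
    estimated = c(
      sum(vars$type == "SNP"),
      sum(vars$type == "SNP" & vars$cls == "transition"),
      sum(vars$type == "SNP" & vars$cls == "transversion"),
      sum(v_small$type == "INS"), sum(v_small$type == "DEL"),
      nrow(v_small), nrow(v_large),
      if (sum(v_small$type == "DEL") > 0)
        sum(v_small$type == "INS") / sum(v_small$type == "DEL") else NA_real_,
      est_repeat)
  )
  is_count <- rows$parameter %in% c("snp", "transition", "transversion",
                                    "small_insertion", "small_deletion",
                                    "small_indel", "large_indel")
  rows$planted_per_kb <- ifelse(is_count, 1000 * rows$planted / ml, NA_real_)
  rows$estimated_per_kb <- ifelse(is_count, 1000 * rows$estimated / ml,
                                  NA_real_)
  rows$relative_error <- ifelse(
    rows$planted == 0,
    ifelse(rows$estimated == 0, 0, NA_real_),
    abs(rows$estimated - rows$planted) / abs(rows$planted))
  rows$pass <- !is.na(rows$relative_error) &
    rows$relative_error <= tolerance
  rows
}
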
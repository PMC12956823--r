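#' Summarize posterior draws
#'
#' One row per parameter: mean, median, central 66% and 95% quantile
#' credible intervals, and positive posterior mass (the fraction of draws
#' greater than zero).
#'
#' @param draws Numeric matrix (draw x parameter, named columns) or vector.
#' @return A data.frame with columns `parameter`, `mean`, `median`,
#'   `ci66_lo`, `ci66_hi`, `ci95_lo`, `ci95_hi`, `ppm`.
#' @export
summarize_posterior <- function(draws) {
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1)
  if (nrow(draws) == 0L) ct_validation_error("no draws to summarize")
  qs <- t(apply(draws, 2, stats::quantile,
                probs = c(0.17, 0.83, 0.025, 0.975), names = FALSE))
  out <- data.frame(
    parameter = colnames(draws) %||% paste0("par", seq_len(ncol(draws))),
    mean = colMeans(draws),
    median = apply(draws, 2, stats::median),
    ci66_lo = qs[, 1], ci66_hi = qs[, 2],
    ci95_lo = qs[, 3], ci95_hi = qs[, 4],
    ppm = colMeans(draws > 0),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

# Append model identifier column and normalize ordering, used by the
# pipeline to build the combined summary table.
summary_with_model <- function(summ, model) {
  cbind(data.frame(model = model, stringsAsFactors = FALSE), summ)
}

write_summary_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
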
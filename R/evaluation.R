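#' Summarize trial records into accuracy and bias tables
#'
#' For every (communality, interfactor correlation, N) scenario, arm and
#' criterion, computes the expected accuracy (proportion of replications
#' retaining exactly the true number of factors) and the expected bias (mean
#' of retained minus true) over `status == "ok"` records. Cells with no valid
#' records are flagged with `NA` rather than silently zeroed.
#'
#' @param records data frame from [run_experiment()] / [run_trial()].
#' @return an object of class `summary_table`: named list over arms, each a
#'   list of two data frames `accuracy` and `bias` (scenario rows by
#'   criterion columns), plus a long-format `long` data frame.
#' @export
summarize_cells <- function(records) {
  if (!nrow(records)) stop("no records to summarize")
  ok <- records[records$status == "ok" & !is.na(records$m_hat), ]
  key <- c("arm", "communality", "theta", "n_obs", "criterion")
  agg_n <- stats::aggregate(cbind(n = rep(1L, nrow(ok))), ok[key], FUN = sum)
  agg_acc <- stats::aggregate(list(accuracy = ok$correct), ok[key], FUN = mean)
  agg_bias <- stats::aggregate(list(bias = ok$bias), ok[key], FUN = mean)
  long <- merge(merge(agg_acc, agg_bias, by = key), agg_n, by = key)

  # planned combinations with no usable records surface as NA rows
  planned <- unique(records[key])
  long <- merge(planned, long, by = key, all.x = TRUE)

  crits <- intersect(all_criteria(), unique(records$criterion))
  arms <- intersect(names(analysis_arms()), unique(records$arm))
  per_arm <- lapply(arms, function(a) {
    sub <- long[long$arm == a, ]
    scen <- unique(sub[c("communality", "theta", "n_obs")])
    scen <- scen[order(scen$communality == "high", scen$theta, scen$n_obs), ]
    wide <- function(value) {
      out <- scen
      for (cr in crits) {
        v <- merge(scen, sub[sub$criterion == cr, ],
                   by = c("communality", "theta", "n_obs"), all.x = TRUE,
                   sort = FALSE)
        out[[cr]] <- v[[value]][match(
          interaction(scen$communality, scen$theta, scen$n_obs),
          interaction(v$communality, v$theta, v$n_obs))]
      }
      rownames(out) <- NULL
      out
    }
    list(accuracy = wide("accuracy"), bias = wide("bias"))
  })
  names(per_arm) <- arms
  structure(c(per_arm, list(long = long)), class = "summary_table")
}

#' Verify the saturated-regression framing of the summaries
#'
#' The study reports expected accuracy and bias as predictions from fully
#' saturated logistic and linear regressions of the correctness dummy and the
#' bias on criterion, sample size, interfactor correlation, communality and
#' arm with all interactions. Being saturated, their fitted values must equal
#' the empirical cell means; this check fits both models and measures the
#' largest deviation (logistic cells with an empirical proportion of exactly
#' 0 or 1 are separated and reported rather than compared).
#'
#' @param records trial records (at least 2 valid replications per cell).
#' @return list with `linear_max_dev`, `logistic_max_dev`,
#'   `n_separated_cells`, `n_cells`, and the fitted models' cell predictions.
#' @export
saturated_fit_check <- function(records) {
  ok <- records[records$status == "ok" & !is.na(records$m_hat), ]
  ok$cellf <- interaction(ok$criterion, ok$n_obs, ok$theta, ok$communality,
                          ok$arm, drop = TRUE)
  counts <- table(ok$cellf)
  if (any(counts < 2))
    stop("cells with fewer than 2 observations: ",
         paste(utils::head(names(counts)[counts < 2]), collapse = ", "))

  fmla <- ~ criterion * factor(n_obs) * factor(theta) * communality * factor(arm)
  X <- stats::model.matrix(fmla, ok)
  means <- tapply(ok$bias, ok$cellf, mean)
  props <- tapply(as.numeric(ok$correct), ok$cellf, mean)

  lin <- stats::lm(ok$bias ~ X - 1)
  lin_pred <- tapply(stats::fitted(lin), ok$cellf, mean)
  linear_max_dev <- max(abs(lin_pred - means))

  logi <- suppressWarnings(stats::glm(ok$correct ~ X - 1, family = stats::binomial()))
  logi_pred <- tapply(stats::fitted(logi), ok$cellf, mean)
  interior <- props > 0 & props < 1
  logistic_max_dev <- if (any(interior))
    max(abs(logi_pred[interior] - props[interior])) else NA_real_

  list(linear_max_dev = linear_max_dev,
       logistic_max_dev = logistic_max_dev,
       n_separated_cells = sum(!interior),
       n_cells = length(props),
       cell_means = means, cell_props = props,
       linear_pred = lin_pred, logistic_pred = logi_pred)
}

#' Export summary tables as CSV files
#'
#' One file per arm and panel (`<prefix><arm-table>A.csv` for accuracy,
#' `...B.csv` for bias), rounded to 2 decimals with fixed formatting, plus an
#' unrounded `_raw` copy of each. Arms map to tables in the order continuous
#' (4), 50-50 Pearson (5), 50-50 tetrachoric (6), 75-25 Pearson (7), 75-25
#' tetrachoric (8).
#'
#' @param summary a [summarize_cells()] result.
#' @param path output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
export_tables <- function(summary, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  table_no <- c(cont_pearson = 4L, d50_pearson = 5L, d50_tetra = 6L,
                d75_pearson = 7L, d75_tetra = 8L)
  files <- character(0)
  for (arm in intersect(names(table_no), names(summary))) {
    for (panel in c(A = "accuracy", B = "bias")) {
      tab <- summary[[arm]][[panel]]
      letter <- names(which(c(A = "accuracy", B = "bias") == panel))
      base <- sprintf("table%d%s", table_no[[arm]], letter)
      raw_file <- file.path(path, paste0(base, "_raw.csv"))
      utils::write.csv(tab, raw_file, row.names = FALSE)
      rounded <- tab
      num <- vapply(rounded, is.numeric, logical(1)) &
        !(names(rounded) %in% c("theta", "n_obs"))
      rounded[num] <- lapply(rounded[num], function(x) sprintf("%.2f", x))
      rounded_file <- file.path(path, paste0(base, ".csv"))
      utils::write.csv(rounded, rounded_file, row.names = FALSE,
                       quote = FALSE)
      files <- c(files, raw_file, rounded_file)
    }
  }
  invisible(files)
}
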
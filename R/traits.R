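#' Read / write the long-format vernalization experiment table
#'
#' Columns: `sample_id`, `duration_weeks`, `replicate`, `days_after_return`
#' (empty when the replicate never flowered), `flowered`.
#'
#' @param path TSV path.
#' @return a `vernalization_response` data.frame.
#' @export
read_vernalization_response <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("sample_id", "duration_weeks", "replicate", "days_after_return",
            "flowered")
  if (!all(need %in% names(df)))
    stop("response table needs columns: ", paste(need, collapse = ", "))
  df$flowered <- as.logical(df$flowered)
  class(df) <- c("vernalization_response", "data.frame")
  df
}

#' @rdname read_vernalization_response
#' @param vr a `vernalization_response` table.
#' @export
write_vernalization_response <- function(vr, path) {
  data.table::fwrite(as.data.frame(vr), path, sep = "\t")
  invisible(path)
}

#' Summarize flowering replicates per accession and treatment duration
#'
#' Means are taken over flowered replicates only. A cell is scored
#' *permissive* (the treatment allowed flowering) iff at least
#' `min_flowered` of its replicates flowered; the default is a strict
#' majority of the replicates present in the cell, so with the standard
#' 3-replicate design two flowered replicates are required.
#'
#' @param vr a `vernalization_response` table.
#' @param min_flowered minimum flowered replicates for a permissive cell, or
#'   NULL for the majority rule.
#' @return data.frame with columns `sample_id`, `duration_weeks`,
#'   `mean_days`, `n_flowered`, `n_total`, `permissive`.
#' @export
summarize_replicates <- function(vr, min_flowered = NULL) {
  dt <- data.table::as.data.table(vr)
  agg <- dt[, list(
    mean_days = if (any(flowered)) mean(days_after_return[flowered]) else NA_real_,
    n_flowered = sum(flowered),
    n_total = .N
  ), by = c("sample_id", "duration_weeks")]
  agg <- as.data.frame(agg)
  thr <- if (is.null(min_flowered)) floor(agg$n_total / 2) + 1L
         else rep_len(min_flowered, nrow(agg))
  agg$permissive <- agg$n_flowered >= thr
  agg[order(match(agg$sample_id, unique(vr$sample_id)), agg$duration_weeks), ,
      drop = FALSE]
}

#' Extract the four flowering-time-related traits
#'
#' From the replicate summaries of a vernalization experiment, derives per
#' accession:
#' * `mtd_weeks` — the minimum threshold duration: the smallest tested
#'   duration whose cell is permissive (left-censored when that is the
#'   smallest tested duration);
#' * `days_after_mtd` — mean post-return days to flower at the MTD;
#' * `saturation_weeks` — the smallest permissive duration `d*` beyond which
#'   no further reduction in days to flower is gained, i.e. all tested
#'   `d >= d*` have mean within `saturation_tol_days` of the mean at `d*`
#'   or above it (right-censored when only the largest duration qualifies);
#' * `days_after_saturation` — days to flower counted from entry into the
#'   cold chamber: `7 * saturation_weeks` plus the mean at saturation.
#'
#' Accessions with no permissive cell are flagged `never_flowered` and carry
#' NA traits; they are excluded from downstream trait analyses.
#'
#' @param vr a `vernalization_response` table.
#' @param saturation_tol_days tolerance in days when reading saturation off
#'   the response curve (default 2, the scoring grid of the assay).
#' @param min_flowered passed to [summarize_replicates()].
#' @return data.frame of class `flowering_traits`: one row per accession with
#'   the four traits and flags `never_flowered`, `mtd_left_censored`,
#'   `saturation_right_censored`.
#' @export
extract_traits <- function(vr, saturation_tol_days = 2, min_flowered = NULL) {
  cells <- summarize_replicates(vr, min_flowered = min_flowered)
  out <- lapply(split(cells, cells$sample_id), function(cc) {
    cc <- cc[order(cc$duration_weeks), , drop = FALSE]
    res <- data.frame(sample_id = cc$sample_id[1L], mtd_weeks = NA_real_,
                      days_after_mtd = NA_real_, saturation_weeks = NA_real_,
                      days_after_saturation = NA_real_, never_flowered = FALSE,
                      mtd_left_censored = FALSE,
                      saturation_right_censored = FALSE)
    perm <- which(cc$permissive)
    if (!length(perm)) {
      res$never_flowered <- TRUE
      return(res)
    }
    i_mtd <- perm[1L]
    res$mtd_weeks <- cc$duration_weeks[i_mtd]
    res$days_after_mtd <- cc$mean_days[i_mtd]
    res$mtd_left_censored <- i_mtd == 1L
    # saturation: left-to-right scan over permissive cells; the first cell
    # from which no tested longer duration improves the mean by more than
    # the tolerance. The last permissive cell always qualifies, so the scan
    # terminates; landing there while the curve was still improving means
    # saturation is right-censored by the design.
    for (i in perm) {
      later <- perm[perm >= i]
      if (all(cc$mean_days[later] >= cc$mean_days[i] - saturation_tol_days)) {
        res$saturation_weeks <- cc$duration_weeks[i]
        res$days_after_saturation <- 7 * cc$duration_weeks[i] + cc$mean_days[i]
        earlier <- perm[perm < i]
        res$saturation_right_censored <- i == perm[length(perm)] &&
          length(earlier) > 0L &&
          any(cc$mean_days[earlier] > cc$mean_days[i] + saturation_tol_days)
        break
      }
    }
    res
  })
  ft <- do.call(rbind, out)
  ft <- ft[match(unique(vr$sample_id), ft$sample_id), , drop = FALSE]
  rownames(ft) <- NULL
  class(ft) <- c("flowering_traits", "data.frame")
  ft
}

#' Pairwise Pearson correlations among the four traits
#'
#' Pairwise-complete Pearson correlations with two-sided t-test p-values.
#' Never-flowered accessions are dropped first. A zero-variance trait yields
#' NA for its pairs, with a warning.
#'
#' @param ft a `flowering_traits` table from [extract_traits()].
#' @return list with matrices `r` and `p` (traits x traits).
#' @export
trait_correlations <- function(ft) {
  ft <- ft[!ft$never_flowered, , drop = FALSE]
  cols <- c("mtd_weeks", "days_after_mtd", "saturation_weeks",
            "days_after_saturation")
  X <- as.matrix(ft[, cols])
  if (nrow(X) < 3) stop("need >= 3 accessions with defined traits")
  k <- length(cols)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  diag(r) <- 1; diag(p) <- 0
  flat <- apply(X, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
  if (any(flat))
    warning("zero variance in trait(s) ", paste(cols[flat], collapse = ", "),
            "; their correlations are undefined")
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    ok <- stats::complete.cases(X[, c(i, j)])
    x <- X[ok, i]; y <- X[ok, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    n <- length(x)
    rr <- stats::cor(x, y)
    tt <- rr * sqrt((n - 2) / (1 - rr^2))
    r[i, j] <- r[j, i] <- rr
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p)
}
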
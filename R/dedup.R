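#' Collapse case versions into one report per case
#'
#' Spontaneous-report databases carry every submitted version of a case;
#' follow-up reports share the `case_id` of the initial report. The
#' screen must count each case once, so for every `case_id` only the row
#' with the greatest `version` is kept (latest-version-wins, the
#' convention of the FDA's published FAERS guidance). Exact duplicates of
#' a (case_id, version) pair keep their first occurrence with a warning.
#' Output rows are sorted by `case_id`, so the result is deterministic,
#' and the operation is idempotent.
#'
#' @param x A [report_set()].
#' @param quiet Suppress the removed-version message.
#' @return A [report_set()] with one report per distinct `case_id`.
#' @export
deduplicate_reports <- function(x, quiet = FALSE) {
  stopifnot(inherits(x, "report_set"))
  r <- x$reports
  if (nrow(r) == 0) return(x)
  dup_pair <- duplicated(r[, c("case_id", "version")])
  if (any(dup_pair)) {
    warning(sum(dup_pair),
            " duplicate (case_id, version) pair(s); keeping first seen",
            call. = FALSE)
    r <- r[!dup_pair, , drop = FALSE]
  }
  # latest version wins within each case
  o <- order(r$case_id, -r$version)
  r <- r[o, , drop = FALSE]
  keep <- r[!duplicated(r$case_id), , drop = FALSE]
  n_removed <- nrow(x$reports) - nrow(keep)
  if (!quiet && n_removed > 0) {
    message(n_removed, " superseded case version(s) removed")
  }
  out <- filter_reports(x, keep$report_id)
  out$reports <- out$reports[order(out$reports$case_id), , drop = FALSE]
  out
}
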
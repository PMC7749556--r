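#' Mean FA of a tract bundle
#'
#' Default reduction pools every stepping point of every streamline in the
#' bundle with equal weight (the per-point FA sampling along fibers makes
#' point-level pooling the natural reduction); `method = "per_streamline"`
#' instead averages each fiber's mean. An empty bundle yields `NA` with a
#' warning rather than an error, so missing tracts propagate as missing
#' cells.
#'
#' @param bundle a `tract_bundle` from [track_parcel()].
#' @param method `"pooled"` (default) or `"per_streamline"`.
#' @return Mean FA in `[0, 1]`, or `NA_real_` for an empty bundle.
#' @export
mean_tract_fa <- function(bundle, method = c("pooled", "per_streamline")) {
  method <- match.arg(method)
  if (length(bundle$streamlines) == 0L) {
    warning(sprintf("bundle '%s' (parcel %s) is empty; mean FA is NA",
                    bundle$name, bundle$parcel))
    return(NA_real_)
  }
  fas <- lapply(bundle$streamlines, `[[`, "fa")
  if (method == "pooled") {
    mean(unlist(fas))
  } else {
    mean(vapply(fas, mean, numeric(1)))
  }
}

#' Assemble the cohort analysis table
#'
#' Builds the subjects x (covariates + cognition + tract mean FA) table
#' that links the imaging and statistics stages: one row per subject, one
#' `fa_<tract>` column per requested tract in the given order. Imaging
#' input per subject is either a list of `tract_bundle`s (reduced with
#' [mean_tract_fa()]) or an already-reduced named numeric vector of tract
#' mean FA. Healthy-control rows must carry (or are checked to carry)
#' illness duration and episode counts of 0, the zero-fill convention for
#' variables undefined in controls.
#'
#' @param subject_fa named list: subject id -> list of `tract_bundle` or
#'   named numeric vector (names = tract names).
#' @param covariates data.frame with columns `subject_id`, `group` (one of
#'   HC / MDD / BD), `age`, `gender`, `duration`, `episodes`, and any
#'   cognition score columns.
#' @param tracts character vector fixing FA column order; defaults to the
#'   union of tract names seen, in first-seen order.
#' @return A `data.frame` of class `cohort_table`.
#' @export
build_cohort_table <- function(subject_fa, covariates, tracts = NULL) {
  ids <- names(subject_fa)
  missing_cov <- setdiff(ids, covariates$subject_id)
  if (length(missing_cov) > 0L) {
    stop_tendtract("missing_covariates",
                   "no covariate record for subject(s): %s",
                   paste(missing_cov, collapse = ", "))
  }
  fa_vectors <- lapply(subject_fa, function(x) {
    if (is.numeric(x)) return(x)
    vals <- vapply(x, mean_tract_fa, numeric(1))
    names(vals) <- vapply(x, `[[`, character(1), "name")
    vals
  })
  if (is.null(tracts)) {
    tracts <- unique(unlist(lapply(fa_vectors, names)))
  }
  fa_mat <- t(vapply(fa_vectors, function(v) {
    out <- rep(NA_real_, length(tracts))
    hit <- match(names(v), tracts)
    out[hit[!is.na(hit)]] <- v[!is.na(hit)]
    out
  }, numeric(length(tracts))))
  colnames(fa_mat) <- paste0("fa_", tracts)

  tab <- covariates[match(ids, covariates$subject_id), , drop = FALSE]
  tab <- cbind(tab, as.data.frame(fa_mat))
  rownames(tab) <- NULL
  as_cohort_table(tab)
}

#' Coerce and validate a cohort table
#'
#' Enforces the table invariants: group labels restricted to HC / MDD /
#' BD, unique subject ids, FA columns within `[0, 1]` (or missing), and
#' zero illness duration / episode counts in every HC row.
#'
#' @param tab a data.frame with the cohort-table columns.
#' @return The table with class `cohort_table` prepended.
#' @export
as_cohort_table <- function(tab) {
  need <- c("subject_id", "group")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop_tendtract("bad_table", "cohort table lacks column(s): %s",
                   paste(miss, collapse = ", "))
  }
  if (!all(tab$group %in% c("HC", "MDD", "BD"))) {
    stop_tendtract("bad_table", "group labels must be HC, MDD or BD")
  }
  if (anyDuplicated(tab$subject_id)) {
    stop_tendtract("bad_table", "duplicate subject ids")
  }
  hc <- tab$group == "HC"
  for (col in intersect(c("duration", "episodes"), names(tab))) {
    if (any(tab[[col]][hc] != 0, na.rm = TRUE)) {
      stop_tendtract("bad_table",
                     "column '%s' must be 0 for every HC row (zero-fill convention)", col)
    }
  }
  fa_cols <- grep("^fa_", names(tab), value = TRUE)
  for (col in fa_cols) {
    v <- tab[[col]]
    if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE)) {
      stop_tendtract("bad_table", "FA column '%s' has values outside [0, 1]", col)
    }
  }
  class(tab) <- unique(c("cohort_table", class(tab)))
  tab
}

#' Read / write a cohort table as CSV
#'
#' Plain CSV with a header row; the round trip is lossless for all
#' columns (numeric columns are written at full precision).
#'
#' @param tab a `cohort_table`.
#' @param path file path.
#' @return `read_cohort` returns a `cohort_table`; `write_cohort` returns
#'   the path invisibly.
#' @export
write_cohort <- function(tab, path) {
  out <- as.data.frame(tab)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), NA, formatC(v, format = "g", digits = 17))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character"))
  as_cohort_table(tab)
}
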
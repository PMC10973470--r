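# Container for right-censored survival data with optional covariates.

#' Construct a survival dataset
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param covariates Optional numeric matrix, samples x features, with
#'   column names.
#' @param sample_ids Optional sample identifiers (defaults to covariate
#'   rownames or 1..n).
#' @return An object of class `survival_data`.
#' @export
survival_data <- function(time, event, covariates = NULL,
                          sample_ids = NULL) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != length(event)) {
    stop("`time` and `event` must have the same length", call. = FALSE)
  }
  if (!all(is.finite(time)) || any(time <= 0)) {
    stop("all times must be positive and finite", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) {
    stop("`event` must be binary 0/1", call. = FALSE)
  }
  n <- length(time)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.numeric(covariates) || nrow(covariates) != n) {
      stop("`covariates` must be a numeric matrix with one row per sample",
           call. = FALSE)
    }
    if (!all(is.finite(covariates))) {
      stop("covariates must be finite", call. = FALSE)
    }
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
    }
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(covariates) %||% as.character(seq_len(n))
  }
  structure(
    list(time = time, event = as.integer(event), x = covariates,
         sample_ids = as.character(sample_ids)),
    class = "survival_data"
  )
}

as_survival_data <- function(data) {
  if (inherits(data, "survival_data")) return(data)
  if (is.data.frame(data) && all(c("time", "event") %in% names(data))) {
    extra <- setdiff(names(data), c("time", "event", "sample_id"))
    x <- if (length(extra)) as.matrix(data[extra]) else NULL
    ids <- if ("sample_id" %in% names(data)) data$sample_id else NULL
    return(survival_data(data$time, data$event, x, ids))
  }
  stop("expected a `survival_data` object or a data frame with ",
       "`time` and `event` columns", call. = FALSE)
}

#' @export
print.survival_data <- function(x, ...) {
  cat(sprintf("survival_data: %d samples, %d events, %d covariate(s)\n",
              length(x$time), sum(x$event),
              if (is.null(x$x)) 0L else ncol(x$x)))
  invisible(x)
}

subset_survival <- function(d, idx) {
  survival_data(d$time[idx], d$event[idx],
                if (is.null(d$x)) NULL else d$x[idx, , drop = FALSE],
                d$sample_ids[idx])
}
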
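#' Event-history tables for recurrent-event analysis
#'
#' An `event_history` is a long-format counting-process table with one row
#' per (subject, event number): the canonical representation used by every
#' model in the package. Each row records the at-risk interval
#' `(start, stop]` for the subject's `k`-th event, the event indicator
#' `status` (1 = the k-th event was observed, 0 = censored), the randomized
#' arm `treatment` (1 = experimental, 0 = control) and any baseline
#' covariates. Two time scales are supported: `"gap"` (the clock restarts
#' at each event, so every `start` is 0) and `"counting_process"` (calendar
#' time since randomization, so each `start` equals the subject's previous
#' `stop`).
#'
#' Structural invariants enforced by the constructor:
#' * `stop > start` on every row;
#' * within a subject, event numbers run 1..m with no gaps and no
#'   duplicates;
#' * a row with `k > 1` exists only if the subject's row `k - 1` has
#'   `status = 1` (only subjects with `k - 1` events are at risk for the
#'   k-th);
#' * `treatment` and baseline covariates are constant within subject.
#'
#' @param data A data.frame with columns `id`, `k`, `start`, `stop`,
#'   `status`, `treatment`; any further numeric columns are treated as
#'   baseline covariates.
#' @param time_scale `"auto"` (default), `"gap"` or `"counting_process"`.
#'   With `"auto"` the scale is inferred: all `start` equal to 0 means gap
#'   time, otherwise counting process (and the start/stop chaining is
#'   checked).
#' @param covariates Optional character vector naming the covariate
#'   columns; defaults to every column not among the six required ones.
#' @param validate Check the structural invariants (default TRUE).
#'   Internal callers that construct tables known to be valid skip the
#'   checks.
#'
#' @return An object of class `event_history`: the validated data.frame
#'   (rows ordered by subject then event number) with attributes
#'   `time_scale` and `covariates`.
#' @seealso [read_event_history()], [as_gap_time()],
#'   [as_counting_process()], [risk_set()], [first_event_subset()]
#' @examples
#' h <- event_history(data.frame(
#'   id = c(1, 1, 2), k = c(1, 2, 1),
#'   start = c(0, 3, 0), stop = c(3, 5, 4),
#'   status = c(1, 0, 0), treatment = c(1, 1, 0)
#' ))
#' max_stratum(h)
#' @export
event_history <- function(data, time_scale = c("auto", "gap", "counting_process"),
                          covariates = NULL, validate = TRUE) {
  time_scale <- match.arg(time_scale)
  required <- c("id", "k", "start", "stop", "status", "treatment")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("event_history: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), required)
  } else {
    bad <- setdiff(covariates, names(data))
    if (length(bad) > 0) {
      stop("event_history: covariate column(s) not found: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  data <- data[order(data$id, data$k), , drop = FALSE]
  rownames(data) <- NULL

  if (validate) {
    for (cl in c("k", "start", "stop", "status", "treatment", covariates)) {
      if (!is.numeric(data[[cl]])) {
        stop("event_history: column '", cl, "' must be numeric",
             call. = FALSE)
      }
      if (anyNA(data[[cl]])) {
        stop("event_history: column '", cl, "' contains missing values",
             call. = FALSE)
      }
    }
    if (!all(data$status %in% c(0, 1))) {
      stop("event_history: status must be 0 or 1", call. = FALSE)
    }
    if (!all(data$treatment %in% c(0, 1))) {
      stop("event_history: treatment must be 0 or 1", call. = FALSE)
    }
    if (any(data$stop <= data$start)) {
      stop("event_history: every interval must satisfy stop > start (",
           sum(data$stop <= data$start), " violating row(s))",
           call. = FALSE)
    }
    # vectorized within-subject checks on the (id, k)-sorted table:
    # `first`/`last` mark subject block boundaries
    first <- !duplicated(data$id)
    last <- !duplicated(data$id, fromLast = TRUE)
    prev <- c(NA, seq_len(nrow(data) - 1L))
    if (any(data$k[first] != 1)) {
      stop("event_history: subject ",
           data$id[first][which(data$k[first] != 1)[1]],
           " has no k = 1 row (event numbers must run 1..m with no gaps)",
           call. = FALSE)
    }
    cont <- !first & data$k != data$k[prev] + 1
    if (any(cont, na.rm = TRUE)) {
      stop("event_history: subject ", data$id[which(cont)[1]],
           " has a gap or duplicate in its event numbers", call. = FALSE)
    }
    if (any(data$status[!last] != 1)) {
      stop("event_history: subject ",
           data$id[!last][which(data$status[!last] != 1)[1]],
           " has a row k > 1 following a censored (status 0) row",
           call. = FALSE)
    }
    for (cl in c("treatment", covariates)) {
      varies <- !first & data[[cl]] != data[[cl]][prev]
      if (any(varies, na.rm = TRUE)) {
        stop("event_history: column '", cl, "' varies within subject ",
             data$id[which(varies)[1]],
             "; baseline variables must be constant", call. = FALSE)
      }
    }
  }

  if (time_scale == "auto") {
    time_scale <- if (all(data$start == 0)) "gap" else "counting_process"
  }
  if (validate) {
    if (time_scale == "gap" && any(data$start != 0)) {
      stop("event_history: gap time scale requires start = 0 on every row",
           call. = FALSE)
    }
    if (time_scale == "counting_process") {
      first <- !duplicated(data$id)
      prev <- c(NA, seq_len(nrow(data) - 1L))
      expected <- ifelse(first, 0, data$stop[prev])
      if (any(abs(data$start - expected) > 1e-8)) {
        stop("event_history: counting-process scale requires each start to ",
             "equal the subject's previous stop (subject ",
             data$id[which(abs(data$start - expected) > 1e-8)[1]], ")",
             call. = FALSE)
      }
    }
  }

  structure(data,
            time_scale = time_scale,
            covariates = covariates,
            class = c("event_history", "data.frame"))
}

#' @export
print.event_history <- function(x, ...) {
  cat("Event history:", n_subjects(x), "subjects,", nrow(x), "at-risk intervals,",
      sum(x$status), "events, K =", max_stratum(x),
      paste0("(", attr(x, "time_scale"), " scale)\n"))
  if (length(attr(x, "covariates")) > 0) {
    cat("Baseline covariates:", paste(attr(x, "covariates"), collapse = ", "), "\n")
  }
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' @rdname event_history
#' @param h An `event_history` object.
#' @export
n_subjects <- function(h) length(unique(h$id))

#' @rdname event_history
#' @export
max_stratum <- function(h) as.integer(max(h$k))

#' Covariate columns of an event history
#'
#' @param h An `event_history`.
#' @return Character vector of baseline covariate column names.
#' @export
covariate_names <- function(h) attr(h, "covariates")

#' Read a long-format event-history table from delimited text
#'
#' Expects a header row; the canonical dialect is
#' `id,k,start,stop,status,treatment,x1..xP` with times as decimals and
#' `status`/`treatment` coded 0/1. Other column names can be mapped onto
#' the canonical ones via `column_map`.
#'
#' @param path Path to a delimited text file.
#' @param column_map Optional named character vector mapping canonical
#'   names to the names used in the file, e.g.
#'   `c(id = "subject", k = "enum")`.
#' @param sep Field separator (default comma).
#' @inheritParams event_history
#' @return An [event_history()].
#' @export
read_event_history <- function(path, column_map = NULL, sep = ",",
                               time_scale = "auto", covariates = NULL) {
  if (!file.exists(path)) {
    stop("read_event_history: file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, sep = sep, check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        stop("read_event_history: mapped column '", src, "' not in file",
             call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  event_history(raw, time_scale = time_scale, covariates = covariates)
}

#' Write an event history to CSV in the canonical dialect
#'
#' @param h An `event_history`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_event_history <- function(h, path) {
  utils::write.csv(as.data.frame(h), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert between gap-time and counting-process risk intervals
#'
#' The two PWP formulations differ only in the risk interval: the
#' counting-process variant measures time from randomization
#' (`h0k(t)`), the gap-time variant restarts the clock at each event
#' (`h0k(t - t_{k-1})`). Conversion preserves durations and statuses, so
#' `as_counting_process(as_gap_time(h))` is the identity.
#'
#' @param h An `event_history`.
#' @return An `event_history` on the requested scale.
#' @export
as_gap_time <- function(h) {
  if (attr(h, "time_scale") == "gap") return(h)
  out <- as.data.frame(h)
  gap <- out$stop - out$start
  out$start <- 0
  out$stop <- gap
  event_history(out, time_scale = "gap", covariates = covariate_names(h),
                validate = FALSE)
}

#' @rdname as_gap_time
#' @export
as_counting_process <- function(h) {
  if (attr(h, "time_scale") == "counting_process") return(h)
  out <- as.data.frame(h)
  gap <- out$stop - out$start
  out <- out[order(out$id, out$k), , drop = FALSE]
  cum <- stats::ave(gap[order(out$id, out$k)], out$id, FUN = cumsum)
  out$stop <- cum
  out$start <- cum - gap
  event_history(out, time_scale = "counting_process",
                covariates = covariate_names(h), validate = FALSE)
}

#' Risk set for the k-th event
#'
#' The k-th risk set contains the subjects eligible to experience the k-th
#' event: all randomized subjects for k = 1, and only those whose (k-1)-th
#' event was observed for k > 1. It is this conditioning on prior events
#' that breaks randomization in later strata and motivates the
#' entropy-balancing weights.
#'
#' @param h An `event_history`.
#' @param k Stratum (event number), `1 <= k <= max_stratum(h)`.
#' @return A list with elements `k`, `member_ids`, `n`, `n_treated`,
#'   `n_control`.
#' @export
risk_set <- function(h, k) {
  K <- max_stratum(h)
  if (length(k) != 1 || k < 1 || k > K || k != round(k)) {
    stop("risk_set: k must be a single integer in 1..", K, call. = FALSE)
  }
  rows <- h$k == k
  ids <- h$id[rows]
  trt <- h$treatment[rows]
  list(k = as.integer(k),
       member_ids = ids,
       n = length(ids),
       n_treated = sum(trt == 1),
       n_control = sum(trt == 0))
}

#' Restrict an event history to first events
#'
#' Keeps only the k = 1 rows, i.e. the data a time-to-first-event Cox
#' analysis uses.
#'
#' @param h An `event_history`.
#' @return An `event_history` with `max_stratum` 1.
#' @export
first_event_subset <- function(h) {
  out <- as.data.frame(h)[h$k == 1, , drop = FALSE]
  event_history(out, time_scale = attr(h, "time_scale"),
                covariates = covariate_names(h), validate = FALSE)
}

#' The bladder tumour recurrence trial
#'
#' Loads the vendored copy of the Veterans Administration study of
#' chemoprophylaxis for recurrent stage I bladder tumours, restricted to
#' the thiotepa and placebo arms: 85 patients (38 thiotepa, 47 placebo)
#' followed for up to 64 months, 132 tumour recurrences in total. Baseline
#' covariates are `number` (count of initial tumours) and `size` (size of
#' the largest initial tumour, cm). The fixture was derived from the
#' `bladder1` data shipped with the survival package: all recurrences are
#' retained (not just the first four), deaths are treated as censoring for
#' recurrence, and the single patient with zero follow-up is dropped.
#'
#' @return An `event_history` on the counting-process scale with
#'   covariates `number` and `size`.
#' @examples
#' h <- bladder_recurrences()
#' n_subjects(h)  # 85
#' sum(h$status)  # 132
#' @export
bladder_recurrences <- function() {
  path <- system.file("extdata", "bladder.csv", package = "repwp")
  if (!nzchar(path)) {
    stop("bladder_recurrences: fixture 'extdata/bladder.csv' not found in ",
         "the installed package", call. = FALSE)
  }
  read_event_history(path, covariates = c("number", "size"))
}
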
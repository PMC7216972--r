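#' Competing-risks data
#'
#' The universal subject-level input: one row per subject with a positive
#' follow-up time, a status code (0 = censored, 1 = cause of interest,
#' 2 = competing cause) and optional covariate columns.  `crdata()` builds
#' the object from vectors; [as_crdata()] converts an existing data frame,
#' optionally remapping column names and status codes.
#'
#' @param time positive follow-up times.
#' @param status integer status codes in `{0, 1, 2}`.
#' @param ... named covariate vectors (numeric or factor), each of the same
#'   length as `time`.
#' @return A data frame of class `"crdata"` with columns `time`, `status`
#'   and the covariates.
#' @examples
#' crdata(time = c(1, 2, 3, 4), status = c(1, 2, 1, 1), x = c(0, 0, 1, 1))
#' @export
crdata <- function(time, status, ...) {
  cov <- list(...)
  d <- data.frame(time = as.numeric(time), status = as.integer(status))
  for (nm in names(cov)) d[[nm]] <- cov[[nm]]
  as_crdata(d)
}

#' Convert a data frame to competing-risks data
#'
#' @param data a data frame.
#' @param time,status names of the time and status columns in `data`.
#' @param status_map optional named vector mapping the codes found in the
#'   status column onto the internal 0/1/2 convention, e.g.
#'   `c(alive = 0, relapse = 1, death = 2)`.
#' @return A validated `"crdata"` data frame (time and status renamed to the
#'   internal convention, covariates untouched).
#' @export
as_crdata <- function(data, time = "time", status = "status",
                      status_map = NULL) {
  stopifnot(is.data.frame(data))
  for (col in c(time, status))
    if (!col %in% names(data))
      stop(sprintf("column '%s' not found in the data", col))
  d <- data
  names(d)[match(c(time, status), names(d))] <- c("time", "status")
  if (!is.null(status_map)) {
    key <- as.character(d$status)
    bad <- !key %in% names(status_map)
    if (any(bad))
      stop(sprintf("unmapped status code(s) %s in row(s) %s",
                   paste(unique(key[bad]), collapse = ", "),
                   paste(utils::head(which(bad), 5), collapse = ", ")))
    d$status <- as.integer(status_map[key])
  }
  d$time <- as.numeric(d$time)
  d$status <- as.integer(d$status)
  if (anyNA(d$time) || any(d$time <= 0))
    stop("all follow-up times must be positive and non-missing")
  bad <- !d$status %in% c(0L, 1L, 2L)
  if (any(bad))
    stop(sprintf("status codes must be 0, 1 or 2; offending row(s): %s",
                 paste(utils::head(which(bad), 5), collapse = ", ")))
  class(d) <- c("crdata", "data.frame")
  d
}

#' @export
print.crdata <- function(x, ...) {
  cat(sprintf("Competing-risks data: %d subjects (%d cause 1, %d cause 2, %d censored)\n",
              nrow(x), sum(x$status == 1), sum(x$status == 2),
              sum(x$status == 0)))
  NextMethod()
}

# TRUE if any two event (status != 0) times coincide
has_event_ties <- function(data) {
  et <- data$time[data$status != 0]
  anyDuplicated(et) > 0
}

stop_if_ties <- function(data, caller) {
  if (has_event_ties(data))
    stop(sprintf("%s requires tie-free event times; run break_ties() first",
                 caller), call. = FALSE)
  invisible(data)
}

#' Break tied event times by seeded jitter
#'
#' The estimators in this package assume no two events (status 1 or 2) share
#' a time.  `break_ties()` perturbs tied event times by a reproducible,
#' seeded jitter smaller than half the smallest gap between distinct
#' observed times, so the ordering relative to all non-tied observations is
#' preserved.  Censored records are left untouched.
#'
#' @param data a [crdata()] object.
#' @param seed integer seed making the jitter reproducible.
#' @return The data with pairwise-distinct event times.
#' @export
break_ties <- function(data, seed = 1L) {
  stopifnot(inherits(data, "crdata"))
  if (!has_event_ties(data)) return(data)
  ut <- sort(unique(data$time))
  eps <- if (length(ut) > 1) min(diff(ut)) / 2 else min(ut) / 2
  out <- data
  # jitter under a local RNG scope so callers' streams are unaffected
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  is_event <- data$status != 0
  dup_times <- unique(data$time[is_event][duplicated(data$time[is_event])])
  for (tt in dup_times) {
    idx <- which(is_event & data$time == tt)
    out$time[idx] <- tt + stats::runif(length(idx), 0, eps)
  }
  # astronomically unlikely, but keep the guarantee
  while (has_event_ties(out)) {
    et <- out$time[out$status != 0]
    tt <- et[duplicated(et)][1]
    idx <- which(out$status != 0 & out$time == tt)
    out$time[idx] <- tt + stats::runif(length(idx), 0, eps / 2)
  }
  out
}

# exchange the roles of causes 1 and 2 (analyses of the competing cause)
swap_causes <- function(data) {
  stopifnot(inherits(data, "crdata"))
  s <- data$status
  data$status <- ifelse(s == 1L, 2L, ifelse(s == 2L, 1L, 0L))
  data
}

#' Read and write competing-risks data as CSV
#'
#' Comma-separated, header row, UTF-8.  `read_crdata()` applies an optional
#' column map and status recoding via [as_crdata()]; `write_crdata()` writes
#' the canonical columns so that a read of a write round-trips.
#'
#' @param path CSV file path.
#' @param time,status,status_map see [as_crdata()].
#' @return `read_crdata()`: a `"crdata"` object.
#' @export
read_crdata <- function(path, time = "time", status = "status",
                        status_map = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_crdata(d, time = time, status = status, status_map = status_map)
}

#' @rdname read_crdata
#' @param data a [crdata()] object.
#' @export
write_crdata <- function(data, path) {
  stopifnot(inherits(data, "crdata"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
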
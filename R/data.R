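# Event-table I/O (NONMEM-style dialect) and the internal fitting container.
#
# Dialect: one CSV row per event. EVID 1 rows are dose events carrying RATE
# (ug/h): a new dose row supersedes the active infusion rate from its TIME
# on; a zero-rate dose row stops the infusion. EVID 0 rows are observations
# carrying DV (ng/mL) unless MDV == 1. TIME is in hours relative to the
# subject's first dose. Covariates (WT, AGE, SEX, SOFA, INOTR, DUR, ...)
# are pretreatment values, constant within subject.

EVENT_COLS <- c("ID", "TIME", "EVID", "AMT", "RATE", "DV", "MDV")

#' Read a NONMEM-style event table
#'
#' Parses and validates a rectangular CSV event table (see the package
#' README for the dialect). Validation failures are reported with row
#' numbers and abort the read.
#'
#' @param path CSV file path; lines starting with `#` are ignored.
#' @return a validated data frame of class `event_table`.
#' @seealso [write_event_table()], [as_poppk_data()]
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  as_event_table(df)
}

#' @rdname read_event_table
#' @param df a data frame in the event-table layout.
#' @export
as_event_table <- function(df) {
  need <- c("ID", "TIME", "EVID")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_invalid("missing required columns: ", paste(miss, collapse = ", "))
  if (is.null(df$DV)) df$DV <- rep(NA_real_, nrow(df))
  if (is.null(df$MDV)) df$MDV <- ifelse(df$EVID != 0 | is.na(df$DV), 1L, 0L)
  if (is.null(df$AMT)) df$AMT <- rep(NA_real_, nrow(df))
  if (is.null(df$RATE)) df$RATE <- rep(NA_real_, nrow(df))
  rows <- function(i) paste(which(i), collapse = ", ")
  if (any(bad <- !df$EVID %in% c(0L, 1L)))
    stop_invalid("unknown event code at row(s) ", rows(bad))
  if (any(bad <- !is.finite(df$TIME) | df$TIME < 0))
    stop_invalid("negative or missing time at row(s) ", rows(bad))
  for (id in unique(df$ID)) {
    sel <- df$ID == id
    if (is.unsorted(df$TIME[sel]))
      stop_invalid("times not non-decreasing within subject ", id)
    dose <- sel & df$EVID == 1
    if (any(duplicated(df$TIME[dose])))
      stop_invalid("overlapping infusion events (duplicate dose times) for subject ", id)
  }
  if (any(bad <- df$EVID == 1 & (!is.finite(df$RATE) | df$RATE < 0)))
    stop_invalid("dose rows need RATE >= 0 (0 stops the infusion); row(s) ", rows(bad))
  if (any(bad <- df$EVID == 0 & df$MDV == 0 & !is.finite(df$DV)))
    stop_invalid("observation rows need DV unless MDV = 1; row(s) ", rows(bad))
  covs <- setdiff(names(df), EVENT_COLS)
  for (cv in covs) for (id in unique(df$ID)) {
    v <- df[[cv]][df$ID == id]
    if (length(unique(v[!is.na(v)])) > 1)
      stop_invalid("covariate ", cv, " varies within subject ", id,
                   " (pretreatment values must be constant)")
  }
  ord <- c(EVENT_COLS, covs)
  structure(df[, ord], class = c("event_table", "data.frame"))
}

#' Write an event table
#'
#' Writes the canonical column order with fixed decimal formatting and a
#' header comment recording the dialect, so written tables are byte-stable
#' across runs and round-trip losslessly through [read_event_table()].
#'
#' @param table an `event_table` (or coercible data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(table, path) {
  table <- as_event_table(as.data.frame(table))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# dexpoppk event table v1 (EVID1 = infusion-rate event, EVID0 = observation)", con)
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "", formatC(x, format = "g", digits = 12))
    else as.character(x)
  }
  out <- as.data.frame(lapply(table, fmt), stringsAsFactors = FALSE)
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# reconstruct per-subject infusion segments from dose rows
segments_from_doses <- function(time, rate, t_end) {
  if (length(time) == 0) return(infusion_schedule(numeric(0), numeric(0), numeric(0)))
  o <- order(time)
  time <- time[o]; rate <- rate[o]
  start <- time
  end <- c(time[-1], max(t_end, time[length(time)] + 1e-9))
  keep <- rate > 0 & end > start
  infusion_schedule(start[keep], end[keep], rate[keep])
}

#' Assemble the internal fitting container from an event table
#'
#' Splits an event table by subject, reconstructs each subject's
#' piecewise-constant infusion schedule from its dose rows, and collects
#' observation times, concentrations (rows with `MDV == 1` are excluded
#' from fitting) and subject-level covariates.
#'
#' @param x an `event_table`, data frame, or CSV path.
#' @return an object of class `poppk_data`: a list of per-subject records
#'   plus a subject-level covariate data frame.
#' @export
as_poppk_data <- function(x) {
  if (inherits(x, "poppk_data")) return(x)
  if (is.character(x)) x <- read_event_table(x)
  tab <- as_event_table(as.data.frame(x))
  ids <- unique(tab$ID)
  covs <- setdiff(names(tab), EVENT_COLS)
  subjects <- vector("list", length(ids))
  covrows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    d <- tab[tab$ID == ids[i], , drop = FALSE]
    doses <- d[d$EVID == 1, , drop = FALSE]
    obs <- d[d$EVID == 0 & d$MDV == 0, , drop = FALSE]
    sched <- segments_from_doses(doses$TIME, doses$RATE, max(d$TIME))
    subjects[[i]] <- list(
      id = ids[i],
      segs = unclass(sched),
      times = as.numeric(obs$TIME),
      dv = as.numeric(obs$DV),
      covariates = as.list(d[1, covs, drop = FALSE])
    )
    covrows[[i]] <- d[1, covs, drop = FALSE]
  }
  cov_df <- if (length(covs)) do.call(rbind, covrows) else
    as.data.frame(matrix(nrow = length(ids), ncol = 0))
  rownames(cov_df) <- NULL
  structure(list(subjects = subjects, covariates = cov_df, ids = ids,
                 events = tab),
            class = "poppk_data")
}

#' @export
print.poppk_data <- function(x, ...) {
  nobs <- sum(vapply(x$subjects, function(s) length(s$dv), 1L))
  cat(sprintf("poppk_data: %d subjects, %d observations\n",
              length(x$subjects), nobs))
  invisible(x)
}

n_obs <- function(data) sum(vapply(data$subjects, function(s) length(s$dv), 1L))
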
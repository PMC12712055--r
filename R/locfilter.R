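#' Filtering configuration for MINFLUX localization tables
#'
#' Bundles the quality and geometry cutoffs applied to raw MINFLUX
#' localizations before trace centers are computed.
#'
#' @param cfr_max Maximum center frequency ratio; localizations with
#'   `cfr > cfr_max` are discarded as potential multi-emitter events.
#' @param efo_max Maximum effective frequency at offset in kHz. `NULL`
#'   (default) selects a per-dataset cutoff at the 95th percentile of the
#'   observed efo values; a number fixes an absolute cutoff.
#' @param min_locs Minimum number of localizations a trace must have to be
#'   kept (traces with fewer are discarded).
#' @param max_axis_sd Maximum per-axis sample standard deviation in nm; a
#'   trace is discarded if any single axis exceeds this.
#' @param trim_head Number of leading localizations (in time order) removed
#'   from each surviving trace; the first localizations of a DNA-PAINT
#'   binding event are often apart from the rest of the cloud.
#' @param z_scale Scaling factor applied to the z coordinate to correct the
#'   refractive-index mismatch between coverslip and sample.
#'
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(cfr_max = 0.8, efo_max = NULL, min_locs = 3,
                          max_axis_sd = 10, trim_head = 2, z_scale = 0.7) {
  if (!is.null(efo_max)) {
    stopifnot(is.numeric(efo_max), length(efo_max) == 1, is.finite(efo_max),
              efo_max > 0)
  }
  stopifnot(
    is.numeric(cfr_max), length(cfr_max) == 1, is.finite(cfr_max), cfr_max > 0,
    is.numeric(min_locs), length(min_locs) == 1, min_locs >= 1,
    is.numeric(max_axis_sd), length(max_axis_sd) == 1, max_axis_sd > 0,
    is.numeric(trim_head), length(trim_head) == 1, trim_head >= 0,
    is.numeric(z_scale), length(z_scale) == 1, z_scale > 0
  )
  structure(
    list(cfr_max = cfr_max, efo_max = efo_max, min_locs = as.integer(min_locs),
         max_axis_sd = max_axis_sd, trim_head = as.integer(trim_head),
         z_scale = z_scale),
    class = "filter_config"
  )
}

.loc_columns <- c("tid", "x_nm", "y_nm", "z_nm", "cfr", "efo", "t_s")

#' Read a MINFLUX localization table
#'
#' Reads the package CSV dialect: comma separated, UTF-8, '.' decimal,
#' header `tid,x_nm,y_nm,z_nm,cfr,efo,t_s`. One row per localization; row
#' order is preserved.
#'
#' @param path Path to a CSV file.
#' @return A data frame of localizations with the columns above (`tid`
#'   integer, the rest numeric).
#' @export
read_localizations <- function(path) {
  if (!file.exists(path)) {
    stop("localization file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  missing <- setdiff(.loc_columns, names(raw))
  if (length(missing) > 0) {
    stop("localization table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[.loc_columns]
  out <- data.frame(tid = integer(nrow(raw)))
  for (col in .loc_columns) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]) & raw[[col]] != "")
    bad <- union(bad, which(is.na(raw[[col]]) | raw[[col]] == ""))
    if (length(bad) > 0) {
      # +1 for the header line so the message points at the file line
      stop(sprintf("non-numeric value in column '%s' at line(s) %s of %s",
                   col, paste(utils::head(bad + 1L, 5), collapse = ", "),
                   path), call. = FALSE)
    }
    out[[col]] <- if (col == "tid") as.integer(vals) else vals
  }
  out
}

#' Write a localization table in the package CSV dialect
#'
#' @param locs Localization data frame (see [read_localizations()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  stopifnot(all(.loc_columns %in% names(locs)))
  utils::write.csv(locs[.loc_columns], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quality-filter localizations by cfr and efo
#'
#' Keeps localizations with `cfr <= cfr_max` and `efo <= efo_cutoff`, where
#' the efo cutoff is either the configured absolute value or the 95th
#' percentile of the observed efo values. Both filters reject potential
#' multi-emitter contamination. Row order is preserved.
#'
#' @param locs Localization data frame.
#' @param config A [filter_config()].
#' @return The filtered data frame, with attributes `removed_cfr`,
#'   `removed_efo` (counts removed by each criterion) and `efo_cutoff`
#'   (the cutoff actually applied, kHz).
#' @export
filter_quality <- function(locs, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  efo_cutoff <- if (is.null(config$efo_max)) {
    as.numeric(stats::quantile(locs$efo, 0.95, names = FALSE, type = 7))
  } else {
    config$efo_max
  }
  ok_cfr <- locs$cfr <= config$cfr_max
  ok_efo <- locs$efo <= efo_cutoff
  out <- locs[ok_cfr & ok_efo, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_cfr") <- sum(!ok_cfr)
  attr(out, "removed_efo") <- sum(ok_cfr & !ok_efo)
  attr(out, "efo_cutoff") <- efo_cutoff
  out
}

#' Group localizations into emission traces by TID
#'
#' Localizations sharing a trace identification number (TID) originate from
#' the same DNA-PAINT binding event. The result is the same table sorted by
#' `(tid, t_s)` and classed so that downstream per-trace operations apply.
#'
#' @param locs Localization data frame.
#' @return A `trace_table`: the input sorted by TID then time.
#' @export
group_traces <- function(locs) {
  ord <- order(locs$tid, locs$t_s)
  out <- locs[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trace_table", "data.frame")
  out
}

#' Number of distinct traces in a trace table
#' @param traces A `trace_table`.
#' @return Integer count of distinct TIDs.
#' @export
n_traces <- function(traces) length(unique(traces$tid))

# per-trace per-axis stats, vectorized over the whole table
.trace_stats <- function(traces) {
  tid <- traces$tid
  f <- factor(tid, levels = unique(tid))
  n <- as.vector(table(f))
  xyz <- as.matrix(traces[, c("x_nm", "y_nm", "z_nm")])
  sums <- rowsum(xyz, f, reorder = FALSE)
  means <- sums / n
  sq <- rowsum(xyz^2, f, reorder = FALSE)
  # sample variance; zero for n = 1
  var <- (sq - n * means^2) / pmax(n - 1, 1)
  var[var < 0] <- 0  # numeric guard
  list(tid = unique(tid), n = n, mean = means, sd = sqrt(var))
}

#' Exclude dispersed and under-sampled traces
#'
#' A trace is excluded if its sample standard deviation exceeds
#' `max_axis_sd` on any single axis, or if it has fewer than `min_locs`
#' localizations. Ties at exactly the SD cutoff are kept (strict `>`).
#'
#' @param traces A `trace_table` from [group_traces()].
#' @param config A [filter_config()].
#' @return The filtered `trace_table`, with attributes `removed_sd` and
#'   `removed_short` (trace counts removed by each rule).
#' @export
filter_traces <- function(traces, config = filter_config()) {
  stopifnot(inherits(traces, "trace_table"), inherits(config, "filter_config"))
  st <- .trace_stats(traces)
  bad_sd <- apply(st$sd > config$max_axis_sd, 1, any)
  bad_n <- st$n < config$min_locs
  keep_tid <- st$tid[!(bad_sd | bad_n)]
  out <- traces[traces$tid %in% keep_tid, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trace_table", "data.frame")
  attr(out, "removed_sd") <- sum(bad_sd & !bad_n)
  attr(out, "removed_short") <- sum(bad_n)
  out
}

#' Trim the first localizations of each trace
#'
#' Removes the first `trim_head` localizations (in time order) of every
#' trace; these often lie apart from the rest of the localization cloud.
#' Traces left with at least one localization are retained.
#'
#' @param traces A `trace_table`.
#' @param config A [filter_config()].
#' @return The trimmed `trace_table`.
#' @export
trim_traces <- function(traces, config = filter_config()) {
  stopifnot(inherits(traces, "trace_table"))
  if (nrow(traces) == 0 || config$trim_head == 0) return(traces)
  idx <- stats::ave(seq_len(nrow(traces)), traces$tid, FUN = seq_along)
  out <- traces[idx > config$trim_head, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trace_table", "data.frame")
  out
}

#' Correct z for the refractive-index mismatch
#'
#' Multiplies every z coordinate by `z_scale` (default 0.7), compensating
#' the focal shift caused by the refractive-index mismatch between the
#' coverslip and the aqueous sample. x and y are unchanged.
#'
#' @param traces A `trace_table` (or any localization data frame).
#' @param config A [filter_config()].
#' @return The input with scaled z.
#' @export
apply_z_scaling <- function(traces, config = filter_config()) {
  traces$z_nm <- traces$z_nm * config$z_scale
  traces
}

#' Center of mass of each trace
#'
#' @param traces A nonempty-per-trace `trace_table`.
#' @return Data frame `tid, x_nm, y_nm, z_nm, n_locs`: the unweighted mean
#'   coordinate of each trace and its localization count.
#' @export
trace_centers <- function(traces) {
  if (nrow(traces) == 0) {
    return(data.frame(tid = integer(), x_nm = numeric(), y_nm = numeric(),
                      z_nm = numeric(), n_locs = integer()))
  }
  st <- .trace_stats(traces)
  data.frame(tid = st$tid, x_nm = st$mean[, "x_nm"], y_nm = st$mean[, "y_nm"],
             z_nm = st$mean[, "z_nm"], n_locs = st$n, row.names = NULL)
}

#' Run the full localization-filtering pipeline
#'
#' Applies, in order: cfr/efo quality filter, trace grouping, trace-level
#' SD and size filter, head trimming, z-scaling, and the per-trace center
#' of mass. The order matters and mirrors the standard MINFLUX
#' post-processing chain; z-scaling and center-of-mass commute, so placing
#' the correction before the centers is consequence-free.
#'
#' @param locs Raw localization data frame.
#' @param config A [filter_config()].
#' @return A list with elements `centers` (trace-center table),
#'   `localizations` (the filtered, trimmed, z-corrected table) and
#'   `report` (named list of per-stage counts and the efo cutoff used).
#' @export
filter_pipeline <- function(locs, config = filter_config()) {
  q <- filter_quality(locs, config)
  tr <- group_traces(q)
  n_traces_in <- n_traces(tr)
  tr <- filter_traces(tr, config)
  removed_sd <- attr(tr, "removed_sd")
  removed_short <- attr(tr, "removed_short")
  tr <- trim_traces(tr, config)
  tr <- apply_z_scaling(tr, config)
  centers <- trace_centers(tr)
  report <- list(
    locs_in = nrow(locs),
    removed_cfr = attr(q, "removed_cfr"),
    removed_efo = attr(q, "removed_efo"),
    efo_cutoff_khz = attr(q, "efo_cutoff"),
    traces_in = n_traces_in,
    traces_removed_sd = removed_sd,
    traces_removed_short = removed_short,
    traces_out = nrow(centers),
    locs_out = nrow(tr)
  )
  list(centers = centers, localizations = tr, report = report)
}
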
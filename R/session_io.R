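#' Write a session bundle
#'
#' A session bundle is a directory holding a JSON manifest (`mouse_id`,
#' `region`, `condition`, `session_duration_s`, `fs_hz`), a lick CSV
#' (`time_s`) and a photometry CSV (`time_s,ch465,ch405`). All times are
#' seconds as decimal floats; files are UTF-8 with header rows.
#'
#' @param session A `lick_session`.
#' @param recording A `photometry_recording`, or `NULL` for behavior-only
#'   bundles.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, recording = NULL, path) {
  stopifnot(inherits(session, "lick_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(mouse_id = session$mouse_id, region = session$region,
                   condition = session$condition,
                   session_duration_s = session$session_duration_s,
                   fs_hz = if (!is.null(recording)) recording$fs_hz
                           else NULL)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(data.frame(time_s = session$lick_times_s),
                   file.path(path, "licks.csv"), row.names = FALSE)
  if (!is.null(recording)) {
    stopifnot(inherits(recording, "photometry_recording"))
    n <- length(recording$ch_signal)
    df <- data.frame(
      time_s = recording$t0_s + (seq_len(n) - 1) / recording$fs_hz,
      ch465 = recording$ch_signal, ch405 = recording$ch_control)
    utils::write.csv(df, file.path(path, "photometry.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a session bundle
#'
#' Reads and validates a bundle written by [write_session()]. Lick times
#' are sorted and de-duplicated (with a warning when repair was needed);
#' condition and region labels must come from the closed vocabularies; a
#' photometry stream whose length disagrees with
#' `session_duration_s * fs_hz` by more than one second is a format error.
#'
#' @param path Bundle directory.
#' @return A list: `session` (`lick_session`) and `recording`
#'   (`photometry_recording` or `NULL`).
#' @export
read_session <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  lick_path <- file.path(path, "licks.csv")
  for (p in c(mf_path, lick_path))
    if (!file.exists(p))
      stop("missing file: ", p, call. = FALSE)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  conditions <- c("Restricted", "Light", "Dark", "Sucralose")
  regions <- c("PVH", "VMH", "none")
  if (!mf$condition %in% conditions)
    stop("format error: condition '", mf$condition,
         "' not one of: ", paste(conditions, collapse = ", "),
         call. = FALSE)
  if (!mf$region %in% regions)
    stop("format error: region '", mf$region, "' not one of: ",
         paste(regions, collapse = ", "), call. = FALSE)
  licks <- utils::read.csv(lick_path)
  if (!"time_s" %in% names(licks))
    stop("format error: licks.csv must have a time_s column",
         call. = FALSE)
  t <- licks$time_s
  if (is.unsorted(t, strictly = FALSE)) {
    warning("lick times were unsorted; repaired", call. = FALSE)
    t <- sort(t)
  }
  if (anyDuplicated(t)) {
    warning("duplicate lick timestamps removed", call. = FALSE)
    t <- unique(t)
  }
  session <- lick_session(t, session_duration_s = mf$session_duration_s,
                          mouse_id = mf$mouse_id, region = mf$region,
                          condition = mf$condition)
  rec <- NULL
  ph_path <- file.path(path, "photometry.csv")
  if (file.exists(ph_path) && !is.null(mf$fs_hz)) {
    ph <- utils::read.csv(ph_path)
    need <- c("time_s", "ch465", "ch405")
    if (!all(need %in% names(ph)))
      stop("format error: photometry.csv must have columns ",
           paste(need, collapse = ", "), call. = FALSE)
    expected <- mf$session_duration_s * mf$fs_hz
    if (abs(nrow(ph) - expected) > mf$fs_hz)  # > 1 s of samples
      stop("format error: stream length ", nrow(ph),
           " inconsistent with duration x fs = ", expected, call. = FALSE)
    rec <- photometry_recording(ph$ch465, ph$ch405, fs_hz = mf$fs_hz,
                                t0_s = ph$time_s[1])
  }
  list(session = session, recording = rec)
}

#' Write an analysis product to disk
#'
#' Dispatches on the product type: bootstrapped waveforms become
#' long-format CSV (`bin_index,time_s,mean,ci_lo,ci_hi,significant_flag`),
#' significance windows become `(start_s, end_s, direction)` CSV (empty
#' window lists still produce a valid header-only file), bout tables and
#' other data.frames become plain CSV, and list results (ANOVA outputs,
#' manifests) become JSON.
#'
#' @param x The analysis product.
#' @param path Output file path.
#' @param ... Method arguments; for waveforms, `windows` supplies the
#'   significance windows used for the flag column (defaults to
#'   [significant_windows()] at the standard 6-bin rule).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, ...) UseMethod("write_results")

#' @export
write_results.bootstrap_waveform <- function(x, path,
                                             windows = NULL, ...) {
  if (is.null(windows)) windows <- significant_windows(x)
  flag <- rep(FALSE, length(x$mean))
  for (i in seq_len(nrow(windows)))
    flag[windows$start_bin[i]:windows$end_bin[i]] <- TRUE
  df <- data.frame(bin_index = seq_along(x$mean), time_s = x$time_s,
                   mean = x$mean, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
                   significant_flag = flag)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.significance_windows <- function(x, path, ...) {
  utils::write.csv(as.data.frame(x)[, c("start_s", "end_s", "direction"),
                                    drop = FALSE],
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.data.frame <- function(x, path, ...) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.list <- function(x, path, ...) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' Read a waveform CSV written by [write_results()]
#'
#' @param path File path.
#' @return A `bootstrap_waveform`-like object carrying `mean`, `ci_lo`,
#'   `ci_hi`, `time_s` and the significance flags (metadata such as
#'   `n_boot` is not stored in the CSV).
#' @export
read_waveform <- function(path) {
  df <- utils::read.csv(path)
  need <- c("bin_index", "time_s", "mean", "ci_lo", "ci_hi",
            "significant_flag")
  if (!all(need %in% names(df)))
    stop("format error: not a waveform CSV", call. = FALSE)
  structure(list(mean = df$mean, ci_lo = df$ci_lo, ci_hi = df$ci_hi,
                 time_s = df$time_s,
                 significant_flag = as.logical(df$significant_flag),
                 n_bouts = NA_integer_, n_boot = NA_integer_,
                 alpha = NA_real_, seed = NA_integer_, layout = NULL),
            class = "bootstrap_waveform")
}

#' Read a significance-window CSV
#'
#' @param path File path.
#' @return A data.frame with `start_s`, `end_s`, `direction` (possibly
#'   zero rows).
#' @export
read_windows <- function(path) {
  df <- utils::read.csv(path, colClasses = c(start_s = "numeric",
                                             end_s = "numeric",
                                             direction = "character"))
  if (!all(c("start_s", "end_s", "direction") %in% names(df)))
    stop("format error: not a windows CSV", call. = FALSE)
  df
}

#' Write / read a multispout trial table
#'
#' CSV with columns `mouse,treatment,trial,concentration_pct,licks`.
#'
#' @param x Multispout session or cohort data.frame.
#' @param path File path.
#' @return `path` (writer) or the validated data.frame (reader).
#' @export
write_multispout <- function(x, path) {
  need <- c("mouse", "treatment", "trial", "concentration_pct", "licks")
  stopifnot(all(need %in% names(x)))
  utils::write.csv(as.data.frame(x)[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_multispout
#' @export
read_multispout <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("mouse", "treatment", "trial", "concentration_pct", "licks")
  if (!all(need %in% names(df)))
    stop("format error: multispout CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  df
}

#' Write / read an in vitro ROI trace CSV (`frame,mean_gray`)
#'
#' @param trace An [roi_trace()].
#' @param path File path.
#' @param ligand_frame Ligand-addition frame supplied on read.
#' @return `path` (writer) or an `roi_trace` (reader).
#' @export
write_roi_trace <- function(trace, path) {
  stopifnot(inherits(trace, "roi_trace"))
  utils::write.csv(data.frame(frame = seq_along(trace$frames),
                              mean_gray = trace$frames),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_trace
#' @export
read_roi_trace <- function(path, ligand_frame) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("frame", "mean_gray") %in% names(df)))
    stop("format error: ROI CSV must have columns frame, mean_gray",
         call. = FALSE)
  roi_trace(df$mean_gray[order(df$frame)], ligand_frame = ligand_frame)
}
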
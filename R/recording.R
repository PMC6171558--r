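#' Construct a raw fTCD recording
#'
#' A recording holds simultaneous cerebral blood flow velocity (CBFV) traces
#' for the left and right middle cerebral arteries plus an integer marker
#' channel with one nonzero sample per trial at stimulus onset
#' (1 = list, 2 = sentence, 3 = word generation).
#'
#' @param left,right Numeric CBFV traces (cm/s), equal length.
#' @param marker Integer vector of the same length; 0 everywhere except at
#'   stimulus-onset samples.
#' @param sample_rate Samples per second (native acquisition rate 100).
#' @return An object of class `"ftcd_recording"`.
#' @export
ftcd_recording <- function(left, right, marker, sample_rate) {
  left <- as.numeric(left); right <- as.numeric(right)
  marker <- as.integer(marker)
  n <- length(left)
  if (n < 1L || length(right) != n || length(marker) != n)
    stop("left, right and marker must have identical length >= 1",
         call. = FALSE)
  if (any(!is.finite(left)) || any(!is.finite(right)))
    stop("all velocity values must be finite", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a positive scalar", call. = FALSE)
  bad <- !marker %in% c(0L, 1L, 2L, 3L)
  if (any(bad))
    stop("unknown marker code(s): ", paste(unique(marker[bad]), collapse = ", "),
         call. = FALSE)
  hits <- which(marker != 0L)
  if (length(hits) > 1L && min(diff(hits)) < 20 * sample_rate)
    stop("markers must be isolated: nonzero samples closer than 20 s",
         call. = FALSE)
  structure(list(left = left, right = right, marker = marker,
                 sample_rate = sample_rate),
            class = "ftcd_recording")
}

#' @export
print.ftcd_recording <- function(x, ...) {
  n <- length(x$left)
  cat(sprintf("fTCD recording: %d samples at %g Hz (%.1f s), %d trial markers\n",
              n, x$sample_rate, n / x$sample_rate, sum(x$marker != 0L)))
  invisible(x)
}

task_codes <- c(list = 1L, sentence = 2L, word = 3L)
task_names <- c("list", "sentence", "word")

decode_task <- function(code) task_names[code]

#' Read a signal TSV file into a recording
#'
#' The signal format is a headered tab-separated file:
#' comment lines starting with `#`, of which one must declare
#' `# sample_rate_hz: <rate>`, followed by data rows
#' `left<TAB>right<TAB>marker` (one row per sample).
#'
#' @param path Path to a signal TSV file.
#' @return An [ftcd_recording()] object.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("signal file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  header <- lines[is_comment]
  m <- regmatches(header, regexec("^#\\s*sample_rate_hz:\\s*([0-9.]+)\\s*$", header))
  rate <- NA_real_
  for (g in m) if (length(g) == 2L) rate <- as.numeric(g[2])
  if (!is.finite(rate))
    stop("signal format error: missing or garbled '# sample_rate_hz:' header",
         call. = FALSE)
  data_idx <- which(!is_comment & nzchar(lines))
  if (!length(data_idx)) stop("signal format error: no data rows", call. = FALSE)
  parts <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    bad <- data_idx[which(nf != 3L)[1]]
    stop(sprintf("signal parse error at line %d: expected 3 tab-separated fields", bad),
         call. = FALSE)
  }
  flat <- unlist(parts, use.names = FALSE)
  vals <- suppressWarnings(as.numeric(flat))
  if (anyNA(vals)) {
    bad <- data_idx[ceiling(which(is.na(vals))[1] / 3)]
    stop(sprintf("signal parse error at line %d: non-numeric value", bad),
         call. = FALSE)
  }
  dim(vals) <- c(3L, length(data_idx))
  ftcd_recording(left = vals[1, ], right = vals[2, ], marker = vals[3, ],
                 sample_rate = rate)
}

#' Write a recording to the signal TSV format
#'
#' Values are written at full double precision so that
#' `read_recording(write_recording(rec, f))` reproduces `rec` bit-for-bit.
#'
#' @param rec An [ftcd_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ftcd_recording"))
  header <- c(sprintf("# sample_rate_hz: %g", rec$sample_rate),
              "# tasks: 1=list,2=sentence,3=word")
  body <- paste(sprintf("%.17g", rec$left),
                sprintf("%.17g", rec$right),
                rec$marker, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

results_columns <- c("participant_id", "task", "n_trials_included", "li",
                     "latency_s", "ci_low", "ci_high", "category", "method",
                     "split_half_odd", "split_half_even")

#' Write a laterality results table to CSV
#'
#' Fixed column order; numeric columns rounded to 6 significant digits so the
#' file round-trips at that precision.
#'
#' @param rows A data frame with the columns of a laterality results table
#'   (see [ftcd_laterality()]); may have zero rows.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0L) {
    rows <- as.data.frame(setNames(rep(list(character(0)), length(results_columns)),
                                   results_columns))
  }
  missing_cols <- setdiff(results_columns, names(rows))
  if (length(missing_cols))
    stop("results rows missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- rows[, results_columns, drop = FALSE]
  if (nrow(out)) {
    if (!all(out$task %in% task_names))
      stop("invalid task label in results", call. = FALSE)
    if (!all(out$category %in% c("left", "bilateral", "right")))
      stop("invalid laterality category in results", call. = FALSE)
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], signif, digits = 6)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results CSV written by [write_results()]
#' @param path CSV path.
#' @return A data frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
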
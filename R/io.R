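frame_columns <- function(n_bins = 19L) {
  c("timestamp",
    paste0("c", rep(1:4, each = n_bins), "_b",
           sprintf("%02d", rep(seq_len(n_bins), 4))))
}

#' Write frames to CSV or JSON-lines
#'
#' CSV: one row per frame, a timestamp column followed by the 76 count
#' columns in channel-major order (`c1_b01 ... c4_b19`). JSON-lines: one
#' object per line with `timestamp` and a 76-element `counts` array.
#'
#' @param frames List of [new_frame()] objects or a `session`.
#' @param path Output file.
#' @param format `"csv"` or `"jsonl"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path, format = NULL) {
  if (inherits(frames, "session")) frames <- frames$frames
  if (is.null(format)) {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  n_bins <- ncol(frames[[1]])
  ts <- vapply(frames, function(f) attr(f, "timestamp"), 0)
  m <- t(vapply(frames, flatten_frame, numeric(4L * n_bins)))
  if (format == "csv") {
    df <- data.frame(timestamp = ts, m)
    names(df) <- frame_columns(n_bins)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_along(frames)) {
      writeLines(jsonlite::toJSON(list(timestamp = ts[i],
                                       counts = as.integer(m[i, ])),
                                  auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Read frames from CSV or JSON-lines
#'
#' Validates the schema strictly: every row must carry a timestamp and all
#' `4 * n_bins` count columns; malformed rows abort with their row numbers.
#' An empty file yields an empty frame list with a warning.
#'
#' @param path Input file.
#' @param format `"csv"` or `"jsonl"` (default from the file extension).
#' @param n_bins Bins per channel.
#' @return List of [new_frame()] objects.
#' @export
read_frames <- function(path, format = NULL, n_bins = 19L) {
  if (is.null(format)) {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  ncol_exp <- 1L + 4L * n_bins
  if (format == "csv") {
    df <- utils::read.csv(path)
    if (nrow(df) == 0L) { warning("empty frame file"); return(list()) }
    if (ncol(df) != ncol_exp) {
      stop("expected ", ncol_exp, " columns, found ", ncol(df), call. = FALSE)
    }
    bad <- which(!stats::complete.cases(df) |
                   apply(df[, -1, drop = FALSE], 1,
                         function(r) any(r < 0 | r != round(r))))
    if (length(bad)) {
      stop("malformed frame rows: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    lapply(seq_len(nrow(df)), function(i) {
      new_frame(as.numeric(df[i, -1]), timestamp = df$timestamp[i],
                n_bins = n_bins)
    })
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) { warning("empty frame file"); return(list()) }
    lapply(seq_along(lines), function(i) {
      obj <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
      if (is.null(obj) || length(obj$counts) != 4L * n_bins) {
        stop("malformed frame row: ", i, call. = FALSE)
      }
      new_frame(obj$counts, timestamp = obj$timestamp, n_bins = n_bins)
    })
  }
}

#' Read a pipeline configuration from YAML
#'
#' Any key present in the file overrides the corresponding
#' [default_pipeline_config()] entry; everything else keeps its default.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_pipeline_config(), user)
}

# 32-bit FNV-1a over the serialised object: a cheap content hash for run
# manifests, not a cryptographic one.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}
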
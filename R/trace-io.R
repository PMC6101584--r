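# Reading, typing, burn-in windowing and combining of MCMC trace files.
#
# Two tab-delimited dialects are supported:
#   * BEAST-style logs: optional comment lines prefixed with `#`, then a
#     header row whose first column is the state counter.
#   * MrBayes `.p` files: a first line of the form `[ID: ...]`, then a
#     header row starting with `Gen`.

STATE_COLUMN_NAMES <- c("state", "sample", "gen", "generation")

#' Infer the type of a trace column
#'
#' Classifies a column of raw text tokens as `"real"`, `"integer"` or
#' `"categorical"`. A column is categorical if any token fails numeric
#' parsing, integer if every token parses to a whole number, and real
#' otherwise.
#'
#' @param tokens Character vector of raw column tokens.
#' @return One of `"real"`, `"integer"`, `"categorical"`.
#' @examples
#' infer_trace_type(c("0.5", "1.25", "3.0"))  # "real"
#' infer_trace_type(c("1", "4", "2"))         # "integer"
#' infer_trace_type(c("hostA", "hostB"))      # "categorical"
#' @export
infer_trace_type <- function(tokens) {
  if (length(tokens) == 0) {
    stop("cannot infer the type of an empty column", call. = FALSE)
  }
  num <- suppressWarnings(as.numeric(tokens))
  if (anyNA(num)) {
    return("categorical")
  }
  if (all(is.finite(num)) && all(num == floor(num))) {
    return("integer")
  }
  "real"
}

new_trace <- function(name, type, values, components = NULL) {
  structure(
    list(name = name, type = type, values = values,
         n = length(values), components = components),
    class = "tk_trace"
  )
}

#' @export
print.tk_trace <- function(x, ...) {
  cat(sprintf("<trace '%s'> type=%s n=%d\n", x$name, x$type, x$n))
  invisible(x)
}

is_discrete <- function(trace) trace$type %in% c("integer", "categorical")
is_numeric_trace <- function(trace) trace$type %in% c("real", "integer")

round_down_to_step <- function(states, step) {
  if (states <= 0) return(0L)
  as.integer(step * (states %/% step))
}

#' Parse an MCMC trace log file
#'
#' Reads a tab-delimited MCMC sample log in either the BEAST dialect
#' (`#`-prefixed comment lines, header row, `state`/`Sample` first
#' column) or the MrBayes `.p` dialect (`[ID: ...]` banner line, header
#' starting `Gen`). Column types are inferred with [infer_trace_type()]
#' unless overridden. The default burn-in is 10% of the final state,
#' rounded down to a multiple of the sampling interval.
#'
#' @param path Path to the log file.
#' @param dialect `"auto"` (default), `"beast"` or `"mrbayes"`.
#'   Auto-detection uses the `[ID:` banner as the MrBayes sentinel.
#' @param burnin Optional burn-in override passed to [set_burnin()];
#'   `NULL` applies the 10% default.
#' @param types Optional named character vector of type overrides
#'   (`"real"`, `"integer"` or `"categorical"`) keyed by column name.
#'   Useful for indicator columns that must stay integer-typed.
#' @return A `trace_file` object.
#' @seealso [set_burnin()], [combine_traces()], [get_trace()]
#' @export
parse_log <- function(path, dialect = c("auto", "beast", "mrbayes"),
                      burnin = NULL, types = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    stop(sprintf("%s: empty file", path), call. = FALSE)
  }

  first_nonempty <- lines[nzchar(trimws(lines))][1]
  looks_mrbayes <- startsWith(trimws(first_nonempty), "[ID:")
  if (dialect == "auto") {
    dialect <- if (looks_mrbayes) "mrbayes" else "beast"
  }

  # line numbers refer to the physical file for error reporting
  keep <- rep(TRUE, length(lines))
  keep[!nzchar(trimws(lines))] <- FALSE
  keep[startsWith(trimws(lines), "#")] <- FALSE
  if (dialect == "mrbayes") {
    banner <- which(startsWith(trimws(lines), "["))
    keep[banner] <- FALSE
  }
  idx <- which(keep)
  if (length(idx) < 3) {
    stop(sprintf("%s: need a header row and at least 2 sample rows", path),
         call. = FALSE)
  }

  header <- strsplit(lines[idx[1]], "\t", fixed = TRUE)[[1]]
  header <- trimws(header)
  ncols <- length(header)
  body_idx <- idx[-1]
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != ncols)) {
    bad <- body_idx[which(widths != ncols)[1]]
    stop(sprintf("%s: line %d has %d fields but the header has %d",
                 path, bad, widths[which(widths != ncols)[1]], ncols),
         call. = FALSE)
  }
  cells <- matrix(trimws(unlist(fields)), ncol = ncols, byrow = TRUE)

  state_col <- which(tolower(header) %in% STATE_COLUMN_NAMES)[1]
  if (is.na(state_col)) {
    warning(sprintf(
      "%s: no recognized state column (state/Sample/Gen/Generation); using the first column '%s'",
      path, header[1]))
    state_col <- 1L
  }
  states <- suppressWarnings(as.numeric(cells[, state_col]))
  if (anyNA(states) || any(states < 0) || any(states != floor(states))) {
    stop(sprintf("%s: state column '%s' must contain non-negative integers",
                 path, header[state_col]), call. = FALSE)
  }
  if (length(states) < 2) {
    stop(sprintf("%s: fewer than 2 samples", path), call. = FALSE)
  }
  d <- diff(states)
  if (any(d <= 0)) {
    stop(sprintf("%s: state column is not strictly increasing", path),
         call. = FALSE)
  }
  if (length(unique(d)) != 1) {
    stop(sprintf("%s: state column is not evenly spaced", path),
         call. = FALSE)
  }
  step_size <- d[1]

  col_names <- header[-state_col]
  columns <- vector("list", length(col_names))
  col_types <- character(length(col_names))
  names(columns) <- names(col_types) <- col_names
  for (j in seq_along(col_names)) {
    raw <- cells[, setdiff(seq_len(ncols), state_col)[j]]
    type <- if (!is.null(types) && col_names[j] %in% names(types)) {
      match.arg(types[[col_names[j]]], c("real", "integer", "categorical"))
    } else {
      infer_trace_type(raw)
    }
    columns[[j]] <- if (type == "categorical") raw else as.numeric(raw)
    col_types[j] <- type
  }

  tf <- structure(
    list(source = path, dialect = dialect,
         states = states, step_size = step_size,
         columns = columns, types = col_types,
         burnin_states = 0L),
    class = "trace_file"
  )
  if (is.null(burnin)) burnin <- 0.1
  set_burnin(tf, burnin)
}

#' @export
print.trace_file <- function(x, ...) {
  cat(sprintf("<trace_file '%s'> dialect=%s states %d..%d by %d, burn-in %d\n",
              x$source, x$dialect, min(x$states), max(x$states),
              x$step_size, x$burnin_states))
  cat(sprintf("  %d traces, %d post-burn-in samples: %s\n",
              length(x$columns), n_samples(x),
              paste(names(x$columns), collapse = ", ")))
  invisible(x)
}

#' Set (or reset) the burn-in of a trace file
#'
#' Re-windows every trace to states at or beyond the burn-in point. The
#' full sample record is retained in the object, so the burn-in can be
#' revised at any time. A `burnin` below 1 is interpreted as a fraction
#' of the final state; otherwise it is a state count, rounded down to a
#' multiple of the sampling interval.
#'
#' @param tf A `trace_file`.
#' @param burnin Burn-in in states, or a fraction in `[0, 1)`.
#' @return The re-windowed `trace_file`.
#' @export
set_burnin <- function(tf, burnin) {
  stopifnot(inherits(tf, "trace_file"))
  final <- max(tf$states)
  if (burnin < 0) stop("burn-in must be non-negative", call. = FALSE)
  states <- if (burnin < 1) burnin * final else burnin
  if (states >= final) {
    stop(sprintf("burn-in of %s states leaves no samples (final state %s)",
                 format(states), format(final)), call. = FALSE)
  }
  tf$burnin_states <- round_down_to_step(states, tf$step_size)
  tf
}

post_burnin_mask <- function(tf) tf$states >= tf$burnin_states

#' Number of post-burn-in samples in a trace file
#' @param tf A `trace_file` or `combined_trace`.
#' @return Integer sample count.
#' @export
n_samples <- function(tf) UseMethod("n_samples")

#' @export
n_samples.trace_file <- function(tf) sum(post_burnin_mask(tf))

#' @export
n_samples.combined_trace <- function(tf) {
  sum(vapply(tf$components, n_samples, integer(1)))
}

#' Names of the traces in a file
#' @param tf A `trace_file` or `combined_trace`.
#' @return Character vector of trace names.
#' @export
trace_names <- function(tf) UseMethod("trace_names")

#' @export
trace_names.trace_file <- function(tf) names(tf$columns)

#' @export
trace_names.combined_trace <- function(tf) trace_names(tf$components[[1]])

#' Extract one trace
#'
#' Returns a single named trace, by default windowed to the post-burn-in
#' samples. For a `combined_trace` the post-burn-in samples of every
#' component file are concatenated in file order and the per-component
#' slices are kept alongside, so autocorrelation never spans the
#' boundary between independent chains.
#'
#' @param tf A `trace_file` or `combined_trace`.
#' @param name Trace (column) name.
#' @param post_burnin Window to post-burn-in samples? Default `TRUE`.
#' @return A `tk_trace` with fields `name`, `type`, `values`, `n`.
#' @export
get_trace <- function(tf, name, post_burnin = TRUE) UseMethod("get_trace")

#' @export
get_trace.trace_file <- function(tf, name, post_burnin = TRUE) {
  if (!name %in% names(tf$columns)) {
    stop(sprintf("no trace named '%s' in %s", name, tf$source), call. = FALSE)
  }
  v <- tf$columns[[name]]
  if (post_burnin) v <- v[post_burnin_mask(tf)]
  new_trace(name, tf$types[[name]], v)
}

#' @export
get_trace.combined_trace <- function(tf, name, post_burnin = TRUE) {
  parts <- lapply(tf$components, get_trace, name = name,
                  post_burnin = post_burnin)
  comp <- lapply(seq_along(parts), function(i) {
    list(values = parts[[i]]$values,
         step_size = tf$components[[i]]$step_size)
  })
  new_trace(name, parts[[1]]$type,
            unlist(lapply(parts, `[[`, "values"), use.names = FALSE),
            components = comp)
}

#' All traces of a file as a named list
#' @inheritParams get_trace
#' @return Named list of `tk_trace` objects.
#' @export
traces <- function(tf, post_burnin = TRUE) {
  stats::setNames(
    lapply(trace_names(tf), get_trace, tf = tf, post_burnin = post_burnin),
    trace_names(tf))
}

#' State values of a trace file
#' @inheritParams get_trace
#' @return Numeric vector of sampled state numbers.
#' @export
state_values <- function(tf, post_burnin = TRUE) {
  stopifnot(inherits(tf, "trace_file"))
  if (post_burnin) tf$states[post_burnin_mask(tf)] else tf$states
}

#' Combine replicate trace files
#'
#' Replicate analyses logging the same collection of parameters can be
#' pooled: the post-burn-in samples of each trace are concatenated in
#' file order. All files must expose identical trace names with
#' identical types. Sampling intervals may differ between components;
#' permutation-invariant statistics are unaffected, and effective sample
#' sizes are summed per component rather than estimated across the
#' concatenation boundary.
#'
#' @param files List of at least two `trace_file` objects (each with its
#'   burn-in already set).
#' @return A `combined_trace`.
#' @export
combine_traces <- function(files) {
  if (length(files) < 2) {
    stop("need at least 2 trace files to combine", call. = FALSE)
  }
  stopifnot(all(vapply(files, inherits, logical(1), "trace_file")))
  ref_names <- trace_names(files[[1]])
  for (f in files[-1]) {
    other <- trace_names(f)
    if (!setequal(ref_names, other)) {
      missing <- setdiff(ref_names, other)
      extra <- setdiff(other, ref_names)
      stop(sprintf("incompatible files: trace names differ (%s)",
                   paste(c(missing, extra), collapse = ", ")),
           call. = FALSE)
    }
    mism <- ref_names[files[[1]]$types[ref_names] != f$types[ref_names]]
    if (length(mism) > 0) {
      stop(sprintf("incompatible files: trace types differ for %s",
                   paste(mism, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(components = files), class = "combined_trace")
}

#' @export
print.combined_trace <- function(x, ...) {
  cat(sprintf("<combined_trace> %d files, %d pooled samples, traces: %s\n",
              length(x$components), n_samples(x),
              paste(trace_names(x), collapse = ", ")))
  invisible(x)
}

format_log_value <- function(v, type) {
  if (type == "categorical") return(v)
  if (type == "integer") return(sprintf("%d", as.integer(v)))
  sprintf("%.17g", v)
}

#' Write a trace file as canonical TSV
#'
#' Re-exports the full (pre-burn-in) sample record of a `trace_file` in
#' either supported dialect, at full double precision so that
#' [parse_log()] recovers identical values.
#'
#' @param tf A `trace_file`.
#' @param path Output path.
#' @param dialect `"beast"` (default) or `"mrbayes"`.
#' @return `path`, invisibly.
#' @export
write_trace_file <- function(tf, path, dialect = c("beast", "mrbayes")) {
  dialect <- match.arg(dialect)
  nm <- names(tf$columns)
  body <- vapply(seq_along(tf$states), function(i) {
    row <- vapply(nm, function(cn)
      format_log_value(tf$columns[[cn]][i], tf$types[[cn]]), character(1))
    paste(c(sprintf("%d", as.integer(tf$states[i])), row), collapse = "\t")
  }, character(1))
  if (dialect == "beast") {
    lines <- c("# canonical trace re-export",
               paste(c("state", nm), collapse = "\t"), body)
  } else {
    lines <- c("[ID: 0001]", paste(c("Gen", nm), collapse = "\t"), body)
  }
  writeLines(lines, path)
  invisible(path)
}
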
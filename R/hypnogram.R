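#' Construct an epoch-scored hypnogram
#'
#' A hypnogram is the time-ordered sequence of per-epoch vigilance state
#' labels for one recording of one subject under one treatment. Epochs are
#' 0-based: epoch `i` covers the half-open interval
#' `[i * epoch_seconds, (i + 1) * epoch_seconds)` seconds from recording
#' start.
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param treatment Treatment label, e.g. `"VEH"`, `"AM5"`, `"AM10"`.
#' @param states Character vector of state codes. Raw hypnograms use
#'   [RAW_STATES]; reclassified sequences use [SPLIT_STATES]. Labels are
#'   case-insensitive and stored upper-case.
#' @param epoch_seconds Epoch length in seconds (default 4).
#' @param treatment_epoch 0-based index of the epoch at which the drug was
#'   administered (default 0).
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(subject_id, treatment, states, epoch_seconds = 4,
                      treatment_epoch = 0L) {
  states <- toupper(as.character(states))
  h <- structure(
    list(
      subject_id = as.character(subject_id)[1],
      treatment = as.character(treatment)[1],
      states = states,
      epoch_seconds = as.numeric(epoch_seconds)[1],
      treatment_epoch = as.integer(treatment_epoch)[1]
    ),
    class = "hypnogram"
  )
  validate_hypnogram(h)
  h
}

#' Validate a hypnogram object
#'
#' Checks length, state labels (raw and reclassified labels both accepted,
#' but never mixed raw REMS with REMS_S/REMS_L), epoch length, and the
#' treatment-epoch index.
#'
#' @param h A `hypnogram`.
#' @return `h`, invisibly; errors on violation.
#' @export
validate_hypnogram <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  if (length(h$states) < 1L) stop("hypnogram must contain at least one epoch")
  ok <- h$states %in% c(RAW_STATES, SPLIT_STATES)
  if (!all(ok)) {
    stop(sprintf("unknown state label(s): %s",
                 paste(unique(h$states[!ok]), collapse = ", ")))
  }
  if (any(h$states == "REMS") && any(h$states %in% c("REMS_S", "REMS_L"))) {
    stop("hypnogram mixes raw REMS with reclassified REMS_S/REMS_L labels")
  }
  if (!is.finite(h$epoch_seconds) || h$epoch_seconds <= 0) {
    stop("epoch_seconds must be a positive number")
  }
  if (is.na(h$treatment_epoch) || h$treatment_epoch < 0L ||
      h$treatment_epoch >= length(h$states)) {
    stop("treatment_epoch must lie in [0, length of hypnogram)")
  }
  invisible(h)
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf(
    "hypnogram: subject %s, treatment %s, %d epochs x %g s (%.1f min)\n",
    x$subject_id, x$treatment, length(x$states), x$epoch_seconds,
    length(x$states) * x$epoch_seconds / 60))
  tab <- table(factor(x$states, levels = intersect(
    c(RAW_STATES, SPLIT_STATES), unique(x$states))))
  print(tab)
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$states)

#' Read epoch-scored hypnograms from CSV
#'
#' The file must contain header columns `subject_id`, `treatment`,
#' `epoch_index`, `state` (extra columns are ignored). Lines starting with
#' `#` before the header are treated as comments; a comment of the form
#' `# epoch_seconds=4` sets the epoch length for all records in the file.
#' Rows are grouped by `(subject_id, treatment)`; within each group epoch
#' indices must be 0-based and contiguous — gaps or duplicates are an error,
#' never silently imputed, because they would corrupt bout lengths.
#'
#' @param path Path to a CSV file.
#' @param treatment_epoch 0-based drug-administration epoch applied to every
#'   hypnogram (default 0).
#' @return A list of [hypnogram] objects, one per `(subject_id, treatment)`
#'   group, in file order.
#' @seealso [write_hypnogram()] for the inverse operation.
#' @export
read_hypnogram <- function(path, treatment_epoch = 0L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  epoch_seconds <- 4
  for (cm in lines[is_comment]) {
    m <- regmatches(cm, regexec("epoch_seconds\\s*=\\s*([0-9.]+)", cm))[[1]]
    if (length(m) == 2L) epoch_seconds <- as.numeric(m[2])
  }
  body <- lines[!is_comment]
  if (length(body) < 1L) stop("no header line found")
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  required <- c("subject_id", "treatment", "epoch_index", "state")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) return(list())
  df$state <- toupper(trimws(df$state))
  bad <- !(df$state %in% RAW_STATES)
  if (any(bad)) {
    row1 <- which(bad)[1]
    stop(sprintf("unknown state label '%s' at data row %d", df$state[row1], row1))
  }
  key <- paste(df$subject_id, df$treatment, sep = "\r")
  groups <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  lapply(groups, function(idx) {
    g <- df[idx, , drop = FALSE]
    g <- g[order(g$epoch_index), , drop = FALSE]
    expected <- seq.int(0L, nrow(g) - 1L)
    if (!identical(as.integer(g$epoch_index), expected)) {
      stop(sprintf(
        "epoch_index not contiguous 0-based for subject %s treatment %s",
        g$subject_id[1], g$treatment[1]))
    }
    hypnogram(g$subject_id[1], g$treatment[1], g$state,
              epoch_seconds = epoch_seconds,
              treatment_epoch = treatment_epoch)
  })
}

#' Write hypnograms to CSV
#'
#' Writes the format read by [read_hypnogram()], including an
#' `# epoch_seconds=` comment line, so that a write/read round trip
#' reproduces the input exactly. An empty collection produces a header-only
#' file.
#'
#' @param hypnograms A single [hypnogram] or a list of them. All must share
#'   the same `epoch_seconds`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hypnograms, path) {
  if (inherits(hypnograms, "hypnogram")) hypnograms <- list(hypnograms)
  lapply(hypnograms, validate_hypnogram)
  es <- if (length(hypnograms) > 0L) {
    unique(vapply(hypnograms, function(h) h$epoch_seconds, numeric(1)))
  } else 4
  if (length(es) > 1L) stop("all hypnograms must share one epoch_seconds")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# epoch_seconds=%g", es), con)
  writeLines("subject_id,treatment,epoch_index,state", con)
  for (h in hypnograms) {
    n <- length(h$states)
    writeLines(sprintf("%s,%s,%d,%s", h$subject_id, h$treatment,
                       seq.int(0L, n - 1L), h$states), con)
  }
  invisible(path)
}
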
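#' Cross-tabulate bout successions into a transition table
#'
#' Counts, for every consecutive bout pair within a subject, the transition
#' from the earlier bout's state (row) to the later bout's state (column).
#' Pairs never cross subjects. Because consecutive bouts always have
#' distinct states, the diagonal is structurally zero. A transition is
#' assigned to the time bin containing the ONSET of the successor bout
#' (consistent with bout binning by onset); passing `bin` restricts the
#' table to transitions of that bin, `bin = NULL` pools all.
#'
#' @param bouts Study bout data frame (reclassified; must carry a `bin`
#'   column when `bin` selection is used), temporally ordered within each
#'   subject or carrying `onset_epoch` to order by.
#' @param bin Optional 0-based bin index to restrict to (`NULL` = all
#'   transitions, including those landing outside the window).
#' @param treatment Optional treatment label to restrict to.
#' @param states State ordering of the table (default [SPLIT_STATES]).
#' @return An object of class `transition_table`: a list with `states`, the
#'   K-by-K observed count matrix `O`, total `N`, row/column marginals
#'   `R`/`C`, and empty slots for `p_obs`, `p_exp`, `E`, `Z`, `mask` filled
#'   by [z_statistics()] and [apply_mask()].
#' @export
cross_tabulate <- function(bouts, bin = NULL, treatment = NULL,
                           states = SPLIT_STATES) {
  stopifnot(is.data.frame(bouts))
  if (!is.null(treatment)) {
    bouts <- bouts[bouts$treatment == treatment, , drop = FALSE]
  }
  K <- length(states)
  O <- matrix(0L, K, K, dimnames = list(from = states, to = states))
  # consecutive pairs within each subject-by-treatment recording
  key <- paste(bouts$subject_id, bouts$treatment, sep = "\r")
  for (idx in split(seq_len(nrow(bouts)), key)) {
    g <- bouts[idx[order(bouts$onset_epoch[idx])], , drop = FALSE]
    if (nrow(g) < 2L) next
    from <- g$state[-nrow(g)]
    to <- g$state[-1L]
    if (!is.null(bin)) {
      keep <- !is.na(g$bin[-1L]) & g$bin[-1L] == bin
      from <- from[keep]
      to <- to[keep]
    }
    if (length(from) == 0L) next
    O <- O + unclass(table(factor(from, levels = states),
                           factor(to, levels = states)))
  }
  storage.mode(O) <- "integer"
  new_transition_table(states, O)
}

#' Build a transition table from an observed count matrix
#'
#' Constructs a `transition_table` directly from a square matrix of
#' observed transition counts (rows = current state, columns = next
#' state). The diagonal must be zero: a state cannot succeed itself, since
#' bouts are maximal runs.
#'
#' @param O Square numeric matrix of non-negative integer counts with zero
#'   diagonal.
#' @param states State labels; default the column names of `O`.
#' @return A `transition_table` with counts and marginals filled.
#' @export
transition_table <- function(O, states = colnames(O)) {
  stopifnot(is.matrix(O), nrow(O) == ncol(O))
  if (is.null(states)) stop("states must be given when O has no dimnames")
  stopifnot(length(states) == nrow(O))
  if (any(O < 0) || any(O != round(O))) {
    stop("counts must be non-negative integers")
  }
  if (any(diag(O) != 0)) stop("diagonal must be structurally zero")
  storage.mode(O) <- "integer"
  dimnames(O) <- list(from = states, to = states)
  new_transition_table(states, O)
}

new_transition_table <- function(states, O) {
  structure(list(
    states = states, O = O, N = sum(O),
    R = rowSums(O), C = colSums(O),
    p_obs = NULL, p_exp = NULL, E = NULL, Z = NULL,
    mask = NULL, method = NULL, scale = NULL
  ), class = "transition_table")
}

#' Standardized residual z-statistics of a transition table
#'
#' Under the "no preference" (independence) null, the probability of the
#' transition i -> j is the product of the row and column marginal
#' probabilities, so the expected count is `E_ij = R_i * C_j / N`, computed
#' from the table as constructed — including its structurally-zero
#' diagonal. The z-statistic standardizes the observed-minus-expected
#' difference:
#' * `pearson` (default): `Z_ij = (O_ij - E_ij) / sqrt(E_ij)`,
#' * `adjusted`: `Z_ij = (O_ij - E_ij) /
#'   sqrt(E_ij * (1 - R_i/N) * (1 - C_j/N))`.
#'
#' Values beyond +/-2 are conventionally read as significant preference
#' (positive) or inhibition (negative) of the transition. `Z` is `NA`
#' wherever `E_ij = 0`. With `scale = "probabilities"` the residual is
#' computed on the probability scale (observed and expected probabilities
#' instead of counts), which divides the count-scale z by `sqrt(N)`; the
#' +/-2 convention presumes the count scale.
#'
#' @param t A `transition_table` from [cross_tabulate()].
#' @param method `"pearson"` or `"adjusted"`.
#' @param scale `"counts"` (default) or `"probabilities"`.
#' @return The table with `p_obs`, `p_exp`, `E`, and `Z` filled.
#' @export
z_statistics <- function(t, method = c("pearson", "adjusted"),
                         scale = c("counts", "probabilities")) {
  stopifnot(inherits(t, "transition_table"))
  method <- match.arg(method)
  scale <- match.arg(scale)
  if (t$N == 0L) stop("empty table: no transitions observed")
  E <- outer(t$R, t$C) / t$N
  denom <- switch(method,
    pearson = sqrt(E),
    adjusted = sqrt(E * outer(1 - t$R / t$N, 1 - t$C / t$N))
  )
  Z <- (t$O - E) / denom
  Z[E == 0] <- NA_real_
  if (scale == "probabilities") Z <- Z / sqrt(t$N)
  t$p_obs <- t$O / t$N
  t$p_exp <- E / t$N
  t$E <- E
  t$Z <- Z
  t$method <- method
  t$scale <- scale
  t
}

#' Mask cells where the z-statistic is not estimable
#'
#' The z-statistic cannot properly be estimated with fewer than
#' `min_count` observations in a cell; such cells, and the structurally
#' zero diagonal, are masked (rendered gray in heatmaps) and carry no z
#' value. By default the rule tests the OBSERVED count; `on = "expected"`
#' applies the conventional rule on the expected count instead (requires
#' [z_statistics()] to have been run).
#'
#' @param t A `transition_table`.
#' @param min_count Minimum observations per cell (default 5).
#' @param on `"observed"` (default) or `"expected"`.
#' @return The table with its logical `mask` filled (`TRUE` = not
#'   estimable) and masked `Z` entries set to `NA`.
#' @export
apply_mask <- function(t, min_count = 5L, on = c("observed", "expected")) {
  stopifnot(inherits(t, "transition_table"))
  on <- match.arg(on)
  base <- if (on == "observed") t$O else {
    if (is.null(t$E)) stop("run z_statistics() before masking on expected counts")
    t$E
  }
  mask <- base < min_count
  diag(mask) <- TRUE
  t$mask <- mask
  if (!is.null(t$Z)) t$Z[mask] <- NA_real_
  t
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("transition table: %d states, N = %d transitions\n",
              length(x$states), x$N))
  print(x$O)
  if (!is.null(x$Z)) {
    cat(sprintf("z-statistics (%s, %s scale):\n", x$method, x$scale))
    print(round(x$Z, 2))
  }
  invisible(x)
}

#' Long-format view of a transition table
#'
#' @param x A `transition_table` (z and mask filled for complete output).
#' @param ... Unused.
#' @return Data frame with columns `from_state`, `to_state`, `observed`,
#'   `expected`, `z`, `masked`.
#' @export
as.data.frame.transition_table <- function(x, ...) {
  K <- length(x$states)
  grid <- expand.grid(from_state = x$states, to_state = x$states,
                      stringsAsFactors = FALSE)
  E <- if (is.null(x$E)) matrix(NA_real_, K, K) else x$E
  Z <- if (is.null(x$Z)) matrix(NA_real_, K, K) else x$Z
  M <- if (is.null(x$mask)) matrix(NA, K, K) else x$mask
  data.frame(grid,
             observed = as.vector(x$O),
             expected = as.vector(E),
             z = as.vector(Z),
             masked = as.vector(M),
             stringsAsFactors = FALSE)
}

#' Render a transition heatmap
#'
#' Tiles show the z-statistic on a diverging colour scale symmetric about
#' zero (blue = inhibited, red = preferred transition); masked cells are
#' gray. Rows (Y axis) are the current state, columns (X axis) the next
#' state, with the first state at the top.
#'
#' @param t A `transition_table` with `Z` and `mask` filled.
#' @param zlim Symmetric colour limit; default `max(|Z|)` of this table.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
transition_heatmap <- function(t, zlim = NULL, title = NULL) {
  stopifnot(inherits(t, "transition_table"))
  if (is.null(t$mask)) {
    stop("run apply_mask() before plotting")
  }
  # an empty (N = 0) table has no z values at all: every tile is gray
  d <- as.data.frame(t)
  d$z[d$masked] <- NA_real_
  if (is.null(zlim)) {
    zlim <- max(abs(d$z), 2, na.rm = TRUE)
  }
  d$from_state <- factor(d$from_state, levels = rev(t$states))
  d$to_state <- factor(d$to_state, levels = t$states)
  ggplot2::ggplot(d, ggplot2::aes(x = to_state, y = from_state,
                                  fill = z)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(-zlim, zlim),
                                  na.value = "grey70", name = "z") +
    ggplot2::scale_x_discrete(position = "top") +
    ggplot2::labs(x = "next state", y = "current state", title = title) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Export a transition table as CSV and heatmap image
#'
#' Writes the long-format table (`from_state`, `to_state`, `observed`,
#' `expected`, `z`, `masked`; z at full precision) and, optionally, a
#' rendered heatmap.
#'
#' @param t A `transition_table` with `Z` and `mask` filled.
#' @param csv_path Output CSV path.
#' @param image_path Optional image path (format from extension, e.g.
#'   `.png` or `.svg`).
#' @param zlim,title Passed to [transition_heatmap()].
#' @return `csv_path`, invisibly.
#' @export
heatmap_export <- function(t, csv_path, image_path = NULL, zlim = NULL,
                           title = NULL) {
  d <- as.data.frame(t)
  # %.17g guarantees an exact numeric round trip through the CSV
  num <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  out <- data.frame(from_state = d$from_state, to_state = d$to_state,
                    observed = d$observed, expected = num(d$expected),
                    z = num(d$z), masked = d$masked)
  utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(image_path)) {
    p <- transition_heatmap(t, zlim = zlim, title = title)
    ggplot2::ggsave(image_path, p, width = 5, height = 4.2, dpi = 150)
  }
  invisible(csv_path)
}

#' Transition heatmap grid over treatments and time bins
#'
#' Builds one pooled transition table per (treatment, bin) cell — the nine
#' contingency tables of a 3-treatment, 3-hour study — with a consistent
#' state ordering, and a composite faceted heatmap on a single colour scale
#' whose limits are the maximum |z| across all panels.
#'
#' @param bouts Study bout data frame (reclassified and binned).
#' @param treatments Treatment levels, in panel (row) order; default the
#'   order of appearance.
#' @param n_bins Number of time bins (panel columns).
#' @param states State ordering.
#' @param method,scale Passed to [z_statistics()].
#' @param min_count,mask_on Passed to [apply_mask()].
#' @return A list with `tables` (named `treatment.bin` list of
#'   `transition_table`s), `plot` (faceted ggplot), and `zlim`.
#' @export
heatmap_grid <- function(bouts, treatments = NULL, n_bins = 3L,
                         states = SPLIT_STATES,
                         method = "pearson", scale = "counts",
                         min_count = 5L, mask_on = "observed") {
  if (is.null(treatments)) treatments <- unique(bouts$treatment)
  tables <- list()
  long <- list()
  for (trt in treatments) {
    for (b in seq.int(0L, n_bins - 1L)) {
      t <- cross_tabulate(bouts, bin = b, treatment = trt, states = states)
      if (t$N > 0L) t <- z_statistics(t, method = method, scale = scale)
      t <- apply_mask(t, min_count = min_count, on = mask_on)
      nm <- sprintf("%s.%d", trt, b)
      tables[[nm]] <- t
      d <- as.data.frame(t)
      d$treatment <- trt
      d$bin <- b
      long[[nm]] <- d
    }
  }
  d <- do.call(rbind, long)
  d$z[d$masked] <- NA_real_
  zlim <- max(abs(d$z), 2, na.rm = TRUE)
  d$from_state <- factor(d$from_state, levels = rev(states))
  d$to_state <- factor(d$to_state, levels = states)
  d$treatment <- factor(d$treatment, levels = treatments)
  d$hour <- factor(d$bin, labels = sprintf("hour %d", seq_len(n_bins)))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = to_state,
                                       y = from_state,
                                       fill = z)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(-zlim, zlim),
                                  na.value = "grey70", name = "z") +
    ggplot2::facet_grid(treatment ~ hour) +
    ggplot2::labs(x = "next state", y = "current state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  list(tables = tables, plot = p, zlim = zlim)
}
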
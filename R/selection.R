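#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values; the headline agreement
#' statistic between actual and predicted per-cell mean intensities.
#' Constant input yields `NA` with a warning (rank correlation is
#' undefined there).
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return scalar in `[-1, 1]`, or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Score a reduced panel with an imputer
#'
#' Masks every marker outside `panel`, imputes, and measures — for each
#' held-out marker — the Spearman correlation between actual and
#' predicted within-mask mean intensities across cells.  The panel score
#' is the mean over held-out markers; undefined correlations (constant
#' predictions or truths) are excluded from the mean with a warning.
#'
#' @param imputer any [impute()]-capable object.
#' @param stack evaluation `cell_stack` (>= 3 cells).
#' @param panel character vector of measured markers.
#' @return list with `mean_rho` and the named `per_marker` vector.
#' @export
score_panel <- function(imputer, stack, panel) {
  if (n_cells(stack) < 3) stop("need at least 3 cells to correlate")
  mask <- panel_to_mask(panel, stack$markers)
  pred <- impute(imputer, stack, mask = mask)
  actual <- mean_intensities(stack)
  predicted <- mean_intensities(stack, data = pred)
  held <- stack$markers[mask$masked]
  per <- vapply(held, function(mk) {
    a <- actual[, mk]; p <- predicted[, mk]
    if (stats::sd(a) == 0 || stats::sd(p) == 0) NA_real_
    else stats::cor(a, p, method = "spearman")
  }, numeric(1))
  if (anyNA(per))
    warning("undefined correlation for marker(s) ",
            paste(held[is.na(per)], collapse = ", "),
            "; excluded from the panel score")
  list(mean_rho = mean(per, na.rm = TRUE), per_marker = per)
}

#' Iterative greedy marker-panel selection
#'
#' Orders markers by predictive value for the rest of the panel.  The
#' panel starts as `{DAPI}`; at every step each remaining marker is
#' tentatively added, the complement is imputed, and the candidate whose
#' addition maximises the mean held-out Spearman correlation joins the
#' panel (ties broken by lowest channel index).  The recursion is
#'
#' \deqn{Panel_1 = \{DAPI\}, \quad
#'   Panel_k = Panel_{k-1} \cup \{\arg\max_c \,
#'   \bar\rho(Y, f(X, Panel_{k-1} \cup \{c\}))\}}
#'
#' where the held-out set Y is always the complement of the candidate
#' panel, so step `k` scores reconstruction of the remaining `C - k`
#' markers.
#'
#' @param imputer any [impute()]-capable object.
#' @param stack the selection split (never the test split).
#' @param max_k largest panel size to grow to (`<= C - 1`).
#' @return an object of class `"panel_trajectory"`: `markers` (the
#'   selection order, starting with DAPI), `scores` (mean held-out rho per
#'   step), and `rho_matrix` (steps x markers, the per-held-out-marker
#'   correlations; `NA` for markers inside the panel).
#' @export
select_panel <- function(imputer, stack, max_k = length(stack$markers) - 1L) {
  markers <- stack$markers
  C <- length(markers)
  if (!("DAPI" %in% markers)) stop("DAPI must be in the marker panel")
  if (max_k > C - 1) stop("max_k must be <= C - 1")
  panel <- "DAPI"
  sc <- score_panel(imputer, stack, panel)
  scores <- sc$mean_rho
  rho_matrix <- matrix(NA_real_, max_k, C, dimnames = list(NULL, markers))
  rho_matrix[1, names(sc$per_marker)] <- sc$per_marker
  if (max_k >= 2) {
    for (k in 2:max_k) {
      cand <- setdiff(markers, panel)
      cand_scores <- vapply(cand, function(cm)
        score_panel(imputer, stack, c(panel, cm))$mean_rho, numeric(1))
      # argmax, ties broken by lowest channel index
      best <- cand[which.max(cand_scores)]
      panel <- c(panel, best)
      sc <- score_panel(imputer, stack, panel)
      scores <- c(scores, sc$mean_rho)
      rho_matrix[k, names(sc$per_marker)] <- sc$per_marker
    }
  }
  structure(list(markers = panel, scores = scores, rho_matrix = rho_matrix),
            class = "panel_trajectory")
}

#' @export
print.panel_trajectory <- function(x, ...) {
  cat("<panel_trajectory>\n")
  df <- data.frame(step = seq_along(x$markers), marker = x$markers,
                   mean_rho = round(x$scores, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.panel_trajectory <- function(x, ...) {
  data.frame(step = seq_along(x$markers), marker = x$markers,
             mean_rho = x$scores,
             as.data.frame(x$rho_matrix[seq_along(x$markers), , drop = FALSE]),
             check.names = FALSE)
}

#' Plot a selection trajectory
#' @param x a `panel_trajectory`; @param ... passed to [graphics::plot()].
#' @export
plot.panel_trajectory <- function(x, ...) {
  graphics::plot(seq_along(x$scores), x$scores, type = "b",
                 xlab = "panel size k", ylab = "mean held-out Spearman rho",
                 ylim = c(min(0, min(x$scores, na.rm = TRUE)), 1), ...)
  graphics::text(seq_along(x$scores), x$scores, x$markers, pos = 3, cex = 0.7)
  invisible(x)
}
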
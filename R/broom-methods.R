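# broom-style accessors and ggplot2 autoplot methods for fitted model
# objects and the regenerated IARV table

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col
#'   facet_wrap labs theme_minimal position_dodge
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @method tidy injury_risk_model
#' @export
tidy.injury_risk_model <- function(x, ...) {
  flds <- x[setdiff(names(x), c("metric", "units", "source"))]
  rows <- lapply(names(flds), function(nm) {
    v <- flds[[nm]]
    if (is.null(v) || !is.numeric(v)) return(NULL)
    term <- if (length(v) > 1L) {
      paste0(nm, "[", if (!is.null(names(v))) names(v) else seq_along(v), "]")
    } else nm
    tibble(term = term, estimate = unname(v))
  })
  bind_rows(rows)
}

#' @method glance injury_risk_model
#' @export
glance.injury_risk_model <- function(x, ...) {
  tibble(family = class(x)[[1L]],
         metric = x$metric,
         units = x$units,
         n_parameters = nrow(tidy(x)),
         source = x$source)
}

#' Risk-curve plot for a fitted injury-risk model
#'
#' Draws the forward dose-response curve(s) of the model over a metric
#' range, one line per available AIS level.
#'
#' @param object An `injury_risk_model`.
#' @param xlim Metric range, `c(min, max)`; a default is chosen from the
#'   model's inverse at 0.1% and 60% risk.
#' @param levels AIS levels to draw (defaults to those parameterized).
#' @param n Number of grid points.
#' @param ... Passed on (unused).
#' @return A ggplot object.
#' @method autoplot injury_risk_model
#' @export
autoplot.injury_risk_model <- function(object, xlim = NULL, levels = NULL,
                                       n = 200, ...) {
  if (is.null(levels)) {
    levels <- if (!is.null(object$cut_points)) {
      as.integer(names(object$cut_points))
    } else if (!is.null(object$scale) && !is.null(names(object$scale))) {
      as.integer(names(object$scale)[!is.na(object$scale)])
    } else 1L
  }
  if (is.null(xlim)) {
    lo <- tryCatch(min(vapply(levels, function(lv)
      iarv(object, 0.001, level = lv), numeric(1))), error = function(e) 0)
    hi <- max(vapply(levels, function(lv)
      iarv(object, 0.6, level = lv), numeric(1)))
    xlim <- c(max(0, lo), hi)
  }
  grid <- seq(xlim[1], xlim[2], length.out = n)
  df <- bind_rows(lapply(levels, function(lv) {
    tibble(x = grid, level = paste0("AIS ≥ ", lv),
           p = injury_risk(object, grid, level = lv))
  }))
  ggplot(df, aes(x = .data$x, y = .data$p, colour = .data$level)) +
    geom_line() +
    labs(x = paste0(object$metric,
                    if (!is.na(object$units) && nzchar(object$units))
                      paste0(" (", object$units, ")") else ""),
         y = "Probability of injury", colour = NULL) +
    theme_minimal()
}

#' IARV table plot
#'
#' Column chart of the tabulated limits per metric, faceted by metric (free
#' scales, since the metrics span three orders of magnitude), colored by
#' landing condition and grouped by crew population.
#'
#' @param object An `iarv_table` from [build_iarv_table()].
#' @param ... Unused.
#' @method autoplot iarv_table
#' @export
autoplot.iarv_table <- function(object, ...) {
  ggplot(object, aes(x = .data$population, y = .data$value,
                     fill = .data$condition)) +
    geom_col(position = position_dodge()) +
    facet_wrap(~label, scales = "free_y") +
    labs(x = NULL, y = "IARV", fill = "Landing condition") +
    theme_minimal()
}

#' Channel-set plot
#'
#' Line plot of every channel in a [channel_set()] against time, faceted by
#' channel with its declared units in the strip label.
#'
#' @param object A `channel_set`.
#' @param ... Unused.
#' @method autoplot channel_set
#' @export
autoplot.channel_set <- function(object, ...) {
  units <- attr(object, "units")
  long <- tidyr::pivot_longer(as_tibble(object), -"time",
                              names_to = "channel", values_to = "value")
  long$channel <- paste0(long$channel, " (", units[long$channel], ")")
  ggplot(long, aes(x = .data$time, y = .data$value)) +
    geom_line() +
    facet_wrap(~channel, scales = "free_y", ncol = 1) +
    labs(x = "Time (s)", y = NULL) +
    theme_minimal()
}

#' @method glance iarv_table
#' @export
glance.iarv_table <- function(x, ...) {
  tibble(n_metrics = length(unique(x$metric)),
         n_cells = nrow(x),
         n_derived = sum(x$status == "derived"),
         n_missing_parameter = sum(x$status == "missing-parameter"),
         n_discrepant = sum(x$status == "paper-discrepancy"),
         all_derived_match = all(
           x$value[x$status == "derived"] == x$published[x$status == "derived"]))
}
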
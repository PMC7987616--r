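#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidiers for extraction results
#'
#' `tidy()` on an extraction returns the attrition table (stage, reason,
#' count); `glance()` a one-row summary of the run (rows, exposed, matched
#' controls, rejections, consistency of the attrition books).  On a rate
#' summary, `tidy()` returns the stratum table with estimate and CI columns
#' under broom-style names.
#'
#' @param x an `ehr_extraction` or `ehr_rates` object.
#' @param ... unused.
#' @return a tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy ehr_extraction
#' @export
tidy.ehr_extraction <- function(x, ...) {
  as_tibble(x$attrition)
}

#' @rdname tidiers
#' @method glance ehr_extraction
#' @export
glance.ehr_extraction <- function(x, ...) {
  tibble(
    n_rows = nrow(x$dataset),
    n_exposed = sum(x$dataset$exposed_flag == 1L),
    n_controls = sum(x$dataset$exposed_flag == 0L),
    n_unmatched_exposed = length(x$unmatched_exposed),
    n_rejected = nrow(x$log),
    attrition_consistent = attr(x$attrition, "consistent"),
    seed = x$seed
  )
}

#' @rdname tidiers
#' @method tidy ehr_rates
#' @export
tidy.ehr_rates <- function(x, ...) {
  out <- as_tibble(x)
  if (attr(x, "measure") == "incidence") {
    rename(out, estimate = "rate_per_1e5", conf.low = "rate_lower",
      conf.high = "rate_upper")
  } else {
    rename(out, estimate = "prevalence", conf.low = "prev_lower",
      conf.high = "prev_upper")
  }
}

#' Plots for extraction results
#'
#' `autoplot()` on an extraction draws the attrition profile (rejection
#' counts by stage and reason); on a rate summary, the stratum estimates
#' with their confidence intervals.  `plot_attrition()` and `plot_rates()`
#' are the underlying verbs.
#'
#' @param object an `ehr_extraction` or `ehr_rates`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_attrition <- function(object) {
  stopifnot(inherits(object, "ehr_extraction"))
  dat <- as_tibble(object$attrition)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$count, y = .data$reason)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$stage), scales = "free_y",
      space = "free_y") +
    ggplot2::labs(x = "patients rejected", y = NULL,
      title = "Attrition by stage and documented reason") +
    ggplot2::theme_minimal()
}

#' @rdname plot_attrition
#' @export
plot_rates <- function(object) {
  stopifnot(inherits(object, "ehr_rates"))
  dat <- tidy(object)
  strata <- setdiff(names(dat), c("events", "person_years", "cases", "population",
    "estimate", "conf.low", "conf.high", "rate_undefined"))
  dat$stratum <- if (length(strata)) {
    do.call(paste, c(dat[strata], sep = " / "))
  } else {
    "overall"
  }
  ylab <- if (attr(object, "measure") == "incidence") {
    "incidence rate per 100,000 person-years"
  } else {
    "prevalence"
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$stratum, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high)) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}

#' @rdname plot_attrition
#' @method autoplot ehr_extraction
#' @export
autoplot.ehr_extraction <- function(object, ...) plot_attrition(object)

#' @rdname plot_attrition
#' @method autoplot ehr_rates
#' @export
autoplot.ehr_rates <- function(object, ...) plot_rates(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
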
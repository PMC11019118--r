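#' FDR plot of a rhythm screen
#'
#' Plots each feature's -log10 p-value against its BH q-value, colouring
#' the significant set -- the visual companion of a screen at a given q
#' threshold.
#'
#' @param object A `chrono_screen` from [jtk_screen()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot chrono_screen
#' @export
autoplot.chrono_screen <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q_value,
                                   y = -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = attr(object, "q_threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = "BH q-value", y = "-log10 p",
                  title = paste("JTK rhythm screen:",
                                attr(object, "group"))) +
    ggplot2::theme_minimal()
}

#' Scores plot of an OPLS model
#'
#' Predictive scores (LV1) against the first orthogonal scores (LVo1);
#' with no orthogonal component the sample index is used for the y axis.
#'
#' @param object An `opls` model.
#' @param colour Optional vector (e.g. ZT hours) to colour points by.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot opls
#' @export
autoplot.opls <- function(object, colour = NULL, ...) {
  df <- tibble(LV1 = object$t,
               LVo1 = if (object$n_ortho > 0) object$T_o[, 1]
                 else seq_along(object$t))
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$LV1, y = .data$LVo1)) +
    ggplot2::labs(x = "LV1 (predictive)",
                  y = if (object$n_ortho > 0) "LVo1 (orthogonal)"
                    else "sample index") +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
      ggplot2::labs(colour = "ZT")
}

#' Daily sleep profile plot
#'
#' Mean sleep per 30-minute bin across flies, per genotype if present.
#'
#' @param data Activity tibble (`fly_id`, `minute`, `count`, optionally
#'   `genotype`) after artifact filtering.
#' @param min_bout Sleep definition (default 5 minutes).
#' @return A ggplot object.
#' @export
plot_sleep_profile <- function(data, min_bout = 5) {
  data <- arrange(data, .data$fly_id, .data$minute)
  data <- data |>
    group_by(.data$fly_id) |>
    mutate(asleep = score_sleep(.data$count, min_bout)$sleep) |>
    ungroup() |>
    mutate(bin = (((.data$minute - 1) %% 1440) %/% 30) / 2)
  keys <- intersect(c("bin", "genotype"), names(data))
  prof <- data |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(sleep_per_30min = 30 * mean(.data$asleep),
              .groups = "drop")
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$bin,
                                          y = .data$sleep_per_30min))
  if ("genotype" %in% keys)
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$genotype))
  else p <- p + ggplot2::geom_line()
  p + ggplot2::labs(x = "hour of day", y = "sleep (min / 30 min)") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the loadings and weights of an OPLS model
#'
#' One row per feature: predictive weight `w` and loading `p`, plus the
#' first orthogonal weight/loading when present.
#'
#' @param x An `opls` model.
#' @param ... Ignored.
#' @return A tibble.
#' @method tidy opls
#' @export
tidy.opls <- function(x, ...) {
  out <- tibble(feature_id = x$features %||% seq_along(x$w),
                weight = x$w, loading = x$p)
  if (x$n_ortho > 0) {
    out$weight_ortho1 <- x$W_o[, 1]
    out$loading_ortho1 <- x$P_o[, 1]
  }
  out
}

#' One-row model summary of an OPLS model
#'
#' @param x An `opls` model.
#' @param ... Ignored.
#' @return A one-row tibble: `n_ortho`, `R2Y`, `R2X_pred`, `R2X_ortho`.
#' @method glance opls
#' @export
glance.opls <- function(x, ...) {
  tibble(n_ortho = x$n_ortho, R2Y = x$R2Y, R2X_pred = x$R2X_pred,
         R2X_ortho = x$R2X_ortho)
}

#' Tidy an OPLS significance verdict
#'
#' @param x An `opls_verdict`.
#' @param ... Ignored.
#' @return One-row tibble with the CV-ANOVA statistics, Q2cum and the
#'   verdict.
#' @method glance opls_verdict
#' @export
glance.opls_verdict <- function(x, ...) {
  bind_cols(tibble(group = x$group %||% NA_character_,
                   n_ortho = x$n_ortho, Q2cum = x$Q2cum,
                   R2Y = x$model$R2Y),
            x$anova,
            tibble(significant = x$significant))
}
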
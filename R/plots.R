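# Plot methods: reward decomposition / cumulative reward for episode
# results and a 2D stick-figure replay of a trajectory log.

#' Plot an episode result
#'
#' Cumulative per-step reward with the final three-term decomposition in
#' the subtitle.
#'
#' @param object An [episode_result()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.episode_result <- function(object, ...) {
  df <- tibble::tibble(step = seq_along(object$reward_trace),
                       cumulative = cumsum(object$reward_trace))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$cumulative)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "simulation step", y = "cumulative reward",
      title = sprintf("J = %.2f", object$J),
      subtitle = sprintf("R_alive = %.2f   R_step = %.2f   R_target = %.2f",
                         object$R_alive, object$R_step, object$R_target)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stick-figure replay of a trajectory
#'
#' Draws the walker (trunk line, both legs, feet) at regularly spaced
#' frames of a trajectory log, displaced along the travelled distance.
#'
#' @param log Trajectory tibble or CSV path.
#' @param model A `walker_config` for the segment lengths.
#' @param every Frame spacing in control steps.
#' @return A ggplot object.
#' @export
plot_replay <- function(log, model = default_walker_config(), every = 50) {
  if (is.character(log)) log <- read_trajectory(log)
  lth <- model$segments$thigh$length
  lsh <- model$segments$shank$length
  lft <- 0.18
  frames <- seq(1, nrow(log), by = every)
  segs <- purrr::map_dfr(frames, function(i) {
    r <- log[i, ]
    hip <- c(r$pel_x, r$pel_height)
    th <- r$pel_pitch
    trunk <- hip + 0.55 * c(-sin(th), cos(th))
    leg <- function(hipang, kneang, ankang, side) {
      a1 <- th + hipang
      knee <- hip + lth * c(sin(a1), -cos(a1))
      a2 <- a1 + kneang
      ank <- knee + lsh * c(sin(a2), -cos(a2))
      a3 <- a2 + ankang
      toe <- ank + lft * c(cos(a3), sin(a3))
      tibble::tibble(
        x = c(hip[1], knee[1], ank[1]), y = c(hip[2], knee[2], ank[2]),
        xend = c(knee[1], ank[1], toe[1]), yend = c(knee[2], ank[2], toe[2]),
        part = side)
    }
    dplyr::bind_rows(
      tibble::tibble(x = hip[1], y = hip[2], xend = trunk[1], yend = trunk[2],
                     part = "trunk"),
      leg(r$hip_r, r$knee_r, r$ankle_r, "right"),
      leg(r$hip_l, r$knee_l, r$ankle_l, "left")) |>
      dplyr::mutate(frame = i)
  })
  ggplot2::ggplot(segs) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$part)) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_manual(values = c(trunk = "black", right = "firebrick",
                                            left = "steelblue")) +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}
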
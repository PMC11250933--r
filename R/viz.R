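#' @title Single-admission ARDS graph
#' @name viz
#' @description
#' One figure integrating every component of the Berlin evaluation on a
#' shared time axis (days since admission): the P/F ratio series with the
#' 300-mmHg threshold, the PEEP series with the 5-cmH2O threshold, a rug of
#' note-level evidence (positive/negative bilateral-infiltrate radiographs,
#' HF/FO evidence), shaded ventilation episodes and BI validity windows, and
#' a vertical onset marker for positive verdicts.
NULL

#' Render the ARDS graph for one admission
#'
#' Writes a stacked-panel figure (P/F ratio, PEEP, evidence rug) aligned on
#' days since admission. Ventilation episodes are shaded across panels, BI
#' validity windows are shaded in the P/F panel, and a vertical line marks
#' the onset when the verdict is positive. Output format follows the file
#' extension: `.png` (default), `.svg` or `.pdf`. Empty series render as
#' empty panels rather than errors.
#'
#' @param admission An `admission_record`.
#' @param verdict The admission's `ards_verdict`.
#' @param timeline The admission's [evidence_timeline()].
#' @param out_path Output image path.
#' @param config The [berlin_config()] used for the verdict (thresholds and
#'   windows to display).
#' @return The assembled plot object, invisibly (the file is written as a
#'   side effect).
#' @export
render_ards_graph <- function(admission, verdict, timeline, out_path,
                              config = berlin_config()) {
  if (!dir.exists(dirname(out_path))) {
    stop("output directory does not exist: ", dirname(out_path), call. = FALSE)
  }
  d <- 1 / 1440  # minutes -> days
  pf <- pf_series(admission, config)
  peep <- obs_series(admission, "peep")
  windows <- build_bi_windows(timeline, config)
  vent <- admission$vent_episodes
  vent$end <- ifelse(is.na(vent$extubation), admission$discharge_time,
                     vent$extubation)
  ev <- rbind(
    if (length(timeline$bi_positive_times) > 0)
      data.frame(time = timeline$bi_positive_times, kind = "BI positive"),
    if (length(timeline$bi_negative_times) > 0)
      data.frame(time = timeline$bi_negative_times, kind = "BI negative"),
    if (length(timeline$hffo_times) > 0)
      data.frame(time = timeline$hffo_times, kind = "HF/FO"))

  xlim <- c(0, max(admission$discharge_time * d, 1))
  base <- function(p) {
    p <- p + ggplot2::coord_cartesian(xlim = xlim) + ggplot2::theme_bw() +
      ggplot2::theme(legend.position = "bottom")
    if (nrow(vent) > 0) {
      p <- p + ggplot2::geom_rect(
        data = vent, inherit.aes = FALSE, fill = "grey80", alpha = 0.4,
        ggplot2::aes(xmin = .data$intubation * d, xmax = .data$end * d,
                     ymin = -Inf, ymax = Inf))
    }
    if (verdict$ards) {
      p <- p + ggplot2::geom_vline(xintercept = verdict$onset_time * d,
                                   colour = "red", linetype = "solid",
                                   linewidth = 0.8)
    }
    p
  }

  p_pf <- ggplot2::ggplot(pf, ggplot2::aes(x = .data$time * d,
                                           y = .data$pf_ratio))
  p_pf <- base(p_pf) +
    ggplot2::geom_hline(yintercept = config$pf_max, linetype = "dashed",
                        colour = "steelblue")
  if (nrow(windows) > 0) {
    p_pf <- p_pf + ggplot2::geom_rect(
      data = windows, inherit.aes = FALSE, fill = "palegreen", alpha = 0.25,
      ggplot2::aes(xmin = .data$lo * d, xmax = .data$hi * d,
                   ymin = -Inf, ymax = Inf))
  }
  if (nrow(pf) > 1) p_pf <- p_pf + ggplot2::geom_line(colour = "grey40")
  if (nrow(pf) > 0) p_pf <- p_pf + ggplot2::geom_point(size = 1.2)
  p_pf <- p_pf +
    ggplot2::labs(y = "PaO2/FiO2 (mmHg)", x = NULL,
                  title = sprintf("%s - %s", admission$admission_id,
                                  if (verdict$ards)
                                    sprintf("ARDS (%s), onset day %.1f",
                                            verdict$severity,
                                            verdict$onset_time * d)
                                  else sprintf("not ARDS (%s)",
                                               verdict$failed_reason)))

  p_peep <- ggplot2::ggplot(peep, ggplot2::aes(x = .data$time * d,
                                               y = .data$value))
  p_peep <- base(p_peep) +
    ggplot2::geom_hline(yintercept = config$peep_min, linetype = "dashed",
                        colour = "steelblue")
  if (nrow(peep) > 1) p_peep <- p_peep + ggplot2::geom_step(colour = "grey40")
  if (nrow(peep) > 0) p_peep <- p_peep + ggplot2::geom_point(size = 1)
  p_peep <- p_peep + ggplot2::labs(y = "PEEP (cmH2O)", x = NULL)

  p_ev <- ggplot2::ggplot()
  if (!is.null(ev) && nrow(ev) > 0) {
    p_ev <- ggplot2::ggplot(ev, ggplot2::aes(x = .data$time * d,
                                             y = .data$kind,
                                             colour = .data$kind,
                                             shape = .data$kind)) +
      ggplot2::geom_point(size = 2.5) +
      ggplot2::scale_colour_manual(values = c("BI positive" = "forestgreen",
                                              "BI negative" = "orange",
                                              "HF/FO" = "purple"))
  }
  p_ev <- base(p_ev) +
    ggplot2::labs(y = NULL, x = "days since admission") +
    ggplot2::guides(colour = "none", shape = "none")

  fig <- patchwork::wrap_plots(p_pf, p_peep, p_ev, ncol = 1,
                               heights = c(3, 2, 1))
  ext <- tolower(tools::file_ext(out_path))
  if (ext == "svg") {
    grDevices::svg(out_path, width = 9, height = 7)
  } else if (ext == "pdf") {
    grDevices::pdf(out_path, width = 9, height = 7)
  } else {
    grDevices::png(out_path, width = 9, height = 7, units = "in", res = 110)
  }
  print(fig)
  grDevices::dev.off()
  invisible(fig)
}
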
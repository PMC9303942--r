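# ggplot2 views of yield curves (optional: ggplot2 is in Suggests)

#' Plot a rescaled yield curve
#'
#' Total catch, nutrient yields, community biomass, fishable biomass and mean
#' maximum size as proportions of their maxima against the community fishing
#' level (effort multiplier) or exploitation rate.
#'
#' @param curve A `mny_yield_curve`.
#' @param x `"effort"` or `"exploitation_rate"`.
#' @return A ggplot object.
#' @export
plot_yield_curve <- function(curve, x = c("effort", "exploitation_rate")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_yield_curve needs the ggplot2 package")
  x <- match.arg(x)
  df <- rescale_curves(curve)
  series <- setdiff(names(df), c("effort", "exploitation_rate",
                                 "n_collapsed"))
  long <- data.frame(
    xval = rep(df[[x]], length(series)),
    series = rep(series, each = nrow(df)),
    value = unlist(df[series], use.names = FALSE))
  ggplot2::ggplot(long, ggplot2::aes(xval, value, colour = series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (x == "effort") "community fishing level (x F_MSY)"
                  else "exploitation rate (catch / biomass)",
                  y = "proportion of maximum", colour = NULL) +
    ggplot2::theme_minimal()
}
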
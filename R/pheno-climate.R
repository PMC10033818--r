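# Climate-anomaly analysis (Lamb standardized anomalies over a reference
# period, growth-season aggregation, period contrasts) and the temporal
# days-to-heading phenotype contrast.

#' Aggregate a monthly climate series over a season
#'
#' Rainfall is summed and temperatures averaged over the requested months of
#' each year (default June-October, the crops' growth season). Years missing
#' any requested month are flagged missing.
#'
#' @param series A `climate_series` data.frame (station, variable, year,
#'   month, value), e.g. from [simulate_climate_series()] or read from a
#'   delimited year-by-month table via [read_climate_table()].
#' @param months Months to aggregate (default `6:10`).
#' @return Data.frame: year, value (`NA` for incomplete years).
#' @export
season_aggregate <- function(series, months = 6:10) {
  stopifnot(all(months %in% 1:12))
  variable <- series$variable[1]
  agg_fun <- if (identical(variable, "rain")) sum else mean
  sub <- series[series$month %in% months, , drop = FALSE]
  years <- sort(unique(series$year))
  value <- vapply(years, function(y) {
    v <- sub$value[sub$year == y]
    if (length(v) < length(months) || anyNA(v)) return(NA_real_)
    agg_fun(v)
  }, numeric(1))
  data.frame(year = years, value = value)
}

#' Read a delimited year-by-month climate table
#'
#' First column the year, then 12 monthly columns; extra columns ignored.
#' @param path Path to the delimited file.
#' @param variable `"rain"`, `"tmin"` or `"tmax"`.
#' @param station Station label.
#' @export
read_climate_table <- function(path, variable = c("rain", "tmin", "tmax"),
                               station = NA_character_) {
  variable <- match.arg(variable)
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(dt) < 13L) stop("expected a year column plus 12 monthly columns")
  out <- data.frame(station = station, variable = variable,
                    year = rep(as.integer(dt[[1]]), each = 12L),
                    month = rep(1:12, nrow(dt)),
                    value = as.numeric(t(as.matrix(dt[, 2:13]))))
  class(out) <- c("climate_series", "data.frame")
  out
}

#' Standardized climate anomalies (Lamb index)
#'
#' \eqn{I_i = (X_i - \bar X) / \sigma}, where the mean and standard
#' deviation are taken over a reference period considered climatologically
#' normal (default 1961-1990, the WMO normal).
#'
#' @param yearly Data.frame with columns year and value, e.g. from
#'   [season_aggregate()].
#' @param ref_period Length-2 vector of first and last reference year.
#' @param sd_type `"sample"` (n - 1 denominator, default) or `"population"`.
#' @return Data.frame of class `anomaly_series`: year, value, index; the
#'   reference mean, sd and period are attached as attributes.
#' @export
lamb_index <- function(yearly, ref_period = c(1961, 1990),
                       sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  ref <- yearly$value[yearly$year >= ref_period[1] &
                        yearly$year <= ref_period[2] & !is.na(yearly$value)]
  if (length(ref) < 2L) stop("need >= 2 reference years with data")
  m <- mean(ref)
  s <- sd(ref)
  if (sd_type == "population") s <- s * sqrt((length(ref) - 1) / length(ref))
  if (s == 0) {
    # a perfectly flat series has zero anomaly everywhere by convention;
    # a zero-variance reference with off-reference departures is undefined
    if (all(yearly$value == m, na.rm = TRUE)) {
      idx <- ifelse(is.na(yearly$value), NA_real_, 0)
    } else {
      stop("zero reference-period standard deviation")
    }
  } else {
    idx <- (yearly$value - m) / s
  }
  out <- data.frame(year = yearly$year, value = yearly$value, index = idx)
  attr(out, "ref_mean") <- m
  attr(out, "ref_sd") <- s
  attr(out, "ref_period") <- ref_period
  class(out) <- c("anomaly_series", "data.frame")
  out
}

#' Difference of period means
#'
#' Mean over `period_b` minus mean over `period_a` (e.g. 1991-2010 versus
#' the 1961-1990 reference).
#'
#' @param yearly Data.frame with year and value columns.
#' @param period_a,period_b Year vectors or length-2 (first, last) ranges.
#' @return List: mean_a, mean_b, difference, n_a, n_b.
#' @export
period_contrast <- function(yearly, period_a, period_b) {
  expand <- function(p) if (length(p) == 2L) seq(p[1], p[2]) else p
  va <- yearly$value[yearly$year %in% expand(period_a) & !is.na(yearly$value)]
  vb <- yearly$value[yearly$year %in% expand(period_b) & !is.na(yearly$value)]
  if (!length(va) || !length(vb)) stop("empty period")
  list(mean_a = mean(va), mean_b = mean(vb),
       difference = mean(vb) - mean(va),
       n_a = length(va), n_b = length(vb))
}

#' Temporal days-to-heading contrast for one genetic group
#'
#' Collect-wise mean DTHD, the advance (collect 1 minus collect 2, so a
#' positive value is an earlier heading in the recent collect), a Welch
#' two-sample t test, and per-collect Shapiro-Wilk normality flags reported
#' as caveats (heading-date distributions of landrace panels are often
#' non-normal).
#'
#' @param pheno Data.frame of phenotype records (accession, group, collect,
#'   dthd), e.g. from [simulate_phenotypes()].
#' @param group Genetic group label to contrast.
#' @return List: group, mean_1, mean_2, advance, t_stat, p_value, n_1, n_2,
#'   normal_1, normal_2 (Shapiro-Wilk p > 0.05).
#' @export
dthd_contrast <- function(pheno, group) {
  sub <- pheno[pheno$group == group, , drop = FALSE]
  if (!nrow(sub)) stop("group not present: ", group)
  d1 <- sub$dthd[sub$collect == 1]
  d2 <- sub$dthd[sub$collect == 2]
  if (length(d1) < 2L || length(d2) < 2L) {
    stop("need >= 2 records per collect in group ", group)
  }
  tt <- t.test(d1, d2)
  norm_p <- function(x) {
    if (length(x) >= 3L && length(x) <= 5000L) shapiro.test(x)$p.value
    else NA_real_
  }
  list(group = group, mean_1 = mean(d1), mean_2 = mean(d2),
       advance = mean(d1) - mean(d2),
       t_stat = unname(tt$statistic), p_value = tt$p.value,
       n_1 = length(d1), n_2 = length(d2),
       normal_1 = norm_p(d1) > 0.05, normal_2 = norm_p(d2) > 0.05)
}

#' Bar plot of standardized anomalies
#'
#' Lamb-index bars by year, positive and negative anomalies coloured apart.
#' Requires ggplot2.
#' @param anomalies An `anomaly_series` from [lamb_index()].
#' @export
plot_anomaly_bars <- function(anomalies) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- as.data.frame(anomalies)
  df$sign <- ifelse(df$index >= 0, "positive", "negative")
  ggplot2::ggplot(df, ggplot2::aes(x = year, y = index, fill = sign)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(positive = "steelblue",
                                          negative = "indianred")) +
    ggplot2::labs(x = "year", y = "standardized anomaly (Lamb index)")
}
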
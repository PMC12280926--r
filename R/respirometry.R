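#' Construct an oxygen trace
#'
#' Container for a closed-respirometry dissolved-oxygen time series and its
#' chamber metadata.
#'
#' @param time Sampling times in minutes, strictly increasing, length >= 3.
#' @param o2 Dissolved oxygen concentrations (mg O2 L^-1), non-negative.
#' @param chamber_vol Chamber volume (L).
#' @param fish_vol Fish volume (L); defaults to \code{mass / 1000}
#'   (near-neutral density) when not measured.
#' @param mass Fish mass (kg).
#' @param temperature,salinity Optional metadata.
#' @return Object of class \code{oxygen_trace}.
#' @export
oxygen_trace <- function(time, o2, chamber_vol, fish_vol = NULL, mass,
                         temperature = NA_real_, salinity = NA_real_) {
  fish_vol <- fish_vol %||% (mass / 1000)
  stopifnot(length(time) == length(o2), length(time) >= 3,
            all(diff(time) > 0), all(o2 >= 0),
            chamber_vol > fish_vol, fish_vol >= 0, mass > 0)
  structure(list(time = as.numeric(time), o2 = as.numeric(o2),
                 chamber_vol = chamber_vol, fish_vol = fish_vol,
                 mass = mass, temperature = temperature,
                 salinity = salinity),
            class = "oxygen_trace")
}

#' @export
print.oxygen_trace <- function(x, ...) {
  cat(sprintf(paste0("Oxygen trace: %d samples over %.1f min, ",
                     "%.2f -> %.2f mg O2/L\n"),
              length(x$time), diff(range(x$time)), x$o2[1],
              x$o2[length(x$o2)]))
  cat(sprintf("  chamber %.3f L, fish %.4f L, mass %.4f kg\n",
              x$chamber_vol, x$fish_vol, x$mass))
  invisible(x)
}

#' Read an oxygen trace from CSV
#'
#' Expects columns \code{time_min} and \code{o2_mg_per_l}; chamber
#' metadata (\code{chamber_vol}, \code{fish_vol}, \code{mass},
#' \code{temperature}, \code{salinity}) is taken from \code{# key=value}
#' header comments, overridable via \code{...}.
#'
#' @param path CSV file path.
#' @param ... Metadata overrides passed to \code{\link{oxygen_trace}}.
#' @return An \code{\link{oxygen_trace}}.
#' @export
read_o2_trace <- function(path, ...) {
  meta <- read_header_meta(path)
  df <- read.table(path, header = TRUE, sep = ",", comment.char = "#")
  stopifnot(all(c("time_min", "o2_mg_per_l") %in% names(df)))
  args <- modifyList(meta, list(...))
  do.call(oxygen_trace, c(list(time = df$time_min, o2 = df$o2_mg_per_l),
                          args))
}

#' Write an oxygen trace to CSV
#'
#' @param trace An \code{\link{oxygen_trace}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_o2_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%.10g",
                     c("chamber_vol", "fish_vol", "mass"),
                     c(trace$chamber_vol, trace$fish_vol, trace$mass)), con)
  write.table(data.frame(time_min = trace$time, o2_mg_per_l = trace$o2),
              con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Parse "# key=value" comment headers at the top of a delimited file.
read_header_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- grep("^#", lines, value = TRUE)
  out <- list()
  for (ln in lines) {
    kv <- sub("^#\\s*", "", ln)
    if (!grepl("=", kv)) next
    key <- trimws(sub("=.*", "", kv))
    val <- trimws(sub("^[^=]*=", "", kv))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (is.na(num)) val else num
  }
  out
}

#' Slope of oxygen decline
#'
#' Ordinary least-squares slope of dissolved O2 against time over an
#' optional window, reported as the magnitude of decline (positive while
#' oxygen falls). A rising O2 trend triggers a warning (aeration or leak).
#' Alternatively, \code{roll_width} selects the window of that width (in
#' minutes) maximizing the fit r-squared, a common practice when parts of
#' a trace are disturbed.
#'
#' @param trace An \code{\link{oxygen_trace}}.
#' @param window Optional \code{c(start, end)} in minutes (inclusive).
#' @param roll_width Optional rolling-window width in minutes; overrides
#'   \code{window}.
#' @return List with \code{slope} (mg L^-1 min^-1, positive = declining),
#'   \code{r2}, and the \code{window} used.
#' @examples
#' tr <- oxygen_trace(0:10, 8 - 0.05 * 0:10, chamber_vol = 0.615,
#'                    mass = 0.01)
#' o2_slope(tr)$slope  # 0.05
#' @export
o2_slope <- function(trace, window = NULL, roll_width = NULL) {
  stopifnot(inherits(trace, "oxygen_trace"))
  if (!is.null(roll_width)) {
    starts <- trace$time[trace$time + roll_width <= max(trace$time)]
    fits <- lapply(starts, function(s)
      o2_slope(trace, window = c(s, s + roll_width)))
    best <- which.max(vapply(fits, `[[`, numeric(1), "r2"))
    return(fits[[best]])
  }
  keep <- rep(TRUE, length(trace$time))
  if (!is.null(window))
    keep <- trace$time >= window[1] & trace$time <= window[2]
  t <- trace$time[keep]; y <- trace$o2[keep]
  if (length(t) < 3) stop("fewer than 3 samples in window")
  if (var(t) == 0) stop("constant time in window")
  fit <- lm(y ~ t)
  b <- unname(coef(fit)[2])
  if (b > 0) warning("oxygen increasing over window (aeration or leak?)")
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum(residuals(fit)^2) / sst
  list(slope = -b, r2 = r2,
       window = window %||% range(trace$time))
}

#' Oxygen consumption rate from a trace
#'
#' Mass-specific metabolic rate
#' \deqn{MO_2 = \mathrm{slope} \times 60 \times (V_{chamber} - V_{fish})
#'   \times M^{-0.9},}
#' where the slope is the O2 decline in mg L^-1 min^-1, the factor 60
#' converts to hourly units, the net water volume is in litres, and the
#' exponent 0.9 corrects for the allometric scaling of metabolic rate with
#' body mass M (kg). Units: mg O2 kg^-1 h^-1.
#'
#' @inheritParams o2_slope
#' @return Scalar MO2 (mg O2 kg^-1 h^-1) with attributes \code{slope} and
#'   \code{r2}.
#' @examples
#' tr <- oxygen_trace(0:10, 8 - 0.05 * 0:10, chamber_vol = 0.61,
#'                    fish_vol = 0.01, mass = 0.01)
#' mo2_from_trace(tr)  # 113.57
#' @export
mo2_from_trace <- function(trace, window = NULL, roll_width = NULL) {
  if (trace$mass <= 0) stop("mass must be positive")
  s <- o2_slope(trace, window, roll_width)
  v <- trace$chamber_vol - trace$fish_vol
  mo2 <- s$slope * 60 * v * trace$mass^-0.9
  structure(mo2, slope = s$slope, r2 = s$r2)
}

#' Net hovering cost and hover-to-rest ratio
#'
#' @param hover,rest MO2 during hovering and at rest (mg O2 kg^-1 h^-1);
#'   \code{rest} must be positive.
#' @return List with \code{mo2_net = hover - rest} and
#'   \code{ratio = hover / rest}.
#' @export
net_and_ratio <- function(hover, rest) {
  if (any(rest <= 0)) stop("rest MO2 must be positive")
  list(mo2_net = hover - rest, ratio = hover / rest)
}

#' Energetic cost of a hovering bout
#'
#' Converts a net oxygen consumption rate to energy via the oxy-calorific
#' equivalent of 3.25 cal per mg O2 (thermochemical calorie, 4.184 J):
#' \code{energy = mo2_net * (minutes/60) * 3.25 * 4.184 / 1000} kJ kg^-1.
#'
#' @param mo2_net Net MO2 (mg O2 kg^-1 h^-1).
#' @param minutes Bout duration in minutes (default 10).
#' @return Energy in kJ kg^-1.
#' @examples
#' energy_kj(120)  # 0.272 kJ/kg for 10 min
#' @export
energy_kj <- function(mo2_net, minutes = 10) {
  stopifnot(minutes > 0)
  mo2_net * (minutes / 60) * 3.25 * 4.184 / 1000
}

#' Full respirometry summary for one individual
#'
#' Convenience wrapper running \code{\link{mo2_from_trace}} on the hovering
#' and resting traces and assembling net cost, ratio and the 10-minute
#' energetic cost.
#'
#' @param hover_trace,rest_trace \code{\link{oxygen_trace}} objects.
#' @param minutes Bout duration for the energy conversion.
#' @param ... Passed to \code{\link{mo2_from_trace}} (window selection).
#' @return Object of class \code{respirometry} (a list with
#'   \code{mo2_hover}, \code{mo2_rest}, \code{mo2_net}, \code{ratio},
#'   \code{energy_kj}, \code{slope_hover}, \code{slope_rest},
#'   \code{r2_hover}, \code{r2_rest}).
#' @export
respirometry <- function(hover_trace, rest_trace, minutes = 10, ...) {
  h <- mo2_from_trace(hover_trace, ...)
  r <- mo2_from_trace(rest_trace, ...)
  nr <- net_and_ratio(as.numeric(h), as.numeric(r))
  structure(list(mo2_hover = as.numeric(h), mo2_rest = as.numeric(r),
                 mo2_net = nr$mo2_net, ratio = nr$ratio,
                 energy_kj = energy_kj(nr$mo2_net, minutes),
                 minutes = minutes,
                 slope_hover = attr(h, "slope"), slope_rest = attr(r, "slope"),
                 r2_hover = attr(h, "r2"), r2_rest = attr(r, "r2")),
            class = "respirometry")
}

#' @export
print.respirometry <- function(x, ...) {
  cat("Respirometry summary (mg O2 kg^-1 h^-1):\n")
  cat(sprintf("  MO2 hover %.2f, rest %.2f, net %.2f, ratio %.2f\n",
              x$mo2_hover, x$mo2_rest, x$mo2_net, x$ratio))
  cat(sprintf("  energy for %g min: %.3f kJ/kg\n", x$minutes, x$energy_kj))
  invisible(x)
}
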
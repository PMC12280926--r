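#' Build a synthetic-data plan
#'
#' A \code{synth_plan} bundles every parameter of the synthetic-data
#' generators so that a single object (and its seed) fully determines all
#' generated inputs: morphology tables with linear metabolic responses,
#' oxygen-decline traces, oscillatory 3D landmark series and phylogenies
#' with optional Brownian trait signal. Identical plans yield identical
#' outputs.
#'
#' Defaults emulate the study conditions the package is built around:
#' 13 species, the packaged reference coefficient vectors
#' (\code{\link{hover_reference_coefs}}), response noise calibrated so the
#' full-model fits sit near R^2 of 0.86 (mo2net) and 0.63 (ratio) given the
#' documented predictor ranges, 60 min oxygen traces sampled every minute,
#' and 1000 fps landmark recordings with 4 deg roll and 2 deg pitch
#' amplitudes.
#'
#' @param seed Integer seed; fixes all generator randomness.
#' @param n_species Number of species rows to generate.
#' @param coeffs Coefficient vector (intercept + 7 predictors) for the
#'   \code{mo2net} response, in response units per predictor unit.
#' @param ratio_coeffs Coefficient vector for the \code{ratio} response.
#' @param predictor_ranges 7 x 2 matrix of (low, high) uniform bounds per
#'   predictor, rows named as \code{\link{hover_predictors}}.
#' @param fineness_cor Correlation (Gaussian copula) between the two
#'   fineness-ratio predictors; 0 (default) draws them independently,
#'   which maximizes identifiability for recovery tests.
#' @param noise_sd,ratio_noise_sd Response noise standard deviations
#'   (response units).
#' @param trace_params List: \code{duration_min}, \code{interval_min},
#'   \code{o2_noise_sd} (mg/L), \code{o2_init} (mg/L).
#' @param motion_params List: \code{roll_amp_deg}, \code{pitch_amp_deg},
#'   \code{fin_freq_hz}, \code{phase_lag_deg}, \code{stroke_path}
#'   (\code{"circle"} or \code{"figure8"}), \code{stroke_radius} (same
#'   units as \code{bl}), \code{fps}, \code{duration_s}, \code{bl} (body
#'   length, cm).
#' @param tree_params List: \code{n_taxa}, \code{signal} (\code{"none"} or
#'   \code{"brownian"}), \code{brownian_sd}.
#' @return An object of class \code{synth_plan}.
#' @export
synth_plan <- function(seed = 1L,
                       n_species = 13L,
                       coeffs = hover_reference_coefs("mo2net"),
                       ratio_coeffs = hover_reference_coefs("ratio"),
                       predictor_ranges = default_predictor_ranges(),
                       fineness_cor = 0,
                       noise_sd = 170,
                       ratio_noise_sd = 0.75,
                       trace_params = list(duration_min = 60,
                                           interval_min = 1,
                                           o2_noise_sd = 0.01,
                                           o2_init = 8),
                       motion_params = list(roll_amp_deg = 4,
                                            pitch_amp_deg = 2,
                                            fin_freq_hz = 3,
                                            phase_lag_deg = 180,
                                            stroke_path = "circle",
                                            stroke_radius = 0.5,
                                            fps = 1000,
                                            duration_s = 2,
                                            bl = 3),
                       tree_params = list(n_taxa = 13L,
                                          signal = "none",
                                          brownian_sd = 1)) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_species >= 1, noise_sd >= 0, ratio_noise_sd >= 0,
            is.matrix(predictor_ranges), ncol(predictor_ranges) == 2,
            fineness_cor >= -1, fineness_cor <= 1,
            motion_params$fps > 0)
  if (any(predictor_ranges[, 1] > predictor_ranges[, 2]))
    stop("predictor_ranges must satisfy low <= high")
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 coeffs = coeffs, ratio_coeffs = ratio_coeffs,
                 predictor_ranges = predictor_ranges,
                 fineness_cor = fineness_cor,
                 noise_sd = noise_sd, ratio_noise_sd = ratio_noise_sd,
                 trace_params = trace_params, motion_params = motion_params,
                 tree_params = tree_params),
            class = "synth_plan")
}

#' Default uniform sampling bounds for the morphological predictors
#'
#' Bounds bracket the morphospace of small aquarium-sized near-neutrally
#' buoyant teleosts (1–20 g; fineness ratios spanning deep-bodied to
#' elongate; COM–COB dorsal–ventral offsets mostly negative, i.e. COB
#' ventral of COM; pectoral fins in the anterior third; caudal fin near the
#' posterior end).
#'
#' @return 7 x 2 matrix (low, high) with predictor row names.
#' @export
default_predictor_ranges <- function() {
  m <- rbind(
    mass           = c(0.001, 0.020),
    fineness_depth = c(2.2, 6.0),
    comcob_ap      = c(-0.10, 0.10),
    comcob_dv      = c(-0.20, 0.02),
    fineness_width = c(3.0, 9.0),
    pect_fin_ap    = c(0.15, 0.45),
    caud_fin_ap    = c(0.85, 1.00)
  )
  colnames(m) <- c("low", "high")
  m
}

#' Generate a synthetic species morphology table with metabolic responses
#'
#' Draws \code{n_species} predictor rows independently and uniformly within
#' the plan's ranges (optionally correlating the two fineness ratios via a
#' Gaussian copula) and computes linear responses
#' \code{response = intercept + sum(c_i * x_i) + Normal(0, noise_sd)} for
#' both \code{mo2net} and \code{ratio}. The exact noiseless responses are
#' returned alongside (\code{mo2net_true}, \code{ratio_true}) for test use.
#'
#' @param plan A \code{\link{synth_plan}}.
#' @return Data frame with columns \code{species}, the seven predictors,
#'   \code{mo2net}, \code{mo2net_true}, \code{ratio}, \code{ratio_true}.
#' @examples
#' tab <- gen_species_table(synth_plan(seed = 1, noise_sd = 0))
#' fit <- hover_lm(mo2_formula("mo2net"), tab)
#' coef(fit)  # recovers the reference vector exactly
#' @export
gen_species_table <- function(plan) {
  stopifnot(inherits(plan, "synth_plan"))
  preds <- hover_predictors()
  rng <- plan$predictor_ranges
  if (!all(preds %in% rownames(rng)))
    stop("predictor_ranges must have rows: ", paste(preds, collapse = ", "))
  rng <- rng[preds, , drop = FALSE]
  for (v in list(plan$coeffs, plan$ratio_coeffs))
    if (length(v) != length(preds) + 1L)
      stop("coefficient vector length must be n predictors + 1 (",
           length(preds) + 1L, "), got ", length(v))
  degen <- rng[, 1] == rng[, 2]
  if (sum(degen) > 1L)
    warning("more than one degenerate (low = high) predictor range: ",
            "the design is collinear and cannot be refit")
  n <- plan$n_species
  with_seed(plan$seed, function() {
    u <- matrix(runif(n * 7L), nrow = n, dimnames = list(NULL, preds))
    if (plan$fineness_cor != 0) {
      # Gaussian copula between the two fineness ratios
      z1 <- qnorm(u[, "fineness_depth"])
      z2 <- plan$fineness_cor * z1 +
        sqrt(1 - plan$fineness_cor^2) * qnorm(u[, "fineness_width"])
      u[, "fineness_width"] <- pnorm(z2)
    }
    x <- sweep(u, 2, rng[, 2] - rng[, 1], `*`)
    x <- sweep(x, 2, rng[, 1], `+`)
    lin <- function(cf) unname(cf[1] + drop(x %*% cf[-1]))
    mo2net_true <- lin(plan$coeffs)
    ratio_true <- lin(plan$ratio_coeffs)
    eps1 <- if (plan$noise_sd > 0) rnorm(n, 0, plan$noise_sd) else numeric(n)
    eps2 <- if (plan$ratio_noise_sd > 0)
      rnorm(n, 0, plan$ratio_noise_sd) else numeric(n)
    data.frame(species = sprintf("sp%02d", seq_len(n)), as.data.frame(x),
               mo2net = mo2net_true + eps1, mo2net_true = mo2net_true,
               ratio = ratio_true + eps2, ratio_true = ratio_true,
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic oxygen-decline trace
#'
#' Constructs a dissolved-oxygen time series whose noiseless slope is the
#' exact inversion of the metabolic-rate formula
#' \code{MO2 = slope * 60 * (chamber_vol - fish_vol) * mass^-0.9} for the
#' requested target, then adds Gaussian measurement noise per the plan's
#' \code{trace_params}. The generating slope and target are attached as
#' attributes for round-trip tests.
#'
#' @param target_mo2 Target oxygen consumption rate (mg O2 kg^-1 h^-1).
#' @param mass Fish mass (kg).
#' @param chamber_vol,fish_vol Chamber and fish volumes (L);
#'   \code{chamber_vol > fish_vol >= 0}.
#' @param plan A \code{\link{synth_plan}} supplying duration, sampling
#'   interval, noise and initial concentration.
#' @return An \code{\link{oxygen_trace}} with attributes \code{true_slope}
#'   (mg L^-1 min^-1) and \code{target_mo2}.
#' @export
gen_o2_trace <- function(target_mo2, mass, chamber_vol, fish_vol = 0,
                         plan = synth_plan()) {
  stopifnot(chamber_vol > fish_vol, fish_vol >= 0, mass > 0, target_mo2 >= 0)
  tp <- plan$trace_params
  slope <- target_mo2 / (60 * (chamber_vol - fish_vol) * mass^-0.9)
  t_min <- seq(0, tp$duration_min, by = tp$interval_min)
  o2_clean <- tp$o2_init - slope * t_min
  if (any(o2_clean < 0))
    stop("trace would be unphysical: implied O2 concentration drops below ",
         "0 mg/L within the duration (lower target_mo2 or duration, or ",
         "raise o2_init)")
  o2 <- o2_clean
  if (tp$o2_noise_sd > 0)
    o2 <- with_seed(plan$seed,
                    function() o2_clean + rnorm(length(o2_clean), 0,
                                                tp$o2_noise_sd))
  tr <- oxygen_trace(time = t_min, o2 = pmax(o2, 0),
                     chamber_vol = chamber_vol, fish_vol = fish_vol,
                     mass = mass)
  attr(tr, "true_slope") <- slope
  attr(tr, "target_mo2") <- target_mo2
  tr
}

# Canonical 15-landmark template for a fish of body length bl, in the body
# frame: x anterior->posterior from the snout, y lateral (left negative),
# z vertical. Units follow bl.
landmark_template <- function(bl) {
  rbind(
    snout           = c(0.00, 0,  0.00),
    eye             = c(0.15, 0,  0.05),
    eye_bottom      = c(0.15, 0,  0.00),
    dorsal_fin_tip  = c(0.50, 0,  0.20),
    pect_base_l     = c(0.30, -0.08, 0.00),
    pect_tip_l      = c(0.30, -0.08, 0.00),  # offset by stroke path
    pect_base_r     = c(0.30,  0.08, 0.00),
    pect_tip_r      = c(0.30,  0.08, 0.00),
    pelv_base_l     = c(0.45, -0.05, -0.10),
    pelv_tip_l      = c(0.50, -0.07, -0.15),
    pelv_base_r     = c(0.45,  0.05, -0.10),
    pelv_tip_r      = c(0.50,  0.07, -0.15),
    anal_fin_tip    = c(0.70, 0, -0.15),
    caudal_peduncle = c(0.90, 0,  0.00),
    caudal_fin_tip  = c(1.05, 0,  0.00)
  ) * bl
}

#' Generate a synthetic 3D landmark series
#'
#' Builds the 15 canonical body/fin landmarks of a hovering fish and
#' animates them: body landmarks are rigidly rotated about the body center
#' by sinusoidal roll (about the longitudinal axis) and pitch (about the
#' lateral axis) at the plan's amplitudes and the fin-beat frequency;
#' pectoral fin tips additionally follow a circular or figure-8 (1:2
#' Lissajous) stroke path in the transverse plane at the fin frequency,
#' with the stated left–right phase lag. The left fin leads: outward
#' abduction of the left tip is \code{r*sin(2*pi*f*t)}, of the right tip
#' \code{r*sin(2*pi*f*t - lag)}.
#'
#' @param plan A \code{\link{synth_plan}}; \code{motion_params$fps} must be
#'   at least 20 times the fin frequency (adequate sampling) and rotation
#'   amplitudes must be below 90 degrees.
#' @return A \code{\link{landmark_series}} whose \code{truth} element
#'   records every generating parameter.
#' @export
gen_landmark_series <- function(plan) {
  mp <- plan$motion_params
  if (mp$roll_amp_deg >= 90 || mp$pitch_amp_deg >= 90)
    stop("rotation amplitude >= 90 degrees is gimbal-degenerate")
  if (mp$fps < 2 * mp$fin_freq_hz * 10)
    stop("fps must be at least 20 x fin frequency for adequate sampling")
  bl <- mp$bl
  base <- landmark_template(bl)
  ctr <- c(0.45 * bl, 0, 0)
  tt <- seq(0, mp$duration_s, by = 1 / mp$fps)
  nt <- length(tt)
  f <- mp$fin_freq_hz
  lag <- mp$phase_lag_deg * pi / 180
  roll <- mp$roll_amp_deg * pi / 180 * sin(2 * pi * f * tt)
  pitch <- mp$pitch_amp_deg * pi / 180 * sin(2 * pi * f * tt + pi / 3)
  r <- mp$stroke_radius
  pts <- array(NA_real_, dim = c(nt, nrow(base), 3),
               dimnames = list(NULL, rownames(base), c("x", "y", "z")))
  for (i in seq_len(nt)) {
    th <- 2 * pi * f * tt[i]
    frame <- base
    # stroke path in the transverse (y-z) plane, abduction = outward y
    dy_l <- -r * sin(th)                 # left side: outward is -y
    dy_r <- r * sin(th - lag)
    if (identical(mp$stroke_path, "figure8")) {
      dz_l <- (r / 2) * sin(2 * th)
      dz_r <- (r / 2) * sin(2 * (th - lag))
    } else {
      dz_l <- -r * cos(th)
      dz_r <- -r * cos(th - lag)
    }
    frame["pect_tip_l", ] <- frame["pect_base_l", ] + c(0, dy_l, dz_l)
    frame["pect_tip_r", ] <- frame["pect_base_r", ] + c(0, dy_r, dz_r)
    cr <- cos(roll[i]); sr <- sin(roll[i])
    cp <- cos(pitch[i]); sp <- sin(pitch[i])
    rx <- rbind(c(1, 0, 0), c(0, cr, -sr), c(0, sr, cr))
    ry <- rbind(c(cp, 0, sp), c(0, 1, 0), c(-sp, 0, cp))
    pts[i, , ] <- t(ry %*% rx %*% (t(frame) - ctr) + ctr)
  }
  landmark_series(points = pts, fps = mp$fps, bl = bl,
                  truth = mp[c("roll_amp_deg", "pitch_amp_deg",
                               "fin_freq_hz", "phase_lag_deg",
                               "stroke_path", "stroke_radius")])
}

#' Generate a random tree with an optional Brownian trait
#'
#' Draws a random bifurcating topology on \code{n_taxa} tips and a trait
#' vector that is i.i.d. Normal when \code{signal = "none"} or evolved by
#' Brownian motion on unit-length branches when \code{signal = "brownian"}.
#'
#' @param plan A \code{\link{synth_plan}}; \code{tree_params$n_taxa} must
#'   be at least 4.
#' @return List with elements \code{tree} (an \code{ape} \code{phylo} with
#'   unit branch lengths) and \code{trait} (named by tip label).
#' @export
gen_tree_with_trait <- function(plan) {
  tp <- plan$tree_params
  if (tp$n_taxa < 4) stop("n_taxa must be >= 4")
  with_seed(plan$seed, function() {
    tree <- ape::rtree(tp$n_taxa)
    tree$edge.length <- rep(1, nrow(tree$edge))
    trait <- switch(tp$signal,
      none = setNames(rnorm(tp$n_taxa), tree$tip.label),
      brownian = ape::rTraitCont(tree, model = "BM",
                                 sigma = tp$brownian_sd),
      stop("tree_params$signal must be 'none' or 'brownian'"))
    list(tree = tree, trait = trait)
  })
}

#' Write a landmark series to TSV
#'
#' Long format: one row per frame and landmark with columns \code{frame},
#' \code{landmark}, \code{x}, \code{y}, \code{z}; \code{fps} and \code{bl}
#' are stored in \code{# key=value} header comments so the file is
#' self-describing.
#'
#' @param series A \code{\link{landmark_series}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_landmarks <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fps=%.10g", series$fps),
               sprintf("# bl=%.10g", series$bl)), con)
  nt <- dim(series$points)[1]
  nm <- dimnames(series$points)[[2]]
  df <- data.frame(
    frame = rep(seq_len(nt), times = length(nm)),
    landmark = rep(nm, each = nt),
    x = as.vector(series$points[, , 1]),
    y = as.vector(series$points[, , 2]),
    z = as.vector(series$points[, , 3]))
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
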
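#' Specify a synthetic abdominal slice phantom
#'
#' Builds the parametric description of a synthetic axial abdominal slice:
#' an elliptical body cross-section carrying a bright subcutaneous fat (SAT)
#' ring of per-quadrant thickness, scattered bright visceral fat (VAT)
#' blobs inside the lean interior, dark background, and optionally two
#' lateral arms with a fat rim. Fat is rendered hyperintense and lean
#' tissue intermediate, emulating the appearance of opposed-phase
#' T1-weighted slices where fat/water interfaces are sharply delineated.
#'
#' The SAT ring is asymmetric by default (thicker posterior quadrant) so
#' that its centroid is measurably displaced from the image center: the
#' downstream VAT/SAT delineation rule compares centroid-to-center
#' distances and degenerates on a perfectly symmetric ring.
#'
#' @param image_height_px,image_width_px Image dimensions in pixels.
#' @param body_center_offset_px Length-2 `(row, col)` displacement of the
#'   body ellipse center from the image center.
#' @param body_axes_px Length-2 semi-axes `(row, col)` of the body ellipse.
#' @param sat_ring_thickness_px Length-4 per-quadrant ring thickness
#'   `(anterior, right, posterior, left)` in pixels; anterior = top of image.
#' @param n_vat_blobs Number of disk-shaped VAT blobs.
#' @param vat_blob_radius_range_px Length-2 `(min, max)` blob radius.
#' @param include_arms Render two lateral fat-rimmed arm ellipses.
#' @param intensity_levels Named mean intensities in `[0, 1]` for
#'   `background`, `lean`, `fat`; must be strictly increasing in that order.
#' @param noise_sd Additive noise standard deviation (image clipped to `[0, 1]`).
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param seed Integer RNG seed; the phantom is a pure function of
#'   (spec, seed).
#' @return An object of class `phantom_spec`.
#' @seealso [generate_slice_phantom()]
#' @export
phantom_spec <- function(image_height_px = 176L,
                         image_width_px = 256L,
                         body_center_offset_px = c(0, 0),
                         body_axes_px = c(60, 72),
                         sat_ring_thickness_px = c(8, 10, 16, 10),
                         n_vat_blobs = 6L,
                         vat_blob_radius_range_px = c(3, 6),
                         include_arms = FALSE,
                         intensity_levels = c(background = 0.05, lean = 0.35, fat = 0.85),
                         noise_sd = 0,
                         noise_model = c("gaussian", "rician"),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(image_height_px >= 16, image_width_px >= 16,
            length(body_center_offset_px) == 2, length(body_axes_px) == 2,
            all(body_axes_px > 0), length(sat_ring_thickness_px) == 4,
            all(sat_ring_thickness_px > 0), n_vat_blobs >= 0,
            length(vat_blob_radius_range_px) == 2,
            vat_blob_radius_range_px[1] >= 1,
            vat_blob_radius_range_px[2] >= vat_blob_radius_range_px[1],
            noise_sd >= 0)
  lv <- intensity_levels
  if (!all(c("background", "lean", "fat") %in% names(lv))) {
    stop("intensity_levels must be named background/lean/fat", call. = FALSE)
  }
  if (!(lv[["fat"]] > lv[["lean"]] && lv[["lean"]] > lv[["background"]])) {
    stop("intensity levels must satisfy fat > lean > background", call. = FALSE)
  }
  if (any(lv < 0) || any(lv > 1)) stop("intensity levels must lie in [0, 1]", call. = FALSE)

  center <- c((image_height_px + 1) / 2, (image_width_px + 1) / 2) + body_center_offset_px
  if (center[1] - body_axes_px[1] < 1 || center[1] + body_axes_px[1] > image_height_px) {
    stop("body ellipse exceeds image bounds in the row dimension", call. = FALSE)
  }
  if (center[2] - body_axes_px[2] < 1 || center[2] + body_axes_px[2] > image_width_px) {
    stop("body ellipse exceeds image bounds in the col dimension", call. = FALSE)
  }
  if (max(sat_ring_thickness_px) >= min(body_axes_px)) {
    stop("SAT ring thickness must be smaller than the body semi-axes", call. = FALSE)
  }
  structure(list(image_height_px = as.integer(image_height_px),
                 image_width_px = as.integer(image_width_px),
                 body_center_offset_px = as.numeric(body_center_offset_px),
                 body_axes_px = as.numeric(body_axes_px),
                 sat_ring_thickness_px = as.numeric(sat_ring_thickness_px),
                 n_vat_blobs = as.integer(n_vat_blobs),
                 vat_blob_radius_range_px = as.numeric(vat_blob_radius_range_px),
                 include_arms = isTRUE(include_arms),
                 intensity_levels = lv,
                 noise_sd = as.numeric(noise_sd),
                 noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Normalized elliptical radius of every pixel w.r.t. center `ctr` and
# semi-axes `ax` (row axis first).
ellipse_rho <- function(grids, ctr, ax) {
  sqrt(((grids$row - ctr[1]) / ax[1])^2 + ((grids$col - ctr[2]) / ax[2])^2)
}

#' Generate a synthetic abdominal slice with ground truth
#'
#' Renders the phantom described by a [phantom_spec()] and returns the
#' intensity image together with the exact ground-truth compartment masks.
#' SAT, VAT, lean tissue, arms and background are mutually exclusive pixel
#' sets; with `noise_sd = 0` and no arms the image takes exactly the three
#' configured intensity levels. VAT blobs are placed by rejection sampling
#' inside the lean interior with a guaranteed gap between blobs so that
#' each blob is its own 8-connected component.
#'
#' @param spec A [phantom_spec()].
#' @param max_attempts Rejection-sampling attempts per VAT blob before
#'   giving up with an error.
#' @return A list with elements `image` (numeric matrix in `[0, 1]`),
#'   `ground_truth` (a [compartment_masks()] with `sat`, `vat`, `tat`),
#'   `arm_mask`, and `abdominal_mask` (the body ellipse; excludes arms).
#' @export
generate_slice_phantom <- function(spec, max_attempts = 200L) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$image_height_px; nc <- spec$image_width_px
  grids <- coord_grids(nr, nc)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2) + spec$body_center_offset_px
  ax <- spec$body_axes_px

  body <- ellipse_rho(grids, ctr, ax) <= 1

  # Per-quadrant ring thickness by pixel angle around the body center.
  # atan2(drow, dcol): 0 = image right, -pi/2 = up (anterior), +pi/2 = down.
  theta <- atan2(grids$row - ctr[1], grids$col - ctr[2])
  thick <- matrix(NA_real_, nr, nc)
  deg <- theta * 180 / pi
  t4 <- spec$sat_ring_thickness_px  # (anterior, right, posterior, left)
  thick[deg >= -135 & deg < -45] <- t4[1]
  thick[deg >= -45 & deg < 45] <- t4[2]
  thick[deg >= 45 & deg < 135] <- t4[3]
  thick[is.na(thick)] <- t4[4]

  rho_inner <- sqrt(((grids$row - ctr[1]) / (ax[1] - thick))^2 +
                      ((grids$col - ctr[2]) / (ax[2] - thick))^2)
  sat <- body & rho_inner > 1
  lean <- body & !sat

  out <- with_seed(spec$seed, {
    vat <- matrix(FALSE, nr, nc)
    blobs <- list()
    if (spec$n_vat_blobs > 0) {
      rr <- spec$vat_blob_radius_range_px
      for (i in seq_len(spec$n_vat_blobs)) {
        placed <- FALSE
        # visceral fat concentrates around the mesentery: the first blob
        # is a dominant mass at the body center, satellites are smaller
        # and stay within 60% of the lean interior radius; this keeps the
        # largest visceral component central, which is what the
        # centroid-distance delineation rule relies on
        central <- i == 1L
        rho_max <- if (central) 0.05 else 0.6
        for (att in seq_len(max_attempts)) {
          r <- if (central) rr[2] else runif(1, rr[1], max(rr[1], 0.7 * rr[2]))
          # the blob must sit fully inside the lean interior with a 2 px
          # margin from the SAT ring (conservatively using the thickest
          # quadrant); sample its center uniformly over that shrunken
          # elliptical region scaled by rho_max
          shrink <- max(t4) + r + 2
          if (ax[1] - shrink <= 0 || ax[2] - shrink <= 0) {
            stop("VAT blob radius too large for the lean interior", call. = FALSE)
          }
          rho <- rho_max * sqrt(runif(1))
          ang <- runif(1, 0, 2 * pi)
          cand <- c(ctr[1] + rho * (ax[1] - shrink) * sin(ang),
                    ctr[2] + rho * (ax[2] - shrink) * cos(ang))
          # keep a >= 3 px gap to earlier blobs so blobs stay 8-disconnected
          clash <- FALSE
          for (b in blobs) {
            if (sqrt(sum((cand - b$center)^2)) < r + b$radius + 3) { clash <- TRUE; break }
          }
          if (clash) next
          blobs[[length(blobs) + 1L]] <- list(center = cand, radius = r)
          vat <- vat | (sqrt((grids$row - cand[1])^2 + (grids$col - cand[2])^2) <= r)
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("could not place VAT blob ", i, " inside the lean region after ",
               max_attempts, " attempts", call. = FALSE)
        }
      }
    }
    lean2 <- lean & !vat

    arm_mask <- matrix(FALSE, nr, nc)
    arm_fat <- matrix(FALSE, nr, nc)
    if (spec$include_arms) {
      # fit each arm into the lateral gap between body edge and image
      # border, keeping a clear background gap from the body so the
      # arm stays a separate component under moderate closing radii
      space <- min(ctr[2] - ax[2] - 1, nc - ctr[2] - ax[2])
      gap <- max(4, 0.5 * space)
      arm_ax <- c(ax[1] * 0.35, max(3, 0.22 * space))
      for (side in c(-1, 1)) {
        arm_ctr <- c(ctr[1], ctr[2] + side * (ax[2] + gap + arm_ax[2]))
        if (arm_ctr[2] - arm_ax[2] < 1 || arm_ctr[2] + arm_ax[2] > nc) {
          stop("arms exceed image bounds in the col dimension", call. = FALSE)
        }
        rho_a <- ellipse_rho(grids, arm_ctr, arm_ax)
        this_arm <- rho_a <= 1
        rim <- this_arm & ellipse_rho(grids, arm_ctr, pmax(arm_ax - 3, 1)) > 1
        arm_mask <- arm_mask | this_arm
        arm_fat <- arm_fat | rim
      }
      if (any(arm_mask & body)) stop("arms overlap the body ellipse", call. = FALSE)
    }
    arm_lean <- arm_mask & !arm_fat

    lv <- spec$intensity_levels
    img <- matrix(lv[["background"]], nr, nc)
    img[lean2 | arm_lean] <- lv[["lean"]]
    img[sat | vat | arm_fat] <- lv[["fat"]]
    if (spec$noise_sd > 0) {
      if (spec$noise_model == "gaussian") {
        img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
      } else {
        # Rician: magnitude of complex signal with iid Gaussian channels
        re <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
        im <- matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
        img <- sqrt(re^2 + im^2)
      }
      img <- pmin(pmax(img, 0), 1)
    }
    list(image = img,
         ground_truth = compartment_masks(sat = mask_int(sat), vat = mask_int(vat)),
         arm_mask = mask_int(arm_mask),
         abdominal_mask = mask_int(body))
  })
  out
}

mask_int <- function(logical_mask) {
  m <- matrix(0L, nrow(logical_mask), ncol(logical_mask))
  m[logical_mask] <- 1L
  m
}

#' Specify a synthetic calibration cohort
#'
#' Describes the data-generating process for a simulated cohort of paired
#' automated/manual adipose areas: the manual-reference area is a linear
#' function of the automated (Otsu-derived) area plus a binary group
#' effect, with additive Gaussian residuals. This is the structure of the
#' bias-correction models the calibration module fits and validates.
#'
#' @param n Number of records.
#' @param coefficients Length-3 numeric `(intercept, slope, group_effect)`
#'   of the generating linear model, in cm² except the unitless slope.
#' @param residual_sd Residual standard deviation in cm².
#' @param predictor_range_cm2 Length-2 `(min, max)` range of the automated
#'   area predictor (drawn uniformly).
#' @param group_fractions Named fractions in `[0, 1]` for the
#'   `male`, `adult`, and `obese` strata.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n,
                            coefficients = c(intercept = 7.224, slope = 1.112, group_effect = 7.583),
                            residual_sd = 0,
                            predictor_range_cm2 = c(20, 300),
                            group_fractions = c(male = 0.45, adult = 0.6, obese = 0.4),
                            seed = 1L) {
  stopifnot(length(coefficients) == 3, residual_sd >= 0,
            length(predictor_range_cm2) == 2,
            predictor_range_cm2[2] >= predictor_range_cm2[1],
            all(group_fractions >= 0), all(group_fractions <= 1))
  if (n < 3) stop("n must be at least the number of model coefficients (3)", call. = FALSE)
  if (!all(c("male", "adult", "obese") %in% names(group_fractions))) {
    stop("group_fractions must be named male/adult/obese", call. = FALSE)
  }
  structure(list(n = as.integer(n),
                 coefficients = setNames(as.numeric(coefficients),
                                         c("intercept", "slope", "group_effect")),
                 residual_sd = as.numeric(residual_sd),
                 predictor_range_cm2 = as.numeric(predictor_range_cm2),
                 group_fractions = group_fractions,
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' Simulate a calibration cohort
#'
#' Draws a cohort table with the columns expected by the calibration
#' module: `case_id`, `sex`, `age_category`, `obesity`, the automated
#' area predictor, and the manual-reference response generated as
#' `intercept + slope * area + group_effect * indicator + N(0, residual_sd)`.
#' For `response = "vat"` the group indicator is obesity status; for
#' `response = "sat"` it is the adult age category.
#'
#' @param spec A [cohort_sim_spec()].
#' @param response `"vat"` or `"sat"`; selects which compartment's
#'   predictor/response columns are filled and which indicator carries the
#'   group effect.
#' @return A data.frame of cohort records.
#' @export
generate_cohort <- function(spec, response = c("vat", "sat")) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  response <- match.arg(response)
  gf <- spec$group_fractions
  with_seed(spec$seed, {
    n <- spec$n
    # deterministic stratum sizes (rounded), shuffled assignment
    take <- function(frac) sample(rep(c(1L, 0L), c(round(frac * n), n - round(frac * n))))
    male <- take(gf[["male"]]); adult <- take(gf[["adult"]]); obese <- take(gf[["obese"]])
    area <- runif(n, spec$predictor_range_cm2[1], spec$predictor_range_cm2[2])
    ind <- if (response == "vat") obese else adult
    co <- spec$coefficients
    lp <- co[["intercept"]] + co[["slope"]] * area + co[["group_effect"]] * ind
    y <- lp + if (spec$residual_sd > 0) rnorm(n, 0, spec$residual_sd) else 0
    df <- data.frame(case_id = sprintf("case%04d", seq_len(n)),
                     sex = ifelse(male == 1L, "male", "female"),
                     age_category = ifelse(adult == 1L, "adult", "child"),
                     obesity = obese,
                     stringsAsFactors = FALSE)
    if (response == "vat") {
      df$vat_otsu_cm2 <- area
      df$vat_manual_cm2 <- y
    } else {
      df$sat_otsu_cm2 <- area
      df$sat_manual_cm2 <- y
    }
    df$linear_predictor_cm2 <- as.numeric(lp)
    df
  })
}
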
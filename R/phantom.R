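#' Specify a synthetic vertebra
#'
#' Geometry and tissue parameters for one vertebral level of a synthetic
#' lumbar phantom. The body is modelled as an elliptic cylinder whose outer
#' shell (of `cortical_thickness_mm`) is painted at a high cortical HU and
#' whose interior is filled with Gaussian trabecular noise; a posterior box
#' stands in for the posterior elements. Anatomical fidelity is irrelevant
#' to the pipeline's arithmetic — what matters is the topology of a dense
#' shell enclosing the trabecular compartment.
#'
#' @param level vertebral level, one of `"L1".."L4"`.
#' @param center numeric(3) world coordinates of the body centre in mm.
#' @param body_radius_mm in-plane body radius (mm); may be length 2 for an
#'   elliptic cross-section.
#' @param body_height_mm cranio-caudal body height (mm).
#' @param cortical_thickness_mm shell width (mm), `< body_radius_mm`.
#' @param trabecular_mean_hu,trabecular_sd_hu Gaussian HU parameters of the
#'   trabecular interior.
#' @param degenerated if `TRUE`, a sclerotic (high-HU) spherical inclusion is
#'   painted inside the body to emulate degenerative change, exercising the
#'   QC exclusion path.
#' @return A `VertebraSpec` (validated list).
#' @export
vertebraSpec <- function(level, center, body_radius_mm = 18,
                         body_height_mm = 28, cortical_thickness_mm = 2,
                         trabecular_mean_hu = 100, trabecular_sd_hu = 20,
                         degenerated = FALSE) {
  level <- match.arg(level, .LEVELS)
  stopifnot(length(center) == 3, is.finite(center),
            length(body_radius_mm) %in% 1:2, body_radius_mm > 0,
            body_height_mm > 0, cortical_thickness_mm >= 0,
            all(body_radius_mm > cortical_thickness_mm),
            trabecular_sd_hu >= 0)
  r <- rep(as.numeric(body_radius_mm), length.out = 2)
  structure(list(level = level, center = as.numeric(center), radius = r,
                 height = as.numeric(body_height_mm),
                 shell = as.numeric(cortical_thickness_mm),
                 mean_hu = as.numeric(trabecular_mean_hu),
                 sd_hu = as.numeric(trabecular_sd_hu),
                 degenerated = isTRUE(degenerated)),
            class = "VertebraSpec")
}

#' Specify pedicle-screw hardware
#'
#' @param screw_radius_mm,screw_length_mm screw cylinder geometry (mm).
#' @param screw_hu attenuation of metal voxels; must be at least 1400 HU so
#'   that hardware is always excludable by the metal threshold.
#' @param trajectories list of `list(entry = xyz mm, direction = xyz)`; each
#'   screw occupies the cylinder of radius `screw_radius_mm` around the
#'   segment from `entry` along the (normalised) `direction` for
#'   `screw_length_mm`.
#' @return A `HardwareSpec` (validated list).
#' @export
hardwareSpec <- function(screw_radius_mm = 3, screw_length_mm = 45,
                         screw_hu = 3000, trajectories = list()) {
  if (screw_hu < 1400)
    stop("screw_hu must be >= 1400 HU: metal below the exclusion threshold ",
         "would leak into the density ROI")
  stopifnot(screw_radius_mm > 0, screw_length_mm > 0, is.list(trajectories))
  for (tr in trajectories)
    stopifnot(length(tr$entry) == 3, length(tr$direction) == 3,
              any(tr$direction != 0))
  structure(list(radius = screw_radius_mm, length = screw_length_mm,
                 hu = screw_hu, trajectories = trajectories),
            class = "HardwareSpec")
}

## world coordinate grids (mm) for a volume of dims d and spacing s;
## voxel indices are 0-based so voxel i sits at i*s
.axisCoords <- function(d, s) lapply(1:3, function(a) (seq_len(d[a]) - 1) * s[a])

## logical array: voxels inside the (elliptic cylinder) body of spec v,
## shrunk inward by `inset` mm on every surface
.bodyRegion <- function(co, v, inset = 0) {
  rx <- v$radius[1] - inset; ry <- v$radius[2] - inset
  hz <- v$height / 2 - inset
  if (rx <= 0 || ry <= 0 || hz <= 0)
    return(array(FALSE, dim = vapply(co, length, 1L)))
  ex <- ((co[[1]] - v$center[1]) / rx)^2
  ey <- ((co[[2]] - v$center[2]) / ry)^2
  inz <- abs(co[[3]] - v$center[3]) <= hz
  inplane <- outer(ex, ey, "+") <= 1
  outer(inplane, inz, "&")
}

## posterior-element box: posterior (+y) of the body, half height
.posteriorRegion <- function(co, v) {
  rx <- v$radius[1]
  inx <- abs(co[[1]] - v$center[1]) <= 0.6 * rx
  y0 <- v$center[2] + v$radius[2]
  iny <- co[[2]] >= y0 & co[[2]] <= y0 + 14
  inz <- abs(co[[3]] - v$center[3]) <= v$height / 4
  outer(outer(inx, iny, "&"), inz, "&")
}

#' Generate a synthetic lumbar CT volume with ground-truth labels
#'
#' Paints each vertebra of `specs` into a grid of soft-tissue background:
#' the cortical shell at `cortical_hu`, the trabecular interior as i.i.d.
#' `Normal(trabecular_mean_hu, trabecular_sd_hu^2)` draws, and a posterior
#' box labelled `100 + level`. Degenerated vertebrae additionally receive a
#' sclerotic spherical inclusion (600 HU). The trabecular noise uses a
#' private RNG stream derived from `seed`, so later pipeline stages (e.g.
#' adding hardware) never perturb it.
#'
#' @param specs list of [vertebraSpec()] objects; levels must be distinct and
#'   bodies must fit in the grid without overlapping.
#' @param grid `list(dim = integer(3), spacing = numeric(3) mm)`.
#' @param background_hu soft-tissue background (default 50 HU).
#' @param cortical_hu shell attenuation (default 800 HU).
#' @param kvp acquisition tube voltage recorded in the volume.
#' @param seed integer seed; output is bit-identical for equal seeds.
#' @return `list(volume = CTVolume, labels = LabelMap)`.
#' @examples
#' ph <- generateVolume(
#'   list(vertebraSpec("L1", center = c(24, 24, 20))),
#'   grid = list(dim = c(48, 64, 40), spacing = c(1, 1, 1)), seed = 1)
#' ph$volume
#' @export
generateVolume <- function(specs, grid, background_hu = 50, cortical_hu = 800,
                           kvp = 120, seed = 1) {
  if (inherits(specs, "VertebraSpec")) specs <- list(specs)
  stopifnot(length(specs) >= 1, length(grid$dim) == 3, length(grid$spacing) == 3)
  lev <- vapply(specs, `[[`, "", "level")
  if (anyDuplicated(lev)) stop("duplicate vertebral levels in specs")
  d <- as.integer(grid$dim); s <- as.numeric(grid$spacing)
  extent <- (d - 1) * s
  co <- .axisCoords(d, s)

  vol <- array(as.numeric(background_hu), dim = d)
  lab <- array(0L, dim = d)
  ## vertebrae painted in level order so the noise stream is reproducible
  specs <- specs[order(match(lev, .LEVELS))]
  occupied <- array(FALSE, dim = d)
  .withStream(seed, 1L, {
    for (v in specs) {
      lo <- v$center - c(v$radius, v$height / 2)
      hi <- v$center + c(v$radius, v$height / 2)
      if (any(lo < 0) || any(hi > extent))
        stop(sprintf("vertebra %s does not fit inside the grid", v$level))
      body <- .bodyRegion(co, v)
      if (any(body & occupied))
        stop(sprintf("vertebra %s overlaps a previously placed vertebra",
                     v$level))
      interior <- .bodyRegion(co, v, inset = v$shell)
      shell <- body & !interior
      vol[shell] <- cortical_hu
      n_in <- sum(interior)
      vol[interior] <- stats::rnorm(n_in, v$mean_hu, v$sd_hu)
      if (v$degenerated) {
        ## deterministic sclerotic inclusion offset toward +x
        rin <- min(v$radius) - v$shell
        ctr <- v$center + c(rin / 2, 0, 0)
        rad <- 0.35 * rin
        sph <- outer(outer((co[[1]] - ctr[1])^2, (co[[2]] - ctr[2])^2, "+"),
                     (co[[3]] - ctr[3])^2, "+") <= rad^2
        vol[sph & interior] <- 600
      }
      post <- .posteriorRegion(co, v)
      if (any(post & occupied))
        stop(sprintf("posterior elements of %s overlap another vertebra",
                     v$level))
      vol[post & lab == 0L] <- cortical_hu
      lab[body] <- .BODY_CODES[[v$level]]
      lab[post & lab == 0L] <- .POSTERIOR_CODES[[v$level]]
      occupied <- occupied | body | post
    }
  })
  list(volume = CTVolume(vol, s, kvp), labels = LabelMap(lab, s))
}

#' Add pedicle-screw instrumentation to a phantom
#'
#' Sets every voxel lying on a screw cylinder to `screw_hu` and relabels it
#' with the hardware code (200). All other voxels — values and labels — are
#' left untouched, so attenuation differs from the bare phantom only at
#' hardware voxels.
#'
#' @param vol a [CTVolume-class].
#' @param labels the co-registered [LabelMap-class].
#' @param hw a [hardwareSpec()].
#' @return `list(volume = CTVolume, labels = LabelMap)` with hardware painted.
#' @export
addInstrumentation <- function(vol, labels, hw) {
  stopifnot(inherits(hw, "HardwareSpec"))
  .checkCoregistered(vol, labels)
  d <- dim(vol@values); s <- vol@spacing
  co <- .axisCoords(d, s)
  values <- vol@values; lab <- labels@labels
  for (tr in hw$trajectories) {
    u <- tr$direction / sqrt(sum(tr$direction^2))
    p0 <- as.numeric(tr$entry)
    p1 <- p0 + u * hw$length
    ## bounding box of the capsule, in 1-based voxel indices
    lo <- pmax(1, floor((pmin(p0, p1) - hw$radius) / s) + 1)
    hi <- pmin(d, ceiling((pmax(p0, p1) + hw$radius) / s) + 1)
    if (any(lo > hi)) stop("screw trajectory does not intersect the grid")
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    g <- expand.grid(x = co[[1]][ix], y = co[[2]][iy], z = co[[3]][iz])
    rel <- cbind(g$x - p0[1], g$y - p0[2], g$z - p0[3])
    tt <- pmin(pmax(rel %*% u, 0), hw$length)
    dist2 <- rowSums((rel - tt %*% t(u))^2)
    inside <- dist2 <= hw$radius^2
    if (!any(inside)) stop("screw trajectory does not intersect the grid")
    idx <- as.matrix(expand.grid(ix, iy, iz))[inside, , drop = FALSE]
    values[idx] <- hw$hu
    lab[idx] <- .HARDWARE_CODE
  }
  list(volume = CTVolume(values, s, vol@kvp), labels = LabelMap(lab, s))
}

#' Specify a simulated case-control cohort
#'
#' Defaults reproduce the matched screw-loosening study population: 23 cases
#' with BMD ~ Normal(86.5, 29.5^2) mg/cm^3 and 23 matched controls with
#' BMD ~ Normal(118.2, 32.9^2); 61% women; age ~ Normal(69.9, 9.1^2) years;
#' surgical constructs distributed 2:16:8:18:2 over L1-5, L2-5, L2-S1,
#' L3-S1, L4-S1.
#'
#' @param n_cases,n_controls group sizes.
#' @param case_bmd_mean,case_bmd_sd,control_bmd_mean,control_bmd_sd group BMD
#'   distributions in mg/cm^3.
#' @param sex_fraction_female proportion of women.
#' @param age_mean,age_sd age distribution in years.
#' @param construct_distribution named probabilities over the five surgical
#'   constructs; must sum to 1.
#' @param seed RNG seed.
#' @return A `CohortSpec` (validated list).
#' @export
cohortSpec <- function(n_cases = 23, n_controls = 23,
                       case_bmd_mean = 86.5, case_bmd_sd = 29.5,
                       control_bmd_mean = 118.2, control_bmd_sd = 32.9,
                       sex_fraction_female = 14 / 23,
                       age_mean = 69.9, age_sd = 9.1,
                       construct_distribution = c(
                         "L1-5" = 2, "L2-5" = 16, "L2-S1" = 8,
                         "L3-S1" = 18, "L4-S1" = 2) / 46,
                       seed = 1) {
  stopifnot(n_cases >= 1, n_controls >= 1, case_bmd_sd >= 0,
            control_bmd_sd >= 0, age_sd >= 0,
            sex_fraction_female >= 0, sex_fraction_female <= 1)
  if (!setequal(names(construct_distribution), .CONSTRUCTS))
    stop("construct_distribution must be named over: ",
         paste(.CONSTRUCTS, collapse = ", "))
  if (abs(sum(construct_distribution) - 1) > 1e-8)
    stop("construct probabilities must sum to 1")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 case_bmd_mean = case_bmd_mean, case_bmd_sd = case_bmd_sd,
                 control_bmd_mean = control_bmd_mean,
                 control_bmd_sd = control_bmd_sd,
                 sex_fraction_female = sex_fraction_female,
                 age_mean = age_mean, age_sd = age_sd,
                 construct_distribution =
                   construct_distribution[.CONSTRUCTS],
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Simulate a matched case-control cohort
#'
#' Draws case BMDs i.i.d. from the case distribution and control BMDs from
#' the control distribution. Covariates emulate the matched design: each
#' case's sex, age and construct are drawn from the configured
#' distributions, and its paired control shares the sex and construct with a
#' small age jitter (the study groups were matched on exactly these
#' variables). When group sizes differ, surplus records draw covariates
#' independently.
#'
#' @param spec a [cohortSpec()].
#' @return A `data.frame` with columns `id, group, sex, age, construct, bmd`.
#' @examples
#' coh <- simulateCohort(cohortSpec(seed = 7))
#' aggregate(bmd ~ group, coh, mean)
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  .withStream(spec$seed, 3L, {
    n1 <- spec$n_cases; n2 <- spec$n_controls
    sex <- ifelse(stats::runif(max(n1, n2)) < spec$sex_fraction_female,
                  "F", "M")
    age <- pmax(30, stats::rnorm(max(n1, n2), spec$age_mean, spec$age_sd))
    cons <- sample(.CONSTRUCTS, max(n1, n2), replace = TRUE,
                   prob = spec$construct_distribution)
    cases <- data.frame(
      id = sprintf("case-%02d", seq_len(n1)), group = "case",
      sex = sex[seq_len(n1)], age = round(age[seq_len(n1)], 1),
      construct = cons[seq_len(n1)],
      bmd = stats::rnorm(n1, spec$case_bmd_mean, spec$case_bmd_sd),
      stringsAsFactors = FALSE)
    ctl_age <- round(age[seq_len(n2)] + stats::rnorm(n2, 0, 2), 1)
    controls <- data.frame(
      id = sprintf("ctrl-%02d", seq_len(n2)), group = "control",
      sex = sex[seq_len(n2)], age = pmax(30, ctl_age),
      construct = cons[seq_len(n2)],
      bmd = stats::rnorm(n2, spec$control_bmd_mean, spec$control_bmd_sd),
      stringsAsFactors = FALSE)
    rbind(cases, controls)
  })
}

#' Invert a calibration equation
#'
#' Maps a target volumetric BMD back to the HU that [calibrate()] would turn
#' into that BMD — used to paint phantom trabecular bone at a known true
#' density. Exact inverse: `calibrate(bmdToHu(x, eq), eq) == x`.
#'
#' @param bmd target density, mg/cm^3.
#' @param eq a [CalibrationEquation-class].
#' @return Attenuation in HU.
#' @export
bmdToHu <- function(bmd, eq) {
  stopifnot(is(eq, "CalibrationEquation"))
  if (eq@slope == 0) stop("calibration slope must be nonzero")
  (bmd - eq@intercept) / eq@slope
}
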
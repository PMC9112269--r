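#' Anthropometric subject profile
#'
#' The seven regression targets: standing height (cm), weight (kg), BMI
#' (kg/m^2, always recomputed from height and weight), and four
#' body-composition percentages from bioelectrical impedance analysis.
#'
#' @param height Height in cm, in (100, 220).
#' @param weight Weight in kg, in (20, 200).
#' @param muscle_pct,skeletal_muscle_pct,body_water_pct,body_fat_pct
#'   Percentages in (0, 100); water + fat must not exceed 100.
#' @param id Optional subject identifier.
#' @return An object of class `uwb_subject`.
#' @export
#' @examples
#' subject_profile(164, 62.2, 39.2, 22.7, 30.6, 17.9)
subject_profile <- function(height, weight, muscle_pct, skeletal_muscle_pct,
                            body_water_pct, body_fat_pct, id = NA_character_) {
  if (!(height > 100 && height < 220)) stop_input("height must be in (100, 220) cm")
  if (!(weight > 20 && weight < 200)) stop_input("weight must be in (20, 200) kg")
  pct <- c(muscle_pct, skeletal_muscle_pct, body_water_pct, body_fat_pct)
  if (any(!is.finite(pct)) || any(pct <= 0) || any(pct >= 100))
    stop_input("all percentages must lie in (0, 100)")
  if (body_water_pct + body_fat_pct > 100)
    stop_input("body water + body fat percentages exceed 100")
  structure(list(height = height, weight = weight,
                 bmi = weight / (height / 100)^2,
                 muscle_pct = muscle_pct,
                 skeletal_muscle_pct = skeletal_muscle_pct,
                 body_water_pct = body_water_pct,
                 body_fat_pct = body_fat_pct, id = id),
            class = "uwb_subject")
}

#' @export
print.uwb_subject <- function(x, ...) {
  cat(sprintf(
    "Subject %s: %.1f cm, %.1f kg, BMI %.1f | muscle %.1f%%, skeletal %.1f%%, water %.1f%%, fat %.1f%%\n",
    x$id, x$height, x$weight, x$bmi, x$muscle_pct, x$skeletal_muscle_pct,
    x$body_water_pct, x$body_fat_pct))
  invisible(x)
}

#' Names of the seven anthropometric parameters
#' @return Character vector of parameter names as used in cohort tables.
#' @export
anthro_parameters <- function() {
  c("height", "weight", "bmi", "muscle_pct", "skeletal_muscle_pct",
    "body_water_pct", "body_fat_pct")
}

#' Population distribution parameters for cohort sampling
#'
#' Defaults reproduce the study population's medians and interquartile ranges
#' (height 164.00 cm, IQR 160.95-172.82; weight 62.20 kg, IQR 55.30-74.62; and
#' the four composition percentages). Spreads are normal SDs obtained from the
#' IQR (`IQR / 1.349`); height and weight share a latent size factor
#' (correlation `hw_cor`), and a latent adiposity factor links body fat
#' (positively) with the muscle percentages (negatively).
#'
#' @param height,weight,muscle_pct,skeletal_muscle_pct,body_water_pct,body_fat_pct
#'   Two-element vectors `c(median, sd)`.
#' @param hw_cor Height-weight correlation in (0, 1).
#' @return A list of class `uwb_population`.
#' @export
population_defaults <- function(height = c(164.00, (172.82 - 160.95) / 1.349),
                                weight = c(62.20, (74.62 - 55.30) / 1.349),
                                muscle_pct = c(39.20, (52.52 - 35.80) / 1.349),
                                skeletal_muscle_pct = c(22.70, (31.42 - 20.40) / 1.349),
                                body_water_pct = c(30.60, (40.85 - 27.95) / 1.349),
                                body_fat_pct = c(17.90, (22.55 - 15.30) / 1.349),
                                hw_cor = 0.7) {
  pop <- list(height = height, weight = weight, muscle_pct = muscle_pct,
              skeletal_muscle_pct = skeletal_muscle_pct,
              body_water_pct = body_water_pct, body_fat_pct = body_fat_pct,
              hw_cor = hw_cor)
  for (nm in setdiff(names(pop), "hw_cor")) {
    v <- pop[[nm]]
    if (length(v) != 2L || !all(is.finite(v)) || v[2] <= 0)
      stop_input("population parameter '", nm, "' needs c(median, sd) with sd > 0")
  }
  if (hw_cor <= -1 || hw_cor >= 1) stop_input("hw_cor must be in (-1, 1)")
  structure(pop, class = "uwb_population")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Sample a synthetic cohort of subjects
#'
#' Draws `n_subjects` profiles from a correlated normal model of the
#' population: height and weight share a latent size factor, a latent
#' adiposity factor raises body fat while lowering the muscle percentages, and
#' BMI is always recomputed from the sampled height and weight. Draws are
#' truncated to the physiologic validity ranges, and water + fat is rescaled
#' to at most 95% in the (rare) tail where the draws would exceed it.
#'
#' @param n_subjects Number of subjects (>= 0).
#' @param seed Integer seed; the cohort is a pure function of it.
#' @param population A [population_defaults()] object.
#' @return A list of [subject_profile()] objects.
#' @export
#' @examples
#' cohort <- sample_population(5, seed = 1)
#' cohort_table(cohort)
sample_population <- function(n_subjects, seed = 1,
                              population = population_defaults()) {
  if (!inherits(population, "uwb_population"))
    population <- do.call(population_defaults, as.list(population))
  if (n_subjects < 0) stop_input("n_subjects must be >= 0")
  if (n_subjects == 0) return(list())
  p <- population
  with_seed(seed, {
    size <- rnorm(n_subjects)                       # latent body size
    hz <- p$hw_cor * size + sqrt(1 - p$hw_cor^2) * rnorm(n_subjects)
    wz <- p$hw_cor * size + sqrt(1 - p$hw_cor^2) * rnorm(n_subjects)
    adip <- 0.4 * wz + sqrt(1 - 0.4^2) * rnorm(n_subjects)  # latent adiposity
    height <- clamp(p$height[1] + p$height[2] * hz, 120, 210)
    weight <- clamp(p$weight[1] + p$weight[2] * wz, 30, 180)
    fat    <- clamp(p$body_fat_pct[1] + p$body_fat_pct[2] * adip, 4, 55)
    mus    <- clamp(p$muscle_pct[1] - p$muscle_pct[2] * 0.6 * adip +
                      p$muscle_pct[2] * 0.8 * rnorm(n_subjects), 12, 75)
    skel   <- clamp(p$skeletal_muscle_pct[1] -
                      p$skeletal_muscle_pct[2] * 0.5 * adip +
                      p$skeletal_muscle_pct[2] * 0.7 * rnorm(n_subjects), 8, 55)
    water  <- clamp(p$body_water_pct[1] + p$body_water_pct[2] * rnorm(n_subjects),
                    12, 70)
    over <- water + fat > 95
    if (any(over)) {
      f <- 95 / (water[over] + fat[over])
      water[over] <- water[over] * f
      fat[over] <- fat[over] * f
    }
    lapply(seq_len(n_subjects), function(i)
      subject_profile(height[i], weight[i], mus[i], skel[i], water[i], fat[i],
                      id = sprintf("S%03d", i)))
  })
}

#' Tabulate a cohort
#' @param cohort List of [subject_profile()] objects.
#' @return A data.frame with one row per subject and the seven parameters.
#' @export
cohort_table <- function(cohort) {
  df <- do.call(rbind, lapply(cohort, function(s)
    data.frame(id = s$id, height = s$height, weight = s$weight, bmi = s$bmi,
               muscle_pct = s$muscle_pct,
               skeletal_muscle_pct = s$skeletal_muscle_pct,
               body_water_pct = s$body_water_pct,
               body_fat_pct = s$body_fat_pct)))
  rownames(df) <- NULL
  df
}

#' Body surface area (Mosteller)
#'
#' \eqn{BSA = \sqrt{height_{cm} \cdot weight_{kg} / 3600}} in m^2; used as the
#' monotone proxy for the radar cross section of a standing body.
#'
#' @param height_cm Height in cm.
#' @param weight_kg Weight in kg.
#' @return Surface area in m^2.
#' @export
body_surface_area <- function(height_cm, weight_kg) {
  sqrt(height_cm * weight_kg / 3600)
}

#' Per-sensor scattering amplitude scale of a subject
#'
#' Larger bodies present a larger radar cross section and return stronger
#' echoes. The package uses the Mosteller body surface area as the amplitude
#' scale, identical for all three sensors; it is strictly increasing in both
#' height and weight and fully deterministic.
#'
#' @param subject A [subject_profile()].
#' @param sensors Sensor names the scale is reported for.
#' @return Named numeric vector of amplitude scales (one per sensor).
#' @export
body_scattering <- function(subject,
                            sensors = c("ceiling", "wall_1", "wall_2")) {
  stopifnot(inherits(subject, "uwb_subject"))
  bsa <- body_surface_area(subject$height, subject$weight)
  structure(rep(bsa, length(sensors)), names = sensors)
}
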
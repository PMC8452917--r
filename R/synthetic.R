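# Seeded generators of synthetic coronary anatomy, stenoses and validation
# cohorts. These emulate the study conditions of an FFR-guided PCI cohort:
# epicardial trees obeying Murray's law truncated near 1.5 mm diameter,
# parametric stenoses of 30-90 % diameter stenosis, and a paired
# "invasive" FFR with configurable bias and Gaussian noise on the FFR
# scale.

#' Describe a parametric stenosis
#'
#' The lesion multiplies the lumen radius by a cosine taper reaching
#' `1 - severity/100` at its center and blending smoothly to 1 at the ends
#' of its extent, so `severity` maps directly to percent diameter stenosis.
#'
#' @param branch_id Branch carrying the lesion.
#' @param s_center Arc position of the throat (mm).
#' @param length Lesion extent (mm); the taper has support
#'   `[s_center - length/2, s_center + length/2]`.
#' @param severity Percent diameter stenosis in \[0, 100).
#' @param shape Taper shape; only `"cosine"` is defined.
#' @return An object of class `stenosis_spec`.
#' @export
stenosis_spec <- function(branch_id, s_center, length, severity,
                          shape = "cosine") {
  shape <- match.arg(shape, "cosine")
  if (!is.finite(severity) || severity < 0 || severity >= 100)
    stop_coroflow("domain_error", "severity must be in [0, 100) percent")
  if (!is.finite(length) || length <= 0)
    stop_coroflow("domain_error", "stenosis length must be positive")
  structure(list(branch_id = as.character(branch_id),
                 s_center = as.numeric(s_center),
                 length = as.numeric(length),
                 severity = as.numeric(severity), shape = shape),
            class = "stenosis_spec")
}

#' Generate a synthetic coronary tree
#'
#' Builds a branching epicardial tree whose bifurcations satisfy Murray's
#' law exactly: `d_parent^gamma = sum(d_child^gamma)` with a seeded daughter
#' asymmetry ratio. Branches are straight constant-radius centerlines laid
#' out in-plane for export; splitting stops at `generations` or when a
#' daughter would fall below the diameter floor (mimicking the ~1.5 mm
#' truncation of lumen segmentation).
#'
#' @param seed Integer seed; identical seeds give identical trees.
#' @param generations Number of bifurcation generations (0 = single branch).
#' @param root_diameter Root lumen diameter (mm).
#' @param murray_exponent Murray exponent gamma (default 3).
#' @param branch_length_range Range (mm) branch lengths are drawn from.
#' @param diameter_floor Minimum daughter diameter (mm); smaller daughters
#'   truncate the subtree.
#' @param asymmetry_range Range of the daughter diameter ratio d2/d1.
#' @param sample_spacing Target centerline sample spacing (mm).
#' @return A `coronary_tree`.
#' @export
generate_tree <- function(seed, generations = 3, root_diameter = 4,
                          murray_exponent = 3,
                          branch_length_range = c(15, 40),
                          diameter_floor = 1.5,
                          asymmetry_range = c(0.6, 1),
                          sample_spacing = 0.5) {
  if (generations < 0 || root_diameter <= 0)
    stop_coroflow("parameter_error",
                  "generations must be >= 0 and root_diameter positive")
  if (root_diameter < diameter_floor)
    stop_coroflow("parameter_error",
                  "root_diameter %.2f mm below the %.2f mm floor",
                  root_diameter, diameter_floor)
  gamma <- murray_exponent
  with_seed(seed, {
    queue <- list(list(parent = NA_character_, attach_s = NA_real_,
                       d = root_diameter, depth = 0L,
                       origin = c(0, 0), angle = 0))
    brs <- list()
    k <- 0L
    while (length(queue) > 0L) {
      nd <- queue[[1L]]; queue <- queue[-1L]
      k <- k + 1L
      id <- paste0("b", k)
      len <- stats::runif(1, branch_length_range[1], branch_length_range[2])
      n <- max(2L, as.integer(round(len / sample_spacing)) + 1L)
      s <- seq(0, len, length.out = n)
      dir <- c(cos(nd$angle), sin(nd$angle))
      xyz <- cbind(nd$origin[1] + dir[1] * s, nd$origin[2] + dir[2] * s, 0)
      brs[[id]] <- branch(id, s = s, r = rep(nd$d / 2, n),
                          parent_id = if (is.na(nd$parent)) NULL else nd$parent,
                          attach_s = nd$attach_s, xyz = xyz)
      if (nd$depth < generations) {
        eta <- stats::runif(1, asymmetry_range[1], asymmetry_range[2])
        spread <- stats::runif(1, 0.35, 0.6)
        d1 <- nd$d / (1 + eta^gamma)^(1 / gamma)
        d2 <- eta * d1
        if (min(d1, d2) >= diameter_floor) {
          tip <- nd$origin + dir * len
          queue <- c(queue, list(
            list(parent = id, attach_s = len, d = d1, depth = nd$depth + 1L,
                 origin = tip, angle = nd$angle + spread),
            list(parent = id, attach_s = len, d = d2, depth = nd$depth + 1L,
                 origin = tip, angle = nd$angle - spread)))
        }
      }
    }
    coronary_tree(unname(brs), radius_floor = min(0.75, diameter_floor / 2))
  })
}

#' Apply a parametric stenosis to a tree
#'
#' Multiplies the radius profile by a cosine taper within the lesion
#' extent; the geometry outside the extent and the input tree itself are
#' untouched. The lesion extent must lie within the branch, and the branch
#' sampling should resolve the taper (several samples across the extent).
#'
#' @param tree A `coronary_tree`.
#' @param spec A [stenosis_spec()].
#' @return A new `coronary_tree` with the lesion applied.
#' @export
apply_stenosis <- function(tree, spec) {
  b <- tree_branch(tree, spec$branch_id)
  lo <- spec$s_center - spec$length / 2
  hi <- spec$s_center + spec$length / 2
  smax <- branch_length(b)
  if (lo < -1e-9 || hi > smax + 1e-9)
    stop_coroflow("geometry_error",
                  "stenosis extent [%.2f, %.2f] exceeds branch '%s' (0..%.2f mm)",
                  lo, hi, spec$branch_id, smax)
  s <- b$samples$s
  inside <- s >= lo & s <= hi
  fac <- rep(1, length(s))
  fac[inside] <- 1 - (spec$severity / 100) *
    0.5 * (1 + cos(2 * pi * (s[inside] - spec$s_center) / spec$length))
  tree$branches[[spec$branch_id]]$samples$r <- b$samples$r * fac
  tree
}

#' Describe a synthetic validation cohort
#'
#' Defaults emulate the conditions of a 25-patient FFR-guided PCI cohort:
#' lesions of 30-90 % diameter stenosis, left-ventricular mass 114 +/- 32 g,
#' systolic/diastolic pressure around 127/74 mmHg, and a simulated invasive
#' FFR that equals the model FFR minus `bias` plus Gaussian noise (so the
#' Bland-Altman mean difference of model minus invasive recovers `bias`).
#'
#' @param n_patients Number of synthetic patients.
#' @param seed Integer seed.
#' @param bias Systematic difference model-FFR minus invasive-FFR.
#' @param noise_sd SD of the additive measurement noise (FFR units).
#' @param severity_range Percent-diameter-stenosis range of lesions.
#' @param mass_range LV mass range (g).
#' @param pressure_ranges List with `sbp` and `dbp` ranges (mmHg).
#' @param generations Bifurcation generations of each synthetic tree.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 25, seed = 1, bias = 0.024,
                        noise_sd = 0.065, severity_range = c(30, 90),
                        mass_range = c(82, 146),
                        pressure_ranges = list(sbp = c(113, 141),
                                               dbp = c(63, 85)),
                        generations = 2) {
  if (n_patients < 1) stop_coroflow("domain_error", "n_patients must be >= 1")
  if (noise_sd < 0) stop_coroflow("domain_error", "noise_sd must be >= 0")
  ordered <- function(r) length(r) == 2L && r[1] <= r[2]
  if (!ordered(severity_range) || !ordered(mass_range) ||
      !ordered(pressure_ranges$sbp) || !ordered(pressure_ranges$dbp))
    stop_coroflow("domain_error", "ranges must be ordered (lo, hi)")
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 bias = bias, noise_sd = noise_sd,
                 severity_range = severity_range, mass_range = mass_range,
                 pressure_ranges = pressure_ranges,
                 generations = as.integer(generations)),
            class = "cohort_spec")
}

#' Generate a synthetic validation cohort
#'
#' For each synthetic patient: generates a tree, places one cosine stenosis
#' on the main vessel, computes the model FFR at a site distal to the
#' lesion (with calibrated resistance outlet boundary conditions), deploys
#' a virtual stent at the reference diameter over the lesion extent,
#' recomputes the post-stent FFR, and simulates paired invasive FFR
#' readings as model FFR minus `bias` plus seeded Gaussian noise, truncated
#' to (0, 1].
#'
#' @param spec A [cohort_spec()].
#' @param params A [hemo_params()] object shared by all cases.
#' @param settings A [solver_settings()] object.
#' @return A list with `patients` (data.frame of physiological records and
#'   lesion severities), `paired` (data.frame with columns `vessel_id`,
#'   `phase`, `ffr_invasive`, `ffr_b` matching the paired-FFR schema of the
#'   agreement statistics), and `cases` (per-patient trees, sites and
#'   specs).
#' @export
generate_validation_cohort <- function(spec, params = hemo_params(),
                                       settings = solver_settings()) {
  if (!inherits(spec, "cohort_spec"))
    stop_coroflow("domain_error", "spec must be a cohort_spec")
  patients <- vector("list", spec$n_patients)
  paired <- vector("list", spec$n_patients)
  cases <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    seed_i <- (spec$seed + i * 9973L) %% 2147483647L
    draws <- with_seed(seed_i, list(
      sbp = stats::runif(1, spec$pressure_ranges$sbp[1],
                         spec$pressure_ranges$sbp[2]),
      dbp = stats::runif(1, spec$pressure_ranges$dbp[1],
                         spec$pressure_ranges$dbp[2]),
      mass = stats::runif(1, spec$mass_range[1], spec$mass_range[2]),
      severity = stats::runif(1, spec$severity_range[1],
                              spec$severity_range[2]),
      noise = stats::rnorm(2, 0, spec$noise_sd)
    ))
    healthy <- generate_tree(seed = seed_i + 1L,
                             generations = spec$generations)
    # lesion on the largest first-generation daughter (an LAD-like vessel);
    # a root (left-main-like) lesion would force the whole hyperemic flow
    # through the throat and is not what the cohort emulates
    kids <- tree_children(healthy)[[healthy$root_id]]
    target_id <- if (nrow(kids) == 0L) healthy$root_id else {
      kd <- vapply(kids$id,
                   function(k) healthy$branches[[k]]$samples$r[1], numeric(1))
      kids$id[which.max(kd)]
    }
    target_br <- healthy$branches[[target_id]]
    len_target <- branch_length(target_br)
    s_grid <- target_br$samples$s
    sten_len <- min(12, 0.5 * len_target)
    s_center <- s_grid[which.min(abs(s_grid - pmax(sten_len / 2,
                                                   0.45 * len_target)))]
    sten <- stenosis_spec(target_id, s_center, sten_len, draws$severity)
    diseased <- apply_stenosis(healthy, sten)
    patient <- patient_record(draws$sbp, draws$dbp, draws$mass,
                              id = sprintf("case%03d", i))
    site <- measurement_site(
      target_id, min(len_target, s_center + sten_len / 2 + 3))

    ffr_pre <- case_ffrb(diseased, patient, site, params, settings)
    ref_d <- 2 * stats::approx(target_br$samples$s, target_br$samples$r,
                               xout = s_center, rule = 2)$y
    stent <- stent_spec(target_id,
                        s_proximal = s_center - sten_len / 2,
                        s_distal = s_center + sten_len / 2,
                        diameter = ref_d)
    stented <- deploy_stent(diseased, stent)
    ffr_post <- case_ffrb(stented, patient, site, params, settings)

    inv <- pmin(1, pmax(1e-3, c(ffr_pre, ffr_post) - spec$bias + draws$noise))
    patients[[i]] <- data.frame(
      patient_id = patient$id, sbp = draws$sbp, dbp = draws$dbp,
      mbp = patient$mbp, lv_mass = draws$mass, severity = draws$severity,
      seed = seed_i)
    paired[[i]] <- data.frame(
      vessel_id = patient$id, phase = c("pre", "post"),
      ffr_invasive = inv, ffr_b = c(ffr_pre, ffr_post))
    cases[[i]] <- list(patient = patient, tree = diseased, healthy = healthy,
                       stenosis = sten, stent = stent, stented = stented,
                       site = site)
  }
  list(patients = do.call(rbind, patients),
       paired = do.call(rbind, paired),
       cases = cases)
}

# Calibrated FFR of one tree/patient/site (internal shared path).
case_ffrb <- function(tree, patient, site, params, settings) {
  bc <- build_outlet_bcs(tree, patient, params)
  cal <- calibrate_total_flow(tree, bc$inlet_pressure, bc$bcs,
                              bc$target_flow, settings, params)
  compute_ffrb(cal$solution, bc$inlet_pressure, site)$ffrb
}

#' Write a synthetic cohort to a directory
#'
#' Emits one JSON tree per case plus `patients.csv` and `paired_ffr.csv`.
#'
#' @param cohort Output of [generate_validation_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cs in cohort$cases) {
    write_tree(cs$tree, file.path(dir, paste0(cs$patient$id, "_tree.json")),
               format = "json")
  }
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$paired, file.path(dir, "paired_ffr.csv"),
                   row.names = FALSE)
  invisible(dir)
}
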
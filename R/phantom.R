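# Synthetic phantom cohort: bilateral ellipsoidal hippocampi (HPC) and
# entorhinal cortices (EC) inside a smooth "brain" ellipsoid, with a
# severity dial that simultaneously shrinks the structures and shifts
# their rim intensity toward the surrounding tissue. Severity emulates
# the clinical continuum from cognitively healthy (CH) to AD.

#' Phantom specification
#'
#' Defines the template-space grid and the generative nuisance model for
#' synthetic subjects: additive Gaussian noise, a smooth multiplicative
#' bias field, and a small random rigid pose.
#'
#' @param grid_extent voxels per axis (isotropic grid, >= 32).
#' @param voxel_size voxel edge length in mm.
#' @param structures list of structure specs, see [default_structures()].
#' @param noise_sigma additive Gaussian noise SD as a fraction of the mean
#'   tissue intensity.
#' @param bias_amplitude peak-to-trough fraction of the multiplicative
#'   bias field, in \[0, 0.5\].
#' @param bias_order polynomial order of the bias field (1-3).
#' @param misalign_trans max absolute subject translation, voxels.
#' @param misalign_rot max absolute subject rotation, degrees.
#' @param tissue_intensity mean brain-tissue intensity (arbitrary units).
#' @param background_intensity background intensity.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_extent = 64L, voxel_size = 1,
                         structures = default_structures(grid_extent),
                         noise_sigma = 0.02, bias_amplitude = 0.1,
                         bias_order = 2L, misalign_trans = 3,
                         misalign_rot = 3, tissue_intensity = 100,
                         background_intensity = 0) {
  grid_extent <- as.integer(grid_extent)
  if (grid_extent < 32L) stop("grid_extent must be >= 32 voxels per axis")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (bias_amplitude < 0 || bias_amplitude > 0.5)
    stop("bias_amplitude must lie in [0, 0.5]")
  if (!bias_order %in% 1:3) stop("bias_order must be 1, 2 or 3")
  for (s in structures) {
    if (any(s$baseline_radii / voxel_size <= 2))
      stop("structure radii must exceed 2 voxels: ", s$name)
    lo <- s$center - s$baseline_radii / voxel_size
    hi <- s$center + s$baseline_radii / voxel_size
    if (any(lo <= 1) || any(hi >= grid_extent))
      stop("structure does not fit strictly inside the grid: ", s$name)
  }
  spec <- list(grid_extent = grid_extent, voxel_size = voxel_size,
               structures = structures, noise_sigma = noise_sigma,
               bias_amplitude = bias_amplitude, bias_order = as.integer(bias_order),
               misalign_trans = misalign_trans, misalign_rot = misalign_rot,
               tissue_intensity = tissue_intensity,
               background_intensity = background_intensity)
  class(spec) <- "phantom_spec"
  spec
}

#' Default bilateral HPC/EC structure layout
#'
#' Centres and semi-axes scale with the grid so the same fractional
#' anatomy is produced at any extent. Left/right pairs are exact mirror
#' images about the midsagittal plane `x = (n+1)/2`.
#'
#' @param n grid extent (voxels per axis).
#' @return list of structure specs (name, center, baseline_radii in mm,
#'   core_intensity, rim_intensity).
#' @export
default_structures <- function(n = 64L) {
  mk <- function(name, cf, rf, core, rim) {
    list(name = name, center = cf * (n + 1), baseline_radii = rf * n,
         core_intensity = core, rim_intensity = rim)
  }
  mirror <- function(s, name) {
    s$name <- name
    s$center[1] <- (n + 1) - s$center[1]
    s
  }
  hpc <- mk("HPC_L", c(0.3125, 0.47, 0.435), c(0.155, 0.11, 0.095), 160, 130)
  ec <- mk("EC_L", c(0.30, 0.66, 0.27), c(0.095, 0.08, 0.066), 150, 125)
  list(hpc, mirror(hpc, "HPC_R"), ec, mirror(ec, "EC_R"))
}

#' Severity profile of the five-group continuum
#'
#' Per-group mean severity on \[0, 1\] plus the gains translating severity
#' into fractional volume loss and rim-intensity change. Severity must be
#' non-decreasing along CH, SCD, eMCI, lMCI, AD.
#'
#' @param levels named per-group severities.
#' @param volume_loss_max fractional structure shrinkage at severity 1.
#' @param intensity_shift_max rim-intensity change (intensity units) at
#'   severity 1; negative pulls the rim toward tissue intensity.
#' @param jitter_sd SD of per-subject severity jitter around the group
#'   level (truncated to \[0, 1\]).
#' @return a `severity_profile` list.
#' @export
severity_profile <- function(levels = c(CH = 0.05, SCD = 0.15, eMCI = 0.40,
                                        lMCI = 0.60, AD = 0.85),
                             volume_loss_max = 0.3,
                             intensity_shift_max = -25,
                             jitter_sd = 0.05) {
  stopifnot(identical(names(levels), c("CH", "SCD", "eMCI", "lMCI", "AD")))
  if (is.unsorted(levels)) stop("severity must be non-decreasing CH..AD")
  if (any(levels < 0 | levels > 1)) stop("severity levels must lie in [0,1]")
  structure(list(levels = levels, volume_loss_max = volume_loss_max,
                 intensity_shift_max = intensity_shift_max,
                 jitter_sd = jitter_sd),
            class = "severity_profile")
}

# squared normalized ellipsoid radius over the full grid
ellipsoid_rho2 <- function(n, center, radii_vox) {
  dx2 <- ((seq_len(n) - center[1]) / radii_vox[1])^2
  dy2 <- ((seq_len(n) - center[2]) / radii_vox[2])^2
  dz2 <- ((seq_len(n) - center[3]) / radii_vox[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}

#' Generate one noise-free phantom with labels
#'
#' Builds the template-space intensity field (background + brain tissue +
#' four bilateral structures) and the matching integer label field at the
#' requested atrophy severity. Structure semi-axes shrink by
#' `(1 - severity * volume_loss_max)^(1/3)` so the enclosed volume falls
#' linearly with severity; the rim shell (normalized radius 0.75-1)
#' shifts by `severity * intensity_shift_max`.
#'
#' @param spec a [phantom_spec()].
#' @param severity atrophy severity in \[0, 1\].
#' @param profile a [severity_profile()] supplying the two gains.
#' @param scale global anatomical scale factor (used for age/sex effects).
#' @param jitter_sd SD of per-call multiplicative jitter on radii and
#'   additive jitter (voxels) on centres; 0 gives the exact deterministic
#'   geometry.
#' @return list with `volume` (pg_volume), `labels` (integer array,
#'   codes in [STRUCTURES]), `brain` (logical mask) and `severity`.
#' @export
make_structure_volume <- function(spec, severity, profile = severity_profile(),
                                  scale = 1, jitter_sd = 0) {
  if (!is.numeric(severity) || severity < 0 || severity > 1)
    stop("severity must lie in [0, 1]")
  n <- spec$grid_extent
  vs <- spec$voxel_size
  vol <- array(spec$background_intensity, dim = c(n, n, n))
  labels <- array(0L, dim = c(n, n, n))

  jr <- function() if (jitter_sd > 0) 1 + rnorm(1, 0, jitter_sd) else 1
  jc <- function() if (jitter_sd > 0) rnorm(3, 0, 0.5) else c(0, 0, 0)

  brain_radii <- c(0.40, 0.43, 0.37) * n * scale * jr()
  ctr <- rep((n + 1) / 2, 3)
  brain <- ellipsoid_rho2(n, ctr, brain_radii) <= 1
  vol[brain] <- spec$tissue_intensity

  shrink <- (1 - severity * profile$volume_loss_max)^(1 / 3)
  for (s in spec$structures) {
    radii_vox <- s$baseline_radii / vs * shrink * scale * jr()
    center <- s$center + jc()
    rho2 <- ellipsoid_rho2(n, center, radii_vox)
    inside <- rho2 <= 1
    core <- rho2 <= 0.75^2
    rim <- inside & !core
    vol[core] <- s$core_intensity
    vol[rim] <- s$rim_intensity + severity * profile$intensity_shift_max
    labels[inside] <- structure_code(s$name)
    brain <- brain | inside
  }
  list(volume = as_volume(vol, vs), labels = labels, brain = brain,
       severity = severity)
}

#' Generate a smooth multiplicative bias field
#'
#' Random low-order polynomial in normalized grid coordinates, rescaled
#' to the requested peak-to-trough amplitude and normalized to mean 1
#' over the brain mask (everywhere, if no mask is given).
#'
#' @param spec a [phantom_spec()].
#' @param mask optional logical array; the field averages to 1 over it.
#' @return 3D array of strictly positive multipliers.
#' @export
make_bias_field <- function(spec, mask = NULL) {
  n <- spec$grid_extent
  if (spec$bias_amplitude == 0) return(array(1, dim = c(n, n, n)))
  u <- (seq_len(n) - (n + 1) / 2) / ((n - 1) / 2)
  field <- array(0, dim = c(n, n, n))
  for (i in 0:spec$bias_order) for (j in 0:spec$bias_order) for (k in 0:spec$bias_order) {
    deg <- i + j + k
    if (deg == 0 || deg > spec$bias_order) next
    cf <- rnorm(1)
    field <- field + cf * outer(outer(u^i, u^j, "*"), u^k, "*")
  }
  rng <- range(field)
  field <- 1 + spec$bias_amplitude * (field - mean(rng)) / diff(rng)
  m <- if (is.null(mask)) mean(field) else mean(field[mask])
  field / m
}

#' Draw a small random rigid subject pose
#'
#' @param spec a [phantom_spec()].
#' @return list with `rot` (degrees), `trans` (mm) and the 4x4 `matrix`
#'   mapping template world coordinates to subject world coordinates.
#' @export
make_pose <- function(spec) {
  rot <- runif(3, -spec$misalign_rot, spec$misalign_rot)
  trans <- runif(3, -spec$misalign_trans, spec$misalign_trans) * spec$voxel_size
  list(rot = rot, trans = trans, matrix = rigid_matrix(rot, trans))
}

#' Add the spec's additive Gaussian noise to a volume
#'
#' Noise SD is `noise_sigma` times the mean tissue intensity; uses the
#' current RNG stream.
#'
#' @param vol a volume.
#' @param spec a [phantom_spec()].
#' @return the noisy volume.
#' @export
add_noise <- function(vol, spec) {
  if (spec$noise_sigma == 0) return(vol)
  sdv <- spec$noise_sigma * spec$tissue_intensity
  as_volume(vol + array(rnorm(length(vol), 0, sdv), dim = dim(vol)),
            voxel_size(vol))
}

#' Build a labeled template library
#'
#' Healthy-control (CN) templates are drawn at low severity (uniform on
#' \[0, 0.1\]) and AD templates at high severity (uniform on \[0.8, 1\]).
#' Each template carries its intensity volume, true label field, brain
#' mask, and a group tag (1 = CN, 2 = AD). Templates live in template
#' space: no pose or bias field, only the spec's additive noise.
#'
#' @param n_cn,n_ad template counts per group (both >= 1).
#' @param spec a [phantom_spec()].
#' @param profile a [severity_profile()].
#' @param seed integer seed; the library is bitwise reproducible.
#' @return a `template_library`: list of templates plus a `meta` table
#'   (template_id, group_tag, severity).
#' @export
make_template_library <- function(n_cn, n_ad, spec = phantom_spec(),
                                  profile = severity_profile(), seed = 1L) {
  if (n_cn < 1 || n_ad < 1)
    stop("template library needs at least one template per group (CN and AD)")
  set.seed(seed)
  tags <- c(rep(1L, n_cn), rep(2L, n_ad))
  templates <- vector("list", n_cn + n_ad)
  for (t in seq_along(tags)) {
    sev <- if (tags[t] == 1L) runif(1, 0, 0.1) else runif(1, 0.8, 1)
    ph <- make_structure_volume(spec, sev, profile, jitter_sd = 0.02)
    templates[[t]] <- list(id = sprintf("t%02d", t),
                           intensity = add_noise(ph$volume, spec),
                           labels = ph$labels, brain = ph$brain,
                           group_tag = tags[t], severity = sev)
  }
  meta <- data.frame(template_id = vapply(templates, `[[`, "", "id"),
                     group_tag = tags,
                     severity = vapply(templates, `[[`, 0, "severity"))
  structure(list(templates = templates, meta = meta, spec = spec,
                 profile = profile, seed = seed),
            class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("<template_library: %d CN + %d AD templates, %d^3 grid>\n",
              sum(x$meta$group_tag == 1L), sum(x$meta$group_tag == 2L),
              x$spec$grid_extent))
  invisible(x)
}

#' Simulate a subject cohort on the clinical continuum
#'
#' Draws, per subject: a clinical record consistent with the group's
#' classification rules (see [classify_participant()]), covariates with
#' the published per-group moments, a severity around the group level,
#' and a phantom volume degraded by bias field, additive noise and a
#' small random rigid pose. Anatomy scales mildly with age and sex so
#' normative covariate adjustment has real signal to remove.
#'
#' @param group_sizes named counts for CH, SCD, eMCI, lMCI, AD.
#' @param profile a [severity_profile()].
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @param apply_pose,apply_bias,apply_noise toggles for the degradation
#'   stages (all on by default).
#' @param keep_truth retain each subject's template-space truth labels
#'   and brain mask (memory permitting).
#' @return list with `table` (one row per subject), `volumes` (list of
#'   pg_volume), `poses` (list of pose objects or NULL) and `truth`.
#' @export
make_cohort <- function(group_sizes = c(CH = 29, SCD = 66, eMCI = 22,
                                        lMCI = 8, AD = 12),
                        profile = severity_profile(), spec = phantom_spec(),
                        seed = 1L, apply_pose = TRUE, apply_bias = TRUE,
                        apply_noise = TRUE, keep_truth = FALSE) {
  stopifnot(all(names(group_sizes) %in% names(profile$levels)),
            all(group_sizes >= 0))
  set.seed(seed)
  rows <- list(); volumes <- list(); poses <- list(); truth <- list()
  idx <- 0L
  for (g in names(group_sizes)) {
    ng <- group_sizes[[g]]
    if (ng == 0) next
    for (s in seq_len(ng)) {
      idx <- idx + 1L
      rec <- gen_clinical_record(g)
      sev <- min(1, max(0, profile$levels[[g]] + rnorm(1, 0, profile$jitter_sd)))
      scale <- (1 - 0.002 * (rec$age - 72)) * ifelse(rec$sex == "M", 1.02, 0.98)
      ph <- make_structure_volume(spec, sev, profile, scale = scale,
                                  jitter_sd = 0.02)
      vol <- ph$volume
      pose <- NULL
      if (apply_pose) {
        pose <- make_pose(spec)
        vol <- resample_affine(vol, pose$matrix,
                               fill = spec$background_intensity)
      }
      if (apply_bias && spec$bias_amplitude > 0)
        vol <- as_volume(vol * make_bias_field(spec), spec$voxel_size)
      if (apply_noise) vol <- add_noise(vol, spec)
      volumes[[idx]] <- vol
      poses[[idx]] <- pose
      if (keep_truth) truth[[idx]] <- list(labels = ph$labels, brain = ph$brain)
      rows[[idx]] <- data.frame(subject_id = sprintf("s%03d", idx), group = g,
                                age = rec$age, sex = rec$sex,
                                education_years = rec$education_years,
                                moca = rec$moca, cdr = rec$cdr,
                                lm_score = rec$lm_score, gai = rec$gai,
                                gds = rec$gds, ravlt = rec$ravlt,
                                complaint = rec$complaint, severity = sev,
                                seed = seed, stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows)
  table$group <- factor(table$group, levels = names(profile$levels))
  list(table = table, volumes = volumes, poses = poses,
       truth = if (keep_truth) truth else NULL)
}

#' Write a cohort to disk
#'
#' Volumes as NIfTI-1, the phenotype table as CSV.
#'
#' @param cohort result of [make_cohort()].
#' @param dir output directory (created).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$volumes))
    write_volume(cohort$volumes[[i]],
                 file.path(dir, paste0(cohort$table$subject_id[i], ".nii.gz")))
  write.csv(cohort$table, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write a template library to disk
#'
#' Per-template `t<k>_intensity.nii.gz` and `t<k>_labels.nii.gz`, plus
#' `library.csv` (template_id, group_tag, severity).
#'
#' @param library a `template_library`.
#' @param dir output directory (created).
#' @export
write_library <- function(library, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tp in library$templates) {
    write_volume(tp$intensity, file.path(dir, paste0(tp$id, "_intensity.nii.gz")))
    write_volume(as_volume(array(as.numeric(tp$labels), dim(tp$labels)),
                           library$spec$voxel_size),
                 file.path(dir, paste0(tp$id, "_labels.nii.gz")))
  }
  write.csv(library$meta, file.path(dir, "library.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a template library from disk
#'
#' @param dir directory written by [write_library()].
#' @param spec the [phantom_spec()] the library was generated with.
#' @return a `template_library` (brain masks reconstructed as
#'   intensity-above-background content masks).
#' @export
read_library <- function(dir, spec = phantom_spec()) {
  meta <- read.csv(file.path(dir, "library.csv"), stringsAsFactors = FALSE)
  thr <- (spec$background_intensity + spec$tissue_intensity) / 2
  templates <- lapply(seq_len(nrow(meta)), function(t) {
    intensity <- read_volume(file.path(dir, paste0(meta$template_id[t], "_intensity.nii.gz")))
    labarr <- read_volume(file.path(dir, paste0(meta$template_id[t], "_labels.nii.gz")))
    labels <- array(as.integer(round(labarr)), dim(labarr))
    list(id = meta$template_id[t], intensity = intensity, labels = labels,
         brain = array(intensity > thr, dim(intensity)) | labels > 0L,
         group_tag = meta$group_tag[t], severity = meta$severity[t])
  })
  structure(list(templates = templates, meta = meta, spec = spec,
                 profile = severity_profile(), seed = NA_integer_),
            class = "template_library")
}
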
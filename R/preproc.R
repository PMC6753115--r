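# Desk-scale preprocessing chain: nonlocal-means denoising, log-domain
# polynomial bias-field correction (a stand-in with the same contract as
# histogram-based inhomogeneity correctors), rigid multiresolution
# registration to template space by normalized correlation, linear
# intensity normalization, and patch-based brain extraction reusing the
# label-fusion engine with brain/non-brain labels. All stages are
# deterministic given their inputs.

#' Estimate additive noise SD of a volume
#'
#' Pseudo-residual estimator: `sqrt(6/7) * (v - mean of 6 neighbours)`
#' has the noise SD under additive white Gaussian noise; a MAD over
#' these residuals makes the estimate robust to edges.
#'
#' @param vol a volume.
#' @return estimated noise SD (intensity units).
#' @export
estimate_noise_sigma <- function(vol) {
  d <- dim(vol)
  shift <- function(ax, by) {
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[ax]] <- pmin(pmax(idx[[ax]] + by, 1), d[ax])
    vol[idx[[1]], idx[[2]], idx[[3]]]
  }
  nb <- (shift(1, 1) + shift(1, -1) + shift(2, 1) + shift(2, -1) +
           shift(3, 1) + shift(3, -1)) / 6
  eps <- sqrt(6 / 7) * (vol - nb)
  1.4826 * median(abs(eps - median(eps)))
}

#' Nonlocal-means denoising
#'
#' Each voxel is replaced by the similarity-weighted average of the
#' centres of nearby patches; weights are `exp(-d / h^2)` with `d` the
#' mean squared patch difference. The bandwidth defaults to
#' `h^2 = 2 * sigma^2` with sigma estimated by [estimate_noise_sigma()].
#'
#' @param vol input volume (finite values).
#' @param patch_radius patch half-width in voxels.
#' @param search_radius search-window half-width in voxels.
#' @param h bandwidth; `NULL` ties it to the estimated noise SD.
#' @return denoised volume on the same grid.
#' @export
denoise_nlm <- function(vol, patch_radius = 1L, search_radius = 3L, h = NULL) {
  if (!all(is.finite(vol))) stop("input volume contains non-finite voxels")
  if (patch_radius < 1 || search_radius < 1) stop("radii must be >= 1")
  if (is.null(h)) h <- sqrt(2) * max(estimate_noise_sigma(vol), 1e-12)
  if (h <= 0) stop("bandwidth h must be > 0")
  out <- .pg_nlm(strip_volume(vol), as.integer(dim(vol)),
                 as.integer(patch_radius), as.integer(search_radius), h^2)
  as_volume(out, voxel_size(vol))
}

poly_design <- function(u, order) {
  # monomials x^i y^j z^k with i+j+k <= order (including the constant)
  terms <- expand.grid(i = 0:order, j = 0:order, k = 0:order)
  terms <- terms[rowSums(terms) <= order, , drop = FALSE]
  X <- matrix(0, nrow(u), nrow(terms))
  for (t in seq_len(nrow(terms)))
    X[, t] <- u[, 1]^terms$i[t] * u[, 2]^terms$j[t] * u[, 3]^terms$k[t]
  X
}

#' Correct a smooth multiplicative bias field
#'
#' Fits a low-order polynomial to the log intensities over the mask,
#' with two trimmed refits (residuals within 2 MADs) so that bright
#' structures embedded in the dominant tissue class do not bend the
#' field. The exponentiated fit, normalized to mean 1 over the mask, is
#' returned as the recovered field; the corrected volume is the input
#' divided by it, so `corrected * field` reproduces the input exactly.
#'
#' @param vol input volume.
#' @param mask logical array of voxels to fit over (non-empty).
#' @param order polynomial order, 1-3.
#' @param max_fit maximum number of voxels used in the fit (evenly
#'   subsampled above this).
#' @return list with `corrected` (volume) and `field` (array, mean 1
#'   over the mask).
#' @export
correct_bias <- function(vol, mask, order = 2L, max_fit = 20000L) {
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  idx <- which(mask)
  if (length(idx) == 0) stop("empty mask")
  vals <- vol[idx]
  pos <- vals > 0
  if (!any(pos)) stop("numerical error: no positive intensities in mask")
  idx <- idx[pos]; vals <- vals[pos]
  if (length(idx) > max_fit) {
    keep <- unique(round(seq(1, length(idx), length.out = max_fit)))
    idx <- idx[keep]; vals <- vals[keep]
  }
  d <- dim(vol)
  ar <- arrayInd(idx, d)
  u <- sweep(sweep(ar, 2, (d + 1) / 2), 2, (d - 1) / 2, "/")
  X <- poly_design(u, order)
  y <- log(vals)
  keep <- rep(TRUE, length(y))
  for (it in 1:3) {
    fit <- lm.fit(X[keep, , drop = FALSE], y[keep])
    r <- y - X %*% fit$coefficients
    s <- mad(r[keep])
    if (s < 1e-12) break
    keep <- abs(r - median(r[keep])) < 2 * s
    if (sum(keep) < ncol(X) * 3) break
  }
  # evaluate the fitted log-field on the full grid
  n <- d[1]
  ug <- (seq_len(n) - (n + 1) / 2) / ((n - 1) / 2)
  grid <- as.matrix(expand.grid(x = ug, y = ug, z = ug))
  fl <- array(poly_design(grid, order) %*% fit$coefficients, dim = d)
  field <- exp(fl - mean(fl[mask]))
  field <- field / mean(field[mask])
  list(corrected = as_volume(vol / field, voxel_size(vol)), field = field)
}

downsample_mean <- function(vol, f) {
  if (f == 1) return(vol)
  d <- dim(vol)
  dn <- d %/% f
  crop <- vol[seq_len(dn[1] * f), seq_len(dn[2] * f), seq_len(dn[3] * f)]
  a <- array(crop, dim = c(f, dn[1], f, dn[2], f, dn[3]))
  out <- apply(a, c(2, 4, 6), mean)
  as_volume(out, voxel_size(vol) * f)
}

#' Rigid registration to a template
#'
#' Six-parameter (rotation + translation) registration maximizing the
#' normalized correlation between the resampled subject and the
#' template, by Nelder-Mead over a coarse-to-fine pyramid. Returns the
#' 4x4 transform taking template world coordinates to subject world
#' coordinates (so resampling the subject through it lands on the
#' template grid) and the resampled subject at the template resolution.
#'
#' @param subject,template volumes (finite values).
#' @param levels number of pyramid levels (downsampling by 2 per level;
#'   the finest level is full resolution).
#' @param init optional initial parameters `c(rx, ry, rz, tx, ty, tz)`
#'   (degrees, mm).
#' @param maxit Nelder-Mead iteration caps, coarsest level first
#'   (recycled to `levels`).
#' @return an `affine_result`: `matrix`, `params`, `nc` (final
#'   normalized correlation), `converged`, `resampled`.
#' @export
register_affine <- function(subject, template, levels = 3L, init = rep(0, 6),
                            maxit = c(400, 200, 120)) {
  if (!all(is.finite(subject)) || !all(is.finite(template)))
    stop("volumes contain non-finite voxels")
  par <- init
  conv <- TRUE
  maxit <- rep_len(maxit, levels)
  for (lev in seq(levels, 1)) {
    f <- 2^(lev - 1)
    s <- downsample_mean(subject, f)
    tm <- downsample_mean(template, f)
    fn <- function(p) {
      A <- rigid_matrix(p[1:3], p[4:6])
      r <- resample_affine(s, A, out_dim = dim(tm),
                           voxel_size_out = voxel_size(tm))
      if (sd(r) < 1e-12) return(1)
      -cor(as.numeric(r), as.numeric(tm))
    }
    opt <- optim(par, fn, method = "Nelder-Mead",
                 control = list(maxit = maxit[levels - lev + 1],
                                reltol = 1e-10))
    par <- opt$par
    if (lev == 1 && opt$convergence != 0) conv <- FALSE
  }
  A <- rigid_matrix(par[1:3], par[4:6])
  res <- resample_affine(subject, A, out_dim = dim(template),
                         voxel_size_out = voxel_size(template))
  structure(list(matrix = A, params = par, nc = -fn_final(subject, template, par),
                 converged = conv, resampled = res),
            class = "affine_result")
}

fn_final <- function(subject, template, p) {
  A <- rigid_matrix(p[1:3], p[4:6])
  r <- resample_affine(subject, A, out_dim = dim(template),
                       voxel_size_out = voxel_size(template))
  if (sd(r) < 1e-12) return(1)
  -cor(as.numeric(r), as.numeric(template))
}

#' Mean voxel displacement between two transforms
#'
#' Average Euclidean distance, over the mask, between where the two
#' transforms send each voxel's world coordinate. Used to quantify
#' registration error in voxels.
#'
#' @param A,B 4x4 transforms.
#' @param mask logical array defining the evaluation region.
#' @param voxel_size voxel edge length in mm.
#' @return mean displacement in voxel units.
#' @export
mean_displacement <- function(A, B, mask, voxel_size = 1) {
  d <- dim(mask)
  ar <- which(mask, arr.ind = TRUE)
  w <- sweep(ar, 2, (d + 1) / 2) * voxel_size
  w <- cbind(w, 1)
  da <- w %*% t(A[1:3, ]) - w %*% t(B[1:3, ])
  mean(sqrt(rowSums(da^2))) / voxel_size
}

#' Linear intensity normalization onto a template
#'
#' Least-squares fit `template ~ a * subject + b` over the mask; returns
#' `a * subject + b`. The gain must come out positive.
#'
#' @param subject,template volumes on the same grid.
#' @param mask logical array (non-empty).
#' @return normalized volume with attribute `coefficients = c(a, b)`.
#' @export
normalize_intensity <- function(subject, template, mask) {
  idx <- which(mask)
  if (length(idx) == 0) stop("empty mask")
  s <- subject[idx]; t <- template[idx]
  vs <- var(s)
  if (vs < 1e-24) stop("zero-variance subject intensities in mask")
  a <- stats::cov(s, t) / vs
  if (a <= 0) stop("non-positive intensity gain; volumes are anti-correlated")
  b <- mean(t) - a * mean(s)
  out <- as_volume(a * subject + b, voxel_size(subject))
  attr(out, "coefficients") <- c(a = a, b = b)
  out
}

#' Patch-based brain extraction
#'
#' Reuses the label-fusion engine with brain/non-brain labels from the
#' template library's content masks. The candidate region is the dilated
#' union of template brain masks; voxels outside it are non-brain.
#'
#' @param subject volume in template space.
#' @param library a `template_library` with per-template `brain` masks.
#' @param cfg a [patch_config()] (small radii by default: brain/non-brain
#'   contrast needs no large search).
#' @param max_templates cap on templates used (evenly spread over the
#'   library) to keep the pass desk-scale.
#' @return logical brain mask with attribute `flagged = TRUE` and a
#'   warning when empty.
#' @export
extract_brain <- function(subject, library,
                          cfg = patch_config(patch_radius = 1L,
                                             search_radius = 1L,
                                             candidate_mask_dilation = 2L),
                          max_templates = 4L) {
  check_library(library)
  n <- length(library$templates)
  pick <- unique(round(seq(1, n, length.out = min(max_templates, n))))
  sub <- library$templates[pick]
  blib <- structure(list(templates = lapply(sub, function(tp) {
    list(id = tp$id, intensity = tp$intensity,
         labels = array(as.integer(tp$brain), dim(tp$brain)),
         brain = tp$brain, group_tag = tp$group_tag, severity = tp$severity)
  }), meta = library$meta[pick, ], spec = library$spec), class = "template_library")

  d <- dim(subject)
  cand <- array(FALSE, d)
  for (tp in sub) cand <- cand | tp$brain
  cand <- dilate_mask(cand, cfg$candidate_mask_dilation)
  vox <- which(cand, arr.ind = TRUE)
  res <- grade_voxels(subject, blib, vox, cfg)
  mask <- array(FALSE, d)
  mask[cand] <- res$label == 1L
  # intensity veto: deep inside the candidate region every template patch
  # is brain, so fusion alone cannot reject content-free subjects there
  t1 <- sub[[1]]
  bgval <- median(t1$intensity[!t1$brain])
  brval <- median(t1$intensity[t1$brain])
  mask <- mask & (subject > bgval + 0.25 * (brval - bgval))
  if (!any(mask)) {
    warning("brain extraction produced an empty mask")
    attr(mask, "flagged") <- TRUE
  }
  mask
}

#' Is a binary mask a single connected component?
#'
#' 26-connectivity flood fill by iterated masked dilation.
#'
#' @param mask logical array.
#' @return TRUE when all foreground voxels are mutually connected.
#' @export
mask_connected <- function(mask) {
  total <- sum(mask)
  if (total == 0) return(FALSE)
  seedidx <- which(mask)[1]
  comp <- array(FALSE, dim(mask))
  comp[seedidx] <- TRUE
  repeat {
    grown <- dilate_mask(comp, 1L) & mask
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  sum(comp) == total
}

#' Run the full preprocessing chain on one subject
#'
#' Denoise, correct the bias field (over a content mask from a simple
#' intensity threshold), rigidly register to the template, normalize
#' intensities over the template brain mask, and extract the brain.
#'
#' @param subject raw subject volume.
#' @param template template-space intensity volume.
#' @param template_brain logical template brain mask.
#' @param library a `template_library` (for brain extraction).
#' @param denoise,bias_correct,register stage toggles.
#' @param bias_order polynomial order for the bias fit.
#' @param levels registration pyramid levels.
#' @param nlm_search search radius for the denoiser.
#' @return list with `volume` (preprocessed, template space), `brain`
#'   (extracted mask), `transform`, `bias_field`, `norm_coef`.
#' @export
preprocess_subject <- function(subject, template, template_brain, library,
                               denoise = TRUE, bias_correct = TRUE,
                               register = TRUE, bias_order = 2L,
                               levels = 3L, nlm_search = 2L) {
  vol <- subject
  if (denoise) vol <- denoise_nlm(vol, search_radius = nlm_search)
  field <- NULL
  if (bias_correct) {
    thr <- 0.5 * quantile(vol, 0.95)
    content <- array(vol > thr, dim(vol))
    bc <- correct_bias(vol, content, order = bias_order)
    vol <- bc$corrected; field <- bc$field
  }
  transform <- NULL
  if (register) {
    reg <- register_affine(vol, template, levels = levels)
    vol <- reg$resampled; transform <- reg$matrix
  }
  vol <- normalize_intensity(vol, template, template_brain)
  brain <- extract_brain(vol, library)
  list(volume = vol, brain = brain, transform = transform,
       bias_field = field, norm_coef = attr(vol, "coefficients"))
}
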
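#' Build a synthetic cortical parcellation atlas
#'
#' Places parcels on two hemispheric unit spheres using a deterministic
#' Fibonacci (low-discrepancy) spiral, mirrored across the midline, and
#' assigns each parcel a Mesulam laminar-differentiation class and a Yeo-7
#' intrinsic-connectivity network in contiguous bands along the
#' anterior-posterior (AP) axis. The default 360-parcel layout mimics the
#' HCP-MMP1.0 scheme (180 parcels per hemisphere) at the level of detail the
#' downstream statistics need: plausible spherical geometry for spin tests
#' and a complete class/network labelling for partition contrasts.
#'
#' Class proportions along the AP axis (anterior to posterior) are
#' paralimbic 12%, heteromodal 40%, unimodal 36%, idiotypic 12%. Networks
#' are banded posterior to anterior as visual, dorsal attention,
#' somatomotor, ventral attention, limbic, frontoparietal, default mode.
#'
#' @param n_parcels total parcel count; must be even and >= 8.
#' @param seed accepted for interface symmetry with the other generators;
#'   the construction is fully deterministic and does not consume it.
#' @return A data.frame of class `parcel_atlas` with columns `parcel_id`
#'   (0-based), `name`, `hemisphere` ("L"/"R"), `x`, `y`, `z` (unit-norm
#'   centroid), `ap_axis` (in \[-1, 1\], +1 anterior), `mesulam_class`,
#'   `yeo_network`.
#' @export
make_parcellation <- function(n_parcels = 360L, seed = 1L) {
  if (length(n_parcels) != 1L || is.na(n_parcels) || n_parcels %% 2L != 0L ||
      n_parcels < 8L) {
    stop("`n_parcels` must be an even integer >= 8")
  }
  nh <- as.integer(n_parcels / 2L)
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(nh) - 1L
  # y is the anterior-posterior coordinate; spiral fills the sphere evenly
  y <- 1 - 2 * (i + 0.5) / nh
  r <- sqrt(pmax(0, 1 - y^2))
  theta <- golden * i
  x <- r * cos(theta)
  z <- r * sin(theta)
  ap <- if (nh > 1L) 2 * (y - min(y)) / (max(y) - min(y)) - 1 else y * 0

  classes <- c("paralimbic", "heteromodal", "unimodal", "idiotypic")
  class_prop <- c(0.12, 0.40, 0.36, 0.12)
  networks <- c("default_mode", "frontoparietal", "limbic",
                "ventral_attention", "somatomotor", "dorsal_attention",
                "visual")
  net_prop <- c(0.20, 0.14, 0.12, 0.12, 0.16, 0.12, 0.14)

  class_lab <- .band_labels(ap, classes, class_prop)
  net_lab <- .band_labels(ap, networks, net_prop)

  build_hemi <- function(hemi) {
    sgn <- if (hemi == "L") -1 else 1
    data.frame(
      name = sprintf("%s_P%03d_ROI", hemi, seq_len(nh)),
      hemisphere = hemi,
      x = sgn * abs(x) , y = y, z = z,
      ap_axis = ap,
      mesulam_class = class_lab,
      yeo_network = net_lab,
      stringsAsFactors = FALSE
    )
  }
  atlas <- rbind(build_hemi("L"), build_hemi("R"))
  atlas <- cbind(parcel_id = seq_len(nrow(atlas)) - 1L, atlas)
  rownames(atlas) <- NULL
  class(atlas) <- c("parcel_atlas", "data.frame")
  atlas
}

# Assign labels to contiguous bands of the ap axis, anterior first, with
# largest-remainder rounding so every label is represented.
.band_labels <- function(ap, labels, prop) {
  n <- length(ap)
  raw <- prop * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  if (any(counts == 0)) {
    # guarantee representation at small n
    for (j in which(counts == 0)) {
      donor <- which.max(counts)
      counts[donor] <- counts[donor] - 1L
      counts[j] <- 1L
    }
  }
  # anterior (largest ap) gets the first label
  ord <- order(ap, decreasing = TRUE)
  lab <- character(n)
  lab[ord] <- rep(labels, times = counts)
  lab
}

#' Validate that a map of parcel values matches an atlas
#' @param values numeric vector of per-parcel values.
#' @param atlas a `parcel_atlas`.
#' @keywords internal
.check_parcel_map <- function(values, atlas) {
  if (length(values) != nrow(atlas) || anyNA(values)) {
    stop("parcel map must be complete on the atlas (one finite value per parcel)")
  }
  invisible(TRUE)
}
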
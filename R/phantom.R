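#' Generate a stylized voxel phantom for a patient
#'
#' Builds a geometric whole-body phantom (head to mid-femur) on a regular
#' voxel grid: an elliptical body whose cross-section scales with BMI,
#' containing all radiosensitive organ classes of the packaged vocabulary
#' appropriate to the patient's sex. Organs are stylized ellipsoids, shells
#' and tubes positioned at anatomically inspired fractions of the body frame;
#' hollow organs are labelled on wall voxels only; the skin is the outermost
#' body shell; cortical bone (spine and pelvis) encloses the red bone marrow.
#' Hounsfield values per tissue class are fixed nominal values with a per-
#' phantom +/-10% jitter; kidneys and thyroid carry contrast-enhanced HU.
#'
#' Named organs can be omitted (`omit`) to emulate individual anatomy such as
#' missing organs after resection or aplasia.
#'
#' @param patient A `patient_record`.
#' @param resolution Voxels per axis (cubic grid), minimum 16.
#' @param seed Integer seed controlling geometric and HU jitter.
#' @param omit Character vector of organ names to leave out.
#' @return A `voxel_phantom`: list with `hu` and `labels` (congruent 3-D
#'   arrays), `spacing` (mm per axis, x/y/z with z the table-feed axis),
#'   `origin` (mm), `patient`, `omitted`.
#' @export
generate_phantom <- function(patient, resolution = 64L, seed = 1L,
                             omit = character()) {
  stopifnot(inherits(patient, "patient_record"))
  resolution <- as.integer(resolution)
  if (resolution < 16L) stop("resolution must be at least 16 voxels per axis")
  vocab <- organ_vocabulary()
  vocab <- vocab[vocab$sex %in% c("both", patient$sex), ]
  unknown <- setdiff(omit, vocab$organ)
  if (length(unknown)) stop("unknown organ in omit: ", paste(unknown, collapse = ", "))
  required <- setdiff(vocab$organ, omit)

  height <- if (is.finite(patient$height)) patient$height else 170
  bmi <- if (is.finite(patient$bmi)) patient$bmi else 26

  # body frame (mm): z spans head to mid-femur; trunk ellipse scales ~sqrt(BMI)
  L <- .scan_length_frac * height * 10      # scan length in mm
  a <- 190 * sqrt(bmi / 26)                 # trunk lateral semi-axis
  b <- 0.65 * a                             # antero-posterior semi-axis

  with_seed(seed, {
    jit <- function(s = 0.05) exp(stats::rnorm(1, 0, s))
    a <- a * jit(0.03); b <- b * jit(0.03)

    ext_xy <- 2.4 * a
    sp <- c(ext_xy / resolution, ext_xy / resolution, L / resolution)
    n <- resolution
    # voxel-center world coordinates, origin at body axis (x, y), z = 0 at head top
    cx <- (seq_len(n) - (n + 1) / 2) * sp[1]
    cy <- (seq_len(n) - (n + 1) / 2) * sp[2]
    cz <- (seq_len(n) - 0.5) * sp[3]
    X <- array(rep(cx, times = n * n), dim = c(n, n, n))
    Y <- array(rep(rep(cy, each = n), times = n), dim = c(n, n, n))
    Z <- array(rep(cz, each = n * n), dim = c(n, n, n))
    zf <- Z / L                                # fractional table position

    # body envelope: head sphere, neck, trunk, pelvis/femur taper
    rad <- function(z) {
      w <- numeric(length(z))
      head_r <- 0.42
      w <- ifelse(z < 0.12, head_r * sqrt(pmax(0, 1 - ((z - 0.06) / 0.065)^2)), w)
      w <- ifelse(z >= 0.12 & z < 0.17, 0.28, w)
      w <- ifelse(z >= 0.17 & z < 0.62, 1, w)
      w <- ifelse(z >= 0.62, pmax(0.45, 1 - 0.9 * (z - 0.62)), w)
      w
    }
    wf <- rad(zf)
    body <- (X / (a * pmax(wf, 1e-6)))^2 + (Y / (b * pmax(wf, 1e-6)))^2 <= 1 & wf > 0

    labels <- array(0L, dim = c(n, n, n))
    hu <- array(-1000, dim = c(n, n, n))
    hu[body] <- 30 + stats::rnorm(1, 0, 3)    # generic soft tissue

    lab_of <- function(org) vocab$label[vocab$organ == org]

    ellipsoid <- function(cxf, cyf, czf, rxf, ryf, rzf, inner = NULL) {
      # fractions of (a, b, L); returns logical mask (optionally shell)
      x0 <- cxf * a; y0 <- cyf * b; z0 <- czf * L
      rx <- rxf * a; ry <- ryf * b; rz <- rzf * L
      d2 <- ((X - x0) / rx)^2 + ((Y - y0) / ry)^2 + ((Z - z0) / rz)^2
      m <- d2 <= 1
      if (!is.null(inner)) m <- m & d2 > inner^2
      m & body
    }

    place <- function(org, mask, hu_val = NULL) {
      if (!org %in% required) return(invisible(NULL))
      mask <- mask & labels == 0L
      if (!any(mask)) {
        stop("resolution too small to place organ: ", org)
      }
      labels[mask] <<- lab_of(org)
      nominal <- if (is.null(hu_val)) vocab$hu_nominal[vocab$organ == org] else hu_val
      hu[mask] <<- nominal * jit(0.05)
      invisible(NULL)
    }

    g <- function(s = 0.02) stats::rnorm(1, 0, s)  # positional jitter (fractions)

    # skeletal frame first: spine (posterior midline rod) and pelvis ring,
    # cortical shell with marrow core
    spine_out <- ellipsoid(0 + g(), -0.55 + g(), 0.40, 0.14, 0.22, 0.26)
    spine_in <- ellipsoid(0, -0.55, 0.40, 0.08, 0.12, 0.25)
    # pelvis: cortical ring with a marrow band just inside it, leaving the
    # pelvic cavity free for bladder, uterus/prostate and gonads
    pelvis_bone <- ellipsoid(0, -0.1, 0.60 + g(0.01), 0.75, 0.75, 0.045, inner = 0.85)
    pelvis_marrow <- ellipsoid(0, -0.1, 0.60, 0.6375, 0.6375, 0.03825, inner = 0.8235)
    skull_out <- ellipsoid(0 + g(0.01), 0 + g(0.01), 0.055, 0.40, 0.62, 0.050)
    skull_in <- ellipsoid(0, 0, 0.055, 0.33, 0.50, 0.040)
    place("brain", skull_in)

    # head / neck
    place("oral_mucosa", ellipsoid(0, 0.35, 0.105 + g(0.005), 0.18, 0.3, 0.018))
    place("salivary_glands",
          ellipsoid(-0.3, 0.15, 0.10, 0.12, 0.2, 0.015) |
            ellipsoid(0.3, 0.15, 0.10, 0.12, 0.2, 0.015))
    place("et_region", ellipsoid(0, 0.3, 0.14 + g(0.005), 0.14, 0.25, 0.03, inner = 0.55))
    place("thyroid", ellipsoid(0, 0.12, 0.175 + g(0.003), 0.16, 0.22, 0.016))

    # thorax
    lungz <- 0.245 + g(0.005)
    place("lung",
          ellipsoid(-0.45, 0.05, lungz, 0.34, 0.62, 0.065) |
            ellipsoid(0.45, 0.05, lungz, 0.34, 0.62, 0.065))
    place("heart", ellipsoid(0.12, 0.25, 0.27 + g(0.004), 0.3, 0.42, 0.045, inner = 0.6))
    place("esophagus", ellipsoid(0, -0.25, 0.24, 0.07, 0.12, 0.075, inner = 0.5))
    place("breast",
          ellipsoid(-0.4, 0.75, 0.24, 0.26, 0.3, 0.035) |
            ellipsoid(0.4, 0.75, 0.24, 0.26, 0.3, 0.035))

    # abdomen
    place("liver", ellipsoid(-0.38 + g(), 0.12, 0.37 + g(0.004), 0.42, 0.58, 0.05))
    place("stomach", ellipsoid(0.3 + g(), 0.25, 0.365, 0.3, 0.4, 0.04, inner = 0.62))
    place("spleen", ellipsoid(0.55 + g(), -0.1, 0.375, 0.18, 0.3, 0.03))
    place("pancreas", ellipsoid(0.05, -0.05, 0.40, 0.3, 0.18, 0.02))
    place("kidney",
          ellipsoid(-0.42, -0.35, 0.425 + g(0.004), 0.16, 0.28, 0.035) |
            ellipsoid(0.42, -0.35, 0.425 + g(0.004), 0.16, 0.28, 0.035))
    place("adrenal_gland",
          ellipsoid(-0.42, -0.35, 0.385, 0.1, 0.18, 0.014) |
            ellipsoid(0.42, -0.35, 0.385, 0.1, 0.18, 0.014))
    place("gall_bladder", ellipsoid(-0.2, 0.42, 0.41, 0.12, 0.18, 0.018, inner = 0.5))
    place("small_intestine", ellipsoid(0 + g(), 0.15, 0.475, 0.42, 0.5, 0.04, inner = 0.45))
    place("colon", ellipsoid(0, 0.1, 0.475 + g(0.003), 0.58, 0.66, 0.055, inner = 0.75))

    # pelvis
    place("bladder", ellipsoid(0, 0.3, 0.575 + g(0.003), 0.22, 0.32, 0.025, inner = 0.55))
    place("uterus", ellipsoid(0, 0.05, 0.575, 0.2, 0.28, 0.022))
    place("prostate", ellipsoid(0, 0.15, 0.615, 0.14, 0.2, 0.016))
    if (patient$sex == "female") {
      place("gonads",
            ellipsoid(-0.25, 0.05, 0.56, 0.1, 0.16, 0.014) |
              ellipsoid(0.25, 0.05, 0.56, 0.1, 0.16, 0.014))
    } else {
      place("gonads", ellipsoid(0, 0.45, 0.655, 0.16, 0.3, 0.018))
    }
    # skeleton after the soft organs so that coarse grids keep the pelvic
    # organs; bone and marrow take the remaining frame voxels
    place("red_bone_marrow", (spine_in | pelvis_marrow))
    place("bone_surface", ((spine_out | skull_out) & !(spine_in | skull_in)) | pelvis_bone)

    place("lymph_nodes",
          ellipsoid(-0.55, 0.3, 0.52, 0.12, 0.2, 0.02) |
            ellipsoid(0.55, 0.3, 0.52, 0.12, 0.2, 0.02))

    # musculature: paraspinal columns along the trunk
    place("muscle",
          ellipsoid(-0.3, -0.62, 0.42, 0.16, 0.3, 0.14) |
            ellipsoid(0.3, -0.62, 0.42, 0.16, 0.3, 0.14))

    # skin: outermost body shell (trunk region), one-voxel rind
    shrink <- 1 - 2 * sp[1] / a
    core <- (X / (a * pmax(wf, 1e-6) * shrink))^2 +
      (Y / (b * pmax(wf, 1e-6) * shrink))^2 <= 1
    place("skin", body & !core & zf >= 0.17 & zf <= 0.62)

    missing <- setdiff(required, vocab$organ[vocab$label %in% unique(as.integer(labels))])
    if (length(missing)) {
      stop("resolution too small to place organ: ", paste(missing, collapse = ", "))
    }

    structure(
      list(hu = hu, labels = labels, spacing = sp,
           origin = c(cx[1], cy[1], cz[1]), patient = patient,
           omitted = omit),
      class = "voxel_phantom"
    )
  })
}

#' Organs present in a phantom label map
#' @param phantom A `voxel_phantom`.
#' @return Character vector of organ names present.
#' @export
phantom_organs <- function(phantom) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  vocab <- organ_vocabulary()
  vocab$organ[vocab$label %in% sort(unique(as.integer(phantom$labels)))]
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat("<voxel_phantom> ", paste(dim(x$hu), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 3), collapse = "/"),
      " mm\n", sep = "")
  cat("  patient: ", x$patient$id, " (", x$patient$sex, ", age ",
      x$patient$age, ", BMI ", x$patient$bmi, ")\n", sep = "")
  cat("  organs: ", length(phantom_organs(x)), "\n", sep = "")
  invisible(x)
}

#' Write a phantom to NIfTI volumes with a JSON vocabulary sidecar
#'
#' Writes `<prefix>_hu.nii.gz` (Hounsfield volume), `<prefix>_labels.nii.gz`
#' (unsigned integer organ labels) and `<prefix>_labels.json` (the organ
#' vocabulary and patient metadata).
#'
#' @param phantom A `voxel_phantom`.
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  paths <- paste0(prefix, c("_hu.nii.gz", "_labels.nii.gz", "_labels.json"))
  img_hu <- RNifti::asNifti(phantom$hu, pixdim = phantom$spacing)
  img_lab <- RNifti::asNifti(array(as.integer(phantom$labels),
                                   dim = dim(phantom$labels)),
                             pixdim = phantom$spacing, datatype = "uint16")
  RNifti::writeNifti(img_hu, paths[1])
  RNifti::writeNifti(img_lab, paths[2])
  vocab <- organ_vocabulary()
  meta <- list(
    vocabulary = stats::setNames(as.list(vocab$label), vocab$organ),
    patient = phantom$patient[c("id", "age", "sex", "height", "weight", "bmi")],
    spacing_mm = phantom$spacing, origin_mm = phantom$origin,
    omitted = phantom$omitted
  )
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a phantom written by [write_phantom()]
#' @param prefix Path prefix used when writing.
#' @return A `voxel_phantom`.
#' @export
read_phantom <- function(prefix) {
  paths <- paste0(prefix, c("_hu.nii.gz", "_labels.nii.gz", "_labels.json"))
  if (!all(file.exists(paths))) stop("phantom files not found for prefix ", prefix)
  hu <- array(as.numeric(RNifti::readNifti(paths[1])),
              dim = dim(RNifti::readNifti(paths[1])))
  lab_img <- RNifti::readNifti(paths[2])
  labels <- array(as.integer(lab_img), dim = dim(lab_img))
  meta <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  pat <- patient_record(
    id = meta$patient$id, age = meta$patient$age, sex = meta$patient$sex,
    height = meta$patient$height, weight = meta$patient$weight,
    bmi = meta$patient$bmi
  )
  structure(
    list(hu = hu, labels = labels, spacing = as.numeric(meta$spacing_mm),
         origin = as.numeric(meta$origin_mm), patient = pat,
         omitted = as.character(meta$omitted %||% character())),
    class = "voxel_phantom"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
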
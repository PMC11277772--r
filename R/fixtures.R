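#' Synthetic lung CT phantoms and planted feature tables
#'
#' The generators in this file provide the ground-truth test substrate for
#' the whole pipeline: 2-D grayscale "phantom" slices that mimic a lung CT
#' section (two dark lung fields on a brighter soft-tissue background) with
#' an optional nodule whose geometry differs by class, plus purely tabular
#' planted-feature datasets for exercising the feature-selection machinery.
#' All generators are pure functions of their arguments including the seed:
#' the same call yields bit-identical output.
#'
#' @name fixtures
NULL

#' Generate one synthetic lung phantom image
#'
#' Draws a `size` x `size` 8-bit grayscale slice containing two dark
#' elliptical lung fields on a brighter background plus additive Gaussian
#' noise.  For `label = "benign"` a smooth circular bright blob (diameter
#' drawn uniformly from 4-10 pixels) is placed inside a lung field; for
#' `label = "malignant"` a larger blob (12-25 pixels) with a radial
#' sinusoidal boundary perturbation (spiculation) and two or three
#' satellite lobes.  The annotation carries LIDC-style 1-5 ordinal scores
#' (margin, spiculation, lobulation, subtlety, malignancy) mapped
#' monotonically from the generating geometry, so by construction benign
#' nodules have spiculation score <= 2 and malignant ones >= 4.
#'
#' @param label one of `"normal"`, `"benign"`, `"malignant"`.
#' @param size image side length in pixels, at least 64.
#' @param seed integer seed; the generator is deterministic given
#'   `(label, size, seed)`.
#' @return a list with `image` (numeric matrix in \[0, 255\], attribute
#'   `bit_depth = 8`) and `annotation` (a `phantom_annotation` list; nodule
#'   fields are `NA` for normal slices).
#' @export
generate_phantom <- function(label, size = 128L, seed = 1L) {
  label <- match.arg(label, c("normal", "benign", "malignant"))
  if (size < 64) stop("`size` must be at least 64")
  set.seed(seed)

  bg <- 175
  img <- matrix(bg, size, size)
  rr <- row(img); cc <- col(img)

  # two dark elliptical lung fields
  cy <- size * 0.52
  for (cx in c(size * 0.30, size * 0.70)) {
    inside <- ((rr - cy) / (size * 0.33))^2 +
      ((cc - cx) / (size * 0.17))^2 <= 1
    img[inside] <- 60
  }

  ann <- list(label = label, diameter_mm = NA_real_, margin = NA_integer_,
              spiculation = NA_integer_, lobulation = NA_integer_,
              subtlety = NA_integer_, malignancy = NA_integer_,
              center_row = NA_real_, center_col = NA_real_, seed = seed)

  if (label != "normal") {
    side <- if (runif(1) < 0.5) 0.30 else 0.70
    ncy <- cy + runif(1, -0.12, 0.12) * size
    ncx <- size * side + runif(1, -0.06, 0.06) * size
    d <- if (label == "benign") runif(1, 4, 10) else runif(1, 12, 25)
    r0 <- d / 2
    amp <- runif(1, 70, 110)
    dist <- sqrt((rr - ncy)^2 + (cc - ncx)^2)

    if (label == "benign") {
      a <- runif(1, 0, 0.05) # essentially round
      img <- img + amp * exp(-(dist / r0)^2 * 1.5)
      lobes <- 0L
    } else {
      a <- runif(1, 0.25, 0.40) # strong spiculation
      kf <- sample(5:9, 1)
      phi <- runif(1, 0, 2 * pi)
      theta <- atan2(rr - ncy, cc - ncx)
      rt <- r0 * (1 + a * sin(kf * theta + phi))
      # heterogeneous interior (radial ripple): malignant lesions show
      # non-uniform attenuation, and the sharp spiculated rim plus the
      # ripple inject the high-frequency transitions typical of them
      inside <- dist <= rt
      img[inside] <- img[inside] +
        amp * (0.70 + 0.45 * sin(dist[inside] * 2.2))
      lobes <- sample(2:3, 1)
      for (lb in seq_len(lobes)) {
        ang <- runif(1, 0, 2 * pi)
        lcy <- ncy + 0.9 * r0 * sin(ang)
        lcx <- ncx + 0.9 * r0 * cos(ang)
        ld <- sqrt((rr - lcy)^2 + (cc - lcx)^2)
        lin <- ld <= r0 * 0.45
        img[lin] <- img[lin] + amp * 0.5 * (1 - ld[lin] / (r0 * 0.45))
      }
    }

    ann$diameter_mm <- d
    ann$center_row <- ncy
    ann$center_col <- ncx
    ann$spiculation <- if (label == "benign") {
      if (a < 0.025) 1L else 2L
    } else {
      if (a < 0.33) 4L else 5L
    }
    ann$margin <- if (label == "benign") {
      if (a < 0.025) 5L else 4L
    } else {
      if (a < 0.33) 2L else 1L
    }
    ann$lobulation <- if (label == "benign") {
      if (a < 0.025) 1L else 2L
    } else {
      lobes + 2L # 4 or 5
    }
    ann$subtlety <- as.integer(pmin(5, pmax(1, round(amp / 25))))
    ann$malignancy <- if (label == "benign") {
      if (d < 7) 1L else 2L
    } else {
      if (d < 18) 4L else 5L
    }
  }

  img <- img + rnorm(length(img), 0, 8)
  img <- pmin(pmax(img, 0), 255)
  attr(img, "bit_depth") <- 8L
  class(ann) <- "phantom_annotation"
  list(image = img, annotation = ann)
}

#' Generate a balanced phantom dataset
#'
#' Produces `3 * n_per_class` phantoms with labels cycling
#' normal/benign/malignant.  Per-item seeds are derived from the master
#' seed through a counter-based split, so extending the dataset never
#' reshuffles earlier items.
#'
#' @param n_per_class phantoms per class, at least 1.
#' @param size image side length, passed to [generate_phantom()].
#' @param seed master integer seed.
#' @return list with `images` (list of matrices) and `annotations`
#'   (list of `phantom_annotation`).
#' @export
generate_phantom_dataset <- function(n_per_class, size = 128L, seed = 1L) {
  if (n_per_class < 1) stop("`n_per_class` must be at least 1")
  labels <- rep(c("normal", "benign", "malignant"), n_per_class)
  out <- lapply(seq_along(labels), function(i) {
    generate_phantom(labels[i], size, derive_seed(seed, i))
  })
  list(images = lapply(out, `[[`, "image"),
       annotations = lapply(out, `[[`, "annotation"))
}

#' Generate a feature table with planted informative features
#'
#' Builds an `N` x `M` table with three balanced classes.  The first
#' `n_informative` features are drawn from class-shifted unit Gaussians
#' whose class means are `effect` standard deviations apart; the remaining
#' features are class-independent standard Gaussians (pure noise).  This
#' mirrors the screening problem of separating a handful of relevant
#' predictors from a sea of noisy ones.
#'
#' @param N number of samples (>= 20).
#' @param M total number of features.
#' @param n_informative number of class-informative features (1..M).
#' @param effect between-class mean separation in units of the feature
#'   standard deviation; 0 gives a pure-noise table.
#' @param seed integer seed.
#' @return a list of class `planted_table` with elements `table`
#'   (a `feature_table`: list of `features` matrix, `labels` integer vector
#'   in 1..3, `feature_names`), `informative_indices` and `noise_indices`.
#' @export
generate_feature_table <- function(N, M, n_informative, effect, seed = 1L) {
  if (n_informative > M) stop("`n_informative` must not exceed `M`")
  if (n_informative < 1) stop("`n_informative` must be at least 1")
  if (N < 20) stop("`N` must be at least 20")
  set.seed(seed)
  labels <- rep_len(1:3, N)
  X <- matrix(rnorm(N * M), N, M)
  for (j in seq_len(n_informative)) {
    X[, j] <- X[, j] + (labels - 2) * effect
  }
  tab <- feature_table(X, labels,
                       feature_names = sprintf("f%02d", seq_len(M)))
  structure(list(table = tab,
                 informative_indices = seq_len(n_informative),
                 noise_indices = setdiff(seq_len(M), seq_len(n_informative))),
            class = "planted_table")
}

#' Construct a feature table
#'
#' The common tabular container used by the selection and classification
#' stages: a numeric feature matrix, integer class labels in `1..c`, and
#' feature names.
#'
#' @param features numeric matrix, samples in rows.
#' @param labels integer class labels in `1..c`.
#' @param feature_names optional character vector, defaults to `V1..VM`.
#' @return a list of class `feature_table`.
#' @export
feature_table <- function(features, labels, feature_names = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels))
    stop("`features` and `labels` disagree on the number of samples")
  if (anyNA(features) || anyNA(labels)) stop("missing values not supported")
  if (length(unique(labels)) < 2) stop("need at least two classes")
  if (is.null(feature_names))
    feature_names <- sprintf("V%d", seq_len(ncol(features)))
  colnames(features) <- feature_names
  structure(list(features = features, labels = labels,
                 feature_names = feature_names),
            class = "feature_table")
}

#' Degrade an image into a low/high resolution training pair
#'
#' The high-resolution member is the input itself; the low-resolution
#' member is obtained by block-averaging `factor` x `factor` pixel blocks
#' and adding Gaussian noise, and is returned at the reduced size
#' (upscaling is the job of the enhancement network).
#'
#' @param image numeric matrix with dimensions divisible by `factor`.
#' @param factor integer downsampling factor, 2, 3 or 4.
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   the low-resolution member, in intensity units.
#' @param seed integer seed for the noise draw.
#' @return list with `low` (H/factor x W/factor) and `high` (the input).
#' @export
degrade_pair <- function(image, factor = 2L, noise_sd = 0, seed = 1L) {
  if (!factor %in% 2:4) stop("`factor` must be 2, 3 or 4")
  h <- nrow(image); w <- ncol(image)
  if (h %% factor != 0 || w %% factor != 0)
    stop("image dimensions must be divisible by `factor`")
  set.seed(seed)
  # block means via index folding
  low <- matrix(0, h / factor, w / factor)
  for (dr in seq_len(factor)) {
    for (dc in seq_len(factor)) {
      low <- low + image[seq(dr, h, by = factor), seq(dc, w, by = factor)]
    }
  }
  low <- low / factor^2
  if (noise_sd > 0) low <- low + rnorm(length(low), 0, noise_sd)
  attr(low, "bit_depth") <- attr(image, "bit_depth")
  list(low = low, high = image)
}

#' Write nodule annotation records to CSV
#'
#' Uses the standard candidate-annotation dialect: a header line exactly
#' `seriesuid,coordX,coordY,coordZ,diameter_mm` followed by one record per
#' line with world coordinates in millimetres.
#'
#' @param records data frame with columns `seriesuid`, `coordX`, `coordY`,
#'   `coordZ`, `diameter_mm`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path) {
  cols <- c("seriesuid", "coordX", "coordY", "coordZ", "diameter_mm")
  if (nrow(records) > 0 && !all(cols %in% names(records)))
    stop("records must carry columns ", paste(cols, collapse = ", "))
  lines <- paste(cols, collapse = ",")
  if (nrow(records) > 0) {
    body <- vapply(seq_len(nrow(records)), function(i) {
      sprintf("%s,%.6f,%.6f,%.6f,%.6f", records$seriesuid[i],
              records$coordX[i], records$coordY[i], records$coordZ[i],
              records$diameter_mm[i])
    }, character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read nodule annotation records from CSV
#'
#' Counterpart of [write_annotations()].  Malformed rows raise an error
#' naming the offending line number; a missing or wrong header raises a
#' format error.
#'
#' @param path CSV file path.
#' @return data frame with columns `seriesuid`, `coordX`, `coordY`,
#'   `coordZ`, `diameter_mm`.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  header <- "seriesuid,coordX,coordY,coordZ,diameter_mm"
  if (length(lines) == 0 || lines[1] != header)
    stop("annotation file must start with header '", header, "'")
  body <- lines[-1]
  body <- body[nzchar(body)]
  recs <- data.frame(seriesuid = character(0), coordX = numeric(0),
                     coordY = numeric(0), coordZ = numeric(0),
                     diameter_mm = numeric(0),
                     stringsAsFactors = FALSE)
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(parts) != 5)
      stop("parse error on line ", i + 1, ": expected 5 fields")
    nums <- suppressWarnings(as.numeric(parts[2:5]))
    if (anyNA(nums) || !nzchar(parts[1]))
      stop("parse error on line ", i + 1, ": non-numeric coordinate or ",
           "empty seriesuid")
    if (nums[4] <= 0)
      stop("parse error on line ", i + 1, ": diameter must be positive")
    recs[nrow(recs) + 1L, ] <- list(parts[1], nums[1], nums[2], nums[3],
                                    nums[4])
  }
  recs
}

#' Read and write grayscale images
#'
#' 8-bit images round-trip through grayscale PNG.  16-bit images (which
#' the PNG writer available here does not emit) round-trip through a
#' plain-text tab-separated grid carrying a one-line `# bit_depth` header.
#'
#' @param image numeric matrix with values in `[0, 2^bit_depth - 1]`.
#' @param path file path (`.png` or `.tsv`).
#' @param bit_depth 8 or 16.
#' @return `path` invisibly for the writer; a numeric matrix with a
#'   `bit_depth` attribute for the reader.
#' @export
write_gray_image <- function(image, path, bit_depth = 8L) {
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  peak <- 2^bit_depth - 1
  q <- round(pmin(pmax(image, 0), peak))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (bit_depth != 8L)
      stop("PNG output supports bit_depth = 8; use a .tsv path for 16-bit")
    png::writePNG(q / peak, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# bit_depth=%d", bit_depth), con)
    utils::write.table(q, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_gray_image
#' @export
read_gray_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3) x <- x[, , 1]
    img <- round(x * 255)
    attr(img, "bit_depth") <- 8L
    return(img)
  }
  first <- readLines(path, n = 1)
  bits <- as.integer(sub("# bit_depth=", "", first, fixed = TRUE))
  img <- as.matrix(utils::read.table(path, sep = "\t", skip = 1))
  dimnames(img) <- NULL
  attr(img, "bit_depth") <- bits
  img
}
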
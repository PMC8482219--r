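# Readers and writers: the annotated eye-tracking CSV schema, scene and run
# configuration files (YAML/JSON), fitted-model JSON and the deterministic
# fixture generator.
#
# CSV dialect: comma separated, dot decimal, header row, UTF-8. Pixel
# coordinates are 0-based with the origin at the top-left of the image or
# screen. Doubles are written with six decimal places, which makes
# write -> read -> write byte-stable.

.EYEINFO_NUM <- c("target_x", "target_y", "pupil_x", "pupil_y",
                  "ellipse_major", "ellipse_minor", "ellipse_angle",
                  as.vector(t(outer(paste0("glint", 1:4), c("_x", "_y"),
                                    paste0))))
.EYEINFO_COLS <- c("frame_number", "target_id", "timestamp", .EYEINFO_NUM)

#' Write records in the annotated eye-tracking CSV schema
#'
#' One row per video frame: frame number, target ID, timestamp (ms), viewed
#' target coordinates, pupil center, fitted-ellipse major/minor axes and
#' angle, and the four enumerated corneal reflections. Missing glints are
#' written as empty fields.
#'
#' @param records data frame with the schema columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_eyeinfo <- function(records, path) {
  miss <- setdiff(.EYEINFO_COLS, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  out <- records[, .EYEINFO_COLS]
  for (cl in .EYEINFO_NUM) {
    v <- out[[cl]]
    s <- sprintf("%.6f", v)
    s[is.na(v)] <- ""
    out[[cl]] <- s
  }
  out$frame_number <- sprintf("%d", as.integer(out$frame_number))
  out$target_id <- sprintf("%d", as.integer(out$target_id))
  out$timestamp <- sprintf("%.3f", out$timestamp)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(.EYEINFO_COLS, collapse = ","), con)
  writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con)
  invisible(path)
}

#' Read an annotated eye-tracking CSV file
#'
#' @param path input file.
#' @param column_map optional named character vector renaming file columns to
#'   schema names (`c(schema_name = "file_name")`), for datasets whose header
#'   spelling differs.
#' @return data frame of typed records (class `eyeinfo`); blank glint fields
#'   become `NA` (missing, not zero). Unknown columns are kept and flagged
#'   with a warning; malformed numeric fields raise an error naming the line.
#' @export
read_eyeinfo <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!is.null(column_map)) {
    for (i in seq_along(column_map)) {
      j <- match(column_map[[i]], names(df))
      if (!is.na(j)) names(df)[j] <- names(column_map)[i]
    }
  }
  miss <- setdiff(.EYEINFO_COLS, names(df))
  if (length(miss)) {
    stop("header does not match the annotated-CSV schema; missing: ",
         paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(df), .EYEINFO_COLS)
  if (length(extra)) {
    warning("unknown columns preserved as metadata: ",
            paste(extra, collapse = ", "))
  }
  for (cl in c("timestamp", .EYEINFO_NUM)) {
    v <- df[[cl]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !(v == "" | is.na(v)))
    if (length(bad)) {
      stop(sprintf("malformed value in column '%s' at line %d", cl,
                   bad[1] + 1L))
    }
    df[[cl]] <- num
  }
  for (cl in c("frame_number", "target_id")) {
    num <- suppressWarnings(as.integer(df[[cl]]))
    if (anyNA(num)) {
      stop(sprintf("malformed value in column '%s' at line %d", cl,
                   which(is.na(num))[1] + 1L))
    }
    df[[cl]] <- num
  }
  if (is.unsorted(df$timestamp)) {
    warning("timestamps are not non-decreasing")
  }
  class(df) <- c("eyeinfo", "data.frame")
  df
}

#' Convert annotated records to a feature set
#'
#' @param records an [read_eyeinfo()] data frame.
#' @return a `feature_set` (raw eye plane) keeping the glint columns.
#' @export
as_feature_set <- function(records) {
  feature_set(as.data.frame(records)[, c("target_id", "target_x", "target_y",
                                         "pupil_x", "pupil_y",
                                         grep("^glint", names(records),
                                              value = TRUE))])
}

#' Export a simulated feature set in the annotated CSV schema
#'
#' Converts metric image coordinates to image pixels using the camera's
#' `pixels_per_mm`/`image_center` and targets to screen pixels using the
#' screen's `pixel_pitch` (origin at the top-left of the target range, y
#' down), then writes one row per record. Ellipse annotations are synthetic
#' placeholders (the simulator does not render images).
#'
#' @param features a `feature_set` with a scene attached.
#' @param path output file.
#' @param fps frame rate used for frame numbers and timestamps.
#' @return `path`, invisibly.
#' @export
write_session_eyeinfo <- function(features, path, fps = 150) {
  stopifnot(inherits(features, "feature_set"))
  sc <- attr(features, "scene")
  if (is.null(sc)) stop("feature set has no scene; cannot convert units")
  rec <- .session_to_records(features, sc, fps = fps,
                             start_frame = 1L)
  write_eyeinfo(rec, path)
}

.image_to_px <- function(xy, camera) {
  s <- camera$pixels_per_mm
  if (is.null(s)) s <- 1
  cbind(camera$image_center[1] + s * xy[, 1],
        camera$image_center[2] - s * xy[, 2])
}

.screen_to_px <- function(xy, screen) {
  pitch <- screen$pixel_pitch
  if (is.null(pitch)) pitch <- 1
  cbind((xy[, 1] - screen$x_range[1]) / pitch,
        (screen$y_range[2] - xy[, 2]) / pitch)
}

.session_to_records <- function(features, sc, fps = 150, start_frame = 1L) {
  n <- nrow(features)
  pu <- .image_to_px(.fs_features(features), sc$camera)
  tg <- .screen_to_px(.fs_targets(features), sc$screen)
  rec <- data.frame(
    frame_number = seq.int(start_frame, length.out = n),
    target_id = features$target_id,
    timestamp = (seq.int(start_frame, length.out = n) - 1) / fps * 1000,
    target_x = tg[, 1], target_y = tg[, 2],
    pupil_x = pu[, 1], pupil_y = pu[, 2],
    ellipse_major = rep(60, n), ellipse_minor = rep(55, n),
    ellipse_angle = rep(0, n)
  )
  for (k in 1:4) {
    gx <- features[[paste0("glint", k, "_x")]]
    gy <- features[[paste0("glint", k, "_y")]]
    if (is.null(gx)) {
      gx <- rep(NA_real_, n)
      gy <- rep(NA_real_, n)
    } else {
      g <- .image_to_px(cbind(gx, gy), sc$camera)
      gx <- g[, 1]
      gy <- g[, 2]
    }
    rec[[paste0("glint", k, "_x")]] <- gx
    rec[[paste0("glint", k, "_y")]] <- gy
  }
  rec
}

#' Deterministic annotated-CSV fixtures
#'
#' Generates simulated sessions in the annotated CSV schema, mirroring the
#' real-data protocol: 35 targets in a 7 x 5 grid shown in sequence, 150
#' samples per target (5250 rows per session) with seeded Gaussian pixel
#' jitter, and a 3 x 3 calibration subset. Three sessions are written:
#' `clean.csv`, `missing_glints.csv` (a fraction of rows lose their glint
#' quad) and `outlier_trial.csv` (one target block carries a gross pupil
#' offset). Identical seeds give identical bytes.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the jitter.
#' @param samples_per_target raw samples per target (default 150).
#' @param jitter_px standard deviation of the pixel jitter.
#' @return named character vector of file paths.
#' @export
make_fixtures <- function(dir, seed = 1, samples_per_target = 150,
                          jitter_px = 0.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- fixture_scene()
  fs <- simulate_session(sc, targets = list(nx = 7, ny = 5))
  rec1 <- .session_to_records(fs, sc)
  set.seed(seed)
  expand <- function(base, spt, jit) {
    idx <- rep(seq_len(nrow(base)), each = spt)
    r <- base[idx, ]
    n <- nrow(r)
    r$frame_number <- seq_len(n)
    r$timestamp <- (seq_len(n) - 1) / 150 * 1000
    num <- c("pupil_x", "pupil_y",
             as.vector(t(outer(paste0("glint", 1:4), c("_x", "_y"),
                               paste0))))
    for (cl in num) r[[cl]] <- r[[cl]] + stats::rnorm(n, 0, jit)
    rownames(r) <- NULL
    r
  }
  clean <- expand(rec1, samples_per_target, jitter_px)
  paths <- c(clean = file.path(dir, "clean.csv"),
             missing_glints = file.path(dir, "missing_glints.csv"),
             outlier_trial = file.path(dir, "outlier_trial.csv"))
  write_eyeinfo(clean, paths[["clean"]])
  mg <- clean
  drop_rows <- sort(sample.int(nrow(mg), round(0.05 * nrow(mg))))
  gcols <- as.vector(t(outer(paste0("glint", 1:4), c("_x", "_y"), paste0)))
  mg[drop_rows, gcols] <- NA_real_
  write_eyeinfo(mg, paths[["missing_glints"]])
  ot <- clean
  bad_target <- 17L  # center of the 7 x 5 grid
  sel <- ot$target_id == bad_target
  ot$pupil_x[sel] <- ot$pupil_x[sel] + 80
  write_eyeinfo(ot, paths[["outlier_trial"]])
  paths
}

#' Scene mirroring the real remote eye-tracker rig
#'
#' A remote setup: the eye 550 mm from the screen, the eye-camera below the
#' screen about 20 cm from the eye, four LEDs at the screen corners, and
#' pixel conversions configured (0.27675 mm screen pitch; 180 px/mm sensor
#' scale on a 1600 x 1200 image).
#'
#' @return a [scene()].
#' @export
fixture_scene <- function() {
  scr <- screen_spec(pixel_pitch = 0.27675)
  scene(
    screen = scr,
    camera = camera_spec(position = c(0, 50, 380),
                         pixels_per_mm = 180, image_center = c(800, 600)),
    leds = corner_leds(scr),
    eye = eye_model()
  )
}

#' Read or write a scene configuration (YAML or JSON by extension)
#'
#' All lengths are millimetres and all angles degrees; every default is
#' materialized in the file so simulations are reproducible from the config
#' alone.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return a [scene()].
#' @export
read_scene <- function(path) {
  cfg <- .read_config(path)
  eye_args <- cfg$eye
  eye <- do.call(eye_model, lapply(eye_args, unlist))
  scr <- do.call(screen_spec, lapply(cfg$screen, unlist))
  cam <- do.call(camera_spec, lapply(cfg$camera, unlist))
  leds <- if (!is.null(cfg$leds)) {
    if (is.matrix(cfg$leds)) {
      cfg$leds
    } else {
      matrix(unlist(cfg$leds), ncol = 3, byrow = TRUE)
    }
  }
  scene(screen = scr, camera = cam, leds = leds, eye = eye)
}

#' @rdname read_scene
#' @param sc a [scene()].
#' @export
write_scene <- function(sc, path) {
  stopifnot(inherits(sc, "scene"))
  cfg <- list(
    units = list(length = "mm", angle = "degree"),
    screen = unclass(sc$screen),
    camera = unclass(sc$camera),
    leds = if (!is.null(sc$leds)) apply(sc$leds, 1, as.numeric,
                                        simplify = FALSE),
    eye = unclass(sc$eye)
  )
  cfg$eye$rotation_limits <- as.list(sc$eye$rotation_limits)
  .write_config(cfg, path)
  invisible(path)
}

.read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json: ", path)
  }
}

.write_config <- function(cfg, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(cfg, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  } else {
    stop("config must be .yaml, .yml or .json: ", path)
  }
}

#' Read a run configuration for [run_pipeline()]
#'
#' @param path YAML or JSON file.
#' @return list of configuration entries.
#' @export
read_run_config <- function(path) {
  cfg <- .read_config(path)
  if (!is.null(cfg$methods)) cfg$methods <- unlist(cfg$methods)
  if (!is.null(cfg$band)) cfg$band <- as.numeric(unlist(cfg$band))
  if (!is.null(cfg$sweep)) cfg$sweep <- lapply(cfg$sweep, unlist)
  if (!is.null(cfg$targets)) cfg$targets <- lapply(cfg$targets, unlist)
  cfg
}

#' Serialize a fitted mapping or distortion model to JSON
#'
#' Coefficients are written under their conventional names: `a0..a5`/`b0..b5`
#' for the second-order polynomial, the 3 x 3 matrix for a homography, and
#' `k1..k6`, `p1`, `p2`, `s1..s4` for the distortion model.
#'
#' @param m a `poly2_map`, `homography_map` or `distortion_model`.
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
write_model <- function(m, path) {
  obj <- if (inherits(m, "poly2_map")) {
    list(type = "poly2",
         a = as.list(stats::setNames(m$a, paste0("a", 0:5))),
         b = as.list(stats::setNames(m$b, paste0("b", 0:5))))
  } else if (inherits(m, "homography_map")) {
    list(type = "homography", H = unclass(as.matrix(m)))
  } else if (inherits(m, "distortion_model")) {
    list(type = "distortion", coefficients = as.list(coef(m)))
  } else {
    stop("unsupported model class")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read a fitted model written by [write_model()]
#'
#' @param path `.json` file.
#' @return the reconstructed model object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(obj$type,
    poly2 = structure(list(a = as.numeric(unlist(obj$a)),
                           b = as.numeric(unlist(obj$b)),
                           residual_rms = NA_real_),
                      class = "poly2_map"),
    homography = {
      H <- matrix(as.numeric(obj$H), 3, 3)
      structure(list(H = H / norm(H, "F"), residual_max = NA_real_),
                class = "homography_map")
    },
    distortion = {
      cf <- as.numeric(unlist(obj$coefficients))
      distortion_model(cf[1:6], cf[7:8], cf[9:12])
    },
    stop("unknown model type: ", obj$type)
  )
}
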
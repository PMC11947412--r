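# File formats: load-case CSV with a `# key=value` metadata block, apparatus
# YAML, registration and surface JSON/YAML, run configs. Numeric values are
# written with 17 significant digits so a write/read round trip is bitwise.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a load-case track to CSV
#'
#' Comma-separated, decimal point, with a metadata comment block
#' (`# adl=...`, `# frequency_hz=...`, `# frame=...`, `# periodised=...`)
#' and a mandatory header row. Values are written with enough digits that
#' reading the file back reproduces the track bitwise.
#'
#' @param track a [load_case_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_load_case_csv <- function(track, path) {
  stopifnot(inherits(track, "load_case_track"))
  df <- cbind(data.frame(time_s = track$time_s), track$channels)
  if (!is.null(track$extra)) df <- cbind(df, track$extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# adl=%s", track$adl),
               sprintf("# frequency_hz=%s", fmt_num(track$frequency_hz)),
               sprintf("# frame=%s", track$frame),
               sprintf("# periodised=%s", if (track$periodised) "true" else "false"),
               "# units=time_s:s,fe_deg:deg,ei_deg:deg,ml_N:N,ap_N:N,is_N:N,abad_Nm:Nm"),
             con)
  writeLines(paste(names(df), collapse = ","), con)
  body <- apply(vapply(df, fmt_num, character(nrow(df))), 1, paste,
                collapse = ",")
  writeLines(body, con)
  invisible(path)
}

#' Read a load-case track from CSV
#'
#' Counterpart of [write_load_case_csv()]. Malformed rows are rejected with
#' their line numbers; a semicolon-separated / comma-decimal dialect is
#' detected and rejected with a hint.
#'
#' @param path input path.
#' @return A [load_case_track()].
#' @export
read_load_case_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta_idx <- grepl("^#", lines)
  meta <- lines[meta_idx]
  body <- lines[!meta_idx]
  body_lineno <- which(!meta_idx)
  if (length(body) < 2) stop("no data rows in ", path)

  kv <- list()
  for (m in sub("^#\\s*", "", meta)) {
    if (grepl("=", m)) {
      k <- sub("=.*", "", m)
      kv[[trimws(k)]] <- trimws(sub("^[^=]*=", "", m))
    }
  }
  for (req in c("adl", "frequency_hz", "frame")) {
    if (is.null(kv[[req]])) {
      stop("metadata header block is missing '# ", req, "=...'")
    }
  }
  header <- body[1]
  if (grepl(";", header)) {
    stop("dialect error: file appears to be semicolon-separated ",
         "(comma-decimal locale?); expected comma separator with ",
         "decimal points")
  }
  cols <- strsplit(header, ",", fixed = TRUE)[[1]]
  missing <- setdiff(c("time_s", track_channel_names), cols)
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  bad_len <- which(lengths(rows) != length(cols))
  if (length(bad_len)) {
    stop("malformed row(s) at line(s) ",
         paste(body_lineno[-1][utils::head(bad_len, 5)], collapse = ", "),
         ": wrong field count")
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                ncol = length(cols), byrow = TRUE,
                dimnames = list(NULL, cols))
  bad_num <- which(apply(is.na(mat), 1, any))
  if (length(bad_num)) {
    stop("malformed row(s) at line(s) ",
         paste(body_lineno[-1][utils::head(bad_num, 5)], collapse = ", "),
         ": non-numeric field (comma-decimal values are not accepted; ",
         "use decimal points)")
  }
  df <- as.data.frame(mat)
  extra_cols <- setdiff(cols, c("time_s", track_channel_names))
  extra <- if (length(extra_cols)) df[extra_cols] else NULL
  load_case_track(adl = kv$adl, time_s = df$time_s,
                  channels = df[track_channel_names],
                  frequency_hz = as.numeric(kv$frequency_hz),
                  frame = kv$frame,
                  periodised = identical(kv$periodised, "true"),
                  extra = extra)
}

#' Write / read a ligament apparatus (YAML)
#'
#' Per strand: name, group, `origin_mm`, `insertion_mm`,
#' `stiffness_N_per_strain`, `reference_strain`; top level: `toe_strain`,
#' `strain_model`. On reading, a strand may alternatively quote
#' `stiffness_N_per_percent`, which is converted (x100) to N per unit
#' strain.
#'
#' @param app a [ligament_apparatus()].
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return `path` invisibly (write); a [ligament_apparatus()] (read).
#' @export
write_apparatus <- function(app, path) {
  stopifnot(inherits(app, "ligament_apparatus"))
  obj <- list(
    toe_strain = app$law$toe_strain,
    strain_model = app$law$strain_model,
    strands = lapply(unname(app$strands), function(s) {
      list(name = s$name, group = s$group, origin_mm = s$origin_mm,
           insertion_mm = s$insertion_mm,
           stiffness_N_per_strain = s$stiffness_N,
           reference_strain = s$reference_strain)
    }))
  write_config_file(obj, path)
  invisible(path)
}

#' @rdname write_apparatus
#' @export
read_apparatus <- function(path) {
  obj <- read_config_file(path)
  if (is.null(obj$strands)) stop("apparatus file has no 'strands' entry")
  law <- ligament_law(toe_strain = obj$toe_strain %||% 0.03,
                      strain_model = obj$strain_model %||% "blankevoort")
  strands <- lapply(obj$strands, function(s) {
    k <- s$stiffness_N_per_strain
    if (is.null(k) && !is.null(s$stiffness_N_per_percent)) {
      k <- 100 * s$stiffness_N_per_percent
    }
    if (is.null(k)) {
      stop(sprintf("strand '%s': no stiffness given", s$name))
    }
    ligament_strand(name = s$name, group = s$group,
                    origin_mm = as.numeric(s$origin_mm),
                    insertion_mm = as.numeric(s$insertion_mm),
                    stiffness_N = as.numeric(k),
                    reference_strain = as.numeric(s$reference_strain %||% 0))
  })
  ligament_apparatus(strands, law = law)
}

#' Write / read a frame registration (JSON or YAML)
#'
#' Serialised as `{rotation_axis, rotation_deg, origin_shift_mm,
#' source_frame, target_frame}`.
#'
#' @param reg a [frame_registration()].
#' @param path file path (`.json`, `.yaml` or `.yml`).
#' @return `path` invisibly (write); a [frame_registration()] (read).
#' @export
write_registration <- function(reg, path) {
  stopifnot(inherits(reg, "frame_registration"))
  aa <- axis_angle(reg$rotation)
  write_config_file(list(rotation_axis = aa$axis,
                         rotation_deg = aa$angle_deg,
                         origin_shift_mm = reg$origin_shift_mm,
                         source_frame = reg$source_frame,
                         target_frame = reg$target_frame), path)
  invisible(path)
}

#' @rdname write_registration
#' @export
read_registration <- function(path) {
  obj <- read_config_file(path)
  frame_registration(
    rotation = rotation_about_axis(as.numeric(obj$rotation_axis),
                                   as.numeric(obj$rotation_deg)),
    origin_shift_mm = as.numeric(obj$origin_shift_mm),
    source_frame = obj$source_frame %||% "source",
    target_frame = obj$target_frame %||% "target")
}

#' Write / read a contact surface (JSON or YAML)
#'
#' @param surface a [contact_surface()].
#' @param path file path.
#' @return `path` invisibly (write); a [contact_surface()] (read).
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "contact_surface"))
  obj <- list(femoral_radius_mm = surface$femoral_radius_mm,
              femoral_centers_mm = apply(surface$femoral_centers_mm, 1,
                                         identity, simplify = FALSE),
              tibial_type = surface$tibial_type,
              condyles = surface$condyles)
  if (surface$tibial_type == "dish") {
    obj$dish_radius_mm <- surface$dish_radius_mm
    obj$dish_centers_mm <- apply(surface$dish_centers_mm, 1, identity,
                                 simplify = FALSE)
  } else {
    obj$plane_y_mm <- surface$plane_y_mm
  }
  write_config_file(obj, path)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  obj <- read_config_file(path)
  contact_surface(
    femoral_radius_mm = as.numeric(obj$femoral_radius_mm),
    femoral_centers_mm = do.call(rbind, lapply(obj$femoral_centers_mm,
                                               as.numeric)),
    tibial_type = obj$tibial_type,
    dish_radius_mm = if (!is.null(obj$dish_radius_mm)) as.numeric(obj$dish_radius_mm),
    dish_centers_mm = if (!is.null(obj$dish_centers_mm)) {
      do.call(rbind, lapply(obj$dish_centers_mm, as.numeric))
    },
    plane_y_mm = if (!is.null(obj$plane_y_mm)) as.numeric(obj$plane_y_mm),
    condyles = unlist(obj$condyles))
}

write_config_file <- function(obj, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(obj, path, precision = 15L)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  }
}

#' Write simulation results (CSV) and run summary (JSON)
#'
#' @param result a [run_load_case()] result.
#' @param csv_path per-step results CSV path.
#' @param summary_path optional JSON run-summary path.
#' @return `csv_path`, invisibly.
#' @export
write_simulation_result <- function(result, csv_path, summary_path = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  utils::write.csv(result$steps, csv_path, row.names = FALSE)
  if (!is.null(summary_path)) {
    jsonlite::write_json(list(
      adl = result$adl, variant = result$variant,
      frequency_hz = result$frequency_hz,
      n_steps = nrow(result$steps),
      n_unconverged = result$n_unconverged,
      failed = result$failed,
      cycle_change = result$cycle_change,
      max_residual_force_N = max(result$steps$residual_force_N),
      max_residual_moment_Nm = max(result$steps$residual_moment_Nm)),
      summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
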
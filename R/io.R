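# rig_io_cli: readers/writers for marker captures (CSV/TRC), force records,
# surface coefficient tables, OBJ meshes, YAML configurations and trajectory
# outputs. CSV dialect: comma-separated, header row, '.' decimal, UTF-8.

#' Write a marker capture to CSV
#'
#' Wide layout: `time`, then `<label>_X/_Y/_Z` per marker. A comment line
#' records the declared units.
#'
#' @param capture a [marker_capture()].
#' @param path output file.
#' @param units `"mm"` or `"m"`; positions are converted on write.
#' @export
write_capture <- function(capture, path, units = c("mm", "m")) {
  units <- match.arg(units)
  scale <- if (units == "mm") 1000 else 1
  df <- data.frame(time = capture$times)
  for (lb in capture$labels) {
    P <- capture$positions[[lb]] * scale
    df[[paste0(lb, "_X")]] <- P[, 1]
    df[[paste0(lb, "_Y")]] <- P[, 2]
    df[[paste0(lb, "_Z")]] <- P[, 3]
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", units), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a marker capture (CSV or TRC)
#'
#' CSV files follow the dialect of [write_capture()]; `.trc` files use the
#' standard tab-separated motion-capture layout (read-only). Positions are
#' converted to meters regardless of the declared units.
#'
#' @param path input file.
#' @param units unit override; default: the declaration in the file
#'   (`# units:` comment or TRC header), else `"mm"`.
#' @param fs expected sampling rate (Hz), validated against the time stamps.
#' @return a [marker_capture()] (positions in m).
#' @export
read_capture <- function(path, units = NULL, fs = 100) {
  if (grepl("\\.trc$", path, ignore.case = TRUE))
    return(read_trc(path, units = units, fs = fs))
  first <- readLines(path, n = 1)
  skip <- 0
  if (grepl("^#", first)) {
    skip <- 1
    decl <- sub(".*units:\\s*", "", first)
    if (is.null(units)) units <- trimws(decl)
  }
  if (is.null(units)) units <- "mm"
  if (!units %in% c("mm", "m")) stop("unknown units: ", units)
  df <- read.csv(path, skip = skip, check.names = FALSE)
  if (!"time" %in% names(df)) stop("capture file has no 'time' column")
  times <- df$time
  if (length(times) >= 2 && max(abs(diff(times) - 1 / fs)) > 1e-6)
    stop("non-uniform sampling: time column is not a uniform grid at fs")
  cols <- setdiff(names(df), "time")
  labs <- unique(sub("_[XYZ]$", "", cols))
  need <- as.vector(outer(labs, c("_X", "_Y", "_Z"), paste0))
  if (!all(need %in% cols)) stop("missing coordinate columns for some markers")
  scale <- if (units == "mm") 1e-3 else 1
  positions <- lapply(labs, function(lb)
    cbind(df[[paste0(lb, "_X")]], df[[paste0(lb, "_Y")]],
          df[[paste0(lb, "_Z")]]) * scale)
  names(positions) <- labs
  marker_capture(times, positions, fs = fs)
}

# minimal TRC reader (tab-separated, standard 5 header rows)
read_trc <- function(path, units = NULL, fs = 100) {
  lines <- readLines(path)
  hdr <- strsplit(lines[3], "\t")[[1]]
  meta <- strsplit(lines[2], "\t")[[1]]
  iu <- match("Units", meta)
  if (is.null(units)) units <- if (!is.na(iu)) hdr[iu] else "mm"
  if (!units %in% c("mm", "m")) stop("unknown units: ", units)
  labels <- strsplit(lines[4], "\t")[[1]]
  labels <- labels[labels != ""][-(1:2)]          # drop Frame#, Time
  data <- do.call(rbind, lapply(lines[-(1:5)], function(l) {
    if (!nzchar(trimws(l))) return(NULL)
    as.numeric(strsplit(l, "\t")[[1]])
  }))
  times <- data[, 2]
  if (length(times) >= 2 && max(abs(diff(times) - 1 / fs)) > 1e-6)
    stop("non-uniform sampling in TRC file")
  scale <- if (units == "mm") 1e-3 else 1
  positions <- lapply(seq_along(labels), function(k)
    data[, (3 * (k - 1) + 3):(3 * (k - 1) + 5), drop = FALSE] * scale)
  names(positions) <- labels
  marker_capture(times, positions, fs = fs)
}

#' Write a force record to CSV
#' @param forces a [force_record()].
#' @param path output file.
#' @export
write_forces <- function(forces, path) {
  df <- data.frame(time = forces$times,
                   tibial_spring_N = forces$tibial_spring,
                   femoral_spring_N = forces$femoral_spring,
                   contact_N = forces$contact_normal)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a force record from CSV
#' @param path input file with columns `time`, `tibial_spring_N`,
#'   `femoral_spring_N`, `contact_N`.
#' @return a [force_record()].
#' @export
read_forces <- function(path) {
  df <- read.csv(path)
  need <- c("time", "tibial_spring_N", "femoral_spring_N", "contact_N")
  if (!all(need %in% names(df)))
    stop("force file must contain columns: ", paste(need, collapse = ", "))
  force_record(df$time, df$tibial_spring_N, df$femoral_spring_N, df$contact_N)
}

#' Write a polynomial surface coefficient table
#'
#' CSV with exponent columns `i`, `j` and `coefficient`; domain and R^2 are
#' stored in comment lines.
#'
#' @param surface a [polynomial_surface()].
#' @param path output file.
#' @export
write_surface <- function(surface, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  d <- surface$fit_domain
  writeLines(sprintf("# domain: %.17g %.17g %.17g %.17g", d[1], d[2], d[3], d[4]), con)
  if (is.finite(surface$r_squared))
    writeLines(sprintf("# r_squared: %.17g", surface$r_squared), con)
  idx <- which(outer(0:4, 0:4, "+") <= 4, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                   coefficient = surface$coefficients[idx])
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a polynomial surface coefficient table
#' @param path file written by [write_surface()].
#' @return a [polynomial_surface()].
#' @export
read_surface <- function(path) {
  lines <- readLines(path)
  dom_line <- grep("^# domain:", lines, value = TRUE)
  r2_line <- grep("^# r_squared:", lines, value = TRUE)
  if (!length(dom_line)) stop("surface file has no domain comment")
  dom <- as.numeric(strsplit(sub("^# domain:\\s*", "", dom_line[1]), "\\s+")[[1]])
  r2 <- if (length(r2_line))
    as.numeric(sub("^# r_squared:\\s*", "", r2_line[1])) else NA_real_
  df <- read.csv(path, comment.char = "#")
  C <- matrix(0, 5, 5)
  for (r in seq_len(nrow(df))) C[df$i[r] + 1, df$j[r] + 1] <- df$coefficient[r]
  polynomial_surface(C, dom, r_squared = r2)
}

#' Read a Wavefront OBJ triangle mesh
#'
#' ASCII `v`/`f` records only (polygonal faces are fan-triangulated); used
#' for oracle meshes.
#'
#' @param path .obj file.
#' @return list with `vertices` and `faces`.
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
    as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
    ids <- as.integer(sub("/.*", "", x[-1]))
    if (length(ids) < 3) stop("face with fewer than 3 vertices")
    cbind(ids[1], ids[2:(length(ids) - 1)], ids[3:length(ids)])
  }))
  list(vertices = verts, faces = faces)
}

#' Write a triangle mesh as Wavefront OBJ
#' @param mesh list with `vertices`, `faces`.
#' @param path output file.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Write / read a rig configuration (YAML)
#' @param config configuration list (see [rig_config()]).
#' @param path file path.
#' @export
write_rig_config <- function(config, path) {
  serial <- rapply(config, function(x) {
    if (is.matrix(x)) list(.matrix = dim(x), values = as.numeric(x)) else x
  }, classes = "matrix", how = "replace")
  yaml::write_yaml(serial, path, precision = 17)
  invisible(path)
}

#' @rdname write_rig_config
#' @return for `read_rig_config`, the configuration list.
#' @export
read_rig_config <- function(path) {
  raw <- yaml::read_yaml(path)
  restore <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$.matrix))
        return(matrix(as.numeric(unlist(x$values)), x$.matrix[[1]], x$.matrix[[2]]))
      return(lapply(x, restore))
    }
    x
  }
  restore(raw)
}

#' Write trajectory channels to CSV
#'
#' Columns: time, button center X/Y/Z in the femur frame, spring tensions,
#' contact normal force, knee flexion (deg).
#'
#' @param trajectory an `mbs_trajectory` from the leg model.
#' @param path output file.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the JSON run summary
#' @param summary named list (settings, diagnostics, events, seeds).
#' @param path output file.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
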
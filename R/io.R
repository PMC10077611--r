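# File interchange: landmarks (JSON), rim curves (CSV or JSON), and surface
# meshes (ASCII STL / OBJ / PLY, vertices only -- all the pipeline needs).

#' Read pelvic landmarks from JSON
#'
#' Expects a JSON object with keys `asis_left`, `asis_right`, `pubic_mid`,
#' `head_center_left`, `head_center_right`, each an `[x, y, z]` array in mm.
#'
#' @param path JSON file path.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("landmark file not found: ", path), class = "hipmorph_io")
  }
  obj <- jsonlite::fromJSON(path)
  need <- c("asis_left", "asis_right", "pubic_mid",
            "head_center_left", "head_center_right")
  missing <- setdiff(need, names(obj))
  if (length(missing)) {
    abort(paste0("landmark file ", path, " is missing keys: ",
                 paste(missing, collapse = ", ")), class = "hipmorph_schema")
  }
  do.call(landmark_set, obj[need])
}

#' @rdname read_landmarks
#' @param landmarks a [landmark_set()] to write.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(unclass(landmarks), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read an acetabular rim curve
#'
#' CSV files need an `x,y,z` header (mm); JSON files hold an array of
#' `[x, y, z]` points. Point order along the file is curve order.
#'
#' @param path rim file (`.csv` or `.json`).
#' @return A [rim_curve()].
#' @export
read_rim <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("rim file not found: ", path), class = "hipmorph_io")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    pts <- jsonlite::fromJSON(path)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
    if (!all(c("x", "y", "z") %in% names(df))) {
      abort(paste0("rim CSV ", path, " must have columns x, y, z"),
            class = "hipmorph_schema")
    }
    pts <- as.matrix(df[, c("x", "y", "z")])
  }
  rim_curve(pts)
}

#' @rdname read_rim
#' @param rim a [rim_curve()] to write (CSV with x,y,z header).
#' @export
write_rim <- function(rim, path) {
  readr::write_csv(tibble::as_tibble(`colnames<-`(rim$points, c("x", "y", "z"))), path)
  invisible(path)
}

#' Read surface-mesh vertices
#'
#' Minimal readers for ASCII STL (`vertex x y z` lines), OBJ (`v x y z`
#' lines), and ASCII PLY (header-declared vertex block). Only vertex
#' coordinates are returned; connectivity is not needed for sphere fitting.
#' STL vertices are de-duplicated (each vertex appears once per incident
#' facet in the format).
#'
#' @param path mesh file (`.stl`, `.obj`, `.ply`).
#' @return An n x 3 matrix of vertex coordinates (mm).
#' @export
read_mesh_vertices <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("mesh file not found: ", path), class = "hipmorph_io")
  }
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  pts <- switch(ext,
    stl = {
      vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
      if (!length(vl)) abort(paste0("no ASCII STL vertices in ", path), class = "hipmorph_io")
      m <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(tok) as.numeric(tok[2:4])))
      unique(m)
    },
    obj = {
      vl <- grep("^v\\s", lines, value = TRUE)
      if (!length(vl)) abort(paste0("no OBJ vertices in ", path), class = "hipmorph_io")
      do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                            function(tok) as.numeric(tok[2:4])))
    },
    ply = {
      if (!grepl("^ply", lines[1])) abort(paste0(path, " is not a PLY file"), class = "hipmorph_io")
      if (!any(grepl("format ascii", lines))) {
        abort(paste0("only ASCII PLY is supported: ", path), class = "hipmorph_io")
      }
      nvert <- as.integer(sub(".*element vertex\\s+(\\d+).*", "\\1",
                              grep("element vertex", lines, value = TRUE)[1]))
      start <- which(grepl("^end_header", lines))[1] + 1
      body <- lines[start:(start + nvert - 1)]
      do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                            function(tok) as.numeric(tok[1:3])))
    },
    abort(paste0("unsupported mesh format: .", ext), class = "hipmorph_io")
  )
  if (any(!is.finite(pts))) {
    abort(paste0("non-numeric vertex data in ", path), class = "hipmorph_io")
  }
  pts
}

# Write a tessellated sphere as ASCII STL (UV tessellation); used by the
# synthetic cohort writer and tests.
write_sphere_stl <- function(center, radius, path, n_theta = 18, n_phi = 36) {
  th <- seq(0, pi, length.out = n_theta + 1)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)
  pt <- function(i, j) {
    center + radius * c(sin(th[i]) * cos(ph[j]), sin(th[i]) * sin(ph[j]), cos(th[i]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid head", con)
  for (i in seq_len(n_theta)) {
    for (j in seq_len(n_phi)) {
      quad <- list(pt(i, j), pt(i + 1, j), pt(i + 1, j + 1), pt(i, j + 1))
      tris <- list(quad[c(1, 2, 3)], quad[c(1, 3, 4)])
      for (tri in tris) {
        nrm <- cross3(tri[[2]] - tri[[1]], tri[[3]] - tri[[1]])
        nn <- vnorm(nrm)
        if (nn < 1e-12) next  # degenerate pole quad
        nrm <- nrm / nn
        writeLines(sprintf("  facet normal %g %g %g", nrm[1], nrm[2], nrm[3]), con)
        writeLines("    outer loop", con)
        for (v in tri) writeLines(sprintf("      vertex %.9g %.9g %.9g", v[1], v[2], v[3]), con)
        writeLines("    endloop", con)
        writeLines("  endfacet", con)
      }
    }
  }
  writeLines("endsolid head", con)
  invisible(path)
}

#' Load a hip model from files
#'
#' Fits the head sphere to the mesh vertices (the mesh is assumed head-only),
#' loads and validates the rim and landmarks, and assembles a [hip_model()].
#' Validation failures (rim off the sphere, side mismatch, schema errors) are
#' raised with the offending rule and index.
#'
#' @param mesh_path surface mesh of the femoral head (STL/PLY/OBJ, mm).
#' @param landmarks_path landmark JSON (see [read_landmarks()]).
#' @param rim_path rim CSV/JSON (see [read_rim()]).
#' @param side,sex hip metadata.
#' @inheritParams hip_model
#' @return A [hip_model()].
#' @export
load_hip_model <- function(mesh_path, landmarks_path, rim_path, side,
                           sex = "unknown", hip_id = NULL, subject_id = NULL,
                           tol_rim = 0.02) {
  sphere <- fit_head_sphere(read_mesh_vertices(mesh_path))
  hip_model(side = side, sex = sex, sphere = sphere,
            rim = read_rim(rim_path), landmarks = read_landmarks(landmarks_path),
            hip_id = hip_id, subject_id = subject_id, mesh_ref = mesh_path,
            tol_rim = tol_rim)
}
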